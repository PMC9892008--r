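---
title: "Detecting strain sharing and transmissibility from per-species phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting strain sharing and transmissibility from per-species phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainshare)
```

## The model

Strain-level metagenomic profilers such as StrainPhlAn reconstruct, for
each species-level genome bin (SGB), a phylogeny of the dominant strains
across samples. `strainshare` turns those trees plus cohort metadata into
transmission inferences in four steps.

**1. Normalized phylogenetic distance.** For samples $x, y$ in the tree of
one species, the patristic distance $d(x,y)$ (sum of branch lengths on the
unique path) is normalized by the total branch length $L$ of that tree:
$\mathrm{nGD}(x,y) = d(x,y)/L$. Since any leaf-to-leaf path is a subset of
the tree's branches, $\mathrm{nGD} \in [0,1]$, and the quantity is
invariant to a uniform rescaling of branch lengths. The *centred* nGD
divides by the tree's median off-diagonal nGD, putting species with very
different overall diversities on a common scale (1 = a typical
inter-sample distance).

**2. Strain-identity thresholds.** Within an individual, a species' strain
usually persists for months, so the nGD distribution between two samples
of the same person taken close in time has a sharp peak near zero, while
unrelated individuals carry phylogenetically scattered strains. A
species-specific cutoff $t$ is placed between the two:

- *Youden calibration* (gut species with $\ge 50$ same-individual pairs
  taken $\le 183$ days apart, the closest-in-time pair per subject):
  candidate cutoffs are midpoints between consecutive sorted unique pooled
  distances plus one candidate below the minimum; among candidates at
  which at most 5% of unrelated pairs fall at/below $t$, the one
  maximizing $J = \mathrm{TPR} + \mathrm{TNR} - 1$ is chosen, ties going
  to the smallest cutoff. The bound caps the false-discovery side of
  downstream sharing calls; the below-minimum candidate makes the
  constrained search always feasible (it classifies nothing as shared).
- *Percentile fallback* (species with fewer longitudinal pairs, and all
  oral species, for which species-specific calibration is unreliable):
  the 3rd percentile of the unrelated nGD distribution, computed by
  linear interpolation between closest ranks (`quantile()` type 7). The
  default 3 is itself data-driven: `derive_fallback_percentile()` returns
  the median percentile at which the Youden cutoffs of well-sampled
  species sit.

Comparison is inclusive ($\mathrm{nGD} \le t$ means same strain), so a
threshold equal to an observed distance captures it; a strict mode is
available. Trees with zero total branch length are rejected rather than
producing 0/0 distances.

**3. Sharing calls and rates.** Strains nearly identical to genomes from
commercial fermented foods (SNV rate $\le 0.0015$, inclusive) are
discarded per species as plausibly diet-derived before any sharing
statistic. Sample-pair calls collapse to subject pairs by the
any-time-point rule: two subjects share a species' strain if *any*
cross-subject sample pair is at/below threshold. Per subject pair, the
strain-sharing rate is $100 \times$ shared strains / jointly
strain-profiled species, reported only when $\ge 10$ species are shared
(the gate is applied after food-strain exclusion, which removes the
excluded sample's strain profile). The offspring strain acquisition rate
is the fraction of the offspring's profiled species shared with the
mother, under the same $\ge 10$ gate. Relationship categories follow the
precedence mother_offspring > father_offspring > twins > partners >
siblings > household > same_village > same_population >
inter_population; subjects with unknown household are treated as
non-cohabiting (conservative for household inference), and "population"
means dataset.

**4. Transmissibility.** For a transmission mode — mother–infant
(offspring $\le 1$ y at sampling), household (cohabiting pairs),
intra-population (non-cohabiting, non-kin, same dataset) — a pair is a
*potential* event for a species when both subjects carry its strain
profile, and an *observed* event when the strain is shared.
Transmissibility = observed/potential, reported only at $\ge 10$
potential events for pooled estimates and $\ge 3$ for single-dataset
estimates (below the gate the value is missing, never zero). A species is
*highly transmitted* when transmissibility $> 0.5$, the within-group
proportion exceeds the among-group (unrelated-pair) proportion, and the
2×2 chi-squared test survives Benjamini–Hochberg correction at 0.05
across the species tested in that mode. Yates continuity correction is on
by default (the conventional default of R's `chisq.test`), and the
among-group baseline per mode is: unrelated mother × infant pairs within
a population (mother–infant), unrelated same-population pairs
(household), and inter-dataset pairs (intra-population). Cross-dataset
concordance uses Spearman correlation over species with assessed
transmissibility in both datasets ($\ge 10$ shared species).

Gut and oral samples are never mixed within a pair; the pipelines run
independently per body site.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fp_bound` | 0.05 | max fraction of unrelated pairs at/below a Youden threshold |
| `min_same_pairs` | 50 | same-individual pairs required for Youden calibration |
| `max_gap_days` | 183 | longitudinal pair gap limit (six months) |
| `fallback_percentile` | 3.0 | percentile of unrelated nGD for the fallback rule |
| `min_unrelated` | 34 | fallback sample-size floor (3rd percentile rests on an interior order statistic) |
| `food_max_snv` | 0.0015 | inclusive SNV-rate cutoff to food genomes (substitutions/site) |
| `min_shared_sgbs` | 10 | shared species required for a sharing/acquisition rate |
| `network_min_strains` | 5 | shared strains for a network edge (50 species for the species variant) |
| `min_potential` | 10 / 3 | potential events required, pooled / per-dataset |
| `alpha`, `t_min` | 0.05, 0.5 | highly-transmitted criteria |

## What the synthetic cohort emulates

The generator builds datasets of villages of households (families with
mother, father and offspring — infants through adults, occasionally
twins — plus adult twin pairs and single adults), gives an exact
fraction of subjects a second sample 30–183 days later, and emits one
Newick tree per species. Strain identity is planted as a partition:
per-relationship Bernoulli edges (probability by category, with an
optional per-species override of the mother–offspring probability that
plants species-specific transmissibility) are closed transitively by
union–find, so "same strain" is an equivalence relation by construction.
Each subject's samples inherit its class except that second samples
defect with probability $1 - p_{\text{retention}}$ (default retention
0.95). Trees join one backbone tip per class (random topology,
exponential branch lengths, mean 0.05) and attach class members with
exponential pendants (mean $10^{-4}$); the enforced pendant/backbone
ratio $\le 0.01$ produces the bimodal nGD structure the calibration
expects — a same-strain peak near zero under a broad unrelated bulk.
Food-origin strains attach beside food-reference leaves with SNV rates
$\le 0.0015$; FMT triads plant donor→post engraftment.

Default study conditions (frozen once): 2 datasets × 2 villages × 12
households (~210 samples), 20 species at 65% carriage, longitudinal
fraction 0.8 (the real calibration cohorts were longitudinal by design,
and this exercises both calibration paths), 30 FMT triads (a validation
set whose trees have diversity comparable to the cohort trees, so
absolute nGD thresholds transfer meaningfully). Planted category
probabilities are mother_offspring 0.50, father_offspring 0.30,
twins 0.30, siblings 0.25, partners 0.13, household 0.12,
village 0.015, population 0.005, inter-population 0. The village and
population values are deliberately below the sharing rates they induce:
transitive closure percolates pairwise edges through households into
larger components, so small planted probabilities already produce
village-level median sharing near 8% and a zero inter-population median.

What passing tests on these data do **not** show about real data: the
generator has no sequencing noise, no coverage-dependent profiling
dropout, no within-class phylogenetic substructure (pendants are i.i.d.),
perfectly known metadata, and same-strain/unrelated components far better
separated than for low-diversity species in practice. Threshold *quality*
on real trees (e.g. the published FMT recall of 0.97) cannot be
established here — only that the estimators recover what was planted and
that the calibration honours its false-positive bound.

## Numerical choices and degenerate inputs

- Candidate thresholds are midpoints of sorted unique pooled values, an
  equivalence-class representative insensitive to float noise; the
  search is $O(n \log n)$ via sorted-rank lookups.
- Percentiles use linear interpolation between closest ranks throughout
  (type 7), recorded here as the package's convention.
- Ties in J break toward the smaller threshold (conservative against
  false positives).
- Zero-margin 2×2 tables yield missing statistics with a message;
  constant transmissibility vectors yield missing Spearman rho.
- Unrelated-pair enumeration uses one sample per subject (seeded draw)
  to avoid pseudo-replicating longitudinal subjects, and pools datasets
  by default (the calibration design pooled several longitudinal
  datasets); a within-dataset mode is available.
- In `classify_all_pairs()` twins require both parental links equal and
  known plus equal recorded age; generated adult twin pairs without
  registered parents fall into the household category, which is also the
  planted probability they receive.

## Design choices on open points

- The FMT evaluation's default triad mapping covers donor and post-FMT
  samples; pre-FMT samples are excluded, since donor–pre pairs are
  neither same-individual nor donor→recipient pairs and would dilute
  recall by construction. The mapping argument of `fmt_validate()` makes
  any other policy a one-line change. In the full pipeline the FMT trees
  are validated against the cohort's calibrated thresholds (median
  threshold when the FMT species has none), which is the honest
  transfer-of-threshold test; on default synthetic conditions it yields
  recall near (not always exactly) 1, mirroring the fact that threshold
  transfer across trees is only as good as the match in tree diversity.
- The ≥10-shared-SGB gate counts species after food-strain exclusion.
- "Significantly higher" is a two-sided chi-squared plus an explicit
  direction check (within > among).

## Problem sizes used in the tests

The shipped suite runs the default ~210-sample study, a 400-family
mother–infant cohort for transmissibility recovery (planted 0.1/0.5/0.9
recovered within ±0.05 at 400 potential events), 1,000-tree and
1,000-table oracle comparisons, and 200 simulated null modes for type-I
control of the highly-transmitted flag. These sizes make the Monte-Carlo
tolerances quoted in the tests meaningful while keeping the whole suite
in the order of a couple of minutes.

## Known limitations

- nGD thresholds are transferable across trees only insofar as total
  branch length scales with true diversity; very small trees make the
  normalization noisy (the reason oral species and sparsely profiled
  species use the fallback rule).
- The generator plants strain identity as a hard partition; real
  strain boundaries are soft, so accuracy numbers here are upper bounds.
- Acquisition-rate direction (mother → offspring) is asserted from
  kinship metadata, not inferred from the data.
- Per-dataset transmissibility uses the household mode for concordance;
  datasets without enough assessed species are silently omitted, as the
  minimum-species rule dictates.
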