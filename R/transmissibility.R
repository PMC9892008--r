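#' Observed and potential strain-sharing events for one species and mode
#'
#' A subject pair is a *potential* transmission event for a species
#' when it belongs to the transmission mode and both subjects carry a
#' strain-level profile for the species; it is an *observed* event when
#' the strain is additionally called shared. Modes: `mother_infant`
#' (mother and her offspring up to one year of age), `household`
#' (cohabiting individuals), `intra_population` (non-cohabiting,
#' non-kin individuals of the same population/dataset).
#'
#' @param sgb_id Species id.
#' @param mode One of `"mother_infant"`, `"household"`,
#'   `"intra_population"`.
#' @param pairs Classified subject-pair table (from [classify_pairs()]
#'   applied to [pair_counts()] rows, or any table with `subject_a`,
#'   `subject_b`, `category`, `offspring_age_bin`).
#' @param subject_calls rbind of [collapse_to_subjects()] across
#'   species (`sgb_id`, `subject_a`, `subject_b`, `shared`).
#' @return list(n_events, n_potential).
#' @export
potential_events <- function(sgb_id, mode, pairs, subject_calls) {
  elig <- mode_eligible(pairs, mode)
  calls <- subject_calls[subject_calls$sgb_id == sgb_id, , drop = FALSE]
  if (nrow(elig) == 0L || nrow(calls) == 0L) {
    return(list(n_events = 0L, n_potential = 0L))
  }
  key <- function(d) paste(pmin(d$subject_a, d$subject_b),
                           pmax(d$subject_a, d$subject_b), sep = "\r")
  hit <- match(key(elig), key(calls))
  pot <- !is.na(hit)
  list(n_events = sum(calls$shared[hit[pot]]),
       n_potential = sum(pot))
}

# Mode eligibility from relationship categories. mother_infant uses the
# parent-offspring category restricted to offspring <=1y; household is
# any cohabiting pair (direct kin included); intra_population is
# same-dataset non-cohabiting non-kin.
mode_eligible <- function(pairs, mode) {
  mode <- match.arg(mode, c("mother_infant", "household", "intra_population"))
  sel <- switch(mode,
    mother_infant = pairs$category == "mother_offspring" &
      !is.na(pairs$offspring_age_bin) & pairs$offspring_age_bin == "<=1y",
    household = pairs$category %in% c("mother_offspring", "father_offspring",
                                      "twins", "partners", "siblings",
                                      "household"),
    intra_population = pairs$category %in% c("same_village", "same_population")
  )
  pairs[sel, , drop = FALSE]
}

#' Transmissibility ratio with a minimum-evidence gate
#'
#' Transmissibility = observed / potential strain-sharing events. To
#' avoid unstable ratios it is reported as missing unless the number of
#' potential events reaches the scope minimum: 10 for pooled
#' multi-dataset estimates, 3 for single-dataset estimates.
#'
#' @param n_events,n_potential Non-negative integers.
#' @param min_potential Scope minimum (10 pooled / 3 single-dataset).
#' @return Ratio in \[0, 1\] or `NA`.
#' @export
compute_transmissibility <- function(n_events, n_potential, min_potential) {
  if (n_events > n_potential) stop("more events than potential events")
  if (n_potential < min_potential) return(NA_real_)
  n_events / n_potential
}

#' Chi-squared test on a 2x2 transmission table
#'
#' Pearson chi-squared (1 d.f.) comparing transmitted vs non-transmitted
#' counts between within-group pairs (e.g. true mother-infant pairs) and
#' among-group pairs (e.g. unrelated mother-infant pairs), with Yates
#' continuity correction by default.
#'
#' @param a,b Within-group events / non-events.
#' @param c_,d_ Among-group events / non-events.
#' @param continuity Apply Yates correction (default TRUE).
#' @return list(statistic, p_value); both `NA` (with a message) when a
#'   table margin is zero.
#' @export
chi2_2x2 <- function(a, b, c_, d_, continuity = TRUE) {
  tab <- matrix(c(a, b, c_, d_), nrow = 2L, byrow = TRUE)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    message("zero margin in 2x2 table; chi-squared undefined")
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = continuity))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Per-species transmissibility table for one mode
#'
#' Computes, for every species, the within-group transmissibility and
#' an among-group baseline, plus the chi-squared comparison between
#' them. Among-group pairs represent the same kind of comparison
#' without the relationship: unrelated mother x infant pairs within a
#' dataset for `mother_infant`; same-population different-household
#' pairs for `household`; inter-dataset pairs for `intra_population`.
#'
#' @param sgb_ids Species to assess.
#' @param mode Transmission mode.
#' @param pairs Classified pair table (all subject pairs with
#'   categories).
#' @param subject_calls rbind of subject-level calls across species.
#' @param min_potential Minimum potential events (default 10, pooled
#'   scope).
#' @param scope Label recorded in the output (default `"all"`).
#' @param continuity Yates correction for the chi-squared (default
#'   TRUE).
#' @return data.frame, one row per species: event/potential counts and
#'   transmissibility for within and among groups, `chi2_stat`,
#'   `p_value`.
#' @param subjects Optional per-subject table ([subject_table()]); when
#'   given, the `mother_infant` baseline is restricted to unrelated
#'   mother x infant pairs.
#' @export
transmissibility_table <- function(sgb_ids, mode, pairs, subject_calls,
                                   min_potential = 10L, scope = "all",
                                   continuity = TRUE, subjects = NULL) {
  among <- among_group_pairs(pairs, mode, subjects)
  rows <- lapply(sgb_ids, function(sgb) {
    w <- potential_events(sgb, mode, pairs, subject_calls)
    a <- .count_events(sgb, among, subject_calls)
    tw <- compute_transmissibility(w$n_events, w$n_potential, min_potential)
    ta <- compute_transmissibility(a$n_events, a$n_potential, min_potential)
    ch <- if (!is.na(tw) && !is.na(ta)) {
      chi2_2x2(w$n_events, w$n_potential - w$n_events,
               a$n_events, a$n_potential - a$n_events,
               continuity = continuity)
    } else list(statistic = NA_real_, p_value = NA_real_)
    data.frame(sgb_id = sgb, mode = mode, scope = scope,
               n_events = w$n_events, n_potential = w$n_potential,
               transmissibility = tw,
               among_events = a$n_events, among_potential = a$n_potential,
               among_transmissibility = ta,
               chi2_stat = ch$statistic, p_value = ch$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Among-group ("unrelated") comparison pairs per mode, built from
# relationship categories already computed on all pairs. With a subject
# table available, the mother_infant baseline is narrowed to unrelated
# mother x infant pairs within a population; otherwise (and for
# household) unrelated same-population pairs serve as the baseline, and
# for intra_population the baseline is inter-dataset pairs.
among_group_pairs <- function(pairs, mode, subjects = NULL) {
  mode <- match.arg(mode, c("mother_infant", "household", "intra_population"))
  sel <- switch(mode,
    mother_infant = pairs$category %in% c("same_village", "same_population"),
    household = pairs$category %in% c("same_village", "same_population"),
    intra_population = pairs$category == "inter_population"
  )
  out <- pairs[sel, , drop = FALSE]
  if (mode == "mother_infant" && !is.null(subjects)) {
    is_mother <- subjects$subject_id %in% stats::na.omit(subjects$mother_id)
    names(is_mother) <- subjects$subject_id
    age <- structure(subjects$age_years, names = subjects$subject_id)
    infant <- !is.na(age) & age <= 1
    mi <- (is_mother[out$subject_a] & infant[out$subject_b]) |
          (is_mother[out$subject_b] & infant[out$subject_a])
    out <- out[mi, , drop = FALSE]
  }
  out
}

.count_events <- function(sgb_id, elig, subject_calls) {
  calls <- subject_calls[subject_calls$sgb_id == sgb_id, , drop = FALSE]
  if (nrow(elig) == 0L || nrow(calls) == 0L) {
    return(list(n_events = 0L, n_potential = 0L))
  }
  key <- function(d) paste(pmin(d$subject_a, d$subject_b),
                           pmax(d$subject_a, d$subject_b), sep = "\r")
  hit <- match(key(elig), key(calls))
  pot <- !is.na(hit)
  list(n_events = sum(calls$shared[hit[pot]]), n_potential = sum(pot))
}

#' Flag highly transmitted species
#'
#' A species is highly transmitted in a mode when (1) its within-group
#' transmissibility exceeds `t_min` (default 0.5), (2) the within-group
#' proportion exceeds the among-group proportion, and (3) the
#' chi-squared comparison is significant after Benjamini-Hochberg
#' correction across all species tested in the mode
#' (`p_adj < alpha`, default 0.05).
#'
#' @param tab Output of [transmissibility_table()].
#' @param alpha Adjusted significance level (default 0.05).
#' @param t_min Transmissibility cutoff (default 0.5).
#' @return `tab` with added `p_adj` and `highly_transmitted` columns
#'   (`NA` flag where the among-group baseline is missing).
#' @export
flag_highly_transmitted <- function(tab, alpha = 0.05, t_min = 0.5) {
  tab$p_adj <- stats::p.adjust(tab$p_value, method = "BH")
  flag <- tab$transmissibility > t_min &
    tab$transmissibility > tab$among_transmissibility &
    tab$p_adj < alpha
  flag[is.na(tab$among_transmissibility)] <- NA
  flag[is.na(tab$transmissibility)] <- NA
  tab$highly_transmitted <- flag
  tab
}

#' Cross-dataset concordance of transmissibility
#'
#' Spearman rank correlation of per-species transmissibility between
#' every pair of datasets sharing at least `min_sgbs` species with a
#' non-missing estimate in both.
#'
#' @param per_dataset Named list: dataset_id -> data.frame with
#'   `sgb_id`, `transmissibility`.
#' @param min_sgbs Minimum shared assessed species (default 10).
#' @return data.frame `dataset_a`, `dataset_b`, `n_sgbs`, `rho`, `p`;
#'   pairs below the minimum are omitted; constant vectors give `NA`
#'   rho with a message.
#' @export
dataset_concordance <- function(per_dataset, min_sgbs = 10L) {
  ds <- names(per_dataset)
  if (length(ds) < 2L) stop("need at least two datasets")
  rows <- list()
  for (i in seq_len(length(ds) - 1L)) {
    for (j in seq.int(i + 1L, length(ds))) {
      a <- per_dataset[[ds[i]]]; b <- per_dataset[[ds[j]]]
      a <- a[!is.na(a$transmissibility), ]
      b <- b[!is.na(b$transmissibility), ]
      common <- intersect(a$sgb_id, b$sgb_id)
      if (length(common) < min_sgbs) next
      va <- a$transmissibility[match(common, a$sgb_id)]
      vb <- b$transmissibility[match(common, b$sgb_id)]
      if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
        message("constant transmissibility vector for ", ds[i], " vs ", ds[j])
        rows[[length(rows) + 1L]] <- data.frame(
          dataset_a = ds[i], dataset_b = ds[j], n_sgbs = length(common),
          rho = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(stats::cor.test(va, vb, method = "spearman"))
      rows[[length(rows) + 1L]] <- data.frame(
        dataset_a = ds[i], dataset_b = ds[j], n_sgbs = length(common),
        rho = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(dataset_a = character(), dataset_b = character(),
                      n_sgbs = integer(), rho = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
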