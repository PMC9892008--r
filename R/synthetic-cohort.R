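#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates all knobs of the synthetic study: cohort
#' structure (datasets, villages, households, kinship, longitudinal
#' sampling), per-relationship planted strain-sharing probabilities,
#' per-species carriage and transmissibility, tree branch-length
#' scales, food-origin strains and FMT triads. The generated data
#' emulate the bimodal per-species nGD structure seen in real strain
#' profiles: a tight same-strain peak near zero against a broad
#' unrelated bulk.
#'
#' @param seed Integer seed; every downstream draw derives from it.
#' @param n_datasets Number of datasets (populations).
#' @param villages_per_dataset Villages within each dataset.
#' @param households_per_village Households within each village.
#' @param longitudinal_fraction Exact fraction of subjects given a
#'   second sample within `max_gap_days`.
#' @param max_gap_days Longitudinal gap limit in days (default 183).
#' @param n_sgbs Number of species (SGBs) to simulate.
#' @param carriage_prob Per-subject, per-species probability of
#'   carrying a strain profile.
#' @param sharing_prob Named vector of planted sharing probabilities by
#'   relationship category (plus `same_individual` retention across the
#'   longitudinal pair).
#' @param per_sgb_transmissibility Optional numeric vector (length
#'   `n_sgbs`) overriding the `mother_offspring` probability per
#'   species; this is the planted species transmissibility for the
#'   mother-infant mode.
#' @param same_strain_scale Mean pendant branch length of samples
#'   within a strain class (substitutions/site).
#' @param backbone_scale Mean branch length of the between-strain
#'   backbone; the ratio `same_strain_scale / backbone_scale` must be
#'   at most 0.01 so planted same-strain distances stay well below
#'   unrelated ones.
#' @param food_sgb_fraction Fraction of species carrying food-reference
#'   genomes.
#' @param food_fraction Fraction of a food species' carrier samples
#'   planted as food-origin strains.
#' @param n_food_refs Food-reference genomes per food species.
#' @param fmt_triads Number of FMT triads for [generate_fmt_triads()].
#' @param engraftment_prob Probability a donor strain engrafts in the
#'   post-FMT sample.
#' @param body_site `"gut"` or `"oral"` stamped on all samples.
#' @return Validated list of class `sim_config`.
#' @export
simulation_config <- function(seed,
                              n_datasets = 2L,
                              villages_per_dataset = 2L,
                              households_per_village = 12L,
                              longitudinal_fraction = 0.8,
                              max_gap_days = 183L,
                              n_sgbs = 20L,
                              carriage_prob = 0.65,
                              sharing_prob = c(same_individual = 0.95,
                                               mother_offspring = 0.50,
                                               father_offspring = 0.30,
                                               twins = 0.30,
                                               partners = 0.13,
                                               siblings = 0.25,
                                               household = 0.12,
                                               same_village = 0.015,
                                               same_population = 0.005,
                                               inter_population = 0.0),
                              per_sgb_transmissibility = NULL,
                              same_strain_scale = 1e-4,
                              backbone_scale = 0.05,
                              food_sgb_fraction = 0.25,
                              food_fraction = 0.08,
                              n_food_refs = 2L,
                              fmt_triads = 30L,
                              engraftment_prob = 1.0,
                              body_site = "gut") {
  cfg <- list(seed = as.integer(seed), n_datasets = as.integer(n_datasets),
              villages_per_dataset = as.integer(villages_per_dataset),
              households_per_village = as.integer(households_per_village),
              longitudinal_fraction = longitudinal_fraction,
              max_gap_days = as.integer(max_gap_days),
              n_sgbs = as.integer(n_sgbs), carriage_prob = carriage_prob,
              sharing_prob = sharing_prob,
              per_sgb_transmissibility = per_sgb_transmissibility,
              same_strain_scale = same_strain_scale,
              backbone_scale = backbone_scale,
              food_sgb_fraction = food_sgb_fraction,
              food_fraction = food_fraction,
              n_food_refs = as.integer(n_food_refs),
              fmt_triads = as.integer(fmt_triads),
              engraftment_prob = engraftment_prob,
              body_site = body_site)
  stopifnot(cfg$n_datasets >= 1L, cfg$villages_per_dataset >= 1L,
            cfg$households_per_village >= 1L, cfg$n_sgbs >= 1L)
  if (any(cfg$sharing_prob < 0 | cfg$sharing_prob > 1)) {
    stop("sharing probabilities must lie in [0, 1]")
  }
  req <- c("same_individual", "mother_offspring", "father_offspring",
           "twins", "partners", "siblings", "household", "same_village",
           "same_population", "inter_population")
  miss <- setdiff(req, names(cfg$sharing_prob))
  if (length(miss)) stop("sharing_prob missing: ", paste(miss, collapse = ", "))
  if (!is.null(cfg$per_sgb_transmissibility)) {
    stopifnot(length(cfg$per_sgb_transmissibility) == cfg$n_sgbs,
              all(cfg$per_sgb_transmissibility >= 0),
              all(cfg$per_sgb_transmissibility <= 1))
  }
  if (cfg$same_strain_scale / cfg$backbone_scale > 0.01) {
    stop("same_strain_scale / backbone_scale must be <= 0.01 ",
         "to keep planted same-strain distances separated")
  }
  if (cfg$longitudinal_fraction < 0 || cfg$longitudinal_fraction > 1) {
    stop("longitudinal_fraction must lie in [0, 1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic cohort metadata table
#'
#' Builds subjects organised into datasets, villages and households.
#' Household composition is drawn from a fixed mix: families (mother,
#' father, one or two offspring with ages spanning infancy to
#' adulthood, occasionally twin offspring), adult twin pairs, and
#' single adults. A fixed quota of subjects (exact, not Bernoulli)
#' receives a second sample 30 days to `max_gap_days` after the first.
#' Deterministic given the configuration seed.
#'
#' @param config `sim_config` object.
#' @return Sample metadata data.frame in the [read_metadata()] layout.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  subj <- list()
  add <- function(id, ds, hh, vil, age, mom = NA_character_,
                  dad = NA_character_) {
    subj[[length(subj) + 1L]] <<- data.frame(
      subject_id = id, dataset_id = ds, household_id = hh, village_id = vil,
      age_years = age, mother_id = mom, father_id = dad,
      stringsAsFactors = FALSE)
  }
  offspring_ages <- c(0.5, 0.8, 2, 8, 16, 25)
  offspring_wts <- c(0.3, 0.2, 0.1, 0.15, 0.1, 0.15)
  for (d in seq_len(config$n_datasets)) {
    ds <- sprintf("D%02d", d)
    for (v in seq_len(config$villages_per_dataset)) {
      vil <- sprintf("%s_V%02d", ds, v)
      for (h in seq_len(config$households_per_village)) {
        hh <- sprintf("%s_H%03d", vil, h)
        type <- sample(c("family", "adult_twins", "single"), 1L,
                       prob = c(0.6, 0.15, 0.25))
        if (type == "family") {
          mom <- paste0(hh, "_mother"); dad <- paste0(hh, "_father")
          add(mom, ds, hh, vil, round(stats::runif(1, 25, 40), 1))
          add(dad, ds, hh, vil, round(stats::runif(1, 27, 45), 1))
          n_off <- sample(1:2, 1L)
          twin_off <- n_off == 2L && stats::runif(1) < 0.3
          age1 <- sample(offspring_ages, 1L, prob = offspring_wts)
          for (k in seq_len(n_off)) {
            age <- if (twin_off) age1 else if (k == 1L) age1 else
              sample(offspring_ages, 1L, prob = offspring_wts)
            add(sprintf("%s_child%d", hh, k), ds, hh, vil, age, mom, dad)
          }
        } else if (type == "adult_twins") {
          # cohabiting adult twins; their parents are outside the study
          # so no parental links are recorded (classified as household)
          age <- round(stats::runif(1, 20, 60), 1)
          add(sprintf("%s_twinA", hh), ds, hh, vil, age)
          add(sprintf("%s_twinB", hh), ds, hh, vil, age)
        } else {
          add(paste0(hh, "_adult"), ds, hh, vil,
              round(stats::runif(1, 20, 70), 1))
        }
      }
    }
  }
  subjects <- do.call(rbind, subj)
  n <- nrow(subjects)
  # exact longitudinal quota
  n_long <- floor(config$longitudinal_fraction * n)
  long_idx <- sample.int(n, n_long)
  rows <- list()
  for (i in seq_len(n)) {
    s <- subjects[i, ]
    day0 <- sample.int(100L, 1L) - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0(s$subject_id, "_t0"), subject_id = s$subject_id,
      dataset_id = s$dataset_id, body_site = config$body_site,
      collection_day = day0, age_years = s$age_years,
      household_id = s$household_id, village_id = s$village_id,
      mother_id = s$mother_id, father_id = s$father_id,
      westernized = s$dataset_id %in% sprintf("D%02d",
        seq(1L, config$n_datasets, by = 2L)),
      stringsAsFactors = FALSE)
    if (i %in% long_idx) {
      gap <- sample(30:config$max_gap_days, 1L)
      r <- rows[[length(rows)]]
      r$sample_id <- paste0(s$subject_id, "_t1")
      r$collection_day <- day0 + gap
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_metadata(out)
}

# Twin detection in the generated cohorts relies on shared parental
# links; adult twin pairs without registered parents land in the
# "household" category, which is the planted probability they receive.

#' Vectorized relationship classification of all subject pairs
#'
#' Same precedence rules as [classify_pair()], applied to every
#' unordered subject pair at once.
#'
#' @param subjects Per-subject table from [subject_table()].
#' @return data.frame `subject_a`, `subject_b`, `category`,
#'   `offspring_age_bin`.
#' @export
classify_all_pairs <- function(subjects) {
  n <- nrow(subjects)
  if (n < 2L) {
    return(data.frame(subject_a = character(), subject_b = character(),
                      category = character(),
                      offspring_age_bin = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- utils::combn(n, 2L)
  a <- idx[1L, ]; b <- idx[2L, ]
  id <- subjects$subject_id; mom <- subjects$mother_id
  dad <- subjects$father_id; hh <- subjects$household_id
  vil <- subjects$village_id; ds <- subjects$dataset_id
  age <- subjects$age_years
  eq <- function(x, y) !is.na(x) & !is.na(y) & x == y
  mo <- eq(mom[a], id[b]) | eq(mom[b], id[a])
  fo <- eq(dad[a], id[b]) | eq(dad[b], id[a])
  tw <- eq(mom[a], mom[b]) & eq(dad[a], dad[b]) & eq(age[a], age[b])
  couple_key <- paste(mom, dad, sep = "\r")
  couple_key <- couple_key[!is.na(mom) & !is.na(dad)]
  pr <- paste(id[a], id[b], sep = "\r") %in% couple_key |
        paste(id[b], id[a], sep = "\r") %in% couple_key
  sib <- eq(mom[a], mom[b]) | eq(dad[a], dad[b])
  hhp <- eq(hh[a], hh[b])
  vlp <- eq(vil[a], vil[b])
  dsp <- eq(ds[a], ds[b])
  category <- rep("inter_population", length(a))
  category[dsp] <- "same_population"
  category[vlp] <- "same_village"
  category[hhp] <- "household"
  category[sib] <- "siblings"
  category[pr] <- "partners"
  category[tw] <- "twins"
  category[fo] <- "father_offspring"
  category[mo] <- "mother_offspring"
  off_age <- rep(NA_real_, length(a))
  par_off <- mo | fo
  child_is_a <- eq(mom[a], id[b]) | eq(dad[a], id[b])
  off_age[par_off] <- ifelse(child_is_a[par_off], age[a][par_off],
                             age[b][par_off])
  bin <- rep(NA_character_, length(a))
  bin[!is.na(off_age) & off_age <= 1] <- "<=1y"
  bin[!is.na(off_age) & off_age > 1 & off_age <= 3] <- "1-3y"
  bin[!is.na(off_age) & off_age > 3 & off_age <= 18] <- "3-18y"
  bin[!is.na(off_age) & off_age > 18 & off_age <= 30] <- "18-30y"
  bin[!is.na(off_age) & off_age >= 50 & off_age <= 85] <- "50-85y"
  bin[!par_off] <- NA_character_
  data.frame(subject_a = id[a], subject_b = id[b], category = category,
             offspring_age_bin = bin, stringsAsFactors = FALSE)
}

# ---- union-find over planted sharing edges --------------------------------

.uf_new <- function(n) seq_len(n)
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
.uf_union <- function(parent, i, j) {
  ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}
.uf_roots <- function(parent) {
  vapply(seq_along(parent), function(i) .uf_find(parent, i), integer(1))
}

#' Generate per-species trees with planted strain sharing
#'
#' For each species: carriers are drawn per subject; planted sharing
#' edges are drawn per subject pair from the per-relationship
#' probabilities (the `mother_offspring` probability can be overridden
#' per species by `per_sgb_transmissibility`, planting species-specific
#' transmissibility); a union-find over the edges yields strain
#' classes, so "same strain" is transitive by construction. Each
#' subject's samples inherit its class, except that the second
#' longitudinal sample defects to a fresh class with probability
#' 1 - `sharing_prob["same_individual"]`. In food species a fraction of
#' samples is reassigned next to food-reference genomes with SNV rates
#' at or below 0.0015. The emitted tree joins one backbone tip per
#' class (random topology, exponential backbone branch lengths) and
#' attaches class members with short exponential pendants, producing
#' the bimodal nGD structure the calibration expects.
#'
#' @param samples Cohort metadata from [generate_cohort()].
#' @param config `sim_config` object.
#' @param dir Optional directory: when given, trees are written as
#'   `<sgb_id>.nwk` plus a long-format SNV-rate TSV.
#' @return list with `dist_sets` (named list of `sgb_dist`), `truth`
#'   (see [export_truth()]), `snv_rates` (long-format data.frame) and
#'   `newick` (named character vector of Newick strings). Species with
#'   fewer than 3 carrier subjects are skipped with a message.
#' @export
generate_sgb_trees <- function(samples, config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  subjects <- subject_table(samples)
  all_pairs <- classify_all_pairs(subjects)
  n_subj <- nrow(subjects)
  sgb_ids <- sprintf("SGB%04d", seq_len(config$n_sgbs))
  n_food_sgbs <- floor(config$food_sgb_fraction * config$n_sgbs)
  food_sgbs <- if (n_food_sgbs > 0) sgb_ids[seq_len(n_food_sgbs)] else character(0)
  dist_sets <- list(); newicks <- character(0)
  truth_partition <- list(); truth_pairs <- list(); truth_food <- list()
  snv_rows <- list()
  planted_t <- if (is.null(config$per_sgb_transmissibility)) {
    rep(config$sharing_prob[["mother_offspring"]], config$n_sgbs)
  } else config$per_sgb_transmissibility
  for (g in seq_along(sgb_ids)) {
    sgb <- sgb_ids[g]
    carrier <- stats::runif(n_subj) < config$carriage_prob
    carriers <- subjects$subject_id[carrier]
    if (length(carriers) < 3L) {
      message("skipping ", sgb, ": fewer than 3 carriers")
      next
    }
    # planted subject-level sharing edges
    cp <- all_pairs[all_pairs$subject_a %in% carriers &
                    all_pairs$subject_b %in% carriers, , drop = FALSE]
    p <- unname(config$sharing_prob[cp$category])
    p[cp$category == "mother_offspring"] <- planted_t[g]
    edge <- stats::runif(nrow(cp)) < p
    parent <- .uf_new(length(carriers))
    ia <- match(cp$subject_a[edge], carriers)
    ib <- match(cp$subject_b[edge], carriers)
    for (k in seq_along(ia)) parent <- .uf_union(parent, ia[k], ib[k])
    subj_class <- .uf_roots(parent)
    # sample-level classes: longitudinal defection
    samp <- samples[samples$subject_id %in% carriers, , drop = FALSE]
    samp <- samp[order(samp$subject_id, samp$collection_day,
                       samp$sample_id), , drop = FALSE]
    cls <- subj_class[match(samp$subject_id, carriers)]
    next_class <- max(subj_class) + 1L
    second <- duplicated(samp$subject_id)
    defect <- second &
      stats::runif(nrow(samp)) >= config$sharing_prob[["same_individual"]]
    for (i in which(defect)) {
      cls[i] <- next_class; next_class <- next_class + 1L
    }
    # food strains: reassign a fraction of samples to food-ref classes
    food_samples <- character(0); food_refs <- character(0)
    ref_class <- integer(0)
    if (sgb %in% food_sgbs && config$n_food_refs > 0L) {
      food_refs <- sprintf("FOODREF_%s_%d", sgb, seq_len(config$n_food_refs))
      ref_class <- next_class + seq_along(food_refs) - 1L
      next_class <- next_class + length(food_refs)
      n_food <- floor(config$food_fraction * nrow(samp))
      if (n_food > 0L) {
        fi <- sample.int(nrow(samp), n_food)
        cls[fi] <- sample(ref_class, n_food, replace = TRUE)
        food_samples <- samp$sample_id[fi]
      }
    }
    leaves <- c(samp$sample_id, food_refs)
    leaf_class <- c(cls, ref_class)
    nwk <- .emit_tree(leaves, leaf_class, config)
    tf <- tempfile(fileext = ".nwk")
    writeLines(nwk, tf)
    dist_sets[[sgb]] <- sgb_distance_set(sgb, read_sgb_tree(tf))
    unlink(tf)
    newicks[[sgb]] <- nwk
    # SNV rates to food refs (only emitted for food species)
    if (length(food_refs)) {
      for (fr in food_refs) {
        near <- samp$sample_id[cls == leaf_class[match(fr, leaves)]]
        for (sid in samp$sample_id) {
          rate <- if (sid %in% near) stats::runif(1, 0, 0.0015) else
            stats::runif(1, 0.005, 0.05)
          snv_rows[[length(snv_rows) + 1L]] <- data.frame(
            sgb_id = sgb, sample_a = sid, sample_b = fr, snv_rate = rate,
            stringsAsFactors = FALSE)
        }
      }
    }
    # ground truth
    truth_partition[[sgb]] <- data.frame(
      sgb_id = sgb, sample_id = samp$sample_id, strain_class = cls,
      stringsAsFactors = FALSE)
    subj_of <- structure(samp$subject_id, names = samp$sample_id)
    keep_samp <- setdiff(samp$sample_id, food_samples)
    pc <- cls[match(keep_samp, samp$sample_id)]
    ps <- subj_of[keep_samp]
    shared <- tapply(pc, ps, function(x) unique(x))
    subj_keep <- sort(unique(ps))
    if (length(subj_keep) >= 2L) {
      pid <- utils::combn(length(subj_keep), 2L)
      sa <- subj_keep[pid[1L, ]]; sb <- subj_keep[pid[2L, ]]
      shr <- mapply(function(x, y) length(intersect(shared[[x]], shared[[y]])) > 0,
                    sa, sb)
      truth_pairs[[sgb]] <- data.frame(
        sgb_id = sgb, subject_a = sa, subject_b = sb, shared = unname(shr),
        stringsAsFactors = FALSE)
    }
    if (length(food_samples)) {
      truth_food[[sgb]] <- data.frame(sgb_id = sgb, sample_id = sort(food_samples),
                                      stringsAsFactors = FALSE)
    }
  }
  truth <- list(
    partition = .rbind_or_empty(truth_partition,
      c("sgb_id", "sample_id", "strain_class")),
    pair_sharing = .rbind_or_empty(truth_pairs,
      c("sgb_id", "subject_a", "subject_b", "shared")),
    food_strains = .rbind_or_empty(truth_food, c("sgb_id", "sample_id")),
    transmissibility = data.frame(sgb_id = sgb_ids,
                                  planted_transmissibility = planted_t,
                                  stringsAsFactors = FALSE)
  )
  snv <- .rbind_or_empty(snv_rows, c("sgb_id", "sample_a", "sample_b", "snv_rate"))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (sgb in names(newicks)) {
      writeLines(newicks[[sgb]], file.path(dir, paste0(sgb, ".nwk")))
    }
    write_tsv(snv, file.path(dir, "snv_rates.tsv"))
  }
  list(dist_sets = dist_sets, truth = truth, snv_rates = snv,
       newick = newicks)
}

.rbind_or_empty <- function(lst, cols) {
  if (length(lst) == 0L) {
    df <- as.data.frame(stats::setNames(replicate(length(cols),
      character(0), simplify = FALSE), cols), stringsAsFactors = FALSE)
    return(df)
  }
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

# Build a Newick string: one backbone node per strain class (random
# binary joins, exponential branch lengths with mean backbone_scale),
# class members attached with exponential pendants (mean
# same_strain_scale). Single-member classes fold the pendant into the
# backbone branch to avoid singleton clades.
.emit_tree <- function(leaves, leaf_class, config) {
  fmt <- function(x) sprintf("%.10f", x)
  classes <- sort(unique(leaf_class))
  nodes <- lapply(classes, function(cl) {
    mem <- leaves[leaf_class == cl]
    pend <- stats::rexp(length(mem), rate = 1 / config$same_strain_scale)
    if (length(mem) == 1L) {
      list(str = mem, extra = pend)
    } else {
      list(str = paste0("(", paste0(mem, ":", fmt(pend), collapse = ","), ")"),
           extra = 0)
    }
  })
  if (length(nodes) == 1L) {
    n <- nodes[[1L]]
    if (n$extra > 0) return(paste0("(", n$str, ":", fmt(n$extra), ");"))
    return(paste0(n$str, ";"))
  }
  while (length(nodes) > 1L) {
    pick <- sample.int(length(nodes), 2L)
    a <- nodes[[pick[1L]]]; b <- nodes[[pick[2L]]]
    la <- stats::rexp(1, 1 / config$backbone_scale) + a$extra
    lb <- stats::rexp(1, 1 / config$backbone_scale) + b$extra
    joined <- list(str = paste0("(", a$str, ":", fmt(la), ",",
                                b$str, ":", fmt(lb), ")"),
                   extra = 0)
    nodes <- c(nodes[-pick], list(joined))
  }
  paste0(nodes[[1L]]$str, ";")
}

#' Generate FMT triads with planted engraftment
#'
#' Each triad holds a donor sample, a patient pre-FMT sample and a
#' patient post-FMT sample. Per species, the donor strain engrafts in
#' the post sample with probability `engraftment_prob` (the donor and
#' post samples then belong to one strain class); pre-FMT samples
#' always carry their own strain. Trees are emitted with the same
#' branch-length scales as the cohort generator.
#'
#' @param config `sim_config`; uses `fmt_triads`, `engraftment_prob`,
#'   `n_sgbs` (capped at 5 species for speed), and the branch scales.
#' @return list with `triads` (data.frame `sample_id`, `triad_id`,
#'   `role`), `dist_sets`, and `truth` (data.frame of planted
#'   donor-post engraftment per species and triad).
#' @export
generate_fmt_triads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$fmt_triads < 1L) {
    return(list(
      triads = data.frame(sample_id = character(), triad_id = character(),
                          role = character(), stringsAsFactors = FALSE),
      dist_sets = list(),
      truth = data.frame(sgb_id = character(), triad_id = character(),
                         engrafted = logical(), stringsAsFactors = FALSE)))
  }
  set.seed(config$seed + 2L)
  n <- config$fmt_triads
  triad_id <- sprintf("T%03d", seq_len(n))
  triads <- data.frame(
    sample_id = c(paste0(triad_id, "_donor"), paste0(triad_id, "_pre"),
                  paste0(triad_id, "_post")),
    triad_id = rep(triad_id, 3L),
    role = rep(c("donor", "pre", "post"), each = n),
    stringsAsFactors = FALSE)
  triads <- triads[order(triads$triad_id, triads$role), , drop = FALSE]
  rownames(triads) <- NULL
  n_sgbs <- min(config$n_sgbs, 5L)
  sgb_ids <- sprintf("FMTSGB%02d", seq_len(n_sgbs))
  dist_sets <- list(); truth <- list(); newicks <- character(0)
  for (sgb in sgb_ids) {
    engraft <- stats::runif(n) < config$engraftment_prob
    # classes: donor class per triad (post joins when engrafted),
    # pre always separate, post separate when not engrafted
    cls <- integer(nrow(triads))
    next_class <- 1L
    for (t in seq_len(n)) {
      donor_class <- next_class; next_class <- next_class + 1L
      pre_class <- next_class; next_class <- next_class + 1L
      post_class <- if (engraft[t]) donor_class else {
        nc <- next_class; next_class <- next_class + 1L; nc
      }
      cls[triads$triad_id == triad_id[t] & triads$role == "donor"] <- donor_class
      cls[triads$triad_id == triad_id[t] & triads$role == "pre"] <- pre_class
      cls[triads$triad_id == triad_id[t] & triads$role == "post"] <- post_class
    }
    nwk <- .emit_tree(triads$sample_id, cls, config)
    tf <- tempfile(fileext = ".nwk")
    writeLines(nwk, tf)
    dist_sets[[sgb]] <- sgb_distance_set(sgb, read_sgb_tree(tf))
    unlink(tf)
    newicks[[sgb]] <- nwk
    truth[[sgb]] <- data.frame(sgb_id = sgb, triad_id = triad_id,
                               engrafted = engraft, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(triads = triads, dist_sets = dist_sets, truth = truth,
       newick = newicks)
}

#' Export ground-truth tables
#'
#' Writes the planted truth of a synthetic study (strain partitions,
#' pair sharing, food strains, per-species transmissibility) as TSVs
#' for test consumption.
#'
#' @param truth `truth` element from [generate_sgb_trees()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
export_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    partition = file.path(dir, "truth_strain_partition.tsv"),
    pair_sharing = file.path(dir, "truth_pair_sharing.tsv"),
    food_strains = file.path(dir, "truth_food_strains.tsv"),
    transmissibility = file.path(dir, "truth_transmissibility.tsv"))
  write_tsv(truth$partition, paths[["partition"]])
  write_tsv(truth$pair_sharing, paths[["pair_sharing"]])
  write_tsv(truth$food_strains, paths[["food_strains"]])
  write_tsv(truth$transmissibility, paths[["transmissibility"]])
  invisible(paths)
}

#' Draw one species' calibration distance sets directly
#'
#' Fast secondary emission for calibration-level experiments: draws
#' same-individual nGD values from a low-scale exponential component
#' near zero and unrelated values from a broad Beta bulk whose lower
#' tail overlaps the same-strain peak (so the false-positive bound is
#' active), without building trees.
#'
#' @param n_same,n_unrelated Numbers of values to draw.
#' @param same_scale Mean of the same-strain exponential component.
#' @param unrel_shape1,unrel_shape2 Beta shape parameters of the
#'   unrelated bulk.
#' @return list(same, unrelated) of numeric vectors in \[0, 1\].
#' @export
simulate_calibration_sgb <- function(n_same, n_unrelated, same_scale = 0.01,
                                     unrel_shape1 = 1.5, unrel_shape2 = 4) {
  same <- pmin(stats::rexp(n_same, rate = 1 / same_scale), 1)
  unrelated <- stats::rbeta(n_unrelated, unrel_shape1, unrel_shape2)
  list(same = same, unrelated = unrelated)
}
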