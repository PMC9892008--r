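#' Select species eligible for strain profiling
#'
#' A species (SGB) is retained when at least one dataset detects it in
#' `min_samples` samples or more AND in at least `min_fraction` of that
#' dataset's samples (defaults 20 samples and 10%).
#'
#' @param detection data.frame with columns `sgb_id`, `dataset_id`,
#'   `n_detected`.
#' @param dataset_sizes Named integer vector: samples per dataset.
#' @param min_samples Minimum detections in one dataset (default 20).
#' @param min_fraction Minimum detected fraction of the dataset
#'   (default 0.10).
#' @return Sorted character vector of selected sgb_ids.
#' @export
select_sgbs_for_profiling <- function(detection, dataset_sizes,
                                      min_samples = 20L, min_fraction = 0.10) {
  unknown <- setdiff(detection$dataset_id, names(dataset_sizes))
  if (length(unknown)) {
    stop("unknown dataset in detection table: ", paste(unknown, collapse = ", "))
  }
  if (any(dataset_sizes <= 0)) stop("dataset sizes must be positive")
  size <- dataset_sizes[detection$dataset_id]
  ok <- detection$n_detected >= min_samples &
    detection$n_detected / size >= min_fraction
  sort(unique(detection$sgb_id[ok]))
}

#' Flag food-origin strains for exclusion
#'
#' Samples whose strain is nearly identical to a genome recovered from
#' commercial fermented food (SNV rate at or below `max_snv`, default
#' 0.0015) are flagged: such strains plausibly come from diet rather
#' than person-to-person transmission and are removed from sharing
#' analysis for that species.
#'
#' @param snv_rate Symmetric SNV-rate matrix over samples and
#'   food-reference genomes (dimnames required), or a long-format
#'   data.frame with columns `sample_a`, `sample_b`, `snv_rate`.
#' @param food_refs Character vector of food-reference ids present in
#'   the matrix.
#' @param max_snv Inclusive SNV-rate cutoff (default 0.0015).
#' @return Character vector of excluded sample ids (empty when no food
#'   references are supplied).
#' @export
flag_food_strains <- function(snv_rate, food_refs, max_snv = 0.0015) {
  if (length(food_refs) == 0L || is.null(snv_rate)) {
    message("no food references supplied; nothing excluded")
    return(character(0))
  }
  if (is.data.frame(snv_rate)) snv_rate <- snv_long_to_matrix(snv_rate)
  if (!all(food_refs %in% rownames(snv_rate))) {
    stop("food references absent from SNV-rate matrix: ",
         paste(setdiff(food_refs, rownames(snv_rate)), collapse = ", "))
  }
  samples <- setdiff(rownames(snv_rate), food_refs)
  if (length(samples) == 0L) return(character(0))
  min_to_food <- apply(snv_rate[samples, food_refs, drop = FALSE], 1L, min)
  sort(names(min_to_food)[min_to_food <= max_snv])
}

#' Convert a long-format SNV-rate table to a symmetric matrix
#'
#' @param df data.frame with columns `sample_a`, `sample_b`, `snv_rate`.
#' @return Symmetric matrix with `NA` for unobserved pairs and zero
#'   diagonal.
#' @export
snv_long_to_matrix <- function(df) {
  ids <- sort(unique(c(df$sample_a, df$sample_b)))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(match(df$sample_a, ids), match(df$sample_b, ids))] <- df$snv_rate
  m[cbind(match(df$sample_b, ids), match(df$sample_a, ids))] <- df$snv_rate
  diag(m) <- 0
  m
}

#' Call strain-sharing events between samples of one species
#'
#' A sample pair shares the strain when its nGD lies at or below the
#' species threshold (inclusive by default; set `inclusive = FALSE` for
#' a strict comparison). Pairs involving excluded (food-origin) samples
#' are dropped.
#'
#' @param dist_set `sgb_dist` object.
#' @param threshold One-row `strain_threshold` for the same species, or
#'   a scalar cutoff.
#' @param excluded Character vector of sample ids to exclude.
#' @param inclusive Use `<=` (default) rather than `<`.
#' @return data.frame `sample_a`, `sample_b`, `ngd`, `shared` over all
#'   unordered retained leaf pairs.
#' @export
call_sharing_events <- function(dist_set, threshold, excluded = character(0),
                                inclusive = TRUE) {
  if (is.data.frame(threshold)) {
    if (!is.na(threshold$sgb_id[1L]) &&
        threshold$sgb_id[1L] != dist_set$sgb_id) {
      stop("threshold sgb_id ", threshold$sgb_id[1L],
           " does not match distance set ", dist_set$sgb_id)
    }
    threshold <- threshold$threshold_ngd[1L]
  }
  keep <- setdiff(dist_set$leaves, excluded)
  if (length(keep) < 2L) {
    return(data.frame(sample_a = character(), sample_b = character(),
                      ngd = numeric(), shared = logical(),
                      stringsAsFactors = FALSE))
  }
  m <- dist_set$ngd[keep, keep, drop = FALSE]
  ut <- which(upper.tri(m), arr.ind = TRUE)
  ngd <- m[ut]
  shared <- if (inclusive) ngd <= threshold else ngd < threshold
  data.frame(sample_a = rownames(m)[ut[, 1L]],
             sample_b = colnames(m)[ut[, 2L]],
             ngd = ngd, shared = shared, stringsAsFactors = FALSE)
}

#' Collapse sample-level sharing calls to subject pairs
#'
#' Two subjects share the species profile when each has at least one
#' retained strain-profiled sample for it; they share the strain when
#' ANY cross-subject sample pair is called shared (sharing at any time
#' point counts).
#'
#' @param calls Output of [call_sharing_events()] for one species.
#' @param sample_subject Named character vector mapping sample id to
#'   subject id (must cover every sample in `calls`).
#' @param sgb_id Species id stamped on the result.
#' @return data.frame `sgb_id`, `subject_a`, `subject_b` (lexicographic,
#'   a < b), `shared`, `min_ngd` over all cross-subject pairs with both
#'   subjects profiled.
#' @export
collapse_to_subjects <- function(calls, sample_subject, sgb_id = NA_character_) {
  if (nrow(calls) == 0L) {
    return(data.frame(sgb_id = character(), subject_a = character(),
                      subject_b = character(), shared = logical(),
                      min_ngd = numeric(), stringsAsFactors = FALSE))
  }
  samp <- unique(c(calls$sample_a, calls$sample_b))
  unmapped <- setdiff(samp, names(sample_subject))
  if (length(unmapped)) {
    stop("samples not mapped to subjects: ", paste(unmapped, collapse = ", "))
  }
  sa <- unname(sample_subject[calls$sample_a])
  sb <- unname(sample_subject[calls$sample_b])
  cross <- sa != sb
  if (!any(cross)) {
    return(data.frame(sgb_id = character(), subject_a = character(),
                      subject_b = character(), shared = logical(),
                      min_ngd = numeric(), stringsAsFactors = FALSE))
  }
  a <- pmin(sa[cross], sb[cross])
  b <- pmax(sa[cross], sb[cross])
  key <- paste(a, b, sep = "\r")
  shared <- tapply(calls$shared[cross], key, any)
  min_ngd <- tapply(calls$ngd[cross], key, min)
  ord <- order(names(shared))
  parts <- strsplit(names(shared)[ord], "\r", fixed = TRUE)
  data.frame(
    sgb_id = sgb_id,
    subject_a = vapply(parts, `[`, "", 1L),
    subject_b = vapply(parts, `[`, "", 2L),
    shared = unname(shared[ord]),
    min_ngd = unname(min_ngd[ord]),
    stringsAsFactors = FALSE
  )
}

#' Per-subject-pair shared-SGB and shared-strain counts
#'
#' Aggregates subject-level calls across species into, per subject
#' pair, the number of species both subjects carry a strain profile for
#' (`n_shared_sgbs`) and how many of those are called shared
#' (`n_shared_strains`).
#'
#' @param subject_calls data.frame rbind of [collapse_to_subjects()]
#'   results over species.
#' @return data.frame `subject_a`, `subject_b`, `n_shared_sgbs`,
#'   `n_shared_strains`.
#' @export
pair_counts <- function(subject_calls) {
  if (nrow(subject_calls) == 0L) {
    return(data.frame(subject_a = character(), subject_b = character(),
                      n_shared_sgbs = integer(), n_shared_strains = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(subject_calls$subject_a, subject_calls$subject_b, sep = "\r")
  sgbs <- tapply(rep(1L, nrow(subject_calls)), key, sum)
  strains <- tapply(subject_calls$shared, key, sum)
  ord <- order(names(sgbs))
  parts <- strsplit(names(sgbs)[ord], "\r", fixed = TRUE)
  out <- data.frame(
    subject_a = vapply(parts, `[`, "", 1L),
    subject_b = vapply(parts, `[`, "", 2L),
    n_shared_sgbs = as.integer(unname(sgbs[ord])),
    n_shared_strains = as.integer(unname(strains[ord])),
    stringsAsFactors = FALSE
  )
  if (any(out$n_shared_strains > out$n_shared_sgbs)) {
    stop("internal inconsistency: more shared strains than shared species")
  }
  out
}

#' Person-to-person strain-sharing rate
#'
#' 100 x shared strains / shared strain-profiled species, per subject
#' pair; reported as missing when fewer than `min_shared_sgbs` species
#' are shared (too few for a robust rate; default 10).
#'
#' @param counts Output of [pair_counts()].
#' @param min_shared_sgbs Minimum shared species (default 10).
#' @return `counts` with an added `sharing_rate_pct` column.
#' @export
sharing_rate <- function(counts, min_shared_sgbs = 10L) {
  rate <- 100 * counts$n_shared_strains / counts$n_shared_sgbs
  rate[counts$n_shared_sgbs < min_shared_sgbs] <- NA_real_
  counts$sharing_rate_pct <- rate
  counts
}

#' Strain acquisition rate of an offspring from its mother
#'
#' The proportion of the offspring's strain-profiled species whose
#' strain is shared with the mother (putatively acquired from her).
#' Missing when mother and offspring share fewer than `min_shared_sgbs`
#' strain-profiled species.
#'
#' @param offspring,mother Subject ids.
#' @param subject_calls rbind of [collapse_to_subjects()] over species.
#' @param profiles Named list: sgb_id -> character vector of subjects
#'   with a strain profile for that species.
#' @param min_shared_sgbs Minimum species in common (default 10).
#' @return Scalar in \[0, 1\], or `NA` below the gate.
#' @export
acquisition_rate <- function(offspring, mother, subject_calls, profiles,
                             min_shared_sgbs = 10L) {
  off_sgbs <- names(profiles)[vapply(profiles, function(s) offspring %in% s,
                                     logical(1))]
  if (length(off_sgbs) == 0L) {
    message("subject ", offspring, " has no strain profiles")
    return(NA_real_)
  }
  both <- names(profiles)[vapply(profiles, function(s)
    offspring %in% s && mother %in% s, logical(1))]
  if (length(both) < min_shared_sgbs) return(NA_real_)
  a <- pmin(offspring, mother); b <- pmax(offspring, mother)
  sel <- subject_calls$subject_a == a & subject_calls$subject_b == b &
    subject_calls$shared
  n_shared <- length(intersect(subject_calls$sgb_id[sel], off_sgbs))
  n_shared / length(off_sgbs)
}

#' Classify the relationship between two subjects
#'
#' Assigns the most specific relationship category in the precedence
#' order mother_offspring > father_offspring > twins > partners >
#' siblings > household > same_village > same_population >
#' inter_population. Twins are siblings (both parental links equal and
#' known) of the same age; partners are the mother and father of a
#' common offspring; subjects with missing household ids are treated as
#' non-cohabiting. "Population" is the dataset. For parent-offspring
#' pairs the offspring age at sampling is binned
#' (<=1y, 1-3y, 3-18y, 18-30y, 50-85y; ages outside the bins get `NA`).
#'
#' @param subject_a,subject_b Subject ids.
#' @param subjects Per-subject table from [subject_table()].
#' @return list(category = character, offspring_age_bin = character or
#'   NA).
#' @export
classify_pair <- function(subject_a, subject_b, subjects) {
  if (!subject_a %in% subjects$subject_id ||
      !subject_b %in% subjects$subject_id) {
    stop("unknown subject: ",
         paste(setdiff(c(subject_a, subject_b), subjects$subject_id),
               collapse = ", "))
  }
  A <- subjects[subjects$subject_id == subject_a, ]
  B <- subjects[subjects$subject_id == subject_b, ]
  eq <- function(x, y) !is.na(x) & !is.na(y) & x == y
  child_of <- function(child, parent, link) eq(child[[link]], parent$subject_id)
  age_bin <- function(age) {
    if (is.na(age)) return(NA_character_)
    if (age <= 1) "<=1y"
    else if (age <= 3) "1-3y"
    else if (age <= 18) "3-18y"
    else if (age <= 30) "18-30y"
    else if (age >= 50 && age <= 85) "50-85y"
    else NA_character_
  }
  offspring <- if (child_of(A, B, "mother_id") || child_of(A, B, "father_id")) A
               else if (child_of(B, A, "mother_id") || child_of(B, A, "father_id")) B
               else NULL
  bin <- if (!is.null(offspring)) age_bin(offspring$age_years) else NA_character_
  category <-
    if (child_of(A, B, "mother_id") || child_of(B, A, "mother_id")) {
      "mother_offspring"
    } else if (child_of(A, B, "father_id") || child_of(B, A, "father_id")) {
      "father_offspring"
    } else if (eq(A$mother_id, B$mother_id) && eq(A$father_id, B$father_id) &&
               eq(A$age_years, B$age_years)) {
      "twins"
    } else if (.are_partners(A, B, subjects)) {
      "partners"
    } else if (eq(A$mother_id, B$mother_id) || eq(A$father_id, B$father_id)) {
      "siblings"
    } else if (eq(A$household_id, B$household_id)) {
      "household"
    } else if (eq(A$village_id, B$village_id)) {
      "same_village"
    } else if (eq(A$dataset_id, B$dataset_id)) {
      "same_population"
    } else {
      "inter_population"
    }
  list(category = category, offspring_age_bin = bin)
}

.are_partners <- function(A, B, subjects) {
  any(!is.na(subjects$mother_id) & !is.na(subjects$father_id) &
        ((subjects$mother_id == A$subject_id & subjects$father_id == B$subject_id) |
         (subjects$mother_id == B$subject_id & subjects$father_id == A$subject_id)))
}

#' Annotate subject pairs with relationship categories
#'
#' @param pairs data.frame with `subject_a`, `subject_b`.
#' @param subjects Per-subject table from [subject_table()].
#' @return `pairs` with added `category` and `offspring_age_bin`
#'   columns.
#' @export
classify_pairs <- function(pairs, subjects) {
  cls <- lapply(seq_len(nrow(pairs)), function(i)
    classify_pair(pairs$subject_a[i], pairs$subject_b[i], subjects))
  pairs$category <- vapply(cls, `[[`, "", "category")
  pairs$offspring_age_bin <- vapply(cls, function(x)
    if (is.na(x$offspring_age_bin)) NA_character_ else x$offspring_age_bin, "")
  pairs
}

#' Sharing-rate summaries by relationship category
#'
#' Median and quartiles of the person-to-person strain-sharing rate per
#' relationship category, with the percentage of pairs in which no
#' strain-sharing event at all was detected (among pairs with a
#' non-missing rate).
#'
#' @param summaries data.frame from [sharing_rate()] with a `category`
#'   column (see [classify_pairs()]).
#' @return data.frame `category`, `n_pairs`, `median_rate`, `q1`, `q3`,
#'   `pct_zero_sharing`.
#' @export
rate_by_relationship <- function(summaries) {
  s <- summaries[!is.na(summaries$sharing_rate_pct), , drop = FALSE]
  cats <- sort(unique(s$category))
  rows <- lapply(cats, function(cat) {
    r <- s$sharing_rate_pct[s$category == cat]
    z <- s$n_shared_strains[s$category == cat] == 0L
    data.frame(category = cat, n_pairs = length(r),
               median_rate = stats::median(r),
               q1 = unname(stats::quantile(r, 0.25, type = 7)),
               q3 = unname(stats::quantile(r, 0.75, type = 7)),
               pct_zero_sharing = 100 * mean(z),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Strain-sharing network edge list
#'
#' Undirected edges between subjects sharing at least
#' `min_shared_strains` strains (default 5). With
#' `what = "species"`, edges instead require at least `min_shared_sgbs`
#' (default 50) species profiled in common, ignoring strain identity.
#'
#' @param counts Output of [pair_counts()].
#' @param min_shared_strains Strain-edge cutoff (default 5).
#' @param what `"strains"` (default) or `"species"`.
#' @param min_shared_sgbs Species-edge cutoff (default 50).
#' @return data.frame `subject_a`, `subject_b`, `n_shared_strains`,
#'   `n_shared_sgbs`, lexicographically ordered, no self-loops.
#' @export
build_sharing_network <- function(counts, min_shared_strains = 5L,
                                  what = c("strains", "species"),
                                  min_shared_sgbs = 50L) {
  what <- match.arg(what)
  keep <- if (what == "strains") {
    counts$n_shared_strains >= min_shared_strains
  } else {
    counts$n_shared_sgbs >= min_shared_sgbs
  }
  edges <- counts[keep & counts$subject_a != counts$subject_b, , drop = FALSE]
  edges <- edges[order(edges$subject_a, edges$subject_b),
                 c("subject_a", "subject_b", "n_shared_strains",
                   "n_shared_sgbs"), drop = FALSE]
  rownames(edges) <- NULL
  edges
}
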