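#' Species-specific strain-identity threshold by constrained Youden's index
#'
#' Chooses the nGD cutoff separating same-individual longitudinal
#' distances (strain retention, the "same strain" class) from
#' unrelated-individual distances ("different strain"), by maximizing
#' Youden's J = sensitivity + specificity - 1 subject to an upper bound
#' on the fraction of unrelated pairs falling at or below the cutoff
#' (a bound on the false-discovery side of strain-sharing calls;
#' default 5%).
#'
#' Candidate cutoffs are the midpoints between consecutive sorted unique
#' values of the pooled distances, plus one candidate below the pooled
#' minimum (midpoints make the choice insensitive to floating-point
#' noise; the below-minimum candidate guarantees feasibility). The
#' comparison is inclusive: a distance equal to the threshold counts as
#' same strain. Ties in J are broken toward the smallest threshold,
#' which is conservative against false positives.
#'
#' @param same_dists Numeric vector of same-individual nGD values.
#' @param unrelated_dists Numeric vector of unrelated-individual nGD
#'   values.
#' @param fp_bound Maximum allowed fraction of unrelated pairs at/below
#'   the threshold (default 0.05).
#' @param sgb_id Optional species id recorded in the result.
#' @return A one-row data.frame of class `strain_threshold` with columns
#'   `sgb_id`, `threshold_ngd`, `method` (`"youden"`), `n_same_pairs`,
#'   `n_unrelated_pairs`, `fp_fraction`, `youden_j`,
#'   `unrelated_percentile` (percentile of the unrelated distribution at
#'   the threshold, i.e. 100 x fp_fraction).
#' @export
youden_threshold <- function(same_dists, unrelated_dists, fp_bound = 0.05,
                             sgb_id = NA_character_) {
  if (length(same_dists) == 0L || length(unrelated_dists) == 0L) {
    stop("both distance sets must be non-empty")
  }
  if (any(same_dists < 0) || any(unrelated_dists < 0)) {
    stop("distances must be non-negative")
  }
  pooled <- sort(unique(c(same_dists, unrelated_dists)))
  cand <- if (length(pooled) > 1L) {
    c(pooled[1L] - (pooled[2L] - pooled[1L]) / 2,
      (pooled[-length(pooled)] + pooled[-1L]) / 2)
  } else {
    pooled - max(pooled / 2, .Machine$double.eps)
  }
  cand[1L] <- max(cand[1L], 0)  # below-minimum candidate, kept non-negative
  # counts at candidates via sorted lookup; candidates never coincide
  # with data values, so findInterval counts values <= candidate
  same_sorted <- sort(same_dists)
  unrel_sorted <- sort(unrelated_dists)
  tpr <- findInterval(cand, same_sorted) / length(same_dists)
  fpf <- findInterval(cand, unrel_sorted) / length(unrelated_dists)
  j <- tpr + (1 - fpf) - 1
  feasible <- fpf <= fp_bound
  if (!any(feasible)) {
    stop("no candidate threshold satisfies the false-positive bound of ",
         fp_bound)
  }
  jf <- j[feasible]
  best <- which(feasible)[which(jf == max(jf))]
  best <- best[which.min(cand[best])]  # smallest threshold on ties
  thr <- cand[best]
  res <- data.frame(
    sgb_id = sgb_id,
    threshold_ngd = thr,
    method = "youden",
    n_same_pairs = length(same_dists),
    n_unrelated_pairs = length(unrelated_dists),
    fp_fraction = fpf[best],
    youden_j = j[best],
    unrelated_percentile = 100 * fpf[best],
    stringsAsFactors = FALSE
  )
  class(res) <- c("strain_threshold", "data.frame")
  res
}

#' Percentile fallback strain-identity threshold
#'
#' For species without enough same-individual longitudinal pairs (and
#' for all oral species, where species-specific calibration is
#' unreliable), the threshold is a low percentile of the
#' unrelated-individual nGD distribution — by default the 3rd
#' percentile, the median percentile at which the constrained Youden
#' cutoffs of well-sampled species sit (see
#' [derive_fallback_percentile()]).
#'
#' Percentiles use linear interpolation between closest ranks
#' ([stats::quantile()] type 7). At least `min_n` values are required so
#' the requested percentile rests on an interior order statistic rather
#' than extrapolation (34 values put the 3rd percentile at/above the
#' first order statistic).
#'
#' @param unrelated_dists Numeric vector of unrelated-individual nGD
#'   values.
#' @param percentile Percentile in (0, 100) of the unrelated
#'   distribution to use as threshold (default 3).
#' @param min_n Minimum number of values required (default 34).
#' @param sgb_id Optional species id recorded in the result.
#' @return One-row `strain_threshold` data.frame with `method`
#'   `"fallback"`; `youden_j` is `NA`.
#' @export
fallback_threshold <- function(unrelated_dists, percentile = 3.0,
                               min_n = 34L, sgb_id = NA_character_) {
  n <- length(unrelated_dists)
  if (n < min_n) {
    stop("fallback threshold needs at least ", min_n,
         " unrelated distances; got ", n, " (short by ", min_n - n, ")")
  }
  if (any(unrelated_dists < 0)) stop("distances must be non-negative")
  thr <- unname(stats::quantile(unrelated_dists, percentile / 100, type = 7))
  res <- data.frame(
    sgb_id = sgb_id,
    threshold_ngd = thr,
    method = "fallback",
    n_same_pairs = NA_integer_,
    n_unrelated_pairs = n,
    fp_fraction = mean(unrelated_dists <= thr),
    youden_j = NA_real_,
    unrelated_percentile = percentile,
    stringsAsFactors = FALSE
  )
  class(res) <- c("strain_threshold", "data.frame")
  res
}

#' Calibrate strain-identity thresholds for a set of species
#'
#' Applies the calibration rule per species: gut species with at least
#' `min_same_pairs` same-individual longitudinal pairs get a
#' constrained-Youden threshold; all other species — too few
#' longitudinal pairs, or oral body site — get the percentile fallback.
#'
#' @param dist_sets Named list of `sgb_dist` objects.
#' @param samples Sample metadata data.frame.
#' @param body_site Named character vector mapping sgb_id to
#'   `"gut"`/`"oral"`; defaults to `"gut"` for all.
#' @param min_same_pairs Minimum same-individual pairs for Youden
#'   calibration (default 50).
#' @param fp_bound False-positive bound for Youden calibration
#'   (default 0.05).
#' @param fallback_percentile Percentile for the fallback rule
#'   (default 3).
#' @param max_gap_days Longitudinal pair gap limit (default 183).
#' @param scope Unrelated-pair scope, see [enumerate_unrelated_pairs()].
#' @param min_unrelated Minimum unrelated distances for the fallback
#'   (default 34).
#' @param seed Optional seed for the one-sample-per-subject draw.
#' @return `strain_threshold` data.frame, one row per calibrated
#'   species; species with no unrelated pairs are skipped with a
#'   warning.
#' @export
calibrate_all <- function(dist_sets, samples, body_site = NULL,
                          min_same_pairs = 50L, fp_bound = 0.05,
                          fallback_percentile = 3.0, max_gap_days = 183L,
                          scope = "pooled", min_unrelated = 34L,
                          seed = NULL) {
  rows <- list()
  for (sgb in names(dist_sets)) {
    d <- dist_sets[[sgb]]
    site <- if (is.null(body_site)) "gut" else body_site[[sgb]]
    long_pairs <- select_longitudinal_pairs(samples, d$leaves, max_gap_days)
    unrel_pairs <- enumerate_unrelated_pairs(samples, d$leaves, scope = scope,
                                             seed = seed)
    if (nrow(unrel_pairs) == 0L) {
      warning("skipping ", sgb, ": no unrelated pairs")
      next
    }
    unrel <- pair_distances(d, unrel_pairs)
    use_youden <- identical(site, "gut") && nrow(long_pairs) >= min_same_pairs
    row <- if (use_youden) {
      same <- pair_distances(d, long_pairs)
      youden_threshold(same, unrel, fp_bound = fp_bound, sgb_id = sgb)
    } else {
      th <- tryCatch(
        fallback_threshold(unrel, percentile = fallback_percentile,
                           min_n = min_unrelated, sgb_id = sgb),
        error = function(e) {
          warning("skipping ", sgb, ": ", conditionMessage(e))
          NULL
        })
      if (is.null(th)) next
      th$n_same_pairs <- nrow(long_pairs)
      th
    }
    rows[[sgb]] <- row
  }
  if (length(rows) == 0L) stop("no species could be calibrated")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("strain_threshold", "data.frame")
  out
}

#' @export
print.strain_threshold <- function(x, ...) {
  cat("strain-identity thresholds:", nrow(x), "species (",
      sum(x$method == "youden"), "Youden,",
      sum(x$method == "fallback"), "fallback )\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Data-driven fallback percentile
#'
#' The percentile of the unrelated-individual nGD distribution at which
#' each constrained-Youden threshold sits, summarised by its median over
#' Youden-calibrated species. This is the empirical justification for
#' the default fallback percentile.
#'
#' @param thresholds `strain_threshold` table from [calibrate_all()].
#' @return Median unrelated-distribution percentile (scalar).
#' @export
derive_fallback_percentile <- function(thresholds) {
  y <- thresholds[thresholds$method == "youden", , drop = FALSE]
  if (nrow(y) == 0L) stop("no Youden-calibrated species available")
  stats::median(y$unrelated_percentile)
}

#' Validate a strain-identity threshold on FMT triads
#'
#' Faecal microbiota transplantation cohorts provide an independent
#' setting where strain transfer is expected: samples within one triad
#' (donor, patient pre-FMT, patient post-FMT) can share strains, while
#' samples from different triads should not. Every leaf pair of the
#' species tree mapped to triads is classified against the threshold:
#' within-triad at/below threshold = true positive, within-triad above =
#' false negative, cross-triad at/below = false positive, cross-triad
#' above = true negative.
#'
#' @param dist_set `sgb_dist` object.
#' @param threshold One-row `strain_threshold` (or a scalar nGD cutoff).
#' @param triad_of Named character vector mapping sample id to triad id;
#'   leaves absent from the mapping are excluded from the evaluation.
#' @return One-row data.frame: `sgb_id`, `tp`, `fp`, `tn`, `fn`,
#'   `recall`, `precision`, `f_score` (NA where undefined).
#' @export
fmt_validate <- function(dist_set, threshold, triad_of) {
  thr <- if (is.data.frame(threshold)) {
    if (!is.na(threshold$sgb_id[1L]) &&
        threshold$sgb_id[1L] != dist_set$sgb_id) {
      stop("threshold is for ", threshold$sgb_id[1L], ", distances for ",
           dist_set$sgb_id)
    }
    threshold$threshold_ngd[1L]
  } else threshold
  leaves <- intersect(dist_set$leaves, names(triad_of))
  if (length(leaves) < 2L) {
    stop("fewer than 2 triad-mapped leaves for ", dist_set$sgb_id)
  }
  m <- dist_set$ngd[leaves, leaves, drop = FALSE]
  tri <- triad_of[leaves]
  ut <- upper.tri(m)
  same_triad <- outer(tri, tri, "==")[ut]
  called <- (m <= thr)[ut]
  tp <- sum(same_triad & called)
  fn <- sum(same_triad & !called)
  fp <- sum(!same_triad & called)
  tn <- sum(!same_triad & !called)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else NA_real_
  data.frame(sgb_id = dist_set$sgb_id, tp = tp, fp = fp, tn = tn, fn = fn,
             recall = recall, precision = precision, f_score = f,
             stringsAsFactors = FALSE)
}
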