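#' Pipeline run configuration
#'
#' Collects paths and tuning parameters for [run_pipeline()]. Defaults
#' are the calibrated operating points of the method: 5% false-positive
#' bound and 50 same-individual pairs for Youden calibration, 3rd
#' percentile fallback, 183-day longitudinal gap, 10 shared species for
#' a sharing rate, 0.0015 food SNV cutoff, 5 shared strains for a
#' network edge, 10/3 minimum potential events (pooled/per-dataset),
#' and the >0.5 + BH-significant criterion for highly transmitted
#' species.
#'
#' @param out_dir Output directory.
#' @param trees_dir Directory of `<sgb_id>.nwk` trees.
#' @param metadata Path to the sample metadata TSV.
#' @param snv_table Optional path to a long-format SNV-rate TSV
#'   (`sgb_id`, `sample_a`, `sample_b`, `snv_rate`).
#' @param fmt_triads Optional path to an FMT triad TSV (`sample_id`,
#'   `triad_id`, `role`) with trees under `trees_dir`.
#' @param thresholds Optional path to a previously written
#'   `thresholds.tsv` (used by the standalone validate-fmt stage).
#' @param seed Integer seed for all stochastic steps.
#' @param fp_bound,fallback_percentile,min_same_pairs,max_gap_days
#'   Calibration parameters.
#' @param min_shared_sgbs,food_max_snv,network_min_strains Sharing
#'   parameters.
#' @param min_potential_pooled,min_potential_dataset,alpha,t_min
#'   Transmissibility parameters.
#' @param inclusive Inclusive threshold comparison (default TRUE).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       trees_dir = NULL,
                       metadata = NULL,
                       snv_table = NULL,
                       fmt_triads = NULL,
                       thresholds = NULL,
                       seed = 1L,
                       fp_bound = 0.05,
                       fallback_percentile = 3.0,
                       min_same_pairs = 50L,
                       max_gap_days = 183L,
                       min_shared_sgbs = 10L,
                       food_max_snv = 0.0015,
                       network_min_strains = 5L,
                       min_potential_pooled = 10L,
                       min_potential_dataset = 3L,
                       alpha = 0.05,
                       t_min = 0.5,
                       inclusive = TRUE) {
  cfg <- as.list(environment())
  stopifnot(cfg$fp_bound > 0, cfg$fp_bound < 1,
            cfg$fallback_percentile > 0, cfg$fallback_percentile < 100,
            cfg$min_same_pairs >= 1, cfg$max_gap_days >= 1,
            cfg$min_shared_sgbs >= 1, cfg$food_max_snv >= 0,
            cfg$network_min_strains >= 1,
            cfg$min_potential_pooled >= 1, cfg$min_potential_dataset >= 1,
            cfg$alpha > 0, cfg$alpha < 1, cfg$t_min >= 0, cfg$t_min <= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Run the strain-sharing pipeline
#'
#' Orchestrates the pipeline stages over the files named in a
#' [run_config()]. Stages: `"simulate"` (synthetic study into
#' `out_dir/simulated/`), `"ngd"` (long-format nGD table),
#' `"calibrate"` (strain-identity thresholds), `"share"` (sharing
#' events, pair summaries, grouped rates, network), `"transmissibility"`
#' (per-mode tables, highly-transmitted flags, cross-dataset
#' concordance), `"validate-fmt"` (FMT precision/recall), and `"all"`
#' (simulate, then every analysis stage on the simulated study). A
#' `manifest.tsv` records configuration, seed, package version and
#' input checksums. Partial outputs of a failing stage are removed.
#'
#' @param stage One of simulate, ngd, calibrate, share,
#'   transmissibility, validate-fmt, all.
#' @param config `run_config` object.
#' @param sim_config Optional [simulation_config()] for the simulate
#'   stage (default: `simulation_config(config$seed)`).
#' @return Invisibly, a named list of the tables computed by the
#'   stage(s).
#' @export
run_pipeline <- function(stage, config, sim_config = NULL) {
  stage <- match.arg(stage, c("simulate", "ngd", "calibrate", "share",
                              "transmissibility", "validate-fmt", "all"))
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write_tsv(df, p)
    written <<- c(written, p)
    p
  }
  result <- tryCatch(
    .run_stages(stage, config, sim_config, emit),
    error = function(e) {
      unlink(written)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  .write_manifest(config, written)
  invisible(result)
}

.run_stages <- function(stage, config, sim_config, emit) {
  out <- list()
  if (stage %in% c("simulate", "all")) {
    sc <- if (is.null(sim_config)) simulation_config(config$seed) else sim_config
    sim_dir <- file.path(config$out_dir, "simulated")
    dir.create(file.path(sim_dir, "trees"), recursive = TRUE,
               showWarnings = FALSE)
    samples <- generate_cohort(sc)
    write_tsv(samples, file.path(sim_dir, "metadata.tsv"))
    trees <- generate_sgb_trees(samples, sc, dir = file.path(sim_dir, "trees"))
    export_truth(trees$truth, file.path(sim_dir, "truth"))
    fmt <- generate_fmt_triads(sc)
    write_tsv(fmt$triads, file.path(sim_dir, "fmt_triads.tsv"))
    if (length(fmt$newick)) {
      fmt_dir <- file.path(sim_dir, "fmt_trees")
      dir.create(fmt_dir, showWarnings = FALSE)
      for (sgb in names(fmt$newick)) {
        writeLines(fmt$newick[[sgb]], file.path(fmt_dir, paste0(sgb, ".nwk")))
      }
    }
    .write_sim_config(sc, file.path(sim_dir, "sim_config.txt"))
    message("simulate: ", nrow(samples), " samples, ",
            length(trees$dist_sets), " species trees, ",
            nrow(fmt$triads), " FMT samples")
    out$samples <- samples
    out$dist_sets <- trees$dist_sets
    out$snv_rates <- trees$snv_rates
    out$truth <- trees$truth
    out$fmt <- fmt
    if (stage == "simulate") return(out)
    config$trees_dir <- file.path(sim_dir, "trees")
    config$metadata <- file.path(sim_dir, "metadata.tsv")
    config$snv_table <- file.path(sim_dir, "snv_rates.tsv")
  }
  # load inputs for analysis stages
  needs_meta <- stage %in% c("calibrate", "share", "transmissibility", "all")
  if (is.null(out$samples) && needs_meta) {
    if (is.null(config$metadata) || !file.exists(config$metadata)) {
      stop("metadata file required but not found: ", config$metadata)
    }
    out$samples <- read_metadata(config$metadata)
  }
  if (is.null(out$dist_sets)) {
    if (is.null(config$trees_dir) || !dir.exists(config$trees_dir)) {
      stop("trees directory required but not found: ", config$trees_dir)
    }
    out$dist_sets <- read_sgb_trees(config$trees_dir)
  }
  if (is.null(out$snv_rates) && !is.null(config$snv_table) &&
      file.exists(config$snv_table)) {
    out$snv_rates <- read_tsv(config$snv_table)
  }
  samples <- out$samples
  dist_sets <- out$dist_sets
  if (stage %in% c("ngd", "all")) {
    emit_path <- file.path(config$out_dir, "ngd_long.tsv")
    write_ngd_long(dist_sets, emit_path)
    message("ngd: wrote ", length(dist_sets), " species to ngd_long.tsv")
  }
  if (stage %in% c("calibrate", "share", "transmissibility", "all")) {
    thresholds <- calibrate_all(
      dist_sets, samples,
      body_site = stats::setNames(
        rep(samples$body_site[1L], length(dist_sets)), names(dist_sets)),
      min_same_pairs = config$min_same_pairs, fp_bound = config$fp_bound,
      fallback_percentile = config$fallback_percentile,
      max_gap_days = config$max_gap_days, seed = config$seed)
    emit(as.data.frame(thresholds), "thresholds.tsv")
    message("calibrate: ", nrow(thresholds), " species (",
            sum(thresholds$method == "youden"), " Youden)")
    out$thresholds <- thresholds
    if (stage == "calibrate") return(out)
  }
  if (stage %in% c("share", "transmissibility", "all")) {
    share <- .stage_share(dist_sets, samples, out$thresholds,
                          out$snv_rates, config)
    emit(share$subject_calls, "sharing_events.tsv")
    emit(share$summaries, "pair_summary.tsv")
    emit(share$grouped, "grouped_rates.tsv")
    emit(share$network, "network_edges.tsv")
    emit(share$excluded, "excluded_food_strains.tsv")
    message("share: ", sum(share$subject_calls$shared), " shared / ",
            nrow(share$subject_calls), " subject-pair calls; ",
            nrow(share$excluded), " food strains excluded")
    out <- c(out, share)
    if (stage == "share") return(out)
  }
  if (stage %in% c("transmissibility", "all")) {
    tr <- .stage_transmissibility(samples, out$subject_calls,
                                  names(dist_sets), config)
    for (mode in names(tr$by_mode)) {
      emit(tr$by_mode[[mode]], paste0("transmissibility_", mode, ".tsv"))
    }
    emit(tr$concordance, "concordance.tsv")
    message("transmissibility: ",
            sum(vapply(tr$by_mode, function(x)
              sum(x$highly_transmitted %in% TRUE), integer(1))),
            " highly transmitted flags across modes")
    out$transmissibility <- tr$by_mode
    out$concordance <- tr$concordance
  }
  if (stage == "validate-fmt" || (stage == "all" && !is.null(out$fmt))) {
    fmtv <- .stage_fmt(out, config)
    emit(fmtv, "fmt_validation.tsv")
    message("validate-fmt: median recall ",
            format(stats::median(fmtv$recall, na.rm = TRUE), digits = 3))
    out$fmt_validation <- fmtv
  }
  out
}

.stage_share <- function(dist_sets, samples, thresholds, snv_rates, config) {
  sample_subject <- structure(samples$subject_id, names = samples$sample_id)
  subjects <- subject_table(samples)
  calls_list <- list(); excl_list <- list()
  for (sgb in names(dist_sets)) {
    th <- thresholds[thresholds$sgb_id == sgb, , drop = FALSE]
    if (nrow(th) == 0L) next
    excluded <- character(0)
    if (!is.null(snv_rates) && nrow(snv_rates) > 0L) {
      snv <- snv_rates[snv_rates$sgb_id == sgb, , drop = FALSE]
      if (nrow(snv) > 0L) {
        ids <- unique(c(snv$sample_a, snv$sample_b))
        refs <- setdiff(ids, samples$sample_id)
        if (length(refs)) {
          excluded <- suppressMessages(
            flag_food_strains(snv, refs, max_snv = config$food_max_snv))
        }
      }
    }
    calls <- call_sharing_events(dist_sets[[sgb]], th,
                                 excluded = c(excluded,
                                   grep("^FOODREF_", dist_sets[[sgb]]$leaves,
                                        value = TRUE)),
                                 inclusive = config$inclusive)
    calls_list[[sgb]] <- collapse_to_subjects(calls, sample_subject, sgb)
    if (length(excluded)) {
      excl_list[[sgb]] <- data.frame(sgb_id = sgb, sample_id = excluded,
                                     stringsAsFactors = FALSE)
    }
  }
  subject_calls <- .rbind_or_empty(calls_list,
    c("sgb_id", "subject_a", "subject_b", "shared", "min_ngd"))
  counts <- pair_counts(subject_calls)
  summaries <- sharing_rate(counts, min_shared_sgbs = config$min_shared_sgbs)
  pairs_cls <- classify_all_pairs(subjects)
  key <- function(d) paste(d$subject_a, d$subject_b, sep = "\r")
  m <- match(key(summaries), key(pairs_cls))
  summaries$category <- pairs_cls$category[m]
  summaries$offspring_age_bin <- pairs_cls$offspring_age_bin[m]
  grouped <- rate_by_relationship(summaries)
  network <- build_sharing_network(counts,
    min_shared_strains = config$network_min_strains)
  excluded <- .rbind_or_empty(excl_list, c("sgb_id", "sample_id"))
  list(subject_calls = subject_calls, summaries = summaries,
       grouped = grouped, network = network, excluded = excluded,
       pairs_cls = pairs_cls)
}

.stage_transmissibility <- function(samples, subject_calls, sgb_ids, config) {
  subjects <- subject_table(samples)
  pairs_cls <- classify_all_pairs(subjects)
  modes <- c("mother_infant", "household", "intra_population")
  by_mode <- list()
  for (mode in modes) {
    tab <- transmissibility_table(sgb_ids, mode, pairs_cls, subject_calls,
                                  min_potential = config$min_potential_pooled,
                                  scope = "all", subjects = subjects)
    by_mode[[mode]] <- flag_highly_transmitted(tab, alpha = config$alpha,
                                               t_min = config$t_min)
  }
  # per-dataset tables (household mode) feed the concordance check
  per_ds <- list()
  for (ds in sort(unique(subjects$dataset_id))) {
    sub <- subjects[subjects$dataset_id == ds, , drop = FALSE]
    if (nrow(sub) < 2L) next
    pc <- classify_all_pairs(sub)
    per_ds[[ds]] <- transmissibility_table(
      sgb_ids, "household", pc, subject_calls,
      min_potential = config$min_potential_dataset, scope = ds,
      subjects = sub)
  }
  concord <- if (length(per_ds) >= 2L) {
    dataset_concordance(per_ds, min_sgbs = 10L)
  } else {
    data.frame(dataset_a = character(), dataset_b = character(),
               n_sgbs = integer(), rho = numeric(), p = numeric(),
               stringsAsFactors = FALSE)
  }
  list(by_mode = by_mode, concordance = concord)
}

.stage_fmt <- function(out, config) {
  if (!is.null(out$fmt)) {
    fmt <- out$fmt
    thresholds <- out$thresholds
  } else {
    if (is.null(config$fmt_triads) || !file.exists(config$fmt_triads)) {
      stop("FMT triad table required but not found: ", config$fmt_triads)
    }
    triads <- read_tsv(config$fmt_triads)
    fmt <- list(triads = triads, dist_sets = out$dist_sets)
    thresholds <- out$thresholds
    if (is.null(thresholds)) {
      if (is.null(config$thresholds) || !file.exists(config$thresholds)) {
        stop("thresholds table required for validate-fmt: run the ",
             "calibrate stage first or set config$thresholds")
      }
      thresholds <- read_tsv(config$thresholds)
    }
  }
  # default positive-pair policy: donor and post-FMT samples form the
  # triad (engraftment comparisons); pre-FMT samples are excluded from
  # the evaluation
  keep <- fmt$triads$role != "pre"
  triad_of <- structure(fmt$triads$triad_id[keep],
                        names = fmt$triads$sample_id[keep])
  rows <- lapply(names(fmt$dist_sets), function(sgb) {
    d <- fmt$dist_sets[[sgb]]
    # FMT species are validated against the cohort's median threshold
    # when no species-specific threshold exists for them
    th <- thresholds$threshold_ngd[thresholds$sgb_id == sgb]
    if (length(th) == 0L) th <- stats::median(thresholds$threshold_ngd)
    fmt_validate(d, th, triad_of)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

.write_sim_config <- function(sc, path) {
  flat <- unlist(sc)
  writeLines(paste(names(flat), unname(vapply(flat, as.character, "")),
                   sep = "\t"), path)
}

.write_manifest <- function(config, written) {
  vals <- config[!vapply(config, is.null, logical(1))]
  rows <- data.frame(key = names(vals),
                     value = vapply(vals, function(v)
                       paste(as.character(v), collapse = ","), ""),
                     stringsAsFactors = FALSE)
  rows <- rbind(rows,
                data.frame(key = "package_version",
                           value = as.character(utils::packageVersion("strainshare")),
                           stringsAsFactors = FALSE))
  inputs <- as.character(unlist(config[c("metadata", "snv_table")],
                                use.names = FALSE))
  inputs <- inputs[file.exists(inputs)]
  if (length(inputs)) {
    rows <- rbind(rows, data.frame(key = paste0("md5:", basename(inputs)),
                                   value = unname(tools::md5sum(inputs)),
                                   stringsAsFactors = FALSE))
  }
  write_tsv(rows, file.path(config$out_dir, "manifest.tsv"))
}
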