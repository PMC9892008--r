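#' Read a per-species phylogenetic tree from a Newick file
#'
#' Reads a StrainPhlAn-style Newick tree whose leaf labels are sample
#' identifiers and whose branch lengths are substitutions per site. The
#' returned object carries the total branch length used to normalize
#' patristic distances into nGD values.
#'
#' @param path Path to a Newick file (plain leaf labels; internal node
#'   labels are ignored; trailing whitespace tolerated).
#' @return An object of class `sgb_tree`: a list with elements `tree`
#'   (an [ape::read.tree()] `phylo` object), `n_leaves`,
#'   `total_branch_length` (sum of all branch lengths) and `degenerate`
#'   (`TRUE` when the total branch length is zero).
#' @details Malformed files fail with an error naming the byte offset of
#'   the first unbalanced parenthesis where that can be determined.
#'   Duplicate leaf labels and negative branch lengths are rejected:
#'   both make leaf-to-leaf distances ill-defined.
#' @seealso [patristic_matrix()], [normalize_ngd()]
#' @export
read_sgb_tree <- function(path) {
  if (!file.exists(path)) {
    stop("Newick file not found: ", path)
  }
  txt <- readChar(path, file.size(path), useBytes = TRUE)
  .check_newick_syntax(txt, path)
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop("Newick parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) {
    stop("Newick parse error in '", path, "': no tree could be read",
         call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("Duplicate leaf labels in '", path, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("Tree in '", path, "' has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("Negative branch length in '", path, "'", call. = FALSE)
  }
  total <- sum(tree$edge.length)
  structure(
    list(tree = tree,
         n_leaves = length(tree$tip.label),
         total_branch_length = total,
         degenerate = total == 0),
    class = "sgb_tree"
  )
}

# Minimal syntactic pre-scan so parse failures can name a byte offset:
# parenthesis balance is checked byte by byte; other dialect errors are
# left to the real parser.
.check_newick_syntax <- function(txt, path) {
  bytes <- charToRaw(txt)
  depth <- 0L
  for (i in seq_along(bytes)) {
    ch <- rawToChar(bytes[i])
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error in '", path,
             "': unbalanced ')' at byte offset ", i, call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("Newick parse error in '", path,
         "': ", depth, " unclosed '(' by byte offset ", length(bytes),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.sgb_tree <- function(x, ...) {
  cat("sgb_tree:", x$n_leaves, "leaves, total branch length",
      format(x$total_branch_length), if (x$degenerate) "(degenerate)" else "",
      "\n")
  invisible(x)
}

#' Leaf-to-leaf patristic distance matrix
#'
#' Sums of branch lengths along the unique path between every pair of
#' leaves.
#'
#' @param x An `sgb_tree` (from [read_sgb_tree()]) or an `ape` `phylo`
#'   object.
#' @return A symmetric numeric matrix with zero diagonal, rows/columns in
#'   tip-label order.
#' @export
patristic_matrix <- function(x) {
  tree <- if (inherits(x, "sgb_tree")) x$tree else x
  if (!inherits(tree, "phylo")) stop("not a phylogenetic tree")
  if (length(tree$tip.label) < 2L) {
    stop("patristic distances need at least 2 leaves")
  }
  d <- ape::cophenetic.phylo(tree)
  d <- d[tree$tip.label, tree$tip.label, drop = FALSE]
  d
}

#' Normalize patristic distances by total tree branch length (nGD)
#'
#' The normalized phylogenetic distance (nGD) of a leaf pair is its
#' patristic distance divided by the total branch length of the tree.
#' Because any leaf-to-leaf path is a subset of the tree's branches, nGD
#' always lies in \[0, 1\].
#'
#' @param patristic Symmetric patristic distance matrix.
#' @param total_branch_length Positive total branch length of the tree.
#' @return nGD matrix, same dimnames as `patristic`.
#' @export
normalize_ngd <- function(patristic, total_branch_length) {
  if (!is.numeric(total_branch_length) || length(total_branch_length) != 1L ||
      is.na(total_branch_length) || total_branch_length <= 0) {
    stop("total_branch_length must be a single positive number")
  }
  ngd <- patristic / total_branch_length
  if (any(ngd < 0 | ngd > 1 + 1e-12)) {
    stop("nGD outside [0, 1]: patristic matrix inconsistent with total branch length")
  }
  pmin(ngd, 1)
}

#' Centred nGD
#'
#' nGD divided by the median off-diagonal nGD of the same tree. Centring
#' makes distance scales comparable across species whose trees differ in
#' overall diversity: a centred nGD of 1 is a typical inter-sample
#' distance for that species.
#'
#' @param ngd Symmetric nGD matrix with at least two leaves.
#' @return Matrix of centred nGD values (diagonal remains zero).
#' @export
centred_ngd <- function(ngd) {
  if (!is.matrix(ngd) || nrow(ngd) < 2L) {
    stop("centred nGD needs a matrix over at least 2 leaves")
  }
  off <- ngd[upper.tri(ngd)]
  med <- stats::median(off)
  if (!is.finite(med) || med == 0) {
    stop("median off-diagonal nGD is zero: degenerate tree, cannot centre")
  }
  ngd / med
}

#' Build the nGD (and centred nGD) set for one species tree
#'
#' Convenience wrapper chaining [patristic_matrix()], [normalize_ngd()]
#' and [centred_ngd()] into the per-species container consumed by
#' calibration and sharing.
#'
#' @param sgb_id Species identifier (SGB id).
#' @param x `sgb_tree` object.
#' @param snv_rate Optional symmetric SNV-rate matrix over the same
#'   leaves plus food-reference genomes.
#' @return An object of class `sgb_dist`: list with `sgb_id`, `leaves`,
#'   `ngd`, `centred`, `total_branch_length`, `snv_rate`.
#' @export
sgb_distance_set <- function(sgb_id, x, snv_rate = NULL) {
  if (x$degenerate) {
    stop("tree for ", sgb_id, " has zero total branch length; ",
         "excluded from calibration and sharing")
  }
  pat <- patristic_matrix(x)
  ngd <- normalize_ngd(pat, x$total_branch_length)
  structure(
    list(sgb_id = sgb_id,
         leaves = rownames(ngd),
         ngd = ngd,
         centred = centred_ngd(ngd),
         total_branch_length = x$total_branch_length,
         snv_rate = snv_rate),
    class = "sgb_dist"
  )
}

#' @export
print.sgb_dist <- function(x, ...) {
  cat("sgb_dist", x$sgb_id, ":", length(x$leaves), "leaves, median nGD",
      format(stats::median(x$ngd[upper.tri(x$ngd)]), digits = 3), "\n")
  invisible(x)
}

#' Read all species trees in a directory
#'
#' Scans a directory for `<sgb_id>.nwk` files and builds one
#' [sgb_distance_set()] per species. Degenerate trees (zero total branch
#' length) are skipped with a warning rather than producing 0/0 nGDs.
#'
#' @param dir Directory containing `*.nwk` files.
#' @param snv_rates Optional named list of SNV-rate matrices keyed by
#'   SGB id.
#' @return Named list of `sgb_dist` objects.
#' @export
read_sgb_trees <- function(dir, snv_rates = NULL) {
  files <- sort(list.files(dir, pattern = "\\.nwk$", full.names = TRUE))
  if (length(files) == 0L) stop("no .nwk files found in ", dir)
  out <- list()
  for (f in files) {
    sgb <- sub("\\.nwk$", "", basename(f))
    tr <- read_sgb_tree(f)
    if (tr$degenerate) {
      warning("skipping ", sgb, ": zero total branch length")
      next
    }
    out[[sgb]] <- sgb_distance_set(sgb, tr, snv_rate = snv_rates[[sgb]])
  }
  out
}

#' Closest-in-time same-individual sample pairs
#'
#' For each subject with at least two strain-profiled samples, selects
#' the single pair of samples closest in time, provided their gap does
#' not exceed `max_gap_days` (default 183 days, i.e. six months). These
#' pairs represent longitudinal strain retention within an individual
#' and form the "same strain" side of threshold calibration.
#'
#' @param samples Sample metadata data.frame (see [read_metadata()]).
#' @param sgb_leaves Character vector of sample ids with a strain
#'   profile for the species.
#' @param max_gap_days Maximum allowed gap in days between the two
#'   samples of a pair.
#' @return data.frame with columns `sample_a`, `sample_b`, `subject_id`,
#'   `gap_days`; zero rows when no subject qualifies.
#' @export
select_longitudinal_pairs <- function(samples, sgb_leaves, max_gap_days = 183L) {
  s <- samples[samples$sample_id %in% sgb_leaves, , drop = FALSE]
  out <- list()
  for (subj in unique(s$subject_id)) {
    ss <- s[s$subject_id == subj, , drop = FALSE]
    if (nrow(ss) < 2L) next
    if (anyNA(ss$collection_day)) {
      stop("subject ", subj, " has multiple samples but missing collection_day")
    }
    ss <- ss[order(ss$collection_day, ss$sample_id), , drop = FALSE]
    # closest-in-time pair is always between time-adjacent samples
    gaps <- diff(ss$collection_day)
    k <- which.min(gaps)
    if (gaps[k] > max_gap_days) next
    out[[subj]] <- data.frame(
      sample_a = ss$sample_id[k],
      sample_b = ss$sample_id[k + 1L],
      subject_id = subj,
      gap_days = gaps[k],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(sample_a = character(), sample_b = character(),
                      subject_id = character(), gap_days = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$subject_id), , drop = FALSE]
}

#' Unrelated-individual sample pairs
#'
#' Enumerates cross-subject sample pairs for the "different strain" side
#' of calibration. Pairs sharing a household, or linked by a direct
#' mother/father relationship, are excluded. To avoid pseudo-replication
#' from longitudinal sampling, one sample per subject is chosen (first
#' by collection day, ties broken by sample id; with `seed` set, a
#' seeded random draw instead).
#'
#' @param samples Sample metadata data.frame.
#' @param sgb_leaves Sample ids with a strain profile for the species.
#' @param scope `"pooled"` (default; all datasets together, mirroring
#'   calibration over several longitudinal datasets) or
#'   `"within_dataset"` (only pairs inside one dataset).
#' @param seed Optional integer; when given, the representative sample
#'   of each multi-sample subject is drawn at random under this seed.
#' @return data.frame with columns `sample_a`, `sample_b`, `subject_a`,
#'   `subject_b`.
#' @export
enumerate_unrelated_pairs <- function(samples, sgb_leaves,
                                      scope = c("pooled", "within_dataset"),
                                      seed = NULL) {
  scope <- match.arg(scope)
  s <- samples[samples$sample_id %in% sgb_leaves, , drop = FALSE]
  if (nrow(s) == 0L) {
    return(data.frame(sample_a = character(), sample_b = character(),
                      subject_a = character(), subject_b = character(),
                      stringsAsFactors = FALSE))
  }
  # one representative sample per subject
  reps <- .one_sample_per_subject(s, seed)
  n <- nrow(reps)
  if (n < 2L) {
    return(data.frame(sample_a = character(), sample_b = character(),
                      subject_a = character(), subject_b = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- utils::combn(n, 2L)
  a <- idx[1L, ]; b <- idx[2L, ]
  keep <- rep(TRUE, length(a))
  if (scope == "within_dataset") {
    keep <- keep & reps$dataset_id[a] == reps$dataset_id[b]
  }
  hh_a <- reps$household_id[a]; hh_b <- reps$household_id[b]
  same_hh <- !is.na(hh_a) & !is.na(hh_b) & hh_a == hh_b
  kin <- .direct_kin(reps$subject_id[a], reps$subject_id[b],
                     reps$mother_id[a], reps$father_id[a],
                     reps$mother_id[b], reps$father_id[b])
  keep <- keep & !same_hh & !kin
  data.frame(
    sample_a = reps$sample_id[a][keep],
    sample_b = reps$sample_id[b][keep],
    subject_a = reps$subject_id[a][keep],
    subject_b = reps$subject_id[b][keep],
    stringsAsFactors = FALSE
  )
}

.one_sample_per_subject <- function(s, seed = NULL) {
  s <- s[order(s$subject_id, s$collection_day, s$sample_id), , drop = FALSE]
  if (is.null(seed)) {
    reps <- s[!duplicated(s$subject_id), , drop = FALSE]
  } else {
    set.seed(seed)
    picked <- tapply(seq_len(nrow(s)), s$subject_id,
                     function(ix) if (length(ix) == 1L) ix else sample(ix, 1L))
    reps <- s[sort(unlist(picked)), , drop = FALSE]
  }
  rownames(reps) <- NULL
  reps
}

.direct_kin <- function(subj_a, subj_b, mom_a, dad_a, mom_b, dad_b) {
  link <- function(x, y) !is.na(x) & x == y
  link(mom_a, subj_b) | link(dad_a, subj_b) |
    link(mom_b, subj_a) | link(dad_b, subj_a)
}

#' Look up pair distances in an nGD matrix
#'
#' @param dist_set An `sgb_dist` object.
#' @param pairs data.frame with `sample_a`, `sample_b` columns.
#' @param what `"ngd"` or `"centred"`.
#' @return Numeric vector of distances, one per pair row.
#' @export
pair_distances <- function(dist_set, pairs, what = c("ngd", "centred")) {
  what <- match.arg(what)
  m <- dist_set[[what]]
  if (nrow(pairs) == 0L) return(numeric(0))
  stopifnot(all(pairs$sample_a %in% rownames(m)),
            all(pairs$sample_b %in% rownames(m)))
  m[cbind(match(pairs$sample_a, rownames(m)),
          match(pairs$sample_b, rownames(m)))]
}

#' Write per-species nGD matrices as long-format TSV
#'
#' One row per unordered leaf pair, columns `sgb_id`, `sample_a`,
#' `sample_b`, `ngd`, `centred_ngd`.
#'
#' @param dist_sets Named list of `sgb_dist` objects.
#' @param path Output TSV path.
#' @export
write_ngd_long <- function(dist_sets, path) {
  rows <- lapply(dist_sets, function(d) {
    ut <- which(upper.tri(d$ngd), arr.ind = TRUE)
    ord <- order(rownames(d$ngd)[ut[, 1L]], colnames(d$ngd)[ut[, 2L]])
    ut <- ut[ord, , drop = FALSE]
    data.frame(sgb_id = d$sgb_id,
               sample_a = rownames(d$ngd)[ut[, 1L]],
               sample_b = colnames(d$ngd)[ut[, 2L]],
               ngd = d$ngd[ut],
               centred_ngd = d$centred[ut],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write_tsv(out, path)
  invisible(out)
}
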