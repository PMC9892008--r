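#' Read cohort sample metadata
#'
#' Reads a tab-separated metadata table in the layout used throughout
#' this package (one row per metagenome sample). Required columns:
#' `sample_id`, `subject_id`, `dataset_id`, `body_site` (gut/oral),
#' `collection_day`, `age_years`, `household_id`, `village_id`,
#' `mother_id`, `father_id`, `westernized`. Empty strings are read as
#' missing.
#'
#' @param path TSV file with a header row.
#' @return data.frame validated by [validate_metadata()].
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = "")
  req <- c("sample_id", "subject_id", "dataset_id", "body_site",
           "collection_day", "age_years", "household_id", "village_id",
           "mother_id", "father_id", "westernized")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  df$collection_day <- as.integer(df$collection_day)
  df$age_years <- as.numeric(df$age_years)
  df$westernized <- as.logical(df$westernized)
  validate_metadata(df)
}

#' Validate cohort metadata invariants
#'
#' Checks sample id uniqueness, the body-site vocabulary, resolvable
#' parental links, and that every subject with more than one sample has
#' collection days (needed to pick longitudinal pairs).
#'
#' @param df Metadata data.frame.
#' @return The data.frame, invisibly unchanged, or an error.
#' @export
validate_metadata <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if (!all(df$body_site %in% c("gut", "oral"))) {
    stop("body_site must be 'gut' or 'oral'")
  }
  subj <- unique(df$subject_id)
  for (col in c("mother_id", "father_id")) {
    bad <- setdiff(stats::na.omit(df[[col]]), subj)
    if (length(bad)) {
      stop(col, " references unknown subjects: ", paste(bad, collapse = ", "))
    }
  }
  multi <- names(which(table(df$subject_id) > 1L))
  for (s in multi) {
    if (anyNA(df$collection_day[df$subject_id == s])) {
      stop("subject ", s, " has >1 sample but missing collection_day")
    }
  }
  df
}

#' Per-subject attribute table
#'
#' Collapses sample-level metadata to one row per subject (attributes
#' constant within a subject; age is taken at the earliest sample).
#'
#' @param samples Metadata data.frame.
#' @return data.frame keyed by `subject_id`.
#' @export
subject_table <- function(samples) {
  s <- samples[order(samples$subject_id, samples$collection_day,
                     samples$sample_id), , drop = FALSE]
  first <- s[!duplicated(s$subject_id), , drop = FALSE]
  out <- first[, c("subject_id", "dataset_id", "household_id", "village_id",
                   "mother_id", "father_id", "age_years", "westernized"),
               drop = FALSE]
  rownames(out) <- out$subject_id
  out
}

# Shared TSV writers: tab-separated, header, empty string for NA, no
# quoting (identifiers never contain tabs), deterministic row order is
# the caller's job.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "",
                    stringsAsFactors = FALSE, ...)
}
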