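#' Read a recording from a plain numeric CSV matrix
#'
#' @param path CSV file of numbers, no header, rows = channels by default
#' @param fs sampling rate in Hz
#' @param labels channel names (length must match the channel count)
#' @param channels_in `"rows"` (default) or `"cols"`
#' @return a [recording()]
#' @export
read_matrix_csv <- function(path, fs, labels = NULL, channels_in = c("rows", "cols")) {
  channels_in <- match.arg(channels_in)
  raw <- tryCatch(
    utils::read.csv(path, header = FALSE, colClasses = "numeric"),
    error = function(e) abort_netsig(
      sprintf("Failed to parse numeric CSV matrix: %s", conditionMessage(e)),
      "netsig_format_error")
  )
  m <- as.matrix(raw)
  if (anyNA(m)) {
    abort_netsig("Non-numeric or missing cells in the CSV matrix.", "netsig_format_error")
  }
  if (channels_in == "cols") m <- t(m)
  recording(m, fs = fs, labels = labels, meta = list(source = path, format = "csv"))
}

#' Write a recording to a plain CSV matrix (rows = channels)
#'
#' @param rec a [recording()]
#' @param path output path
#' @export
write_matrix_csv <- function(rec, path) {
  stopifnot(inherits(rec, "netsig_recording"))
  utils::write.table(rec$data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Expected clinical covariate columns
#'
#' Column dictionary for the per-subject clinical table: outcome plus the
#' binary and numeric predictors commonly reported for drug-resistance risk.
#' @return tibble with columns `column`, `type`, `description`
#' @export
clinical_dictionary <- function() {
  tibble::tribble(
    ~column, ~type, ~description,
    "subject_id", "character", "unique subject identifier",
    "outcome", "integer", "1 = drug-resistant (DRE-like), 0 = responder",
    "sex_female", "binary", "1 = female",
    "age", "numeric", "age at EEG, years",
    "age_onset", "numeric", "age at epilepsy onset, years",
    "duration", "numeric", "epilepsy duration, years",
    "baseline_seizure_freq", "numeric", "seizures per 3 months before first ASM",
    "n_seizure_types", "integer", "number of distinct seizure types",
    "focal", "binary", "1 = focal-onset epilepsy",
    "structural_etiology", "binary", "1 = structural etiology",
    "neuroimaging_abnormal", "binary", "1 = any neuroimaging abnormality",
    "sba", "binary", "1 = structural brain abnormality present (pSBA)",
    "etle", "binary", "1 = extratemporal epilepsy (0 = temporal)",
    "asm1_response", "binary", "1 = >=50% seizure reduction on first ASM"
  )
}

#' Read and validate a clinical covariate table
#'
#' @param path CSV with a header; see [clinical_dictionary()] for the
#'   expected columns. Extra columns are kept.
#' @return a tibble, one row per subject
#' @export
read_clinical_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_clinical(df)
}

validate_clinical <- function(df) {
  dict <- clinical_dictionary()
  missing_cols <- setdiff(c("subject_id", "outcome"), names(df))
  if (length(missing_cols)) {
    abort_netsig(paste("Clinical table is missing columns:",
                       paste(missing_cols, collapse = ", ")),
                 "netsig_format_error")
  }
  if (anyNA(df$outcome) || !all(df$outcome %in% c(0, 1))) {
    abort_netsig("`outcome` must be 0/1 with no missing values.",
                 "netsig_format_error")
  }
  if (anyDuplicated(df$subject_id)) {
    abort_netsig("`subject_id` must be unique.", "netsig_format_error")
  }
  bin_cols <- intersect(dict$column[dict$type == "binary"], names(df))
  for (cl in bin_cols) {
    v <- df[[cl]]
    if (!all(v[!is.na(v)] %in% c(0, 1))) {
      abort_netsig(sprintf("Column `%s` must be coded 0/1.", cl),
                   "netsig_format_error")
    }
  }
  tibble::as_tibble(df)
}
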