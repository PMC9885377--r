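#' Assemble a labeled feature table
#'
#' The central tabular container of the package: one row per sample, feature
#' columns named `feature_0 ... feature_{p-1}`, a binary `label`, a
#' `patient_id` grouping key, an optional `source_id` (acquisition source),
#' and a `provenance_id` linking duplicated or augmented rows back to the
#' original sample they were derived from. For an untransformed sample the
#' provenance id is its own sample identifier.
#'
#' @param features Numeric matrix, `n_samples x n_features`.
#' @param label Binary (0/1) vector of length `n_samples`.
#' @param patient_id Character vector of patient identifiers, one per row.
#' @param source_id Optional character vector of source identifiers
#'   (`NA` when samples have a single, anonymous source).
#' @param provenance_id Character vector of provenance identifiers. Defaults
#'   to a fresh unique identifier per row (i.e. every row is its own origin).
#' @return A tibble with columns `feature_0 ... feature_{p-1}`, `label`,
#'   `patient_id`, `source_id`, `provenance_id`.
#' @examples
#' x <- labeled_table(matrix(rnorm(12), 4), c(0, 1, 0, 1), paste0("P", 1:4))
#' feature_matrix(x)
#' @export
labeled_table <- function(features, label, patient_id,
                          source_id = NA_character_,
                          provenance_id = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (is.null(provenance_id)) {
    provenance_id <- sprintf("s%05d", seq_len(n))
  }
  out <- tibble::as_tibble(features, .name_repair = "minimal")
  names(out) <- sprintf("feature_%d", seq_len(ncol(features)) - 1L)
  out$label <- as.integer(label)
  out$patient_id <- as.character(patient_id)
  out$source_id <- rep_len(as.character(source_id), n)
  out$provenance_id <- as.character(provenance_id)
  validate_labeled_table(out)
}

#' Validate a labeled feature table
#'
#' Checks the structural invariants: consistent column lengths (guaranteed by
#' the data frame), labels in \{0, 1\}, non-empty patient ids, and presence of
#' the bookkeeping columns.
#'
#' @param table A data frame in `labeled_table` layout.
#' @return The table, invisibly coerced to a tibble, or an error.
#' @export
validate_labeled_table <- function(table) {
  table <- tibble::as_tibble(table)
  need <- c("label", "patient_id", "provenance_id")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0) {
    stop("labeled table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"source_id" %in% names(table)) table$source_id <- NA_character_
  if (length(feature_names(table)) == 0) {
    stop("labeled table has no feature_* columns", call. = FALSE)
  }
  if (!all(table$label %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  if (anyNA(table$patient_id) || any(!nzchar(table$patient_id))) {
    stop("every sample needs a nonempty patient_id", call. = FALSE)
  }
  table
}

feature_names <- function(table) {
  grep("^feature_\\d+$", names(table), value = TRUE)
}

#' Extract the feature matrix from a labeled table
#'
#' @param table A labeled table.
#' @return Numeric matrix of the `feature_*` columns, in index order.
#' @export
feature_matrix <- function(table) {
  nm <- feature_names(table)
  nm <- nm[order(as.integer(sub("^feature_", "", nm)))]
  as.matrix(table[nm])
}

#' Read / write labeled tables as CSV
#'
#' Round-trips the `labeled_table` layout through a plain CSV file with
#' columns `feature_0 ... feature_{p-1}, label, patient_id, source_id,
#' provenance_id`.
#'
#' @param table A labeled table.
#' @param path File path.
#' @return `write_labeled_table` returns `path` invisibly;
#'   `read_labeled_table` returns a validated tibble.
#' @export
write_labeled_table <- function(table, path) {
  table <- validate_labeled_table(table)
  ord <- c(feature_names(table), "label", "patient_id", "source_id", "provenance_id")
  readr::write_csv(table[ord], path)
  invisible(path)
}

#' @rdname write_labeled_table
#' @export
read_labeled_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  raw$label <- as.integer(raw$label)
  raw$patient_id <- as.character(raw$patient_id)
  raw$source_id <- as.character(raw$source_id)
  raw$provenance_id <- as.character(raw$provenance_id)
  validate_labeled_table(raw)
}

# Deterministic sub-stream seeds: fold offsets into a 31-bit state so that
# every generator / repetition / arm gets its own reproducible seed derived
# from one master seed.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.numeric(seed) %% 2147483563
  for (o in offs) s <- (s * 69069 + as.numeric(o)) %% 2147483563
  as.integer(s) + 1L
}
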