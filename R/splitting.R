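#' Random row-level three-way split
#'
#' Partitions rows uniformly at random into train/validation/test at the
#' requested ratios, using largest-remainder rounding so the subset sizes
#' are exact and deterministic. Row-level splitting ignores patient and
#' provenance structure — the pitfall the group-coherent variant avoids.
#'
#' @param table A labeled table.
#' @param ratios Named or unnamed numeric vector of three fractions
#'   (train, val, test) summing to 1.
#' @param seed Integer seed.
#' @return A `split_assignment`: a tibble with columns `row` and `subset`
#'   (factor train/val/test), carrying `ratios`, `grouped` and `group_key`
#'   attributes.
#' @export
split_random <- function(table, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  table <- validate_labeled_table(table)
  ratios <- check_ratios(ratios)
  n <- nrow(table)
  if (n == 0) stop("cannot split an empty table", call. = FALSE)
  sizes <- largest_remainder(n, ratios)
  subset <- withr::with_seed(seed, {
    lab <- rep(factor(c("train", "val", "test"), levels = c("train", "val", "test")),
               times = sizes)
    lab[order(sample.int(n))]
  })
  new_split_assignment(subset, ratios, grouped = FALSE, group_key = NA_character_)
}

#' Group-coherent three-way split
#'
#' Partitions *groups* (patients, or provenance lineages) rather than rows:
#' all rows sharing the group key land in the same subset, so no group can
#' span train and test. Group counts per subset follow largest-remainder
#' rounding of the ratios.
#'
#' @inheritParams split_random
#' @param group_key Column to enforce coherence on, `"patient_id"` (default)
#'   or `"provenance_id"`.
#' @return A `split_assignment` with `grouped = TRUE`.
#' @export
split_grouped <- function(table, ratios = c(0.6, 0.2, 0.2),
                          group_key = "patient_id", seed = 1L) {
  table <- validate_labeled_table(table)
  ratios <- check_ratios(ratios)
  if (!group_key %in% names(table)) {
    stop("group_key column not present: ", group_key, call. = FALSE)
  }
  groups <- sort(unique(table[[group_key]]))
  g <- length(groups)
  if (g < sum(ratios > 0)) {
    stop("infeasible split: fewer groups (", g, ") than nonzero-ratio subsets",
         call. = FALSE)
  }
  sizes <- largest_remainder(g, ratios)
  lev <- factor(c("train", "val", "test"), levels = c("train", "val", "test"))
  group_subset <- withr::with_seed(seed, {
    lab <- rep(lev, times = sizes)
    lab[order(sample.int(g))]
  })
  names(group_subset) <- groups
  subset <- group_subset[table[[group_key]]]
  new_split_assignment(unname(subset), ratios, grouped = TRUE, group_key = group_key)
}

new_split_assignment <- function(subset, ratios, grouped, group_key) {
  out <- tibble::tibble(row = seq_along(subset), subset = subset)
  attr(out, "ratios") <- ratios
  attr(out, "grouped") <- grouped
  attr(out, "group_key") <- group_key
  class(out) <- c("split_assignment", class(out))
  out
}

check_ratios <- function(ratios) {
  ratios <- as.numeric(ratios)
  if (length(ratios) != 3 || any(ratios < 0)) {
    stop("ratios must be three non-negative fractions", call. = FALSE)
  }
  if (abs(sum(ratios) - 1) > 1e-9) {
    stop("ratios must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  ratios
}

# Exact deterministic apportionment: floor quotas, then distribute the
# remaining units by largest fractional remainder, earlier subset wins ties.
largest_remainder <- function(n, ratios) {
  quota <- n * ratios
  sizes <- floor(quota)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- quota - sizes
    ord <- order(-frac, seq_along(ratios))
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1
  }
  as.integer(sizes)
}

#' Materialize a split assignment into subset tables
#'
#' @param table The labeled table the assignment was computed on.
#' @param assignment A `split_assignment`.
#' @return A named list of tibbles `train`, `val`, `test`.
#' @export
apply_split <- function(table, assignment) {
  stopifnot(inherits(assignment, "split_assignment"),
            nrow(assignment) == nrow(table))
  lapply(stats::setNames(nm = c("train", "val", "test")), function(s) {
    table[assignment$row[assignment$subset == s], , drop = FALSE]
  })
}

#' Oversample the minority class to exact balance
#'
#' Duplicates minority-class rows, sampled with replacement, until both
#' classes have equal counts. Duplicates keep the origin row's
#' `provenance_id` (and all other fields), which is what lets the leakage
#' auditor detect copies of the same sample landing in different subsets
#' when oversampling is done before splitting.
#'
#' @param table A labeled table with both classes present.
#' @param seed Integer seed.
#' @return The balanced table (original rows first, then duplicates).
#' @export
oversample <- function(table, seed = 1L) {
  table <- validate_labeled_table(table)
  counts <- table(factor(table$label, levels = c(0L, 1L)))
  if (any(counts == 0)) {
    stop("cannot balance a single-class table", call. = FALSE)
  }
  deficit <- abs(counts[["1"]] - counts[["0"]])
  if (deficit == 0) return(table)
  minority <- if (counts[["1"]] < counts[["0"]]) 1L else 0L
  idx <- which(table$label == minority)
  extra <- withr::with_seed(seed, sample(idx, deficit, replace = TRUE))
  dplyr::bind_rows(table, table[extra, , drop = FALSE])
}

#' Augment a table with jittered copies
#'
#' Appends `copies_per_sample` perturbed copies of every row: copy features
#' are the origin features plus i.i.d. Gaussian noise of SD `jitter_sigma`;
#' label, patient id and the origin's `provenance_id` are inherited.
#'
#' @param table A labeled table.
#' @param copies_per_sample Number of copies per row (>= 0).
#' @param jitter_sigma SD of the additive feature noise (>= 0).
#' @param seed Integer seed.
#' @return A table with `n * (1 + copies_per_sample)` rows.
#' @export
augment <- function(table, copies_per_sample = 1, jitter_sigma = 0.1, seed = 1L) {
  table <- validate_labeled_table(table)
  if (copies_per_sample < 0) stop("copies_per_sample must be >= 0", call. = FALSE)
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0", call. = FALSE)
  if (copies_per_sample == 0) return(table)
  n <- nrow(table)
  fn <- feature_names(table)
  copies <- table[rep(seq_len(n), times = copies_per_sample), , drop = FALSE]
  noise <- withr::with_seed(seed, {
    matrix(stats::rnorm(nrow(copies) * length(fn), sd = jitter_sigma),
           nrow(copies), length(fn))
  })
  copies[fn] <- copies[fn] + noise
  dplyr::bind_rows(table, copies)
}

#' Rank features by a two-sample t statistic
#'
#' Scores every feature by the absolute pooled-variance two-sample
#' t statistic between the classes and returns the indices of the top `k`,
#' highest score first, ties broken toward the lower index. A feature with
#' zero variance in both classes and equal class means scores 0; zero
#' pooled variance with unequal means scores infinite (it predicts the
#' label exactly).
#'
#' @param table A labeled table with both classes present.
#' @param k Number of features to return (<= number of features).
#' @return Integer vector of 1-based feature indices (index `i` is column
#'   `feature_{i-1}`), length `k`, in rank order.
#' @export
select_top_features <- function(table, k) {
  table <- validate_labeled_table(table)
  x <- feature_matrix(table)
  if (k > ncol(x)) stop("k exceeds the number of features", call. = FALSE)
  y <- table$label
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  scores <- feature_t_scores(x, y)
  ord <- order(-scores, seq_along(scores))
  ord[seq_len(k)]
}

# Vectorized pooled-variance two-sample t per column.
feature_t_scores <- function(x, y) {
  i1 <- y == 1L
  n1 <- sum(i1); n0 <- sum(!i1)
  m1 <- colMeans(x[i1, , drop = FALSE])
  m0 <- colMeans(x[!i1, , drop = FALSE])
  ss1 <- colSums(sweep(x[i1, , drop = FALSE], 2, m1)^2)
  ss0 <- colSums(sweep(x[!i1, , drop = FALSE], 2, m0)^2)
  sp <- sqrt((ss1 + ss0) / (n1 + n0 - 2))
  denom <- sp * sqrt(1 / n1 + 1 / n0)
  t <- abs(m1 - m0) / denom
  t[denom == 0 & m1 == m0] <- 0
  t[denom == 0 & m1 != m0] <- Inf
  t
}

#' Ordering policy for a split-time transform
#'
#' Captures which transform (oversampling, augmentation, feature selection,
#' or none) is applied and whether it runs before the data split (the
#' leaky ordering) or after it, on training rows only.
#'
#' @param transform One of `"none"`, `"oversample"`, `"augment"`,
#'   `"select_features"`.
#' @param when `"before_split"` or `"after_split"`.
#' @return A list of class `ordering_policy`.
#' @export
ordering_policy <- function(transform = c("none", "oversample", "augment",
                                          "select_features"),
                            when = c("after_split", "before_split")) {
  structure(list(transform = match.arg(transform), when = match.arg(when)),
            class = "ordering_policy")
}

#' Split a table under an explicit transform ordering
#'
#' The workhorse behind the paired experiments. With `when =
#' "before_split"` the transform is applied to the full table and the
#' result is then split — the ordering that leaks duplicated/correlated
#' rows across subsets. With `when = "after_split"` the table is split
#' first and the transform sees training rows only; for feature selection
#' the indices chosen on the training set are then applied to validation
#' and test.
#'
#' @param table A labeled table.
#' @param policy An [ordering_policy()].
#' @param split_kind `"random"` (row-level) or `"grouped"`.
#' @param ratios Three split fractions summing to 1.
#' @param group_key Group column for `split_kind = "grouped"`.
#' @param k Number of features kept by `"select_features"`.
#' @param copies_per_sample,jitter_sigma Parameters of `"augment"`.
#' @param seed Integer seed covering the split and the transform.
#' @return A list with tibbles `train`, `val`, `test` and `audit`, the
#'   [leakage_audit()] of the three subsets.
#' @export
materialize <- function(table, policy = ordering_policy(),
                        split_kind = c("random", "grouped"),
                        ratios = c(0.6, 0.2, 0.2),
                        group_key = "patient_id", k = NULL,
                        copies_per_sample = 1, jitter_sigma = 0.1,
                        seed = 1L) {
  split_kind <- match.arg(split_kind)
  stopifnot(inherits(policy, "ordering_policy"))
  table <- validate_labeled_table(table)
  split_seed <- derive_seed(seed, 1L)
  tf_seed <- derive_seed(seed, 2L)

  do_split <- function(tbl) {
    a <- switch(split_kind,
                random = split_random(tbl, ratios, seed = split_seed),
                grouped = split_grouped(tbl, ratios, group_key, seed = split_seed))
    apply_split(tbl, a)
  }
  transform_full <- function(tbl) {
    switch(policy$transform,
           none = tbl,
           oversample = oversample(tbl, seed = tf_seed),
           augment = augment(tbl, copies_per_sample, jitter_sigma, seed = tf_seed),
           select_features = project_features(tbl, select_top_features(tbl, k)))
  }

  if (policy$when == "before_split") {
    parts <- do_split(transform_full(table))
  } else {
    parts <- do_split(table)
    if (policy$transform == "select_features") {
      keep <- select_top_features(parts$train, k)
      parts <- lapply(parts, project_features, keep = keep)
    } else {
      parts$train <- transform_full(parts$train)
    }
  }
  c(parts, list(audit = leakage_audit(parts$train, parts$val, parts$test)))
}

# Keep the selected feature columns (renumbered 0..k-1 in rank order) plus
# the bookkeeping columns.
project_features <- function(table, keep) {
  nm <- feature_names(table)
  nm <- nm[order(as.integer(sub("^feature_", "", nm)))]
  out <- table[c(nm[keep], "label", "patient_id", "source_id", "provenance_id")]
  names(out)[seq_along(keep)] <- sprintf("feature_%d", seq_along(keep) - 1L)
  out
}

#' Count identifiers spanning more than one subset
#'
#' The leakage auditor: counts provenance ids and patient ids that occur in
#' at least two of train/val/test. Both counts are zero exactly when
#' independence holds at the duplicate (provenance) and patient level.
#'
#' @param train,val,test Labeled tables sharing a schema.
#' @return A one-row tibble with integer columns `provenance_spanning` and
#'   `patient_spanning`.
#' @export
leakage_audit <- function(train, val, test) {
  span_count <- function(col) {
    ids <- list(unique(train[[col]]), unique(val[[col]]), unique(test[[col]]))
    tab <- table(unlist(ids))
    sum(tab >= 2)
  }
  tibble::tibble(provenance_spanning = span_count("provenance_id"),
                 patient_spanning = span_count("patient_id"))
}
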