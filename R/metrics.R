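#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Binary (0/1) vectors of equal length >= 1.
#' @return A list of class `confusion_counts` with integer fields `tp`,
#'   `fp`, `fn`, `tn` summing to the number of samples.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (length(y_true) < 1) stop("need at least one sample", call. = FALSE)
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  structure(list(tp = sum(y_true == 1L & y_pred == 1L),
                 fp = sum(y_true == 0L & y_pred == 1L),
                 fn = sum(y_true == 1L & y_pred == 0L),
                 tn = sum(y_true == 0L & y_pred == 0L)),
            class = "confusion_counts")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Precision is computed for the positive class (in imbalanced problems,
#' the minority of interest). A metric whose denominator is zero is
#' undefined and reported as `NA`; aggregation helpers treat it as 0 with a
#' warning.
#'
#' @param counts A [confusion()] result.
#' @return A one-row tibble with columns `accuracy`, `precision`, `recall`,
#'   `f1`, each in \[0, 1\] or `NA` when undefined.
#' @export
classification_report <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$fn + counts$tn
  if (total <= 0) stop("no evaluated samples", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(counts$tp, counts$tp + counts$fp)
  recall <- safe_div(counts$tp, counts$tp + counts$fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    if (isTRUE(precision == 0) || isTRUE(recall == 0)) 0 else NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(accuracy = (counts$tp + counts$tn) / total,
                 precision = precision, recall = recall, f1 = f1)
}

#' Accuracy of the always-majority-class predictor
#'
#' The naive baseline that predicts every sample as the majority class:
#' its accuracy equals the majority-class frequency, which is why accuracy
#' is a misleading indicator under class imbalance (a 6% prevalence gives
#' the useless baseline 94% accuracy and zero recall).
#'
#' @param labels Nonempty binary vector.
#' @return The majority-class frequency, a fraction in \[0.5, 1\].
#' @export
majority_accuracy <- function(labels) {
  if (length(labels) < 1) stop("labels must be nonempty", call. = FALSE)
  max(mean(labels == 1), mean(labels == 0))
}

#' Dice and IoU overlap of two masks
#'
#' `dice` is `2|X & Y| / (|X| + |Y|)`; `iou` (Jaccard) is
#' `|X & Y| / (X | Y)`. Both are 1 for identical nonempty masks and 0 for
#' disjoint nonempty masks; two empty masks are scored 1 by convention
#' (perfect agreement). Dice is never below IoU, and the two are linked by
#' `dice = 2 * iou / (1 + iou)`.
#'
#' @param x,y Logical arrays of identical shape (any dimensionality).
#' @return A fraction in \[0, 1\].
#' @export
dice <- function(x, y) {
  check_masks(x, y)
  s <- sum(x) + sum(y)
  if (s == 0) return(1)
  2 * sum(x & y) / s
}

#' @rdname dice
#' @export
iou <- function(x, y) {
  check_masks(x, y)
  u <- sum(x | y)
  if (u == 0) return(1)
  sum(x & y) / u
}

check_masks <- function(x, y) {
  dx <- if (is.null(dim(x))) length(x) else dim(x)
  dy <- if (is.null(dim(y))) length(y) else dim(y)
  if (!identical(dx, dy)) stop("masks must have the same shape", call. = FALSE)
  invisible(TRUE)
}

#' Convert an IoU value to the equivalent Dice score
#'
#' The two overlap measures are in bijection: `dice = 2 * iou / (1 + iou)`.
#' Since the map is increasing and lies above the identity on (0, 1), Dice
#' always looks at least as good as IoU for the same segmentation.
#'
#' @param j IoU value in \[0, 1\].
#' @return The corresponding Dice score.
#' @export
dice_from_iou <- function(j) {
  if (any(j < 0 | j > 1)) stop("iou must lie in [0, 1]", call. = FALSE)
  2 * j / (1 + j)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum test of a location difference between two samples. The reported
#' statistic is always the standardized z of the first sample's rank sum
#' (with tie and continuity correction). For small untied samples
#' (`n1 + n2 <= 30`, no tied values) the p-value is computed from the exact
#' permutation distribution of the rank sum, obtained by a subset-sum
#' counting recursion; otherwise the normal approximation with tie and
#' continuity correction is used — mirroring the behaviour of standard
#' scientific libraries, which the exact route makes verifiable at small n.
#'
#' @param a,b Numeric vectors, each nonempty.
#' @return A list with `statistic` (z) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both samples must be nonempty", call. = FALSE)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    stop("degenerate variance: all values identical across both samples",
         call. = FALSE)
  }
  d <- w - mu
  z <- if (d == 0) 0 else (d - 0.5 * sign(d)) / sqrt(sigma2)
  p <- if (tie_term == 0 && n <= 30) {
    exact_ranksum_p(n, n1, w)
  } else {
    min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = z, p_value = p)
}

# Exact two-sided p for the untied rank-sum statistic: count, for every
# attainable rank sum s, the number of size-n1 subsets of {1..n} summing to
# s (dynamic programme over values), then sum the probability of outcomes
# at least as far from the mean as observed.
exact_ranksum_p <- function(n, n1, w) {
  smax <- n * (n + 1) / 2
  f <- matrix(0, n1 + 1, smax + 1)
  f[1, 1] <- 1
  for (v in seq_len(n)) {
    for (k in rev(seq_len(min(n1, v)))) {
      cols <- (v + 1):(smax + 1)
      f[k + 1, cols] <- f[k + 1, cols] + f[k, cols - v]
    }
  }
  counts <- f[n1 + 1, ]
  sums <- 0:smax
  mu <- n1 * (n + 1) / 2
  sum(counts[abs(sums - mu) >= abs(w - mu) - 1e-9]) / choose(n, n1)
}

#' Min / mean / max / SD summary of a score vector
#'
#' @param values Nonempty numeric vector.
#' @return A one-row tibble with `min`, `mean`, `max`, `sd` (sample SD,
#'   n-1 denominator; 0 for a single value).
#' @export
summarize_scores <- function(values) {
  if (length(values) < 1) stop("values must be nonempty", call. = FALSE)
  tibble::tibble(min = min(values), mean = mean(values), max = max(values),
                 sd = if (length(values) == 1) 0 else stats::sd(values))
}

# Undefined (NA) metrics are treated as 0 in aggregates, with one warning.
fill_undefined <- function(x, what = "metric") {
  if (anyNA(x)) {
    warning(sum(is.na(x)), " undefined ", what,
            " value(s) treated as 0 in aggregation", call. = FALSE)
    x[is.na(x)] <- 0
  }
  x
}
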