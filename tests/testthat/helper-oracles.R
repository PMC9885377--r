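# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity.

# Loop-count confusion tallies.
oracle_confusion <- function(y_true, y_pred) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1L
    else if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1L
    else if (y_true[i] == 1 && y_pred[i] == 0) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Exact two-sided permutation p-value for the rank-sum statistic:
# enumerate every assignment of n1 of the pooled values to the first sample
# and count assignments at least as extreme (in |W - E[W]|) as observed.
oracle_wilcoxon_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  n1 <- length(a)
  r <- rank(pooled)
  mu <- n1 * (n + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  splits <- utils::combn(n, n1)
  w <- apply(splits, 2, function(idx) sum(r[idx]))
  mean(abs(w - mu) >= obs - 1e-12)
}

# Brute-force feature ranking by pooled-variance two-sample t, computed
# feature-by-feature with explicit arithmetic.
oracle_t_ranking <- function(x, y) {
  scores <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    a <- v[y == 1]; b <- v[y == 0]
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
      (length(a) + length(b) - 2)
    den <- sqrt(sp2) * sqrt(1 / length(a) + 1 / length(b))
    if (den == 0) {
      if (mean(a) == mean(b)) 0 else Inf
    } else {
      abs(mean(a) - mean(b)) / den
    }
  }, numeric(1))
  order(-scores, seq_along(scores))
}

# Breadth-first flood fill: remove TRUE components touching any grid face.
oracle_remove_border_air <- function(air, connectivity = 6) {
  d <- dim(air)
  offsets <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    as.matrix(expand.grid(-1:1, -1:1, -1:1))[-14, ]
  }
  visited <- array(FALSE, d)
  idx <- which(air, arr.ind = TRUE)
  on_border <- idx[idx[, 1] %in% c(1, d[1]) | idx[, 2] %in% c(1, d[2]) |
                     idx[, 3] %in% c(1, d[3]), , drop = FALSE]
  queue <- lapply(seq_len(nrow(on_border)), function(i) on_border[i, ])
  for (q in queue) visited[q[1], q[2], q[3]] <- TRUE
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    for (k in seq_len(nrow(offsets))) {
      nb <- v + offsets[k, ]
      if (all(nb >= 1) && all(nb <= d) &&
          air[nb[1], nb[2], nb[3]] && !visited[nb[1], nb[2], nb[3]]) {
        visited[nb[1], nb[2], nb[3]] <- TRUE
        queue[[length(queue) + 1]] <- nb
      }
    }
  }
  air & !visited
}

# Expected F1 when predictions are independent of the truth, conditional on
# the margins: E[TP] = m * n1 / n (hypergeometric), F1 = 2 TP / (m + n1).
oracle_chance_f1 <- function(tp, fp, fn, tn) {
  m <- tp + fp
  n1 <- tp + fn
  n <- tp + fp + fn + tn
  ifelse(m + n1 == 0, 0, 2 * m * n1 / (n * (m + n1)))
}

# Random logical array for mask property tests.
random_mask <- function(dim3, p = 0.5) {
  array(stats::runif(prod(dim3)) < p, dim3)
}

# A tiny fully worked labeled table used by splitting/metrics tests.
tiny_table <- function(n = 10, p = 3, n_pos = 3, seed = 42) {
  withr::with_seed(seed, {
    labeled_table(matrix(stats::rnorm(n * p), n, p),
                  label = c(rep(1L, n_pos), rep(0L, n - n_pos)),
                  patient_id = sprintf("P%02d", seq_len(n)))
  })
}
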