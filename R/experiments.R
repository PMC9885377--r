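#' Configure a paired pitfall-vs-correct experiment
#'
#' An experiment pairs two model-building pipelines that differ only in the
#' ordering of one step (or the split kind): the *pitfall* arm applies the
#' transform before data splitting (or splits rows of grouped data at
#' random), the *correct* arm applies it after splitting, to training rows
#' only (or splits group-coherently). Each repetition generates a fresh
#' dataset consumed by both arms, trains the classifier, and records
#' test-set metrics; the two F1 vectors are compared with the Wilcoxon
#' rank-sum test.
#'
#' Default generator configurations are the package's documented study
#' conditions: null-signal data (no true class signal), so that any
#' difference between the arms is attributable to leakage alone.
#'
#' @param kind One of `"oversampling"`, `"augmentation"`,
#'   `"patient_split"`, `"feature_selection"`, `"batch_effect"`, or
#'   `"none"` (identical null arms, used for calibration).
#' @param data A generator config ([tabular_config()], [patch_config()] or
#'   [batch_config()]; defaults chosen per `kind`), or a function
#'   `function(seed)` returning a labeled table (useful for injecting a
#'   recording generator in tests).
#' @param repetitions Number of paired repetitions (default 100).
#' @param classifier `"nn1"` (1-nearest-neighbor, default: memorization
#'   makes duplicate leakage maximally visible), `"random_forest"`, or
#'   `"logistic"`.
#' @param ratios Train/val/test fractions (default 60/20/20; the validation
#'   split is created but unused — no hyperparameter tuning).
#' @param k Features kept by feature selection.
#' @param copies_per_sample,jitter_sigma Augmentation parameters.
#' @param seed Master seed; all per-repetition and per-arm streams are
#'   derived from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(kind = c("oversampling", "augmentation",
                                       "patient_split", "feature_selection",
                                       "batch_effect", "none"),
                              data = NULL, repetitions = 100,
                              classifier = c("nn1", "random_forest", "logistic"),
                              ratios = c(0.6, 0.2, 0.2), k = 10,
                              copies_per_sample = 3, jitter_sigma = 0.1,
                              seed = 1L) {
  kind <- match.arg(kind)
  classifier <- match.arg(classifier)
  if (repetitions < 1) stop("repetitions must be >= 1", call. = FALSE)
  if (is.null(data)) {
    data <- switch(kind,
      oversampling = tabular_config(n_patients = 100, n_features = 10,
                                    class_fraction = 0.1, signal_strength = 0),
      augmentation = tabular_config(n_patients = 100, n_features = 10,
                                    class_fraction = 0.5, signal_strength = 0),
      none = tabular_config(n_patients = 100, n_features = 10,
                            class_fraction = 0.5, signal_strength = 0),
      feature_selection = tabular_config(n_patients = 100, n_features = 1000,
                                         class_fraction = 0.5, signal_strength = 0),
      patient_split = patch_config(n_patients = 20, patches_per_patient = 50,
                                   signature_strength = 3, class_signal = 0),
      batch_effect = batch_config()
    )
  }
  structure(list(kind = kind, data = data,
                 repetitions = as.integer(repetitions),
                 classifier = classifier, ratios = check_ratios(ratios),
                 k = as.integer(k),
                 copies_per_sample = as.integer(copies_per_sample),
                 jitter_sigma = jitter_sigma, seed = as.integer(seed)),
            class = "experiment_config")
}

# Regenerate the configured dataset under a derived seed.
generate_data <- function(data, seed) {
  if (is.function(data)) return(validate_labeled_table(data(seed)))
  data$seed <- seed
  switch(class(data)[1],
         tabular_config = gen_tabular(data),
         patch_config = gen_patient_patches(data),
         stop("unsupported generator config: ", class(data)[1], call. = FALSE))
}

#' Train a classifier and score it on a test set
#'
#' Features are standardized using training-set statistics only (a zero
#' training SD is treated as 1). The classifier is deterministic given the
#' seed.
#'
#' @param train,test Labeled tables sharing a feature schema; the training
#'   set must contain both classes.
#' @param classifier `"nn1"`, `"random_forest"` or `"logistic"`.
#' @param seed Integer seed.
#' @return A one-row tibble as from [classification_report()].
#' @export
train_and_score <- function(train, test, classifier = "nn1", seed = 1L) {
  pred <- predict_labels(train, test, classifier, seed)
  classification_report(confusion(test$label, pred))
}

predict_labels <- function(train, newdata, classifier, seed) {
  if (length(unique(train$label)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  xtr <- feature_matrix(train)
  xte <- feature_matrix(newdata)
  mu <- colMeans(xtr)
  sdev <- apply(xtr, 2, stats::sd)
  sdev[sdev == 0 | is.na(sdev)] <- 1
  xtr <- sweep(sweep(xtr, 2, mu), 2, sdev, "/")
  xte <- sweep(sweep(xte, 2, mu), 2, sdev, "/")
  y <- factor(train$label, levels = c(0L, 1L))
  withr::with_seed(seed, {
    switch(classifier,
      nn1 = as.integer(as.character(class::knn(xtr, xte, y, k = 1))),
      random_forest = {
        fit <- randomForest::randomForest(xtr, y, ntree = 200)
        as.integer(as.character(stats::predict(fit, xte)))
      },
      logistic = {
        df <- as.data.frame(xtr); df$.y <- train$label
        fit <- suppressWarnings(
          stats::glm(.y ~ ., data = df, family = stats::binomial())
        )
        p <- suppressWarnings(
          stats::predict(fit, as.data.frame(xte), type = "response")
        )
        as.integer(p > 0.5)
      },
      stop("unknown classifier: ", classifier, call. = FALSE))
  })
}

# Build pitfall/correct arm tables for one generated dataset. Returns the
# two test-set metric rows, or NULL when a split is degenerate.
run_arms_once <- function(table, config, rep_seed) {
  cls_seed <- derive_seed(rep_seed, 3L)
  arm_spec <- switch(config$kind,
    oversampling = list(
      pitfall = list(policy = ordering_policy("oversample", "before_split"), split = "random"),
      correct = list(policy = ordering_policy("oversample", "after_split"), split = "random")),
    augmentation = list(
      pitfall = list(policy = ordering_policy("augment", "before_split"), split = "random"),
      correct = list(policy = ordering_policy("augment", "after_split"), split = "random")),
    feature_selection = list(
      pitfall = list(policy = ordering_policy("select_features", "before_split"), split = "random"),
      correct = list(policy = ordering_policy("select_features", "after_split"), split = "random")),
    patient_split = list(
      pitfall = list(policy = ordering_policy("none"), split = "random"),
      correct = list(policy = ordering_policy("none"), split = "grouped")),
    none = list(
      pitfall = list(policy = ordering_policy("none"), split = "random"),
      correct = list(policy = ordering_policy("none"), split = "random")),
    stop("run_paired_experiment does not handle kind ", config$kind, call. = FALSE))

  out <- list()
  for (i in seq_along(arm_spec)) {
    arm <- names(arm_spec)[i]
    sp <- arm_spec[[i]]
    parts <- materialize(table, policy = sp$policy, split_kind = sp$split,
                         ratios = config$ratios, k = config$k,
                         copies_per_sample = config$copies_per_sample,
                         jitter_sigma = config$jitter_sigma,
                         seed = derive_seed(rep_seed, 10L * i))
    if (length(unique(parts$train$label)) < 2 ||
        length(unique(parts$test$label)) < 2) {
      return(NULL)
    }
    pred <- predict_labels(parts$train, parts$test, config$classifier, cls_seed)
    cc <- confusion(parts$test$label, pred)
    out[[arm]] <- dplyr::bind_cols(
      classification_report(cc),
      tibble::tibble(tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn),
      parts$audit
    )
  }
  out
}

#' Run a paired pitfall-vs-correct experiment
#'
#' For each repetition, one dataset is generated and consumed by both arms
#' (same data, same classifier seed; only the transform ordering or split
#' kind differs, with arm-specific split randomness). Repetitions whose
#' splits leave a single class in the training or test set are flagged and
#' re-drawn from a fresh derived seed, up to 10 redraws.
#'
#' @param config An [experiment_config()] with `kind != "batch_effect"`.
#' @return An object of class `experiment_result`: per-arm per-repetition
#'   metric tibbles, the Wilcoxon comparison of the F1 vectors, and the
#'   mean F1 difference (pitfall minus correct).
#' @export
run_paired_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$kind == "batch_effect") {
    stop("use run_batch_effect() for the batch-effect experiment", call. = FALSE)
  }
  arms <- purrr::map(seq_len(config$repetitions), function(r) {
    rep_seed <- derive_seed(config$seed, 100L, r)
    for (attempt in 0:10) {
      seed_try <- if (attempt == 0) rep_seed else derive_seed(rep_seed, 1000L + attempt)
      table <- generate_data(config$data, seed_try)
      res <- run_arms_once(table, config, seed_try)
      if (!is.null(res)) return(res)
    }
    stop("repetition ", r, ": no valid split after 10 redraws", call. = FALSE)
  })
  pitfall <- dplyr::bind_rows(purrr::map(arms, "pitfall"), .id = "repetition")
  correct <- dplyr::bind_rows(purrr::map(arms, "correct"), .id = "repetition")
  pitfall$repetition <- as.integer(pitfall$repetition)
  correct$repetition <- as.integer(correct$repetition)
  f1_p <- fill_undefined(pitfall$f1, "F1")
  f1_c <- fill_undefined(correct$f1, "F1")
  wil <- tryCatch(wilcoxon_rank_sum(f1_p, f1_c),
                  error = function(e) list(statistic = NA_real_, p_value = NA_real_))
  structure(list(kind = config$kind, pitfall = pitfall, correct = correct,
                 wilcoxon = wil, mean_f1_delta = mean(f1_p) - mean(f1_c),
                 config = config),
            class = "experiment_result")
}

#' Run the batch-effect experiment
#'
#' Trains on the train split of the source-confounded internal dataset and
#' reports (a) the metric report on the held-out internal test split —
#' where the confound makes the model look excellent — and (b) the fraction
#' of the external dataset (class-0 samples carrying the other source's
#' signature) that is classified correctly, which collapses when the model
#' has learned the source rather than the class.
#'
#' @param config An [experiment_config()] with `kind = "batch_effect"`.
#' @return An object of class `batch_effect_result` with fields `internal`
#'   (one-row metric tibble), `external_fraction`, and `config`.
#' @export
run_batch_effect <- function(config) {
  stopifnot(inherits(config, "experiment_config"), config$kind == "batch_effect")
  data_cfg <- config$data
  data_cfg$seed <- derive_seed(config$seed, 100L, 1L)
  ds <- gen_batch_dataset(data_cfg)
  parts <- apply_split(ds$internal,
                       split_random(ds$internal, config$ratios,
                                    seed = derive_seed(config$seed, 5L)))
  cls_seed <- derive_seed(config$seed, 3L)
  internal <- train_and_score(parts$train, parts$test, config$classifier, cls_seed)
  pred_ext <- predict_labels(parts$train, ds$external, config$classifier, cls_seed)
  structure(list(internal = internal,
                 external_fraction = mean(pred_ext == ds$external$label),
                 config = config),
            class = "batch_effect_result")
}

#' Summarize a paired experiment as table rows
#'
#' @param result An `experiment_result`.
#' @return A tibble with one row per arm: n, min/mean/max/SD of F1, the
#'   mean F1 delta (pitfall minus correct) and the Wilcoxon z and p.
#' @export
summarize_experiment <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  if (nrow(result$pitfall) == 0 || nrow(result$correct) == 0) {
    stop("cannot summarize an experiment with an empty arm", call. = FALSE)
  }
  one <- function(arm, tbl) {
    f1 <- suppressWarnings(fill_undefined(tbl$f1, "F1"))
    dplyr::bind_cols(tibble::tibble(arm = arm, n = nrow(tbl)),
                     summarize_scores(f1))
  }
  out <- dplyr::bind_rows(one("pitfall", result$pitfall),
                          one("correct", result$correct))
  out$mean_f1_delta <- result$mean_f1_delta
  out$wilcoxon_z <- result$wilcoxon$statistic
  out$p_value <- result$wilcoxon$p_value
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a paired experiment into a long per-repetition tibble
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return A tibble with columns `arm`, `repetition`, the four metrics and
#'   the two leakage-audit counts.
#' @method tidy experiment_result
#' @export
tidy.experiment_result <- function(x, ...) {
  dplyr::bind_rows(pitfall = x$pitfall, correct = x$correct, .id = "arm")
}

#' One-row summary of a paired experiment
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return A one-row tibble: kind, repetitions, per-arm mean F1, delta,
#'   Wilcoxon z and p.
#' @method glance experiment_result
#' @export
glance.experiment_result <- function(x, ...) {
  f1_p <- suppressWarnings(fill_undefined(x$pitfall$f1, "F1"))
  f1_c <- suppressWarnings(fill_undefined(x$correct$f1, "F1"))
  tibble::tibble(kind = x$kind, repetitions = nrow(x$pitfall),
                 pitfall_mean_f1 = mean(f1_p), correct_mean_f1 = mean(f1_c),
                 mean_f1_delta = x$mean_f1_delta,
                 wilcoxon_z = x$wilcoxon$statistic,
                 p_value = x$wilcoxon$p_value)
}

#' @rdname glance.experiment_result
#' @method glance batch_effect_result
#' @export
glance.batch_effect_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(kind = "batch_effect"),
    stats::setNames(x$internal,
                    paste0("internal_", names(x$internal))),
    tibble::tibble(external_fraction = x$external_fraction)
  )
}

#' Box plot of per-repetition F1 by arm
#'
#' @param object An `experiment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot experiment_result
#' @export
autoplot.experiment_result <- function(object, ...) {
  d <- tidy(object)
  d$f1[is.na(d$f1)] <- 0
  ggplot2::ggplot(d, ggplot2::aes(x = .data$arm, y = .data$f1, fill = .data$arm)) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(title = paste0("Paired experiment: ", object$kind),
                  subtitle = sprintf("Wilcoxon z = %.2f, p = %.3g",
                                     object$wilcoxon$statistic,
                                     object$wilcoxon$p_value),
                  x = NULL, y = "test-set F1") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Paired experiment (", x$kind, "), ", nrow(x$pitfall), " repetitions\n", sep = "")
  print(summarize_experiment(x))
  invisible(x)
}

#' @export
print.batch_effect_result <- function(x, ...) {
  cat("Batch-effect experiment\n")
  print(glance(x))
  invisible(x)
}
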