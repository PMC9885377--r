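test_that("random split partitions rows at exact largest-remainder sizes", {
  x <- tiny_table(n = 10)
  a <- split_random(x, c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(as.integer(table(a$subset)), c(6L, 2L, 2L))
  expect_setequal(a$row, 1:10)

  all_train <- split_random(x, c(1, 0, 0), seed = 1)
  expect_true(all(all_train$subset == "train"))

  expect_error(split_random(x, c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(split_random(x[0, ], c(0.6, 0.2, 0.2)), "empty")
})

test_that("largest-remainder sizes are exact over many n and ratios", {
  for (n in c(1, 2, 7, 10, 99, 1000)) {
    for (r in list(c(0.6, 0.2, 0.2), c(0.34, 0.33, 0.33), c(0.5, 0.25, 0.25))) {
      s <- mlpitfalls:::largest_remainder(n, r)
      expect_equal(sum(s), n)
      expect_true(all(abs(s - n * r) < 1))
    }
  }
})

test_that("grouped split never lets a group span subsets, across seeds", {
  x <- gen_patient_patches(patch_config(n_patients = 10, patches_per_patient = 200,
                                        seed = 5))
  for (seed in 1:10) {
    a <- split_grouped(x, c(0.6, 0.2, 0.2), "patient_id", seed = seed)
    parts <- apply_split(x, a)
    audit <- leakage_audit(parts$train, parts$val, parts$test)
    expect_equal(audit$patient_spanning, 0L)
  }
  a <- split_grouped(x, c(0.6, 0.2, 0.2), "patient_id", seed = 3)
  parts <- apply_split(x, a)
  expect_equal(sapply(parts, nrow), c(train = 1200L, val = 400L, test = 400L))

  # 3 groups over 3 subsets: one group each, always a valid assignment
  y <- gen_patient_patches(patch_config(n_patients = 4, patches_per_patient = 2, seed = 2))
  y <- y[y$patient_id %in% unique(y$patient_id)[1:3], ]
  for (seed in 1:6) {
    a3 <- split_grouped(y, c(0.34, 0.33, 0.33), "patient_id", seed = seed)
    parts3 <- apply_split(y, a3)
    expect_true(all(sapply(parts3, function(p) length(unique(p$patient_id))) == 1))
  }
  expect_no_error(split_grouped(y, c(0.25, 0.25, 0.5), "provenance_id",
                                seed = 1)) # 6 provenance groups: feasible
  z <- y[y$patient_id == unique(y$patient_id)[1], ]
  expect_error(split_grouped(z, c(0.34, 0.33, 0.33), "patient_id", seed = 1),
               "infeasible")
})

test_that("row-level splitting of patient patches leaks with near certainty", {
  x <- gen_patient_patches(patch_config(n_patients = 10, patches_per_patient = 200,
                                        seed = 6))
  a <- split_random(x, c(0.6, 0.2, 0.2), seed = 7)
  parts <- apply_split(x, a)
  audit <- leakage_audit(parts$train, parts$val, parts$test)
  expect_gt(audit$patient_spanning, 0)
})

test_that("oversampling balances exactly and preserves provenance", {
  x <- tiny_table(n = 100, n_pos = 10)
  y <- oversample(x, seed = 2)
  expect_equal(sum(y$label == 1), sum(y$label == 0))
  expect_equal(nrow(y), 180)
  # duplicates all point at original minority rows
  dup <- y[duplicated(y$provenance_id), ]
  expect_true(all(dup$label == 1))
  expect_true(all(dup$provenance_id %in% x$provenance_id[x$label == 1]))

  balanced <- tiny_table(n = 10, n_pos = 5)
  expect_identical(oversample(balanced, seed = 1), balanced)

  single <- tiny_table(n = 5, n_pos = 0)
  expect_error(oversample(single), "single-class")
})

test_that("augmentation appends jittered copies that inherit provenance", {
  x <- tiny_table(n = 100, n_pos = 50)
  y <- augment(x, copies_per_sample = 3, jitter_sigma = 0.1, seed = 3)
  expect_equal(nrow(y), 400)
  expect_equal(length(unique(y$provenance_id)), 100)

  expect_identical(augment(x, copies_per_sample = 0), x)
  z <- augment(x, copies_per_sample = 1, jitter_sigma = 0, seed = 1)
  expect_identical(feature_matrix(z)[101:200, ], feature_matrix(x))
  expect_error(augment(x, copies_per_sample = -1), "copies_per_sample")
})

test_that("feature ranking matches a frozen hand-computed fixture", {
  # 6 samples, labels 0,0,0,1,1,1; feature_0 equals the label (infinite t),
  # feature_1 separates by 3 pooled SDs (t = 3.674), feature_2 weakly
  # (t = 0.612), feature_3 is constant (score 0)
  x <- labeled_table(
    cbind(c(0, 0, 0, 1, 1, 1),
          c(1, 2, 3, 4, 5, 6),
          c(2, 1, 3, 2.5, 1.5, 3.5),
          c(5, 5, 5, 5, 5, 5)),
    label = c(0, 0, 0, 1, 1, 1),
    patient_id = sprintf("P%d", 1:6)
  )
  expect_identical(select_top_features(x, 4), c(1L, 2L, 3L, 4L))
  expect_identical(select_top_features(x, 1), 1L)
  expect_error(select_top_features(x, 5), "exceeds")
})

test_that("feature ranking agrees with the brute-force t oracle on random tables", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      n <- sample(10:50, 1)
      p <- sample(3:20, 1)
      y <- c(rep(1L, n %/% 2), rep(0L, n - n %/% 2))
      x <- labeled_table(matrix(rnorm(n * p), n, p), y, sprintf("P%03d", 1:n))
    })
    expect_identical(select_top_features(x, p), oracle_t_ranking(feature_matrix(x), x$label))
  }
})

test_that("materialize honors the transform ordering", {
  x <- tiny_table(n = 100, n_pos = 10)

  plain <- materialize(x, ordering_policy("none"), "random", seed = 5)
  expect_equal(plain$audit$provenance_spanning, 0L)
  expect_equal(nrow(plain$train) + nrow(plain$val) + nrow(plain$test), 100)

  after <- materialize(x, ordering_policy("oversample", "after_split"),
                       "random", seed = 5)
  expect_equal(after$audit$provenance_spanning, 0L)
  expect_equal(sum(after$train$label == 1), sum(after$train$label == 0))
  # val and test are untouched by the after-split transform
  expect_equal(nrow(after$val) + nrow(after$test), 40)

  before <- materialize(x, ordering_policy("oversample", "before_split"),
                        "random", seed = 5)
  expect_gt(before$audit$provenance_spanning, 0)

  sel <- materialize(x, ordering_policy("select_features", "after_split"),
                     "random", k = 2, seed = 5)
  expect_equal(length(mlpitfalls:::feature_names(sel$test)), 2)
  # after-split selection is computed on train only: re-ranking train
  # features reproduces the projection
  expect_named(sel$train, names(sel$test))
})

test_that("leakage audit equals brute-force set intersection", {
  x <- oversample(tiny_table(n = 100, n_pos = 10), seed = 9)
  parts <- apply_split(x, split_random(x, c(0.6, 0.2, 0.2), seed = 9))
  audit <- leakage_audit(parts$train, parts$val, parts$test)
  sets <- lapply(parts, function(p) unique(p$provenance_id))
  brute <- length(union(union(
    intersect(sets$train, sets$val),
    intersect(sets$train, sets$test)),
    intersect(sets$val, sets$test)))
  expect_equal(audit$provenance_spanning, brute)
  expect_gt(audit$provenance_spanning, 0)

  # disjoint patients: clean audit
  y <- tiny_table(n = 9, n_pos = 3)
  py <- apply_split(y, split_grouped(y, c(0.34, 0.33, 0.33), "patient_id", seed = 1))
  expect_equal(unlist(leakage_audit(py$train, py$val, py$test)),
               c(provenance_spanning = 0L, patient_spanning = 0L))
})
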