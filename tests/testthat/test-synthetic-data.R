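test_that("generators are deterministic given config and seed", {
  cfgs <- list(
    function() gen_tabular(tabular_config(n_patients = 20, seed = 9)),
    function() gen_patient_patches(patch_config(n_patients = 6,
                                                patches_per_patient = 4, seed = 9)),
    function() gen_batch_dataset(batch_config(n_per_source = 10, seed = 9)),
    function() gen_synthetic_slide(slide_config(image_shape = c(40, 40), seed = 9))
  )
  for (f in cfgs) expect_identical(f(), f())
  v1 <- gen_ct_volume(volume_spec(grid_shape = c(24, 24, 24), seed = 9))
  v2 <- gen_ct_volume(volume_spec(grid_shape = c(24, 24, 24), seed = 9))
  expect_identical(v1, v2)
})

test_that("tabular generator hits the exact positive count and null signal", {
  x <- gen_tabular(tabular_config(n_patients = 100, class_fraction = 0.1, seed = 3))
  expect_equal(sum(x$label), 10)
  expect_equal(nrow(x), 100)

  # no-signal construction: class mean difference within 3 SE of zero
  x0 <- gen_tabular(tabular_config(n_patients = 400, n_features = 1,
                                   class_fraction = 0.5, signal_strength = 0,
                                   seed = 11))
  d <- mean(x0$feature_0[x0$label == 1]) - mean(x0$feature_0[x0$label == 0])
  se <- sqrt(1 / sum(x0$label == 1) + 1 / sum(x0$label == 0))
  expect_lt(abs(d), 3 * se)

  # a positive signal shifts class means by its magnitude, in expectation
  xs <- gen_tabular(tabular_config(n_patients = 2000, n_features = 4,
                                   class_fraction = 0.5, signal_strength = 2,
                                   seed = 12))
  m1 <- colMeans(feature_matrix(xs)[xs$label == 1, ])
  m0 <- colMeans(feature_matrix(xs)[xs$label == 0, ])
  expect_equal(sqrt(sum((m1 - m0)^2)), 2, tolerance = 0.1)

  expect_error(tabular_config(class_fraction = 0), "class_fraction")
  expect_error(tabular_config(n_patients = 2), "n_patients")
})

test_that("patient patches have shared labels and dominant between-patient variance", {
  cfg <- patch_config(n_patients = 10, patches_per_patient = 200,
                      signature_strength = 5, class_signal = 0, seed = 21)
  x <- gen_patient_patches(cfg)
  expect_equal(nrow(x), 2000)
  expect_equal(length(unique(x$patient_id)), 10)
  lab <- tapply(x$label, x$patient_id, function(v) length(unique(v)))
  expect_true(all(lab == 1))

  # variance decomposition: between-patient mean square far exceeds
  # within-patient (signature SD 5 vs unit noise)
  f <- x$feature_0
  gm <- tapply(f, x$patient_id, mean)
  within <- unlist(tapply(f, x$patient_id, function(v) v - mean(v)))
  ratio <- stats::var(gm[x$patient_id]) / stats::var(within)
  expect_gt(ratio, 1)

  expect_error(patch_config(patches_per_patient = 0), "patches_per_patient")
})

test_that("degenerate patch config is i.i.d. noise", {
  x <- gen_patient_patches(patch_config(n_patients = 10, patches_per_patient = 50,
                                        signature_strength = 0, class_signal = 0,
                                        seed = 2))
  f <- feature_matrix(x)
  expect_equal(mean(f), 0, tolerance = 3 / sqrt(length(f)))
  expect_equal(stats::sd(as.vector(f)), 1, tolerance = 0.05)
})

test_that("batch dataset realizes the confound and the external shift", {
  ds <- gen_batch_dataset(batch_config(n_per_source = 500, seed = 8))
  expect_equal(nrow(ds$internal), 1000)
  expect_equal(as.integer(table(ds$internal$label)), c(500L, 500L))
  expect_true(all((ds$internal$source_id == "B") == (ds$internal$label == 1)))
  expect_true(all(ds$external$label == 0))
  expect_true(all(ds$external$source_id == "B"))

  # external centroid lies closer to the internal class-1 (source B) centroid
  fx <- feature_matrix(ds$internal)
  c0 <- colMeans(fx[ds$internal$label == 0, ])
  c1 <- colMeans(fx[ds$internal$label == 1, ])
  ce <- colMeans(feature_matrix(ds$external))
  expect_lt(sqrt(sum((ce - c1)^2)), sqrt(sum((ce - c0)^2)))

  expect_error(batch_config(n_per_source = 1), "n_per_source")
})

test_that("batch dataset with all strengths zero is indistinguishable noise", {
  ds <- gen_batch_dataset(batch_config(n_per_source = 300, signature_strength = 0,
                                       intrinsic_signal = 0, seed = 4))
  fi <- feature_matrix(ds$internal)
  d <- colMeans(fi[ds$internal$label == 1, ]) - colMeans(fi[ds$internal$label == 0, ])
  expect_lt(max(abs(d)), 3 * sqrt(2 / 300))
})

test_that("CT phantom masks satisfy the stated geometry and HU contracts", {
  spec <- volume_spec(grid_shape = c(48, 48, 48), seed = 31)
  ph <- gen_ct_volume(spec)
  lung <- ph$lung_truth
  internal <- ph$internal_air_truth
  expect_true(all(internal[lung]))           # lung is a subset of internal air
  L <- sum(lung)
  E <- sum(internal) - L
  target <- (spec$airway_fraction + spec$bowel_gas_fraction) * L
  expect_lt(abs(E - target) / target, 0.10)

  # every air voxel sits strictly below -400 HU and every tissue voxel
  # strictly above it (noise is clamped at 4 SD)
  hu <- ph$volume$hu
  expect_true(all(hu[internal] < -400))
  expect_true(all(hu[hu >= -400] >= spec$hu_tissue - 4 * spec$sd_tissue))
  expect_true(all(hu[hu < -400] <= spec$hu_air + 4 * spec$sd_air))

  # analytic Dice of internal air vs lung from voxel counts
  expect_equal(dice(internal, lung), 2 * L / (2 * L + E), tolerance = 1e-12)

  # zero extra air collapses internal air onto the lungs
  ph0 <- gen_ct_volume(volume_spec(grid_shape = c(32, 32, 32),
                                   airway_fraction = 0, bowel_gas_fraction = 0,
                                   seed = 1))
  expect_identical(ph0$internal_air_truth, ph0$lung_truth)

  # geometry that leaves the body is rejected
  bad_geo <- spec$lung_geometry
  bad_geo$centers[1, 1] <- -1.2
  expect_error(gen_ct_volume(volume_spec(grid_shape = c(32, 32, 32),
                                         lung_geometry = bad_geo)),
               "outside the body")
})

test_that("no internal-air voxel reaches the border through air", {
  ph <- gen_ct_volume(volume_spec(grid_shape = c(32, 32, 32), seed = 17))
  air <- ph$volume$hu < -400
  kept <- remove_border_air(air)
  expect_identical(kept, ph$internal_air_truth)
})

test_that("synthetic slides hit the foreground fraction exactly and separably", {
  for (f in c(0, 0.5, 1)) {
    sl <- gen_synthetic_slide(slide_config(image_shape = c(64, 64),
                                           foreground_fraction = f, seed = 13))
    expect_equal(mean(sl$foreground_truth), f, tolerance = 1e-9)
  }
  sl <- gen_synthetic_slide(slide_config(image_shape = c(128, 128),
                                         foreground_fraction = 0.5, seed = 3))
  expect_identical(foreground_mask(sl$image, 0.8), sl$foreground_truth)
  expect_error(slide_config(foreground_fraction = 1.5), "foreground_fraction")
})
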