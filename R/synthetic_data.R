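#' Configuration for imbalanced radiomics-like tabular data
#'
#' Describes a cohort of patients, one feature vector per patient, with a
#' binary endpoint at a given prevalence. Features are standard Gaussian
#' noise; a true class signal, when requested, is a mean shift of magnitude
#' `signal_strength` along a fixed random unit direction, so
#' `signal_strength` is the standardized mean difference between the
#' class-conditional feature means. The default `signal_strength = 0`
#' produces a pure-noise cohort: the configuration used by the leakage
#' experiments, where any apparent skill must come from leakage.
#'
#' @param n_patients Number of patients (>= 4).
#' @param n_features Number of features per patient.
#' @param class_fraction Prevalence of the positive class, in (0, 1).
#' @param signal_strength Standardized class-mean separation (>= 0).
#' @param seed Integer master seed for this generator.
#' @return A validated config list of class `tabular_config`.
#' @export
tabular_config <- function(n_patients = 100, n_features = 10,
                           class_fraction = 0.1, signal_strength = 0,
                           seed = 1L) {
  if (n_patients < 4) stop("n_patients must be >= 4", call. = FALSE)
  if (n_features < 1) stop("n_features must be >= 1", call. = FALSE)
  if (!(class_fraction > 0 && class_fraction < 1)) {
    stop("class_fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  if (signal_strength < 0) stop("signal_strength must be >= 0", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 n_features = as.integer(n_features),
                 class_fraction = class_fraction,
                 signal_strength = signal_strength,
                 seed = as.integer(seed)),
            class = "tabular_config")
}

#' Generate an imbalanced tabular cohort
#'
#' One row per patient; exactly `round(class_fraction * n_patients)` rows are
#' labelled positive (which patients are positive is randomized by the seed).
#' Identical configuration and seed give bitwise-identical tables.
#'
#' @param config A [tabular_config()].
#' @return A labeled table (tibble).
#' @export
gen_tabular <- function(config) {
  stopifnot(inherits(config, "tabular_config"))
  withr::with_seed(config$seed, {
    n <- config$n_patients
    p <- config$n_features
    n_pos <- as.integer(round(config$class_fraction * n))
    label <- integer(n)
    label[sample.int(n, n_pos)] <- 1L
    x <- matrix(stats::rnorm(n * p), n, p)
    if (config$signal_strength > 0) {
      u <- stats::rnorm(p)
      u <- u / sqrt(sum(u^2))
      x[label == 1L, ] <- x[label == 1L, , drop = FALSE] +
        rep(config$signal_strength * u, each = sum(label))
    }
    pid <- sprintf("P%04d", seq_len(n))
    labeled_table(x, label, pid, provenance_id = pid)
  })
}

#' Configuration for per-patient patch collections
#'
#' Emulates datasets where each patient contributes many image patches:
#' every patch of a patient shares a patient-specific signature offset
#' (drawn once per patient, per-coordinate Gaussian with SD
#' `signature_strength`) on top of unit Gaussian noise, and the class label
#' is constant within a patient. `class_signal` adds a true class-mean
#' separation along a fixed unit direction; `jitter_sigma` is the SD used
#' when these patches are augmented.
#'
#' @param n_patients Number of patients.
#' @param patches_per_patient Patches contributed by each patient (>= 1).
#' @param n_features Feature dimension.
#' @param signature_strength Per-coordinate SD of the patient offset (>= 0).
#' @param class_signal True class-mean separation (>= 0).
#' @param jitter_sigma Augmentation noise SD (>= 0).
#' @param class_fraction Fraction of patients in the positive class.
#' @param seed Integer master seed.
#' @return A config list of class `patch_config`.
#' @export
patch_config <- function(n_patients = 20, patches_per_patient = 50,
                         n_features = 10, signature_strength = 3,
                         class_signal = 0, jitter_sigma = 0.1,
                         class_fraction = 0.5, seed = 1L) {
  if (patches_per_patient < 1) stop("patches_per_patient must be >= 1", call. = FALSE)
  if (n_patients < 4) stop("n_patients must be >= 4", call. = FALSE)
  if (signature_strength < 0 || class_signal < 0 || jitter_sigma < 0) {
    stop("strength parameters must be >= 0", call. = FALSE)
  }
  if (!(class_fraction > 0 && class_fraction < 1)) {
    stop("class_fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 patches_per_patient = as.integer(patches_per_patient),
                 n_features = as.integer(n_features),
                 signature_strength = signature_strength,
                 class_signal = class_signal,
                 jitter_sigma = jitter_sigma,
                 class_fraction = class_fraction,
                 seed = as.integer(seed)),
            class = "patch_config")
}

#' Generate a per-patient patch table
#'
#' @param config A [patch_config()].
#' @return A labeled table with `n_patients * patches_per_patient` rows;
#'   `provenance_id` is unique per patch, `patient_id` shared within a
#'   patient.
#' @export
gen_patient_patches <- function(config) {
  stopifnot(inherits(config, "patch_config"))
  withr::with_seed(config$seed, {
    np <- config$n_patients
    k <- config$patches_per_patient
    p <- config$n_features
    n <- np * k
    n_pos <- as.integer(round(config$class_fraction * np))
    patient_label <- integer(np)
    patient_label[sample.int(np, n_pos)] <- 1L
    sig <- matrix(stats::rnorm(np * p, sd = config$signature_strength), np, p)
    u <- stats::rnorm(p)
    u <- u / sqrt(sum(u^2))
    rows_patient <- rep(seq_len(np), each = k)
    x <- matrix(stats::rnorm(n * p), n, p) +
      sig[rows_patient, , drop = FALSE] +
      outer(patient_label[rows_patient] * config$class_signal, u)
    pid <- sprintf("P%04d", rows_patient)
    prov <- sprintf("P%04d_k%04d", rows_patient, sequence(rep(k, np)))
    labeled_table(x, patient_label[rows_patient], pid, provenance_id = prov)
  })
}

#' Configuration for a source-confounded (batch-effect) dataset
#'
#' Two acquisition sources, A and B. In the internal dataset source A
#' contributes only class-0 samples and source B only class-1 samples, so
#' the label is perfectly confounded with the source. Each source imprints a
#' signature offset (drawn once per source, per-coordinate SD
#' `signature_strength`) on its samples. The external dataset contains
#' class-0 samples that carry source B's signature — breaking the confound
#' the way a deployment population would. With `intrinsic_signal = 0` the
#' label carries no information beyond the source signature.
#'
#' @param n_per_source Samples per source (>= 2).
#' @param n_features Feature dimension.
#' @param signature_strength Per-coordinate SD of each source offset.
#' @param intrinsic_signal True class-mean separation independent of source
#'   (default 0: the pure-confound condition).
#' @param seed Integer master seed.
#' @return A config list of class `batch_config`.
#' @export
batch_config <- function(n_per_source = 500, n_features = 20,
                         signature_strength = 3, intrinsic_signal = 0,
                         seed = 1L) {
  if (n_per_source < 2) stop("n_per_source must be >= 2", call. = FALSE)
  if (signature_strength < 0 || intrinsic_signal < 0) {
    stop("strength parameters must be >= 0", call. = FALSE)
  }
  structure(list(n_per_source = as.integer(n_per_source),
                 n_features = as.integer(n_features),
                 signature_strength = signature_strength,
                 intrinsic_signal = intrinsic_signal,
                 seed = as.integer(seed)),
            class = "batch_config")
}

#' Generate internal (confounded) and external batch-effect datasets
#'
#' @param config A [batch_config()].
#' @return A list with elements `internal` (2 * n_per_source rows, source_id
#'   identical to label) and `external` (n_per_source class-0 rows carrying
#'   source B's signature).
#' @export
gen_batch_dataset <- function(config) {
  stopifnot(inherits(config, "batch_config"))
  withr::with_seed(config$seed, {
    m <- config$n_per_source
    p <- config$n_features
    off_a <- stats::rnorm(p, sd = config$signature_strength)
    off_b <- stats::rnorm(p, sd = config$signature_strength)
    u <- stats::rnorm(p)
    u <- u / sqrt(sum(u^2))
    mk <- function(n, label, offset) {
      matrix(stats::rnorm(n * p), n, p) +
        rep(offset, each = n) +
        outer(rep(label * config$intrinsic_signal, n), u)
    }
    internal <- labeled_table(
      rbind(mk(m, 0L, off_a), mk(m, 1L, off_b)),
      label = rep(c(0L, 1L), each = m),
      patient_id = sprintf("I%05d", seq_len(2 * m)),
      source_id = rep(c("A", "B"), each = m),
      provenance_id = sprintf("I%05d", seq_len(2 * m))
    )
    external <- labeled_table(
      mk(m, 0L, off_b),
      label = rep(0L, m),
      patient_id = sprintf("E%05d", seq_len(m)),
      source_id = "B",
      provenance_id = sprintf("E%05d", seq_len(m))
    )
    list(internal = internal, external = external)
  })
}

#' Specification of a synthetic CT phantom
#'
#' An ellipsoid-based chest/abdomen phantom on a regular Hounsfield-unit
#' grid: a soft-tissue body ellipsoid surrounded by exterior air, two lung
#' ellipsoids inside it, an airway tube above the lungs, and bowel-gas
#' pockets below — all internal air, none connected to the exterior. Only
#' the HU contrast and the connectivity topology matter for the
#' threshold-based baseline segmenter, so no anatomical realism is
#' attempted.
#'
#' Geometry parameters are in normalized coordinates (fractions of the half
#' grid). `airway_fraction` / `bowel_gas_fraction` set the volume of those
#' air pockets relative to the lung volume; the generator realizes them to
#' the nearest voxel. Defaults give non-lung internal air of about 17% of
#' the lung volume, so the internal-air-vs-lung Dice of an ideal thresholder
#' is about 2/(2 + 0.17) = 0.92.
#'
#' @param grid_shape Integer vector of 3 voxel counts (each >= 8).
#' @param spacing Voxel spacing in mm per axis.
#' @param hu_tissue,sd_tissue Mean/SD of soft-tissue HU (default 40 +- 20).
#' @param hu_air,sd_air Mean/SD of air HU (default -1000 +- 30). Noise is
#'   clamped at 4 SD so air stays strictly below -400 and tissue strictly
#'   above it.
#' @param lung_geometry List with `centers` (2 x 3 matrix) and `semi`
#'   (length-3 semi-axes) for the two lung ellipsoids, plus `body_semi`.
#' @param airway_fraction,bowel_gas_fraction Non-lung internal air volume
#'   relative to lung volume (>= 0).
#' @param seed Integer seed (HU noise).
#' @return A config list of class `volume_spec`.
#' @export
volume_spec <- function(grid_shape = c(64, 64, 64), spacing = c(1, 1, 1),
                        hu_tissue = 40, sd_tissue = 20,
                        hu_air = -1000, sd_air = 30,
                        lung_geometry = NULL,
                        airway_fraction = 0.08, bowel_gas_fraction = 0.09,
                        seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 8)) {
    stop("grid_shape must be 3 counts, each >= 8", call. = FALSE)
  }
  if (airway_fraction < 0 || bowel_gas_fraction < 0) {
    stop("air fractions must be >= 0", call. = FALSE)
  }
  if (!(hu_air + 3 * sd_air < -400 && hu_tissue - 3 * sd_tissue > -400)) {
    stop("air and tissue HU must be separated from -400 by at least 3 SD",
         call. = FALSE)
  }
  if (is.null(lung_geometry)) {
    lung_geometry <- list(
      body_semi = c(0.85, 0.80, 0.90),
      centers = rbind(c(-0.38, 0, 0.05), c(0.38, 0, 0.05)),
      semi = c(0.26, 0.42, 0.52)
    )
  }
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 hu_tissue = hu_tissue, sd_tissue = sd_tissue,
                 hu_air = hu_air, sd_air = sd_air,
                 lung_geometry = lung_geometry,
                 airway_fraction = airway_fraction,
                 bowel_gas_fraction = bowel_gas_fraction,
                 seed = as.integer(seed)),
            class = "volume_spec")
}

# Normalized coordinate grids for a voxel lattice: each axis mapped to
# (-1, 1) across the grid.
norm_coords <- function(shape) {
  lapply(seq_len(3), function(a) {
    (seq_len(shape[a]) - (shape[a] + 1) / 2) / (shape[a] / 2)
  })
}

inside_ellipsoid <- function(cx, cy, cz, center, semi) {
  dx <- (cx - center[1]) / semi[1]
  dy <- (cy - center[2]) / semi[2]
  dz <- (cz - center[3]) / semi[3]
  dx^2 + dy^2 + dz^2 <= 1
}

#' Generate a synthetic CT phantom with ground-truth masks
#'
#' @param spec A [volume_spec()].
#' @return A list with `volume` (a [ct_volume()]), `lung_truth` and
#'   `internal_air_truth` (logical 3D arrays, lung a subset of internal
#'   air). Within the body interior, voxels with HU below -400 are exactly
#'   the internal-air truth.
#' @export
gen_ct_volume <- function(spec) {
  stopifnot(inherits(spec, "volume_spec"))
  shp <- spec$grid_shape
  g <- norm_coords(shp)
  cx <- array(rep(g[[1]], times = shp[2] * shp[3]), shp)
  cy <- array(rep(rep(g[[2]], each = shp[1]), times = shp[3]), shp)
  cz <- array(rep(g[[3]], each = shp[1] * shp[2]), shp)
  geo <- spec$lung_geometry
  body <- inside_ellipsoid(cx, cy, cz, c(0, 0, 0), geo$body_semi)
  lung <- inside_ellipsoid(cx, cy, cz, geo$centers[1, ], geo$semi) |
    inside_ellipsoid(cx, cy, cz, geo$centers[2, ], geo$semi)
  if (any(lung & !body)) {
    stop("lung geometry extends outside the body ellipsoid", call. = FALSE)
  }
  L <- sum(lung)
  # One voxel of tissue shell must separate internal air from the exterior.
  near_ext <- dilate6(!body)

  # Airway: a vertical midline tube between the lungs. Candidate voxels are
  # ordered z-major then radially, and exactly round(airway_fraction * L)
  # are kept, so the realized volume matches the requested fraction to the
  # voxel while staying a connected stack of disks.
  k_air <- as.integer(round(spec$airway_fraction * L))
  airway <- array(FALSE, shp)
  if (k_air > 0) {
    r2 <- cx^2 + cy^2
    cand <- which(body & !lung & !near_ext & r2 <= 0.16^2 &
                    cz > -0.45 & cz < 0.85)
    if (length(cand) < k_air) {
      stop("airway region too small for requested airway_fraction", call. = FALSE)
    }
    ord <- order(cz[cand], r2[cand])
    airway[cand[ord[seq_len(k_air)]]] <- TRUE
  }

  # Bowel gas: a ball grown radially from a point below the lungs, again
  # realized to the exact voxel count (nested balls stay connected).
  k_gas <- as.integer(round(spec$bowel_gas_fraction * L))
  gas <- array(FALSE, shp)
  if (k_gas > 0) {
    ctr <- c(0.25, 0, -0.55)
    d2 <- (cx - ctr[1])^2 + (cy - ctr[2])^2 + (cz - ctr[3])^2
    cand <- which(body & !lung & !airway & !near_ext & d2 <= 0.40^2)
    if (length(cand) < k_gas) {
      stop("bowel-gas region too small for requested bowel_gas_fraction",
           call. = FALSE)
    }
    ord <- order(d2[cand])
    gas[cand[ord[seq_len(k_gas)]]] <- TRUE
  }

  internal_air <- lung | airway | gas
  # Internal air must not touch exterior air (else it would drain out of the
  # body in the border-removal step).
  exterior <- !body
  if (any(internal_air & dilate6(exterior))) {
    stop("internal air touches the exterior: thicken the body shell", call. = FALSE)
  }

  hu <- withr::with_seed(spec$seed, {
    n_vox <- prod(shp)
    tis <- spec$hu_tissue + clamp_sd(stats::rnorm(n_vox), 4) * spec$sd_tissue
    air <- spec$hu_air + clamp_sd(stats::rnorm(n_vox), 4) * spec$sd_air
    is_air <- exterior | internal_air
    out <- array(tis, shp)
    out[is_air] <- air[is_air]
    out
  })
  list(volume = ct_volume(hu, spec$spacing),
       lung_truth = lung,
       internal_air_truth = internal_air)
}

clamp_sd <- function(z, k) pmin(pmax(z, -k), k)

#' Configuration for synthetic whole-slide-style images
#'
#' Near-white background with tissue-colored blobs (a thresholded smooth
#' random field), the standard appearance of an H&E slide thumbnail. The
#' realized foreground fraction is exact to the pixel, and foreground pixels
#' are separable from background by mean-channel luminance.
#'
#' @param n_images Number of slides a cohort-level caller should generate.
#' @param image_shape Height/width in pixels.
#' @param foreground_fraction Fraction of pixels covered by tissue, in
#'   \[0, 1\].
#' @param background_color Near-white RGB triple in \[0, 1\].
#' @param seed Integer master seed.
#' @return A config list of class `slide_config`.
#' @export
slide_config <- function(n_images = 1, image_shape = c(512, 512),
                         foreground_fraction = 0.5,
                         background_color = c(0.96, 0.96, 0.96),
                         seed = 1L) {
  if (foreground_fraction < 0 || foreground_fraction > 1) {
    stop("foreground_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_images = as.integer(n_images),
                 image_shape = as.integer(image_shape),
                 foreground_fraction = foreground_fraction,
                 background_color = background_color,
                 seed = as.integer(seed)),
            class = "slide_config")
}

#' Generate one synthetic slide image with its foreground truth
#'
#' @param config A [slide_config()].
#' @param seed Optional seed override (used by cohort-level callers to give
#'   each slide its own derived stream); defaults to `config$seed`.
#' @return A list with `image` (h x w x 3 array in \[0, 1\]) and
#'   `foreground_truth` (h x w logical matrix).
#' @export
gen_synthetic_slide <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "slide_config"))
  h <- config$image_shape[1]
  w <- config$image_shape[2]
  withr::with_seed(seed, {
    k <- as.integer(round(config$foreground_fraction * h * w))
    field <- smooth_field(h, w)
    if (k <= 0) {
      mask <- matrix(FALSE, h, w)
    } else if (k >= h * w) {
      mask <- matrix(TRUE, h, w)
    } else {
      thr <- sort(field, decreasing = TRUE)[k]
      mask <- field >= thr
      # guard against ties at the threshold (continuous field: improbable)
      if (sum(mask) != k) mask <- array(rank(-field, ties.method = "first") <= k, dim(field))
    }
    img <- array(0, c(h, w, 3))
    bg_noise <- matrix(stats::rnorm(h * w, sd = 0.01), h, w)
    fg_base <- c(0.75, 0.35, 0.55)  # eosin-like pink/purple
    fg_noise <- matrix(stats::rnorm(h * w, sd = 0.04), h, w)
    for (ch in 1:3) {
      bg <- pmin(pmax(config$background_color[ch] + bg_noise, 0.90), 1)
      fg <- pmin(pmax(fg_base[ch] + fg_noise, 0.1), 0.72)
      plane <- bg
      plane[mask] <- fg[mask]
      img[, , ch] <- plane
    }
    list(image = img, foreground_truth = mask)
  })
}

#' @rdname gen_synthetic_slide
#' @return `gen_synthetic_slides` returns a list of `config$n_images`
#'   slides, each generated from a seed derived from the config seed.
#' @export
gen_synthetic_slides <- function(config) {
  stopifnot(inherits(config, "slide_config"))
  lapply(seq_len(config$n_images), function(i) {
    gen_synthetic_slide(config, seed = derive_seed(config$seed, 77L, i))
  })
}

# A blob-like smooth random field: coarse Gaussian noise bilinearly
# upsampled to the image size.
smooth_field <- function(h, w, coarse = 12) {
  gh <- max(2, min(coarse, h))
  gw <- max(2, min(coarse, w))
  z <- matrix(stats::rnorm(gh * gw), gh, gw)
  ry <- seq(1, gh, length.out = h)
  rx <- seq(1, gw, length.out = w)
  y0 <- pmin(floor(ry), gh - 1); fy <- ry - y0
  x0 <- pmin(floor(rx), gw - 1); fx <- rx - x0
  a <- z[cbind(rep(y0, w), rep(x0, each = h))]
  b <- z[cbind(rep(y0 + 1, w), rep(x0, each = h))]
  cc <- z[cbind(rep(y0, w), rep(x0 + 1, each = h))]
  d <- z[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  fyv <- rep(fy, w); fxv <- rep(fx, each = h)
  matrix((1 - fyv) * (1 - fxv) * a + fyv * (1 - fxv) * b +
           (1 - fyv) * fxv * cc + fyv * fxv * d, h, w)
}
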