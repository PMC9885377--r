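#' Patch-extraction specification
#'
#' Parameters of the whole-slide patch pipeline: downscale the image,
#' threshold near-white background by mean-channel luminance, then draw
#' random square patches from the downscaled image, rejecting any candidate
#' with `background_limit` or more background, until the per-image cap is
#' reached. Defaults follow the standard recipe (downscale 4x, 1024-pixel
#' patches, 200 patches per image, patches with >= 75% background
#' excluded); `patch_size` is typically reduced for desk-scale runs.
#'
#' @param downscale_factor Integer block size for mean-pool downscaling.
#' @param patch_size Patch edge length in (downscaled) pixels.
#' @param max_patches_per_image Per-image accepted-patch cap.
#' @param background_limit Rejection boundary: a patch is rejected iff its
#'   background fraction is `>= background_limit` (default 0.75).
#' @param background_luminance_threshold A pixel is background iff its
#'   mean-channel luminance is `>=` this fraction of full brightness
#'   (default 0.8).
#' @param max_attempts_per_patch Sampling budget multiplier: drawing stops
#'   after `max_attempts_per_patch * max_patches_per_image` candidates.
#' @param seed Integer seed.
#' @return A list of class `patch_spec`.
#' @export
patch_spec <- function(downscale_factor = 4, patch_size = 1024,
                       max_patches_per_image = 200, background_limit = 0.75,
                       background_luminance_threshold = 0.8,
                       max_attempts_per_patch = 100, seed = 1L) {
  if (!(background_limit > 0 && background_limit <= 1)) {
    stop("background_limit must lie in (0, 1]", call. = FALSE)
  }
  if (downscale_factor < 1 || patch_size < 1) {
    stop("downscale_factor and patch_size must be >= 1", call. = FALSE)
  }
  structure(list(downscale_factor = as.integer(downscale_factor),
                 patch_size = as.integer(patch_size),
                 max_patches_per_image = as.integer(max_patches_per_image),
                 background_limit = background_limit,
                 background_luminance_threshold = background_luminance_threshold,
                 max_attempts_per_patch = as.integer(max_attempts_per_patch),
                 seed = as.integer(seed)),
            class = "patch_spec")
}

#' Block-mean downscaling of an RGB image
#'
#' Each output pixel is the mean of a `factor x factor` block; trailing
#' rows/columns that do not fill a block are truncated, so the output
#' dimensions are `floor(input / factor)`.
#'
#' @param image `h x w x 3` numeric array (or `h x w` matrix).
#' @param factor Integer >= 1, at most the smaller image dimension.
#' @return Downscaled array of the same rank.
#' @export
downscale <- function(image, factor) {
  factor <- as.integer(factor)
  d <- dim(image)
  if (factor < 1) stop("factor must be >= 1", call. = FALSE)
  if (factor > min(d[1], d[2])) {
    stop("factor exceeds the image size", call. = FALSE)
  }
  if (factor == 1) return(image)
  h <- d[1] %/% factor
  w <- d[2] %/% factor
  pool <- function(m) {
    m <- m[seq_len(h * factor), seq_len(w * factor), drop = FALSE]
    # average rows within blocks, then columns
    m <- apply(array(m, c(factor, h, w * factor)), c(2, 3), mean)
    t(apply(array(t(m), c(factor, w, h)), c(2, 3), mean))
  }
  if (length(d) == 2) return(pool(image))
  out <- array(0, c(h, w, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- pool(image[, , ch])
  out
}

#' Foreground mask by color (luminance) thresholding
#'
#' A pixel is background iff its mean-channel luminance is at or above the
#' threshold (near-white); the mask is `TRUE` on foreground (tissue).
#'
#' @param image `h x w x 3` numeric array with values in \[0, 1\].
#' @param luminance_threshold Background cutoff as a fraction of full
#'   brightness.
#' @return `h x w` logical matrix, `TRUE` = foreground.
#' @export
foreground_mask <- function(image, luminance_threshold = 0.8) {
  lum <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  lum < luminance_threshold
}

#' Extract random foreground patches from one image
#'
#' Draws uniformly random top-left origins on the downscaled image and
#' accepts a candidate iff its background fraction is strictly below
#' `background_limit` (so a patch with exactly 75% background is rejected
#' under the default). Sampling stops when `max_patches_per_image` patches
#' are accepted or the attempt budget is exhausted — a short count is a
#' valid, logged outcome for background-dominated images.
#'
#' @param image `h x w x 3` numeric array in \[0, 1\] (full-resolution).
#' @param spec A [patch_spec()].
#' @param image_id Identifier recorded with each patch.
#' @return A tibble with one row per accepted patch: `parent_image_id`,
#'   `patch_id`, `row`, `col` (top-left, downscaled coordinates),
#'   `background_fraction`, and `pixels` (list column of patch arrays).
#' @export
extract_patches <- function(image, spec = patch_spec(), image_id = "image") {
  stopifnot(inherits(spec, "patch_spec"))
  small <- downscale(image, spec$downscale_factor)
  d <- dim(small)
  ps <- spec$patch_size
  if (ps > min(d[1], d[2])) {
    stop("patch_size exceeds the downscaled image size", call. = FALSE)
  }
  bg <- !foreground_mask(small, spec$background_luminance_threshold)
  # summed-area table -> O(1) background fraction per candidate
  sat <- apply(apply(bg, 2, cumsum), 1, cumsum)  # sat[j, i] = sum bg[1:i, 1:j]
  bg_count <- function(r, cc) {
    r2 <- r + ps - 1L; c2 <- cc + ps - 1L
    sat[c2, r2] -
      (if (r > 1) sat[c2, r - 1] else 0) -
      (if (cc > 1) sat[cc - 1, r2] else 0) +
      (if (r > 1 && cc > 1) sat[cc - 1, r - 1] else 0)
  }
  budget <- spec$max_attempts_per_patch * spec$max_patches_per_image
  acc <- list()
  withr::with_seed(spec$seed, {
    attempts <- 0L
    while (length(acc) < spec$max_patches_per_image && attempts < budget) {
      attempts <- attempts + 1L
      r <- sample.int(d[1] - ps + 1L, 1L)
      cc <- sample.int(d[2] - ps + 1L, 1L)
      frac <- bg_count(r, cc) / (ps * ps)
      if (frac < spec$background_limit) {
        acc[[length(acc) + 1L]] <- tibble::tibble(
          parent_image_id = image_id,
          patch_id = sprintf("%s_p%04d", image_id, length(acc) + 1L),
          row = r, col = cc, background_fraction = frac,
          pixels = list(small[r:(r + ps - 1L), cc:(cc + ps - 1L), , drop = FALSE])
        )
      }
    }
  })
  if (length(acc) == 0) {
    return(tibble::tibble(parent_image_id = character(), patch_id = character(),
                          row = integer(), col = integer(),
                          background_fraction = numeric(), pixels = list()))
  }
  out <- dplyr::bind_rows(acc)
  if (nrow(out) < spec$max_patches_per_image) {
    message("short patch count for ", image_id, ": ", nrow(out), "/",
            spec$max_patches_per_image, " accepted")
  }
  out
}

#' Count accepted patches across a set of images
#'
#' @param images A named list of `h x w x 3` arrays (names are image ids).
#' @param spec A [patch_spec()]; each image gets a seed derived from
#'   `spec$seed` and its position.
#' @return A list with `total` and `per_image` (tibble of image_id,
#'   n_patches).
#' @export
dataset_patch_count <- function(images, spec = patch_spec()) {
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("image%03d", seq_along(images))
  per <- purrr::map2(images, seq_along(images), function(img, i) {
    s <- spec
    s$seed <- derive_seed(spec$seed, 7L, i)
    tibble::tibble(image_id = ids[i],
                   n_patches = nrow(extract_patches(img, s, image_id = ids[i])))
  })
  per_image <- dplyr::bind_rows(per)
  if (nrow(per_image) == 0) {
    per_image <- tibble::tibble(image_id = character(), n_patches = integer())
  }
  list(total = sum(per_image$n_patches), per_image = per_image)
}

#' Read / write RGB images as PNG
#'
#' @param image `h x w x 3` array in \[0, 1\], or a logical matrix for
#'   `write_mask_png`.
#' @param path PNG file path.
#' @return Readers return an array/matrix; writers return `path` invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] > 3) img <- img[, , 1:3]
  img
}

#' @rdname write_image_png
#' @export
write_mask_png <- function(image, path) {
  png::writePNG(matrix(as.numeric(image), nrow(image), ncol(image)), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}
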