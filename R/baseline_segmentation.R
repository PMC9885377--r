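#' A CT volume: Hounsfield-unit grid plus voxel spacing
#'
#' @param hu Finite numeric 3D array of Hounsfield units, each dimension
#'   >= 8.
#' @param spacing Voxel spacing in mm per axis (length 3).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(hu, spacing = c(1, 1, 1)) {
  if (length(dim(hu)) != 3 || any(dim(hu) < 8)) {
    stop("hu must be a 3D array with every dimension >= 8", call. = FALSE)
  }
  if (!all(is.finite(hu))) stop("hu must be finite", call. = FALSE)
  structure(list(hu = hu, spacing = as.numeric(spacing)), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("CT volume ", paste(dim(x$hu), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = " x "), " mm, HU range [",
      round(min(x$hu)), ", ", round(max(x$hu)), "]\n", sep = "")
  invisible(x)
}

#' Threshold a CT volume at an air Hounsfield cutoff
#'
#' Marks every voxel with HU *strictly below* the threshold as air. The
#' conventional cutoff of -400 HU separates air (about -1000 HU) from soft
#' tissue (about 0-60 HU); a voxel at exactly the threshold is excluded.
#'
#' @param volume A [ct_volume()].
#' @param threshold HU cutoff (default -400).
#' @return A logical 3D array, `TRUE` where HU < threshold.
#' @export
threshold_air <- function(volume, threshold = -400) {
  stopifnot(inherits(volume, "ct_volume"))
  volume$hu < threshold
}

# Shift a 3D logical array by one voxel along axis `a` (+1/-1), padding
# with FALSE.
shift3 <- function(m, a, s) {
  d <- dim(m)
  out <- array(FALSE, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  if (s == 1) {
    idx_dst[[a]] <- 2:d[a]; idx_src[[a]] <- 1:(d[a] - 1)
  } else {
    idx_dst[[a]] <- 1:(d[a] - 1); idx_src[[a]] <- 2:d[a]
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# One-step dilation under 6- (face) or 26- (face+edge+corner) connectivity.
dilate6 <- function(m) {
  out <- m
  for (a in 1:3) out <- out | shift3(m, a, 1) | shift3(m, a, -1)
  out
}

dilate26 <- function(m) {
  out <- m
  for (a in 1:3) out <- out | shift3(out, a, 1) | shift3(out, a, -1)
  out
}

border_mask <- function(d) {
  out <- array(FALSE, d)
  out[c(1, d[1]), , ] <- TRUE
  out[, c(1, d[2]), ] <- TRUE
  out[, , c(1, d[3])] <- TRUE
  out
}

#' Remove air components connected to the grid border
#'
#' Deletes every connected component of `TRUE` voxels that touches any face
#' of the grid — operationally, the air outside the body — and keeps
#' interior components. Implemented as morphological reconstruction seeded
#' at the border and masked by the air voxels, iterated to a fixed point.
#'
#' @param air Logical 3D array of air voxels.
#' @param connectivity 6 (face neighbours, default) or 26.
#' @return A logical array containing only interior air components.
#' @export
remove_border_air <- function(air, connectivity = 6) {
  stopifnot(is.logical(air), length(dim(air)) == 3,
            connectivity %in% c(6, 26))
  dil <- if (connectivity == 6) dilate6 else dilate26
  reach <- air & border_mask(dim(air))
  repeat {
    grown <- dil(reach) & air
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  air & !reach
}

#' Trivial lung-proxy segmenter: internal air by thresholding
#'
#' The baseline model: threshold the volume at -400 HU and discard the air
#' connected to the grid border. What remains is all air inside the body —
#' lungs, but also trachea/airways and bowel gas — an *erroneous* proxy for
#' lung segmentation that nonetheless scores high Dice/IoU against a lung
#' ground truth, because the lungs dominate the internal air volume. Any
#' model that a study proposes should beat this baseline before its overlap
#' scores are taken as evidence of quality.
#'
#' @param volume A [ct_volume()].
#' @param threshold HU cutoff (default -400).
#' @param connectivity Connectivity for the border-air removal.
#' @return A logical 3D array of predicted "lung" (actually internal-air)
#'   voxels.
#' @export
baseline_lung_proxy <- function(volume, threshold = -400, connectivity = 6) {
  remove_border_air(threshold_air(volume, threshold), connectivity)
}

#' Evaluate the baseline segmenter against ground truth on a cohort
#'
#' @param cohort A list of elements each containing `volume` (a
#'   [ct_volume()]) and `lung_truth` (logical array of the same shape), as
#'   produced by [gen_ct_volume()]; an `id` element is used when present.
#' @param threshold,connectivity Passed to [baseline_lung_proxy()].
#' @return An object of class `baseline_eval`: `per_volume` (tibble of id,
#'   dice, iou) and `summary` (min/mean/max/SD rows per metric).
#' @export
evaluate_baseline <- function(cohort, threshold = -400, connectivity = 6) {
  if (length(cohort) < 1) stop("cohort must contain at least one volume", call. = FALSE)
  rows <- purrr::imap(cohort, function(item, i) {
    if (!identical(dim(item$volume$hu), dim(item$lung_truth))) {
      stop("volume and truth shapes differ for volume ", i, call. = FALSE)
    }
    pred <- baseline_lung_proxy(item$volume, threshold, connectivity)
    tibble::tibble(id = if (!is.null(item$id)) as.character(item$id) else as.character(i),
                   dice = dice(pred, item$lung_truth),
                   iou = iou(pred, item$lung_truth))
  })
  per_volume <- dplyr::bind_rows(rows)
  summary <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(metric = "dice"), summarize_scores(per_volume$dice)),
    dplyr::bind_cols(tibble::tibble(metric = "iou"), summarize_scores(per_volume$iou))
  )
  structure(list(per_volume = per_volume, summary = summary),
            class = "baseline_eval")
}

#' @export
print.baseline_eval <- function(x, ...) {
  cat("Baseline internal-air segmenter on", nrow(x$per_volume), "volume(s)\n")
  print(x$summary)
  invisible(x)
}

#' Per-volume Dice/IoU plot for a baseline evaluation
#'
#' @param object A `baseline_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot baseline_eval
#' @export
autoplot.baseline_eval <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_volume, c("dice", "iou"),
                           names_to = "metric", values_to = "score")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$id, y = .data$score,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "volume", y = "overlap with lung truth",
                  title = "Internal-air baseline: high overlap, wrong mask") +
    ggplot2::theme_minimal()
}

#' Read / write volumes and masks as NIfTI
#'
#' Masks round-trip as 0/1 integer grids; voxel spacing is taken from the
#' NIfTI pixel dimensions.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param volume A [ct_volume()].
#' @param mask Logical 3D array.
#' @return Readers return a `ct_volume` / logical array; writers return the
#'   path invisibly.
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim(img)), RNifti::pixdim(img)[1:3])
}

#' @rdname read_ct_volume
#' @export
write_ct_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$hu, pixdim = volume$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_ct_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) != 0, dim(img))
}

#' @rdname read_ct_volume
#' @export
write_mask <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim(mask))), path)
  invisible(path)
}
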