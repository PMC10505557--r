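# Mask-based immunofluorescence quantification: maximum projection,
# counterstain-thresholded wall mask, masked mean intensity, fold changes.

#' Two-channel image stack container
#'
#' A counterstain channel (cell-wall stain, e.g. calcofluor) and a target
#' channel (immunolabel) acquired as a z-stack, stored as numeric arrays in
#' `(z, y, x)` order.
#'
#' @param counterstain,target Numeric `(z, y, x)` arrays of equal shape.
#' @param bit_depth Bits per sample (intensities must fit; default 8).
#' @param pixel_size_um Optional pixel size, micrometres.
#' @return A `two_channel_stack` list.
#' @export
two_channel_stack <- function(counterstain, target, bit_depth = 8,
                              pixel_size_um = NULL) {
  if (!identical(dim(counterstain), dim(target)) ||
      length(dim(counterstain)) != 3L) {
    stop("channels must be (z, y, x) arrays of identical shape", call. = FALSE)
  }
  maxval <- 2^bit_depth - 1
  if (min(counterstain, target) < 0 || max(counterstain, target) > maxval) {
    stop(sprintf("intensities must lie in [0, %d] for %d-bit data",
                 maxval, bit_depth), call. = FALSE)
  }
  structure(list(counterstain = counterstain, target = target,
                 bit_depth = bit_depth, pixel_size_um = pixel_size_um),
            class = "two_channel_stack")
}

#' Maximum-intensity projection of a two-channel stack
#'
#' Pixelwise maximum over z, per channel.
#'
#' @param stack A [two_channel_stack()].
#' @return List with 2D matrices `counterstain` and `target`.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "two_channel_stack"))
  proj1 <- function(a) {
    if (dim(a)[1] == 0L) stop("empty stack (z = 0)", call. = FALSE)
    apply(a, c(2, 3), max)
  }
  list(counterstain = proj1(stack$counterstain),
       target = proj1(stack$target))
}

#' Wall mask from the counterstain projection
#'
#' Thresholds the counterstain channel to restrict quantification to the
#' cell-wall area: `mask = (pixel in ROI) & (counterstain > threshold)`.
#' With `threshold = "otsu"` the threshold is chosen by Otsu's method
#' (via \pkg{EBImage}); a numeric threshold reproduces the interactive
#' user-chosen-threshold workflow. An optional ROI polygon (in pixel
#' coordinates, 0-based `(row, column)` vertices) limits the mask to a
#' hand-drawn region.
#'
#' @param counterstain_projection 2D numeric matrix.
#' @param roi Optional polygon: matrix or data frame with two columns
#'   (row, column), >= 3 vertices.
#' @param threshold Numeric threshold, or `"otsu"` (default).
#' @return A `wall_mask`: logical matrix with attributes `threshold` and
#'   `method`.
#' @export
wall_mask <- function(counterstain_projection, roi = NULL, threshold = "otsu") {
  img <- counterstain_projection
  stopifnot(is.matrix(img))
  if (identical(threshold, "otsu")) {
    thr <- EBImage::otsu(img, range = c(min(img), max(img)), levels = 256)
    method <- "otsu"
  } else {
    thr <- as.numeric(threshold)
    if (!is.finite(thr)) stop("invalid threshold", call. = FALSE)
    method <- "manual"
  }
  mask <- img > thr
  if (!is.null(roi)) {
    roi <- as.matrix(roi)
    if (nrow(roi) < 3L) stop("ROI polygon needs >= 3 vertices", call. = FALSE)
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx)) {
      inside <- mgcv::in.out(rbind(roi, roi[1, ]), idx - 1)  # 0-based coords
      mask[idx[!inside, , drop = FALSE]] <- FALSE
    }
  }
  if (!any(mask)) {
    stop("empty wall mask: threshold too high for this image", call. = FALSE)
  }
  if (all(mask)) {
    stop("mask covers the whole image: threshold below background",
         call. = FALSE)
  }
  structure(mask, threshold = thr, method = method, class = "wall_mask")
}

#' Mean fluorescence of the target channel within the wall mask
#'
#' @param target_projection 2D numeric matrix (target channel projection).
#' @param mask A [wall_mask()] (or logical matrix) of the same shape.
#' @return A `quant_result`: list with `mean_intensity`, `pixel_count`,
#'   `threshold`, `method`.
#' @export
mean_fluorescence <- function(target_projection, mask) {
  if (!identical(dim(target_projection), dim(mask))) {
    stop("projection and mask shapes differ", call. = FALSE)
  }
  m <- as.logical(mask)
  if (!any(m)) stop("empty mask", call. = FALSE)
  structure(list(mean_intensity = mean(target_projection[m]),
                 pixel_count = sum(m),
                 threshold = attr(mask, "threshold"),
                 method = attr(mask, "method") %||% "supplied"),
            class = "quant_result")
}

#' Quantify one stack end to end
#'
#' Projection, counterstain mask, masked mean of the target channel.
#'
#' @param stack A [two_channel_stack()].
#' @inheritParams wall_mask
#' @return A `quant_result`.
#' @export
quantify_stack <- function(stack, roi = NULL, threshold = "otsu") {
  pr <- max_project(stack)
  mean_fluorescence(pr$target, wall_mask(pr$counterstain, roi, threshold))
}

#' Fold change of masked fluorescence between two groups of sections
#'
#' Ratio of group means of the per-section mean intensities (sections are
#' the unit of replication, not pixels), with a percentile bootstrap
#' confidence interval obtained by resampling sections within each group.
#' With `aggregate = "pixels"` the per-section means are instead pooled
#' weighted by masked pixel count before taking the ratio.
#'
#' @param samples,references Lists of `quant_result` objects, one per
#'   section.
#' @param n_boot Bootstrap resamples (default 1999).
#' @param conf Confidence level (default 0.95).
#' @param aggregate `"sections"` (default) or `"pixels"`.
#' @param seed Optional seed for the bootstrap.
#' @return List: `fold_change`, `ci` (length-2), `conf`, `n_samples`,
#'   `n_references`.
#' @export
relative_intensity <- function(samples, references, n_boot = 1999,
                               conf = 0.95, aggregate = c("sections", "pixels"),
                               seed = NULL) {
  aggregate <- match.arg(aggregate)
  get <- function(lst, what) vapply(lst, `[[`, numeric(1), what)
  if (length(samples) < 1L || length(references) < 1L) {
    stop("need at least one quantified section per group", call. = FALSE)
  }
  gm <- function(means, wts) {
    if (aggregate == "pixels") stats::weighted.mean(means, wts) else mean(means)
  }
  sm <- get(samples, "mean_intensity"); sw <- get(samples, "pixel_count")
  rm_ <- get(references, "mean_intensity"); rw <- get(references, "pixel_count")
  ref_mean <- gm(rm_, rw)
  if (ref_mean == 0) stop("reference group mean intensity is zero", call. = FALSE)
  fold <- gm(sm, sw) / ref_mean

  if (!is.null(seed)) set.seed(seed)
  boot <- replicate(n_boot, {
    i <- sample.int(length(sm), replace = TRUE)
    j <- sample.int(length(rm_), replace = TRUE)
    gm(sm[i], sw[i]) / gm(rm_[j], rw[j])
  })
  alpha <- (1 - conf) / 2
  list(fold_change = fold,
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       conf = conf,
       n_samples = length(sm), n_references = length(rm_))
}

#' Read a two-channel TIFF z-stack
#'
#' Pages are interpreted as interleaved channels per z-plane; by default the
#' counterstain channel comes first.
#'
#' @param path TIFF file written by [write_image_stack()] or an equivalent
#'   interleaved layout.
#' @param channel_order `c("counterstain", "target")` by default.
#' @param bit_depth Bits per sample (default 8).
#' @return A [two_channel_stack()].
#' @export
read_image_stack <- function(path, channel_order = c("counterstain", "target"),
                             bit_depth = 8) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% 2L != 0L) {
    stop("expected an even number of TIFF pages (2 channels per z-plane)",
         call. = FALSE)
  }
  nz <- length(pages) / 2L
  maxval <- 2^bit_depth - 1
  grab <- function(offset) {
    a <- array(0, dim = c(nz, nrow(pages[[1]]), ncol(pages[[1]])))
    for (z in seq_len(nz)) a[z, , ] <- pages[[2L * (z - 1L) + offset]] * maxval
    a
  }
  ch <- list(grab(1L), grab(2L))
  names(ch) <- channel_order
  two_channel_stack(ch$counterstain, ch$target, bit_depth = bit_depth)
}

#' Write a two-channel stack as an interleaved multi-page TIFF
#'
#' @param stack A [two_channel_stack()].
#' @param path Output TIFF path.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "two_channel_stack"))
  maxval <- 2^stack$bit_depth - 1
  nz <- dim(stack$counterstain)[1]
  pages <- vector("list", 2L * nz)
  for (z in seq_len(nz)) {
    pages[[2L * z - 1L]] <- stack$counterstain[z, , ] / maxval
    pages[[2L * z]] <- stack$target[z, , ] / maxval
  }
  tiff::writeTIFF(pages, path)
  invisible(path)
}
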