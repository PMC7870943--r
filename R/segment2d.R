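# 2D microcolony segmentation: average-intensity z-projection, then ridge
# detection + morphological watershed + intensity thresholding on the
# channel-sum image, then per-colony feature extraction.

#' Average-intensity z-projection of a voxel stack
#'
#' Each output pixel is the arithmetic mean over z of its (x, y) column, per
#' channel -- the projection applied to confocal stacks before 2D analysis.
#'
#' @param stack A [voxel_stack()].
#' @return A [micrograph()] with `pixel_size = stack$voxel_xy`.
#' @export
project_z <- function(stack) {
  stopifnot(inherits(stack, "voxel_stack"))
  if (dim(stack$ch1)[3] < 1) stop("stack has no z-slices")
  micrograph(rowMeans(stack$ch1, dims = 2), rowMeans(stack$ch2, dims = 2),
             pixel_size = stack$voxel_xy)
}

#' Segment microcolonies in a two-channel micrograph
#'
#' Pipeline on the channel-sum image: (1) Gaussian smoothing at the colony
#' scale; (2) foreground by intensity threshold (Otsu by default); (3) dark
#' inter-colony ridges located at the gap scale via the signed largest
#' Hessian eigenvalue and subtracted from the foreground; (4) morphological
#' watershed seeded from smoothed-intensity local maxima (minimum prominence
#' `seed_tolerance` of the dynamic range), constrained to the foreground;
#' (5) components below `min_area` px^2 removed and labels renumbered 1..n.
#'
#' @param img A [micrograph()].
#' @param smooth_sigma Smoothing scale in px (default 2).
#' @param threshold Foreground threshold on the smoothed sum image, or
#'   `"otsu"` (default).
#' @param ridge_sigma Ridge-detection scale in px, matched to the expected
#'   inter-colony gap width (default 3).
#' @param ridge_quantile Quantile of positive largest-eigenvalue values used
#'   as the ridge threshold (default 0.9); `ridge_threshold` overrides with
#'   an absolute value, and `NA` disables ridge subtraction.
#' @param ridge_threshold Optional absolute ridge threshold.
#' @param seed_tolerance Minimum watershed seed prominence as a fraction of
#'   the smoothed image's dynamic range (default 0.1).
#' @param min_area Minimum colony area in px^2 (default 10).
#' @return A `label_mask` object: integer matrix `labels` (0 = background,
#'   colonies numbered 1..n contiguously) plus the parameters used.
#' @export
segment_microcolonies_2d <- function(img, smooth_sigma = 2,
                                     threshold = "otsu", ridge_sigma = 3,
                                     ridge_quantile = 0.9,
                                     ridge_threshold = NULL,
                                     seed_tolerance = 0.1, min_area = 10) {
  stopifnot(inherits(img, "micrograph"))
  s <- channel_sum(img)
  if (any(!is.finite(s))) stop("image contains non-finite pixels")
  params <- list(smooth_sigma = smooth_sigma, threshold = threshold,
                 ridge_sigma = ridge_sigma, ridge_quantile = ridge_quantile,
                 ridge_threshold = ridge_threshold,
                 seed_tolerance = seed_tolerance, min_area = min_area)

  empty <- function() {
    structure(list(labels = matrix(0L, nrow(s), ncol(s)),
                   n = 0L, provenance = params), class = "label_mask")
  }
  rng <- diff(range(s))
  if (rng == 0) return(empty())

  sm <- filter_separable_2d(s, gauss_kernel(smooth_sigma),
                            gauss_kernel(smooth_sigma))
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(sm)
  } else as.numeric(threshold)
  fg <- sm > thr
  params$foreground_px <- sum(fg)
  if (!any(fg)) return(empty())

  # dark separating ridges: positive principal curvature of the smoothed
  # image at the gap scale (bright colony interiors have l1 << 0)
  H <- hessian_derivatives_2d(s, ridge_sigma)
  l1 <- hessian_eigen_2d(H)$l1
  if (is.null(ridge_threshold)) {
    pos <- l1[l1 > 0]
    ridge_threshold <- if (length(pos)) stats::quantile(pos, ridge_quantile,
                                                        names = FALSE) else Inf
  }
  ridge <- is.finite(ridge_threshold) & (l1 > ridge_threshold)
  fg <- fg & !ridge
  if (!any(fg)) return(empty())

  relief <- sm - min(sm)
  relief[!fg] <- 0
  ws <- EBImage::watershed(EBImage::as.Image(relief),
                           tolerance = seed_tolerance * diff(range(sm)),
                           ext = 1L)
  labels <- matrix(as.integer(EBImage::imageData(ws)), nrow(s), ncol(s))

  # drop small components, renumber contiguously in scan order
  if (max(labels) > 0L) {
    sizes <- tabulate(labels, nbins = max(labels))
    keep <- which(sizes >= min_area)
    remap <- integer(max(labels))
    remap[keep] <- seq_along(keep)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
  }
  structure(list(labels = labels, n = max(labels), provenance = params),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d colonies\n",
              nrow(x$labels), ncol(x$labels), x$n))
  invisible(x)
}

#' Otsu threshold of a numeric matrix
#'
#' Histogram-based threshold minimising intra-class variance, computed on the
#' matrix rescaled to `[0, 1]` and mapped back to the original intensity
#' range.
#'
#' @param mat Numeric matrix with finite entries and non-zero range.
#' @param levels Number of histogram bins (default 256).
#' @return Threshold on the original intensity scale.
#' @export
otsu_threshold <- function(mat, levels = 256L) {
  if (any(!is.finite(mat))) stop("non-finite values in image")
  lo <- min(mat); hi <- max(mat)
  if (hi == lo) stop("constant image: Otsu threshold undefined")
  x <- (mat - lo) / (hi - lo)
  t01 <- EBImage::otsu(EBImage::as.Image(x), range = c(0, 1), levels = levels)
  lo + t01 * (hi - lo)
}

#' Extract per-colony features from a label mask
#'
#' Per label: intensity-unweighted pixel centroid (scaled to um), orientation
#' and equivalent-ellipse axis lengths from the second central moments, area,
#' and mean brightness in each channel. Orientation is measured from the +x
#' axis, counter-clockwise positive in the image frame (y down), in degrees
#' in `[-90, 90)`.
#'
#' @param mask A `label_mask` from [segment_microcolonies_2d()].
#' @param img The source [micrograph()] (same shape).
#' @return Data frame (one row per colony): `label`, `x_um`, `y_um`,
#'   `orientation_deg`, `length_um`, `width_um`, `area_um2`, `brightness_1`,
#'   `brightness_2`.
#' @export
extract_colony_features <- function(mask, img) {
  stopifnot(inherits(mask, "label_mask"), inherits(img, "micrograph"),
            identical(dim(mask$labels), dim(img$ch1)))
  px <- img$pixel_size
  n <- mask$n
  out <- data.frame(label = integer(0), x_um = numeric(0), y_um = numeric(0),
                    orientation_deg = numeric(0), length_um = numeric(0),
                    width_um = numeric(0), area_um2 = numeric(0),
                    brightness_1 = numeric(0), brightness_2 = numeric(0))
  if (n == 0L) return(out)
  lab <- mask$labels
  pix <- which(lab > 0L)
  rc <- arrayInd(pix, dim(lab))
  l <- lab[pix]
  # physical coordinates of pixel centres, origin at top-left pixel centre
  xs <- (rc[, 2] - 1) * px
  ys <- (rc[, 1] - 1) * px
  area <- tabulate(l, nbins = n)
  if (any(area == 0L)) stop("label with zero pixels")
  cx <- rowsum(xs, l)[, 1] / area
  cy <- rowsum(ys, l)[, 1] / area
  dx <- xs - cx[l]
  dy <- ys - cy[l]
  mxx <- rowsum(dx * dx, l)[, 1] / area
  myy <- rowsum(dy * dy, l)[, 1] / area
  mxy <- rowsum(dx * dy, l)[, 1] / area
  # single-pixel regularisation: a pixel is a px-by-px square
  reg <- px^2 / 12
  mxx <- mxx + reg; myy <- myy + reg
  common <- sqrt(pmax((mxx - myy)^2 + 4 * mxy^2, 0))
  emax <- (mxx + myy + common) / 2
  emin <- (mxx + myy - common) / 2
  len <- 4 * sqrt(pmax(emax, 0))
  wid <- 4 * sqrt(pmax(emin, 0))
  # orientation of the major axis; y axis points down, so negate for CCW+
  theta <- 0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi
  theta <- -theta
  theta[theta >= 90] <- theta[theta >= 90] - 180
  theta[theta < -90] <- theta[theta < -90] + 180
  b1 <- rowsum(img$ch1[pix], l)[, 1] / area
  b2 <- rowsum(img$ch2[pix], l)[, 1] / area
  data.frame(label = seq_len(n), x_um = cx, y_um = cy,
             orientation_deg = theta, length_um = len, width_um = wid,
             area_um2 = area * px^2, brightness_1 = b1, brightness_2 = b2)
}

#' Call the genotype of each segmented colony from channel brightness
#'
#' @param features Data frame from [extract_colony_features()].
#' @return The same data frame with a `genotype` column (`"A"` if channel 1
#'   is brighter, else `"B"`).
#' @export
call_colony_genotypes <- function(features) {
  features$genotype <- ifelse(features$brightness_1 >= features$brightness_2,
                              "A", "B")
  features
}
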