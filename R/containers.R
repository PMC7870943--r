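#' @keywords internal
"_PACKAGE"

# Label alphabet for genotype masks. Stored as integer matrices so that
# summed-area tables and TIFF round-trips stay exact.
GT_NONE <- 0L
GT_A <- 1L
GT_B <- 2L

#' Two-channel fluorescence micrograph
#'
#' Container for a registered pair of 2D intensity images (one per fluorophore)
#' plus the physical pixel size. Matrices are indexed `[row, col]` with row
#' increasing down the image (y) and column increasing to the right (x);
#' physical coordinates in micrometres place the origin at the centre of the
#' top-left pixel.
#'
#' @param ch1,ch2 Numeric matrices of identical dimension, non-negative.
#' @param pixel_size Pixel edge length in micrometres (default 1.515, the
#'   confocal sampling at which 100 px corresponds to 151.5 um).
#' @return A `micrograph` object.
#' @export
micrograph <- function(ch1, ch2, pixel_size = 1.515) {
  ch1 <- as.matrix(ch1)
  ch2 <- as.matrix(ch2)
  stopifnot(identical(dim(ch1), dim(ch2)), pixel_size > 0)
  if (isTRUE(any(ch1 < 0)) || isTRUE(any(ch2 < 0))) {
    stop("micrograph intensities must be non-negative")
  }
  structure(list(ch1 = ch1, ch2 = ch2, pixel_size = pixel_size),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px, %.3f um/px, 2 channels\n",
              nrow(x$ch1), ncol(x$ch1), x$pixel_size))
  invisible(x)
}

#' Two-channel confocal voxel stack
#'
#' @param ch1,ch2 Numeric 3D arrays `[row, col, z]` of identical dimension.
#' @param voxel_xy Lateral voxel size in micrometres.
#' @param z_step Axial step in micrometres (default 2.73, the confocal
#'   acquisition step).
#' @return A `voxel_stack` object.
#' @export
voxel_stack <- function(ch1, ch2 = NULL, voxel_xy = 1.515, z_step = 2.73) {
  stopifnot(length(dim(ch1)) == 3, voxel_xy > 0, z_step > 0)
  if (is.null(ch2)) ch2 <- array(0, dim(ch1))
  stopifnot(identical(dim(ch1), dim(ch2)))
  if (isTRUE(any(ch1 < 0)) || isTRUE(any(ch2 < 0))) {
    stop("voxel intensities must be non-negative")
  }
  structure(list(ch1 = ch1, ch2 = ch2, voxel_xy = voxel_xy, z_step = z_step),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$ch1)
  cat(sprintf("<voxel_stack> %d x %d x %d voxels, %.3f um xy, %.2f um z\n",
              d[1], d[2], d[3], x$voxel_xy, x$z_step))
  invisible(x)
}

#' Per-pixel genotype mask
#'
#' Integer matrix over the 3-value alphabet 0 = NONE, 1 = A, 2 = B, carrying
#' the pixel size needed to convert neighbourhood spans between px and um.
#'
#' @param labels Integer matrix with values in `{0, 1, 2}`.
#' @param pixel_size Micrometres per pixel.
#' @return A `genotype_mask` object.
#' @export
genotype_mask <- function(labels, pixel_size = 1.515) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% c(GT_NONE, GT_A, GT_B))) {
    stop("genotype mask labels must be 0 (NONE), 1 (A) or 2 (B)")
  }
  stopifnot(pixel_size > 0)
  structure(list(labels = labels, pixel_size = pixel_size),
            class = "genotype_mask")
}

#' @export
print.genotype_mask <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, nbins = 3L)
  cat(sprintf("<genotype_mask> %d x %d px (%.3f um/px): %d A, %d B, %d NONE\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size,
              tab[2], tab[3], tab[1]))
  invisible(x)
}

# internal: channel-sum image used for structural (genotype-blind) operations
channel_sum <- function(img) img$ch1 + img$ch2

stack_channel_sum <- function(stack) stack$ch1 + stack$ch2
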