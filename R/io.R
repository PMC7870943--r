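# File I/O: two-channel micrographs and label/genotype masks as TIFF,
# microcolony tables as CSV.

#' Write / read a two-channel micrograph as multi-page TIFF
#'
#' Channels are stored as two 32-bit float pages. The TIFF container holds
#' values in `[0, 1]`, so both channels are jointly rescaled by the image
#' maximum on write; every downstream operation (thresholding, segmentation,
#' SI) is invariant to this common scale. The pixel size is not carried by
#' the plain-TIFF container and must be re-supplied on read.
#'
#' @param img A [micrograph()].
#' @param path TIFF file path.
#' @param pixel_size Micrometres per pixel to attach on read.
#' @return The path (write) or a [micrograph()] (read).
#' @export
write_micrograph <- function(img, path) {
  stopifnot(inherits(img, "micrograph"))
  scale <- max(img$ch1, img$ch2, 1e-12)
  tiff::writeTIFF(list(img$ch1 / scale, img$ch2 / scale), path,
                  bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_micrograph
#' @export
read_micrograph <- function(path, pixel_size = 1.515) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) stop("expected a 2-page (2-channel) TIFF")
  micrograph(pages[[1]], pages[[2]], pixel_size)
}

#' Write a label mask as 16-bit TIFF
#'
#' @param mask A `label_mask`.
#' @param path TIFF file path.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (mask$n > 65535) stop("more than 65535 labels")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write / read a genotype mask as 8-bit TIFF (palette 0=NONE, 1=A, 2=B)
#'
#' @param mask A [genotype_mask()].
#' @param path TIFF file path.
#' @param pixel_size Micrometres per pixel to attach on read.
#' @export
write_genotype_mask <- function(mask, path) {
  stopifnot(inherits(mask, "genotype_mask"))
  tiff::writeTIFF(mask$labels / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_genotype_mask
#' @export
read_genotype_mask <- function(path, pixel_size = 1.515) {
  m <- tiff::readTIFF(path)
  genotype_mask(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)),
                pixel_size)
}

#' Write / read a microcolony table as CSV
#'
#' Column order: label, x_um, y_um, orientation_deg, length_um, width_um,
#' area_um2, brightness_1, brightness_2, and genotype when present.
#'
#' @param table Microcolony feature data frame.
#' @param path CSV file path.
#' @export
write_colony_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_colony_table
#' @export
read_colony_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
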