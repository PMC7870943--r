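#' Render the idealised reference mask of a printing map
#'
#' Produces the per-pixel genotype image an ideal print of `map` would give:
#' each droplet is drawn as a filled disk of `droplet_diameter` at its lattice
#' position, pixels inside an A (B) droplet are labelled A (B), pixels inside
#' MIXED droplets are labelled A or B independently per pixel with probability
#' `mix_fraction` (seeded), and pixels outside all droplets are NONE. These
#' reference images give the theoretical SI(h) of a printing map against which
#' measured prints are compared.
#'
#' @param map A `printing_map`.
#' @param pixel_size Micrometres per pixel (default 1.515). Must not exceed
#'   the droplet diameter.
#' @param seed Integer seed for the per-pixel assignment inside MIXED
#'   droplets.
#' @param margin_um Background margin added on every side, in micrometres
#'   (default 0: canvas is the print's bounding box).
#' @return A [genotype_mask()].
#' @examples
#' m <- render_reference_image(make_printing_map(2, 2, "checkerboard"),
#'                             pixel_size = 5)
#' table(m$labels)
#' @export
render_reference_image <- function(map, pixel_size = 1.515, seed = 1L,
                                   margin_um = 0) {
  stopifnot(inherits(map, "printing_map"), pixel_size > 0, margin_um >= 0)
  if (pixel_size > map$droplet_diameter) {
    stop("pixel_size exceeds the droplet diameter: droplets are unresolvable")
  }
  width_um <- map$n_x * map$pitch + 2 * margin_um
  height_um <- map$n_y * map$pitch + 2 * margin_um
  nc <- max(1L, ceiling(width_um / pixel_size))
  nr <- max(1L, ceiling(height_um / pixel_size))

  # physical coordinates of pixel centres
  px_x <- (seq_len(nc) - 0.5) * pixel_size
  px_y <- (seq_len(nr) - 0.5) * pixel_size
  labels <- matrix(GT_NONE, nr, nc)

  centres <- droplet_centres(map)
  r <- map$droplet_diameter / 2
  rng_old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(rng_old)) assign(".Random.seed", rng_old, globalenv()))
  for (k in seq_len(nrow(centres))) {
    a <- centres$assignment[k]
    if (a == "EMPTY") next
    cx <- centres$x_um[k] + margin_um
    cy <- centres$y_um[k] + margin_um
    cols <- which(abs(px_x - cx) <= r)
    rows <- which(abs(px_y - cy) <= r)
    if (!length(cols) || !length(rows)) next
    inside <- outer((px_y[rows] - cy)^2, (px_x[cols] - cx)^2, `+`) <= r^2
    lab <- switch(a,
      A = GT_A, B = GT_B,
      MIXED = NULL)
    block <- labels[rows, cols, drop = FALSE]
    if (is.null(lab)) {
      n_in <- sum(inside)
      draw <- ifelse(stats::runif(n_in) < map$mix_fraction, GT_A, GT_B)
      block[inside] <- draw
    } else {
      block[inside] <- lab
    }
    labels[rows, cols] <- block
  }
  genotype_mask(labels, pixel_size)
}
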