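# Synthetic-scene generator: seeded printing maps -> founder cells ->
# microcolonies -> noisy two-channel micrographs (and voxel stacks) with
# ground truth, emulating droplet-printed arrays (110-um droplets, ~70 cells
# per droplet at 1e8 cells/mL, colonies grown to median diameter 15 um).

ML_PER_UM3 <- 1e-12  # 1 um^3 in mL

#' Expected founder cells per droplet
#'
#' Analytic Poisson mean: inoculation density times the spherical droplet
#' volume. At 1e8 cells/mL and 110-um droplets this is 69.7, i.e. the ~70
#' cells per droplet the printer deposits.
#'
#' @param density Cell density in cells per mL.
#' @param droplet_diameter Droplet diameter in micrometres.
#' @return Expected number of cells in one droplet.
#' @export
cells_per_droplet <- function(density = 1e8, droplet_diameter = 110) {
  stopifnot(density >= 0, droplet_diameter > 0)
  density * (4 / 3) * pi * (droplet_diameter / 2)^3 * ML_PER_UM3
}

# droplet-level sub-seed so each droplet's cell stream is independently
# reproducible regardless of how many droplets precede it
.droplet_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Sample founder cells into the droplets of a printing map
#'
#' Per droplet the cell count is Poisson with mean `density` times the
#' spherical droplet volume (or exactly `cells_exact` when given); positions
#' are uniform over the droplet's circular footprint; genotypes follow the
#' droplet assignment, with per-cell Bernoulli(`mix_fraction`) draws inside
#' MIXED droplets. EMPTY droplets receive no cells.
#'
#' @param map A `printing_map`.
#' @param density Cells per mL (default 1e8).
#' @param seed Integer seed; one seed drives a hierarchical per-droplet
#'   stream.
#' @param cells_exact Optional fixed cell count per droplet (deterministic
#'   counts for exact tests).
#' @param confine_radius Optional maximum radial distance of cells from the
#'   droplet centre, in micrometres (defaults to the droplet radius).
#' @return Data frame with columns `x_um`, `y_um`, `genotype`, `row`, `col`.
#' @export
sample_initial_cells <- function(map, density = 1e8, seed = 1L,
                                 cells_exact = NULL, confine_radius = NULL) {
  stopifnot(inherits(map, "printing_map"))
  if (density < 0) stop("density must be non-negative")
  r_drop <- map$droplet_diameter / 2
  r_max <- if (is.null(confine_radius)) r_drop else min(confine_radius, r_drop)
  lambda <- cells_per_droplet(density, map$droplet_diameter)
  centres <- droplet_centres(map)
  out <- vector("list", nrow(centres))
  for (k in seq_len(nrow(centres))) {
    a <- centres$assignment[k]
    if (a == "EMPTY") next
    set.seed(.droplet_seed(seed, k))
    n <- if (is.null(cells_exact)) stats::rpois(1, lambda) else as.integer(cells_exact)
    if (n == 0) next
    # uniform over the disk footprint
    rad <- r_max * sqrt(stats::runif(n))
    ang <- stats::runif(n, 0, 2 * pi)
    gt <- switch(a,
      A = rep("A", n),
      B = rep("B", n),
      MIXED = ifelse(stats::runif(n) < map$mix_fraction, "A", "B"))
    out[[k]] <- data.frame(
      x_um = centres$x_um[k] + rad * cos(ang),
      y_um = centres$y_um[k] + rad * sin(ang),
      genotype = gt, row = centres$row[k], col = centres$col[k],
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(x_um = numeric(), y_um = numeric(),
                      genotype = character(), row = integer(),
                      col = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# log-normal colony diameters: median 15 um, sdlog 0.55 puts the quartiles at
# ~10.4 and ~21.7 um, emulating the reported 15 (10-21) um spread
default_growth <- function() list(median_diameter = 15, sdlog = 0.55)

default_noise <- function() list(background = 0.05, gradient = 0.05, sd = 0.02)

#' Render a synthetic printed-array scene
#'
#' Grows the founder cells of `map` into disk-shaped (2D) or spherical (3D)
#' microcolonies with log-normally distributed diameters (population median =
#' `growth$median_diameter`), draws each colony into its genotype's
#' fluorescence channel, applies an optional whole-print rotation about the
#' print centroid, adds off-print debris colonies, and overlays background,
#' a linear intensity gradient and additive Gaussian noise. Ground truth
#' (colony centres, genotypes, diameters, debris flags) is retained.
#'
#' The canvas leaves a margin of two droplet diameters of background around
#' the print so that rotation and debris stay inside the frame.
#'
#' @param map A `printing_map`.
#' @param growth List with `median_diameter` (um) and `sdlog`; `sdlog = 0`
#'   gives monodisperse colonies.
#' @param noise List with `background`, `gradient` and `sd` (additive noise
#'   scale); all zero gives an exact sum-of-disks image.
#' @param rotation Whole-print rotation in degrees (screen counter-clockwise)
#'   about the print centroid.
#' @param n_debris Number of extra colonies placed outside the print
#'   footprint.
#' @param debris_distance Radial range of debris placement about the print
#'   centre, in multiples of the print side length (default `c(2, 2.5)`).
#' @param seed Integer seed; fully determines the scene.
#' @param density Cells per mL passed to [sample_initial_cells()].
#' @param pixel_size Micrometres per pixel of the rendered image.
#' @param cells_exact,confine_radius Passed to [sample_initial_cells()].
#' @param amplitude Peak intensity a single colony adds to its channel.
#' @param stack If TRUE also render a 3D voxel stack (spheres) with z-step
#'   `z_step`.
#' @param render If FALSE skip image rendering entirely (`image` is NULL):
#'   the fast path for geometry work that only needs the ground-truth point
#'   set.
#' @param z_step Axial voxel size of the rendered stack in micrometres.
#' @return A `synthetic_scene`: list with `map`, `colonies` (ground truth,
#'   coordinates in the image frame), `image` ([micrograph()]), optional
#'   `stack` ([voxel_stack()]), `rotation`, `centre_um` (print centroid in the
#'   image frame), and `seed`.
#' @export
render_scene <- function(map, growth = default_growth(),
                         noise = default_noise(), rotation = 0, n_debris = 0,
                         seed = 1L, density = 1e8, pixel_size = 1.515,
                         cells_exact = NULL, confine_radius = NULL,
                         amplitude = 1, stack = FALSE, z_step = 2.73,
                         render = TRUE, debris_distance = c(2, 2.5)) {
  stopifnot(inherits(map, "printing_map"))
  growth <- utils::modifyList(default_growth(), growth)
  noise <- utils::modifyList(default_noise(), noise)
  if (growth$median_diameter <= 0) {
    stop("colony diameter distribution must have positive support")
  }

  cells <- sample_initial_cells(map, density = density, seed = seed,
                                cells_exact = cells_exact,
                                confine_radius = confine_radius)
  margin <- 2 * map$droplet_diameter
  print_w <- map$n_x * map$pitch
  print_h <- map$n_y * map$pitch
  cx <- margin + print_w / 2
  cy <- margin + print_h / 2

  set.seed(.droplet_seed(seed, 0L))
  n_cells <- nrow(cells)
  diam <- if (n_cells) {
    stats::rlnorm(n_cells, meanlog = log(growth$median_diameter),
                  sdlog = growth$sdlog)
  } else numeric()

  x <- cells$x_um + margin
  y <- cells$y_um + margin
  if (rotation != 0 && n_cells) {
    th <- rotation * pi / 180
    # screen CCW: y axis points down, so the maths rotation angle is -th
    xr <- cx + (x - cx) * cos(th) + (y - cy) * sin(th)
    yr <- cy - (x - cx) * sin(th) + (y - cy) * cos(th)
    x <- xr; y <- yr
  }
  colonies <- data.frame(x_um = x, y_um = y,
                         genotype = if (n_cells) cells$genotype else character(),
                         diameter_um = diam,
                         is_debris = rep(FALSE, n_cells),
                         stringsAsFactors = FALSE)

  if (n_debris > 0) {
    # detached debris / fragments of other prints sit well beyond the print
    # footprint (by default 2-2.5 print side lengths from the centre, so the
    # radial isolation threshold separates them cleanly); debris outside the
    # rendered canvas contributes to the ground truth but not the image
    dd <- data.frame(x_um = numeric(n_debris), y_um = numeric(n_debris),
                     genotype = sample(c("A", "B"), n_debris, replace = TRUE),
                     diameter_um = stats::rlnorm(n_debris,
                                                 log(growth$median_diameter),
                                                 growth$sdlog),
                     is_debris = TRUE, stringsAsFactors = FALSE)
    side <- max(print_w, print_h)
    ang <- stats::runif(n_debris, 0, 2 * pi)
    rad <- stats::runif(n_debris, debris_distance[1] * side,
                        debris_distance[2] * side)
    dd$x_um <- cx + rad * cos(ang)
    dd$y_um <- cy + rad * sin(ang)
    colonies <- rbind(colonies, dd)
  }

  img <- NULL
  stk <- NULL
  if (render) {
  width_um <- print_w + 2 * margin
  height_um <- print_h + 2 * margin
  nc <- ceiling(width_um / pixel_size)
  nr <- ceiling(height_um / pixel_size)
  ch1 <- matrix(0, nr, nc)
  ch2 <- matrix(0, nr, nc)
  px_x <- (seq_len(nc) - 0.5) * pixel_size
  px_y <- (seq_len(nr) - 0.5) * pixel_size

  draw_disk <- function(mat, cx0, cy0, r0) {
    cols <- which(abs(px_x - cx0) <= r0)
    rows <- which(abs(px_y - cy0) <= r0)
    if (!length(cols) || !length(rows)) return(mat)
    inside <- outer((px_y[rows] - cy0)^2, (px_x[cols] - cx0)^2, `+`) <= r0^2
    mat[rows, cols] <- mat[rows, cols] + amplitude * inside
    mat
  }
  for (i in seq_len(nrow(colonies))) {
    r0 <- colonies$diameter_um[i] / 2
    if (colonies$genotype[i] == "A") {
      ch1 <- draw_disk(ch1, colonies$x_um[i], colonies$y_um[i], r0)
    } else {
      ch2 <- draw_disk(ch2, colonies$x_um[i], colonies$y_um[i], r0)
    }
  }

  add_noise <- function(mat) {
    mat <- mat + noise$background +
      noise$gradient * matrix(px_x / width_um, nr, nc, byrow = TRUE)
    if (noise$sd > 0) mat <- mat + matrix(stats::rnorm(nr * nc, 0, noise$sd), nr, nc)
    pmax(mat, 0)
  }
  ch1 <- add_noise(ch1)
  ch2 <- add_noise(ch2)
  img <- micrograph(ch1, ch2, pixel_size)

  if (stack) {
    nz <- max(1L, ceiling(max(colonies$diameter_um, z_step) / z_step) + 2L)
    z_mid <- (nz / 2) * z_step
    s1 <- array(0, c(nr, nc, nz)); s2 <- array(0, c(nr, nc, nz))
    pz <- (seq_len(nz) - 0.5) * z_step
    for (i in seq_len(nrow(colonies))) {
      r0 <- colonies$diameter_um[i] / 2
      for (k in which(abs(pz - z_mid) <= r0)) {
        rz <- sqrt(max(r0^2 - (pz[k] - z_mid)^2, 0))
        if (rz <= 0) next
        if (colonies$genotype[i] == "A") {
          s1[, , k] <- draw_disk(s1[, , k], colonies$x_um[i], colonies$y_um[i], rz)
        } else {
          s2[, , k] <- draw_disk(s2[, , k], colonies$x_um[i], colonies$y_um[i], rz)
        }
      }
    }
    stk <- voxel_stack(s1, s2, voxel_xy = pixel_size, z_step = z_step)
  }
  }

  structure(list(map = map, colonies = colonies, image = img, stack = stk,
                 rotation = rotation, centre_um = c(x = cx, y = cy),
                 margin_um = margin, seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d colonies (%d debris), rotation %.1f deg, seed %d\n",
              nrow(x$colonies), sum(x$colonies$is_debris), x$rotation, x$seed))
  print(x$image)
  invisible(x)
}

#' Synthetic stack of bright spheres for 3D segmentation tests
#'
#' Renders spheres of given centres/radii (in voxels) into a single-channel
#' stack, then smooths slightly so that narrow dark gaps between spheres
#' carry intermediate intensity -- the regime in which a plain intensity
#' threshold fuses closely packed microcolonies and the Hessian separator is
#' needed to split them.
#'
#' @param centres Numeric matrix (n x 3) of sphere centres in voxel units
#'   (row, col, z).
#' @param radii Sphere radii in voxels (recycled).
#' @param dim Stack dimensions `c(nr, nc, nz)`.
#' @param smooth_sigma Gaussian sigma (voxels) of the post-render smoothing.
#' @param voxel_xy,z_step Physical voxel sizes in micrometres.
#' @return A [voxel_stack()].
#' @export
synth_sphere_stack <- function(centres, radii, dim = c(40, 40, 24),
                               smooth_sigma = 1, voxel_xy = 1, z_step = 1) {
  centres <- matrix(centres, ncol = 3)
  radii <- rep_len(radii, nrow(centres))
  a <- array(0, dim)
  idx <- arrayInd(seq_len(prod(dim)), dim)
  for (i in seq_len(nrow(centres))) {
    d2 <- (idx[, 1] - centres[i, 1])^2 + (idx[, 2] - centres[i, 2])^2 +
      (idx[, 3] - centres[i, 3])^2
    a[d2 <= radii[i]^2] <- 1
  }
  if (smooth_sigma > 0) {
    a <- gaussian_smooth_3d(a, sigma = rep(smooth_sigma, 3))
  }
  voxel_stack(a, voxel_xy = voxel_xy, z_step = z_step)
}

#' Write a scene to disk (TIFF image + ground-truth CSV + JSON sidecar)
#'
#' @param scene A `synthetic_scene`.
#' @param prefix Output path prefix; writes `<prefix>.tif`,
#'   `<prefix>_truth.csv` and `<prefix>.json`.
#' @export
write_scene <- function(scene, prefix) {
  stopifnot(inherits(scene, "synthetic_scene"))
  write_micrograph(scene$image, paste0(prefix, ".tif"))
  utils::write.csv(scene$colonies, paste0(prefix, "_truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = scene$seed, rotation = scene$rotation,
         pixel_size = scene$image$pixel_size,
         centre_um = as.list(scene$centre_um),
         map = list(n_x = scene$map$n_x, n_y = scene$map$n_y,
                    pattern = scene$map$pattern,
                    droplet_diameter = scene$map$droplet_diameter,
                    pitch = scene$map$pitch,
                    mix_fraction = scene$map$mix_fraction)),
    paste0(prefix, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(prefix)
}
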