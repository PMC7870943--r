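# Print geometry: isolate a print from debris via a radial threshold on the
# estimated side length, register it to the x-y axes with the k = 4 Fourier
# shape descriptor of its convex hull, and compute Delaunay
# neighbour-neighbour distances.

# L = 6 rbar / (sqrt(2) + log(1 + sqrt(2))): inverts the mean
# centre-to-point distance of a uniform square of side L
SQUARE_RBAR_CONST <- sqrt(2) + log(1 + sqrt(2))

#' Estimate the centre of a print
#'
#' Arithmetic mean of the microcolony x and y coordinates.
#'
#' @param table Data frame with `x_um`, `y_um` columns (a microcolony table).
#' @return Named numeric `c(x, y)` in micrometres.
#' @export
estimate_centre <- function(table) {
  if (!nrow(table)) stop("empty microcolony table")
  c(x = mean(table$x_um), y = mean(table$y_um))
}

#' Estimate the side length of a (square) print
#'
#' From the mean radial distance rbar of microcolonies about the centre:
#' L = 6 rbar / (sqrt(2) + log(1 + sqrt(2))), the exact relation between the
#' side length of a uniformly filled square and the expected distance of its
#' points from the centre.
#'
#' @param table Microcolony table.
#' @param centre Print centre `c(x, y)`; defaults to [estimate_centre()].
#' @return List with `L` (side length, um) and `r_bar` (mean radius, um).
#' @export
estimate_side_length <- function(table, centre = estimate_centre(table)) {
  if (!nrow(table)) stop("empty microcolony table")
  r_bar <- mean(sqrt((table$x_um - centre[1])^2 + (table$y_um - centre[2])^2))
  list(L = 6 * r_bar / SQUARE_RBAR_CONST, r_bar = r_bar)
}

#' Isolate the main print from debris
#'
#' Applies a radial distance threshold of `margin_factor * L * sqrt(2) / 2`
#' (the print's half-diagonal with slack) about the estimated centre, removes
#' microcolonies beyond it, recomputes the centre on the survivors, and
#' re-applies the threshold once with the refined centre.
#'
#' @param table Microcolony table.
#' @param margin_factor Slack on the half-diagonal (default 1.15).
#' @param refine_passes Number of centre/threshold refinement passes
#'   (default 1).
#' @return List with `table` (retained colonies), `removed` (row indices of
#'   the input that were dropped), `centre`, `L`.
#' @export
isolate_print <- function(table, margin_factor = 1.15, refine_passes = 1L) {
  stopifnot(margin_factor > 0)
  if (!nrow(table)) stop("empty microcolony table")
  keep <- rep(TRUE, nrow(table))
  centre <- estimate_centre(table)
  L <- estimate_side_length(table, centre)$L
  for (pass in seq_len(refine_passes + 1L)) {
    thr <- margin_factor * L * sqrt(2) / 2
    d <- sqrt((table$x_um - centre[1])^2 + (table$y_um - centre[2])^2)
    keep <- d <= thr
    if (!any(keep)) stop("radial threshold removed every microcolony")
    centre <- estimate_centre(table[keep, , drop = FALSE])
    L <- estimate_side_length(table[keep, , drop = FALSE], centre)$L
  }
  list(table = table[keep, , drop = FALSE], removed = which(!keep),
       centre = centre, L = L)
}

#' Register a print to the x-y axes via the k = 4 Fourier descriptor
#'
#' Builds the convex hull of the microcolony positions, measures the distance
#' of each hull vertex from the centre, resamples those distances onto `N`
#' regularly spaced polar angles (linear interpolation with circular wrap),
#' subtracts the mean to obtain the radial deviation profile d(phi) -- which
#' peaks at the four print corners -- and recovers the print's rotation from
#' the phase of the discrete Fourier transform of d(phi) at wavenumber 4:
#' theta = (1/4) (pi - arg sum_n d(phi_n) exp(-i 8 pi n / N)).
#'
#' The returned table has the positions rotated about the centre so the print
#' is axis-aligned; `extent` is the (width, height) of the registered
#' bounding box. `theta_deg` is reported in `[-45, 45)`: the print's apparent
#' (screen) rotation modulo the descriptor's 90-degree symmetry.
#'
#' @param table Microcolony table (>= 4 non-collinear positions).
#' @param centre Print centre; defaults to [estimate_centre()].
#' @param n_angles Number of resampling angles N (default 360).
#' @return List with `theta_deg`, `table` (registered positions), `extent`
#'   (named width/height, um), and `profile` (data frame `phi`, `d`).
#' @export
register_print <- function(table, centre = estimate_centre(table),
                           n_angles = 360L) {
  stopifnot(n_angles >= 8)
  if (nrow(table) < 4) stop("need at least 4 microcolonies to register")
  x <- table$x_um - centre[1]
  y <- table$y_um - centre[2]
  hull <- grDevices::chull(x, y)
  if (length(hull) < 3) stop("degenerate (collinear) convex hull")
  hx <- x[hull]; hy <- y[hull]

  # distance from the centre to the hull boundary along each regular polar
  # angle (the polygon's radial support function, by ray-edge intersection)
  phi <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  ux <- cos(phi); uy <- sin(phi)
  d <- rep(NA_real_, n_angles)
  nh <- length(hull)
  for (e in seq_len(nh)) {
    p1x <- hx[e]; p1y <- hy[e]
    j <- if (e == nh) 1L else e + 1L
    dx <- hx[j] - p1x; dy <- hy[j] - p1y
    den <- ux * dy - uy * dx
    ok <- abs(den) > 1e-12
    s <- (p1x * dy - p1y * dx) / den
    t <- (p1x * uy - p1y * ux) / den
    hit <- ok & s > 0 & t >= -1e-9 & t <= 1 + 1e-9
    d[hit] <- ifelse(is.na(d[hit]), s[hit], pmin(d[hit], s[hit]))
  }
  if (anyNA(d)) stop("degenerate hull: centre outside the hull polygon")
  d <- d - mean(d)

  n <- seq_len(n_angles) - 1
  dft4 <- sum(d * exp(-1i * 8 * pi * n / n_angles))
  theta <- (pi - Arg(dft4)) / 4
  # fold into [-45, 45) deg
  theta_deg <- ((theta * 180 / pi + 45) %% 90) - 45

  # undo the apparent rotation: screen-CCW by theta_deg maps to this rotation
  # of (x, y-down) coordinates back to axis alignment
  th <- theta_deg * pi / 180
  xr <- centre[1] + x * cos(th) + y * sin(th)
  yr <- centre[2] - x * sin(th) + y * cos(th)
  reg <- table
  reg$x_um <- xr
  reg$y_um <- yr
  list(theta_deg = theta_deg, table = reg,
       extent = c(width = diff(range(xr)), height = diff(range(yr))),
       profile = data.frame(phi = phi, d = d))
}

#' Delaunay neighbour-neighbour distances of a print
#'
#' Applies Delaunay triangulation to the microcolony positions; directly
#' connected colonies are neighbours. Colonies on the outer convex hull of
#' the print are flagged as boundary and excluded from the reported distance
#' distribution: only edges whose both endpoints are interior contribute.
#'
#' @param table Microcolony table (>= 3 non-collinear positions).
#' @return List with `edges` (data frame `ind1`, `ind2`, `distance_um` for
#'   every Delaunay edge), `boundary` (row indices on the hull), and
#'   `interior_distances` (um, edges between interior colonies only).
#' @export
neighbour_distances <- function(table) {
  if (nrow(table) < 3) stop("need at least 3 microcolonies")
  x <- table$x_um; y <- table$y_um
  if (abs(stats::sd(x)) < 1e-12 || abs(stats::sd(y)) < 1e-12 ||
      qr(cbind(x - mean(x), y - mean(y)))$rank < 2) {
    stop("collinear microcolony positions")
  }
  dd <- deldir::deldir(x, y, suppressMsge = TRUE)
  e <- dd$delsgs
  dist <- sqrt((e$x1 - e$x2)^2 + (e$y1 - e$y2)^2)
  edges <- data.frame(ind1 = e$ind1, ind2 = e$ind2, distance_um = dist)
  boundary <- sort(unique(grDevices::chull(x, y)))
  interior <- !(edges$ind1 %in% boundary) & !(edges$ind2 %in% boundary)
  list(edges = edges, boundary = boundary,
       interior_distances = edges$distance_um[interior])
}

#' Full geometry summary of a microcolony table
#'
#' Convenience wrapper: isolate, register, and triangulate in one pass.
#'
#' @param table Microcolony table.
#' @param margin_factor Passed to [isolate_print()].
#' @param n_angles Passed to [register_print()].
#' @return List with `isolated`, `registration`, `neighbours` and a flat
#'   `summary` list (centre, r_bar, L, theta_deg, extent, median
#'   neighbour distance).
#' @export
print_geometry <- function(table, margin_factor = 1.15, n_angles = 360L) {
  iso <- isolate_print(table, margin_factor)
  reg <- register_print(iso$table, iso$centre, n_angles)
  nb <- neighbour_distances(iso$table)
  sl <- estimate_side_length(iso$table, iso$centre)
  list(isolated = iso, registration = reg, neighbours = nb,
       summary = list(centre = iso$centre, r_bar = sl$r_bar, L = sl$L,
                      theta_deg = reg$theta_deg, extent = reg$extent,
                      median_neighbour_um =
                        stats::median(nb$interior_distances)))
}
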