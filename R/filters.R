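# Separable Gaussian scale-space filtering for 2D images and 3D stacks.
# Derivatives are taken by convolving with sampled Gaussian-derivative
# kernels (not by finite differences on the smoothed image); edges use
# replicate padding.

gauss_kernel <- function(sigma, order = 0L) {
  stopifnot(sigma > 0, order %in% 0:2)
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(order + 1L,
    g,
    -x / sigma^2 * g,
    (x^2 / sigma^4 - 1 / sigma^2) * g)
}

# dense n x n convolution operator with replicate-edge padding
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    j <- pmin(pmax(seq_len(n) + o, 1L), n)
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + kernel[o + r + 1L]
  }
  K
}

# filter a matrix separably: kernel_r along rows (y), kernel_c along cols (x)
filter_separable_2d <- function(mat, kernel_r, kernel_c) {
  Kr <- conv_matrix(nrow(mat), kernel_r)
  Kc <- conv_matrix(ncol(mat), kernel_c)
  Kr %*% mat %*% t(Kc)
}

filter_axis_3d <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  m <- conv_matrix(da[1], kernel) %*% m
  a <- array(m, da)
  aperm(a, order(perm))
}

filter_separable_3d <- function(arr, kernels) {
  for (ax in 1:3) arr <- filter_axis_3d(arr, kernels[[ax]], ax)
  arr
}

#' Gaussian smoothing of a 3D array
#'
#' @param arr Numeric 3D array.
#' @param sigma Per-axis standard deviations in voxels, length 3 (row, col,
#'   z); entries of 0 skip that axis.
#' @return Smoothed array of the same dimension.
#' @export
gaussian_smooth_3d <- function(arr, sigma) {
  stopifnot(length(dim(arr)) == 3, length(sigma) == 3)
  for (ax in 1:3) {
    if (sigma[ax] > 0) arr <- filter_axis_3d(arr, gauss_kernel(sigma[ax]), ax)
  }
  arr
}

# second-derivative images of a 2D matrix at scale sigma (pixel units):
# returns list(xx, xy, yy) with x = columns, y = rows
hessian_derivatives_2d <- function(mat, sigma) {
  g0 <- gauss_kernel(sigma, 0L)
  g1 <- gauss_kernel(sigma, 1L)
  g2 <- gauss_kernel(sigma, 2L)
  list(
    xx = filter_separable_2d(mat, g0, g2),
    xy = filter_separable_2d(mat, g1, g1),
    yy = filter_separable_2d(mat, g2, g0)
  )
}

# signed eigenvalues of the per-pixel symmetric 2x2 Hessian, ordered by
# magnitude |l1| >= |l2|; input from hessian_derivatives_2d
hessian_eigen_2d <- function(H) {
  tr <- H$xx + H$yy
  disc <- sqrt(pmax((H$xx - H$yy)^2 + 4 * H$xy^2, 0))
  e1 <- (tr + disc) / 2
  e2 <- (tr - disc) / 2
  swap <- abs(e2) > abs(e1)
  l1 <- ifelse(swap, e2, e1)
  l2 <- ifelse(swap, e1, e2)
  list(l1 = matrix(l1, nrow(H$xx)), l2 = matrix(l2, nrow(H$xx)))
}

# six Gaussian second-derivative volumes of a 3D array; sigma in voxels per
# axis, spacing = physical voxel size per axis so derivatives are per um
hessian_derivatives_3d <- function(arr, sigma, spacing = c(1, 1, 1)) {
  k <- lapply(1:3, function(ax) list(
    g0 = gauss_kernel(sigma[ax], 0L),
    g1 = gauss_kernel(sigma[ax], 1L) / spacing[ax],
    g2 = gauss_kernel(sigma[ax], 2L) / spacing[ax]^2))
  dd <- function(o1, o2, o3) {
    pick <- function(kk, o) switch(o + 1L, kk$g0, kk$g1, kk$g2)
    filter_separable_3d(arr, list(pick(k[[1]], o1), pick(k[[2]], o2),
                                  pick(k[[3]], o3)))
  }
  # axis 1 = rows = y, axis 2 = cols = x, axis 3 = z
  list(xx = dd(0L, 2L, 0L), yy = dd(2L, 0L, 0L), zz = dd(0L, 0L, 2L),
       xy = dd(1L, 1L, 0L), xz = dd(0L, 1L, 1L), yz = dd(1L, 0L, 1L))
}

# vectorised eigenvalues of symmetric 3x3 matrices (trigonometric method),
# returned ordered by magnitude |l1| >= |l2| >= |l3|
symeig3_by_magnitude <- function(a11, a22, a33, a12, a13, a23) {
  n <- length(a11)
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  e1 <- e2 <- e3 <- q
  ok <- p > .Machine$double.eps * pmax(abs(q), 1)
  if (any(ok)) {
    pp <- p[ok]
    b11 <- (a11[ok] - q[ok]) / pp; b22 <- (a22[ok] - q[ok]) / pp
    b33 <- (a33[ok] - q[ok]) / pp
    b12 <- a12[ok] / pp; b13 <- a13[ok] / pp; b23 <- a23[ok] / pp
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    x1 <- q[ok] + 2 * pp * cos(phi)
    x3 <- q[ok] + 2 * pp * cos(phi + 2 * pi / 3)
    x2 <- 3 * q[ok] - x1 - x3
    e1[ok] <- x1; e2[ok] <- x2; e3[ok] <- x3
  }
  # order each triple by descending magnitude
  E <- cbind(e1, e2, e3)
  A <- abs(E)
  o1 <- max.col(A, ties.method = "first")
  l1 <- E[cbind(seq_len(n), o1)]
  A[cbind(seq_len(n), o1)] <- -Inf
  o2 <- max.col(A, ties.method = "first")
  l2 <- E[cbind(seq_len(n), o2)]
  l3 <- (e1 + e2 + e3) - l1 - l2
  list(l1 = l1, l2 = l2, l3 = l3)
}
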