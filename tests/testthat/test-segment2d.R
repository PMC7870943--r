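test_that("z-projection is the per-column arithmetic mean", {
  slice <- matrix(runif(30), 5, 6)
  stk <- voxel_stack(array(rep(slice, 4), c(5, 6, 4)),
                     array(rep(slice * 2, 4), c(5, 6, 4)))
  p <- project_z(stk)
  expect_equal(p$ch1, slice)
  expect_equal(p$ch2, slice * 2)
  expect_equal(p$pixel_size, stk$voxel_xy)

  two <- voxel_stack(array(c(matrix(0, 2, 2), matrix(2, 2, 2)), c(2, 2, 2)))
  expect_equal(project_z(two)$ch1, matrix(1, 2, 2))

  one <- voxel_stack(array(slice, c(5, 6, 1)))
  expect_equal(project_z(one)$ch1, slice)
})

test_that("segmentation recovers non-touching colonies exactly", {
  sc <- sparse_scene(seed = 3)
  lab <- segment_microcolonies_2d(sc$image)
  expect_equal(lab$n, nrow(sc$colonies))
  # labels contiguous from 1
  expect_equal(sort(unique(as.integer(lab$labels))), 0:lab$n)
  # area conservation: labelled area never exceeds the thresholded
  # foreground area
  expect_lte(sum(lab$labels > 0), lab$provenance$foreground_px)
})

test_that("segmentation count stays within 5% under default noise", {
  sc <- sparse_scene(seed = 11, noise = TRUE)
  lab <- segment_microcolonies_2d(sc$image)
  expect_lte(abs(lab$n - nrow(sc$colonies)) / nrow(sc$colonies), 0.05)
})

test_that("blank and degenerate images are handled", {
  blank <- micrograph(matrix(0, 40, 40), matrix(0, 40, 40))
  expect_equal(segment_microcolonies_2d(blank)$n, 0L)
  bad <- micrograph(matrix(1, 10, 10), matrix(1, 10, 10))
  bad$ch1[5, 5] <- NA
  expect_error(segment_microcolonies_2d(bad), "non-finite")
})

test_that("a dark gap splits two bright disks into two labels", {
  # two disks of radius 10 px with a ~4 px dark gap between them
  nr <- 60; nc <- 90
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  d1 <- (g$r - 30)^2 + (g$c - 34)^2 <= 100
  d2 <- (g$r - 30)^2 + (g$c - 58)^2 <= 100
  ch1 <- matrix(0, nr, nc)
  ch1[cbind(g$r, g$c)[d1 | d2, ]] <- 1
  img <- micrograph(ch1, matrix(0, nr, nc))
  lab <- segment_microcolonies_2d(img)
  expect_equal(lab$n, 2L)
})

test_that("colony features match moment-based oracles", {
  # symmetric disk: centroid in um, equal axis lengths, orientation-free
  lab2 <- matrix(0L, 100, 100)
  g <- expand.grid(r = 1:100, c = 1:100)
  ins <- (g$c - 51)^2 + (g$r - 41)^2 <= 100
  lab2[cbind(g$r, g$c)[ins, ]] <- 1L
  mk <- structure(list(labels = lab2, n = 1L, provenance = list()),
                  class = "label_mask")
  img <- micrograph(matrix(100, 100, 100), matrix(0, 100, 100),
                    pixel_size = 1.515)
  fe <- extract_colony_features(mk, img)
  expect_equal(fe$x_um, 50 * 1.515)
  expect_equal(fe$y_um, 40 * 1.515)
  expect_equal(fe$length_um, 20 * 1.515, tolerance = 0.02)
  expect_equal(fe$width_um, 20 * 1.515, tolerance = 0.02)
  expect_equal(fe$brightness_1, 100)
  expect_equal(fe$brightness_2, 0)
  expect_equal(fe$area_um2, sum(ins) * 1.515^2)

  # axis-ratio-2 ellipse drawn at +30 degrees (screen CCW)
  th <- 30 * pi / 180
  g2 <- expand.grid(r = 1:121, c = 1:121)
  X <- g2$c - 61; Y <- g2$r - 61
  u <- X * cos(th) - Y * sin(th)
  v <- X * sin(th) + Y * cos(th)
  ins2 <- (u / 30)^2 + (v / 15)^2 <= 1
  labE <- matrix(0L, 121, 121)
  labE[cbind(g2$r, g2$c)[ins2, ]] <- 1L
  mkE <- structure(list(labels = labE, n = 1L, provenance = list()),
                   class = "label_mask")
  imgE <- micrograph(matrix(1, 121, 121), matrix(0, 121, 121), 1)
  feE <- extract_colony_features(mkE, imgE)
  expect_equal(feE$orientation_deg, 30, tolerance = 2 / 30)
  expect_equal(feE$length_um / feE$width_um, 2, tolerance = 0.05)
})

test_that("left-right flips mirror centroids and negate orientations", {
  sc <- sparse_scene(seed = 5, n_x = 4, n_y = 4)
  img <- sc$image
  lab <- segment_microcolonies_2d(img)
  fe <- extract_colony_features(lab, img)

  flip <- micrograph(img$ch1[, ncol(img$ch1):1], img$ch2[, ncol(img$ch2):1],
                     img$pixel_size)
  labf <- segment_microcolonies_2d(flip)
  fef <- extract_colony_features(labf, flip)
  expect_equal(labf$n, lab$n)
  width_um <- (ncol(img$ch1) - 1) * img$pixel_size
  o <- order(fe$x_um, fe$y_um)
  of <- order(width_um - fef$x_um, fef$y_um)
  expect_equal(fe$x_um[o], width_um - fef$x_um[of], tolerance = 1e-6)
  expect_equal(fe$y_um[o], fef$y_um[of], tolerance = 1e-6)
  # orientations negate (mod 180, and +/-90 is its own mirror)
  d <- (fe$orientation_deg[o] + fef$orientation_deg[of]) %% 180
  expect_true(all(pmin(d, 180 - d) < 1e-6))
})

test_that("single-channel colonies are dark in the other channel", {
  m <- make_printing_map(3, 3, "checkerboard")
  sc <- render_scene(m, cells_exact = 1, confine_radius = 20,
                     growth = list(sdlog = 0.2), noise = no_noise(), seed = 9)
  lab <- segment_microcolonies_2d(sc$image)
  fe <- call_colony_genotypes(extract_colony_features(lab, sc$image))
  other <- ifelse(fe$genotype == "A", fe$brightness_2, fe$brightness_1)
  expect_true(all(other == 0))
})
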