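test_that("printing map patterns lay out genotypes as designed", {
  m <- make_printing_map(7, 8, "segregated_halves")
  expect_equal(dim(m$assignment), c(8, 7))
  expect_true(all(m$assignment[1:4, ] == "A"))
  expect_true(all(m$assignment[5:8, ] == "B"))

  m1 <- make_printing_map(1, 1, "mixed", mix_fraction = 0.5)
  expect_equal(m1$assignment[1, 1], "MIXED")
  expect_equal(m1$mix_fraction, 0.5)

  cb <- make_printing_map(2, 2, "checkerboard")
  expect_equal(cb$assignment, matrix(c("A", "B", "B", "A"), 2, 2))

  st <- make_printing_map(7, 8, "strips", widths = c(2, 4, 2))
  expect_true(all(st$assignment[1:2, ] == "A"))
  expect_true(all(st$assignment[3:6, ] == "B"))
  expect_true(all(st$assignment[7:8, ] == "A"))

  expect_error(make_printing_map(7, 8, "spiral"))
  expect_error(make_printing_map(2, 2, "custom",
                                 grid = matrix("A", 3, 3)))
  expect_error(make_printing_map(7, 8, "strips", widths = c(3, 3)))
})

test_that("printing maps round-trip through JSON and CSV", {
  m <- make_printing_map(5, 4, "checkerboard", droplet_diameter = 100,
                         pitch = 120)
  fj <- tempfile(fileext = ".json")
  write_printing_map(m, fj)
  m2 <- read_printing_map(fj)
  expect_equal(m2$assignment, m$assignment)
  expect_equal(m2$pitch, 120)

  fc <- tempfile(fileext = ".csv")
  write_printing_map_csv(m, fc)
  m3 <- read_printing_map_csv(fc, droplet_diameter = 100, pitch = 120)
  expect_equal(m3$assignment, m$assignment)
})

test_that("reference masks render disks with the mapped genotypes", {
  all_a <- make_printing_map(3, 3, "custom", grid = matrix("A", 3, 3))
  ref <- render_reference_image(all_a, pixel_size = 5)
  expect_true(all(ref$labels %in% c(0L, 1L)))
  expect_gt(sum(ref$labels == 1L), 0)

  empty <- make_printing_map(2, 2, "custom", grid = matrix("EMPTY", 2, 2))
  expect_true(all(render_reference_image(empty, pixel_size = 5)$labels == 0L))

  # disk area of each droplet close to pi r^2
  one <- make_printing_map(1, 1, "custom", grid = matrix("B", 1, 1))
  refb <- render_reference_image(one, pixel_size = 1)
  expect_equal(sum(refb$labels == 2L), pi * 55^2, tolerance = 0.01)

  expect_error(render_reference_image(all_a, pixel_size = 200),
               "unresolvable")
})

test_that("founder-cell counts follow the Poisson droplet-volume model", {
  expect_equal(cells_per_droplet(1e8, 110), 69.69, tolerance = 1e-3)
  expect_equal(cells_per_droplet(2e8, 110), 139.38, tolerance = 1e-3)

  m <- make_printing_map(2, 2, "mixed")
  expect_equal(nrow(sample_initial_cells(m, density = 0, seed = 1)), 0)
  expect_error(sample_initial_cells(m, density = -1))

  # cells stay inside their droplet footprint
  cells <- sample_initial_cells(m, seed = 5)
  cen <- droplet_centres(m)
  idx <- match(paste(cells$row, cells$col), paste(cen$row, cen$col))
  d <- sqrt((cells$x_um - cen$x_um[idx])^2 + (cells$y_um - cen$y_um[idx])^2)
  expect_true(all(d <= 55 + 1e-9))
})

test_that("scenes are deterministic and honest about their ground truth", {
  m <- make_printing_map(2, 2, "mixed")
  s1 <- render_scene(m, seed = 7, cells_exact = 3)
  s2 <- render_scene(m, seed = 7, cells_exact = 3)
  expect_identical(s1$colonies, s2$colonies)
  expect_identical(s1$image$ch1, s2$image$ch1)
  expect_identical(s1$image$ch2, s2$image$ch2)
  s3 <- render_scene(m, seed = 8, cells_exact = 3)
  expect_false(identical(s1$image$ch1, s3$image$ch1))

  # noise-free image is the exact sum of colony disks on zero background
  sc <- render_scene(m, seed = 2, cells_exact = 2, noise = no_noise())
  px <- sc$image$pixel_size
  nr <- nrow(sc$image$ch1); nc <- ncol(sc$image$ch1)
  px_x <- (seq_len(nc) - 0.5) * px
  px_y <- (seq_len(nr) - 0.5) * px
  expect_sum <- matrix(0, nr, nc)
  for (i in seq_len(nrow(sc$colonies))) {
    r0 <- sc$colonies$diameter_um[i] / 2
    expect_sum <- expect_sum +
      (outer((px_y - sc$colonies$y_um[i])^2,
             (px_x - sc$colonies$x_um[i])^2, `+`) <= r0^2)
  }
  expect_equal(sc$image$ch1 + sc$image$ch2, expect_sum)

  # label honesty: pixels inside exactly one colony emit only in that
  # colony's genotype channel
  single <- which(expect_sum == 1)
  for (i in seq_len(nrow(sc$colonies))) {
    r0 <- sc$colonies$diameter_um[i] / 2
    inside <- outer((px_y - sc$colonies$y_um[i])^2,
                    (px_x - sc$colonies$x_um[i])^2, `+`) <= r0^2
    own <- intersect(which(inside), single)
    if (!length(own)) next
    ch_own <- if (sc$colonies$genotype[i] == "A") sc$image$ch1 else sc$image$ch2
    ch_other <- if (sc$colonies$genotype[i] == "A") sc$image$ch2 else sc$image$ch1
    expect_true(all(ch_own[own] == 1))
    expect_true(all(ch_other[own] == 0))
  }
})

test_that("colony diameters match the reported growth distribution", {
  m <- make_printing_map(7, 8, "mixed")
  sc <- render_scene(m, seed = 1, cells_exact = 20, render = FALSE)
  expect_equal(stats::median(sc$colonies$diameter_um), 15, tolerance = 1 / 15)
  q <- stats::quantile(sc$colonies$diameter_um, c(0.25, 0.75))
  expect_equal(unname(q[1]), 10.4, tolerance = 0.08)
  expect_equal(unname(q[2]), 21.7, tolerance = 0.08)
  expect_error(render_scene(m, growth = list(median_diameter = -1)))
})

test_that("scene files round-trip through TIFF + CSV + JSON", {
  m <- make_printing_map(2, 2, "checkerboard")
  sc <- render_scene(m, seed = 4, cells_exact = 2, pixel_size = 3)
  pre <- tempfile()
  write_scene(sc, pre)
  img <- read_micrograph(paste0(pre, ".tif"), pixel_size = 3)
  expect_equal(dim(img$ch1), dim(sc$image$ch1))
  scale <- max(sc$image$ch1, sc$image$ch2)
  expect_equal(img$ch1, sc$image$ch1 / scale, tolerance = 1e-6)
  truth <- read_colony_table(paste0(pre, "_truth.csv"))
  expect_equal(nrow(truth), nrow(sc$colonies))
  side <- jsonlite::read_json(paste0(pre, ".json"), simplifyVector = TRUE)
  expect_equal(side$seed, 4)
})
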