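test_that("centre and side-length estimators evaluate the printed formulas", {
  sq <- data.frame(x_um = c(-1, 1, 1, -1), y_um = c(-1, -1, 1, 1))
  expect_equal(unname(estimate_centre(sq)), c(0, 0))
  expect_equal(unname(estimate_centre(data.frame(x_um = 3, y_um = 7))),
               c(3, 7))
  expect_error(estimate_centre(data.frame(x_um = numeric(),
                                          y_um = numeric())), "empty")

  # direct evaluation: L = 6 * 100 / (sqrt(2) + log(1 + sqrt(2)))
  t4 <- data.frame(x_um = c(100, -100, 0, 0), y_um = c(0, 0, 100, -100))
  expect_equal(estimate_side_length(t4)$r_bar, 100)
  expect_equal(estimate_side_length(t4)$L,
               600 / (sqrt(2) + log(1 + sqrt(2))))
  expect_equal(estimate_side_length(t4)$L, 261.37, tolerance = 1e-4)

  centred <- data.frame(x_um = c(0, 0), y_um = c(0, 0))
  expect_equal(estimate_side_length(centred)$L, 0)
})

test_that("side-length estimator is consistent on uniform squares", {
  Lh <- vapply(1:50, function(s) {
    set.seed(s)
    tab <- data.frame(x_um = runif(1000, 0, 1000),
                      y_um = runif(1000, 0, 1000))
    estimate_side_length(tab)$L
  }, numeric(1))
  expect_lt(abs(mean(Lh) - 1000) / 1000, 0.02)
})

test_that("print centre estimation hits the generator ground truth", {
  m <- make_printing_map(8, 8, "mixed")
  sc <- render_scene(m, cells_exact = 30, seed = 21, render = FALSE)
  cen <- estimate_centre(sc$colonies[, c("x_um", "y_um")])
  expect_lt(sqrt(sum((cen - sc$centre_um)^2)), 5)
})

test_that("isolation removes exactly the debris and refines the centre", {
  m <- make_printing_map(7, 8, "mixed")
  for (s in 1:5) {
    sc <- render_scene(m, cells_exact = 5, n_debris = 5, seed = s,
                       render = FALSE)
    iso <- isolate_print(sc$colonies[, c("x_um", "y_um")])
    expect_identical(sort(iso$removed), which(sc$colonies$is_debris))
  }

  clean <- render_scene(m, cells_exact = 5, seed = 31, render = FALSE)
  iso0 <- isolate_print(clean$colonies[, c("x_um", "y_um")])
  expect_equal(nrow(iso0$table), nrow(clean$colonies))

  biased <- render_scene(m, cells_exact = 5, n_debris = 8, seed = 2,
                         render = FALSE)
  init <- estimate_centre(biased$colonies[, c("x_um", "y_um")])
  iso <- isolate_print(biased$colonies[, c("x_um", "y_um")])
  err_init <- sqrt(sum((init - biased$centre_um)^2))
  err_ref <- sqrt(sum((iso$centre - biased$centre_um)^2))
  expect_lt(err_ref, err_init)

  tiny <- data.frame(x_um = c(0, 1), y_um = c(0, 1))
  expect_error(isolate_print(tiny, margin_factor = 1e-6), "every microcolony")
})

test_that("the k = 4 descriptor registers square prints", {
  # axis-aligned grid: exactly zero
  sq <- expand.grid(x_um = seq(0, 100, 5), y_um = seq(0, 100, 5))
  expect_lt(abs(register_print(sq)$theta_deg), 0.5)

  m <- make_printing_map(8, 8, "mixed")
  base <- render_scene(m, cells_exact = 50, seed = 12, render = FALSE)
  rot10 <- render_scene(m, cells_exact = 50, rotation = 10, seed = 12,
                        render = FALSE)
  rot100 <- render_scene(m, cells_exact = 50, rotation = 100, seed = 12,
                         render = FALSE)
  th10 <- register_print(rot10$colonies[, c("x_um", "y_um")])$theta_deg
  th100 <- register_print(rot100$colonies[, c("x_um", "y_um")])$theta_deg
  # a +10 degree scene rotation is recovered as -10 modulo the k = 4
  # symmetry, and +100 degrees is indistinguishable from +10
  expect_lt(ang_mod90(th10 + 10), 1)
  expect_lt(abs(th10 - th100), 0.5)

  expect_error(register_print(data.frame(x_um = 1:5, y_um = 1:5)),
               "hull|collinear|degenerate")
})

test_that("registration recovers arbitrary rotations within a degree", {
  m <- make_printing_map(8, 8, "mixed")
  errs <- vapply(1:40, function(s) {
    set.seed(s + 400)
    rot <- runif(1, 0, 360)
    sc <- render_scene(m, cells_exact = 50, rotation = rot, seed = s,
                       render = FALSE)
    th <- register_print(sc$colonies[, c("x_um", "y_um")])$theta_deg
    ang_mod90(th + rot)
  }, numeric(1))
  expect_lt(max(errs), 1)
})

test_that("registered extents are stable under exact 90-degree rotation", {
  m <- make_printing_map(7, 8, "mixed")
  sc <- render_scene(m, cells_exact = 40, seed = 13, render = FALSE)
  tab <- sc$colonies[, c("x_um", "y_um")]
  cen <- estimate_centre(tab)
  rot90 <- data.frame(x_um = cen[1] - (tab$y_um - cen[2]),
                      y_um = cen[2] + (tab$x_um - cen[1]))
  e1 <- register_print(tab)$extent
  e2 <- register_print(rot90)$extent
  expect_equal(sort(unname(e1)), sort(unname(e2)), tolerance = 1e-6)
})

test_that("Delaunay neighbours on lattices show the expected distances", {
  set.seed(9)
  g <- expand.grid(x_um = (1:10) * 18, y_um = (1:10) * 18)
  g$x_um <- g$x_um + rnorm(100, 0, 0.1)
  g$y_um <- g$y_um + rnorm(100, 0, 0.1)
  nb <- neighbour_distances(g)
  d <- nb$interior_distances
  expect_gt(mean(abs(d - 18) < 1 | abs(d - 18 * sqrt(2)) < 1), 0.95)

  # hexagonal lattice: all interior neighbour distances equal the pitch
  a <- 20
  hex <- do.call(rbind, lapply(0:9, function(r) {
    data.frame(x_um = (0:9) * a + (r %% 2) * a / 2, y_um = r * a * sqrt(3) / 2)
  }))
  set.seed(2)
  hex$x_um <- hex$x_um + rnorm(100, 0, 0.05)
  hex$y_um <- hex$y_um + rnorm(100, 0, 0.05)
  dh <- neighbour_distances(hex)$interior_distances
  expect_gt(mean(abs(dh - a) < 1), 0.95)

  # one triangle: every point is on the hull, nothing interior
  tri <- data.frame(x_um = c(0, 10, 5), y_um = c(0, 0, 9))
  expect_length(neighbour_distances(tri)$interior_distances, 0)
  expect_error(neighbour_distances(tri[1:2, ]), "at least 3")
  coll <- data.frame(x_um = c(0, 1, 2), y_um = c(0, 1, 2))
  expect_error(neighbour_distances(coll), "collinear")
})

test_that("the geometry wrapper summarises a debris-laden print", {
  m <- make_printing_map(7, 8, "mixed")
  sc <- render_scene(m, cells_exact = 20, n_debris = 4, rotation = 6,
                     seed = 17, render = FALSE)
  geo <- print_geometry(sc$colonies[, c("x_um", "y_um")])
  expect_equal(length(geo$isolated$removed), 4)
  expect_lt(ang_mod90(geo$summary$theta_deg + 6), 1)
  expect_true(geo$summary$median_neighbour_um > 0)
  # side length close to the designed print extent (770 x 880 um)
  expect_equal(geo$summary$L, 825, tolerance = 0.1)
})
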