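test_that("pixel genotypes follow the dual-Otsu classification", {
  # block image: one region bright only in ch1, one only in ch2, one in both,
  # one in neither
  ch1 <- matrix(0, 20, 20); ch2 <- matrix(0, 20, 20)
  ch1[1:10, 1:10] <- 10                    # A
  ch2[1:10, 11:20] <- 10                   # B
  ch1[11:20, 11:20] <- 10; ch2[11:20, 11:20] <- 10  # both -> NONE
  img <- micrograph(ch1, ch2)
  gm <- assign_pixel_genotypes(img)
  expect_true(all(gm$labels[1:10, 1:10] == 1L))
  expect_true(all(gm$labels[1:10, 11:20] == 2L))
  expect_true(all(gm$labels[11:20, 11:20] == 0L))
  expect_true(all(gm$labels[11:20, 1:10] == 0L))

  # all-dark with explicit thresholds: everything NONE
  dark <- micrograph(matrix(0.1, 5, 5), matrix(0.1, 5, 5))
  gm0 <- assign_pixel_genotypes(dark, thresholds = c(1, 1))
  expect_true(all(gm0$labels == 0L))

  # constant channel: Otsu undefined without an override
  expect_error(assign_pixel_genotypes(dark), "constant")
})

test_that("local SI counts kin over clipped square neighbourhoods", {
  allA <- mk_mask(matrix(1L, 10, 10))
  expect_true(all(local_si(allA, 3) == 1))

  # single A surrounded by 8 B, h = 1: self-inclusive kin fraction 1/9
  lab <- matrix(2L, 3, 3); lab[2, 2] <- 1L
  s <- local_si(mk_mask(lab), 1)
  expect_equal(s[2, 2], 1 / 9)
  # each edge B sees 6 pixels of which 5 kin
  expect_equal(s[1, 2], 5 / 6)

  # checkerboard, interior pixel, h = 1: self + 4 diagonal kin of 9
  cb <- matrix(rep(c(1L, 2L), length.out = 81), 9, 9)
  scb <- local_si(mk_mask(cb), 1)
  expect_equal(scb[5, 5], 5 / 9)

  expect_error(local_si(allA, 0), "h must be")
  expect_error(local_si(mk_mask(matrix(0L, 4, 4)), 1), "no A or B")

  # exclude-self variant: the lone A has zero kin neighbours
  s2 <- local_si(mk_mask(lab), 1, include_self = FALSE)
  expect_equal(s2[2, 2], 0)
})

test_that("global SI spans the mixing range", {
  one <- mk_mask(matrix(1L, 30, 30))
  for (h in c(1, 5, 12)) expect_identical(global_si(one, h)$si, 1)

  set.seed(8)
  rnd <- mk_mask(matrix(sample(1:2, 200 * 200, replace = TRUE), 200, 200))
  expect_equal(global_si(rnd, 60)$si, 0.5, tolerance = 0.01)
  expect_equal(global_si(rnd, 60)$m, 200 * 200)
})

test_that("summed-area SI equals the brute-force oracle exactly", {
  for (seed in 1:3) {
    msk <- random_mask(if (seed == 1) 64 else 32,
                       if (seed == 1) 64 else 48,
                       p_none = 0.3, seed = seed)
    for (h in c(1, 4, 7)) {
      fast <- global_si(msk, h)
      slow <- global_si_bruteforce(msk, h)
      expect_identical(fast$m, slow$m)
      expect_equal(fast$si, slow$si, tolerance = 1e-12)
    }
  }
  # exclude-self variant agrees too
  msk <- random_mask(32, 32, seed = 9)
  expect_equal(global_si(msk, 3, include_self = FALSE)$si,
               global_si_bruteforce(msk, 3, include_self = FALSE)$si,
               tolerance = 1e-12)
})

test_that("SI is invariant to label swaps and right-angle rotations", {
  msk <- random_mask(40, 40, seed = 4)
  base <- global_si(msk, 5)$si
  swapped <- mk_mask(ifelse(msk$labels == 0L, 0L, 3L - msk$labels))
  expect_equal(global_si(swapped, 5)$si, base, tolerance = 1e-12)
  r90 <- mk_mask(t(msk$labels)[ncol(msk$labels):1, ])
  r180 <- mk_mask(msk$labels[nrow(msk$labels):1, ncol(msk$labels):1])
  expect_equal(global_si(r90, 5)$si, base, tolerance = 1e-12)
  expect_equal(global_si(r180, 5)$si, base, tolerance = 1e-12)
  s <- local_si(msk, 5)
  expect_true(all(s >= 0 & s <= 1, na.rm = TRUE))
})

test_that("SI profiles decrease with span on segregated prints", {
  ref <- render_reference_image(make_printing_map(7, 8, "segregated_halves"))
  prof <- si_profile(ref, spans_px = c(5L, 10L, 20L, 50L, 100L))
  expect_true(all(diff(prof$si) < 0))
  expect_equal(prof$span_um, prof$span_px * 1.515)

  single <- si_profile(ref, spans_px = 20L)
  expect_equal(nrow(single), 1)
  expect_equal(single$si, global_si(ref, 20L)$si)

  viaum <- si_profile(ref, spans_um = c(7.6, 151.5))
  expect_equal(viaum$span_px, c(5L, 100L))
  expect_error(si_profile(ref, spans_px = c(10L, 5L)), "increasing")
})

test_that("span conversion follows the px-um table", {
  expect_equal(span_um_to_px(c(7.6, 15.2, 30.3, 75.8, 151.5)),
               c(5L, 10L, 20L, 50L, 100L))
  expect_equal(span_px_to_um(100), 151.5)
})

test_that("reference comparison quantifies printing fidelity", {
  map <- make_printing_map(7, 8, "segregated_halves")
  ref <- render_reference_image(map)
  prof <- si_profile(ref, spans_px = c(10L, 66L))
  self_cmp <- compare_to_reference(prof, map)
  expect_equal(self_cmp$max_abs_delta, 0)

  # low-noise scene generated from the same map reproduces its profile
  sc <- render_scene(map, seed = 6,
                     noise = list(background = 0.02, gradient = 0, sd = 0.01))
  meas <- si_profile(assign_pixel_genotypes(sc$image),
                     spans_px = c(5L, 10L, 20L, 50L, 100L))
  cmp <- compare_to_reference(meas, map)
  expect_lt(cmp$max_abs_delta, 0.05)

  # mixed measurement against a segregated reference: large deviation at
  # the 100-um span (the two analytic endpoints 0.5 vs 0.94)
  mixed <- render_reference_image(make_printing_map(7, 8, "mixed"), seed = 3)
  mprof <- si_profile(mixed, spans_px = 66L)
  mcmp <- compare_to_reference(mprof, map)
  expect_gt(mcmp$max_abs_delta, 0.3)
})

test_that("genotype masks survive the 8-bit TIFF palette round-trip", {
  msk <- random_mask(25, 30, seed = 2, pixel_size = 1.515)
  f <- tempfile(fileext = ".tif")
  write_genotype_mask(msk, f)
  back <- read_genotype_mask(f, pixel_size = 1.515)
  expect_identical(back$labels, msk$labels)
})
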