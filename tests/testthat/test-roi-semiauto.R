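test_that("trace_contour_mask draws a closed 8-connected one-pixel outline", {
  sq <- roi_polygon(x = c(3, 13, 13, 3), y = c(3, 3, 13, 13))
  m <- trace_contour_mask(sq, c(20, 20))
  # square outline: boundary pixels only, interior excluded
  expect_true(all(m[4, 4:14]))
  expect_true(all(m[14, 4:14]))
  expect_true(all(m[4:14, 4]))
  expect_true(all(m[4:14, 14]))
  expect_equal(sum(m), 4 * 11 - 4)
  expect_false(any(m[5:13, 5:13]))

  # every contour pixel has at least 2 contour neighbours (closed loop)
  check_loop <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]; c <- idx[i, 2]
      nb <- mask[max(1, r - 1):min(nrow(mask), r + 1),
                 max(1, c - 1):min(ncol(mask), c + 1)]
      expect_gte(sum(nb) - 1, 2)
    }
  }
  check_loop(m)
  ell <- trace_contour_mask(ellipse_polygon(c(30, 30), c(18, 11), 0.4), c(64, 64))
  check_loop(ell)

  # contour and enclosed interior are disjoint, and interior filling plus
  # contour reproduces the even-odd fill up to the boundary layer
  interior <- enclosed_region(ell)
  expect_false(any(interior & ell))
  expect_gt(sum(interior), 0)
})

test_that("grow_endometrial_roi matches a flood-fill oracle and stops below the ring tolerance", {
  # disc of intensity 200 inside a circular contour of intensity 100
  shape <- c(40, 40)
  circle <- ellipse_polygon(c(20, 20), c(12, 12), n = 48L)
  contour <- trace_contour_mask(circle, shape)
  img <- matrix(0, shape[1], shape[2])
  interior <- enclosed_region(contour)
  img[interior] <- 200
  img[contour] <- 100
  ir <- image2d(img, "IR", ti = 200)

  res <- grow_endometrial_roi(ir, c(20, 20), contour)
  expect_identical(res$mask, interior)     # full disc
  expect_lt(res$tolerance_pct, 50)         # ring enters tolerance at t = 50
  expect_equal(res$tolerance_pct, 49)
  # flood-fill oracle at the chosen tolerance agrees
  oracle <- oracle_flood(img, c(21, 21), 200, res$tolerance_pct / 100)
  expect_identical(res$mask, oracle)

  # isolated seed: neighbours out of tolerance at every admissible t
  img2 <- matrix(1000, shape[1], shape[2])
  img2[21, 21] <- 200
  img2[contour] <- 100
  ir2 <- image2d(img2, "IR", ti = 200)
  res2 <- grow_endometrial_roi(ir2, c(20, 20), contour)
  expect_equal(sum(res2$mask), 1)
  expect_true(res2$mask[21, 21])

  # seed on the contour and outside the enclosed region are rejected
  on_contour <- which(contour, arr.ind = TRUE)[1, ]
  expect_error(
    grow_endometrial_roi(ir, c(on_contour[2] - 1, on_contour[1] - 1), contour),
    "on the contour")
  expect_error(grow_endometrial_roi(ir, c(1, 1), contour), "inside")

  # immediate contact at the initial tolerance is an error
  img3 <- matrix(200, shape[1], shape[2])
  ir3 <- image2d(img3, "IR", ti = 200)
  expect_error(grow_endometrial_roi(ir3, c(20, 20), contour), "initial")
})

test_that("band_mask is the interior minus endometrium minus contour", {
  shape <- c(40, 40)
  circle <- ellipse_polygon(c(20, 20), c(14, 14), n = 48L)
  contour <- trace_contour_mask(circle, shape)
  interior <- enclosed_region(contour)
  endo <- ellipse_mask(shape, c(20, 20), c(6, 6))  # internal helper
  band <- band_mask(endo, contour)
  expect_identical(band, interior & !endo & !contour)

  expect_error(band_mask(interior, contour), "empty")
  none <- matrix(FALSE, shape[1], shape[2])
  expect_identical(band_mask(none, contour), interior & !contour)

  outside <- matrix(FALSE, shape[1], shape[2])
  outside[1, 1] <- TRUE
  expect_error(band_mask(outside, contour), "outside")
})

test_that("filter_sd keeps pixels within z sample SDs, boundary inclusive", {
  shape <- c(10, 10)
  band <- matrix(FALSE, shape[1], shape[2])
  band[2:4, 2:4] <- TRUE
  const <- image2d(matrix(5, shape[1], shape[2]), "IR", ti = 200)
  expect_identical(filter_sd(const, band), band)  # SD 0, deviation 0, kept

  # hand-arithmetic example: {100 x5, 200} -> mean 116.67, SD 40.82,
  # cut 80.01; the 200 pixel (deviation 83.3) is removed
  img <- matrix(0, 3, 3)
  img[1, 1:3] <- 100
  img[2, 1:2] <- 100
  img[2, 3] <- 200
  b <- matrix(FALSE, 3, 3)
  b[1, ] <- TRUE
  b[2, ] <- TRUE
  kept <- filter_sd(image2d(img, "IR", ti = 200), b)
  expect_equal(sum(kept), 5)
  expect_false(kept[2, 3])

  single <- matrix(FALSE, 3, 3)
  single[1, 1] <- TRUE
  expect_error(filter_sd(image2d(img, "IR", ti = 200), single), "SD undefined")
})

test_that("filter_sd retains ~95% of a large Gaussian band", {
  set.seed(99)
  vals <- matrix(rnorm(100 * 100, 100, 10), 100, 100)
  band <- matrix(TRUE, 100, 100)
  kept <- filter_sd(image2d(vals, "IR", ti = 200), band)
  expect_equal(sum(kept) / sum(band), 0.95, tolerance = 0.011)
})

test_that("optimize_shift matches the brute-force SSD oracle and recovers shifts", {
  spec <- phantom_spec(ir_to_spgr_shift = c(3, -2))
  st <- simulate_study(spec)
  tm <- suppressMessages(compute_t1_map(st$spgr_lo, st$spgr_hi))
  contour <- trace_contour_mask(outer_contour_poly(spec), dim(st$ir$pixels))
  grown <- grow_endometrial_roi(st$ir, round(spec$center), contour)
  myo <- filter_sd(st$ir, band_mask(grown$mask, contour))

  reg <- optimize_shift(myo, st$spgr_hi)
  expect_equal(c(reg$dx, reg$dy), c(3, -2))
  oracle <- oracle_ssd_surface(myo, st$spgr_hi$pixels)
  expect_equal(unname(reg$ssd_surface), oracle, tolerance = 1e-10)

  # constant image: all SSD equal, tie-break returns (0, 0)
  const <- image2d(matrix(1, 128, 128), "SPGR", tr = 5, fa = 18)
  reg0 <- optimize_shift(myo, const)
  expect_equal(c(reg0$dx, reg0$dy), c(0, 0))

  # registered phantom: SSD minimal at (0, 0)
  st0 <- simulate_study(phantom_spec())
  contour0 <- trace_contour_mask(outer_contour_poly(st0$spec), c(128, 128))
  grown0 <- grow_endometrial_roi(st0$ir, round(st0$spec$center), contour0)
  myo0 <- filter_sd(st0$ir, band_mask(grown0$mask, contour0))
  regs <- optimize_shift(myo0, st0$spgr_hi)
  expect_equal(c(regs$dx, regs$dy), c(0, 0))

  # a full-frame mask admits only the identity shift; all others are
  # excluded from the search as out of bounds
  full <- matrix(TRUE, 128, 128)
  regf <- optimize_shift(full, st0$spgr_hi)
  expect_equal(c(regf$dx, regf$dy), c(0, 0))
  expect_equal(sum(!is.na(regf$ssd_surface)), 1)
})

test_that("semiauto_qt1 composes the pipeline deterministically", {
  spec <- phantom_spec(ir_to_spgr_shift = c(3, -2))
  st <- simulate_study(spec)
  tm <- suppressMessages(compute_t1_map(st$spgr_lo, st$spgr_hi))
  res <- semiauto_qt1(st$ir, st$spgr_hi, tm, round(spec$center),
                      outer_contour_poly(spec))
  expect_equal(as.numeric(res$mean_qt1), 1500, tolerance = 0.001)
  expect_equal(unname(res$optimal_shift), c(3, -2))
  expect_gte(res$tolerance_pct, 3)
  expect_false(any(res$endo_mask & res$myo_mask))
  expect_true(all(res$myo_mask[res$myo_mask] %in% res$band_mask[res$myo_mask]))
  expect_true(all(which(res$myo_mask) %in% which(res$band_mask)))

  res2 <- semiauto_qt1(st$ir, st$spgr_hi, tm, round(spec$center),
                       outer_contour_poly(spec))
  expect_identical(res, res2)  # bit-identical, no randomness

  # registered phantom gives the same answer without a shift
  st0 <- simulate_study(phantom_spec())
  tm0 <- suppressMessages(compute_t1_map(st0$spgr_lo, st0$spgr_hi))
  res0 <- semiauto_qt1(st0$ir, st0$spgr_hi, tm0, round(st0$spec$center),
                       outer_contour_poly(st0$spec))
  expect_equal(as.numeric(res0$mean_qt1), 1500, tolerance = 0.001)
  expect_equal(unname(res0$optimal_shift), c(0, 0))

  # stage labels propagate
  expect_error(
    semiauto_qt1(st$ir, st$spgr_hi, tm, c(1, 1), outer_contour_poly(spec)),
    "\\[grow_endometrium\\]")
})

test_that("semiauto is more robust to contour jitter than manual (phantom property)", {
  spec <- phantom_spec(noise_sd = 0.8)
  st <- simulate_study(spec, seed = 21)
  tm <- suppressMessages(compute_t1_map(st$spgr_lo, st$spgr_hi))
  outer <- outer_contour_poly(spec)
  endo_poly <- ellipse_polygon(spec$center, spec$endo_axes, spec$rotation, 20L)
  set.seed(31)
  man <- semi <- numeric(8)
  for (i in seq_along(man)) {
    jit <- function(p) roi_polygon(p$x + rnorm(length(p$x), 0, 2),
                                   p$y + rnorm(length(p$y), 0, 2))
    wj <- jit(outer)
    ej <- jit(endo_poly)
    man[i] <- suppressMessages(
      mean_qt1(manual_myometrial_mask(wj, ej, c(128, 128)), tm))
    semi[i] <- suppressMessages(
      semiauto_qt1(st$ir, st$spgr_hi, tm, round(spec$center), wj)$mean_qt1)
  }
  expect_lt(sd(semi), sd(man))
})
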