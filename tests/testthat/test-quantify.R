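# Translocation-ratio and texture quantification, checked against direct
# formula evaluation and the exhaustive pair-enumeration GLCM oracle.

test_that("the translocation ratio follows its defining formula", {
  # complete nuclear / complete cytoplasmic extremes
  expect_equal(translocationRatio(500, 100, 100), 1)
  expect_equal(translocationRatio(100, 500, 100), 0)
  # background-corrected mixed case: (60-10)/((60-10)+(40-10))
  expect_equal(translocationRatio(60, 40, 10), 0.625)
  # no signal above background: invalid, not an error
  expect_true(is.na(translocationRatio(90, 95, 100)))
  # vectorized
  expect_equal(translocationRatio(c(500, 100), c(100, 500), 100), c(1, 0))
})

test_that("the ratio is scale-invariant in intensity units", {
  set.seed(5)
  for (k in 1:20) {
    nuc <- runif(1, 100, 900); cyt <- runif(1, 100, 900)
    bg <- runif(1, 0, 90); g <- runif(1, 0.1, 10)
    expect_equal(translocationRatio(g * nuc, g * cyt, g * bg),
                 translocationRatio(nuc, cyt, bg), tolerance = 1e-6)
  }
})

test_that("per-cell measurements recover the rendered nuclear fraction", {
  cfg <- tiny_config(260L)
  cells <- randomMonolayerCells(12, cfg, seed = 41, nuclear_fraction = 0.8)
  fr <- renderMonolayerFrame(cells, cfg, seed = 42)
  nuc <- segmentNuclei(fr$hoechst, pixelSize(cfg))
  rings <- deriveCytoplasmRings(nuc, 5, gap_px = 2)
  mc <- measureCells(fr$egfp, nuc, rings, background = 100,
                     nucleus_erosion_px = 2)
  expect_equal(nrow(mc), 12L)
  expect_setequal(mc$cell_id, seq_len(nObjects(nuc)))  # ids bijective
  expect_true(all(abs(mc$ratio - 0.8) < 0.05))
  # a frame with no nuclei gives an empty record table
  empty <- labelImage(matrix(0L, 40, 40), 1, "nuclear")
  expect_equal(nrow(measureCells(matrix(0, 40, 40), empty, empty)), 0L)
})

test_that("measured ratio is monotone in the programmed fraction", {
  cfg <- tiny_config(340L)
  fractions <- seq(0, 1, by = 0.1)
  cells <- randomMonolayerCells(length(fractions), cfg, seed = 51,
                                nuclear_fraction = 0)
  cells$nuclear_fraction <- fractions
  fr <- renderMonolayerFrame(cells, cfg, seed = 52)
  nuc <- segmentNuclei(fr$hoechst, pixelSize(cfg))
  rings <- deriveCytoplasmRings(nuc, 5, gap_px = 2)
  mc <- measureCells(fr$egfp, nuc, rings, background = 100,
                     nucleus_erosion_px = 2)
  idx <- match_cells(mc, cells)
  expect_equal(cor(mc$ratio, cells$nuclear_fraction[idx],
                   method = "spearman"), 1)
})

test_that("the co-occurrence matrix matches exhaustive enumeration", {
  # 4x4 two-level checkerboard, horizontal offset: all 12 pairs are (0,1)
  cb <- matrix(rep(c(0, 1), 8), 4, 4)
  cb[, c(2, 4)] <- 1 - cb[, c(2, 4)]
  g <- computeGLCM(cb, levels = 2, offsets = list(c(0L, 1L)))
  expect_equal(g@matrix[1, 2] + g@matrix[2, 1], 1)
  expect_equal(haralickContrast(g), 1)
  # constant image: diagonal concentration, zero contrast
  gc <- computeGLCM(matrix(7, 6, 6), levels = 4, offsets = list(c(0L, 1L)))
  expect_equal(sum(diag(gc@matrix)), 1)
  expect_equal(haralickContrast(gc), 0)
  # random small images against the double-loop oracle
  set.seed(99)
  offs <- glcmOffsets()
  for (k in 1:25) {
    h <- sample(3:16, 1); w <- sample(3:16, 1)
    lev <- sample(2:8, 1)
    img <- matrix(runif(h * w, 0, 100), h, w)
    use <- offs[sample(4, sample(1:4, 1))]
    msk <- matrix(runif(h * w) < 0.8, h, w)
    if (sum(msk) < 4) next
    got <- computeGLCM(img, msk, levels = lev, offsets = use)
    want <- oracle_glcm(img, msk, levels = lev, offsets = use)
    expect_equal(got@matrix, want, tolerance = 1e-12)
    expect_equal(haralickContrast(got), oracle_contrast(want),
                 tolerance = 1e-12)
  }
})

test_that("contrast is invariant to intensity offsets at fixed range", {
  set.seed(17)
  img <- matrix(runif(100, 0, 50), 10, 10)
  g1 <- computeGLCM(img, levels = 16, range = c(0, 150))
  g2 <- computeGLCM(img + 100, levels = 16, range = c(100, 250))
  expect_equal(haralickContrast(g1), haralickContrast(g2))
  expect_error(computeGLCM(img, matrix(FALSE, 10, 10)), "pairs")
  expect_error(computeGLCM(img, levels = 1), "levels")
})

test_that("contrast time-courses track stabilization and detrend bleaching", {
  cfg <- tiny_config(200L)
  times <- seq(0, 4.5, length.out = 8)
  ramp <- seq(0, 1, length.out = 8)
  tl <- renderTubulinTimelapse(cfg, ramp, times, seed = 61)
  ct <- contrastTimecourse(tl$stack, tl$mask, times)
  expect_true(all(diff(ct$contrast) > 0))
  # constant frames give constant contrast
  flat <- renderTubulinTimelapse(cfg, rep(0.4, 5), times[1:5], seed = 62)
  for (k in 2:5) flat$stack[, , k] <- flat$stack[, , 1]
  cf <- contrastTimecourse(flat$stack, flat$mask, times[1:5])
  expect_true(all(abs(cf$contrast - cf$contrast[1]) < 1e-9))
  expect_error(contrastTimecourse(tl$stack, tl$mask, times[1:3]), "mismatch")
  # simulated bleaching is corrected by the control-based detrend
  cfgn <- tiny_config(200L, noise_sd = 5)
  tb <- renderTubulinTimelapse(cfgn, ramp, times, seed = 63,
                               bleach_half_life_h = 4)
  ctrl <- renderTubulinTimelapse(cfgn, rep(0, 8), times, seed = 64,
                                 bleach_half_life_h = 4)
  cc <- contrastTimecourse(ctrl$stack, ctrl$mask, times)
  cb <- contrastTimecourse(tb$stack, tb$mask, times,
                           control_scores = cc$contrast, detrend = TRUE)
  expect_gt(cor(cb$contrast, ramp, method = "spearman"), 0.95)
})
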