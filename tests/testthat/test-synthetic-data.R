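# The generator is first-class code: its ground truth must be exact, its
# randomness reproducible, and its programmed kinetics recoverable.

test_that("integrated EGFP per frame is conserved across nuclear fractions", {
  cfg <- tiny_config(200L)
  totals <- vapply(c(0, 0.3, 0.6, 1), function(f) {
    cells <- cellTable(x_px = c(60, 140), y_px = c(60, 140),
                       nucleus_radius_px = 6, cyto_radius_px = 16,
                       nuclear_fraction = f, total_egfp = 1.2e5,
                       hoechst_intensity = 1500, pixel_size_um = 0.6)
    fr <- renderMonolayerFrame(cells, cfg, seed = 3)
    sum(fr$egfp) - cfg@background_level * length(fr$egfp)
  }, numeric(1))
  expect_true(all(abs(totals / 2.4e5 - 1) < 0.01))
})

test_that("renderers are bit-reproducible for identical inputs and seed", {
  cfg <- tiny_config(120L, noise_sd = 5)
  cells <- randomMonolayerCells(5, cfg, seed = 9)
  a <- renderMonolayerFrame(cells, cfg, seed = 4)
  b <- renderMonolayerFrame(cells, cfg, seed = 4)
  expect_identical(a$egfp, b$egfp)
  expect_identical(a$hoechst, b$hoechst)
  t1 <- renderTubulinFrame(0.5, cfg, seed = 7)
  t2 <- renderTubulinFrame(0.5, cfg, seed = 7)
  expect_identical(t1$image, t2$image)
  expect_false(identical(renderMonolayerFrame(cells, cfg, seed = 5)$egfp,
                         a$egfp))
})

test_that("ground-truth nuclear fraction follows the lagged logistic", {
  kin <- kineticModel(baseline = 0.2, plateau = 0.9, t50_h = 2, slope_h = 0.3,
                      lag_h = 0)
  t <- seq(0, 8, by = 0.25)
  f0 <- nuclearFractionAt(kin, t)
  expect_true(all(diff(f0) >= 0))           # non-decreasing for rising kinetics
  expect_equal(f0[t == 0], 0.2)             # pre-treatment frame at baseline
  # an added lag shifts the curve horizontally by exactly that amount
  f1 <- nuclearFractionAt(kin, t, lag_offset_h = 1)
  sel <- t > 1.5
  expect_equal(f1[sel], nuclearFractionAt(kin, t[sel] - 1), tolerance = 1e-12)
  # plateau = baseline gives a constant readout
  flat <- kineticModel(baseline = 0.4, plateau = 0.4, t50_h = 2)
  expect_true(all(nuclearFractionAt(flat, t) == 0.4))
})

test_that("time-lapse rendering validates its inputs", {
  cfg <- tiny_config(120L)
  cells <- randomMonolayerCells(3, cfg, seed = 2)
  kin <- kineticModel()
  expect_error(renderTranslocationTimelapse(cells, kin, c(0, 1, 1), cfg, 1),
               "strictly increasing")
  # overlapping cytoplasm disks of distinct cells are rejected
  bad <- cellTable(x_px = c(60, 70), y_px = c(60, 60), nucleus_radius_px = 6,
                   cyto_radius_px = 16, nuclear_fraction = 0.5,
                   total_egfp = 1e5, hoechst_intensity = 1500,
                   pixel_size_um = 0.6)
  expect_error(renderMonolayerFrame(bad, cfg, 1), "overlap")
  out <- cellTable(x_px = 5, y_px = 60, nucleus_radius_px = 6,
                   cyto_radius_px = 16, nuclear_fraction = 0.5,
                   total_egfp = 1e5, hoechst_intensity = 1500,
                   pixel_size_um = 0.6)
  expect_error(renderMonolayerFrame(out, cfg, 1), "fit within")
})

test_that("dome layouts validate organoid positions and program lags", {
  org <- data.frame(organoid_id = 1:2, x_um = c(0, 2000), y_um = 0,
                    n_cells = 3L, radius_um = 100)
  lay <- domeLayout(c(0, 0), 2250, org,
                    lag_fun = function(d) 2 * d / 2000)
  d <- sqrt(lay@organoids$x_um^2 + lay@organoids$y_um^2)
  expect_equal(lay@lag_fun(d), c(0, 2))
  bad <- data.frame(organoid_id = 1, x_um = 3000, y_um = 0, n_cells = 3L,
                    radius_um = 100)
  expect_error(domeLayout(c(0, 0), 2250, bad), "within the dome")
  expect_error(domeLayout(c(0, 0), 2250, org[c(1, 1), ]), "unique")
})

test_that("a single centred zero-lag organoid equals the monolayer path", {
  cfg <- tiny_config(220L, noise_sd = 3)
  kin <- kineticModel(baseline = 0.2, plateau = 0.9, t50_h = 1, slope_h = 0.3)
  org <- data.frame(organoid_id = 1L, x_um = 66, y_um = 66, n_cells = 4L,
                    radius_um = 30)
  lay <- domeLayout(c(66, 66), 31, org)
  times <- seq(0, 3, by = 0.5)
  sim <- renderDomeTimelapse(lay, kin, times, cfg, seed = 5,
                             nucleus_radius_px = 5, cyto_radius_px = 9,
                             halo_level = 0)
  ref <- renderTranslocationTimelapse(
    sim$cells, kin, times, cfg, seed = orgaKinetics:::childSeed(5, 2L),
    allow_overlap_within_organoid = TRUE)
  expect_identical(sim$egfp, ref$egfp)
  expect_identical(sim$hoechst, ref$hoechst)
  expect_equal(sim$organoids$lag_h, 0)
  expect_equal(sim$organoids$distance_um, 0)
})

test_that("tubulin frames render the programmed number of bundles", {
  cfg <- tiny_config(200L)
  expect_equal(renderTubulinFrame(0, cfg, seed = 3)$n_bundles, 0L)
  expect_equal(renderTubulinFrame(1, cfg, seed = 3, max_bundles = 25L)$n_bundles,
               25L)
  expect_error(renderTubulinFrame(1.2, cfg, seed = 3), "\\[0, 1\\]")
  expect_error(renderTubulinFrame(-0.1, cfg, seed = 3), "\\[0, 1\\]")
})

test_that("viability plates follow the 4PL with controlled noise", {
  doses <- c(0.1, 0.3, 1, 3, 10)
  pl <- simulateViabilityPlate(doses, top = 100, bottom = 0, ec50 = 1,
                               hill = 1, cv = 0, replicates = 2, seed = 1)
  expect_equal(pl$response[pl$dose == 1], c(50, 50))   # 4PL midpoint
  expect_equal(pl$response[pl$dose == 0], c(100, 100)) # vehicle at top
  expect_equal(fourPLResponse(1e-9, 100, 0, 1, 1), 100, tolerance = 1e-6)
  expect_error(simulateViabilityPlate(doses, ec50 = -1), "ec50")
  expect_error(simulateViabilityPlate(doses, hill = 0), "hill")
  expect_error(simulateViabilityPlate(c(0, doses)), "positive")
  # multiplicative lognormal noise has roughly the requested CV and mean one
  big <- simulateViabilityPlate(1, top = 100, bottom = 100, ec50 = 1,
                                hill = 1, cv = 0.05, replicates = 2000,
                                seed = 8)
  expect_equal(mean(big$response[big$dose > 0]), 100, tolerance = 0.5)
  expect_equal(sd(big$response[big$dose > 0]) / 100, 0.05, tolerance = 0.1)
})

test_that("vehicle normalization rescales to percent of control", {
  pl <- data.frame(dose = c(0, 0, 1), response = c(90, 110, 50))
  expect_equal(normalizeToVehicle(pl)$response_pct, c(90, 110, 50))
  expect_error(normalizeToVehicle(data.frame(dose = 1, response = 5)),
               "vehicle")
})
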