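# Radial distances, half-open binning and per-bin / per-zone aggregation.

test_that("radial distances are Euclidean and sign-invariant", {
  expect_equal(radialDistance(c(0, 0), c(0, 0)), 0)
  expect_equal(radialDistance(c(300, 400), c(0, 0)), 500)
  expect_equal(radialDistance(c(-250, 0), c(0, 0)), 250)
  m <- rbind(c(3, 4), c(-3, -4))
  expect_equal(radialDistance(m, c(0, 0)), c(5, 5))
})

test_that("bin assignment uses half-open 250 um bins with range flags", {
  sch <- binningScheme(c(0, 0), bin_width_um = 250, n_bins = 9L)
  expect_equal(assignBin(0, sch), 0L)
  expect_equal(assignBin(500, sch), 2L)   # [500, 750) -> bin 2
  expect_equal(assignBin(249.999, sch), 0L)
  expect_message(oob <- assignBin(2300, sch), "excluded")
  expect_true(is.na(oob))
  # partition: in-range distances all assigned, counts conserved
  set.seed(3)
  d <- runif(500, 0, 2600)
  idx <- suppressMessages(assignBin(d, sch))
  expect_equal(sum(!is.na(idx)), sum(d < 2250))
  expect_equal(sum(table(idx)), sum(d < 2250))
})

test_that("binned curves aggregate cell ratios per (bin, time)", {
  sch <- binningScheme(c(0, 0), 250, 9L)
  cells <- expand.grid(cell_id = 1:6, time_h = c(0, 1, 2))
  cells$distance_um <- 300
  set.seed(4)
  cells$ratio <- runif(nrow(cells))
  out <- binTimecourses(cells, sch)
  # all cells at one distance: a single populated bin whose curve is the
  # overall mean curve
  expect_setequal(out$bin_index, 1L)
  overall <- aggregate(ratio ~ time_h, cells, mean)
  expect_equal(out$mean_ratio, overall$ratio)
  expect_equal(out$n_cells, rep(6, 3))
  # permutation invariance in cell order
  perm <- cells[sample(nrow(cells)), ]
  expect_equal(binTimecourses(perm, sch), out)
  # weighted recombination of per-bin means equals the global mean
  cells2 <- cells
  cells2$distance_um <- rep(c(100, 600, 1300), each = 6)
  out2 <- binTimecourses(cells2, sch)
  for (t in unique(out2$time_h)) {
    sub <- out2[out2$time_h == t, ]
    expect_equal(sum(sub$mean_ratio * sub$n_cells) / sum(sub$n_cells),
                 mean(cells2$ratio[cells2$time_h == t]), tolerance = 1e-9)
  }
  far <- cells
  far$distance_um <- 5000
  expect_error(suppressMessages(binTimecourses(far, sch)), "no cells")
})

test_that("zero-baseline bins report zero mean at the first frame", {
  sch <- binningScheme(c(0, 0), 250, 9L)
  cells <- data.frame(cell_id = 1:4, time_h = 0,
                      distance_um = c(100, 100, 400, 400), ratio = 0)
  out <- binTimecourses(cells, sch)
  expect_equal(out$mean_ratio, c(0, 0))
})

test_that("zone curves compare core and periphery per size class", {
  t <- seq(0, 5, by = 0.5)
  kin <- kineticModel(baseline = 0.1, plateau = 0.9, t50_h = 2, slope_h = 0.3)
  mk <- function(zone, lag, n = 5) {
    do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(zone = zone, size_class = "large", time_h = t,
                 ratio = nuclearFractionAt(kin, t, lag))))
  }
  # equal programmed lags: normalized curves coincide
  null <- rbind(mk("core", 0.5), mk("periphery", 0.5))
  zc <- zoneTimecourses(null, normalize = TRUE)
  core <- zc$mean_ratio[zc$zone == "core"]
  peri <- zc$mean_ratio[zc$zone == "periphery"]
  expect_lt(max(abs(core - peri)), 0.05)
  # a 1 h core lag is recovered from the fitted half-transition times
  lagged <- rbind(mk("core", 1), mk("periphery", 0))
  zc2 <- zoneTimecourses(lagged, normalize = TRUE)
  fits <- fitGroupedT50(zc2, c("size_class", "zone"))
  d <- fits$t50_h[fits$zone == "core"] - fits$t50_h[fits$zone == "periphery"]
  expect_equal(d, 1, tolerance = 0.15)
  bad <- null
  bad$zone[1] <- NA
  expect_error(zoneTimecourses(bad), "zone missing")
})
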