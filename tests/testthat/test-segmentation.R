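# Segmentation operations are checked against generator ground truth and
# analytic geometry oracles.

test_that("nuclei are recovered exactly on a clean synthetic frame", {
  cfg <- tiny_config(420L)
  cells <- randomMonolayerCells(50, cfg, seed = 21)
  fr <- renderMonolayerFrame(cells, cfg, seed = 22)
  nuc <- segmentNuclei(fr$hoechst, pixelSize(cfg))
  expect_equal(nObjects(nuc), 50L)
  # labels are consecutive from 1
  expect_setequal(unique(as.vector(labelMatrix(nuc)))[-1], 1:50)
})

test_that("an empty frame yields an empty label image with a warning", {
  img <- matrix(100, 64, 64)
  expect_warning(nuc <- segmentNuclei(img, 1), "empty")
  expect_equal(nObjects(nuc), 0L)
})

test_that("touching nuclei are split by the watershed", {
  cfg <- tiny_config(120L)
  # centres 14 px apart with radius-6 nuclei: blurred disks touch
  cells <- cellTable(x_px = c(53, 67), y_px = c(60, 60),
                     nucleus_radius_px = 6, cyto_radius_px = 16,
                     nuclear_fraction = 0.5, total_egfp = 1e5,
                     hoechst_intensity = 1500, pixel_size_um = 0.6)
  hoechst <- orgaKinetics:::.renderChannels(cells, c(0.5, 0.5), cfg)$hoechst
  nuc <- segmentNuclei(hoechst + cfg@background_level, 0.6)
  expect_equal(nObjects(nuc), 2L)
  cen <- orgaKinetics:::labelCentroidsUm(labelMatrix(nuc), 1)
  expect_equal(sort(cen$x_um), c(53, 67), tolerance = 0.15)
})

test_that("cytoplasmic rings match the analytic annulus area", {
  lab <- matrix(0L, 120, 120)
  lab[disk_mask(120, 60, 60, 10)] <- 1L
  nuc <- labelImage(lab, 1, "nuclear")
  rings <- deriveCytoplasmRings(nuc, ring_width_px = 5)
  a <- sum(labelMatrix(rings) == 1L)
  # digital dilation of a digital disk: allow discretization slack
  expect_equal(a, pi * (15^2 - 10^2), tolerance = 0.08)
  # rings and nuclei have disjoint supports, ring touches its nucleus
  expect_true(all(labelMatrix(rings)[lab > 0] == 0L))
  grown <- EBImage::dilate(labelMatrix(rings) == 1L, EBImage::makeBrush(3, "disc"))
  expect_true(any(grown & lab > 0))
})

test_that("rings of adjacent nuclei partition by the nearest nucleus", {
  lab <- matrix(0L, 160, 160)
  lab[disk_mask(160, 60, 60, 8)] <- 1L
  lab[disk_mask(160, 100, 60, 8)] <- 2L
  nuc <- labelImage(lab, 1, "nuclear")
  rings <- deriveCytoplasmRings(nuc, ring_width_px = 6)
  r <- labelMatrix(rings)
  expect_true(all(r[lab > 0] == 0L))
  # every ring pixel is closer to (or equidistant from) its own nucleus
  idx <- which(r > 0, arr.ind = TRUE)
  d1 <- sqrt((idx[, 2] - 0.5 - 60)^2 + (idx[, 1] - 0.5 - 60)^2) - 8
  d2 <- sqrt((idx[, 2] - 0.5 - 100)^2 + (idx[, 1] - 0.5 - 60)^2) - 8
  own <- ifelse(r[idx] == 1L, d1, d2)
  other <- ifelse(r[idx] == 1L, d2, d1)
  expect_true(all(own <= other + 1.5))
  # a nucleus at the border yields a clipped ring without error
  lab2 <- matrix(0L, 60, 60)
  lab2[disk_mask(60, 3, 30, 6)] <- 1L
  r2 <- deriveCytoplasmRings(labelImage(lab2, 1, "nuclear"), 5)
  expect_gt(sum(labelMatrix(r2) > 0), 0)
})

test_that("organoid records carry area, distance and size class", {
  px <- 1
  mkdisk <- function(r) {
    img <- matrix(100, 220, 220)
    img[disk_mask(220, 110, 110, r)] <- 400
    img
  }
  flat <- matrix(100, 220, 220)
  # area 10000 um^2 -> large (threshold 8000); 5000 um^2 -> small
  for (spec in list(c(sqrt(10000 / pi), 1), c(sqrt(5000 / pi), 0))) {
    res <- segmentOrganoids(mkdisk(spec[1]), flat, px, min_area_um2 = 1000)
    expect_equal(nrow(res$organoids), 1L)
    expect_equal(res$organoids$area_um2, pi * spec[1]^2, tolerance = 0.1)
    expect_equal(res$organoids$size_class,
                 if (spec[2] == 1) "large" else "small")
    expect_equal(res$organoids$x_um, 110, tolerance = 2)
  }
  expect_error(segmentOrganoids(flat, matrix(0, 10, 10), px), "mismatch")
})

test_that("organoid area in um^2 is invariant to pixel size", {
  mk <- function(side, r, px) {
    img <- matrix(100, side, side)
    img[disk_mask(side, side / 2, side / 2, r)] <- 400
    segmentOrganoids(img, matrix(100, side, side), px,
                     min_area_um2 = 500)$organoids$area_um2
  }
  a1 <- mk(200L, 40, 2)    # radius 80 um at 2 um/px
  a2 <- mk(400L, 80, 1)    # same physical disk at 1 um/px
  expect_equal(a1, a2, tolerance = 0.02)
})

test_that("the rim rule allocates nuclei by distance to the boundary", {
  side <- 200L
  olab <- matrix(0L, side, side)
  olab[disk_mask(side, 100, 100, 80)] <- 1L
  nlab <- matrix(0L, side, side)
  # nuclei at 50 px (periphery, rim 30) and 10 px (core) from centre:
  # boundary distances 30+? -> use rim_width 30
  centres <- list(c(150, 100, 1L), c(110, 100, 2L))  # bdist 30-? and 70
  for (cc in centres) nlab[disk_mask(side, cc[1], cc[2], 4)] <- cc[3]
  nuc <- labelImage(nlab, 1, "nuclear")
  res <- assignCorePeriphery(labelImage(olab, 1, "combined"), nuc,
                             rim_width_px = 40)
  expect_equal(res$zone[res$nucleus_id == 1L], "periphery")  # bdist ~30
  expect_equal(res$zone[res$nucleus_id == 2L], "core")       # bdist ~70
  # |core| + |periphery| covers all nuclei inside organoids
  expect_equal(nrow(res), 2L)
  # rim covering the whole organoid makes everything periphery
  res2 <- assignCorePeriphery(labelImage(olab, 1, "combined"), nuc,
                              rim_width_px = 85)
  expect_true(all(res2$zone == "periphery"))
  expect_error(assignCorePeriphery(labelImage(olab, 1, "combined"), nuc,
                                   rim_width_px = 0), "positive")
  # nuclei outside any organoid are skipped with a warning
  nlab2 <- nlab; nlab2[disk_mask(side, 10, 10, 3)] <- 3L
  expect_warning(
    res3 <- assignCorePeriphery(labelImage(olab, 1, "combined"),
                                labelImage(nlab2, 1, "nuclear"), 40),
    "outside")
  expect_equal(nrow(res3), 2L)
})

test_that("cell-area segmentation recovers the rendered region", {
  cfg <- tiny_config(220L)
  fr <- renderTubulinFrame(0.5, cfg, seed = 11)
  ca <- segmentCellArea(fr$image, pixelSize(cfg))
  m <- labelMatrix(ca) > 0
  iou <- sum(m & fr$mask) / sum(m | fr$mask)
  expect_gt(iou, 0.9)
  expect_warning(empty <- segmentCellArea(matrix(0, 40, 40), 1), "empty")
  expect_equal(nObjects(empty), 0L)
  full <- segmentCellArea(matrix(300, 40, 40), 1)
  expect_true(all(labelMatrix(full) == 1L))
})

test_that("background estimation is exact on clean frames and falls back", {
  cfg <- tiny_config(200L)
  cells <- randomMonolayerCells(8, cfg, seed = 31)
  fr <- renderMonolayerFrame(cells, cfg, seed = 32)
  nuc <- segmentNuclei(fr$hoechst, pixelSize(cfg))
  rings <- deriveCytoplasmRings(nuc, 5, gap_px = 2)
  fg <- labelMatrix(nuc) > 0 | labelMatrix(rings) > 0
  expect_equal(estimateBackground(fr$egfp, fg, dilate_px = 8), 100)
  expect_message(v <- estimateBackground(matrix(1:100, 10), matrix(TRUE, 10, 10)),
                 "5th percentile")
  expect_equal(v, as.numeric(quantile(matrix(1:100, 10), 0.05)))
  expect_equal(estimateBackground(matrix(0, 20, 20)), 0)
})
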