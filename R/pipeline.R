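# End-to-end scenario orchestration: images -> per-cell tables -> curves ->
# fits -> comparison reports, with YAML configs, CSV/JSON outputs and a
# plain-text provenance record. Runs are deterministic given (config, seed).

#' Default run configuration for a scenario
#'
#' Returns the study conditions used by \code{\link{runScenario}} for each
#' supported scenario; every field can be overridden before the run. The
#' scenarios mirror the experimental designs the package models:
#' \describe{
#'   \item{monolayer_scaffold}{monolayer wells covered with no gel /
#'     synthetic hydrogel / Matrigel, programmed translocation lags of
#'     0 / 1 / 3 h, three independent experiments per condition, frames
#'     every 30 min for 8 h.}
#'   \item{dome_binning}{organoids across a 2250 µm scaffold dome with a
#'     linear 0 to 2 h lag gradient, analysed in 9 radial bins of 250 µm,
#'     frames every 30 min for 5 h.}
#'   \item{core_periphery}{one large organoid per well with a programmed
#'     1 h extra lag in the core (beyond a 100 px rim), two wells.}
#'   \item{dose_response}{two viability plates whose EC50s differ 10-fold
#'     (single cells vs assembled organoids), 8 doses, 3 replicates,
#'     5% CV.}
#' }
#'
#' @param scenario one of \code{"monolayer_scaffold"}, \code{"dome_binning"},
#'   \code{"core_periphery"}, \code{"dose_response"}.
#' @return a nested configuration list.
#' @export
defaultRunConfig <- function(scenario = c("monolayer_scaffold",
                                          "dome_binning", "core_periphery",
                                          "dose_response")) {
  scenario <- match.arg(scenario)
  base_kin <- list(baseline = 0.2, plateau = 0.9, t50_h = 1.5,
                   slope_h = 0.3)
  switch(scenario,
    monolayer_scaffold = list(
      scenario = scenario,
      imaging = list(width_px = 300L, height_px = 300L, pixel_size_um = 0.6,
                     background_level = 100, noise_sd = 5, psf_sigma_px = 1),
      cells = list(n = 25L, nucleus_radius_px = 6, cyto_radius_px = 16),
      kinetics = base_kin,
      conditions = list(no_gel = 0, noviogel = 1, matrigel = 3),
      n_experiments = 3L,
      experiment_lag_sd_h = 0.05,
      times_h = seq(0, 8, by = 0.5),
      segmentation = list(min_area_px = 30, max_area_px = 5000,
                          ring_width_px = 5, ring_gap_px = 2,
                          nucleus_erosion_px = 2)),
    dome_binning = list(
      scenario = scenario,
      imaging = list(width_px = 960L, height_px = 960L, pixel_size_um = 5,
                     background_level = 100, noise_sd = 5, psf_sigma_px = 1),
      dome = list(dome_radius_um = 2250, organoid_radius_um = 150,
                  n_cells = 5L, n_per_bin = 2L, lag_range_h = c(0, 2)),
      cells = list(nucleus_radius_px = 5, cyto_radius_px = 9),
      kinetics = list(baseline = 0.2, plateau = 0.9, t50_h = 1,
                      slope_h = 0.25),
      binning = list(bin_width_um = 250, n_bins = 9L),
      times_h = seq(0, 5, by = 0.5),
      segmentation = list(min_area_px = 20, max_area_px = 2000,
                          ring_width_px = 4, min_organoid_area_um2 = 20000,
                          organoid_smooth_sigma = 4)),
    core_periphery = list(
      scenario = scenario,
      imaging = list(width_px = 768L, height_px = 768L, pixel_size_um = 0.3,
                     background_level = 100, noise_sd = 5, psf_sigma_px = 1),
      organoid = list(radius_um = 75, n_cells = 24L, core_lag_h = 1,
                      rim_width_px = 100, zone_margin_px = 10),
      cells = list(nucleus_radius_px = 10, cyto_radius_px = 18),
      kinetics = list(baseline = 0.2, plateau = 0.9, t50_h = 1,
                      slope_h = 0.25),
      n_wells = 2L,
      times_h = seq(0, 5, by = 0.5),
      segmentation = list(min_area_px = 100, max_area_px = 10000,
                          ring_width_px = 6, min_organoid_area_um2 = 3000,
                          organoid_smooth_sigma = 8,
                          area_threshold_um2 = 8000)),
    dose_response = list(
      scenario = scenario,
      doses = 10^seq(-2, 1, length.out = 8),
      conditions = list(single_cells = list(top = 100, bottom = 0,
                                            ec50 = 0.1, hill = 1),
                        organoids = list(top = 100, bottom = 0,
                                         ec50 = 1, hill = 1)),
      cv = 0.05, replicates = 3L))
}

# Segment one static time-lapse well and measure every frame. The scene is
# static, so nucleus/ring masks from the first (pre-treatment) frame are
# re-used across frames.
analyzeTimelapse <- function(sim, seg = list()) {
  px <- pixelSize(sim$config)
  nuclei <- segmentNuclei(sim$hoechst[, , 1L], px,
                          min_area_px = seg$min_area_px %||% 30,
                          max_area_px = seg$max_area_px %||% 5000)
  rings <- deriveCytoplasmRings(nuclei, seg$ring_width_px %||% 5,
                                gap_px = seg$ring_gap_px %||% 0)
  fg <- labelMatrix(nuclei) > 0L | labelMatrix(rings) > 0L
  bg <- estimateBackground(sim$egfp[, , 1L], fg, dilate_px = 6)
  cells <- measureStack(sim$egfp, nuclei, rings, sim$times_h, background = bg,
                        nucleus_erosion_px = seg$nucleus_erosion_px %||% 0)
  list(nuclei = nuclei, rings = rings, background = bg, cells = cells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Scenario drivers

.runMonolayerScaffold <- function(cfg, seed) {
  config <- do.call(imagingConfig, cfg$imaging)
  kin0 <- do.call(kineticModel, cfg$kinetics)
  conds <- cfg$conditions
  t50 <- list(); curves <- list(); all_cells <- list()
  k <- 0L
  for (cn in names(conds)) {
    t50[[cn]] <- numeric(0)
    for (ex in seq_len(cfg$n_experiments)) {
      k <- k + 1L
      lag_jit <- withSeed(childSeed(seed, 1000L + k),
                          stats::rnorm(1, 0, cfg$experiment_lag_sd_h))
      kin <- kineticModel(baseline = kin0@baseline, plateau = kin0@plateau,
                          t50_h = kin0@t50_h, slope_h = kin0@slope_h,
                          lag_h = max(0, conds[[cn]] + lag_jit))
      cells <- randomMonolayerCells(cfg$cells$n, config,
                                    seed = childSeed(seed, 2000L + k),
                                    nucleus_radius_px = cfg$cells$nucleus_radius_px,
                                    cyto_radius_px = cfg$cells$cyto_radius_px,
                                    nuclear_fraction = kin@baseline)
      sim <- renderTranslocationTimelapse(cells, kin, cfg$times_h, config,
                                          seed = childSeed(seed, 3000L + k))
      ana <- analyzeTimelapse(sim, cfg$segmentation)
      well <- paste0(cn, "_exp", ex)
      ana$cells$well_id <- well
      ana$cells$condition <- cn
      all_cells[[well]] <- ana$cells
      mc <- stats::aggregate(ratio ~ time_h, data = ana$cells[ana$cells$valid, ],
                             FUN = mean)
      fit <- fitSigmoidTime(mc$time_h, mc$ratio)
      t50[[cn]] <- c(t50[[cn]], tHalf(fit))
      curves[[well]] <- data.frame(condition = cn, experiment = ex,
                                   time_h = mc$time_h, mean_ratio = mc$ratio)
    }
  }
  comp <- if (cfg$n_experiments >= 2L) compareTHalf(t50) else NULL
  ref <- names(conds)[1L]
  deltas <- vapply(names(conds)[-1L], function(cn)
    mean(t50[[cn]]) - mean(t50[[ref]]), numeric(1))
  list(scenario = "monolayer_scaffold", t50_by_condition = t50,
       delta_t50_vs_control_h = deltas, comparisons = comp,
       curves = do.call(rbind, curves), cells = do.call(rbind, all_cells))
}

.runDomeBinning <- function(cfg, seed) {
  config <- do.call(imagingConfig, cfg$imaging)
  kin <- do.call(kineticModel, cfg$kinetics)
  center_um <- c(config@width_px, config@height_px) / 2 * config@pixel_size_um
  lr <- cfg$dome$lag_range_h
  R <- cfg$dome$dome_radius_um
  lag_fun <- function(d) lr[1L] + (lr[2L] - lr[1L]) * d / R
  layout <- randomDomeLayout(center_um, dome_radius_um = R,
                             organoid_radius_um = cfg$dome$organoid_radius_um,
                             n_cells = cfg$dome$n_cells,
                             seed = childSeed(seed, 11L), lag_fun = lag_fun,
                             n_bins = cfg$binning$n_bins,
                             n_per_bin = cfg$dome$n_per_bin)
  sim <- renderDomeTimelapse(layout, kin, cfg$times_h, config,
                             seed = childSeed(seed, 12L),
                             nucleus_radius_px = cfg$cells$nucleus_radius_px,
                             cyto_radius_px = cfg$cells$cyto_radius_px)
  ana <- analyzeTimelapse(sim, cfg$segmentation)
  seg <- cfg$segmentation
  orgs <- segmentOrganoids(sim$hoechst[, , 1L], sim$egfp[, , 1L],
                           pixelSize(config),
                           min_area_um2 = seg$min_organoid_area_um2 %||% 2000,
                           smooth_sigma = seg$organoid_smooth_sigma %||% 6,
                           center_xy_um = center_um)
  cells <- annotateCellsWithOrganoids(ana$cells, ana$nuclei, orgs)
  scheme <- binningScheme(center_um, cfg$binning$bin_width_um,
                          cfg$binning$n_bins)
  binned <- binTimecourses(cells, scheme)
  fits <- fitGroupedT50(binned, "bin_index")
  list(scenario = "dome_binning", organoids = orgs$organoids,
       binned_curves = binned, t50_by_bin = fits, cells = cells,
       ground_truth = sim$organoids)
}

.runCorePeriphery <- function(cfg, seed, core_lag_h = NULL) {
  config <- do.call(imagingConfig, cfg$imaging)
  kin <- do.call(kineticModel, cfg$kinetics)
  if (is.null(core_lag_h)) core_lag_h <- cfg$organoid$core_lag_h
  seg <- cfg$segmentation
  center_um <- c(config@width_px, config@height_px) / 2 * config@pixel_size_um
  all_cells <- list()
  for (wwell in seq_len(cfg$n_wells)) {
    org <- data.frame(organoid_id = 1L, x_um = center_um[1L],
                      y_um = center_um[2L], n_cells = cfg$organoid$n_cells,
                      radius_um = cfg$organoid$radius_um)
    layout <- domeLayout(center_um, dome_radius_um = cfg$organoid$radius_um + 1,
                         organoids = org)
    sim <- renderDomeTimelapse(layout, kin, cfg$times_h, config,
                               seed = childSeed(seed, 20L + wwell),
                               nucleus_radius_px = cfg$cells$nucleus_radius_px,
                               cyto_radius_px = cfg$cells$cyto_radius_px,
                               core_lag_h = core_lag_h,
                               rim_width_px = cfg$organoid$rim_width_px,
                               cell_sep_px = 2 * cfg$cells$cyto_radius_px + 2,
                               zone_margin_px = cfg$organoid$zone_margin_px)
    ana <- analyzeTimelapse(sim, seg)
    orgs <- segmentOrganoids(sim$hoechst[, , 1L], sim$egfp[, , 1L],
                             pixelSize(config),
                             min_area_um2 = seg$min_organoid_area_um2 %||% 2000,
                             smooth_sigma = seg$organoid_smooth_sigma %||% 8,
                             center_xy_um = center_um,
                             area_threshold_um2 = seg$area_threshold_um2 %||% 8000)
    zones <- assignCorePeriphery(orgs$mask, ana$nuclei,
                                 rim_width_px = cfg$organoid$rim_width_px)
    cells <- annotateCellsWithOrganoids(ana$cells, ana$nuclei, orgs,
                                        zones = zones)
    cells$well_id <- paste0("well", wwell)
    all_cells[[wwell]] <- cells
  }
  cells <- do.call(rbind, all_cells)
  zc <- zoneTimecourses(cells[!is.na(cells$zone), ], normalize = TRUE)
  fits <- fitGroupedT50(zc, c("size_class", "zone"))
  large <- fits[fits$size_class == "large", ]
  delta <- if (all(c("core", "periphery") %in% large$zone)) {
    large$t50_h[large$zone == "core"] - large$t50_h[large$zone == "periphery"]
  } else NA_real_
  list(scenario = "core_periphery", zone_curves = zc, t50_by_zone = fits,
       delta_t50_core_minus_periphery_h = delta, cells = cells)
}

.runDoseResponse <- function(cfg, seed) {
  plates <- list(); fits <- list()
  k <- 0L
  for (cn in names(cfg$conditions)) {
    k <- k + 1L
    pars <- cfg$conditions[[cn]]
    plate <- simulateViabilityPlate(cfg$doses, top = pars$top,
                                    bottom = pars$bottom, ec50 = pars$ec50,
                                    hill = pars$hill, cv = cfg$cv,
                                    replicates = cfg$replicates,
                                    seed = childSeed(seed, 30L + k))
    plate <- normalizeToVehicle(plate)
    plates[[cn]] <- plate
    fits[[cn]] <- fit4PL(plate$dose, plate$response_pct, n_boot = 200L,
                         seed = childSeed(seed, 40L + k))
  }
  cmp <- compareDoseCurves(plates[[1L]], plates[[2L]])
  list(scenario = "dose_response", plates = plates, fits = fits,
       shift_test = cmp[c("F", "df", "p")])
}

#' Attach organoid identity, distance and zone annotations to cell records
#'
#' Looks up each nucleus centroid in the organoid mask; cells outside any
#' organoid get \code{NA} annotations. Cells inherit their organoid's
#' radial distance and size class, and (optionally) a core/periphery zone
#' from \code{\link{assignCorePeriphery}} output.
#'
#' @param cells per-cell records from \code{\link{measureStack}}.
#' @param nuclei the \linkS4class{LabelImage} the records came from.
#' @param orgs result of \code{\link{segmentOrganoids}}.
#' @param zones optional result of \code{\link{assignCorePeriphery}}.
#' @return \code{cells} with added columns \code{organoid_id, distance_um,
#'   size_class} (and \code{zone} when \code{zones} is given).
#' @export
annotateCellsWithOrganoids <- function(cells, nuclei, orgs, zones = NULL) {
  olab <- labelMatrix(orgs$mask)
  cen <- labelCentroidsUm(labelMatrix(nuclei), 1)  # pixel units
  org_of <- rep(NA_integer_, max(cen$label))
  i <- pmin(pmax(round(cen$y_um + 0.5), 1L), nrow(olab))
  j <- pmin(pmax(round(cen$x_um + 0.5), 1L), ncol(olab))
  org_of[cen$label] <- olab[cbind(i, j)]
  org_of[org_of == 0L] <- NA_integer_
  cells$organoid_id <- org_of[cells$cell_id]
  rec <- orgs$organoids
  m <- match(cells$organoid_id, rec$organoid_id)
  cells$distance_um <- rec$distance_um[m]
  cells$size_class <- rec$size_class[m]
  if (!is.null(zones)) {
    zm <- match(cells$cell_id, zones$nucleus_id)
    cells$zone <- zones$zone[zm]
  }
  cells
}

#' Run an end-to-end scenario
#'
#' Simulates the scenario's images or plates, runs segmentation,
#' quantification, spatial grouping and kinetic/dose-response fitting, and
#' (optionally) writes per-cell CSV, curve CSV, fit JSON and a provenance
#' record to \code{out_dir}. Deterministic given (config, seed).
#'
#' @param config configuration list (see \code{\link{defaultRunConfig}});
#'   a scenario name is also accepted and expanded to its defaults.
#' @param seed integer seed driving all randomness.
#' @param out_dir output directory (created if needed); \code{NULL} skips
#'   writing.
#' @return a run-report list with the scenario's tables, fitted parameters
#'   and comparison statistics, plus a \code{provenance} record.
#' @export
runScenario <- function(config, seed = 1L, out_dir = NULL) {
  if (is.character(config)) config <- defaultRunConfig(config)
  if (is.null(config$scenario))
    stop("config must name a scenario")
  report <- switch(config$scenario,
    monolayer_scaffold = .runMonolayerScaffold(config, seed),
    dome_binning = .runDomeBinning(config, seed),
    core_periphery = .runCorePeriphery(config, seed),
    dose_response = .runDoseResponse(config, seed),
    stop("unknown scenario: ", config$scenario))
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("orgaKinetics")),
    seed = seed, scenario = config$scenario,
    config_yaml = yaml::as.yaml(config), timestamp = format(Sys.time()))
  if (!is.null(out_dir)) writeRunReport(report, out_dir)
  invisible(report)
}

#' Write a run report's tables and fits to disk
#'
#' @param report result of \code{\link{runScenario}}.
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
writeRunReport <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(obj, file) {
    p <- file.path(out_dir, file)
    utils::write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(report$cells)) wr(report$cells, "cells.csv")
  for (nm in c("curves", "binned_curves", "zone_curves"))
    if (!is.null(report[[nm]])) wr(report[[nm]], paste0(nm, ".csv"))
  fits <- report[intersect(names(report),
                           c("t50_by_condition", "delta_t50_vs_control_h",
                             "t50_by_bin", "t50_by_zone",
                             "delta_t50_core_minus_periphery_h",
                             "shift_test"))]
  if (!is.null(report$fits))
    fits$dose_response <- lapply(report$fits, function(f)
      list(top = f@top, bottom = f@bottom, ec50 = f@ec50, hill = f@hill,
           ci95_ec50 = f@ci95_ec50))
  p <- file.path(out_dir, "fits.json")
  jsonlite::write_json(fits, p, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "provenance.txt")
  writeLines(c(paste0("package: orgaKinetics ",
                      report$provenance$package_version),
               paste0("scenario: ", report$provenance$scenario),
               paste0("seed: ", report$provenance$seed),
               paste0("timestamp: ", report$provenance$timestamp),
               "config:", report$provenance$config_yaml), p)
  invisible(c(paths, p))
}

# ---------------------------------------------------------------------------
# Image stack I/O

#' Write an image stack as a multi-page 16-bit TIFF with sidecar metadata
#'
#' One page per frame; counts are stored as 16-bit unsigned integers. Pixel
#' size and frame times are written to a sidecar YAML next to the TIFF
#' (resolution metadata is also read back from TIFF tags when present).
#'
#' @param stack array (height, width, n_frames) of counts.
#' @param path output TIFF path.
#' @param pixel_size_um µm per pixel (sidecar metadata).
#' @param times_h optional frame times (sidecar metadata).
#' @return invisibly, \code{path}.
#' @export
writeImageStack <- function(stack, path, pixel_size_um, times_h = NULL) {
  if (length(dim(stack)) == 2L) stack <- array(stack, c(dim(stack), 1L))
  pages <- lapply(seq_len(dim(stack)[3L]), function(it)
    pmin(pmax(stack[, , it], 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(pixel_size_um = pixel_size_um)
  if (!is.null(times_h)) meta$times_h <- as.numeric(times_h)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read an image stack written by the package (or any TIFF series)
#'
#' @param paths one multi-page TIFF or several single-page TIFFs of equal
#'   shape.
#' @param pixel_size_um pixel size override; when given it wins over tag or
#'   sidecar metadata (a mismatch is reported via \code{message}).
#' @param times_h frame times override; required if no sidecar metadata
#'   provides them.
#' @return list with \code{stack} (counts array), \code{pixel_size_um} and
#'   \code{times_h}.
#' @export
readImageStack <- function(paths, pixel_size_um = NULL, times_h = NULL) {
  pages <- list(); meta <- list()
  for (p in paths) {
    pg <- tiff::readTIFF(p, all = TRUE, info = TRUE)
    pages <- c(pages, pg)
    side <- paste0(p, ".meta.yaml")
    if (file.exists(side)) meta <- utils::modifyList(meta, yaml::read_yaml(side))
    xres <- attr(pg[[1L]], "x.resolution")
    if (!is.null(xres) && is.null(meta$pixel_size_um) && xres > 0)
      meta$pixel_size_um <- 10000 / xres  # pixels per cm -> µm per pixel
  }
  shapes <- vapply(pages, function(x) paste(dim(x), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L) stop("inconsistent frame shapes")
  if (!is.null(pixel_size_um)) {
    if (!is.null(meta$pixel_size_um) &&
        abs(meta$pixel_size_um - pixel_size_um) > 1e-9)
      message("pixel size mismatch: using the configured value ",
              pixel_size_um, " um/px over ", meta$pixel_size_um)
    meta$pixel_size_um <- pixel_size_um
  }
  if (is.null(meta$pixel_size_um))
    stop("pixel size not found in metadata; supply pixel_size_um")
  if (!is.null(times_h)) meta$times_h <- times_h
  if (is.null(meta$times_h))
    stop("frame times not found in metadata; supply times_h")
  if (length(meta$times_h) != length(pages))
    stop("frame/time count mismatch")
  h <- dim(pages[[1L]])[1L]; w <- dim(pages[[1L]])[2L]
  stack <- array(0, c(h, w, length(pages)))
  for (it in seq_along(pages))
    stack[, , it] <- round(pages[[it]] * 65535)
  list(stack = stack, pixel_size_um = meta$pixel_size_um,
       times_h = as.numeric(meta$times_h))
}

#' Write a rendered simulation to disk as TIFF stacks plus ground truth
#'
#' @param sim result of \code{\link{renderTranslocationTimelapse}} or
#'   \code{\link{renderDomeTimelapse}}.
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  px <- pixelSize(sim$config)
  p1 <- file.path(out_dir, "hoechst.tif")
  p2 <- file.path(out_dir, "egfp.tif")
  writeImageStack(sim$hoechst, p1, px, sim$times_h)
  writeImageStack(sim$egfp, p2, px, sim$times_h)
  utils::write.csv(sim$ground_truth,
                   file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$cells, file.path(out_dir, "cells_truth.csv"),
                   row.names = FALSE)
  if (!is.null(sim$organoids))
    utils::write.csv(sim$organoids,
                     file.path(out_dir, "organoids_truth.csv"),
                     row.names = FALSE)
  invisible(out_dir)
}
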