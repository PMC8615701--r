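# Synthetic microscopy and plate-data generator. Every renderer takes an
# explicit seed and returns exact ground truth, so downstream stages are
# tested by parameter recovery. Cells are rendered as disks/annuli: ground
# truth stays exact and recovery, not realism, is the point.

#' Programmed nuclear fraction over time
#'
#' Ground-truth readout of a \linkS4class{KineticModel}:
#' \code{baseline + (plateau - baseline) * plogis((t - lag - t50)/slope)},
#' clipped to [0, 1]; times at or before 0 return the baseline (the
#' pre-treatment frame).
#'
#' @param model a \linkS4class{KineticModel}.
#' @param times_h numeric vector of times in hours.
#' @param lag_offset_h additional lag added to the model's lag (e.g. a
#'   position- or zone-dependent delay).
#' @return numeric vector of nuclear fractions in [0, 1].
#' @examples
#' m <- kineticModel(baseline = 0.2, plateau = 0.9, t50_h = 2)
#' nuclearFractionAt(m, c(0, 1, 2, 4, 8))
#' @export
nuclearFractionAt <- function(model, times_h, lag_offset_h = 0) {
  lag <- model@lag_h + lag_offset_h
  v <- model@baseline + (model@plateau - model@baseline) *
    stats::plogis((times_h - lag - model@t50_h) / model@slope_h)
  v[times_h <= 0] <- model@baseline
  pmin(pmax(v, 0), 1)
}

# ---------------------------------------------------------------------------
# Cell tables and layouts

#' Random non-overlapping monolayer cell layout
#'
#' Samples cell centres uniformly in the frame (keeping a border margin)
#' with pairwise separation of at least two cytoplasm radii, so that
#' cytoplasm disks of distinct cells never overlap and per-cell ground truth
#' is unambiguous.
#'
#' @param n number of cells.
#' @param config an \linkS4class{ImagingConfig}.
#' @param seed integer seed.
#' @param nucleus_radius_px,cyto_radius_px cell geometry in pixels
#'   (cytoplasm radius must exceed the nucleus radius).
#' @param nuclear_fraction per-cell nuclear fraction in [0, 1]; a single
#'   value is recycled; \code{NULL} draws uniform(0, 1) values.
#' @param total_egfp total EGFP signal per cell in counts.
#' @param hoechst_intensity nuclear-channel amplitude in counts.
#' @return a data.frame of cell specifications (one row per cell) with
#'   pixel-coordinate centres and physical positions in µm.
#' @export
randomMonolayerCells <- function(n, config, seed, nucleus_radius_px = 6,
                                 cyto_radius_px = 16, nuclear_fraction = NULL,
                                 total_egfp = 1.2e5,
                                 hoechst_intensity = 1500) {
  stopifnot(cyto_radius_px > nucleus_radius_px, nucleus_radius_px > 0)
  margin <- cyto_radius_px + 4 * config@psf_sigma_px + 2
  min_sep <- 2 * cyto_radius_px + 2
  withSeed(seed, {
    xs <- numeric(0); ys <- numeric(0); tries <- 0L
    while (length(xs) < n && tries < 20000L) {
      tries <- tries + 1L
      px <- stats::runif(1, margin, config@width_px - margin)
      py <- stats::runif(1, margin, config@height_px - margin)
      if (length(xs) == 0L ||
          all((xs - px)^2 + (ys - py)^2 >= min_sep^2)) {
        xs <- c(xs, px); ys <- c(ys, py)
      }
    }
    if (length(xs) < n)
      stop("could not place ", n, " non-overlapping cells in the frame")
    f <- if (is.null(nuclear_fraction)) stats::runif(n)
         else rep_len(nuclear_fraction, n)
    cellTable(x_px = xs, y_px = ys, nucleus_radius_px = nucleus_radius_px,
              cyto_radius_px = cyto_radius_px, nuclear_fraction = f,
              total_egfp = total_egfp, hoechst_intensity = hoechst_intensity,
              pixel_size_um = config@pixel_size_um)
  })
}

#' Build a validated cell specification table
#'
#' @param x_px,y_px continuous pixel coordinates of cell centres.
#' @param nucleus_radius_px,cyto_radius_px cell geometry in pixels.
#' @param nuclear_fraction values in [0, 1]; ground-truth value of the
#'   translocation ratio (nuclear share of the EGFP intensity partition).
#' @param total_egfp integrated EGFP per cell in counts.
#' @param hoechst_intensity nuclear-channel amplitude in counts.
#' @param pixel_size_um µm per pixel, used to derive physical positions.
#' @param organoid_id optional organoid membership.
#' @param lag_offset_h optional per-cell kinetic lag offset (h).
#' @return data.frame with one row per cell.
#' @export
cellTable <- function(x_px, y_px, nucleus_radius_px, cyto_radius_px,
                      nuclear_fraction, total_egfp, hoechst_intensity,
                      pixel_size_um, organoid_id = NA_integer_,
                      lag_offset_h = 0) {
  n <- length(x_px)
  stopifnot(length(y_px) == n)
  df <- data.frame(cell_id = seq_len(n), x_px = x_px, y_px = y_px,
                   nucleus_radius_px = rep_len(nucleus_radius_px, n),
                   cyto_radius_px = rep_len(cyto_radius_px, n),
                   nuclear_fraction = rep_len(nuclear_fraction, n),
                   total_egfp = rep_len(total_egfp, n),
                   hoechst_intensity = rep_len(hoechst_intensity, n),
                   organoid_id = rep_len(organoid_id, n),
                   lag_offset_h = rep_len(lag_offset_h, n))
  df$x_um <- df$x_px * pixel_size_um
  df$y_um <- df$y_px * pixel_size_um
  if (any(df$nuclear_fraction < 0 | df$nuclear_fraction > 1))
    stop("nuclear_fraction must lie in [0, 1]")
  if (any(df$cyto_radius_px <= df$nucleus_radius_px))
    stop("cyto_radius_px must exceed nucleus_radius_px")
  df
}

# Check the monolayer precondition: cytoplasm disks of distinct cells must
# not overlap (ground truth would be ambiguous) and cells must fit in frame.
.checkLayout <- function(cells, config, allow_overlap_within_organoid = FALSE) {
  w <- config@width_px; h <- config@height_px
  rc <- cells$cyto_radius_px
  if (any(cells$x_px - rc < 0 | cells$x_px + rc > w |
          cells$y_px - rc < 0 | cells$y_px + rc > h))
    stop("cells must fit within the frame")
  n <- nrow(cells)
  if (n < 2L) return(invisible(TRUE))
  d2 <- as.matrix(stats::dist(cbind(cells$x_px, cells$y_px)))^2
  lim <- outer(rc, rc, "+")^2
  same_org <- outer(cells$organoid_id, cells$organoid_id, "==")
  same_org[is.na(same_org)] <- FALSE
  bad <- d2 < lim & upper.tri(d2)
  if (allow_overlap_within_organoid) bad <- bad & !same_org
  if (any(bad))
    stop("overlapping cytoplasm disks of distinct cells: layout rejected ",
         "(ground truth would be ambiguous)")
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Frame rendering

# Linear pixel indices of the annulus r_in < d <= r_out around the
# continuous pixel coordinate (x, y) in an h x w frame.
.annulusIndices <- function(h, w, x, y, r_in, r_out) {
  j0 <- max(1L, floor(x - r_out)); j1 <- min(w, ceiling(x + r_out) + 1L)
  i0 <- max(1L, floor(y - r_out)); i1 <- min(h, ceiling(y + r_out) + 1L)
  if (j0 > j1 || i0 > i1) return(integer(0))
  ii <- i0:i1; jj <- j0:j1
  d2 <- outer((ii - 0.5 - y)^2, (jj - 0.5 - x)^2, "+")
  sel <- which(d2 <= r_out^2 & d2 > r_in^2)
  ri <- ((sel - 1L) %% length(ii)) + i0
  ci <- ((sel - 1L) %/% length(ii)) + j0
  (ci - 1L) * h + ri
}

# Precompute the pixel supports of every cell's nucleus and annulus (cells
# are static in a time-lapse, so this is done once per scene).
.cellSprites <- function(cells, config) {
  h <- config@height_px; w <- config@width_px
  lapply(seq_len(nrow(cells)), function(k) {
    nuc <- .annulusIndices(h, w, cells$x_px[k], cells$y_px[k], -1,
                           cells$nucleus_radius_px[k])
    ann <- .annulusIndices(h, w, cells$x_px[k], cells$y_px[k],
                           cells$nucleus_radius_px[k],
                           cells$cyto_radius_px[k])
    list(nuc = nuc, ann = ann, a_nuc = length(nuc), a_ann = length(ann))
  })
}

# Render the two channels for one frame, without noise or rounding.
# `fractions` overrides the cells' nuclear_fraction (one value per cell).
# The EGFP channel partitions each cell's intensity between nucleus and
# cytoplasmic annulus so that the nucleus mean density is proportional to f
# and the annulus mean density to (1 - f), scaled so the integrated signal
# equals total_egfp for every f (the mean-based translocation ratio of the
# pristine cell is then exactly f). `halos` is an optional data.frame
# (x_px, y_px, r_px, level) of diffuse nuclear-channel disks (organoid body).
.renderChannels <- function(cells, fractions, config, halos = NULL,
                            sprites = NULL, channels = c("hoechst", "egfp")) {
  h <- config@height_px; w <- config@width_px
  if (is.null(sprites)) sprites <- .cellSprites(cells, config)
  out <- list()
  if ("hoechst" %in% channels) {
    hoechst <- numeric(h * w)
    for (k in seq_len(nrow(cells))) {
      sp <- sprites[[k]]
      hoechst[sp$nuc] <- hoechst[sp$nuc] + cells$hoechst_intensity[k]
    }
    if (!is.null(halos) && nrow(halos)) {
      for (k in seq_len(nrow(halos))) {
        idx <- .annulusIndices(h, w, halos$x_px[k], halos$y_px[k], -1,
                               halos$r_px[k])
        hoechst[idx] <- hoechst[idx] + halos$level[k]
      }
    }
    out$hoechst <- matrix(hoechst, h, w)
  }
  if ("egfp" %in% channels) {
    egfp <- numeric(h * w)
    for (k in seq_len(nrow(cells))) {
      sp <- sprites[[k]]
      f <- fractions[k]
      scale <- cells$total_egfp[k] / (f * sp$a_nuc + (1 - f) * sp$a_ann)
      if (f > 0) egfp[sp$nuc] <- egfp[sp$nuc] + f * scale
      if (f < 1) egfp[sp$ann] <- egfp[sp$ann] + (1 - f) * scale
    }
    out$egfp <- matrix(egfp, h, w)
  }
  if (config@psf_sigma_px > 0)
    out <- lapply(out, EBImage::gblur, sigma = config@psf_sigma_px)
  out
}

# Apply background, read noise, rounding and the camera's dynamic range.
# Assumes the RNG state has already been seeded by the caller.
.digitize <- function(img, config) {
  img <- img + config@background_level
  if (config@noise_sd > 0)
    img <- img + stats::rnorm(length(img), sd = config@noise_sd)
  img <- round(img)
  pmin(pmax(img, 0), 2^config@bit_depth - 1)
}

#' Render a two-channel monolayer frame with ground truth
#'
#' Channel 1 (Hoechst) contains Gaussian-blurred nuclear disks; channel 2
#' (EGFP) distributes each cell's signal between its nuclear disk and the
#' surrounding cytoplasmic annulus according to \code{nuclear_fraction},
#' plus background and Gaussian read noise. The integrated EGFP per cell
#' (before noise, above background) is conserved across nuclear fractions.
#'
#' @param cells a cell table from \code{\link{randomMonolayerCells}} or
#'   \code{\link{cellTable}}.
#' @param config an \linkS4class{ImagingConfig}.
#' @param seed integer seed for the read noise.
#' @return list with matrices \code{hoechst} and \code{egfp} (counts), the
#'   \code{ground_truth} cell table and the \code{config}.
#' @export
renderMonolayerFrame <- function(cells, config, seed) {
  .checkLayout(cells, config)
  ch <- .renderChannels(cells, cells$nuclear_fraction, config)
  withSeed(seed, {
    list(hoechst = .digitize(ch$hoechst, config),
         egfp = .digitize(ch$egfp, config),
         ground_truth = cells, config = config)
  })
}

#' Render a two-channel translocation time-lapse with ground truth
#'
#' The scene is static (no cell motion or division); each cell's nuclear
#' fraction follows the lagged logistic of \code{kinetics}, shifted by the
#' cell's \code{lag_offset_h}. Frame times must be strictly increasing with
#' a pre-treatment first frame at the baseline.
#'
#' @param cells cell table (see \code{\link{cellTable}}).
#' @param kinetics a \linkS4class{KineticModel} shared by all cells (per-cell
#'   delays go through \code{lag_offset_h}).
#' @param times_h strictly increasing frame times in hours; the first frame
#'   should be at or before 0 (baseline).
#' @param config an \linkS4class{ImagingConfig}.
#' @param seed integer seed for the read noise.
#' @param halos optional data.frame (x_px, y_px, r_px, level) of diffuse
#'   nuclear-channel disks rendering the organoid body.
#' @param allow_overlap_within_organoid allow cytoplasm overlap between
#'   cells of the same organoid (their kinetics are shared, so the measured
#'   ratio time-course is unaffected).
#' @return list with arrays \code{hoechst} and \code{egfp} of dimension
#'   (height, width, n_frames), \code{times_h}, the \code{cells} table, the
#'   long-format \code{ground_truth} (cell_id, time_h, nuclear_fraction) and
#'   the \code{config}.
#' @export
renderTranslocationTimelapse <- function(cells, kinetics, times_h, config,
                                         seed, halos = NULL,
                                         allow_overlap_within_organoid = FALSE) {
  if (any(diff(times_h) <= 0))
    stop("times_h must be strictly increasing")
  .checkLayout(cells, config, allow_overlap_within_organoid)
  nt <- length(times_h)
  h <- config@height_px; w <- config@width_px
  hoechst <- array(0, c(h, w, nt))
  egfp <- array(0, c(h, w, nt))
  gt <- vector("list", nt)
  sprites <- .cellSprites(cells, config)
  # the nuclear channel is static: render and blur it once, then only the
  # read noise differs between frames
  hoechst_base <- .renderChannels(cells, cells$nuclear_fraction, config,
                                  halos, sprites, channels = "hoechst")$hoechst
  withSeed(seed, {
    for (it in seq_len(nt)) {
      f <- nuclearFractionAt(kinetics, times_h[it], cells$lag_offset_h)
      ch <- .renderChannels(cells, f, config, sprites = sprites,
                            channels = "egfp")
      hoechst[, , it] <- .digitize(hoechst_base, config)
      egfp[, , it] <- .digitize(ch$egfp, config)
      gt[[it]] <- data.frame(cell_id = cells$cell_id, time_h = times_h[it],
                             nuclear_fraction = f)
    }
  })
  list(hoechst = hoechst, egfp = egfp, times_h = times_h, cells = cells,
       ground_truth = do.call(rbind, gt), config = config)
}

# ---------------------------------------------------------------------------
# Dome scenarios

#' Random organoid layout within a scaffold dome
#'
#' Places organoids uniformly at random in the dome with non-overlapping
#' footprints. With \code{stratify_bins = TRUE} (the default) the radial
#' range is divided into \code{n_bins} equal annuli and
#' \code{n_per_bin} organoids are placed in each, mirroring wells in which
#' organoids populate the full dome cross-section; this guarantees every
#' radial bin is represented.
#'
#' @param center_xy_um dome centre (x, y) in µm.
#' @param dome_radius_um dome radius in µm.
#' @param organoid_radius_um organoid radius in µm.
#' @param n_cells cells per organoid.
#' @param seed integer seed.
#' @param lag_fun function mapping distance from the dome centre (µm) to the
#'   programmed kinetic lag (h).
#' @param n_bins,n_per_bin stratified placement (see above).
#' @param n_organoids total organoids when \code{stratify_bins = FALSE}.
#' @param stratify_bins logical.
#' @return a \linkS4class{DomeLayout}.
#' @export
randomDomeLayout <- function(center_xy_um, dome_radius_um = 2250,
                             organoid_radius_um = 150, n_cells = 5L,
                             seed = 1L,
                             lag_fun = function(d) rep(0, length(d)),
                             n_bins = 9L, n_per_bin = 2L,
                             n_organoids = 18L, stratify_bins = TRUE) {
  min_sep <- 2.2 * organoid_radius_um
  withSeed(seed, {
    for (attempt in 1:50) {
      xs <- numeric(0); ys <- numeric(0); failed <- FALSE
      place <- function(rlo, rhi, n) {
        tries <- 0L; placed <- 0L
        while (placed < n && tries < 5000L) {
          tries <- tries + 1L
          r <- sqrt(stats::runif(1, rlo^2, rhi^2))
          a <- stats::runif(1, 0, 2 * pi)
          px <- center_xy_um[1L] + r * cos(a)
          py <- center_xy_um[2L] + r * sin(a)
          if (length(xs) == 0L ||
              all((xs - px)^2 + (ys - py)^2 >= min_sep^2)) {
            xs <<- c(xs, px); ys <<- c(ys, py); placed <- placed + 1L
          }
        }
        placed == n
      }
      if (stratify_bins) {
        bw <- dome_radius_um / n_bins
        for (b in seq_len(n_bins) - 1L) {
          if (!place(b * bw, min((b + 1L) * bw, dome_radius_um - 1e-6),
                     n_per_bin)) {
            failed <- TRUE
            break
          }
        }
      } else {
        failed <- !place(0, dome_radius_um, n_organoids)
      }
      if (!failed) break
    }
    if (failed)
      stop("could not place organoids without overlap; reduce density")
    org <- data.frame(organoid_id = seq_along(xs), x_um = xs, y_um = ys,
                      n_cells = as.integer(n_cells),
                      radius_um = organoid_radius_um)
    domeLayout(center_xy_um, dome_radius_um, org, lag_fun)
  })
}

#' Render a dome time-lapse with position-dependent kinetic lags
#'
#' Each organoid is a cluster of cells around its position; its kinetic lag
#' is \code{lag_fun(distance from dome centre)}, plus an optional extra
#' \code{core_lag_h} for cells deeper than \code{rim_width_px} from the
#' organoid boundary (periphery cells keep the organoid lag). A diffuse
#' nuclear-channel halo renders the organoid body so organoid masks are
#' recoverable by segmentation.
#'
#' @param layout a \linkS4class{DomeLayout}.
#' @param kinetics a \linkS4class{KineticModel}; the per-organoid and
#'   per-zone lags are added to its \code{lag_h}.
#' @param times_h strictly increasing frame times (h).
#' @param config an \linkS4class{ImagingConfig}; the dome must fit in frame.
#' @param seed integer seed.
#' @param nucleus_radius_px,cyto_radius_px cell geometry in pixels.
#' @param core_lag_h extra lag (h) for organoid-core cells.
#' @param rim_width_px rim width (pixels from the organoid boundary) that
#'   defines the ground-truth periphery when \code{core_lag_h != 0}.
#' @param cell_sep_px minimum separation of cell centres within an organoid;
#'   defaults to non-touching nuclei (cytoplasm may overlap within an
#'   organoid when all its cells share kinetics).
#' @param zone_margin_px when non-zero, cell positions whose distance to
#'   the organoid boundary falls within this margin of \code{rim_width_px}
#'   are rejected, so every rendered cell has an unambiguous ground-truth
#'   zone (analogous to the non-overlap rule for monolayer layouts).
#' @param halo_level nuclear-channel counts of the organoid body disk.
#' @param total_egfp,hoechst_intensity per-cell signal amplitudes (counts).
#' @return as \code{\link{renderTranslocationTimelapse}}, plus
#'   \code{organoids} (ground-truth table with distance, lag, area) and
#'   per-cell \code{zone_true} / \code{lag_offset_h} columns in
#'   \code{cells}.
#' @export
renderDomeTimelapse <- function(layout, kinetics, times_h, config, seed,
                                nucleus_radius_px = 5, cyto_radius_px = 9,
                                core_lag_h = 0, rim_width_px = 100,
                                cell_sep_px = NULL, zone_margin_px = 0,
                                halo_level = 250, total_egfp = 1e5,
                                hoechst_intensity = 1500) {
  px <- config@pixel_size_um
  org <- layout@organoids
  d_um <- sqrt((org$x_um - layout@center_xy_um[1L])^2 +
               (org$y_um - layout@center_xy_um[2L])^2)
  if (any(d_um > layout@dome_radius_um))
    stop("organoid outside dome")
  lag_org <- layout@lag_fun(d_um)
  if (any(!is.finite(lag_org)))
    stop("lag_fun must be defined on [0, dome_radius_um]")
  if (is.null(cell_sep_px)) cell_sep_px <- 2 * nucleus_radius_px + 4
  allow_overlap <- cell_sep_px < 2 * cyto_radius_px
  cell_list <- vector("list", nrow(org))
  withSeed(childSeed(seed, 1L), {
    for (k in seq_len(nrow(org))) {
      cx <- org$x_um[k] / px; cy <- org$y_um[k] / px
      r_px <- org$radius_um[k] / px
      accept <- if (zone_margin_px > 0) {
        function(qx, qy) {
          bd <- r_px - sqrt((qx - cx)^2 + (qy - cy)^2)
          abs(bd - rim_width_px) > zone_margin_px
        }
      } else NULL
      pos <- samplePackedDisk(org$n_cells[k], cx, cy,
                              r_px - cyto_radius_px - 1, cell_sep_px,
                              accept = accept)
      r_rel <- sqrt((pos[, "x"] - cx)^2 + (pos[, "y"] - cy)^2)
      boundary_dist <- r_px - r_rel
      zone <- ifelse(boundary_dist > rim_width_px, "core", "periphery")
      lag <- lag_org[k] + ifelse(zone == "core", core_lag_h, 0)
      cl <- cellTable(x_px = pos[, "x"], y_px = pos[, "y"],
                      nucleus_radius_px = nucleus_radius_px,
                      cyto_radius_px = cyto_radius_px,
                      nuclear_fraction = kinetics@baseline,
                      total_egfp = total_egfp,
                      hoechst_intensity = hoechst_intensity,
                      pixel_size_um = px,
                      organoid_id = org$organoid_id[k], lag_offset_h = lag)
      cl$zone_true <- zone
      cell_list[[k]] <- cl
    }
  })
  cells <- do.call(rbind, cell_list)
  cells$cell_id <- seq_len(nrow(cells))
  halos <- data.frame(x_px = org$x_um / px, y_px = org$y_um / px,
                      r_px = org$radius_um / px, level = halo_level)
  sim <- renderTranslocationTimelapse(
    cells, kinetics, times_h, config, seed = childSeed(seed, 2L),
    halos = halos, allow_overlap_within_organoid = allow_overlap)
  sim$organoids <- data.frame(org, distance_um = d_um, lag_h = lag_org,
                              area_um2 = pi * org$radius_um^2)
  sim$layout <- layout
  sim
}

# ---------------------------------------------------------------------------
# Tubulin texture frames

# Bundle geometry and mottle field for a tubulin scene, drawn from the seed
# independently of the stabilization level so that frames at increasing
# stabilization share a nested bundle set.
.tubulinScene <- function(config, seed, max_bundles, region_radius_frac) {
  h <- config@height_px; w <- config@width_px
  cx <- w / 2; cy <- h / 2
  R <- region_radius_frac * min(w, h)
  withSeed(seed, {
    bundles <- lapply(seq_len(max_bundles), function(i) {
      r <- R * 0.85 * sqrt(stats::runif(1)); a <- stats::runif(1, 0, 2 * pi)
      bx <- cx + r * cos(a); by <- cy + r * sin(a)
      ang <- stats::runif(1, 0, pi); len <- stats::runif(1, 20, 50)
      list(x = bx, y = by, angle = ang, length = len)
    })
    mottle <- EBImage::gblur(matrix(stats::rnorm(h * w), h, w), sigma = 6)
    mottle <- mottle / stats::sd(mottle)
    list(cx = cx, cy = cy, R = R, bundles = bundles, mottle = mottle)
  })
}

# Rasterize one bundle (line segment of given width) into unique pixel
# indices of an h x w frame.
.bundlePixels <- function(b, h, w, width_px = 2) {
  tt <- seq(-b$length / 2, b$length / 2, by = 0.4)
  off <- seq(-width_px / 2, width_px / 2, by = 0.5)
  xs <- as.vector(outer(b$x + tt * cos(b$angle), off * -sin(b$angle), "+"))
  ys <- as.vector(outer(b$y + tt * sin(b$angle), off * cos(b$angle), "+"))
  i <- round(ys + 0.5); j <- round(xs + 0.5)
  keep <- i >= 1 & i <= h & j >= 1 & j <= w
  unique((j[keep] - 1L) * h + i[keep])
}

#' Render a single-channel tubulin frame at a given stabilization level
#'
#' Renders a diffuse cell-area disk plus \code{round(stabilization *
#' max_bundles)} bright line-segment bundles of fixed width, emulating
#' taxane-induced microtubule bundling. For a fixed seed the bundle set is
#' nested across stabilization levels, so texture contrast increases
#' strictly with stabilization.
#'
#' @param stabilization level in [0, 1].
#' @param config an \linkS4class{ImagingConfig}.
#' @param seed integer seed.
#' @param max_bundles bundles at full stabilization.
#' @param region_radius_frac cell-area disk radius as a fraction of the
#'   frame's shorter side.
#' @param base_level diffuse cell-area intensity (counts).
#' @param bundle_level added intensity of bundle pixels (counts).
#' @param mottle_sd sd (counts) of the smooth intensity mottle within the
#'   cell area.
#' @return list with the \code{image} matrix, the ground-truth cell-area
#'   \code{mask} (logical matrix) and \code{n_bundles}.
#' @export
renderTubulinFrame <- function(stabilization, config, seed, max_bundles = 40L,
                               region_radius_frac = 0.42, base_level = 300,
                               bundle_level = 1200, mottle_sd = 40) {
  if (!is.finite(stabilization) || stabilization < 0 || stabilization > 1)
    stop("stabilization must lie in [0, 1]")
  scene <- .tubulinScene(config, childSeed(seed, 1L), max_bundles,
                         region_radius_frac)
  sim <- renderTubulinSeries(list(scene = scene, config = config),
                             stabilization, times_h = 0,
                             seed = childSeed(seed, 2L),
                             base_level = base_level,
                             bundle_level = bundle_level,
                             mottle_sd = mottle_sd)
  list(image = sim$stack[, , 1L], mask = sim$mask,
       n_bundles = sim$truth$n_bundles[1L])
}

#' Render a tubulin stabilization time-lapse
#'
#' One frame per entry of \code{stabilization}; the bundle set is nested
#' over frames (frames at higher stabilization contain all bundles of lower
#' ones). An optional exponential bleaching decay multiplies the signal
#' (not the camera background) to exercise the bleaching caveat of the
#' texture readout.
#'
#' @param config an \linkS4class{ImagingConfig}.
#' @param stabilization vector of levels in [0, 1], one per frame.
#' @param times_h frame times (h), same length.
#' @param seed integer seed.
#' @param bleach_half_life_h half-life of the multiplicative signal decay;
#'   \code{Inf} (default) disables bleaching.
#' @param max_bundles,region_radius_frac,base_level,bundle_level,mottle_sd
#'   see \code{\link{renderTubulinFrame}}.
#' @return list with the image \code{stack} (h x w x n_frames), the
#'   cell-area \code{mask}, \code{times_h} and the ground-truth \code{truth}
#'   table (time_h, stabilization, n_bundles, bleach_factor).
#' @export
renderTubulinTimelapse <- function(config, stabilization, times_h, seed,
                                   bleach_half_life_h = Inf,
                                   max_bundles = 40L,
                                   region_radius_frac = 0.42,
                                   base_level = 300, bundle_level = 1200,
                                   mottle_sd = 40) {
  stopifnot(length(stabilization) == length(times_h))
  if (any(stabilization < 0 | stabilization > 1))
    stop("stabilization must lie in [0, 1]")
  scene <- .tubulinScene(config, childSeed(seed, 1L), max_bundles,
                         region_radius_frac)
  renderTubulinSeries(list(scene = scene, config = config), stabilization,
                      times_h, seed = childSeed(seed, 2L),
                      bleach_half_life_h = bleach_half_life_h,
                      base_level = base_level, bundle_level = bundle_level,
                      mottle_sd = mottle_sd)
}

# Shared renderer over a fixed scene.
renderTubulinSeries <- function(scene_cfg, stabilization, times_h, seed,
                                bleach_half_life_h = Inf, base_level = 300,
                                bundle_level = 1200, mottle_sd = 40) {
  scene <- scene_cfg$scene; config <- scene_cfg$config
  h <- config@height_px; w <- config@width_px
  ii <- matrix(seq_len(h), h, w); jj <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- (ii - 0.5 - scene$cy)^2 + (jj - 0.5 - scene$cx)^2 <= scene$R^2
  base <- matrix(0, h, w)
  base[mask] <- base_level + mottle_sd * scene$mottle[mask]
  base[base < 0] <- 0
  nt <- length(stabilization)
  stack <- array(0, c(h, w, nt))
  nb <- integer(nt); bleach <- numeric(nt)
  max_b <- length(scene$bundles)
  withSeed(seed, {
    for (it in seq_len(nt)) {
      n <- as.integer(round(stabilization[it] * max_b))
      nb[it] <- n
      img <- base
      if (n > 0L) {
        for (b in scene$bundles[seq_len(n)]) {
          idx <- .bundlePixels(b, h, w)
          img[idx] <- img[idx] + bundle_level
        }
      }
      img[!mask] <- 0
      fac <- if (is.finite(bleach_half_life_h))
        2^(-max(times_h[it], 0) / bleach_half_life_h) else 1
      bleach[it] <- fac
      img <- img * fac
      if (config@psf_sigma_px > 0)
        img <- EBImage::gblur(img, sigma = config@psf_sigma_px)
      stack[, , it] <- .digitize(img, config)
    }
  })
  list(stack = stack, mask = mask, times_h = times_h,
       truth = data.frame(time_h = times_h, stabilization = stabilization,
                          n_bundles = nb, bleach_factor = bleach))
}

# ---------------------------------------------------------------------------
# Viability plates

#' Four-parameter logistic dose-response function
#'
#' \eqn{r(d) = bottom + (top - bottom) / (1 + (d/EC_{50})^{hill})}; at
#' \eqn{d = 0} the vehicle limit \eqn{top} is returned (for positive Hill
#' slopes, i.e. responses that fall with dose).
#'
#' @param dose dose vector (>= 0).
#' @param top,bottom,ec50,hill curve parameters; \code{ec50 > 0}.
#' @return response vector.
#' @examples
#' fourPLResponse(1, top = 100, bottom = 0, ec50 = 1, hill = 1)  # midpoint
#' @export
fourPLResponse <- function(dose, top, bottom, ec50, hill) {
  stopifnot(ec50 > 0)
  term <- ifelse(dose > 0, exp(hill * (log(dose) - log(ec50))), 0)
  bottom + (top - bottom) / (1 + term)
}

#' Simulate a viability plate from a 4PL dose-response
#'
#' Each well's response is the 4PL value multiplied by mean-one lognormal
#' noise with coefficient of variation \code{cv}; vehicle wells (dose 0)
#' respond at \code{top}.
#'
#' @param doses positive dose vector (one entry per dose level).
#' @param top,bottom,ec50,hill true 4PL parameters; \code{ec50 > 0},
#'   \code{hill != 0}.
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param replicates wells per dose (>= 1).
#' @param n_vehicle vehicle wells (default: same as \code{replicates}).
#' @param seed integer seed.
#' @return data.frame with columns \code{well_id, dose, response}; the true
#'   parameters are attached as \code{attr(, "truth")}.
#' @export
simulateViabilityPlate <- function(doses, top = 100, bottom = 0, ec50 = 1,
                                   hill = 1, cv = 0.05, replicates = 3L,
                                   n_vehicle = NULL, seed = 1L) {
  if (any(doses <= 0)) stop("doses must be positive (vehicle wells are added separately)")
  if (ec50 <= 0) stop("ec50 must be positive")
  if (hill == 0) stop("hill must be non-zero")
  if (cv < 0) stop("cv must be >= 0")
  if (replicates < 1L) stop("replicates must be >= 1")
  if (is.null(n_vehicle)) n_vehicle <- replicates
  d <- c(rep(0, n_vehicle), rep(doses, each = replicates))
  mu <- fourPLResponse(d, top, bottom, ec50, hill)
  withSeed(seed, {
    noise <- if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      exp(stats::rnorm(length(d), -sdlog^2 / 2, sdlog))
    } else rep(1, length(d))
    out <- data.frame(well_id = seq_along(d), dose = d,
                      response = mu * noise)
    attr(out, "truth") <- list(top = top, bottom = bottom, ec50 = ec50,
                               hill = hill, cv = cv)
    out
  })
}

#' Normalize plate responses to vehicle controls
#'
#' @param plate data.frame with columns \code{dose} and \code{response}.
#' @return the same data.frame with a \code{response_pct} column, responses
#'   as a percentage of the mean vehicle (dose 0) response.
#' @export
normalizeToVehicle <- function(plate) {
  veh <- plate$response[plate$dose == 0]
  if (!length(veh)) stop("no vehicle (dose 0) wells to normalize to")
  plate$response_pct <- 100 * plate$response / mean(veh)
  plate
}
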