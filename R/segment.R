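# Nucleus, perinuclear-ring, whole-cell-area and organoid segmentation.
# Primitives (Gaussian smoothing, Otsu, distance transform, watershed,
# Voronoi propagation, hole filling) come from EBImage; the operations
# below fix the algorithmic choices: global Otsu on the smoothed channel,
# distance-transform watershed to split touching nuclei, nearest-nucleus
# partition of the perinuclear rings, and centroid-based rim allocation.

# Relabel a label matrix to consecutive labels 1..K (order of first
# appearance of the original labels, ascending).
.relabel <- function(labels, keep = NULL) {
  ids <- sort(unique(labels[labels > 0]))
  if (!is.null(keep)) ids <- ids[ids %in% keep]
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (k in seq_along(ids)) out[labels == ids[k]] <- k
  out
}

#' Segment nuclei from the nuclear-stain channel
#'
#' Global Otsu threshold on the Gaussian-smoothed Hoechst channel, followed
#' by a distance-transform watershed to split touching nuclei. Objects with
#' areas outside \code{[min_area_px, max_area_px]} are discarded and the
#' surviving labels renumbered consecutively from 1.
#'
#' @param image single-channel matrix (counts).
#' @param pixel_size_um µm per pixel, carried into the result.
#' @param min_area_px,max_area_px area gate in pixels.
#' @param smooth_sigma Gaussian smoothing sigma (pixels) before
#'   thresholding.
#' @param watershed_tolerance minimum object-separating depth of the
#'   distance transform.
#' @return a \linkS4class{LabelImage} (empty, with a warning, when the image
#'   carries no foreground).
#' @export
segmentNuclei <- function(image, pixel_size_um, min_area_px = 30,
                          max_area_px = 5000, smooth_sigma = 2,
                          watershed_tolerance = 1) {
  stopifnot(min_area_px < max_area_px)
  empty <- function() {
    warning("no foreground found: returning empty label image")
    labelImage(matrix(0L, nrow(image), ncol(image)), pixel_size_um, "nuclear")
  }
  rng <- range(image)
  if (diff(rng) < 1e-12) return(empty())
  sm <- if (smooth_sigma > 0) EBImage::gblur(image, sigma = smooth_sigma)
        else image
  nrm <- (sm - min(sm)) / diff(range(sm))
  thr <- EBImage::otsu(nrm, range = c(0, 1))
  bin <- nrm > thr
  if (!any(bin)) return(empty())
  lab <- EBImage::watershed(EBImage::distmap(bin),
                            tolerance = watershed_tolerance, ext = 1)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(areas >= min_area_px & areas <= max_area_px)
  if (!length(keep)) return(empty())
  labelImage(.relabel(lab, keep), pixel_size_um, "nuclear")
}

#' Derive perinuclear cytoplasmic rings around segmented nuclei
#'
#' The ring of nucleus k is its dilation by \code{ring_width_px} minus all
#' nuclei, with contested pixels assigned to the nearest nucleus (geodesic
#' Voronoi propagation). Rings carry their nucleus' label; rings and nuclei
#' are disjoint by construction. An optional \code{gap_px} offsets the ring
#' outward from the nucleus boundary, keeping point-spread-function
#' spill-over from the nucleus out of the cytoplasmic measurement.
#'
#' @param nuclei a \linkS4class{LabelImage} of nuclei.
#' @param ring_width_px ring width in pixels (>= 1).
#' @param gap_px gap between the nucleus boundary and the ring (default 0:
#'   the ring starts at the nucleus boundary).
#' @return a \linkS4class{LabelImage} of rings.
#' @export
deriveCytoplasmRings <- function(nuclei, ring_width_px = 5, gap_px = 0) {
  stopifnot(ring_width_px >= 1, gap_px >= 0)
  lab <- labelMatrix(nuclei)
  if (max(lab) == 0L)
    return(labelImage(lab, pixelSize(nuclei), "ring"))
  bin <- lab > 0L
  outer_r <- as.integer(ring_width_px + gap_px)
  zone <- EBImage::dilate(bin, EBImage::makeBrush(2L * outer_r + 1L, "disc"))
  rings <- EBImage::propagate(matrix(0, nrow(lab), ncol(lab)), seeds = lab,
                              mask = zone)
  rings <- matrix(as.integer(rings), nrow(lab), ncol(lab))
  excl <- if (gap_px > 0) {
    EBImage::dilate(bin, EBImage::makeBrush(2L * as.integer(gap_px) + 1L,
                                            "disc")) > 0
  } else bin
  rings[excl] <- 0L
  labelImage(rings, pixelSize(nuclei), "ring")
}

#' Segment organoids from the combined nuclear and EGFP channels
#'
#' The organoid mask is obtained from the sum of the two channels (each
#' rescaled to [0, 1]), smoothed, Otsu-thresholded and hole-filled. Objects
#' below \code{min_area_um2} are dropped. Each record carries the physical
#' centroid, cross-sectional area, radial distance from \code{center_xy_um}
#' and a size class (\code{large} iff area > \code{area_threshold_um2}).
#'
#' @param hoechst_image,egfp_image single-channel matrices of equal shape.
#' @param pixel_size_um µm per pixel.
#' @param min_area_um2 minimum organoid cross-sectional area (µm²).
#' @param smooth_sigma Gaussian smoothing sigma (pixels).
#' @param center_xy_um reference centre for radial distances; defaults to
#'   the frame centre.
#' @param area_threshold_um2 large/small size threshold (µm², default 8000).
#' @param clip_quantile intensities above this quantile of the combined
#'   image are clipped before thresholding, so that sparse bright nuclei
#'   do not dominate Otsu's split and the dimmer organoid body is kept in
#'   the foreground class.
#' @return list with \code{mask} (a \linkS4class{LabelImage}) and
#'   \code{organoids} (data.frame: organoid_id, x_um, y_um, area_um2,
#'   distance_um, size_class).
#' @export
segmentOrganoids <- function(hoechst_image, egfp_image, pixel_size_um,
                             min_area_um2 = 2000, smooth_sigma = 6,
                             center_xy_um = NULL,
                             area_threshold_um2 = 8000,
                             clip_quantile = 0.98) {
  if (!all(dim(hoechst_image) == dim(egfp_image)))
    stop("channel shape mismatch")
  if (is.null(center_xy_um))
    center_xy_um <- c(ncol(hoechst_image), nrow(hoechst_image)) / 2 *
      pixel_size_um
  nrm <- function(x) {
    # background (median) to 0, clip bright outliers, scale to [0, 1]
    x0 <- pmax(x - stats::median(x), 0)
    cap <- stats::quantile(x0, clip_quantile)
    if (cap < 1e-12) matrix(0, nrow(x), ncol(x)) else pmin(x0, cap) / cap
  }
  comb <- nrm(hoechst_image) + nrm(egfp_image)
  empty <- labelImage(matrix(0L, nrow(comb), ncol(comb)), pixel_size_um,
                      "combined")
  if (diff(range(comb)) < 1e-12) {
    warning("no foreground found: returning empty organoid mask")
    return(list(mask = empty,
                organoids = .organoidRecords(empty, center_xy_um,
                                             area_threshold_um2)))
  }
  sm <- if (smooth_sigma > 0) EBImage::gblur(comb, sigma = smooth_sigma)
        else comb
  nsm <- sm / max(sm)
  bin <- nsm > EBImage::otsu(nsm, range = c(0, 1))
  lab <- EBImage::fillHull(EBImage::bwlabel(bin))
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  if (max(lab) > 0L) {
    areas_um2 <- tabulate(lab[lab > 0L], nbins = max(lab)) * pixel_size_um^2
    lab <- .relabel(lab, keep = which(areas_um2 >= min_area_um2))
  }
  mask <- labelImage(lab, pixel_size_um, "combined")
  list(mask = mask,
       organoids = .organoidRecords(mask, center_xy_um, area_threshold_um2))
}

.organoidRecords <- function(mask, center_xy_um, area_threshold_um2) {
  lab <- labelMatrix(mask)
  px <- pixelSize(mask)
  if (max(lab) == 0L)
    return(data.frame(organoid_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), area_um2 = numeric(0),
                      distance_um = numeric(0), size_class = character(0)))
  cen <- labelCentroidsUm(lab, px)
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))[cen$label] * px^2
  d <- sqrt((cen$x_um - center_xy_um[1L])^2 + (cen$y_um - center_xy_um[2L])^2)
  data.frame(organoid_id = cen$label, x_um = cen$x_um, y_um = cen$y_um,
             area_um2 = areas, distance_um = d,
             size_class = ifelse(areas > area_threshold_um2, "large", "small"))
}

#' Allocate nuclei to organoid core or periphery by the rim rule
#'
#' Computes the per-pixel Euclidean distance to the organoid boundary inside
#' each organoid; a nucleus is allocated to the periphery iff its centroid
#' lies within \code{rim_width_px} of the boundary, and to the core
#' otherwise. Nuclei outside any organoid are skipped with a warning.
#'
#' @param organoid_mask a \linkS4class{LabelImage} of organoids.
#' @param nuclei a \linkS4class{LabelImage} of nuclei.
#' @param rim_width_px rim width in pixels (> 0; default 100).
#' @return data.frame with columns \code{nucleus_id, organoid_id, zone,
#'   boundary_distance_px}.
#' @export
assignCorePeriphery <- function(organoid_mask, nuclei, rim_width_px = 100) {
  if (rim_width_px <= 0) stop("rim_width_px must be positive")
  olab <- labelMatrix(organoid_mask)
  nlab <- labelMatrix(nuclei)
  if (!all(dim(olab) == dim(nlab))) stop("mask shape mismatch")
  dist_px <- EBImage::distmap(olab > 0L)
  cen <- labelCentroidsUm(nlab, 1)  # pixel units
  if (!nrow(cen))
    return(data.frame(nucleus_id = integer(0), organoid_id = integer(0),
                      zone = character(0), boundary_distance_px = numeric(0)))
  i <- pmin(pmax(round(cen$y_um + 0.5), 1L), nrow(olab))
  j <- pmin(pmax(round(cen$x_um + 0.5), 1L), ncol(olab))
  idx <- cbind(i, j)
  org <- olab[idx]
  bd <- dist_px[idx]
  out <- data.frame(nucleus_id = cen$label, organoid_id = org,
                    zone = ifelse(bd <= rim_width_px, "periphery", "core"),
                    boundary_distance_px = as.numeric(bd))
  outside <- out$organoid_id == 0L
  if (any(outside)) {
    warning(sum(outside), " nuclei outside any organoid were skipped")
    out <- out[!outside, , drop = FALSE]
  }
  out
}

#' Segment the total cell area from the tubulin channel
#'
#' Binary foreground = Otsu-thresholded, hole-filled tubulin signal; used as
#' the mask for texture scoring. Returns a single foreground label.
#'
#' @param image single-channel matrix.
#' @param pixel_size_um µm per pixel.
#' @param smooth_sigma Gaussian smoothing sigma (pixels).
#' @param flat_threshold for a perfectly flat frame (no contrast for Otsu):
#'   the whole frame is foreground when its value exceeds this, otherwise
#'   the mask is empty (default 0, so a zero frame is empty and a uniform
#'   positive signal is all foreground).
#' @return a \linkS4class{LabelImage} with a single foreground label (empty,
#'   with a warning, for a featureless image).
#' @export
segmentCellArea <- function(image, pixel_size_um, smooth_sigma = 2,
                            flat_threshold = 0) {
  if (diff(range(image)) < 1e-12) {
    if (image[1L] > flat_threshold) {
      return(labelImage(matrix(1L, nrow(image), ncol(image)), pixel_size_um,
                        "tubulin"))
    }
    warning("no foreground found: returning empty cell-area mask")
    return(labelImage(matrix(0L, nrow(image), ncol(image)), pixel_size_um,
                      "tubulin"))
  }
  sm <- if (smooth_sigma > 0) EBImage::gblur(image, sigma = smooth_sigma)
        else image
  nrm <- (sm - min(sm)) / diff(range(sm))
  bin <- nrm > EBImage::otsu(nrm, range = c(0, 1))
  bin <- EBImage::fillHull(bin)
  lab <- matrix(0L, nrow(image), ncol(image))
  lab[bin > 0] <- 1L
  labelImage(lab, pixel_size_um, "tubulin")
}

#' Estimate the image background level
#'
#' Median intensity of pixels outside the dilated foreground; when fewer
#' than 1% of pixels are background the 5th percentile of the whole image is
#' used instead (logged via \code{message}).
#'
#' @param image single-channel matrix.
#' @param foreground_mask logical matrix or \linkS4class{LabelImage} marking
#'   foreground; \code{NULL} treats everything as background.
#' @param dilate_px dilation radius (pixels) applied to the foreground
#'   before exclusion, to keep blurred signal tails out of the estimate.
#' @return scalar background level in counts.
#' @export
estimateBackground <- function(image, foreground_mask = NULL, dilate_px = 5) {
  fg <- if (is.null(foreground_mask)) {
    matrix(FALSE, nrow(image), ncol(image))
  } else if (is(foreground_mask, "LabelImage")) {
    labelMatrix(foreground_mask) > 0L
  } else {
    foreground_mask > 0
  }
  if (any(fg) && dilate_px > 0)
    fg <- EBImage::dilate(fg, EBImage::makeBrush(2L * as.integer(dilate_px) + 1L,
                                                 "disc")) > 0
  bg <- image[!fg]
  if (length(bg) < 0.01 * length(image)) {
    message("fewer than 1% background pixels: falling back to the 5th percentile")
    return(as.numeric(stats::quantile(image, 0.05)))
  }
  stats::median(bg)
}
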