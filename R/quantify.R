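# Per-cell relative nuclear translocation and Haralick-contrast texture
# scoring. The translocation statistic is
#   ratio = n / (n + c),  n = max(nuc - background, 0),
#                         c = max(cyt - background, 0)
# on background-corrected region *means*, so 0 is complete cytoplasmic and
# 1 complete nuclear localization regardless of region sizes.

#' Relative nuclear translocation ratio
#'
#' Background-corrected nuclear over total EGFP signal:
#' \code{n/(n + c)} with \code{n = max(nuc_raw - background, 0)} and
#' \code{c = max(cyt_raw - background, 0)}. Cells with no signal above
#' background (\code{n + c = 0}) are flagged invalid and return \code{NA}
#' rather than raising an error.
#'
#' @param nuc_raw,cyt_raw mean counts over the nuclear and perinuclear
#'   regions (vectorized).
#' @param background background level in counts (>= 0).
#' @return ratio in [0, 1]; \code{NA} for invalid cells.
#' @examples
#' translocationRatio(60, 40, background = 10)  # 50/(50 + 30) = 0.625
#' @export
translocationRatio <- function(nuc_raw, cyt_raw, background = 0) {
  stopifnot(all(is.finite(background)), all(background >= 0))
  n <- pmax(nuc_raw - background, 0)
  c <- pmax(cyt_raw - background, 0)
  tot <- n + c
  out <- ifelse(tot > 0, n / tot, NA_real_)
  out
}

#' Measure per-cell translocation from one frame
#'
#' For each nucleus label k, computes the mean EGFP over nucleus k and over
#' ring k, background-corrects both, and forms the translocation ratio.
#' Nuclei whose ring is empty, or with no signal above background, are
#' flagged invalid (\code{valid = FALSE}, ratio \code{NA}). Ratios are
#' clipped to [0, 1]; clip events are counted in
#' \code{attr(result, "n_clipped")}.
#'
#' @param egfp_image EGFP channel matrix (counts).
#' @param nuclei,rings \linkS4class{LabelImage}s from the same frame, with
#'   matching labels.
#' @param background background counts (scalar).
#' @param frame_time_h,well_id annotations carried into the records.
#' @param nucleus_erosion_px erode each nucleus by this radius before
#'   averaging, keeping point-spread-function mixing at the nuclear
#'   boundary out of the nuclear mean (labels whose erosion would be empty
#'   keep their full support); default 0.
#' @return data.frame with one row per nucleus: \code{cell_id, well_id,
#'   time_h, nuc_mean, cyt_mean, ratio, valid, x_um, y_um}.
#' @export
measureCells <- function(egfp_image, nuclei, rings, background = 0,
                         frame_time_h = NA_real_, well_id = NA_character_,
                         nucleus_erosion_px = 0) {
  nlab <- labelMatrix(nuclei)
  rlab <- labelMatrix(rings)
  if (nucleus_erosion_px > 0 && max(nlab) > 0L) {
    er <- EBImage::erode(nlab > 0L,
                         EBImage::makeBrush(2L * as.integer(nucleus_erosion_px) + 1L,
                                            "disc"))
    nlab_er <- nlab
    nlab_er[!(er > 0)] <- 0L
    lost <- setdiff(unique(nlab[nlab > 0L]), unique(nlab_er[nlab_er > 0L]))
    for (k in lost) nlab_er[nlab == k] <- k
    meas_nlab <- nlab_er
  } else meas_nlab <- nlab
  if (!all(dim(nlab) == dim(egfp_image)) || !all(dim(rlab) == dim(egfp_image)))
    stop("mask shape mismatch")
  k <- max(nlab)
  if (k == 0L) {
    out <- data.frame(cell_id = integer(0), well_id = character(0),
                      time_h = numeric(0), nuc_mean = numeric(0),
                      cyt_mean = numeric(0), ratio = numeric(0),
                      valid = logical(0), x_um = numeric(0),
                      y_um = numeric(0))
    attr(out, "n_clipped") <- 0L
    return(out)
  }
  nuc_raw <- labelMeans(egfp_image, meas_nlab)
  cyt_raw <- labelMeans(egfp_image, rlab)
  if (length(cyt_raw) < k) cyt_raw <- c(cyt_raw, rep(NA_real_, k - length(cyt_raw)))
  cen <- labelCentroidsUm(nlab, pixelSize(nuclei))
  nuc_mean <- pmax(nuc_raw - background, 0)
  cyt_mean <- pmax(cyt_raw - background, 0)
  ratio <- translocationRatio(nuc_raw, cyt_raw, background)
  valid <- !is.na(ratio) & !is.na(cyt_raw)
  ratio[!valid] <- NA_real_
  n_clipped <- sum(ratio < 0 | ratio > 1, na.rm = TRUE)
  ratio <- pmin(pmax(ratio, 0), 1)
  out <- data.frame(cell_id = seq_len(k), well_id = well_id,
                    time_h = frame_time_h, nuc_mean = nuc_mean,
                    cyt_mean = cyt_mean, ratio = ratio, valid = valid,
                    x_um = NA_real_, y_um = NA_real_)
  out$x_um[cen$label] <- cen$x_um
  out$y_um[cen$label] <- cen$y_um
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Measure per-cell translocation across a time-lapse stack
#'
#' Applies \code{\link{measureCells}} to every frame of a static scene,
#' re-using one set of nucleus/ring masks (cells neither move nor divide in
#' the supported experiments).
#'
#' @param egfp_stack array (height, width, n_frames).
#' @param nuclei,rings \linkS4class{LabelImage}s shared by all frames.
#' @param times_h frame times (h), one per frame.
#' @param background background counts (scalar or one per frame).
#' @param well_id annotation carried into the records.
#' @param nucleus_erosion_px see \code{\link{measureCells}}.
#' @return row-bound data.frame of per-frame \code{\link{measureCells}}
#'   records.
#' @export
measureStack <- function(egfp_stack, nuclei, rings, times_h, background = 0,
                         well_id = NA_character_, nucleus_erosion_px = 0) {
  nt <- dim(egfp_stack)[3L]
  stopifnot(length(times_h) == nt)
  background <- rep_len(background, nt)
  do.call(rbind, lapply(seq_len(nt), function(it) {
    measureCells(egfp_stack[, , it], nuclei, rings, background[it],
                 frame_time_h = times_h[it], well_id = well_id,
                 nucleus_erosion_px = nucleus_erosion_px)
  }))
}

# ---------------------------------------------------------------------------
# Gray-level co-occurrence and Haralick contrast

#' Default GLCM offsets: 4 directions at distance 1
#'
#' @return list of (dy, dx) offsets: horizontal, vertical and both
#'   diagonals.
#' @export
glcmOffsets <- function() list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

#' Compute a normalized gray-level co-occurrence matrix
#'
#' Intensities within the mask are linearly quantized to
#' \code{0..levels - 1} over a fixed range (\code{range}; defaults to the
#' min/max of the masked pixels — pass an explicit range for comparability
#' across a time series). Pairs (p, p + offset) with both pixels in the
#' mask are counted over all offsets, symmetrized and normalized.
#'
#' @param image single-channel matrix.
#' @param mask logical matrix or \linkS4class{LabelImage}; \code{NULL} uses
#'   the whole frame.
#' @param levels number of gray levels (>= 2, default 32).
#' @param offsets list of (dy, dx) integer offsets.
#' @param range length-2 numeric quantization range; values outside are
#'   clamped to the extreme levels.
#' @return a \linkS4class{GLCMatrix}.
#' @examples
#' img <- matrix(rep(c(0, 1), length.out = 16), 4, 4)  # checkerboard-ish
#' g <- computeGLCM(img, levels = 2, offsets = list(c(0L, 1L)))
#' haralickContrast(g)
#' @export
computeGLCM <- function(image, mask = NULL, levels = 32L,
                        offsets = glcmOffsets(), range = NULL) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  if (!length(offsets)) stop("offsets must be non-empty")
  msk <- if (is.null(mask)) matrix(TRUE, nrow(image), ncol(image))
         else if (is(mask, "LabelImage")) labelMatrix(mask) > 0L
         else mask > 0
  if (!all(dim(msk) == dim(image))) stop("mask shape mismatch")
  vals <- image[msk]
  if (is.null(range)) range <- if (length(vals)) base::range(vals) else c(0, 1)
  lo <- range[1L]; hi <- range[2L]
  q <- if (hi > lo) {
    pmin(pmax(floor((image - lo) / (hi - lo) * levels), 0), levels - 1L)
  } else matrix(0, nrow(image), ncol(image))
  storage.mode(q) <- "integer"
  h <- nrow(image); w <- ncol(image)
  counts <- matrix(0, levels, levels)
  total_pairs <- 0L
  for (off in offsets) {
    dy <- off[1L]; dx <- off[2L]
    ri <- seq_len(h - abs(dy)); ci <- seq_len(w - abs(dx))
    r1 <- if (dy >= 0) ri else ri + abs(dy)
    c1 <- if (dx >= 0) ci else ci + abs(dx)
    r2 <- r1 + dy; c2 <- c1 + dx
    m1 <- msk[r1, c1, drop = FALSE] & msk[r2, c2, drop = FALSE]
    if (!any(m1)) next
    i1 <- q[r1, c1, drop = FALSE][m1]
    i2 <- q[r2, c2, drop = FALSE][m1]
    tab <- tabulate(i1 * levels + i2 + 1L, nbins = levels * levels)
    counts <- counts + matrix(tab, levels, levels, byrow = TRUE)
    total_pairs <- total_pairs + sum(m1)
  }
  if (total_pairs < 1L)
    stop("mask admits no pixel pairs for the given offsets")
  sym <- counts + t(counts)
  new("GLCMatrix", matrix = sym / sum(sym), levels = levels,
      offsets = offsets)
}

#' Haralick contrast of a co-occurrence matrix
#'
#' \eqn{\sum_{i,j} P(i, j) (i - j)^2}: zero for an image constant within
#' the mask along all offsets, large for high-frequency fibrous textures
#' such as bundled microtubules.
#'
#' @param glcm a \linkS4class{GLCMatrix}.
#' @return non-negative contrast value.
#' @export
haralickContrast <- function(glcm) {
  stopifnot(is(glcm, "GLCMatrix"))
  idx <- seq_len(glcm@levels) - 1L
  d2 <- outer(idx, idx, function(i, j) (i - j)^2)
  sum(glcm@matrix * d2)
}

#' Haralick-contrast time-course of a tubulin stack
#'
#' One contrast score per frame, computed over the per-frame (or shared)
#' cell-area mask with a fixed quantization range (default: global min/max
#' of the masked pixels across all frames, so contrast changes reflect
#' texture rather than rescaling). With \code{detrend = TRUE} and an
#' untreated-control trajectory supplied, the control's fitted drift
#' (photobleaching) is removed from the scores: multiplicatively from a
#' log-linear fit (\code{detrend_method = "ratio"}, default — bleaching
#' scales intensities and hence contrast), or subtractively from a linear
#' fit (\code{"linear"}).
#'
#' @param stack array (height, width, n_frames).
#' @param masks a single mask (logical matrix or \linkS4class{LabelImage})
#'   shared by all frames, or a list with one mask per frame.
#' @param times_h frame times (h).
#' @param levels,offsets,range see \code{\link{computeGLCM}}.
#' @param control_scores optional numeric vector: contrast trajectory of an
#'   untreated control well at the same times.
#' @param detrend remove the control's fitted drift (default \code{FALSE}).
#' @param detrend_method \code{"ratio"} (default) or \code{"linear"}.
#' @return data.frame with columns \code{time_h, contrast, n_pixels}.
#' @export
contrastTimecourse <- function(stack, masks, times_h, levels = 32L,
                               offsets = glcmOffsets(), range = NULL,
                               control_scores = NULL, detrend = FALSE,
                               detrend_method = c("ratio", "linear")) {
  detrend_method <- match.arg(detrend_method)
  nt <- dim(stack)[3L]
  if (length(times_h) != nt) stop("frame/time count mismatch")
  mask_list <- if (is.list(masks)) masks else rep(list(masks), nt)
  if (length(mask_list) != nt) stop("frame/mask count mismatch")
  as_bin <- function(m) if (is(m, "LabelImage")) labelMatrix(m) > 0L else m > 0
  mask_list <- lapply(mask_list, as_bin)
  if (is.null(range)) {
    vals <- unlist(lapply(seq_len(nt), function(it) {
      base::range(stack[, , it][mask_list[[it]]])
    }))
    range <- base::range(vals)
  }
  contrast <- vapply(seq_len(nt), function(it) {
    haralickContrast(computeGLCM(stack[, , it], mask_list[[it]],
                                 levels = levels, offsets = offsets,
                                 range = range))
  }, numeric(1))
  npx <- vapply(mask_list, sum, numeric(1))
  if (detrend) {
    if (is.null(control_scores) || length(control_scores) != nt)
      stop("detrending requires control_scores of one value per frame")
    if (detrend_method == "ratio") {
      fit <- stats::lm(log(pmax(control_scores, 1e-12)) ~ times_h)
      contrast <- contrast / exp(stats::fitted(fit) - stats::fitted(fit)[1L])
    } else {
      fit <- stats::lm(control_scores ~ times_h)
      contrast <- contrast - (stats::fitted(fit) - stats::fitted(fit)[1L])
    }
  }
  data.frame(time_h = times_h, contrast = contrast, n_pixels = npx)
}
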