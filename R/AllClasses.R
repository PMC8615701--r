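#' @import methods
NULL

# ---------------------------------------------------------------------------
# ImagingConfig

#' Imaging configuration for the synthetic microscope
#'
#' Describes the virtual camera and optics used by all renderers: frame size,
#' physical pixel size, bit depth, mean background level of cell-free pixels,
#' Gaussian read-noise standard deviation and the Gaussian PSF sigma applied
#' after rendering.
#'
#' @slot width_px,height_px frame dimensions in pixels.
#' @slot pixel_size_um physical pixel size in micrometres per pixel.
#' @slot bit_depth camera bit depth; intensities live in [0, 2^bit_depth).
#' @slot background_level mean counts of cell-free background.
#' @slot noise_sd Gaussian read-noise standard deviation in counts.
#' @slot psf_sigma_px Gaussian blur sigma (pixels) applied after rendering.
#' @export
setClass("ImagingConfig",
  representation(width_px = "integer", height_px = "integer",
                 pixel_size_um = "numeric", bit_depth = "integer",
                 background_level = "numeric", noise_sd = "numeric",
                 psf_sigma_px = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@width_px <= 0L || object@height_px <= 0L)
      msg <- c(msg, "width_px and height_px must be positive")
    if (object@pixel_size_um <= 0)
      msg <- c(msg, "pixel_size_um must be positive")
    if (object@background_level < 0 ||
        object@background_level >= 2^object@bit_depth)
      msg <- c(msg, "background_level must lie in [0, 2^bit_depth)")
    if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
    if (object@psf_sigma_px < 0) msg <- c(msg, "psf_sigma_px must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct an ImagingConfig
#'
#' @param width_px,height_px frame dimensions in pixels.
#' @param pixel_size_um micrometres per pixel.
#' @param bit_depth camera bit depth (default 16).
#' @param background_level mean background counts.
#' @param noise_sd Gaussian read-noise sd in counts.
#' @param psf_sigma_px PSF Gaussian sigma in pixels.
#' @return an \linkS4class{ImagingConfig}.
#' @examples
#' imagingConfig(width_px = 256, height_px = 256, pixel_size_um = 0.6)
#' @export
imagingConfig <- function(width_px = 512L, height_px = 512L,
                          pixel_size_um = 0.6, bit_depth = 16L,
                          background_level = 100, noise_sd = 5,
                          psf_sigma_px = 1) {
  new("ImagingConfig", width_px = as.integer(width_px),
      height_px = as.integer(height_px), pixel_size_um = pixel_size_um,
      bit_depth = as.integer(bit_depth), background_level = background_level,
      noise_sd = noise_sd, psf_sigma_px = psf_sigma_px)
}

setMethod("show", "ImagingConfig", function(object) {
  cat(sprintf(
    "ImagingConfig: %d x %d px, %.3g um/px, %d-bit, bg %.3g, noise sd %.3g, psf %.3g px\n",
    object@width_px, object@height_px, object@pixel_size_um,
    object@bit_depth, object@background_level, object@noise_sd,
    object@psf_sigma_px))
})

# ---------------------------------------------------------------------------
# KineticModel

#' Lagged logistic kinetic model for a drug-response readout
#'
#' Response over time follows
#' \deqn{f(t) = baseline + (plateau - baseline) \cdot
#'   logistic((t - lag - t_{50}) / slope)}
#' clipped to [0, 1], with \eqn{f(t \le 0) = baseline} (the pre-treatment
#' frame). The true half-transition time of the readout is
#' \code{lag_h + t50_h}.
#'
#' @slot baseline response before drug addition.
#' @slot plateau asymptotic response.
#' @slot t50_h time (h) at half-transition, measured after the lag.
#' @slot slope_h logistic steepness (h).
#' @slot lag_h additive delay (h) before the transition starts.
#' @export
setClass("KineticModel",
  representation(baseline = "numeric", plateau = "numeric", t50_h = "numeric",
                 slope_h = "numeric", lag_h = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@slope_h <= 0) msg <- c(msg, "slope_h must be > 0")
    if (object@lag_h < 0) msg <- c(msg, "lag_h must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a KineticModel
#'
#' @param baseline,plateau response levels before drug and at the asymptote.
#' @param t50_h half-transition time (h) after the lag.
#' @param slope_h logistic steepness (h).
#' @param lag_h additive delay (h).
#' @return a \linkS4class{KineticModel}.
#' @examples
#' m <- kineticModel(baseline = 0.2, plateau = 0.9, t50_h = 1.5, lag_h = 1)
#' trueHalfTime(m)
#' @export
kineticModel <- function(baseline = 0.2, plateau = 0.9, t50_h = 1.5,
                         slope_h = 0.3, lag_h = 0) {
  new("KineticModel", baseline = baseline, plateau = plateau, t50_h = t50_h,
      slope_h = slope_h, lag_h = lag_h)
}

setMethod("show", "KineticModel", function(object) {
  cat(sprintf(
    "KineticModel: baseline %.3g -> plateau %.3g, t50 %.3g h, slope %.3g h, lag %.3g h (true t1/2 %.3g h)\n",
    object@baseline, object@plateau, object@t50_h, object@slope_h,
    object@lag_h, object@lag_h + object@t50_h))
})

#' True half-transition time of a kinetic model
#'
#' @param model a \linkS4class{KineticModel}.
#' @return \code{lag_h + t50_h}, the time at which the programmed response
#'   reaches half of its transition.
#' @export
trueHalfTime <- function(model) model@lag_h + model@t50_h

# ---------------------------------------------------------------------------
# LabelImage

#' Integer-labelled segmentation mask
#'
#' A raster of non-negative integer labels (0 = background, k > 0 = object k)
#' sharing shape and pixel size with its source image.
#'
#' @slot labels integer matrix of object labels.
#' @slot pixel_size_um physical pixel size (µm/pixel).
#' @slot channel_of_origin tag naming the source channel.
#' @export
setClass("LabelImage",
  representation(labels = "matrix", pixel_size_um = "numeric",
                 channel_of_origin = "character"),
  validity = function(object) {
    msg <- character(0)
    if (any(object@labels < 0)) msg <- c(msg, "labels must be non-negative")
    if (any(object@labels != round(object@labels)))
      msg <- c(msg, "labels must be integers")
    if (object@pixel_size_um <= 0)
      msg <- c(msg, "pixel_size_um must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct a LabelImage
#'
#' @param labels integer matrix, 0 = background.
#' @param pixel_size_um µm per pixel.
#' @param channel_of_origin tag for the source channel.
#' @return a \linkS4class{LabelImage}.
#' @export
labelImage <- function(labels, pixel_size_um, channel_of_origin = "unknown") {
  storage.mode(labels) <- "integer"
  new("LabelImage", labels = labels, pixel_size_um = pixel_size_um,
      channel_of_origin = channel_of_origin)
}

#' @rdname labelImage
#' @param x a \linkS4class{LabelImage}.
#' @export
labelMatrix <- function(x) x@labels

#' @rdname labelImage
#' @export
nObjects <- function(x) max(0L, max(x@labels))

#' Physical pixel size accessor
#'
#' @param x an object carrying a pixel size.
#' @return pixel size in µm/pixel.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "LabelImage", function(x) x@pixel_size_um)

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "ImagingConfig", function(x) x@pixel_size_um)

setMethod("show", "LabelImage", function(object) {
  cat(sprintf("LabelImage: %d x %d px (%.3g um/px), %d objects, channel '%s'\n",
              nrow(object@labels), ncol(object@labels), object@pixel_size_um,
              nObjects(object), object@channel_of_origin))
})

# ---------------------------------------------------------------------------
# GLCMatrix

#' Normalized gray-level co-occurrence matrix
#'
#' Symmetric joint distribution P(i, j) of quantized intensity levels of
#' pixel pairs at fixed offsets, summed over offsets and normalized to 1.
#'
#' @slot matrix levels x levels matrix of co-occurrence probabilities.
#' @slot levels number of gray levels.
#' @slot offsets list of (dy, dx) integer offsets used.
#' @export
setClass("GLCMatrix",
  representation(matrix = "matrix", levels = "integer", offsets = "list"),
  validity = function(object) {
    msg <- character(0)
    if (any(object@matrix < 0)) msg <- c(msg, "entries must be >= 0")
    if (abs(sum(object@matrix) - 1) > 1e-9)
      msg <- c(msg, "entries must sum to 1")
    if (max(abs(object@matrix - t(object@matrix))) > 1e-12)
      msg <- c(msg, "matrix must be symmetric")
    if (!all(dim(object@matrix) == object@levels))
      msg <- c(msg, "matrix must be levels x levels")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "GLCMatrix", function(object) {
  cat(sprintf("GLCMatrix: %d levels, %d offsets, contrast %.4g\n",
              object@levels, length(object@offsets),
              haralickContrast(object)))
})

# ---------------------------------------------------------------------------
# SigmoidFit

#' Fitted sigmoidal time-course
#'
#' Least-squares fit of
#' \eqn{v(t) = baseline + (plateau - baseline) / (1 + e^{-(t - t_{50})/slope})}.
#' \code{status} is one of \code{"ok"}, \code{"not attained"} (the observed
#' series does not reach its plateau so no half-transition time is reported)
#' or \code{"not converged"}.
#'
#' @slot baseline,plateau,t50_h,slope_h fitted parameters.
#' @slot converged did the optimizer converge.
#' @slot plateau_reached does the observed series reach its fitted plateau.
#' @slot rss residual sum of squares.
#' @slot n_points number of observations.
#' @slot status character summary (see above).
#' @export
setClass("SigmoidFit",
  representation(baseline = "numeric", plateau = "numeric", t50_h = "numeric",
                 slope_h = "numeric", converged = "logical",
                 plateau_reached = "logical", rss = "numeric",
                 n_points = "integer", status = "character"))

#' Half-transition time of a fitted time-course
#'
#' @param fit a \linkS4class{SigmoidFit}.
#' @return the fitted t50 in hours, or \code{NA} when the fit did not
#'   converge or the plateau was not attained within the observed window.
#' @export
tHalf <- function(fit) {
  stopifnot(is(fit, "SigmoidFit"))
  if (fit@converged && fit@plateau_reached) fit@t50_h else NA_real_
}

setMethod("show", "SigmoidFit", function(object) {
  t50txt <- if (object@converged && object@plateau_reached)
    sprintf("%.3g h", object@t50_h) else object@status
  cat(sprintf(
    "SigmoidFit (%s): t1/2 = %s; baseline %.3g, plateau %.3g, slope %.3g h, rss %.3g (n=%d)\n",
    object@status, t50txt, object@baseline, object@plateau, object@slope_h,
    object@rss, object@n_points))
})

# ---------------------------------------------------------------------------
# FourPLFit

#' Fitted four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \eqn{r(d) = bottom + (top - bottom) / (1 + (d/EC_{50})^{hill})}.
#'
#' @slot top,bottom,ec50,hill fitted parameters.
#' @slot rss residual sum of squares.
#' @slot ci95_ec50 95% bootstrap confidence interval for EC50 (NA when the
#'   bootstrap was not requested).
#' @slot converged did the optimizer converge.
#' @slot no_dose_dependence TRUE when the Hill slope is not distinguishable
#'   from 0 (fit returned with a warning flag).
#' @slot n_points number of observations.
#' @export
setClass("FourPLFit",
  representation(top = "numeric", bottom = "numeric", ec50 = "numeric",
                 hill = "numeric", rss = "numeric", ci95_ec50 = "numeric",
                 converged = "logical", no_dose_dependence = "logical",
                 n_points = "integer"),
  validity = function(object) {
    if (object@converged && (!is.finite(object@ec50) || object@ec50 <= 0))
      "ec50 must be positive for a converged fit" else TRUE
  })

#' EC50 accessor
#'
#' @param fit a \linkS4class{FourPLFit}.
#' @return the fitted EC50 (same units as the doses).
#' @export
ec50 <- function(fit) {
  stopifnot(is(fit, "FourPLFit"))
  fit@ec50
}

setMethod("show", "FourPLFit", function(object) {
  cat(sprintf(
    "FourPLFit: top %.3g, bottom %.3g, EC50 %.3g [%.3g, %.3g], hill %.3g, rss %.3g (n=%d)%s\n",
    object@top, object@bottom, object@ec50, object@ci95_ec50[1L],
    object@ci95_ec50[2L], object@hill, object@rss, object@n_points,
    if (object@no_dose_dependence) " [warning: no dose dependence]" else ""))
})

# ---------------------------------------------------------------------------
# DomeLayout

#' Layout of organoids within a hemispherical scaffold dome
#'
#' Positions are physical coordinates (µm) relative to the well; every
#' organoid must lie within \code{dome_radius_um} of the dome centre. The
#' \code{lag_fun} maps radial distance from the dome centre (µm) to the
#' kinetic lag (h) programmed for organoids at that distance, emulating
#' diffusion-limited drug availability deeper in the dome.
#'
#' @slot center_xy_um dome centre (x, y) in µm.
#' @slot dome_radius_um dome radius in µm.
#' @slot organoids data.frame with columns \code{organoid_id, x_um, y_um,
#'   n_cells, radius_um}.
#' @slot lag_fun function(distance_um) -> lag_h, defined on
#'   [0, dome_radius_um].
#' @export
setClass("DomeLayout",
  representation(center_xy_um = "numeric", dome_radius_um = "numeric",
                 organoids = "data.frame", lag_fun = "function"),
  validity = function(object) {
    msg <- character(0)
    org <- object@organoids
    need <- c("organoid_id", "x_um", "y_um", "n_cells", "radius_um")
    if (!all(need %in% names(org)))
      return(paste("organoids must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(org$organoid_id))
      msg <- c(msg, "organoid ids must be unique")
    d <- sqrt((org$x_um - object@center_xy_um[1L])^2 +
              (org$y_um - object@center_xy_um[2L])^2)
    if (any(d > object@dome_radius_um))
      msg <- c(msg, "every organoid must lie within the dome radius")
    if (object@dome_radius_um <= 0)
      msg <- c(msg, "dome_radius_um must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct a DomeLayout
#'
#' @param center_xy_um dome centre (x, y) in µm.
#' @param dome_radius_um dome radius in µm.
#' @param organoids data.frame with columns \code{organoid_id, x_um, y_um,
#'   n_cells, radius_um}.
#' @param lag_fun function mapping distance from the dome centre (µm) to the
#'   programmed kinetic lag (h). The default, no position effect, is a
#'   constant 0.
#' @return a \linkS4class{DomeLayout}.
#' @export
domeLayout <- function(center_xy_um, dome_radius_um, organoids,
                       lag_fun = function(d) rep(0, length(d))) {
  new("DomeLayout", center_xy_um = center_xy_um,
      dome_radius_um = dome_radius_um, organoids = organoids,
      lag_fun = lag_fun)
}

setMethod("show", "DomeLayout", function(object) {
  cat(sprintf("DomeLayout: %d organoids in a %.0f um dome centred at (%.0f, %.0f) um\n",
              nrow(object@organoids), object@dome_radius_um,
              object@center_xy_um[1L], object@center_xy_um[2L]))
})

# ---------------------------------------------------------------------------
# BinningScheme

#' Radial binning scheme for organoid positions
#'
#' Half-open bins \eqn{[k w, (k+1) w)} of width \code{bin_width_um} on the
#' radial distance from \code{center_xy_um}; distances at or beyond
#' \code{n_bins * bin_width_um} are out of range. Bin indices are 0-based.
#'
#' @slot center_xy_um reference centre (x, y) in µm.
#' @slot bin_width_um bin width in µm (default 250).
#' @slot n_bins number of bins (default 9).
#' @export
setClass("BinningScheme",
  representation(center_xy_um = "numeric", bin_width_um = "numeric",
                 n_bins = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@bin_width_um <= 0) msg <- c(msg, "bin_width_um must be > 0")
    if (object@n_bins < 1L) msg <- c(msg, "n_bins must be >= 1")
    if (length(object@center_xy_um) != 2L)
      msg <- c(msg, "center_xy_um must have length 2")
    if (length(msg)) msg else TRUE
  })

#' Construct a BinningScheme
#'
#' @param center_xy_um reference centre (x, y) in µm.
#' @param bin_width_um bin width in µm.
#' @param n_bins number of bins.
#' @return a \linkS4class{BinningScheme}.
#' @examples
#' binningScheme(center_xy_um = c(0, 0))
#' @export
binningScheme <- function(center_xy_um = c(0, 0), bin_width_um = 250,
                          n_bins = 9L) {
  new("BinningScheme", center_xy_um = center_xy_um,
      bin_width_um = bin_width_um, n_bins = as.integer(n_bins))
}

setMethod("show", "BinningScheme", function(object) {
  cat(sprintf("BinningScheme: %d bins of %.0f um around (%.0f, %.0f) um\n",
              object@n_bins, object@bin_width_um, object@center_xy_um[1L],
              object@center_xy_um[2L]))
})
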