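# Radial-distance computation, 9-bin grouping of organoids within the
# scaffold dome, and per-bin / per-zone aggregation of translocation
# time-courses. Cells inherit their organoid's distance: binning is per
# organoid, applied to its cells.

#' Radial distance from a reference centre
#'
#' Euclidean distance \eqn{\sqrt{x^2 + y^2}} of positions relative to the
#' centre.
#'
#' @param position_xy_um numeric vector (x, y) or a two-column matrix of
#'   positions in µm.
#' @param center_xy_um reference centre (x, y) in µm.
#' @return numeric distance(s) in µm.
#' @examples
#' radialDistance(c(300, 400), c(0, 0))  # 500
#' @export
radialDistance <- function(position_xy_um, center_xy_um = c(0, 0)) {
  p <- if (is.matrix(position_xy_um)) position_xy_um
       else matrix(position_xy_um, ncol = 2L)
  sqrt((p[, 1L] - center_xy_um[1L])^2 + (p[, 2L] - center_xy_um[2L])^2)
}

#' Assign radial distances to bins
#'
#' Half-open bins \eqn{[k w, (k+1) w)}: index = \code{floor(distance/width)}
#' (0-based). Distances at or beyond \code{n_bins * width} are out of range
#' and return \code{NA} (count reported via \code{message}).
#'
#' @param distance_um non-negative distances in µm.
#' @param scheme a \linkS4class{BinningScheme}.
#' @return integer bin indices (0-based) with \code{NA} for out-of-range
#'   distances.
#' @export
assignBin <- function(distance_um, scheme) {
  stopifnot(all(distance_um >= 0, na.rm = TRUE))
  idx <- floor(distance_um / scheme@bin_width_um)
  oor <- !is.na(idx) & idx >= scheme@n_bins
  if (any(oor))
    message(sum(oor), " distances beyond the binning range were excluded")
  idx[oor] <- NA_integer_
  as.integer(idx)
}

#' Per-bin mean translocation time-courses
#'
#' Unweighted mean of cell ratios per (bin, time); empty (bin, time) cells
#' are omitted. Cells must carry their organoid's radial distance
#' (\code{distance_um}), a frame time (\code{time_h}) and a \code{ratio};
#' invalid cells (\code{valid == FALSE} or \code{NA} ratio) are dropped.
#'
#' @param cells data.frame of per-cell records across frames.
#' @param scheme a \linkS4class{BinningScheme}.
#' @return data.frame with columns \code{bin_index, time_h, mean_ratio,
#'   n_cells}, ordered by bin then time.
#' @export
binTimecourses <- function(cells, scheme) {
  need <- c("distance_um", "time_h", "ratio")
  if (!all(need %in% names(cells)))
    stop("cells must have columns: ", paste(need, collapse = ", "))
  keep <- !is.na(cells$ratio)
  if ("valid" %in% names(cells)) keep <- keep & cells$valid
  cells <- cells[keep, , drop = FALSE]
  cells$bin_index <- assignBin(cells$distance_um, scheme)
  cells <- cells[!is.na(cells$bin_index), , drop = FALSE]
  if (!nrow(cells)) stop("no cells fall in any bin")
  agg <- stats::aggregate(ratio ~ bin_index + time_h, data = cells,
                          FUN = mean)
  n <- stats::aggregate(ratio ~ bin_index + time_h, data = cells,
                        FUN = length)
  out <- data.frame(bin_index = agg$bin_index, time_h = agg$time_h,
                    mean_ratio = agg$ratio, n_cells = n$ratio)
  out[order(out$bin_index, out$time_h), , drop = FALSE]
}

#' Core and periphery mean time-courses per organoid size class
#'
#' Mean cell ratio per (size class, zone, time). With
#' \code{normalize = TRUE} each (size class, zone) curve is min-max
#' normalized to [0, 1], allowing direct comparison of translocation
#' dynamics between the dimmer organoid core and the brighter periphery.
#'
#' @param cells data.frame with columns \code{zone}, \code{size_class},
#'   \code{time_h}, \code{ratio} (plus optional \code{valid}).
#' @param normalize min-max normalize each curve (default \code{FALSE}).
#' @return data.frame with columns \code{size_class, zone, time_h,
#'   mean_ratio, n_cells}.
#' @export
zoneTimecourses <- function(cells, normalize = FALSE) {
  need <- c("zone", "size_class", "time_h", "ratio")
  if (!all(need %in% names(cells)))
    stop("cells must have columns: ", paste(need, collapse = ", "))
  if (any(is.na(cells$zone))) stop("zone missing for some cells")
  keep <- !is.na(cells$ratio)
  if ("valid" %in% names(cells)) keep <- keep & cells$valid
  cells <- cells[keep, , drop = FALSE]
  if (!nrow(cells)) stop("no valid cells")
  agg <- stats::aggregate(ratio ~ size_class + zone + time_h, data = cells,
                          FUN = mean)
  n <- stats::aggregate(ratio ~ size_class + zone + time_h, data = cells,
                        FUN = length)
  out <- data.frame(size_class = agg$size_class, zone = agg$zone,
                    time_h = agg$time_h, mean_ratio = agg$ratio,
                    n_cells = n$ratio)
  out <- out[order(out$size_class, out$zone, out$time_h), , drop = FALSE]
  if (normalize) {
    key <- paste(out$size_class, out$zone)
    for (k in unique(key)) {
      sel <- key == k
      v <- out$mean_ratio[sel]
      r <- range(v)
      out$mean_ratio[sel] <- if (diff(r) > 0) (v - r[1L]) / diff(r) else 0
    }
  }
  out
}

#' Fit half-transition times to grouped mean curves
#'
#' Convenience wrapper: fits \code{\link{fitSigmoidTime}} to the mean-ratio
#' curve of each group (e.g. each bin or each zone) and collects the
#' half-transition times.
#'
#' @param curves data.frame with a time column, a value column and one or
#'   more grouping columns.
#' @param group_cols names of the grouping columns.
#' @param time_col,value_col column names (defaults \code{time_h},
#'   \code{mean_ratio}).
#' @return data.frame of the grouping columns plus \code{t50_h} (NA when
#'   not attained or not converged) and \code{status}.
#' @export
fitGroupedT50 <- function(curves, group_cols, time_col = "time_h",
                          value_col = "mean_ratio") {
  key <- do.call(paste, c(curves[group_cols], sep = "\r"))
  res <- lapply(unique(key), function(k) {
    sub <- curves[key == k, , drop = FALSE]
    sub <- sub[order(sub[[time_col]]), , drop = FALSE]
    fit <- fitSigmoidTime(sub[[time_col]], sub[[value_col]])
    cbind(sub[1L, group_cols, drop = FALSE],
          data.frame(t50_h = tHalf(fit), status = fit@status))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
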