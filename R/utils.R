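# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# global .Random.seed is restored afterwards so no global state leaks.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a base seed, kept below .Machine$integer.max.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 9973) %% 2147483587)
}

# Add `value` to the pixels of an annulus (r_in < d <= r_out) centred at the
# continuous pixel coordinate (x, y); x runs along columns, y along rows, and
# the centre of pixel [i, j] is at (j - 0.5, i - 0.5). r_in <= 0 gives a disk.
addAnnulus <- function(img, x, y, r_in, r_out, value) {
  h <- nrow(img); w <- ncol(img)
  j0 <- max(1L, floor(x - r_out)); j1 <- min(w, ceiling(x + r_out) + 1L)
  i0 <- max(1L, floor(y - r_out)); i1 <- min(h, ceiling(y + r_out) + 1L)
  if (j0 > j1 || i0 > i1) return(img)
  ii <- i0:i1; jj <- j0:j1
  d2 <- outer((ii - 0.5 - y)^2, (jj - 0.5 - x)^2, "+")
  sel <- d2 <= r_out^2 & d2 > r_in^2
  if (any(sel)) {
    sub <- img[ii, jj, drop = FALSE]
    sub[sel] <- sub[sel] + value
    img[ii, jj] <- sub
  }
  img
}

# Pixel count of the digital disk of radius r centred at (x, y), clipped to
# an image of dimensions dim = c(nrow, ncol).
diskPixelCount <- function(dim, x, y, r_in, r_out) {
  h <- dim[1L]; w <- dim[2L]
  j0 <- max(1L, floor(x - r_out)); j1 <- min(w, ceiling(x + r_out) + 1L)
  i0 <- max(1L, floor(y - r_out)); i1 <- min(h, ceiling(y + r_out) + 1L)
  if (j0 > j1 || i0 > i1) return(0L)
  d2 <- outer(((i0:i1) - 0.5 - y)^2, ((j0:j1) - 0.5 - x)^2, "+")
  sum(d2 <= r_out^2 & d2 > r_in^2)
}

# Rejection-sample n points inside a disk (radius R around (cx, cy)) with
# pairwise minimum separation; an optional accept(px, py) predicate vetoes
# candidate positions. Stops with an informative error if the packing is
# infeasible within max_tries draws.
samplePackedDisk <- function(n, cx, cy, R, min_sep, max_tries = 5000L,
                             accept = NULL) {
  xs <- numeric(0); ys <- numeric(0); tries <- 0L
  while (length(xs) < n && tries < max_tries) {
    tries <- tries + 1L
    r <- R * sqrt(stats::runif(1)); a <- stats::runif(1, 0, 2 * pi)
    px <- cx + r * cos(a); py <- cy + r * sin(a)
    if (!is.null(accept) && !accept(px, py)) next
    if (length(xs) == 0L || all((xs - px)^2 + (ys - py)^2 >= min_sep^2)) {
      xs <- c(xs, px); ys <- c(ys, py)
    }
  }
  if (length(xs) < n)
    stop("could not place ", n, " points with separation ", min_sep,
         " inside radius ", R)
  cbind(x = xs, y = ys)
}

# Per-label mean of image values; labels is an integer matrix with 0 =
# background. Returns a named vector over 1..max(labels) (NA where a label
# has no pixels).
labelMeans <- function(image, labels) {
  k <- max(labels)
  if (k == 0L) return(numeric(0))
  sel <- labels > 0L
  s <- rowsum(as.numeric(image[sel]), group = labels[sel])
  cnt <- tabulate(labels[sel], nbins = k)
  out <- rep(NA_real_, k)
  out[as.integer(rownames(s))] <- s[, 1L]
  ifelse(cnt > 0L, out / cnt, NA_real_)
}

# Centroids of labelled objects in physical units (µm); pixel [i, j] centre
# maps to ((j - 0.5) * px, (i - 0.5) * px).
labelCentroidsUm <- function(labels, pixel_size_um) {
  k <- max(labels)
  if (k == 0L)
    return(data.frame(label = integer(0), x_um = numeric(0), y_um = numeric(0)))
  sel <- labels > 0L
  idx <- which(sel, arr.ind = TRUE)
  lab <- labels[sel]
  cnt <- tabulate(lab, nbins = k)
  sx <- rep(0, k); sy <- rep(0, k)
  sx_part <- rowsum(idx[, 2L] - 0.5, lab)
  sy_part <- rowsum(idx[, 1L] - 0.5, lab)
  sx[as.integer(rownames(sx_part))] <- sx_part[, 1L]
  sy[as.integer(rownames(sy_part))] <- sy_part[, 1L]
  keep <- which(cnt > 0L)
  data.frame(label = keep,
             x_um = sx[keep] / cnt[keep] * pixel_size_um,
             y_um = sy[keep] / cnt[keep] * pixel_size_um)
}
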