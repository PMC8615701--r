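# Independent oracles and small fixture builders used across the suite.

# Exhaustive pair-enumeration gray-level co-occurrence oracle: a direct
# double loop over all pixels and offsets, independent of computeGLCM's
# vectorized implementation.
oracle_glcm <- function(img, mask = NULL, levels = 8L,
                        offsets = list(c(0L, 1L)), range = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  vals <- img[mask]
  if (is.null(range)) range <- base::range(vals)
  lo <- range[1]; hi <- range[2]
  q <- if (hi > lo) {
    pmin(pmax(floor((img - lo) / (hi - lo) * levels), 0), levels - 1)
  } else matrix(0, nrow(img), ncol(img))
  P <- matrix(0, levels, levels)
  for (off in offsets) {
    for (i in seq_len(nrow(img))) {
      for (j in seq_len(ncol(img))) {
        i2 <- i + off[1]; j2 <- j + off[2]
        if (i2 >= 1 && i2 <= nrow(img) && j2 >= 1 && j2 <= ncol(img) &&
            mask[i, j] && mask[i2, j2]) {
          a <- q[i, j] + 1; b <- q[i2, j2] + 1
          P[a, b] <- P[a, b] + 1
        }
      }
    }
  }
  P <- P + t(P)
  P / sum(P)
}

oracle_contrast <- function(P) {
  idx <- seq_len(nrow(P)) - 1
  sum(P * outer(idx, idx, function(a, b) (a - b)^2))
}

# Noisy realization of a programmed translocation curve (ratio scale).
simulate_ratio_curve <- function(kin, times_h, noise_sd = 0.02, seed = 1L) {
  set.seed(seed)
  pmin(pmax(nuclearFractionAt(kin, times_h) +
              rnorm(length(times_h), 0, noise_sd), 0), 1)
}

# A small noise-free imaging configuration for fast rendering tests.
tiny_config <- function(side = 160L, noise_sd = 0, ...) {
  imagingConfig(width_px = side, height_px = side, noise_sd = noise_sd, ...)
}

# Binary disk mask (logical) of radius r centred at (cx, cy).
disk_mask <- function(side, cx, cy, r) {
  ii <- matrix(seq_len(side), side, side)
  jj <- t(ii)
  (ii - 0.5 - cy)^2 + (jj - 0.5 - cx)^2 <= r^2
}

# Match measured cells to ground-truth cells by nearest centroid.
match_cells <- function(measured, truth) {
  vapply(seq_len(nrow(measured)), function(k) {
    which.min((truth$x_um - measured$x_um[k])^2 +
                (truth$y_um - measured$y_um[k])^2)
  }, integer(1))
}
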