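# Sigmoidal time-course fitting (half-transition times), Welch t-tests with
# Bonferroni correction, four-parameter logistic dose-response fitting and
# the extra-sum-of-squares F test for curve differences. Nonlinear least
# squares go through minpack.lm::nlsLM (Levenberg-Marquardt with bounds).

#' Fit a sigmoidal time-course and extract the half-transition time
#'
#' Least-squares fit of
#' \eqn{v(t) = baseline + (plateau - baseline)/(1 + e^{-(t - t_{50})/slope})}.
#' The half-transition time is reported only when the observed series
#' reaches its plateau: the last observation must lie at or above 90% of
#' the fitted transition and the fitted plateau must fall within the
#' observed value range extended by 20% of its span. Otherwise the fit is
#' returned with status \code{"not attained"} (mirroring treatment
#' conditions whose response does not saturate within the imaging window)
#' and \code{\link{tHalf}} returns \code{NA}. Flat series (spread below
#' \code{flat_tol}) return status \code{"not converged"}.
#'
#' @param times_h strictly increasing times (h), at least 5 points.
#' @param values observed responses.
#' @param flat_tol minimal value spread treated as a real transition.
#' @param rise_frac,range_frac thresholds of the plateau-reached rule
#'   (defaults 0.9 and 0.2).
#' @return a \linkS4class{SigmoidFit}.
#' @examples
#' t <- seq(0, 8, by = 0.5)
#' v <- 0.2 + 0.7 * plogis((t - 3) / 0.4)
#' tHalf(fitSigmoidTime(t, v))
#' @export
fitSigmoidTime <- function(times_h, values, flat_tol = 1e-3,
                           rise_frac = 0.9, range_frac = 0.2) {
  if (length(times_h) < 5L) stop("need at least 5 time points")
  if (any(diff(times_h) <= 0)) stop("times_h must be strictly increasing")
  if (length(values) != length(times_h)) stop("length mismatch")
  n <- length(values)
  rng <- diff(range(values))
  failed <- function(status) {
    new("SigmoidFit", baseline = min(values), plateau = max(values),
        t50_h = NA_real_, slope_h = NA_real_, converged = FALSE,
        plateau_reached = FALSE, rss = NA_real_, n_points = n,
        status = status)
  }
  if (rng < flat_tol) return(failed("not converged"))
  lo <- min(values); hi <- max(values)
  mid <- (lo + hi) / 2
  above <- which(values >= mid)
  t50_0 <- if (length(above)) times_h[above[1L]] else stats::median(times_h)
  span <- diff(range(times_h))
  start <- list(b = lo, p = hi, t50 = t50_0, s = span / 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      values ~ b + (p - b) / (1 + exp(-(times_h - t50) / s)),
      start = start,
      lower = c(b = lo - rng, p = lo, t50 = min(times_h) - 2 * span,
                s = span / 1e4),
      upper = c(b = hi, p = hi + 10 * rng, t50 = max(times_h) + 2 * span,
                s = 2 * span),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed("not converged"))
  cf <- stats::coef(fit)
  trans <- cf[["p"]] - cf[["b"]]
  # plateau reached: the last observed value sits high on the fitted
  # transition, the fitted plateau is consistent with the observed range,
  # and the window extends past the time at which the fitted curve itself
  # reaches the rise threshold (the last condition is noise-immune: a
  # lucky last value cannot fake saturation the fitted times deny)
  plateau_reached <-
    (values[n] >= cf[["b"]] + rise_frac * trans) &&
    (cf[["p"]] <= hi + range_frac * rng) &&
    (cf[["p"]] >= lo - range_frac * rng) &&
    (times_h[n] >= cf[["t50"]] + stats::qlogis(rise_frac) * cf[["s"]])
  new("SigmoidFit", baseline = cf[["b"]], plateau = cf[["p"]],
      t50_h = cf[["t50"]], slope_h = cf[["s"]], converged = TRUE,
      plateau_reached = plateau_reached,
      rss = sum(stats::resid(fit)^2), n_points = n,
      status = if (plateau_reached) "ok" else "not attained")
}

#' Pairwise comparison of half-transition times across groups
#'
#' Welch unpaired two-tailed t-tests between every pair of groups, with
#' Bonferroni correction over \code{m_tests} comparisons (default: the
#' number of pairs performed). The replication unit is the independent
#' experiment: average technical-replicate t50s per experiment before
#' calling this.
#'
#' @param groups named list of numeric vectors of per-experiment
#'   half-transition times; every group needs at least 2 replicates.
#' @param m_tests number of tests for the Bonferroni correction.
#' @return data.frame with one row per pair: \code{group1, group2,
#'   statistic, df, raw_p, adjusted_p, m_tests}.
#' @export
compareTHalf <- function(groups, m_tests = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) stop("every group needs at least 2 replicates")
  pairs <- utils::combn(names(groups), 2L)
  m <- if (is.null(m_tests)) ncol(pairs) else m_tests
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- groups[[pairs[1L, k]]]; b <- groups[[pairs[2L, k]]]
    if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12) {
      # degenerate: both groups constant
      equal <- isTRUE(all.equal(mean(a), mean(b)))
      stat <- if (equal) 0 else Inf
      p <- if (equal) 1 else 0
      df <- length(a) + length(b) - 2
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE,
                          alternative = "two.sided")
      stat <- unname(tt$statistic); p <- tt$p.value
      df <- unname(tt$parameter)
    }
    data.frame(group1 = pairs[1L, k], group2 = pairs[2L, k],
               statistic = stat, df = df, raw_p = p,
               adjusted_p = min(1, m * p), m_tests = m)
  })
  do.call(rbind, res)
}

# 4PL in the (top, bottom, log ec50, hill) parametrization used by the
# optimizer; d = 0 returns top (vehicle limit for hill > 0).
.f4pl <- function(d, top, bottom, lec50, hill) {
  term <- ifelse(d > 0, exp(hill * (log(d) - lec50)), 0)
  bottom + (top - bottom) / (1 + term)
}

# Weights for relative (constant-CV) error: 1 / fitted^2, floored at 5% of
# the curve maximum so near-zero responses cannot dominate.
.relWeights <- function(mu) 1 / pmax(mu, 0.05 * max(mu))^2

# One 4PL least-squares fit with optional iteratively reweighted least
# squares for relative errors. Returns NULL on failure, else the fit, its
# coefficients and the final weights.
.fit4plCore <- function(d, r, weighting = "relative", n_irls = 2L,
                        fixed_weights = NULL) {
  lo <- min(r); hi <- max(r); rng <- max(hi - lo, 1e-12)
  pos <- unique(d[d > 0])
  start <- list(top = hi, bottom = lo,
                lec50 = stats::median(log(pos)), hill = 1)
  w <- fixed_weights %||% rep(1, length(d))
  n_rounds <- if (!is.null(fixed_weights) || weighting == "none") 0L
              else n_irls
  one <- function(start, w) {
    tryCatch(
      minpack.lm::nlsLM(r ~ .f4pl(d, top, bottom, lec50, hill),
                        start = start, weights = w,
                        lower = c(top = lo - rng, bottom = lo - rng,
                                  lec50 = min(log(pos)) - 7, hill = -20),
                        upper = c(top = hi + rng, bottom = hi + rng,
                                  lec50 = max(log(pos)) + 7, hill = 20),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- one(start, w)
  if (is.null(fit)) {
    # exactly-noiseless data can yield a spuriously singular gradient in
    # the optimizer; a deterministic perturbation far below data scale
    # restores a well-posed problem without affecting the estimates
    r <- r + rng * 1e-9 * sin(seq_along(r))
    fit <- one(start, w)
  }
  if (is.null(fit)) return(NULL)
  for (k in seq_len(n_rounds)) {
    cf <- as.list(stats::coef(fit))
    w <- .relWeights(.f4pl(d, cf$top, cf$bottom, cf$lec50, cf$hill))
    fit2 <- one(cf, w)
    if (is.null(fit2)) break
    fit <- fit2
  }
  cf <- stats::coef(fit)
  list(fit = fit, coef = cf, weights = w,
       rss = sum(stats::resid(fit)^2),
       wrss = sum(w * stats::resid(fit)^2))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \eqn{r(d) = bottom + (top - bottom)/(1 + (d/EC_{50})^{hill})} to
#' vehicle-normalized responses; EC50 is fitted on the log scale. Vehicle
#' wells (dose 0) participate as the \eqn{d \to 0} limit. Luminescence
#' viability errors scale with the signal, so the default fit is
#' iteratively reweighted least squares with \eqn{1/\hat{r}^2} weights
#' (constant coefficient of variation); \code{weighting = "none"} gives
#' ordinary least squares. The EC50 confidence interval is a nonparametric
#' bootstrap (wells resampled within dose levels). When the Hill slope is
#' not distinguishable from 0 the fit is returned with the
#' \code{no_dose_dependence} warning flag set.
#'
#' @param doses dose vector (>= 0; at least 4 distinct positive doses).
#' @param responses vehicle-normalized responses (same length).
#' @param n_boot bootstrap resamples for the EC50 CI (default 1000; 0
#'   skips the bootstrap).
#' @param seed seed for the bootstrap.
#' @param weighting \code{"relative"} (default) or \code{"none"}.
#' @return a \linkS4class{FourPLFit}.
#' @export
fit4PL <- function(doses, responses, n_boot = 1000L, seed = 1L,
                   weighting = c("relative", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(length(doses) == length(responses))
  if (any(doses < 0)) stop("doses must be >= 0")
  pos <- unique(doses[doses > 0])
  if (length(pos) < 4L) stop("need at least 4 distinct positive doses")
  res <- .fit4plCore(doses, responses, weighting)
  if (is.null(res)) {
    return(new("FourPLFit", top = NA_real_, bottom = NA_real_,
               ec50 = NA_real_, hill = NA_real_, rss = NA_real_,
               ci95_ec50 = c(NA_real_, NA_real_), converged = FALSE,
               no_dose_dependence = TRUE, n_points = length(doses)))
  }
  cf <- res$coef
  se <- tryCatch(sqrt(diag(stats::vcov(res$fit)))[["hill"]],
                 error = function(e) Inf)
  no_dep <- !is.finite(se) || abs(cf[["hill"]]) < 1.96 * se
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    strata <- split(seq_along(doses), doses)
    boots <- withSeed(seed, vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(strata, function(ix)
        ix[sample.int(length(ix), replace = TRUE)]), use.names = FALSE)
      bf <- .fit4plCore(doses[idx], responses[idx], weighting)
      if (is.null(bf)) NA_real_ else exp(bf$coef[["lec50"]])
    }, numeric(1)))
    ci <- unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }
  new("FourPLFit", top = cf[["top"]], bottom = cf[["bottom"]],
      ec50 = exp(cf[["lec50"]]), hill = cf[["hill"]],
      rss = res$rss, ci95_ec50 = ci, converged = TRUE,
      no_dose_dependence = no_dep, n_points = length(doses))
}

# Shared model for two vehicle-normalized datasets: common log EC50 and
# Hill slope; per-dataset top and bottom absorb the plate-specific
# normalization scale (a nuisance introduced by dividing each plate by its
# own noisy vehicle mean).
.f4plShared <- function(d, g, topA, botA, topB, botB, lec50, hill) {
  term <- ifelse(d > 0, exp(hill * (log(d) - lec50)), 0)
  top <- ifelse(g == 1, topA, topB)
  bot <- ifelse(g == 1, botA, botB)
  bot + (top - bot) / (1 + term)
}

#' Extra-sum-of-squares F test for a difference between dose-response curves
#'
#' Nested-model F test between "one potency for both datasets" and
#' "separate 4PLs per dataset". With \code{scale_nuisance = TRUE} (default)
#' the shared model shares EC50 and Hill slope but keeps per-dataset top
#' and bottom, so plate-specific normalization scale (each plate is divided
#' by its own noisy vehicle mean) is treated as a nuisance and the test is
#' calibrated for potency shifts; with \code{FALSE} all four parameters are
#' shared. The test uses ordinary (unweighted) residuals by default — the
#' classical extra-sum-of-squares setting; estimated variance weights add
#' sampling noise to the F statistic — while \code{weighting = "relative"}
#' fixes constant-CV weights from the separate fits across both models.
#'
#' @param dataA,dataB data.frames with columns \code{dose} and a response
#'   column (\code{response_pct} preferred, else \code{response}); both
#'   vehicle-normalized.
#' @param scale_nuisance share only (EC50, Hill) in the null model
#'   (default \code{TRUE}).
#' @param weighting \code{"relative"} (default) or \code{"none"}.
#' @return list with \code{F}, \code{df} (numerator, denominator),
#'   \code{p}, and the underlying \linkS4class{FourPLFit}s.
#' @export
compareDoseCurves <- function(dataA, dataB, scale_nuisance = TRUE,
                              weighting = c("none", "relative")) {
  weighting <- match.arg(weighting)
  pick <- function(d) {
    col <- if ("response_pct" %in% names(d)) "response_pct" else "response"
    list(dose = d$dose, resp = d[[col]])
  }
  a <- pick(dataA); b <- pick(dataB)
  coreA <- .fit4plCore(a$dose, a$resp, weighting)
  coreB <- .fit4plCore(b$dose, b$resp, weighting)
  if (is.null(coreA) || is.null(coreB))
    stop("separate fits did not converge")
  # fix the weights from the separate fits for both nested models
  w <- c(coreA$weights, coreB$weights)
  d <- c(a$dose, b$dose); r <- c(a$resp, b$resp)
  g <- rep(1:2, c(length(a$dose), length(b$dose)))
  sepA <- .fit4plCore(a$dose, a$resp, fixed_weights = coreA$weights)
  sepB <- .fit4plCore(b$dose, b$resp, fixed_weights = coreB$weights)
  if (is.null(sepA) || is.null(sepB))
    stop("separate fits did not converge")
  pos <- d[d > 0]
  shared <- if (scale_nuisance) {
    start <- list(topA = max(a$resp), botA = min(a$resp),
                  topB = max(b$resp), botB = min(b$resp),
                  lec50 = stats::median(log(pos)), hill = 1)
    tryCatch(minpack.lm::nlsLM(
      r ~ .f4plShared(d, g, topA, botA, topB, botB, lec50, hill),
      start = start, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  } else {
    fs <- .fit4plCore(d, r, fixed_weights = w)
    if (is.null(fs)) NULL else fs$fit
  }
  if (is.null(shared)) stop("shared fit did not converge")
  rss_sep <- sepA$wrss + sepB$wrss
  wrss_shared <- sum(w * stats::resid(shared)^2)
  n <- length(d)
  df1 <- if (scale_nuisance) 2L else 4L
  df2 <- n - 8L
  Fstat <- max(0, ((wrss_shared - rss_sep) / df1) / (rss_sep / df2))
  mkfit <- function(core, npts) {
    cf <- core$coef
    new("FourPLFit", top = cf[["top"]], bottom = cf[["bottom"]],
        ec50 = exp(cf[["lec50"]]), hill = cf[["hill"]], rss = core$rss,
        ci95_ec50 = c(NA_real_, NA_real_), converged = TRUE,
        no_dose_dependence = FALSE, n_points = npts)
  }
  list(F = Fstat, df = c(df1, df2),
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       fitA = mkfit(coreA, length(a$dose)), fitB = mkfit(coreB, length(b$dose)),
       fitShared = shared)
}
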