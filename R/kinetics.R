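# Kitz-Wilson analysis of irreversible inhibition.
#
# Mechanism: E + I <->(Ki) EI ->(k2) EI', with [I] >> [E], so the loss of
# active enzyme is pseudo-first-order, ln[E] = -k' t + ln[E0], and
# k' = k2 [I] / (Ki + [I]).  Linearized: 1/k' = (Ki/k2)(1/[I]) + 1/k2.
# Concentrations are entered in uM; Ki is reported in mM (the customary
# scale for these constants), k2 in 1/min.

# coefficient of determination without summary.lm's near-perfect-fit warning
rsq <- function(y, yhat) {
  ss <- sum((y - mean(y))^2)
  if (ss == 0) return(1)
  max(0, 1 - sum((y - yhat)^2) / ss)
}

#' Construct an inactivation time series
#'
#' @param conc_uM inhibitor concentration in uM (single positive number).
#' @param time_min time points in minutes (non-negative, increasing).
#' @param activity residual activity as fraction of initial, in (0, 1].
#' @return object of class `opb_series`.
#' @export
inactivation_series <- function(conc_uM, time_min, activity) {
  if (length(conc_uM) != 1 || conc_uM <= 0) stop("[I] must be a single positive value")
  if (is.unsorted(time_min, strictly = TRUE) || any(time_min < 0))
    stop("time points must be non-negative and increasing")
  if (length(activity) != length(time_min))
    stop("activity and time lengths differ")
  if (any(activity > 1 + 1e-9))
    stop("activities above 1: residual activity is a fraction of initial")
  structure(list(conc_uM = conc_uM, time_min = as.numeric(time_min),
                 activity = as.numeric(activity)),
            class = "opb_series")
}

#' Pseudo-first-order inactivation constant
#'
#' Ordinary least squares of ln(activity) on time; `k_prime` is minus the
#' slope.  A non-positive slope estimate is flagged `no_inactivation`.
#'
#' @param series an [inactivation_series()] (or data.frame with columns
#'   `time_min` and `activity`).
#' @return list with `k_prime` (1/min), `r_squared`, `conc_uM`, `flags`.
#' @export
fit_pseudo_first_order <- function(series) {
  if (is.data.frame(series))
    series <- inactivation_series(series$conc_uM[1], series$time_min,
                                  series$activity)
  if (length(series$time_min) < 3) stop("need at least 3 time points")
  if (any(series$activity <= 0))
    stop("non-positive activity: log-linear fit undefined")
  fit <- lm(log(series$activity) ~ series$time_min)
  kp <- -unname(coef(fit)[2])
  r2 <- rsq(log(series$activity), fitted(fit))
  flags <- if (kp <= 0) "no_inactivation" else character(0)
  list(k_prime = max(kp, 0), r_squared = r2, conc_uM = series$conc_uM,
       flags = flags)
}

#' Kitz-Wilson double-reciprocal fit
#'
#' OLS of `1/k'` on `1/[I]`; `k_2` is the inverse intercept and `K_i` is
#' slope times `k_2`.  The direct nonlinear fit of
#' `k' = k2 [I] / (Ki + [I])` is also run as a cross-check and reported
#' alongside (it is not the headline estimator).
#'
#' @param pairs data.frame with columns `conc_uM` and `k_prime` (all
#'   positive; at least 3 distinct concentrations).
#' @return object of class `opb_kinetics` with `Ki_mM`, `k2_per_min`,
#'   `intercept`, `slope`, `r_squared`, `nls_Ki_mM`, `nls_k2_per_min`,
#'   `flags`.
#' @export
fit_kitz_wilson <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (length(unique(pairs$conc_uM)) < 3)
    stop("need at least 3 distinct inhibitor concentrations")
  if (any(pairs$k_prime <= 0))
    stop("all k' must be positive for the reciprocal fit")
  x <- 1 / pairs$conc_uM
  y <- 1 / pairs$k_prime
  fit <- lm(y ~ x)
  intercept <- unname(coef(fit)[1]); slope <- unname(coef(fit)[2])
  if (intercept <= 0)
    stop("saturation not identifiable: non-positive reciprocal intercept")
  k2 <- 1 / intercept
  Ki_uM <- slope * k2
  flags <- character(0)
  # a (near-)zero or negative slope means no measurable concentration
  # dependence of 1/k': Ki degenerates to 0
  if (slope * max(x) <= 1e-9 * intercept) {
    flags <- "degenerate_slope"
    Ki_uM <- max(Ki_uM, 0)
  }
  r2 <- rsq(y, fitted(fit))
  nls_fit <- tryCatch({
    # scaleOffset makes the fit well-posed on noiseless data
    nf <- nls(k_prime ~ k2n * conc_uM / (Kin + conc_uM), data = pairs,
              start = list(k2n = k2, Kin = max(Ki_uM, 1)),
              control = stats::nls.control(scaleOffset = 1))
    coef(nf)
  }, error = function(e) c(k2n = NA_real_, Kin = NA_real_))
  structure(list(
    per_series = pairs,
    Ki_mM = Ki_uM / 1000, k2_per_min = k2,
    intercept = intercept, slope = slope, r_squared = r2,
    nls_Ki_mM = unname(nls_fit["Kin"]) / 1000,
    nls_k2_per_min = unname(nls_fit["k2n"]),
    flags = flags), class = "opb_kinetics")
}

#' @export
print.opb_kinetics <- function(x, ...) {
  cat(sprintf("<opb_kinetics> Ki = %.3g mM, k2 = %.3g min^-1 (reciprocal R^2 %.4f)\n",
              x$Ki_mM, x$k2_per_min, x$r_squared))
  if (is.finite(x$nls_Ki_mM))
    cat(sprintf("  nonlinear cross-check: Ki = %.3g mM, k2 = %.3g min^-1\n",
                x$nls_Ki_mM, x$nls_k2_per_min))
  invisible(x)
}

#' Full inactivation analysis
#'
#' Fits every series' pseudo-first-order constant, then the Kitz-Wilson
#' reciprocal line.
#'
#' @param series_list list of [inactivation_series()], or a long data.frame
#'   with columns `conc_uM`, `time_min`, `activity_frac` (one row per
#'   measurement, as read from CSV).
#' @return `opb_kinetics` object; `per_series` gains `r_squared` per series.
#' @export
fit_inactivation <- function(series_list) {
  if (is.data.frame(series_list)) {
    df <- series_list
    series_list <- lapply(split(df, df$conc_uM), function(s)
      inactivation_series(s$conc_uM[1], s$time_min, s$activity_frac))
  }
  fits <- lapply(series_list, fit_pseudo_first_order)
  pairs <- data.frame(
    conc_uM = vapply(fits, `[[`, numeric(1), "conc_uM"),
    k_prime = vapply(fits, `[[`, numeric(1), "k_prime"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"))
  out <- fit_kitz_wilson(pairs)
  out$per_series <- pairs
  out
}

#' Simulate pseudo-first-order inactivation curves
#'
#' Activity decays as `exp(-k' t)` with `k' = k2 [I] / (Ki + [I])`;
#' multiplicative lognormal noise of the given fractional standard deviation
#' is applied when `noise_sd > 0` (values are capped at 1, activities being
#' fractions of initial).
#'
#' @param Ki_mM dissociation constant of the enzyme-inhibitor complex (mM).
#' @param k2_per_min alkylation rate constant (1/min).
#' @param concentrations_uM inhibitor concentrations (uM).
#' @param times_min time points (min).
#' @param noise_sd fractional noise SD (0 = noiseless).
#' @param seed RNG seed (used only if `noise_sd > 0`).
#' @return list of [inactivation_series()], one per concentration, with the
#'   planted `k_prime` of each stored in `attr(, "truth")`.
#' @export
simulate_inactivation <- function(Ki_mM, k2_per_min,
                                  concentrations_uM = c(50, 100, 150, 200, 260),
                                  times_min = seq(0, 20, by = 2),
                                  noise_sd = 0, seed = NULL) {
  stopifnot(Ki_mM > 0, k2_per_min > 0, all(concentrations_uM > 0))
  if (!is.null(seed)) set.seed(seed)
  Ki_uM <- Ki_mM * 1000
  truth <- k2_per_min * concentrations_uM / (Ki_uM + concentrations_uM)
  out <- lapply(seq_along(concentrations_uM), function(i) {
    act <- exp(-truth[i] * times_min)
    if (noise_sd > 0)
      act <- pmin(1, act * exp(rnorm(length(act), 0, noise_sd)))
    inactivation_series(concentrations_uM[i], times_min, act)
  })
  attr(out, "truth") <- data.frame(conc_uM = concentrations_uM,
                                   k_prime = truth)
  out
}
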