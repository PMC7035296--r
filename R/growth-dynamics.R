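#' Fit an exponential growth law by log-linear least squares
#'
#' Fits `y = y0 * exp(alpha * t)` by ordinary least squares of `ln y` on
#' `t` inside a time window (the reference analysis uses 5 h to T1, the
#' moment the first apex reaches the panorama edge). Uncertainties are
#' reported as twice the standard error of the regression coefficients.
#'
#' @param t times, hours.
#' @param y positive measurements (counts or lengths).
#' @param window `c(t_min, t_max)`; points outside are ignored.
#' @return list with `alpha` (h^-1), `alpha_se2`, `prefactor`,
#'   `prefactor_se2`, `n` (points used), `window`.
#' @examples
#' t <- seq(5, 18, by = 0.5)
#' fitExponential(t, 3 * exp(0.341 * t))$alpha
#' @export
fitExponential <- function(t, y, window = c(5, Inf)) {
  stopifnot(length(t) == length(y), length(window) == 2)
  keep <- t >= window[1] & t <= window[2] & is.finite(y)
  if (any(keep & y <= 0)) {
    warning("dropping ", sum(keep & y <= 0), " non-positive value(s)")
    keep <- keep & y > 0
  }
  if (sum(keep) < 4)
    stop("need at least 4 positive points inside the fit window")
  fit <- lm(log(y[keep]) ~ t[keep])
  cf <- summary(fit)$coefficients
  list(alpha = unname(cf[2, 1]), alpha_se2 = unname(2 * cf[2, 2]),
       prefactor = exp(unname(cf[1, 1])),
       prefactor_se2 = exp(unname(cf[1, 1])) * unname(2 * cf[1, 2]),
       n = sum(keep), window = window)
}

#' Single-rate exponential fit over pooled experiments
#'
#' Pools the points of several series and fits one rate and one prefactor,
#' the prefactor box-constrained to an interval representing the known
#' initial condition (e.g. 3 +/- 1 apexes, 1.5 +/- 1 nodes). Profile least
#' squares: for each candidate rate the optimal log-prefactor is the
#' clamped mean of `ln y - alpha t`; the rate minimizing the profiled
#' residual sum of squares is returned. When the unconstrained optimum
#' lies inside the box the result equals the plain pooled fit.
#'
#' @param series list of `(t, y)` pairs: each element a list or data.frame
#'   with components `t` and `y`.
#' @param prefactor_bounds `c(lo, hi)`, both > 0; `c(0, Inf)` disables the
#'   constraint.
#' @param window fit window as in [fitExponential()].
#' @return list with `alpha`, `alpha_se2`, `prefactor`, `pinned` (logical:
#'   did the prefactor hit a bound), `n`.
#' @examples
#' s <- lapply(1:3, function(i) list(t = seq(5, 18, 0.5),
#'                                   y = 3 * exp(0.322 * seq(5, 18, 0.5))))
#' mergedFit(s, prefactor_bounds = c(2, 4))$alpha
#' @export
mergedFit <- function(series, prefactor_bounds = c(0, Inf),
                      window = c(5, Inf)) {
  stopifnot(length(series) >= 1, length(prefactor_bounds) == 2)
  if (prefactor_bounds[1] > prefactor_bounds[2] || prefactor_bounds[2] <= 0)
    stop("infeasible prefactor bounds")
  t <- unlist(lapply(series, function(s) s$t))
  y <- unlist(lapply(series, function(s) s$y))
  keep <- t >= window[1] & t <= window[2] & is.finite(y) & y > 0
  t <- t[keep]; y <- y[keep]
  if (length(t) < 4) stop("need at least 4 positive points inside the window")
  lo <- log(max(prefactor_bounds[1], .Machine$double.xmin))
  hi <- log(prefactor_bounds[2])
  ly <- log(y)
  profile_sse <- function(alpha) {
    c0 <- min(max(mean(ly - alpha * t), lo), hi)
    sum((ly - c0 - alpha * t)^2)
  }
  a0 <- unname(coef(lm(ly ~ t))[2])
  opt <- optimize(profile_sse, interval = a0 + c(-1, 1) * max(0.5, abs(a0)),
                  tol = 1e-10)
  alpha <- opt$minimum
  c0 <- min(max(mean(ly - alpha * t), lo), hi)
  pinned <- c0 <= lo + 1e-12 || c0 >= hi - 1e-12
  n <- length(t)
  if (pinned) {
    res <- ly - c0 - alpha * t
    se <- sqrt(sum(res^2) / (n - 1) / sum(t^2))
  } else {
    se <- summary(lm(ly ~ t))$coefficients[2, 2]
  }
  list(alpha = alpha, alpha_se2 = 2 * se, prefactor = exp(c0),
       pinned = pinned, n = n)
}

#' Decompose growth exponents into branching and anastomosis rates
#'
#' Every branching event adds one apex and one node; every anastomosis
#' removes one apex and adds one node. Hence the exponents of the node and
#' apex counts satisfy `alpha_N = alpha_b + alpha_a` and
#' `alpha_A = alpha_b - alpha_a`, giving `alpha_b = (alpha_N + alpha_A)/2`
#' and `alpha_a = (alpha_N - alpha_A)/2`.
#'
#' @param alpha_N node-count exponent, h^-1.
#' @param alpha_A apex-count exponent, h^-1.
#' @param se2_N,se2_A optional 2-sigma uncertainties, propagated in
#'   quadrature and halved.
#' @return list with `alpha_b`, `alpha_a` (h^-1) and, when uncertainties
#'   are supplied, `alpha_b_se2`, `alpha_a_se2`.
#' @examples
#' decomposeRates(0.426, 0.322)   # 0.374, 0.052
#' @export
decomposeRates <- function(alpha_N, alpha_A, se2_N = NA_real_,
                           se2_A = NA_real_) {
  if (alpha_N < alpha_A)
    warning("alpha_N < alpha_A implies a negative anastomosis rate")
  se2 <- if (is.finite(se2_N) && is.finite(se2_A))
    sqrt(se2_N^2 + se2_A^2) / 2 else NA_real_
  list(alpha_b = (alpha_N + alpha_A) / 2,
       alpha_a = (alpha_N - alpha_A) / 2,
       alpha_b_se2 = se2, alpha_a_se2 = se2)
}

#' Branching-to-anastomosis ratio from the node-vs-apex scaling exponent
#'
#' With `rho = alpha_N / alpha_A` (the log-log slope of node count against
#' apex count), the rate decomposition gives
#' `alpha_b / alpha_a = (rho + 1) / (rho - 1)`.
#'
#' @param rho scaling exponent, must exceed 1.
#' @return the ratio `alpha_b / alpha_a`.
#' @examples
#' branchingAnastomosisRatio(1.28)   # about 8.14
#' @export
branchingAnastomosisRatio <- function(rho) {
  stopifnot(rho > 1)
  (rho + 1) / (rho - 1)
}

#' Doubling time of an exponential quantity
#' @param alpha growth rate, h^-1 (> 0).
#' @return `ln 2 / alpha`, hours.
#' @examples
#' doublingTime(log(2))  # 1 hour
#' @export
doublingTime <- function(alpha) {
  stopifnot(all(alpha > 0))
  log(2) / alpha
}

#' Node-vs-apex scaling exponent
#'
#' Least-squares slope of `log Ng` against `log A`, restricted to an apex
#' range (the reference analysis pools three experiments over
#' `10 < A < 1000`).
#'
#' @param A apex counts.
#' @param Ng node counts.
#' @param range `c(A_min, A_max)`.
#' @return list with `slope`, `slope_se2`, `n`.
#' @examples
#' A <- round(10^seq(1, 3, 0.1)); scalingExponent(A, A^1.3)$slope
#' @export
scalingExponent <- function(A, Ng, range = c(10, 1000)) {
  stopifnot(length(A) == length(Ng))
  keep <- A > range[1] & A < range[2] & A > 0 & Ng > 0
  if (sum(keep) < 4) stop("need at least 4 in-range points")
  fit <- summary(lm(log(Ng[keep]) ~ log(A[keep])))$coefficients
  list(slope = unname(fit[2, 1]), slope_se2 = unname(2 * fit[2, 2]),
       n = sum(keep))
}

#' Linear densities of apexes and nodes along the network
#'
#' Element-wise `A/L` and `Ng/L` in mm^-1, plus the time of the interior
#' minimum of each density (the end of the lag phase in the reference
#' dynamics, where the density bottoms out around 0.5 mm^-1).
#'
#' @param series a [GrowthSeries-class] or a data.frame with columns
#'   `time_h`, `A`, `Ng`, `L_mm`.
#' @return data.frame with `time_h`, `density_A`, `density_Ng` and
#'   attributes `argmin_A`, `argmin_Ng` (times of the minima).
#' @export
linearDensities <- function(series) {
  tl <- if (is(series, "GrowthSeries")) tallies(series) else series
  stopifnot(all(c("time_h", "A", "Ng", "L_mm") %in% names(tl)))
  if (any(tl$L_mm <= 0)) stop("L must be > 0 on every frame")
  out <- data.frame(time_h = tl$time_h,
                    density_A = tl$A / tl$L_mm,
                    density_Ng = tl$Ng / tl$L_mm)
  attr(out, "argmin_A") <- tl$time_h[which.min(out$density_A)]
  attr(out, "argmin_Ng") <- tl$time_h[which.min(out$density_Ng)]
  out
}

#' Fit growth laws to a tally series and decompose the rates
#'
#' Convenience wrapper running [fitExponential()] on A, Ng (and N when
#' present) and L of one or more tally series, [scalingExponent()] on the
#' pooled points, and [decomposeRates()] on the apex and node exponents
#' (corrected N when available, geometrical Ng otherwise).
#'
#' @param series a [GrowthSeries-class] or list of them.
#' @param window fit window, hours; `NA` upper bound means each series'
#'   T1 (falling back to its last frame).
#' @param prefactor_bounds_A,prefactor_bounds_N boxes for the merged-fit
#'   prefactors.
#' @return a [RateEstimates-class].
#' @export
estimateRates <- function(series, window = c(5, NA),
                          prefactor_bounds_A = c(2, 4),
                          prefactor_bounds_N = c(0.5, 2.5)) {
  if (is(series, "GrowthSeries")) series <- list(series)
  stopifnot(all(vapply(series, is, TRUE, "GrowthSeries")))
  get_win <- function(s) {
    hi <- window[2]
    if (is.na(hi)) hi <- if (is.finite(s@T1)) s@T1 else max(tallies(s)$time_h)
    c(window[1], hi)
  }
  pool <- function(col) lapply(series, function(s) {
    tl <- tallies(s); w <- get_win(s)
    k <- tl$time_h >= w[1] & tl$time_h <= w[2]
    list(t = tl$time_h[k], y = tl[[col]][k])
  })
  has_N <- all(vapply(series, function(s) "N" %in% names(tallies(s)), TRUE))
  fa <- mergedFit(pool("A"), prefactor_bounds_A, window = c(-Inf, Inf))
  fn_g <- mergedFit(pool("Ng"), prefactor_bounds_N, window = c(-Inf, Inf))
  fl <- mergedFit(pool("L_mm"), c(0, Inf), window = c(-Inf, Inf))
  fn <- if (has_N) mergedFit(pool("N"), prefactor_bounds_N,
                             window = c(-Inf, Inf)) else fn_g
  if (!has_N)
    message("no corrected N column; using Ng exponent for the decomposition ",
            "(N is expected to be proportional to Ng)")
  rates <- data.frame(
    quantity = c("A", "Ng", if (has_N) "N", "L"),
    alpha = c(fa$alpha, fn_g$alpha, if (has_N) fn$alpha, fl$alpha),
    se2 = c(fa$alpha_se2, fn_g$alpha_se2, if (has_N) fn$alpha_se2,
            fl$alpha_se2),
    prefactor = c(fa$prefactor, fn_g$prefactor, if (has_N) fn$prefactor,
                  fl$prefactor),
    n_points = c(fa$n, fn_g$n, if (has_N) fn$n, fl$n))
  dec <- decomposeRates(fn$alpha, fa$alpha, fn$alpha_se2, fa$alpha_se2)
  allA <- unlist(lapply(pool("A"), `[[`, "y"))
  allNg <- unlist(lapply(pool("Ng"), `[[`, "y"))
  sc <- tryCatch(scalingExponent(allA, allNg)$slope, error = function(e) NA_real_)
  new("RateEstimates", rates = rates,
      alpha_b = dec$alpha_b, alpha_a = dec$alpha_a,
      alpha_b_se2 = dec$alpha_b_se2, alpha_a_se2 = dec$alpha_a_se2,
      scaling_exponent = sc,
      doubling_times = setNames(log(2) / rates$alpha, rates$quantity))
}
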