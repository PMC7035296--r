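test_that("log-linear fitting recovers exact exponentials", {
  t <- seq(5, 18.4, by = 0.3)
  f <- fitExponential(t, 3 * exp(0.341 * t), window = c(5, 18.4))
  expect_equal(f$alpha, 0.341, tolerance = 1e-10)
  expect_equal(f$prefactor, 3, tolerance = 1e-8)
  # constant series: zero rate
  expect_equal(fitExponential(t, rep(7, length(t)))$alpha, 0)
  # non-positive points dropped with a warning; too few points error
  expect_warning(fitExponential(1:10, c(-1, 2:10), window = c(1, 10)),
                 "non-positive")
  expect_error(fitExponential(1:3, exp(1:3), window = c(1, 3)),
               "at least 4")
})

test_that("two-sigma intervals cover the truth at the nominal rate", {
  set.seed(42)
  alpha_true <- 0.30
  hits <- vapply(1:400, function(i) {
    t <- seq(0, 12, length.out = 50)
    y <- 5 * exp(alpha_true * t) * exp(rnorm(50, 0, 0.05))
    f <- fitExponential(t, y, window = c(0, 12))
    abs(f$alpha - alpha_true) <= f$alpha_se2
  }, TRUE)
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.99)
})

test_that("merged fits pool series and honour prefactor boxes", {
  t <- seq(5, 18, 0.5)
  s <- lapply(1:3, function(i) list(t = t, y = 3 * exp(0.322 * t)))
  f <- mergedFit(s, prefactor_bounds = c(2, 4))
  expect_equal(f$alpha, fitExponential(t, 3 * exp(0.322 * t))$alpha,
               tolerance = 1e-6)
  expect_false(f$pinned)
  # noisy pooled recovery
  set.seed(5)
  sn <- lapply(1:3, function(i)
    list(t = t, y = 3 * exp(0.322 * t) * exp(rnorm(length(t), 0, 0.08))))
  fn <- mergedFit(sn, prefactor_bounds = c(2, 4))
  expect_lt(abs(fn$alpha - 0.322), 2 * fn$alpha_se2 + 0.01)
  # bounds excluding the truth pin the prefactor; grid-search oracle
  set.seed(7)
  y <- 10 * exp(0.3 * t) * exp(rnorm(length(t), 0, 0.05))
  fp <- mergedFit(list(list(t = t, y = y)), prefactor_bounds = c(2, 4))
  expect_true(fp$pinned)
  expect_equal(fp$prefactor, 4, tolerance = 1e-6)
  grid_a <- seq(0.25, 0.45, 5e-5)
  sse <- vapply(grid_a, function(a) {
    c0 <- min(max(mean(log(y) - a * t), log(2)), log(4))
    sum((log(y) - c0 - a * t)^2)
  }, 1)
  expect_lt(abs(fp$alpha - grid_a[which.min(sse)]), 1e-4)
  expect_error(mergedFit(list(list(t = t, y = y)),
                         prefactor_bounds = c(4, 2)), "infeasible")
})

test_that("rate decomposition matches the branching/anastomosis balance", {
  d <- decomposeRates(0.426, 0.322)
  expect_equal(d$alpha_b, 0.374)
  expect_equal(d$alpha_a, 0.052)
  expect_equal(decomposeRates(0.5, 0.3)[c("alpha_b", "alpha_a")],
               list(alpha_b = 0.4, alpha_a = 0.1))
  expect_equal(decomposeRates(0.3, 0.3)$alpha_a, 0)
  # involution: recompose recovers the inputs exactly
  expect_equal(d$alpha_b + d$alpha_a, 0.426)
  expect_equal(d$alpha_b - d$alpha_a, 0.322)
  expect_warning(decomposeRates(0.2, 0.3), "negative")
})

test_that("the scaling exponent maps to the rate ratio", {
  expect_equal(round(branchingAnastomosisRatio(1.28), 2), 8.14)
  expect_equal(branchingAnastomosisRatio(3), 2)
  expect_lt(branchingAnastomosisRatio(1e9), 1 + 1e-8)
  expect_error(branchingAnastomosisRatio(0.9))
})

test_that("doubling times follow ln2 over the rate", {
  expect_equal(doublingTime(log(2)), 1)
  expect_equal(round(doublingTime(mean(c(0.341, 0.333, 0.311))), 2), 2.11)
  expect_equal(round(doublingTime(mean(c(0.302, 0.305, 0.310))), 2), 2.27)
  f <- fitExponential(seq(0, 10, 0.5), 2 * exp(0.4 * seq(0, 10, 0.5)),
                      window = c(0, 10))
  expect_equal(doublingTime(f$alpha), log(2) / 0.4, tolerance = 1e-9)
})

test_that("node-vs-apex scaling slope is a restricted log-log fit", {
  A <- round(10^seq(1.05, 2.95, 0.1))
  expect_equal(scalingExponent(A, A^1.3)$slope, 1.3, tolerance = 1e-3)
  expect_equal(scalingExponent(A, 0.7 * A)$slope, 1, tolerance = 1e-9)
  set.seed(9)
  Ng <- rpois(length(A), 0.5 * A^1.28)
  s <- scalingExponent(A, Ng)
  expect_lt(abs(s$slope - 1.28), 2 * s$slope_se2 + 0.02)
})

test_that("linear densities locate the lag-phase minimum", {
  df <- data.frame(time_h = c(1, 2), A = c(10, 0), Ng = c(5, 0),
                   L_mm = c(20, 10))
  ld <- linearDensities(df)
  expect_equal(ld$density_A, c(0.5, 0))
  # A exponential from t=0, L exponential only after a 5 h lag:
  # the density has an interior minimum near the end of the lag
  t <- seq(0, 15, 0.25)
  A <- 3 * exp(0.33 * t)
  L <- ifelse(t < 5, 1 + 2 * t, 11 * exp(0.30 * (t - 5)))
  ld <- linearDensities(data.frame(time_h = t, A = A, Ng = A, L_mm = L))
  tmin <- attr(ld, "argmin_A")
  expect_gt(tmin, 1)
  expect_lt(tmin, 6)
  expect_error(linearDensities(data.frame(time_h = 1, A = 1, Ng = 1,
                                          L_mm = 0)), "L must be")
})

test_that("estimateRates closes the loop on birth-death ensembles", {
  p <- simParams(branch_rate = 0.37, anastomosis_rate = 0.05,
                 anastomosis_mode = "rate", duration = 16,
                 frame_interval = 0.5, seed = 21)
  ens <- simulateCounts(p, replicates = 40)
  keep <- which(!ens@extinct)[1:30]
  series <- lapply(keep, function(j) {
    tl <- data.frame(frame = seq_along(ens@time), time_h = ens@time,
                     A = ens@A[, j], Ng = ens@N[, j], N = ens@N[, j],
                     L_mm = NA_real_, sigma_A = sqrt(ens@A[, j]),
                     sigma_Ng = sqrt(ens@N[, j]), sigma_L = NA_real_)
    tl$L_mm <- 1 + cumsum(ens@A[, j]) * 0.09   # length proxy for the fit
    new("GrowthSeries", tallies = tl, label = paste0("r", j), T1 = 16)
  })
  est <- estimateRates(series, window = c(5, 16))
  expect_lt(abs(est@alpha_b - 0.37), 0.04)
  expect_lt(abs(est@alpha_a - 0.05), 0.03)
  expect_equal(est@doubling_times[["A"]],
               log(2) / est@rates$alpha[est@rates$quantity == "A"])
})
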