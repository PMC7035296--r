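#' Exact birth--death simulation of apex and node counts
#'
#' Non-spatial per-apex interpretation of mycelial growth: each apex
#' branches at rate `alpha_b` (apexes + 1, nodes + 1) and anastomoses at
#' rate `alpha_a` (apexes - 1, nodes + 1), so the expected counts obey
#' `alpha_A = alpha_b - alpha_a` and the node excess over the apexes is
#' the cumulative anastomosis count. Trajectories are generated by exact
#' event-driven (Gillespie) scheduling and sampled on the frame grid.
#'
#' @param params a [SimParams-class]; `branch_rate` and `anastomosis_rate`
#'   are used, `anastomosis_mode` is ignored (this model is rate-based by
#'   construction).
#' @param replicates number of trajectories (>= 1).
#' @param allow_subcritical set TRUE to permit
#'   `branch_rate <= anastomosis_rate` (default rejects such ensembles,
#'   which drift to extinction).
#' @return a [CountEnsemble-class]. Trajectories whose apex count hits 0
#'   are flagged `extinct` (the count then stays 0).
#' @examples
#' ens <- simulateCounts(simParams(branch_rate = 0.37,
#'                                 anastomosis_rate = 0.05,
#'                                 anastomosis_mode = "rate",
#'                                 duration = 6), replicates = 20)
#' dim(ens@A)
#' @export
simulateCounts <- function(params, replicates = 1,
                           allow_subcritical = FALSE) {
  stopifnot(is(params, "SimParams"), replicates >= 1)
  ab <- params@branch_rate
  aa <- params@anastomosis_rate
  if (ab <= aa && !allow_subcritical)
    stop("subcritical ensemble (branch_rate <= anastomosis_rate); ",
         "pass allow_subcritical = TRUE to override")
  A0 <- round(params@initial_apexes)
  N0 <- params@initial_nodes
  grid <- seq(0, params@duration, by = params@frame_interval)
  nf <- length(grid)
  Am <- matrix(NA_real_, nf, replicates)
  Nm <- matrix(NA_real_, nf, replicates)
  extinct <- logical(replicates)
  nbr <- numeric(replicates)
  nan <- numeric(replicates)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(params@seed)
  total <- ab + aa
  for (r in seq_len(replicates)) {
    A <- A0; Nn <- N0; t <- 0; gi <- 1
    b <- 0; an <- 0
    while (TRUE) {
      t_next <- if (A > 0 && total > 0) t + rexp(1, total * A) else Inf
      while (gi <= nf && grid[gi] <= min(t_next, params@duration)) {
        Am[gi, r] <- A; Nm[gi, r] <- Nn; gi <- gi + 1
      }
      if (t_next > params@duration || gi > nf) break
      t <- t_next
      if (runif(1) < ab / total) {
        A <- A + 1; b <- b + 1
      } else {
        A <- A - 1; an <- an + 1
      }
      Nn <- Nn + 1
      if (A == 0) extinct[r] <- TRUE
    }
    nbr[r] <- b; nan[r] <- an
  }
  new("CountEnsemble", time = grid, A = Am, N = Nm, extinct = extinct,
      branch_events = nbr, anastomosis_events = nan, params = params)
}

#' Fit the apex growth exponent of a count ensemble
#'
#' Averages `ln A(t)` over the surviving replicates and fits a
#' least-squares slope inside the window, mirroring the log-linear fit
#' applied to experimental apex counts.
#'
#' @param ensemble a [CountEnsemble-class].
#' @param window fit window, hours.
#' @param include_extinct include extinct trajectories (default FALSE;
#'   extinct thalli are not observed in the reference data).
#' @return list with `alpha`, `alpha_se2`, `n_replicates`.
#' @export
fitEnsembleRate <- function(ensemble, window = c(5, Inf),
                            include_extinct = FALSE) {
  stopifnot(is(ensemble, "CountEnsemble"))
  keep <- if (include_extinct) rep(TRUE, ncol(ensemble@A)) else
    !ensemble@extinct
  if (!any(keep)) stop("no surviving replicates")
  A <- ensemble@A[, keep, drop = FALSE]
  mlog <- rowMeans(log(pmax(A, .Machine$double.xmin)))
  f <- fitExponential(ensemble@time, exp(mlog), window = window)
  list(alpha = f$alpha, alpha_se2 = f$alpha_se2, n_replicates = sum(keep))
}
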