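#' Count geometrical nodes lying close to another node
#'
#' The 2-D projection of a thick network turns a hyphal overlap into two
#' distinct but very close degree-3 vertices, whereas a genuine branching
#' or anastomosis node is usually isolated. This counts the degree-3
#' vertices having at least one other degree-3 vertex within `n_px`
#' pixels (Euclidean, centre to centre); both members of a close pair are
#' counted.
#'
#' @param graph a [NetworkGraph-class].
#' @param n_px proximity radius in pixels (>= 1); 20 is the reference
#'   operating point for 7-px-wide hyphae.
#' @param pixel_scale µm per pixel; defaults to the graph's own scale.
#' @return integer: the number of close nodes `Ng_close`.
#' @export
proximityNodeCount <- function(graph, n_px = 20,
                               pixel_scale = graph@pixel_scale) {
  stopifnot(is(graph, "NetworkGraph"), n_px >= 1)
  v <- graphVertices(graph)
  nodes <- v[v$degree >= 3, , drop = FALSE]
  if (nrow(nodes) == 0) return(0L)
  # a degree-d junction counts as d-2 coincident degree-3 nodes, matching
  # the tally rule; coincident copies are mutually close by construction
  mult <- nodes$degree - 2L
  xy <- cbind(rep(nodes$x_um, mult), rep(nodes$y_um, mult))
  if (nrow(xy) < 2) return(0L)
  d <- as.matrix(dist(xy)) / pixel_scale
  diag(d) <- Inf
  sum(apply(d, 1, min) <= n_px)
}

#' Estimate the biological node count from geometrical nodes
#'
#' Overlap artifacts are excluded by the proximity criterion: with
#' `r = Ng_close / Ng` approximately constant over the growth, the
#' biological node count is `N = (1 - r) Ng`. The uncertainty is
#' propagated to first order from `dNg = sqrt(Ng)` (Poisson) and
#' `dr = 3 sigma_r` (a conservative three-standard-deviation band on the
#' pooled ratio): `dN = sqrt(((1-r) dNg)^2 + (Ng dr)^2)`.
#'
#' @param Ng per-frame geometrical node counts.
#' @param Ng_close per-frame close-node counts (same length).
#' @param r_override,sigma_r_override optional externally supplied pooled
#'   ratio and spread (e.g. the reference operating point r = 0.20,
#'   sigma_r = 0.016); when `NULL` they are estimated from the frames
#'   with `Ng > 0`.
#' @return list with per-frame vectors `r`, `N`, `sigma_N`, and pooled
#'   `r_pooled`, `sigma_r`.
#' @examples
#' biologicalNodeEstimate(Ng = c(61, 271, 877), Ng_close = c(14, 54, 161))
#' @export
biologicalNodeEstimate <- function(Ng, Ng_close, r_override = NULL,
                                   sigma_r_override = NULL) {
  stopifnot(length(Ng) == length(Ng_close), all(Ng_close <= Ng),
            all(Ng_close >= 0))
  ok <- Ng > 0
  if (!any(ok)) stop("no nodes: every frame has Ng = 0")
  r_frame <- ifelse(ok, Ng_close / Ng, NA_real_)
  r_pooled <- if (is.null(r_override)) mean(r_frame[ok]) else r_override
  sigma_r <- if (is.null(sigma_r_override)) {
    if (sum(ok) > 1) sd(r_frame[ok]) else 0
  } else sigma_r_override
  N <- (1 - r_pooled) * Ng
  dNg <- sqrt(Ng)
  dr <- 3 * sigma_r
  sigma_N <- sqrt(((1 - r_pooled) * dNg)^2 + (Ng * dr)^2)
  list(r = r_frame, N = N, sigma_N = sigma_N,
       r_pooled = r_pooled, sigma_r = sigma_r)
}

#' Poisson counting uncertainty
#'
#' Each per-frame apex or node count is treated as a Poisson variable, so
#' its standard deviation is the square root of the count.
#'
#' @param count non-negative count(s).
#' @return `sqrt(count)`.
#' @examples
#' countUncertainty(9)   # 3
#' @export
countUncertainty <- function(count) {
  stopifnot(all(count >= 0))
  sqrt(count)
}

#' Length uncertainty by node-exclusion resampling
#'
#' Replicates a jackknife-style perturbation of the extracted network:
#' each replicate removes a uniform fraction (10 % by default) of the
#' degree-3 vertices, deletes each removed vertex's shortest incident
#' edge, and re-sums the length. `sigma_L` is the standard deviation of
#' the replicate lengths. Applied across frames of a growth series, the
#' log-log slope of `sigma_L` against `L` gives the scaling exponent of
#' the length-uncertainty estimator (0.61 in the reference data).
#'
#' @param graph a [NetworkGraph-class].
#' @param exclusion_fraction fraction of nodes removed per replicate.
#' @param replicates number of replicates (>= 30).
#' @param seed integer seed for the resampling.
#' @return list with `sigma_L_mm`, `L_mm`, `replicate_L_mm`, and
#'   `fallback` (TRUE when the graph has fewer than 10 nodes and the
#'   Poisson surrogate `sqrt(L_mm)` was used).
#' @export
lengthUncertainty <- function(graph, exclusion_fraction = 0.10,
                              replicates = 200, seed = 1) {
  stopifnot(is(graph, "NetworkGraph"), replicates >= 30)
  v <- graphVertices(graph)
  e <- graphEdges(graph)
  L <- sum(e$length_um) / 1000
  nodes <- v$id[v$degree >= 3]
  if (length(nodes) < 10) {
    return(list(sigma_L_mm = sqrt(L), L_mm = L,
                replicate_L_mm = numeric(0), fallback = TRUE))
  }
  # shortest incident edge of each node, precomputed
  inc <- lapply(nodes, function(id) which(e$from == id | e$to == id))
  shortest <- vapply(inc, function(ix)
    if (length(ix)) ix[which.min(e$length_um[ix])] else NA_integer_, 1L)
  k <- max(1L, round(exclusion_fraction * length(nodes)))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  reps <- vapply(seq_len(replicates), function(i) {
    drop <- unique(shortest[sample.int(length(nodes), k)])
    drop <- drop[!is.na(drop)]
    (sum(e$length_um) - sum(e$length_um[drop])) / 1000
  }, numeric(1))
  list(sigma_L_mm = sd(reps), L_mm = L, replicate_L_mm = reps,
       fallback = FALSE)
}

#' Scaling exponent of the length uncertainty across frames
#'
#' @param graphs list of [NetworkGraph-class], one per frame.
#' @param ... passed to [lengthUncertainty()].
#' @return list with `exponent`, `exponent_se2`, and the per-frame
#'   data.frame `frames` (`L_mm`, `sigma_L_mm`, `fallback`).
#' @export
lengthUncertaintyExponent <- function(graphs, ...) {
  res <- lapply(graphs, lengthUncertainty, ...)
  df <- data.frame(L_mm = vapply(res, `[[`, 1, "L_mm"),
                   sigma_L_mm = vapply(res, `[[`, 1, "sigma_L_mm"),
                   fallback = vapply(res, `[[`, TRUE, "fallback"))
  ok <- !df$fallback & df$sigma_L_mm > 0 & df$L_mm > 0
  if (sum(ok) < 3) stop("need at least 3 frames with resampled sigma_L")
  fit <- summary(lm(log(df$sigma_L_mm[ok]) ~ log(df$L_mm[ok])))$coefficients
  list(exponent = unname(fit[2, 1]), exponent_se2 = unname(2 * fit[2, 2]),
       frames = df)
}

#' False-positive detection ratios
#'
#' Bookkeeping of manually audited detections: the ratio of false-positive
#' apexes (or nodes) to detected apexes (or nodes).
#'
#' @param apex_fp,apex_detected apex false positives and detections.
#' @param node_fp,node_detected node false positives and detections.
#' @return list with the four counts and `apex_ratio`, `node_ratio`.
#' @examples
#' detectionErrorRates(16, 185, 3, 566)
#' @export
detectionErrorRates <- function(apex_fp, apex_detected, node_fp,
                                node_detected) {
  stopifnot(apex_detected > 0, node_detected > 0,
            apex_fp >= 0, node_fp >= 0)
  list(apex_fp = apex_fp, apex_detected = apex_detected,
       node_fp = node_fp, node_detected = node_detected,
       apex_ratio = apex_fp / apex_detected,
       node_ratio = node_fp / node_detected)
}

#' Apply the node correction to a growth series
#'
#' Runs [proximityNodeCount()] on each frame's graph, pools the close-node
#' ratio, and appends `r`, `N` and `sigma_N` columns to the tally table.
#'
#' @param series a [GrowthSeries-class].
#' @param graphs list of [NetworkGraph-class], one per frame of `series`.
#' @param n_px proximity radius, pixels.
#' @return the series with corrected columns, plus attributes
#'   `r_pooled` and `sigma_r` on the tally table.
#' @export
correctNodes <- function(series, graphs, n_px = 20) {
  stopifnot(is(series, "GrowthSeries"),
            length(graphs) == nrow(tallies(series)))
  tl <- tallies(series)
  close <- vapply(graphs, proximityNodeCount, 0L, n_px = n_px)
  est <- biologicalNodeEstimate(tl$Ng, pmin(close, tl$Ng))
  tl$r <- est$r
  tl$N <- est$N
  tl$sigma_N <- est$sigma_N
  attr(tl, "r_pooled") <- est$r_pooled
  attr(tl, "sigma_r") <- est$sigma_r
  initialize(series, tallies = tl)
}
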