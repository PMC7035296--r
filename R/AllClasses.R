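#' @import methods
#' @importFrom stats coef lm median optimize quantile rexp rnorm runif sd
#'   setNames spline var wilcox.test complete.cases
#' @importFrom utils head tail read.csv write.csv
#' @useDynLib mycelia, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Parameters of the stochastic mycelium growth simulator
#'
#' Container for all tunable parameters of the two simulators (the exact
#' birth--death count model and the spatial tip-growth model). Defaults
#' describe a wild-type thallus growing from a germinating ascospore:
#' apex elongation of a few micrometres per minute, per-apex lateral
#' branching close to 0.37 per hour, anastomosis close to 0.05 per hour,
#' three initial apexes and about one millimetre of initial hypha.
#'
#' @slot elongation_speed apex elongation speed, micrometres per hour.
#' @slot branch_rate per-apex lateral branching rate, per hour.
#' @slot anastomosis_mode `"proximity"` (tips fuse when they come within
#'   `fusion_distance` of another hypha) or `"rate"` (tips fuse as a
#'   Poisson process at `anastomosis_rate`, snapping to the nearest hypha).
#' @slot anastomosis_rate per-apex anastomosis rate, per hour (rate mode).
#' @slot fusion_distance tip-to-hypha fusion distance, micrometres.
#' @slot branch_angle mean absolute branching angle, degrees.
#' @slot branch_angle_spread half-width of the uniform branching-angle
#'   jitter, degrees.
#' @slot direction_persistence standard deviation of the per-step angular
#'   perturbation of a tip direction, radians per sqrt(hour); 0 gives
#'   perfectly straight hyphae.
#' @slot initial_apexes number of tips at time zero.
#' @slot initial_nodes node-count offset at time zero (may be fractional,
#'   it only shifts the tally).
#' @slot initial_length total hyphal length at time zero, millimetres.
#' @slot duration simulated time, hours.
#' @slot frame_interval time between recorded frames, hours.
#' @slot time_step integration step of the spatial model, hours.
#' @slot tip_cap abort threshold on the live tip count (runaway guard).
#' @slot seed integer seed; every simulation records it.
#' @export
setClass("SimParams", representation(
  elongation_speed = "numeric",
  branch_rate = "numeric",
  anastomosis_mode = "character",
  anastomosis_rate = "numeric",
  fusion_distance = "numeric",
  branch_angle = "numeric",
  branch_angle_spread = "numeric",
  direction_persistence = "numeric",
  initial_apexes = "numeric",
  initial_nodes = "numeric",
  initial_length = "numeric",
  duration = "numeric",
  frame_interval = "numeric",
  time_step = "numeric",
  tip_cap = "numeric",
  seed = "numeric"
))

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@elongation_speed < 0) msg <- c(msg, "elongation_speed must be >= 0")
  if (object@branch_rate < 0) msg <- c(msg, "branch_rate must be >= 0")
  if (object@anastomosis_rate < 0) msg <- c(msg, "anastomosis_rate must be >= 0")
  if (!object@anastomosis_mode %in% c("proximity", "rate", "off"))
    msg <- c(msg, "anastomosis_mode must be 'proximity', 'rate' or 'off'")
  if (object@anastomosis_mode == "proximity" && object@fusion_distance <= 0)
    msg <- c(msg, "proximity mode requires fusion_distance > 0")
  if (object@duration < 0) msg <- c(msg, "duration must be >= 0")
  if (object@frame_interval <= 0) msg <- c(msg, "frame_interval must be > 0")
  if (object@time_step <= 0) msg <- c(msg, "time_step must be > 0")
  if (object@initial_apexes < 1) msg <- c(msg, "initial_apexes must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct simulator parameters
#'
#' @param elongation_speed µm/h per apex (default 180, i.e. 3 µm/min).
#' @param branch_rate h^-1 per apex (default 0.37).
#' @param anastomosis_mode "proximity", "rate" or "off".
#' @param anastomosis_rate h^-1 per apex, used in rate mode (default 0.05).
#' @param fusion_distance µm (default 25, the rendered hypha stroke width:
#'   two centerlines closer than this touch in the raster, so fusion in
#'   the simulator coincides with contact in the image).
#' @param branch_angle degrees (default 60).
#' @param branch_angle_spread degrees (default 20).
#' @param direction_persistence rad/sqrt(h) angular diffusion (default 0.35).
#' @param initial_apexes count (default 3).
#' @param initial_nodes count offset (default 1.5).
#' @param initial_length mm (default 1).
#' @param duration h (default 10).
#' @param frame_interval h (default 17/60, the acquisition cadence).
#' @param time_step h (default 0.01).
#' @param tip_cap maximum live tip count (default 5000).
#' @param seed integer seed (default 1).
#' @return A [SimParams-class] object.
#' @examples
#' simParams(branch_rate = 0.37, anastomosis_rate = 0.05, duration = 8)
#' @export
simParams <- function(elongation_speed = 180, branch_rate = 0.37,
                      anastomosis_mode = c("proximity", "rate", "off"),
                      anastomosis_rate = 0.05, fusion_distance = 25,
                      branch_angle = 60, branch_angle_spread = 20,
                      direction_persistence = 0.35,
                      initial_apexes = 3, initial_nodes = 1.5,
                      initial_length = 1, duration = 10,
                      frame_interval = 17 / 60, time_step = 0.01,
                      tip_cap = 5000, seed = 1) {
  anastomosis_mode <- match.arg(anastomosis_mode)
  new("SimParams", elongation_speed = elongation_speed,
      branch_rate = branch_rate, anastomosis_mode = anastomosis_mode,
      anastomosis_rate = anastomosis_rate, fusion_distance = fusion_distance,
      branch_angle = branch_angle, branch_angle_spread = branch_angle_spread,
      direction_persistence = direction_persistence,
      initial_apexes = initial_apexes, initial_nodes = initial_nodes,
      initial_length = initial_length, duration = duration,
      frame_interval = frame_interval, time_step = time_step,
      tip_cap = tip_cap, seed = seed)
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams: v =", object@elongation_speed, "um/h,",
      "alpha_b =", object@branch_rate, "/h,",
      "anastomosis =", object@anastomosis_mode,
      if (object@anastomosis_mode == "rate")
        paste0("(alpha_a = ", object@anastomosis_rate, "/h)")
      else if (object@anastomosis_mode == "proximity")
        paste0("(d_fuse = ", object@fusion_distance, " um)"),
      "\n  A0 =", object@initial_apexes, ", L0 =", object@initial_length,
      "mm, T =", object@duration, "h, tau =",
      round(object@frame_interval, 4), "h, seed =", object@seed, "\n")
})

#' Ensemble of birth--death count trajectories
#'
#' Result of [simulateCounts()]: apex and node counts of every replicate,
#' sampled on the common frame grid.
#'
#' @slot time frame times, hours.
#' @slot A apex-count matrix, frames x replicates.
#' @slot N node-count matrix, frames x replicates.
#' @slot extinct logical, per replicate: did A hit zero before the horizon.
#' @slot branch_events,anastomosis_events per-replicate event totals.
#' @slot params the generating [SimParams-class].
#' @export
setClass("CountEnsemble", representation(
  time = "numeric", A = "matrix", N = "matrix", extinct = "logical",
  branch_events = "numeric", anastomosis_events = "numeric",
  params = "SimParams"
))

setMethod("show", "CountEnsemble", function(object) {
  cat("CountEnsemble:", ncol(object@A), "replicates x",
      length(object@time), "frames over", max(object@time), "h;",
      sum(object@extinct), "extinct\n")
})

#' Spatial mycelium simulation state
#'
#' Result of [simulateNetwork()]: the full piecewise-linear network (every
#' recorded polyline point with its hypha id and creation time), the event
#' log, and the ground-truth tallies on the frame grid.
#'
#' @slot points matrix with columns `hypha`, `x`, `y`, `t` (µm, hours);
#'   consecutive rows of one hypha are its segments in creation order.
#' @slot hyphae data.frame: `id`, `parent`, `birth_time`.
#' @slot events data.frame: `time`, `type` (`branch`/`anastomosis`).
#' @slot truth data.frame: `frame`, `time_h`, `A`, `N`, `L_mm` ground truth.
#' @slot params the generating [SimParams-class].
#' @export
setClass("MyceliumSim", representation(
  points = "matrix", hyphae = "data.frame", events = "data.frame",
  truth = "data.frame", params = "SimParams"
))

setMethod("show", "MyceliumSim", function(object) {
  tr <- object@truth
  last <- tr[nrow(tr), ]
  cat("MyceliumSim:", nrow(object@hyphae), "hyphae,",
      nrow(object@points), "polyline points,", nrow(tr), "frames\n",
      " final tallies: A =", last$A, ", N =", last$N,
      ", L =", round(last$L_mm, 2), "mm at t =", round(last$time_h, 2), "h\n")
})

#' Ground-truth tallies of a simulation
#' @param object a [MyceliumSim-class]
#' @return data.frame with columns frame, time_h, A, N, L_mm
#' @export
setGeneric("simTruth", function(object) standardGeneric("simTruth"))

#' @rdname simTruth
#' @export
setMethod("simTruth", "MyceliumSim", function(object) object@truth)

#' One time-stamped raster frame of the thallus
#'
#' @slot pixels integer matrix (rows = y, columns = x), 0 background /
#'   1 hypha for binary frames, 0..255 for grayscale.
#' @slot time_h acquisition time, hours since germination.
#' @slot pixel_scale µm per pixel (3.516 by default throughout).
#' @slot frame_index integer frame number.
#' @export
setClass("Panorama", representation(
  pixels = "matrix", time_h = "numeric", pixel_scale = "numeric",
  frame_index = "integer"
))

setValidity("Panorama", function(object) {
  if (object@pixel_scale <= 0) "pixel_scale must be > 0" else TRUE
})

setMethod("show", "Panorama", function(object) {
  cat("Panorama", object@frame_index, ":", nrow(object@pixels), "x",
      ncol(object@pixels), "px at", object@pixel_scale, "um/px, t =",
      round(object@time_h, 2), "h,",
      sum(object@pixels > 0), "foreground px\n")
})

#' Spatial centerline graph of a thallus
#'
#' Vertices are junctions (degree >= 3), apexes (degree 1) and isolated
#' loop anchors; hypha interiors are carried as edge polylines. All
#' coordinates are micrometres in the panorama frame (x right, y down,
#' origin at the top-left pixel corner).
#'
#' @slot vertices data.frame: `id`, `x_um`, `y_um`, `degree`, `kind`
#'   (`apex`/`node`/`loop`), `boundary` (apex within the border margin).
#' @slot edges data.frame: `from`, `to`, `length_um`.
#' @slot polylines list of two-column µm matrices, one per edge.
#' @slot pixel_scale µm per pixel of the source raster.
#' @slot dim_px source raster dimension `c(nrow, ncol)`.
#' @slot pruned_spurs number of short skeleton spurs removed.
#' @export
setClass("NetworkGraph", representation(
  vertices = "data.frame", edges = "data.frame", polylines = "list",
  pixel_scale = "numeric", dim_px = "numeric", pruned_spurs = "numeric"
))

setValidity("NetworkGraph", function(object) {
  if (nrow(object@edges) != length(object@polylines))
    return("one polyline per edge required")
  TRUE
})

setMethod("show", "NetworkGraph", function(object) {
  v <- object@vertices
  cat("NetworkGraph:", nrow(v), "vertices (",
      sum(v$degree == 1), "apexes,", sum(v$degree >= 3), "junctions ),",
      nrow(object@edges), "edges, L =",
      round(sum(object@edges$length_um) / 1000, 3), "mm\n")
})

#' @describeIn NetworkGraph-class vertex table accessor
#' @param object a NetworkGraph
#' @export
setGeneric("graphVertices", function(object) standardGeneric("graphVertices"))
#' @rdname NetworkGraph-class
#' @export
setMethod("graphVertices", "NetworkGraph", function(object) object@vertices)

#' @describeIn NetworkGraph-class edge table accessor
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))
#' @rdname NetworkGraph-class
#' @export
setMethod("graphEdges", "NetworkGraph", function(object) object@edges)

#' Per-frame tally series of a growth experiment
#'
#' @slot tallies data.frame with columns `frame`, `time_h`, `A`, `Ng`,
#'   `L_mm`, `sigma_A`, `sigma_Ng`, `sigma_L` (and, after node correction,
#'   `r`, `N`, `sigma_N`).
#' @slot label experiment label.
#' @slot T1 end of the analysis window (first apex at the panorama edge),
#'   hours; `NA` when not reached.
#' @export
setClass("GrowthSeries", representation(
  tallies = "data.frame", label = "character", T1 = "numeric"
))

setMethod("show", "GrowthSeries", function(object) {
  tl <- object@tallies
  cat("GrowthSeries '", object@label, "': ", nrow(tl), " frames, t in [",
      round(min(tl$time_h), 2), ", ", round(max(tl$time_h), 2), "] h, ",
      "final A = ", tl$A[nrow(tl)], ", Ng = ", tl$Ng[nrow(tl)],
      ", L = ", round(tl$L_mm[nrow(tl)], 2), " mm\n", sep = "")
})

#' Tally table accessor
#' @param object a [GrowthSeries-class]
#' @return the tally data.frame
#' @export
setGeneric("tallies", function(object) standardGeneric("tallies"))
#' @rdname tallies
#' @export
setMethod("tallies", "GrowthSeries", function(object) object@tallies)

#' Fitted growth-rate estimates
#'
#' @slot rates data.frame: `quantity`, `alpha` (h^-1), `se2` (2 sigma),
#'   `prefactor`, `n_points`.
#' @slot alpha_b,alpha_a branching and anastomosis rates, h^-1.
#' @slot alpha_b_se2,alpha_a_se2 their 2 sigma uncertainties.
#' @slot scaling_exponent slope of log Ng vs log A.
#' @slot doubling_times named vector, hours.
#' @export
setClass("RateEstimates", representation(
  rates = "data.frame", alpha_b = "numeric", alpha_a = "numeric",
  alpha_b_se2 = "numeric", alpha_a_se2 = "numeric",
  scaling_exponent = "numeric", doubling_times = "numeric"
))

setMethod("show", "RateEstimates", function(object) {
  cat("RateEstimates:\n")
  r <- object@rates
  for (i in seq_len(nrow(r)))
    cat(sprintf("  alpha_%-3s = %.3f +/- %.3f /h (doubling %.2f h)\n",
                r$quantity[i], r$alpha[i], r$se2[i], log(2) / r$alpha[i]))
  if (length(object@alpha_b))
    cat(sprintf("  alpha_b = %.3f +/- %.3f /h, alpha_a = %.3f +/- %.3f /h\n",
                object@alpha_b, object@alpha_b_se2,
                object@alpha_a, object@alpha_a_se2))
})

#' The enclosed faces (intra-thallus areas) of one frame
#'
#' @slot faces data.frame: `id`, `area_px`, `area_mm2`, `cx_um`, `cy_um`,
#'   `crow`, `ccol` (representative interior pixel), `appearance_time_h`.
#' @slot label_matrix integer matrix mapping pixels to face ids (0 = none).
#' @slot time_h frame time.
#' @slot pixel_scale µm per pixel.
#' @export
setClass("FaceSet", representation(
  faces = "data.frame", label_matrix = "matrix", time_h = "numeric",
  pixel_scale = "numeric"
))

setMethod("show", "FaceSet", function(object) {
  f <- object@faces
  cat("FaceSet at t =", round(object@time_h, 2), "h:", nrow(f), "faces, S =",
      round(sum(f$area_mm2), 3), "mm^2\n")
})

#' Face table accessor
#' @param object a [FaceSet-class]
#' @export
setGeneric("faces", function(object) standardGeneric("faces"))
#' @rdname faces
#' @export
setMethod("faces", "FaceSet", function(object) object@faces)

#' Annulus/sector partition of the thallus
#'
#' @slot center c(x, y) µm.
#' @slot annuli matrix with columns `R_in`, `R_out` (µm).
#' @slot n_sectors sectors per annulus (60 in the reference layout).
#' @export
setClass("SectorGrid", representation(
  center = "numeric", annuli = "matrix", n_sectors = "integer"
))

setValidity("SectorGrid", function(object) {
  a <- object@annuli
  if (any(a < 0) || any(a[, 2] <= a[, 1]))
    return("annulus radii must be non-negative with R_out > R_in")
  if (object@n_sectors < 1) return("n_sectors must be >= 1")
  TRUE
})

setMethod("show", "SectorGrid", function(object) {
  cat("SectorGrid:", nrow(object@annuli), "annuli x", object@n_sectors,
      "sectors, width", paste(unique(round(diff(t(object@annuli)))),
                              collapse = "/"), "um\n")
})

#' Per-sector local measures at one time point
#'
#' @slot measures data.frame: `annulus`, `sector`, `A`, `N`, `L_mm`.
#' @slot grid the generating [SectorGrid-class].
#' @slot time_h measurement time.
#' @export
setClass("SectorMeasures", representation(
  measures = "data.frame", grid = "SectorGrid", time_h = "numeric"
))

setMethod("show", "SectorMeasures", function(object) {
  cat("SectorMeasures at t =", round(object@time_h, 2), "h:",
      nrow(object@measures), "cells, total L =",
      round(sum(object@measures$L_mm), 2), "mm\n")
})

#' Measure table accessor
#' @param object a [SectorMeasures-class]
#' @export
setGeneric("sectorTable", function(object) standardGeneric("sectorTable"))
#' @rdname sectorTable
#' @export
setMethod("sectorTable", "SectorMeasures", function(object) object@measures)
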