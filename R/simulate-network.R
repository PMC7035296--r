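#' Spatial lattice-free simulation of a growing mycelium
#'
#' Tips advance at `elongation_speed` with a persistent random direction
#' (zero-mean angular perturbation each step), branch laterally at
#' `branch_rate` (new tip at about `branch_angle` degrees from the
#' parent), and anastomose either on proximity (a tip coming within
#' `fusion_distance` of a non-parent hypha fuses: the tip is removed and a
#' node created) or as a Poisson process at `anastomosis_rate` that snaps
#' the tip onto the nearest reachable hypha. The network starts from
#' `initial_apexes` straight starter hyphae radiating from the origin with
#' total length `initial_length`. The full piecewise-linear trace is kept,
#' so ground-truth tallies are exact sums over the segment list.
#'
#' Fusion eligibility excludes a tip's own hypha, the first
#' `3 * fusion_distance` µm of its parent hypha around the branch point,
#' and the first stretch of its own side branches, so that the geometry of
#' a lateral branch is not misread as an immediate anastomosis.
#'
#' @param params a [SimParams-class].
#' @return a [MyceliumSim-class] with per-frame ground-truth tallies.
#' @examples
#' sim <- simulateNetwork(simParams(duration = 3, seed = 2))
#' tail(simTruth(sim), 3)
#' @export
simulateNetwork <- function(params) {
  stopifnot(is(params, "SimParams"))
  if (params@anastomosis_mode == "proximity" && params@fusion_distance <= 0)
    stop("proximity mode requires fusion_distance > 0")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(params@seed)

  v <- params@elongation_speed
  dt <- params@time_step
  step_um <- v * dt
  fd <- params@fusion_distance
  excl <- 3 * fd
  cell <- max(fd, 1)
  check_every <- 3L
  A0 <- round(params@initial_apexes)
  L0_um <- params@initial_length * 1000

  # point store: hypha id, x, y, t, s (path length from hypha birth)
  cap <- 20000L
  P <- matrix(NA_real_, cap, 5)
  colnames(P) <- c("hypha", "x", "y", "t", "s")
  np <- 0L
  bins <- new.env(hash = TRUE, parent = emptyenv())
  push_pt <- function(h, x, y, t, s) {
    if (np + 1L > cap) {
      cap <<- cap * 2L
      P2 <- matrix(NA_real_, cap, 5); P2[seq_len(np), ] <- P[seq_len(np), ]
      colnames(P2) <- colnames(P); P <<- P2
    }
    np <<- np + 1L
    P[np, ] <<- c(h, x, y, t, s)
    key <- paste(floor(x / cell), floor(y / cell))
    bins[[key]] <- c(bins[[key]], np)
    np
  }
  near_pts <- function(x, y, reach_cells = 1L) {
    ix <- floor(x / cell); iy <- floor(y / cell)
    rng <- -reach_cells:reach_cells
    out <- integer(0)
    for (dx in rng) for (dy in rng) {
      idx <- bins[[paste(ix + dx, iy + dy)]]
      if (!is.null(idx)) out <- c(out, idx)
    }
    out
  }

  # hyphae bookkeeping
  h_parent <- integer(0); h_birth <- numeric(0)
  new_hypha <- function(parent, t) {
    h_parent[length(h_parent) + 1L] <<- parent
    h_birth[length(h_birth) + 1L] <<- t
    length(h_parent)
  }

  # tips: parallel vectors
  tp_h <- integer(0); tp_x <- numeric(0); tp_y <- numeric(0)
  tp_dir <- numeric(0); tp_bx <- numeric(0); tp_by <- numeric(0)
  tp_path <- numeric(0); tp_parent <- integer(0)

  ev_t <- numeric(0); ev_type <- character(0)
  L_um <- 0

  # starter hyphae: A0 straight radial segments summing to L0
  seg0 <- L0_um / A0
  for (i in seq_len(A0)) {
    th <- 2 * pi * (i - 1) / A0 + runif(1, -0.3, 0.3)
    h <- new_hypha(0L, 0)
    npt <- if (step_um > 0 && seg0 > 0)
      max(2L, ceiling(seg0 / step_um) + 1L) else 2L
    ss <- seq(0, seg0, length.out = npt)
    for (s in ss) push_pt(h, s * cos(th), s * sin(th), 0, s)
    tp_h <- c(tp_h, h); tp_x <- c(tp_x, seg0 * cos(th))
    tp_y <- c(tp_y, seg0 * sin(th)); tp_dir <- c(tp_dir, th)
    tp_bx <- c(tp_bx, 0); tp_by <- c(tp_by, 0)
    tp_path <- c(tp_path, seg0); tp_parent <- c(tp_parent, 0L)
    L_um <- L_um + seg0
  }

  frame_times <- seq(0, params@duration, by = params@frame_interval)
  nf <- length(frame_times)
  fr_A <- integer(nf); fr_N <- numeric(nf); fr_L <- numeric(nf)
  record <- function(fi) {
    fr_A[fi] <<- length(tp_h)
    fr_N[fi] <<- params@initial_nodes + length(ev_t)
    fr_L[fi] <<- L_um / 1000
  }
  record(1L)

  n_steps <- ceiling(params@duration / dt)
  fi <- 2L
  p_branch <- params@branch_rate * dt
  p_fuse <- params@anastomosis_rate * dt
  sigma_dir <- params@direction_persistence * sqrt(dt)

  try_fuse <- function(i, reach_cells) {
    cand <- near_pts(tp_x[i], tp_y[i], reach_cells)
    if (!length(cand)) return(FALSE)
    ch <- P[cand, 1]
    ok <- ch != tp_h[i]
    # parent hypha: only beyond the branch neighbourhood
    on_parent <- ok & ch == tp_parent[i]
    if (any(on_parent)) {
      d_birth <- sqrt((P[cand, 2] - tp_bx[i])^2 + (P[cand, 3] - tp_by[i])^2)
      ok[on_parent & d_birth < excl] <- FALSE
    }
    # own side branches: skip their first stretch
    child_of_tip <- ok & h_parent[ch] == tp_h[i]
    ok[child_of_tip & P[cand, 5] < excl] <- FALSE
    if (!any(ok)) return(FALSE)
    cand <- cand[ok]
    d2 <- (P[cand, 2] - tp_x[i])^2 + (P[cand, 3] - tp_y[i])^2
    jmin <- which.min(d2)
    reach <- if (reach_cells == 1L) fd else reach_cells * cell
    if (sqrt(d2[jmin]) > reach) return(FALSE)
    j <- cand[jmin]
    dlen <- sqrt(d2[jmin])
    push_pt(tp_h[i], P[j, 2], P[j, 3], t_now, tp_path[i] + dlen)
    L_um <<- L_um + dlen
    ev_t <<- c(ev_t, t_now); ev_type <<- c(ev_type, "anastomosis")
    TRUE
  }

  t_now <- 0
  for (step in seq_len(n_steps)) {
    t_now <- step * dt
    # frames strictly inside (t_prev, t_now) see the pre-step state
    while (fi <= nf && frame_times[fi] < t_now - 1e-9) {
      record(fi); fi <- fi + 1L
    }
    ntip <- length(tp_h)
    if (ntip == 0) next # whole colony stalled (only possible via fusion)
    if (ntip > params@tip_cap)
      stop("runaway growth: ", ntip, " tips exceed tip_cap = ",
           params@tip_cap, " at t = ", round(t_now, 2), " h")
    # advance
    tp_dir <- tp_dir + rnorm(ntip, 0, sigma_dir)
    tp_x <- tp_x + step_um * cos(tp_dir)
    tp_y <- tp_y + step_um * sin(tp_dir)
    tp_path <- tp_path + step_um
    for (i in seq_len(ntip))
      push_pt(tp_h[i], tp_x[i], tp_y[i], t_now, tp_path[i])
    L_um <- L_um + step_um * ntip

    # branching
    br <- which(runif(ntip) < p_branch)
    for (i in br) {
      side <- sample(c(-1, 1), 1)
      ang <- tp_dir[i] + side * (params@branch_angle +
        runif(1, -params@branch_angle_spread, params@branch_angle_spread)) *
        pi / 180
      h <- new_hypha(tp_h[i], t_now)
      push_pt(h, tp_x[i], tp_y[i], t_now, 0)
      tp_h <- c(tp_h, h); tp_x <- c(tp_x, tp_x[i]); tp_y <- c(tp_y, tp_y[i])
      tp_dir <- c(tp_dir, ang); tp_bx <- c(tp_bx, tp_x[i])
      tp_by <- c(tp_by, tp_y[i]); tp_path <- c(tp_path, 0)
      tp_parent <- c(tp_parent, tp_h[i])
      ev_t <- c(ev_t, t_now); ev_type <- c(ev_type, "branch")
    }

    # anastomosis
    ntip <- length(tp_h)
    dead <- logical(ntip)
    if (params@anastomosis_mode == "proximity" &&
        step %% check_every == 0L) {
      for (i in seq_len(ntip)) {
        if (tp_path[i] <= excl) next
        if (try_fuse(i, 1L)) dead[i] <- TRUE
      }
    } else if (params@anastomosis_mode == "rate") {
      hit <- which(runif(ntip) < p_fuse & tp_path > excl)
      for (i in hit) if (try_fuse(i, 2L)) dead[i] <- TRUE
    }
    if (any(dead)) {
      keep <- !dead
      tp_h <- tp_h[keep]; tp_x <- tp_x[keep]; tp_y <- tp_y[keep]
      tp_dir <- tp_dir[keep]; tp_bx <- tp_bx[keep]; tp_by <- tp_by[keep]
      tp_path <- tp_path[keep]; tp_parent <- tp_parent[keep]
    }
  }
  while (fi <= nf) { record(fi); fi <- fi + 1L }

  new("MyceliumSim",
      points = P[seq_len(np), , drop = FALSE],
      hyphae = data.frame(id = seq_along(h_parent), parent = h_parent,
                          birth_time = h_birth),
      events = data.frame(time = ev_t, type = ev_type,
                          stringsAsFactors = FALSE),
      truth = data.frame(frame = seq_len(nf), time_h = frame_times,
                         A = fr_A, N = fr_N, L_mm = fr_L),
      params = params)
}

#' Segment list of a simulation at a given frame
#'
#' @param sim a [MyceliumSim-class].
#' @param frame frame index (1-based); defaults to the last frame.
#' @return matrix with columns `x1, y1, x2, y2` (µm): every network
#'   segment whose endpoints both exist at the frame time.
#' @export
simSegments <- function(sim, frame = nrow(sim@truth)) {
  stopifnot(is(sim, "MyceliumSim"))
  t_max <- sim@truth$time_h[frame]
  P <- sim@points
  keep <- P[, "t"] <= t_max + 1e-9
  P <- P[keep, , drop = FALSE]
  ord <- order(P[, "hypha"], P[, "s"])
  P <- P[ord, , drop = FALSE]
  same <- diff(P[, "hypha"]) == 0
  i1 <- which(same)
  cbind(x1 = P[i1, "x"], y1 = P[i1, "y"],
        x2 = P[i1 + 1, "x"], y2 = P[i1 + 1, "y"])
}

#' Render a simulation frame as a binary panorama
#'
#' Draws every segment existing at the frame time as a stroke of
#' `hypha_width` pixels (disc-shaped pen), on a raster covering the whole
#' simulation extent plus a margin. Deterministic given the state.
#'
#' @param sim a [MyceliumSim-class].
#' @param frame frame index (1-based).
#' @param pixel_scale µm per pixel (default 3.516).
#' @param hypha_width stroke width in pixels (default 7).
#' @param extent_um optional `c(xmin, xmax, ymin, ymax)` µm; default: the
#'   bounding box of the final network plus a margin, so all frames of
#'   one simulation share a common raster.
#' @return a [Panorama-class]; `attr(pixels, "origin_um")` maps pixel
#'   (1,1) back to simulation coordinates.
#' @export
renderPanorama <- function(sim, frame = nrow(sim@truth),
                           pixel_scale = 3.516, hypha_width = 7,
                           extent_um = NULL) {
  stopifnot(is(sim, "MyceliumSim"), hypha_width >= 1)
  if (pixel_scale <= 0) stop("pixel_scale must be > 0")
  if (is.null(extent_um)) {
    Pall <- sim@points
    m <- hypha_width * pixel_scale + 4 * pixel_scale
    extent_um <- c(min(Pall[, "x"]) - m, max(Pall[, "x"]) + m,
                   min(Pall[, "y"]) - m, max(Pall[, "y"]) + m)
  }
  nr <- ceiling((extent_um[4] - extent_um[3]) / pixel_scale)
  nc <- ceiling((extent_um[2] - extent_um[1]) / pixel_scale)
  img <- matrix(0L, nr, nc)
  seg <- simSegments(sim, frame)
  if (nrow(seg) > 0) {
    lens <- sqrt((seg[, 3] - seg[, 1])^2 + (seg[, 4] - seg[, 2])^2)
    seg <- seg[lens > 0, , drop = FALSE]
    lens <- lens[lens > 0]
  }
  if (nrow(seg) > 0) {
    nsamp <- pmax(2L, ceiling(lens / (0.5 * pixel_scale)) + 1L)
    xs <- unlist(lapply(seq_len(nrow(seg)), function(i)
      seq(seg[i, 1], seg[i, 3], length.out = nsamp[i])))
    ys <- unlist(lapply(seq_len(nrow(seg)), function(i)
      seq(seg[i, 2], seg[i, 4], length.out = nsamp[i])))
    col <- pmin(pmax(floor((xs - extent_um[1]) / pixel_scale) + 1L, 1L), nc)
    row <- pmin(pmax(floor((ys - extent_um[3]) / pixel_scale) + 1L, 1L), nr)
    rad <- (hypha_width - 1) / 2
    w <- floor(rad)
    offs <- expand.grid(dr = -ceiling(rad):ceiling(rad),
                        dc = -ceiling(rad):ceiling(rad))
    offs <- offs[offs$dr^2 + offs$dc^2 <= max(rad, 0.5)^2 + 1e-9, ,
                 drop = FALSE]
    if (nrow(offs) == 0) offs <- data.frame(dr = 0, dc = 0)
    base <- unique((col - 1L) * nr + row)  # 1-based linear index
    for (k in seq_len(nrow(offs))) {
      r2 <- ((base - 1L) %% nr) + 1L + offs$dr[k]
      c2 <- ((base - 1L) %/% nr) + 1L + offs$dc[k]
      okk <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
      img[(c2[okk] - 1L) * nr + r2[okk]] <- 1L
    }
  }
  attr(img, "origin_um") <- c(extent_um[1], extent_um[3])
  new("Panorama", pixels = img, time_h = sim@truth$time_h[frame],
      pixel_scale = pixel_scale, frame_index = as.integer(frame))
}

#' Write a simulation as panoramas plus ground-truth sidecars
#'
#' Writes `frame_%04d.tif` (single-channel 8-bit), `frames.csv`
#' (frame, time_h, pixel_scale_um), `truth.csv` (frame, time_h, A, N,
#' L_mm) and `segments.csv` (x1, y1, x2, y2 µm, final frame).
#'
#' @param sim a [MyceliumSim-class].
#' @param dir output directory (created if needed).
#' @param frames frame indices to write (default: all).
#' @param ... passed to [renderPanorama()].
#' @return invisibly, the vector of written image paths.
#' @export
writeFrames <- function(sim, dir, frames = seq_len(nrow(sim@truth)), ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Pall <- sim@points
  ps <- list(...)$pixel_scale
  if (is.null(ps)) ps <- 3.516
  paths <- character(0)
  for (f in frames) {
    pan <- renderPanorama(sim, f, ...)
    path <- file.path(dir, sprintf("frame_%04d.tif", f))
    tiff::writeTIFF(pan@pixels * 1.0, path, bits.per.sample = 8)
    paths <- c(paths, path)
  }
  write.csv(data.frame(frame = frames,
                       time_h = sim@truth$time_h[frames],
                       pixel_scale_um = ps),
            file.path(dir, "frames.csv"), row.names = FALSE)
  write.csv(sim@truth, file.path(dir, "truth.csv"), row.names = FALSE)
  write.csv(as.data.frame(simSegments(sim)),
            file.path(dir, "segments.csv"), row.names = FALSE)
  invisible(paths)
}
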