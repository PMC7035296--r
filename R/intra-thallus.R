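#' Extract the intra-thallus areas (enclosed faces) of one frame
#'
#' The thallus is the 8-connected foreground component containing
#' `center`; its intra-thallus areas are the 4-connected background
#' components completely enclosed by it (the holes of the component --
#' the faces of the planar network). Areas are pixel counts, also
#' reported in mm^2. Crescent-shaped faces whose geometric centroid falls
#' outside the face get the nearest interior pixel as representative
#' point (`crow`, `ccol`), used by the centroid-containment rules.
#'
#' @param mask binary matrix (0/1) or binary [Panorama-class].
#' @param center `c(row, col)` pixel on the thallus; `"auto"` picks the
#'   foreground pixel closest to the mask centroid.
#' @param pixel_scale µm per pixel (default 3.516, ignored when `mask` is
#'   a Panorama).
#' @param time_h frame time (ignored when `mask` is a Panorama).
#' @param min_face_px optional filter: drop faces smaller than this many
#'   pixels (default 0 = keep all).
#' @return a [FaceSet-class].
#' @export
extractFaces <- function(mask, center = "auto", pixel_scale = 3.516,
                         time_h = NA_real_, min_face_px = 0) {
  if (is(mask, "Panorama")) {
    pixel_scale <- mask@pixel_scale
    time_h <- mask@time_h
    mask <- mask@pixels
  }
  stopifnot(is.matrix(mask))
  fg <- mask > 0
  if (!any(fg)) stop("center not on thallus: empty mask")
  if (identical(center, "auto")) {
    idx <- which(fg)
    rows <- ((idx - 1L) %% nrow(mask)) + 1L
    cols <- ((idx - 1L) %/% nrow(mask)) + 1L
    ctr <- c(mean(rows), mean(cols))
    k <- which.min((rows - ctr[1])^2 + (cols - ctr[2])^2)
    center <- c(rows[k], cols[k])
  }
  center <- round(center)
  if (!fg[center[1], center[2]]) stop("center not on thallus")
  lab <- .cc_label(fg, 8L)
  comp <- lab == lab[center[1], center[2]]
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(
    matrix(as.integer(comp), nrow(mask), ncol(mask))))) > 0
  holes <- filled & !comp
  flab <- .cc_label(holes, 4L)
  nf <- max(flab)
  fdf <- data.frame(id = integer(0), area_px = integer(0),
                    area_mm2 = numeric(0), cx_um = numeric(0),
                    cy_um = numeric(0), crow = integer(0),
                    ccol = integer(0), appearance_time_h = numeric(0))
  if (nf > 0) {
    idx <- which(flab > 0)
    rows <- ((idx - 1L) %% nrow(mask)) + 1L
    cols <- ((idx - 1L) %/% nrow(mask)) + 1L
    ids <- factor(flab[idx], levels = seq_len(nf))
    area <- as.integer(table(ids))
    crow_m <- tapply(rows, ids, mean)
    ccol_m <- tapply(cols, ids, mean)
    crow <- integer(nf); ccol <- integer(nf)
    for (f in seq_len(nf)) {
      r0 <- round(crow_m[f]); c0 <- round(ccol_m[f])
      if (r0 >= 1 && r0 <= nrow(mask) && c0 >= 1 && c0 <= ncol(mask) &&
          flab[r0, c0] == f) {
        crow[f] <- r0; ccol[f] <- c0
      } else {
        sel <- which(as.integer(ids) == f)
        k <- which.min((rows[sel] - crow_m[f])^2 + (cols[sel] - ccol_m[f])^2)
        crow[f] <- rows[sel][k]; ccol[f] <- cols[sel][k]
      }
    }
    um <- .px_to_um(crow_m, ccol_m, pixel_scale)
    fdf <- data.frame(id = seq_len(nf), area_px = area,
                      area_mm2 = area * (pixel_scale / 1000)^2,
                      cx_um = um[, 1], cy_um = um[, 2],
                      crow = crow, ccol = ccol,
                      appearance_time_h = NA_real_)
    if (min_face_px > 0) {
      drop <- fdf$area_px < min_face_px
      if (any(drop)) {
        flab[flab %in% fdf$id[drop]] <- 0L
        fdf <- fdf[!drop, , drop = FALSE]
      }
    }
    rownames(fdf) <- NULL
  }
  new("FaceSet", faces = fdf, label_matrix = flab, time_h = time_h,
      pixel_scale = pixel_scale)
}

#' Summary statistics of a face set
#'
#' @param fs a [FaceSet-class].
#' @param n_classes number of natural-breaks area classes for mapping
#'   (default 8, Fisher-Jenks, ties to the lower class).
#' @return list with `n`, `S_mm2`, `S_px`, `mean_mm2`, `rel_std`
#'   (sd of the areas over their mean), `class_breaks` (mm^2) and
#'   `class` (per-face class index).
#' @export
faceStatistics <- function(fs, n_classes = 8) {
  stopifnot(is(fs, "FaceSet"))
  a <- faces(fs)$area_mm2
  if (!length(a)) stop("face set is empty")
  n <- length(a)
  S <- sum(a)
  m <- S / n
  rel <- if (n > 1) sd(a) / m else 0
  breaks <- if (n >= n_classes)
    .jenks_breaks(a, k = n_classes) else numeric(0)
  cls <- if (length(breaks)) findInterval(a, breaks, left.open = TRUE) + 1L
         else rep(1L, n)
  list(n = n, S_mm2 = S, S_px = sum(faces(fs)$area_px), mean_mm2 = m,
       rel_std = rel, class_breaks = breaks, class = cls)
}

#' Assign appearance times to faces across a frame series
#'
#' Chains faces through time by centroid containment, with two
#' conventions. `"child-in-parent"` (default, matching the fragmentation
#' bookkeeping): a face inherits the appearance time of the previous
#' frame's face that contains the current face's representative point, so
#' both halves of a subdivided face keep the parent's age and only faces
#' closed anew at the colony rim get a fresh date. `"parent-in-child"`: a
#' face inherits only if a previous face's representative point lies
#' inside it, so when a face splits exactly one child (the one containing
#' the parent's point) inherits and the other is dated at its own frame.
#'
#' @param framewise list of [FaceSet-class], ordered in time, sharing one
#'   raster geometry.
#' @param rule centroid convention, see above.
#' @return the list with `appearance_time_h` filled in every frame.
#' @export
appearanceTimes <- function(framewise,
                            rule = c("child-in-parent", "parent-in-child")) {
  rule <- match.arg(rule)
  stopifnot(length(framewise) >= 1,
            all(vapply(framewise, is, TRUE, "FaceSet")))
  prev <- NULL
  for (k in seq_along(framewise)) {
    fs <- framewise[[k]]
    fdf <- faces(fs)
    if (nrow(fdf)) {
      app <- rep(fs@time_h, nrow(fdf))
      if (!is.null(prev)) {
        pf <- faces(prev)
        if (rule == "child-in-parent") {
          pid <- prev@label_matrix[cbind(fdf$crow, fdf$ccol)]
          hit <- pid > 0
          app[hit] <- pf$appearance_time_h[match(pid[hit], pf$id)]
        } else if (nrow(pf)) {
          cur <- fs@label_matrix[cbind(pf$crow, pf$ccol)]
          for (j in which(cur > 0)) {
            tgt <- match(cur[j], fdf$id)
            app[tgt] <- min(app[tgt], pf$appearance_time_h[j])
          }
        }
      }
      fdf$appearance_time_h <- app
      framewise[[k]] <- initialize(fs, faces = fdf)
    }
    prev <- framewise[[k]]
  }
  framewise
}

#' Track the fragmentation of intra-thallus areas
#'
#' Partitions the faces into epoch cohorts: at each epoch (a frame taken
#' every `delta_t` from `t_start`), the faces whose representative point
#' does not fall inside any face of the previous epoch form the cohort of
#' newly created surfaces; all other faces belong to the cohort of the
#' face that contains them. Each cohort is then followed through the
#' later epochs, reporting its face count `n_prime` and mean area
#' (pixels) -- subdivision raises `n_prime` and drives the mean area
#' down.
#'
#' @param framewise list of [FaceSet-class] ordered in time.
#' @param t_start first epoch time, hours.
#' @param delta_t epoch spacing, hours (1.6 h, i.e. five panoramas, in
#'   the reference analysis).
#' @return data.frame: `cohort_t`, `epoch_t`, `n_prime`, `mean_area_px`,
#'   `total_area_px`.
#' @export
trackFragmentation <- function(framewise, t_start, delta_t) {
  stopifnot(length(framewise) >= 2)
  times <- vapply(framewise, function(f) f@time_h, 1)
  epochs <- seq(t_start, max(times) + 1e-9, by = delta_t)
  sel <- vapply(epochs, function(e) which.min(abs(times - e)), 1L)
  keep <- !duplicated(sel)
  sel <- sel[keep]; epochs <- times[sel]
  if (length(sel) < 2) stop("need at least two epochs inside the series")
  cohort <- list()  # per epoch: vector of cohort times, aligned to faces
  out <- NULL
  for (k in seq_along(sel)) {
    fs <- framewise[[sel[k]]]
    fdf <- faces(fs)
    co <- rep(epochs[k], nrow(fdf))
    if (k > 1 && nrow(fdf)) {
      prev <- framewise[[sel[k - 1]]]
      pid <- prev@label_matrix[cbind(fdf$crow, fdf$ccol)]
      hit <- pid > 0
      co[hit] <- cohort[[k - 1]][match(pid[hit], faces(prev)$id)]
    }
    cohort[[k]] <- co
    if (nrow(fdf)) {
      agg <- tapply(fdf$area_px, co, function(a)
        c(n = length(a), mean = mean(a), tot = sum(a)))
      out <- rbind(out, data.frame(
        cohort_t = as.numeric(names(agg)),
        epoch_t = epochs[k],
        n_prime = vapply(agg, `[[`, 1, "n"),
        mean_area_px = vapply(agg, `[[`, 1, "mean"),
        total_area_px = vapply(agg, `[[`, 1, "tot")))
    }
  }
  rownames(out) <- NULL
  out
}

#' Densification slope: face count against total length
#'
#' Least-squares slope of the face count `n` on the total hyphal length
#' `L` (mm), the rate at which densification subdivides the thallus
#' (about 1.7 faces per mm in the reference data).
#'
#' @param n_series face counts.
#' @param L_series_mm total lengths, mm.
#' @return list with `slope_per_mm`, `slope_se2`, `n`.
#' @export
densificationSlope <- function(n_series, L_series_mm) {
  stopifnot(length(n_series) == length(L_series_mm))
  ok <- is.finite(n_series) & is.finite(L_series_mm)
  if (sum(ok) < 3) stop("need at least 3 points")
  fit <- summary(lm(n_series[ok] ~ L_series_mm[ok]))$coefficients
  list(slope_per_mm = unname(fit[2, 1]), slope_se2 = unname(2 * fit[2, 2]),
       n = sum(ok))
}
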