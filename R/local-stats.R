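#' Build an annulus/sector partition
#'
#' Concentric annuli of equal radial width, each divided into equal-angle
#' (hence equal-area) sectors. The reference layout uses three annuli of
#' width 3516 µm with inner radii 1758, 3516 and 5274 µm and 60 sectors;
#' sector 1 starts at angle 0 (east), counterclockwise in the image frame
#' (y pointing down).
#'
#' @param center `c(x, y)` µm.
#' @param annuli two-column matrix of `(R_in, R_out)` µm; default the
#'   reference layout.
#' @param n_sectors sectors per annulus (default 60).
#' @return a [SectorGrid-class].
#' @export
buildSectorGrid <- function(center,
                            annuli = cbind(R_in = c(1758, 3516, 5274),
                                           R_out = c(5274, 7032, 8790)),
                            n_sectors = 60) {
  new("SectorGrid", center = as.numeric(center),
      annuli = as.matrix(annuli), n_sectors = as.integer(n_sectors))
}

#' Areas of the cells of a sector grid
#' @param grid a [SectorGrid-class].
#' @return matrix annuli x 1 of per-sector areas, µm^2.
#' @export
sectorAreas <- function(grid) {
  a <- grid@annuli
  pi * (a[, 2]^2 - a[, 1]^2) / grid@n_sectors
}

# cell of point(s): annulus index (0 = none) and sector index
.cell_of <- function(x, y, grid) {
  dx <- x - grid@center[1]; dy <- y - grid@center[2]
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx) %% (2 * pi)
  sec <- pmin(floor(th / (2 * pi / grid@n_sectors)) + 1L, grid@n_sectors)
  ann <- integer(length(x))
  for (k in seq_len(nrow(grid@annuli)))
    ann[r >= grid@annuli[k, 1] & r < grid@annuli[k, 2]] <- k
  list(annulus = ann, sector = sec)
}

#' Local measures per annulus sector
#'
#' Counts the apexes and nodes of the graph falling inside each sector
#' and clips every edge polyline against the annulus circles and sector
#' rays, so that an edge crossing a boundary contributes its inside
#' portion to each side exactly (the clipped pieces of one segment sum to
#' its full length). Node counts use the same degree-decomposition rule
#' as the global tally (a degree-d junction counts d - 2).
#'
#' @param graph a [NetworkGraph-class].
#' @param grid a [SectorGrid-class] in the same µm frame.
#' @param time_h measurement time.
#' @return a [SectorMeasures-class] with one row per (annulus, sector).
#' @export
sectorMeasures <- function(graph, grid, time_h = NA_real_) {
  stopifnot(is(graph, "NetworkGraph"), is(grid, "SectorGrid"))
  if (any(!is.finite(grid@center))) stop("center undefined")
  na <- nrow(grid@annuli); ns <- grid@n_sectors
  m <- expand.grid(sector = seq_len(ns), annulus = seq_len(na))
  m <- data.frame(annulus = m$annulus, sector = m$sector,
                  A = 0L, N = 0L, L_mm = 0)
  cell_row <- function(ann, sec) (ann - 1L) * ns + sec
  v <- graphVertices(graph)
  if (nrow(v)) {
    cl <- .cell_of(v$x_um, v$y_um, grid)
    ap <- which(v$degree == 1L & !v$boundary & cl$annulus > 0)
    for (i in ap) {
      r <- cell_row(cl$annulus[i], cl$sector[i])
      m$A[r] <- m$A[r] + 1L
    }
    nd <- which(v$degree >= 3L & cl$annulus > 0)
    for (i in nd) {
      r <- cell_row(cl$annulus[i], cl$sector[i])
      m$N[r] <- m$N[r] + (v$degree[i] - 2L)
    }
  }
  radii <- sort(unique(as.numeric(grid@annuli)))
  angles <- (seq_len(ns) - 1L) * 2 * pi / ns
  for (p in graph@polylines) {
    if (nrow(p) < 2) next
    for (s in seq_len(nrow(p) - 1)) {
      pieces <- .split_segment(p[s, ] - grid@center, p[s + 1, ] - grid@center,
                               radii, angles)
      for (q in pieces) {
        mid <- grid@center + (q$a + q$b) / 2
        cl <- .cell_of(mid[1], mid[2], grid)
        if (cl$annulus > 0) {
          r <- cell_row(cl$annulus, cl$sector)
          m$L_mm[r] <- m$L_mm[r] + q$len / 1000
        }
      }
    }
  }
  new("SectorMeasures", measures = m, grid = grid, time_h = time_h)
}

# split segment a->b (coordinates relative to the grid center) at every
# crossing of the given circles (radii) and sector rays (angles);
# returns list of pieces with endpoints (absolute-relative) and length
.split_segment <- function(a, b, radii, angles) {
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len == 0) return(list())
  ts <- c(0, 1)
  # circle crossings: |a + t d|^2 = R^2
  A <- sum(d^2); B <- 2 * sum(a * d)
  for (R in radii) {
    C <- sum(a^2) - R^2
    disc <- B^2 - 4 * A * C
    if (disc > 0) {
      rt <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
      ts <- c(ts, rt[rt > 0 & rt < 1])
    }
  }
  # ray crossings: only angles inside the segment's angular span can cross
  th_a <- atan2(a[2], a[1]) %% (2 * pi)
  th_b <- atan2(b[2], b[1]) %% (2 * pi)
  dth <- abs(th_a - th_b)
  dth <- min(dth, 2 * pi - dth)
  circ <- abs(angles - th_a)
  circ <- pmin(circ, 2 * pi - circ)
  for (th in angles[circ <= dth + 1e-9]) {
    u <- c(cos(th), sin(th))
    denom <- d[2] * u[1] - d[1] * u[2]
    if (abs(denom) < 1e-12) next
    t <- (a[1] * u[2] - a[2] * u[1]) / denom
    if (t > 0 && t < 1) {
      pnt <- a + t * d
      if (sum(pnt * u) > 0) ts <- c(ts, t)
    }
  }
  ts <- sort(unique(ts))
  out <- vector("list", length(ts) - 1)
  for (k in seq_len(length(ts) - 1)) {
    pa <- a + ts[k] * d; pb <- a + ts[k + 1] * d
    out[[k]] <- list(a = pa, b = pb, len = (ts[k + 1] - ts[k]) * len)
  }
  out
}

#' Median of the standardized sector distribution
#'
#' For each annulus and each quantity, standardizes the sector values as
#' `(x - mu_x) / sigma_x` and reports their median. A symmetric sector
#' distribution gives 0; degenerate annuli (all sectors equal,
#' `sigma_x = 0`) are flagged `NA`.
#'
#' @param measures a [SectorMeasures-class] or list of them (a time
#'   series).
#' @return data.frame: `time_h`, `annulus`, `quantity`, `median_std`.
#' @export
standardizedMedianSeries <- function(measures) {
  if (is(measures, "SectorMeasures")) measures <- list(measures)
  out <- NULL
  for (sm in measures) {
    df <- sectorTable(sm)
    for (ann in unique(df$annulus)) {
      sub <- df[df$annulus == ann, ]
      for (qn in c("A", "N", "L_mm")) {
        x <- sub[[qn]]
        s <- sd(x)
        v <- if (!is.finite(s) || s == 0) NA_real_ else
          median((x - mean(x)) / s)
        out <- rbind(out, data.frame(time_h = sm@time_h, annulus = ann,
                                     quantity = qn, median_std = v))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Mann-Whitney comparison of local node densities across experiments
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) tests on the per-sector
#' node densities `N_i / L_i` of two experiments, using alternate-sector
#' subsets (odd sectors of one experiment against even sectors of the
#' other, and so on) to keep the samples spatially independent. Sectors
#' with zero length are dropped (count reported). The exact null
#' distribution is used when there are no ties, the normal approximation
#' with tie correction otherwise.
#'
#' @param exp1,exp2 [SectorMeasures-class] objects or lists of them
#'   (matched time series).
#' @param subsets list of `c(subset1, subset2)` parity pairs to test;
#'   `"odd"`/`"even"`. Default: all four combinations.
#' @return data.frame: `time_h`, `annulus`, `subset1`, `subset2`, `p`,
#'   `n1`, `n2`, `dropped`.
#' @export
mannWhitneyCompare <- function(exp1, exp2,
                               subsets = list(c("odd", "odd"),
                                              c("odd", "even"),
                                              c("even", "odd"),
                                              c("even", "even"))) {
  if (is(exp1, "SectorMeasures")) exp1 <- list(exp1)
  if (is(exp2, "SectorMeasures")) exp2 <- list(exp2)
  stopifnot(length(exp1) == length(exp2))
  pick <- function(df, ann, parity) {
    sub <- df[df$annulus == ann, ]
    sel <- if (parity == "odd") sub$sector %% 2 == 1 else sub$sector %% 2 == 0
    sub <- sub[sel, ]
    ok <- sub$L_mm > 0
    list(x = sub$N[ok] / sub$L_mm[ok], dropped = sum(!ok))
  }
  out <- NULL
  for (k in seq_along(exp1)) {
    d1 <- sectorTable(exp1[[k]]); d2 <- sectorTable(exp2[[k]])
    for (ann in intersect(unique(d1$annulus), unique(d2$annulus))) {
      for (ss in subsets) {
        s1 <- pick(d1, ann, ss[1]); s2 <- pick(d2, ann, ss[2])
        p <- if (length(s1$x) >= 2 && length(s2$x) >= 2)
          suppressWarnings(wilcox.test(s1$x, s2$x,
                                       alternative = "two.sided")$p.value)
          else NA_real_
        out <- rbind(out, data.frame(
          time_h = exp1[[k]]@time_h, annulus = ann,
          subset1 = ss[1], subset2 = ss[2], p = p,
          n1 = length(s1$x), n2 = length(s2$x),
          dropped = s1$dropped + s2$dropped))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Null model for sector measures
#'
#' Generates a [SectorMeasures-class] whose sector values are independent
#' draws from a stationary null (Poisson apex/node counts, gamma length),
#' identical in distribution across sectors -- the reference case for
#' calibrating the type-I error of [mannWhitneyCompare()].
#'
#' @param grid a [SectorGrid-class].
#' @param mean_A,mean_N Poisson means of the per-sector counts.
#' @param mean_L_mm,cv_L mean and coefficient of variation of the
#'   per-sector length.
#' @param time_h nominal time stamp.
#' @param seed integer seed.
#' @return a [SectorMeasures-class].
#' @export
nullSectorMeasures <- function(grid, mean_A = 5, mean_N = 8,
                               mean_L_mm = 2, cv_L = 0.4,
                               time_h = 0, seed = 1) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  na <- nrow(grid@annuli); ns <- grid@n_sectors
  n <- na * ns
  shape <- 1 / cv_L^2
  m <- data.frame(
    annulus = rep(seq_len(na), each = ns),
    sector = rep(seq_len(ns), na),
    A = stats::rpois(n, mean_A),
    N = stats::rpois(n, mean_N),
    L_mm = stats::rgamma(n, shape = shape, rate = shape / mean_L_mm))
  new("SectorMeasures", measures = m, grid = grid, time_h = time_h)
}
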