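# Internal helpers shared across modules.

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(saved) {
  if (!is.null(saved))
    assign(".Random.seed", saved, envir = globalenv())
  invisible(NULL)
}

# pixel centre (row, col) -> micrometres (x right, y down, origin at the
# top-left corner of pixel (1,1))
.px_to_um <- function(row, col, pixel_scale) {
  cbind(x_um = (col - 0.5) * pixel_scale, y_um = (row - 0.5) * pixel_scale)
}

.polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

# moving-average smoothing of a polyline, endpoints kept fixed
.smooth_polyline <- function(p, window = 5) {
  n <- nrow(p)
  if (n <= window || window < 3) return(p)
  half <- window %/% 2
  sm <- apply(p, 2, function(z) {
    cs <- cumsum(c(0, z))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  })
  sm[1, ] <- p[1, ]
  sm[n, ] <- p[n, ]
  sm
}

# small enclosed background region (a hole of at most `cap` pixels not
# reaching the raster border) containing (r, c): returns its pixels as a
# two-column matrix, or NULL. 4-connected BFS.
.enclosed_bg_region <- function(fg, r, c, cap = 25L) {
  nr <- nrow(fg); nc <- ncol(fg)
  if (fg[r, c]) return(NULL)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  stack <- list(c(r, c))
  seen[[paste(r, c)]] <- TRUE
  out <- matrix(0L, cap, 2)
  size <- 0L
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    size <- size + 1L
    if (size > cap) return(NULL)
    if (p[1] <= 1L || p[1] >= nr || p[2] <= 1L || p[2] >= nc) return(NULL)
    out[size, ] <- p
    for (d in 1:4) {
      r2 <- p[1] + c(-1L, 1L, 0L, 0L)[d]
      c2 <- p[2] + c(0L, 0L, -1L, 1L)[d]
      key <- paste(r2, c2)
      if (!fg[r2, c2] && is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        stack[[length(stack) + 1L]] <- c(r2, c2)
      }
    }
  }
  out[seq_len(size), , drop = FALSE]
}

# shift a matrix by (dr, dc), padding with 0
.shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Fisher-Jenks natural-breaks classification. Exact dynamic programme on
# the sorted values; inputs with more than `max_n` values are condensed to
# `max_n` weighted quantile bins first so the O(k n^2) DP stays tractable.
# Ties are broken toward the lower class. Returns the k-1 interior breaks.
.jenks_breaks <- function(x, k = 8, max_n = 800) {
  x <- sort(x[is.finite(x)])
  n0 <- length(x)
  if (n0 < k) stop("need at least k values")
  if (n0 > max_n) {
    w_x <- x
    idx <- round(seq(1, n0, length.out = max_n))
    x <- x[idx]
    w <- diff(c(0, idx))
  } else {
    w <- rep(1, n0)
  }
  n <- length(x)
  cw <- cumsum(w); cwx <- cumsum(w * x); cwx2 <- cumsum(w * x^2)
  ssd <- function(i, j) { # weighted SSD of x[i..j]
    W <- cw[j] - if (i > 1) cw[i - 1] else 0
    S <- cwx[j] - if (i > 1) cwx[i - 1] else 0
    S2 <- cwx2[j] - if (i > 1) cwx2[i - 1] else 0
    S2 - S^2 / W
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in seq_len(n)) D[1, j] <- ssd(1, j)
  for (cl in 2:k) {
    for (j in cl:n) {
      prev <- (cl - 1):(j - 1)
      cand <- D[cl - 1, prev] + vapply(prev + 1, ssd, 1, j = j)
      m <- which.min(cand)
      D[cl, j] <- cand[m]
      B[cl, j] <- prev[m]
    }
  }
  breaks <- numeric(k - 1)
  j <- n
  for (cl in k:2) {
    j <- B[cl, j]
    breaks[cl - 1] <- x[j]
    }
  sort(breaks)
}
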