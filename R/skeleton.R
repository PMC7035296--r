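# Morphological thinning (Zhang-Suen) and skeleton-pixel helpers.
# Operates on 0/1 integer matrices; fully vectorized over the raster.

# neighbours clockwise from north: P2..P9 as matrices aligned on (i,j)
.neighbours8 <- function(m) {
  list(P2 = .shift_mat(m, 1, 0),   # (i-1, j)
       P3 = .shift_mat(m, 1, -1),  # (i-1, j+1)
       P4 = .shift_mat(m, 0, -1),  # (i,   j+1)
       P5 = .shift_mat(m, -1, -1), # (i+1, j+1)
       P6 = .shift_mat(m, -1, 0),  # (i+1, j)
       P7 = .shift_mat(m, -1, 1),  # (i+1, j-1)
       P8 = .shift_mat(m, 0, 1),   # (i,   j-1)
       P9 = .shift_mat(m, 1, 1))   # (i-1, j-1)
}

#' Thin a binary mask to a one-pixel-wide skeleton
#'
#' Zhang-Suen iterative thinning (8-connectivity). Topology-preserving:
#' connected components and enclosed holes of the mask survive in the
#' skeleton, which is what makes skeleton-graph cycle counts comparable
#' with face counts.
#'
#' @param mask binary matrix (0/1 or logical).
#' @return integer 0/1 matrix of the same dimension.
#' @export
thinMask <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- .neighbours8(m)
      B <- nb$P2 + nb$P3 + nb$P4 + nb$P5 + nb$P6 + nb$P7 + nb$P8 + nb$P9
      seqs <- nb[c("P2", "P3", "P4", "P5", "P6", "P7", "P8", "P9", "P2")]
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) A <- A + (seqs[[k]] == 0L & seqs[[k + 1]] == 1L)
      if (sub == 1) {
        c1 <- nb$P2 * nb$P4 * nb$P6 == 0L
        c2 <- nb$P4 * nb$P6 * nb$P8 == 0L
      } else {
        c1 <- nb$P2 * nb$P4 * nb$P8 == 0L
        c2 <- nb$P2 * nb$P6 * nb$P8 == 0L
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c1 & c2
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# number of 8-neighbours that are skeleton pixels
.neighbour_count <- function(m) {
  nb <- .neighbours8(m)
  Reduce(`+`, nb)
}
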