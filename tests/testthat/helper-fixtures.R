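# Shared fixtures: small rasters drawn in code and cached simulations.

# draw a stroke of disc radius `w` px along (x0,y0)->(x1,y1), pixel coords
draw_stroke <- function(m, x0, y0, x1, y1, w = 3) {
  n <- max(2L, ceiling(sqrt((x1 - x0)^2 + (y1 - y0)^2) / 0.3))
  for (k in 0:n) {
    r <- round(y0 + (y1 - y0) * k / n)
    c <- round(x0 + (x1 - x0) * k / n)
    for (dr in -w:w) for (dc in -w:w) {
      if (dr^2 + dc^2 > w^2) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m))
        m[rr, cc] <- 1L
    }
  }
  m
}

# Y-shaped mask: three arms of `arm_px` pixels at 120 degrees
y_mask <- function(arm_px = 28.4, size = 141, w = 3) {
  m <- matrix(0L, size, size)
  ctr <- (size + 1) / 2
  for (th in pi / 2 + c(0, 2 * pi / 3, 4 * pi / 3))
    m <- draw_stroke(m, ctr, ctr, ctr + arm_px * cos(th),
                     ctr + arm_px * sin(th), w)
  m
}

# X crossing mask
x_mask <- function(size = 121, w = 3) {
  m <- matrix(0L, size, size)
  ctr <- (size + 1) / 2
  m <- draw_stroke(m, ctr - 40, ctr - 40, ctr + 40, ctr + 40, w)
  draw_stroke(m, ctr - 40, ctr + 40, ctr + 40, ctr - 40, w)
}

# filled annulus (ring): one enclosed face
ring_mask <- function(size = 101, r_out = 35, r_in = 25) {
  ctr <- (size + 1) / 2
  d2 <- outer(seq_len(size) - ctr, seq_len(size) - ctr,
              function(a, b) a^2 + b^2)
  matrix(as.integer(d2 <= r_out^2 & d2 >= r_in^2), size, size)
}

# cached spatial simulations (several test files reuse the same runs)
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed, duration, mode = "proximity") {
  key <- paste(seed, duration, mode)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulateNetwork(
      simParams(duration = duration, seed = seed, anastomosis_mode = mode))
  .sim_cache[[key]]
}

# a NetworkGraph built directly from tables (for unit tests of operations
# that consume graphs)
manual_graph <- function(vertices, edges, pixel_scale = 3.516,
                         dim_px = c(1000, 1000)) {
  polys <- lapply(seq_len(nrow(edges)), function(i) {
    a <- vertices[match(edges$from[i], vertices$id), c("x_um", "y_um")]
    b <- vertices[match(edges$to[i], vertices$id), c("x_um", "y_um")]
    rbind(as.numeric(a), as.numeric(b))
  })
  new("NetworkGraph", vertices = vertices, edges = edges,
      polylines = polys, pixel_scale = pixel_scale, dim_px = dim_px,
      pruned_spurs = 0)
}

# cycle rank of the largest connected component of an extracted graph
main_cycle_rank <- function(g) {
  e <- graphEdges(g)
  if (!nrow(e)) return(0L)
  ig <- igraph::graph_from_edgelist(as.matrix(e[, 1:2]), directed = FALSE)
  comp <- igraph::components(ig)$membership
  tab <- table(comp[e$from])
  main <- as.integer(names(tab)[which.max(tab)])
  sum(comp[e$from] == main) - sum(comp == main) + 1L
}
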