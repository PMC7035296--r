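#' Extract the centerline graph of a binary thallus mask
#'
#' Skeletonizes the mask (Zhang-Suen), builds the skeleton-pixel graph on
#' a reduced adjacency (a diagonal link is kept only when no orthogonal
#' two-step path exists, which dissolves staircase artifacts of the
#' thinning), classifies pixels into junctions (>= 3 neighbours) and
#' chain pixels, collapses junction-pixel clusters lying within one hypha
#' radius into single vertices, and traces the chains between them into
#' edge polylines with Euclidean lengths in micrometres. Short terminal
#' spurs (skeletonization artifacts shorter than one hypha width) are
#' pruned, isolated components below a minimum size are dropped, and
#' apexes within a border margin are flagged `boundary` (cut by the field
#' of view).
#'
#' @param mask binary matrix (0 background, >0 hypha).
#' @param pixel_scale µm per pixel (default 3.516).
#' @param hypha_width typical rasterized hypha width, pixels (default 7);
#'   sets the default spur threshold.
#' @param junction_merge_px junction-pixel clusters with centroids within
#'   this radius are collapsed into one vertex (default 2: thinning
#'   splits one biological junction into clusters at most a couple of
#'   pixels apart, while genuinely distinct overlap nodes stay separate).
#' @param spur_min_px terminal spurs shorter than this are pruned
#'   (default `hypha_width / 2`, the stroke radius: tip caps cannot
#'   produce longer artifacts).
#' @param min_component_px drop skeleton components smaller than this
#'   (default `2 * hypha_width`).
#' @param border_margin_px apexes within this many pixels of the raster
#'   border are flagged (default `2 + ceiling(hypha_width/2)`: thinning
#'   retreats the endpoint of a border-cut stroke by about half a stroke
#'   width, so the margin covers the 2-px band plus that erosion).
#' @param prune_spurs prune short terminal spurs (default TRUE).
#' @return a [NetworkGraph-class]; empty mask gives an empty graph.
#' @export
extractGraph <- function(mask, pixel_scale = 3.516, hypha_width = 7,
                         junction_merge_px = 2,
                         spur_min_px = hypha_width / 2,
                         min_component_px = 2 * hypha_width,
                         border_margin_px = 2 + ceiling(hypha_width / 2),
                         prune_spurs = TRUE) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  empty <- function() new("NetworkGraph",
    vertices = data.frame(id = integer(0), x_um = numeric(0),
                          y_um = numeric(0), degree = integer(0),
                          kind = character(0), boundary = logical(0)),
    edges = data.frame(from = integer(0), to = integer(0),
                       length_um = numeric(0)),
    polylines = list(), pixel_scale = pixel_scale, dim_px = c(nr, nc),
    pruned_spurs = 0)
  Ml <- mask > 0
  S <- thinMask(mask)
  if (!any(S == 1L)) return(empty())

  # drop small isolated components
  lab <- .cc_label(S == 1L, 8L)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_component_px)
  if (length(small)) S[lab %in% small] <- 0L
  if (!any(S == 1L)) return(empty())

  # --- skeleton-pixel graph on reduced adjacency ------------------------
  px <- which(S == 1L)               # linear indices, column-major
  npx <- length(px)
  pid <- integer(nr * nc)            # pixel -> node id
  pid[px] <- seq_len(npx)
  prow <- ((px - 1L) %% nr) + 1L
  pcol <- ((px - 1L) %/% nr) + 1L
  Sl <- S == 1L
  at <- function(dr, dc) {           # is the (dr,dc) neighbour skeleton?
    r <- prow + dr; c <- pcol + dc
    ok <- r >= 1L & r <= nr & c >= 1L & c <= nc
    res <- logical(npx)
    res[ok] <- Sl[cbind(r[ok], c[ok])]
    res
  }
  nb_id <- function(dr, dc) pid[px + dr + dc * nr]
  e_right <- which(at(0, 1))
  e_down <- which(at(1, 0))
  e_se <- which(at(1, 1) & !at(0, 1) & !at(1, 0))
  e_ne <- which(at(-1, 1) & !at(0, 1) & !at(-1, 0))
  efrom <- c(e_right, e_down, e_se, e_ne)
  eto <- c(nb_id(0, 1)[e_right], nb_id(1, 0)[e_down],
           nb_id(1, 1)[e_se], nb_id(-1, 1)[e_ne])
  adj <- vector("list", npx)
  if (length(efrom)) {
    alla <- c(efrom, eto); allb <- c(eto, efrom)
    o <- order(alla)
    adj <- unname(split(allb[o], factor(alla[o], levels = seq_len(npx))))
  }
  deg_px <- lengths(adj)
  isJ <- deg_px >= 3L

  # --- junction clusters ------------------------------------------------
  merge_radius <- junction_merge_px
  jcl_raw <- integer(npx)            # raw cluster per J pixel
  ncl_raw <- 0L
  if (any(isJ)) {
    jj <- which(isJ)
    # components over J-J reduced edges
    jedges <- cbind(efrom, eto)
    jedges <- jedges[isJ[efrom] & isJ[eto], , drop = FALSE]
    g <- igraph::make_empty_graph(n = length(jj), directed = FALSE)
    if (nrow(jedges)) {
      remap <- integer(npx); remap[jj] <- seq_along(jj)
      g <- igraph::add_edges(g, t(cbind(remap[jedges[, 1]],
                                        remap[jedges[, 2]])))
    }
    memb <- igraph::components(g)$membership
    jcl_raw[jj] <- memb
    ncl_raw <- max(memb)
  }
  # merge clusters whose centroids are within one hypha radius
  jmap <- seq_len(max(ncl_raw, 0L))
  ncl <- ncl_raw
  cent <- NULL
  if (ncl_raw > 0) {
    f <- factor(jcl_raw[jcl_raw > 0], levels = seq_len(ncl_raw))
    cent <- cbind(row = tapply(prow[jcl_raw > 0], f, mean),
                  col = tapply(pcol[jcl_raw > 0], f, mean))
    if (ncl_raw > 1) {
      d <- as.matrix(dist(cent))
      adjm <- d <= merge_radius
      diag(adjm) <- FALSE
      if (any(adjm)) {
        gm <- igraph::graph_from_adjacency_matrix(adjm, mode = "undirected")
        jmap <- igraph::components(gm)$membership
      }
    }
    ncl <- max(jmap)
    fm <- factor(jmap, levels = seq_len(ncl))
    cent <- cbind(row = tapply(cent[, "row"], fm, mean),
                  col = tapply(cent[, "col"], fm, mean))
  }
  cluster_of <- function(node) {     # merged cluster id of a J node
    r <- jcl_raw[node]
    ifelse(r > 0, jmap[r], 0L)
  }

  # --- chains -----------------------------------------------------------
  chain_member <- integer(npx)
  if (any(!isJ)) {
    ce <- cbind(efrom, eto)
    ce <- ce[!isJ[efrom] & !isJ[eto], , drop = FALSE]
    cc_nodes <- which(!isJ)
    remap <- integer(npx); remap[cc_nodes] <- seq_along(cc_nodes)
    gch <- igraph::make_empty_graph(n = length(cc_nodes), directed = FALSE)
    if (nrow(ce))
      gch <- igraph::add_edges(gch, t(cbind(remap[ce[, 1]],
                                            remap[ce[, 2]])))
    chain_member[cc_nodes] <- igraph::components(gch)$membership
  }
  nch <- max(chain_member)

  verts <- list()
  vid <- ncl
  edges_from <- integer(0); edges_to <- integer(0)
  polys <- list()

  j_neighbours <- function(node) {
    nb <- adj[[node]]
    unique(cluster_of(nb[isJ[nb]]))
  }
  chain_adj <- function(node) {
    nb <- adj[[node]]
    nb[!isJ[nb]]
  }

  # slivers of enclosed background already accounted for by a loop edge
  claimed <- new.env(hash = TRUE, parent = emptyenv())
  claim_slivers <- function(ord_px) {
    # claim every small enclosed hole adjacent to these pixels; returns
    # TRUE when at least one previously unclaimed hole was found
    found <- FALSE
    for (pp in ord_px) {
      for (d in 1:4) {
        r2 <- prow[pp] + c(-1L, 1L, 0L, 0L)[d]
        c2 <- pcol[pp] + c(0L, 0L, -1L, 1L)[d]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || Ml[r2, c2]) next
        if (!is.null(claimed[[paste(r2, c2)]])) next
        reg <- .enclosed_bg_region(Ml, r2, c2, 25L)
        if (is.null(reg)) next
        for (q in seq_len(nrow(reg)))
          claimed[[paste(reg[q, 1], reg[q, 2])]] <- TRUE
        found <- TRUE
      }
    }
    found
  }

  for (ch in seq_len(nch)) {
    members <- which(chain_member == ch)
    n <- length(members)
    deg_in <- vapply(members, function(k) length(chain_adj(k)), 1L)
    ends <- members[deg_in <= 1L]
    is_cycle <- length(ends) == 0L
    start <- if (is_cycle) members[1] else ends[1]
    ord <- integer(n)
    visited <- logical(npx)
    cur <- start; ord[1] <- cur; visited[cur] <- TRUE
    k <- 1L
    while (k < n) {
      nxt <- chain_adj(cur)
      nxt <- nxt[!visited[nxt]]
      if (!length(nxt)) break
      cur <- nxt[1]
      k <- k + 1L
      ord[k] <- cur
      visited[cur] <- TRUE
    }
    ord <- ord[seq_len(k)]
    end1 <- ord[1]; end2 <- ord[k]
    if (is_cycle) {
      vid <- vid + 1L
      verts[[length(verts) + 1L]] <- c(prow[end1], pcol[end1], vid)
      v1 <- v2 <- vid
      pts <- cbind(prow[ord], pcol[ord])
      pts <- rbind(pts, pts[1, ])
    } else {
      c1 <- j_neighbours(end1)
      c2 <- j_neighbours(end2)
      c1 <- c1[c1 > 0]; c2 <- c2[c2 > 0]
      # prefer distinct clusters when one end sees several
      v1 <- if (length(c1)) c1[1] else 0L
      v2 <- if (length(c2)) {
        alt <- setdiff(c2, v1)
        if (length(alt)) alt[1] else c2[1]
      } else 0L
      if (v1 == 0L && length(c1) == 0L) {
        vid <- vid + 1L
        verts[[length(verts) + 1L]] <- c(prow[end1], pcol[end1], vid)
        v1 <- vid
      }
      if (v2 == 0L) {
        vid <- vid + 1L
        verts[[length(verts) + 1L]] <- c(prow[end2], pcol[end2], vid)
        v2 <- vid
      }
      pts <- cbind(prow[ord], pcol[ord])
      if (v1 <= ncl) pts <- rbind(cent[v1, c("row", "col")], pts)
      if (v2 <= ncl) pts <- rbind(pts, cent[v2, c("row", "col")])
    }
    if (v1 == v2) {
      if (v1 <= ncl && k <= 2L) {
        # degenerate micro-loop absorbed by one merged cluster: keep it
        # only when it encircles a genuine enclosed background sliver
        # that no other loop already accounts for
        if (!claim_slivers(ord)) next
      } else {
        # ordinary self-loop or isolated ring: claim its slivers so that
        # neighbouring micro-chains do not duplicate the cycle
        claim_slivers(ord)
      }
    }
    edges_from <- c(edges_from, v1); edges_to <- c(edges_to, v2)
    polys[[length(polys) + 1L]] <- pts
  }

  # direct junction-junction contacts across different merged clusters
  if (ncl > 0 && length(efrom)) {
    jj_e <- isJ[efrom] & isJ[eto]
    ca <- cluster_of(efrom[jj_e]); cb <- cluster_of(eto[jj_e])
    cross <- ca != cb
    if (any(cross)) {
      pairs <- unique(cbind(pmin(ca[cross], cb[cross]),
                            pmax(ca[cross], cb[cross])))
      for (kk in seq_len(nrow(pairs))) {
        a <- pairs[kk, 1]; b <- pairs[kk, 2]
        edges_from <- c(edges_from, a); edges_to <- c(edges_to, b)
        polys[[length(polys) + 1L]] <- rbind(cent[a, c("row", "col")],
                                             cent[b, c("row", "col")])
      }
    }
  }

  # --- vertex table, lengths, pruning -----------------------------------
  vtab <- data.frame(id = integer(0), row = numeric(0), col = numeric(0))
  if (ncl > 0)
    vtab <- data.frame(id = seq_len(ncl), row = cent[, "row"],
                       col = cent[, "col"])
  if (length(verts)) {
    vm <- do.call(rbind, verts)
    vtab <- rbind(vtab, data.frame(id = vm[, 3], row = vm[, 1],
                                   col = vm[, 2]))
  }
  vtab <- vtab[order(vtab$id), ]

  polys_um <- lapply(polys, function(p) {
    um <- .px_to_um(p[, 1], p[, 2], pixel_scale)
    .smooth_polyline(um, window = 5)
  })
  lens <- vapply(polys_um, .polyline_length, 1)
  edges <- data.frame(from = edges_from, to = edges_to, length_um = lens)

  degree_of <- function(ed) {
    d <- integer(nrow(vtab))
    if (nrow(ed)) {
      t1 <- tabulate(ed$from, nbins = nrow(vtab))
      t2 <- tabulate(ed$to, nbins = nrow(vtab))
      d <- t1 + t2
    }
    d
  }
  deg <- degree_of(edges)

  pruned <- 0L
  if (prune_spurs && nrow(edges)) {
    spur_um <- spur_min_px * pixel_scale
    repeat {
      tip_end <- (deg[edges$from] == 1L & deg[edges$to] >= 3L) |
                 (deg[edges$to] == 1L & deg[edges$from] >= 3L)
      cand <- which(tip_end & edges$length_um < spur_um)
      if (!length(cand)) break
      drop <- cand[which.min(edges$length_um[cand])]
      edges <- edges[-drop, , drop = FALSE]
      polys_um <- polys_um[-drop]
      pruned <- pruned + 1L
      deg <- degree_of(edges)
    }
  }

  keepv <- deg > 0L
  newid <- cumsum(keepv)
  vtab <- vtab[keepv, , drop = FALSE]
  deg <- deg[keepv]
  edges$from <- newid[edges$from]
  edges$to <- newid[edges$to]
  vtab$id <- seq_len(nrow(vtab))

  um <- .px_to_um(vtab$row, vtab$col, pixel_scale)
  kind <- ifelse(deg == 1L, "apex", ifelse(deg >= 3L, "node", "hypha"))
  boundary <- deg == 1L &
    (vtab$row <= border_margin_px | vtab$row > nr - border_margin_px |
     vtab$col <= border_margin_px | vtab$col > nc - border_margin_px)
  vertices <- data.frame(id = vtab$id, x_um = um[, 1], y_um = um[, 2],
                         degree = deg, kind = kind, boundary = boundary)
  rownames(vertices) <- NULL
  rownames(edges) <- NULL
  new("NetworkGraph", vertices = vertices, edges = edges,
      polylines = polys_um, pixel_scale = pixel_scale, dim_px = c(nr, nc),
      pruned_spurs = pruned)
}

#' Classify vertices and tally one frame
#'
#' Apexes are degree-1 vertices (boundary-flagged ones excluded from the
#' count: they are cut by the field of view); geometrical nodes are
#' degree-3 vertices, with any vertex of degree d >= 4 decomposed into
#' d - 2 adjacent degree-3 nodes (a perfect crossing therefore tallies as
#' two very close nodes). Count uncertainties are Poisson.
#'
#' @param graph a [NetworkGraph-class].
#' @param time time of the frame, hours.
#' @param frame frame index.
#' @return one-row data.frame: `frame`, `time_h`, `A`, `Ng`, `L_mm`,
#'   `sigma_A`, `sigma_Ng`, `sigma_L` (NA; see [lengthUncertainty()]),
#'   plus `n_decomposed` (vertices of degree >= 4 that were decomposed)
#'   and `n_boundary` (excluded boundary apexes).
#' @export
classifyAndTally <- function(graph, time = NA_real_, frame = NA_integer_) {
  stopifnot(is(graph, "NetworkGraph"))
  v <- graphVertices(graph)
  A <- sum(v$degree == 1L & !v$boundary)
  hi <- v$degree >= 3L
  Ng <- sum(pmax(v$degree[hi] - 2L, 1L))
  L_mm <- sum(graphEdges(graph)$length_um) / 1000
  data.frame(frame = frame, time_h = time, A = A, Ng = Ng, L_mm = L_mm,
             sigma_A = sqrt(A), sigma_Ng = sqrt(Ng), sigma_L = NA_real_,
             n_decomposed = sum(v$degree >= 4L),
             n_boundary = sum(v$degree == 1L & v$boundary))
}

#' Total network length with polyline refinement
#'
#' Sums the Euclidean lengths of all edge polylines. Chord sums
#' systematically underestimate curved hyphae, so each polyline with at
#' least three vertices is interpolated by a cubic spline (parameterized
#' by cumulative chord length) and resampled on nested grids of doubling
#' density until two successive estimates differ by less than
#' `refinement_tolerance`; nesting makes the estimate monotonically
#' non-decreasing across refinement levels.
#'
#' @param graph a [NetworkGraph-class], or a list of polylines (two-column
#'   µm matrices).
#' @param refinement_tolerance relative convergence tolerance (default
#'   0.001, i.e. 0.1 %).
#' @param max_levels maximum number of doublings (default 6).
#' @return total length in mm, with attribute `levels_used`.
#' @export
totalLength <- function(graph, refinement_tolerance = 0.001,
                        max_levels = 6) {
  stopifnot(refinement_tolerance > 0)
  polys <- if (is(graph, "NetworkGraph")) graph@polylines else graph
  if (!length(polys)) return(structure(0, levels_used = 0L))
  total_at <- function(level) {
    sum(vapply(polys, function(p) {
      if (nrow(p) < 3 || level == 0) return(.polyline_length(p))
      .refined_length(p, level)
    }, 1))
  }
  prev <- total_at(0)
  lev <- 0L
  while (lev < max_levels) {
    lev <- lev + 1L
    cur <- total_at(lev)
    if (abs(cur - prev) <= refinement_tolerance * max(cur,
                                                      .Machine$double.eps)) {
      prev <- cur
      break
    }
    prev <- cur
  }
  structure(prev / 1000, levels_used = lev)
}

# chord length of the spline through polyline p sampled with 2^level
# subdivisions per original interval (nested grids)
.refined_length <- function(p, level) {
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  dup <- duplicated(s)
  if (any(dup)) { s <- s[!dup]; p <- p[!dup, , drop = FALSE] }
  if (nrow(p) < 3) return(.polyline_length(p))
  k <- 2^level
  ss <- unlist(lapply(seq_len(length(s) - 1), function(i)
    seq(s[i], s[i + 1], length.out = k + 1)[-(k + 1)]))
  ss <- c(ss, s[length(s)])
  x <- spline(s, p[, 1], xout = ss, method = "fmm")$y
  y <- spline(s, p[, 2], xout = ss, method = "fmm")$y
  sum(sqrt(diff(x)^2 + diff(y)^2))
}
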