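test_that("proximity node count follows the pixel-distance definition", {
  v <- data.frame(id = 1:4,
                  x_um = c(0, 10 * 3.516, 500, 1000),
                  y_um = c(0, 0, 500, 1000),
                  degree = c(3L, 3L, 1L, 1L),
                  kind = c("node", "node", "apex", "apex"),
                  boundary = FALSE)
  e <- data.frame(from = c(1, 2, 3), to = c(2, 3, 4),
                  length_um = c(35, 700, 700))
  g <- manual_graph(v, e)
  expect_equal(proximityNodeCount(g, n_px = 20), 2)   # 10 px apart
  expect_equal(proximityNodeCount(g, n_px = 5), 0)
  # isolated single node
  v1 <- v[c(1, 3), ]; e1 <- data.frame(from = 1, to = 3, length_um = 700)
  expect_equal(proximityNodeCount(manual_graph(v1, e1), n_px = 50), 0)
  # a degree-4 vertex counts as two coincident nodes, always close
  v4 <- v; v4$degree[1] <- 4L
  expect_equal(proximityNodeCount(manual_graph(v4, e), n_px = 5), 2)
})

test_that("the close-node ratio is scale free", {
  set.seed(3)
  v <- data.frame(id = 1:20, x_um = runif(20, 0, 2000),
                  y_um = runif(20, 0, 2000), degree = 3L,
                  kind = "node", boundary = FALSE)
  e <- data.frame(from = 1:19, to = 2:20, length_um = 100)
  g1 <- manual_graph(v, e)
  v2 <- v; v2$x_um <- 2 * v2$x_um; v2$y_um <- 2 * v2$y_um
  g2 <- manual_graph(v2, e)
  expect_equal(proximityNodeCount(g1, n_px = 40),
               proximityNodeCount(g2, n_px = 80))
})

test_that("biological node estimate and its uncertainty are propagated", {
  # no close nodes: N equals Ng exactly
  est0 <- biologicalNodeEstimate(Ng = c(50, 80), Ng_close = c(0, 0))
  expect_equal(est0$N, c(50, 80))
  expect_equal(est0$r_pooled, 0)
  # reference operating point: N = 80, dN ~ 9.33
  est <- biologicalNodeEstimate(100, 20, r_override = 0.2,
                                sigma_r_override = 0.016)
  expect_equal(est$N, 80)
  expect_equal(est$sigma_N, sqrt((0.8 * 10)^2 + (100 * 0.048)^2),
               tolerance = 1e-9)
  # Monte-Carlo cross-check of the quadrature
  set.seed(1)
  mc <- sd((1 - (0.2 + 0.048 * rnorm(2e5))) * (100 + 10 * rnorm(2e5)))
  expect_lt(abs(est$sigma_N - mc) / mc, 0.05)
  # the "at least 80% biological" bound with ~5% uncertainty
  expect_equal(1 - est$r_pooled, 0.8)
  expect_lt(3 * est$sigma_r, 0.05)
  expect_error(biologicalNodeEstimate(c(0, 0), c(0, 0)), "no nodes")
})

test_that("count uncertainty is the Poisson square root", {
  expect_equal(countUncertainty(9), 3)
  expect_equal(countUncertainty(0), 0)
  expect_equal(round(countUncertainty(4930), 1), 70.2)
})

test_that("node-exclusion length resampling scales as sqrt(L) for iid edges", {
  make_iid_graph <- function(n_nodes, seed = n_nodes) {
    set.seed(seed)
    v <- data.frame(id = seq_len(2 * n_nodes),
                    x_um = rep(seq_len(n_nodes) * 1000, 2),
                    y_um = rep(c(0, 1000), each = n_nodes),
                    degree = rep(c(3L, 1L), each = n_nodes),
                    kind = rep(c("node", "apex"), each = n_nodes),
                    boundary = FALSE)
    e <- data.frame(from = seq_len(n_nodes), to = n_nodes + seq_len(n_nodes),
                    length_um = runif(n_nodes, 50, 300))
    manual_graph(v, e)
  }
  graphs <- lapply(c(50, 100, 200, 400, 800), make_iid_graph)
  res <- lengthUncertaintyExponent(graphs, replicates = 300, seed = 2)
  # binomial thinning: sigma_L proportional to sqrt(L)
  expect_lt(abs(res$exponent - 0.5), 2 * res$exponent_se2)
  # determinism for a fixed seed
  g <- graphs[[2]]
  r1 <- lengthUncertainty(g, replicates = 50, seed = 9)
  r2 <- lengthUncertainty(g, replicates = 50, seed = 9)
  expect_identical(r1$replicate_L_mm, r2$replicate_L_mm)
  # small graphs fall back to the Poisson surrogate, flagged
  small <- make_iid_graph(4)
  expect_true(lengthUncertainty(small, replicates = 50)$fallback)
  # convergence: 30-replicate estimate close to a 10x oracle rerun
  lo <- lengthUncertainty(g, replicates = 60, seed = 3)$sigma_L_mm
  hi <- lengthUncertainty(g, replicates = 600, seed = 4)$sigma_L_mm
  expect_lt(abs(lo - hi) / hi, 0.35)
})

test_that("detection error ratios reproduce the audited bookkeeping", {
  er <- detectionErrorRates(16, 185, 3, 566)
  expect_equal(round(er$node_ratio, 3), 0.005)
  expect_equal(round(er$apex_ratio, 4), 0.0865)
  expect_equal(detectionErrorRates(0, 10, 0, 10)$apex_ratio, 0)
  expect_error(detectionErrorRates(1, 0, 1, 5))
})

test_that("correctNodes appends consistent columns to a series", {
  graphs <- lapply(c(5, 6, 7), function(d)
    extractGraph(renderPanorama(cached_sim(11, 7),
                                frame = round(d / (17 / 60)))@pixels))
  tal <- do.call(rbind, lapply(seq_along(graphs), function(i)
    classifyAndTally(graphs[[i]], time = c(5, 6, 7)[i], frame = i)))
  ser <- new("GrowthSeries", tallies = tal, label = "t", T1 = NA_real_)
  out <- correctNodes(ser, graphs, n_px = 20)
  tl <- tallies(out)
  expect_true(all(tl$N <= tl$Ng))
  expect_equal(tl$N / tl$Ng, rep(1 - attr(tl, "r_pooled"), nrow(tl)))
})
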