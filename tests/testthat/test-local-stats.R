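test_that("sector grids partition annuli into equal-area cells", {
  g <- buildSectorGrid(c(0, 0))
  expect_equal(nrow(g@annuli) * g@n_sectors, 180)
  expect_equal(unname(diff(t(g@annuli))[1, ]), rep(3516, 3))
  # quadrants of a single annulus
  q <- buildSectorGrid(c(0, 0), annuli = cbind(100, 300), n_sectors = 4)
  expect_equal(sectorAreas(q), pi * (300^2 - 100^2) / 4)
  # partition: sector areas sum to the annulus areas
  g3 <- buildSectorGrid(c(0, 0))
  expect_equal(sum(rep(sectorAreas(g3), each = g3@n_sectors)),
               sum(pi * (g3@annuli[, 2]^2 - g3@annuli[, 1]^2)))
})

test_that("vertices land in exactly one cell of the partition", {
  grid <- buildSectorGrid(c(0, 0))
  th <- 10 * pi / 180
  v <- data.frame(id = 1:2,
                  x_um = c(4000 * cos(th), 9500),
                  y_um = c(4000 * sin(th), 0),
                  degree = 1L, kind = "apex", boundary = FALSE)
  e <- data.frame(from = c(1, 2), to = c(2, 1), length_um = c(1, 1))
  sm <- sectorMeasures(manual_graph(v, e), grid)
  df <- sectorTable(sm)
  expect_equal(sum(df$A), 1)                  # second apex outside all annuli
  hit <- df[df$A == 1, ]
  expect_equal(hit$annulus, 2)                # 4000 um is the middle annulus
  expect_equal(hit$sector, ceiling(10 / 6))   # 6-degree sectors
})

test_that("edge clipping conserves length across boundaries", {
  grid <- buildSectorGrid(c(0, 0),
                          annuli = cbind(c(0, 600), c(600, 1200)),
                          n_sectors = 12)
  set.seed(4)
  for (i in 1:40) {
    a <- runif(2, -900, 900); b <- runif(2, -900, 900)
    pieces <- mycelia:::.split_segment(a, b,
                                       radii = c(0, 600, 1200),
                                       angles = (0:11) * pi / 6)
    expect_equal(sum(vapply(pieces, `[[`, 1, "len")),
                 sqrt(sum((b - a)^2)), tolerance = 1e-9)
  }
})

test_that("sector lengths match a dense-sampling oracle", {
  sim <- cached_sim(3, 7)
  g <- extractGraph(renderPanorama(sim)@pixels)
  v <- graphVertices(g)
  ctr <- c(mean(v$x_um), mean(v$y_um))
  grid <- buildSectorGrid(ctr, annuli = cbind(c(0, 500, 1000),
                                              c(500, 1000, 1500)),
                          n_sectors = 12)
  df <- sectorTable(sectorMeasures(g, grid))
  # dense point sampling of every polyline step
  bf <- numeric(nrow(df))
  for (p in g@polylines) for (s in seq_len(nrow(p) - 1)) {
    len <- sqrt(sum((p[s + 1, ] - p[s, ])^2))
    if (len == 0) next
    np <- max(2, ceiling(len * 2))
    ts <- (seq_len(np) - 0.5) / np
    cl <- mycelia:::.cell_of(p[s, 1] + ts * (p[s + 1, 1] - p[s, 1]),
                             p[s, 2] + ts * (p[s + 1, 2] - p[s, 2]), grid)
    ok <- cl$annulus > 0
    if (any(ok)) {
      cell <- (cl$annulus[ok] - 1) * 12 + cl$sector[ok]
      tb <- table(cell)
      ix <- as.integer(names(tb))
      bf[ix] <- bf[ix] + as.numeric(tb) * len / np / 1000
    }
  }
  expect_lt(abs(sum(df$L_mm) - sum(bf)) / max(sum(bf), 1e-9), 0.005)
  expect_lt(max(abs(df$L_mm - bf)), 0.005 * max(sum(bf), 1e-9) + 1e-4)
  # partition conservation for apexes: exact integer equality
  cl <- mycelia:::.cell_of(v$x_um, v$y_um, grid)
  inside <- sum(v$degree == 1 & !v$boundary & cl$annulus > 0)
  expect_equal(sum(df$A), inside)
})

test_that("standardized medians flag degenerate annuli and centre symmetry", {
  grid <- buildSectorGrid(c(0, 0), annuli = cbind(100, 300), n_sectors = 8)
  mk <- function(A) new("SectorMeasures", measures = data.frame(
    annulus = 1L, sector = 1:8, A = A, N = A, L_mm = A + 1),
    grid = grid, time_h = 1)
  out <- standardizedMedianSeries(mk(rep(4, 8)))
  expect_true(all(is.na(out$median_std[out$quantity == "A"])))
  sym <- standardizedMedianSeries(mk(c(1, 2, 3, 4, 4, 3, 2, 1)))
  expect_equal(sym$median_std[sym$quantity == "A"], 0)
})

test_that("Mann-Whitney comparisons behave at the extremes", {
  grid <- buildSectorGrid(c(0, 0))
  m1 <- nullSectorMeasures(grid, seed = 1)
  mw_same <- mannWhitneyCompare(m1, m1, subsets = list(c("odd", "odd")))
  expect_true(all(mw_same$p > 0.9))
  # complete separation
  m2 <- m1
  m2@measures$N <- m2@measures$N + 1000
  mw_sep <- mannWhitneyCompare(m1, m2, subsets = list(c("odd", "even")))
  expect_true(all(mw_sep$p < 1e-9))
  # symmetry under swapping the experiments
  m3 <- nullSectorMeasures(grid, seed = 2)
  p12 <- mannWhitneyCompare(m1, m3, subsets = list(c("odd", "even")))$p
  p21 <- mannWhitneyCompare(m3, m1, subsets = list(c("even", "odd")))$p
  expect_equal(p12, p21)
  # zero-length sectors are dropped and reported
  m4 <- nullSectorMeasures(grid, seed = 3)
  m4@measures$L_mm[m4@measures$sector == 1] <- 0
  mw0 <- mannWhitneyCompare(m4, m3, subsets = list(c("odd", "odd")))
  expect_true(all(mw0$dropped >= 1))
  expect_true(all(mw0$n1 == 29))
})
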