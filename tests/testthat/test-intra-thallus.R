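# build a wall-and-rooms raster: walls are foreground (1), rooms are the
# enclosed faces; returns the mask
rooms_mask <- function(nr, nc, rooms) {
  m <- matrix(1L, nr, nc)
  for (r in rooms) m[r[1]:r[2], r[3]:r[4]] <- 0L
  m
}

test_that("faces are the enclosed holes of the thallus component", {
  m <- ring_mask(size = 101, r_out = 35, r_in = 25)
  fs <- extractFaces(m, pixel_scale = 1)
  expect_equal(nrow(faces(fs)), 1)
  d2 <- outer(seq_len(101) - 51, seq_len(101) - 51, function(a, b) a^2 + b^2)
  expect_equal(faces(fs)$area_px, sum(d2 < 25^2))
  # a tree (no cycles) has no faces
  tree <- y_mask()
  expect_equal(nrow(faces(extractFaces(tree, pixel_scale = 1))), 0)
  # center off the thallus is an error
  expect_error(extractFaces(m, center = c(51, 51)), "center not on thallus")
})

test_that("face counts equal the cycle rank of the centerline graph", {
  for (sd in c(1, 3, 4)) {
    sim <- cached_sim(sd, 6.5)
    m <- renderPanorama(sim)@pixels
    g <- extractGraph(m)
    fs <- extractFaces(m, pixel_scale = 3.516)
    expect_equal(nrow(faces(fs)), main_cycle_rank(g))
  }
})

test_that("face statistics compute sums, means and natural breaks", {
  mk_fs <- function(areas_px, scale = 1) {
    n <- length(areas_px)
    new("FaceSet", faces = data.frame(
      id = seq_len(n), area_px = areas_px,
      area_mm2 = areas_px * (scale / 1000)^2,
      cx_um = seq_len(n), cy_um = seq_len(n),
      crow = seq_len(n), ccol = seq_len(n),
      appearance_time_h = NA_real_),
      label_matrix = matrix(0L, 1, 1), time_h = 0, pixel_scale = scale)
  }
  st <- mk_fs(c(1, 1, 1, 1, 96) * 1e6)    # areas in px -> mm2 with scale 1
  s <- faceStatistics(st, n_classes = 2)
  expect_equal(s$mean_mm2, 20)
  expect_equal(round(s$rel_std, 2), 2.12)
  # all faces equal: zero spread
  expect_equal(faceStatistics(mk_fs(rep(25, 10)), n_classes = 2)$rel_std, 0)
  # natural breaks separate well-separated groups
  st2 <- mk_fs(c(rep(10, 5), rep(1000, 5)) * 1e6)
  s2 <- faceStatistics(st2, n_classes = 2)
  expect_equal(sort(unique(s2$class)), 1:2)
  expect_true(all(s2$class == rep(1:2, each = 5)))
})

test_that("appearance times chain through frames by the centroid rules", {
  # frame 1: one room; frame 2: the room split in two by a 1-px wall
  m1 <- rooms_mask(40, 60, list(c(5, 35, 5, 55)))
  m2 <- m1; m2[, 36] <- 1L   # off-centre wall: parent centroid in one child
  f1 <- extractFaces(m1, pixel_scale = 1, time_h = 2)
  f2 <- extractFaces(m2, pixel_scale = 1, time_h = 3)
  # fragmentation convention: both halves inherit the parent's age
  out <- appearanceTimes(list(f1, f2))
  expect_equal(faces(out[[2]])$appearance_time_h, c(2, 2))
  # formation-time convention: exactly one child keeps the parent's date
  out2 <- appearanceTimes(list(f1, f2), rule = "parent-in-child")
  app <- sort(faces(out2[[2]])$appearance_time_h)
  expect_equal(app, c(2, 3))
  # a face present unchanged keeps its original date under both rules
  out3 <- appearanceTimes(list(f1, f1, f1))
  expect_equal(faces(out3[[3]])$appearance_time_h, 2)
})

test_that("fragmentation tracking reproduces the reference cohort numbers", {
  # epoch 1 (t = 4.9 h): two strips of 10905 px each (mean 10905);
  # epoch 2 (t = 17.9 h): subdivided into 9 rooms with mean 1337 px
  nr <- 40; nc <- 1500
  parents <- list(c(5, 19, 10, 736),     # 15 x 727 = 10905
                  c(24, 38, 10, 736))
  m1 <- rooms_mask(nr, nc, parents)
  # children: 9-row rooms inside the parent strips, total 9 x 1337
  w1 <- c(140, 140, 140, 140, 140)        # strip 1: 5 rooms, 9 rows
  w2 <- c(159, 159, 159, 160)             # strip 2: 4 rooms
  stopifnot(9 * (sum(w1) + sum(w2)) == 9 * 1337)
  rooms2 <- list()
  off <- 10
  for (w in w1) { rooms2[[length(rooms2) + 1]] <- c(8, 16, off, off + w - 1)
                  off <- off + w + 3 }
  off <- 10
  for (w in w2) { rooms2[[length(rooms2) + 1]] <- c(27, 35, off, off + w - 1)
                  off <- off + w + 3 }
  m2 <- rooms_mask(nr, nc, rooms2)
  f1 <- extractFaces(m1, pixel_scale = 1, time_h = 4.9)
  f2 <- extractFaces(m2, pixel_scale = 1, time_h = 17.9)
  expect_equal(nrow(faces(f1)), 2)
  expect_equal(faces(f1)$area_px, c(10905, 10905))
  tr <- trackFragmentation(list(f1, f2), t_start = 4.9, delta_t = 13)
  first <- tr[tr$epoch_t == 4.9, ]
  last <- tr[tr$epoch_t == 17.9, ]
  expect_equal(first$n_prime, 2)
  expect_equal(first$mean_area_px, 10905)
  expect_equal(last$n_prime, 9)
  expect_equal(last$mean_area_px, 1337)
  expect_equal(last$cohort_t, 4.9)        # children inherit the cohort
})

test_that("area is conserved under pure subdivision up to the wall pixels", {
  m1 <- rooms_mask(60, 60, list(c(5, 54, 5, 54)))   # 50x50 room
  m2 <- m1; m2[, 30] <- 1L                          # 1-px dividing wall
  a1 <- faces(extractFaces(m1, pixel_scale = 1))$area_px
  a2 <- faces(extractFaces(m2, pixel_scale = 1))$area_px
  perimeter <- 2 * (50 + 50)
  expect_lte(a1 - sum(a2), perimeter)
  expect_gte(a1 - sum(a2), 0)
})

test_that("densification slope measures faces per millimetre", {
  L <- seq(2, 30, 2)
  expect_equal(densificationSlope(1.7 * L, L)$slope_per_mm, 1.7,
               tolerance = 1e-9)
  expect_equal(densificationSlope(rep(5, 10), L[1:10])$slope_per_mm, 0)
  # simulated densifying series: face count grows with length
  sim <- cached_sim(11, 8)
  tr <- simTruth(sim)
  frames <- round(seq(12, nrow(tr), length.out = 4))
  n_faces <- vapply(frames, function(f)
    nrow(faces(extractFaces(renderPanorama(sim, f)@pixels,
                            pixel_scale = 3.516))), 1L)
  sl <- densificationSlope(n_faces, tr$L_mm[frames])
  expect_gt(sl$slope_per_mm, 0)
})
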