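test_that("LoG detection finds rendered spots with sub-pixel accuracy", {
  expect_equal(nrow(detect_nuclei(matrix(0, 60, 60))), 0L)
  expect_error(detect_nuclei(matrix(0, 10, 10), blob_sigma = -1),
               "blob_sigma")

  set.seed(21)
  xs <- runif(20, 15, 185); ys <- runif(20, 15, 185)
  repeat {  # enforce separation so ground truth is unambiguous
    d <- as.matrix(dist(cbind(xs, ys))); diag(d) <- Inf
    bad <- which(d < 25, arr.ind = TRUE)
    if (!nrow(bad)) break
    xs[bad[1, 1]] <- runif(1, 15, 185); ys[bad[1, 1]] <- runif(1, 15, 185)
  }
  fr <- spot_frame(200, 200, xs, ys, sigma = 3, amplitude = 0.9)
  sp <- detect_nuclei(fr, blob_sigma = 3, detect_threshold = 0.1)
  expect_equal(nrow(sp), 20L)
  derr <- sapply(seq_along(xs), function(i)
    min(sqrt((sp$x_px - xs[i])^2 + (sp$y_px - ys[i])^2)))
  expect_lt(max(derr), 1)
})

test_that("detections closer than one sigma merge into one", {
  fr <- spot_frame(60, 60, c(30, 31.5), c(30, 30), sigma = 3,
                   amplitude = 0.9)
  expect_equal(nrow(detect_nuclei(fr, 3, 0.1)), 1L)
})

test_that("greedy linking follows stationary and terminating spots", {
  spots <- tidyr::crossing(frame = 1:6,
                           tibble::tibble(x_um = c(10, 40, 70),
                                          y_um = c(10, 20, 30)))
  ts <- link_tracks(spots, max_link_distance = 5)
  expect_equal(length(unique(ts$track_id)), 3L)
  expect_true(all(table(ts$track_id) == 6))

  vanish <- spots[!(spots$frame > 3 & spots$x_um == 40), ]
  ts2 <- link_tracks(vanish, max_link_distance = 5)
  lens <- table(ts2$track_id)
  expect_equal(sort(as.integer(lens)), c(3L, 6L, 6L))
  expect_error(link_tracks(spots[spots$frame == 1, ]), "2 frames")
})

test_that("link identity accuracy exceeds 95% on a 200-cell scene", {
  # full-size track sampling; no rendering needed to test the linker
  cfg <- scene_config(noise_sd = 0, speed_noise_sd = 0)
  tr <- sample_cell_tracks(cfg)
  fake_scene <- list(truth = list(tracks = tr, config = cfg))
  expect_gte(link_accuracy(fake_scene), 0.95)
})

test_that("radial angle follows the toward-gap convention", {
  geom <- tibble::tibble(frame = 1:2, t_h = c(0, 1), cx_um = 0, cy_um = 0,
                         boundary = rep(list(cbind(20 * cos(seq(0, 2 * pi,
                                                                length.out = 90)),
                                                   20 * sin(seq(0, 2 * pi,
                                                                length.out = 90)))),
                                        2))
  mk <- function(p0, p1) tibble::tibble(track_id = 1L, frame = 1:2,
                                        t_h = c(0, 1),
                                        x_um = c(p0[1], p1[1]),
                                        y_um = c(p0[2], p1[2]))
  # straight toward the centroid
  expect_equal(migration_stats(mk(c(100, 0), c(90, 0)), geom)$radial_angle_deg,
               0)
  # perpendicular to the radial direction: tangential, 90 deg
  expect_equal(migration_stats(mk(c(100, 0), c(100, 10)), geom)$radial_angle_deg,
               90)
  # diagonal between radial and tangential
  expect_equal(migration_stats(mk(c(100, 0), c(90, 10)), geom)$radial_angle_deg,
               45)
  # away from the gap folds to 180
  expect_equal(migration_stats(mk(c(100, 0), c(110, 0)), geom)$radial_angle_deg,
               180)
  expect_error(migration_stats(mk(c(100, 0), c(90, 0)), geom,
                               interval = c(2, 2)), "zero-length")
})

test_that("radial angles are invariant under global rotation", {
  set.seed(31)
  phi <- seq(0, 2 * pi, length.out = 120)
  bnd <- cbind(30 * cos(phi), 25 * sin(phi))
  geom <- tibble::tibble(frame = 1:3, t_h = 0:2, cx_um = 0, cy_um = 0,
                         boundary = rep(list(bnd), 3))
  tracks <- tidyr::crossing(track_id = 1:8, frame = 1:3)
  tracks$t_h <- tracks$frame - 1
  tracks$x_um <- rnorm(24, sd = 60)
  tracks$y_um <- rnorm(24, sd = 60)
  s0 <- migration_stats(tracks, geom)

  a <- 37 * pi / 180
  rot <- function(x, y) cbind(x * cos(a) - y * sin(a),
                              x * sin(a) + y * cos(a))
  rtracks <- tracks
  rxy <- rot(tracks$x_um, tracks$y_um)
  rtracks$x_um <- rxy[, 1]; rtracks$y_um <- rxy[, 2]
  rgeom <- geom
  rgeom$boundary <- rep(list(rot(bnd[, 1], bnd[, 2])), 3)
  s1 <- migration_stats(rtracks, rgeom)
  expect_equal(s1$radial_angle_deg, s0$radial_angle_deg, tolerance = 1e-8)
  expect_equal(s1$max_speed_um_h, s0$max_speed_um_h, tolerance = 1e-8)
})

test_that("edge and distal classes recover generator construction", {
  cfg <- small_scene_config(noise_sd = 0, n_cells = 30L, edge_fraction = 0.3,
                            speed_noise_sd = 0)
  tr <- sample_cell_tracks(cfg)
  truth_class <- tr$class[!duplicated(tr$cell_id)]
  names(tr)[names(tr) == "cell_id"] <- "track_id"
  geom <- truth_gap_geometry(list(areas = gap_area_trajectory(cfg),
                                  config = cfg))
  st <- migration_stats(tr, geom, edge_band = cfg$edge_band_width,
                        distal_distance = cfg$distal_distance,
                        interval = c(0, 1))
  expect_equal(st$class[order(st$track_id)], truth_class)
  # noiseless construction: tangential cells near 90 deg, radial cells near 0
  expect_true(all(abs(st$radial_angle_deg[st$class == "edge"] - 90) < 10))
  expect_true(all(st$radial_angle_deg[st$class == "distal"] < 10))
})

test_that("windrose bins percentages that total 100", {
  set.seed(41)
  st <- tibble::tibble(track_id = 1:50, class = "edge",
                       radial_angle_deg = runif(50, 0, 180))
  wr <- windrose(st, bin_width = 20)
  expect_equal(sum(wr$percent), 100, tolerance = 0.01)
  expect_equal(nrow(wr), 9L)

  two <- tibble::tibble(track_id = 1:2, class = "edge",
                        radial_angle_deg = c(10, 80))
  wr2 <- windrose(two, bin_width = 30)
  expect_equal(wr2$percent, c(50, 0, 50, 0, 0, 0))
  expect_error(windrose(two, bin_width = 30, class = "distal"),
               "no eligible")
})

test_that("speed table reports per-track maximum frame-to-frame speed", {
  cfg <- small_scene_config(n_cells = 20L, edge_fraction = 0.5,
                            tangential_speed = 12, speed_noise_sd = 0,
                            noise_sd = 0)
  tr <- sample_cell_tracks(cfg)
  names(tr)[names(tr) == "cell_id"] <- "track_id"
  geom <- truth_gap_geometry(list(areas = gap_area_trajectory(cfg),
                                  config = cfg))
  st <- migration_stats(tr, geom, interval = c(0, 2))
  sp <- speed_table(st, class = "edge")
  expect_true(all(sp$class == "edge"))
  expect_equal(sp$max_speed_um_h, rep(12, nrow(sp)), tolerance = 0.01)

  still <- tidyr::crossing(track_id = 1:3, frame = 1:4)
  still$t_h <- still$frame * 1.0; still$x_um <- still$track_id * 30
  still$y_um <- 10
  st0 <- migration_stats(still, tibble::tibble(frame = 1:4, t_h = 1:4,
                                               cx_um = 0, cy_um = 0,
                                               boundary = rep(list(cbind(0, 0)), 4)))
  expect_equal(speed_table(st0)$max_speed_um_h, rep(0, 3))
})
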