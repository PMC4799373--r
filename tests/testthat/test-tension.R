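mk_defl <- function(d0, d1, t = NULL) {
  n <- length(d0)
  if (is.null(t)) t <- (seq_len(n) - 1) * 0.5
  tibble::tibble(frame = rep(seq_len(n), 2), t_h = rep(t, 2),
                 cantilever = rep(0:1, each = n),
                 deflection_um = c(d0, d1))
}

test_that("tension is the spring constant times summed deflections", {
  # k = 2.67 uN/um with both cantilevers at 0.5 um -> 2.67 uN
  ten <- total_tension(mk_defl(0.5, 0.5), k = 2.67)
  expect_equal(ten$tension_uN, 2.67)
  expect_equal(total_tension(mk_defl(3, 5), k = 2.67)$tension_uN, 21.36)
  expect_equal(total_tension(mk_defl(0, 0), k = 2.67)$tension_uN, 0)
  expect_error(total_tension(mk_defl(1, 1), k = 0), "k must be")
})

test_that("tension is linear in k and in each deflection", {
  set.seed(51)
  d0 <- runif(8); d1 <- runif(8)
  t1 <- total_tension(mk_defl(d0, d1), k = 2)$tension_uN
  expect_equal(total_tension(mk_defl(d0, d1), k = 6)$tension_uN, 3 * t1)
  t2 <- total_tension(mk_defl(2 * d0, d1), k = 2)$tension_uN
  expect_equal(t2 - t1, 2 * d0)
})

test_that("deflections average beads and project on the tissue axis", {
  base <- tibble::tibble(bead_id = 1:4, x_um = c(10, 10, 90, 90),
                         y_um = c(20, 40, 20, 40))
  tracks <- tidyr::crossing(frame = 1:3, bead_id = 1:4)
  tracks$t_h <- (tracks$frame - 1) * 0.5
  tracks$cantilever <- ifelse(tracks$bead_id <= 2, 0L, 1L)
  tracks$x_um <- base$x_um[tracks$bead_id]
  tracks$y_um <- base$y_um[tracks$bead_id]

  d0 <- deflections(tracks, base)
  expect_equal(d0$deflection_um, rep(0, 6))

  # cantilever 0 beads +1.5 um along the axis (toward midline)
  shift <- tracks
  shift$x_um <- shift$x_um + ifelse(shift$cantilever == 0L, 1.5, 0)
  d1 <- deflections(shift, base)
  expect_equal(d1$deflection_um[d1$cantilever == 0], rep(1.5, 3))
  expect_equal(d1$deflection_um[d1$cantilever == 1], rep(0, 3))

  # mean rule: beads displaced 1.0 and 2.0 um -> 1.5 um
  two <- tracks
  two$x_um[two$bead_id == 1] <- two$x_um[two$bead_id == 1] + 1
  two$x_um[two$bead_id == 2] <- two$x_um[two$bead_id == 2] + 2
  expect_equal(deflections(two, base)$deflection_um[
    deflections(two, base)$cantilever == 0], rep(1.5, 3))

  # a cantilever with all beads lost is an error
  lostall <- tracks
  lostall$lost <- lostall$cantilever == 1L
  expect_error(deflections(lostall, base), "zero valid beads")
  expect_error(deflections(tracks, base[1:3, ]), "baseline")

  # magnitude mode ignores direction
  mag <- deflections(shift, base, mode = "magnitude")
  expect_equal(mag$deflection_um[mag$cantilever == 0], rep(1.5, 3))
})

test_that("normalization maps the pre-wound window to 1", {
  d <- mk_defl(rep(1.2, 6), rep(1.2, 6), t = c(0, 0.5, 1, 1.5, 2, 2.5))
  ten <- total_tension(d, k = 2)
  nt <- normalize_tension(ten)
  expect_equal(nt$tension_norm, rep(1, 6))
  expect_error(normalize_tension(total_tension(mk_defl(0, 0), k = 2)),
               "baseline")
})

test_that("bead tracking recovers static and moving beads", {
  # static: constant tension profile -> beads never move
  cfg_static <- small_scene_config(duration = 2, n_cells = 2L, noise_sd = 0,
                                   tension_baseline = 4, tension_min = 4,
                                   tension_peak = 4, tension_plateau = 4,
                                   peak_time = 1)
  sc <- render_scene(cfg_static)
  init <- sc$truth$beads[sc$truth$beads$frame == 1,
                         c("bead_id", "cantilever", "x_um", "y_um")]
  bt <- track_beads(sc$beads, init, search_radius = 6)
  err <- abs(bt$x_um - sc$truth$beads$x_um[order(sc$truth$beads$bead_id,
                                                 sc$truth$beads$frame)])
  expect_lt(max(err), 0.2 * cfg_static$pixel_size)
  expect_false(any(bt$lost))

  # moving: default profile, displacement recovered within 0.1 um
  cfg_mv <- small_scene_config(duration = 4, n_cells = 2L, noise_sd = 0,
                               peak_time = 3)
  sc2 <- render_scene(cfg_mv)
  init2 <- sc2$truth$beads[sc2$truth$beads$frame == 1,
                           c("bead_id", "cantilever", "x_um", "y_um")]
  bt2 <- track_beads(sc2$beads, init2, search_radius = 6)
  truth2 <- sc2$truth$beads[order(sc2$truth$beads$bead_id,
                                  sc2$truth$beads$frame), ]
  expect_lt(max(abs(bt2$x_um - truth2$x_um)), 0.1)

  # a bead jumping outside the search radius is flagged lost
  fr1 <- spot_frame(50, 50, 25, 25, sigma = 2, amplitude = 0.9)
  fr2 <- spot_frame(50, 50, 45, 25, sigma = 2, amplitude = 0.9)
  st <- frame_stack(list(fr1, fr2), pixel_size = 1, frame_interval = 0.5)
  btl <- track_beads(st, tibble::tibble(bead_id = 1, cantilever = 0,
                                        x_um = 25, y_um = 25),
                     search_radius = 5)
  expect_true(btl$lost[2])
})

test_that("tension recovery on a noisy scene is accurate and ordered", {
  sc <- cached_scene("small_noisy", function()
    render_scene(small_scene_config()))
  truth <- sc$truth
  init <- truth$beads[truth$beads$frame == 1,
                      c("bead_id", "cantilever", "x_um", "y_um")]
  bt <- track_beads(sc$beads, init, search_radius = 6)
  rest <- unique(truth$beads[, c("bead_id", "rest_x_um", "rest_y_um")])
  names(rest) <- c("bead_id", "x_um", "y_um")
  ten <- total_tension(deflections(bt, rest), k = truth$config$spring_constant)
  rel_rms <- sqrt(mean((ten$tension_uN - truth$tension$tension_uN)^2)) /
    sqrt(mean(truth$tension$tension_uN^2))
  expect_lt(rel_rms, 0.05)

  nt <- normalize_tension(ten)
  post <- nt$tension_norm[-1]
  n <- nrow(nt)
  # min(post-wound) < plateau < baseline < peak
  expect_lt(min(post), nt$tension_norm[n])
  expect_lt(nt$tension_norm[n], 1)
  expect_gt(max(post), 1)
  expect_equal(which.min(nt$tension_norm), 2L)   # first post-wound frame
  expect_lt(abs(nt$t_h[which.max(nt$tension_norm)] -
                  truth$config$peak_time), 1)
})
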