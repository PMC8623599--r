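test_that("motion signal modes follow their definitions", {
  still <- cbind(rep(3, 10), rep(4, 10))
  expect_equal(motion_signal(still, "displacement"), rep(0, 9))
  expect_equal(motion_signal(still, "radial"), rep(0, 9))

  xy <- rbind(c(0, 0), c(3, 4))
  expect_equal(motion_signal(xy, "displacement"), 25)

  ## equal radii: radial mode is blind to motion along a circle
  arc <- rbind(c(3, 4), c(4, 3))
  expect_equal(motion_signal(arc, "radial"), 0)
  expect_equal(motion_signal(arc, "displacement"), 2)

  ## translation invariance holds for displacement, not radial
  xy2 <- xy + 100
  expect_identical(motion_signal(xy2, "displacement"),
                   motion_signal(xy, "displacement"))
  expect_false(isTRUE(all.equal(motion_signal(xy2, "radial"),
                                motion_signal(xy, "radial"))))
  expect_error(motion_signal(xy[1, , drop = FALSE]), "2 frames")
})

test_that("stance runs recover the simulator's stance durations", {
  p <- gait_params(duration = 5, stride_period = 1.0, swing_time_left = 0.4,
                   swing_time_right = 0.4, noise_sd = 0)
  sim <- simulate_walker(p)
  idx <- body25_index()
  toe <- t(vapply(sim$seq$frames, function(f) f$poses[[1]][idx["l_big_toe"], ],
                  numeric(3)))
  runs <- detect_stance_runs(motion_signal(toe[, 1:2]))
  lens <- runs[, "end"] - runs[, "start"] + 1
  ## stance = 0.6 s = 18 frames; the smoothstep swing profile moves below
  ## threshold for about one extra frame at each end of the swing
  interior <- lens[-c(1, length(lens))]
  expect_true(all(abs(interior - 18) <= 2))

  expect_equal(unname(detect_stance_runs(rep(0, 20))), cbind(1L, 20L),
               ignore_attr = TRUE)
  ## never-stationary signal yields no runs
  expect_equal(nrow(detect_stance_runs(rep(5, 20) + sin(1:20) * 0.1)), 0)
  expect_error(detect_stance_runs(c(0, 0)), "short")
})

test_that("event detection localizes toe-off and heel-strike against truth", {
  for (noise in c(0, 1)) {
    tol <- if (noise == 0) 1 else 2
    p <- gait_params(duration = 5, stride_period = 1.1, swing_time_left = 0.5,
                     swing_time_right = 0.42, noise_sd = noise,
                     paretic_side = "left", seed = 17)
    sim <- simulate_walker(p)
    idx <- body25_index()
    take <- function(ki) t(vapply(sim$seq$frames,
                                  function(f) f$poses[[1]][ki, ], numeric(3)))
    for (side in c("left", "right")) {
      heel_i <- if (side == "left") "l_heel" else "r_heel"
      toe_i <- if (side == "left") "l_big_toe" else "r_big_toe"
      ft <- foot_trajectory(take(idx[heel_i]), take(idx[toe_i]), side, p$fps)
      ev <- detect_events(ft)
      tru <- sim$truth$walkers[[1]]$events[[side]]
      expect_gte(length(ev$toe_off), 3)
      for (e in ev$toe_off)
        expect_lte(min(abs(e - tru$toe_off)), tol)
      for (e in ev$heel_strike)
        expect_lte(min(abs(e - tru$heel_strike)), tol)
    }
  }
  ## stationary foot: no events
  still <- cbind(50, 60, 0.9)[rep(1, 60), ]
  ft <- foot_trajectory(still, still, "left", 30)
  ev <- detect_events(ft)
  expect_length(ev$toe_off, 0)
  expect_length(ev$heel_strike, 0)
})

test_that("swing times pair events and gate artifacts", {
  ev <- list(toe_off = c(12L), heel_strike = c(24L))
  expect_equal(swing_times(ev, 30)$durations, 0.4)
  ev2 <- list(toe_off = c(10L, 40L), heel_strike = c(22L, 52L))
  st <- swing_times(ev2, 30)
  expect_equal(st$durations, c(0.4, 0.4))
  expect_equal(st$mean, 0.4)
  ## 3 frames at 30 fps = 0.1 s: at the artifact gate, discarded
  expect_length(swing_times(list(toe_off = 10L, heel_strike = 13L), 30)$durations, 0)
  expect_length(swing_times(list(toe_off = integer(0),
                                 heel_strike = integer(0)), 30)$durations, 0)
})

test_that("asymmetry follows the paretic/non-paretic convention with validity gating", {
  sw <- function(d) list(durations = d, mean = mean(d))
  ## paretic 0.62 vs non-paretic 0.50 gives the dependent-gait reference 1.24
  r <- asymmetry(sw(c(0.62, 0.62)), sw(c(0.5, 0.5)), "left")
  expect_true(r$valid)
  expect_equal(r$ratio, 1.24)
  r2 <- asymmetry(sw(c(0.5, 0.5)), sw(c(0.62, 0.62)), "right")
  expect_equal(r2$ratio, 1.24)
  ## one cycle on one side: invalid, no ratio
  r3 <- asymmetry(sw(0.5), sw(c(0.5, 0.5)), "left")
  expect_false(r3$valid)
  expect_true(is.na(r3$ratio))
  ## unknown side falls back to max/min
  r4 <- asymmetry(sw(c(0.4, 0.4)), sw(c(0.5, 0.5)), "none")
  expect_equal(r4$ratio, 1.25)
})

test_that("clip asymmetry recovers the configured ratio and mirrors to its reciprocal", {
  p <- gait_params(duration = 5, stride_period = 1.1, swing_time_left = 0.55,
                   swing_time_right = 0.45, noise_sd = 0.5,
                   paretic_side = "left", seed = 21)
  sim <- simulate_walker(p)
  est <- clip_asymmetry(sim$seq, "left")
  expect_true(est$valid)
  expect_lt(abs(est$ratio - p$swing_time_left / p$swing_time_right) /
              est$ratio, 0.1)
  ## mirror: relabeling the same left/right trajectories inverts the ratio
  idx <- body25_index()
  take <- function(ki) t(vapply(sim$seq$frames,
                                function(f) f$poses[[1]][ki, ], numeric(3)))
  fl <- foot_trajectory(take(idx["l_heel"]), take(idx["l_big_toe"]), "left", 30)
  fr <- foot_trajectory(take(idx["r_heel"]), take(idx["r_big_toe"]), "right", 30)
  sw_l <- swing_times(detect_events(fl), 30)
  sw_r <- swing_times(detect_events(fr), 30)
  fwd <- asymmetry(sw_l, sw_r, "left")
  mir <- asymmetry(sw_r, sw_l, "left")   # trajectories swapped
  expect_lt(abs(mir$ratio - 1 / fwd$ratio), 0.02)

  ## symmetric gait is near 1
  ps <- gait_params(duration = 5, noise_sd = 0.5, seed = 22)
  expect_lt(abs(clip_asymmetry(simulate_walker(ps)$seq, "none")$ratio - 1), 0.05)
})

test_that("missing keypoints are interpolated and excess missingness invalidates", {
  p <- gait_params(duration = 5, stride_period = 1.1, swing_time_left = 0.55,
                   swing_time_right = 0.45, paretic_side = "left", seed = 3)
  sim <- simulate_walker(p)
  ## drop 10% of heel/toe confidences at random frames
  seq2 <- sim$seq
  with_seed <- get("with_seed", envir = asNamespace("ambustride"))
  drop_at <- with_seed(9, sample(150, 15))
  idx <- body25_index()
  for (i in drop_at)
    seq2$frames[[i]]$poses[[1]][c(idx["l_heel"], idx["l_big_toe"]), 3] <- 0
  est <- clip_asymmetry(seq2, "left")
  expect_true(est$valid)
  expect_lt(abs(est$ratio - 0.55 / 0.45) / est$ratio, 0.1)
  ## > 30% missing on a foot invalidates the measurement
  for (i in 1:60)
    seq2$frames[[i]]$poses[[1]][c(idx["l_heel"], idx["l_big_toe"]), 3] <- 0
  expect_false(clip_asymmetry(seq2, "left")$valid)
})
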