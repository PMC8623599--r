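#' Gait simulation parameters
#'
#' Parameters of a single simulated walker. The kinematic model: a hip
#' reference point translates at `walk_speed` (derived from step length and
#' cadence unless overridden); each foot alternates a stance phase (foot fixed
#' in world coordinates for `stride_period - swing_time` seconds) and a swing
#' phase (foot advances `2 * step_length` pixels along a smoothstep profile
#' for `swing_time` seconds, with a sinusoidal lift). Heel and toe keypoints
#' are fixed offsets from the foot point; the remaining keypoints follow a
#' rigid trunk/head with pendulum arm swing. Isotropic Gaussian jitter of sd
#' `noise_sd` (truncated at 3 sd) emulates pose-estimator noise.
#'
#' @param fps Frames per second (default 30, the recording rate emulated).
#' @param duration Sequence length in seconds.
#' @param stride_period Seconds per full gait cycle.
#' @param swing_time_left,swing_time_right Swing duration per side (s); must
#'   be positive and below `stride_period`.
#' @param step_length Pixels advanced per step (the foot travels twice this
#'   per cycle).
#' @param walk_speed Pixels/s of the hip point; default
#'   `2 * step_length / stride_period`, which keeps feet and trunk consistent.
#' @param start_position `c(x, y)` pixel position of the hip at t = 0.
#' @param body_scale Hip-to-head distance in pixels.
#' @param noise_sd Keypoint jitter sd in pixels (>= 0).
#' @param paretic_side `"left"`, `"right"` or `"none"`.
#' @param trunk_lean Forward trunk lean in degrees (stooped gait when large).
#' @param direction +1 walks rightward, -1 leftward.
#' @param image_size `c(width, height)` of the simulated camera frame.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return An object of class `gait_params`.
#' @export
gait_params <- function(fps = 30, duration = 5, stride_period = 1.0,
                        swing_time_left = 0.4, swing_time_right = 0.4,
                        step_length = 80, walk_speed = NULL,
                        start_position = c(150, 250), body_scale = 170,
                        noise_sd = 0, paretic_side = c("none", "left", "right"),
                        trunk_lean = 3, direction = 1,
                        image_size = c(960, 540), seed = 1) {
  paretic_side <- match.arg(paretic_side)
  if (fps <= 0) stop("fps must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (swing_time_left <= 0 || swing_time_left >= stride_period)
    stop("swing_time_left must lie in (0, stride_period)")
  if (swing_time_right <= 0 || swing_time_right >= stride_period)
    stop("swing_time_right must lie in (0, stride_period)")
  if (is.null(walk_speed)) walk_speed <- 2 * step_length / stride_period
  structure(list(
    fps = fps, duration = duration, stride_period = stride_period,
    swing_time_left = swing_time_left, swing_time_right = swing_time_right,
    step_length = step_length, walk_speed = walk_speed,
    start_position = start_position, body_scale = body_scale,
    noise_sd = noise_sd, paretic_side = paretic_side,
    trunk_lean = trunk_lean, direction = sign(direction),
    image_size = image_size, seed = as.integer(seed)
  ), class = "gait_params")
}

smoothstep <- function(u) u * u * (3 - 2 * u)

## Per-foot horizontal progress and vertical lift at continuous times t.
## offset: phase offset in seconds (right foot leads by half a cycle).
foot_profile <- function(t, stride_period, swing_time, offset, step_length,
                         body_scale) {
  tau <- (t + offset) %% stride_period
  k <- floor((t + offset) / stride_period)
  stance_dur <- stride_period - swing_time
  in_swing <- tau >= stance_dur
  u <- ifelse(in_swing, (tau - stance_dur) / swing_time, 0)
  progress <- 2 * step_length * (k + ifelse(in_swing, smoothstep(u), 0))
  lift <- ifelse(in_swing, 0.12 * body_scale * sin(pi * u), 0)
  list(progress = progress, lift = lift)
}

## Exact event times (s) for one foot: toe-off at each stance->swing
## boundary, heel-strike at the matching swing->stance boundary. All events
## inside [0, duration) are reported; `pairs` additionally marks the cycles
## whose both events fall inside the sequence (the measurable swing cycles).
foot_event_times <- function(stride_period, swing_time, offset, duration) {
  stance_dur <- stride_period - swing_time
  k <- -2:ceiling(duration / stride_period + 2)
  toe_off <- k * stride_period + stance_dur - offset
  heel_strike <- toe_off + swing_time
  paired <- toe_off >= 0 & heel_strike < duration
  list(toe_off = toe_off[toe_off >= 0 & toe_off < duration],
       heel_strike = heel_strike[heel_strike >= 0 & heel_strike < duration],
       pair_toe_off = toe_off[paired], pair_heel_strike = heel_strike[paired])
}

#' Simulate a single walker
#'
#' Generates a keypoint sequence for one walker together with the exact
#' ground truth of its gait: per-cycle toe-off/heel-strike frames, true swing
#' times, the true swing-time asymmetry (paretic over non-paretic mean), and
#' the dependence label implied by the asymmetry. At `noise_sd = 0` stance
#' feet are world-stationary and the truth asymmetry equals the configured
#' swing-time ratio exactly.
#'
#' @param params A [gait_params()] object.
#' @return List with elements `seq` (a [kp_sequence()]) and `truth` (a
#'   `scene_truth` with one walker).
#' @export
simulate_walker <- function(params) {
  stopifnot(inherits(params, "gait_params"))
  p <- params
  n <- floor(p$fps * p$duration)
  t <- (0:(n - 1)) / p$fps
  dir <- p$direction
  idx <- body25_index()

  hip_x <- p$start_position[1] + dir * p$walk_speed * t
  hip_y <- p$start_position[2] +
    0.02 * p$body_scale * sin(4 * pi * t / p$stride_period)
  leg <- 0.9 * p$body_scale
  ground_y <- p$start_position[2] + leg

  off_l <- 0; off_r <- p$stride_period / 2
  anchor <- function(offset) p$start_position[1] -
    dir * (p$step_length / 2 + 2 * p$step_length * offset / p$stride_period)
  fl <- foot_profile(t, p$stride_period, p$swing_time_left, off_l,
                     p$step_length, p$body_scale)
  fr <- foot_profile(t, p$stride_period, p$swing_time_right, off_r,
                     p$step_length, p$body_scale)
  lfoot_x <- anchor(off_l) + dir * fl$progress
  rfoot_x <- anchor(off_r) + dir * fr$progress
  lfoot_y <- ground_y - fl$lift
  rfoot_y <- ground_y - fr$lift

  lean <- p$trunk_lean * pi / 180
  trunk <- 0.72 * p$body_scale
  head <- 0.28 * p$body_scale
  neck_x <- hip_x + dir * trunk * sin(lean)
  neck_y <- hip_y - trunk * cos(lean)
  nose_x <- neck_x + dir * head * sin(lean + 0.15)
  nose_y <- neck_y - head * cos(lean + 0.15)

  ## arm pendulum: left arm swings with the right leg and vice versa
  upper_arm <- 0.30 * p$body_scale; forearm <- 0.26 * p$body_scale
  arm_l <- 0.6 * sin(2 * pi * (t + off_r) / p$stride_period)
  arm_r <- 0.6 * sin(2 * pi * (t + off_l) / p$stride_period)

  frames <- vector("list", n)
  noise <- NULL
  if (p$noise_sd > 0) {
    noise <- with_seed(p$seed, {
      z <- rnorm(n * 25 * 2, sd = p$noise_sd)
      pmin(pmax(z, -3 * p$noise_sd), 3 * p$noise_sd)
    })
    dim(noise) <- c(25, 2, n)
  }
  for (i in seq_len(n)) {
    m <- matrix(0, 25, 3, dimnames = list(BODY25_NAMES, c("x", "y", "conf")))
    m[idx["mid_hip"], 1:2] <- c(hip_x[i], hip_y[i])
    m[idx["l_hip"], 1:2] <- c(hip_x[i] + 6, hip_y[i])
    m[idx["r_hip"], 1:2] <- c(hip_x[i] - 6, hip_y[i])
    m[idx["neck"], 1:2] <- c(neck_x[i], neck_y[i])
    m[idx["nose"], 1:2] <- c(nose_x[i], nose_y[i])
    m[idx["l_eye"], 1:2] <- c(nose_x[i] + 4, nose_y[i] - 3)
    m[idx["r_eye"], 1:2] <- c(nose_x[i] - 4, nose_y[i] - 3)
    m[idx["l_ear"], 1:2] <- c(nose_x[i] + 7, nose_y[i])
    m[idx["r_ear"], 1:2] <- c(nose_x[i] - 7, nose_y[i])

    ## legs: ankle at the foot point, knee midway with forward bow
    la <- c(lfoot_x[i], lfoot_y[i] - 8)
    ra <- c(rfoot_x[i], rfoot_y[i] - 8)
    m[idx["l_ankle"], 1:2] <- la
    m[idx["r_ankle"], 1:2] <- ra
    m[idx["l_knee"], 1:2] <- (c(hip_x[i] + 6, hip_y[i]) + la) / 2 + c(dir * 8, 0)
    m[idx["r_knee"], 1:2] <- (c(hip_x[i] - 6, hip_y[i]) + ra) / 2 + c(dir * 8, 0)

    ## feet: heel behind, big toe ahead, small toe beside the big toe
    m[idx["l_heel"], 1:2] <- c(lfoot_x[i] - dir * 7, lfoot_y[i])
    m[idx["l_big_toe"], 1:2] <- c(lfoot_x[i] + dir * 14, lfoot_y[i] + 2)
    m[idx["l_small_toe"], 1:2] <- c(lfoot_x[i] + dir * 12, lfoot_y[i] + 3)
    m[idx["r_heel"], 1:2] <- c(rfoot_x[i] - dir * 7, rfoot_y[i])
    m[idx["r_big_toe"], 1:2] <- c(rfoot_x[i] + dir * 14, rfoot_y[i] + 2)
    m[idx["r_small_toe"], 1:2] <- c(rfoot_x[i] + dir * 12, rfoot_y[i] + 3)

    ## arms
    sh_l <- c(neck_x[i] + 7, neck_y[i] + 4)
    sh_r <- c(neck_x[i] - 7, neck_y[i] + 4)
    m[idx["l_shoulder"], 1:2] <- sh_l
    m[idx["r_shoulder"], 1:2] <- sh_r
    el_l <- sh_l + c(dir * upper_arm * sin(arm_l[i]), upper_arm * cos(arm_l[i]))
    el_r <- sh_r + c(dir * upper_arm * sin(arm_r[i]), upper_arm * cos(arm_r[i]))
    m[idx["l_elbow"], 1:2] <- el_l
    m[idx["r_elbow"], 1:2] <- el_r
    m[idx["l_wrist"], 1:2] <- el_l +
      c(dir * forearm * sin(arm_l[i] + 0.3), forearm * cos(arm_l[i] + 0.3))
    m[idx["r_wrist"], 1:2] <- el_r +
      c(dir * forearm * sin(arm_r[i] + 0.3), forearm * cos(arm_r[i] + 0.3))

    m[, 3] <- 0.9
    if (!is.null(noise)) m[, 1:2] <- m[, 1:2] + noise[, , i]
    m[, 1] <- pmin(pmax(m[, 1], 0), p$image_size[1] - 1)
    m[, 2] <- pmin(pmax(m[, 2], 0), p$image_size[2] - 1)
    frames[[i]] <- list(frame_index = i - 1L, poses = list(m))
  }

  ev_l <- foot_event_times(p$stride_period, p$swing_time_left, off_l, p$duration)
  ev_r <- foot_event_times(p$stride_period, p$swing_time_right, off_r, p$duration)
  truth_events <- list(
    left = list(toe_off = as.integer(round(ev_l$toe_off * p$fps)),
                heel_strike = as.integer(round(ev_l$heel_strike * p$fps)),
                pair_toe_off = as.integer(round(ev_l$pair_toe_off * p$fps)),
                pair_heel_strike = as.integer(round(ev_l$pair_heel_strike * p$fps))),
    right = list(toe_off = as.integer(round(ev_r$toe_off * p$fps)),
                 heel_strike = as.integer(round(ev_r$heel_strike * p$fps)),
                 pair_toe_off = as.integer(round(ev_r$pair_toe_off * p$fps)),
                 pair_heel_strike = as.integer(round(ev_r$pair_heel_strike * p$fps))))
  swings <- list(left = rep(p$swing_time_left, length(ev_l$pair_toe_off)),
                 right = rep(p$swing_time_right, length(ev_r$pair_toe_off)))
  asym <- switch(p$paretic_side,
                 left = p$swing_time_left / p$swing_time_right,
                 right = p$swing_time_right / p$swing_time_left,
                 none = p$swing_time_left / p$swing_time_right)
  walker <- list(
    id = 1L, events = truth_events, swing_times = swings,
    asymmetry = asym, paretic_side = p$paretic_side,
    label = if (asym >= 1.13) "dependent" else "independent",
    params = p)
  truth <- structure(
    list(walkers = list(walker),
         frame_ids = replicate(n, 1L, simplify = FALSE)),
    class = "scene_truth")
  list(seq = kp_sequence(frames, fps = p$fps, image_size = p$image_size),
       truth = truth)
}

#' Simulate a multi-walker scene
#'
#' Merges several walkers into shared frames, recording the true identity of
#' every pose in every frame. With `crossing = TRUE` and two or more walkers,
#' the second walker is re-aimed to walk in the opposite direction through the
#' first walker's path so their bounding boxes overlap mid-sequence — a
#' stress case for identity maintenance.
#'
#' @param walkers List of [gait_params()].
#' @param crossing If `TRUE`, construct intersecting trajectories.
#' @param shuffle_seed Seed for the per-frame pose order shuffle (detections
#'   arrive unordered in real pose streams).
#' @return List with `seq` and `truth` as in [simulate_walker()].
#' @export
simulate_scene <- function(walkers, crossing = FALSE, shuffle_seed = 99L) {
  stopifnot(length(walkers) >= 1)
  if (length(walkers) == 1) {
    out <- simulate_walker(walkers[[1]])
    return(out)
  }
  if (crossing && length(walkers) >= 2) {
    w1 <- walkers[[1]]; w2 <- walkers[[2]]
    dur <- min(w1$duration, w2$duration)
    ## aim walker 2 against walker 1 so they meet near dur/2
    meet_x <- w1$start_position[1] + w1$direction * w1$walk_speed * dur / 2
    w2$direction <- -w1$direction
    w2$start_position <- c(meet_x - w2$direction * w2$walk_speed * dur / 2,
                           w1$start_position[2])
    walkers[[2]] <- do.call(gait_params, w2[setdiff(names(w2), "walk_speed")])
  }
  sims <- lapply(walkers, simulate_walker)
  n <- min(vapply(sims, function(s) n_frames(s$seq), 1L))
  fps <- sims[[1]]$seq$fps
  image_size <- sims[[1]]$seq$image_size
  orders <- with_seed(shuffle_seed,
                      replicate(n, sample(length(sims)), simplify = FALSE))
  frames <- vector("list", n)
  frame_ids <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- orders[[i]]
    poses <- lapply(ord, function(j) sims[[j]]$seq$frames[[i]]$poses[[1]])
    frames[[i]] <- list(frame_index = i - 1L, poses = poses)
    frame_ids[[i]] <- as.integer(ord)
  }
  walkers_truth <- lapply(seq_along(sims), function(j) {
    w <- sims[[j]]$truth$walkers[[1]]
    w$id <- as.integer(j)
    w
  })
  truth <- structure(list(walkers = walkers_truth, frame_ids = frame_ids),
                     class = "scene_truth")
  list(seq = kp_sequence(frames, fps = fps, image_size = image_size),
       truth = truth)
}
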