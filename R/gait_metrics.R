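#' Gait event detection configuration
#'
#' @param threshold_fraction Stance threshold as a fraction of the 90th
#'   percentile of the smoothed motion signal.
#' @param min_run Minimum stance-run length in signal samples.
#' @param smooth_window Moving-average window (samples) applied before
#'   thresholding.
#' @param mode Motion signal mode, see [motion_signal()].
#' @param min_swing,max_swing Plausibility gate (s) on swing durations;
#'   durations outside are discarded as artifacts.
#' @param min_cycles Cycles required per side for a valid asymmetry.
#' @param max_missing Maximum tolerated fraction of missing frames per foot.
#' @return An object of class `gait_config`.
#' @export
gait_config <- function(threshold_fraction = 0.15, min_run = 3,
                        smooth_window = 3, mode = c("displacement", "radial"),
                        min_swing = 0.1, max_swing = 2,
                        min_cycles = 2, max_missing = 0.3) {
  mode <- match.arg(mode)
  structure(list(threshold_fraction = threshold_fraction, min_run = min_run,
                 smooth_window = smooth_window, mode = mode,
                 min_swing = min_swing, max_swing = max_swing,
                 min_cycles = min_cycles, max_missing = max_missing),
            class = "gait_config")
}

#' A foot trajectory
#'
#' Heel and big-toe keypoint tracks of one foot in a static-camera coordinate
#' frame (image coordinates, or patient-centered coordinates un-projected via
#' [crop_to_image()]). Stationarity of the planted foot is the physical
#' signal the event detector relies on, so the frame must not translate with
#' the walker.
#'
#' @param heel,toe n x 3 matrices (x, y, confidence) per frame.
#' @param side `"left"` or `"right"`.
#' @param fps Frames per second.
#' @return An object of class `foot_trajectory`.
#' @export
foot_trajectory <- function(heel, toe, side = c("left", "right"), fps) {
  side <- match.arg(side)
  stopifnot(nrow(heel) == nrow(toe), fps > 0)
  structure(list(heel = heel, toe = toe, side = side, fps = fps),
            class = "foot_trajectory")
}

#' Foot trajectories from a track
#'
#' @param track An `amb_track` (poses in image coordinates).
#' @param side `"left"` or `"right"`.
#' @param fps Frames per second of the source video.
#' @return A [foot_trajectory()].
#' @export
track_foot_trajectory <- function(track, side = c("left", "right"), fps) {
  side <- match.arg(side)
  idx <- body25_index()
  heel_i <- if (side == "left") idx["l_heel"] else idx["r_heel"]
  toe_i <- if (side == "left") idx["l_big_toe"] else idx["r_big_toe"]
  heel <- t(vapply(track$poses, function(p) p[heel_i, ], numeric(3)))
  toe <- t(vapply(track$poses, function(p) p[toe_i, ], numeric(3)))
  foot_trajectory(heel, toe, side, fps)
}

#' Foot trajectories from a patient stream
#'
#' Un-projects the patient-centered heel/toe keypoints back to image
#' coordinates through the stored crop transforms, where the planted foot is
#' stationary, then builds the trajectory.
#'
#' @param stream A `patient_stream`.
#' @param side `"left"` or `"right"`.
#' @return A [foot_trajectory()].
#' @export
stream_foot_trajectory <- function(stream, side = c("left", "right")) {
  side <- match.arg(side)
  idx <- body25_index()
  heel_i <- if (side == "left") idx["l_heel"] else idx["r_heel"]
  toe_i <- if (side == "left") idx["l_big_toe"] else idx["r_big_toe"]
  n <- length(stream$centered_poses)
  unproject <- function(ki) {
    t(vapply(seq_len(n), function(k) {
      p <- stream$centered_poses[[k]][ki, ]
      if (p[3] <= 0) return(c(0, 0, 0))
      c(crop_to_image(stream, matrix(p[1:2], 1, 2), k), p[3])
    }, numeric(3)))
  }
  foot_trajectory(unproject(heel_i), unproject(toe_i), side, stream$fps)
}

## Linearly interpolate frames with confidence 0; error when all missing.
interpolate_missing <- function(mat) {
  ok <- mat[, 3] > 0
  if (!any(ok)) stop("all frames of the trajectory are missing")
  if (all(ok)) return(mat[, 1:2, drop = FALSE])
  n <- nrow(mat)
  x <- approx(which(ok), mat[ok, 1], xout = seq_len(n), rule = 2)$y
  y <- approx(which(ok), mat[ok, 2], xout = seq_len(n), rule = 2)$y
  cbind(x, y)
}

#' Per-frame motion signal of a keypoint track
#'
#' Displacement mode (default): `d_t = (x_{t+1}-x_t)^2 + (y_{t+1}-y_t)^2`,
#' the squared frame-to-frame motion — origin-invariant and zero exactly when
#' the point is stationary. Radial mode: `|(x_{t+1}^2+y_{t+1}^2) -
#' (x_t^2+y_t^2)|`, the change in squared distance from the coordinate
#' origin — kept as an alternative reading; it depends on the origin and can
#' vanish for motion along a circle about it.
#'
#' @param xy n x 2 coordinate matrix (n >= 2), missing frames already
#'   interpolated.
#' @param mode `"displacement"` or `"radial"`.
#' @return Nonnegative numeric vector of length n - 1.
#' @export
motion_signal <- function(xy, mode = c("displacement", "radial")) {
  mode <- match.arg(mode)
  if (nrow(xy) < 2) stop("need at least 2 frames")
  if (mode == "displacement") {
    diff(xy[, 1])^2 + diff(xy[, 2])^2
  } else {
    abs(diff(xy[, 1]^2 + xy[, 2]^2))
  }
}

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- (w - 1) %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + (w - 1 - half), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect stance runs in a motion signal
#'
#' Stance = maximal runs where the smoothed signal falls below
#' `threshold_fraction` times its 90th percentile; runs shorter than
#' `min_run` samples are discarded. An all-zero signal (no gait) yields a
#' single run covering the whole signal.
#'
#' @param signal Nonnegative motion signal from [motion_signal()].
#' @param cfg A [gait_config()].
#' @return Integer matrix with columns `start`, `end` (1-based, inclusive,
#'   in signal samples).
#' @export
detect_stance_runs <- function(signal, cfg = gait_config()) {
  n <- length(signal)
  if (n < 5) stop("signal too short (need >= 5 samples)")
  if (all(signal == 0))
    return(matrix(c(1L, n), 1, 2, dimnames = list(NULL, c("start", "end"))))
  sm <- moving_average(signal, cfg$smooth_window)
  ref <- quantile(sm, 0.9, names = FALSE)
  if (ref <= 0) ref <- max(sm)
  theta <- cfg$threshold_fraction * ref
  low <- sm < theta
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= cfg$min_run
  out <- cbind(start = starts[keep], end = ends[keep])
  storage.mode(out) <- "integer"
  out
}

#' Detect toe-off and heel-strike events of one foot
#'
#' Toe-off is the last frame of each stance run of the toe motion signal (the
#' moment the toe stops being stationary); heel-strike is the first frame of
#' each stance run of the heel signal (the moment the heel becomes
#' stationary). Runs touching the sequence boundary cannot witness the
#' corresponding transition and are not converted into events. Frames are
#' 0-based.
#'
#' @param foot A [foot_trajectory()].
#' @param cfg A [gait_config()].
#' @return List with `toe_off` and `heel_strike` integer frame vectors.
#' @export
detect_events <- function(foot, cfg = gait_config()) {
  stopifnot(inherits(foot, "foot_trajectory"))
  for (part in c("heel", "toe")) {
    miss <- mean(foot[[part]][, 3] <= 0)
    if (miss > cfg$max_missing)
      return(list(toe_off = integer(0), heel_strike = integer(0)))
  }
  toe_xy <- interpolate_missing(foot$toe)
  heel_xy <- interpolate_missing(foot$heel)
  toe_runs <- detect_stance_runs(motion_signal(toe_xy, cfg$mode), cfg)
  heel_runs <- detect_stance_runs(motion_signal(heel_xy, cfg$mode), cfg)
  n_sig <- nrow(toe_xy) - 1L
  ## signal sample i (1-based) spans frames (i-1, i) in 0-based numbering:
  ## a run [a, b] means frames a-1 .. b are stationary.
  toe_off <- toe_runs[toe_runs[, "end"] < n_sig, "end", drop = TRUE]
  heel_strike <- heel_runs[heel_runs[, "start"] > 1L, "start", drop = TRUE] - 1L
  list(toe_off = as.integer(toe_off), heel_strike = as.integer(heel_strike))
}

#' Swing times from paired events
#'
#' Each toe-off is paired with the next heel-strike of the same foot
#' (skipping to the next toe-off invalidates the earlier one); unpaired
#' events are dropped. Durations outside the plausibility gate are discarded
#' as artifacts.
#'
#' @param events Event list from [detect_events()].
#' @param fps Frames per second.
#' @param cfg A [gait_config()].
#' @return List with `durations` (s) and `mean` (NA when empty).
#' @export
swing_times <- function(events, fps, cfg = gait_config()) {
  to <- sort(events$toe_off)
  hs <- sort(events$heel_strike)
  durations <- numeric(0)
  for (i in seq_along(to)) {
    nxt <- hs[hs > to[i]]
    if (length(nxt) == 0) next
    if (i < length(to) && nxt[1] > to[i + 1]) next  # no strike before next toe-off
    durations <- c(durations, (nxt[1] - to[i]) / fps)
  }
  durations <- durations[durations > cfg$min_swing & durations < cfg$max_swing]
  list(durations = durations,
       mean = if (length(durations)) mean(durations) else NA_real_)
}

#' Swing-time asymmetry
#'
#' Ratio of the mean paretic-side swing time to the mean non-paretic-side
#' swing time; approximately 1 for symmetric gait and elevated in
#' hemiparetic gait. Valid only when both sides contribute at least
#' `min_cycles` cycles. With an unknown paretic side the ratio falls back to
#' max/min (flagged), since the clinical convention puts the paretic side in
#' the numerator.
#'
#' @param swing_left,swing_right Outputs of [swing_times()].
#' @param paretic_side `"left"`, `"right"` or `"none"`.
#' @param cfg A [gait_config()].
#' @return An object of class `asymmetry_result`: `ratio`,
#'   `n_cycles_paretic`, `n_cycles_nonparetic`, `valid`, `paretic_side`.
#' @export
asymmetry <- function(swing_left, swing_right,
                      paretic_side = c("none", "left", "right"),
                      cfg = gait_config()) {
  paretic_side <- match.arg(paretic_side)
  nl <- length(swing_left$durations); nr <- length(swing_right$durations)
  res <- list(ratio = NA_real_, n_cycles_paretic = NA_integer_,
              n_cycles_nonparetic = NA_integer_, valid = FALSE,
              paretic_side = paretic_side)
  if (paretic_side == "left") {
    par <- swing_left; nonpar <- swing_right
    res$n_cycles_paretic <- nl; res$n_cycles_nonparetic <- nr
  } else if (paretic_side == "right") {
    par <- swing_right; nonpar <- swing_left
    res$n_cycles_paretic <- nr; res$n_cycles_nonparetic <- nl
  } else {
    ## unknown side: larger mean over smaller, flagged via paretic_side
    if (nl >= cfg$min_cycles && nr >= cfg$min_cycles &&
        is.finite(swing_left$mean) && is.finite(swing_right$mean) &&
        min(swing_left$mean, swing_right$mean) > 0) {
      res$ratio <- max(swing_left$mean, swing_right$mean) /
        min(swing_left$mean, swing_right$mean)
      res$n_cycles_paretic <- max(nl, nr)
      res$n_cycles_nonparetic <- min(nl, nr)
      res$valid <- TRUE
    }
    class(res) <- "asymmetry_result"
    return(res)
  }
  if (res$n_cycles_paretic >= cfg$min_cycles &&
      res$n_cycles_nonparetic >= cfg$min_cycles &&
      is.finite(nonpar$mean) && nonpar$mean > 0) {
    res$ratio <- par$mean / nonpar$mean
    res$valid <- TRUE
  }
  class(res) <- "asymmetry_result"
  res
}

#' @export
print.asymmetry_result <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<asymmetry> ratio %.3f (paretic %s; %d vs %d cycles)\n",
                x$ratio, x$paretic_side, x$n_cycles_paretic,
                x$n_cycles_nonparetic))
  else cat("<asymmetry> invalid (insufficient gait cycles)\n")
  invisible(x)
}

#' Swing-time asymmetry of a clip or track
#'
#' Convenience pipeline: builds both foot trajectories (from a
#' `patient_stream`, an `amb_track`, or a single-walker [kp_sequence()]),
#' detects events, and computes the asymmetry ratio.
#'
#' @param x A `patient_stream`, `amb_track`, or single-person `kp_sequence`.
#' @param paretic_side `"left"`, `"right"` or `"none"`.
#' @param cfg A [gait_config()].
#' @param fps Required when `x` is an `amb_track`.
#' @return An `asymmetry_result`.
#' @export
clip_asymmetry <- function(x, paretic_side = "none", cfg = gait_config(),
                           fps = NULL) {
  if (inherits(x, "patient_stream")) {
    fl <- stream_foot_trajectory(x, "left")
    fr <- stream_foot_trajectory(x, "right")
  } else if (inherits(x, "amb_track")) {
    if (is.null(fps)) stop("fps required for a track")
    fl <- track_foot_trajectory(x, "left", fps)
    fr <- track_foot_trajectory(x, "right", fps)
  } else if (inherits(x, "kp_sequence")) {
    idx <- body25_index()
    take <- function(ki) t(vapply(x$frames, function(f) {
      if (length(f$poses) == 0) c(0, 0, 0) else f$poses[[1]][ki, ]
    }, numeric(3)))
    fl <- foot_trajectory(take(idx["l_heel"]), take(idx["l_big_toe"]),
                          "left", x$fps)
    fr <- foot_trajectory(take(idx["r_heel"]), take(idx["r_big_toe"]),
                          "right", x$fps)
  } else stop("unsupported input for clip_asymmetry")
  ev_l <- detect_events(fl, cfg)
  ev_r <- detect_events(fr, cfg)
  asymmetry(swing_times(ev_l, fl$fps, cfg), swing_times(ev_r, fr$fps, cfg),
            paretic_side, cfg)
}
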