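#' Extract the patient-centered stream of a target track
#'
#' For every frame a target track covers, its margin-expanded box is made
#' square (the short side is padded symmetrically), the square is cropped
#' from the video frame and resized to `out_size` x `out_size`, and the
#' keypoints are re-expressed in crop coordinates (translation plus isotropic
#' scale). Cropping along the walker yields a soft image-registration effect:
#' the background moves, the patient stays centered.
#'
#' Frames may be a list of `height x width x 3` arrays or a function from
#' 0-based frame index to such an array (see [frame_provider()]); crops are
#' produced lazily through `$get_frame(k)` so long sequences never need all
#' frames in memory. `frames = NULL` gives a pose-only stream.
#'
#' @param seq The [kp_sequence()] the tracks came from.
#' @param frames List of RGB arrays, a provider function, or `NULL`.
#' @param tracks Output of [track_sequence()].
#' @param target_id Track id of the patient (clinician-selected).
#' @param margin Extra margin fraction applied to the track box.
#' @param out_size Side of the square crop in pixels.
#' @return An object of class `patient_stream`: `frame_indices` (0-based),
#'   `fps`, `out_size`, `transforms` (per frame `c(x0, y0, scale)`:
#'   crop = (image - (x0, y0)) * scale), `centered_poses`, `get_frame`.
#' @export
extract_patient <- function(seq, frames, tracks, target_id,
                            margin = 0.10, out_size = 128) {
  ids <- vapply(tracks, function(tr) tr$id, 1L)
  ti <- which(ids == target_id)
  if (length(ti) != 1)
    stop("target id ", target_id, " not among tracks (available: ",
         paste(ids, collapse = ", "), ")")
  tr <- tracks[[ti]]
  n <- length(tr$frames)
  transforms <- matrix(0, n, 3, dimnames = list(NULL, c("x0", "y0", "scale")))
  centered <- vector("list", n)
  for (k in seq_len(n)) {
    box <- tr$boxes[k, ]
    w <- box[3] - box[1]; h <- box[4] - box[2]
    pad <- margin * max(w, h)
    box <- box + c(-pad, -pad, pad, pad)
    w <- box[3] - box[1]; h <- box[4] - box[2]
    side <- max(w, h)
    cx <- (box[1] + box[3]) / 2; cy <- (box[2] + box[4]) / 2
    x0 <- cx - side / 2; y0 <- cy - side / 2
    sc <- out_size / side
    transforms[k, ] <- c(x0, y0, sc)
    pose <- tr$poses[[k]]
    cp <- pose
    cp[, 1] <- (pose[, 1] - x0) * sc
    cp[, 2] <- (pose[, 2] - y0) * sc
    cp[pose[, 3] <= 0, 1:2] <- 0
    centered[[k]] <- cp
  }
  get_src <- if (is.null(frames)) NULL
  else if (is.function(frames)) frames
  else function(i) frames[[i + 1L]]
  force(out_size)
  get_frame <- function(k) {
    if (is.null(get_src)) stop("stream has no video frames")
    img <- get_src(tr$frames[k])
    tf <- transforms[k, ]
    ## sample the square region on the out_size grid (replicate edge)
    gx <- (seq_len(out_size) - 0.5) / tf[3] + tf[1] - 0.5
    gy <- (seq_len(out_size) - 0.5) / tf[3] + tf[2] - 0.5
    vals <- sample_bilinear(img, rep(gx, each = out_size),
                            rep(gy, times = out_size))
    array(vals, dim = c(out_size, out_size, 3))
  }
  structure(list(target_id = tr$id, frame_indices = tr$frames,
                 fps = seq$fps, out_size = out_size,
                 transforms = transforms, centered_poses = centered,
                 get_frame = get_frame),
            class = "patient_stream")
}

#' Map crop coordinates back to image coordinates
#'
#' Inverse of the crop transform of frame `k` of a patient stream; composing
#' with the forward transform is the identity to well under half a pixel.
#'
#' @param stream A `patient_stream`.
#' @param xy n x 2 matrix of crop coordinates.
#' @param k Frame position within the stream (1-based).
#' @return n x 2 matrix of image coordinates.
#' @export
crop_to_image <- function(stream, xy, k) {
  tf <- stream$transforms[k, ]
  cbind(xy[, 1] / tf[3] + tf[1], xy[, 2] / tf[3] + tf[2])
}

#' Split a patient stream into 5-second clips
#'
#' Non-overlapping consecutive windows of `clip_seconds`; a trailing
#' remainder shorter than the window is dropped. Gaps in the stream (frames
#' the track missed) start a new run, so every clip is contiguous video.
#'
#' @param stream A `patient_stream` from [extract_patient()].
#' @param clip_seconds Window length in seconds (default 5).
#' @param action_label Action metadata attached to every clip (action
#'   annotation is manual upstream; the simulator produces walking only).
#' @return List of `amb_clip` objects; empty if the stream is too short.
#' @export
split_clips <- function(stream, clip_seconds = 5, action_label = "walk") {
  stopifnot(inherits(stream, "patient_stream"))
  n_per <- round(clip_seconds * stream$fps)
  fi <- stream$frame_indices
  runs <- split(seq_along(fi), cumsum(c(1L, diff(fi) != 1L)))
  clips <- list()
  for (run in runs) {
    n_full <- floor(length(run) / n_per)
    for (w in seq_len(n_full)) {
      pos <- run[((w - 1) * n_per + 1):(w * n_per)]
      clips[[length(clips) + 1]] <- structure(list(
        source_id = stream$target_id,
        start_frame = fi[pos[1]],
        end_frame = fi[pos[length(pos)]] + 1L,
        positions = pos, fps = stream$fps,
        action_label = action_label, stream = stream),
        class = "amb_clip")
    }
  }
  clips
}

#' @export
print.amb_clip <- function(x, ...) {
  cat(sprintf("<amb_clip> track %d frames [%d, %d) @ %g fps, action '%s'\n",
              x$source_id, x$start_frame, x$end_frame, x$fps,
              x$action_label %||% "<missing>"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Keep only walk-action clips
#'
#' @param clips List of clips from [split_clips()].
#' @return The walking clips in their original order; clips without an action
#'   label are excluded with a warning.
#' @export
filter_walk <- function(clips) {
  miss <- vapply(clips, function(cl) is.null(cl$action_label), TRUE)
  if (any(miss))
    warning(sum(miss), " clip(s) without action label excluded")
  clips <- clips[!miss]
  clips[vapply(clips, function(cl) identical(cl$action_label, "walk"), TRUE)]
}

#' Build the network input tensor of a clip
#'
#' Samples 25 frames at a uniform 5 Hz stride from the clip (nearest frame
#' when the stride is non-integer), each already cropped to 128 x 128 by the
#' patient stream, giving a `25 x 128 x 128 x 3` array (time x width x
#' height x color) with values in `[0, 1]`.
#'
#' @param clip An `amb_clip`.
#' @param n_t Number of sampled frames (25 at 5 Hz over 5 s).
#' @return An object of class `clip_tensor` (4D array).
#' @export
to_tensor <- function(clip, n_t = 25) {
  stopifnot(inherits(clip, "amb_clip"))
  stride <- clip$fps / 5
  rel <- round(seq(0, by = stride, length.out = n_t))
  if (length(clip$positions) < n_t || max(rel) + 1 > length(clip$positions))
    stop("clip too short to sample ", n_t, " frames at 5 Hz")
  pos <- clip$positions[rel + 1]
  sz <- clip$stream$out_size
  arr <- array(0, dim = c(n_t, sz, sz, 3))
  for (k in seq_len(n_t)) {
    img <- clip$stream$get_frame(pos[k])   # sz x sz x 3, rows = y
    ## tensor layout is time x width x height x color
    arr[k, , , ] <- aperm(img, c(2, 1, 3))
  }
  arr <- pmin(pmax(arr, 0), 1)
  structure(arr, class = c("clip_tensor", "array"))
}

#' Materialize the cropped frames of a clip
#' @param clip An `amb_clip`.
#' @return List of cropped RGB arrays.
#' @export
clip_frames <- function(clip) {
  lapply(clip$positions, clip$stream$get_frame)
}
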