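#' Construct a keypoint sequence
#'
#' A keypoint sequence is the package's canonical container for a multi-person
#' 2D pose stream: an ordered list of frames, each holding zero or more
#' 25-keypoint poses, plus the frame rate and pixel size of the companion
#' video. Coordinates are 0-based pixels, origin top-left, y downward; a
#' missing detection is encoded as confidence 0 (its x/y carry no meaning).
#'
#' @param frames List of frames; each frame is a list with `frame_index`
#'   (0-based integer) and `poses` (list of 25x3 matrices with columns
#'   x, y, confidence).
#' @param fps Frames per second (> 0).
#' @param image_size Integer vector `c(width, height)` in pixels.
#' @return An object of class `kp_sequence`.
#' @export
kp_sequence <- function(frames, fps, image_size) {
  stopifnot(is.numeric(fps), length(fps) == 1, fps > 0,
            length(image_size) == 2, all(image_size > 0))
  seq <- structure(
    list(frames = frames, fps = as.numeric(fps),
         image_size = as.numeric(image_size)),
    class = "kp_sequence")
  validate_kp_sequence(seq)
}

#' @export
print.kp_sequence <- function(x, ...) {
  cat(sprintf("<kp_sequence> %d frames @ %g fps, %dx%d px, %s poses/frame\n",
              length(x$frames), x$fps, x$image_size[1], x$image_size[2],
              paste(range(vapply(x$frames, function(f) length(f$poses), 1L)),
                    collapse = "-")))
  invisible(x)
}

validate_kp_sequence <- function(seq) {
  n <- length(seq$frames)
  if (n > 0) {
    idx <- vapply(seq$frames, function(f) as.integer(f$frame_index), 1L)
    if (!identical(idx, seq(0L, n - 1L)))
      stop("frame indices must be contiguous from 0")
    for (f in seq$frames) {
      for (p in f$poses) {
        if (!is.matrix(p) || nrow(p) != 25 || ncol(p) != 3)
          stop("each pose must be a 25x3 matrix (x, y, confidence)")
        if (any(p[, 3] < 0 | p[, 3] > 1))
          stop("confidences must lie in [0, 1]")
        v <- p[, 3] > 0
        if (any(v)) {
          if (any(p[v, 1] < 0 | p[v, 1] >= seq$image_size[1]) ||
              any(p[v, 2] < 0 | p[v, 2] >= seq$image_size[2]))
            stop("valid keypoint coordinates must lie inside image bounds")
        }
      }
    }
  }
  seq
}

#' Number of frames in a sequence
#' @param seq A `kp_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) length(seq$frames)

#' Read a directory of OpenPose per-frame JSON files
#'
#' Parses the per-frame JSON emitted by OpenPose-style pose estimators: each
#' file holds a `people` list whose entries carry a flat 75-value
#' `pose_keypoints_2d` array (x, y, confidence triplets in BODY-25 order).
#' Files are ordered by the last run of digits in their file names. Poses
#' whose 25 confidences are all zero are dropped; an empty `people` list
#' yields a frame with zero poses (the frame is retained).
#'
#' @param path Directory containing `*.json` files, one per frame.
#' @param fps Frame rate of the companion video (Hz).
#' @param image_size `c(width, height)` of the companion video in pixels.
#' @return A [kp_sequence()].
#' @export
read_openpose_dir <- function(path, fps, image_size) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- list.files(path, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0) stop("no JSON files in ", path)
  num <- vapply(files, function(f) {
    m <- regmatches(basename(f), gregexpr("[0-9]+", basename(f)))[[1]]
    if (length(m) == 0) NA_real_ else as.numeric(m[length(m)])
  }, 1.0)
  if (anyNA(num)) num <- seq_along(files)
  files <- files[order(num)]
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    doc <- tryCatch(jsonlite::fromJSON(files[i], simplifyVector = FALSE),
                    error = function(e) stop("corrupt JSON file: ", files[i],
                                             " (", conditionMessage(e), ")"))
    if (is.null(doc$people)) stop("missing 'people' list in ", files[i])
    poses <- list()
    for (person in doc$people) {
      kp <- unlist(person$pose_keypoints_2d)
      if (length(kp) != 75)
        stop("pose_keypoints_2d must have 75 values in ", files[i],
             " (got ", length(kp), ")")
      m <- matrix(kp, ncol = 3, byrow = TRUE,
                  dimnames = list(BODY25_NAMES, c("x", "y", "conf")))
      ## zero-confidence keypoints carry meaningless coordinates: zero them
      m[m[, 3] <= 0, 1:2] <- 0
      m[m[, 3] <= 0, 3] <- 0
      if (any(m[, 3] > 0)) poses[[length(poses) + 1]] <- m
    }
    frames[[i]] <- list(frame_index = i - 1L, poses = poses)
  }
  kp_sequence(frames, fps = fps, image_size = image_size)
}

#' Write / read the internal newline-delimited JSON sequence format
#'
#' The on-disk format is one JSON record per line: a header record carrying
#' `fps` and `image_size`, followed by one record per frame with the poses as
#' flat 75-value arrays. Numbers are written with 17 significant digits so the
#' round trip `read_sequence(write_sequence(s))` reproduces `s` exactly,
#' including zero confidences.
#'
#' @param seq A [kp_sequence()].
#' @param path Output (or input) file path.
#' @return `write_sequence` returns `path` invisibly; `read_sequence` returns
#'   a [kp_sequence()].
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "kp_sequence"))
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  header <- sprintf('{"type":"header","fps":%s,"image_size":[%s,%s]}',
                    fmt_dbl(seq$fps), fmt_dbl(seq$image_size[1]),
                    fmt_dbl(seq$image_size[2]))
  lines <- character(1 + length(seq$frames))
  lines[1] <- header
  for (i in seq_along(seq$frames)) {
    f <- seq$frames[[i]]
    pose_strs <- vapply(f$poses, function(p) {
      paste0("[", paste(fmt_dbl(as.numeric(t(p))), collapse = ","), "]")
    }, "")
    lines[i + 1] <- sprintf('{"type":"frame","frame_index":%d,"poses":[%s]}',
                            as.integer(f$frame_index),
                            paste(pose_strs, collapse = ","))
  }
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty sequence file: ", path)
  header <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)
  if (!identical(header$type, "header")) stop("missing header record in ", path)
  frames <- vector("list", length(lines) - 1L)
  for (i in seq_along(frames)) {
    rec <- jsonlite::fromJSON(lines[i + 1], simplifyVector = FALSE)
    poses <- lapply(rec$poses, function(kp) {
      matrix(unlist(kp), ncol = 3, byrow = TRUE,
             dimnames = list(BODY25_NAMES, c("x", "y", "conf")))
    })
    frames[[i]] <- list(frame_index = as.integer(rec$frame_index), poses = poses)
  }
  kp_sequence(frames, fps = header$fps, image_size = unlist(header$image_size))
}

#' Bounding box from a pose
#'
#' Axis-aligned box spanning the valid (confidence > 0) keypoints of a pose,
#' expanded by `margin` times the larger box side on every side, then clamped
#' to the image if `image_size` is given. Keypoints sit inside the body
#' silhouette, so a margin is needed for crops to contain the whole person.
#'
#' @param pose 25x3 keypoint matrix.
#' @param margin Fraction of `max(width, height)` added on each side.
#' @param image_size Optional `c(width, height)` to clamp against.
#' @return Numeric vector `c(x_min, y_min, x_max, y_max)`.
#' @export
bbox_from_pose <- function(pose, margin = 0.10, image_size = NULL) {
  v <- pose[, 3] > 0
  if (sum(v) < 2) stop("untrackable pose: fewer than 2 valid keypoints")
  x <- pose[v, 1]; y <- pose[v, 2]
  box <- c(min(x), min(y), max(x), max(y))
  pad <- margin * max(box[3] - box[1], box[4] - box[2])
  box <- box + c(-pad, -pad, pad, pad)
  if (!is.null(image_size)) {
    box[c(1, 3)] <- pmin(pmax(box[c(1, 3)], 0), image_size[1] - 1)
    box[c(2, 4)] <- pmin(pmax(box[c(2, 4)], 0), image_size[2] - 1)
  }
  names(box) <- c("x_min", "y_min", "x_max", "y_max")
  box
}
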