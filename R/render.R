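## Rasterization of keypoint skeletons into RGB frames. Deterministic given
## the sequence: constant background, limbs drawn as capsules (distance to
## segment <= half thickness) between skeleton-adjacent keypoints.

RENDER_BG <- 0.05
RENDER_FG <- c(0.95, 0.80, 0.65)

## Linear pixel indices (into an h x w plane) of a thick segment, computed
## over the pixels of the segment's bounding box only.
segment_hits <- function(h, w, p0, p1, thickness) {
  r <- thickness / 2
  x0 <- max(1, floor(min(p0[1], p1[1]) - r)); x1 <- min(w, ceiling(max(p0[1], p1[1]) + r))
  y0 <- max(1, floor(min(p0[2], p1[2]) - r)); y1 <- min(h, ceiling(max(p0[2], p1[2]) + r))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys)) - 1  # pixel centers in 0-based coords
  py <- rep(ys, times = length(xs)) - 1
  d <- p1 - p0
  len2 <- sum(d * d)
  if (len2 < 1e-12) {
    dist2 <- (px - p0[1])^2 + (py - p0[2])^2
  } else {
    tt <- pmin(pmax(((px - p0[1]) * d[1] + (py - p0[2]) * d[2]) / len2, 0), 1)
    dist2 <- (px - (p0[1] + tt * d[1]))^2 + (py - (p0[2] + tt * d[2]))^2
  }
  hit <- dist2 <= r * r
  (py[hit] + 1) + px[hit] * h
}

#' Render one frame of poses
#'
#' @param poses List of 25x3 keypoint matrices (image coordinates).
#' @param image_size `c(width, height)` pixels.
#' @param style `"stick"` (thin limbs) or `"blob"` (thick silhouette-like
#'   limbs). Both draw the same skeleton; support regions agree within a
#'   small dilation.
#' @return `height x width x 3` array in `[0, 1]`.
#' @export
render_frame <- function(poses, image_size, style = c("stick", "blob")) {
  style <- match.arg(style)
  w <- image_size[1]; h <- image_size[2]
  canvas <- array(RENDER_BG, dim = c(h, w, 3))
  thickness <- if (style == "stick") 4 else 9
  hits <- vector("list", length(poses))
  for (i in seq_along(poses)) {
    pose <- poses[[i]]
    segs <- lapply(seq_len(nrow(BODY25_LIMBS)), function(e) {
      a <- BODY25_LIMBS[e, 1]; b <- BODY25_LIMBS[e, 2]
      if (pose[a, 3] > 0 && pose[b, 3] > 0)
        segment_hits(h, w, pose[a, 1:2], pose[b, 1:2], thickness)
      else integer(0)
    })
    ## head disc at the nose keypoint
    if (pose[1, 3] > 0)
      segs[[length(segs) + 1]] <- segment_hits(h, w, pose[1, 1:2],
                                               pose[1, 1:2], thickness * 2.5)
    hits[[i]] <- unlist(segs)
  }
  lin <- unique(unlist(hits))
  if (length(lin)) {
    n <- h * w
    canvas[lin] <- RENDER_FG[1]
    canvas[lin + n] <- RENDER_FG[2]
    canvas[lin + 2 * n] <- RENDER_FG[3]
  }
  canvas
}

#' Render a keypoint sequence to frames
#'
#' @param seq A [kp_sequence()].
#' @param style Rendering style, see [render_frame()].
#' @return List of `height x width x 3` arrays, one per frame.
#' @export
render_video <- function(seq, style = c("stick", "blob")) {
  style <- match.arg(style)
  lapply(seq$frames, function(f) render_frame(f$poses, seq$image_size, style))
}

#' A lazy frame provider for a sequence
#'
#' Returns `function(frame_index)` (0-based) rendering one frame on demand —
#' the memory-safe way to feed long sequences into [extract_patient()].
#'
#' @inheritParams render_video
#' @return A function from 0-based frame index to an RGB array.
#' @export
frame_provider <- function(seq, style = c("stick", "blob")) {
  style <- match.arg(style)
  force(seq)
  function(frame_index) {
    f <- seq$frames[[frame_index + 1L]]
    render_frame(f$poses, seq$image_size, style)
  }
}

## Bilinear sampling of img (H x W x 3) at 0-based pixel coords (x, y),
## replicate-edge outside the image. x, y are equal-length vectors.
sample_bilinear <- function(img, x, y) {
  h <- dim(img)[1]; w <- dim(img)[2]
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  n <- h * w
  out <- matrix(0, length(x), 3)
  i00 <- (y0 + 1) + x0 * h
  i10 <- (y1 + 1) + x0 * h
  i01 <- (y0 + 1) + x1 * h
  i11 <- (y1 + 1) + x1 * h
  for (c in 1:3) {
    off <- (c - 1) * n
    out[, c] <- (1 - fx) * ((1 - fy) * img[i00 + off] + fy * img[i10 + off]) +
      fx * ((1 - fy) * img[i01 + off] + fy * img[i11 + off])
  }
  out
}

## Resize an H x W x 3 image to out_h x out_w by bilinear interpolation.
resize_bilinear <- function(img, out_h, out_w) {
  sx <- dim(img)[2] / out_w
  sy <- dim(img)[1] / out_h
  xs <- (seq_len(out_w) - 0.5) * sx - 0.5
  ys <- (seq_len(out_h) - 0.5) * sy - 0.5
  x <- rep(xs, each = out_h)
  y <- rep(ys, times = out_w)
  vals <- sample_bilinear(img, x, y)
  array(vals, dim = c(out_h, out_w, 3))
}
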