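## Shared fixtures: tiny poses, a naive conv oracle, and scaled-down model
## configurations used across the unit tests.

## A minimal valid pose: all 25 keypoints on a grid, confidence 0.9.
tiny_pose <- function(x0 = 10, y0 = 10, conf = 0.9) {
  m <- cbind(x = x0 + seq(0, 24) %% 5 * 4,
             y = y0 + seq(0, 24) %/% 5 * 6,
             conf = conf)
  rownames(m) <- names(body25_index())
  m
}

## Write an OpenPose-style per-frame JSON directory; people is a list of
## 25x3 matrices per frame.
write_openpose_dir <- function(dir, frames_people) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames_people)) {
    people <- lapply(frames_people[[i]], function(m) {
      list(pose_keypoints_2d = as.numeric(t(m)))
    })
    jsonlite::write_json(list(version = 1.3, people = people),
                         file.path(dir, sprintf("video_%012d_keypoints.json",
                                                i - 1)),
                         auto_unbox = TRUE, digits = NA)
  }
  dir
}

## Direct-loop 3D convolution (zero "same" padding), the independent oracle
## for the im2col/GEMM implementation. x: (T,H,W,C); W: (kt*kh*kw*cin) x cout.
naive_conv3d <- function(x, W, b, kernel, stride) {
  d <- dim(x)
  kt <- kernel[1]; kh <- kernel[2]; kw <- kernel[3]
  pt <- (kt - 1) %/% 2; ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  To <- (d[1] + 2 * pt - kt) %/% stride[1] + 1
  Ho <- (d[2] + 2 * ph - kh) %/% stride[2] + 1
  Wo <- (d[3] + 2 * pw - kw) %/% stride[3] + 1
  cout <- ncol(W)
  Wa <- array(W, dim = c(kt, kh, kw, d[4], cout))
  out <- array(0, dim = c(To, Ho, Wo, cout))
  for (co in seq_len(cout)) for (to in seq_len(To)) for (ho in seq_len(Ho))
    for (wo in seq_len(Wo)) {
      acc <- b[co]
      for (c in seq_len(d[4])) for (dt in seq_len(kt)) for (dh in seq_len(kh))
        for (dw in seq_len(kw)) {
          ti <- (to - 1) * stride[1] - pt + dt
          hi <- (ho - 1) * stride[2] - ph + dh
          wi <- (wo - 1) * stride[3] - pw + dw
          if (ti >= 1 && ti <= d[1] && hi >= 1 && hi <= d[2] &&
              wi >= 1 && wi <= d[3])
            acc <- acc + x[ti, hi, wi, c] * Wa[dt, dh, dw, c, co]
        }
      out[to, ho, wo, co] <- acc
    }
  out
}

## A 7-block model on a small input, for fast unit tests of the network.
tiny_model_config <- function(seed = 1) {
  blocks <- list(
    list(kernel = c(1, 3, 3), channels = 4, stride = c(1, 2, 2)),
    list(kernel = c(3, 3, 3), channels = 4, stride = c(1, 2, 2)),
    list(kernel = c(1, 3, 3), channels = 6, stride = c(1, 1, 1)),
    list(kernel = c(3, 3, 3), channels = 6, stride = c(2, 2, 2)),
    list(kernel = c(1, 3, 3), channels = 8, stride = c(1, 1, 1)),
    list(kernel = c(5, 3, 3), channels = 8, stride = c(1, 2, 2)),
    list(kernel = c(1, 1, 1), channels = 8, stride = c(1, 1, 1)))
  model_config(input_shape = c(7, 16, 16, 3), blocks = blocks,
               dense_units = c(8, 4, 1), width_multiplier = 1, seed = seed)
}

## Two-class separable toy tensors for fast training tests: class 1 carries a
## bright moving bar, class 0 a dim static one.
toy_tensor <- function(label, seed) {
  with_seed <- get("with_seed", envir = asNamespace("ambustride"))
  with_seed(seed, {
    x <- array(runif(7 * 16 * 16 * 3, 0, 0.1), dim = c(7, 16, 16, 3))
    if (label == 1) {
      for (t in 1:7) x[t, , ((t - 1) %% 14) + 1:2, ] <- 0.95
    } else {
      x[, , 8:9, ] <- 0.4
    }
    x
  })
}
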