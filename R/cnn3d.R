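## Kernel shapes (t x h x w) admissible in a convolutional block.
ALLOWED_KERNELS <- list(c(1, 1, 3), c(1, 3, 3), c(1, 5, 5),
                        c(3, 3, 3), c(5, 3, 3), c(1, 1, 1))

kernel_allowed <- function(k) {
  any(vapply(ALLOWED_KERNELS, function(a) all(a == k), TRUE))
}

#' Default convolutional blocks
#'
#' Seven blocks in series, each one convolution with kernels drawn from the
#' admissible set, channel progression 16-24-32-48-64-96-128 (scaled by the
#' model's width multiplier) and strides that shrink 128 x 128 x 25 input to
#' a 2 x 2 x 4 feature map before global average pooling — a reduced-width,
#' faithful-shape relative of the mobile video network family this
#' architecture follows.
#'
#' @return List of 7 block specifications (`kernel`, `channels`, `stride`).
#' @export
default_blocks <- function() {
  list(
    list(kernel = c(1, 3, 3), channels = 16,  stride = c(1, 2, 2)),
    list(kernel = c(3, 3, 3), channels = 24,  stride = c(2, 2, 2)),
    list(kernel = c(1, 3, 3), channels = 32,  stride = c(1, 2, 2)),
    list(kernel = c(3, 3, 3), channels = 48,  stride = c(2, 2, 2)),
    list(kernel = c(1, 3, 3), channels = 64,  stride = c(1, 2, 2)),
    list(kernel = c(5, 3, 3), channels = 96,  stride = c(2, 2, 2)),
    list(kernel = c(1, 1, 1), channels = 128, stride = c(1, 1, 1))
  )
}

#' Model configuration
#'
#' @param input_shape `c(time, width, height, color)`; the production input
#'   is `c(25, 128, 128, 3)` (5 s of patient-centered video at 5 Hz).
#' @param blocks Exactly 7 convolutional blocks (see [default_blocks()]).
#' @param dense_units Three dense layer widths ending in 1 (sigmoid output).
#' @param width_multiplier Channel scaling (> 0); conv parameter count grows
#'   roughly quadratically with it. 0.25 is the desk-scale default.
#' @param seed Seed for deterministic parameter initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_shape = c(25, 128, 128, 3),
                         blocks = default_blocks(),
                         dense_units = c(64, 32, 1),
                         width_multiplier = 0.25, seed = 1) {
  if (length(blocks) != 7)
    stop("exactly 7 convolutional blocks are required (got ",
         length(blocks), ")")
  for (b in blocks) {
    if (!kernel_allowed(b$kernel))
      stop("kernel ", paste(b$kernel, collapse = "x"),
           " is not in the admissible set")
    if (b$channels < 1) stop("block channels must be >= 1")
  }
  if (length(dense_units) != 3 || dense_units[3] != 1)
    stop("dense_units must be three layers ending in 1 unit")
  if (width_multiplier <= 0) stop("width_multiplier must be positive")
  structure(list(input_shape = as.integer(input_shape), blocks = blocks,
                 dense_units = as.integer(dense_units),
                 width_multiplier = width_multiplier, seed = as.integer(seed)),
            class = "model_config")
}

conv_out_len <- function(n, k, s) (n + 2 * ((k - 1) %/% 2) - k) %/% s + 1

## Arch table and per-layer dims for a config.
plan_arch <- function(cfg) {
  w <- cfg$width_multiplier
  dims <- list(cfg$input_shape)
  rows <- NULL
  cin <- cfg$input_shape[4]
  for (b in cfg$blocks) {
    cout <- max(1L, as.integer(round(b$channels * w)))
    rows <- rbind(rows, c(b$kernel, b$stride, cin, cout))
    d <- dims[[length(dims)]]
    dims[[length(dims) + 1]] <- c(
      conv_out_len(d[1], b$kernel[1], b$stride[1]),
      conv_out_len(d[2], b$kernel[2], b$stride[2]),
      conv_out_len(d[3], b$kernel[3], b$stride[3]),
      cout)
    cin <- cout
  }
  colnames(rows) <- c("kt", "kh", "kw", "st", "sh", "sw", "cin", "cout")
  storage.mode(rows) <- "integer"
  if (any(dims[[length(dims)]] < 1))
    stop("input shape too small for the block strides")
  list(conv = rows, dims = dims)
}

#' Build the dependence classifier network
#'
#' Maps a `25 x 128 x 128 x 3` clip tensor (values scaled to `[0, 1]`,
#' centered internally) to a scalar in `[0, 1]` — the closer to 1, the more
#' dependent the ambulation. Seven convolutional blocks with swish
#' activations, global average pooling over space and time, then three dense
#' layers with a sigmoid output. Weights use He-uniform initialization under
#' the config seed, so identical seeds give identical parameters.
#'
#' @param cfg A [model_config()].
#' @return An object of class `amb_cnn3d`.
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  plan <- plan_arch(cfg)
  conv_w <- list(); conv_b <- list()
  dense_w <- list(); dense_b <- list()
  ## He-style uniform init with a gain of 2 on swish layers: swish has slope
  ## ~1/2 near zero, so un-gained init lets activations decay twofold per
  ## layer (vanishing features after 7 blocks). The gain keeps activation
  ## scale roughly constant through the stack.
  swish_gain <- 2
  with_seed(cfg$seed, {
    for (l in seq_len(nrow(plan$conv))) {
      p <- plan$conv[l, ]
      fan_in <- p["kt"] * p["kh"] * p["kw"] * p["cin"]
      lim <- swish_gain * sqrt(6 / fan_in)
      conv_w[[l]] <- matrix(runif(fan_in * p["cout"], -lim, lim),
                            nrow = fan_in, ncol = p["cout"])
      conv_b[[l]] <- rep(0, p["cout"])
    }
    d_in <- plan$dims[[length(plan$dims)]][4]
    for (l in seq_along(cfg$dense_units)) {
      d_out <- cfg$dense_units[l]
      lim <- swish_gain * sqrt(6 / d_in)
      dense_w[[l]] <- matrix(runif(d_in * d_out, -lim, lim), d_in, d_out)
      dense_b[[l]] <- rep(0, d_out)
      d_in <- d_out
    }
    ## zero-init the output layer so training starts at p = 0.5
    dense_w[[length(dense_w)]][] <- 0
  })
  structure(list(config = cfg, arch = plan$conv, dims = plan$dims,
                 conv_w = conv_w, conv_b = conv_b,
                 dense_w = dense_w, dense_b = dense_b),
            class = "amb_cnn3d")
}

#' Parameter counts of a model
#' @param model An `amb_cnn3d`.
#' @return List with `conv`, `dense` and `total` parameter counts.
#' @export
n_params <- function(model) {
  conv <- sum(vapply(model$conv_w, length, 1)) +
    sum(vapply(model$conv_b, length, 1))
  dense <- sum(vapply(model$dense_w, length, 1)) +
    sum(vapply(model$dense_b, length, 1))
  list(conv = conv, dense = dense, total = conv + dense)
}

#' @export
print.amb_cnn3d <- function(x, ...) {
  np <- n_params(x)
  cat(sprintf("<amb_cnn3d> input %s, 7 conv blocks, %d params (width %.2f)\n",
              paste(x$config$input_shape, collapse = "x"),
              np$total, x$config$width_multiplier))
  invisible(x)
}

#' Training configuration
#'
#' Stochastic gradient descent with a cyclic (warm-restart) cosine schedule:
#' the learning rate starts at `peak_lr` at the beginning of each cycle and
#' decays to zero by cosine within it; cycle lengths double (10, 20, 40
#' epochs), totalling 70 epochs. Loss is binary cross-entropy.
#'
#' @param peak_lr Peak learning rate (5e-4).
#' @param cycle_epochs Cycle lengths; each must be double the previous.
#' @param batch_size Mini-batch size.
#' @param momentum SGD momentum.
#' @param seed Seed controlling the epoch shuffles.
#' @return An object of class `train_config`.
#' @export
train_config <- function(peak_lr = 5e-4, cycle_epochs = c(10, 20, 40),
                         batch_size = 8, momentum = 0.9, seed = 1) {
  if (length(cycle_epochs) > 1 &&
      !all(cycle_epochs[-1] == 2 * cycle_epochs[-length(cycle_epochs)]))
    stop("cycle lengths must double: e[k+1] = 2 * e[k]")
  structure(list(peak_lr = peak_lr, cycle_epochs = as.integer(cycle_epochs),
                 total_epochs = as.integer(sum(cycle_epochs)),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cyclic learning-rate schedule
#'
#' Cosine decay from `peak_lr` to 0 within each cycle; cycles restart at
#' epochs 0, 10 and 30 under the default (10, 20, 40) cycle lengths.
#'
#' @param epoch 0-based epoch (vectorized), `0 <= epoch < total_epochs`.
#' @param cfg A [train_config()].
#' @return Learning rate(s).
#' @export
lr_schedule <- function(epoch, cfg = train_config()) {
  if (any(epoch < 0 | epoch >= cfg$total_epochs))
    stop("epoch out of range [0, ", cfg$total_epochs, ")")
  starts <- cumsum(c(0, cfg$cycle_epochs))
  vapply(epoch, function(e) {
    ci <- findInterval(e, starts)
    pos <- e - starts[ci]
    len <- cfg$cycle_epochs[ci]
    cfg$peak_lr * 0.5 * (1 + cos(pi * pos / len))
  }, 1.0)
}

as_input <- function(x, shape) {
  if (inherits(x, "clip_tensor")) x <- unclass(x)
  if (!is.array(x) || !identical(dim(x), as.integer(shape)))
    stop("input tensor must have shape ", paste(shape, collapse = " x "))
  as.numeric(x)
}

#' Train the classifier
#'
#' Runs the full cyclic-SGD schedule with binary cross-entropy on labeled
#' clip tensors. Deterministic for a fixed model/config seed pair. The learning
#' rate applied at every epoch is exactly [lr_schedule()].
#'
#' @param model An `amb_cnn3d` from [build_model()].
#' @param x List of clip tensors (shape `model$config$input_shape`).
#' @param y Labels: 1/`"dependent"` = dependent ambulation, 0/`"independent"`.
#' @param cfg A [train_config()].
#' @return List with `model` (trained) and `log` (data.frame epoch/lr/loss).
#' @export
train_cnn3d <- function(model, x, y, cfg = train_config()) {
  stopifnot(inherits(model, "amb_cnn3d"), inherits(cfg, "train_config"))
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "dependent")
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("training needs at least 2 examples per class")
  n <- length(x)
  shape <- model$config$input_shape
  xs <- lapply(x, as_input, shape = shape)
  lr <- lr_schedule(0:(cfg$total_epochs - 1), cfg)
  order <- with_seed(cfg$seed, {
    t(vapply(seq_len(cfg$total_epochs), function(e) sample(n) - 1L,
             integer(n)))
  })
  res <- cnn3d_train_cpp(list(conv = model$arch), shape,
                         model$conv_w, model$conv_b,
                         model$dense_w, model$dense_b,
                         xs, y, lr, order, cfg$batch_size, cfg$momentum)
  model$conv_w <- res$conv_w
  model$conv_b <- lapply(res$conv_b, as.numeric)
  model$dense_w <- res$dense_w
  model$dense_b <- lapply(res$dense_b, as.numeric)
  list(model = model,
       log = data.frame(epoch = 0:(cfg$total_epochs - 1), lr = lr,
                        loss = as.numeric(res$loss)))
}

#' Predict dependence probability
#'
#' @param model A (trained or freshly built) `amb_cnn3d`.
#' @param x A single clip tensor or a list of them.
#' @return Numeric vector of probabilities in `[0, 1]` (1 = dependent).
#' @export
predict_cnn3d <- function(model, x) {
  stopifnot(inherits(model, "amb_cnn3d"))
  if (!is.list(x)) x <- list(x)
  shape <- model$config$input_shape
  xs <- lapply(x, as_input, shape = shape)
  as.numeric(cnn3d_predict_cpp(list(conv = model$arch), shape,
                               model$conv_w, model$conv_b,
                               model$dense_w, model$dense_b, xs))
}
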