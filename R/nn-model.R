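# RegNet-style 1D residual network: a small, regular design space — one
# stem convolution, a few stages each holding identical residual blocks
# with non-decreasing widths and stride-2 downsampling at stage entry,
# global average pooling, and a linear classification head.

#' Model configuration
#'
#' @param in_channels input channels (3 accelerometer axes).
#' @param input_length window length in samples (400 = 4 s at 100 Hz).
#' @param stem_width stem convolution width.
#' @param stage_depths residual blocks per stage.
#' @param stage_widths channel width per stage (non-decreasing).
#' @param kernel_size odd convolution kernel size inside blocks.
#' @param stem_kernel odd stem kernel size.
#' @param n_classes output classes.
#' @param seed initialization seed.
#' @return a validated `model_config`.
#' @export
model_config <- function(in_channels = 3, input_length = 400,
                         stem_width = 32, stage_depths = c(2, 2, 2),
                         stage_widths = c(32, 64, 128), kernel_size = 3,
                         stem_kernel = 7, n_classes = 2, seed = 1L) {
  if (length(stage_depths) != length(stage_widths))
    stop("stage_depths and stage_widths must have equal length")
  if (is.unsorted(stage_widths))
    stop("stage_widths must be non-decreasing")
  if (kernel_size %% 2 != 1 || stem_kernel %% 2 != 1)
    stop("kernel sizes must be odd")
  total_stride <- 2^(1 + length(stage_depths))   # stem + one per stage
  if (input_length < total_stride)
    stop(sprintf("input_length %d too short for the stride schedule (minimum %d)",
                 input_length, total_stride))
  structure(list(in_channels = in_channels, input_length = input_length,
                 stem_width = stem_width, stage_depths = stage_depths,
                 stage_widths = stage_widths, kernel_size = kernel_size,
                 stem_kernel = stem_kernel, n_classes = as.integer(n_classes),
                 seed = as.integer(seed)),
            class = "model_config")
}

he_init <- function(fan_in, n_out, n_in) {
  matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / fan_in)), n_out, n_in)
}

new_conv <- function(C_in, C_out, k, stride, L_in) {
  pad <- (k - 1L) %/% 2L
  meta <- list(k = k, stride = stride, pad = pad,
               im = make_im2col_index(C_in, L_in, k, stride, pad))
  list(W = he_init(C_in * k, C_out, C_in * k), meta = meta,
       C_in = C_in, C_out = C_out, L_in = L_in, L_out = meta$im$L_out)
}

new_bn <- function(C) list(gamma = rep(1, C), beta = rep(0, C),
                           state = list(mean = rep(0, C), var = rep(1, C)))

#' Build a RegNet-style 1D residual network
#'
#' Architecture: stem conv (stride 2) + BN + ReLU, then stages of residual
#' blocks (conv-BN-ReLU-conv-BN plus identity skip; a strided 1x1
#' projection + BN on shape change at stage entry), global average
#' pooling, and a linear head. Initialization is deterministic under
#' `config$seed` (He-normal weights).
#'
#' @param config a [model_config()].
#' @return a `gesture_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  L <- config$input_length
  stem <- list(conv = new_conv(config$in_channels, config$stem_width,
                               config$stem_kernel, 2L, L),
               bn = new_bn(config$stem_width))
  L <- stem$conv$L_out
  C <- config$stem_width
  stages <- list()
  for (s in seq_along(config$stage_depths)) {
    blocks <- list()
    width <- config$stage_widths[s]
    for (b in seq_len(config$stage_depths[s])) {
      stride <- if (b == 1L) 2L else 1L
      proj <- NULL
      L_out <- conv_out_len(L, config$kernel_size, stride,
                            (config$kernel_size - 1L) %/% 2L)
      if (stride != 1L || C != width)
        proj <- list(conv = new_conv(C, width, 1L, stride, L),
                     bn = new_bn(width))
      blocks[[b]] <- list(
        conv1 = new_conv(C, width, config$kernel_size, stride, L),
        bn1 = new_bn(width),
        conv2 = new_conv(width, width, config$kernel_size, 1L, L_out),
        bn2 = new_bn(width),
        proj = proj)
      L <- L_out; C <- width
    }
    stages[[s]] <- blocks
  }
  head <- list(W = he_init(C, config$n_classes, C),
               b = rep(0, config$n_classes))
  structure(list(config = config, stem = stem, stages = stages,
                 head = head, feature_dim = C, final_length = L),
            class = "gesture_model")
}

#' @export
print.gesture_model <- function(x, ...) {
  cat(sprintf("<gesture_model> 3x%d -> %d classes; stem %d, stages [%s] x widths [%s]; %d parameters\n",
              x$config$input_length, x$config$n_classes, x$config$stem_width,
              paste(x$config$stage_depths, collapse = ","),
              paste(x$config$stage_widths, collapse = ","),
              count_params(x)))
  invisible(x)
}

#' Total trainable parameter count
#'
#' Counts convolution weights, batch-norm scale/shift pairs and the head
#' weights/bias (running statistics are buffers, not parameters).
#'
#' @param model a `gesture_model`.
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  n <- length(model$stem$conv$W) + 2L * length(model$stem$bn$gamma)
  for (st in model$stages) for (bl in st) {
    n <- n + length(bl$conv1$W) + 2L * length(bl$bn1$gamma) +
      length(bl$conv2$W) + 2L * length(bl$bn2$gamma)
    if (!is.null(bl$proj))
      n <- n + length(bl$proj$conv$W) + 2L * length(bl$proj$bn$gamma)
  }
  n + length(model$head$W) + length(model$head$b)
}

block_forward <- function(bl, X, training) {
  c1 <- conv1d_forward(X, bl$conv1$W, bl$conv1$meta)
  b1 <- bn_forward(c1$out, bl$bn1$gamma, bl$bn1$beta, bl$bn1$state, training)
  r1 <- relu_forward(b1$out)
  c2 <- conv1d_forward(r1$out, bl$conv2$W, bl$conv2$meta)
  b2 <- bn_forward(c2$out, bl$bn2$gamma, bl$bn2$beta, bl$bn2$state, training)
  if (is.null(bl$proj)) {
    skip <- X; pcache <- NULL; pstate <- NULL
  } else {
    pc <- conv1d_forward(X, bl$proj$conv$W, bl$proj$conv$meta)
    pb <- bn_forward(pc$out, bl$proj$bn$gamma, bl$proj$bn$beta,
                     bl$proj$bn$state, training)
    skip <- pb$out
    pcache <- list(conv = pc$cache, bn = pb$cache)
    pstate <- pb$state
  }
  r2 <- relu_forward(b2$out + skip)
  list(out = r2$out,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                    proj = pcache),
       states = list(bn1 = b1$state, bn2 = b2$state, proj = pstate))
}

block_backward <- function(bl, cache, dY) {
  d <- relu_backward(dY, cache$r2)
  # d splits into the main branch (through bn2) and the skip
  b2 <- bn_backward(d, bl$bn2$gamma, cache$b2)
  c2 <- conv1d_backward(b2$dX, bl$conv2$W, bl$conv2$meta, cache$c2)
  r1 <- relu_backward(c2$dX, cache$r1)
  b1 <- bn_backward(r1, bl$bn1$gamma, cache$b1)
  c1 <- conv1d_backward(b1$dX, bl$conv1$W, bl$conv1$meta, cache$c1)
  grads <- list(conv1.W = c1$dW, bn1.gamma = b1$dgamma, bn1.beta = b1$dbeta,
                conv2.W = c2$dW, bn2.gamma = b2$dgamma, bn2.beta = b2$dbeta)
  if (is.null(bl$proj)) {
    dX <- c1$dX + d
  } else {
    pb <- bn_backward(d, bl$proj$bn$gamma, cache$proj$bn)
    pc <- conv1d_backward(pb$dX, bl$proj$conv$W, bl$proj$conv$meta,
                          cache$proj$conv)
    grads$proj.conv.W <- pc$dW
    grads$proj.bn.gamma <- pb$dgamma
    grads$proj.bn.beta <- pb$dbeta
    dX <- c1$dX + pc$dX
  }
  list(dX = dX, grads = grads)
}

#' Forward pass
#'
#' @param model a `gesture_model`.
#' @param X batch array (C, L, N) of standardized windows.
#' @param training use batch statistics and update running stats.
#' @return list with `logits` (n_classes x N), `features` (feature_dim x
#'   N, the post-pooling pre-head embedding), and — when `training` — the
#'   caches needed for [backward_model()] plus updated BN states.
#' @export
forward_model <- function(model, X, training = FALSE) {
  if (length(dim(X)) == 2) dim(X) <- c(dim(X), 1L)
  st <- conv1d_forward(X, model$stem$conv$W, model$stem$conv$meta)
  sb <- bn_forward(st$out, model$stem$bn$gamma, model$stem$bn$beta,
                   model$stem$bn$state, training)
  sr <- relu_forward(sb$out)
  out <- sr$out
  caches <- list(stem = list(conv = st$cache, bn = sb$cache, relu = sr$cache))
  states <- list(stem = sb$state)
  for (s in seq_along(model$stages)) {
    for (b in seq_along(model$stages[[s]])) {
      bf <- block_forward(model$stages[[s]][[b]], out, training)
      out <- bf$out
      caches[[paste0("s", s, "b", b)]] <- bf$cache
      states[[paste0("s", s, "b", b)]] <- bf$states
    }
  }
  gp <- gap_forward(out)
  hd <- linear_forward(gp$out, model$head$W, model$head$b)
  caches$gap <- gp$cache
  caches$head <- hd$cache
  list(logits = hd$out, features = gp$out,
       caches = if (training) caches else NULL,
       bn_states = if (training) states else NULL)
}

#' Backward pass: gradients of the loss w.r.t. every parameter
#'
#' @param model a `gesture_model`.
#' @param caches caches from a training-mode [forward_model()].
#' @param dlogits gradient of the loss at the logits (n_classes x N).
#' @return named flat list of gradients keyed like `s1b2.conv1.W`.
#' @export
backward_model <- function(model, caches, dlogits) {
  hd <- linear_backward(dlogits, model$head$W, caches$head)
  grads <- list(head.W = hd$dW, head.b = hd$db)
  d <- gap_backward(hd$dX, caches$gap)
  for (s in rev(seq_along(model$stages))) {
    for (b in rev(seq_along(model$stages[[s]]))) {
      key <- paste0("s", s, "b", b)
      bb <- block_backward(model$stages[[s]][[b]], caches[[key]], d)
      d <- bb$dX
      for (nm in names(bb$grads)) grads[[paste0(key, ".", nm)]] <- bb$grads[[nm]]
    }
  }
  sr <- relu_backward(d, caches$stem$relu)
  sb <- bn_backward(sr, model$stem$bn$gamma, caches$stem$bn)
  sc <- conv1d_backward(sb$dX, model$stem$conv$W, model$stem$conv$meta,
                        caches$stem$conv)
  grads$stem.conv.W <- sc$dW
  grads$stem.bn.gamma <- sb$dgamma
  grads$stem.bn.beta <- sb$dbeta
  grads
}

# Enumerate parameter paths with weight-decay eligibility (conv/linear
# weights decay; BN scale/shift and biases do not).
param_paths <- function(model) {
  paths <- list(list(path = c("stem", "conv", "W"), decay = TRUE),
                list(path = c("stem", "bn", "gamma"), decay = FALSE),
                list(path = c("stem", "bn", "beta"), decay = FALSE))
  for (s in seq_along(model$stages)) for (b in seq_along(model$stages[[s]])) {
    base <- c("stages", s, b)
    paths <- c(paths, list(
      list(path = c(base, "conv1", "W"), decay = TRUE),
      list(path = c(base, "bn1", "gamma"), decay = FALSE),
      list(path = c(base, "bn1", "beta"), decay = FALSE),
      list(path = c(base, "conv2", "W"), decay = TRUE),
      list(path = c(base, "bn2", "gamma"), decay = FALSE),
      list(path = c(base, "bn2", "beta"), decay = FALSE)))
    if (!is.null(model$stages[[s]][[b]]$proj))
      paths <- c(paths, list(
        list(path = c(base, "proj", "conv", "W"), decay = TRUE),
        list(path = c(base, "proj", "bn", "gamma"), decay = FALSE),
        list(path = c(base, "proj", "bn", "beta"), decay = FALSE)))
  }
  c(paths, list(list(path = c("head", "W"), decay = TRUE),
                list(path = c("head", "b"), decay = FALSE)))
}

# Map a parameter path to the backward_model() gradient name.
grad_name <- function(path) {
  if (path[1] == "stem") return(paste(path, collapse = "."))
  if (path[1] == "head") return(paste(path, collapse = "."))
  key <- paste0("s", path[2], "b", path[3])
  paste(c(key, path[-(1:3)]), collapse = ".")
}

pluck_path <- function(model, path) {
  node <- model
  for (k in path) node <- node[[if (grepl("^[0-9]+$", k)) as.integer(k) else k]]
  node
}

assign_path <- function(model, path, value) {
  # recursive functional update
  if (length(path) == 1) {
    model[[if (grepl("^[0-9]+$", path)) as.integer(path) else path]] <- value
    return(model)
  }
  k <- if (grepl("^[0-9]+$", path[1])) as.integer(path[1]) else path[1]
  model[[k]] <- assign_path(model[[k]], path[-1], value)
  model
}

#' Predict class probabilities for a window set
#'
#' @param model a `gesture_model`.
#' @param ws a standardized `window_set` (or a (C, L, N) array).
#' @param batch_size evaluation batch size.
#' @return matrix N x n_classes of softmax probabilities.
#' @export
predict_proba <- function(model, ws, batch_size = 256) {
  X <- if (inherits(ws, "window_set")) ws$data else ws
  N <- dim(X)[3]
  out <- matrix(NA_real_, N, model$config$n_classes)
  for (i0 in seq(1, N, by = batch_size)) {
    i1 <- min(N, i0 + batch_size - 1L)
    fw <- forward_model(model, X[, , i0:i1, drop = FALSE], training = FALSE)
    out[i0:i1, ] <- t(softmax_cols(fw$logits))
  }
  out
}

#' Extract pooled pre-head embeddings
#'
#' @param model a `gesture_model`.
#' @param ws a standardized `window_set` (or array).
#' @return matrix N x feature_dim.
#' @export
embed <- function(model, ws) {
  X <- if (inherits(ws, "window_set")) ws$data else ws
  fw <- forward_model(model, X, training = FALSE)
  t(fw$features)
}
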