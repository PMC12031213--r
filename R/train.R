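# AdamW optimization with validation-based early stopping. The optimizer
# keeps decoupled weight decay (applied directly to the weights, never
# through the adaptive moments); batch-norm parameters and biases are
# exempt from decay, as is standard.

#' Training configuration
#'
#' @param learning_rate AdamW step size.
#' @param weight_decay decoupled weight decay coefficient.
#' @param batch_size minibatch size.
#' @param max_epochs epoch budget.
#' @param patience epochs without selection-metric improvement before
#'   stopping (0 = stop at the first non-improving epoch).
#' @param selection_metric `"val_loss"` (minimized) or `"val_macro_f1"`
#'   (maximized).
#' @param class_weighting weight classes inversely to frequency in the
#'   cross-entropy loss.
#' @param seed shuffling/initialization seed.
#' @return a `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-2,
                         batch_size = 64, max_epochs = 50, patience = 10,
                         selection_metric = c("val_loss", "val_macro_f1"),
                         class_weighting = FALSE, seed = 1L) {
  selection_metric <- match.arg(selection_metric)
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            max_epochs >= 1, patience >= 0, patience <= max_epochs)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 selection_metric = selection_metric,
                 class_weighting = class_weighting, seed = as.integer(seed)),
            class = "train_config")
}

adamw_init <- function(model) {
  pp <- param_paths(model)
  lapply(pp, function(p) {
    val <- pluck_path(model, p$path)
    list(path = p$path, decay = p$decay, is_vec = is.null(dim(val)),
         m = array(0, dim = dim(val) %||% length(val)),
         v = array(0, dim = dim(val) %||% length(val)))
  })
}

adamw_step <- function(model, opt, grads, lr, wd, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(opt)) {
    o <- opt[[i]]
    g <- grads[[grad_name(o$path)]]
    if (is.null(g)) stop("missing gradient for ", grad_name(o$path))
    p <- pluck_path(model, o$path)
    g <- array(g, dim = dim(o$m))
    o$m <- beta1 * o$m + (1 - beta1) * g
    o$v <- beta2 * o$v + (1 - beta2) * g^2
    upd <- (o$m / bc1) / (sqrt(o$v / bc2) + eps)
    if (o$decay) upd <- upd + wd * as.vector(p)
    p <- p - lr * array(upd, dim = dim(p) %||% length(p))
    if (o$is_vec) p <- as.vector(p)
    model <- assign_path(model, o$path, p)
    opt[[i]] <- o
  }
  list(model = model, opt = opt)
}

# install updated BN running stats returned by a training forward pass
install_bn_states <- function(model, states) {
  model$stem$bn$state <- states$stem
  for (s in seq_along(model$stages)) for (b in seq_along(model$stages[[s]])) {
    st <- states[[paste0("s", s, "b", b)]]
    model$stages[[s]][[b]]$bn1$state <- st$bn1
    model$stages[[s]][[b]]$bn2$state <- st$bn2
    if (!is.null(st$proj)) model$stages[[s]][[b]]$proj$bn$state <- st$proj
  }
  model
}

eval_loss_f1 <- function(model, X, y, classes, batch_size = 256) {
  N <- dim(X)[3]
  loss <- 0
  pred <- integer(N)
  for (i0 in seq(1, N, by = batch_size)) {
    i1 <- min(N, i0 + batch_size - 1L)
    fw <- forward_model(model, X[, , i0:i1, drop = FALSE], training = FALSE)
    ce <- cross_entropy(fw$logits, y[i0:i1])
    loss <- loss + ce$loss * (i1 - i0 + 1L)
    pred[i0:i1] <- max.col(t(fw$logits))
  }
  cm <- confusion(classes[y], classes[pred], classes)
  list(loss = loss / N, macro_f1 = metrics_report(cm)$macro["f1"],
       pred = pred)
}

#' Train a gesture model
#'
#' Minibatch AdamW on the training windows with per-epoch evaluation on
#' the validation windows; the returned model carries the weights of the
#' best epoch under the selection metric, not the last. Test windows are
#' never touched here.
#'
#' @param model a freshly built `gesture_model`.
#' @param ws a standardized `window_set` covering train and val windows.
#' @param assignment a [split_bouts()] result over the same bouts.
#' @param tcfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list: `model` (best-epoch weights), `history` (data.frame of
#'   per-epoch train/val loss and macro F1), `best_epoch`, `classes`.
#' @export
train_model <- function(model, ws, assignment, tcfg, verbose = FALSE) {
  stopifnot(inherits(tcfg, "train_config"))
  tr_idx <- split_indices(ws, assignment, "train")
  va_idx <- split_indices(ws, assignment, "val")
  if (!length(va_idx)) stop("empty validation set; cannot early-stop")
  if (!length(tr_idx)) stop("empty training set")
  classes <- sort(unique(ws$labels[c(tr_idx, va_idx)]))
  if (length(classes) != model$config$n_classes)
    stop(sprintf("model expects %d classes but data has %d",
                 model$config$n_classes, length(classes)))
  y_all <- match(ws$labels, classes)
  if (any(table(y_all[tr_idx]) < 1) || length(unique(y_all[va_idx])) < 1)
    stop("need at least one window per class in train and val")
  Xtr <- ws$data[, , tr_idx, drop = FALSE]; ytr <- y_all[tr_idx]
  Xva <- ws$data[, , va_idx, drop = FALSE]; yva <- y_all[va_idx]
  cw <- NULL
  if (tcfg$class_weighting) {
    tb <- tabulate(ytr, length(classes))
    cw <- sum(tb) / (length(classes) * pmax(tb, 1))
  }
  set.seed(tcfg$seed)
  opt <- adamw_init(model)
  best <- list(metric = Inf, model = model, epoch = 0L)
  sign_sel <- if (tcfg$selection_metric == "val_loss") 1 else -1
  history <- list()
  t_step <- 0L
  n_bad <- 0L
  for (epoch in seq_len(tcfg$max_epochs)) {
    ord <- sample.int(length(ytr))
    ep_loss <- 0
    for (i0 in seq(1, length(ord), by = tcfg$batch_size)) {
      idx <- ord[i0:min(length(ord), i0 + tcfg$batch_size - 1L)]
      fw <- forward_model(model, Xtr[, , idx, drop = FALSE], training = TRUE)
      model <- install_bn_states(model, fw$bn_states)
      ce <- cross_entropy(fw$logits, ytr[idx], cw)
      if (!is.finite(ce$loss))
        stop(sprintf("non-finite training loss at epoch %d; aborting", epoch))
      grads <- backward_model(model, fw$caches, ce$grad)
      t_step <- t_step + 1L
      st <- adamw_step(model, opt, grads, tcfg$learning_rate,
                       tcfg$weight_decay, t_step)
      model <- st$model; opt <- st$opt
      ep_loss <- ep_loss + ce$loss * length(idx)
    }
    tr_eval <- eval_loss_f1(model, Xtr, ytr, classes)
    va_eval <- eval_loss_f1(model, Xva, yva, classes)
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = tr_eval$loss, val_loss = va_eval$loss,
      train_macro_f1 = unname(tr_eval$macro_f1),
      val_macro_f1 = unname(va_eval$macro_f1))
    if (verbose)
      message(sprintf("epoch %02d  train loss %.4f F1 %.3f | val loss %.4f F1 %.3f",
                      epoch, tr_eval$loss, tr_eval$macro_f1,
                      va_eval$loss, va_eval$macro_f1))
    sel <- sign_sel * (if (tcfg$selection_metric == "val_loss")
      va_eval$loss else va_eval$macro_f1)
    if (sel < best$metric - 1e-9) {
      best <- list(metric = sel, model = model, epoch = epoch)
      n_bad <- 0L
    } else {
      n_bad <- n_bad + 1L
      if (n_bad > tcfg$patience) break
    }
  }
  list(model = best$model, history = do.call(rbind, history),
       best_epoch = best$epoch, classes = classes)
}
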