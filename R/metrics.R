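# Confusion-matrix-derived metrics. Conventions: rows = true class,
# columns = predicted class; macro averaging = unweighted mean over
# classes; any vanishing denominator yields 0 with an explicit flag.

#' Confusion matrix from label vectors
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param classes ordered class labels (defaults to sorted union).
#' @return k x k integer matrix, `counts[i, j] = #{true = i & pred = j}`.
#' @export
confusion <- function(true_labels, predicted_labels,
                      classes = sort(unique(c(true_labels, predicted_labels)))) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  unknown <- setdiff(unique(c(true_labels, predicted_labels)), classes)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  tt <- factor(true_labels, levels = classes)
  pp <- factor(predicted_labels, levels = classes)
  cm <- table(true = tt, predicted = pp)
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Precision/recall/F1 report from a confusion matrix
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, and F1 (the
#' harmonic mean `2PR/(P+R)`, defined as 0 when `P+R = 0`); macro values
#' are unweighted means over classes. Also returns the column-normalized
#' precision matrix and row-normalized recall matrix. Classes with zero
#' support or zero predictions get 0 for the undefined metric and are
#' listed in `undefined`.
#'
#' @param cm a [confusion()] matrix.
#' @return a `metrics_report` list: `per_class` (data.frame), `macro`
#'   (named vector), `precision_matrix`, `recall_matrix`, `support`,
#'   `undefined`.
#' @export
metrics_report <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  classes <- rownames(cm)
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  undefined <- character(0)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  if (any(predicted == 0))
    undefined <- c(undefined, paste0("precision:", classes[predicted == 0]))
  if (any(support == 0))
    undefined <- c(undefined, paste0("recall:", classes[support == 0]))
  pr <- precision + recall
  f1 <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
  recall_matrix <- sweep(cm, 1, pmax(support, 1), "/")
  recall_matrix[support == 0, ] <- NA_real_
  precision_matrix <- sweep(cm, 2, pmax(predicted, 1), "/")
  precision_matrix[, predicted == 0] <- NA_real_
  structure(list(
    per_class = data.frame(class = classes, precision = unname(precision),
                           recall = unname(recall), f1 = unname(f1),
                           support = unname(support)),
    macro = c(precision = mean(precision), recall = mean(recall),
              f1 = mean(f1)),
    precision_matrix = precision_matrix, recall_matrix = recall_matrix,
    support = support, undefined = undefined, confusion = cm),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(render_metrics_table(x))
  invisible(x)
}

# Half-up rounding to `digits` decimals (report display convention).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Render a metrics report as a plain-text table
#'
#' Macro block first, then per-class precision/recall/F1 rounded half-up
#' to two decimals; absent (zero-support) classes print `NA`.
#'
#' @param report a [metrics_report()].
#' @return a single string.
#' @export
render_metrics_table <- function(report) {
  fmt <- function(v) sprintf("%.2f", round_half_up(v))
  lines <- c(
    sprintf("%-16s %9s %9s %9s %9s", "class", "precision", "recall", "F1",
            "support"),
    sprintf("%-16s %9s %9s %9s %9s", "macro",
            fmt(report$macro["precision"]), fmt(report$macro["recall"]),
            fmt(report$macro["f1"]), sum(report$support)))
  for (i in seq_len(nrow(report$per_class))) {
    r <- report$per_class[i, ]
    absent <- r$support == 0
    lines <- c(lines, sprintf("%-16s %9s %9s %9s %9d", r$class,
                              if (absent) "NA" else fmt(r$precision),
                              if (absent) "NA" else fmt(r$recall),
                              if (absent) "NA" else fmt(r$f1), r$support))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write a metrics report to CSV
#'
#' @param report a [metrics_report()].
#' @param path output CSV (per-class rows plus a macro row).
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  df <- rbind(
    data.frame(class = "macro", precision = report$macro["precision"],
               recall = report$macro["recall"], f1 = report$macro["f1"],
               support = sum(report$support)),
    report$per_class)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Precision-recall curve for one class
#'
#' Sweeps every distinct score threshold (one-vs-rest) and returns the
#' (recall, precision) operating points, recall non-decreasing.
#'
#' @param scores per-window score for `class` (e.g. its softmax
#'   probability).
#' @param true_labels true labels.
#' @param class the positive class.
#' @return data.frame with `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(scores, true_labels, class) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- true_labels == class
  if (all(pos) || !any(pos))
    stop("degenerate input: truth contains a single class")
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  # keep the last point at each distinct score (threshold = that score)
  s <- scores[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(threshold = s[keep],
             recall = tp[keep] / sum(pos),
             precision = tp[keep] / (tp[keep] + fp[keep]))
}

#' Project embeddings to 2-D with t-SNE
#'
#' Exact (dense) t-SNE with perplexity-calibrated Gaussian affinities,
#' PCA initialization, early exaggeration and momentum gradient descent.
#' Deterministic under `seed`. Suitable for the few-hundred-window
#' embedding sets this pipeline produces.
#'
#' @param embeddings n x d numeric matrix.
#' @param seed integer seed.
#' @param perplexity effective neighborhood size; must satisfy
#'   `n >= 3 * perplexity + 1`.
#' @param n_iter gradient-descent iterations.
#' @return n x 2 matrix of coordinates.
#' @export
project_embeddings <- function(embeddings, seed = 1L, perplexity = 10,
                               n_iter = 400) {
  X <- as.matrix(embeddings)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 embeddings to project")
  if (n < 3 * perplexity + 1)
    stop(sprintf("perplexity %g too large for %d points (need n >= 3*perplexity+1)",
                 perplexity, n))
  D2 <- as.matrix(stats::dist(X))^2
  if (max(D2) < 1e-12)
    stop("degenerate geometry: all embeddings identical")
  # per-point precision via binary search on entropy
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(as.integer(seed))
  pc <- stats::prcomp(X, rank. = 2)
  Y <- pc$x[, 1:2, drop = FALSE]
  if (ncol(Y) < 2) Y <- cbind(Y, 0)
  Y <- scale(Y, scale = apply(Y, 2, function(c) max(stats::sd(c), 1e-9))) * 1e-2
  Y <- Y + matrix(stats::rnorm(2 * n, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  momentum <- 0.5
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100) 4 else 1
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    dY <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- pmax(0.01, ifelse(sign(dY) != sign(G), gains + 0.2, gains * 0.8))
    G <- momentum * G - 200 * gains * dY
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
    if (it == 250) momentum <- 0.8
  }
  unname(Y)
}
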