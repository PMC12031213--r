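# Shared fixtures and independent oracles used across the suite.

tiny_sim_config <- function(seed = 1, ...) {
  sim_config(n_participants = 1, sessions_per_participant = 1, seed = seed, ...)
}

tiny_model_config <- function(input_length = 64, ...) {
  model_config(in_channels = 3, input_length = input_length, stem_width = 4,
               stage_depths = c(1, 1), stage_widths = c(4, 8),
               kernel_size = 3, stem_kernel = 5, ...)
}

# Two-class, noiseless, well-separated toy window set: class A is a low
# sinusoid, class B a higher-frequency one. Used for capacity checks.
toy_window_set <- function(n_per_class = 20, L = 64, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  dat <- array(0, c(3, L, n))
  labels <- character(n)
  t <- seq_len(L) / L
  for (i in seq_len(n)) {
    cls <- if (i <= n_per_class) "A" else "B"
    f <- if (cls == "A") 2 else 6
    ph <- runif(1, 0, 2 * pi)
    for (c in 1:3) dat[c, , i] <- sin(2 * pi * f * t + ph + c)
    labels[i] <- cls
  }
  prov <- data.frame(bout_ref = sprintf("b%03d", seq_len(n)),
                     recording_ref = "P01_S01", participant_id = "P01",
                     label = labels, wrist = "right", padded = FALSE)
  structure(list(data = dat, labels = labels, provenance = prov,
                 window_len = L / 100, sampling_rate = 100),
            class = "window_set")
}

# Trivial total split over a toy window set (no leakage concerns in toys).
toy_assignment <- function(ws, n_val_per_class = 4, n_test_per_class = 0,
                           seed = 1) {
  set.seed(seed)
  mem <- rep("train", length(ws$labels))
  for (cl in unique(ws$labels)) {
    idx <- which(ws$labels == cl)
    pick <- sample(idx, n_val_per_class + n_test_per_class)
    mem[pick[seq_len(n_val_per_class)]] <- "val"
    if (n_test_per_class > 0)
      mem[pick[n_val_per_class + seq_len(n_test_per_class)]] <- "test"
  }
  structure(list(strategy = "gesture", train_fraction = 0.8,
                 val_fraction_of_train = 0.1, seed = seed,
                 membership = data.frame(bout_ref = ws$provenance$bout_ref,
                                         set = mem)),
            class = "split_assignment")
}

# Brute-force confusion matrix by nested loops (independent of confusion()).
brute_confusion <- function(true, pred, classes) {
  k <- length(classes)
  m <- matrix(0L, k, k, dimnames = list(true = classes, predicted = classes))
  for (i in seq_along(true))
    for (a in seq_len(k)) for (b in seq_len(k))
      if (true[i] == classes[a] && pred[i] == classes[b])
        m[a, b] <- m[a, b] + 1L
  m
}

# Brute-force per-class precision/recall/F1 straight from label pairs.
brute_metrics <- function(true, pred, classes) {
  out <- data.frame(class = classes, precision = 0, recall = 0, f1 = 0)
  for (j in seq_along(classes)) {
    cl <- classes[j]
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    out$precision[j] <- p; out$recall[j] <- r
    out$f1[j] <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  out
}

# Brute-force PR point at one threshold.
brute_pr_point <- function(scores, true, class, thr) {
  pred_pos <- scores >= thr
  tp <- sum(pred_pos & true == class)
  fp <- sum(pred_pos & true != class)
  fn <- sum(!pred_pos & true == class)
  c(recall = tp / (tp + fn), precision = if (tp + fp > 0) tp / (tp + fp) else NA)
}
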