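test_that("forward pass produces finite logits of the right shape", {
  cfg <- tiny_model_config(n_classes = 2, seed = 1)
  m <- build_model(cfg)
  set.seed(1)
  X <- array(rnorm(3 * 64 * 8), c(3, 64, 8))
  fw <- forward_model(m, X)
  expect_identical(dim(fw$logits), c(2L, 8L))
  expect_true(all(is.finite(fw$logits)))
  # softmax normalizes per sample
  expect_true(all(abs(colSums(medgest:::softmax_cols(fw$logits)) - 1) < 1e-6))
})

test_that("initialization is deterministic under the config seed", {
  cfg <- tiny_model_config(seed = 77)
  m1 <- build_model(cfg); m2 <- build_model(cfg)
  expect_identical(m1$stem$conv$W, m2$stem$conv$W)
  expect_identical(m1$head$W, m2$head$W)
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
})

test_that("parameter count matches the closed-form layer arithmetic", {
  cfg <- model_config(in_channels = 3, input_length = 64, stem_width = 8,
                      stage_depths = c(1, 1), stage_widths = c(8, 16),
                      kernel_size = 3, stem_kernel = 5, n_classes = 2)
  m <- build_model(cfg)
  # hand count: stem conv 8*3*5 + bn 2*8
  expected <- 8 * 3 * 5 + 16
  # stage 1 block (stride 2, 8 -> 8): proj needed for stride
  expected <- expected + 8 * 8 * 3 + 16 + 8 * 8 * 3 + 16 + 8 * 8 * 1 + 16
  # stage 2 block (stride 2, 8 -> 16)
  expected <- expected + 16 * 8 * 3 + 32 + 16 * 16 * 3 + 32 + 16 * 8 * 1 + 32
  # head
  expected <- expected + 2 * 16 + 2
  expect_identical(count_params(m), as.integer(expected))
})

test_that("inputs too short for the stride schedule are rejected", {
  expect_error(model_config(input_length = 8, stage_depths = c(2, 2, 2),
                            stage_widths = c(8, 16, 32)),
               "minimum 16")
})

test_that("analytic gradients match finite differences everywhere", {
  cfg <- model_config(in_channels = 2, input_length = 24, stem_width = 3,
                      stage_depths = c(1, 1), stage_widths = c(3, 5),
                      kernel_size = 3, stem_kernel = 5, n_classes = 3,
                      seed = 2)
  m <- build_model(cfg)
  set.seed(4)
  X <- array(rnorm(2 * 24 * 4), c(2, 24, 4))
  y <- c(1L, 2L, 3L, 1L)
  fw <- forward_model(m, X, training = TRUE)
  grads <- backward_model(m, fw$caches, cross_entropy(fw$logits, y)$grad)
  loss_at <- function(model) {
    f <- forward_model(model, X, training = TRUE)
    cross_entropy(f$logits, y)$loss
  }
  eps <- 1e-5
  for (p in medgest:::param_paths(m)) {
    val <- medgest:::pluck_path(m, p$path)
    g <- grads[[medgest:::grad_name(p$path)]]
    expect_false(is.null(g))
    for (i in sample(length(val), min(2, length(val)))) {
      v <- val; v[i] <- v[i] + eps
      lp <- loss_at(medgest:::assign_path(m, p$path, v))
      v[i] <- val[i] - eps
      lm <- loss_at(medgest:::assign_path(m, p$path, v))
      fd <- (lp - lm) / (2 * eps)
      expect_lt(abs(fd - as.vector(g)[i]),
                1e-5 * max(1, abs(fd)))
    }
  }
})

test_that("embeddings have the last stage width and are pure in eval mode", {
  cfg <- tiny_model_config(n_classes = 2, seed = 3)
  m <- build_model(cfg)
  set.seed(2)
  X <- array(rnorm(3 * 64 * 4), c(3, 64, 4))
  e1 <- embed(m, X)
  expect_identical(dim(e1), c(4L, 8L))        # last stage width 8
  X2 <- X; X2[, , 2] <- X[, , 1]              # duplicate window
  e2 <- embed(m, X2)
  expect_identical(e2[1, ], e2[2, ])
  expect_identical(e1, embed(m, X))           # deterministic eval forward
})

test_that("the model reaches perfect training F1 on a separable toy set", {
  ws <- toy_window_set(20, L = 64, seed = 5)
  std <- fit_standardizer(ws)
  ws <- apply_standardizer(std, ws)
  assignment <- toy_assignment(ws, n_val_per_class = 4)
  m <- build_model(tiny_model_config(n_classes = 2, seed = 6))
  fit <- train_model(m, ws, assignment,
                     train_config(learning_rate = 5e-3, weight_decay = 0,
                                  max_epochs = 80, patience = 80,
                                  batch_size = 16, seed = 6))
  last <- fit$history[nrow(fit$history), ]
  expect_lt(last$train_loss, 0.05)
  expect_equal(last$train_macro_f1, 1.0)
})
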