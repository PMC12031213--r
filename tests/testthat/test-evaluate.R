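test_that("confusion counts match definition and brute force", {
  # perfect predictions: diagonal with full trace
  cm <- confusion(rep(c("a", "b"), 5), rep(c("a", "b"), 5), c("a", "b"))
  expect_equal(unname(diag(cm)), c(5L, 5L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  # constant predictor on balanced input
  cm2 <- confusion(rep(c("a", "b"), each = 5), rep("a", 10), c("a", "b"))
  expect_equal(unname(cm2[, "a"]), c(5L, 5L))
  expect_equal(unname(cm2[, "b"]), c(0L, 0L))
  # random labels vs nested-loop counting
  set.seed(31)
  classes <- c("x", "y", "z")
  true <- sample(classes, 1000, replace = TRUE)
  pred <- sample(classes, 1000, replace = TRUE)
  expect_equal(confusion(true, pred, classes),
               brute_confusion(true, pred, classes))
  expect_error(confusion("a", "q", classes = c("a", "b")), "unknown label")
  expect_error(confusion(c("a", "b"), "a"), "equal length")
})

test_that("precision/recall/F1 follow the harmonic-mean formula", {
  # boundary identities
  cm <- matrix(c(10L, 0L, 0L, 10L), 2, 2,
               dimnames = list(true = c("a", "b"), predicted = c("a", "b")))
  r <- metrics_report(cm)
  expect_equal(unname(r$macro["f1"]), 1)
  expect_equal(r$per_class$f1, c(1, 1))
  # P = 0 forces F1 = 0 under the zero-division convention
  cm0 <- confusion(c("a", "b"), c("b", "b"), c("a", "b"))
  r0 <- metrics_report(cm0)
  expect_equal(r0$per_class$f1[r0$per_class$class == "a"], 0)
  # full report against brute force on random fixtures
  set.seed(17)
  for (k in 2:4) {
    classes <- letters[seq_len(k)]
    true <- sample(classes, 500, replace = TRUE)
    pred <- sample(classes, 500, replace = TRUE)
    rep_ <- metrics_report(confusion(true, pred, classes))
    bf <- brute_metrics(true, pred, classes)
    expect_equal(rep_$per_class$precision, bf$precision)
    expect_equal(rep_$per_class$recall, bf$recall)
    expect_equal(rep_$per_class$f1, bf$f1)
    expect_equal(unname(rep_$macro["f1"]), mean(bf$f1))
  }
})

test_that("recall matrix rows and precision matrix columns normalize to 1", {
  set.seed(23)
  classes <- c("a", "b", "c")
  cm <- confusion(sample(classes, 300, TRUE), sample(classes, 300, TRUE),
                  classes)
  r <- metrics_report(cm)
  expect_true(all(abs(rowSums(r$recall_matrix) - 1) < 1e-9))
  expect_true(all(abs(colSums(r$precision_matrix) - 1) < 1e-9))
})

test_that("zero-support classes are flagged and rendered as NA", {
  cm <- confusion(c("a", "a"), c("a", "b"), classes = c("a", "b", "c"))
  r <- metrics_report(cm)
  expect_true(any(grepl("recall:c", r$undefined)))
  expect_equal(r$per_class$f1[r$per_class$class == "c"], 0)
  txt <- render_metrics_table(r)
  expect_match(txt, "c .*NA")
})

test_that("report display rounds half-up to two decimals", {
  expect_equal(medgest:::round_half_up(0.005), 0.01)
  expect_equal(medgest:::round_half_up(0.8647), 0.86)
  expect_equal(medgest:::round_half_up(0.915), 0.92)
})

test_that("PR curves match brute-force threshold sweeps", {
  set.seed(41)
  n <- 100
  true <- sample(c("pos", "neg"), n, replace = TRUE)
  scores <- runif(n)
  curve <- pr_curve(scores, true, "pos")
  expect_true(all(diff(curve$recall) >= 0))
  for (i in sample(nrow(curve), 10)) {
    bf <- brute_pr_point(scores, true, "pos", curve$threshold[i])
    expect_equal(curve$recall[i], unname(bf["recall"]))
    expect_equal(curve$precision[i], unname(bf["precision"]))
  }
})

test_that("a perfect ranking reaches the (1, 1) operating point", {
  true <- rep(c("pos", "neg"), each = 50)
  scores <- c(runif(50, 0.6, 1), runif(50, 0, 0.4))
  curve <- pr_curve(scores, true, "pos")
  expect_true(any(curve$recall == 1 & curve$precision == 1))
  expect_error(pr_curve(runif(5), rep("pos", 5), "pos"), "degenerate")
})

test_that("random scores give precision near class prevalence", {
  set.seed(53)
  n <- 2000
  true <- sample(c("pos", "neg"), n, replace = TRUE, prob = c(0.5, 0.5))
  curve <- pr_curve(runif(n), true, "pos")
  mid <- curve[curve$recall > 0.2, ]
  expect_lt(max(abs(mid$precision - mean(true == "pos"))), 0.1)
})

test_that("relabeling before metrics equals metrics on pre-merged labels", {
  set.seed(61)
  raw_classes <- c("methadone", "buprenorphine", "daily")
  merge_map <- c(methadone = "medication", buprenorphine = "medication",
                 daily = "daily")
  true <- sample(raw_classes, 400, replace = TRUE)
  pred <- sample(raw_classes, 400, replace = TRUE)
  merged_first <- metrics_report(confusion(merge_map[true], merge_map[pred],
                                           c("daily", "medication")))
  # merging the confusion counts of pre-merged labels must agree
  direct <- metrics_report(confusion(unname(merge_map[true]),
                                     unname(merge_map[pred]),
                                     c("daily", "medication")))
  expect_equal(merged_first$per_class, direct$per_class)
  expect_equal(merged_first$macro, direct$macro)
})

test_that("t-SNE projection is deterministic and separates clear clusters", {
  set.seed(71)
  n <- 60
  X <- rbind(matrix(rnorm(n / 2 * 5), ncol = 5),
             matrix(rnorm(n / 2 * 5, mean = 10), ncol = 5))
  lab <- rep(1:2, each = n / 2)
  y1 <- project_embeddings(X, seed = 4, perplexity = 8)
  y2 <- project_embeddings(X, seed = 4, perplexity = 8)
  expect_identical(y1, y2)
  expect_identical(dim(y1), c(as.integer(n), 2L))
  sil <- cluster::silhouette(lab, dist(y1))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  # degenerate inputs are rejected with explicit errors
  expect_error(project_embeddings(matrix(1, 40, 3), seed = 1), "degenerate")
  expect_error(project_embeddings(X[1:10, ], perplexity = 10), "perplexity")
  expect_error(project_embeddings(X[1:2, ]), "at least 3")
})
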