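# Leakage-controlled holdout splitting at three independence levels:
#   gesture     — no bout contributes windows to more than one set
#                 (participants/recordings may span sets);
#   recording   — no recording id spans train+val vs test;
#   participant — no participant id spans train+val vs test.
# Gesture-level splits are stratified by class; grouped splits stratify at
# the group level on the group's majority class. Validation is always
# carved from the training side only.

#' Split bouts into train/validation/test sets
#'
#' @param bouts bout data.frame with `bout_ref`, `label`, `recording_ref`
#'   and (derivable) `participant_id` columns.
#' @param strategy `"gesture"`, `"recording"`, or `"participant"`.
#' @param train_fraction fraction of bouts (or groups) kept out of the
#'   test set (default 0.8).
#' @param val_fraction_of_train fraction of the training side carved into
#'   a validation set (default 0.1).
#' @param seed integer seed; splits are deterministic given it.
#' @return a `split_assignment`: data.frame `membership`
#'   (`bout_ref`, `set` in train/val/test) plus the strategy and seed.
#' @export
split_bouts <- function(bouts, strategy = c("gesture", "recording", "participant"),
                        train_fraction = 0.8, val_fraction_of_train = 0.1,
                        seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(train_fraction > 0, train_fraction < 1,
            val_fraction_of_train >= 0, val_fraction_of_train < 1)
  if (!"bout_ref" %in% names(bouts)) stop("bouts must carry bout_ref")
  if (anyDuplicated(bouts$bout_ref)) stop("duplicate bout_ref values")
  if (!"participant_id" %in% names(bouts))
    bouts$participant_id <- sub("_S[0-9]+$", "", bouts$recording_ref)

  set.seed(as.integer(seed))
  membership <- rep(NA_character_, nrow(bouts))

  if (strategy == "gesture") {
    for (cl in unique(bouts$label)) {
      idx <- which(bouts$label == cl)
      if (length(idx) < 2)
        stop("class '", cl, "' has fewer than 2 bouts; cannot stratify")
      idx <- idx[sample.int(length(idx))]
      n_test <- max(1L, round((1 - train_fraction) * length(idx)))
      test <- idx[seq_len(n_test)]
      tr <- idx[-seq_len(n_test)]
      n_val <- round(val_fraction_of_train * length(tr))
      val <- if (n_val > 0) tr[seq_len(n_val)] else integer(0)
      train <- setdiff(tr, val)
      membership[test] <- "test"; membership[val] <- "val"
      membership[train] <- "train"
    }
  } else {
    key <- if (strategy == "recording") bouts$recording_ref else bouts$participant_id
    groups <- unique(key)
    if (length(groups) < 2)
      stop("need at least 2 ", strategy, " groups to split")
    # majority class per group, for group-level stratification
    gmaj <- vapply(groups, function(g) {
      tb <- table(bouts$label[key == g])
      names(tb)[which.max(tb)]
    }, character(1))
    gset <- stats::setNames(rep(NA_character_, length(groups)), groups)
    for (cl in unique(gmaj)) {
      gs <- groups[gmaj == cl]
      gs <- gs[sample.int(length(gs))]
      n_test <- max(1L, round((1 - train_fraction) * length(gs)))
      if (n_test >= length(gs)) n_test <- length(gs) - 1L
      test_g <- gs[seq_len(n_test)]
      tr_g <- gs[-seq_len(n_test)]
      n_val <- round(val_fraction_of_train * length(tr_g))
      val_g <- if (n_val > 0 && length(tr_g) > n_val) tr_g[seq_len(n_val)] else character(0)
      gset[test_g] <- "test"; gset[val_g] <- "val"
      gset[setdiff(tr_g, val_g)] <- "train"
    }
    membership <- unname(gset[key])
  }
  # a class can end up without validation bouts; fall back to borrowing the
  # smallest training class slice so early stopping always has data
  if (!any(membership == "val") && val_fraction_of_train > 0) {
    tr_idx <- which(membership == "train")
    n_val <- max(1L, round(val_fraction_of_train * length(tr_idx)))
    membership[sample(tr_idx, n_val)] <- "val"
  }
  structure(list(strategy = strategy, train_fraction = train_fraction,
                 val_fraction_of_train = val_fraction_of_train,
                 seed = as.integer(seed),
                 membership = data.frame(bout_ref = bouts$bout_ref,
                                         set = membership)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  tb <- table(x$membership$set)
  cat(sprintf("<split_assignment> strategy=%s seed=%d: %s\n", x$strategy,
              x$seed, paste(names(tb), tb, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Indices of a window set belonging to one split
#'
#' @param ws a `window_set`.
#' @param assignment a [split_bouts()] result.
#' @param set `"train"`, `"val"`, or `"test"`.
#' @return integer indices into the window set.
#' @export
split_indices <- function(ws, assignment, set) {
  mem <- assignment$membership
  refs <- mem$bout_ref[mem$set == set]
  which(ws$provenance$bout_ref %in% refs)
}
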