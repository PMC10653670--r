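# Population-membership prediction harness: the three train/test splits,
# class-balance-aware random-forest training, permutation-null significance
# of classification accuracy, and consensus feature importance. The tree
# ensemble itself is the randomForest package; the tested surface here is
# the split design, balanced sampling, permutation null and consensus
# ranking.

#' Build the three train/test splits
#'
#' Tank-1-train/tank-2-test, tank-2-train/tank-1-test, and a seeded random
#' split of `train_size` fish (default 80) versus the rest.
#'
#' @param meta a `sample_table` with a `tank` column.
#' @param seed master seed for the random split.
#' @param train_size training-set size for the random split (default 80).
#' @return a list of three `split_spec` objects, each with `name`, `train`,
#'   `test` and `seed`.
#' @export
make_splits <- function(meta, seed = 1L, train_size = 80L) {
  if (is.null(meta$tank)) stop_gs("metadata has no tank column")
  ids <- meta$sample_id
  t1 <- ids[meta$tank == 1L]
  t2 <- ids[meta$tank == 2L]
  if (!length(t1) || !length(t2)) stop_gs("both tanks must be non-empty")
  if (length(ids) <= train_size)
    stop_gs("need more than %d samples for the random split (have %d)",
            train_size, length(ids))
  rnd_train <- with_seed(derive_seed(seed, 0L),
                         sort(sample(ids, train_size)))
  mk <- function(name, train, test)
    structure(list(name = name, train = train, test = test, seed = seed),
              class = "split_spec")
  list(mk("tank1_to_tank2", t1, t2),
       mk("tank2_to_tank1", t2, t1),
       mk(sprintf("random_%d_%d", train_size, length(ids) - train_size),
          rnd_train, sort(setdiff(ids, rnd_train))))
}

align_features_labels <- function(features, labels) {
  X <- unclass(as.matrix(features))
  if (is.null(rownames(X))) stop_gs("features need sample rownames")
  if (is.null(names(labels))) {
    if (length(labels) != nrow(X))
      stop_gs("labels must be named or match the feature rows")
    names(labels) <- rownames(X)
  }
  ids <- align_ids(rownames(X), names(labels))
  list(X = X[ids, , drop = FALSE],
       y = factor(setNames(as.character(labels[ids]), ids)))
}

fit_rf <- function(X, y, train, balance, n_trees, seed) {
  ytr <- droplevels(y[train])
  if (nlevels(ytr) < 2L) stop_gs("fewer than 2 classes in the training set")
  args <- list(x = X[train, , drop = FALSE], y = ytr, ntree = n_trees)
  if (balance) {
    nmin <- min(table(ytr))
    args$strata <- ytr
    args$sampsize <- rep(nmin, nlevels(ytr))
  }
  with_seed(seed, do.call(randomForest::randomForest, args))
}

#' Train a class-balanced random forest on one split and evaluate it
#'
#' When `balance = TRUE` each bootstrap draws an equal number of training
#' samples per class (the minimum class size), via randomForest's
#' `strata`/`sampsize` mechanism, so training is not dominated by the most
#' common population. Test-set accuracy is the plain proportion correct
#' (test-set imbalance is deliberately not corrected).
#'
#' @param features samples x ASVs matrix (typically log-CPM from
#'   [cpm_log_normalize()]).
#' @param labels population factor, named by sample id (or aligned with the
#'   feature rows).
#' @param split a `split_spec` from [make_splits()].
#' @param balance equalize per-class bootstrap sampling (default `TRUE`).
#' @param n_trees trees in the ensemble (default 500).
#' @param seed master seed.
#' @return an object of class `rf_report`: `split`, `total_accuracy`,
#'   `class_accuracy` (per population), ranked `importances` and settings.
#' @export
rf_train_evaluate <- function(features, labels, split, balance = TRUE,
                              n_trees = 500L, seed = 1L) {
  al <- align_features_labels(features, labels)
  X <- al$X; y <- al$y
  train <- intersect(split$train, rownames(X))
  test <- intersect(split$test, rownames(X))
  if (!length(train) || !length(test)) stop_gs("split ids not found in data")
  if (!all(levels(droplevels(y[c(train, test)])) %in%
           levels(droplevels(y[train]))))
    stop_gs("class absent from the training set")
  rf <- fit_rf(X, y, train, balance, n_trees, derive_seed(seed, 0L))
  pred <- stats::predict(rf, X[test, , drop = FALSE])
  ytest <- factor(y[test], levels = levels(rf$y))
  total <- mean(as.character(pred) == as.character(ytest))
  cls <- vapply(levels(ytest), function(lev) {
    m <- ytest == lev
    if (!any(m)) NA_real_
    else mean(as.character(pred)[m] == lev)
  }, 1)
  imp <- rf$importance[, "MeanDecreaseGini"]
  imp <- sort(imp, decreasing = TRUE)
  structure(list(split = split, total_accuracy = total,
                 class_accuracy = cls,
                 importances = data.frame(feature = names(imp),
                                          importance = unname(imp)),
                 n_trees = n_trees, balance = balance, seed = seed),
            class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  cat(sprintf("rf_report [%s]: total accuracy %.3f\n", x$split$name,
              x$total_accuracy))
  print(round(x$class_accuracy, 3))
  if (!is.null(x$permutation_p))
    cat(sprintf("permutation p = %.4g (%d null refits)\n", x$permutation_p,
                length(x$null_accuracies)))
  invisible(x)
}

#' Permutation-null significance of random-forest accuracy
#'
#' Retrains the classifier `n_null` times with the *training* labels
#' randomly shuffled (test labels untouched) and compares the observed total
#' accuracy against the null accuracies:
#' `p = (1 + #\{null >= observed\}) / (n_null + 1)`.
#'
#' @inheritParams rf_train_evaluate
#' @param n_null number of label-shuffled refits (default 999).
#' @return the `rf_report` from [rf_train_evaluate()] augmented with
#'   `permutation_p` and `null_accuracies`.
#' @export
rf_permutation_null <- function(features, labels, split, n_null = 999L,
                                balance = TRUE, n_trees = 500L, seed = 1L) {
  if (n_null < 1L) stop_gs("n_null must be at least 1")
  report <- rf_train_evaluate(features, labels, split, balance = balance,
                              n_trees = n_trees, seed = seed)
  al <- align_features_labels(features, labels)
  X <- al$X; y <- al$y
  train <- intersect(split$train, rownames(X))
  test <- intersect(split$test, rownames(X))
  nulls <- vapply(seq_len(n_null), function(k) {
    sk <- derive_seed(seed, k)
    ysh <- y
    ysh[train] <- with_seed(sk, sample(y[train]))
    rf <- fit_rf(X, ysh, train, balance, n_trees, sk + 1L)
    pred <- stats::predict(rf, X[test, , drop = FALSE])
    mean(as.character(pred) == as.character(y[test]))
  }, 1)
  report$null_accuracies <- nulls
  report$permutation_p <- perm_pvalue(nulls, report$total_accuracy, n_null)
  report
}

#' Consensus feature importance across reports
#'
#' Ranks features by the number of reports in whose top-`top_k` importance
#' list they appear, ties broken by mean rank (over the reports where they
#' appear in the top-`top_k`).
#'
#' @param reports list of at least two `rf_report` objects.
#' @param top_k list depth per report (default 10).
#' @return data frame `feature`, `support`, `mean_rank`, ordered by
#'   decreasing support then increasing mean rank.
#' @export
consensus_importance <- function(reports, top_k = 10L) {
  if (top_k < 1L) stop_gs("top_k must be at least 1")
  if (length(reports) < 2L) stop_gs("need at least 2 reports")
  tops <- lapply(reports, function(r)
    head(r$importances$feature, top_k))
  feats <- unique(unlist(tops))
  support <- vapply(feats, function(f)
    sum(vapply(tops, function(t) f %in% t, TRUE)), 1L)
  mean_rank <- vapply(feats, function(f) {
    rk <- vapply(tops, function(t) match(f, t), 1L)
    mean(rk, na.rm = TRUE)
  }, 1)
  out <- data.frame(feature = feats, support = support,
                    mean_rank = mean_rank)
  out <- out[order(-out$support, out$mean_rank, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
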