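#' Balanced k-fold split plans for an unbalanced two-class cohort
#'
#' The minority class is partitioned into `k` folds. For each fold, the
#' training set is the other `k - 1` minority folds plus an equal-sized
#' random subset of the majority class — so every training set is exactly
#' class-balanced — and the test set is the held-out minority fold plus all
#' remaining (excess) majority participants. Every participant is therefore
#' tested at least once per repetition (the majority class is folded as well,
#' and a member's own fold is excluded from its training draw), and the
#' test-set imbalance is why accuracy is reported *balanced* downstream.
#'
#' Each plan also carries a stratified `inner` fold assignment over its
#' training rows, used by stacking and by hyperparameter tuning.
#'
#' @param labels full label vector (-1/+1 or two-level factor).
#' @param k number of folds; the minority class must have at least `k`
#'   members.
#' @param seed integer seed driving the randomization.
#' @param inner_k inner folds attached to each plan.
#' @return list of `k` split plans: lists with `train`, `test`, `inner`,
#'   `fold`, `seed`.
#' @export
balanced_split <- function(labels, k = 5, seed = 1L, inner_k = 5) {
  y <- as_pm1(labels)
  classes <- c(-1, 1)
  sizes <- c(sum(y == -1), sum(y == 1))
  min_i <- which.min(sizes)          # ties: either class may serve as minority
  minority <- classes[min_i]
  majority <- classes[-min_i]
  if (sizes[min_i] < k)
    stop("minority class smaller than k", call. = FALSE)

  withr_seed(seed, {
    min_idx <- sample(which(y == minority))
    maj_idx <- sample(which(y == majority))
    fold_of <- rep_len(seq_len(k), length(min_idx))
    # majority is folded too: a member's own fold keeps it out of training,
    # so every participant is tested at least once per repetition
    fold_maj <- rep_len(seq_len(k), length(maj_idx))
    plans <- vector("list", k)
    for (f in seq_len(k)) {
      test_min <- min_idx[fold_of == f]
      train_min <- min_idx[fold_of != f]
      train_maj <- sample(maj_idx[fold_maj != f], length(train_min))
      train <- sample(c(train_min, train_maj))
      test <- c(test_min, setdiff(maj_idx, train_maj))
      inner_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      plans[[f]] <- list(train = train, test = test,
                         inner = stratified_folds(y[train], inner_k,
                                                  seed = inner_seed),
                         fold = f, seed = inner_seed)
    }
    plans
  })
}

# stratified fold assignment: within each class, shuffle then deal fold ids
# round-robin, so every fold contains both classes whenever possible
stratified_folds <- function(y, k, seed = 1L) {
  withr_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      i <- sample(which(y == cl))
      fold[i] <- rep_len(seq_len(k), length(i))
    }
    fold
  })
}

#' Balanced classification accuracy
#'
#' Mean of the per-class accuracies (sensitivity and specificity), as a
#' percentage. Insensitive to class imbalance in the test set: any constant
#' classifier scores exactly 50.
#'
#' @param true true labels (both classes must be present).
#' @param pred predicted labels.
#' @return accuracy in percent, in `[0, 100]`.
#' @export
balanced_accuracy <- function(true, pred) {
  true <- as_pm1(true)
  pred <- as_pm1(pred)
  if (length(true) != length(pred)) stop("length mismatch", call. = FALSE)
  if (length(unique(true)) != 2)
    stop("both classes must be present in 'true'", call. = FALSE)
  100 * mean(c(mean(pred[true == 1] == 1), mean(pred[true == -1] == -1)))
}

#' Tune the EasyMKL regularization by inner cross-validation
#'
#' Grid search over `grid`, scoring each candidate by the mean balanced
#' accuracy over `inner_k` balanced inner splits of the training rows — the
#' same score used for outer evaluation. Ties are broken towards the
#' smallest lambda (the weaker penalty on informative kernels).
#'
#' @param pipeline a pipeline function `(sets, y, split, lam) -> margins`.
#' @param sets named list of feature matrices (full cohort rows).
#' @param y full label vector.
#' @param train outer-training row indices; tuning never touches other rows.
#' @param grid ordered lambda values in `[0, 1]`.
#' @param inner_k inner folds.
#' @param seed integer seed for the inner splits.
#' @return the selected lambda, with attribute `score` (mean inner balanced
#'   accuracy per grid value).
#' @export
tune_lambda <- function(pipeline, sets, y, train, grid = seq(0, 1, 0.1),
                        inner_k = 5, seed = 1L) {
  if (!length(grid)) stop("empty lambda grid", call. = FALSE)
  if (any(grid < 0 | grid > 1)) stop("lambda grid must lie in [0, 1]", call. = FALSE)
  grid <- sort(grid)
  y <- as_pm1(y)
  sub_sets <- lapply(sets, function(X) X[train, , drop = FALSE])
  inner_plans <- balanced_split(y[train], k = inner_k, seed = seed)
  score <- vapply(grid, function(lam) {
    mean(vapply(inner_plans, function(pl) {
      m <- pipeline(sub_sets, y[train], pl, lam)
      balanced_accuracy(y[train][pl$test], predict_labels(m))
    }, numeric(1)))
  }, numeric(1))
  best <- grid[which.max(score)]   # which.max takes the first (smallest) tie
  structure(best, score = stats::setNames(score, grid))
}

#' Repeated matched cross-validation over several methods
#'
#' For each of `R` repetitions, one seed generates a set of balanced k-fold
#' split plans, and *every* method is evaluated on those identical plans
#' ("matched" splits), so per-repetition accuracy differences between
#' methods are directly interpretable. A repetition's accuracy for a method
#' is the mean over the k folds of the fold-level balanced accuracy.
#'
#' @param methods named list of functions `(split) -> test margins`; bind
#'   feature sets, labels and lambda via closures, e.g.
#'   `function(split) intermediate_pipeline(sets, y, split, lam = 0.5)`.
#' @param y full label vector (drives the splits and scores the folds).
#' @param R number of repetitions.
#' @param k outer folds per repetition.
#' @param base_seed integer; spawns the per-repetition seeds deterministically,
#'   and the identical stream drives every method.
#' @return object of class `cv_result`: list with `accuracy` (R x methods
#'   matrix, percent), `rep_seeds`, `methods`, `k`.
#' @export
repeated_cv <- function(methods, y, R = 100, k = 5, base_seed = 1L) {
  if (!length(methods)) stop("need at least one method", call. = FALSE)
  if (is.null(names(methods)) || any(names(methods) == ""))
    stop("methods must be named", call. = FALSE)
  y <- as_pm1(y)
  rep_seeds <- withr_seed(base_seed,
                          sample.int(.Machine$integer.max - 1L, R))
  acc <- matrix(NA_real_, R, length(methods),
                dimnames = list(NULL, names(methods)))
  for (r in seq_len(R)) {
    plans <- balanced_split(y, k = k, seed = rep_seeds[r])
    for (m in seq_along(methods)) {
      fold_acc <- vapply(plans, function(pl) {
        marg <- methods[[m]](pl)
        balanced_accuracy(y[pl$test], predict_labels(marg))
      }, numeric(1))
      acc[r, m] <- mean(fold_acc)
    }
  }
  structure(list(accuracy = acc, rep_seeds = rep_seeds,
                 methods = names(methods), k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Repeated matched cross-validation: ", nrow(x$accuracy),
      " repetitions x ", length(x$methods), " method(s), k = ", x$k, "\n",
      sep = "")
  mu <- colMeans(x$accuracy)
  sdv <- apply(x$accuracy, 2, stats::sd)
  for (m in x$methods)
    cat(sprintf("  %-28s %.1f (%.1f)\n", m, mu[m], sdv[m]))
  invisible(x)
}

#' Paired accuracy difference between two matched methods
#'
#' Per-repetition differences `A - B` of matched accuracies, summarized by
#' their mean and by the percentage of repetitions in which A was strictly
#' better — an approximation of the reliability of A's improvement over B.
#' Exact ties are reported both ways: excluded under the strict count, and
#' contributing one half under `pct_greater_half_ties`.
#'
#' @param res a [repeated_cv()] result (or two such results with identical
#'   seeds, passed as `res` and `res_b`).
#' @param a,b method names (columns of `res`).
#' @param res_b optional second result holding method `b`.
#' @return object of class `paired_diff`: list with `mean_diff`,
#'   `pct_greater`, `pct_greater_half_ties`, `diffs`.
#' @export
paired_difference <- function(res, a, b, res_b = res) {
  stopifnot(inherits(res, "cv_result"), inherits(res_b, "cv_result"))
  if (!identical(res$rep_seeds, res_b$rep_seeds))
    stop("results are not matched (different split seeds)", call. = FALSE)
  if (!a %in% res$methods) stop("unknown method: ", a, call. = FALSE)
  if (!b %in% res_b$methods) stop("unknown method: ", b, call. = FALSE)
  d <- res$accuracy[, a] - res_b$accuracy[, b]
  structure(list(mean_diff = mean(d),
                 pct_greater = 100 * mean(d > 0),
                 pct_greater_half_ties = 100 * (mean(d > 0) + 0.5 * mean(d == 0)),
                 diffs = d, a = a, b = b),
            class = "paired_diff")
}

#' @export
print.paired_diff <- function(x, ...) {
  cat(sprintf("%s vs %s: %+0.2f / %.1f%%\n", x$a, x$b,
              x$mean_diff, x$pct_greater))
  invisible(x)
}

#' @export
format.paired_diff <- function(x, ...) {
  sprintf("%+0.2f / %.1f%%", x$mean_diff, x$pct_greater)
}
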