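test_that("balanced splits follow the minority-partition rule", {
  # 10 majority (+1) / 8 minority (-1), k = 2
  y <- c(rep(1, 10), rep(-1, 8))
  plans <- balanced_split(y, k = 2, seed = 1)
  expect_length(plans, 2)
  for (pl in plans) {
    expect_length(intersect(pl$train, pl$test), 0)
    expect_equal(sum(y[pl$train] == 1), 4)
    expect_equal(sum(y[pl$train] == -1), 4)
    expect_equal(sum(y[pl$test] == -1), 4)
    expect_equal(sum(y[pl$test] == 1), 6)
  }
  # held-out minority folds partition the minority class
  held <- lapply(plans, function(pl) pl$test[y[pl$test] == -1])
  expect_setequal(unlist(held), which(y == -1))
  expect_equal(sum(lengths(held)), 8)

  expect_error(balanced_split(y, k = 9), "smaller than k")
})

test_that("cohort-sized splits are balanced with all excess majority in test", {
  y <- c(rep(-1, 163), rep(1, 144))   # 163 controls, 144 patients
  plans <- balanced_split(y, k = 5, seed = 2)
  for (pl in plans) {
    expect_equal(sum(y[pl$train] == 1), sum(y[pl$train] == -1))
    # test contains every majority member not sampled into training
    expect_equal(sort(c(pl$train, pl$test)), 1:307)
    # every participant tested at least once over the repetition
  }
  tested <- sort(unique(unlist(lapply(plans, `[[`, "test"))))
  expect_equal(tested, 1:307)
  # inner folds are stratified over the training rows
  pl <- plans[[1]]
  for (f in unique(pl$inner))
    expect_setequal(unique(y[pl$train[pl$inner == f]]), c(-1, 1))
})

test_that("balanced accuracy has its defining properties", {
  y <- c(rep(1, 9), rep(-1, 3))
  expect_equal(balanced_accuracy(y, y), 100)
  expect_equal(balanced_accuracy(y, rep(1, 12)), 50)
  expect_equal(balanced_accuracy(y, rep(-1, 12)), 50)
  # sensitivity 1, specificity 1/3
  pred <- y; pred[10] <- 1; pred[11] <- 1
  expect_equal(balanced_accuracy(y, pred), 100 * mean(c(1, 1 / 3)))
  # sensitivity 1.0, specificity 0.5 -> 75
  y2 <- c(rep(1, 4), rep(-1, 4))
  expect_equal(balanced_accuracy(y2, c(rep(1, 4), 1, 1, -1, -1)), 75)
  expect_error(balanced_accuracy(rep(1, 4), rep(1, 4)), "both classes")
})

test_that("matched repeated CV is deterministic and shared across methods", {
  tab <- small_cohort(15, 15, seed = 12)
  y <- labels_of(tab)
  sets <- list(s = generate_group_features(tab, 20, informative = 1:5,
                                           d = 1, seed = 12))
  f <- function(split) early_pipeline(sets, y, split, 0.5)
  res <- repeated_cv(list(a = f, b = f), y, R = 5, k = 3, base_seed = 7)
  # identical methods give identical accuracy columns (matched splits)
  expect_equal(res$accuracy[, "a"], res$accuracy[, "b"])
  # end-to-end reproducibility from the base seed
  res2 <- repeated_cv(list(a = f, b = f), y, R = 5, k = 3, base_seed = 7)
  expect_identical(res$accuracy, res2$accuracy)
  res3 <- repeated_cv(list(a = f), y, R = 5, k = 3, base_seed = 8)
  expect_false(identical(res$accuracy[, "a"], res3$accuracy[, "a"]))
})

test_that("paired differences summarize matched accuracy gaps", {
  tab <- small_cohort(15, 15, seed = 13)
  y <- labels_of(tab)
  sets <- list(s = generate_group_features(tab, 20, seed = 13))
  f <- function(split) early_pipeline(sets, y, split, 0.5)
  res <- repeated_cv(list(a = f, b = f), y, R = 4, k = 3, base_seed = 9)

  # A = B: mean 0, strictly-greater percentage 0, half-ties 50
  pd <- paired_difference(res, "a", "b")
  expect_equal(pd$mean_diff, 0)
  expect_equal(pd$pct_greater, 0)
  expect_equal(pd$pct_greater_half_ties, 50)

  # A = B + 1 everywhere
  res$accuracy[, "a"] <- res$accuracy[, "b"] + 1
  pd1 <- paired_difference(res, "a", "b")
  expect_equal(pd1$mean_diff, 1)
  expect_equal(pd1$pct_greater, 100)
  expect_match(format(pd1), "^\\+1\\.00 / 100\\.0%$")

  resx <- repeated_cv(list(a = f), y, R = 4, k = 3, base_seed = 10)
  expect_error(paired_difference(res, "a", "b", resx), "not matched")
  expect_error(paired_difference(res, "zz", "b"), "unknown method")
})

test_that("lambda tuning maximizes inner balanced accuracy with smallest-tie rule", {
  tab <- small_cohort(20, 20, seed = 14)
  y <- labels_of(tab)
  sets <- list(s = generate_group_features(tab, 20, informative = 1:10,
                                           d = 1.2, seed = 14))
  # one-value grid returns that value
  l1 <- tune_lambda(early_pipeline, sets, y, train = 1:40, grid = 0.3,
                    seed = 1)
  expect_equal(as.numeric(l1), 0.3)
  # deterministic under a fixed seed
  g <- c(0, 0.5, 1)
  a <- tune_lambda(early_pipeline, sets, y, 1:40, g, seed = 5)
  b <- tune_lambda(early_pipeline, sets, y, 1:40, g, seed = 5)
  expect_identical(a, b)
  expect_true(as.numeric(a) %in% g)
  expect_length(attr(a, "score"), 3)
  expect_error(tune_lambda(early_pipeline, sets, y, 1:40, numeric(0)),
               "empty")
  expect_error(tune_lambda(early_pipeline, sets, y, 1:40, c(0.1, 2)),
               "\\[0, 1\\]")
})

test_that("lambda selection shows no strong preference on pure noise", {
  picks <- vapply(1:24, function(s) {
    tab <- small_cohort(12, 12, seed = s + 300)
    y <- labels_of(tab)
    sets <- list(s = generate_group_features(tab, 15, seed = s + 600))
    as.numeric(tune_lambda(early_pipeline, sets, y, train = 1:24,
                           grid = c(0, 0.5, 1), inner_k = 3, seed = s))
  }, numeric(1))
  expect_lt(max(table(picks)) / 24, 0.8)
})

test_that("protocol is unbiased over noise simulations and monotone in effect size", {
  tab <- small_cohort(20, 20, seed = 15)
  y <- labels_of(tab)
  # unbiasedness is a property over noise draws: fresh label-independent
  # features per fold (a fixed finite null dataset is conditionally biased
  # because disjoint train/test subsample gaps anti-correlate)
  mk <- function(d) {
    res <- repeated_cv(list(m = function(split) {
      sets <- list(s = generate_group_features(
        tab, 25, informative = 1:10, d = d,
        seed = split$seed %% 100003))
      intermediate_pipeline(sets, y, split, 0.5)
    }), y, R = 25, k = 4, base_seed = 21)
    c(mean(res$accuracy), sd(res$accuracy) / sqrt(nrow(res$accuracy)))
  }
  out <- vapply(c(0, 0.7, 1.4), mk, numeric(2))
  expect_lt(abs(out[1, 1] - 50), 3 * out[2, 1] + 1)   # null at chance
  # larger effects never decrease accuracy (within simulation error)
  expect_gt(out[1, 2], out[1, 1] - 2)
  expect_gt(out[1, 3], out[1, 2] - 2)
  expect_gt(out[1, 3], out[1, 1] + 5)     # strong effect clearly learnable
})

test_that("matched splits shrink the variance of accuracy differences", {
  tab <- small_cohort(16, 16, seed = 16)
  y <- labels_of(tab)
  s1 <- list(s = generate_group_features(tab, 20, informative = 1:5, d = 0.8,
                                         seed = 16))
  s2 <- list(s = generate_group_features(tab, 20, informative = 6:10, d = 0.8,
                                         seed = 17))
  fa <- function(split) early_pipeline(s1, y, split, 0.5)
  fb <- function(split) early_pipeline(s2, y, split, 0.5)
  res <- repeated_cv(list(a = fa, b = fb), y, R = 40, k = 4, base_seed = 31)
  resA <- repeated_cv(list(a = fa), y, R = 40, k = 4, base_seed = 32)
  resB <- repeated_cv(list(b = fb), y, R = 40, k = 4, base_seed = 33)
  v_matched <- var(res$accuracy[, "a"] - res$accuracy[, "b"])
  v_indep <- var(resA$accuracy[, "a"] - resB$accuracy[, "b"])
  expect_lt(v_matched, v_indep)
})
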