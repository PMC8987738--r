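toy_separable <- function() {
  x <- matrix(c(-2, -1, 1, 2), ncol = 1)
  list(K = tcrossprod(x), y = c(-1, -1, 1, 1), x = x)
}

test_that("kernel weights live on the probability simplex for every fit", {
  for (s in 1:5) {
    sim <- generate_kernel_sim(2, 2, 30, signal_strength = 0.8, seed = s)
    for (lam in c(0, 0.3, 0.7, 1)) {
      eta <- kernel_weights(fit_easymkl(sim$kernels, sim$labels, lam))
      expect_equal(sum(eta), 1, tolerance = 1e-9)
      expect_true(all(eta >= 0))
    }
  }
})

test_that("lambda = 1 yields the exact uniform per-class solution", {
  sim <- generate_kernel_sim(1, 1, 12, seed = 2)
  m <- fit_easymkl(sim$kernels, sim$labels, lam = 1)
  npos <- sum(sim$labels > 0); nneg <- sum(sim$labels < 0)
  expect_identical(m$gamma[sim$labels > 0], rep(1 / npos, npos))
  expect_identical(m$gamma[sim$labels < 0], rep(1 / nneg, nneg))
  # margins on the training set are symmetric about zero per class
  ks <- lapply(sim$kernels, function(K) mkl_kernel(K, K))
  f <- decision_values(m, ks)
  mpos <- mean(f[sim$labels > 0]); mneg <- mean(f[sim$labels < 0])
  expect_equal(mpos + mneg, 0, tolerance = 1e-9)
})

test_that("solver matches a brute-force grid search on an L = 6 toy", {
  set.seed(42)
  x <- c(-2, -1, -0.5, 0.5, 1, 2)
  y <- c(-1, -1, -1, 1, 1, 1)
  Ks <- tcrossprod(x)
  Kn <- tcrossprod(rnorm(6))
  for (lam in c(0.25, 0.5, 0.75)) {
    m <- fit_easymkl(list(sig = Ks, noi = Kn), y, lam)
    expect_gt(m$eta[["sig"]], m$eta[["noi"]])
    # final-stage QP objective at the solver's gamma beats the grid optimum
    Kw <- m$eta[["sig"]] * Ks + m$eta[["noi"]] * Kn
    grid <- grid_qp_min(Kw, y, lam, step = 0.05)
    expect_lte(easymkl_objective(Kw, y, lam, m$gamma),
               grid$objective + 1e-9)
    expect_lt(max(abs(m$gamma - grid$gamma)), 0.05)   # within a grid step
  }
})

test_that("solver agrees with an independent interior-point QP solver", {
  sim <- generate_kernel_sim(1, 1, 20, signal_strength = 0.8, seed = 3)
  y <- sim$labels
  for (lam in c(0.3, 0.5, 0.8)) {
    Kbar <- Reduce(`+`, sim$kernels)
    H <- 2 * ((1 - lam) * (Kbar * tcrossprod(y)) + lam * diag(20))
    A <- rbind(as.numeric(y > 0), as.numeric(y < 0))
    ip <- kernlab::ipop(c = rep(0, 20), H = H, A = A, b = c(1, 1),
                        l = rep(0, 20), u = rep(1, 20), r = c(0, 0))
    g_ip <- kernlab::primal(ip)
    r <- mkfusion:::.qp_biclass_simplex(H, which(y > 0) - 1L,
                                        which(y < 0) - 1L, 1e-10, 50000)
    expect_lt(max(abs(g_ip - r$gamma)), 1e-5)
  }
})

test_that("solver beats random feasible points (optimality spot-check)", {
  set.seed(9)
  sim <- generate_kernel_sim(1, 2, 16, signal_strength = 0.7, seed = 9)
  y <- sim$labels
  lam <- 0.4
  m <- fit_easymkl(sim$kernels, y, lam)
  Kw <- Reduce(`+`, Map(`*`, m$eta, sim$kernels))
  f_star <- easymkl_objective(Kw, y, lam, m$gamma)
  pos <- which(y > 0); neg <- which(y < 0)
  worst <- min(vapply(1:10000, function(i) {
    g <- numeric(length(y))
    g[pos] <- stats::rexp(length(pos)); g[pos] <- g[pos] / sum(g[pos])
    g[neg] <- stats::rexp(length(neg)); g[neg] <- g[neg] / sum(g[neg])
    easymkl_objective(Kw, y, lam, g)
  }, numeric(1)))
  expect_gte(worst, f_star - 1e-9)
})

test_that("decision function is the alpha-weighted kernel expansion plus bias", {
  toy <- toy_separable()
  m <- fit_easymkl(list(K = toy$K), toy$y, lam = 0.5)
  ks <- list(mkl_kernel(toy$K, toy$K))
  f <- decision_values(m, ks)
  expect_equal(f, drop(toy$K %*% m$alpha) + m$b)
  # separable toy: training signs recovered
  expect_equal(predict_labels(f), toy$y)
  expect_equal(m$alpha, m$gamma * toy$y)

  # all-zero kernels: f = b everywhere
  m0 <- fit_easymkl(list(K = toy$K), toy$y, lam = 0.5)
  f0 <- decision_values(m0, list(matrix(0, 3, 4)))
  expect_equal(f0, rep(m0$b, 3))
})

test_that("prediction sign rule and shared-scaling invariance", {
  expect_equal(predict_labels(c(0.3, -0.2)), c(1, -1))
  expect_equal(predict_labels(0), 1)

  sim <- generate_kernel_sim(1, 1, 20, signal_strength = 1, seed = 4)
  test <- seq(2, 20, 4); train <- setdiff(1:20, test)
  ks <- lapply(sim$kernels, function(K) mkl_kernel(K[train, train], K[test, train]))
  ks4 <- lapply(sim$kernels, function(K) mkl_kernel(4 * K[train, train], 4 * K[test, train]))
  m1 <- fit_easymkl(ks, sim$labels[train], 0.5)
  m4 <- fit_easymkl(ks4, sim$labels[train], 0.5)
  expect_equal(predict_labels(decision_values(m1, ks)),
               predict_labels(decision_values(m4, ks4)))
})

test_that("weights are symmetric under duplication and kernel-order permutation", {
  sim <- generate_kernel_sim(1, 1, 20, signal_strength = 1, seed = 6)
  K <- sim$kernels[[1]]
  m <- fit_easymkl(list(a = K, b = K), sim$labels, 0.5)
  expect_equal(m$eta[["a"]], m$eta[["b"]], tolerance = 1e-9)

  m1 <- fit_easymkl(sim$kernels, sim$labels, 0.5)
  m2 <- fit_easymkl(rev(sim$kernels), sim$labels, 0.5)
  expect_equal(m1$eta, m2$eta[names(m1$eta)], tolerance = 1e-8)
  # single kernel: weight is exactly 1
  expect_equal(unname(kernel_weights(fit_easymkl(sim$kernels[1], sim$labels, 0.5))), 1)
})

test_that("noise kernels are down-weighted on average across seeds", {
  d <- vapply(1:50, function(s) {
    sim <- generate_kernel_sim(1, 1, 30, signal_strength = 0.8, seed = s)
    eta <- kernel_weights(fit_easymkl(sim$kernels, sim$labels, 0.5))
    eta[["signal1"]] - eta[["noise1"]]
  }, numeric(1))
  expect_gt(mean(d), 0)
})

test_that("degenerate inputs are rejected", {
  K <- diag(4)
  expect_error(fit_easymkl(list(K), rep(1, 4), 0.5), "both classes")
  expect_error(fit_easymkl(list(K), c(-1, -1, 1, 1), 1.5), "\\[0, 1\\]")
  expect_error(fit_easymkl(list(), c(-1, 1), 0.5), "non-empty")
  expect_error(fit_easymkl(list(diag(3)), c(-1, -1, 1, 1), 0.5), "train blocks")
  m <- fit_easymkl(list(K), c(-1, -1, 1, 1), 0.5)
  expect_error(decision_values(m, list(matrix(0, 2, 3))), "columns")
  expect_error(decision_values(m, list(K, K)), "expected 1 kernels")
  expect_error(kernel_weights(list()), "not a fitted")
})

test_that("fitted models serialize to JSON for audit", {
  sim <- generate_kernel_sim(1, 1, 12, seed = 8)
  m <- fit_easymkl(sim$kernels, sim$labels, 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_easymkl_json(m, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$lambda, 0.5)
  expect_equal(sum(unlist(back$eta)), 1, tolerance = 1e-9)
  expect_equal(back$alpha, m$alpha, tolerance = 1e-12)
  expect_error(write_easymkl_json(list(), path), "not a fitted")
})
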