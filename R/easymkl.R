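#' @useDynLib mkfusion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Pull the train block out of whatever the caller handed us: a plain square
# matrix or an `mkl_kernel` object.
kernel_train_block <- function(k) {
  if (inherits(k, "mkl_kernel")) k$train else as.matrix(k)
}

kernel_test_block <- function(k) {
  if (inherits(k, "mkl_kernel")) {
    if (is.null(k$test)) stop("kernel has no test block", call. = FALSE)
    k$test
  } else {
    as.matrix(k)
  }
}

#' Fit an EasyMKL classifier
#'
#' EasyMKL learns a convex combination of base kernels together with a
#' maximum-margin two-class decision rule, by solving a regularized quadratic
#' program over per-example coefficients `gamma` constrained to the bi-class
#' probability simplex (`gamma >= 0`, summing to one within each class).
#'
#' The procedure is two-stage. First the QP
#' \deqn{\min_\gamma (1-\lambda)\,\gamma^\top Y \bar K Y \gamma +
#'       \lambda \|\gamma\|^2}
#' is solved with \eqn{\bar K} the plain sum of the base kernels and
#' \eqn{Y = \mathrm{diag}(y)}. The kernel weights are then read off as
#' \eqn{\eta_n \propto \gamma^\top Y k_n Y \gamma}, normalized to the simplex,
#' and the same QP is re-solved with the weighted kernel
#' \eqn{K = \sum_n \eta_n k_n} to obtain the final coefficients. The decision
#' expansion uses \eqn{\alpha_i = \gamma_i y_i} and a bias placed at the
#' midpoint of the gamma-weighted class margin means, so margins are symmetric
#' about zero on a balanced training set.
#'
#' The regularization weight `lam` lies in `[0, 1]`: values near 1 shrink
#' towards uniform per-class weights (under-fitting), values near 0 give the
#' pure margin objective, which can be sensitive to training outliers.
#'
#' Min-max normalized kernels are not guaranteed positive semi-definite; the
#' solver is a projected-gradient method that tolerates (regularized)
#' indefinite problems, and any negative raw kernel weight is truncated to
#' zero before simplex normalization.
#'
#' @param kernels list of base kernels: square train-block matrices (all of
#'   identical dimension) or [mkl_kernel] objects. Names are carried into the
#'   fitted weights.
#' @param y numeric vector of class labels in `{-1, +1}` (or a two-level
#'   factor, converted with the first level mapped to -1).
#' @param lam regularization weight in `[0, 1]`.
#' @param tol solver convergence tolerance on the iterate change.
#' @param maxit maximum solver iterations.
#' @return an object of class `easymkl`: list with elements `eta` (named
#'   simplex weights), `gamma`, `alpha`, `b`, `lambda`, `y`, `n_train`,
#'   `kernel_names`.
#' @seealso [decision_values()], [kernel_weights()], [predict.easymkl()]
#' @examples
#' X <- matrix(c(-2, -1, 1, 2), ncol = 1)
#' K <- tcrossprod(X)
#' m <- fit_easymkl(list(K), y = c(-1, -1, 1, 1), lam = 0.5)
#' kernel_weights(m)
#' @export
fit_easymkl <- function(kernels, y, lam = 0.5, tol = 1e-8, maxit = 50000) {
  if (!is.list(kernels) || length(kernels) == 0)
    stop("'kernels' must be a non-empty list", call. = FALSE)
  y <- as_pm1(y)
  if (length(unique(y)) != 2)
    stop("both classes must be present in 'y'", call. = FALSE)
  if (!is.numeric(lam) || length(lam) != 1 || is.na(lam) || lam < 0 || lam > 1)
    stop("'lam' must be a single value in [0, 1]", call. = FALSE)

  Ks <- lapply(kernels, kernel_train_block)
  L <- length(y)
  ok <- vapply(Ks, function(k) is.matrix(k) && all(dim(k) == c(L, L)), logical(1))
  if (!all(ok))
    stop("all kernels must be ", L, "x", L, " train blocks", call. = FALSE)

  nm <- names(kernels)
  if (is.null(nm)) nm <- paste0("kernel", seq_along(Ks))
  pos <- which(y > 0)
  neg <- which(y < 0)
  yy <- tcrossprod(y)

  solve_for <- function(K) {
    H <- 2 * ((1 - lam) * (K * yy) + lam * diag(L))
    H <- (H + t(H)) / 2
    res <- .qp_biclass_simplex(H, pos - 1L, neg - 1L, tol, as.integer(maxit))
    res$gamma
  }

  Kbar <- Reduce(`+`, Ks)
  gamma0 <- solve_for(Kbar)

  gy <- gamma0 * y
  eta_raw <- vapply(Ks, function(k) drop(crossprod(gy, k %*% gy)), numeric(1))
  eta_raw <- pmax(eta_raw, 0)
  eta <- if (sum(eta_raw) > 0) eta_raw / sum(eta_raw) else rep(1 / length(Ks), length(Ks))
  names(eta) <- nm

  if (length(Ks) == 1L) {
    gamma <- gamma0
    Kw <- Ks[[1]]
  } else {
    Kw <- Reduce(`+`, Map(`*`, eta, Ks))
    gamma <- solve_for(Kw)
  }

  alpha <- gamma * y
  f_tr <- drop(Kw %*% alpha)
  m_pos <- sum(gamma[pos] * f_tr[pos])
  m_neg <- sum(gamma[neg] * f_tr[neg])
  b <- -0.5 * (m_pos + m_neg)

  structure(list(eta = eta, gamma = gamma, alpha = alpha, b = b,
                 lambda = lam, y = y, n_train = L, kernel_names = nm),
            class = "easymkl")
}

#' Learned kernel weights
#'
#' Returns the simplex-constrained kernel weights `eta` of a fitted EasyMKL
#' model: non-negative, summing to one, named by kernel. Kernels carrying no
#' class information are down-weighted.
#'
#' @param model a fitted [fit_easymkl()] model.
#' @return named numeric vector on the probability simplex.
#' @export
kernel_weights <- function(model) {
  if (!inherits(model, "easymkl")) stop("not a fitted easymkl model", call. = FALSE)
  model$eta
}

#' Decision values of an EasyMKL model
#'
#' Evaluates the decision function
#' \eqn{f(x) = \sum_i \alpha_i K(x, x_i) + b}
#' with `K` the eta-weighted combination of the supplied kernel blocks.
#' Margins are signed distances to the decision boundary: positive predicts
#' the `+1` class.
#'
#' @param model a fitted [fit_easymkl()] model.
#' @param kernels list of kernels aligned with the training kernels: either
#'   `mkl_kernel` objects (their test blocks are used) or plain
#'   `n_eval x n_train` matrices. To evaluate on the training set, pass the
#'   train blocks themselves.
#' @return numeric vector of margins, one per evaluated row.
#' @export
decision_values <- function(model, kernels) {
  if (!inherits(model, "easymkl")) stop("not a fitted easymkl model", call. = FALSE)
  if (length(kernels) != length(model$eta))
    stop("expected ", length(model$eta), " kernels, got ", length(kernels),
         call. = FALSE)
  Kt <- lapply(kernels, kernel_test_block)
  nc <- vapply(Kt, ncol, integer(1))
  if (any(nc != model$n_train))
    stop("test blocks must have ", model$n_train, " columns (training size)",
         call. = FALSE)
  if (length(unique(vapply(Kt, nrow, integer(1)))) != 1)
    stop("test blocks disagree in number of rows", call. = FALSE)
  K <- Reduce(`+`, Map(`*`, model$eta, Kt))
  drop(K %*% model$alpha) + model$b
}

#' Labels from decision values
#'
#' Sign rule on the margins; a margin of exactly zero is assigned to the
#' positive class (documented tie rule).
#'
#' @param d numeric vector of margins.
#' @return numeric vector of labels in `{-1, +1}`.
#' @export
predict_labels <- function(d) {
  ifelse(d >= 0, 1, -1)
}

#' @describeIn fit_easymkl predict method: labels on new kernel blocks.
#' @param object fitted model.
#' @param kernels kernels as in [decision_values()].
#' @param ... unused.
#' @export
predict.easymkl <- function(object, kernels, ...) {
  predict_labels(decision_values(object, kernels))
}

#' @export
print.easymkl <- function(x, ...) {
  cat("EasyMKL model: ", length(x$eta), " kernel(s), L = ", x$n_train,
      ", lambda = ", x$lambda, "\n", sep = "")
  cat("kernel weights (eta):\n")
  print(round(x$eta, 4))
  invisible(x)
}

# map factor / 0-1 / -1,+1 labels onto -1/+1
as_pm1 <- function(y) {
  if (is.factor(y)) {
    lev <- levels(droplevels(y))
    if (length(lev) != 2) stop("'y' must have exactly two levels", call. = FALSE)
    return(ifelse(y == lev[1], -1, 1))
  }
  y <- as.numeric(y)
  u <- sort(unique(y))
  if (identical(u, c(0, 1))) return(ifelse(y > 0, 1, -1))
  if (!all(y %in% c(-1, 1))) stop("labels must be two-valued", call. = FALSE)
  y
}

#' Serialize a fitted EasyMKL model to JSON
#'
#' Writes the audit-relevant state — kernel weights, expansion coefficients,
#' bias, regularization and training size — as a JSON document.
#'
#' @param model a fitted [fit_easymkl()] model.
#' @param path file path; `".json"` by convention.
#' @return `path`, invisibly.
#' @export
write_easymkl_json <- function(model, path) {
  if (!inherits(model, "easymkl")) stop("not a fitted easymkl model", call. = FALSE)
  jsonlite::write_json(
    list(eta = as.list(model$eta), alpha = model$alpha, gamma = model$gamma,
         b = model$b, lambda = model$lambda, n_train = model$n_train,
         kernel_names = model$kernel_names),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
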