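#' Fit a feature standardizer on training rows
#'
#' Learns per-feature center and scale (mean and SD, `n - 1` denominator)
#' from the training rows only, so that held-out rows are transformed with
#' training statistics and no test information leaks into the transform.
#' A feature constant on the training rows (SD 0, e.g. a binary confound
#' within a fold) keeps its scale replaced by 1 so it maps to all-zero rather
#' than erroring.
#'
#' @param X numeric matrix, participants x features.
#' @param train_idx integer indices of the training rows (default: all rows).
#' @return object of class `standardizer` with `center` and `scale`.
#' @export
fit_standardizer <- function(X, train_idx = seq_len(nrow(X))) {
  X <- as.matrix(X)
  if (length(train_idx) < 2)
    stop("need at least 2 training rows", call. = FALSE)
  Xt <- X[train_idx, , drop = FALSE]
  n <- nrow(Xt)
  ctr <- colMeans(Xt)
  scl <- sqrt(colSums(sweep(Xt, 2, ctr, "-")^2) / (n - 1))
  scl[!is.finite(scl) | scl == 0] <- 1
  structure(list(center = ctr, scale = scl, n_features = ncol(X)),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param st a [fit_standardizer()] object.
#' @param X matrix with the same feature count the standardizer was fit on.
#' @param idx optional row subset to transform (default: all rows).
#' @return matrix of z-scores `(x - center) / scale`.
#' @export
apply_standardizer <- function(st, X, idx = NULL) {
  if (!inherits(st, "standardizer")) stop("'st' is not a standardizer", call. = FALSE)
  X <- as.matrix(X)
  if (ncol(X) != st$n_features)
    stop("feature count mismatch: standardizer has ", st$n_features,
         ", data has ", ncol(X), call. = FALSE)
  if (!is.null(idx)) X <- X[idx, , drop = FALSE]
  sweep(sweep(X, 2, st$center, "-"), 2, st$scale, "/")
}

#' Linear kernel between two feature matrices
#'
#' Entry `(i, j)` is the inner product of row `i` of `X_a` with row `j` of
#' `X_b`. With `X_b = X_a` this is the Gram matrix, which is symmetric
#' positive semi-definite.
#'
#' @param X_a,X_b numeric matrices with equal feature counts.
#' @return `nrow(X_a) x nrow(X_b)` matrix.
#' @export
linear_kernel <- function(X_a, X_b = X_a) {
  X_a <- as.matrix(X_a); X_b <- as.matrix(X_b)
  if (ncol(X_a) != ncol(X_b))
    stop("feature counts differ: ", ncol(X_a), " vs ", ncol(X_b), call. = FALSE)
  tcrossprod(X_a, X_b)
}

#' Kernel container with train and test blocks
#'
#' A kernel over one feature set, holding the square train x train similarity
#' block and (optionally) the rectangular test x train block, both indexed
#' consistently with the participant ordering of the originating features.
#'
#' @param train square symmetric matrix (train x train).
#' @param test optional test x train matrix.
#' @param name feature-set name the kernel was derived from.
#' @return object of class `mkl_kernel`.
#' @export
mkl_kernel <- function(train, test = NULL, name = "kernel") {
  train <- as.matrix(train)
  if (nrow(train) != ncol(train)) stop("train block must be square", call. = FALSE)
  if (!is.null(test)) {
    test <- as.matrix(test)
    if (ncol(test) != ncol(train))
      stop("test block columns must match the train block", call. = FALSE)
  }
  structure(list(train = train, test = test, name = name), class = "mkl_kernel")
}

#' Min-max normalize a kernel to the unit interval
#'
#' Affinely maps kernel entries onto the unit interval using the minimum and
#' maximum of the *train* block, and applies the same map to the test block.
#' Test entries that fall beyond the training range are deliberately left
#' outside `[0, 1]` (not clipped): any renormalization that looked at the test
#' block would leak test information into the model. Note that this affine
#' map does not preserve positive semi-definiteness; downstream solvers must
#' tolerate (regularized) indefinite kernels.
#'
#' @param K an [mkl_kernel()] or a plain square matrix (treated as the train
#'   block).
#' @return object of the same kind, entries rescaled; the map is monotone, so
#'   entry ranking is preserved.
#' @export
normalize_kernel_minmax <- function(K) {
  plain <- !inherits(K, "mkl_kernel")
  if (plain) K <- mkl_kernel(K)
  lo <- min(K$train); hi <- max(K$train)
  if (hi <= lo)
    stop("constant kernel (max <= min): uninformative, cannot normalize",
         call. = FALSE)
  K$train <- (K$train - lo) / (hi - lo)
  if (!is.null(K$test)) K$test <- (K$test - lo) / (hi - lo)
  if (plain) K$train else K
}

#' Build a normalized linear kernel for one feature set on a split
#'
#' Convenience composition of the leakage-safe steps every pipeline uses:
#' z-score on the training rows, linear kernel, min-max normalization by the
#' train-block extremes.
#'
#' @param X participants x features matrix (all participants).
#' @param train,test integer row indices.
#' @param name feature-set name.
#' @return an [mkl_kernel()] with normalized train and test blocks.
#' @export
build_kernel <- function(X, train, test = integer(0), name = "kernel") {
  st <- fit_standardizer(X, train)
  Ztr <- apply_standardizer(st, X, train)
  Kt <- linear_kernel(Ztr)
  Ke <- if (length(test)) linear_kernel(apply_standardizer(st, X, test), Ztr)
  normalize_kernel_minmax(mkl_kernel(Kt, Ke, name))
}

#' Principal component projection fit on training rows
#'
#' Fits PCA on the training rows and retains the smallest number of leading
#' components whose cumulative explained variance reaches `var_frac`. The
#' projection is then applied unchanged to held-out rows, so dimensionality
#' reduction never sees test data.
#'
#' @param X numeric matrix (ordinarily standardized features).
#' @param train_idx training row indices.
#' @param var_frac fraction of total variance to retain, in `(0, 1]`.
#' @return object of class `pca_projection` with `center`, `rotation`,
#'   `n_components`, `explained`.
#' @export
fit_pca <- function(X, train_idx = seq_len(nrow(X)), var_frac = 0.95) {
  if (!is.numeric(var_frac) || length(var_frac) != 1 ||
      is.na(var_frac) || var_frac <= 0 || var_frac > 1)
    stop("'var_frac' must be in (0, 1]", call. = FALSE)
  X <- as.matrix(X)
  if (length(train_idx) < 2) stop("need at least 2 training rows", call. = FALSE)
  p <- stats::prcomp(X[train_idx, , drop = FALSE], center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  frac <- cumsum(v) / sum(v)
  k <- which(frac >= var_frac - 1e-12)[1]
  structure(list(center = p$center,
                 rotation = p$rotation[, seq_len(k), drop = FALSE],
                 n_components = k, explained = frac[k]),
            class = "pca_projection")
}

#' Apply a fitted PCA projection
#'
#' @param projection a [fit_pca()] object.
#' @param X matrix with the original feature count.
#' @param idx optional row subset.
#' @return participants x components score matrix.
#' @export
apply_pca <- function(projection, X, idx = NULL) {
  if (!inherits(projection, "pca_projection"))
    stop("'projection' is not a fitted PCA projection", call. = FALSE)
  X <- as.matrix(X)
  if (!is.null(idx)) X <- X[idx, , drop = FALSE]
  if (ncol(X) != length(projection$center))
    stop("feature count mismatch", call. = FALSE)
  sweep(X, 2, projection$center, "-") %*% projection$rotation
}
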