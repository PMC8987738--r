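#' Confound feature sets
#'
#' One single-column feature set per potential confound: site and sex
#' (encoded 0/1 so single-feature linear kernels are well defined), age,
#' time of day, mean and SD head translation, *squared* sensor distance
#' (magnetic field strength falls off with at least the square of distance,
#' so the squared distance is the physically relevant confound), and
#' education. The cognitive screening score (MMSE) is deliberately excluded:
#' it informs the patient diagnosis, so it would be a circular predictor.
#'
#' @param table imputed participant table.
#' @return named list of 8 one-column matrices.
#' @export
confound_features <- function(table) {
  needed <- c("site", "sex", "age", "time_of_day", "mean_translation",
              "sd_translation", "sensor_distance", "education")
  absent <- setdiff(needed, names(table))
  if (length(absent))
    stop("missing confound column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  if (anyNA(table[, needed]))
    stop("confounds contain missing values; impute first", call. = FALSE)
  num <- function(v) {
    if (is.factor(v) || is.character(v)) {
      f <- as.factor(v)
      as.numeric(f == levels(f)[1])
    } else as.numeric(v)
  }
  vals <- list(
    site = num(table$site),
    sex = num(table$sex),
    age = num(table$age),
    time_of_day = num(table$time_of_day),
    mean_translation = num(table$mean_translation),
    sd_translation = num(table$sd_translation),
    sensor_distance_sq = num(table$sensor_distance)^2,
    education = num(table$education)
  )
  lapply(vals, function(v) matrix(v, ncol = 1,
                                  dimnames = list(table$participant_id, NULL)))
}

#' Confound kernels
#'
#' The 8 confound feature sets of [confound_features()], each turned into a
#' min-max normalized linear kernel of the z-scored single variable on the
#' given split (or over the whole table when no split is given).
#'
#' @param table imputed participant table.
#' @param train,test row indices; default: all rows train.
#' @return named list of 8 [mkl_kernel()] objects.
#' @export
confound_kernels <- function(table, train = seq_len(nrow(table)),
                             test = integer(0)) {
  feats <- confound_features(table)
  Map(function(X, nm) build_kernel(X, train, test, nm), feats, names(feats))
}

#' Early combination: feature concatenation
#'
#' Each feature set is z-scored on the training rows (so sets with
#' incommensurate units become comparable), the columns are concatenated,
#' and a single normalized linear kernel is fed to the margin classifier
#' (EasyMKL with one kernel). Test margins are returned.
#'
#' @param sets named list of participants x features matrices (full cohort
#'   rows, consistently ordered).
#' @param y full label vector (-1/+1 or two-level factor).
#' @param split a split with `train` and `test` indices, e.g. from
#'   [balanced_split()].
#' @param lam EasyMKL regularization in `[0, 1]`.
#' @return numeric test margins with attribute `model`.
#' @export
early_pipeline <- function(sets, y, split, lam = 0.5) {
  check_sets(sets)
  y <- as_pm1(y)
  Z <- do.call(cbind, lapply(sets, function(X) {
    st <- fit_standardizer(X, split$train)
    apply_standardizer(st, X)
  }))
  K <- build_raw_kernel(Z, split$train, split$test)
  m <- fit_easymkl(list(combined = K), y[split$train], lam)
  structure(decision_values(m, list(K)), model = m)
}

#' Intermediate combination: multiple kernel learning over feature kernels
#'
#' One normalized linear kernel per feature set; a single EasyMKL fit learns
#' the simplex weighting across them and the decision rule jointly.
#'
#' @inheritParams early_pipeline
#' @return numeric test margins with attribute `model`.
#' @export
intermediate_pipeline <- function(sets, y, split, lam = 0.5) {
  check_sets(sets)
  y <- as_pm1(y)
  ks <- Map(function(X, nm) build_kernel(X, split$train, split$test, nm),
            sets, names(sets))
  m <- fit_easymkl(ks, y[split$train], lam)
  structure(decision_values(m, ks), model = m)
}

#' Late combination: stacked decision-level fusion
#'
#' Two-stage stacking. Stage 1 fits one margin classifier per feature set:
#' out-of-fold margins for every training participant are collected over
#' `inner_k` stratified inner folds (so no training example is scored by a
#' model that saw it), while the test set is scored by a model refit on the
#' full training set. Stage 2 treats each set's margin vector as a one-column
#' feature set — z-scored, kernelized and min-max normalized like any
#' modality — and a meta-level EasyMKL fit over these decision kernels
#' produces the final test margins.
#'
#' With a single feature set there is no meta-level to learn and the stage-1
#' margins are returned directly, so Early, Intermediate and Late combination
#' coincide exactly in that case.
#'
#' @inheritParams early_pipeline
#' @param lam_stage1 regularization for the per-modality classifiers.
#' @param lam_stage2 regularization for the meta classifier (defaults to
#'   `lam_stage1`).
#' @param inner_k number of stratified inner folds for out-of-fold margins;
#'   used only when `split` carries no precomputed `inner` assignment.
#' @return numeric test margins with attribute `model` (the meta model) and
#'   `stage1_margins`.
#' @export
late_pipeline <- function(sets, y, split, lam_stage1 = 0.5,
                          lam_stage2 = lam_stage1, inner_k = 5) {
  check_sets(sets)
  y <- as_pm1(y)
  if (length(sets) == 1L)
    return(early_pipeline(sets, y, split, lam_stage1))

  train <- split$train
  inner <- split$inner
  if (is.null(inner))
    inner <- stratified_folds(y[train], inner_k, seed = split$seed)

  oof <- matrix(NA_real_, length(train), length(sets),
                dimnames = list(NULL, names(sets)))
  test_m <- matrix(NA_real_, length(split$test), length(sets),
                   dimnames = list(NULL, names(sets)))
  for (s in seq_along(sets)) {
    X <- sets[[s]]
    # full-train model scores the held-out test set
    K <- build_kernel(X, train, split$test, names(sets)[s])
    m_full <- fit_easymkl(list(K), y[train], lam_stage1)
    test_m[, s] <- decision_values(m_full, list(K))
    # inner folds give out-of-fold margins for the training rows
    for (f in sort(unique(inner))) {
      in_tr <- train[inner != f]
      in_te <- train[inner == f]
      Ki <- build_kernel(X, in_tr, in_te, names(sets)[s])
      mi <- fit_easymkl(list(Ki), y[in_tr], lam_stage1)
      oof[inner == f, s] <- decision_values(mi, list(Ki))
    }
  }

  meta_sets <- lapply(seq_along(sets), function(s)
    rbind(matrix(oof[, s], ncol = 1), matrix(test_m[, s], ncol = 1)))
  names(meta_sets) <- names(sets)
  n_tr <- length(train)
  meta_split <- list(train = seq_len(n_tr),
                     test = n_tr + seq_along(split$test))
  ks <- Map(function(X, nm) build_kernel(X, meta_split$train, meta_split$test, nm),
            meta_sets, names(meta_sets))
  meta <- fit_easymkl(ks, y[train], lam_stage2)
  structure(decision_values(meta, ks), model = meta,
            stage1_margins = list(train_oof = oof, test = test_m))
}

#' Append confound sets to a pipeline's inputs
#'
#' Runs any base pipeline with the 8 confound feature sets appended to the
#' modality list: Early concatenates them with the features, Intermediate
#' adds 8 confound kernels, and Late adds 8 decision kernels at the meta
#' stage (e.g. one modality + confounds gives 9 stage-2 inputs). Passing an
#' empty `sets` list fits the confound-only model.
#'
#' @param pipeline one of [early_pipeline()], [intermediate_pipeline()],
#'   [late_pipeline()].
#' @param sets named list of modality feature matrices (possibly empty).
#' @param table imputed participant table supplying the confounds.
#' @inheritParams early_pipeline
#' @param ... further arguments passed to the pipeline (e.g. `lam`).
#' @return the pipeline's test margins.
#' @export
with_confounds <- function(pipeline, sets, table, y, split, ...) {
  conf <- confound_features(table)
  pipeline(c(sets, conf), y, split, ...)
}

# shared input validation for pipelines
check_sets <- function(sets) {
  if (!is.list(sets) || length(sets) == 0)
    stop("need at least one feature set", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("feature sets must be named", call. = FALSE)
  n <- vapply(sets, nrow, integer(1))
  if (length(unique(n)) != 1)
    stop("feature sets disagree in row count", call. = FALSE)
  invisible(TRUE)
}

# normalized linear kernel of an already-standardized matrix
build_raw_kernel <- function(Z, train, test = integer(0), name = "kernel") {
  Ztr <- Z[train, , drop = FALSE]
  Kt <- linear_kernel(Ztr)
  Ke <- if (length(test)) linear_kernel(Z[test, , drop = FALSE], Ztr)
  normalize_kernel_minmax(mkl_kernel(Kt, Ke, name))
}
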