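PARTICIPANT_COLUMNS <- c("participant_id", "group", "site", "sex", "age",
                         "time_of_day", "mean_translation", "sd_translation",
                         "sensor_distance", "education", "mmse")

#' Read a participant table from TSV
#'
#' Tab-separated file with a header row, modeled on the BIDS
#' `participants.tsv` layout. The required columns are typed (factors for
#' group/site/sex, numeric otherwise); unknown columns are preserved as
#' read.
#'
#' @param path file path.
#' @return participant `data.frame`.
#' @export
read_participants <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = c("NA", "n/a", ""))
  absent <- setdiff(PARTICIPANT_COLUMNS, names(tab))
  if (length(absent))
    stop("participant file is missing required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  tab$group <- factor(tab$group)
  if (nlevels(tab$group) != 2)
    stop("'group' must have exactly two levels", call. = FALSE)
  tab$site <- factor(tab$site)
  tab$sex <- factor(tab$sex)
  for (v in c("age", "time_of_day", "mean_translation", "sd_translation",
              "sensor_distance", "education", "mmse"))
    tab[[v]] <- as.numeric(tab[[v]])
  if (anyDuplicated(tab$participant_id))
    stop("duplicate participant ids", call. = FALSE)
  tab
}

#' Write a participant table to TSV
#'
#' @param table participant `data.frame`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' Run a configured classification experiment
#'
#' Single declarative entry point tying the stages together: generate (or
#' read) a cohort, build the configured feature sets, run the chosen
#' combination pipelines under matched repeated cross-validation, and write
#' all artifacts — per-repetition accuracies as CSV, a JSON summary with
#' means, SDs and the pairwise percent-greater matrix, and a resolved copy
#' of the configuration — so every emitted number is reproducible from the
#' config alone.
#'
#' @param cfg a list with elements:
#'   \describe{
#'     \item{cohort}{list passed to [cohort_spec()] (or `participants_path`
#'       to read a table instead).}
#'     \item{feature_sets}{named list; each element a list with `n_features`,
#'       optional `informative`, `d`, `seed`.}
#'     \item{pipelines}{character subset of `c("early", "intermediate",
#'       "late")`.}
#'     \item{confounds}{logical; append the 8 confound sets to each
#'       pipeline.}
#'     \item{lambda}{fixed regularization weight in `[0, 1]`.}
#'     \item{R, k}{repetitions and folds for [repeated_cv()].}
#'     \item{seed}{base seed.}
#'   }
#' @param out_dir output directory (created if needed).
#' @return the [repeated_cv()] result, invisibly; artifacts on disk.
#' @export
run_experiment <- function(cfg, out_dir) {
  stopifnot(is.list(cfg))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- utils::modifyList(
    list(pipelines = c("early", "intermediate", "late"),
         confounds = FALSE, lambda = 0.5, R = 100, k = 5, seed = 1L),
    cfg)
  bad <- setdiff(cfg$pipelines, c("early", "intermediate", "late"))
  if (length(bad))
    stop("[config] unknown pipeline(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  table <- if (!is.null(cfg$participants_path)) {
    read_participants(cfg$participants_path)
  } else {
    spec <- do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed)))
    generate_cohort(spec)
  }
  table <- impute_missing(table)
  y <- ifelse(table$group == levels(table$group)[2], 1, -1)

  if (is.null(cfg$feature_sets) || !length(cfg$feature_sets))
    stop("[config] no feature sets configured", call. = FALSE)
  sets <- lapply(seq_along(cfg$feature_sets), function(i) {
    fs <- cfg$feature_sets[[i]]
    generate_group_features(table,
                            n_features = fs$n_features,
                            informative = fs$informative %||% integer(0),
                            d = fs$d %||% numeric(0),
                            seed = fs$seed %||% (cfg$seed + i))
  })
  names(sets) <- names(cfg$feature_sets)

  pipe_fun <- list(early = early_pipeline,
                   intermediate = intermediate_pipeline,
                   late = late_pipeline)
  methods <- lapply(cfg$pipelines, function(p) {
    f <- pipe_fun[[p]]
    if (isTRUE(cfg$confounds)) {
      function(split) with_confounds(f, sets, table, y, split, cfg$lambda)
    } else {
      function(split) f(sets, y, split, cfg$lambda)
    }
  })
  names(methods) <- cfg$pipelines

  res <- repeated_cv(methods, y, R = cfg$R, k = cfg$k, base_seed = cfg$seed)

  acc <- res$accuracy
  long <- data.frame(repetition = rep(seq_len(nrow(acc)), ncol(acc)),
                     method = rep(colnames(acc), each = nrow(acc)),
                     balanced_accuracy = as.vector(acc))
  utils::write.csv(long, file.path(out_dir, "cv_accuracy.csv"),
                   row.names = FALSE)

  pg <- outer(colnames(acc), colnames(acc), Vectorize(function(a, b)
    100 * mean(acc[, a] - acc[, b] > 0)))
  dimnames(pg) <- list(colnames(acc), colnames(acc))
  summary <- list(
    methods = colnames(acc),
    mean_accuracy = as.list(colMeans(acc)),
    sd_accuracy = as.list(apply(acc, 2, stats::sd)),
    pct_greater = as.data.frame(pg),
    n_repetitions = nrow(acc), k = res$k
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_participants(table, file.path(out_dir, "participants-imputed.tsv"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
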