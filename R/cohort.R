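#' Default confound distribution parameters for the synthetic cohort
#'
#' Marginal per-group distributions of the demographic, acquisition and
#' movement variables the generator emulates for a two-site MCI/control
#' study. Continuous variables are normal with the listed mean and SD;
#' `site` and `sex` are Bernoulli with the listed probability of the first
#' category (site = CBU, sex = male). MMSE is generated but is *not* a
#' confound: it informs the patient diagnosis, so using it as a predictor
#' would be circular.
#'
#' Units: age and education in years, time of day in hours (24 h clock),
#' head translations in mm, sensor distance in mm.
#'
#' @return named list; each element has per-group parameters for one variable.
#' @export
default_confound_params <- function() {
  list(
    site = list(type = "categorical",
                p_first = c(control = 89 / 163, patient = 63 / 144),
                levels = c("CBU", "CTB")),
    sex = list(type = "categorical",
               p_first = c(control = 82 / 163, patient = 74 / 144),
               levels = c("M", "F")),
    age = list(type = "continuous",
               mean = c(control = 71.2, patient = 72.8),
               sd = c(control = 7.0, patient = 6.8)),
    time_of_day = list(type = "continuous",
                       mean = c(control = 12.8, patient = 12.6),
                       sd = c(control = 2.4, patient = 2.1)),
    mean_translation = list(type = "continuous",
                            mean = c(control = 2.0, patient = 2.1),
                            sd = c(control = 1.8, patient = 1.8)),
    sd_translation = list(type = "continuous",
                          mean = c(control = 1.1, patient = 1.2),
                          sd = c(control = 1.1, patient = 1.1)),
    sensor_distance = list(type = "continuous",
                           mean = c(control = 113.0e3, patient = 113.3e3),
                           sd = c(control = 1.5e3, patient = 2.3e3)),
    education = list(type = "continuous",
                     mean = c(control = 14.5, patient = 11.0),
                     sd = c(control = 4.4, patient = 5.2)),
    mmse = list(type = "continuous",
                mean = c(control = 28.8, patient = 25.9),
                sd = c(control = 1.2, patient = 3.4))
  )
}

#' Default missing-data rates for the synthetic cohort
#'
#' Per-variable fraction of cells blanked by [generate_cohort()], chosen to
#' mirror the scale of missingness in a real two-site study: a few missing
#' cognitive scores, somewhat more missing education and head-movement
#' summaries.
#'
#' @return named numeric vector of rates in `[0, 1)`.
#' @export
default_missing_rates <- function() {
  c(mmse = 0.016, education = 0.037,
    mean_translation = 0.08, sd_translation = 0.08)
}

#' Specification of a synthetic two-group cohort
#'
#' @param n_control,n_patient group sizes (default 163 controls, 144
#'   patients).
#' @param confound_params per-variable per-group distribution parameters; see
#'   [default_confound_params()].
#' @param missing_rates named per-variable missingness rates in `[0, 1)`
#'   (continuous variables only).
#' @param seed integer seed; the generator is fully reproducible given the
#'   spec.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 163, n_patient = 144,
                        confound_params = default_confound_params(),
                        missing_rates = default_missing_rates(),
                        seed = 1L) {
  if (!is.numeric(n_control) || !is.numeric(n_patient) ||
      n_control < 1 || n_patient < 1)
    stop("group counts must be positive", call. = FALSE)
  for (v in names(confound_params)) {
    cp <- confound_params[[v]]
    if (cp$type == "continuous" && any(cp$sd < 0))
      stop("negative SD for variable '", v, "'", call. = FALSE)
    if (cp$type == "categorical" && any(cp$p_first < 0 | cp$p_first > 1))
      stop("invalid category probability for variable '", v, "'", call. = FALSE)
  }
  if (length(missing_rates) &&
      (any(missing_rates < 0) || any(missing_rates >= 1)))
    stop("missing rates must lie in [0, 1)", call. = FALSE)
  if (!all(names(missing_rates) %in% names(confound_params)))
    stop("missing_rates names unknown: ",
         paste(setdiff(names(missing_rates), names(confound_params)),
               collapse = ", "), call. = FALSE)
  structure(list(n_control = as.integer(n_control),
                 n_patient = as.integer(n_patient),
                 confound_params = confound_params,
                 missing_rates = missing_rates,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic participant table
#'
#' Draws one row per participant: group label, site, sex, and the continuous
#' demographic/acquisition variables, each from its per-group marginal
#' distribution (variables are independent within group; only marginals are
#' specified). Missing cells are then blanked at the per-variable rates of
#' the spec so that imputation code is exercised.
#'
#' @param spec a [cohort_spec()].
#' @return `data.frame` with columns `participant_id`, `group` (factor
#'   control/patient), `site`, `sex` (factors), and numeric `age`,
#'   `time_of_day`, `mean_translation`, `sd_translation`, `sensor_distance`,
#'   `education`, `mmse`.
#' @examples
#' tab <- generate_cohort(cohort_spec(seed = 7))
#' table(tab$group)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec", call. = FALSE)
  n <- spec$n_control + spec$n_patient
  group <- factor(rep(c("control", "patient"),
                      c(spec$n_control, spec$n_patient)),
                  levels = c("control", "patient"))
  out <- data.frame(
    participant_id = sprintf("sub-%04d", seq_len(n)),
    group = group,
    stringsAsFactors = FALSE
  )
  withr_seed(spec$seed, {
    for (v in names(spec$confound_params)) {
      cp <- spec$confound_params[[v]]
      if (cp$type == "categorical") {
        val <- character(n)
        for (g in levels(group)) {
          i <- group == g
          val[i] <- ifelse(stats::runif(sum(i)) < cp$p_first[[g]],
                           cp$levels[1], cp$levels[2])
        }
        out[[v]] <- factor(val, levels = cp$levels)
      } else {
        val <- numeric(n)
        for (g in levels(group)) {
          i <- group == g
          val[i] <- stats::rnorm(sum(i), cp$mean[[g]], cp$sd[[g]])
        }
        out[[v]] <- val
      }
    }
    for (v in names(spec$missing_rates)) {
      r <- spec$missing_rates[[v]]
      if (r > 0) {
        n_miss <- round(r * n)
        if (n_miss > 0) out[[v]][sample.int(n, n_miss)] <- NA_real_
      }
    }
  })
  out
}

# evaluate `code` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Nearest-neighbour imputation of missing cells
#'
#' Each missing cell is filled with the value from the nearest *complete* row
#' in Euclidean distance, computed over the continuous variables observed in
#' both rows after per-variable standardization (without standardization the
#' distance would be dominated by the largest-scale variable, e.g. sensor
#' distance in mm). One neighbour is used (`k = 1`).
#'
#' @param table a participant `data.frame` as from [generate_cohort()].
#' @param vars variables eligible for imputation; defaults to all numeric
#'   columns.
#' @return the table with no missing cells among `vars`.
#' @export
impute_missing <- function(table,
                           vars = names(table)[vapply(table, is.numeric, logical(1))]) {
  miss_any <- vapply(vars, function(v) anyNA(table[[v]]), logical(1))
  if (!any(miss_any)) return(table)
  all_missing <- vars[vapply(vars, function(v) all(is.na(table[[v]])), logical(1))]
  if (length(all_missing))
    stop("variable(s) missing in every row, cannot impute: ",
         paste(all_missing, collapse = ", "), call. = FALSE)

  X <- as.matrix(table[, vars, drop = FALSE])
  mu <- colMeans(X, na.rm = TRUE)
  sg <- apply(X, 2, stats::sd, na.rm = TRUE)
  sg[!is.finite(sg) | sg == 0] <- 1
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sg, "/")

  complete <- which(stats::complete.cases(X))
  if (!length(complete))
    stop("no complete rows available for nearest-neighbour imputation",
         call. = FALSE)
  for (i in which(!stats::complete.cases(X))) {
    obs <- which(!is.na(X[i, ]))
    d <- sqrt(colSums((t(Z[complete, obs, drop = FALSE]) - Z[i, obs])^2))
    nn <- complete[which.min(d)]
    gap <- is.na(X[i, ])
    X[i, gap] <- X[nn, gap]
  }
  table[, vars] <- as.data.frame(X)
  table
}

#' Two-sample pooled-variance t statistic from group summaries
#'
#' Computes the classical pooled two-sample t statistic (and its degrees of
#' freedom, `n1 + n2 - 2`) from per-group means, SDs and sizes — the check a
#' reader performs on a published demographics table, e.g. the education gap
#' between patients and controls.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return list with `t`, `df`.
#' @examples
#' two_sample_t_summary(14.5, 4.4, 163, 11.0, 5.2, 144)
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = n1 + n2 - 2)
}
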