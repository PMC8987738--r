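#' Group-effect specification for synthetic features
#'
#' Declares where and how strongly the patient group differs from controls in
#' the synthetic feature generators: a set of "atrophied" ROIs with a
#' standardized mean difference for the MRI-like features, and a band-limited
#' covariance perturbation for the MEG-like time series.
#'
#' @param mri_rois integer indices (1-based, `<= 110`) of affected ROIs.
#' @param mri_d standardized group difference (Cohen's d) in those ROIs;
#'   recycled over `mri_rois`. Patients are shifted downwards (atrophy).
#' @param meg_bands character names of affected frequency bands (subset of
#'   `meg_bands()$name`).
#' @param meg_channels integer indices of affected channels.
#' @param meg_effect amplitude of the shared band-limited component added to
#'   the affected channels of patients, in units of the per-band noise SD.
#' @param noise_sd positive noise scale for the feature generators.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(mri_rois = integer(0), mri_d = numeric(0),
                        meg_bands = character(0), meg_channels = integer(0),
                        meg_effect = 0, noise_sd = 1) {
  if (length(mri_rois)) {
    if (any(mri_rois < 1 | mri_rois > 110))
      stop("ROI indices must lie in 1..110", call. = FALSE)
    mri_d <- rep_len(mri_d, length(mri_rois))
  }
  if (length(meg_bands) && !all(meg_bands %in% meg_bands()$name))
    stop("unknown band(s): ",
         paste(setdiff(meg_bands, meg_bands()$name), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be non-negative", call. = FALSE)
  structure(list(mri_rois = as.integer(mri_rois), mri_d = mri_d,
                 meg_bands = meg_bands,
                 meg_channels = as.integer(meg_channels),
                 meg_effect = meg_effect, noise_sd = noise_sd),
            class = "effect_spec")
}

#' Generic two-group Gaussian feature matrix
#'
#' Workhorse behind [generate_mri_features()] and the abstract modality
#' simulations: i.i.d. Gaussian noise per feature, with a mean shift of
#' `d * noise_sd` between groups in the designated informative features, so
#' the injected standardized difference is exactly `d`. Patients are shifted
#' down (mimicking regional atrophy).
#'
#' @param table participant table with a two-level `group` column.
#' @param n_features number of columns.
#' @param informative integer indices of informative features.
#' @param d standardized group difference, recycled over `informative`.
#' @param noise_sd noise scale.
#' @param seed integer seed.
#' @param prefix column-name prefix.
#' @return participants x `n_features` numeric matrix, rownames =
#'   participant ids.
#' @export
generate_group_features <- function(table, n_features, informative = integer(0),
                                    d = numeric(0), noise_sd = 1, seed = 1L,
                                    prefix = "f") {
  if (length(informative) && any(informative < 1 | informative > n_features))
    stop("informative indices out of range", call. = FALSE)
  d <- rep_len(d, length(informative))
  n <- nrow(table)
  patient <- table$group == levels(table$group)[2]
  X <- withr_seed(seed,
    matrix(stats::rnorm(n * n_features, sd = noise_sd), n, n_features))
  if (length(informative))
    X[patient, informative] <- sweep(X[patient, informative, drop = FALSE],
                                     2, d * noise_sd, "-")
  dimnames(X) <- list(table$participant_id,
                      paste0(prefix, seq_len(n_features)))
  X
}

#' Synthetic MRI ROI gray-matter features
#'
#' Generates the 110-dimensional ROI feature vector per participant
#' (emulating mean gray-matter volume within the 110 anatomical ROIs of the
#' Harvard-Oxford atlas): pure Gaussian noise except in the "atrophied" ROIs
#' listed in the effect spec, which show the requested standardized group
#' deficit in patients.
#'
#' @param table participant table.
#' @param effects an [effect_spec()].
#' @param seed integer seed.
#' @return participants x 110 matrix, columns `roi1..roi110`.
#' @export
generate_mri_features <- function(table, effects = effect_spec(), seed = 1L) {
  if (!inherits(effects, "effect_spec"))
    stop("'effects' must be an effect_spec", call. = FALSE)
  generate_group_features(table, n_features = 110L,
                          informative = effects$mri_rois, d = effects$mri_d,
                          noise_sd = effects$noise_sd, seed = seed,
                          prefix = "roi")
}

#' Synthetic resting-state MEG sensor time series
#'
#' Builds each participant's recording as a sum of independent band-limited
#' Gaussian processes, one per canonical frequency band, produced by passing
#' white noise through the package's own zero-phase order-5 Butterworth
#' band-pass. In the bands named by the effect spec, patients additionally
#' receive a *shared* band-limited component on the affected channels, scaled
#' by `meg_effect`, which perturbs the patient-group sensor covariance (and
#' per-channel power) in those bands only. Optional isolated spikes at 10x
#' the channel SD provide unambiguous targets for the outlier clipper.
#'
#' @param table participant table.
#' @param effects an [effect_spec()].
#' @param n_channels one of 102 (magnetometer-like), 204
#'   (gradiometer-like) or 306 (full array).
#' @param fs sampling rate in Hz (default 500).
#' @param duration_s recording length in seconds (default 120, i.e. 60000
#'   samples at 500 Hz).
#' @param spikes_per_channel number of injected spike artifacts per channel.
#' @param seed integer seed.
#' @return named list (one element per participant) of [sensor_ts()] objects.
#' @export
generate_meg_timeseries <- function(table, effects = effect_spec(),
                                    n_channels = 102L, fs = 500,
                                    duration_s = 120,
                                    spikes_per_channel = 0L, seed = 1L) {
  if (!n_channels %in% c(102L, 204L, 306L))
    stop("'n_channels' must be 102, 204 or 306", call. = FALSE)
  if (!inherits(effects, "effect_spec"))
    stop("'effects' must be an effect_spec", call. = FALSE)
  n_samp <- as.integer(round(fs * duration_s))
  bands <- meg_bands()
  patient <- table$group == levels(table$group)[2]
  ch_type <- unname(c(`102` = "MAG", `204` = "GRD",
                      `306` = "mixed")[as.character(n_channels)])

  withr_seed(seed, {
    out <- vector("list", nrow(table))
    names(out) <- table$participant_id
    for (i in seq_len(nrow(table))) {
      x <- matrix(0, n_channels, n_samp)
      if (effects$noise_sd > 0) {
        for (b in seq_len(nrow(bands))) {
          nb <- matrix(stats::rnorm(n_channels * n_samp, sd = effects$noise_sd),
                       n_channels, n_samp)
          xb <- bandpass_matrix(nb, fs, bands$low[b], bands$high[b])
          if (patient[i] && bands$name[b] %in% effects$meg_bands &&
              length(effects$meg_channels) && effects$meg_effect != 0) {
            latent <- bandpass_matrix(
              matrix(stats::rnorm(n_samp, sd = effects$noise_sd), 1, n_samp),
              fs, bands$low[b], bands$high[b])
            xb[effects$meg_channels, ] <-
              xb[effects$meg_channels, , drop = FALSE] +
              rep(effects$meg_effect * drop(latent), each = length(effects$meg_channels))
          }
          x <- x + xb
        }
      }
      if (spikes_per_channel > 0) {
        for (ch in seq_len(n_channels)) {
          s <- stats::sd(x[ch, ])
          if (s == 0) s <- 1
          at <- sample.int(n_samp, spikes_per_channel)
          x[ch, at] <- 10 * s * sign(stats::runif(spikes_per_channel) - 0.5)
        }
      }
      out[[i]] <- sensor_ts(x, fs = fs, channel_type = ch_type)
    }
    out
  })
}

#' Abstract signal/noise kernel simulation
#'
#' Builds the classical multiple-kernel-learning benchmark problem: a set of
#' "signal" kernels derived from features correlated with the class label at
#' strength `signal_strength`, and "noise" kernels from label-independent
#' features. Each kernel is the linear kernel of its z-scored feature block,
#' min-max normalized to `[0, 1]`. Used to check that the MKL classifier
#' concentrates weight on informative kernels and stays at chance when none
#' is informative.
#'
#' @param n_signal,n_noise kernel counts (at least one kernel in total).
#' @param n_participants cohort size; labels are balanced (+1/-1).
#' @param signal_strength standardized label effect added to every feature of
#'   a signal kernel.
#' @param features_per_kernel features behind each kernel (default 10).
#' @param seed integer seed.
#' @return list with `kernels` (named list of `n x n` matrices, signal
#'   kernels first), `labels` (+1/-1), `features` (the generating blocks).
#' @export
generate_kernel_sim <- function(n_signal, n_noise, n_participants,
                                signal_strength = 1,
                                features_per_kernel = 10L, seed = 1L) {
  if (n_signal + n_noise < 1) stop("need at least one kernel", call. = FALSE)
  if (n_participants < 4) stop("need at least 4 participants", call. = FALSE)
  n <- as.integer(n_participants)
  y <- rep(c(-1, 1), length.out = n)

  withr_seed(seed, {
    mk <- function(signal) {
      X <- matrix(stats::rnorm(n * features_per_kernel), n, features_per_kernel)
      if (signal) X <- X + signal_strength * y
      X
    }
    feats <- c(lapply(seq_len(n_signal), function(i) mk(TRUE)),
               lapply(seq_len(n_noise), function(i) mk(FALSE)))
  })
  names(feats) <- c(if (n_signal) paste0("signal", seq_len(n_signal)),
                    if (n_noise) paste0("noise", seq_len(n_noise)))
  kernels <- lapply(feats, function(X) {
    Z <- apply_standardizer(fit_standardizer(X), X)
    normalize_kernel_minmax(linear_kernel(Z))
  })
  list(kernels = kernels, labels = y, features = feats)
}

#' Canonical multimodal simulation cohort
#'
#' The package's reference synthetic problem for studying modality
#' combination: a balanced two-group cohort with
#' \describe{
#'   \item{`mri`}{110 ROI-like features, 10 of them "atrophied" with a focal
#'     standardized deficit of d = 0.8 in patients — few, individually
#'     strong features;}
#'   \item{`meg`}{2000 covariance-like features, 60 of them carrying a
#'     distributed d = 0.45 patient effect — many, individually weak
#'     features, statistically independent of the MRI noise so the two
#'     modalities are complementary;}
#'   \item{`noise1..n`}{optional pure-noise feature sets of 500 features
#'     each, for probing robustness of kernel- versus decision-level
#'     combination to uninformative kernels.}
#' }
#'
#' @param n_per_group participants per group (default 60).
#' @param n_noise_sets number of pure-noise sets appended (default 0).
#' @param seed integer seed; drives cohort and all feature draws.
#' @return list with `table`, `labels` (-1 control / +1 patient),
#'   `modalities` (named list: mri, meg), `noise` (named list, possibly
#'   empty).
#' @export
simulate_multimodal_cohort <- function(n_per_group = 60, n_noise_sets = 0,
                                       seed = 1L) {
  tab <- generate_cohort(cohort_spec(n_per_group, n_per_group, seed = seed))
  y <- ifelse(tab$group == "patient", 1, -1)
  modalities <- list(
    mri = generate_group_features(tab, 110, informative = 1:10, d = 0.8,
                                  seed = seed + 101L, prefix = "roi"),
    meg = generate_group_features(tab, 2000, informative = 1:60, d = 0.45,
                                  seed = seed + 202L, prefix = "cov")
  )
  noise <- list()
  if (n_noise_sets > 0) {
    noise <- lapply(seq_len(n_noise_sets), function(j)
      generate_group_features(tab, 500, seed = seed + 300L + j))
    names(noise) <- paste0("noise", seq_len(n_noise_sets))
  }
  list(table = tab, labels = y, modalities = modalities, noise = noise)
}
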