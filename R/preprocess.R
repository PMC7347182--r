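# Preprocessing chain: high-pass -> adaptive noise cancellation -> 1-Hz
# RMS/WL features -> Hampel -> per-test z-scoring.

#' Preprocessing parameters
#'
#' @param hp_cutoff_hz High-pass cutoff in Hz (default 20, the standard sEMG
#'   movement-artifact/drift cutoff).
#' @param hp_order Butterworth order of the one-pass design (default 4);
#'   applied forward-backward, so the effective attenuation is doubled and the
#'   net phase shift is zero.
#' @param anc_step NLMS adaptation step size (default 0.1).
#' @param anc_len NLMS filter length in taps (default 32).
#' @param hampel_k Hampel half-window in samples of the 1-Hz feature series
#'   (default 3).
#' @param hampel_t Hampel outlier threshold in robust standard deviations
#'   (default 3).
#' @return A list of class `prep_config`.
#' @export
prep_config <- function(hp_cutoff_hz = 20, hp_order = 4,
                        anc_step = 0.1, anc_len = 32L,
                        hampel_k = 3L, hampel_t = 3) {
  stopifnot(hp_cutoff_hz > 0, hp_order >= 1, anc_step > 0, anc_len >= 1,
            hampel_k >= 1, hampel_t > 0)
  structure(list(hp_cutoff_hz = hp_cutoff_hz, hp_order = hp_order,
                 anc_step = anc_step, anc_len = as.integer(anc_len),
                 hampel_k = as.integer(hampel_k), hampel_t = hampel_t),
            class = "prep_config")
}

#' Zero-phase Butterworth high-pass filter
#'
#' Removes DC, baseline drift and movement artifacts below the cutoff.
#' The filter is applied forward-backward ([signal::filtfilt()]) so event
#' timestamps stay aligned with the filtered signal.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz; must exceed `2 * cutoff_hz`.
#' @param cutoff_hz Cutoff frequency in Hz (default 20).
#' @param order Butterworth order of the one-pass design (default 4).
#' @return Filtered signal, same length as `x`.
#' @examples
#' x <- sin(2 * pi * 100 * (0:999) / 1000)
#' y <- highpass_filter(x, fs = 1000)
#' @export
highpass_filter <- function(x, fs, cutoff_hz = 20, order = 4) {
  if (fs <= 2 * cutoff_hz)
    stop("fs must exceed twice the cutoff frequency")
  min_len <- 3 * (2 * order + 1)
  if (length(x) <= min_len)
    stop("signal too short for the filter warm-up (need > ", min_len,
         " samples)")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  iir_filtfilt(bf$b, bf$a, x)
}

#' Reference-channel adaptive noise cancellation (NLMS)
#'
#' Classical adaptive noise cancellation: a normalized least-mean-squares
#' filter predicts the component of `primary` that is linearly related to the
#' (already high-pass filtered) `reference` - here the shared 50-Hz power-line
#' interference and, in electrical tests, the stimulation pulse artifacts
#' carried by the frontalis reference - and subtracts it. Muscle activity
#' uncorrelated with the reference passes through.
#'
#' @param primary Contaminated signal.
#' @param reference Noise reference of the same length.
#' @param step_size NLMS step size mu (default 0.1).
#' @param filter_len Adaptive filter length in taps (default 32).
#' @return The cleaned signal (`primary` minus the adaptively predicted
#'   reference-correlated component). A zero-variance reference yields
#'   `primary` unchanged, with a warning.
#' @export
adaptive_noise_cancel <- function(primary, reference, step_size = 0.1,
                                  filter_len = 32L) {
  stopifnot(length(primary) == length(reference), step_size > 0,
            filter_len >= 1)
  if (sd(reference) == 0) {
    warning("zero-variance reference: returning primary unchanged")
    return(primary)
  }
  nlms_cancel(primary, reference, step_size, as.integer(filter_len))
}

#' Root-mean-square of a feature window
#'
#' @param window Numeric vector of at least one sample.
#' @return `sqrt(mean(window^2))`.
#' @examples
#' rms_feature(c(3, 4)) # sqrt(25 / 2)
#' @export
rms_feature <- function(window) {
  if (length(window) < 1) stop("RMS requires a non-empty window")
  sqrt(mean(window^2))
}

#' Waveform length of a feature window
#'
#' Sum of absolute successive sample differences; an sEMG complexity measure
#' sensitive to both amplitude and frequency content.
#'
#' @param window Numeric vector of at least two samples.
#' @return `sum(abs(diff(window)))`.
#' @examples
#' wl_feature(c(0, 1, 0, 1)) # 3
#' @export
wl_feature <- function(window) {
  if (length(window) < 2) stop("waveform length requires at least 2 samples")
  sum(abs(diff(window)))
}

#' Extract 1-Hz RMS and waveform-length features
#'
#' Segments each cleaned muscle channel into non-overlapping 1-s windows
#' aligned to the recording start (the trailing partial window is dropped)
#' and computes RMS and WL per window, yielding the ten features
#' `corrms, corwl, ..., riswl`.
#'
#' @param channels Numeric matrix with (at least) the five muscle columns
#'   `cor, orb, lev, zyg, ris`.
#' @param fs Sampling rate in Hz (window length in samples).
#' @return A tibble with `time_s` (window start, seconds from recording
#'   start) and the ten feature columns.
#' @export
extract_features <- function(channels, fs) {
  stopifnot(all(MUSCLES %in% colnames(channels)))
  n <- nrow(channels)
  if (n < fs) stop("need at least one full 1-s window")
  nw <- floor(n / fs)
  out <- tibble::tibble(time_s = as.numeric(seq_len(nw) - 1))
  for (m in MUSCLES) {
    x <- matrix(channels[seq_len(nw * fs), m], nrow = fs)
    out[[paste0(m, "rms")]] <- sqrt(colMeans(x^2))
    out[[paste0(m, "wl")]] <- colSums(abs(x[-1, , drop = FALSE] -
                                            x[-fs, , drop = FALSE]))
  }
  out
}

#' Hampel filter for outlier removal
#'
#' Sliding-window median filter: a point deviating from its window median by
#' more than `t` robust standard deviations (1.4826 * MAD of the window) is
#' replaced by that median. Windows are truncated at the series edges; series
#' shorter than `2K + 1` are returned unchanged. Applied per feature and per
#' test to the 1-Hz series to remove residual artifact spikes of extremely
#' high amplitude.
#'
#' @param x Numeric series.
#' @param k Half-window `K` in samples (default 3).
#' @param t Outlier threshold in robust SDs (default 3).
#' @return The filtered series.
#' @examples
#' hampel_filter(c(1, 1, 1, 100, 1, 1, 1))
#' @export
hampel_filter <- function(x, k = 3L, t = 3) {
  n <- length(x)
  if (n < 2 * k + 1) return(x)
  out <- x
  for (i in seq_len(n)) {
    win <- x[max(1L, i - k):min(n, i + k)]
    med <- median(win)
    s <- 1.4826 * median(abs(win - med))
    if (abs(x[i] - med) > t * s) out[i] <- med
  }
  out
}

#' Z-score standardization of one test's feature rows
#'
#' Standardizes each feature to zero mean and unit population SD over all the
#' test's rows (the no-pain baseline period included), making sEMG activity
#' comparable within and between subjects. A zero-SD feature (flatlined
#' electrode) is set to 0 with a warning rather than propagating NaN.
#'
#' @param rows A data frame of one test's 1-Hz rows containing the ten
#'   feature columns.
#' @param feature_cols Feature column names (default the ten standard ones
#'   present in `rows`).
#' @return A list with `rows` (standardized), and per-feature `center` and
#'   `scale` (population SD) vectors.
#' @export
zscore_standardize <- function(rows, feature_cols = intersect(FEATURES,
                                                              names(rows))) {
  stopifnot(nrow(rows) >= 2, length(feature_cols) >= 1)
  center <- scale <- setNames(numeric(length(feature_cols)), feature_cols)
  for (f in feature_cols) {
    x <- rows[[f]]
    mu <- mean(x)
    sg <- sqrt(mean((x - mu)^2))
    center[f] <- mu
    scale[f] <- sg
    if (sg == 0) {
      warning("feature ", f, " has zero variance in this test; set to 0")
      rows[[f]] <- rep(0, length(x))
    } else {
      rows[[f]] <- (x - mu) / sg
    }
  }
  list(rows = rows, center = center, scale = scale)
}

#' Preprocess the raw channels of one test
#'
#' High-pass filters all six channels, then removes reference-correlated
#' interference from each muscle channel by NLMS adaptive noise cancellation
#' against the high-pass filtered frontalis reference.
#'
#' @param test A `raw_test` from [simulate_test()] (or any list with `fs` and
#'   a `channels` matrix holding the six named columns).
#' @param prep A [prep_config()].
#' @return Matrix of the five cleaned muscle channels.
#' @export
preprocess_test <- function(test, prep = prep_config()) {
  ch <- test$channels
  fs <- test$fs
  ref <- highpass_filter(ch[, "frontalis_ref"], fs, prep$hp_cutoff_hz,
                         prep$hp_order)
  out <- matrix(0, nrow(ch), length(MUSCLES),
                dimnames = list(NULL, MUSCLES))
  for (m in MUSCLES) {
    hp <- highpass_filter(ch[, m], fs, prep$hp_cutoff_hz, prep$hp_order)
    out[, m] <- adaptive_noise_cancel(hp, ref, prep$anc_step, prep$anc_len)
  }
  out
}

# Hampel across the ten feature columns of one test's rows.
hampel_rows <- function(rows, k, t) {
  for (f in intersect(FEATURES, names(rows)))
    rows[[f]] <- hampel_filter(rows[[f]], k, t)
  rows
}

#' Compute unstandardized 1-Hz features for a whole cohort (streaming)
#'
#' Runs simulate -> preprocess -> feature extraction -> Hampel test by test,
#' discarding each raw signal once its 1-Hz rows are extracted, so the
#' default 120-test cohort never holds more than one raw recording in memory.
#'
#' @param config A [cohort_config()].
#' @param prep A [prep_config()].
#' @return A list with `features` (tibble: `subject_id`, `test_id`,
#'   `stimulus_type`, `time_s`, ten unstandardized feature columns),
#'   `manifest`, `profiles` and `config`.
#' @export
cohort_features <- function(config = cohort_config(), prep = prep_config()) {
  sch <- cohort_schedule(config)
  rows <- lapply(which(sch$manifest$included), function(i) {
    meta <- sch$manifest[i, ]
    prof <- sch$profiles[sch$profiles$subject_id == meta$subject_id, ]
    test <- simulate_test(meta, prof, config)
    feats <- extract_features(preprocess_test(test, prep), test$fs)
    feats <- hampel_rows(feats, prep$hampel_k, prep$hampel_t)
    feats$subject_id <- meta$subject_id
    feats$test_id <- meta$test_id
    feats$stimulus_type <- meta$stimulus_type
    dplyr::relocate(feats, "subject_id", "test_id", "stimulus_type")
  })
  list(features = dplyr::bind_rows(rows), manifest = sch$manifest,
       profiles = sch$profiles, config = config)
}
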