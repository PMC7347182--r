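# Synthetic cohort generation: schedules, subject profiles and raw signals.

#' Sample test durations for one stimulus type
#'
#' Draws `(t2 - t1, t3 - t2)` pairs from the configured truncated normal
#' distributions. Truncation at `duration_params$floor_s` guarantees each of
#' the four pain periods spans at least `floor_s / 2` seconds. A zero SD
#' yields the (floored) mean deterministically.
#'
#' @param stimulus_type `"heat"` or `"electrical"`.
#' @param duration_params See [default_duration_params()].
#' @param n Number of pairs to draw.
#' @return A data frame with columns `threshold_s` (t2 - t1) and
#'   `tolerance_s` (t3 - t2).
#' @examples
#' set.seed(1)
#' sample_test_durations("heat", default_duration_params(), n = 3)
#' @export
sample_test_durations <- function(stimulus_type = c("heat", "electrical"),
                                  duration_params = default_duration_params(),
                                  n = 1L) {
  stimulus_type <- match.arg(stimulus_type)
  p <- duration_params[[stimulus_type]]
  floor_s <- duration_params$floor_s
  data.frame(
    threshold_s = rtruncnorm(n, p$threshold[["mean"]], p$threshold[["sd"]],
                             floor_s),
    tolerance_s = rtruncnorm(n, p$tolerance[["mean"]], p$tolerance[["sd"]],
                             floor_s)
  )
}

# Truncated-below normal draws via inverse CDF; sd = 0 collapses to the
# floored mean (point mass).
rtruncnorm <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(max(mean, lower), n))
  p0 <- pnorm(lower, mean, sd)
  if (p0 > 1 - 1e-12) return(rep(lower, n))
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

#' Draw the cohort schedule: subjects, tests, timestamps
#'
#' Samples subject expressiveness profiles and per-test metadata (stimulus
#' type, side, event timestamps t1/t2/t3, per-test simulation sub-seed) and
#' marks the randomly excluded tests. All signal synthesis randomness is
#' derived from the per-test sub-seeds, so schedules and signals are fully
#' reproducible from `config$seed` and a cohort can be materialized test by
#' test without holding raw signals in memory.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort_schedule` with elements `manifest`
#'   (a tibble; one row per test including excluded ones, flagged by
#'   `included`), `profiles` (per-subject expressiveness and per-muscle
#'   gains) and `config`.
#' @export
cohort_schedule <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  ns <- config$n_subjects
  tps <- config$tests_per_subject
  ep <- config$envelope_params

  subject_id <- sprintf("S%02d", seq_len(ns))
  expressiveness <- exp(rnorm(ns, -ep$expressiveness_sdlog^2 / 2,
                              ep$expressiveness_sdlog))
  low <- runif(ns) < config$responder_mix$low_fraction
  expressiveness[low] <- expressiveness[low] * config$responder_mix$low_scale
  gains <- outer(expressiveness, ep$base_gain * ep$gain_scale)
  colnames(gains) <- paste0("gain_", MUSCLES)
  profiles <- tibble::tibble(
    subject_id = subject_id,
    responder_class = ifelse(low, "low_expressive", "expressive"),
    expressiveness = expressiveness
  )
  profiles <- dplyr::bind_cols(profiles, tibble::as_tibble(gains))

  # alternating so that truncated designs (tests_per_subject < 4) still
  # cover both stimulus types; the full design is two heat + two electrical
  stim_order <- c("heat", "electrical", "heat", "electrical")[seq_len(tps)]
  side_order <- c("left", "left", "right", "right")[seq_len(tps)]
  manifest <- tidyr::expand_grid(subject_id = subject_id,
                                 test_no = seq_len(tps))
  manifest$stimulus_type <- stim_order[manifest$test_no]
  manifest$side <- side_order[manifest$test_no]
  manifest$test_id <- sprintf("%s_T%d", manifest$subject_id, manifest$test_no)

  dur <- lapply(seq_len(nrow(manifest)), function(i)
    sample_test_durations(manifest$stimulus_type[i], config$duration_params, 1L))
  dur <- do.call(rbind, dur)
  manifest$t1 <- config$baseline_lead_s
  manifest$t2 <- manifest$t1 + dur$threshold_s
  manifest$t3 <- manifest$t2 + dur$tolerance_s
  manifest$duration_s <- manifest$t3 - manifest$t1
  manifest$sim_seed <- sample.int(.Machine$integer.max - 1L, nrow(manifest))
  manifest$included <- TRUE
  if (config$n_excluded_tests > 0L) {
    excl <- sample.int(nrow(manifest), config$n_excluded_tests)
    manifest$included[excl] <- FALSE
  }

  structure(list(manifest = manifest, profiles = profiles, config = config),
            class = "cohort_schedule")
}

# Band-limited unit-variance Gaussian noise, synthesized in the frequency
# domain: independent complex-Gaussian spectrum on the passband bins
# (Hermitian-symmetric), one inverse FFT at the next highly-composite length
# (fast mixed-radix FFT), then truncation - harmless for stationary noise.
band_noise <- function(n, fs, band) {
  m <- stats::nextn(n)
  half <- floor(m / 2)
  fr <- (1:half) * fs / m
  keep <- which(fr >= band[1] & fr <= band[2] & (1:half) < (m + 1) / 2)
  xf <- complex(length.out = m)
  z <- complex(real = rnorm(length(keep)), imaginary = rnorm(length(keep)))
  xf[keep + 1] <- z
  xf[m + 1 - keep] <- Conj(z)
  y <- Re(fft(xf, inverse = TRUE))[seq_len(n)]
  s <- sd(y)
  if (s > 0) y / s else y
}

# Piecewise-linear pain-response shapes, clamped to [0, 1].
envelope_shape <- function(tt, muscle, t1, t2, t3) {
  if (muscle == "cor") {
    pmin(pmax((tt - t1) / (t3 - t1), 0), 1)
  } else {
    pmin(pmax((tt - t2) / (t3 - t2), 0), 1)
  }
}

#' Synthesize the six raw channels of one test
#'
#' Builds the five muscle channels plus the frontalis reference as
#' amplitude-modulated band-limited Gaussian noise. Each muscle carries the
#' envelope `noise_floor * (1 + g_m * f_m(t) + talking)`, an
#' activation-dependent low/high band carrier mixture (the spectral shift that
#' makes waveform length more informative than RMS), shared 50-Hz mains
#' interference, slow baseline drift, sparse spike artifacts and - for
#' electrical tests - the TENS pulse-artifact train. The frontalis reference
#' carries the shared interference and pulse train plus its own EMG noise but
#' no pain-modulated envelope. Draws come from the current R RNG state; seed
#' beforehand for reproducibility (as [simulate_test()] does).
#'
#' @param profile A one-row slice of the schedule's `profiles` table (or any
#'   list with `gain_cor` ... `gain_ris`).
#' @param stimulus_type `"heat"` or `"electrical"`.
#' @param t1,t2,t3 Event times in seconds from recording start
#'   (`t1 < t2 < t3`).
#' @param noise_params See [default_noise_params()].
#' @param envelope_params See [default_envelope_params()]; only the spectral
#'   shift and talking parameters are read here (gains live in `profile`).
#' @param fs Sampling rate in Hz.
#' @param n_samples Total number of samples to generate.
#' @return A numeric matrix with columns `cor, orb, lev, zyg, ris,
#'   frontalis_ref`. The true per-second mean envelope of each muscle is
#'   attached as attribute `"envelope_1hz"`.
#' @export
synthesize_channels <- function(profile, stimulus_type, t1, t2, t3,
                                noise_params = default_noise_params(),
                                envelope_params = default_envelope_params(),
                                fs = 1000, n_samples = ceiling((t3 + 2) * fs)) {
  stopifnot(t1 < t2, t2 < t3)
  np <- noise_params
  ep <- envelope_params
  n <- as.integer(n_samples)
  tt <- (seq_len(n) - 1) / fs
  lo_band <- c(np$carrier_band[1], np$carrier_split_hz)
  hi_band <- c(np$carrier_split_hz, np$carrier_band[2])

  # Talking bursts before stimulus start, gating the lower-face channels.
  talk_sec <- runif(max(floor(t1), 0)) < ep$talk_prob
  talk <- numeric(n)
  if (any(talk_sec)) {
    sec_idx <- pmin(floor(tt) + 1, length(talk_sec))
    talk[tt < t1] <- as.numeric(talk_sec[sec_idx[tt < t1]])
  }

  # Shared deterministic interference components.
  mains <- sin(2 * pi * np$mains_hz * tt + runif(1, 0, 2 * pi))
  pulse <- numeric(n)
  if (identical(stimulus_type, "electrical") && np$pulse_amp > 0) {
    active <- tt >= t1 & tt <= t3
    phase <- (tt - t1) %% np$pulse_period_s
    level <- floor((tt - t1) / np$pulse_period_s)
    burst <- active & phase < np$pulse_burst_s
    pulse[burst] <- np$pulse_amp * (1 + 0.15 * level[burst]) *
      sin(2 * pi * np$pulse_hz * tt[burst])
  }

  nw <- floor(n / fs)
  env_1hz <- matrix(NA_real_, nw, length(MUSCLES),
                    dimnames = list(NULL, MUSCLES))
  out <- matrix(0, n, length(MUSCLES) + 1L,
                dimnames = list(NULL, c(MUSCLES, "frontalis_ref")))

  for (m in MUSCLES) {
    g <- profile[[paste0("gain_", m)]]
    f <- envelope_shape(tt, m, t1, t2, t3)
    u <- expression_fluctuation(tt, ep$fluct_sdlog, ep$fluct_tau_s)
    a <- np$noise_floor * (1 + g * f * u)
    if (m %in% c("lev", "zyg", "ris")) a <- a + np$noise_floor * ep$talk_amp * talk
    lambda <- pmin(0.9, ep$spectral_shift_base + ep$spectral_shift_gain * g * f)
    w_lo <- band_noise(n, fs, lo_band)
    w_hi <- band_noise(n, fs, hi_band)
    x <- a * (sqrt(1 - lambda) * w_lo + sqrt(lambda) * w_hi)
    x <- x + runif(1, 0.8, 1.2) * np$mains_amp * mains
    x <- x + slow_drift(tt, np$drift_amp)
    x <- x + runif(1, 0.6, 1.0) * pulse
    x <- add_spikes(x, fs, np$spike_rate, np$spike_amp * np$noise_floor)
    out[, m] <- x
    if (nw > 0)
      env_1hz[, m] <- colMeans(matrix(a[seq_len(nw * fs)], nrow = fs))
  }

  ref <- np$ref_noise_sd * band_noise(n, fs, np$carrier_band) +
    runif(1, 0.8, 1.2) * np$mains_amp * mains +
    slow_drift(tt, np$drift_amp) + pulse
  out[, "frontalis_ref"] <- ref
  attr(out, "envelope_1hz") <- env_1hz
  out
}

# Slow mean-one log-normal expression fluctuation: an Ornstein-Uhlenbeck
# process sampled per second (correlation time tau_s), exponentiated with
# mean correction and linearly interpolated to the sample grid. Models the
# episodic flare/relax dynamics of voluntary facial expression.
expression_fluctuation <- function(tt, sdlog, tau_s) {
  if (sdlog <= 0) return(rep(1, length(tt)))
  n_sec <- ceiling(max(tt)) + 1L
  phi <- exp(-1 / tau_s)
  z <- numeric(n_sec)
  z[1] <- rnorm(1)
  innov <- rnorm(n_sec - 1L)
  for (i in seq_len(n_sec - 1L))
    z[i + 1L] <- phi * z[i] + sqrt(1 - phi^2) * innov[i]
  u_sec <- exp(sdlog * z - sdlog^2 / 2)
  stats::approx(x = seq_len(n_sec) - 1, y = u_sec, xout = tt, rule = 2)$y
}

# Two slow random sinusoids well below the high-pass cutoff.
slow_drift <- function(tt, amp) {
  if (amp <= 0) return(numeric(length(tt)))
  f <- runif(2, 0.05, 0.3)
  a <- amp * runif(2, 0.5, 1)
  ph <- runif(2, 0, 2 * pi)
  a[1] * sin(2 * pi * f[1] * tt + ph[1]) + a[2] * sin(2 * pi * f[2] * tt + ph[2])
}

# Sparse biphasic high-amplitude spikes at a Poisson rate per second.
add_spikes <- function(x, fs, rate, amp) {
  if (rate <= 0 || amp <= 0) return(x)
  n_spk <- rpois(1, rate * length(x) / fs)
  if (n_spk == 0) return(x)
  pos <- sample.int(length(x) - 3L, n_spk)
  mag <- amp * runif(n_spk, 0.75, 1.5) * sample(c(-1, 1), n_spk, replace = TRUE)
  shape <- c(0.5, 1, -0.7)
  for (i in seq_len(n_spk))
    x[pos[i] + 0:2] <- x[pos[i] + 0:2] + mag[i] * shape
  x
}

#' Simulate one raw test from its schedule entry
#'
#' Seeds the RNG with the test's schedule-drawn sub-seed, draws the per-test
#' gain jitter and synthesizes the six channels.
#'
#' @param meta A one-row manifest slice from [cohort_schedule()].
#' @param profile The matching one-row `profiles` slice.
#' @param config The [cohort_config()].
#' @return A `raw_test` object: a list with the test metadata, `fs`,
#'   `t1`/`t2`/`t3` and the channel matrix.
#' @export
simulate_test <- function(meta, profile, config) {
  set.seed(meta$sim_seed)
  ep <- config$envelope_params
  jit <- exp(rnorm(1, -ep$test_gain_sdlog^2 / 2, ep$test_gain_sdlog))
  prof <- as.list(profile)
  for (m in MUSCLES) prof[[paste0("gain_", m)]] <- prof[[paste0("gain_", m)]] * jit
  fs <- config$sampling_rate
  channels <- synthesize_channels(
    prof, meta$stimulus_type, meta$t1, meta$t2, meta$t3,
    noise_params = config$noise_params, envelope_params = ep,
    fs = fs, n_samples = ceiling((meta$t3 + config$tail_s) * fs)
  )
  structure(list(subject_id = meta$subject_id, test_id = meta$test_id,
                 stimulus_type = meta$stimulus_type, side = meta$side,
                 fs = fs, t1 = meta$t1, t2 = meta$t2, t3 = meta$t3,
                 channels = channels),
            class = "raw_test")
}

#' @export
print.raw_test <- function(x, ...) {
  cat(sprintf("<raw_test %s: %s/%s, %.1f s at %g Hz, t1=%g t2=%.1f t3=%.1f>\n",
              x$test_id, x$stimulus_type, x$side,
              nrow(x$channels) / x$fs, x$fs, x$t1, x$t2, x$t3))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Materializes every included test of the schedule as a [simulate_test()]
#' `raw_test`. For the default configuration this holds about 1 GB of raw
#' signal; prefer the streaming [cohort_features()] when only the 1-Hz
#' features are needed.
#'
#' @param config A [cohort_config()].
#' @return A list of class `semg_cohort` with `tests` (list of `raw_test`,
#'   included tests only), `manifest`, `profiles` and `config`.
#' @examples
#' cfg <- cohort_config(n_subjects = 2, tests_per_subject = 1,
#'                      n_excluded_tests = 0, seed = 7)
#' cohort <- generate_cohort(cfg)
#' length(cohort$tests)
#' @export
generate_cohort <- function(config = cohort_config()) {
  sch <- cohort_schedule(config)
  keep <- which(sch$manifest$included)
  tests <- lapply(keep, function(i) {
    meta <- sch$manifest[i, ]
    prof <- sch$profiles[sch$profiles$subject_id == meta$subject_id, ]
    simulate_test(meta, prof, config)
  })
  structure(list(tests = tests, manifest = sch$manifest,
                 profiles = sch$profiles, config = config),
            class = "semg_cohort")
}

#' @export
print.semg_cohort <- function(x, ...) {
  cat(sprintf("<semg_cohort: %d analyzed tests, %d subjects, seed %d>\n",
              length(x$tests), x$config$n_subjects, x$config$seed))
  invisible(x)
}

#' Write a cohort to delimited text files
#'
#' One CSV per test (`time_s` plus the six channels), a `manifest.csv`
#' listing every test with its metadata and timestamps, and a JSON echo of
#' the configuration including the seed.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest with a `file` column.
#' @export
write_cohort <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sch <- cohort_schedule(config)
  manifest <- sch$manifest
  manifest$file <- ifelse(manifest$included,
                          file.path(dir, paste0(manifest$test_id, ".csv")),
                          NA_character_)
  for (i in which(manifest$included)) {
    meta <- manifest[i, ]
    prof <- sch$profiles[sch$profiles$subject_id == meta$subject_id, ]
    test <- simulate_test(meta, prof, config)
    df <- data.frame(time_s = (seq_len(nrow(test$channels)) - 1) / test$fs,
                     signif(test$channels, 7))
    write.csv(df, meta$file, row.names = FALSE)
  }
  write.csv(manifest[, c("subject_id", "test_id", "stimulus_type", "side",
                         "t1", "t2", "t3", "included", "file")],
            file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(config_echo(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

config_echo <- function(config) {
  unclass(config)
}
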