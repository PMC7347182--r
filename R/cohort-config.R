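#' Default per-stimulus test duration distributions
#'
#' Durations are drawn from truncated normal distributions, one pair per
#' stimulus type: `threshold` is the time from stimulus start to the
#' self-reported pain threshold (t2 - t1) and `tolerance` the time from
#' threshold to tolerance (t3 - t2), both in seconds. Heat ramps are slower
#' than the stepped electrical stimulation, so heat tests run longer. The
#' default means/SDs are calibrated so that a default cohort of 120 analyzed
#' tests has mean total duration close to 110 s with SD close to 42 s.
#' Both components are truncated below at `floor_s` (default 8 s) so every
#' pain period spans at least two 1-s feature samples.
#'
#' @return A list with elements `heat`, `electrical` (each a list of
#'   `threshold` and `tolerance`, named numeric vectors with `mean` and `sd`)
#'   and the scalar `floor_s`.
#' @export
default_duration_params <- function() {
  list(
    heat = list(threshold = c(mean = 70, sd = 38),
                tolerance = c(mean = 40, sd = 32)),
    electrical = list(threshold = c(mean = 48, sd = 28),
                      tolerance = c(mean = 36, sd = 28)),
    floor_s = 8
  )
}

#' Default pain-response envelope parameters
#'
#' The muscle activity model is band-limited Gaussian noise multiplied by a
#' time-varying envelope `a_m(t) = noise_floor * (1 + g_{s,m} * f_m(t))`.
#' The corrugator shape `f_cor` ramps linearly from 0 at stimulus start (t1)
#' to 1 at pain tolerance (t3); all other muscles stay near baseline until the
#' pain threshold (t2) and then ramp to 1 at t3. Per-muscle base gains encode
#' the corrugator-dominant response; a per-subject log-normal expressiveness
#' multiplier (plus a low-expressive mixture, see [cohort_config()]) and a
#' mild per-test jitter spread the gains across the cohort.
#'
#' `spectral_shift_base`/`spectral_shift_gain` control the fraction of
#' high-band carrier power, which grows with activation: contracting muscle
#' shifts sEMG power upwards in frequency, so waveform length (amplitude x
#' mean frequency) carries more pain information than RMS (amplitude only).
#'
#' Facial pain expression is episodic rather than a smooth ramp, so the pain
#' component of each envelope is multiplied by a slow mean-one log-normal
#' fluctuation process (`fluct_sdlog` log-scale SD, Ornstein-Uhlenbeck
#' correlation time `fluct_tau_s` seconds): muscles intermittently relax and
#' flare even as the stimulus grows, which is what keeps the period labels
#' only partially predictable from the features. `talk_amp`/`talk_prob`
#' shape the talking bursts that inflate the lower-face channels during the
#' pre-stimulus baseline.
#'
#' @return Named list of envelope parameters.
#' @export
default_envelope_params <- function() {
  list(
    base_gain = c(cor = 1.00, orb = 0.45, lev = 0.55, zyg = 0.25, ris = 0.30),
    gain_scale = 0.045,
    expressiveness_sdlog = 0.9,
    test_gain_sdlog = 0.2,
    spectral_shift_base = 0.15,
    spectral_shift_gain = 0.55,
    fluct_sdlog = 1.25,
    fluct_tau_s = 10,
    talk_amp = 1.2,
    talk_prob = 0.35
  )
}

#' Default artifact and noise parameters
#'
#' Controls every non-muscular signal component: the baseline carrier
#' amplitude (`noise_floor`, arbitrary amplifier units), the frontalis
#' reference channel's own EMG noise (`ref_noise_sd`), shared 50-Hz power-line
#' interference, slow baseline drift, sparse high-amplitude spike artifacts
#' (Poisson rate per second, magnitude in multiples of `noise_floor`), and the
#' electrical-stimulation pulse artifact: 100-Hz bursts recurring every 3 s
#' with stepwise-increasing amplitude, mirroring a TENS program whose level is
#' raised every three seconds. Pulse artifacts are injected coherently into
#' the frontalis reference so adaptive noise cancellation can remove them.
#' `carrier_band` (Hz) is the EMG carrier bandwidth, split at
#' `carrier_split_hz` into the low/high bands used for the activation-
#' dependent spectral shift.
#'
#' @return Named list of noise parameters.
#' @export
default_noise_params <- function() {
  list(
    noise_floor = 1.0,
    ref_noise_sd = 0.8,
    mains_hz = 50, mains_amp = 0.5,
    drift_amp = 0.3,
    spike_rate = 0.02, spike_amp = 8,
    pulse_amp = 1.5, pulse_period_s = 3, pulse_burst_s = 0.3, pulse_hz = 100,
    carrier_band = c(20, 450),
    carrier_split_hz = 150
  )
}

#' Synthetic cohort configuration
#'
#' Assembles and validates the configuration that fully determines a synthetic
#' facial sEMG cohort. Together with `seed` it fixes every random draw, so two
#' calls of [generate_cohort()] with the same configuration are identical.
#'
#' @param n_subjects Number of subjects (default 31).
#' @param tests_per_subject Tests per subject, up to 4 (two heat then two
#'   electrical, alternating left/right sides).
#' @param n_excluded_tests Number of tests removed at random from the cohort
#'   (default 4, emulating technical exclusions), leaving
#'   `n_subjects * tests_per_subject - n_excluded_tests` analyzed tests.
#' @param sampling_rate Sampling rate in Hz (default 1000). Must exceed twice
#'   the highest deterministic interference frequency and twice the upper
#'   carrier band edge.
#' @param baseline_lead_s Seconds of pre-stimulus recording before t1; must be
#'   at least 30 so the baseline period P0 = \[t1 - 30, t1) is fully recorded.
#' @param duration_params Per-stimulus duration distributions, see
#'   [default_duration_params()].
#' @param envelope_params Pain-response envelope model, see
#'   [default_envelope_params()].
#' @param responder_mix List with `low_fraction` (probability that a subject
#'   is low-expressive) and `low_scale` (gain multiplier for that class).
#' @param noise_params Artifact/noise model, see [default_noise_params()].
#' @param tail_s Seconds of recording kept after t3.
#' @param seed Integer seed controlling all cohort randomness.
#'
#' @return An object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_subjects = 2, tests_per_subject = 1,
#'                      n_excluded_tests = 0)
#' @export
cohort_config <- function(n_subjects = 31L,
                          tests_per_subject = 4L,
                          n_excluded_tests = 4L,
                          sampling_rate = 1000,
                          baseline_lead_s = 35,
                          duration_params = default_duration_params(),
                          envelope_params = default_envelope_params(),
                          responder_mix = list(low_fraction = 0.2,
                                               low_scale = 0.25),
                          noise_params = default_noise_params(),
                          tail_s = 2,
                          seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    tests_per_subject = as.integer(tests_per_subject),
    n_excluded_tests = as.integer(n_excluded_tests),
    sampling_rate = sampling_rate,
    baseline_lead_s = baseline_lead_s,
    duration_params = duration_params,
    envelope_params = envelope_params,
    responder_mix = responder_mix,
    noise_params = noise_params,
    tail_s = tail_s,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1L,
            cfg$tests_per_subject >= 1L, cfg$tests_per_subject <= 4L)
  n_total <- cfg$n_subjects * cfg$tests_per_subject
  if (cfg$n_excluded_tests < 0L || cfg$n_excluded_tests >= n_total)
    stop("n_excluded_tests must lie in [0, n_subjects * tests_per_subject)")
  if (cfg$baseline_lead_s < 30)
    stop("baseline_lead_s must be >= 30 so that P0 is fully recorded")
  dp <- cfg$duration_params
  for (stim in c("heat", "electrical")) {
    for (part in c("threshold", "tolerance")) {
      p <- dp[[stim]][[part]]
      if (!is.numeric(p) || p[["mean"]] <= 0 || p[["sd"]] < 0)
        stop("duration_params$", stim, "$", part,
             ": mean must be positive and sd nonnegative")
    }
  }
  if (dp$floor_s <= 0) stop("duration_params$floor_s must be positive")
  np <- cfg$noise_params
  if (any(np$carrier_band <= 0) || diff(np$carrier_band) <= 0)
    stop("carrier_band must be an increasing positive pair of frequencies")
  f_max <- max(np$mains_hz, np$pulse_hz)
  if (cfg$sampling_rate <= 2 * f_max)
    stop("sampling_rate must exceed twice the highest interference frequency (",
         f_max, " Hz)")
  if (np$carrier_band[2] >= cfg$sampling_rate / 2)
    stop("upper carrier band edge must be below the Nyquist frequency")
  if (np$carrier_split_hz <= np$carrier_band[1] ||
      np$carrier_split_hz >= np$carrier_band[2])
    stop("carrier_split_hz must lie inside carrier_band")
  ep <- cfg$envelope_params
  if (any(ep$base_gain < 0) || ep$gain_scale < 0)
    stop("envelope gains must be nonnegative")
  if (is.null(names(ep$base_gain)) || !setequal(names(ep$base_gain), MUSCLES))
    stop("base_gain must be named with the five muscles: ",
         paste(MUSCLES, collapse = ", "))
  rm_ <- cfg$responder_mix
  if (rm_$low_fraction < 0 || rm_$low_fraction > 1 || rm_$low_scale < 0 ||
      rm_$low_scale > 1)
    stop("responder_mix: low_fraction in [0,1], low_scale in [0,1] required")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d subjects x %d tests, %d excluded (seed %d)\n",
              x$n_subjects, x$tests_per_subject, x$n_excluded_tests, x$seed))
  cat(sprintf("  fs = %g Hz, baseline lead %g s, gain scale %g\n",
              x$sampling_rate, x$baseline_lead_s,
              x$envelope_params$gain_scale))
  invisible(x)
}
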