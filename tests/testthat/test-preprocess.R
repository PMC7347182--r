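# Preprocessing chain: filters, features, Hampel, standardization.

tone <- function(freq, fs, dur) sin(2 * pi * freq * (0:(fs * dur - 1)) / fs)

mid <- function(x, drop = 1000) x[(drop + 1):(length(x) - drop)]

test_that("high-pass filter rejects DC and drift, preserves the EMG band", {
  fs <- 1000
  out <- highpass_filter(rep(5, 4000), fs)
  expect_lt(max(abs(mid(out, 500))), 1e-6 * 5)

  x100 <- tone(100, fs, 4)
  out <- highpass_filter(x100, fs)
  amp <- sqrt(2) * sqrt(mean(mid(out, 500)^2))
  expect_lt(abs(amp - 1), 0.01)

  x2 <- tone(2, fs, 6)
  out <- highpass_filter(x2, fs)
  amp <- sqrt(2) * sqrt(mean(mid(out, 1000)^2))
  expect_lt(20 * log10(amp / 1), -30)

  expect_error(highpass_filter(rnorm(10), fs), "too short")
  expect_error(highpass_filter(rnorm(1000), fs = 30, cutoff_hz = 20),
               "twice the cutoff")
})

test_that("adaptive noise cancellation removes only reference-correlated power", {
  fs <- 1000
  set.seed(31)
  n <- 20000
  clean <- rnorm(n)
  ref_indep <- rnorm(n)
  out <- adaptive_noise_cancel(clean, ref_indep)
  half <- (n / 2):n
  expect_lt(abs(mean(out[half]^2) / mean(clean[half]^2) - 1), 0.10)

  # shared 50-Hz interference, delayed and scaled in the primary channel
  ref <- 2 * tone(50, fs, n / fs) + 0.3 * rnorm(n)
  interf <- 0.8 * c(rep(0, 3), ref[1:(n - 3)])
  primary <- clean + interf
  out <- adaptive_noise_cancel(primary, ref)
  goertzel <- function(x) abs(sum(x * exp(-2i * pi * 50 *
                                            seq_along(x) / fs)))
  before <- goertzel(primary[half])
  after <- goertzel(out[half])
  expect_lt(20 * log10(after / before), -10)

  expect_warning(out <- adaptive_noise_cancel(clean, rep(0, n)),
                 "zero-variance")
  expect_identical(out, clean)
})

test_that("pulse-artifact bursts shared with the reference are attenuated", {
  fs <- 1000
  set.seed(32)
  n <- 30000
  tt <- (0:(n - 1)) / fs
  burst <- (tt %% 3) < 0.3
  pulse <- ifelse(burst, sin(2 * pi * 100 * tt), 0)
  primary <- rnorm(n) + 0.8 * pulse
  ref <- 0.5 * rnorm(n) + pulse
  out <- adaptive_noise_cancel(primary, ref)
  late <- tt > 15
  rms_before <- sqrt(mean(primary[late & burst]^2))
  rms_after <- sqrt(mean(out[late & burst]^2))
  expect_lt(rms_after, rms_before)
})

test_that("RMS and WL compute their closed forms", {
  expect_equal(rms_feature(c(0, 0, 0, 0)), 0)
  expect_equal(rms_feature(c(3, 4)), sqrt(25 / 2))
  expect_equal(rms_feature(rep(-2.5, 7)), 2.5)
  expect_error(rms_feature(numeric(0)), "non-empty")

  expect_equal(wl_feature(c(5, 5, 5)), 0)
  expect_equal(wl_feature(c(0, 1, 0, 1)), 3)
  expect_equal(wl_feature(c(1, 3, 2, 5)), 6)
  expect_error(wl_feature(5), "at least 2")

  # sign-flip invariance; WL shift invariance
  set.seed(41)
  w <- rnorm(50)
  expect_equal(rms_feature(-w), rms_feature(w))
  expect_equal(wl_feature(-w), wl_feature(w))
  expect_equal(wl_feature(w + 7), wl_feature(w))
})

test_that("feature extraction windows the signal exactly", {
  fs <- 1000
  ch <- matrix(rnorm(10700 * 5), ncol = 5,
               dimnames = list(NULL, semgpain:::MUSCLES))
  f <- extract_features(ch, fs)
  expect_equal(nrow(f), 10) # trailing 0.7 s dropped
  expect_equal(f$time_s, 0:9)

  sq <- rep_len(c(1, -1), 5000)
  ch <- matrix(rep(sq, 5), ncol = 5,
               dimnames = list(NULL, semgpain:::MUSCLES))
  f <- extract_features(ch, fs)
  expect_true(all(f$corrms == 1))
  expect_true(all(f$zygwl == 2 * (fs - 1)))

  set.seed(42)
  x <- 2 * rnorm(100 * fs)
  ch <- matrix(rep(x, 5), ncol = 5,
               dimnames = list(NULL, semgpain:::MUSCLES))
  f <- extract_features(ch, fs)
  se_mean <- 2 / sqrt(2 * fs) / sqrt(100)
  expect_lt(abs(mean(f$corrms) - 2), 3 * se_mean)
})

test_that("time reversal reverses the feature rows", {
  fs <- 200
  set.seed(43)
  x <- rnorm(10 * fs)
  ch <- matrix(rep(x, 5), ncol = 5,
               dimnames = list(NULL, semgpain:::MUSCLES))
  chr <- matrix(rep(rev(x), 5), ncol = 5,
                dimnames = list(NULL, semgpain:::MUSCLES))
  f <- extract_features(ch, fs)
  fr <- extract_features(chr, fs)
  expect_equal(fr$corrms, rev(f$corrms))
  expect_equal(fr$corwl, rev(f$corwl))
})

test_that("Hampel filter replaces outliers and matches the sliding oracle", {
  expect_equal(hampel_filter(c(1, 1, 1, 100, 1, 1, 1)), rep(1, 7))
  expect_equal(hampel_filter(as.numeric(1:20)), as.numeric(1:20))
  expect_equal(hampel_filter(rep(3, 9)), rep(3, 9))
  expect_equal(hampel_filter(c(1, 50, 2)), c(1, 50, 2)) # shorter than 2K+1

  set.seed(44)
  for (rep_i in 1:20) {
    x <- rnorm(40)
    x[sample(40, 3)] <- x[sample(40, 3)] + sample(c(-1, 1), 3, TRUE) * 20
    expect_equal(hampel_filter(x), hampel_oracle(x))
  }
})

test_that("z-scoring standardizes per test with population SD", {
  rows <- tibble::tibble(corrms = c(2, 4, 6))
  z <- zscore_standardize(rows, "corrms")
  expect_equal(z$rows$corrms, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(unname(z$scale["corrms"]), sqrt(8 / 3))

  # idempotence
  z2 <- zscore_standardize(z$rows, "corrms")
  expect_equal(z2$rows$corrms, z$rows$corrms, tolerance = 1e-12)

  # affine invariance (a > 0)
  rows2 <- tibble::tibble(corrms = 3.7 * c(2, 4, 6) - 11)
  z3 <- zscore_standardize(rows2, "corrms")
  expect_equal(z3$rows$corrms, z$rows$corrms, tolerance = 1e-12)

  rows3 <- tibble::tibble(corrms = rep(4, 5))
  expect_warning(z4 <- zscore_standardize(rows3, "corrms"), "zero variance")
  expect_equal(z4$rows$corrms, rep(0, 5))
})

test_that("Hampel must precede standardization on spiky series", {
  set.seed(45)
  x <- rnorm(50)
  x[25] <- 40
  rows <- tibble::tibble(corrms = x)
  pipeline_order <- zscore_standardize(
    tibble::tibble(corrms = hampel_filter(x)), "corrms")$rows$corrms
  swapped <- hampel_filter(
    zscore_standardize(rows, "corrms")$rows$corrms)
  expect_gt(max(abs(pipeline_order - swapped)), 0.01)
})
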