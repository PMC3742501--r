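# Spectral measurements: q50, peak frequency, Wiener entropy, measurement
# windows, full feature extraction, standardization and screening.

tone_wave <- function(freq, dur = 0.5, sr = 44100) {
  sin(2 * pi * freq * (seq_len(round(dur * sr)) - 1) / sr)
}

test_that("q50 follows the first-crossing rule on constructed spectra", {
  # equal energy in 4 bins: cumulative reaches half at the second bin
  expect_equal(q50_of_spectrum(c(1, 1, 1, 1)), 2)
  expect_equal(q50_of_spectrum(c(0, 0, 5, 0)), 3)
  # flat over N bins: within one bin of the midpoint
  n <- 64
  freq <- seq(0, 1000, length.out = n)
  expect_lt(abs(q50_of_spectrum(rep(1, n), freq) - 500),
            diff(freq)[1] + 1e-9)
  # brute-force cumulative-sum oracle on random spectra
  set.seed(1)
  for (i in 1:20) {
    amp <- runif(32)
    e <- amp^2
    oracle <- which(cumsum(e) >= sum(e) / 2)[1]
    expect_equal(q50_of_spectrum(amp), oracle)
  }
  expect_error(q50_of_spectrum(numeric(10)), "no energy")
})

test_that("q50 shifts by exactly m bins when the spectrum is translated", {
  set.seed(2)
  amp <- c(runif(24), rep(0, 8))
  for (m in c(1, 3, 5)) {
    shifted <- c(rep(0, m), amp[seq_len(32 - m)])
    expect_equal(q50_of_spectrum(shifted), q50_of_spectrum(amp) + m)
  }
})

test_that("peak frequency takes the lowest-frequency maximum", {
  expect_equal(peak_frequency(c(0, 7, 0)), 2)
  expect_equal(peak_frequency(c(0, 3, 0, 3)), 2)   # tie -> lower bin
  expect_error(peak_frequency(numeric(5)), "no energy")
})

test_that("wiener entropy is 1 on flat, 0 with a zero bin, bounded in [0,1]", {
  expect_equal(wiener_entropy(rep(3, 16)), 1)
  expect_equal(wiener_entropy(c(0, 10, 1, 1)), 0)
  set.seed(3)
  for (i in 1:25) {
    e <- wiener_entropy(runif(40) + 1e-6)
    expect_gte(e, 0); expect_lte(e, 1)
  }
})

test_that("pure tones localize to one 43 Hz bin; entropy orders noise > tone", {
  sr <- 44100
  params <- spectro_params(sr)
  bin <- params$bin_width
  for (f0 in c(1000, 2000, 5000)) {
    spec <- call_spectrum(tone_wave(f0), sr, 0, 0.5, params)
    expect_lt(abs(peak_frequency(spec) - f0), bin + 1e-9)
    expect_lt(abs(q50_of_spectrum(spec) - f0), bin + 1e-9)
  }
  set.seed(4)
  noise <- rnorm(22050); noise <- noise / sqrt(mean(noise^2))
  tone <- tone_wave(2000) / sqrt(mean(tone_wave(2000)^2))
  ent_noise <- wiener_entropy(call_spectrum(noise, sr, 0, 0.5, params))
  ent_tone <- wiener_entropy(call_spectrum(tone, sr, 0, 0.5, params))
  expect_gt(ent_noise, ent_tone)
  expect_lt(ent_tone, 0.1)
  # long white-noise call: spectrum approximately flat away from DC
  long_noise <- rnorm(sr * 2)
  sp <- call_spectrum(long_noise, sr, 0, 2, params)
  amp <- sp$amp[-(1:2)]
  expect_lt(sd(amp) / mean(amp), 0.25)
  # zero signal: all-zero spectrum is returned, downstream measures error
  sp0 <- call_spectrum(numeric(sr), sr, 0, 1, params)
  expect_true(all(sp0$amp == 0))
  expect_error(q50_of_spectrum(sp0), "no energy")
})

test_that("measurement windows follow the 11-window scheme keeping 9", {
  w <- measurement_windows(0, 1)
  expect_equal(w$index, 1:9)
  expect_equal(w$time, seq(0.1, 0.9, by = 0.1))
  w2 <- measurement_windows(2, 2.5)
  expect_equal(diff(w2$time), rep(0.05, 8))
  # retained offsets are symmetric about the call midpoint
  off <- w2$time - 2
  expect_equal(off + rev(off), rep(0.5, 9))
  expect_error(measurement_windows(0, 0.01), "analysis window")
})

test_that("feature extraction recovers controlled signal parameters", {
  sr <- 44100
  params <- spectro_params(sr)
  bin <- params$bin_width
  # constant 1000 Hz tone embedded in silence
  pad <- numeric(round(0.05 * sr))
  wave <- c(pad, tone_wave(1000, dur = 0.4), pad)
  f <- extract_features(wave, sr, 0.05, 0.45, params)
  expect_equal(f$dur, 0.4)
  for (v in c("q50", "q50start", "q50end", "q50min"))
    expect_lt(abs(f[[v]] - 1000), bin + 1e-9)
  expect_equal(f$q50maxloc, 1)      # all windows tie -> earliest
  # upward sweep: end above start, maximum at the last window
  proto <- list(label = "sweep", f_start = 800, f_end = 3000,
                tonal_fraction = 1, dur_mean = 0.4)
  w <- synth_call_wave(proto, sr, seed = 6)
  fs <- extract_features(w$wave, sr, w$start, w$end, params)
  expect_gt(fs$q50end, fs$q50start)
  expect_equal(fs$q50maxloc, 9)
  expect_lte(fs$q50min, min(fs$q50start, fs$q50end))
})

test_that("sweep direction is recovered in nearly all synthetic calls", {
  sr <- 44100
  params <- spectro_params(sr)
  ok <- 0L
  n <- 60L
  for (i in seq_len(n)) {
    up <- i %% 2 == 0
    proto <- list(f_start = if (up) 700 else 2600,
                  f_end = if (up) 2600 else 700,
                  tonal_fraction = 0.8, dur_mean = 0.25)
    w <- synth_call_wave(proto, sr, seed = 100 + i)
    f <- extract_features(w$wave, sr, w$start, w$end, params)
    if (sign(f$q50end - f$q50start) == (if (up) 1 else -1)) ok <- ok + 1L
  }
  expect_gte(ok / n, 0.99)
})

test_that("standardization is exact, idempotent and invertible", {
  # two points 1 unit either side of the mean, sample-sd convention:
  # sd = sqrt(2), so z = +/- 1/sqrt(2) and var(z) = 1 exactly
  expect_equal(as.vector(standardize_features(cbind(v = c(1, 3)))$z),
               c(-1, 1) / sqrt(2))
  set.seed(7)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  sc <- standardize_features(x)
  expect_equal(unname(colMeans(sc$z)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(sc$z, 2, var)), rep(1, 4), tolerance = 1e-9)
  twice <- standardize_features(sc$z)
  expect_equal(twice$z, sc$z, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unstandardize(sc, sc$z), x, tolerance = 1e-12,
               ignore_attr = TRUE)
  held_out <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, letters[1:4]))
  expect_equal(apply_scaling(sc, held_out),
               sweep(sweep(held_out, 2, sc$center), 2, sc$scale, "/"))
  x[, 2] <- 5
  expect_error(standardize_features(x), "zero-variance.*b")
})

test_that("correlation screening drops the later member of tight pairs", {
  set.seed(8)
  a <- rnorm(100)
  x <- cbind(a = a, b = rnorm(100), a_copy = a)
  kept <- screen_variables(x)
  expect_equal(as.character(kept), c("a", "b"))
  expect_equal(attr(kept, "dropped")$dropped, "a_copy")
  # independent columns are all retained at the 0.9 default
  y <- matrix(rnorm(3000), 500, 6, dimnames = list(NULL, letters[1:6]))
  expect_equal(as.character(screen_variables(y)), letters[1:6])
})

test_that("the default synthetic study keeps all 8 variables at the 0.9 screen", {
  calls <- simulate_calls(study_design(), seed = 21)
  kept <- screen_variables(calls[, feature_cols])
  expect_equal(as.character(kept), feature_cols)
})
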