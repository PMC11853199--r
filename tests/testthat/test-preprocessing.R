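db <- function(m) 20 * log10(m)

test_that("the default Butterworth cascade has the textbook response", {
  spec <- design_filter("butterworth", 5, 80, 1000, 4000)
  fr <- frequency_response(spec, n_points = 8192)
  # high-pass section kills DC
  expect_lt(fr$magnitude[1], 1e-6)
  # band center is transparent
  at <- function(f) fr$magnitude[which.min(abs(fr$frequency - f))]
  expect_lt(abs(db(at(283))), 0.1)
  # each edge sits at the -3 dB point of its own section, the other section
  # being transparent there
  expect_lt(abs(db(at(80)) - (-3)), 0.5)
  expect_lt(abs(db(at(1000)) - (-3)), 0.5)
  expect_error(design_filter("butterworth", 5, 80, 2500, 4000),
               class = "respscreen_contract_error")
})

test_that("Butterworth passband is monotone-flat; Chebyshev sections are equiripple", {
  bw <- design_filter("butterworth", 5, 80, 1000, 4000)
  fr <- frequency_response(bw, n_points = 16384)
  band <- fr$frequency >= 150 & fr$frequency <= 800
  mag_db <- db(fr$magnitude[band])
  slopes <- diff(mag_db)
  slopes <- slopes[abs(slopes) > 1e-10]
  # rising then falling once: a unimodal curve has at most one sign change
  expect_lte(sum(diff(sign(slopes)) != 0), 1)

  ch <- design_filter("chebyshev1", 5, 80, 1000, 4000, ripple_db = 1)
  hp <- frequency_response(ch, n_points = 16384, section = "highpass")
  pass <- hp$frequency >= 80
  swing <- max(db(hp$magnitude[pass])) - min(db(hp$magnitude[pass]))
  expect_gt(swing, 0.9)
  expect_lt(swing, 1.1)

  # all families: bandpass shape means Nyquist is quieter than band center
  for (family in c("butterworth", "chebyshev1", "chebyshev2", "elliptic")) {
    fam <- design_filter(family, 5, 80, 1000, 4000)
    fr <- frequency_response(fam, n_points = 4096)
    at <- function(f) fr$magnitude[which.min(abs(fr$frequency - f))]
    expect_lt(fr$magnitude[nrow(fr)], at(283))
  }
})

test_that("zero-phase filtering attenuates stopband tones and passes band tones", {
  spec <- design_filter("butterworth", 5, 80, 1000, 4000)
  rms_ratio <- function(freq) {
    rec <- sine_recording(freq)
    out <- apply_filter(spec, rec)
    rms(out$samples) / rms(rec$samples)
  }
  expect_lt(rms_ratio(40), 0.05)
  expect_lt(abs(rms_ratio(300) - 1), 0.05)
  # zero in, zero out
  zero <- audio_recording(numeric(24000), 4000)
  expect_equal(apply_filter(spec, zero)$samples, numeric(24000))
  # rate mismatch is a contract error
  expect_error(apply_filter(spec, sine_recording(300, sample_rate = 8000)),
               class = "respscreen_contract_error")
})

test_that("zero-phase filtering introduces no group delay and is linear", {
  spec <- design_filter("butterworth", 5, 80, 1000, 4000)
  tone <- sine_recording(300)$samples
  filtered <- apply_filter(spec, tone)
  lags <- -20:20
  xc <- vapply(lags, function(l) {
    idx <- 500:23500
    sum(tone[idx] * filtered[idx + l])
  }, numeric(1))
  expect_identical(lags[which.max(xc)], 0L)

  x <- withr::with_seed(3, rnorm(4000))
  y <- withr::with_seed(4, rnorm(4000))
  lhs <- apply_filter(spec, 2 * x + 3 * y)
  rhs <- 2 * apply_filter(spec, x) + 3 * apply_filter(spec, y)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
})

test_that("normalization scales to peak one, idempotently, rejecting silence", {
  expect_equal(normalize_recording(c(2, -4, 1)), c(0.5, -1, 0.25))
  rec <- audio_recording(c(0.25, -1, 0.5), 4000)
  expect_equal(normalize_recording(rec)$samples, rec$samples)
  expect_error(normalize_recording(audio_recording(numeric(10), 4000)),
               class = "respscreen_degenerate_input_error")
})

test_that("segmentation yields exact 6-s windows and discards the remainder", {
  rec <- audio_recording(withr::with_seed(5, runif(15 * 4000, -1, 1)), 4000,
                         subject_id = "s1", label = "healthy")
  segs <- segment_recording(rec)
  expect_length(segs, 2)
  expect_true(all(vapply(segs, function(s) length(s$samples), integer(1)) ==
                    24000))
  expect_identical(segs[[2]]$segment_index, 2L)
  expect_identical(segs[[1]]$label, "healthy")
  # normalization then segmentation preserves the amplitude bound
  segs_n <- segment_recording(normalize_recording(rec))
  expect_true(all(vapply(segs_n, function(s) max(abs(s$samples)),
                         numeric(1)) <= 1))
  expect_length(segment_recording(sine_recording(100, duration = 6)), 1)
  expect_error(segment_recording(sine_recording(100, duration = 5)),
               class = "respscreen_too_short_error")
})

test_that("the periodogram satisfies Parseval and isolates aligned tones", {
  x <- withr::with_seed(6, rnorm(24000))
  ps <- power_spectrum(x, 4000)
  expect_lt(abs(sum(ps$power) - mean(x^2)) / mean(x^2), 1e-9)
  expect_true(all(ps$power >= 0))
  expect_true(all(diff(ps$frequency) > 0))

  tone <- sine_recording(500)   # 500 Hz is bin-aligned for 24000 @ 4000 Hz
  pt <- power_spectrum(tone)
  expect_gte(max(pt$power) / sum(pt$power), 0.99)

  # band-limited noise: stopband at least 30 dB below the passband
  spec <- design_filter("butterworth", 5, 80, 1000, 4000)
  filt <- apply_filter(spec, withr::with_seed(7, rnorm(48000)))
  pf <- power_spectrum(filt, 4000)
  pass <- mean(pf$power[pf$frequency >= 100 & pf$frequency <= 900])
  stopb <- mean(pf$power[pf$frequency >= 1200 & pf$frequency <= 2000])
  expect_gte(10 * log10(pass / stopb), 30)
})
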