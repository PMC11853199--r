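# Shared fixtures, all generated in code.

# Pure sinusoid as an audio_recording.
sine_recording <- function(freq, sample_rate = 4000, duration = 6,
                           amplitude = 1) {
  t <- (seq_len(round(duration * sample_rate)) - 1) / sample_rate
  audio_recording(amplitude * sin(2 * pi * freq * t), sample_rate)
}

# Small synthetic corpus spec for fast end-to-end tests.
tiny_spec <- function(n_per_class = 3, duration = 6, seed = 1L, ...) {
  synthetic_spec(
    duration = duration,
    counts_per_class = c(healthy = n_per_class, pneumonia = n_per_class,
                         copd = n_per_class, other = n_per_class),
    seed = seed, ...)
}

# Linearly separable 4-class toy feature table: well-separated Gaussian
# blobs at the corners of a square in a 2-feature space.
toy_table <- function(n_per_class = 4, sd = 0.2, seed = 1L) {
  centers <- matrix(c(-2, -2, 2, -2, -2, 2, 2, 2), ncol = 2, byrow = TRUE)
  labels <- class_labels()
  withr::with_seed(seed, {
    rows <- lapply(1:4, function(k) {
      data.frame(
        label = labels[k],
        f1 = rnorm(n_per_class, centers[k, 1], sd),
        f2 = rnorm(n_per_class, centers[k, 2], sd))
    })
    do.call(rbind, rows)
  })
}

# Fast classifier configuration for tests that exercise procedure, not
# asymptotic accuracy.
fast_config <- function(seed = 1L, ...) {
  model_config(n_hidden = 16L, max_epochs = 200L,
               early_stopping_patience = 20L, batch_size = 16L,
               seed = seed, ...)
}

# Tolerance of one unit in the last printed decimal place, for comparing
# against values transcribed at fixed precision (whose last digit may come
# from rounding or truncation).
printed_tol <- function(printed) {
  s <- sub("^[^.]*", "", format(printed, trim = TRUE))
  decimals <- max(nchar(s) - 1L, 0L)
  10^(-decimals) + 1e-9
}

expect_printed <- function(actual, printed) {
  expect_lt(abs(actual - printed), printed_tol(printed))
}
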