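#' Specification of a synthetic auscultation corpus
#'
#' Parameters of the generative acoustic model used for testing the
#' pipeline end to end: band-limited breath noise amplitude-modulated by a
#' raised-cosine breath-cycle envelope, with class-dependent adventitious
#' sounds layered on top (short damped-sinusoid crackle transients for
#' pneumonia, sustained expiratory tonal wheezes for COPD, and a randomized
#' mild mixture for the pooled "other" class).
#'
#' @param sample_rate Sampling rate in Hz (default 4000: the smallest round
#'   rate whose Nyquist clears the 1000 Hz band edge while a 6-s segment
#'   still supports a 10-level db7 decomposition).
#' @param duration Recording length in seconds (>= 6; default 12, giving
#'   two 6-s segments).
#' @param breath_cycle_period Breath-cycle length in seconds (default 4, so
#'   every 6-s segment spans at least one full cycle).
#' @param base_noise_band Passband (Hz) of the breath-noise floor.
#' @param crackle_rate Expected crackle events per breath cycle (pneumonia).
#' @param wheeze_frequencies Tonal wheeze frequencies in Hz (COPD).
#' @param snr_db Signal-to-noise ratio of the additive sensor noise in dB.
#' @param counts_per_class Named integer vector of recordings per class.
#' @param seed Integer master seed; per-recording seeds are derived from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(sample_rate = 4000, duration = 12,
                           breath_cycle_period = 4,
                           base_noise_band = c(100, 900),
                           crackle_rate = 12,
                           wheeze_frequencies = c(250, 420),
                           snr_db = 15,
                           counts_per_class = c(healthy = 40, pneumonia = 40,
                                                copd = 40, other = 40),
                           seed = 1L) {
  if (duration < 6) {
    stop_respscreen("duration must be >= 6 s (one analysis segment)",
                    class = "respscreen_contract_error")
  }
  if (any(wheeze_frequencies < 80 | wheeze_frequencies > 1000)) {
    stop_respscreen("wheeze frequencies must lie within 80-1000 Hz",
                    class = "respscreen_contract_error")
  }
  stopifnot(length(base_noise_band) == 2L,
            base_noise_band[1] > 0,
            base_noise_band[2] < sample_rate / 2,
            base_noise_band[1] < base_noise_band[2])
  counts <- counts_per_class[class_labels()]
  names(counts) <- class_labels()
  counts[is.na(counts)] <- 0L
  if (any(counts < 0)) {
    stop_respscreen("counts must be >= 0",
                    class = "respscreen_contract_error")
  }
  structure(
    list(sample_rate = sample_rate, duration = duration,
         breath_cycle_period = breath_cycle_period,
         base_noise_band = base_noise_band, crackle_rate = crackle_rate,
         wheeze_frequencies = wheeze_frequencies, snr_db = snr_db,
         counts_per_class = counts, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Raised-cosine breath envelope: inspiratory bump over the first 35% of the
# cycle, an expiratory bump (relative amplitude exp_gain) over 40-85%, a
# pause for the remainder, plus a small floor so the airway noise never
# gates fully off. Returns values in (0, 1].
breath_envelope <- function(t, period, exp_gain = 0.7, floor_level = 0.08) {
  u <- (t %% period) / period
  env <- numeric(length(t))
  insp <- u < 0.35
  env[insp] <- sin(pi * u[insp] / 0.35)^2
  expi <- u >= 0.40 & u < 0.85
  env[expi] <- exp_gain * sin(pi * (u[expi] - 0.40) / 0.45)^2
  pmax(env, floor_level)
}

# Expiratory gate of the same shape, zero outside expiration (for wheezes).
expiration_gate <- function(t, period) {
  u <- (t %% period) / period
  gate <- numeric(length(t))
  expi <- u >= 0.40 & u < 0.85
  gate[expi] <- sin(pi * (u[expi] - 0.40) / 0.45)^2
  gate
}

band_noise <- function(n, band, sample_rate) {
  spec <- design_filter("butterworth", 4L, band[1], band[2], sample_rate)
  apply_filter(spec, rnorm(n))
}

# Superimpose Poisson-placed exponentially damped sinusoid transients
# (5-15 ms, 200-600 Hz) within the inspiratory phase of each cycle.
add_crackles <- function(x, t, period, sample_rate, rate_per_cycle,
                         amp_ref, amp_range = c(8, 14)) {
  n_cycles <- max(1L, floor(max(t) / period))
  for (cycle in seq_len(n_cycles) - 1L) {
    n_events <- rpois(1, rate_per_cycle)
    if (n_events == 0) next
    onsets <- cycle * period + runif(n_events, 0, 0.35 * period)
    for (onset in onsets) {
      dur <- runif(1, 0.005, 0.015)
      f <- runif(1, 200, 600)
      amp <- runif(1, amp_range[1], amp_range[2]) * amp_ref
      i0 <- floor(onset * sample_rate) + 1L
      i1 <- min(i0 + ceiling(dur * sample_rate * 3), length(x))
      if (i0 >= length(x)) next
      tt <- (seq(i0, i1) - i0) / sample_rate
      x[i0:i1] <- x[i0:i1] +
        amp * exp(-tt / (dur / 5)) * sin(2 * pi * f * tt)
    }
  }
  x
}

#' Generate one synthetic labeled recording
#'
#' Deterministic for a fixed `(label, spec, seed)` triple. All classes share
#' the envelope-modulated band-noise breath model; pneumonia adds crackle
#' transients, COPD adds sustained expiratory wheezes at
#' `spec$wheeze_frequencies`, and "other" draws a randomized mild mixture
#' (shifted breath period, low-frequency wheeze, sparse crackles, wider
#' noise band) whose distribution differs from the three named classes.
#'
#' @param label One of [class_labels()].
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed for this recording.
#' @param subject_id,measurement_point Metadata for the recording.
#' @return A labeled [audio_recording()] with peak amplitude 0.9.
#' @export
generate_recording <- function(label, spec = synthetic_spec(), seed = 1L,
                               subject_id = NA_character_,
                               measurement_point = NA_integer_) {
  assert_class_label(label)
  stopifnot(inherits(spec, "synthetic_spec"))
  fs <- spec$sample_rate
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  x <- with_seed(seed, {
    period <- spec$breath_cycle_period
    band <- spec$base_noise_band
    exp_gain <- 0.7
    breath <- NULL
    sig <- switch(label,
      healthy = {
        breath_envelope(t, period, exp_gain) * band_noise(n, band, fs)
      },
      pneumonia = {
        breath <- breath_envelope(t, period, exp_gain) *
          band_noise(n, band, fs)
        add_crackles(breath, t, period, fs, spec$crackle_rate,
                     amp_ref = rms(breath))
      },
      copd = {
        breath <- breath_envelope(t, period, exp_gain) *
          band_noise(n, band, fs)
        gate <- expiration_gate(t, period)
        ref <- rms(breath)
        tone <- numeric(n)
        for (f in spec$wheeze_frequencies) {
          f_jit <- f * runif(1, 0.995, 1.005)
          tone <- tone + sin(2 * pi * f_jit * t + runif(1, 0, 2 * pi))
        }
        breath + 1.2 * ref * gate * tone / sqrt(length(spec$wheeze_frequencies))
      },
      other = {
        period_o <- runif(1, 2.2, 3.2)
        exp_gain_o <- runif(1, 0.9, 1.2)
        band_o <- c(150, min(1200, fs / 2 - 1))
        breath <- breath_envelope(t, period_o, exp_gain_o) *
          band_noise(n, band_o, fs)
        ref <- rms(breath)
        f_o <- runif(1, 110, 190)
        tone <- 0.6 * ref * expiration_gate(t, period_o) *
          sin(2 * pi * f_o * t + runif(1, 0, 2 * pi))
        add_crackles(breath + tone, t, period_o, fs, rate_per_cycle = 2,
                     amp_ref = ref, amp_range = c(1.2, 2))
      })
    noise_sd <- rms(sig) / 10^(spec$snr_db / 20)
    sig + rnorm(n, sd = noise_sd)
  })
  x <- 0.9 * x / max(abs(x))
  audio_recording(x, fs, subject_id = subject_id,
                  measurement_point = measurement_point, label = label)
}

#' Generate a labeled synthetic corpus
#'
#' Produces `spec$counts_per_class` recordings per class; each recording's
#' seed is derived deterministically from `spec$seed` and its index, so the
#' corpus is reproducible and individual recordings can be regenerated in
#' isolation.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `recordings` (list of labeled [audio_recording()]s) and
#'   `manifest` (data frame with `recording_path` placeholders, subject ids,
#'   measurement points and labels).
#' @export
generate_corpus <- function(spec = synthetic_spec()) {
  counts <- spec$counts_per_class
  if (sum(counts) < 1) {
    stop_respscreen("counts_per_class must total >= 1",
                    class = "respscreen_contract_error")
  }
  labels <- rep(names(counts), counts)
  recordings <- vector("list", length(labels))
  manifest <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    subject <- sprintf("%s_%03d", labels[i], sum(labels[seq_len(i)] == labels[i]))
    point <- ((i - 1L) %% 5L) + 1L
    recordings[[i]] <- generate_recording(
      labels[i], spec, seed = derive_seed(spec$seed, i),
      subject_id = subject, measurement_point = point)
    manifest[[i]] <- data.frame(
      recording_path = sprintf("%s.wav", subject), subject_id = subject,
      measurement_point = point, label = labels[i],
      stringsAsFactors = FALSE)
  }
  list(recordings = recordings, manifest = do.call(rbind, manifest))
}

#' Write a generated corpus to disk
#'
#' Saves each recording as 16-bit PCM WAV plus the CSV manifest linking
#' files to subject ids, measurement points and labels.
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(corpus$recordings)) {
    save_recording(corpus$recordings[[i]],
                   file.path(dir, corpus$manifest$recording_path[i]))
  }
  path <- file.path(dir, "manifest.csv")
  write_manifest(corpus$manifest, path)
  invisible(path)
}
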