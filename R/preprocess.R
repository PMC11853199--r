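#' Design a bandpass filter as cascaded high-pass and low-pass sections
#'
#' The screening band (default 80-1000 Hz) is realized as a cascade of an
#' order-`order` high-pass at `low_cut_hz` and an order-`order` low-pass at
#' `high_cut_hz`, rather than a single bandpass prototype. Keeping the two
#' sections separate is numerically robust at narrow normalized cutoffs and
#' lets each section retain its textbook cutoff property (-3 dB at the edge
#' for Butterworth, equiripple passband for Chebyshev type 1, and so on).
#'
#' Four families are supported for comparison: `butterworth` (maximally flat),
#' `chebyshev1` (passband ripple `ripple_db`), `chebyshev2` (stopband
#' attenuation `attenuation_db`) and `elliptic` (both).
#'
#' @param family One of `"butterworth"`, `"chebyshev1"`, `"chebyshev2"`,
#'   `"elliptic"`.
#' @param order Order of each section (default 5).
#' @param low_cut_hz,high_cut_hz Band edges in Hz, `0 < low < high < fs/2`.
#' @param sample_rate Sampling rate in Hz.
#' @param ripple_db Passband ripple in dB (chebyshev1/elliptic).
#' @param attenuation_db Stopband attenuation in dB (chebyshev2/elliptic).
#' @return A `filter_spec` object holding the two sections' transfer-function
#'   coefficients.
#' @export
#' @examples
#' design_filter("butterworth", 5, 80, 1000, 4000)
design_filter <- function(family = c("butterworth", "chebyshev1",
                                     "chebyshev2", "elliptic"),
                          order = 5L, low_cut_hz = 80, high_cut_hz = 1000,
                          sample_rate = 4000, ripple_db = 1,
                          attenuation_db = 40) {
  family <- match.arg(family)
  nyq <- sample_rate / 2
  if (!(low_cut_hz > 0 && low_cut_hz < high_cut_hz && high_cut_hz < nyq)) {
    stop_respscreen(
      "band edges must satisfy 0 < low (%g) < high (%g) < Nyquist (%g)",
      low_cut_hz, high_cut_hz, nyq, class = "respscreen_contract_error")
  }
  wl <- low_cut_hz / nyq
  wh <- high_cut_hz / nyq
  section <- function(w, type) {
    f <- switch(family,
      butterworth = signal::butter(order, w, type = type),
      chebyshev1  = signal::cheby1(order, ripple_db, w, type = type),
      chebyshev2  = signal::cheby2(order, attenuation_db, w, type = type),
      elliptic    = signal::ellip(order, ripple_db, attenuation_db, w,
                                  type = type))
    list(b = as.numeric(f$b), a = as.numeric(f$a))
  }
  structure(
    list(family = family, order = as.integer(order),
         low_cut_hz = low_cut_hz, high_cut_hz = high_cut_hz,
         sample_rate = sample_rate,
         ripple_db = ripple_db, attenuation_db = attenuation_db,
         highpass = section(wl, "high"), lowpass = section(wh, "low")),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s bandpass %g-%g Hz @ fs %g Hz\n", x$family,
              x$low_cut_hz, x$high_cut_hz, x$sample_rate))
  cat(sprintf("  cascade: order-%d high-pass x order-%d low-pass\n",
              x$order, x$order))
  invisible(x)
}

# |H(e^{jw})| of one b/a section on angular frequencies w (radians/sample).
section_magnitude <- function(section, w) {
  z <- exp(-1i * w)
  num <- outer(z, seq_along(section$b) - 1, `^`) %*% section$b
  den <- outer(z, seq_along(section$a) - 1, `^`) %*% section$a
  as.numeric(Mod(num / den))
}

#' Magnitude frequency response of a designed filter
#'
#' Evaluates the single-pass magnitude response on a linear frequency grid
#' from 0 to Nyquist; used to compare the four filter families. The cascade
#' response is the product of the two sections; per-section curves are also
#' available (for example to inspect the Chebyshev equiripple behavior of one
#' section in isolation).
#'
#' @param spec A [design_filter()] result.
#' @param n_points Number of grid points (>= 2).
#' @param section `"cascade"` (default), `"highpass"`, or `"lowpass"`.
#' @return Data frame with columns `frequency` (Hz) and `magnitude` (linear
#'   gain).
#' @export
frequency_response <- function(spec, n_points = 2048L,
                               section = c("cascade", "highpass", "lowpass")) {
  stopifnot(inherits(spec, "filter_spec"), n_points >= 2L)
  section <- match.arg(section)
  f <- seq(0, spec$sample_rate / 2, length.out = n_points)
  w <- 2 * pi * f / spec$sample_rate
  mag <- switch(section,
    cascade  = section_magnitude(spec$highpass, w) *
               section_magnitude(spec$lowpass, w),
    highpass = section_magnitude(spec$highpass, w),
    lowpass  = section_magnitude(spec$lowpass, w))
  data.frame(frequency = f, magnitude = mag)
}

# Zero-phase application of one b/a section with odd-reflection edge padding.
filtfilt_section <- function(section, x) {
  n_edge <- 3L * (max(length(section$a), length(section$b)) - 1L)
  if (length(x) <= n_edge) {
    stop_respscreen(
      "signal too short (%d samples) for zero-phase filtering (need > %d)",
      length(x), n_edge, class = "respscreen_contract_error")
  }
  front <- 2 * x[1] - x[(n_edge + 1L):2L]
  back <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - n_edge)]
  ext <- c(front, x, back)
  y <- signal::filter(section$b, section$a, ext)
  y <- rev(signal::filter(section$b, section$a, rev(y)))
  as.numeric(y[(n_edge + 1L):(n_edge + length(x))])
}

#' Apply a filter with zero phase
#'
#' Runs the cascade forward and then time-reversed (with odd-reflection edge
#' padding), so the output has no group delay. The effective magnitude is the
#' square of the designed response; the designed -3 dB cutoffs become -6 dB
#' after the two passes.
#'
#' @param spec A [design_filter()] result.
#' @param recording An [audio_recording()] (or bare numeric vector) at
#'   `spec$sample_rate`.
#' @return Filtered recording of the same length and type as the input.
#' @export
apply_filter <- function(spec, recording) {
  stopifnot(inherits(spec, "filter_spec"))
  if (inherits(recording, "audio_recording")) {
    if (!isTRUE(all.equal(recording$sample_rate, spec$sample_rate))) {
      stop_respscreen("recording rate %g Hz does not match filter rate %g Hz",
                      recording$sample_rate, spec$sample_rate,
                      class = "respscreen_contract_error")
    }
    out <- recording
    out$samples <- filtfilt_section(spec$lowpass,
                                    filtfilt_section(spec$highpass,
                                                     recording$samples))
    return(out)
  }
  filtfilt_section(spec$lowpass, filtfilt_section(spec$highpass,
                                                  as.numeric(recording)))
}

#' Peak-normalize a recording to \[-1, 1\]
#'
#' Divides every sample by the maximum absolute amplitude, so at least one
#' sample reaches magnitude exactly 1. Applied per recording, before
#' segmentation.
#'
#' @param recording An [audio_recording()] or numeric vector.
#' @return Normalized recording of the same type.
#' @export
normalize_recording <- function(recording) {
  x <- if (inherits(recording, "audio_recording")) recording$samples
       else as.numeric(recording)
  peak <- max(abs(x))
  if (peak == 0) {
    stop_respscreen("cannot normalize an all-zero signal",
                    class = "respscreen_degenerate_input_error")
  }
  if (inherits(recording, "audio_recording")) {
    recording$samples <- x / peak
    recording
  } else {
    x / peak
  }
}

#' Cut a recording into fixed-length segments
#'
#' Consecutive non-overlapping windows of `seg_seconds` (default 6 s, the
#' length covering a full breathing cycle); any trailing remainder shorter
#' than one window is discarded.
#'
#' @param recording An [audio_recording()].
#' @param seg_seconds Segment length in seconds.
#' @param recording_id Identifier stored in each segment's origin (defaults
#'   to the recording's subject id).
#' @return List of `audio_segment` objects (samples, sample_rate,
#'   recording_id, segment_index, label).
#' @export
segment_recording <- function(recording, seg_seconds = 6,
                              recording_id = NULL) {
  stopifnot(inherits(recording, "audio_recording"))
  n_seg_samples <- round(seg_seconds * recording$sample_rate)
  n <- length(recording$samples)
  if (n < n_seg_samples) {
    stop_respscreen(
      "recording (%.2f s) is shorter than one %g-s segment",
      n / recording$sample_rate, seg_seconds,
      class = "respscreen_too_short_error")
  }
  if (is.null(recording_id)) {
    recording_id <- if (!is.na(recording$subject_id)) recording$subject_id
                    else "recording"
  }
  n_segments <- n %/% n_seg_samples
  lapply(seq_len(n_segments), function(k) {
    idx <- ((k - 1L) * n_seg_samples + 1L):(k * n_seg_samples)
    structure(
      list(samples = recording$samples[idx],
           sample_rate = recording$sample_rate,
           recording_id = recording_id, segment_index = k,
           label = recording$label),
      class = "audio_segment"
    )
  })
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment> %s #%d: %d samples @ %g Hz\n",
              x$recording_id, x$segment_index, length(x$samples),
              x$sample_rate))
  invisible(x)
}

#' One-sided power spectrum (periodogram)
#'
#' Rectangular-window periodogram normalized so that the power summed over
#' the one-sided grid equals the mean-square amplitude of the signal
#' (discrete Parseval identity).
#'
#' @param x Numeric vector, [audio_recording()], or `audio_segment`.
#' @param sample_rate Sampling rate in Hz (taken from `x` when it carries
#'   one).
#' @return Data frame of class `power_spectrum` with columns `frequency`
#'   (Hz, 0 to Nyquist) and `power`.
#' @export
power_spectrum <- function(x, sample_rate = NULL) {
  if (inherits(x, c("audio_recording", "audio_segment"))) {
    sample_rate <- x$sample_rate
    x <- x$samples
  }
  x <- as.numeric(x)
  if (length(x) < 2L) {
    stop_respscreen("need at least 2 samples for a power spectrum",
                    class = "respscreen_contract_error")
  }
  if (is.null(sample_rate)) {
    stop_respscreen("sample_rate is required for bare numeric input",
                    class = "respscreen_contract_error")
  }
  n <- length(x)
  spec <- Mod(fft(x))^2 / n^2
  n_keep <- n %/% 2L + 1L
  one_sided <- spec[seq_len(n_keep)]
  # double the bins that have a mirrored negative-frequency twin
  last_paired <- if (n %% 2L == 0L) n_keep - 1L else n_keep
  if (last_paired >= 2L) {
    one_sided[2:last_paired] <- 2 * one_sided[2:last_paired]
  }
  out <- data.frame(frequency = (seq_len(n_keep) - 1) * sample_rate / n,
                    power = one_sided)
  class(out) <- c("power_spectrum", "data.frame")
  out
}
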