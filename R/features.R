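#' Names of the 13 segment features in canonical order
#'
#' Shannon entropy and spectral entropy are computed on the segment itself
#' (before the wavelet transform); the remaining 11 features are the root
#' mean square of the level-10 approximation and of each detail coefficient
#' set of the db7 decomposition.
#'
#' @return Character vector of length 13.
#' @export
#' @examples
#' feature_names()
feature_names <- function() {
  c("Entropy", "Spec.Entropy", "RMScA", paste0("RMScD", 1:10))
}

#' Shannon entropy of binned amplitudes
#'
#' Amplitudes are histogrammed on `n_bins` equal-width bins spanning
#' \[-1, 1\] (values outside are clipped into the end bins); bin
#' probabilities are relative counts, and the entropy is
#' \eqn{-\sum_i p_i \log_2 p_i} with \eqn{0 \log 0 := 0}. For normalized
#' segments the result lies in \[0, log2(n_bins)\] bits. The default of 256
#' bins corresponds to 8-bit amplitude quantization.
#'
#' @param values Numeric vector of amplitudes.
#' @param n_bins Number of histogram bins (>= 2).
#' @return Entropy in bits.
#' @export
#' @examples
#' shannon_entropy(rep(0.5, 100))            # 0: a single occupied bin
#' shannon_entropy(c(rep(-0.5, 50), rep(0.5, 50)))  # 1 bit
shannon_entropy <- function(values, n_bins = 256L) {
  if (inherits(values, c("audio_recording", "audio_segment"))) {
    values <- values$samples
  }
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop_respscreen("cannot compute entropy of an empty sequence",
                    class = "respscreen_contract_error")
  }
  if (n_bins < 2L) {
    stop_respscreen("n_bins must be >= 2", class = "respscreen_contract_error")
  }
  bin <- floor((pmin(pmax(values, -1), 1) + 1) / 2 * n_bins) + 1L
  bin[bin > n_bins] <- n_bins
  p <- tabulate(bin, nbins = n_bins) / length(values)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Spectral entropy of a segment
#'
#' Shannon entropy of the power spectral density treated as a probability
#' distribution: the one-sided periodogram is normalized to sum to one over
#' its frequency grid (0 to the Nyquist frequency) and
#' \eqn{-\sum_f P(f) \log_2 P(f)} is returned. A pure tone gives about 0
#' bits; spectrally flat noise approaches the log2 of the number of bins.
#'
#' @param x Numeric vector, [audio_recording()], or `audio_segment`.
#' @param sample_rate Sampling rate (only needed for bare numeric input; the
#'   result does not depend on it).
#' @return Spectral entropy in bits.
#' @export
spectral_entropy <- function(x, sample_rate = NULL) {
  ps <- power_spectrum(x, sample_rate %||% 1)
  total <- sum(ps$power)
  if (total == 0) {
    stop_respscreen("cannot compute spectral entropy of an all-zero signal",
                    class = "respscreen_degenerate_input_error")
  }
  p <- ps$power / total
  p <- p[p > 0]
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Root mean square of a coefficient set
#'
#' \eqn{\sqrt{\sum_i D_i^2 / N}} where the \eqn{D_i} are the coefficients of
#' one frequency-component set and \eqn{N} is their count.
#'
#' @param values Non-empty numeric vector.
#' @return Non-negative scalar.
#' @export
#' @examples
#' rms(c(3, -4))  # sqrt(12.5)
rms <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop_respscreen("cannot compute the RMS of an empty sequence",
                    class = "respscreen_contract_error")
  }
  sqrt(sum(values^2) / length(values))
}

#' Extract the 13-feature vector of a segment
#'
#' Computes Shannon entropy and spectral entropy on the raw segment, then
#' decomposes it with the 10-level db7 wavelet transform and takes the RMS
#' of the approximation and of each detail coefficient set. The result is a
#' named vector in the canonical [feature_names()] order.
#'
#' @param segment An `audio_segment`, [audio_recording()], or numeric
#'   vector (paired with `sample_rate`).
#' @param n_bins Histogram bins for [shannon_entropy()].
#' @param wavelet,levels,mode Passed to [dwt_decompose()].
#' @param sample_rate Sampling rate for bare numeric input.
#' @return Named numeric vector of length 13.
#' @export
extract_feature_vector <- function(segment, n_bins = 256L, wavelet = "db7",
                                   levels = 10L, mode = "symmetric",
                                   sample_rate = NULL) {
  coefs <- dwt_decompose(segment, wavelet = wavelet, levels = levels,
                         mode = mode)
  out <- c(
    Entropy = shannon_entropy(segment, n_bins = n_bins),
    Spec.Entropy = spectral_entropy(segment, sample_rate = sample_rate),
    RMScA = rms(coefs$cA),
    vapply(coefs$cD, rms, numeric(1))
  )
  names(out) <- c("Entropy", "Spec.Entropy", "RMScA",
                  paste0("RMScD", seq_len(levels)))
  out
}

#' Build a labeled feature table from recordings
#'
#' Runs the full preprocessing chain (bandpass filter, peak normalization,
#' 6-s segmentation) on each recording and extracts the 13-feature vector of
#' every segment.
#'
#' @param recordings List of [audio_recording()] objects (labels taken from
#'   each recording), or a single recording.
#' @param filter_spec A [design_filter()] result, or `NULL` for the default
#'   5th-order Butterworth 80-1000 Hz at the recordings' rate.
#' @param seg_seconds Segment length in seconds.
#' @param n_bins Histogram bins for Shannon entropy.
#' @return Data frame with columns `recording_id`, `segment_index`, `label`
#'   and the 13 features.
#' @export
extract_features <- function(recordings, filter_spec = NULL,
                             seg_seconds = 6, n_bins = 256L) {
  if (inherits(recordings, "audio_recording")) recordings <- list(recordings)
  rows <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    spec <- filter_spec %||%
      design_filter("butterworth", 5L, 80, 1000, rec$sample_rate)
    rec_id <- if (!is.na(rec$subject_id)) rec$subject_id
              else sprintf("rec%04d", i)
    proc <- normalize_recording(apply_filter(spec, rec))
    segs <- segment_recording(proc, seg_seconds, recording_id = rec_id)
    do.call(rbind, lapply(segs, function(s) {
      fv <- extract_feature_vector(s, n_bins = n_bins)
      cbind(data.frame(recording_id = s$recording_id,
                       segment_index = s$segment_index,
                       label = if (is.na(s$label)) NA_character_ else s$label,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(fv), check.names = FALSE))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write or read a feature table CSV
#'
#' The header names the 13 features in canonical order alongside the origin
#' (`recording_id`, `segment_index`) and `label` columns. Lines starting
#' with `#` carry provenance metadata and are skipped on read.
#'
#' @param table Feature table from [extract_features()].
#' @param path CSV path.
#' @param metadata Optional named character vector written as `# key: value`
#'   header lines.
#' @return `read_feature_table()` returns the feature table data frame.
#' @export
write_feature_table <- function(table, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata)) {
    writeLines(sprintf("# %s: %s", names(metadata), metadata), con)
  }
  write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  read.csv(path, comment.char = "#", check.names = FALSE,
           stringsAsFactors = FALSE)
}
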