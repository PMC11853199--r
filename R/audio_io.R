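#' Construct an audio recording
#'
#' Container for a mono auscultation recording: an amplitude vector, its
#' sample rate, and the metadata the screening application attaches (subject
#' identifier, chest-wall measurement point 1-5, and an optional class label).
#'
#' @param samples Numeric vector of amplitudes (non-empty, finite).
#' @param sample_rate Sampling rate in Hz (positive).
#' @param subject_id Opaque subject identifier string, or `NA`.
#' @param measurement_point Integer in 1..5 (the auscultation positions over
#'   the chest wall), or `NA` when not recorded.
#' @param label One of [class_labels()], or `NA` when unlabeled.
#' @return An object of class `audio_recording`.
#' @export
audio_recording <- function(samples, sample_rate, subject_id = NA_character_,
                            measurement_point = NA_integer_,
                            label = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop_respscreen("recording must contain at least one sample",
                    class = "respscreen_empty_input_error")
  }
  if (!all(is.finite(samples))) {
    stop_respscreen("recording contains non-finite samples",
                    class = "respscreen_contract_error")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      sample_rate <= 0) {
    stop_respscreen("sample_rate must be a positive scalar (Hz)",
                    class = "respscreen_contract_error")
  }
  if (!is.na(measurement_point)) {
    measurement_point <- as.integer(measurement_point)
    if (!measurement_point %in% 1:5) {
      stop_respscreen("measurement_point must be in 1..5",
                      class = "respscreen_contract_error")
    }
  }
  if (!is.na(label)) assert_class_label(label)
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         subject_id = subject_id,
         measurement_point = as.integer(measurement_point), label = label),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate
  cat(sprintf("<audio_recording> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$sample_rate, dur))
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  if (!is.na(x$measurement_point)) cat("  point:", x$measurement_point, "\n")
  if (!is.na(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' @export
length.audio_recording <- function(x) length(x$samples)

#' Duration of a recording in seconds
#' @param recording An [audio_recording()].
#' @return Duration in seconds.
#' @export
duration <- function(recording) {
  stopifnot(inherits(recording, "audio_recording"))
  length(recording$samples) / recording$sample_rate
}

#' Load a WAV recording
#'
#' Reads a RIFF/WAVE file (integer PCM or IEEE float), averages channels to
#' mono, and optionally resamples to a target rate. Amplitudes are returned
#' on the file's native full scale mapped to \[-1, 1\].
#'
#' @param path Path to a WAV file.
#' @param target_rate Optional target sample rate in Hz; when given, the
#'   signal is resampled with a polyphase anti-aliasing resampler.
#' @param subject_id,measurement_point,label Metadata forwarded to
#'   [audio_recording()].
#' @return An [audio_recording()].
#' @export
load_recording <- function(path, target_rate = NULL,
                           subject_id = NA_character_,
                           measurement_point = NA_integer_,
                           label = NA_character_) {
  wav <- read_wav(path)
  samples <- rowMeans(wav$samples)
  rate <- wav$sample_rate
  rec <- audio_recording(samples, rate, subject_id = subject_id,
                         measurement_point = measurement_point, label = label)
  if (!is.null(target_rate) && !isTRUE(all.equal(target_rate, rate))) {
    rec <- resample_recording(rec, target_rate)
  }
  rec
}

#' Resample a recording to a new rate
#'
#' Rational-factor polyphase resampling (via [signal::resample()]); the
#' resampling ratio is taken from the integer-reduced rate fraction.
#'
#' @param recording An [audio_recording()].
#' @param target_rate New sample rate in Hz.
#' @return The resampled [audio_recording()].
#' @export
resample_recording <- function(recording, target_rate) {
  stopifnot(inherits(recording, "audio_recording"))
  if (!is.numeric(target_rate) || target_rate <= 0) {
    stop_respscreen("target_rate must be positive",
                    class = "respscreen_contract_error")
  }
  g <- gcd(round(target_rate), round(recording$sample_rate))
  p <- round(target_rate) / g
  q <- round(recording$sample_rate) / g
  y <- signal::resample(recording$samples, p = p, q = q)
  n_out <- round(length(recording$samples) * p / q)
  y <- y[seq_len(min(n_out, length(y)))]
  audio_recording(y, target_rate, subject_id = recording$subject_id,
                  measurement_point = recording$measurement_point,
                  label = recording$label)
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' Save a recording as 16-bit PCM WAV
#'
#' @param recording An [audio_recording()] with amplitudes in \[-1, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_recording <- function(recording, path) {
  stopifnot(inherits(recording, "audio_recording"))
  write_wav(recording$samples, recording$sample_rate, path)
}

#' Read or write a label manifest
#'
#' The manifest is a CSV with columns `recording_path`, `subject_id`,
#' `measurement_point`, `label` that associates each WAV file with its
#' metadata and class label.
#'
#' @param path Manifest CSV path.
#' @return `read_manifest()` returns a data frame with the four columns.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("recording_path", "subject_id", "measurement_point", "label")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0L) {
    stop_respscreen("manifest is missing columns: %s",
                    paste(missing, collapse = ", "),
                    class = "respscreen_format_error")
  }
  m
}

#' @rdname read_manifest
#' @param manifest Data frame with the manifest columns.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
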