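# Daubechies db7 analysis low-pass filter (14 taps, 7 vanishing moments).
# The high-pass and synthesis filters follow from the quadrature-mirror
# relations of an orthogonal wavelet, so only this vector is stored.
DB7_DEC_LO <- c(
  0.00035371379997452024, -0.0018016407040474908, 0.0004295779729213665,
  0.01255099855609984, -0.01657454163066688, -0.03802993693501441,
  0.08061260915108308, 0.07130921926683026, -0.22403618499387498,
  -0.14390600392856498, 0.4697822874051931, 0.7291320908462351,
  0.3965393194819173, 0.07785205408500918
)

# Filter bank for an orthogonal wavelet given its analysis low-pass filter.
wavelet_filters <- function(wavelet = "db7") {
  if (!identical(wavelet, "db7")) {
    stop_respscreen("only the db7 wavelet is built in (got %s)", wavelet,
                    class = "respscreen_contract_error")
  }
  lo <- DB7_DEC_LO
  n <- length(lo)
  hi <- rev(lo) * (-1)^seq_len(n)           # quadrature-mirror high-pass
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi),
       length = n)
}

# Full linear convolution via the C-level FIR filter in stats::filter.
conv_full <- function(x, h) {
  L <- length(h)
  padded <- c(numeric(L - 1L), x, numeric(L - 1L))
  y <- stats::filter(padded, h, method = "convolution", sides = 1L)
  as.numeric(y[L:(L + length(x) + L - 2L)])
}

# "Valid" part of the convolution (every lag where the filter fully overlaps).
conv_valid <- function(x, h) {
  full <- conv_full(x, h)
  L <- length(h)
  full[L:(length(x))]
}

# One analysis step: returns list(cA, cD).
dwt_single <- function(x, filters, mode = c("symmetric", "periodic")) {
  mode <- match.arg(mode)
  n <- length(x)
  L <- filters$length
  if (mode == "symmetric") {
    if (n < L) {
      stop_respscreen("signal of length %d too short for filter length %d",
                      n, L, class = "respscreen_contract_error")
    }
    ext <- c(x[(L - 1L):1L], x, x[n:(n - L + 2L)])
    lo <- conv_valid(ext, filters$dec_lo)
    hi <- conv_valid(ext, filters$dec_hi)
    keep <- seq(2L, length(lo), by = 2L)
    list(cA = lo[keep], cD = hi[keep])
  } else {
    if (n %% 2L == 1L) {
      x <- c(x, x[n])        # repeat the last sample to reach even length
      n <- n + 1L
    }
    ext <- c(x[(n - L + 1L):n], x, x[1:L])
    lo <- conv_valid(ext, filters$dec_lo)
    hi <- conv_valid(ext, filters$dec_hi)
    # downsampling phase chosen so the periodized transform is orthonormal
    keep <- seq(L - 5L, by = 2L, length.out = n %/% 2L)
    list(cA = lo[keep], cD = hi[keep])
  }
}

upsample2 <- function(x) {
  y <- numeric(2L * length(x))
  y[seq(1L, length(y), by = 2L)] <- x
  y
}

# One synthesis step inverting dwt_single.
idwt_single <- function(cA, cD, filters, mode = c("symmetric", "periodic"),
                        out_len) {
  mode <- match.arg(mode)
  L <- filters$length
  if (mode == "symmetric") {
    full <- conv_full(upsample2(cA), filters$rec_lo) +
            conv_full(upsample2(cD), filters$rec_hi)
    y <- full[(L - 1L):(length(full) - L + 1L)]
  } else {
    n2 <- 2L * length(cA)
    uA <- upsample2(cA)
    uD <- upsample2(cD)
    uAe <- c(uA[(n2 - L + 1L):n2], uA, uA[1:L])
    uDe <- c(uD[(n2 - L + 1L):n2], uD, uD[1:L])
    full <- conv_full(uAe, filters$rec_lo) + conv_full(uDe, filters$rec_hi)
    y <- full[(L + L %/% 2L):(L + L %/% 2L + n2 - 1L)]
  }
  y[seq_len(min(out_len, length(y)))]
}

#' Multilevel discrete wavelet decomposition
#'
#' Decomposes a segment with the db7 wavelet to the requested depth
#' (default 10 levels), returning the level-10 approximation and the ten
#' detail coefficient sets. A 6-s segment at 4000 Hz (24000 samples)
#' supports the full depth. The `"symmetric"` boundary mode (mirror
#' extension) is the default used for feature extraction; `"periodic"`
#' (periodized) keeps the transform exactly orthogonal, conserving energy
#' and giving perfect reconstruction to rounding error.
#'
#' @param x Numeric vector, [audio_recording()], or `audio_segment`.
#' @param wavelet Wavelet name; only `"db7"` is built in.
#' @param levels Decomposition depth (default 10).
#' @param mode Boundary handling: `"symmetric"` or `"periodic"`.
#' @return Object of class `wavelet_coefficients`: list with `cA`
#'   (approximation at the deepest level) and `cD` (list `cD1`..`cD<levels>`,
#'   `cD1` the finest), plus the bookkeeping needed by
#'   [dwt_reconstruct()].
#' @export
dwt_decompose <- function(x, wavelet = "db7", levels = 10L,
                          mode = c("symmetric", "periodic")) {
  mode <- match.arg(mode)
  if (inherits(x, c("audio_recording", "audio_segment"))) x <- x$samples
  x <- as.numeric(x)
  filters <- wavelet_filters(wavelet)
  max_levels <- floor(log2(length(x) / (filters$length - 1)))
  if (levels < 1L || levels > max_levels) {
    stop_respscreen(
      "cannot decompose %d samples to %d levels with %s (max %d)",
      length(x), levels, wavelet, max_levels,
      class = "respscreen_contract_error")
  }
  lengths <- integer(levels)
  details <- vector("list", levels)
  approx <- x
  for (lev in seq_len(levels)) {
    lengths[lev] <- length(approx)
    step <- dwt_single(approx, filters, mode)
    details[[lev]] <- step$cD
    approx <- step$cA
  }
  names(details) <- paste0("cD", seq_len(levels))
  structure(
    list(cA = approx, cD = details, wavelet = wavelet, levels = levels,
         mode = mode, input_lengths = lengths),
    class = "wavelet_coefficients"
  )
}

#' @export
print.wavelet_coefficients <- function(x, ...) {
  cat(sprintf("<wavelet_coefficients> %s, %d levels, %s boundary\n",
              x$wavelet, x$levels, x$mode))
  cat(sprintf("  cA: %d coefficients; cD1..cD%d: %s\n", length(x$cA),
              x$levels,
              paste(rev(vapply(x$cD, length, integer(1))), collapse = ", ")))
  invisible(x)
}

#' Invert a multilevel wavelet decomposition
#'
#' @param coefs A [dwt_decompose()] result.
#' @return Numeric vector of the original length.
#' @export
dwt_reconstruct <- function(coefs) {
  stopifnot(inherits(coefs, "wavelet_coefficients"))
  filters <- wavelet_filters(coefs$wavelet)
  approx <- coefs$cA
  for (lev in rev(seq_len(coefs$levels))) {
    approx <- idwt_single(approx, coefs$cD[[lev]], filters, coefs$mode,
                          out_len = coefs$input_lengths[lev])
  }
  approx
}

#' All coefficient sets of a decomposition as a named list
#'
#' @param coefs A [dwt_decompose()] result.
#' @return Named list `cA`, `cD1`, ..., `cD<levels>`.
#' @export
coefficient_sets <- function(coefs) {
  stopifnot(inherits(coefs, "wavelet_coefficients"))
  c(list(cA = coefs$cA), coefs$cD)
}
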