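#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft median qchisq rnorm runif rpois sd var predict
#' @importFrom utils head read.csv write.csv
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a child seed < 2^31 from a parent seed and an index.
# Splitmix-style integer mixing done in double precision (exact below 2^53).
derive_seed <- function(seed, index) {
  x <- (as.numeric(seed) %% 2147483647) * 69069 + as.numeric(index) * 362437 + 1
  x <- x %% 2147483647
  x <- (x * 48271) %% 2147483647
  as.integer(x %% 2147483629 + 1)
}

# Polynomial rolling hash of a character vector, reported as 8 hex digits;
# used to stamp artifacts with a fingerprint of the configuration that
# produced them. Exact in double precision (all intermediates < 2^53).
config_hash <- function(x) {
  stopifnot(is.character(x))
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 127 + b) %% 2147483647
  sprintf("%08x", h)
}

stop_respscreen <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "respscreen_error")))
}

#' Canonical respiratory class labels
#'
#' The four screening classes in their canonical order. `"other"` pools the
#' remaining respiratory conditions (coronavirus disease, LRTI, URTI, asthma,
#' bronchiolitis, bronchiectasis) into a single class.
#'
#' @return Character vector `c("healthy", "pneumonia", "copd", "other")`.
#' @export
#' @examples
#' class_labels()
class_labels <- function() c("healthy", "pneumonia", "copd", "other")

assert_class_label <- function(label) {
  if (!is.character(label) || length(label) != 1L ||
      !(label %in% class_labels())) {
    stop_respscreen("unknown class label: %s (must be one of %s)",
                    paste(format(label), collapse = ", "),
                    paste(class_labels(), collapse = ", "),
                    class = "respscreen_contract_error")
  }
  label
}
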