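stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a stable child seed from a master seed and a string key
#'
#' Child seeds for independent pipeline stages (one per preprocessing method
#' and repeat, one per grid point of the k-means ensemble) are derived from a
#' single master seed with a polynomial string hash, so that adding a method
#' or repeat never perturbs the seeds of the others. The result is always a
#' valid 32-bit R seed.
#'
#' @param master_seed integer master seed.
#' @param ... character/numeric components of the key, e.g. a method name and
#'   a repeat index.
#' @return an integer in \[0, 2^31 - 2\].
#' @export
stable_seed <- function(master_seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  h <- as.double(as.integer(master_seed)) %% 2147483647
  if (h < 0) h <- h + 2147483647
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# All listed components must be non-NULL scalars of the given predicate.
check_scalar <- function(x, name, pred, what) {
  if (length(x) != 1L || is.na(x) || !pred(x))
    stopf("'%s' must be a single %s", name, what)
  invisible(x)
}

check_fraction <- function(x, name) {
  check_scalar(x, name, function(v) is.numeric(v) && v >= 0 && v <= 1,
               "number in [0, 1]")
}

check_count <- function(x, name, min = 1L) {
  check_scalar(x, name, function(v) is.numeric(v) && v >= min && v == floor(v),
               sprintf("integer >= %d", min))
  as.integer(x)
}
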