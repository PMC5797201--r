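# Internal helpers shared across modules.

#' @useDynLib petquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom jsonlite toJSON fromJSON write_json read_json
#' @importFrom stats rpois runif rnorm optim spline approx sd quantile rbinom
#' @importFrom utils head tail
NULL

# 32-bit FNV-1a hash of a character scalar, returned as 8-char hex string.
# Used to stamp containers with the geometry they were produced under.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256; keep h in doubles (> 2^31)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619
    lo16 <- h %% 65536
    hi16 <- (h - lo16) / 65536
    h <- (lo16 * 16777619 + (hi16 * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

check_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) stop2("%s must be TRUE or FALSE", what)
  x
}
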