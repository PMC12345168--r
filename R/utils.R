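# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_fmt(...)
  invisible(TRUE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x > 0 && x == floor(x)
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

is_nonneg <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0
}

# FNV-1a 32-bit hash of a character scalar; returned as hex string.
# Used for config hashes and input checksums in the run manifest so the
# package needs no external digest dependency.
fnv1a <- function(x) {
  # 32-bit modular multiply in doubles: split the multiplicand so no
  # intermediate exceeds 2^53.
  mul32 <- function(h, p) {
    hi <- h %/% 65536
    lo <- h %% 65536
    (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h a double since it
    # exceeds .Machine$integer.max
    h <- mul32(h - (h %% 256) + bitwXor(h %% 256, b), 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Derive a per-stage seed (< 2^31) from a global seed and a stage label.
derive_seed <- function(seed, stage) {
  h <- strtoi(substr(fnv1a(stage), 1, 7), base = 16L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
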