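# Internal helpers shared across modules: classed error conditions (the CLI
# maps them to exit codes), hierarchical seed derivation, and small numerics.

cord_stop <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "cord_error"), call = call))
}

config_error  <- function(msg) cord_stop(msg, "cord_config_error")
data_error    <- function(msg) cord_stop(msg, "cord_data_error")
numeric_error <- function(msg) cord_stop(msg, "cord_numeric_error")

#' Derive a child seed from a parent seed and integer path
#'
#' One global seed drives a hierarchical stream (embryo -> section -> cell
#' batch) so adding sections or embryos never perturbs earlier draws. The
#' mixing is a small multiplicative congruential fold kept strictly below
#' 2^31 - 1 so it is exact in double precision and valid for [set.seed()].
#'
#' @param seed integer parent seed.
#' @param ... integer path components (e.g. embryo index, level index,
#'   section index).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647           # 2^31 - 1, prime
  s <- as.numeric(seed) %% m
  for (k in c(...)) {
    # multiplier small enough that s * 7919 + k < 2^53 stays exact
    s <- (s * 7919 + as.numeric(k) + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# trapezoidal rule on an increasing grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# FNV-1a 32-bit hash of a character scalar, for config provenance.
# Arithmetic kept in doubles below 2^53 via a 16-bit split multiply.
fnv1a_hash <- function(txt) {
  bytes <- utf8ToInt(enc2utf8(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b %% 256)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor of two non-negative doubles < 2^32 without integer overflow
bitwXor_dbl <- function(a, b) {
  r <- 0; p <- 1
  for (i in 1:32) {
    r <- r + p * ((a %% 2 + b %% 2) %% 2)
    a <- a %/% 2; b <- b %/% 2; p <- p * 2
    if (a == 0 && b == 0) break
  }
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
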