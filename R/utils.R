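BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' @param x character scalar over A/C/G/T/N (case-insensitive).
#' @return character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  intToUtf8(rev(utf8ToInt(chartr("ACGTUacgtu", "TGCAAtgcaa", x))))
}

#' Random nucleotide sequence
#'
#' Uniform i.i.d. A/C/G/T string drawn from the current RNG stream.
#'
#' @param n length in bases.
#' @return character scalar of length `n`.
#' @export
random_dna <- function(n) {
  stopifnot(n >= 0)
  if (n == 0) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# stable 32-bit FNV-1a hash of a string, folded to a valid set.seed() value;
# used to derive per-gene RNG sub-streams independent of generation order
stable_seed <- function(key, base_seed) {
  bytes <- utf8ToInt(paste0(base_seed, ":", key))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor64(h, b)
    h <- mulmod32(h, 16777619)
  }
  as.integer(h %% 2147483647)
}

# xor of a value < 2^32 with a byte, exact in doubles
bitwXor64 <- function(h, b) {
  lo <- h %% 2^16
  hi <- (h - lo) / 2^16
  lo2 <- bitwXor(as.integer(lo), as.integer(b))
  hi * 2^16 + lo2
}

# (h * m) mod 2^32 without exceeding exact double precision
mulmod32 <- function(h, m) {
  lo <- h %% 2^16
  hi <- (h - lo) / 2^16
  (((hi * m) %% 2^16) * 2^16 + lo * m) %% 2^32
}

# interval columns are 0-based half-open throughout the package
check_interval <- function(start, end, what = "interval") {
  if (any(start < 0) || any(end < start)) {
    stop(sprintf("invalid %s: need 0 <= start <= end", what), call. = FALSE)
  }
  invisible(TRUE)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
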