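# Karp-Rabin style fingerprints of b-length DNA windows, reduced modulo a
# Mersenne number q = 2^w - 1. Equality of fingerprints is a necessary
# condition for equality of the windows (no false negatives); candidate hits
# are re-verified character by character downstream.

#' Fingerprint parameters
#'
#' Bundles the window length `b`, the modulus exponent `w` (giving
#' `q = 2^w - 1`), and the mismatch radius `k` of the Hamming-aware hash.
#' Only `k = 0` is supported: the witness set of fingerprint differences
#' compatible with k mismatches then collapses to `{0}` and a candidate
#' match is exact fingerprint equality. The default `q = 2^30 - 1` keeps the
#' false-positive rate of the shortlist low while fitting comfortably in
#' double-precision arithmetic.
#'
#' @param b Window length in bases (default 20).
#' @param w Modulus exponent; the modulus is `q = 2^w - 1` (default 30).
#' @param k Maximum Hamming distance the hash is allowed to miss (only 0
#'   supported; kept as a field for forward compatibility).
#' @return A list of class `fp_params` with fields `b`, `w`, `q`, `k`, `Z`
#'   (the witness set of accepted residue differences).
#' @export
fingerprint_params <- function(b = 20L, w = 30L, k = 0L) {
  stopifnot(b >= 1L, w >= 2L, w <= 52L)
  if (k != 0L)
    stop("only k = 0 (exact window match) is implemented; Z(k, q) for k > 0 is not supported")
  structure(
    list(b = as.integer(b), w = as.integer(w), q = 2^w - 1, k = 0L, Z = 0),
    class = "fp_params"
  )
}

#' @export
print.fp_params <- function(x, ...) {
  cat("fingerprint parameters: b =", x$b, " q = 2^", x$w, "- 1 =", format(x$q),
      " k =", x$k, "\n")
  invisible(x)
}

# powers of 4 (most significant digit first), exact in doubles for b <= 26
.pow4 <- function(b) 4^((b - 1L):0L)

#' Fingerprint of a b-length window
#'
#' Treats the window `s[p, ..., p + b - 1]` (0-based start `p`) as a base-4
#' number with the 2-bit base codes as digits, most significant digit first,
#' and reduces it modulo `q`. For `b <= 26` the base-4 value is accumulated
#' exactly in double precision and reduced once; longer windows fall back to
#' a Horner loop with reduction at every step (identical result).
#'
#' @param codes Integer base-code vector (see [dna_codes()]).
#' @param p 0-based start position of the window.
#' @param params An `fp_params` object.
#' @return The fingerprint, a number in `0, ..., q - 1`.
#' @export
#' @examples
#' p <- fingerprint_params(b = 4, w = 5)         # q = 31
#' fingerprint(dna_codes("ACGT"), 0, p)          # (0*64 + 1*16 + 2*4 + 3) %% 31 = 27
fingerprint <- function(codes, p, params) {
  b <- params$b
  if (p < 0 || p + b > length(codes))
    stop("fingerprint window [", p, ", ", p + b - 1, "] out of range for sequence of length ",
         length(codes))
  win <- codes[(p + 1L):(p + b)]
  if (b <= 26L) {
    sum(win * .pow4(b)) %% params$q
  } else {
    v <- 0
    for (d in win) v <- (v * 4 + d) %% params$q
    v
  }
}

# fingerprints of many windows at once: starts is a 0-based vector, all
# windows must fit. Returns a numeric vector. Exact for b <= 26 via a
# matrix product (sums stay below 2^53).
fingerprint_windows <- function(codes, starts, params) {
  b <- params$b
  if (length(starts) == 0L) return(numeric(0))
  if (any(starts < 0) || any(starts + b > length(codes)))
    stop("fingerprint window out of range")
  if (b <= 26L) {
    idx <- outer(starts, seq_len(b), `+`)      # 1-based column indices
    m <- matrix(codes[idx], nrow = length(starts))
    as.vector(m %*% .pow4(b)) %% params$q
  } else {
    vapply(starts, function(p) fingerprint(codes, p, params), numeric(1))
  }
}

#' Can two fingerprints belong to matching windows?
#'
#' With `k = 0` this is exact fingerprint equality, phrased as the residue
#' difference `(f1 - f2) mod q` lying in the witness set `Z = {0}`. A `TRUE`
#' answer is necessary but not sufficient for the windows to be identical:
#' the caller must re-verify characters.
#'
#' @param f1,f2 Fingerprints in `0, ..., q - 1`.
#' @param params An `fp_params` object.
#' @return Logical.
#' @export
candidate_match <- function(f1, f2, params) {
  ((f1 - f2) %% params$q) %in% params$Z
}
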