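# 2-bit base codes: A=0, C=1, G=2, T=3. All engine-internal sequence work is
# done on integer code vectors; the packed raw form (4 bases/byte) is the
# compact storage representation.

.BASES <- c("A", "C", "G", "T")

#' Convert a DNA string to integer base codes
#'
#' Maps A, C, G, T to the integer codes 0, 1, 2, 3 (the 2-bit encoding used
#' throughout the package). Any other character is an error: reads containing
#' ambiguous bases must be filtered before they reach the assembler.
#'
#' @param s A single character string over the alphabet ACGT (lower case
#'   accepted).
#' @return An integer vector of base codes, one element per base.
#' @seealso [dna_string()], [encode_dna()]
#' @export
#' @examples
#' dna_codes("ACGT")  # 0 1 2 3
dna_codes <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  if (nchar(s) == 0L) return(integer(0))
  raw <- charToRaw(toupper(s))
  codes <- .CHAR_LUT[as.integer(raw) + 1L]
  if (anyNA(codes)) {
    bad <- rawToChar(raw[is.na(codes)][1L])
    stop("non-ACGT character '", bad, "' in sequence; filter such reads upstream",
         call. = FALSE)
  }
  codes
}

# lookup table from ASCII byte to code (NA for everything but ACGT)
.CHAR_LUT <- {
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  lut
}

#' Convert integer base codes back to a DNA string
#'
#' @param codes Integer vector of base codes in 0..3.
#' @return A single character string.
#' @export
dna_string <- function(codes) {
  if (length(codes) == 0L) return("")
  stopifnot(all(codes >= 0L & codes <= 3L))
  paste(.BASES[codes + 1L], collapse = "")
}

#' Reverse complement of base codes
#'
#' The complement of code x is 3 - x (A<->T, C<->G), so the reverse
#' complement is an involution by construction.
#'
#' @param codes Integer vector of base codes.
#' @return Integer vector of the reverse-complemented codes.
#' @export
revcomp_codes <- function(codes) {
  if (length(codes) == 0L) return(integer(0))
  rev(3L - codes)
}

#' Pack a DNA string into the 2-bit representation
#'
#' Stores a sequence over ACGT at 2 bits per base (A=00, C=01, G=10, T=11),
#' four bases per byte, least-significant bits first within a byte. This is
#' the compact storage form of a read; [decode_dna()] inverts it exactly.
#'
#' @param s A DNA string over ACGT.
#' @return An object of class `packed_dna`: a list with `bits` (raw vector)
#'   and `length` (number of bases).
#' @export
#' @examples
#' x <- encode_dna("ACGT")
#' decode_dna(x)  # "ACGT"
encode_dna <- function(s) {
  codes <- dna_codes(s)
  n <- length(codes)
  if (n == 0L) {
    return(structure(list(bits = raw(0), length = 0L), class = "packed_dna"))
  }
  nb <- (n + 3L) %/% 4L
  padded <- c(codes, integer(nb * 4L - n))
  m <- matrix(padded, nrow = 4L)
  bytes <- as.raw(m[1L, ] + m[2L, ] * 4L + m[3L, ] * 16L + m[4L, ] * 64L)
  structure(list(bits = bytes, length = n), class = "packed_dna")
}

#' Unpack a 2-bit packed sequence
#'
#' @param x A `packed_dna` object from [encode_dna()].
#' @return The original DNA string.
#' @export
decode_dna <- function(x) {
  stopifnot(inherits(x, "packed_dna"))
  if (x$length == 0L) return("")
  v <- as.integer(x$bits)
  m <- rbind(v %% 4L, (v %/% 4L) %% 4L, (v %/% 16L) %% 4L, (v %/% 64L) %% 4L)
  dna_string(as.vector(m)[seq_len(x$length)])
}

#' Reverse complement
#'
#' Generic reverse complement for DNA strings and `packed_dna` objects.
#' `revcomp(revcomp(s))` equals `s` for every input.
#'
#' @param x A DNA character string or a `packed_dna` object.
#' @return An object of the same type as the input.
#' @export
revcomp <- function(x) UseMethod("revcomp")

#' @export
revcomp.character <- function(x) {
  stopifnot(length(x) == 1L)
  dna_string(revcomp_codes(dna_codes(x)))
}

#' @export
revcomp.packed_dna <- function(x) {
  encode_dna(dna_string(revcomp_codes(dna_codes(decode_dna(x)))))
}

#' @export
print.packed_dna <- function(x, ...) {
  s <- decode_dna(x)
  shown <- if (nchar(s) > 60L) paste0(substr(s, 1L, 60L), "...") else s
  cat("<packed_dna> ", x$length, " bases: ", shown, "\n", sep = "")
  invisible(x)
}
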