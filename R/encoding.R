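#' 2-bit integer encoding of q-mers
#'
#' Maps a q-mer over `{A,C,G,T}` to its base-4 positional code with digit map
#' A=0, C=1, G=2, T=3, most significant digit first. This is the hash key used
#' by the seed index; the key space has size `4^q`. Codes are returned as
#' doubles so that `q` up to 26 stays exactly representable.
#'
#' @param s A DNA string over `{A,C,G,T}`.
#' @return A numeric code in `[0, 4^q)`.
#' @examples
#' encode_kmer("ACGT")  # 27
#' @export
encode_kmer <- function(s) {
  if (length(s) != 1L || !is.character(s))
    stop("`s` must be a single string", call. = FALSE)
  digits <- kmer_digits(s)
  if (length(digits) > 25L)
    stop("k-mers longer than 25 are not supported (code space 4^q must stay ",
         "exactly representable)", call. = FALSE)
  bad <- which(is.na(digits))
  if (length(bad))
    stop("invalid character '", substr(s, bad[1L], bad[1L]),
         "' at position ", bad[1L], call. = FALSE)
  q <- length(digits)
  sum(digits * 4^((q - 1L):0))
}

# base-4 digits of a DNA string; NA for characters outside {A,C,G,T}
kmer_digits <- function(s) {
  codes <- utf8ToInt(s)
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  ifelse(codes < 128L, lut[codes + 1L], NA_integer_)
}

#' Decode a q-mer code back to its DNA string
#'
#' Inverse of [encode_kmer()].
#'
#' @param code Numeric code in `[0, 4^q)`.
#' @param q The k-mer length.
#' @return The DNA string of length `q`.
#' @examples
#' decode_kmer(27, 4)  # "ACGT"
#' @export
decode_kmer <- function(code, q) {
  code <- as.numeric(code); q <- as.integer(q)
  if (length(code) != 1L || is.na(code) || code < 0 || code >= 4^q ||
      code != floor(code))
    stop("code must be an integer in [0, 4^q)", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  out <- character(q)
  for (i in q:1) {
    out[i] <- bases[code %% 4 + 1]
    code <- code %/% 4
  }
  paste(out, collapse = "")
}

#' Hamming-ball neighbourhood of a q-mer in code space
#'
#' Enumerates the m-mutant list of a q-mer: every code whose decoded string
#' lies at Hamming distance between 1 and `m` from the input. The input code
#' itself is excluded (the identity match is handled by the same-bucket pass
#' of the search engine), so the list has exactly `3q` entries for `m = 1` and
#' `9q(q-1)/2 + 3q` entries for `m = 2`.
#'
#' Mutants are generated by digit substitution on the base-4 representation,
#' in deterministic order: increasing mutated position (most significant
#' first), then increasing substituted digit; for `m = 2`, position pairs in
#' lexicographic order with the same digit order nested.
#'
#' @param code Numeric q-mer code.
#' @param q The k-mer length.
#' @param m Mutant radius, 1 or 2.
#' @return Numeric vector of mutant codes, no duplicates.
#' @examples
#' length(mutant_codes(encode_kmer("ACGT"), 4, 1))  # 3*4 = 12
#' @export
mutant_codes <- function(code, q, m) {
  q <- as.integer(q); m <- as.integer(m)
  if (!m %in% c(1L, 2L))
    stop("`m` must be 1 or 2", call. = FALSE)
  if (length(code) != 1L || is.na(code) || code < 0 || code >= 4^q)
    stop("code must be in [0, 4^q)", call. = FALSE)
  pw <- 4^((q - 1L):0)               # place value of each position
  dig <- integer(q)
  c0 <- code
  for (i in q:1) { dig[i] <- c0 %% 4; c0 <- c0 %/% 4 }

  out <- numeric(if (m == 1L) 3L * q else 9L * q * (q - 1L) / 2L + 3L * q)
  idx <- 0L
  for (i in seq_len(q)) {
    for (a in 0:3) {
      if (a == dig[i]) next
      idx <- idx + 1L
      out[idx] <- code + (a - dig[i]) * pw[i]
    }
  }
  if (m == 2L) {
    for (i in seq_len(q - 1L)) {
      for (j in (i + 1L):q) {
        for (a in 0:3) {
          if (a == dig[i]) next
          for (b in 0:3) {
            if (b == dig[j]) next
            idx <- idx + 1L
            out[idx] <- code + (a - dig[i]) * pw[i] + (b - dig[j]) * pw[j]
          }
        }
      }
    }
  }
  out
}
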