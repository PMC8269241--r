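# Internal sequence utilities. Sequences are plain upper-case character
# strings over A/C/G/T (other letters tolerated where stated); the integer
# encoding A=0, C=1, G=2, T=3 backs all k-mer arithmetic.

.BASES <- c("A", "C", "G", "T")

# lookup table: utf8 code -> base integer (NA for non-ACGT)
.base_lut <- local({
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("a")] <- 0L
  lut[utf8ToInt("C")] <- 1L; lut[utf8ToInt("c")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("g")] <- 2L
  lut[utf8ToInt("T")] <- 3L; lut[utf8ToInt("t")] <- 3L
  lut
})

seq_to_int <- function(s) {
  u <- utf8ToInt(s)
  u[u > 128L] <- 1L  # maps to NA slot
  .base_lut[u]
}

int_to_seq <- function(x) {
  intToUtf8(utf8ToInt("ACGT")[x + 1L])
}

#' Reverse complement of a DNA string
#'
#' @param s A character scalar over A/C/G/T (case preserved per base map).
#' @return The reverse complement as a character scalar.
#' @export
#' @examples
#' revcomp("ACCGT")
revcomp <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", s))))
}

# Rolling k-mer codes (base-4) for an integer-encoded sequence.
# Windows containing non-ACGT (NA) positions get NA codes.
kmer_codes <- function(xint, k) {
  n <- length(xint)
  if (n < k) return(integer(0))
  code <- xint[seq_len(n - k + 1L)]
  for (j in 2:k) {
    code <- code * 4L + xint[j:(n - k + j)]
  }
  code
}

# Deterministic child-seed derivation: one user-facing seed expands into
# per-component seeds via a tagged mix, all < 2^31.
child_seed <- function(seed, tag) {
  h <- as.double(seed %% 2147483647L)
  for (u in utf8ToInt(tag)) {
    h <- (h * 131 + u) %% 2147483629
  }
  as.integer(h %% 2147483587) + 1L
}

# Uniform random DNA of length n (requires an initialized RNG state).
random_dna <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# Substitute exactly the positions `pos` (1-based) of integer-encoded x with
# a uniformly chosen different base.
mutate_positions <- function(xint, pos) {
  if (length(pos) == 0L) return(xint)
  shift <- sample.int(3L, length(pos), replace = TRUE)
  xint[pos] <- (xint[pos] + shift) %% 4L
  xint
}

# Hamming identity of two equal-length integer-encoded sequences.
hamming_identity <- function(a, b) {
  stopifnot(length(a) == length(b))
  mean(a == b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
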