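# One-hot encoding. Channel order A,C,G,T; N (and any non-ACGT base) is an
# all-zero row, encoding absence of evidence rather than a uniform prior.

# lookup indexed by UTF-8 code + 1
.base_lut <- local({
  lut <- rep(4L, 256L)
  lut[utf8ToInt("Aa") + 1L] <- 0L
  lut[utf8ToInt("Cc") + 1L] <- 1L
  lut[utf8ToInt("Gg") + 1L] <- 2L
  lut[utf8ToInt("Tt") + 1L] <- 3L
  lut
})

# Integer codes (0=A,1=C,2=G,3=T,4=N) for one sequence, centered in L:
# shorter sequences are padded with N symmetrically (extra base on the
# right), longer sequences are center-cropped.
seq_to_codes <- function(seq, L) {
  codes <- .base_lut[utf8ToInt(seq) + 1L]
  n <- length(codes)
  if (n > L) {
    off <- (n - L) %/% 2L
    codes <- codes[(off + 1L):(off + L)]
  } else if (n < L) {
    left <- (L - n) %/% 2L
    codes <- c(rep(4L, left), codes, rep(4L, L - n - left))
  }
  codes
}

# Codes matrix (L x n), one column per sequence.
seqs_to_code_matrix <- function(seqs, L) {
  vapply(seqs, seq_to_codes, integer(L), L = L, USE.NAMES = FALSE)
}

#' One-hot encode a DNA sequence
#'
#' Encodes a sequence into an `L x 4` matrix over channel order A, C, G, T.
#' The sequence is centered in `L`: shorter sequences are zero-padded
#' symmetrically, longer sequences are center-cropped. `N` (or any
#' non-ACGT character) becomes an all-zero row.
#'
#' @param seq Nucleotide string.
#' @param L Target length in bp.
#' @return Numeric matrix of shape `(L, 4)` with row sums in `{0, 1}`.
#' @examples
#' one_hot_encode("AC", 4) # zero row, A, C, zero row
#' @export
one_hot_encode <- function(seq, L = nchar(seq)) {
  codes <- seq_to_codes(seq, L)
  out <- matrix(0, nrow = L, ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  keep <- codes < 4L
  out[cbind(which(keep), codes[keep] + 1L)] <- 1
  out
}

# Reverse complement on code matrices (columns = sequences).
rc_code_matrix <- function(codes) {
  codes <- codes[rev(seq_len(nrow(codes))), , drop = FALSE]
  acgt <- codes < 4L
  codes[acgt] <- 3L - codes[acgt]
  codes
}
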