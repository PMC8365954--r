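# Genome sequences are held as a Biostrings DNAStringSet; all fetches are
# bounds-checked against the 0-based half-open interval convention.

#' Read a genome FASTA
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return A `Biostrings::DNAStringSet` named by chromosome.
#' @export
read_genome_fasta <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  genome <- Biostrings::readDNAStringSet(path)
  # drop FASTA description text after the first whitespace
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Write a genome FASTA
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @return Named integer vector of lengths (bp).
#' @export
chrom_lengths <- function(genome) {
  if (is.character(genome)) {
    stats::setNames(nchar(genome), names(genome))
  } else {
    stats::setNames(Biostrings::width(genome), names(genome))
  }
}

#' Fetch the sequence of an interval
#'
#' Returns the uppercase sequence of a 0-based half-open interval.
#' Characters outside `{A,C,G,T}` (ambiguity codes, soft-masked leftovers)
#' are mapped to `N`; lowercase (soft-masked) bases are uppercased rather
#' than masked. Out-of-bounds intervals and unknown chromosomes are errors.
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start.
#' @param end Exclusive end.
#' @return Character scalar of length `end - start`.
#' @export
fetch_sequence <- function(genome, chrom, start, end) {
  lens <- chrom_lengths(genome)
  stop_if(!chrom %in% names(lens), "unknown chromosome: ", chrom)
  stop_if(start < 0 || end > lens[[chrom]] || start >= end,
          "interval [", start, ",", end, ") out of bounds on ", chrom,
          " (length ", lens[[chrom]], ")")
  s <- if (is.character(genome)) {
    substr(genome[[chrom]], start + 1L, end)
  } else {
    as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
  }
  s <- toupper(s)
  gsub("[^ACGT]", "N", s)
}

#' Reverse complement
#'
#' Involution over the alphabet `{A,C,G,T,N}`; `N` is a fixed point.
#' Vectorized. Characters outside the alphabet are an error.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Reverse-complemented strings of the same lengths.
#' @examples
#' reverse_complement("AAGC") # "GCTT"
#' @export
reverse_complement <- function(seq) {
  bad <- grepl("[^ACGTN]", seq)
  stop_if(any(bad), "unknown character in sequence: ",
          substr(seq[bad][1L], 1L, 30L))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  names(out) <- names(seq)
  out
}
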