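#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a DNA sequence with the standard genetic code
#'
#' Translates complete codons from the first base; a trailing partial codon is
#' ignored. Stop codons translate to `*`.
#'
#' @param x a single DNA string.
#' @return single amino-acid string (may contain `*`).
#' @export
translate_dna <- function(x) {
  stopifnot(length(x) == 1L)
  n <- nchar(x) %/% 3L
  if (n == 0L) return("")
  codons <- substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[toupper(codons)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# one-letter -> three-letter amino-acid codes (HGVS protein naming)
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln", E = "Glu",
  G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys", M = "Met", F = "Phe",
  P = "Pro", S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val", `*` = "Ter")

aa1to3 <- function(aa) {
  out <- AA_THREE[strsplit(aa, "")[[1L]]]
  if (anyNA(out)) stop("unknown amino-acid code in: ", aa)
  paste(out, collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

is_dna <- function(x) grepl("^[ACGTN]*$", x)

#' Read sequences from a FASTA file
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(s)), names(s))
}

#' Write sequences to a FASTA file
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file (optionally gzipped)
#' @param path FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(toupper(as.character(s)), names(s))
}

#' Write reads to a FASTQ file with constant quality
#' @param seqs named character vector of reads.
#' @param path output file.
#' @param quality_char single quality character applied to every base.
#' @export
write_fastq <- function(seqs, path, quality_char = "I") {
  set <- Biostrings::DNAStringSet(seqs)
  quals <- Biostrings::BStringSet(strrep(quality_char, nchar(seqs)))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = quals)
  invisible(path)
}
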