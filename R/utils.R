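#' @useDynLib vdjprof, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rgeom runif setNames aggregate
#' @importFrom utils write.table read.table
NULL

LOCI <- c("TRA", "TRB", "IGH", "IGK", "IGL")
D_LOCI <- c("TRB", "IGH")
DNA_BASES <- c("A", "C", "G", "T")

#' Translate nucleotide sequences in frame 1
#'
#' Translates each sequence from its first base; trailing bases that do not
#' complete a codon are dropped. Codons containing `N` translate to `X`.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of amino-acid sequences (`*` marks stop codons).
#' @export
translate_nt <- function(x) {
  x <- as.character(x)
  out <- character(length(x))
  nz <- nchar(x) >= 3L
  if (any(nz)) {
    trimmed <- substr(x[nz], 1L, (nchar(x[nz]) %/% 3L) * 3L)
    aa <- Biostrings::translate(Biostrings::DNAStringSet(trimmed),
                                if.fuzzy.codon = "X")
    out[nz] <- as.character(aa)
  }
  out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random nucleotide strings
#' @noRd
random_nt <- function(n, len, probs = rep(0.25, 4)) {
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i) {
    if (len[min(i, length(len))] == 0L) return("")
    paste(sample(DNA_BASES, len[min(i, length(len))], replace = TRUE,
                 prob = probs), collapse = "")
  }, character(1))
}

phred_to_int <- function(q) {
  lapply(q, function(s) utf8ToInt(s) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
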