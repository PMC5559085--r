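# Shared fixtures: tiny germline databases and plain-text FASTQ/FASTA
# writers, all built in code.

tiny_trb_db <- function(seed = 5) {
  synthetic_germline_db("TRB", n_v = 6, n_d = 2, n_j = 3, seed = seed)
}

tiny_tra_db <- function(seed = 7) {
  synthetic_germline_db("TRA", n_v = 4, n_j = 3, seed = seed)
}

tiny_igh_db <- function(seed = 9) {
  synthetic_germline_db("IGH", n_v = 4, n_d = 2, n_j = 3, seed = seed)
}

qstring <- function(q) intToUtf8(q + 33L)

write_fastq_file <- function(path, ids, seqs, quals) {
  lines <- as.vector(rbind(paste0("@", ids), seqs,
                           "+", vapply(quals, qstring, character(1))))
  writeLines(lines, path)
  path
}

write_fasta_file <- function(path, seqs) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

# read-pair list straight from in-memory vectors (phred ints)
make_pairs <- function(seq1, seq2, qual1 = NULL, qual2 = NULL,
                       ids = NULL) {
  n <- length(seq1)
  if (is.null(qual1)) qual1 <- lapply(nchar(seq1), function(L) rep(30L, L))
  if (is.null(qual2)) qual2 <- lapply(nchar(seq2), function(L) rep(30L, L))
  if (is.null(ids)) ids <- sprintf("r%03d", seq_len(n))
  list(read_id = ids, seq1 = seq1, seq2 = seq2, qual1 = qual1,
       qual2 = qual2)
}

# one-row V gene record for fr3_span / anchor tests
gene_row <- function(seq, segment = "V", functional = TRUE,
                     anchor = NA_integer_, name = "G1", locus = "TRB") {
  data.frame(gene_name = name, locus = locus, segment = segment,
             sequence = seq, functional = functional, anchor_pos = anchor,
             fr3_start = NA_integer_, fr3_end = NA_integer_,
             stringsAsFactors = FALSE)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# mutation_profiles object built directly from per-position counts
make_profiles <- function(df, codon = NULL) {
  if (is.null(codon))
    codon <- data.frame(gene_name = character(0), codon = integer(0),
                        coverage = numeric(0), mismatches = numeric(0))
  structure(list(nt = df, codon = codon), class = "mutation_profiles")
}

profile_row <- function(gene, pos, ref, cov, alt_counts) {
  counts <- setNames(rep(0, 4), c("A", "C", "G", "T"))
  counts[names(alt_counts)] <- alt_counts
  counts[ref] <- cov - sum(alt_counts)
  data.frame(gene_name = gene, position = pos, ref_base = ref,
             coverage = cov, mismatches = sum(alt_counts),
             A = counts[["A"]], C = counts[["C"]], G = counts[["G"]],
             T = counts[["T"]], stringsAsFactors = FALSE)
}
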