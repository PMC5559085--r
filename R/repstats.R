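# Repertoire summary statistics: usage, CDR3 length/rank/composition,
# junction indel length distributions, inserted-nucleotide composition.

weight_counts <- function(table, weight) {
  if (weight == "read") table$read_count else rep(1L, nrow(table))
}

#' Gene usage frequencies
#'
#' Relative usage of each V gene, J gene, or V-J pair, weighted by read
#' abundance (each sequence counts toward the gene it aligned best with) or,
#' optionally, by distinct clonotype.
#'
#' @param table clonotype table from [repertoire_table()].
#' @param axis `"V"`, `"J"`, or `"VJ"`.
#' @param weight `"read"` (default) or `"clonotype"`.
#' @return A data frame of genes (or pairs) and `frequency` summing to 1.
#' @export
usage_frequencies <- function(table, axis = c("V", "J", "VJ"),
                              weight = c("read", "clonotype")) {
  axis <- match.arg(axis)
  weight <- match.arg(weight)
  if (nrow(table) == 0L) stop("empty repertoire table")
  w <- weight_counts(table, weight)
  key <- switch(axis, V = list(v_gene = table$v_gene),
                J = list(j_gene = table$j_gene),
                VJ = list(v_gene = table$v_gene, j_gene = table$j_gene))
  out <- aggregate(list(weight = w), by = key, FUN = sum)
  out$frequency <- out$weight / sum(out$weight)
  out$weight <- NULL
  out <- out[do.call(order, unname(out[setdiff(names(out), "frequency")])), ]
  rownames(out) <- NULL
  out
}

#' CDR3 length distribution
#'
#' @param table clonotype table.
#' @param unit `"aa"` or `"nt"`.
#' @param weight `"read"` or `"clonotype"`.
#' @return A data frame (`length`, `frequency`) with frequencies summing
#'   to 1.
#' @export
cdr3_length_distribution <- function(table, unit = c("aa", "nt"),
                                     weight = c("read", "clonotype")) {
  unit <- match.arg(unit)
  weight <- match.arg(weight)
  len <- if (unit == "aa") nchar(table$cdr3_aa) else nchar(table$cdr3_nt)
  w <- weight_counts(table, weight)
  out <- aggregate(list(weight = w), by = list(length = len), FUN = sum)
  out$frequency <- out$weight / sum(out$weight)
  out$weight <- NULL
  out[order(out$length), ]
}

#' Clonotype rank-abundance curve
#'
#' Clonotype frequencies sorted from highest to lowest; frequency ties are
#' broken by CDR3 nucleotide lexicographic order.
#'
#' @param table clonotype table.
#' @return A data frame (`rank`, `cdr3_nt`, `v_gene`, `j_gene`,
#'   `frequency`).
#' @export
rank_abundance <- function(table) {
  if (nrow(table) == 0L) stop("empty repertoire table")
  ord <- order(-table$read_count, table$cdr3_nt)
  data.frame(rank = seq_len(nrow(table)),
             cdr3_nt = table$cdr3_nt[ord], v_gene = table$v_gene[ord],
             j_gene = table$j_gene[ord],
             frequency = table$read_count[ord] / sum(table$read_count),
             stringsAsFactors = FALSE)
}

#' Amino-acid composition of the CDR3 repertoire
#'
#' Read-weighted frequency of each of the 20 amino acids pooled over all
#' CDR3 positions.
#'
#' @param table clonotype table with `cdr3_aa`.
#' @param weight `"read"` or `"clonotype"`.
#' @return A data frame (`aa`, `frequency`), frequencies summing to 1.
#' @export
aa_composition <- function(table, weight = c("read", "clonotype")) {
  weight <- match.arg(weight)
  w <- weight_counts(table, weight)
  aas <- strsplit(table$cdr3_aa, "")
  # weighted pooling: expand letters by clonotype weight
  letters_all <- unlist(mapply(function(a, k) rep(a, k), aas, w,
                               SIMPLIFY = FALSE))
  counts <- table(factor(letters_all, levels = AA20))
  data.frame(aa = AA20, frequency = as.numeric(counts) / sum(counts))
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

#' Junction indel length distributions
#'
#' One read-weighted length histogram per applicable junction section: 3'-V
#' deletion, 5'-J deletion and, for D loci, 5'-D/3'-D deletions and V-D/D-J
#' insertions; for loci without D, the single V-J insertion.
#'
#' @param ann annotation frame with junction fields (one row per read).
#' @return A data frame (`section`, `length`, `frequency`); frequencies sum
#'   to 1 within each section.
#' @export
junction_indel_distributions <- function(ann) {
  has_d <- any(!is.na(ann$d_gene))
  locus_d <- ann$locus[1] %in% D_LOCI
  sections <- if (locus_d)
    list(del_3v = ann$del_3v, del_5d = ann$del_5d, del_3d = ann$del_3d,
         del_5j = ann$del_5j, ins_vd = nchar(ann$ins_vd),
         ins_dj = nchar(ann$ins_dj))
  else
    list(del_3v = ann$del_3v, del_5j = ann$del_5j,
         ins_vj = nchar(ann$ins_vj))
  out <- do.call(rbind, lapply(names(sections), function(s) {
    x <- sections[[s]]
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NULL)
    tb <- table(x)
    data.frame(section = s, length = as.integer(names(tb)),
               frequency = as.numeric(tb) / sum(tb),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Composition of inserted nucleotides
#'
#' Pooled base frequencies over every non-template inserted nucleotide in
#' all insertion sections.
#'
#' @param ann annotation frame with insertion fields.
#' @return A data frame (`base`, `frequency`) summing to 1, or a zero-row
#'   frame with attribute `undefined = TRUE` when no insertions exist.
#' @export
inserted_nt_composition <- function(ann) {
  ins <- c(ann$ins_vd, ann$ins_dj, ann$ins_vj)
  ins <- ins[!is.na(ins) & nzchar(ins)]
  if (length(ins) == 0L) {
    out <- data.frame(base = DNA_BASES, frequency = NA_real_)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  counts <- table(factor(unlist(strsplit(ins, "")), levels = DNA_BASES))
  data.frame(base = DNA_BASES, frequency = as.numeric(counts) / sum(counts))
}

#' Fraction of the possible V-J pairing space observed
#'
#' @param table clonotype table.
#' @param n_v,n_j functional gene counts defining the possible space.
#' @return Observed distinct V-J pairs divided by `n_v * n_j`.
#' @export
fraction_combinations_captured <- function(table, n_v, n_j) {
  obs <- nrow(unique(table[, c("v_gene", "j_gene")]))
  obs / count_possible_pairings(n_v, n_j)
}
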