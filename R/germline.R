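# Germline V/(D)/J database handling: FASTA reading, conserved-motif
# functionality filtering, anchor and FR3 coordinates.

#' Read germline genes from a FASTA file
#'
#' Reads one segment of a germline database. The token before the first
#' whitespace in each FASTA header becomes the gene name; lowercase bases are
#' uppercased. IMGT-gapped references (containing `.`) are degapped; the FR3
#' span (gapped positions 196-310) is mapped onto the degapped sequence and
#' kept in `fr3_start`/`fr3_end`.
#'
#' @param path path to a FASTA file.
#' @param locus one of `"TRA"`, `"TRB"`, `"IGH"`, `"IGK"`, `"IGL"`.
#' @param segment one of `"V"`, `"D"`, `"J"`.
#' @return A data frame with one row per gene: `gene_name`, `locus`,
#'   `segment`, `sequence`, `functional` (all `FALSE` until
#'   [filter_functional()] is applied), `anchor_pos`, `fr3_start`, `fr3_end`.
#' @export
read_germline_fasta <- function(path, locus, segment) {
  locus <- match.arg(locus, LOCI)
  segment <- match.arg(segment, c("V", "D", "J"))
  if (!file.exists(path)) stop("germline FASTA not found: ", path)
  recs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("malformed FASTA '", path, "': ",
                                            conditionMessage(e), call. = FALSE))
  if (length(recs) == 0L) {
    warning("empty germline FASTA: ", path)
    return(empty_gene_table())
  }
  names(recs) <- sub("\\s.*$", "", names(recs))
  seqs <- toupper(as.character(recs))
  fr3_start <- rep(NA_integer_, length(seqs))
  fr3_end <- rep(NA_integer_, length(seqs))
  gapped <- grepl(".", seqs, fixed = TRUE)
  for (i in which(gapped)) {
    keep <- strsplit(seqs[i], "")[[1]] != "."
    map <- cumsum(keep)            # gapped position -> degapped position
    if (length(map) >= 196L) {
      fr3_start[i] <- map[196L] + as.integer(!keep[196L])
      fr3_end[i] <- map[min(310L, length(map))]
    }
    seqs[i] <- gsub(".", "", seqs[i], fixed = TRUE)
  }
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop("non-ACGT symbol in germline gene(s): ",
         paste(names(recs)[bad], collapse = ", "))
  }
  if (anyDuplicated(names(recs))) {
    stop("duplicated gene names in ", path, ": ",
         paste(unique(names(recs)[duplicated(names(recs))]), collapse = ", "))
  }
  data.frame(
    gene_name = names(recs), locus = locus, segment = segment,
    sequence = unname(seqs), functional = FALSE, anchor_pos = NA_integer_,
    fr3_start = fr3_start, fr3_end = fr3_end,
    stringsAsFactors = FALSE
  )
}

empty_gene_table <- function() {
  data.frame(gene_name = character(0), locus = character(0),
             segment = character(0), sequence = character(0),
             functional = logical(0), anchor_pos = integer(0),
             fr3_start = integer(0), fr3_end = integer(0),
             stringsAsFactors = FALSE)
}

#' Keep germline genes carrying the conserved CDR3 anchor motif
#'
#' V genes are kept when an in-frame cysteine codon (`TGT`/`TGC`, frame
#' defined from position 1 of the reference) starts within the last 30
#' nucleotides; the rightmost such codon becomes the anchor. J genes are kept
#' when some reading frame contains the \[FW\]GXG motif; the 5'-most hit
#' (across all three frames) becomes the anchor. Kept genes get
#' `functional = TRUE` and `anchor_pos` set to the first nucleotide of the
#' motif codon.
#'
#' @param genes gene table as returned by [read_germline_fasta()].
#' @param segment `"V"` or `"J"`. D genes are not motif-filtered.
#' @return The filtered gene table.
#' @export
filter_functional <- function(genes, segment) {
  segment <- match.arg(segment, c("V", "J", "D"))
  if (segment == "D") stop("D genes are not motif-filtered")
  if (nrow(genes) == 0L) return(genes)
  anchor <- vapply(genes$sequence, function(s) {
    if (segment == "V") v_anchor(s) else j_anchor(s)
  }, integer(1), USE.NAMES = FALSE)
  keep <- !is.na(anchor)
  out <- genes[keep, , drop = FALSE]
  out$functional <- rep(TRUE, nrow(out))
  out$anchor_pos <- anchor[keep]
  rownames(out) <- NULL
  out
}

# rightmost in-frame TGT/TGC codon starting within the last 30 nt, or NA
v_anchor <- function(seq) {
  n <- nchar(seq)
  starts <- seq.int(1L, n - 2L, by = 3L)
  starts <- starts[starts >= n - 29L]
  if (length(starts) == 0L) return(NA_integer_)
  codons <- substring(seq, starts, starts + 2L)
  hit <- starts[codons %in% c("TGT", "TGC")]
  if (length(hit) == 0L) NA_integer_ else max(hit)
}

# 5'-most [FW]GXG across the three frames: nt position of the [FW] codon
j_anchor <- function(seq) {
  best <- NA_integer_
  for (f in 1:3) {
    aa <- translate_nt(substring(seq, f))
    m <- regexpr("[FW]G.G", aa)
    if (m > 0L) {
      nt <- f + 3L * (as.integer(m) - 1L)
      if (is.na(best) || nt < best) best <- nt
    }
  }
  best
}

#' Assemble a per-locus germline database
#'
#' @param locus locus code.
#' @param v,j functional-filtered V and J gene tables.
#' @param d D gene table, required for TRB/IGH and forbidden otherwise.
#' @param version_tag free-text database version label.
#' @return An object of class `germline_db` with elements `locus`, `v`, `d`,
#'   `j`, `version_tag`.
#' @export
germline_db <- function(locus, v, j, d = NULL, version_tag = "unversioned") {
  locus <- match.arg(locus, LOCI)
  if (!(locus %in% D_LOCI)) {
    if (!is.null(d) && nrow(d) > 0L)
      stop(locus, " databases must not contain D genes")
    d <- empty_gene_table()
  } else if (is.null(d)) {
    d <- empty_gene_table()
  }
  all_names <- c(v$gene_name, d$gene_name, j$gene_name)
  if (anyDuplicated(all_names))
    stop("gene names must be unique within a database")
  structure(list(locus = locus, v = v, d = d, j = j,
                 version_tag = version_tag),
            class = "germline_db")
}

#' @export
print.germline_db <- function(x, ...) {
  cat(sprintf("<germline_db %s: %d V, %d D, %d J genes (%s)>\n", x$locus,
              nrow(x$v), nrow(x$d), nrow(x$j), x$version_tag))
  invisible(x)
}

#' FR3 coordinates on a V reference
#'
#' Under the IMGT unique numbering the FR3 of a V gene spans nucleotides
#' 196-310. The span is clipped to the reference length; references degapped
#' on read keep their gapped-numbering FR3 via `fr3_start`/`fr3_end`.
#'
#' @param gene a single-row V gene record (functional).
#' @return Named integer vector `c(start, end)`, 1-based inclusive.
#' @export
fr3_span <- function(gene) {
  stopifnot(nrow(gene) == 1L, gene$segment == "V")
  if (!isTRUE(gene$functional)) stop("fr3_span requires a functional V gene")
  n <- nchar(gene$sequence)
  start <- if (!is.na(gene$fr3_start)) gene$fr3_start else 196L
  end <- if (!is.na(gene$fr3_end)) gene$fr3_end else 310L
  if (n < start) stop("no FR3: V reference '", gene$gene_name,
                      "' is shorter than ", start, " nt")
  c(start = start, end = min(end, n))
}

#' Size of the possible V-J pairing space
#'
#' @param n_v,n_j numbers of functional V and J genes.
#' @return `n_v * n_j`.
#' @export
count_possible_pairings <- function(n_v, n_j) {
  stopifnot(n_v >= 0, n_j >= 0)
  n_v * n_j
}

#' Write a germline gene table to TSV
#'
#' @param db a `germline_db`.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_gene_table <- function(db, path) {
  stopifnot(inherits(db, "germline_db"))
  g <- rbind(db$v, db$d, db$j)
  out <- data.frame(gene_name = g$gene_name, locus = g$locus,
                    segment = g$segment, length = nchar(g$sequence),
                    functional = g$functional, anchor_pos = g$anchor_pos)
  write_tsv(out, path)
  invisible(path)
}
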