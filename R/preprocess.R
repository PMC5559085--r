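# Read quality control and pair merging.

#' Read a pair of FASTQ files
#'
#' @param path1,path2 paths to the mate-1 and mate-2 FASTQ files (phred+33).
#' @return A list with `read_id`, `seq1`, `seq2` (character vectors) and
#'   `qual1`, `qual2` (lists of integer phred scores).
#' @export
read_fastq_pair <- function(path1, path2) {
  read_quiet <- function(p) {
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(p),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  f1 <- read_quiet(path1)
  f2 <- read_quiet(path2)
  if (length(f1) != length(f2))
    stop("mate files differ in read count")
  ids <- sub("/[12]$", "", sub("\\s.*$", "", names(f1)))
  suppressWarnings(list(
    read_id = ids,
    seq1 = as.character(f1), seq2 = as.character(f2),
    qual1 = as.list(as(Biostrings::quality(f1), "IntegerList")),
    qual2 = as.list(as(Biostrings::quality(f2), "IntegerList"))))
}

#' Quality-filter read pairs
#'
#' A pair is dropped when either mate has an arithmetic mean phred score
#' below `min_mean_q` or an `N` fraction above `max_n_frac`.
#'
#' @param pairs read-pair list from [read_fastq_pair()].
#' @param min_mean_q minimum mean phred quality per mate (default 15).
#' @param max_n_frac maximum tolerated `N` base fraction per mate
#'   (default 0.05).
#' @return A data frame with `read_id`, `keep`, and `reason`
#'   (`ok`, `low_quality`, or `n_excess`).
#' @export
quality_filter <- function(pairs, min_mean_q = 15, max_n_frac = 0.05) {
  n1 <- nchar(pairs$seq1)
  n2 <- nchar(pairs$seq2)
  if (any(lengths(pairs$qual1) != n1) || any(lengths(pairs$qual2) != n2))
    stop("sequence/quality length mismatch")
  mq1 <- vapply(pairs$qual1, mean, numeric(1))
  mq2 <- vapply(pairs$qual2, mean, numeric(1))
  nf1 <- count_n(pairs$seq1) / n1
  nf2 <- count_n(pairs$seq2) / n2
  low_q <- mq1 < min_mean_q | mq2 < min_mean_q
  n_exc <- nf1 > max_n_frac | nf2 > max_n_frac
  reason <- ifelse(low_q, "low_quality", ifelse(n_exc, "n_excess", "ok"))
  data.frame(read_id = pairs$read_id, keep = reason == "ok",
             reason = reason, stringsAsFactors = FALSE)
}

count_n <- function(x) {
  nchar(x) - nchar(gsub("N", "", x, fixed = TRUE))
}

#' Merge read pairs by exhaustive overlap search
#'
#' Mate 2 is reverse-complemented, then every overlap offset is scored; the
#' offset with the most matched bases wins (ties toward the longest overlap)
#' provided the overlap is at least `min_overlap` with a mismatch rate at
#' most `max_mismatch_rate`. At disagreeing positions the higher-quality base
#' is taken. `N` bases neither match nor mismatch.
#'
#' @param pairs read-pair list from [read_fastq_pair()], usually already
#'   quality-filtered (subset with [subset_pairs()]).
#' @param min_overlap minimum overlap length (default 10).
#' @param max_mismatch_rate maximum overlap mismatch fraction (default 0.1).
#' @return A data frame with `read_id`, `merged`, `sequence`, `overlap_len`,
#'   `n_mismatches_in_overlap`. Unmerged pairs keep `NA` fields.
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, max_mismatch_rate = 0.1) {
  s2rc <- revcomp(pairs$seq2)
  q2r <- lapply(pairs$qual2, rev)
  n <- length(pairs$seq1)
  sequence <- rep(NA_character_, n)
  overlap <- rep(NA_integer_, n)
  mism <- rep(NA_integer_, n)
  merged <- logical(n)
  for (i in seq_len(n)) {
    res <- cpp_merge_pair(pairs$seq1[i], s2rc[i], pairs$qual1[[i]], q2r[[i]],
                          min_overlap, max_mismatch_rate)
    if (isTRUE(res$merged)) {
      merged[i] <- TRUE
      sequence[i] <- res$sequence
      overlap[i] <- res$overlap_len
      mism[i] <- res$n_mismatches_in_overlap
    }
  }
  data.frame(read_id = pairs$read_id, merged = merged, sequence = sequence,
             overlap_len = overlap, n_mismatches_in_overlap = mism,
             stringsAsFactors = FALSE)
}

#' Subset a read-pair list
#' @param pairs read-pair list.
#' @param keep logical or integer index.
#' @return The subset read-pair list.
#' @export
subset_pairs <- function(pairs, keep) {
  list(read_id = pairs$read_id[keep], seq1 = pairs$seq1[keep],
       seq2 = pairs$seq2[keep], qual1 = pairs$qual1[keep],
       qual2 = pairs$qual2[keep])
}

#' QC and merge a pair of FASTQ files
#'
#' @param path1,path2 paired FASTQ files.
#' @param min_mean_q,max_n_frac see [quality_filter()].
#' @param min_overlap,max_mismatch_rate see [merge_pairs()].
#' @return A list with `merged` (data frame of merged sequences) and
#'   `report` (reads_in, dropped_low_quality, dropped_n_excess, merged,
#'   unmerged).
#' @export
preprocess_reads <- function(path1, path2, min_mean_q = 15,
                             max_n_frac = 0.05, min_overlap = 10L,
                             max_mismatch_rate = 0.1) {
  pairs <- read_fastq_pair(path1, path2)
  qc <- quality_filter(pairs, min_mean_q, max_n_frac)
  kept <- subset_pairs(pairs, qc$keep)
  mg <- merge_pairs(kept, min_overlap, max_mismatch_rate)
  report <- data.frame(
    reads_in = length(pairs$read_id),
    dropped_low_quality = sum(qc$reason == "low_quality"),
    dropped_n_excess = sum(qc$reason == "n_excess"),
    merged = sum(mg$merged),
    unmerged = sum(!mg$merged)
  )
  list(merged = mg[mg$merged, c("read_id", "sequence", "overlap_len",
                                "n_mismatches_in_overlap")],
       qc = qc, report = report)
}
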