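# V/(D)/J assignment, CDR3 extraction, productivity, junction decomposition.

#' Annotation parameters
#' @param min_v_len,min_j_len minimum alignment length (columns) for an
#'   assignment to count.
#' @param min_v_identity,min_j_identity minimum alignment identity.
#' @param min_d_match minimum contiguous exact D-segment match.
#' @param min_anchor_run junction-side boundary rule: a trailing (V) or
#'   leading (J) match run shorter than this, separated from the alignment
#'   body by a mismatch, is treated as coincidental junction sequence and
#'   trimmed off the alignment.
#' @param match,mismatch,gap_open,gap_ext local-alignment scoring; a gap of
#'   length L costs `gap_open + L * gap_ext`.
#' @return A list of annotation parameters.
#' @export
annotate_params <- function(min_v_len = 40L, min_v_identity = 0.8,
                            min_j_len = 15L, min_j_identity = 0.8,
                            min_d_match = 5L, min_anchor_run = 4L,
                            match = 1L, mismatch = -1L, gap_open = 3L,
                            gap_ext = 1L) {
  as.list(environment())
}

# drop trailing columns: while the trailing match run (bounded by a mismatch)
# is shorter than min_run, drop the run and its bounding mismatch
trim_tail_cols <- function(is_match, min_run) {
  n <- length(is_match)
  while (n > 0L) {
    if (!is_match[n]) { n <- n - 1L; next }
    r <- 0L
    while (n - r > 0L && is_match[n - r]) r <- r + 1L
    if (r == n || r >= min_run) break
    n <- n - r - 1L
  }
  n
}

trim_head_cols <- function(is_match, min_run) {
  length(is_match) - trim_tail_cols(rev(is_match), min_run) + 1L
}

align_one <- function(seq, ref, p) {
  a <- cpp_sw_align(seq, ref, p$match, p$mismatch, p$gap_open, p$gap_ext)
  a$identity <- if (a$n_columns > 0L) a$n_match / a$n_columns else 0
  a
}

#' Assign the best V and J gene to each sequence
#'
#' Every sequence is locally aligned against every functional V and J gene;
#' the best score wins per segment (score ties go to the lexicographically
#' smaller gene name and are flagged). Assignments failing the minimum
#' length/identity thresholds are left unassigned. The junction-proximal
#' alignment boundary (V 3' end, J 5' start) is trimmed by the
#' `min_anchor_run` rule of [annotate_params()] so that short coincidental
#' matches into the junction are not attributed to germline.
#'
#' @param seqs character vector of merged sequences.
#' @param db functional-filtered [germline_db()].
#' @param params an [annotate_params()] list.
#' @return A data frame with per-read V and J alignment fields (scores,
#'   identities, 1-based query/reference coordinates, tie flags), V
#'   mismatch positions (`v_mismatches`, encoded `refpos:REF>ALT;...`), and
#'   internal anchor mappings used by [extract_cdr3()].
#' @export
assign_vj <- function(seqs, db, params = annotate_params()) {
  stopifnot(inherits(db, "germline_db"))
  if (nrow(db$v) == 0L || nrow(db$j) == 0L) stop("empty germline database")
  p <- params
  vord <- order(db$v$gene_name)
  jord <- order(db$j$gene_name)
  vdb <- db$v[vord, , drop = FALSE]
  jdb <- db$j[jord, , drop = FALSE]
  vs <- cpp_sw_scores(seqs, vdb$sequence, p$match, p$mismatch, p$gap_open,
                      p$gap_ext)
  js <- cpp_sw_scores(seqs, jdb$sequence, p$match, p$mismatch, p$gap_open,
                      p$gap_ext)
  n <- length(seqs)
  out <- data.frame(row = seq_len(n))
  cols <- c("gene", "score", "identity", "tie", "qstart", "qend", "rstart",
            "rend", "anchor_q", "anchor_q_end")
  for (seg in c("v", "j")) {
    for (cl in cols) out[[paste0(seg, "_", cl)]] <-
      if (cl %in% c("gene")) NA_character_
      else if (cl == "tie") FALSE
      else if (cl == "identity") NA_real_ else NA_integer_
  }
  out$v_mismatches <- NA_character_
  out$assigned <- FALSE
  out$assign_reason <- "ok"

  for (i in seq_len(n)) {
    bi <- which.max(vs[i, ])
    a <- align_one(seqs[i], vdb$sequence[bi], p)
    keep_v <- a$n_columns >= p$min_v_len && a$identity >= p$min_v_identity
    bj <- which.max(js[i, ])
    aj <- align_one(seqs[i], jdb$sequence[bj], p)
    keep_j <- aj$n_columns >= p$min_j_len && aj$identity >= p$min_j_identity
    if (!keep_v || !keep_j) {
      out$assign_reason[i] <- if (!keep_v) "v_below_threshold"
                              else "j_below_threshold"
      next
    }
    # V: trim the junction-proximal (3') boundary
    ve <- trim_tail_cols(a$is_match, p$min_anchor_run)
    if (ve == 0L) { out$assign_reason[i] <- "v_below_threshold"; next }
    # J: trim the junction-proximal (5') boundary
    jsc <- trim_head_cols(aj$is_match, p$min_anchor_run)
    if (jsc > length(aj$is_match)) {
      out$assign_reason[i] <- "j_below_threshold"; next
    }
    out$assigned[i] <- TRUE
    out$v_gene[i] <- vdb$gene_name[bi]
    out$v_score[i] <- a$score
    out$v_identity[i] <- a$identity
    out$v_tie[i] <- sum(vs[i, ] == vs[i, bi]) > 1L
    out$v_qstart[i] <- a$query_pos[1]
    out$v_qend[i] <- a$query_pos[ve]
    out$v_rstart[i] <- a$ref_pos[1]
    out$v_rend[i] <- a$ref_pos[ve]
    mm <- which(!a$is_match[seq_len(ve)])
    if (length(mm)) {
      ref <- vdb$sequence[bi]
      out$v_mismatches[i] <- paste(sprintf(
        "%d:%s>%s", a$ref_pos[mm],
        substring(ref, a$ref_pos[mm], a$ref_pos[mm]),
        substring(seqs[i], a$query_pos[mm], a$query_pos[mm])), collapse = ";")
    }
    # the whole anchor codon must lie within the trimmed V alignment
    va <- vdb$anchor_pos[bi]
    hit <- match(va, a$ref_pos[seq_len(ve)])
    if (!is.na(hit) && !is.na(match(va + 2L, a$ref_pos[seq_len(ve)])))
      out$v_anchor_q[i] <- a$query_pos[hit]

    out$j_gene[i] <- jdb$gene_name[bj]
    out$j_score[i] <- aj$score
    out$j_identity[i] <- aj$identity
    out$j_tie[i] <- sum(js[i, ] == js[i, bj]) > 1L
    ncols <- length(aj$is_match)
    out$j_qstart[i] <- aj$query_pos[jsc]
    out$j_qend[i] <- aj$query_pos[ncols]
    out$j_rstart[i] <- aj$ref_pos[jsc]
    out$j_rend[i] <- aj$ref_pos[ncols]
    ja <- jdb$anchor_pos[bj]
    jcols <- aj$ref_pos[jsc:ncols]
    h1 <- match(ja, jcols)
    h2 <- match(ja + 2L, jcols)
    if (!is.na(h1) && !is.na(h2)) {
      out$j_anchor_q[i] <- aj$query_pos[jsc:ncols][h1]
      out$j_anchor_q_end[i] <- aj$query_pos[jsc:ncols][h2]
    }
  }
  out$row <- NULL
  out
}

#' Extract the CDR3 from anchor codons mapped through the alignments
#'
#' The CDR3 spans the conserved V cysteine codon through the J \[FW\] codon,
#' both inclusive, and is translated in the cysteine-anchored frame.
#'
#' @param seqs merged sequences.
#' @param ann annotation frame from [assign_vj()].
#' @return `ann` with `cdr3_nt`, `cdr3_aa` and `cdr3_reason`
#'   (`ok` or `anchor_missing`/`unassigned`).
#' @export
extract_cdr3 <- function(seqs, ann) {
  n <- nrow(ann)
  ann$cdr3_nt <- NA_character_
  ann$cdr3_aa <- NA_character_
  ann$cdr3_reason <- ifelse(ann$assigned, "anchor_missing", "unassigned")
  ok <- ann$assigned & !is.na(ann$v_anchor_q) & !is.na(ann$j_anchor_q_end) &
    ann$v_anchor_q < ann$j_anchor_q_end
  ann$cdr3_nt[ok] <- substr(seqs[ok], ann$v_anchor_q[ok],
                            ann$j_anchor_q_end[ok])
  ann$cdr3_aa[ok] <- translate_nt(ann$cdr3_nt[ok])
  ann$cdr3_reason[ok] <- "ok"
  ann
}

#' Classify rearrangements as productive
#'
#' Productive means: CDR3 length divisible by 3, no stop codon in the
#' cysteine-anchored frame from the anchor through the end of the J
#' alignment, and functional V and J genes (guaranteed when the database was
#' functionality-filtered).
#'
#' @param seqs merged sequences.
#' @param ann annotation frame after [extract_cdr3()].
#' @return `ann` with `productive` and `productive_reason`
#'   (`ok`, `out_of_frame`, `stop_codon`, `nonfunctional_gene`, `no_cdr3`).
#' @export
classify_productive <- function(seqs, ann) {
  n <- nrow(ann)
  ann$productive <- FALSE
  ann$productive_reason <- "no_cdr3"
  has <- !is.na(ann$cdr3_nt)
  oof <- has & nchar(ann$cdr3_nt) %% 3L != 0L
  ann$productive_reason[oof] <- "out_of_frame"
  cand <- which(has & !oof)
  if (length(cand)) {
    span <- substr(seqs[cand], ann$v_anchor_q[cand], ann$j_qend[cand])
    aa <- translate_nt(span)
    stop_hit <- grepl("*", aa, fixed = TRUE)
    ann$productive_reason[cand[stop_hit]] <- "stop_codon"
    ann$productive[cand[!stop_hit]] <- TRUE
    ann$productive_reason[cand[!stop_hit]] <- "ok"
  }
  ann
}

#' Decompose the junction into the seven indel sections
#'
#' From the trimmed V-end and J-start alignment boundaries: the inter-anchor
#' gap is searched for the longest contiguous exact D-gene match (D loci,
#' at least `min_d_match` nt); remaining gap bases become V-D and D-J
#' insertions (or the whole gap is the V-J insertion for loci without D).
#' Deletions are the unaligned reference ends. If the V and J alignments
#' overlap on the read the lower-scoring one is trimmed back to the boundary.
#'
#' @param seqs merged sequences.
#' @param ann annotation frame from [assign_vj()] (or later).
#' @param db the germline database.
#' @param params an [annotate_params()] list.
#' @return `ann` with `d_gene`, `del_3v`, `del_5d`, `del_3d`, `del_5j`,
#'   `ins_vd`, `ins_dj`, `ins_vj`, `junction_conflict`.
#' @export
assign_d_and_decompose <- function(seqs, ann, db, params = annotate_params()) {
  has_d <- db$locus %in% D_LOCI
  n <- nrow(ann)
  ann$d_gene <- NA_character_
  ann$del_3v <- ann$del_5d <- ann$del_3d <- ann$del_5j <- NA_integer_
  ann$ins_vd <- ann$ins_dj <- ann$ins_vj <- NA_character_
  ann$junction_conflict <- FALSE
  v_len <- setNames(nchar(db$v$sequence), db$v$gene_name)
  for (i in which(ann$assigned)) {
    v_end_q <- ann$v_qend[i]; v_end_r <- ann$v_rend[i]
    j_start_q <- ann$j_qstart[i]; j_start_r <- ann$j_rstart[i]
    if (j_start_q <= v_end_q) {
      shift <- v_end_q - j_start_q + 1L
      if (ann$v_score[i] >= ann$j_score[i]) {
        j_start_q <- j_start_q + shift
        j_start_r <- j_start_r + shift
        if (j_start_q > ann$j_qend[i] + 1L) {
          ann$junction_conflict[i] <- TRUE
          next
        }
      } else {
        v_end_q <- v_end_q - shift
        v_end_r <- v_end_r - shift
        if (v_end_q < ann$v_qstart[i] - 1L) {
          ann$junction_conflict[i] <- TRUE
          next
        }
      }
    }
    gap <- if (j_start_q - 1L >= v_end_q + 1L)
      substr(seqs[i], v_end_q + 1L, j_start_q - 1L) else ""
    ann$del_3v[i] <- v_len[[ann$v_gene[i]]] - v_end_r
    ann$del_5j[i] <- j_start_r - 1L
    if (has_d) {
      sp <- split_gap_d(gap, db$d, params$min_d_match)
      ann$d_gene[i] <- sp$d_gene
      ann$del_5d[i] <- sp$del_5d
      ann$del_3d[i] <- sp$del_3d
      ann$ins_vd[i] <- sp$ins_vd
      ann$ins_dj[i] <- sp$ins_dj
      ann$ins_vj[i] <- ""
    } else {
      ann$ins_vj[i] <- gap
      ann$ins_vd[i] <- ann$ins_dj[i] <- ""
    }
  }
  ann
}

#' Annotate merged sequences end to end
#'
#' Runs [assign_vj()], [extract_cdr3()], [classify_productive()] and
#' [assign_d_and_decompose()].
#'
#' @param read_id read identifiers.
#' @param seqs merged sequences.
#' @param db functional-filtered germline database.
#' @param params an [annotate_params()] list.
#' @return The full annotation data frame (one row per read).
#' @export
annotate_reads <- function(read_id, seqs, db, params = annotate_params()) {
  ann <- assign_vj(seqs, db, params)
  ann <- extract_cdr3(seqs, ann)
  ann <- classify_productive(seqs, ann)
  ann <- assign_d_and_decompose(seqs, ann, db, params)
  cbind(data.frame(read_id = read_id, locus = db$locus,
                   stringsAsFactors = FALSE), ann)
}

#' Demultiplex mixed kappa/lambda light-chain sequences
#'
#' Assigns each sequence the locus whose best V-gene local-alignment score is
#' higher; equal best scores are left `unresolved`.
#'
#' @param seqs merged sequences.
#' @param igk_db,igl_db functional-filtered IGK and IGL databases.
#' @param params an [annotate_params()] list.
#' @return Character vector of `"IGK"`, `"IGL"` or `"unresolved"`.
#' @export
split_igkl <- function(seqs, igk_db, igl_db, params = annotate_params()) {
  p <- params
  sk <- cpp_sw_scores(seqs, igk_db$v$sequence, p$match, p$mismatch,
                      p$gap_open, p$gap_ext)
  sl <- cpp_sw_scores(seqs, igl_db$v$sequence, p$match, p$mismatch,
                      p$gap_open, p$gap_ext)
  bk <- apply(sk, 1, max)
  bl <- apply(sl, 1, max)
  ifelse(bk > bl, "IGK", ifelse(bl > bk, "IGL", "unresolved"))
}

#' Collapse likely PCR/sequencing-error clonotypes
#'
#' A clonotype (CDR3 nt, V, J) whose read count is at most `ratio` times
#' that of another clonotype with the same V and J and at most `max_dist`
#' CDR3 mismatches is merged into the larger clonotype. Applied once,
#' largest-first, on the original counts.
#'
#' @param ann annotation frame with `cdr3_nt`, `cdr3_aa`, `v_gene`,
#'   `j_gene`.
#' @param max_dist maximum CDR3 hamming distance (default 1).
#' @param ratio maximum abundance ratio for absorption (default 0.01).
#' @return `ann` with corrected clonotype fields and a logical
#'   `clonotype_collapsed` column.
#' @export
collapse_errors <- function(ann, max_dist = 1L, ratio = 0.01) {
  ann$clonotype_collapsed <- FALSE
  use <- which(!is.na(ann$cdr3_nt))
  if (length(use) == 0L) return(ann)
  key <- paste(ann$cdr3_nt[use], ann$v_gene[use], ann$j_gene[use], sep = "|")
  tab <- aggregate(list(count = rep(1L, length(use))),
                   by = list(key = key, cdr3_nt = ann$cdr3_nt[use],
                             cdr3_aa = ann$cdr3_aa[use],
                             v_gene = ann$v_gene[use],
                             j_gene = ann$j_gene[use]), FUN = sum)
  tab <- tab[order(-tab$count, tab$cdr3_nt), ]
  tab$len <- nchar(tab$cdr3_nt)
  absorb <- rep(NA_integer_, nrow(tab))
  grp <- split(seq_len(nrow(tab)),
               paste(tab$v_gene, tab$j_gene, tab$len, sep = "|"))
  for (g in grp) {
    if (length(g) < 2L) next
    for (bi in rev(seq_along(g))) {       # smallest first
      b <- g[bi]
      for (ai in seq_len(bi - 1L)) {      # candidates are larger (sorted)
        a <- g[ai]
        if (tab$count[b] > ratio * tab$count[a]) next
        if (cpp_hamming(tab$cdr3_nt[b], tab$cdr3_nt[a]) <= max_dist) {
          absorb[b] <- a
          break                            # largest qualifying absorber
        }
      }
    }
  }
  hit <- which(!is.na(absorb))
  if (length(hit)) {
    map <- setNames(absorb, tab$key)
    idx <- match(key, tab$key)
    to <- absorb[idx]
    moved <- !is.na(to)
    ann$cdr3_nt[use[moved]] <- tab$cdr3_nt[to[moved]]
    ann$cdr3_aa[use[moved]] <- tab$cdr3_aa[to[moved]]
    ann$clonotype_collapsed[use[moved]] <- TRUE
  }
  ann
}

#' Build a clonotype abundance table
#'
#' A clonotype is the triple (CDR3 nucleotide sequence, V gene, J gene).
#'
#' @param ann annotation frame.
#' @param productive_only restrict to productive rearrangements
#'   (default `TRUE`).
#' @return A data frame (`cdr3_nt`, `cdr3_aa`, `v_gene`, `j_gene`,
#'   `read_count`) with the locus in `attr(, "locus")`.
#' @export
repertoire_table <- function(ann, productive_only = TRUE) {
  keep <- !is.na(ann$cdr3_nt)
  if (productive_only) keep <- keep & ann$productive
  sub <- ann[keep, , drop = FALSE]
  if (nrow(sub) == 0L) {
    out <- data.frame(cdr3_nt = character(0), cdr3_aa = character(0),
                      v_gene = character(0), j_gene = character(0),
                      read_count = integer(0))
  } else {
    out <- aggregate(list(read_count = rep(1L, nrow(sub))),
                     by = list(cdr3_nt = sub$cdr3_nt, cdr3_aa = sub$cdr3_aa,
                               v_gene = sub$v_gene, j_gene = sub$j_gene),
                     FUN = sum)
    out <- out[order(-out$read_count, out$cdr3_nt), ]
    rownames(out) <- NULL
  }
  attr(out, "locus") <- if ("locus" %in% names(ann) && nrow(ann))
    ann$locus[1] else NA_character_
  out
}
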