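# Per-position FR3 somatic hypermutation profiling, hotspot calling, and
# polymorphic-site (unreported germline allele) inference.

parse_mismatches <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(position = integer(0), ref = character(0),
                      alt = character(0)))
  }
  ev <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- regmatches(ev, regexec("^(\\d+):([ACGTN])>([ACGTN])$", ev))
  data.frame(position = as.integer(vapply(m, `[`, "", 2)),
             ref = vapply(m, `[`, "", 3), alt = vapply(m, `[`, "", 4),
             stringsAsFactors = FALSE)
}

#' Build per-gene FR3 mutation profiles
#'
#' For each functional V gene, accumulates read-weighted coverage, mismatch
#' counts, and the observed base composition at every FR3 reference position
#' (196-310, clipped to the reference length) from the V alignments of the
#' sequences that aligned best with that gene. Codon-level counts (a codon
#' with any mismatching base is one amino-acid event; only codons fully
#' inside the FR3 and fully covered by the alignment are counted) are
#' accumulated alongside for amino-acid-level rates.
#'
#' @param ann annotation frame from [annotate_reads()] for a B-cell locus.
#' @param db the germline database used for annotation.
#' @return An object of class `mutation_profiles`: a list with `nt`
#'   (gene_name, position, ref_base, coverage, mismatches, A, C, G, T) and
#'   `codon` (gene_name, codon, coverage, mismatches).
#' @export
build_profiles <- function(ann, db) {
  if (!(db$locus %in% c("IGH", "IGK", "IGL")))
    stop("mutation profiling applies to B-cell loci only")
  nt_rows <- list()
  codon_rows <- list()
  for (gi in seq_len(nrow(db$v))) {
    g <- db$v$gene_name[gi]
    vseq <- db$v$sequence[gi]
    span <- fr3_span(db$v[gi, , drop = FALSE])
    fs <- span[["start"]]; fe <- span[["end"]]
    npos <- fe - fs + 1L
    idx <- which(ann$assigned & ann$v_gene == g)
    cov_delta <- numeric(npos + 1L)
    mm_count <- matrix(0, nrow = npos, ncol = 4L,
                       dimnames = list(NULL, DNA_BASES))
    k_min <- ceiling((fs + 2L) / 3L)
    k_max <- fe %/% 3L
    nk <- k_max - k_min + 1L
    ck_delta <- numeric(nk + 1L)
    ck_mut <- numeric(nk)
    for (i in idx) {
      lo <- max(fs, ann$v_rstart[i]); hi <- min(fe, ann$v_rend[i])
      mm <- parse_mismatches(ann$v_mismatches[i])
      mm <- mm[mm$position >= fs & mm$position <= fe, , drop = FALSE]
      if (lo <= hi) {
        cov_delta[lo - fs + 1L] <- cov_delta[lo - fs + 1L] + 1
        cov_delta[hi - fs + 2L] <- cov_delta[hi - fs + 2L] - 1
        for (r in seq_len(nrow(mm))) {
          p <- mm$position[r] - fs + 1L
          mm_count[p, mm$alt[r]] <- mm_count[p, mm$alt[r]] + 1
        }
        # codons fully covered by this read and fully inside the FR3
        ck_lo <- max(k_min, ceiling((ann$v_rstart[i] + 2L) / 3L))
        ck_hi <- min(k_max, ann$v_rend[i] %/% 3L)
        if (ck_lo <= ck_hi) {
          ck_delta[ck_lo - k_min + 1L] <- ck_delta[ck_lo - k_min + 1L] + 1
          ck_delta[ck_hi - k_min + 2L] <- ck_delta[ck_hi - k_min + 2L] - 1
          mk <- unique(ceiling(mm$position / 3L))
          mk <- mk[mk >= ck_lo & mk <= ck_hi]
          for (k in mk) ck_mut[k - k_min + 1L] <- ck_mut[k - k_min + 1L] + 1
        }
      }
    }
    coverage <- cumsum(cov_delta[seq_len(npos)])
    ref_bases <- strsplit(substr(vseq, fs, fe), "")[[1]]
    mismatches <- rowSums(mm_count)
    comp <- mm_count
    for (b in DNA_BASES) {
      own <- ref_bases == b
      comp[own, b] <- comp[own, b] + coverage[own] - mismatches[own]
    }
    nt_rows[[g]] <- data.frame(
      gene_name = g, position = fs:fe, ref_base = ref_bases,
      coverage = coverage, mismatches = mismatches,
      A = comp[, "A"], C = comp[, "C"], G = comp[, "G"], T = comp[, "T"],
      stringsAsFactors = FALSE)
    codon_rows[[g]] <- data.frame(
      gene_name = g, codon = k_min:k_max,
      coverage = cumsum(ck_delta[seq_len(nk)]), mismatches = ck_mut,
      stringsAsFactors = FALSE)
  }
  out <- list(nt = do.call(rbind, c(nt_rows, make.row.names = FALSE)),
              codon = do.call(rbind, c(codon_rows, make.row.names = FALSE)))
  class(out) <- "mutation_profiles"
  out
}

#' @export
print.mutation_profiles <- function(x, ...) {
  cat(sprintf("<mutation_profiles: %d genes, %d FR3 positions>\n",
              length(unique(x$nt$gene_name)), nrow(x$nt)))
  invisible(x)
}

#' Overall FR3 mutation rate
#'
#' Nucleotide level: mutated bases divided by sequenced bases, pooled over
#' all genes and positions (read abundance included). Amino-acid level:
#' mutated codons divided by sequenced codons.
#'
#' @param profiles a `mutation_profiles` object.
#' @param level `"nt"` or `"aa"`.
#' @return The rate; `NA` with attribute `undefined = TRUE` when nothing was
#'   sequenced.
#' @export
overall_rate <- function(profiles, level = c("nt", "aa")) {
  level <- match.arg(level)
  tab <- if (level == "nt") profiles$nt else profiles$codon
  tot <- sum(tab$coverage)
  if (tot == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  sum(tab$mismatches) / tot
}

#' Per-gene FR3 mutation rates
#'
#' @inheritParams overall_rate
#' @return A data frame (`gene_name`, `rate`); genes with no aligned reads
#'   are excluded with a warning.
#' @export
per_gene_rate <- function(profiles, level = c("nt", "aa")) {
  level <- match.arg(level)
  tab <- if (level == "nt") profiles$nt else profiles$codon
  agg <- aggregate(cbind(coverage, mismatches) ~ gene_name, data = tab,
                   FUN = sum)
  empty <- agg$coverage == 0
  if (any(empty))
    warning("no aligned reads for: ",
            paste(agg$gene_name[empty], collapse = ", "))
  data.frame(gene_name = agg$gene_name[!empty],
             rate = agg$mismatches[!empty] / agg$coverage[!empty],
             stringsAsFactors = FALSE)
}

#' Call FR3 mutation hotspots
#'
#' A hotspot is a position with mutation frequency strictly greater than
#' `threshold` at coverage of at least `min_coverage` (positions with
#' coverage of 30 or fewer bases are excluded by default, mirroring the
#' grey cells of a coverage-filtered heatmap).
#'
#' @param profiles a `mutation_profiles` object.
#' @param min_coverage minimum sequenced bases per position (default 31,
#'   i.e. exclude coverage of 30 or less).
#' @param threshold mutation frequency that must be strictly exceeded
#'   (default 0.10).
#' @return A data frame (`gene_name`, `position`, `coverage`, `mut_freq`,
#'   `status`) with status `hotspot`, `not_hotspot`, or `low_coverage`.
#' @export
call_hotspots <- function(profiles, min_coverage = 31L, threshold = 0.10) {
  tab <- profiles$nt
  freq <- ifelse(tab$coverage > 0, tab$mismatches / tab$coverage, NA_real_)
  status <- ifelse(tab$coverage < min_coverage, "low_coverage",
                   ifelse(freq > threshold, "hotspot", "not_hotspot"))
  data.frame(gene_name = tab$gene_name, position = tab$position,
             coverage = tab$coverage, mut_freq = freq, status = status,
             stringsAsFactors = FALSE)
}

#' Detect potential germline polymorphic sites
#'
#' A position is a potential polymorphic site (an unreported heterozygous
#' allele rather than hypermutation) when its coverage is at least
#' `min_coverage`, a single non-reference base accounts for a fraction of
#' coverage inside `band` (40-60% by default: roughly balanced transcription
#' of two alleles), and that base makes up at least `dominance` of all
#' mismatches there (one dominant mutated type). Sites meeting every
#' condition except that the fraction falls in the wider `candidate_band`
#' are reported as `candidate`.
#'
#' @param profiles a `mutation_profiles` object.
#' @param band inclusive alt-fraction band for a confident call.
#' @param min_coverage minimum coverage (default 1000).
#' @param dominance minimum share of mismatches from the top alternative
#'   base (default 0.8).
#' @param candidate_band wider band for near-miss candidate sites.
#' @return A data frame (`gene_name`, `position`, `ref_base`, `alt_base`,
#'   `alt_fraction`, `coverage`, `verdict`, `reason`) with verdict
#'   `polymorphic`, `candidate`, or `not_polymorphic`.
#' @export
detect_polymorphic_sites <- function(profiles, band = c(0.40, 0.60),
                                     min_coverage = 1000L, dominance = 0.8,
                                     candidate_band = c(0.30, 0.70)) {
  tab <- profiles$nt
  alt_mat <- as.matrix(tab[, DNA_BASES])
  alt_mat[cbind(seq_len(nrow(tab)), match(tab$ref_base, DNA_BASES))] <- 0
  top <- max.col(alt_mat, ties.method = "first")
  top_count <- alt_mat[cbind(seq_len(nrow(tab)), top)]
  alt_fraction <- ifelse(tab$coverage > 0, top_count / tab$coverage, 0)
  mm <- tab$mismatches
  dom <- ifelse(mm > 0, top_count / mm, 0)
  verdict <- rep("not_polymorphic", nrow(tab))
  reason <- rep("no_mismatches", nrow(tab))
  has <- mm > 0
  reason[has] <- "outside_band"
  low <- tab$coverage < min_coverage
  reason[has & low] <- "low_coverage"
  weak <- has & !low & dom < dominance
  reason[weak] <- "not_dominant"
  in_band <- has & !low & dom >= dominance &
    alt_fraction >= band[1] & alt_fraction <= band[2]
  near <- has & !low & dom >= dominance & !in_band &
    alt_fraction >= candidate_band[1] & alt_fraction <= candidate_band[2]
  verdict[in_band] <- "polymorphic"
  reason[in_band] <- "ok"
  verdict[near] <- "candidate"
  reason[near] <- "near_band"
  data.frame(gene_name = tab$gene_name, position = tab$position,
             ref_base = tab$ref_base, alt_base = DNA_BASES[top],
             alt_fraction = alt_fraction, coverage = tab$coverage,
             verdict = verdict, reason = reason, stringsAsFactors = FALSE)
}

#' Substitution spectrum of FR3 mutations
#'
#' Nucleotide level: relative frequency of each of the 12 reference-to-
#' alternative base substitution types. Amino-acid level: frequencies of
#' reference-to-alternative amino-acid types, derived per position from the
#' reference codon with the single observed base substituted (codons hit at
#' several bases in one read are not resolved at this level); a `rank`
#' column supports a top-15 view.
#'
#' @param profiles a `mutation_profiles` object.
#' @param level `"nt"` or `"aa"`.
#' @param db germline database (required for `level = "aa"`).
#' @return A data frame (`from`, `to`, `count`, `frequency`, `rank`),
#'   frequencies summing to 1; zero-row with attribute `undefined = TRUE`
#'   when there are no mismatches.
#' @export
substitution_spectrum <- function(profiles, level = c("nt", "aa"),
                                  db = NULL) {
  level <- match.arg(level)
  tab <- profiles$nt
  rows <- list()
  for (b in DNA_BASES) {
    sel <- tab$ref_base != b & tab[[b]] > 0
    if (!any(sel)) next
    rows[[b]] <- data.frame(gene_name = tab$gene_name[sel],
                            position = tab$position[sel],
                            from = tab$ref_base[sel], to = b,
                            count = tab[[b]][sel], stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev) || nrow(ev) == 0L) {
    out <- data.frame(from = character(0), to = character(0),
                      count = numeric(0), frequency = numeric(0),
                      rank = integer(0))
    attr(out, "undefined") <- TRUE
    return(out)
  }
  if (level == "aa") {
    if (is.null(db)) stop("amino-acid spectra need the germline database")
    vseq <- setNames(db$v$sequence, db$v$gene_name)
    k <- ceiling(ev$position / 3L)
    cs <- 3L * k - 2L
    ref_codon <- substr(vseq[ev$gene_name], cs, cs + 2L)
    off <- ev$position - cs + 1L
    alt_codon <- ref_codon
    substr(alt_codon, off, off) <- ev$to
    ev$from <- translate_nt(ref_codon)
    ev$to <- translate_nt(alt_codon)
  }
  agg <- aggregate(count ~ from + to, data = ev, FUN = sum)
  agg <- agg[order(-agg$count, agg$from, agg$to), ]
  agg$frequency <- agg$count / sum(agg$count)
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg
}
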