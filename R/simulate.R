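# Ground-truthed simulation of rearranged receptor repertoires and
# paired-end reads.

#' Simulation configuration
#'
#' Collects every tunable of the repertoire and read simulator. Defaults are
#' chosen for a generic locus; per-study settings (rates, weights, alleles)
#' are supplied explicitly.
#'
#' @param locus locus code (`TRA`, `TRB`, `IGH`, `IGK`, `IGL`).
#' @param n_clonotypes number of distinct rearrangements to generate.
#' @param seed integer seed; every stage of the simulator is deterministic
#'   given the seed.
#' @param clone_alpha exponent of the discrete power-law clone-size model
#'   (larger = less skewed).
#' @param max_clone_size truncation point of the clone-size distribution;
#'   `1` gives exactly one read pair per clonotype.
#' @param v_usage_weights,d_usage_weights,j_usage_weights optional named
#'   non-negative weights per gene; `NULL` means uniform.
#' @param del_mean named means of the geometric trimming models for the four
#'   deletion sections (`v3`, `d5`, `d3`, `j5`).
#' @param ins_mean named means of the geometric insertion-length models
#'   (`vd`, `dj`, `vj`).
#' @param insertion_base_probs probabilities over A/C/G/T for non-template
#'   inserted bases; must sum to 1.
#' @param shm_rate per-nucleotide somatic hypermutation probability (B-cell
#'   loci only).
#' @param shm_hotspots optional data frame (`gene`, `position`, `rate`) of
#'   per-position elevated SHM rates on the V reference.
#' @param shm_substitution optional 4x4 row-stochastic matrix (rows/cols
#'   A,C,G,T, zero diagonal) giving the mutated-base distribution; `NULL`
#'   means uniform over the three alternatives.
#' @param polymorphic_alleles optional data frame (`gene`, `position`,
#'   `alt_base`, `fraction`) of heterozygous germline polymorphisms carried
#'   by a clonotype with probability `fraction`.
#' @param read_length sequencing read length (default 100).
#' @param fragment_length library fragment length; the template is truncated
#'   to its 3'-most `fragment_length` nucleotides before read generation so
#'   the junction and FR3 are covered by both mates.
#' @param per_base_error_rate substitution sequencing-error rate.
#' @param n_rate per-base probability of an uncalled (`N`) base.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(locus, n_clonotypes = 1000L, seed = 1L,
                       clone_alpha = 2.5, max_clone_size = 1L,
                       v_usage_weights = NULL, d_usage_weights = NULL,
                       j_usage_weights = NULL,
                       del_mean = c(v3 = 2, d5 = 1, d3 = 1, j5 = 2),
                       ins_mean = c(vd = 4, dj = 4, vj = 4),
                       insertion_base_probs = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25),
                       shm_rate = 0, shm_hotspots = NULL,
                       shm_substitution = NULL, polymorphic_alleles = NULL,
                       read_length = 100L, fragment_length = 180L,
                       per_base_error_rate = 0, n_rate = 0) {
  locus <- match.arg(locus, LOCI)
  if (abs(sum(insertion_base_probs) - 1) > 1e-9)
    stop("insertion_base_probs must sum to 1")
  if (!all(DNA_BASES %in% names(insertion_base_probs)))
    stop("insertion_base_probs must be named A, C, G, T")
  if (!(locus %in% D_LOCI) && !is.null(d_usage_weights))
    stop("d_usage_weights must be empty for ", locus)
  if (shm_rate < 0 || shm_rate >= 1) stop("shm_rate must be in [0, 1)")
  if (shm_rate > 0 && !(locus %in% c("IGH", "IGK", "IGL")))
    stop("SHM applies to B-cell loci only")
  if (!is.null(shm_substitution)) {
    stopifnot(is.matrix(shm_substitution),
              all(dim(shm_substitution) == c(4L, 4L)))
    if (any(abs(rowSums(shm_substitution) - 1) > 1e-9) ||
        any(diag(shm_substitution) != 0))
      stop("shm_substitution rows must sum to 1 with a zero diagonal")
  }
  structure(list(
    locus = locus, n_clonotypes = as.integer(n_clonotypes),
    seed = as.integer(seed), clone_alpha = clone_alpha,
    max_clone_size = as.integer(max_clone_size),
    v_usage_weights = v_usage_weights, d_usage_weights = d_usage_weights,
    j_usage_weights = j_usage_weights, del_mean = del_mean,
    ins_mean = ins_mean,
    insertion_base_probs = insertion_base_probs[DNA_BASES],
    shm_rate = shm_rate, shm_hotspots = shm_hotspots,
    shm_substitution = shm_substitution,
    polymorphic_alleles = polymorphic_alleles,
    read_length = as.integer(read_length),
    fragment_length = as.integer(fragment_length),
    per_base_error_rate = per_base_error_rate, n_rate = n_rate
  ), class = "sim_config")
}

# geometric draw with given mean (support 0, 1, 2, ...)
rgeom_mean <- function(n, mean) {
  if (mean <= 0) return(integer(n))
  rgeom(n, prob = 1 / (1 + mean))
}

#' Generate a synthetic germline database
#'
#' Builds random germline V/(D)/J genes carrying valid CDR3 anchors: each V
#' gene holds a single in-frame cysteine codon 15 nt from its 3' end (and no
#' in-frame stop codons), each J gene a \[FW\]GXG motif whose \[FW\] codon
#' starts at nucleotide 28. Gene counts default to the functional-gene
#' inventory of the rhesus macaque loci (59/13 TRB, 31/55 TRA, 83/4 IGK,
#' 83/5 IGL, 19/6 IGH). Unlike real paralogous gene families the genes are
#' mutually unrelated random sequences.
#'
#' @param locus locus code.
#' @param n_v,n_d,n_j gene counts; `NULL` picks the locus default.
#' @param v_length V reference length in nt (>= 310 so the full FR3 exists).
#' @param seed integer seed.
#' @return A `germline_db` with functionality filtering already applied.
#' @export
synthetic_germline_db <- function(locus, n_v = NULL, n_d = NULL, n_j = NULL,
                                  v_length = 321L, seed = 42L) {
  locus <- match.arg(locus, LOCI)
  defaults <- list(TRB = c(59L, 2L, 13L), TRA = c(31L, 0L, 55L),
                   IGK = c(83L, 0L, 4L), IGL = c(83L, 0L, 5L),
                   IGH = c(19L, 6L, 6L))[[locus]]
  if (is.null(n_v)) n_v <- defaults[1]
  if (is.null(n_d)) n_d <- defaults[2]
  if (is.null(n_j)) n_j <- defaults[3]
  if (!(locus %in% D_LOCI)) n_d <- 0L
  stopifnot(v_length %% 3L == 0L, v_length >= 312L)
  set.seed(seed)

  make_v <- function(i) {
    s <- strsplit(random_nt(1, v_length), "")[[1]]
    starts <- seq.int(1L, v_length - 2L, by = 3L)
    anchor <- v_length - 14L            # codon start, 15 nt from the 3' end
    stopifnot(anchor %% 3L == 1L)
    s[anchor:(anchor + 2L)] <- c("T", "G", "T")
    for (st in starts) {
      codon <- paste(s[st:(st + 2L)], collapse = "")
      if (st != anchor && codon %in% c("TGT", "TGC") && st >= v_length - 29L)
        s[st] <- "A"                    # keep the anchor cysteine rightmost
      if (codon %in% c("TAA", "TAG", "TGA"))
        s[st] <- "C"                    # no in-frame stops in the reference
    }
    paste(s, collapse = "")
  }
  make_j <- function(i) {
    len <- 48L
    repeat {
      s <- strsplit(random_nt(1, len), "")[[1]]
      s[28:30] <- strsplit(sample(c("TTT", "TGG"), 1), "")[[1]]
      s[31:33] <- c("G", "G", "T")
      s[37:39] <- c("G", "G", "C")
      # no stops in the anchor frame (CDR3 tail and FR4 are stop-free in
      # real J genes)
      for (st in seq.int(1L, len - 2L, by = 3L)) {
        if (st >= 28L && st <= 33L) next
        if (paste(s[st:(st + 2L)], collapse = "") %in% c("TAA", "TAG", "TGA"))
          s[st] <- "C"
      }
      seq <- paste(s, collapse = "")
      a <- j_anchor(seq)
      if (!is.na(a) && a == 28L) return(seq)
    }
  }

  v <- data.frame(gene_name = sprintf("%sV%d", locus, seq_len(n_v)),
                  locus = locus, segment = "V",
                  sequence = vapply(seq_len(n_v), make_v, character(1)),
                  functional = FALSE, anchor_pos = NA_integer_,
                  fr3_start = NA_integer_, fr3_end = NA_integer_,
                  stringsAsFactors = FALSE)
  j <- data.frame(gene_name = sprintf("%sJ%d", locus, seq_len(n_j)),
                  locus = locus, segment = "J",
                  sequence = vapply(seq_len(n_j), make_j, character(1)),
                  functional = FALSE, anchor_pos = NA_integer_,
                  fr3_start = NA_integer_, fr3_end = NA_integer_,
                  stringsAsFactors = FALSE)
  v <- filter_functional(v, "V")
  j <- filter_functional(j, "J")
  stopifnot(nrow(v) == n_v, nrow(j) == n_j)
  d <- empty_gene_table()
  if (n_d > 0L) {
    d <- data.frame(gene_name = sprintf("%sD%d", locus, seq_len(n_d)),
                    locus = locus, segment = "D",
                    sequence = random_nt(n_d, sample(12:16, n_d, TRUE)),
                    functional = TRUE, anchor_pos = NA_integer_,
                    fr3_start = NA_integer_, fr3_end = NA_integer_,
                    stringsAsFactors = FALSE)
  }
  germline_db(locus, v = v, j = j, d = d, version_tag = "synthetic")
}

# Split a junction gap into ins/(D)/ins by the longest exact D match
# (>= min_d_match nt). Tie-break: longest, then leftmost in the gap, then
# lexicographically smallest gene name. Shared by the simulator's canonical
# ground truth and the annotator.
split_gap_d <- function(gap, d_genes, min_d_match = 5L) {
  none <- list(d_gene = NA_character_, del_5d = NA_integer_,
               del_3d = NA_integer_, ins_vd = gap, ins_dj = "")
  if (nrow(d_genes) == 0L || nchar(gap) < min_d_match) return(none)
  ord <- order(d_genes$gene_name)
  best <- NULL
  for (k in ord) {
    hit <- cpp_lcs(gap, d_genes$sequence[k])
    if (hit[1] < min_d_match) next
    if (is.null(best) || hit[1] > best$len ||
        (hit[1] == best$len && hit[2] < best$a)) {
      best <- list(len = hit[1], a = hit[2], b = hit[3], k = k)
    }
  }
  if (is.null(best)) return(none)
  d_len <- nchar(d_genes$sequence[best$k])
  list(d_gene = d_genes$gene_name[best$k],
       del_5d = best$b - 1L,
       del_3d = d_len - (best$b + best$len - 1L),
       ins_vd = substr(gap, 1L, best$a - 1L),
       ins_dj = substr(gap, best$a + best$len, nchar(gap)))
}

# length of the common prefix of two strings
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- utf8ToInt(substr(a, 1L, n))
  bv <- utf8ToInt(substr(b, 1L, n))
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1] - 1L
}

common_suffix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- rev(utf8ToInt(a))[seq_len(n)]
  bv <- rev(utf8ToInt(b))[seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1] - 1L
}

# Canonical (identifiable) junction decomposition of a pre-mutation template:
# maximal exact V extension from the 5' end, maximal exact J extension from
# the 3' end (V wins an overlap), then the shared D split of the gap.
canonical_junction <- function(template, v_seq, j_seq, d_genes, has_d,
                               min_d_match = 5L) {
  tl <- nchar(template)
  v_end <- common_prefix_len(template, v_seq)
  l_suf <- common_suffix_len(template, j_seq)
  j_start <- tl - l_suf + 1L
  j_ref_start <- nchar(j_seq) - l_suf + 1L
  if (j_start <= v_end) {             # overlap: trim the J side back
    shift <- v_end - j_start + 1L
    j_start <- j_start + shift
    j_ref_start <- j_ref_start + shift
  }
  gap <- if (j_start - 1L >= v_end + 1L)
    substr(template, v_end + 1L, j_start - 1L) else ""
  out <- list(del_3v = nchar(v_seq) - v_end,
              del_5j = j_ref_start - 1L,
              v_end = v_end, j_start = j_start)
  if (has_d) {
    out <- c(out, split_gap_d(gap, d_genes, min_d_match), list(ins_vj = ""))
  } else {
    out <- c(out, list(d_gene = NA_character_, del_5d = NA_integer_,
                       del_3d = NA_integer_, ins_vd = "", ins_dj = "",
                       ins_vj = gap))
  }
  out
}

#' Simulate a ground-truthed repertoire
#'
#' Draws `n_clonotypes` rearrangements from a functional germline database:
#' genes by (normalized) usage weights, exonucleolytic trims and non-template
#' insertions per junction section, optional heterozygous allele carriage and
#' somatic hypermutation, and a power-law clone size. Random stages consume
#' the RNG in a fixed order (genes, trims, insertions, alleles, SHM,
#' abundance), so the output is byte-identical for a fixed seed.
#'
#' The stored junction fields are the canonical decomposition re-derived from
#' the assembled sequence by maximal exact germline extension: an inserted
#' base that happens to equal the next germline base is indistinguishable
#' from germline, so only the canonical form is identifiable downstream.
#'
#' @param config a [sim_config()].
#' @param db a functional-filtered [germline_db()] for the same locus.
#' @return A data frame with one row per clonotype: genes, the seven junction
#'   section values, `full_sequence`, `cdr3_nt`, `shm_events` and
#'   `allele_events` (encoded `pos:REF>ALT` separated by `;`), `abundance`.
#' @export
simulate_repertoire <- function(config, db) {
  stopifnot(inherits(config, "sim_config"), inherits(db, "germline_db"))
  if (db$locus != config$locus) stop("config and database locus differ")
  n <- config$n_clonotypes
  has_d <- config$locus %in% D_LOCI
  if (nrow(db$v) == 0L || nrow(db$j) == 0L || (has_d && nrow(db$d) == 0L))
    stop("empty gene collection for a required segment")
  set.seed(config$seed)

  pick <- function(genes, weights) {
    w <- rep(1, nrow(genes))
    if (!is.null(weights)) {
      w <- weights[genes$gene_name]
      if (anyNA(w)) stop("usage weights name unknown genes")
    }
    sample.int(nrow(genes), n, replace = TRUE, prob = w)
  }
  vi <- pick(db$v, config$v_usage_weights)
  di <- if (has_d) pick(db$d, config$d_usage_weights) else rep(NA_integer_, n)
  ji <- pick(db$j, config$j_usage_weights)

  v_seq <- db$v$sequence[vi]; v_len <- nchar(v_seq)
  j_seq <- db$j$sequence[ji]; j_len <- nchar(j_seq)
  d_seq <- if (has_d) db$d$sequence[di] else rep("", n)
  d_len <- nchar(d_seq)

  del_3v <- pmin(rgeom_mean(n, config$del_mean[["v3"]]), v_len - 31L)
  del_5d <- del_3d <- integer(n)
  if (has_d) {
    del_5d <- pmin(rgeom_mean(n, config$del_mean[["d5"]]), d_len)
    del_3d <- pmin(rgeom_mean(n, config$del_mean[["d3"]]), d_len - del_5d)
  }
  del_5j <- pmin(rgeom_mean(n, config$del_mean[["j5"]]), j_len - 6L)

  ins_probs <- config$insertion_base_probs
  if (has_d) {
    ins_vd <- random_nt(n, rgeom_mean(n, config$ins_mean[["vd"]]), ins_probs)
    ins_dj <- random_nt(n, rgeom_mean(n, config$ins_mean[["dj"]]), ins_probs)
    ins_vj <- rep("", n)
  } else {
    ins_vd <- ins_dj <- rep("", n)
    ins_vj <- random_nt(n, rgeom_mean(n, config$ins_mean[["vj"]]), ins_probs)
  }

  v_trim <- substr(v_seq, 1L, v_len - del_3v)
  j_trim <- substr(j_seq, del_5j + 1L, j_len)
  mid <- if (has_d)
    paste0(ins_vd, substr(d_seq, del_5d + 1L, d_len - del_3d), ins_dj)
  else ins_vj
  template <- paste0(v_trim, mid, j_trim)

  canon <- vector("list", n)
  for (i in seq_len(n)) {
    canon[[i]] <- canonical_junction(template[i], v_seq[i], j_seq[i],
                                     db$d, has_d)
  }

  # heterozygous germline alleles, carried per clonotype before SHM
  allele_events <- rep("", n)
  pa <- config$polymorphic_alleles
  if (!is.null(pa) && nrow(pa) > 0L) {
    for (k in seq_len(nrow(pa))) {
      idx <- which(db$v$gene_name[vi] == pa$gene[k])
      if (length(idx) == 0L) next
      if (pa$position[k] > min(nchar(db$v$sequence[db$v$gene_name == pa$gene[k]])))
        stop("polymorphic position beyond the V reference")
      carrier <- idx[runif(length(idx)) < pa$fraction[k]]
      carrier <- carrier[pa$position[k] <= nchar(v_trim[carrier])]
      for (i in carrier) {
        ref <- substr(template[i], pa$position[k], pa$position[k])
        substr(template[i], pa$position[k], pa$position[k]) <- pa$alt_base[k]
        allele_events[i] <- paste0(allele_events[i],
                                   if (nzchar(allele_events[i])) ";",
                                   pa$position[k], ":", ref, ">",
                                   pa$alt_base[k])
      }
    }
  }

  shm <- shm_stage(template, db$v$gene_name[vi], nchar(v_trim), config)
  full <- shm$sequence

  abundance <- if (config$max_clone_size <= 1L) rep(1L, n) else {
    sizes <- seq_len(config$max_clone_size)
    sample(sizes, n, replace = TRUE, prob = sizes^(-config$clone_alpha))
  }

  # the anchor codons are present iff the canonical germline extensions
  # cover them (an inserted base recreating germline counts as germline)
  cdr3 <- rep(NA_character_, n)
  v_anchor <- db$v$anchor_pos[vi]
  j_anchor <- db$j$anchor_pos[ji]
  canon_v_end <- vapply(canon, `[[`, integer(1), "v_end")
  canon_del_5j <- vapply(canon, `[[`, integer(1), "del_5j")
  ok <- (canon_v_end >= v_anchor + 2L) & (canon_del_5j < j_anchor)
  t_j_anchor <- nchar(full) - (j_len - j_anchor)
  cdr3[ok] <- substr(full[ok], v_anchor[ok], t_j_anchor[ok] + 2L)

  data.frame(
    clonotype_id = sprintf("c%06d", seq_len(n)),
    v_gene = db$v$gene_name[vi],
    d_gene = vapply(canon, `[[`, character(1), "d_gene"),
    j_gene = db$j$gene_name[ji],
    del_3v = vapply(canon, `[[`, integer(1), "del_3v"),
    del_5d = vapply(canon, `[[`, integer(1), "del_5d"),
    del_3d = vapply(canon, `[[`, integer(1), "del_3d"),
    del_5j = vapply(canon, `[[`, integer(1), "del_5j"),
    ins_vd = vapply(canon, `[[`, character(1), "ins_vd"),
    ins_dj = vapply(canon, `[[`, character(1), "ins_dj"),
    ins_vj = vapply(canon, `[[`, character(1), "ins_vj"),
    full_sequence = full, cdr3_nt = cdr3,
    shm_events = shm$events, allele_events = allele_events,
    abundance = abundance,
    # generative draws before canonicalization (for model validation; the
    # del_/ins_ fields above are the identifiable canonical decomposition)
    gen_del_3v = del_3v, gen_del_5d = del_5d, gen_del_3d = del_3d,
    gen_del_5j = del_5j, gen_ins_vd = ins_vd, gen_ins_dj = ins_dj,
    gen_ins_vj = ins_vj, stringsAsFactors = FALSE
  )
}

# SHM stage: per-position independent substitution at shm_rate (or a hotspot
# override on V reference positions), mutated base drawn from the
# substitution matrix row of the reference base.
shm_stage <- function(template, v_gene, v_trim_len, config) {
  n <- length(template)
  events <- rep("", n)
  if (config$shm_rate == 0 && is.null(config$shm_hotspots))
    return(list(sequence = template, events = events))
  sub <- config$shm_substitution
  if (is.null(sub)) {
    sub <- matrix(1 / 3, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
    diag(sub) <- 0
  }
  hs <- config$shm_hotspots
  for (i in seq_len(n)) {
    len <- nchar(template[i])
    rate <- rep(config$shm_rate, len)
    if (!is.null(hs) && nrow(hs) > 0L) {
      rows <- which(hs$gene == v_gene[i])
      for (k in rows) {
        if (hs$position[k] > len)
          stop("hotspot position beyond the simulated sequence")
        if (hs$position[k] <= v_trim_len[i]) rate[hs$position[k]] <- hs$rate[k]
      }
    }
    hit <- which(runif(len) < rate)
    if (length(hit) == 0L) next
    chars <- strsplit(template[i], "")[[1]]
    ev <- character(length(hit))
    for (m in seq_along(hit)) {
      p <- hit[m]
      ref <- chars[p]
      alt <- sample(DNA_BASES, 1L, prob = sub[ref, ])
      chars[p] <- alt
      ev[m] <- paste0(p, ":", ref, ">", alt)
    }
    template[i] <- paste(chars, collapse = "")
    events[i] <- paste(ev, collapse = ";")
  }
  list(sequence = template, events = events)
}

#' Apply somatic hypermutation to a simulated repertoire
#'
#' Standalone SHM stage for rearrangements simulated with `shm_rate = 0`.
#' A no-op for T-cell loci. Uses a seed derived from the configuration so the
#' result is deterministic.
#'
#' @param rearr rearrangement table from [simulate_repertoire()].
#' @param config a [sim_config()] carrying the SHM parameters.
#' @param db the germline database (for V gene names).
#' @return The rearrangement table with mutated `full_sequence` and filled
#'   `shm_events`.
#' @export
apply_shm <- function(rearr, config, db) {
  if (!(config$locus %in% c("IGH", "IGK", "IGL"))) return(rearr)
  set.seed(config$seed + 7L)
  v_len <- nchar(db$v$sequence[match(rearr$v_gene, db$v$gene_name)])
  shm <- shm_stage(rearr$full_sequence, rearr$v_gene,
                   v_len - rearr$del_3v, config)
  rearr$full_sequence <- shm$sequence
  rearr$shm_events <- shm$events
  rearr
}

#' Emit paired-end reads and the ground-truth table
#'
#' Each clonotype contributes `abundance` read pairs. The template is first
#' truncated to its 3'-most `fragment_length` nucleotides (the junction- and
#' FR3-containing end that the library chemistry covers); read 1 runs from
#' the fragment 5' end, read 2 is the reverse complement of the fragment
#' 3' end. Substitution errors (Q15) and `N` bases (Q2) are injected at the
#' configured rates on a Q30 baseline; qualities are phred+33. Sequencing
#' noise uses a stream derived from `config$seed`, so re-simulating the
#' repertoire does not shift the read errors.
#'
#' @param rearr rearrangement table from [simulate_repertoire()].
#' @param config the same [sim_config()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, a list with paths `read1`, `read2`, `truth`, `config`.
#' @export
emit_reads <- function(rearr, config, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 101L)
  rl <- config$read_length
  idx <- rep(seq_len(nrow(rearr)), rearr$abundance)
  copy <- sequence(rearr$abundance)
  tmpl <- rearr$full_sequence[idx]
  tl <- nchar(tmpl)
  frag <- substr(tmpl, pmax(1L, tl - config$fragment_length + 1L), tl)
  fl <- nchar(frag)
  r1 <- substr(frag, 1L, pmin(rl, fl))
  r2 <- revcomp(substr(frag, pmax(1L, fl - rl + 1L), fl))
  ids <- paste0(rearr$clonotype_id[idx], "_", copy)

  noisy <- function(seqs) {
    qual <- lapply(nchar(seqs), function(L) rep(30L, L))
    if (config$per_base_error_rate > 0 || config$n_rate > 0) {
      for (i in seq_along(seqs)) {
        L <- nchar(seqs[i])
        err <- which(runif(L) < config$per_base_error_rate)
        nn <- which(runif(L) < config$n_rate)
        if (length(err)) {
          ch <- strsplit(seqs[i], "")[[1]]
          for (p in err) {
            ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
            qual[[i]][p] <- 15L
          }
          seqs[i] <- paste(ch, collapse = "")
        }
        if (length(nn)) {
          ch <- strsplit(seqs[i], "")[[1]]
          ch[nn] <- "N"
          qual[[i]][nn] <- 2L
          seqs[i] <- paste(ch, collapse = "")
        }
      }
    }
    list(seq = seqs, qual = qual)
  }
  out1 <- noisy(r1)
  out2 <- noisy(r2)

  p1 <- file.path(dir, paste0(prefix, "_R1.fastq"))
  p2 <- file.path(dir, paste0(prefix, "_R2.fastq"))
  write_fastq(ids, out1$seq, out1$qual, p1, mate = 1L)
  write_fastq(ids, out2$seq, out2$qual, p2, mate = 2L)
  truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_tsv(rearr, truth_path)
  cfg_path <- file.path(dir, paste0(prefix, "_config.txt"))
  write_config_echo(config, cfg_path)
  invisible(list(read1 = p1, read2 = p2, truth = truth_path,
                 config = cfg_path))
}

write_fastq <- function(ids, seqs, quals, path, mate) {
  qc <- int_to_phred(quals)
  lines <- as.vector(rbind(paste0("@", ids, "/", mate), seqs, "+", qc))
  writeLines(lines, path)
  invisible(path)
}

write_config_echo <- function(config, path) {
  flat <- vapply(names(unclass(config)), function(k) {
    v <- config[[k]]
    if (is.null(v)) "NULL"
    else if (is.data.frame(v) || is.matrix(v)) paste0("<", class(v)[1], ">")
    else paste(ifelse(nzchar(names2(v)), paste0(names2(v), "="), ""), v,
               sep = "", collapse = ",")
  }, character(1))
  writeLines(paste0(names(flat), "\t", flat), path)
  invisible(path)
}

names2 <- function(x) if (is.null(names(x))) rep("", length(x)) else names(x)

#' Simulate a repertoire and write all outputs
#'
#' Convenience wrapper: [simulate_repertoire()] then [emit_reads()].
#'
#' @inheritParams emit_reads
#' @param db a functional-filtered germline database.
#' @return The list of output paths, invisibly.
#' @export
simulate_to_files <- function(config, db, dir, prefix = "sim") {
  rearr <- simulate_repertoire(config, db)
  emit_reads(rearr, config, dir, prefix)
}
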