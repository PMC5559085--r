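# End-to-end orchestration: preprocess -> annotate -> statistics ->
# diversity (-> SHM for B-cell loci), with per-stage accounting.

#' Pipeline run configuration
#'
#' Every tunable of every stage with its default; unknown keys are rejected.
#'
#' @param locus locus code.
#' @param read1,read2 paired FASTQ paths.
#' @param outdir output directory.
#' @param db a functional-filtered [germline_db()] (or `NULL` to load from
#'   `germline_fasta`).
#' @param germline_fasta optional named list of FASTA paths
#'   (`v`, `d`, `j`) read and functionality-filtered on run.
#' @param seed integer seed (rarefaction subsampling).
#' @param min_mean_q,max_n_frac quality-filter thresholds.
#' @param min_overlap,max_mismatch_rate pair-merging thresholds.
#' @param params [annotate_params()] list.
#' @param collapse apply [collapse_errors()] (default `TRUE`).
#' @param collapse_max_dist,collapse_ratio error-collapse parameters.
#' @param diversity_unit `"aa"` and/or `"nt"` richness reporting.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(locus, read1, read2, outdir, db = NULL,
                            germline_fasta = NULL, seed = 1L,
                            min_mean_q = 15, max_n_frac = 0.05,
                            min_overlap = 10L, max_mismatch_rate = 0.1,
                            params = annotate_params(), collapse = TRUE,
                            collapse_max_dist = 1L, collapse_ratio = 0.01,
                            diversity_unit = c("nt", "aa")) {
  locus <- match.arg(locus, LOCI)
  structure(as.list(environment()), class = "run_config")
}

#' Run the repertoire profiling pipeline
#'
#' Executes quality control and pair merging, V/(D)/J annotation with CDR3
#' extraction and junction decomposition, repertoire statistics, rarefaction
#' diversity, and (for B-cell loci) FR3 mutation profiling. All tables are
#' written as TSV into `outdir` together with a machine-readable stage-count
#' summary (`run_summary.tsv`): raw pairs, QC-passed, merged, assigned,
#' productive, distinct CDR3.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `annotations`, `table`, `summary`, and the
#'   statistic tables.
#' @export
run_repertoire_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  db <- config$db
  if (is.null(db)) {
    if (is.null(config$germline_fasta))
      stop("either db or germline_fasta must be given", call. = FALSE)
    gf <- config$germline_fasta
    v <- filter_functional(read_germline_fasta(gf$v, config$locus, "V"), "V")
    j <- filter_functional(read_germline_fasta(gf$j, config$locus, "J"), "J")
    d <- if (!is.null(gf$d)) read_germline_fasta(gf$d, config$locus, "D")
    db <- germline_db(config$locus, v = v, j = j, d = d)
  }

  pp <- preprocess_reads(config$read1, config$read2, config$min_mean_q,
                         config$max_n_frac, config$min_overlap,
                         config$max_mismatch_rate)
  ann <- annotate_reads(pp$merged$read_id, pp$merged$sequence, db,
                        config$params)
  if (isTRUE(config$collapse))
    ann <- collapse_errors(ann, config$collapse_max_dist,
                           config$collapse_ratio)
  tab <- repertoire_table(ann, productive_only = TRUE)

  out <- list(annotations = ann, table = tab, qc_report = pp$report)
  write_tsv(ann, file.path(config$outdir, "annotations.tsv"))
  write_tsv(tab, file.path(config$outdir, "clonotypes.tsv"))

  if (nrow(tab) > 0L) {
    out$v_usage <- usage_frequencies(tab, "V")
    out$j_usage <- usage_frequencies(tab, "J")
    out$vj_usage <- usage_frequencies(tab, "VJ")
    out$cdr3_length_aa <- cdr3_length_distribution(tab, "aa")
    out$rank_abundance <- rank_abundance(tab)
    out$aa_composition <- aa_composition(tab)
    out$junction_lengths <-
      junction_indel_distributions(ann[ann$productive, , drop = FALSE])
    out$inserted_nt <-
      inserted_nt_composition(ann[ann$productive, , drop = FALSE])
    for (nm in c("v_usage", "j_usage", "vj_usage", "cdr3_length_aa",
                 "rank_abundance", "aa_composition", "junction_lengths",
                 "inserted_nt"))
      write_tsv(out[[nm]], file.path(config$outdir, paste0(nm, ".tsv")))

    div <- list()
    for (unit in config$diversity_unit) {
      rc <- richness_counts(tab, unit)
      est <- chao1(rc$s_obs, rc$f1, rc$f2)
      div[[unit]] <- data.frame(unit = unit, s_obs = rc$s_obs, f1 = rc$f1,
                                f2 = rc$f2, chao1 = as.numeric(est),
                                fraction_captured =
                                  fraction_captured(rc$s_obs,
                                                    as.numeric(est)))
      rar <- rarefaction(tab, unit, seed = config$seed)
      write_tsv(rar, file.path(config$outdir,
                               paste0("rarefaction_", unit, ".tsv")))
    }
    out$diversity <- do.call(rbind, div)
    write_tsv(out$diversity, file.path(config$outdir, "diversity.tsv"))

    if (config$locus %in% c("IGH", "IGK", "IGL")) {
      prof <- build_profiles(ann, db)
      out$profiles <- prof
      out$hotspots <- call_hotspots(prof)
      out$polymorphic <- detect_polymorphic_sites(prof)
      out$spectrum_nt <- substitution_spectrum(prof, "nt")
      write_tsv(prof$nt, file.path(config$outdir, "fr3_profiles.tsv"))
      write_tsv(out$hotspots, file.path(config$outdir, "hotspots.tsv"))
      write_tsv(out$polymorphic,
                file.path(config$outdir, "polymorphic_sites.tsv"))
      write_tsv(out$spectrum_nt,
                file.path(config$outdir, "mutation_spectrum_nt.tsv"))
    }
  }

  summary <- data.frame(
    raw_pairs = pp$report$reads_in,
    qc_passed = pp$report$reads_in - pp$report$dropped_low_quality -
      pp$report$dropped_n_excess,
    dropped_low_quality = pp$report$dropped_low_quality,
    dropped_n_excess = pp$report$dropped_n_excess,
    merged = pp$report$merged,
    assigned = sum(ann$assigned),
    productive = sum(ann$productive),
    distinct_cdr3_nt = length(unique(tab$cdr3_nt)),
    distinct_clonotypes = nrow(tab)
  )
  out$summary <- summary
  write_tsv(summary, file.path(config$outdir, "run_summary.tsv"))
  invisible(out)
}
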