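test_that("exact germline containment is assigned with identity 1", {
  db <- tiny_trb_db()
  v <- db$v$sequence[2]
  j <- db$j$sequence[3]
  seq <- paste0(substr(v, nchar(v) - 119, nchar(v)), j)
  ann <- assign_vj(seq, db)
  expect_true(ann$assigned)
  expect_equal(ann$v_gene, db$v$gene_name[2])
  expect_equal(ann$j_gene, db$j$gene_name[3])
  expect_equal(ann$v_identity, 1)
  expect_equal(ann$j_identity, 1)
  expect_false(ann$v_tie)
})

test_that("score ties go to the lexicographically smaller gene name and are flagged", {
  db <- tiny_trb_db()
  twin <- db$v[1:2, ]
  twin$gene_name <- c("TRBV_Z", "TRBV_A")
  twin$sequence[1] <- twin$sequence[2]
  twin$anchor_pos[1] <- twin$anchor_pos[2]
  db2 <- germline_db("TRB", v = twin, j = db$j, d = db$d)
  seq <- paste0(substr(twin$sequence[1], 100, 321), db$j$sequence[1])
  ann <- assign_vj(seq, db2)
  expect_equal(ann$v_gene, "TRBV_A")
  expect_true(ann$v_tie)
})

test_that("sequences matching nothing are left unassigned", {
  db <- tiny_trb_db()
  set.seed(10)
  ann <- assign_vj(random_dna(150), db)
  expect_false(ann$assigned)
  expect_equal(ann$assign_reason, "v_below_threshold")
  empty <- db
  empty$v <- empty$v[0, ]
  expect_error(assign_vj("ACGT", empty), "empty germline")
})

test_that("CDR3 spans the conserved cysteine through the [FW] codon", {
  # V ends ...TGTGCCAGCAGC with the anchor at the TGT; J carries
  # TTTGGCCAAGGG with the anchor at the TTT
  set.seed(11)
  v <- gene_row(paste0(strrep("GCA", 20), "TGTGCCAGCAGC"), name = "Vx")
  v <- filter_functional(v, "V")
  j <- gene_row(paste0("TTTGGCCAAGGGT", random_dna(8)), segment = "J",
                name = "Jx")
  j <- filter_functional(j, "J")
  expect_equal(j$anchor_pos, 1L)
  db <- germline_db("TRA", v = v, j = j)
  read <- paste0(v$sequence, "TTAGGGACT", j$sequence)
  ann <- extract_cdr3(read, assign_vj(read, db))
  expect_equal(ann$cdr3_nt, "TGTGCCAGCAGCTTAGGGACTTTT")
  expect_equal(ann$cdr3_aa, "CASSLGTF")
  expect_equal(ann$cdr3_reason, "ok")
})

test_that("a V alignment ending before the anchor yields no CDR3", {
  db <- synthetic_germline_db("TRA", n_v = 1, n_j = 1, seed = 12)
  v <- db$v
  # the read stops 10 nt short of the anchor cysteine codon
  read <- paste0(substr(v$sequence, 1, v$anchor_pos - 10L),
                 db$j$sequence[1])
  ann <- extract_cdr3(read, assign_vj(read, db))
  expect_true(ann$assigned)
  expect_equal(ann$cdr3_reason, "anchor_missing")
  expect_true(is.na(ann$cdr3_nt))
})

test_that("productivity follows frame, stop-codon, and CDR3 rules", {
  set.seed(13)
  v <- gene_row(paste0(strrep("GCA", 20), "TGTGCCAGCAGC"), name = "Vx")
  v <- filter_functional(v, "V")
  j <- gene_row(paste0("TTTGGCCAAGGGT", random_dna(8)), segment = "J",
                name = "Jx")
  j <- filter_functional(j, "J")
  db <- germline_db("TRA", v = v, j = j)
  run <- function(mid) {
    read <- paste0(v$sequence, mid, j$sequence)
    classify_productive(read, extract_cdr3(read, assign_vj(read, db)))
  }
  in_frame <- run("TTAGGGACT")          # 24 nt CDR3, no stop
  expect_true(in_frame$productive)
  expect_equal(in_frame$productive_reason, "ok")
  shifted <- run("TTAGGGAC")            # 23 nt CDR3
  expect_false(shifted$productive)
  expect_equal(shifted$productive_reason, "out_of_frame")
  stopped <- run("TAGGGGACT")           # TAG immediately after the cysteine
  expect_false(stopped$productive)
  expect_equal(stopped$productive_reason, "stop_codon")
})

test_that("null junctions decompose to all-zero sections", {
  db <- synthetic_germline_db("TRB", n_v = 2, n_d = 1, n_j = 2, seed = 15)
  cfg <- sim_config("TRB", n_clonotypes = 20, seed = 2,
                    del_mean = c(v3 = 0, d5 = 0, d3 = 0, j5 = 0),
                    ins_mean = c(vd = 0, dj = 0, vj = 0))
  r <- simulate_repertoire(cfg, db)
  dir <- withr::local_tempdir()
  out <- emit_reads(r, cfg, dir)
  pp <- preprocess_reads(out$read1, out$read2)
  ann <- annotate_reads(pp$merged$read_id, pp$merged$sequence, db)
  a <- ann[ann$assigned, ]
  expect_gt(nrow(a), 0L)
  expect_true(all(a$del_3v == 0 & a$del_5j == 0 &
                    a$del_5d == 0 & a$del_3d == 0))
  expect_true(all(a$ins_vd == "" & a$ins_dj == ""))
  expect_true(all(!is.na(a$d_gene)))
})

test_that("V-J loci report only the V-J insertion section", {
  db <- synthetic_germline_db("IGK", n_v = 3, n_j = 2, seed = 16)
  cfg <- sim_config("IGK", n_clonotypes = 30, seed = 3)
  r <- simulate_repertoire(cfg, db)
  dir <- withr::local_tempdir()
  out <- emit_reads(r, cfg, dir)
  pp <- preprocess_reads(out$read1, out$read2)
  ann <- annotate_reads(pp$merged$read_id, pp$merged$sequence, db)
  expect_true(all(is.na(ann$d_gene)))
  expect_true(all(is.na(ann$del_5d) & is.na(ann$del_3d)))
  expect_true(all(ann$ins_vd[ann$assigned] == ""))
  truth <- r[match(sub("_[0-9]+$", "", ann$read_id), r$clonotype_id), ]
  expect_gt(mean(ann$ins_vj == truth$ins_vj, na.rm = TRUE), 0.95)
})

test_that("best gene and score agree with an exhaustive dynamic-programming oracle", {
  db <- synthetic_germline_db("TRA", n_v = 4, n_j = 3, seed = 18)
  cfg <- sim_config("TRA", n_clonotypes = 20, seed = 4,
                    per_base_error_rate = 0.02)
  r <- simulate_repertoire(cfg, db)
  dir <- withr::local_tempdir()
  out <- emit_reads(r, cfg, dir)
  pp <- preprocess_reads(out$read1, out$read2)
  seqs <- gsub("N", "A", pp$merged$sequence)   # oracle matrix is ACGT-only
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  scores <- vdjprof:::cpp_sw_scores(seqs, db$v$sequence)
  for (i in seq_along(seqs)) {
    oracle <- vapply(db$v$sequence, function(ref) {
      Biostrings::pairwiseAlignment(seqs[i], ref, type = "local",
                                    substitutionMatrix = mat,
                                    gapOpening = 3, gapExtension = 1,
                                    scoreOnly = TRUE)
    }, numeric(1))
    expect_equal(as.numeric(scores[i, ]), as.numeric(oracle))
  }
})

test_that("junction reconstruction reproduces the read span byte for byte", {
  db <- tiny_trb_db()
  cfg <- sim_config("TRB", n_clonotypes = 150, seed = 6)
  r <- simulate_repertoire(cfg, db)
  dir <- withr::local_tempdir()
  out <- emit_reads(r, cfg, dir)
  pp <- preprocess_reads(out$read1, out$read2)
  ann <- annotate_reads(pp$merged$read_id, pp$merged$sequence, db)
  vs <- setNames(db$v$sequence, db$v$gene_name)
  ds <- setNames(db$d$sequence, db$d$gene_name)
  js <- setNames(db$j$sequence, db$j$gene_name)
  # restrict to reads whose kept alignment columns are mismatch-free, so
  # the germline-based reconstruction is exact (mismatches retained inside
  # an alignment are mutations, not junction bookkeeping)
  for (i in which(ann$assigned & !ann$junction_conflict &
                    is.na(ann$v_mismatches) & ann$j_identity == 1)) {
    v <- vs[[ann$v_gene[i]]]
    j <- js[[ann$j_gene[i]]]
    mid <- if (!is.na(ann$d_gene[i])) {
      d <- ds[[ann$d_gene[i]]]
      paste0(ann$ins_vd[i],
             substr(d, ann$del_5d[i] + 1, nchar(d) - ann$del_3d[i]),
             ann$ins_dj[i])
    } else ann$ins_vd[i]
    span <- paste0(
      substr(v, ann$v_rstart[i], nchar(v) - ann$del_3v[i]), mid,
      substr(j, ann$del_5j[i] + 1, ann$j_rend[i]))
    read_span <- substr(pp$merged$sequence[i], ann$v_qstart[i],
                        ann$j_qend[i])
    expect_identical(span, read_span)
  }
})

test_that("mixed kappa/lambda sequences demultiplex by best V score", {
  igk <- synthetic_germline_db("IGK", n_v = 3, n_j = 2, seed = 20)
  igl <- synthetic_germline_db("IGL", n_v = 3, n_j = 2, seed = 21)
  ck <- sim_config("IGK", n_clonotypes = 60, seed = 7)
  cl <- sim_config("IGL", n_clonotypes = 60, seed = 8)
  rk <- simulate_repertoire(ck, igk)
  rl <- simulate_repertoire(cl, igl)
  seqs <- c(rk$full_sequence, rl$full_sequence)
  lab <- split_igkl(seqs, igk, igl)
  truth <- rep(c("IGK", "IGL"), each = 60)
  expect_gte(mean(lab == truth), 0.99)
  # an identical V in both databases gives an unresolved tie
  igl2 <- igl
  igl2$v$sequence[1] <- igk$v$sequence[1]
  expect_equal(split_igkl(igk$v$sequence[1], igk, igl2), "unresolved")
})

test_that("error collapsing absorbs rare neighbours and respects guards", {
  mk_ann <- function(cdr3, v, j, n) {
    data.frame(cdr3_nt = rep(cdr3, n), cdr3_aa = rep("X", n),
               v_gene = rep(v, n), j_gene = rep(j, n),
               stringsAsFactors = FALSE)
  }
  a <- "TGTGCCAGCAGCTTAGGGACTTTT"
  b <- a; substr(b, 5, 5) <- "T"
  ann <- rbind(mk_ann(a, "V1", "J1", 1000), mk_ann(b, "V1", "J1", 5))
  out <- collapse_errors(ann)
  expect_true(all(out$cdr3_nt == a))
  expect_equal(sum(out$clonotype_collapsed), 5L)
  # ratio guard: 900 vs 1000 is far above 1%
  ann2 <- rbind(mk_ann(a, "V1", "J1", 100), mk_ann(b, "V1", "J1", 90))
  out2 <- collapse_errors(ann2)
  expect_false(any(out2$clonotype_collapsed))
  # different V genes are never merged even at distance 0
  ann3 <- rbind(mk_ann(a, "V1", "J1", 1000), mk_ann(a, "V2", "J1", 2))
  out3 <- collapse_errors(ann3)
  expect_false(any(out3$clonotype_collapsed))
})

test_that("repertoire tables aggregate productive clonotypes", {
  ann <- data.frame(
    locus = "TRB",
    cdr3_nt = c("AAA", "AAA", "CCC", "GGG"),
    cdr3_aa = c("K", "K", "P", "G"),
    v_gene = "V1", j_gene = "J1",
    productive = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  tab <- repertoire_table(ann)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$read_count[tab$cdr3_nt == "AAA"], 2L)
  expect_equal(attr(tab, "locus"), "TRB")
})
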