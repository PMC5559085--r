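test_that("zero-editing simulation concatenates germline V and J exactly", {
  db <- synthetic_germline_db("TRA", n_v = 1, n_j = 1, seed = 3)
  cfg <- sim_config("TRA", n_clonotypes = 5, seed = 1,
                    del_mean = c(v3 = 0, d5 = 0, d3 = 0, j5 = 0),
                    ins_mean = c(vd = 0, dj = 0, vj = 0))
  r <- simulate_repertoire(cfg, db)
  expect_true(all(r$full_sequence ==
                    paste0(db$v$sequence[1], db$j$sequence[1])))
  expect_true(all(r$del_3v == 0 & r$del_5j == 0 & r$ins_vj == ""))
})

test_that("simulation is byte-identical for a fixed seed", {
  db <- tiny_trb_db()
  cfg <- sim_config("TRB", n_clonotypes = 50, seed = 99,
                    per_base_error_rate = 0.01, n_rate = 0.005)
  r1 <- simulate_repertoire(cfg, db)
  r2 <- simulate_repertoire(cfg, db)
  expect_identical(r1, r2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  o1 <- simulate_to_files(cfg, db, d1)
  o2 <- simulate_to_files(cfg, db, d2)
  expect_identical(readLines(o1$read1), readLines(o2$read1))
  expect_identical(readLines(o1$read2), readLines(o2$read2))
})

test_that("empirical V usage matches the configured weights", {
  db <- synthetic_germline_db("TRA", n_v = 5, n_j = 3, seed = 13)
  cfg <- sim_config("TRA", n_clonotypes = 10000, seed = 2)
  r <- simulate_repertoire(cfg, db)
  p <- table(factor(r$v_gene, levels = db$v$gene_name)) / nrow(r)
  se <- sqrt(0.2 * 0.8 / nrow(r))
  expect_true(all(abs(p - 0.2) <= 3 * se))
  # skewed weights are respected too
  w <- setNames(c(6, 1, 1, 1, 1), db$v$gene_name)
  cfg2 <- sim_config("TRA", n_clonotypes = 10000, seed = 2,
                     v_usage_weights = w)
  r2 <- simulate_repertoire(cfg2, db)
  expect_equal(mean(r2$v_gene == db$v$gene_name[1]), 0.6,
               tolerance = 3 * sqrt(0.6 * 0.4 / 10000) / 0.6)
})

test_that("ground truth reconstructs the stored sequence exactly", {
  db <- tiny_igh_db()
  cfg <- sim_config("IGH", n_clonotypes = 300, seed = 21, shm_rate = 0.03)
  r <- simulate_repertoire(cfg, db)
  vs <- setNames(db$v$sequence, db$v$gene_name)
  ds <- setNames(db$d$sequence, db$d$gene_name)
  js <- setNames(db$j$sequence, db$j$gene_name)
  apply_events <- function(seq, events) {
    if (!nzchar(events)) return(seq)
    for (ev in strsplit(events, ";", fixed = TRUE)[[1]]) {
      m <- regmatches(ev, regexec("^([0-9]+):([ACGT])>([ACGT])$", ev))[[1]]
      p <- as.integer(m[2])
      stopifnot(substr(seq, p, p) == m[3])
      substr(seq, p, p) <- m[4]
    }
    seq
  }
  for (i in seq_len(nrow(r))) {
    v <- vs[[r$v_gene[i]]]
    j <- js[[r$j_gene[i]]]
    mid <- if (!is.na(r$d_gene[i])) {
      d <- ds[[r$d_gene[i]]]
      paste0(r$ins_vd[i],
             substr(d, r$del_5d[i] + 1L, nchar(d) - r$del_3d[i]),
             r$ins_dj[i])
    } else r$ins_vd[i]
    tmpl <- paste0(substr(v, 1, nchar(v) - r$del_3v[i]), mid,
                   substr(j, r$del_5j[i] + 1L, nchar(j)))
    tmpl <- apply_events(tmpl, r$allele_events[i])
    tmpl <- apply_events(tmpl, r$shm_events[i])
    expect_identical(tmpl, r$full_sequence[i])
  }
})

test_that("SHM stage hits the expected per-sequence mutation load", {
  db <- synthetic_germline_db("IGK", n_v = 3, n_j = 2, seed = 17)
  cfg0 <- sim_config("IGK", n_clonotypes = 400, seed = 5)
  r0 <- simulate_repertoire(cfg0, db)
  expect_true(all(r0$shm_events == ""))
  cfg <- sim_config("IGK", n_clonotypes = 400, seed = 5, shm_rate = 0.05)
  r <- simulate_repertoire(cfg, db)
  n_mut <- lengths(strsplit(r$shm_events, ";", fixed = TRUE))
  expected <- mean(nchar(r$full_sequence)) * 0.05
  se <- sqrt(sum(nchar(r$full_sequence)) * 0.05 * 0.95) / nrow(r)
  expect_lt(abs(mean(n_mut) - expected), 4 * se)
})

test_that("heterozygous allele carriage is binomial in the configured fraction", {
  db <- synthetic_germline_db("IGK", n_v = 1, n_j = 2, seed = 19)
  ref <- substr(db$v$sequence[1], 250, 250)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  pa <- data.frame(gene = db$v$gene_name[1], position = 250,
                   alt_base = alt, fraction = 0.5)
  cfg <- sim_config("IGK", n_clonotypes = 1000, seed = 31,
                    polymorphic_alleles = pa)
  r <- simulate_repertoire(cfg, db)
  carriers <- sum(nzchar(r$allele_events))
  expect_lt(abs(carriers - 500), 3 * sqrt(250))
  expect_true(all(substr(r$full_sequence[nzchar(r$allele_events)],
                         250, 250) == alt))
  bad <- data.frame(gene = db$v$gene_name[1], position = 9999,
                    alt_base = "A", fraction = 0.5)
  cfgb <- sim_config("IGK", n_clonotypes = 10, seed = 1,
                     polymorphic_alleles = bad)
  expect_error(simulate_repertoire(cfgb, db), "beyond")
})

test_that("error-free reads are exact template substrings with the expected overlap", {
  db <- tiny_tra_db()
  cfg <- sim_config("TRA", n_clonotypes = 30, seed = 8,
                    fragment_length = 150L)
  r <- simulate_repertoire(cfg, db)
  dir <- withr::local_tempdir()
  out <- emit_reads(r, cfg, dir)
  pairs <- read_fastq_pair(out$read1, out$read2)
  tmpl <- r$full_sequence[match(sub("_[0-9]+$", "", pairs$read_id),
                                r$clonotype_id)]
  rc2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(pairs$seq2)))
  ok1 <- mapply(grepl, pairs$seq1, tmpl, MoreArgs = list(fixed = TRUE))
  ok2 <- mapply(grepl, rc2, tmpl, MoreArgs = list(fixed = TRUE))
  expect_true(all(ok1) && all(ok2))
  # 150 nt fragment with 2 x 100 bp reads: 50 nt overlap
  mg <- merge_pairs(pairs)
  long <- nchar(tmpl) >= 150
  expect_true(all(mg$merged[long]))
  expect_true(all(mg$overlap_len[long] == 50L))
  expect_true(all(mg$n_mismatches_in_overlap[long] == 0L))
})

test_that("QC removal under N noise matches the binomial tail", {
  db <- tiny_tra_db()
  cfg <- sim_config("TRA", n_clonotypes = 2000, seed = 77, n_rate = 0.06)
  dir <- withr::local_tempdir()
  out <- simulate_to_files(cfg, db, dir)
  pairs <- read_fastq_pair(out$read1, out$read2)
  qc <- quality_filter(pairs)
  # a mate fails when its N count exceeds 5% of 100 bases
  p_mate <- 1 - pbinom(5, 100, 0.06)
  p_pair <- 1 - (1 - p_mate)^2
  drop <- mean(!qc$keep)
  expect_lt(abs(drop - p_pair), 4 * sqrt(p_pair * (1 - p_pair) / 2000))
  expect_true(all(qc$reason[!qc$keep] == "n_excess"))
})

test_that("insertion lengths and base composition follow the configured models", {
  db <- tiny_trb_db()
  probs <- c(A = 0.17, C = 0.27, G = 0.39, T = 0.17)
  cfg <- sim_config("TRB", n_clonotypes = 10000, seed = 41,
                    insertion_base_probs = probs)
  r <- simulate_repertoire(cfg, db)
  bases <- unlist(strsplit(c(r$gen_ins_vd, r$gen_ins_dj), ""))
  obs <- table(factor(bases, levels = c("A", "C", "G", "T")))
  expect_gt(chisq.test(obs, p = probs)$p.value, 0.01)
  # geometric(mean 4) insertion lengths and geometric(mean 2) V trims
  gof_geom <- function(x, m) {
    p <- 1 / (1 + m)
    lev <- 0:max(x)
    p_exp <- dgeom(lev, p)
    p_exp[length(p_exp)] <- 1 - pgeom(max(x) - 1, p)
    keep <- p_exp * length(x) >= 5
    obs <- table(factor(x, levels = lev))[keep]
    chisq.test(obs, p = p_exp[keep] / sum(p_exp[keep]))$p.value
  }
  expect_gt(gof_geom(nchar(r$gen_ins_vd), 4), 0.01)
  expect_gt(gof_geom(r$gen_del_3v, 2), 0.01)
  expect_gt(gof_geom(r$gen_del_5j, 2), 0.01)
})

test_that("clone sizes follow the truncated power law", {
  db <- tiny_tra_db()
  cfg <- sim_config("TRA", n_clonotypes = 5000, seed = 3,
                    max_clone_size = 50L, clone_alpha = 2)
  r <- simulate_repertoire(cfg, db)
  expect_true(all(r$abundance >= 1 & r$abundance <= 50))
  p_exp <- (1:50)^-2 / sum((1:50)^-2)
  obs <- table(factor(r$abundance, levels = 1:50))
  keep <- p_exp * 5000 >= 5
  expect_gt(chisq.test(obs[keep], p = p_exp[keep] / sum(p_exp[keep]))$p.value,
            0.01)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config("TRA", insertion_base_probs = c(A = 1, C = 1,
                                                          G = 0, T = 0)),
               "sum to 1")
  expect_error(sim_config("IGK", d_usage_weights = c(D1 = 1)), "empty")
  expect_error(sim_config("TRB", shm_rate = 0.05), "B-cell")
  db <- tiny_tra_db()
  empty <- db
  empty$j <- empty$j[0, ]
  cfg <- sim_config("TRA", n_clonotypes = 5)
  expect_error(simulate_repertoire(cfg, empty), "empty gene collection")
})
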