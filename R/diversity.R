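# Chao1 richness estimation and rarefaction.

#' Chao1 richness estimator
#'
#' `S1 = S_obs + F1^2 / (2 * F2)`, where `F1` and `F2` are the numbers of
#' species (distinct CDR3s) seen exactly once and exactly twice. When
#' `F2 = 0` the bias-corrected form
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` is used and the result carries
#' `attr(, "fallback") = TRUE`.
#'
#' @param s_obs observed number of distinct species.
#' @param f1 number of singletons.
#' @param f2 number of doubletons.
#' @return The estimate (numeric scalar), never below `s_obs`.
#' @export
chao1 <- function(s_obs, f1, f2) {
  if (s_obs < 0 || f1 < 0 || f2 < 0) stop("counts must be non-negative")
  if (f1 > s_obs || f2 > s_obs) stop("F1 and F2 cannot exceed S_obs")
  if (f2 > 0) {
    out <- s_obs + f1^2 / (2 * f2)
    attr(out, "fallback") <- FALSE
  } else {
    out <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    attr(out, "fallback") <- TRUE
  }
  out
}

#' Singleton/doubleton tally of a clonotype table
#'
#' @param table clonotype table from [repertoire_table()].
#' @param unit `"aa"` or `"nt"`: the CDR3 level at which species are
#'   distinct.
#' @return A list with `s_obs`, `f1`, `f2`.
#' @export
richness_counts <- function(table, unit) {
  unit <- match.arg(unit, c("aa", "nt"))
  key <- if (unit == "aa") table$cdr3_aa else table$cdr3_nt
  counts <- tapply(table$read_count, key, sum)
  list(s_obs = length(counts), f1 = sum(counts == 1L),
       f2 = sum(counts == 2L))
}

#' Fraction of the estimated richness captured by sequencing
#'
#' @param s_obs observed distinct CDR3 count.
#' @param chao1_estimate Chao1 estimate for the same repertoire.
#' @return `100 * s_obs / chao1_estimate`, rounded to the nearest integer
#'   percent.
#' @export
fraction_captured <- function(s_obs, chao1_estimate) {
  if (s_obs <= 0) stop("s_obs must be positive")
  if (chao1_estimate < s_obs)
    stop("Chao1 estimate below observed richness")
  round(100 * s_obs / chao1_estimate)
}

#' Rarefaction of repertoire richness
#'
#' At each sample fraction 0.1, 0.2, ..., 1.0, reads (clonotype rows
#' expanded by abundance) are drawn without replacement and the observed
#' richness and Chao1 estimate computed; each fraction is repeated
#' `replicates` times. Deterministic for a fixed seed; at fraction 1.0 the
#' sample is exhaustive so all replicates are identical.
#'
#' @param table clonotype table.
#' @param unit `"aa"` or `"nt"` (no default: the diversity unit must be
#'   chosen explicitly).
#' @param seed integer seed.
#' @param fractions sample fractions (default ten 0.1 steps).
#' @param replicates replicates per fraction (default 10).
#' @return A data frame (`fraction`, `replicate`, `s_obs`, `chao1`).
#' @export
rarefaction <- function(table, unit, seed,
                        fractions = seq(0.1, 1, by = 0.1),
                        replicates = 10L) {
  unit <- match.arg(unit, c("aa", "nt"))
  if (nrow(table) == 0L) stop("empty repertoire table")
  key <- if (unit == "aa") table$cdr3_aa else table$cdr3_nt
  reads <- rep(key, table$read_count)
  n <- length(reads)
  set.seed(seed)
  rows <- list()
  for (f in fractions) {
    k <- floor(f * n)
    if (k < 1L) {
      warning("fraction ", f, " yields no reads; skipped")
      next
    }
    for (r in seq_len(replicates)) {
      sub <- if (k == n) reads else sample(reads, k)
      counts <- table(sub)
      s_obs <- length(counts)
      est <- chao1(s_obs, sum(counts == 1L), sum(counts == 2L))
      rows[[length(rows) + 1L]] <- data.frame(fraction = f, replicate = r,
                                              s_obs = s_obs,
                                              chao1 = as.numeric(est))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
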