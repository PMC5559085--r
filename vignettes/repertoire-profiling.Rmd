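---
title: "Profiling immune repertoires with vdjprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling immune repertoires with vdjprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdjprof)
```

## The problem

Adaptive immune receptors (T-cell receptors and B-cell immunoglobulins) are
assembled somatically by V(D)J recombination: one Variable, optionally one
Diversity, and one Joining germline gene are joined, with exonucleolytic
trimming of the joined ends and non-template (N) nucleotide insertion at the
junctions. The third complementarity-determining region (CDR3) — spanning
the conserved V-gene cysteine through the conserved J-gene
phenylalanine/tryptophan of the [FW]GXG motif — is the hypervariable loop
that contacts antigen, and its nucleotide sequence together with the V and J
gene identifies a clonotype. B-cell receptors additionally acquire somatic
hypermutation (SHM): stepwise single-nucleotide substitutions across the
variable region during affinity maturation.

`vdjprof` profiles such repertoires from paired-end amplicon reads: it
quality-filters and merges read pairs, assigns the best V/(D)/J genes by
local alignment, extracts and translates the CDR3, decomposes each junction
into its seven indel sections, and computes gene-usage, CDR3-length,
composition, diversity (Chao1/rarefaction), and per-position FR3 mutation
statistics including hotspot and germline-polymorphism inference. A
ground-truthed simulator generates realistic repertoires so every stage can
be validated against known truth.

## Germline handling

Germline V and J genes are kept only when they carry the anchors that define
a CDR3:

* **V genes** need an in-frame cysteine codon (`TGT`/`TGC`) whose codon
  starts within the last 30 nucleotides of the reference. The reading frame
  is frame 1 of the (degapped) reference, which is how IMGT-style V
  references are laid out. When several such codons exist the rightmost is
  the anchor — the CDR3 starts at the *last* cysteine.
* **J genes** need the [FW]GXG tetrapeptide in some reading frame; all three
  frames are scanned and the 5'-most hit anchors the CDR3 end. This choice
  is the junction-proximal one; J references are short enough that multiple
  hits are rare.

References containing IMGT gap characters (`.`) are degapped on read, and
the FR3 interval — nucleotides 196–310 of the V reference under the IMGT
unique numbering, clipped to the reference length — is remapped through the
gap pattern so reported positions keep the gapped numbering. All external
coordinates are 1-based and inclusive.

Functionality filtering here is purely motif-based; curated
pseudogene/open-reading-frame annotations from source databases are not
consulted (they are not generally available for the loci this package
targets).

## The simulator and what it does (and does not) emulate

`sim_config()` + `simulate_repertoire()` draw, per clonotype: V/(D)/J genes
from configurable usage weights; trimming lengths for the four deletion
sections (3'V, 5'D, 3'D, 5'J) from geometric distributions (default means
2, 1, 1, 2 nt); insertion lengths (default mean 4 nt) and insertion bases
from a configurable base distribution; optional heterozygous germline
alleles carried with a configurable fraction; per-position SHM (with
hotspot overrides and a configurable substitution matrix) for B-cell loci;
and a truncated power-law clone size. Geometric length models and the
power-law rank-abundance are conventional choices for data whose generative
form is not known; every parameter is exposed.

Random draws consume the generator in a fixed stage order (genes, trims,
insertions, alleles, SHM, abundance), so a seed fully determines the
repertoire. Sequencing noise in `emit_reads()` uses a stream derived from
the same seed with a fixed offset, so regenerating the repertoire does not
shift the read errors — each stage is reproducible in isolation.

**Canonical junction ground truth.** After assembly the stored junction
decomposition is re-derived from the sequence by maximal exact germline
extension (V extended rightward, J leftward, V winning any overlap, then
the longest exact D match of at least 5 nt). An inserted base that happens
to equal the next germline base is indistinguishable from germline, so only
this canonical form is identifiable by any annotator; storing the raw
generative draws as truth would make exact recovery impossible in
principle. The raw draws are kept in `gen_*` columns for validating the
generative distributions. The reconstruction invariant — germline parts
plus insertions plus recorded mutation events rebuild `full_sequence`
byte-for-byte — holds for the canonical fields.

**Read layout.** Real libraries in this design sequence from the constant
side, and sonication selects 150–250 bp fragments, so reads reach the FR3
but not CDR2. The simulator emulates the informative part of that layout:
the template is truncated to its 3'-most `fragment_length` nucleotides
(default 180 nt) and a 2×100 bp pair is generated from the fragment ends.
180 nt sits inside the empirical fragment-size band while leaving a 20 nt
overlap so pairs can be merged; with 250 nt fragments a 2×100 bp pair has
no overlap at all and could never merge, which would disconnect the
simulator from the downstream contract. Qualities are a flat Q30 baseline
with errored bases at Q15 and `N` bases at Q2 — only the QC thresholds
downstream depend on qualities, so a richer quality model would add nothing
testable.

The synthetic germline genes are mutually unrelated random sequences with
valid anchors (V length 321 nt so the full FR3 exists; J anchors at
position 28; no in-frame stop codons in V or in the J anchor frame, as in
real references). Real gene families are paralogous — members differ at a
minority of positions — so gene assignment on real data is harder than on
these fixtures. Passing recovery tests here demonstrates the pipeline's
bookkeeping is exact, not that assignment is robust to allele-level
ambiguity; 5'-RACE chemistry artifacts, PCR duplicate families and UMI
structure are likewise not modelled.

## Preprocessing

A pair is dropped when either mate's arithmetic mean phred score is below
15 or its `N` fraction exceeds 5%. Merging reverse-complements mate 2 and
scores every overlap offset exhaustively (reads are only ~100 nt, so no
seeding heuristic is needed); the offset with the most matched bases wins,
ties going to the longest overlap, subject to a minimum overlap of 10 nt
and at most a 10% overlap mismatch rate. At disagreeing positions the
higher-quality base is kept. `N` bases neither match nor mismatch.

## Annotation

Merged sequences are aligned against every functional V and J gene with a
striped local aligner (match +1, mismatch −1; a gap of length L costs
3 + L, i.e. affine with open 3 and extension 1, the same convention as
`Biostrings::pairwiseAlignment`, which serves as an independent oracle in
the test suite). The best score wins per segment; ties go to the
lexicographically smaller gene name and are flagged. Declared default
thresholds — V alignments of at least 40 columns at 80% identity, J at
least 15 columns at 80% — tolerate SHM while rejecting junk; they are
config-exposed because the upstream literature does not state any.

**Junction-side boundary rule.** A local alignment happily extends through
a junction when a few inserted bases coincidentally match the germline
continuation (the expected score gain makes this profitable roughly 11% of
the time at these scores). The annotator therefore trims the
junction-proximal end of each alignment: a terminal match run shorter than
`min_anchor_run` (default 4 nt) separated from the alignment body by a
mismatch is treated as coincidence and removed. This mirrors the
simulator's canonical maximal-exact-extension convention — computed by an
independent code path from the alignment — and is what makes ≥99% exact
junction recovery achievable on error-free data. With SHM, mutations near
the V 3' end still shift boundaries occasionally; junction statistics on
heavily mutated repertoires carry that irreducible ambiguity.

The CDR3 is cut between the anchor codons mapped through the alignments
(both codons must lie inside the kept alignment columns) and translated in
the cysteine frame. A read is productive when its CDR3 length is a
multiple of 3, the cysteine-anchored frame is stop-free through the end of
the J alignment, and both genes are functional. The D segment is the
longest exact match of at least 5 nt inside the inter-boundary gap
(shorter matches are indistinguishable from N nucleotides); remaining gap
bases split into V-D and D-J insertions. For loci without D the whole gap
is the V-J insertion. Mixed kappa/lambda pools are demultiplexed by the
higher best-V score, equal scores staying unresolved.

Error collapsing merges a clonotype into a CDR3 neighbour (same V and J,
Hamming distance ≤ 1) at least 100× its size, once, largest-first — a
declared stand-in for proprietary error-correction internals, exposed via
`collapse_max_dist` and `collapse_ratio`.

All repertoire statistics weight by read abundance (each sequence counts
toward the gene it aligned best with); a clonotype-weighted mode is
available behind the `weight` argument since the convention used for
published composition figures is usually unstated.

## Diversity

Chao1 is `S_obs + F1²/(2·F2)` with the bias-corrected fallback
`S_obs + F1(F1−1)/(2(F2+1))` when no doubletons exist (the printed form is
undefined there). Because published observed-richness figures are
ambiguous about whether species are amino-acid or nucleotide CDR3s, the
unit is a required argument throughout — there is no silent default.
Rarefaction draws reads (clonotypes expanded by abundance) without
replacement at fractions 0.1–1.0, ten replicates each; at fraction 1.0 the
draw is exhaustive, so replicate variance is exactly zero, a property the
tests assert.

## FR3 mutation analysis

For each functional V gene of a B-cell locus, the V alignments of its reads
accumulate coverage, mismatch counts and observed-base composition at every
FR3 position (alignment gaps are rare at these error rates; coverage uses
the aligned reference interval). Amino-acid level counts treat a codon with
any mismatching base as one event — which is why aa-level rates exceed
nt-level rates — over codons fully inside positions 196–309 (position 310
starts a codon that ends outside the FR3 and is ignored at the codon
level).

* **Hotspots**: mutation frequency strictly greater than 10% at coverage of
  at least 31 bases. The coverage cut excludes positions with ≤30 sequenced
  bases, where PCR and sequencing errors dominate; excluded positions are
  reported with a `low_coverage` status (the grey heatmap cells).
* **Polymorphic sites**: coverage ≥ 1000, one dominant non-reference base
  (≥80% of mismatches — the dominance threshold quantifies "one mutated
  type") at 40–60% of coverage, consistent with balanced transcription of
  two alleles. Sites passing everything but falling in a wider 30–70% band
  are reported as `candidate` rather than silently dropped or promoted:
  published worked examples include a site at 36% called polymorphic, so
  the stated band and its worked examples disagree, and the candidate tier
  records exactly those near-band sites.
* **Spectra**: the 12 nucleotide substitution types, and amino-acid types
  derived from the reference codon with the observed base substituted
  (multi-hit codons are not resolved at this level).

Reads are compared against their single best-matching gene only; there is
no multi-allele reassignment loop as in dedicated novel-allele discovery
tools, so a true novel allele inflates its gene's apparent mutation rate
exactly as the polymorphic-site detector expects.

## Worked example

```{r example, eval = FALSE}
db <- synthetic_germline_db("TRB", seed = 5)       # 59 V, 2 D, 13 J
cfg <- sim_config("TRB", n_clonotypes = 1000, seed = 11,
                  max_clone_size = 20)
paths <- simulate_to_files(cfg, db, "sim_out")
run <- pipeline_config("TRB", paths$read1, paths$read2,
                       outdir = "run_out", db = db, seed = 1)
res <- run_repertoire_pipeline(run)
res$summary
res$diversity
```

## Problem sizes and numerical choices

The validation suites run at the scales the methods need, chosen once: 5000
clonotypes for exact-recovery checks (binomially, a true 0.5% failure rate
would be seen), 10 000 draws for distribution goodness-of-fit at α = 0.01,
and 1000 random tables for the Chao1 lower-bound property. Frequency tables
are checked to sum to 1 within 1e-9; insertion-base probabilities must sum
to 1 within the same tolerance. Degenerate inputs (empty gene collections,
empty repertoires, zero coverage, no insertions) raise typed errors or
carry `undefined` attributes rather than returning silent zeros.

## Known limitations

* Synthetic germline genes are unrelated random sequences; assignment
  ambiguity between paralogous alleles is untested by construction.
* Junction decomposition reports the canonical (maximal germline) form;
  generative trims are not identifiable and no tool can recover them.
* SHM near alignment boundaries can shift junction boundaries; junction
  length distributions from heavily mutated repertoires are approximate.
* Coverage accumulation uses the aligned reference interval, ignoring rare
  alignment gaps; at the simulated error rates the effect is negligible.
* Single-repertoire profiling only: no cross-animal or cross-repertoire
  statistical comparison, and no clonal lineage reconstruction.
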