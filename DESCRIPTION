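Package: vdjprof
Title: Immune Repertoire Profiling and Simulation for V(D)J Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiling of T- and B-cell receptor repertoires from paired-end
    V(D)J amplicon sequencing. Provides germline V/(D)/J database handling
    with conserved-motif functionality filtering, a ground-truthed simulator
    of rearranged receptor reads (junction trimming and non-template
    insertions, somatic hypermutation with hotspots and heterozygous
    germline polymorphism, clonal abundance skew, paired-end sequencing
    errors), read quality control and pair merging, local-alignment V/J/D
    assignment with CDR3 extraction and productivity calling, repertoire
    summary statistics (gene usage, V-J pairing, CDR3 length and amino-acid
    composition, junction indel length distributions, inserted-nucleotide
    composition), Chao1 and rarefaction diversity estimation, and
    per-position framework-region-3 mutation profiling with hotspot and
    polymorphic-site inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
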