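Package: xenoscreen
Title: Gene Presence-Absence Screening, Synteny Confirmation and
    Response-Element Scanning in Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens genome assemblies for the presence or loss of a target
    gene by translated homology search summarized as per-residue coverage
    vectors, with competitive filtering against a decoy paralog; confirms
    putative losses by the scaffold placement of two conserved flanking
    genes; and characterizes promoter regions by scanning for degenerate
    xenobiotic response elements and for nuclear-receptor response elements
    (direct, inverted and everted half-site repeats) with a hidden Markov
    model. Includes a synthetic-data generator that plants diverged genes
    and motifs with machine-readable truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
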