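---
title: "Screening genome assemblies for gene loss: methods and design"
author: "xenoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genome assemblies for gene loss: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Deciding that a gene is *absent* from a genome assembly is harder than
deciding it is present. Low-coverage assemblies fragment genes across
scaffolds, paralogous families cross-match (nuclear receptors share a
highly conserved DNA-binding domain), and a negative search result may
reflect assembly gaps rather than biology. `xenoscreen` addresses this
with three mutually reinforcing lines of evidence: per-residue hit
coverage of the query protein, competitive filtering against a decoy
paralog, and synteny of a conserved flanking-gene pair. A fourth
component scans promoter windows of candidate compensating genes for
xenobiotic response elements (XREs) and nuclear-receptor response
elements.

# Translated search and its statistics

The engine aligns the protein query locally against all six frame
translations of every scaffold (Smith–Waterman–Gotoh, affine gaps,
implemented in C++). Scores convert to e-values by the Karlin–Altschul
formula $E = K m n e^{-\lambda S}$ with the published gapped BLOSUM62
11/1 constants ($\lambda = 0.267$, $K = 0.041$) as defaults; both are
configuration values of `scoringParams()`. The search space $n$ is the
total nucleotide length of the genome; BLAST's effective-length
corrections are deliberately not reproduced. E-values from the internal
engine and from parsed tabular files are never mixed in one comparison;
hit tables carry a provenance tag and `decoyFilter()` refuses
cross-provenance input.

Numerical choices:

* a gap of length $L$ costs `gapOpen` $+ L \cdot$ `gapExtend`
  (defaults 10/1, equivalent to BLAST's 11/1), chosen so that scores
  are exactly comparable with the exhaustive-DP oracle used in the
  tests;
* stop codons inside a reading frame score a flat $-4$ instead of
  truncating the frame — fragmented and erroneous assemblies would
  otherwise lose real hits; codons containing `N` translate to `X`,
  which scores 0 against everything;
* alignment tie-breaking is fixed (first-maximum end cell, traceback
  preferring diagonal over gap-in-subject over gap-in-query), so
  results are reproducible to the byte;
* multiple non-overlapping alignments per scaffold frame are recovered
  by iteratively masking the subject span of each accepted alignment
  (cap: 8 per frame), emulating the multiple HSPs a heuristic search
  reports.

The reporting threshold `maxEvalue = 1e-5` is a configuration value; it
was chosen conservatively such that the expected number of chance hits
per genome at desk scale is far below one.

# Presence calls

Coverage vectors count, for every query residue, how many retained hits
overlap it. Calls anchor on the ligand-binding domain: the DBD is so
conserved across receptor families that DBD-only coverage is evidence
of *some* family member, not of the target. The call rule is:

* **present** — fraction of LBD residues covered $\geq$
  `minLbdFraction` (default 0.3);
* **ambiguous** — LBD below threshold but DBD at or above it;
* **absent** — otherwise.

No published numeric threshold exists for heat-map-based judgments;
0.3 was fixed once, before any recovery measurement, on the rationale
that a true retained gene yields broad LBD coverage while cross-family
noise does not, and every call records its underlying fractions so the
threshold can be audited. The decoy rule interprets "out-competed" as
*subject-side* competition: the decoy hit must overlap the target hit
on the genome (default $\geq$ 50% of the shorter interval, same
strand) at a strictly lower e-value; ties keep the target. The
alternative — discarding any target hit whenever the decoy scores lower
anywhere in the genome — would erase true target loci in species
carrying both genes.

# Synteny classification

`assessSynteny()` is total over all structural configurations of
(flank5, target, flank3) and scaffold placement: both flanks on one
scaffold with the target strictly between them confirms presence; an
intact flank pair with an empty interval is the loss signature; flanks
on different scaffolds are unresolved (a fragmented assembly cannot
distinguish loss from a split block — the hake-like case where the
target travels with one flank only); a missing flank dominates
everything. "Between" is judged on coordinates irrespective of strand
and flank order because conserved blocks appear inverted in some
assemblies. A target overlapping a flank interval (shared-exon
mis-chaining) is classified present with a warning flag, conservative
toward presence. Fragmented gene models are consolidated by greedy
chaining of same-scaffold same-strand hits with a `maxGap` of 5 kb; a
user-supplied locus table can override the internal search for
annotated genomes.

# The response-element HMM

The scanner is a generative HMM over DNA: a background state (emissions
= background composition, default uniform) and three match-state
chains. Each chain emits a 6-bp half-site, a spacer of 0–8 background
bases (uniform over allowed lengths, implemented with per-state exit
hazards $1/(s_{max}-j+1)$), and a second half-site:

* **DR** (direct repeat): PWM, spacer, PWM;
* **IR** (inverted repeat): PWM, spacer, reverse-complemented PWM;
* **ER** (everted repeat): reverse-complemented PWM, spacer, PWM.

The background enters each chain with probability 0.01, so its
self-transition is $1 - 3 \times 0.01 = 0.97$. The half-site PWM is a
sharp consensus over `AGGTCA` — the canonical nuclear-receptor
half-site — with probability $1 - 3\epsilon$ on the consensus base and
$\epsilon = 0.01$ elsewhere; a matrix file can replace it. The spacer
range 0–8 covers the configurations relevant to receptor heterodimers
(DR3/DR4/DR5, IR6, ER6/ER8).

Viterbi decoding produces the site calls; each complete chain traversal
becomes one element with its configuration, spacer length and log-odds
(path log-probability minus the background-only log-probability of the
same span). Forward–backward posterior decoding is provided as the
independent cross-check: on planted consensus elements the posterior of
the correct chain at the element start is typically above 0.99. It can
dip a few percent when the flanking background happens to contain a
near-consensus half-site adjacent to the planting — the model then
spreads mass over alternative within-chain parses — which is real model
behavior, not a decoding error; the tests assert the 0.99 level on the
median across seeded plantings and 0.95 per instance. `N` bases emit
with probability 1 in every state (score-neutral) and spans containing
them are flagged. Both strands are decoded and duplicate same-span
same-configuration hits (IR and ER arrangements are their own reverse
complements) are merged.

The XRE scan is separate and exact: the degenerate consensus `KNGCGTGM`
(16 words) is matched in forward, reverse and complement orientations
by default — the literal reading of scanning "in forward, reverse and
complementary directions" — with reverse-complement available as a
fourth orientation; duplicate windows across orientations are merged by
default and the orientations recorded. Windows containing `N` never
match.

Promoter windows are fixed at 13,000 bases upstream of the gene start
(reverse complemented for minus-strand loci, clipped with a warning at
scaffold edges), matching standard practice for cytochrome P450
promoter scans.

# The synthetic-data generator

`simulatePanel()` emulates the screening scenario end to end: per
species, background scaffolds at GC 0.42 carry reverse-translated,
mutationally diverged copies of the flank, target and decoy proteins.
The decoy is planted in *every* species so the filter is always
exercised; `split_flanks` reproduces the fragmented-assembly
arrangement. The mutation model is uniform per-site substitution (no
transition/transversion bias) plus geometric indels — a deliberate
simplification that keeps the Binomial oracle for substitution counts
exact. Default study conditions for recovery experiments are 20
species, divergence 0.15, indel rate 0.001, 6-kb main scaffolds,
200-residue target with LBD 96–200 and a decoy at 20% amino-acid
distance; these sizes keep a full-pipeline run to minutes on one CPU
while leaving the per-species search statistically meaningful.

What passing recovery tests do **not** show about real data: real
divergence is codon-structured and branch-correlated, real assemblies
contain gaps, repeats and base-call errors beyond uniform noise, and
real paralogs differ domain-wise rather than uniformly. The generator
validates the pipeline's logic, not the biology of any particular
clade.

# Known limitations and scope decisions

* The internal engine is exact Smith–Waterman per frame; it does not
  clone heuristic BLAST statistics (no effective-length correction, no
  sum statistics) or spliced alignment. Real-data users can feed
  tabular BLAST output instead.
* Reciprocal-best-hit orthology uses all-vs-all local alignment scores;
  ties yield no pair and are flagged ambiguous rather than broken
  arbitrarily.
* Only the two-flank synteny pattern is modeled; no multi-gene blocks
  or whole-genome alignment.
* The NR half-site PWM is a stated default, not a fit to any published
  matrix; byte-level agreement with external scanners is not claimed.
* Cross-species positional alignment of response-element maps is out of
  scope; the package emits per-promoter tables only.
* The per-module shell commands that a larger deployment might expose
  are intentionally not shipped; the exported functions and
  `scripts/acceptance.R` are the interface.
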