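---
title: "Mining type III secretion systems: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining type III secretion systems: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t3ssmine)
```

This vignette explains what each stage of the pipeline computes, which
choices were genuinely open when the package was designed, and what the
synthetic-data tests do and do not demonstrate about real genomes.

## The screening model

The pipeline mirrors the standard two-step in-silico screen for type III
effectors in Gram-negative genomes, followed by component-cluster
characterization and distance phylogenetics.

### hrp-box motif scan

The hrp box is the promoter element recognized by the HrpL/RspL sigma
factor. Two renderings of the consensus circulate in the literature and
they disagree: the screening form `xGGAACx[N15–16]CCACxxAG` and the
shorter consensus `GGAACC-N15/16-CCACNNA`. The package ships both
(`hrp_box_pattern("screening")`, `hrp_box_pattern("consensus")`); the
screening form is the default because it is the one used for genome-wide
screens, and the choice is a config key rather than a silent constant.

A match is an assignment of a start position and one admissible spacer
length; all assignments are enumerated, overlapping matches are all
reported, and only bit-identical `(start, spacer)` duplicates are
collapsed. Scanning is restricted to the coding strand of the upstream
region — a sigma-factor element is directional — with an exploratory
`both_strands` switch.

Distance filtering keeps matches whose gap between the motif's last base
and the base preceding the start codon lies in [30, 300] bp. That gap
definition is the only self-consistent reading of "space between the motif
and the regulated gene" for a fixed-span motif, and it fixes the default
upstream window at 300 + 31 = 331 nt so a motif ending exactly at the
300-bp bound is still inside the window.

Matching rules chosen conservatively for ambiguous assemblies:

* a subject base that is not a concrete A/C/G/T (e.g. `N`) never matches
  any motif symbol — wildcard *and* spacer positions included;
* mismatches default to 0; a per-fixed-element mismatch budget
  (`max_mismatch`) exists because published motif figures show divergent
  positions, but no published mismatch budget exists, so none is guessed;
* upstream windows are *not* truncated at neighboring CDS by default
  (`truncate_at_cds = TRUE` enables it), reproducing a plain fixed-window
  screen.

One geometric note: with the hrp-box patterns themselves, a spacer of 15
and of 16 can never complete a match at the same anchor, because
`CCAC...` cannot overlap itself at a shift of one. Multi-spacer hits at
one anchor are still handled (and tested) for patterns where the 3'
element permits it.

### N-terminal effector filter

Four criteria, each evaluated independently over the first
`min(window, length)` residues with Met as position 1 and recorded as its
own pass/fail flag:

| criterion | default | unit |
|---|---|---|
| Ser fraction | ≥ 0.10 | fraction of window |
| polar fraction | ≥ 0.40 | fraction of window |
| acidic residues in positions 1–12 | ≤ 1 | count of D/E |
| aliphatic residue at position 3 or 4 | required | membership |

The literature behind these criteria never quantifies "abundance" nor
enumerates the residue sets, so the thresholds, the polar set
{S, T, N, Q, C, Y, G, H} and the aliphatic set {I, L, V, A, P} are
explicit, configurable arguments of `effector_thresholds()`. The window
of 50 aa follows the N-terminal secretion-signal literature's convention.
The acidic criterion is genuinely contradictory across sources (a cap of
one acidic residue versus an *abundance* of acidic residues);
`acidic_rule` selects among `at_most_one` (default), `none` and
`at_least_one`, and the selected rule is echoed into the run report's log
rather than resolved silently.

A gene is a putative effector only if it is hrp-box positive *and* passes
every enabled criterion, so the candidate set is a subset of the
hrp-box-positive set by construction — the funnel can only narrow.
Proteins shorter than 12 aa leave the first-12 criterion undefined and
are reported as `unevaluable` rather than dropped; `compute_features()`
itself refuses proteins shorter than 4 aa since position 3/4 is undefined.

### Component search and cluster assembly

Each predicted protein is aligned locally (Smith–Waterman, affine gaps)
against every entry of the reference panel and assigned its best-scoring
component; hits are kept when percent identity over aligned columns is
≥ 30 % and at least half the panel sequence is covered. The 30 % floor
mirrors the lower end of the similarity range observed between the
components of related beneficial-*Pseudomonas* systems; BLOSUM62 with gap
open 11 / extend 1 is the BLAST-conventional protein scoring. Percent
identity is computed over aligned columns, matching the convention behind
published similarity figures. In this package's gap convention a gap of
length L costs `open + (L − 1) × extend`.

Clusters are single-linkage chains of hits whose genomic gaps are at most
`max_gap` (default 5 kb — larger than typical intra-operon spacing, much
smaller than the distance to a scattered orphan effector gene). The span
is first-to-last member, the convention also used to report cluster sizes
in the source literature, where such clusters run 18–28 kb. Each cluster
reports the conserved-core components it lacks (*rscV, N, Q, R, S, T, U,
C, J; rspL, R*).

The shipped panel (`t3ss_panel_synthetic.faa`) carries the real component
names and roles but synthetic stand-in sequences, because no public
per-component sequence set is bundled with the package; the panel is a
versioned, swappable FASTA asset and every result table names the panel
entries it used.

### Distance phylogenetics

For nucleotide alignments the Kimura-80 distance
`d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` separates transitions (P) from
transversions (Q); for protein alignments the 20-state equal-rates
(Jukes–Cantor) correction `d = −(19/20) ln(1 − 20p/19)` is applied to the
mismatch fraction p. Columns with gaps or ambiguity codes are
pairwise-deleted by default — the choice that preserves the most
comparable sites on sparse alignments — with complete deletion available
as a switch, since tools that popularized these analyses do not document
which they use. When a log argument reaches zero the pair is saturated:
the distance is flagged `Inf` with a warning rather than silently
truncated, and tree building refuses saturated matrices.

Neighbor joining follows Saitou–Nei with the standard Q-criterion.
Two numerical policies make it reproducible:

* ties in Q are broken by the lexicographically smallest pair of cluster
  representatives (the smallest original taxon label in each cluster), so
  degenerate matrices give deterministic trees;
* negative branch-length estimates are clamped to zero
  (Kuhner–Felsenstein convention) with the clamped deficit recorded in
  `attr(tree, "clamped")`, not redistributed — the simplest rule that
  keeps path lengths interpretable.

Bootstrap resampling draws alignment columns with replacement, rebuilds
an NJ tree per replicate, and reports for each internal bipartition of
the original tree the percentage of replicates containing it. A replicate
whose distance matrix saturates is skipped and counted (`n_skipped`);
supports are percentages of the successful replicates. Supports are
rounded to integer percent for Newick node labels; raw counts and
fractions are kept in the JSON report. For an alignment of identical
sequences every replicate yields the same tie-broken topology, so all its
bipartitions are reported at 100 — the documented convention for that
degenerate case. Alignment construction is out of scope: the module
consumes any aligner's multi-FASTA output.

## The synthetic-genome generator

`generate_genome()` builds a single contig (default 2 Mb, 60 % GC —
*Pseudomonas*-like) containing, as independent gene cassettes on both
strands:

* 5 conformant hrp boxes upstream of plain genes;
* 10 near-miss decoys cycling through the four single-defect classes:
  wrong spacer (14 or 17 nt), distance below 30 bp, distance above 300 bp,
  mutated GGAAC core;
* 10 true-effector ORFs and 10 decoy ORFs, all with conformant boxes, the
  decoys each violating exactly one N-terminal criterion; true-effector
  N-termini exceed every fractional threshold with a margin of at least
  0.05, so small threshold changes are meaningful tests;
* a contiguous cluster of all 15 panel components, each protein mutated
  at 20 % of residues (within the 30–97 % similarity band seen between
  real related systems), with 400-bp intergaps;
* 10 background genes with motif-free promoters.

Every scanned stretch of background (promoter windows, cluster intergaps)
is rejection-sampled against the motif, and each planted window is
re-verified to contain exactly the intended match set, so the manifest is
the *complete* truth: precision and recall of the screens can be scored
exactly and equal 1.0 at default thresholds on noiseless configurations.
Generation is bit-for-bit reproducible from `(config, seed)`.

What the generator does **not** emulate: codon usage and amino-acid
composition biases, operon structure, rearrangements, horizontal
transfer, sequencing artifacts, or annotation errors. Passing the
planted-truth tests therefore demonstrates the correctness of the
scanning, filtering, aligning and chaining machinery — not the biological
error rate of the criteria on real genomes, which depends on thresholds
the source literature leaves open (and on the real component panel). The
headline candidate counts published for real strains (62/73 hrp-box genes
narrowing to 15/11 effectors) require those strains' assemblies and are
deliberately not asserted anywhere in this package.

`generate_alignment()` evolves i.i.d. sites along a given tree with
closed-form K80 (transition/transversion ratio κ, default 2) or 20-state
equal-rates transition probabilities, in expected substitutions per site;
it underpins the simulation-consistency tests (NJ topology recovery at
10 kb sites; distance estimates within three standard errors of the
generating branch lengths).

## Problem sizes used in the checks

The packaged verification runs use: 1,000 random regions (≤ 200 nt)
against a brute-force enumeration oracle for the scanner; the full 2-Mb
default genome for planted-truth recovery; 100 random additive trees
(≤ 12 taxa, branch-length recovery to 1e−9) for NJ; 500 random pairs
(≤ 30 aa) against an exhaustive Gotoh dynamic program plus the classic
HEAGAWGHEE/PAWHEAE = 28 check for the aligner; and 100 fixed-seed
replicates for bootstrap determinism. These sizes make every oracle
comparison exhaustive at small scale while each check completes in
seconds.

## Known limitations

* GenBank support covers simple and `complement()` CDS locations with
  `locus_tag`/`translation` qualifiers; fuzzy locations and joins are
  rejected explicitly. Gene calling on unannotated contigs is out of
  scope — annotate first (e.g. with prodigal).
* No PWM or mismatch-probability model for the motif: the screen is the
  deterministic IUPAC pattern the published screens used.
* The effector filter is the classical compositional rule set, not a
  machine-learned predictor; its per-criterion flags are always emitted
  so alternative thresholds can be replayed from the feature table.
* Phylogenetics is distance-based NJ only (the method the cluster
  analyses used); likelihood or Bayesian inference is out of scope.
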