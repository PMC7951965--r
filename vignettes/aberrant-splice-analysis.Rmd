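---
title: "Models and methods behind crypticsplice"
author: "crypticsplice authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crypticsplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crypticsplice)
```

This vignette is the package's own account of its models: what is
computed, under which assumptions, which parameters matter, and where the
design was genuinely open.

## Coordinates and records

All internal coordinates are 0-based half-open on the **gene's sense
strand**; TSV/JSON record files and reports use 1-based inclusive
positions, the convention of curated aberrant-splice-site databases and
HGVS-style reports. Minus-strand genes are reverse-complemented once at
read time (`gene_sense_sequence()`), so every downstream module sees one
orientation. A splice-site *boundary* is the position of the first
intronic base (donors) or the first exonic base (acceptors).

Reference validation checks the recorded reference allele against the
genome and the aberrant boundary's dinucleotide on the **post-mutation**
sequence, because the mutation is often precisely what creates the GT.
GC donors are accepted as legal: GC 5'ss drive ~1% of human introns and
include the decoy site at the heart of the composite-exon analysis; any
dinucleotide other than GT/GC (donor) or AG (acceptor) fails.

## Intrinsic strength models

Strength is a log₂-odds in bits, `log2(P_signal/P_decoy)`, over the donor
9-mer (exon −3..−1, intron +1..+6) or acceptor 23-mer (intron −20..−1,
exon +1..+3). Footprints follow the scoring models' windows; the source
material never states them explicitly, so they are fixed here as package
constants.

* **First-order Markov model** — positional base distribution at
  position 1 plus per-position conditional tables, smoothed with a
  pseudocount of 0.5 per cell (the field's usual half-count; the choice
  only matters for rare contexts, and unsmoothed models raise an explicit
  error when a decoy probability of 0 would make the odds infinite).
* **Maximum-entropy model** — the distribution of maximal entropy over
  the enumerable 4^k window domain (k ≤ 9) matching positional and
  position-pair marginals, fitted by generalized iterative scaling. Each
  constraint group activates exactly one feature per sequence, so the GIS
  exponent is 1/(number of groups) and convergence is monitored as the
  maximum marginal deviation (`tol` default 1e-4, `max_iter` 5000;
  non-convergence warns and flags rather than fails).
* **Acceptor decomposition** — 23-mers are scored as products of ≤9-mer
  fragment probabilities divided by overlap marginals, the chain-rule
  factorization; overlap marginals are prefix marginals under the
  downstream fragment's model.

The package deliberately does **not** ship the published maximum-entropy
parameterization; `read_score_table()` imports any externally published
k-mer score table so that parameterization can be dropped in. Absolute
score reproduction (e.g. specific median excesses on curated data)
depends on that import; everything computed here from synthetic data uses
the package's own trained models or deterministic tables.

## Cryptic vs de novo, multiplicity, size constraints

A record is *cryptic* when its mutation lies inside the authentic
consensus footprint — donors: exon −3..intron +6; acceptors: intron
−3..exon +1 — and *de novo* otherwise. The acceptor footprint is the
short YAG/G only: substitutions in the polypyrimidine tract or branch
point upstream create *de novo* sites under this rule, which matches how
deep-3'ss-region events are described in the curation literature.

Multiplicity (several aberrant sites per mutation) is reported with both
denominators — events and records — because published percentages use the
record denominator; `fraction_multiple()` returns both.

For strong-cryptic/weak-authentic pairs (strict inequality; ties are not
"stronger") the *relevant flank* is fixed per quadrant: intronic 3'ss →
downstream exon, intronic 5'ss → upstream exon, exonic 3'ss → upstream
intron, exonic 5'ss → downstream intron, with the residual intron (the
piece still to be spliced) reported for intronic sites. Thresholds are
configuration, not constants: small exon ≤ 100 nt, small intron ≤ 200 nt
(both inclusive — boundary cases are covered by tests), minimum
spliceable intron 70 nt. The median is the midpoint convention (mean of
the two central order statistics). The Fisher exact test is implemented
by hypergeometric enumeration of all tables with the observed margins
(two-sided: summing probabilities ≤ the observed table's, with a 1e-7
relative slack for ties); the t test is the pooled-variance Student form.

## Transposed-element clusters

The RepeatMasker `.out` reader normalizes 'C'-orientation consensus
coordinates so `cons_begin ≤ cons_end` and tolerates the ID/asterisk
columns by count sniffing. Nested insertions are called from geometry
only, never from subfamily age tables:

* **split signature** — two same-family, same-orientation fragments
  adjacent in query order whose consensus resumes within `gap_tol`
  (default 30 nt, the scale of target-site duplications plus edge
  truncation; negative gaps — short duplicated consensus — count by
  absolute value), bracketing at least one different-family hit;
* **containment** — a different-family hit entirely inside another hit's
  query span.

The interrupted element is the older one by construction. Homologous
decoy-5'ss discovery aligns candidates globally (match +1, mismatch −1,
gap open −5, extend −1 — ordinary nucleotide-alignment defaults, stated
because no aligner or parameters are prescribed anywhere) and requires
the candidate to align a base onto the anchor's 5'ss column with ≥80%
identity over the 9-mer footprint; both the column identity and the
9-mer identity are reported, since "same decoy site" can reasonably mean
either.

## Probing normalization and differential reactivity

The processing order is fixed as: normalize each lane to its full-length
band → subtract the no-reagent control → optional 2/8 rescale → clip at
−2. The steps are standard but their order is not prescribed; this order
makes the chain exactly scale-invariant (multiplying a lane's bands and
full-length signal by any c > 0 changes nothing), which is the property a
gel-loading normalization should have. The 2/8 rule excludes the top
`ceil(0.02 n)` values and divides by the mean of the next `ceil(0.08 n)`
— ceilings so short profiles behave deterministically; the plain
percentile variant is implemented (not the boxplot-outlier variant).
Cleavage fold-changes flag >3-fold differences with an ε = 1e-6
pseudo-floor in both terms so zero-signal positions neither divide by
zero nor flag spuriously.

The differential test is a per-position one-way ANOVA. With two groups
Tukey's HSD adjustment is the identity, so the F-test p value is reported
directly (this also avoids the studentized-range quantile approximation,
which is only ~1e-3 accurate at tiny degrees of freedom); with more
groups the Tukey-adjusted mutant-vs-WT contrast is used. Zero
within-group variance yields p ∈ {0, 1} with a `degenerate` flag.

## The folding engine

The energy model is a deliberately simplified nearest-neighbour
parameterization, versioned inside `energy_model()`: stack energies
−(s₁+s₂)/2 kcal/mol with pair strengths GC/CG = 3, AU/UA = 2, GU/UG = 1;
hairpin loops 3.0 + 1.75·RT·ln(L/3); bulge/internal loops
2.0 + 1.75·RT·ln(u), capped at 30 unpaired nt; multiloops affine
a + b·branches + c·unpaired with (3.4, 0.4, 0.1); minimum hairpin loop
3 nt; no dangles, coaxial stacking or terminal mismatches. Full Turner
parameters are out of scope and the model is pluggable — consequences:
absolute energies are not comparable to laboratory tools, MFE structures
of long sequences will differ from Turner-model predictions, and no
attempt is made to reproduce any published structure figure. What *is*
guaranteed: the dynamic programming recursions (Zuker-style MFE; McCaskill
inside/outside for the partition function and pair probabilities) compute
exactly the ensemble defined by the explicit loop decomposition
`structure_energy()`, verified against exhaustive enumeration on ~200
seeded sequences of 8–16 nt at 1e-9 relative tolerance.

PU values are partition-function ratios, `Z(window forced unpaired)/Z` —
equivalent in exact arithmetic to the free-energy-difference formulation.
Windows are arbitrary; per-nucleotide profiles are width-1 windows.
Reactivity constraints are hard (positions above 0.7 on the
2/8-normalized scale are forced unpaired); pseudo-energy slope/intercept
constraints are an extension point, not implemented. MFE traceback
breaks ties (within 1e-9 kcal/mol) toward fewer pairs, examining options
in a fixed enumeration order, so outputs are reproducible byte for byte.
The practical length limit is a few hundred nt: the partition function is
computed in linear scale (overflow warned), the outside pass is O(n⁴),
and the probes analysed here are ≤ ~180 nt.

## ESRseq hexamers

Windows containing a position number six (fewer near sequence ends, by
the closed form min(pos,5)+min(len−1−pos,5)−4); windows fully containing
a trinucleotide number four. Assignment is the score's sign; a score of
exactly 0 and a hexamer absent from the table are both Neutral, which
matches every printed row of the bundled fixture. The bundled table
(`inst/extdata/esr_hexamers_probe_fixture.tsv`) holds only the 16
published hexamer scores needed around the probed adenines and the
apical triloop; the full genome-wide table is user-supplied in the same
two-column TSV format. Whether published "Neutral" means exactly 0 or a
dead zone around 0 is unresolved in the source material; the sign rule
reproduces all printed rows.

## What the synthetic generators emulate — and what they do not

All generators are pure functions of (spec, seed) and emit a truth table;
no test reads truth from observables.

* `gen_gene()` — log-normal exon sizes centred on the 139-nt human
  internal-exon median (sdlog 0.45) and log-normal introns (median
  800 nt, sdlog 0.6, floor 70 nt); GT..AG introns with consensus-biased
  donor 9-mers and polypyrimidine acceptor 23-mers (per-position match
  probability 0.85). Not emulated: codon structure, GC isochores,
  branch-point placement, alternative transcripts.
* `gen_aberrant_event()` — cryptic events weaken the authentic donor
  inside its footprint next to a pre-planted intronic decoy; de novo
  events plant a donor whose GT is completed by the emitted mutation
  120 nt into the intron. The aberrant 9-mer is chosen from signal-model
  draws to realize a target score delta within ±0.3 bits (resampled, then
  an error — some contexts cannot realize extreme deltas).
* `gen_nested_te()` — random 150–300 nt consensus families (no real
  repeat sequences are bundled, deliberately); insertions applied oldest
  first, nesting with probability `nest_prob`, point-mutation divergence,
  and a hit table written the way an annotator reports a split copy.
  Not emulated: 5' truncation of new insertions, target-site
  duplications, deletions/insertions within copies.
* `gen_reactivity()` — log-normal band intensities (mean 1 at unit
  signal; sigma 0.25) with means 0.1/1.0 for paired/unpaired positions,
  a shared RT-stop background in both lanes (so subtraction is exact in
  the noiseless limit), DMS signal restricted to A/C, and a full-length
  band attenuated by `fl_decay`. Three replicates per condition by
  default: with two (a common published design) the per-position ANOVA
  has two residual degrees of freedom and, at this noise level, roughly
  three-quarters power for a paired→unpaired transition, below the ≥95%
  recovery bar the package's calibration tests demand; three replicates
  meet it with margin. Two-replicate analyses remain fully supported.
  Not emulated: RT drop-off gradients, primer artifacts, band
  compression.
* `gen_pair_table()` — fully deterministic: quadrant sizes 50/11/20/11
  (intronic 5'ss / exonic 5'ss / intronic 3'ss / exonic 3'ss, totalling
  92) with small-flank counts by round-half-up, quadrant flank medians
  pinned (125 and 127 nt for the intron-located quadrants), and score
  excesses placed symmetrically around the per-kind medians (1.17 bits
  donors, 1.51 bits acceptors). The two exon-located quadrant medians
  and the symmetric ±0.02-bit spacing are arbitrary-but-fixed; the seed
  only shuffles row order. `gen_inclusion_table()` plants an exact
  sample Pearson correlation by residualization (n = 21, r = −0.09 at
  the defaults).
* `gen_record_set()` — plants exact multi-site record counts (pairs,
  plus one triple when the count is odd) and an exact stronger-than-
  authentic count (round-half-up of the requested fraction).

Because these are constructions, recovery tests demonstrate that the
*counting, filtering and measuring operations* are correct — not that
real curated data have these values. Quadrant sizes and the exon-located
fractions are package defaults chosen once to match the reported
marginal fractions; the underlying per-quadrant totals of the curated
data are not public in machine-readable form.

## Problem sizes and runtime choices

The test suite folds sequences of 8–54 nt (enumeration oracle to 16 nt,
200 cases), runs 100-replicate calibration loops for the differential
test on a 54-nt probe, and 50 seeded nested-insertion genomes of ~1.5 kb;
the whole suite and the acceptance script each complete in well under a
minute on a single core. These sizes were picked so the exhaustive
oracles stay exact and fast; nothing in the implementation is specific
to them.

## Known limitations

* The folding model is intentionally minimal; use it for ensemble
  *comparisons* (WT vs mutant, constrained vs not), not absolute ΔG.
* The cryptic/de-novo rule is binary and footprint-based; borderline
  acceptor events near the PPT are called de novo by design.
* `find_homologous_5ss()` is a pairwise, anchor-based screen, not a
  multiple alignment; column identity can shift when candidates carry
  large indels near the anchor column.
* The RepeatMasker reader parses the classic column layout (plus ID/`*`);
  exotic dialect variants are out of scope.
* No live database retrieval, genome downloads, or transcript-model
  resolution: a gene model must be supplied explicitly.
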