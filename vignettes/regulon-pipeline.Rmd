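---
title: "Methods: from ChIP coverage to a characterised regulon"
author: "ChIPregulon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ChIP coverage to a characterised regulon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChIPregulon)
```

ChIPregulon reimplements, as tested and reusable functions, the
computational chain used to characterise a bacterial
transcription-factor regulon: a windowed-enrichment ChIP-seq peak caller
with a negative-binomial null, discovery and scanning of
pseudo-palindromic (inverted-repeat) binding sites, a conservation scan
with a reciprocal best-hit orthologue screen, steady-state SPR affinity
analysis, and qPCR quantification. The demonstration system is the RccR
regulon of *Pseudomonas fluorescens*: a RpiR-family repressor of
glyoxylate-shunt and gluconeogenesis genes whose paralog HexR shares its
effector ligand (KDPG) but controls a different gene set. Everything
here runs on synthetic data with known ground truth; this vignette
explains each model, the tunable parameters, and the design choices
taken where the procedure left room.

## Coordinate contract

All internal coordinates are 0-based half-open on the forward strand.
GFF3 (1-based inclusive) is converted at the I/O boundary; BED and
bedGraph are natively 0-based and pass through unchanged. One convention
everywhere removes the usual off-by-one drift between formats.

## The synthetic study system

`chip_sim_config()` fixes the simulated experiment. Defaults:

* **Genome**: 1 Mb circular replicon, i.i.d. uniform ACGT, 40 genes of
  0.9–1.5 kb on alternating strands with intergenic spacers of at least
  400 bp. This is a desk-scale stand-in for a ~6.7 Mb chromosome with
  several thousand genes: large enough that the 4001-nt background
  window and multiple-testing burden behave realistically, small enough
  that a full simulation-plus-calling cycle takes seconds.
* **Binding sites**: `plant_sites()` writes inverted-repeat sites —
  `TGTAGT` + unconstrained linker + `ACTACA` — into the intergenic
  region upstream of named target genes. Linker lengths of 3, 16 and
  17 nt give the three site classes of 15, 28 and 29 bp. The default
  plan (`default_site_plan()`) mirrors the demonstration regulon: a
  28 bp site upstream of each of eight targets, except `pckA` (the
  29 bp variant) and `aceE` (two 15 bp sites 68 bp apart, the pair that
  produces that promoter's characteristic double peak).
* **Coverage**: the control track is per-base negative-binomial noise,
  NB(mean 5, size 3) — overdispersed, as sequencing coverage is. The
  ChIP track draws from the same law with its mean raised around each
  site by a triangular kernel of half-width `fragment_length` (500 bp,
  the sonication target size): the expected pile-up of uniformly
  positioned 500 bp fragments overlapping a point source, with the
  summit scaled so that expected summit coverage equals
  `enrichment_fold × background_mean` (default 10 × 5). The generator
  works at the coverage level; read-level simulation (FASTQ, mapping
  artefacts, duplicate reads) is out of scope, so depth is
  parameterised directly by `background_mean`.

The generators are bit-reproducible given `(config, seed)`, and every
planted site is returned as a truth record that downstream stages can
be scored against. What passing tests on this generator do **not**
show: robustness to mappability gaps, GC bias, copy-number variation,
or non-uniform fragmentation — real-data effects the simulation does
not model.

## The peak caller

At every 25th position (step `s`), the **enrichment ratio** is the mean
coverage in a 51-nt window divided by the mean coverage in a 4001-nt
window centred on it. Using window *means* (rather than raw sums) makes
the ratio exactly 1 on uniform coverage, which is what a retention
threshold of 1.5 presupposes; the raw sum-over-sum variant (bounded
above by 1 and thus unusable with that threshold) is kept behind
`ratio_mode = "sum"` for audit. Circular replicons wrap both windows;
linear replicons truncate at the ends and use the truncated width in
the mean. Positions whose background mean is zero have no defined
ratio and are skipped.

Positions with ratio below `ratio_threshold` (1.5) are removed. The
survivors are tested against a negative-binomial null and the p-values
are Benjamini–Hochberg adjusted over exactly that retained set,
preserving the filter-then-test order of operations.

**What the null is fitted to.** The NB is discrete, so something must
be rounded; and the null must describe unenriched signal for tail
p-values at enriched positions to mean anything. Two variants are
implemented:

* `null_on = "coverage"` (default): the NB is fitted (maximum
  likelihood via `MASS::fitdistr`, method-of-moments start) to the
  track's per-base coverage — integers already — deterministically
  subsampled to at most 2×10⁵ values, and the tested statistic is the
  rounded 51-nt window mean at each retained position. On a track with
  background mean 5 this null is dominated by unenriched bases (planted
  sites occupy <1% of the genome), so summit windows score p-values
  orders of magnitude below the threshold.
* `null_on = "ratio"`: the NB is fitted to the retained enrichment
  ratios themselves, rounded to integers (or scaled by `round_scale`
  first), and the rounded ratio is tested against it.

The coverage null is the default because the ratio null is circular
whenever the retention filter works well: at realistic background depth
the ratio's sampling noise is far too small for background positions to
reach 1.5, so the retained set *is* the enriched positions, the null is
fitted to the very signal being tested, and nothing is ever
significant. (At those depths the retained ratios are also
underdispersed — variance below mean — where no NB maximum-likelihood
fit exists; `fit_nb_null()` then falls back to a moments estimate with
the `size` parameter capped at 10⁶, i.e. effectively Poisson, and
warns.) The ratio option is retained for low-coverage regimes where
noise floods the retained set and the retained-ratio distribution is a
meaningful background.

**Peak construction** is deliberately simple: significant positions
(adjusted p ≤ 0.05 *and* ratio ≥ 1.5) within one step of each other are
merged; runs shorter than `min_consecutive = 2` are discarded
(suppressing single-window noise); a peak spans the outermost
short-window edges of its run, and the summit is the position of
maximum ratio. **Control screening** keeps a peak only if its maximum
ratio is at least `control_fold = 2` times the control-track ratio at
the evaluated control position nearest the summit (a peak with no
control position within one step is kept, flagged with fold `NA`).
**Annotation** flags a peak intergenic when its summit overlaps no gene
body, records the flanking genes, and lists candidate targets: genes
whose own-strand start lies within 500 bp downstream of the summit, so
a divergent promoter region yields two candidates and a convergent gene
pair none. The merge gap, the 2-fold control screen, the
two-window minimum and the 500 bp candidate window are this package's
choices — the original analysis reported only final sites — and all are
configurable.

With the default simulation (fold 10, mean 5) the caller recovers all
eight planted regions with zero false positives across seeds; the
tests assert this end to end.

## Binding-site model and scanning

The site model (`palindrome_spec()`) is an inverted-repeat pair —
`TGTAGT`/`ACTACA`, the right arm defaulting to the reverse complement
of the left — separated by a linker whose length defines the site
class. `find_pseudopalindromes()` counts mismatches **in the arms
only** (pooled across both arms), because the observed sites vary
freely in the linker; `arm_only = FALSE` switches to whole-site IUPAC
matching with an `N` linker, reproducing a plain consensus string
search. `scan_iupac()` is the general consensus scanner: a window
matches when the number of positions failing IUPAC containment is
within the mismatch budget. Conventions shared by both scanners:

* `N` in the *subject* always counts as a mismatch (conservative
  treatment of undetermined genome positions).
* Both strands are scanned; hits are reported in forward-strand
  coordinates with the matched sequence 5'→3' on the hit strand. A hit
  whose reverse complement maps onto itself — always, when the arms are
  an exact reverse-complement pair — is reported once, on `+`.
* Overlapping and nested hits are all reported; `dedupe_hits()` (fewest
  mismatches, then leftmost, then `+`) is an optional post-filter.

`build_consensus()` turns aligned site sequences into a
position-frequency matrix and the *minimal* IUPAC string covering all
observed bases per position — by design a hard-containment consensus,
not a probabilistic motif model (no PWM scoring, no information
content). `extract_upstream()` returns strand-aware upstream windows,
defaulting to 300 bp: bacterial operator sites sit within core promoter
regions, typically well inside 300 bp of the start codon, and the
sites planted by the simulator 60–250 bp upstream are comfortably
covered; the length is configurable.

## Conservation scan and orthologue screen

`regulon_scan()` applies upstream extraction plus scanning across a
panel of genomes with annotations, returning a per-genome, per-gene hit
table with a per-genome summary — the single-genome demonstration and a
genus-wide panel differ only in input size. `reciprocal_best_hits()`
separates the regulator from its paralog without alignment E-value
statistics: "best" is the raw Smith–Waterman local-alignment score
(BLOSUM62, affine gaps 11/1, via `Biostrings::pairwiseAlignment`), a
pair is kept only if each member is the other's best hit, and the
aligned-query coverage fraction (aligned query residues ÷ query length)
must exceed `min_hcov = 0.7`. Score ties break lexicographically on
subject id, with a message. This is deterministic and dependency-free,
and preserves the reciprocity logic that distinguishes two
high-identity paralogs.

## SPR analytics

For a reusable DNA-capture chip, the theoretical maximum response is
`Rmax = stoichiometry × 2 × monomer mass ÷ DNA mass × captured-DNA
response`, assuming one analyte **dimer** per captured duplex (the
factor 2 is dropped when the analyte mass is given as total mass per
bound unit). `percent_rmax()` expresses observed responses on that
scale. Affinity is fitted from steady-state responses with the one-site
Langmuir isotherm `R(C) = Rmax·C/(Kd + C)` by constrained least squares
(`minpack.lm::nlsLM`, chosen over `stats::nls` because it is stable on
the zero-residual noiseless case used to validate exact inversion);
full kinetic sensorgram fitting (kon/koff) is out of scope.
`classify_effector()` calls an effector's influence from a binding
readout across an increasing effector ladder: *increases*/*decreases*
require every successive step in the same direction **and** a total
change beyond `tolerance` (10%) of the zero-effector baseline;
everything else is *none*. The tolerance guards against calling an
effect from instrument-level wobble.

## qPCR quantification

`relative_expression_ddct()` implements the 2^−ΔΔCt readout: replicate
Ct values aggregated by mean (median available), ΔCt against the
reference gene (`rpoD` by default) within each sample, ΔΔCt against the
calibrator sample, fold = base^(−ΔΔCt) with base 2 at the default 100%
amplification efficiency (the efficiency parameter rescales folds
monotonically and is exposed, not estimated). Per-replicate ΔCt values
are retained — paired by replicate index when target and reference well
counts match, otherwise against the aggregated reference — and feed
`ddct_t_test()`, a plain Student's t-test on ΔCt.
`absolute_quantify()` fits the standard curve `Ct = a·log10(copies) +
b` by ordinary least squares, requires the physically necessary
negative slope, inverts it at the sample Ct, and flags extrapolation
beyond the standards' Ct range.

At the simulator's well-noise default of 0.1 cycles and 3 wells, the
ΔΔCt standard error is ~0.12 cycles (≈8% on the fold scale); tests
therefore assert typical (median) recovery error, exact recovery being
reserved for the noiseless case.

## Numerical choices and degenerate inputs

* Ratios/statistics are rounded with R's `round()` (half-to-even); the
  `round_scale` option preserves one decimal before rounding if wanted.
* `fit_nb_null()` refuses fewer than 10 observations, falls back to
  moments on ML failure, and caps `size` at 10⁶ (the Poisson limit)
  with a warning on under/equi-dispersed input.
* An all-zero coverage track yields an empty enrichment table (every
  background mean is zero) rather than infinite ratios.
* `bh_adjust()` validates p-value ranges and delegates to
  `stats::p.adjust(method = "BH")`; peaks inherit `min_padj ≥ max
  pvalue` monotonicity from it.
* Gene-free genomes, empty site plans, empty peak sets and empty
  proteomes all return typed empty results or informative errors — the
  tests exercise each.

## Problem sizes

The shipped analyses and tests use 1 Mb genomes (the full simulation),
0.2–0.3 Mb genomes for property-style checks, 20 replicate simulations
for the recovery analysis, 500 random cases for scanner/oracle
equivalence, 1000 vectors for BH/oracle equivalence, 50 seeds for Kd
recovery and 10 for ΔΔCt recovery — sizes at which every stochastic
assertion has comfortable margin while a full run stays in the minutes
range on one core.

## Known limitations

* The caller assumes one coverage track per condition; replicate
  irreproducibility analysis and cross-library normalisation are out of
  scope.
* The NB null is genome-global (one fit per track); locally varying
  background (e.g. copy-number structure) is handled only through the
  4001-nt ratio normalisation, not the null.
* The consensus model is containment-based; a single aberrant site
  degenerates the affected positions towards `N`.
* The orthologue screen scores with one substitution matrix and fixed
  gap costs; it is a screen, not a phylogenetic method.
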