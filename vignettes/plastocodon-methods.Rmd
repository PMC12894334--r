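---
title: "Methods: comparative plastome structure, codon usage and selection"
author: "plastocodon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome structure, codon usage and selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastocodon)
```

# Scope

`plastocodon` implements the standard comparative-analysis battery for
annotated chloroplast genomes: quadripartite structure detection, perfect
microsatellite (SSR) scanning, codon-usage bias statistics, the three
classical evolutionary-force diagnostics (ENC--GC3s, neutrality plot, PR2
plot, plus correspondence analysis), and NG86 Ka/Ks with a three-way
selection classification. Every stage can be exercised on synthetic
plastomes with exact ground truth, so the whole pipeline is testable
without any external sequence database.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the design decisions taken where the
underlying methods literature leaves options open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

# Quadripartite structure detection

Land-plant plastomes are circular molecules organised as a large
single-copy region (LSC), a small single-copy region (SSC) and two
identical inverted repeats (IRa/IRb). `detect_quadripartite()` finds the
longest pair of disjoint, *exactly* reverse-complementary segments of
length at least `min_ir` (default 10,000 bp, safely below any plastid IR
and far above random matches) by k-mer anchoring (`seed_k = 25`) between
the doubled sequence and its reverse complement, followed by vectorised
mismatch-free extension along each anchored diagonal. Doubling the
sequence makes detection invariant under rotation of the circular
coordinate origin, including cuts that fall inside an IR.

Decisions:

* Exact identity only. Real IR pairs are typically identical; tolerating
  isolated mismatches requires a scoring model and is left as future work.
  A genome without an exact repeat of `min_ir` bp raises a structured
  `plastocodon_no_ir` condition rather than guessing.
* LSC and SSC are assigned by size (LSC is by definition the larger
  single-copy region); IRb is the repeat immediately following the LSC in
  input orientation. Plastomes occur in two SSC-orientation isomers; the
  structure is reported in input orientation with no canonical flipping.
* Coordinates are 1-based inclusive everywhere; an interval whose start
  exceeds its end wraps the origin.

The region lengths always satisfy `lsc + ssc + 2*ir = genome length`; this
is asserted, not assumed.

# Region classification

`classify_regions()` labels every base `CDS`, `intron` or `IGS` with
precedence CDS > intron > IGS: a base is CDS if covered by any CDS part;
otherwise intron if it lies between consecutive parts of a multi-part gene
(including tRNA/rRNA introns); otherwise IGS. tRNA/rRNA exons therefore
count as IGS in the three-class scheme used for SSR densities. The labels
partition the genome exactly — `|CDS| + |intron| + |IGS| = genome length`
is a tested invariant. SSR loci are assigned to the region containing
their midpoint (`floor((start+end)/2)`), a documented tie-break so that
densities are reproducible.

# SSR scanning

`scan_ssrs()` reports all maximal perfect tandem repeats with primitive
motifs of unit length 1--6 meeting per-unit-length minimum copy numbers,
default `{1:10, 2:5, 3:4, 4:3, 5:3, 6:3}` (the thresholds commonly used
for plastome surveys with IMEx-style scanners). Details that fix the
output uniquely:

* *Maximality*: for unit length `k` the boolean match vector
  `s[i] == s[i+k]` is run-length encoded; a maximal run of length `L`
  starting at `i` is a tandem span of `L + k` bases. Partial trailing
  units extend the span but never the copy count (`copies =
  floor((L+k)/k)`); the reported locus ends at its last full unit.
* *Primitivity*: motifs that are powers of a shorter string (e.g. `ATAT`)
  are suppressed; the locus is reported at its primitive period. Loci
  sharing an identical span keep the shortest unit.
* `N` never matches anything and so breaks any repeat. The scan is linear
  and does not wrap the circular origin, matching common scanners.
* Motifs are reported as scanned, canonicalized only by lexicographically
  minimal rotation; merging with reverse complements is optional
  (`strand_merge`) and off by default, since published motif tables list
  plain motifs.

Compound/interrupted repeats are out of scope: only perfect repeats are
modelled. The scanner is verified against an exhaustive quadratic oracle
on random fixtures in the test suite.

# Codon usage statistics

All codon statistics use translation table 11 (plant plastid). Codons
containing `N` are excluded from all counts; a terminal stop is recorded
but excluded from `n_codons`. Synonymous families follow the CodonW
convention: 2-fold x9, 3-fold x1 (Ile), 4-fold x5 and 6-fold x3 (Leu,
Ser, Arg) kept whole rather than split 2+4; ATG and TGG have no synonyms
and are excluded from the 59-codon analysis vector (their RSCU is 1 by
definition).

**RSCU.** For codon *c* in a *k*-fold family with observed family total
*T*, `RSCU(c) = count(c) / (T/k)`. Families with `T = 0` are missing
(`NA`), never 0 — a zero would feed spurious structure into downstream
multivariate analysis. Within every observed family the RSCU values
average to exactly 1 (tested to 1e-12).

**Positional GC.** GC1/GC2/GC3 are computed over all sense codons; GC12 is
their first/second-position mean; GC3s is third-position GC restricted to
codons of synonymously degenerate families (ATG, TGG, stops excluded). On
sequences made only of 4-fold-family codons GC3s equals GC3, a tested
identity.

**ENC.** Wright's effective number of codons: per family with `n >= 2`
observations the homozygosity is `F = (n * sum(p_i^2) - 1)/(n - 1)`; the
class means F2, F3, F4, F6 enter `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`,
clamped to [20, 61]. Missing-class handling: an inestimable F3 (no
observed Ile) is imputed as `(F2 + F4)/2`, Wright's prescription; any
other inestimable class is imputed as the family-count-weighted mean of
the estimable class means, and the imputation is recorded per result. The
limits are exact: one codon per family gives ENC = 20; uniform usage at
10,000 codons lands in [60, 61].

**Expected-ENC curve.** The reference curve of the ENC--GC3s plot is
Wright's expectation `ENC*(s) = 2 + s + 29/(s^2 + (1-s)^2)`. A widely
reproduced variant omits the `+ s` term; both are implemented
(`variant = "no_s"`), the standard form is the default, and the
discrepancy is documented rather than resolved: at `s = 0.5` the two forms
give 60.5 and 60.0 respectively.

**Aggregation levels.** Species-level statistics are computed on the
pooled codon counts of a genome's QC-passing coding sequences
("concatenated CDS", with IR-duplicated gene names deduplicated);
gene-level values feed the diagnostics and plots. Both modes are exposed
because the aggregation level is frequently left unstated in the
literature; the package declares its convention instead of guessing what
any particular study did.

# Evolutionary-force diagnostics

**Neutrality plot.** Ordinary least squares of GC12 on GC3 across a
species' genes (slope near 1: mutation pressure; near 0: selection). The
fit is defined only for at least 3 complete genes with positive GC3
variance; degenerate inputs return a structured undefined result. The
implementation equals the closed form `slope = cov/var` to 1e-12 (tested).

**PR2.** Third-position parity ratios `A3/(A3+T3)` and `G3/(G3+C3)` per
gene, with (0.5, 0.5) the mutation–selection equilibrium. The default
tallies all sense codons' third positions — the pragmatic choice when
plots colour every gene — while `codon_set = "fourfold"` restricts to the
five strictly 4-fold families, the classical PR2 definition. A zero
denominator yields a missing ratio, never 0/0.

**Correspondence analysis.** Classical chi-square-metric CA of the gene x
59-codon RSCU matrix: `P = X/sum(X)`, standardized residuals
`S = D_r^{-1/2}(P - rc')D_c^{-1/2}`, SVD, principal coordinates scaled by
marginals and singular values, inertia fractions `sigma_i^2/sum(sigma^2)`.
Running CA on RSCU rather than raw counts follows the common practice for
codon-usage studies; rows are weighted by their row sums as in standard
CA, and a count-based analysis is available by passing a count matrix.
Numerical choices: singular values below
`max(100 * eps * max(dim) * sigma_max, 1e-12)` are treated as zero, so a
rank-one matrix returns a zero-inertia result instead of noise; the sign
of each axis is fixed by making the largest-magnitude column loading
positive; missing RSCU entries are set to 0 on input (`na_as_zero`) and
all-zero rows/columns are dropped with a message. Genes with fewer than
30 codons (configurable) are excluded from all diagnostics to avoid
degenerate ratios.

Pooled versus per-species CA: both are provided; the pipeline default
pools all genomes' genes into one matrix, which matches how single
axis-inertia percentages are usually quoted for multi-species panels.

# Ka/Ks estimation

`ng86()` implements Nei–Gojobori counting with Jukes–Cantor correction on
codon-aligned pairs:

* *Sites*: per codon position, the synonymous fraction is the proportion
  of synonymous changes among changes that do not create a stop codon;
  stop-creating changes are excluded and the fractions renormalized, so
  synonymous + nonsynonymous sites always total exactly `3 *
  n_codons` (a tested invariant). Implementations in the literature differ
  on whether stop-changes count as nonsynonymous sites; the renormalized
  convention is used here because it matches a mutation process in which
  stop mutations are never observed — exactly the simulator below.
  Fractional sites are averaged over the two sequences.
* *Differences*: codon pairs differing at 2 or 3 positions are averaged
  over all minimal mutational pathways with equal weights; pathways
  passing through a stop codon are excluded (if every pathway is blocked,
  all are used). The 64 x 64 pathway tables are precomputed once and
  cached.
* *Correction*: `d = -(3/4) log(1 - (4/3) p)`; `p >= 3/4` makes the rate
  undefined. `ratio = ka/ks` requires `ks > 0`; otherwise the result is
  reported as undefined and excluded from category denominators.
* *Categories*: strong purifying (`ratio < 0.5`), relaxed purifying
  (`0.5 <= ratio <= 1`), positive (`ratio > 1`) — thresholds exactly 0.5
  and 1.0.

NG86 was chosen as the estimator because it is fully specifiable from
first principles and has an exact hand-computable oracle; model-averaged
or maximum-likelihood estimators (gamma-series, branch-site models) are
out of scope. Homologs are paired by identical gene name across genomes
(first feature per name, so IR duplicates are not double-counted), in
all-vs-reference or all-pairs mode; codon alignment is assumed as input
and only equal-length pairs are analysable.

# The synthetic-data generator

`make_plastome()` emits an annotated GenBank record plus a truth table
that is re-checkable against the emitted sequence by direct string
comparison (`validate_truth()`).

What it emulates, and the defaults (all overridable):

* the quadripartite layout, LSC 87,673 bp / SSC 15,866 bp / IR 26,802 bp
  (the canonical citrus-type plastome; total 157,143 bp), with IRa the
  exact reverse complement of IRb;
* 86 protein-coding genes (start ATG, one terminal stop, 100--300 internal
  codons, ~15% carrying one intron), 37 tRNA and 8 rRNA features;
* codon draws from per-family probability vectors, by default built from a
  synonymous third-position GC target of 0.32: within each family a
  codon's weight is `gc3` if it ends G/C and `1-gc3` otherwise, with
  uniform amino-acid usage;
* intergenic/intron/structural filler with AT fraction 0.63, chosen so
  that with the coding composition above the genome-wide GC lands at the
  38.4% typical of citrus-type plastomes;
* planted SSRs (default 12 loci covering all unit-length categories and
  all three region classes) inserted with 10 bp guards whose junction
  bases are fixed so each planted locus is exactly maximal; all remaining
  non-coding sequence is swept with the package's own scanner and
  point-mutated until no unplanned threshold-passing repeat survives.
  Rare repeats that emerge inside coding sequence are never mutated (that
  would distort the codon draws) and are instead recorded in the truth
  table with `planted = FALSE`.

One integer seed drives every draw; generation is byte-deterministic and
the RNG state of the caller is restored afterwards.

What it does **not** emulate — and hence what passing tests do not show
about real data: IR expansion/contraction and gene-order evolution,
indels, near-identical (mismatched) IRs, compound SSRs, amino-acid
composition biases beyond uniform usage, GC heterogeneity along the
genome, and sequencing/annotation errors. Tests on synthetic data verify
the algorithms against their definitions, not the biology of any
particular lineage.

`make_homolog_pair()` diverges a coding sequence by single-nucleotide
proposals accepted with probability `min(1, 1/omega)` if synonymous and
`min(1, omega)` if nonsynonymous (so `omega > 1` accelerates
nonsynonymous fixation without requiring probabilities above one);
proposals creating stops are rejected and the terminal stop is never
touched. `t` is the expected number of proposed mutations per codon.
Realized substitution counts are recorded as ground truth.
`derive_plastome()` applies this per gene to build diverged cohort members
while leaving non-coding sequence, planted SSRs and the quadripartite
layout untouched (genes hosting recorded repeats are left unevolved so
the truth table stays exact).

# Problem sizes used by the tests

The suite runs on scaled-down genomes (LSC 12 kb, SSC 2.6 kb, IR 6 kb, 12
genes) chosen so each structural case still exercises every code path;
statistical recoveries use 10,000-codon draws for RSCU/ENC limits, 500
codons x 50 replicates for NG86 omega recovery at omega in {0.2, 0.7,
1.0, 1.5} (3 Monte-Carlo standard errors of the median), 50 simulated
species for the neutral-slope check, and 100 random 2 kb fixtures for
scanner/oracle equivalence. `scripts/acceptance.R` regenerates a
full-size five-genome cohort from scratch and reports the headline
quantities it computes.

# Known limitations

* IR detection requires exact repeats; a plastome whose IRs differ by a
  single substitution is reported as non-quadripartite.
* Gene counts are reported as annotated (IR duplicates included); counting
  conventions differ between published tables, so totals are reported but
  never asserted.
* NG86 saturates (`p >= 3/4`) on highly diverged pairs; such pairs are
  reported undefined rather than extrapolated.
* The internal codon "alignment" is positional: only equal-length CDS
  pairs are compared; indel-containing homologs need an external aligner.
* A Ka/Ks ratio above 1 is classified "positive" by threshold; on its own
  it is not proof of positive selection, and no branch-site modelling is
  attempted.
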