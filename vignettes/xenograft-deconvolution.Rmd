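---
title: "Species-of-origin deconvolution of xenograft RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-of-origin deconvolution of xenograft RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenosplit)
```

## The problem

RNA-seq of a patient-derived xenograft (PDX) samples a mixture of two
transcriptomes: the engrafted human tumor cells and the supporting mouse
stroma, vasculature and infiltrate. Any analysis of the human tumor
transcriptome must first decide, read by read, which genome each fragment
came from. `xenosplit` implements a comparative dual-genome strategy: the
same reads are aligned independently to a human and a mouse reference, and
each fragment is assigned to the genome it matches with fewer mismatching
bases.

## Species classification model

For each fragment the classifier records the best (minimum) `NM` edit
distance over all reported alignments in each genome; for paired ends the
two mates' best values are summed, and a genome only counts if both mates
map there. The decision rule is:

* aligned in one genome only → that species;
* aligned in both → the genome with strictly fewer mismatches;
* equal mismatch counts → **ambiguous** (excluded from species-specific
  analyses downstream);
* aligned in neither → **unaligned**.

The ambiguous class is irreducible: a fragment whose covered bases are
identical in the two genomes carries no species information at all. The
unaligned class is kept explicit (rather than folded into the denominator)
so that reported fractions always refer to all input fragments; when every
read aligns, the three-class view is recovered exactly.

Two classification conventions were genuinely open:

* **Fragment vs mate level.** Mates are classified jointly (mismatches
  summed over the fragment). This is the conservative choice — a fragment
  is never split between species — and it is configurable in the sense that
  single-end input is classified per read.
* **Fidelity = mismatches only.** Alignment scores, gap penalties and
  mapping quality are deliberately ignored; the comparison is defined on
  base mismatches alone, with `MD`-tag fallback when `NM` is missing and a
  hard error when neither is present (guessing would silently corrupt the
  partition).

On simulated pure-human data (per-base human–mouse divergence 0.12,
sequencing error 0.01, 50 bp reads) the misclassification rate as mouse is
of order 0.005% — a read can only flip species when a sequencing error at a
substituted site recreates the other genome's allele, which requires a
window with very few substitutions and a coincident error.

## Gene quantification

Counting uses an exon-containment rule: a read is ascribed to a gene only if
its aligned interval lies **entirely within a single merged exon** of that
gene. Exons of each gene are unioned across annotation sources before
testing. Each mate is tested separately and the fragment counts once, for
the gene wholly containing both mates; fragments contained in exons of more
than one gene are discarded and tallied as ambiguous-assignment (this
prevents double counting while keeping the loss auditable), and everything
else is tallied unassigned, so `assigned + ambiguous + unassigned = total`
always holds. Counting is unstranded, matching the unstranded library
preparation the pipeline targets.

Normalization is counts per million: `count / (library_total / 1e6)`, with
the library total defaulting to the sample's species-classified fragment
count (not the assigned-count sum), so that per-million values are
comparable across samples with different assignment rates.

Coordinates: GTF and SAM are both 1-based; interval logic is delegated to
`GenomicRanges`/`IRanges` in that representation, so no conversion layer
exists to get wrong.

## Orthologue joint analysis

To compare the human and murine components of one xenograft on a common
axis, a strictly 1:1 orthologue table maps human to mouse genes; any gene
appearing more than once on either side is dropped (with a count) rather
than resolved heuristically. Each physical sample then contributes a human
(`-H`) and a mouse (`-M`) pseudo-sample over orthologue pairs.

Values default to `log2(CPM + 1)`. The log transform is the standard choice
for correlation and clustering of expression; raw CPM is available via
`transform = identity` since pairwise correlations on the raw scale weight
highly expressed genes far more heavily, and the two modes answer different
questions.

Clustering follows a fixed two-stage recipe: all-pairs Pearson correlation
between pseudo-samples; Euclidean distance between the rows of that
correlation matrix; agglomerative hierarchical clustering, average linkage
by default (complete and single configurable — the linkage choice was open
and average is the least extreme). Dendrograms are also exported as Newick
text.

The shipped housekeeping list (`default_housekeeping_genes()`) is a small
illustrative set for subset correlations, not a curated consensus; real
analyses should supply their own.

## Differential expression

The DE engine is a conditional negative-binomial exact-style test with
moment/shrinkage dispersions:

* **Dispersion.** Per gene, a method-of-moments estimate
  `phi = (var - mean) / mean^2` on counts rescaled to a common library
  size, pooled across groups, floored at 0, then shrunk toward the all-gene
  median with fixed weight 0.7. The strong fixed shrinkage stabilizes the
  very noisy per-gene moments at typical replicate numbers (3–5); because
  the shrinkage target is the all-gene median, homogeneous-dispersion
  simulations are nearly unaffected by the weight while heterogeneous
  outliers are tamed.
* **Test.** Group sums are modeled as NB (their size parameters add);
  conditional on the pooled total, the two-sided p-value sums all splits
  with probability not exceeding the observed one (minimum-likelihood
  convention, the same convention as the two-tailed Fisher test). At
  `dispersion = 0` the conditional law is exactly binomial in the
  library-size share, which provides an enumeration oracle for tests.
* **Normalization.** Library totals are rescaled by median-of-ratios size
  factors by default. With raw totals, a minority of strongly changed genes
  inflates its group's totals and every null gene acquires a spurious
  opposite shift — the classic composition bias that TMM-style methods
  exist to remove; median-of-ratios restores FDR control in planted-effect
  simulations (observed FDR ≈ 0.05 at fold change 6, 5% DE genes, n = 5 per
  group). Raw totals remain available as an option.
* **Multiplicity.** Benjamini–Hochberg step-up adjustment; genes with
  FDR < 0.05 are called differentially expressed. Log2 fold changes use
  mean CPM with a 0.5 offset so zero counts stay finite.

This engine deliberately does not reproduce any specific GLM/likelihood
implementation bit for bit; its contract is statistical — type-I control
(null p-values uniform, KS distance < 0.05 at 2000 genes), power on planted
effects, and rank agreement with an independent exact-test implementation —
and each clause is enforced in the test suite.

## Gene-set enrichment

Over- and under-representation of gene sets among DE genes uses the
Wallenius non-central hypergeometric distribution: sampling without
replacement where in-set genes carry a common bias weight. The odds
parameter is the ratio of mean in-set to mean out-of-set weights; uniform
weights give odds 1 and reduce **exactly** to the central hypergeometric.

No installed package provides this distribution, so the pmf is computed
from its integral representation. After the substitution `u = t^(1/D)`
(with `D` the weighted mass of undrawn items) the integrand is smooth and
adaptive quadrature is reliable; at odds 1 the integral has an exact beta
closed form, which is used directly. The pmf is normalized over its support
before tail sums, bounding residual quadrature error. The general path is
validated against a 10^6-draw Monte-Carlo oracle (exponential-race
formulation of weighted sampling without replacement).

## Variant allele tallies

At user-specified loci, reads covering the position (located via a full
CIGAR walk; deletions and reference skips over the position are ignored)
are tallied as WT/mutant by strand from the SAM reverse-strand flag. No
base- or mapping-quality filter is applied by default (a minimum base
quality is available); overlapping mates are counted independently, since
forward- and reverse-strand evidence is reported separately anyway.

Percentages are integers over WT + mutant reads only (third alleles are
excluded from the denominator but reported). The wild-type percentage is
rounded half-up and the mutant percentage is defined as its complement —
the only convention under which the two columns always sum to 100 and all
arithmetic-consistent published-style examples reproduce exactly (e.g.
counts 2, 5, 1, 0 give 37.5%/62.5% → 38%/62%).

## Growth kinetics

Tumor volume series are fitted as `V(t) = V0 * exp(k t)` by least squares
on `ln(volume)`; doubling time is `Td = ln 2 / k` and R² is computed on the
log scale, consistent with the linearized fit. A series is classified
non-exponential when R² < 0.5 (strict) or the fitted rate is not positive;
flat series get `k = 0`, `R² = 0` and an undefined `Td`, and shrinking
tumors keep their negative `k` with `Td` undefined. Fits are
scale-equivariant in volume and invariant to time shifts, and both
properties are tested.

## The synthetic-data generator

All pipeline stages are exercised on synthetic data built by the package
itself:

* **References.** Orthologous transcript pairs: a random "human" sequence
  and a "mouse" copy with independent per-base substitutions (never to the
  same base, no indels) at a configurable divergence, default 0.12 — the
  order of typical human–mouse exonic divergence. Genes are single-exon,
  each on its own contig, so containment counting and pileup are exactly
  checkable; splicing is an aligner concern and out of scope here.
* **Reads.** Fragments drawn per a species mixture with uniform gene and
  start positions, default 50 bp (paired by default, insert capped at
  200 bp), with independent per-base errors (default 0.01). Both mates come
  from one fragment of one species and the truth label attaches to the
  fragment.
* **Alignments.** Because the simulator knows each fragment's true locus
  and the orthologous locus in the other genome, it writes both SAM files
  directly with `NM` equal to the true Hamming distance, bypassing an
  aligner entirely. A configurable per-mate mismatch cutoff (default 10)
  emits unmapped records beyond it, emulating an aligner's tolerance while
  leaving the mismatch comparison — not alignment failure — as the main
  classification signal.
* **Counts and growth.** NB count matrices with planted fold changes
  (Poisson at dispersion 0) and exponential growth series with log-normal
  noise close the loop for the statistical modules.

Identical configuration and seed reproduce every output byte for byte.

What the generator does **not** emulate: splicing and introns, indels,
quality-score variation, GC and positional bias, duplicate reads, 3'
coverage bias, and many-to-many orthology. Passing tests therefore
demonstrate the correctness of the decision rules and statistics under the
stated model, not robustness to every artifact of real libraries; on real
data the alignment step (out of scope) absorbs several of these effects.

## Problem sizes and numerical choices

The test suite runs simulations sized for completeness per unit time:
misclassification bounds use 50,000 single-end reads over 60 orthologue
pairs; DE calibration uses 1000–2000 genes at 5 replicates per group;
clustering recovery uses planted two-lineage designs; the Wallenius oracle
uses 10^6 Monte-Carlo draws; Fisher's test is checked against exhaustive
enumeration over all tables with margins ≤ 12. Ties in both exact tests use
the minimum-likelihood convention with a 1e-7 relative slack so that
floating-point noise cannot drop the observed outcome from its own tail.

## Known limitations

* The species classifier cannot rescue reads from regions identical between
  the genomes; they are ambiguous by construction and excluded downstream.
* The NB test conditions on group sums, which is exact only for equal
  within-group library sizes; unequal sizes are handled through the mean
  parameterization and are approximate.
* The containment counting rule ignores spliced alignments that cross exon
  junctions (per-exon containment is the rule being implemented, and the
  simulator's gene models are single-exon).
* Wallenius p-values rely on adaptive quadrature away from odds 1; extreme
  odds (≫ 10^3) or very large universes may need tightened tolerances.
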