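# xenosplit

Species-of-origin deconvolution and downstream analysis of xenograft
RNA-seq, in R.

RNA-seq of a patient-derived xenograft (PDX) mixes two transcriptomes: the
engrafted human tumor cells and the mouse stroma, vasculature and immune
infiltrate that support them. Before any tumor-specific analysis, every
sequenced fragment has to be attributed to one genome. `xenosplit`
implements the comparative dual-genome strategy: the same reads are aligned
to both the human and the mouse reference, and each fragment is classified
by alignment fidelity —

* fewer mismatching bases against human → **human**;
* fewer against mouse → **mouse**;
* equal mismatch counts → **ambiguous** (excluded downstream);
* mapped to neither → **unaligned**.

Around that core the package provides the full downstream pipeline:

* gene-level quantification of the partitioned alignments by an
  exon-containment rule (a read counts for a gene only if it lies entirely
  within one merged exon), with counts-per-million (CPM) normalization;
* joint human/mouse expression over strictly 1:1 orthologue pairs, pairwise
  Pearson correlations (optionally on a housekeeping subset), and
  hierarchical clustering of pseudo-samples (correlation matrix →
  Euclidean distances → average-linkage agglomeration, Newick export);
* differential expression via a conditional negative-binomial exact-style
  test (moment/shrinkage dispersions, median-of-ratios normalization) with
  Benjamini–Hochberg FDR and an FDR < 0.05 call;
* gene-set enrichment under the Wallenius non-central hypergeometric
  distribution (reducing exactly to Fisher's test at odds 1), plus the
  two-tailed Fisher's exact test for 2×2 tables;
* strand-stratified WT/mutant allele tallies at specified loci with
  integer percent allele fractions;
* exponential tumor growth fits `V(t) = V0·e^(kt)` with doubling time
  `Td = ln2/k`, log-scale R², and a non-exponential call at R² < 0.5;
* a stromal/epithelial signature score calling each xenograft CX
  (carcinoma xenograft) or SX (stromal xenograft).

A synthetic-data generator produces every input the pipeline needs — paired
orthologous references at configurable divergence, truth-labeled reads with
sequencing error, dual-genome SAM alignments with exact `NM` tags, NB count
matrices with planted fold changes, and noisy growth series — so every
stage is tested end to end without any external data.

## Worked example

Simulate a xenograft-like sample (90% human / 10% mouse fragments, 12%
human–mouse divergence, 1% sequencing error) and partition it:

```r
library(xenosplit)

cfg  <- sim_config(n_genes = 40, divergence = 0.12, error_rate = 0.01,
                   species_mix = c(human = 0.9, mouse = 0.1), seed = 1)
refs  <- generate_reference_set(cfg, out_dir = "demo")
reads <- simulate_reads(refs, n_reads = 10000, out_dir = "demo")
emit_alignments(reads, refs, "demo/human.sam", "demo/mouse.sam")

partition_sample("demo/human.sam", "demo/mouse.sam", "PDX1")
#> xs_partition 'PDX1': 10000 fragments
#>   human           8956   89.56%
#>   mouse           1044   10.44%
#>   ambiguous          0    0.00%
#>   unaligned          0    0.00%
```

The partition matches the simulated truth exactly here: 89.56% of the
fragments really were human (`mean(reads$truth$true_species == "human")`),
and with ~100 bp of covered sequence per fragment at 12% divergence,
windows without any discriminating substitution are vanishingly rare, so
nothing lands in the ambiguous class.

Quantify the human component and fit a growth curve:

```r
models <- load_gene_models(refs$paths$human_gtf, species = "human")
cm <- count_contained_reads("demo/human.sam", models, sample_id = "PDX1")
head(cpm_normalize(cm)[, 1], 3)
#> HGENE0001 HGENE0002 HGENE0003
#>     23100     25200     25900

fit_exponential(simulate_growth(100, 4, seq(0, 21, 3), noise_sd = 0.1, seed = 3))
#> exponential growth fit: V0 = 92.3, k = 0.1801 /day, Td = 3.85 days, R2 = 0.998 (exponential)

fisher_exact(matrix(c(3, 11, 26, 19), 2, byrow = TRUE))
#> [1] 0.03034142
```

CPM values are counts divided by the library total in millions (10,000
fragments here, so one read ≈ 100 CPM). The growth fit recovers the
planted 4-day doubling time within 4% despite 10% log-scale noise; the 2×2
example is an engraftment-route comparison (3/14 successes in one arm vs
26/45 in the other) giving two-tailed p ≈ 0.03.

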