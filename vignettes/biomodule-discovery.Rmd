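---
title: "Biomodule discovery from chromatin co-occupancy and expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomodule discovery from chromatin co-occupancy and expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomodules)
```

## The problem

Repressive chromatin regulators such as the histone methyltransferase EZH2
silence genes through the H3K27me3 mark. Regions where ChIP-seq peaks of the
regulator and of its mark co-occur are candidate silenced loci, but a
genomic region is not a gene: most co-enriched regions are intergenic, and
distal regulatory elements act over large distances (on the order of a
hundred kilobases), in either direction, and independently of the target
gene's orientation. On the transcriptome side, loss or gain of such
silencing leaves only a subtle signature, so single-gene differential
expression is a weak instrument. This package implements an integrative
procedure for that setting:

1. **Co-enrichment**: intersect the peak sets of two chromatin marks into
   co-enriched genomic regions.
2. **seq2gene**: link each region to *all* candidate target genes within a
   search radius on both sides, with a category per link (exonic, promoter,
   intronic, intergenic).
3. **Expression preprocessing**: collapse probes to genes, adjust
   multi-cohort batch effects by an empirical-Bayes model, and keep the
   most variable half of genes.
4. **Biomodule discovery (the PGNet step)**: order all genes by two
   independent statistics — co-expression with a chosen seed gene, and
   case–control differential expression — quantify the concordance of the
   two orderings by a weighted prefix-overlap score with a permutation
   test, and take the genes in the top ranks of both lists as the
   *biomodule*.
5. **Enrichment**: test the biomodule against a gene-set collection with a
   conditional hypergeometric test restricted to the "true background" of
   genes present in both the assay and the collection.

## Region-to-gene linking

The annotation is held in two flat tables (one row per transcript with its
TSS, one per exon, both keyed by stable feature ids; `write_annotation_tables()`
emits them) and queried by bisection: features are sorted by start position
per chromosome and a pair of binary searches (on the starts and on the
running maximum of the ends) brackets the candidates for any query
interval. Results are defined to be identical to a linear scan, and the
test suite enforces that equivalence on fuzzed genomes.

`classify_region()` links a region to every gene within `radius` bp on
either side and assigns the highest-priority category that applies, one
link per (region, gene):

* **exonic** — the region overlaps an exon of the gene;
* **promoter** — it overlaps a window of `promoter_halfwidth` bp around
  any transcript TSS (default ±2 kb, the conventional promoter window);
* **intronic** — it lies inside the gene span but touches neither exon nor
  promoter window;
* **intergenic** — the gene does not overlap the region but its span is
  within the radius; the signed distance is reported in reference
  orientation (negative left of the region).

Two genuinely open choices are resolved as follows and exposed as options.
Distance is measured span-to-gap rather than TSS-to-region (the search is
about physical proximity of the regulatory element to the gene territory;
`distance_from = "tss"` is available). And intergenic linking keeps *all*
genes within the radius rather than the nearest one, because several
distal elements commonly converge on one gene and one element can regulate
several genes; `nearest_only = TRUE` restores the classical annotation
behaviour. The default radius of 150 kb covers the typical distal-element
distance of ~120 kb with margin. Gene strand is deliberately ignored for
linking.

"Intersecting two peak sets" is implemented as genomic *segment*
intersection (every output base pair is covered by both inputs, book-ended
segments merged, each input merged first), not as "peaks of A touching B";
the latter is available as `mode = "peaks_a"`.

## Expression preprocessing

* `collapse_probes()` keeps, per gene, the probe with the largest mean
  intensity (ties by probe id) — the standard conservative collapse for
  arrays.
* `correct_batches()` implements the parametric empirical-Bayes
  location–scale model: per gene the data are standardized against a
  batch-free fit, per-batch additive effects γ and multiplicative effects
  δ² are estimated, shrunk toward normal and inverse-gamma priors whose
  hyperparameters come from cross-gene moments, and removed. Phenotype
  protection (`protect = TRUE`, the default) carries the group labels as a
  covariate so real group differences are not absorbed; it errors when
  batch and phenotype are confounded, since the two effects are then
  inestimable. Protection defaults on because multi-cohort case–control
  designs typically spread the groups unevenly across cohorts.
  Degenerate priors are handled exactly: if the batch effect is identical
  across genes the prior variance is zero and the common effect is removed
  without shrinkage residue — a pure constant shift between batches is
  eliminated to machine precision. On well-conditioned data the adjustment
  agrees closely with the reference ComBat implementation (enforced in the
  test suite).
* `iqr_filter()` keeps the `ceiling(f·G)` genes with the largest
  interquartile range, computed with type-7 (linearly interpolated)
  quantiles — stated explicitly because quantile conventions differ across
  software. The default `f = 0.5` keeps the most variable half (8442 genes
  in, 4221 out).

## Ranking statistics

Differential expression uses a moderated two-sample t: pooled per-gene
variances `s²_g` on `d_g` df are shrunk toward a prior `s₀²` with `d₀` df
estimated by the method of moments on `log s²_g` (digamma/trigamma moments
of the log chi-square; the trigamma inverse is solved by Newton
iteration), giving `s̃² = (d₀s₀² + d_g s²_g)/(d₀ + d_g)` and
`t = logFC / (s̃·√(1/n_a + 1/n_b))` on `d₀ + d_g` df. The statistic is
implemented here rather than delegated, as a documented approximation to
the standard empirical-Bayes approach; the `limma` implementation serves
as an independent cross-check in the tests. `prior_df = 0` recovers the
ordinary t exactly, `prior_df = Inf` pools all variances. Fold changes are
reported as `2^logFC` with `logFC = mean(case) − mean(control)` on log2
data, and the selection rule `select_de_genes()` applies Q < 0.05 with
FC ≥ 2 or ≤ 0.5.

Co-expression is the Pearson correlation with the seed gene across all
samples, with the exact t-transform p-value on n−2 df. Q-values are
Benjamini–Hochberg by default; `method = "storey"` rescales by
π̂₀ = min(1, mean(p > λ)/(1−λ)) at a single fixed λ = 0.5 — simpler and
deterministic compared with a λ-grid smoother, and never larger than BH.

## The biomodule statistic

Let the universe of N genes be ordered twice (ties always broken by gene
id so prefixes are deterministic). The overlap step function
`O(n) = |top_n(list A) ∩ top_n(list B)|` is summarised by the weighted
score

```
score = Σ_{n=1..n_max} exp(−β·n) · O(n)
```

with default `β = 1/n_top`, i.e. e-fold weight decay at the rank threshold
that defines the module — early ranks dominate but the whole prefix
contributes. Under independent orderings `O(n)` is
Hypergeometric(N, n, n) with mean `n²/N`; `expected_overlap_ci()` provides
that reference band, drawn by `plot()`.

Significance comes from permuting *one* list uniformly B times (equivalent
in distribution to permuting both, at half the cost) and the add-one
estimator `p = (1 + #{null ≥ observed})/(B + 1)`, which can never return
zero. Top and bottom ranks are analysed and reported separately, because
concordance driven by a module of up-regulated, positively correlated
genes appears at the top ranks only. The biomodule itself is the
intersection of the two top-`n_top` prefixes (default 150), which makes
`extract_biomodule()` invariant to any strictly monotone transform of
either statistic.

One subtlety the synthetic experiments exposed: even with no planted
signal the two orderings are not independent, because both statistics are
computed from the same matrix — a gene's correlation with the seed
co-varies with its own group contrast through the seed's *realized*
contrast. The chance module is therefore somewhat larger than the raw
`n²/N` baseline. The permutation null is unaffected (it permutes ranks,
conditioning on both observed orderings), which is exactly why the
empirical p, not the hypergeometric band, carries the inference.

## Conditional enrichment

`enrich()` forms, for each gene set, the 2×2 table over the restricted
background — the intersection of the assay's genes with the union of all
collection members — after intersecting both the module and the set with
that background. The p-value is the upper hypergeometric tail
P(X ≥ a), identical to the one-sided Fisher exact p on the same table
(the tests verify equality to 1e-12 on random tables). The odds ratio is
`ad/(bc)` with the Haldane–Anscombe 0.5 correction only when a zero cell
occurs; a perfect-association table (b = c = 0) is reported as `Inf`.
Both published threshold conventions are supported: the default filters on
raw p ≤ 0.001 with count > 5 and reports BH q alongside
(`filter_on = "q"` switches the filter to the q-value). Because the
original's "Size" column is ambiguous, both the full set size and the
background-restricted size are emitted.

## What the synthetic generators emulate

`simulate_genome()` lays out non-overlapping genes (1–3 transcripts, 1–8
exons) at a density of about one gene per 160 kb — mammalian-like — with
31% of genes coding, matching the coding share typical of region-linked
gene sets. `simulate_peaks()` places, for each planted target, a pair of
overlapping peaks near the TSS (promoter-biased, always within the search
radius), plus uniformly placed background peaks per mark; a background
peak co-occurs across marks with probability `co_occupancy_rate`
(default 0.1 — incidental overlap of mark-specific noise), and the default
of 25 background peaks per mark models stringent peak calls in which noise
is a minority. The generator records which regions were planted, so
benchmarks can attribute false target genes specifically to background
peaks: a *by-design* consequence of radius linking is that neighbours of a
true region are also linked, and counting those as false positives would
measure the generator, not the method. The false-target rate is therefore
defined as the fraction of non-planted genes linked by co-enriched regions
that do not stem from a planted peak pair.

`simulate_expression()` uses a Gaussian log2-intensity model (microarray
like, not counts): a latent per-sample signal z ~ N(0,1); the seed gene is
`σ·z` plus a `log2_effect` shift in cases; each module gene is
`σ(ρ·z + √(1−ρ²)·ε)` plus the same shift; all other genes are independent
noise around gene-specific baselines N(7, 1). The defaults — 2000 genes,
28 cases vs 24 controls, a 40-gene module, ρ = 0.7, effect 1.0 log2 units,
σ = 1 — mirror a realistic multi-cohort case–control study of moderate
effect size. Note that the planted ρ applies to the *noise component*;
the raw all-sample correlation of a module gene with the seed exceeds ρ
because the shared case shift adds covariance, so generator checks
estimate ρ on group-centred data. Optional batch designs layer additive
shifts (and multiplicative residual scalings) on top, interleaved within
groups by default so batch is never confounded with phenotype.

What these generators do **not** emulate: read-level ChIP-seq noise, peak
width/intensity distributions, correlated gene-gene structure outside the
module, count-based RNA-seq error, missing values, or probe-level
artifacts. Passing the recovery benchmarks therefore demonstrates the
correctness and calibration of the algorithms under their stated model,
not performance on any particular real data set.

## Numerical and reproducibility choices

* Coordinates are 1-based inclusive throughout (GFF convention); BED input
  is converted on read and BED output on write.
* Every ordering that could tie is resolved by (start, id) or by gene id.
* All generators and the permutation test are pure functions of their seed
  arguments; `run_pipeline()` writes a manifest (package version, config,
  input checksums, headline results) sufficient to reproduce a run.
* Default problem sizes in the test suite (genomes of 100–2000 genes,
  matrices up to 2000×52, 1000 permutations, 50 replicate fits) were
  chosen so the full suite exercises every code path at study-default
  parameters while remaining quick to run on a laptop.

## Worked example

```{r example}
sim <- simulate_expression(n_genes = 600, n_case = 14, n_control = 12,
                           module_size = 25, rho = 0.75, log2_effect = 1.2,
                           rng_seed = 5)
fit <- pgnet(sim$expression, seed_gene = sim$truth$seed_gene,
             group_a = "case", group_b = "control",
             n_top = 80, B = 500, rng_seed = 5)
fit
length(intersect(fit$genes, sim$truth$module_genes))
```

```{r plot, fig.width = 6, fig.height = 4}
plot(fit)
```

## Limitations

* The moderated t assumes roughly normal log intensities and equal
  group variances per gene; count data should be transformed (or analysed
  with a count model) first.
* The permutation test permutes gene labels of one ordering; it conditions
  on both marginal orderings and does not model gene-gene correlation.
* The batch model is location–scale only; it cannot remove batch effects
  that interact with phenotype, and it refuses confounded designs rather
  than guessing.
* seq2gene links by proximity; it does not predict enhancer–promoter
  contacts, score conservation, or scan motifs.
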