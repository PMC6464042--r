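---
title: "Coessentiality networks from pooled CRISPR knockout screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coessentiality networks from pooled CRISPR knockout screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coessnet)
```

# The method

Pooled CRISPR knockout screens measure, for every gene in every cell line,
how strongly loss of the gene impairs growth. Genes that work together —
members of a complex, a pathway, a context-specific dependency — tend to be
essential in the *same* cell lines, so the correlation of two genes'
essentiality profiles across a panel of screens is evidence of shared
function. `coessnet` turns raw guide-level read counts into such a
"coessentiality" network and decomposes it into functional modules.

The pipeline runs in fixed order:

1. **Fold changes.** Each sample column is scaled to a common library size
   (10 million reads), then for each guide
   $\mathrm{fc} = \log_2\frac{s + c_0}{t_0 + c_0}$ against the matched
   T0/plasmid control of its batch, with pseudocount $c_0 = 5$ and a
   minimum-control-read filter (default 0). Guides annotated to multiple
   genes are removed on input.
2. **Bayes factors.** For each screen we estimate kernel densities
   $\hat f_E$ and $\hat f_N$ of guide fold changes over curated
   core-essential and nonessential reference genes and score every guide by
   $\log_2 \hat f_E(\mathrm{fc}) / \hat f_N(\mathrm{fc})$. A gene's Bayes
   factor (BF) is the sum of its guides' log-ratios, so $BF > 0$ means the
   knockout depletion pattern looks essential. Reference genes are scored
   under 10-fold cross-validation so no gene is evaluated by a model trained
   on itself. Because a density ratio is only supported where both classes
   have data, a linear fit of the log-ratio against fold change extends the
   classifier's dynamic range beyond the fit interval; the extension is
   anchored at the interval boundary so the score is continuous. Screens
   whose reference classes are statistically indistinguishable (non-negative
   slope) are declared unscorable and dropped.
3. **Quality control.** Per screen we compute precision-recall against the
   reference sets and the F-measure at $BF = 5$; screens with
   $F > 0.85$ and fewer than 2,000 essential genes pass (both strict
   inequalities; thresholds are configuration keys because other libraries
   warrant looser cuts, e.g. $F > 0.80$).
4. **Network.** Passing columns are quantile-normalized (each column mapped
   onto the per-rank mean distribution, ties averaged), genes essential in
   fewer than 3 lines are discarded (their profile variation is noise), all
   remaining pairs are scored by Pearson correlation with two-sided p-values
   from the $t = r\sqrt{(n-2)/(1-r^2)}$ transform, same-chromosome pairs
   closer than 20 Mb are removed (copy-number segments depress neighboring
   guides and fake correlation), and edges are kept at Bonferroni
   $p < 0.05$ over the tested family (positive correlations only; the
   *strict* network) or Benjamini–Hochberg $q < 0.01$ with both signs (the
   *extended* network).
5. **Off-target flags.** For each edge we look for guides of one endpoint
   within Hamming distance 1 of a guide of the other; if any exist, both
   profiles are re-scored without those guides (from cached per-guide
   log-ratios) and the edge is marked `offtarget_suspect` when the re-scored
   pair no longer meets its significance tier.
6. **Modules.** A self-contained Markov Cluster Algorithm (expansion by
   matrix squaring, inflation $I$, column renormalization, pruning below
   $10^{-5}$, convergence at $10^{-8}$) partitions the network; clusters are
   the connected components of the converged flow matrix, which resolves
   attractor overlaps deterministically. The default inflation is 2.0;
   `selectInflation()` scores a grid by the functional coherence (LLS) of
   within-cluster pairs if a pathway standard is supplied.
7. **Benchmark.** Ranked pairs are binned (1,000 labeled pairs per bin) and
   scored by the log-likelihood score
   $\mathrm{LLS} = \ln\frac{TP/FP}{P/N}$, the within-pathway odds in the bin
   over the background odds among all annotated pairs. Pathways larger than
   200 genes (ribosome, spliceosome, proteasome and kin) are excluded
   because they dominate the statistic; pairs with an unannotated gene are
   excluded from numerator and denominator alike.
8. **Annotation.** Per cluster: mean member BF per line; "case" lines are
   those where the median member BF exceeds 5; tissue specificity by
   two-sided Wilcoxon rank-sum of each tissue versus the rest, Bonferroni
   over tissues; expression association by Welch t-test on
   $\log_2(\mathrm{FPKM}+0.5)$; copy-number and mutation associations by
   two-sided Fisher tests (CNV discretized at $|\log CN| \ge 0.4$,
   amplifications and deletions separately, silent mutations counted
   wild-type); drug sensitivity by Pearson correlation of cluster mean BF
   against log(IC50), keeping negative correlations with $p < 10^{-4}$ over
   at least 34 shared lines; and an amplification-artifact label for genes
   whose essentiality tracks their own copy number but not their own
   expression.

# Parameters that matter

| parameter | default | unit / scale | why |
|---|---|---|---|
| `pseudocount` | 5 | scaled reads | stabilizes log-ratios at low counts |
| `lib_size` | 1e7 | reads | common column scale before the ratio |
| `n_folds` | 10 | folds | reference cross-validation granularity |
| `bf_threshold` | 5 | log2 BF | essential call for QC, mask, case lines |
| `f_min` / `max_essential` | 0.85 / 2000 | — | screen QC; strict inequalities |
| `min_lines` | 3 | cell lines | drop genes never or almost never essential |
| `window_bp` | 2e7 | bp | proximity filter for copy-number artifacts |
| `strict_alpha` / `extended_q` | 0.05 / 0.01 | — | Bonferroni / BH edge tiers |
| `inflation` | 2.0 | — | MCL granularity |
| `lls_bin` | 1000 | pairs | enrichment resolution |
| `pathway_max` | 200 | genes | large-complex bias guard |
| `cnv_cut` | 0.4 | log ratio | amplified / deleted discretization |
| `drug_p`, `min_drug_pairs` | 1e-4, 34 | — | drug-hit stringency |

Numerical choices: kernel density bandwidth follows Scott's rule (`bw =
"nrd"`); the density support floor is $2^{-7}$ of each density's maximum;
the evaluation grid has 1,024 points spanning the observed fold changes
plus one unit on each side. The Bonferroni family is the number of pairs
actually tested after the essentiality mask and proximity filter — the
conservative literal count. Ranking ties are broken by $(-|r|,$ gene A,
gene B$)$ so all outputs are deterministic. Gene coordinates are taken as
supplied (start, midpoint or TSS at the caller's discretion; BED input is
converted 0-based to 1-based). Wilcoxon tests use the exact distribution
for small tie-free groups and the continuity-corrected normal approximation
otherwise (the `stats::wilcox.test` switch at $n = 50$).

# Design choices where the ground was open

* **Unscorable versus well-separated screens.** A screen fails only when
  the reference classes cannot be ordered (non-negative slope of the
  log-ratio). When the two densities are so cleanly separated that they
  never jointly exceed the support floor, the model falls back to a
  floored-density log-ratio over the union support — perfect separation is
  maximal evidence, not failure.
* **Off-target re-scoring** uses cached per-guide log-ratios rather than a
  full re-fit of the reference model (a configuration choice; the
  contaminated guides are a tiny fraction of the training data, so the
  cached model is numerically indistinguishable), and re-tests the raw
  (unnormalized) profiles of the two genes.
* **Extended-tier re-test for flagged edges** compares the recomputed
  p-value to the nominal FDR level, since a single recomputed pair has no
  BH family.
* **Cluster-level artifact labels** are the majority label of significant
  member genes, ties to `cnv_artifact`; per-gene significance is Bonferroni
  over the genes tested at `alpha = 1e-4`.
* **The BF floor of −10** that makes heat maps readable is applied only in
  visualization exports, never to statistics.

# What the synthetic compendium emulates

`simulateScreens()` generates the full input stack with known truth:
negative-binomial counts (mean 500 reads/guide, size 10) for a control and
60 treated lines over 4 tissues; 200 core-essential genes depleted
everywhere (log2 shift −4); 6 planted modules of 8 genes depleted only in
their context lines (shift −4, penetrance 0.9) — modules 1–4 context =
one tissue each, modules 5–6 = random line subsets so no two modules share
a context; 600 nonessential genes; 10 copy-number-artifact genes whose
depletion is proportional to a planted amplified log copy ratio while
their expression stays independent; per-guide knockout efficiency
U(0.4, 1), as real spacer potency varies; optional promiscuous guides one
mismatch away from a module gene's guide, carrying the sum of both loci's
depletion; a genomic layout that puts exactly one member pair per module
inside the 20 Mb window; and molecular layers (expression, CNV, binary
mutations, tissues, drug log-IC50 with drug 1 planted against module 1's
context).

It does **not** emulate replicate structure, time courses, batch effects
beyond a single control, guide-specific PCR biases, or the empirical count
distribution of any real library. Passing the planted-truth tests shows the
statistical machinery is correct at these effect sizes; it does not certify
performance on a particular real compendium, where screen quality, lineage
imbalance and annotation staleness dominate.

Problem sizes used by the test suite and the acceptance script (e.g. 5–20
simulation seeds, 50–100 null replicates, 40–60 cell lines) were chosen as
the smallest panels at which the planted effects are comfortably detected
by design, keeping the whole validation run in minutes on a laptop.

# Known limitations

* Bayes factors inherit the density-ratio scale: nonessential genes score
  strongly negative (≈ −6.5 per guide at the nonessential mode under a
  two-normal model), not near zero; thresholds are calibrated accordingly.
* The strict Bonferroni tier is conservative by construction; biologically
  real but modest correlations land only in the extended tier.
* Hamming-distance off-target matching is guide-versus-guide; it cannot see
  genomic near-matches outside the library.
* The MCL implementation uses dense matrices: fine to a few thousand nodes,
  not for 10^5-node graphs.
* Quantile normalization assumes columns are exchangeable after QC; a
  screen with a genuinely different essentiality spectrum is forced onto
  the common distribution.
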