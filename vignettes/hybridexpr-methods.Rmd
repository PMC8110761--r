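---
title: "Methods: models, thresholds and design choices in hybridexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices in hybridexpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridexpr)
```

# The problem

Interspecific hybrids often misexpress genes relative to their parents, and in
*Drosophila* the extent of misexpression in the male germline tracks the
severity of hybrid sterility. Given gene-level read counts for two parental
lines and their reciprocal hybrids in one or more tissues, `hybridexpr`
answers three questions per tissue and cross direction:

1. which genes are differentially expressed between any two conditions
   (hybrid vs each parent, parent vs parent);
2. what inheritance mode each gene's hybrid expression follows — conserved,
   additive (intermediate), dominant for one parent, or transgressive
   (over/underdominant, i.e. outside the parental range); and
3. whether transgressive genes are biased toward under- or overexpression,
   which gene sets are shared between crosses, and which annotation terms
   they are enriched for.

# Differential expression model

Counts for gene *g* in sample *j* are modelled as negative binomial with mean
$s_j q_{g,c(j)}$ and variance $\mu + \alpha_g \mu^2$, where $s_j$ is a
per-sample size factor, $q_{g,c}$ the condition mean, and $\alpha_g$ the
gene-wise dispersion ($\alpha = 0$ degenerates to Poisson).

**Size factors** are median-of-ratios: the reference is the per-gene
geometric mean across samples, restricted to genes with nonzero counts in
every sample, and $s_j$ is the median across those genes of
$k_{gj}/\mathrm{ref}_g$. Because the reference is recomputed from the data, a
global rescaling of all samples leaves the size factors unchanged (the
factors are identified only up to scale, which cancels in every contrast).
When no gene is nonzero everywhere, the `poscounts`-style fallback uses
per-sample positive counts against a geometric mean over nonzero entries.

**Dispersion** is estimated by method of moments on normalized counts:
per condition $\hat\alpha = (v - m)/m^2$ (sample variance $v$, mean $m$),
pooled across conditions with residual-degree-of-freedom weights and floored
at 0. Two replicates per condition make the gene-wise estimate very noisy, so
it is shrunk toward a fitted mean–dispersion trend $a_0 + a_1/\mu$ (least
squares, coefficients clamped non-negative) by a weighted average with
default weight 0.5. This is deliberately simpler than full empirical-Bayes
shrinkage; the null-simulation tests show the resulting Wald p-values are
close to uniform (Kolmogorov–Smirnov distance < 0.05 at 5,000 genes with two
replicates) and that the twofold + FDR 0.01 call rule keeps the false call
rate well under 2% in an all-conserved world. No equivalence to any specific
published DE engine is claimed — only this distributional calibration.

**Testing.** Condition means are fitted per gene by Fisher scoring with
size-factor offsets and fixed dispersion; the Wald statistic is
$\log_2(q_1/q_2)$ divided by its standard error from the Fisher information,
with a two-sided normal reference. A gene with zero counts in one condition
gets a pseudo-mean floor (default 0.5 normalized counts) so the fold change
stays finite; a gene with zero counts in both is flagged and assigned
$p = 1$. P-values are adjusted by the Benjamini–Hochberg step-up (written
out explicitly, stable under ties), and a gene is called `over`/`under` only
when adjusted $p <$ 0.01 **and** $|\log_2 \mathrm{FC}| > 1$ — the
twofold-change rule appropriate for low-replicate designs.

**Low-count filter.** Before testing, genes with fewer than 10 reads summed
across replicates in *every* condition of the analysed trio are removed.
"Weak everywhere" (rather than "weak anywhere") is the literal reading of
the exclusion rule and keeps condition-specific genes; whether the original
analyses summed per condition or per sample is not documented, so
`filter_low_counts(per = "sample")` exposes the alternative. DEG percentages
are always reported against the per-trio expressed-gene universe.

# Inheritance classification

Each gene yields three calls at the shared thresholds: `c1` (hybrid vs P1),
`c2` (hybrid vs P2), `cp` (P1 vs P2), each in {+, −, 0}. The mapping to
categories is exhaustive over all 27 patterns:

| pattern | category |
|---|---|
| c1 = 0, c2 = 0 | conserved |
| c1 = +, c2 = + | overdominant |
| c1 = −, c2 = − | underdominant |
| c1, c2 opposite signs, cp ≠ 0, sign(cp) = sign(c2) | additive |
| c1 = 0, c2 ≠ 0, cp ≠ 0, sign(cp) = sign(c2) | P1-dominant |
| c2 = 0, c1 ≠ 0, cp ≠ 0, sign(cp) = −sign(c1) | P2-dominant |
| anything else | ambiguous |

Two design choices deserve comment. First, dominance and additivity demand a
*direction-consistent* parental call: "similar to one parent only"
presupposes that the parents differ, and a sign-inconsistent triple (e.g.
hybrid above one parent, below the other, parents not different) is a
threshold artifact, not a biological mode. Second, the residual patterns go
to an explicit `ambiguous` category that is reported separately and never
merged into conserved — classification stays exhaustive and auditable. The
classifier operates on DE calls directly; a "log percentage" transformation
sometimes mentioned in this literature is not defined anywhere we could
verify, so no such transformation is applied.

Reciprocal-cross profiles are compared with Pearson's chi-square on the
2 × k table of category counts (no continuity correction, zero-sum
categories dropped symmetrically). Maternal/paternal dominance is a
relabelling of P1/P2 by cross direction, not a separate algorithm.

# Transgressive sets and the bias test

`over_both`/`under_both` are the genes called over (under) against *both*
parents; by construction they coincide with the over/underdominant classes
of the classifier on the same inputs (a cross-module consistency the tests
enforce). The over/under balance is tested as a one-sample proportion test
against 0.5 in its chi-square form with Yates continuity correction,
$X^2 = \sum (|O - E| - 0.5)^2/E$. The correction is applied *uncapped*: at
exact balance (`n_over = n_under`) this yields the small positive statistic
0.01 rather than `prop.test()`'s hard zero; everywhere else
(|O − E| ≥ 0.5) the two agree exactly. `correct = FALSE` disables the
correction.

# Enrichment

Focal genes are translated to a reference species through a single-valued
ortholog map (partial by design: unmapped genes are reported, mirroring real
ortholog coverage of roughly 76–85%). Per term, the p-value is the
upper-tail hypergeometric probability $P(X \ge k)$ for $k$ study hits among
$n$ mapped study genes, given $K$ annotated genes in a background of $N$ —
the one-sided Fisher test that matches over-representation usage; a
two-sided Fisher variant is available by flag. The background defaults to
the expressed (post-filter) genes with an ortholog, the defensible local
analogue of a platform-wide reference list. BH adjustment is used, consistent
with the DE module. Terms annotating byte-identical gene sets are merged
(exact-duplicate collapse, recorded per row); no semantic/graph-based
redundancy reduction is attempted.

# The synthetic world

`simulate_experiment()` draws, per gene and tissue, a baseline mean from a
log-normal (default meanlog = log 200, sdlog = 1.5, floored at 1 expected
read — a realistic bulk RNA-seq dynamic range chosen once, since no
empirical effect-size distribution is available), then assigns inheritance
modes and condition means, and finally samples NB counts with per-sample
depth factors (default drawn Uniform(0.5, 2)) and dispersion α = 0.05.

The stated world behind the defaults: 11,654 genes, two replicates per
condition, ovary and testis, parental divergence 2 log2 units for diverged
genes, transgressive shift 2 log2 units, and per-tissue category mixtures
that emulate a mildly misregulated ovary (~2% non-conserved) versus a
strongly misregulated testis (~17% non-conserved, dominant inheritance
prominent, 67.5% of transgressive genes underdominant).

A structural point: the two reciprocal hybrids share one pair of parents, so
a gene's parental divergence is a property of the gene, not of the cross.
The generator therefore draws the divergence state once per gene — diverged
genes host the additive/dominant modes, equal-parent genes host
conserved/transgressive modes — and then draws each hybrid's mode
independently within the compatible set. Marginal category frequencies equal
the configured proportions exactly, while reciprocal asymmetry (maternal
effects) can still arise. Additive hybrids sit at the geometric mean of the
parents (the log-scale midpoint, consistent with log2 thresholds);
transgressive hybrids sit `transgressive_shift_log2` beyond the more extreme
parent. One consequence worth knowing: a truly additive gene lies *exactly*
at the twofold threshold from each parent when divergence is 2, so its
recovery through the DE path is near 50% per comparison by construction —
the recovery criteria hold because additive genes are rare in the stated
world, as they are in the real tissues being emulated.

What a green test does **not** establish: the generator has no GC or length
bias, no outlier samples, no correlated genes, no isoform structure and no
allele-specific signal; recovery rates on it bound sanity, not field
performance.

# Numerical choices

* Fisher scoring for group means: 60 iterations max, step clamped to ±5 on
  the log scale, mean bounded in `exp(±30)`; with equal size factors within
  a group the MLE equals the normalized mean exactly, so small fixtures are
  exact.
* BH ties: standard step-up on the sorted vector; stable order, NA passed
  through.
* `bias_test` continuity correction uncapped (see above).
* Chi-square profile comparison refuses all-zero profiles and degenerate
  single-category tables rather than returning NaN; the pipeline logs and
  skips the comparison in that case.
* All pipeline stages are deterministic given their inputs; the only RNG in
  the package is in the two simulators, each seeded from a single integer.

# Known limitations

* Two-group contrasts only; no covariates, batch terms or GLM designs.
* Dispersion shrinkage is a fixed-weight trend average, not empirical Bayes;
  with a single replicate per condition the test degenerates to relying on
  the pooled trend (a warning is emitted).
* Enrichment treats terms as flat labels — no ontology graph propagation.
* The JSON pipeline config replaces a YAML interface because no YAML parser
  is available in the supported dependency set.
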