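---
title: "Models and methods behind gc2mat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gc2mat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gc2mat analyses the silencing of germ-cell genes during *Drosophila*
oocyte specification from four data modalities: bulk RNA-seq of germline
knockdowns, polysome-profiling RNA-seq (polysome vs input fractions),
CAGE 5'-end profiles, and binned CUT&RUN histone-mark signal. This
vignette explains the statistical models, the parameters that matter, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## The negative-binomial count engine

All expression stages share one engine. Counts for gene $g$ in sample $j$
are modelled as

$$y_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g), \qquad
  \log \mu_{gj} = o_j + x_j^\top \beta_g,$$

with variance $\mu + \alpha\mu^2$ and a log link. Designs are one-hot
condition indicators (group-means parameterization, no intercept), which
keeps every coefficient interpretable as a log condition mean and lets the
IRLS update decouple across coefficients.

**Normalization and offsets.** Two estimators are provided.
Median-of-ratios computes, over genes with positive counts in every
sample, the median of each sample's ratios to the gene-wise geometric
mean; these factors carry the samples' relative depth, so the offset is
$o_j = \log f_j$. TMM computes a doubly trimmed (30% on M, 5% on A),
precision-weighted mean of gene-wise log2 ratios against a reference
sample (the one whose scaled upper quartile is closest to the mean),
centred to geometric mean 1; TMM factors are composition corrections on
top of depth, so there $o_j = \log(N_j f_j)$ with $N_j$ the library size.
Conflating the two conventions biases all fold changes by the depth ratio,
which is visible as an excess of spurious calls on one side of a volcano
plot; the package therefore derives the offset from the factor's `method`
tag.

**Dispersion.** Gene-wise dispersions maximize the Cox–Reid adjusted
profile likelihood $\mathrm{APL}_g(\alpha) = \ell_g(\hat\beta_g; \alpha) -
\tfrac12 \log\det(X^\top W X)$ on a 15-point log-spaced grid from $10^{-4}$
to $10$, refined by quadratic interpolation in $\log\alpha$. Shrinkage is
weighted-likelihood empirical Bayes: the shrunk estimate maximizes
$(1-w)\,\mathrm{APL}_g(\alpha) + w\,\overline{\mathrm{APL}}(\alpha)$,
where $\overline{\mathrm{APL}}$ is the ensemble average and
$w = d_0/(d_0 + d_r)$ with prior degrees of freedom $d_0 = 10$ (default)
and residual degrees of freedom $d_r$. With two replicates per condition
this weight is strong (e.g. $w = 10/14$ for the four-condition polysome
design), which is what keeps the likelihood-ratio test close to its
nominal size at such small $n$; the estimate is clamped between the
gene-wise and common maximizers so shrinkage can only interpolate.
$w = 1$ (or `shrinkage_weight = 1`) returns the common dispersion for
every gene.

**Fitting.** IRLS with deviance-based step halving (up to 12 halvings),
relative deviance tolerance $10^{-8}$, at most 100 iterations, linear
predictors capped at $\pm 30$ to keep exponentials finite. One-hot designs
use a fully vectorized update (the Fisher information is diagonal);
general designs (the reparameterized LRT designs) solve one small system
per gene. All-zero genes are flagged degenerate with coefficients at the
lower bound and are never tested; genes that fail to converge are flagged
and retained.

**Testing.** Wald tests use the observed Fisher information at the
optimum: $z = c^\top\hat\beta / \sqrt{c^\top (X^\top W X)^{-1} c}$ with a
two-sided normal p. The likelihood-ratio test reparameterizes the design
with an invertible map whose first row is the contrast (completed
orthonormally), fits the full model and the reduced model with that
coefficient dropped, and refers $2(\ell_1 - \ell_0)$ (floored at 0 against
roundoff) to $\chi^2_1$. Because the full model spans the same column
space, the reported effect equals the Wald estimate of the same contrast —
two routes, one number. BH adjustment excludes filtered genes from the
number of tests.

## Stage-specific rules

**Differential expression.** Genes with fewer than five total reads
across all samples are removed before anything else (so the BH family is
exactly the tested genes; whether the original analyses filtered before or
after normalization is unstated, and filtering first is the conservative
reading). Classification offers two documented conventions — `fold2`
(twofold or higher change, $|\log_2 FC| \ge 1$) and `log2fc2`
($|\log_2 FC| \ge 2$) — because the field uses both; `fold2` is the
default and the mode is recorded in output headers. Each knockdown is
tested independently against the shared control.

**Translational efficiency.** The four conditions are one-hot coded and
the interaction contrast
$(KO_{Poly} - KO_{In}) - (WT_{Poly} - WT_{In})$ is tested by LRT.
Classification uses the raw $p < 0.05$ by default (with the BH column also
emitted and a `use_fdr` switch), and the low-count filter is applied once
to the pooled four-condition table rather than per fraction. A
fraction-wide multiplicative shift of the polysome libraries is absorbed
by the condition means: the interaction estimate is exactly invariant
under Poisson weighting, and invariant up to the precision weighting of
rescaled counts for NB fits — the test suite checks both forms.

**Overlap statistics.** The randomization test redraws each set uniformly
at its observed size from the universe and counts iterations whose k-way
intersection reaches the observed one (ties count against significance),
reporting the add-one estimate $(x+1)/(n+1)$ so p can never be zero. The
intersection of independent uniform fixed-size subsets is a chain of
hypergeometric draws — the overlap of each new set with the running
intersection — and the implementation samples that chain directly, which
is distributionally identical to materializing the sets and makes $10^6$
iterations run in under a second; tests verify it against brute-force
enumeration of all subsets on a tiny universe. The default universe is
the filtered gene set of the relevant comparison (the original
randomization universe is unstated), and the redraws preserve set sizes
only, with no expression or length matching. The hypergeometric test is
the exact upper tail $P(X \ge k)$.

**Stage signatures.** The NB regression treats genes as the observational
units and the library group as the sole predictor, mirroring how average
signature expression is compared between groups; TPM is rounded to the
nearest integer because NB likelihoods need counts (the original
parameterization and pseudocount are unstated — rounding is logged as this
package's choice). The fit uses `MASS::glm.nb`, falling back to Poisson if
$\theta$ estimation fails. Profile classification calls a gene
germ-cell-like when mean TPM over GSC/CB/cyst is at least $r = 2$ times
the whole-ovary TPM (configurable), maternal-like for the reverse, and
flat otherwise — the threshold formalizes a qualitative pattern.

**TOP motifs.** The TSS is the single modal CAGE position — no tag
clustering — with ties broken toward the 5'-most position (smallest
coordinate on +, largest on −), which favours the longest 5'UTR and is the
conservative choice for TOP detection. A terminus is TOP when its first
base is C/U and the initial pyrimidine run (counting the first base)
reaches `min_run = 5`; no minimum is stated in the motif's verbal
definition, and the C/U-plus-four-downstream-pyrimidines convention from
the TOP literature motivates the default. Classification is invariant to
case and T/U.

**Chromatin marks.** RPKM is $10^9 x / (N w)$ for bin value $x$, total
reads $N$, bin width $w$ bp. Binarization calls a bin bound when its count
is in the extreme Poisson upper tail ($P < 10^{-4}$) of the genome-wide
mean rate — a deliberate simplification standing in for multi-state
chromatin segmentation, sufficient for gain/loss semantics but not for
state-for-state comparisons. Promoters default to TSS ± 500 bp
(strand-aware; "promoter-associated" has no published definition here) and
quantification is overlap-weighted over bins, which commutes with RPKM
scaling. Differential calls use $\log_2((KD + c)/(WT + c))$ with
threshold 1 and require the losing (gaining) condition to exceed the
genome-wide median background; the pseudocount $c$ is the RPKM equivalent
of one read per bin, the classic add-one-read damping — a literal 1-RPKM
constant would be negligible at realistic coverage and leave background
ratios undamped. The redistribution index is
$\min(lost, gained)/\max(lost, gained)$, 0 when either is 0. Meta-region
matrices use the scale-regions layout: fixed-width flank bins (3 kb
default) around a body rescaled to 100 bins; regions shorter than one bin
collapse to a single bin with a warning. Coordinates are 0-based
half-open throughout, converted only at I/O boundaries.

## The synthetic-data generators

Each generator is a pure function of its configuration (seed included) and
returns the dataset together with a ground-truth table sufficient to score
every downstream stage. Defaults mirror the study designs: two biological
replicates per condition, NB counts with dispersion 0.05 (typical for bulk
RNA-seq), log-normal baseline means (median 100 counts), a 100-gene
germ-cell cohort up $2^2$-fold in knockdowns with a 50-gene maternal
cohort down, a 100-gene translational cohort at $\pm 2$ log2 units with a
fraction-wide polysome scaling of 1.5 to exercise normalization, an
8-fold stage gradient, TOP termini with runs of 5–14 nt and CAGE profiles
multinomially peaked at the planted TSS, and Poisson mark tracks
(background rate 5 per 200-bp bin, promoter peaks +45) with a 4-fold
knockdown reduction over a loss cohort and knockdown-only peaks over a
gain cohort on a 2-Mb toy chromosome carrying ~20 TADs.

The generators emulate the statistical structure the analyses assume —
NB sampling noise, composition effects, fraction-wide scaling, peaked
5'-end profiles, promoter-shaped mark enrichment. They do not emulate
GC or length bias, alignment and quantification artifacts, correlated
dispersion across genes, CAGE tag clusters with multiple TSSs, spike-in
calibration, or fragment-size structure in CUT&RUN. Passing tests
therefore certify the statistical machinery under its stated model, not
robustness to upstream artifacts in real libraries.

## Problem sizes and reproducibility

The test suite and the acceptance script run at the scale of the designs
they check: 2000 genes for calibration and recovery simulations, $10^6$
randomization iterations, a 10,000-bin toy genome for the chromatin
module, and two full pipeline runs for the determinism check — all within
a couple of minutes on one CPU. Every stochastic stage takes an explicit
seed; generators save and restore the global RNG state, and the pipeline
writes md5 checksums of all stage outputs so a rerun with the same
configuration can be verified byte for byte.

## Known limitations

* Wald and LRT p-values at $n = 2$ per condition lean on empirical-Bayes
  dispersion shrinkage; with very few genes the ensemble APL is noisy and
  calibration degrades.
* The engine fits MLE fold changes; no shrinkage estimator for effect
  sizes is provided, so volcano plots show unmoderated log2FCs.
* Quasi-likelihood F-tests, trended dispersions, count-outlier handling,
  and independent filtering are out of scope.
* The randomization test does not match redrawn sets on expression or
  length, so it tests uniform exchangeability of gene labels within the
  chosen universe.
* The chromatin gain/loss caller is a thresholded ratio, not a count-level
  test; its error rates are controlled by the background rule and
  pseudocount rather than by a sampling model.
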