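---
title: "Transcriptome-wide association from summary-level eQTL data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-wide association from summary-level eQTL data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumtwas)
```

## The problem

A transcriptome-wide association study (TWAS) tests whether the genetically
regulated component of a gene's expression is associated with a trait. The
standard two-stage design first learns per-gene SNP weights
$\hat{\mathbf w}$ from an expression reference panel, then combines those
weights with GWAS summary statistics. The limiting factor is usually the
expression panel: individual-level cohorts with measured expression are
small (hundreds of samples), while *summary-level* cis-eQTL releases pool
tens of thousands (the largest whole-blood meta-analysis covers 31,684
samples). `sumtwas` trains the weights directly from such summary
statistics, so the large-N resource becomes usable for prediction.

## Expression prediction from marginal statistics

For standardized genotypes $\mathbf X$ ($N \times p$ cis-SNPs within 1 Mb
of the gene body) and covariate-residualized expression $\mathbf Y$, the
penalized least-squares objective

$$ f(\mathbf w) = \frac{(\mathbf Y-\mathbf X\mathbf w)'(\mathbf Y-\mathbf X\mathbf w)}{N} + J_\lambda(\mathbf w) $$

depends on the data only through the marginal correlations
$\mathbf r = \mathbf X'\mathbf Y/N$ and the LD matrix
$\mathbf R = \mathbf X'\mathbf X/N$. Neither requires individual-level
data: $r_j$ is recovered from the reported z-score and per-SNP sample size
as

$$ \tilde r_j = \frac{Z_j}{\sqrt{N_j - 1 + Z_j^2}}, $$

(each SNP's own meta-analysis $N_j$, never the largest cohort size), and
$\mathbf R$ from a reference genotype panel. The working objective is

$$ \tilde f(\mathbf w) = \mathbf w'\tilde{\mathbf R}\mathbf w - 2\,\mathbf w'\tilde{\mathbf r} + \theta\,\mathbf w'\mathbf w + J_\lambda(\mathbf w), $$

with an explicit ridge $\theta \ge 0$ that guarantees a unique minimizer
when $\tilde{\mathbf R}$ is rank-deficient (always true when the panel is
smaller than the SNP count).

### A note on the penalty scale

The LASSO coordinate update used throughout soft-thresholds the partial
residual $z_j = \tilde r_j - \sum_{l\neq j}\tilde R_{jl}\hat w_l$ at
$\lambda$ and divides by $1+\theta$. For that update to be the *exact*
coordinate minimizer of the quadratic above, the penalty must enter as
$2J_\lambda$ (equivalently: halve the quadratic, the glmnet convention).
`sq_objective()` therefore evaluates
$\mathbf w'\tilde{\mathbf R}\mathbf w - 2\mathbf w'\tilde{\mathbf r} +
\theta \mathbf w'\mathbf w + 2J_\lambda(\mathbf w)$, which makes the
objective provably non-increasing under every sweep — the property the
test suite asserts. On this scale the summary-based LASSO with in-sample
$\mathbf r,\mathbf R$ coincides with `glmnet` at the *same* $\lambda$
values, which the suite uses as an independent oracle.

### Penalty families

Five families are fitted per gene; each coordinate update is the exact
univariate minimizer, and all reduce to the LASSO rule when their extra
parameters vanish:

| family | update for partial residual $z$ | defaults |
|---|---|---|
| LASSO | $S(z,\lambda)/(1+\theta)$ | — |
| elastic net | $S(z,\alpha\lambda)/(1+\theta+(1-\alpha)\lambda)$ | $\alpha=0.5$ |
| MCP | $S(z,\lambda)/(1+\theta-1/\gamma)$ if $|z|\le\gamma\lambda(1+\theta)$, else $z/(1+\theta)$ | $\gamma=3$ |
| SCAD | three-piece rule with breakpoints $\lambda(2+\theta)$ and $\gamma\lambda(1+\theta)$ | $\gamma=3.7$ |
| MNet | MCP thresholding with the elastic-net ridge in the denominator | $\gamma=3,\ \alpha=0.5$ |

$S(z,t)$ is the soft-threshold operator. MCP/MNet require $\gamma>1$, SCAD
$\gamma>2$; the implementation enforces these. Concave families are only
guaranteed a local minimum; warm starts along the $\lambda$ path from
$\mathbf w = \mathbf 0$ (the convention here) give deterministic,
reproducible solutions.

### Tuning grids

The package defaults are a 50-point $\lambda$ path log-spaced from
$\lambda_{\max}=\max_j |\tilde r_j|$ (scaled by $1/\alpha$ for mixed
penalties) down to $0.01\,\lambda_{\max}$, ridge grid
$\theta \in \{0, 0.1, 0.2, 0.4, 0.8\}$, and $\alpha = 0.5$. Convergence is
declared when no coordinate moves more than $10^{-5}$ in a sweep (at most
1,000 sweeps). Grid points are scored by the squared correlation between
predicted and observed expression on an individual-level tuning panel;
ties go to the sparser model, then the larger $\lambda$. Predictions with
zero variance (the all-zero model) score 0, never `NaN`.

The simulation experiments (below) default to a lighter grid — 25
$\lambda$ points down to $0.02\,\lambda_{\max}$ and
$\theta\in\{0,0.1,0.4\}$ — chosen after verifying that the tuning optimum
sits at $\lambda/\lambda_{\max}\approx 0.04$–$0.15$ and that $\theta$
barely moves the attainable accuracy, so replicated experiments stay
affordable.

## The shrinkage LD estimator

Raw sample LD from a modest reference panel is noisy and indefinite. The
estimator used here multiplies each off-diagonal entry by
$\exp(-2N_e c_{ij}/m)$, where $c_{ij}$ is the genetic distance in
centimorgans, $N_e = 11{,}400$ the effective population size and $m = 183$
the genetic-map sample size; entries whose factor falls below
$c = 10^{-3}$ become exactly zero. At these defaults the factor at 0.01 cM
is $\approx 0.288$ and entries vanish beyond
$m\ln(1/c)/(2N_e) \approx 0.0554$ cM. Genetic positions are linearly
interpolated from a bp-to-cM map, clamped at the map ends; the map's exact
interpolation scheme is a free choice and linear interpolation was chosen
for determinism. Shrinkage never increases a magnitude, preserves symmetry
and the unit diagonal, and in every fixture the shrunk matrix plus any
$\theta > 0$ ridge is positive definite.

## Model admission

Models are tuned on one panel and *validated* on a disjoint one; a model is
admitted when its validation $R^2 \ge 0.005$ (boundary included). The
threshold is deliberately below the conventional 0.01: under the null, the
$R^2$ of a $p$-regressor model on $n$ samples follows
$\mathrm{Beta}\!\big((p-1)/2,\,(n-p)/2\big)$ (Cramér), and with the median
admitted model size $p = 34$ at $n = 31{,}684$ the $(1-\alpha)$ quantile at
$\alpha = 0.05/16{,}884$ is $\approx 0.00263$ — so 0.005 is conservative
even before accounting for regularization. `cramer_r2_threshold()`
computes this quantile.

## Association testing

With GWAS z-scores $\mathbf Z$ over a model's SNPs and their LD
$\mathbf V$, the burden-type statistic is
$\tilde Z = \mathbf Z\hat{\mathbf w}/\sqrt{\hat{\mathbf w}'\mathbf V\hat{\mathbf w}}$
with a two-sided normal p-value; it is invariant to positive rescaling of
the weights. $\mathbf V$ defaults to the same shrinkage estimator as
training (a flag restores raw sample LD) — the shrunk form also guards
against indefinite $\mathbf V$ making
$\hat{\mathbf w}'\mathbf V\hat{\mathbf w} \le 0$. When individual-level
GWAS data are available, `glm_association()` fits
$f(E[P]) = \alpha C + \beta\,\mathbf X\hat{\mathbf w}$ under an identity or
logit link; the two routes agree on matched data, which the suite checks.

Per-gene p-values from the admitted models are combined with the Cauchy
combination statistic
$T = \sum_j \tilde R_j^2 \tan\{(0.5-p_j)\pi\}$, weights
$\tilde R_j^2 = R_j^2/\sum_k R_k^2$ (the *validation* $R^2$ — it is the
externally checked quantity), and combined p-value
$0.5 - \arctan(T)/\pi$. The combination is exact for one model, invariant
to rescaling all weights, and needs no estimate of the dependence between
models. For $p_j < 10^{-15}$ the term is replaced by the tail-equivalent
$\tilde R_j^2/(p_j\pi)$, and a huge $T$ maps back through $1/(\pi T)$;
both guards are exact in the regime where they activate. One model per
penalty family enters the combination. Association direction is the
majority sign of the per-model $\tilde Z$; an exact tie is reported as
`unknown`. Bonferroni correction uses the number of genes actually tested
(at least one admitted model and one overlapping GWAS SNP), which the scan
logs.

## The synthetic-data generator

The simulation framework emulates the full data flow without any external
download. Genotypes come from a latent-Gaussian threshold model: each of
two haplotypes is multivariate normal with block-AR(1) correlation
(blocks of 20 SNPs, per-block $\rho \sim U(0.2, 0.9)$), thresholded at the
normal quantile of a per-SNP MAF drawn from $U(0.01, 0.5)$, and summed.
SNPs sit 2.4 kb apart (877 SNPs span about 2.1 Mb) on a constant 1 cM/Mb
map — the genome-wide human average. Expression is
$\mathbf E = \mathbf X\mathbf w + \epsilon_e$ with
$\lceil p_{\text{causal}}\,p \rceil$ causal SNPs, normal effects rescaled
so the realized $\mathrm{var}(\mathbf X\mathbf w)$ equals $h_e^2$ exactly,
and $\epsilon_e \sim N(0, 1-h_e^2)$; the phenotype is
$\mathbf Y = \beta\mathbf E + \epsilon_p$ with $\beta$ rescaled so
$\mathrm{var}(\beta\mathbf E) = h_p^2$ (an alternative convention that
scales the *genetic* component is exposed as `hp2_mode = "genetic"`,
because published power figures are sensitive to the choice and the
definition in circulation — variance of phenotype explained by expression
— matches the default). Summary statistics are derived the same way real
releases are: per-SNP simple regression z-scores on standardized
genotypes, with $N_j = n$ for every SNP.

What the generator does *not* reproduce is the redundancy of real imputed
genotype data. Dichotomizing a latent Gaussian caps the genotype-level
correlation at the arcsine-transformed value ($\tfrac{2}{\pi}\arcsin\rho$,
e.g. $1/3$ at $\rho = 0.5$), so even the $\rho = 0.9$ blocks carry far
fewer near-duplicate SNPs than a dense imputed region, where adjacent
$r^2 > 0.95$ is routine. That redundancy is precisely what lets a
penalized fit on tens of thousands of samples recover essentially the full
heritable signal in real data. Consequently the experiments here recover
roughly 75–80% of the expression-heritability ceiling at
$h_e^2 = 0.05$ and less in the low-heritability regimes — the *relative*
behaviour (summary-based fits matching individual-level fits to within
0.002, accuracy and power increasing with training size, correct
heritability ordering, calibrated type-I error) is faithful, while
absolute accuracy levels sit below those reported for real genotype
panels. Tests that pass on this generator therefore certify the machinery
and its invariances, not absolute real-data accuracy.

In small simulated cohorts a rare SNP (MAF near 0.01) can be monomorphic;
experiment cohorts leave such columns at zero (no information) rather than
failing, whereas the user-facing `standardize_genotypes()` treats a
monomorphic SNP as an error, naming it.

## Experiments and their scale

* `run_accuracy_experiment()` — per replicate: draw a gene (fresh LD model
  and causal set), train from the training cohort's derived summary
  statistics against shrunk in-cohort LD, tune on $n = 369$, report the
  selected model's squared correlation on $n = 10{,}000$ held-out samples.
  `include_oracle = TRUE` fits the individual-level arm (exact in-sample
  marginal correlations, raw LD) — mathematically the individual-level
  penalized fit — in parallel.
* `run_power_experiment()` — adds an independent GWAS cohort, derives GWAS
  z-scores, runs burden + Cauchy over admitted models, and counts
  rejections at $0.05/20{,}000 = 2.5\times10^{-6}$; replicates with no
  admitted model are non-rejections.
* `run_type1_experiment()` — reuses trained weight sets across many null
  GWAS replicates ($\beta = 0$) and reports empirical rejection rates.

Defaults follow the study conditions (877 SNPs; cohorts of
31,684 / 369 / 10,000). One full-size training replicate costs roughly half
a minute on a single core, so the shipped test suite runs 6 replicates for
the full-N accuracy comparison, 6 per low-heritability setting, 4 per
training-size point for the power curve, and 8 weight sets × 700 nulls
(5,600 replicates) for type-I error — sizes chosen so each check's
Monte-Carlo standard error is comfortably inside the tolerance it asserts.
Replicate $r$ of a run with seed $s$ uses the derived stream
$s + 13r$, so experiments are bit-reproducible and individual replicates
can be re-run in isolation.

## Numerical and design choices

* Coordinates are 1-based closed intervals (bim/VCF convention); cis-window
  boundary SNPs are kept; `MAF < maf_min` is removed, the boundary kept.
* Indels, multi-allelic records and strand-ambiguous (A/T, C/G) SNPs are
  dropped during filtering/harmonization; allele pairs that match the panel
  neither directly nor swapped are dropped and counted rather than
  strand-corrected, since labels alone cannot resolve a flip.
* Missing reference genotypes are mean-imputed per SNP before
  standardization.
* Zeroed LD entries are stored as exact zeros in a dense matrix; cis-SNP
  counts (hundreds to a few thousand) do not justify sparse storage.
* The genetic map is interpolated per SNP position; distances are absolute
  cM differences.
* $R^2$ against a zero-variance prediction is defined as 0.
* All thresholds (admission $R^2$, MAF, window, shrinkage constants,
  significance levels) are configuration, with the defaults above.

## Limitations

* Single-tissue only; no cross-tissue borrowing, fine-mapping,
  colocalization or conditional analysis.
* No BGEN/dosage input and no liftover; PLINK bed/bim/fam and VCF only.
* The Cauchy combination's uniformity is approximate for correlated,
  non-extreme p-values; its accuracy is best exactly where it matters, in
  the far tail.
* Burden tests with a shrunk $\mathbf V$ trade a small calibration bias
  (the suite measures type-I ≈ 0.057 at $\alpha = 0.05$ over 5,600 nulls,
  within three binomial SEs) for guaranteed positive-definiteness.
* Synthetic-genotype caveats above: absolute accuracy levels are not
  comparable with real imputed panels.
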