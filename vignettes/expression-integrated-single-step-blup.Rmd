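---
title: "Expression-integrated single-step BLUP: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-integrated single-step BLUP: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssexp)
```

## The problem

Genomic prediction estimates an individual's genetic merit from genome-wide
markers. Transcriptome data sit between genotype and phenotype and can carry
signal that markers dilute, but expression is usually measured on far fewer
individuals than are genotyped or pedigreed — in a typical F2 resource
population, a few dozen expression profiles against a few hundred genotyped
animals. `ssexp` addresses that coverage asymmetry with the single-step idea:
embed the relationship matrix of the data-rich few into the relationship
matrix of the many, and fit one joint mixed model.

## Relationship matrices

Four base matrices describe genetic similarity from different data layers:

* **A** (pedigree): the numerator relationship matrix, computed by the
  tabular method — founders have $a_{ii}=1$, and in an order where parents
  precede offspring, $a_{ij} = \tfrac12(a_{j,s(i)} + a_{j,d(i)})$ and
  $a_{ii} = 1 + \tfrac12 a_{s(i),d(i)}$. Inbreeding emerges from the
  recursion; unknown parents contribute zero. We verify it against an
  independent gene-dropping estimate of expected identity-by-descent.
* **G** (genomic additive): $G = M_G M_G^\top / \sum_i 2p_i(1-p_i)$, where
  the column for marker $i$ codes genotypes aa/Aa/AA as
  $-2p_i,\,1-2p_i,\,2-2p_i$ and $p_i$ is the counted-allele frequency in all
  genotyped individuals. Monomorphic markers contribute nothing and are
  logged, not silently absorbed.
* **D** (genomic dominance): genotypic coding
  $(-2p_{AA}p_{Aa},\ 4p_{AA}p_{aa},\ -2p_{aa}p_{Aa})/c$ with
  $c = p_{AA}+p_{aa}-(p_{AA}-p_{aa})^2$, normalized by
  $\mathrm{tr}(M_D M_D^\top)/n$ so that $\mathrm{tr}(D)=n$. Markers with
  $c \le 10^{-12}$ have undefined codes (0/0); they are skipped and excluded
  from the trace normalization rather than being patched.
* **E** (transcriptomic): $E = RR^\top/r$ with gene columns centered to mean
  zero. "Standardized" is ambiguous in much of the literature; the default
  here is center-only, with unit-variance scaling behind an explicit flag,
  because the two choices weight high-variance genes very differently.

Genotype QC precedes G and D: markers failing call rate (< 0.95), then —
after optional naive rounded-mean imputation — markers failing MAF (< 0.01)
are removed, each counted once at its first failing stage.

Allele orientation is fixed by the reader (first ALT for VCF, the
lexicographically smaller allele for PLINK text) and recorded per marker;
G and D are invariant to a consistent flip, which the test suite checks
rather than assumes.

## The single-step combiner

Let subset 2 be the individuals with the richer layer $k$, subset 1 the
rest, and $V$ the full-coverage matrix with blocks $V_{11}, V_{12}, V_{21},
V_{22}$. Because $K$ and $V_{22}$ are on different scales, $K$ is first
affinely adjusted, $K^* = \alpha K + \beta$, with $(\alpha,\beta)$ solving

$$\mathrm{Avg(diag}K)\,\alpha + \beta = \mathrm{Avg(diag}V_{22}),\qquad
  \mathrm{Avg(offdiag}K)\,\alpha + \beta = \mathrm{Avg(offdiag}V_{22}),$$

then blended with the matching block, $K_w = (1-w)K^* + wV_{22}$, where the
weighting factor $w \in [0,1]$ represents the fraction of genetic variation
the richer layer does not capture. The combined matrix is

$$H_{11} = V_{11} + V_{12}V_{22}^{-1}(K_w - V_{22})V_{22}^{-1}V_{21},\quad
  H_{12} = V_{12}V_{22}^{-1}K_w,\quad H_{22} = K_w.$$

Useful identities — at $w=1$, $H = V$; with subset 1 empty, $H = K_w$ —
hold to machine precision and are asserted in tests, as is agreement with a
brute-force transcription of the block formula using explicit inverses.

Numerical choices worth stating:

* The scale-adjustment system is singular when $K$'s diagonal and
  off-diagonal averages coincide (e.g. an all-ones matrix). The fallback
  keeps the diagonal scale ($\alpha$ from the diagonal equation, $\beta=0$)
  and warns — silent repair would hide a degenerate input.
* $V_{22}$ must be invertible; a condition-number gate (default $10^{12}$)
  raises an error naming the remedies (raise $w$, pass a ridge, or repair
  $V$) instead of returning garbage. The ridge is off by default because $w$
  is the conditioning device the method itself provides, and $w$ does not
  enter $V_{22}$.
* $H$ is symmetrized as $(H+H^\top)/2$ on output; the formula is symmetric
  in exact arithmetic but its off-diagonal blocks are computed
  asymmetrically.

**Triple integration.** For expression + genotype + pedigree the package
composes the combiner twice: $H_{GA}$ embeds G (genotyped subset) into A
(everyone), and the final matrix embeds E (expression subset) into
$H_{GA}$. This order — expression outermost — follows the coverage nesting
(expression $\subset$ genotyped $\subset$ pedigree): each embedding step
requires the inner matrix's subset to sit inside the outer matrix's
universe. The same $w$ is applied at both levels by default, matching a
single-$w$ sweep; separate `w_inner` / `w_outer` are exposed because the
composition order and per-level weighting are genuinely open choices, and a
user bracketing them should not have to fork the code.

## The mixed model and AI-REML

All models share the form

$$y = Xb + Za + Wd + e,\qquad a \sim N(0, K_a\sigma^2_a),\quad
  d \sim N(0, K_D\sigma^2_d),\quad e \sim N(0, I\sigma^2_e),$$

with fixed effects intercept, sex and birth year (reference-level coding;
single-level covariates dropped). $K_a$ is whichever of A, G, or a
single-step H the model names; the dominance matrix is always D. In an F2
population both additive and dominance variation segregate widely, which is
why the dominance term is kept in every model rather than treated as an
option.

Variance components are estimated by average-information REML: score
$s_i = -\tfrac12[\mathrm{tr}(PV_i) - y^\top PV_iPy]$, update via the AI
matrix $AI_{ij} = \tfrac12 y^\top PV_iPV_jPy$. Three safeguards make the
optimizer boring in the good sense:

* **Step halving**: any proposal that lowers the REML log-likelihood is
  halved toward the current point, so accepted iterations are monotone (the
  test suite asserts this on every fit it runs).
* **Active-set steps at the boundary**: when the AI step drives a component
  negative, that component is pinned at the clamp ($10^{-8}\,\mathrm{var}(y)$)
  and a reduced AI step is taken in the rest — this is what prevents the
  slow geometric crawl that a pure EM fallback produces when, say, the
  dominance component is truly near zero.
* **EM-style multiplicative fallback** when even the reduced system fails.

Convergence requires both a log-likelihood change below `tol` ($10^{-6}$)
and a relative parameter change below `100 * tol`. A singular AI matrix at
convergence with more than one free component is reported as a
non-identifiability error (the canonical case: $K_a$ and $K_D$ both
identity), with its condition number — not papered over.

BLUP solutions use the inverse-free form $\hat b = (X^\top V^{-1}X)^{-1}
X^\top V^{-1}y$, $\hat a = \sigma^2_a K_a Z^\top Py$: because $\hat a$ runs
over every individual in $K_a$'s index, record-less individuals (the
validation set, ungenotyped relatives) get predictions through the
off-diagonal blocks of $K_a$ with no extra machinery. The GBLUP/SNP-BLUP
duality (predictions equal ridge-penalized marker-effect predictions) is
checked against an independent mixed-model-equations solve.

## Phenotype transformation

Small-sample phenotypes are often skewed, and some traits take negative
values, so the package implements the negative-allowed Box–Cox family
$z = \tfrac12(y + \sqrt{y^2+\gamma^2})$, $y(\lambda,\gamma) = (z^\lambda -
1)/\lambda$ (log branch at $\lambda = 0$; $|\lambda| < 10^{-8}$ snaps to it
to avoid cancellation). Parameters are estimated by maximizing the
normal-theory profile likelihood including the Jacobian term, over a grid
($\lambda \in [-2,2]$ step 0.05, $\gamma$ log-spaced against the spread of
$y$, plus $\gamma = 0$ when all values are positive) with Nelder–Mead
refinement. The transform is fitted once per trait on the full vector
before cross-validation — mirroring the usual preprocessing order — which
is a mild, documented information leak; a strict per-fold protocol can be
had by calling `transform_phenotypes()` inside a fold loop instead.

## Cross-validation and the w-sweep

`cross_validate()` runs replicated k-fold CV (default 10 × 10): per
replicate, the phenotyped individuals are shuffled with a stream derived
from (seed, replicate) and dealt into folds whose sizes differ by at most
one. Per fold, variance components are re-estimated on training records
only — the leakage-free choice, since nothing guarantees components
estimated on all data would not flatter the validation fold. Relationship
matrices are built once per (model, w), outside the fold loop, because they
do not depend on phenotypes.

Accuracy is the Pearson correlation between the predicted genetic value
$\hat a + \hat d$ of validation individuals and their fixed-effect-adjusted
phenotype $y - X\hat b$ (training-fold $\hat b$). The literature is not
uniform on this statistic — $\hat a$ alone, raw phenotypes, and
$\sqrt{h^2}$-scaled versions all appear — so the alternatives are exposed
through `metric =`, letting a user bracket an unspecified choice.
`sweep_w()` sweeps $w$ from 0 to 1 (default step 0.05) and reports the
per-model argmax, breaking exact ties toward the smaller $w$ (smaller $w$
trusts the richer data layer more; ties should not drift toward the
baseline).

## The simulator

`simulate_population()` generates the ground truth everything else is
tested against: two founder breeds with mirrored allele-frequency spectra
(drawn from a scaled Beta, so the F2 segregates strongly at many loci — the
structure that makes dominance estimable), Mendelian gene-dropping through
F1 to F2 at unlinked loci, additive and dominance effects at a QTL subset,
and gene expression built as sparse linear combinations of "mediated" QTL
genotypes plus independent noise, so a configurable share of the additive
signal flows through the transcriptome. Phenotype = mean + sex + birth-year
+ additive + dominance + residual.

Effects are rescaled post hoc so *realized* variance components equal the
configured targets exactly, giving recovery tests exact truths rather than
expectations. Defaults mirror an F2 resource population: 393 F2
individuals, all genotyped, about 75% phenotyped, about 11% with
expression; variance fractions 0.3/0.1/0.6 (a moderately heritable complex
trait); half the additive signal mediated by expression. Marker and gene
counts default to 2000 and 500 — deliberately below chip scale, which
changes nothing structural, only the density of neutral markers.

What the simulator does **not** emulate: linkage and LD decay along
chromosomes (loci are unlinked), selection, tissue- or time-specific
expression programs, array normalization artifacts, and genotyping error.
Tests passing on these simulations therefore certify the algebra, the
estimation machinery and the protocol plumbing — not the field performance
of any model on real data.

## Problem sizes used in the checks

The automated checks run at deliberately modest sizes chosen to exercise
every code path with known truths: brute-force H-matrix comparisons up to
n = 50; variance-component recovery on n = 400 with 50 replicates; the
directional experiment (expression-integrated single-step vs pedigree and
genomic baselines) on ten simulated populations of 160 F2 individuals with
35% expression coverage and 90% of the additive signal mediated, scored by
a sign test; the CV-null check over six independent phenotype permutations.
One permutation's fold accuracies are mutually correlated — the same
permuted vector aligns by chance with the relationship structure in every
fold — so the null mean is estimated across permutations, not within one.

## Known limitations

* Dense algebra throughout; appropriate for populations up to a few
  thousand, not for national evaluations (no sparse/APY inverse).
* Single trait, single record per individual; no repeated measures or
  multi-trait covariance.
* Dominance predictions exist only for individuals in $K_D$ (genotyped);
  others contribute zero dominance to predicted genetic values.
* The accuracy statistic and the EGA composition order are field
  conventions chosen here, not universal standards; both are configurable.
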