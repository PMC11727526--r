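# ssexp — expression-integrated single-step BLUP

`ssexp` is an R toolkit for genomic prediction that combines pedigree,
genotype and gene-expression data in one linear mixed model. It is aimed at
quantitative geneticists working with resource populations (e.g. two-breed
F2 crosses) where expression is measured on far fewer individuals than are
genotyped or pedigreed, and the question is whether that small
transcriptome layer can still lift prediction accuracy for everyone.

## The method in brief

Genetic covariance between individuals is described by relationship
matrices: pedigree **A** (tabular numerator relationship), genomic additive
**G** = M<sub>G</sub>M<sub>G</sub>ᵀ / Σ 2pᵢ(1−pᵢ), genomic dominance **D**
(genotypic-frequency coding, normalized so tr(D) = n), and transcriptomic
**E** = RRᵀ/r from column-centered expression. A limited-coverage matrix K
(over the individuals with the richer layer) is embedded into a
full-coverage matrix V by the single-step H matrix:

> K\* = αK + β  (α, β equalize the average diagonal and off-diagonal with V₂₂)
>
> K_w = (1−w) K\* + w V₂₂,  w ∈ [0, 1]
>
> H₁₁ = V₁₁ + V₁₂V₂₂⁻¹(K_w − V₂₂)V₂₂⁻¹V₂₁, H₁₂ = V₁₂V₂₂⁻¹K_w, H₂₂ = K_w

Triple integration (E + G + A) composes this twice: G into A, then E into
the result. Each model fits

> y = Xb + Za + Wd + e,  a ~ N(0, K_a σ²_a), d ~ N(0, K_D σ²_d), e ~ N(0, I σ²_e)

with variance components estimated by average-information REML, and
prediction accuracy evaluated by replicated k-fold cross-validation over a
sweep of w. A negative-allowed Box–Cox transform (z = ½(y + √(y² + γ²)))
handles skewed traits with negative values, and a population simulator with
known ground truth (gene-dropped F2 genotypes, genotype-coupled expression)
makes the whole pipeline testable offline.

## Worked example

Simulate an F2 population in which 90% of the additive signal flows through
the transcriptome but only 30% of individuals have expression data, then
compare pedigree, genomic and expression-integrated single-step models:

```r
library(ssexp)

sim <- simulate_population(sim_config(
  n_f2 = 200, n_f1 = 30, m_markers = 500, r_genes = 100, n_qtl = 25,
  var_additive = 0.45, var_dominance = 0.05, var_residual = 0.5,
  prop_additive_mediated = 0.9, expression_noise_sd = 0.5,
  frac_expressed = 0.3, frac_phenotyped = 1, seed = 42))
sim <- prepare_matrices(sim)   # QC + A, G, D, E

fit <- fit_blup(sim, "trait1", kind = "EGA", w = 0.25)
glance(fit)
#> # A tibble: 1 × 8
#>   logLik sigma2_additive sigma2_dominance sigma2_residual h2_narrow n_records
#>    <dbl>           <dbl>            <dbl>           <dbl>     <dbl>     <int>
#> 1  -94.8           0.364            0.115           0.519     0.365       200

plan <- cv_plan(n_folds = 5, n_replicates = 2, seed = 42, w_grid = c(0, 0.25, 0.5))
sw <- sweep_w(sim, "trait1", kinds = c("A", "G", "EGA"), plan = plan)
attr(sw, "best")
#> # A tibble: 3 × 7
#>   trait  model           w mean_acc sd_acc n_folds n_failed
#>   <chr>  <chr>       <dbl>    <dbl>  <dbl>   <int>    <int>
#> 1 trait1 ABLUP_D     NA       0.129  0.152      10        0
#> 2 trait1 GBLUP_D     NA       0.186  0.164      10        0
#> 3 trait1 ssEGABLUP_D  0.25    0.306  0.142      10        0
```

The fit recovers the simulated variance components (true values 0.45 /
0.05 / 0.5 on this data's scale), and cross-validated accuracy of the
expression-integrated single-step model (0.31 at its best w) clearly beats
the pedigree (0.13) and genomic (0.19) baselines — the expected behaviour
when expression mediates most of the genetic signal and the H matrix
propagates it to individuals without expression data. `autoplot(sw)` draws
the accuracy-versus-w figure.

A thin command-line front end over the same functions lives at
`inst/cli/ssexp.R` (subcommands `simulate`, `kinship`, `hmatrix`,
`transform`, `fit`, `cv`).

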