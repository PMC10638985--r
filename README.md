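# mdcfa — modeling missing data in factor analysis of binary items

`mdcfa` implements the *missing data latent variable* approach to
confirmatory factor analysis (CFA) of binary items under planned missing
data designs, with tetrachoric correlations as input. Instead of imputing
what is missing, an extra orthogonal factor is added to the measurement
model to absorb the systematic variation that structured missingness
creates, so that the fit of the substantive model can be judged as if the
data were complete.

## The model

The customary congeneric (one-factor) model for a centered vector of p
manifest variables is

    x = λ_attribute ξ_attribute + δ .

When some columns of a data set carry planned missingness and missing
responses are replaced by zeros (the policy that tetrachoric software for
complete data forces), the marginal probability of a correct response in an
affected item is attenuated,

    Pr(X_i = 1)_incomplete = Pr(X_i = 1 | ξ_attribute) · [1 − Pr(X_i missing)] ,

and — because the same respondents are affected across the design columns —
the affected items gain common variation of their own. The missing data
model adds a latent variable for exactly that component:

    x = λ_attribute ξ_attribute + λ_missing ξ_missing + δ ,

a bifactor-type two-factor model in which `λ_missing` is nonzero only on
the design columns (fixed to 1 there in the fixed-loadings variant, with
the variance φ_missing free; or free with φ_missing fixed to 1).

Estimation minimizes the ML discrepancy

    F(θ) = ln|Σ(θ)| + tr(S Σ(θ)⁻¹) − ln|S| − p ,

where S is the tetrachoric correlation matrix (two-step ML per pair:
thresholds τ_i = Φ⁻¹(1 − Pr(X_i = 1)) from the margins, then a
one-dimensional likelihood maximization over the latent correlation), made
positive definite by a ridge option when necessary. Test statistics are
Satorra–Bentler scaled, χ²_scaled = χ²_raw / c with c = tr(U Γ)/df, where Γ
is a respondent-bootstrap estimate of the asymptotic covariance of the
unique tetrachoric correlations (the bootstrap re-runs the whole pipeline,
zero replacement included). RMSEA, SRMR, NNFI, CFI and AIC are reported,
and models are compared with the ΔCFI ≥ 0.01 / ΔRMSEA ≥ 0.015 criteria.

## Worked example

Generate one 500 × 20 unidimensional binary data set (population
inter-item correlation 0.35², median split), delete 60 % of the entries of
columns 11–20 for one shared block of respondents, and investigate the
structure with and without a missing data latent variable:

```r
library(mdcfa)

pop    <- population_model(p = 20, loading = 0.35, n = 500)
design <- missing_design(11:20, rate = 0.6, scheme = "shared")
dat    <- generate_binary(pop, seed = 42, design = design)

corr  <- ensure_pd(tetrachoric_matrix(dat))      # zero replacement inside
gamma <- estimate_gamma(dat, B = 100, seed = 43)

one <- sb_scale(fit_ml(corr$matrix, build_one_factor(20, "fixed"), 500), gamma)
two <- sb_scale(fit_ml(corr$matrix,
                       build_missing_data_model(20, 11:20, "fixed"), 500), gamma)
one; two
compare_models(two, one)
```

```
Satorra-Bentler scaled fit: chi-square 696.91 (raw 2889.62, c = 4.146), df = 189
  RMSEA 0.0734  SRMR 0.3295  NNFI 0.8976  CFI 0.8982  AIC 738.9
Satorra-Bentler scaled fit: chi-square 216.75 (raw 1169.25, c = 5.395), df = 188
  RMSEA 0.0175  SRMR 0.0776  NNFI 0.9942  CFI 0.9942  AIC 260.7
```

The one-factor model is badly distorted by the missingness (RMSEA 0.073,
CFI 0.898), although the data are perfectly unidimensional. One additional
missing data factor — one extra parameter — restores close-to-complete-data
fit (RMSEA 0.018, CFI 0.994); `compare_models()` flags both differences as
substantial (ΔRMSEA −0.056, ΔCFI +0.096).

The full simulation design (one-/two-factor × fixed/free loadings ×
{4, 10} design columns × rates 0.2/0.4/0.6, plus complete-data reference
cells) is run by `run_design()`, which emits four table-style summaries
with means and 95 % confidence intervals per fit index, the
model-comparison deltas, and recovery percentages. A command-line front
end with `generate`, `tetrachoric`, `fit`, `simulate` and `report`
subcommands is installed at `inst/cli/mdcfa.R`.

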