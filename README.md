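# agedelta

Does a large "brain age delta" mean someone is *aging faster*, or that
their brain has simply *always been different*? From one scan per person
the two are indistinguishable at the individual level, but across a
population they leave different fingerprints: genuine between-subject
variation in aging rate makes the spread of deltas grow with age
("delta-expansion"), while fixed baseline differences leave it constant.
`agedelta` separates the two, for the classical all-in-one brain-age model
and for multiple data-driven modes of brain aging, and ships the
simulation machinery to validate the whole procedure.

Audience: researchers working with imaging-derived phenotypes (IDPs) or
pre-computed brain-aging mode scores who want to know how much of their
delta variance reflects ongoing aging — and whether per-subject deltas can
honestly be interpreted as aging rates.

## The model

Ages are rescaled to `Y ∈ [0, 1]`. Each feature follows, per subject `i`,

    x_i = x0_i + xhat(Y_i) + Y_i * beta_i + noise,

with population mean curve `xhat` (quadratic), zero-mean subject baseline
`x0` and aging rate `beta`. After subtracting the fitted curve (and
orthogonalising against age), the delta satisfies

    E[delta_i^2] = B + Y_i^2 * E,     B = Var(x0),  E = Var(beta),

a heteroscedastic model fitted by maximum likelihood (Gaussian, iterative,
method-of-moments initialised), twice: as written and with `Y → 1−Y`
(delta-contraction), keeping the better-fitting direction. The variance
fractions

    Bf = B / (B + mean(Y^2)*E),   Ef = mean(Y^2)*E / (B + mean(Y^2)*E)

sum to 1; `Ef` is reported negative under contraction. Fisher-information
standard errors are inflated by `sqrt(2)` when two timepoints per subject
are pooled. With paired data the package also splits deltas into the
cross-sectional mean `delta_cross` and interval-normalised change
`delta_long`, whose correlation `r_xl` confirms (or refutes) estimated
expansion against actually observed change.

## Worked example

Simulate a realistic two-timepoint cohort (4,400 subjects, 16 modes) and
decompose its most strongly expanding mode:

```r
library(agedelta)

sim <- simulate_cohort(default_params(), seed = 1)
co  <- sim$cohort
co
#> cohort: 8800 samples x 16 features
#>   age range: 46.1-80.8 y  (two pooled timepoints per subject)
#>   subjects: 4400

d9  <- compute_mode_delta(co$features[, 9], co$age_norm, feature_id = "mode_09")
fit <- fit_expansion(d9, co$age_norm, paired = TRUE)
fit
#> expansion_fit 'mode_09' (expand): B = 0.3031 (SE 0.0141), E = 2.193 (SE 0.0887)
#>   Bf = 0.299 (SE 0.0139), Ef = 0.701 (SE 0.0283), signed Ef = 0.701
#>   loglik = -11618.8180, n = 8800 (paired, SEs sqrt(2)-inflated)

cross_long_split(d9, co)
#> longitudinal_summary 'mode_09': rxl = 0.189 (p = 1.05e-36, n = 4400)
```

Reading the numbers: 70% of this mode's delta variance is explained by
between-subject differences in ongoing aging rate (`Ef = 0.70`, true
simulated value 0.667) and 30% by fixed baseline spread; the positive,
highly significant `r_xl` shows the cross-sectional deltas really do
predict each subject's longitudinal change — the signature of genuine
expansion. For a baseline-dominated mode, `Ef` would sit near 0 and
`r_xl` near 0, and per-subject deltas should *not* be read as aging rates.

Full pipeline from an IDP table (outliers → confounds → SVD soft-impute →
feature-space ICA → deltas → expansion fits → longitudinal table):

```r
run_pipeline("idps.tsv", out_dir = "results", n_modes = 16, seed = 1)
```

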