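# ptesr

Source apportionment and deterministic ingestion-risk assessment of
potentially toxic elements (PTEs — Fe, Mn, Cu, Zn, Al, Hg, As, Se, Cd,
Pb, Li, B, Ba, Sb, Ni, Co, Mo) measured in surface, ground and mine
water. The package is aimed at hydrochemists and environmental-health
analysts who have a sample-by-analyte concentration table (μg/L) with
per-analyte method detection limits, and who want to (i) characterize
the data against drinking-water limits, (ii) resolve the mixture into
non-negative source contributions and profiles, and (iii) translate
concentrations into population-stratified health-risk metrics.

## The models

**Uncertainty-weighted positive matrix factorization (PMF).** The
n × m concentration matrix X is decomposed as

    X = G F + E,        G ≥ 0 (n × p),  F ≥ 0 (p × m),

by minimizing the scaled-residual objective

    Q = Σᵢⱼ (eᵢⱼ / uᵢⱼ)²,

where the per-cell measurement uncertainty is built from each analyte's
method detection limit (MDL) and error fraction (EF):

    uᵢⱼ = (5/6)·MDLⱼ                          if xᵢⱼ ≤ MDLⱼ,
    uᵢⱼ = √((EFⱼ·xᵢⱼ)² + (0.5·MDLⱼ)²)          otherwise.

Cells reported below detection enter the working matrix at MDL/2. The
optimizer alternates exact non-negative weighted least-squares updates
of the columns of G and rows of F over `n_starts` random
initializations; Q is non-increasing within a run and the lowest-Q
solution wins. Because transformations `G A, A⁻¹ F` that keep both
matrices non-negative leave Q exactly unchanged, the fit finishes with
a deterministic polish that reports the sparsest-profile representative
of the winning equivalence class (see the methods vignette). Q/Q_expected,
with Q_expected = nm − p(n+m), is near 1 when the uncertainty model
matches the residual noise.

**Deterministic oral-ingestion risk (USEPA model).** For each sample,
analyte and population group (children / men / women):

    CDI = (C_w·10⁻³ · IR · EF · ED) / (BW · AT)    [mg/(kg·d)]
    HQ  = CDI / RfD          HI  = Σ HQ            (AT = ED·365 d)
    CR  = CDI · SF           CCR = Σ CR            (AT = LE·365 d)

HI ≤ 1 is level I (acceptable), HI > 1 level II. CR is banded I–V at
10⁻⁶, 10⁻⁵, 10⁻⁴, 10⁻³ (half-open at the lower edge). Reference doses
for the 15 assessed analytes and the single slope factor (As, 1.5) are
bundled, as are editable exposure-parameter defaults.

A synthetic generator (`generate_synthetic()`) draws tables with known
factor structure, multiplicative noise and left-censoring at the MDL,
so the whole pipeline is testable without external data.

## Worked example

```r
library(ptesr)

fx <- make_worked_fixtures()      # engineered 34-sample surface survey
exceedance(fx$table, "Fe")$percent
#> [1] 79.41176
s <- summarize_concentrations(fx$table)
head(rank_analytes(s, "mean"))
#> [1] "Fe" "Al" "Zn" "Ba" "Mn" "B"

assess_risk(fx$table)
#> <risk_table> 34 samples x 3 groups
#>      group hi_below_1_percent cr_level_I_percent cr_level_II_percent
#> 1 children              94.12                  0               26.47
#> 2      men              94.12                  0               26.47
#> 3    women              94.12                  0               26.47
#>   cr_level_III_percent cr_level_IV_percent cr_level_V_percent
#> 1                73.53                   0                  0
#> ...
```

79.41% of samples exceed the Fe and Al class III limits; 94.12% of
samples carry an acceptable total non-carcinogenic risk (HI ≤ 1) for
every population group; 73.5% sit in carcinogenic level III (CR between
10⁻⁵ and 10⁻⁴, driven by As), the rest in level II.

Source apportionment on synthetic data with known truth:

```r
syn <- generate_synthetic(synth_spec(), seed = 1)   # 34+5+2 samples, 4 sources
fit <- pmf(filter_water_type(syn$table, "surface"), p = 4, seed = 1)
fit
#> Uncertainty-weighted PMF: 34 samples x 17 analytes, p = 4
#>   Q = 152.53 (Q/Q_expected = 0.408), converged after 321 iterations (start 3 of 20)
#>   factor shares (%): 9.3, 50.8, 11.5, 28.4
match_factors(fit$F, syn$truth$F_true)$mean_cosine
#> [1] 0.998
```

The fitted profiles match the generating ones to a mean cosine of
0.998 after permutation alignment. `run_all()` chains
describe → pmf → risk on one input and writes CSV/JSON artifacts plus a
run report; `pmf_scan_p()` helps choose the number of factors.

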