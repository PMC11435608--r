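---
title: "Methods: uncertainty-weighted PMF and ingestion risk in ptesr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty-weighted PMF and ingestion risk in ptesr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptesr)
```

`ptesr` implements the two quantitative backbones of a PTE
(potentially toxic element) survey of river water — receptor modelling
by positive matrix factorization and the USEPA deterministic
oral-ingestion risk chain — together with the descriptive layer and a
synthetic-data generator that makes the whole pipeline verifiable
without access to field data. This vignette records the models, their
assumptions, the tunable parameters, and the design decisions that were
genuinely open.

## Data model and censoring

Concentrations are held in μg/L throughout; mg/L inputs must be
converted beforehand. Each analyte carries a method detection limit
(MDL, μg/L) and an error fraction (EF, dimensionless in (0, 1)). Cells
reported only as "below detection" are flagged and recorded at the MDL
bound; `substitute_censored()` gives them the working value MDL/2, the
convention of receptor-modelling practice. The substitution is
idempotent and never touches a measured cell; the censored flags are
kept so that uncertainty construction still routes those cells through
the below-detection branch.

The bundled analyte configuration (`inst/extdata/analytes.yml`) ships
MDL/EF values that are *synthetic placeholders* of realistic magnitude
— laboratories report their own — and drinking limits only for Hg
(1 μg/L), Cd (5 μg/L), As and Se (10 μg/L). All other limits are the
user's responsibility because they depend on the applicable standard.

## Descriptive layer

Summaries use the working (post-substitution) values. The coefficient
of variation is 100·sd/mean with the sample (n−1) standard deviation; a
zero mean yields an `NA` marker rather than an infinity. Exceedance
against a limit counts *strict* exceedances — a value equal to the
limit is compliant — with a `strict = FALSE` escape; the percentage is
kept at full precision and rounded (two decimals) only for display.
Rankings are descending with lexicographic tie-break, so they are
deterministic. Summaries default to surface-water samples, the usual
reporting convention for drinking-water statistics; pass
`water_type = NULL` to include ground and mine water.

## The factorization

The model is X = G F + E with G (n samples × p sources) and F
(p × m analytes) non-negative, fitted by minimizing

$$Q = \sum_{ij} \left( \frac{x_{ij} - \sum_k g_{ik} f_{kj}}{u_{ij}} \right)^2,$$

with per-cell uncertainties

$$u_{ij} = \tfrac{5}{6}\,\mathrm{MDL}_j \quad (x_{ij} \le \mathrm{MDL}_j), \qquad
u_{ij} = \sqrt{(\mathrm{EF}_j x_{ij})^2 + (0.5\,\mathrm{MDL}_j)^2} \quad (x_{ij} > \mathrm{MDL}_j).$$

The boundary case x = MDL uses the below-detection branch.

**Optimizer.** Alternating non-negative weighted least squares in
HALS form: each column of G, then each row of F, is updated to its
exact constrained minimizer given the rest (closed form with clipping
at zero), with weights 1/u². Exact coordinate minimization makes Q
non-increasing by construction; the trajectory is stored and asserted
in the tests. A run converges when the relative Q decrease stays below
`rel_tol` (default 1e-9) for 20 consecutive iterations, up to
`max_iter` (default 5000). On exactly factorizable data Q decays
geometrically toward zero and the relative-change rule may never
trigger; the best solution is still returned, with `converged = FALSE`
and a warning.

**Multi-start.** `n_starts` (default 20) random initializations: G
uniform with columns scaled to mean 1, F uniform scaled to 2/p times
the column means of X so the initial reconstruction has the right
magnitude. The lowest-Q run wins; everything is deterministic given
`seed`.

**Rotational ambiguity and the `simplify` polish.** Any transformation
G → G A, F → A⁻¹ F that keeps both matrices non-negative leaves G F —
and therefore Q — exactly unchanged. The minimizer is thus an
equivalence class, and which representative a multi-start search
returns is an accident of initialization: on synthetic data the matched
cosine to the generating profiles varied between 0.88 and 0.99 across
starts of *equal* Q. Rather than leave that choice to chance, `pmf()`
by default reports a canonical representative: each profile row is
repeatedly reduced by the largest multiple of every other row it can
shed while staying essentially non-negative (a robust 10% quantile of
the entrywise ratio, so isolated zero entries produced by clipping do
not block the move; the complementary exact transfer
G·ₖ ← G·ₖ + δ G·ₗ preserves G F), with short plain sweeps after each
round to repair the clipping. Profile sets with distinct source
signatures — rows that each have zeros where other sources are active —
are fixed points of this map, so when the data-generating sources are
distinguishable the polish lands on them. The polish is accepted only
if Q is preserved within 0.1% relative (plus a numerical-zero
allowance); otherwise the unpolished representative is kept. It is a
reporting convention within the optimum, not a rotation tool: it never
trades fit for interpretability, and `simplify = FALSE` disables it.

**Normalizations and summaries.** After fitting, columns of G are
scaled to mean 1 with the scale absorbed into F, so F rows are in
concentration units. A factor's share of the apportionment is its share
of the total reconstructed mass, 100·Σᵢⱼ gᵢₖfₖⱼ / Σᵢⱼₖ gᵢₖfₖⱼ (summing
to 100); how published factor percentages are normalized is rarely
stated, and this mass-share convention is the documented choice here.
`profile_percent` gives each analyte's split across factors (columns
summing to 100). `q_expected` = nm − p(n+m) approximates E[Q] when the
uncertainty model matches the noise; `pmf_scan_p()` reports
Q/Q_expected over a range of p to assist choosing the number of
sources, which remains a user decision. The robust mode (off by
default) down-weights cells with scaled residuals beyond 4,
EPA-style; it is iteratively reweighted and therefore loses the strict
monotone-Q guarantee, which is why it is not the default.

**Recovery testing.** `match_factors()` aligns recovered to generating
profiles by exhaustive permutation search (p ≤ 8) on unit-normalized
rows and reports the mean cosine.

## The risk chain

For concentration C_w (μg/L), the chronic daily intake is

$$\mathrm{CDI} = \frac{C_w \cdot 10^{-3} \cdot \mathrm{IR} \cdot \mathrm{EF} \cdot \mathrm{ED}}{\mathrm{BW} \cdot \mathrm{AT}},$$

the 10⁻³ converting μg/L to mg/L since RfD and SF are in mg/(kg·d)
terms. The averaging time is AT = ED·365 days for the non-carcinogenic
horizon and AT = LE·365 days (life expectancy) for the carcinogenic
horizon — the standard USEPA convention. With EF = 365 d/yr the
non-carcinogenic CDI reduces to C_w·10⁻³·IR/BW. Then HQ = CDI/RfD,
HI = Σ HQ over the assessed analytes, CR = CDI·SF for carcinogens (here
only As, SF = 1.5 (kg·d)/mg) and CCR = Σ CR. All quantities are
homogeneous of degree 1 in concentration and exactly additive, which
the property tests exercise.

Classification: HI ≤ 1 → level I, HI > 1 → level II. CR bands are
half-open at the lower edge — [10⁻⁶, 10⁻⁵) is level II, and so on up to
level V at ≥ 10⁻³ — because interval notation in the literature is
ambiguous at shared endpoints and a tie must fall somewhere
deterministic.

Exposure defaults (children IR 1.0 L/d, BW 16 kg, ED 6 y; men 2.2/65/30;
women 1.7/56/30; EF 365 d/y; LE 70 y) are commonly used Chinese
technical-guideline values shipped as an editable configuration; they
are deliberately *not* baked into any equation, and site studies should
supply their own. Under these defaults children's IR/BW exceeds both
adult groups', so children's HQ dominates cell-by-cell — the expected
pattern for drinking-water exposure.

**HI sensitivity.** The default score for "which analytes drive HI" is
the mean contribution share mean(HQⱼ)/mean(HI), which sums to 1 across
analytes; a Spearman rank-correlation mode (concentration vs HI across
samples) is provided for comparison since published sensitivity figures
rarely state their method. Constant-zero HI yields `NA` markers.

## The synthetic generator

`synth_spec()` defaults emulate a small river-network survey: 34
surface + 5 ground + 2 mine samples over the 17-element panel, p = 4
sources, gamma-distributed contributions (shape 2, unit mean, per-factor
scale in [0.6, 1.4]), 10% multiplicative Gaussian noise truncated at
zero, and per-analyte MDLs placed at the 5% quantile of the generated
values so a realistic fraction of cells is censored. Error fractions
are set to the noise CV, so above the MDL the uncertainty model matches
the generating noise.

Profiles are built for identifiability, the stated purpose of the
module: analytes are assigned a dominant factor greedily so every
factor carries a comparable share of total mass (avoiding factors whose
signature lives only in trace analytes, which unit-norm cosines would
barely see); a `profile_sparsity` fraction (default 0.5) of non-dominant
entries is exactly zero; and each factor's heaviest analyte is a pure
tracer with all other factors zero there — the separability condition
under which non-negative factorizations are essentially unique. Column
scales follow typical surface-water magnitudes (Fe and Al in the
hundreds of μg/L down to Sb near 0.1), reproducing the concentration
and CV rankings such surveys report.

What the generator does *not* emulate: spatial autocorrelation along
rivers, correlated measurement error between analytes, laboratory batch
effects, or any attempt to mimic a specific survey's concentration
values. Passing recovery tests therefore demonstrate that the engine
solves the stated inverse problem at the stated scale — not that four
sources are identifiable in any particular real data set.

With `mdl_quantile = 0` the MDL is set to a negligible 10⁻⁶ of the
analyte scale (not the column minimum), so "no censoring" also means no
MDL inflation of the uncertainties; this is the correctly specified
configuration in which Q/Q_expected is expected to sit near 1, and the
corresponding sanity test measures it there (observed ≈ 0.97–1.17
across seeds). With the default 5% censoring the 0.5·MDL term inflates
u relative to the purely multiplicative noise and the ratio drops to
roughly 0.3 — a property of the uncertainty model, not a misfit.

`make_worked_fixtures()` is different in kind: a deterministic
34-sample table *engineered* so the standard pipeline reproduces the
canonical worked-example counts (27/34 Fe and Al exceedances → 79.41%,
1/34 Mn and Zn → 2.94%, 2/34 samples with HI > 1 for every group →
94.12% acceptable, 25/34 at CR level III → 73.5% with 9/34 → 26.5% at
level II) under the bundled exposure and toxicity defaults. Its values
are synthetic; the elevated samples are driven by As (CR band) and Co
(HI), and its analyte configuration carries class III limits
(Fe 300, Al 200, Mn 100, Zn 1000 μg/L and the bundled Hg/As/Se/Cd
values). Level-III percentages are reported at one decimal.

## Numerical choices and degenerate inputs

- Convergence: relative Q change < 1e-9 sustained over 20 iterations;
  5000-iteration cap; warnings, not errors, on non-convergence.
- CSV numerics are written with 17 significant digits (`%.17g`), so a
  write/read cycle reproduces doubles exactly.
- Ties in rankings break lexicographically; the CR bands are half-open
  at the lower edge; exceedance is strict.
- p must satisfy 1 ≤ p ≤ min(n, m) − 1; non-finite or negative inputs
  to the factorization are rejected, as are zero body weights or
  averaging times, negative risks, and missing MDL/EF/RfD/SF entries —
  each error names the offender.
- All-zero reconstructions make factor shares undefined and error out;
  an all-zero analyte column yields an `NA` CV marker.
- Empty HQ sets sum to an HI of 0 with a warning.

## Problem sizes

The test suite fits factorizations at n ≤ 34, m ≤ 17, p ≤ 4 with up to
20 starts, and the recovery study runs ten seeds at the survey scale
(34 × 17, p = 4); the descriptive-convergence property uses one
n = 2000 draw. The full suite runs in about two and a half minutes on
one CPU, and `scripts/acceptance.R` in about two.

## Known limitations

- No bootstrap, displacement, or other rotational-uncertainty
  diagnostics; the `simplify` polish picks a canonical representative
  but does not quantify the width of the equivalence class.
- Oral ingestion only; no dermal or inhalation pathways, and no
  probabilistic (Monte Carlo) risk — the risk model is deterministic by
  design.
- Exposure and MDL/EF defaults are placeholders in the documented
  sense; conclusions about real populations require site-specific
  values.
- Coordinates are pass-through metadata: no spatial modelling or map
  rendering.
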