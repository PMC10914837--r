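---
title: "Assessing groundwater potability: methods behind gwqi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing groundwater potability: methods behind gwqi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwqi)
```

This vignette explains the models and conventions the package implements,
the parameters that matter, the choices made where the design was open, and
what the synthetic generator can and cannot tell you about real data.

## The weighted-arithmetic water quality index

The index condenses twelve physicochemical parameters — fluoride, total
alkalinity (as CaCO3), TDS, chloride, sodium, potassium, sulphate, nitrate,
magnesium, calcium, total hardness (as CaCO3), and pH — into one score.
Three quantities define it. The *unit weight* of parameter $n$ is inversely
proportional to its permissible standard $X_s$,

$$W_n = K / X_s, \qquad K = 1 \big/ \sum_n X_s,$$

so a constituent that is dangerous at low concentration (fluoride,
$X_s = 1.5$ mg/L) dominates one that is tolerable at high concentration
(TDS, $X_s = 1000$ mg/L). The *quality rating*

$$Q_n = 100 \, (X_n - X_i) / (X_s - X_i)$$

scales the measured value $X_n$ so that the ideal value $X_i$ maps to 0 and
the permissible standard to 100; ratings above 100 mean the standard is
exceeded. $X_i = 0$ for every parameter except pH, whose ideal is neutral 7.
The index is then the weighted mean $\mathrm{WQI} = \sum Q_n W_n / \sum W_n$,
which is invariant to rescaling all weights — only the *relative* standards
matter.

**The pH convention.** Applied literally, the rating formula gives negative
$Q_n$ for pH below 7, which would *reward* acidic water. The package
default rates pH by absolute deviation, $100\,|X_n - 7| / (X_s - 7)$,
treating acid and alkaline excursions symmetrically; the raw signed form
remains available (`ph_rating = "signed"`) for strict reproduction of the
printed formula. This is the single place the implementation deliberately
departs from the formula as usually printed, and it is recorded in every
run manifest.

**Bands.** Classification follows the conventional five classes — 0–25
potable, 26–50 palatable, 51–75 moderately poor, 76–100 poor, above 100
unfit — implemented with upper-closed intervals so that a WQI of exactly
100 is "poor" and anything beyond is "unfit". A water sitting exactly at
the WHO standards therefore indexes to exactly 100, the poor/unfit
boundary: a useful fixed point that the tests exercise.

**Guidelines.** The WHO standards are the default; the BIS (IS 10500)
alternative resolves each printed range to its upper (permissible) bound
because the index needs a single $X_s$ per parameter. BIS publishes no
limit for sodium or potassium, so those two fall back to WHO values and are
flagged in the table rather than merged silently. Users can load their own
table from CSV/YAML (`read_standards()`). All twelve parameters enter the
index by default; the set is configurable (`include =`) since different
agencies index different subsets, and the weights are always recomputed
from the included set.

**Village aggregation.** Two defensible aggregations exist: average the
per-sample indices within a village ("mean-of-wqi", the default), or index
the village-mean water ("wqi-of-mean"). They differ because the index is
linear in concentrations only above the ideal point and through the pH
fold. Both are provided; the manifest names the one used.

## Charge-balance quality control

Electroneutrality gives an internal consistency check on an ionic analysis:
in milliequivalents per litre (mg/L divided by equivalent weight =
formula weight / |charge|), the cation sum (Ca, Mg, Na, K) should equal the
anion sum (HCO3, Cl, SO4, NO3, F). The package uses the standard-methods
convention

$$\mathrm{CBE} = 100 \, \frac{\Sigma_\mathrm{cat} - \Sigma_\mathrm{an}}
                             {\Sigma_\mathrm{cat} + \Sigma_\mathrm{an}},$$

gated at ±5%. Two deliberate choices: the minor anions NO3 and F *are*
included (they are measured, and excluding them only inflates apparent
imbalance), and failing samples are flagged rather than dropped (a
`drop_qc_failures` switch exists). Bicarbonate is taken from a measured
`HCO3` column when present, otherwise derived from total alkalinity as
$\mathrm{TA} \times 61.02/50.04$ (the HCO3:CaCO3 equivalent-weight ratio);
which path was used is recorded, since the choice shifts the anion sum.

## Piper and Schoeller geometry

The Piper construction excludes NO3 and F: the classical diagram is built
on the six/seven major ions, with cation percentages over Ca, Mg, Na+K and
anion percentages over HCO3+CO3, SO4, Cl. The two triangle positions
project into the central diamond as $d_1 = \%(\mathrm{Na{+}K})$ and
$d_2 = \%(\mathrm{SO_4{+}Cl})$. Carbonate is folded into the bicarbonate
apex and defaults to zero — at the pH 8–9 typical of the waters this
package targets, free carbonate is minor and rarely titrated separately.
Note the asymmetry with the QC stage: the charge balance *includes* NO3 and
F; the two ion sums are intentionally different.

A facies label is the dominant cation and anion — dominant meaning strictly
above 50% of its triangle, with a "mixed" fallback so every sample gets a
decidable label. Na+K dominance is reported as Na and HCO3+CO3 as HCO3,
matching how facies like Na-HCO3 and Ca-Cl are conventionally written.

Schoeller profiles are $\log_{10}$ meq/L along parallel ion axes. The
default uses seven axes (Ca, Mg, Na, K, Cl, SO4, HCO3); a six-axis mode
combines Na and K, since both conventions circulate. Non-positive
concentrations have no logarithm and are returned as censored points
rather than plotted at an arbitrary floor.

## Correlation and principal components

Spearman rank correlation (midrank ties) is the right association measure
for hydrochemical solutes, whose relationships are monotone but rarely
linear and whose distributions are skewed. A constant column has no defined
rank correlation; the package flags it `NA` instead of writing 0, which
would assert independence that was never measured.

PCA runs on the *correlation* matrix: the twelve parameters span four
orders of magnitude (fluoride ≈ 1.6 mg/L vs TDS ≈ 1300 mg/L), so
covariance PCA would simply rank variances. Loadings are eigenvectors
scaled by $\sqrt{\lambda}$, so the full loading matrix reconstructs the
correlation matrix and eigenvalues sum to the number of variables — both
identities are asserted in tests at $10^{-8}$. Components are retained by
the strict Kaiser rule ($\lambda > 1$) applied to the *unrotated*
spectrum; rotation then acts on the retained columns. The alternative
reading — apply the rule after rotation — is coherent, but rotation
redistributes variance among retained columns and is conventionally done
*after* deciding how many to keep; the manifest records the rule so no
reader has to guess.

Varimax is implemented as classical pairwise planar rotations, raw
(unnormalized) by default, with Kaiser row normalization available since
SPSS defaults to it. The criterion — the summed per-component variance of
squared loadings — is checked to be non-decreasing at every sweep, and
convergence is a criterion gain below $10^{-6}$ per sweep (at most 100
sweeps; the best iterate is returned with a warning on non-convergence,
which does not occur in practice at these sizes). A deterministic sign
convention (the largest-magnitude loading of each component is made
positive) keeps output reproducible across linear-algebra backends.
Loading strength follows the usual interpretive bands — strong ≥ 0.75,
moderate 0.50–0.75, weak 0.30–0.50 — extended with "negligible" below
0.30, which the conventional bands leave unnamed.

## IDW interpolation

A grid value is $\sum w_i v_i / \sum w_i$ with $w_i = 1/d_i^p$; a grid
point on a site takes the site value exactly (the $p \to \infty$ and
$d \to 0$ limits agree). Defaults are $p = 2$ and an all-sites
neighborhood, the commonest GIS defaults; both are arguments, and a
k-nearest mode exists. The surface is by construction a convex combination,
bounded by the site extremes — property-tested over random configurations —
so IDW never extrapolates beyond observed values. Coordinates are assumed
planar; a survey block a few kilometres across does not need geodesy, and
lon/lat users should project first. Surfaces export as long-format CSV or
ESRI ASCII rasters.

## The synthetic generator

No raw per-sample table is publicly deposited for the survey this package
is modelled on, so the generator reproduces the structure that *is*
published and the pipeline is exercised on that. It emulates three things:

1. **Marginals** — the published min/max/mean/SD of the twelve parameters
   over 50 samples (`default_marginals()`). Each margin is a truncated
   normal with the published mean/SD as location/scale on [min, max].
   Location/scale are *not* re-inverted to match post-truncation moments
   exactly — a fixture generator does not need that inversion — so tests
   compare against the analytic truncated-normal moments
   (`truncnorm_moments()`), the correct oracle.
2. **Dependence** — the published rank-correlation matrix (symmetrized,
   since a few printed cells disagree between triangles), imposed by a
   Gaussian copula. The Spearman target converts to the latent Pearson
   scale by $2\sin(\pi\rho/6)$, exact for bivariate normals; because each
   margin map is monotone, the rank correlation survives the
   transformation exactly. The converted matrix is not guaranteed positive
   semidefinite and is repaired by eigenvalue clipping (rescaled to unit
   diagonal); the *effective* target after repair is attached to the
   output so fidelity checks compare against what was actually imposed.
   At n = 5000 the achieved rank correlations sit within 0.05 of that
   target entrywise.
3. **Grouping** — 10 villages × 5 samples, with a village-level shared
   shift of 0.3 SD per parameter added to the location before truncation.
   That fraction gives visible within-village resemblance (testable as an
   ANOVA variance share) without pushing values past the marginal bounds,
   which truncation enforces exactly.

An optional `balance_ions` mode rescales each sample's anions minimally so
|CBE| ≤ 5%, emulating a survey in which every sample passed QC (it targets
a hair inside the gate so floating-point rounding cannot flip the flag);
it is off by default because closure can push an anion slightly outside
its marginal bounds. With default settings roughly half the simulated
samples pass the ±5% gate — the published marginals and correlations do
not by themselves encode electroneutrality, which is worth remembering
when reading simulated QC reports.

`generate_block_structured()` plants a known factor structure (within-block
latent loading 0.85, blocks independent) for component-recovery testing.
The default blocks mirror the three-component pattern reported for the
motivating survey: a large salinity/alkalinity block, a hardness block
(TH, Ca, Mg), and potassium alone. A standardized singleton block has
population eigenvalue exactly 1 — precisely on the Kaiser boundary — so
its retention is a finite-sample effect; the generator warns about this,
and at the sizes used in the tests (n = 500) the third eigenvalue lands
just above 1.

**What passing tests do not show.** The generator draws from truncated
normals with a fixed correlation; real groundwater chemistry has mixing
end-members, detection limits, spatial autocorrelation beyond village
membership, and seasonal structure, none of which are emulated. Passing
recovery tests shows the *estimators* are correct, not that the generator
is a hydrogeochemical model.

## Numerical choices and problem sizes

Tolerances: ternary closure and meq round-trips at $10^{-9}$; spectral
identities and communality preservation at $10^{-8}$; varimax convergence
at $10^{-6}$ per sweep. Degenerate inputs: all-zero ion vectors are an
error for the charge balance (the ratio is undefined), zero Piper sums are
an error, exact dominance ties fall back to a fixed catalog order with a
tie flag, and rank-deficient correlation matrices have tiny negative
eigenvalues clipped at zero with a warning. The test and example sizes —
50-sample surveys, n = 500 block recovery, n = 5000 marginal fidelity,
grids of 10–60 ticks per axis — were chosen as the smallest sizes at which
the statistical assertions are stable, so the whole suite runs in well
under a minute.

## Known limitations

No speciation or activity modelling (concentrations are taken at face
value); no kriging or variogram-based spatial modelling (IDW only); no
alternative index families (CCME, NSF multiplicative, entropy-weighted);
no oblique rotations or factor-score regression beyond projection on
retained components. The published component loadings and correlation
matrix of the motivating survey are used to anchor *format and banding*
only — without the raw samples they are not numerically reproducible, and
the package does not pretend otherwise.
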