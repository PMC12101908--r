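---
title: "Elemental scope-for-growth budgets: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elemental scope-for-growth budgets: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elembudget)
```

## The physiological model

Suspension-feeding bivalves acquire carbon and nitrogen by clearing
particles from the water column, absorb a diet-dependent fraction of
what they ingest, and lose carbon through respiration and nitrogen
through ammonia excretion.  The *scope for growth* (SFG) of an element
is the net balance — what remains for tissue synthesis.  For a
replicate with clearance rate $CR$ (L h$^{-1}$), overall organic
(Conover) absorption efficiency $AE$, oxygen consumption $\dot VO_2$
(µL h$^{-1}$) and ammonia excretion $\dot V_{NH_4\text{-}N}$
(µg N h$^{-1}$), feeding on a suspension with particulate organic
matter concentration $POM$ and element mass fractions $N\%$ and $C\%$:

$$
\begin{aligned}
PON &= POM \times N\%/100, & POC &= POM \times C\%/100,\\
IR_N &= PON \times CR, & IR_C &= POC \times CR,\\
ER_X &= OIR\,(1 - AE)\,\tfrac{X\%_{feces}}{100}, & OIR &= POM \times CR,\\
AR_X &= IR_X - ER_X, & AE_X &= AR_X / IR_X,\\
SFG_N &= AR_N - E_N, & SFG_C &= AR_C - R_C,
\end{aligned}
$$

with $X \in \{N, C\}$, $E_N$ the excreted nitrogen and $R_C$ the
respired carbon.  All internal rates are µg h$^{-1}$, concentrations
µg L$^{-1}$; converters live only at the I/O boundary.

The model's key assumptions are worth stating plainly:

* **One overall absorption efficiency drives egestion.**  The Conover
  $AE$ applies to bulk organics; element selectivity enters only
  through the fecal composition ($N\%_{feces}$, $C\%_{feces}$).  If the
  supplied fecal composition is inconsistent with $AE$, per-element
  efficiencies can leave $[0,1]$; the package warns and *retains* such
  values rather than clipping, so inconsistencies stay visible.
* **All nitrogen loss is ammonia.**  Dissolved organic N losses are not
  modelled.
* **Respiration maps linearly to carbon loss.**  See the conversion
  constant below.

## Stoichiometric trajectory and its partition

Along the budget the C:N ratio typically declines: fecal organics are
relatively C-rich (preferential N absorption, the *pre-absorptive*
adjustment) and metabolic losses are overwhelmingly carbon
(respiration dwarfs ammonia-N, the *post-absorptive* adjustment).
With $I_{C:N}$, $A_{C:N}$ and $SFG_{C:N}$ the ratios of the ingested,
absorbed and retained fractions, the package partitions the total
decline as

$$
\text{pre} = \frac{I_{C:N} - A_{C:N}}{I_{C:N} - SFG_{C:N}}, \qquad
\text{post} = \frac{A_{C:N} - SFG_{C:N}}{I_{C:N} - SFG_{C:N}},
$$

which sum to one whenever the total change is nonzero.  Fractions may
individually leave $[0,1]$ when a trajectory is non-monotone
(e.g. absorption *raising* C:N); they are reported as computed.

A useful internal identity — tested to $10^{-9}$ — is that mass balance
forces $I_{C:N}$ to be the N-weighted mean of $E_{C:N}$ and $A_{C:N}$:
the ingested ratio always lies between the egested and absorbed ones,
even though $A_{C:N}$ need not lie between $I_{C:N}$ and $E_{C:N}$.

### Mean-of-ratios policy

Ratio parameters (C:N ratios, $AE_{C:N}$, metabolic C:N) are computed
per replicate and averaged upward at every pooling step, never as
ratios of pooled means.  The two differ materially for noisy
denominators (metabolic C:N group values can differ by >1 unit between
the two conventions).  When the package reproduces published pooled
values *from published group means*, it uses unweighted means of those
group values, which is how the source study pooled them.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| respiration conversion | 0.351 | µg C µL$^{-1}$ O$_2$ | see below |
| standard weight | 29.14 | mg dry tissue | reference weight of the modelled study |
| allometric $b$, clearance | 0.66 | — | conventional bivalve feeding exponent |
| allometric $b$, VO$_2$ / excretion | 0.75 | — | conventional metabolic exponent |
| `n_per_cell` | 5 | replicates | the modelled study's replication |
| decay-fit rate units | mg h$^{-1}$ | — | guards the µg-vs-mg trap: at µg scale the decay constant shrinks 1000-fold |

**The conversion constant.**  With a respiratory quotient of 0.9 and a
molar volume of 22.4 L mol$^{-1}$, the textbook conversion would be
$0.9 \times 12 / 22.4 \approx 0.482$ µg C µL$^{-1}$ O$_2$.  The
published respired-carbon values of the study this package models are,
however, uniformly their oxygen-consumption means times **0.351**
(all eight high-ration groups agree within ±0.01 µg h$^{-1}$).  Since
reproducing the published budgets takes precedence, 0.351 is the
default and the constant is exposed everywhere
(`conversion` argument, `--conversion-ugC-per-ulO2` flag).  The
provenance of the effective 0.351 is an open question we flag rather
than resolve; users deriving budgets for new data should choose
deliberately.

**Organic ingestion rate.**  $OIR = POM \times CR$.  Egestion/absorption
consistency checks against the published tables confirm this
definition reproduces them.

**Size standardization.**  $Y_{std} = Y_{obs} (W_{std}/W_{obs})^b$.
Published group means are already standardized, so the pipeline
defaults to `standardize = FALSE`; raw field data should switch it on.
Standardization round-trips to $10^{-12}$ relative precision.

## The synthetic-data generator

`generate_experiment()` emulates the *statistical structure* of the
modelled experiment: a 2×2×2×2 design (conditioning diet × exposure
diet × ration × growth phenotype), five replicates per cell, with the
published cell means and SDs of the four measurements.  Draws are
truncated normal — at zero for rates, to $(0,1)$ for the absorption
efficiency — via the inverse-CDF transform.  Measurements are
independent within a replicate by default; clearance and metabolism
plausibly covary in reality, so that independence is a documented
simplification (a correlation hook would slot into the per-cell draw).

Diet concentrations are back-derived from the published budgets: at
high ration POC = 625, PON = 120 µg L$^{-1}$ for the microalgae-rich
D1 (C:N 5.21) and POC = 662, PON = 129.8 µg L$^{-1}$ for the
yeast-rich D3 (C:N 5.10); the low ration halves all concentrations.
The experiment-period diet C:N values are used (not the stock
characterization, which differs slightly) because every published
budget number depends on them.  Bulk POM is not printed anywhere; we
fix 1.3 mg L$^{-1}$ at high ration for both diets — a realistic load
for a 2 mm$^3$ L$^{-1}$ algal suspension — which only sets the element
*fractions*, not the element budgets.  Fecal composition is likewise
never printed; the defaults (D1-fed: C 49.85 %, N 7.73 %; D3-fed:
C 49.97 %, N 9.27 %) are back-derived so egested C:N matches the
published fecal ratios (≈6.4 D1-fed, ≈5.4 D3-fed).

Seeding: one integer seed; each cell's substream is keyed by a hash of
its factor labels, so adding or removing cells never shifts the draws
of the others.

What passing tests on synthetic data do **not** show: the generator
reproduces means, dispersions and the design — not replicate-level
covariance, non-normal tails, or measurement error structure of real
flow-through chambers.  Conclusions about estimator behaviour under
those features require the raw data.

## Statistical components

**Exponential AE–IR decay.**  For poorly digestible diets absorption
efficiency falls with ingestion rate as $AE = a e^{-b \cdot IR}$.
`fit_exp_decay()` runs true nonlinear least squares
(Levenberg–Marquardt) initialized from the log-linear OLS fit; the NLS
result is rejected in favour of the initializer only if (pathological
case) it fails to improve the residual sum of squares.  Unweighted
least squares is used — there is no replication structure to justify
weights.  Reference decays ($a = 0.73$, $b = 13.99$ for nitrogen;
$a = 0.72$, $b = 3.34$ for carbon, IR in mg h$^{-1}$) are recovered to
$10^{-6}$ from noise-free data and to ~10 % in the median from noisy
data at study-like $n$.

**Factorial ANOVA.**  Fully crossed fixed-effects models over 2 or 3
two-level factors.  Balanced designs (the study's case: $n = 5$ per
cell) use the sequential decomposition, which is exact — term plus
residual sums of squares equal the total, and Type I = Type III.
Unbalanced user data fall back to Type III with sum-to-zero contrasts,
matching the field's customary software.  Terms with zero sum of
squares (e.g. a diet-determined C:N ratio analysed across rations,
where the fit is perfect) get $F = 0$, $p = 1$ by convention rather
than 0/0.  Normality/homoscedasticity screening and rank-based
alternatives are left to the standard implementations
(`shapiro.test`, `car::leveneTest`, rank transforms) and are outside
this package's tested surface.

## Numerical and degenerate-input choices

* Missing values propagate as `NA`, never as zero.
* `ir = 0` makes the element AE undefined (`NA`), not zero.
* Zero excretion or zero decline makes the dependent ratio or
  partition `NA`; the total reduction is 0 when ingested and retained
  C:N coincide.
* Negative absorption (egestion > ingestion) warns and propagates.
* Pipeline CSVs round to 4 decimals by default (mirroring table
  precision) and are byte-stable across reruns of the same seed; a
  full-precision flag exists.

## Problem sizes used by the test-suite

The suite exercises the estimators at deliberately modest sizes that
still pin down their behaviour: 100 random budgets for the exact
mass-balance identity and oracle equivalence; 200 noisy replicates of
the decay fit; 500 null simulations (2000 interaction p-values) for
the nominal 5 % type-I rate of the three-way ANOVA; 200 replicates per
cell for generator-mean recovery within three standard errors.

## Known limitations

* Energy budgets are out of scope except for the element-per-Joule
  ratios, whose absorbed-energy denominator uses the overall organic
  AE as a proxy for the unmeasured energy-specific AE (configurable).
* Total C:N-reduction percentages pooled across rations depend on
  replicate-level data not published anywhere; the pipeline reports
  them for user data but asserts nothing about them.
* Gut-passage kinetics and metabolic fecal losses are not modelled as
  state; they surface only implicitly through the fecal composition.
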