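---
title: "Electron balance, kinetics and expression normalization for syntrophic alkane-oxidizing cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron balance, kinetics and expression normalization for syntrophic alkane-oxidizing cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alkanox)
```

This vignette documents the models behind `alkanox`, the choices made where
the underlying methodology leaves room, and what the synthetic-data tests
do and do not establish about measured data.

## The electron-balance model

An n-alkane C~n~H~2n+2~ carries 6n + 2 transferable electrons: its mean
carbon oxidation state is −(2n+2)/n, and full oxidation to bicarbonate
(+4 per carbon) releases n·(4 + (2n+2)/n) = 6n + 2 electrons. Dissimilatory
sulfate reduction accepts 8 electrons per sulfate (SO₄²⁻ → HS⁻), fixing the
sulfate coefficient at (6n+2)/8 = 0.75n + 0.25 and giving the balanced
equation

$$\mathrm{C}_n\mathrm{H}_{2n+2} + (0.75n+0.25)\,\mathrm{SO}_4^{2-}
  \rightarrow n\,\mathrm{HCO}_3^- + (0.75n+0.25)\,\mathrm{HS}^- +
  \mathrm{H_2O} + (0.25n-0.25)\,\mathrm{H}^+.$$

`alkane_stoichiometry()` generates these coefficients; the test suite
verifies charge, hydrogen, oxygen and electron conservation exactly for
n = 1–30. The diagnostic quantity is the ratio of DIC production to sulfate
reduction, r = n/(0.75n + 0.25), which rises from 1 (methane) through 1.25
(pentane) towards its supremum 4/3.

### Carbon assimilation

If a fraction $f$ of alkane carbon is assimilated into biomass at mean
carbon oxidation state $z$ instead of reaching DIC, the carbon flux to DIC
falls linearly while the electron flux falls less (assimilated carbon still
releases the electrons needed to reach state $z$). Bookkeeping per mole of
alkane yields the forward model

$$r(n, f, z) = \frac{8n(1-f)}{(1-f)(6n+2) + f(2n+2+zn)},$$

implemented in `predicted_ratio()` and inverted in closed form by
`infer_assimilation()`:

$$f = \frac{r(6n+2) - 8n}{r\,n\,(4-z) - 8n}.$$

Assumptions: all released electrons are drawn to sulfate (no fermentation
products accumulate), biomass is the only non-DIC carbon sink, and the
culture is a closed, well-mixed bulk phase in mM units with no headspace
partitioning correction.

**Choice of z.** The biomass oxidation state is not measurable here; we
default to $z = 0$ (carbohydrate-like CH₂O equivalents, the conventional
first approximation for bulk biomass). With $z = 0$ the measured hexane and
tetradecane ratios of 1.21 and 1.09 invert to $f = 0.107$ and $f = 0.358$ —
"around 10%" and "around 35%". The sensitivity is modest: `z` in ±0.5
moves the inferred $f$ by a few percentage points, which is why
`infer_assimilation()` also reports $f$ rounded to the nearest 5 points.

**Domain limits.** $r$ above the complete-oxidation ratio implies negative
$f$ and is rejected with an explicit error; $r \ge 8/(4-z)$ (2 for
$z = 0$) crosses the model's singularity and is likewise rejected.

### Estimating the ratio from trajectories

`measured_ratio()` defaults to first-to-last endpoint differences per
replicate, control-corrected if an abiotic control series is supplied —
the most conservative reading of a concentration-versus-time figure, and
the default because it makes no assumption beyond mass balance between the
two endpoints. A `method = "regression"` alternative uses the whole
trajectory: DIC and sulfate are each regressed on sulfide, the common
reaction-progress variable, and the ratio is the negated quotient of the
two slopes. Because both regressions share the same noisy predictor, the
errors-in-variables attenuation that biases a direct DIC-on-sulfate
regression cancels in the quotient. The regression estimator is markedly
more precise on noisy series (see the recovery study below); when no
sulfide column is available it falls back to a through-origin fit of
produced DIC on consumed sulfate.

### Hydrogen equivalents

Were hydrogen the sole electron carrier between the alkane oxidizer and
the sulfate reducer, each mole of sulfate reduced would demand 4 moles of
H₂ (8 electrons vs 2). `hydrogen_equivalent()` and `hydrogen_fraction()`
express measured H₂ accumulation (e.g. under molybdate inhibition of
sulfate reduction) as a percentage of that requirement; small percentages
argue against hydrogen as the main carrier.

## Activity kinetics

Sulfide time series are segmented at recorded 1:3 dilution events
(`segment_series()`; dilutions are input flags, not auto-detected, because
concentration drops can also be sampling artefacts). Within a segment,
`fit_exponential()` fits $y = n_0 e^{mt}$ by ordinary least squares of
$\ln y$ on time — the log-linear reading of an exponential trend line —
and reports the doubling time $\ln(2)/m$ in days.

Two filters precede the fit, both configurable:

* `min_sulfide = 1` mM — points below assay background are excluded;
* `plateau_fraction = 0.9` — points above 90% of the segment maximum are
  excluded, because sulfide production stalls near 12–15 mM (sulfide
  toxicity / substrate limitation) and plateau points would bias $m$ low.

Neither cutoff has a canonical published value; both were fixed once at
these defaults. At least three usable points are required; a non-positive
rate yields an undefined doubling time with a warning rather than an
error, so screening over many segments does not abort.

`doubling_time_summary()` fits the first two segments per replicate (the
reporting convention for activity doubling times) and averages
arithmetically, without weighting by fit quality.
`classify_sustained_activity()` encodes the substrate-range success rule:
at least `required_segments = 2` *consecutive* segments must each push
sulfide above `threshold = 10` mM. The classifier is monotone in the
threshold, which the property tests exercise.

## Expression normalization

Starting from per-gene fragment counts $C_i$ with gene lengths $L_i$ (bp)
and rRNA flags:

1. **rRNA exclusion** (`filter_rrna()`) — rRNA dominates total-RNA
   libraries and is removed before any normalization.
2. **FPK** (`fpk()`) — $\mathrm{FPK}_i = C_i / (L_i/1000)$. No
   sequencing-depth scaling is applied (contrast FPKM): the downstream
   uses are within-sample comparisons and the compositional CLR.
3. **CLR** (`clr()`) — with $x_i = (C_i + 0.5)/(L_i/1000)$,
   $\mathrm{CLR}_i = \log_{10}(x_i / \bar{g})$, where $\bar{g}$ is the
   geometric mean of all $x_i$ in the composition. The pseudocount 0.5 is
   added to every count (zeros included) *before* length normalization,
   inside the per-gene numerator. The logarithm is base 10 by convention
   of the normalization being reproduced, although natural logs are more
   common for CLR; the choice only scales the values. The geometric mean
   is computed as the exponential of the mean of logs for numerical
   stability. The composition is each organism's gene set within each
   sample when an `organism` column is present (per-genome normalization),
   otherwise the whole table.

CLR values in a composition sum to zero and are invariant to common
scaling of the $x_i$; both are enforced to 10⁻⁹ in property tests over
seeded random tables. `mean_expression()` draws the per-organism average
expression line (arithmetic mean FPK), and `rank_genes()` ranks genes by
FPK with competition ranking (ties share the smaller rank; the rank after
a two-way tie at 1 is 3), the tie rule fixed here because "top-N expressed
genes" statements need one.

## Sequence screens

**CxxCH motifs.** `scan_cxxch()` reports every window matching
Cys-X-X-Cys-His, 1-based, overlapping windows included (an overlap policy
must be fixed; counting all windows is the conservative choice for a
five-residue haem-binding motif). The wildcard positions accept any
residue including X but not a stop. `classify_multihaem()` calls a protein
a multihaem cytochrome at ≥ 2 motifs by default — there is no canonical
count, so the threshold is exposed. The scan is verified against an
exhaustive window-enumeration oracle on 1,000 random proteins.

**Probe evaluation.** `evaluate_probe()` screens an oligonucleotide
against target and non-target sequence sets. Probes hybridize to rRNA, so
the reverse complement of the probe is slid along each subject's sense
strand (a flag enables same-strand matching); the minimum-mismatch window
per subject is scored, with IUPAC ambiguity codes counting as mismatches
unless exactly equal — a deliberately conservative rule. The criteria,
each reported separately so a failure names its cause: 100% of targets
with a perfect site; at most 5 non-targets with perfect sites; at least
one mismatch to every non-target; GC content below 60%; probe length 19 nt
(skippable). Melting temperature and rRNA-position criteria are recorded
as metadata only: they belong to the probe-design software ecosystem and
have no single published formula to reproduce.

## The synthetic-data generators

`sim_config()` fixes the simulated study conditions once; the defaults
describe a hexane-oxidizing culture at 70 °C: n = 6, f = 0.107, z = 0,
doubling time 20 d (within the reported 13–40 d range for these cultures),
triplicates, weekly sampling over 112 d, sulfide from 0.5 mM to a 15 mM
plateau (the upper dilution trigger), 1:3 dilutions, 28 mM fresh-medium
sulfate (seawater-like), 10 mM initial DIC (bicarbonate-buffered medium),
and 5% relative measurement noise. Noise is multiplicative lognormal
because concentrations are positive and assay errors scale with signal.

`simulate_culture()` couples the three analytes through the forward model:
each mM of sulfide produced consumes 1 mM sulfate and releases
`predicted_ratio(n, f, z)` mM DIC. At a dilution event the culture is
mixed 1:3 with fresh medium — sulfide is divided by 3 exactly, while
sulfate and DIC relax two-thirds of the way to the medium composition.
(Dividing *all* concentrations by 3 would drive sulfate negative over
repeated segments; the mixing rule is what a 1:3 transfer into fresh
medium physically does, and it leaves the sulfide behaviour — the quantity
the kinetic analyses consume — identical.) The plateau is a hard cap, a
modelling simplification of the gradual stall real cultures show.

`simulate_counts()` plants one gene whose FPK strictly exceeds every
competitor's and flags rRNA genes at 100× the median count;
`simulate_sequences()` plants CxxCH motifs on a cysteine-free background
(so the truth table is provably complete), exact probe sites in every
target, and degenerate sites in non-targets. All generators are pure
functions of the seed.

### What the recovery study shows — and does not

Across 200 seeds at the default 5% noise, the tests require the median
doubling-time error to stay within 10% (it does, comfortably: the
log-linear fit pools ~11 points per replicate) and the assimilated
fraction to be recovered within 0.05 absolute at the tetradecane condition
(n = 14, f = 0.358), where the assimilation signal is large (the ratio
drops from 1.30 to 1.09). At the hexane condition the signal is
intrinsically small — f = 0.107 moves the ratio by only ~0.05, the same
order as the ratio precision that triplicate trajectories at 5% noise can
deliver — so the test there asserts recovery within 0.10 absolute and
unbiasedness instead. This mirrors practice: measured hexane ratios carry
replicate scatter of similar magnitude, which is why assimilated fractions
are quoted "around" the nearest 5–10%.

Passing these tests shows the estimators are correct and well-calibrated
*under the generator's assumptions*: exact exponential growth, perfect
stoichiometric coupling, independent lognormal noise. Real cultures add
lag phases, drifting activity, autocorrelated assay errors, abiotic
sulfide losses and carbonate-system buffering of DIC — none of which the
generator emulates, so agreement on synthetic data does not by itself
validate a field measurement.

## Numerical and degenerate-case choices

* Stoichiometric identities are exact in double precision (coefficients
  are quarters); balance tests assert to 10⁻¹².
* The assimilation inversion clamps round-off negatives (|f| < 10⁻¹²) to
  zero so that r at exactly the theoretical ratio returns f = 0.
* The closed-form inversion is cross-checked against interval bisection of
  the forward model to 10⁻⁹ in tests, keeping the check independent of the
  algebra it verifies.
* An empty series segments to an empty result; a dilution flag on the
  first record would create an empty leading segment and is dropped with a
  warning.
* Subjects shorter than a probe score as no-hit with a warning rather than
  an error, so one fragmentary sequence does not abort a screen.
* Problem sizes in the test suite (200-seed recovery studies, 1,000-protein
  oracle comparisons, 2,000-gene tables) were chosen so the full suite
  completes in about a minute and a half on one core while still giving
  the stochastic properties a meaningful sample.

## Known limitations

* No thermodynamics: free-energy yields, pH and carbonate speciation, and
  isotope systematics are out of scope; DIC is treated as one bulk pool.
* The growth model is purely exponential; logistic or Gompertz fits, lag
  detection and temperature-response modelling are not provided.
* Expression tools stop at normalization and ranking; differential
  expression belongs to dedicated count-model packages.
* Probe evaluation checks given candidates; it does not search probe
  space, and it ignores hybridization thermodynamics.
* The multihaem threshold (≥ 2 CxxCH) and the biomass oxidation state
  (z = 0) are explicit, configurable conventions, not measured facts.
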