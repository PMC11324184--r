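---
title: "Methods behind befmf: multifunctionality, partitioning, multimodel inference and piecewise SEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind befmf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(befmf)
```

`befmf` packages the statistical chain commonly used to relate plant and
soil microbial diversity to ecosystem multifunctionality, together with
synthetic-data generators that emulate the two study designs the chain is
typically applied to: a full-factorial greenhouse microcosm experiment and
a global grassland survey. This vignette explains each method, the
assumptions behind it, the tunable parameters and their defaults, and the
design decisions taken where several defensible choices existed.

## Multifunctionality indices

Each raw ecosystem function is rescaled to the unit interval by min–max
standardization, optionally after a log10 (strictly positive data) or
square-root (non-negative data) transform. Transforms are **explicit
per-function configuration**, never chosen automatically by a normality
test: automatic selection makes results depend on the sample at hand and is
unreproducible across subsets. A constant column is an error, not silently
0.5 — a function with no variation carries no information and almost always
indicates an upstream data problem.

Standardized functions are averaged within named **ecosystem services**
(`multifunctionality()` requires the service map to partition the function
set), and the *weighted* index is the mean of service means while the
*averaged* index is the flat mean. The two coincide when all services have
equal size; on the default microcosm conditions (6 services of sizes
3, 2, 3, 2, 3, 3 over 16 functions) they correlate with R² above 0.9, which
is the usual justification for reporting the service-weighted index as
"the" multifunctionality.

Missing cells are excluded pairwise: a missing value drops out of its
function's min/max and of its service mean; a sample in which an entire
service is missing keeps an EMF (mean of the remaining services) but is
flagged `complete = FALSE`.

Two properties worth knowing:

- EMF is invariant to strictly increasing affine maps of any raw function —
  units and offsets never matter.
- Because standardization and thresholds use the **maximum observed in the
  analyzed sample set** (not a theoretical maximum), subsetting samples
  changes both standardized values and threshold counts. This is inherent
  to the approach; comparisons are only meaningful within one analyzed set.

## Multi-threshold profiles

For threshold $t$ (percent), the count for sample $s$ is
$N_{s,t} = \#\{f : y_{s,f} > (t/100)\,\max_s y_{s,f}\}$. Exceedance is
**strict** by default ("exceed" a threshold), with a documented `strict =
FALSE` switch. Counting is done on the raw scale unless a transform map is
passed; on monotone transforms the counts are unchanged, so this matters
only when a transform is combined with thresholding conventions from other
software. The default grid is 5–99% in steps of 1, which contains the
conventional reporting set {10, 25, 50, 75, 90}.

`threshold_slope_curve()` regresses counts on a diversity metric per
threshold (OLS; optionally the better of linear and quadratic by adjusted
R², ties going to the linear fit, as in `best_fit_regression()`). Constant
counts return a slope of exactly 0 with zero explained variance rather than
an error, because fully saturated or fully empty thresholds are expected at
the grid edges.

## Composite richness and covariate axes

`composite_richness()` min–max standardizes each group's richness and
averages the groups equally, so that, e.g., bacteria and fungi contribute
equally to "microbial richness" even though bacterial richness is an order
of magnitude larger.

`pca_first_axis()` works on z-scored columns (a correlation-matrix PCA):
the input tables mix units (pH, °C, %, mm), so covariance PCA would be
dominated by whichever variable has the largest numeric range. The sign of
an eigenvector is arbitrary; it is fixed deterministically so that the
loading of the first input column is non-negative, making downstream
regression coefficients reproducible. Scores are returned z-scored.

`jaccard_pcoa_axis()` computes binary Jaccard dissimilarities
($d = 1 - |A \cap B| / |A \cup B|$, via `stats::dist(method = "binary")`)
and classical scaling (`stats::cmdscale`). Negative eigenvalues are
reported, not corrected: Jaccard distances are generally non-Euclidean and
silently Cailliez- or Lingoes-correcting them changes the axis. A pair of
all-zero rows has an undefined Jaccard distance, so all-zero rows are
rejected by name. Where an NMDS axis is the conventional composition
covariate, this package substitutes the PCoA leading axis: it is
deterministic, has no stress-convergence failure mode, and the method tag
on the returned object records the substitution.

Aridity is $AI = \mathrm{MAP}/\mathrm{PET}$ with UNEP classes — hyperarid
$< 0.05 \le$ arid $< 0.2 \le$ semiarid $< 0.5 \le$ dry subhumid $< 0.65
\le$ humid. Only the four dry classes have conventional printed bounds;
"humid" is defined here as $AI \ge 0.65$, the standard UNEP complement.
Lower bounds are inclusive, upper exclusive.

## Variation partitioning

`varpart()` decomposes the **adjusted** R² (Ezekiel:
$1 - (1 - R^2)(n-1)/(n-p-1)$) of a univariate response over $k$ = 2–4
predictor groups. All $2^k - 1$ subset models are fit; the fraction
attributed to exactly the group set $A$ is obtained by Möbius
inclusion–exclusion,
$c_A = \sum_{T \subseteq A} (-1)^{|T|+1} R^2_{adj}(T \cup \bar A)$,
which guarantees that the untruncated fractions sum *exactly* to the
full-model adjusted R² (tested to 1e-12). Adjusted fractions can be
negative; they are reported raw and also truncated to zero, following the
convention that negative explained fractions are interpreted as zeros —
truncation is for display, the raw values are the estimates. OLS with a
single response is used rather than RDA because every response in this
chain (EMF, a service, one function) is univariate. Predictors are z-scored
within groups; R² is scale-invariant, so this only stabilizes the numerics.

No standard closed-form test exists for a unique fraction, and published
tables typically do not name one. The package uses the standard for partial
fractions: a **Freedman–Lane permutation test** — the pseudo-F compares the
reduced (conditioning-only) and full models, and the null distribution is
built by permuting reduced-model residuals added back to reduced-model
fitted values (seed default 17, $p = (\#\{F^* \ge F\} + 1)/(n_{perm}+1)$).
Its type-I error is verified by simulation in the test suite.

## AICc multimodel inference

`model_average()` fits every predictor subset (at most 12 predictors, i.e.
4096 models) by OLS on z-scored response and predictors, so coefficients
are standardized. AICc counts $k$ = coefficients + intercept + residual
variance. Akaike weights give model-averaged coefficients; two conventions
are implemented:

- **zero method** (default): a predictor absent from a model contributes a
  coefficient of 0 — averaging is over the full model set;
- **natural method**: averaging only over models containing the predictor.

The zero method matches the framing of importance across the whole model
set and is the default; the natural method is the less-shrunken estimator
and is the one to use when the goal is coefficient recovery rather than
ranking (the parameter-recovery checks in the test suite use it for exactly
that reason). Importance is the literal share
$100\,|\bar\beta_j| / \sum_j |\bar\beta_j|$; the model-averaged adjusted R²
($\sum_m w_m R^2_{adj,m}$) is reported separately as the total-variance
figure, because importance shares by construction sum to 100 regardless of
how much variance the model set explains. Unconditional SEs include the
between-model variance term
$\sum_m w_m \sqrt{se_{jm}^2 + (\beta_{jm} - \bar\beta_j)^2}$. Exactly
collinear predictors are rejected by a condition-number guard: subset
models containing both copies are not estimable, and which copy "wins" in a
pivoted fit is arbitrary.

## Mixed models

`fit_mixed()` is a thin, contract-enforcing wrapper over
`lmerTest::lmer()`: a Gaussian model with one random intercept — in the
microcosm design, the plant species *combination*, absorbing compositional
variation not captured by the richness level — fitted by REML with
Satterthwaite degrees of freedom for the fixed effects. When the true group
variance is zero the REML estimate sits on the boundary in a large share of
datasets, and the fixed effects then equal OLS exactly; with a single-level
grouping factor the model degenerates and the function falls back to OLS
with an explicit flag and warning rather than failing.

## Piecewise SEM

`sem_spec()` declares a DAG (formula list or edge table); cycles,
self-loops and duplicated edges are rejected, and a deterministic
topological order (Kahn's algorithm, lexicographic tie-break) is stored so
that every run of the same spec produces claims in the same order.

`fit_sem()` fits each endogenous node's equation separately — OLS, or the
mixed fit above where a random grouping is declared for that equation.
Path coefficients are standardized by $b \cdot sd(x)/sd(y)$; for a
single-parent Gaussian equation this equals the Pearson correlation.
Binary treatments enter as numeric 0/1 regressors. Composite variables are
formed as the fitted linear combination of their indicators from the
regression of the composite's (topologically first) child on the
indicators, then standardized — the composite is a modelling device for
"joint richness" style predictors, not a latent variable.

The d-separation **basis set** contains one claim per non-adjacent pair
(including exogenous–exogenous pairs), conditioned on the union of both
nodes' parents, with the later node in the topological order used as the
response when the claim is tested (the p-value of $u$ in the regression of
$v$ on $parents(v) \cup parents(u) \cup \{u\}$). Claims are invariant, as a
set, to which valid topological order is used. Fisher's
$C = -2\sum \ln p_i$ is compared to $\chi^2_{2k}$; the model is
conventionally accepted when $p_C > 0.05$. A saturated DAG (empty basis
set) reports $C = 0$, $df = 0$, $p_C = 1$ with an explicit `saturated`
flag rather than `NA`, so the acceptance rule stays applicable; a claim
p-value of exactly 0 reports $C = \infty$ with a `degenerate` flag. The
model-level AIC is the piecewise form $C + 2K$ with $K$ the total number of
parameters estimated across the structural equations; it is labelled as
such and is not comparable to likelihood-based AICs.

## The synthetic-data generators

The generators are first-class, tested code: they provide data with known
ground truth so that every downstream stage has a parameter-recovery test,
and their defaults *are* the packaged study conditions.

**Microcosm** (`microcosm_config()` / `generate_microcosm()`): a full
factorial of plant richness (1–4 species drawn from a 5-species pool) ×
dilution level (HD/MD/LD) × drought (0/1), with `n_replicates = 8` pots per
cell (192 pots, close to typical greenhouse designs of this shape).
Dilution-to-extinction is modelled as **independent Bernoulli survival per
zOTU**, so realized richness is Binomial(pool, retention); only richness
fractions are calibrated — MD retains 91% (bacteria) / 86% (fungi), LD 48%
/ 27%, reproducing reductions of 9/14% and 52/73% — and no abundance
dynamics are simulated. Baseline pools default to 2000 bacterial and 400
fungal zOTUs, typical amplicon richness magnitudes for grassland soil;
fungal guild pools (mycorrhizal 60, saprotroph 200, pathogen 80) use the
fungal retention calibration, since kingdom-level calibrations are all that
is available. Each of the 16 functions follows
$y = \beta_1 z(\text{plant}) + \beta_2 z(\text{microbial composite}) +
\beta_3\,\text{drought} + b_{comb} + \varepsilon$ with
$b_{comb} \sim N(0, \sigma_{comb}^2)$ per species combination and Gaussian
residuals. Defaults: $\beta = (0.3, 0.3, -0.3)$ — moderate standardized
effects of the size BEF experiments typically detect — except drought
*increasing* total soil P (reduced uptake under drought),
$\sigma_{comb} = 0.3$, $\sigma_{resid} = 1$. Within-pot residuals are
independent by default, with an exchangeable-correlation knob
(`resid_cor`), since the within-pot covariance of functions is not part of
the calibrated conditions. Pot attrition is an optional dropout rate,
default 0. All randomness flows from one seed through named per-table
streams, so adding an output table never perturbs earlier draws and
identical configs are byte-identical.

**Survey** (`survey_config()` / `generate_survey()`): 101 sites;
environmental covariates uniform within observed gradient ranges (pH
4.3–8.6, MAP 26–1471 mm/yr, MAT −2.7–27.2 °C); sites apportioned to
aridity classes by largest remainder from a mixture (default
25/15/30/20/10% humid → hyperarid, so every class is represented at
n = 101), AI uniform within each class range and PET derived as MAP/AI;
richness linearly coupled to the aridity gradient (wetter sites richer);
5 functions in 3 services from the same linear ground-truth model.

What the generators deliberately do **not** emulate: sequence-level
artefacts (reads, chimeras, rarefaction), abundance-weighted dilution,
greenhouse micro-climate, spatial autocorrelation among survey sites, and
non-linear diversity–function shapes. Passing tests therefore demonstrate
the *statistical machinery* is correct under linear Gaussian conditions
with known truth — not that real data meet those conditions.

## Numerical choices and degenerate inputs

- Constant columns: errors in standardization, composites and PCA;
  a zero-slope result in threshold curves; centered-at-zero predictors in
  the generators (a constant design column carries no signal).
- Ordination signs fixed deterministically (first-column loading /
  covariance non-negative).
- Rank deficiency is an error naming the equation (SEM) or group
  (varpart), except the Freedman–Lane test where a focal group duplicating
  the conditioning set legitimately yields $F = 0$, $p \approx 1$.
- Ties in best-fit selection go to the simpler (linear) model.
- Permutation p-values use the add-one convention, so the attainable
  minimum is $1/(n_{perm}+1)$.

## Problem sizes used in the test suite

The suite exercises the calibration and calibration-sensitive statistics at
sizes chosen to keep Monte Carlo error well inside the asserted tolerances:
200 paired communities per dilution level for the retention checks, 1000
random instances for the exact varpart identities, 500 simulated datasets
(n = 500) for the Fisher's C size check, 200 simulations (192- and 96-pot
designs) for coverage of OLS, mixed-model and model-averaged estimates, and
2000 simulations for the uniformity of Spearman p-values.

## Known limitations

- Variation partitioning is univariate-response only (no multivariate RDA
  partitioning or hierarchical partitioning over individual predictors).
- Piecewise SEM supports no latent variables, correlated-error claims or
  model search; the basis set follows the union-of-parents rule, which is
  conservative for DAGs where finer separating sets exist.
- `model_average()` is all-subsets and therefore capped at 12 predictors.
- The mixed-model wrapper fits exactly one random intercept — the design
  contract of the microcosm analysis — not general random-effect
  structures.
- Threshold counts depend on the analyzed sample set through the observed
  maxima (see above).
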