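# befmf — biodiversity–ecosystem-function multifunctionality analysis

`befmf` implements the statistical machinery used to link plant and soil
microbial diversity to **ecosystem multifunctionality (EMF)** — the capacity
of a site, plot or pot to sustain many ecosystem functions at once. It is
aimed at ecologists analysing biodiversity–ecosystem-function (BEF) data
from observational surveys or manipulative experiments, and at
methodologists who want the individual building blocks (multifunctionality
indices, variation partitioning, multimodel inference, piecewise SEM) as
tested, reusable functions rather than one-off analysis scripts.

## What it computes

**Multifunctionality indices.** Every raw function *f* is min–max
standardized, `(f − min f) / (max f − min f)` (optionally after a log10 or
square-root transform). Functions are averaged within named *ecosystem
services*, and

- the **weighted EMF** is the mean over service means, so every service
  contributes equally regardless of how many functions it holds;
- the **averaged EMF** is the flat mean over all standardized functions.

**Multi-threshold profiles.** For each threshold *t* ∈ (0, 100), the count
per sample of functions exceeding *t*% of the maximum observed level of that
function, and the OLS slope of that count on a diversity metric — the
slope-versus-threshold curve shows whether diversity supports high or low
levels of functioning.

**Composite richness.** Richness of each organism group (plants, bacteria,
fungi, fungal guilds) min–max standardized and averaged equally (microbial,
multitrophic composites).

**Variation partitioning.** The adjusted R² (Ezekiel,
`1 − (1 − R²)(n − 1)/(n − p − 1)`) of a response is decomposed over 2–4
predictor groups into unique and shared fractions by inclusion–exclusion
over all subset models; fractions sum exactly to the full-model adjusted R²,
negative fractions are reported raw and truncated to 0, and each unique
fraction gets a Freedman–Lane permutation p-value (pseudo-F on permuted
reduced-model residuals).

**AICc multimodel inference.** All-subsets OLS on z-scored data, Akaike
weights `w ∝ exp(−ΔAICc/2)`, model-averaged standardized coefficients
(zero-method by default, natural averaging available), unconditional SEs,
and predictor importance `100·|β̄_j| / Σ|β̄|`.

**Mixed models.** A single-random-intercept Gaussian mixed model (REML via
`lme4`/`lmerTest`), the contract used for pot experiments where the plant
species *combination* is a random effect.

**Piecewise SEM.** A user-declared DAG fit as separate local regressions;
standardized path coefficients, direct/indirect/total effects, the
d-separation basis set (union-of-parents conditioning), and Fisher's
`C = −2 Σ ln p_i ~ χ²(2k)`, with the model accepted when `p_C > 0.05`.
Composite variables (e.g. microbial richness from bacterial + fungal
richness) are supported.

**Covariates.** Aridity index (MAP/PET) with the UNEP classes (hyperarid
< 0.05 ≤ arid < 0.2 ≤ semiarid < 0.5 ≤ dry subhumid < 0.65 ≤ humid),
leading PCA axis of mixed-unit environmental tables, leading PCoA axis of
Jaccard distances on presence/absence community tables, and the Shannon
index.

**Synthetic data with known ground truth.** Two generators emulate the
study designs this machinery is built for: a full-factorial *microcosm*
experiment (plant richness 1–4 from a 5-species pool × HD/MD/LD
dilution-to-extinction microbial diversity × drought, 16 functions in 6
services, random plant-combination intercepts) and a *global grassland
survey* (101 sites, humid → hyperarid aridity gradient, 5 functions in 3
services). Dilution is modelled as independent Bernoulli survival per zOTU,
calibrated so MD retains 91% of bacterial and 86% of fungal richness and LD
retains 48% and 27% (i.e. reductions of 9/14% and 52/73%). Every dataset
ships its generating betas, realized random effects and realized retention.

## Worked example

```r
library(befmf)

cfg <- microcosm_config(seed = 1)          # packaged study conditions
dat <- generate_microcosm(cfg)             # 192 pots, 16 functions
mf  <- multifunctionality(dat$functions, dat$service_map)
mf
#> Ecosystem multifunctionality
#>   192 samples, 16 functions in 6 services
#>   weighted EMF:  mean 0.482  range [0.226, 0.724]
#>   averaged EMF:  mean 0.480  range [0.216, 0.714]

micro <- composite_richness(dat$diversity[, c("bacteria", "fungi")])
varpart(mf$emf_weighted,
        list(plant = dat$diversity$plant_richness,
             microbial = micro,
             drought = dat$design$drought),
        nperm = 999, seed = 17)
#> Variation partitioning (adjusted R^2), n = 192
#>   full model R^2adj = 0.6581
#>                 fraction     raw truncated     p
#>                    plant  0.3570    0.3570 0.001
#>                microbial  0.2669    0.2669 0.001
#>          plant:microbial -0.0039    0.0000    NA
#>                  drought  0.0424    0.0424 0.001
#>            plant:drought -0.0021    0.0000    NA
#>        microbial:drought -0.0022    0.0000    NA
#>  plant:microbial:drought  0.0000    0.0000    NA
#>                 residual  0.3419    0.3419    NA
```

Plant and microbial richness each explain a sizeable unique share of
multifunctionality (35.7% and 26.7% of the variance, both p = 0.001, the
minimum attainable with 999 permutations), drought a smaller one, and the
overlaps are negligible — as expected here, since the generator draws the
three drivers near-orthogonally. Model averaging tells the same story in
importance terms:

```r
model_average(mf$emf_weighted,
              cbind(plant = dat$diversity$plant_richness,
                    microbial = micro, drought = dat$design$drought))
#> AICc model averaging (zero method), 8 models, n = 192
#>           beta_avg     se importance_pct
#> plant       0.5958 0.0423           45.1
#> microbial   0.5157 0.0423           39.0
#> drought    -0.2091 0.0423           15.8
#> model-averaged R^2adj = 0.6581
```

The whole chain — generation, EMF, threshold curves, variation
partitioning, model averaging and a piecewise SEM — can also be run with
one call: `run_pipeline("microcosm", seed = 1, out_dir = "out")`.

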