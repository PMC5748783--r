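---
title: "Modeling protein and amino acid adequacy under plant-for-animal substitution"
author: "protswap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling protein and amino acid adequacy under plant-for-animal substitution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protswap)
```

## The question

Western diets obtain roughly two thirds of their protein from animal foods.
As populations shift toward plant protein, two distinct risks appear: plant
foods consumed today (dominated by cereals) carry less protein per calorie
than animal foods, so an energy-neutral substitution lowers total protein
intake; and cereal protein is poor in lysine, so at high plant shares the
*quality* of protein — its indispensable amino acid (IAA) profile — can
become limiting even where quantity is not. `protswap` implements the full
chain needed to quantify both risks from multi-day food records: misreporter
screening, usual-intake estimation, probability-approach adequacy, and
graded substitution simulation.

## The probability approach

For a nutrient with Estimated Average Requirement `EAR` and requirement
coefficient of variation `cv` (default 0.125 for protein and all IAA),
an individual with usual intake $y$ (per kg body weight) has inadequacy
probability

$$ P(\text{requirement} > y) = \Phi\!\left(\frac{EAR - y}{cv \cdot EAR}\right), $$

with $\Phi$ the standard normal CDF. At $y = EAR$ this is exactly 50%; at
$y = EAR(1 + 2\,cv)$ it is $1 - \Phi(2) = 2.275\%$ — note that the exact CDF
gives 97.72% adequacy at two requirement SDs, not the conventionally quoted
97.5%; the package uses the exact value. Population prevalence is the
survey-weighted mean of individual probabilities — the best estimate of the
proportion of the population below its own requirement — and carries a Wald
binomial interval $p \pm z\sqrt{p(100-p)/n}$ computed on the *unweighted*
sample size. Weights therefore move the point estimate but not the CI
half-width; this matches how such intervals are reported at the reference
sample size of 1678 and is a documented limitation rather than a
design-effect-corrected interval.

Protein EARs default to 0.66 g/kg/day and the nine IAA EARs to the
FAO/WHO/UNU adult values (his 10, ile 20, leu 39, lys 30, SAA 15, AAA 25,
thr 15, trp 4, val 26 mg/kg/day); all are overridable via `ear_table()`.
Sulfur (met+cys) and aromatic (phe+tyr) amino acids are pooled because their
requirements are defined jointly; single amino acids beyond the nine keys
are out of scope.

## From records to usual intakes

`daily_nutrients()` converts (food, grams) consumptions with a composition
table into daily protein, energy and IAA intakes. Each food's protein is
split into animal and plant parts by its `animal_protein_fraction`; the
plant part — protein *and* the amino acids computed from it — is multiplied
by a digestibility penalty (default 0.95), encoding the roughly 5% lower
real ileal digestibility of plant protein. The penalty is applied before
any intake or adequacy quantity is computed, so all reported intakes are on
the penalised scale.

`usual_intakes()` removes within-person day-to-day variability with a
simplified Multiple-Source-Method core, per nutrient:

1. **Box-Cox transform**, power fitted once on the pooled daily values by a
   profile-likelihood grid search over $[-1, 2]$ in steps of 0.1, ties
   broken toward $\lambda = 1$ (no transform).
2. **One-way variance decomposition** (method of moments, unbalanced-design
   correction) into between-person $\sigma^2_b$ and within-person
   $\sigma^2_w$ components; a negative moment estimate of $\sigma^2_b$ is
   clipped to zero.
3. **Shrinkage**: the individual's transformed mean is pulled toward the
   population mean by the best-linear-unbiased-predictor factor
   $\sigma^2_b / (\sigma^2_b + \sigma^2_w / D_i)$, $D_i$ the individual's
   number of recorded days.
4. **Back-transform** with the second-order correction
   $g^{-1}(t) + \tfrac12 \sigma^2_w\, (g^{-1})''(t)$, which for the log
   transform reduces to the familiar half-variance factor
   $\exp(t + \sigma^2_w/2)$.

The full MSM's covariate regression and consumption-probability component
are deliberately omitted: protein and amino acids are consumed every day,
so there is no episodic part to model, and no covariate specification is
imposed. Two consequences are documented rather than hidden. First,
shrinkage compresses the between-person spread, so the *distribution* of
usual intakes is slightly narrower than the true usual-intake distribution
(prevalences in the tails are correspondingly conservative). Second, the
half-variance back-transform targets each individual's mean on the original
scale but can shift the *population* mean by a percent or two when the
between-person variance is sizeable; tests therefore verify generator
targets on the raw daily means and verify the estimator separately by
parameter recovery (variance components recovered within 15% at n = 500,
7 days). Degenerate inputs (zero variance, non-positive values) fall back
to individual means with a warning.

## Misreporter screening

Energy misreporting is screened with the Goldberg cut-off in Black's
confidence-limit form: the plausible EI:BMR window for physical activity
level `PAL` is $PAL \times \exp(\mp 1.96\, s/100)$ with
$s = \sqrt{CV_{EI}^2/D + CV_{BMR}^2 + CV_{PAL}^2}$ and the standard
constants 23%, 8.5% and 15%. PALs 1.4 / 1.6 / 1.8 map from little active /
moderately active / active lifestyles. Basal metabolic rate comes from the
Henry (2005) coefficient tables, both the weight-only and weight-and-height
variants (selectable; the weight-height form is the default as the more
precise one). The EI:BMR ratio uses *total* reported energy including
alcohol — misreporting concerns total energy — while all substitution
accounting later uses non-alcohol energy only. Ages strictly above 65 are
excluded (a 65.0-year-old is retained); the bound is configurable.

## The substitution models

Substitution acts on each individual's mean daily food pattern. A fraction
$s$ of the individual's *substitutable* animal protein is removed by scaling
every substitutable animal food's grams by $1 - s$, which keeps the
proportion of protein from each animal food within total animal protein
constant. Animal protein embedded in mixed dishes marked non-substitutable
stays in the diet, which is why the attainable plant share saturates below
100%. The removed quantity is then replaced:

* **Model P** (protein-conserving): the removed *protein* is added back from
  the plant foods the individual already consumes, scaled on their
  plant-protein pattern. Total (pre-penalty) protein is conserved exactly;
  energy inflates, since plant foods carry more energy per gram of protein.
* **Model A** (energy-conserving): the removed *non-alcohol energy* is added
  from the individual's own plant foods, scaled on their plant-energy
  pattern. Energy is conserved exactly; protein falls.
* **Model B**: the removed energy is supplied by a population-level mix of
  legumes, nuts and seeds (LNS), with per-food shares proportional to the
  observed population intake on the energy basis (`build_lns_mix()`; the
  basis is switchable to protein, as the observation is not tied to one
  currency).
* **Model C** with LNS fraction $\lambda$: $\lambda$ of the removed energy
  via the LNS mix, $1 - \lambda$ via the Model-A pattern; $\lambda = 0$ and
  $1$ recover Models A and B.

Both conservation laws hold to 1e-9 relative at every grid point — they are
algebraic identities of the construction, and the test suite checks them on
a two-food toy diet and on synthetic populations. The added plant protein
carries the digestibility penalty like all other plant protein.

`simulate_curve()` applies the substitution to every individual, shifts
each individual's usual intakes by the resulting deterministic per-kg delta,
and recomputes prevalence per nutrient. Shifting the usual intake, rather
than re-estimating it from perturbed records, is exact under the model's own
assumption: the substitution changes an individual's mean pattern, not their
day-to-day variability, so within-person variance is unchanged.
`find_crossing()` then locates, by linear interpolation on the (mean plant
share, prevalence) pairs, the plant-protein share at which a prevalence
level (say 5%) is crossed; a level never bracketed returns `NA` rather than
an error. The default grid is $s = 0, 0.02, \ldots, 1$.

## The synthetic survey generator

The real survey microdata behind this kind of analysis are not
redistributable, so the package ships a generator whose defaults *are* the
study conditions: 1678 adults (717 men, 961 women), 7-day records, mean
penalised protein intake 1.34 (men) and 1.25 (women) g/kg/day with 20%
between-person CV, 31% of protein from plants (SD 0.06 across individuals),
cereals 67% of plant protein, meat 59% (men) / 51% (women) of animal
protein, 25% within-person day-to-day CV, and 5% of animal protein embedded
in mixed dishes. The 24-food composition table is anchored on well-known
food-science values: cereals at ~15% protein as energy and lysine
~30 mg/g protein, legumes at 25–30% protein as energy and lysine
~70 mg/g protein, red meat lysine ~90 mg/g protein, meat at 50–80% protein
as energy.

Choices the sources leave open, fixed here once as field-realistic values:
anthropometry (men 77 ± 11 kg, 176 ± 7 cm; women 63 ± 10 kg, 163 ± 6 cm),
activity distribution (30/50/20% low/moderate/high with ±0.07 PAL noise),
survey weights lognormal with CV 0.4 normalised to mean one, per-individual
jitter of the within-animal and within-plant group weights (lognormal,
SD 0.25–0.35 on the log scale; the cereal/non-cereal split is drawn on the
logit scale so its mean is essentially unbiased), equal splits among foods
within a group, and a zero-protein added-fats-and-sugar item that tops each
individual's energy up to BMR × PAL so that screening retains essentially
everyone by construction. Day-to-day noise is a single mean-preserving
lognormal multiplier per individual-day applied to the whole pattern:
nutrient-level day CVs equal the configured value exactly, at the price of
perfect within-day correlation across foods. Consecutive-day
autocorrelation is deliberately not modelled (the estimator itself assumes
independence); nor are intake–plant-share correlations, seasonal effects,
under-reporting behaviour, or the long tail of a real food list. Passing
tests on this world therefore demonstrate the *machinery* — conservation
laws, estimator calibration, qualitative orderings — not empirical claims
about any real population.

## What the simulations show on the synthetic defaults

Running `scripts/acceptance.R` (n = 1678, one CPU, a few seconds)
reproduces the qualitative structure expected from the science: baseline
protein inadequacy is a fraction of a percent and every IAA is lower still;
under Model A protein inadequacy rises monotonically with the plant share
and crosses 5% near a 47% plant share, lysine crosses later, and lysine
overtakes protein only above ~80% plant share; adding LNS to the
substituting mix (C models, then B) pushes every crossing to higher plant
shares, in strict λ-order; Model P conserves protein but inflates energy by
several hundred kcal per 10 points of plant share. In this synthetic world
Model P's lysine inadequacy never reaches 5% — its plant pattern retains
enough lysine from potatoes, vegetables and soy — which the script reports
by omitting that crossing rather than forcing a number.

## Numerical choices and edge cases

* Box-Cox requires strictly positive values; an all-zero nutrient (nobody
  consumes it) returns means with a warning instead of failing.
* The λ grid tie-break prefers the identity transform for parsimony.
* Crossing detection returns the grid point itself on an exact hit and the
  first crossing in increasing-share order when the curve is not monotone.
* Individuals with no plant foods cannot be substituted under Models P or A;
  the error directs users to λ > 0 rather than silently skipping them.
* Probabilities are clipped to [0, 1] and prevalences to [0, 100]; the
  requirement distribution is normal (no lognormal-requirement option), as
  the probability approach specifies.
* CSV round-trips preserve 15 significant digits; all randomness flows from
  a single integer seed, and equal seeds give byte-identical outputs.

## Known limitations

The estimator is a deliberate simplification of the full Multiple Source
Method (no covariates, no episodic component, shrinkage-compressed tails).
Wald intervals ignore the survey design effect. Mixed dishes are not
decomposed into ingredients — they carry a single animal-protein fraction
and contribute to one food group, so group contribution tables count a mixed
dish's protein in its assigned group. Substitution behaviour is homogeneous
across individuals by construction; no diet optimisation, cost, or
environmental accounting is attempted.
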