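---
title: "Fragment-contribution models for skin permeability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-contribution models for skin permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(fragkin))
```

## The model

The permeability coefficient Kp (cm/s) of a compound through excised human
skin is modeled on the log10 scale as a linear function of functional-group
counts:

$$\log K_p = a_0 + \sum_{j=1}^{n} a_j x_j$$

where $x_j$ is the number of occurrences of group $j$ in the molecule and
$a_j$ its additive contribution. The intercept $a_0$ is the best estimate of
logKp when no modeled group is present (or none has an effect). Ten groups
are modeled — amide, amine, aromatic, bromine, carboxylic acid, chlorine,
ester, ether, hydroxyl, ketone — chosen as the most commonly encountered in
the source permeability database. Multiplicity matters: a molecule with two
aromatic rings receives the aromatic contribution twice.

The model's appeal is that it needs no measured or estimated physicochemical
property. Its cost is a strong additivity assumption: group effects are
independent of position, neighbouring substituents and molecular size. A
halogen attached to an aromatic ring contributes the same as one on an alkyl
chain; intramolecular hydrogen bonding, which can mask a hydroxyl's effect
on partitioning, is invisible. These are accepted limitations of the model
class, not implementation choices.

## Fitting: normal equations, σ̂, significance, elimination

Coefficients minimise $q = \sum_i (y_i - a_0 - \sum_j a_j x_{ij})^2$, whose
matrix solution is $\mathbf{a} = (X^TX)^{-1}(X^TY)$ with $X$ the $m \times
(n+1)$ design matrix whose first column is all ones. `fitOLS()` solves by QR
decomposition for stability but reports $c_{jj}$, the diagonal of
$(X^TX)^{-1}$, from the explicitly formed inverse, because the significance
criterion is defined on it. A reciprocal condition number below $10^{-12}$
raises a typed error suggesting removal of collinear or constant columns
rather than returning meaningless coefficients.

The residual standard deviation is the maximum-likelihood estimate

$$\hat\sigma = \sqrt{\frac{Y^TY - \mathbf{a}^TX^TY}{m}}$$

dividing by $m$, not by the residual degrees of freedom. This is the
estimator the method defines, and it is the default; the unbiased
$m-n-1$ variant is available (`sigmaHat(..., unbiased = TRUE)`) because
which of the two the original spreadsheet fits used cannot be determined.
For the model sizes involved (m of tens to hundreds, n ≤ 10) the difference
is a few percent of σ̂.

A coefficient is declared **not** significantly different from zero when

$$|a_j| < t_{df} \cdot \hat\sigma \sqrt{\frac{m\,|c_{jj}|}{df}}$$

with $t_{df}$ the two-sided critical value at the chosen level (default
α = 0.05, the conventional limit). The source formula writes the degrees of
freedom as $m - n$ while fitting $n+1$ parameters; this is ambiguous, so the
package defaults to $df = m - (\text{parameters fitted}) = m - n - 1$, with
`dfMode = "terms"` giving $m - n$. At the data sizes here the two t quantiles
differ in the third decimal and never flipped a flag in our testing. Two
degenerate cases are pinned down explicitly: with a perfect fit the
threshold collapses to zero, and a nonzero coefficient is then significant
while an exactly-zero one is not.

Model selection is **top-down elimination**: fit the full ten-group model,
remove the single least significant non-significant term, refit, and repeat
until every remaining term passes. "Least significant" is the smallest
ratio $|a_j| / \text{threshold}_j$; exact ties are broken by smaller
$|a_j|$, then alphabetically, so the procedure is deterministic. The
intercept is never a candidate. The overall ANOVA F,
$F = (SSR/n)/(SSE/(m-n-1))$ with its upper-tail p, is reported with every
fit (the source text does not print its formula; this is the standard
overall-regression test).

Two R² conventions are supported and always distinguishable:
`rSquared(..., "sst")` is $1 - SSE/SST$ (default for training fits, can be
negative for a bad fixed model) and `"pearson"` is the squared correlation
of predictions with observations, the natural choice for a fixed model on
held-out data — a published test-set R² exceeding the training R² on a
7-compound test set is consistent with either reading, so evaluation reports
both.

## The published models and their transcription

All registry constants live in `inst/extdata/models.dcf`, one plain-text
block per model, so every number can be proofread against its source line by
line. Three transcription decisions were needed:

* one scenario row prints only "−6.063 (Hydroxyl)", which could be a
  constant or a hydroxyl coefficient with no intercept; it is stored as a
  constant model with a provenance note;
* rows with R² printed as "N/A" are constant-only models (coefficients
  empty);
* one temperature bin printed as "36–ss40" is read as 36–40.

Exactly 27 scenario models are registered over the 96 possible scenario
keys (3 sources × 4 layers × 2 donor classes × 4 temperature bins); the
tests assert the count, the key validity, and that every model returns its
transcribed intercept bit-exactly at the all-zero profile.

The DERMWIN comparator is stored as printed, on the log10 cm/h scale;
`convertLogKpPerHourToPerSecond()` applies the −log10(3600) shift before
residual metrics. Potts & Guy constants are not printed in the source and
are therefore not bundled: `comparatorModel()` accepts user-supplied
constants from the original reference.

## Counting fragments

The source defines the ten groups only by name. The package fixes one SMARTS
pattern per group (see `fragmentSmarts()`), with precedence encoded in the
patterns so that each atom feeds at most one group:

* a carbonyl carbon is carboxylic acid, ester, amide or ketone — never two
  of these (the ketone pattern requires two carbon neighbours, which is
  structurally incompatible with the other three);
* a divalent oxygen is an acid OH, ester bridge, ether or hydroxyl — never
  two (ether and hydroxyl patterns exclude oxygens on a carbonyl carbon);
* amine excludes amide nitrogens, nitro groups, and aromatic ring nitrogens;
  anilines count as amines.

"Aromatic" is counted as the number of aromatic rings in the smallest set of
smallest rings, so naphthalene counts 2 — consistent with the published
"× 2" multiplicity convention for a two-ring compound. Two conventions the
source leaves open are resolved permissively and documented here:
heteroaromatic rings (pyridine) count as aromatic, and phenolic OH counts as
hydroxyl (the methyl-phenol literature context behind the model suggests
both). Aldehydes match none of the ten patterns and contribute zero — a
documented property of the model, not an error. Matches are deduplicated by
matched atom set, so symmetric molecules are not double-counted.

Parsing and matching are delegated to OpenBabel via ChemmineR/ChemmineOB;
counts are invariant to SMILES spelling (tested over frozen atom-renumbered
spellings) and to explicit hydrogens. The seven excluded groups — boron,
cyanide, epoxide, fluorine, nitro, phosphate, thiol — use deliberately broad
patterns, since they act only as an applicability filter: a compound
carrying any of them is flagged ineligible for the published models
(prediction proceeds with a warning if forced).

## Record selection and stratification

`readRecords()` consumes a documented CSV schema mirroring the public
database fields (compound, smiles, logkp or kp_cm_s, source, layer, donor,
temperature_c, ph, reference). Validation failures go to a rejects report
with row numbers; nothing is silently dropped. Donor-class vocabulary is
normalized ("neat"/"concentrated" → saturated). Temperature bins are closed
integer bins (20–25, …, 36–40) with nearest-integer rounding first, since
the printed bins tile integers, not reals.

The published reduction of multiple measurements to one per compound names
the preferred conditions but not a full procedure. The package applies the
preference lists lexicographically (source, then layer, then donor, then
temperature bin) and resolves remaining ties by averaging logKp, logging
every merge — deterministic and auditable. Records with missing pH are kept
by default (the published selection maximised dataset size); a strict mode
drops them. Outlier removal defaults to "none" because the published rule is
unstated; the opt-in z-rule drops records more than τ standard deviations
from their stratum mean, skipping strata smaller than 3 or with zero spread.

## Synthetic data: what it does and does not emulate

`generateProfiles()` draws counts independently per group from Poisson
distributions with rates 0.3–0.8 (defaults in `defaultCountRates()`),
calibrated so most synthetic molecules carry one to three functional groups,
as small drug-like molecules do, while keeping the design matrix full-rank.
`generateDataset()` adds Gaussian noise of configurable standard deviation to
the model prediction. A deterministic grid design (`gridProfiles()`: the
zero row, unit and doubled unit vectors, and adjacent pairs — 31 full-rank
rows with counts 0–2) supports exact-recovery checks.

This emulates exactly the statistical structure the regression assumes —
independent count covariates, additive homoscedastic noise — and therefore
validates the *fitting machinery*, not the *chemistry*. Real fragment counts
are correlated (esters co-occur with ethers, aromatic rings with halogens),
noise on measured logKp is neither independent nor Gaussian across
laboratories, and no synthetic compound violates additivity. Passing
recovery tests shows the solver and elimination behave correctly under the
model's own assumptions; it says nothing about how well the model class fits
real skin data.

Problem sizes used in the tests were chosen to make the statistical
assertions sharp at desk scale: exact recovery on the 31-row grid
(tolerance 1e-9), stochastic recovery at n = 500 and noise sd 0.3 over 20
seeds (mean absolute coefficient error < 0.05), elimination of a planted
noise column at n = 200 over 50 seeds (≥ 90% success), oracle agreement with
`lm()` on 100 random instances at relative tolerance 1e-8, and a
Kolmogorov–Smirnov uniformity check of the ANOVA p under the null over 500
replicates.

## What is deliberately out of scope

The published training/test R² and RMSE of the two headline equations are
not reproduced: they depend on the full database download, unrecorded
outlier exclusions, and an unrecorded random 80:20 split. The package
instead verifies everything that is checkable from the printed constants
(intercepts, individual contributions, the correlation p-values recomputed
from printed R² and n — both match within the rounding of the printed
inputs) and validates the machinery on synthetic data. There is no tautomer
or protonation handling, no 3D structure, no regularized regression, no
cross-validation beyond the single split, and no applicability-domain
scoring beyond the excluded-group flag: predictions for compounds far from
the training chemistry should be treated with caution regardless of the
flag.

## A compact demonstration

```{r demo}
prof <- countFragments("CC(=O)Oc1ccccc1C(=O)O")  # aspirin
fragmentCounts(prof)[fragmentCounts(prof) > 0]
predictLogKp(getModel("eq2"), prof)

d <- generateDataset(getModel("eq2"), n = 500, noiseSd = 0.3, seed = 42)
w <- fitWorkflow(d$profiles, d$logkp, alpha = 0.05, seed = 42)
w$trace@steps
round(w$model@coefficients - getModel("eq2")@coefficients[names(w$model@coefficients)], 3)
```
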