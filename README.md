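# fragkin

Fragment-contribution (group-contribution) models for predicting the human
skin permeability coefficient.

## The problem

Whether a chemical crosses human skin — a drug in a transdermal patch, a
solvent on a production line, a UV filter in sunscreen — is summarised by its
permeability coefficient Kp (cm/s), conventionally modeled on the log10 scale
as logKp. Measuring Kp on human skin is slow and expensive, and most
predictive equations (Potts & Guy, DERMWIN) need physicochemical inputs such
as logKow and molecular weight. A fragment-contribution model needs none of
that: the predicted logKp is an intercept plus a fixed additive contribution
per occurrence of each functional group,

```
logKp = a0 + Σ_j a_j · x_j
```

where `x_j` counts occurrences of group `j` in the molecule (ten groups are
modeled: amide, amine, aromatic, bromine, carboxylic acid, chlorine, ester,
ether, hydroxyl, ketone). Anyone who can read a structural formula can apply
it.

`fragkin` is for researchers in percutaneous absorption and drug discovery
who want to (a) apply the published fragment equations to new compounds, and
(b) refit such models from their own permeability tables with the same
statistical machinery: ordinary least squares via the normal equations
`a = (XᵀX)⁻¹XᵀY`, a maximum-likelihood residual standard deviation
`σ̂ = sqrt((YᵀY − aᵀXᵀY)/m)`, the per-coefficient significance criterion
`|a_j| < t_{df} · σ̂ · sqrt(m·|c_jj|/df)`, and top-down elimination of
non-significant terms.

The package bundles, in one proofreadable plain-text file:

* **eq1** — the global ten-group equation (intercept −5.622, fitted on 180
  compounds);
* **eq2** — the selected scenario equation for abdomen / epidermis / diluted
  donor / 31–35 °C (intercept −4.916), the best-performing published model;
* all **27 scenario-stratified equations** over the 96 experimental scenarios
  (skin source × layer × donor concentration × temperature bin);
* the **DERMWIN** comparator `logKp (cm/h) = −2.80 + 0.66·logKow − 0.0056·MW`
  and a constructor for user-supplied comparators (e.g. Potts & Guy);
* the **mean-baseline** constant model, the floor any model must beat.

Functional groups are counted from SMILES by SMARTS matching
(ChemmineR/OpenBabel), with precedence rules so that each atom feeds at most
one group — an ester oxygen never double-counts as an ether, an acid OH
never as a hydroxyl. Seven "unusual" groups (boron, cyanide, epoxide,
fluorine, nitro, phosphate, thiol) flag a compound as outside the models'
applicability domain.

## Worked example

```r
library(fragkin)

prof <- countFragments("CC(=O)Oc1ccccc1C(=O)O")   # aspirin
prof
#> FragmentProfile: aromatic=1, carboxylic_acid=1, ester=1

predictLogKp(getModel("eq2"), prof)
#> [1] -6.124
```

The prediction is the intercept plus one contribution per occurrence:
−4.916 + 0.168 (aromatic) − 1.521 (carboxylic acid) + 0.145 (ester) =
−6.124, i.e. Kp ≈ 7.5 × 10⁻⁷ cm/s. A two-ring compound adds the aromatic
term twice.

Scenario-specific prediction and the applicability flag:

```r
m <- lookupScenario(ScenarioKey("abdomen", "epidermis", "diluted", "31-35"))
predictLogKp(m, prof)
#> [1] -6.173

excludedIn(countFragments("Fc1ccccc1"))
#> [1] "fluorine"     # outside the models' domain
```

Refitting a model from a permeability table (here a synthetic one):

```r
d <- generateDataset(getModel("eq2"), n = 500, noiseSd = 0.3, seed = 42)
w <- fitWorkflow(d$profiles, d$logkp, alpha = 0.05, seed = 42)
w$model
#> FragmentModel 'fitted': logKp = -4.924 -0.166 (amide) -1.155 (amine)
#>   +0.153 (aromatic) -1.496 (carboxylic_acid) +0.679 (chlorine)
#>   +0.137 (ester) +0.588 (ether) -0.528 (hydroxyl) -0.126 (ketone)
w$trainReport$rmse
#> [1] 0.315
```

Top-down elimination removed the bromine term (its generating coefficient is
zero); every surviving coefficient sits within a few hundredths of its
generating value. The CLI wraps the same functions:

```sh
Rscript inst/scripts/fragkin.R predict --model eq2 --smiles "CC(=O)Oc1ccccc1C(=O)O"
Rscript inst/scripts/fragkin.R prepare --input my_table.csv --output prepared.csv
Rscript inst/scripts/fragkin.R fit --input prepared.csv --seed 1 --output-dir out/
```

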