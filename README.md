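# nestsym

Procrustes ANOVA for biological shapes with simple or hierarchically
**nested symmetries**, in R.

Geometric morphometrics routinely separates shape variation in
bilaterally symmetric structures into among-individual variation,
directional asymmetry (DA, the population-average deviation from perfect
symmetry) and fluctuating asymmetry (FA, small random individual
deviations). Many phenotypes, however, combine symmetries hierarchically:
the motivating case here is the Aristotle's lantern of regular sea
urchins, whose five pyramids are each bilaterally symmetric (object
symmetry, group C1v) while being arranged with five-fold rotational
matching symmetry (group C5), the whole forming C5v. `nestsym` is for
morphometricians who want to decompose and test such variation at every
level of the symmetric organisation.

## The models

For landmark configurations Y indexed by individual *i*, part *j*,
reflection copy *k* and replicate *r* (all analyses operate on
partial-GPA tangent coordinates):

* **Analysis A1** (rotational matching symmetry; parts symmetrized
  first): `Y_ijr = mu + a_i + beta_j + (ab)_ij + E_ijr` — a two-way mixed
  model with individual random, part fixed (rotational DA), their
  interaction the rotational FA.
* **Analysis A2** (bilateral object symmetry, parts pooled across
  individuals after a mean correction): `Y_jkr = mu + alpha_j + beta_k +
  (alphabeta)_jk + E_jkr` — fixed part and reflection (bilateral DA)
  effects and their interaction (bilateral FA), tested against the
  symmetric and asymmetric components of measurement error respectively.
* **Analysis A3** (bilateral nested in rotational, C5v):
  `Y_ijkr = mu + a_i + beta_j + gamma_k(j) + (ab)_ij + (ag)_ik(j) +
  E_r(ijk)` — individual and both FA terms random, rotational DA
  (`beta_j`) and nested bilateral DA (`gamma_k(j)`) fixed.

Effects are tested with Goodall's F (conventional df multiplied by the
dimension of the symmetric or asymmetric tangent subspace the effect
occupies, 2p + u − 2 for p landmark pairs and u on-axis landmarks in 2D)
and, to relax the isotropy assumption, with Pillai's-trace MANOVA on a
generalized inverse, plus restricted permutation tests per effect.
Centroid-size ANOVA, expected-mean-square recovery of per-effect
covariance matrices, PCA/lollipop export of shape changes, a seeded
synthetic-data generator, TPS/CSV/YAML I/O and a command-line pipeline
complete the toolkit.

## Worked example

Simulate a lantern-structured dataset at the default study conditions
(10 individuals × 5 parts × 2 replicates, 12 landmarks) and fit the full
nested design:

```r
library(nestsym)
scheme <- lanternScheme()
sim <- simulateLanterns(varianceComponents(), scheme, seed = 1)
fit <- nestedAnova(sim$landmarks, scheme, nPerm = 999, seed = 2)
fit
#> Procrustes ANOVA effect table (design A3)
#>            effect convDf shapeDf         ss          ms         f       pParam pPerm  pillai pillaiPParam pillaiPPerm
#>        individual      9      90 0.08075400 8.97267e-04 91.379500 1.88462e-202 0.001 7.56627  6.57114e-85       0.001
#>              part      4      40 0.00075841 1.89603e-05  1.930950  9.57360e-04 0.002 1.55468  3.94322e-03       0.001
#>  reflectionInPart      5      50 0.00971658 1.94332e-04 11.611200  2.02172e-54 0.001 1.54632  2.63173e-03       0.001
#>          indXpart     36     360 0.00353488 9.81912e-06  0.586688  1.00000e+00 0.173      NA           NA          NA
#>    indXreflection     45     450 0.00753143 1.67365e-05  5.570540  6.31792e-67 0.001 8.29440  6.55591e-58       0.001
#>    symmetricError     45     450 0.00129593 2.87985e-06        NA           NA    NA      NA           NA          NA
#>   asymmetricError     45     450 0.00135201 3.00447e-06        NA           NA    NA      NA           NA          NA
#>        totalError     45     900 0.00264794 2.94216e-06        NA           NA    NA      NA           NA          NA
```

Reading the table: individuals differ strongly in symmetric shape
(`individual`, F = 91.4); there is clear bilateral DA nested in the parts
(`reflectionInPart`, F = 11.6) and bilateral FA (`indXreflection`,
F = 5.6), while rotational FA is absent by construction at these
magnitudes relative to its denominator (`indXpart`, F = 0.59, P ≈ 1) —
the same qualitative pattern as in the sea-urchin case study. Parametric
and permutation P values agree. Conventional df (9, 4, 5, 36, 45, …) are
multiplied by the subspace dimension (10) into shape df.

The generating variance components are recovered by the
expected-mean-squares estimator:

```r
round(estimateVarianceComponents(fit), 5)
#> sigmaIndividual      sigmaRotFA      sigmaBilFA      sigmaError
#>         0.00942         0.00190         0.00265         0.00163
```

(truth: 0.0111, 0.0019, 0.0027, 0.0016 shape units per tangent
coordinate). `effectCovariances()` + `lollipopData()` export per-landmark
shape-change vectors for each effect, and `centroidSizeAnova()` gives the
size table. From a shell, the same pipeline runs over TPS input:

```sh
Rscript inst/scripts/symmetry-anova.R --input data.tps --scheme scheme.yaml \
  --design A3 --nperm 10000 --seed 42 --out results/
```

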