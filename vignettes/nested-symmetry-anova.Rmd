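---
title: "Procrustes ANOVA for nested symmetries: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Procrustes ANOVA for nested symmetries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestsym)
```

## The problem

Many biological structures repeat a unit under a symmetry group: butterfly
wings under reflection, flower petals under rotation, body segments under
translation. Some structures combine symmetries hierarchically. The
motivating case implemented here is the masticatory apparatus of regular
sea urchins (the Aristotle's lantern): each of its five pyramids is
bilaterally symmetric about its interradial suture (object symmetry: the
axis passes through the part), and the five pyramids are arranged with
five-fold rotational symmetry around the oral axis (matching symmetry:
physically separate repeats), the whole forming the group C5v.

Given 2D landmark configurations digitized per pyramid — indexed by
individual, pyramid (1–5, oriented consistently across individuals, e.g.
against the madreporite), and digitizing replicate — the package
decomposes total shape variation into biologically meaningful components:

* among-individual (symmetric) variation,
* **directional asymmetry (DA)**: the population-average systematic
  deviation from perfect symmetry, a fixed effect (part or reflection
  main effect),
* **fluctuating asymmetry (FA)**: small random individual deviations
  around the DA, an individual-by-part or individual-by-reflection
  interaction,
* measurement error, estimable when replicates exist.

## Geometry

All analyses start from a partial generalized Procrustes analysis
(`partialGPA()`): configurations are centered, scaled to unit centroid
size, and rotated (never reflected — reflections would destroy exactly
the asymmetry signal under study; they enter only as explicit
transform-and-relabel copies) to minimize the summed squared distance to
an iteratively re-estimated consensus. The aligned pre-shapes are then
projected orthogonally onto the tangent plane at the consensus
(`tangentProjection()`); every statistical step operates on these tangent
coordinates. Convergence is declared when the consensus moves by less
than `tol = 1e-10` between iterations (cap `maxIter = 100`); the
objective is monitored and an increase raises a warning. The consensus is
initialized from the first configuration, which makes runs deterministic;
the overall orientation of the aligned set is therefore arbitrary up to
the orientation of that configuration, as in any GPA.

## Symmetry machinery

A `SymmetryScheme` declares the landmark pairing swapped by the bilateral
reflection, the on-axis (unpaired) landmarks, and the number of repeated
parts. The reflection convention negates the x coordinate; any axis works
after superimposition, and fixing one keeps runs reproducible.

For object symmetry the dataset is doubled with reflected-relabelled
copies (`expandObjectSymmetry()`). During the GPA of an expanded set the
consensus is additionally averaged with its own reflected copy each
iteration. This is exact, not a correction: the symmetric consensus is a
fixed point of the iteration, and enforcing it guarantees (i) a consensus
symmetric to machine precision and (ii) aligned mirror pairs that are
exact mirror images, which in turn makes the symmetric/asymmetric
decomposition exact rather than approximate.

With p landmark pairs and u on-axis landmarks in 2D, the symmetric and
asymmetric subspaces of the shape tangent space each have dimension
2p + u − 2: of the four similarity dimensions removed from the 2k raw
coordinates, translation along the axis and scale are symmetric while
translation across the axis and rotation are antisymmetric.
`subspaceProjectors()` builds both projectors at the consensus and
asserts the closed-form dimensions against the numerical ranks, guarding
against a scheme that does not match the data. For the lantern scheme
(p = 4, u = 4) both dimensions are 10.

## The three designs and their conventions

All designs assume complete balanced index grids; unbalanced data are
rejected rather than approximated, because every formula below relies on
balance.

**A1 — rotational matching symmetry** (`rotationalAnova()`). Each
configuration is first replaced by its symmetric average (the consensus
of itself and its reflected copy, `symmetrizeConfigs()`), the symmetrized
parts are aligned by one GPA, and a two-way mixed model is fitted:
individual (random) + part (fixed, rotational DA) + individual × part
(rotational FA, random) + error. F denominators: individual and part
against the interaction, the interaction against error. Shape degrees of
freedom are the conventional df times the symmetric-subspace dimension.

**A2 — bilateral object symmetry** (`bilateralAnova()`). The expanded
data are fitted with the two-way fixed-effects model part + reflection
(bilateral DA) + part × reflection (bilateral FA). Because labelled parts
are pooled across individuals, the records are first corrected for
differences in means: the default (`correction = "full"`) removes the
per-individual cell means in both subspaces — the individual effect, the
individual deviations from rotational symmetry, and the per-individual
bilateral-FA deviations — leaving pure replicate measurement error as the
error term. The alternative `correction = "symmetric"` removes only
symmetric-component means, in which case per-individual bilateral-FA
deviations remain in the asymmetric error (whose conventional df grows
accordingly). The part effect is tested against the symmetric component
of measurement error; reflection and the interaction against the
asymmetric component.

**A3 — nested symmetries** (`nestedAnova()`). The full mixed model with
crossed and nested factors: individual (random, symmetric subspace) +
part (fixed rotational DA, symmetric) + reflection-within-part (fixed
bilateral DA, asymmetric) + individual × part (rotational FA, symmetric)
+ individual × reflection-within-part (bilateral FA, asymmetric) + error.
Denominators: individual and part → individual × part;
reflection(part) and individual × part → individual × reflection(part);
individual × reflection(part) → asymmetric error. Note that the
rotational-FA term is thereby tested against a same-magnitude term from
the *other* subspace; this is the construction under which the reference
tables' F values reproduce, and the MANOVA column is left blank for that
row because Pillai's trace is not defined across subspaces.

**Size** (`centroidSizeAnova()`). The same two-way mixed design on
centroid size, with conventional degrees of freedom. Size asymmetry only
exists under matching symmetry — a structure analysed purely as object
symmetry has a single configuration and hence no size asymmetry — so
object-mode schemes are rejected.

### Sums of squares and df conventions

Two conventions deserve explicit statement because they are easy to get
wrong and are not interchangeable:

1. *Expanded-set SS are divided by the group order (2)*, so each physical
   observation counts once. This makes the symmetric error of A2/A3
   numerically identical to the measurement error of A1 on the same data,
   and makes A2's reflection + interaction SS sum exactly to A3's nested
   DA SS.
2. *Error degrees of freedom.* The replicate-contrast count is
   nInd × nParts × (r − 1) (50 for the lantern). The effect tables of the
   object-symmetry designs print nParts × (nInd − 1) × (r − 1) (45),
   the convention under which the reference F ratios reproduce (the
   per-part mean corrections of the pooled analysis are charged to the
   error term). Variance-component estimation
   (`effectCovariances()`, `estimateVarianceComponents()`) always uses
   the replicate-contrast df, because the printed convention would bias
   the error variance (and everything downstream of it) upward by
   50/45 − 1 ≈ 11%. The table is a testing surface; the EMS algebra is an
   estimation surface.

## Inference

**Goodall's F** compares Procrustes mean squares with shape degrees of
freedom, assuming isotropic variation around the mean shape. To relax
isotropy, each tested effect also carries a **Pillai trace** MANOVA:
trace(H (H+E)^−), with a generalized inverse (Moore–Penrose, singular
values below dim · eps · max treated as zero) because shape subspaces are
rank-deficient in the raw coordinate basis. The parametric P uses the
standard F approximation of Pillai's trace with the dimensionality taken
as the numerical rank of H + E and conventional df — the combination that
reproduces the reference tables' MANOVA P values.

**Permutation tests** (`permutationTest()`, or the `nPerm` argument of
the design functions) use restricted schemes per effect:

* random main effect: units (individual-by-part cells, with their
  replicate and reflection rows) permuted across individuals within part
  strata;
* fixed part main effect: part labels permuted within each individual;
* reflection and nested-reflection effects: reflection copies flipped
  per unit (within the nesting level by construction);
* interactions: residuals of the reduced model (main and nested fixed
  effects subtracted) permuted at the record level across all index
  slots, with reflected copies moving alongside their physical record,
  and the full statistic — numerator and denominator — recomputed from
  the permuted field.

The last point is a deliberate design choice. Permuting *cell-level*
residuals after subtracting the main effects looks natural but is badly
anti-conservative: the residualized field has exactly zero margins, so
the observed arrangement maximizes the interaction SS over all cell
rearrangements, and every permutation can only shrink it. Record-level
residual permutation with full refitting (the randomized-residual
approach common in modern morphometrics) removes that artifact because
re-estimated margins absorb a proportional share in both the numerator
and the denominator. The null calibration in the test suite checks the
part-effect scheme empirically (rejection rate at the 5% level inside the
99% binomial band over 200 null simulations with 999 permutations each).

P values use the add-one convention, P = (1 + #{permuted ≥ observed}) /
(1 + nPerm), and when fewer distinct permutations exist than requested
the exact P is computed by exhaustive enumeration with a notice. The
analysis functions default to `nPerm = 0` (parametric only) so that
Monte-Carlo studies can opt in; the command-line pipeline defaults to
10,000 permutations and demands a seed.

## Effect covariances and visualization

`effectCovariances()` recovers the covariance matrix attached to each
effect by subtracting mean-square matrices along the design's expected
mean squares — e.g. for the nested design, Cov(individual) =
(MS_individual − MS_indXpart) / (nParts · r); Cov(bilateral FA) =
(MS_indXrefl − MS_asymError) / r; the rotational-FA term subtracts the
*symmetric* error mean square, which is its EMS partner even though its
F denominator lies in the other subspace. Subtraction can produce
indefinite matrices on real data; they are reported as-is with a warning
(that is what gets visualized in common workflows), with `clip = TRUE`
available to truncate at zero, and `mode = "ms"` to skip subtraction
entirely. `pcaEffect()` and `lollipopData()` turn any of these matrices
into per-landmark displacement vectors anchored at the consensus
(scaled by the square root of the eigenvalue times an amplification
factor; ten-fold amplification is the conventional display choice for
subtle DA), exported as data rather than pixels.

## The synthetic-data generator

`simulateLanterns()` is the validation bed for every design. It draws the
random effects as isotropic Gaussians in the tangent space at a symmetric
template, each projected into its declared subspace — individual effect
and rotational FA into the symmetric subspace, bilateral FA into the
asymmetric one, measurement error into both — adds fixed rotational and
bilateral DA vectors (validated by projection to lie in their subspaces),
composes landmark configurations around the template, scales them to
centroid sizes drawn from an additive size model, and optionally applies
random rotations and translations that the GPA must remove. All
randomness flows from a single seed.

The default `varianceComponents()` are the study conditions of the
lantern case: 10 individuals × 5 parts × 2 replicates, 12 landmarks with
4 on-axis, and magnitudes back-calculated from the reference ANOVA via
the EMS relations — σ(individual) = 0.0111, σ(rotational FA) = 0.0019,
σ(bilateral FA) = 0.0027, σ(error) = 0.0016 shape units per tangent
coordinate, bilateral DA of norm 0.0103, per-part rotational DA of norm
0.00207, and millimetre-scale centroid sizes (mean 10) with the size
variance components implied by the size table. The default DA directions
are deterministic patterns built from the scheme (a sinusoid over parts
for the rotational level, a lateral shift of an on-axis landmark for the
bilateral level), so simulations are reproducible without a hidden seed.

What the generator emulates: the index structure, the subspace placement
of every variance component, balanced replicates, nuisance
position/orientation/scale, and realistic magnitudes. What it does not:
anisotropic or spatially correlated landmark noise (an optional
full-covariance error mode is deliberately out of the default path),
allometry, digitizing outliers, or unbalanced designs. Passing tests on
simulated data therefore certify the decomposition, df bookkeeping, and
estimator calibration — not robustness to violations of the Procrustes
ANOVA assumptions on real material.

## Numerical choices and degenerate inputs

* GPA convergence 1e-10 on consensus displacement, 100 iterations, error
  (with the iteration count) on non-convergence.
* Optimal rotations via SVD with a determinant sign fix restricting to
  SO(2).
* Degenerate configurations (all landmarks coincident) are rejected at
  centroid-size computation.
* A single replicate makes measurement error inestimable: the designs
  refuse it unless `allowSingleReplicate = TRUE` explicitly requests the
  reduced table.
* Zero denominator SS in an F ratio yields NA with a warning rather than
  infinity.
* Negative method-of-moments variance estimates are truncated at zero
  only in `estimateVarianceComponents()` (scalar summaries); covariance
  matrices keep their negative eigenvalues unless clipping is requested.

## Problem sizes used in the shipped checks

The test suite and the acceptance script validate on: the full lantern
structure (10 × 5 × 2, k = 12) for df bookkeeping, table reproduction
and 200-replicate variance recovery; a 6 × 3 × 2, k = 5 toy structure for
null calibration (200 runs × 999 permutations) and property sweeps
(100 random parameter draws); 2 × 2 structures for exhaustive-enumeration
checks; and n = 50 individuals for directional-asymmetry recovery. These
sizes give Monte-Carlo standard errors comfortably below the asserted
bands while keeping a full run in the minutes range on one CPU.

## Known limitations

Balanced 2D designs only (the data model accepts 3D coordinates, but
subspace dimension accounting and the designs are validated for 2D);
no sliding semilandmarks, missing-landmark estimation, REML for
unbalanced data, allometry correction, or across-effect multiple-testing
adjustment. Rotational copies are never generated for the matching level
— rotational symmetry of physically separate parts is bookkeeping on part
labels, not a coordinate transformation — so structures whose parts are
connected through the rotation axis need a different (pure object
symmetry) treatment.
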