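---
title: "From intracellular-pocket conformations to signaling efficacy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From intracellular-pocket conformations to signaling efficacy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketsig)
```

## The scientific problem

Agonists of 7TM receptors differ not only in potency but in *which*
transducer they engage: at the μ-opioid receptor, G-protein signaling
mediates analgesia while β-arrestin-2 recruitment is associated with adverse
effects, so quantifying both efficacies for a candidate ligand matters.
The working hypothesis of this package's model is that a ligand's maximal
efficacy along each pathway is determined by the equilibrium population of
intracellular-pocket conformations its complex samples: the pocket is the
surface the transducers engage, so a mixture weighted toward
transducer-competent shapes yields high efficacy. The pipeline estimates
those populations from structural ensembles and maps them linearly to
efficacy.

## Featurization

Each frame is reduced to three vectors over the intracellular half of the
receptor (defaults follow the μ-opioid construct; both the residue ranges
and anchors are arguments):

* **Torsions** ψ, φ, χ₁, χ₂ (radians, wrapped to [−π, π)) for every residue
  in four ranges spanning the intracellular ends of the TM bundle and
  helix 8 (residues 84–116, 156–194, 246–291, 328–349). Residues lacking an
  angle contribute only their defined angles (no χ for Gly/Ala, no χ₂ for
  Ser/Thr/Cys/Val); the realized angle list is stored in the
  `feature_spec`, so N<sub>θ</sub> is explicit. χ angles use the IUPAC
  heavy-atom definitions; for residues with symmetric terminal atoms the
  lower-numbered branch is used, making each dihedral's identity
  reproducible.
* **Cα distances** (Å) between all pairs of 22 anchor residues (helix
  midpoints/intracellular ends, loop middles) with sequence separation ≥ 2.
* **Hydrogen-bond donor–acceptor distances** (Å): every heavy-atom
  donor/acceptor pair (backbone N/O plus standard polar side-chain N and O
  atoms) among the intracellular residues whose distance in a user-supplied
  reference structure is within a cutoff (default 8 Å). Hydrogens are not
  required — the distance is between heavy atoms. Pairs within one residue
  are excluded, since their near-constant distances carry no conformational
  signal. Because donor/acceptor chemistry conventions vary between tools,
  the pair *count* obtained here may differ from other implementations;
  the derivation is deterministic given the convention above.

Dihedrals use the standard atan2 formulation and error on collinear
geometry. Featurization is rigid-motion invariant by construction and is
exercised against toy structures whose torsions and distances are placed
exactly by internal-coordinate (NeRF) construction.

## The configuration distance

Components are root-mean-square per-feature differences — periodic for
torsions (Δ = min(|a−b|, 2π−|a−b|)) — and the combined distance is the
convex combination w<sub>θ</sub>d<sub>θ</sub> + w<sub>C</sub>d<sub>C</sub> +
w<sub>H</sub>d<sub>H</sub> with weights summing to one. The RMS
normalization makes the three components commensurate despite very
different dimensionalities (hundreds of torsions versus hundreds of
distance pairs on different scales), which a weighted sum presupposes; both
the per-component form and the linear combination are isolated behind
`torsion_component()` / `vector_component()` / `combined_distance()` so
either choice can be swapped without touching the rest of the pipeline.
Torsions are radians throughout; the combined distance is unitless only in
the sense that its weights absorb the Å/radian mix.

An important computational property follows: for fixed features the
combined distance is *linear in the weights*, so the three component
matrices are computed once (`component_matrices()`) and every weight
pattern in a grid search is a cheap matrix combination.

## Two-stage conformation clustering

1. Complete-linkage agglomerative clustering (`stats::hclust`) of the
   pairwise distance matrix, cut at *H* clusters. Complete linkage bounds
   within-cluster diameter, appropriate for carving a continuous ensemble
   into compact states.
2. Each cluster is represented by its **medoid** (the member minimizing
   summed distance to the others; ties go to the lowest frame index). A
   medoid–medoid distance matrix is converted to a Gaussian similarity
   S = exp(−D²/2δ²) and grouped into *C* conformations by spectral
   clustering with **pivoted-QR assignment**: the C leading eigenvectors of
   the symmetrically normalized affinity (rescaled by inverse square-root
   degree) are clustered by column-pivoted QR + SVD alignment. Unlike
   k-means assignment this stage has no random initialization, so the whole
   model is a deterministic function of its inputs — a property the tests
   assert directly.

When frames carry Cartesian coordinates, the medoid–medoid matrix is the
superposed Cα RMSD (proper-rotation Kabsch, `superpose_rmsd()`), with the
RMSD atom set defaulting to the Cα atoms of the intracellular ranges — the
object of study. Feature-table-only inputs (the synthetic scenarios, or any
precomputed feature CSV) have no coordinates, so the medoid distances
default to the combined feature-space distance (`medoid_metric =
"feature"`). The two metrics order medoid pairs very similarly — both are
dominated by the same intracellular rearrangements — and the choice is an
explicit argument of `fit_conformation_model()`.

Degenerate corner: `c == h` bypasses the spectral stage with the identity
map (every hierarchical cluster its own conformation); the spectral routine
itself requires `2 ≤ c ≤ h − 1`.

Held-out ligands are never part of the clustering. Their frames are
assigned post hoc to the conformation of the nearest cluster medoid under
the combined distance (ties to the lowest conformation id), matching the
intended use case: predicting efficacy for a ligand with a known binding
pose but unknown pharmacology.

## The efficacy model and nested leave-one-out training

Per pathway, efficacy is an intercept-free least-squares regression of the
observed per-ligand medians on occupancy fractions. No intercept is used
because fractions sum to one, so an intercept would be confounded with a
constant shift of all slopes. With ~10 training ligands and up to 14
conformations the design is routinely rank-deficient; the fit returns the
SVD minimum-norm solution (unvisited conformations get slope exactly 0) and
warns, rather than failing. Targets are per-(ligand, pathway) medians over
assay records, robust to outlying assays.

Training is nested leave-one-out:

* **Inner loss** for a hyperparameter cell (w, H, δ, C): each training
  ligand in turn is held out of the clustering, assigned externally,
  predicted, and the loss is the mean squared error per pathway; the grid
  search minimizes loss<sub>G</sub> + loss<sub>βarr2</sub>. Ties resolve in
  the deterministic order weights → H → δ → C, ascending.
* **Outer validation**: each ligand is held out entirely; hyperparameters
  are re-searched on the remaining ligands (per fold), the final model is
  refitted, and the held-out ligand predicted. Every ligand is also
  predicted under every fold's model, giving the per-ligand SD across
  cross-validation models reported next to each prediction.

The default grid mirrors the published search space — weight patterns
(w, w, 1−2w), (w, 1−2w, w), (1−2w, w, w) for w ∈ {0.1, 0.2, 0.25, 0.33, 1}
(the w = 1 patterns have a negative entry and are skipped with a notice;
the third printed pattern is completed to the symmetric triple), H from 2
to 40, δ from 1 to 3, C from 2 to H−1 — and `reference_hyperparameters()`
records the selected values every published fold agreed on
(w = 0.25/0.25/0.5, H = 40, δ = 2, C = 14). The grid engine evaluates one
dendrogram per (weight pattern, fold) and reuses it across all (H, δ, C)
cells, which is algebraically identical to evaluating each cell
independently and keeps nested searches tractable at desk scale; exhaustive
evaluation of the full default grid remains expensive and the worked
examples use reduced grids.

**Slope statistics across folds.** Conformation indices from different
per-fold clusterings do not correspond to one another, so across-model
means and SDs of slopes are computed in a single shared conformation space:
the model is fitted once on all ligands with the modal selected
hyperparameters, and each fold's slopes are refitted on that space's
training fractions. Held-out predictions, by contrast, always come from the
per-fold models — the shared space is a reporting device, not a shortcut.
Whether hyperparameters should be refit per fold or fixed globally is
genuinely open; we refit per fold (the more conservative choice) and report
the per-fold selections in the run report.

## Efficacy response functions

For each structural feature, a histogram density of its values is estimated
within each conformation. Torsion samples are triplicated at Φ ± 2π before
binning so the estimate is continuous across the ±π seam, then normalized
so the numerical integral over [−π, π] is one; distance features use the
sample range padded by 0.5 Å. The ERF is the slope-weighted sum
r(x) = Σ<sub>c</sub> β̄<sub>c</sub> p<sub>c</sub>(x) per pathway; it may be
negative and is not normalized. The general activation function is the
sign-gated minimum magnitude where both pathways' ERFs agree in sign,
a(x) = sign(r<sub>G</sub>)·min(|r<sub>G</sub>|, |r<sub>β</sub>|), the
selective counterpart fires where the signs oppose, and each is summarized
by a rectangle-rule integral over 1000 evenly spaced points. The exact
algebra of the gates is not nailed down by the source text; the form above
satisfies every stated property (nonzero exactly under sign
agreement/opposition, the sign carries directionality, bounded by both
ERFs) and is confined to two small functions.

Numerical choices: the evaluation grid uses 1000 midpoints, so the
rectangle rule is exact for constants (score of a constant c over a
length-L domain is exactly cL); the default bin count is 50 because it
divides the 1000-point grid evenly, making the quadrature of any histogram
density exact as well (a histogram evaluated on a non-commensurate grid
would carry an O(1/points-per-bin) quadrature error). Bin count is a
parameter; ERFs can be computed for any feature table aligned with the
frame labels, including binding-pocket features that never entered the
distance metric.

## The synthetic generator

No trajectories are deposited for the original study, so the generator
defines the study conditions the tests run under. Ensembles are i.i.d.
mixture draws: each frame picks a conformation from the ligand's mixture
and adds noise to that conformation's feature center — wrapped-normal on
torsions (so the periodic metric is exercised at the seam), normal
truncated positive on distances. Efficacies invert the model:
value = Σ β*<sub>c</sub> f<sub>l,c</sub> + N(0, σ), optionally with
several records per key to exercise the median. Everything is reproducible
from a single seed, and the scenario definition (centers, mixtures, slopes)
is fixed per preset, independent of the sampling seed.

Presets:

* `separable_small` — 3 well-separated conformations (center separation
  > 4× the within-conformation spread under the combined distance), 6
  ligands × 200 frames, noise-free efficacies. Ground-truth recovery must
  be exact here: adjusted Rand index 1.0, slopes to ~1e-8, held-out
  predictions to ~1e-13.
* `noisy_medium` — 4 conformations, 8 ligands × 150 frames, moderate
  feature noise, 5% efficacy noise.
* `paper_shaped` — the study's shape: 11 ligands × 3 pooled replicates,
  14 planted conformations, 2 pathways, 5% efficacy noise (a realistic
  assay spread). Occupancies are sparse — each complex dominated (0.60) by
  one conformation with two minor states (0.25/0.15), three conformations
  unique to single ligands — plus a weak uniform thermal floor (0.12 spread
  over all states) reflecting that a receptor samples every state with
  nonzero probability. Frame counts (3 × 40 per ligand) are chosen so the
  full nested pipeline runs in seconds; they are the package's working
  problem size for this preset.

What the generator does **not** emulate: time correlation within
trajectories (frames are exchangeable), force-field or sampling bias,
binding-pose uncertainty, and structure–activity smoothness (slopes are
planted per conformation, not derived from center geometry). Consequently,
passing tests demonstrate that the pipeline recovers the model's own
generative structure — not that the linear population model is true of real
receptors, nor that real MD ensembles are this separable. On `paper_shaped`
the held-out accuracy is limited by the same n < p rank deficiency the real
study faced (10 training ligands, 14 conformations); typical held-out MAE
is in the 10–20% range with R² sensitive to the seed, and the acceptance
script reports whatever the current seed produces.

## Known limitations

* The linear population model ignores interactions between conformations
  and any nonlinearity in transducer coupling.
* Minimum-norm regression shrinks slopes along unidentified directions;
  slopes for rarely visited conformations are reported but weakly
  determined (visible in their across-fold SDs).
* The feature-space medoid metric is a stand-in ordering, not an RMSD, for
  coordinate-free inputs; models fitted with the two metrics can differ in
  borderline spectral groupings.
* PDB round trips quantize coordinates to 0.001 Å; features recomputed from
  written files agree to ~5e-3 rather than machine precision.
* Only multi-model PDB ensembles are read natively; trajectory formats
  (DCD/XTC) should be converted upstream or supplied as feature CSVs.
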