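---
title: "Model refinement with Gaussian mixtures and differentiable stereochemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model refinement with Gaussian mixtures and differentiable stereochemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmmrefine)
```

## The model

`gmmrefine` refines atomic models against cryo-EM density maps. The model is
represented as a Gaussian mixture: one isotropic 3D Gaussian per non-hydrogen
atom, each carrying five parameters (amplitude, width, and the three center
coordinates). Amplitudes default to the atomic number (relative to carbon) and
a single width shared across the model is set from the target resolution,
$\sigma = 0.225\,d$ for a target resolution $d$ in ångströms. Because the
mixture is analytic, its 2D projection along any view axis is again a mixture
of 2D Gaussians, so map–model agreement can be evaluated on projection images
without ever voxelising the model.

Map–model similarity is the Fourier ring correlation (FRC) between analytic
projections of the mixture and line-integral projections of the map, averaged
over rings up to the frequency $1/d$. Each ring is independently normalised,
which makes the score insensitive to B-factor-style sharpening or low-pass
filtering of the reconstruction — only the phase/amplitude agreement within
each resolution shell matters. The training loss is the negative mean FRC
over a batch of projections.

Stereochemistry enters the same loss as differentiable re-formulations of the
standard validation metrics:

* **Bonds and angles** — Gaussian negative log-likelihood against ideal
  values, plus a soft hinge activated beyond 4.5σ (slightly tighter than the
  5σ used for reporting outliers, to absorb coordinate-precision and
  table-mismatch effects).
* **Planarity** — angular deviation of planar quads from 0/180°, with a 30°
  threshold for the peptide ω and 10° for other planar groups (sp²
  sidechains, nucleotide bases).
* **Ramachandran** — each residue's (φ, ψ) is scored on a continuous surface,
  a Gaussian mixture over the periodic torsion plane evaluated in the log
  domain $\ln(R + C)$ with $C = e^{-10}$. Six residue classes are used
  (General, Gly, trans-Pro, cis-Pro, pre-Pro, Ile). The loss uses smooth
  (sigmoid) fractions of outlier- and allowed-level residues; the report uses
  the hard thresholds (outlier level 0.0005 on the max-1 histogram scale,
  allowed level 0.02 — the latter is a package choice, configurable, since
  only the outlier level is fixed by validation practice).
* **Rotamers** — χ-angle vectors scored on per-residue-type mixtures with
  components at the library rotamer peaks; likelihood plus outlier hinge.
* **Clashes** — non-bonded pairs closer than the sum of VdW radii minus
  0.4 Å count as clashes; potential hydrogen-bond pairs (H with O/N, not
  covalently linked) get a 0.8 Å allowance. Hydrogens are invisible to the
  map term but required for clash scoring, so they are placed
  deterministically from the heavy atoms (template internal coordinates,
  rotatable torsions fixed — the zero-torsion convention of validation
  servers) and their gradients are chained back to the parent atoms. Each
  atom tracks up to 128 spatial neighbor candidates, excluding pairs within
  3 covalent bonds; the list is refreshed every 100 iterations.
* **RNA suites** — seven backbone dihedrals per base (δ−1, ε−1, ζ−1, α, β,
  γ, δ) compared against 46 suite cluster centers with a Gaussian kernel on
  the wrapped per-angle distance (width 28° per angle; the reference tool's
  exact kernel constants are not published, so this is a package choice with
  the same 0.001 assignment threshold). The reported mean imitates
  validation — bases whose best score is below 0.001 are excluded — while
  the loss keeps every base, so outliers remain under gradient pressure
  instead of being silently dropped.

All terms return analytic gradients with respect to the heavy-atom
coordinates; every gradient is verified against central finite differences in
the test suite (relative tolerance 10⁻³).

## Decoders and the refinement protocol

Refinement is driven by small dense decoder networks (four hidden tanh layers,
width 64, zero-initialised output layer so training starts at the identity
deformation). The decoder input is a 4-vector: the constant $[1,1,1,1]$ in
single-model mode, or the latent conformation coordinate (padded to length 4)
in series mode. Three decoders form a hierarchy:

1. **D1** outputs one rigid transform (translation + rotation vector about the
   patch center) per patch, where patches come from K-means clustering of
   residue centers of mass (64 by default; atoms of a residue always share a
   patch).
2. **D2** outputs one rigid transform per residue.
3. **D3** outputs per-atom offsets.

Their displacement fields are added on top of the baseline coordinates.
Single-model refinement runs five steps: (1) topology precompilation,
(2) D1 alone against the map term, (3) D1+D2 with bond/angle, planarity and
clash terms added, (4) optional rotamer rebuild — every library peak is
instantiated and scored by local map density, the best kept — followed by
direct Adam optimisation of the χ angles, (5) all three decoders plus free χ
torsion offsets under every constraint. Each step's output model becomes the
next step's baseline, so no decoder weights need to be stored. Step 5 can run
by itself without a map as a geometry-only polish of an existing model.

The relative weight of geometry versus map terms is set by a probe: two
iterations of map-only refinement measure how much geometry likelihood is
sacrificed per unit of FRC gain, and the weight is the reciprocal of that
ratio, so both terms move at a similar scale during training. On fixtures
that start with ideal geometry the probe overestimates the ratio (its
geometry delta is curvature-dominated noise), so the computed weight is
clamped into [0.005, 0.05] — the band in which, measured on the bundled
problem class, the per-iteration weighted-geometry delta actually stays
within an order of magnitude of the map delta, which is the rule's stated
intent. The probe runs full-batch so its two iterations give a reliable
descent direction; a probe with no geometry change at all falls back to
weight 1 with a warning.

In series mode the decoders are conditioned on each projection's latent
coordinate, perturbed by a small seeded Gaussian (default 5% of the latent
range) so that neighbouring latents overlap and the decoded motion is
continuous between the discretely sampled maps. Stages are trained with
persistent weights (D1, then D1+D2, then all three): unlike single-model
mode, the weights *are* the artifact, mapping any latent point to a model.
A final geometry-only polish trains on latents drawn uniformly over the
trajectory range; the coarse patch decoder is frozen during polish so the
map-facing conformations are preserved while local geometry is cleaned up at
frames the input maps never sampled.

## Reference tables and surfaces

The bundled templates (atoms, ideal coordinates including hydrogens, bond
connectivity) derive from standard chemical component definitions; bond and
angle ideal values are recomputed from the ideal coordinates at load time
with restraint-style sigmas (0.02 Å for bonds, 2.0° for angles, standard
values for the inter-residue links). Two deliberate template adjustments make
the idealized nucleotides usable for helical fixtures: the idealized ribose
in the component definitions is flat (δ ≈ 98°, not a realistic pucker), and
with it the 2'-hydroxyl points into the path of the next phosphate, so O2'
is mirrored to the opposite sugar face and pyrimidine bases are rotated 135°
about the glycosidic bond. The RNA suite library is correspondingly
*synthetic*: its A-form anchor is the 7-angle vector the templates actually
produce, and the remaining 45 centers are deterministic combinations of
canonical backbone torsion values. It has the size, spread and threshold
semantics of the real suite set but not its empirical centers — RNA suite
scores from this package are internally consistent, not comparable with
validation-server numbers.

The Ramachandran surfaces are likewise generated from region definitions
(favored centers with allowed halos, normalised to maximum 1) rather than
from empirical counts; the discrete histograms used as test oracles are the
binned form of the same surfaces, which keeps the package self-contained with
no downloads. `fit_reference_gmm()` is the general fitting path for users
with real histograms: seeded k-means initialisation over high-density bins,
then Levenberg–Marquardt least squares with an analytic Jacobian, optionally
in the log domain, with an escalating boundary penalty that forces every
histogram-outlier bin below the surface outlier threshold (the test suite
asserts 100% on the bundled histograms at reduced component count; 2500
components reproduce the full-accuracy regime but are not exercised in the
default tests for run-time reasons).

## Numerical choices

* Soft hinges are `softplus` with sharpness 10 per σ (or per degree/Å), so
  hard thresholds emerge in report mode while gradients stay finite.
* Orientations are sampled quasi-uniformly (Fibonacci sphere with
  golden-ratio in-plane angles, seeded offset); 32 projections per map in
  single-model mode, 16 per map in series mode.
* FRC rings are one Fourier pixel wide with a hard frequency cutoff at
  $1/d$.
* Optimisation is Adam; default step sizes are 0.002 (coarse), 0.002
  (residue), 0.005 (χ), 0.001 (full), decays not needed at desk scale.
  The coarse stage needs genuinely coarse patches to find collective
  motions: a straight helix imaged at 8 Å is self-similar below its pitch,
  so with many small patches the map term can be satisfied by re-registering
  stretches of chain without recovering the true arrangement. For the
  bundled 40-residue two-domain fixtures the examples therefore use 2
  patches — one per quasi-rigid body, the scaled-down analogue of 64
  patches on a 100 000-atom complex. Choose the patch count at the scale of
  the domains you expect to move.
* Chain breaks are declared when consecutive residues' link distance
  (C–N or O3'–P) exceeds 2.5 Å; no link restraint is emitted across a break.
* Alternate locations collapse to the highest-occupancy conformer at read
  time; insertion codes are preserved.
* The shared Gaussian width is held fixed during training: with per-ring
  normalisation the FRC is only weakly informative about the global width,
  and a fixed resolution-matched width avoids a poorly constrained degree of
  freedom.

## What the synthetic fixtures do and do not show

The fixture generator builds toy polypeptides (ideal backbone at recipe
φ/ψ, sidechains grafted from templates at library rotamer peaks chosen
greedily for clearance) and A-form-like polynucleotides, simulates maps as
Gaussian-blurred atom densities at a stated resolution, and produces
two-state hinge-motion map series with outlier-free ground-truth models
(hinge junctions are re-idealized by local geometry-only minimisation; the
default test problems are 40-residue, ~200-atom chains with 48³ maps at 8 Å).
Passing the bundled recovery experiments shows that the optimisation
machinery can recover collective motions and maintain validation-style
geometry on clean, noise-free, single-chain problems whose density is
unambiguous at the target resolution. It does not demonstrate performance on
experimental reconstructions — no noise, no solvent, no B-factor variation,
no map anisotropy, no multi-chain packing — nor that the synthetic reference
tables match the empirical ones used by validation servers. Very dense
mixed-sequence helices can also exceed what the coarse rotamer grid can
build without contacts; the bundled fixtures use sequences that build clean.

## Known limitations

* Only the 20 amino acids and 4 RNA nucleotides are parameterised: no
  ligands, waters, DNA base geometry, disulfides or covalent modifications.
* The rotamer library is a coarse ±60/180 grid (aromatics ±90 for χ2,
  proline from its ring template), not an empirical rotamer set.
* Suite scores are internally consistent but not comparable to reference
  suite-naming tools (synthetic centers, approximate kernel).
* Occupancies and B-factors are carried through I/O but never refined.
* Handedness and initial rigid docking are assumed correct on input.
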