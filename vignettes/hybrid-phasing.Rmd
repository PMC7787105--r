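---
title: "Hybrid phasing of cyclic-oligomer crystals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid phasing of cyclic-oligomer crystals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, algorithms and design choices behind
`cyclophase`. The package implements, at desk scale, the phasing route used
for large ring-shaped assemblies such as bacteriophage portal proteins: a
crystal diffracts to moderate resolution but cannot be phased
experimentally, while cryo-EM yields a medium-resolution (7-8 Å) map of the
same ring into which only a partial polyalanine model can be built. The
partial model, expanded to the full Cn ring, is enough to phase the crystal
by molecular replacement, and density modification with n-fold
non-crystallographic symmetry (NCS) averaging then turns the poor starting
phases into an interpretable map.

## The self-rotation function

The self-rotation function (SRF) is the overlap of the Patterson function
with a rotated copy of itself,

$$\mathrm{SRF}(R) \;=\; \sum_{u} P(u)\, P(Ru),$$

evaluated here by direct summation over a spherical shell of Patterson grid
points with trilinear interpolation (`rotation_overlap()`), normalized so
the identity rotation scores 100. Rotations are organized in chi sections:
all rotations by a fixed angle chi, displayed over the axis directions
(theta from the crystal c axis, phi from a). An n-fold NCS axis produces a
peak at chi = 360/n: 32.7, 30, 27.7 and 25.7 degrees for orders 11-14
(`chi_for_order()`), so comparing the best peaks of those sections
identifies the oligomeric order (`detect_ncs_order()`).

Patterson coefficients are shell-normalized squared amplitudes
(|F|^2 / <|F|^2> - 1), which removes the origin ramp and resolution falloff.
Two shells matter:

* **Ranking window** (default: data between 10 and 4 Å, shell radii
  45%-100% of 0.45 times the shortest cell edge). Small-radius Patterson
  points carry almost no angular discrimination, and for a ring most of the
  n-fold signal sits in the inter-protomer vectors; a wide, outer shell
  ranks candidate orders reliably.
* **Axis localization.** In an orthorhombic crystal the Patterson contains
  *two* symmetry-related images of the ring-axis direction (related by the
  dyads), and their broad, cylindrically symmetric ridges overlap. The
  superposition biases the peak of the broad engine by up to ~1.5 degrees.
  `detect_ncs_order(sharpen_axis = TRUE)` therefore re-localizes the winning
  axis on a 0.5-degree local grid with a *sharp* engine (a narrow
  high-resolution window at the data limit and a wide shell), where the
  discrete n-fold modulation dominates the smooth ridges; on the bundled
  fixtures this recovers the constructed axis to a fraction of a degree.

**Equatorial twofolds.** When a Cn axis is perpendicular to a
crystallographic dyad (here b), the products of the dyad with the n ring
rotations are twofold axes in the plane perpendicular to the ring axis,
spaced 180/n degrees apart -- n axis lines in total, one of which coincides
with the dyad itself. The package scans chi = 180 rotations around that
great circle (`equatorial_twofold_profile()`) and counts circular local
maxima (`count_equatorial_twofolds()`): 13 peaks for a tridecamer, 12 for a
dodecamer, *counting the member that coincides with b*, exactly as these
sections are read in practice. The profile can carry weak half-period
ripples (the Patterson is centrosymmetric, so each protomer also correlates
with its mirror); when the candidate order is known -- the count is used as
a consistency check of the order detected from the chi sections -- the merge
window is set just above half the expected 180/n spacing, which absorbs
those ripples. A full-hemisphere peak count would not reproduce the
published convention: both symmetry-related axis images contribute their own
perpendicular family, so the hemisphere holds up to 2(n-1) non-crystallographic
twofold directions.

## Structure factors and maps

Atomic scattering uses the standard Cromer-Mann 4-Gaussian coefficients
(H, C, N, O, S; unknown elements fall back to carbon with a warning) with
isotropic B factors. The default FFT route samples artificially smeared
atomic density on a grid of spacing d_min/3 and sharpens back in reciprocal
space: with the extra smearing B chosen as `7.7 d_min^2 - B_min`, the
aliased spectral images folded back onto the working sphere are attenuated
by better than ~0.3%, and the tests hold the FFT route to <1% of the direct
summation (`method = "direct"`), which remains the reference path. F(000)
is excluded everywhere, so synthesized maps are mean zero. All crystal maps
wrap periodically; EM-style box maps do not. Map i/o uses the CCP4/MRC
mode-2 format with X,Y,Z fast-to-slow axes; no axis permutation is accepted
silently.

## Constrained molecular replacement

The SRF fixes the ring-axis direction, leaving the spin psi about the axis
(periodic with 360/n), the axis sign, and the translation. For every
orientation on the psi grid (both axis signs), a full-symmetry product
translation function

$$O(t) = \sum_h I_o(h)\,\bigl|\,\textstyle\sum_s F_m(hR_s)
  e^{2\pi i h\tau_s} e^{2\pi i (hR_s)\cdot t}\bigr|^2$$

is evaluated on a grid by accumulating the cross terms at indices
h(R_s - R_s') in reciprocal space and one FFT. Intensities are
shell-normalized throughout (E^2-like): raw intensities are dominated by a
handful of strong low-resolution terms and barely discriminate.

Scoring uses **two resolution windows**. The scan window (default 15-4.5 Å)
feeds the translation-function peak search. But a ring's low-resolution
envelope supports look-alike placements -- wrong spin, the partial model
docked onto the wrong helices of the register, the ring flipped -- that a
medium-resolution correlation cannot reject. Re-scoring, translation
polishing and the final local refinement therefore run in a
high-resolution window (default 8 Å to the data limit), where such decoys
lose decisively on the synthetic fixtures. The best candidates are refined
locally (two axis tilts, the spin, and the translation, by coordinate
descent with step halving), which also absorbs the residual degree-scale
orientation error of the SRF axis. Solutions are reported with the Pearson
correlation of normalized intensities; translations are deduplicated under
the permissible origin shifts of P2(1)2(1)2(1) (all half-cell
combinations). Likelihood scores (LLG/TFZ) are intentionally out of scope.

## Per-protomer rigid bodies and the magnification diagnostic

`rigid_body_refine()` optimizes each chain's six rigid parameters against
the amplitude correlation by cyclic coordinate descent (translations first,
steps halved from 1 Å/1 degree down to 0.02, each chain's contribution
updated incrementally). The report separates each protomer's motion into a
radial component dr with respect to the ring axis and a tangential rest --
deliberately, because a *uniform radial* drift of all protomers is the
signature of a cryo-EM magnification (pixel-size) calibration error, not of
ordinary model error. The inferred scale `s = mean(start radius)/mean(refined
radius)` converts to a particle-diameter change via
`magnification_diagnostic()`: a model built on a 1.42 Å/pixel map that
should have been 1.37 Å/pixel inflates a 180 Å ring by about 6.6 Å. The
workflow rescales the model by 1/s and re-places it whenever |s - 1| exceeds
1%.

## Density modification with phase extension

`run_dm()` iterates, on a figure-of-merit weighted map:

1. **NCS averaging** of the placed ring copy: every voxel of the averaging
   mask is replaced by the mean over its n images (trilinear, periodic).
   The *average NCS correlation* -- the mean pairwise Pearson correlation
   between the n images before averaging -- is the per-cycle quality
   statistic, and the quantity protocols are compared on.
2. **Histogram matching** of the protein region: a rank-preserving map of
   the densities onto a reference distribution. The reference is sampled
   from the *densest voxels* of a map synthesized from a reference
   structure at the current resolution cutoff (for the synthetic cases, the
   truth model; in real use any refined structure at matching resolution).
   Sampling the reference's own protein region this way keeps the histogram
   frame-invariant -- a solution on an alternative origin must see the same
   distribution. Without a reference the step is skipped.
3. **Crystal-copy rebuild**: the other symmetry copies' regions are
   overwritten with the modified copy-1 density through the space-group
   operators, and
4. **solvent flattening** sets everything outside the protein mask to the
   solvent mean.
5. **Inversion and Sim-weighted recombination.** Amplitudes are never
   altered. New phases come from the modified map; their reliability is a
   Sim weight m = I1(X)/I0(X) with X = 2 D F_o F_c / sigma_Delta^2
   estimated in resolution shells after shell-wise scaling. The factor D --
   the shell amplitude correlation between F_o and the map amplitudes,
   floored at zero -- damps the weight where the map carries no real
   information (plain Sim weights are notoriously overconfident there: an
   uninformative map still gets a nonzero X from scaling alone; with the
   damping a random map earns a mean figure of merit near 0.01 instead of
   0.35). The phase probability is *recombined with the starting
   (molecular-replacement) phase probability* every cycle by adding the
   phase-concentration vectors; without that anchor the iteration can drift
   into a self-consistent but wrong map -- high NCS correlation is
   necessary, not sufficient.

**Phase extension** admits reflections in equal 1/d steps from `d_start`
(default 7.9 Å) to the data limit, cycles split evenly over the steps (the
first block runs before any extension); newly admitted reflections take
their first phases from the inverted modified map and enter the synthesis
with a weight ramped over one extension block, so a fresh shell cannot
destabilize the map before its phases settle. Masks come from the EM
map: thresholded at the protein volume implied by the solvent fraction,
resampled onto the crystal grid through the placement transform, and updated
on the configured cadences (defaults 50 and 20 cycles, 104 cycles in total)
by re-thresholding the current map *inside the static EM-derived footprint*
-- anchoring the update region prevents the mask from drifting toward the
partial model's features and losing the unmodelled protein. The NCS
operators implied by the placement carry degree-scale errors that the 7.9 Å
starting map tolerates but extension to 4 Å does not; they are therefore
refined against the starting map (`refine_ncs_ops()`, axis tilts and centre
by coordinate descent) before the first cycle, and deliberately *not*
re-refined later, when the map is biased toward the partial model. A run
aborts if the NCS correlation decreases for ten consecutive cycles *and*
the cumulative loss over the streak is material (> 0.02): a slow
sub-0.02 sag while newly admitted shells settle is part of normal
extension, a sustained real slide is not.

## The synthetic fixtures

`make_ring_case()` builds fully known test crystals: a protomer of ideal
polyalanine helices (CA radius 2.3 Å, rise 1.5 Å, 100 degrees/residue;
consecutive CA-CA 3.8 Å), stacked on a radial-by-vertical grid with seeded
jitter, per-column vertical stagger and small axis tilts; the protomer is
expanded to a Cn ring, rotated so the ring axis lies in the ac plane at
(theta = 70, phi = 0), and placed in a P2(1)2(1)2(1) cell grown until no two
symmetry copies approach within 4 Å. Observed amplitudes are computed from
the truth (optionally with multiplicative noise set by a target <I/sigma>);
an EM-style map of the ring is simulated at the stated resolution and pixel
size (Gaussian density, cosine-edged Fourier cutoff, non-periodic box), and
a partial model -- a subset of helices closest to the requested residue
fraction -- is cut out in the EM frame. A pixel-size error `mag_error`
dilates the EM frame (map and partial model), never the crystal truth.

The deliberate *asymmetry* of the protomer (length spread, jitter, stagger,
tilts) matters: a ring of identical, regularly packed vertical rods is
nearly continuous, leaving almost no n-fold Patterson modulation for the
SRF, and its internal regularities support wrong-register and flipped
placements. Real protomers are large irregular domains; the stagger is the
minimal realism the synthetic geometry needs for the methods to face an
honest problem. What the fixtures do **not** emulate: real folds and side
chains, sequence, measurement-error structure beyond a flat <I/sigma>,
cryo-EM image formation (CTF, particle heterogeneity, B-factor gradients),
or crystal-packing interfaces. Passing tests demonstrate the algorithms'
correctness and the workflow's behaviour on an idealized but fully known
problem, not performance on real data.

Presets: `portal` (C13, 536-residue protomer of nine helices, ~180 Å ring,
data to 3.74 Å, <I/sigma> = 9.1), `portal-mini` (C13, 66-residue protomer of
six helices, ~90 Å ring, noiseless data to 4 Å) and its C12 counterpart, and
`tiny-c5` for fast unit tests. The test-suite and the acceptance script run
on `portal-mini`-scale problems (unit cells around 110 x 165 x 175 Å,
15,000-30,000 unique reflections, maps of ~1.5 million voxels), which keeps
a full pipeline run in minutes; the full-size preset is provided for
completeness.

## Numerical choices and degenerate inputs

* Grids sample at d_min/3 with 2,3,5-smooth dimensions; interpolation is
  trilinear everywhere (exact at nodes).
* All optimizers are derivative-free coordinate descent with step halving
  and monotone acceptance; rigid-body moves are bounded at 2 Å / 2 degrees.
* Ties in `detect_ncs_order()` within 2% relative height are reported as
  ambiguous with the full score table -- no guess is made; the workflow
  halts there (CLI exit code 2).
* `choose_dm_protocol()` breaks ties within 1e-3 toward the earlier
  candidate and flags them.
* Degenerate inputs error early: (0,0,0) reflections, non-positive cells or
  masses or scale factors, constant maps in `mask_from_em()`, zero-variance
  inputs to `map_correlation()`, grids too coarse for the requested
  resolution (`invert_map()`), antiparallel axes in `align_axis()` resolve
  to a deterministic perpendicular.
* Every stochastic element of the fixtures derives from one integer seed;
  cases are bit-identical for equal (parameters, seed). The DM engine itself
  is deterministic.

## Known limitations

* Space-group support is P1 and P2(1)2(1)2(1) (operator lists, no general
  parser); amplitudes only (no intensities/French-Wilson, no anomalous
  signal, no twinning).
* Placement assumes the SRF axis is approximately correct (it searches spin,
  sign and translation, and refines a few degrees around the axis); there is
  no general 3D rotation search.
* The Sim/anchor phase combination is a deliberate simplification of
  Hendrickson-Lattman machinery; no sigma-A map coefficients, no free-R
  cross-validation.
* The magnification diagnostic reads a *uniform radial* drift; anisotropic
  magnification error is out of scope.
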