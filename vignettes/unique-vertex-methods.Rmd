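---
title: "Locating the unique packaging vertex: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the unique packaging vertex: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Icosahedral dsDNA viruses package their genome through a molecular machine
that occupies exactly one of the twelve capsid vertices. Under icosahedral
averaging this unique vertex is invisible: it is smeared over all twelve
vertex positions at one-twelfth weight. Recovering it requires a
*symmetry-free* reconstruction, and the central difficulty is that an
icosahedrally aligned particle image is compatible with 60 equivalent
orientations — 12 vertex locations times 5 rotational attachments at a
five-fold axis. `cryovertex` implements this workflow at desk scale, on
synthetic phantoms with planted ground truth, so that every stage can be
validated quantitatively.

The package follows the classic two-stage strategy:

1. determine each particle's *icosahedral* orientation (projection
   matching against a symmetrized reference, with a consistency-based
   particle filter);
2. resolve the 60-fold ambiguity by scoring a masked 3-D *vertex model*
   against each of the 60 candidate placements, iterating between
   assignment and unsymmetrized reconstruction until the map converges.

A second mode anchors the search on the eleven *regular* five-fold
vertices instead, which localizes the unique vertex even in mutant
particles whose vertex machinery is absent — the situation in which the
unique-vertex scorer can only report ambiguity.

# Conventions

All stages share one set of conventions, asserted in the test suite:
volumes are cubic, even-sized arrays `[x, y, z]` with the physical centre
at 0-based index `N %/% 2`; Euler angles are intrinsic ZYZ in degrees with
`phi` the in-plane angle; a pose rotation maps reference-frame coordinates
to the laboratory frame and projections integrate along laboratory z;
shifts are in Angstrom. The icosahedral group is realized in the "222"
setting (two-fold axes on the coordinate axes); vertex axis 1 — the axis
with the largest +z component — carries the planted unique vertex. Because
the group setting is a convention, all results are checked to be invariant
under relabeling (composing all poses with a fixed group element permutes
candidate indices but not the physical solution).

# The phantom generator

`phantom_spec()` parameterizes a membrane-containing icosahedral virion:

* two raised-cosine radial shells (capsid and inner membrane) whose
  full-width-at-half-maximum extents equal the specified radii *exactly*,
  so shell metrology can be validated against construction (virion
  defaults: capsid 283–322 Å, membrane 223–260 Å, i.e. a 37 Å bilayer, as
  measured for the mature virion of the motivating system);
* one unique vertex on axis 1: the penton and peripentonal capsid density
  is carved from a 20° cone and replaced by an external portal with exact
  12-fold symmetry at capsid radii and a transmembrane conduit with exact
  6-fold symmetry, both enclosing an empty 45 Å axial channel (the
  literature range is 40–50 Å);
* particle states: `virion_spec()` (portal + conduit + packed core,
  membrane at 100% relative intensity), `procapsid_spec()` (conduit only,
  genome-free, expanded membrane at 80%), `sus_spec()` (packaging-mutant
  state: no portal, no conduit, disordered membrane at 62%);
* optional decorations: `spikes_present` places receptor-complex-like
  Gaussians at the eleven regular vertices, displaced tangentially off
  axis so the constellation is chiral; `capsomer_texture` adds an exactly
  icosahedral quasi-random bump lattice over the capsid shell.

The default desk-scale geometry is a 96-voxel box at 5 Å/voxel with a
global scale factor of 0.5 (the full-size option, 160 voxels at 4.28 Å,
is available but 8× slower). Phantoms are evaluated on a 2× supersampled
grid and block-averaged: shells only a few voxels thick would otherwise
alias into a grid-locked pattern that contaminates whitened correlation
scores far more than one would guess.

`simulate_stack()` draws uniform orientations (quaternion method) and
uniform shifts within ±5 Å, projects through a supersampled scattering
projector, and adds white Gaussian noise scaled so that
var(signal)/var(noise) over the circular particle support equals the
requested SNR. Membrane disorder is a per-particle radial jitter of the
membrane shell. Ground truth records the pose, the canonical icosahedral
pose, and the true candidate index among 60.

## What the generator does and does not emulate

The phantom reproduces the *geometry* a map-analysis pipeline measures
(shell radii, relative intensities, rotational symmetry folds, channel
width) and the 60-fold assignment problem. It does not model the CTF
beyond an optional phase-flip at simulation time, structural noise,
per-micrograph defocus variation, conformational heterogeneity, or an
atomistic capsid. Passing tests therefore demonstrate algorithmic
correctness under controlled conditions, not end-to-end performance on
micrographs. Two deliberate idealizations matter for interpretation: the
phantom's genome proxy is a featureless filled core (no quantitative
claims should rest on it), and an *undecorated* two-shell phantom is so
nearly spherically symmetric that its icosahedral orientation is close to
unidentifiable — which is physically correct, and is why the textured and
spiked variants exist for orientation-determination studies (a real
capsid's protein lattice plays that role).

# Icosahedral alignment

`icos_align()` replaces the original stochastic multi-path annealing
search with a deterministic two-stage procedure chosen for testability:

1. the particle centre is found by FFT cross-correlation against the
   circularly averaged reference template (windowed, with parabolic
   sub-pixel refinement);
2. the recentred image is resampled on a polar grid, each ring's mean is
   subtracted, and the whitened representation is correlated against
   reference projections on a direction grid covering one icosahedral
   asymmetric unit. In polar coordinates the in-plane rotation is an exact
   circular shift (one FFT per direction gives all in-plane angles at 2°
   resolution), so the in-plane search adds no resampling bias.

Two numerical choices proved load-bearing. First, reference templates are
rendered by Fourier-slice extraction from a 2× zero-padded transform with
cubic (Keys) interpolation; real-space resampling leaves rotation-dependent
artifacts of the same order as the whitened orientation signal of a
quasi-spherical particle. Second, near a symmetry axis the in-plane
correlation has several near-equal peaks (pseudo-symmetric views), so the
local refinement hill-climbs the viewing direction separately from each
strong in-plane peak, tracking that peak's basin, and keeps the global
best. Defaults: 4° grid (8° in the faster presets), band limit 3× the
voxel size (the same "use only low-resolution information" logic as the
original protocol's 10 Å limit), shift window ±8 px.

`consistency_filter()` repeats the alignment from independently perturbed
starting conditions (a random in-plane rotation and shift of the image,
undone afterwards) and keeps a particle only if all pairwise orientation
differences — geodesic distance modulo the icosahedral group — are below
0.5° and all centre differences below 3 Å, the selection rule of the
original study. On noiseless decorated phantoms this keeps essentially
every particle; on pure noise it rejects essentially all.

# Breaking the 60-fold ambiguity

`vertex_model()` segments the vertex feature from a map: a cone of 25°
half-angle about vertex axis 1, restricted radially from the membrane
inner radius to 1.05× the capsid outer radius, thresholded at the map
mean + 0.5 σ (the "very low density threshold" of the original
workflow). Two details are essential on phantom data:

* the model is built from a *residual* — the map minus its spherical
  average, or minus its icosahedral average when one is available —
  because the shells common to every candidate otherwise drown the
  vertex signal;
* the residual model keeps **both signs**: at the unique vertex the
  strongest signature is the *missing* penton/peripentonal density
  (negative residual), with the portal/conduit density (positive) on top
  of it.

`score_candidates()` builds, per particle, the library of 60 2-D masks
(projected support of the 3-D cone) and 60 model projections, and scores
the masked image region against each projection by normalized
cross-correlation. Before scoring, the image is whitened about its
(shifted) particle centre, or — better, when a symmetrized reference map
exists — the reference's projection at the icosahedral pose is subtracted,
which removes everything the 60 candidates share. A cross-common-lines
scorer (correlating matched central Fourier lines of the masked image and
the model projections) is provided as an alternative backend; the original
description names the method but not a formula, so the real-space scorer,
which is fully specifiable, is the default, and both backends must agree
on noiseless planted-truth recovery. The ambiguity flag follows the rule
that the margin (best minus second-best score) must exceed twice the
standard deviation of the 59 non-best scores.

`assign_regular_anchor()` scores each candidate as the mean masked
correlation of the 11 *non*-unique vertex positions against a
regular-vertex model, excluding the candidate's hypothesized unique
position. Because the regular model is effectively five-fold symmetric,
the 60 scores are exactly 5-fold degenerate: margins and accuracy are
therefore defined at the level of the 12 distinct vertex hypotheses — the
five in-plane attachments are genuinely indistinguishable without an
asymmetric vertex feature. On a whitened image the carved vertex
anticorrelates strongly with the shell template, which is why the mode
localizes a *missing* vertex so robustly.

`refine_unique_vertex()` iterates: score all particles → reconstruct
unsymmetrized half-maps from the current assignments → re-extract the
vertex model from each half map (as the residual against that map's own
icosahedral average) → rescore, stopping when fewer than 2% of particles
change assignment, with divergence (worsening agreement three iterations
running) reported rather than ignored. Assignments are refined
independently per even/odd half-set, and the combined map is formed only
after both halves converge.

## The attachment gauge

One genuine identifiability limit deserves emphasis. Starting from any
C5-averaged initial model (for example one segmented from the icosahedral
map), the five in-plane attachments of the correct vertex are *exactly*
equivalent: the data determine the solution only up to a global rotation
of the final map about the unique axis, and which gauge the iteration
locks onto is decided by numerical noise. Planted-truth attachment
accuracy is therefore only meaningful when the initial model carries the
truth gauge — which is how the planted-recovery experiments are defined
(the initial model is segmented from the phantom itself). Vertex-location
accuracy (12 hypotheses) is gauge-free and is the quantity the pipeline
logs.

# Reconstruction and validation

`backproject()` is a direct Fourier-inversion reconstruction: each image's
centred transform is inserted as a central slice with trilinear weight
accumulation on a 2× zero-padded grid (padding the insertion grid is the
field's standard remedy for interpolation losses; without it the
round-trip FSC falls off well before 0.9× Nyquist), normalized with a
Wiener-style floor of 1e-3 of the maximum weight, and inverse-transformed.
Empty Fourier shells below Nyquist are reported as underdetermined rather
than silently zeroed. Icosahedral symmetrization averages the 60 rotated
copies, with cubic interpolation by default (trilinear resampling breaks
the invariance of thin shells at the several-percent level).

`gold_standard_refine()` keeps the two half-sets fully independent from
separately seeded random spherical starting models (a soft sphere plus a
seeded smooth random field; the original protocol names the construction
but not a recipe); using the same seed for both halves is a hard error.
The band limit can be annealed over iterations (frequency marching).
A deterministic desk-scale bootstrap from a random sphere is, however, a
much weaker optimizer than the stochastic annealing search it replaces:
on the undecorated phantom the orientation landscape is nearly degenerate,
and the half-map FSC of such a bootstrap should be read as a consistency
check, not a resolution claim. The pipeline's gold-standard FSC is
computed from the half maps of the assignment refinement, which inherit
the half-set discipline.

`fsc()` uses unmasked inputs and integer-voxel shells (the binning
convention is not specified in the original protocol; integer shells are
documented here once). `resolution_at()` reports the first downward
crossing of 0.143 (half-map criterion) or 0.5 (map-versus-model),
linearly interpolated in frequency, with an explicit flag when the curve
never crosses.

# Map metrology

* `radial_profile()` averages over 3-D shells or over annuli of the
  central section; `fwhm_extent()` reads shell radii at full width half
  maximum with baseline subtraction and linear interpolation (a Gaussian
  peak of width σ must return 2.3548 σ).
* `relative_membrane_intensity()` is the central-section annular mean of
  the membrane window as a percentage of the capsid window's; in
  practice the windows should be each map's *own* measured FWHM extents,
  which is also how the original measurements were tabulated.
* `rotational_correlation()` resamples a cylindrical annulus about a
  vertex axis and correlates it with its own rotation at every sampled
  angle. The dominant fold is taken from the strongest harmonic of the
  correlation curve — a plain argmax over "mean correlation at multiples
  of 360/n" always reports a divisor fold, because C2n contains Cn. A
  flat curve (featureless region) yields an explicitly undetermined fold.
* `difference_map()` filters both maps to a common resolution
  (raised-cosine edge; the exactly idempotent sharp variant is available
  with `edge_shells = 0` — a soft transition band cannot be idempotent,
  so the two properties are offered as alternatives) and scales the
  subtrahend to equal mean absolute capsid-shell density before
  subtracting; subtraction across arbitrary intensity scales is
  meaningless, and the identity `diff(A + B, A) = B` therefore holds for
  `scale = "none"`.
* `segment_volume()` requires an explicit threshold — there is no
  defensible default contour level — and `volume_to_mass()` uses
  1.212 nm³/kDa, back-derived from the worked example in the motivating
  study (83.6 nm³ ↔ ~69 kDa) and consistent with the standard protein
  partial specific volume.

# Problem sizes used in the shipped tests

The test suite runs the planted-recovery and anchor-mode experiments at
the full study condition (96-voxel box, 200 particles, seeds fixed in the
tests), orientation-determination tests on a 48-voxel textured phantom,
and reconstruction round-trips on 32-voxel volumes with a few hundred
projections — sizes chosen so the whole suite completes on a single CPU
in well under half an hour while still exercising every stage at the
scale the headline experiments use.

# Known limitations

* The CTF model is a simulation-time phase flip at best; there is no
  per-particle defocus handling in alignment or reconstruction.
* The deterministic alignment bootstrap cannot do ab-initio structure
  determination on feature-poor particles (see above); it needs either a
  meaningful reference or a decorated phantom.
* The cross-common-lines scorer is a faithful-in-spirit reimplementation;
  the original's weighting, line count and band limits are not published,
  so only qualitative agreement with the real-space scorer is claimed.
* Rates of particle rejection on real data (the original study discarded
  about half of its virion particles) are data-dependent and are not
  reproduced — only the filter's logic is.
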