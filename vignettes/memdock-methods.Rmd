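---
title: "Methods: measuring membrane docking interfaces and bilayer relaxation"
author: "memdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring membrane docking interfaces and bilayer relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memdock)
```

## Scope and model

When two lipid vesicles dock tightly — apposed at sub-nanometre separation,
with protein cleared from the contact — the membranes at the contact zone
thicken locally. memdock implements the quantitative chain that supports
this observation at two scales:

1. **Image scale.** Membrane thickness is measured from intensity profiles
   of micrograph-like images as the distance between the two peaks marking
   the headgroup layers of a bilayer: line scans across docking interfaces,
   azimuthally averaged radial profiles on free (undocked) membrane.
   Docking interfaces are classified loose vs tight from the ratio of
   background-subtracted protein signal at the interface to that on free
   membrane of the same pair.
2. **Particle scale.** From labelled particle coordinates of one or two
   bilayers (P and N headgroup particles, chain beads, waters), per-frame
   observables are computed: P-layer thickness and inter-membrane distance,
   lateral area and area per lipid, membrane volume, headgroup tilt
   `cos(phi)` of the P-to-N vector against the membrane normal (the z
   axis), the chain order parameter `S = (3<cos^2 theta> - 1)/2`, gap
   hydration, and the leaflet-internal electrostatic energy. Relaxations of
   tilt, area and thickness toward the docked (double-bilayer) equilibrium
   are fitted per replica with `f(t) = x_inf + (x0 - x_inf) exp(-t/tau)`,
   and the medians of `tau_tilt`, `tau_area`, `tau_thickn` order the causal
   chain: headgroup tilting, then area shrinkage, then thickening.

Everything runs on synthetic data with known ground truth; the generators
are first-class, tested code, and their defaults define the study
conditions used by the test suite and the acceptance script.

## Synthetic specimens

### Vesicle images

A membrane is rendered as two Gaussian ridges (amplitude 1, width
`headgroup_ridge_sigma_nm`, default 0.6 nm) along the membrane contour,
separated by the local true thickness (default 4.0 nm peak to peak). Docked
pairs share a flat contact chord of half-width `contact_halfwidth_nm`
(default 15 nm); tight interfaces add `interface_thickening_nm` (default
0.6 nm) inside the chord and scale the protein-channel contour by
`protein_interface_ratio` (defaults: 0.15 tight, 1.6 loose). Pixel size
defaults to 0.5 nm/px and iid Gaussian pixel noise (sigma 0.05 of the ridge
amplitude) is added after rendering. These are free parameters of the
generator, chosen as typical of intermediate-magnification cryo-electron
micrographs of liposomes; no instrument model (CTF, defocus) is attempted.

Two deliberate choices deserve note:

* **Proximal ridge separation.** The default separation between the two
  proximal headgroup ridges across a tight contact is 2.2 nm. Truly tight
  contacts can push the proximal layers so close that their ridges blend
  into a single line; two equal Gaussian ridges merge mathematically when
  their separation falls below twice the effective ridge width, at which
  point a per-membrane thickness is no longer defined. The default keeps
  the four interface peaks resolvable so per-membrane interface thickness
  (the quantity of interest) is measurable; the merged regime is exercised
  separately and is reported as `resolved = FALSE`, never as a number.
* **Peak-pull bias.** Even resolvable neighbouring ridges attract each
  other's detected maxima slightly once the profile is smoothed. At the
  defaults this biases tight-interface thickness upward by about 0.1 nm; on
  the difference tight-minus-free this is well inside the 0.2 nm acceptance
  band and it shrinks as the pixel size or the smoothing decreases (the
  estimator-consistency test checks the trend).

### Bilayer frames

Lipids sit on a jittered square lattice (default 100 per leaflet in an
8.1 nm box, a typical small atomistic patch). P layers realise the
requested thickness and inter-membrane distance exactly before noise. The
N particle is placed at fixed bond length (0.45 nm) from P with polar angle
`acos(mean_tilt_cos)` from the leaflet outward normal and uniformly random
azimuth — so the per-lipid tilt cosine equals the target exactly, noise or
not. Chain beads descend toward the midplane with a fixed bond polar angle,
making the chain order parameter exactly `(3 cos^2 - 1)/2` by
construction. Positional noise is applied to the lipid anchor only, which
keeps tilt and order recovery exact and thickness estimation unbiased.
Partial charges default to a zwitterionic headgroup stand-in (`P = -1`,
`N = +1`, neutral chains); there is no lipid chemistry beyond this.

### Relaxation ensembles

Each replica is the closed-form exponential plus iid Gaussian noise
(sigma 0.05), sampled at 1 ps over 1 ns, 500 replicas, with
`tau = 0.05 / 0.15 / 0.40` ns for tilt / area / thickness. Replica noise
comes from per-replica sub-streams of one master seed, so any subset is
reproducible. Real relaxation data have correlated noise and imperfect
single-exponential behaviour; passing these tests therefore demonstrates
the estimator chain, not the physics.

## Measurement chain choices

* **Peak detection.** Profiles are smoothed with a Gaussian kernel
  (default sigma 1 sample); strict local maxima are kept if their
  topographic prominence exceeds 10% of the smoothed dynamic range, peaks
  closer than 1 nm keep only the more prominent, and positions are refined
  by a three-point parabola (matches a dense-grid oracle to < 0.1 px at
  the generator's ridge widths). The original analysis pipeline's
  smoothing and thresholds are not published; these defaults are this
  package's own and are exposed as arguments.
* **Interface peak assignment.** Up to four peaks across a docked double
  membrane are assigned outer/inner pairs by position order; fewer than
  four means the proximal peaks merged, and both membranes are flagged
  unresolved rather than guessed.
* **Classification threshold.** The qualitative rule "protein signal
  decreased or absent" is made operational as
  `interface_ratio < 0.6 => tight`, with a tie going to loose
  (conservative). The ratio construction makes calls invariant to global
  intensity rescaling; the threshold is a config value, not hard-coded.
* **Background.** Median intensity over a 5-px image border, as no
  background protocol is published for the original measurements.
* **Group tests.** Thickness classes are compared with a one-tailed
  unpaired Student t-test (equal variances, the conventional "unpaired
  t-test"); paired interface-vs-free comparisons use the Wilcoxon
  matched-pairs signed-ranks test. The signed-rank p-value is computed by
  exact enumeration of sign assignments over midranks for n <= 16 — the
  standard exact routine abandons exactness under ties, and ties are
  expected in rounded thickness data. Zero differences are dropped; all
  zeros gives p = 1, flagged.

## Trajectory metric conventions

* The membrane normal is fixed to the z axis throughout; no local normal
  estimation.
* Leaflets are found by 1D clustering of P z-coordinates (ordered
  largest-gap split refined by k-means). Overlapping layer distributions
  are a hard error naming the ambiguous lipids — silent misassignment
  would poison every downstream observable.
* Membrane volume is defined as lateral area times P-layer thickness.
  Other definitions (Voronoi volumes, density-threshold volumes) exist;
  this one makes the incompressibility argument checkable in closed form:
  at fixed volume, a 5% area shrinkage must raise thickness by exactly
  1/0.95.
* Leaflet-internal electrostatics is a direct cutoff Coulomb sum
  (`f = 138.935` kJ mol^-1 nm e^-2, cutoff 1.2 nm, minimum image in x and
  y) over all intra-leaflet pairs, with no bonded exclusions. A
  reciprocal-space (PME) term cannot be decomposed per leaflet, so a
  cutoff sum is the observable's natural form; the vectorised
  implementation is tested against an independent O(N^2) double loop.
* Headgroup tilt uses the P-to-N vector; the opposite convention only
  flips the sign (verified by the antisymmetry test), and the bias
  potential exposes the same convention.

## Relaxation fitting and ordering

Fits use Levenberg-Marquardt over `(x0, x_inf, tau)` with `tau` bounded
positive. Initialisation is derivative-free: `x0` from the first sample,
`x_inf` from the mean of the last 10%, `tau` from the 63% traversal time.
Constant series and non-converged optimisations return
`converged = FALSE`; they are excluded from medians but counted. Between
single- and double-bilayer endpoints, observables are normalised by the
affine map sending the single-bilayer equilibrium to 0 and the
double-bilayer equilibrium to 1.

The source analysis reports the tau ordering without an uncertainty
procedure. This package adds one: bootstrap over replicas (default 1000
resamples) of each observable's median tau, with the support for
`tau_a < tau_b` being the fraction of resamples preserving that order. A
full ordering is declared only when every pairwise support reaches 0.95.
Under an equal-tau null this declares an ordering in far fewer than 5% of
repeats (checked over 100 simulated repeats with 50 replicas each — sizes
chosen so the whole suite stays quick while the binomial error on the rate
is still informative).

## The bias potential and the toy dynamics

The angle restraint `E = k (1 - cos(phi - phi0))` (k in 0.5-30 kJ/mol,
`phi0` at 90 deg to tilt headgroups into the plane or 0 deg to straighten
them) is implemented with analytic gradients on both particle positions,
validated against central finite differences to 1e-6 relative. The
gradient has the usual polar singularity at `phi = 0, pi` when
`phi0` is away from the pole; the implementation errors there rather than
returning a large finite vector. `demo_tilt_relaxation()` is explicitly a
toy: overdamped orientation-only dynamics on the outward hemisphere with
tangential thermal noise, used to produce bias-driven tilt series for the
kinetics stage — it is not molecular dynamics and conserves nothing except
the bond length, which is fixed by construction.

## Numerical and degenerate-input conventions

* All generator randomness flows through one explicit seed; replica
  sub-streams are derived from it, and identical spec + seed is bit-identical.
* Profiles must be uniform and at least 8 samples; empty radial bins are
  `NA` and flagged, never interpolated.
* A flat profile has no peaks (empty result, not an error); fewer peaks
  than a context expects yields `resolved = FALSE`.
* Zero-variance t-tests, coincident P/N particles, equal normalisation
  endpoints, and all-diverged observables are hard errors.
* File formats: GRO positions round to 0.001 nm (format precision); the
  TIFF codec available here stores scaled 32-bit samples, so pixel size
  and intensity scale travel in a JSON sidecar; MRC (mode 2, float32)
  is the bit-exact float path and carries the pixel size natively.

## Problem sizes

The shipped tests and the acceptance script use: 50 free + 50 tight
specimens (256 px images at 0.5 nm/px), 20 + 20 classification pairs,
100-lipid-per-leaflet frames (<= 4 050 particles), a 500-replica ensemble
at 1 ps sampling for tau recovery, and 100 equal-tau repeats of 50
replicas at 10 ps sampling for the false-declaration rate. These sizes
give sub-percent Monte-Carlo error on every reported rate.

## Known limitations

* The image model has no CTF, defocus ramp, or 3D projection; thickness
  bias under a realistic PSF will differ from the Gaussian-ridge case.
* Docking classification assumes the provided scan segments actually
  cross the interface and free membrane; there is no vesicle detection.
* Single-exponential fitting is by design; stretched or multi-exponential
  kinetics are out of scope.
* Electrostatics is a bare cutoff sum — comparable between leaflets and
  distances, but not an absolute force-field energy.
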