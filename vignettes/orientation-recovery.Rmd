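---
title: "Water layers, radiation damage and orientation recovery in single-particle imaging"
author: "spiOrient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water layers, radiation damage and orientation recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In X-ray free-electron-laser single-particle imaging (SPI), each pulse
produces one photon-sparse diffraction pattern of one copy of the particle
in an unknown orientation.  Assembling thousands of such patterns into a 3D
reciprocal-space intensity volume — orientation recovery — is the step that
makes phase retrieval possible, and it degrades when the pattern carries
scattering from anything other than the particle.  Two such contaminants
dominate in practice: the residual water layer around an
electrospray-delivered particle, and the radiation-damage-driven expansion
and ionization of the sample during the femtosecond pulse.  `spiOrient`
provides a complete, desk-scalable simulation and analysis chain to
quantify both effects:

1. a forward model from atomic coordinates (hydrated, optionally damaged)
   to Poisson photon counts on an Ewald-mapped detector;
2. an expand–maximize–compress (EMC) reconstruction of the intensity
   volume from unoriented patterns;
3. two quality metrics — the per-shell R-factor against the ideal volume
   and the orientation disconcurrence (OD), the posterior-weighted RMS
   angular ambiguity in decoding held-out "sentinel" patterns.

## Geometry and conventions

Scattering vectors use $q = 2\sin\theta/\lambda$ (no $2\pi$), so $1/q$ is
the full-period resolution, and the structure-factor phase is
$e^{2\pi i\,q\cdot r}$.  The reference detector is an $81\times 81$ array
of 1200 µm pixels at 130 mm and 4.96 keV; the edge midpoint then sits at
$q = 0.14$ Å$^{-1}$ (7 Å full-period resolution) and the corner at
0.19 Å$^{-1}$.  Pixels are mapped onto the Ewald sphere exactly
($k_{out}-k_{in}$ with $|k| = 1/\lambda$); the flat-Ewald Friedel
equivalence (a $\pi$ rotation about the beam) is therefore only
approximate at the ~20° maximum scattering angle, which is why the OD
metric quotients it out explicitly.  Solid-angle and polarization
corrections are omitted (the per-pixel weight slot exists to add them);
at these angles the error is a few percent and common to all conditions.

A pattern at orientation $\Omega$ samples the reference-frame intensity at
$R(\Omega)\,q_t$.  With this convention the particle's point group acts on
the left of a decoded orientation and the Friedel group on the right,
matching the quotient distance
$\theta_{z,s}(\Omega_\alpha,\Omega_\beta)=\min_{\sigma\in s,\zeta\in z}
\theta(\sigma\Omega_\alpha\zeta,\ \Omega_\beta)$ used throughout.

## Rotation sampling

SO(3) is sampled by subdividing each tetrahedral cell of the 600-cell at
level $n$ (`num_div`), projecting the barycentric lattice to the 3-sphere
and identifying antipodes; the count is exactly $10(5n^3+n)$ — 204960 at
the production level 16.  Lattice coordinates are exact elements of
$\mathbf{Z}[\sqrt5]/4$, so shared points and antipodes are identified in
integer arithmetic and the count is structural, not tolerance-dependent.
Each sample is weighted by the summed projected volume of its incident
Kuhn sub-simplices, normalized to 1; these weights serve as the quadrature
weights of every posterior integral.

## Forward model

Ideal intensities are
$I(q)=\bigl|\sum_j s_j f_j(|q|) e^{2\pi i q\cdot r_j}\bigr|^2$ with
Cromer–Mann form factors ($s=q/2$ convention); water molecules enter as
single effective scatterers $f_O+2f_H$ at bulk number density
0.0334 Å$^{-3}$, placed by dart-throwing into the region between the
contact distance (2.8 Å) and contact + $T_w$ from the nearest solute atom
with a 2.8 Å minimum separation.  A first phase of darts estimates the
shell volume so placement stops at the requested density rather than at
random-sequential-addition jamming (which, for 2.8 Å spheres, happens to
sit only ~5% above bulk water).

Radiation damage is a two-parameter phenomenological stand-in, not
plasma physics: per pulse bin with prior cumulative dose $D$, atomic
positions expand radially by $1+e\,D$ and effective electron counts scale
by $\max(0,1-i\,D)$.  It reproduces the qualitative signatures that matter
for orientation recovery — speckle contraction toward the centre and
late-pulse blurring — and, with a spiky 9 fs pulse and strong expansion,
the final 2.6 fs bin contributes well under 5% of the detected intensity,
so time-integrated patterns remain usable.  Pulse profiles are gamma-
distributed spike intensities under a Gaussian envelope of 9 fs FDHM
binned at 2.6 fs; single realizations have FDHMs fluctuating by a bin or
two, while the seed-ensemble mean recovers the envelope width.

Patterns are Poisson draws from the oriented expectation rescaled to the
photon budget.  The budget is imposed on the *orientation-ensemble mean*
(default 500 photons/pattern), not per pattern: incident fluence is fixed,
so per-pattern totals legitimately fluctuate with orientation.  (The
single-pattern simulator, used for fixtures, normalizes its one pattern
exactly.)  Inelastic scattering is an isotropic background consuming a
configurable fraction of the budget (default 0.1 in the pipeline); no
spectral model is attempted.

## EMC

The reconstruction alternates expand (trilinear slices of the model volume
on the rotated pixel map), maximize (tempered responsibilities
$P_{dr}\propto w_r\exp[\beta\log p(K_d|r)]$ under the per-pixel Poisson
likelihood, followed by the responsibility-weighted mean-pattern update)
and compress (the trilinear scatter-adjoint).  Per-pattern incident-scale
nuisance is absorbed by one global scale that matches the model's mean
photon count to the data mean each iteration; responsibilities are not
carried across level changes.  The volume grid defaults to the detector's
central q-pitch with an edge containing the full corner Ewald cap; the
initial volume is i.i.d. uniform(0.5, 1.5) at the data scale, seeded.

The production schedule starts at $\beta=0.01$, `num_div` 5 and multiplies
$\beta$ by 1.5 and increments the level every 10 iterations for 120
iterations (level capped at 16), then runs 10 final iterations at
$\beta=1$, level 16.  The desk preset (`emcConfigDesk()`) keeps 30 total
iterations, level cap 6 and a $33^3$ grid but spends them as 10 main + 20
final: at desk scale the slow $\beta$ ramp never leaves the regime where
responsibilities are essentially the quadrature weights — the model
collapses to the rotational average and stays there — whereas the long
$\beta=1$ phase converges from that average.  Two numerical guards
matter: tomogram values are floored at $10^{-10}$ inside logarithms, and
responsibilities below $10^{-30}$ are flushed to zero (they are
meaningless and, as single-precision denormals, catastrophically slow).
The two sparse matrix products in the maximize step run in single
precision; the responsibilities are ratios of like quantities and agree
with a double-precision reference to $10^{-4}$.

### Sampling criterion for desk-scale runs

A particle of extent $D$ has speckles of width $1/D$; the volume grid must
resolve them with ~3 voxels.  On the $33^3$ desk grid
($\Delta q \approx 0.0127$ Å$^{-1}$) that caps the particle at ~25 Å —
the desk toy particle is therefore 40 atoms in a 25 Å ball, while the
full-scale preset keeps the paper-scale 10 nm extent on its
detector-matched grid.  Ignoring this criterion is not a graceful
degradation: with <1 voxel per speckle neither expand/compress round
trips nor EMC recovery are meaningful.

## Metrics

**Shell R-factor.** Per q-shell,
$R(s)=\sum_{q\in s}\bigl|\sqrt{I}/\Sigma\sqrt{I}-
\sqrt{I_{ideal}}/\Sigma\sqrt{I_{ideal}}\bigr|$ — scale-free in $[0,2]$.
Shells default to one voxel pitch; region means over
A ($q<0.08$), B ($0.08\le q<0.1$) and C ($q\ge0.1$ Å$^{-1}$) are
voxel-weighted.  Reconstructions are first aligned to the reference by
exhaustive rotation search maximizing the Pearson correlation of
$\sqrt{I}$ (dynamic-range compression), refined by coordinate-wise
golden-section on the three rotation parameters.

**Orientation disconcurrence.** For each sentinel pattern the Poisson
posterior over the rotation grid is truncated to the smallest support
holding $1-\varepsilon$ mass ($\varepsilon=10^{-6}$, hard cap 256 by
default), and
$\Theta^2 = \sum_{g,h} p_A(g)\,p_B(h)\,
\theta_{z,s}^2(\Omega_g\Omega_A^{-1},\ \Omega_h)$
is averaged over sentinels and minimized over the overall orientation
$\Omega_A$ ($\Omega_B$ is fixed to the identity — one of the two overall
orientations is absorbed by bi-invariance of the geodesic).  The
minimization scans the full rotation grid with MAP-only supports (cheap),
evaluates the full double sum at the best few candidates, and refines by
golden section.  Volumes are rescaled so the mean tomogram photon sum
matches the sentinel mean count before likelihoods are evaluated; with
that normalization the whole pipeline is invariant under rescaling the
input volume.  Self-OD passes the same volume twice.  Sentinels carry
provenance tags and the computation refuses (overridably) volumes whose
recorded training patterns overlap them.

At desk scale the OD is grid-limited: with level-4 sampling
(nearest-neighbour spacing ~0.32 rad) a perfectly decoded sentinel still
contributes ~0.1 rad, and 500-photon decoding of the 25 Å toy particle
misassigns a fraction of sentinels outright, giving self-OD values of
order 0.1–0.7 rad.  These numbers are not comparable to production-scale
values (level 16, a 10 nm protein); what carries over is the ordering —
OD grows as the water layer thickens and as the photon budget shrinks —
and that is what the tests assert.

## The condition-scan pipeline

`runExperiment()` executes generate → reconstruct (×repeats) → align →
shell-R + self-OD per condition ($T_w$ × damage), with every stage seed
derived deterministically from the plan seed; reports (JSON + TSV) and
figures (central slices with circles at 0.08/0.10 Å$^{-1}$, shell-R
curves, OD vs $T_w$) are pure functions of the plan.  `deskPlan()` runs
2000 patterns / 50 sentinels / 1 repeat on a 41×41 two-fold-binned
detector covering the production q-range; `fullPlan()` mirrors the
production design (20000 patterns, 500 sentinels, 3 repeats, full
schedule, 81×81) and is cluster-scale.  The plan's `odSource` chooses
between self-OD of each reconstruction (production analysis) and of the
ground-truth volume (repeat-independent, used for fast scaled-down
trend checks).  Damage conditions build one time-integrated volume per
SASE pulse realization (default 5 at desk scale, vs the production 55)
and cycle them across patterns.

```{r example}
library(spiOrient)
plan <- deskPlan(seed = 1L)
report <- runExperiment(plan, verbose = TRUE)
writeReport(report, "report")
makeFigures(report, "report")
```

### Full-scale replication of the production anchor

With the deposited coordinates of the nitrogenase iron protein (PDB 2NIP)
available locally, the ground-truth self-OD anchor (no water, no damage,
500 sentinels of ~500 photons, expected $\Delta\theta \approx 0.027$ rad)
is:

```{r anchor}
protein <- readPDBStructure("2nip.pdb")
geom <- detectorGeometry()
pm <- buildPixelMap(geom)
grid <- defaultVolumeGrid(geom)
truth <- idealIntensityVolume(protein, grid$edge, grid$dq)
sent <- generateDataset(truth, 500, pm, meanPhotons = 500, seed = 1,
                        role = "sentinel")
od <- disconcurrence(truth, sentinels = sent,
                     config = odConfig(level = 16L,
                                       pointGroup = makeGroup("C2")))
```

This is hours of compute at level 16 and is not run by the test suite.
Note the C2 axis of the deposited model must be supplied if it is not the
frame z-axis.

## Numerical choices and degenerate inputs

- Antipodal quaternion representative: first nonzero component positive.
- Trilinear interpolation everywhere a volume is sampled; the exact
  atom-path slice is retained for fixtures and tests (they agree to ~1%
  when speckles are resolved).
- Posterior truncation $\varepsilon=10^{-6}$; an exhaustive mode
  ($\varepsilon=0$) exists for tests and agrees to $10^{-3}$ relative.
- Empty or zero-intensity shells are skipped with a warning; a photon on
  a zero-intensity pixel yields $-\infty$ log-likelihood; an all-zero
  pattern set is an error.
- $T_w=0$ water shells, zero damage rates and single-bin pulses reduce
  exactly to their undecorated counterparts.

## Limitations

The damage stand-in is parametric, not physical (no plasma dynamics,
Auger cascades or explicit trajectories); water shells are effective
single-site scatterers without hydrogen-bond structure; inelastic
scattering is an isotropic fraction; the detector is a single flat panel
with unit weights.  Passing desk-scale tests therefore demonstrates the
correctness and the qualitative orderings of the analysis chain, not the
production-scale values, which require the full 20000-pattern, level-16
runs the full preset encodes.
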