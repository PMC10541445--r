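# spiOrient

Orientation-recovery quality in X-ray single-particle imaging (SPI):
how much does the residual water layer around a particle, and the
radiation damage it suffers during a femtosecond XFEL pulse, degrade the
assembly of photon-sparse diffraction patterns into a 3D reciprocal-space
intensity volume?

`spiOrient` is an R package for structural-biology and XFEL-methods
researchers that implements the complete computational chain needed to
ask that question quantitatively, at desk scale or at production scale:

- **Forward model** — Ewald-sphere pixel maps (`q = 2 sin θ / λ`),
  Cromer–Mann atomic scattering, hydration shells of thickness `T_w`
  (effective one-site waters at bulk density), spiky SASE-like pulse
  profiles, a two-parameter expansion/ionization damage stand-in, and
  Poisson photon sampling at a fixed incident fluence
  (`~500` photons/pattern on average).
- **EMC reconstruction** — the expand–maximize–compress algorithm over a
  600-cell-based quadrature sampling of SO(3) (exactly `10(5n³+n)`
  samples at refinement level `n`; 204 960 at the production level 16),
  with the `beta × 1.5` / `num_div + 1`-every-10-iterations annealing
  schedule and a final phase at `beta = 1`.
- **Quality metrics** — the per-shell R-factor

  ```
  R(s) = Σ_{q∈s} | √I(q)/Σ√I − √I_ideal(q)/Σ√I_ideal |   ∈ [0, 2]
  ```

  with region means over A (`q < 0.08 Å⁻¹`), B (`0.08 ≤ q < 0.1`) and
  C (`q ≥ 0.1`), and the **orientation disconcurrence (OD)**: the
  posterior-weighted RMS quotient-angle disagreement

  ```
  Δθ = min_{Ω_A} sqrt⟨ Σ_{g,h} p_A(g) p_B(h) θ²_{z,s}(Ω_g Ω_A⁻¹, Ω_h) ⟩_sentinels
  ```

  where `θ_{z,s}` is the geodesic distance on SO(3) quotiented by the
  particle point group `s` (C2 supported) and the Friedel group `z`,
  evaluated on held-out *sentinel* patterns never used for
  reconstruction.

## Worked example

```r
library(spiOrient)

geom <- detectorGeometry()          # 81x81, 1200 um, 130 mm, 4.96 keV
geom
#> DetectorGeometry: 81 x 81 px, 1200 um pitch, 130.0 mm, 4.96 keV
#>   lambda = 2.4997 A, edge |q| = 0.1408 A^-1 (7.10 A full period)

fluence(beamParameters())           # 7.5e12 photons on a 250x160 nm^2 focus
#> 1.49e+07  (J/cm^2)

sampleRotations(16)                 # production rotation sampling
#> RotationSet: level 16, 204960 samples, weights sum 1.000000

# A reduced water-layer scan (ground-truth self-OD, quick):
plan <- deskPlan(patternsPerCondition = 600L, sentinelsPerCondition = 40L,
                 emc = emcConfigDesk(mainIterations = 5L, finalIterations = 15L),
                 odSource = "groundTruth", seed = 1L)
report <- runExperiment(plan)
report
#> SPIReport: 2 condition(s)
#>   condition Tw damage deltaThetaMean deltaThetaSD RbarA RbarB RbarC
#> 1       Tw0  0  FALSE          0.169           NA 0.305 0.363 0.438
#> 2      Tw20 20  FALSE          1.334           NA 0.390 0.442 0.556
#>   alignCorrMean
#> 1         0.683
#> 2         0.871

writeReport(report, "report")       # JSON + TSV
makeFigures(report, "report")       # slices, shell-R curves, OD vs T_w
```

Reading the numbers: the self-OD `Δθ` (radians) jumps from 0.17 with no
water layer to 1.33 under a 20 Å layer — the water's quasi-spherical
scattering swamps the orientation information in the 500-photon
patterns — and the shell R-factor of the EMC reconstruction rises from
low-q region A to high-q region C in every condition.  At desk scale the
absolute `Δθ` values are limited by the coarse rotation grid (level 4)
and the small toy particle; the production-scale analysis (`fullPlan()`:
20 000 patterns and 500 sentinels per condition, 3 EMC repeats, level 16)
recovers the regime where the ground-truth, water-free self-OD is a few
hundredths of a radian.  The methods vignette
(`vignettes/orientation-recovery.Rmd`) documents the model, the
parameters and the desk-scale design choices.

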