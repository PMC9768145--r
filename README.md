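# boneRad

Quantifying primary X-ray radiation damage in bone and other mineralized
collagenous tissues.

When a hard X-ray microbeam hits bone, the calcium (and phosphorus) in
the carbonated-apatite nanocrystals absorbs most of the incident photons
and ejects inner-shell photoelectrons — at 18 keV, a 13.9619 keV electron
per Ca K ionization. These electrons scatter micrometers through the
matrix and fragment the collagen backbone well outside the illuminated
spot, so the damaged region is systematically larger than the beam, and
*relatively* more so the smaller the beam. boneRad is for beamline
scientists and bone-biomechanics researchers who need to predict or
measure that spread.

## What it computes

**Damage-spread model.** A rect beam source of width *w* is convolved
with the photoelectron penetration-depth distribution *P(d_e)* obtained
from a built-in single-scattering Monte-Carlo transport model
(screened-Rutherford elastic scattering, Joy–Luo stopping power):

    η(w, x) = ∫ B(w, ξ) P(x − ξ) dξ / ∫ P(ξ) dξ        (∫ η dx = w)
    H(w, x, Δt) = Δt · η(w, x)
    H(w, x_w, Δt) = 0.05                                (damage threshold)
    ζ(w, Δt) = 2 |x_w| / w
    Z(w, Δt) = ζ_H · ζ_V                                (relative damaged volume)

**SHG quantification.** Z-projection of confocal second-harmonic stacks,
background-relative segmentation of burn-off imprints, full-width
(half-depth) extent measurement, and relative damaged area ζ_H·ζ_V.

**XRD strain relaxation.** Detector-gap masking, full-azimuth integration
of (002) Debye rings, Voigt + linear peak fits, Bragg conversion to the
c-lattice parameter, and saturating-exponential fits of the Δc/c
relaxation that tracks collagen damage in pre-stressed mineral.

**Synthetic data.** Seeded generators for SHG stacks, diffraction-frame
sequences and damage/strain time series with ground truth, so every
stage is testable end to end.

## Worked example

```r
library(boneRad)
bone <- materialPreset("bone")          # Ca .09863 P .05918 O .31413 ... at 1.41 g/cm^3

photoelectronEnergy(18, "Ca", "K")
#> [1] 13.9619

sim <- simulateElectrons(13.9619, bone, n = 10000, seed = 1,
                         keepPaths = FALSE)
sim
#> ElectronTrajectories: 10000 electrons at 13.9619 keV in 'bone' (seed 1, cutoff 0.2 keV)
#>   CSDA range 3.916 um; median |d_e| 1.234 um

P <- penetrationDistribution(sim)
attenuationLength(P)                    # 1/e depth of the survival function
#> [1] 1.508111

damageSweep(P, widths = c(5, 10, 20, 100), dts = 320)
#>   w_um dt_s  xw_um zeta_h zeta_v Z_percent
#> 1    5  320  5.793  2.317      1     231.7
#> 2   10  320  8.293  1.659      1     165.9
#> 3   20  320 13.292  1.329      1     132.9
#> 4  100  320 53.292  1.066      1     106.6
```

Reading the sweep: after 320 s, a 100 μm beam damages ~107% of its own
cross-section — barely more than the illuminated area — while a 5 μm beam
damages ~232%: the photoelectron reach (~1.5 μm attenuation depth,
bounded by the ~3.9 μm CSDA range) is fixed by the electron energy, so
shrinking the beam inflates the *relative* damaged volume. Literature
values reported for pike bone under these conditions are ~120%, ~150%
and ~260% for 100/20/5 μm; `compareToReference()` tabulates the per-width
deviations (here about −11% for each of those, a consequence of the
bespoke transport model's slightly conservative electron reach).

The full pipeline — transport → damage sweep → synthetic SHG round trip →
synthetic XRD strain series → reference comparison — is one call:

```r
res <- runEndToEnd(runConfig(mcN = 2000, seed = 1))
res$strain
#> StrainSeries: 9 points, c 6.88013 -> 6.89327 A, relaxation rate 0.0102 1/s, plateau 0.199%
```

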