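#' @import methods
NULL

#' Material: elemental composition and mass density
#'
#' A material is defined by atomic (number) fractions of its constituent
#' elements and a bulk mass density. Atomic fractions are normalized to sum
#' to one on construction; only elements with packaged physical constants
#' (H, C, N, O, P, Ca) are allowed.
#'
#' @slot name material label
#' @slot atomicFractions named numeric vector of atomic fractions (sum 1)
#' @slot density mass density in g/cm^3
#' @export
setClass("Material",
  representation(name = "character",
                 atomicFractions = "numeric",
                 density = "numeric"))

setValidity("Material", function(object) {
  msg <- character()
  f <- object@atomicFractions
  if (is.null(names(f)) || any(!nzchar(names(f))))
    msg <- c(msg, "atomicFractions must be a named vector")
  if (any(f <= 0)) msg <- c(msg, "atomic fractions must be strictly positive")
  if (abs(sum(f) - 1) > 1e-9) msg <- c(msg, "atomic fractions must sum to 1")
  if (length(object@density) != 1 || object@density <= 0)
    msg <- c(msg, "density must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Beam specification
#'
#' Photon energy, flux and lateral dimensions of the incident X-ray
#' microbeam. `widthH`/`widthV` are the rect-profile beam widths (the `w`
#' entering the damage-spread model) in micrometers.
#'
#' @slot energy photon energy in keV
#' @slot flux photons per second
#' @slot widthH,widthV lateral beam dimensions in um
#' @slot profile "rect" or "rect-gaussian-smeared"
#' @slot smearSigma Gaussian smear sigma in um (0 for a sharp rect)
#' @export
setClass("BeamSpec",
  representation(energy = "numeric", flux = "numeric",
                 widthH = "numeric", widthV = "numeric",
                 profile = "character", smearSigma = "numeric"))

setValidity("BeamSpec", function(object) {
  msg <- character()
  if (object@energy <= 0) msg <- c(msg, "energy must be > 0")
  if (object@flux < 0) msg <- c(msg, "flux must be >= 0")
  if (object@widthH <= 0 || object@widthV <= 0)
    msg <- c(msg, "beam widths must be > 0")
  if (!object@profile %in% c("rect", "rect-gaussian-smeared"))
    msg <- c(msg, "profile must be 'rect' or 'rect-gaussian-smeared'")
  if (object@smearSigma < 0) msg <- c(msg, "smearSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Monte-Carlo electron trajectory set
#'
#' Compact result of a photoelectron transport simulation. Per-electron
#' summaries (maximum axis-projected displacement, final position, path
#' length, deposited energy) are always present; full vertex paths are kept
#' only when requested.
#'
#' @slot energy start energy in keV
#' @slot material material name
#' @slot seed RNG seed used
#' @slot cutoff termination energy in keV
#' @slot csdaRange continuous-slowing-down range at the start energy (um)
#' @slot summary data.frame with one row per electron
#' @slot paths list of per-electron vertex matrices (x, y, z, energy), or
#'   an empty list when paths were not kept
#' @export
setClass("ElectronTrajectories",
  representation(energy = "numeric", material = "character",
                 seed = "integer", cutoff = "numeric",
                 csdaRange = "numeric", summary = "data.frame",
                 paths = "list"))

#' Photoelectron penetration-depth distribution P(d_e)
#'
#' Symmetric histogram of the signed penetration depth d_e along a fixed
#' axis radiating outward from the beam center. Symmetry
#' P(+|d_e|) = P(-|d_e|) holds exactly by mirror construction and total
#' probability mass is 1.
#'
#' @slot binEdges signed bin edges in um (symmetric about 0)
#' @slot mass probability mass per bin (sums to 1)
#' @slot nElectrons number of simulated electrons (NA for analytic forms)
#' @slot material,energy,seed provenance metadata
#' @export
setClass("PenetrationDistribution",
  representation(binEdges = "numeric", mass = "numeric",
                 nElectrons = "numeric", material = "character",
                 energy = "numeric", seed = "numeric"))

setValidity("PenetrationDistribution", function(object) {
  msg <- character()
  ne <- length(object@binEdges)
  if (ne != length(object@mass) + 1)
    msg <- c(msg, "binEdges must have length(mass) + 1 entries")
  if (any(diff(object@binEdges) <= 0))
    msg <- c(msg, "binEdges must be strictly increasing")
  if (abs(sum(object@mass) - 1) > 1e-9)
    msg <- c(msg, "total probability mass must be 1")
  if (max(abs(object@binEdges + rev(object@binEdges))) > 1e-9)
    msg <- c(msg, "bin edges must be symmetric about 0")
  if (max(abs(object@mass - rev(object@mass))) > 1e-12)
    msg <- c(msg, "mass must be symmetric (P(+d) = P(-d))")
  if (length(msg)) msg else TRUE
})

#' Damage-spread model configuration
#'
#' @slot threshold dimensionless energy threshold on H beyond which damage
#'   is observed (default 0.05)
#' @slot gridStep spatial grid step in um (NA: chosen automatically as
#'   min(beam width, P bin width)/8)
#' @slot gridExtent half-extent of the grid in um (NA: automatic)
#' @slot zetaVMode "unity" (anisotropic tissue, zeta_V = 1) or "computed"
#' @export
setClass("DamageModelConfig",
  representation(threshold = "numeric", gridStep = "numeric",
                 gridExtent = "numeric", zetaVMode = "character"))

setValidity("DamageModelConfig", function(object) {
  msg <- character()
  if (object@threshold <= 0) msg <- c(msg, "threshold must be > 0")
  if (!is.na(object@gridStep) && object@gridStep <= 0)
    msg <- c(msg, "gridStep must be > 0")
  if (!object@zetaVMode %in% c("unity", "computed"))
    msg <- c(msg, "zetaVMode must be 'unity' or 'computed'")
  if (length(msg)) msg else TRUE
})

#' Sampled deposition profile (eta or H)
#'
#' One-dimensional sampled function on a symmetric grid: either the
#' normalized energy-deposition profile eta(w, x) (beam rect convolved with
#' P(d_e)) or its exposure-time accumulation H(w, x, dt) = dt * eta.
#'
#' @slot x grid in um
#' @slot value sampled values
#' @slot w beam width in um
#' @slot dt exposure time in s (0 for eta)
#' @slot kind "eta" or "H"
#' @export
setClass("DepositionProfile",
  representation(x = "numeric", value = "numeric", w = "numeric",
                 dt = "numeric", kind = "character"))

#' Damage-spread model result for one (w, dt) pair
#'
#' @slot w beam width um; @slot dt exposure s
#' @slot x grid um; @slot eta,H sampled profiles
#' @slot xw damage half-extent um (NA when H never exceeds the threshold)
#' @slot zetaH,zetaV damage-to-beam diameter ratios
#' @slot Z relative damaged volume (dimensionless; multiply by 100 for %)
#' @slot threshold threshold used
#' @export
setClass("DamageModelResult",
  representation(w = "numeric", dt = "numeric", x = "numeric",
                 eta = "numeric", H = "numeric", xw = "numeric",
                 zetaH = "numeric", zetaV = "numeric", Z = "numeric",
                 threshold = "numeric"))

#' SHG image stack
#'
#' 3D stack of second-harmonic-generation intensity slices with lateral
#' pixel size and slice (voxel) depth in um.
#'
#' @slot voxels 3D numeric array (row, col, slice), intensities >= 0
#' @slot pixelSize lateral um per pixel
#' @slot voxelDepth um per slice
#' @slot metadata acquisition metadata list
#' @export
setClass("ImageStack",
  representation(voxels = "array", pixelSize = "numeric",
                 voxelDepth = "numeric", metadata = "list"))

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3)
    msg <- c(msg, "voxels must be a 3D array")
  if (any(object@voxels < 0)) msg <- c(msg, "intensities must be >= 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@voxelDepth <= 0) msg <- c(msg, "voxelDepth must be > 0")
  if (length(msg)) msg else TRUE
})

#' Z-projection of an SHG stack
#' @slot pixels 2D matrix; @slot pixelSize um per pixel; @slot mode "max" or "std"
#' @export
setClass("ShgProjection",
  representation(pixels = "matrix", pixelSize = "numeric", mode = "character"))

#' Segmented collagen damage imprint
#'
#' @slot center imprint center (x, y) in um
#' @slot extentH,extentV full-width extents in um (NA until measured)
#' @slot meanIntensityDrop fractional intensity drop inside the mask
#' @slot mask logical matrix marking the connected imprint region
#' @slot pixelSize um per pixel of the source image
#' @export
setClass("DamageImprint",
  representation(center = "numeric", extentH = "numeric", extentV = "numeric",
                 meanIntensityDrop = "numeric", mask = "matrix",
                 pixelSize = "numeric"))

#' Area-detector geometry
#'
#' @slot distance sample-to-detector distance in mm
#' @slot pixelSize detector pixel size in um
#' @slot beamCenter beam center (x = column, y = row) in pixels
#' @slot wavelength photon wavelength in Angstrom
#' @export
setClass("DetectorGeometry",
  representation(distance = "numeric", pixelSize = "numeric",
                 beamCenter = "numeric", wavelength = "numeric"))

setValidity("DetectorGeometry", function(object) {
  msg <- character()
  if (object@distance <= 0) msg <- c(msg, "distance must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(object@beamCenter) != 2)
    msg <- c(msg, "beamCenter must be (x, y)")
  if (object@wavelength <= 0) msg <- c(msg, "wavelength must be > 0")
  if (length(msg)) msg else TRUE
})

#' Azimuthally integrated radial profile
#' @slot twoTheta 2theta bin centers in degrees (strictly increasing)
#' @slot intensity mean counts per bin (NA for bins with no valid pixel)
#' @slot npix number of contributing pixels per bin
#' @slot azimuthRange degrees of azimuth integrated (360 for full rings)
#' @export
setClass("RadialProfile",
  representation(twoTheta = "numeric", intensity = "numeric",
                 npix = "numeric", azimuthRange = "numeric"))

setValidity("RadialProfile", function(object) {
  msg <- character()
  if (any(diff(object@twoTheta) <= 0))
    msg <- c(msg, "twoTheta must be strictly increasing")
  if (length(object@twoTheta) != length(object@intensity))
    msg <- c(msg, "twoTheta and intensity lengths differ")
  if (length(msg)) msg else TRUE
})

#' Voigt + linear background peak fit
#' @slot center,centerSe fitted peak center and its standard error (deg 2theta)
#' @slot sigma Gaussian sigma (deg); @slot gamma Lorentzian HWHM (deg)
#' @slot amplitude peak area (counts x deg)
#' @slot bgSlope,bgIntercept linear background
#' @slot rss residual sum of squares
#' @export
setClass("PeakFitResult",
  representation(center = "numeric", centerSe = "numeric", sigma = "numeric",
                 gamma = "numeric", amplitude = "numeric", bgSlope = "numeric",
                 bgIntercept = "numeric", rss = "numeric"))

#' Time-resolved (002) residual-strain series
#'
#' c-lattice parameters from successive peak fits and the percentage strain
#' change relative to the first exposure point, with a saturating
#' exponential relaxation fit.
#'
#' @slot exposure exposure times in s
#' @slot cLattice c-lattice parameters in Angstrom
#' @slot strainPct 100 * (c - c[1]) / c[1]
#' @slot strainSe per-point strain standard errors (percentage points)
#' @slot flux photon flux of the series (ph/s, NA if unknown)
#' @slot relaxationFit list(rate, plateau, rateSe, plateauSe)
#' @export
setClass("StrainSeries",
  representation(exposure = "numeric", cLattice = "numeric",
                 strainPct = "numeric", strainSe = "numeric",
                 flux = "numeric", relaxationFit = "list"))

setValidity("StrainSeries", function(object) {
  msg <- character()
  n <- length(object@exposure)
  if (length(object@cLattice) != n || length(object@strainPct) != n)
    msg <- c(msg, "exposure, cLattice and strainPct must have equal length")
  if (n > 0 && abs(object@strainPct[1]) > 1e-9)
    msg <- c(msg, "strainPct must be 0 at the reference (first) point")
  if (length(msg)) msg else TRUE
})

#' Synthetic-data scenario
#'
#' Bundles everything the seeded generators need: beam, material,
#' exposure ladder, the penetration distribution feeding programmed damage
#' extents, noise levels and the strain-relaxation schedule. All outputs
#' are reproducible bit-exactly from (scenario, seed).
#'
#' @slot seed integer RNG seed recorded in every output's metadata
#' @slot beam BeamSpec; @slot material Material
#' @slot exposureLadder exposure times in s (default 40/80/160/320)
#' @slot penetration PenetrationDistribution used to program damage extents
#' @slot damageConfig DamageModelConfig
#' @slot noisePoissonScale counts per intensity unit for Poisson noise
#'   (0 disables); @slot noiseGaussianSd additive Gaussian sd as a fraction
#'   of background
#' @slot strainRate relaxation rate in 1/s; @slot strainPlateau plateau in
#'   percent strain
#' @export
setClass("SyntheticScenario",
  representation(seed = "integer", beam = "BeamSpec", material = "Material",
                 exposureLadder = "numeric",
                 penetration = "PenetrationDistribution",
                 damageConfig = "DamageModelConfig",
                 noisePoissonScale = "numeric", noiseGaussianSd = "numeric",
                 strainRate = "numeric", strainPlateau = "numeric"))

#' End-to-end run configuration
#' @slot widths beam widths to sweep (um)
#' @slot exposures exposure times to sweep (s)
#' @slot mcN number of Monte-Carlo electrons
#' @slot seed master seed; @slot cutoff transport cutoff keV
#' @slot energy photoelectron start energy keV
#' @slot material Material simulated
#' @slot threshold damage threshold
#' @slot outDir output directory ("" to keep results in memory only)
#' @export
setClass("RunConfig",
  representation(widths = "numeric", exposures = "numeric", mcN = "numeric",
                 seed = "integer", cutoff = "numeric", energy = "numeric",
                 material = "Material", threshold = "numeric",
                 outDir = "character"))
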