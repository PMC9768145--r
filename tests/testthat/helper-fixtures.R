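# Shared fixtures, built in code and cached for the duration of one test
# run. The Monte-Carlo runs are the expensive pieces; everything else is
# cheap to rebuild.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

boneMaterial <- function() materialPreset("bone")

# moderate-size transport run used by most module tests
mcSim <- function() fixture("mcSim", function()
  simulateElectrons(13.9619, boneMaterial(), n = 3000, seed = 7,
                    keepPaths = FALSE))

mcP <- function() fixture("mcP", function()
  penetrationDistribution(mcSim(), nBins = 100))

# small run with full vertex paths for trajectory-level invariants
mcSimPaths <- function() fixture("mcSimPaths", function()
  simulateElectrons(13.9619, boneMaterial(), n = 60, seed = 3,
                    keepPaths = TRUE))

# acceptance-scale transport run (n = 10000, as the desk-scale analyses
# specify); shared across the acceptance tests
mcPBig <- function() fixture("mcPBig", function()
  penetrationDistribution(
    simulateElectrons(13.9619, boneMaterial(), n = 10000, seed = 1,
                      keepPaths = FALSE),
    nBins = 100))

# finely binned Laplace penetration for closed-form oracles
laplaceFine <- function(lambda = 1.5) fixture("laplaceFine", function()
  laplacePenetration(lambda, maxRange = 36, nBins = 3600))

# numerical Voigt oracle: direct Gaussian x Lorentzian convolution
voigtNumeric <- function(x, center, sigma, gamma) {
  vapply(x, function(xi)
    stats::integrate(function(u)
      stats::dnorm(u, sd = sigma) *
        stats::dcauchy(xi - center - u, scale = gamma),
      -Inf, Inf, rel.tol = 1e-10)$value,
    numeric(1))
}

# plain synthetic projection with elliptical dips on a flat background
flatEllipseImage <- function(dim = c(120, 160), centers, axesUm,
                             dip = 0.4, pixelSize = 0.6, bg = 1,
                             sharp = 0.02) {
  nr <- dim[1]; nc <- dim[2]
  X <- matrix(rep((seq_len(nc) - 0.5) * pixelSize, each = nr), nr)
  Y <- matrix(rep((seq_len(nr) - 0.5) * pixelSize, times = nc), nr)
  px <- matrix(bg, nr, nc)
  for (i in seq_len(nrow(centers))) {
    r <- sqrt(((X - centers[i, 1]) / (axesUm[i, 1] / 2))^2 +
                ((Y - centers[i, 2]) / (axesUm[i, 2] / 2))^2)
    px <- px * (1 - dip / (1 + exp((r - 1) / sharp)))
  }
  new("ShgProjection", pixels = px, pixelSize = pixelSize, mode = "max")
}

syntheticDetectorGeometry <- function()
  detectorGeometry(distance_mm = 85, pixel_um = 75, beamCenter = c(261, 261))
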