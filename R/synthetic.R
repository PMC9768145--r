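## Seeded synthetic-data generators. They emulate the statistical
## structure the analyses assume (fibrous SHG texture with elliptical
## damage dips, anisotropic (002) Debye arcs with gap stripes, noisy
## damage/strain time series) and always emit ground truth alongside.

#' Construct a synthetic-data scenario
#'
#' Defaults encode the study conditions emulated throughout: an 18 keV,
#' 5.5e7 ph/s, 20 um beam; dry pike bone; the 40/80/160/320 s exposure
#' ladder; Poisson noise plus additive Gaussian noise at 5% of background;
#' and a strain relaxation schedule of 0.2% plateau at 0.01 1/s. The
#' penetration distribution defaults to a Laplace tail with the 1.5 um
#' attenuation length characteristic of ~14 keV photoelectrons in bone.
#'
#' @param seed integer seed; all generator output is reproducible
#'   bit-exactly from (scenario, seed)
#' @param beam a [BeamSpec-class]
#' @param material a [Material-class]
#' @param exposureLadder exposure times in s
#' @param penetration a [PenetrationDistribution-class] programming the
#'   damage extents
#' @param damageConfig a [DamageModelConfig-class]
#' @param noisePoissonScale expected counts per unit intensity (0 disables
#'   Poisson noise)
#' @param noiseGaussianSd additive Gaussian sd as a fraction of background
#' @param strainRate relaxation rate 1/s
#' @param strainPlateau plateau in percent strain
#' @return a [SyntheticScenario-class]
#' @export
syntheticScenario <- function(seed = 1L,
                              beam = beamSpec(),
                              material = materialPreset("bone"),
                              exposureLadder = c(40, 80, 160, 320),
                              penetration = laplacePenetration(1.5),
                              damageConfig = damageModelConfig(),
                              noisePoissonScale = 200,
                              noiseGaussianSd = 0.05,
                              strainRate = 0.01,
                              strainPlateau = 0.2) {
  new("SyntheticScenario", seed = as.integer(seed), beam = beam,
      material = material, exposureLadder = exposureLadder,
      penetration = penetration, damageConfig = damageConfig,
      noisePoissonScale = noisePoissonScale,
      noiseGaussianSd = noiseGaussianSd,
      strainRate = strainRate, strainPlateau = strainPlateau)
}

.withSeed <- function(seed, expr) {
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)
  force(expr)
}

## oriented band-pass texture: white noise smoothed strongly along the
## fiber direction (vertical) and weakly across it, giving the streaky
## collagen-bundle appearance; returns values around 1
.fiberTexture <- function(nr, nc, amp = 0.08, alongLen = 15, acrossLen = 2) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  kAlong <- rep(1, alongLen) / alongLen
  kAcross <- rep(1, acrossLen) / acrossLen
  sm <- apply(noise, 2, function(col)
    stats::filter(col, kAlong, circular = TRUE))
  sm <- t(apply(sm, 1, function(row)
    stats::filter(row, kAcross, circular = TRUE)))
  1 + amp * sm / stats::sd(sm)
}

#' Generate a synthetic SHG stack with programmed damage imprints
#'
#' Builds a fibrous background (oriented band-pass noise emulating
#' vertically aligned collagen bundles), places one elliptical intensity
#' dip per exposure-ladder entry with axes zeta_H x w and zeta_V x w from
#' the damage-spread model (damage extends horizontally, orthogonal to the
#' fiber direction), then applies Poisson and additive Gaussian noise per
#' slice. The ground-truth imprint table is returned alongside.
#'
#' @param scenario a [SyntheticScenario-class]
#' @param nSlices number of z slices
#' @param pixelSize lateral um per pixel
#' @param dip fractional intensity drop at the imprint center
#' @param margin border margin in um around the imprints
#' @param edgeSharpness logistic edge width as a fraction of the semi-axis
#'   (the half-depth contour sits exactly on the programmed ellipse)
#' @return list(stack = [ImageStack-class], truth = data.frame)
#' @export
genShgStack <- function(scenario, nSlices = 5, pixelSize = 0.6, dip = 0.7,
                        margin = 25, edgeSharpness = 0.02) {
  stopifnot(is(scenario, "SyntheticScenario"))
  beam <- scenario@beam
  sweep <- damageSweep(scenario@penetration, widths = beam@widthH,
                       dts = scenario@exposureLadder,
                       config = scenario@damageConfig)
  extH <- sweep$zeta_h * beam@widthH
  extV <- ifelse(sweep$zeta_v == 1 &
                   identical(scenario@damageConfig@zetaVMode, "unity"),
                 beam@widthV, sweep$zeta_v * beam@widthV)
  nSites <- length(scenario@exposureLadder)
  pitch <- max(extH) + 2 * margin
  widthUm <- pitch * nSites
  heightUm <- max(extV) + 2 * margin
  nr <- ceiling(heightUm / pixelSize)
  nc <- ceiling(widthUm / pixelSize)
  cxs <- (seq_len(nSites) - 0.5) * pitch
  cy <- heightUm / 2
  if (any(cxs - extH / 2 < 0 | cxs + extH / 2 > widthUm |
            cy - extV / 2 < 0 | cy + extV / 2 > heightUm))
    stop("programmed imprint overlaps the frame border")

  .withSeed(scenario@seed, {
    tex <- .fiberTexture(nr, nc)
    xs <- (seq_len(nc) - 0.5) * pixelSize
    ys <- (seq_len(nr) - 0.5) * pixelSize
    X <- matrix(rep(xs, each = nr), nr)
    Y <- matrix(rep(ys, times = nc), nr)
    damp <- matrix(1, nr, nc)
    for (s in seq_len(nSites)) {
      r <- sqrt(((X - cxs[s]) / (extH[s] / 2))^2 +
                  ((Y - cy) / (extV[s] / 2))^2)
      damp <- damp * (1 - dip / (1 + exp((r - 1) / edgeSharpness)))
    }
    base <- tex * damp
    v <- array(0, c(nr, nc, nSlices))
    for (k in seq_len(nSlices)) {
      sl <- base
      if (scenario@noisePoissonScale > 0)
        sl <- stats::rpois(length(sl),
                           pmax(sl, 0) * scenario@noisePoissonScale) /
          scenario@noisePoissonScale
      sl <- sl + stats::rnorm(length(sl), sd = scenario@noiseGaussianSd)
      v[, , k] <- pmax(matrix(sl, nr, nc), 0)
    }
    truth <- data.frame(site = seq_len(nSites),
                        exposure_s = scenario@exposureLadder,
                        center_x_um = cxs, center_y_um = cy,
                        extent_h_um = extH, extent_v_um = extV,
                        dip = dip, zeta_h = sweep$zeta_h,
                        zeta_v = sweep$zeta_v,
                        Z_percent = sweep$Z_percent)
    list(stack = imageStack(v, pixelSize = pixelSize,
                            metadata = list(seed = scenario@seed,
                                            generator = "genShgStack")),
         truth = truth)
  })
}

#' Programmed strain-relaxation schedule
#'
#' strain(t) = plateau (1 - exp(-rate t)) in percent; the c-lattice
#' parameter follows c(t) = c0 (1 + strain(t)/100).
#'
#' @param scenario a [SyntheticScenario-class]
#' @param times times in s
#' @param c0 unirradiated c-lattice parameter in Angstrom
#' @export
strainSchedule <- function(scenario, times, c0 = 6.88) {
  strain <- scenario@strainPlateau * (1 - exp(-scenario@strainRate * times))
  data.frame(time_s = times, strain_pct = strain,
             c_A = c0 * (1 + strain / 100))
}

#' Generate a synthetic diffraction-frame sequence
#'
#' Frames carry a (002) Debye arc whose radius follows the programmed
#' c-lattice relaxation schedule, with azimuthal intensity concentrated in
#' upper and lower arcs (axially textured mineral), a flat background,
#' detector gap stripes set to zero, and Poisson counting noise.
#'
#' @param scenario a [SyntheticScenario-class]
#' @param geometry a [DetectorGeometry-class]
#' @param frameShape c(nrow, ncol) in pixels
#' @param times frame exposure timestamps in s
#' @param c0 starting c-lattice parameter in Angstrom
#' @param peakAmplitude arc peak counts; @param background flat counts
#' @param radialSigma radial arc width in pixels
#' @param azimuthSigma azimuthal concentration (sd of cos(phi), smaller =
#'   stronger texture)
#' @param gaps detector gap stripes as for [buildDetectorMask()]
#' @return list(frames, times, geometry, mask, truth)
#' @export
genDiffractionSequence <- function(scenario, geometry,
                                   frameShape = c(521, 521),
                                   times = seq(0, 320, by = 40),
                                   c0 = 6.88, peakAmplitude = 400,
                                   background = 20, radialSigma = 2.5,
                                   azimuthSigma = 0.45,
                                   gaps = list(list(dir = "v", start = 80,
                                                    width = 6),
                                               list(dir = "h", start = 410,
                                                    width = 6))) {
  stopifnot(is(scenario, "SyntheticScenario"), is(geometry, "DetectorGeometry"))
  truth <- strainSchedule(scenario, times, c0 = c0)
  tt <- cToTwoTheta(truth$c_A, geometry)
  r_px <- geometry@distance * tan(tt * pi / 180) * 1000 / geometry@pixelSize
  if (any(r_px >= min(frameShape) / 2 - 1))
    stop("ring radius exceeds the frame")
  truth$two_theta_deg <- tt
  truth$r_px <- r_px

  mask <- buildDetectorMask(frameShape, gaps)
  cx <- geometry@beamCenter[1]; cy <- geometry@beamCenter[2]
  X <- matrix(rep(seq_len(frameShape[2]), each = frameShape[1]), frameShape[1])
  Y <- matrix(rep(seq_len(frameShape[1]), times = frameShape[2]), frameShape[1])
  R <- sqrt((X - cx)^2 + (Y - cy)^2)
  cphi <- (X - cx) / pmax(R, 1e-9)   # cos(azimuth); arcs peak at +/-90 deg

  .withSeed(scenario@seed, {
    frames <- lapply(seq_along(times), function(i) {
      lambda <- background +
        peakAmplitude * exp(-(R - r_px[i])^2 / (2 * radialSigma^2)) *
          exp(-cphi^2 / (2 * azimuthSigma^2))
      f <- matrix(stats::rpois(length(lambda), lambda),
                  frameShape[1], frameShape[2])
      f[!mask] <- 0
      f
    })
    list(frames = frames, times = times, geometry = geometry, mask = mask,
         truth = truth)
  })
}

#' Generate a noisy first-order damage-accumulation curve
#'
#' D(t) = plateau - (plateau - 100) exp(-k t) plus Gaussian noise.
#'
#' @param k rate in 1/s; @param plateau asymptotic damage in % (>= 100)
#' @param noiseSd Gaussian noise sd in percentage points
#' @param nPoints number of time points over [0, tMax]
#' @param seed integer seed
#' @param tMax final exposure time in s
#' @return data.frame(time_s, damage_pct, truth_pct)
#' @export
genDamageCurve <- function(k, plateau, noiseSd = 3, nPoints = 20, seed = 1,
                           tMax = 320) {
  if (plateau < 100) stop("plateau must be >= 100%")
  times <- seq(0, tMax, length.out = nPoints)
  truth <- plateau - (plateau - 100) * exp(-k * times)
  .withSeed(seed, {
    data.frame(time_s = times,
               damage_pct = truth + stats::rnorm(nPoints, sd = noiseSd),
               truth_pct = truth)
  })
}
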