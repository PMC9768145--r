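test_that("detector masks mark exactly the requested stripes", {
  m <- buildDetectorMask(c(50, 60))
  expect_true(all(m))
  m1 <- buildDetectorMask(c(50, 60), list(list(dir = "v", start = 10,
                                               width = 10)))
  expect_equal(sum(!m1), 10 * 50)
  m2 <- buildDetectorMask(c(50, 60), list(list(dir = "h", start = 5,
                                               width = 3)))
  expect_equal(sum(!m2), 3 * 60)
  expect_error(buildDetectorMask(c(50, 60), list(list(dir = "v",
                                                      start = 58,
                                                      width = 10))),
               "outside frame")
})

test_that("azimuthal integration places rings at the geometric angle", {
  geom <- detectorGeometry(distance_mm = 100, pixel_um = 200,
                           beamCenter = c(101, 101))
  X <- matrix(rep(1:201, each = 201), 201)
  Y <- matrix(rep(1:201, times = 201), 201)
  R <- sqrt((X - 101)^2 + (Y - 101)^2)
  rpx <- 60
  frame <- exp(-(R - rpx)^2 / 2)
  prof <- azimuthalIntegration(frame, geom, nBins = 300)
  ttExpected <- atan(rpx * 0.2 / 100) * 180 / pi
  binW <- diff(prof@twoTheta[1:2])
  expect_lt(abs(prof@twoTheta[which.max(prof@intensity)] - ttExpected),
            binW)

  # uniform frame integrates to a flat profile
  pf <- azimuthalIntegration(matrix(3, 201, 201), geom, nBins = 50)
  expect_true(all(abs(pf@intensity[!is.na(pf@intensity)] - 3) < 1e-12))

  # quarter-turn about the beam center leaves the full-azimuth profile
  # unchanged
  rot <- t(frame)[, 201:1]
  profRot <- azimuthalIntegration(rot, geom, nBins = 300)
  expect_equal(profRot@intensity, prof@intensity, tolerance = 1e-12)
})

test_that("azimuthal integration conserves total counts", {
  geom <- detectorGeometry(distance_mm = 100, pixel_um = 200,
                           beamCenter = c(51, 51))
  set.seed(4)
  frame <- matrix(stats::rpois(101 * 101, 30), 101, 101)
  mask <- buildDetectorMask(c(101, 101), list(list(dir = "v", start = 20,
                                                   width = 5)))
  prof <- azimuthalIntegration(frame, geom, mask = mask, nBins = 80)
  ok <- !is.na(prof@intensity)
  expect_equal(sum(prof@intensity[ok] * prof@npix[ok]), sum(frame[mask]),
               tolerance = 1e-9)
  # masked integration of a clean frame equals the gap-free integration
  clean <- azimuthalIntegration(frame, geom, nBins = 80)
  dev <- abs(prof@intensity[ok] - clean@intensity[ok])
  expect_lt(stats::median(dev) / 30, 0.1)  # within counting noise
})

test_that("empty-beam subtraction is pointwise with strict grid matching", {
  geom <- detectorGeometry(distance_mm = 100, pixel_um = 200,
                           beamCenter = c(51, 51))
  set.seed(5)
  sig <- matrix(stats::rpois(101 * 101, 50), 101, 101)
  bgf <- matrix(20, 101, 101)
  p1 <- azimuthalIntegration(sig + bgf, geom, nBins = 60)
  p2 <- azimuthalIntegration(bgf, geom, nBins = 60)
  diffp <- subtractEmptyBeam(p1, p2)
  expect_equal(diffp@intensity, p1@intensity - 20, tolerance = 1e-12)
  expect_true(all(subtractEmptyBeam(p1, p1)@intensity == 0))
  zero <- new("RadialProfile", twoTheta = p1@twoTheta,
              intensity = rep(0, length(p1@twoTheta)),
              npix = p1@npix, azimuthRange = 360)
  expect_equal(subtractEmptyBeam(p1, zero)@intensity, p1@intensity)
  bad <- new("RadialProfile", twoTheta = p1@twoTheta + 1e-9,
             intensity = p1@intensity, npix = p1@npix, azimuthRange = 360)
  expect_error(subtractEmptyBeam(p1, bad), "do not match")
})

test_that("the Voigt profile matches direct numerical convolution", {
  xs <- c(-2, -0.5, 0, 0.3, 1, 2.5)
  for (par in list(c(0.4, 0.2), c(0.1, 0.5), c(0.8, 0.05))) {
    v <- voigtProfile(xs, 0, par[1], par[2])
    vo <- voigtNumeric(xs, 0, par[1], par[2])
    expect_equal(v, vo, tolerance = 2e-4)
  }
  # degenerate limits
  expect_equal(voigtProfile(xs, 0, 0.5, 0), stats::dnorm(xs, sd = 0.5))
  expect_equal(voigtProfile(xs, 0, 0, 0.5),
               stats::dcauchy(xs, scale = 0.5))
  # unit area
  expect_equal(stats::integrate(voigtProfile, -Inf, Inf, center = 0,
                                sigma = 0.3, gamma = 0.2)$value, 1,
               tolerance = 1e-4)
})

test_that("Voigt+linear fits recover known peaks", {
  tt <- seq(10.5, 12.5, length.out = 160)
  shape <- function(c0) 800 * voigtProfile(tt, c0, 0.06, 0.04) +
    50 - 2 * (tt - 11)
  prof <- new("RadialProfile", twoTheta = tt, intensity = shape(11.49),
              npix = rep(100, 160), azimuthRange = 360)
  fit <- fitVoigtLinear(prof)
  expect_equal(fit@center, 11.49, tolerance = 1e-4)
  expect_equal(fit@sigma, 0.06, tolerance = 1e-3)
  expect_equal(fit@gamma, 0.04, tolerance = 1e-3)
  expect_equal(fit@amplitude, 800, tolerance = 1e-3)

  # translation equivariance: shifting the peak shifts the center
  prof2 <- new("RadialProfile", twoTheta = tt, intensity = shape(11.50),
               npix = rep(100, 160), azimuthRange = 360)
  fit2 <- fitVoigtLinear(prof2)
  expect_equal(fit2@center - fit@center, 0.01, tolerance = 1e-5)

  # noisy replicates: center bias stays below 5% of the bin width
  binW <- diff(tt[1:2])
  set.seed(9)
  centers <- vapply(1:60, function(i) {
    noisy <- stats::rpois(length(tt), shape(11.49))
    p <- new("RadialProfile", twoTheta = tt, intensity = noisy,
             npix = rep(100, 160), azimuthRange = 360)
    fitVoigtLinear(p)@center
  }, numeric(1))
  expect_lt(abs(mean(centers) - 11.49), 0.05 * binW)

  # NA bins inside the window are reported
  holey <- prof
  holey@intensity[80] <- NA
  expect_error(fitVoigtLinear(holey), "empty 2-theta bins")
})

test_that("Bragg conversion between 2-theta and c is exact", {
  geom <- detectorGeometry(energy_keV = 18, beamCenter = c(1, 1))
  expect_equal(geom@wavelength, 12.3984 / 18, tolerance = 1e-4)
  tt <- cToTwoTheta(6.88, geom)
  expect_equal(tt, 2 * asin((12.3984 / 18) / (2 * 3.44)) * 180 / pi)
  expect_equal(tt, 11.49, tolerance = 0.001)
  expect_equal(twoThetaToC(tt, geom), 6.88, tolerance = 1e-10)
  # halving the wavelength halves sin(theta)
  geom2 <- detectorGeometry(wavelength_A = geom@wavelength / 2,
                            beamCenter = c(1, 1))
  expect_equal(sin(cToTwoTheta(6.88, geom2) / 2 * pi / 180),
               sin(tt / 2 * pi / 180) / 2, tolerance = 1e-12)
  expect_error(twoThetaToC(190, geom), "out of range")
})

test_that("strain series reference to the first point and fit relaxation", {
  geom <- syntheticDetectorGeometry()
  mkFit <- function(c0) new("PeakFitResult", center = cToTwoTheta(c0, geom),
                            centerSe = 1e-4, sigma = 0.05, gamma = 0.03,
                            amplitude = 100, bgSlope = 0, bgIntercept = 0,
                            rss = 0)
  # constant c: all-zero strain
  ss0 <- strainSeries(lapply(rep(6.88, 4), mkFit), c(0, 40, 80, 120), geom)
  expect_true(all(abs(ss0@strainPct) < 1e-10))

  # programmed relaxation, noise-free: exact recovery
  times <- seq(0, 400, by = 40)
  strain <- 0.2 * (1 - exp(-0.01 * times))
  cs <- 6.88 * (1 + strain / 100)
  ss <- strainSeries(lapply(cs, mkFit), times, geom)
  expect_equal(ss@strainPct, strain, tolerance = 1e-6)
  expect_equal(ss@relaxationFit$rate, 0.01, tolerance = 1e-4)
  expect_equal(ss@relaxationFit$plateau, 0.2, tolerance = 1e-4)
})

test_that("the XRD pipeline round-trips a programmed strain schedule", {
  geom <- syntheticDetectorGeometry()
  scen <- syntheticScenario(seed = 5)
  seqd <- genDiffractionSequence(scen, geom)
  fits <- lapply(seqd$frames, function(f) {
    prof <- azimuthalIntegration(f, geom, mask = seqd$mask, nBins = 250,
                                 twoThetaRange = c(10, 13.2))
    fitVoigtLinear(prof, window = c(10.5, 12.5))
  })
  ss <- strainSeries(fits, seqd$times, geom)
  ref <- seqd$truth$strain_pct - seqd$truth$strain_pct[1]
  expect_lt(max(abs(ss@strainPct - ref)), 0.01)  # percentage points
  expect_true(all(diff(ss@strainPct) > -0.01)) # monotone within tolerance
  expect_equal(ss@relaxationFit$rate, scen@strainRate, tolerance = 0.1)
})

test_that("faster programmed relaxation yields larger recovered rates", {
  geom <- syntheticDetectorGeometry()
  rates <- c(0.004, 0.01, 0.025)  # emulating three increasing fluxes
  recovered <- vapply(seq_along(rates), function(i) {
    scen <- syntheticScenario(seed = 20 + i, strainRate = rates[i])
    seqd <- genDiffractionSequence(scen, geom)
    fits <- lapply(seqd$frames, function(f) {
      prof <- azimuthalIntegration(f, geom, mask = seqd$mask, nBins = 250,
                                   twoThetaRange = c(10, 13.2))
      fitVoigtLinear(prof, window = c(10.5, 12.5))
    })
    strainSeries(fits, seqd$times, geom)@relaxationFit$rate
  }, numeric(1))
  expect_true(all(diff(recovered) > 0))
})
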