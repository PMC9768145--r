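## (002) Debye-ring analysis: detector masking, full-azimuth radial
## integration, empty-beam subtraction, Voigt+linear peak fitting, and the
## c-lattice residual-strain relaxation series.

#' Construct a detector geometry
#'
#' @param distance_mm sample-to-detector distance in mm
#' @param pixel_um detector pixel size in um
#' @param beamCenter beam center c(x = column, y = row) in pixels
#' @param energy_keV photon energy; converted to wavelength as
#'   lambda = 12.3984 / E (Angstrom)
#' @param wavelength_A wavelength in Angstrom (overrides energy_keV)
#' @return a [DetectorGeometry-class]
#' @export
detectorGeometry <- function(distance_mm = 345, pixel_um = 75,
                             beamCenter, energy_keV = 18,
                             wavelength_A = NULL) {
  if (is.null(wavelength_A)) wavelength_A <- 12.3984 / energy_keV
  new("DetectorGeometry", distance = distance_mm, pixelSize = pixel_um,
      beamCenter = as.numeric(beamCenter), wavelength = wavelength_A)
}

#' Build a detector gap mask
#'
#' Marks vertical/horizontal stripes of dead pixels (module gaps of large
#' hybrid pixel detectors) as invalid.
#'
#' @param frameShape c(nrow, ncol) of the frame
#' @param gaps list of gap specs, each list(dir = "v" or "h",
#'   start = first pixel index, width = stripe width in pixels)
#' @return logical matrix, TRUE on valid pixels
#' @export
buildDetectorMask <- function(frameShape, gaps = list()) {
  m <- matrix(TRUE, frameShape[1], frameShape[2])
  for (g in gaps) {
    idx <- seq.int(g$start, g$start + g$width - 1L)
    if (g$dir == "v") {
      if (any(idx < 1 | idx > frameShape[2]))
        stop("vertical stripe outside frame")
      m[, idx] <- FALSE
    } else if (g$dir == "h") {
      if (any(idx < 1 | idx > frameShape[1]))
        stop("horizontal stripe outside frame")
      m[idx, ] <- FALSE
    } else stop("gap dir must be 'v' or 'h'")
  }
  m
}

## per-pixel scattering angle in degrees
.pixelTwoTheta <- function(frameShape, geometry) {
  cx <- geometry@beamCenter[1]; cy <- geometry@beamCenter[2]
  X <- matrix(rep(seq_len(frameShape[2]), each = frameShape[1]),
              frameShape[1])
  Y <- matrix(rep(seq_len(frameShape[1]), times = frameShape[2]),
              frameShape[1])
  r_mm <- sqrt((X - cx)^2 + (Y - cy)^2) * geometry@pixelSize / 1000
  atan(r_mm / geometry@distance) * 180 / pi
}

#' Full-azimuth radial integration of a detector frame
#'
#' Assigns each unmasked pixel a scattering angle from its radial distance
#' and the detector geometry, then averages intensities in 2-theta bins
#' over the full 0-360 degree azimuth. Bins without any valid pixel get NA
#' intensity.
#'
#' @param frame 2D counts matrix
#' @param geometry a [DetectorGeometry-class]
#' @param mask logical matrix (TRUE = valid); NULL for no mask
#' @param nBins number of 2-theta bins
#' @param twoThetaRange optional c(lo, hi) in degrees; default spans the
#'   frame
#' @return a [RadialProfile-class]
#' @export
azimuthalIntegration <- function(frame, geometry, mask = NULL, nBins = 400,
                                 twoThetaRange = NULL) {
  stopifnot(is(geometry, "DetectorGeometry"))
  tt <- .pixelTwoTheta(dim(frame), geometry)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(frame), ncol(frame))
  if (!identical(dim(mask), dim(frame))) stop("mask shape mismatch")
  if (is.null(twoThetaRange)) twoThetaRange <- range(tt)
  edges <- seq(twoThetaRange[1], twoThetaRange[2], length.out = nBins + 1)
  sel <- mask & tt >= edges[1] & tt <= edges[nBins + 1]
  bin <- findInterval(tt[sel], edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  v <- frame[sel]
  sums <- rowsum(v, bin)
  cnt <- tabulate(bin, nbins = nBins)
  intensity <- rep(NA_real_, nBins)
  intensity[as.integer(rownames(sums))] <-
    sums[, 1] / cnt[as.integer(rownames(sums))]
  new("RadialProfile",
      twoTheta = (edges[-1] + edges[-(nBins + 1)]) / 2,
      intensity = intensity, npix = as.numeric(cnt), azimuthRange = 360)
}

#' Subtract an empty-beam profile
#'
#' Pointwise difference on exactly matching 2-theta grids, clipped at 0.
#'
#' @param profile,empty [RadialProfile-class] objects on the same grid
#' @return a [RadialProfile-class]
#' @export
subtractEmptyBeam <- function(profile, empty) {
  if (length(profile@twoTheta) != length(empty@twoTheta) ||
      max(abs(profile@twoTheta - empty@twoTheta)) > 0)
    stop("2-theta grids do not match")
  new("RadialProfile", twoTheta = profile@twoTheta,
      intensity = pmax(profile@intensity - empty@intensity, 0),
      npix = profile@npix, azimuthRange = profile@azimuthRange)
}

#' Fit a Voigt peak plus linear background
#'
#' Least-squares fit of
#' I(2t) = A * V(2t; center, sigma, gamma) + b0 + b1 * 2t over a window
#' containing one dominant peak. Initialized from the window centroid and
#' spread, with documented multi-starts over the Gaussian/Lorentzian width
#' split; reports the standard error of the fitted center.
#'
#' @param profile a [RadialProfile-class]
#' @param window c(lo, hi) 2-theta window in degrees
#' @return a [PeakFitResult-class]
#' @export
fitVoigtLinear <- function(profile, window = c(10.5, 12.5)) {
  sel <- profile@twoTheta >= window[1] & profile@twoTheta <= window[2]
  x <- profile@twoTheta[sel]
  y <- profile@intensity[sel]
  if (any(is.na(y)))
    stop("empty 2-theta bins inside the fit window: ",
         paste(signif(x[is.na(y)], 6), collapse = ", "))
  if (length(x) < 8) stop("fit window contains too few bins")

  # linear baseline estimate from the window ends
  nEnd <- max(3L, length(x) %/% 10)
  ends <- c(seq_len(nEnd), seq.int(length(x) - nEnd + 1L, length(x)))
  bl <- stats::lm(y[ends] ~ x[ends])
  base <- stats::coef(bl)[1] + stats::coef(bl)[2] * x
  yc <- pmax(y - base, 0)
  c0 <- sum(x * yc) / sum(yc)
  spread <- sqrt(sum((x - c0)^2 * yc) / sum(yc))
  A0 <- sum(yc) * mean(diff(x))

  df <- data.frame(x = x, y = y)
  starts <- list(c(sg = 0.7, gm = 0.3), c(sg = 0.3, gm = 0.7),
                 c(sg = 1.0, gm = 0.05))
  lastErr <- NULL
  for (sres in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * voigtProfile(x, c0f, sg, gm) + b0 + b1 * x,
        data = df,
        start = list(A = A0, c0f = c0, sg = sres[["sg"]] * spread,
                     gm = sres[["gm"]] * spread,
                     b0 = unname(stats::coef(bl)[1]),
                     b1 = unname(stats::coef(bl)[2])),
        lower = c(A = 0, c0f = window[1], sg = 1e-6, gm = 0,
                  b0 = -Inf, b1 = -Inf),
        upper = c(A = Inf, c0f = window[2], sg = Inf, gm = Inf,
                  b0 = Inf, b1 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (!inherits(fit, "error")) {
      co <- stats::coef(fit)
      se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                     error = function(e) rep(NA_real_, 6))
      return(new("PeakFitResult", center = unname(co["c0f"]),
                 centerSe = unname(se[2]), sigma = unname(co["sg"]),
                 gamma = unname(co["gm"]), amplitude = unname(co["A"]),
                 bgSlope = unname(co["b1"]), bgIntercept = unname(co["b0"]),
                 rss = sum(stats::resid(fit)^2)))
    }
    lastErr <- fit
  }
  stop("Voigt fit failed after ", length(starts), " starts: ",
       conditionMessage(lastErr))
}

#' c-lattice parameter from the (002) peak position
#'
#' Bragg's law: d = lambda / (2 sin theta); for the (002) reflection the
#' c-lattice parameter is c = 2 d.
#'
#' @param twoTheta peak center in degrees (0 < 2theta < 180)
#' @param geometry a [DetectorGeometry-class] carrying the wavelength
#' @return c in Angstrom
#' @export
twoThetaToC <- function(twoTheta, geometry) {
  if (any(twoTheta <= 0 | twoTheta >= 180))
    stop("2-theta out of range (0, 180)")
  theta <- twoTheta / 2 * pi / 180
  geometry@wavelength / sin(theta)
}

#' @rdname twoThetaToC
#' @param cA c-lattice parameter in Angstrom
#' @return 2-theta in degrees
#' @export
cToTwoTheta <- function(cA, geometry) {
  s <- geometry@wavelength / cA
  if (any(s <= 0 | s > 1)) stop("no Bragg angle for this c and wavelength")
  2 * asin(s) * 180 / pi
}

#' Time-resolved (002) strain series
#'
#' Converts successive peak fits to c-lattice parameters, references the
#' strain to the first exposure point
#' (strain% = 100 (c - c[1]) / c[1]), propagates peak-center standard
#' errors to the strain by first-order error propagation, and fits a
#' saturating exponential relaxation (plateau in % strain) when at least
#' three points are available.
#'
#' @param fits list of [PeakFitResult-class] objects
#' @param exposures exposure times in s (same length)
#' @param geometry a [DetectorGeometry-class]
#' @param flux photon flux of the series (ph/s), for bookkeeping
#' @return a [StrainSeries-class]
#' @export
strainSeries <- function(fits, exposures, geometry, flux = NA_real_) {
  if (length(fits) != length(exposures)) stop("length mismatch")
  if (length(fits) < 2) stop("need at least 2 time points")
  ctr <- vapply(fits, function(f) f@center, numeric(1))
  se2t <- vapply(fits, function(f) f@centerSe, numeric(1))
  cA <- twoThetaToC(ctr, geometry)
  strain <- 100 * (cA - cA[1]) / cA[1]
  # dc/d(2theta) = -c cos(theta)/sin(theta) * (pi/360)
  theta <- ctr / 2 * pi / 180
  dcd2t <- -cA * cos(theta) / sin(theta) * pi / 360
  strainSe <- 100 * abs(dcd2t) * se2t / cA[1]
  relax <- if (length(fits) >= 3) {
    f <- tryCatch(.fitSaturatingExponential(exposures - exposures[1],
                                            strain, y0 = 0),
                  error = function(e) NULL)
    if (is.null(f)) list() else
      list(rate = f$k, plateau = f$plateau, rateSe = f$kSe,
           plateauSe = f$plateauSe)
  } else list()
  new("StrainSeries", exposure = exposures, cLattice = cA,
      strainPct = strain, strainSe = strainSe, flux = flux,
      relaxationFit = relax)
}

setMethod("show", "StrainSeries", function(object) {
  cat("StrainSeries: ", length(object@exposure), " points, c ",
      signif(object@cLattice[1], 6), " -> ",
      signif(object@cLattice[length(object@cLattice)], 6), " A",
      sep = "")
  if (length(object@relaxationFit))
    cat(", relaxation rate ", signif(object@relaxationFit$rate, 3),
        " 1/s, plateau ", signif(object@relaxationFit$plateau, 3), "%",
        sep = "")
  cat("\n")
})

setMethod("show", "PeakFitResult", function(object) {
  cat("PeakFitResult: center ", signif(object@center, 6), " +/- ",
      signif(object@centerSe, 3), " deg, sigma ", signif(object@sigma, 4),
      ", gamma ", signif(object@gamma, 4), "\n", sep = "")
})
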