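## Single-scattering Monte-Carlo photoelectron transport.
##
## Physics: continuous slowing down between discrete elastic collisions.
## Stopping power follows the Joy-Luo modified Bethe expression; elastic
## scattering uses the screened-Rutherford cross-section, both standard
## choices for keV electrons in low-Z matter and the published physics of
## widely used microanalysis simulators.

.JOY_LUO_CONST <- 7.85  # keV/um for rho in g/cm^3, E and J in keV

.stoppingTerms <- function(mat) {
  mf <- atomicToMassFractions(mat)
  tab <- .constTable("atomic_constants")
  i <- match(names(mf), tab$element)
  list(massFrac = as.numeric(mf), Z = tab$Z[i], A = tab$atomic_weight[i],
       J = tab$mean_ionization_eV[i] / 1000,
       k = 0.734 * tab$Z[i]^0.037)
}

#' Electron stopping power (Joy-Luo modified Bethe)
#'
#' Continuous-slowing-down stopping power per unit path length, summed
#' over elements with mass-fraction weights and scaled by density. The
#' low-energy correction term k*J keeps the logarithm positive down to the
#' transport cutoff.
#'
#' @param energy_keV electron energy (vectorized), within [cutoff, 100]
#' @param mat a [Material-class]
#' @param cutoff minimum supported energy in keV
#' @return stopping power in keV/um
#' @export
stoppingPower <- function(energy_keV, mat, cutoff = 0.2) {
  stopifnot(is(mat, "Material"))
  if (any(energy_keV < cutoff))
    stop("energy below transport cutoff (", cutoff, " keV)")
  if (any(energy_keV > 100)) stop("energy above 100 keV not supported")
  tr <- .stoppingTerms(mat)
  s <- numeric(length(energy_keV))
  for (i in seq_along(tr$Z)) {
    s <- s + tr$massFrac[i] * tr$Z[i] / tr$A[i] *
      log(1.166 * (energy_keV + tr$k[i] * tr$J[i]) / tr$J[i])
  }
  .JOY_LUO_CONST * mat@density / energy_keV * s
}

#' Continuous-slowing-down (CSDA) range
#'
#' Numerically integrates 1/S(E) from the cutoff up to the start energy
#' (trapezoidal rule on a fine grid). This bounds the path length of any
#' simulated trajectory.
#'
#' @inheritParams stoppingPower
#' @param nGrid number of quadrature points
#' @return range in um
#' @export
csdaRange <- function(energy_keV, mat, cutoff = 0.2, nGrid = 4000) {
  stopifnot(length(energy_keV) == 1)
  if (energy_keV <= cutoff) return(0)
  e <- seq(cutoff, energy_keV, length.out = nGrid)
  f <- 1 / stoppingPower(e, mat, cutoff = cutoff)
  sum((f[-1] + f[-nGrid]) / 2 * diff(e))
}

## screened-Rutherford elastic cross-section per atom, cm^2
.elasticAlpha <- function(energy_keV, Z) 3.4e-3 * Z^0.67 / energy_keV

.elasticSigma <- function(energy_keV, Z) {
  a <- .elasticAlpha(energy_keV, Z)
  5.21e-21 * (Z / energy_keV)^2 * 4 * pi / (a * (1 + a)) *
    ((energy_keV + 511) / (energy_keV + 1022))^2
}

## per-element macroscopic elastic cross-sections (1/um) for a vector of
## energies; returns a matrix [electron, element]
.macroSigma <- function(energy_keV, tr, density) {
  out <- matrix(0, length(energy_keV), length(tr$Z))
  for (i in seq_along(tr$Z)) {
    out[, i] <- 6.022140e23 * density * tr$massFrac[i] / tr$A[i] *
      .elasticSigma(energy_keV, tr$Z[i]) * 1e-4  # cm^-1 -> um^-1
  }
  out
}

#' Simulate photoelectron trajectories
#'
#' Electrons start at the origin with isotropic directions and undergo
#' free flights sampled from the elastic mean free path, polar deflections
#' sampled from the screened-Rutherford angular distribution, and
#' continuous energy loss along each step. A trajectory terminates when
#' its energy reaches the cutoff; the small residual range at the cutoff
#' is appended to the final step. Results are reproducible bit-exactly
#' from the seed.
#'
#' @param energy_keV start energy in keV
#' @param mat a [Material-class]
#' @param n number of electrons (>= 1)
#' @param seed integer RNG seed
#' @param cutoff termination energy in keV
#' @param keepPaths store full vertex paths (memory ~ n x steps); summaries
#'   are always kept
#' @return an [ElectronTrajectories-class] object
#' @export
simulateElectrons <- function(energy_keV, mat, n = 2000, seed = 1,
                              cutoff = 0.2, keepPaths = TRUE) {
  stopifnot(is(mat, "Material"))
  if (n <= 0) stop("n must be >= 1")
  n <- as.integer(n)
  seed <- as.integer(seed)

  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)

  tr <- .stoppingTerms(mat)
  rho <- mat@density
  rangeFull <- csdaRange(energy_keV, mat, cutoff = cutoff)
  # first-order residual range below the cutoff, appended to the last step
  resRange <- if (energy_keV > cutoff) cutoff / stoppingPower(cutoff, mat,
                                                              cutoff = cutoff)
              else 0

  px <- py <- pz <- numeric(n)
  # isotropic initial directions
  cu <- stats::runif(n, -1, 1)
  ph <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(pmax(0, 1 - cu^2))
  dx <- st * cos(ph); dy <- st * sin(ph); dz <- cu
  E <- rep(energy_keV, n)
  active <- rep(energy_keV > cutoff, n)
  deMax <- numeric(n)
  path <- numeric(n)
  nSteps <- integer(n)

  snapX <- list(); snapY <- list(); snapZ <- list(); snapE <- list()
  iter <- 0L
  while (any(active)) {
    iter <- iter + 1L
    if (iter > 100000L) stop("transport did not terminate")
    ia <- which(active)
    Ea <- E[ia]
    sig <- .macroSigma(Ea, tr, rho)       # [electron, element], 1/um
    sigTot <- rowSums(sig)
    step <- -log(stats::runif(length(ia))) / sigTot
    S <- stoppingPower(Ea, mat, cutoff = cutoff)
    # midpoint-corrected continuous energy loss over the step (keeps the
    # summed path length at the CSDA range instead of slightly above it)
    dE <- S * step
    dE <- stoppingPower(pmax(Ea - dE / 2, cutoff), mat, cutoff = cutoff) *
      step
    dE <- pmin(dE, Ea - cutoff / 2)
    dying <- (Ea - dE) <= cutoff
    # shorten the final step to land on the cutoff, then extend by the
    # residual sub-cutoff range
    step[dying] <- (Ea[dying] - cutoff) / S[dying] + resRange
    dE[dying] <- Ea[dying] - cutoff

    px[ia] <- px[ia] + dx[ia] * step
    py[ia] <- py[ia] + dy[ia] * step
    pz[ia] <- pz[ia] + dz[ia] * step
    path[ia] <- path[ia] + step
    deMax[ia] <- pmax(deMax[ia], abs(px[ia]))
    E[ia] <- Ea - dE
    nSteps[ia] <- nSteps[ia] + 1L

    if (keepPaths) {
      vx <- rep(NA_real_, n); vy <- vx; vz <- vx; ve <- vx
      vx[ia] <- px[ia]; vy[ia] <- py[ia]; vz[ia] <- pz[ia]; ve[ia] <- E[ia]
      snapX[[iter]] <- vx; snapY[[iter]] <- vy
      snapZ[[iter]] <- vz; snapE[[iter]] <- ve
    }

    active[ia[dying]] <- FALSE
    surv <- ia[!dying]
    if (length(surv)) {
      Es <- E[surv]
      sigS <- sig[!dying, , drop = FALSE]
      # element responsible for the collision, by macroscopic contribution
      pEl <- sigS / rowSums(sigS)
      r <- stats::runif(length(surv))
      # cumulative element probabilities per electron; first exceedance
      cm <- apply(pEl, 1, cumsum)            # [element, electron]
      elIdx <- max.col(t(cm >= rep(r, each = nrow(cm))),
                       ties.method = "first")
      alpha <- .elasticAlpha(Es, tr$Z[elIdx])
      R <- stats::runif(length(surv))
      cosT <- 1 - 2 * alpha * R / (1 + alpha - R)
      cosT <- pmin(1, pmax(-1, cosT))
      sinT <- sqrt(pmax(0, 1 - cosT^2))
      phi <- stats::runif(length(surv), 0, 2 * pi)
      # rotate direction by (theta, phi) about the current direction
      u <- dx[surv]; v <- dy[surv]; w <- dz[surv]
      sq <- sqrt(pmax(1e-30, 1 - w^2))
      cp <- cos(phi); sp <- sin(phi)
      nearPole <- sq < 1e-8
      du <- sinT * (u * w * cp - v * sp) / sq + u * cosT
      dv <- sinT * (v * w * cp + u * sp) / sq + v * cosT
      dw <- -sq * sinT * cp + w * cosT
      if (any(nearPole)) {
        sgn <- sign(w[nearPole])
        du[nearPole] <- sinT[nearPole] * cp[nearPole] * sgn
        dv[nearPole] <- sinT[nearPole] * sp[nearPole] * sgn
        dw[nearPole] <- cosT[nearPole] * sgn
      }
      nrm <- sqrt(du^2 + dv^2 + dw^2)
      dx[surv] <- du / nrm; dy[surv] <- dv / nrm; dz[surv] <- dw / nrm
    }
  }

  summ <- data.frame(deMax = deMax, finalX = px, finalY = py, finalZ = pz,
                     pathLength = path,
                     deposited = rep(energy_keV, n) - E,
                     nSteps = nSteps)
  paths <- list()
  if (keepPaths && iter > 0L) {
    X <- do.call(rbind, snapX); Y <- do.call(rbind, snapY)
    Zm <- do.call(rbind, snapZ); Em <- do.call(rbind, snapE)
    paths <- lapply(seq_len(n), function(i) {
      ok <- !is.na(X[, i])
      cbind(x = c(0, X[ok, i]), y = c(0, Y[ok, i]), z = c(0, Zm[ok, i]),
            energy = c(energy_keV, Em[ok, i]))
    })
  }
  new("ElectronTrajectories", energy = energy_keV, material = mat@name,
      seed = seed, cutoff = cutoff, csdaRange = rangeFull,
      summary = summ, paths = paths)
}

#' Build the symmetric penetration-depth distribution P(d_e)
#'
#' The penetration depth of each electron is its maximum displacement
#' projected on a fixed axis (alternatively the final resting position).
#' Depths are binned on a positive grid and mirrored to signed bins, so
#' the symmetry P(+|d_e|) = P(-|d_e|) holds exactly and total mass is 1.
#'
#' @param traj an [ElectronTrajectories-class] object
#' @param nBins number of bins per side
#' @param statistic "max_projection" (default) or "final_position"
#' @return a [PenetrationDistribution-class]
#' @export
penetrationDistribution <- function(traj, nBins = 100,
                                    statistic = c("max_projection",
                                                  "final_position")) {
  stopifnot(is(traj, "ElectronTrajectories"))
  statistic <- match.arg(statistic)
  d <- switch(statistic,
              max_projection = traj@summary$deMax,
              final_position = abs(traj@summary$finalX))
  if (!length(d)) stop("empty trajectory set")
  dmax <- max(d)
  if (dmax <= 0) dmax <- max(traj@csdaRange, 1e-6)
  edgesPos <- seq(0, dmax * (1 + 1e-9), length.out = nBins + 1)
  cnt <- tabulate(findInterval(d, edgesPos, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = nBins)
  mPos <- cnt / (2 * length(d))
  new("PenetrationDistribution",
      binEdges = c(-rev(edgesPos[-1]), edgesPos),
      mass = c(rev(mPos), mPos),
      nElectrons = length(d), material = traj@material,
      energy = traj@energy, seed = as.numeric(traj@seed))
}

#' Analytic penetration distributions for oracle tests
#'
#' `laplacePenetration` bins a double-exponential (Laplace) density with
#' scale `lambda`; `pointMassPenetration` places all mass at +/- d0.
#'
#' @param lambda Laplace scale in um
#' @param maxRange truncation radius in um
#' @param nBins bins per side
#' @return a [PenetrationDistribution-class]
#' @export
laplacePenetration <- function(lambda, maxRange = 12 * lambda, nBins = 600) {
  edgesPos <- seq(0, maxRange, length.out = nBins + 1)
  # one-sided mass in each bin: (1/2) (exp(-a/l) - exp(-b/l)), renormalized
  mPos <- 0.5 * (exp(-edgesPos[-(nBins + 1)] / lambda) -
                   exp(-edgesPos[-1] / lambda))
  mPos <- mPos / (2 * sum(mPos))
  new("PenetrationDistribution",
      binEdges = c(-rev(edgesPos[-1]), edgesPos),
      mass = c(rev(mPos), mPos),
      nElectrons = NA_real_, material = "analytic-laplace",
      energy = NA_real_, seed = NA_real_)
}

#' @rdname laplacePenetration
#' @param d0 displacement of the two point masses in um
#' @param halfWidth half width of the two narrow bins holding the mass
#' @export
pointMassPenetration <- function(d0, halfWidth = max(d0 * 1e-3, 1e-6)) {
  if (d0 <= 0) {  # degenerate: identity kernel at the origin
    edges <- c(-halfWidth, 0, halfWidth)
    return(new("PenetrationDistribution", binEdges = edges,
               mass = c(0.5, 0.5), nElectrons = NA_real_,
               material = "analytic-point", energy = NA_real_,
               seed = NA_real_))
  }
  edgesPos <- c(0, d0 - halfWidth, d0 + halfWidth)
  mPos <- c(0, 0.5)
  new("PenetrationDistribution",
      binEdges = c(-rev(edgesPos[-1]), edgesPos),
      mass = c(rev(mPos), mPos),
      nElectrons = NA_real_, material = "analytic-point",
      energy = NA_real_, seed = NA_real_)
}

#' Bin centers and masses of a penetration distribution
#' @param P a [PenetrationDistribution-class]
#' @export
binCenters <- function(P) (P@binEdges[-1] + P@binEdges[-length(P@binEdges)]) / 2

#' @rdname binCenters
#' @export
binMass <- function(P) P@mass

#' 1/e attenuation length of the penetration distribution
#'
#' Characteristic decay length of the one-sided survival function
#' S(d) = P(|d_e| > d).
#'
#' `method = "survival"` (default) returns the depth at which S crosses
#' 1/e, interpolated linearly in log S. This is the standard reading of an
#' attenuation length and remains meaningful for electron penetration
#' distributions, whose support is bounded by the CSDA range so that the
#' extreme tail steepens instead of decaying exponentially.
#'
#' `method = "tail_fit"` fits a straight line to log S over the outermost
#' `tailFraction` of one-sided probability mass and returns the negative
#' inverse slope. For a genuinely exponential tail both methods agree; for
#' a range-limited Monte-Carlo distribution the tail fit measures the
#' steep terminal slope near the maximum range and is therefore much
#' shorter.
#'
#' @param P a [PenetrationDistribution-class]
#' @param tailFraction fraction of one-sided mass defining the tail for
#'   `method = "tail_fit"`, in (0, 0.5]
#' @param method "survival" or "tail_fit"
#' @return attenuation length in um
#' @export
attenuationLength <- function(P, tailFraction = 0.2,
                              method = c("survival", "tail_fit")) {
  method <- match.arg(method)
  ctr <- binCenters(P)
  pos <- ctr > 0
  d <- ctr[pos]
  m <- P@mass[pos]
  tot <- sum(m)
  # survival evaluated at bin centers (half of the bin's own mass counted)
  surv <- (rev(cumsum(rev(m))) - m / 2) / tot
  if (method == "survival") {
    keep <- surv > 0
    if (sum(keep) < 2) stop("too few populated bins for the 1/e crossing")
    ls <- log(surv[keep]); dd <- d[keep]
    if (min(ls) > -1)
      stop("survival never falls below 1/e; distribution support too short")
    ord <- order(ls)
    return(stats::approx(ls[ord], dd[ord], xout = -1, ties = mean)$y)
  }
  if (tailFraction <= 0 || tailFraction > 0.5)
    stop("tailFraction must be in (0, 0.5]")
  # fit over two decades of decay below the tail threshold; the terminal
  # bins of a bounded-support histogram would otherwise dominate the slope
  use <- surv <= tailFraction & surv >= tailFraction / 100 & m > 0
  if (sum(use) < 4)
    stop("fewer than 4 populated tail bins; increase nBins or tailFraction")
  fit <- stats::lm(log(surv[use]) ~ d[use])
  sl <- unname(stats::coef(fit)[2])
  if (sl >= 0) stop("tail survival is not decaying; cannot fit")
  -1 / sl
}

setMethod("show", "ElectronTrajectories", function(object) {
  cat("ElectronTrajectories: ", nrow(object@summary), " electrons at ",
      object@energy, " keV in '", object@material, "' (seed ", object@seed,
      ", cutoff ", object@cutoff, " keV)\n", sep = "")
  cat("  CSDA range ", signif(object@csdaRange, 4), " um; median |d_e| ",
      signif(stats::median(object@summary$deMax), 4), " um\n", sep = "")
})

setMethod("show", "PenetrationDistribution", function(object) {
  cat("PenetrationDistribution: ", length(object@mass), " bins over [",
      signif(min(object@binEdges), 4), ", ", signif(max(object@binEdges), 4),
      "] um (", object@material, ", ",
      if (is.na(object@nElectrons)) "analytic"
      else paste0(object@nElectrons, " electrons"), ")\n", sep = "")
})
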