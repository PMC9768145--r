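#' Construct a Material
#'
#' @param name material label
#' @param atomicFractions named numeric vector of atomic fractions; any
#'   positive weights are accepted and normalized to sum to 1
#' @param density mass density in g/cm^3
#' @return a [Material-class] object
#' @examples
#' material("water-ish", c(H = 2, O = 1), density = 1.0)
#' @export
material <- function(name, atomicFractions, density) {
  if (is.null(names(atomicFractions)))
    stop("atomicFractions must be named by element symbol")
  for (el in names(atomicFractions)) .elementRow(el)  # errors on unknowns
  if (any(atomicFractions <= 0))
    stop("atomic fractions must be strictly positive")
  f <- atomicFractions / sum(atomicFractions)
  new("Material", name = name, atomicFractions = f, density = density)
}

#' Material presets for dry pike bone, its mineral phase, and collagen
#'
#' Compositions and densities follow published values for dry fish bone:
#' mineral H2 O26 P6 Ca10 at 1.01 g/cm^3, collagen
#' H0.49514 C0.31554 N0.08738 O0.10194 at 0.41 g/cm^3, and whole bone
#' Ca0.09863 P0.05918 O0.31413 N0.04946 C0.17861 H0.3 at 1.41 g/cm^3.
#'
#' @param name one of "bone", "mineral", "collagen"
#' @return a [Material-class] object
#' @export
materialPreset <- function(name = c("bone", "mineral", "collagen")) {
  name <- match.arg(name)
  path <- system.file("extdata", "materials.conf", package = "boneRad")
  mats <- readMaterialConfig(path)
  m <- mats[[name]]
  if (is.null(m)) stop("no preset named '", name, "'")
  m
}

#' Read materials from a key-value config file
#'
#' The format is blocks of `key: value` lines separated by blank lines,
#' with keys `name`, `elements` (space-separated symbols), `fractions`
#' (space-separated numbers, normalized on read) and `density` (g/cm^3).
#'
#' @param path config file path
#' @return named list of [Material-class] objects
#' @export
readMaterialConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  out <- list()
  for (b in blocks) {
    b <- b[nzchar(trimws(b))]
    if (!length(b)) next
    kv <- regmatches(b, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", b))
    keys <- vapply(kv, `[`, character(1), 2)
    vals <- vapply(kv, `[`, character(1), 3)
    names(vals) <- keys
    req <- c("name", "elements", "fractions", "density")
    if (!all(req %in% keys))
      stop("material block missing keys: ",
           paste(setdiff(req, keys), collapse = ", "))
    els <- strsplit(trimws(vals[["elements"]]), "\\s+")[[1]]
    fr <- as.numeric(strsplit(trimws(vals[["fractions"]]), "\\s+")[[1]])
    if (length(els) != length(fr))
      stop("elements and fractions differ in length for material '",
           vals[["name"]], "'")
    names(fr) <- els
    out[[vals[["name"]]]] <-
      material(vals[["name"]], fr, as.numeric(vals[["density"]]))
  }
  out
}

#' Convert atomic fractions to mass fractions
#'
#' Mass fraction of element i is proportional to its atomic fraction times
#' its standard atomic weight. The result sums to 1 and is invariant under
#' rescaling of the atomic fractions.
#'
#' @param mat a [Material-class] object
#' @return named numeric vector of mass fractions
#' @export
atomicToMassFractions <- function(mat) {
  stopifnot(is(mat, "Material"))
  f <- mat@atomicFractions
  w <- f * atomicWeight(names(f))
  w / sum(w)
}

#' Photoelectron kinetic energy after inner-shell ionization
#'
#' The ejected electron carries the incident photon energy minus the shell
#' binding energy. For an 18 keV beam ionizing the Ca K shell this is
#' 18 - 4.0381 = 13.9619 keV.
#'
#' @param incident_keV incident photon energy in keV
#' @param element absorbing element symbol
#' @param shell electron shell ("K")
#' @return photoelectron kinetic energy in keV
#' @export
photoelectronEnergy <- function(incident_keV, element, shell = "K") {
  eb <- bindingEnergy(element, shell)
  if (incident_keV < eb)
    stop("below absorption edge: incident ", incident_keV,
         " keV < ", element, " ", shell, "-edge ", eb, " keV")
  incident_keV - eb
}

#' Beer-Lambert transmission through a material slab
#'
#' Uses the mass-fraction-weighted mixture rule for mu/rho with packaged
#' elemental attenuation coefficients (log-log interpolated).
#'
#' @param mat a [Material-class] object
#' @param thickness_um slab thickness in um (>= 0)
#' @param energy_keV photon energy in keV (within the packaged 2-100 keV grid)
#' @return transmitted fraction in (0, 1]
#' @export
transmission <- function(mat, thickness_um, energy_keV) {
  stopifnot(is(mat, "Material"))
  if (any(thickness_um < 0)) stop("thickness must be >= 0")
  mf <- atomicToMassFractions(mat)
  muRho <- 0
  for (el in names(mf))
    muRho <- muRho + mf[[el]] * .elementMuRho(el, energy_keV)
  exp(-muRho * mat@density * thickness_um * 1e-4)
}

#' Mixture mass attenuation coefficient
#' @inheritParams transmission
#' @return mu/rho of the mixture in cm^2/g
#' @export
massAttenuation <- function(mat, energy_keV) {
  stopifnot(is(mat, "Material"))
  mf <- atomicToMassFractions(mat)
  out <- 0
  for (el in names(mf))
    out <- out + mf[[el]] * .elementMuRho(el, energy_keV)
  out
}

#' Construct a beam specification
#'
#' Defaults correspond to the moderate-flux 18 keV microbeam configuration
#' used for point irradiation of bone (5.5e7 ph/s through a 20 um pinhole).
#'
#' @param energy photon energy keV
#' @param flux photons per second
#' @param widthH,widthV lateral beam widths in um
#' @param profile "rect" or "rect-gaussian-smeared"
#' @param smearSigma Gaussian smear sigma in um
#' @return a [BeamSpec-class] object
#' @export
beamSpec <- function(energy = 18, flux = 5.5e7, widthH = 20, widthV = widthH,
                     profile = "rect", smearSigma = 0) {
  new("BeamSpec", energy = energy, flux = flux, widthH = widthH,
      widthV = widthV, profile = profile, smearSigma = smearSigma)
}

#' Absorbed dose in the illuminated volume
#'
#' Dose (Gy) = absorbed energy / illuminated mass, with absorbed energy =
#' flux x exposure x photon energy x (1 - transmission) and illuminated
#' mass = density x beam cross-section x thickness. The beam cross-section
#' is the ellipse pi * (widthH/2) * (widthV/2).
#'
#' @param beam a [BeamSpec-class]
#' @param mat a [Material-class]
#' @param thickness_um sample thickness in um
#' @param exposure_s exposure time in s (> 0)
#' @return absorbed dose in Gy
#' @export
absorbedDose <- function(beam, mat, thickness_um, exposure_s) {
  stopifnot(is(beam, "BeamSpec"), is(mat, "Material"))
  if (exposure_s < 0) stop("exposure must be non-negative")
  area_cm2 <- pi * (beam@widthH / 2) * (beam@widthV / 2) * 1e-8
  if (area_cm2 <= 0) stop("zero beam area")
  mass_g <- mat@density * area_cm2 * thickness_um * 1e-4
  eJ <- beam@energy * 1.602177e-16
  absorbed <- beam@flux * exposure_s * eJ *
    (1 - transmission(mat, thickness_um, beam@energy))
  absorbed / (mass_g * 1e-3)
}

setMethod("show", "Material", function(object) {
  f <- object@atomicFractions
  cat("Material '", object@name, "': ",
      paste0(names(f), sprintf("%.4f", f), collapse = " "),
      ", density ", object@density, " g/cm^3\n", sep = "")
})

setMethod("show", "BeamSpec", function(object) {
  cat("BeamSpec: ", object@energy, " keV, ", format(object@flux), " ph/s, ",
      object@widthH, " x ", object@widthV, " um (", object@profile, ")\n",
      sep = "")
})
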