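## Packaged constant tables (atomic weights, binding energies, mean
## ionization potentials, elemental mu/rho grids). Loaded lazily from
## inst/extdata; sources documented in inst/extdata/README.

.boneRadEnv <- new.env(parent = emptyenv())

.constTable <- function(which) {
  key <- paste0("tbl_", which)
  if (!exists(key, envir = .boneRadEnv)) {
    path <- system.file("extdata", paste0(which, ".csv"), package = "boneRad")
    if (!nzchar(path))
      stop("packaged constant table '", which, "' not found")
    assign(key, utils::read.csv(path, stringsAsFactors = FALSE),
           envir = .boneRadEnv)
  }
  get(key, envir = .boneRadEnv)
}

#' Elements with packaged physical constants
#' @return character vector of element symbols
#' @export
knownElements <- function() .constTable("atomic_constants")$element

.elementRow <- function(element) {
  tab <- .constTable("atomic_constants")
  i <- match(element, tab$element)
  if (is.na(i))
    stop("unknown element symbol: '", element,
         "' (packaged constants cover ", paste(tab$element, collapse = ", "),
         ")")
  tab[i, ]
}

#' Standard atomic weight of an element
#' @param element element symbol (e.g. "Ca")
#' @export
atomicWeight <- function(element)
  unname(vapply(element, function(e) .elementRow(e)$atomic_weight, numeric(1)))

#' K-shell binding energy in keV
#' @param element element symbol
#' @param shell electron shell; only "K" is packaged
#' @export
bindingEnergy <- function(element, shell = "K") {
  if (!identical(shell, "K"))
    stop("only K-shell binding energies are packaged")
  e <- unname(vapply(element, function(s) .elementRow(s)$k_binding_keV,
              numeric(1)))
  if (any(is.na(e)))
    stop("no packaged binding energy for: ",
         paste(element[is.na(e)], collapse = ", "))
  e
}

#' K-alpha fluorescence line energy in keV
#' @inheritParams bindingEnergy
#' @export
fluorescenceEnergy <- function(element, shell = "K") {
  if (!identical(shell, "K"))
    stop("only K-series fluorescence lines are packaged")
  e <- unname(vapply(element, function(s) .elementRow(s)$kalpha_keV,
              numeric(1)))
  if (any(is.na(e)))
    stop("no packaged fluorescence line for: ",
         paste(element[is.na(e)], collapse = ", "))
  e
}

## log-log interpolation of elemental mu/rho; absorption edges are stored
## as paired rows just below/above the edge, so interpolation never
## crosses an edge.
.elementMuRho <- function(element, energy_keV) {
  tab <- .constTable("mass_attenuation")
  sub <- tab[tab$element == element, ]
  if (nrow(sub) == 0)
    stop("no packaged mass attenuation data for element '", element, "'")
  rng <- range(sub$energy_keV)
  if (any(energy_keV < rng[1] | energy_keV > rng[2]))
    stop("energy outside packaged mass-attenuation range [",
         rng[1], ", ", rng[2], "] keV")
  exp(stats::approx(log(sub$energy_keV), log(sub$mu_rho_cm2_g),
                    xout = log(energy_keV), ties = "ordered")$y)
}
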