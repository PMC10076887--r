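# Atomic masses (g/mol), IUPAC conventional values
.ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)

#' C-mol properties of a compound
#'
#' Computes the C-molar mass and the degree of reduction (available
#' electrons per C-mol, referenced to CO2, H2O and NH3) of a compound
#' given its elemental composition. These are the two quantities needed
#' to write carbon and electron balances over a black-box description of
#' growth.
#'
#' @param c,h,o,n Atoms per molecule (or per formula unit). `c` must be
#'   positive; fractional values are allowed, as is conventional for
#'   biomass formulae such as CH1.8O0.5N0.2.
#' @return A list with `cmol_mass` (g per C-mol) and `gamma` (electrons
#'   per C-mol).
#' @examples
#' cmol_properties(3, 8, 3, 0)  # glycerol: 30.70 g/C-mol, gamma 4.667
#' cmol_properties(1, 1.8, 0.5, 0.2)  # generic yeast biomass
#' @export
cmol_properties <- function(c, h, o, n) {
  if (!is.numeric(c) || c <= 0) stop("'c' (carbon atoms) must be > 0")
  if (h < 0 || o < 0 || n < 0) stop("'h', 'o', 'n' must be >= 0")
  list(
    cmol_mass = (.ATOMIC_MASS["C"] * c + .ATOMIC_MASS["H"] * h +
                 .ATOMIC_MASS["O"] * o + .ATOMIC_MASS["N"] * n) / c,
    gamma = (4 * c + h - 2 * o - 3 * n) / c
  )
}

#' Define a compound for elemental bookkeeping
#'
#' @param name Compound label.
#' @param c,h,o,n Atoms per molecule; see [cmol_properties()].
#' @return An object of class `compound` with fields `name`, `c`, `h`,
#'   `o`, `n`, `cmol_mass` and `gamma`.
#' @seealso [compound_library()] for ready-made presets.
#' @export
compound <- function(name, c, h, o, n = 0) {
  p <- cmol_properties(c, h, o, n)
  structure(
    list(name = name, c = c, h = h, o = o, n = n,
         cmol_mass = unname(p$cmol_mass), gamma = unname(p$gamma)),
    class = "compound"
  )
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound> %s  C%sH%sO%sN%s  %.3f g/C-mol  gamma %.3f\n",
              x$name, x$c, x$h, x$o, x$n, x$cmol_mass, x$gamma))
  invisible(x)
}

#' Built-in compound presets
#'
#' Small library of compounds used throughout the package. Two biomass
#' presets ship with the package: a generic yeast composition
#' CH1.8O0.5N0.2 and a composition typical of glycerol-grown
#' *K. phaffii* from published elemental analyses (CH1.785O0.572N0.166,
#' ash-free). Ammonia is the assumed nitrogen source (cultures pH
#' controlled with NH4OH), so degrees of reduction are NH3-referenced.
#'
#' @param name Optional preset name; one of `"glycerol"`,
#'   `"biomass_generic"`, `"biomass_kphaffii_glycerol"`, `"glucose"`.
#'   If missing, the full list is returned.
#' @return A single `compound` or a named list of them.
#' @export
compound_library <- function(name) {
  lib <- list(
    glycerol = compound("glycerol", 3, 8, 3),
    glucose = compound("glucose", 6, 12, 6),
    biomass_generic = compound("biomass CH1.8O0.5N0.2", 1, 1.8, 0.5, 0.2),
    biomass_kphaffii_glycerol =
      compound("K. phaffii biomass (glycerol-grown)", 1, 1.785, 0.572, 0.166)
  )
  if (missing(name)) return(lib)
  if (!name %in% names(lib))
    stop("unknown compound preset '", name, "'; available: ",
         paste(names(lib), collapse = ", "))
  lib[[name]]
}

#' Convert a mass-based biomass yield to C-mol basis
#'
#' @param Y_mass Biomass-on-substrate yield, g biomass per g substrate.
#' @param substrate,biomass `compound` objects.
#' @return Yield in C-mol biomass per C-mol substrate.
#' @examples
#' mass_yield_to_cmol(0.54, compound_library("glycerol"),
#'                    compound_library("biomass_generic"))
#' @export
mass_yield_to_cmol <- function(Y_mass, substrate, biomass) {
  if (Y_mass < 0) stop("'Y_mass' must be >= 0")
  Y_mass * substrate$cmol_mass / biomass$cmol_mass
}

#' Black-box gas exchange rates from substrate uptake and yield
#'
#' Predicts specific O2 consumption and CO2 production rates from the
#' specific substrate uptake rate and the biomass yield, using the
#' carbon balance (CO2 carbon = substrate carbon not fixed in biomass)
#' and the electron balance (O2 takes up the electrons not conserved in
#' biomass). Product carbon is neglected: the secreted enzyme is
#' quantified in activity units only, so its elemental contribution is
#' unknown; the resulting bias lowers the predicted RQ slightly.
#'
#' @param q_S Specific substrate uptake rate, g substrate / g DCW / h.
#' @param Y_XS Biomass yield, g DCW / g substrate.
#' @param substrate,biomass `compound` objects (defaults: glycerol and
#'   generic yeast biomass).
#' @param X Optional biomass concentration (g DCW/L); when given, the
#'   vessel-level OUR and CER (mmol/L/h) are also returned.
#' @return An object of class `gas_rates`: list with `q_O2`, `q_CO2`
#'   (mmol / g DCW / h), `RQ`, and `OUR`, `CER` (mmol/L/h, `NA` unless
#'   `X` is supplied).
#' @examples
#' gas_rates_from_yields(0.046, 0.54)  # RQ ~ 0.71
#' gas_rates_from_yields(0.05, 0)      # pure combustion of glycerol, RQ 6/7
#' @export
gas_rates_from_yields <- function(q_S, Y_XS,
                                  substrate = compound_library("glycerol"),
                                  biomass = compound_library("biomass_generic"),
                                  X = NULL) {
  if (q_S < 0) stop("'q_S' must be >= 0")
  if (Y_XS < 0) stop("'Y_XS' must be >= 0")
  Y_cmol <- mass_yield_to_cmol(Y_XS, substrate, biomass)
  if (Y_cmol > 1)
    stop("infeasible yield: more biomass carbon than substrate carbon")
  co2_per_cmolS <- 1 - Y_cmol                                  # carbon balance
  o2_per_cmolS <- (substrate$gamma - Y_cmol * biomass$gamma) / 4  # electron balance
  if (o2_per_cmolS < 0)
    stop("infeasible yield: electron balance implies negative O2 uptake")
  qS_cmol <- q_S / substrate$cmol_mass * 1000   # mmol C-mol substrate /g/h
  q_CO2 <- co2_per_cmolS * qS_cmol
  q_O2 <- o2_per_cmolS * qS_cmol
  structure(
    list(q_O2 = q_O2, q_CO2 = q_CO2,
         RQ = if (q_O2 > 0) q_CO2 / q_O2 else NA_real_,
         OUR = if (is.null(X)) NA_real_ else q_O2 * X,
         CER = if (is.null(X)) NA_real_ else q_CO2 * X),
    class = "gas_rates"
  )
}

#' @export
print.gas_rates <- function(x, ...) {
  cat(sprintf("<gas_rates> qO2 %.4g  qCO2 %.4g mmol/g/h  RQ %.3f\n",
              x$q_O2, x$q_CO2, x$RQ))
  invisible(x)
}
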