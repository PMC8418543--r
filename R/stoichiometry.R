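# Global growth stoichiometry for M. gryphiswaldense MSR-1.
#
# The published global growth equation for this organism is carried with its
# coefficients exactly as printed at the source (the printed typography is
# corrupted; species identities are reconstructed from context: lactic acid
# substrate counted per 3-carbon molecule, nitrate and ammonium nitrogen
# sources, C-mol biomass):
#
#   352 C3H6O3 + 33.6 NO3- + 133 NH4+ + 6.46 O2 + 1.25 Fe3+
#     -> 718.4 CH2.06 O0.13 N0.28 Fe0.00174 + 591.3 H2O + 314 CO2
#
# The equation does not balance element-by-element; the imbalance is a
# property of the source data, so residuals are REPORTED, never forced to
# zero or raised as errors.

#' MSR-1 growth stoichiometry (as published)
#'
#' @return a `StoichiometrySpec`: list with `coefficients` (named molar
#'   coefficients), `biomass_formula` (element indices per C-mol of biomass)
#'   and `substrate_formula` (elements per substrate molecule)
#' @export
msr1_stoichiometry <- function() {
  list(
    coefficients = c(substrate = 352, nitrate = 33.6, ammonium = 133,
                     oxygen = 6.46, ferric = 1.25,
                     biomass = 718.4, water = 591.3, co2 = 314),
    biomass_formula = c(C = 1, H = 2.06, O = 0.13, N = 0.28, Fe = 0.00174),
    substrate_formula = c(C = 3, H = 6, O = 3))
}

# molar mass of one C-mol of biomass (g/mol)
biomass_molar_mass <- function(st) {
  w <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, Fe = 55.845)
  sum(w[names(st$biomass_formula)] * st$biomass_formula)
}

#' Yield coefficients and element-balance residuals
#'
#' Ratios of the printed stoichiometric coefficients (mol/mol), plus the
#' per-element balance residual (moles in minus moles out, per the printed
#' equation).  Residuals are reported, not enforced: the printed equation is
#' out of balance (the nitrogen residual, for instance, is -34.55 mol) and
#' the model treats that as a property of the source data.
#'
#' @param st a stoichiometry spec, see [msr1_stoichiometry()]
#' @return list with `biomass_per_substrate`, `fe_per_biomass`,
#'   `o2_per_substrate`, `co2_per_substrate` (mol/mol) and `residuals`
#'   (named vector, mol, elements C/H/O/N/Fe)
#' @examples
#' y <- stoichiometric_yields()
#' y$biomass_per_substrate   # 718.4 / 352
#' y$residuals["N"]
#' @export
stoichiometric_yields <- function(st = msr1_stoichiometry()) {
  co <- st$coefficients
  if (!is.numeric(co) || any(co <= 0))
    stop("all stoichiometric coefficients must be strictly positive",
         call. = FALSE)
  bf <- st$biomass_formula
  sf <- st$substrate_formula

  inn <- c(
    C  = co[["substrate"]] * sf[["C"]],
    H  = co[["substrate"]] * sf[["H"]] + co[["ammonium"]] * 4,
    O  = co[["substrate"]] * sf[["O"]] + co[["nitrate"]] * 3 +
         co[["oxygen"]] * 2,
    N  = co[["nitrate"]] + co[["ammonium"]],
    Fe = co[["ferric"]])
  out <- c(
    C  = co[["biomass"]] * bf[["C"]] + co[["co2"]],
    H  = co[["biomass"]] * bf[["H"]] + co[["water"]] * 2,
    O  = co[["biomass"]] * bf[["O"]] + co[["water"]] + co[["co2"]] * 2,
    N  = co[["biomass"]] * bf[["N"]],
    Fe = co[["biomass"]] * bf[["Fe"]])

  list(
    biomass_per_substrate = co[["biomass"]] / co[["substrate"]],
    fe_per_biomass        = co[["ferric"]] / co[["biomass"]],
    o2_per_substrate      = co[["oxygen"]] / co[["substrate"]],
    co2_per_substrate     = co[["co2"]] / co[["substrate"]],
    residuals             = inn - out)
}
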