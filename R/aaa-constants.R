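# Physical constants and the solute registry shared by all modules.
#
# Working unit conventions (documented in the methods vignette):
#   concentration  mM  (= pmol/nl)
#   tubular flow   nl/min (per nephron or per duct)
#   length         cm
#   potential      mV
#   pressure       mmHg
#   solute flux    pmol/(min.cm tubule)
#   water flux     nl/(min.cm tubule)
#   permeability   cm/s
#   transporter maximal rate ("activity")  pmol/(min.cm2 membrane)

## RT/F at 310 K, in mV
RTF <- 26.7

## temperature (K), fixed
TEMP_K <- 310

## convert P[cm/s] * area[cm2/cm] * C[mM] to pmol/(min.cm)
FLUX_CONV <- 6e7

## convert Pf[cm/s] * area[cm2/cm] * dC[mOsm] to nl/(min.cm)
## (includes the 18 cm3/mol partial molar volume of water)
WATER_CONV <- 18e-6 * 6e7

## osmotic pressure of 1 mM ideal solute at 310 K, in mmHg
MMHG_PER_MOSM <- 19.33

## tubular fluid viscosity, g/(cm.s) (= 0.69 cP at 37 C)
VISCOSITY <- 6.9e-3

#' Solute registry
#'
#' The model tracks 15 solutes: the major electrolytes, the CO2/bicarbonate
#' system, the ammonia, phosphate and formate buffer pairs, protons, urea and
#' glucose.  Valences are fixed by chemistry.
#'
#' @return A data.frame with one row per solute: `name`, `valence`,
#'   `is_buffer_member`, and `partner` (the buffer reaction the solute takes
#'   part in, or `NA`).
#' @export
#' @examples
#' solute_table()
solute_table <- function() {
  data.frame(
    name = c("Na", "K", "Cl", "HCO3", "H2CO3", "CO2", "NH3", "NH4",
             "H2PO4", "HPO4", "H", "HCO2", "H2CO2", "urea", "glucose"),
    valence = c(1L, 1L, -1L, -1L, 0L, 0L, 0L, 1L,
                -1L, -2L, 1L, -1L, 0L, 0L, 0L),
    is_buffer_member = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                         TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    partner = c(NA, NA, NA, "carbonic", "carbonic", "carbonic",
                "ammonia", "ammonia", "phosphate", "phosphate",
                "carbonic;ammonia;phosphate;formate",
                "formate", "formate", NA, NA),
    stringsAsFactors = FALSE
  )
}

## cached fast-path versions used throughout the numerics
SOLUTES <- c("Na", "K", "Cl", "HCO3", "H2CO3", "CO2", "NH3", "NH4",
             "H2PO4", "HPO4", "H", "HCO2", "H2CO2", "urea", "glucose")
VALENCE <- c(1, 1, -1, -1, 0, 0, 0, 1, -1, -2, 1, -1, 0, 0, 0)
names(VALENCE) <- SOLUTES
N_SOL <- 15L

VALENCE3 <- rep(VALENCE, 3)

## index helpers (fixed order; used in hot loops)
I_NA <- 1L; I_K <- 2L; I_CL <- 3L; I_HCO3 <- 4L; I_H2CO3 <- 5L
I_CO2 <- 6L; I_NH3 <- 7L; I_NH4 <- 8L; I_H2PO4 <- 9L; I_HPO4 <- 10L
I_H <- 11L; I_HCO2 <- 12L; I_H2CO2 <- 13L; I_UREA <- 14L; I_GLC <- 15L

## Buffer reaction constants.  Equilibrium constants are expressed in mM so
## that e.g. [H][NH3]/[NH4] = K_NH with all concentrations in mM.
## pKa(molar) -> K[mM] = 10^(3 - pKa).
BUFFER_K <- list(
  ## H2CO3 <-> H+ + HCO3-  (apparent, with CO2/H2CO3 handled separately)
  K_HCO3 = 10^(3 - 3.57),
  ## CO2 + H2O <-> H2CO3 hydration/dehydration rate constants (1/s)
  kh_CO2 = 0.0436,
  kd_CO2 = 49.6,
  ## NH4+ <-> NH3 + H+
  K_NH = 10^(3 - 9.15),
  ## H2PO4- <-> HPO4-- + H+
  K_P = 10^(3 - 6.8),
  ## H2CO2 (formic acid) <-> HCO2- + H+
  K_F = 10^(3 - 3.75)
)

`%||%` <- function(a, b) if (is.null(a)) b else a
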