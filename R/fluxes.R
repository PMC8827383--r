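# Pure flux-law library.
#
# Every law is a pure function of (state, parameters).  Sign conventions:
# fluxes are positive from side 1 to side 2 of the membrane; at the apical
# membrane side 1 is the lumen, at the basolateral membrane side 1 is the
# cell, at the tight junction side 1 is the lumen.  Solute fluxes are in
# pmol/(min.cm tubule), water fluxes in nl/(min.cm tubule).

#' Osmotic water flux across a membrane
#'
#' Volume flux driven by the effective osmotic difference (reflection-
#' coefficient weighted) plus the hydrostatic pressure difference:
#' \deqn{J_v = P_f A \bar V_w \left(\sum_i \sigma_i (C_{2,i} - C_{1,i}) +
#'   (P_1 - P_2)/RT\right)}
#' Positive flux moves water from side 1 to side 2 (for the apical membrane
#' and the tight junction, lumen-to-epithelium, i.e. reabsorption).
#'
#' @param pf osmotic water permeability (cm/s)
#' @param area membrane area per unit tubule length (cm2/cm)
#' @param c1,c2 solute concentrations on each face (mM, vectors)
#' @param sigma reflection coefficients (0-1, recycled over solutes)
#' @param p1,p2 hydrostatic pressures (mmHg)
#' @return water flux, nl/(min.cm)
#' @export
water_flux <- function(pf, area, c1, c2, sigma = 1, p1 = 0, p2 = 0) {
  if (pf < 0 || area <= 0) stop("water_flux: pf must be >= 0 and area > 0")
  drive <- sum(sigma * (c2 - c1)) + (p1 - p2) / MMHG_PER_MOSM
  pf * area * WATER_CONV * drive
}

#' Goldman-Hodgkin-Katz electrodiffusive flux
#'
#' Constant-field flux of a charged solute across a membrane held at
#' potential difference `dv = V1 - V2`.  For an uncharged solute the law
#' reduces to Fick diffusion `P A (C1 - C2)`; the implementation is
#' continuous through `dv = 0` (series expansion of the field factor for
#' small arguments).  Vectorised over solutes.
#'
#' @param perm permeability (cm/s), vector over solutes
#' @param area membrane area per unit tubule length (cm2/cm)
#' @param z valence vector
#' @param c1,c2 concentrations (mM) on side 1 / side 2
#' @param dv potential difference `V1 - V2` (mV)
#' @return molar flux, pmol/(min.cm), positive from side 1 to side 2
#' @export
electrodiffusive_flux <- function(perm, area, z, c1, c2, dv) {
  u <- z * dv / RTF
  phi <- u / (1 - exp(-u))
  small <- abs(u) < 1e-6
  if (any(small))                      # series branch, continuous at 0
    phi[small] <- 1 + u[small] / 2 + u[small] * u[small] / 12
  perm * area * FLUX_CONV * phi * (c1 - c2 * exp(-u))
}

#' Paracellular (tight-junction) solute flux
#'
#' Electrodiffusive GHK term across the junction plus solvent drag carried
#' by the junctional water flux:
#' \deqn{J = J_{GHK} + (1-\sigma)\,\bar C\, J_{v,tj}}
#' with \eqn{\bar C} the logarithmic mean of the two face concentrations.
#' The flux may be negative (secretion into the lumen), as for Na+ along the
#' proximal straight tubule under strong osmotic diuresis.
#'
#' @inheritParams electrodiffusive_flux
#' @param sigma junction reflection coefficients
#' @param jv_tj junctional water flux (nl/(min.cm), positive lumen-to-
#'   interstitium)
#' @return molar flux, pmol/(min.cm)
#' @export
paracellular_flux <- function(perm, area, z, c1, c2, dv, sigma, jv_tj) {
  diffusive <- electrodiffusive_flux(perm, area, z, c1, c2, dv)
  cbar <- log_mean(c1, c2)
  diffusive + (1 - sigma) * cbar * jv_tj
}

## logarithmic mean concentration, continuous at c1 == c2
log_mean <- function(c1, c2) {
  r <- log(c1 / c2)
  out <- (c1 - c2) / r
  same <- abs(r) < 1e-8
  if (any(same)) out[same] <- (c1[same] + c2[same]) / 2
  out
}

#' Na+/K+-ATPase pump flux
#'
#' Saturable Hill form in cytosolic Na+ (cooperativity 3) modulated by
#' external (peritubular) K+ (cooperativity 2); the flux ratio is fixed at
#' the physiological 3 Na+ out : 2 K+ in stoichiometry.
#'
#' @param cell_na cytosolic Na+ (mM)
#' @param ext_k peritubular K+ (mM)
#' @param activity maximal rate density (pmol/(min.cm2))
#' @param area membrane area per unit tubule length (cm2/cm)
#' @param k_na,k_k half-saturation constants (mM)
#' @return list with `Na` (positive = out of cell) and `K` (negative of 2/3
#'   the Na+ flux, i.e. into the cell), pmol/(min.cm)
#' @export
nak_atpase_flux <- function(cell_na, ext_k, activity, area = 1,
                            k_na = 12, k_k = 1.5) {
  if (activity < 0) stop("pump activity must be non-negative")
  jna <- activity * area * (cell_na / (cell_na + k_na))^3 *
    (ext_k / (ext_k + k_k))^2
  list(Na = jna, K = -2 / 3 * jna)
}

#' Sodium-glucose cotransporter flux (SGLT1/SGLT2)
#'
#' Reversible saturable carrier with thermodynamically consistent
#' equilibrium: the flux vanishes exactly when the combined electrochemical
#' driving force of n Na+ plus one glucose is zero.  SGLT2 is the
#' high-capacity low-affinity isoform (1 Na+ : 1 glucose); SGLT1 the
#' low-capacity high-affinity isoform (2 Na+ : 1 glucose).
#'
#' @param lumen_na,lumen_glc luminal Na+ and glucose (mM)
#' @param cell_na,cell_glc cytosolic Na+ and glucose (mM)
#' @param dv potential difference lumen minus cell (mV)
#' @param isoform `"SGLT2"` or `"SGLT1"`
#' @param activity maximal rate density (pmol glucose/(min.cm2))
#' @param area apical membrane area per unit tubule length (cm2/cm)
#' @return list with `glucose` and `Na` fluxes (pmol/(min.cm), positive into
#'   the cell); `Na` is exactly n times `glucose`
#' @export
sglt_flux <- function(lumen_na, lumen_glc, cell_na, cell_glc, dv,
                      isoform = "SGLT2", activity, area = 1) {
  if (isoform == "SGLT2") {
    n <- 1; k_na <- 25; k_glc <- 10
  } else if (isoform == "SGLT1") {
    n <- 2; k_na <- 15; k_glc <- 1
  } else stop("unknown SGLT isoform: ", isoform)
  u <- dv / RTF
  af <- (lumen_na / k_na)^n * (lumen_glc / k_glc) * exp( n * u / 2)
  ar <- (cell_na  / k_na)^n * (cell_glc  / k_glc) * exp(-n * u / 2)
  jg <- activity * area * (af - ar) / (1 + af + ar)
  list(glucose = jg, Na = n * jg)
}

#' Facilitated glucose transport (GLUT1/GLUT2)
#'
#' Symmetric carrier; sign follows the concentration gradient, zero flux at
#' equal concentrations, half-saturation at the isoform Km.
#'
#' @param c1,c2 glucose on the two faces (mM); positive flux is 1 to 2
#' @param isoform `"GLUT2"` (Km 17 mM) or `"GLUT1"` (Km 2 mM)
#' @param activity maximal rate density (pmol/(min.cm2))
#' @param area membrane area per unit tubule length (cm2/cm)
#' @return glucose flux, pmol/(min.cm)
#' @export
glut_flux <- function(c1, c2, isoform = "GLUT2", activity, area = 1) {
  km <- if (isoform == "GLUT2") 17
        else if (isoform == "GLUT1") 2
        else stop("unknown GLUT isoform: ", isoform)
  activity * area * (c1 / (c1 + km) - c2 / (c2 + km))
}

#' Electroneutral cotransporter flux (NKCC2, NCC, KCC)
#'
#' Flux proportional to the thermodynamic affinity (log mass-action ratio)
#' of the coupled translocation; component fluxes are in exact
#' stoichiometric ratio and vanish together at equilibrium.  The
#' stoichiometry must be electroneutral.
#'
#' @param stoich named vector of stoichiometric coefficients
#'   (e.g. `c(Na = 1, K = 1, Cl = 2)` for NKCC2)
#' @param c1,c2 named concentration vectors on side 1 / side 2 (mM); must
#'   contain the names of `stoich`
#' @param activity rate density per unit log affinity (pmol/(min.cm2))
#' @param area membrane area per unit tubule length (cm2/cm)
#' @return named vector of component fluxes (pmol/(min.cm), positive 1 to 2)
#' @export
cotransport_flux <- function(stoich, c1, c2, activity, area = 1) {
  nm <- names(stoich)
  zs <- VALENCE[nm]
  if (anyNA(zs) || abs(sum(zs * stoich)) > 1e-12)
    stop("cotransport stoichiometry must be electroneutral over known solutes")
  aff <- sum(stoich * log(c1[nm] / c2[nm]))
  j <- activity * area * aff
  stats::setNames(as.numeric(stoich) * j, nm)
}

#' NHE3 Na+/H+ (and Na+/NH4+) exchanger flux
#'
#' Antiporter carrier: external Na+ exchanges for internal H+ with
#' competition from internal NH4+ at the proton site.  Saturable in all
#' substrates; zero flux for a symmetric state.
#'
#' @param lumen_na,cell_na Na+ (mM)
#' @param lumen_h,cell_h H+ (mM)
#' @param lumen_nh4,cell_nh4 NH4+ (mM)
#' @param activity maximal rate density (pmol/(min.cm2))
#' @param area apical membrane area per unit tubule length (cm2/cm)
#' @param k_na,k_h,k_nh4 half-saturation constants (mM); `k_h` sets the
#'   luminal pH at which the exchanger self-limits (~pH 6.6)
#' @return list of fluxes `Na` (positive into the cell), `H` and `NH4`
#'   (positive out of the cell); `Na = H + NH4` exactly
#' @export
nhe3_flux <- function(lumen_na, cell_na, lumen_h, cell_h,
                      lumen_nh4, cell_nh4, activity, area = 1,
                      k_na = 30, k_h = 2.5e-4, k_nh4 = 2) {
  if (activity < 0) stop("NHE3 activity must be non-negative")
  s_l <- lumen_na / (lumen_na + k_na)
  s_c <- cell_na / (cell_na + k_na)
  occ <- function(h, nh4) {
    d <- 1 + h / k_h + nh4 / k_nh4
    c(h = (h / k_h) / d, n = (nh4 / k_nh4) / d)
  }
  o_l <- occ(lumen_h, lumen_nh4)
  o_c <- occ(cell_h, cell_nh4)
  jh <- activity * area * (s_l * o_c[["h"]] - s_c * o_l[["h"]])
  jn <- activity * area * (s_l * o_c[["n"]] - s_c * o_l[["n"]])
  list(Na = jh + jn, H = jh, NH4 = jn)
}

#' H+-ATPase flux
#'
#' Minimal proton pump for the collecting duct: saturable in cytosolic H+
#' and stalling smoothly as the luminal pH approaches a minimal value
#' (luminal acidification limit).
#'
#' @param cell_h cytosolic H+ (mM)
#' @param lumen_h luminal H+ (mM)
#' @param activity maximal rate density (pmol/(min.cm2))
#' @param area apical membrane area per unit tubule length (cm2/cm)
#' @param k_h half-saturation in cytosolic H+ (mM)
#' @param ph_min luminal pH at which the pump stalls
#' @return H+ flux, pmol/(min.cm), positive into the lumen
#' @export
h_atpase_flux <- function(cell_h, lumen_h, activity, area = 1,
                          k_h = 3e-4, ph_min = 4.3) {
  if (activity < 0) stop("pump activity must be non-negative")
  ph_l <- -log10(max(lumen_h, 1e-12) * 1e-3)
  gate <- 1 / (1 + exp(-(ph_l - ph_min) / 0.25))
  activity * area * (cell_h / (cell_h + k_h)) * gate
}

#' Flow-dependent (microvillous torque) activity multiplier
#'
#' Proximal tubule cells scale their transcellular transport density with
#' the drag torque exerted on the microvilli by luminal flow.  The torque is
#' taken proportional to the wall shear, \eqn{T \propto \mu F / r^3}, and
#' the multiplier is linear in the torque ratio with slope `s`, clamped to
#' [0.5, 2.5].
#'
#' @param flow local luminal flow (nl/min)
#' @param radius local luminal radius (cm)
#' @param ref_flow,ref_radius reference flow and radius defining unit torque
#' @param s dimensionless torque sensitivity (0 disables the effect)
#' @param viscosity,ref_viscosity luminal fluid viscosity (g/(cm.s))
#' @return dimensionless multiplier in [0.5, 2.5]
#' @export
torque_factor <- function(flow, radius, ref_flow, ref_radius, s = 1,
                          viscosity = VISCOSITY, ref_viscosity = VISCOSITY) {
  stopifnot(ref_flow > 0, ref_radius > 0)
  t_ratio <- (viscosity * flow / radius^3) /
    (ref_viscosity * ref_flow / ref_radius^3)
  pmin(pmax(1 + s * (t_ratio - 1), 0.5), 2.5)
}
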