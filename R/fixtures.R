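# Toy problems and independent oracles.
#
# These single-segment fixtures exercise the solver components against
# closed-form or brute-force reference solutions, without the full kidney
# model.  The oracles used in the test suite are implemented there,
# independently of the solver code paths.

#' Osmotic equilibration toy problem
#'
#' A water-permeable, solute-impermeable tube flowing against a fixed
#' hypertonic bath: luminal osmolality approaches the bath osmolality
#' along the tube while the impermeant solute mass flow F*C stays
#' constant.  Returns the toy specification (a compiled passive segment, an
#' inflow state and a constant-interstitium function) together with the
#' parameters needed by an independent fine-grid integration oracle.
#'
#' @param pf water permeability (cm/s); 0 gives the no-transport limit
#' @param length tube length (cm)
#' @param lumen_osm,bath_osm inlet and bath osmolality carried by urea (mM)
#' @param flow inlet flow (nl/min)
#' @return list with `comp`, `inflow`, `inter_at`, and the closed-form
#'   descriptor (`k` the equilibration rate constant per unit length)
#' @export
make_osmotic_equilibration_toy <- function(pf = 0.02, length = 1,
                                           lumen_osm = 290, bath_osm = 580,
                                           flow = 50) {
  trace <- 1e-3
  base <- stats::setNames(rep(trace, N_SOL), SOLUTES)
  base[["H"]] <- 10^(3 - 7.4)
  lum <- base; lum[["urea"]] <- lumen_osm - sum(base) + base[["urea"]]
  bath <- base; bath[["urea"]] <- bath_osm - sum(base) + base[["urea"]]
  seg <- list(length = length, diameter = 2e-3, n_nodes = 40,
              depth = c(0, 0), epithelium = "passive",
              tj = list(pf = pf, sigma_default = 1, perm = list()))
  comp <- prepare_segment(seg, "osmotic_toy")
  inter_at <- function(d) list(conc = bath, p = 5)
  list(comp = comp,
       inflow = list(flow = flow, conc = lum, p = 5),
       inter_at = inter_at,
       bath_osm = sum(bath),
       k = pf * pi * seg$diameter * WATER_CONV)   # nl/(min.cm.mOsm)
}

#' Pump-leak toy cell
#'
#' A single epithelial node whose basolateral membrane carries only the
#' Na+/K+-ATPase and Na+/K+ leak channels against an identical bath on
#' both sides; the classic steady state has low cytosolic Na+ and high
#' cytosolic K+.  With zero pump activity the cell relaxes to a Donnan
#' equilibrium.  The independent reference solution (dense bisection on
#' the reduced 4-unknown system) lives in the test suite.
#'
#' @param pump Na+/K+-ATPase activity (pmol/(min.cm2))
#' @param p_na,p_k basolateral leak permeabilities (cm/s)
#' @return list with `comp`, `lumen`, `inter` ready for [solve_node()]
#' @export
make_pump_leak_toy <- function(pump = 4e4, p_na = 2e-6, p_k = 2e-5) {
  bath <- compose_fluid(list(Na = 140, K = 5, Cl = 113, HCO3 = 24,
                             pH = 7.4, NH_total = 0.2, PO4_total = 2.2,
                             formate_total = 1, urea = 5), glucose = 5)
  seg <- list(length = 0.1, diameter = 2e-3, n_nodes = 2, depth = c(0, 0),
              area_apical = 1, area_basolateral = 1,
              cell_volume = 6e-6, ca_cell = 0,
              apical = list(pf = 0, perm = list()),
              basolateral = list(pf = 0.05,
                                 perm = list(Na = p_na, K = p_k)),
              tj = list(pf = 0, sigma_default = 1, perm = list()),
              transporters = list(
                list(id = "NaK_ATPase", membrane = "basolateral",
                     activity = pump)))
  comp <- prepare_segment(seg, "pump_leak_toy")
  list(comp = comp,
       lumen = list(conc = bath, p = 5),
       inter = list(conc = bath, p = 5))
}

#' Independent filtered-load oracle for a scenario
#'
#' Recomputes the per-solute filtered loads of a scenario from first
#' principles (population-weighted SNGFR times plasma composition, with
#' direct unit conversion), independently of the simulator's delivery
#' bookkeeping.  Used to cross-check the model's PCT-inlet deliveries.
#'
#' @param config a [scenario_config()]
#' @param catalogue parameter catalogue
#' @return named vector: `water` (L/day) and each solute (mol/day)
#' @export
filtered_load_oracle <- function(config, catalogue = load_catalogue()) {
  params <- build_scenario_params(config, catalogue)
  cls <- params$nephron_classes
  tot_nl_min <- sum(cls$fraction * cls$sngfr) * params$gfr_scale *
    params$n_nephrons
  plasma <- scenario_plasma(params)
  water_l_day <- tot_nl_min * 1440 / 1e9
  c(water = water_l_day, water_l_day * plasma / 1e3)
}
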