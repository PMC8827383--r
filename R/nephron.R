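# Nephron and kidney assembly: chains segments into the six nephron
# classes, merges connecting-tubule outflows into the collecting system,
# and aggregates population-weighted whole-kidney outputs.

SUPERFICIAL_CHAIN <- c("PCT", "S3", "SDL", "mTAL", "cTAL", "DCT", "CNT")
JUXTAMEDULLARY_CHAIN <- c("PCT", "S3", "SDL", "LDL", "LAL",
                          "mTAL", "cTAL", "DCT", "CNT")

## compiled segment for one class, with loop geometry resolved
class_segment <- function(params, seg_id, class_row) {
  seg <- params$segments[[seg_id]]
  med <- params$physics$medulla_length
  omf <- params$physics$om_fraction
  if (seg_id %in% c("LDL", "LAL")) {
    span <- (class_row$loop_depth - omf) * med
    if (span <= 0) stop("juxtamedullary loop depth must exceed the ",
                        "outer-inner medullary boundary")
    seg$length <- seg$length * span
    seg$depth <- if (seg_id == "LDL") c(omf, class_row$loop_depth)
                 else c(class_row$loop_depth, omf)
  }
  prepare_segment(seg, seg_id)
}

#' Solve one nephron class from the glomerulus to the connecting tubule
#'
#' Chains PCT, S3, and loop-of-Henle segments (short loops turn at the
#' outer-inner medullary boundary; juxtamedullary loops descend to their
#' class-specific depth), then the distal convoluted and connecting
#' tubules, feeding each segment the upstream outflow.
#'
#' @param class_row one row of `params$nephron_classes`
#' @param params a `parameter_set`
#' @param inter_at interstitium interpolator (from internal
#'   `interstitium_fun()`); built from `params` when `NULL`
#' @param ref_flows optional torque reference: list with `PCT` and `S3`
#'   functions of normalized position returning reference flow (nl/min)
#' @param grid_scale multiply all node counts (grid-convergence studies)
#' @return a `nephron_result`: per-segment `profiles`, `delivery` (mass
#'   rates at segment entry, pmol/min per nephron), `transport`
#'   (transmural totals), the end-cTAL state, and the CNT outflow
#' @export
solve_nephron <- function(class_row, params, inter_at = NULL,
                          ref_flows = NULL, grid_scale = 1,
                          prefix_env = NULL) {
  if (is.null(inter_at)) inter_at <- interstitium_fun(params)
  chain <- if (class_row$label == "superficial") SUPERFICIAL_CHAIN
           else JUXTAMEDULLARY_CHAIN
  sngfr <- class_row$sngfr * params$gfr_scale
  plasma <- scenario_plasma(params)
  if (sngfr <= 0) {
    ## degenerate unfiltered nephron: every delivery and transport is zero
    zero <- stats::setNames(numeric(N_SOL + 1), c("water", SOLUTES))
    z <- lapply(stats::setNames(chain, chain), function(s) zero)
    return(structure(list(
      label = class_row$label, fraction = class_row$fraction, sngfr = 0,
      profiles = list(), delivery = z, transport = z,
      reacted = lapply(z, function(v) v[SOLUTES]),
      ctal_end = list(flow = 0, cl = NA_real_),
      outflow = list(flow = 0, conc = plasma, p = 0)
    ), class = "nephron_result"))
  }
  inflow <- list(flow = sngfr, conc = plasma,
                 p = params$physics$inlet_pressure)
  profiles <- list()
  delivery <- list()
  prev_x <- NULL
  for (seg_id in chain) {
    comp <- class_segment(params, seg_id, class_row)
    rf <- if (comp$torque && !is.null(ref_flows)) ref_flows[[seg_id]]
    n <- max(2L, as.integer(round(comp$n_nodes * grid_scale)))
    delivery[[seg_id]] <- c(water = inflow$flow, inflow$flow * inflow$conc)
    ## segments upstream of the loop split are identical for all classes
    ## with the same SNGFR: share their solutions within one run
    ckey <- if (seg_id %in% c("PCT", "S3", "SDL") && !is.null(prefix_env))
      paste(seg_id, class_row$sngfr)
    if (!is.null(ckey) && !is.null(prefix_env[[ckey]])) {
      pr <- prefix_env[[ckey]]
      profiles[[seg_id]] <- pr
      prev_x <- pr$last_x
      inflow <- list(flow = pr$outflow$flow, conc = pr$outflow$conc,
                     p = pr$outflow$p)
      next
    }
    pr <- tryCatch(
      solve_segment(comp, inflow, inter_at, ref_flow = rf,
                    torque_s = params$physics$torque_s, n_nodes = n,
                    x0_inlet = prev_x),
      error = function(e) {
        e$message <- paste0(e$message, " [nephron class ", class_row$label,
                            ", scenario ", params$sex, "/", params$disease,
                            if (params$sglt2i) "/SGLT2i", "]")
        stop(e)
      })
    profiles[[seg_id]] <- pr
    if (!is.null(ckey)) prefix_env[[ckey]] <- pr
    prev_x <- pr$last_x
    inflow <- list(flow = pr$outflow$flow, conc = pr$outflow$conc,
                   p = pr$outflow$p)
  }
  ctal <- profiles$cTAL$outflow
  structure(list(
    label = class_row$label,
    fraction = class_row$fraction,
    sngfr = sngfr,
    profiles = profiles,
    delivery = delivery,
    transport = lapply(profiles, function(p)
      c(water = p$water_reab, p$transmural)),
    reacted = lapply(profiles, `[[`, "reacted"),
    ctal_end = list(flow = ctal$flow, cl = ctal$conc[["Cl"]]),
    outflow = profiles$CNT$outflow
  ), class = "nephron_result")
}

#' Merge connecting-tubule outflows into the collecting-duct entry stream
#'
#' Flow-weighted, mass-conserving mixing of the population-scaled CNT
#' outflows of all nephron classes.
#'
#' @param outflows list of outflow states (`flow` nl/min per nephron,
#'   `conc` mM, `p` mmHg)
#' @param weights nephron population of each class (count)
#' @return merged inflow state with `flow` the total nl/min over all ducts
#' @export
merge_cnt_to_ccd <- function(outflows, weights) {
  stopifnot(length(outflows) == length(weights))
  fl <- vapply(outflows, `[[`, 0, "flow")
  if (any(fl < 0) || any(weights < 0)) stop("negative flow in CNT merge")
  ftot <- sum(weights * fl)
  mass <- Reduce(`+`, Map(function(o, w) w * o$flow * o$conc,
                          outflows, as.list(weights)))
  p <- sum(weights * fl * vapply(outflows, `[[`, 0, "p")) / ftot
  list(flow = ftot, conc = mass / ftot, p = p)
}

#' Solve the collecting system (CCD, OMCD, IMCD) down to the urine
#'
#' The merged connecting-tubule stream enters the cortical collecting
#' ducts; in the inner medulla the ducts coalesce stepwise (10:1 merges at
#' equal axial intervals), which concentrates per-duct flow and reduces
#' total transport area towards the papilla.  The terminal IMCD outflow is
#' the final urine.
#'
#' @param ccd_inflow merged inflow (total flow over all ducts, nl/min)
#' @param params a `parameter_set`
#' @param inter_at interstitium interpolator; built from `params` if `NULL`
#' @param grid_scale node-count multiplier
#' @return list with per-segment `profiles` and the `urine` state (total
#'   flow nl/min, concentrations mM)
#' @export
solve_collecting_system <- function(ccd_inflow, params, inter_at = NULL,
                                    grid_scale = 1) {
  if (is.null(inter_at)) inter_at <- interstitium_fun(params)
  cc <- params$collecting %||% list()
  n_ccd <- cc$n_ccd %||% 1e5
  merges <- cc$imcd_merges %||% 2
  ratio <- cc$imcd_merge_ratio %||% 10
  inflow <- ccd_inflow
  profiles <- list()
  for (seg_id in c("CCD", "OMCD", "IMCD")) {
    comp <- prepare_segment(params$segments[[seg_id]], seg_id)
    n <- max(2L, as.integer(round(comp$n_nodes * grid_scale)))
    count <- if (seg_id == "IMCD") {
      ## stepwise coalescence at equal axial intervals
      brk <- seq_len(merges) / (merges + 1)
      gen <- findInterval(seq(0, 1, length.out = n), brk)
      n_ccd / ratio^gen
    } else rep(n_ccd, n)
    pr <- solve_segment(comp, inflow, inter_at, count = count,
                        torque_s = 0, n_nodes = n)
    profiles[[seg_id]] <- pr
    inflow <- list(flow = pr$outflow$flow, conc = pr$outflow$conc,
                   p = pr$outflow$p)
  }
  list(profiles = profiles,
       urine = list(flow = inflow$flow, conc = inflow$conc))
}

#' Macula-densa chloride readout
#'
#' Luminal [Cl-] at the end of the cortical thick ascending limb: for the
#' superficial nephron directly, and as the flow-weighted average over the
#' five juxtamedullary classes (population x luminal flow weighting).
#'
#' @param nephron_results list of `nephron_result` objects
#' @return list with `superficial` and `juxtamedullary` [Cl-] (mM)
#' @export
macula_densa_cl <- function(nephron_results) {
  labs <- vapply(nephron_results, `[[`, "", "label")
  sup <- nephron_results[[which(labs == "superficial")]]
  jm <- nephron_results[labs != "superficial"]
  w <- vapply(jm, function(r) r$fraction * r$ctal_end$flow, 0)
  cl <- vapply(jm, function(r) r$ctal_end$cl, 0)
  list(superficial = sup$ctal_end$cl,
       juxtamedullary = sum(w * cl) / sum(w))
}

## pmol/min -> mol/day and nl/min -> L/day
PMOLMIN_TO_MOLDAY <- 1440 / 1e12
NLMIN_TO_LDAY <- 1440 / 1e9

#' Assemble the whole-kidney report
#'
#' Population-weighted deliveries and segmental transport (mol/day), urine
#' flow (L/day) and urinary excretions (mol/day), the macula-densa [Cl-]
#' readouts, filtered loads and scenario metadata.
#'
#' @param nephron_results list of `nephron_result`s (all six classes)
#' @param collecting result of [solve_collecting_system()]
#' @param params the scenario `parameter_set`
#' @return a `kidney_report`
#' @export
kidney_totals <- function(nephron_results, collecting, params) {
  n_neph <- params$n_nephrons
  plasma <- scenario_plasma(params)
  gfr <- total_gfr_df(params$nephron_classes, n_neph) * params$gfr_scale
  filtered <- c(water = gfr * 1e-3 * 1440,           # L/day
                gfr * 1e-3 * 1440 * plasma * 1e-3)   # mol/day

  seg_ids <- c(JUXTAMEDULLARY_CHAIN, "CCD", "OMCD", "IMCD")
  agg <- function(results, field, scale_pop = TRUE) {
    out <- matrix(0, length(seg_ids), N_SOL + 1,
                  dimnames = list(seg_ids, c("water", SOLUTES)))
    for (r in results) {
      w <- if (scale_pop) r$fraction * n_neph else 1
      for (s in names(r[[field]]))
        out[s, ] <- out[s, ] + w * r[[field]][[s]][c("water", SOLUTES)]
    }
    out
  }
  delivery <- agg(nephron_results, "delivery") * PMOLMIN_TO_MOLDAY
  transport <- agg(nephron_results, "transport") * PMOLMIN_TO_MOLDAY
  ## water was aggregated in nl/min scaled by the molar factor: rescale
  ## the water column to L/day
  delivery[, "water"] <- delivery[, "water"] * 1e3
  transport[, "water"] <- transport[, "water"] * 1e3

  ## collecting system (already totals over all ducts)
  for (s in c("CCD", "OMCD", "IMCD")) {
    pr <- collecting$profiles[[s]]
    delivery[s, ] <- c(pr$inflow$flow * NLMIN_TO_LDAY,
                       pr$inflow$flow * pr$inflow$conc * PMOLMIN_TO_MOLDAY)
    transport[s, ] <- c(pr$water_reab * NLMIN_TO_LDAY,
                        pr$transmural * PMOLMIN_TO_MOLDAY)
  }
  urine_flow <- collecting$urine$flow * NLMIN_TO_LDAY
  excretion <- collecting$urine$flow * collecting$urine$conc *
    PMOLMIN_TO_MOLDAY

  ## whole-kidney mass closure: filtered = transported + reacted + excreted
  reacted <- stats::setNames(numeric(N_SOL), SOLUTES)
  for (r in nephron_results)
    reacted <- reacted + r$fraction * n_neph *
      Reduce(`+`, r$reacted) * PMOLMIN_TO_MOLDAY
  for (s in c("CCD", "OMCD", "IMCD"))
    reacted <- reacted + collecting$profiles[[s]]$reacted * PMOLMIN_TO_MOLDAY
  closure <- (filtered[SOLUTES] - colSums(transport[, SOLUTES, drop = FALSE]) +
                reacted - excretion) /
    pmax(abs(filtered[SOLUTES]), abs(excretion), 1e-9)
  closure_water <- (filtered[["water"]] - sum(transport[, "water"]) -
                      urine_flow) / filtered[["water"]]

  structure(list(
    scenario = list(sex = params$sex, disease = params$disease,
                    sglt2i = params$sglt2i,
                    plasma_glucose = params$plasma_glucose,
                    gfr_scale = params$gfr_scale,
                    catalogue_version = params$catalogue_version),
    gfr = gfr,
    filtered = filtered,
    delivery = delivery,
    transport = transport,
    urine_flow = urine_flow,
    excretion = excretion,
    macula_densa = macula_densa_cl(nephron_results),
    mass_closure = c(closure, water = closure_water),
    nephrons = nephron_results,
    collecting = collecting
  ), class = "kidney_report")
}

#' @export
print.kidney_report <- function(x, ...) {
  sc <- x$scenario
  cat("<kidney_report>", sc$sex, "| disease:", sc$disease,
      "| SGLT2i:", sc$sglt2i, "\n")
  cat(sprintf("  GFR %.1f mL/min | urine %.2f L/day\n", x$gfr, x$urine_flow))
  for (s in c("Na", "K", "Cl", "glucose", "urea"))
    cat(sprintf("  %-8s excretion %8.4f mol/day (filtered %8.3f)\n",
                s, x$excretion[[s]], x$filtered[[s]]))
  md <- x$macula_densa
  cat(sprintf("  macula densa [Cl-]: superficial %.1f mM, juxtamedullary %.1f mM\n",
              md$superficial, md$juxtamedullary))
  cat(sprintf("  worst mass-closure residual: %.2e\n",
              max(abs(x$mass_closure))))
  invisible(x)
}
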