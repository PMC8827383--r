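# Scenario orchestration: the twelve canonical runs, cross-scenario
# comparisons, the sensitivity scan, and table emission.

## Torque reference: the PCT/S3 flow profile of the same-sex, non-diabetic,
## no-drug parameter set solved with the torque effect disabled.  This is a
## fixed point: with the reference in place the baseline scenario itself
## has torque factor 1 everywhere.
torque_reference <- function(sex, class_row, catalogue = load_catalogue()) {
  key <- paste("ref", sex, class_row$sngfr, catalogue$version)
  hit <- .nephroflux_env[[key]]
  if (!is.null(hit)) return(hit)
  params <- build_baseline(sex, catalogue)
  inter_at <- interstitium_fun(params)
  inflow <- list(flow = class_row$sngfr, conc = scenario_plasma(params),
                 p = params$physics$inlet_pressure)
  out <- list()
  prev_x <- NULL
  for (seg_id in c("PCT", "S3")) {
    comp <- class_segment(params, seg_id, class_row)
    pr <- solve_segment(comp, inflow, inter_at, torque_s = 0,
                        x0_inlet = prev_x)
    prev_x <- pr$last_x
    out[[seg_id]] <- stats::approxfun(pr$x / comp$length, pr$flow,
                                      rule = 2)
    inflow <- list(flow = pr$outflow$flow, conc = pr$outflow$conc,
                   p = pr$outflow$p)
  }
  assign(key, out, envir = .nephroflux_env)
  out
}

#' Run one scenario end to end
#'
#' Builds the scenario parameter set (sex, diabetes, inhibition layers plus
#' overrides), solves all six nephron classes, merges the connecting-tubule
#' outflows, solves the collecting system and returns the whole-kidney
#' report.  Deterministic given the configuration and catalogue; results
#' are memoised per session unless a custom parameter set is supplied.
#'
#' @param config a [scenario_config()]
#' @param params optional pre-built `parameter_set` (bypasses the cache)
#' @param catalogue parameter catalogue
#' @param grid_scale node-count multiplier for convergence studies
#' @param use_cache memoise results for identical configurations
#' @return a `kidney_report`
#' @export
run_scenario <- function(config = scenario_config(), params = NULL,
                         catalogue = load_catalogue(), grid_scale = 1,
                         use_cache = TRUE) {
  cacheable <- is.null(params) && use_cache && grid_scale == 1
  key <- NULL
  if (cacheable) {
    key <- paste("scenario", config$sex, config$disease, config$sglt2i,
                 paste(deparse(config$overrides), collapse = ""),
                 catalogue$version)
    hit <- .nephroflux_env[[key]]
    if (!is.null(hit)) return(hit)
  }
  if (is.null(params)) params <- build_scenario_params(config, catalogue)
  inter_at <- interstitium_fun(params)
  cls <- params$nephron_classes
  prefix_env <- new.env(parent = emptyenv())
  results <- lapply(seq_len(nrow(cls)), function(i) {
    row <- cls[i, ]
    refs <- torque_reference(params$sex, row, catalogue)
    solve_nephron(row, params, inter_at, ref_flows = refs,
                  grid_scale = grid_scale, prefix_env = prefix_env)
  })
  merged <- merge_cnt_to_ccd(lapply(results, `[[`, "outflow"),
                             cls$fraction * params$n_nephrons)
  collecting <- solve_collecting_system(merged, params, inter_at,
                                        grid_scale = grid_scale)
  report <- kidney_totals(results, collecting, params)
  if (cacheable) assign(key, report, envir = .nephroflux_env)
  report
}

#' All twelve canonical scenarios
#'
#' 2 sexes x 3 disease states x SGLT2 inhibition on/off.
#'
#' @param catalogue parameter catalogue
#' @return named list of `kidney_report`s, names like `"female_moderate_sglt2i"`
#' @export
run_suite <- function(catalogue = load_catalogue()) {
  out <- list()
  for (sex in c("female", "male"))
    for (dz in c("none", "moderate", "severe"))
      for (drug in c(FALSE, TRUE)) {
        nm <- paste0(sex, "_", dz, if (drug) "_sglt2i")
        out[[nm]] <- run_scenario(scenario_config(sex, dz, drug),
                                  catalogue = catalogue)
      }
  out
}

#' Compare two kidney reports (within sex)
#'
#' Percent changes (and absolute deltas) of urine volume and per-solute
#' urinary excretions, treatment relative to reference, following the
#' convention of reporting drug effects against the same-sex, same-disease
#' no-drug reference.
#'
#' @param reference,treatment `kidney_report`s with the same sex
#' @return data.frame with `quantity`, `reference`, `treatment`,
#'   `delta`, and `pct_change` (NA where the reference is zero)
#' @export
compare_reports <- function(reference, treatment) {
  if (!identical(reference$scenario$sex, treatment$scenario$sex))
    stop("comparisons are within-sex: reports have different sex")
  q <- c("urine volume", SOLUTES)
  ref <- c(reference$urine_flow, reference$excretion)
  trt <- c(treatment$urine_flow, treatment$excretion)
  pct <- ifelse(abs(ref) > 1e-12, 100 * (trt - ref) / ref, NA_real_)
  data.frame(quantity = q, reference = ref, treatment = trt,
             delta = trt - ref, pct_change = pct, row.names = NULL)
}

#' Transporter sensitivity scan
#'
#' Varies the activity of each listed transporter by `delta` (default
#' +/-20%) in every segment expressing it and reruns the scenario.  Under
#' SGLT2 inhibition the perturbation is relative to the inhibited activity
#' level.  Individual run failures are recorded and the scan continues.
#'
#' @param config scenario to perturb
#' @param transporters character vector of transporter ids
#' @param delta fractional perturbations
#' @param catalogue parameter catalogue
#' @return data.frame: transporter, delta, urine volume (L/day) and
#'   Na/K/Cl/glucose excretions (mol/day), plus an unperturbed row
#'   (`transporter = "none"`); failed runs carry NA and the error message
#' @export
sensitivity_scan <- function(config,
                             transporters = c("SGLT2", "SGLT1", "GLUT2",
                                              "NKCC2", "NaK_ATPase"),
                             delta = c(-0.2, 0.2),
                             catalogue = load_catalogue()) {
  base_params <- build_scenario_params(config, catalogue)
  one <- function(params) {
    rep <- run_scenario(config, params = params, catalogue = catalogue,
                        use_cache = FALSE)
    c(urine = rep$urine_flow, rep$excretion[c("Na", "K", "Cl", "glucose")])
  }
  rows <- list()
  base_rep <- run_scenario(config, catalogue = catalogue)
  base <- c(urine = base_rep$urine_flow,
            base_rep$excretion[c("Na", "K", "Cl", "glucose")])
  rows[[1]] <- data.frame(transporter = "none", delta = 0, t(base),
                          error = NA_character_)
  for (tr in transporters) for (d in delta) {
    params <- base_params
    for (s in names(params$segments))
      params <- scale_activity(params, s, tr, 1 + d)
    res <- tryCatch(one(params), error = function(e) e)
    rows[[length(rows) + 1]] <- if (inherits(res, "error")) {
      data.frame(transporter = tr, delta = d, urine = NA, Na = NA, K = NA,
                 Cl = NA, glucose = NA, error = conditionMessage(res))
    } else data.frame(transporter = tr, delta = d, t(res),
                      error = NA_character_)
  }
  out <- do.call(rbind, rows)
  names(out) <- c("transporter", "delta", "urine", "Na", "K", "Cl",
                  "glucose", "error")
  rownames(out) <- NULL
  out
}

#' Write figure-style CSV tables and a JSON aggregate for a set of reports
#'
#' One CSV per quantity family (delivery to segment entry, transport by
#' segment, excretion summary) with one column per scenario, plus a JSON
#' dump of the headline numbers.
#'
#' @param reports named list of `kidney_report`s
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
emit_tables <- function(reports, dir = ".") {
  stopifnot(length(reports) >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wide <- function(field) {
    tabs <- lapply(reports, function(r) {
      m <- r[[field]]
      df <- data.frame(segment = rep(rownames(m), ncol(m)),
                       solute = rep(colnames(m), each = nrow(m)),
                       value = as.vector(m))
      df
    })
    out <- tabs[[1]][, c("segment", "solute")]
    for (nm in names(tabs)) out[[nm]] <- tabs[[nm]]$value
    out
  }
  for (field in c("delivery", "transport")) {
    p <- file.path(dir, paste0(field, ".csv"))
    utils::write.csv(wide(field), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  exc <- data.frame(quantity = c("urine_volume_L_day",
                                 paste0(SOLUTES, "_mol_day")))
  for (nm in names(reports))
    exc[[nm]] <- c(reports[[nm]]$urine_flow, reports[[nm]]$excretion)
  p <- file.path(dir, "excretion.csv")
  utils::write.csv(exc, p, row.names = FALSE)
  paths <- c(paths, p)
  agg <- lapply(reports, function(r) list(
    scenario = r$scenario, gfr = r$gfr, urine_flow = r$urine_flow,
    excretion = as.list(r$excretion),
    macula_densa = r$macula_densa,
    worst_mass_closure = max(abs(r$mass_closure))))
  p <- file.path(dir, "reports.json")
  jsonlite::write_json(agg, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
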