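# Parameter catalogue and scenario transformation layers.
#
# All baseline magnitudes and every scenario constant (sex deltas, diabetes
# factors, inhibition settings) live in the YAML catalogue shipped under
# inst/extdata; the functions here only apply the transformations the
# catalogue describes.

.nephroflux_env <- new.env(parent = emptyenv())

#' Load the parameter catalogue
#'
#' Reads and normalises the YAML parameter catalogue (baseline segment
#' geometries, permeabilities, transporter activities, interstitial
#' profiles, nephron-class definitions and the scenario constant tables).
#'
#' @param path catalogue file; default is the catalogue shipped with the
#'   package
#' @return catalogue list (class `nephroflux_catalogue`)
#' @export
load_catalogue <- function(path = NULL) {
  path <- path %||% system.file("extdata", "catalogue_baseline.yaml",
                                package = "nephroflux")
  key <- paste0(path, "|", file.mtime(path))
  hit <- .nephroflux_env$catalogue_cache
  if (!is.null(hit) && identical(hit$key, key)) return(hit$value)
  cat_ <- yaml::read_yaml(path)
  ## name transporter lists by id for dotted-path addressing
  for (s in names(cat_$segments)) {
    tr <- cat_$segments[[s]]$transporters
    if (!is.null(tr))
      names(cat_$segments[[s]]$transporters) <-
        vapply(tr, `[[`, "", "id")
  }
  class(cat_) <- "nephroflux_catalogue"
  validate_catalogue(cat_)
  .nephroflux_env$catalogue_cache <- list(key = key, value = cat_)
  cat_
}

validate_catalogue <- function(cat_) {
  cls <- cat_$nephron_classes
  fr <- vapply(cls, `[[`, 0, "fraction")
  stopifnot(abs(sum(fr) - 1) < 1e-9)
  for (s in names(cat_$segments)) {
    seg <- cat_$segments[[s]]
    stopifnot(seg$length > 0, seg$diameter > 0, seg$n_nodes >= 2)
    for (b in c("apical", "basolateral", "tj")) {
      bb <- seg[[b]]
      if (is.null(bb)) next
      stopifnot(all(unlist(bb$perm) >= 0), (bb$pf %||% 0) >= 0)
      if (!is.null(bb$sigma)) stopifnot(all(unlist(bb$sigma) <= 1),
                                        all(unlist(bb$sigma) >= 0))
    }
    for (tr in seg$transporters %||% list())
      stopifnot(tr$activity >= 0)
  }
  ## interstitial osmolality must not decrease towards the papilla
  osm <- interstitial_osmolalities(cat_)
  stopifnot(all(diff(osm) > -1e-9))
  invisible(cat_)
}

interstitial_osmolalities <- function(cat_, glucose = NULL) {
  an <- cat_$interstitium
  glc <- glucose %||% cat_$plasma$glucose
  vapply(seq_along(an$depths), function(i) {
    sp <- compose_fluid(list(
      Na = an$Na[[i]], K = an$K[[i]], Cl = an$Cl[[i]], HCO3 = an$HCO3[[i]],
      pH = an$pH[[i]], NH_total = an$NH_total[[i]],
      PO4_total = an$PO4_total[[i]], formate_total = an$formate_total[[i]],
      urea = an$urea[[i]]), glucose = glc * an$glucose_scale[[i]])
    sum(sp)
  }, 0)
}

#' Build the non-diabetic baseline parameter set for one sex
#'
#' The catalogue stores the male baseline; the female set is derived from
#' it by the sex-difference layer: basolateral water permeability of the
#' proximal convoluted tubule lowered by 36%, distal-tubule and
#' collecting-duct water permeability doubled, proximal paracellular Na+
#' and Cl- permeabilities lowered by 50% and 60%, distal apical Na+
#' (ENaC-like) permeability raised by 40%, and NKCC2 / Na+/K+-ATPase
#' activity raised by 20% in the ascending limbs, distal convoluted and
#' connecting tubules.  Segment geometry is identical between the sexes.
#'
#' @param sex `"male"` or `"female"`
#' @param catalogue a catalogue from [load_catalogue()]
#' @return a `parameter_set` object
#' @export
build_baseline <- function(sex = c("male", "female"),
                           catalogue = load_catalogue()) {
  if (!is.character(sex) || length(sex) != 1 ||
      !sex %in% c("male", "female"))
    stop("unknown sex identifier: ", paste(sex, collapse = ", "),
         " (expected \"female\" or \"male\")")
  params <- list(
    sex = sex, disease = "none", sglt2i = FALSE,
    plasma_spec = catalogue$plasma,
    plasma_glucose = catalogue$plasma$glucose,
    gfr_scale = 1,
    nephron_classes = do.call(rbind, lapply(catalogue$nephron_classes,
      function(cl) data.frame(label = cl$label, fraction = cl$fraction,
                              sngfr = cl$sngfr,
                              loop_depth = cl$loop_depth))),
    n_nephrons = catalogue$physics$n_nephrons,
    segments = catalogue$segments,
    collecting = catalogue$collecting,
    interstitium = catalogue$interstitium,
    physics = catalogue$physics,
    scenarios = catalogue$scenarios,
    catalogue_version = catalogue$version
  )
  class(params) <- "parameter_set"
  if (sex == "female") {
    sx <- catalogue$scenarios$sex_female
    params <- scale_barrier(params, "PCT", "basolateral", "pf", sx$pct_bl_pf)
    for (s in c("DCT", "CNT", "CCD", "OMCD", "IMCD")) {
      params <- scale_barrier(params, s, "apical", "pf", sx$distal_cd_pf)
      params <- scale_barrier(params, s, "basolateral", "pf", sx$distal_cd_pf)
    }
    for (s in c("PCT", "S3")) {
      params <- scale_perm(params, s, "tj", "Na", sx$proximal_tj_na)
      params <- scale_perm(params, s, "tj", "Cl", sx$proximal_tj_cl)
    }
    for (s in c("DCT", "CNT", "CCD"))
      params <- scale_perm(params, s, "apical", "Na", sx$distal_na_perm)
    for (s in c("mTAL", "cTAL"))
      params <- scale_activity(params, s, "NKCC2", sx$nkcc2_nak)
    for (s in c("mTAL", "cTAL", "DCT", "CNT"))
      params <- scale_activity(params, s, "NaK_ATPase", sx$nkcc2_nak)
  }
  params
}

scale_barrier <- function(params, seg, barrier, field, factor) {
  cur <- params$segments[[seg]][[barrier]][[field]] %||% 0
  params$segments[[seg]][[barrier]][[field]] <- cur * factor
  params
}
scale_perm <- function(params, seg, barrier, solute, factor) {
  cur <- params$segments[[seg]][[barrier]]$perm[[solute]]
  if (is.null(cur)) return(params)
  params$segments[[seg]][[barrier]]$perm[[solute]] <- cur * factor
  params
}
scale_activity <- function(params, seg, id, factor) {
  tr <- params$segments[[seg]]$transporters
  if (is.null(tr) || is.null(tr[[id]])) return(params)
  params$segments[[seg]]$transporters[[id]]$activity <-
    tr[[id]]$activity * factor
  params
}

#' Apply the diabetes scenario layer
#'
#' Tubular hypertrophy (proximal length and diameter up 10% in moderate and
#' 28% in severe diabetes; distal diameters up 18% / 42% with lengths up
#' 7%), the transporter up/down-regulation table (sex- and
#' severity-specific), enhanced collecting-duct transcellular water
#' permeability, elevated plasma glucose (8.6 / 20 mM), and the
#' hyperfiltration GFR scale.
#'
#' @param params a `parameter_set`
#' @param disease `"moderate"` or `"severe"` (`"none"` returns the input
#'   with a warning)
#' @param sex used to pick the transporter-regulation column; defaults to
#'   the parameter set's own sex
#' @return transformed `parameter_set`
#' @export
apply_diabetes <- function(params, disease = c("moderate", "severe", "none"),
                           sex = params$sex) {
  disease <- match.arg(disease)
  if (disease == "none") {
    warning("apply_diabetes called with disease = \"none\": identity")
    return(params)
  }
  dz <- params$scenarios$diabetes[[disease]]
  ## geometry
  for (s in c("PCT", "S3")) {
    params$segments[[s]]$length <- params$segments[[s]]$length *
      dz$proximal_geom
    params$segments[[s]]$diameter <- params$segments[[s]]$diameter *
      dz$proximal_geom
  }
  distal <- setdiff(names(params$segments), c("PCT", "S3"))
  for (s in distal) {
    params$segments[[s]]$diameter <- params$segments[[s]]$diameter *
      dz$distal_diam
    params$segments[[s]]$length <- params$segments[[s]]$length *
      dz$distal_len
  }
  ## transporter regulation table
  col <- if (sex == "female") "female" else "male"
  for (row in params$scenarios$diabetes$transporters) {
    fac <- row[[disease]][[col]]
    for (s in row$segments) {
      if (identical(fac, "split_profile")) {
        ## female-severe IMCD pump: +50% along the first 2/3 of the
        ## segment and +150% along the rest
        tr <- params$segments[[s]]$transporters[[row$id]]
        if (is.null(tr)) next
        params$segments[[s]]$transporters[[row$id]]$profile <-
          list(breaks = 2 / 3, values = c(1.5, 2.5))
      } else {
        params <- scale_activity(params, s, row$id, fac)
      }
    }
  }
  ## collecting-duct transcellular water permeability
  for (s in c("CCD", "IMCD")) {
    params <- scale_barrier(params, s, "apical", "pf", dz$cd_pf)
    params <- scale_barrier(params, s, "basolateral", "pf", dz$cd_pf)
  }
  params$plasma_glucose <- dz$plasma_glucose
  params$gfr_scale <- dz$gfr_scale
  params$disease <- disease
  params
}

#' Apply SGLT2 inhibition
#'
#' 90% knockdown of SGLT2 activity in all nephron classes.  In the
#' non-diabetic kidney SNGFR falls by 3% in every nephron; in a diabetic
#' kidney the hyperfiltration is normalised instead (GFR returned to the
#' non-diabetic 105 mL/min).  Plasma glucose is unchanged.
#'
#' @param params a `parameter_set`
#' @return transformed `parameter_set`
#' @export
apply_sglt2i <- function(params) {
  if (isTRUE(params$sglt2i)) {
    warning("SGLT2 inhibition applied twice: idempotence violation flagged; ",
            "returning input unchanged")
    return(params)
  }
  gl <- params$scenarios$sglt2i
  for (s in names(params$segments))
    params <- scale_activity(params, s, "SGLT2", gl$sglt2_factor)
  if (params$disease == "none") {
    params$nephron_classes$sngfr <- params$nephron_classes$sngfr *
      gl$sngfr_factor_nondiabetic
  } else {
    base <- total_gfr_df(params$nephron_classes, params$n_nephrons)
    params$gfr_scale <- gl$target_gfr_diabetic / base
  }
  params$sglt2i <- TRUE
  params
}

#' Whole-kidney glomerular filtration rate
#'
#' Population-weighted sum of single-nephron GFRs.
#'
#' @param classes data.frame with `fraction` and `sngfr` (nl/min) columns,
#'   or a list of per-class lists with those fields
#' @param n_nephrons nephron count (default one million)
#' @return GFR in mL/min
#' @export
total_gfr <- function(classes, n_nephrons = 1e6) {
  if (!is.data.frame(classes))
    classes <- do.call(rbind, lapply(classes, function(cl)
      data.frame(fraction = cl$fraction, sngfr = cl$sngfr)))
  if (any(classes$sngfr < 0)) stop("negative SNGFR")
  if (abs(sum(classes$fraction) - 1) > 1e-9)
    stop("nephron-class fractions must sum to 1")
  total_gfr_df(classes, n_nephrons)
}

total_gfr_df <- function(classes, n_nephrons) {
  sum(classes$fraction * classes$sngfr) * n_nephrons * 1e-6
}

#' Filtered load of a solute
#'
#' @param gfr glomerular filtration rate (mL/min)
#' @param plasma_conc plasma concentration (mM)
#' @return filtered load in mol/day
#' @export
filtered_load <- function(gfr, plasma_conc) {
  stopifnot(gfr >= 0, plasma_conc >= 0)
  gfr * 1e-3 * 1440 * plasma_conc * 1e-3
}

#' Scenario descriptor
#'
#' @param sex `"female"` or `"male"`
#' @param disease `"none"`, `"moderate"` or `"severe"`
#' @param sglt2i logical, SGLT2 inhibition on/off
#' @param overrides named list of dotted-path parameter overrides applied
#'   after all scenario layers (e.g.
#'   `list("segments.PCT.transporters.SGLT2.activity" = 3000)`)
#' @return a `scenario_config` object
#' @export
scenario_config <- function(sex = "male", disease = "none",
                            sglt2i = FALSE, overrides = list()) {
  sex <- match.arg(sex, c("male", "female"))
  disease <- match.arg(disease, c("none", "moderate", "severe"))
  structure(list(sex = sex, disease = disease, sglt2i = isTRUE(sglt2i),
                 overrides = overrides),
            class = "scenario_config")
}

#' Build the full parameter set for a scenario
#'
#' Applies the layers in the fixed order sex -> diabetes -> inhibition ->
#' overrides; the transformation is deterministic and pure.
#'
#' @param config a [scenario_config()]
#' @param catalogue parameter catalogue
#' @return a `parameter_set`
#' @export
build_scenario_params <- function(config, catalogue = load_catalogue()) {
  params <- build_baseline(config$sex, catalogue)
  if (config$disease != "none")
    params <- apply_diabetes(params, config$disease)
  if (config$sglt2i) params <- apply_sglt2i(params)
  for (path in names(config$overrides))
    params <- set_param(params, path, config$overrides[[path]])
  params
}

#' Set one parameter by dotted path
#'
#' @param params a `parameter_set`
#' @param path dotted path, e.g. `"segments.mTAL.transporters.NKCC2.activity"`
#' @param value replacement value
#' @return modified `parameter_set`
#' @export
set_param <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(node, keys) {
    if (length(keys) == 0) return(value)
    k <- keys[[1]]
    if (is.null(node[[k]]) && length(keys) > 1)
      stop("unknown parameter path component: ", k)
    node[[k]] <- rec(node[[k]], keys[-1])
    node
  }
  out <- rec(unclass(params), keys)
  class(out) <- "parameter_set"
  out
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>", x$sex, "| disease:", x$disease,
      "| SGLT2i:", x$sglt2i, "\n")
  cat("  plasma glucose:", x$plasma_glucose, "mM | GFR scale:",
      signif(x$gfr_scale, 4), "\n")
  cat("  segments:", paste(names(x$segments), collapse = " "), "\n")
  invisible(x)
}

## effective SNGFR (nl/min) per class under the scenario
effective_sngfr <- function(params) {
  params$nephron_classes$sngfr * params$gfr_scale
}

## plasma (filtrate) composition for the scenario, exactly electroneutral
scenario_plasma <- function(params) {
  compose_fluid(params$plasma_spec, glucose = params$plasma_glucose,
                balance = TRUE)
}

## interstitium interpolator: function(depth in [0,1]) -> list(conc, p)
interstitium_fun <- function(params) {
  an <- params$interstitium
  glc <- params$plasma_glucose
  depths <- unlist(an$depths)
  species <- vapply(seq_along(depths), function(i) {
    compose_fluid(list(
      Na = an$Na[[i]], K = an$K[[i]], Cl = an$Cl[[i]], HCO3 = an$HCO3[[i]],
      pH = an$pH[[i]], NH_total = an$NH_total[[i]],
      PO4_total = an$PO4_total[[i]], formate_total = an$formate_total[[i]],
      urea = an$urea[[i]]), glucose = glc * an$glucose_scale[[i]])
  }, numeric(N_SOL))
  pr <- unlist(an$pressure)
  function(d) {
    conc <- vapply(seq_len(N_SOL), function(k)
      stats::approx(depths, species[k, ], xout = d, rule = 2)$y, 0)
    names(conc) <- SOLUTES
    list(conc = conc,
         p = stats::approx(depths, pr, xout = d, rule = 2)$y)
  }
}
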