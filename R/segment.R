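# Axial integration of the luminal balance equations along one segment.
#
# d(F C_i)/dx = -J_i(x)   and   dF/dx = -J_w(x)
#
# marched with a trapezoidal (second-order) implicit scheme; the nonlinear
# step equations are solved by Picard iteration, re-solving the epithelial
# node system at every iterate, with automatic step subdivision on
# failure.  After each accepted step the luminal fluid is re-speciated to
# buffer equilibrium (fast proton-transfer reactions); the reacted amounts
# are recorded so every per-species mass audit closes exactly.

#' Integrate the luminal profile along one segment
#'
#' Marches luminal flow, composition, pressure and potential from the
#' segment inlet to its outlet, solving the epithelial steady-state node
#' system at every axial position.  This is the axial-advance operation of
#' the solver: the inlet boundary condition is the upstream outflow (or the
#' filtrate for the proximal tubule).
#'
#' @param comp compiled segment parameters (from `prepare_segment()`)
#' @param inflow list with `flow` (nl/min, total over the merged tubules),
#'   `conc` (named 15-vector, mM) and `p` (mmHg)
#' @param inter_at function(depth_norm) returning the local interstitium as
#'   a list with `conc` and `p`
#' @param ref_flow optional reference flow values at the grid nodes for the
#'   torque effect (nl/min, per tubule)
#' @param count tubule count at each grid node (collecting-duct
#'   coalescence); default 1
#' @param torque_s torque sensitivity (0 disables)
#' @param n_nodes optional grid override
#' @return a `tubular_profile` object: grid, flow, concentrations,
#'   pressure, potential, per-solute transmural and reacted totals, inflow
#'   and outflow states, and solver diagnostics
#' @export
solve_segment <- function(comp, inflow, inter_at, ref_flow = NULL,
                          count = NULL, torque_s = 1, n_nodes = NULL,
                          x0_inlet = NULL) {
  n <- n_nodes %||% comp$n_nodes
  stopifnot(n >= 2)
  xs <- seq(0, comp$length, length.out = n)
  depths <- comp$depth[[1]] + (comp$depth[[2]] - comp$depth[[1]]) * xs /
    comp$length
  if (is.null(count)) count <- rep(1, n)
  stopifnot(length(count) == n)
  inter <- lapply(depths, inter_at)
  passive <- comp$epithelium == "passive"

  conc <- matrix(NA_real_, n, N_SOL, dimnames = list(NULL, SOLUTES))
  flow <- pres <- vlum <- numeric(n)
  transmural <- stats::setNames(numeric(N_SOL), SOLUTES)
  reacted <- stats::setNames(numeric(N_SOL), SOLUTES)
  water_reab <- 0
  iters <- 0L

  tq <- function(f_tub, j) {
    if (!comp$torque || torque_s == 0 || is.null(ref_flow)) return(1)
    torque_factor(f_tub, comp$radius, ref_flow(xs[[j]] / comp$length),
                  comp$radius, torque_s)
  }
  nsolve <- function(lum, j, f_tub, x0 = NULL, jac = NULL, act_scale = 1,
                     scales = NULL) {
    if (passive) return(solve_passive_node(lum, inter[[j]], comp))
    sol <- solve_node(lum, inter[[j]], comp, x0 = x0,
                      x_norm = xs[[j]] / comp$length,
                      torque_mult = tq(f_tub, j) * act_scale, jac = jac,
                      scales = scales)
    iters <<- iters + sol$iterations
    sol
  }
  ## inlet node: optional upstream warm start, then an activity-ramp
  ## continuation on failure
  nsolve_inlet <- function(lum, f_tub) {
    tryCatch(nsolve(lum, 1L, f_tub, x0 = x0_inlet),
             nephroflux_node_error = function(e) {
      sol <- NULL
      for (lam in c(0.05, 0.15, 0.3, 0.5, 0.7, 0.85, 0.95, 1)) {
        s_try <- tryCatch(
          nsolve(lum, 1L, f_tub, x0 = sol$x, jac = sol$jac,
                 act_scale = lam),
          nephroflux_node_error = function(e2) e2$best)
        if (!is.null(s_try$x)) sol <- s_try
      }
      if (is.null(sol) || is.null(sol$residual_norm) ||
          sol$residual_norm > 1e-8)
        sol <- nsolve(lum, 1L, f_tub, x0 = sol$x, jac = sol$jac)
      sol
    })
  }
  loss <- function(fl) {            # per-tubule luminal loss rates
    list(s = fl$ap + fl$tj, w = fl$jw_ap + fl$jw_tj)
  }

  ## inlet node
  lum <- list(conc = inflow$conc, p = inflow$p)
  f_t <- inflow$flow
  sol <- nsolve_inlet(lum, f_t / count[[1]])
  conc[1, ] <- inflow$conc; flow[[1]] <- f_t; pres[[1]] <- inflow$p
  vlum[[1]] <- sol$state$vl

  for (j in seq_len(n - 1L)) {
    dx <- xs[[j + 1L]] - xs[[j]]
    res <- advance_step(lum, sol, f_t, dx, j, comp, inter, count, xs,
                        nsolve, loss, depth = 0L)
    transmural <- transmural + res$transmural
    water_reab <- water_reab + res$water
    reacted <- reacted + res$reacted
    lum <- res$lum; sol <- res$sol; f_t <- res$f_t
    ## Poiseuille pressure drop at the per-tubule flow
    f_tub <- f_t / count[[j + 1L]]
    dpdx <- 8 * VISCOSITY * (f_tub * 1e-6 / 60) / (pi * comp$radius^4) /
      1333.22   # dyn/cm3 -> mmHg/cm
    lum$p <- lum$p - dpdx * dx
    conc[j + 1L, ] <- lum$conc
    flow[[j + 1L]] <- f_t
    pres[[j + 1L]] <- lum$p
    vlum[[j + 1L]] <- sol$state$vl
  }

  structure(list(
    id = comp$id, x = xs, depth = depths, flow = flow, conc = conc,
    pressure = pres, v_lumen = vlum, count = count,
    transmural = transmural, water_reab = water_reab, reacted = reacted,
    inflow = inflow,
    outflow = list(flow = f_t, conc = lum$conc, p = lum$p),
    last_node = sol$state, last_x = sol$x, node_iterations = iters
  ), class = "tubular_profile")
}

## One trapezoidal step with Picard iteration and recursive subdivision.
advance_step <- function(lum0, sol0, f0, dx, j, comp, inter, count, xs,
                         nsolve, loss, depth) {
  L0 <- loss(sol0$fluxes)
  n0 <- count[[j]]
  ## interstitium/parameters for a partial step are evaluated at node j+1
  ## only when the step reaches it; sub-steps reuse node j+1 boundary data
  n1 <- count[[j + 1L]]
  full_dx <- xs[[j + 1L]] - xs[[j]]
  frac <- dx / full_dx

  mass0 <- f0 * lum0$conc
  y_mass0 <- f0 * cons_vars(lum0$conc)
  ly0 <- cons_vars(L0$s)
  f_new <- max(f0 - dx * L0$w * n0, 0.02 * f0)   # explicit predictor
  c_new <- lum0$conc
  sol1 <- sol0
  ok <- FALSE
  dried <- f0 - dx * L0$w * n0 <= 0.02 * f0
  ## luminal-osmolality part of the water flux is handled implicitly:
  ## Jw(F) = b - c/F with the cell state frozen at the current iterate,
  ## which removes the near-isotonic stiffness from the Picard loop
  ap <- comp$apical; tj <- comp$tj
  a_ap <- ap$pf * ap$area * WATER_CONV
  a_tj <- tj$pf * tj$area * WATER_CONV
  ## diagonal flux-sensitivity bounds in the conserved-variable space:
  ## the solute update is advanced semi-implicitly for the conserved
  ## quantities (species, buffer totals, net acid charge), which damps
  ## the fast-equilibrating species (CO2, NH3, protons) without biasing
  ## the converged step -- the correction vanishes at the Picard fixed
  ## point because re-speciation preserves every conserved variable.
  g_y <- cons_sensitivity(step_sensitivity(comp, lum0$conc), lum0$conc)
  a_y <- dx / 2 * g_y * n1 * 1.6
  ## residual scales are fixed per step (they only set the residual
  ## normalization), so compute them once for all Picard iterates
  step_scales <- if (comp$epithelium == "cell")
    node_scales(lum0, inter[[j + 1L]], comp, 1)
  dc_prev <- Inf
  ## torque is evaluated at the step-initial flow: freezing it across the
  ## Picard iterates removes its feedback from the iteration at an O(dx)
  ## lag on the torque argument only
  f_tq <- f0 / n1
  for (k in seq_len(50L)) {
    lum1 <- list(conc = c_new, p = lum0$p)
    s_try <- tryCatch(
      nsolve(lum1, j + 1L, f_tq, x0 = sol1$x, jac = sol1$jac,
             scales = step_scales),
      nephroflux_node_error = function(e) NULL)
    if (is.null(s_try)) break
    sol1 <- s_try
    L1 <- loss(sol1$fluxes)
    ry <- y_mass0 - dx / 2 * (ly0 * n0 + cons_vars(L1$s) * n1)
    if (any(ry[1:9] <= 0)) break
    yc <- cons_vars(c_new)
    my <- tryCatch(
      solve(diag(10) + a_y / f_new, ry + a_y %*% yc)[, 1],
      error = function(e) (ry + diag(a_y) * yc) / (1 + diag(a_y) / f_new))
    ## the glucose carrier (SGLT) is too nonlinear near its static head
    ## for the linearized correction: solve its step update exactly
    ## against the frozen cell state
    if (comp$has_sglt) {
      mg <- refine_glucose(comp, sol1, c_new,
                           y_mass0[[5]] - dx / 2 * ly0[[5]] * n0,
                           dx / 2 * n1, f_new)
      if (!is.null(mg)) my[[5]] <- mg
    }
    if (any(my[1:9] <= 0)) break
    m_lag <- f_new * c_new
    if (comp$epithelium == "cell") {
      cellosm <- sum(ap$sigma * sol1$state$conc) + sol1$state$c_imp
      b <- a_ap * (cellosm + (lum0$p - inter[[j + 1L]]$p) / MMHG_PER_MOSM) +
        a_tj * (sum(tj$sigma * inter[[j + 1L]]$conc) +
                  (lum0$p - inter[[j + 1L]]$p) / MMHG_PER_MOSM)
      cc <- a_ap * sum(ap$sigma * m_lag) + a_tj * sum(tj$sigma * m_lag)
    } else {
      b <- a_tj * (sum(tj$sigma * inter[[j + 1L]]$conc) +
                     (lum0$p - inter[[j + 1L]]$p) / MMHG_PER_MOSM)
      cc <- a_tj * sum(tj$sigma * m_lag)
    }
    a0 <- f0 - dx / 2 * L0$w * n0 - dx / 2 * n1 * b
    f_up <- (a0 + sqrt(a0^2 + 2 * dx * n1 * cc)) / 2
    if (!is.finite(f_up) || f_up <= 0.01 * f0) {
      dried <- dried || (is.finite(f_up) && f_up <= 0.01 * f0)
      break
    }
    c_up <- speciate_cons(my / f_up, h_start = c_new[[I_H]])
    ## convergence on concentrations with a 0.01 mM floor so trace species
    ## at the re-speciation noise level do not stall the iteration
    dc <- max(abs(c_up - c_new) / (abs(c_new) + 1e-2),
              abs(f_up - f_new) / f_new)
    ## under-relax only when the iteration is not contracting
    relax <- if (dc > dc_prev) 0.5 else 1
    dc_prev <- dc
    c_new <- relax * c_up + (1 - relax) * c_new
    f_new <- relax * f_up + (1 - relax) * f_new
    if (dc < 4e-9) { ok <- TRUE; break }
  }
  if (!ok) {
    if (depth >= 9L) {
      if (dried || f_new <= 0.02 * f0)
        stop(simpleCondition_run_dry(comp$id))
      stop(sprintf("axial step failed to converge in segment %s near x=%.4f",
                   comp$id, xs[[j]] + dx))
    }
    h1 <- advance_step(lum0, sol0, f0, dx / 2, j, comp, inter, count, xs,
                       nsolve, loss, depth + 1L)
    h2 <- advance_step(h1$lum, h1$sol, h1$f_t, dx / 2, j, comp, inter,
                       count, xs, nsolve, loss, depth + 1L)
    return(list(lum = h2$lum, sol = h2$sol, f_t = h2$f_t,
                transmural = h1$transmural + h2$transmural,
                water = h1$water + h2$water,
                reacted = h1$reacted + h2$reacted))
  }
  L1 <- loss(sol1$fluxes)
  transmural <- dx / 2 * (L0$s * n0 + L1$s * n1)
  list(lum = list(conc = c_new, p = lum0$p), sol = sol1, f_t = f_new,
       transmural = transmural,
       water = f0 - f_new,
       reacted = f_new * c_new - (mass0 - transmural))
}

## Solve f*G + dxh*J_glc(G) = m_target for the luminal glucose of the next
## node, with the epithelial state frozen at the current Picard iterate.
## The SGLT flux is rescaled from the current apical glucose flux, so the
## effective activity (including torque) is preserved.  Returns the
## glucose mass flow, or NULL when no meaningful carrier flux exists.
refine_glucose <- function(comp, sol1, c_new, m_target, dxh, f) {
  j_cur <- sol1$fluxes$ap[[I_GLC]]
  st <- sol1$state
  if (is.null(st$conc)) return(NULL)
  iso <- comp$sglt_isoform
  if (iso == "SGLT2") { n <- 1; k_na <- 25; k_glc <- 10 }
  else { n <- 2; k_na <- 15; k_glc <- 1 }
  u <- (st$vl - st$vc) / RTF
  kap <- (c_new[[I_NA]] / k_na)^n * exp(n * u / 2) / k_glc
  ar <- (st$conc[[I_NA]] / k_na)^n * (st$conc[[I_GLC]] / k_glc) *
    exp(-n * u / 2)
  r <- function(g) (kap * g - ar) / (1 + kap * g + ar)
  r0 <- r(c_new[[I_GLC]])
  if (!is.finite(j_cur) || abs(r0) < 1e-9) return(NULL)
  scl <- j_cur / r0
  if (scl <= 0) return(NULL)
  phi <- function(g) f * g + dxh * scl * r(g) - m_target
  hi <- 4 * max(c_new[[I_GLC]], m_target / f, ar / kap) + 1e-9
  lo <- 1e-13
  if (phi(lo) >= 0) return(f * lo)
  if (phi(hi) <= 0) return(NULL)
  g <- stats::uniroot(phi, c(lo, hi), tol = 1e-14)$root
  f * g
}

## Map per-species flux-sensitivity bounds into the conserved-variable
## space: dJ_y/dy_j ~ sum_i G_i |dc_i/dy_j|, with the speciation
## derivatives taken numerically around the local composition.  Buffering
## makes the conserved-space sensitivities far milder than the raw proton
## or CO2 sensitivities.
cons_sensitivity <- function(G, conc) {
  y0 <- cons_vars(conc)
  c0 <- speciate_cons(y0, h_start = conc[[I_H]])
  ## members (and weights) of each conserved variable: only their own
  ## flux responses enter the diagonal sensitivity
  members <- list(I_NA, I_K, I_CL, I_UREA, I_GLC,
                  c(I_HCO3, I_H2CO3, I_CO2), c(I_NH3, I_NH4),
                  c(I_H2PO4, I_HPO4), c(I_HCO2, I_H2CO2),
                  c(I_H, I_NH4, I_HCO3, I_H2PO4, I_HPO4, I_HCO2))
  wts <- list(1, 1, 1, 1, 1, c(1, 1, 1), c(1, 1), c(1, 1), c(1, 1),
              c(1, 1, 1, 1, 2, 1))
  g <- matrix(0, 10, 10)
  for (k in 1:10) {
    eps <- 1e-4 * (abs(y0[[k]]) + 1e-2)
    yk <- y0
    yk[[k]] <- yk[[k]] + eps
    ck <- speciate_cons(yk, h_start = c0[[I_H]])
    dcdy <- (ck - c0) / eps
    for (j in 1:10) {
      m <- members[[j]]
      g[j, k] <- sum(wts[[j]] * G[m] * dcdy[m])
    }
  }
  g
}

## Upper bound on the diagonal sensitivity of luminal loss rates to the
## local luminal concentration, dJ_i/dC_i (pmol/(min.cm.mM)), from the
## permeability structure and carrier slopes.  Overestimates are safe (the
## semi-implicit correction only damps the Picard iteration).
step_sensitivity <- function(comp, cref) {
  ## GHK field factor bounded for ~|90| mV, either sign
  G <- FLUX_CONV * (comp$apical$perm * comp$apical$area +
                      comp$tj$perm * comp$tj$area) * exp(1.7 * abs(VALENCE))
  tq_bound <- if (comp$torque) 1.3 else 1
  for (tr in comp$transporters) {
    a <- tr$activity * tq_bound * comp$apical$area
    if (tr$membrane != "apical" || a == 0) next
    switch(tr$id,
      SGLT2 = { G[[I_GLC]] <- G[[I_GLC]] + a / 10
                G[[I_NA]] <- G[[I_NA]] + a / 25 },
      SGLT1 = { G[[I_GLC]] <- G[[I_GLC]] + a
                G[[I_NA]] <- G[[I_NA]] + 2 * a / 15 },
      NHE3 = { G[[I_NA]] <- G[[I_NA]] + a / 30
               G[[I_H]] <- G[[I_H]] + a / (4 * 2.5e-4)
               G[[I_NH4]] <- G[[I_NH4]] + a / 8 },
      NKCC2 = { G[[I_NA]] <- G[[I_NA]] + 3 * a / cref[[I_NA]]
                G[[I_K]] <- G[[I_K]] + 4.5 * a / cref[[I_K]]
                G[[I_CL]] <- G[[I_CL]] + 6 * a / cref[[I_CL]] },
      NCC = { G[[I_NA]] <- G[[I_NA]] + 2 * a / cref[[I_NA]]
              G[[I_CL]] <- G[[I_CL]] + 2 * a / cref[[I_CL]] },
      NULL)
  }
  G
}

simpleCondition_run_dry <- function(seg_id) {
  cond <- simpleError(sprintf(
    "tubule ran dry: luminal flow vanished before the end of segment %s",
    seg_id))
  class(cond) <- c("nephroflux_run_dry", class(cond))
  cond
}

#' Audit luminal mass conservation over a solved segment
#'
#' Verifies, for water and each of the 15 solutes, that the inflow minus
#' outflow mass rate equals the integrated transmural transport minus the
#' luminal buffer reaction source.  Reports the worst relative offender.
#'
#' @param profile a `tubular_profile` from [solve_segment()]
#' @param tol relative tolerance (default 1e-6)
#' @param strict error (rather than report) on violation
#' @return data.frame with one row per balance (15 solutes + water):
#'   inflow, outflow, transmural, reacted, residual and relative error;
#'   attribute `worst` names the worst balance
#' @export
audit_conservation <- function(profile, tol = 1e-6, strict = FALSE) {
  stopifnot(inherits(profile, "tubular_profile"))
  n <- length(profile$flow)
  m_in <- profile$inflow$flow * profile$inflow$conc
  m_out <- profile$outflow$flow * profile$outflow$conc
  resid <- m_in - m_out - profile$transmural + profile$reacted
  rel <- abs(resid) / pmax(abs(m_in), abs(m_out), abs(profile$transmural),
                           1e-8)
  w_resid <- profile$inflow$flow - profile$outflow$flow - profile$water_reab
  w_rel <- abs(w_resid) / max(profile$inflow$flow, 1e-8)
  out <- data.frame(
    balance = c(SOLUTES, "water"),
    inflow = c(m_in, profile$inflow$flow),
    outflow = c(m_out, profile$outflow$flow),
    transmural = c(profile$transmural, profile$water_reab),
    reacted = c(profile$reacted, 0),
    residual = c(resid, w_resid),
    rel_error = c(rel, w_rel)
  )
  worst <- out$balance[[which.max(out$rel_error)]]
  attr(out, "worst") <- worst
  if (strict && max(out$rel_error) > tol)
    stop("conservation audit failed for ", worst,
         " (rel error ", signif(max(out$rel_error), 3), ")")
  out
}
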