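# Steady-state epithelial node problem.
#
# At one axial position the unknowns are the 15 cytosolic concentrations,
# the cytosolic impermeant-anion concentration, the cell potential and the
# luminal potential (18 unknowns).  The residuals are the steady-state cell
# mass balances (with buffer reaction sources), the fast buffer equilibria,
# a net-acid balance, cell electroneutrality, cell water balance, and zero
# net electrical current leaving the lumen (axial currents neglected).
# Concentrations are solved in log space so positivity is structural.
#
# The lateral intercellular space is assumed fully equilibrated with the
# (prescribed) interstitium, so the basolateral membrane and tight junction
# both face the interstitial boundary composition.

## Compile one segment's parameter block into flat numeric structures used
## by the hot loops.  `seg` is one entry of params$segments.
prepare_segment <- function(seg, seg_id) {
  circ <- pi * seg$diameter
  getv <- function(lst, default) {
    v <- rep(default, N_SOL)
    names(v) <- SOLUTES
    if (!is.null(lst)) for (nm in names(lst)) v[[nm]] <- lst[[nm]]
    v
  }
  barrier <- function(b, area_mult, sigma_default = 1) {
    list(perm = getv(b$perm, 0),
         sigma = getv(b$sigma, b$sigma_default %||% sigma_default),
         pf = b$pf %||% 0,
         area = circ * area_mult)
  }
  tr <- lapply(seg$transporters %||% list(), function(t) {
    list(id = t$id, membrane = t$membrane, activity = t$activity,
         profile = t$profile)   # profile: list(breaks=..., values=...)
  })
  names(tr) <- vapply(tr, `[[`, "", "id")
  out <- list(
    id = seg_id,
    epithelium = seg$epithelium %||% "cell",
    length = seg$length, radius = seg$diameter / 2,
    n_nodes = seg$n_nodes,
    depth = seg$depth %||% c(0, 0),
    apical = barrier(seg$apical %||% list(), seg$area_apical %||% 1),
    basolateral = barrier(seg$basolateral %||% list(),
                          seg$area_basolateral %||% 1),
    tj = barrier(seg$tj %||% list(), seg$area_tj %||% 1, 1),
    transporters = tr,
    cell_volume = seg$cell_volume %||% 8e-6,
    ## floored so the CO2 hydration residual always pins the carbonic
    ## speciation even in sealed cells
    ca_cell = max(seg$ca_cell %||% 10, 1e-2),
    z_imp = seg$z_imp %||% -1,
    torque = isTRUE(seg$torque)
  )
  ## which solutes have any pathway into the cell (membrane permeability or
  ## carrier)?  Balance residuals of disconnected solutes are replaced by
  ## concentration pins to keep the node Jacobian non-singular.
  touched <- out$apical$perm > 0 | out$basolateral$perm > 0
  tsol <- list(SGLT2 = c("Na", "glucose"), SGLT1 = c("Na", "glucose"),
               GLUT2 = "glucose", GLUT1 = "glucose",
               NaK_ATPase = c("Na", "K"), NKCC2 = c("Na", "K", "Cl"),
               NCC = c("Na", "Cl"), KCC = c("K", "Cl"),
               NHE3 = c("Na", "H", "NH4"), H_ATPase = "H")
  for (t in tr) if (t$activity > 0) touched[tsol[[t$id]]] <- TRUE
  out$connected <- touched
  out$water_ok <- (out$apical$pf + out$basolateral$pf) > 0
  out$current_ok <- any((out$apical$perm > 0 | out$tj$perm > 0) &
                          VALENCE != 0) ||
    any(vapply(tr, function(t)
      t$activity > 0 && t$id %in% c("SGLT2", "SGLT1", "H_ATPase"),
      TRUE))
  out$acid_ok <- any(touched[c("H", "HCO3", "NH4", "HPO4", "HCO2")])
  ## precomputed permeability*area blocks for the fused GHK evaluation
  out$pa_all <- c(out$apical$perm * out$apical$area,
                  out$basolateral$perm * out$basolateral$area,
                  out$tj$perm * out$tj$area) * FLUX_CONV
  sglt <- intersect(names(tr), c("SGLT2", "SGLT1"))
  out$has_sglt <- length(sglt) > 0 &&
    any(vapply(tr[sglt], function(t) t$activity > 0, TRUE))
  out$sglt_isoform <- if (out$has_sglt) sglt[[1]] else NA_character_
  out
}

## transporter activity at normalized axial position x (piecewise profile)
transporter_activity <- function(tr, x) {
  a <- tr$activity
  if (!is.null(tr$profile)) {
    i <- findInterval(x, tr$profile$breaks) + 1L
    a <- a * tr$profile$values[[i]]
  }
  a
}

## All membrane fluxes at one node.  Returns per-solute vectors `ap`
## (lumen -> cell), `bl` (cell -> interstitium), `tj` (lumen ->
## interstitium) and the three water fluxes.  When `detail = TRUE` a
## per-transporter attribution matrix is included.
node_fluxes <- function(conc_l, conc_c, conc_i, vl, vc, p_l, p_i,
                        comp, x = 0, torque_mult = 1, detail = FALSE,
                        c_imp = 0) {
  ap_b <- comp$apical; bl_b <- comp$basolateral; tj_b <- comp$tj

  ## the cytosolic impermeant anion is fully osmotically active
  jw_ap <- water_flux(ap_b$pf, ap_b$area, conc_l, conc_c, ap_b$sigma,
                      p_l, p_i) +
    ap_b$pf * ap_b$area * WATER_CONV * c_imp
  jw_bl <- water_flux(bl_b$pf, bl_b$area, conc_c, conc_i, bl_b$sigma,
                      p_i, p_i) -
    bl_b$pf * bl_b$area * WATER_CONV * c_imp
  jw_tj <- water_flux(tj_b$pf, tj_b$area, conc_l, conc_i, tj_b$sigma,
                      p_l, p_i)

  ## fused GHK evaluation over the three barriers (same law as
  ## electrodiffusive_flux / paracellular_flux, evaluated in one block)
  u <- VALENCE3 * c(rep(vl - vc, N_SOL), rep(vc, N_SOL),
                    rep(vl, N_SOL)) / RTF
  phi <- u / (1 - exp(-u))
  small <- abs(u) < 1e-6
  if (any(small)) phi[small] <- 1 + u[small] / 2 + u[small]^2 / 12
  j3 <- comp$pa_all * phi *
    (c(conc_l, conc_c, conc_l) - c(conc_c, conc_i, conc_i) * exp(-u))
  ap <- j3[1:15]
  bl <- j3[16:30]
  tj <- j3[31:45] + (1 - tj_b$sigma) * log_mean(conc_l, conc_i) * jw_tj
  names(ap) <- names(bl) <- names(tj) <- SOLUTES

  attribution <- if (detail) list() else NULL
  add <- function(side, sol, j, id) {
    if (side == "ap") ap[sol] <<- ap[sol] + j else bl[sol] <<- bl[sol] + j
    if (detail) {
      v <- stats::setNames(numeric(N_SOL), SOLUTES); v[sol] <- j
      attribution[[id]] <<- v
    }
  }
  for (tr in comp$transporters) {
    act <- transporter_activity(tr, x) * torque_mult
    if (act == 0) next
    switch(tr$id,
      SGLT2 = , SGLT1 = {
        j <- sglt_flux(conc_l[[I_NA]], conc_l[[I_GLC]],
                       conc_c[[I_NA]], conc_c[[I_GLC]], vl - vc,
                       tr$id, act, ap_b$area)
        add("ap", c(I_GLC, I_NA), c(j$glucose, j$Na), tr$id)
      },
      GLUT2 = , GLUT1 = {
        j <- glut_flux(conc_c[[I_GLC]], conc_i[[I_GLC]], tr$id, act,
                       bl_b$area)
        add("bl", I_GLC, j, tr$id)
      },
      NaK_ATPase = {
        j <- nak_atpase_flux(conc_c[[I_NA]], conc_i[[I_K]], act, bl_b$area)
        add("bl", c(I_NA, I_K), c(j$Na, j$K), tr$id)
      },
      NKCC2 = {
        j <- cotransport_flux(c(Na = 1, K = 1, Cl = 2), conc_l, conc_c,
                              act, ap_b$area)
        add("ap", c(I_NA, I_K, I_CL), j[c("Na", "K", "Cl")], tr$id)
      },
      NCC = {
        j <- cotransport_flux(c(Na = 1, Cl = 1), conc_l, conc_c,
                              act, ap_b$area)
        add("ap", c(I_NA, I_CL), j[c("Na", "Cl")], tr$id)
      },
      KCC = {
        j <- cotransport_flux(c(K = 1, Cl = 1), conc_c, conc_i,
                              act, bl_b$area)
        add("bl", c(I_K, I_CL), j[c("K", "Cl")], tr$id)
      },
      NHE3 = {
        j <- nhe3_flux(conc_l[[I_NA]], conc_c[[I_NA]],
                       conc_l[[I_H]], conc_c[[I_H]],
                       conc_l[[I_NH4]], conc_c[[I_NH4]], act, ap_b$area)
        add("ap", c(I_NA, I_H, I_NH4), c(j$Na, -j$H, -j$NH4), tr$id)
      },
      H_ATPase = {
        j <- h_atpase_flux(conc_c[[I_H]], conc_l[[I_H]], act, ap_b$area)
        add("ap", I_H, -j, tr$id)
      },
      stop("unknown transporter id: ", tr$id)
    )
  }
  list(ap = ap, bl = bl, tj = tj,
       jw_ap = jw_ap, jw_bl = jw_bl, jw_tj = jw_tj,
       attribution = attribution)
}

## unknown vector <-> node state
pack_node <- function(conc_c, c_imp, vc, vl) c(log(conc_c), log(c_imp), vc, vl)
unpack_node <- function(x) {
  list(conc = stats::setNames(exp(x[1:N_SOL]), SOLUTES),
       c_imp = exp(x[[16]]), vc = x[[17]], vl = x[[18]])
}

#' Residuals of the steady-state epithelial node system
#'
#' Assembles the 18 scaled residuals of the cell-and-lumen-potential system
#' at one axial position: per-solute cell mass balances with buffer
#' reaction sources, the fast buffer equilibrium constraints, the CO2
#' hydration kinetic balance, a net-acid balance, cell electroneutrality,
#' cell water balance, and zero net current leaving the lumen.
#'
#' @param x unknown vector: log cytosolic concentrations (15), log
#'   impermeant concentration, cell potential (mV), luminal potential (mV)
#' @param lumen list with `conc` (named 15-vector, mM) and `p` (mmHg)
#' @param inter list with `conc` and `p` for the local interstitium
#' @param comp compiled segment parameters (internal structure)
#' @param x_norm normalized axial position in the segment
#' @param torque_mult transcellular activity multiplier (torque effect)
#' @param scales fixed residual scales from `node_scales()`; computed on
#'   the fly when `NULL`
#' @return numeric vector of 18 dimensionless residuals; the flux set used
#'   is attached as attribute `"fluxes"`
#' @export
assemble_node_residuals <- function(x, lumen, inter, comp,
                                    x_norm = 0, torque_mult = 1,
                                    scales = NULL) {
  if (is.null(scales)) scales <- node_scales(lumen, inter, comp, torque_mult)
  st <- unpack_node(x)
  conc_c <- st$conc
  fl <- node_fluxes(lumen$conc, conc_c, inter$conc, st$vl, st$vc,
                    lumen$p, inter$p, comp, x_norm, torque_mult,
                    c_imp = st$c_imp)
  if (any(!is.finite(fl$ap)) || any(!is.finite(fl$bl)) ||
      any(!is.finite(fl$tj)))
    stop("non-finite membrane flux in segment ", comp$id,
         " (check state/parameters)")
  jnet <- fl$ap - fl$bl            # net into the cell, pmol/(min.cm)
  kb <- BUFFER_K
  ## CO2 hydration source, converted from mM/s to pmol/(min.cm)
  r_hyd <- comp$ca_cell *
    (kb$kh_CO2 * conc_c[[I_CO2]] - kb$kd_CO2 * conc_c[[I_H2CO3]]) *
    comp$cell_volume * FLUX_CONV
  s <- scales$flux
  eqres <- function(a, b) (a - b) / (abs(a) + abs(b) + 1e-12)

  con <- comp$connected
  cin <- inter$conc
  pin <- function(i) log(conc_c[[i]] / cin[[i]])
  pin_tot <- function(idx) log(sum(conc_c[idx]) / sum(cin[idx]))

  r <- numeric(18)
  r[1] <- jnet[[I_NA]] / s[[I_NA]]
  r[2] <- jnet[[I_K]] / s[[I_K]]
  r[3] <- if (con[[I_CL]]) jnet[[I_CL]] / s[[I_CL]] else pin(I_CL)
  r[4] <- if (con[[I_UREA]]) jnet[[I_UREA]] / s[[I_UREA]] else pin(I_UREA)
  r[5] <- if (con[[I_GLC]]) jnet[[I_GLC]] / s[[I_GLC]] else pin(I_GLC)
  ## carbonic trio: total balance, hydration kinetics, fast equilibrium
  tri <- c(I_HCO3, I_H2CO3, I_CO2)
  r[6] <- if (any(con[tri])) sum(jnet[tri]) / sum(s[tri])
          else pin_tot(tri)
  r[7] <- (jnet[[I_CO2]] - r_hyd) / (s[[I_CO2]] + scales$hyd)
  r[8] <- eqres(conc_c[[I_H]] * conc_c[[I_HCO3]],
                kb$K_HCO3 * conc_c[[I_H2CO3]])
  ## ammonia pair
  nh <- c(I_NH3, I_NH4)
  r[9] <- if (any(con[nh])) sum(jnet[nh]) / sum(s[nh]) else pin_tot(nh)
  r[10] <- eqres(conc_c[[I_H]] * conc_c[[I_NH3]],
                 kb$K_NH * conc_c[[I_NH4]])
  ## phosphate pair
  po <- c(I_H2PO4, I_HPO4)
  r[11] <- if (any(con[po])) sum(jnet[po]) / sum(s[po]) else pin_tot(po)
  r[12] <- eqres(conc_c[[I_H]] * conc_c[[I_HPO4]],
                 kb$K_P * conc_c[[I_H2PO4]])
  ## formate pair
  fo <- c(I_H2CO2, I_HCO2)
  r[13] <- if (any(con[fo])) sum(jnet[fo]) / sum(s[fo]) else pin_tot(fo)
  r[14] <- eqres(conc_c[[I_H]] * conc_c[[I_HCO2]],
                 kb$K_F * conc_c[[I_H2CO2]])
  ## net acid balance (protons corrected for buffer interconversion)
  if (comp$acid_ok) {
    acid <- jnet[[I_H]] - jnet[[I_HCO3]] + jnet[[I_NH4]] -
      jnet[[I_HPO4]] - jnet[[I_HCO2]]
    r[15] <- acid / scales$acid
  } else r[15] <- pin(I_H)
  ## cell electroneutrality (z_imp * c_imp closes the charge)
  qs <- sum(VALENCE * conc_c)
  r[16] <- (qs + comp$z_imp * st$c_imp) / (sum(abs(VALENCE * conc_c)) +
                                             abs(st$c_imp))
  ## cell water balance (isotonic pin if the cell is water-impermeable)
  r[17] <- if (comp$water_ok)
    (fl$jw_ap - fl$jw_bl) / scales$water
  else (sum(conc_c) + st$c_imp - sum(cin)) / sum(cin)
  ## zero net current leaving the lumen
  r[18] <- if (comp$current_ok) {
    sum(VALENCE * (fl$ap + fl$tj)) / scales$current
  } else st$vl / 100
  attr(r, "fluxes") <- fl
  r
}

## Fixed characteristic residual scales for one node solve, computed from
## the boundary states and parameters only (never from the unknowns), so
## the scaled residuals stay smooth in the unknowns.
node_scales <- function(lumen, inter, comp, torque_mult = 1) {
  cref <- pmax(lumen$conc, inter$conc)
  s <- (comp$apical$perm * comp$apical$area +
          comp$basolateral$perm * comp$basolateral$area) *
    FLUX_CONV * cref
  cur <- sum(abs(VALENCE) * (comp$apical$perm * comp$apical$area +
                               comp$tj$perm * comp$tj$area) *
               FLUX_CONV * cref)
  for (tr in comp$transporters) {
    aa <- tr$activity * torque_mult *
      max(if (!is.null(tr$profile)) tr$profile$values else 1)
    a_ap <- comp$apical$area; a_bl <- comp$basolateral$area
    add <- switch(tr$id,
      SGLT2 = c(Na = aa * a_ap, glucose = aa * a_ap),
      SGLT1 = c(Na = 2 * aa * a_ap, glucose = aa * a_ap),
      GLUT2 = , GLUT1 = c(glucose = aa * a_bl),
      NaK_ATPase = c(Na = aa * a_bl, K = 2 / 3 * aa * a_bl),
      NKCC2 = c(Na = 3 * aa * a_ap, K = 3 * aa * a_ap,
                Cl = 6 * aa * a_ap),
      NCC = c(Na = 3 * aa * a_ap, Cl = 3 * aa * a_ap),
      KCC = c(K = 3 * aa * a_bl, Cl = 3 * aa * a_bl),
      NHE3 = c(Na = aa * a_ap, H = aa * a_ap, NH4 = aa * a_ap),
      H_ATPase = c(H = aa * a_ap))
    s[names(add)] <- s[names(add)] + add
    if (tr$id %in% c("SGLT2", "SGLT1", "H_ATPase"))
      cur <- cur + add[[1]]
  }
  s <- pmax(s, 1e-3)
  kb <- BUFFER_K
  hyd <- comp$ca_cell * kb$kd_CO2 * max(inter$conc[[I_H2CO3]], 1e-4) *
    comp$cell_volume * FLUX_CONV
  list(
    flux = s,
    water = (comp$apical$pf * comp$apical$area +
               comp$basolateral$pf * comp$basolateral$area) *
      WATER_CONV * 5 + 1e-3,
    current = max(cur, 1e-3),
    acid = sum(s[c(I_H, I_HCO3, I_NH4, I_HPO4, I_HCO2)]),
    hyd = hyd
  )
}

## generic cold-start cell guess, speciated to internal buffer equilibrium
cold_cell_guess <- function(lumen, comp) {
  h <- 10^(3 - 7.2)
  conc <- speciate(na = 20, k = 130, cl = 25,
                   ct = 25 + (1 + BUFFER_K$kd_CO2 / BUFFER_K$kh_CO2) *
                     h * 25 / BUFFER_K$K_HCO3,
                   nt = 0.5, pt = 2.2, ft = 1,
                   urea = lumen$conc[[I_UREA]],
                   glc = max(lumen$conc[[I_GLC]], 1), h = h)
  c_imp <- max(sum(VALENCE * conc) / -comp$z_imp, 10)
  pack_node(conc, c_imp, -70, -1)
}

#' Solve the epithelial node system
#'
#' Damped Newton iteration with finite-difference Jacobian on the
#' log-transformed node unknowns.  The Jacobian can be reused across warm
#' starts (quasi-Newton chord steps) and is refreshed automatically when
#' progress stalls.
#'
#' @param lumen,inter boundary states (lists with `conc`, `p`)
#' @param comp compiled segment parameters
#' @param x0 initial unknown vector; defaults to a generic epithelial guess
#' @param x_norm,torque_mult position and torque multiplier
#' @param tol convergence tolerance on the scaled residual norm
#' @param max_iter Newton iteration cap
#' @param jac optional Jacobian (with factorization) to reuse
#' @param scales fixed residual scales (recomputed when `NULL`); the axial
#'   marcher shares one set across the Picard iterates of a step
#' @return list with the node `state`, the flux set `fluxes`, the unknown
#'   vector `x`, `residual_norm`, `iterations`, and the final `jac`
#' @export
solve_node <- function(lumen, inter, comp, x0 = NULL, x_norm = 0,
                       torque_mult = 1, tol = 1e-10, max_iter = 40,
                       jac = NULL, scales = NULL) {
  if (is.null(x0)) x0 <- cold_cell_guess(lumen, comp)
  if (is.null(scales)) scales <- node_scales(lumen, inter, comp, torque_mult)
  fn <- function(x) assemble_node_residuals(x, lumen, inter, comp,
                                            x_norm, torque_mult, scales)
  sol <- newton_solve(fn, x0, tol = tol, max_iter = max_iter, jac = jac)
  if (!sol$converged) {
    ## multistart fallback: generic guess plus perturbed variants
    base <- cold_cell_guess(lumen, comp)
    starts <- list(base,
                   { g <- base; g[[17]] <- -40; g },
                   { g <- base; g[[I_GLC]] <- log(0.2); g },
                   { g <- base; g[[I_NA]] <- log(35); g[[17]] <- -55; g })
    for (g in starts) {
      sol2 <- newton_solve(fn, g, tol = tol, max_iter = 2 * max_iter)
      if (sol2$converged) { sol <- sol2; break }
      if (sol2$residual_norm < sol$residual_norm) sol <- sol2
    }
  }
  if (!sol$converged) {
    cond <- simpleError(sprintf(
      "node solve failed in segment %s at x=%.3f (residual %.3e)",
      comp$id, x_norm, sol$residual_norm))
    cond$best <- sol
    class(cond) <- c("nephroflux_node_error", class(cond))
    stop(cond)
  }
  st <- unpack_node(sol$x)
  r <- fn(sol$x)
  list(state = st, fluxes = attr(r, "fluxes"), x = sol$x,
       residual_norm = max(abs(r)), iterations = sol$iterations,
       jac = sol$jac)
}

## Damped Newton with forward-difference Jacobian.  A supplied Jacobian is
## tried first (chord step, the common warm-start case along a segment) and
## refreshed as soon as the contraction rate degrades.
newton_solve <- function(fn, x0, tol = 1e-10, max_iter = 40, jac = NULL) {
  x <- x0
  r <- fn(x)
  rn <- max(abs(r))
  it <- 0L
  fresh <- FALSE
  refresh <- is.null(jac)
  while (rn > tol && it < max_iter) {
    if (refresh) {
      jac <- fd_jacobian(fn, x, r)
      fresh <- TRUE
      refresh <- FALSE
    }
    dx <- tryCatch(solve(jac, -as.numeric(r)), error = function(e) NULL)
    if (is.null(dx) && !fresh) {
      refresh <- TRUE
      next
    }
    if (is.null(dx))
      dx <- tryCatch(-qr.solve(qr(jac, LAPACK = TRUE), as.numeric(r)),
                     error = function(e) NULL)
    if (is.null(dx)) break
    ## cap steps in log-concentration space to keep iterates physical
    dx <- pmin(pmax(dx, -4), 4)
    lam <- 1
    rnew <- NULL
    repeat {
      xn <- x + lam * dx
      rtry <- tryCatch(fn(xn), error = function(e) NULL)
      if (!is.null(rtry) && all(is.finite(rtry)) &&
          max(abs(rtry)) < rn * (1 - 1e-4 * lam) + 1e-14) {
        rnew <- rtry
        break
      }
      lam <- lam / 2
      if (lam < 1 / 1024) break
    }
    if (fresh && (is.null(rnew) || lam < 1 / 32)) {
      ## narrow curved valley: Levenberg-Marquardt trust-region step
      jtj <- crossprod(jac)
      jtr <- crossprod(jac, as.numeric(r))
      d <- diag(jtj) + 1e-12
      for (mu in 10^seq(-6, 2, by = 1)) {
        dlm <- tryCatch(-solve(jtj + mu * diag(d), jtr)[, 1],
                        error = function(e) NULL)
        if (is.null(dlm)) next
        dlm <- pmin(pmax(dlm, -4), 4)
        rtry <- tryCatch(fn(x + dlm), error = function(e) NULL)
        if (!is.null(rtry) && all(is.finite(rtry)) &&
            (max(abs(rtry)) < rn * (1 - 1e-6) ||
               sum(rtry^2) < sum(r^2) * (1 - 1e-6))) {
          rnew <- rtry
          xn <- x + dlm
          lam <- 1
          break
        }
      }
    }
    if (is.null(rnew)) {
      ## no progress along this direction
      if (fresh) break
      refresh <- TRUE
      next
    }
    rho <- max(abs(rnew)) / rn
    x <- xn; r <- rnew; rn <- max(abs(r))
    it <- it + 1L
    ## once we move, the Jacobian is no longer current; recompute unless
    ## the chord step is contracting fast
    fresh <- FALSE
    if (lam < 1 || rho > 0.4) refresh <- TRUE
  }
  list(x = x, residual_norm = rn, iterations = it,
       converged = rn <= tol, jac = jac)
}

fd_jacobian <- function(fn, x, r0 = NULL) {
  if (is.null(r0)) r0 <- fn(x)
  n <- length(x)
  J <- matrix(0, length(r0), n)
  for (j in seq_len(n)) {
    h <- 1e-7 * (1 + abs(x[[j]]))
    xj <- x
    xj[[j]] <- xj[[j]] + h
    J[, j] <- (fn(xj) - r0) / h
  }
  J
}

## Passive (thin-limb) node: no cell compartment; the epithelium is a
## single barrier (stored in the `tj` slot) between lumen and interstitium.
## The luminal potential is set by the zero-current condition.
solve_passive_node <- function(lumen, inter, comp) {
  b <- comp$tj
  current <- function(vl) {
    jw <- water_flux(b$pf, b$area, lumen$conc, inter$conc, b$sigma,
                     lumen$p, inter$p)
    j <- paracellular_flux(b$perm, b$area, VALENCE, lumen$conc, inter$conc,
                           vl, b$sigma, jw)
    sum(VALENCE * j)
  }
  vl <- tryCatch(
    stats::uniroot(current, c(-120, 120), tol = 1e-10)$root,
    error = function(e) 0)
  jw <- water_flux(b$pf, b$area, lumen$conc, inter$conc, b$sigma,
                   lumen$p, inter$p)
  j <- paracellular_flux(b$perm, b$area, VALENCE, lumen$conc, inter$conc,
                         vl, b$sigma, jw)
  list(state = list(conc = NULL, c_imp = NA, vc = NA, vl = vl),
       fluxes = list(ap = stats::setNames(numeric(N_SOL), SOLUTES),
                     bl = stats::setNames(numeric(N_SOL), SOLUTES),
                     tj = j, jw_ap = 0, jw_bl = 0, jw_tj = jw),
       x = NULL, jac = NULL, iterations = 0L, residual_norm = 0)
}
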