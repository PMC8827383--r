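# Acid-base / buffer chemistry.
#
# The CO2 hydration reaction (CO2 + H2O <-> H2CO3, carbonic-anhydrase
# accelerated) is treated with finite-rate kinetics; all proton-transfer
# reactions (H2CO3, NH4+, H2PO4-, formic acid) are fast and treated as
# equilibria.  Luminal fluid is re-speciated to equilibrium after every
# axial step (operator splitting), conserving buffer totals and charge; the
# reacted amounts are recorded so that per-species mass audits close.

#' Buffer reaction source terms
#'
#' Net production rate (mM/s) of every solute from the buffer reactions at
#' the given composition.  CO2 hydration uses finite-rate kinetics scaled by
#' the local carbonic-anhydrase factor; the proton-transfer reactions use
#' stiff mass-action rates relaxing towards their pKa equilibria.  The
#' sources conserve each buffer total and total charge exactly, by
#' construction.
#'
#' @param conc named concentration vector over the 15 solutes (mM)
#' @param ca_factor carbonic-anhydrase acceleration of CO2 hydration
#' @param k_fast rate constant of the fast proton-transfer relaxations (1/s)
#' @return named vector of source terms (mM/s) over the 15 solutes
#' @export
buffer_sources <- function(conc, ca_factor = 1, k_fast = 1e3) {
  stopifnot(all(conc > 0))
  kb <- BUFFER_K
  r_hyd <- ca_factor * (kb$kh_CO2 * conc[["CO2"]] - kb$kd_CO2 * conc[["H2CO3"]])
  r_c <- k_fast * (conc[["H2CO3"]] - conc[["H"]] * conc[["HCO3"]] / kb$K_HCO3)
  r_n <- k_fast * (conc[["NH4"]] - conc[["H"]] * conc[["NH3"]] / kb$K_NH)
  r_p <- k_fast * (conc[["H2PO4"]] - conc[["H"]] * conc[["HPO4"]] / kb$K_P)
  r_f <- k_fast * (conc[["H2CO2"]] - conc[["H"]] * conc[["HCO2"]] / kb$K_F)
  src <- stats::setNames(numeric(N_SOL), SOLUTES)
  src[["CO2"]] <- -r_hyd
  src[["H2CO3"]] <- r_hyd - r_c
  src[["HCO3"]] <- r_c
  src[["NH4"]] <- -r_n
  src[["NH3"]] <- r_n
  src[["H2PO4"]] <- -r_p
  src[["HPO4"]] <- r_p
  src[["H2CO2"]] <- -r_f
  src[["HCO2"]] <- r_f
  src[["H"]] <- r_c + r_n + r_p + r_f
  src
}

## Equilibrium speciation of a fluid given buffer totals and a free-[H+]
## value: returns the 15-solute vector.  `ct`, `nt`, `pt`, `ft` are the
## carbonic, ammonia, phosphate and formate totals.
speciate <- function(na, k, cl, ct, nt, pt, ft, urea, glc, h) {
  kb <- BUFFER_K
  rho <- kb$kd_CO2 / kb$kh_CO2
  h2co3 <- ct / (1 + rho + kb$K_HCO3 / h)
  conc <- c(
    Na = na, K = k, Cl = cl,
    HCO3 = h2co3 * kb$K_HCO3 / h, H2CO3 = h2co3, CO2 = rho * h2co3,
    NH3 = nt * kb$K_NH / (h + kb$K_NH), NH4 = nt * h / (h + kb$K_NH),
    H2PO4 = pt * h / (h + kb$K_P), HPO4 = pt * kb$K_P / (h + kb$K_P),
    H = h,
    HCO2 = ft * kb$K_F / (h + kb$K_F), H2CO2 = ft * h / (h + kb$K_F),
    urea = urea, glucose = glc
  )
  conc[SOLUTES]
}

#' Re-speciate a fluid to buffer equilibrium
#'
#' Projects a composition onto the manifold of buffer equilibria while
#' conserving the four buffer totals and the total charge.  The free [H+]
#' is found by a monotone one-dimensional root solve on pH.  Used for the
#' luminal fluid after every axial transport step.
#'
#' @param conc named 15-solute concentration vector (mM)
#' @return named 15-solute concentration vector at equilibrium
#' @export
equilibrate_buffers <- function(conc) {
  kb <- BUFFER_K
  ct <- conc[["HCO3"]] + conc[["H2CO3"]] + conc[["CO2"]]
  nt <- conc[["NH3"]] + conc[["NH4"]]
  pt <- conc[["H2PO4"]] + conc[["HPO4"]]
  ft <- conc[["HCO2"]] + conc[["H2CO2"]]
  q0 <- sum(VALENCE * conc)
  rho <- kb$kd_CO2 / kb$kh_CO2
  ## charge excess as a function of free [H+] (mM); strictly increasing
  f <- function(h) {
    h2co3 <- ct / (1 + rho + kb$K_HCO3 / h)
    hco3 <- h2co3 * kb$K_HCO3 / h
    nh4 <- nt * h / (h + kb$K_NH)
    h2po4 <- pt * h / (h + kb$K_P)
    hpo4 <- pt - h2po4
    hco2 <- ft * kb$K_F / (h + kb$K_F)
    conc[["Na"]] + conc[["K"]] - conc[["Cl"]] - hco3 + nh4 - h2po4 -
      2 * hpo4 + h - hco2 - q0
  }
  ## damped Newton on log[H+], warm-started from the incoming value
  x <- log(max(conc[["H"]], 1e-10))
  ok <- FALSE
  for (i in 1:30) {
    h <- exp(x)
    fx <- f(h)
    if (abs(fx) < 1e-13 * max(1, abs(q0))) { ok <- TRUE; break }
    dh <- h * 1e-6
    d <- (f(h + dh) - fx) / dh
    step <- -fx / (d * h)          # d(log h)
    x <- x + pmin(pmax(step, -2), 2)
  }
  h <- exp(x)
  if (!ok || !is.finite(h)) {
    root <- stats::uniroot(function(ph) f(10^(3 - ph)), c(2, 13),
                           tol = 1e-13, extendInt = "downX")
    h <- 10^(3 - root$root)
  }
  speciate(conc[["Na"]], conc[["K"]], conc[["Cl"]],
           ct, nt, pt, ft, conc[["urea"]], conc[["glucose"]], h)
}

## Conserved luminal variables: the 10 quantities invariant under the fast
## buffer reactions -- Na, K, Cl, urea, glucose, the four buffer-group
## totals, and the net acid charge Qa = H + NH4 - HCO3 - H2PO4 - 2 HPO4 -
## HCO2.  Linear, so it applies to concentrations, masses and rates alike.
cons_vars <- function(v) {
  c(v[[I_NA]], v[[I_K]], v[[I_CL]], v[[I_UREA]], v[[I_GLC]],
    v[[I_HCO3]] + v[[I_H2CO3]] + v[[I_CO2]],
    v[[I_NH3]] + v[[I_NH4]],
    v[[I_H2PO4]] + v[[I_HPO4]],
    v[[I_HCO2]] + v[[I_H2CO2]],
    v[[I_H]] + v[[I_NH4]] - v[[I_HCO3]] - v[[I_H2PO4]] -
      2 * v[[I_HPO4]] - v[[I_HCO2]])
}

## Reconstruct the full equilibrated 15-species composition from the
## conserved variables: free [H+] is the root of Qa(H) = y[10] (monotone).
speciate_cons <- function(y, h_start = 4e-5) {
  kb <- BUFFER_K
  rho <- kb$kd_CO2 / kb$kh_CO2
  ct <- y[[6]]; nt <- y[[7]]; pt <- y[[8]]; ft <- y[[9]]
  qa <- function(h) {
    h2co3 <- ct / (1 + rho + kb$K_HCO3 / h)
    h + nt * h / (h + kb$K_NH) - h2co3 * kb$K_HCO3 / h -
      pt * h / (h + kb$K_P) - 2 * pt * kb$K_P / (h + kb$K_P) -
      ft * kb$K_F / (h + kb$K_F)
  }
  ## clamp the target into the achievable net-acid-charge range (transient
  ## Picard iterates can overshoot it; the converged step lies interior)
  qlo <- qa(10^(3 - 13.8))
  qhi <- qa(10^(3 - 0.5))
  target <- min(max(y[[10]], qlo * (1 - sign(qlo) * 1e-10) + 1e-12),
                qhi - abs(qhi) * 1e-10)
  x <- log(max(h_start, 1e-10))
  ok <- FALSE
  for (i in 1:40) {
    h <- exp(x)
    fx <- qa(h) - target
    if (abs(fx) < 1e-13 * max(1, abs(target))) { ok <- TRUE; break }
    dh <- h * 1e-6
    d <- (qa(h + dh) - qa(h)) / dh
    x <- x + pmin(pmax(-fx / (d * h), -2), 2)
  }
  if (!ok || !is.finite(x)) {
    root <- stats::uniroot(function(ph) qa(10^(3 - ph)) - target,
                           c(0.5, 13.8), tol = 1e-14)
    x <- log(10^(3 - root$root))
  }
  speciate(y[[1]], y[[2]], y[[3]], ct, nt, pt, ft, y[[4]], y[[5]], exp(x))
}

## Build an equilibrated composition from a compact description
## (Na, K, Cl, HCO3, pH, ammonia/phosphate/formate totals, urea, glucose).
## With `balance = TRUE` the Cl concentration is adjusted so the fluid is
## exactly electroneutral (required for the filtrate: axial charge flow is
## conserved along the tubule, so any inlet imbalance would be
## concentrated as water is reabsorbed).
compose_fluid <- function(spec, glucose = NULL, balance = FALSE) {
  h <- 10^(3 - spec$pH)
  kb <- BUFFER_K
  rho <- kb$kd_CO2 / kb$kh_CO2
  h2co3 <- h * spec$HCO3 / kb$K_HCO3
  ct <- spec$HCO3 + h2co3 + rho * h2co3
  out <- speciate(spec$Na, spec$K, spec$Cl, ct, spec$NH_total,
                  spec$PO4_total, spec$formate_total, spec$urea,
                  glucose %||% spec$glucose, h)
  if (balance) {
    out[["Cl"]] <- out[["Cl"]] + sum(VALENCE * out)
    stopifnot(out[["Cl"]] > 0)
  }
  out
}
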