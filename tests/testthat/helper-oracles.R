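# Independent brute-force oracles used by the test suite.  These are
# deliberately simple (quadrature, dense grids, bisection, explicit
# time-stepping) and never call the solver code paths they check.

RTF_O <- 26.7
FLUX_CONV_O <- 6e7

## Nernst-Planck quadrature oracle for the constant-field membrane flux:
## integrate dc/dx = -j - z*u*c across a unit membrane (linear potential),
## shooting on the flux j so that c(1) = c2.  Returns the flux in the same
## units as electrodiffusive_flux (P, area, mM, mV).
ghk_oracle <- function(perm, area, z, c1, c2, dv, n = 20000) {
  u <- z * dv / RTF_O
  shoot <- function(j) {
    ## RK4 on the Nernst-Planck profile dc/dx = u*c - j, c(0) = c1
    h <- 1 / n
    c <- c1
    f <- function(c) u * c - j
    for (i in seq_len(n)) {
      k1 <- f(c); k2 <- f(c + h / 2 * k1)
      k3 <- f(c + h / 2 * k2); k4 <- f(c + h * k3)
      c <- c + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    c - c2
  }
  lim <- 10 * (abs(c1) + abs(c2)) * (1 + abs(u)) + 1
  j <- stats::uniroot(shoot, c(-lim, lim), tol = 1e-12)$root
  perm * area * FLUX_CONV_O * j
}

## Hand unit-conversion oracle for the osmotic water flux of an impermeant
## gradient: Pf [cm/s] * area [cm2/cm] * Vw [18 cm3/mol] * dC [osmol/L].
water_conv_oracle <- function(pf, area, d_osm_mM) {
  cm3_per_s_per_cm <- pf * area * 18 * (d_osm_mM * 1e-6)  # mol/cm3
  cm3_per_s_per_cm * 1e6 * 60                             # nl/(min.cm)
}

## 0-D closed-system relaxation of the buffer reactions (stiff ODE,
## integrated with lsoda); returns the steady composition.
buffer_relax_oracle <- function(conc, ca_factor = 1, t_end = 10) {
  rhs <- function(t, y, p) {
    y <- stats::setNames(pmax(y, 1e-15), names(conc))
    list(as.numeric(nephroflux::buffer_sources(y, ca_factor)))
  }
  out <- deSolve::ode(y = as.numeric(conc), times = c(0, t_end),
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-14)
  stats::setNames(pmax(out[nrow(out), -1], 1e-15), names(conc))
}

## Reduced pump-leak steady state: unknowns cytosolic Na, K, the
## impermeant concentration and the membrane potential, with Cl and all
## buffers pinned to the bath.  Solved by nested bisection: for a given V,
## Na and K balances are monotone scalar root problems; the outer root is
## the osmotic (isotonic) condition combined with electroneutrality.
pump_leak_oracle <- function(bath, pump, p_na, p_k, area = 1,
                             z_imp = -1) {
  ghk1 <- function(p, z, cin, cout, v) {
    u <- z * v / RTF_O
    phi <- if (abs(u) < 1e-8) 1 + u / 2 else u / (1 - exp(-u))
    p * area * FLUX_CONV_O * phi * (cin - cout * exp(-u))
  }
  pump_na <- function(na) pump * area * (na / (na + 12))^3 *
    (bath[["K"]] / (bath[["K"]] + 1.5))^2
  na_of_v <- function(v) {
    f <- function(na) ghk1(p_na, 1, na, bath[["Na"]], v) + pump_na(na)
    stats::uniroot(f, c(1e-6, 2000), tol = 1e-12,
                   extendInt = "upX")$root
  }
  k_of_v <- function(v, na) {
    f <- function(k) ghk1(p_k, 1, k, bath[["K"]], v) - 2 / 3 * pump_na(na)
    stats::uniroot(f, c(1e-6, 500), tol = 1e-12)$root
  }
  ## fixed (pinned) solutes contribute bath values to charge and osmolality
  pin <- bath
  pin[["Na"]] <- 0; pin[["K"]] <- 0
  q_pin <- sum(nephroflux::solute_table()$valence * pin)
  osm_pin <- sum(pin)
  resid <- function(v) {
    na <- na_of_v(v)
    k <- k_of_v(v, na)
    c_imp_q <- (na + k + q_pin) / -z_imp          # electroneutrality
    c_imp_o <- sum(bath) - (na + k + osm_pin)     # isotonic cell
    c_imp_q - c_imp_o
  }
  v <- stats::uniroot(resid, c(-50, -0.5), tol = 1e-10)$root
  na <- na_of_v(v)
  k <- k_of_v(v, na)
  list(Na = na, K = k, V = v,
       c_imp = sum(bath) - (na + k + osm_pin))
}

## fine-grid RK4 oracle for the osmotic-equilibration tube:
## dF/dx = -k (bath_osm - M/F), with conserved osmole flow M = F0*osm0.
osmotic_tube_oracle <- function(f0, osm0, bath_osm, k, length, n = 40000) {
  m <- f0 * osm0
  f <- f0
  h <- length / n
  dfdx <- function(f) -k * (bath_osm - m / f)
  for (i in seq_len(n)) {
    k1 <- dfdx(f); k2 <- dfdx(f + h / 2 * k1)
    k3 <- dfdx(f + h / 2 * k2); k4 <- dfdx(f + h * k3)
    f <- f + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(flow = f, osm = m / f)
}

## shared fixture: a catalogue and simple states
test_catalogue <- function() nephroflux::load_catalogue()

test_plasma <- function(glucose = 5) {
  params <- nephroflux::build_baseline("male", test_catalogue())
  nephroflux:::scenario_plasma(params)
}
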