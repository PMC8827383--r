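# Flux-law library: equilibria, stoichiometry, limits, and independent
# oracles.

test_that("water flux vanishes at osmotic and pressure equilibrium and is
           linear in the permeability", {
  expect_equal(water_flux(1e-3, 1, c(150, 140), c(150, 140), 1, 5, 5), 0)
  j1 <- water_flux(1e-3, 1, 290, 300, 1)
  j2 <- water_flux(2e-3, 1, 290, 300, 1)
  expect_equal(j2, 2 * j1)
  ## 10 mM impermeant excess outside, sigma 1: matches the hand-converted
  ## unit chain Pf*A*Vw*dC
  expect_equal(water_flux(1e-3, 1, 290, 300, 1),
               water_conv_oracle(1e-3, 1, 10), tolerance = 1e-12)
})

test_that("GHK flux reduces to Fick for an uncharged solute and is
           continuous through zero potential", {
  expect_equal(electrodiffusive_flux(1e-5, 1, 0, 10, 140, -60),
               1e-5 * 1 * 6e7 * (10 - 140))
  expect_equal(electrodiffusive_flux(1e-5, 1, 1, 10, 10, 0), 0)
  ## continuity at dv = 0
  below <- electrodiffusive_flux(1e-5, 1, 1, 10, 20, -1e-7)
  above <- electrodiffusive_flux(1e-5, 1, 1, 10, 20, 1e-7)
  at <- electrodiffusive_flux(1e-5, 1, 1, 10, 20, 0)
  expect_lt(abs(below - at), 1e-6 * abs(at))
  expect_lt(abs(above - at), 1e-6 * abs(at))
})

test_that("GHK flux vanishes at the Nernst potential and matches the
           Nernst-Planck quadrature oracle away from it", {
  c_in <- 10; c_out <- 140; z <- 1
  v_nernst <- -nephroflux:::RTF * log(c_out / c_in)   # V1 - V2 at equilibrium
  j <- electrodiffusive_flux(1e-5, 1, z, c_in, c_out, -v_nernst)
  expect_lt(abs(j), 1e-10 * abs(electrodiffusive_flux(1e-5, 1, z, c_in,
                                                      c_out, 0)))
  ## quadrature oracle at a physiological driving force
  j_model <- electrodiffusive_flux(2e-5, 0.5, 1, 10, 140, -60)
  j_oracle <- ghk_oracle(2e-5, 0.5, 1, 10, 140, -60)
  expect_equal(j_model, j_oracle, tolerance = 1e-6)
  ## and for an anion
  j_model2 <- electrodiffusive_flux(1e-5, 1, -1, 110, 30, 15)
  j_oracle2 <- ghk_oracle(1e-5, 1, -1, 110, 30, 15)
  expect_equal(j_model2, j_oracle2, tolerance = 1e-6)
})

test_that("paracellular flux is antisymmetric in the gradient and adds
           solvent drag", {
  expect_equal(paracellular_flux(1e-4, 1, 1, 100, 100, 0, 0.7, 0), 0)
  fwd <- paracellular_flux(1e-4, 1, 0, 120, 80, 0, 0.7, 0)
  rev <- paracellular_flux(1e-4, 1, 0, 80, 120, 0, 0.7, 0)
  expect_equal(fwd, -rev)
  with_drag <- paracellular_flux(1e-4, 1, 0, 100, 100, 0, 0.7, 10)
  expect_equal(with_drag, (1 - 0.7) * 100 * 10)
})

test_that("Na/K pump obeys 3:2 stoichiometry, vanishes without substrate,
           and saturates at its maximal rate", {
  expect_equal(nak_atpase_flux(0, 5, 1e5)$Na, 0)
  for (na in c(2, 10, 30, 80)) {
    j <- nak_atpase_flux(na, 5, 1e5)
    expect_equal(j$K, -2 / 3 * j$Na)
  }
  ## saturating cytosolic Na and external K approach the activity
  j_inf <- nak_atpase_flux(1e6, 1e6, 1e5)$Na
  expect_equal(j_inf / 1e5, 1, tolerance = 1e-4)
})

test_that("SGLT flux is zero at electrochemical equilibrium, keeps exact
           stoichiometry, and scales sublinearly with activity", {
  ## equilibrium: (Na_l/Na_c)^n (G_l/G_c) exp(n u) = 1
  u <- 40 / nephroflux:::RTF
  gl <- 5 * (20 / 140)^1 * exp(-u)     # SGLT2, n = 1
  j <- sglt_flux(140, gl, 20, 5, 40, "SGLT2", 1000)
  expect_lt(abs(j$glucose), 1e-12 * 1000)
  ## SGLT1 carries 2 Na per glucose at every state
  set.seed(1)
  for (i in 1:20) {
    st <- sglt_flux(runif(1, 50, 150), runif(1, 0.01, 20),
                    runif(1, 5, 40), runif(1, 0.5, 20),
                    runif(1, -20, 80), "SGLT1", 500)
    expect_equal(st$Na, 2 * st$glucose)
  }
  ## 90% inhibition scales flux by <= 0.1 at every grid state (Vmax law)
  grid <- expand.grid(nal = c(60, 140), gl = c(0.5, 5, 20),
                      nac = c(10, 30), gc = c(1, 8), dv = c(0, 60))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    j1 <- sglt_flux(g$nal, g$gl, g$nac, g$gc, g$dv, "SGLT2", 1000)$glucose
    j2 <- sglt_flux(g$nal, g$gl, g$nac, g$gc, g$dv, "SGLT2", 100)$glucose
    expect_equal(j2, 0.1 * j1, tolerance = 1e-12)
  }
})

test_that("GLUT flux follows the gradient with half-saturation at Km", {
  expect_equal(glut_flux(8, 8, "GLUT2", 1000), 0)
  expect_equal(glut_flux(10, 2, "GLUT1", 1000),
               -glut_flux(2, 10, "GLUT1", 1000))
  ## closed-form kinetic check: with zero trans concentration the flux is
  ## half-maximal at the isoform Km
  expect_equal(glut_flux(17, 0, "GLUT2", 1000), 500, tolerance = 1e-12)
  expect_equal(glut_flux(2, 0, "GLUT1", 1000), 500, tolerance = 1e-12)
})

test_that("electroneutral cotransport vanishes at mass-action equilibrium,
           keeps stoichiometric ratios, and its sign follows the affinity", {
  c_cell <- c(Na = 15, K = 130, Cl = 25)
  ## equilibrium state: ratio 1 by construction
  c_eq <- c(Na = 15 * 2, K = 130 / 4, Cl = 25 * sqrt(2))
  j <- cotransport_flux(c(Na = 1, K = 1, Cl = 2), c_eq, c_cell, 1000)
  expect_lt(max(abs(j)), 1e-10)
  set.seed(7)
  for (i in 1:25) {
    lum <- c(Na = runif(1, 20, 250), K = runif(1, 0.5, 10),
             Cl = runif(1, 10, 250))
    j <- cotransport_flux(c(Na = 1, K = 1, Cl = 2), lum, c_cell, 1000)
    expect_equal(j[["Cl"]], 2 * j[["Na"]])
    expect_equal(j[["K"]], j[["Na"]])
    aff <- log(lum[["Na"]] / 15) + log(lum[["K"]] / 130) +
      2 * log(lum[["Cl"]] / 25)
    expect_equal(sign(j[["Na"]]), sign(aff))
  }
  expect_error(cotransport_flux(c(Na = 1, K = 1), c_cell, c_cell, 1),
               "electroneutral")
})

test_that("NHE3 is symmetric-state silent, linear in activity, and its
           direction matches the occupancy affinity", {
  j0 <- nhe3_flux(140, 140, 6e-5, 6e-5, 0.5, 0.5, 1e5)
  expect_lt(abs(j0$Na), 1e-10)
  j1 <- nhe3_flux(140, 20, 6e-5, 9e-5, 0.3, 0.7, 1e5)
  j2 <- nhe3_flux(140, 20, 6e-5, 9e-5, 0.3, 0.7, 2e5)
  expect_equal(j2$Na, 2 * j1$Na)
  expect_equal(j1$Na, j1$H + j1$NH4)   # exchange stoichiometry
  ## sign oracle: independent occupancy computation
  occ <- function(h, nh4, kh = 2.5e-4, kn = 2)
    (h / kh + nh4 / kn) / (1 + h / kh + nh4 / kn)
  set.seed(11)
  for (i in 1:25) {
    nal <- runif(1, 30, 200); nac <- runif(1, 5, 50)
    hl <- 10^runif(1, -5, -3.3); hc <- 10^runif(1, -5, -3.3)
    nl <- runif(1, 0.01, 2); nc <- runif(1, 0.01, 2)
    j <- nhe3_flux(nal, nac, hl, hc, nl, nc, 1e5)
    drive <- nal / (nal + 30) * occ(hc, nc) - nac / (nac + 30) * occ(hl, nl)
    expect_equal(sign(j$Na), sign(drive))
  }
})

test_that("torque multiplier is 1 at reference, inert at zero sensitivity,
           clamped, and strictly increasing in flow", {
  expect_equal(torque_factor(30, 1e-3, 30, 1e-3, s = 1.3), 1)
  expect_equal(torque_factor(90, 1e-3, 30, 1e-3, s = 0), 1)
  expect_equal(torque_factor(1e4, 1e-3, 30, 1e-3, s = 1.3), 2.5)
  expect_equal(torque_factor(0, 1e-3, 30, 1e-3, s = 1.3), 0.5)
  flows <- seq(20, 60, by = 5)
  tf <- torque_factor(flows, 1e-3, 30, 1e-3, s = 1)
  expect_true(all(diff(tf) > 0))
})
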