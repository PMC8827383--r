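# Epithelial node system: manufactured equilibria, Jacobian structure,
# fixed-point behaviour and multistart robustness.

## a sealed epithelium: no permeabilities, no transporters
sealed_comp <- function() {
  seg <- list(length = 0.1, diameter = 2e-3, n_nodes = 2, depth = c(0, 0),
              apical = list(pf = 0, perm = list()),
              basolateral = list(pf = 0, perm = list()),
              tj = list(pf = 0, perm = list()),
              transporters = list(), ca_cell = 0)
  nephroflux:::prepare_segment(seg, "sealed")
}

test_that("a manufactured all-fluxes-zero state has vanishing residuals", {
  bath <- test_plasma()
  comp <- sealed_comp()
  lum <- list(conc = bath, p = 5)
  inter <- list(conc = bath, p = 5)
  x <- nephroflux:::pack_node(bath, 1e-12, 0, 0)
  r <- assemble_node_residuals(x, lum, inter, comp)
  expect_lt(max(abs(r)), 1e-12)
})

test_that("membrane fluxes are homogeneous of degree one in the membrane
           areas at a fixed state", {
  toy <- make_pump_leak_toy()
  st <- nephroflux:::unpack_node(
    nephroflux:::cold_cell_guess(toy$lumen, toy$comp))
  f1 <- nephroflux:::node_fluxes(toy$lumen$conc, st$conc, toy$inter$conc,
                                 st$vl, st$vc, 5, 5, toy$comp,
                                 c_imp = st$c_imp)
  ## rebuild the compiled segment with doubled area amplifications
  seg2 <- list(length = 0.1, diameter = 2e-3, n_nodes = 2, depth = c(0, 0),
               area_apical = 2, area_basolateral = 2,
               cell_volume = 6e-6, ca_cell = 0,
               apical = list(pf = 0, perm = list()),
               basolateral = list(pf = 0.05,
                                  perm = list(Na = 2e-6, K = 2e-5)),
               tj = list(pf = 0, sigma_default = 1, perm = list()),
               transporters = list(
                 list(id = "NaK_ATPase", membrane = "basolateral",
                      activity = 4e4)))
  comp2 <- nephroflux:::prepare_segment(seg2, "pump_leak_x2")
  f2 <- nephroflux:::node_fluxes(toy$lumen$conc, st$conc, toy$inter$conc,
                                 st$vl, st$vc, 5, 5, comp2,
                                 c_imp = st$c_imp)
  expect_equal(f2$bl, 2 * f1$bl, tolerance = 1e-12)
  expect_equal(f2$jw_bl, 2 * f1$jw_bl, tolerance = 1e-12)
})

test_that("the fused barrier evaluation agrees with the public flux laws", {
  cat_ <- test_catalogue()
  params <- build_baseline("male", cat_)
  comp <- nephroflux:::prepare_segment(params$segments$PCT, "PCT")
  comp$transporters <- list()       # compare the passive pathways only
  pl <- test_plasma()
  cell <- pl * exp(seq(-0.3, 0.3, length.out = 15))
  inter <- pl * exp(seq(0.2, -0.2, length.out = 15))
  vl <- -1.8; vc <- -68
  fl <- nephroflux:::node_fluxes(pl, cell, inter, vl, vc, 13, 5, comp,
                                 c_imp = 60)
  z <- solute_table()$valence
  expect_equal(as.numeric(fl$ap),
               as.numeric(electrodiffusive_flux(comp$apical$perm,
                                                comp$apical$area, z,
                                                pl, cell, vl - vc)),
               tolerance = 1e-12)
  expect_equal(as.numeric(fl$bl),
               as.numeric(electrodiffusive_flux(comp$basolateral$perm,
                                                comp$basolateral$area, z,
                                                cell, inter, vc)),
               tolerance = 1e-12)
  expect_equal(as.numeric(fl$tj),
               as.numeric(paracellular_flux(comp$tj$perm, comp$tj$area, z,
                                            pl, inter, vl, comp$tj$sigma,
                                            fl$jw_tj)),
               tolerance = 1e-12)
})

test_that("the finite-difference Jacobian has the expected sparsity for a
           pump-leak cell", {
  toy <- make_pump_leak_toy()
  scales <- nephroflux:::node_scales(toy$lumen, toy$inter, toy$comp, 1)
  fn <- function(x) assemble_node_residuals(x, toy$lumen, toy$inter,
                                            toy$comp, scales = scales)
  sol <- solve_node(toy$lumen, toy$inter, toy$comp)
  J <- nephroflux:::fd_jacobian(fn, sol$x)
  ## urea is disconnected: perturbing cytosolic urea (unknown 14) touches
  ## only its own pin (residual 4), electroneutrality is charge-blind to
  ## it, and the water balance through osmolality
  touched <- which(abs(J[, nephroflux:::I_UREA]) > 1e-6)
  expect_true(all(touched %in% c(4L, 17L)))
  ## perturbing cell Na (unknown 1) must touch the Na balance
  expect_gt(abs(J[1, nephroflux:::I_NA]), 1e-4)
})

test_that("re-solving from a converged solution is an immediate fixed
           point and the node tolerance is reached", {
  toy <- make_pump_leak_toy()
  sol <- solve_node(toy$lumen, toy$inter, toy$comp)
  expect_lt(sol$residual_norm, 1e-10)
  again <- solve_node(toy$lumen, toy$inter, toy$comp, x0 = sol$x,
                      jac = sol$jac)
  expect_lte(again$iterations, 1L)
})

test_that("the node solution is invariant to the initial guess", {
  toy <- make_pump_leak_toy()
  s1 <- solve_node(toy$lumen, toy$inter, toy$comp)
  g2 <- nephroflux:::cold_cell_guess(toy$lumen, toy$comp)
  g2[[17]] <- -30          # different starting potential
  g2[[1]] <- log(60)       # and cytosolic Na
  s2 <- solve_node(toy$lumen, toy$inter, toy$comp, x0 = g2)
  expect_equal(s1$state$conc, s2$state$conc, tolerance = 1e-8)
  expect_equal(s1$state$vc, s2$state$vc, tolerance = 1e-6)
})

test_that("the Jacobian at the solution is consistent under a different
           difference step", {
  toy <- make_pump_leak_toy()
  sol <- solve_node(toy$lumen, toy$inter, toy$comp)
  scales <- nephroflux:::node_scales(toy$lumen, toy$inter, toy$comp, 1)
  fn <- function(x) assemble_node_residuals(x, toy$lumen, toy$inter,
                                            toy$comp, scales = scales)
  J1 <- nephroflux:::fd_jacobian(fn, sol$x)
  ## central differences with a 30x larger step as the independent check
  n <- length(sol$x)
  J2 <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 3e-6 * (1 + abs(sol$x[[j]]))
    xp <- sol$x; xp[[j]] <- xp[[j]] + h
    xm <- sol$x; xm[[j]] <- xm[[j]] - h
    J2[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  big <- abs(J2) > 1e-3
  expect_lt(max(abs(J1[big] - J2[big]) / abs(J2[big])), 1e-3)
})

test_that("the cell electroneutrality invariant holds at every converged
           node", {
  toy <- make_pump_leak_toy()
  sol <- solve_node(toy$lumen, toy$inter, toy$comp)
  z <- solute_table()$valence
  q <- sum(z * sol$state$conc) - sol$state$c_imp
  expect_lt(abs(q) / sum(abs(z * sol$state$conc)), 1e-9)
})
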