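# Axial marching: conservation, grid convergence, degenerate limits and
# the conservation audit.

## a fully sealed tube: no permeability at all
sealed_tube <- function(n = 10) {
  seg <- list(length = 0.5, diameter = 2e-3, n_nodes = n, depth = c(0, 0),
              epithelium = "passive",
              tj = list(pf = 0, sigma_default = 1, perm = list()))
  nephroflux:::prepare_segment(seg, "sealed_tube")
}

const_inter <- function(conc, p = 5) function(d) list(conc = conc, p = p)

test_that("a zero-permeability, zero-transport segment returns its inflow
           unchanged", {
  pl <- test_plasma()
  pr <- solve_segment(sealed_tube(), list(flow = 40, conc = pl, p = 10),
                      const_inter(pl))
  expect_equal(pr$outflow$flow, 40)
  expect_equal(pr$outflow$conc, pl, tolerance = 1e-12)
  expect_lt(max(abs(pr$transmural)), 1e-12)
})

test_that("the conservation audit closes every balance on a solved
           proximal segment and flags an injected fault", {
  cat_ <- test_catalogue()
  params <- build_baseline("male", cat_)
  inter_at <- nephroflux:::interstitium_fun(params)
  comp <- nephroflux:::prepare_segment(params$segments$PCT, "PCT")
  pl <- test_plasma()
  pr <- solve_segment(comp, list(flow = 100, conc = pl, p = 13), inter_at,
                      torque_s = 0)
  aud <- audit_conservation(pr, strict = TRUE)
  expect_lt(max(aud$rel_error), 1e-6)
  expect_equal(nrow(aud), 16L)   # 15 solutes + water
  ## corrupting one recorded flux must break exactly that balance
  bad <- pr
  bad$transmural[["K"]] <- bad$transmural[["K"]] * 1.05
  aud2 <- audit_conservation(bad)
  broken <- aud2$balance[aud2$rel_error > 1e-6]
  expect_identical(broken, "K")
  expect_error(audit_conservation(bad, strict = TRUE), "K")
})

test_that("halving the grid spacing changes segment outflow by less than
           0.1 percent", {
  cat_ <- test_catalogue()
  params <- build_baseline("male", cat_)
  inter_at <- nephroflux:::interstitium_fun(params)
  comp <- nephroflux:::prepare_segment(params$segments$PCT, "PCT")
  pl <- test_plasma()
  base <- solve_segment(comp, list(flow = 100, conc = pl, p = 13),
                        inter_at, torque_s = 0)
  fine <- solve_segment(comp, list(flow = 100, conc = pl, p = 13),
                        inter_at, torque_s = 0,
                        n_nodes = 2L * comp$n_nodes - 1L)
  expect_lt(abs(fine$outflow$flow - base$outflow$flow) /
              base$outflow$flow, 1e-3)
  major <- c("Na", "K", "Cl", "HCO3", "urea", "glucose")
  expect_lt(max(abs(fine$outflow$conc[major] - base$outflow$conc[major]) /
                  base$outflow$conc[major]), 1e-3)
})

test_that("a water-impermeable tube with pure NaCl removal concentrates
           urea monotonically", {
  pl <- test_plasma()
  bath <- pl
  bath[["Na"]] <- 40; bath[["Cl"]] <- 13    # steep outward NaCl gradient
  seg <- list(length = 0.5, diameter = 2e-3, n_nodes = 12, depth = c(0, 0),
              epithelium = "passive",
              tj = list(pf = 0, sigma_default = 1,
                        perm = list(Na = 2e-5, Cl = 2e-5)))
  comp <- nephroflux:::prepare_segment(seg, "nacl_tube")
  pr <- solve_segment(comp, list(flow = 20, conc = pl, p = 10),
                      const_inter(bath))
  expect_equal(pr$outflow$flow, 20)            # no water pathway
  expect_true(all(diff(pr$conc[, "urea"]) > -1e-12))
  expect_gt(pr$transmural[["Na"]], 0)
})

test_that("a tube losing its luminal fluid raises the run-dry condition", {
  pl <- test_plasma()
  bath <- pl
  bath[["urea"]] <- pl[["urea"]] + 600       # strongly hypertonic bath
  seg <- list(length = 3, diameter = 1e-3, n_nodes = 12, depth = c(0, 0),
              epithelium = "passive",
              tj = list(pf = 0.5, sigma_default = 1, perm = list()))
  comp <- nephroflux:::prepare_segment(seg, "dry_tube")
  expect_error(
    solve_segment(comp, list(flow = 0.25, conc = pl, p = 10),
                  const_inter(bath)),
    class = "nephroflux_run_dry")
})
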