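# Catalogue, baseline construction and the scenario transformation layers.

test_that("the catalogue loads, validates, and registers exactly the 15
           solutes with fixed valences", {
  cat_ <- test_catalogue()
  expect_s3_class(cat_, "nephroflux_catalogue")
  tab <- solute_table()
  expect_equal(nrow(tab), 15L)
  expect_setequal(tab$name, c("Na", "K", "Cl", "HCO3", "H2CO3", "CO2",
                              "NH3", "NH4", "H2PO4", "HPO4", "H", "HCO2",
                              "H2CO2", "urea", "glucose"))
  expect_equal(tab$valence[tab$name == "glucose"], 0L)
  expect_equal(tab$valence[tab$name == "Na"], 1L)
  expect_equal(tab$valence[tab$name == "HPO4"], -2L)
  fr <- vapply(cat_$nephron_classes, `[[`, 0, "fraction")
  expect_equal(sum(fr), 1)
  expect_equal(fr[[1]], 0.85)
  expect_equal(sum(fr[-1]), 0.15)
})

test_that("interstitial osmolality is non-decreasing from cortex to
           papilla", {
  osm <- nephroflux:::interstitial_osmolalities(test_catalogue())
  expect_true(all(diff(osm) >= 0))
})

test_that("the female baseline applies the sex-difference factors exactly
           and is a pure function", {
  cat_ <- test_catalogue()
  m <- build_baseline("male", cat_)
  f <- build_baseline("female", cat_)
  expect_equal(f$segments$PCT$basolateral$pf / m$segments$PCT$basolateral$pf,
               0.64)
  expect_equal(f$segments$IMCD$apical$pf / m$segments$IMCD$apical$pf, 2)
  expect_equal(f$segments$PCT$tj$perm$Na / m$segments$PCT$tj$perm$Na, 0.5)
  expect_equal(f$segments$S3$tj$perm$Cl / m$segments$S3$tj$perm$Cl, 0.4)
  expect_equal(f$segments$CNT$apical$perm$Na /
                 m$segments$CNT$apical$perm$Na, 1.4)
  expect_equal(f$segments$mTAL$transporters$NKCC2$activity /
                 m$segments$mTAL$transporters$NKCC2$activity, 1.2)
  expect_equal(f$segments$DCT$transporters$NaK_ATPase$activity /
                 m$segments$DCT$transporters$NaK_ATPase$activity, 1.2)
  ## geometry identical between sexes
  expect_equal(f$segments$PCT$length, m$segments$PCT$length)
  expect_equal(f$segments$mTAL$diameter, m$segments$mTAL$diameter)
  ## determinism: building twice yields identical parameter sets
  expect_identical(build_baseline("male", cat_), m)
  expect_error(build_baseline("other", cat_), "unknown sex")
})

test_that("the diabetes layer applies Table-style regulation, hypertrophy,
           plasma glucose and the GFR scale", {
  cat_ <- test_catalogue()
  m <- build_baseline("male", cat_)
  sev_m <- apply_diabetes(m, "severe")
  expect_equal(sev_m$segments$PCT$transporters$SGLT2$activity /
                 m$segments$PCT$transporters$SGLT2$activity, 1.38)
  expect_equal(sev_m$segments$PCT$transporters$GLUT2$activity /
                 m$segments$PCT$transporters$GLUT2$activity, 1.50)
  expect_equal(sev_m$segments$PCT$length / m$segments$PCT$length, 1.28)
  expect_equal(sev_m$segments$DCT$diameter / m$segments$DCT$diameter, 1.42)
  expect_equal(sev_m$segments$DCT$length / m$segments$DCT$length, 1.07)
  expect_equal(sev_m$plasma_glucose, 20)
  expect_equal(sev_m$gfr_scale, 1.24)

  f <- build_baseline("female", cat_)
  sev_f <- apply_diabetes(f, "severe")
  expect_equal(sev_f$segments$PCT$transporters$SGLT2$activity /
                 f$segments$PCT$transporters$SGLT2$activity, 1.28)
  expect_equal(sev_f$segments$mTAL$transporters$NaK_ATPase$activity /
                 f$segments$mTAL$transporters$NaK_ATPase$activity, 1.10)
  ## female-severe IMCD pump: split axial profile, +50% along the first
  ## two thirds and +150% along the rest
  prof <- sev_f$segments$IMCD$transporters$NaK_ATPase$profile
  expect_equal(prof$breaks, 2 / 3)
  expect_equal(prof$values, c(1.5, 2.5))
  ## male severe IMCD stays uniform
  expect_null(sev_m$segments$IMCD$transporters$NaK_ATPase$profile)
  expect_equal(sev_m$segments$IMCD$transporters$NaK_ATPase$activity /
                 m$segments$IMCD$transporters$NaK_ATPase$activity, 2.5)

  mod_f <- apply_diabetes(f, "moderate")
  expect_equal(mod_f$segments$mTAL$transporters$NKCC2$activity /
                 f$segments$mTAL$transporters$NKCC2$activity, 1.10)
  expect_equal(mod_f$segments$CCD$apical$pf / f$segments$CCD$apical$pf,
               1.55)
  expect_equal(mod_f$plasma_glucose, 8.6)
  expect_warning(apply_diabetes(m, "none"), "identity")
})

test_that("SGLT2 inhibition knocks activity down 90%, adjusts filtration,
           and flags double application", {
  cat_ <- test_catalogue()
  m <- build_baseline("male", cat_)
  mi <- apply_sglt2i(m)
  expect_equal(mi$segments$PCT$transporters$SGLT2$activity /
                 m$segments$PCT$transporters$SGLT2$activity, 0.1)
  expect_equal(mi$nephron_classes$sngfr, m$nephron_classes$sngfr * 0.97)
  expect_equal(mi$plasma_glucose, m$plasma_glucose)
  ## on a diabetic kidney the GFR is normalised to 105 mL/min exactly
  sev <- apply_diabetes(m, "severe")
  sev_i <- apply_sglt2i(sev)
  expect_equal(nephroflux:::total_gfr_df(sev_i$nephron_classes, 1e6) *
                 sev_i$gfr_scale, 105)
  ## 1.38 * baseline knocked down to 0.138 * baseline
  expect_equal(sev_i$segments$PCT$transporters$SGLT2$activity /
                 m$segments$PCT$transporters$SGLT2$activity, 0.138)
  expect_warning(again <- apply_sglt2i(mi), "idempotence")
  expect_identical(again, mi)
})

test_that("total GFR and filtered loads match the analytic values", {
  cat_ <- test_catalogue()
  m <- build_baseline("male", cat_)
  gfr <- total_gfr(m$nephron_classes, m$n_nephrons)
  expect_equal(signif(gfr, 3), 105)   # 0.85*100 + 0.15*133 per nephron
  expect_equal(total_gfr(data.frame(fraction = c(0.3, 0.7),
                                    sngfr = c(0, 0))), 0)
  expect_equal(total_gfr(data.frame(fraction = c(0.2, 0.8),
                                    sngfr = c(100, 100))), 100)
  expect_error(total_gfr(data.frame(fraction = 1, sngfr = -5)), "negative")
  expect_equal(round(filtered_load(105, 20), 1), 3.0)
  expect_equal(round(filtered_load(105, 8.6), 1), 1.3)
  expect_equal(filtered_load(0, 20), 0)
})

test_that("all twelve canonical scenario parameter sets are valid and the
           transform chain is reproducible", {
  cat_ <- test_catalogue()
  for (sex in c("female", "male"))
    for (dz in c("none", "moderate", "severe"))
      for (drug in c(FALSE, TRUE)) {
        cfg <- scenario_config(sex, dz, drug)
        p1 <- build_scenario_params(cfg, cat_)
        p2 <- build_scenario_params(cfg, cat_)
        expect_identical(p1, p2)
        for (s in names(p1$segments)) {
          seg <- p1$segments[[s]]
          for (tr in seg$transporters %||% list())
            expect_gte(tr$activity, 0)
          for (b in c("apical", "basolateral", "tj")) {
            bb <- seg[[b]]
            if (is.null(bb)) next
            expect_true(all(unlist(bb$perm) >= 0))
            expect_gte(bb$pf %||% 0, 0)
          }
        }
      }
})

test_that("dotted-path overrides reach nested parameters and reject
           unknown components", {
  cat_ <- test_catalogue()
  m <- build_baseline("male", cat_)
  m2 <- set_param(m, "segments.mTAL.transporters.NKCC2.activity", 123)
  expect_equal(m2$segments$mTAL$transporters$NKCC2$activity, 123)
  expect_error(set_param(m, "segments.NOPE.transporters.x.activity", 1),
               "unknown parameter path")
  cfg <- scenario_config("male", overrides = list(
    "segments.PCT.transporters.SGLT2.activity" = 999))
  p <- build_scenario_params(cfg, cat_)
  expect_equal(p$segments$PCT$transporters$SGLT2$activity, 999)
})
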