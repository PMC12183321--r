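test_that("disposition index integrates the early secretion over SSPG", {
  isr <- tibble::tibble(time = seq(0, 165, by = 15), isr = rep(2, 12))
  expect_equal(disposition_index(isr, 120), 0.5)
  # linear in the secretion rate
  isr2 <- isr
  isr2$isr <- isr$isr * 2
  expect_equal(disposition_index(isr2, 120), 1.0)
  # decreasing in SSPG at fixed secretion
  expect_lt(disposition_index(isr, 200), disposition_index(isr, 100))
  expect_error(disposition_index(isr, 0), "positive")
  expect_error(disposition_index(isr, -5), "positive")
})

test_that("incretin effect is the relative OGTT/IIGI C-peptide AUC gap", {
  grid <- cpeptide_grid()
  ogtt <- analyte_series("a", "OGTT", "cpeptide", grid, rep(10, 7))
  iigi <- analyte_series("a", "IIGI", "cpeptide", grid, rep(10, 7))
  expect_equal(incretin_effect(ogtt, iigi), 0)
  zero <- analyte_series("a", "IIGI", "cpeptide", grid, rep(0, 7))
  expect_equal(incretin_effect(ogtt, zero), 100)
  # AUC 1800 vs 1080 is the 200-vs-120 ratio: 40%
  iigi2 <- analyte_series("a", "IIGI", "cpeptide", grid, rep(6, 7))
  expect_equal(incretin_effect(ogtt, iigi2), 40)
})

test_that("incretin effect is scale invariant and bounded above by 100", {
  grid <- cpeptide_grid()
  withr::with_seed(11, {
    for (i in 1:20) {
      vo <- runif(7, 1, 20)
      vi <- runif(7, 0, 20)
      ogtt <- analyte_series("a", "OGTT", "cpeptide", grid, vo)
      iigi <- analyte_series("a", "IIGI", "cpeptide", grid, vi)
      ie <- incretin_effect(ogtt, iigi)
      expect_lte(ie, 100)
      c <- runif(1, 0.1, 10)
      sc <- incretin_effect(
        analyte_series("a", "OGTT", "cpeptide", grid, c * vo),
        analyte_series("a", "IIGI", "cpeptide", grid, c * vi))
      expect_equal(sc, ie, tolerance = 1e-12)
    }
  })
})

test_that("incretin effect rejects mismatched grids and zero OGTT AUC", {
  ogtt <- analyte_series("a", "OGTT", "cpeptide", cpeptide_grid(),
                         rep(10, 7))
  short <- analyte_series("a", "IIGI", "cpeptide", c(0, 30, 60), rep(5, 3))
  expect_error(incretin_effect(ogtt, short), "same grid")
  zero_o <- analyte_series("a", "OGTT", "cpeptide", cpeptide_grid(),
                           rep(0, 7))
  zero_i <- analyte_series("a", "IIGI", "cpeptide", cpeptide_grid(),
                           rep(0, 7))
  expect_error(incretin_effect(zero_o, zero_i), "undefined")
})

test_that("Deurenberg body fat matches hand arithmetic", {
  expect_equal(body_fat_percent(25, 50, 0), 36.1, tolerance = 1e-12)
  expect_equal(body_fat_percent(25, 50, 1), 25.3, tolerance = 1e-12)
  expect_equal(body_fat_percent(30, 40, 1) - body_fat_percent(30, 40, 0),
               -10.8, tolerance = 1e-12)
  expect_error(body_fat_percent(25, 50, 2), "sex")
})

test_that("hepatic IR index matches its regression formula", {
  expect_equal(hepatic_ir_index(1, 1, 1, 1), -0.091, tolerance = 1e-12)
  expect_equal(hepatic_ir_index(9000, 32, 60, 26),
               -0.091 + 0.4 * log(9000) + 0.346 * log(32) -
                 0.408 * log(60) + 0.435 * log(26), tolerance = 1e-12)
  expect_gt(hepatic_ir_index(10000, 32, 60, 26),
            hepatic_ir_index(9000, 32, 60, 26))
  expect_lt(hepatic_ir_index(9000, 32, 80, 26),
            hepatic_ir_index(9000, 32, 60, 26))
  expect_error(hepatic_ir_index(0, 32, 60, 26), "positive")
})

test_that("fasting surrogates match their defining arithmetic", {
  s <- surrogate_markers(90, 4.5)
  expect_equal(s$homa_ir, 1.0)
  expect_equal(s$homa_b, 60)
  expect_true(is.na(surrogate_markers(63, 4.5)$homa_b))
  # HOMA-IR increasing in both inputs
  expect_gt(surrogate_markers(100, 4.5)$homa_ir, s$homa_ir)
  expect_gt(surrogate_markers(90, 6)$homa_ir, s$homa_ir)
  # constant OGTT series collapse Matsuda to 10000/(fpg*fpi)
  grid <- cpeptide_grid()
  glu <- analyte_series("a", "OGTT", "glucose", grid, rep(90, 7))
  ins <- analyte_series("a", "OGTT", "insulin", grid, rep(4.5, 7))
  expect_equal(surrogate_markers(90, 4.5, glu, ins)$matsuda,
               10000 / (90 * 4.5), tolerance = 1e-12)
})

test_that("polygenic score sums dosages and mean-imputes missing variants", {
  w <- c(v1 = 0.5, v2 = 0.5, v3 = 0.5)
  d <- c(v1 = 1, v2 = 1, v3 = 1)
  expect_equal(polygenic_score(d, w), 1.5)
  # a missing variant with weight 2 and frequency 0.5 contributes 2
  w2 <- c(v1 = 1, v2 = 2)
  expect_equal(polygenic_score(c(v1 = 1), w2, c(v2 = 0.5)), 1 + 2)
  expect_warning(out <- polygenic_score(d, numeric(0)), "empty")
  expect_equal(out, 0)
  expect_error(polygenic_score(c(v1 = 1), w2, c(v9 = 0.5)), "missing")
})

test_that("threshold labels follow the cohort cut-points", {
  p <- tibble::tibble(participant_id = c("s07", "b", "c"),
                      sspg = c(60, 120, 150),
                      di = c(2.58, 1.58, 0.9),
                      ie_pct = c(63.7, 30, 70),
                      hepatic_ir = c(4.3, 5.0, 3.5))
  lab <- classify_measures(p)
  expect_equal(lab$muscle_ir, c(FALSE, TRUE, TRUE))   # IR iff SSPG >= 120
  expect_equal(lab$beta_dysfunction, c(FALSE, FALSE, TRUE)) # 1.58 is normal
  expect_equal(lab$ie_class, c("intermediate", "dysfunction", "normal"))
  expect_equal(lab$di_class, c("normal", "intermediate", "dysfunction"))
  expect_equal(lab$hepatic_class,
               c("intermediate", "resistant", "sensitive"))
})
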