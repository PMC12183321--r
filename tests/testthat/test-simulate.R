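test_that("covariate sampling is seed-deterministic and validated", {
  a <- sample_covariates(50, seed = 1)
  b <- sample_covariates(50, seed = 1)
  expect_identical(a, b)
  c <- sample_covariates(50, seed = 2)
  expect_false(identical(a$bmi, c$bmi))
  expect_error(sample_covariates(0), "positive count")
  # growing the cohort never reshuffles earlier participants
  big <- sample_covariates(60, seed = 1)
  expect_identical(a, big[1:50, ])
})

test_that("covariate marginals match the configured cohort profile", {
  x <- sample_covariates(10000, seed = 2)
  expect_lt(abs(mean(x$bmi) - 26), 0.2)
  expect_true(all(x$bmi >= 23 & x$bmi <= 40))
  # the 30-70 y eligibility window is asymmetric around 55, so the mean is
  # the closed-form truncated-normal mean (~53.8 y), not the location 55
  a <- (30 - 55) / 10
  b <- (70 - 55) / 10
  age_expected <- 55 + 10 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(x$age) - age_expected), 0.4)
  expect_true(all(x$age >= 30 & x$age <= 70))
  expect_lt(abs(mean(x$fasting_insulin) - 10), 0.5)
  expect_true(all(x$hdl > 20))
  expect_lt(abs(mean(x$sex) - 0.5), 0.03)
})

test_that("latent states recover the configured copula correlations", {
  cfg <- simulation_config(n_participants = 5000, seed = 3)
  covs <- sample_covariates(5000, 3)
  lat <- sample_latent_state(covs, cfg)
  expect_lt(abs(cor(lat$z_muscle, lat$z_hepatic) - 0.7), 0.05)
  expect_lt(abs(cor(lat$z_muscle, lat$z_beta) - 0.6), 0.05)
  # on the physiologic scales the association survives the transforms
  expect_lt(abs(cor(lat$sspg, lat$hep_ir) - 0.7), 0.05)
  expect_true(all(lat$sspg >= 40 & lat$sspg <= 300))
  expect_true(all(lat$ie_frac >= 0 & lat$ie_frac <= 1))
  expect_true(all(lat$beta_capacity > 0))
  expect_identical(lat, sample_latent_state(covs, cfg))
})

test_that("an identity copula gives uncorrelated latents", {
  cfg <- simulation_config(n_participants = 5000, seed = 4,
                           latent_correlations = diag(4))
  lat <- sample_latent_state(sample_covariates(5000, 4), cfg)
  z <- as.matrix(lat[, c("z_muscle", "z_beta", "z_incretin", "z_hepatic")])
  off <- cor(z)[upper.tri(diag(4))]
  expect_true(all(abs(off) < 0.05))
})

test_that("a non-positive-definite correlation matrix is rejected", {
  bad <- matrix(0.99, 4, 4)
  bad[1, 2] <- bad[2, 1] <- -0.99
  diag(bad) <- 1
  expect_error(simulation_config(latent_correlations = bad),
               "positive definite")
  expect_error(simulation_config(plasma_noise_sd = -1), "non-negative")
})

test_that("glucose curves respond to the programmed latent effects", {
  cfg <- simulation_config(seed = 1, plasma_noise_sd = 0)
  state <- function(zm) tibble::tibble(participant_id = "s", z_muscle = zm,
                                       z_beta = 0, z_incretin = 0,
                                       z_hepatic = 0)
  hi <- simulate_ogtt_glucose(state(2), seed = 9, config = cfg)
  lo <- simulate_ogtt_glucose(state(-2), seed = 9, config = cfg)
  expect_gt(trapz_auc(hi$times, hi$values, from = 0, to = 180),
            trapz_auc(lo$times, lo$values, from = 0, to = 180))
  expect_equal(length(hi$times), 16)
  expect_true(hi$canonical)
  expect_true(all(hi$values > 0))
  # zero effect sizes and zero noise: every state gives the same curve
  flat_cfg <- simulation_config(
    seed = 1, plasma_noise_sd = 0,
    effects = list(amp_sspg = 0, amp_beta = 0, amp_incretin = 0,
                   tau_beta = 0, tau_sspg = 0, g0_hepatic = 0))
  c1 <- simulate_ogtt_glucose(state(2), seed = 9, config = flat_cfg)
  c2 <- simulate_ogtt_glucose(state(-2), seed = 9, config = flat_cfg)
  expect_identical(c1$values, c2$values)
  expect_error(simulate_ogtt_glucose(state(0), grid = c(10, 20), seed = 1,
                                     config = cfg), "include t = 0")
})

test_that("the C-peptide pair encodes the incretin fraction exactly", {
  cfg <- simulation_config(seed = 1, plasma_noise_sd = 0,
                           secretion = list(noise_cv = 0))
  kin <- kinetic_parameters("normal")
  state <- function(ie) tibble::tibble(participant_id = "s", z_muscle = 0.5,
                                       z_beta = 0, z_incretin = 0,
                                       z_hepatic = 0, beta_capacity = 1,
                                       ie_frac = ie)
  glu <- simulate_ogtt_glucose(state(0), seed = 3, config = cfg)
  p0 <- simulate_cpeptide_pair(state(0), glu, kin, seed = 3, config = cfg)
  expect_equal(p0$ogtt$values, p0$iigi$values)
  expect_equal(incretin_effect(p0$ogtt, p0$iigi), 0)
  p5 <- simulate_cpeptide_pair(state(0.5), glu, kin, seed = 3, config = cfg)
  expect_equal(incretin_effect(p5$ogtt, p5$iigi), 50, tolerance = 0.04)
  p5b <- simulate_cpeptide_pair(state(0.5), glu, kin, seed = 3, config = cfg)
  expect_identical(p5$ogtt$values, p5b$ogtt$values)
  bad <- glucose_curve("s", c(0, 60, 120, 180), rep(100, 4))
  expect_error(simulate_cpeptide_pair(state(0.5), bad, kin, seed = 3,
                                      config = cfg), "canonical")
})

test_that("noise-free undelayed CGM equals the interpolated plasma curve", {
  cfg0 <- simulation_config(seed = 1, cgm_noise_sd = 0, cgm_lag = 0,
                            cgm_cv_target = 0)
  covs <- sample_covariates(1, 5)
  lat <- sample_latent_state(covs, simulation_config(seed = 5))
  plasma <- simulate_ogtt_glucose(lat[1, ], seed = 6,
                                  config = simulation_config(seed = 5))
  reps <- simulate_cgm(plasma, 2, cfg0, seed = 6)
  keep <- plasma$times >= 0
  interp <- approx(plasma$times[keep], plasma$values[keep],
                   xout = cgm_grid(), rule = 2)$y
  expect_equal(reps[[1]]$values, pmax(interp, 40), tolerance = 1e-10)
  expect_equal(cor(reps[[1]]$values, interp), 1)
  reps2 <- simulate_cgm(plasma, 2, cfg0, seed = 6)
  expect_identical(reps[[2]]$values, reps2[[2]]$values)
  expect_error(simulate_cgm(plasma, 0, cfg0, seed = 1), ">= 1")
})

test_that("programmed effect directions are recovered across a cohort", {
  cfg <- simulation_config(n_participants = 1000, seed = 31)
  covs <- sample_covariates(1000, 31)
  lat <- sample_latent_state(covs, cfg)
  feats <- extract_features_cohort(lapply(seq_len(1000), function(i) {
    simulate_ogtt_glucose(lat[i, ],
                          seed = ogttpheno:::participant_seed(31, i, 2L),
                          config = cfg)
  }))
  di_proxy <- lat$beta_capacity / lat$sspg   # secretion over resistance
  expect_gt(cor(feats$auc, lat$sspg), 0)
  expect_lt(cor(feats$g_120, di_proxy), 0)
  expect_lt(cor(feats$pauc, lat$ie_frac), 0)
})

test_that("cohort generation writes cross-referenced reproducible files", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- simulation_config(n_participants = 50, seed = 8)
  generate_cohort(cfg, dir = dir1)
  generate_cohort(cfg, dir = dir2)
  for (f in c("glucose.csv", "analytes.csv", "covariates.csv",
              "latent_truth.csv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  g <- readr::read_csv(file.path(dir1, "glucose.csv"),
                       show_col_types = FALSE)
  a <- readr::read_csv(file.path(dir1, "analytes.csv"),
                       show_col_types = FALSE)
  cv <- readr::read_csv(file.path(dir1, "covariates.csv"),
                        show_col_types = FALSE)
  lt <- readr::read_csv(file.path(dir1, "latent_truth.csv"),
                        show_col_types = FALSE)
  ids <- sort(unique(cv$participant_id))
  expect_equal(length(ids), 50)
  expect_setequal(unique(g$participant_id), ids)
  expect_setequal(unique(a$participant_id), ids)
  expect_setequal(lt$participant_id, ids)
  manifest <- yaml::read_yaml(file.path(dir1, "manifest.yaml"))
  expect_equal(manifest$seed, 8)
  expect_equal(manifest$n_participants, 50)
})
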