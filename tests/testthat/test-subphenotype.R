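make_profiles <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    participant_id = sprintf("S%02d", seq_len(n)),
    sspg = runif(n, 40, 280),
    di = runif(n, 0.5, 4.5),
    ie_pct = runif(n, 0, 90),
    hepatic_ir = runif(n, 3.5, 5.2)))
}

test_that("deviance scores are cohort Z-scores with DI and IE reversed", {
  p <- tibble::tibble(participant_id = c("a", "b", "c"),
                      sspg = c(1, 2, 3), di = c(1, 2, 3),
                      ie_pct = c(1, 2, 3), hepatic_ir = c(1, 2, 3))
  d <- deviance_scores(p)
  expect_equal(d$muscle_ir, c(-1, 0, 1))
  expect_equal(d$hepatic_ir, c(-1, 0, 1))
  # healthier (higher) DI and IE give *lower* abnormality deviance
  expect_equal(d$beta_cell, c(1, 0, -1))
  expect_equal(d$incretin, c(1, 0, -1))
})

test_that("per-measure deviances have mean 0 and SD 1 in every cohort", {
  for (seed in 1:5) {
    d <- deviance_scores(make_profiles(25, seed))
    for (m in c("muscle_ir", "beta_cell", "incretin", "hepatic_ir")) {
      expect_equal(mean(d[[m]]), 0, tolerance = 1e-12)
      expect_equal(sd(d[[m]]), 1, tolerance = 1e-12)
    }
  }
})

test_that("a participant at the cohort mean gets an all-zero vector", {
  p <- make_profiles(9)
  p[9, c("sspg", "di", "ie_pct", "hepatic_ir")] <-
    as.list(colMeans(p[-9, c("sspg", "di", "ie_pct", "hepatic_ir")]))
  # replace with exact column means of the full cohort by iteration:
  for (m in c("sspg", "di", "ie_pct", "hepatic_ir")) {
    vals <- p[[m]][1:8]
    p[[m]][9] <- mean(vals)             # mean of others == cohort mean
  }
  d <- deviance_scores(p)
  expect_equal(unlist(d[9, -1]), c(muscle_ir = 0, beta_cell = 0,
                                   incretin = 0, hepatic_ir = 0),
               tolerance = 1e-12)
})

test_that("degenerate and incomplete cohorts are handled explicitly", {
  p <- make_profiles(5)
  p$sspg <- 100
  expect_error(deviance_scores(p), "zero variance")
  p2 <- make_profiles(5)
  p2$di[2] <- NA
  expect_message(d <- deviance_scores(p2), "excluded")
  expect_equal(nrow(d), 4)
  expect_error(deviance_scores(make_profiles(1)), "at least 2")
})

test_that("dominance rule splits dominant, co-dominant and unclassified", {
  dv <- function(...) {
    stats::setNames(c(...), c("muscle_ir", "beta_cell", "incretin",
                              "hepatic_ir"))
  }
  a <- assign_dominance(dv(2.0, 0.5, 0.0, -1.0))
  expect_equal(a$category, "dominant")
  expect_equal(a$measures, "muscle_ir")
  b <- assign_dominance(dv(1.0, 0.8, 0.0, -0.5))
  expect_equal(b$category, "co_dominant")
  expect_setequal(b$measures, c("muscle_ir", "beta_cell"))
  c <- assign_dominance(dv(1.0, 0.8, 0.7, 0.0))
  expect_equal(c$category, "unclassified")
  # exact tie at the top is co-dominant; gap exactly delta is dominant
  expect_equal(assign_dominance(dv(1, 1, 0, -1))$category, "co_dominant")
  expect_equal(assign_dominance(dv(1.5, 1.0, 0.4, 0))$category, "dominant")
  expect_error(assign_dominance(dv(NaN, 1, 0, 0)), "finite")
})

test_that("dominance is invariant to measure order and constant shifts", {
  withr::with_seed(42, {
    for (i in 1:25) {
      d <- stats::setNames(rnorm(4), c("muscle_ir", "beta_cell",
                                       "incretin", "hepatic_ir"))
      a <- assign_dominance(d)
      perm <- assign_dominance(d[sample(4)])
      shift <- assign_dominance(d + runif(1, -5, 5))
      expect_equal(perm$category, a$category)
      expect_equal(perm$measures, a$measures)
      expect_equal(shift$category, a$category)
      expect_equal(shift$measures, a$measures)
    }
  })
})

test_that("every participant receives exactly one assignment category", {
  d <- deviance_scores(make_profiles(40, seed = 3))
  a <- assign_dominance_cohort(d)
  expect_equal(nrow(a), 40)
  expect_true(all(a$category %in% c("dominant", "co_dominant",
                                    "unclassified")))
  s <- summarize_dominance(a)
  expect_equal(s$n_dominant + s$n_co_dominant + s$n_unclassified, s$n)
  expect_equal(sum(s$dominant_counts), s$n_dominant)
  expect_equal(sum(s$co_dominant_pairs$n), s$n_co_dominant)
})

test_that("dominance summary counts pairs and physiology axes", {
  a <- tibble::tibble(
    participant_id = sprintf("p%d", 1:5),
    category = c("dominant", "dominant", "co_dominant", "co_dominant",
                 "unclassified"),
    measure_1 = c("muscle_ir", "beta_cell", "hepatic_ir", "beta_cell", NA),
    measure_2 = c(NA, NA, "muscle_ir", "incretin", NA))
  # summarize_dominance expects sorted pair names as assign_dominance emits
  a$measure_1[3] <- "hepatic_ir"; a$measure_2[3] <- "muscle_ir"
  s <- summarize_dominance(a)
  expect_equal(s$n_dominant, 2)
  expect_equal(unname(s$dominant_counts["muscle_ir"]), 1L)
  expect_equal(s$ir_axis_total, 2)        # muscle dominant + hepatic/muscle
  expect_equal(s$secretion_axis_total, 2) # beta dominant + beta/incretin
  # a cohort of identical assignments concentrates in one cell
  same <- a[rep(1, 4), ]
  s2 <- summarize_dominance(same)
  expect_equal(unname(s2$dominant_counts["muscle_ir"]), 4L)
  expect_equal(sum(s2$dominant_counts), 4)
})
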