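#' Synthetic-cohort simulation configuration
#'
#' Defaults define the study conditions the generator emulates: a
#' middle-aged, BMI 23-40 cohort spanning insulin sensitivity to marked
#' resistance; latent abnormality correlations (muscle IR with hepatic IR
#' 0.7, with beta-cell deficiency 0.6, others 0.2); glucose-curve effect
#' sizes per SD of each latent trait; assay and CGM sensor noise; and an
#' 11% target for the across-test CGM coefficient of variation.
#'
#' @param n_participants Cohort size.
#' @param seed Integer master seed; per-participant streams are derived by a
#'   counter offset so growing the cohort never reshuffles earlier
#'   participants.
#' @param latent_correlations 4x4 correlation matrix over the latent
#'   abnormalities (muscle IR, beta-cell deficiency, incretin deficiency,
#'   hepatic IR), symmetric positive semi-definite.
#' @param effects Named list of glucose-kernel effect sizes (mg/dl or min
#'   per SD of the latent trait): `amp_base`, `amp_sspg`, `amp_beta`,
#'   `amp_incretin`, `tau_base`, `tau_beta`, `tau_sspg`, `g0_base`,
#'   `g0_hepatic`, `shape_k`.
#' @param secretion Named list: `basal` (pmol/kg/min), `response`
#'   (pmol/kg/min per mg/dl glucose excursion), `noise_cv` (%).
#' @param plasma_noise_sd Assay noise SD, mg/dl.
#' @param cgm_noise_sd CGM sensor noise SD, mg/dl.
#' @param cgm_lag CGM sensor delay, minutes.
#' @param cgm_cv_target Across-test CV target, percent.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 200, seed = 1,
                              latent_correlations = default_latent_corr(),
                              effects = list(), secretion = list(),
                              plasma_noise_sd = 3, cgm_noise_sd = 7,
                              cgm_lag = 5, cgm_cv_target = 11) {
  R <- as.matrix(latent_correlations)
  if (!isTRUE(all.equal(R, t(R))) ||
      inherits(tryCatch(chol(R), error = function(e) e), "error")) {
    stop("latent correlation matrix must be symmetric positive definite",
         call. = FALSE)
  }
  if (plasma_noise_sd < 0 || cgm_noise_sd < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  eff <- utils::modifyList(
    list(amp_base = 55, amp_sspg = 18, amp_beta = 8, amp_incretin = 10,
         tau_base = 40, tau_beta = 12, tau_sspg = 4,
         g0_base = 92, g0_hepatic = 6, shape_k = 2), effects)
  sec <- utils::modifyList(
    list(basal = 1.6, response = 0.2, noise_cv = 4), secretion)
  structure(list(n_participants = n_participants, seed = seed,
                 latent_correlations = R, effects = eff, secretion = sec,
                 plasma_noise_sd = plasma_noise_sd,
                 cgm_noise_sd = cgm_noise_sd, cgm_lag = cgm_lag,
                 cgm_cv_target = cgm_cv_target),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_latent_corr <- function() {
  R <- matrix(0.2, 4, 4)
  dimnames(R) <- rep(list(c("muscle_ir", "beta_def", "incretin_def",
                            "hepatic_ir")), 2)
  R["muscle_ir", "hepatic_ir"] <- R["hepatic_ir", "muscle_ir"] <- 0.7
  R["muscle_ir", "beta_def"] <- R["beta_def", "muscle_ir"] <- 0.6
  diag(R) <- 1
  R
}

# one truncated-normal draw by rejection within the caller's RNG stream
rtrunc1 <- function(mu, sd, lo = -Inf, hi = Inf) {
  for (i in 1:1000) {
    x <- stats::rnorm(1, mu, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mu, lo), hi)
}

# location of a truncated normal with given sigma/bounds whose *truncated*
# mean equals `target`
truncnorm_location <- function(target, sd, lo, hi) {
  f <- function(mu) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a)) - target
  }
  stats::uniroot(f, c(target - 4 * sd, hi))$root
}

#' Sample baseline covariates for a synthetic cohort
#'
#' Age ~ N(55, 10) within 30-70 years; BMI from a truncated normal (sigma 5,
#' bounds 23-40 kg/m^2) whose location is solved so the truncated mean is
#' 26; sex ~ Bernoulli(0.5) (1 = male); HDL ~ N(60, 22) above 20 mg/dl;
#' FPG ~ N(98, 14) within the non-diabetic screening range; fasting insulin
#' log-normal with mean 10 uIU/ml; HbA1c ~ N(5.6, 0.4); ethnicity and family
#' history frequencies typical of the emulated cohort. Deterministic under a
#' fixed seed, participant by participant.
#'
#' @param n Cohort size (>= 1).
#' @param seed Integer seed.
#' @return Tibble, one row per participant.
#' @export
sample_covariates <- function(n, seed = 1) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  bmi_mu <- truncnorm_location(26, 5, 23, 40)
  eth_levels <- c("caucasian", "asian", "hispanic", "african_american")
  eth_prob <- c(0.72, 0.25, 0.02, 0.01)
  rows <- lapply(seq_len(n), function(i) {
    with_seed(participant_seed(seed, i, stream = 0L), {
      tibble::tibble(
        participant_id = sprintf("P%04d", i),
        age = rtrunc1(55, 10, 30, 70),
        sex = stats::rbinom(1, 1, 0.5),
        bmi = rtrunc1(bmi_mu, 5, 23, 40),
        ethnicity = sample(eth_levels, 1, prob = eth_prob),
        family_history = stats::rbinom(1, 1, 0.3) == 1,
        hba1c = rtrunc1(5.6, 0.4, 4.6, 6.6),
        fpg = rtrunc1(98, 14, 60, 125),
        fasting_insulin = stats::rlnorm(1, log(10) - 0.18, 0.6),
        hdl = rtrunc1(60, 22, 20, Inf))
    })
  })
  dplyr::bind_rows(rows)
}

#' Sample latent metabolic states through a Gaussian copula
#'
#' Correlated standard-normal abnormality scores (muscle IR, beta-cell
#' deficiency, incretin deficiency, hepatic IR) are drawn with the
#' configured correlation matrix and mapped to physiologic scales: SSPG
#' `= 140 + 55 z` clamped to the observed 40-300 mg/dl range; beta-cell
#' capacity `= exp(-0.45 z)` (secretion multiplier); incretin fraction
#' `= 0.53 - 0.13 z` clamped to `[0.02, 0.98]`; hepatic IR severity kept on
#' the standardized scale.
#'
#' @param covariates Tibble from [sample_covariates()] (supplies ids and
#'   cohort size).
#' @param config A [simulation_config()].
#' @return Tibble with ids, the four z-scores (`z_*`) and the physiologic
#'   latents `sspg`, `beta_capacity`, `ie_frac`, `hep_ir`.
#' @export
sample_latent_state <- function(covariates, config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  L <- chol(config$latent_correlations)   # config constructor validated PSD
  rows <- lapply(seq_len(nrow(covariates)), function(i) {
    z <- with_seed(participant_seed(config$seed, i, stream = 1L),
                   drop(t(L) %*% stats::rnorm(4)))
    tibble::tibble(
      participant_id = covariates$participant_id[i],
      z_muscle = z[1], z_beta = z[2], z_incretin = z[3], z_hepatic = z[4],
      sspg = min(max(140 + 55 * z[1], 40), 300),
      beta_capacity = exp(-0.45 * z[2]),
      ie_frac = min(max(0.53 - 0.13 * z[3], 0.02), 0.98),
      hep_ir = z[4])
  })
  dplyr::bind_rows(rows)
}

glucose_kernel <- function(t, tau, k) {
  ifelse(t <= 0, 0, (t / tau)^k * exp(k * (1 - t / tau)))
}

#' Simulate one plasma OGTT glucose curve
#'
#' Baseline plus a unimodal gamma-shaped response kernel,
#' `g(t) = G0 + A (t/tau)^k exp(k (1 - t/tau))` (peak `A` at `t = tau`):
#' peak amplitude grows with muscle IR, beta-cell deficiency and incretin
#' deficiency; the peak shifts later (raising 2-h glucose) with beta-cell
#' deficiency; baseline rises with hepatic IR. Additive assay noise; the
#' -10-min sample is baseline plus noise. Mono-phasic shapes only.
#'
#' @param state One row of [sample_latent_state()] (needs the `z_*`
#'   columns).
#' @param grid Sampling grid, minutes; must be strictly increasing and
#'   include 0.
#' @param seed Integer seed for the noise stream.
#' @param config A [simulation_config()].
#' @return A canonical [glucose_curve()] (source `"plasma"`).
#' @export
simulate_ogtt_glucose <- function(state, grid = ogtt_grid(), seed = 1,
                                  config = simulation_config()) {
  if (is.unsorted(grid, strictly = TRUE) || !(0 %in% grid)) {
    stop("grid must be strictly increasing and include t = 0", call. = FALSE)
  }
  e <- config$effects
  g0 <- e$g0_base + e$g0_hepatic * state$z_hepatic
  amp <- max(e$amp_base + e$amp_sspg * state$z_muscle +
               e$amp_beta * state$z_beta + e$amp_incretin * state$z_incretin,
             5)
  tau <- min(max(e$tau_base + e$tau_beta * state$z_beta +
                   e$tau_sspg * state$z_muscle, 20), 80)
  mean_curve <- g0 + amp * glucose_kernel(grid, tau, e$shape_k)
  noise <- with_seed(seed, stats::rnorm(length(grid), 0,
                                        config$plasma_noise_sd))
  glucose_curve(state$participant_id, grid, pmax(mean_curve + noise, 40),
                source = "plasma", test_id = "ogtt")
}

#' Simulate the paired OGTT / IIGI C-peptide series
#'
#' A true prehepatic secretion rate, basal plus a term proportional to
#' beta-cell capacity times the glucose excursion above baseline, is pushed
#' through the two-compartment C-peptide kinetic model ([cpeptide_forward()])
#' and sampled on the 7-point grid. The IIGI series uses the same kinetics
#' with the whole secretion rate scaled by `(1 - ie_frac)` (initial
#' condition at the matching steady state), so by linearity the AUC-based
#' incretin effect recovers `ie_frac` exactly in the noise-free limit.
#' Multiplicative log-normal assay noise at the configured CV.
#'
#' @param state One row of [sample_latent_state()].
#' @param glucose The participant's canonical plasma [glucose_curve()].
#' @param kinetics A [kinetic_parameters()] object.
#' @param seed Integer seed.
#' @param config A [simulation_config()].
#' @return List with `ogtt` and `iigi` [analyte_series()], plus `secretion`
#'   (the true OGTT secretion on the 15-min grid).
#' @export
simulate_cpeptide_pair <- function(state, glucose,
                                   kinetics = kinetic_parameters("normal"),
                                   seed = 1,
                                   config = simulation_config()) {
  stopifnot(inherits(glucose, "glucose_curve"))
  if (!glucose$canonical) {
    stop("glucose curve must be on the canonical grid", call. = FALSE)
  }
  sec <- config$secretion
  step <- 15
  t_sec <- seq(0, 180 - step, by = step)
  # excursion at interval midpoints, from the sampled curve
  g0 <- glucose$values[glucose$times == 0]
  mid <- t_sec + step / 2
  g_mid <- stats::approx(glucose$times, glucose$values, xout = mid,
                         rule = 2)$y
  excur <- pmax(g_mid - g0, 0)
  s_ogtt <- sec$basal + state$beta_capacity * sec$response * excur
  s_iigi <- (1 - state$ie_frac) * s_ogtt
  c0_ogtt <- sec$basal / (kinetics$k01 * kinetics$V)
  c0_iigi <- (1 - state$ie_frac) * c0_ogtt
  grid7 <- cpeptide_grid()
  sample_forward <- function(s, c0, stream) {
    fine <- cpeptide_forward(s, kinetics, c0, step = step)
    v <- fine$cpeptide[match(grid7, fine$time)]
    if (sec$noise_cv > 0) {
      cv <- sec$noise_cv / 100
      v <- v * with_seed(participant_seed(seed, 1L, stream = stream),
                         stats::rlnorm(length(v), -cv^2 / 2, cv))
    }
    v
  }
  list(
    ogtt = analyte_series(state$participant_id, "OGTT", "cpeptide",
                          grid7, sample_forward(s_ogtt, c0_ogtt, 2L)),
    iigi = analyte_series(state$participant_id, "IIGI", "cpeptide",
                          grid7, sample_forward(s_iigi, c0_iigi, 3L)),
    secretion = tibble::tibble(time = t_sec, isr = s_ogtt))
}

#' Simulate at-home CGM replicates of an OGTT
#'
#' Each replicate is the plasma curve interpolated to 5-min sampling,
#' delayed by the sensor lag, given a per-test calibration level shift and
#' additive sensor noise. The level-shift SD is derived from the across-test
#' CV target: `shift_sd = sqrt(max((cv/100 * mean)^2 - noise_sd^2, 0))`.
#'
#' @param plasma The participant's plasma [glucose_curve()].
#' @param n_tests Number of home tests (>= 1; the study used 2).
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List of [glucose_curve()] objects (source `"cgm_home"`, test ids
#'   `"home1"`, `"home2"`, ...).
#' @export
simulate_cgm <- function(plasma, n_tests = 2, config = simulation_config(),
                         seed = 1) {
  stopifnot(inherits(plasma, "glucose_curve"))
  if (!is.numeric(n_tests) || n_tests < 1) {
    stop("`n_tests` must be >= 1", call. = FALSE)
  }
  grid <- cgm_grid()
  keep <- plasma$times >= 0
  lagged <- stats::approx(plasma$times[keep] + config$cgm_lag,
                          plasma$values[keep], xout = grid, rule = 2)$y
  level <- mean(lagged)
  # the reported CV uses the sample SD across n_tests replicates, whose
  # expectation is c4 * sigma; inflate the generating SD so the *estimated*
  # CV averages the target
  n_eff <- max(n_tests, 2)
  c4 <- sqrt(2 / (n_eff - 1)) * gamma(n_eff / 2) / gamma((n_eff - 1) / 2)
  target_sd <- config$cgm_cv_target / 100 * level / c4
  shift_sd <- sqrt(max(target_sd^2 - config$cgm_noise_sd^2, 0))
  lapply(seq_len(n_tests), function(j) {
    v <- with_seed(participant_seed(seed, j, stream = 4L), {
      shift <- stats::rnorm(1, 0, shift_sd)
      lagged + shift + stats::rnorm(length(grid), 0, config$cgm_noise_sd)
    })
    glucose_curve(plasma$participant_id, grid, pmax(v, 40),
                  source = "cgm_home", test_id = paste0("home", j))
  })
}

simulate_incretins <- function(state, seed) {
  z_healthy <- -state$z_incretin
  with_seed(participant_seed(seed, 1L, stream = 6L), {
    grid <- incretin_grid()
    shape <- c(0.2, 1, 0.9, 0.75)        # rise to 30-60 min then wane
    gip <- 350 * exp(0.4 * z_healthy + stats::rnorm(1, 0, 0.3)) * shape
    glp1 <- 15 * exp(0.15 * z_healthy + stats::rnorm(1, 0, 0.4)) * shape
    list(gip = analyte_series(state$participant_id, "OGTT", "GIP",
                              grid, pmax(gip, 1)),
         glp1 = analyte_series(state$participant_id, "OGTT", "GLP1",
                               grid, pmax(glp1, 0.5)))
  })
}

simulate_insulin <- function(state, secretion, fasting_insulin, seed,
                             config = simulation_config()) {
  sec <- config$secretion
  grid7 <- cpeptide_grid()
  isr_at <- stats::approx(c(secretion$time, 180),
                          c(secretion$isr, secretion$isr[nrow(secretion)]),
                          xout = grid7, rule = 2)$y
  base <- fasting_insulin * (isr_at / sec$basal)^0.85
  mult <- c(1, rep(exp(0.3 * state$z_hepatic), length(grid7) - 1))
  noise <- with_seed(participant_seed(seed, 1L, stream = 7L),
                     stats::rlnorm(length(grid7), -0.005, 0.1))
  analyte_series(state$participant_id, "OGTT", "insulin", grid7,
                 pmax(base * mult * noise, 1))
}

#' Generate a complete synthetic cohort on disk
#'
#' Samples covariates and latent states, simulates plasma OGTT curves,
#' paired OGTT/IIGI C-peptide, OGTT insulin and incretin series, and two
#' at-home CGM replicates per participant, then writes four cross-referenced
#' CSVs (`glucose.csv`, `analytes.csv`, `covariates.csv`,
#' `latent_truth.csv`) plus a `manifest.yaml` recording the configuration
#' and seed. Latent truth is kept separate from the observables.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed); `NULL` returns the
#'   in-memory dataset without writing.
#' @return Invisibly, the dataset list: `covariates`, `latent`,
#'   `glucose_curves` (list), `analytes` (list), `paths` (when written).
#' @export
generate_cohort <- function(config = simulation_config(), dir = NULL) {
  covs <- sample_covariates(config$n_participants, config$seed)
  latent <- sample_latent_state(covs, config)
  curves <- list()
  analytes <- list()
  for (i in seq_len(nrow(covs))) {
    st <- latent[i, ]
    seed_i <- participant_seed(config$seed, i, stream = 2L)
    plasma <- simulate_ogtt_glucose(st, ogtt_grid(), seed = seed_i,
                                    config = config)
    g120 <- plasma$values[plasma$times == 120]
    kin <- kinetic_parameters(assign_kinetic_class(covs$fpg[i], g120,
                                                   covs$hba1c[i],
                                                   covs$bmi[i]))
    cp <- simulate_cpeptide_pair(st, plasma, kin, seed = seed_i,
                                 config = config)
    ins <- simulate_insulin(st, cp$secretion, covs$fasting_insulin[i],
                            seed = seed_i, config = config)
    inc <- simulate_incretins(st, seed_i)
    cgm <- simulate_cgm(plasma, 2, config, seed = seed_i)
    curves <- c(curves, list(plasma), cgm)
    analytes <- c(analytes, list(cp$ogtt, cp$iigi, ins, inc$gip, inc$glp1))
  }
  # PRS tracks HbA1c moderately, as reported for T2D polygenic scores
  prs_noise <- vapply(seq_len(nrow(covs)), function(i) {
    with_seed(participant_seed(config$seed, i, stream = 8L),
              stats::rnorm(1))
  }, numeric(1))
  covs$prs <- 0.48 * as.numeric(scale(covs$hba1c)) +
    sqrt(1 - 0.48^2) * prs_noise
  covs$sspg <- latent$sspg          # gold-standard IST result is observable
  dataset <- list(covariates = covs, latent = latent,
                  glucose_curves = curves, analytes = analytes,
                  config = config)
  if (!is.null(dir)) {
    dataset$paths <- write_cohort_bundle(dataset, dir)
  }
  invisible(dataset)
}
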