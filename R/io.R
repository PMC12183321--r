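#' Write a cohort dataset to cross-referenced CSVs
#'
#' Layout: `glucose.csv` (participant_id, source, test_id, time_min,
#' glucose_mg_dl), `analytes.csv` (participant_id, test_type, analyte,
#' time_min, value), `covariates.csv` (one row per participant),
#' `latent_truth.csv`, and `manifest.yaml` holding the simulation
#' configuration and seed.
#'
#' @param dataset List as returned by [generate_cohort()].
#' @param dir Output directory, created if missing.
#' @return Named list of file paths.
#' @export
write_cohort_bundle <- function(dataset, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) {
      stop("cannot create output directory: ", dir, call. = FALSE)
    }
  }
  glucose <- dplyr::bind_rows(lapply(dataset$glucose_curves, function(cv) {
    tibble::tibble(participant_id = cv$participant_id, source = cv$source,
                   test_id = cv$test_id, time_min = cv$times,
                   glucose_mg_dl = cv$values)
  }))
  analytes <- dplyr::bind_rows(lapply(dataset$analytes, function(s) {
    tibble::tibble(participant_id = s$participant_id,
                   test_type = s$test_type, analyte = s$analyte,
                   time_min = s$times, value = s$values)
  }))
  paths <- list(glucose = file.path(dir, "glucose.csv"),
                analytes = file.path(dir, "analytes.csv"),
                covariates = file.path(dir, "covariates.csv"),
                latent = file.path(dir, "latent_truth.csv"),
                manifest = file.path(dir, "manifest.yaml"))
  readr::write_csv(glucose, paths$glucose)
  readr::write_csv(analytes, paths$analytes)
  readr::write_csv(dataset$covariates, paths$covariates)
  readr::write_csv(dataset$latent, paths$latent)
  cfg <- dataset$config
  manifest <- list(
    package = "ogttpheno",
    seed = cfg$seed,
    n_participants = cfg$n_participants,
    config_hash = rlang::hash(unclass(cfg)),
    config = list(
      plasma_noise_sd = cfg$plasma_noise_sd,
      cgm_noise_sd = cfg$cgm_noise_sd, cgm_lag = cfg$cgm_lag,
      cgm_cv_target = cfg$cgm_cv_target,
      effects = cfg$effects, secretion = cfg$secretion,
      latent_correlations = as.vector(cfg$latent_correlations)))
  yaml::write_yaml(manifest, paths$manifest)
  paths
}

#' Read a cohort bundle back into memory
#'
#' Validates every row against the container invariants (strictly increasing
#' times, positive glucose, non-negative analytes); offending rows are
#' dropped with a message naming the file and count.
#'
#' @param path Directory holding the CSVs of [write_cohort_bundle()].
#' @return List: `covariates`, `latent` (when present), `glucose_curves`,
#'   `analytes`, `manifest` (when present), `n_rejected`.
#' @export
read_cohort_bundle <- function(path) {
  need <- file.path(path, c("glucose.csv", "analytes.csv",
                            "covariates.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    stop("cohort bundle incomplete; missing: ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  }
  glucose <- readr::read_csv(need[1], show_col_types = FALSE)
  analytes <- readr::read_csv(need[2], show_col_types = FALSE)
  covariates <- readr::read_csv(need[3], show_col_types = FALSE)
  for (col in c("participant_id", "source", "test_id", "time_min",
                "glucose_mg_dl")) {
    if (!col %in% names(glucose)) {
      stop("glucose.csv lacks mandatory column: ", col, call. = FALSE)
    }
  }
  for (col in c("participant_id", "test_type", "analyte", "time_min",
                "value")) {
    if (!col %in% names(analytes)) {
      stop("analytes.csv lacks mandatory column: ", col, call. = FALSE)
    }
  }
  n_rejected <- 0L
  bad_g <- !is.finite(glucose$glucose_mg_dl) | glucose$glucose_mg_dl <= 0 |
    !is.finite(glucose$time_min)
  if (any(bad_g)) {
    message(sum(bad_g), " invalid row(s) dropped from glucose.csv (lines ",
            paste(utils::head(which(bad_g) + 1, 5), collapse = ", "), " ...)")
    n_rejected <- n_rejected + sum(bad_g)
    glucose <- glucose[!bad_g, ]
  }
  bad_a <- !is.finite(analytes$value) | analytes$value < 0 |
    !is.finite(analytes$time_min)
  if (any(bad_a)) {
    message(sum(bad_a), " invalid row(s) dropped from analytes.csv")
    n_rejected <- n_rejected + sum(bad_a)
    analytes <- analytes[!bad_a, ]
  }
  gkey <- paste(glucose$participant_id, glucose$source, glucose$test_id)
  curves <- lapply(split(glucose, gkey), function(d) {
    d <- d[order(d$time_min), ]
    glucose_curve(d$participant_id[1], d$time_min, d$glucose_mg_dl,
                  source = d$source[1], test_id = d$test_id[1])
  })
  akey <- paste(analytes$participant_id, analytes$test_type,
                analytes$analyte)
  series <- lapply(split(analytes, akey), function(d) {
    d <- d[order(d$time_min), ]
    analyte_series(d$participant_id[1], d$test_type[1], d$analyte[1],
                   d$time_min, d$value)
  })
  latent_path <- file.path(path, "latent_truth.csv")
  manifest_path <- file.path(path, "manifest.yaml")
  list(covariates = covariates,
       latent = if (file.exists(latent_path)) {
         readr::read_csv(latent_path, show_col_types = FALSE)
       } else NULL,
       glucose_curves = unname(curves), analytes = unname(series),
       manifest = if (file.exists(manifest_path)) {
         yaml::read_yaml(manifest_path)
       } else NULL,
       n_rejected = n_rejected)
}

find_series <- function(analytes, id, test_type, analyte) {
  for (s in analytes) {
    if (s$participant_id == id && s$test_type == test_type &&
        s$analyte == analyte) {
      return(s)
    }
  }
  NULL
}

find_curve <- function(curves, id, source, test_id = NULL) {
  for (cv in curves) {
    if (cv$participant_id == id && cv$source == source &&
        (is.null(test_id) || cv$test_id == test_id)) {
      return(cv)
    }
  }
  NULL
}

#' Compute per-participant metabolic profiles from a cohort dataset
#'
#' Runs the full index pipeline for each participant: kinetic-class
#' assignment, C-peptide deconvolution and disposition index, AUC-based
#' incretin effect from the OGTT/IIGI pair, hepatic IR index (via the
#' Deurenberg body-fat estimate and the 0-180 min insulin AUC), fasting and
#' Matsuda surrogates, and 2-h incretin concentrations; then labels the
#' measures against the thresholds.
#'
#' @param dataset List as from [generate_cohort()] or
#'   [read_cohort_bundle()]. SSPG must be present in `covariates`.
#' @param thresholds Threshold list, see [default_thresholds()].
#' @param error_cv Deconvolution error CV, percent.
#' @return Tibble, one row per participant, with covariates, the four
#'   measures, surrogates and labels.
#' @export
compute_metabolic_profiles <- function(dataset,
                                       thresholds = default_thresholds(),
                                       error_cv = 5) {
  covs <- dataset$covariates
  if (!"sspg" %in% names(covs)) {
    stop("covariates must carry the SSPG measurement", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(covs)), function(i) {
    id <- covs$participant_id[i]
    plasma <- find_curve(dataset$glucose_curves, id, "plasma")
    cp_ogtt <- find_series(dataset$analytes, id, "OGTT", "cpeptide")
    cp_iigi <- find_series(dataset$analytes, id, "IIGI", "cpeptide")
    insulin <- find_series(dataset$analytes, id, "OGTT", "insulin")
    gip <- find_series(dataset$analytes, id, "OGTT", "GIP")
    glp1 <- find_series(dataset$analytes, id, "OGTT", "GLP1")
    g120 <- if (!is.null(plasma)) {
      stats::approx(plasma$times, plasma$values, xout = 120)$y
    } else NA_real_
    di <- NA_real_
    if (!is.null(cp_ogtt) && is.finite(g120)) {
      kin <- kinetic_parameters(
        assign_kinetic_class(covs$fpg[i], g120, covs$hba1c[i], covs$bmi[i]))
      isr <- deconvolve_insulin_secretion(cp_ogtt, kin,
                                          error_cv = error_cv)
      di <- disposition_index(isr, covs$sspg[i])
    }
    ie <- if (!is.null(cp_ogtt) && !is.null(cp_iigi)) {
      incretin_effect(cp_ogtt, cp_iigi)
    } else NA_real_
    hep <- NA_real_
    bf <- body_fat_percent(covs$bmi[i], covs$age[i], covs$sex[i])
    if (!is.null(insulin) && bf > 0) {
      ins_auc <- trapz_auc(insulin$times, insulin$values, from = 0, to = 180)
      hep <- hepatic_ir_index(ins_auc, bf, covs$hdl[i], covs$bmi[i])
    }
    glu7 <- if (!is.null(plasma)) {
      analyte_series(id, "OGTT", "glucose", cpeptide_grid(),
                     stats::approx(plasma$times, plasma$values,
                                   xout = cpeptide_grid())$y)
    } else NULL
    sur <- surrogate_markers(covs$fpg[i], covs$fasting_insulin[i],
                             glu7, insulin)
    tibble::tibble(
      participant_id = id,
      sspg = covs$sspg[i], di = di, ie_pct = ie, hepatic_ir = hep,
      bf_pct = bf, homa_ir = sur$homa_ir, homa_b = sur$homa_b,
      matsuda = sur$matsuda,
      gip_2h = if (!is.null(gip)) gip$values[gip$times == 120] else NA_real_,
      glp1_2h = if (!is.null(glp1)) glp1$values[glp1$times == 120]
                else NA_real_)
  })
  profiles <- dplyr::left_join(covs, dplyr::bind_rows(rows),
                               by = "participant_id",
                               suffix = c("", ".computed"))
  classify_measures(profiles, thresholds)
}

#' Default end-to-end pipeline configuration
#'
#' @return Nested list: simulation settings, thresholds, preprocessing
#'   (smoothing parameter 0.35), CV protocol (k = 5, repeats, seed),
#'   benchmark scope.
#' @export
default_config <- function() {
  list(simulation = list(n_participants = 200, seed = 1),
       thresholds = default_thresholds(),
       preprocessing = list(smoothing_parameter = 0.35),
       protocol = list(k = 5, repeats = 10, seed = 1, test_fraction = 0.2,
                       selection = "auroc"),
       benchmark = list(phenotypes = c("muscle_ir", "beta_dysfunction",
                                       "incretin_dysfunction",
                                       "hepatic_ir_flag"),
                        feature_sets = names(feature_set_specs())))
}

#' @rdname default_config
#' @param config Configuration list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) yaml::write_yaml(config, path)

#' @rdname default_config
#' @export
read_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' simulate -> metabolic indices -> deviance subphenotyping -> curve
#' features and reduced representation -> classifier benchmark -> CGM
#' concordance, writing every table to `out_dir` stamped with the
#' configuration hash and seed. Deterministic stages are bit-identical
#' under a repeated configuration.
#'
#' @param config List as from [default_config()] (partial lists are filled
#'   with defaults).
#' @param out_dir Output directory.
#' @return Invisibly, a list with all result tables.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  config <- utils::modifyList(default_config(), config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim_cfg <- do.call(simulation_config, config$simulation)
  dataset <- generate_cohort(sim_cfg, dir = file.path(out_dir, "cohort"))

  profiles <- compute_metabolic_profiles(dataset,
                                         thresholds = config$thresholds)
  readr::write_csv(profiles, file.path(out_dir, "profiles.csv"))

  dev <- deviance_scores(profiles)
  assignments <- assign_dominance_cohort(
    dev, delta = config$thresholds$dominance_delta)
  readr::write_csv(dplyr::left_join(dev, assignments,
                                    by = "participant_id"),
                   file.path(out_dir, "deviances.csv"))

  plasma <- lapply(profiles$participant_id, function(id) {
    find_curve(dataset$glucose_curves, id, "plasma")
  })
  features <- extract_features_cohort(lapply(plasma, impute_curve))
  readr::write_csv(features, file.path(out_dir, "features.csv"))
  correlations <- feature_phenotype_correlations(features, profiles)
  readr::write_csv(correlations, file.path(out_dir, "correlations.csv"))

  sp <- config$preprocessing$smoothing_parameter
  curve_matrix <- do.call(rbind, lapply(plasma, preprocess_curve,
                                        smoothing_parameter = sp))
  rownames(curve_matrix) <- profiles$participant_id

  bench_profiles <- dplyr::left_join(profiles, features,
                                     by = "participant_id")
  benchmark <- benchmark_feature_sets(
    bench_profiles, curves = curve_matrix,
    phenotypes = config$benchmark$phenotypes,
    feature_sets = config$benchmark$feature_sets,
    protocol = config$protocol)
  readr::write_csv(benchmark, file.path(out_dir, "benchmark.csv"))

  homes <- lapply(profiles$participant_id, function(id) {
    list(find_curve(dataset$glucose_curves, id, "cgm_home", "home1"),
         find_curve(dataset$glucose_curves, id, "cgm_home", "home2"))
  })
  names(homes) <- profiles$participant_id
  canonical_homes <- lapply(homes, function(p) lapply(p, resample_to_canonical))
  concordance <- concordance_report(canonical_homes)
  cvres <- intraindividual_cv(canonical_homes)
  readr::write_csv(concordance$per_participant,
                   file.path(out_dir, "cgm_concordance.csv"))

  stamp <- list(seed = sim_cfg$seed,
                config_hash = rlang::hash(config),
                n_participants = sim_cfg$n_participants)
  yaml::write_yaml(stamp, file.path(out_dir, "run_stamp.yaml"))

  invisible(list(dataset = dataset, profiles = profiles, deviances = dev,
                 assignments = assignments, features = features,
                 correlations = correlations, benchmark = benchmark,
                 curve_matrix = curve_matrix, concordance = concordance,
                 cgm_cv = cvres, stamp = stamp))
}
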