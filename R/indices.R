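#' @importFrom rlang %||% .data
NULL

#' Disposition index from an insulin secretion rate series
#'
#' Early-phase beta-cell function adjusted for insulin resistance:
#' \deqn{DI = \frac{\int_0^{30} ISR(t)\, dt}{SSPG}}
#' with the integral taken by the trapezoid rule over the deconvolution grid
#' restricted to 0-30 minutes. Units: (pmol dl)/(kg ml) when ISR is in
#' pmol/kg/min and SSPG in mg/dl.
#'
#' @param isr Tibble with `time` (minutes, interval starts) and `isr`
#'   (pmol/kg/min), e.g. from [deconvolve_insulin_secretion()]. Must cover
#'   0-30 min.
#' @param sspg Steady-state plasma glucose, mg/dl (> 0).
#' @return Disposition index (scalar).
#' @export
disposition_index <- function(isr, sspg) {
  if (!is.numeric(sspg) || length(sspg) != 1 || sspg <= 0) {
    stop("`sspg` must be a positive scalar", call. = FALSE)
  }
  t <- isr$time
  v <- isr$isr
  if (min(t) > 0 || max(t) < 30) {
    # piecewise-constant rates: the interval starting at 15 covers [15, 30)
    if (min(t) > 0 || max(t) + 1e-9 < 15) {
      stop("secretion series must cover [0, 30] minutes", call. = FALSE)
    }
  }
  # extend the piecewise-constant series to an evaluable curve on [0, 30]
  keep <- t <= 30
  tt <- t[keep]
  vv <- v[keep]
  if (max(tt) < 30) {
    # constant over the last interval
    tt <- c(tt, 30)
    vv <- c(vv, vv[length(vv)])
  }
  trapz_auc(tt, vv, from = 0, to = 30) / sspg
}

#' Incretin effect from paired OGTT and IIGI C-peptide series
#'
#' The percentage by which oral glucose elicits more C-peptide than the
#' glucose-matched intravenous infusion:
#' \deqn{IE\% = 100 \times \frac{AUC_{OGTT} - AUC_{IIGI}}{AUC_{OGTT}}}
#' with trapezoid AUCs over 0-180 min. May be negative; never exceeds 100.
#'
#' @param cpep_ogtt,cpep_iigi [analyte_series()] C-peptide series on the same
#'   grid covering 0-180 min.
#' @return Incretin effect, percent.
#' @export
incretin_effect <- function(cpep_ogtt, cpep_iigi) {
  stopifnot(inherits(cpep_ogtt, "analyte_series"),
            inherits(cpep_iigi, "analyte_series"))
  if (!identical(cpep_ogtt$times, cpep_iigi$times)) {
    stop("OGTT and IIGI series must share the same grid", call. = FALSE)
  }
  if (min(cpep_ogtt$times) > 0 || max(cpep_ogtt$times) < 180) {
    stop("series must cover [0, 180] minutes", call. = FALSE)
  }
  auc_o <- trapz_auc(cpep_ogtt$times, cpep_ogtt$values, from = 0, to = 180)
  auc_i <- trapz_auc(cpep_iigi$times, cpep_iigi$values, from = 0, to = 180)
  if (auc_o == 0) stop("OGTT C-peptide AUC is zero; IE undefined",
                       call. = FALSE)
  100 * (auc_o - auc_i) / auc_o
}

#' Body fat percentage (Deurenberg index)
#'
#' `BF% = -5.4 + 1.2 BMI + 0.23 Age - 10.8 Sex`, with sex coded 1 for male
#' and 0 for female.
#'
#' @param bmi kg/m^2 (> 0).
#' @param age Years (> 0).
#' @param sex 1 = male, 0 = female.
#' @return Estimated body fat, percent.
#' @export
body_fat_percent <- function(bmi, age, sex) {
  if (!all(sex %in% c(0, 1))) stop("sex must be 0 or 1", call. = FALSE)
  if (any(bmi <= 0) || any(age <= 0)) {
    stop("bmi and age must be positive", call. = FALSE)
  }
  -5.4 + 1.2 * bmi + 0.23 * age - 10.8 * sex
}

#' Hepatic insulin-resistance index
#'
#' Regression surrogate for liver insulin resistance:
#' \deqn{-0.091 + 0.4 \log(AUC_{ins}) + 0.346 \log(BF\%) - 0.408 \log(HDL)
#'   + 0.435 \log(BMI)}
#' with natural logarithms; insulin AUC over 0-180 min of the OGTT in
#' uIU/ml x min, HDL in mg/dl, BMI in kg/m^2.
#'
#' @param insulin_auc_0_180 Trapezoid insulin AUC over 0-180 min (> 0).
#' @param bf_pct Body fat percent (> 0), e.g. from [body_fat_percent()].
#' @param hdl HDL cholesterol, mg/dl (> 0).
#' @param bmi kg/m^2 (> 0).
#' @return Hepatic IR index (dimensionless).
#' @export
hepatic_ir_index <- function(insulin_auc_0_180, bf_pct, hdl, bmi) {
  args <- cbind(insulin_auc_0_180, bf_pct, hdl, bmi)
  if (any(args <= 0)) {
    stop("all arguments must be positive (logarithms)", call. = FALSE)
  }
  -0.091 + 0.4 * log(insulin_auc_0_180) + 0.346 * log(bf_pct) -
    0.408 * log(hdl) + 0.435 * log(bmi)
}

#' Fasting and OGTT surrogate markers
#'
#' HOMA-IR `= FPG x FPI / 405`, HOMA-B `= 360 x FPI / (FPG - 63)` (requires
#' FPG > 63) and the Matsuda index
#' `= 10000 / sqrt(FPG x FPI x Gbar x Ibar)` where `Gbar`, `Ibar` are the
#' trapezoid time-weighted mean OGTT glucose and insulin over 0-120 min.
#' Glucose in mg/dl, insulin in uIU/ml.
#'
#' @param fpg Fasting plasma glucose, mg/dl.
#' @param fasting_insulin Fasting insulin, uIU/ml.
#' @param ogtt_glucose,ogtt_insulin Optional [analyte_series()] (or tibbles
#'   with `times`/`values`) covering 0-120 min; when absent the Matsuda index
#'   is returned as `NA`.
#' @return Named list: `homa_ir`, `homa_b`, `matsuda`.
#' @export
surrogate_markers <- function(fpg, fasting_insulin,
                              ogtt_glucose = NULL, ogtt_insulin = NULL) {
  stopifnot(fpg > 0, fasting_insulin > 0)
  homa_ir <- fpg * fasting_insulin / 405
  homa_b <- if (fpg > 63) 360 * fasting_insulin / (fpg - 63) else NA_real_
  matsuda <- NA_real_
  if (!is.null(ogtt_glucose) && !is.null(ogtt_insulin)) {
    tw_mean <- function(s) {
      t <- s$times
      v <- s$values
      trapz_auc(t, v, from = 0, to = 120) / 120
    }
    gbar <- tw_mean(ogtt_glucose)
    ibar <- tw_mean(ogtt_insulin)
    matsuda <- 10000 / sqrt(fpg * fasting_insulin * gbar * ibar)
  }
  list(homa_ir = homa_ir, homa_b = homa_b, matsuda = matsuda)
}

#' Additive polygenic score with mean imputation of missing variants
#'
#' `PRS = sum(dosage x weight)` over genotyped variants plus
#' `2 x weight x allele frequency` for variants absent from the dosage table.
#'
#' @param dosages Named numeric vector of allele dosages in `[0, 2]`
#'   (names = variant ids).
#' @param weights Named numeric vector of per-variant effect weights; defines
#'   the scored variant set.
#' @param allele_freqs Named numeric vector of population allele frequencies
#'   for imputing variants missing from `dosages`.
#' @param standardize Optional cohort mean/sd (length-2 numeric) to return a
#'   standardized score.
#' @return Polygenic score (scalar).
#' @export
polygenic_score <- function(dosages, weights, allele_freqs = NULL,
                            standardize = NULL) {
  if (length(weights) == 0) {
    warning("empty weight set; polygenic score is 0")
    return(0)
  }
  if (is.null(names(weights))) stop("weights must be named", call. = FALSE)
  ids <- names(weights)
  present <- ids[ids %in% names(dosages)]
  missing <- setdiff(ids, present)
  if (length(missing) > 0) {
    if (is.null(allele_freqs) || !all(missing %in% names(allele_freqs))) {
      stop("variant(s) missing from both dosages and allele_freqs: ",
           paste(utils::head(setdiff(missing, names(allele_freqs)), 5),
                 collapse = ", "), call. = FALSE)
    }
  }
  if (any(dosages[present] < 0 | dosages[present] > 2)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  prs <- sum(dosages[present] * weights[present]) +
    sum(2 * weights[missing] * allele_freqs[missing])
  if (!is.null(standardize)) prs <- (prs - standardize[1]) / standardize[2]
  unname(prs)
}

#' Default classification thresholds
#'
#' Cohort-derived cut-points used throughout: muscle IR at SSPG >= 120 mg/dl;
#' binary beta-cell dysfunction at DI < 1.58, incretin dysfunction at
#' IE < 53.38%, hepatic IR at index >= 4.35 (50th percentiles of the
#' reference cohort); ternary bands DI (1.2, 2.2), IE (39, 64), hepatic
#' index (3.95, 4.8); dominance gap delta 0.5.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(sspg_ir = 120,
       di_binary = 1.58, ie_binary = 53.38, hepatic_binary = 4.35,
       di_ternary = c(1.2, 2.2), ie_ternary = c(39, 64),
       hepatic_ternary = c(3.95, 4.8),
       dominance_delta = 0.5)
}

#' Label metabolic measures against the threshold table
#'
#' Adds binary flags (`muscle_ir`, `beta_dysfunction`, `incretin_dysfunction`,
#' `hepatic_ir_flag`) and ternary classes (`di_class`, `ie_class`,
#' `hepatic_class`) to a profile table. Boundary values are assigned to the
#' non-dysfunction side for DI/IE binary cuts (DI exactly 1.58 is normal) and
#' to IR for SSPG/hepatic (>= cut).
#'
#' @param profiles Tibble with columns `sspg`, `di`, `ie_pct`, `hepatic_ir`
#'   (missing measures give `NA` labels).
#' @param thresholds List as from [default_thresholds()].
#' @return `profiles` with label columns appended.
#' @export
classify_measures <- function(profiles, thresholds = default_thresholds()) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  tern <- function(x, lo, hi, low_lab, mid_lab, high_lab) {
    dplyr::case_when(is.na(x) ~ NA_character_,
                     x < lo ~ low_lab,
                     x <= hi ~ mid_lab,
                     TRUE ~ high_lab)
  }
  dplyr::mutate(
    tibble::as_tibble(profiles),
    muscle_ir = .data$sspg >= th$sspg_ir,
    beta_dysfunction = .data$di < th$di_binary,
    incretin_dysfunction = .data$ie_pct < th$ie_binary,
    hepatic_ir_flag = .data$hepatic_ir >= th$hepatic_binary,
    di_class = tern(.data$di, th$di_ternary[1], th$di_ternary[2],
                    "dysfunction", "intermediate", "normal"),
    ie_class = tern(.data$ie_pct, th$ie_ternary[1], th$ie_ternary[2],
                    "dysfunction", "intermediate", "normal"),
    hepatic_class = tern(.data$hepatic_ir, th$hepatic_ternary[1],
                         th$hepatic_ternary[2],
                         "sensitive", "intermediate", "resistant"))
}
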