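#' Impute missing points of a glucose curve
#'
#' Interior gaps are filled by linear interpolation in time; leading and
#' trailing gaps by the nearest observed value. At least two observed points
#' are required.
#'
#' @param curve A [glucose_curve()] (values may contain `NA`).
#' @return The curve with no missing values.
#' @export
impute_curve <- function(curve) {
  stopifnot(inherits(curve, "glucose_curve"))
  obs <- !is.na(curve$values)
  if (sum(obs) < 2) {
    stop("need at least 2 observed points to impute", call. = FALSE)
  }
  if (all(obs)) return(curve)
  curve$values <- stats::approx(curve$times[obs], curve$values[obs],
                                xout = curve$times, rule = 2)$y
  curve
}

#' The 14 engineered OGTT glucose-curve features
#'
#' From a complete curve on the canonical 16-point grid, computes: glucose at
#' 0/60/120/180 min and at the peak (`g_0`, `g_60`, `g_120`, `g_180`,
#' `g_peak`); curve arc length over 0-180 min (`curve_size`, raw mixed
#' units); trapezoid `auc` over 0-180; positive/negative/incremental areas
#' relative to baseline `g_0` (`pauc`, `nauc`, `iauc = pauc - nauc`);
#' coefficient of variation of all 16 values (`cv`, sample SD / mean); time
#' from baseline to peak (`t_baseline2peak`, with peak = max over 0-180,
#' earliest-time tie-break); and the two slopes `s_baseline2peak`
#' (`(g_peak - g_0)/t_peak`, 0 if the peak is at 0) and `s_peak2end`
#' (`(g_180 - g_peak)/(180 - t_peak)`, 0 if the peak is at 180).
#'
#' The -10-min sample is excluded from integrals and slopes (features are
#' defined on 0-180 with baseline `g_0`) but participates in `cv`.
#'
#' @param curve A complete canonical [glucose_curve()].
#' @return One-row tibble of the 14 features.
#' @export
extract_features <- function(curve) {
  stopifnot(inherits(curve, "glucose_curve"))
  if (!curve$canonical) {
    stop("features are defined on the canonical 16-point grid", call. = FALSE)
  }
  if (anyNA(curve$values)) {
    stop("curve has missing values; impute first", call. = FALSE)
  }
  t_all <- curve$times
  g_all <- curve$values
  on <- t_all >= 0
  t <- t_all[on]
  g <- g_all[on]
  g0 <- g[t == 0]
  peak_idx <- which.max(g)            # which.max takes the earliest maximum
  g_peak <- g[peak_idx]
  t_peak <- t[peak_idx]
  pos <- pmax(g - g0, 0)
  neg <- pmax(g0 - g, 0)
  tibble::tibble(
    g_0 = g0,
    g_60 = g[t == 60],
    g_120 = g[t == 120],
    g_180 = g[t == 180],
    g_peak = g_peak,
    curve_size = sum(sqrt(diff(t)^2 + diff(g)^2)),
    auc = trapz_auc(t, g),
    pauc = trapz_auc(t, pos),
    nauc = trapz_auc(t, neg),
    iauc = trapz_auc(t, pos) - trapz_auc(t, neg),
    cv = stats::sd(g_all) / mean(g_all),
    t_baseline2peak = t_peak,
    s_baseline2peak = if (t_peak == 0) 0 else (g_peak - g0) / t_peak,
    s_peak2end = if (t_peak == 180) 0 else (g[t == 180] - g_peak) /
      (180 - t_peak))
}

#' Curve features for a list of curves
#'
#' @param curves List of complete canonical [glucose_curve()] objects.
#' @return Tibble with `participant_id` plus the 14 feature columns.
#' @export
extract_features_cohort <- function(curves) {
  dplyr::bind_rows(lapply(curves, function(cv) {
    dplyr::bind_cols(tibble::tibble(participant_id = cv$participant_id),
                     extract_features(cv))
  }))
}

#' Pearson correlations between curve features and metabolic measures
#'
#' For every feature x measure pair, the Pearson r and its two-sided t-test
#' p-value (n - 2 degrees of freedom), with a significance flag at p < 0.05.
#' Zero-variance features give `NA` with a flag.
#'
#' @param features Tibble from [extract_features_cohort()].
#' @param profiles Tibble with `participant_id` and the measure columns
#'   (default `sspg`, `di`, `ie_pct`, `hepatic_ir`).
#' @param measures Character vector of profile columns to correlate against.
#' @return Tibble with `feature`, `measure`, `r`, `p`, `significant`, `n`.
#' @export
feature_phenotype_correlations <- function(features, profiles,
                                           measures = c("sspg", "di",
                                                        "ie_pct",
                                                        "hepatic_ir")) {
  joined <- dplyr::inner_join(features, profiles, by = "participant_id")
  if (nrow(joined) < 3) {
    stop("need at least 3 complete participants", call. = FALSE)
  }
  feat_cols <- setdiff(names(features), "participant_id")
  grid <- expand.grid(feature = feat_cols, measure = measures,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- joined[[grid$feature[i]]]
    y <- joined[[grid$measure[i]]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(tibble::tibble(feature = grid$feature[i],
                            measure = grid$measure[i],
                            r = NA_real_, p = NA_real_,
                            significant = NA, n = n))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(feature = grid$feature[i], measure = grid$measure[i],
                   r = unname(ct$estimate), p = ct$p.value,
                   significant = ct$p.value < 0.05, n = n)
  })
  dplyr::bind_rows(rows)
}
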