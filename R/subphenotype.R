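#' Standardized deviance scores for the four metabolic measures
#'
#' For each measure the cohort Z-score
#' \deqn{deviance = (x - mean(x)) / sd(x)}
#' is computed with the sample (n-1) standard deviation, after negating DI
#' and IE so that a higher deviance always points in the unhealthy direction
#' (muscle IR and hepatic IR are already oriented that way).
#'
#' @param profiles Tibble with `participant_id`, `sspg`, `di`, `ie_pct`,
#'   `hepatic_ir`. Participants missing any measure are excluded from cohort
#'   statistics and from the output (with a message).
#' @return Tibble with `participant_id` and deviances `muscle_ir`,
#'   `beta_cell`, `incretin`, `hepatic_ir`; attribute `excluded` lists
#'   dropped participants.
#' @export
deviance_scores <- function(profiles) {
  profiles <- tibble::as_tibble(profiles)
  need <- c("participant_id", "sspg", "di", "ie_pct", "hepatic_ir")
  miss <- setdiff(need, names(profiles))
  if (length(miss) > 0) {
    stop("profiles lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  complete <- stats::complete.cases(profiles[, need[-1]])
  excluded <- profiles$participant_id[!complete]
  if (length(excluded) > 0) {
    message(length(excluded),
            " participant(s) excluded for missing measures: ",
            paste(utils::head(excluded, 5), collapse = ", "))
  }
  p <- profiles[complete, ]
  if (nrow(p) < 2) {
    stop("need at least 2 participants with all four measures", call. = FALSE)
  }
  zscore <- function(x) {
    s <- stats::sd(x)
    if (s == 0) stop("degenerate cohort: a measure has zero variance",
                     call. = FALSE)
    (x - mean(x)) / s
  }
  out <- tibble::tibble(
    participant_id = p$participant_id,
    muscle_ir = zscore(p$sspg),
    beta_cell = zscore(-p$di),        # higher DI = healthier, so negate
    incretin = zscore(-p$ie_pct),     # higher IE = healthier, so negate
    hepatic_ir = zscore(p$hepatic_ir))
  attr(out, "excluded") <- excluded
  out
}

#' Dominant / co-dominant subphenotype assignment
#'
#' Sort the four deviances descending, `d(1) >= d(2) >= d(3) >= d(4)`:
#' the top measure is *dominant* if `d(1) - d(2) >= delta`; the top two are
#' *co-dominant* if `d(1) - d(2) < delta` and `d(1) - d(3) >= delta`;
#' otherwise (three or more within `delta` of the top) the participant is
#' *unclassified*. Exact ties at the top are co-dominant (gap 0 < delta).
#'
#' @param deviances Length-4 named numeric vector, or a row of the tibble
#'   from [deviance_scores()]. Names must be the four measures.
#' @param delta Minimum deviance gap (default 0.5).
#' @return List with `category` (`"dominant"`, `"co_dominant"`,
#'   `"unclassified"`) and `measures` (character vector of the implicated
#'   measures; empty when unclassified).
#' @export
assign_dominance <- function(deviances, delta = 0.5) {
  d <- unlist(deviances[c("muscle_ir", "beta_cell", "incretin",
                          "hepatic_ir")])
  if (anyNA(d) || any(!is.finite(d))) {
    stop("all four deviances must be finite", call. = FALSE)
  }
  ord <- order(d, decreasing = TRUE)
  ds <- d[ord]
  if (ds[1] - ds[2] >= delta) {
    list(category = "dominant", measures = names(ds)[1])
  } else if (ds[1] - ds[3] >= delta) {
    list(category = "co_dominant", measures = sort(names(ds)[1:2]))
  } else {
    list(category = "unclassified", measures = character(0))
  }
}

#' Cohort-level dominance assignments
#'
#' Applies [assign_dominance()] row-wise and returns one row per participant
#' with the category and implicated measure(s).
#'
#' @param deviances Tibble from [deviance_scores()].
#' @inheritParams assign_dominance
#' @return Tibble with `participant_id`, `category`, `measure_1`,
#'   `measure_2` (`NA` where not applicable).
#' @export
assign_dominance_cohort <- function(deviances, delta = 0.5) {
  rows <- lapply(seq_len(nrow(deviances)), function(i) {
    a <- assign_dominance(deviances[i, ], delta = delta)
    tibble::tibble(participant_id = deviances$participant_id[i],
                   category = a$category,
                   measure_1 = if (length(a$measures) >= 1) a$measures[1]
                               else NA_character_,
                   measure_2 = if (length(a$measures) >= 2) a$measures[2]
                               else NA_character_)
  })
  dplyr::bind_rows(rows)
}

#' Summarize a cohort's dominance assignments
#'
#' Counts dominant participants per measure, co-dominant pairs, the
#' unclassified remainder, and the two physiology-axis totals: the IR axis
#' (dominant or co-dominant in muscle and/or hepatic IR) and the secretion
#' axis (beta-cell and/or incretin).
#'
#' @param assignments Tibble from [assign_dominance_cohort()].
#' @return List with `n`, `n_dominant`, `n_co_dominant`, `n_unclassified`,
#'   `dominant_counts` (named), `co_dominant_pairs` (tibble), `ir_axis_total`,
#'   `secretion_axis_total`.
#' @export
summarize_dominance <- function(assignments) {
  a <- tibble::as_tibble(assignments)
  dom <- a[a$category == "dominant", ]
  cod <- a[a$category == "co_dominant", ]
  measures <- c("muscle_ir", "beta_cell", "incretin", "hepatic_ir")
  dominant_counts <- vapply(measures,
                            function(m) sum(dom$measure_1 == m), integer(1))
  pair_key <- paste(cod$measure_1, cod$measure_2, sep = "+")
  pairs <- if (nrow(cod) > 0) {
    tab <- table(pair_key)
    tibble::tibble(pair = names(tab), n = as.integer(tab))
  } else tibble::tibble(pair = character(0), n = integer(0))
  involved <- function(ms) {
    a$category != "unclassified" &
      (a$measure_1 %in% ms | (!is.na(a$measure_2) & a$measure_2 %in% ms))
  }
  list(n = nrow(a),
       n_dominant = nrow(dom),
       n_co_dominant = nrow(cod),
       n_unclassified = sum(a$category == "unclassified"),
       dominant_counts = dominant_counts,
       co_dominant_pairs = pairs,
       ir_axis_total = sum(involved(c("muscle_ir", "hepatic_ir"))),
       secretion_axis_total = sum(involved(c("beta_cell", "incretin"))))
}
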