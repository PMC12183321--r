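#' Window a CGM trace to OGTT-relative minutes
#'
#' Re-indexes a 5-min CGM trace to minutes since glucola start, keeping
#' the 0-180 min window, and linearly interpolates short sensor dropouts
#' (at most `max_gap` consecutive missing readings; longer gaps abort).
#'
#' @param trace A [glucose_curve()] on a 5-min grid (absolute minutes);
#'   values may contain `NA` for dropped readings.
#' @param t0 Clock time (same units as `trace$times`) of glucola start.
#' @param max_gap Maximum run of consecutive missing readings tolerated
#'   (default 2, i.e. 10 minutes).
#' @return A [glucose_curve()] on 0, 5, ..., 180 relative minutes.
#' @export
align_cgm_to_ogtt <- function(trace, t0, max_gap = 2) {
  stopifnot(inherits(trace, "glucose_curve"))
  rel <- trace$times - t0
  keep <- rel >= 0 & rel <= 180
  grid <- cgm_grid()
  if (!all(grid %in% rel[keep])) {
    stop("trace does not cover [t0, t0 + 180] on the 5-min grid",
         call. = FALSE)
  }
  v <- trace$values[match(grid, rel)]
  if (anyNA(v)) {
    runs <- rle(is.na(v))
    if (any(runs$values & runs$lengths > max_gap)) {
      stop("sensor gap exceeds ", max_gap, " consecutive readings",
           call. = FALSE)
    }
    if (is.na(v[1]) || is.na(v[length(v)])) {
      stop("window edges missing; cannot interpolate", call. = FALSE)
    }
    v <- stats::approx(grid[!is.na(v)], v[!is.na(v)], xout = grid)$y
  }
  glucose_curve(trace$participant_id, grid, v, source = trace$source,
                test_id = trace$test_id)
}

#' Resample a windowed CGM curve onto the canonical 16-point grid
#'
#' Linear interpolation onto the canonical OGTT timepoints; the -10-min slot
#' (which a CGM started at glucola time cannot observe) is filled with the
#' t = 0 value and flagged.
#'
#' @param windowed A [glucose_curve()] on 0-180 relative minutes.
#' @return A canonical [glucose_curve()]; attribute
#'   `synthetic_baseline = TRUE` marks the filled -10-min slot.
#' @export
resample_to_canonical <- function(windowed) {
  stopifnot(inherits(windowed, "glucose_curve"))
  grid <- ogtt_grid()
  pos <- grid[grid >= 0]
  v <- stats::approx(windowed$times, windowed$values, xout = pos)$y
  out <- glucose_curve(windowed$participant_id, grid, c(v[1], v),
                       source = windowed$source, test_id = windowed$test_id)
  attr(out, "synthetic_baseline") <- TRUE
  out
}

#' Average repeated home-test curves pointwise
#'
#' @param curves List of canonical [glucose_curve()] objects from one
#'   participant on a common grid.
#' @return A [glucose_curve()] whose values are the pointwise mean
#'   (test id `"home_mean"`).
#' @export
average_home_tests <- function(curves) {
  stopifnot(length(curves) >= 1)
  times <- curves[[1]]$times
  for (cv in curves) {
    if (!identical(cv$times, times)) {
      stop("curves must share a common grid", call. = FALSE)
    }
  }
  vals <- rowMeans(vapply(curves, function(cv) cv$values,
                          numeric(length(times))))
  glucose_curve(curves[[1]]$participant_id, times, vals,
                source = curves[[1]]$source, test_id = "home_mean")
}

#' Concordance between paired glucose curves across settings
#'
#' Per participant, the Pearson correlation between the two curves of each
#' pair over their shared timepoints, plus the cohort median and quartiles.
#' Typical comparisons: plasma vs clinic CGM, home replicate 1 vs 2, plasma
#' vs the mean home curve.
#'
#' @param pairs Named list; each element is a list of two [glucose_curve()]
#'   objects on a common grid, named by participant.
#' @return List with `per_participant` (tibble: `participant_id`, `r`,
#'   `constant` flag) and `summary` (median, q1, q3 over defined r values).
#' @export
concordance_report <- function(pairs) {
  rows <- lapply(names(pairs), function(id) {
    p <- pairs[[id]]
    a <- p[[1]]
    b <- p[[2]]
    shared <- intersect(a$times, b$times)
    if (length(shared) < 3) {
      stop("pair for ", id, " shares fewer than 3 timepoints", call. = FALSE)
    }
    va <- a$values[match(shared, a$times)]
    vb <- b$values[match(shared, b$times)]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
      tibble::tibble(participant_id = id, r = NA_real_, constant = TRUE)
    } else {
      tibble::tibble(participant_id = id, r = stats::cor(va, vb),
                     constant = FALSE)
    }
  })
  per <- dplyr::bind_rows(rows)
  rs <- per$r[!is.na(per$r)]
  list(per_participant = per,
       summary = list(median = stats::median(rs),
                      q1 = unname(stats::quantile(rs, 0.25)),
                      q3 = unname(stats::quantile(rs, 0.75)),
                      n = length(rs)))
}

#' Intra-individual coefficient of variation across repeat tests
#'
#' Per timepoint, CV = sample SD / mean across a participant's repeat
#' curves; the overall figure averages the per-timepoint CVs over timepoints
#' and participants.
#'
#' @param repeats_by_participant Named list; each element a list of >= 2
#'   [glucose_curve()] objects on a common grid.
#' @return List with `per_participant` (tibble: `participant_id`,
#'   `mean_cv_pct`) and `overall_cv_pct`.
#' @export
intraindividual_cv <- function(repeats_by_participant) {
  rows <- lapply(names(repeats_by_participant), function(id) {
    curves <- repeats_by_participant[[id]]
    if (length(curves) < 2) {
      stop("participant ", id, " has fewer than 2 repeats", call. = FALSE)
    }
    times <- curves[[1]]$times
    M <- vapply(curves, function(cv) {
      if (!identical(cv$times, times)) {
        stop("repeats must share a common grid", call. = FALSE)
      }
      cv$values
    }, numeric(length(times)))
    cv_t <- apply(M, 1, stats::sd) / rowMeans(M)
    tibble::tibble(participant_id = id, mean_cv_pct = 100 * mean(cv_t))
  })
  per <- dplyr::bind_rows(rows)
  list(per_participant = per, overall_cv_pct = mean(per$mean_cv_pct))
}
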