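#' Canonical OGTT sampling grids
#'
#' The frequently sampled OGTT draws plasma at 16 timepoints; C-peptide and
#' insulin are assayed at 7 of them and the incretin hormones at 4. These
#' constants define the grids every curve- and series-level function checks
#' against.
#'
#' @return Integer vector of minutes.
#' @export
ogtt_grid <- function() c(-10L, 0L, 10L, 15L, 20L, 30L, 40L, 50L, 60L,
                          75L, 90L, 105L, 120L, 135L, 150L, 180L)

#' @rdname ogtt_grid
#' @export
cpeptide_grid <- function() c(0L, 15L, 30L, 60L, 90L, 120L, 180L)

#' @rdname ogtt_grid
#' @export
incretin_grid <- function() c(0L, 30L, 60L, 120L)

#' @rdname ogtt_grid
#' @export
cgm_grid <- function() seq(0L, 180L, by = 5L)

#' Trapezoidal area under a sampled curve
#'
#' @param times Strictly increasing sampling times (minutes).
#' @param values Values at `times`.
#' @param from,to Optional integration limits; values at the limits are
#'   obtained by linear interpolation if the limits are not sampled.
#' @return Area in value-units times minutes.
#' @export
trapz_auc <- function(times, values, from = NULL, to = NULL) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (!is.null(from) || !is.null(to)) {
    from <- if (is.null(from)) times[1] else from
    to <- if (is.null(to)) times[length(times)] else to
    if (from < times[1] || to > times[length(times)] || from >= to) {
      stop("integration limits outside the sampled range", call. = FALSE)
    }
    keep <- times > from & times < to
    times2 <- c(from, times[keep], to)
    values2 <- c(stats::approx(times, values, xout = from)$y,
                 values[keep],
                 stats::approx(times, values, xout = to)$y)
    times <- times2
    values <- values2
  }
  sum(diff(times) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Construct a glucose curve record
#'
#' A `glucose_curve` is a light S3 wrapper around a sampled glucose time
#' series with its provenance (`plasma`, `cgm_clinic` or `cgm_home`).
#'
#' @param participant_id Identifier string.
#' @param times Minutes, strictly increasing.
#' @param values Glucose, mg/dl. `NA` allowed (imputed downstream).
#' @param source One of `"plasma"`, `"cgm_clinic"`, `"cgm_home"`.
#' @param test_id Test label (e.g. `"ogtt"`, `"home1"`).
#' @return An object of class `glucose_curve`.
#' @export
glucose_curve <- function(participant_id, times, values,
                          source = c("plasma", "cgm_clinic", "cgm_home"),
                          test_id = "ogtt") {
  source <- match.arg(source)
  stopifnot(length(times) == length(values))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("curve times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.na(values) & values <= 0)) {
    stop("glucose values must be positive", call. = FALSE)
  }
  structure(
    list(participant_id = as.character(participant_id),
         source = source, test_id = as.character(test_id),
         times = as.numeric(times), values = as.numeric(values),
         canonical = identical(as.numeric(times), as.numeric(ogtt_grid()))),
    class = "glucose_curve")
}

#' @export
print.glucose_curve <- function(x, ...) {
  cat(sprintf("<glucose_curve> %s [%s/%s] %d points, %g-%g min\n",
              x$participant_id, x$source, x$test_id, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Construct an analyte series record
#'
#' Holds one analyte (C-peptide, insulin, glucose, GLP-1, GIP or glucagon)
#' measured during one test (OGTT or IIGI). C-peptide in pmol/l, insulin in
#' uIU/ml, glucose in mg/dl.
#'
#' @param participant_id Identifier.
#' @param test_type `"OGTT"` or `"IIGI"`.
#' @param analyte One of `"cpeptide"`, `"insulin"`, `"glucose"`, `"GLP1"`,
#'   `"GIP"`, `"glucagon"`.
#' @param times Minutes, strictly increasing.
#' @param values Concentrations, non-negative.
#' @return An object of class `analyte_series`.
#' @export
analyte_series <- function(participant_id, test_type = c("OGTT", "IIGI"),
                           analyte = c("cpeptide", "insulin", "glucose",
                                       "GLP1", "GIP", "glucagon"),
                           times, values) {
  test_type <- match.arg(test_type)
  analyte <- match.arg(analyte)
  stopifnot(length(times) == length(values))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("series times must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("analyte concentrations must be non-negative", call. = FALSE)
  }
  structure(
    list(participant_id = as.character(participant_id),
         test_type = test_type, analyte = analyte,
         times = as.numeric(times), values = as.numeric(values)),
    class = "analyte_series")
}

#' @export
print.analyte_series <- function(x, ...) {
  cat(sprintf("<analyte_series> %s %s/%s %d points\n",
              x$participant_id, x$test_type, x$analyte, length(x$times)))
  invisible(x)
}

# Per-participant deterministic seed stream: a counter offset on the global
# seed so growing the cohort never reshuffles earlier participants.
participant_seed <- function(seed, i, stream = 0L) {
  base <- (as.integer(seed) %% 1000003L)
  (base * 1009L + as.integer(i) * 13L + as.integer(stream)) %% 2147483647L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
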