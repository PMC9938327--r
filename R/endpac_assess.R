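# New-onset diabetes (NOD) triage via the questionnaire-level ENDPAC
# criteria: self-reported weight loss together with self-reported
# higher-than-normal fasting glucose around the age of 50 or later, in a
# respondent not already diagnosed with pancreatic cancer.
#
# The published three-variable ENDPAC point model (bins over age at glycemic
# onset, weight change, and glucose change) is supported structurally via a
# user-supplied config; no default parameterization ships with the package.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Percent weight change over one year
#'
#' `100 * (current - previous) / previous`, rounded half away from zero to
#' an integer percent. Weight loss is negative by convention.
#'
#' @param current_lb,previous_lb weights in pounds; both strictly positive.
#' @return integer percent change.
#' @export
#' @examples
#' percent_weight_change(209, 242)  # -14
#' percent_weight_change(175, 183)  # -4
percent_weight_change <- function(current_lb, previous_lb) {
  if (any(is.na(c(current_lb, previous_lb))) ||
      current_lb <= 0 || previous_lb <= 0)
    stop("weights must be known and strictly positive", call. = FALSE)
  as.integer(round_half_away(100 * (current_lb - previous_lb) / previous_lb))
}

#' Can a respondent be assessed for the NOD criteria?
#'
#' A respondent who completed the NOD section is assessable iff the fasting
#' glucose answer is not "unknown" AND both weights were recalled. A
#' respondent who never completed the section is outside the assessability
#' denominator altogether (returns `FALSE`, but see
#' [cohort_flow()] for the funnel bookkeeping).
#'
#' @param r a [patient_response()].
#' @return logical.
#' @export
nod_assessable <- function(r) {
  nod <- r$nod
  nod$section_completed &&
    nod$glucose_elevated != "unknown" &&
    !is.na(nod$weight_current_lb) &&
    !is.na(nod$weight_one_year_ago_lb)
}

#' Assess the ENDPAC criteria for one respondent
#'
#' Verdict precedence:
#' \enumerate{
#'   \item `excluded_prior_pc` if the respondent already has a pancreatic
#'     cancer diagnosis (exclusion dominates everything);
#'   \item `not_assessable` if [nod_assessable()] is `FALSE`;
#'   \item `meets` iff weight change is negative (any self-reported loss; a
#'     stricter minimum can be set with `min_loss_pct`) AND glucose is
#'     reported elevated AND the glycemic change occurred around age 50 or
#'     later; otherwise `does_not_meet`.
#' }
#'
#' @param r a [patient_response()].
#' @param min_loss_pct minimum percent loss required to qualify; default 0
#'   means any loss (`weight_change_pct < 0`) qualifies.
#' @return an object of class `endpac_assessment`: `patient_id`,
#'   `assessable`, `weight_change_pct` (integer or `NA` when either weight
#'   is unknown), `glucose_flag` (logical or `NA`), `verdict`.
#' @export
meets_endpac_criteria <- function(r, min_loss_pct = 0) {
  stopifnot(inherits(r, "patient_response"))
  nod <- r$nod
  assessable <- nod_assessable(r)
  wc <- if (!is.na(nod$weight_current_lb) && !is.na(nod$weight_one_year_ago_lb))
    percent_weight_change(nod$weight_current_lb, nod$weight_one_year_ago_lb)
  else NA_integer_
  gf <- switch(nod$glucose_elevated, yes = TRUE, no = FALSE, NA)
  verdict <-
    if (r$preexisting_pancreatic_cancer) "excluded_prior_pc"
    else if (!assessable) "not_assessable"
    else if (wc < 0 && abs(wc) >= min_loss_pct && isTRUE(gf) &&
             identical(nod$glycemic_change_around_age_50_or_later, "yes"))
      "meets"
    else "does_not_meet"
  structure(
    list(patient_id = r$patient_id,
         assessable = assessable,
         weight_change_pct = wc,
         glucose_flag = gf,
         verdict = verdict),
    class = "endpac_assessment"
  )
}

#' @export
print.endpac_assessment <- function(x, ...) {
  cat(sprintf("<endpac_assessment> id=%s verdict=%s (weight change %s%%)\n",
              x$patient_id, x$verdict,
              if (is.na(x$weight_change_pct)) "?" else x$weight_change_pct))
  invisible(x)
}

#' Construct an ENDPAC point model from bins
#'
#' The full published ENDPAC model assigns points to bins of three
#' components: age at glycemic onset (years), percent weight change, and
#' glucose change (mg/dL). This package ships NO default parameterization;
#' the model must be supplied by the user, e.g. via
#' [load_endpac_model()]. Each `*_bins` argument is a data frame (or
#' coercible list) with columns `lower`, `upper` (half-open intervals
#' `[lower, upper)`, `-Inf`/`Inf` allowed) and `points` (integer).
#'
#' @param age_bins,weight_bins,glucose_bins bin tables as described.
#' @param threshold integer decision threshold on the summed score.
#' @return an object of class `endpac_point_model`.
#' @export
endpac_point_model <- function(age_bins, weight_bins, glucose_bins, threshold) {
  as_bins <- function(b, what) {
    b <- as.data.frame(b)
    if (!all(c("lower", "upper", "points") %in% names(b)))
      stop(what, " bins need columns lower, upper, points", call. = FALSE)
    b <- b[order(b$lower), ]
    if (any(b$lower >= b$upper))
      stop(what, " bins must have lower < upper", call. = FALSE)
    if (nrow(b) > 1L && any(b$upper[-nrow(b)] != b$lower[-1L]))
      stop(what, " bins must partition their domain (contiguous)", call. = FALSE)
    b$points <- as.integer(b$points)
    b
  }
  structure(
    list(age_bins = as_bins(age_bins, "age"),
         weight_bins = as_bins(weight_bins, "weight"),
         glucose_bins = as_bins(glucose_bins, "glucose"),
         threshold = as.integer(threshold)),
    class = "endpac_point_model"
  )
}

#' Load an ENDPAC point model from a JSON config
#'
#' @param path JSON file with keys `age_bins`, `weight_bins`, `glucose_bins`
#'   (arrays of `{lower, upper, points}` objects; `"-Inf"`/`"Inf"` strings
#'   allowed for open ends) and `threshold`.
#' @return an `endpac_point_model`.
#' @export
load_endpac_model <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  fix_inf <- function(b) {
    b$lower <- as.numeric(b$lower)
    b$upper <- as.numeric(b$upper)
    b
  }
  endpac_point_model(fix_inf(cfg$age_bins), fix_inf(cfg$weight_bins),
                     fix_inf(cfg$glucose_bins), cfg$threshold)
}

bin_points <- function(x, bins) {
  hit <- which(x >= bins$lower & x < bins$upper)
  if (length(hit) != 1L)
    stop("value ", x, " falls in ", length(hit), " bins", call. = FALSE)
  bins$points[hit]
}

#' Score the full ENDPAC point model
#'
#' Sums the bin points of the three components under a user-supplied model.
#' There is no shipped default: the published parameterization must be
#' provided as config (see Sharma et al. 2018, Gastroenterology, for the
#' original bins).
#'
#' @param age_at_onset age at glycemic onset in years.
#' @param weight_change_pct percent weight change (loss negative).
#' @param glucose_change glucose change in mg/dL.
#' @param model an [endpac_point_model()]; a missing model is a
#'   configuration error.
#' @return list with `score` (integer) and `above_threshold` (logical).
#' @export
endpac_score <- function(age_at_onset, weight_change_pct, glucose_change,
                         model) {
  if (missing(model) || is.null(model))
    stop("no ENDPAC point model supplied; provide the published ",
         "parameterization (Sharma et al. 2018) as a config via ",
         "endpac_point_model() or load_endpac_model()", call. = FALSE)
  stopifnot(inherits(model, "endpac_point_model"))
  s <- bin_points(age_at_onset, model$age_bins) +
    bin_points(weight_change_pct, model$weight_bins) +
    bin_points(glucose_change, model$glucose_bins)
  list(score = as.integer(s), above_threshold = s >= model$threshold)
}
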