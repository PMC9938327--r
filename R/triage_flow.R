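# Per-patient triage combining the two independent pathways (familial
# scoring -> genetic-counseling referral; ENDPAC criteria -> high-risk
# clinic enrollment) and cohort-level funnel counts.

#' Triage one respondent
#'
#' Evaluates both pathways independently: a respondent can trigger either,
#' both, or neither. Respondents with a pre-existing pancreatic cancer
#' diagnosis still receive familial scoring (a personal pancreatic history
#' scores 3 points like any other event) but are excluded from ENDPAC
#' enrollment.
#'
#' @param r a [patient_response()].
#' @param table a `point_table`.
#' @param min_loss_pct passed to [meets_endpac_criteria()].
#' @return an object of class `triage_outcome`: `patient_id`, `famhx_refer`,
#'   `score`, `endpac_verdict`, and `actions` (character vector; one or both
#'   of `"refer_genetic_counseling"`, `"enroll_high_risk_clinic"`, or
#'   `"none"`).
#' @export
triage_patient <- function(r, table = default_point_table(), min_loss_pct = 0) {
  sc <- score_family_history(r, table)
  ea <- meets_endpac_criteria(r, min_loss_pct = min_loss_pct)
  actions <- c(
    if (sc$refer) "refer_genetic_counseling",
    if (ea$verdict == "meets") "enroll_high_risk_clinic")
  if (is.null(actions)) actions <- "none"
  structure(
    list(patient_id = r$patient_id,
         famhx_refer = sc$refer,
         score = sc$total,
         endpac_verdict = ea$verdict,
         actions = actions),
    class = "triage_outcome"
  )
}

#' Triage a cohort into a per-patient table
#'
#' @param cohort list of [patient_response()] objects.
#' @inheritParams triage_patient
#' @return data frame with columns `patient_id`, `score`, `famhx_refer`,
#'   `endpac_verdict`, `actions` (`;`-joined).
#' @export
triage_cohort <- function(cohort, table = default_point_table(),
                          min_loss_pct = 0) {
  out <- lapply(cohort, triage_patient, table = table,
                min_loss_pct = min_loss_pct)
  data.frame(
    patient_id = vapply(out, `[[`, character(1), "patient_id"),
    score = vapply(out, `[[`, integer(1), "score"),
    famhx_refer = vapply(out, `[[`, logical(1), "famhx_refer"),
    endpac_verdict = vapply(out, `[[`, character(1), "endpac_verdict"),
    actions = vapply(out, function(o) paste(o$actions, collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE)
}

#' Cohort funnel counts
#'
#' Deterministic tallies of the outcome funnel: every respondent is counted
#' exactly once per stratum. The NOD strata nest as
#' `n_nod_section_completed = n_nod_assessable + n_nod_unknown_glucose +
#' (glucose-known respondents with an unrecalled weight)`;
#' `n_nod_unknown_weight` counts all completed respondents missing a weight
#' regardless of the glucose answer, so it can overlap
#' `n_nod_unknown_glucose`.
#'
#' @param cohort list of [patient_response()] objects.
#' @inheritParams triage_patient
#' @return an object of class `flow_counts` (a named integer list):
#'   `n_total`, `n_score_ge_threshold`, `n_score_lt_threshold`,
#'   `n_prior_genetic_testing`, `n_preexisting_pc`,
#'   `n_nod_section_completed`, `n_nod_unknown_glucose`,
#'   `n_nod_unknown_weight`, `n_nod_assessable`, `n_endpac_met`.
#' @export
#' @examples
#' cohort_flow(fixture_cohort())$n_score_ge_threshold  # 117
cohort_flow <- function(cohort, table = default_point_table(),
                        min_loss_pct = 0) {
  n <- length(cohort)
  scores <- vapply(cohort, function(r)
    score_family_history(r, table)$total, integer(1))
  ge <- sum(scores >= table$referral_threshold)
  verdicts <- vapply(cohort, function(r)
    meets_endpac_criteria(r, min_loss_pct = min_loss_pct)$verdict, character(1))
  completed <- vapply(cohort, function(r) r$nod$section_completed, logical(1))
  gl_unknown <- completed & vapply(cohort, function(r)
    r$nod$glucose_elevated == "unknown", logical(1))
  wt_unknown <- completed & vapply(cohort, function(r)
    is.na(r$nod$weight_current_lb) || is.na(r$nod$weight_one_year_ago_lb),
    logical(1))
  assessable <- vapply(cohort, nod_assessable, logical(1))
  structure(
    list(n_total = n,
         n_score_ge_threshold = as.integer(ge),
         n_score_lt_threshold = as.integer(n - ge),
         n_prior_genetic_testing = sum(vapply(cohort, function(r)
           r$prior_genetic_testing, logical(1))),
         n_preexisting_pc = sum(vapply(cohort, function(r)
           r$preexisting_pancreatic_cancer, logical(1))),
         n_nod_section_completed = sum(completed),
         n_nod_unknown_glucose = sum(gl_unknown),
         n_nod_unknown_weight = sum(wt_unknown),
         n_nod_assessable = sum(assessable),
         n_endpac_met = sum(verdicts == "meets")),
    class = "flow_counts"
  )
}

#' @export
print.flow_counts <- function(x, ...) {
  cat("<flow_counts>\n")
  for (f in names(x)) cat(sprintf("  %-26s %d\n", f, x[[f]]))
  invisible(x)
}
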