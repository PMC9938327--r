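# Questionnaire data model: controlled vocabularies, record constructors,
# and per-record validation.

#' Controlled vocabularies for the questionnaire schema
#'
#' @description
#' The questionnaire captures first-degree family cancer history (self,
#' mother, father, siblings), per-event cancer types from a fixed
#' vocabulary, and tri-state answers where "unknown" is a first-class value
#' distinct from "no". These constants define the legal values; every
#' constructor and validator checks against them.
#'
#' @name pcrt-vocab
#' @keywords internal
NULL

CANCER_TYPES <- c("pancreatic", "breast", "ovarian", "colorectal",
                  "prostate", "thyroid", "melanoma", "other")
RELATIONS <- c("self", "mother", "father", "sibling")
TRISTATE <- c("yes", "no", "unknown")
SEXES <- c("female", "male")
ETHNICITIES <- c("White", "African American", "Asian", "Other")

is_tristate <- function(x) is.character(x) && length(x) == 1L && x %in% TRISTATE

#' Create a cancer event
#'
#' One diagnosed cancer on one person. `dx_at_or_before_50` is the
#' questionnaire's age flag ("Was ... diagnosed ... before or at the age of
#' 50?"); "unknown" means the respondent could not say, and is never treated
#' as "no" downstream.
#'
#' @param cancer_type one of `"pancreatic"`, `"breast"`, `"ovarian"`,
#'   `"colorectal"`, `"prostate"`, `"thyroid"`, `"melanoma"`, `"other"`.
#' @param dx_at_or_before_50 `"yes"`, `"no"` or `"unknown"`.
#' @param label free text naming an `"other"` cancer; ignored otherwise.
#' @return an object of class `cancer_event`.
#' @export
#' @examples
#' cancer_event("breast", dx_at_or_before_50 = "yes")
cancer_event <- function(cancer_type, dx_at_or_before_50 = "unknown",
                         label = NA_character_) {
  stopifnot(is.character(cancer_type), length(cancer_type) == 1L)
  if (!cancer_type %in% CANCER_TYPES)
    stop("unknown cancer_type: ", cancer_type, call. = FALSE)
  if (!is_tristate(dx_at_or_before_50))
    stop("dx_at_or_before_50 must be yes/no/unknown", call. = FALSE)
  structure(
    list(cancer_type = cancer_type,
         dx_at_or_before_50 = dx_at_or_before_50,
         label = as.character(label)),
    class = "cancer_event"
  )
}

#' Create a person history
#'
#' Cancer history of the respondent (`relation = "self"`) or of one
#' first-degree relative. Multiple siblings are distinguished by
#' `relation_index`; multiple cancers on the same person are separate
#' [cancer_event()]s and score independently.
#'
#' @param relation `"self"`, `"mother"`, `"father"` or `"sibling"`.
#' @param events list of [cancer_event()] objects (possibly empty).
#' @param relation_index positive integer distinguishing multiple siblings.
#' @return an object of class `person_history`.
#' @export
person_history <- function(relation, events = list(), relation_index = 1L) {
  if (!relation %in% RELATIONS)
    stop("unknown relation: ", relation, call. = FALSE)
  stopifnot(is.list(events))
  for (e in events)
    if (!inherits(e, "cancer_event")) stop("events must be cancer_event objects")
  structure(
    list(relation = relation,
         relation_index = as.integer(relation_index),
         events = events),
    class = "person_history"
  )
}

#' Create the new-onset-diabetes (NOD) answer block
#'
#' Self-reported items used by the ENDPAC-criteria triage: current weight,
#' weight one year ago (pounds; `NA` = could not recall), whether fasting
#' blood glucose has been higher than normal, and whether the glycemic
#' change occurred around the age of 50 or later. `section_completed`
#' records whether the respondent answered this section at all; respondents
#' with `section_completed = FALSE` fall outside the assessability funnel
#' denominator.
#'
#' @param section_completed logical; did the respondent complete the section?
#' @param weight_current_lb current weight in pounds, or `NA` if unknown.
#' @param weight_one_year_ago_lb weight one year ago in pounds, or `NA`.
#' @param glucose_elevated tri-state: fasting glucose higher than normal?
#' @param diabetes_or_glucose_intolerance logical; known diabetes or glucose
#'   intolerance (a Table-1 descriptive variable, not part of the triage rule).
#' @param glycemic_change_around_age_50_or_later tri-state questionnaire item.
#' @return an object of class `nod_responses`.
#' @export
nod_responses <- function(section_completed = TRUE,
                          weight_current_lb = NA_real_,
                          weight_one_year_ago_lb = NA_real_,
                          glucose_elevated = "unknown",
                          diabetes_or_glucose_intolerance = FALSE,
                          glycemic_change_around_age_50_or_later = "unknown") {
  if (!is_tristate(glucose_elevated))
    stop("glucose_elevated must be yes/no/unknown", call. = FALSE)
  if (!is_tristate(glycemic_change_around_age_50_or_later))
    stop("glycemic_change_around_age_50_or_later must be yes/no/unknown",
         call. = FALSE)
  structure(
    list(section_completed = isTRUE(section_completed),
         weight_current_lb = as.numeric(weight_current_lb),
         weight_one_year_ago_lb = as.numeric(weight_one_year_ago_lb),
         glucose_elevated = glucose_elevated,
         diabetes_or_glucose_intolerance = isTRUE(diabetes_or_glucose_intolerance),
         glycemic_change_around_age_50_or_later =
           glycemic_change_around_age_50_or_later),
    class = "nod_responses"
  )
}

#' Create a full questionnaire record
#'
#' One respondent: demographics, Ashkenazi ancestry per parent (scored once
#' as a flat bonus), personal and family cancer histories, and the NOD
#' answer block.
#'
#' @param patient_id opaque identifier, unique within a cohort.
#' @param age age in years (study eligibility requires >= 18).
#' @param sex `"female"` or `"male"`.
#' @param ethnicity one of `"White"`, `"African American"`, `"Asian"`, `"Other"`.
#' @param ashkenazi_mother,ashkenazi_father tri-state ancestry flags.
#' @param current_smoker,prior_genetic_testing,preexisting_pancreatic_cancer
#'   logical flags.
#' @param persons list of [person_history()]; must contain exactly one
#'   `"self"` entry.
#' @param nod a [nod_responses()] object.
#' @return an object of class `patient_response`.
#' @export
#' @examples
#' patient_response("P1", age = 60, sex = "female",
#'   persons = list(
#'     person_history("self"),
#'     person_history("mother", list(cancer_event("pancreatic")))))
patient_response <- function(patient_id, age, sex,
                             ethnicity = "White",
                             ashkenazi_mother = "unknown",
                             ashkenazi_father = "unknown",
                             current_smoker = FALSE,
                             prior_genetic_testing = FALSE,
                             preexisting_pancreatic_cancer = FALSE,
                             persons = list(person_history("self")),
                             nod = nod_responses(section_completed = FALSE)) {
  structure(
    list(patient_id = as.character(patient_id),
         age = as.integer(age),
         sex = as.character(sex),
         ethnicity = as.character(ethnicity),
         ashkenazi_mother = as.character(ashkenazi_mother),
         ashkenazi_father = as.character(ashkenazi_father),
         current_smoker = isTRUE(current_smoker),
         prior_genetic_testing = isTRUE(prior_genetic_testing),
         preexisting_pancreatic_cancer = isTRUE(preexisting_pancreatic_cancer),
         persons = persons,
         nod = nod),
    class = "patient_response"
  )
}

#' @export
print.patient_response <- function(x, ...) {
  n_events <- sum(vapply(x$persons, function(p) length(p$events), integer(1)))
  cat(sprintf("<patient_response> id=%s age=%d sex=%s events=%d nod=%s\n",
              x$patient_id, x$age, x$sex, n_events,
              if (x$nod$section_completed) "completed" else "not completed"))
  invisible(x)
}

issue <- function(field, severity, message) {
  data.frame(field = field, severity = severity, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a questionnaire record
#'
#' Checks a single record against the schema invariants. Problems are
#' reported, never raised: the result carries a data frame of issues with
#' `severity` `"error"` or `"warning"`. An empty issue table means the
#' record is fully conformant.
#'
#' Checks: age >= 18 (eligibility), strictly positive known weights, exactly
#' one `self` history, at most one history per (relation, index), and
#' membership of every enum-valued field in its vocabulary.
#'
#' @param r a [patient_response()].
#' @return an object of class `validation_report` with elements
#'   `patient_id`, `issues` (data frame) and `valid` (no error-severity
#'   issues).
#' @export
validate_response <- function(r) {
  stopifnot(inherits(r, "patient_response"))
  iss <- list()
  add <- function(x) iss[[length(iss) + 1L]] <<- x

  if (is.na(r$age) || r$age < 18L)
    add(issue("age", "error", "age must be >= 18 (study eligibility)"))
  if (!r$sex %in% SEXES)
    add(issue("sex", "error", paste0("sex not in vocabulary: ", r$sex)))
  if (!r$ethnicity %in% ETHNICITIES)
    add(issue("ethnicity", "error",
              paste0("ethnicity not in vocabulary: ", r$ethnicity)))
  for (f in c("ashkenazi_mother", "ashkenazi_father")) {
    if (!r[[f]] %in% TRISTATE)
      add(issue(f, "error", paste0(f, " must be yes/no/unknown")))
  }

  rels <- vapply(r$persons, function(p) p$relation, character(1))
  idxs <- vapply(r$persons, function(p) p$relation_index, integer(1))
  if (sum(rels == "self") != 1L)
    add(issue("persons", "error", "record must have exactly one self history"))
  key <- paste(rels, idxs)
  if (anyDuplicated(key))
    add(issue("persons", "error",
              "duplicate (relation, relation_index) person history"))
  for (p in r$persons) {
    for (e in p$events) {
      if (!e$cancer_type %in% CANCER_TYPES)
        add(issue("persons", "error",
                  paste0("cancer_type not in vocabulary: ", e$cancer_type)))
      if (!e$dx_at_or_before_50 %in% TRISTATE)
        add(issue("persons", "error", "dx_at_or_before_50 must be yes/no/unknown"))
    }
  }

  nod <- r$nod
  for (f in c("weight_current_lb", "weight_one_year_ago_lb")) {
    w <- nod[[f]]
    if (!is.na(w) && w <= 0)
      add(issue(f, "error", paste0(f, " must be strictly positive when known")))
  }
  if (nod$section_completed) {
    if (!nod$glucose_elevated %in% TRISTATE)
      add(issue("glucose_elevated", "error", "must be yes/no/unknown"))
  }

  issues <- if (length(iss)) do.call(rbind, iss) else
    issue(character(0), character(0), character(0))
  structure(
    list(patient_id = r$patient_id, issues = issues,
         valid = !any(issues$severity == "error")),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> id=%s %s\n", x$patient_id,
              if (x$valid) "OK" else paste0(nrow(x$issues), " issue(s)")))
  if (nrow(x$issues)) print(x$issues)
  invisible(x)
}

#' Validate a cohort
#'
#' Runs [validate_response()] on every record and additionally enforces
#' cohort-level uniqueness of `patient_id`.
#'
#' @param cohort list of [patient_response()] objects.
#' @return list of `validation_report`s, one per record; duplicate ids are
#'   an error.
#' @export
validate_cohort <- function(cohort) {
  ids <- vapply(cohort, function(r) r$patient_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate patient_id in cohort: ", paste(dup, collapse = ", "),
         call. = FALSE)
  lapply(cohort, validate_response)
}
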