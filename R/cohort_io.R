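# Cohort serialization. Two dialects:
#   JSON: one document per cohort, {"respondents": [...]}; lossless.
#   CSV:  one row per respondent; repeated-group columns
#         mother_cancer1_type, mother_cancer1_le50, ..., sibling2_cancer1_type, ...;
#         empty string = unknown (tri-states) / not recorded (weights).
# A machine-readable JSON Schema for the JSON dialect ships in
# inst/extdata/pcrt-schema.json.

tristate_to_cell <- function(x) if (identical(x, "unknown")) "" else x
cell_to_tristate <- function(x) {
  x <- trimws(as.character(x))
  if (is.na(x) || x == "") "unknown" else x
}
bool_to_cell <- function(x) if (isTRUE(x)) "true" else "false"
cell_to_bool <- function(x) {
  x <- tolower(trimws(as.character(x)))
  !is.na(x) && x %in% c("true", "1", "yes", "t")
}
num_to_cell <- function(x) if (is.na(x)) "" else format(x, scientific = FALSE)
cell_to_num <- function(x) {
  x <- trimws(as.character(x))
  if (is.na(x) || x == "") NA_real_ else as.numeric(x)
}

response_to_list <- function(r) {
  list(
    patient_id = r$patient_id,
    age = r$age,
    sex = r$sex,
    ethnicity = r$ethnicity,
    ashkenazi_mother = r$ashkenazi_mother,
    ashkenazi_father = r$ashkenazi_father,
    current_smoker = r$current_smoker,
    prior_genetic_testing = r$prior_genetic_testing,
    preexisting_pancreatic_cancer = r$preexisting_pancreatic_cancer,
    persons = lapply(r$persons, function(p) {
      list(relation = p$relation,
           relation_index = p$relation_index,
           events = lapply(p$events, function(e) {
             list(cancer_type = e$cancer_type,
                  dx_at_or_before_50 = e$dx_at_or_before_50,
                  label = if (is.na(e$label)) NULL else e$label)
           }))
    }),
    nod = {
      n <- unclass(r$nod)
      # unknown weights serialize as JSON null, not the string "NA"
      for (f in c("weight_current_lb", "weight_one_year_ago_lb"))
        if (is.na(n[[f]])) n[f] <- list(NULL)
      n
    }
  )
}

list_to_response <- function(x, record_no = NA_integer_) {
  need <- c("patient_id", "age", "sex", "persons", "nod")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("record ", record_no, ": missing field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  persons <- lapply(x$persons, function(p) {
    person_history(
      relation = p$relation,
      relation_index = if (is.null(p$relation_index)) 1L else p$relation_index,
      events = lapply(p$events, function(e) {
        cancer_event(e$cancer_type,
                     dx_at_or_before_50 = e$dx_at_or_before_50 %||% "unknown",
                     label = e$label %||% NA_character_)
      }))
  })
  n <- x$nod
  patient_response(
    patient_id = x$patient_id,
    age = x$age,
    sex = x$sex,
    ethnicity = x$ethnicity %||% "Other",
    ashkenazi_mother = x$ashkenazi_mother %||% "unknown",
    ashkenazi_father = x$ashkenazi_father %||% "unknown",
    current_smoker = isTRUE(x$current_smoker),
    prior_genetic_testing = isTRUE(x$prior_genetic_testing),
    preexisting_pancreatic_cancer = isTRUE(x$preexisting_pancreatic_cancer),
    persons = persons,
    nod = nod_responses(
      section_completed = isTRUE(n$section_completed),
      weight_current_lb = if (is.null(n$weight_current_lb)) NA_real_ else n$weight_current_lb,
      weight_one_year_ago_lb = if (is.null(n$weight_one_year_ago_lb)) NA_real_ else n$weight_one_year_ago_lb,
      glucose_elevated = n$glucose_elevated %||% "unknown",
      diabetes_or_glucose_intolerance = isTRUE(n$diabetes_or_glucose_intolerance),
      glycemic_change_around_age_50_or_later =
        n$glycemic_change_around_age_50_or_later %||% "unknown")
  )
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

BASE_CSV_COLS <- c("patient_id", "age", "sex", "ethnicity",
                   "ashkenazi_mother", "ashkenazi_father",
                   "current_smoker", "prior_genetic_testing",
                   "preexisting_pancreatic_cancer",
                   "nod_section_completed",
                   "weight_current_lb", "weight_one_year_ago_lb",
                   "glucose_elevated", "diabetes_or_glucose_intolerance",
                   "glycemic_change_around_age_50_or_later")

person_prefix <- function(relation, relation_index) {
  if (relation == "sibling") paste0("sibling", relation_index) else relation
}

cohort_to_frame <- function(cohort) {
  # column layout driven by maxima across the cohort
  max_events <- c(self = 0L, mother = 0L, father = 0L)
  max_sib <- 0L
  max_sib_events <- 0L
  for (r in cohort) for (p in r$persons) {
    ne <- length(p$events)
    if (p$relation == "sibling") {
      max_sib <- max(max_sib, p$relation_index)
      max_sib_events <- max(max_sib_events, ne)
    } else {
      max_events[p$relation] <- max(max_events[p$relation], ne)
    }
  }
  prefixes <- c("self", "mother", "father",
                if (max_sib > 0L) paste0("sibling", seq_len(max_sib)))
  slots <- c(max_events, rep(max_sib_events, max_sib))
  names(slots) <- prefixes

  event_cols <- character(0)
  for (pf in prefixes) {
    k <- slots[[pf]]
    if (k > 0L)
      event_cols <- c(event_cols, as.vector(rbind(
        paste0(pf, "_cancer", seq_len(k), "_type"),
        paste0(pf, "_cancer", seq_len(k), "_le50"),
        paste0(pf, "_cancer", seq_len(k), "_label"))))
  }
  cols <- c(BASE_CSV_COLS, event_cols)

  rows <- lapply(cohort, function(r) {
    row <- stats::setNames(as.list(rep("", length(cols))), cols)
    row$patient_id <- r$patient_id
    row$age <- as.character(r$age)
    row$sex <- r$sex
    row$ethnicity <- r$ethnicity
    row$ashkenazi_mother <- tristate_to_cell(r$ashkenazi_mother)
    row$ashkenazi_father <- tristate_to_cell(r$ashkenazi_father)
    row$current_smoker <- bool_to_cell(r$current_smoker)
    row$prior_genetic_testing <- bool_to_cell(r$prior_genetic_testing)
    row$preexisting_pancreatic_cancer <- bool_to_cell(r$preexisting_pancreatic_cancer)
    row$nod_section_completed <- bool_to_cell(r$nod$section_completed)
    row$weight_current_lb <- num_to_cell(r$nod$weight_current_lb)
    row$weight_one_year_ago_lb <- num_to_cell(r$nod$weight_one_year_ago_lb)
    row$glucose_elevated <- tristate_to_cell(r$nod$glucose_elevated)
    row$diabetes_or_glucose_intolerance <-
      bool_to_cell(r$nod$diabetes_or_glucose_intolerance)
    row$glycemic_change_around_age_50_or_later <-
      tristate_to_cell(r$nod$glycemic_change_around_age_50_or_later)
    for (p in r$persons) {
      pf <- person_prefix(p$relation, p$relation_index)
      for (k in seq_along(p$events)) {
        e <- p$events[[k]]
        row[[paste0(pf, "_cancer", k, "_type")]] <- e$cancer_type
        row[[paste0(pf, "_cancer", k, "_le50")]] <-
          tristate_to_cell(e$dx_at_or_before_50)
        row[[paste0(pf, "_cancer", k, "_label")]] <-
          if (is.na(e$label)) "" else e$label
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE, check.names = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                  check.names = FALSE)
}

frame_to_cohort <- function(df) {
  miss <- setdiff(BASE_CSV_COLS, names(df))
  if (length(miss))
    stop("CSV is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ev_cols <- grep("^(self|mother|father|sibling[0-9]+)_cancer[0-9]+_type$",
                  names(df), value = TRUE)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    persons <- list()
    # collect events per person prefix, in column order
    by_prefix <- split(ev_cols, sub("_cancer[0-9]+_type$", "", ev_cols))
    # keep stable ordering: self, mother, father, sibling1, sibling2, ...
    ord <- c("self", "mother", "father",
             sort(grep("^sibling", names(by_prefix), value = TRUE)))
    ord <- ord[ord %in% names(by_prefix) | ord == "self"]
    for (pf in unique(c("self", ord))) {
      type_cols <- by_prefix[[pf]]
      events <- list()
      for (tc in type_cols) {
        typ <- trimws(as.character(row[[tc]]))
        if (is.na(typ) || typ == "") next
        stem <- sub("_type$", "", tc)
        lab <- trimws(as.character(row[[paste0(stem, "_label")]] %||% ""))
        events[[length(events) + 1L]] <- cancer_event(
          typ,
          dx_at_or_before_50 = cell_to_tristate(row[[paste0(stem, "_le50")]]),
          label = if (is.na(lab) || lab == "") NA_character_ else lab)
      }
      if (pf == "self" || length(events)) {
        relation <- sub("[0-9]+$", "", pf)
        idx <- if (grepl("^sibling", pf))
          as.integer(sub("^sibling", "", pf)) else 1L
        persons[[length(persons) + 1L]] <-
          person_history(relation, events, relation_index = idx)
      }
    }
    patient_response(
      patient_id = as.character(row$patient_id),
      age = as.integer(row$age),
      sex = as.character(row$sex),
      ethnicity = as.character(row$ethnicity),
      ashkenazi_mother = cell_to_tristate(row$ashkenazi_mother),
      ashkenazi_father = cell_to_tristate(row$ashkenazi_father),
      current_smoker = cell_to_bool(row$current_smoker),
      prior_genetic_testing = cell_to_bool(row$prior_genetic_testing),
      preexisting_pancreatic_cancer = cell_to_bool(row$preexisting_pancreatic_cancer),
      persons = persons,
      nod = nod_responses(
        section_completed = cell_to_bool(row$nod_section_completed),
        weight_current_lb = cell_to_num(row$weight_current_lb),
        weight_one_year_ago_lb = cell_to_num(row$weight_one_year_ago_lb),
        glucose_elevated = cell_to_tristate(row$glucose_elevated),
        diabetes_or_glucose_intolerance =
          cell_to_bool(row$diabetes_or_glucose_intolerance),
        glycemic_change_around_age_50_or_later =
          cell_to_tristate(row$glycemic_change_around_age_50_or_later))
    )
  })
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("json", "csv")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "csv")) ext else
    stop("cannot infer format from extension '", ext,
         "'; pass format = \"json\" or \"csv\"", call. = FALSE)
}

#' Read a questionnaire cohort from disk
#'
#' Reads a cohort written by [write_cohort()] (or hand-authored in either
#' dialect). Blank CSV cells for tri-state items map to `"unknown"`, never
#' to `"no"`; blank weight cells map to `NA` (not recalled).
#'
#' @param path file path.
#' @param format `"json"` or `"csv"`; inferred from the extension if `NULL`.
#' @return list of [patient_response()] objects.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- infer_format(path, format)
  cohort <- if (format == "json") {
    doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                    error = function(e)
                      stop("malformed JSON in ", path, ": ",
                           conditionMessage(e), call. = FALSE))
    if (is.null(doc$respondents))
      stop("JSON cohort must be an object with a 'respondents' array",
           call. = FALSE)
    lapply(seq_along(doc$respondents), function(i)
      list_to_response(doc$respondents[[i]], record_no = i))
  } else {
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
    frame_to_cohort(df)
  }
  ids <- vapply(cohort, function(r) r$patient_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate patient_id in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  cohort
}

#' Write a questionnaire cohort to disk
#'
#' The JSON dialect is lossless. The CSV dialect flattens repeated groups
#' into numbered columns (`mother_cancer1_type`, `mother_cancer1_le50`,
#' `mother_cancer1_label`, ..., `sibling2_cancer1_type`, ...); relatives
#' without any cancer event occupy no columns, so records should be in
#' canonical form (no event-less relative entries) for an exact round trip.
#'
#' @param cohort list of [patient_response()] objects.
#' @param path destination file path.
#' @param format `"json"` or `"csv"`; inferred from the extension if `NULL`.
#' @return invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, format = NULL) {
  format <- infer_format(path, format)
  if (format == "json") {
    doc <- list(respondents = lapply(cohort, response_to_list))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    df <- cohort_to_frame(cohort)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
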