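# Point-based familial cancer-risk scoring with a genetic-counseling
# referral threshold.
#
# The rule is an integer sum over every reported cancer event on the
# respondent and their first-degree relatives: each cancer type has a base
# point value, breast cancer carries an extra age modifier when diagnosed at
# or before age 50, and Ashkenazi ancestry in either parent adds one flat
# bonus. Personal and family events score identically. A total at or above
# the referral threshold (default 3) indicates referral to genetic
# counseling.

#' Default scoring table
#'
#' Returns the package's default point table: pancreatic = 3, ovarian = 3,
#' thyroid = 2, breast = 1 (+2 when diagnosed at or before 50), colorectal =
#' 1, prostate = 1, melanoma = 1, other = 0; a flat Ashkenazi ancestry bonus
#' of 2 applied once if either parent is of Ashkenazi descent; referral
#' threshold 3. Only breast carries an age modifier. This is the minimal
#' small-integer completion consistent with the published worked-example
#' scores; the thyroid/ovarian split (2/3) follows the relative weighting of
#' NCCN-style referral criteria and is config-overridable (see
#' [load_point_table()]).
#'
#' @return an object of class `point_table` with fields `base_points`,
#'   `age_modifier_points` (both named integer vectors over the cancer
#'   vocabulary), `ancestry_bonus` and `referral_threshold`.
#' @export
#' @examples
#' t <- default_point_table()
#' t$base_points[["pancreatic"]]   # 3
default_point_table <- function() {
  base <- c(pancreatic = 3L, breast = 1L, ovarian = 3L, colorectal = 1L,
            prostate = 1L, thyroid = 2L, melanoma = 1L, other = 0L)
  mod <- stats::setNames(integer(length(CANCER_TYPES)), CANCER_TYPES)
  mod[["breast"]] <- 2L
  point_table(base_points = base, age_modifier_points = mod,
              ancestry_bonus = 2L, referral_threshold = 3L)
}

#' Construct a scoring table
#'
#' @param base_points named non-negative integer vector, one entry per
#'   cancer type in the vocabulary.
#' @param age_modifier_points named non-negative integer vector; added to an
#'   event's points when `dx_at_or_before_50 == "yes"`. Types absent from
#'   the vector default to 0.
#' @param ancestry_bonus non-negative integer added once when either parent
#'   is flagged Ashkenazi.
#' @param referral_threshold positive integer; total >= threshold triggers
#'   referral.
#' @return an object of class `point_table`.
#' @export
point_table <- function(base_points, age_modifier_points = NULL,
                        ancestry_bonus = 0L, referral_threshold = 3L) {
  base_points <- vapply(base_points, as.integer, integer(1))
  if (is.null(age_modifier_points))
    age_modifier_points <- stats::setNames(integer(length(base_points)),
                                           names(base_points))
  age_modifier_points <- vapply(age_modifier_points, as.integer, integer(1))
  ancestry_bonus <- as.integer(ancestry_bonus)
  referral_threshold <- as.integer(referral_threshold)
  if (any(base_points < 0L) || any(age_modifier_points < 0L) ||
      ancestry_bonus < 0L)
    stop("point values must be non-negative integers", call. = FALSE)
  if (referral_threshold < 1L)
    stop("referral_threshold must be >= 1", call. = FALSE)
  structure(
    list(base_points = base_points,
         age_modifier_points = age_modifier_points,
         ancestry_bonus = ancestry_bonus,
         referral_threshold = referral_threshold),
    class = "point_table"
  )
}

#' Load a scoring table from a JSON config file
#'
#' The file is a flat JSON object with keys `base_points` (object mapping
#' cancer type to integer), `age_modifier_points` (object, optional),
#' `ancestry_bonus` and `referral_threshold`.
#'
#' @param path path to the JSON config.
#' @return a `point_table`.
#' @export
load_point_table <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  point_table(
    base_points = unlist(cfg$base_points),
    age_modifier_points = if (!is.null(cfg$age_modifier_points))
      unlist(cfg$age_modifier_points),
    ancestry_bonus = cfg$ancestry_bonus %||% 0L,
    referral_threshold = cfg$referral_threshold %||% 3L)
}

person_label <- function(p) {
  if (p$relation == "sibling" && p$relation_index > 1L)
    paste0("sibling ", p$relation_index) else p$relation
}

#' Score a respondent's personal and family cancer history
#'
#' Computes the familial risk total as the sum, over all persons and events,
#' of base points plus the age modifier when the event was diagnosed at or
#' before age 50 (`dx_at_or_before_50 == "yes"`; an unknown diagnosis age
#' scores base points only), plus the flat ancestry bonus if either parent
#' is flagged Ashkenazi. The referral decision is `total >=
#' referral_threshold`.
#'
#' @param r a [patient_response()].
#' @param table a `point_table`; defaults to [default_point_table()].
#' @return an object of class `risk_score_result`: `patient_id`, `total`,
#'   `refer`, and `contributions` (data frame with columns `person`,
#'   `source`, `points` itemizing every addend, persons in input order, then
#'   ancestry).
#' @export
#' @examples
#' r <- patient_response("P1", 60, "female", persons = list(
#'   person_history("self"),
#'   person_history("mother", list(cancer_event("pancreatic")))))
#' score_family_history(r)$total   # 3
score_family_history <- function(r, table = default_point_table()) {
  stopifnot(inherits(r, "patient_response"), inherits(table, "point_table"))
  rows <- list()
  for (p in r$persons) {
    for (e in p$events) {
      if (!e$cancer_type %in% names(table$base_points))
        stop("cancer_type '", e$cancer_type, "' is not in the point table",
             call. = FALSE)
      pts <- table$base_points[[e$cancer_type]]
      src <- e$cancer_type
      if (identical(e$dx_at_or_before_50, "yes")) {
        amod <- table$age_modifier_points[e$cancer_type]
        amod <- if (is.na(amod)) 0L else as.integer(amod)
        pts <- pts + amod
        if (amod > 0L) src <- paste0(src, " (dx at/before 50)")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        person = person_label(p), source = src, points = pts,
        stringsAsFactors = FALSE)
    }
  }
  if (r$ashkenazi_mother == "yes" || r$ashkenazi_father == "yes")
    rows[[length(rows) + 1L]] <- data.frame(
      person = "parents", source = "ancestry", points = table$ancestry_bonus,
      stringsAsFactors = FALSE)
  contributions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(person = character(0), source = character(0),
               points = integer(0), stringsAsFactors = FALSE)
  total <- as.integer(sum(contributions$points))
  structure(
    list(patient_id = r$patient_id,
         total = total,
         refer = total >= table$referral_threshold,
         contributions = contributions,
         threshold = table$referral_threshold),
    class = "risk_score_result"
  )
}

#' Render a human-readable score itemization
#'
#' One line per contribution (persons in input order, ancestry last) plus a
#' total line; the rendered points always sum to `res$total`.
#'
#' @param res a `risk_score_result` from [score_family_history()].
#' @return character vector of lines.
#' @export
explain_score <- function(res) {
  stopifnot(inherits(res, "risk_score_result"))
  k <- nrow(res$contributions)
  lines <- if (k == 0L) "no scoring factors" else
    sprintf("%s: %s = %d point%s",
            res$contributions$person, res$contributions$source,
            res$contributions$points,
            ifelse(res$contributions$points == 1L, "", "s"))
  c(lines,
    sprintf("total = %d (referral %s, threshold %d)",
            res$total, if (res$refer) "indicated" else "not indicated",
            res$threshold))
}

#' @export
print.risk_score_result <- function(x, ...) {
  cat(sprintf("<risk_score_result> id=%s\n", x$patient_id))
  cat(paste0("  ", explain_score(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Score every respondent in a cohort
#'
#' @param cohort list of [patient_response()] objects.
#' @param table a `point_table`.
#' @return data frame with one row per respondent: `patient_id`, `total`,
#'   `refer`.
#' @export
score_cohort <- function(cohort, table = default_point_table()) {
  res <- lapply(cohort, score_family_history, table = table)
  data.frame(
    patient_id = vapply(res, `[[`, character(1), "patient_id"),
    total = vapply(res, `[[`, integer(1), "total"),
    refer = vapply(res, `[[`, logical(1), "refer"),
    stringsAsFactors = FALSE)
}
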