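# Synthetic questionnaire cohorts.
#
# Two generators:
#   generate_cohort(cfg) — random cohorts with configurable prevalences,
#     one top-level seed, per-respondent substreams derived by counter so
#     that inserting a respondent never perturbs the others;
#   fixture_cohort() — a deterministic 453-record cohort whose funnel
#     tallies under default triage exactly reproduce the published counts
#     (117 high-risk; 18 prior testing; 6 pre-existing pancreatic cancer;
#     348 NOD-section completed; 128 glucose-unknown with 16 weight-unknown
#     nested inside; 220 assessable; 4 meeting ENDPAC criteria), and which
#     contains the six published worked-example patients verbatim.

#' Cohort simulation configuration
#'
#' Defaults emulate the marginal frequencies of a GI-outpatient screening
#' cohort: n = 453 respondents, 55.4% female, ages centred on a median of
#' ~65, ~19% with a personal cancer history, ~5% Ashkenazi ancestry, 76.8%
#' completing the NOD section, 36.8% of completers unable to answer the
#' glucose item, and 12.5% of those additionally unable to recall their
#' weight (the weight-unknown stratum nests inside the glucose-unknown
#' stratum).
#'
#' @param n cohort size.
#' @param seed top-level integer seed; respondent i draws from a substream
#'   keyed by `(seed, i)`.
#' @param event_probs named list `relation -> named numeric vector` of
#'   per-cancer event probabilities (independent Bernoulli per type).
#' @param p_dx_le50 probability that an event is flagged diagnosed at or
#'   before 50, given the flag is known.
#' @param p_dx_age_unknown probability the age flag is "unknown".
#' @param sibling_lambda Poisson mean number of siblings (truncated at 4).
#' @param ashkenazi_prevalence probability of any Ashkenazi ancestry;
#'   attributed to mother/father/both with probabilities 0.4/0.4/0.2.
#' @param nod_section_completion_rate probability the NOD section is
#'   completed.
#' @param glucose_unknown_rate P(glucose answer unknown | section completed).
#' @param weight_unknown_rate P(weight one year ago not recalled | glucose
#'   unknown) — nested, per the funnel reconciliation.
#' @param glucose_elevated_rate P(glucose elevated | glucose answer known).
#' @param glycemic_change_rate P(glycemic change around age 50 or later =
#'   yes | glucose elevated).
#' @param weight_prev_mean,weight_prev_sd previous-weight distribution (lb).
#' @param weight_change_mean,weight_change_sd percent weight-change
#'   distribution.
#' @param preexisting_pc_rate,prior_testing_rate,diabetes_rate,smoking_rate
#'   Bernoulli rates for the corresponding flags.
#' @param age_mean,age_sd age distribution (clamped to 18..95).
#' @param female_rate P(female).
#' @param ethnicity_probs named probability vector over the ethnicity
#'   vocabulary.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(
    n = 453L,
    seed = 1L,
    event_probs = list(
      self    = c(pancreatic = 0.005, breast = 0.04, ovarian = 0.01,
                  colorectal = 0.04, prostate = 0.03, thyroid = 0.01,
                  melanoma = 0.03, other = 0.04),
      mother  = c(pancreatic = 0.015, breast = 0.08, ovarian = 0.02,
                  colorectal = 0.06, prostate = 0, thyroid = 0.01,
                  melanoma = 0.02, other = 0.05),
      father  = c(pancreatic = 0.015, breast = 0.005, ovarian = 0,
                  colorectal = 0.06, prostate = 0.08, thyroid = 0.005,
                  melanoma = 0.02, other = 0.05),
      sibling = c(pancreatic = 0.01, breast = 0.04, ovarian = 0.01,
                  colorectal = 0.03, prostate = 0.02, thyroid = 0.01,
                  melanoma = 0.02, other = 0.03)),
    p_dx_le50 = 0.3,
    p_dx_age_unknown = 0.1,
    sibling_lambda = 1.5,
    ashkenazi_prevalence = 0.05,
    nod_section_completion_rate = 348 / 453,
    glucose_unknown_rate = 128 / 348,
    weight_unknown_rate = 16 / 128,
    glucose_elevated_rate = 0.15,
    glycemic_change_rate = 0.5,
    weight_prev_mean = 180, weight_prev_sd = 35,
    weight_change_mean = 0, weight_change_sd = 5,
    preexisting_pc_rate = 6 / 453,
    prior_testing_rate = 18 / 453,
    diabetes_rate = 104 / 453,
    smoking_rate = 33 / 453,
    age_mean = 63, age_sd = 13,
    female_rate = 0.554,
    ethnicity_probs = c("White" = 0.9, "African American" = 0.06,
                        "Asian" = 0.015, "Other" = 0.025)) {
  cfg <- as.list(environment())
  probs <- c(unlist(cfg$event_probs), p_dx_le50, p_dx_age_unknown,
             ashkenazi_prevalence, nod_section_completion_rate,
             glucose_unknown_rate, weight_unknown_rate,
             glucose_elevated_rate, glycemic_change_rate,
             preexisting_pc_rate, prior_testing_rate, diabetes_rate,
             smoking_rate, female_rate, ethnicity_probs)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$n < 0) stop("n must be >= 0", call. = FALSE)
  cfg$n <- as.integer(cfg$n)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "cohort_config")
}

# evaluate expr under a local RNG state keyed by an integer, restoring the
# caller's state afterwards
with_substream <- function(key, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(key)
  expr
}

substream_key <- function(seed, i) {
  # distinct key per (seed, respondent counter), kept below 2^31
  (as.numeric(seed) * 100003 + i * 7919) %% 2147483647
}

#' Generate a random synthetic cohort
#'
#' Reproducible given `cfg$seed`: respondent i is drawn from a substream
#' keyed by `(seed, i)`, so cohorts are bit-identical across runs and
#' prefix-stable in n. Marginal frequencies converge to the configured
#' probabilities as n grows. Every generated record passes
#' [validate_response()].
#'
#' @param cfg a [cohort_config()].
#' @return list of [patient_response()] objects of length `cfg$n`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 50, seed = 7))
#' length(cohort)
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  lapply(seq_len(cfg$n), function(i)
    with_substream(substream_key(cfg$seed, i), generate_respondent(cfg, i)))
}

draw_events <- function(probs, cfg) {
  if (is.null(names(probs)) || !all(names(probs) %in% CANCER_TYPES))
    stop("event probabilities must be named by cancer type", call. = FALSE)
  hit <- names(probs)[stats::runif(length(probs)) < probs]
  lapply(hit, function(typ) {
    flag <- if (stats::runif(1) < cfg$p_dx_age_unknown) "unknown"
    else if (stats::runif(1) < cfg$p_dx_le50) "yes" else "no"
    cancer_event(typ, dx_at_or_before_50 = flag,
                 label = if (typ == "other") "unspecified" else NA_character_)
  })
}

generate_respondent <- function(cfg, i) {
  age <- max(18L, min(95L, as.integer(round(
    stats::rnorm(1, cfg$age_mean, cfg$age_sd)))))
  sex <- if (stats::runif(1) < cfg$female_rate) "female" else "male"
  ethnicity <- sample(names(cfg$ethnicity_probs), 1,
                      prob = cfg$ethnicity_probs)

  ash_m <- "no"; ash_f <- "no"
  if (stats::runif(1) < cfg$ashkenazi_prevalence) {
    which_parent <- sample(c("mother", "father", "both"), 1,
                           prob = c(0.4, 0.4, 0.2))
    if (which_parent %in% c("mother", "both")) ash_m <- "yes"
    if (which_parent %in% c("father", "both")) ash_f <- "yes"
  }

  persons <- list(person_history("self", draw_events(cfg$event_probs$self, cfg)))
  for (rel in c("mother", "father")) {
    ev <- draw_events(cfg$event_probs[[rel]], cfg)
    if (length(ev)) persons[[length(persons) + 1L]] <- person_history(rel, ev)
  }
  n_sib <- min(4L, stats::rpois(1, cfg$sibling_lambda))
  sib_slot <- 0L
  for (s in seq_len(n_sib)) {
    ev <- draw_events(cfg$event_probs$sibling, cfg)
    if (length(ev)) {
      sib_slot <- sib_slot + 1L
      persons[[length(persons) + 1L]] <-
        person_history("sibling", ev, relation_index = sib_slot)
    }
  }

  completed <- stats::runif(1) < cfg$nod_section_completion_rate
  nod <- if (!completed) nod_responses(section_completed = FALSE) else {
    gl_unknown <- stats::runif(1) < cfg$glucose_unknown_rate
    wt_prev <- max(90, stats::rnorm(1, cfg$weight_prev_mean, cfg$weight_prev_sd))
    wt_cur <- wt_prev * (1 + stats::rnorm(1, cfg$weight_change_mean,
                                          cfg$weight_change_sd) / 100)
    wt_prev <- round(wt_prev); wt_cur <- max(90, round(wt_cur))
    if (gl_unknown && stats::runif(1) < cfg$weight_unknown_rate)
      wt_prev <- NA_real_
    glucose <- if (gl_unknown) "unknown"
    else if (stats::runif(1) < cfg$glucose_elevated_rate) "yes" else "no"
    glycemic <- if (glucose == "yes" &&
                    stats::runif(1) < cfg$glycemic_change_rate) "yes" else "no"
    nod_responses(
      section_completed = TRUE,
      weight_current_lb = wt_cur,
      weight_one_year_ago_lb = wt_prev,
      glucose_elevated = glucose,
      diabetes_or_glucose_intolerance = stats::runif(1) < cfg$diabetes_rate,
      glycemic_change_around_age_50_or_later = glycemic)
  }

  patient_response(
    patient_id = sprintf("S%06d", i),
    age = age, sex = sex, ethnicity = ethnicity,
    ashkenazi_mother = ash_m, ashkenazi_father = ash_f,
    current_smoker = stats::runif(1) < cfg$smoking_rate,
    prior_genetic_testing = stats::runif(1) < cfg$prior_testing_rate,
    preexisting_pancreatic_cancer = stats::runif(1) < cfg$preexisting_pc_rate,
    persons = persons,
    nod = nod)
}

#' The six published worked-example patients
#'
#' Returns the six vignette respondents whose risk scores are printed in the
#' source tables: four pathogenic-variant carriers (labelled by gene —
#' fixture labels only, no genetics is modelled) scoring 8, 6, 6, 6, and the
#' two patients meeting ENDPAC criteria scoring 1 and 3 with weight changes
#' -14% and -4%.
#'
#' @return named list of [patient_response()] objects with names `RET`,
#'   `ATM`, `APC`, `SDHA`, `ENDPAC1`, `ENDPAC2`.
#' @export
worked_example_patients <- function() {
  list(
    # score 8: personal thyroid; sibling breast <=50; mother ovarian <=50
    RET = patient_response(
      "V-RET", age = 54L, sex = "female",
      persons = list(
        person_history("self", list(cancer_event("thyroid", "no"))),
        person_history("sibling", list(cancer_event("breast", "yes"))),
        person_history("mother", list(cancer_event("ovarian", "yes")))),
      nod = nod_responses(weight_current_lb = 150, weight_one_year_ago_lb = 150,
                          glucose_elevated = "no",
                          glycemic_change_around_age_50_or_later = "no")),
    # score 6: Ashkenazi mother with pancreatic cancer; father with prostate
    ATM = patient_response(
      "V-ATM", age = 65L, sex = "female", ashkenazi_mother = "yes",
      persons = list(
        person_history("self"),
        person_history("mother", list(cancer_event("pancreatic", "no"))),
        person_history("father", list(cancer_event("prostate", "no")))),
      nod = nod_responses(weight_current_lb = 160, weight_one_year_ago_lb = 160,
                          glucose_elevated = "no",
                          glycemic_change_around_age_50_or_later = "no")),
    # score 6: both parents Ashkenazi; mother breast and colon, both <=50
    APC = patient_response(
      "V-APC", age = 75L, sex = "male",
      ashkenazi_mother = "yes", ashkenazi_father = "yes",
      persons = list(
        person_history("self"),
        person_history("mother", list(cancer_event("breast", "yes"),
                                      cancer_event("colorectal", "yes")))),
      nod = nod_responses(weight_current_lb = 185, weight_one_year_ago_lb = 185,
                          glucose_elevated = "no",
                          glycemic_change_around_age_50_or_later = "no")),
    # score 6: personal pancreatic cancer; mother breast <=50
    SDHA = patient_response(
      "V-SDHA", age = 67L, sex = "female",
      preexisting_pancreatic_cancer = TRUE,
      persons = list(
        person_history("self", list(cancer_event("pancreatic", "no"))),
        person_history("mother", list(cancer_event("breast", "yes")))),
      nod = nod_responses(weight_current_lb = 140, weight_one_year_ago_lb = 145,
                          glucose_elevated = "no",
                          glycemic_change_around_age_50_or_later = "no")),
    # score 1: father with colorectal cancer; met ENDPAC criteria (-14%)
    ENDPAC1 = patient_response(
      "V-NOD1", age = 59L, sex = "female",
      persons = list(
        person_history("self"),
        person_history("father", list(cancer_event("colorectal", "no")))),
      nod = nod_responses(weight_current_lb = 209, weight_one_year_ago_lb = 242,
                          glucose_elevated = "yes",
                          glycemic_change_around_age_50_or_later = "yes")),
    # score 3: sibling with pancreatic cancer; met ENDPAC criteria (-4%);
    # previous genetic testing negative
    ENDPAC2 = patient_response(
      "V-NOD2", age = 81L, sex = "female", prior_genetic_testing = TRUE,
      persons = list(
        person_history("self"),
        person_history("sibling", list(cancer_event("pancreatic", "no")))),
      nod = nod_responses(weight_current_lb = 175, weight_one_year_ago_lb = 183,
                          glucose_elevated = "yes",
                          glycemic_change_around_age_50_or_later = "yes"))
  )
}

#' Deterministic fixture cohort matching the published funnel
#'
#' A 453-record cohort constructed so that [cohort_flow()] under the default
#' point table returns exactly the published counts: 117 respondents with
#' score >= 3; 18 with prior genetic testing (15 of them high-risk); 6 with
#' a pre-existing pancreatic cancer diagnosis; 348 completing the NOD
#' section; of those, 128 with an unknown glucose answer, 16 of whom (a
#' subset) also could not recall their weight; hence 220 assessable; and 4
#' meeting the ENDPAC criteria. The six [worked_example_patients()] are
#' included verbatim. Unconstrained fields (ages, sexes, ethnicities,
#' descriptive flags) are filled deterministically from a fixed internal
#' seed; only the funnel counts are guaranteed.
#'
#' @return list of 453 [patient_response()] objects.
#' @export
#' @examples
#' fc <- fixture_cohort()
#' cohort_flow(fc)$n_endpac_met  # 4
fixture_cohort <- function() {
  n <- 453L
  vignettes <- worked_example_patients()

  cohort <- with_substream(20230116, {
    ages <- pmax(18L, pmin(95L, as.integer(round(stats::rnorm(n, 63, 13)))))
    sexes <- ifelse(stats::runif(n) < 0.554, "female", "male")
    eths <- sample(ETHNICITIES, n, replace = TRUE,
                   prob = c(0.9, 0.06, 0.015, 0.025))
    diab <- stats::runif(n) < 104 / 453
    smoke <- stats::runif(n) < 33 / 453
    weights <- pmax(90, round(stats::rnorm(n, 180, 35)))
    lapply(seq_len(n), function(i) {
      patient_response(
        patient_id = sprintf("F%03d", i),
        age = ages[i], sex = sexes[i], ethnicity = eths[i],
        ashkenazi_mother = "no", ashkenazi_father = "no",
        current_smoker = smoke[i],
        persons = list(person_history("self")),
        nod = nod_responses(
          section_completed = TRUE,
          weight_current_lb = weights[i],
          weight_one_year_ago_lb = weights[i],
          glucose_elevated = "no",
          diabetes_or_glucose_intolerance = diab[i],
          glycemic_change_around_age_50_or_later = "no"))
    })
  })

  keep_id_nod <- function(template, v) {
    # splice a worked-example patient in, keeping the fixture id
    v$patient_id <- template$patient_id
    v
  }
  cohort[[1]] <- keep_id_nod(cohort[[1]], vignettes$RET)
  cohort[[2]] <- keep_id_nod(cohort[[2]], vignettes$ATM)
  cohort[[3]] <- keep_id_nod(cohort[[3]], vignettes$APC)
  cohort[[4]] <- keep_id_nod(cohort[[4]], vignettes$SDHA)
  cohort[[5]] <- keep_id_nod(cohort[[5]], vignettes$ENDPAC1)
  cohort[[6]] <- keep_id_nod(cohort[[6]], vignettes$ENDPAC2)

  # two further ENDPAC-met respondents (enrolled in surveillance), score < 3
  for (i in 7:8) {
    cohort[[i]]$nod$weight_one_year_ago_lb <- 200
    cohort[[i]]$nod$weight_current_lb <- 190
    cohort[[i]]$nod$glucose_elevated <- "yes"
    cohort[[i]]$nod$glycemic_change_around_age_50_or_later <- "yes"
  }

  # 112 further high-risk respondents: mother with pancreatic cancer (3 pts)
  for (i in 9:120)
    cohort[[i]]$persons <- list(
      person_history("self"),
      person_history("mother", list(cancer_event("pancreatic", "no"))))

  # prior genetic testing: 18 total = ENDPAC2 + 14 high-risk + 3 low-risk
  for (i in c(9:22, 121:123)) cohort[[i]]$prior_genetic_testing <- TRUE

  # pre-existing pancreatic cancer: 6 total = SDHA + 5 low-risk
  for (i in 124:128) cohort[[i]]$preexisting_pancreatic_cancer <- TRUE

  # 105 respondents never completed the NOD section
  for (i in 130:234)
    cohort[[i]]$nod <- nod_responses(section_completed = FALSE)

  # 128 completers with an unknown glucose answer ...
  for (i in 235:362) cohort[[i]]$nod$glucose_elevated <- "unknown"
  # ... 16 of whom also could not recall their weight one year ago
  for (i in 235:250) cohort[[i]]$nod$weight_one_year_ago_lb <- NA_real_

  cohort
}
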