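# Shared test helpers: compact record builders and an independent
# brute-force scoring oracle (flattens events to a table and sums lookups,
# a separate code path from score_family_history's accumulation loop).

make_record <- function(id = "T1", age = 60L, sex = "female",
                        events = list(), ashk_m = "no", ashk_f = "no",
                        nod = nod_responses(section_completed = FALSE), ...) {
  # events: list of c(relation, cancer_type, le50) character triples
  persons <- list(person_history("self"))
  sib_idx <- 0L
  for (ev in events) {
    rel <- ev[[1]]; typ <- ev[[2]]
    le50 <- if (length(ev) >= 3) ev[[3]] else "unknown"
    e <- cancer_event(typ, dx_at_or_before_50 = le50)
    hit <- FALSE
    if (rel != "sibling") {
      for (k in seq_along(persons)) {
        if (persons[[k]]$relation == rel) {
          persons[[k]]$events <- c(persons[[k]]$events, list(e))
          hit <- TRUE
          break
        }
      }
    }
    if (!hit && rel != "sibling")
      persons[[length(persons) + 1L]] <- person_history(rel, list(e))
    if (rel == "sibling") {
      sib_idx <- sib_idx + 1L
      persons[[length(persons) + 1L]] <-
        person_history("sibling", list(e), relation_index = sib_idx)
    }
  }
  patient_response(id, age = age, sex = sex,
                   ashkenazi_mother = ashk_m, ashkenazi_father = ashk_f,
                   persons = persons, nod = nod, ...)
}

# independent oracle: vectorized lookup over a flattened event table
oracle_score <- function(r, t = default_point_table()) {
  types <- character(0); le50 <- character(0)
  for (p in r$persons) for (e in p$events) {
    types <- c(types, e$cancer_type)
    le50 <- c(le50, e$dx_at_or_before_50)
  }
  base <- unname(t$base_points[types])
  mods <- unname(t$age_modifier_points[types])
  mods[is.na(mods)] <- 0L
  ancestry <- (r$ashkenazi_mother == "yes" || r$ashkenazi_father == "yes") *
    t$ancestry_bonus
  sum(base) + sum(mods[le50 == "yes"]) + ancestry
}

# the six published (history, score) pairs used to pin the default table
printed_vignette_scores <- c(RET = 8L, ATM = 6L, APC = 6L, SDHA = 6L,
                             ENDPAC1 = 1L, ENDPAC2 = 3L)

small_cohort <- function(n = 25, seed = 42)
  generate_cohort(cohort_config(n = n, seed = seed))
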