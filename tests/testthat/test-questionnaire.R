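test_that("constructors enforce controlled vocabularies", {
  expect_error(cancer_event("lung"), "unknown cancer_type")
  expect_error(cancer_event("breast", "maybe"), "yes/no/unknown")
  expect_error(person_history("cousin"), "unknown relation")
  expect_error(nod_responses(glucose_elevated = "high"), "yes/no/unknown")
})

test_that("validate_response flags schema violations and passes clean records", {
  clean <- make_record()
  rep1 <- validate_response(clean)
  expect_true(rep1$valid)
  expect_identical(nrow(rep1$issues), 0L)

  young <- make_record(age = 15L)
  rep2 <- validate_response(young)
  expect_false(rep2$valid)
  expect_identical(rep2$issues$field, "age")

  r3 <- make_record(nod = nod_responses(weight_current_lb = -5,
                                        glucose_elevated = "no"))
  rep3 <- validate_response(r3)
  expect_false(rep3$valid)
  expect_true("weight_current_lb" %in% rep3$issues$field)

  # missing self entry
  r4 <- make_record()
  r4$persons <- list(person_history("mother"))
  expect_false(validate_response(r4)$valid)

  # duplicate (relation, index)
  r5 <- make_record()
  r5$persons <- c(r5$persons, list(person_history("mother"),
                                   person_history("mother")))
  expect_false(validate_response(r5)$valid)

  # out-of-vocabulary enum injected after construction
  r6 <- make_record()
  r6$ethnicity <- "Martian"
  expect_false(validate_response(r6)$valid)
})

test_that("cohorts round-trip losslessly through JSON and CSV", {
  cohort <- small_cohort(n = 12, seed = 9)
  for (fmt in c("json", "csv")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_cohort(cohort, path)
    back <- read_cohort(path)
    expect_identical(back, cohort, label = paste(fmt, "round trip"))
  }
})

test_that("an 'other' cancer's free-text label survives both formats", {
  r <- make_record()
  r$persons[[1]]$events <- list(
    cancer_event("other", "no", label = "salivary gland"))
  for (fmt in c("json", "csv")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_cohort(list(r), path)
    back <- read_cohort(path)
    expect_identical(back[[1]]$persons[[1]]$events[[1]]$label,
                     "salivary gland")
  }
})

test_that("empty cohorts produce valid, re-readable files", {
  for (fmt in c("json", "csv")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_cohort(list(), path)
    expect_identical(read_cohort(path), list())
  }
})

test_that("blank CSV cells map to 'unknown', never to 'no'", {
  cohort <- list(make_record(nod = nod_responses(
    section_completed = TRUE,
    weight_current_lb = 180, weight_one_year_ago_lb = 185,
    glucose_elevated = "yes")))
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  # blank out the glucose cell
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  df$glucose_elevated <- ""
  df$glycemic_change_around_age_50_or_later <- ""
  utils::write.csv(df, path, row.names = FALSE)
  back <- read_cohort(path)
  expect_identical(back[[1]]$nod$glucose_elevated, "unknown")
  expect_identical(back[[1]]$nod$glycemic_change_around_age_50_or_later,
                   "unknown")
})

test_that("duplicate patient ids are rejected at read and cohort validation", {
  twins <- list(make_record(id = "P1"), make_record(id = "P1"))
  expect_error(validate_cohort(twins), "duplicate patient_id")
  path <- tempfile(fileext = ".json")
  write_cohort(twins, path)
  expect_error(read_cohort(path), "duplicate patient_id.*P1")
})

test_that("malformed inputs produce informative parse errors", {
  p1 <- tempfile(fileext = ".json")
  writeLines("{not json", p1)
  expect_error(read_cohort(p1), "malformed JSON")
  p2 <- tempfile(fileext = ".json")
  writeLines('{"patients": []}', p2)
  expect_error(read_cohort(p2), "respondents")
  p3 <- tempfile(fileext = ".csv")
  writeLines("patient_id,age\nP1,44", p3)
  expect_error(read_cohort(p3), "missing required column")
})
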