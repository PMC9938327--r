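test_that("percent weight change matches the printed worked examples", {
  expect_identical(percent_weight_change(209, 242), -14L)
  expect_identical(percent_weight_change(175, 183), -4L)
  expect_identical(percent_weight_change(200, 200), 0L)
})

test_that("percent weight change rounds half away from zero, loss negative", {
  expect_identical(percent_weight_change(241, 200), 21L)   # +20.5
  expect_identical(percent_weight_change(159, 200), -21L)  # -20.5
  expect_identical(percent_weight_change(180, 200), -10L)
  expect_error(percent_weight_change(0, 200), "strictly positive")
  expect_error(percent_weight_change(200, -1), "strictly positive")
  expect_error(percent_weight_change(NA, 200), "strictly positive")
})

nod_full <- function(glucose = "yes", cur = 180, prev = 200,
                     glycemic = "yes", completed = TRUE)
  nod_responses(section_completed = completed,
                weight_current_lb = cur, weight_one_year_ago_lb = prev,
                glucose_elevated = glucose,
                glycemic_change_around_age_50_or_later = glycemic)

test_that("assessability requires a glucose answer and both weights", {
  expect_false(nod_assessable(make_record(nod = nod_full(glucose = "unknown"))))
  expect_false(nod_assessable(make_record(nod = nod_full(prev = NA))))
  expect_false(nod_assessable(make_record(nod = nod_full(completed = FALSE))))
  expect_true(nod_assessable(make_record(nod = nod_full(glucose = "no"))))
})

test_that("ENDPAC criteria verdicts follow the stated precedence", {
  # published patient 1: 209 vs 242 lb, glucose elevated, no prior dx
  p1 <- make_record(nod = nod_full(cur = 209, prev = 242))
  a1 <- meets_endpac_criteria(p1)
  expect_identical(a1$verdict, "meets")
  expect_identical(a1$weight_change_pct, -14L)

  # identical inputs with a pre-existing pancreatic cancer diagnosis
  p2 <- p1
  p2$preexisting_pancreatic_cancer <- TRUE
  expect_identical(meets_endpac_criteria(p2)$verdict, "excluded_prior_pc")

  # weight gain fails the loss requirement
  p3 <- make_record(nod = nod_full(cur = 210, prev = 200))
  expect_identical(meets_endpac_criteria(p3)$verdict, "does_not_meet")

  # unknown glucose is not assessable — and is never coerced to "no"
  p4 <- make_record(nod = nod_full(glucose = "unknown"))
  expect_identical(meets_endpac_criteria(p4)$verdict, "not_assessable")

  # glycemic change not around age 50 or later
  p5 <- make_record(nod = nod_full(glycemic = "no"))
  expect_identical(meets_endpac_criteria(p5)$verdict, "does_not_meet")

  # assessability invariant: weight_change_pct defined iff both weights known
  p6 <- make_record(nod = nod_full(prev = NA))
  a6 <- meets_endpac_criteria(p6)
  expect_true(is.na(a6$weight_change_pct))
  expect_identical(a6$verdict, "not_assessable")
})

test_that("min_loss_pct raises the qualifying loss threshold", {
  r <- make_record(nod = nod_full(cur = 192, prev = 200))  # -4 %
  expect_identical(meets_endpac_criteria(r)$verdict, "meets")
  expect_identical(meets_endpac_criteria(r, min_loss_pct = 5)$verdict,
                   "does_not_meet")
  expect_identical(meets_endpac_criteria(r, min_loss_pct = 4)$verdict,
                   "meets")
})

test_that("the full ENDPAC point model requires explicit configuration", {
  expect_error(endpac_score(60, -5, 20), "no ENDPAC point model supplied")
  expect_error(
    endpac_point_model(
      age_bins = data.frame(lower = 0, upper = 50, points = 0),
      weight_bins = data.frame(lower = c(-Inf, 0), upper = c(-2, Inf),
                               points = c(1, 0)),
      glucose_bins = data.frame(lower = -Inf, upper = Inf, points = 0),
      threshold = 1),
    "partition")
})

test_that("endpac_score equals an independent bin lookup on random models", {
  set.seed(99)
  mk_bins <- function(cuts, pts)
    data.frame(lower = c(-Inf, cuts), upper = c(cuts, Inf), points = pts)
  for (rep in 1:20) {
    cuts_a <- sort(sample(30:80, 2))
    cuts_w <- sort(sample(-20:0, 2))
    cuts_g <- sort(sample(5:60, 2))
    m <- endpac_point_model(
      age_bins = mk_bins(cuts_a, sample(0:3, 3, replace = TRUE)),
      weight_bins = mk_bins(cuts_w, sample(0:3, 3, replace = TRUE)),
      glucose_bins = mk_bins(cuts_g, sample(0:3, 3, replace = TRUE)),
      threshold = 3)
    age <- runif(1, 20, 95); wc <- runif(1, -30, 10); gc <- runif(1, 0, 80)
    # independent lookup via findInterval on the cut points
    lookup <- function(x, cuts, pts) pts[findInterval(x, cuts) + 1L]
    expected <- lookup(age, cuts_a, m$age_bins$points) +
      lookup(wc, cuts_w, m$weight_bins$points) +
      lookup(gc, cuts_g, m$glucose_bins$points)
    got <- endpac_score(age, wc, gc, m)
    expect_identical(got$score, as.integer(expected))
    expect_identical(got$above_threshold, expected >= 3)
  }
})

test_that("a single-bin model worth k per component scores 3k", {
  one <- function(k) data.frame(lower = -Inf, upper = Inf, points = k)
  m <- endpac_point_model(one(2), one(2), one(2), threshold = 6)
  expect_identical(endpac_score(55, -10, 30, m)$score, 6L)
  m0 <- endpac_point_model(one(0), one(0), one(0), threshold = 1)
  expect_identical(endpac_score(55, -10, 30, m0)$score, 0L)
})
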