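# Cohort-level group summaries: low-risk (score < threshold) vs high-risk
# (score >= threshold), with the conventional test per variable type
# (chi-square without continuity correction for binary frequencies,
# Mann-Whitney for ordinal/continuous, Fisher's exact for sparse
# categorical) and one-decimal percentage formatting.

#' Format a percentage to one decimal
#'
#' `100 * numerator / denominator`, rounded half away from zero to one
#' decimal place, returned as a string (e.g. `"25.8"`).
#'
#' @param numerator count.
#' @param denominator positive count.
#' @return character scalar.
#' @export
#' @examples
#' format_percent(117, 453)  # "25.8"
#' format_percent(18, 453)   # "4.0"
format_percent <- function(numerator, denominator) {
  if (is.na(denominator) || denominator <= 0)
    stop("denominator must be > 0", call. = FALSE)
  pct <- 100 * numerator / denominator
  sprintf("%.1f", round_half_away(pct * 10) / 10)
}

#' Compare a variable between two groups
#'
#' @param variable label for the output row.
#' @param group_a,group_b the two groups' values. For `"chi_square"` and
#'   `"fisher_exact"`, logical (or 0/1) vectors, or factors/characters
#'   forming an r x 2 contingency table; for `"mann_whitney"`, numeric
#'   vectors.
#' @param test one of `"chi_square"`, `"fisher_exact"`, `"mann_whitney"`.
#' @param correct apply Yates continuity correction to the chi-square test
#'   (default `FALSE`).
#' @return an object of class `group_comparison`: `variable`, `test`,
#'   `statistic` (`NA` for Fisher), `p_value`. Chi-square expected-count
#'   warnings are surfaced as R warnings, not errors.
#' @export
#' @examples
#' group_compare("female",
#'   c(rep(TRUE, 170), rep(FALSE, 148)),
#'   c(rep(TRUE, 67), rep(FALSE, 50)), "chi_square")$p_value  # ~0.48
group_compare <- function(variable, group_a, group_b,
                          test = c("chi_square", "fisher_exact",
                                   "mann_whitney"),
                          correct = FALSE) {
  test <- match.arg(test)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (test == "mann_whitney") {
    ht <- stats::wilcox.test(as.numeric(group_a), as.numeric(group_b),
                             exact = FALSE, correct = FALSE)
    stat <- unname(ht$statistic)
  } else {
    tab <- rbind(table(factor(group_a, levels = sort(unique(c(group_a, group_b))))),
                 table(factor(group_b, levels = sort(unique(c(group_a, group_b))))))
    if (test == "chi_square") {
      ht <- stats::chisq.test(tab, correct = correct)
      stat <- unname(ht$statistic)
    } else {
      ht <- stats::fisher.test(tab)
      stat <- NA_real_
    }
  }
  structure(
    list(variable = variable, test = test, statistic = stat,
         p_value = unname(ht$p.value)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s [%s] p = %.4g\n",
              x$variable, x$test, x$p_value))
  invisible(x)
}

count_pct <- function(k, n) sprintf("%d (%s)", k, format_percent(k, n))

median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%g (%.1f - %.1f)", q[2], q[1], q[3])
}

#' Demographic summary table by risk group
#'
#' Builds a two-group summary (score below vs at/above the referral
#' threshold) with the conventional test per variable: chi-square for
#' binary frequencies (female, diabetes/glucose intolerance, smoking,
#' personal cancer history, Ashkenazi ancestry), Mann-Whitney for age
#' (reported as median with IQR, not mean), Fisher's exact for the
#' ethnicity distribution. Categorical rows are shown as `n (%)` using
#' [format_percent()]. With fewer than two non-empty groups the comparison
#' tests are omitted (`p_value = NA`).
#'
#' @param cohort list of [patient_response()] objects.
#' @param table a `point_table` (supplies the threshold).
#' @return an object of class `summary_table`: a data frame with columns
#'   `variable`, `low_risk`, `high_risk`, `test`, `p_value`, plus attributes
#'   `n_low`/`n_high`.
#' @export
summarize_cohort <- function(cohort, table = default_point_table()) {
  scores <- vapply(cohort, function(r)
    score_family_history(r, table)$total, integer(1))
  hi <- scores >= table$referral_threshold
  grp <- list(low = cohort[!hi], high = cohort[hi])
  n_low <- length(grp$low); n_high <- length(grp$high)
  both <- n_low > 0L && n_high > 0L

  pull <- function(g, f) vapply(grp[[g]], f, FUN.VALUE = logical(1))
  p_of <- function(fa, fb, test) {
    if (!both) return(NA_real_)
    group_compare("", fa, fb, test)$p_value
  }

  female <- function(r) r$sex == "female"
  diab <- function(r) r$nod$diabetes_or_glucose_intolerance
  smoker <- function(r) r$current_smoker
  pers_ca <- function(r) {
    self <- Find(function(p) p$relation == "self", r$persons)
    !is.null(self) && length(self$events) > 0L
  }
  ashk <- function(r) r$ashkenazi_mother == "yes" || r$ashkenazi_father == "yes"

  bin_row <- function(name, f, test = "chi_square") {
    a <- pull("low", f); b <- pull("high", f)
    data.frame(
      variable = name,
      low_risk = if (n_low) count_pct(sum(a), n_low) else "-",
      high_risk = if (n_high) count_pct(sum(b), n_high) else "-",
      test = test,
      p_value = p_of(a, b, test),
      stringsAsFactors = FALSE)
  }

  ages_low <- vapply(grp$low, function(r) as.numeric(r$age), numeric(1))
  ages_high <- vapply(grp$high, function(r) as.numeric(r$age), numeric(1))
  age_row <- data.frame(
    variable = "Age, median (IQR)",
    low_risk = if (n_low) median_iqr(ages_low) else "-",
    high_risk = if (n_high) median_iqr(ages_high) else "-",
    test = "mann_whitney",
    p_value = if (both) group_compare("age", ages_low, ages_high,
                                      "mann_whitney")$p_value else NA_real_,
    stringsAsFactors = FALSE)

  eth_low <- vapply(grp$low, function(r) r$ethnicity, character(1))
  eth_high <- vapply(grp$high, function(r) r$ethnicity, character(1))
  eth_p <- if (both && length(unique(c(eth_low, eth_high))) > 1L)
    group_compare("ethnicity", eth_low, eth_high, "fisher_exact")$p_value
  else NA_real_
  eth_rows <- do.call(rbind, lapply(ETHNICITIES, function(e) {
    data.frame(
      variable = paste0("Ethnicity: ", e),
      low_risk = if (n_low) count_pct(sum(eth_low == e), n_low) else "-",
      high_risk = if (n_high) count_pct(sum(eth_high == e), n_high) else "-",
      test = "fisher_exact",
      p_value = NA_real_,
      stringsAsFactors = FALSE)
  }))
  eth_rows$p_value[1] <- eth_p

  out <- rbind(
    bin_row("Female, n (%)", female),
    age_row,
    eth_rows,
    bin_row("Diabetes or glucose intolerance, n (%)", diab),
    bin_row("Currently tobacco smoking, n (%)", smoker),
    bin_row("Personal history of any cancer, n (%)", pers_ca),
    bin_row("Ashkenazi Jewish ancestry, n (%)", ashk))
  attr(out, "n_low") <- n_low
  attr(out, "n_high") <- n_high
  class(out) <- c("summary_table", class(out))
  out
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("Cohort summary: score < threshold (n = %d) vs >= threshold (n = %d)\n",
              attr(x, "n_low"), attr(x, "n_high")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
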