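# Age bands as conventionally printed in report-characteristics tables:
# both endpoints inclusive on whole years, fractional ages floored.
AGE_BANDS <- list("<=19" = c(-Inf, 19), "20-39" = c(20, 39),
                  "40-59" = c(40, 59), "60-79" = c(60, 79),
                  ">=80" = c(80, Inf))

#' Frequency table with percentages of a fixed total
#'
#' The building block of the descriptive summaries: counts per category with
#' percentages of `total`, rounded to 2 decimals as customarily printed.
#' `total` defaults to `sum(counts)` but is usually the corpus-wide number
#' of events, so that non-exhaustive categorizations (top countries,
#' serious outcomes) are still expressed as shares of all events.
#'
#' @param category Character vector of labels.
#' @param count Nonnegative integer counts.
#' @param total Denominator for the percentages.
#' @return Tibble (class `freq_table`) with `category`, `count`,
#'   `percentage`; the denominator is kept in attribute `total`.
#' @examples
#' frequency_table(c("male", "female", "unknown"),
#'                 c(5925, 11224, 2433), total = 19582)
#' @export
frequency_table <- function(category, count, total = sum(count)) {
  stopifnot(length(category) == length(count), all(count >= 0), total > 0)
  out <- tibble::tibble(category = as.character(category),
                        count = as.numeric(count),
                        percentage = round(100 * count / total, 2))
  class(out) <- c("freq_table", class(out))
  attr(out, "total") <- total
  out
}

#' Demographic summaries of a case collection
#'
#' Gender (male/female/unknown), age bands (<=19, 20-39, 40-59, 60-79,
#' >=80, unknown; endpoints inclusive on floored integer years) and the
#' top-ranked reporting countries. All percentages use the grand total of
#' events (cases) as denominator, including the country rows.
#'
#' @param cases A `faers_cases` collection.
#' @param top_countries How many top-ranked countries to list.
#' @return Named list of `freq_table`s: `gender`, `age`, `country`.
#' @export
demographics_summary <- function(cases, top_countries = 6) {
  stopifnot(inherits(cases, "faers_cases"))
  total <- nrow(cases$cases)

  g <- factor(cases$cases$gender, levels = c("male", "female", "unknown"))
  g[is.na(g)] <- "unknown"
  gender <- frequency_table(levels(g), as.integer(table(g)), total)

  band <- age_band(cases$cases$age_years)
  age <- frequency_table(levels(band), as.integer(table(band)), total)

  ctry <- cases$cases$country[!is.na(cases$cases$country)]
  tab <- sort(table(ctry), decreasing = TRUE)
  tab <- head(tab, top_countries)
  country <- frequency_table(names(tab), as.integer(tab), total)

  list(gender = gender, age = age, country = country)
}

age_band <- function(age_years) {
  yrs <- floor(age_years)
  lab <- rep("unknown", length(yrs))
  for (b in names(AGE_BANDS)) {
    r <- AGE_BANDS[[b]]
    lab[!is.na(yrs) & yrs >= r[1] & yrs <= r[2]] <- b
  }
  factor(lab, levels = c(names(AGE_BANDS), "unknown"))
}

#' Serious-outcome summary of a case collection
#'
#' Counts cases per principal clinical outcome category: death (DE),
#' disability (DS), hospitalization (HO), and life-threatening (LT).
#' Categories are not mutually exclusive — a case counts once in every
#' distinct category it reports — so the rows are each a share of the total
#' number of events, not a partition. Remaining FAERS codes (CA, RI, OT)
#' are pooled into an `other` row excluded from the four headline
#' categories.
#'
#' @param cases A `faers_cases` collection.
#' @param include_other Append the pooled `other` row; default `TRUE`.
#' @return A `freq_table`.
#' @export
outcomes_summary <- function(cases, include_other = TRUE) {
  stopifnot(inherits(cases, "faers_cases"))
  total <- nrow(cases$cases)
  oc <- cases$outcomes
  headline <- c(death = "DE", disability = "DS",
                hospitalization = "HO", `life-threatening` = "LT")
  cnt <- vapply(headline, function(code) {
    dplyr::n_distinct(oc$caseid[oc$outcome == code])
  }, numeric(1))
  labels <- names(headline)
  if (include_other) {
    other <- dplyr::n_distinct(oc$caseid[oc$outcome %in% c("CA", "RI", "OT")])
    cnt <- c(cnt, other)
    labels <- c(labels, "other")
  }
  frequency_table(labels, cnt, total)
}

#' Combine the descriptive tables into one long report table
#'
#' @param cases A `faers_cases` collection.
#' @param top_countries Passed to [demographics_summary()].
#' @return Tibble with `section`, `category`, `count`, `percentage`.
#' @export
descriptives_report <- function(cases, top_countries = 6) {
  demo <- demographics_summary(cases, top_countries = top_countries)
  out <- outcomes_summary(cases)
  dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(demo$gender), section = "gender"),
    dplyr::mutate(tibble::as_tibble(demo$age), section = "age"),
    dplyr::mutate(tibble::as_tibble(demo$country), section = "country"),
    dplyr::mutate(tibble::as_tibble(out), section = "serious_outcome")
  )[, c("section", "category", "count", "percentage")]
}
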