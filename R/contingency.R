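#' Build the 2x2 contingency table for one drug-event pair
#'
#' The disproportionality 2x2 table counts unique deduplicated cases:
#' \describe{
#'   \item{a}{cases exposed to the target drug that report the target event}
#'   \item{b}{cases exposed to the target drug with only other events}
#'   \item{c}{cases not exposed to the target drug that report the event}
#'   \item{d}{all remaining cases}
#' }
#' A case is drug-exposed iff it has a mention of `drug` with a role code in
#' `role_filter`; it contributes to the event column iff any of its reactions
#' (mapped to its primary SOC when `level = "SOC"`) equals `event`. Each case
#' is counted once per cell — a case whose PT is listed twice, or several of
#' whose PTs map to the target SOC, still counts once.
#'
#' @param cases A `faers_cases` collection (deduplicated by construction).
#' @param drug Target drug concept id.
#' @param event PT code (when `level = "PT"`) or SOC code (when `"SOC"`).
#' @param level `"PT"` or `"SOC"`.
#' @param role_filter Role codes defining exposure; default `"PS"` (primary
#'   suspect), the conventional restriction for attributing a report to a
#'   drug. Use `faersignal::FAERS_ROLES`-style vectors for all mentions.
#' @return Object of class `contingency_table` with fields `a`, `b`, `c`,
#'   `d`, `n`, `drug`, `event`, `level`.
#' @export
build_contingency <- function(cases, drug, event,
                              level = c("PT", "SOC"), role_filter = "PS") {
  stopifnot(inherits(cases, "faers_cases"))
  level <- match.arg(level)
  n_total <- nrow(cases$cases)
  if (n_total == 0) stop("empty corpus: no cases, N = 0")

  exposed <- unique(cases$drugs$caseid[cases$drugs$concept == drug &
                                         cases$drugs$role %in% role_filter])
  if (length(exposed) == 0) {
    warning("drug '", drug, "' has no exposed cases under the role filter")
  }
  event_ids <- event_caseids(cases, event, level)

  a <- sum(exposed %in% event_ids)
  b <- length(exposed) - a
  c_ <- length(event_ids) - a
  d <- n_total - a - b - c_
  new_contingency(a, b, c_, d, drug = drug, event = event, level = level)
}

event_caseids <- function(cases, event, level) {
  rx <- cases$reactions
  if (level == "PT") {
    unique(rx$caseid[rx$pt_code == event])
  } else {
    soc <- map_pt_to_soc(rx$pt_code, cases$hierarchy)
    unique(rx$caseid[soc == event])
  }
}

new_contingency <- function(a, b, c, d, drug = NA_character_,
                            event = NA_character_, level = NA_character_) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d,
                 drug = drug, event = event, level = level),
            class = "contingency_table")
}

#' Construct a contingency table from its four cell counts
#'
#' @param a,b,c,d Nonnegative cell counts (target drug & target event,
#'   target drug & other events, other drugs & target event, remainder).
#' @param drug,event,level Optional labels.
#' @return A `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, drug = NA_character_,
                              event = NA_character_, level = NA_character_) {
  new_contingency(a, b, c, d, drug, event, level)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("2x2 contingency table", if (!is.na(x$drug))
    paste0(" [", x$drug, " x ", x$event, " @", x$level, "]"), "\n", sep = "")
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("target event", "other events")))
  print(m)
  cat("N =", format(x$n, big.mark = ","), "\n")
  invisible(x)
}

#' All event tables for one drug
#'
#' One 2x2 table per event observed among the drug-exposed cases with
#' `a >= min_a`, sorted by `a` descending (ties by event code).
#'
#' @inheritParams build_contingency
#' @param min_a Minimum target-drug/target-event case count for a pair to be
#'   tabulated; default 1. (The "N >= 3" inclusion rule of the positivity
#'   criteria is applied at classification time, not here.)
#' @return Tibble with columns `drug`, `event`, `event_name`, `level`, `a`,
#'   `b`, `c`, `d`, `n`.
#' @export
all_event_tables <- function(cases, drug, level = c("PT", "SOC"),
                             role_filter = "PS", min_a = 1) {
  stopifnot(inherits(cases, "faers_cases"))
  level <- match.arg(level)
  n_total <- nrow(cases$cases)
  if (n_total == 0) stop("empty corpus: no cases, N = 0")

  exposed <- unique(cases$drugs$caseid[cases$drugs$concept == drug &
                                         cases$drugs$role %in% role_filter])
  rx <- cases$reactions
  if (level == "SOC") {
    rx <- tibble::tibble(caseid = rx$caseid,
                         code = map_pt_to_soc(rx$pt_code, cases$hierarchy))
  } else {
    rx <- tibble::tibble(caseid = rx$caseid, code = rx$pt_code)
  }
  rx <- dplyr::distinct(rx)               # one contribution per case per code

  ev_tot <- table(rx$code)                # cases per event, whole corpus
  ev_exp <- table(rx$code[rx$caseid %in% exposed])
  keep <- names(ev_exp)[ev_exp >= min_a]

  a <- as.numeric(ev_exp[keep])
  c_ <- as.numeric(ev_tot[keep]) - a
  out <- tibble::tibble(
    drug = drug,
    event = keep,
    event_name = event_label(keep, cases$hierarchy, level),
    level = level,
    a = a,
    b = length(exposed) - a,
    c = c_,
    d = n_total - length(exposed) - c_,
    n = n_total
  )
  out[order(-out$a, out$event), , drop = FALSE]
}

event_label <- function(code, hierarchy, level) {
  if (level == "SOC") {
    nm <- hierarchy$soc$soc_name[match(code, hierarchy$soc$soc_code)]
  } else {
    nm <- hierarchy$pt$pt_name[match(code, hierarchy$pt$pt_code)]
  }
  ifelse(is.na(nm), code, nm)
}

#' Reconstruct a 2x2 table from a published disproportionality row
#'
#' Signal-detection papers print, per drug-event pair, the exposed-event
#' count `a`, the ROR, the PRR, and the chi-square statistic, but not the
#' full table. Those four numbers determine the table: from
#' `PRR = (a + ROR b) / (a + b)` one gets `b = a (PRR - 1) / (ROR - PRR)`;
#' `ROR = ad / bc` then fixes `d` given `c`, and the chi-square value pins
#' `c` down by a monotone one-dimensional root search. Useful for auditing
#' or re-deriving statistics from published tables.
#'
#' @param a Exposed-and-event case count as printed.
#' @param ror,prr Printed point estimates (requires `ror > prr > 1`).
#' @param chi2 Printed chi-square statistic.
#' @param interval Search interval for cell `c`.
#' @return A `contingency_table` (cells rounded to whole cases).
#' @export
reconstruct_table <- function(a, ror, prr, chi2, interval = c(1, 1e10)) {
  stopifnot(a > 0, ror > prr, prr > 1)
  b <- a * (prr - 1) / (ror - prr)
  f <- function(cc) {
    d <- ror * b * cc / a
    n <- a + b + cc + d
    n * (a * d - b * cc)^2 /
      ((a + b) * (cc + d) * (a + cc) * (b + d)) - chi2
  }
  cc <- stats::uniroot(f, interval, tol = 1e-9)$root
  d <- ror * b * cc / a
  new_contingency(a, round(b), round(cc), round(d))
}
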