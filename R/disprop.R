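# Four disproportionality statistics on the 2x2 table
#
#   ROR  = ad / bc                          (reporting odds ratio)
#   PRR  = a(c+d) / c(a+b)                  (proportional reporting ratio)
#   chi2 = N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)), N = a+b+c+d, 1 df, no
#          continuity correction
#   IC   = log2( aN / ((a+b)(a+c)) )        (information component, BCPNN)
#   EBGM = aN / ((a+b)(a+c))                (relative-reporting-ratio form)
#
# so IC == log2(EBGM) identically, and for ad > bc with all cells positive
# ROR >= PRR >= EBGM. CIs: ROR and EBGM use the log-scale delta-method
# dispersion sqrt(1/a+1/b+1/c+1/d) with z = 1.96; PRR uses the delta-method
# term sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)); the IC interval is
# E(IC) +/- 2 sqrt(V(IC)) with V(IC) selectable (see vic_variance).

# Vectorized engine shared by the scalar statistics and signal_table().
disprop_core <- function(a, b, c, d, vic_method = "delta", haldane = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  zero_cell <- a == 0 | b == 0 | c == 0 | d == 0
  if (haldane) {
    adj <- zero_cell
    a <- a + 0.5 * adj; b <- b + 0.5 * adj
    c <- c + 0.5 * adj; d <- d + 0.5 * adj
    undefined <- rep(FALSE, length(a))
  } else {
    undefined <- zero_cell
  }
  n <- a + b + c + d
  se_or <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)

  ror <- (a * d) / (b * c)
  ror_l <- exp(log(ror) - 1.96 * se_or)
  ror_u <- exp(log(ror) + 1.96 * se_or)

  prr <- (a * (c + d)) / (c * (a + b))
  se_prr <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  prr_l <- exp(log(prr) - 1.96 * se_prr)
  prr_u <- exp(log(prr) + 1.96 * se_prr)

  chi2 <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))

  ebgm <- a * n / ((a + b) * (a + c))
  ebgm_l <- exp(log(ebgm) - 1.96 * se_or)
  ebgm_u <- exp(log(ebgm) + 1.96 * se_or)

  ic <- log2(ebgm)
  vic <- vic_variance(a, b, c, d, method = vic_method)
  ic_l <- ic - 2 * sqrt(vic)
  ic_u <- ic + 2 * sqrt(vic)

  out <- tibble::tibble(a = a, b = b, c = c, d = d, n = n,
                        ror = ror, ror_lower = ror_l, ror_upper = ror_u,
                        prr = prr, prr_lower = prr_l, prr_upper = prr_u,
                        chi2 = chi2,
                        ic = ic, ic_lower = ic_l, ic_upper = ic_u,
                        ebgm = ebgm, ebgm_lower = ebgm_l, ebgm_upper = ebgm_u,
                        undefined = undefined)
  if (any(undefined)) {
    num <- setdiff(names(out), c("a", "b", "c", "d", "n", "undefined"))
    out[undefined, num] <- NA_real_
  }
  out
}

#' Variance of the information component
#'
#' The IC interval is `E(IC) +/- 2 sqrt(V(IC))`. The `"delta"` strategy uses
#' the same log-scale dispersion term as the ROR/EBGM intervals, transformed
#' to log2 units: `V(IC) = (1/ln 2)^2 (1/a + 1/b + 1/c + 1/d)`. The strategy
#' argument exists so a fully Bayesian BCPNN posterior variance can be added
#' without changing callers.
#'
#' @param a,b,c,d Cell counts.
#' @param method Variance strategy; currently `"delta"`.
#' @return Numeric vector of variances (log2 units squared).
#' @export
vic_variance <- function(a, b, c, d, method = c("delta")) {
  method <- match.arg(method)
  (1 / log(2))^2 * (1 / a + 1 / b + 1 / c + 1 / d)
}

as_cells <- function(t) {
  if (inherits(t, "contingency_table")) {
    list(a = t$a, b = t$b, c = t$c, d = t$d)
  } else if (is.numeric(t) && length(t) == 4) {
    list(a = t[[1]], b = t[[2]], c = t[[3]], d = t[[4]])
  } else {
    stop("expected a contingency_table or a numeric vector c(a, b, c, d)")
  }
}

new_estimate_ci <- function(point, lower, upper, undefined, label) {
  structure(list(point = point, lower95 = lower, upper95 = upper,
                 undefined = undefined, label = label),
            class = "estimate_ci")
}

#' @export
print.estimate_ci <- function(x, ...) {
  if (x$undefined) {
    cat(x$label, ": undefined (zero cell)\n", sep = "")
  } else {
    cat(sprintf("%s %.4g (95%% CI %.4g-%.4g)\n",
                x$label, x$point, x$lower95, x$upper95))
  }
  invisible(x)
}

#' Reporting odds ratio with 95% CI
#'
#' `ROR = ad/bc`, interval `exp(ln ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`.
#' A zero cell yields an undefined, flagged result (classified negative)
#' unless `haldane = TRUE` adds 0.5 to every cell of the affected table.
#'
#' @param t A `contingency_table` or numeric `c(a, b, c, d)`.
#' @param haldane Apply the Haldane-Anscombe +0.5 correction to zero-cell
#'   tables; default off.
#' @return An `estimate_ci` with `point`, `lower95`, `upper95`, `undefined`.
#' @examples
#' ror_stat(c(10, 90, 100, 9900))
#' @export
ror_stat <- function(t, haldane = FALSE) {
  x <- as_cells(t)
  s <- disprop_core(x$a, x$b, x$c, x$d, haldane = haldane)
  new_estimate_ci(s$ror, s$ror_lower, s$ror_upper, s$undefined, "ROR")
}

#' Proportional reporting ratio, 95% CI and chi-square
#'
#' `PRR = a(c+d) / c(a+b)`; the companion statistic is the 1-df Pearson
#' chi-square `N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))` without continuity
#' correction. The interval uses the log-scale delta-method dispersion
#' `sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`.
#'
#' @inheritParams ror_stat
#' @return An `estimate_ci` with an extra `chi2` field.
#' @examples
#' prr_stat(c(10, 90, 100, 9900))
#' @export
prr_stat <- function(t, haldane = FALSE) {
  x <- as_cells(t)
  s <- disprop_core(x$a, x$b, x$c, x$d, haldane = haldane)
  out <- new_estimate_ci(s$prr, s$prr_lower, s$prr_upper, s$undefined, "PRR")
  out$chi2 <- s$chi2
  out
}

#' Information component (BCPNN) with 95% interval
#'
#' `IC = log2(aN / ((a+b)(a+c)))`, the log2 observed-to-expected reporting
#' ratio; the interval is `E(IC) +/- 2 sqrt(V(IC))` (see [vic_variance()]).
#' The lower bound is the IC025 used by the positivity criterion.
#'
#' @inheritParams ror_stat
#' @param vic_method Variance strategy passed to [vic_variance()].
#' @return An `estimate_ci` in log2 units.
#' @examples
#' ic_stat(c(10, 90, 100, 9900))
#' @export
ic_stat <- function(t, vic_method = "delta", haldane = FALSE) {
  x <- as_cells(t)
  s <- disprop_core(x$a, x$b, x$c, x$d, vic_method = vic_method,
                    haldane = haldane)
  new_estimate_ci(s$ic, s$ic_lower, s$ic_upper, s$undefined, "IC")
}

#' Empirical Bayes geometric mean (relative-reporting-ratio form)
#'
#' `EBGM = aN / ((a+b)(a+c))`, i.e. the observed-to-expected reporting ratio
#' (so `IC = log2(EBGM)` exactly); no Bayesian shrinkage is applied. The
#' interval is `exp(ln EBGM +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`; the lower
#' bound is the EBGM05 used by the positivity criterion.
#'
#' @inheritParams ror_stat
#' @return An `estimate_ci`.
#' @examples
#' ebgm_stat(c(10, 90, 100, 9900))
#' @export
ebgm_stat <- function(t, haldane = FALSE) {
  x <- as_cells(t)
  s <- disprop_core(x$a, x$b, x$c, x$d, haldane = haldane)
  new_estimate_ci(s$ebgm, s$ebgm_lower, s$ebgm_upper, s$undefined, "EBGM")
}

#' Classify a pair against the four positivity criteria
#'
#' A pair is flagged positive by
#' \itemize{
#'   \item ROR: lower 95% bound > 1 and `a >= 3`;
#'   \item PRR: `PRR >= 2`, `chi2 >= 4` and `a >= 3`;
#'   \item BCPNN: `IC025 > 0`;
#'   \item EBGM: `EBGM05 > 2`.
#' }
#' The case-count condition "N >= 3" is read as the cell `a` (target drug
#' and target event cases), the conventional reading in disproportionality
#' practice. Undefined (zero-cell) statistics classify negative.
#'
#' @param stats A one-or-more-row tibble from [disprop_core] layout, e.g. a
#'   [signal_table()] result, or a `contingency_table` (statistics are then
#'   computed with defaults).
#' @param ... Passed to the statistics when `stats` is a table.
#' @return Tibble with logical columns `ror_positive`, `prr_positive`,
#'   `bcpnn_positive`, `ebgm_positive`, `any_positive`, `all_positive`.
#' @examples
#' classify_signals(contingency_table(10, 90, 100, 9900))
#' @export
classify_signals <- function(stats, ...) {
  if (inherits(stats, "contingency_table")) {
    stats <- disprop_core(stats$a, stats$b, stats$c, stats$d, ...)
  }
  ok <- !stats$undefined
  f <- function(x) ok & !is.na(x) & x
  out <- tibble::tibble(
    ror_positive  = f(stats$ror_lower > 1 & stats$a >= 3),
    prr_positive  = f(stats$prr >= 2 & stats$chi2 >= 4 & stats$a >= 3),
    bcpnn_positive = f(stats$ic_lower > 0),
    ebgm_positive = f(stats$ebgm_lower > 2)
  )
  out$any_positive <- out$ror_positive | out$prr_positive |
    out$bcpnn_positive | out$ebgm_positive
  out$all_positive <- out$ror_positive & out$prr_positive &
    out$bcpnn_positive & out$ebgm_positive
  out
}

#' Ranked signal table for one drug
#'
#' One row per event observed among exposed cases, with the 2x2 cells, the
#' four statistics with their 95% bounds, and the positivity flags. Default
#' sort is case count (`a`) descending; `sort = "ebgm"` ranks by EBGM point
#' estimate descending instead (ties broken by event code).
#'
#' @inheritParams all_event_tables
#' @param sort `"cases"` or `"ebgm"`.
#' @param vic_method,haldane Passed to the statistics.
#' @return Tibble with one row per event.
#' @export
signal_table <- function(cases, drug, level = c("PT", "SOC"),
                         role_filter = "PS", min_a = 1,
                         sort = c("cases", "ebgm"),
                         vic_method = "delta", haldane = FALSE) {
  level <- match.arg(level)
  sort <- match.arg(sort)
  tab <- all_event_tables(cases, drug, level = level,
                          role_filter = role_filter, min_a = min_a)
  stats <- disprop_core(tab$a, tab$b, tab$c, tab$d,
                        vic_method = vic_method, haldane = haldane)
  out <- dplyr::bind_cols(tab[c("drug", "event", "event_name", "level")],
                          stats, classify_signals(stats))
  names(out)[names(out) == "a"] <- "case_reports"
  ord <- if (sort == "cases") {
    order(-out$case_reports, out$event)
  } else {
    order(-ifelse(is.na(out$ebgm), -Inf, out$ebgm), out$event)
  }
  out[ord, , drop = FALSE]
}

#' Top-k signals by case count or EBGM
#'
#' Stable descending sort with ties broken by event code; `k` larger than
#' the number of rows returns all rows.
#'
#' @param signals A [signal_table()] tibble.
#' @param k Number of rows to return.
#' @param sort_key `"case_reports"` or `"ebgm"`.
#' @export
top_signals <- function(signals, k = 5, sort_key = c("case_reports", "ebgm")) {
  sort_key <- match.arg(sort_key)
  key <- signals[[sort_key]]
  key[is.na(key)] <- -Inf
  ord <- order(-key, signals$event)
  head(signals[ord, , drop = FALSE], k)
}

#' Format a signal table for reporting
#'
#' Rounds to 2 decimals and collapses estimate/CI pairs into the customary
#' `"point (lower-upper)"` strings; internal computation stays full
#' precision.
#'
#' @param signals A [signal_table()] tibble.
#' @return Tibble with character presentation columns.
#' @export
format_signal_table <- function(signals) {
  r2 <- function(x) as.character(round(x, 2))
  est <- function(p, l, u) {
    ifelse(is.na(p), "ND", paste0(r2(p), " (", r2(l), "-", r2(u), ")"))
  }
  tibble::tibble(
    event = signals$event,
    event_name = signals$event_name,
    level = signals$level,
    case_reports = signals$case_reports,
    ror = est(signals$ror, signals$ror_lower, signals$ror_upper),
    prr = est(signals$prr, signals$prr_lower, signals$prr_upper),
    chi2 = ifelse(is.na(signals$chi2), "ND", r2(signals$chi2)),
    ic = ifelse(is.na(signals$ic), "ND",
                paste0(r2(signals$ic), " (", r2(signals$ic_lower), ")")),
    ebgm = ifelse(is.na(signals$ebgm), "ND",
                  paste0(r2(signals$ebgm), " (", r2(signals$ebgm_lower), ")")),
    ror_positive = signals$ror_positive,
    prr_positive = signals$prr_positive,
    bcpnn_positive = signals$bcpnn_positive,
    ebgm_positive = signals$ebgm_positive,
    all_positive = signals$all_positive
  )
}
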