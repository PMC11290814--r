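# Reference table used throughout: (a,b,c,d) = (10, 90, 100, 9900).
# Expected values frozen from independent hand arithmetic on the printed
# formulas (log-space for the intervals).
REF <- c(10, 90, 100, 9900)

test_that("the uniform table is null for every statistic", {
  t <- c(5, 5, 5, 5)
  expect_equal(ror_stat(t)$point, 1)
  expect_lt(ror_stat(t)$lower95, 1)
  expect_gt(ror_stat(t)$upper95, 1)
  p <- prr_stat(t)
  expect_equal(p$point, 1)
  expect_equal(p$chi2, 0)
  expect_equal(ic_stat(t)$point, 0)
  expect_equal(ebgm_stat(t)$point, 1)
  flags <- classify_signals(contingency_table(5, 5, 5, 5))
  expect_false(any(unlist(flags)))
})

test_that("statistics match hand-computed values on the reference table", {
  r <- ror_stat(REF)
  expect_equal(r$point, 11)
  expect_equal(r$lower95, 5.559515, tolerance = 1e-6)
  expect_equal(r$upper95, 21.764489, tolerance = 1e-6)

  p <- prr_stat(REF)
  expect_equal(p$point, 10)
  expect_equal(p$chi2, 74.447174, tolerance = 1e-6)
  expect_equal(p$lower95, 5.382154, tolerance = 1e-6)
  expect_equal(p$upper95, 18.579922, tolerance = 1e-6)

  e <- ebgm_stat(REF)
  expect_equal(e$point, 9.181818, tolerance = 1e-6)
  expect_equal(e$lower95, 4.640587, tolerance = 1e-6)
  expect_equal(e$upper95, 18.167053, tolerance = 1e-6)

  i <- ic_stat(REF)
  expect_equal(i$point, 3.198780, tolerance = 1e-6)
  expect_equal(i$lower95, 2.194216, tolerance = 1e-6)
  expect_equal(i$upper95, 4.203344, tolerance = 1e-6)
})

test_that("chi-square equals the generic Pearson statistic from expected counts", {
  # single table to 12 digits
  m <- matrix(c(10, 100, 90, 9900), 2, 2)
  ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$statistic)
  expect_equal(prr_stat(REF)$chi2, unname(ref), tolerance = 1e-12)
  # and over random tables
  tabs <- random_tables(300, seed = 41)
  for (i in seq_len(nrow(tabs))) {
    m <- matrix(c(tabs$a[i], tabs$c[i], tabs$b[i], tabs$d[i]), 2, 2)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$statistic)
    expect_equal(prr_stat(c(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]))$chi2,
                 unname(ref), tolerance = 1e-10)
  }
})

test_that("IC equals log2(EBGM) at machine precision and ordering holds", {
  tabs <- random_tables(500, seed = 43)
  for (i in seq_len(nrow(tabs))) {
    t <- c(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    ic <- ic_stat(t)$point
    eb <- ebgm_stat(t)$point
    expect_identical(ic, log2(eb))
    if (tabs$a[i] * tabs$d[i] > tabs$b[i] * tabs$c[i]) {
      expect_gte(ror_stat(t)$point, prr_stat(t)$point)
      expect_gte(prr_stat(t)$point, eb)
    }
  }
})

test_that("point estimates increase strictly in a with b, c, d fixed", {
  b <- 500; c_ <- 300; d <- 20000
  prev <- c(-Inf, -Inf, -Inf, -Inf)
  for (a in c(1, 2, 5, 10, 50, 200)) {
    t <- c(a, b, c_, d)
    cur <- c(ror_stat(t)$point, prr_stat(t)$point,
             ic_stat(t)$point, ebgm_stat(t)$point)
    expect_true(all(cur > prev))
    prev <- cur
  }
})

test_that("zero cells flag undefined results unless Haldane-corrected", {
  z <- c(0, 5, 5, 5)
  r <- ror_stat(z)
  expect_true(r$undefined)
  expect_true(is.na(r$point))
  expect_true(prr_stat(z)$undefined)
  expect_true(is.na(ic_stat(z)$point))
  expect_true(is.na(ebgm_stat(z)$point))
  # undefined classifies negative on all four criteria
  flags <- classify_signals(contingency_table(0, 5, 5, 5))
  expect_false(any(unlist(flags)))
  # Haldane +0.5 gives the finite corrected estimate
  rh <- ror_stat(z, haldane = TRUE)
  expect_false(rh$undefined)
  expect_equal(rh$point, (0.5 * 5.5) / (5.5 * 5.5))
  # tables without zeros are untouched by the option
  expect_equal(ror_stat(REF, haldane = TRUE)$point, ror_stat(REF)$point)
})

test_that("positivity criteria follow the four published rules", {
  flags <- classify_signals(contingency_table(10, 90, 100, 9900))
  expect_true(flags$ror_positive)   # lower ROR bound 5.56 > 1, a >= 3
  expect_true(flags$prr_positive)   # PRR 10 >= 2, chi2 74.4 >= 4, a >= 3
  expect_true(flags$bcpnn_positive) # IC025 2.19 > 0
  expect_true(flags$ebgm_positive)  # EBGM05 4.64 > 2
  expect_true(flags$all_positive && flags$any_positive)

  # enormous ROR with a = 2 still fails the a >= 3 case-count rule
  f2 <- classify_signals(contingency_table(2, 1, 1, 10000))
  expect_false(f2$ror_positive)
  expect_false(f2$prr_positive)
  # all_positive implies any_positive over random tables
  tabs <- random_tables(200, seed = 47)
  fl <- classify_signals(disprop_core(tabs$a, tabs$b, tabs$c, tabs$d))
  expect_true(all(!fl$all_positive | fl$any_positive))
})

test_that("lower95 <= point <= upper95 whenever all cells are positive", {
  tabs <- random_tables(200, seed = 53)
  s <- disprop_core(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_true(all(s$ror_lower <= s$ror & s$ror <= s$ror_upper))
  expect_true(all(s$prr_lower <= s$prr & s$prr <= s$prr_upper))
  expect_true(all(s$ic_lower <= s$ic & s$ic <= s$ic_upper))
  expect_true(all(s$ebgm_lower <= s$ebgm & s$ebgm <= s$ebgm_upper))
})

test_that("signal_table ranks events and carries flags", {
  cfg <- synthetic_config(
    4000, duplicate_rate = 0,
    implanted = tibble::tibble(concept = "CSA", pt_code = "PT009", rho = 10),
    seed = 59)
  sim <- simulate_cases(cfg)
  cases <- make_cases(drugs = sim$truth$drugs,
                      reactions = sim$truth$reactions,
                      hierarchy = synthetic_hierarchy(cfg))
  st <- signal_table(cases, "CSA", level = "PT",
                     role_filter = FAERS_ROLES, sort = "ebgm")
  st3 <- st[st$case_reports >= 3, ]
  # the implanted pair ranks first by EBGM among pairs with a >= 3
  expect_equal(st3$event[1], "PT009")
  # within rows where ad > bc, ROR >= PRR >= EBGM
  up <- !is.na(st$ror) & st$ror > 1
  expect_true(all(st$ror[up] >= st$prr[up] - 1e-12))
  expect_true(all(st$prr[up] >= st$ebgm[up] - 1e-12))
  # default sort: case counts descending
  st_c <- signal_table(cases, "CSA", level = "PT", role_filter = FAERS_ROLES)
  expect_true(all(diff(st_c$case_reports) <= 0))

  # single-event corpus gives a single row
  one <- make_cases(
    drugs = tibble::tibble(caseid = c("1", "2"), concept = c("X", "Y"),
                           role = "PS"),
    reactions = tibble::tibble(caseid = c("1", "2"), pt_code = "E"))
  expect_equal(nrow(signal_table(one, "X", level = "PT")), 1L)
})

test_that("top_signals sorts stably with ties broken by event code", {
  st <- tibble::tibble(event = c("B", "A", "C"),
                       case_reports = c(5, 9, 5),
                       ebgm = c(2, 2, 7))
  expect_equal(top_signals(st, 5, "case_reports")$event, c("A", "B", "C"))
  expect_equal(top_signals(st, 2, "ebgm")$event, c("C", "A"))
  expect_equal(nrow(top_signals(st, 10, "ebgm")), 3L)
})
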