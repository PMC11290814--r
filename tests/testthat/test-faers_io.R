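test_that("read_quarter parses a fixture quarter and preserves row counts", {
  dir <- write_toy_quarter(
    demo_lines = c("1001$100$1$20140101$F$45$YR$US",
                   "1002$101$1$20140215$M$45$MON$JP",
                   "1003$102$1$bogus$$$$"),
    drug_lines = c("1001$100$1$PS$CYCLOSPORINE",
                   "1001$100$2$C$ASPIRIN",
                   "1002$101$1$PS$NEORAL",
                   "1003$102$1$SS$DRUGX"),
    reac_lines = c("1001$100$Event E", "1001$100$Event F",
                   "1002$101$Event E", "1003$102$Event G",
                   "1003$102$Event H"),
    outc_lines = c("1001$100$HO"))
  q <- read_quarter(dir)
  expect_equal(q$log$rows, c(3L, 4L, 5L, 1L))
  # unparseable date flagged missing, counted, not dropped
  expect_true(is.na(q$demo$fda_dt[3]))
  expect_equal(q$log$bad_dates[1], 1L)
  expect_equal(q$demo$fda_dt[1], as.Date("2014-01-01"))
})

test_that("an empty DEMO file with header only yields zero demo rows", {
  dir <- write_toy_quarter()
  q <- read_quarter(dir)
  expect_equal(nrow(q$demo), 0L)
  expect_equal(nrow(q$reac), 0L)
})

test_that("a missing mandatory file is a hard error naming it", {
  dir <- write_toy_quarter()
  file.remove(file.path(dir, "REAC.txt"))
  expect_error(read_quarter(dir), "REAC")
})

test_that("ages are normalized to years across units", {
  dir <- write_toy_quarter(
    demo_lines = c("1001$100$1$20140101$F$45$MON$US",
                   "1002$101$1$20140101$M$45$YR$US",
                   "1003$102$1$20140101$F$104.36$WK$US",
                   "1004$103$1$20140101$F$36$$US"),
    drug_lines = sprintf("100%d$10%d$1$PS$DRUGX", 1:4, 0:3),
    reac_lines = sprintf("100%d$10%d$Event E", 1:4, 0:3))
  cases <- assemble_case_reports(read_quarter(dir), toy_dictionary(),
                                 toy_hierarchy())
  ages <- setNames(cases$cases$age_years, cases$cases$caseid)
  expect_equal(unname(ages["100"]), 45 / 12)   # 3.75
  expect_equal(unname(ages["101"]), 45)
  expect_equal(unname(ages["102"]), 104.36 / 52.18, tolerance = 1e-10)
  expect_equal(unname(ages["103"]), 36)        # missing unit -> years
})

test_that("deduplication keeps the latest receipt date, then version, then order", {
  demo <- tibble::tibble(
    primaryid = c("a", "b", "c", "d", "e"),
    caseid = c("100", "100", "200", "200", "300"),
    caseversion = c(1L, 2L, 2L, 1L, 1L),
    fda_dt = as.Date(c("2014-01-01", "2015-06-01",
                       "2016-01-01", "2016-01-01", NA)))
  kept <- deduplicate_cases(demo)
  expect_equal(sort(kept$primaryid), c("b", "c", "e"))
  # idempotence
  expect_identical(deduplicate_cases(kept), kept)
  # unique input untouched
  uni <- demo[c(1, 3, 5), ]
  expect_identical(deduplicate_cases(uni), uni)
  # missing date loses against any present date
  demo2 <- tibble::tibble(primaryid = c("p", "q"), caseid = "1",
                          caseversion = c(5L, 1L),
                          fda_dt = as.Date(c(NA, "2013-01-01")))
  expect_equal(deduplicate_cases(demo2)$primaryid, "q")
  # same date and version: last file order wins
  demo3 <- tibble::tibble(primaryid = c("p", "q"), caseid = "1",
                          caseversion = 1L, fda_dt = as.Date("2013-01-01"))
  expect_equal(deduplicate_cases(demo3)$primaryid, "q")
})

test_that("deduplication matches a group-by oracle on versioned rows", {
  withr::with_seed(11, {
    n <- 200
    demo <- tibble::tibble(
      primaryid = as.character(seq_len(n)),
      caseid = as.character(sample(1:60, n, TRUE)),
      caseversion = sample(1:4, n, TRUE),
      fda_dt = as.Date("2013-01-01") + sample(0:1000, n, TRUE))
  })
  kept <- deduplicate_cases(demo)
  expect_equal(nrow(kept), dplyr::n_distinct(demo$caseid))
  # oracle: explicit per-case scan
  for (id in unique(demo$caseid)) {
    g <- demo[demo$caseid == id, ]
    g <- g[g$fda_dt == max(g$fda_dt), ]
    g <- g[g$caseversion == max(g$caseversion), ]
    expect_equal(kept$primaryid[kept$caseid == id], g$primaryid[nrow(g)])
  }
  expect_identical(deduplicate_cases(kept), kept)
})

test_that("assembly joins tables, dedups across quarters and drops reaction-free cases", {
  d1 <- write_toy_quarter(
    demo_lines = "1001$100$1$20130105$F$50$YR$US",
    drug_lines = "1001$100$1$PS$CYCLOSPORINE",
    reac_lines = "1001$100$Event E",
    outc_lines = "1001$100$HO")
  d2 <- write_toy_quarter(
    demo_lines = c("1002$100$2$20140601$F$50$YR$US",
                   "2001$200$1$20140610$M$30$YR$JP"),
    drug_lines = c("1002$100$1$PS$NEORAL", "2001$200$1$PS$DRUGY"),
    reac_lines = c("1002$100$Event F", "2001$200$Event G"),
    outc_lines = "1002$100$DE")
  cases <- assemble_case_reports(list(read_quarter(d1), read_quarter(d2)),
                                 toy_dictionary(), toy_hierarchy())
  # cross-quarter dedup: case 100 appears once, via its 2014 version
  expect_equal(nrow(cases$cases), 2L)
  c100 <- cases$reactions[cases$reactions$caseid == "100", ]
  expect_equal(c100$pt_code, "F")
  expect_equal(cases$drugs$concept[cases$drugs$caseid == "100"], "C1")
  expect_equal(cases$outcomes$outcome[cases$outcomes$caseid == "100"], "DE")
  expect_equal(cases$cases$gender[cases$cases$caseid == "200"], "male")

  # one complete case from a single quarter populates every field
  one <- assemble_case_reports(read_quarter(d1), toy_dictionary(),
                               toy_hierarchy())
  expect_equal(nrow(one$cases), 1L)
  expect_equal(one$cases$age_years, 50)
  expect_equal(one$cases$country, "US")
  expect_equal(one$outcomes$outcome, "HO")

  # unknown reaction term: error by default, bucket on request
  d3 <- write_toy_quarter(
    demo_lines = "3001$300$1$20130105$F$50$YR$US",
    drug_lines = "3001$300$1$PS$DRUGX",
    reac_lines = "3001$300$Mystery term")
  expect_error(assemble_case_reports(read_quarter(d3), toy_dictionary(),
                                     toy_hierarchy()), "Mystery term")
  bucketed <- assemble_case_reports(read_quarter(d3), toy_dictionary(),
                                    toy_hierarchy(), unknown_pt = "bucket")
  expect_equal(bucketed$reactions$pt_code, "UNKNOWN")

  # a case with no reactions is excluded and counted
  d4 <- write_toy_quarter(
    demo_lines = c("4001$400$1$20130105$F$50$YR$US",
                   "5001$500$1$20130105$M$60$YR$US"),
    drug_lines = c("4001$400$1$PS$DRUGX", "5001$500$1$PS$DRUGX"),
    reac_lines = "4001$400$Event E")
  a4 <- assemble_case_reports(read_quarter(d4), toy_dictionary(),
                              toy_hierarchy())
  expect_equal(nrow(a4$cases), 1L)
  expect_equal(a4$log$rows[a4$log$stage == "dropped_no_reaction"], 1L)
})

test_that("repeated assembly of the same files is identical", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(150, seed = 5)
  generate_faers(cfg, file.path(dir, "c"))
  x1 <- assemble_generated(file.path(dir, "c"))
  x2 <- assemble_generated(file.path(dir, "c"))
  expect_identical(x1$cases, x2$cases)
  expect_identical(x1$reactions, x2$reactions)
})
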