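# Small in-code fixtures shared across the test files.

toy_hierarchy <- function() {
  meddra_hierarchy(
    pt = tibble::tibble(
      pt_code = c("E", "F", "G", "H"),
      pt_name = c("Event E", "Event F", "Event G", "Event H"),
      soc_code = c("S1", "S1", "S2", "S2")),
    soc = tibble::tibble(soc_code = c("S1", "S2"),
                         soc_name = c("Organ class 1", "Organ class 2")))
}

toy_dictionary <- function() {
  tibble::tibble(synonym = c("DRUGX", "DRUGY", "CYCLOSPORINE", "NEORAL"),
                 concept_id = c("X", "Y", "C1", "C1"))
}

# Build a faers_cases collection directly from its relational tables;
# demographics default to unknown/missing.
make_cases <- function(drugs, reactions, demo = NULL, outcomes = NULL,
                       hierarchy = toy_hierarchy()) {
  ids <- unique(c(drugs$caseid, reactions$caseid))
  if (is.null(demo)) {
    demo <- tibble::tibble(caseid = ids,
                           receipt_date = as.Date(NA),
                           gender = "unknown",
                           age_years = NA_real_,
                           country = NA_character_)
  }
  if (is.null(outcomes)) {
    outcomes <- tibble::tibble(caseid = character(0), outcome = character(0))
  }
  structure(list(cases = tibble::as_tibble(demo),
                 drugs = tibble::as_tibble(drugs),
                 reactions = tibble::as_tibble(reactions),
                 outcomes = tibble::as_tibble(outcomes),
                 hierarchy = hierarchy,
                 log = tibble::tibble(stage = character(0),
                                      rows = integer(0))),
            class = "faers_cases")
}

# The four-cases-one-per-cell corpus: (drugX,E), (drugX,F), (drugY,E),
# (drugY,F).
four_cell_cases <- function() {
  make_cases(
    drugs = tibble::tibble(caseid = c("1", "2", "3", "4"),
                           concept = c("X", "X", "Y", "Y"),
                           role = "PS"),
    reactions = tibble::tibble(caseid = c("1", "2", "3", "4"),
                               pt_code = c("E", "F", "E", "F")))
}

# Write a handcrafted $-delimited quarter to a temp dir and return its path.
write_toy_quarter <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                              demo_lines = NULL, drug_lines = NULL,
                              reac_lines = NULL, outc_lines = NULL) {
  hdr <- list(
    demo = "primaryid$caseid$caseversion$fda_dt$sex$age$age_cod$reporter_country",
    drug = "primaryid$caseid$drug_seq$role_cod$drugname",
    reac = "primaryid$caseid$pt",
    outc = "primaryid$caseid$outc_cod")
  body <- list(demo = demo_lines, drug = drug_lines,
               reac = reac_lines, outc = outc_lines)
  for (tag in names(hdr)) {
    writeLines(c(hdr[[tag]], body[[tag]]),
               file.path(dir, paste0(toupper(tag), ".txt")))
  }
  dir
}

# Brute-force quadratic-scan oracle: per-case membership loops, independent
# of the tabulation path in the package.
oracle_cells <- function(cases, drug, event, level, role_filter = "PS") {
  ids <- cases$cases$caseid
  exposed <- vapply(ids, function(id) {
    any(cases$drugs$concept == drug & cases$drugs$caseid == id &
          cases$drugs$role %in% role_filter)
  }, logical(1))
  has_event <- vapply(ids, function(id) {
    pts <- cases$reactions$pt_code[cases$reactions$caseid == id]
    codes <- if (level == "SOC") map_pt_to_soc(pts, cases$hierarchy) else pts
    event %in% codes
  }, logical(1))
  c(a = sum(exposed & has_event), b = sum(exposed & !has_event),
    c = sum(!exposed & has_event), d = sum(!exposed & !has_event))
}

# Assemble a generated on-disk corpus back into cases.
assemble_generated <- function(dir) {
  qdirs <- list.dirs(dir, recursive = FALSE)
  qdirs <- qdirs[basename(qdirs) != "truth"]
  quarters <- lapply(qdirs, read_quarter)
  dict <- read_drug_dictionary(file.path(dir, "dictionary.csv"))
  h <- read_meddra_hierarchy(file.path(dir, "meddra_pt.csv"),
                             file.path(dir, "meddra_soc.csv"))
  assemble_case_reports(quarters, dict, h)
}

# Random strictly-positive 2x2 tables for property tests.
random_tables <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(a = sample(1:200, n, TRUE),
                   b = sample(1:5000, n, TRUE),
                   c = sample(1:5000, n, TRUE),
                   d = sample(1:100000, n, TRUE))
  })
}
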