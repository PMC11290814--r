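#' Read one quarter of FAERS-dialect ASCII files
#'
#' Parses the `$`-delimited quarterly distribution: DEMO (case-version
#' demographics), DRUG (drug mentions with role codes), REAC (MedDRA PT
#' reactions) and OUTC (serious-outcome codes). All four files are mandatory;
#' a missing file is a hard error naming it. Malformed rows are counted in
#' the attached parse log, never silently dropped; unparseable dates are set
#' missing and counted.
#'
#' @param path Directory holding the four files of one quarter.
#' @param delim Field delimiter, default `"$"` as in the ASCII distribution.
#' @param file_patterns Named character vector of regular expressions used to
#'   locate each table's file inside `path` (case-insensitive).
#' @return An object of class `faers_quarter`: a list of tibbles `demo`,
#'   `drug`, `reac`, `outc`, plus `path` and a `log` tibble with per-file row
#'   and malformed-row counts.
#' @export
read_quarter <- function(path, delim = "$",
                         file_patterns = c(demo = "DEMO", drug = "DRUG",
                                           reac = "REAC", outc = "OUTC")) {
  if (!dir.exists(path)) stop("quarter directory does not exist: ", path)
  files <- list.files(path, full.names = TRUE)
  locate <- function(tag) {
    hit <- files[grepl(file_patterns[[tag]], basename(files),
                       ignore.case = TRUE)]
    if (length(hit) == 0) {
      stop("mandatory FAERS file missing in ", path, ": no file matching '",
           file_patterns[[tag]], "'")
    }
    sort(hit)[1]
  }
  read_one <- function(file) {
    x <- readr::read_delim(file, delim = delim,
                           col_types = readr::cols(.default = "c"),
                           na = c("", "NA"), trim_ws = TRUE,
                           progress = FALSE, show_col_types = FALSE)
    probs <- readr::problems(x)
    attr(x, "n_malformed") <- length(unique(probs$row))
    x
  }
  demo <- read_one(locate("demo"))
  drug <- read_one(locate("drug"))
  reac <- read_one(locate("reac"))
  outc <- read_one(locate("outc"))

  bad_dates <- 0L
  if (nrow(demo)) {
    demo$caseversion <- suppressWarnings(as.integer(demo$caseversion))
    demo$age <- suppressWarnings(as.numeric(demo$age))
    raw_dt <- demo$fda_dt
    demo$fda_dt <- parse_faers_date(raw_dt)
    bad_dates <- sum(!is.na(raw_dt) & is.na(demo$fda_dt))
  } else {
    demo$caseversion <- integer(0)
    demo$age <- numeric(0)
    demo$fda_dt <- as.Date(character(0))
  }
  if (nrow(drug)) {
    drug$drug_seq <- suppressWarnings(as.integer(drug$drug_seq))
  }

  log <- tibble::tibble(
    file = c("demo", "drug", "reac", "outc"),
    rows = c(nrow(demo), nrow(drug), nrow(reac), nrow(outc)),
    malformed = c(attr(demo, "n_malformed"), attr(drug, "n_malformed"),
                  attr(reac, "n_malformed"), attr(outc, "n_malformed")),
    bad_dates = c(bad_dates, 0L, 0L, 0L)
  )
  structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                 path = path, log = log),
            class = "faers_quarter")
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat("FAERS quarter <", x$path, ">\n", sep = "")
  print(x$log)
  invisible(x)
}

parse_faers_date <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & grepl("^[0-9]{8}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  out
}

# Conversion factors from FAERS age-unit codes to years. A present age with a
# missing/unknown unit is treated as already in years.
AGE_UNIT_YEARS <- c(YR = 1, MON = 1 / 12, WK = 1 / 52.18,
                    DY = 1 / 365.25, HR = 1 / 8766)

age_in_years <- function(age, age_cod) {
  f <- AGE_UNIT_YEARS[toupper(trimws(ifelse(is.na(age_cod), "YR", age_cod)))]
  f[is.na(f)] <- 1
  out <- age * unname(f)
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' Deduplicate versioned FAERS case rows
#'
#' FAERS resubmits updated versions of the same case across quarters; an
#' analysis keeps exactly one record per case id. The retained row is the one
#' with the latest receipt date; ties are broken by the largest case version,
#' then by the latest file order (row position), so the result is
#' deterministic for a fixed input. A missing receipt date loses to any
#' present date. The operation is idempotent.
#'
#' @param demo Tibble of case-version rows with at least `caseid`; columns
#'   `fda_dt` (Date) and `caseversion` (integer) are used when present.
#' @return The input rows restricted to one row per `caseid`, in first-seen
#'   case order.
#' @export
deduplicate_cases <- function(demo) {
  if (!"caseid" %in% names(demo)) stop("deduplicate_cases() needs a caseid column")
  n <- nrow(demo)
  dt <- if ("fda_dt" %in% names(demo)) demo$fda_dt else as.Date(rep(NA, n))
  ver <- if ("caseversion" %in% names(demo)) demo$caseversion else rep(1L, n)
  ver[is.na(ver)] <- -1L
  dtn <- as.numeric(dt)
  dtn[is.na(dtn)] <- -Inf                             # missing date loses
  ord <- order(dtn, ver, seq_len(n))                  # worst ... best
  keep_last <- !duplicated(demo$caseid[ord], fromLast = TRUE)
  kept <- sort(ord[keep_last])                        # back to file order
  demo[kept, , drop = FALSE]
}

#' Assemble deduplicated case reports from one or more quarters
#'
#' Joins DEMO/DRUG/REAC/OUTC by case version across quarters, deduplicates
#' case versions across the full span (not per quarter), normalizes drug
#' names against the dictionary, resolves reaction verbatims to PT codes, and
#' converts ages to years. Cases left with no resolvable reaction are
#' excluded and counted in the assembly log.
#'
#' @param quarters A `faers_quarter` or list of them, in file order.
#' @param dictionary Drug synonym dictionary (see [read_drug_dictionary()]).
#' @param hierarchy A [meddra_hierarchy()].
#' @param unknown_pt What to do with reaction verbatims absent from the
#'   hierarchy: `"error"` (default — silent loss of reactions corrupts the
#'   contingency margins) or `"bucket"`, which routes them to PT code
#'   `"UNKNOWN"`.
#' @return An object of class `faers_cases`: tibbles `cases` (caseid,
#'   receipt_date, gender, age_years, country), `drugs` (caseid, concept,
#'   role), `reactions` (caseid, pt_code), `outcomes` (caseid, outcome), the
#'   `hierarchy`, and a `log` of per-stage row counts.
#' @export
assemble_case_reports <- function(quarters, dictionary, hierarchy,
                                  unknown_pt = c("error", "bucket")) {
  unknown_pt <- match.arg(unknown_pt)
  if (inherits(quarters, "faers_quarter")) quarters <- list(quarters)
  if (length(quarters) == 0) stop("at least one quarter is required")

  demo <- dplyr::bind_rows(lapply(quarters, `[[`, "demo"))
  drug <- dplyr::bind_rows(lapply(quarters, `[[`, "drug"))
  reac <- dplyr::bind_rows(lapply(quarters, `[[`, "reac"))
  outc <- dplyr::bind_rows(lapply(quarters, `[[`, "outc"))

  log <- list(demo_rows = nrow(demo), drug_rows = nrow(drug),
              reac_rows = nrow(reac), outc_rows = nrow(outc))

  kept <- deduplicate_cases(demo)
  log$distinct_cases <- nrow(kept)

  # Child tables attach to the retained version of each case.
  keep_ids <- kept$primaryid
  drug <- drug[drug$primaryid %in% keep_ids, , drop = FALSE]
  reac <- reac[reac$primaryid %in% keep_ids, , drop = FALSE]
  outc <- outc[outc$primaryid %in% keep_ids, , drop = FALSE]

  drugs <- tibble::tibble(
    caseid = drug$caseid,
    concept = normalize_drug_name(drug$drugname, dictionary),
    role = toupper(trimws(drug$role_cod))
  )
  drugs <- dplyr::distinct(drugs)
  log$unmapped_drug_mentions <- sum(drugs$concept == UNMAPPED)

  pt_code <- pt_code_for_name(reac$pt, hierarchy)
  if (anyNA(pt_code)) {
    bad <- unique(reac$pt[is.na(pt_code)])
    if (unknown_pt == "error") {
      stop("reaction term(s) not in hierarchy: ", paste(bad, collapse = ", "))
    }
    pt_code[is.na(pt_code)] <- "UNKNOWN"
  }
  log$unknown_pt_rows <- sum(pt_code == "UNKNOWN")
  reactions <- dplyr::distinct(
    tibble::tibble(caseid = reac$caseid, pt_code = pt_code))

  outcomes <- dplyr::distinct(tibble::tibble(
    caseid = outc$caseid, outcome = toupper(trimws(outc$outc_cod))))

  sex <- toupper(trimws(ifelse(is.na(kept$sex), "", kept$sex)))
  cases <- tibble::tibble(
    caseid = kept$caseid,
    receipt_date = kept$fda_dt,
    gender = dplyr::case_when(sex == "M" ~ "male",
                              sex == "F" ~ "female",
                              TRUE ~ "unknown"),
    age_years = age_in_years(kept$age, kept$age_cod),
    country = kept$reporter_country
  )

  # A case report must carry at least one reaction to be analyzable.
  has_reac <- cases$caseid %in% reactions$caseid
  log$dropped_no_reaction <- sum(!has_reac)
  cases <- cases[has_reac, , drop = FALSE]
  drugs <- drugs[drugs$caseid %in% cases$caseid, , drop = FALSE]
  reactions <- reactions[reactions$caseid %in% cases$caseid, , drop = FALSE]
  outcomes <- outcomes[outcomes$caseid %in% cases$caseid, , drop = FALSE]
  log$assembled_cases <- nrow(cases)

  structure(list(cases = cases, drugs = drugs, reactions = reactions,
                 outcomes = outcomes, hierarchy = hierarchy,
                 log = tibble::tibble(stage = names(log),
                                      rows = unlist(log, use.names = FALSE))),
            class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("FAERS case collection: ", nrow(x$cases), " deduplicated cases, ",
      nrow(x$reactions), " case-PT pairs, ",
      nrow(x$drugs), " case-drug mentions\n", sep = "")
  invisible(x)
}

#' Case-level and pair-level corpus counts
#'
#' Published FAERS analyses report sizes in several units at once (case
#' reports, distinct adverse-event terms, drug-linked terms); rather than
#' guessing one unit, both case-level and pair-level counts are exposed.
#'
#' @param cases A `faers_cases` collection.
#' @param drug Optional drug concept id; when given, adds counts restricted
#'   to cases mentioning that drug.
#' @param role_filter Role codes defining exposure for the drug-restricted
#'   counts; default primary suspect only.
#' @return A named list of counts: `n_cases`, `n_case_pt_pairs`,
#'   `n_distinct_pts`, and (with `drug`) `n_drug_cases`, `n_drug_pts`,
#'   `n_drug_case_pt_pairs`.
#' @export
corpus_counts <- function(cases, drug = NULL, role_filter = "PS") {
  stopifnot(inherits(cases, "faers_cases"))
  out <- list(n_cases = nrow(cases$cases),
              n_case_pt_pairs = nrow(cases$reactions),
              n_distinct_pts = dplyr::n_distinct(cases$reactions$pt_code))
  if (!is.null(drug)) {
    exposed <- unique(cases$drugs$caseid[cases$drugs$concept == drug &
                                           cases$drugs$role %in% role_filter])
    rx <- cases$reactions[cases$reactions$caseid %in% exposed, , drop = FALSE]
    out$n_drug_cases <- length(exposed)
    out$n_drug_pts <- dplyr::n_distinct(rx$pt_code)
    out$n_drug_case_pt_pairs <- nrow(rx)
  }
  out
}
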