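#' Default drug catalog for the synthetic corpus
#'
#' A target immunosuppressant plus a background of common co-reported drug
#' classes. `p_exposure` is the per-case probability of a mention;
#' `p_ps` the probability that a mention carries the primary-suspect role
#' (otherwise SS/C/I equiprobably).
#'
#' @return Tibble with `concept`, `name`, `p_exposure`, `p_ps`.
#' @export
default_drug_catalog <- function() {
  tibble::tibble(
    concept = c("CSA", "TAC", "MMF", "PRED", "ASA", "PARA"),
    name = c("CYCLOSPORINE", "TACROLIMUS", "MYCOPHENOLATE MOFETIL",
             "PREDNISONE", "ASPIRIN", "PARACETAMOL"),
    p_exposure = c(0.05, 0.08, 0.06, 0.15, 0.20, 0.25),
    p_ps = c(0.70, 0.70, 0.50, 0.30, 0.30, 0.30)
  )
}

#' Default preferred-term catalog for the synthetic corpus
#'
#' A small PT set spread over six SOCs with per-case baseline occurrence
#' probabilities in the range typical of common-to-rare reported events.
#' `PT000` ("Drug ineffective", the most-reported term in spontaneous
#' reporting) doubles as the filler reaction guaranteeing every case at
#' least one PT; it can never carry an implanted signal, which keeps the
#' implanted pairs' reporting ratios exactly at their configured values.
#'
#' @return Tibble with `pt_code`, `pt_name`, `soc_code`, `soc_name`,
#'   `p_base`.
#' @export
default_pt_catalog <- function() {
  tibble::tibble(
    pt_code = c("PT000", "PT001", "PT002", "PT003", "PT004", "PT005",
                "PT006", "PT007", "PT008", "PT009", "PT010", "PT011",
                "PT012"),
    pt_name = c("Drug ineffective", "Scleral hyperaemia", "Eye irritation",
                "Vision blurred", "Renal impairment",
                "Blood creatinine increased", "Hypertension", "Tremor",
                "Headache", "Gingival hyperplasia", "Nausea", "Diarrhoea",
                "Infection"),
    soc_code = c("SOC00", "SOC01", "SOC01", "SOC01", "SOC02", "SOC02",
                 "SOC03", "SOC04", "SOC04", "SOC05", "SOC05", "SOC05",
                 "SOC06"),
    soc_name = c("General disorders and administration site conditions",
                 rep("Eye disorders", 3),
                 rep("Renal and urinary disorders", 2),
                 "Vascular disorders",
                 rep("Nervous system disorders", 2),
                 rep("Gastrointestinal disorders", 3),
                 "Infections and infestations"),
    p_base = c(0.100, 0.010, 0.030, 0.040, 0.025, 0.020, 0.060,
               0.030, 0.080, 0.005, 0.090, 0.070, 0.050)
  )
}

#' Configuration of the synthetic FAERS generator
#'
#' Defines a corpus of spontaneous case reports with known ground truth:
#' versioned case ids (duplicates), demographics with missingness, one or
#' more drug mentions per case with role codes, one or more PT reactions,
#' serious-outcome codes, and implanted drug-event pairs whose true
#' reporting-rate ratio `rho` multiplies the PT's baseline probability among
#' cases exposed to the drug (capped at 1, other PTs untouched), so the true
#' reporting ratio equals `rho` whenever uncapped. The demographic and
#' outcome marginals default to values typical of a drug-centred FAERS
#' extract: mostly-female reporting, over half of ages missing, US-dominated
#' reporter countries, hospitalization the most common serious outcome.
#'
#' @param n_cases Number of distinct cases (>= 1).
#' @param n_quarters Number of quarterly directories, starting 2013Q1.
#' @param drugs Drug catalog tibble, see [default_drug_catalog()].
#' @param pts PT catalog tibble, see [default_pt_catalog()].
#' @param implanted Tibble `concept`, `pt_code`, `rho` of implanted pairs;
#'   must reference catalog entries other than the filler PT. Default: none.
#' @param filler_pt Catalog PT assigned to cases whose sampled reaction set
#'   came out empty (every case report carries at least one reaction).
#'   Excluded from implantation so implanted reporting ratios stay exact.
#' @param duplicate_rate Probability a case gets a second, later-dated
#'   version (value-identical except date/version).
#' @param missing_gender,missing_age,missing_country Missingness rates.
#' @param gender_split Probabilities of male/female among non-missing.
#' @param age_band_probs Probabilities over the five age bands among
#'   non-missing ages.
#' @param countries Named weights over reporter countries among non-missing.
#' @param outcome_probs Named per-case probabilities of outcome codes.
#' @param seed Integer seed; one pseudo-random stream per run, no global
#'   state is disturbed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_cases,
                             n_quarters = 4,
                             drugs = default_drug_catalog(),
                             pts = default_pt_catalog(),
                             implanted = NULL,
                             filler_pt = "PT000",
                             duplicate_rate = 0.10,
                             missing_gender = 0.124,
                             missing_age = 0.563,
                             missing_country = 0.20,
                             gender_split = c(male = 0.345, female = 0.655),
                             age_band_probs = c("<=19" = 0.137,
                                                "20-39" = 0.151,
                                                "40-59" = 0.295,
                                                "60-79" = 0.344,
                                                ">=80" = 0.073),
                             countries = c(US = 0.561, JP = 0.103,
                                           CA = 0.064, GB = 0.031,
                                           FR = 0.021, CN = 0.020,
                                           OTHER = 0.200),
                             outcome_probs = c(HO = 0.1187, DE = 0.0972,
                                               LT = 0.0179, DS = 0.0079,
                                               OT = 0.15),
                             seed = 1L) {
  if (is.null(implanted)) {
    implanted <- tibble::tibble(concept = character(0),
                                pt_code = character(0), rho = numeric(0))
  }
  implanted <- tibble::as_tibble(implanted)
  cfg <- list(n_cases = as.integer(n_cases), n_quarters = as.integer(n_quarters),
              drugs = tibble::as_tibble(drugs), pts = tibble::as_tibble(pts),
              implanted = implanted, filler_pt = filler_pt,
              duplicate_rate = duplicate_rate,
              missing_gender = missing_gender, missing_age = missing_age,
              missing_country = missing_country, gender_split = gender_split,
              age_band_probs = age_band_probs, countries = countries,
              outcome_probs = outcome_probs, seed = as.integer(seed))

  probs <- c(duplicate_rate, missing_gender, missing_age, missing_country,
             cfg$drugs$p_exposure, cfg$drugs$p_ps, cfg$pts$p_base,
             gender_split, age_band_probs, countries, outcome_probs)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (cfg$n_cases < 1) stop("n_cases must be >= 1")
  if (!filler_pt %in% cfg$pts$pt_code) {
    stop("filler_pt '", filler_pt, "' is not in the PT catalog")
  }
  if (nrow(implanted)) {
    if (any(implanted$rho < 0)) stop("rho must be >= 0")
    bad_d <- setdiff(implanted$concept, cfg$drugs$concept)
    bad_p <- setdiff(implanted$pt_code, cfg$pts$pt_code)
    if (length(bad_d) || length(bad_p)) {
      stop("implanted pairs reference unknown catalog entries: ",
           paste(c(bad_d, bad_p), collapse = ", "))
    }
    if (filler_pt %in% implanted$pt_code) {
      stop("the filler PT cannot carry an implanted signal")
    }
  }
  structure(cfg, class = "synthetic_config")
}

#' Hierarchy and dictionary implied by a synthetic configuration
#'
#' @param cfg A [synthetic_config()].
#' @return `synthetic_hierarchy()`: a [meddra_hierarchy()];
#'   `synthetic_dictionary()`: a dictionary tibble mapping each catalog
#'   drug name to its concept.
#' @export
synthetic_hierarchy <- function(cfg) {
  meddra_hierarchy(
    pt = cfg$pts[c("pt_code", "pt_name", "soc_code")],
    soc = dplyr::distinct(cfg$pts[c("soc_code", "soc_name")])
  )
}

#' @rdname synthetic_hierarchy
#' @export
synthetic_dictionary <- function(cfg) {
  tibble::tibble(synonym = canonical_term(cfg$drugs$name),
                 concept_id = cfg$drugs$concept)
}

quarter_labels <- function(n_quarters, start_year = 2013) {
  q <- seq_len(n_quarters) - 1L
  paste0(start_year + q %/% 4, "Q", q %% 4 + 1L)
}

quarter_start <- function(idx, start_year = 2013) {
  q <- idx - 1L
  as.Date(sprintf("%d-%02d-01", start_year + q %/% 4, (q %% 4) * 3 + 1))
}

quarter_of_date <- function(dates, start_year = 2013) {
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  (y - start_year) * 4L + (m - 1L) %/% 3L + 1L
}

#' Simulate a synthetic FAERS corpus in memory
#'
#' The in-memory half of [generate_faers()]: draws the corpus and returns
#' the four FAERS-dialect tables plus the ground truth, without touching
#' disk. Deterministic for a fixed config (single seeded stream).
#'
#' @param cfg A [synthetic_config()].
#' @return List with `demo`, `drug`, `reac`, `outc` tibbles (each carrying a
#'   `quarter` assignment column), and `truth`: `cases` (caseid, final
#'   version/primaryid, n_versions, gender, age_band, country), `drugs`,
#'   `reactions` (the per-case ground truth sets), `pairs` (per implantable
#'   pair true rho), and `outcomes`.
#' @export
simulate_cases <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, simulate_cases_impl(cfg))
}

simulate_cases_impl <- function(cfg) {
  n <- cfg$n_cases
  nq <- cfg$n_quarters
  caseid <- sprintf("%08d", 10000000L + seq_len(n))

  qtr <- sample.int(nq, n, replace = TRUE)
  qstart <- quarter_start(qtr)
  date1 <- qstart + floor(runif(n, 0, 90))

  g_missing <- runif(n) < cfg$missing_gender
  sex <- sample(c("M", "F"), n, replace = TRUE,
                prob = cfg$gender_split[c("male", "female")])
  sex[g_missing] <- NA_character_

  a_missing <- runif(n) < cfg$missing_age
  bands <- names(cfg$age_band_probs)
  band <- sample(bands, n, replace = TRUE, prob = cfg$age_band_probs)
  lo <- c("<=19" = 0, "20-39" = 20, "40-59" = 40, "60-79" = 60, ">=80" = 80)
  hi <- c("<=19" = 20, "20-39" = 40, "40-59" = 60, "60-79" = 80, ">=80" = 96)
  age_true <- runif(n, lo[band], hi[band])
  # infants reported in months to exercise unit conversion
  in_months <- !a_missing & age_true < 2
  age_val <- ifelse(in_months, round(age_true * 12), floor(age_true))
  age_cod <- ifelse(in_months, "MON", "YR")
  age_val[a_missing] <- NA_real_
  age_cod[a_missing] <- NA_character_
  band[a_missing] <- "unknown"

  c_missing <- runif(n) < cfg$missing_country
  country <- sample(names(cfg$countries), n, replace = TRUE,
                    prob = cfg$countries)
  country[c_missing] <- NA_character_

  # drug exposure, one column per catalog drug
  nd <- nrow(cfg$drugs)
  expo <- matrix(runif(n * nd), n, nd) <
    matrix(cfg$drugs$p_exposure, n, nd, byrow = TRUE)
  none <- which(rowSums(expo) == 0)
  if (length(none)) {
    forced <- sample.int(nd, length(none), replace = TRUE,
                         prob = cfg$drugs$p_exposure)
    expo[cbind(none, forced)] <- TRUE
  }
  drug_rows <- lapply(seq_len(nd), function(j) {
    idx <- which(expo[, j])
    if (!length(idx)) return(NULL)
    is_ps <- runif(length(idx)) < cfg$drugs$p_ps[j]
    other <- sample(c("SS", "C", "I"), length(idx), replace = TRUE)
    tibble::tibble(caseid = caseid[idx], drug_j = j,
                   role_cod = ifelse(is_ps, "PS", other),
                   drugname = decorate_verbatim(cfg$drugs$name[j],
                                                length(idx)))
  })
  drug_long <- dplyr::bind_rows(drug_rows)
  drug_long <- drug_long[order(drug_long$caseid, drug_long$drug_j), ]
  drug_long$drug_seq <- stats::ave(seq_len(nrow(drug_long)),
                                   drug_long$caseid, FUN = seq_along)

  # reactions: baseline probability, boosted for implanted pairs among
  # cases exposed to the implicated drug
  np <- nrow(cfg$pts)
  reac_rows <- lapply(seq_len(np), function(k) {
    p <- rep(cfg$pts$p_base[k], n)
    imp <- cfg$implanted[cfg$implanted$pt_code == cfg$pts$pt_code[k], ]
    for (i in seq_len(nrow(imp))) {
      j <- match(imp$concept[i], cfg$drugs$concept)
      p[expo[, j]] <- pmin(1, imp$rho[i] * cfg$pts$p_base[k])
    }
    idx <- which(runif(n) < p)
    if (!length(idx)) return(NULL)
    tibble::tibble(caseid = caseid[idx], pt_k = k)
  })
  reac_long <- dplyr::bind_rows(reac_rows)
  missing_rx <- setdiff(caseid, reac_long$caseid)
  if (length(missing_rx)) {           # every case carries >= 1 reaction
    filler_k <- match(cfg$filler_pt, cfg$pts$pt_code)
    reac_long <- dplyr::bind_rows(
      reac_long, tibble::tibble(caseid = missing_rx, pt_k = filler_k))
  }
  reac_long <- reac_long[order(reac_long$caseid, reac_long$pt_k), ]
  reac_long$pt <- cfg$pts$pt_name[reac_long$pt_k]

  oc_rows <- lapply(names(cfg$outcome_probs), function(code) {
    idx <- which(runif(n) < cfg$outcome_probs[[code]])
    if (!length(idx)) return(NULL)
    tibble::tibble(caseid = caseid[idx], outc_cod = code)
  })
  outc_long <- dplyr::bind_rows(oc_rows)
  if (nrow(outc_long)) outc_long <- outc_long[order(outc_long$caseid), ]

  # versioned duplicates: identical content, strictly later receipt date
  dup <- runif(n) < cfg$duplicate_rate
  demo1 <- tibble::tibble(
    primaryid = paste0(caseid, "1"), caseid = caseid, caseversion = 1L,
    fda_dt = format(date1, "%Y%m%d"), sex = sex, age = age_val,
    age_cod = age_cod, reporter_country = country, quarter = qtr)
  demo <- demo1
  dup_ids <- character(0)
  if (any(dup)) {
    idx <- which(dup)
    date2 <- date1[idx] + sample(30:180, length(idx), replace = TRUE)
    q2 <- pmin(quarter_of_date(date2), nq)
    demo2 <- demo1[idx, ]
    demo2$primaryid <- paste0(caseid[idx], "2")
    demo2$caseversion <- 2L
    demo2$fda_dt <- format(date2, "%Y%m%d")
    demo2$quarter <- q2
    demo <- dplyr::bind_rows(demo1, demo2)
    dup_ids <- caseid[idx]
  }
  demo <- demo[order(demo$quarter, demo$caseid, demo$caseversion), ]

  version_of <- function(child) {
    out <- dplyr::left_join(child, demo[c("primaryid", "caseid",
                                          "caseversion", "quarter")],
                            by = "caseid", relationship = "many-to-many")
    out[order(out$quarter, out$caseid, out$caseversion), ]
  }
  drug_tab <- version_of(drug_long[c("caseid", "drug_seq", "role_cod",
                                     "drugname")])
  reac_tab <- version_of(reac_long[c("caseid", "pt")])
  outc_tab <- version_of(outc_long)

  truth <- list(
    cases = tibble::tibble(
      caseid = caseid,
      final_version = ifelse(caseid %in% dup_ids, 2L, 1L),
      final_primaryid = paste0(caseid, ifelse(caseid %in% dup_ids, "2", "1")),
      n_versions = ifelse(caseid %in% dup_ids, 2L, 1L),
      gender = dplyr::case_when(is.na(sex) ~ "unknown", sex == "M" ~ "male",
                                TRUE ~ "female"),
      age_band = band, country = country),
    drugs = tibble::tibble(caseid = drug_long$caseid,
                           concept = cfg$drugs$concept[drug_long$drug_j],
                           role = drug_long$role_cod),
    reactions = tibble::tibble(caseid = reac_long$caseid,
                               pt_code = cfg$pts$pt_code[reac_long$pt_k]),
    outcomes = outc_long,
    pairs = truth_pairs(cfg)
  )

  list(demo = demo,
       drug = drug_tab[c("primaryid", "caseid", "drug_seq", "role_cod",
                         "drugname", "quarter")],
       reac = reac_tab[c("primaryid", "caseid", "pt", "quarter")],
       outc = outc_tab[c("primaryid", "caseid", "outc_cod", "quarter")],
       truth = truth)
}

truth_pairs <- function(cfg) {
  grid <- tidyr::expand_grid(concept = cfg$drugs$concept,
                             pt_code = cfg$pts$pt_code)
  grid$rho <- 1
  for (i in seq_len(nrow(cfg$implanted))) {
    hit <- grid$concept == cfg$implanted$concept[i] &
      grid$pt_code == cfg$implanted$pt_code[i]
    grid$rho[hit] <- cfg$implanted$rho[i]
  }
  grid
}

# Random case/punctuation decoration of verbatim drug names; all variants
# normalize back to the same concept.
decorate_verbatim <- function(name, n) {
  style <- sample.int(3, n, replace = TRUE)
  out <- rep(name, n)
  out[style == 2] <- paste0(name, ".")
  low <- paste0(substr(name, 1, 1), tolower(substr(name, 2, nchar(name))))
  out[style == 3] <- low
  out
}

#' Generate a synthetic FAERS corpus on disk
#'
#' Writes `$`-delimited quarterly directories (`2013Q1/DEMO.txt`, ...) in
#' the layout [read_quarter()] reads, the drug dictionary and hierarchy CSVs
#' implied by the catalogs, a `truth/` directory with the ground-truth
#' tables, and a `manifest.yaml` echoing the full configuration. Runs with
#' the same config are byte-identical.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `quarter_dirs` and the in-memory
#'   `truth`.
#' @export
generate_faers <- function(cfg, dir) {
  sim <- simulate_cases(cfg)
  labels <- quarter_labels(cfg$n_quarters)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  wq <- function(tab, q, file) {
    sub <- tab[tab$quarter == q, setdiff(names(tab), "quarter"), drop = FALSE]
    readr::write_delim(sub, file, delim = "$", na = "")
  }
  qdirs <- character(cfg$n_quarters)
  for (q in seq_len(cfg$n_quarters)) {
    qd <- file.path(dir, labels[q])
    dir.create(qd, showWarnings = FALSE)
    wq(sim$demo, q, file.path(qd, "DEMO.txt"))
    wq(sim$drug, q, file.path(qd, "DRUG.txt"))
    wq(sim$reac, q, file.path(qd, "REAC.txt"))
    wq(sim$outc, q, file.path(qd, "OUTC.txt"))
    qdirs[q] <- qd
  }

  readr::write_csv(synthetic_dictionary(cfg), file.path(dir, "dictionary.csv"))
  h <- synthetic_hierarchy(cfg)
  readr::write_csv(h$pt, file.path(dir, "meddra_pt.csv"))
  readr::write_csv(h$soc, file.path(dir, "meddra_soc.csv"))

  td <- file.path(dir, "truth")
  dir.create(td, showWarnings = FALSE)
  readr::write_csv(sim$truth$cases, file.path(td, "truth_cases.csv"))
  readr::write_csv(sim$truth$drugs, file.path(td, "truth_drugs.csv"))
  readr::write_csv(sim$truth$reactions, file.path(td, "truth_reactions.csv"))
  readr::write_csv(sim$truth$pairs, file.path(td, "truth_pairs.csv"))
  if (nrow(sim$truth$outcomes)) {
    readr::write_csv(sim$truth$outcomes, file.path(td, "truth_outcomes.csv"))
  }
  yaml::write_yaml(config_as_list(cfg), file.path(dir, "manifest.yaml"))
  invisible(list(dir = dir, quarter_dirs = qdirs, truth = sim$truth))
}

config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$drugs <- as.list(as.data.frame(out$drugs))
  out$pts <- as.list(as.data.frame(out$pts))
  out$implanted <- as.list(as.data.frame(out$implanted))
  out$gender_split <- as.list(out$gender_split)
  out$age_band_probs <- as.list(out$age_band_probs)
  out$countries <- as.list(out$countries)
  out$outcome_probs <- as.list(out$outcome_probs)
  out
}

#' Realized reporting-rate ratio of a drug-PT pair
#'
#' Computes `[a/(a+b)] / [c/(c+d)]` from an assembled corpus, for verifying
#' that an implanted signal was realized at its configured strength.
#'
#' @param cases A `faers_cases` collection.
#' @param drug Drug concept id.
#' @param pt_code Preferred-term code.
#' @param role_filter Role codes defining exposure; defaults to all roles,
#'   since implantation conditions on any mention of the drug.
#' @return List with `rr`, the cells `a`, `b`, `c`, `d`, and `defined`
#'   (`FALSE`, with `rr = NA`, when a margin is empty).
#' @export
empirical_rr <- function(cases, drug, pt_code,
                         role_filter = c("PS", "SS", "C", "I")) {
  t <- suppressWarnings(
    build_contingency(cases, drug, pt_code, level = "PT",
                      role_filter = role_filter))
  defined <- (t$a + t$b) > 0 && t$c > 0 && (t$c + t$d) > 0
  rr <- if (defined) (t$a / (t$a + t$b)) / (t$c / (t$c + t$d)) else NA_real_
  list(rr = rr, a = t$a, b = t$b, c = t$c, d = t$d, defined = defined)
}
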