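#' Read a MedDRA-style hierarchy from CSV files
#'
#' Loads a preferred-term (PT) to System Organ Class (SOC) mapping of the kind
#' used to aggregate adverse-event terms for signal detection. Only the two
#' levels actually used analytically (PT and SOC) are required; HLGT/HLT
#' columns, if present in `pt_file`, are carried through untouched.
#'
#' @param pt_file CSV with columns `pt_code`, `pt_name`, `soc_code` (one row
#'   per PT; each PT maps to exactly one primary SOC).
#' @param soc_file CSV with columns `soc_code`, `soc_name`.
#' @return An object of class `meddra_hierarchy`: a list with tibbles `pt`
#'   and `soc`.
#' @examples
#' h <- read_meddra_hierarchy(
#'   system.file("extdata", "meddra_pt.csv", package = "faersignal"),
#'   system.file("extdata", "meddra_soc.csv", package = "faersignal")
#' )
#' map_pt_to_soc(h$pt$pt_code[1], h)
#' @export
read_meddra_hierarchy <- function(pt_file, soc_file) {
  pt <- readr::read_csv(pt_file, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  soc <- readr::read_csv(soc_file, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  req_pt <- c("pt_code", "pt_name", "soc_code")
  if (!all(req_pt %in% names(pt))) {
    stop("PT file must have columns: ", paste(req_pt, collapse = ", "))
  }
  if (!all(c("soc_code", "soc_name") %in% names(soc))) {
    stop("SOC file must have columns: soc_code, soc_name")
  }
  meddra_hierarchy(pt, soc)
}

#' Construct a MedDRA-style hierarchy from tibbles
#'
#' @param pt Tibble with `pt_code`, `pt_name`, `soc_code`.
#' @param soc Tibble with `soc_code`, `soc_name`.
#' @return A `meddra_hierarchy` object.
#' @export
meddra_hierarchy <- function(pt, soc) {
  pt <- tibble::as_tibble(pt)
  soc <- tibble::as_tibble(soc)
  if (anyDuplicated(pt$pt_code)) {
    dup <- unique(pt$pt_code[duplicated(pt$pt_code)])
    stop("PT codes map to more than one SOC: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(soc$soc_code)) {
    stop("SOC codes are not unique")
  }
  orphan <- setdiff(pt$soc_code, soc$soc_code)
  if (length(orphan)) {
    stop("PT rows reference unknown SOC codes: ", paste(orphan, collapse = ", "))
  }
  structure(list(pt = pt, soc = soc), class = "meddra_hierarchy")
}

#' @export
print.meddra_hierarchy <- function(x, ...) {
  cat("MedDRA-style hierarchy: ", nrow(x$pt), " PTs in ",
      nrow(x$soc), " SOCs\n", sep = "")
  invisible(x)
}

#' Map preferred-term codes to their primary System Organ Class
#'
#' @param pt Character vector of PT codes.
#' @param hierarchy A [meddra_hierarchy()].
#' @return Character vector of SOC codes, same length as `pt`.
#'   Unknown PT codes are an error listing the offending codes; callers that
#'   want to keep unmapped reactions route them to an explicit UNKNOWN bucket
#'   before calling (see `unknown_pt` in [assemble_case_reports()]).
#' @export
map_pt_to_soc <- function(pt, hierarchy) {
  stopifnot(inherits(hierarchy, "meddra_hierarchy"))
  idx <- match(pt, hierarchy$pt$pt_code)
  if (anyNA(idx)) {
    bad <- unique(pt[is.na(idx)])
    stop("unknown PT code(s): ", paste(bad, collapse = ", "))
  }
  hierarchy$pt$soc_code[idx]
}

#' Look up a PT code from its name
#'
#' Case-insensitive, whitespace-collapsed match of reaction verbatims (FAERS
#' REAC rows carry PT names, not codes) against the hierarchy.
#'
#' @param pt_name Character vector of PT names.
#' @param hierarchy A [meddra_hierarchy()].
#' @return Character vector of PT codes; `NA` where the name is unknown.
#' @export
pt_code_for_name <- function(pt_name, hierarchy) {
  stopifnot(inherits(hierarchy, "meddra_hierarchy"))
  key <- canonical_term(pt_name)
  tab <- canonical_term(hierarchy$pt$pt_name)
  hierarchy$pt$pt_code[match(key, tab)]
}

#' Read a drug synonym dictionary
#'
#' A minimal stand-in for an RxNorm-style normalization table: a two-column
#' CSV mapping uppercase verbatim synonyms (brand names, salts, misspellings)
#' to a single analytic concept id per ingredient.
#'
#' @param file CSV with columns `synonym`, `concept_id`.
#' @return A tibble with uppercase-trimmed `synonym` and `concept_id`.
#' @export
read_drug_dictionary <- function(file) {
  d <- readr::read_csv(file, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (!all(c("synonym", "concept_id") %in% names(d))) {
    stop("dictionary must have columns: synonym, concept_id")
  }
  d$synonym <- canonical_term(d$synonym)
  if (anyDuplicated(d$synonym)) {
    stop("dictionary has duplicated synonyms after normalization")
  }
  tibble::as_tibble(d)
}

#' Normalize verbatim drug names to concept ids
#'
#' Matching is case-insensitive after trimming, collapsing internal
#' whitespace, and stripping leading/trailing punctuation. Verbatims absent
#' from the dictionary return the sentinel `"UNMAPPED"` — a value, not an
#' error — so unmapped exposure is visible downstream rather than silently
#' dropped.
#'
#' @param verbatim Character vector of drug name strings as reported.
#' @param dictionary Tibble from [read_drug_dictionary()] (or with the same
#'   columns).
#' @return Character vector of concept ids.
#' @examples
#' dict <- tibble::tibble(synonym = c("CYCLOSPORINE", "NEORAL"),
#'                        concept_id = c("C1", "C1"))
#' normalize_drug_name(c("Cyclosporine.", "NEORAL", "XYZZY"), dict)
#' @export
normalize_drug_name <- function(verbatim, dictionary) {
  key <- canonical_term(verbatim)
  idx <- match(key, dictionary$synonym)
  out <- dictionary$concept_id[idx]
  out[is.na(out)] <- UNMAPPED
  out
}

# Shared canonical form for dictionary/hierarchy matching: uppercase, trim,
# collapse internal whitespace, strip leading/trailing punctuation runs.
canonical_term <- function(x) {
  x <- toupper(trimws(x))
  x <- gsub("\\s+", " ", x)
  x <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", x)
  trimws(x)
}
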