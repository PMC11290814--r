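#' Run the full signal-detection pipeline from a configuration
#'
#' Single entry point wiring the modules together: obtain a corpus (either
#' existing quarterly directories or a generated synthetic corpus), assemble
#' and deduplicate case reports, and write the report bundle — a
#' descriptives CSV, one ranked signal CSV per requested level, a log with
#' row counts at every stage, and a manifest echoing the full configuration
#' so any run can be reproduced. On error, partial outputs written by the
#' failed run are removed before the error propagates.
#'
#' Configuration fields (YAML file or list): exactly one of `input` (with
#' `quarters`, `dictionary`, `hierarchy_pt`, `hierarchy_soc`) or `generate`
#' (a [synthetic_config()] argument list); `drug` (target concept id);
#' optional `role_filter` (default `"PS"`), `levels` (default SOC and PT),
#' `min_a`, `sort`, `vic_method`, `haldane`, `top_countries`, `unknown_pt`,
#' `seed`.
#'
#' @param config Path to a YAML config or an equivalent named list.
#' @param output Output directory; overrides the config's `output` field.
#' @return Invisibly, a list with the assembled `cases`, the signal tables,
#'   and the paths written.
#' @export
run_pipeline <- function(config, output = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  out_dir <- output %||% config$output
  if (is.null(out_dir)) stop("config must name an output directory")
  has_input <- !is.null(config$input)
  has_gen <- !is.null(config$generate)
  if (has_input == has_gen) {
    stop("config must have exactly one of 'input' or 'generate'")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  written <- character(0)
  note <- function(path) { written <<- c(written, path); path }
  log_lines <- character(0)
  log_add <- function(stage, n) {
    log_lines <<- c(log_lines, sprintf("%-28s %d", stage, n))
  }

  run_impl <- function() {
    if (has_gen) {
      gen_args <- config$generate
      if (is.null(gen_args$seed)) gen_args$seed <- config$seed %||% 1L
      if (!is.null(gen_args$implanted)) {
        gen_args$implanted <- dplyr::bind_rows(gen_args$implanted)
      }
      cfg <- do.call(synthetic_config, gen_args)
      corpus_dir <- file.path(out_dir, "synthetic_corpus")
      gen <- generate_faers(cfg, corpus_dir)
      note(corpus_dir)
      quarter_dirs <- gen$quarter_dirs
      dictionary <- read_drug_dictionary(file.path(corpus_dir, "dictionary.csv"))
      hierarchy <- read_meddra_hierarchy(file.path(corpus_dir, "meddra_pt.csv"),
                                         file.path(corpus_dir, "meddra_soc.csv"))
    } else {
      quarter_dirs <- config$input$quarters
      missing_dirs <- quarter_dirs[!dir.exists(quarter_dirs)]
      if (length(missing_dirs)) {
        stop("input quarter directory not found: ",
             paste(missing_dirs, collapse = ", "))
      }
      dictionary <- read_drug_dictionary(config$input$dictionary)
      hierarchy <- read_meddra_hierarchy(config$input$hierarchy_pt,
                                         config$input$hierarchy_soc)
    }

    quarters <- lapply(quarter_dirs, read_quarter)
    for (q in quarters) {
      log_add(paste0("read ", basename(q$path), " demo rows"),
              q$log$rows[q$log$file == "demo"])
      log_add(paste0("read ", basename(q$path), " malformed rows"),
              sum(q$log$malformed))
    }
    cases <- assemble_case_reports(
      quarters, dictionary, hierarchy,
      unknown_pt = config$unknown_pt %||% "error")
    for (i in seq_len(nrow(cases$log))) {
      log_add(cases$log$stage[i], cases$log$rows[i])
    }

    desc <- descriptives_report(cases,
                                top_countries = config$top_countries %||% 6)
    readr::write_csv(desc, note(file.path(out_dir, "descriptives.csv")))

    drug <- config$drug
    role_filter <- config$role_filter %||% "PS"
    levels <- config$levels %||% c("SOC", "PT")
    if (length(levels) && is.null(drug)) {
      stop("config must name a target 'drug' concept")
    }
    signals <- list()
    for (lv in levels) {
      st <- signal_table(cases, drug, level = lv,
                         role_filter = role_filter,
                         min_a = config$min_a %||% 1,
                         sort = config$sort %||% "cases",
                         vic_method = config$vic_method %||% "delta",
                         haldane = isTRUE(config$haldane))
      signals[[lv]] <- st
      log_add(paste0("signal rows (", lv, ")"), nrow(st))
      readr::write_csv(format_signal_table(st),
                       note(file.path(out_dir,
                                      paste0("signals_", lv, ".csv"))))
    }

    writeLines(log_lines, note(file.path(out_dir, "pipeline_log.txt")))
    manifest <- list(
      package = "faersignal",
      version = as.character(utils::packageVersion("faersignal")),
      config = config)
    yaml::write_yaml(manifest, note(file.path(out_dir, "manifest.yaml")))
    invisible(list(cases = cases, signals = signals, files = written,
                   output = out_dir))
  }

  tryCatch(run_impl(), error = function(e) {
    unlink(written, recursive = TRUE, force = TRUE)
    stop(e)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
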