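# End-to-end screening workflow: scan tables + MSP library in, per-sample
# report (compound, four channel scores, average, hit, SIR confirmation)
# out as CSV, with the run configuration persisted alongside the outputs
# for provenance.

#' Run configuration
#'
#' @param library_msp Path to the reference library (MSP).
#' @param samples List of sample descriptors: each a list with `name`,
#'   `scan_table` (full-scan CSV path) and optional `sir_table` (SIR CSV
#'   path).
#' @param criteria A [match_criteria()] or a list of its arguments.
#' @param score_mode Passed to [screen()].
#' @param snr_min SIR confirmation cut.
#' @param out_dir Output directory for reports.
#' @return A validated `run_config` list.
#' @export
run_config <- function(library_msp, samples, criteria = match_criteria(),
                       score_mode = "reference", snr_min = 3.0,
                       out_dir = ".") {
  if (!inherits(criteria, "match_criteria")) {
    criteria <- do.call(match_criteria, criteria)
  }
  for (s in samples) {
    if (is.null(s$name) || is.null(s$scan_table)) {
      stop("each sample needs a name and a scan_table path")
    }
  }
  structure(
    list(library_msp = library_msp, samples = samples, criteria = criteria,
         score_mode = score_mode, snr_min = snr_min, out_dir = out_dir),
    class = "run_config"
  )
}

#' Persist / reload a run configuration
#'
#' Plain-text round trip via R's deparse syntax: the persisted file
#' reproduces the run exactly.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  dput(unclass_recursive(config), file = path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- dget(path)
  run_config(raw$library_msp, raw$samples, raw$criteria, raw$score_mode,
             raw$snr_min, raw$out_dir)
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_recursive)
  }
  if (!is.null(attr(x, "class"))) attr(x, "class") <- NULL
  x
}

#' Run the full screening workflow
#'
#' Loads the library, screens every sample's scan table, confirms hits
#' against SIR chronograms where a SIR table is supplied, writes one CSV
#' report per sample plus a combined summary into `out_dir`, and persists
#' the configuration next to them.
#'
#' @param config A [run_config()].
#' @param registry A `compound_registry`.
#' @return Named list of `screening_report`s, invisibly; reports are also
#'   written to `out_dir`.
#' @export
run_screening_workflow <- function(config, registry = default_registry()) {
  library <- library_from_msp(config$library_msp, registry)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- list()
  for (s in config$samples) {
    query <- read_scan_table(s$scan_table)
    rep <- screen(query, library, config$criteria, mode = config$score_mode)
    if (!is.null(s$sir_table)) {
      chron <- read_sir_table(s$sir_table)
      rep <- confirm_hits(rep, chron, registry, snr_min = config$snr_min)
    }
    utils::write.csv(as.data.frame(rep),
                     file.path(config$out_dir,
                               paste0("report_", gsub("\\W+", "_", s$name), ".csv")),
                     row.names = FALSE)
    reports[[s$name]] <- rep
  }
  summary <- do.call(rbind, lapply(names(reports), function(n) {
    r <- reports[[n]]
    hits <- r[r$hit, , drop = FALSE]
    data.frame(
      sample = n,
      n_hits = nrow(hits),
      hits = paste(hits$compound, collapse = ";"),
      sir_confirmed = if ("sir_confirmed" %in% names(r)) {
        paste(r$compound[r$sir_confirmed], collapse = ";")
      } else NA_character_
    )
  }))
  utils::write.csv(summary, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  write_run_config(config, file.path(config$out_dir, "run_config.R"))
  invisible(reports)
}
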