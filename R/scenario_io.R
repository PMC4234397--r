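#' Read a coverage scenario from CSV
#'
#' Expected columns: `intervention, year, baseline_coverage, target_coverage`
#' (UTF-8, comma-separated, header row, '.' decimal). Coverages are
#' fractions unless the file carries a `units` column declaring `percent` on
#' every row.
#'
#' @param path CSV path.
#' @return A [coverage_scenario()].
#' @export
read_coverage_scenario <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("units" %in% names(df)) {
    units <- unique(df$units)
    if (length(units) != 1L || !units %in% c("percent", "fraction")) {
      stop("scenario 'units' column must be uniformly 'percent' or 'fraction'",
           call. = FALSE)
    }
    if (units == "percent") {
      for (col in c("baseline_coverage", "target_coverage")) {
        if (any(df[[col]] > 100, na.rm = TRUE)) {
          stop(col, ": value exceeds 100 but units are 'percent'", call. = FALSE)
        }
        df[[col]] <- df[[col]] / 100
      }
    }
    df$units <- NULL
  }
  coverage_scenario(df)
}

#' Write a coverage scenario to CSV
#' @param scenario a [coverage_scenario()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_coverage_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "coverage_scenario"))
  utils::write.csv(as.data.frame(scenario), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a mortality envelope from CSV
#'
#' Expected columns: `year, diarrhea_deaths`.
#' @param path CSV path.
#' @return A [mortality_envelope()].
#' @export
read_mortality_envelope <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("year", "diarrhea_deaths")) {
    if (!col %in% names(df)) {
      stop("envelope CSV is missing column: ", col, call. = FALSE)
    }
  }
  mortality_envelope(df$diarrhea_deaths, year = df$year)
}

#' Write a mortality envelope to CSV
#' @param envelope a [mortality_envelope()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_mortality_envelope <- function(envelope, path) {
  stopifnot(inherits(envelope, "mortality_envelope"))
  utils::write.csv(as.data.frame(envelope), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a run report as CSV plus a JSON summary
#'
#' Produces `report.csv` (columns `year, intervention, averted, residual` in
#' cascade order) and `summary.json` (stable key order; per-year totals that
#' reconcile arithmetically, `baseline = total_averted + residual`; MD5
#' digests of the input files when given). The generation timestamp is
#' isolated inside the `meta` object so that re-running a deterministic
#' scenario produces identical files apart from that one field.
#'
#' @param report a `run_report` from [run_scenario()].
#' @param out_dir output directory (created if missing).
#' @param inputs optional named character vector of input file paths to
#'   digest into the summary.
#' @return Invisibly, the paths of the two files written.
#' @export
write_run_report <- function(report, out_dir, inputs = NULL) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(out_dir, "report.csv")
  json_path <- file.path(out_dir, "summary.json")
  utils::write.csv(report$steps, csv_path, row.names = FALSE, quote = FALSE)

  digests <- NULL
  if (!is.null(inputs)) {
    md5 <- tools::md5sum(inputs)
    digests <- stats::setNames(as.list(unname(md5)), names(inputs))
  }
  summary <- list(
    schema_version = report$meta$schema_version %||% PACK_SCHEMA_VERSION,
    years = lapply(seq_len(nrow(report$years)), function(i) {
      row <- report$years[i, ]
      list(year = row$year, baseline = row$baseline,
           total_averted = row$total_averted, residual = row$residual)
    }),
    inputs = digests,
    meta = list(strict = isTRUE(report$meta$strict),
                generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}
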