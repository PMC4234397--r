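#' Mortality envelope: baseline diarrhea deaths per year, children 1-59 months
#'
#' The envelope holds the annual number of diarrhea deaths among children aged
#' 1 to 59 months that the intervention cascade depletes. Only this single
#' cause and age window are modelled; no other causes of death enter the
#' model. An envelope may carry one row per projection year.
#'
#' @param diarrhea_deaths non-negative numeric vector of annual diarrhea
#'   deaths.
#' @param year calendar year(s); recycled to the length of `diarrhea_deaths`.
#'   Defaults to `1, 2, ...` when not supplied.
#' @return A `mortality_envelope`: a data frame with columns `year` and
#'   `diarrhea_deaths`.
#' @examples
#' mortality_envelope(10000)
#' mortality_envelope(c(10000, 9500), year = c(2024, 2025))
#' @export
mortality_envelope <- function(diarrhea_deaths, year = NULL) {
  deaths <- check_nonneg(diarrhea_deaths, "diarrhea_deaths")
  if (is.null(year)) year <- seq_along(deaths)
  if (length(year) != length(deaths)) {
    stop("'year' must have one entry per diarrhea_deaths value", call. = FALSE)
  }
  if (anyDuplicated(year)) stop("'year' values must be unique", call. = FALSE)
  out <- data.frame(year = as.integer(year), diarrhea_deaths = deaths)
  class(out) <- c("mortality_envelope", "data.frame")
  out
}

envelope_deaths <- function(envelope, year = NULL) {
  if (is.numeric(envelope) && length(envelope) == 1L) {
    return(check_nonneg(envelope, "diarrhea_deaths"))
  }
  stopifnot(inherits(envelope, "mortality_envelope"))
  if (is.null(year)) {
    if (nrow(envelope) != 1L) {
      stop("envelope has multiple years; supply 'year'", call. = FALSE)
    }
    return(envelope$diarrhea_deaths)
  }
  i <- match(as.integer(year), envelope$year)
  if (is.na(i)) stop(sprintf("no envelope entry for year %s", year), call. = FALSE)
  envelope$diarrhea_deaths[i]
}

#' Define an intervention
#'
#' An intervention is described by its cause-specific efficacy (the
#' proportional reduction in diarrhea mortality it achieves at full coverage
#' among the deaths it can act on), the affected fraction (the share of
#' diarrhea deaths it is mechanistically able to act on, such as the
#' Shigella-attributable share for dysentery antibiotics), its role in the
#' cascade, and an optional link to diarrhea incidence.
#'
#' Prevention interventions act on the mortality envelope before treatment
#' interventions; within a role group, input order is preserved (the final
#' residual does not depend on order, only the per-step attribution labels
#' do).
#'
#' @param name identifier, unique within a parameter pack.
#' @param role `"prevention"` or `"treatment"`; determines cascade position.
#' @param efficacy fraction in \[0, 1\]: reduction in cause-specific mortality
#'   among the affected fraction at full coverage.
#' @param affected_fraction fraction in \[0, 1\] of diarrhea deaths the
#'   intervention can act on (default 1, i.e. all diarrhea deaths).
#' @param incidence_efficacy fraction in \[0, 1\]: reduction of diarrhea
#'   incidence at full coverage (0 when the intervention has no incidence
#'   link).
#' @param incidence_affected_fraction fraction in \[0, 1\] of diarrhea
#'   incidence the incidence link acts on (for example the rotavirus share of
#'   episodes for rotavirus vaccine); default 1.
#' @param age_band target ages in months, `c(lower, upper)`.
#' @return An `intervention_spec` object.
#' @examples
#' # a vaccine halving diarrhea mortality among all 1-59 month deaths
#' intervention_spec("vaccine_a", "prevention", efficacy = 0.5)
#' # dysentery antibiotics: 99% effective on the 3.9% of deaths due to Shigella
#' intervention_spec("antibiotics_dysentery", "treatment",
#'                   efficacy = 0.99, affected_fraction = 0.039)
#' @export
intervention_spec <- function(name,
                              role = c("prevention", "treatment"),
                              efficacy = 0,
                              affected_fraction = 1,
                              incidence_efficacy = 0,
                              incidence_affected_fraction = 1,
                              age_band = c(1, 59)) {
  role <- match.arg(role)
  spec <- structure(list(
    name = check_string(name, "name"),
    role = role,
    efficacy = check_fraction(efficacy, "efficacy"),
    affected_fraction = check_fraction(affected_fraction, "affected_fraction"),
    incidence_efficacy = check_fraction(incidence_efficacy, "incidence_efficacy"),
    incidence_affected_fraction =
      check_fraction(incidence_affected_fraction, "incidence_affected_fraction"),
    age_band = as.numeric(age_band)
  ), class = "intervention_spec")
  spec
}

#' @export
print.intervention_spec <- function(x, ...) {
  cat(sprintf("<intervention_spec> %s (%s)\n", x$name, x$role))
  cat(sprintf("  efficacy %.3f on affected fraction %.3f of deaths\n",
              x$efficacy, x$affected_fraction))
  if (x$incidence_efficacy > 0) {
    cat(sprintf("  incidence efficacy %.3f on fraction %.3f of episodes\n",
                x$incidence_efficacy, x$incidence_affected_fraction))
  }
  invisible(x)
}

#' Coverage scenario: per-intervention coverage by year
#'
#' The model operates on the coverage *change* (target minus baseline) for
#' each intervention and year; worked scale-up examples that "introduce" an
#' intervention have an implicit baseline of zero.
#'
#' @param x a data frame with columns `intervention`, `year`,
#'   `baseline_coverage`, `target_coverage` (all coverages as fractions in
#'   \[0, 1\]), or a named numeric vector of coverage *changes* (baseline 0,
#'   year 1) as a shorthand for single-year scenarios.
#' @return A `coverage_scenario` data frame.
#' @examples
#' coverage_scenario(c(vaccine_a = 0.5))
#' coverage_scenario(data.frame(intervention = "ors", year = 2025,
#'                              baseline_coverage = 0.3, target_coverage = 0.74))
#' @export
coverage_scenario <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- data.frame(intervention = names(x), year = 1L,
                    baseline_coverage = 0, target_coverage = as.numeric(x))
  }
  required <- c("intervention", "year", "baseline_coverage", "target_coverage")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("scenario is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x)[required]
  x$intervention <- as.character(x$intervention)
  x$year <- as.integer(x$year)
  check_fraction(x$baseline_coverage, "baseline_coverage")
  check_fraction(x$target_coverage, "target_coverage")
  if (anyDuplicated(x[c("intervention", "year")])) {
    stop("duplicate (intervention, year) entries in scenario", call. = FALSE)
  }
  class(x) <- c("coverage_scenario", "data.frame")
  x
}

#' @export
print.coverage_scenario <- function(x, ...) {
  cat(sprintf("<coverage_scenario> %d entr%s, %d intervention(s), year(s) %s\n",
              nrow(x), if (nrow(x) == 1) "y" else "ies",
              length(unique(x$intervention)),
              paste(sort(unique(x$year)), collapse = ", ")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# Coverage changes for one year as a named vector over `names`; interventions
# absent from the scenario that year contribute a change of 0.
scenario_changes <- function(scenario, names, year = NULL, strict = TRUE) {
  if (is.numeric(scenario) && !is.null(names(scenario))) {
    scenario <- coverage_scenario(scenario)
  }
  stopifnot(inherits(scenario, "coverage_scenario"))
  rows <- if (is.null(year)) scenario else scenario[scenario$year == as.integer(year), ]
  if (is.null(year) && length(unique(scenario$year)) > 1L) {
    stop("scenario spans multiple years; supply 'year'", call. = FALSE)
  }
  unknown <- setdiff(setdiff(rows$intervention, names), "bf_promotion")
  if (length(unknown)) {
    stop("scenario references unknown intervention(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  delta <- stats::setNames(rep(0, length(names)), names)
  keep <- rows$intervention %in% names
  delta[rows$intervention[keep]] <-
    rows$target_coverage[keep] - rows$baseline_coverage[keep]
  if (strict && any(delta < 0)) {
    stop("coverage declines (target < baseline) for: ",
         paste(names(delta)[delta < 0], collapse = ", "),
         "; rerun with strict = FALSE to model declines", call. = FALSE)
  }
  delta
}
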