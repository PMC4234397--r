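#' Deaths averted by a single intervention
#'
#' The elementary lives-saved calculation: the change in coverage times the
#' efficacy of the intervention times the affected fraction, applied to the
#' cause-specific deaths. With 10,000 baseline deaths, an intervention that is
#' 50% effective reaching 50% of children averts 10,000 x 0.5 x 0.5 = 2,500
#' deaths, leaving 7,500.
#'
#' @param deaths non-negative count of diarrhea deaths the intervention acts
#'   on.
#' @param spec an [intervention_spec()].
#' @param coverage_change change in coverage as a fraction in \[0, 1\]
#'   (\[-1, 1\] with `strict = FALSE`, where a decline yields negative averted
#'   deaths).
#' @param strict reject negative coverage changes (default `TRUE`).
#' @return Deaths averted; never exceeds `deaths`.
#' @examples
#' vac <- intervention_spec("vaccine_a", "prevention", efficacy = 0.5)
#' deaths_averted_single(10000, vac, 0.5) # 2500
#' @export
deaths_averted_single <- function(deaths, spec, coverage_change, strict = TRUE) {
  deaths <- check_nonneg(deaths, "deaths")
  stopifnot(inherits(spec, "intervention_spec"))
  if (strict) {
    coverage_change <- check_fraction(coverage_change, "coverage_change")
  } else if (!is.numeric(coverage_change) || anyNA(coverage_change) ||
             abs(coverage_change) > 1) {
    stop("'coverage_change' must lie in [-1, 1]", call. = FALSE)
  }
  deaths * spec$efficacy * spec$affected_fraction * coverage_change
}

#' Apply a package of interventions as a residual-deaths cascade
#'
#' Each intervention removes `efficacy x affected_fraction x coverage_change`
#' of the deaths *remaining* after the interventions before it, so the joint
#' impact of a package is never double counted: the residual is the baseline
#' times the product of the per-intervention survival factors
#' `(1 - e_i * AF_i * dc_i)`. Prevention interventions act on diarrhea
#' mortality first; treatment interventions then act on the residual. The
#' final residual is order-invariant (the product is commutative); only the
#' per-step attribution labels depend on order.
#'
#' @param envelope a [mortality_envelope()] (or a single baseline death
#'   count).
#' @param specs list of [intervention_spec()] objects.
#' @param scenario a [coverage_scenario()] or named vector of coverage
#'   changes.
#' @param year projection year to evaluate (required when the envelope or
#'   scenario spans several years).
#' @param strict reject coverage declines (default `TRUE`). With
#'   `strict = FALSE` declines add deaths back.
#' @param ceiling optional upper bound on the residual under coverage
#'   declines (unbounded when `NULL`).
#' @return A `cascade_result` with elements `baseline_deaths`,
#'   `residual_deaths`, `total_averted` and `averted_by_step` (a data frame
#'   with one row per intervention in application order, columns
#'   `intervention`, `averted`, `residual`).
#' @examples
#' vac <- intervention_spec("vaccine_a", "prevention", efficacy = 0.5)
#' cascade(mortality_envelope(10000), list(vac), c(vaccine_a = 0.5))
#' @export
cascade <- function(envelope, specs, scenario, year = NULL, strict = TRUE,
                    ceiling = NULL) {
  deaths0 <- envelope_deaths(envelope, year)
  specs <- as_spec_list(specs)
  delta <- scenario_changes(scenario, vapply(specs, `[[`, "", "name"),
                            year, strict)
  # stable prevention-first ordering
  role <- vapply(specs, `[[`, "", "role")
  specs <- c(specs[role == "prevention"], specs[role == "treatment"])

  residual <- deaths0
  steps <- data.frame(intervention = character(0), averted = numeric(0),
                      residual = numeric(0))
  for (spec in specs) {
    averted <- deaths_averted_single(residual, spec, delta[[spec$name]],
                                     strict = strict)
    residual <- residual - averted
    if (!is.null(ceiling) && residual > ceiling) {
      averted <- averted + (residual - ceiling)
      residual <- ceiling
    }
    steps <- rbind(steps, data.frame(intervention = spec$name,
                                     averted = averted, residual = residual))
  }
  structure(list(
    baseline_deaths = deaths0,
    residual_deaths = residual,
    total_averted = deaths0 - residual,
    averted_by_step = steps,
    year = if (is.null(year)) NA_integer_ else as.integer(year)
  ), class = "cascade_result")
}

as_spec_list <- function(specs) {
  if (inherits(specs, "intervention_spec")) specs <- list(specs)
  if (!is.list(specs) ||
      !all(vapply(specs, inherits, TRUE, "intervention_spec"))) {
    stop("'specs' must be a list of intervention_spec objects", call. = FALSE)
  }
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("duplicate intervention names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  specs
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result>\n")
  cat(sprintf("  baseline deaths : %s\n", format(round_half_up(x$baseline_deaths))))
  cat(sprintf("  total averted   : %s\n", format(round_half_up(x$total_averted))))
  cat(sprintf("  residual deaths : %s\n", format(round_half_up(x$residual_deaths))))
  if (nrow(x$averted_by_step)) {
    cat("  by step:\n")
    df <- x$averted_by_step
    df$averted <- round_half_up(df$averted)
    df$residual <- round_half_up(df$residual)
    print.data.frame(df, row.names = FALSE)
  }
  invisible(x)
}

#' Extrapolate an observed effect linearly in coverage
#'
#' Community studies report a relative mortality reduction at the coverage
#' their program achieved. Assuming a linear trend between the relative
#' reduction in mortality and achieved coverage, the effect at another
#' coverage is `observed_effect * target_coverage / observed_coverage`,
#' clamped to 1. ORS, reported to reduce diarrhea mortality by 69% at 74%
#' coverage, extrapolates to a 93% reduction at full coverage.
#'
#' @param observed_effect relative mortality reduction observed, fraction in
#'   \[0, 1\].
#' @param observed_coverage coverage at which the effect was observed, in
#'   (0, 1\].
#' @param target_coverage coverage to extrapolate to, fraction in \[0, 1\].
#' @return Extrapolated effect as a fraction in \[0, 1\].
#' @examples
#' linear_effectiveness_at_coverage(0.69, 0.74, 1.0) # 0.9324...
#' @export
linear_effectiveness_at_coverage <- function(observed_effect, observed_coverage,
                                             target_coverage) {
  check_fraction(observed_effect, "observed_effect")
  check_fraction(target_coverage, "target_coverage")
  check_fraction(observed_coverage, "observed_coverage")
  if (observed_coverage == 0) {
    stop("'observed_coverage' is 0: the effect-per-coverage slope is undefined",
         call. = FALSE)
  }
  min(1, observed_effect * target_coverage / observed_coverage)
}

#' Attribute deaths averted to interventions by isolation runs
#'
#' Because the cascade applies each intervention to residual deaths, the
#' joint impact of a package is smaller than the sum of single-intervention
#' impacts, and per-step attribution depends on cascade position. To
#' understand one intervention's own potential contribution, the model is run
#' several times isolating individual interventions: each intervention is run
#' alone at its scenario coverage against the full baseline.
#'
#' @inheritParams cascade
#' @return An `isolation_attribution`: list with `per_intervention` (data
#'   frame of `intervention`, `isolated_averted`) and `package_total` (deaths
#'   averted by the full package run jointly). For interventions with
#'   affected fraction 1 the isolated effects sum to at least the package
#'   total.
#' @examples
#' specs <- list(intervention_spec("a", "prevention", efficacy = 0.5),
#'               intervention_spec("b", "treatment", efficacy = 0.5))
#' attribute_by_isolation(10000, specs, c(a = 0.5, b = 0.5))
#' @export
attribute_by_isolation <- function(envelope, specs, scenario, year = NULL,
                                   strict = TRUE) {
  specs <- as_spec_list(specs)
  if (is.numeric(scenario) && !is.null(names(scenario))) {
    scenario <- coverage_scenario(scenario)
  }
  full <- cascade(envelope, specs, scenario, year, strict)
  iso <- vapply(specs, function(sp) {
    solo <- scenario[scenario$intervention == sp$name, , drop = FALSE]
    class(solo) <- class(scenario)
    cascade(envelope, list(sp), solo, year, strict)$total_averted
  }, numeric(1))
  structure(list(
    per_intervention = data.frame(
      intervention = vapply(specs, `[[`, "", "name"),
      isolated_averted = iso
    ),
    package_total = full$total_averted
  ), class = "isolation_attribution")
}

#' @export
print.isolation_attribution <- function(x, ...) {
  cat("<isolation_attribution>\n")
  df <- x$per_intervention
  df$isolated_averted <- round_half_up(df$isolated_averted)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("  full-package total averted: %s\n",
              format(round_half_up(x$package_total))))
  invisible(x)
}

#' Ratio of deaths averted at two coverage levels
#'
#' Deaths averted by a single intervention are strictly proportional to the
#' coverage change: halving coverage halves the deaths prevented. This
#' returns the averted-deaths ratio between a lower and a higher coverage,
#' which equals `coverage_lo / coverage_hi` exactly.
#'
#' @param spec an [intervention_spec()] with nonzero
#'   `efficacy * affected_fraction`.
#' @param coverage_hi reference coverage change, in (0, 1\].
#' @param coverage_lo comparison coverage change, fraction in \[0, 1\].
#' @param deaths baseline deaths used for the computation (cancels in the
#'   ratio).
#' @return `averted(coverage_lo) / averted(coverage_hi)`.
#' @examples
#' zinc <- intervention_spec("zinc_treatment", "treatment", efficacy = 0.23)
#' coverage_linearity_ratio(zinc, 1.0, 0.5) # 0.5
#' @export
coverage_linearity_ratio <- function(spec, coverage_hi, coverage_lo,
                                     deaths = 10000) {
  check_positive(coverage_hi, "coverage_hi")
  hi <- deaths_averted_single(deaths, spec, coverage_hi)
  if (hi == 0) {
    stop("intervention has zero effect (efficacy x affected_fraction = 0); ",
         "the averted-deaths ratio is undefined", call. = FALSE)
  }
  deaths_averted_single(deaths, spec, coverage_lo) / hi
}
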