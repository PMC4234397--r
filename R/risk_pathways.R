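#' Diarrhea incidence state
#'
#' Most lives-saved calculations work on mortality alone, but diarrhea
#' incidence is kept in the model because it drives the stunting pathway:
#' fewer episodes per child-year mean less stunting, and less stunting means
#' lower diarrhea mortality.
#'
#' @param episodes_per_child_year non-negative diarrhea episode rate.
#' @param etiologic_fractions optional named vector of the fraction of
#'   incidence due to each etiology (each in \[0, 1\]).
#' @return An `incidence_state` object.
#' @examples
#' incidence_state(3.2, c(rotavirus = 0.4))
#' @export
incidence_state <- function(episodes_per_child_year, etiologic_fractions = NULL) {
  rate <- check_nonneg(episodes_per_child_year, "episodes_per_child_year")
  if (!is.null(etiologic_fractions)) {
    check_fraction(etiologic_fractions, "etiologic_fractions")
  }
  structure(list(episodes_per_child_year = rate,
                 etiologic_fractions = etiologic_fractions),
            class = "incidence_state")
}

#' Risk-factor distribution with per-stratum mortality relative risks
#'
#' Stunting (height-for-age) and wasting (weight-for-height) are modelled as
#' ordered severity strata, each with a prevalence and a relative risk of
#' diarrhea death; the risk of death increases with the degree of
#' undernutrition. The first stratum is the reference and must have relative
#' risk exactly 1. The default strata are the conventional four
#' height-for-age bands (HAZ >= -1, -1 to -2, -2 to -3, below -3), with the
#' two bands below -2 counting as stunted.
#'
#' @param factor `"stunting"` or `"wasting"`.
#' @param prevalences fractions summing to 1, one per stratum.
#' @param mortality_rr non-negative relative risks of diarrhea death, one per
#'   stratum; the first (reference) stratum must be exactly 1.
#' @param strata stratum labels (default: four HAZ/WHZ bands).
#' @param affected logical, which strata count as the affected (stunted or
#'   wasted) group moved by the incidence pathway; defaults to the strata
#'   below -2.
#' @return A `risk_factor_distribution` object.
#' @examples
#' risk_factor_distribution("stunting",
#'   prevalences = c(0.45, 0.25, 0.20, 0.10),
#'   mortality_rr = c(1, 1.2, 1.6, 2.1))
#' @export
risk_factor_distribution <- function(factor = c("stunting", "wasting"),
                                     prevalences, mortality_rr,
                                     strata = c("z>=-1", "-1>z>=-2",
                                                "-2>z>=-3", "z<-3"),
                                     affected = NULL) {
  factor <- match.arg(factor)
  strata <- as.character(strata)
  n <- length(strata)
  if (length(prevalences) != n || length(mortality_rr) != n) {
    stop("'prevalences' and 'mortality_rr' must have one value per stratum",
         call. = FALSE)
  }
  p <- check_fraction(prevalences, "prevalences")
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("prevalences must sum to 1 (got %.10f)", sum(p)), call. = FALSE)
  }
  rr <- check_nonneg(mortality_rr, "mortality_rr")
  if (rr[1] != 1) {
    stop("reference stratum (first) must have mortality_rr exactly 1",
         call. = FALSE)
  }
  if (is.null(affected)) {
    affected <- if (n == 4) c(FALSE, FALSE, TRUE, TRUE) else c(FALSE, rep(TRUE, n - 1))
  }
  stopifnot(is.logical(affected), length(affected) == n)
  structure(list(factor = factor, strata = strata,
                 prevalences = stats::setNames(p, strata),
                 mortality_rr = stats::setNames(rr, strata),
                 affected = stats::setNames(affected, strata)),
            class = "risk_factor_distribution")
}

#' @export
print.risk_factor_distribution <- function(x, ...) {
  cat(sprintf("<risk_factor_distribution> %s\n", x$factor))
  print.data.frame(data.frame(stratum = x$strata,
                              prevalence = x$prevalences,
                              mortality_rr = x$mortality_rr,
                              affected = x$affected),
                   row.names = FALSE)
  invisible(x)
}

#' Table of diarrhea death fractions by etiology
#'
#' The proportion of diarrhea deaths attributable to a specific pathogen
#' (rotavirus, Shigella/dysentery, cholera, ...) is used as the affected
#' fraction of etiology-specific interventions. Values are regional defaults
#' that should be overridden with country-specific information when
#' available; etiologies whose fraction is unknown may be entered as `NA`
#' and must be supplied before an intervention can link to them.
#'
#' @param fractions named numeric vector, etiology to fraction of diarrhea
#'   deaths (each in \[0, 1\], `NA` allowed for user-supplied placeholders).
#' @param region free-text region tag for provenance.
#' @return An `etiology_fraction_table` object.
#' @examples
#' etiology_fraction_table(c(dysentery = 0.039, rotavirus = NA), "global")
#' @export
etiology_fraction_table <- function(fractions, region = "global") {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("'fractions' must be a named vector of etiologies", call. = FALSE)
  }
  known <- fractions[!is.na(fractions)]
  if (length(known)) check_fraction(known, "fractions")
  structure(list(fractions = fractions, region = check_string(region, "region")),
            class = "etiology_fraction_table")
}

etiology_fraction <- function(table, etiology) {
  stopifnot(inherits(table, "etiology_fraction_table"))
  if (!etiology %in% names(table$fractions)) {
    stop(sprintf("unknown etiology '%s'; table (%s) has: %s", etiology,
                 table$region, paste(names(table$fractions), collapse = ", ")),
         call. = FALSE)
  }
  f <- table$fractions[[etiology]]
  if (is.na(f)) {
    stop(sprintf("etiology '%s' has no death fraction in table (%s); ",
                 etiology, table$region),
         "supply a regional or country-specific value", call. = FALSE)
  }
  f
}

#' Incidence multiplier from intervention scale-up
#'
#' Interventions with an incidence link (for example rotavirus vaccine, which
#' halves rotavirus diarrhea incidence) reduce the diarrhea episode rate by
#' `incidence_efficacy x incidence_affected_fraction x coverage_change` each,
#' compounded multiplicatively across interventions in analogy with the
#' mortality cascade.
#'
#' @param specs list of [intervention_spec()] objects.
#' @param scenario a [coverage_scenario()] or named vector of coverage
#'   changes.
#' @param year projection year (when the scenario spans several).
#' @param strict reject coverage declines (default `TRUE`).
#' @return Multiplier in (0, 1\] to apply to episodes per child-year.
#' @examples
#' rota <- intervention_spec("rotavirus_vaccine", "prevention",
#'                           incidence_efficacy = 0.5,
#'                           incidence_affected_fraction = 0.4)
#' incidence_multiplier(list(rota), c(rotavirus_vaccine = 1)) # 0.8
#' @export
incidence_multiplier <- function(specs, scenario, year = NULL, strict = TRUE) {
  specs <- as_spec_list(specs)
  if (!length(specs)) return(1)
  delta <- scenario_changes(scenario, vapply(specs, `[[`, "", "name"),
                            year, strict)
  mult <- 1
  for (spec in specs) {
    mult <- mult * (1 - spec$incidence_efficacy *
                      spec$incidence_affected_fraction * delta[[spec$name]])
  }
  mult
}

#' Shift a stunting distribution in response to an incidence change
#'
#' The impact of diarrhea incidence on stunting is modelled as a log-odds
#' transform: the odds of being in the affected (stunted) strata are scaled
#' by `odds_per_episode` raised to the change in episodes per child-year.
#' The per-episode odds multiplier is an external parameter estimated from
#' pooled cohort analyses and must be supplied explicitly: using this
#' pathway with a nonzero incidence change and no parameter is an error,
#' never a silent default. Prevalence mass moves between the affected and
#' unaffected groups proportionally within each group, and the result is
#' renormalized to sum to 1.
#'
#' @param baseline a [risk_factor_distribution()].
#' @param incidence_mult incidence multiplier from
#'   [incidence_multiplier()]; 1 leaves the distribution unchanged.
#' @param odds_per_episode positive odds multiplier for stunting per
#'   additional episode per child-year (values > 1 mean more episodes cause
#'   more stunting).
#' @param episodes_per_child_year baseline episode rate, used to convert the
#'   incidence multiplier into a change in episodes:
#'   `delta = episodes * (incidence_mult - 1)`.
#' @return A shifted `risk_factor_distribution`.
#' @examples
#' d <- risk_factor_distribution("stunting", c(0.6, 0.4), c(1, 2),
#'                               strata = c("not_stunted", "stunted"),
#'                               affected = c(FALSE, TRUE))
#' # halving an episode rate of 4/child-year removes 2 episodes
#' stunting_shift_from_incidence(d, 0.5, odds_per_episode = 1.05,
#'                               episodes_per_child_year = 4)
#' @export
stunting_shift_from_incidence <- function(baseline, incidence_mult,
                                          odds_per_episode = NULL,
                                          episodes_per_child_year = NULL) {
  stopifnot(inherits(baseline, "risk_factor_distribution"))
  check_fraction(incidence_mult, "incidence_mult")
  if (incidence_mult == 1) return(baseline)
  if (is.null(odds_per_episode)) {
    stop("the incidence-to-", baseline$factor, " pathway is unparameterized: ",
         "supply 'odds_per_episode' (pathway_params) before modelling a ",
         "nonzero incidence change", call. = FALSE)
  }
  check_positive(odds_per_episode, "odds_per_episode")
  if (odds_per_episode == 1) return(baseline)
  if (is.null(episodes_per_child_year)) {
    stop("supply 'episodes_per_child_year' to convert the incidence ",
         "multiplier into a change in episodes", call. = FALSE)
  }
  check_nonneg(episodes_per_child_year, "episodes_per_child_year")

  delta_episodes <- episodes_per_child_year * (incidence_mult - 1)
  p <- sum(baseline$prevalences[baseline$affected])
  if (p <= 0 || p >= 1) return(baseline)  # degenerate: nothing to move
  odds_new <- p / (1 - p) * odds_per_episode^delta_episodes
  p_new <- odds_new / (1 + odds_new)

  new_prev <- baseline$prevalences
  new_prev[baseline$affected] <- new_prev[baseline$affected] * p_new / p
  new_prev[!baseline$affected] <- new_prev[!baseline$affected] * (1 - p_new) / (1 - p)
  new_prev <- new_prev / sum(new_prev)
  risk_factor_distribution(baseline$factor, new_prev, baseline$mortality_rr,
                           strata = baseline$strata,
                           affected = baseline$affected)
}

#' Mortality multiplier from a risk-factor distribution shift
#'
#' A shift in the stunting (or wasting) distribution scales diarrhea deaths
#' by the ratio of prevalence-weighted mean mortality relative risks after
#' versus before the shift. This multiplier is applied to the mortality
#' envelope after prevention interventions and before the treatment cascade.
#'
#' @param before,after [risk_factor_distribution()] objects on the same
#'   factor and strata.
#' @return Multiplier `sum(after * RR) / sum(before * RR)`; 1 for identical
#'   distributions or flat relative risks.
#' @examples
#' b <- risk_factor_distribution("stunting", c(0.6, 0.4), c(1, 4),
#'                               strata = c("ok", "stunted"),
#'                               affected = c(FALSE, TRUE))
#' a <- risk_factor_distribution("stunting", c(0.8, 0.2), c(1, 4),
#'                               strata = c("ok", "stunted"),
#'                               affected = c(FALSE, TRUE))
#' mortality_multiplier_from_shift(b, a) # 1.6 / 2.2
#' @export
mortality_multiplier_from_shift <- function(before, after) {
  stopifnot(inherits(before, "risk_factor_distribution"),
            inherits(after, "risk_factor_distribution"))
  if (before$factor != after$factor ||
      !identical(before$strata, after$strata)) {
    stop("risk-factor distributions disagree on factor or strata", call. = FALSE)
  }
  sum(after$prevalences * before$mortality_rr) /
    sum(before$prevalences * before$mortality_rr)
}

#' Set an intervention's affected fraction from deficiency prevalence
#'
#' Vitamin A and preventive zinc supplementation only benefit children at
#' risk of the corresponding micronutrient deficiency; the percent of
#' children in the target age group at risk of deficiency is used as the
#' intervention's affected fraction. The cascade mathematics are otherwise
#' unchanged.
#'
#' @param intervention an [intervention_spec()].
#' @param deficiency_prevalence fraction in \[0, 1\] of children at risk of
#'   deficiency.
#' @return The spec with `affected_fraction` replaced.
#' @examples
#' vita <- intervention_spec("vitamin_a", "prevention", efficacy = 0.2)
#' deficiency_affected_fraction(vita, 0.3)$affected_fraction # 0.3
#' @export
deficiency_affected_fraction <- function(intervention, deficiency_prevalence) {
  stopifnot(inherits(intervention, "intervention_spec"))
  intervention$affected_fraction <-
    check_fraction(deficiency_prevalence, "deficiency_prevalence")
  intervention
}

#' Register a user-defined intervention
#'
#' New interventions (a cholera vaccine, an ETEC or Shigella vaccine trialled
#' through the blank "dummy vaccine" slots) are defined by naming their links
#' to outcomes — direct diarrhea mortality and/or diarrhea incidence — with
#' an efficacy per link. At least one link must be given; a template with
#' blank links is rejected until the user defines it. Linking the
#' intervention to an etiology sets its affected fraction to that etiology's
#' share of diarrhea deaths (and of incidence, for the incidence link).
#'
#' @param name identifier for the new intervention.
#' @param role `"prevention"` or `"treatment"`.
#' @param efficacy reduction in cause-specific mortality at full coverage
#'   (`NULL` for no direct mortality link).
#' @param incidence_efficacy reduction in diarrhea incidence at full coverage
#'   (`NULL` for no incidence link).
#' @param etiology optional etiology name; must exist (with a value) in
#'   `etiology_table`.
#' @param etiology_table an [etiology_fraction_table()], required when
#'   `etiology` is given.
#' @param age_band target ages in months.
#' @return A fully usable [intervention_spec()].
#' @examples
#' tab <- etiology_fraction_table(c(cholera = 0.05))
#' register_custom_intervention("cholera_vaccine", "prevention",
#'                              efficacy = 0.6, etiology = "cholera",
#'                              etiology_table = tab)
#' @export
register_custom_intervention <- function(name,
                                         role = c("prevention", "treatment"),
                                         efficacy = NULL,
                                         incidence_efficacy = NULL,
                                         etiology = NULL,
                                         etiology_table = NULL,
                                         age_band = c(1, 59)) {
  role <- match.arg(role)
  if (is.null(efficacy) && is.null(incidence_efficacy)) {
    stop(sprintf("intervention '%s' has no links: specify at least one of ",
                 name), "'efficacy' (direct mortality) or 'incidence_efficacy'",
         call. = FALSE)
  }
  af <- 1
  inc_af <- 1
  if (!is.null(etiology)) {
    if (is.null(etiology_table)) {
      stop("an 'etiology_table' is required when linking to an etiology",
           call. = FALSE)
    }
    af <- etiology_fraction(etiology_table, etiology)
    inc_af <- af
  }
  intervention_spec(name, role,
                    efficacy = efficacy %||% 0,
                    affected_fraction = af,
                    incidence_efficacy = incidence_efficacy %||% 0,
                    incidence_affected_fraction =
                      if (is.null(incidence_efficacy)) 1 else inc_af,
                    age_band = age_band)
}
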