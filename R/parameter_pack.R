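PACK_SCHEMA_VERSION <- "1.0"
PACK_KEYS <- c("schema_version", "units", "interventions", "breastfeeding",
               "etiology_fractions", "risk_factors", "pathway_params",
               "custom_interventions")

#' Assemble a parameter pack programmatically
#'
#' A parameter pack bundles everything the model needs apart from the
#' scenario and the mortality envelope: the intervention catalogue,
#' breastfeeding patterns with their promotion effects and mortality relative
#' risks, etiology death fractions, risk-factor distributions, and the
#' incidence-pathway parameters. Packs are usually read from file with
#' [load_parameter_pack()]; this constructor builds one from objects, e.g.
#' in the fixture generator.
#'
#' @param interventions list of [intervention_spec()] objects.
#' @param breastfeeding optional list with elements `bands` (named list per
#'   age band of `list(baseline = bf_pattern, promotion = promotion_effect)`),
#'   `rrs` (named list per band of per-category mortality relative risks) and
#'   optional `death_shares` (named fractions, one per band).
#' @param etiology_fractions optional [etiology_fraction_table()].
#' @param risk_factors optional list with elements `stunting` and/or
#'   `wasting`, each a [risk_factor_distribution()].
#' @param pathway_params list; recognised entries `odds_per_episode` and
#'   `episodes_per_child_year` parameterize the incidence-to-stunting
#'   pathway. Both default to `NULL`, which keeps the pathway inert until the
#'   user supplies values (it errors rather than guessing).
#' @param custom_interventions list of templates for user-definable
#'   interventions; blank templates carry `links = NULL` and are unusable
#'   until defined through [register_custom_intervention()].
#' @param schema_version pack schema version string.
#' @return A `parameter_pack` object.
#' @export
parameter_pack <- function(interventions,
                           breastfeeding = NULL,
                           etiology_fractions = NULL,
                           risk_factors = NULL,
                           pathway_params = list(odds_per_episode = NULL,
                                                 episodes_per_child_year = NULL),
                           custom_interventions = list(),
                           schema_version = PACK_SCHEMA_VERSION) {
  interventions <- as_spec_list(interventions)
  names(interventions) <- vapply(interventions, `[[`, "", "name")
  pack <- structure(list(
    schema_version = check_string(schema_version, "schema_version"),
    interventions = interventions,
    breastfeeding = breastfeeding,
    etiology_fractions = etiology_fractions,
    risk_factors = risk_factors,
    pathway_params = pathway_params,
    custom_interventions = custom_interventions
  ), class = "parameter_pack")
  validate_parameter_pack(pack)
  pack
}

#' @export
print.parameter_pack <- function(x, ...) {
  cat(sprintf("<parameter_pack> schema %s\n", x$schema_version))
  cat(sprintf("  interventions: %s\n",
              paste(names(x$interventions), collapse = ", ")))
  if (!is.null(x$breastfeeding)) {
    cat(sprintf("  breastfeeding bands: %s\n",
                paste(names(x$breastfeeding$bands), collapse = ", ")))
  }
  if (!is.null(x$etiology_fractions)) {
    cat(sprintf("  etiologies (%s): %s\n", x$etiology_fractions$region,
                paste(names(x$etiology_fractions$fractions), collapse = ", ")))
  }
  invisible(x)
}

#' Validate a parameter pack (and optionally a scenario against it)
#'
#' Checks the structural invariants that the constructors cannot see in
#' isolation: intervention names are unique, every etiology reference
#' resolves, breastfeeding bands are consistent with their relative-risk
#' vectors, and every intervention a scenario references exists in the pack.
#'
#' @param pack a `parameter_pack`.
#' @param scenario optional [coverage_scenario()] to cross-check.
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_parameter_pack <- function(pack, scenario = NULL) {
  stopifnot(inherits(pack, "parameter_pack"))
  as_spec_list(pack$interventions)
  if (!is.null(pack$etiology_fractions)) {
    stopifnot(inherits(pack$etiology_fractions, "etiology_fraction_table"))
  }
  if (!is.null(pack$breastfeeding)) {
    bf <- pack$breastfeeding
    for (band in names(bf$bands)) {
      entry <- bf$bands[[band]]
      if (!inherits(entry$baseline, "bf_pattern")) {
        stop(sprintf("breastfeeding.bands.%s.baseline is not a bf_pattern", band),
             call. = FALSE)
      }
      if (entry$baseline$age_band != band) {
        stop(sprintf("breastfeeding.bands.%s carries a pattern for band %s",
                     band, entry$baseline$age_band), call. = FALSE)
      }
      if (!is.null(entry$promotion) &&
          !inherits(entry$promotion, "promotion_effect")) {
        stop(sprintf("breastfeeding.bands.%s.promotion is not a promotion_effect",
                     band), call. = FALSE)
      }
      rr <- bf$rrs[[band]]
      if (!is.null(rr)) {
        missing_rr <- setdiff(names(entry$baseline$prevalences), names(rr))
        if (length(missing_rr)) {
          stop(sprintf("breastfeeding.rrs.%s is missing categories: %s", band,
                       paste(missing_rr, collapse = ", ")), call. = FALSE)
        }
      }
    }
    if (!is.null(bf$death_shares)) {
      extra <- setdiff(names(bf$death_shares), names(bf$bands))
      if (length(extra)) {
        stop("breastfeeding.death_shares names unknown band(s): ",
             paste(extra, collapse = ", "), call. = FALSE)
      }
      check_fraction(unlist(bf$death_shares), "breastfeeding.death_shares")
    }
  }
  for (factor in names(pack$risk_factors)) {
    d <- pack$risk_factors[[factor]]
    if (!is.null(d) && !inherits(d, "risk_factor_distribution")) {
      stop(sprintf("risk_factors.%s is not a risk_factor_distribution", factor),
           call. = FALSE)
    }
  }
  pp <- pack$pathway_params
  if (!is.null(pp$odds_per_episode)) {
    check_positive(pp$odds_per_episode, "pathway_params.odds_per_episode")
  }
  if (!is.null(pp$episodes_per_child_year)) {
    check_nonneg(pp$episodes_per_child_year,
                 "pathway_params.episodes_per_child_year")
  }
  if (!is.null(scenario)) {
    scenario_changes(scenario, names(pack$interventions),
                     year = unique(scenario$year)[1], strict = FALSE)
    for (yr in unique(scenario$year)) {
      scenario_changes(scenario, names(pack$interventions), yr, strict = FALSE)
    }
  }
  invisible(TRUE)
}

# ---- file IO ---------------------------------------------------------------

pack_read_raw <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop("parameter pack must be .json, .yaml or .yml, got: ", path,
         call. = FALSE)
  }
}

# unit-aware numeric extraction; `at` is a JSON-pointer-style path used in
# error messages
pp_num <- function(x, at, percent = FALSE, scaled = TRUE) {
  if (is.null(x)) return(NULL)
  x <- unlist(x, use.names = TRUE)
  if (!is.numeric(x)) stop(sprintf("%s: expected a number", at), call. = FALSE)
  if (percent && scaled) {
    if (any(x > 100, na.rm = TRUE)) {
      stop(sprintf("%s: value %s exceeds 100 but units are 'percent'",
                   at, format(max(x, na.rm = TRUE))), call. = FALSE)
    }
    x <- x / 100
  }
  x
}

#' Load and validate a parameter pack from JSON or YAML
#'
#' Reads a pack file, normalizes units to fractions, resolves
#' observed-effect-at-coverage entries into full-coverage efficacies via
#' [linear_effectiveness_at_coverage()], resolves etiology links into
#' affected fractions, and validates every invariant before returning.
#'
#' The file declares its units once, at the top level: `"units": "percent"`
#' or `"units": "fraction"`. Under percent units, all efficacies, coverages,
#' prevalences and fractions are divided by 100 on load; a percent value
#' above 100 is a unit error. Relative risks, odds multipliers and episode
#' rates are never unit-scaled.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` pack file.
#' @param strict reject unknown top-level keys (default `TRUE`).
#' @return A validated `parameter_pack` with all values as fractions.
#' @examples
#' pack <- default_parameter_pack()
#' pack$interventions$zinc_treatment$efficacy # 0.23
#' @export
load_parameter_pack <- function(path, strict = TRUE) {
  raw <- pack_read_raw(path)
  unknown <- setdiff(names(raw), PACK_KEYS)
  if (strict && length(unknown)) {
    stop("unknown parameter-pack key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  units <- raw$units %||% "fraction"
  if (!units %in% c("percent", "fraction")) {
    stop("units: must declare 'percent' or 'fraction', got '", units, "'",
         call. = FALSE)
  }
  pct <- units == "percent"

  etio <- NULL
  if (!is.null(raw$etiology_fractions)) {
    fr <- raw$etiology_fractions$fractions
    vals <- vapply(fr, function(v) {
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    vals[!is.na(vals)] <- pp_num(vals[!is.na(vals)], "etiology_fractions", pct)
    etio <- etiology_fraction_table(
      stats::setNames(vals, names(fr)),
      region = raw$etiology_fractions$region %||% "global")
  }

  specs <- lapply(seq_along(raw$interventions), function(i) {
    rec <- raw$interventions[[i]]
    at <- sprintf("interventions[%d]", i)
    name <- rec$name %||% stop(at, ".name is required", call. = FALSE)
    af <- pp_num(rec$affected_fraction, paste0(at, ".affected_fraction"), pct) %||% 1
    inc_af <- pp_num(rec$incidence_affected_fraction,
                     paste0(at, ".incidence_affected_fraction"), pct) %||% 1
    if (!is.null(rec$etiology)) {
      if (is.null(etio)) {
        stop(at, ".etiology: pack declares no etiology_fractions table",
             call. = FALSE)
      }
      af <- etiology_fraction(etio, rec$etiology)
    }
    eff <- pp_num(rec$efficacy, paste0(at, ".efficacy"), pct)
    if (!is.null(rec$observed_effect)) {
      # an observed effect at an achieved coverage extrapolates linearly to
      # an efficacy at full coverage
      eff <- linear_effectiveness_at_coverage(
        pp_num(rec$observed_effect, paste0(at, ".observed_effect"), pct),
        pp_num(rec$observed_coverage, paste0(at, ".observed_coverage"), pct),
        1.0)
    }
    intervention_spec(
      name = name,
      role = rec$role %||% "prevention",
      efficacy = eff %||% 0,
      affected_fraction = af,
      incidence_efficacy =
        pp_num(rec$incidence_efficacy, paste0(at, ".incidence_efficacy"), pct) %||% 0,
      incidence_affected_fraction = inc_af,
      age_band = as.numeric(unlist(rec$age_band %||% c(1, 59)))
    )
  })

  bf <- NULL
  if (!is.null(raw$breastfeeding)) {
    bands <- lapply(names(raw$breastfeeding$bands), function(band) {
      entry <- raw$breastfeeding$bands[[band]]
      baseline <- bf_pattern(band, pp_num(entry$baseline,
                                          sprintf("breastfeeding.bands.%s.baseline", band),
                                          pct))
      promo <- NULL
      if (!is.null(entry$promotion)) {
        mode <- entry$promotion$mode %||% "target_rate"
        value <- entry$promotion$value
        # relative risks are ratios, never percent-scaled
        value <- if (mode == "target_rate") {
          pp_num(value, sprintf("breastfeeding.bands.%s.promotion.value", band), pct)
        } else {
          as.numeric(value)
        }
        promo <- promotion_effect(mode, value,
                                  promotion_coverage =
                                    as.numeric(entry$promotion$promotion_coverage %||% 1))
      }
      list(baseline = baseline, promotion = promo)
    })
    names(bands) <- names(raw$breastfeeding$bands)
    rrs <- lapply(raw$breastfeeding$rrs, function(v) unlist(v))
    shares <- if (!is.null(raw$breastfeeding$death_shares)) {
      pp_num(raw$breastfeeding$death_shares, "breastfeeding.death_shares", pct)
    }
    bf <- list(bands = bands, rrs = rrs, death_shares = shares)
  }

  rf <- NULL
  if (!is.null(raw$risk_factors)) {
    rf <- lapply(names(raw$risk_factors), function(factor) {
      rec <- raw$risk_factors[[factor]]
      if (is.null(rec)) return(NULL)
      risk_factor_distribution(
        factor,
        prevalences = pp_num(rec$prevalences,
                             sprintf("risk_factors.%s.prevalences", factor), pct),
        mortality_rr = as.numeric(unlist(rec$mortality_rr)),
        strata = as.character(unlist(rec$strata)),
        affected = if (!is.null(rec$affected)) as.logical(unlist(rec$affected))
      )
    })
    names(rf) <- names(raw$risk_factors)
  }

  pp <- list(
    odds_per_episode =
      if (!is.null(raw$pathway_params$odds_per_episode))
        as.numeric(raw$pathway_params$odds_per_episode),
    episodes_per_child_year =
      if (!is.null(raw$pathway_params$episodes_per_child_year))
        as.numeric(raw$pathway_params$episodes_per_child_year)
  )

  parameter_pack(
    interventions = specs,
    breastfeeding = bf,
    etiology_fractions = etio,
    risk_factors = rf,
    pathway_params = pp,
    custom_interventions = raw$custom_interventions %||% list(),
    schema_version = raw$schema_version %||% PACK_SCHEMA_VERSION
  )
}

#' Write a parameter pack to JSON
#'
#' Serializes with units declared as fractions and stable key order, so that
#' a save–load round trip reproduces the pack exactly.
#'
#' @param pack a `parameter_pack`.
#' @param path output path ending in `.json`.
#' @return Invisibly, `path`.
#' @export
write_parameter_pack <- function(pack, path) {
  stopifnot(inherits(pack, "parameter_pack"))
  out <- list(
    schema_version = pack$schema_version,
    units = "fraction",
    interventions = lapply(unname(pack$interventions), function(sp) {
      list(name = sp$name, role = sp$role, efficacy = sp$efficacy,
           affected_fraction = sp$affected_fraction,
           incidence_efficacy = sp$incidence_efficacy,
           incidence_affected_fraction = sp$incidence_affected_fraction,
           age_band = sp$age_band)
    })
  )
  if (!is.null(pack$breastfeeding)) {
    bf <- pack$breastfeeding
    out$breastfeeding <- list(
      bands = lapply(bf$bands, function(entry) {
        rec <- list(baseline = as.list(entry$baseline$prevalences))
        if (!is.null(entry$promotion)) {
          rec$promotion <- list(mode = entry$promotion$mode,
                                value = entry$promotion$value,
                                promotion_coverage = entry$promotion$promotion_coverage)
        }
        rec
      }),
      rrs = lapply(bf$rrs, as.list),
      death_shares = if (!is.null(bf$death_shares)) as.list(bf$death_shares)
    )
  }
  if (!is.null(pack$etiology_fractions)) {
    out$etiology_fractions <- list(
      region = pack$etiology_fractions$region,
      fractions = lapply(as.list(pack$etiology_fractions$fractions),
                         function(v) if (is.na(v)) NULL else v)
    )
  }
  if (!is.null(pack$risk_factors)) {
    out$risk_factors <- lapply(pack$risk_factors, function(d) {
      if (is.null(d)) return(NULL)
      list(strata = d$strata, prevalences = unname(d$prevalences),
           mortality_rr = unname(d$mortality_rr), affected = unname(d$affected))
    })
  }
  out$pathway_params <- list(
    odds_per_episode = pack$pathway_params$odds_per_episode,
    episodes_per_child_year = pack$pathway_params$episodes_per_child_year
  )
  out$custom_interventions <- pack$custom_interventions
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' The bundled default parameter pack
#'
#' Loads the pack shipped with the package. It carries only the published
#' headline effectiveness values for the direct diarrhea interventions —
#' zinc treatment efficacy 23%, dysentery antibiotics efficacy 99% acting on
#' the 3.9% Shigella share of diarrhea deaths, rotavirus vaccine halving
#' rotavirus diarrhea incidence, ORS at a 69% mortality reduction observed at
#' 74% coverage (so 93% extrapolated to full coverage) — plus the worked
#' breastfeeding patterns for the 0-1 and 1-5 month bands and blank
#' "vaccine B"/"vaccine C" templates. Regional quantities with no published
#' headline number (the rotavirus death fraction, deficiency prevalences,
#' stunting prevalences and relative risks, the incidence-to-stunting odds
#' parameter) are left null or inert for the user to supply.
#'
#' @return A `parameter_pack`.
#' @export
default_parameter_pack <- function() {
  load_parameter_pack(system.file("extdata", "default_pack.json",
                                  package = "averted", mustWork = TRUE))
}
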