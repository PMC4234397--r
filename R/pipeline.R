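#' Run a coverage scenario through the full pipeline
#'
#' Executes, for each projection year, the full ordering of effects:
#' \enumerate{
#'   \item prevention interventions act on direct mortality (residual
#'     cascade) and on diarrhea incidence;
#'   \item the reduced incidence shifts the stunting distribution (when the
#'     pathway is parameterized);
#'   \item the stunting-shift mortality multiplier — and, when the scenario
#'     scales up the `bf_promotion` pseudo-intervention, the
#'     breastfeeding-pattern multiplier — applies to the residual;
#'   \item treatment interventions act on the remaining residual deaths.
#' }
#' Each year's cascade starts from that year's envelope; there are no
#' within-year dynamics. With the indirect pathways neutral (no incidence
#' links, odds multiplier 1, flat relative risks) the result equals the
#' direct-only [cascade()].
#'
#' @param pack a `parameter_pack`.
#' @param scenario a [coverage_scenario()]. A row with intervention
#'   `bf_promotion` drives breastfeeding promotion at that coverage change.
#' @param envelope a [mortality_envelope()] (single- or multi-year) or a
#'   single baseline death count applied to every scenario year.
#' @param strict reject coverage declines (default `TRUE`).
#' @return A `run_report`: list with `years` (data frame `year`, `baseline`,
#'   `total_averted`, `residual`), `steps` (data frame `year`,
#'   `intervention`, `averted`, `residual` in application order, including
#'   pseudo-steps `stunting_pathway` and `bf_promotion` when active) and
#'   `meta`.
#' @examples
#' pack <- default_parameter_pack()
#' sc <- coverage_scenario(data.frame(intervention = "ors", year = 1,
#'                                    baseline_coverage = 0,
#'                                    target_coverage = 0.5))
#' run_scenario(pack, sc, mortality_envelope(10000))
#' @export
run_scenario <- function(pack, scenario, envelope, strict = TRUE) {
  stopifnot(inherits(pack, "parameter_pack"))
  if (is.numeric(scenario)) scenario <- coverage_scenario(scenario)
  validate_parameter_pack(pack, scenario)
  years <- sort(unique(scenario$year))
  if (!length(years)) {
    # an empty scenario is the identity over the envelope's own years
    years <- if (inherits(envelope, "mortality_envelope")) envelope$year else 1L
  }
  specs <- unname(pack$interventions)
  role <- vapply(specs, `[[`, "", "role")
  prev_specs <- specs[role == "prevention"]
  treat_specs <- specs[role == "treatment"]
  sub_scenario <- function(names) {
    out <- scenario[scenario$intervention %in% names, , drop = FALSE]
    class(out) <- class(scenario)
    out
  }
  prev_scenario <- sub_scenario(vapply(prev_specs, `[[`, "", "name"))
  treat_scenario <- sub_scenario(vapply(treat_specs, `[[`, "", "name"))
  all_scenario <- sub_scenario(vapply(specs, `[[`, "", "name"))

  steps_all <- NULL
  summary_rows <- NULL
  for (yr in years) {
    baseline <- if (is.numeric(envelope) || nrow(envelope) == 1L) {
      envelope_deaths(envelope)
    } else {
      envelope_deaths(envelope, yr)
    }

    # (1) prevention: direct mortality + incidence
    res_prev <- cascade(baseline, prev_specs, prev_scenario, yr, strict)
    steps <- res_prev$averted_by_step
    residual <- res_prev$residual_deaths
    inc_mult <- incidence_multiplier(specs, all_scenario, yr, strict)

    # (2)+(3) incidence -> stunting shift -> mortality multiplier
    stunt <- pack$risk_factors$stunting
    if (!is.null(stunt) && inc_mult != 1) {
      shifted <- stunting_shift_from_incidence(
        stunt, inc_mult,
        odds_per_episode = pack$pathway_params$odds_per_episode,
        episodes_per_child_year = pack$pathway_params$episodes_per_child_year)
      m_stunt <- mortality_multiplier_from_shift(stunt, shifted)
      if (m_stunt != 1) {
        averted <- residual * (1 - m_stunt)
        residual <- residual * m_stunt
        steps <- rbind(steps, data.frame(intervention = "stunting_pathway",
                                         averted = averted, residual = residual))
      }
    }

    # (3) breastfeeding promotion multiplier
    m_bf <- bf_promotion_multiplier(pack, scenario, yr, strict)
    if (m_bf != 1) {
      averted <- residual * (1 - m_bf)
      residual <- residual * m_bf
      steps <- rbind(steps, data.frame(intervention = "bf_promotion",
                                       averted = averted, residual = residual))
    }

    # (4) treatment cascade on the residual
    res_treat <- cascade(residual, treat_specs, treat_scenario, yr, strict)
    steps <- rbind(steps, res_treat$averted_by_step)
    residual <- res_treat$residual_deaths

    if (nrow(steps)) steps <- cbind(year = yr, steps)
    steps_all <- rbind(steps_all, steps)
    summary_rows <- rbind(summary_rows, data.frame(
      year = yr, baseline = baseline,
      total_averted = baseline - residual, residual = residual))
  }
  structure(list(years = summary_rows,
                 steps = steps_all %||%
                   data.frame(year = integer(0), intervention = character(0),
                              averted = numeric(0), residual = numeric(0)),
                 meta = list(schema_version = pack$schema_version,
                             strict = strict)),
            class = "run_report")
}

# Combined per-band breastfeeding multiplier, weighted by each band's share
# of diarrhea deaths (equal shares when the pack declares none).
bf_promotion_multiplier <- function(pack, scenario, year, strict = TRUE) {
  if (is.null(pack$breastfeeding)) return(1)
  rows <- scenario[scenario$intervention == "bf_promotion" &
                     scenario$year == as.integer(year), ]
  if (!nrow(rows)) return(1)
  delta <- rows$target_coverage[1] - rows$baseline_coverage[1]
  if (strict && delta < 0) {
    stop("coverage declines (target < baseline) for: bf_promotion",
         call. = FALSE)
  }
  if (delta == 0) return(1)
  bf <- pack$breastfeeding
  bands <- names(bf$bands)
  shares <- bf$death_shares %||%
    stats::setNames(rep(1 / length(bands), length(bands)), bands)
  total <- 0
  weight <- 0
  for (band in bands) {
    entry <- bf$bands[[band]]
    if (is.null(entry$promotion)) next
    before <- entry$baseline
    eff <- entry$promotion
    eff_scaled <- if (eff$mode == "relative_risk") {
      promotion_effect("relative_risk", eff$value,
                       promotion_coverage = eff$promotion_coverage * delta)
    } else {
      # a target rate reached at full promotion coverage is approached
      # linearly in the coverage change
      base_opt <- before$prevalences[[bf_optimal_category(band)]]
      promotion_effect("target_rate",
                       base_opt + (eff$value - base_opt) * delta)
    }
    after <- apply_promotion(before, eff_scaled)
    rr <- bf$rrs[[band]]
    m <- if (is.null(rr)) 1 else pattern_mortality_multiplier(before, after, rr)
    w <- shares[[band]] %||% 0
    total <- total + w * m
    weight <- weight + w
  }
  if (weight == 0) 1 else total / weight
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  df <- x$years
  df$total_averted <- round_half_up(df$total_averted)
  df$residual <- round_half_up(df$residual)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Attribute pipeline impact to interventions by isolation runs
#'
#' Runs the full pipeline once per intervention named in the scenario with
#' all other coverage changes removed, and once for the whole package, per
#' year. The `bf_promotion` pseudo-intervention is isolated like any other.
#'
#' @inheritParams run_scenario
#' @return A data frame with columns `year`, `intervention`,
#'   `isolated_averted`, `package_total`.
#' @export
attribute_scenario <- function(pack, scenario, envelope, strict = TRUE) {
  if (is.numeric(scenario)) scenario <- coverage_scenario(scenario)
  full <- run_scenario(pack, scenario, envelope, strict)
  out <- NULL
  for (nm in unique(scenario$intervention)) {
    sub <- scenario[scenario$intervention == nm, ]
    class(sub) <- class(scenario)
    rep_i <- run_scenario(pack, sub, envelope, strict)
    merged <- merge(rep_i$years[c("year", "total_averted")],
                    full$years[c("year", "total_averted")],
                    by = "year", all.x = TRUE, suffixes = c("_iso", "_full"))
    out <- rbind(out, data.frame(year = merged$year, intervention = nm,
                                 isolated_averted = merged$total_averted_iso,
                                 package_total =
                                   ifelse(is.na(merged$total_averted_full), 0,
                                          merged$total_averted_full)))
  }
  out[order(out$year, out$intervention), , drop = FALSE]
}
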