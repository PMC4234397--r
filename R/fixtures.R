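#' Generate a reproducible random fixture
#'
#' Builds a random-but-valid parameter pack, coverage scenario and mortality
#' envelope for tests and demos. Efficacies and affected fractions are drawn
#' in \[0, 1\], coverage trajectories are monotone non-decreasing over years,
#' and the incidence-to-stunting pathway is parameterized with a neutral
#' odds multiplier of 1, so fixtures always validate and run without
#' unparameterized-pathway errors. The same seed always yields a
#' byte-identical fixture; the generator saves and restores the caller's RNG
#' state rather than touching global state.
#'
#' @param seed integer seed.
#' @param n_interventions number of interventions (>= 0).
#' @param years number of projection years.
#' @param start_year first calendar year (default 2025).
#' @return A list with elements `pack` (a `parameter_pack`), `scenario` (a
#'   [coverage_scenario()]) and `envelope` (a [mortality_envelope()]).
#' @examples
#' fx <- generate_fixture(42, n_interventions = 3, years = 2)
#' run_scenario(fx$pack, fx$scenario, fx$envelope)
#' @export
generate_fixture <- function(seed, n_interventions = 4, years = 1,
                             start_year = 2025) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  if (n_interventions < 0) stop("'n_interventions' must be >= 0", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  specs <- lapply(seq_len(n_interventions), function(i) {
    has_incidence <- stats::runif(1) < 0.4
    intervention_spec(
      name = sprintf("intervention_%02d", i),
      role = sample(c("prevention", "treatment"), 1),
      efficacy = round(stats::runif(1, 0.05, 0.8), 3),
      affected_fraction = if (stats::runif(1) < 0.3)
        round(stats::runif(1, 0.02, 1), 3) else 1,
      incidence_efficacy = if (has_incidence)
        round(stats::runif(1, 0.1, 0.6), 3) else 0,
      incidence_affected_fraction = if (has_incidence)
        round(stats::runif(1, 0.2, 1), 3) else 1
    )
  })

  yrs <- seq.int(start_year, length.out = years)
  scenario_df <- do.call(rbind, lapply(specs, function(sp) {
    targets <- sort(round(stats::runif(years, 0, 0.9), 3))
    data.frame(intervention = sp$name, year = yrs,
               baseline_coverage = 0, target_coverage = targets)
  })) %||% data.frame(intervention = character(0), year = integer(0),
                      baseline_coverage = numeric(0),
                      target_coverage = numeric(0))

  stunting_prev <- stats::runif(4)
  stunting_prev <- round(stunting_prev / sum(stunting_prev), 6)
  stunting_prev[4] <- 1 - sum(stunting_prev[1:3])
  pack <- parameter_pack(
    interventions = specs,
    etiology_fractions = etiology_fraction_table(
      c(dysentery = 0.039, rotavirus = round(stats::runif(1, 0.2, 0.4), 3)),
      region = "synthetic"),
    risk_factors = list(stunting = risk_factor_distribution(
      "stunting",
      prevalences = stunting_prev,
      mortality_rr = c(1, round(sort(stats::runif(3, 1, 4)), 2)))),
    pathway_params = list(odds_per_episode = 1,
                          episodes_per_child_year = round(stats::runif(1, 2, 5), 2)),
    custom_interventions = list()
  )

  envelope <- mortality_envelope(
    round(stats::runif(years, 5000, 20000)), year = yrs)

  list(pack = pack,
       scenario = coverage_scenario(scenario_df),
       envelope = envelope)
}

#' Write a fixture's three files to a directory
#'
#' @param fixture result of [generate_fixture()].
#' @param out_dir output directory; writes `pack.json`, `scenario.csv`,
#'   `envelope.csv`.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(fixture, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pack = file.path(out_dir, "pack.json"),
             scenario = file.path(out_dir, "scenario.csv"),
             envelope = file.path(out_dir, "envelope.csv"))
  write_parameter_pack(fixture$pack, paths[["pack"]])
  write_coverage_scenario(fixture$scenario, paths[["scenario"]])
  write_mortality_envelope(fixture$envelope, paths[["envelope"]])
  invisible(paths)
}
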