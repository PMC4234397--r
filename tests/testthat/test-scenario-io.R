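test_that("the bundled default pack loads with published effect sizes as fractions", {
  pack <- default_parameter_pack()
  expect_s3_class(pack, "parameter_pack")
  expect_equal(pack$interventions$zinc_treatment$efficacy, 0.23)
  expect_equal(pack$interventions$antibiotics_dysentery$efficacy, 0.99)
  expect_equal(pack$interventions$antibiotics_dysentery$affected_fraction, 0.039)
  expect_equal(pack$interventions$rotavirus_vaccine$incidence_efficacy, 0.5)
  # ORS: observed 69% at 74% coverage, extrapolated linearly to 100%
  expect_equal(pack$interventions$ors$efficacy, 0.69 / 0.74)
  # regional placeholders stay unset until the user supplies them
  expect_true(is.na(pack$etiology_fractions$fractions[["rotavirus"]]))
  expect_null(pack$pathway_params$odds_per_episode)
  # blank dummy-vaccine templates ship with null links
  nms <- vapply(pack$custom_interventions, `[[`, "", "name")
  expect_setequal(nms, c("vaccine_b", "vaccine_c"))
  expect_true(all(vapply(pack$custom_interventions,
                         function(x) is.null(x$links), TRUE)))
})

test_that("packs with out-of-range or ill-declared units are rejected", {
  write_pack <- function(lines) {
    path <- tempfile(fileext = ".json")
    writeLines(lines, path)
    path
  }
  # fraction above 1
  p1 <- write_pack('{"units":"fraction","interventions":[
    {"name":"x","role":"treatment","efficacy":1.5}]}')
  expect_error(load_parameter_pack(p1), "efficacy")
  # percent above 100 is a unit error
  p2 <- write_pack('{"units":"percent","interventions":[
    {"name":"x","role":"treatment","efficacy":150}]}')
  expect_error(load_parameter_pack(p2), "100")
  # unknown keys rejected in strict mode only
  p3 <- write_pack('{"units":"fraction","interventions":[
    {"name":"x","role":"treatment","efficacy":0.5}],"surprise":1}')
  expect_error(load_parameter_pack(p3), "surprise")
  expect_s3_class(load_parameter_pack(p3, strict = FALSE), "parameter_pack")
  # bad unit declaration
  p4 <- write_pack('{"units":"permille","interventions":[]}')
  expect_error(load_parameter_pack(p4), "percent")
})

test_that("a save-load round trip reproduces the pack", {
  pack <- default_parameter_pack()
  path <- withr::local_tempfile(fileext = ".json")
  write_parameter_pack(pack, path)
  again <- load_parameter_pack(path)
  expect_equal(again$interventions, pack$interventions)
  expect_equal(again$breastfeeding$bands, pack$breastfeeding$bands)
  expect_equal(again$etiology_fractions$fractions,
               pack$etiology_fractions$fractions)
  expect_equal(again$risk_factors, pack$risk_factors)
  # and the round trip is idempotent at the byte level
  path2 <- withr::local_tempfile(fileext = ".json")
  write_parameter_pack(again, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("YAML packs load like JSON packs", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("units: fraction",
               "interventions:",
               "  - name: zinc_treatment",
               "    role: treatment",
               "    efficacy: 0.23"), path)
  pack <- load_parameter_pack(path)
  expect_equal(pack$interventions$zinc_treatment$efficacy, 0.23)
})

test_that("scenario CSV round-trips and validates coverage bounds", {
  sc <- coverage_scenario(data.frame(
    intervention = c("ors", "zinc_treatment"), year = 2025,
    baseline_coverage = c(0.3, 0), target_coverage = c(0.74, 0.5)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_coverage_scenario(sc, path)
  back <- read_coverage_scenario(path)
  expect_equal(as.data.frame(back), as.data.frame(sc))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("intervention,year,baseline_coverage,target_coverage",
               "ors,2025,0,1.5"), bad)
  expect_error(read_coverage_scenario(bad), "target_coverage")
})

test_that("fixtures are reproducible and leave the caller's RNG untouched", {
  fx1 <- generate_fixture(42, n_interventions = 4, years = 3)
  fx2 <- generate_fixture(42, n_interventions = 4, years = 3)
  expect_identical(fx1, fx2)
  expect_false(identical(fx1, generate_fixture(43, n_interventions = 4, years = 3)))

  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_fixture(7)); after <- runif(1)
  expect_identical(before, after)

  # written fixtures are byte-identical across regenerations
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(fx1, d1); write_fixture(fx2, d2)
  for (f in c("pack.json", "scenario.csv", "envelope.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("a zero-intervention fixture runs as the identity", {
  fx <- generate_fixture(5, n_interventions = 0, years = 1)
  rep <- run_scenario(fx$pack, fx$scenario, fx$envelope)
  expect_equal(rep$years$residual, fx$envelope$diarrhea_deaths)
  expect_equal(rep$years$total_averted, 0)
})

test_that("random fixtures never violate pack or report invariants", {
  for (seed in 1:40) {
    fx <- generate_fixture(seed,
                           n_interventions = (seed %% 5) + 1,
                           years = (seed %% 3) + 1)
    expect_true(validate_parameter_pack(fx$pack, fx$scenario))
    rep <- run_scenario(fx$pack, fx$scenario, fx$envelope)
    # totals reconcile each year and residuals stay within the envelope
    for (i in seq_len(nrow(rep$years))) {
      yr <- rep$years$year[i]
      expect_gte(rep$years$residual[i], 0)
      expect_lte(rep$years$residual[i], rep$years$baseline[i])
      averted_yr <- sum(rep$steps$averted[rep$steps$year == yr])
      expect_equal(averted_yr + rep$years$residual[i], rep$years$baseline[i],
                   tolerance = 1e-9)
    }
  }
})

test_that("run reports are deterministic apart from the metadata timestamp", {
  fx <- generate_fixture(13, n_interventions = 3, years = 2)
  rep <- run_scenario(fx$pack, fx$scenario, fx$envelope)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_run_report(rep, d1)
  Sys.sleep(1.1)
  write_run_report(rep, d2)
  expect_identical(readLines(file.path(d1, "report.csv")),
                   readLines(file.path(d2, "report.csv")))
  drop_meta <- function(dir) {
    j <- jsonlite::read_json(file.path(dir, "summary.json"))
    j$meta$generated_at <- NULL
    j
  }
  expect_identical(drop_meta(d1), drop_meta(d2))
})

cli_fixture_dir <- function(seed = 7, n = 3, years = 2) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_fixture(generate_fixture(seed, n_interventions = n, years = years), dir)
  dir
}

test_that("the CLI reproduces the worked vaccine example through `run`", {
  dir <- withr::local_tempdir()
  pack <- parameter_pack(list(
    intervention_spec("vaccine_a", "prevention", efficacy = 0.5)))
  write_parameter_pack(pack, file.path(dir, "pack.json"))
  write_coverage_scenario(coverage_scenario(c(vaccine_a = 0.5)),
                          file.path(dir, "scenario.csv"))
  status <- run_cli(c("run", "--params", file.path(dir, "pack.json"),
                      "--scenario", file.path(dir, "scenario.csv"),
                      "--deaths", "10000",
                      "--out", file.path(dir, "out"),
                      "--log-level", "quiet"))
  expect_identical(status, 0L)
  summary <- jsonlite::read_json(file.path(dir, "out", "summary.json"))
  expect_equal(summary$years[[1]]$residual, 7500)
  report <- read.csv(file.path(dir, "out", "report.csv"))
  expect_equal(report$averted, 2500)
})

test_that("`validate` exits nonzero on a corrupted pack", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"units":"fraction","interventions":[{"name":"x","efficacy":2}]}',
             bad)
  expect_message(status <- run_cli(c("validate", "--params", bad)), "error")
  expect_identical(status, 1L)
  ok <- cli_fixture_dir()
  expect_identical(run_cli(c("validate", "--params", file.path(ok, "pack.json"),
                             "--scenario", file.path(ok, "scenario.csv"),
                             "--log-level", "quiet")), 0L)
})

test_that("`attribute` agrees with repeated single-intervention `run`s", {
  dir <- cli_fixture_dir(seed = 19, n = 3, years = 1)
  out <- withr::local_tempdir()
  status <- run_cli(c("attribute", "--params", file.path(dir, "pack.json"),
                      "--scenario", file.path(dir, "scenario.csv"),
                      "--envelope", file.path(dir, "envelope.csv"),
                      "--out", out, "--log-level", "quiet"))
  expect_identical(status, 0L)
  attr_df <- read.csv(file.path(out, "attribution.csv"))

  scenario <- read_coverage_scenario(file.path(dir, "scenario.csv"))
  pack <- load_parameter_pack(file.path(dir, "pack.json"))
  envelope <- read_mortality_envelope(file.path(dir, "envelope.csv"))
  for (nm in unique(scenario$intervention)) {
    solo <- scenario[scenario$intervention == nm, ]
    class(solo) <- class(scenario)
    rep_solo <- run_scenario(pack, solo, envelope)
    expect_equal(attr_df$isolated_averted[attr_df$intervention == nm],
                 rep_solo$years$total_averted, tolerance = 1e-9)
  }
})

test_that("the CLI fixture subcommand writes a reproducible fixture", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  expect_identical(run_cli(c("fixture", "--seed", "3", "--out", out1,
                             "--log-level", "quiet")), 0L)
  expect_identical(run_cli(c("fixture", "--seed", "3", "--out", out2,
                             "--log-level", "quiet")), 0L)
  expect_identical(readLines(file.path(out1, "pack.json")),
                   readLines(file.path(out2, "pack.json")))
  expect_identical(run_cli(c("frobnicate")), 1L)
})
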