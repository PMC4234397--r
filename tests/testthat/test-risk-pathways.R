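two_strata <- function(p_stunted, rr_stunted = 2) {
  risk_factor_distribution("stunting",
                           prevalences = c(1 - p_stunted, p_stunted),
                           mortality_rr = c(1, rr_stunted),
                           strata = c("not_stunted", "stunted"),
                           affected = c(FALSE, TRUE))
}

test_that("the incidence multiplier compounds per-intervention reductions", {
  # a vaccine halving etiology-specific incidence on a 0.4 share of episodes
  rota <- make_spec("rota", 0, inc_e = 0.5, inc_af = 0.4)
  expect_equal(incidence_multiplier(list(rota), c(rota = 1)), 0.8)
  # no incidence-linked interventions
  plain <- make_spec("plain", 0.5)
  expect_equal(incidence_multiplier(list(plain), c(plain = 1)), 1)
  # two independent interventions: product, either order
  wash <- make_spec("wash", 0, inc_e = 0.3, inc_af = 1)
  both_ab <- incidence_multiplier(list(rota, wash), c(rota = 1, wash = 0.5))
  both_ba <- incidence_multiplier(list(wash, rota), c(rota = 1, wash = 0.5))
  expect_equal(both_ab, 0.8 * (1 - 0.3 * 0.5))
  expect_equal(both_ab, both_ba)
})

test_that("multipliers stay in (0, 1] for non-negative efficacies and coverage", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(1:5, 1)
    specs <- lapply(seq_len(n), function(k) {
      make_spec(paste0("s", k), runif(1), inc_e = runif(1), inc_af = runif(1))
    })
    cov <- setNames(runif(n), paste0("s", seq_len(n)))
    m <- incidence_multiplier(specs, cov)
    expect_gt(m, 0)
    expect_lte(m, 1)
  }
})

test_that("the incidence-to-stunting odds shift matches the hand computation", {
  d <- two_strata(0.40)
  # odds 0.4/0.6 scaled by 1.05^-2 = 0.604686...; p = odds/(1+odds)
  odds <- 0.4 / 0.6 * 1.05^-2
  expected_p <- odds / (1 + odds)
  # episode rate 4/child-year halved -> 2 fewer episodes
  shifted <- stunting_shift_from_incidence(d, 0.5, odds_per_episode = 1.05,
                                           episodes_per_child_year = 4)
  expect_equal(shifted$prevalences[["stunted"]], expected_p, tolerance = 1e-12)
  expect_equal(round(shifted$prevalences[["stunted"]], 4), 0.3768)
  expect_equal(sum(shifted$prevalences), 1, tolerance = 1e-12)
})

test_that("neutral incidence or a unit odds parameter leave stunting unchanged", {
  d <- two_strata(0.40)
  expect_equal(stunting_shift_from_incidence(d, 1), d)
  expect_equal(stunting_shift_from_incidence(d, 0.7, odds_per_episode = 1,
                                             episodes_per_child_year = 3), d)
})

test_that("a nonzero incidence change without the odds parameter errors loudly", {
  d <- two_strata(0.40)
  expect_error(stunting_shift_from_incidence(d, 0.8), "unparameterized")
})

test_that("shifted prevalences renormalize to 1 across random inputs", {
  set.seed(71)
  for (i in 1:25) {
    p <- runif(4)
    p <- p / sum(p)
    d <- risk_factor_distribution("stunting", p, c(1, 1.3, 1.9, 3.1))
    shifted <- stunting_shift_from_incidence(d, runif(1, 0.3, 0.99),
                                             odds_per_episode = runif(1, 1.01, 1.2),
                                             episodes_per_child_year = runif(1, 1, 6))
    expect_equal(sum(shifted$prevalences), 1, tolerance = 1e-9)
    expect_true(all(shifted$prevalences >= 0))
    # fewer episodes can only reduce the stunted share
    expect_lte(sum(shifted$prevalences[shifted$affected]),
               sum(d$prevalences[d$affected]) + 1e-12)
  }
})

test_that("the risk-factor mortality multiplier is the weighted-RR ratio", {
  before <- two_strata(0.4, rr_stunted = 4)
  after <- two_strata(0.2, rr_stunted = 4)
  # (0.8 + 0.2*4) / (0.6 + 0.4*4) = 1.6 / 2.2
  expect_equal(mortality_multiplier_from_shift(before, after), 1.6 / 2.2,
               tolerance = 1e-12)
  expect_equal(mortality_multiplier_from_shift(before, before), 1)
  flat_b <- two_strata(0.4, rr_stunted = 1)
  flat_a <- two_strata(0.1, rr_stunted = 1)
  expect_equal(mortality_multiplier_from_shift(flat_b, flat_a), 1)
  other <- risk_factor_distribution("stunting", c(0.5, 0.3, 0.1, 0.1),
                                    c(1, 2, 3, 4))
  expect_error(mortality_multiplier_from_shift(before, other), "strata")
})

test_that("reference stratum must carry relative risk exactly 1", {
  expect_error(risk_factor_distribution("stunting", c(0.6, 0.4), c(1.2, 2),
                                        strata = c("a", "b"),
                                        affected = c(FALSE, TRUE)),
               "exactly 1")
})

test_that("deficiency prevalence substitutes the affected fraction", {
  vita <- make_spec("vitamin_a", 0.2)
  expect_equal(deficiency_affected_fraction(vita, 0.3)$affected_fraction, 0.3)
  inert <- deficiency_affected_fraction(vita, 0)
  expect_equal(deaths_averted_single(10000, inert, 1), 0)
  full <- deficiency_affected_fraction(vita, 1)
  expect_equal(deaths_averted_single(10000, full, 1),
               deaths_averted_single(10000, vita, 1))
  expect_error(deficiency_affected_fraction(vita, 1.2), "deficiency_prevalence")
})

test_that("custom interventions take their affected fraction from the etiology", {
  tab <- etiology_fraction_table(c(cholera = 0.05, dysentery = 0.039),
                                 region = "synthetic")
  chol <- register_custom_intervention("cholera_vaccine", "prevention",
                                       efficacy = 0.6, etiology = "cholera",
                                       etiology_table = tab)
  expect_equal(deaths_averted_single(10000, chol, 1), 300)
  # blank dummy-vaccine template: no links, unusable until defined
  expect_error(register_custom_intervention("vaccine_b"), "no links")
  expect_error(register_custom_intervention("x", efficacy = 0.5,
                                            etiology = "norovirus",
                                            etiology_table = tab), "norovirus")
  # an etiology with no value yet must be supplied first
  tab_na <- etiology_fraction_table(c(rotavirus = NA))
  expect_error(register_custom_intervention("x", efficacy = 0.5,
                                            etiology = "rotavirus",
                                            etiology_table = tab_na),
               "rotavirus")
})

test_that("a custom spec with built-in parameters gives identical cascades", {
  builtin <- make_spec("zinc_like", 0.23, role = "treatment")
  custom <- register_custom_intervention("zinc_like", "treatment",
                                         efficacy = 0.23)
  expect_equal(cascade(10000, list(builtin), c(zinc_like = 1))$residual_deaths,
               cascade(10000, list(custom), c(zinc_like = 1))$residual_deaths)
})

test_that("neutralized indirect pathways reproduce the direct-only cascade", {
  fx <- generate_fixture(99, n_interventions = 4, years = 1)
  # fixture ships odds_per_episode = 1 and flat breastfeeding risks: the
  # pipeline must agree with the plain cascade on the same inputs
  piped <- run_scenario(fx$pack, fx$scenario, fx$envelope)
  direct <- cascade(fx$envelope, unname(fx$pack$interventions), fx$scenario,
                    year = fx$scenario$year[1])
  expect_equal(piped$years$residual[1], direct$residual_deaths,
               tolerance = 1e-12)
  expect_equal(piped$years$total_averted[1], direct$total_averted,
               tolerance = 1e-12)
})

test_that("full-pipeline ordering applies the stunting multiplier between roles", {
  prev <- make_spec("prev", 0.5, role = "prevention", inc_e = 0.5)
  treat <- make_spec("treat", 0.5, role = "treatment")
  pack <- parameter_pack(
    interventions = list(prev, treat),
    risk_factors = list(stunting = two_strata(0.4, rr_stunted = 2)),
    pathway_params = list(odds_per_episode = 1.1, episodes_per_child_year = 3))
  sc <- coverage_scenario(c(prev = 1, treat = 1))
  rep <- run_scenario(pack, sc, 10000)

  # oracle assembled step by step from the component operations
  r1 <- 10000 * (1 - 0.5)                       # prevention direct
  inc <- 1 - 0.5 * 1 * 1                        # incidence halved
  shifted <- stunting_shift_from_incidence(two_strata(0.4), inc,
                                           odds_per_episode = 1.1,
                                           episodes_per_child_year = 3)
  m <- mortality_multiplier_from_shift(two_strata(0.4), shifted)
  r2 <- r1 * m
  r3 <- r2 * (1 - 0.5)                          # treatment on the residual
  expect_equal(rep$years$residual, r3, tolerance = 1e-12)
  expect_equal(rep$steps$intervention,
               c("prev", "stunting_pathway", "treat"))
  expect_equal(sum(rep$steps$averted) + rep$years$residual,
               rep$years$baseline, tolerance = 1e-9)
})
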