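---
title: "A deterministic lives-saved cascade for child diarrhea mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deterministic lives-saved cascade for child diarrhea mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(averted)
```

## The model

`averted` implements a deterministic, linear model of the kind used in
lives-saved tools for child-survival program planning: it converts changes in
the coverage of diarrhea prevention and treatment interventions into diarrhea
deaths averted among children aged 1–59 months. The model is deterministic in
the strict sense — identical inputs always produce bit-identical outputs —
and linear in coverage: an intervention's full effect is realized at 100%
coverage, and at 50% coverage exactly half of the preventable deaths are
prevented.

The central quantity is the **mortality envelope** $D$, the annual number of
diarrhea deaths in the 1–59-month population. A single intervention with
cause-specific efficacy $e$ (the proportional reduction in diarrhea mortality
it achieves at full coverage among the deaths it can act on), affected
fraction $AF$ (the share of diarrhea deaths it is mechanistically able to act
on) and coverage change $\Delta c$ averts

$$A = D \cdot e \cdot AF \cdot \Delta c.$$

A package of interventions is applied as a **residual cascade**: each
intervention acts only on the deaths remaining after the interventions before
it, so joint impact is never double counted. The residual after $k$
interventions is

$$D_k = D \prod_{i=1}^{k} \left(1 - e_i \, AF_i \, \Delta c_i\right),$$

a commutative product — the final residual does not depend on the order of
application, only the per-step attribution labels do. By convention,
prevention interventions act on the envelope first and treatment
interventions act on the residual. Because per-step attribution depends on
cascade position, the contribution of a single intervention is better
assessed by **isolation runs** (`attribute_by_isolation()`,
`attribute_scenario()`): the model is re-run with each intervention alone,
and the isolated effects — whose sum exceeds the joint package total when
affected fractions overlap — are reported next to it.

Three refinements sit on top of the basic cascade:

* **Affected fractions from etiology or deficiency.** Etiology-specific
  interventions act only on their pathogen's share of diarrhea deaths
  (dysentery antibiotics on the Shigella-attributable 3.9%, a cholera or
  rotavirus vaccine on that etiology's fraction); micronutrient
  supplementation acts only on the fraction of children at risk of the
  deficiency (`deficiency_affected_fraction()`). Both substitute the share
  for $AF$ and leave the cascade arithmetic unchanged.
* **Linear effectiveness extrapolation.** Community effectiveness studies
  report a mortality reduction at the coverage their program achieved.
  Assuming the relative reduction is linear in achieved coverage and passes
  through the origin, an effect of 69% observed at 74% coverage extrapolates
  to $0.69 \cdot 1.0 / 0.74 = 93\%$ at full coverage
  (`linear_effectiveness_at_coverage()`, clamped to $[0,1]$). This is how the
  bundled ORS efficacy is derived at load time.
* **Indirect risk-factor pathways**, described next.

## Breastfeeding patterns and promotion

Feeding practice is represented as a prevalence distribution over ordered
categories per age band: exclusive / predominant / partial / none under six
months (0–1 and 1–5 months), collapsing to any (continued) / none at 6–11 and
12–23 months. Exclusive breastfeeding is optimal under six months;
any/continued breastfeeding is optimal thereafter.

Promotion moves the optimal category to a promoted rate — either directly to
a target rate, or via the relative risk of appropriate breastfeeding given
promotion, composed with the promotion coverage change as
$p' = p + (RR - 1)\,p\,\Delta c$ and capped at 1. The remaining sub-optimal
mass is redistributed across the sub-optimal categories **in proportion to
their shares before promotion**, which preserves their ratios:

```{r}
base <- bf_pattern("0-1", c(exclusive = 0.620, predominant = 0.250,
                            partial = 0.103, none = 0.027))
after <- apply_promotion(base, promotion_effect("target_rate", 0.696))
round_half_up(100 * after$prevalences, 1)
```

A pattern shift becomes a mortality effect through per-category relative
risks of diarrhea death (optimal category 1 by convention):
`pattern_mortality_multiplier()` scales deaths by the ratio of
prevalence-weighted mean relative risks after versus before the shift. The
multiplier is scale-invariant in the relative risks, and flat risks make the
pathway inert — which is how the bundled pack ships, because the per-category
effect sizes are estimates users should supply from their own evidence
review. Setting rates directly and promoting to the same target are
equivalent downstream by construction.

## The incidence–stunting pathway

Diarrhea incidence is kept in the model because it drives stunting, and
stunting drives diarrhea mortality. Interventions with an incidence link
(rotavirus vaccine halves rotavirus diarrhea incidence; WASH interventions
reduce all-cause incidence) compound multiplicatively into an incidence
multiplier $\prod_i (1 - e^{inc}_i AF^{inc}_i \Delta c_i)$.

The incidence→stunting step is modelled as a log-odds transform: the odds of
being in the stunted strata are scaled by $\theta^{\Delta E}$, where
$\Delta E$ is the change in episodes per child-year and $\theta$ the odds
multiplier per episode. The published description of this link cites pooled
cohort analyses without a closed functional form, so the transform here was
chosen as the simplest monotone form that renormalizes cleanly, and $\theta$
is a **mandatory user parameter**: running the pathway with a nonzero
incidence change and no `odds_per_episode` raises an explicit
unparameterized-pathway error rather than inventing an effect size. Stunting
strata default to the conventional four height-for-age bands
($z \ge -1$, $-1$ to $-2$, $-2$ to $-3$, $< -3$), with the two bands below
$-2$ counting as stunted; strata are configurable, and wasting is wired
identically but ships unparameterized. Pregnancy interventions that reduce
preterm birth or small-for-gestational-age — upstream risk factors for
stunting — are representable only as user-supplied shifts to the baseline
stunting distribution, not as first-class interventions.

The full pipeline (`run_scenario()`) applies, per projection year:
(1) prevention interventions to direct mortality and incidence, (2) the
stunting shift, (3) the stunting and breastfeeding mortality multipliers to
the residual, (4) the treatment cascade on what remains. Time stepping is
annual with each year's cascade starting from that year's envelope; there are
no within-year dynamics, and stunting shifts apply in the same year (the
evidence base is silent on lag, and introducing one would be a modelling
choice with no anchor). When every indirect pathway is neutral the pipeline
reproduces the direct-only cascade exactly; this equivalence is
regression-tested.

## Parameters, units and numerical choices

* **Units.** Internal computation is always on fractions in $[0,1]$.
  Parameter packs declare `"units": "percent"` or `"fraction"` once per file
  (never per field, to prevent mixed-unit packs); percent values above 100
  are unit errors. Reports render percents to one decimal and deaths rounded
  half-up to integers; rounding happens only at the presentation layer
  because reproduction of published tables depends on display rounding, not
  computation rounding. `round_half_up()` is used because R's banker's
  rounding differs on exact halves.
* **Coverage semantics.** The engine operates on coverage *change*
  (target − baseline); introducing a new intervention means baseline 0.
  Declines are rejected by default (`strict = TRUE`); with `strict = FALSE`
  they yield negative averted deaths, optionally bounded by a residual
  ceiling.
* **Bundled defaults.** The shipped pack carries only headline published
  values: zinc treatment efficacy 23%, dysentery antibiotics 99% on a 3.9%
  dysentery death fraction, rotavirus incidence efficacy 50%, ORS 69% at 74%
  coverage, and the worked breastfeeding patterns for the two under-6-month
  bands. Everything regional — the rotavirus death fraction, deficiency
  prevalences, stunting prevalences and relative risks, $\theta$ — is null or
  inert until supplied, and erroring or staying inert is always preferred to
  a silent default.
* **Custom interventions.** `register_custom_intervention()` requires at
  least one link (direct mortality and/or incidence); the blank
  `vaccine_b`/`vaccine_c` templates in the pack are rejected until defined.
  Linking to an etiology sets the affected fraction from the etiology table.
* **Degenerate inputs.** Promotion on an all-optimal baseline with a
  promoted rate below 1 is a degenerate-distribution error; a promoted rate
  above 1 warns and caps; an all-stunted or no-stunted distribution passes
  through the odds shift unchanged; an empty intervention list is the
  identity, not an error.
* **Tolerances.** Tests compare counts to within one death and rendered
  percents to within 0.05 percentage points; distribution sums are enforced
  to 1e-9.

## The fixture generator

`generate_fixture()` produces random-but-valid inputs for tests and demos:
efficacies and affected fractions in $[0,1]$, monotone non-decreasing
coverage trajectories, baseline envelopes of 5,000–20,000 deaths/year, and a
*neutral* incidence→stunting pathway ($\theta = 1$) so fixtures never hit the
unparameterized-pathway error. The generator emulates the shape of real
scenario inputs — it does not emulate real-world covariance between
intervention coverages (coverages are drawn independently, mirroring the
model's own independence assumption), herd immunity, secondary cross-cause
effects, or measurement error in coverage surveys. Tests passing on fixtures
therefore demonstrate the engine's arithmetic and invariants, not the
realism of any particular country scenario. The generator uses a named seed
and restores the caller's RNG state; the same seed yields byte-identical
fixtures.

Problem sizes throughout the test suite are deliberately small — envelopes of
order $10^4$ deaths, up to six interventions, up to three years, forty-odd
random fixtures — because the model is closed-form linear algebra whose
properties do not change with scale.

## Known limitations

* No demographic projection, cohort accounting, fertility or all-cause
  mortality: one cause, one age window.
* No herd immunity and no secondary cross-cause effects; intervention
  coverages are assumed independent.
* No uncertainty intervals: effect-size uncertainty lives in the source
  reviews, and the model propagates point estimates only.
* Per-step attribution is sequential as literally described for the cascade;
  joint normalization schemes would be a different (and undocumented)
  choice, which is why isolation runs are provided as the supported
  attribution method.
* The incidence→stunting functional form is this package's explicit
  construction (log-odds linear in episodes); alternative forms fit the same
  verbal description.
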