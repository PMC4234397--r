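BF_BANDS <- c("0-1", "1-5", "6-11", "12-23")
BF_CATEGORIES_UNDER6 <- c("exclusive", "predominant", "partial", "none")
BF_CATEGORIES_OVER6 <- c("any", "none")

bf_categories <- function(age_band) {
  if (age_band %in% c("0-1", "1-5")) BF_CATEGORIES_UNDER6 else BF_CATEGORIES_OVER6
}

bf_optimal_category <- function(age_band) {
  # exclusive breastfeeding is optimal under 6 months; any/continued
  # breastfeeding is optimal at 6-23 months
  if (age_band %in% c("0-1", "1-5")) "exclusive" else "any"
}

#' Breastfeeding pattern distribution for one age band
#'
#' Prevalence of the degrees of breastfeeding within an age band. Under six
#' months the categories are exclusive, predominant, partial and none, with
#' exclusive breastfeeding optimal; at 6-11 and 12-23 months the categories
#' collapse to any (continued) versus none, with any/continued optimal.
#'
#' @param age_band one of `"0-1"`, `"1-5"`, `"6-11"`, `"12-23"` (months).
#' @param prevalences named numeric vector of category prevalences (fractions
#'   summing to 1 within 1e-9), named by the band's categories.
#' @return A `bf_pattern` object.
#' @examples
#' bf_pattern("0-1", c(exclusive = 0.620, predominant = 0.250,
#'                     partial = 0.103, none = 0.027))
#' @export
bf_pattern <- function(age_band, prevalences) {
  age_band <- match.arg(age_band, BF_BANDS)
  cats <- bf_categories(age_band)
  if (is.null(names(prevalences)) || !setequal(names(prevalences), cats)) {
    stop(sprintf("age band %s months requires prevalences named exactly: %s",
                 age_band, paste(cats, collapse = ", ")), call. = FALSE)
  }
  p <- check_fraction(prevalences[cats], sprintf("prevalences[%s]", age_band))
  names(p) <- cats
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("prevalences for band %s must sum to 1 (got %.10f)",
                 age_band, sum(p)), call. = FALSE)
  }
  structure(list(age_band = age_band, prevalences = p), class = "bf_pattern")
}

#' @export
print.bf_pattern <- function(x, ...) {
  cat(sprintf("<bf_pattern> %s months\n", x$age_band))
  for (cat_ in names(x$prevalences)) {
    cat(sprintf("  %-12s %5.1f%%\n", cat_, 100 * x$prevalences[[cat_]]))
  }
  invisible(x)
}

#' Breastfeeding promotion effect
#'
#' Promotion (counselling, education) raises the prevalence of the optimal
#' feeding category. The effect can be expressed as the relative risk of
#' appropriate breastfeeding given promotion (`mode = "relative_risk"`,
#' composed with the change in promotion coverage), or by setting the
#' post-promotion appropriate-breastfeeding rate directly
#' (`mode = "target_rate"`, the way users directly change breastfeeding
#' rates).
#'
#' @param mode `"relative_risk"` or `"target_rate"`.
#' @param value positive relative risk, or target appropriate-breastfeeding
#'   fraction in \[0, 1\].
#' @param promotion_coverage change in promotion coverage, fraction in
#'   \[0, 1\] (used in relative-risk mode; default 1).
#' @return A `promotion_effect` object.
#' @examples
#' promotion_effect("target_rate", 0.696)
#' promotion_effect("relative_risk", 1.3, promotion_coverage = 0.5)
#' @export
promotion_effect <- function(mode = c("relative_risk", "target_rate"), value,
                             promotion_coverage = 1) {
  mode <- match.arg(mode)
  if (mode == "relative_risk") {
    check_positive(value, "value (relative risk)")
  } else {
    check_fraction(value, "value (target rate)")
  }
  structure(list(mode = mode, value = as.numeric(value),
                 promotion_coverage = check_fraction(promotion_coverage,
                                                     "promotion_coverage")),
            class = "promotion_effect")
}

#' Apply breastfeeding promotion to a pattern
#'
#' Moves the optimal category (exclusive under 6 months, any/continued at
#' 6-23 months) to its promoted rate and distributes the remaining
#' sub-optimal mass among the sub-optimal categories in proportion to their
#' shares prior to promotion scale-up. In relative-risk mode the promoted
#' rate is `baseline + (RR - 1) * baseline * promotion_coverage`, capped at 1
#' (with a warning); in target-rate mode the optimal category is set to the
#' target directly.
#'
#' @param pattern a [bf_pattern()].
#' @param effect a [promotion_effect()].
#' @return A new `bf_pattern` on the same age band, summing to 1.
#' @examples
#' base <- bf_pattern("0-1", c(exclusive = 0.620, predominant = 0.250,
#'                             partial = 0.103, none = 0.027))
#' apply_promotion(base, promotion_effect("target_rate", 0.696))
#' @export
apply_promotion <- function(pattern, effect) {
  stopifnot(inherits(pattern, "bf_pattern"), inherits(effect, "promotion_effect"))
  opt <- bf_optimal_category(pattern$age_band)
  base_opt <- pattern$prevalences[[opt]]
  promoted <- switch(effect$mode,
    target_rate = effect$value,
    relative_risk = base_opt + (effect$value - 1) * base_opt *
      effect$promotion_coverage
  )
  if (promoted > 1) {
    warning(sprintf("promoted %s rate %.4f exceeds 1; capping at 1",
                    opt, promoted), call. = FALSE)
    promoted <- 1
  }
  if (promoted < 0) {
    stop("promotion effect drives the optimal rate below 0", call. = FALSE)
  }
  sub <- setdiff(names(pattern$prevalences), opt)
  sub_mass <- 1 - base_opt
  new_p <- pattern$prevalences
  new_p[[opt]] <- promoted
  if (sub_mass <= 1e-12) {
    if (promoted < 1 - 1e-12) {
      stop("degenerate distribution: no sub-optimal mass at baseline to ",
           "redistribute while the promoted rate is below 1", call. = FALSE)
    }
    new_p[sub] <- 0
  } else {
    # proportional redistribution preserves the ratios among the
    # sub-optimal categories
    new_p[sub] <- pattern$prevalences[sub] * (1 - promoted) / sub_mass
  }
  bf_pattern(pattern$age_band, new_p)
}

#' Mortality multiplier from a breastfeeding pattern shift
#'
#' Lack of appropriate breastfeeding is modelled as a mortality risk factor:
#' each feeding category carries a relative risk of diarrhea death
#' (conventionally 1 for the optimal category). A shift in the pattern scales
#' diarrhea deaths in that age band by the ratio of prevalence-weighted mean
#' relative risks after versus before the shift.
#'
#' @param before,after [bf_pattern()] objects on the same age band.
#' @param rrs named numeric vector of per-category mortality relative risks.
#' @return The multiplier `sum(after * RR) / sum(before * RR)`; 1 when the
#'   patterns are equal or all relative risks are equal.
#' @examples
#' b <- bf_pattern("6-11", c(any = 0.5, none = 0.5))
#' a <- bf_pattern("6-11", c(any = 1, none = 0))
#' pattern_mortality_multiplier(b, a, c(any = 1, none = 2)) # 2/3
#' @export
pattern_mortality_multiplier <- function(before, after, rrs) {
  stopifnot(inherits(before, "bf_pattern"), inherits(after, "bf_pattern"))
  if (before$age_band != after$age_band) {
    stop(sprintf("age band mismatch: before is %s, after is %s",
                 before$age_band, after$age_band), call. = FALSE)
  }
  cats <- names(before$prevalences)
  missing_rr <- setdiff(cats, names(rrs))
  if (length(missing_rr)) {
    stop("missing mortality relative risk for category: ",
         paste(missing_rr, collapse = ", "), call. = FALSE)
  }
  check_nonneg(rrs[cats], "rrs")
  denom <- sum(before$prevalences[cats] * rrs[cats])
  if (denom == 0) stop("baseline pattern has zero total risk weight", call. = FALSE)
  sum(after$prevalences[cats] * rrs[cats]) / denom
}
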