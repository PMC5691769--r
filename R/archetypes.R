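# Default subgroup archetypes for the synthetic-cohort generator.
#
# Means are the published per-subgroup summary values; sds are reconstructed
# from the printed bootstrap CI95 of each subgroup mean as
# sd = half-width * sqrt(n) / 1.96, with subgroup sizes 143/160/250/323.

#' Construct an archetype specification
#'
#' An archetype is one nutritional/socio-economic subgroup profile the
#' synthetic generator draws from: trait means and sds, categorical
#' probabilities, the subgroup's 5-year incident-anemia probability, and
#' its mixing weight in the population.
#'
#' @param name subgroup label (e.g. `"I"`)
#' @param region_prob_south probability of southern residence
#' @param trait_means,trait_sds named numeric vectors over the same traits;
#'   all sds positive
#' @param incidence_5yr probability of incident anemia over five years among
#'   baseline-non-anemic members
#' @param mixing_weight relative population share (weights are validated to
#'   sum to 1 across the archetype list)
#' @param cat_probs named list of categorical distributions: `female`,
#'   `urban` (scalars), `education`, `income`, `smoking` (probability
#'   vectors over the vocabulary levels), `manual` (scalar)
#' @return an object of class `archetype_spec`
#' @export
archetype_spec <- function(name, region_prob_south, trait_means, trait_sds,
                           incidence_5yr, mixing_weight, cat_probs = list()) {
  probs <- c(region_prob_south, incidence_5yr, mixing_weight,
             unlist(cat_probs, use.names = FALSE))
  if (any(probs < 0 | probs > 1))
    stop_config("archetype '", name, "': probabilities must be in [0, 1]")
  if (!identical(sort(names(trait_means)), sort(names(trait_sds))))
    stop_config("archetype '", name, "': trait_means and trait_sds must name the same traits")
  if (any(trait_sds <= 0))
    stop_config("archetype '", name, "': all trait sds must be positive")
  structure(list(
    name = name, region_prob_south = region_prob_south,
    trait_means = trait_means, trait_sds = trait_sds[names(trait_means)],
    incidence_5yr = incidence_5yr, mixing_weight = mixing_weight,
    cat_probs = cat_probs
  ), class = "archetype_spec")
}

# income-level multinomial whose 1000/3500/5000 encoding has a given mean;
# medium is held at 0.2, valid for target means in [1500, 4700].
income_probs_for_mean <- function(target) {
  p_low <- (4700 - target) / 4000
  stopifnot(p_low >= 0, p_low <= 0.8)
  c(low = p_low, medium = 0.2, high = 0.8 - p_low)
}

education_probs <- function(p_low) {
  c(low = p_low, medium = 0.8 * (1 - p_low), high = 0.2 * (1 - p_low))
}

#' Default subgroup archetypes
#'
#' The four published subgroup profiles — High Fibre (I), Low Vegetable
#' (II), Low Fibre (III), High Rice (IV) — with trait means taken from the
#' per-subgroup summary table and sds reconstructed from its bootstrap CI95
#' half-widths (sd = half-width x sqrt(n) / 1.96; n = 143/160/250/323).
#' Mixing weights are proportional to the subgroup sizes; 5-year incident
#' anemia probabilities are 10/25/10/27%. Income enters as a three-level
#' multinomial calibrated so the 1000/3500/5000 Yuan/person encoding matches
#' the published subgroup mean.
#'
#' @return list of four [archetype_spec()] objects
#' @export
default_archetypes <- function() {
  n <- c(143, 160, 250, 323)
  f <- sqrt(n) / 1.96
  means <- list(
    age             = c(46, 52, 50, 47),
    bmi             = c(23, 24, 24, 24),
    ferritin        = c(73, 106, 110, 107),
    total_calories  = c(2760, 1988, 1954, 2733),
    rice            = c(137, 193, 271, 372),
    wheat           = c(277, 157, 46, 49),
    total_meat      = c(61, 94, 177, 198),
    total_vegetable = c(434, 286, 307, 422),
    legumes         = c(24, 13, 13, 14),
    fibre           = c(27, 11, 7, 11),
    soy_sauce       = c(17, 8, 8, 11),
    iron            = c(35, 21, 20, 28)
  )
  halfwidths <- list(
    age             = c(2, 2, 2, 1),
    bmi             = c(0.5, 0.5, 0.5, 0.5),
    ferritin        = c(10.5, 13.5, 10.5, 9.5),
    total_calories  = c(106.5, 71.5, 53, 63.5),
    rice            = c(20.5, 19, 11, 12.5),
    wheat           = c(31, 20.5, 7.5, 9.5),
    total_meat      = c(12.5, 13, 11.5, 13),
    total_vegetable = c(43.5, 22, 13, 18),
    legumes         = c(5, 3, 2, 2.5),
    fibre           = c(2.5, 0.5, 0.5, 1),
    soy_sauce       = c(4.5, 1.5, 1, 1.5),
    iron            = c(1.5, 1, 0.5, 1)
  )
  south <- c(0.03, 0.34, 0.98, 0.83)
  urban <- c(0.04, 0.24, 0.26, 0.06)
  female <- c(0.59, 0.48, 0.59, 0.51)
  low_edu <- c(0.65, 0.62, 0.42, 0.46)
  income_mean <- c(1542, 2741, 4154, 3984)
  incidence <- c(0.10, 0.25, 0.10, 0.27)
  labels <- c("I", "II", "III", "IV")
  lapply(seq_along(labels), function(k) {
    archetype_spec(
      name = labels[k],
      region_prob_south = south[k],
      trait_means = vapply(means, `[`, 0, k),
      trait_sds = vapply(halfwidths, function(h) h[k] * f[k], 0),
      incidence_5yr = incidence[k],
      mixing_weight = n[k] / sum(n),
      cat_probs = list(
        female = female[k],
        urban = urban[k],
        education = education_probs(low_edu[k]),
        income = income_probs_for_mean(income_mean[k]),
        smoking = c(none = 0.75, light = 0.12, heavy = 0.13),
        manual = 0.5
      )
    )
  })
}

#' Construct a synthetic-cohort generator configuration
#'
#' @param n_participants cohort size (>= 1)
#' @param archetypes list of [archetype_spec()]; defaults to
#'   [default_archetypes()]
#' @param female_fraction fallback probability of being female for
#'   archetypes without a `female` entry in `cat_probs` (population default
#'   0.64)
#' @param age_range inclusive age bounds in years, within \[20, 87\]
#' @param hb_mean_sd_by_sex list with `female` and `male` elements, each
#'   `c(mean, sd)` of hemoglobin in g/L; the defaults put baseline anemia
#'   prevalence near 29%
#' @param ferritin_sdlog log-scale sd of the lognormal ferritin draw; the
#'   log-mean is solved per archetype so the arithmetic mean matches the
#'   archetype's ferritin trait mean
#' @param loss_to_followup list with `fraction` (share lost) and `shifts`,
#'   a named vector of selection-score coefficients in within-cohort sd
#'   units for `age`, `iron`, `hemoglobin` and `male` (the lost subset is
#'   younger, higher-iron, higher-hemoglobin and more male by default)
#' @param trait_correlations list of `list(trait_a, trait_b, rho)` within-
#'   archetype Gaussian-copula correlations; default couples rice with total
#'   calories and fibre with iron
#' @param seed integer RNG seed controlling every draw
#' @return an object of class `generator_config`
#' @export
generator_config <- function(n_participants = 2000,
                             archetypes = default_archetypes(),
                             female_fraction = 0.64,
                             age_range = c(20, 87),
                             hb_mean_sd_by_sex = list(female = c(128, 15),
                                                      male = c(138, 15)),
                             ferritin_sdlog = 0.7,
                             loss_to_followup = list(
                               fraction = 1587 / 2849,
                               shifts = c(age = -0.25, iron = 0.15,
                                          hemoglobin = 0.2, male = 0.5)),
                             trait_correlations = list(
                               list("rice", "total_calories", 0.4),
                               list("fibre", "iron", 0.4)),
                             seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 1)
    stop_config("n_participants must be >= 1")
  if (age_range[1] < 20 || age_range[2] > 87 || age_range[1] > age_range[2])
    stop_config("age_range must lie within [20, 87]")
  if (female_fraction < 0 || female_fraction > 1)
    stop_config("female_fraction must be in [0, 1]")
  w <- vapply(archetypes, function(a) a$mixing_weight, 0)
  if (abs(sum(w) - 1) > 1e-8)
    stop_config("archetype mixing weights must sum to 1 (got ", sum(w), ")")
  fr <- loss_to_followup$fraction
  if (is.null(fr) || fr < 0 || fr > 1)
    stop_config("loss_to_followup$fraction must be in [0, 1]")
  structure(list(
    n_participants = as.integer(n_participants), archetypes = archetypes,
    female_fraction = female_fraction, age_range = age_range,
    hb_mean_sd_by_sex = hb_mean_sd_by_sex, ferritin_sdlog = ferritin_sdlog,
    loss_to_followup = loss_to_followup,
    trait_correlations = trait_correlations, seed = as.integer(seed)
  ), class = "generator_config")
}
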