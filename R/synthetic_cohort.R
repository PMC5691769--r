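# Seeded synthetic-cohort generator: archetype mixture with ground-truth
# labels, baseline anemia from hemoglobin draws, differential loss to
# follow-up, and per-archetype incident anemia.

#' Generate a synthetic cohort
#'
#' Draws a cohort of participants from the archetype mixture in `config`.
#' Archetype traits are zero-truncated normals whose underlying means are
#' calibrated so the realized means equal the configured ones; configured
#' within-archetype trait correlations are imposed through a Gaussian
#' copula. Sex, region, urbanicity, education, income level and smoking are
#' archetype-specific multinomials; hemoglobin is a sex-specific normal and
#' ferritin a mean-matched lognormal. Baseline anemia is derived from the
#' hemoglobin draw via [classify_anemia()]. Deterministic given
#' `config$seed`.
#'
#' @param config a [generator_config()]
#' @return an object of class `synthetic_cohort`: a list with `cohort`
#'   (data.frame per [cohort_schema()]), `true_subgroup` (named archetype
#'   label per participant) and `followed_up` (named logical, `NA` until
#'   [apply_loss_to_followup()] runs)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_participants
  arch <- config$archetypes
  ids <- sprintf("P%06d", seq_len(n))
  weights <- vapply(arch, function(a) a$mixing_weight, 0)
  labels <- vapply(arch, function(a) a$name, "")
  k <- sample.int(length(arch), n, replace = TRUE, prob = weights)

  p_cat <- function(field, fallback) {
    vapply(arch, function(a) a$cat_probs[[field]] %||% fallback, 0)[k]
  }
  female <- runif(n) < p_cat("female", config$female_fraction)
  sex <- ifelse(female, "female", "male")
  region <- ifelse(runif(n) < vapply(arch, function(a) a$region_prob_south, 0)[k],
                   "south", "north")
  urban <- runif(n) < p_cat("urban", 0.2)
  draw_multi <- function(field, levels, fallback) {
    probs <- lapply(arch, function(a) {
      p <- a$cat_probs[[field]] %||% fallback
      p / sum(p)
    })
    vapply(seq_len(n), function(i) {
      levels[sample.int(length(levels), 1, prob = probs[[k[i]]])]
    }, "")
  }
  education <- draw_multi("education", cohort_vocab$education, c(0.5, 0.35, 0.15))
  income_level <- draw_multi("income", cohort_vocab$income_level, c(1, 1, 1) / 3)
  smoking <- draw_multi("smoking", cohort_vocab$smoking, c(0.75, 0.12, 0.13))
  occupation <- ifelse(runif(n) < p_cat("manual", 0.5), "manual", "non_manual")

  # archetype quantitative traits: copula-correlated standard normals, then
  # mean-calibrated zero truncation (age is range-truncated instead)
  traits <- names(arch[[1]]$trait_means)
  mu <- vapply(arch, function(a) a$trait_means[traits], setNames(numeric(length(traits)), traits))
  sg <- vapply(arch, function(a) a$trait_sds[traits], setNames(numeric(length(traits)), traits))
  z <- matrix(rnorm(n * length(traits)), n, length(traits),
              dimnames = list(NULL, traits))
  for (pair in config$trait_correlations) {
    a <- pair[[1]]; b <- pair[[2]]; rho <- pair[[3]]
    if (all(c(a, b) %in% traits))
      z[, b] <- rho * z[, a] + sqrt(1 - rho^2) * z[, b]
  }
  tmat <- matrix(NA_real_, n, length(traits), dimnames = list(NULL, traits))
  for (j in seq_along(traits)) {
    tj <- traits[j]
    if (tj %in% c("age", "ferritin")) next
    mu_cal <- vapply(seq_along(arch), function(g)
      truncnorm_calibrate_mean(mu[tj, g], sg[tj, g]), 0)
    x <- mu_cal[k] + sg[tj, k] * z[, j]
    bad <- which(x < 0)
    while (length(bad)) {  # redraw truncated entries
      x[bad] <- rnorm(length(bad), mu_cal[k[bad]], sg[tj, k[bad]])
      bad <- bad[x[bad] < 0]
    }
    tmat[, j] <- x
  }
  age <- rnorm(n, mu["age", k], sg["age", k])
  out_of_range <- which(age < config$age_range[1] | age > config$age_range[2])
  while (length(out_of_range)) {
    age[out_of_range] <- rnorm(length(out_of_range), mu["age", k[out_of_range]],
                               sg["age", k[out_of_range]])
    out_of_range <- out_of_range[age[out_of_range] < config$age_range[1] |
                                   age[out_of_range] > config$age_range[2]]
  }
  age <- round(age)
  ferritin <- if ("ferritin" %in% traits) {
    sdl <- config$ferritin_sdlog
    rlnorm(n, log(mu["ferritin", k]) - sdl^2 / 2, sdl)
  } else rlnorm(n, log(95) - 0.245, 0.7)

  hbp <- config$hb_mean_sd_by_sex
  hemoglobin <- ifelse(female,
                       rnorm(n, hbp$female[1], hbp$female[2]),
                       rnorm(n, hbp$male[1], hbp$male[2]))
  hemoglobin <- pmax(hemoglobin, 40)

  height <- rnorm(n, ifelse(female, 158, 168), 6)
  bmi <- if ("bmi" %in% traits) tmat[, "bmi"] else rtruncnorm0(n, 24, 3.5)
  weight <- bmi * (height / 100)^2
  waist <- 2.5 * bmi + ifelse(female, 20, 26) + rnorm(n, 0, 5)
  sbp <- rtruncnorm0(n, 125, 15)
  dbp <- rtruncnorm0(n, 78, 10)
  glucose <- rlnorm(n, log(5.2), 0.15)
  triglycerides <- rlnorm(n, log(99) - 0.21, 0.65)
  hdl <- rtruncnorm0(n, 51, 12)
  total_cholesterol <- rtruncnorm0(n, 149, 37)
  on_antihypertensives <- runif(n) < 0.08

  # nutrient columns beyond the archetype profile: independent noise with
  # population-plausible scales (present so the network stage has enough nodes)
  noise_spec <- list(
    organ_meat = c(5, 1.5), other_meat = c(7, 1.5), fruit = c(80, 0.9),
    alcohol = c(30, 1.2)
  )
  lnoise <- lapply(noise_spec, function(p) rlnorm(n, log(p[1]) - p[2]^2 / 2, p[2]))
  tnoise_spec <- list(
    fat = c(70, 25), carbohydrate = c(330, 90), protein = c(70, 20),
    copper = c(2, 0.8), magnesium = c(350, 100), manganese = c(6, 2),
    phosphorus = c(1000, 250), potassium = c(1800, 500), selenium = c(45, 15),
    zinc = c(11, 3), vitamin_a = c(500, 300), vitamin_b1 = c(1, 0.3),
    vitamin_b2 = c(0.9, 0.3), vitamin_c = c(80, 40), niacin = c(14, 5),
    retinol = c(300, 200)
  )
  tnoise <- lapply(tnoise_spec, function(p) rtruncnorm0(n, p[1], p[2]))

  cohort <- data.frame(
    id = ids, sex = sex, age = age, region = region, urban = urban,
    height = height, weight = weight, waist = waist, sbp = sbp, dbp = dbp,
    glucose = glucose, triglycerides = triglycerides, hdl = hdl,
    total_cholesterol = total_cholesterol, hemoglobin = hemoglobin,
    ferritin = ferritin, education = education, occupation = occupation,
    smoking = smoking, income_level = income_level,
    on_antihypertensives = on_antihypertensives,
    stringsAsFactors = FALSE
  )
  for (tj in setdiff(traits, c("age", "bmi", "ferritin"))) cohort[[tj]] <- tmat[, tj]
  for (nm in names(lnoise)) cohort[[nm]] <- lnoise[[nm]]
  for (nm in names(tnoise)) cohort[[nm]] <- tnoise[[nm]]
  missing_intakes <- setdiff(intake_columns, names(cohort))
  for (nm in missing_intakes) cohort[[nm]] <- rtruncnorm0(n, 10, 5)
  cohort$anemia_baseline <- classify_anemia(cohort$hemoglobin, cohort$sex)
  cohort$anemia_followup <- NA
  cohort$followed_up <- NA
  cohort <- cohort[, cohort_schema()$column]

  structure(list(
    cohort = cohort,
    true_subgroup = setNames(labels[k], ids),
    followed_up = setNames(rep(NA, n), ids)
  ), class = "synthetic_cohort")
}

#' Apply differential loss to follow-up
#'
#' Marks a configured fraction of the cohort as lost to follow-up. Selection
#' is by a latent score combining standard-normal noise with the configured
#' covariate shifts, so the lost subset is (by default) younger, has higher
#' baseline iron intake and hemoglobin, and is more male than the retained
#' subset, while BMI, ferritin and total calories are not differentially
#' selected. Zero shifts give completely random loss.
#'
#' @param sc a `synthetic_cohort` from [generate_cohort()]
#' @param config the [generator_config()] used to create it
#' @return the `synthetic_cohort` with `followed_up` filled in (also mirrored
#'   into the `followed_up` cohort column)
#' @export
apply_loss_to_followup <- function(sc, config) {
  stopifnot(inherits(sc, "synthetic_cohort"))
  fr <- config$loss_to_followup$fraction
  if (fr < 0 || fr > 1) stop_config("loss fraction must be in [0, 1]")
  co <- sc$cohort
  n <- nrow(co)
  shifts <- config$loss_to_followup$shifts %||% numeric(0)
  # z-scores within archetype so selection shifts the targeted covariates
  # without distorting the archetype mixture (which would leak into
  # archetype-linked traits like total calories)
  lab <- sc$true_subgroup[co$id]
  zs <- function(x) {
    mu <- ave(x, lab, FUN = mean)
    sg <- ave(x, lab, FUN = sd)
    ifelse(sg > 0, (x - mu) / sg, 0)
  }
  add <- function(w, v) if (length(w) == 1 && !is.na(w)) w * v else 0
  score <- withr::with_seed(config$seed + 101L, rnorm(n)) +
    add(shifts["age"], zs(co$age)) +
    add(shifts["iron"], zs(co$iron)) +
    add(shifts["hemoglobin"], zs(co$hemoglobin)) +
    add(shifts["male"], as.numeric(co$sex == "male") -
          ave(as.numeric(co$sex == "male"), lab, FUN = mean))
  n_lost <- round(fr * n)
  lost <- rank(-score, ties.method = "first") <= n_lost
  sc$followed_up <- setNames(!lost, co$id)
  sc$cohort$followed_up <- !lost
  sc
}

#' Simulate incident anemia at the five-year follow-up
#'
#' Among participants without anemia at baseline (and, when loss to
#' follow-up has been applied, only those followed up), draws incident
#' anemia as an independent Bernoulli with the participant's archetype
#' `incidence_5yr` probability. Everyone else gets `NA`.
#'
#' @inheritParams apply_loss_to_followup
#' @return the `synthetic_cohort` with the `anemia_followup` column filled
#' @export
simulate_incident_anemia <- function(sc, config) {
  stopifnot(inherits(sc, "synthetic_cohort"))
  co <- sc$cohort
  inc <- vapply(config$archetypes, function(a) a$incidence_5yr, 0)
  names(inc) <- vapply(config$archetypes, function(a) a$name, "")
  p <- inc[sc$true_subgroup[co$id]]
  at_risk <- !co$anemia_baseline &
    (is.na(co$followed_up) | co$followed_up)
  draw <- withr::with_seed(config$seed + 202L, runif(nrow(co)))
  co$anemia_followup <- ifelse(at_risk, draw < p, NA)
  sc$cohort <- co
  sc
}
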