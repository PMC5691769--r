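# Univariate association machinery: age residualization, Fisher p-value
# combination, Benjamini-Hochberg FDR, sex-stratified trait comparison with
# number-weighted descriptives, and adjusted logistic models.

#' Remove age covariation from a quantitative variable
#'
#' Residualizes `values` on `age` by simple linear regression and adds the
#' overall mean back, so the result is uncorrelated with age but keeps the
#' original location. Constant age gives the identity with a warning.
#'
#' @param values numeric vector (length >= 3)
#' @param age ages in years
#' @return residualized vector, same length and mean
#' @export
residualize_age <- function(values, age) {
  stopifnot(length(values) == length(age), length(values) >= 3)
  if (sd(age) == 0) {
    warning("age is constant; returning values unchanged")
    return(values)
  }
  ac <- age - mean(age)
  slope <- sum(ac * (values - mean(values))) / sum(ac^2)
  values - slope * ac
}

#' Combine p-values with Fisher's method
#'
#' `X = -2 * sum(log(p))` follows a chi-squared distribution with `2k`
#' degrees of freedom under the global null; the combined p-value is its
#' upper-tail probability. Symmetric and monotone in every argument; a
#' single p-value is returned unchanged. Zeros are clipped to the smallest
#' positive double with a warning.
#'
#' @param pvals numeric vector of p-values in (0, 1]
#' @return combined p-value
#' @export
fisher_combine <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0) return(NA_real_)
  if (any(pvals < 0 | pvals > 1)) stop_validation("p-values must be in [0, 1]")
  if (any(pvals == 0)) {
    warning("p-value of 0 clipped to smallest positive double")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  pchisq(-2 * sum(log(pvals)), df = 2 * length(pvals), lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min_{j >= i}
#' p_(j) * n / j`, capped at 1. Monotone in the p-value ranks, and every
#' `q >= p`.
#'
#' @param pvals numeric vector of p-values
#' @return q-values in the original order
#' @export
bh_fdr <- function(pvals) {
  stopifnot(length(pvals) >= 1)
  n <- length(pvals)
  ord <- order(pvals)
  q <- pvals[ord] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(ord)]
}

#' Sex-stratified trait comparison with Fisher combination
#'
#' Compares a trait between outcome groups separately within women and men,
#' then combines. Quantitative traits are age-residualized (unless
#' `age_adjust = FALSE`) and tested by a Welch two-sample t-test (or
#' Mann-Whitney with `test = "wilcox"`); binary traits are tested by the
#' trait coefficient of a per-sex logistic model `outcome ~ trait (+ age)`.
#' Per-sex p-values are combined with [fisher_combine()] and descriptive
#' group means are combined as number-weighted means across the sex strata.
#' A stratum with an empty outcome group is skipped.
#'
#' @param cohort cohort data.frame
#' @param trait name of the trait column (numeric or logical)
#' @param outcome name of a logical outcome column (e.g. `anemia_baseline`)
#' @param age_adjust set `FALSE` for variables that must bypass age
#'   adjustment
#' @param test `"welch"` or `"wilcox"` for quantitative traits
#' @return a `trait_comparison` list: per-group number-weighted `mean` and
#'   `sd`, `p_female`, `p_male`, `p_combined`, and stratum sizes
#' @export
compare_trait <- function(cohort, trait, outcome, age_adjust = TRUE,
                          test = c("welch", "wilcox")) {
  test <- match.arg(test)
  use <- !is.na(cohort[[trait]]) & !is.na(cohort[[outcome]]) & !is.na(cohort$sex)
  df <- cohort[use, , drop = FALSE]
  x <- df[[trait]]
  if (is.logical(x)) x <- as.numeric(x)
  y <- df[[outcome]]
  binary <- all(x %in% c(0, 1))
  p_sex <- c(female = NA_real_, male = NA_real_)
  desc <- list()
  for (s in cohort_vocab$sex) {
    rows <- df$sex == s
    if (sum(rows & y) == 0 || sum(rows & !y) == 0) next
    xs <- x[rows]; ys <- y[rows]; ages <- df$age[rows]
    desc[[s]] <- data.frame(
      group = c("control", "case"),
      n = c(sum(!ys), sum(ys)),
      mean = c(mean(xs[!ys]), mean(xs[ys])),
      sd = c(sd(xs[!ys]), sd(xs[ys])))
    if (binary) {
      fml <- if (age_adjust) ys ~ xs + ages else ys ~ xs
      fit <- suppressWarnings(glm(fml, family = binomial()))
      p_sex[s] <- summary(fit)$coefficients["xs", 4]
    } else {
      xr <- if (age_adjust) residualize_age(xs, ages) else xs
      p_sex[s] <- if (test == "welch") welch_p(xr[ys], xr[!ys]) else
        suppressWarnings(stats::wilcox.test(xr[ys], xr[!ys])$p.value)
    }
  }
  if (length(desc) == 0) stop_validation("no stratum with both outcome groups")
  weighted <- do.call(rbind, desc)
  agg <- lapply(c("control", "case"), function(g) {
    rows <- weighted[weighted$group == g, , drop = FALSE]
    c(n = sum(rows$n),
      mean = sum(rows$n * rows$mean) / sum(rows$n),
      sd = sum(rows$n * rows$sd) / sum(rows$n))
  })
  names(agg) <- c("control", "case")
  structure(list(
    trait = trait, group_means = agg,
    p_female = unname(p_sex["female"]), p_male = unname(p_sex["male"]),
    p_combined = fisher_combine(p_sex[!is.na(p_sex)]),
    age_adjusted = age_adjust, binary = binary
  ), class = "trait_comparison")
}

#' Univariate association table over many traits
#'
#' Runs [compare_trait()] for every trait and attaches Benjamini-Hochberg
#' q-values over the whole family (one analysis = one FDR family).
#'
#' @inheritParams compare_trait
#' @param traits character vector of trait columns
#' @param no_age_adjust traits that bypass age adjustment
#' @return data.frame with group means/sds, per-sex p, combined p and q
#' @export
univariate_table <- function(cohort, traits, outcome, no_age_adjust = character(0)) {
  rows <- lapply(traits, function(tr) {
    cmp <- compare_trait(cohort, tr, outcome,
                         age_adjust = !(tr %in% no_age_adjust))
    data.frame(trait = tr,
               control_n = cmp$group_means$control[["n"]],
               control_mean = cmp$group_means$control[["mean"]],
               control_sd = cmp$group_means$control[["sd"]],
               case_n = cmp$group_means$case[["n"]],
               case_mean = cmp$group_means$case[["mean"]],
               case_sd = cmp$group_means$case[["sd"]],
               p_female = cmp$p_female, p_male = cmp$p_male,
               p_combined = cmp$p_combined,
               age_adjusted = cmp$age_adjusted,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_combined)
  out
}

#' Multivariable adjusted logistic regression
#'
#' Maximum-likelihood logistic fit of a binary outcome on a set of
#' predictors, reporting odds ratios with Wald 95% CIs. Complete or
#' quasi-complete separation is detected (fitted probabilities numerically
#' at 0/1 or exploding standard errors) and reported in the `separation`
#' field rather than silently returning unstable estimates.
#'
#' @param cohort cohort data.frame
#' @param outcome name of a logical outcome column
#' @param predictors character vector of predictor columns (logical,
#'   numeric, or categorical)
#' @return list with `coefficients` (term, estimate, se, or, ci_low,
#'   ci_high, p), `converged`, and `separation` flags
#' @export
fit_adjusted_logistic <- function(cohort, outcome, predictors) {
  df <- cohort[, c(outcome, predictors), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- suppressWarnings(glm(fml, family = binomial(), data = df))
  mu <- fit$fitted.values
  sm <- summary(fit)$coefficients
  separated <- any(mu < 1e-8 | mu > 1 - 1e-8) || any(sm[, 2] > 100)
  if (separated)
    warning("possible separation: estimates for some terms are unreliable")
  # aliased terms (e.g. constant predictors) carry no information: report
  # them as a null effect rather than dropping the row
  full <- names(coef(fit))
  est <- setNames(rep(0, length(full)), full)
  se <- p <- setNames(rep(NA_real_, length(full)), full)
  est[rownames(sm)] <- sm[, 1]
  se[rownames(sm)] <- sm[, 2]
  p[rownames(sm)] <- sm[, 4]
  list(
    coefficients = data.frame(
      term = full, estimate = est, se = se,
      or = exp(est),
      ci_low = exp(est - qnorm(0.975) * se),
      ci_high = exp(est + qnorm(0.975) * se),
      p = p, row.names = NULL, stringsAsFactors = FALSE),
    converged = fit$converged,
    separation = separated
  )
}
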