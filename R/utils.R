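# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("anemiasom_config_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("anemiasom_validation_error", "error")))
}

#' Solve the underlying mean of a zero-truncated normal
#'
#' Finds `mu` such that a normal with mean `mu` and sd `sigma`, truncated at
#' zero from below, has expectation `target`. Used so that generated intake
#' variables reproduce their configured means exactly despite truncation.
#'
#' @param target desired mean of the truncated variable (> 0)
#' @param sigma sd of the underlying normal (> 0)
#' @return the underlying mean `mu`
#' @keywords internal
#' @noRd
truncnorm_calibrate_mean <- function(target, sigma) {
  stopifnot(target > 0, sigma > 0)
  if (target / sigma > 6) return(target)  # truncation numerically irrelevant
  trunc_mean <- function(mu) {
    a <- -mu / sigma
    mu + sigma * dnorm(a) / (1 - pnorm(a)) - target
  }
  uniroot(trunc_mean, c(target - 8 * sigma, target + sigma), tol = 1e-10)$root
}

# Analytic mean/sd of N(mu, sigma) truncated below at 0.
truncnorm_moments <- function(mu, sigma) {
  a <- -mu / sigma
  lambda <- dnorm(a) / (1 - pnorm(a))
  m <- mu + sigma * lambda
  v <- sigma^2 * (1 + a * lambda - lambda^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Draw from N(mu, sigma) truncated below at 0 by rejection (vectors recycled).
rtruncnorm0 <- function(n, mu, sigma) {
  x <- rnorm(n, mu, sigma)
  bad <- which(x < 0)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mu[pmin(bad, length(mu))], sigma[pmin(bad, length(sigma))])
    bad <- bad[x[bad] < 0]
  }
  x
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to label permutation), ~0 for independent
#' ones. Used to score recovery of ground-truth archetypes by the subtyping
#' pipeline.
#'
#' @param a,b vectors of cluster labels of equal length
#' @return the adjusted Rand index (a scalar, at most 1)
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  expected <- s(rowSums(tab)) * s(colSums(tab)) / choose(length(a), 2)
  maxi <- (s(rowSums(tab)) + s(colSums(tab))) / 2
  if (maxi == expected) return(0)
  (s(tab) - expected) / (maxi - expected)
}

# Welch two-sample t-test p-value that tolerates zero-variance degeneracy:
# identical constant groups compare equal (p = 1), different constants p = 0.
welch_p <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  t.test(x, y)$p.value
}
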