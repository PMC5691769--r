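# Age-matched case-control selection and PC-score matching of the
# subtype-model training set.

new_match_result <- function(case_ids, control_ids, stratum, balance_tests,
                             method, extra = list()) {
  structure(c(list(case_ids = case_ids, control_ids = control_ids,
                   stratum = stratum, balance_tests = balance_tests,
                   method = method), extra),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("match_result (", x$method, ", stratum: ", x$stratum, ")\n", sep = "")
  cat("  cases: ", length(x$case_ids), "  controls/selected: ",
      length(x$control_ids), "\n", sep = "")
  cat("  balance p-values:",
      paste(names(x$balance_tests),
            signif(unlist(x$balance_tests), 3), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Age-matched control selection, stratified by sex
#'
#' Within each sex stratum, starts from all eligible controls and greedily
#' removes the control whose age is farthest from the case mean age (ties
#' broken by participant id) until the two-sample balance test on age gives
#' p > 0.05, so as many controls as possible are retained. Cases and
#' controls never share ids and strata never mix sexes.
#'
#' @param cases,eligible character vectors of participant ids
#' @param cohort cohort data.frame with `id`, `sex`, `age`
#' @param test `"welch"` (default, Welch two-sample t-test on age) or
#'   `"ks"` (Kolmogorov-Smirnov)
#' @param alpha balance threshold; selection stops once p > `alpha`
#' @return named list with one `match_result` per sex stratum present
#' @export
match_age_controls <- function(cases, eligible, cohort, test = c("welch", "ks"),
                               alpha = 0.05) {
  test <- match.arg(test)
  eligible <- setdiff(eligible, cases)
  rows <- function(ids) cohort[match(ids, cohort$id), , drop = FALSE]
  out <- list()
  for (s in intersect(cohort_vocab$sex, unique(rows(c(cases, eligible))$sex))) {
    ca <- rows(cases); ca <- ca$id[ca$sex == s & !is.na(ca$sex)]
    el <- rows(eligible); el <- el$id[el$sex == s & !is.na(el$sex)]
    if (length(ca) == 0 || length(el) == 0) next
    case_age <- cohort$age[match(ca, cohort$id)]
    sel <- el[order(el)]
    p <- balance_p(case_age, cohort$age[match(sel, cohort$id)], test)
    while (length(sel) > 0 && !is.na(p) && p <= alpha) {
      ages <- cohort$age[match(sel, cohort$id)]
      dist <- abs(ages - mean(case_age))
      drop_i <- order(-dist, sel)[1]
      sel <- sel[-drop_i]
      p <- if (length(sel) >= 2)
        balance_p(case_age, cohort$age[match(sel, cohort$id)], test)
      else NA_real_
    }
    if (length(sel) == 0 || is.na(p)) {
      warning("no balanced control subset found for stratum '", s, "'")
      sel <- character(0); p <- NA_real_
    }
    out[[s]] <- new_match_result(ca, sel, s, list(age = p),
                                 method = paste0("age-greedy-", test))
  }
  if (length(out) == 0) stop_validation("no stratum had both cases and eligible controls")
  out
}

balance_p <- function(x, y, test) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (test == "welch") welch_p(x, y)
  else suppressWarnings(stats::ks.test(x, y)$p.value)
}

#' Match a training set to a reference set on module PC scores
#'
#' Greedy nearest-neighbour pairing in standardized module principal-
#' component score space: repeatedly links the globally closest unused
#' (reference, candidate) pair (Euclidean distance; ties broken by ids).
#' After pairing, balance of the selected candidates against the reference
#' set is tested on `balance_vars` (Welch t-test for quantitative variables,
#' chi-squared for `sex`); if any p <= 0.05, the farthest pairs are dropped
#' until balance is reached or the selection would fall below half the
#' reference size, which is an error naming the offending variables.
#'
#' @param candidates,reference character id vectors (disjoint)
#' @param scores numeric matrix of concatenated per-module PC1/PC2 scores
#'   with rownames = participant ids (see [module_scores()])
#' @param balance_vars cohort variables to balance; `"sex"` is tested by
#'   chi-squared, the rest by Welch t-test
#' @param cohort cohort data.frame
#' @param alpha balance threshold
#' @param on_failure what to do when balance is unattainable before the
#'   selection falls below half the reference size: `"error"` (default)
#'   raises a condition of class `anemiasom_balance_failure` naming the
#'   offending variables; `"best"` returns the full pairing with
#'   `balanced = FALSE` and the failed tests attached (used by
#'   [subtype_pipeline()], where unmatched noise dimensions of synthetic
#'   cohorts can make balance impossible by construction)
#' @return a `match_result` with `case_ids` = reference, `control_ids` =
#'   selected candidates, pairing `pairs` (data.frame reference, candidate,
#'   distance), per-variable `balance_tests` and a `balanced` flag
#' @export
match_training_set <- function(candidates, reference, scores, balance_vars,
                               cohort, alpha = 0.05,
                               on_failure = c("error", "best")) {
  on_failure <- match.arg(on_failure)
  stopifnot(length(intersect(candidates, reference)) == 0)
  missing <- setdiff(c(candidates, reference), rownames(scores))
  if (length(missing))
    stop_validation("no PC scores for id(s): ", paste(head(missing, 3), collapse = ", "))
  z <- scale(scores[c(reference, candidates), , drop = FALSE])
  z[, attr(z, "scaled:scale") == 0] <- 0
  ref <- sort(reference); cand <- sort(candidates)
  dm <- as.matrix(stats::dist(z))[ref, cand, drop = FALSE]
  n_pairs <- min(length(ref), length(cand))
  pr <- pc <- character(n_pairs); pd <- numeric(n_pairs)
  for (step in seq_len(n_pairs)) {
    i <- which.min(dm)  # ties: first in column-major (candidate, reference) id order
    ri <- (i - 1L) %% nrow(dm) + 1L
    ci <- (i - 1L) %/% nrow(dm) + 1L
    pr[step] <- rownames(dm)[ri]; pc[step] <- colnames(dm)[ci]
    pd[step] <- dm[ri, ci]
    dm[ri, ] <- Inf; dm[, ci] <- Inf
  }
  pairs <- data.frame(reference = pr, candidate = pc, distance = pd,
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(-pairs$distance), ]
  all_pairs <- pairs
  floor_n <- ceiling(0.5 * length(reference))
  balanced <- TRUE
  repeat {
    bt <- training_balance(pairs$candidate, reference, balance_vars, cohort)
    failing <- names(bt)[!is.na(unlist(bt)) & unlist(bt) <= alpha]
    if (length(failing) == 0) break
    if (nrow(pairs) - 1 < floor_n) {
      if (on_failure == "error") {
        stop(errorCondition(
          paste0("training-set balance unattainable above the 50% floor; ",
                 "offending variable(s): ", paste(failing, collapse = ", ")),
          class = c("anemiasom_balance_failure", "error"),
          variables = failing, balance = bt))
      }
      warning("training-set balance unattainable (", paste(failing, collapse = ", "),
              "); returning the full pairing unbalanced")
      pairs <- all_pairs
      bt <- training_balance(pairs$candidate, reference, balance_vars, cohort)
      balanced <- FALSE
      break
    }
    pairs <- pairs[-1, , drop = FALSE]  # drop current worst (farthest) pair
  }
  new_match_result(reference, pairs$candidate, "pooled", bt,
                   method = "pc-greedy-nn",
                   extra = list(pairs = pairs, balanced = balanced))
}

training_balance <- function(selected, reference, balance_vars, cohort) {
  sel <- cohort[match(selected, cohort$id), , drop = FALSE]
  ref <- cohort[match(reference, cohort$id), , drop = FALSE]
  out <- list()
  for (v in balance_vars) {
    if (v == "sex") {
      tab <- rbind(table(factor(sel$sex, cohort_vocab$sex)),
                   table(factor(ref$sex, cohort_vocab$sex)))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      out[[v]] <- if (ncol(tab) < 2) 1 else
        suppressWarnings(chisq.test(tab)$p.value)
    } else {
      out[[v]] <- welch_p(sel[[v]], ref[[v]])
    }
  }
  out
}
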