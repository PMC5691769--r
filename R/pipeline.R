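# End-to-end subtyping pipeline: derived variables, correlation-network
# module scores, training-set matching, SOM subtyping, and subgroup
# summaries, as one orchestrated call.

#' Default SOM training variables
#'
#' The nutritional and socio-economic profile used for map training: staple
#' foods, fibre, soy sauce, iron, total calories, encoded income and urban
#' residency. Region is deliberately excluded from training (it is an
#' outcome-like descriptor used for coloring).
#'
#' @return character vector of cohort column names
#' @export
som_training_variables <- function() {
  c("rice", "wheat", "total_meat", "total_vegetable", "legumes", "fibre",
    "soy_sauce", "iron", "total_calories", "income_numeric", "urban")
}

# quantitative variables entering the correlation network
network_variables <- function() {
  c("age", "height", "weight", "waist", "sbp", "dbp", "glucose",
    "triglycerides", "hdl", "total_cholesterol", "hemoglobin", "ferritin",
    "income_numeric", intake_columns)
}

#' Run the full subtyping pipeline
#'
#' Orchestrates the analysis on a cohort with baseline and follow-up anemia
#' flags: (1) derives income encoding and height-calibrated intakes;
#' (2) builds the sex-weighted Spearman network over all quantitative
#' baseline variables, prunes it to its maximum spanning forest and detects
#' modules; (3) computes per-module PC scores and matches a training set of
#' lost-to-follow-up, baseline-non-anemic individuals to the evaluation set
#' (followed-up, baseline-non-anemic) on the concatenated first two PCs per
#' module, balancing age, sex, hemoglobin, ferritin, total calories and
#' iron; (4) sex-rank-normalizes the training profiles, trains the batch
#' SOM, assigns evaluation participants to their best-matching units and
#' cuts the map into `K` contiguous subgroups; (5) summarizes subgroup
#' traits with a percentile bootstrap.
#'
#' @param cohort cohort data.frame with `anemia_baseline`, `followed_up`
#'   and (for summaries) `anemia_followup`
#' @param K number of subgroups
#' @param grid,epochs,radius SOM geometry, see [train_som()]
#' @param n_boot bootstrap replicates for the subgroup summary
#' @param seed master seed for matching-independent stages
#' @param calibrate_intakes residualize intakes on height per sex first
#' @return list with `network`, `pruned`, `modules`, `training_match`,
#'   `model`, `subgroups`, `eval_ids`, `membership` (named by id),
#'   `summary`, and `incidence` (per-subgroup incident-anemia proportions)
#' @export
subtype_pipeline <- function(cohort, K = 4, grid = c(8, 6), epochs = 20,
                             radius = c(4, 1), n_boot = 10000, seed = 1L,
                             calibrate_intakes = TRUE) {
  validate_cohort(cohort)
  cohort$income_numeric <- encode_income(cohort$income_level)
  if (calibrate_intakes) {
    cohort[, intake_columns] <- calibrate_by_height(
      cohort[, intake_columns], cohort$height, cohort$sex)
  }
  eval_ids <- cohort$id[cohort$followed_up %in% TRUE & !cohort$anemia_baseline]
  cand_ids <- cohort$id[cohort$followed_up %in% FALSE & !cohort$anemia_baseline]
  if (length(eval_ids) < 10 || length(cand_ids) < 10)
    stop_validation("need at least 10 evaluation and 10 training candidates")

  netvars <- intersect(network_variables(), names(cohort))
  mat <- as.matrix(cohort[, netvars])
  rownames(mat) <- cohort$id
  network <- sex_weighted_spearman(mat, cohort$sex)
  pruned <- prune_spanning_tree(network)
  modules <- detect_modules(pruned)
  modules <- module_scores(mat, modules)

  balance_vars <- c("age", "sex", "hemoglobin", "ferritin",
                    "total_calories", "iron")
  training_match <- suppressWarnings(
    match_training_set(cand_ids, eval_ids, modules$scores, balance_vars,
                       cohort, on_failure = "best"))
  train_ids <- training_match$control_ids

  train_rows <- match(train_ids, cohort$id)
  eval_rows <- match(eval_ids, cohort$id)
  vars <- intersect(som_training_variables(), names(cohort))
  train_mat <- as.matrix(cohort[train_rows, vars])
  rownames(train_mat) <- train_ids
  rt <- rank_transform_by_sex(train_mat, cohort$sex[train_rows])
  model <- train_som(rt$ranked, grid = grid, epochs = epochs,
                     radius = radius, seed = seed)
  eval_mat <- as.matrix(cohort[eval_rows, vars])
  rownames(eval_mat) <- eval_ids
  eval_ranked <- apply_rank_transform(rt, eval_mat, cohort$sex[eval_rows])
  bmu <- assign_bmu(model, eval_ranked)
  subgroups <- define_subgroups(model, K = K, assignments = bmu, seed = seed)
  membership <- setNames(subgroups$membership, eval_ids)

  inc <- tapply(as.numeric(cohort$anemia_followup[eval_rows]), membership, mean,
                na.rm = TRUE)
  sum_traits <- cohort[eval_rows, intersect(
    c("anemia_followup", "age", "hemoglobin", "ferritin", "total_calories",
      som_training_variables()), names(cohort))]
  sum_traits$southern <- cohort$region[eval_rows] == "south"
  summary <- subgroup_summary(membership, sum_traits, n_boot = n_boot,
                              seed = seed)
  list(network = network, pruned = pruned, modules = modules,
       training_match = training_match, model = model, subgroups = subgroups,
       eval_ids = eval_ids, membership = membership, summary = summary,
       incidence = inc, rank_transform = rt)
}
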