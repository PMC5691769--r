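# Small deterministic cohort fixtures built in code.

# schema-complete cohort with simple deterministic values; fields can be
# overridden column-wise through `...`
toy_cohort_df <- function(n = 10, ...) {
  sch <- cohort_schema()
  df <- data.frame(id = sprintf("T%03d", seq_len(n)), stringsAsFactors = FALSE)
  df$sex <- rep(c("female", "male"), length.out = n)
  df$age <- 30 + (seq_len(n) %% 40)
  df$region <- rep(c("north", "south"), length.out = n)
  df$urban <- rep(c(TRUE, FALSE), length.out = n)
  df$height <- 160 + (seq_len(n) %% 20)
  df$weight <- 60 + (seq_len(n) %% 15)
  df$waist <- 80 + (seq_len(n) %% 10)
  df$sbp <- 120; df$dbp <- 78; df$glucose <- 5.2
  df$triglycerides <- 100; df$hdl <- 50; df$total_cholesterol <- 150
  df$hemoglobin <- 135 + (seq_len(n) %% 10)
  df$ferritin <- 90
  df$education <- rep(c("low", "medium", "high"), length.out = n)
  df$occupation <- rep(c("manual", "non_manual"), length.out = n)
  df$smoking <- rep(c("none", "light", "heavy"), length.out = n)
  df$income_level <- rep(c("low", "medium", "high"), length.out = n)
  df$on_antihypertensives <- FALSE
  for (col in sch$column[!(sch$column %in% names(df))]) {
    df[[col]] <- switch(col,
      anemia_baseline = FALSE, anemia_followup = NA, followed_up = TRUE,
      10 + (seq_len(n) %% 7))
  }
  df <- df[, sch$column]
  overrides <- list(...)
  for (nm in names(overrides)) df[[nm]] <- overrides[[nm]]
  df
}

# generated synthetic cohort with follow-up structure, cached per options
small_synthetic <- function(n = 800, seed = 5) {
  cfg <- generator_config(n_participants = n, seed = seed)
  simulate_incident_anemia(apply_loss_to_followup(generate_cohort(cfg), cfg), cfg)
}

# shorthands for package-internal constructors used by fixtures
new_net <- function(nodes, edges, pruned = FALSE) {
  anemiasom:::new_correlation_network(nodes, edges, pruned)
}
new_module_set <- function(assignment) anemiasom:::new_module_set(assignment)
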