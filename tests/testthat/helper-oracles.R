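# Brute-force O(n^2) pairwise concordance: the independent oracle for the
# rank-based horizon AUC.
auc_pairwise_oracle <- function(values, alive) {
  va <- values[alive]
  vd <- values[!alive]
  tot <- 0
  for (a in va) for (d in vd)
    tot <- tot + if (a > d) 1 else if (a == d) 0.5 else 0
  tot / (length(va) * length(vd))
}

# Minimal hand-built cohort with all documented columns.
make_tiny_cohort <- function(n = 3, survival = TRUE, seed = 11) {
  set.seed(seed)
  df <- data.frame(
    patient_id = sprintf("T%02d", seq_len(n)),
    age = round(runif(n, 30, 90), 1),
    sex = sample(c("female", "male"), n, replace = TRUE),
    bmi = round(runif(n, 15, 35), 1),
    charlson = runif(n) < 0.5,
    prior_systemic = runif(n) < 0.5,
    prior_radiation = runif(n) < 0.3,
    visceral_mets = runif(n) < 0.4,
    brain_mets = runif(n) < 0.1,
    lymph_node_mets = runif(n) < 0.3,
    n_bone_mets = sample(c("single", "multiple"), n, replace = TRUE),
    fracture_status = sample(c("impending", "complete"), n,
                             replace = TRUE),
    ecog = sample(0:4, n, replace = TRUE),
    asa = sample(1:4, n, replace = TRUE),
    primary_tumor = sample(c("lung", "breast", "other"), n,
                           replace = TRUE),
    stringsAsFactors = FALSE)
  for (v in pss_labs()) df[[v]] <- round(runif(n, 1, 10), 2)
  if (survival) {
    df$survival_months <- round(runif(n, 0.5, 24), 2)
    df$death_observed <- runif(n) < 0.5
  }
  as_pss_cohort(df, "synthetic")
}

# Default-condition config with the heterogeneity prediction models need.
frailty_config <- function(n, dropout = TRUE, frailty_sd = 1.5) {
  asc <- c(356, 350, 342, 326, 314, 302)
  if (!dropout) asc <- rep(356, 6)
  sim_config(n_patients = n, target_ascertained = asc * n / 356,
             frailty_sd = frailty_sd)
}

# Writeable view of a cohort (booleans as 0/1) for crafting malformed CSVs.
format_cohort_for_test <- function(co) {
  out <- as.data.frame(co)
  for (v in c("charlson", "prior_systemic", "prior_radiation",
              "visceral_mets", "brain_mets", "lymph_node_mets",
              "death_observed"))
    if (v %in% names(out)) out[[v]] <- as.integer(out[[v]])
  out
}
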