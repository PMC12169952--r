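# Shared fixtures built in code.

# Minimal three-food specification used by measurement-error tests:
# one episodic food with no never-consumers plus two daily foods, at
# moderate log-normal variability.
recovery_food_groups <- function() {
  fg <- default_food_groups()
  fg <- fg[fg$name %in% c("vegetables", "other_foods", "fish"), ]
  fg$p_consumer[fg$name == "fish"] <- 1
  fg$p_day_given_consumer[fg$name == "fish"] <- 0.7
  fg$sd_log_between <- 0.45
  fg$sd_log_within <- 0.45
  fg
}

no_bias <- function() {
  list(p_under = 0, p_over = 0, under_factor = 1, over_factor = 1)
}

# Participant-truth contrast data frame: true usual intakes scored and
# priced directly (no recalls, no measurement error).
truth_contrast_df <- function(n, seed, spec = default_eat_i_spec()) {
  cc <- cohort_config(n_participants = n, seed = seed)
  coh <- generate_cohort(cc)
  fg <- cc$food_groups
  U <- as.matrix(coh[paste0("true_", fg$name)])
  colnames(U) <- fg$name
  sc <- score_intake_matrix(U, coh$true_energy, spec, intake_unit = "kg")
  data.frame(participant_id = coh$participant_id,
             cost = as.numeric(U %*% fg$true_price),
             energy = coh$true_energy,
             weight = coh$balancing_weight,
             score = sc$total,
             stringsAsFactors = FALSE)
}

# Daily energy table from raw recall records (no costing needed).
recall_energy_table <- function(recalls) {
  key <- paste(recalls$participant_id, recalls$recall_index)
  en <- tapply(recalls$energy_kcal, key, sum)
  ids <- do.call(rbind, strsplit(names(en), " "))
  data.frame(participant_id = ids[, 1],
             recall_index = as.integer(ids[, 2]),
             cost = 0, energy_kcal = as.numeric(en),
             stringsAsFactors = FALSE)
}
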