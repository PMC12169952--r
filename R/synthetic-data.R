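# Synthetic cohort, recall and sales-price generator with known ground
# truth. The generator emulates the features of a web-based repeated
# 24-h recall study linked to a retail food-price database: three
# recalls per person over three weeks, recall-sequence and weekend
# effects (Friday counted as a weekend day), zero-inflated episodic
# food groups, correlated person-level usual intakes, within-person
# day-to-day noise, person-level energy under/over-reporting, stratified
# sampling requiring balancing weights, and store-level sales volumes.

#' Default synthetic food-group specifications
#'
#' A table of food groups mapped to the components of the EAT-Lancet
#' dietary index, with log-normal usual-intake parameters, episodic
#' consumption probabilities, energy densities and true consumer prices.
#' `loading` is the group's loading on a single latent "healthy, more
#' expensive eater" factor that induces the between-person correlation
#' of usual intakes, and with it a known score-cost relationship:
#' vegetables, fruits, fish, legumes and nuts are expensive and load
#' positively; free sugars and other energy-dense filler foods are cheap
#' and load negatively; poultry and eggs are cheap protein loading
#' positively (so people with low poultry/egg intake - who score high on
#' that in-range component - tend to have cheap diets overall).
#'
#' @return data.frame with one row per food group.
#' @export
default_food_groups <- function() {
  df <- data.frame(
    name = c("whole_grains", "tubers", "vegetables", "fruits", "dairy",
             "red_processed_meat", "poultry", "eggs", "fish", "legumes",
             "nuts", "sat_fats", "unsat_fats", "free_sugars", "other_foods"),
    category = c("grains", "vegetables", "vegetables", "fruits", "dairy",
                 "animal_protein", "animal_protein", "animal_protein",
                 "plant_protein", "plant_protein", "plant_protein",
                 "added_fats", "added_fats", "sweets", "sweets"),
    episodic = c(FALSE, TRUE, FALSE, TRUE, FALSE,
                 TRUE, TRUE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, TRUE, FALSE, FALSE),
    mean_log_usual = log(c(0.050, 0.070, 0.180, 0.150, 0.250,
                           0.080, 0.060, 0.030, 0.035, 0.040,
                           0.020, 0.015, 0.020, 0.055, 0.400)),
    sd_log_between = c(0.40, 0.45, 0.40, 0.45, 0.45,
                       0.45, 0.45, 0.50, 0.50, 0.50,
                       0.50, 0.45, 0.45, 0.50, 0.30),
    sd_log_within = c(0.50, 0.45, 0.40, 0.45, 0.40,
                      0.45, 0.45, 0.50, 0.50, 0.50,
                      0.50, 0.45, 0.45, 0.50, 0.35),
    p_consumer = c(1, 0.95, 1, 0.97, 1,
                   0.90, 0.95, 0.95, 0.90, 0.85,
                   0.90, 0.98, 0.98, 1, 1),
    p_day_given_consumer = c(1, 0.45, 1, 0.80, 1,
                             0.60, 0.40, 0.35, 0.25, 0.30,
                             0.40, 0.70, 0.75, 1, 1),
    energy_density = c(2500, 900, 350, 550, 800,
                       2500, 1600, 1450, 1500, 1150,
                       6000, 7500, 8800, 3870, 1800),
    true_price = c(5.0, 2.5, 7.0, 6.0, 3.5,
                   13.0, 9.0, 7.0, 20.0, 4.0,
                   18.0, 8.0, 10.0, 3.0, 4.5),
    loading = c(0.45, -0.10, 0.80, 0.70, 0.05,
                -0.50, 0.45, 0.35, 0.60, 0.50,
                0.50, -0.40, 0.40, -0.70, -0.20),
    base_kg_sales = c(2e5, 4e5, 6e5, 5e5, 8e5,
                      3e5, 2.5e5, 1.5e5, 1e5, 1e5,
                      8e4, 6e4, 7e4, 2e5, 9e5),
    stringsAsFactors = FALSE
  )
  df
}

#' Default sampling strata
#'
#' Region x sex x age-group cells with target population proportions,
#' emulating a stratified recruitment over five administrative regions
#' (two metropolitan, three smaller).
#' @return data.frame with columns region, sex, age_group, prop.
#' @export
default_strata <- function() {
  g <- expand.grid(
    region = c("metro_A", "region_B", "region_C", "metro_D", "region_E"),
    sex = c("male", "female"),
    age_group = c("18-34", "35-49", "50-65"),
    stringsAsFactors = FALSE
  )
  region_p <- c(0.30, 0.10, 0.10, 0.40, 0.10)
  age_p <- c(0.35, 0.33, 0.32)
  g$prop <- region_p[match(g$region, unique(g$region))] * 0.5 *
    age_p[match(g$age_group, unique(g$age_group))]
  g
}

#' Build a synthetic-cohort configuration
#'
#' @param n_participants number of participants.
#' @param strata data.frame of stratum cells with a `prop` column summing
#'   to 1 (see [default_strata()]).
#' @param n_recalls recalls per participant (>= 2; the measurement-error
#'   model needs replicates).
#' @param seed integer seed controlling every draw made from this config.
#' @param food_groups food-group specification table
#'   (see [default_food_groups()]).
#' @param reporting_bias list with elements `p_under`, `p_over`,
#'   `under_factor`, `over_factor`: a person-level multiplicative factor
#'   applied to all reported amounts (defaults 20% at x0.75 and 15% at
#'   x1.25).
#' @param missing list with MCAR missingness fractions `income` and
#'   `education`, and `mechanism` ("MCAR" or "MAR"; MAR ties missingness
#'   to the youngest age group).
#' @param correlation optional between-person correlation matrix of
#'   log usual intakes (groups x groups). Default is built from the
#'   single-factor `loading` column; a non-positive-definite supplied
#'   matrix is repaired to the nearest correlation matrix with a warning.
#' @param sequence_mult multiplicative inflation of first-recall amounts.
#' @param weekend_mult weekend/weekday amount ratio (Friday, Saturday and
#'   Sunday count as weekend). Amounts are centred so the long-run mean
#'   equals the true usual intake.
#' @param energy_balance list with `enabled` and `eq_cv`. When enabled
#'   (default), each person's true usual intakes are rescaled by a
#'   common factor so that true usual energy equals their predicted
#'   energy requirement (lightly active) times a log-normal person
#'   deviation with CV `eq_cv` - i.e. people eat what they expend, up
#'   to prediction-equation error. Density-based index scores are
#'   invariant to this whole-diet scaling; costs gain a realistic
#'   body-size component.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 1000,
                          strata = default_strata(),
                          n_recalls = 3,
                          seed = 20151147,
                          food_groups = default_food_groups(),
                          reporting_bias = list(p_under = 0.20, p_over = 0.15,
                                                under_factor = 0.75,
                                                over_factor = 1.25),
                          missing = list(income = 0.14, education = 0.05,
                                         mechanism = "MCAR"),
                          correlation = NULL,
                          sequence_mult = 1.06,
                          weekend_mult = 1.10,
                          energy_balance = list(enabled = TRUE,
                                                eq_cv = 0.082)) {
  stopifnot(is.data.frame(strata), "prop" %in% names(strata))
  if (any(strata$prop < 0)) stop("stratum proportions must be nonnegative")
  if (abs(sum(strata$prop) - 1) > 1e-9)
    stop("stratum proportions must sum to 1 (tolerance 1e-9)")
  if (n_recalls < 2) stop("n_recalls must be >= 2")
  fg <- food_groups
  stopifnot(all(fg$p_consumer >= 0 & fg$p_consumer <= 1),
            all(fg$p_day_given_consumer >= 0 & fg$p_day_given_consumer <= 1),
            all(fg$sd_log_between >= 0), all(fg$sd_log_within >= 0),
            all(fg$energy_density >= 0), all(fg$true_price >= 0))
  stopifnot(reporting_bias$p_under + reporting_bias$p_over <= 1)
  if (!is.null(correlation)) {
    stopifnot(nrow(correlation) == nrow(fg))
    correlation <- nearest_pd_corr(correlation)
  }
  structure(list(n_participants = n_participants, strata = strata,
                 n_recalls = n_recalls, seed = seed, food_groups = fg,
                 reporting_bias = reporting_bias, missing = missing,
                 correlation = correlation,
                 sequence_mult = sequence_mult,
                 weekend_mult = weekend_mult,
                 energy_balance = energy_balance),
            class = "cohort_config")
}

# Between-person correlation from single-factor loadings.
loading_corr <- function(l) {
  R <- tcrossprod(l)
  diag(R) <- 1
  R
}

#' Generate a synthetic cohort with known true usual intakes
#'
#' Draws participants into strata multinomially around the target
#' proportions, computes post-stratification balancing weights so that
#' weighted stratum shares equal the targets, assigns sociodemographic
#' covariates (with configurable missingness in income and education),
#' anthropometry, a person-level reporting-bias factor, and true usual
#' intakes from a correlated log-normal model. For episodic groups a
#' never-consumer indicator (probability `1 - p_consumer`) zeroes the
#' true usual intake.
#'
#' @param config a [cohort_config()].
#' @return data.frame of participants; true usual intakes are in columns
#'   `true_<group>` (kg/d) and `true_energy` (kcal/d).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants
  st <- config$strata
  fg <- config$food_groups
  s_idx <- sample.int(nrow(st), n, replace = TRUE, prob = st$prop)
  counts <- tabulate(s_idx, nbins = nrow(st))
  wt <- st$prop / (counts / n)
  wt[counts == 0] <- NA_real_
  age_lo <- c(`18-34` = 18, `35-49` = 35, `50-65` = 50)
  age_hi <- c(`18-34` = 34, `35-49` = 49, `50-65` = 65)
  ag <- st$age_group[s_idx]
  sex <- st$sex[s_idx]
  cohort <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    sex = sex,
    age_group = ag,
    age = round(stats::runif(n, age_lo[ag], age_hi[ag])),
    region = st$region[s_idx],
    stratum_id = s_idx,
    balancing_weight = wt[s_idx],
    education = sample(c("none", "high_school", "trade_cegep", "university"),
                       n, replace = TRUE, prob = c(0.10, 0.25, 0.20, 0.45)),
    income = sample(c("<30k", "30-60k", "60-90k", ">=90k"),
                    n, replace = TRUE, prob = c(0.15, 0.25, 0.26, 0.34)),
    smoking = sample(c("smoker", "non_smoker"), n, replace = TRUE,
                     prob = c(0.18, 0.82)),
    stringsAsFactors = FALSE
  )
  cohort$height_m <- ifelse(sex == "male",
                            stats::rnorm(n, 1.76, 0.07),
                            stats::rnorm(n, 1.62, 0.06))
  cohort$weight_kg <- pmax(ifelse(sex == "male",
                                  stats::rnorm(n, 85, 14),
                                  stats::rnorm(n, 70, 13)), 40)
  rb <- config$reporting_bias
  u <- stats::runif(n)
  cohort$reporting_factor <- ifelse(u < rb$p_under, rb$under_factor,
                             ifelse(u < rb$p_under + rb$p_over,
                                    rb$over_factor, 1))
  # missingness
  mis <- config$missing
  if (identical(mis$mechanism, "MAR")) {
    p_inc <- mis$income * ifelse(ag == "18-34", 1.5, 0.75)
    p_edu <- mis$education * ifelse(ag == "18-34", 1.5, 0.75)
  } else {
    p_inc <- rep(mis$income, n); p_edu <- rep(mis$education, n)
  }
  cohort$income[stats::runif(n) < p_inc] <- NA
  cohort$education[stats::runif(n) < p_edu] <- NA
  # true usual intakes: correlated log-normal, zeroed for never-consumers
  R <- config$correlation %||% nearest_pd_corr(loading_corr(fg$loading))
  Z <- rmvn(n, rep(0, nrow(fg)), R)
  U <- exp(sweep(sweep(Z, 2, fg$sd_log_between, `*`), 2, fg$mean_log_usual, `+`))
  consumer <- matrix(1, n, nrow(fg))
  for (g in which(fg$episodic & fg$p_consumer < 1))
    consumer[, g] <- as.numeric(stats::runif(n) < fg$p_consumer[g])
  U <- U * consumer
  eb <- config$energy_balance
  if (isTRUE(eb$enabled)) {
    eer <- predicted_eer(cohort$sex, cohort$age, cohort$weight_kg,
                         cohort$height_m, pal = "low_active")
    target <- eer * exp(stats::rnorm(n, 0, eb$eq_cv) - eb$eq_cv^2 / 2)
    U <- U * (target / as.numeric(U %*% fg$energy_density))
  }
  colnames(U) <- paste0("true_", fg$name)
  cohort <- cbind(cohort, as.data.frame(U))
  cohort$true_energy <- as.numeric(U %*% fg$energy_density)
  attr(cohort, "config") <- config
  cohort
}

#' Generate replicate 24-h recall records
#'
#' Simulates `n_recalls` recall days per participant. Episodic groups are
#' consumed with probability `p_day_given_consumer` (never for
#' never-consumers, whose true usual intake is zero); positive amounts
#' are log-normal around the person's consumption-day amount
#' (`true usual / p_day`) with mean-one multiplicative noise, so the
#' long-run average of reported days equals the true usual intake.
#' A first-recall inflation factor and a weekend/weekday ratio (centred
#' to preserve the long-run mean; Friday counts as weekend) are applied
#' multiplicatively, and the person's reporting-bias factor scales all
#' amounts. Record energy is `amount x energy density`.
#'
#' @param cohort output of [generate_cohort()].
#' @param food_specs food-group table (defaults to the cohort's config).
#' @param seed integer seed.
#' @return data.frame with one row per participant x recall x food group
#'   (zero amounts retained): `participant_id`, `recall_index`,
#'   `weekend`, `food_group`, `amount_kg`, `energy_kcal`.
#' @export
generate_recalls <- function(cohort, food_specs = NULL, seed = 1L) {
  config <- attr(cohort, "config")
  fg <- food_specs %||% config$food_groups
  set.seed(seed)
  n <- nrow(cohort)
  K <- config$n_recalls
  G <- nrow(fg)
  wmult <- config$weekend_mult
  cmix <- (4 + 3 * wmult) / 7   # centring constant: E[day multiplier] = 1
  smult <- config$sequence_mult
  U <- as.matrix(cohort[paste0("true_", fg$name)])
  long <- vector("list", K)
  for (k in seq_len(K)) {
    weekend <- stats::runif(n) < 3 / 7
    daymult <- ifelse(weekend, wmult, 1) / cmix
    seqmult <- if (k == 1) smult else 1
    eats <- matrix(1, n, G)
    for (g in which(fg$episodic)) {
      eats[, g] <- as.numeric(stats::runif(n) < fg$p_day_given_consumer[g])
    }
    # base consumption-day amount; never-consumers have U = 0 hence 0
    pd <- rep(1, G)
    pd[fg$episodic] <- fg$p_day_given_consumer[fg$episodic]
    base <- sweep(U, 2, pd, `/`)
    noise <- exp(sweep(matrix(stats::rnorm(n * G), n, G), 2,
                       fg$sd_log_within, `*`) -
                 matrix(fg$sd_log_within^2 / 2, n, G, byrow = TRUE))
    amt <- base * noise * eats * daymult * seqmult * cohort$reporting_factor
    long[[k]] <- data.frame(
      participant_id = rep(cohort$participant_id, G),
      recall_index = k,
      weekend = rep(weekend, G),
      food_group = rep(fg$name, each = n),
      amount_kg = as.vector(amt),
      energy_kcal = as.vector(sweep(amt, 2, fg$energy_density, `*`)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, long)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic store-level sales database
#'
#' Per (food group, store): kilograms sold drawn log-normal around the
#' group's base sales volume; dollars are kg x a store-level price
#' jittered log-normally (mean-one) around the true price. Groups listed
#' in `missing_groups` are emitted with no rows at all, emulating price
#' databases that do not cover every food group.
#'
#' @param food_specs food-group table with `true_price`, `base_kg_sales`.
#' @param n_stores number of stores.
#' @param dispersion standard deviation of log store-level prices;
#'   0 gives exact price recovery.
#' @param missing_groups character vector of group names to omit.
#' @param seed integer seed.
#' @return data.frame with columns food_group, store, kg, dollars.
#' @export
generate_sales_db <- function(food_specs, n_stores = 6, dispersion = 0.05,
                              missing_groups = character(0), seed = 1L) {
  stopifnot(all(food_specs$true_price >= 0))
  set.seed(seed)
  fg <- food_specs[!food_specs$name %in% missing_groups, ]
  m <- nrow(fg) * n_stores
  kg <- exp(log(rep(fg$base_kg_sales, each = n_stores)) +
              stats::rnorm(m, 0, 0.5)) / n_stores
  price <- rep(fg$true_price, each = n_stores) *
    exp(stats::rnorm(m, 0, dispersion) - dispersion^2 / 2)
  data.frame(
    food_group = rep(fg$name, each = n_stores),
    store = rep(sprintf("store_%02d", seq_len(n_stores)), nrow(fg)),
    kg = kg,
    dollars = kg * price,
    stringsAsFactors = FALSE
  )
}

#' Ground-truth table for a synthetic cohort
#'
#' Computes, per participant, the true usual daily diet cost (true usual
#' intakes priced with the supplied price table), true usual energy, and
#' the true EAT-I total and component scores from true usual intakes.
#' This is the oracle against which the estimated pipeline is validated.
#'
#' @param cohort output of [generate_cohort()].
#' @param food_specs food-group table (defaults to the cohort's config).
#' @param price_table a price table (see [build_price_table()]); defaults
#'   to the true prices in `food_specs`.
#' @param eat_spec EAT-I component specification
#'   (see [default_eat_i_spec()]).
#' @return data.frame keyed by participant_id with true_cost, true_energy,
#'   true_score and true component scores.
#' @export
oracle_truth <- function(cohort, food_specs = NULL, price_table = NULL,
                         eat_spec = default_eat_i_spec()) {
  config <- attr(cohort, "config")
  fg <- food_specs %||% config$food_groups
  U <- as.matrix(cohort[paste0("true_", fg$name)])
  colnames(U) <- fg$name
  if (is.null(price_table)) {
    prices <- stats::setNames(fg$true_price, fg$name)
  } else {
    prices <- stats::setNames(price_table$price_per_kg, price_table$food_group)
    if (!all(fg$name %in% names(prices)))
      stop("price table does not cover all food groups")
    prices <- prices[fg$name]
  }
  true_cost <- as.numeric(U %*% prices)
  true_energy <- as.numeric(U %*% fg$energy_density)
  sc <- score_intake_matrix(U, true_energy, eat_spec, intake_unit = "kg")
  out <- data.frame(participant_id = cohort$participant_id,
                    balancing_weight = cohort$balancing_weight,
                    true_cost = true_cost,
                    true_energy = true_energy,
                    true_score = sc$total,
                    stringsAsFactors = FALSE)
  comp <- sc$components
  colnames(comp) <- paste0("true_score_", colnames(comp))
  cbind(out, as.data.frame(comp))
}

#' Write the synthetic study tables as CSV
#'
#' @param cohort,recalls,sales,truth tables from the generator.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_synthetic_study <- function(cohort, recalls, sales, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("cohort.csv", "recalls.csv", "sales.csv",
                            "truth.csv"))
  utils::write.csv(cohort, paths[1], row.names = FALSE)
  utils::write.csv(recalls, paths[2], row.names = FALSE)
  utils::write.csv(sales, paths[3], row.names = FALSE)
  utils::write.csv(truth, paths[4], row.names = FALSE)
  invisible(paths)
}
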