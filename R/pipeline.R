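# End-to-end study orchestration: synthetic data (or supplied tables),
# single FCS imputation of missing sociodemographics, sales-weighted
# pricing and recall costing, plausibility report, measurement-error
# fit with pseudo-individual simulation, EAT-I scoring, spline
# contrasts overall / per component / by subgroup, and the synthetic
# ground-truth comparison.

#' Single imputation of categorical covariates by chained equations
#'
#' Fully conditional specification: each incomplete categorical variable
#' is imputed from a multinomial model on the other covariates (and the
#' other target variables at their current completed values), cycled a
#' fixed number of times; one completed data set is returned.
#' `<var>_imputed` flags are retained.
#'
#' @param cohort participant table.
#' @param vars variables to impute (default income and education).
#' @param predictors complete covariates used in every imputation model.
#' @param n_cycles chained-equation cycles (default 10).
#' @param seed integer seed.
#' @return the cohort with missing values imputed and flag columns added.
#' @export
impute_fcs <- function(cohort, vars = c("income", "education"),
                       predictors = c("sex", "age_group", "region",
                                      "smoking"),
                       n_cycles = 10, seed = 1L) {
  miss <- lapply(vars, function(v) which(is.na(cohort[[v]])))
  names(miss) <- vars
  for (v in vars) cohort[[paste0(v, "_imputed")]] <- seq_len(nrow(cohort)) %in% miss[[v]]
  if (!any(lengths(miss) > 0)) return(cohort)
  set.seed(seed)
  # initialise by drawing from the observed marginal
  for (v in vars) {
    if (length(miss[[v]]))
      cohort[[v]][miss[[v]]] <- sample(cohort[[v]][!is.na(cohort[[v]])],
                                       length(miss[[v]]), replace = TRUE)
  }
  for (cyc in seq_len(n_cycles)) {
    for (v in vars) {
      if (!length(miss[[v]])) next
      rhs <- c(predictors, setdiff(vars, v))
      dat <- cohort[c(v, rhs)]
      dat[[v]] <- factor(dat[[v]])
      obs <- setdiff(seq_len(nrow(dat)), miss[[v]])
      fml <- stats::as.formula(paste(v, "~", paste(rhs, collapse = "+")))
      fit <- nnet::multinom(fml, data = dat[obs, ], trace = FALSE)
      pr <- stats::predict(fit, newdata = dat[miss[[v]], , drop = FALSE],
                           type = "probs")
      if (is.null(dim(pr))) {  # two-level outcome: vector of P(level 2)
        lv <- levels(dat[[v]])
        draw <- ifelse(stats::runif(length(pr)) < pr, lv[2], lv[1])
      } else {
        draw <- apply(pr, 1, function(p)
          sample(colnames(pr), 1, prob = p))
      }
      cohort[[v]][miss[[v]]] <- draw
    }
  }
  cohort
}

#' Study configuration
#'
#' One object controlling an end-to-end run. Defaults reproduce the
#' package's reference synthetic study design: three recalls over three
#' weeks, stratified sampling with balancing weights, episodic food
#' groups, under/over-reporting, a store-level sales database, and the
#' default EAT-I specification.
#'
#' @param cohort synthetic-cohort configuration ([cohort_config()]).
#' @param sales list: `n_stores`, `dispersion`, `missing_groups` for
#'   [generate_sales_db()].
#' @param yield_factors optional named yield factors for [apply_yield()].
#' @param manual_prices optional manual fallback prices.
#' @param eat_spec_path optional path to an EAT-I YAML specification.
#' @param me_options overrides for [me_spec()] (covariates, mcmc,
#'   n_pseudo, ...).
#' @param block_size foods per measurement-error block.
#' @param knot_percentiles default knot placement for the total score.
#' @param component_knots named list of knot placements overriding the
#'   default for skewed component score distributions.
#' @param linear_components components fitted with a plain linear term.
#' @param subgroup_vars grouping variables for the subgroup table.
#' @param n_boot bootstrap resamples.
#' @param seed master seed; all stage seeds derive from it.
#' @return object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_config(),
                         sales = list(n_stores = 6, dispersion = 0.05,
                                      missing_groups = "sat_fats"),
                         yield_factors = NULL,
                         manual_prices = NULL,
                         eat_spec_path = NULL,
                         me_options = list(),
                         block_size = 6,
                         knot_percentiles = c(5, 35, 65, 95),
                         component_knots = list(
                           tubers_starchy_vegetables = c(10, 50, 90),
                           vegetables = c(10, 50, 90),
                           fruits = c(10, 50, 90)),
                         linear_components = "dairy_foods",
                         subgroup_vars = c("sex", "age_group", "education",
                                           "income", "smoking", "region"),
                         n_boot = 200,
                         seed = 1L) {
  structure(list(cohort = cohort, sales = sales,
                 yield_factors = yield_factors,
                 manual_prices = manual_prices,
                 eat_spec_path = eat_spec_path,
                 me_options = me_options, block_size = block_size,
                 knot_percentiles = knot_percentiles,
                 component_knots = component_knots,
                 linear_components = linear_components,
                 subgroup_vars = subgroup_vars,
                 n_boot = n_boot, seed = seed),
            class = "study_config")
}

#' Run the full diet-cost study
#'
#' Executes every stage on a synthetic cohort with known ground truth
#' and returns descriptives, overall and per-component percentile
#' contrasts, the subgroup table, the plausibility summary, the oracle
#' (truth-table) contrasts, and run metadata.
#'
#' @param config a [study_config()].
#' @param output_dir optional directory; result tables are written as
#'   CSV when given.
#' @return list of class `study_results`.
#' @export
run_study <- function(config = study_config(), output_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  fg <- config$cohort$food_groups
  eat_spec <- default_eat_i_spec(config$eat_spec_path)

  # 1. data
  cohort <- generate_cohort(config$cohort)
  recalls <- generate_recalls(cohort, seed = seed + 1L)
  sales <- generate_sales_db(fg, n_stores = config$sales$n_stores,
                             dispersion = config$sales$dispersion,
                             missing_groups = config$sales$missing_groups,
                             seed = seed + 2L)

  # 2. imputation of missing sociodemographics
  cohort <- impute_fcs(cohort, seed = seed + 3L)

  # 3. prices and daily costs
  pt <- build_price_table(sales)
  if (!is.null(config$yield_factors)) pt <- apply_yield(pt, config$yield_factors)
  pt <- fill_missing_prices(pt, data.frame(name = fg$name,
                                           category = fg$category),
                            manual_prices = config$manual_prices,
                            referenced_groups = fg$name)
  daily <- cost_recalls(recalls, pt)
  ea_cost <- energy_adjusted_cost(daily)
  w_by_id <- stats::setNames(cohort$balancing_weight, cohort$participant_id)
  mean_cost_2500 <- wmean(ea_cost$cost_per_ref,
                          w_by_id[ea_cost$participant_id])

  # 4. plausibility (diagnostic only; nobody is excluded)
  plaus <- classify_plausibility(cohort, daily)

  # 5. episodic classification and measurement-error model
  cls <- classify_episodic(recalls, weights = w_by_id)
  wide <- recalls_to_wide(recalls, daily)
  usual <- fit_usual_intakes(wide, cohort,
                             episodic_vars = cls$episodic,
                             daily_vars = cls$daily,
                             spec_options = config$me_options,
                             block_size = config$block_size,
                             seed = seed + 4L)
  pseudo <- usual$pseudo

  # 6. EAT-I scoring of pseudo-individuals
  food_cols <- fg$name
  sc <- score_intake_matrix(as.matrix(pseudo[food_cols]), pseudo$energy,
                            eat_spec, intake_unit = "kg")
  pseudo$score <- sc$total
  prm <- population_ratio_mean(as.matrix(pseudo[food_cols]), pseudo$energy,
                               pseudo$weight, eat_spec,
                               participant_id = pseudo$participant_id,
                               n_boot = config$n_boot, seed = seed + 5L)

  # 7. contrast data frame (pseudo level, covariates attached)
  cidx <- match(pseudo$participant_id, cohort$participant_id)
  cdf <- data.frame(participant_id = pseudo$participant_id,
                    cost = pseudo$cost, energy = pseudo$energy,
                    weight = pseudo$weight, score = pseudo$score,
                    cohort[cidx, config$subgroup_vars],
                    stringsAsFactors = FALSE)

  base_cfg <- function(adj, kp = config$knot_percentiles, lin = FALSE)
    spline_config(knot_percentiles = kp, linear_only = lin,
                  energy_adjust = adj)
  overall <- rbind(
    spline_contrast(cdf, base_cfg(FALSE), n_boot = config$n_boot,
                    seed = seed + 6L, score_variable = "eat_i_total"),
    spline_contrast(cdf, base_cfg(TRUE), n_boot = config$n_boot,
                    seed = seed + 6L, score_variable = "eat_i_total"))

  comp_rows <- list()
  for (cn in colnames(sc$components)) {
    d <- cdf
    d$score <- sc$components[, cn]
    kp <- config$component_knots[[cn]] %||% config$knot_percentiles
    lin <- cn %in% config$linear_components
    comp_rows[[cn]] <- spline_contrast(
      d, base_cfg(TRUE, kp = kp, lin = lin), n_boot = config$n_boot,
      seed = seed + 7L, score_variable = cn)
  }
  components <- do.call(rbind, comp_rows)
  rownames(components) <- NULL

  subgroups <- subgroup_contrasts(cdf, config$subgroup_vars,
                                  base_cfg(TRUE), n_boot = config$n_boot,
                                  seed = seed + 8L)

  # 8. oracle: the same contrast machinery on the ground truth
  truth <- oracle_truth(cohort, fg, pt, eat_spec)
  tdf <- data.frame(participant_id = truth$participant_id,
                    cost = truth$true_cost, energy = truth$true_energy,
                    weight = truth$balancing_weight,
                    score = truth$true_score, stringsAsFactors = FALSE)
  oracle <- rbind(
    spline_contrast(tdf, base_cfg(FALSE), n_boot = config$n_boot,
                    seed = seed + 9L, score_variable = "eat_i_total_truth"),
    spline_contrast(tdf, base_cfg(TRUE), n_boot = config$n_boot,
                    seed = seed + 9L, score_variable = "eat_i_total_truth"))

  res <- list(
    descriptives = list(
      n = nrow(cohort),
      mean_eat_i = prm,
      mean_cost_per_2500 = mean_cost_2500,
      usual_summaries = usual_summaries(pseudo,
                                        vars = c(food_cols, "energy", "cost"))),
    plausibility = plaus,
    episodic_classification = cls,
    overall = overall,
    components = components,
    subgroups = subgroups,
    oracle = oracle,
    truth = truth,
    pseudo = pseudo,
    price_table = pt,
    meta = list(seed = seed, config_hash = config_hash(config),
                n_pseudo = attr(pseudo, "n_pseudo"),
                package_version = as.character(utils::packageVersion("eatcost")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  )
  class(res) <- "study_results"
  if (!is.null(output_dir)) write_study_results(res, output_dir)
  res
}

#' Write study result tables to CSV (plus a JSON run summary)
#' @param res a `study_results`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_study_results <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$overall, file.path(dir, "overall_contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(res$components, file.path(dir, "component_contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(res$subgroups, file.path(dir, "subgroup_contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(res$plausibility$results,
                   file.path(dir, "plausibility.csv"), row.names = FALSE)
  utils::write.csv(res$descriptives$usual_summaries,
                   file.path(dir, "usual_summaries.csv"), row.names = FALSE)
  utils::write.csv(res$price_table, file.path(dir, "price_table.csv"),
                   row.names = FALSE)
  summary_json <- list(
    mean_eat_i = res$descriptives$mean_eat_i$mean_score,
    mean_eat_i_ci = res$descriptives$mean_eat_i$ci,
    mean_cost_per_2500 = res$descriptives$mean_cost_per_2500,
    plausibility = as.list(res$plausibility$summary),
    meta = res$meta)
  jsonlite::write_json(summary_json, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.study_results <- function(x, ...) {
  cat("Diet-cost study results\n")
  cat(sprintf("  n = %d participants, %d pseudo-individuals each\n",
              x$descriptives$n, x$meta$n_pseudo))
  cat(sprintf("  mean EAT-I (population ratio): %.1f (95%% CI %.1f, %.1f)\n",
              x$descriptives$mean_eat_i$mean_score,
              x$descriptives$mean_eat_i$ci[1],
              x$descriptives$mean_eat_i$ci[2]))
  cat(sprintf("  mean energy-adjusted cost: %.2f $/2500 kcal\n",
              x$descriptives$mean_cost_per_2500))
  cat(sprintf("  misreporting: %.1f%% under, %.1f%% over\n",
              100 * x$plausibility$summary["under"],
              100 * x$plausibility$summary["over"]))
  ov <- x$overall
  for (i in seq_len(nrow(ov)))
    cat(sprintf("  P75-P25 cost contrast (%senergy-adjusted): %.2f $/d (95%% CI %.2f, %.2f)\n",
                if (ov$energy_adjusted[i]) "" else "not ",
                ov$delta_cost[i], ov$ci_low[i], ov$ci_high[i]))
  invisible(x)
}
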