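test_that("balancing weights reproduce target stratum shares", {
  # single stratum: everyone gets weight exactly 1
  st1 <- data.frame(region = "R", sex = "male", age_group = "18-34", prop = 1)
  coh <- generate_cohort(cohort_config(n_participants = 10, strata = st1,
                                       seed = 3))
  expect_equal(coh$balancing_weight, rep(1, 10))

  # two strata targeted 50/50: weighted shares equal the target even
  # though the realized split is not 50/50
  st2 <- data.frame(region = "R", sex = c("male", "female"),
                    age_group = "18-34", prop = c(0.5, 0.5))
  coh2 <- generate_cohort(cohort_config(n_participants = 200, strata = st2,
                                        seed = 11))
  realized <- table(coh2$sex) / nrow(coh2)
  expect_false(isTRUE(all.equal(unname(realized["male"]), 0.5)))
  w_share <- tapply(coh2$balancing_weight, coh2$sex, sum) /
    sum(coh2$balancing_weight)
  expect_equal(as.numeric(w_share[c("male", "female")]), c(0.5, 0.5),
               tolerance = 1e-9)
  # and the per-person weight is the post-stratification ratio
  n_m <- sum(coh2$sex == "male")
  expect_equal(unique(coh2$balancing_weight[coh2$sex == "male"]),
               0.5 / (n_m / 200))
})

test_that("cohort generation validates its configuration", {
  st <- data.frame(region = "R", sex = "male", age_group = "18-34",
                   prop = 0.9)
  expect_error(cohort_config(strata = st), "sum to 1")
  expect_error(cohort_config(n_recalls = 1), "n_recalls")
  bad_R <- matrix(1, 15, 15)  # rank-1 with unit diagonal: not PD
  bad_R[1, 2] <- bad_R[2, 1] <- 2
  expect_warning(cohort_config(correlation = bad_R), "nearest-PD")
})

test_that("identical seed and config give identical outputs at every stage", {
  cc <- cohort_config(n_participants = 60, seed = 5)
  c1 <- generate_cohort(cc); c2 <- generate_cohort(cc)
  expect_identical(c1, c2)
  r1 <- generate_recalls(c1, seed = 8); r2 <- generate_recalls(c2, seed = 8)
  expect_identical(r1, r2)
  s1 <- generate_sales_db(cc$food_groups, seed = 4)
  s2 <- generate_sales_db(cc$food_groups, seed = 4)
  expect_identical(s1, s2)
})

test_that("recalls equal true usual intakes in the noise-free limit", {
  fg <- default_food_groups()
  fg <- fg[!fg$episodic, ]
  fg$sd_log_within <- 0
  cc <- cohort_config(n_participants = 25, food_groups = fg,
                      reporting_bias = no_bias(),
                      sequence_mult = 1, weekend_mult = 1, seed = 2)
  coh <- generate_cohort(cc)
  rec <- generate_recalls(coh, seed = 3)
  truth <- as.matrix(coh[paste0("true_", fg$name)])
  for (g in fg$name) {
    sub <- rec[rec$food_group == g, ]
    expect_equal(sub$amount_kg,
                 truth[match(sub$participant_id, coh$participant_id),
                       paste0("true_", g)],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("episodic consumption days follow the configured probability", {
  fg <- default_food_groups()[1:3, ]
  fg$episodic <- c(TRUE, FALSE, FALSE)
  fg$p_consumer <- 1
  fg$p_day_given_consumer <- c(0.5, 1, 1)
  cc <- cohort_config(n_participants = 4000, food_groups = fg,
                      reporting_bias = no_bias(), seed = 21)
  coh <- generate_cohort(cc)
  rec <- generate_recalls(coh, seed = 22)
  sub <- rec[rec$food_group == fg$name[1], ]
  frac <- mean(sub$amount_kg > 0)           # 12000 person-days
  mc_sd <- sqrt(0.5 * 0.5 / nrow(sub))
  expect_lt(abs(frac - 0.5), 3 * mc_sd)
})

test_that("weekend multiplier shows up as the weekend/weekday geometric mean ratio", {
  fg <- default_food_groups()
  fg <- fg[!fg$episodic, ]
  cc <- cohort_config(n_participants = 2500, food_groups = fg,
                      reporting_bias = no_bias(),
                      sequence_mult = 1, weekend_mult = 1.2, seed = 31)
  coh <- generate_cohort(cc)
  rec <- generate_recalls(coh, seed = 32)
  sub <- rec[rec$food_group == "vegetables" & rec$amount_kg > 0, ]
  lwe <- log(sub$amount_kg[sub$weekend]); lwd <- log(sub$amount_kg[!sub$weekend])
  ratio <- exp(mean(lwe) - mean(lwd))
  mc_sd <- sqrt(var(lwe) / length(lwe) + var(lwd) / length(lwd))
  expect_lt(abs(log(ratio) - log(1.2)), 3 * mc_sd)
})

test_that("episodic prevalence on recall 1 matches 1 - p_consumer * p_day", {
  fg <- default_food_groups()[1:2, ]
  fg$episodic <- c(TRUE, FALSE)
  fg$p_consumer <- c(0.8, 1)
  fg$p_day_given_consumer <- c(0.5, 1)
  cc <- cohort_config(n_participants = 4000, food_groups = fg,
                      reporting_bias = no_bias(), seed = 41)
  coh <- generate_cohort(cc)
  rec <- generate_recalls(coh, seed = 42)
  sub <- rec[rec$food_group == fg$name[1] & rec$recall_index == 1, ]
  expect_lt(abs(mean(sub$amount_kg == 0) - (1 - 0.8 * 0.5)),
            3 * sqrt(0.4 * 0.6 / nrow(sub)))
})

test_that("sales database recovers prices and honours missing groups", {
  fg <- default_food_groups()
  s0 <- generate_sales_db(fg, n_stores = 3, dispersion = 0, seed = 1)
  pt0 <- build_price_table(s0)
  expect_equal(pt0$price_per_kg[match(fg$name, pt0$food_group)],
               fg$true_price, tolerance = 1e-12)

  s1 <- generate_sales_db(fg, missing_groups = c("nuts", "fish"), seed = 2)
  expect_false(any(s1$food_group %in% c("nuts", "fish")))

  s2 <- generate_sales_db(fg, n_stores = 3, dispersion = 0.05, seed = 3)
  pt2 <- build_price_table(s2)
  got <- pt2$price_per_kg[match(fg$name, pt2$food_group)]
  expect_true(all(abs(got - fg$true_price) < 3 * 0.05 * fg$true_price))
})

test_that("oracle truth prices true usual intakes and scores them", {
  cc <- cohort_config(n_participants = 40, seed = 9)
  coh <- generate_cohort(cc)
  fg <- cc$food_groups
  tr <- oracle_truth(coh)
  U <- as.matrix(coh[paste0("true_", fg$name)])
  expect_equal(tr$true_cost, as.numeric(U %*% fg$true_price),
               tolerance = 1e-12)
  expect_equal(tr$true_energy, coh$true_energy)
  expect_true(all(tr$true_score >= 0 & tr$true_score <= 80))
  # component scores sum to the total
  comp <- as.matrix(tr[grep("^true_score_", names(tr))])
  expect_equal(rowSums(comp), tr$true_score, tolerance = 1e-10)
})
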