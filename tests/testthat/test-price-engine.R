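test_that("sales-weighted price is the pooled dollars-over-kg ratio", {
  s <- data.frame(food_group = "a", store = "s1", kg = 2, dollars = 10)
  expect_equal(build_price_table(s)$price_per_kg, 5)

  # pooled ratio differs from the unweighted mean of row prices
  s3 <- data.frame(food_group = "a", store = c("s1", "s2", "s3"),
                   kg = c(2, 2, 1), dollars = c(10, 30, 5))
  pooled <- build_price_table(s3)$price_per_kg
  expect_equal(pooled, 45 / 5)
  mor <- build_price_table(s3, method = "mean_of_ratios")$price_per_kg
  expect_equal(mor, mean(c(5, 15, 5)))
  expect_false(isTRUE(all.equal(pooled, mor)))

  # a group absent from sales is absent from the table
  pt <- build_price_table(data.frame(food_group = "b", kg = 1, dollars = 2))
  expect_false("a" %in% pt$food_group)

  # invalid rows are rejected with their row identifier
  bad <- data.frame(food_group = c("a", "a"), kg = c(1, 0), dollars = c(1, 1))
  expect_error(build_price_table(bad), "rows 2")
})

test_that("pooled ratio equals the brute-force oracle on random tables", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    s <- data.frame(food_group = sample(letters[1:3], n, replace = TRUE),
                    kg = runif(n, 0.1, 50), dollars = runif(n, 0, 200))
    pt <- build_price_table(s)
    for (g in unique(s$food_group)) {
      num <- den <- 0
      for (r in which(s$food_group == g)) {  # explicit row-by-row oracle
        num <- num + s$dollars[r]; den <- den + s$kg[r]
      }
      expect_equal(pt$price_per_kg[pt$food_group == g], num / den,
                   tolerance = 1e-9)
    }
  }
})

test_that("yield adjustment rescales purchased prices to edible prices", {
  pt <- build_price_table(data.frame(food_group = c("a", "b", "c"),
                                     kg = c(1, 1, 1),
                                     dollars = c(4, 7, 5)))
  out <- apply_yield(pt, c(a = 0.5, c = 1.25))
  expect_equal(out$price_per_kg[out$food_group == "a"], 8)     # loss
  expect_equal(out$price_per_kg[out$food_group == "b"], 7)     # untouched
  expect_equal(out$price_per_kg[out$food_group == "c"], 4)     # cooking gain
  expect_error(apply_yield(pt, c(a = 0)), "> 0")
})

test_that("fallback hierarchy fills missing prices in order", {
  groups <- data.frame(name = c("a", "b", "x", "y", "z"),
                       category = c("cat1", "cat1", "cat1", "cat2", "cat3"))
  pt <- build_price_table(data.frame(food_group = c("a", "b"),
                                     kg = c(1, 1), dollars = c(5, 7)))
  # x: category mean of priced siblings a, b
  out <- fill_missing_prices(pt, groups, manual_prices = c(y = 3.25),
                             referenced_groups = c("a", "b", "x", "y"))
  expect_equal(out$price_per_kg[out$food_group == "x"], 6)
  expect_equal(out$provenance[out$food_group == "x"], "fallback:category_mean")
  # y: no sibling, manual price
  expect_equal(out$price_per_kg[out$food_group == "y"], 3.25)
  expect_equal(out$provenance[out$food_group == "y"], "fallback:manual")
  # z: no sibling, no manual -> global sales-weighted mean
  expect_equal(out$price_per_kg[out$food_group == "z"], 12 / 2)
  expect_equal(out$provenance[out$food_group == "z"], "fallback:global_mean")

  # a referenced group that no rule can price is a hard error
  pt_empty <- pt[0, ]
  attr(pt_empty, "global_price") <- NaN
  class(pt_empty) <- c("price_table", "data.frame")
  expect_error(fill_missing_prices(pt_empty, groups,
                                   referenced_groups = "x"), "x")
  # unreferenced priceless group is allowed
  expect_silent(fill_missing_prices(pt_empty, groups,
                                    referenced_groups = character(0)))
})

test_that("daily cost is the price-weighted sum of recall amounts", {
  pt <- build_price_table(data.frame(food_group = c("a", "b"),
                                     kg = c(1, 1), dollars = c(5, 10)))
  rec <- data.frame(participant_id = c("P1", "P1", "P2", "P2"),
                    recall_index = 1L,
                    food_group = c("a", "b", "a", "b"),
                    amount_kg = c(0.2, 0.1, 0, 0),
                    energy_kcal = c(100, 50, 0, 0))
  dc <- cost_recalls(rec, pt)
  expect_equal(dc$cost[dc$participant_id == "P1"], 2.00)
  expect_equal(dc$cost[dc$participant_id == "P2"], 0)   # empty day
  expect_equal(dc$energy_kcal[dc$participant_id == "P1"], 150)

  # positive amount in an unpriced group is an error
  rec2 <- rec; rec2$food_group[1] <- "zz"
  expect_error(cost_recalls(rec2, pt), "zz")
})

test_that("full synthetic day matches an independent summation oracle", {
  cc <- cohort_config(n_participants = 15, seed = 17)
  coh <- generate_cohort(cc)
  rec <- generate_recalls(coh, seed = 18)
  sales <- generate_sales_db(cc$food_groups, seed = 19)
  pt <- build_price_table(sales)
  dc <- cost_recalls(rec, pt)
  prices <- setNames(pt$price_per_kg, pt$food_group)
  for (i in sample(nrow(dc), 10)) {
    rows <- rec[rec$participant_id == dc$participant_id[i] &
                  rec$recall_index == dc$recall_index[i], ]
    manual <- 0
    for (r in seq_len(nrow(rows)))
      manual <- manual + rows$amount_kg[r] * prices[rows$food_group[r]]
    expect_equal(dc$cost[i], unname(manual), tolerance = 1e-9)
  }
})

test_that("cost is linear in amounts and monotone in prices", {
  cc <- cohort_config(n_participants = 10, seed = 23)
  coh <- generate_cohort(cc)
  rec <- generate_recalls(coh, seed = 24)
  pt <- build_price_table(generate_sales_db(cc$food_groups, seed = 25))
  dc <- cost_recalls(rec, pt)
  rec2 <- rec; rec2$amount_kg <- 2 * rec2$amount_kg
  expect_equal(cost_recalls(rec2, pt)$cost, 2 * dc$cost, tolerance = 1e-12)
  pt2 <- pt; pt2$price_per_kg[3] <- pt2$price_per_kg[3] * 1.5
  expect_true(all(cost_recalls(rec, pt2)$cost >= dc$cost - 1e-12))
})

test_that("energy adjustment rescales to the reference energy", {
  dc <- data.frame(participant_id = c("P1", "P1", "P2"),
                   recall_index = c(1L, 2L, 1L),
                   cost = c(10, 8, 6), energy_kcal = c(2000, 2500, 2500))
  ea <- energy_adjusted_cost(dc)
  expect_equal(ea$cost_per_ref[ea$participant_id == "P1"],
               mean(c(10 * 2500 / 2000, 8)))
  expect_equal(ea$cost_per_ref[ea$participant_id == "P2"], 6)  # identity
  dc$energy_kcal[1] <- 0
  expect_error(energy_adjusted_cost(dc), "onpositive")
})
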