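test_that("restricted cubic spline basis has the textbook form", {
  knots <- c(1, 3, 5, 9)
  k <- length(knots)
  set.seed(13)
  x <- runif(100, -2, 12)
  B <- rcs_basis(x, knots)
  expect_equal(ncol(B), k - 1)
  expect_equal(ncol(rcs_basis(x, c(0, 1, 2))), 2)
  # independent formula evaluation, term by term
  for (j in 1:(k - 2)) {
    cube <- function(u) ifelse(u > 0, u^3, 0)
    ref <- (cube(x - knots[j]) -
              cube(x - knots[k - 1]) * (knots[k] - knots[j]) /
              (knots[k] - knots[k - 1]) +
              cube(x - knots[k]) * (knots[k - 1] - knots[j]) /
              (knots[k] - knots[k - 1])) / (knots[k] - knots[1])^2
    expect_equal(B[, j + 1], ref, tolerance = 1e-10, ignore_attr = TRUE)
  }
  # exactly linear beyond the boundary knots: second differences vanish
  for (grid in list(seq(-30, 0.9, length.out = 50),
                    seq(9.1, 40, length.out = 50))) {
    Bg <- rcs_basis(grid, knots)
    for (j in seq_len(ncol(Bg)))
      expect_lt(max(abs(diff(diff(Bg[, j])))), 1e-8)
  }
  expect_error(rcs_basis(x, c(1, 2)), "k >= 3")
})

test_that("noise-free linear data is fitted exactly", {
  set.seed(21)
  df <- data.frame(participant_id = sprintf("P%03d", 1:200),
                   score = runif(200, 10, 70))
  df$cost <- 2 + 0.5 * df$score
  df$weight <- 1
  m <- fit_cost_model(df, spline_config())
  ct <- percentile_contrast(m)
  q <- unname(quantile(df$score, c(0.25, 0.75), type = 7))
  expect_equal(ct$delta, 0.5 * (q[2] - q[1]), tolerance = 1e-8)
  expect_equal(ct$score_lo, q[1], tolerance = 1e-9)
  # predictions reproduce the line everywhere, including beyond knots
  xs <- c(0, 15, 42.5, 90)
  expect_equal(predict_cost(m, xs), 2 + 0.5 * xs, tolerance = 1e-7)
})

test_that("weighted fit equals the replication-expanded unweighted fit", {
  set.seed(22)
  df <- data.frame(participant_id = sprintf("P%03d", 1:60),
                   score = runif(60, 0, 50), weight = sample(1:3, 60, TRUE))
  df$cost <- 3 + 0.2 * df$score + rnorm(60, 0, 0.5)
  cfg <- spline_config(knots = unname(quantile(df$score, c(0.1, 0.5, 0.9))))
  m_w <- fit_cost_model(df, cfg)
  exp_df <- df[rep(seq_len(60), df$weight), ]
  exp_df$weight <- 1
  m_e <- fit_cost_model(exp_df, cfg)
  expect_equal(coef(m_w$fit), coef(m_e$fit), tolerance = 1e-8)
})

test_that("energy adjustment leaves an energy-independent truth unchanged", {
  set.seed(23)
  n <- 4000
  df <- data.frame(participant_id = sprintf("P%04d", 1:n),
                   score = runif(n, 0, 60), weight = 1,
                   energy = rnorm(n, 2500, 300))
  df$cost <- 1 + 0.1 * df$score + rnorm(n, 0, 0.2)
  d_raw <- spline_contrast(df, spline_config(energy_adjust = FALSE),
                           n_boot = 10, seed = 1)
  d_adj <- spline_contrast(df, spline_config(energy_adjust = TRUE),
                           n_boot = 10, seed = 1)
  expect_lt(abs(d_adj$delta_cost - d_raw$delta_cost), 0.05)
})

test_that("percentile contrasts have the right sign and anchors", {
  set.seed(24)
  df <- data.frame(participant_id = sprintf("P%03d", 1:300),
                   score = runif(300, 0, 40), weight = 1)
  df$cost <- 5
  m_flat <- fit_cost_model(df, spline_config())
  expect_equal(percentile_contrast(m_flat)$delta, 0, tolerance = 1e-10)
  df$cost <- exp(df$score / 20)
  m_up <- fit_cost_model(df, spline_config())
  expect_gt(percentile_contrast(m_up)$delta, 0)
  # hand evaluation of the fitted spline at two fixed abscissae
  co <- coef(m_up$fit)
  for (x0 in c(12.3, 31.9)) {
    manual <- co[1] + sum(co[-1] * rcs_basis(x0, m_up$knots)[1, ])
    expect_equal(predict_cost(m_up, x0), unname(manual), tolerance = 1e-10)
  }
})

test_that("bootstrap is deterministic and degenerates to zero SE", {
  # identical participants: every resample gives the same estimate
  base <- data.frame(pseudo = 1:10, score = seq(10, 55, 5))
  df <- do.call(rbind, lapply(sprintf("P%02d", 1:25), function(id)
    data.frame(participant_id = id, score = base$score,
               cost = 1 + 0.3 * base$score, weight = 1)))
  ct <- spline_contrast(df, spline_config(), n_boot = 30, seed = 5)
  expect_equal(ct$se, 0)
  expect_equal(ct$ci_low, ct$delta_cost)
  # fixed seed reproduces the CI exactly
  set.seed(77)
  df2 <- data.frame(participant_id = rep(sprintf("P%02d", 1:40), each = 3),
                    score = runif(120, 0, 50), weight = 1)
  df2$cost <- 2 + 0.1 * df2$score + rnorm(120, 0, 0.4)
  c1 <- spline_contrast(df2, spline_config(), n_boot = 40, seed = 9)
  c2 <- spline_contrast(df2, spline_config(), n_boot = 40, seed = 9)
  expect_identical(c1, c2)
  expect_true(c1$ci_low <= c1$delta_cost && c1$delta_cost <= c1$ci_high)
})

test_that("degenerate score distributions are skipped with a reason", {
  df <- data.frame(participant_id = sprintf("P%02d", 1:50),
                   score = rep(5, 50), cost = rnorm(50, 10), weight = 1)
  expect_message(ct <- spline_contrast(df, spline_config(), n_boot = 5,
                                       seed = 1), "degenerate")
  expect_true(ct$skipped)
  expect_true(is.na(ct$delta_cost))
})

test_that("subgroup contrasts cover all groupings and collapse correctly", {
  set.seed(31)
  df <- data.frame(participant_id = sprintf("P%03d", 1:240),
                   score = runif(240, 0, 50), weight = 1,
                   sex = rep(c("male", "female"), 120),
                   smoking = rep(c("yes", "no"), each = 120),
                   onelevel = "all")
  df$cost <- 1 + 0.2 * df$score + rnorm(240, 0, 0.3)
  res <- subgroup_contrasts(df, c("sex", "smoking", "onelevel"),
                            spline_config(), n_boot = 15, seed = 2)
  expect_setequal(res$grouping, c("sex", "smoking", "onelevel"))
  expect_equal(nrow(res), 5)
  expect_true(all(res$n > 0))
  # a grouping with a single level reproduces the overall analysis
  overall <- spline_contrast(df, spline_config(), n_boot = 15, seed = 2)
  expect_equal(res$delta_cost[res$grouping == "onelevel"],
               overall$delta_cost, tolerance = 1e-10)
})

test_that("rank deficiency is reported with the offending columns", {
  df <- data.frame(participant_id = sprintf("P%02d", 1:30),
                   score = runif(30), weight = 1, cost = rnorm(30),
                   energy = NA_real_)
  df$energy <- df$score * 2  # energy collinear with the linear term
  expect_error(fit_cost_model(df, spline_config(linear_only = TRUE,
                                                energy_adjust = TRUE)),
               "collinear")
})
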