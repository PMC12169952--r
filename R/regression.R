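# Restricted-cubic-spline regression of usual diet cost on dietary
# index scores, summarised as the cost difference between the 75th and
# 25th percentiles of the score distribution, with bootstrap confidence
# intervals resampling participants (pseudo-individuals travel with
# their participant, as they are not independent observations).

#' Restricted cubic spline basis
#'
#' Standard restricted-cubic-spline (natural spline, truncated-power
#' form) basis with linear tails beyond the boundary knots: for `k`
#' knots `t1 < ... < tk` the basis has `k - 1` columns - the linear term
#' plus, for `j = 1 .. k-2`,
#' `[(x - tj)+^3 - (x - t_{k-1})+^3 (tk - tj)/(tk - t_{k-1})
#'   + (x - tk)+^3 (t_{k-1} - tj)/(tk - t_{k-1})] / (tk - t1)^2`.
#'
#' @param x numeric vector.
#' @param knots increasing knot locations (>= 3).
#' @return matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  stopifnot(k >= 3, !is.unsorted(knots, strictly = TRUE))
  scl <- (knots[k] - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    out[, j + 1] <- (pos3(x - knots[j]) -
      pos3(x - knots[k - 1]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1]) +
      pos3(x - knots[k]) * (knots[k - 1] - knots[j]) / (knots[k] - knots[k - 1])) / scl
  }
  colnames(out) <- c("x", paste0("s", seq_len(k - 2)))
  out
}

#' Spline regression configuration
#'
#' @param knot_percentiles knot placement as percentiles of the weighted
#'   score distribution; default `c(5, 35, 65, 95)`; `c(10, 50, 90)` is
#'   the alternative for skewed score distributions.
#' @param linear_only fit a plain linear term instead of splines (used
#'   for near-degenerate score distributions such as the dairy
#'   component).
#' @param energy_adjust include usual energy intake as a covariate.
#' @param p_hi,p_lo percentiles contrasted (default 75 and 25).
#' @param knots explicit knot locations overriding the percentile
#'   placement (rarely needed; mainly for method comparisons).
#' @return object of class `spline_config`.
#' @export
spline_config <- function(knot_percentiles = c(5, 35, 65, 95),
                          linear_only = FALSE, energy_adjust = FALSE,
                          p_hi = 75, p_lo = 25, knots = NULL) {
  stopifnot(length(knot_percentiles) >= 3 || linear_only,
            !is.unsorted(knot_percentiles, strictly = TRUE),
            all(knot_percentiles > 0 & knot_percentiles < 100))
  structure(list(knot_percentiles = knot_percentiles,
                 linear_only = linear_only, energy_adjust = energy_adjust,
                 p_hi = p_hi, p_lo = p_lo, knots = knots),
            class = "spline_config")
}

#' Fit the weighted cost-vs-score regression
#'
#' Weighted least squares of usual cost on the restricted-cubic-spline
#' basis of the score (knots at weighted percentiles of the score
#' distribution), optionally adjusted for usual energy intake.
#'
#' @param df data.frame with columns `cost`, `score`, `weight` and (when
#'   energy-adjusting) `energy`.
#' @param config a [spline_config()].
#' @return list of class `cost_model` (coefficients, knots, weighted
#'   energy mean, the score distribution and weights for percentile
#'   computation).
#' @export
fit_cost_model <- function(df, config = spline_config()) {
  stopifnot(inherits(config, "spline_config"),
            all(c("cost", "score", "weight") %in% names(df)))
  w <- df$weight
  if (config$linear_only) {
    Xs <- matrix(df$score, ncol = 1, dimnames = list(NULL, "x"))
    knots <- NULL
  } else {
    knots <- config$knots %||%
      unname(weighted_quantile(df$score, config$knot_percentiles / 100, w))
    if (anyDuplicated(knots))
      stop("degenerate score distribution: duplicated knots")
    Xs <- rcs_basis(df$score, knots)
  }
  dat <- data.frame(cost = df$cost, Xs, check.names = FALSE)
  if (config$energy_adjust) dat$energy <- df$energy
  fit <- stats::lm(cost ~ ., data = dat, weights = w)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient regression; collinear columns: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  structure(list(fit = fit, knots = knots, config = config,
                 energy_mean = if (config$energy_adjust)
                   wmean(df$energy, w) else NULL,
                 score = df$score, weight = w),
            class = "cost_model")
}

#' Predicted cost at given score values
#'
#' Other covariates (energy) are held at their weighted means.
#' @param model a `cost_model`.
#' @param score score values.
#' @return predicted cost, $/d.
#' @export
predict_cost <- function(model, score) {
  Xs <- if (model$config$linear_only)
    matrix(score, ncol = 1, dimnames = list(NULL, "x"))
  else rcs_basis(score, model$knots)
  nd <- data.frame(Xs, check.names = FALSE)
  if (model$config$energy_adjust) nd$energy <- model$energy_mean
  as.numeric(stats::predict(model$fit, newdata = nd))
}

#' Cost difference between two score percentiles
#'
#' @param model a `cost_model`.
#' @param p_hi,p_lo percentiles (of the weighted score distribution the
#'   model was fitted on) to contrast; defaults from the model's config.
#' @return list with `delta` (cost at `p_hi` minus cost at `p_lo`),
#'   `score_hi`, `score_lo`.
#' @export
percentile_contrast <- function(model, p_hi = NULL, p_lo = NULL) {
  p_hi <- p_hi %||% model$config$p_hi
  p_lo <- p_lo %||% model$config$p_lo
  q <- weighted_quantile(model$score, c(p_lo, p_hi) / 100, model$weight)
  pred <- predict_cost(model, q)
  list(delta = pred[2] - pred[1], score_hi = unname(q[2]),
       score_lo = unname(q[1]))
}

# weighted IQR-degeneracy check used before component regressions
score_degenerate <- function(score, weight, p_hi = 75, p_lo = 25) {
  q <- weighted_quantile(score, c(p_lo, p_hi) / 100, weight)
  diff(q) <= 0
}

#' Percentile contrast with bootstrap confidence interval
#'
#' Fits the cost-vs-score model, computes the P75-P25 (by default)
#' contrast, and attaches a bootstrap CI from resampling participants
#' with replacement: each resample re-runs knot placement, fitting and
#' percentile computation. The CI is a normal approximation using the
#' bootstrap SE (`ci_type = "percentile"` gives percentile bounds).
#' A score distribution whose contrasted percentiles coincide (zero
#' weighted IQR) is skipped with a reason rather than an error.
#'
#' @param df data.frame with `cost`, `score`, `weight`,
#'   `participant_id` and (if adjusting) `energy`.
#' @param config a [spline_config()].
#' @param n_boot bootstrap resamples (default 200).
#' @param seed integer seed.
#' @param ci_type "normal" or "percentile".
#' @param score_variable label stored in the result.
#' @return data.frame (one row) of class `spline_contrast`: `delta_cost`,
#'   `se`, `ci_low`, `ci_high`, `n_boot`, `energy_adjusted`, `n`,
#'   `skipped`, `reason`.
#' @export
spline_contrast <- function(df, config = spline_config(), n_boot = 200,
                            seed = 1L, ci_type = c("normal", "percentile"),
                            score_variable = "score") {
  ci_type <- match.arg(ci_type)
  ids <- unique(df$participant_id)
  base_row <- data.frame(score_variable = score_variable,
                         delta_cost = NA_real_, se = NA_real_,
                         ci_low = NA_real_, ci_high = NA_real_,
                         n_boot = n_boot,
                         energy_adjusted = config$energy_adjust,
                         n = length(ids), skipped = FALSE, reason = "",
                         stringsAsFactors = FALSE)
  if (score_degenerate(df$score, df$weight, config$p_hi, config$p_lo)) {
    base_row$skipped <- TRUE
    base_row$reason <- "degenerate score distribution (zero weighted IQR)"
    message("skipping ", score_variable, ": ", base_row$reason)
    class(base_row) <- c("spline_contrast", "data.frame")
    return(base_row)
  }
  run <- function(d) {
    m <- fit_cost_model(d, config)
    percentile_contrast(m)$delta
  }
  est <- run(df)
  rows_by_id <- split(seq_len(nrow(df)), df$participant_id)[as.character(ids)]
  set.seed(seed)
  bs <- vapply(seq_len(n_boot), function(b) {
    take <- sample.int(length(ids), replace = TRUE)
    d <- df[unlist(rows_by_id[take], use.names = FALSE), ]
    tryCatch(run(d), error = function(e) NA_real_)
  }, numeric(1))
  bs <- bs[!is.na(bs)]
  se <- if (length(bs) > 1) stats::sd(bs) else 0
  if (ci_type == "normal") {
    ci <- est + c(-1, 1) * stats::qnorm(0.975) * se
  } else {
    ci <- unname(stats::quantile(bs, c(0.025, 0.975), type = 7))
  }
  base_row$delta_cost <- est
  base_row$se <- se
  base_row$ci_low <- min(ci[1], est)
  base_row$ci_high <- max(ci[2], est)
  class(base_row) <- c("spline_contrast", "data.frame")
  base_row
}

#' Subgroup percentile contrasts
#'
#' Re-runs the full contrast pipeline within each level of each
#' grouping variable; score percentiles are recomputed within subgroup.
#'
#' @param df contrast data frame (as in [spline_contrast()]) with the
#'   grouping columns attached.
#' @param groupings character vector of grouping column names (e.g.
#'   sex, age_group, education, income, smoking, region).
#' @param config a [spline_config()].
#' @param n_boot,seed,ci_type passed to [spline_contrast()].
#' @return data.frame: one row per grouping x level with the contrast
#'   and its CI.
#' @export
subgroup_contrasts <- function(df, groupings, config = spline_config(),
                               n_boot = 200, seed = 1L,
                               ci_type = "normal") {
  out <- list()
  for (g in groupings) {
    stopifnot(g %in% names(df))
    for (lev in sort(unique(df[[g]]))) {
      sub <- df[df[[g]] == lev, ]
      ct <- spline_contrast(sub, config, n_boot = n_boot, seed = seed,
                            ci_type = ci_type,
                            score_variable = paste0(g, "=", lev))
      ct$grouping <- g
      ct$level <- as.character(lev)
      out[[paste(g, lev)]] <- ct
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
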