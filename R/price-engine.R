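# Sales-weighted food-group pricing and recall-to-cost linkage.

#' Build a sales-weighted price table from store sales data
#'
#' The consumer price of a food group is total dollars sold divided by
#' total kilograms sold, pooled over foods and stores. The pooled ratio
#' is exactly the sales-volume-weighted mean of item prices. An
#' unweighted mean of per-row prices is available for sensitivity
#' analyses via `method = "mean_of_ratios"`.
#'
#' @param sales data.frame with columns `food_group`, `kg` (> 0) and
#'   `dollars` (>= 0); a `store` column is allowed and ignored.
#' @param method "pooled" (default, sum dollars / sum kg) or
#'   "mean_of_ratios" (unweighted mean of row-level dollars/kg).
#' @return data.frame of class `price_table` with columns `food_group`,
#'   `price_per_kg`, `provenance` ("observed") and `yield_factor` (1).
#'   Groups with no sales rows are simply absent, pending
#'   [fill_missing_prices()]. The overall pooled price (all groups) is
#'   kept in the `"global_price"` attribute for the global fallback rule.
#' @export
build_price_table <- function(sales, method = c("pooled", "mean_of_ratios")) {
  method <- match.arg(method)
  stopifnot(all(c("food_group", "kg", "dollars") %in% names(sales)))
  bad <- which(!(sales$kg > 0))
  if (length(bad))
    stop("sales rows with kg <= 0: rows ", paste(bad, collapse = ", "))
  if (any(sales$dollars < 0)) stop("sales rows with negative dollars")
  if (method == "pooled") {
    d <- tapply(sales$dollars, sales$food_group, sum)
    k <- tapply(sales$kg, sales$food_group, sum)
    price <- d / k
  } else {
    price <- tapply(sales$dollars / sales$kg, sales$food_group, mean)
  }
  out <- data.frame(food_group = names(price),
                    price_per_kg = as.numeric(price),
                    provenance = "observed",
                    yield_factor = 1,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "global_price") <- sum(sales$dollars) / sum(sales$kg)
  class(out) <- c("price_table", "data.frame")
  out
}

#' Adjust purchased prices for preparation loss and cooking gain
#'
#' Converts price per kg purchased to price per kg as eaten:
#' `price_edible = price_purchased / yield_factor`. A yield factor below
#' 1 (moisture/fat loss) raises the edible price; above 1 (cooking gain,
#' e.g. grains absorbing water) lowers it. Groups without an entry keep
#' yield 1.
#'
#' @param price_table a `price_table`.
#' @param yield_factors named numeric vector (names are food groups) or
#'   data.frame with columns `food_group`, `yield_factor`; values > 0.
#' @return the adjusted `price_table` (yield_factor column updated).
#' @export
apply_yield <- function(price_table, yield_factors) {
  if (is.data.frame(yield_factors))
    yield_factors <- stats::setNames(yield_factors$yield_factor,
                                     yield_factors$food_group)
  stopifnot(all(yield_factors > 0))
  idx <- match(price_table$food_group, names(yield_factors))
  yf <- ifelse(is.na(idx), 1, yield_factors[idx])
  ga <- attr(price_table, "global_price")
  price_table$price_per_kg <- price_table$price_per_kg / yf
  price_table$yield_factor <- price_table$yield_factor * yf
  attr(price_table, "global_price") <- ga
  price_table
}

#' Fill missing food-group prices by an ordered fallback hierarchy
#'
#' Groups referenced in the food list but absent from the price table
#' are filled, in order, by (1) the unweighted mean price of already
#' priced groups in the same parent category, (2) a user-supplied manual
#' price, (3) the global sales-weighted mean price. The rule that fired
#' is recorded in `provenance`. A group that is still priceless after
#' all rules and is referenced by recalls is a hard error.
#'
#' @param price_table a `price_table` from [build_price_table()].
#' @param groups data.frame with columns `name` and `category` listing
#'   all food groups and their parent categories (e.g.
#'   [default_food_groups()]).
#' @param manual_prices optional named numeric vector of manual prices.
#' @param referenced_groups character vector of groups that appear in
#'   recalls (these must end up priced); default all of `groups$name`.
#' @param verbose log each fallback firing with `message()`.
#' @return completed `price_table` covering all of `groups$name` that
#'   could be priced; unreferenced priceless groups are dropped with
#'   provenance logged.
#' @export
fill_missing_prices <- function(price_table, groups, manual_prices = NULL,
                                referenced_groups = NULL, verbose = FALSE) {
  stopifnot(all(c("name", "category") %in% names(groups)))
  referenced_groups <- referenced_groups %||% groups$name
  missing <- setdiff(groups$name, price_table$food_group)
  global <- attr(price_table, "global_price")
  add <- list()
  still <- character(0)
  for (g in missing) {
    cat_g <- groups$category[groups$name == g]
    sib <- price_table$food_group[price_table$food_group %in%
                                    groups$name[groups$category == cat_g]]
    sib <- setdiff(sib, g)
    if (length(sib)) {
      p <- mean(price_table$price_per_kg[match(sib, price_table$food_group)])
      rule <- "fallback:category_mean"
    } else if (!is.null(manual_prices) && g %in% names(manual_prices)) {
      p <- unname(manual_prices[g])
      rule <- "fallback:manual"
    } else if (!is.null(global) && is.finite(global)) {
      p <- global
      rule <- "fallback:global_mean"
    } else {
      still <- c(still, g)
      next
    }
    if (verbose)
      message(sprintf("price fallback for %s: %s = %.4f $/kg", g, rule, p))
    add[[g]] <- data.frame(food_group = g, price_per_kg = p,
                           provenance = rule, yield_factor = 1,
                           stringsAsFactors = FALSE)
  }
  # manual price overrides category mean if explicitly supplied
  if (!is.null(manual_prices)) {
    for (g in intersect(names(manual_prices), names(add))) {
      add[[g]]$price_per_kg <- unname(manual_prices[g])
      add[[g]]$provenance <- "fallback:manual"
    }
  }
  unpriceable <- intersect(still, referenced_groups)
  if (length(unpriceable))
    stop("no price obtainable for recall-referenced groups: ",
         paste(unpriceable, collapse = ", "))
  if (length(still) && verbose)
    message("unreferenced groups left unpriced: ", paste(still, collapse = ", "))
  out <- rbind(price_table, do.call(rbind, add))
  rownames(out) <- NULL
  attr(out, "global_price") <- global
  class(out) <- c("price_table", "data.frame")
  out
}

#' Convert recall records into daily diet costs
#'
#' Each record's amount (kg) is multiplied by its food group's price per
#' kg and summed within the recall day; record energies are summed the
#' same way.
#'
#' @param recalls data.frame of recall records (`participant_id`,
#'   `recall_index`, `food_group`, `amount_kg`, `energy_kcal`).
#' @param price_table completed `price_table` covering every group with
#'   a positive recall amount.
#' @return data.frame with one row per participant x recall:
#'   `participant_id`, `recall_index`, `cost`, `energy_kcal`.
#' @export
cost_recalls <- function(recalls, price_table) {
  idx <- match(recalls$food_group, price_table$food_group)
  used <- recalls$amount_kg > 0
  if (any(is.na(idx[used]))) {
    stop("no price for food groups: ",
         paste(unique(recalls$food_group[used][is.na(idx[used])]),
               collapse = ", "))
  }
  p <- price_table$price_per_kg[idx]
  p[is.na(p)] <- 0
  key <- interaction(recalls$participant_id, recalls$recall_index, drop = TRUE)
  cost <- tapply(recalls$amount_kg * p, key, sum)
  energy <- tapply(recalls$energy_kcal, key, sum)
  ids <- do.call(rbind, strsplit(names(cost), ".", fixed = TRUE))
  out <- data.frame(participant_id = ids[, 1],
                    recall_index = as.integer(ids[, 2]),
                    cost = as.numeric(cost),
                    energy_kcal = as.numeric(energy),
                    stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, out$recall_index), ]
  rownames(out) <- NULL
  out
}

#' Energy-adjusted daily diet cost per person
#'
#' Scales each recall-day cost to a reference energy intake
#' (`cost x reference_kcal / energy`) and averages over a person's
#' recall days. Used for descriptive tables only; the regression module
#' adjusts for energy as a covariate instead.
#'
#' @param daily_costs output of [cost_recalls()].
#' @param reference_kcal reference energy, default 2500 kcal.
#' @return data.frame per participant with `cost_per_ref` ($ per
#'   `reference_kcal`) and `n_days`.
#' @export
energy_adjusted_cost <- function(daily_costs, reference_kcal = 2500) {
  if (any(daily_costs$energy_kcal <= 0))
    stop("nonpositive daily energy; cannot energy-adjust")
  adj <- daily_costs$cost * reference_kcal / daily_costs$energy_kcal
  m <- tapply(adj, daily_costs$participant_id, mean)
  data.frame(participant_id = names(m),
             cost_per_ref = as.numeric(m),
             n_days = as.integer(table(daily_costs$participant_id)[names(m)]),
             stringsAsFactors = FALSE)
}
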