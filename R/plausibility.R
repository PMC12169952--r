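# Energy-misreporting plausibility screening: each participant's mean
# reported energy intake is compared with their predicted energy
# requirement, and classified as under-, plausibly or over-reported when
# the ratio falls outside a +/- 1 SD band that accounts for within-person
# intake variation, prediction-equation error and day-to-day biological
# variation in energy expenditure. Classification is diagnostic only;
# participants are not excluded downstream.

# Institute of Medicine adult EER physical-activity coefficients.
.pal_coef <- list(
  male = c(sedentary = 1.00, low_active = 1.11, active = 1.25,
           very_active = 1.48),
  female = c(sedentary = 1.00, low_active = 1.12, active = 1.27,
             very_active = 1.45)
)

#' Predicted energy requirement (IOM adult equations)
#'
#' Sex-specific Institute of Medicine estimated energy requirement for
#' adults, defaulting to the low-active (lightly active) physical
#' activity level:
#' men `662 - 9.53 age + PA (15.91 wt + 539.6 ht)`,
#' women `354 - 6.91 age + PA (9.36 wt + 726 ht)`
#' with age in years, weight in kg, height in metres.
#'
#' @param sex "male" or "female" (vectorised).
#' @param age years.
#' @param weight kg.
#' @param height metres.
#' @param pal one of "sedentary", "low_active", "active", "very_active".
#' @return kcal/d.
#' @export
predicted_eer <- function(sex, age, weight, height, pal = "low_active") {
  pal <- match.arg(pal, names(.pal_coef$male))
  pa <- ifelse(sex == "male", .pal_coef$male[pal], .pal_coef$female[pal])
  ifelse(sex == "male",
         662 - 9.53 * age + pa * (15.91 * weight + 539.6 * height),
         354 - 6.91 * age + pa * (9.36 * weight + 726 * height))
}

#' Half-width of the plausible reporting band
#'
#' The 1-SD percentage band for the ratio of mean reported energy intake
#' to predicted requirement:
#' `sqrt(cv_within_EI^2 / n_recalls + cv_pEER^2 + cv_TEE^2)`.
#'
#' @param cv_within_EI_pct within-person CV of energy intake, percent.
#' @param n_recalls recalls averaged per person.
#' @param cv_pEER_pct CV of the prediction equation, percent.
#' @param cv_TEE_pct day-to-day biological CV of total energy
#'   expenditure, percent (8.2 is the commonly used value).
#' @return SD of the EI/pEER ratio, percent.
#' @export
plausibility_cutoff <- function(cv_within_EI_pct, n_recalls,
                                cv_pEER_pct = 8.2, cv_TEE_pct = 8.2) {
  stopifnot(n_recalls >= 1)
  sqrt(cv_within_EI_pct^2 / n_recalls + cv_pEER_pct^2 + cv_TEE_pct^2)
}

# Within-person CV (%) of energy intake from replicate recalls, via a
# log-scale one-way variance decomposition (within-person mean square).
estimate_cv_within <- function(energy, participant_id) {
  le <- log(energy[energy > 0])
  id <- participant_id[energy > 0]
  n_i <- tapply(le, id, length)
  keep <- id %in% names(n_i)[n_i >= 2]
  le <- le[keep]; id <- droplevels(factor(id[keep]))
  m <- tapply(le, id, mean)
  ss <- sum((le - m[as.character(id)])^2)
  df <- length(le) - nlevels(id)
  s2w <- ss / df
  100 * sqrt(exp(s2w) - 1)
}

#' Classify reported energy intake plausibility
#'
#' Computes each participant's mean reported energy over completed
#' recalls, their predicted requirement at the given activity level, and
#' classifies the ratio against the band from [plausibility_cutoff()].
#' The within-person CV of energy is estimated from the recall data on
#' the log scale unless supplied.
#'
#' @param cohort data.frame with `participant_id`, `sex`, `age`,
#'   `weight_kg`, `height_m` and `balancing_weight`.
#' @param daily_costs per-recall table with `participant_id` and
#'   `energy_kcal` (e.g. from [cost_recalls()]).
#' @param cv_within_EI_pct within-person CV of energy intake (percent);
#'   estimated from the data when `NULL`.
#' @param cv_pEER_pct,cv_TEE_pct see [plausibility_cutoff()].
#' @param k number of SDs for the band (default 1).
#' @param pal physical activity level for the prediction equations.
#' @return list with `results` (per-participant table with ratio and
#'   class), `summary` (weighted fractions under/plausible/over),
#'   `cutoff_sd_pct` and `cv_within_EI_pct`.
#' @export
classify_plausibility <- function(cohort, daily_costs,
                                  cv_within_EI_pct = NULL,
                                  cv_pEER_pct = 8.2, cv_TEE_pct = 8.2,
                                  k = 1, pal = "low_active") {
  if (nrow(daily_costs) == 0L) stop("no recall records supplied")
  mean_ei <- tapply(daily_costs$energy_kcal, daily_costs$participant_id, mean)
  n_rec <- tapply(daily_costs$energy_kcal, daily_costs$participant_id, length)
  idx <- match(names(mean_ei), cohort$participant_id)
  if (anyNA(idx)) stop("recalls reference unknown participants")
  cv_w <- cv_within_EI_pct %||%
    estimate_cv_within(daily_costs$energy_kcal, daily_costs$participant_id)
  peer <- predicted_eer(cohort$sex[idx], cohort$age[idx],
                        cohort$weight_kg[idx], cohort$height_m[idx], pal)
  sd_pct <- plausibility_cutoff(cv_w, round(mean(n_rec)), cv_pEER_pct,
                                cv_TEE_pct)
  ratio <- 100 * as.numeric(mean_ei) / peer
  cls <- ifelse(ratio < 100 - k * sd_pct, "under",
                ifelse(ratio > 100 + k * sd_pct, "over", "plausible"))
  res <- data.frame(participant_id = names(mean_ei),
                    mean_reported_EI = as.numeric(mean_ei),
                    predicted_EER = peer,
                    ratio_pct = ratio,
                    cutoff_sd_pct = sd_pct,
                    class = cls,
                    stringsAsFactors = FALSE)
  w <- cohort$balancing_weight[idx]
  summ <- c(under = wmean(cls == "under", w),
            plausible = wmean(cls == "plausible", w),
            over = wmean(cls == "over", w))
  list(results = res, summary = summ, cutoff_sd_pct = sd_pct,
       cv_within_EI_pct = cv_w)
}
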