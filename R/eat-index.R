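# EAT-Lancet dietary index (EAT-I) scoring engine. Components are
# declared in a YAML specification (kind, points, targets/cut-offs and
# the intake variables mapped to each), so cut-offs can be aligned with
# any published scoring table without touching code. The default index
# has ten main components and a 0-80 point total: adequacy components
# score higher with higher intake, moderation components with lower
# intake, and optional components score highest inside an intake range.

#' Load an EAT-I component specification
#'
#' Reads and validates a YAML component specification (defaulting to the
#' one shipped with the package, seeded with EAT-Lancet reference
#' targets for 2500 kcal/d).
#'
#' @param path YAML file path; default the packaged specification.
#' @return list of component specs, class `eat_i_spec`.
#' @export
default_eat_i_spec <- function(path = NULL) {
  path <- path %||% system.file("extdata", "eat_i_components.yaml",
                                package = "eatcost")
  spec <- yaml::read_yaml(path)$components
  for (comp in spec) validate_component(comp)
  structure(spec, class = "eat_i_spec")
}

validate_component <- function(comp) {
  stopifnot(!is.null(comp$name), !is.null(comp$kind))
  if (!comp$max_points %in% c(5, 10))
    stop("component ", comp$name, ": max_points must be 5 or 10")
  if (!is.null(comp$subcomponents)) {
    pts <- vapply(comp$subcomponents, function(s) s$points, numeric(1))
    if (abs(sum(pts) - comp$max_points) > 1e-9)
      stop("component ", comp$name,
           ": subcomponent points must sum to max_points")
    for (s in comp$subcomponents) validate_curve(s, s$points)
  } else {
    validate_curve(comp, comp$max_points)
  }
  invisible(TRUE)
}

validate_curve <- function(x, pts) {
  kind <- x$kind
  if (kind == "adequacy") {
    if (is.null(x$target) || x$target <= 0)
      stop("adequacy curve ", x$name, ": positive target required")
  } else if (kind == "moderation") {
    if (is.null(x$target) || is.null(x$upper) || x$upper <= x$target)
      stop("moderation curve ", x$name, ": need target < upper")
  } else if (kind == "optional") {
    ok <- !is.null(x$lower) && !is.null(x$upper) &&
      x$lower_outer <= x$lower && x$lower <= x$upper &&
      x$upper <= x$upper_outer
    if (!ok) stop("optional curve ", x$name, ": cut-offs must be ordered")
  } else stop("unknown curve kind: ", kind)
  invisible(TRUE)
}

# Points for one scoring curve, vectorised over intake (g/d).
curve_points <- function(intake, x, pts) {
  if (any(intake < 0)) stop("negative intake for ", x$name)
  switch(x$kind,
    adequacy = pts * pmin(intake / x$target, 1),
    moderation = pts * pmin(pmax((x$upper - intake) / (x$upper - x$target), 0), 1),
    optional = {
      p <- rep(pts, length(intake))
      if (x$lower > x$lower_outer) {
        lo <- intake < x$lower
        p[lo] <- pts * pmax((intake[lo] - x$lower_outer) /
                              (x$lower - x$lower_outer), 0)
      } else p[intake < x$lower] <- 0
      hi <- intake > x$upper
      if (x$upper_outer > x$upper) {
        p[hi] <- pts * pmax((x$upper_outer - intake[hi]) /
                              (x$upper_outer - x$upper), 0)
      } else p[hi] <- 0
      p
    },
    stop("unknown curve kind"))
}

# Summed mapped intake for a curve, from a matrix of density intakes.
mapped_intake <- function(M, mapping, name) {
  miss <- setdiff(mapping, colnames(M))
  if (length(miss))
    stop("missing intake variable(s) for ", name, ": ",
         paste(miss, collapse = ", "))
  if (length(mapping) == 1L) M[, mapping] else rowSums(M[, mapping, drop = FALSE])
}

#' Standardize intakes to a reference energy density
#'
#' Scales intakes to a fixed reference energy (`intake x ref / energy`),
#' the density convention under which EAT-Lancet targets are defined.
#'
#' @param intakes numeric vector/matrix of intakes.
#' @param energy daily energy, kcal (scalar or one per row).
#' @param reference_kcal reference energy, default 2500.
#' @return rescaled intakes.
#' @export
standardize_intake <- function(intakes, energy, reference_kcal = 2500) {
  if (any(energy <= 0)) stop("energy must be positive")
  intakes * (reference_kcal / energy)
}

#' Score one EAT-I component
#'
#' @param density_intake named numeric vector of intake variables in g/d
#'   (per 2500 kcal if density scoring is used).
#' @param comp a single component spec from an `eat_i_spec`.
#' @return points for that component (subcomponents scored independently
#'   and summed).
#' @export
score_component <- function(density_intake, comp) {
  M <- matrix(density_intake, nrow = 1,
              dimnames = list(NULL, names(density_intake)))
  unname(score_component_matrix(M, comp)[1])
}

score_component_matrix <- function(M, comp) {
  if (!is.null(comp$subcomponents)) {
    pts <- rep(0, nrow(M))
    for (s in comp$subcomponents)
      pts <- pts + curve_points(mapped_intake(M, s$mapping, s$name), s, s$points)
    pts
  } else {
    curve_points(mapped_intake(M, comp$mapping, comp$name), comp,
                 comp$max_points)
  }
}

#' Score a matrix of intakes against an EAT-I specification
#'
#' Vectorised scorer used throughout the package (single diets, truth
#' tables, pseudo-populations). Intakes are optionally standardized to
#' 2500 kcal before scoring (the default; set
#' `energy_standardize = FALSE` to score absolute intakes).
#'
#' @param intakes matrix (rows = diets) with food/nutrient variables as
#'   named columns, in kg/d (`intake_unit = "kg"`) or g/d (`"g"`).
#' @param energy daily energy per row, kcal.
#' @param spec an `eat_i_spec`.
#' @param intake_unit "kg" or "g".
#' @param energy_standardize standardize to `reference_kcal` first.
#' @param reference_kcal reference energy for density scoring.
#' @return list with `components` (matrix, one column per component) and
#'   `total` (numeric, 0-80 under the default spec).
#' @export
score_intake_matrix <- function(intakes, energy, spec,
                                intake_unit = c("kg", "g"),
                                energy_standardize = TRUE,
                                reference_kcal = 2500) {
  intake_unit <- match.arg(intake_unit)
  stopifnot(inherits(spec, "eat_i_spec"))
  M <- as.matrix(intakes)
  if (intake_unit == "kg") M <- M * 1000
  if (energy_standardize)
    M <- M * (reference_kcal / energy)
  comp <- sapply(spec, function(cp) score_component_matrix(M, cp))
  if (is.null(dim(comp))) comp <- matrix(comp, nrow = 1)
  colnames(comp) <- vapply(spec, `[[`, "", "name")
  list(components = comp, total = rowSums(comp))
}

#' Score a single diet
#'
#' @param intakes named numeric vector of intakes (kg/d by default).
#' @param energy daily energy, kcal.
#' @inheritParams score_intake_matrix
#' @return list with per-component `points` and `total`, class
#'   `eat_i_score`.
#' @export
score_total <- function(intakes, energy, spec, intake_unit = c("kg", "g"),
                        energy_standardize = TRUE, reference_kcal = 2500) {
  sc <- score_intake_matrix(matrix(intakes, nrow = 1,
                                   dimnames = list(NULL, names(intakes))),
                            energy, spec, intake_unit = intake_unit,
                            energy_standardize = energy_standardize,
                            reference_kcal = reference_kcal)
  structure(list(points = sc$components[1, ], total = sc$total[1]),
            class = "eat_i_score")
}

#' @export
print.eat_i_score <- function(x, ...) {
  cat("EAT-I total score:", format(x$total, digits = 4), "\n")
  print(round(x$points, 2))
  invisible(x)
}

#' Construct the intake vector of a fully optimal diet
#'
#' For each scoring curve: adequacy at its target, moderation at zero,
#' optional at the midpoint of its full-score range. Scoring this diet
#' under the same specification attains the maximum total (80 points
#' under the default spec).
#'
#' @param spec an `eat_i_spec`.
#' @return named vector of intakes in g/d (per 2500 kcal).
#' @export
optimal_intake <- function(spec) {
  out <- numeric(0)
  put <- function(x) {
    v <- switch(x$kind,
                adequacy = x$target,
                moderation = 0,
                optional = (x$lower + x$upper) / 2)
    stats::setNames(rep(v / length(x$mapping), length(x$mapping)), x$mapping)
  }
  for (comp in spec) {
    if (!is.null(comp$subcomponents)) {
      for (s in comp$subcomponents) out <- c(out, put(s))
    } else out <- c(out, put(comp))
  }
  out
}

#' Population mean EAT-I score by the population ratio method
#'
#' Scores the weighted mean intake (and energy) vector of the population
#' - a ratio of means, not a mean of individual ratios - and attaches a
#' bootstrap confidence interval from resampling participants (all
#' pseudo-individuals travel with their participant). The weighted mean
#' of individual scores is returned as a diagnostic; it differs from the
#' ratio method wherever the scoring curves are nonlinear.
#'
#' @param intakes matrix of usual intakes (rows = pseudo-individuals or
#'   participants), kg/d by default.
#' @param energy usual energy per row, kcal.
#' @param weights nonnegative weights per row.
#' @param spec an `eat_i_spec`.
#' @param participant_id participant identifier per row (bootstrap
#'   resampling unit); default each row its own participant.
#' @param n_boot bootstrap resamples for the CI (default 200).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level.
#' @inheritParams score_intake_matrix
#' @return list with `mean_score`, `ci` (normal approximation),
#'   `se`, `mean_of_scores` diagnostic, `n_boot`.
#' @export
population_ratio_mean <- function(intakes, energy, weights, spec,
                                  participant_id = NULL, n_boot = 200,
                                  seed = 1L, conf = 0.95,
                                  intake_unit = c("kg", "g"),
                                  energy_standardize = TRUE,
                                  reference_kcal = 2500) {
  intake_unit <- match.arg(intake_unit)
  M <- as.matrix(intakes)
  participant_id <- participant_id %||% seq_len(nrow(M))
  ratio_score <- function(rows) {
    w <- weights[rows]
    mi <- colSums(M[rows, , drop = FALSE] * w) / sum(w)
    me <- sum(energy[rows] * w) / sum(w)
    score_intake_matrix(matrix(mi, 1, dimnames = list(NULL, colnames(M))),
                        me, spec, intake_unit = intake_unit,
                        energy_standardize = energy_standardize,
                        reference_kcal = reference_kcal)$total
  }
  est <- ratio_score(seq_len(nrow(M)))
  ind <- score_intake_matrix(M, energy, spec, intake_unit = intake_unit,
                             energy_standardize = energy_standardize,
                             reference_kcal = reference_kcal)$total
  mos <- wmean(ind, weights)
  ids <- unique(participant_id)
  rows_by_id <- split(seq_len(nrow(M)), participant_id)[as.character(ids)]
  set.seed(seed)
  bs <- vapply(seq_len(n_boot), function(b) {
    take <- sample.int(length(ids), replace = TRUE)
    ratio_score(unlist(rows_by_id[take], use.names = FALSE))
  }, numeric(1))
  se <- stats::sd(bs)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(mean_score = est, se = se, ci = c(est - z * se, est + z * se),
       mean_of_scores = mos, n_boot = n_boot)
}
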