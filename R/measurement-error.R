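# Multivariate measurement-error model for repeated 24-h recalls,
# following the NCI multivariate model class: episodic variables get a
# two-part model (probit consumption part with a person random effect,
# plus a Box-Cox-transformed amount part), daily variables get the
# amount part only; all person random effects are jointly multivariate
# normal with unstructured covariance, within-person amount errors are
# multivariate normal, and the model is fitted by Gibbs sampling with
# data augmentation (latent probit values; amounts on non-consumption
# days). Usual intakes are then simulated as pseudo-individuals from the
# posterior of the person random effects, back-transforming the Box-Cox
# mean with a second-order Taylor bias correction.
#
# This is a re-implementation of the published model class, not a port
# of the SAS macros; within-day probit and amount errors are taken as
# independent (their correlation is carried by the random effects).

#' Measurement-error model specification
#'
#' @param episodic_vars character vector of episodic variable names.
#' @param daily_vars character vector of daily variable names (must
#'   include the energy and cost variables when present).
#' @param covariates person/day covariates entering the fixed effects;
#'   subset of `c("sequence", "weekend", "age_group", "smoking",
#'   "income", "education", "region")`.
#' @param strata stratification variable (default "sex"); `NULL` fits a
#'   single stratum.
#' @param n_pseudo pseudo-individuals per participant (default 500).
#' @param mcmc list with `n_iter`, `n_burn`, `thin`.
#' @param boxcox_grid candidate Box-Cox lambdas (0 = log).
#' @param min_stratum_n minimum participants per stratum.
#' @param rhat_threshold split-chain diagnostic threshold for a
#'   convergence warning.
#' @return object of class `me_spec`.
#' @export
me_spec <- function(episodic_vars, daily_vars,
                    covariates = c("sequence", "weekend"),
                    strata = "sex", n_pseudo = 500,
                    mcmc = list(n_iter = 5000, n_burn = 2500, thin = 5),
                    boxcox_grid = seq(0, 1, by = 0.1),
                    min_stratum_n = 25, rhat_threshold = 1.2) {
  if (length(intersect(episodic_vars, daily_vars)))
    stop("variables classified both episodic and daily: ",
         paste(intersect(episodic_vars, daily_vars), collapse = ", "))
  stopifnot(n_pseudo >= 1, mcmc$n_iter > mcmc$n_burn)
  structure(list(episodic_vars = episodic_vars, daily_vars = daily_vars,
                 covariates = covariates, strata = strata,
                 n_pseudo = n_pseudo, mcmc = mcmc,
                 boxcox_grid = boxcox_grid,
                 min_stratum_n = min_stratum_n,
                 rhat_threshold = rhat_threshold),
            class = "me_spec")
}

#' Classify dietary variables as episodic or daily
#'
#' A variable is episodic iff the (weighted) fraction of participants
#' reporting zero intake on their first recall is at least `threshold`
#' (inclusive, so exactly 10% is episodic). Energy and diet cost are
#' always daily.
#'
#' @param recalls long recall table (`participant_id`, `recall_index`,
#'   `food_group`, `amount_kg`).
#' @param weights optional named vector of participant balancing weights.
#' @param threshold zero-fraction threshold, default 0.10.
#' @param force_daily variables never classified episodic.
#' @return list with `episodic`, `daily` and the per-variable
#'   `zero_fraction` on recall 1.
#' @export
classify_episodic <- function(recalls, weights = NULL, threshold = 0.10,
                              force_daily = c("energy", "cost")) {
  r1 <- recalls[recalls$recall_index == 1, ]
  w <- if (is.null(weights)) rep(1, nrow(r1)) else {
    unname(weights[r1$participant_id])
  }
  zf <- tapply(seq_len(nrow(r1)), r1$food_group, function(i)
    sum(w[i] * (r1$amount_kg[i] == 0)) / sum(w[i]))
  zf <- unlist(zf)
  episodic <- setdiff(names(zf)[zf >= threshold], force_daily)
  daily <- setdiff(names(zf), episodic)
  list(episodic = episodic, daily = daily, zero_fraction = zf)
}

#' Reshape long recalls (plus daily costs) to one row per recall day
#'
#' @param recalls long recall table.
#' @param daily_costs optional output of [cost_recalls()]; adds `energy`
#'   and `cost` columns.
#' @return data.frame with `participant_id`, `recall_index`, `weekend`
#'   and one amount column per food group.
#' @export
recalls_to_wide <- function(recalls, daily_costs = NULL) {
  key <- unique(recalls[c("participant_id", "recall_index", "weekend")])
  key <- key[order(key$participant_id, key$recall_index), ]
  rownames(key) <- NULL
  groups <- unique(recalls$food_group)
  kk <- paste(key$participant_id, key$recall_index)
  for (g in groups) {
    sub <- recalls[recalls$food_group == g, ]
    key[[g]] <- sub$amount_kg[match(kk, paste(sub$participant_id,
                                              sub$recall_index))]
    key[[g]][is.na(key[[g]])] <- 0
  }
  if (!is.null(daily_costs)) {
    m <- match(kk, paste(daily_costs$participant_id,
                         daily_costs$recall_index))
    key$energy <- daily_costs$energy_kcal[m]
    key$cost <- daily_costs$cost[m]
  }
  key
}

# Fixed-effects design matrix for one stratum's recall-day rows.
me_design <- function(wide, cohort, covariates, check_rank = TRUE) {
  n_seq <- max(wide$recall_index)
  X <- cbind(intercept = rep(1, nrow(wide)))
  if ("sequence" %in% covariates && n_seq >= 2) {
    for (k in seq_len(n_seq - 1))
      X <- cbind(X, stats::setNames(
        data.frame(as.numeric(wide$recall_index == k)), paste0("seq", k)))
  }
  if ("weekend" %in% covariates)
    X <- cbind(X, weekend = as.numeric(wide$weekend))
  idx <- match(wide$participant_id, cohort$participant_id)
  for (v in setdiff(covariates, c("sequence", "weekend"))) {
    val <- cohort[[v]][idx]
    if (anyNA(val))
      stop("covariate ", v, " has missing values; impute first")
    f <- factor(val)
    if (nlevels(f) > 1) {
      D <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(D) <- paste0(v, "_", levels(f)[-1])
      X <- cbind(X, D)
    }
  }
  X <- as.matrix(X)
  if (check_rank && qr(X)$rank < ncol(X)) {
    stop("design matrix rank deficient; check covariates: ",
         paste(colnames(X), collapse = ", "))
  }
  X
}

# Split-chain potential scale reduction (Gelman-Rubin) for one series.
split_rhat <- function(x) {
  m <- length(x) %/% 2
  if (m < 2) return(NA_real_)
  h <- list(x[1:m], x[(m + 1):(2 * m)])
  means <- vapply(h, mean, 0); vars <- vapply(h, stats::var, 0)
  W <- mean(vars); B <- m * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((m - 1) / m * W + B / m) / W)
}

# Gibbs sampler for one stratum. Returns stored draws and metadata.
fit_me_stratum <- function(Y, C, X, pid, spec, var_names, episodic) {
  p <- ncol(Y); E <- sum(episodic); q <- E + p
  n <- length(unique(pid))
  pid_f <- factor(pid, levels = unique(pid))
  pid_i <- as.integer(pid_f)
  N <- nrow(Y)
  d <- ncol(X)
  ep_cols <- which(episodic)

  # Box-Cox lambda per amount variable, chosen on the grid from the
  # profile log-likelihood of observed positive amounts.
  lambda <- numeric(p); shift <- numeric(p)
  T0 <- matrix(NA_real_, N, p)
  for (v in seq_len(p)) {
    obs <- if (episodic[v]) C[, match(v, ep_cols)] == 1 else rep(TRUE, N)
    y <- Y[obs, v]
    if (any(y <= 0)) { shift[v] <- min(y[y > 0]) / 2; y <- y + shift[v] }
    ll <- vapply(spec$boxcox_grid, function(l)
      boxcox_grid_loglik(y, X[obs, , drop = FALSE], l), numeric(1))
    lambda[v] <- spec$boxcox_grid[which.max(ll)]
    T0[obs, v] <- boxcox_tr(y, lambda[v])
  }
  Miss <- is.na(T0)

  # initial values
  B <- matrix(0, d, p); A <- matrix(0, d, E)
  for (v in seq_len(p)) {
    obs <- !Miss[, v]
    B[, v] <- stats::lm.fit(X[obs, , drop = FALSE], T0[obs, v])$coefficients
  }
  B[is.na(B)] <- 0
  if (E > 0) {
    for (e in seq_len(E))
      A[1, e] <- stats::qnorm(pmin(pmax(mean(C[, e]), 0.02), 0.98))
  }
  Tm <- T0
  XB <- X %*% B
  Tm[Miss] <- XB[Miss]
  b <- matrix(0, n, q)
  Sb <- diag(0.2, q)
  Sw <- diag(pmax(diag(stats::var(Tm - XB)) * 0.6, 1e-3), p)
  nu0 <- q + 2; Psi0 <- diag(0.01, q)
  nu0w <- p + 2; Psi0w <- diag(0.01, p)
  J <- tabulate(pid_i, nbins = n)
  J_groups <- split(seq_len(n), J)
  XtX <- crossprod(X)
  XtX_inv <- solve(XtX)
  Rx <- chol(XtX_inv)
  # missing patterns (rows sharing which amount columns are unobserved)
  pat_key <- apply(Miss, 1, function(z) paste(which(z), collapse = ","))
  pat_rows <- split(seq_len(N), pat_key)
  pat_rows <- pat_rows[names(pat_rows) != ""]

  mc <- spec$mcmc
  keep_iters <- seq(mc$n_burn + mc$thin %||% 1, mc$n_iter, by = mc$thin %||% 1)
  S <- length(keep_iters)
  store <- list(b = vector("list", S), A = vector("list", S),
                B = vector("list", S), Sw = vector("list", S),
                Sb = vector("list", S))
  s_out <- 0L
  Z <- matrix(0, N, max(E, 1))

  for (it in seq_len(mc$n_iter)) {
    v_rep <- if (E > 0) b[pid_i, seq_len(E), drop = FALSE] else NULL
    u_rep <- b[pid_i, E + seq_len(p), drop = FALSE]
    XA <- if (E > 0) X %*% A else NULL
    XB <- X %*% B
    # 1. latent probit values
    if (E > 0) {
      m <- XA + v_rep
      Z <- matrix(rtnorm_sign(as.vector(m), as.vector(C == 1)), N, E)
    }
    # 2. augment unobserved amounts from their conditional normal
    Mu <- XB + u_rep
    for (pk in names(pat_rows)) {
      rows <- pat_rows[[pk]]
      mi <- as.integer(strsplit(pk, ",")[[1]])
      oi <- setdiff(seq_len(p), mi)
      if (length(oi)) {
        So_inv <- solve(Sw[oi, oi, drop = FALSE])
        coef <- Sw[mi, oi, drop = FALSE] %*% So_inv
        cond_cov <- Sw[mi, mi, drop = FALSE] -
          coef %*% Sw[oi, mi, drop = FALSE]
        cm <- Mu[rows, mi, drop = FALSE] +
          (Tm[rows, oi, drop = FALSE] - Mu[rows, oi, drop = FALSE]) %*% t(coef)
      } else {
        cond_cov <- Sw
        cm <- Mu[rows, , drop = FALSE]
      }
      cond_cov <- (cond_cov + t(cond_cov)) / 2
      Tm[rows, mi] <- cm + matrix(stats::rnorm(length(rows) * length(mi)),
                                  length(rows)) %*% chol(cond_cov)
    }
    # 3. person random effects (same conditional precision within a
    #    recall-count group, so drawn group-wise)
    Swi <- solve(Sw)
    Sbi <- solve(Sb)
    R2 <- rowsum(Tm - XB, pid_i, reorder = TRUE) %*% Swi
    rhs <- if (E > 0) cbind(rowsum(Z - XA, pid_i, reorder = TRUE), R2) else R2
    P <- diag(q) * 0
    if (E > 0) P[seq_len(E), seq_len(E)] <- diag(E)
    P[E + seq_len(p), E + seq_len(p)] <- Swi
    for (jg in names(J_groups)) {
      g <- J_groups[[jg]]
      V <- solve(Sbi + as.numeric(jg) * P)
      V <- (V + t(V)) / 2
      b[g, ] <- rhs[g, , drop = FALSE] %*% V +
        matrix(stats::rnorm(length(g) * q), length(g)) %*% chol(V)
    }
    v_rep <- if (E > 0) b[pid_i, seq_len(E), drop = FALSE] else NULL
    u_rep <- b[pid_i, E + seq_len(p), drop = FALSE]
    # 4. fixed effects
    if (E > 0) {
      Ahat <- XtX_inv %*% crossprod(X, Z - v_rep)
      A <- Ahat + t(Rx) %*% matrix(stats::rnorm(d * E), d, E)
    }
    Bhat <- XtX_inv %*% crossprod(X, Tm - u_rep)
    B <- Bhat + t(Rx) %*% matrix(stats::rnorm(d * p), d, p) %*% chol(Sw)
    # 5. covariances
    Sb <- riwish(nu0 + n, Psi0 + crossprod(b))
    resid <- Tm - X %*% B - u_rep
    Sw <- riwish(nu0w + N, Psi0w + crossprod(resid))
    if (it %in% keep_iters) {
      s_out <- s_out + 1L
      store$b[[s_out]] <- b
      store$A[[s_out]] <- A
      store$B[[s_out]] <- B
      store$Sw[[s_out]] <- Sw
      store$Sb[[s_out]] <- Sb
    }
  }
  # convergence diagnostics on variance components
  vc <- t(vapply(seq_len(S), function(s)
    c(diag(store$Sb[[s]]), diag(store$Sw[[s]])), numeric(q + p)))
  rhat <- apply(vc, 2, split_rhat)
  if (any(rhat > spec$rhat_threshold, na.rm = TRUE))
    warning("split-chain diagnostic above ", spec$rhat_threshold,
            " for some variance components (max ",
            round(max(rhat, na.rm = TRUE), 3), "); consider a longer chain")
  list(store = store, lambda = lambda, shift = shift,
       var_names = var_names, episodic = episodic,
       persons = levels(pid_f), rhat = rhat, n_stored = S,
       d = d, design_cols = colnames(X))
}

#' Fit the multivariate measurement-error model
#'
#' Fits the two-part/amount model by Gibbs sampling within each stratum
#' (typically sex). The recall-day table must contain one amount column
#' per modelled variable.
#'
#' @param wide recall-day table from [recalls_to_wide()].
#' @param cohort participant table (covariates and stratum variable).
#' @param spec an [me_spec()].
#' @return object of class `me_fit`.
#' @export
fit_me_model <- function(wide, cohort, spec) {
  stopifnot(inherits(spec, "me_spec"))
  vars <- c(spec$episodic_vars, spec$daily_vars)
  miss <- setdiff(vars, names(wide))
  if (length(miss)) stop("variables absent from recall table: ",
                         paste(miss, collapse = ", "))
  episodic <- vars %in% spec$episodic_vars
  strat_val <- if (is.null(spec$strata)) rep("all", nrow(cohort)) else
    cohort[[spec$strata]]
  strata_levels <- unique(strat_val)
  fits <- list()
  for (s in strata_levels) {
    ids <- cohort$participant_id[strat_val == s]
    sub <- wide[wide$participant_id %in% ids, ]
    if (length(unique(sub$participant_id)) < spec$min_stratum_n)
      stop("stratum ", s, " has fewer than ", spec$min_stratum_n,
           " participants")
    X <- me_design(sub, cohort, spec$covariates)
    Y <- as.matrix(sub[vars])
    C <- (Y[, episodic, drop = FALSE] > 0) * 1L
    fits[[s]] <- fit_me_stratum(Y, C, X, sub$participant_id, spec,
                                vars, episodic)
  }
  structure(list(strata = fits, spec = spec, vars = vars,
                 episodic = episodic),
            class = "me_fit")
}

#' @export
print.me_fit <- function(x, ...) {
  cat("Multivariate measurement-error model fit\n")
  cat("  variables:", paste(x$vars, collapse = ", "), "\n")
  cat("  episodic:", paste(x$vars[x$episodic], collapse = ", "), "\n")
  for (s in names(x$strata)) {
    f <- x$strata[[s]]
    cat(sprintf("  stratum %s: %d participants, %d stored draws, max Rhat %.3f\n",
                s, length(f$persons), f$n_stored, max(f$rhat, na.rm = TRUE)))
    cat("    lambda:", paste(sprintf("%s=%.1f", f$var_names, f$lambda),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

# Reference design rows (weekday and weekend versions) for prediction.
# The first-recall indicator is set to 0 (its inflation is a reporting
# artifact); the remaining sequence indicators are averaged uniformly
# over recalls 2..K so that per-recall sampling noise cancels. Weekend
# versions differ only in the weekend column; person covariates are at
# their observed values.
reference_design <- function(fit_s, cohort, spec) {
  sub <- cohort[match(fit_s$persons, cohort$participant_id), ]
  fake <- data.frame(participant_id = sub$participant_id,
                     recall_index = 999L, weekend = FALSE)
  Xwd <- me_design(fake, cohort, setdiff(spec$covariates, "sequence"),
                   check_rank = FALSE)
  # rebuild with the fitted design's columns: zero out sequence cols
  full <- matrix(0, nrow(sub), fit_s$d,
                 dimnames = list(NULL, fit_s$design_cols))
  for (cn in colnames(Xwd)) if (cn %in% colnames(full)) full[, cn] <- Xwd[, cn]
  seq_cols <- grep("^seq[0-9]+$", colnames(full), value = TRUE)
  later <- setdiff(seq_cols, "seq1")
  if (length(seq_cols)) {
    # recalls 2..K each get weight 1/(K-1); recall K is the implicit
    # reference level, so the later-recall dummies each take that weight
    full[, later] <- 1 / (length(seq_cols))
    full[, "seq1"] <- 0
  }
  Xwe <- full
  if ("weekend" %in% colnames(full)) Xwe[, "weekend"] <- 1
  list(wd = full, we = Xwe, ids = sub$participant_id,
       weight = sub$balancing_weight)
}

#' Simulate pseudo-individual usual intakes from a fitted model
#'
#' For each participant, draws `n_pseudo` posterior random-effect
#' vectors (stored Gibbs draws, with the matching fixed-effect and
#' covariance draws) and maps each to a usual-intake vector on the
#' original scale: the Box-Cox mean is back-transformed with a
#' second-order Taylor bias correction, predictions are averaged over a
#' 4/7 weekday + 3/7 weekend mix with sequence effects at their
#' reference (non-first-recall) level, and episodic usual intake is the
#' consumption probability times the usual consumption-day amount.
#'
#' @param fit an `me_fit`.
#' @param cohort participant table.
#' @param n_pseudo pseudo-individuals per participant (default from the
#'   spec).
#' @param seed integer seed.
#' @return data.frame (long): `participant_id`, `pseudo_index`, one
#'   column per variable, `balancing_weight` and `weight`
#'   (= balancing_weight / n_pseudo).
#' @export
simulate_usual <- function(fit, cohort, n_pseudo = NULL, seed = 1L) {
  stopifnot(inherits(fit, "me_fit"))
  spec <- fit$spec
  n_pseudo <- n_pseudo %||% spec$n_pseudo
  set.seed(seed)
  vars <- fit$vars; episodic <- fit$episodic
  p <- length(vars); E <- sum(episodic)
  out <- list()
  for (s in names(fit$strata)) {
    f <- fit$strata[[s]]
    ref <- reference_design(f, cohort, spec)
    n <- length(f$persons)
    draw_idx <- sample.int(f$n_stored, n_pseudo, replace = n_pseudo > f$n_stored)
    res <- vector("list", n_pseudo)
    for (m in seq_len(n_pseudo)) {
      sidx <- draw_idx[m]
      b <- f$store$b[[sidx]]; A <- f$store$A[[sidx]]
      B <- f$store$B[[sidx]]; Sw <- f$store$Sw[[sidx]]
      U <- matrix(0, n, p, dimnames = list(NULL, vars))
      for (v in seq_len(p)) {
        u <- b[, E + v]
        mu_wd <- as.numeric(ref$wd %*% B[, v]) + u
        mu_we <- as.numeric(ref$we %*% B[, v]) + u
        amt <- (4 / 7) * boxcox_bt_mean(mu_wd, f$lambda[v], Sw[v, v]) +
               (3 / 7) * boxcox_bt_mean(mu_we, f$lambda[v], Sw[v, v])
        amt <- pmax(amt - f$shift[v], 0)
        if (episodic[v]) {
          e <- match(v, which(episodic))
          pr <- (4 / 7) * stats::pnorm(as.numeric(ref$wd %*% A[, e]) + b[, e]) +
                (3 / 7) * stats::pnorm(as.numeric(ref$we %*% A[, e]) + b[, e])
          amt <- pr * amt
        }
        U[, v] <- amt
      }
      res[[m]] <- data.frame(participant_id = ref$ids, pseudo_index = m,
                             U, balancing_weight = ref$weight,
                             stringsAsFactors = FALSE)
    }
    out[[s]] <- do.call(rbind, res)
  }
  pp <- do.call(rbind, out)
  pp$weight <- pp$balancing_weight / n_pseudo
  rownames(pp) <- NULL
  attr(pp, "n_pseudo") <- n_pseudo
  pp
}

#' Weighted distribution summaries of usual intakes
#'
#' @param pseudo pseudo-population from [simulate_usual()].
#' @param vars variables to summarise (default: all modelled columns).
#' @param weights weight column name (default "weight").
#' @param probs percentiles to report.
#' @return data.frame with one row per variable: weighted mean and
#'   percentiles over all pseudo-individuals.
#' @export
usual_summaries <- function(pseudo, vars = NULL,
                            weights = "weight",
                            probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  vars <- vars %||% setdiff(names(pseudo),
                            c("participant_id", "pseudo_index",
                              "balancing_weight", "weight"))
  w <- pseudo[[weights]]
  rows <- lapply(vars, function(v) {
    q <- weighted_quantile(pseudo[[v]], probs, w)
    c(mean = wmean(pseudo[[v]], w), q)
  })
  out <- data.frame(variable = vars, do.call(rbind, rows),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit usual intakes in correlated blocks and pool pseudo-populations
#'
#' High-dimensional variable sets are fitted in blocks of foods, each
#' block augmented with the energy and cost variables so that every
#' food's correlation with energy and cost is preserved; energy and cost
#' usual values are taken from the first block. This is the documented
#' approximation used for full-pipeline runs.
#'
#' @param wide recall-day table from [recalls_to_wide()] (with `energy`
#'   and `cost` columns).
#' @param cohort participant table.
#' @param episodic_vars,daily_vars variable classification (see
#'   [classify_episodic()]); `daily_vars` excludes energy/cost, which
#'   are added to every block automatically.
#' @param spec_options list of overrides passed to [me_spec()]
#'   (covariates, mcmc, n_pseudo, ...).
#' @param block_size foods per block (default 6).
#' @param seed integer seed for the simulation step.
#' @return list with `pseudo` (merged pseudo-population) and `fits`
#'   (one `me_fit` per block).
#' @export
fit_usual_intakes <- function(wide, cohort, episodic_vars, daily_vars,
                              spec_options = list(), block_size = 6,
                              seed = 1L) {
  foods <- c(episodic_vars, setdiff(daily_vars, c("energy", "cost")))
  blocks <- split(foods, ceiling(seq_along(foods) / block_size))
  fits <- list(); pseudo <- NULL
  for (bi in seq_along(blocks)) {
    bvars <- blocks[[bi]]
    args <- utils::modifyList(
      list(episodic_vars = intersect(bvars, episodic_vars),
           daily_vars = c(setdiff(bvars, episodic_vars), "energy", "cost")),
      spec_options)
    spec <- do.call(me_spec, args)
    fit <- fit_me_model(wide, cohort, spec)
    fits[[bi]] <- fit
    pp <- simulate_usual(fit, cohort, seed = seed + bi)
    if (is.null(pseudo)) {
      pseudo <- pp
    } else {
      key <- paste(pp$participant_id, pp$pseudo_index)
      key0 <- paste(pseudo$participant_id, pseudo$pseudo_index)
      for (v in bvars) pseudo[[v]] <- pp[[v]][match(key0, key)]
    }
  }
  list(pseudo = pseudo, fits = fits)
}
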