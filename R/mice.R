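# Chained-equations multiple imputation for measurement error. Non-validated
# respondents' measured variables are treated as missing data and multiply
# imputed from the self-reports and covariates; covariate item nonresponse is
# imputed in the same chained process. Imputers: predictive mean matching
# with Bayesian linear draws, Bayesian-draw logistic regression, score-scale
# PMM for categorical covariates, and random-forest terminal-node donor
# draws. All imputers draw from the active RNG stream so a chain is fully
# reproducible from its seed.

mime_measured_vars <- function() {
  c("meas_height", "meas_weight", "meas_hypertension",
    "meas_hypercholesterolemia")
}

default_predictors <- function(data, var) {
  base <- intersect(c("age", "sex", "education", "household_size", "province"),
                    names(data))
  if ("wave_year" %in% names(data) && length(unique(data$wave_year)) > 1) {
    base <- c(base, "wave_year")
  }
  sr <- switch(var,
    meas_height = "sr_height",
    meas_weight = "sr_weight",
    meas_hypertension = "sr_hypertension",
    meas_hypercholesterolemia = "sr_hypercholesterolemia",
    NULL)
  # chained-equations principle: condition on all other variables, so the
  # other measured variables enter too (keeps the joint distribution of
  # height and weight, hence BMI, coherent)
  other_meas <- intersect(setdiff(mime_measured_vars(), var), names(data))
  preds <- c(sr, other_meas, setdiff(base, var))
  setdiff(preds, var)
}

default_method <- function(data, var, engine) {
  if (engine == "rf") return("rf")
  y <- data[[var]]
  if (is.factor(y) || is.character(y)) return("cat_pmm")
  vals <- unique(na.omit(y))
  if (all(vals %in% c(0, 1)) && length(vals) <= 2) return("logistic")
  "pmm"
}

#' Specify a chained-equations imputation run
#'
#' Builds the per-variable imputation plan: which variables to impute, with
#' which method (`"pmm"`, `"logistic"`, `"cat_pmm"` or `"rf"`) and which
#' predictors, plus the engine settings. By default the four measured
#' variables (height, weight, hypertension, hypercholesterolemia) are imputed
#' from the self-report of the same condition plus age, sex, education,
#' household size and province (and wave year when several waves are
#' present), and any covariate with item nonresponse is imputed in the same
#' process. The default visit sequence orders variables by ascending
#' missingness (most-missing last).
#'
#' @param data Survey tibble the run will operate on.
#' @param engine `"parametric"` (PMM + logistic) or `"rf"` (random forest
#'   for every variable).
#' @param variables Variables to impute; default: the measured variables
#'   plus covariates containing `NA`.
#' @param predictors Named list overriding the predictor set per variable
#'   (e.g. a wider sensitivity-analysis set).
#' @param method Named character vector overriding the method per variable.
#' @param m Number of completed datasets.
#' @param n_iterations Chained-equation sweeps per imputation.
#' @param n_trees Trees per random forest.
#' @param pmm_donors Donor-pool size for predictive mean matching.
#' @param visit_sequence Ordered variable list; `NULL` for the default.
#' @param seed Master seed; per-imputation sub-streams are derived from it.
#' @return An object of class `imputation_spec`.
#' @export
imputation_spec <- function(data, engine = c("parametric", "rf"),
                            variables = NULL, predictors = list(),
                            method = character(0), m = 10,
                            n_iterations = 100, n_trees = 100,
                            pmm_donors = 5, visit_sequence = NULL,
                            seed = 1L) {
  engine <- match.arg(engine)
  if (m < 2) abort("m must be >= 2", class = "surveymime_config_error")
  if (n_iterations < 1) abort("n_iterations must be >= 1",
                              class = "surveymime_config_error")
  if (n_trees < 1) abort("n_trees must be >= 1",
                         class = "surveymime_config_error")
  if (pmm_donors < 1) abort("pmm_donors must be >= 1",
                            class = "surveymime_config_error")
  if (is.null(variables)) {
    covs <- c("age", "sex", "education", "household_size", "province")
    variables <- c(intersect(mime_measured_vars(), names(data)),
                   covs[covs %in% names(data) &
                          vapply(covs, function(v) anyNA(data[[v]]), logical(1))])
  }
  plan <- list()
  for (v in variables) {
    if (!v %in% names(data)) {
      abort(paste("variable not in data:", v),
            class = "surveymime_config_error")
    }
    if (all(is.na(data[[v]]))) {
      abort(paste("variable has no observed values:", v),
            class = "surveymime_config_error")
    }
    preds <- predictors[[v]] %||% default_predictors(data, v)
    missing_preds <- setdiff(preds, names(data))
    if (length(missing_preds)) {
      abort(paste("predictors not in data:",
                  paste(missing_preds, collapse = ", ")),
            class = "surveymime_config_error")
    }
    # a predictor with missing cells is only usable if it is itself imputed
    usable <- vapply(preds, function(p) {
      !anyNA(data[[p]]) || p %in% variables
    }, logical(1))
    preds <- preds[usable]
    mth <- if (v %in% names(method)) method[[v]] else
      default_method(data, v, engine)
    plan[[v]] <- list(method = mth, predictors = preds)
  }
  if (is.null(visit_sequence)) {
    miss_frac <- vapply(names(plan),
                        function(v) mean(is.na(data[[v]])), numeric(1))
    visit_sequence <- names(sort(miss_frac))
  }
  structure(list(plan = plan, engine = engine, m = as.integer(m),
                 n_iterations = as.integer(n_iterations),
                 n_trees = as.integer(n_trees),
                 pmm_donors = as.integer(pmm_donors),
                 visit_sequence = visit_sequence,
                 seed = as.integer(seed)),
            class = "imputation_spec")
}

# ---- low-level imputers (draw from the active RNG stream) ------------------

check_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(paste("singular design matrix; collinear columns:",
                paste(bad, collapse = ", ")),
          class = "surveymime_fit_error")
  }
  invisible(TRUE)
}

# Bayesian linear regression draw (normal approximation with a small ridge)
bayes_lm_draw <- function(y, X, ridge = 1e-5) {
  p <- ncol(X)
  xtx <- crossprod(X)
  pen <- diag(pmax(diag(xtx), 1) * ridge, p)
  xtx_r <- xtx + pen
  beta_hat <- solve(xtx_r, crossprod(X, y))
  resid <- y - drop(X %*% beta_hat)
  df <- max(length(y) - p, 1)
  sigma2 <- sum(resid^2) / stats::rchisq(1, df)
  v <- sigma2 * solve(xtx_r)
  beta_star <- beta_hat + drop(rnorm(p) %*% chol((v + t(v)) / 2))
  list(beta_hat = drop(beta_hat), beta_star = drop(beta_star),
       sigma = sqrt(sigma2))
}

# For each target predicted mean, draw uniformly among its k nearest observed
# rows by predicted mean. The k-nearest set of a target inserted at position
# p of the sorted observed predictions lies within the 2k-wide window
# [p - k + 1, p + k], so candidate search is restricted to that window and
# the k smallest distances are extracted with vectorized max.col passes.
# Ties are broken by sort position.
match_donors <- function(yhat_obs, yhat_mis, y_obs, donors) {
  n <- length(y_obs)
  m <- length(yhat_mis)
  if (!m) return(y_obs[integer(0)])
  k <- min(donors, n)
  ord <- order(yhat_obs)
  ys <- yhat_obs[ord]
  yo <- y_obs[ord]
  win <- min(2L * k, n)
  lo <- pmin(pmax(findInterval(yhat_mis, ys) - k + 1L, 1L), n - win + 1L)
  idx <- outer(lo, 0:(win - 1L), "+")
  dist <- abs(matrix(ys[idx], m) - yhat_mis)
  rows <- seq_len(m)
  chosen <- matrix(0L, m, k)
  for (s in seq_len(k)) {
    j <- max.col(-dist, ties.method = "first")
    chosen[, s] <- idx[cbind(rows, j)]
    dist[cbind(rows, j)] <- Inf
  }
  pick <- if (k == 1) rep(1L, m) else sample.int(k, m, replace = TRUE)
  yo[chosen[cbind(rows, pick)]]
}

#' Predictive mean matching imputation
#'
#' Draws regression coefficients from the approximate posterior of a
#' Bayesian linear regression of `y_obs` on `X_obs`, computes predicted
#' means for the observed rows (posterior-mean coefficients) and for the
#' missing rows (drawn coefficients), and imputes each missing row with the
#' observed `y` of one of its `donors` closest observed rows by predicted
#' mean (uniform draw, random tie-break). Every imputed value is therefore a
#' member of the observed-value set.
#'
#' @param y_obs Observed outcome values.
#' @param X_obs,X_mis Numeric design matrices (including the intercept) for
#'   observed and missing rows.
#' @param donors Donor-pool size.
#' @return Imputed values, one per row of `X_mis`.
#' @export
impute_pmm <- function(y_obs, X_obs, X_mis, donors = 5) {
  if (length(y_obs) <= ncol(X_obs)) {
    abort("need more observed rows than predictors",
          class = "surveymime_input_error")
  }
  check_rank(X_obs)
  if (length(unique(y_obs)) == 1) {
    return(rep(y_obs[1], nrow(X_mis)))
  }
  draw <- bayes_lm_draw(y_obs, X_obs)
  yhat_obs <- drop(X_obs %*% draw$beta_hat)
  yhat_mis <- drop(X_mis %*% draw$beta_star)
  match_donors(yhat_obs, yhat_mis, y_obs, donors)
}

# penalized IRLS for a weakly-informative normal prior on the coefficients
# (prior sd `prior_sd` per standardized predictor, 10 on the intercept);
# returns the posterior mode and its Gaussian-approximation covariance.
ridge_logistic <- function(X, y, prior_sd = 2.5, max_iter = 30) {
  p <- ncol(X)
  s <- apply(X, 2, sd)
  is_intercept <- s == 0
  lam <- ifelse(is_intercept, 1 / 100, s^2 / prior_sd^2)
  Lam <- diag(lam, p)
  beta <- rep(0, p)
  A <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X, X * w) + Lam
    beta_new <- drop(solve(A, crossprod(X, w * z)))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < 1e-8) break
  }
  list(beta = beta, vcov = solve(A))
}

#' Bayesian-draw logistic imputation of a binary variable
#'
#' Fits a logistic regression of `y_obs` on `X_obs`, draws coefficients from
#' the normal approximation of their posterior, and imputes missing rows as
#' Bernoulli draws of the drawn-coefficient probabilities. The fit carries a
#' weakly informative normal prior (SD 2.5 per standardized coefficient),
#' which leaves ordinary fits essentially untouched but keeps the posterior
#' draw proper under (quasi-)separation — e.g. a perfectly informative
#' self-report. When `y_obs` contains a single class the model is
#' degenerate; imputation falls back to draws of the shrunken observed
#' prevalence `(sum(y) + 0.5) / (n + 1)` with a warning.
#'
#' @inheritParams impute_pmm
#' @return Integer 0/1 imputations, one per row of `X_mis`.
#' @export
impute_logistic <- function(y_obs, X_obs, X_mis) {
  n <- length(y_obs)
  if (length(unique(y_obs)) < 2) {
    warn("single-class outcome; falling back to prevalence draws")
    p <- (sum(y_obs) + 0.5) / (n + 1)
    return(rbinom(nrow(X_mis), 1, p))
  }
  fit <- ridge_logistic(X_obs, y_obs)
  mu_obs <- plogis(drop(X_obs %*% fit$beta))
  if (all(abs(y_obs - mu_obs) < 0.05)) {
    # the observed relationship is (near-)deterministic: the Gaussian
    # posterior approximation is unusable under complete separation, and a
    # donor draw on the fitted score reproduces the deterministic mapping
    mu_mis <- plogis(drop(X_mis %*% fit$beta))
    return(as.integer(match_donors(mu_obs, mu_mis, y_obs, 5L)))
  }
  vc <- (fit$vcov + t(fit$vcov)) / 2
  ch <- tryCatch(chol(vc + diag(1e-10, nrow(vc))), error = function(e) NULL)
  beta_star <- fit$beta
  if (!is.null(ch)) {
    beta_star <- fit$beta + drop(rnorm(length(fit$beta)) %*% ch)
  }
  p_mis <- plogis(drop(X_mis %*% beta_star))
  rbinom(nrow(X_mis), 1, p_mis)
}

# score-scale PMM for categorical variables: Bayesian linear regression on
# the integer level codes, donor matching on the predicted score, imputation
# by the donor's observed level
impute_cat_pmm <- function(y_obs, X_obs, X_mis, donors = 5) {
  lev <- levels(factor(y_obs))
  codes <- as.integer(factor(y_obs, levels = lev))
  if (length(lev) == 1) return(factor(rep(lev, nrow(X_mis)), levels = lev))
  draw <- bayes_lm_draw(codes, X_obs)
  yhat_obs <- drop(X_obs %*% draw$beta_hat)
  yhat_mis <- drop(X_mis %*% draw$beta_star)
  imp <- match_donors(yhat_obs, yhat_mis, codes, donors)
  factor(lev[imp], levels = lev)
}

#' Random-forest donor imputation
#'
#' Fits `n_trees` trees on bootstrap resamples of the observed rows (via
#' ranger), then for each missing row picks one tree at random, drops the
#' row to its terminal node, and imputes a uniform draw among the observed
#' outcomes landing in that node — a donor-based draw that preserves
#' imputation variability and keeps continuous imputations inside the
#' observed-value set. Binary/categorical outcomes use classification trees.
#' A degenerate single-node tree reduces the draw to a bootstrap draw from
#' the observed outcomes.
#'
#' With `abb = TRUE` (the default inside the chained engine) the whole
#' donor pool is first resampled with replacement — an approximate Bayesian
#' bootstrap — before the forest is grown, so that repeated imputations also
#' reflect the sampling uncertainty of the observed pool; without it,
#' forest imputations share almost no between-imputation parameter
#' uncertainty and Rubin's between-variance is understated.
#'
#' @param y_obs Observed outcome (numeric, 0/1 or factor).
#' @param X_obs,X_mis Data frames of predictor columns for observed and
#'   missing rows (factors allowed; no dummy coding needed).
#' @param n_trees Number of trees.
#' @param abb Resample the donor pool (approximate Bayesian bootstrap)
#'   before fitting.
#' @return Imputed values, one per row of `X_mis`, of the same type as
#'   `y_obs`.
#' @export
impute_rf <- function(y_obs, X_obs, X_mis, n_trees = 100, abb = TRUE) {
  if (nrow(X_obs) < 2) abort("need at least 2 observed rows",
                             class = "surveymime_input_error")
  if (length(unique(y_obs)) == 1) {
    return(rep(y_obs[1], nrow(X_mis)))
  }
  if (abb) {
    boot <- sample.int(length(y_obs), replace = TRUE)
    y_obs <- y_obs[boot]
    X_obs <- X_obs[boot, , drop = FALSE]
    if (length(unique(y_obs)) == 1) {
      return(rep(y_obs[1], nrow(X_mis)))
    }
  }
  binary <- all(y_obs %in% c(0, 1)) && !is.factor(y_obs)
  y_fit <- if (binary || is.character(y_obs)) factor(y_obs) else y_obs
  df_obs <- data.frame(.y = y_fit, X_obs, check.names = TRUE)
  rf_seed <- sample.int(.Machine$integer.max - 1L, 1)
  # under ABB the donor pool itself is the bootstrap resample, so trees are
  # grown on it directly (diversity comes from mtry/split randomization);
  # without ABB each tree bags its own resample
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df_obs,
    num.trees = n_trees, num.threads = 1, seed = rf_seed,
    replace = !abb, sample.fraction = 1,
    respect.unordered.factors = "order",
    min.node.size = if (is.factor(y_fit)) 1 else 5)
  n_obs <- nrow(X_obs)
  n_mis <- nrow(X_mis)
  both <- rbind(data.frame(X_obs, check.names = TRUE),
                data.frame(X_mis, check.names = TRUE))
  nodes <- predict(fit, both, type = "terminalNodes",
                   num.threads = 1)$predictions
  nodes_obs <- nodes[seq_len(n_obs), , drop = FALSE]
  nodes_mis <- nodes[n_obs + seq_len(n_mis), , drop = FALSE]
  tree_pick <- sample.int(n_trees, n_mis, replace = TRUE)
  donor <- integer(n_mis)
  fast_split <- function(x, ids) {
    u <- unique(ids)
    split(x, structure(match(ids, u), levels = as.character(u),
                       class = "factor"))
  }
  for (t in unique(tree_pick)) {
    rows <- which(tree_pick == t)
    pools <- fast_split(seq_len(n_obs), nodes_obs[, t])
    groups <- fast_split(rows, nodes_mis[rows, t])
    for (nd in names(groups)) {
      pool <- pools[[nd]]
      # degenerate/unpopulated node: fall back to a bootstrap draw
      if (is.null(pool)) pool <- seq_len(n_obs)
      g <- groups[[nd]]
      donor[g] <- pool[sample.int(length(pool), length(g), replace = TRUE)]
    }
  }
  out <- y_obs[donor]
  if (binary) out <- as.integer(out)
  out
}

# ---- the chained engine ----------------------------------------------------

# draw initial fills for the missing cells of one chain from the observed
# values of each variable (chain RNG stream must already be seeded)
fill_initial <- function(data, plan, miss_idx) {
  for (v in names(plan)) {
    mis <- miss_idx[[v]]
    if (!length(mis)) next
    obs_vals <- data[[v]][!is.na(data[[v]])]
    data[[v]][mis] <- sample(obs_vals, length(mis), replace = TRUE)
  }
  data
}

#' Initialize the imputation chains
#'
#' Returns the `m` starting states of a chained run: each missing cell filled
#' by a random draw from the variable's observed values, using independent
#' per-imputation sub-streams derived from the master seed (so the initial
#' states match those used by [run_chained()] with the same spec).
#'
#' @param data Survey tibble.
#' @param spec An [imputation_spec()].
#' @return List of `m` completed starting tibbles.
#' @export
initialize_chains <- function(data, spec) {
  miss_idx <- lapply(names(spec$plan), function(v) which(is.na(data[[v]])))
  names(miss_idx) <- names(spec$plan)
  chain_seeds <- derive_seeds(spec$seed, spec$m)
  lapply(seq_len(spec$m), function(c) {
    set.seed(chain_seeds[c])
    fill_initial(data, spec$plan, miss_idx)
  })
}

# model matrix for one variable update: intercept + predictors, zero-variance
# columns (empty factor levels among observed rows) dropped
build_design <- function(state, preds, obs_rows) {
  frame <- state[, preds, drop = FALSE]
  for (v in preds) {
    if (is.character(frame[[v]])) frame[[v]] <- factor(frame[[v]])
  }
  mm <- model.matrix(~ ., data = frame)
  keep <- c(TRUE, apply(mm[obs_rows, -1, drop = FALSE], 2,
                        function(col) var(col) > 0))
  mm[, keep, drop = FALSE]
}

# Pre-split design for variables whose predictors carry no missing cells:
# their design matrix is identical across iterations and chains.
static_design <- function(data, plan, miss_idx) {
  out <- list()
  for (v in names(plan)) {
    preds <- plan[[v]]$predictors
    if (any(vapply(preds, function(p) anyNA(data[[p]]), logical(1)))) next
    mis <- miss_idx[[v]]
    obs <- setdiff(seq_len(nrow(data)), mis)
    if (plan[[v]]$method == "rf") {
      X <- data[, preds, drop = FALSE]
      out[[v]] <- list(X_obs = X[obs, , drop = FALSE],
                       X_mis = X[mis, , drop = FALSE])
    } else {
      mm <- build_design(data, preds, obs)
      out[[v]] <- list(X_obs = mm[obs, , drop = FALSE],
                       X_mis = mm[mis, , drop = FALSE])
    }
  }
  out
}

update_variable <- function(state, v, vplan, mis, spec, cached = NULL) {
  obs <- setdiff(seq_len(nrow(state)), mis)
  y_obs <- state[[v]][obs]
  if (vplan$method == "rf") {
    if (is.null(cached)) {
      X <- state[, vplan$predictors, drop = FALSE]
      cached <- list(X_obs = X[obs, , drop = FALSE],
                     X_mis = X[mis, , drop = FALSE])
    }
    imp <- impute_rf(y_obs, cached$X_obs, cached$X_mis,
                     n_trees = spec$n_trees)
  } else {
    if (is.null(cached)) {
      mm <- build_design(state, vplan$predictors, obs)
      cached <- list(X_obs = mm[obs, , drop = FALSE],
                     X_mis = mm[mis, , drop = FALSE])
    }
    imp <- switch(vplan$method,
      pmm = impute_pmm(y_obs, cached$X_obs, cached$X_mis,
                       donors = spec$pmm_donors),
      logistic = impute_logistic(y_obs, cached$X_obs, cached$X_mis),
      cat_pmm = impute_cat_pmm(y_obs, cached$X_obs, cached$X_mis,
                               donors = spec$pmm_donors),
      abort(paste("unknown method:", vplan$method),
            class = "surveymime_config_error"))
  }
  state[[v]][mis] <- imp
  state
}

trace_stats <- function(vals) {
  num <- if (is.factor(vals)) as.numeric(vals) else as.numeric(vals)
  c(mean = mean(num), sd = if (length(num) > 1) sd(num) else 0)
}

derive_passive <- function(state) {
  if (all(c("meas_height", "meas_weight") %in% names(state))) {
    state <- add_bmi_indicators(state, "meas_height", "meas_weight")
  }
  if ("meas_hypertension" %in% names(state)) {
    state$hypertension <- state$meas_hypertension
  }
  if ("meas_hypercholesterolemia" %in% names(state)) {
    state$hypercholesterolemia <- state$meas_hypercholesterolemia
  }
  state
}

#' Run the chained-equations imputation engine
#'
#' For each of `m` imputations, fills the missing cells with draws from the
#' observed values and then performs `n_iterations` sweeps through the visit
#' sequence, updating each variable from a model fitted on its currently
#' completed predictors. BMI and the overweight/obesity flags are derived
#' passively from the completed height and weight after every sweep — never
#' imputed directly — and observed cells are never overwritten. A trace of
#' the mean and SD of the imputed values per (imputation, iteration,
#' variable) supports convergence assessment via [convergence_summary()].
#'
#' @param data Survey tibble (measured variables `NA` outside the validation
#'   subsample).
#' @param spec An [imputation_spec()].
#' @return An object of class `completed_set`: list with `imputations` (m
#'   completed tibbles, each carrying derived `bmi`, `overweight`, `obesity`,
#'   `hypertension`, `hypercholesterolemia` columns), `trace` (long tibble),
#'   `spec`, and `miss_idx`.
#' @export
run_chained <- function(data, spec) {
  if (!inherits(spec, "imputation_spec")) {
    abort("spec must be an imputation_spec", class = "surveymime_config_error")
  }
  plan <- spec$plan
  miss_idx <- lapply(names(plan), function(v) which(is.na(data[[v]])))
  names(miss_idx) <- names(plan)
  active <- names(plan)[vapply(miss_idx, length, integer(1)) > 0]
  cache <- static_design(data, plan[active], miss_idx)
  chain_seeds <- derive_seeds(spec$seed, spec$m)

  trace <- vector("list", spec$m)
  imputations <- vector("list", spec$m)
  for (c in seq_len(spec$m)) {
    set.seed(chain_seeds[c])
    state <- fill_initial(data, plan, miss_idx)
    rows <- vector("list", spec$n_iterations * max(length(active), 1))
    r <- 0
    for (it in seq_len(spec$n_iterations)) {
      for (v in intersect(spec$visit_sequence, active)) {
        state <- update_variable(state, v, plan[[v]], miss_idx[[v]], spec,
                                 cached = cache[[v]])
        st <- trace_stats(state[[v]][miss_idx[[v]]])
        if (!is.finite(st["mean"])) {
          abort(paste0("divergent imputation for ", v, " (chain ", c,
                       ", iteration ", it, "); trace:\n",
                       paste(utils::capture.output(print(
                         dplyr::bind_rows(rows[seq_len(r)]))), collapse = "\n")),
                class = "surveymime_numeric_error")
        }
        r <- r + 1
        rows[[r]] <- tibble::tibble(imputation = c, iteration = it,
                                    variable = v, mean = st[["mean"]],
                                    sd = st[["sd"]])
      }
      state <- derive_passive(state)
    }
    trace[[c]] <- dplyr::bind_rows(rows[seq_len(r)])
    imputations[[c]] <- derive_passive(state)
  }
  structure(list(imputations = imputations,
                 trace = dplyr::bind_rows(trace),
                 spec = spec, miss_idx = miss_idx),
            class = "completed_set")
}

#' @export
print.completed_set <- function(x, ...) {
  cat("<completed_set> m =", length(x$imputations),
      "| iterations =", x$spec$n_iterations,
      "| engine =", x$spec$engine, "\n")
  cat("  imputed variables:",
      paste(names(x$miss_idx)[vapply(x$miss_idx, length, integer(1)) > 0],
            collapse = ", "), "\n")
  invisible(x)
}

#' Between/within-chain stability of the imputation traces
#'
#' Over the final `window` iterations, compares the spread of the chain-level
#' mean imputed values *between* chains with the iteration-to-iteration
#' spread *within* chains. For each variable the ratio
#' `B / (W / window)` (between-chain variance of the window means over the
#' sampling variance a stationary chain would imply) is reported and flagged
#' when it exceeds `threshold` — stationary, well-mixed chains give values
#' around 1.
#'
#' @param trace Trace tibble from [run_chained()] (or a `completed_set`).
#' @param window Number of final iterations to use.
#' @param threshold Flag level for the stability ratio.
#' @return Tibble: `variable`, `between_var`, `within_var`, `ratio`, `flag`.
#' @export
convergence_summary <- function(trace, window = 5, threshold = 5) {
  if (inherits(trace, "completed_set")) trace <- trace$trace
  n_it <- max(trace$iteration)
  if (n_it < 2) abort("need at least 2 logged iterations",
                      class = "surveymime_input_error")
  if (window > n_it) abort("window longer than the chain",
                           class = "surveymime_input_error")
  last <- dplyr::filter(trace, .data$iteration > n_it - window)
  out <- lapply(unique(last$variable), function(v) {
    tv <- dplyr::filter(last, .data$variable == v)
    chain_means <- tapply(tv$mean, tv$imputation, mean)
    within <- mean(tapply(tv$mean, tv$imputation, var), na.rm = TRUE)
    between <- var(as.numeric(chain_means))
    ratio <- if (is.na(within) || within == 0) {
      if (is.na(between) || between == 0) 0 else Inf
    } else {
      between / (within / window)
    }
    tibble::tibble(variable = v, between_var = between, within_var = within,
                   ratio = ratio, flag = ratio > threshold)
  })
  dplyr::bind_rows(out)
}
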