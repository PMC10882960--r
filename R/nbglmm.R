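#' Specification of the introduction-count model
#'
#' Fixed effects are drawn from the four panel covariates; the intercept is
#' always included and the random-effect structure (independent random
#' intercepts for importer-within-period and exporter-within-period) is fixed
#' across candidate models. Transforms follow the count model: cumulative
#' trade enters as z-scored `log1p(TR)`, species counts as plain logs, and
#' distance untransformed (per km), so the trade coefficient is per standard
#' deviation of log trade while the distance coefficient keeps physical units.
#'
#' @param fixed_effects Character subset of `c("log_tr", "distance",
#'   "log_s_e", "log_s_i")`.
#' @param scale_vars Which covariates are z-scored after their transform.
#' @param random_effects Random-intercept factors to include; the default is
#'   the full structure. `character(0)` drops the random effects entirely
#'   (equivalent to fixing their variances at zero), reducing the model to a
#'   plain negative-binomial GLM.
#' @return An object of class `invacf_model_spec`.
#' @export
model_spec <- function(fixed_effects = c("log_tr", "distance",
                                         "log_s_e", "log_s_i"),
                       scale_vars = "log_tr",
                       random_effects = c("importer_period",
                                          "exporter_period")) {
  all_vars <- c("log_tr", "distance", "log_s_e", "log_s_i")
  bad <- setdiff(fixed_effects, all_vars)
  if (length(bad)) {
    abort(sprintf("Unknown fixed effect(s): %s", paste(bad, collapse = ", ")))
  }
  bad_re <- setdiff(random_effects, c("importer_period", "exporter_period"))
  if (length(bad_re)) {
    abort(sprintf("Unknown random-effect factor(s): %s",
                  paste(bad_re, collapse = ", ")))
  }
  structure(
    list(fixed_effects = intersect(all_vars, fixed_effects),
         scale_vars = intersect(all_vars, scale_vars),
         random_effects = random_effects),
    class = "invacf_model_spec"
  )
}

# transformed (pre-scaling) covariates from a panel
panel_transform <- function(panel) {
  assert_columns(panel, c("TR", "D", "S_e", "S_i"), "`panel`")
  if (any(panel$S_e < 1) || any(panel$S_i < 1)) {
    abort("`S_e` and `S_i` must be >= 1 for the log transform.")
  }
  assert_nonneg(panel$TR, "`TR`")
  tibble::tibble(
    log_tr = log1p(panel$TR),
    distance = panel$D,
    log_s_e = log(panel$S_e),
    log_s_i = log(panel$S_i)
  )
}

# design columns after applying (or computing) scaling constants
panel_design <- function(panel, spec, scaling = NULL) {
  raw <- panel_transform(panel)
  vars <- spec$fixed_effects
  if (is.null(scaling)) {
    scaling <- purrr::map(setNames(vars, vars), function(v) {
      if (v %in% spec$scale_vars) {
        c(mean = mean(raw[[v]]), sd = sd(raw[[v]]))
      } else {
        c(mean = 0, sd = 1)
      }
    })
  }
  for (v in vars) {
    s <- scaling[[v]]
    if (is.null(s)) abort(sprintf("`scaling` lacks an entry for '%s'.", v))
    if (!is.finite(s[["sd"]]) || s[["sd"]] <= 0) {
      abort(sprintf("Scaling sd for '%s' must be positive.", v))
    }
    raw[[v]] <- (raw[[v]] - s[["mean"]]) / s[["sd"]]
  }
  list(design = raw[vars], scaling = scaling)
}

#' Spearman collinearity screen of panel covariates
#'
#' Rank correlations between all pairs of (transformed) covariates; the screen
#' fails when any absolute correlation reaches the threshold.
#'
#' @param panel Panel tibble with columns `TR, D, S_e, S_i` (at least 3 rows).
#' @param vars Covariates to screen (transformed names).
#' @param threshold Failure threshold on `|rho|` (default 0.5).
#' @return List with `matrix` (Spearman correlations; `NA` for constant
#'   variables), `pairs` (tibble of pairwise values), and `pass`.
#' @export
spearman_screen <- function(panel, vars = c("log_tr", "distance",
                                            "log_s_e", "log_s_i"),
                            threshold = 0.5) {
  if (nrow(panel) < 3) abort("Need at least 3 rows for the Spearman screen.")
  x <- panel_transform(panel)[vars]
  constant <- purrr::map_lgl(x, ~ length(unique(.x)) == 1L)
  m <- suppressWarnings(cor(as.matrix(x), method = "spearman"))
  m[constant, ] <- NA_real_
  m[, constant] <- NA_real_
  diag(m) <- 1
  combos <- utils::combn(vars, 2)
  pairs <- tibble::tibble(
    var1 = combos[1, ], var2 = combos[2, ],
    rho = m[cbind(combos[1, ], combos[2, ])]
  )
  list(matrix = m, pairs = pairs,
       pass = all(is.na(pairs$rho) | abs(pairs$rho) < threshold))
}

#' Fit the negative-binomial mixed model for introduction counts
#'
#' Fits `AS ~ covariates + (1 | importer:period) + (1 | exporter:period)` with
#' a negative-binomial response and log link by maximising the
#' Laplace-approximated marginal likelihood (via \pkg{glmmTMB}). The linear
#' predictor uses the transforms of [model_spec()]; the scaling constants
#' actually applied are stored on the fit and reused at prediction time.
#'
#' @param panel Panel tibble (`exporter, importer, decade_end, TR, D, S_e,
#'   S_i, AS`).
#' @param spec A [model_spec()].
#' @param scaling Optional named list of `c(mean, sd)` per covariate; when
#'   `NULL`, constants are computed from `panel` for the variables named in
#'   `spec$scale_vars`.
#' @return An object of class `invacf_glmm`: coefficients with standard
#'   errors, dispersion `theta`, random-effect variances, log-likelihood,
#'   `aicc` (with `k` counting fixed effects, intercept excluded from... see
#'   Details), sample size, scaling, convergence flag and the underlying
#'   model object.
#' @details The AICc penalty counts `k` = number of fixed effects (including
#'   the intercept) + 1 dispersion + one variance per random-effect factor:
#'   `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`. Non-convergence is never
#'   silent: the fit is returned with `convergence = FALSE` and a message.
#' @export
fit_nb_glmm <- function(panel, spec = model_spec(), scaling = NULL) {
  stopifnot(inherits(spec, "invacf_model_spec"))
  assert_columns(panel, c("exporter", "importer", "decade_end", "AS"),
                 "`panel`")
  if (any(!is.finite(panel$AS)) || any(panel$AS < 0)) {
    abort("`AS` must be non-negative counts without missing values.")
  }
  des <- panel_design(panel, spec, scaling)
  dat <- dplyr::bind_cols(
    tibble::tibble(
      AS = panel$AS,
      importer_period = factor(paste(panel$importer, panel$decade_end,
                                     sep = ":")),
      exporter_period = factor(paste(panel$exporter, panel$decade_end,
                                     sep = ":"))
    ),
    des$design
  )
  if (anyNA(dat)) abort("Missing values in model variables.")
  rhs <- paste(c("1", spec$fixed_effects,
                 sprintf("(1 | %s)", spec$random_effects)),
               collapse = " + ")
  form <- stats::as.formula(paste("AS ~", rhs))
  model <- glmmTMB::glmmTMB(form, data = dat, family = glmmTMB::nbinom2())
  converged <- isTRUE(model$fit$convergence == 0) &&
    isTRUE(model$sdr$pdHess)
  if (!converged) {
    inform("Mixed-model fit did not converge cleanly; inspect diagnostics.")
  }
  beta_hat <- glmmTMB::fixef(model)$cond
  se <- tryCatch(sqrt(diag(stats::vcov(model)$cond)),
                 error = function(e) rep(NA_real_, length(beta_hat)))
  vc <- glmmTMB::VarCorr(model)$cond
  re_var <- purrr::map_dbl(vc, ~ attr(.x, "stddev")[[1]]^2)
  boundary <- any(re_var < 1e-8)
  ll <- as.numeric(stats::logLik(model))
  n <- nrow(dat)
  k <- length(beta_hat) + 1L + length(re_var)
  aicc <- aicc_value(ll, k, n)
  structure(
    list(
      spec = spec,
      beta = tibble::tibble(
        term = names(beta_hat),
        estimate = unname(beta_hat),
        std_error = unname(se)
      ),
      theta = glmmTMB::sigma(model),
      re_variances = re_var,
      loglik = ll, aicc = aicc, n_obs = n, k = k,
      scaling = des$scaling,
      convergence = converged, boundary = boundary,
      model = model
    ),
    class = "invacf_glmm"
  )
}

#' Small-sample Akaike information criterion
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return `-2 loglik + 2k + 2k(k+1)/(n-k-1)`; `NA` when `n <= k + 1`.
#' @examples
#' aicc_value(-100, 5, 50)
#' @export
aicc_value <- function(loglik, k, n) {
  if (n <= k + 1) return(NA_real_)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit and rank candidate fixed-effect sets by AICc
#'
#' @param panel Panel tibble.
#' @param candidates List of [model_spec()] objects; by default all subsets of
#'   the four covariates (random-effect structure fixed).
#' @return Tibble ranked by ascending AICc (ties broken by fewer parameters):
#'   `rank, fixed_effects, k, loglik, aicc, converged, fit`. Candidates whose
#'   AICc is undefined (`n <= k + 1`) are excluded with a note.
#' @export
select_model <- function(panel, candidates = NULL) {
  if (is.null(candidates)) {
    vars <- c("log_tr", "distance", "log_s_e", "log_s_i")
    subsets <- unlist(
      lapply(0:4, function(m) utils::combn(vars, m, simplify = FALSE)),
      recursive = FALSE
    )
    candidates <- purrr::map(subsets, model_spec)
  }
  if (!length(candidates)) abort("Need at least one candidate model.")
  fits <- purrr::map(candidates, ~ fit_nb_glmm(panel, .x))
  tab <- tibble::tibble(
    fixed_effects = purrr::map_chr(fits, function(f) {
      s <- paste(f$spec$fixed_effects, collapse = "+")
      if (s == "") "(intercept only)" else s
    }),
    k = purrr::map_int(fits, "k"),
    loglik = purrr::map_dbl(fits, "loglik"),
    aicc = purrr::map_dbl(fits, "aicc"),
    converged = purrr::map_lgl(fits, "convergence"),
    fit = fits
  )
  dropped <- is.na(tab$aicc)
  if (any(dropped)) {
    inform(sprintf(
      "Excluded %d candidate(s) with undefined AICc (n <= k + 1).",
      sum(dropped)
    ))
    tab <- tab[!dropped, ]
  }
  tab <- tab[order(tab$aicc, tab$k), ]
  tab$rank <- seq_len(nrow(tab))
  dplyr::select(tab, "rank", dplyr::everything())
}

#' Expected introduction count for given covariates
#'
#' Evaluates the fitted model mean `exp(eta)` at new covariate values, after
#' applying the scaling stored in the fit. Population mode sets the random
#' effects to zero, so predictions generalise beyond the training levels;
#' conditional mode adds the estimated random-intercept modes of the levels
#' named in `newdata`'s `importer_period` / `exporter_period` columns.
#'
#' @param fit An `invacf_glmm`.
#' @param newdata Tibble with columns `TR, D, S_e, S_i` (and the two period
#'   factors in conditional mode).
#' @param mode `"population"` or `"conditional"`.
#' @return Numeric vector of expected counts.
#' @export
predict_mean <- function(fit, newdata, mode = c("population", "conditional")) {
  stopifnot(inherits(fit, "invacf_glmm"))
  mode <- match.arg(mode)
  des <- panel_design(newdata, fit$spec, fit$scaling)$design
  beta <- setNames(fit$beta$estimate, fit$beta$term)
  eta <- rep(beta[["(Intercept)"]], nrow(newdata))
  for (v in fit$spec$fixed_effects) eta <- eta + beta[[v]] * des[[v]]
  if (mode == "conditional") {
    assert_columns(newdata, fit$spec$random_effects,
                   "`newdata` (conditional mode)")
    re <- glmmTMB::ranef(fit$model)$cond
    for (f in fit$spec$random_effects) {
      modes <- setNames(re[[f]][["(Intercept)"]], rownames(re[[f]]))
      lev <- as.character(newdata[[f]])
      unknown <- setdiff(unique(lev), names(modes))
      if (length(unknown)) {
        abort(sprintf("Unknown %s level(s): %s", f,
                      paste(unknown, collapse = ", ")))
      }
      eta <- eta + modes[lev]
    }
  }
  unname(exp(eta))
}

#' Nakagawa-style variance decomposition for the fitted model
#'
#' Latent-scale decomposition for the log-link negative-binomial mixed model:
#' fixed-effect variance is the variance of the linear predictor over the
#' training data, random-effect variance the sum of intercept variances, and
#' the distribution-specific variance uses the log-normal approximation
#' `ln(1 + 1/mu_bar + 1/theta)`.
#'
#' @param fit An `invacf_glmm`.
#' @return List with `marginal`, `conditional` (0 <= marginal <= conditional
#'   <= 1), the variance components, and `boundary` (TRUE when a
#'   random-effect variance collapsed to zero, in which case the
#'   decomposition carries a caveat).
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "invacf_glmm"))
  if (!fit$convergence) {
    warn("Variance decomposition requested for a non-converged fit.")
  }
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(c("1", fit$spec$fixed_effects),
                                       collapse = "+"))),
    data = fit$model$frame
  )
  beta <- setNames(fit$beta$estimate, fit$beta$term)
  eta_fixed <- as.vector(X %*% beta[colnames(X)])
  var_f <- stats::var(eta_fixed)
  var_re <- sum(fit$re_variances)
  mu_bar <- exp(mean(eta_fixed) + 0.5 * var_re)
  var_d <- log1p(1 / mu_bar + 1 / fit$theta)
  tot <- var_f + var_re + var_d
  list(
    marginal = var_f / tot,
    conditional = (var_f + var_re) / tot,
    var_fixed = var_f, var_random = var_re, var_dist = var_d,
    boundary = fit$boundary
  )
}

#' @export
print.invacf_glmm <- function(x, ...) {
  cat(sprintf(
    "<invacf_glmm> NB mixed model, n = %d, theta = %.3f, AICc = %.2f%s\n",
    x$n_obs, x$theta, x$aicc,
    if (x$convergence) "" else " [NOT CONVERGED]"
  ))
  print(x$beta)
  cat(sprintf("random-effect variances: %s\n",
              paste(sprintf("%s = %.4f", names(x$re_variances),
                            x$re_variances), collapse = ", ")))
  invisible(x)
}

#' @rdname fit_nb_glmm
#' @param x An `invacf_glmm` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.invacf_glmm <- function(x, ...) {
  dplyr::mutate(
    x$beta,
    statistic = .data$estimate / .data$std_error,
    p_value = 2 * stats::pnorm(-abs(.data$statistic))
  )
}

#' @rdname fit_nb_glmm
#' @exportS3Method generics::glance
glance.invacf_glmm <- function(x, ...) {
  r2 <- r2_nakagawa(x)
  tibble::tibble(
    n_obs = x$n_obs, theta = x$theta, loglik = x$loglik, aicc = x$aicc,
    r2_marginal = r2$marginal, r2_conditional = r2$conditional,
    converged = x$convergence
  )
}

#' Serialise a fitted model's numbers to JSON
#'
#' Writes coefficients, dispersion, random-effect variances, AICc and scaling
#' constants -- everything needed to reproduce predictions -- to a JSON file.
#'
#' @param fit An `invacf_glmm`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(
      fixed_effects = fit$spec$fixed_effects,
      coefficients = setNames(as.list(fit$beta$estimate), fit$beta$term),
      std_errors = setNames(as.list(fit$beta$std_error), fit$beta$term),
      theta = fit$theta,
      re_variances = as.list(fit$re_variances),
      loglik = fit$loglik, aicc = fit$aicc, n_obs = fit$n_obs,
      scaling = fit$scaling,
      convergence = fit$convergence
    ),
    path, auto_unbox = TRUE, digits = I(17)
  )
  invisible(path)
}
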