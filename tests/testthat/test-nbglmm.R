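# panel with two countries and one decade: two levels per random-effect
# factor, used for the quadrature oracle
tiny_panel <- function(n = 60, seed = 31, theta = 5) {
  set.seed(seed)
  tr <- exp(runif(n, 0, 12))
  z <- (log1p(tr) - mean(log1p(tr))) / sd(log1p(tr))
  flip <- rep(c(TRUE, FALSE), length.out = n)
  u <- rnorm(2, 0, 0.4)
  v <- rnorm(2, 0, 0.4)
  imp <- ifelse(flip, 1L, 2L)
  exp_ <- ifelse(flip, 2L, 1L)
  eta <- 2.5 + 0.5 * z + u[imp] + v[exp_]
  tibble::tibble(
    exporter = c("A", "B")[exp_],
    importer = c("A", "B")[imp],
    decade_end = 1879L,
    TR = tr, D = 1000, S_e = 50L, S_i = 40L,
    AS = rnbinom(n, mu = exp(eta), size = theta)
  )
}

test_that("Spearman screen flags monotone dependence and passes noise", {
  set.seed(4)
  base <- tibble::tibble(
    TR = exp(rnorm(1000, 8, 2)), D = runif(1000, 10, 1e4),
    S_e = 50L, S_i = 40L
  )
  # y = x: perfect rank correlation fails the screen
  p1 <- dplyr::mutate(base, D = TR)
  s1 <- spearman_screen(p1, c("log_tr", "distance"))
  expect_equal(s1$pairs$rho, 1)
  expect_false(s1$pass)
  # y = -x
  p2 <- dplyr::mutate(base, D = max(TR) - TR)
  s2 <- spearman_screen(p2, c("log_tr", "distance"))
  expect_equal(s2$pairs$rho, -1)
  expect_false(s2$pass)
  # independent draws: |rho| < 0.1 with high probability at n = 1000
  s3 <- spearman_screen(base, c("log_tr", "distance"))
  expect_lt(abs(s3$pairs$rho), 0.1)
  expect_true(s3$pass)
  # constant variable reported as NA
  s4 <- spearman_screen(base, c("log_tr", "log_s_e"))
  expect_true(is.na(s4$pairs$rho))
  expect_true(s4$pass)
})

test_that("the AICc penalty follows the small-sample formula", {
  expect_equal(aicc_value(-100, 5, 50), 211.3636, tolerance = 1e-4)
  expect_equal(aicc_value(-100, 5, 50),
               200 + 10 + 2 * 5 * 6 / (50 - 5 - 1))
  expect_true(is.na(aicc_value(-100, 5, 6))) # n <= k + 1
})

test_that("without random effects the fit matches a plain NB GLM oracle", {
  set.seed(11)
  n <- 500
  tr <- exp(runif(n, 0, 14))
  d <- runif(n, 100, 15000)
  s_e <- sample(30:600, n, replace = TRUE)
  s_i <- sample(30:600, n, replace = TRUE)
  z <- (log1p(tr) - mean(log1p(tr))) / sd(log1p(tr))
  eta <- -1 + 0.3 * z - 5e-5 * d + 0.5 * log(s_e) - 0.2 * log(s_i)
  panel <- tibble::tibble(
    exporter = "A", importer = "B", decade_end = 1879L,
    TR = tr, D = d, S_e = s_e, S_i = s_i,
    AS = rnbinom(n, mu = exp(eta), size = 2)
  )
  fit <- fit_nb_glmm(panel, model_spec(random_effects = character(0)))
  oracle <- MASS::glm.nb(
    AS ~ z + d + log(s_e) + log(s_i),
    data = data.frame(AS = panel$AS, z = z, d = d, s_e = s_e, s_i = s_i)
  )
  got <- setNames(fit$beta$estimate, fit$beta$term)
  want <- coef(oracle)
  expect_equal(got[["(Intercept)"]], want[["(Intercept)"]], tolerance = 1e-4)
  expect_equal(got[["log_tr"]], want[["z"]], tolerance = 1e-4)
  expect_equal(got[["distance"]], want[["d"]], tolerance = 1e-4)
  expect_equal(got[["log_s_e"]], want[["log(s_e)"]], tolerance = 1e-4)
  expect_equal(got[["log_s_i"]], want[["log(s_i)"]], tolerance = 1e-4)
  expect_equal(fit$theta, oracle$theta, tolerance = 1e-3)
})

test_that("the Laplace likelihood matches Gauss-Hermite integration", {
  panel <- tiny_panel()
  fit <- fit_nb_glmm(panel, model_spec(fixed_effects = "log_tr"))
  beta <- setNames(fit$beta$estimate, fit$beta$term)
  des <- log1p(panel$TR)
  s <- fit$scaling$log_tr
  z <- (des - s[["mean"]]) / s[["sd"]]
  eta_fixed <- beta[["(Intercept)"]] + beta[["log_tr"]] * z
  ll_gh <- gh_marginal_loglik(
    y = panel$AS, eta_fixed = eta_fixed,
    f1 = factor(panel$importer), f2 = factor(panel$exporter),
    theta = fit$theta,
    sd1 = sqrt(fit$re_variances[["importer_period"]]),
    sd2 = sqrt(fit$re_variances[["exporter_period"]]),
    ngh = 40
  )
  expect_equal(fit$loglik, ll_gh, tolerance = 1e-3)
})

test_that("model selection ranks candidates by AICc", {
  panel <- tiny_panel(n = 80)
  # single candidate is returned as best
  one <- select_model(panel, list(model_spec(fixed_effects = "log_tr")))
  expect_equal(nrow(one), 1L)
  expect_equal(one$rank, 1L)
  # intercept-only vs trade model on trade-driven data: trade model wins
  both <- select_model(panel, list(
    model_spec(fixed_effects = character(0)),
    model_spec(fixed_effects = "log_tr")
  ))
  expect_equal(both$fixed_effects[both$rank == 1], "log_tr")
  expect_true(all(diff(both$aicc) >= 0))
  # candidates with undefined AICc are excluded with a note
  mini <- tiny_panel(n = 8)
  expect_message(
    sel <- select_model(mini, list(
      model_spec(fixed_effects = character(0),
                 random_effects = character(0)),
      model_spec(fixed_effects = c("log_tr", "distance",
                                   "log_s_e", "log_s_i"))
    )),
    "Excluded"
  )
  expect_equal(nrow(sel), 1L)
})

test_that("population predictions evaluate the link at stored scaling", {
  # hand-computed exp(X beta) for a printed toy design
  beta <- c("(Intercept)" = -6, log_tr = 0.01, distance = -3.6e-5,
            log_s_e = 0.84, log_s_i = 0.33)
  scaling <- list(
    log_tr = c(mean = 10, sd = 4),
    distance = c(mean = 0, sd = 1),
    log_s_e = c(mean = 0, sd = 1),
    log_s_i = c(mean = 0, sd = 1)
  )
  fit <- forge_fit(beta, scaling)
  nd <- tibble::tibble(TR = exp(12) - 1, D = 5000, S_e = 100, S_i = 50)
  want <- exp(-6 + 0.01 * (12 - 10) / 4 - 3.6e-5 * 5000 +
                0.84 * log(100) + 0.33 * log(50))
  expect_equal(predict_mean(fit, nd), want, tolerance = 1e-12)

  # intercept-only model: prediction is exp(c) everywhere
  fit0 <- forge_fit(c("(Intercept)" = 1.3),
                    spec = model_spec(fixed_effects = character(0)))
  expect_equal(predict_mean(fit0, nd), exp(1.3))

  # monotonicity in TR under a positive trade coefficient
  tr_grid <- tibble::tibble(TR = seq(0, 1e6, length.out = 20),
                            D = 5000, S_e = 100, S_i = 50)
  mu <- predict_mean(fit, tr_grid)
  expect_true(all(diff(mu) > 0))
})

test_that("conditional predictions add the estimated random-intercept modes", {
  panel <- tiny_panel()
  fit <- fit_nb_glmm(panel, model_spec(fixed_effects = "log_tr"))
  nd <- panel[1:2, ]
  nd$importer_period <- paste(nd$importer, nd$decade_end, sep = ":")
  nd$exporter_period <- paste(nd$exporter, nd$decade_end, sep = ":")
  pop <- predict_mean(fit, nd, mode = "population")
  cond <- predict_mean(fit, nd, mode = "conditional")
  re <- glmmTMB::ranef(fit$model)$cond
  shift <- re$importer_period[nd$importer_period[1], 1] +
    re$exporter_period[nd$exporter_period[1], 1]
  expect_equal(cond[1], pop[1] * exp(shift), tolerance = 1e-10)
  nd_bad <- dplyr::mutate(nd, importer_period = "X:1879")
  expect_error(predict_mean(fit, nd_bad, mode = "conditional"), "Unknown")
})

test_that("variance decomposition follows the latent-scale plug-in formula", {
  fitinfo <- small_world_fit()
  r2 <- r2_nakagawa(fitinfo$fit)
  # independent plug-in computation from the fit's own components
  beta <- setNames(fitinfo$fit$beta$estimate, fitinfo$fit$beta$term)
  des <- panel_design_oracle(fitinfo$panel, fitinfo$fit$scaling)
  eta <- beta[["(Intercept)"]] +
    as.matrix(des) %*% beta[c("log_tr", "distance", "log_s_e", "log_s_i")]
  vf <- var(as.vector(eta))
  vr <- sum(fitinfo$fit$re_variances)
  mu_bar <- exp(mean(eta) + 0.5 * vr)
  vd <- log(1 + 1 / mu_bar + 1 / fitinfo$fit$theta)
  expect_equal(r2$marginal, vf / (vf + vr + vd), tolerance = 1e-8)
  expect_equal(r2$conditional, (vf + vr) / (vf + vr + vd), tolerance = 1e-8)
  expect_true(r2$marginal >= 0 && r2$marginal <= r2$conditional &&
                r2$conditional <= 1)

  # without random effects the marginal and conditional shares coincide
  set.seed(21)
  panel0 <- tiny_panel(n = 200, theta = 2)
  fit0 <- fit_nb_glmm(panel0, model_spec(fixed_effects = "log_tr",
                                         random_effects = character(0)))
  r20 <- r2_nakagawa(fit0)
  expect_equal(r20$marginal, r20$conditional, tolerance = 1e-12)
})
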