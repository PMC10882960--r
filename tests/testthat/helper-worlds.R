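# Small worlds shared across test files, generated once per run.
.world_cache <- new.env(parent = emptyenv())

cached_world <- function(key, config) {
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- generate_world(config)
  }
  .world_cache[[key]]
}

small_world <- function() {
  cached_world("small", world_config(
    seed = 101, n_countries = 8, n_species = 3000
  ))
}

# world with a fitted model, shared by fate-factor and acceptance tests
small_world_fit <- function() {
  if (is.null(.world_cache$small_fit)) {
    w <- small_world()
    panel <- build_panel(w)
    .world_cache$small_fit <- list(
      world = w, panel = panel, fit = fit_nb_glmm(panel)
    )
  }
  .world_cache$small_fit
}

# hand-made fit object for direct-evaluation tests: population-mode
# predictions only need coefficients, spec and scaling
forge_fit <- function(beta, scaling = NULL,
                      spec = model_spec()) {
  vars <- spec$fixed_effects
  if (is.null(scaling)) {
    scaling <- lapply(setNames(vars, vars), function(v) c(mean = 0, sd = 1))
  }
  structure(
    list(
      spec = spec,
      beta = tibble::tibble(
        term = c("(Intercept)", vars),
        estimate = unname(beta[c("(Intercept)", vars)]),
        std_error = NA_real_
      ),
      theta = 1, re_variances = numeric(0),
      loglik = NA_real_, aicc = NA_real_, n_obs = 0L, k = NA_integer_,
      scaling = scaling, convergence = TRUE, boundary = FALSE, model = NULL
    ),
    class = "invacf_glmm"
  )
}
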