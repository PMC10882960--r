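red_list_threatened <- c("VU", "EN", "CR", "EX", "EW")
severity_levels <- c("slow_significant", "rapid", "very_rapid",
                     "unknown", "none")
qualifying_severity <- c("slow_significant", "rapid", "very_rapid")
category_levels <- c("LC", "NT", red_list_threatened, "DD")
dd_options_all <- c("dd_predicted", "dd_not_threatened", "dd_threatened")

#' Potentially disappeared fraction of species per country
#'
#' The PDF of a country is the fraction of its assessed native species that
#' are extinct or threatened with extinction (Red-List categories VU, EN, CR,
#' EX, EW) *and* decline due to invasive alien species: at least one threat
#' row whose code belongs to the invasive-alien classification and whose
#' severity is a slow-significant, rapid or very-rapid decline. The
#' denominator counts species whose threats were assessed at a comparable
#' level of detail: at least one threat row with severity other than
#' "unknown".
#'
#' Data-deficient (DD) species carry no Red-List risk category; three options
#' resolve them: `dd_predicted` counts only DD species flagged as predicted
#' threatened, `dd_not_threatened` counts none, `dd_threatened` counts all.
#' For every country `dd_not_threatened <= dd_predicted <= dd_threatened`.
#'
#' @param threats Tibble `species, country, category, threat_code, severity,
#'   dd_predicted_threatened` (one row per species x country x threat).
#' @param dd_option How to treat DD species in the numerator.
#' @param ias_codes Threat codes mapped to "invasive non-native/alien
#'   species"; the classification scheme's code set must be supplied
#'   explicitly by the data preparer.
#' @param natives Optional tibble `species, country`; when given, threat rows
#'   of species not native to the row's country are discarded first.
#' @return Tibble `country, pdf, n_threatened, n_assessed`; countries with an
#'   empty denominator are excluded with a message.
#' @export
compute_pdf <- function(threats,
                        dd_option = c("dd_predicted", "dd_not_threatened",
                                      "dd_threatened"),
                        ias_codes = c("8.1", "8.1.1", "8.1.2"),
                        natives = NULL) {
  dd_option <- match.arg(dd_option)
  assert_columns(threats, c("species", "country", "category",
                            "threat_code", "severity"), "`threats`")
  bad_cat <- setdiff(unique(threats$category), category_levels)
  if (length(bad_cat)) {
    abort(sprintf("Unknown Red-List category: %s",
                  paste(bad_cat, collapse = ", ")))
  }
  bad_sev <- setdiff(unique(threats$severity), severity_levels)
  if (length(bad_sev)) {
    abort(sprintf("Unknown threat severity: %s",
                  paste(bad_sev, collapse = ", ")))
  }
  if (!is.null(natives)) {
    threats <- dplyr::semi_join(threats, natives,
                                by = c("species", "country"))
  }
  if (!"dd_predicted_threatened" %in% names(threats)) {
    threats$dd_predicted_threatened <- NA
  }

  per_species <- threats %>%
    dplyr::group_by(.data$country, .data$species) %>%
    dplyr::summarise(
      assessed = any(.data$severity != "unknown"),
      category = dplyr::first(.data$category),
      dd_predicted_threatened =
        any(.data$dd_predicted_threatened %in% TRUE),
      ias_hit = any(.data$threat_code %in% ias_codes &
                      .data$severity %in% qualifying_severity),
      .groups = "drop"
    )
  threatened <- per_species$category %in% red_list_threatened |
    (per_species$category == "DD" & switch(
      dd_option,
      dd_predicted = per_species$dd_predicted_threatened,
      dd_not_threatened = FALSE,
      dd_threatened = TRUE
    ))
  per_species$qualifies <- per_species$assessed & threatened &
    per_species$ias_hit

  out <- per_species %>%
    dplyr::group_by(.data$country) %>%
    dplyr::summarise(
      n_threatened = sum(.data$qualifies),
      n_assessed = sum(.data$assessed),
      .groups = "drop"
    )
  empty <- out$n_assessed == 0
  if (any(empty)) {
    inform(sprintf("Excluded %d country(ies) with no assessed species: %s",
                   sum(empty), paste(out$country[empty], collapse = ", ")))
    out <- out[!empty, ]
  }
  out$pdf <- out$n_threatened / out$n_assessed
  dplyr::select(out, "country", "pdf", "n_threatened", "n_assessed")
}

#' Country-level alien species fraction from first records
#'
#' Counts each country's natives and the distinct species first-recorded
#' there (records of species in their own native country are ignored), and
#' applies the alien-species-fraction definition.
#'
#' @param natives Tibble `species, country`.
#' @param first_records Tibble `species, country, year`.
#' @return Tibble `country, n_native, n_alien, asf`; countries with zero
#'   total species are excluded.
#' @export
country_asf <- function(natives, first_records) {
  assert_columns(natives, c("species", "country"), "`natives`")
  assert_columns(first_records, c("species", "country"), "`first_records`")
  aliens <- first_records %>%
    dplyr::anti_join(natives, by = c("species", "country")) %>%
    dplyr::distinct(.data$species, .data$country) %>%
    dplyr::count(.data$country, name = "n_alien")
  nat <- natives %>% dplyr::count(.data$country, name = "n_native")
  out <- dplyr::full_join(nat, aliens, by = "country") %>%
    dplyr::mutate(
      n_native = dplyr::coalesce(.data$n_native, 0L),
      n_alien = dplyr::coalesce(.data$n_alien, 0L)
    ) %>%
    dplyr::filter(.data$n_native + .data$n_alien > 0)
  out$asf <- asf(out$n_alien, out$n_native)
  dplyr::arrange(out, .data$country)
}

#' Country effect rows for the stressor-response regression
#'
#' Joins the alien species fraction, the PDF under all three data-deficient
#' options, and the log10-area weight. Only countries present in all input
#' tables enter; areas below 10 km2 get the weight floor log10(10) = 1.
#'
#' @param threats,natives,first_records,countries Input tables (see
#'   [compute_pdf()], [country_asf()]; `countries` needs `id, area_km2`).
#' @param ias_codes Passed to [compute_pdf()].
#' @return Tibble `country, asf, pdf_dd_predicted, pdf_dd_not_threatened,
#'   pdf_dd_threatened, weight, n_assessed`.
#' @export
effect_rows <- function(threats, natives, first_records, countries,
                        ias_codes = c("8.1", "8.1.1", "8.1.2")) {
  assert_columns(countries, c("id", "area_km2"), "`countries`")
  asf_tab <- country_asf(natives, first_records)
  pdfs <- purrr::map(
    setNames(dd_options_all, dd_options_all),
    function(opt) {
      compute_pdf(threats, opt, ias_codes, natives = natives) %>%
        dplyr::select("country", "n_assessed", pdf = "pdf")
    }
  )
  base <- pdfs$dd_predicted %>%
    dplyr::rename(pdf_dd_predicted = "pdf") %>%
    dplyr::inner_join(
      dplyr::select(pdfs$dd_not_threatened, "country",
                    pdf_dd_not_threatened = "pdf"),
      by = "country"
    ) %>%
    dplyr::inner_join(
      dplyr::select(pdfs$dd_threatened, "country", pdf_dd_threatened = "pdf"),
      by = "country"
    ) %>%
    dplyr::inner_join(dplyr::select(asf_tab, "country", "asf"),
                      by = "country") %>%
    dplyr::inner_join(
      dplyr::transmute(countries, country = .data$id,
                       weight = pmax(log10(.data$area_km2), 1)),
      by = "country"
    )
  dplyr::select(base, "country", "asf", "pdf_dd_predicted",
                "pdf_dd_not_threatened", "pdf_dd_threatened", "weight",
                "n_assessed")
}

# exact minimiser of sum_i w_i * rho_tau(y - a - b x): the check-loss
# objective is a piecewise-linear convex LP whose optimal vertex interpolates
# two observations with distinct x; enumerate all such basic solutions.
solve_wqr <- function(x, y, w, tau) {
  n <- length(x)
  stopifnot(length(y) == n, length(w) == n)
  if (n < 3) abort("Need at least 3 points for the quantile fit.")
  if (any(w <= 0)) abort("Weights must be strictly positive.")
  if (tau <= 0 || tau >= 1) abort("`tau` must lie in (0, 1).")
  if (length(unique(x)) < 2) {
    abort("Quantile-regression slope undefined: all x values identical.")
  }
  idx <- utils::combn(n, 2)
  dx <- x[idx[2, ]] - x[idx[1, ]]
  keep <- abs(dx) > .Machine$double.eps^0.5 * max(abs(x), 1)
  idx <- idx[, keep, drop = FALSE]
  b <- (y[idx[2, ]] - y[idx[1, ]]) / (x[idx[2, ]] - x[idx[1, ]])
  a <- y[idx[1, ]] - b * x[idx[1, ]]
  # residual matrix: n points x P candidate lines
  R <- matrix(y, n, length(b)) - matrix(a, n, length(b), byrow = TRUE) -
    outer(x, b)
  loss <- colSums(w * R * (tau - (R < 0)))
  best <- order(loss, b, a)[1]
  list(intercept = a[best], slope = b[best], loss = loss[best])
}

# KKT condition of the check-loss LP: 0 must lie in the subgradient interval
# of the objective with respect to both intercept and slope.
wqr_optimality <- function(x, y, w, tau, intercept, slope, tol = 1e-9) {
  r <- y - intercept - slope * x
  scale <- max(abs(y), 1)
  on_line <- abs(r) <= tol * scale
  g <- ifelse(r > 0, -tau, 1 - tau)
  g[on_line] <- 0
  interval <- function(z) {
    lo <- sum(w * g * z) + sum(pmin(-tau * w[on_line] * z[on_line],
                                    (1 - tau) * w[on_line] * z[on_line]))
    hi <- sum(w * g * z) + sum(pmax(-tau * w[on_line] * z[on_line],
                                    (1 - tau) * w[on_line] * z[on_line]))
    c(lo, hi)
  }
  ia <- interval(rep(1, length(x)))
  ib <- interval(x)
  slack <- tol * sum(w) * max(abs(x), 1)
  list(
    intercept_interval = ia, slope_interval = ib,
    optimal = ia[1] <= slack && ia[2] >= -slack &&
      ib[1] <= slack && ib[2] >= -slack,
    n_on_line = sum(on_line)
  )
}

#' Weighted quantile regression of PDF on ASF
#'
#' Fits the line minimising the weighted tilted-absolute (check) loss at
#' quantile `tau`. The objective is a linear program; because the model has
#' two free parameters an optimal vertex interpolates two observations, and
#' the solver enumerates all such basic solutions exactly (ties broken by
#' smallest slope, then intercept). Optimality is verified through the LP
#' subgradient condition and exposed in the result.
#'
#' A low quantile (default 5th percentile) traces the lower envelope of the
#' scatter: confounding threats only inflate the PDF, so the envelope
#' reflects the component attributable to alien pressure.
#'
#' @param rows Tibble of country effect rows.
#' @param tau Quantile in (0, 1).
#' @param y,x,weight Column names of response, regressor and weight.
#' @param nboot Number of weighted pairs-bootstrap resamples for the
#'   confidence interval; 0 skips the interval.
#' @param conf_level Confidence level (default 0.95).
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `invacf_ef`: `tau`, `slope` (PDF per ASF),
#'   `intercept`, `ci_lower`, `ci_upper`, `loss`, `n`, `optimality`, plus the
#'   data used (for plotting).
#' @export
weighted_quantile_fit <- function(rows, tau, y = "pdf", x = "asf",
                                  weight = "weight", nboot = 0,
                                  conf_level = 0.95, seed = NULL) {
  assert_columns(rows, c(y, x, weight), "`rows`")
  xx <- rows[[x]]; yy <- rows[[y]]; ww <- rows[[weight]]
  ok <- complete.cases(xx, yy, ww)
  xx <- xx[ok]; yy <- yy[ok]; ww <- ww[ok]
  fit <- solve_wqr(xx, yy, ww, tau)
  opt <- wqr_optimality(xx, yy, ww, tau, fit$intercept, fit$slope)
  ci <- c(NA_real_, NA_real_)
  boot_slopes <- NULL
  if (nboot > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(xx)
    boot_slopes <- vapply(seq_len(nboot), function(b) {
      id <- sample.int(n, n, replace = TRUE)
      if (length(unique(xx[id])) < 2) return(NA_real_)
      solve_wqr(xx[id], yy[id], ww[id], tau)$slope
    }, numeric(1))
    alpha <- (1 - conf_level) / 2
    ci <- unname(quantile(boot_slopes, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  structure(
    list(
      tau = tau, slope = fit$slope, intercept = fit$intercept,
      ci_lower = ci[1], ci_upper = ci[2], conf_level = conf_level,
      loss = fit$loss, n = length(xx), optimality = opt,
      data = tibble::tibble(x = xx, y = yy, w = ww),
      x_name = x, y_name = y
    ),
    class = "invacf_ef"
  )
}

#' @export
print.invacf_ef <- function(x, ...) {
  cat(sprintf(
    "<invacf_ef> tau = %.2f: slope = %.4g, intercept = %.4g (n = %d)\n",
    x$tau, x$slope, x$intercept, x$n
  ))
  if (!is.na(x$ci_lower)) {
    cat(sprintf("  %d%% bootstrap CI for slope: [%.4g, %.4g]\n",
                round(100 * x$conf_level), x$ci_lower, x$ci_upper))
  }
  invisible(x)
}

#' @rdname weighted_quantile_fit
#' @param x An `invacf_ef` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.invacf_ef <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    ci_lower = c(NA_real_, x$ci_lower),
    ci_upper = c(NA_real_, x$ci_upper)
  )
}

#' @rdname weighted_quantile_fit
#' @exportS3Method generics::glance
glance.invacf_ef <- function(x, ...) {
  tibble::tibble(
    tau = x$tau, n = x$n, loss = x$loss,
    optimal = x$optimality$optimal
  )
}

#' Effect factors across quantiles and data-deficient options
#'
#' Runs [weighted_quantile_fit()] for every combination of quantile and DD
#' option; the headline effect factor is the 5th-percentile slope under the
#' `dd_predicted` option.
#'
#' @param rows Country effect rows from [effect_rows()] (columns
#'   `pdf_dd_*`), or any tibble with a single `pdf` column, in which case the
#'   DD option is reported as `"pdf"`.
#' @param taus Quantiles to fit.
#' @param dd_options DD numerator options to fit.
#' @param nboot,conf_level,seed Bootstrap settings (see
#'   [weighted_quantile_fit()]).
#' @return Tibble `tau, dd_option, slope, intercept, ci_lower, ci_upper, n`
#'   with the fit objects in the attribute `"fits"`.
#' @export
effect_factor <- function(rows, taus = c(0.05, 0.10, 0.15),
                          dd_options = dd_options_all,
                          nboot = 1000, conf_level = 0.95, seed = NULL) {
  cols <- if ("pdf" %in% names(rows)) {
    "pdf"
  } else {
    paste0("pdf_", dd_options)
  }
  grid <- tidyr::expand_grid(tau = taus, pdf_col = cols)
  fits <- purrr::map2(grid$tau, grid$pdf_col, function(tt, cc) {
    weighted_quantile_fit(rows, tt, y = cc, nboot = nboot,
                          conf_level = conf_level, seed = seed)
  })
  out <- tibble::tibble(
    tau = grid$tau,
    dd_option = sub("^pdf_?", "", grid$pdf_col),
    slope = purrr::map_dbl(fits, "slope"),
    intercept = purrr::map_dbl(fits, "intercept"),
    ci_lower = purrr::map_dbl(fits, "ci_lower"),
    ci_upper = purrr::map_dbl(fits, "ci_upper"),
    n = purrr::map_int(fits, "n")
  )
  out$dd_option[out$dd_option == ""] <- "pdf"
  attr(out, "fits") <- fits
  out
}

#' Serialise effect factors to JSON
#'
#' @param ef_table Tibble from [effect_factor()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ef_json <- function(ef_table, path) {
  jsonlite::write_json(
    purrr::pmap(ef_table, function(tau, dd_option, slope, intercept,
                                   ci_lower, ci_upper, n) {
      list(tau = tau, dd_option = dd_option, slope = slope,
           intercept = intercept, ci_lower = ci_lower,
           ci_upper = ci_upper, n = n)
    }),
    path, auto_unbox = TRUE, digits = I(17), na = "null"
  )
  invisible(path)
}
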