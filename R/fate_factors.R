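#' Alien species fraction
#'
#' Fraction of extant alien species relative to all species present (alien
#' plus native) in a country.
#'
#' @param alien_count,native_count Non-negative counts (vectorised).
#' @return `alien / (alien + native)`, in `[0, 1)`.
#' @examples
#' asf(50, 50)
#' asf(0, 100)
#' @export
asf <- function(alien_count, native_count) {
  assert_nonneg(alien_count, "`alien_count`")
  assert_nonneg(native_count, "`native_count`")
  total <- alien_count + native_count
  if (any(total == 0)) {
    abort("ASF is undefined when both counts are zero.")
  }
  alien_count / total
}

#' Eligibility of country pairs for fate factors
#'
#' Pairs qualify when their mean transport rate over the study horizon --
#' cumulative kg at the last decade endpoint divided by the horizon length --
#' reaches the threshold. The boundary (exactly the threshold) is eligible.
#'
#' @param panel Panel tibble with `exporter, importer, decade_end, TR`.
#' @param horizon_years Study horizon in years (default 150).
#' @param min_rate_kg_yr Eligibility threshold in kg per year (default 100).
#' @return Tibble `exporter, importer, cum_kg, rate_kg_yr, eligible`.
#' @export
filter_pairs <- function(panel, horizon_years = 150, min_rate_kg_yr = 100) {
  assert_columns(panel, c("exporter", "importer", "decade_end", "TR"),
                 "`panel`")
  last_end <- max(panel$decade_end)
  panel %>%
    dplyr::filter(.data$decade_end == last_end) %>%
    dplyr::transmute(
      .data$exporter, .data$importer,
      cum_kg = .data$TR,
      rate_kg_yr = .data$TR / horizon_years,
      eligible = .data$rate_kg_yr >= min_rate_kg_yr
    )
}

#' Fate factors per country pair
#'
#' Computes average and/or marginal fate factors (FF, in ASF x year per kg)
#' for each eligible ordered country pair from a fitted count model.
#'
#' The average FF contrasts the expected number of alien species at the full
#' cumulative transported quantity with the expectation at zero trade; the
#' difference is divided by the number of species present in the importer and
#' by the mean transport rate (cumulative kg over the horizon). The marginal
#' FF perturbs the 2019 cumulative quantity by one additional year of trade at
#' the mean annual rate of the final decade and divides by that rate. With a
#' concave species-import relationship the marginal FF never exceeds the
#' average FF.
#'
#' Predictions use population mode by default (random effects at zero) so the
#' factors generalise beyond the training levels.
#'
#' @param fit An `invacf_glmm` from [fit_nb_glmm()].
#' @param panel Panel tibble the factors are computed for.
#' @param aliens Optional tibble `country, n_alien` (aliens present by the
#'   final year). Required for `s_total = "all_present"`.
#' @param kind `"marginal"`, `"average"`, or both.
#' @param horizon_years Study horizon (years).
#' @param min_rate_kg_yr Eligibility threshold (kg/yr).
#' @param s_total `"all_present"` (natives + aliens, the default) or
#'   `"natives_only"` -- which species count weights the ASF change.
#' @param mode Prediction mode passed to [predict_mean()].
#' @return Tibble `exporter, importer, kind, value, delta_as,
#'   denominator_rate, s_total_i, eligible`. Ineligible pairs and pairs with
#'   zero denominator are retained with `NA` value and `eligible = FALSE`;
#'   skipped pairs are reported via an attribute `"skipped"`.
#' @export
fate_factors <- function(fit, panel, aliens = NULL,
                         kind = c("marginal", "average"),
                         horizon_years = 150, min_rate_kg_yr = 100,
                         s_total = c("all_present", "natives_only"),
                         mode = "population") {
  stopifnot(inherits(fit, "invacf_glmm"))
  kind <- match.arg(kind, c("marginal", "average"), several.ok = TRUE)
  s_total <- match.arg(s_total)
  assert_columns(panel, c("exporter", "importer", "decade_end",
                          "TR", "D", "S_e", "S_i"), "`panel`")
  ends <- sort(unique(panel$decade_end))
  last_end <- ends[length(ends)]
  prev_end <- if (length(ends) >= 2) ends[length(ends) - 1] else NA_real_

  last <- panel %>% dplyr::filter(.data$decade_end == last_end)
  prev <- panel %>%
    dplyr::filter(.data$decade_end == prev_end) %>%
    dplyr::select("exporter", "importer", TR_prev = "TR")
  base <- dplyr::left_join(last, prev, by = c("exporter", "importer"))
  base$TR_prev <- dplyr::coalesce(base$TR_prev, 0)

  if (s_total == "all_present") {
    if (is.null(aliens)) {
      abort("`aliens` (country, n_alien) is required for s_total = \"all_present\".")
    }
    assert_columns(aliens, c("country", "n_alien"), "`aliens`")
    base <- dplyr::left_join(base, aliens, by = c("importer" = "country"))
    base$n_alien <- dplyr::coalesce(base$n_alien, 0L)
    base$s_total_i <- base$S_i + base$n_alien
  } else {
    base$s_total_i <- base$S_i
  }

  elig <- filter_pairs(panel, horizon_years, min_rate_kg_yr)
  base <- dplyr::left_join(
    base, dplyr::select(elig, "exporter", "importer", "eligible"),
    by = c("exporter", "importer")
  )

  pred_at <- function(df, tr) {
    nd <- df
    nd$TR <- tr
    predict_mean(fit, nd, mode = mode)
  }

  out <- list()
  if ("average" %in% kind) {
    d <- base
    d$denominator_rate <- d$TR / horizon_years
    usable <- d$eligible & d$TR > 0
    delta <- rep(NA_real_, nrow(d))
    delta[usable] <- pred_at(d[usable, ], d$TR[usable]) -
      pred_at(d[usable, ], 0)
    d$delta_as <- delta
    d$value <- ifelse(usable,
                      (delta / d$s_total_i) / d$denominator_rate, NA_real_)
    d$kind <- "average"
    out$average <- d
  }
  if ("marginal" %in% kind) {
    d <- base
    q <- (d$TR - d$TR_prev) / 10
    d$denominator_rate <- q
    usable <- d$eligible & q > 0
    delta <- rep(NA_real_, nrow(d))
    delta[usable] <- pred_at(d[usable, ], d$TR[usable] + q[usable]) -
      pred_at(d[usable, ], d$TR[usable])
    d$delta_as <- delta
    d$value <- ifelse(usable, (delta / d$s_total_i) / q, NA_real_)
    d$kind <- "marginal"
    out$marginal <- d
  }
  res <- dplyr::bind_rows(out) %>%
    dplyr::select("exporter", "importer", "kind", "value", "delta_as",
                  "denominator_rate", "s_total_i", "eligible")
  skipped <- res[res$eligible & is.na(res$value), ]
  if (nrow(skipped)) {
    inform(sprintf(
      "%d eligible pair(s) skipped (zero cumulative or last-decade trade).",
      nrow(skipped)
    ))
  }
  attr(res, "skipped") <- skipped
  res
}

#' Aliens present per country by the end of the study period
#'
#' Counts distinct species first-recorded in each country, the alien part of
#' the "all species present" weighting of the fate factor.
#'
#' @param first_records Tibble `species, country, year`.
#' @param by_year Count records up to this year only (default: all).
#' @return Tibble `country, n_alien`.
#' @export
count_aliens <- function(first_records, by_year = NULL) {
  assert_columns(first_records, c("species", "country", "year"),
                 "`first_records`")
  fr <- first_records
  if (!is.null(by_year)) fr <- fr[fr$year <= by_year, ]
  fr %>%
    dplyr::distinct(.data$species, .data$country) %>%
    dplyr::count(.data$country, name = "n_alien")
}
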