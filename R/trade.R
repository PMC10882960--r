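#' Fit a zero-intercept quadratic back-cast model for one country pair
#'
#' Historical transported mass (kg) is reconstructed from monetary flows by a
#' least-squares fit of `mass = c1 * money + c2 * money^2` with the intercept
#' fixed at zero, estimated over the years where both series are observed.
#'
#' @param money,mass Numeric vectors of monetary value and transported mass on
#'   the overlap years (same length, pairwise observed).
#' @return A list of class `invacf_backcast` with `coef1` (kg per value),
#'   `coef2` (kg per value squared), `r_squared` (computed on the fitted
#'   years; 1 minus residual over centred total sum of squares, so it can be
#'   negative), `n_overlap`, and `unfit`. With fewer than 3 overlap points the
#'   model is marked unfit and carries no coefficients.
#' @examples
#' m <- fit_backcast(money = 1:5, mass = 2 * (1:5))
#' m$coef1
#' @export
fit_backcast <- function(money, mass) {
  stopifnot(length(money) == length(mass))
  keep <- is.finite(money) & is.finite(mass)
  money <- money[keep]; mass <- mass[keep]
  if (length(money) < 3) {
    return(structure(
      list(coef1 = NA_real_, coef2 = NA_real_, r_squared = NA_real_,
           n_overlap = length(money), unfit = TRUE),
      class = "invacf_backcast"
    ))
  }
  X <- cbind(money, money^2)
  fit <- stats::lm.fit(X, mass)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0 # rank deficiency (e.g. all-zero money): drop the term
  fitted <- X %*% cf
  ss_res <- sum((mass - fitted)^2)
  ss_tot <- sum((mass - mean(mass))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else ifelse(ss_res == 0, 1, -Inf)
  structure(
    list(coef1 = unname(cf[1]), coef2 = unname(cf[2]), r_squared = r2,
         n_overlap = length(money), unfit = FALSE),
    class = "invacf_backcast"
  )
}

#' Predict transported mass from monetary value
#'
#' Evaluates a fitted back-cast model; negative raw predictions are clamped to
#' zero (mass cannot be negative) and the clamping is flagged.
#'
#' @param model An `invacf_backcast` from [fit_backcast()].
#' @param money Numeric vector of monetary values.
#' @return Numeric vector of kg with attribute `clamped` (logical vector
#'   marking where the raw prediction was negative).
#' @export
predict_mass <- function(model, money) {
  stopifnot(inherits(model, "invacf_backcast"))
  if (isTRUE(model$unfit)) {
    abort("Cannot predict from an unfit back-cast model (< 3 overlap years).")
  }
  raw <- model$coef1 * money + model$coef2 * money^2
  out <- pmax(raw, 0)
  attr(out, "clamped") <- raw < 0
  out
}

#' Back-cast models for every country pair
#'
#' Fits [fit_backcast()] per ordered exporter-importer pair on the years where
#' both mass and money are observed.
#'
#' @param trade_mass Tibble `exporter, importer, year, kg` (observed window).
#' @param trade_money Tibble `exporter, importer, year, value`.
#' @return Tibble `exporter, importer, coef1, coef2, r_squared, n_overlap,
#'   unfit`, one row per pair appearing in either input.
#' @export
backcast_models <- function(trade_mass, trade_money) {
  assert_columns(trade_mass, c("exporter", "importer", "year", "kg"),
                 "`trade_mass`")
  assert_columns(trade_money, c("exporter", "importer", "year", "value"),
                 "`trade_money`")
  joined <- dplyr::inner_join(
    trade_mass, trade_money,
    by = c("exporter", "importer", "year")
  )
  all_pairs <- dplyr::distinct(
    dplyr::bind_rows(
      dplyr::select(trade_mass, "exporter", "importer"),
      dplyr::select(trade_money, "exporter", "importer")
    )
  )
  fits <- joined %>%
    dplyr::group_by(.data$exporter, .data$importer) %>%
    dplyr::summarise(
      fit = list(fit_backcast(.data$value, .data$kg)),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      coef1 = purrr::map_dbl(.data$fit, "coef1"),
      coef2 = purrr::map_dbl(.data$fit, "coef2"),
      r_squared = purrr::map_dbl(.data$fit, "r_squared"),
      n_overlap = purrr::map_int(.data$fit, "n_overlap"),
      unfit = purrr::map_lgl(.data$fit, "unfit")
    ) %>%
    dplyr::select(-"fit")
  out <- dplyr::left_join(all_pairs, fits, by = c("exporter", "importer"))
  out$unfit[is.na(out$unfit)] <- TRUE
  out$n_overlap[is.na(out$n_overlap)] <- 0L
  out
}

#' Reconstruct the full yearly transported-mass series
#'
#' Merges the observed mass window with back-cast predictions from monetary
#' flows for all other years. Observed values are never overwritten by
#' predictions. Pairs whose back-cast model could not be fitted (fewer than 3
#' overlap years) get zero pre-window mass, with a warning naming how many
#' pairs were affected. Years with neither observation nor money are filled
#' with 0 kg.
#'
#' @inheritParams backcast_models
#' @param year_range Two calendar years delimiting the reconstructed series.
#' @return Tibble `exporter, importer, year, kg, source` with `source` one of
#'   `"observed"`, `"backcast"`, `"zero_fill"`; the per-pair model table is
#'   attached as attribute `"models"`.
#' @export
reconstruct_trade <- function(trade_mass, trade_money, year_range) {
  check_year_range(year_range)
  models <- backcast_models(trade_mass, trade_money)
  if (any(models$unfit)) {
    warn(sprintf(
      "%d pair(s) had < 3 overlap years; pre-window mass set to zero for them.",
      sum(models$unfit)
    ))
  }
  years <- year_range[1]:year_range[2]
  grid <- tidyr::expand_grid(
    dplyr::distinct(models[, c("exporter", "importer")]),
    year = years
  )
  out <- grid %>%
    dplyr::left_join(
      dplyr::rename(trade_mass, observed_kg = "kg"),
      by = c("exporter", "importer", "year")
    ) %>%
    dplyr::left_join(trade_money, by = c("exporter", "importer", "year")) %>%
    dplyr::left_join(models, by = c("exporter", "importer"))
  predicted <- ifelse(
    !out$unfit & !is.na(out$value),
    pmax(out$coef1 * out$value + out$coef2 * out$value^2, 0),
    NA_real_
  )
  out$kg <- dplyr::coalesce(out$observed_kg, predicted, 0)
  out$source <- dplyr::case_when(
    !is.na(out$observed_kg) ~ "observed",
    !is.na(predicted) ~ "backcast",
    TRUE ~ "zero_fill"
  )
  res <- dplyr::select(out, "exporter", "importer", "year", "kg", "source")
  attr(res, "models") <- models
  res
}

#' Cumulate a yearly series into 10-year timesteps
#'
#' Computes the running cumulative transported quantity per pair, evaluated at
#' each decade endpoint. For the default 1870--2019 period this yields exactly
#' 15 endpoints (1879, ..., 2019), the last being the grand total.
#'
#' @param series Tibble `exporter, importer, year, kg`; missing pair-years
#'   count as 0 kg.
#' @param start_year,end_year Period bounds (length divisible by 10).
#' @return Tibble `exporter, importer, decade_end, cum_kg`.
#' @export
cumulate_decades <- function(series, start_year, end_year) {
  assert_columns(series, c("exporter", "importer", "year", "kg"), "`series`")
  ends <- decade_endpoints(start_year, end_year)
  inside <- series[series$year >= start_year & series$year <= end_year, ]
  assert_nonneg(inside$kg, "`kg`")
  inside$decade_end <- decade_end_of(inside$year, start_year)
  per_decade <- inside %>%
    dplyr::group_by(.data$exporter, .data$importer, .data$decade_end) %>%
    dplyr::summarise(kg = sum(.data$kg), .groups = "drop")
  grid <- tidyr::expand_grid(
    dplyr::distinct(series[, c("exporter", "importer")]),
    decade_end = ends
  )
  grid %>%
    dplyr::left_join(per_decade, by = c("exporter", "importer", "decade_end")) %>%
    dplyr::mutate(kg = dplyr::coalesce(.data$kg, 0)) %>%
    dplyr::group_by(.data$exporter, .data$importer) %>%
    dplyr::arrange(.data$decade_end, .by_group = TRUE) %>%
    dplyr::mutate(cum_kg = cumsum(.data$kg)) %>%
    dplyr::ungroup() %>%
    dplyr::select("exporter", "importer", "decade_end", "cum_kg")
}

#' Distance between two countries
#'
#' Looks the pair up in a distance table; when the pair is absent and country
#' centroids are supplied, falls back to the great-circle (haversine) distance
#' with a flag. The same country maps to distance 0.
#'
#' @param e,i Country ids (exporter, importer).
#' @param distances Optional tibble `exporter, importer, km`.
#' @param centroids Optional tibble `id, lon, lat`.
#' @return Distance in km, with attribute `fallback` (TRUE when the haversine
#'   fallback was used).
#' @export
pair_distance <- function(e, i, distances = NULL, centroids = NULL) {
  if (e == i) {
    out <- 0
    attr(out, "fallback") <- FALSE
    return(out)
  }
  if (!is.null(distances)) {
    hit <- distances$km[(distances$exporter == e & distances$importer == i) |
                          (distances$exporter == i & distances$importer == e)]
    if (length(hit)) {
      out <- hit[1]
      attr(out, "fallback") <- FALSE
      return(out)
    }
  }
  if (!is.null(centroids)) {
    a <- match(e, centroids$id)
    b <- match(i, centroids$id)
    if (is.na(a) || is.na(b)) {
      abort(sprintf("Unknown country id: %s", if (is.na(a)) e else i))
    }
    out <- haversine_km(centroids$lon[a], centroids$lat[a],
                        centroids$lon[b], centroids$lat[b])
    attr(out, "fallback") <- TRUE
    return(out)
  }
  abort(sprintf(
    "No distance available for pair (%s, %s) and no centroids supplied.", e, i
  ))
}
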