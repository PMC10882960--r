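#' Build yearly species pools with bridgehead effects
#'
#' The species pool of a country in a given year is the set of its native
#' species plus every species first-recorded there in or before that year.
#' Including earlier arrivals lets established alien populations act as
#' sources for onward introductions (the bridgehead effect).
#'
#' Records of a species in its own native country are dropped with a warning:
#' a native cannot be alien at home.
#'
#' @param natives Tibble `species, country` (native ranges).
#' @param first_records Tibble `species, country, year`.
#' @param year_range Two calendar years; record years must fall inside.
#' @return An object of class `invacf_pools` used by [pool_members()],
#'   [pool_sizes()] and [attribute_introductions()].
#' @export
build_pools <- function(natives, first_records, year_range) {
  assert_columns(natives, c("species", "country"), "`natives`")
  assert_columns(first_records, c("species", "country", "year"),
                 "`first_records`")
  check_year_range(year_range)
  bad_year <- first_records$year < year_range[1] |
    first_records$year > year_range[2]
  if (any(bad_year)) {
    abort(sprintf("%d first-record year(s) outside %d-%d.",
                  sum(bad_year), year_range[1], year_range[2]))
  }
  key_nat <- paste(natives$species, natives$country)
  key_rec <- paste(first_records$species, first_records$country)
  native_rec <- key_rec %in% key_nat
  if (any(native_rec)) {
    warn(sprintf(
      "Dropped %d first record(s) of species in their own native country.",
      sum(native_rec)
    ))
    first_records <- first_records[!native_rec, ]
  }
  # earliest record per species x country defines arrival
  records <- if (nrow(first_records)) {
    first_records %>%
      dplyr::group_by(.data$species, .data$country) %>%
      dplyr::summarise(year = min(.data$year), .groups = "drop")
  } else {
    first_records[, c("species", "country", "year")]
  }
  structure(
    list(
      natives = natives,
      natives_by_country = split(natives$species, natives$country),
      records = records,
      records_by_country = split(
        records[, c("species", "year")], records$country
      ),
      year_range = as.integer(year_range)
    ),
    class = "invacf_pools"
  )
}

#' Members of a country's species pool in a year
#'
#' @param pools An `invacf_pools` object.
#' @param country Country id.
#' @param year Calendar year.
#' @return Character vector of species ids (natives plus aliens recorded in or
#'   before `year`).
#' @export
pool_members <- function(pools, country, year) {
  stopifnot(inherits(pools, "invacf_pools"))
  nat <- pools$natives_by_country[[country]] %||% character(0)
  rec <- pools$records_by_country[[country]]
  ali <- if (is.null(rec)) character(0) else rec$species[rec$year <= year]
  union(nat, ali)
}

#' Pool sizes for country-year combinations
#'
#' @inheritParams pool_members
#' @param countries,years Vectors combined elementwise after recycling via
#'   [tidyr::expand_grid()] when lengths differ.
#' @return Tibble `country, year, pool_size`. Pool size is nondecreasing in
#'   year for every country.
#' @export
pool_sizes <- function(pools, countries, years) {
  grid <- if (length(countries) == length(years)) {
    tibble::tibble(country = countries, year = years)
  } else {
    tidyr::expand_grid(country = countries, year = years)
  }
  grid$pool_size <- purrr::map2_int(
    grid$country, grid$year,
    function(c, y) length(pool_members(pools, c, y))
  )
  grid
}

#' Attribute alien first records to candidate exporting countries
#'
#' Every first record of species `s` in importer `i` at year `y` is credited
#' with full (unsplit) weight to every country `e != i` whose species pool at
#' year `y - 1` contains `s` -- all transportation routes that could have
#' carried the species contribute. The species must have been available
#' before the recorded arrival, hence the one-year lag.
#'
#' @param first_records Tibble `species, country, year`.
#' @param pools An `invacf_pools` object (from the same native ranges and
#'   records).
#' @return Tibble `exporter, importer, year, count`; records without any
#'   candidate exporter are counted nowhere and reported in the
#'   `"unattributed"` attribute (a tibble of the offending records).
#' @export
attribute_introductions <- function(first_records, pools) {
  stopifnot(inherits(pools, "invacf_pools"))
  assert_columns(first_records, c("species", "country", "year"),
                 "`first_records`")
  recs <- first_records
  recs$record_id <- seq_len(nrow(recs))
  # candidates from native range: the species' native countries
  from_native <- recs %>%
    dplyr::inner_join(pools$natives, by = "species",
                      relationship = "many-to-many",
                      suffix = c("", "_exp")) %>%
    dplyr::transmute(.data$record_id, exporter = .data$country_exp,
                     importer = .data$country, .data$year)
  # candidates from bridgeheads: countries where the species was already
  # recorded by the year before the arrival
  from_bridge <- recs %>%
    dplyr::inner_join(
      dplyr::rename(pools$records, exporter = "country",
                    arrival_year = "year"),
      by = "species", relationship = "many-to-many"
    ) %>%
    dplyr::filter(.data$arrival_year <= .data$year - 1) %>%
    dplyr::transmute(.data$record_id, .data$exporter,
                     importer = .data$country, .data$year)
  cand <- dplyr::bind_rows(from_native, from_bridge) %>%
    dplyr::filter(.data$exporter != .data$importer) %>%
    dplyr::distinct(.data$record_id, .data$exporter,
                    .data$importer, .data$year)
  unattributed <- !(recs$record_id %in% cand$record_id)
  out <- cand %>%
    dplyr::count(.data$exporter, .data$importer, .data$year, name = "count")
  if (any(unattributed)) {
    inform(sprintf("%d first record(s) had no candidate exporter.",
                   sum(unattributed)))
  }
  attr(out, "unattributed") <- first_records[unattributed, ]
  out
}

#' Assemble the pair-by-decade panel for the count model
#'
#' One row per ordered country pair and 10-year timestep, carrying the
#' cumulative transported quantity at the decade endpoint (`TR`, kg), the
#' pair distance (`D`, km), the exporter's species-pool size at the decade's
#' first year (`S_e`), the importer's constant native richness (`S_i`), and
#' the attributed introduction count summed over the decade (`AS`). Rows with
#' zero trade are retained; eligibility filtering happens later.
#'
#' @param introductions Tibble `exporter, importer, year, count` from
#'   [attribute_introductions()].
#' @param decade_trade Tibble `exporter, importer, decade_end, cum_kg` from
#'   [cumulate_decades()].
#' @param distances Tibble `exporter, importer, km`.
#' @param pools An `invacf_pools` object.
#' @param natives Tibble `species, country`.
#' @param year_range Two calendar years (divisible into decades).
#' @return Tibble `exporter, importer, decade_end, TR, D, S_e, S_i, AS`.
#' @export
aggregate_panel <- function(introductions, decade_trade, distances, pools,
                            natives, year_range) {
  check_year_range(year_range)
  ends <- decade_endpoints(year_range[1], year_range[2])
  pair_set <- dplyr::distinct(decade_trade[, c("exporter", "importer")])
  ids <- union(pair_set$exporter, pair_set$importer)
  stray <- setdiff(union(introductions$exporter, introductions$importer), ids)
  if (length(stray)) {
    abort(sprintf("Introduction records name unknown countries: %s",
                  paste(stray, collapse = ", ")))
  }
  missing_d <- dplyr::anti_join(pair_set, distances,
                                by = c("exporter", "importer"))
  if (nrow(missing_d)) {
    abort(sprintf("Distance table lacks %d pair(s), e.g. (%s, %s).",
                  nrow(missing_d), missing_d$exporter[1], missing_d$importer[1]))
  }

  intro <- introductions
  intro$decade_end <- decade_end_of(intro$year, year_range[1])
  as_decade <- intro %>%
    dplyr::group_by(.data$exporter, .data$importer, .data$decade_end) %>%
    dplyr::summarise(AS = sum(.data$count), .groups = "drop")

  s_i_tab <- natives %>% dplyr::count(.data$country, name = "S_i")
  s_e_tab <- pool_sizes(pools, ids, ends - 9L) %>%
    dplyr::rename(exporter = "country", S_e = "pool_size") %>%
    dplyr::mutate(decade_end = .data$year + 9L) %>%
    dplyr::select("exporter", "decade_end", "S_e")

  tidyr::expand_grid(pair_set, decade_end = ends) %>%
    dplyr::left_join(decade_trade, by = c("exporter", "importer", "decade_end")) %>%
    dplyr::left_join(distances, by = c("exporter", "importer")) %>%
    dplyr::left_join(s_e_tab, by = c("exporter", "decade_end")) %>%
    dplyr::left_join(s_i_tab, by = c("importer" = "country")) %>%
    dplyr::left_join(as_decade, by = c("exporter", "importer", "decade_end")) %>%
    dplyr::mutate(
      AS = as.integer(dplyr::coalesce(.data$AS, 0L)),
      S_i = dplyr::coalesce(.data$S_i, 0L)
    ) %>%
    dplyr::rename(TR = "cum_kg", D = "km") %>%
    dplyr::select("exporter", "importer", "decade_end",
                  "TR", "D", "S_e", "S_i", "AS")
}

#' Run the data pipeline from raw tables to the model panel
#'
#' Convenience wrapper chaining [reconstruct_trade()], [cumulate_decades()],
#' [build_pools()], [attribute_introductions()] and [aggregate_panel()].
#'
#' @param world An `invacf_world`, the list returned by [world_from_csv()], or
#'   any list with elements `trade_mass`, `trade_money`, `natives`,
#'   `first_records`, `distances`.
#' @param year_range Two calendar years (default 1870--2019).
#' @return The panel tibble, with the reconstructed yearly series and pools
#'   attached as attributes `"trade_series"` and `"pools"`.
#' @export
build_panel <- function(world, year_range = c(1870L, 2019L)) {
  series <- reconstruct_trade(world$trade_mass, world$trade_money, year_range)
  decade_trade <- cumulate_decades(series, year_range[1], year_range[2])
  pools <- build_pools(world$natives, world$first_records, year_range)
  intro <- attribute_introductions(world$first_records, pools)
  panel <- aggregate_panel(intro, decade_trade, world$distances, pools,
                           world$natives, year_range)
  attr(panel, "trade_series") <- series
  attr(panel, "pools") <- pools
  panel
}
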