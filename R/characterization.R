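#' Mean global extinction probability per country
#'
#' Averages the per-taxon GEP values (fractions in `[0, 1]`) of each country
#' with equal weight across the available taxon groups.
#'
#' @param gep Tibble `country, taxon_group, gep`.
#' @return Tibble `country, gep_mean`.
#' @export
gep_mean <- function(gep) {
  assert_columns(gep, c("country", "taxon_group", "gep"), "`gep`")
  if (any(gep$gep < 0 | gep$gep > 1)) {
    abort("GEP values must lie in [0, 1].")
  }
  gep %>%
    dplyr::group_by(.data$country) %>%
    dplyr::summarise(gep_mean = mean(.data$gep), .groups = "drop")
}

#' Characterization factors from fate factors, effect factor and GEP
#'
#' The regional CF of an ordered country pair is the product of its fate
#' factor (ASF x year per kg) and the constant effect factor (PDF per ASF),
#' giving PDF x year per kg in the importing country. The global CF further
#' multiplies by the importer's mean global extinction probability, converting
#' regional relative species loss into expected global extinctions. Since GEP
#' is at most 1 the global CF never exceeds the regional CF.
#'
#' @param ff Fate-factor tibble from [fate_factors()].
#' @param ef Either an `invacf_ef` object or a single numeric slope (PDF per
#'   ASF).
#' @param gep Optional tibble `country, taxon_group, gep`; when missing or
#'   lacking an importer, the `global_cf` field is left `NA` and the affected
#'   importers are reported via a message.
#' @return Tibble `exporter, importer, kind, regional_cf, global_cf,
#'   gep_mean` (only eligible pairs with defined fate factors).
#' @export
characterization_factors <- function(ff, ef, gep = NULL) {
  assert_columns(ff, c("exporter", "importer", "kind", "value", "eligible"),
                 "`ff`")
  slope <- if (inherits(ef, "invacf_ef")) ef$slope else as.numeric(ef)
  if (length(slope) != 1 || !is.finite(slope)) {
    abort("`ef` must supply a single finite slope.")
  }
  out <- ff %>%
    dplyr::filter(.data$eligible, !is.na(.data$value)) %>%
    dplyr::transmute(
      .data$exporter, .data$importer, .data$kind,
      regional_cf = .data$value * slope
    )
  if (!is.null(gep)) {
    gm <- gep_mean(gep)
    out <- dplyr::left_join(out, gm, by = c("importer" = "country"))
    missing <- unique(out$importer[is.na(out$gep_mean)])
    if (length(missing)) {
      inform(sprintf(
        "No GEP for importer(s) %s; their global CF is left NA.",
        paste(missing, collapse = ", ")
      ))
    }
    out$global_cf <- out$regional_cf * out$gep_mean
  } else {
    out$gep_mean <- NA_real_
    out$global_cf <- NA_real_
  }
  dplyr::select(out, "exporter", "importer", "kind",
                "regional_cf", "global_cf", "gep_mean")
}

#' Impact of a transported mass
#'
#' Multiplies a transported mass by a characterization factor. Impacts of
#' alien-species CFs are independent of transport distance at application
#' time: distance already shaped the fate factor.
#'
#' @param mass_kg Transported mass (kg, non-negative; vectorised).
#' @param cf Characterization factor (PDF x year per kg).
#' @return Impact in PDF x year.
#' @examples
#' apply_cf(1000, 2e-15)
#' @export
apply_cf <- function(mass_kg, cf) {
  assert_nonneg(mass_kg, "`mass_kg`")
  mass_kg * cf
}

#' Compare alien-species impacts with a reference stressor
#'
#' The reference stressor (for example climate change from shipping
#' emissions) scales with both mass and distance; the alien-species impact
#' scales with mass only. Reference CFs are user-supplied constants per
#' kg x km of the chosen transport inventory.
#'
#' @param mass_kg Transported mass (kg).
#' @param distance_km Transport distance (km).
#' @param alien_cf Alien-species CF (PDF x year per kg).
#' @param reference_cf_per_kgkm Reference CF (PDF x year per kg x km).
#' @return Tibble `alien_impact, reference_impact, ratio` (alien over
#'   reference), all in PDF x year.
#' @examples
#' compare_with_reference(1000, 10000, 2e-15, 1e-19)
#' @export
compare_with_reference <- function(mass_kg, distance_km, alien_cf,
                                   reference_cf_per_kgkm) {
  assert_nonneg(mass_kg, "`mass_kg`")
  assert_nonneg(distance_km, "`distance_km`")
  if (any(reference_cf_per_kgkm < 0) || any(alien_cf < 0)) {
    abort("Characterization factors must be non-negative.")
  }
  alien <- mass_kg * alien_cf
  ref <- mass_kg * distance_km * reference_cf_per_kgkm
  tibble::tibble(
    alien_impact = alien,
    reference_impact = ref,
    ratio = ifelse(ref > 0, alien / ref, NA_real_)
  )
}

#' Run the full pipeline on a synthetic world
#'
#' Chains panel construction, count-model fitting, fate factors, effect
#' factors and characterization factors; the single entry point used by the
#' command-line interface and the acceptance script.
#'
#' @param world An `invacf_world` or the table list from [world_from_csv()].
#' @param year_range Study period.
#' @param taus Quantiles for the effect factor.
#' @param nboot Bootstrap resamples for the effect-factor CI (0 = none).
#' @param seed Seed for the bootstrap.
#' @param spec Count-model specification.
#' @return List with `panel`, `fit`, `ff`, `effect_rows`, `ef` (full table),
#'   `ef_headline` (tau = 0.05, `dd_predicted`), and `cf`.
#' @export
run_pipeline <- function(world, year_range = c(1870L, 2019L),
                         taus = c(0.05, 0.10, 0.15), nboot = 0,
                         seed = NULL, spec = model_spec()) {
  panel <- build_panel(world, year_range)
  fit <- fit_nb_glmm(panel, spec)
  aliens <- count_aliens(world$first_records)
  ff <- fate_factors(fit, panel, aliens = aliens)
  rows <- effect_rows(world$threats, world$natives, world$first_records,
                      world$countries)
  ef <- effect_factor(rows, taus = taus, nboot = nboot, seed = seed)
  headline <- ef[ef$tau == 0.05 & ef$dd_option == "dd_predicted", ]
  cf <- characterization_factors(ff, headline$slope[1], world$gep)
  list(panel = panel, fit = fit, ff = ff, effect_rows = rows, ef = ef,
       ef_headline = headline, cf = cf)
}
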