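#' Configuration of a synthetic world
#'
#' Bundles every parameter of the synthetic-data generator: the planted
#' fixed-effect coefficients of the count model, its negative-binomial
#' dispersion, random-effect standard deviations, the planted effect-factor
#' slope relating country-level PDF to the alien species fraction, and the
#' scale of the strictly non-negative confounder noise added to PDF. The
#' generative count model is exactly the model the fitting stage estimates, so
#' refitting a generated world recovers the planted parameters.
#'
#' @param seed Integer seed; identical configurations generate identical
#'   worlds.
#' @param n_countries Number of countries (>= 3).
#' @param n_species Number of vascular-plant species in the global pool
#'   (>= 10). Each species is native to exactly one country.
#' @param year_range Two calendar years (start, end); the period length must
#'   be a multiple of 10. Default 1870--2019 (15 decade timesteps).
#' @param beta Named numeric vector of fixed effects on the log link:
#'   `intercept`, `log_tr` (z-scored log1p cumulative trade, kg), `distance`
#'   (per km), `log_s_e` (log exporter species-pool size), `log_s_i` (log
#'   importer native richness).
#' @param theta Negative-binomial dispersion (> 0); the variance of a count
#'   with mean `mu` is `mu + mu^2 / theta`.
#' @param re_sd Named standard deviations (>= 0) of the random intercepts for
#'   `importer_period` and `exporter_period`.
#' @param ef_slope Planted PDF-per-ASF slope (>= 0).
#' @param confounder_scale Scale of the half-normal, strictly non-negative
#'   extra-threat noise added to each country's PDF (>= 0).
#' @param mass_years,money_years Calendar windows over which transported mass
#'   (kg) and monetary flows are observed, emulating a recent physical-trade
#'   window and a long historical monetary record.
#' @param trade_growth Exponential yearly growth rate of trade volumes.
#' @param trade_level_meanlog,trade_level_sdlog Log-normal parameters of the
#'   per-pair base trade level (kg/yr).
#' @param trade_year_sdlog Log-normal sd of year-to-year trade noise.
#' @param price_noise_sd Log-normal sd of the price factor converting mass to
#'   monetary value; 0 makes money exactly proportional to mass.
#' @param natives_sdlog Log-normal sd of relative native richness across
#'   countries.
#' @param dd_rate Fraction of assessed native species labelled Data Deficient.
#' @param unknown_severity_rate Fraction of native species whose only threat
#'   row has severity "unknown" (excluded from the PDF denominator).
#' @return An object of class `invacf_world_config`.
#' @seealso [generate_world()]
#' @export
world_config <- function(seed = 1L,
                         n_countries = 25L,
                         n_species = 20000L,
                         year_range = c(1870L, 2019L),
                         beta = c(intercept = -7.4,
                                  log_tr = 9.3e-3,
                                  distance = -3.6e-5,
                                  log_s_e = 8.4e-1,
                                  log_s_i = 3.3e-1),
                         theta = 1,
                         re_sd = c(importer_period = 0.5,
                                   exporter_period = 0.5),
                         ef_slope = 0.038,
                         confounder_scale = 0.03,
                         mass_years = c(1995L, 2019L),
                         money_years = c(1870L, 2014L),
                         trade_growth = 0.02,
                         trade_level_meanlog = log(5e5),
                         trade_level_sdlog = 2,
                         trade_year_sdlog = 0.3,
                         price_noise_sd = 0.05,
                         natives_sdlog = 0.4,
                         dd_rate = 0.06,
                         unknown_severity_rate = 0.05) {
  check_year_range(year_range)
  decade_endpoints(year_range[1], year_range[2]) # validates divisibility
  if (n_countries < 3) abort("`n_countries` must be at least 3.")
  if (n_species < 10) abort("`n_species` must be at least 10.")
  if (!is.finite(theta) || theta <= 0) abort("`theta` must be positive.")
  if (any(re_sd < 0)) abort("all `re_sd` must be non-negative.")
  if (ef_slope < 0) abort("`ef_slope` must be non-negative.")
  if (confounder_scale < 0) abort("`confounder_scale` must be non-negative.")
  needed <- c("intercept", "log_tr", "distance", "log_s_e", "log_s_i")
  if (!all(needed %in% names(beta))) {
    abort(sprintf("`beta` must name all of: %s", paste(needed, collapse = ", ")))
  }
  if (!all(c("importer_period", "exporter_period") %in% names(re_sd))) {
    abort("`re_sd` must name importer_period and exporter_period.")
  }
  structure(
    list(
      seed = as.integer(seed), n_countries = as.integer(n_countries),
      n_species = as.integer(n_species),
      year_range = as.integer(year_range),
      beta = beta[needed], theta = theta,
      re_sd = re_sd[c("importer_period", "exporter_period")],
      ef_slope = ef_slope, confounder_scale = confounder_scale,
      mass_years = as.integer(mass_years), money_years = as.integer(money_years),
      trade_growth = trade_growth,
      trade_level_meanlog = trade_level_meanlog,
      trade_level_sdlog = trade_level_sdlog,
      trade_year_sdlog = trade_year_sdlog,
      price_noise_sd = price_noise_sd,
      natives_sdlog = natives_sdlog,
      dd_rate = dd_rate,
      unknown_severity_rate = unknown_severity_rate
    ),
    class = "invacf_world_config"
  )
}

# sample() that never falls into the scalar-x trap
resample <- function(x, size) x[sample.int(length(x), size)]

#' Generate a synthetic world with recorded ground truth
#'
#' Draws a self-consistent world: countries with areas, centroids and native
#' species pools; bilateral trade mass and monetary flows; alien first records
#' realised from negative-binomial introduction counts whose log-link linear
#' predictor is built exactly as the fitting stage builds it; and Red-List
#' style threat records that encode a planted PDF-vs-ASF slope plus strictly
#' non-negative confounder noise.
#'
#' Species are native to exactly one country, and when counts are realised the
#' generator prefers never-before-exported natives of the exporting country,
#' so that exporter attribution of each first record is unambiguous and the
#' panel reconstructed by [attribute_introductions()] and [aggregate_panel()]
#' reproduces the latent counts exactly. Draws that had to fall back on shared
#' (already-travelled) species or were truncated by pool exhaustion are logged
#' in `truth$n_fallback` / `truth$n_truncated`. Species pools are updated
#' decade-wise; realised first records carry the year `decade_start + 1` so
#' the pool a fitter evaluates at the decade's first year and the candidate
#' check at the year before the record both see exactly the previous decades'
#' arrivals.
#'
#' @param config An [world_config()] object.
#' @return An object of class `invacf_world`: a list of tibbles (`countries`,
#'   `natives`, `distances`, `gep`, `trade_mass`, `trade_money`,
#'   `first_records`, `threats`) plus `truth`, which echoes the configuration
#'   and records the latent pair-by-decade panel, realised random effects, the
#'   trade-scaling constants, per-country effect rows, and truncation logs.
#' @examples
#' w <- generate_world(world_config(seed = 1, n_countries = 5, n_species = 500))
#' w$truth$panel
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "invacf_world_config"))
  set.seed(config$seed)
  n_c <- config$n_countries
  n_s <- config$n_species
  yr <- config$year_range
  ends <- decade_endpoints(yr[1], yr[2])

  ## -- countries ------------------------------------------------------------
  ids <- sprintf("C%03d", seq_len(n_c))
  countries <- tibble::tibble(
    id = ids,
    area_km2 = rlnorm(n_c, log(3e5), 1.5),
    lon = runif(n_c, -180, 180),
    lat = asin(runif(n_c, -1, 1)) * 180 / pi
  )

  ## -- native ranges: each species native to exactly one country ------------
  w_nat <- rlnorm(n_c, 0, config$natives_sdlog)
  n_nat <- floor(n_s * w_nat / sum(w_nat))
  rem <- n_s - sum(n_nat)
  if (rem > 0) {
    top <- order(w_nat, decreasing = TRUE)[seq_len(rem)]
    n_nat[top] <- n_nat[top] + 1L
  }
  species_country <- rep(seq_len(n_c), times = n_nat) # index by species id
  natives <- tibble::tibble(
    species = sprintf("S%05d", seq_len(n_s)),
    country = ids[species_country]
  )
  natives_of <- split(seq_len(n_s), species_country)

  ## -- GEP ------------------------------------------------------------------
  gep <- tidyr::expand_grid(
    country = ids,
    taxon_group = c("amphibians", "birds", "mammals")
  )
  gep$gep <- rbeta(nrow(gep), 2, 100)

  ## -- distances ------------------------------------------------------------
  pairs <- tidyr::expand_grid(exporter = ids, importer = ids)
  pairs <- pairs[pairs$exporter != pairs$importer, ]
  ei <- match(pairs$exporter, ids)
  ii <- match(pairs$importer, ids)
  pairs$km <- haversine_km(countries$lon[ei], countries$lat[ei],
                           countries$lon[ii], countries$lat[ii])
  distances <- pairs

  ## -- trade ----------------------------------------------------------------
  years <- yr[1]:yr[2]
  n_p <- nrow(pairs)
  level <- rlnorm(n_p, config$trade_level_meanlog, config$trade_level_sdlog)
  growth <- exp(config$trade_growth * (years - yr[1]))
  mass <- outer(level, growth) *
    matrix(rlnorm(n_p * length(years), 0, config$trade_year_sdlog),
           n_p, length(years))
  trade_full <- tibble::tibble(
    exporter = rep(pairs$exporter, times = length(years)),
    importer = rep(pairs$importer, times = length(years)),
    year = rep(years, each = n_p),
    kg = as.vector(mass)
  )
  money_years <- config$money_years[1]:config$money_years[2]
  money_idx <- match(money_years, years)
  money <- mass[, money_idx, drop = FALSE] *
    matrix(rlnorm(n_p * length(money_years), 0, config$price_noise_sd),
           n_p, length(money_years))
  trade_money <- tibble::tibble(
    exporter = rep(pairs$exporter, times = length(money_years)),
    importer = rep(pairs$importer, times = length(money_years)),
    year = rep(money_years, each = n_p),
    value = as.vector(money)
  )
  mass_years <- config$mass_years[1]:config$mass_years[2]
  trade_mass <- trade_full[trade_full$year %in% mass_years, ]
  names(trade_mass) <- c("exporter", "importer", "year", "kg")

  ## cumulative transported quantity at each decade endpoint (true mass)
  cum_all <- t(apply(mass, 1, cumsum))
  tr_mat <- cum_all[, match(ends, years), drop = FALSE] # n_p x 15

  ## scaling for the z-scored log trade covariate (computed on the full panel)
  log_tr_all <- log1p(as.vector(tr_mat))
  sd_tr <- sd(log_tr_all)
  if (!is.finite(sd_tr) || sd_tr == 0) sd_tr <- 1 # degenerate: no-trade world
  scaling <- c(mean = mean(log_tr_all), sd = sd_tr)

  ## -- realise introduction counts decade by decade -------------------------
  b <- config$beta
  s_i_nat <- n_nat # constant importer native richness
  present <- matrix(FALSE, n_s, n_c) # species present in country
  present[cbind(seq_len(n_s), species_country)] <- TRUE
  unexported <- rep(TRUE, n_s)
  aliens_of <- vector("list", n_c) # integer species ids, aliens present
  for (k in seq_len(n_c)) aliens_of[[k]] <- integer(0)

  n_fallback <- 0L
  n_truncated <- 0L
  rec_species <- integer(0)
  rec_country <- integer(0)
  rec_year <- integer(0)
  panel_rows <- vector("list", length(ends))
  re_rows <- vector("list", length(ends))

  for (d in seq_along(ends)) {
    start_y <- ends[d] - 9L
    s_e_pool <- colSums(present) # pool size at decade start
    u_ip <- rnorm(n_c, 0, config$re_sd[["importer_period"]])
    u_ep <- rnorm(n_c, 0, config$re_sd[["exporter_period"]])
    z_tr <- (log1p(tr_mat[, d]) - scaling[["mean"]]) / scaling[["sd"]]
    eta <- b[["intercept"]] + b[["log_tr"]] * z_tr +
      b[["distance"]] * pairs$km +
      b[["log_s_e"]] * log(s_e_pool[ei]) +
      b[["log_s_i"]] * log(s_i_nat[ii]) +
      u_ip[ii] + u_ep[ei]
    as_latent <- rnbinom(n_p, mu = exp(eta), size = config$theta)

    claimed <- vector("list", n_c) # species claimed per importer this decade
    for (k in seq_len(n_c)) claimed[[k]] <- integer(0)
    as_real <- integer(n_p)
    ord <- order(pairs$exporter, pairs$importer)
    for (r in ord) {
      k <- as_latent[r]
      if (k == 0L) next
      e <- ei[r]; i <- ii[r]
      nat_e <- natives_of[[e]]
      pref <- nat_e[unexported[nat_e]]
      if (length(claimed[[i]])) pref <- setdiff(pref, claimed[[i]])
      chosen <- resample(pref, min(k, length(pref)))
      if (length(chosen) < k) {
        fb <- aliens_of[[e]]
        fb <- fb[!present[fb, i, drop = TRUE]]
        fb <- setdiff(fb, claimed[[i]])
        extra <- resample(fb, min(k - length(chosen), length(fb)))
        n_fallback <- n_fallback + length(extra)
        chosen <- c(chosen, extra)
      }
      if (length(chosen) < k) n_truncated <- n_truncated + (k - length(chosen))
      if (length(chosen)) {
        claimed[[i]] <- c(claimed[[i]], chosen)
        unexported[chosen] <- FALSE
        rec_species <- c(rec_species, chosen)
        rec_country <- c(rec_country, rep(i, length(chosen)))
        rec_year <- c(rec_year, rep(start_y + 1L, length(chosen)))
      }
      as_real[r] <- length(chosen)
    }
    for (k in seq_len(n_c)) {
      if (length(claimed[[k]])) {
        present[claimed[[k]], k] <- TRUE
        aliens_of[[k]] <- c(aliens_of[[k]], claimed[[k]])
      }
    }
    panel_rows[[d]] <- tibble::tibble(
      exporter = pairs$exporter, importer = pairs$importer,
      decade_end = ends[d], TR = tr_mat[, d], D = pairs$km,
      S_e = as.integer(s_e_pool[ei]), S_i = as.integer(s_i_nat[ii]),
      AS = as_real, AS_latent = as_latent
    )
    re_rows[[d]] <- tibble::tibble(
      decade_end = ends[d], country = ids,
      u_importer_period = u_ip, u_exporter_period = u_ep
    )
  }
  panel <- dplyr::bind_rows(panel_rows)
  first_records <- tibble::tibble(
    species = sprintf("S%05d", rec_species),
    country = ids[rec_country],
    year = rec_year
  )

  ## -- threat records encoding the planted PDF ~ ASF relationship -----------
  n_alien <- colSums(present) - n_nat
  asf_i <- n_alien / (n_alien + n_nat)
  eps <- abs(rnorm(n_c, 0, config$confounder_scale))
  pdf_target <- config$ef_slope * asf_i + eps

  threat_rows <- vector("list", n_c)
  eff_rows <- vector("list", n_c)
  qual_sev <- c("slow_significant", "rapid", "very_rapid")
  for (k in seq_len(n_c)) {
    nat <- natives_of[[k]]
    n_unknown <- round(config$unknown_severity_rate * length(nat))
    unk <- resample(nat, n_unknown)
    assessed <- setdiff(nat, unk)
    s_assessed <- length(assessed)
    n_q <- min(round(pdf_target[k] * s_assessed), s_assessed)
    q <- resample(assessed, n_q)
    non_q <- setdiff(assessed, q)
    n_dd <- round(config$dd_rate * s_assessed)
    dd <- resample(assessed, n_dd)
    cat_of <- rep(NA_character_, length(nat))
    names(cat_of) <- as.character(nat)
    cat_of[as.character(q)] <- sample(c("VU", "EN", "CR", "EX"), n_q,
                                      replace = TRUE,
                                      prob = c(0.45, 0.3, 0.2, 0.05))
    cat_of[as.character(non_q)] <- sample(c("LC", "NT"), length(non_q),
                                          replace = TRUE, prob = c(0.85, 0.15))
    cat_of[as.character(unk)] <- "LC"
    cat_of[as.character(dd)] <- "DD"
    dd_in_q <- intersect(dd, q)
    predicted <- dd_in_q[runif(length(dd_in_q)) < 0.7]

    code <- rep("2.1", length(nat))
    names(code) <- as.character(nat)
    code[as.character(q)] <- "8.1"
    sev <- rep(NA_character_, length(nat))
    names(sev) <- as.character(nat)
    sev[as.character(q)] <- sample(qual_sev, n_q, replace = TRUE)
    sev[as.character(non_q)] <- sample(c("none", "slow_significant"),
                                       length(non_q), replace = TRUE,
                                       prob = c(0.8, 0.2))
    sev[as.character(unk)] <- "unknown"
    code[as.character(unk)] <- "2.1"

    dd_flag <- rep(NA, length(nat))
    names(dd_flag) <- as.character(nat)
    dd_flag[as.character(dd)] <- FALSE
    dd_flag[as.character(predicted)] <- TRUE

    threat_rows[[k]] <- tibble::tibble(
      species = sprintf("S%05d", nat),
      country = ids[k],
      category = unname(cat_of[as.character(nat)]),
      threat_code = unname(code[as.character(nat)]),
      severity = unname(sev[as.character(nat)]),
      dd_predicted_threatened = unname(dd_flag[as.character(nat)])
    )
    n_not <- length(setdiff(q, dd))
    eff_rows[[k]] <- tibble::tibble(
      country = ids[k], asf = asf_i[k], pdf_target = pdf_target[k],
      pdf_dd_predicted = (n_not + length(predicted)) / s_assessed,
      pdf_dd_not_threatened = n_not / s_assessed,
      pdf_dd_threatened = (n_not + length(dd_in_q)) / s_assessed,
      n_assessed = s_assessed
    )
  }
  threats <- dplyr::bind_rows(threat_rows)

  structure(
    list(
      countries = countries,
      natives = natives,
      distances = distances,
      gep = gep,
      trade_mass = trade_mass,
      trade_money = trade_money,
      first_records = first_records,
      threats = threats,
      truth = list(
        config = config,
        scaling = scaling,
        panel = panel,
        trade_mass_full = trade_full,
        random_effects = dplyr::bind_rows(re_rows),
        effect_rows = dplyr::bind_rows(eff_rows),
        n_fallback = n_fallback,
        n_truncated = n_truncated
      )
    ),
    class = "invacf_world"
  )
}

#' @export
print.invacf_world <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(
    "<invacf_world> %d countries, %d species, %d-%d (seed %d)\n",
    cfg$n_countries, cfg$n_species, cfg$year_range[1], cfg$year_range[2],
    cfg$seed
  ))
  cat(sprintf(
    "  first records: %d | latent introductions: %d (fallback %d, truncated %d)\n",
    nrow(x$first_records), sum(x$truth$panel$AS_latent),
    x$truth$n_fallback, x$truth$n_truncated
  ))
  invisible(x)
}

#' Simulate country-level effect rows with a planted slope
#'
#' Generates the country table consumed by the effect-factor stage directly:
#' alien species fractions, PDF values equal to `ef_slope * ASF` plus
#' half-normal (strictly non-negative) confounder noise, areas and the
#' log10-area weights. This is the fixture for quantile-slope recovery at the
#' sample size of the country-level analysis (140 countries) without the
#' discretisation that per-species threat records impose.
#'
#' @param n Number of countries.
#' @param ef_slope Planted PDF-per-ASF slope.
#' @param confounder_scale Half-normal scale of the additive PDF noise.
#' @param seed Optional integer seed.
#' @return Tibble with columns `country`, `asf`, `pdf`, `area_km2`, `weight`.
#' @export
simulate_effect_rows <- function(n = 140, ef_slope = 0.038,
                                 confounder_scale = 0.03, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  asf <- rbeta(n, 2, 5)
  area <- rlnorm(n, log(3e5), 1.5)
  tibble::tibble(
    country = sprintf("C%03d", seq_len(n)),
    asf = asf,
    pdf = ef_slope * asf + abs(rnorm(n, 0, confounder_scale)),
    area_km2 = area,
    weight = pmax(log10(area), 1)
  )
}

#' Write a synthetic world to CSV files
#'
#' Writes the eight plain-text tables the pipeline readers accept
#' (`countries.csv`, `distances.csv`, `gep.csv`, `natives.csv`,
#' `first_records.csv`, `trade_mass.csv`, `trade_money.csv`, `threats.csv`)
#' plus `config.yaml` echoing the generator configuration. Ground truth is not
#' written; it lives only on the in-memory object.
#'
#' @param world An `invacf_world`.
#' @param dir Writable directory (created if absent).
#' @return `dir`, invisibly.
#' @export
world_to_csv <- function(world, dir) {
  stopifnot(inherits(world, "invacf_world"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create directory '%s'.", dir))
  }
  wr <- function(df, name) {
    path <- file.path(dir, name)
    tryCatch(readr::write_csv(df, path),
             error = function(e) abort(sprintf(
               "Failed writing '%s': %s", path, conditionMessage(e))))
  }
  wr(world$countries, "countries.csv")
  wr(world$distances, "distances.csv")
  wr(world$gep, "gep.csv")
  wr(world$natives, "natives.csv")
  wr(world$first_records, "first_records.csv")
  wr(world$trade_mass, "trade_mass.csv")
  wr(world$trade_money, "trade_money.csv")
  wr(world$threats, "threats.csv")
  cfg <- world$truth$config
  yaml::write_yaml(
    lapply(unclass(cfg), function(x) if (is.numeric(x)) as.list(x) else x),
    file.path(dir, "config.yaml")
  )
  invisible(dir)
}

#' Read a world back from CSV files
#'
#' Counterpart of [world_to_csv()]; returns the same tables as tibbles (without
#' ground truth). Reading a freshly written world reproduces the written
#' tables exactly.
#'
#' @param dir Directory holding the CSV files.
#' @return A list of tibbles with class `invacf_world_csv`.
#' @export
world_from_csv <- function(dir) {
  # base read.csv: its double parser is correctly rounded, so numbers written
  # by the shortest-round-trip writer come back bit-identical
  rd <- function(name, classes) {
    path <- file.path(dir, name)
    if (!file.exists(path)) abort(sprintf("Missing input file '%s'.", path))
    tibble::as_tibble(utils::read.csv(path, colClasses = classes))
  }
  structure(
    list(
      countries = rd("countries.csv",
                     c("character", "numeric", "numeric", "numeric")),
      distances = rd("distances.csv", c("character", "character", "numeric")),
      gep = rd("gep.csv", c("character", "character", "numeric")),
      natives = rd("natives.csv", c("character", "character")),
      first_records = rd("first_records.csv",
                         c("character", "character", "integer")),
      trade_mass = rd("trade_mass.csv",
                      c("character", "character", "integer", "numeric")),
      trade_money = rd("trade_money.csv",
                       c("character", "character", "integer", "numeric")),
      threats = rd("threats.csv",
                   c("character", "character", "character", "character",
                     "character", "logical"))
    ),
    class = "invacf_world_csv"
  )
}
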