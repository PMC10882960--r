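toy_threats <- function() {
  # country X: 10 natives, all assessed; 2 qualify (threatened category with
  # an invasive-alien threat in declining severity)
  tibble::tibble(
    species = sprintf("t%02d", 1:10),
    country = "X",
    category = c("VU", "EN", rep("LC", 7), "NT"),
    threat_code = c("8.1", "8.1.1", rep("2.1", 8)),
    severity = c("rapid", "slow_significant", rep("none", 8)),
    dd_predicted_threatened = NA
  )
}

test_that("the PDF is a hand-countable share of assessed natives", {
  out <- compute_pdf(toy_threats())
  expect_equal(out$pdf, 0.2)
  expect_equal(out$n_assessed, 10L)

  # all least-concern: zero
  all_lc <- dplyr::mutate(toy_threats(), category = "LC")
  expect_equal(compute_pdf(all_lc)$pdf, 0)

  # a threatened species without an invasive-alien threat row does not count
  wrong_code <- dplyr::mutate(
    toy_threats(),
    threat_code = ifelse(species == "t01", "2.1", threat_code)
  )
  expect_equal(compute_pdf(wrong_code)$pdf, 0.1)

  # severity "unknown" drops a species from the denominator
  unk <- dplyr::mutate(
    toy_threats(),
    severity = ifelse(species == "t10", "unknown", severity)
  )
  expect_equal(compute_pdf(unk)$n_assessed, 9L)
  expect_equal(compute_pdf(unk)$pdf, 2 / 9)

  # vocabulary is closed
  expect_error(compute_pdf(dplyr::mutate(toy_threats(),
                                         category = "XX")), "category")
  expect_error(compute_pdf(dplyr::mutate(toy_threats(),
                                         severity = "huge")), "severity")

  # empty denominator excludes the country with a message
  none <- dplyr::mutate(toy_threats(), severity = "unknown")
  expect_message(out0 <- compute_pdf(none), "Excluded")
  expect_equal(nrow(out0), 0L)
})

test_that("data-deficient options differ by exactly the DD species", {
  # one DD species with an invasive-alien declining threat, predicted
  # threatened: the three options differ by 1/denominator steps
  th <- dplyr::bind_rows(
    toy_threats(),
    tibble::tibble(
      species = "t11", country = "X", category = "DD",
      threat_code = "8.1", severity = "very_rapid",
      dd_predicted_threatened = TRUE
    )
  )
  p_pred <- compute_pdf(th, "dd_predicted")$pdf
  p_not <- compute_pdf(th, "dd_not_threatened")$pdf
  p_thr <- compute_pdf(th, "dd_threatened")$pdf
  expect_equal(p_not, 2 / 11)
  expect_equal(p_pred, 3 / 11)
  expect_equal(p_thr, 3 / 11)
  # flip the prediction flag: dd_predicted falls back to the lower count
  th2 <- dplyr::mutate(th, dd_predicted_threatened =
                         ifelse(species == "t11", FALSE, NA))
  expect_equal(compute_pdf(th2, "dd_predicted")$pdf, 2 / 11)
  expect_equal(compute_pdf(th2, "dd_threatened")$pdf, 3 / 11)

  # monotonicity across options on a generated world
  w <- small_world()
  rows <- effect_rows(w$threats, w$natives, w$first_records, w$countries)
  expect_true(all(rows$pdf_dd_not_threatened <= rows$pdf_dd_predicted))
  expect_true(all(rows$pdf_dd_predicted <= rows$pdf_dd_threatened))
})

test_that("country ASF shares the fraction definition", {
  natives <- tibble::tibble(
    species = c("n1", "n2", "n3"), country = c("A", "A", "B")
  )
  fr <- tibble::tibble(
    species = c("n3", "x1"), country = c("A", "A"), year = c(1900L, 1950L)
  )
  out <- country_asf(natives, fr)
  expect_equal(out$asf[out$country == "A"], 2 / 4) # 2 aliens, 2 natives
  expect_equal(out$asf[out$country == "B"], 0)
})

test_that("the exact solver minimises the weighted check loss", {
  # points exactly on a line: any quantile returns that line
  rows <- tibble::tibble(asf = c(0.1, 0.2, 0.4, 0.7),
                         pdf = 0.04 * c(0.1, 0.2, 0.4, 0.7),
                         weight = c(1, 2, 3, 1))
  for (tau in c(0.05, 0.5, 0.9)) {
    f <- weighted_quantile_fit(rows, tau)
    expect_equal(f$slope, 0.04, tolerance = 1e-12)
    expect_equal(f$intercept, 0, tolerance = 1e-12)
    expect_true(f$optimality$optimal)
  }

  # random instances: solution matches an independent brute-force
  # enumeration and satisfies the subgradient optimality condition
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    x <- runif(n)
    y <- 0.05 * x + abs(rnorm(n, 0, 0.02))
    w <- runif(n, 0.5, 3)
    tau <- sample(c(0.05, 0.1, 0.25, 0.5, 0.75), 1)
    rows_i <- tibble::tibble(asf = x, pdf = y, weight = w)
    f <- weighted_quantile_fit(rows_i, tau)
    oracle <- wqr_brute_force(x, y, w, tau)
    expect_equal(f$loss, oracle$loss, tolerance = 1e-10)
    expect_equal(f$slope, oracle$slope, tolerance = 1e-8)
    expect_equal(f$intercept, oracle$intercept, tolerance = 1e-8)
    expect_true(f$optimality$optimal)
    # weighted share of points strictly below the line is at most tau (and
    # strictly above at most 1 - tau)
    r <- y - f$intercept - f$slope * x
    on <- abs(r) <= 1e-9
    expect_lte(sum(w[r < 0 & !on]), tau * sum(w) + 1e-9)
    expect_lte(sum(w[r > 0 & !on]), (1 - tau) * sum(w) + 1e-9)
  }

  # degenerate x errors
  expect_error(
    weighted_quantile_fit(tibble::tibble(
      asf = c(0.1, 0.1, 0.1), pdf = c(0, 0.1, 0.2), weight = 1
    ), 0.05),
    "identical"
  )
})

test_that("the solver agrees with the simplex quantile-regression oracle", {
  set.seed(9)
  for (n in c(8, 40, 140)) {
    x <- rbeta(n, 2, 5)
    y <- 0.038 * x + abs(rnorm(n, 0, 0.03))
    w <- pmax(log10(rlnorm(n, log(3e5), 1.5)), 1)
    for (tau in c(0.05, 0.5)) {
      rows_i <- tibble::tibble(asf = x, pdf = y, weight = w)
      f <- weighted_quantile_fit(rows_i, tau)
      o <- quantreg::rq(y ~ x, tau = tau, weights = w)
      loss <- function(a, b) {
        r <- y - a - b * x
        sum(w * r * (tau - (r < 0)))
      }
      expect_equal(f$loss, loss(coef(o)[1], coef(o)[2]), tolerance = 1e-8)
      expect_equal(f$slope, unname(coef(o)[2]), tolerance = 1e-6)
    }
  }
})

test_that("bootstrap intervals are seeded and cover a planted slope", {
  rows <- simulate_effect_rows(n = 140, seed = 12)
  f1 <- weighted_quantile_fit(rows, 0.05, nboot = 100, seed = 7)
  f2 <- weighted_quantile_fit(rows, 0.05, nboot = 100, seed = 7)
  expect_equal(f1$ci_lower, f2$ci_lower)
  expect_equal(f1$ci_upper, f2$ci_upper)
  expect_lte(f1$ci_lower, f1$slope)
  expect_gte(f1$ci_upper, f1$slope)
})

test_that("effect factors sweep quantiles and DD options", {
  w <- small_world()
  rows <- effect_rows(w$threats, w$natives, w$first_records, w$countries)
  ef <- effect_factor(rows, nboot = 0)
  expect_equal(nrow(ef), 9L)
  expect_setequal(unique(ef$dd_option),
                  c("dd_predicted", "dd_not_threatened", "dd_threatened"))
  # a table with no DD differences collapses to identical fits
  rows_same <- dplyr::mutate(
    rows,
    pdf_dd_not_threatened = pdf_dd_predicted,
    pdf_dd_threatened = pdf_dd_predicted
  )
  ef_same <- effect_factor(rows_same, taus = 0.05, nboot = 0)
  expect_equal(length(unique(ef_same$slope)), 1L)

  # single-column input works and is labelled "pdf"
  ef_single <- effect_factor(simulate_effect_rows(n = 60, seed = 5),
                             taus = 0.05, nboot = 0)
  expect_equal(ef_single$dd_option, "pdf")
})

test_that("quantile slopes weakly increase with tau under one-sided noise", {
  # averaged over seeds so the property reflects the estimand, not one draw
  slopes <- sapply(1:8, function(s) {
    rows <- simulate_effect_rows(n = 140, seed = 100 + s)
    sapply(c(0.05, 0.10, 0.15),
           function(tt) weighted_quantile_fit(rows, tt)$slope)
  })
  m <- rowMeans(slopes)
  expect_true(all(diff(m) > -0.005))
})

test_that("a zero-slope world yields an effect factor near zero", {
  rows <- simulate_effect_rows(n = 140, ef_slope = 0, seed = 33)
  f <- weighted_quantile_fit(rows, 0.05, nboot = 200, seed = 1)
  expect_lt(abs(f$slope), 0.02)
  expect_lte(f$ci_lower, 1e-6)
})
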