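test_that("SMA slope is exact on cubic data and matches a brute-force oracle", {
  L <- c(12, 15, 17, 20, 24)
  expect_equal(fit_sma_slope(L^3, L), 3, tolerance = 1e-12)
  # scale invariance in mass: multiplying masses shifts only the intercept
  expect_equal(fit_sma_slope(5 * L^3, L), 3, tolerance = 1e-12)

  # noisy allometric sample vs first-principle sums
  set.seed(101)
  len <- runif(50, 12, 25)
  mass <- exp(3.1 * log(len) - 6 + rnorm(50, 0, 0.08))
  x <- log(len); y <- log(mass)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  b_ols <- sxy / sxx
  r <- sxy / sqrt(sxx * syy)
  expect_equal(fit_sma_slope(mass, len), b_ols / r, tolerance = 1e-12)
  expect_equal(fit_sma_slope(7 * mass, len), b_ols / r, tolerance = 1e-12)

  expect_error(fit_sma_slope(c(1, 2), c(1, 2)), ">= 3")
  expect_error(fit_sma_slope(c(1, 2, -1), c(1, 2, 3)), "positive")
  expect_error(fit_sma_slope(c(1, 2, 3), c(2, 2, 2)), "degenerate")
})

test_that("scaled mass index follows its closed form", {
  p <- smi_params(beta_sma = 3, reference_length = 20)
  expect_equal(scaled_mass_index(2, 10, p), 16)  # 2 * (20/10)^3
  # identity at the reference length and with exponent zero
  expect_equal(scaled_mass_index(1.37, 20, p), 1.37)
  p0 <- smi_params(beta_sma = 0, reference_length = 20)
  expect_equal(scaled_mass_index(2.2, 13, p0), 2.2)
  # scale equivariance in mass
  pd <- smi_params()  # study defaults: beta 3.203, L0 17.43
  expect_equal(pd$beta_sma, 3.203)
  expect_equal(pd$reference_length, 17.43)
  expect_equal(scaled_mass_index(3 * 0.21, 16.2, pd),
               3 * scaled_mass_index(0.21, 16.2, pd), tolerance = 1e-12)
  expect_error(scaled_mass_index(-1, 10, p), "domain")
})

test_that("coloration proportion is exact arithmetic with bounds", {
  expect_equal(coloration_proportion(10, 5, 100), 0.15)
  expect_equal(coloration_proportion(0, 0, 50), 0)
  expect_equal(coloration_proportion(30, 70, 100), 1)
  expect_error(coloration_proportion(10, 5, 0), "domain")
  expect_error(coloration_proportion(80, 30, 100), "exceeds")
  # fuzzed inputs stay in [0, 1]
  set.seed(7)
  for (i in 1:50) {
    body <- runif(1, 10, 200)
    o <- runif(1, 0, body / 2); bl <- runif(1, 0, body / 2)
    v <- coloration_proportion(o, bl, body)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("sperm vitality pools subsamples and respects bounds", {
  expect_equal(sperm_vitality(c(20, 30, 25), c(0, 0, 0)), 1)
  expect_equal(sperm_vitality(c(10, 10, 10), c(10, 10, 10)), 0.5)
  expect_equal(sperm_vitality(c(12, 8, 10), c(3, 2, 5)), 0.75)
  expect_error(sperm_vitality(c(0, 0), c(0, 0)), "undefined vitality")
  expect_error(sperm_vitality(c(-1, 2), c(1, 1)), "domain")
  set.seed(8)
  for (i in 1:50) {
    l <- rpois(3, 20); d <- rpois(3, 10)
    if (sum(l) + sum(d) == 0) next
    v <- sperm_vitality(l, d)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("sperm count averages subsamples and applies the scaling", {
  expect_equal(sperm_count(c(50, 50, 50), c(0, 0, 0), dilution_factor = 1), 50)
  expect_equal(sperm_count(c(30, 40, 45), c(10, 10, 15), 10), 500)
  expect_equal(sperm_count(c(0, 0, 0), c(0, 0, 0), 5), 0)
  expect_equal(sperm_count(c(20, 30), c(5, 5), 2, volume_scale = 50), 3000)
  expect_error(sperm_count(c(10, 10), c(1, 1)), "dilution_factor")
  expect_error(sperm_count(numeric(0), numeric(0), 1), "subsample")
})

test_that("mean VCL is the tracked-count-weighted average", {
  expect_equal(mean_vcl(c(100, 100), c(50, 80)), 100)
  expect_equal(mean_vcl(c(90, 120), c(30, 60)), 110)
  expect_equal(mean_vcl(75, 40), 75)
  # samples with zero tracked sperm are excluded
  expect_equal(mean_vcl(c(90, 120, 999), c(30, 60, 0)), 110)
  expect_equal(mean_vcl(c(90, 120), c(30, 60), weighting = "equal"), 105)
  expect_error(mean_vcl(c(80, 90), c(0, 0)), "undefined velocity")
})

test_that("standardization gives exact z-scores and round-trips", {
  dat <- generate_population(tiny_design(seed = 2), known_truth("paper-like"),
                             seed = 2)
  std <- standardize_traits(dat)
  for (tr in unique(std$table$trait)) {
    v <- std$table$value[std$table$trait == tr]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  # trial recoded to 0-based
  expect_equal(sort(unique(std$table$occasion)), c(0, 1, 2))
  back <- unstandardize_traits(std$table, std$params)
  expect_equal(back$value, dat$value, tolerance = 1e-12)
  expect_equal(back$occasion, dat$occasion)
  # zero-variance trait is rejected by name
  bad <- dat
  bad$value[bad$trait == "coloration"] <- 0.5
  expect_error(standardize_traits(bad), "coloration")
})

test_that("raw measurement tables produce the derived phenotypes", {
  morpho <- data.frame(
    individual_id = c("a", "b", "c", "d"),
    body_mass = c(0.20, 0.25, 0.30, 0.22),
    standard_length = c(16, 18, 19.5, 17),
    gonopodium_length = c(4.1, 4.5, 4.8, 4.2),
    body_area = c(120, 140, 160, 125),
    orange_area = c(12, 10, 20, 8),
    black_area = c(6, 9, 12, 6))
  out <- derive_morpho_traits(morpho, sma = smi_params())
  expect_equal(out$body_condition,
               morpho$body_mass * (17.43 / morpho$standard_length)^3.203)
  expect_equal(out$coloration[1], 18 / 120)
  vel <- data.frame(individual_id = c("a", "a", "b"),
                    vcl = c(90, 120, 80), n_tracked = c(30, 60, 50))
  cts <- data.frame(individual_id = rep(c("a", "b"), each = 3),
                    live = c(12, 8, 10, 20, 20, 20),
                    dead = c(3, 2, 5, 0, 0, 0),
                    dilution_factor = rep(c(10, 1), each = 3))
  ej <- derive_ejaculate_traits(vel, cts)
  expect_equal(ej$sperm_velocity[ej$individual_id == "a"], 110)
  expect_equal(ej$sperm_vitality[ej$individual_id == "a"], 0.75)
  expect_equal(ej$sperm_count[ej$individual_id == "a"], (15 + 10 + 15) / 3 * 10)
  expect_equal(ej$sperm_vitality[ej$individual_id == "b"], 1)
})
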