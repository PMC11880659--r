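test_that("paper-mirror design yields the expected table shape", {
  cfg <- paper_design(seed = 3)
  dat <- generate_population(cfg, known_truth("paper-like"))
  # 144 individuals; 2 behaviours x 3 trials + 6 single traits = 12 rows each
  expect_equal(length(unique(dat$individual_id)), 144)
  expect_equal(nrow(dat), 2 * 3 * 144 + 6 * 144)
  expect_equal(sort(unique(dat$treatment)), sort(c("control", "low", "high")))
  expect_equal(length(unique(dat$mesocosm_id)), 12)
  # single-measure traits have exactly one occasion per individual
  once <- dat[!dat$trait %in% pols_behaviours(), ]
  expect_true(all(table(once$individual_id, once$trait) == 1))
  beh <- dat[dat$trait %in% pols_behaviours(), ]
  expect_true(all(table(beh$individual_id, beh$trait) == 3))
})

test_that("generation is bit-identical given the same seed", {
  cfg <- tiny_design(seed = 9)
  truth <- known_truth("paper-like")
  d1 <- generate_population(cfg, truth, seed = 42)
  d2 <- generate_population(cfg, truth, seed = 42)
  expect_identical(d1, d2)
  d3 <- generate_population(cfg, truth, seed = 43)
  expect_false(identical(d1$value, d3$value))
})

test_that("degenerate generator returns the trait means exactly", {
  traits <- pols_traits()
  T_ <- length(traits)
  mu <- seq(-0.7, 0.7, length.out = T_)
  zeroS <- matrix(0, T_, T_)
  truth <- parameter_set(
    mu = mu, beta_treat = matrix(0, T_, 2),
    gamma_trial = c(0, 0), sigma_mesocosm = rep(0, T_),
    Sigma_B = list(zeroS, zeroS, zeroS),
    sigma_W = matrix(0, 3, 2), sigma_fixed = 0)
  dat <- generate_population(tiny_design(), truth, seed = 1)
  expect_equal(dat$value, mu[match(dat$trait, traits)], tolerance = 1e-12)
})

test_that("between-individual variance of trial means matches the law of total variance", {
  # Sigma_B = I, sigma_W = 1: var of per-individual behaviour means -> 1 + 1/3
  traits <- pols_traits()
  T_ <- length(traits)
  truth <- parameter_set(
    mu = rep(0, T_), beta_treat = matrix(0, T_, 2),
    gamma_trial = c(0, 0), sigma_mesocosm = rep(0, T_),
    Sigma_B = rep(list(diag(T_)), 3),
    sigma_W = matrix(1, 3, 2))
  cfg <- design_config(n_mesocosms_per_treatment = 4,
                       n_individuals_per_mesocosm = 170, seed = 5)
  dat <- generate_population(cfg, truth, seed = 5)  # 2040 individuals
  act <- dat[dat$trait == "activity", ]
  mns <- tapply(act$value, act$individual_id, mean)
  expect_equal(unname(var(mns)), 1 + 1 / 3, tolerance = 0.08)
  # once-measured trait: variance = Sigma_B + sigma_fixed^2
  gono <- dat[dat$trait == "gonopodium_length", ]
  expect_equal(unname(var(gono$value)), 1 + 0.01, tolerance = 0.08)
})

test_that("built-in scenarios satisfy their contracts", {
  expect_error(known_truth("unheard-of"), "arg")
  for (sc in c("null", "paper-like", "strong-syndrome")) {
    tr <- known_truth(sc)
    for (S in tr$Sigma_B) {
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      expect_true(all(ev > -1e-8))
    }
  }
  nl <- known_truth("null")
  expect_true(all(nl$beta_treat == 0))
  expect_true(all(sapply(nl$Sigma_B, function(S) all(S[upper.tri(S)] == 0))))
  pl <- known_truth("paper-like")
  # control males more plastic (higher within-individual variance) than low
  expect_gt(pl$sigma_W["control", "activity"], pl$sigma_W["low", "activity"])
  expect_gt(pl$sigma_W["control", "refuge_use"], pl$sigma_W["low", "refuge_use"])
  # negative activity/refuge syndrome in every treatment
  for (k in pl$treatment_names)
    expect_lt(pl$Sigma_B[[k]]["activity", "refuge_use"], 0)
})

test_that("dimension mismatches and invalid covariances are rejected", {
  cfg <- tiny_design()
  truth <- known_truth("null")
  cfg_bad <- cfg
  cfg_bad$trait_names <- cfg$trait_names[1:5]
  cfg_bad$repeated <- "activity"
  expect_error(generate_population(cfg_bad, truth, seed = 1),
               "configuration error")
  notpsd <- diag(8)
  notpsd[1, 2] <- notpsd[2, 1] <- 2
  expect_error(
    parameter_set(mu = rep(0, 8), beta_treat = matrix(0, 8, 2),
                  gamma_trial = c(0, 0), sigma_mesocosm = rep(0.1, 8),
                  Sigma_B = list(notpsd, diag(8), diag(8)),
                  sigma_W = matrix(0.5, 3, 2)),
    "positive semi-definite")
  expect_error(
    parameter_set(mu = rep(0, 8), beta_treat = matrix(0, 8, 3),
                  gamma_trial = c(0, 0), sigma_mesocosm = rep(0.1, 8),
                  Sigma_B = rep(list(diag(8)), 3),
                  sigma_W = matrix(0.5, 3, 2)),
    "reference coding")
})

test_that("ground truth round-trips through YAML", {
  truth <- known_truth("paper-like")
  f <- tempfile(fileext = ".yaml")
  write_truth(truth, f)
  back <- read_truth(f)
  expect_equal(back$mu, truth$mu)
  expect_equal(back$beta_treat, truth$beta_treat)
  expect_equal(back$Sigma_B, truth$Sigma_B, tolerance = 1e-9)
  expect_equal(back$sigma_W, truth$sigma_W, tolerance = 1e-9)
  unlink(f)
})
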