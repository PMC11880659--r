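test_that("paper-mirror data compiles to the expected structure", {
  dat <- generate_population(paper_design(seed = 4), known_truth("null"))
  mod <- build_model(mvmm_spec(), dat)
  expect_s3_class(mod, "pols_model")
  expect_equal(mod$T, 8)
  expect_equal(mod$K, 3)
  expect_equal(mod$nI, 144)
  expect_equal(mod$M, 12)
  expect_equal(mod$N, 1728)
  # 8 intercepts + 16 treatment offsets + 2 trial slopes
  expect_equal(mod$p, 26)
  # trial covariate left-centred: first trial = 0
  expect_equal(sort(unique(mod$trial_c)), c(0, 1, 2))
  # one complete-data pattern per treatment
  expect_equal(length(mod$patterns), 3)
})

test_that("structural violations are rejected with row references", {
  dat <- generate_population(tiny_design(seed = 5), known_truth("null"))
  bad <- dat
  bad$trait[1] <- "nonexistent"
  expect_error(build_model(mvmm_spec(), bad), "unknown trait")

  split_ind <- dat
  i1 <- split_ind$individual_id == "ind_001"
  split_ind$treatment[i1 & split_ind$trait == "activity"] <- "high"
  expect_error(build_model(mvmm_spec(), split_ind), "more than one")

  dup_occ <- dat
  extra <- dat[dat$trait == "coloration" & i1, ][1, ]
  extra$occasion <- 2
  dup_occ <- rbind(dup_occ, extra)
  expect_error(build_model(mvmm_spec(), dup_occ), "fixed residual")

  dup_key <- rbind(dat, dat[1, ])
  expect_error(build_model(mvmm_spec(), dup_key), "duplicate")
})

test_that("missing cells are skipped, not imputed", {
  dat <- generate_population(tiny_design(seed = 6), known_truth("null"))
  # drop all sperm traits for one individual (as for males without ejaculate)
  drop <- dat$individual_id == "ind_002" & grepl("^sperm", dat$trait)
  dat2 <- dat[!drop, ]
  mod <- build_model(mvmm_spec(), dat2)
  expect_equal(mod$N, nrow(dat) - 3)
  expect_equal(mod$nI, length(unique(dat$individual_id)))
  # the reduced individual forms its own pattern
  expect_gt(length(mod$patterns), 3)
  dr <- sample_posterior(mod, chains = 1, iter = 30, warmup = 10, thin = 1,
                         seed = 2)
  expect_false(anyNA(dr))
})

test_that("log density matches a brute-force term-by-term sum", {
  # 10 random tiny instances, <= 3 individuals and <= 2 traits
  for (rep in 1:10) {
    set.seed(rep)
    n_ind <- sample(2:3, 1)
    truth <- two_trait_truth(meso_sd = 0.3)
    cfg <- design_config(
      n_treatments = 1, n_mesocosms_per_treatment = 1,
      n_individuals_per_mesocosm = n_ind, n_trials_behaviour = 3,
      trait_names = c("activity", "body_condition"), repeated = "activity",
      treatment_names = "control", seed = rep)
    dat <- generate_population(cfg, truth, seed = rep)
    spec <- two_trait_spec(include_mesocosm = TRUE)
    mod <- build_model(spec, dat)
    par <- random_params(mod, seed = 100 + rep)
    expect_equal(log_density(par, mod, include_prior = TRUE),
                 brute_force_log_density(par, mod, include_prior = TRUE),
                 tolerance = 1e-10)
    expect_equal(log_density(par, mod, include_prior = FALSE),
                 brute_force_log_density(par, mod, include_prior = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("log density base cases: standard normal point and additivity", {
  spec <- mvmm_spec(trait_names = "resp", repeated = character(0),
                    treatment_names = "control", sigma_fixed = 1,
                    priors = prior_set(n_traits = 1),
                    include_mesocosm = FALSE, include_individual = FALSE)
  one <- data.frame(individual_id = "i1", mesocosm_id = "m1",
                    treatment = "control", trait = "resp", occasion = 1,
                    value = 0)
  mod1 <- build_model(spec, one)
  par <- list(theta = 0, b = matrix(0, 1, 1), u = matrix(0, 1, 1),
              sigma2_meso = 1, Sigma_B = list(diag(1)),
              sigma2_W = matrix(1, 1, 0))
  expect_equal(log_density(par, mod1, include_prior = FALSE),
               -0.5 * log(2 * pi), tolerance = 1e-12)
  # independent observations: log terms add exactly
  two <- rbind(one, data.frame(individual_id = "i2", mesocosm_id = "m1",
                               treatment = "control", trait = "resp",
                               occasion = 1, value = 1.7))
  mod2 <- build_model(spec, two)
  par2 <- par
  par2$u <- matrix(0, 2, 1)
  expect_equal(log_density(par2, mod2, include_prior = FALSE),
               log_density(par, mod1, include_prior = FALSE) +
                 dnorm(1.7, 0, 1, log = TRUE), tolerance = 1e-12)
})

test_that("non-positive-definite covariance yields -Inf, not an error", {
  dat <- generate_population(two_trait_design(n_ind = 3), two_trait_truth(),
                             seed = 3)
  mod <- build_model(two_trait_spec(), dat)
  par <- random_params(mod, seed = 1)
  par$Sigma_B[[1]] <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_identical(log_density(par, mod), -Inf)
})
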