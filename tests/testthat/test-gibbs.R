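test_that("conjugate toy model matches the closed-form posterior", {
  # one once-measured trait, residual SD pinned at 1, near-flat prior on mu:
  # posterior is N(sum(y) / (n + 1/tau2), 1 / (n + 1/tau2))
  n <- 40
  set.seed(42)
  yv <- rnorm(n, 1.3, 1)
  dat <- data.frame(individual_id = sprintf("i%02d", 1:n),
                    mesocosm_id = "m1", treatment = "control",
                    trait = "resp", occasion = 1, value = yv)
  spec <- mvmm_spec(trait_names = "resp", repeated = character(0),
                    treatment_names = "control",
                    priors = prior_set("flat", n_traits = 1),
                    sigma_fixed = 1, include_mesocosm = FALSE,
                    include_individual = FALSE)
  mod <- build_model(spec, dat)
  dr <- sample_posterior(mod, chains = 2, iter = 3000, warmup = 500,
                         thin = 1, seed = 8)
  tau2 <- 100
  post_var <- 1 / (n + 1 / tau2)
  post_mean <- post_var * sum(yv)
  ndr <- nrow(dr)
  mc_se_mean <- sqrt(post_var / ndr)           # draws are iid here
  mc_se_sd <- sqrt(post_var) / sqrt(2 * ndr)
  expect_lt(abs(mean(dr[, 1]) - post_mean), 3 * mc_se_mean)
  expect_lt(abs(sd(dr[, 1]) - sqrt(post_var)), 3 * mc_se_sd)
})

test_that("same seed reproduces draws bit for bit; settings give the draw count", {
  dat <- generate_population(tiny_design(seed = 3), known_truth("null"))
  mod <- build_model(mvmm_spec(), dat)
  d1 <- sample_posterior(mod, chains = 2, iter = 80, warmup = 30, thin = 2,
                         seed = 17)
  d2 <- sample_posterior(mod, chains = 2, iter = 80, warmup = 30, thin = 2,
                         seed = 17)
  expect_identical(unclass(d1), unclass(d2))
  expect_equal(nrow(d1), 2 * (80 - 30) / 2)
  d3 <- sample_posterior(mod, chains = 2, iter = 80, warmup = 30, thin = 2,
                         seed = 18)
  expect_false(identical(unclass(d1), unclass(d3)))
  # reference settings arithmetic: 4 x (8000 - 3000) / 2 = 10000
  expect_equal(4 * (8000 - 3000) / 2, 10000)
  expect_error(sample_posterior(mod, chains = 2, iter = 80, warmup = 30),
               "seed")
})

test_that("row order of the input table does not change the posterior", {
  dat <- generate_population(tiny_design(seed = 6), known_truth("paper-like"))
  set.seed(99)
  perm <- dat[sample.int(nrow(dat)), ]
  f1 <- quick_fit(dat, iter = 150, warmup = 50, seed = 4)
  f2 <- quick_fit(perm, iter = 150, warmup = 50, seed = 4)
  expect_identical(unclass(f1$draws), unclass(f2$draws))
})

test_that("prior-only sampling reproduces the stated priors", {
  dat <- generate_population(tiny_design(seed = 2), known_truth("null"))
  mod <- build_model(mvmm_spec(), dat)
  dr <- sample_posterior(mod, chains = 1, iter = 5000, warmup = 0, thin = 1,
                         seed = 5, prior_only = TRUE)
  pr <- mod$spec$priors
  ig_cdf <- function(q) 1 - pgamma(1 / q, pr$var_shape, rate = pr$var_rate)
  ks1 <- ks.test(dr[, "sd_meso[activity]"]^2, ig_cdf)
  expect_gt(ks1$p.value, 0.001)
  ks2 <- ks.test(dr[, "sd_W[low,refuge_use]"]^2, ig_cdf)
  expect_gt(ks2$p.value, 0.001)
  # fixed effects under their normal prior
  ks3 <- ks.test(dr[, "mu[activity]"], "pnorm", 0, pr$fixed_sd)
  expect_gt(ks3$p.value, 0.001)
  # correlation draws form valid matrices
  cors <- dr[, grep("^cor_B\\[", colnames(dr))]
  expect_true(all(cors >= -1 & cors <= 1))
})

test_that("fixed-effect posteriors barely move between prior flavours", {
  dat <- generate_population(paper_design(seed = 8), known_truth("paper-like"))
  spec_wi <- mvmm_spec(priors = prior_set("weakly_informative"))
  spec_fl <- mvmm_spec(priors = prior_set("flat"))
  f1 <- mvmm(dat, spec = spec_wi, chains = 2, iter = 1500, warmup = 500,
             thin = 1, seed = 11, check = FALSE)
  f2 <- mvmm(dat, spec = spec_fl, chains = 2, iter = 1500, warmup = 500,
             thin = 1, seed = 11, check = FALSE)
  expect_lt(max(abs(coef(f1) - coef(f2))), 0.1)
})

test_that("fit object methods are coherent", {
  dat <- generate_population(tiny_design(seed = 12, n_ind = 4),
                             known_truth("paper-like"))
  fit <- quick_fit(dat, iter = 300, warmup = 100, seed = 3)
  expect_s3_class(fit, "mvmm")
  expect_output(print(fit), "multivariate mixed model")
  expect_length(coef(fit), fit$model$p)
  expect_length(fitted(fit), fit$model$N)
  expect_equal(residuals(fit), fit$model$y - fitted(fit))
  # residuals should be small for fixed-variance traits (residual SD 0.1)
  rs <- residuals(fit)[fit$model$resid_id == 0]
  expect_lt(sd(rs), 0.3)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.mvmm")
  expect_true(all(c("trait", "term", "mean", "supported") %in%
                    names(sm$fixed)))
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), nrow(dat))
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  tab <- plot(fit)
  grDevices::dev.off()
  expect_true(all(tab$l95 <= tab$l89))
  unlink(f)
})
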