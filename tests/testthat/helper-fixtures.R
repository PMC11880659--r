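# Small shared fixtures for the test suite. Everything is generated in code;
# sizes are kept small so the whole suite runs quickly.

tiny_design <- function(seed = 1L, n_ind = 3L, n_meso = 2L, trials = 3L) {
  design_config(n_treatments = 3, n_mesocosms_per_treatment = n_meso,
                n_individuals_per_mesocosm = n_ind,
                n_trials_behaviour = trials, seed = seed)
}

paper_design <- function(seed = 1L) design_config(seed = seed)

quick_fit <- function(data, chains = 2, iter = 500, warmup = 200, thin = 1,
                      seed = 1, ...) {
  mvmm(data, chains = chains, iter = iter, warmup = warmup, thin = thin,
       seed = seed, check = FALSE, ...)
}

# two-trait single-treatment design used by focused sampler tests
two_trait_truth <- function(vb = c(0.35, 0.8), vw = 0.55, rho = 0.2,
                            gamma = -0.2, meso_sd = 0) {
  S <- matrix(c(vb[1], rho * sqrt(prod(vb)), rho * sqrt(prod(vb)), vb[2]), 2)
  parameter_set(
    mu = c(0.3, -0.2), beta_treat = matrix(0, 2, 0),
    gamma_trial = c(activity = gamma), sigma_mesocosm = rep(meso_sd, 2),
    Sigma_B = list(S), sigma_W = matrix(sqrt(vw), 1, 1),
    trait_names = c("activity", "body_condition"), repeated = "activity",
    treatment_names = "control")
}

two_trait_design <- function(n_ind = 60, seed = 1) {
  design_config(n_treatments = 1, n_mesocosms_per_treatment = 1,
                n_individuals_per_mesocosm = n_ind, n_trials_behaviour = 3,
                trait_names = c("activity", "body_condition"),
                repeated = "activity", treatment_names = "control",
                seed = seed)
}

two_trait_spec <- function(include_mesocosm = FALSE) {
  mvmm_spec(trait_names = c("activity", "body_condition"),
            repeated = "activity", treatment_names = "control",
            priors = prior_set(n_traits = 2),
            include_mesocosm = include_mesocosm)
}

# independently coded brute-force joint log posterior: plain loops over
# every observation, random effect and prior term
brute_force_log_density <- function(params, model, include_prior = TRUE) {
  spec <- model$spec
  pr <- spec$priors
  d <- model$data
  traits <- model$traits
  theta <- params$theta
  names(theta) <- model$coef_names
  total <- 0
  for (r in seq_len(nrow(d))) {
    tr <- d$trait[r]
    ti <- match(tr, traits)
    ki <- match(d$treatment[r], model$treatments)
    eta <- theta[paste0("mu[", tr, "]")]
    if (ki > 1)
      eta <- eta + theta[paste0("beta[", model$treatments[ki], ",", tr, "]")]
    if (tr %in% spec$repeated) {
      occ0 <- d$occasion[r] - min(d$occasion)
      eta <- eta + theta[paste0("gamma[", tr, "]")] * occ0
      sd_r <- sqrt(params$sigma2_W[ki, match(tr, spec$repeated)])
    } else sd_r <- spec$sigma_fixed
    if (spec$include_mesocosm)
      eta <- eta + params$b[match(d$mesocosm_id[r], model$meso_ids), ti]
    if (spec$include_individual)
      eta <- eta + params$u[match(d$individual_id[r], model$ind_ids), ti]
    z <- (d$value[r] - eta) / sd_r
    total <- total - 0.5 * log(2 * pi) - log(sd_r) - 0.5 * z^2
  }
  if (spec$include_mesocosm) {
    for (m in seq_len(model$M)) for (ti in seq_along(traits)) {
      s <- sqrt(params$sigma2_meso[ti])
      total <- total - 0.5 * log(2 * pi) - log(s) -
        0.5 * (params$b[m, ti] / s)^2
    }
  }
  if (spec$include_individual) {
    for (i in seq_len(model$nI)) {
      S <- params$Sigma_B[[model$ind_treat[i]]]
      ui <- params$u[i, ]
      total <- total - 0.5 * (length(ui) * log(2 * pi) +
        determinant(S, logarithm = TRUE)$modulus +
        drop(t(ui) %*% solve(S) %*% ui))
    }
  }
  if (include_prior) {
    for (th in params$theta)
      total <- total + dnorm(th, 0, pr$fixed_sd, log = TRUE)
    ig <- function(x, a, b) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
    if (spec$include_mesocosm)
      for (v in params$sigma2_meso)
        total <- total + ig(v, pr$var_shape, pr$var_rate)
    if (length(spec$repeated))
      for (v in as.numeric(params$sigma2_W))
        total <- total + ig(v, pr$var_shape, pr$var_rate)
    if (spec$include_individual) {
      T_ <- length(traits)
      S0 <- diag(pr$wishart_scale, T_)
      nu <- pr$wishart_df
      lmg <- T_ * (T_ - 1) / 4 * log(pi) +
        sum(lgamma(nu / 2 + (1 - seq_len(T_)) / 2))
      for (S in params$Sigma_B) {
        total <- total + nu / 2 *
          determinant(S0, logarithm = TRUE)$modulus -
          nu * T_ / 2 * log(2) - lmg -
          (nu + T_ + 1) / 2 * determinant(S, logarithm = TRUE)$modulus -
          0.5 * sum(diag(solve(S) %*% S0))
      }
    }
  }
  as.numeric(total)
}

# random valid parameter configuration for a model
random_params <- function(model, seed) {
  set.seed(seed)
  T_ <- model$T; K <- model$K; B <- model$B
  Sig <- lapply(seq_len(K), function(k) {
    A <- matrix(rnorm(T_ * (T_ + 2)), T_ + 2, T_)
    crossprod(A) / (T_ + 2)
  })
  list(theta = rnorm(model$p, 0, 0.5),
       b = matrix(rnorm(model$M * T_, 0, 0.3), model$M, T_),
       u = matrix(rnorm(model$nI * T_, 0, 0.5), model$nI, T_),
       sigma2_meso = runif(T_, 0.05, 0.5),
       Sigma_B = Sig,
       sigma2_W = matrix(runif(K * B, 0.1, 1), K, B))
}

# flatten a ground-truth parameter set into the sampler's column naming
truth_as_draw <- function(truth) {
  out <- c()
  tr <- truth$trait_names; trt <- truth$treatment_names
  out[paste0("mu[", tr, "]")] <- truth$mu
  for (k in trt[-1]) out[paste0("beta[", k, ",", tr, "]")] <-
      truth$beta_treat[, k]
  out[paste0("gamma[", truth$repeated, "]")] <- truth$gamma_trial
  out[paste0("sd_meso[", tr, "]")] <- truth$sigma_mesocosm
  for (k in trt) {
    S <- truth$Sigma_B[[k]]
    sdv <- sqrt(diag(S))
    R <- S / tcrossprod(sdv)
    out[paste0("sd_B[", k, ",", tr, "]")] <- sdv
    ut <- which(upper.tri(S), arr.ind = TRUE)
    out[paste0("cor_B[", k, ",", tr[ut[, 1]], ",", tr[ut[, 2]], "]")] <-
      R[upper.tri(R)]
  }
  for (k in trt) out[paste0("sd_W[", k, ",", truth$repeated, "]")] <-
      truth$sigma_W[k, ]
  out
}
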