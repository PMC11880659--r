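#' Draw multivariate normal deviates (internal)
#'
#' Symmetric (eigen) square root, so semi-definite covariance matrices are
#' accepted; draws are reproducible for a given RNG state.
#' @noRd
rmvnorm_chol <- function(n, Sigma) {
  d <- nrow(Sigma)
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  ev$values[ev$values < 0] <- 0
  A <- ev$vectors %*% (sqrt(ev$values) * t(ev$vectors))
  matrix(stats::rnorm(n * d), n, d) %*% A
}

#' Generate a synthetic population from the generative model
#'
#' Draws a long-format trait table from the exact generative mirror of the
#' fitted multivariate mixed model: for individual i in treatment k housed in
#' mesocosm m, the value of trait t on occasion o is
#' \deqn{y = \mu_t + \beta_{k,t} + \gamma_t (o - 1) + b_{m,t} + u_{i,t} +
#'   \varepsilon,}
#' with mesocosm effects \eqn{b_{m,t} \sim N(0, \sigma^2_{meso,t})}
#' independent across traits, individual effects
#' \eqn{u_i \sim MVN(0, \Sigma_B^{(k)})} (the treatment-specific
#' between-individual covariance), and residual SD equal to the treatment's
#' within-individual SD for repeated traits or `sigma_fixed` otherwise. The
#' trial slope \eqn{\gamma_t} exists only for repeated traits and acts on the
#' left-centred occasion index.
#'
#' @param config A [design_config()].
#' @param truth A [parameter_set()] whose dimensions match `config`.
#' @param seed Integer seed; defaults to `config$seed`. The output is
#'   bit-identical for identical `(config, truth, seed)`.
#' @return A `data.frame` of class `"pols_longtable"` with columns
#'   `individual_id`, `mesocosm_id`, `treatment`, `trait`, `occasion`,
#'   `value`; one row per individual x trait x occasion.
#' @export
generate_population <- function(config, truth, seed = config$seed) {
  stopifnot(inherits(config, "pols_design"), inherits(truth, "pols_truth"))
  if (!identical(config$trait_names, truth$trait_names) ||
      !identical(config$repeated, truth$repeated))
    stop("configuration error: trait roster of config and truth differ")
  if (config$n_treatments != length(truth$treatment_names))
    stop("configuration error: treatment count of config and truth differ")

  set.seed(as.integer(seed))
  traits <- config$trait_names
  T_ <- length(traits)
  rep_flag <- traits %in% config$repeated
  K <- config$n_treatments
  Mk <- config$n_mesocosms_per_treatment
  Jm <- config$n_individuals_per_mesocosm
  n_tr <- config$n_trials_behaviour
  treats <- truth$treatment_names

  M <- K * Mk
  nI <- M * Jm
  meso_treat <- rep(seq_len(K), each = Mk)
  ind_meso <- rep(seq_len(M), each = Jm)
  ind_treat <- meso_treat[ind_meso]

  # mesocosm effects: M x T, independent across traits
  b <- matrix(stats::rnorm(M * T_), M, T_) *
    matrix(truth$sigma_mesocosm, M, T_, byrow = TRUE)

  # individual effects: per treatment, MVN with that treatment's Sigma_B
  u <- matrix(0, nI, T_)
  for (k in seq_len(K)) {
    idx <- which(ind_treat == k)
    u[idx, ] <- rmvnorm_chol(length(idx), truth$Sigma_B[[k]])
  }

  occ_per_trait <- ifelse(rep_flag, n_tr, 1L)
  rows_per_ind <- sum(occ_per_trait)
  N <- nI * rows_per_ind

  trait_col <- rep(rep(seq_len(T_), times = occ_per_trait), times = nI)
  occ_col <- rep(unlist(lapply(occ_per_trait, seq_len)), times = nI)
  ind_col <- rep(seq_len(nI), each = rows_per_ind)
  meso_col <- ind_meso[ind_col]
  treat_col <- ind_treat[ind_col]

  gamma_full <- stats::setNames(rep(0, T_), traits)
  gamma_full[config$repeated] <- truth$gamma_trial[config$repeated]
  beta_full <- cbind(0, truth$beta_treat)  # reference column of zeros

  eta <- truth$mu[trait_col] +
    beta_full[cbind(trait_col, treat_col)] +
    gamma_full[trait_col] * (occ_col - 1) +
    b[cbind(meso_col, trait_col)] +
    u[cbind(ind_col, trait_col)]

  res_sd <- rep(truth$sigma_fixed, N)
  for (j in which(rep_flag)) {
    bj <- match(traits[j], truth$repeated)
    sel <- trait_col == j
    res_sd[sel] <- truth$sigma_W[treat_col[sel], bj]
  }
  value <- eta + stats::rnorm(N) * res_sd

  out <- data.frame(
    individual_id = sprintf("ind_%03d", ind_col),
    mesocosm_id = sprintf("meso_%02d", meso_col),
    treatment = treats[treat_col],
    trait = traits[trait_col],
    occasion = occ_col,
    value = value,
    stringsAsFactors = FALSE)
  class(out) <- c("pols_longtable", "data.frame")
  attr(out, "treatment_levels") <- treats
  attr(out, "trait_levels") <- traits
  out
}

#' Serialize / restore a parameter set as a YAML config file
#'
#' Round-trips every field of a [parameter_set()] through structured text so
#' simulation ground truth can be stored next to the generated data.
#'
#' @param truth A `"pols_truth"` object.
#' @param path File path to write to / read from.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` returns
#'   the restored `"pols_truth"`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "pols_truth"))
  obj <- list(
    trait_names = truth$trait_names,
    repeated = truth$repeated,
    treatment_names = truth$treatment_names,
    mu = as.numeric(truth$mu),
    beta_treat = lapply(seq_len(ncol(truth$beta_treat)),
                        function(j) as.numeric(truth$beta_treat[, j])),
    gamma_trial = as.numeric(truth$gamma_trial),
    sigma_mesocosm = as.numeric(truth$sigma_mesocosm),
    Sigma_B = lapply(truth$Sigma_B, function(S)
      lapply(seq_len(nrow(S)), function(i) as.numeric(S[i, ]))),
    sigma_W = lapply(seq_len(nrow(truth$sigma_W)),
                     function(i) as.numeric(truth$sigma_W[i, ])),
    sigma_fixed = truth$sigma_fixed)
  atomic_write(path, function(p) yaml::write_yaml(obj, p, precision = 15))
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  T_ <- length(obj$trait_names)
  K <- length(obj$treatment_names)
  parameter_set(
    mu = obj$mu,
    beta_treat = do.call(cbind, obj$beta_treat),
    gamma_trial = obj$gamma_trial,
    sigma_mesocosm = obj$sigma_mesocosm,
    Sigma_B = lapply(obj$Sigma_B, function(rows) do.call(rbind, rows)),
    sigma_W = do.call(rbind, obj$sigma_W),
    sigma_fixed = obj$sigma_fixed,
    trait_names = obj$trait_names,
    repeated = obj$repeated,
    treatment_names = obj$treatment_names)
}
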