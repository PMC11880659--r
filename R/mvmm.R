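#' Fit the Bayesian multivariate mixed-effects model
#'
#' The model behind the package: a multivariate Gaussian mixed model over a
#' trait roster, with per-trait intercepts, treatment fixed effects
#' (reference coding), a linear trial slope for repeated traits (on the
#' left-centred occasion index), per-trait mesocosm random intercepts,
#' an individual random-intercept vector with a treatment-specific
#' between-individual covariance matrix, treatment-specific within-individual
#' (residual) variances for repeated traits, and a residual variance pinned
#' to a small reference value (0.01 by default) for once-measured traits.
#' Residuals are independent across traits within an occasion; all
#' between-trait association is carried by the between-individual
#' covariances. Fitting is by the conjugate block Gibbs sampler of
#' [sample_posterior()].
#'
#' Data are expected on the standardized scale (see [standardize_traits()]);
#' the default priors are calibrated for that scale.
#'
#' @param data A long table (columns `individual_id`, `mesocosm_id`,
#'   `treatment`, `trait`, `occasion`, `value`).
#' @param spec A [mvmm_spec()]; by default inferred for the standard 8-trait
#'   roster with the treatments found in `data` (reference = first of
#'   control/low/high present, else first alphabetically).
#' @param chains,iter,warmup,thin Sampler settings; defaults are the
#'   reference analysis settings (4 chains, 8000 iterations, 3000 warmup,
#'   thinning 2, i.e. 10000 retained draws).
#' @param seed Integer seed (mandatory; same seed, same draws).
#' @param check Run convergence checks and store them (default `TRUE`); a
#'   failed check warns and is recorded in the fit, never silently dropped.
#' @return An object of class `"mvmm"` with methods `print`, `summary`,
#'   `coef`, `fitted`, `residuals`, `simulate` and `plot`.
#' @examples
#' cfg <- design_config(n_mesocosms_per_treatment = 2,
#'                      n_individuals_per_mesocosm = 4)
#' dat <- generate_population(cfg, known_truth("null"), seed = 7)
#' fit <- mvmm(dat, chains = 2, iter = 300, warmup = 100, thin = 1,
#'             seed = 7, check = FALSE)
#' coef(fit)[1:4]
#' @export
mvmm <- function(data, spec = NULL, chains = 4, iter = 8000, warmup = 3000,
                 thin = 2, seed, check = TRUE) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (is.null(spec)) {
    tr <- unique(data$treatment)
    std <- c("control", "low", "high")
    levels <- c(std[std %in% tr], sort(setdiff(tr, std)))
    traits <- attr(data, "trait_levels")
    if (is.null(traits)) {
      traits <- intersect(pols_traits(), unique(data$trait))
      if (!setequal(traits, unique(data$trait)))
        traits <- sort(unique(data$trait))
    }
    repeated <- intersect(pols_behaviours(), traits)
    spec <- mvmm_spec(trait_names = traits, repeated = repeated,
                      treatment_names = levels,
                      priors = prior_set(n_traits = length(traits)))
  }
  model <- build_model(spec, data)
  draws <- sample_posterior(model, chains = chains, iter = iter,
                            warmup = warmup, thin = thin, seed = seed)
  diag_ <- if (check && chains >= 2) check_convergence(draws) else NULL
  structure(list(
    draws = draws, model = model, spec = spec,
    settings = attr(draws, "settings"),
    diagnostics = diag_,
    call = match.call()
  ), class = "mvmm")
}

#' @export
print.mvmm <- function(x, ...) {
  m <- x$model
  s <- x$settings
  cat("Bayesian multivariate mixed model (conjugate block Gibbs)\n")
  cat("  ", m$N, " observations | ", m$nI, " individuals | ", m$M,
      " mesocosms | ", m$K, " treatments\n", sep = "")
  cat("  traits:", paste(m$traits, collapse = ", "), "\n")
  cat("  repeated:", paste(m$traits[m$beh_idx], collapse = ", "),
      "(treatment-specific within-individual variances)\n")
  cat("  draws: ", nrow(x$draws), " (", s$chains, " chains x ",
      s$iter, " iter, warmup ", s$warmup, ", thin ", s$thin, ")\n", sep = "")
  if (!is.null(x$diagnostics))
    cat("  convergence: max split-Rhat ",
        round(x$diagnostics$max_rhat, 4), ", min bulk ESS ",
        round(x$diagnostics$min_ess), if (x$diagnostics$ok) " [ok]"
        else " [FLAGGED]", "\n", sep = "")
  invisible(x)
}

#' @export
coef.mvmm <- function(object, ...) {
  colMeans(object$draws[, object$model$coef_names, drop = FALSE])
}

#' @export
fitted.mvmm <- function(object, ...) {
  m <- object$model
  th <- coef(object)
  eta <- as.vector(m$X %*% th)
  bm <- attr(object$draws, "b_mean")
  um <- attr(object$draws, "u_mean")
  if (m$spec$include_mesocosm) eta <- eta + bm[cbind(m$im, m$it)]
  if (m$spec$include_individual) eta <- eta + um[cbind(m$ii, m$it)]
  eta
}

#' @export
residuals.mvmm <- function(object, ...) {
  object$model$y - fitted(object)
}

#' Simulate replicate datasets from the fitted model
#'
#' Draws `nsim` datasets: for each one a retained posterior draw is selected
#' at random, converted back into a full parameter set, and a new population
#' of the same design is generated from it (posterior-predictive replication
#' of new individuals and mesocosms).
#'
#' @param object A fitted [mvmm()] object.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` long tables.
#' @export
simulate.mvmm <- function(object, nsim = 1, seed = 1, ...) {
  m <- object$model
  if (!m$spec$include_individual || !m$spec$include_mesocosm)
    stop("simulate() needs the full random-effect structure")
  set.seed(as.integer(seed))
  pick <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  sub_seeds <- sample.int(2^30, nsim)
  cfg <- design_config(
    n_treatments = m$K,
    n_mesocosms_per_treatment = max(1L, m$M %/% m$K),
    n_individuals_per_mesocosm = max(1L, m$nI %/% max(1L, m$M)),
    n_trials_behaviour = if (m$B > 0) max(m$trial_c) + 1L else 1L,
    trait_names = m$traits, repeated = m$traits[m$beh_idx],
    treatment_names = m$treatments)
  lapply(seq_len(nsim), function(i) {
    truth <- draw_to_parameter_set(object$draws[pick[i], ], m)
    generate_population(cfg, truth, seed = sub_seeds[i])
  })
}

# reconstruct a pols_truth from one named draw vector
draw_to_parameter_set <- function(dr, model) {
  traits <- model$traits; treats <- model$treatments
  T_ <- model$T; K <- model$K; B <- model$B
  beh <- traits[model$beh_idx]
  mu <- dr[paste0("mu[", traits, "]")]
  beta <- matrix(0, T_, max(K - 1, 0),
                 dimnames = list(traits, treats[-1]))
  for (k in treats[-1])
    beta[, k] <- dr[paste0("beta[", k, ",", traits, "]")]
  gamma <- if (B > 0) dr[paste0("gamma[", beh, "]")] else numeric(0)
  sdm <- dr[paste0("sd_meso[", traits, "]")]
  Sig <- lapply(treats, function(k) {
    sdv <- dr[paste0("sd_B[", k, ",", traits, "]")]
    R <- diag(T_)
    ut <- which(upper.tri(R), arr.ind = TRUE)
    vals <- dr[paste0("cor_B[", k, ",", traits[ut[, 1]], ",",
                      traits[ut[, 2]], "]")]
    R[upper.tri(R)] <- vals
    R[lower.tri(R)] <- t(R)[lower.tri(R)]
    cov_from_sd_cor(unname(sdv), R)
  })
  sW <- matrix(0, K, B, dimnames = list(treats, beh))
  for (k in treats) sW[k, ] <- dr[paste0("sd_W[", k, ",", beh, "]")]
  parameter_set(mu = unname(mu), beta_treat = beta,
                gamma_trial = unname(gamma), sigma_mesocosm = unname(sdm),
                Sigma_B = Sig, sigma_W = sW,
                sigma_fixed = model$spec$sigma_fixed,
                trait_names = traits, repeated = beh,
                treatment_names = treats)
}

#' Posterior interval plot for a fitted model
#'
#' Base-graphics dot-and-interval plot (posterior mean, 89% and 95%
#' equal-tailed intervals) for a family of parameters.
#'
#' @param x A fitted [mvmm()] object.
#' @param pars Regular expression selecting parameter columns (default:
#'   treatment fixed effects).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted summary table.
#' @export
plot.mvmm <- function(x, pars = "^beta\\[", ...) {
  cols <- grep(pars, colnames(x$draws), value = TRUE)
  if (!length(cols)) stop("no parameters match '", pars, "'")
  m <- colMeans(x$draws[, cols, drop = FALSE])
  q89 <- apply(x$draws[, cols, drop = FALSE], 2, stats::quantile,
               probs = c(0.055, 0.945))
  q95 <- apply(x$draws[, cols, drop = FALSE], 2, stats::quantile,
               probs = c(0.025, 0.975))
  n <- length(cols)
  old <- graphics::par(mar = c(4, 12, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(m, seq_len(n), xlim = range(q95), ylim = c(0.5, n + 0.5),
                 yaxt = "n", xlab = "posterior value", ylab = "", pch = 16,
                 ...)
  graphics::axis(2, at = seq_len(n), labels = cols, las = 1, cex.axis = 0.7)
  graphics::segments(q95[1, ], seq_len(n), q95[2, ], seq_len(n), lwd = 1)
  graphics::segments(q89[1, ], seq_len(n), q89[2, ], seq_len(n), lwd = 3)
  graphics::abline(v = 0, lty = 2)
  invisible(data.frame(parameter = cols, mean = m,
                       l89 = q89[1, ], u89 = q89[2, ],
                       l95 = q95[1, ], u95 = q95[2, ]))
}

#' @export
summary.mvmm <- function(object, ...) {
  out <- list(
    fixed = summarize_fixed_effects(object),
    variances = summarize_variances(object),
    diagnostics = object$diagnostics,
    settings = object$settings)
  class(out) <- "summary.mvmm"
  out
}

#' @export
print.summary.mvmm <- function(x, digits = 3, ...) {
  cat("Fixed effects (posterior mean, 89% and 95% equal-tailed CI):\n")
  print(format_ci_table(x$fixed, digits))
  cat("\nVariance components (posterior means):\n")
  print(format_ci_table(x$variances, digits))
  if (!is.null(x$diagnostics))
    cat("\nmax split-Rhat:", round(x$diagnostics$max_rhat, 4),
        "| min bulk ESS:", round(x$diagnostics$min_ess),
        if (x$diagnostics$ok) "| converged" else "| FLAGGED", "\n")
  invisible(x)
}

format_ci_table <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}
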