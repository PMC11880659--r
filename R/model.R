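#' Prior set for the multivariate mixed model
#'
#' Two built-in flavours, both fully conjugate to the Gaussian hierarchy:
#'
#' * `"weakly_informative"` (default, appropriate for standardized traits):
#'   Normal(0, 1) on every fixed effect; inverse-gamma(1, 0.1) on the
#'   mesocosm and within-individual variances; inverse-Wishart with
#'   `df = T + 2` and scale `0.5 I` on each between-individual covariance
#'   matrix (prior mean `0.5 I`, correlations centred on zero).
#' * `"flat"`: near-improper versions of the same families
#'   (Normal(0, 100) fixed effects, inverse-gamma(0.001, 0.001) variances,
#'   inverse-Wishart `df = T + 1`, scale `0.1 I`), used for the
#'   prior-robustness check.
#'
#' @param flavour `"weakly_informative"` or `"flat"`.
#' @param n_traits Dimension of the between-individual covariance matrices.
#' @param fixed_sd Prior SD of fixed effects.
#' @param var_shape,var_rate Inverse-gamma shape/rate for group and residual
#'   variances.
#' @param wishart_df,wishart_scale Inverse-Wishart degrees of freedom and
#'   scalar scale (the scale matrix is `wishart_scale * I`).
#' @return An object of class `"pols_priors"`.
#' @export
prior_set <- function(flavour = c("weakly_informative", "flat"),
                      n_traits = 8,
                      fixed_sd = NULL, var_shape = NULL, var_rate = NULL,
                      wishart_df = NULL, wishart_scale = NULL) {
  flavour <- match.arg(flavour)
  def <- if (flavour == "weakly_informative") {
    list(fixed_sd = 1, var_shape = 1, var_rate = 0.1,
         wishart_df = n_traits + 2, wishart_scale = 0.5)
  } else {
    list(fixed_sd = 10, var_shape = 0.001, var_rate = 0.001,
         wishart_df = n_traits + 1, wishart_scale = 0.1)
  }
  out <- list(
    flavour = flavour,
    fixed_sd = if (is.null(fixed_sd)) def$fixed_sd else fixed_sd,
    var_shape = if (is.null(var_shape)) def$var_shape else var_shape,
    var_rate = if (is.null(var_rate)) def$var_rate else var_rate,
    wishart_df = if (is.null(wishart_df)) def$wishart_df else wishart_df,
    wishart_scale = if (is.null(wishart_scale)) def$wishart_scale
                    else wishart_scale)
  if (out$fixed_sd <= 0 || out$var_shape <= 0 || out$var_rate <= 0 ||
      out$wishart_scale <= 0 || out$wishart_df < n_traits + 1)
    stop("invalid prior hyperparameters")
  structure(out, class = "pols_priors")
}

#' Model specification for the multivariate mixed model
#'
#' Declares the trait roster and which traits are repeated, the treatment
#' coding (first level = reference), the random-effect structure and the
#' priors. Once-measured traits get a fixed residual variance
#' (`sigma_fixed^2`, default 0.01) so that their between-individual variance
#' absorbs essentially all non-mesocosm variation; repeated traits get a
#' treatment-specific within-individual (residual) variance.
#'
#' @param trait_names Trait labels (responses of the multivariate model).
#' @param repeated Labels of traits with repeated measures (get a trial
#'   slope and estimated within-individual variances).
#' @param treatment_names Treatment levels; the first is the reference of
#'   the dummy coding.
#' @param priors A [prior_set()].
#' @param sigma_fixed Residual SD pinned for once-measured traits.
#' @param include_mesocosm Include per-trait mesocosm random intercepts.
#' @param include_individual Include the individual random-intercept vector
#'   with treatment-specific covariance (disable only for degenerate toy
#'   models).
#' @return An object of class `"pols_spec"`.
#' @export
mvmm_spec <- function(trait_names = pols_traits(),
                      repeated = pols_behaviours(),
                      treatment_names = c("control", "low", "high"),
                      priors = prior_set(n_traits = length(trait_names)),
                      sigma_fixed = sqrt(0.01),
                      include_mesocosm = TRUE,
                      include_individual = TRUE) {
  trait_names <- as.character(trait_names)
  if (!all(repeated %in% trait_names))
    stop("repeated traits must be a subset of trait_names")
  if (anyDuplicated(trait_names)) stop("duplicate trait names")
  if (length(treatment_names) < 1) stop("need >= 1 treatment")
  if (sigma_fixed <= 0) stop("sigma_fixed must be positive")
  structure(list(
    trait_names = trait_names,
    repeated = as.character(repeated),
    treatment_names = as.character(treatment_names),
    priors = priors,
    sigma_fixed = sigma_fixed,
    include_mesocosm = isTRUE(include_mesocosm),
    include_individual = isTRUE(include_individual)
  ), class = "pols_spec")
}

#' Compile a long table against a model specification
#'
#' Validates the data against the spec (known traits, each individual in
#' exactly one treatment and mesocosm, once-measured traits with exactly one
#' occasion per individual), canonicalizes the row order (individual, trait,
#' occasion) so results are invariant to input row permutations, and builds
#' the fixed-effect design matrix and the index maps used by the sampler.
#' Missing trait/individual cells are simply absent rows: the likelihood
#' skips them.
#'
#' @param spec A [mvmm_spec()].
#' @param data A long table with columns `individual_id`, `mesocosm_id`,
#'   `treatment`, `trait`, `occasion`, `value`.
#' @return An object of class `"pols_model"` (design matrices + index maps).
#' @export
build_model <- function(spec, data) {
  stopifnot(inherits(spec, "pols_spec"))
  need <- c("individual_id", "mesocosm_id", "treatment", "trait",
            "occasion", "value")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("long table lacks column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data, stringsAsFactors = FALSE)

  traits <- spec$trait_names
  T_ <- length(traits)
  unknown <- setdiff(unique(data$trait), traits)
  if (length(unknown))
    stop("unknown trait(s) in data: ", paste(unknown, collapse = ", "),
         " (first offending row ",
         which(data$trait %in% unknown)[1], ")")
  treats <- spec$treatment_names
  bad_tr <- setdiff(unique(data$treatment), treats)
  if (length(bad_tr))
    stop("unknown treatment(s) in data: ", paste(bad_tr, collapse = ", "))
  if (nrow(data) > 0 && !(treats[1] %in% data$treatment))
    stop("reference treatment '", treats[1], "' absent from data")
  if (any(!is.finite(data$value)))
    stop("non-finite trait value at row ", which(!is.finite(data$value))[1])

  # canonical ordering: individual, trait (roster order), occasion
  it <- match(data$trait, traits)
  ord <- order(data$individual_id, it, data$occasion)
  data <- data[ord, , drop = FALSE]
  it <- it[ord]

  ind_ids <- sort(unique(data$individual_id))
  ii <- match(data$individual_id, ind_ids)
  nI <- length(ind_ids)

  # each individual in exactly one mesocosm & treatment
  imap <- unique(data.frame(ii = ii, meso = data$mesocosm_id,
                            treat = data$treatment,
                            stringsAsFactors = FALSE))
  if (anyDuplicated(imap$ii)) {
    dup <- imap$ii[duplicated(imap$ii)][1]
    stop("individual '", ind_ids[dup],
         "' appears in more than one mesocosm/treatment (rows ",
         paste(which(ii == dup)[1:2], collapse = ", "), ")")
  }
  imap <- imap[order(imap$ii), ]
  meso_ids <- sort(unique(data$mesocosm_id))
  ind_meso <- match(imap$meso, meso_ids)
  ind_treat <- match(imap$treat, treats)
  M <- length(meso_ids)
  im <- ind_meso[ii]
  ik <- ind_treat[ii]

  # occasion structure: repeated traits may have >1 occasion, others exactly 1
  rep_flag <- traits %in% spec$repeated
  key <- (ii - 1L) * T_ + it
  occ_n <- tabulate(key, nbins = nI * T_)
  occm <- matrix(occ_n, nrow = T_)  # traits x individuals
  for (j in which(!rep_flag)) {
    bad <- which(occm[j, ] > 1)
    if (length(bad))
      stop("trait '", traits[j], "' has ", occm[j, bad[1]],
           " occasions for individual '", ind_ids[bad[1]],
           "' but carries a fixed residual variance (exactly 1 allowed)")
  }
  dupkey <- paste(ii, it, data$occasion)
  if (anyDuplicated(dupkey)) {
    d <- which(duplicated(dupkey))[1]
    stop("duplicate (individual, trait, occasion) at canonical row ", d)
  }

  # fixed-effect design: per-trait intercept, treatment dummies, trial slope
  K <- length(treats)
  B <- sum(rep_flag)
  beh_idx <- which(rep_flag)
  # left-centre: first observed occasion maps to 0
  trial_c <- if (nrow(data) > 0)
    ifelse(rep_flag[it], data$occasion - min(data$occasion), 0) else numeric(0)
  p_mu <- T_
  p_beta <- T_ * (K - 1)
  p_gamma <- B
  p <- p_mu + p_beta + p_gamma
  N <- nrow(data)
  X <- matrix(0, N, p)
  coef_names <- c(paste0("mu[", traits, "]"),
                  if (K > 1) as.vector(outer(traits, treats[-1], function(t, k)
                    paste0("beta[", k, ",", t, "]"))),
                  if (B > 0) paste0("gamma[", traits[beh_idx], "]"))
  colnames(X) <- coef_names
  if (N > 0) {
    X[cbind(seq_len(N), it)] <- 1
    if (K > 1) {
      nonref <- ik > 1
      colb <- p_mu + (ik - 2L) * T_ + it
      X[cbind(which(nonref), colb[nonref])] <- 1
    }
    if (B > 0) {
      isb <- rep_flag[it]
      colg <- p_mu + p_beta + match(it, beh_idx)
      X[cbind(which(isb), colg[isb])] <- trial_c[isb]
    }
  }

  # residual-variance index: 0 = fixed, else (treatment, behaviour) slot
  resid_id <- integer(N)
  if (N > 0) {
    isb <- rep_flag[it]
    resid_id[isb] <- (ik[isb] - 1L) * B + match(it[isb], beh_idx)
  }

  # group individuals by identical (treatment, row layout) pattern: all
  # members share the same trait/occasion row sequence, hence the same
  # per-individual design block and marginal covariance. The sampler shares
  # one factorization per pattern per sweep.
  rows_by_ind <- split(seq_len(N), ii)
  sig <- vapply(seq_len(nI), function(i) {
    r <- rows_by_ind[[as.character(i)]]
    paste(ind_treat[i], paste(it[r], data$occasion[r], collapse = ";"),
          sep = "|")
  }, character(1))
  patterns <- lapply(sort(unique(sig)), function(pk) {
    idx <- which(sig == pk)
    r1 <- rows_by_ind[[as.character(idx[1])]]
    rowsmat <- vapply(idx, function(i) rows_by_ind[[as.character(i)]],
                      integer(length(r1)))
    list(indiv = idx, treat = ind_treat[idx[1]],
         counts = occm[, idx[1]],
         rows = matrix(rowsmat, nrow = length(r1)),
         it = it[r1], rid = resid_id[r1],
         X = X[r1, , drop = FALSE], meso = ind_meso[idx])
  })

  structure(list(
    spec = spec, data = data,
    traits = traits, T = T_, rep_flag = rep_flag, beh_idx = beh_idx, B = B,
    treatments = treats, K = K,
    ind_ids = ind_ids, nI = nI, ind_meso = ind_meso, ind_treat = ind_treat,
    meso_ids = meso_ids, M = M,
    y = data$value, it = it, ii = ii, im = im, ik = ik, trial_c = trial_c,
    X = X, p = p, coef_names = coef_names,
    resid_id = resid_id, patterns = patterns,
    N = N
  ), class = "pols_model")
}

#' @export
print.pols_model <- function(x, ...) {
  cat("Multivariate mixed model:", x$N, "observations,", x$nI,
      "individuals,", x$M, "mesocosms\n")
  cat("  ", x$T, "traits (", x$B, "repeated ),", x$K, "treatments;",
      x$p, "fixed-effect coefficients\n")
  invisible(x)
}

lmvgamma <- function(a, d) {
  d * (d - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}

ldinvwishart <- function(Sigma, df, S0) {
  d <- nrow(Sigma)
  cS <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(cS)) return(-Inf)
  ldetS0 <- as.numeric(determinant(S0, logarithm = TRUE)$modulus)
  ldetSig <- 2 * sum(log(diag(cS)))
  tr <- sum(diag(solve(Sigma, S0)))
  df / 2 * ldetS0 - df * d / 2 * log(2) - lmvgamma(df / 2, d) -
    (df + d + 1) / 2 * ldetSig - 0.5 * tr
}

ldinvgamma <- function(x, shape, rate) {
  ifelse(x > 0,
         shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x,
         -Inf)
}

#' Joint log posterior density of the multivariate mixed model
#'
#' Evaluates the (unnormalised w.r.t. nothing: all terms included) joint log
#' posterior at a full parameter configuration, including the random effects:
#' Gaussian observation terms, Gaussian mesocosm and individual random-effect
#' terms, and (optionally) the prior terms. Used for validating the sampler
#' against brute-force computation and for debugging; a non-positive-definite
#' covariance yields `-Inf` rather than an error.
#'
#' @param params Named list with elements `theta` (fixed-effect vector in
#'   `model$coef_names` order), `b` (M x T mesocosm effects, 0-row allowed
#'   when mesocosm effects are disabled), `u` (nI x T individual effects),
#'   `sigma2_meso` (length T), `Sigma_B` (list of K T x T matrices),
#'   `sigma2_W` (K x B matrix).
#' @param model A [build_model()] object.
#' @param include_prior Include the prior density terms (default `TRUE`).
#' @return Scalar log density (finite for valid parameters, `-Inf` for
#'   non-PSD covariance inputs).
#' @export
log_density <- function(params, model, include_prior = TRUE) {
  stopifnot(inherits(model, "pols_model"))
  spec <- model$spec
  pr <- spec$priors
  theta <- as.numeric(params$theta)
  if (length(theta) != model$p) stop("theta has wrong length")
  T_ <- model$T; K <- model$K; B <- model$B

  u <- if (spec$include_individual) as.matrix(params$u) else
    matrix(0, model$nI, T_)
  b <- if (spec$include_mesocosm) as.matrix(params$b) else
    matrix(0, model$M, T_)
  if (spec$include_individual && !all(dim(u) == c(model$nI, T_)))
    stop("u has wrong dimensions")
  if (spec$include_mesocosm && !all(dim(b) == c(model$M, T_)))
    stop("b has wrong dimensions")

  # residual variance per row
  s2W <- matrix(as.numeric(params$sigma2_W), nrow = K, ncol = B)
  rvar <- rep(spec$sigma_fixed^2, model$N)
  if (B > 0 && model$N > 0) {
    sel <- model$resid_id > 0
    rvar[sel] <- t(s2W)[model$resid_id[sel]]
  }
  if (any(rvar <= 0)) return(-Inf)

  eta <- as.vector(model$X %*% theta) +
    b[cbind(model$im, model$it)] + u[cbind(model$ii, model$it)]
  ll <- sum(stats::dnorm(model$y, eta, sqrt(rvar), log = TRUE))

  # random-effect terms
  if (spec$include_mesocosm && model$M > 0) {
    s2m <- as.numeric(params$sigma2_meso)
    if (any(s2m <= 0)) return(-Inf)
    ll <- ll + sum(stats::dnorm(b, 0,
                                rep(sqrt(s2m), each = model$M), log = TRUE))
  }
  if (spec$include_individual && model$nI > 0) {
    for (k in seq_len(K)) {
      idx <- which(model$ind_treat == k)
      if (!length(idx)) next
      Sig <- as.matrix(params$Sigma_B[[k]])
      cS <- tryCatch(chol(Sig), error = function(e) NULL)
      if (is.null(cS)) return(-Inf)
      Uk <- u[idx, , drop = FALSE]
      z <- backsolve(cS, t(Uk), transpose = TRUE)
      ll <- ll - length(idx) * (T_ / 2 * log(2 * pi) + sum(log(diag(cS)))) -
        0.5 * sum(z^2)
    }
  }

  if (include_prior) {
    ll <- ll + sum(stats::dnorm(theta, 0, pr$fixed_sd, log = TRUE))
    if (spec$include_mesocosm)
      ll <- ll + sum(ldinvgamma(as.numeric(params$sigma2_meso),
                                pr$var_shape, pr$var_rate))
    if (B > 0)
      ll <- ll + sum(ldinvgamma(as.numeric(s2W), pr$var_shape, pr$var_rate))
    if (spec$include_individual) {
      S0 <- diag(pr$wishart_scale, T_)
      for (k in seq_len(K))
        ll <- ll + ldinvwishart(as.matrix(params$Sigma_B[[k]]),
                                pr$wishart_df, S0)
    }
  }
  ll
}
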