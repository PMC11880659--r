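riwish <- function(df, S) {
  # if W ~ Wishart(df, S^{-1}) then W^{-1} ~ inverse-Wishart(df, S)
  W <- stats::rWishart(1, df, chol2inv(chol(S)))[, , 1]
  Sig <- chol2inv(chol(W))
  (Sig + t(Sig)) / 2
}

draw_colnames <- function(model) {
  traits <- model$traits
  treats <- model$treatments
  beh <- traits[model$beh_idx]
  nm <- model$coef_names
  if (model$spec$include_mesocosm)
    nm <- c(nm, paste0("sd_meso[", traits, "]"))
  if (model$spec$include_individual) {
    for (k in treats) {
      nm <- c(nm, paste0("sd_B[", k, ",", traits, "]"))
      ut <- which(upper.tri(diag(model$T)), arr.ind = TRUE)
      nm <- c(nm, paste0("cor_B[", k, ",", traits[ut[, 1]], ",",
                         traits[ut[, 2]], "]"))
    }
  }
  if (model$B > 0)
    for (k in treats)
      nm <- c(nm, paste0("sd_W[", k, ",", beh, "]"))
  nm
}

record_state <- function(st, model) {
  out <- st$theta
  if (model$spec$include_mesocosm) out <- c(out, sqrt(st$s2meso))
  if (model$spec$include_individual) {
    ut <- upper.tri(diag(model$T))
    for (k in seq_len(model$K)) {
      S <- st$Sig[[k]]
      sdv <- sqrt(diag(S))
      R <- S / tcrossprod(sdv)
      out <- c(out, sdv, R[ut])
    }
  }
  if (model$B > 0) out <- c(out, sqrt(st$s2W))
  out
}

#' Draw from the posterior of the multivariate mixed model by block Gibbs
#'
#' A fully conjugate block Gibbs sampler: the fixed-effect vector, the
#' mesocosm effects and the individual random-intercept vectors have Gaussian
#' full conditionals; the mesocosm and within-individual variances have
#' inverse-gamma full conditionals; each treatment's between-individual
#' covariance matrix has an inverse-Wishart full conditional. Individuals
#' sharing a treatment and missingness pattern share one Cholesky
#' factorization per sweep, which keeps the sampler fast at the study's size.
#' Draws are bit-reproducible given `(seed, settings)`; chain `c` uses seed
#' `seed + c - 1`.
#'
#' @param model A [build_model()] object.
#' @param chains Number of chains (>= 2 needed for convergence diagnostics).
#' @param iter Iterations per chain (including warmup).
#' @param warmup Burn-in iterations discarded per chain.
#' @param thin Keep every `thin`-th post-warmup draw.
#' @param seed Integer seed (mandatory).
#' @param prior_only If `TRUE`, ignore the likelihood and draw from the
#'   prior (every sweep is then an independent prior draw).
#' @return An object of class `"mvmm_draws"`: a draws x parameters matrix
#'   with a `chain` attribute, sampler settings, data hash and the running
#'   posterior means of the random effects (`u_mean`, `b_mean`).
#' @export
sample_posterior <- function(model, chains = 4, iter = 8000, warmup = 3000,
                             thin = 2, seed, prior_only = FALSE) {
  stopifnot(inherits(model, "pols_model"))
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (warmup >= iter) stop("warmup must be smaller than iter")
  if (chains < 1 || thin < 1) stop("chains and thin must be >= 1")
  spec <- model$spec
  pr <- spec$priors
  T_ <- model$T; K <- model$K; B <- model$B
  M <- model$M; nI <- model$nI; N <- model$N
  tau2 <- pr$fixed_sd^2
  a0 <- pr$var_shape; b0 <- pr$var_rate
  nu0 <- pr$wishart_df
  S0 <- diag(pr$wishart_scale, T_)
  s2fix <- spec$sigma_fixed^2

  X <- model$X; y <- model$y
  it <- model$it; ii <- model$ii; im <- model$im
  idx_ut <- if (N > 0) ii + (it - 1L) * nI else integer(0)
  rid <- model$resid_id
  sel_W <- which(rid > 0L)
  nW <- tabulate(rid[sel_W], nbins = K * B)
  treat_rows <- lapply(seq_len(K), function(k) which(model$ind_treat == k))
  n_treat <- lengths(treat_rows)

  n_keep <- floor((iter - warmup) / thin)
  cn <- draw_colnames(model)
  P <- length(cn)
  draws <- matrix(NA_real_, chains * n_keep, P)
  colnames(draws) <- cn
  chain_id <- rep(seq_len(chains), each = n_keep)
  u_acc <- matrix(0, nI, T_)
  b_acc <- matrix(0, M, T_)

  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    theta <- numeric(model$p)
    b <- matrix(0, M, T_)
    u <- matrix(0, nI, T_)
    s2meso <- rep(0.25, T_)
    Sig <- rep(list(diag(0.5, T_)), K)
    s2W <- rep(0.25, K * B)
    row0 <- (ch - 1L) * n_keep

    for (s in seq_len(iter)) {
      if (prior_only) {
        theta <- stats::rnorm(model$p, 0, sqrt(tau2))
        s2meso <- 1 / stats::rgamma(T_, a0, rate = b0)
        b <- matrix(stats::rnorm(M * T_), M, T_) *
          matrix(sqrt(s2meso), M, T_, byrow = TRUE)
        Sig <- lapply(seq_len(K), function(k) riwish(nu0, S0))
        for (k in seq_len(K)) if (n_treat[k] > 0)
          u[treat_rows[[k]], ] <- rmvnorm_chol(n_treat[k], Sig[[k]])
        if (K * B > 0) s2W <- 1 / stats::rgamma(K * B, a0, rate = b0)
      } else {
        rvar <- rep(s2fix, N)
        if (length(sel_W)) rvar[sel_W] <- s2W[rid[sel_W]]
        w <- 1 / rvar
        collapse_u <- spec$include_individual && nI > 0

        # per-pattern marginal pieces: with the individual effect integrated
        # out, the rows of one individual have covariance
        # V = Sigma_B[traits, traits] + diag(residual); identical within a
        # pattern, so one factorization serves all its members
        pat <- lapply(model$patterns, function(g) {
          Rg <- ifelse(g$rid > 0L, s2W[pmax(g$rid, 1L)], s2fix)
          Vg <- if (collapse_u)
            Sig[[g$treat]][g$it, g$it, drop = FALSE] + diag(Rg, length(Rg))
            else diag(Rg, length(Rg))
          Vinv <- chol2inv(chol(Vg))
          list(g = g, Vinv = Vinv,
               XtVi = crossprod(g$X, Vinv),
               Yg = matrix(y[g$rows], nrow = nrow(g$rows)))
        })

        # fixed effects from the collapsed likelihood
        A <- diag(1 / tau2, model$p)
        rhs <- numeric(model$p)
        for (pg in pat) {
          g <- pg$g
          Cb <- t(b[g$meso, , drop = FALSE])[g$it, , drop = FALSE]
          A <- A + length(g$indiv) * (pg$XtVi %*% g$X)
          rhs <- rhs + pg$XtVi %*% rowSums(pg$Yg - Cb)
        }
        Rch <- chol((A + t(A)) / 2)
        m <- backsolve(Rch, backsolve(Rch, rhs, transpose = TRUE))
        theta <- as.numeric(m + backsolve(Rch, stats::rnorm(model$p)))

        # mesocosm effect vectors from the collapsed likelihood
        # (coupled across traits through V), then their per-trait variance
        if (spec$include_mesocosm && M > 0) {
          Pacc <- array(0, c(T_, T_, M))
          racc <- matrix(0, T_, M)
          for (pg in pat) {
            g <- pg$g
            ZtVi <- rowsum(pg$Vinv, g$it)          # T' x r rows present
            tpres <- as.integer(rownames(ZtVi))
            Gg <- matrix(0, T_, T_)
            Gg[tpres, tpres] <- t(rowsum(t(ZtVi), g$it))
            Resid <- pg$Yg - as.vector(g$X %*% theta)
            Hg <- matrix(0, T_, length(g$indiv))
            Hg[tpres, ] <- ZtVi %*% Resid
            cnt <- tabulate(g$meso, nbins = M)
            for (mm in which(cnt > 0)) Pacc[, , mm] <- Pacc[, , mm] +
                cnt[mm] * Gg
            agg <- rowsum(t(Hg), g$meso)
            racc[, as.integer(rownames(agg))] <-
              racc[, as.integer(rownames(agg))] + t(agg)
          }
          for (mm in seq_len(M)) {
            Pm <- Pacc[, , mm]
            diag(Pm) <- diag(Pm) + 1 / s2meso
            Rp <- chol((Pm + t(Pm)) / 2)
            mb <- backsolve(Rp, backsolve(Rp, racc[, mm], transpose = TRUE))
            b[mm, ] <- as.numeric(mb + backsolve(Rp, stats::rnorm(T_)))
          }
          s2meso <- 1 / stats::rgamma(T_, a0 + M / 2,
                                      rate = b0 + colSums(b^2) / 2)
        }
        eta_fix <- as.vector(X %*% theta)

        # regenerate individual effect vectors from their exact conditional
        if (collapse_u) {
          resid2 <- y - eta_fix - b[cbind(im, it)]
          dflat <- numeric(nI * T_)
          tmp <- rowsum(w * resid2, idx_ut)
          dflat[as.integer(rownames(tmp))] <- tmp
          dmat <- matrix(dflat, nI, T_)
          for (g in model$patterns) {
            k <- g$treat
            rk <- rep(s2fix, T_)
            if (B > 0) rk[model$beh_idx] <- s2W[(k - 1L) * B + seq_len(B)]
            Pm <- chol2inv(chol(Sig[[k]])) + diag(g$counts / rk, T_)
            Rp <- chol(Pm)
            Dg <- t(dmat[g$indiv, , drop = FALSE])
            mg <- backsolve(Rp, backsolve(Rp, Dg, transpose = TRUE))
            Zg <- matrix(stats::rnorm(T_ * length(g$indiv)), T_)
            u[g$indiv, ] <- t(mg + backsolve(Rp, Zg))
          }
          # treatment-specific between-individual covariance
          for (k in seq_len(K)) {
            if (n_treat[k] == 0) { Sig[[k]] <- riwish(nu0, S0); next }
            Sk <- S0 + crossprod(u[treat_rows[[k]], , drop = FALSE])
            Sig[[k]] <- riwish(nu0 + n_treat[k], (Sk + t(Sk)) / 2)
          }
        }

        # within-individual variances (repeated traits, per treatment)
        if (K * B > 0) {
          resid3 <- y - eta_fix - b[cbind(im, it)] - u[cbind(ii, it)]
          rss <- numeric(K * B)
          if (length(sel_W)) {
            tmp <- rowsum(resid3[sel_W]^2, rid[sel_W])
            rss[as.integer(rownames(tmp))] <- tmp
          }
          s2W <- 1 / stats::rgamma(K * B, a0 + nW / 2, rate = b0 + rss / 2)
        }
      }

      if (s > warmup && (s - warmup) %% thin == 0) {
        j <- row0 + (s - warmup) %/% thin
        st <- list(theta = theta, s2meso = s2meso, Sig = Sig, s2W = s2W)
        draws[j, ] <- record_state(st, model)
        u_acc <- u_acc + u
        b_acc <- b_acc + b
      }
    }
  }

  total <- chains * n_keep
  structure(draws, class = c("mvmm_draws", "matrix"),
            chain = chain_id,
            settings = list(chains = chains, iter = iter, warmup = warmup,
                            thin = thin, seed = as.integer(seed),
                            prior_only = prior_only,
                            prior_flavour = pr$flavour),
            data_hash = hash_long_table(model$data),
            u_mean = u_acc / max(total, 1),
            b_mean = b_acc / max(total, 1),
            model_dims = list(T = T_, K = K, B = B, M = M, nI = nI, N = N))
}

#' Number of retained posterior draws
#' @param draws An `"mvmm_draws"` object.
#' @return Integer draw count (chains x (iter - warmup) / thin).
#' @export
n_draws <- function(draws) nrow(draws)

hash_long_table <- function(data) {
  f <- tempfile()
  on.exit(unlink(f))
  utils::write.csv(data, f, row.names = FALSE)
  unname(tools::md5sum(f))
}
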