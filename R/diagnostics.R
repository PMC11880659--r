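split_chain_matrix <- function(x, chain) {
  # columns = split half-chains of one parameter
  chains <- unique(chain)
  halves <- list()
  for (ch in chains) {
    v <- x[chain == ch]
    n <- length(v)
    h <- n %/% 2
    halves[[length(halves) + 1]] <- v[seq_len(h)]
    halves[[length(halves) + 1]] <- v[(n - h + 1):n]
  }
  len <- min(lengths(halves))
  vapply(halves, function(v) v[seq_len(len)], numeric(len))
}

#' Split-chain potential scale reduction statistic (Rhat)
#'
#' Gelman-Rubin statistic computed on split half-chains: each chain is cut in
#' two, the between- and within-half-chain variances are compared, and
#' \eqn{\hat R = \sqrt{((n-1)/n\, W + B/n) / W}}. Values near 1 indicate the
#' chains agree; the package flags parameters with `Rhat > 1.01`.
#'
#' @param draws An `"mvmm_draws"` object (or numeric matrix with a `chain`
#'   attribute).
#' @param parameter Parameter name (column); if `NULL`, all columns.
#' @return Named numeric vector of Rhat values (>= 1 up to floating error;
#'   `NA` for parameters with zero variance, e.g. constants).
#' @export
rhat <- function(draws, parameter = NULL) {
  chain <- attr(draws, "chain")
  if (is.null(chain)) stop("draws must carry a chain attribute")
  if (length(unique(chain)) < 2)
    stop("diagnostic unavailable: need >= 2 chains")
  if (min(table(chain)) < 10)
    stop("diagnostic unavailable: need >= 10 draws per chain")
  cols <- if (is.null(parameter)) colnames(draws) else parameter
  miss <- setdiff(cols, colnames(draws))
  if (length(miss)) stop("unknown parameter: ", paste(miss, collapse = ", "))
  out <- vapply(cols, function(cl) {
    m <- split_chain_matrix(draws[, cl], chain)
    n <- nrow(m)
    mu <- colMeans(m)
    W <- mean(apply(m, 2, stats::var))
    Bv <- n * stats::var(mu)
    if (!is.finite(W) || W <= 0) return(NA_real_)
    sqrt(((n - 1) / n * W + Bv / n) / W)
  }, numeric(1))
  names(out) <- cols
  out
}

#' Bulk effective sample size
#'
#' Effective number of independent draws, computed on split half-chains from
#' the multi-chain autocorrelation estimate with Geyer's initial monotone
#' positive sequence truncation.
#'
#' @inheritParams rhat
#' @return Named numeric vector of ESS values.
#' @export
ess_bulk <- function(draws, parameter = NULL) {
  chain <- attr(draws, "chain")
  if (is.null(chain)) stop("draws must carry a chain attribute")
  cols <- if (is.null(parameter)) colnames(draws) else parameter
  out <- vapply(cols, function(cl) {
    m <- split_chain_matrix(draws[, cl], chain)
    n <- nrow(m); nc <- ncol(m)
    if (n < 4) return(NA_real_)
    acov <- apply(m, 2, function(v) {
      v <- v - mean(v)
      a <- stats::acf(v, lag.max = n - 1, plot = FALSE,
                      type = "covariance", demean = FALSE)$acf[, 1, 1]
      a
    })
    mean_var <- mean(acov[1, ]) * n / (n - 1)
    var_plus <- mean_var * (n - 1) / n
    if (nc > 1) var_plus <- var_plus + stats::var(colMeans(m))
    if (var_plus <= 0) return(NA_real_)
    rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
    # Geyer: sum lag pairs (rho_{2t} + rho_{2t+1}) while positive, then
    # enforce monotone decrease
    P <- numeric(0)
    tt <- 0
    repeat {
      i1 <- 2 * tt + 1; i2 <- 2 * tt + 2
      if (i2 > length(rho)) break
      p <- rho[i1] + rho[i2]
      if (p < 0) break
      P <- c(P, p)
      tt <- tt + 1
    }
    if (length(P) > 1)
      for (j in 2:length(P)) P[j] <- min(P[j], P[j - 1])
    tau <- max(-1 + 2 * sum(P), 1 / log10(n * nc + 10))
    min(nc * n / tau, nc * n * log10(nc * n))
  }, numeric(1))
  names(out) <- cols
  out
}

#' Convergence check for a set of posterior draws
#'
#' Flags the fit when any split-Rhat exceeds `rhat_max` or any bulk ESS falls
#' below `ess_min`. Constant parameters (zero posterior variance) are ignored.
#'
#' @param draws An `"mvmm_draws"` object.
#' @param rhat_max Threshold on split-Rhat (default 1.01).
#' @param ess_min Threshold on bulk ESS (default 400).
#' @param warn Emit a warning when flagged (default `TRUE`).
#' @return List: `ok`, `max_rhat`, `min_ess`, `flagged` (parameter names).
#' @export
check_convergence <- function(draws, rhat_max = 1.01, ess_min = 400,
                              warn = TRUE) {
  r <- rhat(draws)
  e <- ess_bulk(draws)
  keep <- !is.na(r)
  bad <- names(r)[keep & (r > rhat_max | (!is.na(e) & e < ess_min))]
  ok <- length(bad) == 0
  if (!ok && warn)
    warning("convergence flagged for ", length(bad), " parameter(s), e.g. ",
            paste(utils::head(bad, 3), collapse = ", "),
            " (max Rhat ", round(max(r[keep]), 4), ", min ESS ",
            round(min(e[keep], na.rm = TRUE)), ")")
  list(ok = ok, max_rhat = max(r[keep]),
       min_ess = min(e[keep], na.rm = TRUE), flagged = bad)
}
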