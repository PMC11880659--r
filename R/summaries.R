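#' Equal-tailed posterior credible interval
#'
#' Quantile interval at the stated level (e.g. 0.89 gives the 5.5% and 94.5%
#' quantiles). Both 89% and 95% intervals are used in reporting; inference is
#' based on the 89% interval excluding zero.
#'
#' @param draws Numeric sample of posterior draws.
#' @param level Coverage level in (0, 1).
#' @return Numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(draws, level = 0.89) {
  if (!is.numeric(draws) || !length(draws)) stop("draws must be numeric")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (length(draws) < 100)
    warning("fewer than 100 draws: interval endpoints are imprecise")
  a <- (1 - level) / 2
  unname(stats::quantile(draws, probs = c(a, 1 - a), names = FALSE))
}

#' Does a credible interval exclude zero?
#'
#' The reporting rule for "clear evidence of an effect": `TRUE` iff the whole
#' interval lies on one side of zero.
#'
#' @param interval Numeric `c(lower, upper)`.
#' @return Logical flag.
#' @export
ci_excludes_zero <- function(interval) {
  if (length(interval) != 2 || any(!is.finite(interval)))
    stop("interval must be two finite numbers")
  interval[1] > 0 || interval[2] < 0
}

get_draws <- function(fit) {
  if (inherits(fit, "mvmm")) fit$draws
  else if (inherits(fit, "mvmm_draws")) fit
  else stop("need an 'mvmm' fit or 'mvmm_draws' object")
}

get_model_labels <- function(fit) {
  if (inherits(fit, "mvmm"))
    return(list(traits = fit$model$traits,
                repeated = fit$model$traits[fit$model$beh_idx],
                treatments = fit$model$treatments))
  d <- attr(fit, "model_dims")
  cn <- colnames(fit)
  traits <- unique(sub("^mu\\[(.*)\\]$", "\\1",
                       grep("^mu\\[", cn, value = TRUE)))
  repeated <- unique(sub("^gamma\\[(.*)\\]$", "\\1",
                         grep("^gamma\\[", cn, value = TRUE)))
  treatments <- unique(sub("^sd_B\\[([^,]*),.*$", "\\1",
                           grep("^sd_B\\[", cn, value = TRUE)))
  list(traits = traits, repeated = repeated, treatments = treatments)
}

variance_draws <- function(fit, trait, level, treatment) {
  draws <- get_draws(fit)
  lb <- get_model_labels(fit)
  if (!trait %in% lb$traits) stop("unknown trait '", trait, "'")
  if (!treatment %in% lb$treatments)
    stop("unknown treatment '", treatment, "'")
  if (level == "between") {
    draws[, paste0("sd_B[", treatment, ",", trait, "]")]^2
  } else if (level == "within") {
    if (!trait %in% lb$repeated)
      stop("invalid request: trait '", trait,
           "' is once-measured; within-individual variance is fixed")
    draws[, paste0("sd_W[", treatment, ",", trait, "]")]^2
  } else stop("level must be 'between' or 'within'")
}

#' Posterior contrast between two variance components (Delta-V)
#'
#' The draw-wise difference `V(group_a) - V(group_b)` between the posterior
#' distributions of the same variance component (between-individual variance
#' of any trait, or within-individual variance of a repeated trait) in two
#' treatments, summarised by its mean and 89%/95% equal-tailed intervals.
#' Both group labels are kept in the output so the sign convention is always
#' explicit.
#'
#' @param fit A fitted [mvmm()] (or its draws).
#' @param trait Trait label.
#' @param level `"between"` or `"within"`.
#' @param group_a,group_b Treatment labels; the contrast is A minus B.
#' @return An object of class `"variance_contrast"` with the draws, mean and
#'   intervals.
#' @export
delta_v <- function(fit, trait, level = c("between", "within"),
                    group_a, group_b) {
  level <- match.arg(level)
  va <- variance_draws(fit, trait, level, group_a)
  vb <- variance_draws(fit, trait, level, group_b)
  d <- va - vb
  ci89 <- credible_interval(d, 0.89)
  ci95 <- credible_interval(d, 0.95)
  structure(list(trait = trait, level = level,
                 group_a = group_a, group_b = group_b,
                 draws = d, mean = mean(d),
                 ci89 = ci89, ci95 = ci95,
                 supported = ci_excludes_zero(ci89)),
            class = "variance_contrast")
}

#' @export
print.variance_contrast <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Delta-V (%s) %s: %s - %s = %s [89%% CI %s, %s] [95%% CI %s, %s]%s\n",
    x$level, x$trait, x$group_a, x$group_b,
    format(round(x$mean, digits)),
    format(round(x$ci89[1], digits)), format(round(x$ci89[2], digits)),
    format(round(x$ci95[1], digits)), format(round(x$ci95[2], digits)),
    if (x$supported) " *" else ""))
  invisible(x)
}

#' Between-individual (syndrome) correlations for one treatment
#'
#' Posterior summary of the between-individual correlation matrix of one
#' treatment: posterior-mean matrix plus, for each unique trait pair, the
#' 89% and 95% equal-tailed intervals and the supported flag (89% interval
#' excluding zero).
#'
#' @param fit A fitted [mvmm()] (or its draws).
#' @param treatment Treatment label.
#' @return An object of class `"correlation_summary"`: fields `treatment`,
#'   `matrix` (posterior means, unit diagonal), `pairs` (data.frame with one
#'   row per unique pair).
#' @export
between_individual_correlations <- function(fit, treatment) {
  draws <- get_draws(fit)
  lb <- get_model_labels(fit)
  if (!treatment %in% lb$treatments)
    stop("unknown treatment '", treatment, "'")
  traits <- lb$traits
  T_ <- length(traits)
  Rm <- diag(T_)
  dimnames(Rm) <- list(traits, traits)
  ut <- which(upper.tri(Rm), arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(ut)), function(j) {
    t1 <- traits[ut[j, 1]]; t2 <- traits[ut[j, 2]]
    d <- draws[, paste0("cor_B[", treatment, ",", t1, ",", t2, "]")]
    ci89 <- credible_interval(d, 0.89)
    ci95 <- credible_interval(d, 0.95)
    data.frame(trait_1 = t1, trait_2 = t2, mean = mean(d),
               l89 = ci89[1], u89 = ci89[2],
               l95 = ci95[1], u95 = ci95[2],
               supported = ci_excludes_zero(ci89),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  Rm[upper.tri(Rm)] <- pairs$mean
  Rm[lower.tri(Rm)] <- t(Rm)[lower.tri(Rm)]
  structure(list(treatment = treatment, matrix = Rm, pairs = pairs),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, digits = 2, ...) {
  cat("Between-individual correlations,", x$treatment, "treatment\n")
  sup <- x$pairs[x$pairs$supported, , drop = FALSE]
  if (nrow(sup)) {
    cat("supported pairs (89% CI excludes zero):\n")
    print(format_ci_table(sup, digits), row.names = FALSE)
  } else cat("no pair's 89% CI excludes zero\n")
  invisible(x)
}

#' Posterior repeatability of a repeated trait
#'
#' Draw-wise `V_B / (V_B + V_W)`: the proportion of (non-mesocosm) variance
#' attributable to stable between-individual differences, for one trait in
#' one treatment. Defined only for repeated traits.
#'
#' @param fit A fitted [mvmm()] (or its draws).
#' @param trait Repeated trait label.
#' @param treatment Treatment label.
#' @return List with `draws`, `mean`, `ci89`, `ci95` (all in `[0, 1]`).
#' @export
repeatability <- function(fit, trait, treatment) {
  vb <- variance_draws(fit, trait, "between", treatment)
  vw <- variance_draws(fit, trait, "within", treatment)  # errors if fixed
  d <- vb / (vb + vw)
  list(trait = trait, treatment = treatment, draws = d, mean = mean(d),
       ci89 = credible_interval(d, 0.89), ci95 = credible_interval(d, 0.95))
}

#' Fixed-effect summary table
#'
#' One row per trait x coefficient (intercept, each treatment offset, trial
#' slope for repeated traits) with posterior mean, 89% and 95% equal-tailed
#' intervals and the supported flag (89% CI excluding zero).
#'
#' @param fit A fitted [mvmm()] (or its draws).
#' @return data.frame with columns `trait`, `term`, `mean`, `l89`, `u89`,
#'   `l95`, `u95`, `supported`.
#' @export
summarize_fixed_effects <- function(fit) {
  draws <- get_draws(fit)
  cn <- grep("^(mu|beta|gamma)\\[", colnames(draws), value = TRUE)
  rows <- lapply(cn, function(cl) {
    d <- draws[, cl]
    base <- sub("^([a-z]+)\\[.*$", "\\1", cl)
    inner <- sub("^[a-z]+\\[(.*)\\]$", "\\1", cl)
    parts <- strsplit(inner, ",")[[1]]
    trait <- parts[length(parts)]
    term <- switch(base, mu = "intercept",
                   beta = paste0("treatment:", parts[1]),
                   gamma = "trial")
    ci89 <- credible_interval(d, 0.89)
    ci95 <- credible_interval(d, 0.95)
    data.frame(trait = trait, term = term, mean = mean(d),
               l89 = ci89[1], u89 = ci89[2], l95 = ci95[1], u95 = ci95[2],
               supported = ci_excludes_zero(ci89), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Variance-component summary table
#'
#' Posterior means and intervals for every mesocosm SD, between-individual
#' SD (per treatment) and within-individual SD (per treatment, repeated
#' traits).
#'
#' @param fit A fitted [mvmm()] (or its draws).
#' @return data.frame with columns `component`, `treatment`, `trait`, `mean`,
#'   `l89`, `u89`, `l95`, `u95`.
#' @export
summarize_variances <- function(fit) {
  draws <- get_draws(fit)
  cn <- grep("^sd_(meso|B|W)\\[", colnames(draws), value = TRUE)
  rows <- lapply(cn, function(cl) {
    d <- draws[, cl]
    comp <- sub("^sd_([a-zA-Z]+)\\[.*$", "\\1", cl)
    inner <- sub("^sd_[a-zA-Z]+\\[(.*)\\]$", "\\1", cl)
    parts <- strsplit(inner, ",")[[1]]
    treatment <- if (length(parts) == 2) parts[1] else NA_character_
    trait <- parts[length(parts)]
    ci89 <- credible_interval(d, 0.89)
    ci95 <- credible_interval(d, 0.95)
    data.frame(component = switch(comp, meso = "sd_mesocosm",
                                  B = "sd_between", W = "sd_within"),
               treatment = treatment, trait = trait, mean = mean(d),
               l89 = ci89[1], u89 = ci89[2], l95 = ci95[1], u95 = ci95[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
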