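#' Standardized major-axis slope of log mass on log length
#'
#' The allometric exponent used by the scaled mass index: the SMA (reduced
#' major axis) slope of `ln(mass)` regressed on `ln(length)`, computed as the
#' OLS slope divided by the Pearson correlation (Peig & Green estimator).
#'
#' @param masses Body masses (g), all positive.
#' @param lengths Standard lengths (mm), all positive, not all equal.
#' @return The SMA exponent (dimensionless).
#' @examples
#' L <- c(14, 17, 20, 23)
#' fit_sma_slope(L^3, L)  # exactly 3 on perfectly cubic data
#' @export
fit_sma_slope <- function(masses, lengths) {
  if (length(masses) != length(lengths) || length(masses) < 3)
    stop("need >= 3 paired mass/length values")
  if (any(masses <= 0) || any(lengths <= 0))
    stop("domain error: masses and lengths must be positive")
  x <- log(lengths)
  y <- log(masses)
  if (stats::var(x) == 0)
    stop("degenerate input: zero variance in lengths")
  if (stats::var(y) == 0)
    stop("degenerate input: zero variance in masses")
  b_ols <- stats::cov(x, y) / stats::var(x)
  r <- stats::cor(x, y)
  if (r == 0) stop("degenerate input: mass and length are uncorrelated")
  b_ols / r
}

#' Scaled mass index (body condition)
#'
#' \eqn{SMI = M (L_0 / L)^{\beta}}: the mass each fish would have at the
#' reference length \eqn{L_0}, along the population allometry with exponent
#' \eqn{\beta} (see [fit_sma_slope()]).
#'
#' @param mass Body mass (g), positive.
#' @param length Standard length (mm), positive.
#' @param params List/object with fields `beta_sma` and `reference_length`;
#'   see [smi_params()].
#' @return SMI in grams (vectorised over `mass`/`length`).
#' @export
scaled_mass_index <- function(mass, length, params) {
  if (any(mass <= 0) || any(length <= 0) || params$reference_length <= 0)
    stop("domain error: mass, length and reference length must be positive")
  mass * (params$reference_length / length)^params$beta_sma
}

#' Parameters of the scaled mass index
#'
#' Defaults are the exposure study's values: SMA exponent 3.203 and mean
#' standard length 17.43 mm.
#'
#' @param beta_sma Allometric exponent.
#' @param reference_length Reference standard length (mm), positive.
#' @return A list with fields `beta_sma`, `reference_length`.
#' @export
smi_params <- function(beta_sma = 3.203, reference_length = 17.43) {
  if (reference_length <= 0) stop("reference_length must be positive")
  list(beta_sma = beta_sma, reference_length = reference_length)
}

#' Proportion of body area covered by colour patches
#'
#' `(orange_area + black_area) / body_area`, i.e. total coloration after
#' accounting for body size; lies in `[0, 1]`.
#'
#' @param orange_area,black_area,body_area Patch and body areas in the same
#'   (arbitrary) square units; areas must be non-negative, `body_area`
#'   positive, and patches cannot exceed the body.
#' @return Proportion in `[0, 1]` (vectorised).
#' @export
coloration_proportion <- function(orange_area, black_area, body_area) {
  if (any(body_area <= 0)) stop("domain error: body_area must be positive")
  if (any(orange_area < 0) || any(black_area < 0))
    stop("domain error: patch areas must be non-negative")
  if (any(orange_area + black_area > body_area * (1 + 1e-12)))
    stop("domain error: colour patch area exceeds body area")
  pmin((orange_area + black_area) / body_area, 1)
}

#' Sperm vitality from live/dead haemocytometer counts
#'
#' Ratio of live to total sperm pooled over the counting subsamples.
#'
#' @param live_counts,dead_counts Non-negative counts per subsample
#'   (typically 3 subsamples).
#' @return Proportion of live sperm in `[0, 1]`.
#' @export
sperm_vitality <- function(live_counts, dead_counts) {
  if (any(live_counts < 0) || any(dead_counts < 0))
    stop("domain error: counts must be non-negative")
  tot <- sum(live_counts) + sum(dead_counts)
  if (tot == 0) stop("undefined vitality: zero total sperm counted")
  sum(live_counts) / tot
}

#' Estimated total sperm count per ejaculate
#'
#' Mean of the per-subsample totals (live + dead), scaled by the dilution
#' factor and a chamber volume scale to estimate the ejaculate total. The
#' scaling is explicit because chamber geometry and extender volume vary
#' between protocols.
#'
#' @param live_counts,dead_counts Non-negative counts per subsample.
#' @param dilution_factor Dilution of the counted sample relative to the
#'   ejaculate (>= 1 typically); required.
#' @param volume_scale Ratio of total sample volume to counted chamber
#'   volume (default 1: report counts on the chamber scale).
#' @return Estimated sperm count (non-negative).
#' @export
sperm_count <- function(live_counts, dead_counts, dilution_factor,
                        volume_scale = 1) {
  if (missing(dilution_factor) || is.null(dilution_factor) ||
      is.na(dilution_factor))
    stop("configuration error: dilution_factor is required")
  if (length(live_counts) < 1) stop("need >= 1 counting subsample")
  if (length(live_counts) != length(dead_counts))
    stop("live and dead counts must be paired per subsample")
  if (any(live_counts < 0) || any(dead_counts < 0))
    stop("domain error: counts must be non-negative")
  mean(live_counts + dead_counts) * dilution_factor * volume_scale
}

#' Tracked-count-weighted mean sperm velocity
#'
#' Combines per-sample mean curvilinear velocities (VCL) into one value per
#' male, weighting each sample by the number of sperm tracked in it, so
#' samples in which more cells were measured count proportionally more.
#'
#' @param vcl Per-sample mean VCL (um/s).
#' @param n_tracked Number of sperm tracked per sample (>= 1 for any sample
#'   contributing to the mean).
#' @param weighting `"count"` (default) weights by `n_tracked`; `"equal"`
#'   averages the sample means unweighted.
#' @return Weighted mean VCL (um/s).
#' @export
mean_vcl <- function(vcl, n_tracked, weighting = c("count", "equal")) {
  weighting <- match.arg(weighting)
  if (length(vcl) < 1 || length(vcl) != length(n_tracked))
    stop("vcl and n_tracked must be matched, non-empty vectors")
  if (any(n_tracked < 0)) stop("domain error: tracked counts must be >= 0")
  keep <- n_tracked >= 1
  if (!any(keep)) stop("undefined velocity: no sample tracked any sperm")
  if (weighting == "equal") return(mean(vcl[keep]))
  sum(vcl[keep] * n_tracked[keep]) / sum(n_tracked[keep])
}

#' Standardize traits of a long table to z-scores
#'
#' Mean-centres and scales every trait to SD 1, pooling observations across
#' treatments, mesocosms and occasions (one global mean/SD per trait), and
#' left-centres the occasion index so the first trial is 0. Returns the
#' per-trait parameters needed for exact back-transformation.
#'
#' @param table A long table with columns `trait`, `occasion`, `value`
#'   (e.g. from [generate_population()] or [read_long_table()]).
#' @return A list with elements `table` (standardized long table, occasions
#'   recoded 0-based) and `params` (data.frame of trait, mean, sd).
#' @seealso [unstandardize_traits()]
#' @export
standardize_traits <- function(table) {
  stopifnot(all(c("trait", "occasion", "value") %in% names(table)))
  sp <- split(table$value, table$trait)
  mu <- vapply(sp, mean, numeric(1))
  sd_ <- vapply(sp, stats::sd, numeric(1))
  zero <- names(sd_)[is.na(sd_) | sd_ == 0]
  if (length(zero))
    stop("degenerate input: zero variance in trait(s) ",
         paste(zero, collapse = ", "))
  params <- data.frame(trait = names(mu), mean = unname(mu),
                       sd = unname(sd_), stringsAsFactors = FALSE)
  i <- match(table$trait, params$trait)
  table$value <- (table$value - params$mean[i]) / params$sd[i]
  table$occasion <- table$occasion - min(table$occasion)
  list(table = table, params = params)
}

#' Invert [standardize_traits()]
#'
#' @param table A standardized long table.
#' @param params The `params` data.frame returned by [standardize_traits()].
#' @param occasion_base Value the first occasion should take after the
#'   back-transformation (default 1, the file convention).
#' @return The long table on the original scale.
#' @export
unstandardize_traits <- function(table, params, occasion_base = 1) {
  i <- match(table$trait, params$trait)
  if (anyNA(i)) stop("unknown trait in table: not present in params")
  table$value <- table$value * params$sd[i] + params$mean[i]
  table$occasion <- table$occasion - min(table$occasion) + occasion_base
  table
}

#' Derive per-individual morphological phenotypes from raw measurements
#'
#' Computes body condition (scaled mass index), coloration proportion and
#' passes through gonopodium length from a wide morphometric table.
#'
#' @param morpho data.frame with columns `individual_id`, `body_mass`,
#'   `standard_length`, `gonopodium_length`, `body_area`, `orange_area`,
#'   `black_area`.
#' @param sma Optional [smi_params()]; if `NULL`, the exponent is fitted from
#'   the supplied masses/lengths with [fit_sma_slope()] and the reference
#'   length set to the mean standard length.
#' @return data.frame: `individual_id`, `body_condition`, `coloration`,
#'   `gonopodium_length`.
#' @export
derive_morpho_traits <- function(morpho, sma = NULL) {
  need <- c("individual_id", "body_mass", "standard_length",
            "gonopodium_length", "body_area", "orange_area", "black_area")
  miss <- setdiff(need, names(morpho))
  if (length(miss)) stop("morphometric table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(sma)) {
    sma <- smi_params(
      beta_sma = fit_sma_slope(morpho$body_mass, morpho$standard_length),
      reference_length = mean(morpho$standard_length))
  }
  data.frame(
    individual_id = morpho$individual_id,
    body_condition = scaled_mass_index(morpho$body_mass,
                                       morpho$standard_length, sma),
    coloration = coloration_proportion(morpho$orange_area,
                                       morpho$black_area, morpho$body_area),
    gonopodium_length = morpho$gonopodium_length,
    stringsAsFactors = FALSE)
}

#' Derive per-individual ejaculate phenotypes from raw sample tables
#'
#' @param velocity data.frame with columns `individual_id`, `vcl`,
#'   `n_tracked` (one row per velocity sample).
#' @param counts data.frame with columns `individual_id`, `live`, `dead`,
#'   `dilution_factor` (one row per counting subsample; the dilution factor
#'   is per individual and must be constant within one).
#' @param volume_scale Chamber volume scale passed to [sperm_count()].
#' @param weighting Velocity weighting passed to [mean_vcl()].
#' @return data.frame: `individual_id`, `sperm_vitality`, `sperm_count`,
#'   `sperm_velocity`. Individuals present in only one input get `NA` for the
#'   other block's traits.
#' @export
derive_ejaculate_traits <- function(velocity, counts, volume_scale = 1,
                                    weighting = "count") {
  stopifnot(all(c("individual_id", "vcl", "n_tracked") %in% names(velocity)),
            all(c("individual_id", "live", "dead", "dilution_factor")
                %in% names(counts)))
  ids <- sort(unique(c(velocity$individual_id, counts$individual_id)))
  out <- data.frame(individual_id = ids,
                    sperm_vitality = NA_real_,
                    sperm_count = NA_real_,
                    sperm_velocity = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    v <- velocity[velocity$individual_id == ids[i], , drop = FALSE]
    if (nrow(v))
      out$sperm_velocity[i] <- mean_vcl(v$vcl, v$n_tracked,
                                        weighting = weighting)
    cts <- counts[counts$individual_id == ids[i], , drop = FALSE]
    if (nrow(cts)) {
      dil <- unique(cts$dilution_factor)
      if (length(dil) != 1)
        stop("configuration error: dilution_factor varies within individual ",
             ids[i])
      out$sperm_vitality[i] <- sperm_vitality(cts$live, cts$dead)
      out$sperm_count[i] <- sperm_count(cts$live, cts$dead, dil,
                                        volume_scale = volume_scale)
    }
  }
  out
}
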