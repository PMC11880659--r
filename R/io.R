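#' Atomic file write (temp + rename)
#'
#' Writes through a temporary file in the same directory and renames it into
#' place, so an interrupted run never leaves a half-written file.
#' @noRd
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file into place at ", path)
  invisible(path)
}

long_table_columns <- function() {
  c("individual_id", "mesocosm_id", "treatment", "trait", "occasion",
    "value")
}

#' Write a long trait table as delimited text
#'
#' CSV with header, columns `individual_id`, `mesocosm_id`, `treatment`,
#' `trait`, `occasion`, `value`; written atomically.
#'
#' @param table Long table (e.g. from [generate_population()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(table, path) {
  miss <- setdiff(long_table_columns(), names(table))
  if (length(miss))
    stop("long table lacks column(s): ", paste(miss, collapse = ", "))
  atomic_write(path, function(p)
    utils::write.csv(as.data.frame(table)[long_table_columns()], p,
                     row.names = FALSE, quote = FALSE))
}

#' Read and validate a long trait table
#'
#' Reads the CSV written by [write_long_table()], checks the header, value
#' types and key uniqueness; duplicate `(individual, trait, occasion)` rows
#' are rejected with the offending line number.
#'
#' @param path CSV file path.
#' @return A validated long table of class `"pols_longtable"`.
#' @export
read_long_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(long_table_columns(), names(tab))
  if (length(miss))
    stop("schema mismatch in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if (!is.numeric(tab$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$value))))[1]
    stop("non-numeric value at line ", bad + 1L, " of ", path)
  }
  if (anyNA(tab$value))
    stop("missing value at line ", which(is.na(tab$value))[1] + 1L,
         " of ", path)
  if (!is.numeric(tab$occasion))
    stop("non-numeric occasion in ", path)
  key <- paste(tab$individual_id, tab$trait, tab$occasion)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("duplicate (individual, trait, occasion) key at line ", d + 1L,
         " of ", path)
  }
  class(tab) <- c("pols_longtable", "data.frame")
  tab
}

write_tsv_report <- function(df, path) {
  atomic_write(path, function(p)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE))
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the stages end to end: obtain data (generate a synthetic
#' scenario, or read a long table / raw measurement tables), standardize,
#' fit the multivariate mixed model, summarise the posterior, and write the
#' report files. Every output is written atomically; rerunning with the same
#' configuration reproduces the report bit for bit.
#'
#' The configuration is a named list (or path to a YAML file) with fields:
#' \describe{
#'   \item{scenario}{Synthetic scenario label (see [known_truth()]), or}
#'   \item{input}{List of file paths: `long_table`, or raw tables
#'     `behaviour` (long rows of the behavioural traits), `morphometrics`,
#'     `velocity`, `counts` plus `design` columns for treatment/mesocosm.}
#'   \item{seed}{Mandatory integer seed.}
#'   \item{out_dir}{Output directory.}
#'   \item{standardize}{Standardize traits before fitting (default `TRUE`
#'     for file input; synthetic scenarios are generated on the model scale
#'     and fitted as-is unless this is set).}
#'   \item{sampler}{Optional list: `chains`, `iter`, `warmup`, `thin`.}
#'   \item{prior_flavour}{`"weakly_informative"` (default) or `"flat"`.}
#' }
#'
#' @param config Named list or YAML file path.
#' @return Invisibly, a list with the fit, the summary tables and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("validation error: config$seed is mandatory")
  seed <- as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  has_scenario <- !is.null(config$scenario)
  has_input <- !is.null(config$input)
  if (has_scenario == has_input)
    stop("validation error: supply exactly one of scenario / input")

  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  std_params <- NULL
  if (has_scenario) {
    say("stage simulate: scenario '", config$scenario, "', seed ", seed)
    truth <- known_truth(config$scenario)
    cfg_args <- config$design
    cfg <- if (is.null(cfg_args)) design_config(seed = seed)
      else do.call(design_config, c(cfg_args, list(seed = seed)))
    dat <- generate_population(cfg, truth, seed = seed)
    write_long_table(dat, file.path(out_dir, "long_table.csv"))
    write_truth(truth, file.path(out_dir, "truth.yaml"))
    if (isTRUE(config$standardize)) {
      std <- standardize_traits(dat)
      dat <- std$table
      std_params <- std$params
    }
  } else {
    dat <- ingest_inputs(config$input)
    say("stage derive/read: ", nrow(dat), " rows ingested")
    if (!identical(config$standardize, FALSE)) {
      std <- standardize_traits(dat)
      dat <- std$table
      std_params <- std$params
      say("stage standardize: ", nrow(std$params), " traits z-scored")
    }
  }
  if (!is.null(std_params))
    write_tsv_report(std_params,
                     file.path(out_dir, "standardization_params.tsv"))
  write_long_table(dat, file.path(out_dir, "long_table_fitted.csv"))

  sset <- config$sampler
  chains <- if (is.null(sset$chains)) 4 else sset$chains
  iter <- if (is.null(sset$iter)) 8000 else sset$iter
  warmup <- if (is.null(sset$warmup)) 3000 else sset$warmup
  thin <- if (is.null(sset$thin)) 2 else sset$thin
  flavour <- if (is.null(config$prior_flavour)) "weakly_informative"
    else config$prior_flavour

  traits <- if (!is.null(attr(dat, "trait_levels")))
    attr(dat, "trait_levels") else sort(unique(dat$trait))
  spec <- mvmm_spec(
    trait_names = traits,
    repeated = intersect(pols_behaviours(), traits),
    treatment_names = {
      tr <- unique(dat$treatment)
      std <- c("control", "low", "high")
      c(std[std %in% tr], sort(setdiff(tr, std)))
    },
    priors = prior_set(flavour, n_traits = length(traits)))

  say("stage fit: ", chains, " chains x ", iter, " iterations (warmup ",
      warmup, ", thin ", thin, "), priors ", flavour)
  fit <- mvmm(dat, spec = spec, chains = chains, iter = iter,
              warmup = warmup, thin = thin, seed = seed, check = chains >= 2)
  if (!is.null(fit$diagnostics)) {
    say("stage fit: max split-Rhat ", round(fit$diagnostics$max_rhat, 4),
        ", min bulk ESS ", round(fit$diagnostics$min_ess),
        if (fit$diagnostics$ok) " (converged)" else " (FLAGGED)")
  }

  say("stage summarize: writing report tables")
  paths <- write_report(fit, out_dir)

  meta <- list(seed = seed,
               settings = fit$settings,
               data_hash = attr(fit$draws, "data_hash"),
               prior_flavour = flavour,
               convergence = if (is.null(fit$diagnostics)) NULL else
                 list(ok = fit$diagnostics$ok,
                      max_rhat = fit$diagnostics$max_rhat,
                      min_ess = fit$diagnostics$min_ess),
               spec = list(traits = spec$trait_names,
                           repeated = spec$repeated,
                           treatments = spec$treatment_names,
                           sigma_fixed = spec$sigma_fixed))
  atomic_write(file.path(out_dir, "run_metadata.yaml"),
               function(p) yaml::write_yaml(meta, p))
  atomic_write(file.path(out_dir, "run_log.txt"),
               function(p) writeLines(log_lines, p))
  invisible(list(fit = fit, paths = paths, log = log_lines))
}

ingest_inputs <- function(input) {
  if (!is.null(input$long_table))
    return(read_long_table(input$long_table))
  if (is.null(input$behaviour) || is.null(input$design))
    stop("validation error: raw input needs 'behaviour' and 'design' paths")
  beh <- utils::read.csv(input$behaviour, stringsAsFactors = FALSE)
  design <- utils::read.csv(input$design, stringsAsFactors = FALSE)
  need <- c("individual_id", "mesocosm_id", "treatment")
  if (!all(need %in% names(design)))
    stop("design table lacks columns: ",
         paste(setdiff(need, names(design)), collapse = ", "))
  wide <- design[need]
  if (!is.null(input$morphometrics)) {
    morpho <- derive_morpho_traits(
      utils::read.csv(input$morphometrics, stringsAsFactors = FALSE))
    wide <- merge(wide, morpho, by = "individual_id", all.x = TRUE)
  }
  if (!is.null(input$velocity) && !is.null(input$counts)) {
    ej <- derive_ejaculate_traits(
      utils::read.csv(input$velocity, stringsAsFactors = FALSE),
      utils::read.csv(input$counts, stringsAsFactors = FALSE))
    wide <- merge(wide, ej, by = "individual_id", all.x = TRUE)
  }
  # wide once-measured traits -> long rows with occasion 1
  value_cols <- setdiff(names(wide), need)
  long_once <- do.call(rbind, lapply(value_cols, function(cl) {
    keep <- !is.na(wide[[cl]])
    data.frame(individual_id = wide$individual_id[keep],
               mesocosm_id = wide$mesocosm_id[keep],
               treatment = wide$treatment[keep],
               trait = cl, occasion = 1L, value = wide[[cl]][keep],
               stringsAsFactors = FALSE)
  }))
  need_beh <- c("individual_id", "trait", "occasion", "value")
  if (!all(need_beh %in% names(beh)))
    stop("behaviour table lacks columns: ",
         paste(setdiff(need_beh, names(beh)), collapse = ", "))
  beh <- merge(beh[need_beh], design, by = "individual_id")
  out <- rbind(long_once[long_table_columns()],
               beh[long_table_columns()])
  class(out) <- c("pols_longtable", "data.frame")
  out
}

#' Write the posterior report tables of a fitted model
#'
#' Emits the fixed-effect table, the variance-component table, both Delta-V
#' contrast tables (between-individual for all traits, within-individual for
#' repeated traits; all ordered treatment pairs), one correlation table per
#' treatment, and a human-readable summary. All files are tab-separated text
#' written atomically.
#'
#' @param fit A fitted [mvmm()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the paths written, invisibly.
#' @export
write_report <- function(fit, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  m <- fit$model
  paths <- character(0)
  add <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv_report(df, p)
    paths <<- c(paths, p)
  }
  add(summarize_fixed_effects(fit), "fixed_effects.tsv")
  add(summarize_variances(fit), "variance_components.tsv")

  pairs <- utils::combn(m$treatments, 2, simplify = FALSE)
  dv_rows <- function(traits, level) {
    do.call(rbind, lapply(traits, function(tr)
      do.call(rbind, lapply(pairs, function(pp) {
        d <- delta_v(fit, tr, level, pp[1], pp[2])
        data.frame(trait = tr, level = level,
                   group_a = pp[1], group_b = pp[2], mean = d$mean,
                   l89 = d$ci89[1], u89 = d$ci89[2],
                   l95 = d$ci95[1], u95 = d$ci95[2],
                   supported = d$supported, stringsAsFactors = FALSE)
      }))))
  }
  if (m$K > 1) {
    add(dv_rows(m$traits, "between"), "delta_v_between.tsv")
    if (m$B > 0)
      add(dv_rows(m$traits[m$beh_idx], "within"), "delta_v_within.tsv")
  }
  for (k in m$treatments) {
    cs <- between_individual_correlations(fit, k)
    add(cs$pairs, paste0("correlations_", k, ".tsv"))
  }
  if (m$B > 0) {
    rep_rows <- do.call(rbind, lapply(m$traits[m$beh_idx], function(tr)
      do.call(rbind, lapply(m$treatments, function(k) {
        r <- repeatability(fit, tr, k)
        data.frame(trait = tr, treatment = k, mean = r$mean,
                   l89 = r$ci89[1], u89 = r$ci89[2],
                   l95 = r$ci95[1], u95 = r$ci95[2],
                   stringsAsFactors = FALSE)
      }))))
    add(rep_rows, "repeatability.tsv")
  }
  invisible(paths)
}
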