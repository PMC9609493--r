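# Config-driven orchestration of the full analysis graph: instrument
# selection -> harmonization -> univariable estimators -> diagnostics ->
# multivariable MR -> mediation, with a provenance ledger. A rerun with an
# identical config and seed produces bitwise-identical output tables.

.default_thresholds <- function() {
  list(p_threshold = 5e-8, window_kb = 10000, r2_limit = 0.001,
       maf_min = 0.01, palindrome_band = c(0.42, 0.58),
       drop_palindromic_ambiguous = TRUE)
}

.default_methods <- function() {
  list(ivw_model = "random", n_boot = 1000, n_sim = 5000,
       outlier_alpha = 0.05, mediation_method = "product")
}

#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML (or equivalent R list) with fields:
#' `seed` (mandatory integer), `output_dir`, `traits` (named list, each
#' with `file` and optional `column_map`), `edges` (list of
#' `exposure`/`outcome` pairs), optional `mvmr` (lists of `exposures` +
#' `outcome`), optional `mediation` (lists of `exposure`, `mediators`,
#' `outcome`, optional `method`), optional `thresholds` and `methods`
#' overrides, optional `exclude_file` (one variant ID per line).
#'
#' @param config Path to a YAML file, or an R list with the same shape.
#' @return A validated list of class `"pipeline_config"` with defaults
#'   filled in and a `hash` field (MD5 of the canonical serialization).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config must set a seed")
  if (is.null(config$traits) || length(config$traits) == 0) {
    stop("config must define at least one trait")
  }
  if (anyDuplicated(names(config$traits))) {
    stop("each trait must be defined exactly once")
  }
  refs <- c(
    unlist(lapply(config$edges, function(e) c(e$exposure, e$outcome))),
    unlist(lapply(config$mvmr, function(e) c(e$exposures, e$outcome))),
    unlist(lapply(config$mediation,
                  function(e) c(e$exposure, e$mediators, e$outcome)))
  )
  unknown <- setdiff(refs, names(config$traits))
  if (length(unknown) > 0) {
    stop("config references undefined trait(s): ",
         paste(unique(unknown), collapse = ", "))
  }
  config$thresholds <- utils::modifyList(.default_thresholds(),
                                         config$thresholds %||% list())
  config$methods <- utils::modifyList(.default_methods(),
                                      config$methods %||% list())
  config$seed <- as.integer(config$seed)
  config$hash <- .config_hash(config)
  class(config) <- "pipeline_config"
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# MD5 of the canonically serialized config (hash field excluded)
.config_hash <- function(config) {
  config$hash <- NULL
  config <- config[order(names(config))]
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

.load_traits <- function(config) {
  lapply(config$traits, function(tr) {
    read_sumstats(tr$file, column_map = unlist(tr$column_map))
  })
}

#' Run the full MR analysis pipeline
#'
#' Executes, for every configured exposure-outcome edge: instrument
#' selection, harmonization, the five univariable estimators (IVW,
#' MR-Egger, weighted median, maximum likelihood, RAPS), heterogeneity and
#' pleiotropy diagnostics (Cochran's Q, Egger intercept), leave-one-out,
#' and MR-PRESSO (edges with at least 4 instruments); then any configured
#' multivariable MR fits and two-step mediation decompositions. Per-edge
#' seeds are derived from the master seed via a counter so edges are
#' independent yet reproducible. Every output table carries the config
#' hash and master seed.
#'
#' @param config A [pipeline_config()] (or path / list accepted by it).
#' @param output_dir Optional override of the config's output directory;
#'   `NULL` writes no files.
#' @return A report bundle (list of class `"mr_report"`): `estimates`,
#'   `heterogeneity`, `presso`, `leave_one_out` (named list of tables),
#'   `mvmr`, `mediation`, `provenance`, `config_hash`, `seed`.
#' @export
run_pipeline <- function(config, output_dir) {
  config <- pipeline_config(config)
  if (missing(output_dir)) output_dir <- config$output_dir
  th <- config$thresholds
  me <- config$methods
  traits <- .load_traits(config)
  exclude <- if (!is.null(config$exclude_file)) {
    read_exclusion_list(config$exclude_file)
  } else character(0)

  edge_seed <- local({
    counter <- 0L
    function() {
      counter <<- counter + 1L
      as.integer((as.double(config$seed) + 104729 * counter) %% 2147483629)
    }
  })

  estimates <- list(); heterogeneity <- list(); presso <- list()
  loo_tables <- list(); provenance <- list()

  for (edge in config$edges) {
    label <- paste0(edge$exposure, "->", edge$outcome)
    t0 <- proc.time()[["elapsed"]]
    sel <- select_instruments(traits[[edge$exposure]],
                              p_threshold = th$p_threshold,
                              window_kb = th$window_kb,
                              r2_limit = th$r2_limit,
                              maf_min = th$maf_min, exclude = exclude)
    iv <- harmonize(sel, traits[[edge$outcome]],
                    palindrome_eaf_band = th$palindrome_band,
                    drop_palindromic_ambiguous = th$drop_palindromic_ambiguous)
    if (nrow(iv) < 3) {
      stop("stage estimators, edge ", label, ": only ", nrow(iv),
           " harmonized instruments")
    }
    s <- edge_seed()
    est <- mr_all_methods(iv, n_boot = me$n_boot, seed = s,
                          ivw_model = me$ivw_model)
    est <- cbind(exposure = edge$exposure, outcome = edge$outcome, est,
                 stringsAsFactors = FALSE)
    estimates[[label]] <- est

    q <- cochran_q(iv)
    eg <- egger_intercept_test(iv)
    heterogeneity[[label]] <- data.frame(
      exposure = edge$exposure, outcome = edge$outcome, method = "IVW",
      cochran_q = q$Q, df = q$df, q_pval = q$pval, i_squared = q$i_squared,
      egger_intercept = eg$egger_intercept,
      egger_ci_low = eg$egger_intercept_ci_low,
      egger_ci_high = eg$egger_intercept_ci_high,
      egger_pval = eg$egger_intercept_pval, stringsAsFactors = FALSE)

    loo_tables[[label]] <- cbind(exposure = edge$exposure,
                                 outcome = edge$outcome,
                                 leave_one_out(iv, model = me$ivw_model),
                                 stringsAsFactors = FALSE)

    if (nrow(iv) >= 4) {
      pr <- mr_presso(iv, n_sim = me$n_sim,
                      outlier_alpha = me$outlier_alpha,
                      seed = edge_seed(), model = me$ivw_model)
      corrected <- pr$corrected_estimate
      presso[[label]] <- data.frame(
        exposure = edge$exposure, outcome = edge$outcome,
        n_raw = pr$raw_estimate$n_snps, beta_raw = pr$raw_estimate$beta,
        pval_raw = pr$raw_estimate$pval,
        n_outliers = length(pr$outlier_ids),
        n_corrected = if (is.null(corrected)) NA_integer_ else corrected$n_snps,
        beta_corrected = if (is.null(corrected)) NA_real_ else corrected$beta,
        pval_corrected = if (is.null(corrected)) NA_real_ else corrected$pval,
        global_pval = pr$global_pval, global_pval_label = pr$global_pval_label,
        distortion_pval = pr$distortion_pval, stringsAsFactors = FALSE)
    }

    counts <- attr(iv, "counts")
    provenance[[label]] <- data.frame(
      edge = label, step = names(counts), count = as.integer(counts),
      stringsAsFactors = FALSE)
    message(sprintf("[edge %s] %d instruments, %.2fs", label, nrow(iv),
                    proc.time()[["elapsed"]] - t0))
  }

  mvmr_rows <- list()
  for (mv in config$mvmr) {
    label <- paste0(paste(mv$exposures, collapse = "+"), "->", mv$outcome)
    mvset <- mvmr_harmonize(traits[mv$exposures], traits[[mv$outcome]],
                            p_threshold = th$p_threshold,
                            maf_min = th$maf_min, exclude = exclude,
                            palindrome_eaf_band = th$palindrome_band,
                            drop_palindromic_ambiguous = th$drop_palindromic_ambiguous)
    fit <- mvmr_ivw(mvset)
    mvmr_rows[[label]] <- cbind(analysis = label, outcome = mv$outcome,
                                fit$estimates, n_snps = fit$n_snps,
                                stringsAsFactors = FALSE)
  }

  mediation_rows <- list()
  for (md in config$mediation) {
    label <- paste0(md$exposure, "->{", paste(md$mediators, collapse = ","),
                    "}->", md$outcome)
    dec <- two_step_mediation(
      traits[[md$exposure]], traits[md$mediators], traits[[md$outcome]],
      method = md$method %||% me$mediation_method,
      ivw_model = me$ivw_model, p_threshold = th$p_threshold,
      maf_min = th$maf_min, exclude = exclude,
      palindrome_eaf_band = th$palindrome_band,
      drop_palindromic_ambiguous = th$drop_palindromic_ambiguous)
    mediation_rows[[label]] <- cbind(analysis = label,
                                     exposure = md$exposure,
                                     outcome = md$outcome, dec$table,
                                     stringsAsFactors = FALSE)
  }

  bind <- function(lst) if (length(lst) == 0) NULL else do.call(rbind, lst)
  stamp <- function(df) {
    if (is.null(df)) return(NULL)
    df$config_hash <- config$hash
    df$seed <- config$seed
    rownames(df) <- NULL
    df
  }
  report <- structure(list(
    estimates = stamp(bind(estimates)),
    heterogeneity = stamp(bind(heterogeneity)),
    presso = stamp(bind(presso)),
    leave_one_out = lapply(loo_tables, stamp),
    mvmr = stamp(bind(mvmr_rows)),
    mediation = stamp(bind(mediation_rows)),
    provenance = stamp(bind(provenance)),
    config_hash = config$hash, seed = config$seed
  ), class = "mr_report")

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      if (!is.null(df)) write_table(df, file.path(output_dir, name))
    }
    wr(report$estimates, "estimates.tsv")
    wr(report$heterogeneity, "heterogeneity.tsv")
    wr(report$presso, "presso.tsv")
    wr(report$mvmr, "mvmr.tsv")
    wr(report$mediation, "mediation.tsv")
    wr(report$provenance, "provenance.tsv")
    for (nm in names(report$leave_one_out)) {
      safe <- gsub("[^A-Za-z0-9._-]+", "_", nm)
      wr(report$leave_one_out[[nm]], paste0("leave_one_out-", safe, ".tsv"))
    }
  }
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat("MR pipeline report (config", substr(x$config_hash, 1, 8),
      "seed", x$seed, ")\n")
  if (!is.null(x$estimates)) {
    cat("\nEstimates:\n")
    print(x$estimates[, c("exposure", "outcome", "method", "beta", "se",
                          "or", "pval", "n_snps")],
          row.names = FALSE, digits = 4)
  }
  if (!is.null(x$mediation)) {
    cat("\nMediation:\n")
    print(x$mediation[, c("analysis", "mediator", "method",
                          "proportion_mediated", "inconsistent")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write a synthetic scenario to disk with a ready-to-run config
#'
#' Simulates a two-sample scenario from a [sim_truth()] object, writes one
#' canonical summary-statistics file per trait, the ground-truth parameters
#' as YAML, and a pipeline config wiring up exposure -> outcome,
#' exposure -> each mediator, each mediator -> outcome, the all-mediator
#' multivariable fit, and the mediation decomposition.
#'
#' @param truth A [sim_truth()] object.
#' @param dir Output directory (created if needed).
#' @param mediation_method Mediation method recorded in the config.
#' @return Path to the written config file, invisibly; the simulated data
#'   are under `dir`.
#' @export
simulate_scenario <- function(truth, dir, mediation_method = "both") {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_two_sample(truth)
  files <- list(exposure = file.path(dir, "exposure.tsv"),
                outcome = file.path(dir, "outcome.tsv"))
  write_table(sim$exposure, files$exposure)
  write_table(sim$outcome, files$outcome)
  med_names <- names(sim$mediators)
  for (nm in med_names) {
    files[[nm]] <- file.path(dir, paste0(nm, ".tsv"))
    write_table(sim$mediators[[nm]], files[[nm]])
  }
  truth_out <- unclass(truth)
  yaml::write_yaml(truth_out, file.path(dir, "truth.yaml"))

  traits <- c(list(exposure = list(file = files$exposure),
                   outcome = list(file = files$outcome)),
              stats::setNames(lapply(med_names,
                                     function(nm) list(file = files[[nm]])),
                              med_names))
  edges <- c(list(list(exposure = "exposure", outcome = "outcome")),
             lapply(med_names, function(nm)
               list(exposure = "exposure", outcome = nm)),
             lapply(med_names, function(nm)
               list(exposure = nm, outcome = "outcome")))
  config <- list(
    seed = truth$seed,
    output_dir = file.path(dir, "results"),
    traits = traits,
    edges = edges,
    mvmr = list(list(exposures = c("exposure", med_names),
                     outcome = "outcome")),
    mediation = list(list(exposure = "exposure", mediators = med_names,
                          outcome = "outcome", method = mediation_method))
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}
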