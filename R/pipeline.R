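# Orchestration: selection -> harmonisation -> estimation -> diagnostics per
# (target, outcome) pair from a single config, with per-pair error isolation
# and a forest-style report table.

#' Analysis configuration
#'
#' Builds/validates the configuration driving [run_analysis()]. Inputs may
#' be given as file paths (read with the package readers) or as in-memory
#' objects (`sumstats`, `region_catalog`, `ld_matrix`).
#'
#' @param exposure Exposure summary statistics: path or `sumstats`.
#' @param outcomes Named list of outcome summary statistics (paths or
#'   `sumstats`), e.g. `list(AS = ..., RA = ...)`.
#' @param regions Region catalog: path or `region_catalog`.
#' @param ld LD matrix: path or `ld_matrix`.
#' @param targets Character vector of target gene names.
#' @param selection A [selection_config()].
#' @param seed Base seed for the estimation stage (bootstrap, PRESSO).
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @param n_sim MR-PRESSO simulation replicates.
#' @param phi Weighted-mode bandwidth multiplier.
#' @param loss MR-RAPS loss (`"huber"` or `"l2"`).
#' @param genome_build Free-text metadata carried into the report (the
#'   package never converts coordinates between builds).
#' @return A list with class `analysis_config`.
#' @export
analysis_config <- function(exposure, outcomes, regions, ld, targets,
                            selection = selection_config(), seed = 1,
                            n_boot = 1000, n_sim = 1000, phi = 1,
                            loss = "huber", genome_build = NA_character_) {
  if (length(targets) < 1) stop_config("at least one target is required")
  if (length(outcomes) < 1 || is.null(names(outcomes)) ||
      any(names(outcomes) == "")) {
    stop_config("outcomes must be a non-empty named list")
  }
  structure(
    list(exposure = exposure, outcomes = outcomes, regions = regions,
         ld = ld, targets = targets, selection = selection,
         seed = as.integer(seed), n_boot = n_boot, n_sim = n_sim,
         phi = phi, loss = loss, genome_build = genome_build),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' Expects the fields of [analysis_config()] with `selection` as a nested
#' map of [selection_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  sel <- do.call(selection_config, y$selection %||% list())
  analysis_config(
    exposure = y$exposure, outcomes = y$outcomes, regions = y$regions,
    ld = y$ld, targets = y$targets, selection = sel,
    seed = y$seed %||% 1, n_boot = y$n_boot %||% 1000,
    n_sim = y$n_sim %||% 1000, phi = y$phi %||% 1,
    loss = y$loss %||% "huber",
    genome_build = y$genome_build %||% NA_character_
  )
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

# Deterministic hash of the config: canonical JSON (sorted names, paths and
# in-memory objects serialised alike) -> md5.
config_hash <- function(config) {
  canon <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                            force = TRUE, null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(canon), tmp)
  unname(tools::md5sum(tmp))
}

analyze_pair <- function(instruments_sel, outcome, target, outcome_name,
                         config) {
  harm <- harmonize(instruments_sel$instruments, outcome)
  oriented <- orient_exposure_increasing(harm)
  k <- nrow(oriented)
  if (k == 0) {
    stop_validation("no instruments remain after harmonisation")
  }
  battery <- mr_all(oriented, n_boot = config$n_boot, seed = config$seed,
                    phi = config$phi, loss = config$loss)
  het <- if (k >= 2) cochran_q(oriented) else NULL
  loo <- if (k >= 3) leave_one_out(oriented) else NULL
  presso <- if (k >= 4) {
    mr_presso(oriented, n_sim = config$n_sim, seed = config$seed + 10)
  } else NULL
  influence <- if (k >= 4) {
    cooks_outliers(oriented, n_boot = config$n_boot, seed = config$seed + 20,
                   phi = config$phi, loss = config$loss)
  } else NULL
  plots <- plot_data(oriented, battery$estimates, battery$egger)
  list(
    target = target, outcome = outcome_name,
    selection = instruments_sel,
    droplog = harmonization_droplog(oriented),
    n_instruments = k,
    battery = battery,
    heterogeneity = het,
    leave_one_out = loo,
    presso = presso,
    influence = influence,
    plot_data = plots,
    error = NULL
  )
}

#' Run the full drug-target MR analysis
#'
#' For every target: select instruments from the exposure GWAS (region
#' extraction, Bonferroni threshold, LD clumping, palindrome exclusion);
#' then for every outcome: harmonise, orient to the biomarker-increasing
#' allele, run the estimator battery (Wald for single-instrument targets,
#' otherwise IVW plus the sensitivity methods whose preconditions hold) and
#' the diagnostics (Cochran's Q, leave-one-out, MR-PRESSO, Cook's screen
#' with rerun). A failure in one pair is recorded and does not stop the
#' others.
#'
#' @param config An [analysis_config()].
#' @return An `analysis_report`: `pairs` (list keyed `target:outcome`, each
#'   as returned by the per-pair analysis or carrying an `error` string),
#'   `provenance` (config hash, seed, package version), `config`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  exposure <- resolve_input(config$exposure, read_sumstats)
  regions <- resolve_input(config$regions, read_regions)
  ld <- resolve_input(config$ld, read_ld_matrix)
  outcomes <- lapply(config$outcomes, resolve_input, reader = read_sumstats)

  pairs <- list()
  for (target in config$targets) {
    sel <- tryCatch(
      select_instruments(exposure, regions, target, ld, config$selection),
      dtmr_error = function(e) e
    )
    for (outcome_name in names(outcomes)) {
      key <- paste(target, outcome_name, sep = ":")
      if (inherits(sel, "condition")) {
        pairs[[key]] <- list(target = target, outcome = outcome_name,
                             error = conditionMessage(sel))
        next
      }
      pairs[[key]] <- tryCatch(
        analyze_pair(sel, outcomes[[outcome_name]], target, outcome_name,
                     config),
        dtmr_error = function(e) {
          list(target = target, outcome = outcome_name, selection = sel,
               error = conditionMessage(e))
        }
      )
    }
  }
  structure(
    list(
      pairs = pairs,
      provenance = list(
        config_hash = config_hash(config),
        seed = config$seed,
        package_version = as.character(utils::packageVersion("dtmr"))
      ),
      config = config
    ),
    class = "analysis_report"
  )
}

#' Forest-style results table
#'
#' One row per (target, outcome, method) with the OR per unit biomarker
#' decrease and its CI; methods whose preconditions failed appear with a
#' `note` instead of an estimate, and failed pairs carry their error
#' message.
#'
#' @param report An `analysis_report`.
#' @return Data.frame sorted by target, outcome, then method.
#' @export
render_forest_table <- function(report) {
  rows <- list()
  for (pair in report$pairs) {
    if (!is.null(pair$error)) {
      rows[[length(rows) + 1]] <- data.frame(
        target = pair$target, outcome = pair$outcome, method = NA_character_,
        n_snps = NA_integer_, theta = NA_real_, se = NA_real_,
        or_per_decrease = NA_real_, or_ci_low = NA_real_,
        or_ci_high = NA_real_, pval = NA_real_,
        note = paste("error:", pair$error), stringsAsFactors = FALSE
      )
      next
    }
    for (m in names(pair$battery$estimates)) {
      e <- pair$battery$estimates[[m]]
      rows[[length(rows) + 1]] <- data.frame(
        target = pair$target, outcome = pair$outcome, method = m,
        n_snps = e$n_snps, theta = e$theta, se = e$se,
        or_per_decrease = e$or_per_decrease, or_ci_low = e$or_ci_low,
        or_ci_high = e$or_ci_high, pval = e$pval, note = NA_character_,
        stringsAsFactors = FALSE
      )
    }
    for (m in names(pair$battery$not_applicable)) {
      rows[[length(rows) + 1]] <- data.frame(
        target = pair$target, outcome = pair$outcome, method = m,
        n_snps = pair$n_instruments, theta = NA_real_, se = NA_real_,
        or_per_decrease = NA_real_, or_ci_low = NA_real_,
        or_ci_high = NA_real_, pval = NA_real_,
        note = pair$battery$not_applicable[[m]], stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$target, out$outcome, out$method), , drop = FALSE]
  rownames(out) <- NULL
  out
}

diagnostics_table <- function(report) {
  rows <- list()
  for (pair in report$pairs) {
    if (!is.null(pair$error)) next
    het <- pair$heterogeneity
    presso <- pair$presso
    egger <- pair$battery$egger
    influence <- pair$influence
    rows[[length(rows) + 1]] <- data.frame(
      target = pair$target, outcome = pair$outcome,
      q = if (is.null(het)) NA_real_ else het$q,
      q_df = if (is.null(het)) NA_integer_ else het$df,
      q_pval = if (is.null(het)) NA_real_ else het$pval,
      egger_intercept = if (is.null(egger)) NA_real_ else egger$intercept,
      egger_intercept_pval = if (is.null(egger)) NA_real_ else egger$intercept_pval,
      presso_global_pval = if (is.null(presso)) NA_real_ else presso$global_pval,
      presso_n_outliers = if (is.null(presso)) NA_integer_ else length(presso$outlier_rsids),
      presso_distortion_pval = if (is.null(presso)) NA_real_ else presso$distortion_pval,
      cooks_n_excluded = if (is.null(influence)) NA_integer_ else length(influence$excluded_rsids),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) return(data.frame())
  do.call(rbind, rows)
}

droplog_table <- function(report) {
  rows <- list()
  for (pair in report$pairs) {
    if (is.null(pair$droplog) || nrow(pair$droplog) == 0) next
    rows[[length(rows) + 1]] <- cbind(
      data.frame(target = pair$target, outcome = pair$outcome,
                 stringsAsFactors = FALSE),
      pair$droplog
    )
  }
  if (length(rows) == 0) {
    return(data.frame(target = character(), outcome = character(),
                      rsid = character(), reason = character()))
  }
  do.call(rbind, rows)
}

report_to_json_list <- function(report) {
  pairs <- lapply(report$pairs, function(pair) {
    if (!is.null(pair$error)) {
      return(list(target = pair$target, outcome = pair$outcome,
                  error = pair$error))
    }
    sel <- pair$selection
    list(
      target = pair$target, outcome = pair$outcome,
      selection = list(
        n_region_snps = sel$n_region_snps, p_threshold = sel$p_threshold,
        n_significant = sel$n_significant, n_post_clump = sel$n_post_clump,
        n_post_palindrome = sel$n_post_palindrome,
        kept_rsids = sel$kept_rsids
      ),
      n_instruments = pair$n_instruments,
      estimates = lapply(pair$battery$estimates, function(e) unclass(e)),
      not_applicable = as.list(pair$battery$not_applicable),
      egger_intercept = if (is.null(pair$battery$egger)) NULL else list(
        intercept = pair$battery$egger$intercept,
        se = pair$battery$egger$intercept_se,
        pval = pair$battery$egger$intercept_pval
      ),
      raps = if (is.null(pair$battery$raps)) NULL else list(
        tau2 = pair$battery$raps$tau2, loss = pair$battery$raps$loss
      ),
      heterogeneity = if (is.null(pair$heterogeneity)) NULL else
        unclass(pair$heterogeneity),
      presso = if (is.null(pair$presso)) NULL else list(
        rss_observed = pair$presso$rss_observed,
        global_pval = pair$presso$global_pval,
        outlier_rsids = pair$presso$outlier_rsids,
        distortion_pval = pair$presso$distortion_pval
      ),
      cooks = if (is.null(pair$influence)) NULL else list(
        excluded_rsids = pair$influence$excluded_rsids,
        threshold = pair$influence$threshold
      )
    )
  })
  list(pairs = pairs, provenance = report$provenance)
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (full report), `forest.csv`
#' ([render_forest_table()]), `diagnostics.csv`, `droplog.csv` and
#' `run.log` (seed and config hash). Re-running with an identical config
#' produces byte-identical files.
#'
#' @param report An `analysis_report`.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of paths written, invisibly.
#' @export
write_report <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(
    json = file.path(outdir, "report.json"),
    forest = file.path(outdir, "forest.csv"),
    diagnostics = file.path(outdir, "diagnostics.csv"),
    droplog = file.path(outdir, "droplog.csv"),
    log = file.path(outdir, "run.log")
  )
  jsonlite::write_json(report_to_json_list(report), paths[["json"]],
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  data.table::fwrite(render_forest_table(report), paths[["forest"]])
  data.table::fwrite(diagnostics_table(report), paths[["diagnostics"]])
  data.table::fwrite(droplog_table(report), paths[["droplog"]])
  writeLines(c(
    sprintf("config_hash: %s", report$provenance$config_hash),
    sprintf("seed: %d", report$provenance$seed),
    sprintf("package_version: %s", report$provenance$package_version),
    sprintf("pairs: %d", length(report$pairs)),
    sprintf("failed_pairs: %d",
            sum(vapply(report$pairs, function(p) !is.null(p$error), logical(1))))
  ), paths[["log"]])
  invisible(paths)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Drug-target MR analysis: %d pair(s), config %s\n",
              length(x$pairs), substr(x$provenance$config_hash, 1, 8)))
  for (key in names(x$pairs)) {
    p <- x$pairs[[key]]
    if (!is.null(p$error)) {
      cat(sprintf("  %s: ERROR (%s)\n", key, p$error))
    } else {
      ivw <- p$battery$estimates$ivw_re %||% p$battery$estimates$wald
      cat(sprintf("  %s: k = %d, %s OR per decrease = %.3f [%.3f, %.3f]\n",
                  key, p$n_instruments, ivw$method, ivw$or_per_decrease,
                  ivw$or_ci_low, ivw$or_ci_high))
    }
  }
  invisible(x)
}
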