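#' Classify a p-value under a Bonferroni multiplicity scheme
#'
#' With n_tests risk factors examined, an association is classed
#' \code{"significant"} when p is strictly below 0.05 / n_tests,
#' \code{"suggestive"} when p is strictly below 0.05 but not Bonferroni
#' significant, and \code{"null"} otherwise. Both inequalities are strict:
#' p exactly equal to 0.05 / n_tests is suggestive, not significant.
#'
#' @param p p-value in (0, 1].
#' @param n_tests number of tests (default 24).
#' @return \code{"significant"}, \code{"suggestive"} or \code{"null"}.
#'   Vectorised over \code{p}.
#' @export
#' @examples
#' bonferroni_classify(2.4e-6, 24)  # significant
#' bonferroni_classify(0.01, 24)    # suggestive
bonferroni_classify <- function(p, n_tests = 24) {
  stopifnot(all(p > 0 & p <= 1), n_tests >= 1)
  ifelse(p < 0.05 / n_tests, "significant",
         ifelse(p < 0.05, "suggestive", "null"))
}

#' Build a multi-risk-factor study configuration
#'
#' @param factors list of per-factor entries; each a list with fields
#'   \code{name}, \code{exposure} (path to exposure summary table),
#'   \code{outcome} (path to outcome table), and optionally
#'   \code{unit_scale} (default 1), \code{scale_label}, \code{exclude}
#'   (variant identifiers to remove), \code{outcome_p_filter} (p-value
#'   threshold for \code{\link{filter_outcome_associated}}), \code{top_k},
#'   \code{proxy_map} (path), \code{ld_matrix} (path),
#'   \code{r2_threshold} (LD pruning, default 0.2),
#'   \code{force_sensitivity} (logical), \code{column_map}.
#' @param n_tests Bonferroni denominator (default 24).
#' @param seed bootstrap seed.
#' @param n_boot bootstrap replicates for median-method SEs.
#' @param conf_level confidence level (default 0.95).
#' @param palindrome_policy,eaf_tolerance,strand harmonisation settings,
#'   see \code{\link{harmonize}}.
#' @return list of class \code{study_config}.
#' @export
study_config <- function(factors, n_tests = 24, seed = 1, n_boot = 1000,
                         conf_level = 0.95,
                         palindrome_policy = "frequency_infer",
                         eaf_tolerance = 0.08, strand = "complement") {
  stopifnot(n_tests >= 1, length(factors) == 0 || is.list(factors[[1]]))
  for (f in factors) {
    if (is.null(f$name)) stop("every factor entry needs a name")
    if (!is.null(f$unit_scale) && f$unit_scale <= 0)
      stop("unit_scale must be positive (factor ", f$name, ")")
  }
  structure(list(factors = factors, n_tests = n_tests, seed = seed,
                 n_boot = n_boot, conf_level = conf_level,
                 palindrome_policy = palindrome_policy,
                 eaf_tolerance = eaf_tolerance, strand = strand),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' The YAML mirrors the arguments of \code{\link{study_config}}: top-level
#' keys \code{n_tests}, \code{seed}, \code{n_boot}, \code{conf_level},
#' harmonisation settings, and a \code{factors} sequence of per-factor
#' mappings. Relative file paths are resolved against the config file's
#' directory.
#'
#' @param path YAML file.
#' @return a \code{study_config}.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  factors <- lapply(y$factors, function(f) {
    for (k in c("exposure", "outcome", "proxy_map", "ld_matrix"))
      f[[k]] <- resolve(f[[k]])
    f
  })
  study_config(factors,
               n_tests = y$n_tests %||% 24,
               seed = y$seed %||% 1,
               n_boot = y$n_boot %||% 1000,
               conf_level = y$conf_level %||% 0.95,
               palindrome_policy = y$palindrome_policy %||% "frequency_infer",
               eaf_tolerance = y$eaf_tolerance %||% 0.08,
               strand = y$strand %||% "complement")
}

analyse_factor <- function(f, config) {
  cmap <- if (!is.null(f$column_map)) unlist(f$column_map) else NULL
  exposure <- if (is.data.frame(f$exposure)) f$exposure
              else read_summary_table(f$exposure, column_map = cmap)
  outcome <- if (is.data.frame(f$outcome)) f$outcome
             else read_summary_table(f$outcome, column_map = cmap)
  if (!is.null(f$ld_matrix)) {
    ld <- if (is.matrix(f$ld_matrix)) f$ld_matrix
          else read_ld_matrix(f$ld_matrix)
    exposure <- prune_ld(exposure, ld, f$r2_threshold %||% 0.2)
  }
  if (!is.null(f$proxy_map)) {
    pm <- if (is.data.frame(f$proxy_map)) f$proxy_map
          else read_proxy_map(f$proxy_map)
    outcome <- apply_proxy_map(outcome, exposure$variant_id, pm)
  }
  iv <- harmonize(exposure, outcome,
                  palindrome_policy = config$palindrome_policy,
                  eaf_tolerance = config$eaf_tolerance,
                  strand = config$strand, risk_factor = f$name)
  if (!is.null(f$exclude)) iv <- exclude_variants(iv, unlist(f$exclude))
  if (!is.null(f$outcome_p_filter))
    iv <- filter_outcome_associated(iv, f$outcome_p_filter)
  if (!is.null(f$top_k)) iv <- top_k_by_exposure(iv, f$top_k)

  ivw_fit <- mr_fit(iv, methods = "ivw", conf_level = config$conf_level,
                    unit_scale = f$unit_scale %||% 1,
                    scale_label = f$scale_label)
  head_est <- ivw_fit$estimates[[1]]
  run_sens <- isTRUE(f$force_sensitivity) || head_est$pvalue < 0.05
  fit <- if (run_sens && nrow(iv) >= 3L) {
    mr_fit(iv, n_boot = config$n_boot, seed = config$seed,
           conf_level = config$conf_level,
           unit_scale = f$unit_scale %||% 1, scale_label = f$scale_label)
  } else ivw_fit
  sens <- if (nrow(iv) >= 2L)
    sensitivity_report(iv, r_squared = f$r_squared, n_gwas = f$n_gwas)
  else NULL
  list(name = f$name, fit = fit, sensitivity = sens,
       significance = bonferroni_classify(head_est$pvalue, config$n_tests),
       instruments = iv)
}

#' Run the full multi-risk-factor study
#'
#' For every configured risk factor: read the tables, prune/proxy as
#' configured, harmonise, apply the configured exclusions and filters, run
#' the IVW analysis, run the median and Egger sensitivity suite when the
#' IVW p-value is below 0.05 (or always, when forced by config), compute
#' leave-one-out and F-statistic diagnostics, convert to odds ratios on the
#' configured unit scale, and classify significance under the Bonferroni
#' scheme. A factor that fails (unreadable file, no surviving variants) is
#' reported and skipped rather than aborting the run. Deterministic for a
#' given config and seed.
#'
#' @param config a \code{\link{study_config}} or path to a YAML file.
#' @return object of class \code{study_report}: list with \code{factors}
#'   (per-factor results), \code{failures} (named character vector of error
#'   messages), \code{n_tests}, \code{bonferroni_threshold}.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  results <- list()
  failures <- character(0)
  for (f in config$factors) {
    res <- tryCatch(analyse_factor(f, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[f$name] <- conditionMessage(res)
      warning("factor '", f$name, "' skipped: ", conditionMessage(res))
    } else {
      results[[f$name]] <- res
    }
  }
  structure(list(factors = results, failures = failures,
                 n_tests = config$n_tests,
                 bonferroni_threshold = 0.05 / config$n_tests),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Mendelian randomisation study report: ", length(x$factors),
      " factor(s) analysed, ", length(x$failures), " failed\n", sep = "")
  cat("Bonferroni threshold: p < ", signif(x$bonferroni_threshold, 3),
      " (", x$n_tests, " tests)\n", sep = "")
  if (length(x$factors)) print(forest_table(x), row.names = FALSE)
  if (length(x$failures))
    cat("Failures:\n", paste(" ", names(x$failures), ":", x$failures,
                             collapse = "\n"), "\n")
  invisible(x)
}

#' Flatten a study report into a forest-plot table
#'
#' One row per (risk factor, method): odds ratio, confidence bounds,
#' p-value, variant count, scale label and significance class. Column order
#' is fixed: factor, method, or, ci_low, ci_high, pvalue, n_variants,
#' scale_label, significance. ORs/CIs are reported at full precision;
#' round for display.
#'
#' @param report a \code{study_report}.
#' @return data.frame as described.
#' @export
forest_table <- function(report) {
  stopifnot(inherits(report, "study_report"))
  rows <- lapply(report$factors, function(res) {
    tab <- do.call(rbind, lapply(res$fit$estimates, to_odds_ratio,
                                 unit_scale = res$fit$unit_scale,
                                 scale_label = res$fit$scale_label))
    cbind(factor = res$name, tab, significance = res$significance,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("factor", "method", "or", "ci_low", "ci_high", "pvalue",
          "n_variants", "scale_label", "significance")]
}

#' Write study outputs to a directory
#'
#' Emits the forest table (2-decimal ORs/CIs, 2-significant-figure p-values,
#' as typically presented), a full-precision machine-readable companion,
#' per-factor leave-one-out tables, and a structured-text run report
#' including every provenance action (each dropped variant and why).
#'
#' @param report a \code{study_report}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_study_outputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  full <- forest_table(report)
  disp <- full
  disp$or <- sprintf("%.2f", disp$or)
  disp$ci_low <- sprintf("%.2f", disp$ci_low)
  disp$ci_high <- sprintf("%.2f", disp$ci_high)
  disp$pvalue <- signif(disp$pvalue, 2)
  utils::write.table(disp, file.path(dir, "forest_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fullw <- full
  for (cl in c("or", "ci_low", "ci_high", "pvalue"))
    fullw[[cl]] <- sprintf("%.17g", fullw[[cl]])
  utils::write.table(fullw, file.path(dir, "forest_table_full.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(file.path(dir, "run_report.txt"), "w")
  on.exit(close(con))
  writeLines(sprintf("risk factors analysed: %d; failed: %d",
                     length(report$factors), length(report$failures)), con)
  writeLines(sprintf("bonferroni threshold: %.6g",
                     report$bonferroni_threshold), con)
  for (res in report$factors) {
    writeLines(sprintf("\n== %s (%s, %d variants) ==", res$name,
                       res$significance, nrow(res$instruments)), con)
    prov <- attr(res$instruments, "provenance")
    if (nrow(prov))
      writeLines(sprintf("  %s %s: %s", prov$action, prov$variant_id,
                         prov$detail), con)
    if (!is.null(res$sensitivity)) {
      writeLines(sprintf("  mean per-variant F: %.2f",
                         res$sensitivity$f_statistic$mean_f), con)
      if (!is.null(res$sensitivity$loo_table)) {
        loo <- res$sensitivity$loo_table
        loo$beta <- sprintf("%.17g", loo$beta)
        loo$se <- sprintf("%.17g", loo$se)
        loo$ci_low <- sprintf("%.17g", loo$ci_low)
        loo$ci_high <- sprintf("%.17g", loo$ci_high)
        loo$pvalue <- sprintf("%.17g", loo$pvalue)
        utils::write.table(loo,
                           file.path(dir, paste0("loo_", gsub("[^A-Za-z0-9_-]",
                                                              "_", res$name),
                                                 ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  for (nm in names(report$failures))
    writeLines(sprintf("\nFAILED %s: %s", nm, report$failures[nm]), con)
  invisible(dir)
}

#' Re-analyse a directory of published per-variant tables
#'
#' Convenience wrapper for reproducing a published multi-factor analysis
#' from its supplementary SNP-level tables: the directory must contain one
#' \code{<factor>_exposure.tsv} and \code{<factor>_outcome.tsv} pair per
#' risk factor in the dialect \code{\link{read_summary_table}} consumes,
#' and optionally a \code{units.tsv} (columns \code{factor},
#' \code{unit_scale}, \code{scale_label}). Runs \code{\link{run_study}}
#' over all pairs found.
#'
#' @param table_dir directory of summary tables.
#' @param ... passed to \code{\link{study_config}}.
#' @return a \code{study_report}.
#' @export
reproduce_study <- function(table_dir, ...) {
  exp_files <- list.files(table_dir, "_exposure\\.tsv$", full.names = TRUE)
  if (!length(exp_files))
    stop("no <factor>_exposure.tsv files found in ", table_dir)
  units_path <- file.path(table_dir, "units.tsv")
  units <- if (file.exists(units_path))
    utils::read.table(units_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else NULL
  factors <- lapply(exp_files, function(ef) {
    nm <- sub("_exposure\\.tsv$", "", basename(ef))
    u <- if (!is.null(units) && nm %in% units$factor)
      units[units$factor == nm, , drop = FALSE] else NULL
    list(name = nm, exposure = ef,
         outcome = file.path(table_dir, paste0(nm, "_outcome.tsv")),
         unit_scale = if (!is.null(u)) u$unit_scale else 1,
         scale_label = if (!is.null(u)) u$scale_label else NULL,
         force_sensitivity = TRUE)
  })
  run_study(study_config(factors, ...))
}
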