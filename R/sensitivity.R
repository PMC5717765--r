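#' Leave-one-out influence analysis
#'
#' Omits each variant in turn and recomputes the IVW estimate on the
#' remaining n - 1 instruments, exposing variants that single-handedly drive
#' the pooled result.
#'
#' @param instruments an \code{\link{instrument_set}} with at least 2
#'   variants.
#' @param conf_level confidence level (default 0.95).
#' @return data.frame with one row per omitted variant: \code{omitted},
#'   \code{beta}, \code{se}, \code{ci_low}, \code{ci_high}, \code{pvalue},
#'   \code{n_variants}.
#' @export
leave_one_out <- function(instruments, conf_level = 0.95) {
  n <- nrow(instruments)
  if (n < 2L) stop("leave-one-out requires at least 2 variants")
  rows <- lapply(seq_len(n), function(i) {
    est <- mr_ivw(instrument_set(as.data.frame(instruments)[-i, ,
                                                            drop = FALSE]),
                  conf_level)
    data.frame(omitted = instruments$variant_id[i], beta = est$beta,
               se = est$se, ci_low = est$ci_low, ci_high = est$ci_high,
               pvalue = est$pvalue, n_variants = est$n_variants,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Remove named variants from an instrument set
#'
#' Used for the exclusion analyses in which individual variants known or
#' suspected to be pleiotropic (for example a variant near a gene with broad
#' effects) are removed and the analysis repeated.
#'
#' @param instruments an \code{\link{instrument_set}}.
#' @param ids variant identifiers to remove; identifiers not present raise a
#'   warning, not an error.
#' @return the reduced \code{instrument_set}, with the exclusion recorded in
#'   its provenance.
#' @export
exclude_variants <- function(instruments, ids) {
  if (!length(ids)) return(instruments)
  absent <- setdiff(ids, instruments$variant_id)
  if (length(absent))
    warning("variant(s) not present: ", paste(absent, collapse = ", "))
  hit <- instruments$variant_id %in% ids
  if (!any(hit)) return(instruments)
  prov <- add_provenance(attr(instruments, "provenance"), "exclude",
                         instruments$variant_id[hit],
                         sprintf("named exclusion (%d removed)", sum(hit)))
  instrument_set(as.data.frame(instruments)[!hit, , drop = FALSE],
                 risk_factor = attr(instruments, "risk_factor"),
                 provenance = prov)
}

#' Remove variants directly associated with the outcome
#'
#' Variants whose association with the outcome is itself significant may act
#' through pathways other than the exposure; this filter removes those with
#' an outcome-association p-value below the threshold. When the harmonised
#' set lacks outcome p-values they are recomputed as two-sided normal
#' p-values from \code{beta_outcome / se_outcome}.
#'
#' @param instruments an \code{\link{instrument_set}}.
#' @param p_threshold removal threshold (e.g. 0.05); a threshold of 0
#'   removes nothing.
#' @return the filtered \code{instrument_set}, count recorded in provenance.
#' @export
filter_outcome_associated <- function(instruments, p_threshold = 0.05) {
  p <- instruments$pvalue_outcome
  if (is.null(p)) p <- rep(NA_real_, nrow(instruments))
  p[is.na(p)] <- normal_p(instruments$beta_outcome,
                          instruments$se_outcome)[is.na(p)]
  hit <- p < p_threshold
  if (!any(hit)) return(instruments)
  prov <- add_provenance(attr(instruments, "provenance"), "filter",
                         instruments$variant_id[hit],
                         sprintf("outcome-associated at p < %g (%d removed)",
                                 p_threshold, sum(hit)))
  instrument_set(as.data.frame(instruments)[!hit, , drop = FALSE],
                 risk_factor = attr(instruments, "risk_factor"),
                 provenance = prov)
}

#' Restrict to the k variants most strongly associated with the exposure
#'
#' Keeps the k variants with the smallest exposure-association p-value
#' (recomputed from \code{beta_exposure / se_exposure} under normality when
#' absent). Ties are broken by \code{|beta_exposure / se_exposure|}
#' descending, then variant identifier, so the selection is deterministic.
#'
#' @param instruments an \code{\link{instrument_set}}.
#' @param k number of variants to keep; if \code{k >= n} all are kept (with
#'   a warning when \code{k > n}).
#' @return the restricted \code{instrument_set}.
#' @export
top_k_by_exposure <- function(instruments, k) {
  stopifnot(k >= 1)
  n <- nrow(instruments)
  if (k > n) {
    warning("k = ", k, " exceeds the ", n, " available variants; keeping all")
    return(instruments)
  }
  p <- instruments$pvalue_exposure
  if (is.null(p)) p <- rep(NA_real_, n)
  zabs <- abs(instruments$beta_exposure / instruments$se_exposure)
  p[is.na(p)] <- normal_p(instruments$beta_exposure,
                          instruments$se_exposure)[is.na(p)]
  ord <- order(p, -zabs, instruments$variant_id)
  keep_ids <- instruments$variant_id[ord[seq_len(k)]]
  hit <- instruments$variant_id %in% keep_ids
  if (all(hit)) return(instruments)
  prov <- add_provenance(attr(instruments, "provenance"), "filter",
                         instruments$variant_id[!hit],
                         sprintf("outside top %d by exposure association (%d removed)",
                                 k, sum(!hit)))
  instrument_set(as.data.frame(instruments)[hit, , drop = FALSE],
                 risk_factor = attr(instruments, "risk_factor"),
                 provenance = prov)
}

#' Instrument-strength F statistics
#'
#' Weak instruments bias two-sample Mendelian randomisation estimates
#' towards the null; the F statistic quantifies strength. Two quantities are
#' reported and labelled distinctly: the per-variant
#' \code{F_j = (beta_exposure / se_exposure)^2} with its mean, and — when
#' the exposure variance explained \code{r_squared} and the exposure GWAS
#' sample size are supplied — the overall
#' \code{F = r2 (n - k - 1) / ((1 - r2) k)} over the k instruments.
#'
#' @param instruments an \code{\link{instrument_set}}.
#' @param r_squared optional fraction of exposure variance explained by the
#'   instruments jointly.
#' @param n_gwas optional exposure GWAS sample size.
#' @return list with \code{per_variant_f}, \code{mean_f}, and
#'   \code{overall_f} (NA unless \code{r_squared} and \code{n_gwas} given).
#' @export
instrument_strength <- function(instruments, r_squared = NULL,
                                n_gwas = NULL) {
  fj <- (instruments$beta_exposure / instruments$se_exposure)^2
  overall <- NA_real_
  if (!is.null(r_squared) && !is.null(n_gwas)) {
    k <- nrow(instruments)
    overall <- r_squared * (n_gwas - k - 1) / ((1 - r_squared) * k)
  }
  list(per_variant_f = stats::setNames(fj, instruments$variant_id),
       mean_f = mean(fj),
       overall_f = overall)
}

#' Full sensitivity report for an instrument set
#'
#' Bundles the leave-one-out table, Egger intercept test, instrument
#' strength and the provenance of applied filters into one object.
#'
#' @param instruments an \code{\link{instrument_set}} (>= 3 variants for the
#'   Egger component; it is omitted below that).
#' @param r_squared,n_gwas passed to \code{\link{instrument_strength}}.
#' @return object of class \code{sensitivity_report}.
#' @export
sensitivity_report <- function(instruments, r_squared = NULL,
                               n_gwas = NULL) {
  n <- nrow(instruments)
  structure(list(
    loo_table = if (n >= 2L) leave_one_out(instruments) else NULL,
    egger_intercept = if (n >= 3L) mr_egger(instruments)$intercept else NULL,
    f_statistic = instrument_strength(instruments, r_squared, n_gwas),
    filters_applied = attr(instruments, "provenance"),
    n_variants = n), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity report (", x$n_variants, " variants)\n", sep = "")
  cat(sprintf("  mean per-variant F: %.1f\n", x$f_statistic$mean_f))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  Egger intercept: %.4g (p = %.2g)\n",
                x$egger_intercept$estimate, x$egger_intercept$pvalue))
  if (!is.null(x$loo_table)) {
    rng <- range(x$loo_table$beta)
    cat(sprintf("  leave-one-out beta range: %.4g to %.4g\n",
                rng[1], rng[2]))
  }
  if (nrow(x$filters_applied))
    cat("  ", nrow(x$filters_applied), " provenance action(s) recorded\n",
        sep = "")
  invisible(x)
}
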