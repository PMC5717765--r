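#' Fit two-sample Mendelian randomisation estimators to an instrument set
#'
#' The central fitting function: given a harmonised instrument set it runs
#' the requested causal estimators — fixed-effect inverse-variance weighted
#' (IVW), weighted median, penalised weighted median and MR-Egger — and
#' returns them in a single fitted object. Instrument sets with fewer than
#' 3 variants are fitted with IVW only (a single variant degenerates to the
#' Wald ratio and is labelled as such); the median and Egger methods need
#' at least 3 variants and are silently omitted below that.
#'
#' @param instruments an \code{\link{instrument_set}} (or a data.frame with
#'   the same columns, which is validated and upgraded).
#' @param methods subset of \code{c("ivw", "weighted_median",
#'   "penalized_weighted_median", "mr_egger")}.
#' @param n_boot bootstrap replicates for median-method standard errors.
#' @param seed RNG seed for the bootstraps.
#' @param conf_level confidence level for all intervals (default 0.95).
#' @param penalty_scale penalisation constant for the penalised weighted
#'   median (default 20).
#' @param unit_scale,scale_label unit rescaling applied when reporting odds
#'   ratios (see \code{\link{to_odds_ratio}}).
#' @return object of class \code{mr_fit}: list with components
#'   \code{estimates} (named list of \code{causal_estimate}s),
#'   \code{egger} (the full \code{egger_result} or NULL),
#'   \code{ratios} (per-variant Wald ratio table), \code{instruments},
#'   \code{unit_scale}, \code{scale_label}.
#' @seealso \code{\link{mr_ivw}}, \code{\link{mr_weighted_median}},
#'   \code{\link{mr_penalized_weighted_median}}, \code{\link{mr_egger}},
#'   \code{\link{leave_one_out}}, \code{\link{instrument_strength}}
#' @export
#' @examples
#' sim <- simulate_summary_stats(sim_config(n_variants = 20, theta = 0.2,
#'                                          seed = 7))
#' iv <- harmonize(sim$exposure, sim$outcome)
#' fit <- mr_fit(iv, seed = 7, n_boot = 200)
#' fit
#' coef(fit)
mr_fit <- function(instruments,
                   methods = c("ivw", "weighted_median",
                               "penalized_weighted_median", "mr_egger"),
                   n_boot = 1000, seed = 1, conf_level = 0.95,
                   penalty_scale = 20, unit_scale = 1, scale_label = NULL) {
  if (!inherits(instruments, "instrument_set"))
    instruments <- instrument_set(instruments)
  methods <- match.arg(methods, several.ok = TRUE)
  n <- nrow(instruments)
  ests <- list()
  egger <- NULL
  if ("ivw" %in% methods) {
    est <- mr_ivw(instruments, conf_level)
    ests[[est$method]] <- est
  }
  if (n >= 3L) {
    if ("weighted_median" %in% methods)
      ests$weighted_median <-
        mr_weighted_median(instruments, n_boot, seed, conf_level)
    if ("penalized_weighted_median" %in% methods)
      ests$penalized_weighted_median <-
        mr_penalized_weighted_median(instruments, penalty_scale,
                                     n_boot, seed, conf_level)
    if ("mr_egger" %in% methods) {
      egger <- mr_egger(instruments, conf_level)
      ests$mr_egger <- egger$slope
    }
  }
  for (m in names(ests)) ests[[m]]$scale_label <- scale_label
  structure(list(estimates = ests, egger = egger,
                 ratios = ratios_from_set(instruments),
                 instruments = instruments,
                 unit_scale = unit_scale,
                 scale_label = scale_label,
                 conf_level = conf_level),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat("Two-sample Mendelian randomisation fit:",
      attr(x$instruments, "risk_factor"), "\n")
  cat(nrow(x$instruments), "instrument(s)\n\n")
  for (est in x$estimates) print(est, digits = digits)
  if (!is.null(x$egger))
    cat(sprintf("Egger intercept: %.*g (p = %.2g)\n", digits,
                x$egger$intercept$estimate, x$egger$intercept$pvalue))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, `[[`, numeric(1), "beta")
}

#' @export
confint.mr_fit <- function(object, parm, level, ...) {
  out <- t(vapply(object$estimates,
                  function(e) c(e$ci_low, e$ci_high), numeric(2)))
  colnames(out) <- sprintf("%g %%", 100 * c((1 - object$conf_level) / 2,
                                            1 - (1 - object$conf_level) / 2))
  out
}

#' Summarise a Mendelian randomisation fit as an odds-ratio table
#'
#' @param object an \code{mr_fit}.
#' @param ... unused.
#' @return object of class \code{summary.mr_fit}: the odds-ratio table (one
#'   row per method, on the fit's unit scale) plus instrument-strength and
#'   Egger-intercept diagnostics.
#' @export
summary.mr_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$estimates, to_odds_ratio,
                               unit_scale = object$unit_scale,
                               scale_label = object$scale_label))
  rownames(tab) <- NULL
  fstat <- instrument_strength(object$instruments)
  structure(list(table = tab,
                 mean_f = fstat$mean_f,
                 egger_intercept = if (!is.null(object$egger))
                   object$egger$intercept else NULL,
                 risk_factor = attr(object$instruments, "risk_factor")),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 3, ...) {
  cat("Risk factor:", x$risk_factor, "\n")
  tab <- x$table
  tab$or <- round(tab$or, 2)
  tab$ci_low <- round(tab$ci_low, 2)
  tab$ci_high <- round(tab$ci_high, 2)
  tab$pvalue <- signif(tab$pvalue, 2)
  print.data.frame(tab, row.names = FALSE)
  cat(sprintf("Mean per-variant F statistic: %.1f\n", x$mean_f))
  if (!is.null(x$egger_intercept))
    cat(sprintf("Egger intercept p-value: %.2g\n", x$egger_intercept$pvalue))
  invisible(x)
}

#' Forest-style plot of per-variant ratios and summary estimates
#'
#' Base-graphics plot showing each variant's Wald ratio with its 95\%
#' interval, followed by the summary estimates of the fitted methods.
#'
#' @param x an \code{mr_fit}.
#' @param ... passed to \code{plot.default}.
#' @return \code{x}, invisibly.
#' @export
plot.mr_fit <- function(x, ...) {
  r <- x$ratios
  z <- stats::qnorm(1 - (1 - x$conf_level) / 2)
  labs <- c(r$variant_id, paste0("[", names(x$estimates), "]"))
  est <- c(r$theta, vapply(x$estimates, `[[`, numeric(1), "beta"))
  lo <- c(r$theta - z * r$se_theta,
          vapply(x$estimates, `[[`, numeric(1), "ci_low"))
  hi <- c(r$theta + z * r$se_theta,
          vapply(x$estimates, `[[`, numeric(1), "ci_high"))
  ypos <- rev(seq_along(est))
  op <- graphics::par(mar = c(4, 8, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(est, ypos, xlim = range(lo, hi, finite = TRUE),
                 yaxt = "n", ylab = "", pch = 15,
                 xlab = "causal effect (log odds per exposure unit)", ...)
  graphics::segments(lo, ypos, hi, ypos)
  graphics::abline(v = 0, lty = 3)
  graphics::axis(2, at = ypos, labels = labs, las = 1, cex.axis = 0.7)
  invisible(x)
}
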