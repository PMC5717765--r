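#' Per-variant Wald ratio estimate
#'
#' The ratio estimate for one variant divides the effect on the outcome
#' (log odds for a binary outcome) by the effect on the exposure, giving a
#' causal effect per exposure unit. The standard error uses the first-order
#' delta approximation \code{se_y / |beta_x|}, which ignores uncertainty in
#' the exposure effect and matches the fixed-effect inverse-variance
#' weighting convention.
#'
#' @param beta_x,se_x variant-exposure effect and standard error.
#' @param beta_y,se_y variant-outcome effect and standard error.
#' @param variant_id optional identifier(s).
#' @return data.frame with columns \code{variant_id}, \code{theta},
#'   \code{se_theta}, \code{weight} (\code{= se_theta^-2}). Vectorised.
#' @export
#' @examples
#' wald_ratio(0.1, 0.01, 0.2, 0.05)  # theta 2, se 0.5
wald_ratio <- function(beta_x, se_x, beta_y, se_y, variant_id = NULL) {
  if (any(beta_x == 0))
    stop("undefined ratio: beta_x is zero for ",
         paste(if (is.null(variant_id)) which(beta_x == 0)
               else variant_id[beta_x == 0], collapse = ", "))
  theta <- beta_y / beta_x
  se_theta <- se_y / abs(beta_x)
  data.frame(variant_id = variant_id %||% paste0("v", seq_along(theta)),
             theta = theta, se_theta = se_theta,
             weight = se_theta^-2, stringsAsFactors = FALSE)
}

# Build a causal_estimate object from a point estimate and SE.
causal_estimate <- function(method, beta, se, n_variants,
                            conf_level = 0.95, df = Inf,
                            scale_label = NULL) {
  z <- if (is.finite(df)) stats::qt(1 - (1 - conf_level) / 2, df)
       else stats::qnorm(1 - (1 - conf_level) / 2)
  p <- if (is.finite(df)) 2 * stats::pt(-abs(beta / se), df)
       else 2 * stats::pnorm(-abs(beta / se))
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - z * se, ci_high = beta + z * se,
                 pvalue = p, n_variants = n_variants,
                 conf_level = conf_level, df = df,
                 scale_label = scale_label),
            class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s estimate (%d variant%s): beta = %.*g (SE %.*g), %g%% CI [%.*g, %.*g], p = %.*g\n",
              x$method, x$n_variants, if (x$n_variants == 1) "" else "s",
              digits, x$beta, digits, x$se, 100 * x$conf_level,
              digits, x$ci_low, digits, x$ci_high, 2, x$pvalue))
  if (!is.null(x$scale_label)) cat("  scale: ", x$scale_label, "\n", sep = "")
  invisible(x)
}

ratios_from_set <- function(instruments) {
  wald_ratio(instruments$beta_exposure, instruments$se_exposure,
             instruments$beta_outcome, instruments$se_outcome,
             variant_id = instruments$variant_id)
}

#' Fixed-effect inverse-variance weighted estimate
#'
#' Combines the per-variant Wald ratios with weights equal to the inverse of
#' their squared standard errors: \code{beta = sum(w * theta) / sum(w)},
#' \code{se = sum(w)^(-1/2)}. This equals the slope of a zero-intercept
#' weighted least-squares regression of the outcome effects on the exposure
#' effects with weights \code{se_outcome^-2}. Two-sided p-value from the
#' normal distribution.
#'
#' With a single variant the estimate degenerates to that variant's Wald
#' ratio and the result is labelled \code{"wald_ratio"}.
#'
#' @param instruments an \code{\link{instrument_set}}.
#' @param conf_level confidence level (default 0.95).
#' @return a \code{causal_estimate} with method \code{"ivw"} (or
#'   \code{"wald_ratio"} when only one variant is available).
#' @export
mr_ivw <- function(instruments, conf_level = 0.95) {
  r <- ratios_from_set(instruments)
  if (nrow(r) < 1L) stop("at least one variant required")
  beta <- sum(r$weight * r$theta) / sum(r$weight)
  se <- sum(r$weight)^-0.5
  causal_estimate(if (nrow(r) == 1L) "wald_ratio" else "ivw",
                  beta, se, nrow(r), conf_level)
}

# Weighted-median point estimate: order the ratios, place each order
# statistic at the percentile 100 * (S_j - w'_j / 2) of the normalised
# cumulative weight, and linearly interpolate at the 50th percentile.
weighted_median_point <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  wn <- w[o] / sum(w)
  p <- 100 * (cumsum(wn) - wn / 2)
  n <- length(th)
  if (p[1] >= 50) return(th[1])
  if (p[n] <= 50) return(th[n])
  j <- max(which(p < 50))
  th[j] + (th[j + 1] - th[j]) * (50 - p[j]) / (p[j + 1] - p[j])
}

# Parametric bootstrap SE in ratio space: resample theta_j* ~ N(theta_j,
# se_theta_j) and take the SD of the re-estimated statistic.
bootstrap_se <- function(theta, se_theta, estimator, n_boot, seed) {
  with_seed(seed, {
    n <- length(theta)
    ests <- vapply(seq_len(n_boot), function(b) {
      estimator(stats::rnorm(n, theta, se_theta))
    }, numeric(1))
    stats::sd(ests)
  })
}

#' Weighted median estimate
#'
#' The weighted median of the per-variant Wald ratios under inverse-variance
#' weights. It is a consistent estimate of the causal effect as long as
#' valid instruments contribute more than half of the total weight, so it
#' tolerates up to 50 percent invalid (pleiotropic) weight. The standard
#' error is obtained by parametric bootstrap: each ratio is resampled from a
#' normal distribution centred on its estimate with its own standard error,
#' and the median is recomputed.
#'
#' @param instruments an \code{\link{instrument_set}} with at least 3
#'   variants.
#' @param n_boot bootstrap replicates for the SE (default 1000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @param conf_level confidence level (default 0.95).
#' @return a \code{causal_estimate} with method \code{"weighted_median"}.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = 1,
                               conf_level = 0.95) {
  r <- ratios_from_set(instruments)
  if (nrow(r) < 3L)
    stop("weighted median requires at least 3 variants")
  beta <- weighted_median_point(r$theta, r$weight)
  se <- bootstrap_se(r$theta, r$se_theta,
                     function(th) weighted_median_point(th, r$weight),
                     n_boot, seed)
  causal_estimate("weighted_median", beta, se, nrow(r), conf_level)
}

# Penalised weights: down-weight variants whose ratio is heterogeneous with
# the weighted-median estimate. Q_j = w_j (theta_j - theta_wm)^2 is referred
# to a chi-squared(1) tail, and w_j is multiplied by min(1, penalty * q_j).
penalized_weights <- function(theta, w, penalty_scale) {
  wm <- weighted_median_point(theta, w)
  Q <- w * (theta - wm)^2
  q <- stats::pchisq(Q, df = 1, lower.tail = FALSE)
  w * pmin(1, penalty_scale * q)
}

#' Penalised weighted median estimate
#'
#' As \code{\link{mr_weighted_median}}, but variants whose ratio estimates
#' are strongly heterogeneous with the (unpenalised) weighted median have
#' their weights down-weighted before the median is recomputed: the
#' per-variant heterogeneity statistic is referred to a one-degree-of-freedom
#' chi-squared tail and the weight multiplied by \code{min(1, penalty_scale
#' * tail_probability)}. Homogeneous sets are left untouched, and as
#' \code{penalty_scale} grows the estimate reverts to the plain weighted
#' median. The bootstrap SE re-runs the full penalised procedure on each
#' resample.
#'
#' @inheritParams mr_weighted_median
#' @param penalty_scale penalisation constant (default 20).
#' @return a \code{causal_estimate} with method
#'   \code{"penalized_weighted_median"}.
#' @export
mr_penalized_weighted_median <- function(instruments, penalty_scale = 20,
                                         n_boot = 1000, seed = 1,
                                         conf_level = 0.95) {
  r <- ratios_from_set(instruments)
  if (nrow(r) < 3L)
    stop("penalised weighted median requires at least 3 variants")
  pen_est <- function(th) {
    wstar <- penalized_weights(th, r$weight, penalty_scale)
    weighted_median_point(th, wstar)
  }
  beta <- pen_est(r$theta)
  se <- bootstrap_se(r$theta, r$se_theta, pen_est, n_boot, seed)
  causal_estimate("penalized_weighted_median", beta, se, nrow(r), conf_level)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure effects
#' with a free intercept and weights \code{se_outcome^-2}, after orienting
#' every variant so its exposure effect is non-negative (both betas negated
#' when \code{beta_exposure < 0}). The slope estimates the causal effect;
#' the intercept estimates the average directional pleiotropic effect, and
#' its test is the standard check for directional pleiotropy. Standard
#' errors are the sigma-free coefficient SEs inflated by
#' \code{max(1, residual standard error)}, so under-dispersion never shrinks
#' them; p-values use the t distribution with n - 2 degrees of freedom.
#'
#' @param instruments an \code{\link{instrument_set}} with at least 3
#'   variants.
#' @param conf_level confidence level (default 0.95).
#' @return object of class \code{egger_result}: list with \code{slope} (a
#'   \code{causal_estimate}, method \code{"mr_egger"}), \code{intercept}
#'   (list with \code{estimate}, \code{se}, \code{pvalue}, \code{ci_low},
#'   \code{ci_high}) and \code{overdispersion_factor} (>= 1).
#' @export
mr_egger <- function(instruments, conf_level = 0.95) {
  if (nrow(instruments) < 3L)
    stop("MR-Egger requires at least 3 variants")
  sgn <- ifelse(instruments$beta_exposure < 0, -1, 1)
  bx <- sgn * instruments$beta_exposure
  by <- sgn * instruments$beta_outcome
  w <- instruments$se_outcome^-2
  fit <- stats::lm(by ~ bx, weights = w)
  sigma <- summary(fit)$sigma
  infl <- max(1, sigma)
  # sigma-free coefficient SEs from (X' W X)^-1, times the overdispersion
  # factor; computed directly so an exactly-fitting line stays finite
  X <- cbind("(Intercept)" = 1, bx = bx)
  base_se <- sqrt(diag(solve(crossprod(X, w * X))))
  se <- base_se * infl
  df <- nrow(instruments) - 2L
  slope <- causal_estimate("mr_egger", unname(stats::coef(fit)["bx"]),
                           unname(se["bx"]), nrow(instruments),
                           conf_level, df = df)
  a <- unname(stats::coef(fit)["(Intercept)"])
  a_se <- unname(se["(Intercept)"])
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(list(slope = slope,
                 intercept = list(estimate = a, se = a_se,
                                  pvalue = 2 * stats::pt(-abs(a / a_se), df),
                                  ci_low = a - tq * a_se,
                                  ci_high = a + tq * a_se),
                 overdispersion_factor = infl),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, digits = 4, ...) {
  print(x$slope, digits = digits)
  cat(sprintf("  intercept (directional pleiotropy): %.*g (SE %.*g), p = %.*g\n",
              digits, x$intercept$estimate, digits, x$intercept$se,
              2, x$intercept$pvalue))
  cat(sprintf("  overdispersion factor: %.*g\n", digits,
              x$overdispersion_factor))
  invisible(x)
}

#' Convert a causal estimate to an odds ratio on a chosen unit scale
#'
#' Rescales the log-odds effect by \code{unit_scale} (for example 10 to
#' report per 10 cigarettes/day when the estimate is per cigarette/day) and
#' exponentiates the estimate and its confidence bounds. The p-value is
#' scale-invariant and carried through unchanged.
#'
#' @param estimate a \code{causal_estimate}.
#' @param unit_scale positive multiplier applied on the log-odds scale
#'   before exponentiation (default 1).
#' @param scale_label optional label, e.g. \code{"per year of education"}.
#' @return data.frame with columns \code{method}, \code{or}, \code{ci_low},
#'   \code{ci_high}, \code{pvalue}, \code{n_variants}, \code{scale_label}.
#' @export
to_odds_ratio <- function(estimate, unit_scale = 1, scale_label = NULL) {
  stopifnot(inherits(estimate, "causal_estimate"), unit_scale > 0)
  data.frame(method = estimate$method,
             or = exp(estimate$beta * unit_scale),
             ci_low = exp(estimate$ci_low * unit_scale),
             ci_high = exp(estimate$ci_high * unit_scale),
             pvalue = estimate$pvalue,
             n_variants = estimate$n_variants,
             scale_label = scale_label %||% estimate$scale_label %||% "",
             stringsAsFactors = FALSE)
}
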