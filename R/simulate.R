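#' Configuration for the summary-statistic simulator
#'
#' Describes a two-sample generative model at the summary-statistic level.
#' Each variant j receives a true exposure effect gamma_j (magnitude drawn
#' uniformly from \code{gamma_dist$min}--\code{gamma_dist$max}, sign
#' positive with probability \code{gamma_dist$prob_positive}); the observed
#' exposure effect is gamma_j plus normal noise with the variant's exposure
#' SE, and the observed outcome effect is \code{theta * gamma_j + alpha_j}
#' plus noise with the outcome SE. Valid instruments have pleiotropic effect
#' alpha_j = 0; a fraction \code{invalid_fraction} of variants is invalid,
#' with alpha_j drawn Normal(mu_alpha, sd_alpha^2) (\code{"balanced"} forces
#' mu_alpha = 0; \code{"directional"} uses the configured mean).
#'
#' Defaults emulate a modern GWAS-based analysis: per-variant effects of a
#' few hundredths of a unit with exposure SEs giving per-variant F
#' statistics from single digits to several hundred (spanning weak and
#' strong instrument regimes), outcome SEs typical of a case-control GWAS
#' of tens of thousands of samples, and allele frequencies uniform on
#' 0.05--0.95.
#'
#' @param n_variants number of instruments.
#' @param theta true causal log-odds effect per exposure unit.
#' @param gamma_dist list(min, max, prob_positive) for the true exposure
#'   effects.
#' @param se_x_range,se_y_range length-2 positive ranges for the per-variant
#'   exposure and outcome standard errors.
#' @param invalid_fraction fraction of invalid (pleiotropic) variants, in
#'   [0, 1).
#' @param pleiotropy \code{"none"}, \code{"balanced"} or
#'   \code{"directional"}.
#' @param mu_alpha,sd_alpha mean and SD of pleiotropic effects on the
#'   outcome for invalid variants.
#' @param eaf_range allele-frequency range.
#' @param palindromic_prob probability a variant is assigned a palindromic
#'   (A/T or C/G) allele pair.
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_variants = 100, theta = 0,
                       gamma_dist = list(min = 0.02, max = 0.1,
                                         prob_positive = 0.5),
                       se_x_range = c(0.003, 0.009),
                       se_y_range = c(0.015, 0.035),
                       invalid_fraction = 0, pleiotropy = c("none",
                                                            "balanced",
                                                            "directional"),
                       mu_alpha = 0, sd_alpha = 0.02,
                       eaf_range = c(0.05, 0.95),
                       palindromic_prob = 0.2, seed = 1) {
  pleiotropy <- match.arg(pleiotropy)
  if (invalid_fraction < 0 || invalid_fraction >= 1)
    stop("invalid_fraction must lie in [0, 1)")
  if (any(se_x_range <= 0) || any(se_y_range <= 0))
    stop("SE ranges must be positive")
  if (pleiotropy == "balanced") mu_alpha <- 0
  structure(list(n_variants = n_variants, theta = theta,
                 gamma_dist = gamma_dist, se_x_range = se_x_range,
                 se_y_range = se_y_range,
                 invalid_fraction = invalid_fraction,
                 pleiotropy = pleiotropy, mu_alpha = mu_alpha,
                 sd_alpha = sd_alpha, eaf_range = eaf_range,
                 palindromic_prob = palindromic_prob, seed = seed),
            class = "sim_config")
}

# Assign allele pairs; palindromic pairs (A/T, C/G) with the configured
# probability, otherwise a non-palindromic pair.
draw_alleles <- function(n, palindromic_prob) {
  pal <- stats::runif(n) < palindromic_prob
  eff <- oth <- character(n)
  pal_first <- sample(c("A", "C"), n, replace = TRUE)
  eff[pal] <- pal_first[pal]
  oth[pal] <- complement_allele(pal_first[pal])
  for (i in which(!pal)) {
    repeat {
      pair <- sample(BASES, 2)
      if (complement_allele(pair[1]) != pair[2]) break
    }
    eff[i] <- pair[1]; oth[i] <- pair[2]
  }
  list(effect = eff, other = oth)
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Generates matched exposure and outcome association tables under the
#' linear causal model described in \code{\link{sim_config}}, plus the
#' generating truth (theta, per-variant gamma and pleiotropic effects,
#' validity flags) for parameter-recovery assertions. Both tables share
#' variant identifiers, allele labels and allele frequencies, as two GWAS
#' of the same ancestry would; harmonisation of the raw output is therefore
#' a no-op, and \code{\link{corrupt_allele_encoding}} can be applied to
#' exercise it.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{exposure} and \code{outcome} association
#'   data.frames (the dialect \code{\link{read_summary_table}} consumes) and
#'   \code{truth} (list: \code{theta}, \code{gamma}, \code{alpha},
#'   \code{valid}).
#' @export
simulate_summary_stats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_variants
    gd <- config$gamma_dist
    gamma <- stats::runif(n, gd$min, gd$max) *
      ifelse(stats::runif(n) < (gd$prob_positive %||% 0.5), 1, -1)
    n_invalid <- round(config$invalid_fraction * n)
    valid <- rep(TRUE, n)
    if (n_invalid > 0) valid[sample.int(n, n_invalid)] <- FALSE
    alpha <- numeric(n)
    if (config$pleiotropy != "none" && n_invalid > 0)
      alpha[!valid] <- stats::rnorm(n_invalid, config$mu_alpha,
                                    config$sd_alpha)
    se_x <- stats::runif(n, config$se_x_range[1], config$se_x_range[2])
    se_y <- stats::runif(n, config$se_y_range[1], config$se_y_range[2])
    beta_x <- stats::rnorm(n, gamma, se_x)
    beta_y <- stats::rnorm(n, config$theta * gamma + alpha, se_y)
    eaf <- stats::runif(n, config$eaf_range[1], config$eaf_range[2])
    al <- draw_alleles(n, config$palindromic_prob)
    ids <- sprintf("rs%06d", seq_len(n))
    exposure <- data.frame(variant_id = ids, effect_allele = al$effect,
                           other_allele = al$other, eaf = eaf,
                           beta = beta_x, se = se_x,
                           pvalue = normal_p(beta_x, se_x),
                           n = NA_real_, stringsAsFactors = FALSE)
    outcome <- data.frame(variant_id = ids, effect_allele = al$effect,
                          other_allele = al$other, eaf = eaf,
                          beta = beta_y, se = se_y,
                          pvalue = normal_p(beta_y, se_y),
                          n = NA_real_, stringsAsFactors = FALSE)
    list(exposure = exposure, outcome = outcome,
         truth = list(theta = config$theta, gamma = gamma, alpha = alpha,
                      valid = valid))
  })
}

#' Randomly corrupt the allele encoding of an association table
#'
#' Exercises the harmoniser: with probability \code{swap_prob} a variant's
#' effect and other alleles are exchanged (negating its beta and
#' complementing its frequency — the same association reported for the
#' opposite allele), and with probability \code{flip_prob} its allele labels
#' are strand-complemented (beta and frequency unchanged — the same
#' association reported from the opposite strand). The two corruptions are
#' independent and can co-occur.
#'
#' @param table association data.frame.
#' @param swap_prob,flip_prob corruption probabilities in [0, 1].
#' @param seed RNG seed.
#' @return the corrupted table, with attribute \code{"manifest"}: a
#'   data.frame (\code{variant_id}, \code{swapped}, \code{flipped}).
#' @export
corrupt_allele_encoding <- function(table, swap_prob = 0, flip_prob = 0,
                                    seed = 1) {
  stopifnot(swap_prob >= 0, swap_prob <= 1, flip_prob >= 0, flip_prob <= 1)
  validate_assoc(table)
  with_seed(seed, {
    n <- nrow(table)
    swap <- stats::runif(n) < swap_prob
    flip <- stats::runif(n) < flip_prob
    out <- table
    if (any(swap)) {
      tmp <- out$effect_allele[swap]
      out$effect_allele[swap] <- out$other_allele[swap]
      out$other_allele[swap] <- tmp
      out$beta[swap] <- -out$beta[swap]
      if ("eaf" %in% names(out)) out$eaf[swap] <- 1 - out$eaf[swap]
    }
    if (any(flip)) {
      out$effect_allele[flip] <- complement_allele(out$effect_allele[flip])
      out$other_allele[flip] <- complement_allele(out$other_allele[flip])
    }
    attr(out, "manifest") <- data.frame(variant_id = table$variant_id,
                                        swapped = swap, flipped = flip,
                                        stringsAsFactors = FALSE)
    out
  })
}
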