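# Shared fixture builders; everything is generated in code.

# Minimal association data.frame with sensible defaults.
make_assoc <- function(variant_id, effect_allele = "A", other_allele = "G",
                       eaf = 0.3, beta = 0.1, se = 0.02,
                       pvalue = NA_real_, n = NA_real_) {
  data.frame(variant_id = variant_id, effect_allele = effect_allele,
             other_allele = other_allele, eaf = eaf, beta = beta, se = se,
             pvalue = ifelse(is.na(pvalue), 2 * pnorm(-abs(beta / se)),
                             pvalue),
             n = n, stringsAsFactors = FALSE)
}

# Instrument set built directly from per-variant effects.
make_instruments <- function(beta_x, se_x, beta_y, se_y,
                             ids = sprintf("rs%d", seq_along(beta_x))) {
  instrument_set(data.frame(variant_id = ids,
                            beta_exposure = beta_x, se_exposure = se_x,
                            beta_outcome = beta_y, se_outcome = se_y,
                            stringsAsFactors = FALSE))
}

# Random instrument set for property-style tests.
random_instruments <- function(n = 10) {
  bx <- runif(n, 0.03, 0.15) * sample(c(-1, 1), n, replace = TRUE)
  make_instruments(beta_x = bx,
                   se_x = runif(n, 0.004, 0.01),
                   beta_y = rnorm(n, 0.3 * bx, 0.02),
                   se_y = runif(n, 0.015, 0.03))
}

write_tsv_fixture <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Independent weighted-median oracle: brute-force search on a fine percentile
# grid of the cumulative weight function, kept separate from the package's
# interpolation code path.
grid_weighted_median <- function(theta, w, grid_n = 200001) {
  o <- order(theta)
  th <- theta[o]
  wn <- w[o] / sum(w)
  p <- cumsum(wn) - wn / 2
  stats::approx(p, th, xout = 0.5, rule = 2)$y
}
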