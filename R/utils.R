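# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

BASES <- c("A", "C", "G", "T")

complement_allele <- function(a) {
  c(A = "T", C = "G", G = "C", T = "A")[a]
}

is_palindromic <- function(effect, other) {
  unname(complement_allele(effect) == other)
}

# Two-sided normal p-value from an estimate and its SE.
normal_p <- function(beta, se) {
  2 * stats::pnorm(-abs(beta / se))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
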