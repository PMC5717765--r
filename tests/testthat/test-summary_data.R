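test_that("summary tables are parsed, validated and rejected per row", {
  f <- write_tsv_fixture(c(
    "variant_id\teffect_allele\tother_allele\teaf\tbeta\tse\tpvalue",
    "rs1\tA\tG\t0.3\t0.10\t0.02\t1e-8",
    "rs2\tc\tt\t0.5\t-0.05\t0.01\t2e-9",
    "rs3\tG\tT\t0.1\t0.07\t0.015\t4e-8"))
  tab <- read_summary_table(f)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$variant_id, c("rs1", "rs2", "rs3"))
  expect_equal(tab$beta, c(0.10, -0.05, 0.07))
  expect_equal(tab$se, c(0.02, 0.01, 0.015))
  expect_equal(tab$effect_allele, c("A", "C", "G"))  # uppercased

  # bad rows are rejected with reasons, good rows kept in order
  g <- write_tsv_fixture(c(
    "variant_id\teffect_allele\tother_allele\teaf\tbeta\tse\tpvalue",
    "rs1\tA\tG\t0.3\t0.10\t0.02\t1e-8",
    "rs2\tA\tG\t0.5\t0.05\t0\t1e-9",
    "rs3\tA\tG\t0.1\tnot_a_number\t0.01\t1e-8",
    "rs4\tA\tA\t0.1\t0.02\t0.01\t1e-8"))
  expect_warning(tab2 <- read_summary_table(g), "rejected")
  expect_equal(tab2$variant_id, "rs1")
  rej <- attr(tab2, "rejected")
  expect_setequal(rej$variant_id, c("rs2", "rs3", "rs4"))
  expect_equal(rej$reason[rej$variant_id == "rs2"], "non-positive SE")

  # comma dialect + column mapping
  h <- write_tsv_fixture(c("SNP,EA,OA,freq,b,stderr,p",
                           "rs9,A,G,0.2,0.04,0.008,1e-7"), ext = ".csv")
  tab3 <- read_summary_table(h, column_map = c(
    variant_id = "SNP", effect_allele = "EA", other_allele = "OA",
    eaf = "freq", beta = "b", se = "stderr", pvalue = "p"))
  expect_equal(tab3$beta, 0.04)
  expect_error(read_summary_table(h), "mandatory column")
})

test_that("read -> write -> read round-trips all fields bit-identically", {
  set.seed(11)
  tab <- make_assoc(sprintf("rs%d", 1:8),
                    effect_allele = rep(c("A", "C"), 4),
                    other_allele = rep(c("G", "T"), 4),
                    eaf = runif(8), beta = rnorm(8) * 0.1,
                    se = runif(8, 0.001, 0.05))
  tab$pvalue <- runif(8)
  f <- tempfile(fileext = ".tsv")
  write_summary_table(tab, f)
  back <- read_summary_table(f)
  for (col in c("eaf", "beta", "se", "pvalue"))
    expect_identical(back[[col]], tab[[col]], label = col)
  f2 <- tempfile(fileext = ".tsv")
  write_summary_table(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("harmonisation flips swapped alleles and keeps identical labels", {
  exposure <- make_assoc("rs1", "A", "G", eaf = 0.3, beta = 0.1)
  outcome_swapped <- make_assoc("rs1", "G", "A", eaf = 0.7, beta = -0.05)
  iv <- harmonize(exposure, outcome_swapped)
  expect_equal(iv$beta_outcome, 0.05)
  expect_equal(iv$eaf_outcome, 0.3)
  expect_true("flip" %in% attr(iv, "provenance")$action)

  outcome_same <- make_assoc("rs1", "A", "G", eaf = 0.3, beta = -0.05)
  iv2 <- harmonize(exposure, outcome_same)
  expect_equal(iv2$beta_outcome, -0.05)

  # strand-complement labelling: T/C is A/G on the other strand
  outcome_comp <- make_assoc("rs1", "T", "C", eaf = 0.3, beta = -0.05)
  expect_equal(harmonize(exposure, outcome_comp)$beta_outcome, -0.05)
  expect_error(harmonize(exposure, outcome_comp, strand = "drop"),
               "no variants remain")

  # incompatible pair is dropped with a reason
  exposure2 <- rbind(exposure, make_assoc("rs2", "A", "G"))
  outcome_bad <- rbind(outcome_same, make_assoc("rs2", "A", "C"))
  iv3 <- harmonize(exposure2, outcome_bad)
  expect_equal(iv3$variant_id, "rs1")
  prov <- attr(iv3, "provenance")
  expect_equal(prov$detail[prov$variant_id == "rs2"],
               "incompatible alleles")
})

test_that("palindromic variants follow the frequency-inference policy", {
  exposure <- make_assoc("rs1", "A", "T", eaf = 0.30, beta = 0.1)

  # opposite frequency sides outside the tolerance band: flip
  out_flip <- make_assoc("rs1", "A", "T", eaf = 0.72, beta = -0.05)
  iv <- harmonize(exposure, out_flip, eaf_tolerance = 0.08)
  expect_equal(iv$beta_outcome, 0.05)

  # same side: keep orientation
  out_keep <- make_assoc("rs1", "A", "T", eaf = 0.35, beta = -0.05)
  expect_equal(harmonize(exposure, out_keep)$beta_outcome, -0.05)

  # frequency inside 0.42-0.58: unresolvable, dropped
  out_mid <- make_assoc("rs1", "A", "T", eaf = 0.5, beta = -0.05)
  expect_error(harmonize(exposure, out_mid), "no variants remain")

  # drop policy removes palindromes outright
  expect_error(harmonize(exposure, out_flip, palindrome_policy = "drop"),
               "no variants remain")

  # missing frequency forces a drop
  out_na <- out_flip; out_na$eaf <- NA_real_
  expect_error(harmonize(exposure, out_na), "no variants remain")
})

test_that("harmonisation is idempotent and flipping is an involution", {
  set.seed(21)
  sim <- simulate_summary_stats(sim_config(n_variants = 40, theta = 0.2,
                                           seed = 21))
  iv <- harmonize(sim$exposure, sim$outcome)

  # feed the harmonised orientation back through: nothing changes
  re_exposure <- sim$exposure[match(iv$variant_id, sim$exposure$variant_id), ]
  re_outcome <- re_exposure
  re_outcome$beta <- iv$beta_outcome
  re_outcome$se <- iv$se_outcome
  re_outcome$eaf <- iv$eaf_outcome
  iv2 <- harmonize(re_exposure, re_outcome)
  expect_equal(iv2$beta_outcome, iv$beta_outcome)
  expect_equal(iv2$variant_id, iv$variant_id)

  # swap labels + negate beta on the outcome, harmonise: same set back
  sw <- sim$outcome
  tmp <- sw$effect_allele
  sw$effect_allele <- sw$other_allele
  sw$other_allele <- tmp
  sw$beta <- -sw$beta
  sw$eaf <- 1 - sw$eaf
  iv3 <- harmonize(sim$exposure, sw)
  expect_equal(iv3$variant_id, iv$variant_id)
  expect_equal(iv3$beta_outcome, iv$beta_outcome)
})

test_that("proxy substitution relabels high-LD stand-ins and logs them", {
  outcome <- make_assoc(c("rs11", "rs2", "rs3", "rs21"),
                        beta = c(0.01, 0.02, 0.03, 0.04))
  wanted <- c("rs1", "rs2", "rs3", "rs4", "rs5")
  proxies <- data.frame(index_id = c("rs1", "rs4", "rs5"),
                        proxy_id = c("rs11", "rs21", "rs99"),
                        r2 = c(0.95, 0.99, 0.97),
                        stringsAsFactors = FALSE)
  out <- apply_proxy_map(outcome, wanted, proxies)
  # rs1 and rs4 proxied; rs5's proxy absent so rs5 stays missing
  expect_setequal(out$variant_id, c("rs1", "rs2", "rs3", "rs4"))
  expect_equal(out$beta[out$variant_id == "rs1"], 0.01)
  expect_equal(out$beta[out$variant_id == "rs4"], 0.04)
  subs <- attr(out, "substitutions")
  expect_equal(nrow(subs), 2)
  expect_setequal(subs$index_id, c("rs1", "rs4"))

  # empty map: intersection only
  none <- apply_proxy_map(outcome, wanted,
                          proxies[0, , drop = FALSE])
  expect_setequal(none$variant_id, c("rs2", "rs3"))
  expect_equal(nrow(attr(none, "substitutions")), 0)

  # r2 at or below 0.9 violates the proxy definition
  bad <- proxies; bad$r2[1] <- 0.9
  expect_error(apply_proxy_map(outcome, wanted, bad), "exceed 0.9")
})

test_that("LD pruning keeps the lowest-p variant of each correlated block", {
  cand <- make_assoc(c("rs1", "rs2"), beta = c(0.1, 0.08),
                     pvalue = c(1e-10, 1e-8))
  ld <- matrix(c(1, 0.5, 0.5, 1), 2,
               dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  expect_equal(prune_ld(cand, ld)$variant_id, "rs1")

  # independent variants are all kept
  ld0 <- diag(2); dimnames(ld0) <- dimnames(ld)
  expect_equal(nrow(prune_ld(cand, ld0)), 2)

  # missing coverage is a hard error
  expect_error(prune_ld(make_assoc("rs9"), ld), "does not cover")
})

test_that("pruned sets are r2-independent and every drop is justified", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 8
    ids <- sprintf("rs%d", 1:n)
    # random correlation blocks
    ld <- diag(n)
    block <- sample(n, 3)
    for (i in block) for (j in block) if (i != j) ld[i, j] <- 0.8
    extra <- sample(setdiff(seq_len(n), block), 2)
    ld[extra[1], extra[2]] <- ld[extra[2], extra[1]] <- runif(1, 0.2, 0.6)
    dimnames(ld) <- list(ids, ids)
    cand <- make_assoc(ids, beta = runif(n, 0.01, 0.1),
                       pvalue = runif(n, 1e-12, 1e-6))
    kept <- prune_ld(cand, ld, 0.2)
    kid <- kept$variant_id
    # no kept pair correlated at or above threshold
    if (length(kid) > 1)
      expect_true(max(ld[kid, kid][upper.tri(diag(length(kid)))]) < 0.2)
    # every dropped variant conflicts with a kept variant of lower p
    for (d in setdiff(ids, kid)) {
      pd <- cand$pvalue[cand$variant_id == d]
      conflicts <- kid[ld[d, kid] >= 0.2]
      expect_true(any(cand$pvalue[cand$variant_id %in% conflicts] <= pd),
                  label = paste("drop justified for", d))
    }
  }
})

test_that("instrument sets enforce their invariants", {
  expect_error(make_instruments(numeric(0), numeric(0), numeric(0),
                                numeric(0)), "at least 1")
  expect_error(make_instruments(c(0.1, 0.1), c(0.01, 0.01), c(0.1, 0.1),
                                c(0.01, 0.01), ids = c("rs1", "rs1")),
               "duplicate")
  expect_error(make_instruments(0.1, -0.01, 0.1, 0.01), "positive")
})
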