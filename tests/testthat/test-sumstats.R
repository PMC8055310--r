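# Reading, validation, harmonization and orientation.

test_that("reader preserves order, normalizes alleles, rejects bad rows", {
  txt <- paste(
    "SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
    "rs1\t1\t1000\ta\tg\t0.2\t0.10\t0.01\t1e-10\t50000",
    "rs2\t1\t2000\tT\tC\t0.5\t-0.05\t0.02\t1e-4\t50000",
    "rs3\t2\t3000\tG\tA\t0.9\t0.08\t0.015\t1e-8\t50000",
    sep = "\n"
  )
  f <- tempfile(fileext = ".tsv")
  writeLines(txt, f)
  ss <- read_summary_stats(f)
  expect_equal(nrow(ss), 3)
  expect_equal(ss$variant_id, c("rs1", "rs2", "rs3"))  # order preserved
  expect_equal(ss$effect_allele[1], "A")               # upper-cased
  expect_equal(ss$other_allele[1], "G")

  # se = 0 and an unparseable beta are rejected with their file row reported
  bad <- paste(
    "SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
    "rs1\t1\t1000\tA\tG\t0.2\t0.10\t0\t1e-10\t50000",
    "rs2\t1\t2000\tT\tC\t0.5\tnot_a_number\t0.02\t1e-4\t50000",
    "rs3\t2\t3000\tG\tA\t0.9\t0.08\t0.015\t1e-8\t50000",
    sep = "\n"
  )
  writeLines(bad, f)
  expect_warning(ss2 <- read_summary_stats(f), "failed validation")
  expect_equal(ss2$variant_id, "rs3")
  probs <- attr(ss2, "problems")
  expect_setequal(probs$row, c(2, 3))
  expect_true(any(grepl("se", probs$reason)))

  # a missing mapped column is a configuration error
  writeLines(sub("\tSE", "\tSTDERR", txt), f)
  expect_error(read_summary_stats(f), "SE")
  # custom map fixes it
  ss3 <- read_summary_stats(f, column_map = c(se = "STDERR"))
  expect_equal(ss3$se, c(0.01, 0.02, 0.015))
})

test_that("reader accepts comma-delimited files", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("SNP,CHR,POS,EA,OA,EAF,BETA,SE,P,N",
               "rs1,1,1000,A,G,0.2,0.1,0.01,1e-10,1000"), f)
  ss <- read_summary_stats(f)
  expect_equal(ss$beta, 0.1)
})

exposure3 <- tibble::tibble(
  variant_id = c("rs1", "rs2", "rs3"),
  effect_allele = c("A", "A", "A"), other_allele = c("G", "T", "T"),
  eaf = c(0.2, 0.10, 0.45),
  beta = c(0.10, 0.10, 0.10), se = rep(0.01, 3), pvalue = rep(1e-10, 3)
)

test_that("allele swap flips the outcome effect; palindromes follow policy", {
  outcome <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("G", "A", "A"), other_allele = c("A", "T", "T"),
    eaf = c(0.8, 0.12, 0.45),
    beta = c(0.05, 0.02, 0.02), se = rep(0.01, 3), pvalue = rep(0.01, 3)
  )
  h <- harmonize(exposure3, outcome, maf_ambiguity_threshold = 0.42)
  expect_s3_class(h, "mr_harmonized")
  # rs1: swapped A/G vs G/A -> flipped, outcome beta negated, eaf complemented
  expect_equal(h$action[h$variant_id == "rs1"], "flipped")
  expect_equal(h$beta_outcome[h$variant_id == "rs1"], -0.05)
  expect_equal(h$eaf_outcome[h$variant_id == "rs1"], 0.2)
  # rs2: palindromic A/T, eaf 0.10 vs 0.12, both unambiguous, same side
  expect_equal(h$action[h$variant_id == "rs2"], "frequency_inferred")
  expect_equal(h$beta_outcome[h$variant_id == "rs2"], 0.02)
  # rs3: palindromic with maf 0.45 >= threshold -> dropped
  expect_equal(h$action[h$variant_id == "rs3"], "dropped_palindromic")
  # conservation: every shared variant accounted for by exactly one action
  expect_equal(nrow(h), 3)
  expect_true(all(h$action %in% c("direct", "flipped", "frequency_inferred",
                                  "dropped_palindromic", "dropped_mismatch")))
  # dropped variants are listed in the audit
  expect_equal(attr(h, "audit")$variant_id, "rs3")
})

test_that("strand complements are resolved before declaring mismatch", {
  outcome <- tibble::tibble(
    variant_id = c("rs1", "rs1b"),
    effect_allele = c("T", "C"), other_allele = c("C", "T"),
    eaf = c(0.2, 0.8), beta = c(0.05, 0.05), se = c(0.01, 0.01),
    pvalue = c(0.1, 0.1)
  )
  exposure <- tibble::tibble(
    variant_id = c("rs1", "rs1b"),
    effect_allele = c("A", "A"), other_allele = c("G", "G"),
    eaf = c(0.2, 0.2), beta = c(0.1, 0.1), se = c(0.01, 0.01),
    pvalue = c(1e-9, 1e-9)
  )
  h <- harmonize(exposure, outcome)
  # T/C is the strand complement of A/G -> direct
  expect_equal(h$action[h$variant_id == "rs1"], "direct")
  expect_equal(h$beta_outcome[h$variant_id == "rs1"], 0.05)
  # C/T is the complement of the swapped pair -> flipped
  expect_equal(h$action[h$variant_id == "rs1b"], "flipped")
  expect_equal(h$beta_outcome[h$variant_id == "rs1b"], -0.05)

  # an incompatible pair is dropped as a mismatch
  outcome_bad <- tibble::tibble(
    variant_id = "rs1", effect_allele = "A", other_allele = "C",
    eaf = 0.2, beta = 0.05, se = 0.01, pvalue = 0.1
  )
  h2 <- harmonize(exposure[1, ], outcome_bad)
  expect_equal(h2$action, "dropped_mismatch")
})

test_that("harmonization policies and edge cases behave as specified", {
  pal_exp <- exposure3[2, ]
  pal_out <- tibble::tibble(
    variant_id = "rs2", effect_allele = "A", other_allele = "T",
    eaf = NA_real_, beta = 0.02, se = 0.01, pvalue = 0.1
  )
  # infer_by_frequency with a missing eaf falls back to dropping, with warning
  expect_warning(h <- harmonize(pal_exp, pal_out), "lack eaf")
  expect_equal(h$action, "dropped_palindromic")
  # drop_all drops regardless of frequency
  h2 <- harmonize(exposure3[2, ],
                  tibble::tibble(variant_id = "rs2", effect_allele = "A",
                                 other_allele = "T", eaf = 0.1, beta = 0.02,
                                 se = 0.01, pvalue = 0.1),
                  palindrome_policy = "drop_all")
  expect_equal(h2$action, "dropped_palindromic")
  # keep_as_is trusts the labels
  h3 <- harmonize(exposure3[2, ],
                  tibble::tibble(variant_id = "rs2", effect_allele = "T",
                                 other_allele = "A", eaf = 0.9, beta = 0.02,
                                 se = 0.01, pvalue = 0.1),
                  palindrome_policy = "keep_as_is")
  expect_equal(h3$action, "flipped")
  expect_equal(h3$beta_outcome, -0.02)
  # empty intersection is an analysis error
  expect_error(
    harmonize(exposure3,
              tibble::tibble(variant_id = "zz", effect_allele = "A",
                             other_allele = "G", eaf = 0.2, beta = 1,
                             se = 1, pvalue = 0.5)),
    "no shared variants"
  )
})

test_that("harmonization is idempotent and a double allele flip is identity", {
  sim <- simulate_summary_stats(J = 30, beta_true = 0.2, seed = 11,
                                palindromic_fraction = 0.2)
  h1 <- harmonize(sim$exposure, sim$outcome)
  # re-harmonizing the harmonized pair changes nothing
  out_as_assoc <- tibble::tibble(
    variant_id = h1$variant_id, effect_allele = h1$effect_allele,
    other_allele = h1$other_allele, eaf = h1$eaf_outcome,
    beta = h1$beta_outcome, se = h1$se_outcome, pvalue = h1$pvalue_outcome
  )
  exp_as_assoc <- tibble::tibble(
    variant_id = h1$variant_id, effect_allele = h1$effect_allele,
    other_allele = h1$other_allele, eaf = h1$eaf_exposure,
    beta = h1$beta_exposure, se = h1$se_exposure, pvalue = h1$pvalue_exposure
  )
  keep <- !startsWith(h1$action, "dropped")
  h2 <- harmonize(exp_as_assoc[keep, ], out_as_assoc[keep, ])
  expect_equal(h2$beta_outcome, h1$beta_outcome[keep])
  expect_equal(h2$beta_exposure, h1$beta_exposure[keep])
  expect_true(all(h2$action %in% c("direct", "frequency_inferred")))

  # flipping the outcome's allele labels twice reproduces the original set
  flip_labels <- function(df) {
    tibble::tibble(
      variant_id = df$variant_id, effect_allele = df$other_allele,
      other_allele = df$effect_allele, eaf = 1 - df$eaf,
      beta = -df$beta, se = df$se, pvalue = df$pvalue
    )
  }
  h_flip2 <- harmonize(sim$exposure, flip_labels(flip_labels(sim$outcome)))
  expect_equal(h_flip2$beta_outcome, h1$beta_outcome)
  expect_equal(h_flip2$action, h1$action)
})

test_that("estimates are invariant to which allele the files call 'effect'", {
  sim <- simulate_summary_stats(J = 25, beta_true = 0.15, seed = 21)
  h_orig <- harmonize(sim$exposure, sim$outcome)
  # flip a subset of outcome rows' labels: harmonization must undo it
  out2 <- sim$outcome
  idx <- seq(1, 25, by = 2)
  tmp <- out2$effect_allele[idx]
  out2$effect_allele[idx] <- out2$other_allele[idx]
  out2$other_allele[idx] <- tmp
  out2$beta[idx] <- -out2$beta[idx]
  out2$eaf[idx] <- 1 - out2$eaf[idx]
  h_flip <- harmonize(sim$exposure, out2)
  expect_equal(mr_ivw(h_flip)$estimate, mr_ivw(h_orig)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_egger(h_flip)$estimate, mr_egger(h_orig)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_egger(h_flip)$intercept, mr_egger(h_orig)$intercept,
               tolerance = 1e-12)
  expect_equal(mr_cochran_q(h_flip)$q_stat, mr_cochran_q(h_orig)$q_stat,
               tolerance = 1e-12)
  expect_equal(
    mr_weighted_median(h_flip, n_boot = 0)$estimate,
    mr_weighted_median(h_orig, n_boot = 0)$estimate,
    tolerance = 1e-12
  )
})

test_that("orientation makes every exposure effect non-negative, ratios intact", {
  h <- make_instruments(
    g = c(-0.1, 0.2, 0.05), sg = c(0.01, 0.01, 0.01),
    G = c(-0.02, 0.04, 0.01), sG = c(0.005, 0.005, 0.005)
  )
  o <- orient_exposure_increasing(h)
  expect_true(all(o$beta_exposure >= 0))
  expect_equal(o$beta_exposure[1], 0.1)
  expect_equal(o$beta_outcome[1], 0.02)
  expect_equal(o$beta_outcome / o$beta_exposure,
               h$beta_outcome / h$beta_exposure)
  # all-positive input returned unchanged
  expect_equal(orient_exposure_increasing(o), o)
  # exact zero exposure effect excluded with a warning
  h0 <- make_instruments(g = c(0, 0.1), sg = c(0.01, 0.01),
                         G = c(0.1, 0.02), sG = c(0.01, 0.01))
  expect_warning(o0 <- orient_exposure_increasing(h0), "exactly 0")
  expect_equal(nrow(o0), 1)
  # IVW identical before and after orientation, to machine precision
  set.seed(4)
  hm <- make_instruments(
    g = rnorm(12, 0, 0.1), sg = runif(12, 0.005, 0.02),
    G = rnorm(12, 0, 0.03), sG = runif(12, 0.005, 0.02)
  )
  expect_equal(mr_ivw(hm)$estimate,
               mr_ivw(orient_exposure_increasing(hm))$estimate,
               tolerance = 1e-14)
})
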