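# Instrument selection (clumping) and instrument-property summaries.

test_that("clumping keeps the stronger of a perfect-LD pair and all independents", {
  cands <- tibble::tibble(
    variant_id = c("a", "b"), chrom = c("1", "1"), pos = c(1000, 6000),
    pvalue = c(1e-10, 1e-8)
  )
  ld <- tibble::tibble(id_a = "a", id_b = "b", r2 = 1.0)
  expect_equal(clump(cands, ld), "a")
  # four mutually independent variants are all retained
  cands4 <- tibble::tibble(
    variant_id = letters[1:4], chrom = "1", pos = c(1e3, 2e3, 3e3, 4e3),
    pvalue = c(1e-8, 1e-9, 1e-10, 1e-11)
  )
  expect_setequal(clump(cands4, NULL), letters[1:4])
  # empty input
  expect_equal(clump(cands4[0, ], NULL), character(0))
  # missing positions with non-empty LD is an error
  bad <- cands; bad$pos <- NA_real_
  expect_error(clump(bad, ld), "chrom and pos")
})

test_that("clumping matches the step-by-step greedy trace on crafted and random instances", {
  # crafted 6-variant instance over two chromosomes with mixed r2
  cands <- tibble::tibble(
    variant_id = c("v1", "v2", "v3", "v4", "v5", "v6"),
    chrom = c("1", "1", "1", "2", "2", "2"),
    pos = c(1e6, 1.5e6, 9e6, 1e6, 2e6, 40e6),
    pvalue = c(1e-12, 1e-9, 1e-10, 1e-8, 1e-11, 1e-9)
  )
  ld <- tibble::tibble(
    id_a = c("v1", "v1", "v2", "v4", "v4"),
    id_b = c("v2", "v3", "v3", "v5", "v6"),
    r2 = c(0.9, 0.005, 0.5, 0.8, 0.95)
  )
  expect_equal(clump(cands, ld, r2_max = 0.01, window_kb = 10000),
               oracle_clump(cands, ld, r2_max = 0.01, window_kb = 10000))
  # v6 is 38 Mb from v4: outside the window, retained despite r2 = 0.95
  expect_true("v6" %in% clump(cands, ld, r2_max = 0.01, window_kb = 10000))

  # random instances against the trace oracle
  for (rep in 1:25) {
    set.seed(rep)
    n <- sample(3:10, 1)
    cands <- tibble::tibble(
      variant_id = sprintf("s%02d", 1:n),
      chrom = sample(c("1", "2"), n, replace = TRUE),
      pos = sample(1:20, n) * 1e6,
      pvalue = 10^runif(n, -12, -6)
    )
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.5
    ld <- tibble::tibble(
      id_a = cands$variant_id[pairs[keep, 1]],
      id_b = cands$variant_id[pairs[keep, 2]],
      r2 = runif(sum(keep))
    )
    got <- clump(cands, ld, r2_max = 0.05, window_kb = 5000)
    expect_equal(got, oracle_clump(cands, ld, 0.05, 5000))
    # invariant: no retained pair violates the constraint
    kept <- cands[cands$variant_id %in% got, ]
    if (nrow(kept) > 1) {
      for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
        same <- kept$chrom[i] == kept$chrom[j] &&
          abs(kept$pos[i] - kept$pos[j]) <= 5000 * 1000
        hit <- (ld$id_a == kept$variant_id[i] & ld$id_b == kept$variant_id[j]) |
          (ld$id_b == kept$variant_id[i] & ld$id_a == kept$variant_id[j])
        r2ij <- if (any(hit)) max(ld$r2[hit]) else 0
        expect_false(same && r2ij > 0.05)
      }
    }
  }
})

test_that("clumping is permutation-invariant given the tie-break order", {
  set.seed(99)
  cands <- tibble::tibble(
    variant_id = sprintf("s%02d", 1:8), chrom = "1", pos = (1:8) * 1e6,
    pvalue = 10^runif(8, -12, -8)
  )
  ld <- tibble::tibble(id_a = cands$variant_id[1:7],
                       id_b = cands$variant_id[2:8], r2 = 0.5)
  base <- clump(cands, ld, 0.01, 10000)
  perm <- clump(cands[sample(8), ], ld, 0.01, 10000)
  expect_equal(sort(base), sort(perm))
  expect_equal(base, perm)  # retention order also deterministic
})

test_that("instrument selection filters, clumps, records parameters", {
  set.seed(5)
  assocs <- tibble::tibble(
    variant_id = sprintf("rs%02d", 1:10), chrom = "1", pos = (1:10) * 20e6,
    beta = rnorm(10, 0, 0.05), se = 0.005, n = 1e5,
    pvalue = c(1e-10, 1e-9, 4e-8, rep(1e-4, 7))
  )
  set <- select_instruments(assocs, p_threshold = 5e-8)
  expect_s3_class(set, "instrument_set")
  expect_equal(nrow(set), 3)
  expect_equal(attr(set, "selection_params")$p_threshold, 5e-8)
  expect_false(is.na(attr(set, "total_r2")))
  # all above threshold -> empty with warning
  expect_warning(empty <- select_instruments(assocs, p_threshold = 1e-12),
                 "no variants")
  expect_equal(nrow(empty), 0)
  # relaxed threshold retains a superset of the stringent one
  relaxed <- select_instruments(assocs, p_threshold = 1e-3)
  expect_true(all(set$variant_id %in% relaxed$variant_id))
  # invalid threshold
  expect_error(select_instruments(assocs, p_threshold = 2), "p_threshold")
})

test_that("continuous variance explained follows both closed forms", {
  # freq-based plug-in: 2 * 0.25 * 0.01
  expect_equal(variance_explained_continuous(0.1, eaf = 0.5,
                                             mode = "freq_based"), 0.005)
  # null effect is 0 in both modes
  expect_equal(variance_explained_continuous(0, eaf = 0.3,
                                             mode = "freq_based"), 0)
  expect_equal(variance_explained_continuous(0, se = 0.01, n = 1e5), 0)
  # z-based equals z^2/(z^2 + n - 2)
  z2 <- (0.05 / 0.005)^2
  expect_equal(variance_explained_continuous(0.05, se = 0.005, n = 1e5),
               z2 / (z2 + 1e5 - 2))
  # errors name the missing field
  expect_error(variance_explained_continuous(0.1, mode = "freq_based"), "eaf")
  expect_error(variance_explained_continuous(0.1, se = 0.01, n = NULL), "n")
})

test_that("z-based variance explained matches a genotype-phenotype simulation", {
  # simulate a genotype with known effect; the squared sample correlation of
  # trait on genotype is the oracle for the summary-statistic formula
  set.seed(42)
  n <- 100000
  eaf <- 0.3
  beta <- 0.05
  genotype <- rbinom(n, 2, eaf)
  trait <- beta * genotype + rnorm(n)
  fit <- summary(lm(trait ~ genotype))
  got <- variance_explained_continuous(
    beta = fit$coefficients[2, 1], se = fit$coefficients[2, 2],
    n = n, mode = "z_based"
  )
  expect_equal(got, fit$r.squared, tolerance = 1e-6)
  # and both agree with the theoretical 2pq beta^2 within Monte-Carlo error
  expect_equal(got, 2 * eaf * (1 - eaf) * beta^2, tolerance = 0.25)
})

test_that("liability-scale variance explained is internally consistent", {
  # null odds ratio explains nothing
  expect_equal(variance_explained_binary_liability(1, 0.3, 0.085), 0)
  expect_equal(variance_explained_binary_liability(1, 0.7, 0.4), 0)

  # Monte-Carlo liability oracle: genotypes at HWE receive their solved mean
  # liabilities plus unit normal residuals; disease is liability above the
  # (1 - prevalence) quantile; the empirical variance ratio and the empirical
  # odds ratio must match the analytic result and the input OR
  or <- 1.2; raf <- 0.3; prev <- 0.085
  v <- variance_explained_binary_liability(or, raf, prev)
  set.seed(7)
  n <- 2e6
  geno <- rbinom(n, 2, raf)
  # reconstruct the genotype mean liabilities the method implies
  gf <- c((1 - raf)^2, 2 * raf * (1 - raf), raf^2)
  f <- uniroot(function(lo0) {
    odds <- exp(lo0) * or^(0:2); sum(gf * odds / (1 + odds)) - prev
  }, c(-30, 30), tol = 1e-12)$root
  penetrance <- exp(f) * or^(0:2) / (1 + exp(f) * or^(0:2))
  mu <- qnorm(1 - prev) - qnorm(1 - penetrance)
  liab <- mu[geno + 1] + rnorm(n)
  case <- liab > quantile(liab, 1 - prev)
  # empirical variance of genotype means over total liability variance
  v_mc <- var(mu[geno + 1]) / var(liab)
  expect_equal(v, v_mc, tolerance = 0.02)
  # empirical per-allele odds ratio close to the input
  or_mc <- exp(coef(glm(case ~ geno, family = binomial()))[2])
  expect_equal(unname(or_mc), or, tolerance = 0.02)
  expect_equal(mean(case), prev, tolerance = 0.02)
})

test_that("variance explained is monotone and regimes agree at the limits", {
  # monotone in |beta| / OR departing from 1
  v1 <- variance_explained_continuous(c(0.05, 0.1, 0.2), eaf = 0.3,
                                      mode = "freq_based")
  expect_true(all(diff(v1) > 0))
  v2 <- variance_explained_binary_liability(c(1.05, 1.2, 1.5), 0.3, 0.085)
  expect_true(all(diff(v2) > 0))
  v2d <- variance_explained_binary_liability(c(0.95, 0.8, 0.6), 0.3, 0.085)
  expect_true(all(diff(v2d) > 0))

  # at prevalence 0.5 and OR -> 1+eps the liability method agrees with the
  # freq-based formula applied to the implied liability-scale effect
  # (per-allele shift ~ log(OR) * K(1-K)/phi(threshold) = log(OR)/(4*phi(0)))
  or <- 1.02; raf <- 0.4; prev <- 0.5
  b_liab <- log(or) * prev * (1 - prev) / dnorm(qnorm(1 - prev))
  expect_equal(
    variance_explained_binary_liability(or, raf, prev),
    variance_explained_continuous(b_liab, eaf = raf, mode = "freq_based"),
    tolerance = 0.01
  )
})

test_that("mean F statistic is the mean squared z", {
  h <- make_instruments(g = c(0.1, 0.08), sg = c(0.1 / 6, 0.01),
                        G = c(0, 0), sG = c(1, 1))
  # z = 6 and z = 8 -> mean of 36 and 64 = 50
  expect_equal(mean_f_statistic(h), 50)
  single <- tibble::tibble(beta = 0.1, se = 0.01)
  expect_equal(mean_f_statistic(single), 100)
  expect_error(mean_f_statistic(single[0, ]), "empty")
  # F grows with sample size
  f_at_n <- sapply(c(1e4, 1e5, 1e6), function(n) {
    sim <- simulate_summary_stats(J = 40, gamma_sd = 0.05, n_exposure = n,
                                  seed = 3)
    mean_f_statistic(sim$exposure)
  })
  expect_true(all(diff(f_at_n) > 0))
})
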