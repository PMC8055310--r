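# Synthetic GWAS summary statistics with known causal truth, LD fixtures,
# and a study-shaped end-to-end bundle.

#' Describe a pleiotropy model for the generator
#'
#' * `none`: every instrument valid.
#' * `balanced`: direct effects `alpha ~ N(0, sd)` (InSIDE holds, no bias in
#'   expectation).
#' * `directional`: `alpha ~ N(mean, sd)` independent of instrument strength
#'   (InSIDE holds; biases IVW, recovered by the Egger intercept).
#' * `inside_violating`: `alpha` correlated with the instrument strength with
#'   correlation `rho` and marginal sd `sd`.
#' * `outliers`: a fraction of variants receive a fixed pleiotropic offset of
#'   `offset` times their outcome standard error.
#'
#' @param type One of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`, `"outliers"`.
#' @param mean,sd,rho,fraction,offset Model parameters (see above).
#' @return A list describing the model.
#' @export
pleiotropy_model <- function(type = c("none", "balanced", "directional",
                                      "inside_violating", "outliers"),
                             mean = 0, sd = 0, rho = 0,
                             fraction = 0, offset = 0) {
  type <- match.arg(type)
  if (sd < 0) abort("pleiotropy sd must be non-negative")
  if (fraction < 0 || fraction > 1) abort("outlier fraction must be in [0, 1]")
  list(type = type, mean = mean, sd = sd, rho = rho,
       fraction = fraction, offset = offset)
}

draw_alleles <- function(J, palindromic_fraction) {
  non_pal <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                  c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pal <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  is_pal <- runif(J) < palindromic_fraction
  pairs <- lapply(seq_len(J), function(j) {
    if (is_pal[j]) pal[[sample.int(4, 1)]] else non_pal[[sample.int(8, 1)]]
  })
  list(ea = vapply(pairs, `[`, character(1), 1),
       oa = vapply(pairs, `[`, character(1), 2))
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Per variant: an allele frequency is drawn uniformly on `eaf_range`; a true
#' exposure effect `gamma_true ~ N(0, gamma_sd)`; a direct (pleiotropic)
#' outcome effect `alpha` per the chosen model; standard errors scale as
#' `1 / sqrt(2 * eaf * (1 - eaf) * n)` with the respective sample sizes; the
#' observed exposure effect is `N(gamma_true, se_exposure)` and the observed
#' outcome effect `N(beta_true * gamma_true + alpha, se_outcome)`. The two
#' samples are independent (two-sample design, no overlap). Allele pairs are
#' assigned with the configured palindromic fraction; both tables use the same
#' effect-allele labels so they harmonize to `direct` actions. With
#' `ascertain_p` set, (`gamma_true`, observed exposure effect) pairs are
#' redrawn until the observed exposure p-value reaches the threshold,
#' emulating significance-ascertained instruments (winner's curse included).
#' Identical seeds give identical output.
#'
#' @param J Number of instruments.
#' @param beta_true True causal effect of the exposure on the outcome (a log
#'   odds ratio when `outcome_type = "binary_logodds"`).
#' @param gamma_sd SD of true exposure effects.
#' @param n_exposure,n_outcome Sample sizes (effective sample sizes for
#'   case-control traits).
#' @param eaf_range Uniform bounds for the effect allele frequency.
#' @param pleiotropy A [pleiotropy_model()].
#' @param outcome_type `"continuous"` or `"binary_logodds"` (label only; the
#'   generative mechanics are identical on the log-odds scale).
#' @param palindromic_fraction Fraction of variants given strand-ambiguous
#'   (A/T, C/G) allele pairs.
#' @param ascertain_p Optional significance threshold the observed exposure
#'   association must reach (instrument ascertainment); `NULL` disables.
#' @param seed Optional integer seed.
#' @return A list of class `mr_simulation`: `exposure` and `outcome` tibbles in
#'   the summary-statistics schema and a `truth` tibble (`variant_id`, `eaf`,
#'   `gamma_true`, `alpha`, `is_outlier`) with attribute `beta_true`.
#' @export
simulate_summary_stats <- function(J = 100, beta_true = 0, gamma_sd = 0.1,
                                   n_exposure = 1e5, n_outcome = 1e5,
                                   eaf_range = c(0.05, 0.95),
                                   pleiotropy = pleiotropy_model("none"),
                                   outcome_type = c("continuous",
                                                    "binary_logodds"),
                                   palindromic_fraction = 0,
                                   ascertain_p = NULL, seed = NULL) {
  outcome_type <- match.arg(outcome_type)
  if (J < 1) abort("J must be at least 1")
  if (diff(range(eaf_range)) <= 0 || any(eaf_range <= 0) ||
      any(eaf_range >= 1)) {
    abort("eaf_range must be increasing bounds inside (0, 1)")
  }
  with_seed_maybe(seed, {
    eaf <- runif(J, eaf_range[1], eaf_range[2])
    se_g <- 1 / sqrt(2 * eaf * (1 - eaf) * n_exposure)
    se_G <- 1 / sqrt(2 * eaf * (1 - eaf) * n_outcome)
    gamma_true <- rnorm(J, 0, gamma_sd)
    g_obs <- rnorm(J, gamma_true, se_g)
    if (!is.null(ascertain_p)) {
      # Exact draw from the joint (gamma_true, g_obs) distribution conditioned
      # on genome-wide significance of the observed effect: the observed
      # effect's marginal is N(0, sqrt(gamma_sd^2 + se^2)); sample it
      # truncated to the rejection region, then the true effect from its
      # conditional normal given the observed one.
      z_min <- qnorm(ascertain_p / 2, lower.tail = FALSE)
      s_marg <- sqrt(gamma_sd^2 + se_g^2)
      p_tail <- pnorm(-z_min * se_g / s_marg)
      u <- runif(J, 0, p_tail)
      sign <- ifelse(runif(J) < 0.5, -1, 1)
      g_obs <- sign * (-qnorm(u)) * s_marg
      shrink <- gamma_sd^2 / s_marg^2
      gamma_true <- rnorm(J, shrink * g_obs,
                          sqrt(gamma_sd^2 * se_g^2) / s_marg)
    }
    is_outlier <- rep(FALSE, J)
    alpha <- switch(pleiotropy$type,
      none = rep(0, J),
      balanced = rnorm(J, 0, pleiotropy$sd),
      directional = rnorm(J, pleiotropy$mean, pleiotropy$sd),
      inside_violating = {
        rho <- pleiotropy$rho
        pleiotropy$sd * (rho * gamma_true / gamma_sd +
                           sqrt(max(0, 1 - rho^2)) * rnorm(J))
      },
      outliers = {
        n_out <- round(pleiotropy$fraction * J)
        idx <- if (n_out > 0) sample.int(J, n_out) else integer(0)
        is_outlier[idx] <- TRUE
        a <- rep(0, J)
        a[idx] <- pleiotropy$offset * se_G[idx]
        a
      }
    )
    # Pleiotropic effects are defined in the exposure-increasing orientation
    # (the only frame where "directional" is meaningful, since allele
    # labelling is arbitrary); applying them with the sign of the true
    # exposure effect realizes that convention in the labelled frame.
    alpha <- sign(gamma_true) * alpha
    G_obs <- rnorm(J, beta_true * gamma_true + alpha, se_G)
    al <- draw_alleles(J, palindromic_fraction)
    ids <- sprintf("rs%06d", seq_len(J))
    chrom <- as.character(rep_len(1:22, J))
    pos <- 1e6 + 25e6 * (seq_len(J) - 1) %/% 22

    mk <- function(beta, se, n) tibble::tibble(
      variant_id = ids, chrom = chrom, pos = pos,
      effect_allele = al$ea, other_allele = al$oa, eaf = eaf,
      beta = beta, se = se, pvalue = pmax(z_p(beta / se), 1e-320), n = n
    )
    structure(
      list(
        exposure = mk(g_obs, se_g, n_exposure),
        outcome = mk(G_obs, se_G, n_outcome),
        truth = structure(
          tibble::tibble(variant_id = ids, eaf = eaf,
                         gamma_true = gamma_true, alpha = alpha,
                         is_outlier = is_outlier),
          beta_true = beta_true
        )
      ),
      class = "mr_simulation"
    )
  })
}

#' Harmonize a simulation's exposure and outcome tables
#'
#' Convenience wrapper running [harmonize()] on the two tables of an
#' [simulate_summary_stats()] result.
#'
#' @param sim An `mr_simulation` object.
#' @param ... Passed to [harmonize()].
#' @return A harmonized instrument tibble.
#' @export
harmonize_simulation <- function(sim, ...) {
  harmonize(sim$exposure, sim$outcome, ...)
}

#' Simulate an LD block with distance-decaying correlation
#'
#' Positions on a regular grid; pairwise r-squared decays exponentially with
#' distance (`r2 = exp(-distance / decay_bp)`), truncated below 1e-4 to keep
#' the table sparse. When a seed is supplied the grid spacing is uniformly
#' jittered by up to 10 percent.
#'
#' @param n_variants Number of variants (>= 1).
#' @param chrom Chromosome label.
#' @param start_pos Position of the first variant (bp).
#' @param spacing_bp Grid spacing (bp).
#' @param decay_bp Distance at which r-squared falls to `exp(-1)`.
#' @param seed Optional seed for the position jitter.
#' @return A list: `positions` tibble (`variant_id`, `chrom`, `pos`) and `ld`
#'   tibble (`id_a`, `id_b`, `r2`; symmetric pairs stored once).
#' @export
simulate_ld_block <- function(n_variants, chrom = "1", start_pos = 1e6,
                              spacing_bp = 5000, decay_bp = 10000,
                              seed = NULL) {
  if (n_variants < 1) abort("n_variants must be at least 1")
  pos <- start_pos + spacing_bp * (seq_len(n_variants) - 1)
  if (!is.null(seed)) {
    pos <- with_seed_maybe(seed, {
      jitter <- c(0, round(runif(n_variants - 1, -0.1, 0.1) * spacing_bp))
      sort(pos + jitter)
    })
  }
  ids <- sprintf("ld%03d", seq_len(n_variants))
  positions <- tibble::tibble(variant_id = ids, chrom = chrom, pos = pos)
  if (n_variants == 1) {
    ld <- tibble::tibble(id_a = character(0), id_b = character(0),
                         r2 = numeric(0))
  } else {
    pairs <- utils::combn(n_variants, 2)
    r2 <- exp(-abs(pos[pairs[2, ]] - pos[pairs[1, ]]) / decay_bp)
    keep <- r2 >= 1e-4
    ld <- tibble::tibble(id_a = ids[pairs[1, keep]],
                         id_b = ids[pairs[2, keep]],
                         r2 = r2[keep])
  }
  list(positions = positions, ld = ld)
}

# Effective sample size of a case-control GWAS.
effective_n <- function(n_cases, n_controls) {
  4 / (1 / n_cases + 1 / n_controls)
}

# Fixture gamma scales, calibrated a priori so the ascertained instruments
# reproduce the study totals of variance explained (12.7% on the liability
# scale over 289 T2D instruments at prevalence 8.5%; 2.6% over 333 HbA1c
# instruments). See the methods vignette for the calibration.
FIXTURE_TAU_T2D <- 0.0593
FIXTURE_TAU_HBA1C <- 0.0022

#' A study-shaped synthetic fixture
#'
#' A bundle of synthetic summary statistics shaped like a two-exposure,
#' five-outcome stroke MR study: a binary "T2D-like" exposure with 289
#' significance-ascertained instruments (case-control effective sample size
#' from 74,124 cases / 824,006 controls) and a continuous "HbA1c-like"
#' exposure with 333 instruments (n = 421,923); binary outcomes at the
#' case-control scales of large ischemic-stroke consortia (any ischemic
#' stroke, large artery, cardioembolic, small vessel, intracerebral
#' hemorrhage). True causal effects are fixed per exposure-outcome pair
#' (attribute `truth`), no pleiotropy. The exposure gamma scales are
#' calibrated so the instruments explain about 12.7% (liability scale) and
#' 2.6% of trait variance. Runs end-to-end through [run_mr_grid()] in well
#' under a minute.
#'
#' @param seed Integer seed; identical seeds give identical bundles.
#' @return A list: `exposures` and `outcomes` named lists ready for
#'   [mr_analysis_config()] (each with `data` and `trait_type`), `truth`
#'   (tibble of exposure, outcome, true log-OR), and `config` (a ready
#'   [mr_analysis_config()] with the IVW, weighted median, Egger and PRESSO
#'   methods).
#' @export
study_shaped_fixture <- function(seed = 1L) {
  seed <- as.integer(seed)
  exposures_spec <- list(
    t2d = list(J = 289L, gamma_sd = FIXTURE_TAU_T2D,
               n = effective_n(74124, 824006), trait_type = "binary"),
    hba1c = list(J = 333L, gamma_sd = FIXTURE_TAU_HBA1C,
                 n = 421923, trait_type = "continuous")
  )
  outcomes_spec <- list(
    any_ischemic_stroke = list(n = effective_n(60341, 451210)),
    large_artery_stroke = list(n = effective_n(6688, 238513)),
    cardioembolic_stroke = list(n = effective_n(9006, 352852)),
    small_vessel_stroke = list(n = effective_n(11710, 287067)),
    intracerebral_hemorrhage = list(n = effective_n(1545, 1481))
  )
  # True log odds ratios per exposure x outcome.
  truth <- tibble::tribble(
    ~exposure, ~outcome, ~beta_true,
    "t2d", "any_ischemic_stroke", log(1.11),
    "t2d", "large_artery_stroke", log(1.22),
    "t2d", "cardioembolic_stroke", log(1.05),
    "t2d", "small_vessel_stroke", log(1.18),
    "t2d", "intracerebral_hemorrhage", log(1.09),
    "hba1c", "any_ischemic_stroke", log(1.36),
    "hba1c", "large_artery_stroke", log(2.06),
    "hba1c", "cardioembolic_stroke", 0,
    "hba1c", "small_vessel_stroke", log(1.85),
    "hba1c", "intracerebral_hemorrhage", 0
  )
  exposures <- list()
  outcome_parts <- lapply(outcomes_spec, function(o) list())
  k <- 0L
  for (exp_name in names(exposures_spec)) {
    sp <- exposures_spec[[exp_name]]
    # One shared latent instrument set per exposure; each outcome gets its own
    # independent outcome draw for the same variants.
    base <- simulate_summary_stats(
      J = sp$J, beta_true = 0, gamma_sd = sp$gamma_sd,
      n_exposure = sp$n, n_outcome = sp$n,
      eaf_range = c(0.1, 0.9), ascertain_p = 5e-8,
      seed = cell_seed(seed, "fixture", exp_name)
    )
    exposure_tbl <- base$exposure
    exposure_tbl$variant_id <- paste0(exp_name, "_", exposure_tbl$variant_id)
    # Spread exposures across distinct position blocks so grids never collide.
    k <- k + 1L
    exposure_tbl$pos <- exposure_tbl$pos + k * 5e8
    exposures[[exp_name]] <- list(data = exposure_tbl,
                                  trait_type = sp$trait_type)
    for (out_name in names(outcomes_spec)) {
      b <- truth$beta_true[truth$exposure == exp_name &
                             truth$outcome == out_name]
      n_out <- outcomes_spec[[out_name]]$n
      se_G <- 1 / sqrt(2 * base$truth$eaf * (1 - base$truth$eaf) * n_out)
      G_obs <- with_seed_maybe(
        cell_seed(seed, "fixture", exp_name, out_name),
        rnorm(sp$J, b * base$truth$gamma_true, se_G)
      )
      part <- exposure_tbl
      part$beta <- G_obs
      part$se <- se_G
      part$pvalue <- pmax(z_p(G_obs / se_G), 1e-320)
      part$n <- n_out
      part$eaf <- exposure_tbl$eaf
      outcome_parts[[out_name]][[exp_name]] <- part
    }
  }
  outcomes <- lapply(names(outcomes_spec), function(out_name) {
    list(data = dplyr::bind_rows(outcome_parts[[out_name]]),
         trait_type = "binary")
  })
  names(outcomes) <- names(outcomes_spec)
  config <- mr_analysis_config(
    exposures = exposures, outcomes = outcomes,
    methods = c("ivw", "weighted_median", "egger", "presso"),
    seed = seed
  )
  list(exposures = exposures, outcomes = outcomes, truth = truth,
       config = config)
}
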