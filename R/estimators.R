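# Core two-sample MR estimators on harmonized instruments: Wald ratio, IVW,
# Cochran Q, weighted median, MR-Egger.

# Per-variant ratio SE under the chosen delta-method expansion.
ratio_se <- function(g, sg, G, sG,
                     delta_order = c("first_full", "first_simple", "second")) {
  delta_order <- match.arg(delta_order)
  switch(delta_order,
    first_simple = sG / abs(g),
    first_full = sqrt(sG^2 / g^2 + G^2 * sg^2 / g^4),
    second = sqrt(sG^2 / g^2 + G^2 * sg^2 / g^4 + sG^2 * sg^2 / g^4)
  )
}

#' Per-variant Wald ratio estimates
#'
#' The causal effect implied by a single instrument is the ratio of the
#' variant-outcome to the variant-exposure effect; its standard error comes
#' from a delta-method expansion of the ratio. `first_simple` ignores the
#' uncertainty in the exposure effect (`se_outcome / |beta_exposure|`);
#' `first_full` (default) keeps both first-order terms; `second` adds the
#' second-order cross term.
#'
#' @param instruments Harmonized instrument tibble ([harmonize()]); rows with
#'   `beta_exposure == 0` are not allowed (pre-filter with
#'   [orient_exposure_increasing()]).
#' @param delta_order Delta-method expansion for the ratio SE.
#' @return A tibble with one row per variant: `variant_id`, `estimate`
#'   (the ratio), `std.error`, `weight` (`1 / std.error^2`).
#' @export
mr_wald_ratio <- function(instruments,
                          delta_order = c("first_full", "first_simple",
                                          "second")) {
  delta_order <- match.arg(delta_order)
  v <- instrument_vectors(instruments)
  if (any(v$g == 0)) {
    abort("Wald ratio undefined for beta_exposure == 0; filter such variants")
  }
  se <- ratio_se(v$g, v$sg, v$G, v$sG, delta_order)
  tibble::tibble(
    variant_id = v$id,
    estimate = v$G / v$g,
    std.error = se,
    weight = 1 / se^2
  )
}

# Fixed-effect IVW core on raw vectors (shared by estimators and PRESSO).
# Equivalent to the origin-constrained weighted regression of Gamma on gamma
# with weights 1/se_Gamma^2, i.e. ratio weights gamma^2/se_Gamma^2.
ivw_core <- function(g, sg, G, sG) {
  ratio <- G / g
  w <- g^2 / sG^2
  sw <- sum(w)
  beta <- sum(w * ratio) / sw
  Q <- sum(w * (ratio - beta)^2)
  list(beta = beta, se_fixed = sqrt(1 / sw), Q = Q, w = w, ratio = ratio)
}

#' Inverse-variance weighted (IVW) estimate
#'
#' Pools the per-variant Wald ratios with inverse-variance weights
#' `beta_exposure^2 / se_outcome^2`, identically the weighted regression of
#' the outcome effects on the exposure effects through the origin with
#' weights `1 / se_outcome^2`. Three dispersion models: `fixed`
#' (`se = 1/sqrt(sum w)`); `multiplicative` (default, the conventional
#' random-effects IVW) inflates the fixed SE by `max(1, sqrt(Q/(J-1)))`;
#' `additive_dl` adds a DerSimonian-Laird between-variant variance to each
#' weight. Cochran Q heterogeneity is attached whenever at least two
#' instruments are available.
#'
#' @param instruments Harmonized instrument tibble.
#' @param re_model Dispersion model (see Details).
#' @return A one-row `mr_estimate` tibble: `method`, `n_snp`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`, `q_stat`,
#'   `q_df`, `q_pvalue` (plus `intercept*` columns, `NA` here).
#' @export
mr_ivw <- function(instruments,
                   re_model = c("multiplicative", "fixed", "additive_dl")) {
  re_model <- match.arg(re_model)
  v <- instrument_vectors(instruments)
  J <- length(v$g)
  if (J == 0) abort("no instruments available for IVW")
  if (J == 1) {
    wr <- mr_wald_ratio(instruments)
    z <- wr$estimate / wr$std.error
    return(new_mr_estimate(
      method = "ivw (single-variant Wald ratio)", n_snp = 1L,
      estimate = wr$estimate, std.error = wr$std.error,
      p.value = z_p(z),
      conf.low = wr$estimate - qnorm(0.975) * wr$std.error,
      conf.high = wr$estimate + qnorm(0.975) * wr$std.error
    ))
  }
  core <- ivw_core(v$g, v$sg, v$G, v$sG)
  df <- J - 1
  if (re_model == "additive_dl") {
    w <- core$w
    tau2 <- max(0, (core$Q - df) / (sum(w) - sum(w^2) / sum(w)))
    w_star <- 1 / (1 / w + tau2)
    beta <- sum(w_star * core$ratio) / sum(w_star)
    se <- sqrt(1 / sum(w_star))
  } else {
    beta <- core$beta
    se <- core$se_fixed
    if (re_model == "multiplicative") se <- se * max(1, sqrt(core$Q / df))
  }
  z <- beta / se
  new_mr_estimate(
    method = paste0("ivw_", re_model), n_snp = J,
    estimate = beta, std.error = se, p.value = z_p(z),
    conf.low = beta - qnorm(0.975) * se,
    conf.high = beta + qnorm(0.975) * se,
    q_stat = core$Q, q_df = df, q_pvalue = pchisq(core$Q, df, lower.tail = FALSE)
  )
}

#' Cochran Q heterogeneity of the per-variant ratio estimates
#'
#' `Q = sum w_j (ratio_j - beta_ivw_fixed)^2` with the IVW weights; under
#' homogeneity Q is chi-squared with J - 1 degrees of freedom. Large Q signals
#' dispersion beyond sampling noise, e.g. horizontal pleiotropy.
#'
#' @param instruments Harmonized instrument tibble (at least 2 variants).
#' @return A one-row tibble: `q_stat`, `q_df`, `q_pvalue`.
#' @export
mr_cochran_q <- function(instruments) {
  v <- instrument_vectors(instruments)
  J <- length(v$g)
  if (J < 2) abort("Cochran Q requires at least 2 instruments")
  core <- ivw_core(v$g, v$sg, v$G, v$sG)
  tibble::tibble(
    q_stat = core$Q, q_df = J - 1,
    q_pvalue = pchisq(core$Q, J - 1, lower.tail = FALSE)
  )
}

# Weighted median with linear interpolation of the ratio at normalized
# cumulative weight 0.5 (centered positions (cumsum(w) - w/2)/sum(w)).
weighted_median_value <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  approx(p, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' The median of the per-variant Wald ratios under the inverse-variance
#' weights: ratios are ordered, cumulative weights normalized, and the ratio
#' at cumulative weight 0.5 is linearly interpolated. Consistent as long as
#' valid instruments carry at least half the total weight. The standard error
#' comes from a parametric bootstrap: exposure and outcome effects are
#' redrawn from their normal sampling distributions `n_boot` times and the
#' weighted median recomputed.
#'
#' @param instruments Harmonized instrument tibble (at least 3 variants).
#' @param n_boot Bootstrap replicates for the SE (default 1000); `0` skips
#'   the bootstrap and returns `NA` SE/p/CI (point estimate only).
#' @param seed Optional integer seed for the bootstrap.
#' @return A one-row `mr_estimate` tibble.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = NULL) {
  v <- instrument_vectors(instruments)
  J <- length(v$g)
  if (J < 3) abort("weighted median requires at least 3 instruments")
  if (n_boot > 0 && n_boot < 100) {
    warn("n_boot < 100 gives an unstable bootstrap standard error")
  }
  se_r <- ratio_se(v$g, v$sg, v$G, v$sG, "first_simple")
  w <- 1 / se_r^2
  est <- weighted_median_value(v$G / v$g, w)
  se <- NA_real_
  if (n_boot > 0) {
    boots <- with_seed_maybe(seed, {
      vapply(seq_len(n_boot), function(b) {
        gb <- rnorm(J, v$g, v$sg)
        Gb <- rnorm(J, v$G, v$sG)
        seb <- v$sG / abs(gb)
        weighted_median_value(Gb / gb, 1 / seb^2)
      }, numeric(1))
    })
    se <- sd(boots)
  }
  new_mr_estimate(
    method = "weighted_median", n_snp = J,
    estimate = est, std.error = se,
    p.value = if (is.na(se)) NA_real_ else z_p(est / se),
    conf.low = est - qnorm(0.975) * se,
    conf.high = est + qnorm(0.975) * se
  )
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects with
#' an intercept, weights `1 / se_outcome^2`, after orienting every instrument
#' exposure-increasing (the orientation under which the fit is invariant to
#' allele labelling). The slope estimates the causal effect under the InSIDE
#' assumption; the intercept estimates the average directional pleiotropic
#' effect, and its p-value (`intercept_p < 0.05`) flags unbalanced
#' pleiotropy. Standard errors use multiplicative residual dispersion floored
#' at 1 and t-distribution inference with J - 2 degrees of freedom.
#'
#' @param instruments Harmonized instrument tibble (at least 3 variants with
#'   non-constant exposure effects).
#' @return A one-row `mr_estimate` tibble for the slope, carrying
#'   `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(instruments) {
  instruments <- orient_exposure_increasing(kept_instruments(instruments))
  v <- instrument_vectors(instruments)
  J <- length(v$g)
  if (J < 3) abort("MR-Egger requires at least 3 instruments")
  if (isTRUE(all.equal(stats::var(v$g), 0)) || stats::var(v$g) == 0) {
    abort("MR-Egger slope unidentifiable: no variance in exposure effects")
  }
  w <- 1 / v$sG^2
  fit <- lm(v$G ~ v$g, weights = w)
  sm <- summary(fit)
  disp <- max(1, sm$sigma)               # floor dispersion at 1
  ses <- sqrt(diag(sm$cov.unscaled)) * disp
  int <- unname(coef(fit)[1]); int_se <- unname(ses[1])
  slope <- unname(coef(fit)[2]); slope_se <- unname(ses[2])
  df <- J - 2
  tq <- qt(0.975, df)
  new_mr_estimate(
    method = "mr_egger", n_snp = J,
    estimate = slope, std.error = slope_se,
    statistic = slope / slope_se,
    p.value = t_p(slope / slope_se, df),
    conf.low = slope - tq * slope_se,
    conf.high = slope + tq * slope_se,
    intercept = int, intercept_se = int_se,
    intercept_p = t_p(int / int_se, df)
  )
}
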