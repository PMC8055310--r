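# Internal helpers shared across modules.

ALLELES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(x) unname(COMPLEMENT[x])

is_palindromic_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Run `code` under a fixed seed when one is supplied, leaving the global RNG
# state untouched; otherwise use the ambient RNG stream.
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Deterministic per-cell seed substream: combines the top-level analysis seed
# with a string key (exposure/outcome/method). Stays well inside 32-bit range.
cell_seed <- function(seed, ...) {
  key <- paste(..., collapse = "::")
  codes <- utf8ToInt(key)
  h <- sum(codes * seq_along(codes)) %% 1000003L
  as.integer((as.integer(seed) %% 2146483L) * 1000L + h %% 1000L + h)
}

# Normal-theory two-sided p-value, floored away from exact zero so reported
# p-values always satisfy the (0, 1] contract.
z_p <- function(z) pmax(2 * pnorm(-abs(z)), 1e-320)

# t-theory two-sided p-value with the same floor.
t_p <- function(t, df) pmax(2 * pt(-abs(t), df), 1e-320)

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# One-row estimate tibble shared by all estimators so grid rows bind cleanly.
new_mr_estimate <- function(method, n_snp, estimate, std.error,
                            statistic = estimate / std.error,
                            p.value, conf.low, conf.high,
                            q_stat = NA_real_, q_df = NA_real_,
                            q_pvalue = NA_real_,
                            intercept = NA_real_, intercept_se = NA_real_,
                            intercept_p = NA_real_) {
  out <- tibble::tibble(
    method = method, n_snp = as.integer(n_snp),
    estimate = estimate, std.error = std.error, statistic = statistic,
    p.value = p.value, conf.low = conf.low, conf.high = conf.high,
    q_stat = q_stat, q_df = q_df, q_pvalue = q_pvalue,
    intercept = intercept, intercept_se = intercept_se,
    intercept_p = intercept_p
  )
  class(out) <- c("mr_estimate", class(out))
  out
}

#' Express a log odds ratio estimate on the odds ratio scale
#'
#' Adds exponentiated `or`, `or_conf.low`, `or_conf.high` columns to an
#' estimate whose `estimate` column is a log odds ratio (binary outcome).
#' A one-unit log-odds increment corresponds to an `exp(1)` (about 2.72)
#' fold change in odds.
#'
#' @param estimates A tibble with `estimate`, `conf.low`, `conf.high`
#'   columns (e.g. the output of [mr_ivw()]).
#' @return The input with `or`, `or_conf.low`, `or_conf.high` appended.
#' @export
#' @examples
#' est <- tibble::tibble(estimate = log(1.2), conf.low = log(1.1),
#'                       conf.high = log(1.3))
#' add_odds_scale(est)
add_odds_scale <- function(estimates) {
  assert_columns(estimates, c("estimate", "conf.low", "conf.high"),
                 "estimate table")
  estimates$or <- exp(estimates$estimate)
  estimates$or_conf.low <- exp(estimates$conf.low)
  estimates$or_conf.high <- exp(estimates$conf.high)
  estimates
}

# Keep only instruments that survived harmonization (estimators must never
# see dropped records).
kept_instruments <- function(h) {
  if ("action" %in% names(h)) {
    h <- h[!startsWith(h$action, "dropped"), , drop = FALSE]
  }
  h
}

# Extract the (gamma, se_gamma, Gamma, se_Gamma) vectors an estimator needs.
instrument_vectors <- function(h) {
  h <- kept_instruments(h)
  assert_columns(
    h, c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome"),
    "harmonized instrument table"
  )
  list(
    g = h$beta_exposure, sg = h$se_exposure,
    G = h$beta_outcome, sG = h$se_outcome,
    id = if ("variant_id" %in% names(h)) h$variant_id
         else paste0("v", seq_len(nrow(h)))
  )
}
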