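# Instrument selection (significance filter + greedy LD clumping) and
# instrument-property summaries (variance explained, mean F statistic).

#' Read a pairwise LD table from delimited text
#'
#' Three columns (`id_a`, `id_b`, `r2`); pairs absent from the table are
#' treated as r-squared zero everywhere in the package.
#'
#' @param path Path to a tab- or comma-delimited file with a header.
#' @return A tibble with columns `id_a`, `id_b`, `r2`.
#' @export
read_ld_table <- function(path) {
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
  ld <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  names(ld)[1:3] <- c("id_a", "id_b", "r2")
  ld$r2 <- as.numeric(ld$r2)
  if (any(ld$r2 < 0 | ld$r2 > 1, na.rm = TRUE)) {
    abort("r2 values must lie in [0, 1]")
  }
  tibble::as_tibble(ld[, c("id_a", "id_b", "r2")])
}

# Symmetric lookup environment keyed "a|b" for fast pairwise r2 queries.
ld_lookup <- function(ld) {
  env <- new.env(parent = emptyenv(), size = max(2L * nrow(ld), 16L))
  if (!is.null(ld) && nrow(ld) > 0) {
    for (i in seq_len(nrow(ld))) {
      assign(paste(ld$id_a[i], ld$id_b[i], sep = "|"), ld$r2[i], envir = env)
      assign(paste(ld$id_b[i], ld$id_a[i], sep = "|"), ld$r2[i], envir = env)
    }
  }
  function(a, b) {
    if (a == b) return(1)
    val <- get0(paste(a, b, sep = "|"), envir = env, ifnotfound = 0)
    val
  }
}

#' Greedy LD clumping of candidate variants
#'
#' PLINK-style greedy clumping: candidates are ranked by ascending p-value
#' (ties broken by chromosome, position, then variant id); the best remaining
#' variant is retained and every remaining variant on the same chromosome
#' within `window_kb` kilobases either side whose pairwise r-squared with it
#' exceeds `r2_max` is discarded; repeat until no candidates remain. The
#' retained set never contains a pair violating the (`r2_max`, `window_kb`)
#' constraint.
#'
#' @param candidates Association tibble with `variant_id`, `pvalue` and, when
#'   `ld` is non-empty, `chrom` and `pos` (1-based base pairs).
#' @param ld LD tibble (`id_a`, `id_b`, `r2`) or `NULL`; absent pairs count as
#'   r-squared 0.
#' @param r2_max Maximum tolerated pairwise r-squared (default 0.01).
#' @param window_kb Half-window in kilobases around the index variant within
#'   which LD is considered (default 10,000 kB).
#' @return Character vector of retained `variant_id`s, in retention order.
#' @export
clump <- function(candidates, ld = NULL, r2_max = 0.01, window_kb = 10000) {
  if (nrow(candidates) == 0) return(character(0))
  assert_columns(candidates, c("variant_id", "pvalue"), "candidates")
  if (!(r2_max > 0 && r2_max < 1)) abort("r2_max must lie in (0, 1)")
  if (!(window_kb > 0)) abort("window_kb must be positive")
  has_ld <- !is.null(ld) && nrow(ld) > 0
  if (has_ld &&
      (!all(c("chrom", "pos") %in% names(candidates)) ||
       anyNA(candidates$pos) || anyNA(candidates$chrom))) {
    abort("candidates must carry chrom and pos when an LD table is supplied")
  }
  r2 <- if (has_ld) ld_lookup(ld) else function(a, b) if (a == b) 1 else 0
  chrom <- if ("chrom" %in% names(candidates)) as.character(candidates$chrom)
           else rep("1", nrow(candidates))
  pos <- if ("pos" %in% names(candidates)) as.numeric(candidates$pos)
         else rep(0, nrow(candidates))
  ord <- order(candidates$pvalue, chrom, pos, candidates$variant_id)
  active <- rep(TRUE, nrow(candidates))
  retained <- character(0)
  window_bp <- window_kb * 1000
  for (i in ord) {
    if (!active[i]) next
    retained <- c(retained, candidates$variant_id[i])
    active[i] <- FALSE
    in_window <- active & chrom == chrom[i] & abs(pos - pos[i]) <= window_bp
    for (j in which(in_window)) {
      if (r2(candidates$variant_id[i], candidates$variant_id[j]) > r2_max) {
        active[j] <- FALSE
      }
    }
  }
  retained
}

#' Select genetic instruments by significance threshold and LD clumping
#'
#' Filters to associations with `pvalue <= p_threshold` and clumps the
#' survivors with [clump()]. The conventional genome-wide settings (p below
#' 5e-8, r-squared below 0.01 within a 10,000 kB window) are the defaults.
#'
#' @inheritParams clump
#' @param assocs Association tibble (from [read_summary_stats()]).
#' @param p_threshold Significance threshold in (0, 1); default `5e-8`.
#' @param exposure_name Label recorded on the returned set.
#' @return A tibble of the retained associations (class `instrument_set`) with
#'   attributes `exposure_name`, `selection_params` and `total_r2` (the summed
#'   variance explained when `se` and `n` allow the summary-statistic formula,
#'   otherwise `NA`).
#' @export
select_instruments <- function(assocs, p_threshold = 5e-8, ld = NULL,
                               r2_max = 0.01, window_kb = 10000,
                               exposure_name = "exposure") {
  if (!(is.numeric(p_threshold) && p_threshold > 0 && p_threshold < 1)) {
    abort("p_threshold must lie in (0, 1)")
  }
  assert_columns(assocs, c("variant_id", "pvalue"), "associations")
  hits <- assocs[!is.na(assocs$pvalue) & assocs$pvalue <= p_threshold, ,
                 drop = FALSE]
  if (nrow(hits) == 0) {
    warn(sprintf("no variants reach p <= %g for %s", p_threshold,
                 exposure_name))
    members <- hits
  } else {
    keep <- clump(hits, ld = ld, r2_max = r2_max, window_kb = window_kb)
    members <- hits[match(keep, hits$variant_id), , drop = FALSE]
  }
  total_r2 <- NA_real_
  if (nrow(members) > 0 && all(c("beta", "se", "n") %in% names(members)) &&
      !anyNA(members$se) && !anyNA(members$n)) {
    total_r2 <- sum(variance_explained_continuous(
      beta = members$beta, se = members$se, n = members$n, mode = "z_based"
    ))
  }
  attr(members, "exposure_name") <- exposure_name
  attr(members, "selection_params") <- list(
    p_threshold = p_threshold, r2_max = r2_max, window_kb = window_kb
  )
  attr(members, "total_r2") <- total_r2
  class(members) <- c("instrument_set", class(members))
  members
}

#' Variance explained by a variant for a continuous trait
#'
#' Two summary-statistic formulas, vectorized over variants. `freq_based`
#' requires a standardized (SD-unit) effect and the effect allele frequency:
#' r-squared = `2 * eaf * (1 - eaf) * beta^2`. `z_based` (default) uses only
#' the z-statistic and the sample size: r-squared = `z^2 / (z^2 + n - 2)` with
#' `z = beta / se`, the squared sample correlation implied by the test
#' statistic. Results are clipped to \[0, 1\].
#'
#' @param beta Per-allele effect (SD units for `freq_based`).
#' @param eaf Effect allele frequency (needed for `freq_based`).
#' @param n Sample size (needed for `z_based`).
#' @param se Standard error of `beta` (needed for `z_based`).
#' @param mode `"z_based"` or `"freq_based"`.
#' @return Numeric vector of variance fractions in \[0, 1\].
#' @export
variance_explained_continuous <- function(beta, eaf = NULL, n = NULL,
                                          se = NULL,
                                          mode = c("z_based", "freq_based")) {
  mode <- match.arg(mode)
  if (mode == "freq_based") {
    if (is.null(eaf) || anyNA(eaf)) abort("freq_based mode requires eaf")
    r2 <- 2 * eaf * (1 - eaf) * beta^2
  } else {
    if (is.null(se) || anyNA(se)) abort("z_based mode requires se")
    if (is.null(n) || anyNA(n)) abort("z_based mode requires n")
    z2 <- (beta / se)^2
    r2 <- z2 / (z2 + n - 2)
  }
  pmin(pmax(r2, 0), 1)
}

#' Variance explained on the liability scale for a binary trait
#'
#' So et al.-style liability-threshold calculation from an allelic odds ratio.
#' Under Hardy-Weinberg genotype frequencies and multiplicative per-allele
#' odds, the baseline odds are solved so the population prevalence matches
#' `prevalence`; each genotype's penetrance is mapped to a mean liability via
#' the inverse normal against the population threshold; the variance of those
#' genotype-specific mean liabilities (total liability variance 1) is
#' returned. Vectorized over variants.
#'
#' @param odds_ratio Per-allele odds ratio (> 0).
#' @param raf Risk (effect) allele frequency in (0, 1).
#' @param prevalence Population disease prevalence in (0, 1).
#' @return Numeric vector of liability-scale variance fractions in \[0, 1\].
#' @export
variance_explained_binary_liability <- function(odds_ratio, raf, prevalence) {
  if (any(odds_ratio <= 0)) abort("odds_ratio must be positive")
  if (any(raf <= 0 | raf >= 1)) abort("raf must lie in (0, 1)")
  if (any(prevalence <= 0 | prevalence >= 1)) {
    abort("prevalence must lie in (0, 1)")
  }
  n <- max(length(odds_ratio), length(raf), length(prevalence))
  odds_ratio <- rep_len(odds_ratio, n)
  raf <- rep_len(raf, n)
  prevalence <- rep_len(prevalence, n)
  vapply(seq_len(n), function(i) {
    or <- odds_ratio[i]; p <- raf[i]; K <- prevalence[i]
    geno_freq <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    prev_given_log_odds0 <- function(lo0) {
      odds <- exp(lo0) * or^(0:2)
      sum(geno_freq * odds / (1 + odds)) - K
    }
    root <- tryCatch(
      uniroot(prev_given_log_odds0, interval = c(-40, 40), tol = 1e-12),
      error = function(e) abort(sprintf(
        "no penetrance solution in (0, 1) for odds_ratio=%g raf=%g prevalence=%g",
        or, p, K
      ))
    )
    odds <- exp(root$root) * or^(0:2)
    penetrance <- odds / (1 + odds)
    threshold <- qnorm(1 - K)
    mu <- threshold - qnorm(1 - penetrance)
    v <- sum(geno_freq * mu^2) - sum(geno_freq * mu)^2
    min(max(v, 0), 1)
  }, numeric(1))
}

#' Mean instrument F statistic
#'
#' Mean over variants of the squared z-statistic of the variant-exposure
#' association, the usual summary of instrument strength (values well above
#' 10 rule out weak-instrument bias).
#'
#' @param instruments Either an instrument/association tibble with `beta` and
#'   `se`, or a harmonized tibble with `beta_exposure` and `se_exposure`.
#' @return A single non-negative number.
#' @export
mean_f_statistic <- function(instruments) {
  instruments <- kept_instruments(instruments)
  if (all(c("beta_exposure", "se_exposure") %in% names(instruments))) {
    b <- instruments$beta_exposure; s <- instruments$se_exposure
  } else {
    assert_columns(instruments, c("beta", "se"), "instrument table")
    b <- instruments$beta; s <- instruments$se
  }
  if (length(b) == 0) abort("cannot compute mean F statistic on empty input")
  mean((b / s)^2)
}

#' Write an instrument set to TSV
#'
#' @param instruments Output of [select_instruments()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_instruments <- function(instruments, path) {
  readr::write_tsv(tibble::as_tibble(instruments), path, progress = FALSE)
  invisible(path)
}
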