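# Orchestration of the full study design: exposure x outcome grid, analysis
# variants, FDR across the grid, bidirectional analyses, annotation-based
# instrument exclusion, reporting.

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate q-values with enforced monotonicity, returned
#' in the input order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.na(pvalues) & (pvalues <= 0 | pvalues > 1))) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Exclude instruments annotated with a secondary trait
#'
#' Removes every instrument that any annotation row associates with a
#' secondary trait at `p < p_cut` (strict inequality: an annotation at exactly
#' `p_cut` is retained). Used e.g. to strip HbA1c instruments acting through
#' erythrocyte biology rather than glycemia.
#'
#' @param instruments Instrument tibble (e.g. from [select_instruments()]).
#' @param annotation Tibble with `variant_id`, `trait`, `p` (secondary-trait
#'   association p-values); an empty table is the identity.
#' @param p_cut Exclusion threshold in (0, 1); default 0.001.
#' @return The filtered instrument tibble, attributes preserved, with an
#'   `"audit"` attribute listing the removed variants and the trait that
#'   triggered removal.
#' @export
exclude_annotated <- function(instruments, annotation, p_cut = 0.001) {
  if (!(p_cut > 0 && p_cut < 1)) abort("p_cut must lie in (0, 1)")
  atts <- attributes(instruments)
  if (is.null(annotation) || nrow(annotation) == 0) {
    attr(instruments, "audit") <- tibble::tibble(
      variant_id = character(0), stage = character(0), reason = character(0)
    )
    return(instruments)
  }
  assert_columns(annotation, c("variant_id", "p"), "annotation")
  hits <- annotation[annotation$p < p_cut, , drop = FALSE]
  removed <- instruments$variant_id %in% hits$variant_id
  reason_trait <- if ("trait" %in% names(hits)) {
    vapply(instruments$variant_id[removed], function(id) {
      paste(unique(hits$trait[hits$variant_id == id]), collapse = ";")
    }, character(1))
  } else rep("annotated", sum(removed))
  out <- instruments[!removed, , drop = FALSE]
  for (a in setdiff(names(atts), c("row.names", "names"))) {
    attr(out, a) <- atts[[a]]
  }
  attr(out, "audit") <- tibble::tibble(
    variant_id = instruments$variant_id[removed],
    stage = "annotation_exclusion",
    reason = paste0("associated at p < ", p_cut, " with ", reason_trait)
  )
  out
}

#' Assemble an analysis configuration for the exposure-by-outcome grid
#'
#' @param exposures Named list; each element a list with `data` (association
#'   tibble or file path), `trait_type` (`"continuous"` or `"binary"`),
#'   optional `ld` (LD tibble) and optional `exclusions` (named list of
#'   sensitivity variants, each a list with `annotation` tibble and optional
#'   `p_cut`, default 0.001).
#' @param outcomes Named list; each element a list with `data` and
#'   `trait_type`.
#' @param selection List of instrument-selection parameters: `p_threshold`
#'   (default 5e-8), `r2_max` (0.01), `window_kb` (10000).
#' @param methods Methods to run per cell, subset of `"ivw"`,
#'   `"weighted_median"`, `"egger"`, `"presso"`; IVW is the primary method
#'   and the FDR family.
#' @param fdr_alpha FDR significance level (default 0.05).
#' @param bidirectional_p_threshold Relaxed instrument threshold for reverse
#'   analyses (default 1e-6).
#' @param seed Integer seed from which all per-cell random streams (median
#'   bootstrap, pleiotropy simulations) are derived deterministically.
#' @return A list of class `mr_config`.
#' @export
mr_analysis_config <- function(exposures, outcomes,
                               selection = list(),
                               methods = c("ivw", "weighted_median", "egger",
                                           "presso"),
                               fdr_alpha = 0.05,
                               bidirectional_p_threshold = 1e-6,
                               seed = 1L) {
  if (length(exposures) == 0 || length(outcomes) == 0) {
    abort("config needs at least one exposure and one outcome")
  }
  if (is.null(names(exposures)) || is.null(names(outcomes))) {
    abort("exposures and outcomes must be named lists")
  }
  sel <- utils::modifyList(
    list(p_threshold = 5e-8, r2_max = 0.01, window_kb = 10000), selection
  )
  for (thr in c(sel$p_threshold, fdr_alpha, bidirectional_p_threshold)) {
    if (!(thr > 0 && thr < 1)) abort("thresholds must lie in (0, 1)")
  }
  methods <- match.arg(methods, c("ivw", "weighted_median", "egger", "presso"),
                       several.ok = TRUE)
  structure(
    list(exposures = exposures, outcomes = outcomes, selection = sel,
         methods = methods, fdr_alpha = fdr_alpha,
         bidirectional_p_threshold = bidirectional_p_threshold,
         seed = as.integer(seed)),
    class = "mr_config"
  )
}

load_assoc <- function(data, trait_type = "continuous") {
  if (is.character(data)) {
    read_summary_stats(data, trait_type = trait_type)
  } else {
    data
  }
}

# Minimum instrument counts per method.
method_min_snps <- c(ivw = 2L, weighted_median = 3L, egger = 3L, presso = 4L)

empty_cell_row <- function(method, n_snp, note) {
  out <- new_mr_estimate(
    method = method, n_snp = n_snp, estimate = NA_real_,
    std.error = NA_real_, statistic = NA_real_, p.value = NA_real_,
    conf.low = NA_real_, conf.high = NA_real_
  )
  out$note <- note
  out
}

run_cell_method <- function(method, oriented, seed) {
  min_needed <- method_min_snps[[method]]
  J <- nrow(kept_instruments(oriented))
  if (J < min_needed) {
    return(empty_cell_row(method, J, sprintf(
      "too few instruments (%d < %d)", J, min_needed
    )))
  }
  row <- switch(method,
    ivw = mr_ivw(oriented),
    weighted_median = mr_weighted_median(oriented, n_boot = 1000, seed = seed),
    egger = mr_egger(oriented),
    presso = {
      pr <- mr_presso(oriented, n_sim = 1000, seed = seed)
      est <- pr$corrected %||% pr$raw
      est$method <- if (is.null(pr$corrected)) "presso_raw"
                    else "presso_corrected"
      est$presso_global_p <- pr$global_p
      est$n_outliers <- length(pr$outliers)
      attr(est, "presso") <- pr
      est
    }
  )
  row$note <- NA_character_
  row
}

#' Run the full exposure-by-outcome analysis grid
#'
#' For every exposure: selects instruments (significance filter + clumping)
#' and builds the configured analysis variants (`primary` plus one per
#' annotation-exclusion list). For every exposure x outcome x variant cell:
#' harmonizes, orients exposure-increasing, runs the configured methods with a
#' deterministic per-cell random stream derived from the config seed, and
#' collects one row per method. Benjamini-Hochberg q-values are computed
#' across the primary-method (IVW) family within each analysis variant, with
#' the significance tiers `fdr_significant` (q below `fdr_alpha`), `nominal`
#' (raw p < 0.05 but q at or above `fdr_alpha`) and `null`. Binary-outcome
#' estimates are also reported on the odds ratio scale. Cell-level errors are
#' caught and recorded in the `note` column; the grid never aborts wholesale.
#'
#' @param config An [mr_analysis_config()] object.
#' @return A tibble of class `mr_results` with columns `exposure`, `outcome`,
#'   `analysis`, `method`, the `mr_estimate` columns, `presso_global_p`,
#'   `n_outliers`, `or`/`or_conf.low`/`or_conf.high` (binary outcomes),
#'   `q_value`, `significance` and `note`; an audit tibble of every dropped
#'   instrument (with stage and reason) is attached as attribute `"audit"`.
#' @export
run_mr_grid <- function(config) {
  stopifnot(inherits(config, "mr_config"))
  audit <- list()
  note_audit <- function(df, exposure, outcome, analysis) {
    if (!is.null(df) && nrow(df) > 0) {
      df$exposure <- exposure; df$outcome <- outcome; df$analysis <- analysis
      audit[[length(audit) + 1]] <<- df
    }
  }
  rows <- list()
  for (exp_name in names(config$exposures)) {
    exp_spec <- config$exposures[[exp_name]]
    exp_data <- load_assoc(exp_spec$data, exp_spec$trait_type %||% "continuous")
    sel <- config$selection
    base_set <- select_instruments(
      exp_data, p_threshold = sel$p_threshold, ld = exp_spec$ld,
      r2_max = sel$r2_max, window_kb = sel$window_kb,
      exposure_name = exp_name
    )
    variants <- list(primary = base_set)
    for (ex_name in names(exp_spec$exclusions %||% list())) {
      ex <- exp_spec$exclusions[[ex_name]]
      filtered <- exclude_annotated(base_set, ex$annotation,
                                    p_cut = ex$p_cut %||% 0.001)
      note_audit(attr(filtered, "audit"), exp_name, NA_character_, ex_name)
      variants[[ex_name]] <- filtered
    }
    for (out_name in names(config$outcomes)) {
      out_spec <- config$outcomes[[out_name]]
      out_data <- load_assoc(out_spec$data,
                             out_spec$trait_type %||% "continuous")
      for (an_name in names(variants)) {
        inst <- variants[[an_name]]
        cell <- tryCatch({
          h <- harmonize(inst, out_data)
          note_audit(attr(h, "audit"), exp_name, out_name, an_name)
          oriented <- suppressWarnings(orient_exposure_increasing(h))
          dropped_zero <- setdiff(kept_instruments(h)$variant_id,
                                  kept_instruments(oriented)$variant_id)
          if (length(dropped_zero) > 0) {
            note_audit(tibble::tibble(
              variant_id = dropped_zero, stage = "orientation",
              reason = "exposure effect exactly 0"
            ), exp_name, out_name, an_name)
          }
          purrr::map(config$methods, function(m) {
            mseed <- cell_seed(config$seed, exp_name, out_name, an_name, m)
            row <- tryCatch(
              run_cell_method(m, oriented, mseed),
              error = function(e) empty_cell_row(m, nrow(oriented),
                                                 conditionMessage(e))
            )
            pr <- attr(row, "presso")
            if (!is.null(pr) && length(pr$outliers) > 0) {
              note_audit(tibble::tibble(
                variant_id = pr$outliers, stage = "presso",
                reason = "flagged as pleiotropic outlier"
              ), exp_name, out_name, an_name)
            }
            attr(row, "presso") <- NULL
            row
          })
        }, error = function(e) {
          list(empty_cell_row(config$methods[1], 0L, conditionMessage(e)))
        })
        for (row in cell) {
          row$exposure <- exp_name
          row$outcome <- out_name
          row$analysis <- an_name
          row$outcome_type <- out_spec$trait_type %||% "continuous"
          rows[[length(rows) + 1]] <- row
        }
      }
    }
  }
  res <- dplyr::bind_rows(rows)
  if (!"presso_global_p" %in% names(res)) res$presso_global_p <- NA_real_
  if (!"n_outliers" %in% names(res)) res$n_outliers <- NA_integer_
  res <- add_odds_scale(res)
  res$or[res$outcome_type != "binary"] <- NA_real_
  res$or_conf.low[res$outcome_type != "binary"] <- NA_real_
  res$or_conf.high[res$outcome_type != "binary"] <- NA_real_

  # FDR family: primary-method (IVW) tests within each analysis variant.
  res$q_value <- NA_real_
  res$significance <- NA_character_
  primary <- startsWith(res$method, "ivw") & !is.na(res$p.value)
  for (an in unique(res$analysis[primary])) {
    fam <- primary & res$analysis == an
    res$q_value[fam] <- bh_fdr(res$p.value[fam])
    res$significance[fam] <- dplyr::case_when(
      res$q_value[fam] < config$fdr_alpha ~ "fdr_significant",
      res$p.value[fam] < 0.05 ~ "nominal",
      TRUE ~ "null"
    )
  }
  res <- dplyr::relocate(res, "exposure", "outcome", "analysis", "method")
  attr(res, "audit") <- if (length(audit) > 0) dplyr::bind_rows(audit) else
    tibble::tibble(variant_id = character(0), stage = character(0),
                   reason = character(0), exposure = character(0),
                   outcome = character(0), analysis = character(0))
  attr(res, "config") <- config
  class(res) <- c("mr_results", class(res))
  res
}

#' Bidirectional Mendelian randomization
#'
#' Runs the forward analysis (exposure on outcome, genome-wide instrument
#' threshold) and the reverse analysis (former outcome as exposure, selecting
#' its instruments at the relaxed `reverse_p_threshold`, conventionally 1e-6
#' because disease GWAS yield few genome-wide hits), reporting both directions
#' side by side with the primary IVW method.
#'
#' @param exposure,outcome Lists with `data` (tibble or path), `trait_type`
#'   and optional `ld`, as in [mr_analysis_config()].
#' @param exposure_name,outcome_name Labels for the report.
#' @param selection Instrument-selection parameters for the forward direction
#'   (defaults as in [mr_analysis_config()]).
#' @param reverse_p_threshold Relaxed selection threshold for the reverse
#'   direction (default 1e-6).
#' @return A two-row tibble (forward, reverse) in the `mr_results` schema with
#'   a `direction` column; an unestimable reverse direction is flagged via
#'   `note`.
#' @export
mr_bidirectional <- function(exposure, outcome,
                             exposure_name = "exposure",
                             outcome_name = "outcome",
                             selection = list(),
                             reverse_p_threshold = 1e-6) {
  sel <- utils::modifyList(
    list(p_threshold = 5e-8, r2_max = 0.01, window_kb = 10000), selection
  )
  exp_data <- load_assoc(exposure$data, exposure$trait_type %||% "continuous")
  out_data <- load_assoc(outcome$data, outcome$trait_type %||% "continuous")
  one_direction <- function(from, to, from_ld, p_thr, label) {
    row <- tryCatch({
      inst <- select_instruments(from, p_threshold = p_thr, ld = from_ld,
                                 r2_max = sel$r2_max,
                                 window_kb = sel$window_kb)
      if (nrow(inst) < 2) {
        r <- empty_cell_row("ivw_multiplicative", nrow(inst),
                            "too few instruments at this threshold")
      } else {
        h <- suppressWarnings(orient_exposure_increasing(harmonize(inst, to)))
        r <- mr_ivw(h)
        r$note <- NA_character_
      }
      r
    }, error = function(e) {
      empty_cell_row("ivw_multiplicative", 0L, conditionMessage(e))
    })
    row$direction <- label
    row
  }
  fwd <- one_direction(exp_data, out_data, exposure$ld, sel$p_threshold,
                       "forward")
  rev <- one_direction(out_data, exp_data, outcome$ld, reverse_p_threshold,
                       "reverse")
  fwd$exposure <- exposure_name; fwd$outcome <- outcome_name
  rev$exposure <- outcome_name; rev$outcome <- exposure_name
  dplyr::relocate(dplyr::bind_rows(fwd, rev),
                  "direction", "exposure", "outcome", "method")
}

#' Write a results table to TSV
#'
#' @param results An `mr_results` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mr_results <- function(results, path) {
  readr::write_tsv(tibble::as_tibble(results), path, progress = FALSE)
  invisible(path)
}

#' Read a results table written by [write_mr_results()]
#'
#' @param path File path.
#' @return An `mr_results` tibble.
#' @export
read_mr_results <- function(path) {
  res <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      exposure = "c", outcome = "c", analysis = "c", method = "c",
      note = "c", significance = "c", outcome_type = "c", n_snp = "i"
    )
  )
  class(res) <- c("mr_results", class(res))
  res
}
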