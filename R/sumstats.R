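# Reading, validating and harmonizing GWAS summary statistics.

default_column_map <- function() {
  c(variant_id = "SNP", chrom = "CHR", pos = "POS",
    effect_allele = "EA", other_allele = "OA", eaf = "EAF",
    beta = "BETA", se = "SE", pvalue = "P", n = "N")
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited association file, renames columns through a
#' configurable map, upper-cases alleles, and validates every row against the
#' summary-statistic invariants (alleles in A/C/G/T and distinct, `se > 0`,
#' `pvalue` in (0, 1], `eaf` in \[0, 1\] when present). Rows failing validation
#' are dropped with a warning that lists their file row numbers; the dropped
#' rows are attached as the `"problems"` attribute.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping internal field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`) to the file's column names. Defaults to
#'   `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`. `chrom`, `pos`, `eaf` and
#'   `n` are optional; the rest must be present in the file.
#' @param trait_type `"continuous"` or `"binary"`; for binary traits `beta`
#'   is interpreted as a log odds ratio. Recorded as an attribute.
#' @param delim Field delimiter; guessed from the file extension and header
#'   line when `NULL`.
#' @return A tibble of validated associations, in file order, with columns
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n` and attributes `trait_type` and `problems`.
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               trait_type = c("continuous", "binary"),
                               delim = NULL) {
  trait_type <- match.arg(trait_type)
  map <- default_column_map()
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  if (is.null(delim)) {
    header <- readLines(path, n = 1)
    delim <- if (grepl("\t", header)) "\t"
             else if (grepl(",", header)) ","
             else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  required <- c("variant_id", "effect_allele", "other_allele",
                "beta", "se", "pvalue")
  missing_required <- required[!(map[required] %in% names(raw))]
  if (length(missing_required) > 0) {
    abort(sprintf(
      "column(s) mapped for %s not found in '%s': expected %s",
      paste(missing_required, collapse = ", "), path,
      paste(map[missing_required], collapse = ", ")
    ))
  }
  grab <- function(field, parser = identity) {
    col <- map[[field]]
    if (!is.null(col) && col %in% names(raw)) parser(raw[[col]])
    else rep(NA, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- tibble::tibble(
    variant_id = as.character(grab("variant_id")),
    chrom = as.character(grab("chrom")),
    pos = num(grab("pos")),
    effect_allele = toupper(as.character(grab("effect_allele"))),
    other_allele = toupper(as.character(grab("other_allele"))),
    eaf = num(grab("eaf")),
    beta = num(grab("beta")),
    se = num(grab("se")),
    pvalue = num(grab("pvalue")),
    n = num(grab("n"))
  )
  out <- validate_summary_stats(out, source = path)
  attr(out, "trait_type") <- trait_type
  out
}

# Row-level invariant checks; failing rows are removed and reported.
validate_summary_stats <- function(df, source = "summary statistics") {
  bad <- !is.na(df$variant_id) & FALSE
  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[cond & is.na(reason)] <<- why
    bad <<- bad | cond
  }
  flag(is.na(df$variant_id) | df$variant_id == "", "missing variant_id")
  flag(!(df$effect_allele %in% ALLELES), "effect_allele not in A/C/G/T")
  flag(!(df$other_allele %in% ALLELES), "other_allele not in A/C/G/T")
  flag(df$effect_allele == df$other_allele, "identical alleles")
  flag(is.na(df$beta), "unparseable beta")
  flag(is.na(df$se) | df$se <= 0, "se not a positive number")
  flag(is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1,
       "pvalue outside (0, 1]")
  flag(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "eaf outside [0, 1]")
  flag(!is.na(df$n) & df$n <= 0, "non-positive n")
  problems <- tibble::tibble(
    row = which(bad) + 1L,  # file row numbers (header is row 1)
    variant_id = df$variant_id[bad],
    reason = reason[bad]
  )
  if (nrow(problems) > 0) {
    warn(sprintf(
      "%d row(s) of %s failed validation and were dropped (file rows %s)",
      nrow(problems), source,
      paste(head(problems$row, 10), collapse = ", ")
    ))
  }
  out <- df[!bad, , drop = FALSE]
  attr(out, "problems") <- problems
  out
}

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Aligns per-variant exposure and outcome association estimates so both refer
#' to the same effect allele on the same strand. For each variant shared by
#' the two tables: an identical allele pair is kept as-is (`direct`); a
#' swapped pair has the outcome effect negated and its frequency complemented
#' (`flipped`); strand-complemented pairs are complemented before matching;
#' palindromic (A/T, G/C) pairs are resolved per `palindrome_policy`; any
#' other pair is `dropped_mismatch`. Dropped records stay in the output with
#' their `action` so the accounting is complete, and are excluded by every
#' estimator.
#'
#' @param exposure,outcome Association tibbles as returned by
#'   [read_summary_stats()] (columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue`, optionally `eaf`, `chrom`, `pos`).
#' @param palindrome_policy `"infer_by_frequency"` (default) aligns a
#'   palindromic variant only when both allele frequencies fall on the same
#'   side of 0.5 and both minor allele frequencies are below
#'   `maf_ambiguity_threshold`, otherwise drops it; `"drop_all"` drops every
#'   palindromic variant; `"keep_as_is"` trusts the reported allele labels.
#' @param maf_ambiguity_threshold Minor-allele-frequency bound below which a
#'   palindromic variant's strand can be inferred from frequency (default
#'   0.42).
#' @return A tibble of class `mr_harmonized` with one row per shared variant:
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `beta_exposure`, `se_exposure`, `pvalue_exposure`, `eaf_exposure`,
#'   `beta_outcome`, `se_outcome`, `pvalue_outcome`, `eaf_outcome`, `action`
#'   (one of `direct`, `flipped`, `frequency_inferred`, `dropped_palindromic`,
#'   `dropped_mismatch`). An audit tibble of dropped variants is attached as
#'   attribute `"audit"`.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer_by_frequency", "drop_all",
                                            "keep_as_is"),
                      maf_ambiguity_threshold = 0.42) {
  palindrome_policy <- match.arg(palindrome_policy)
  for (nm in c("variant_id", "effect_allele", "other_allele", "beta", "se")) {
    assert_columns(exposure, nm, "exposure")
    assert_columns(outcome, nm, "outcome")
  }
  opt_col <- function(df, col) if (col %in% names(df)) df[[col]] else NA
  x <- tibble::tibble(
    variant_id = exposure$variant_id,
    chrom = as.character(opt_col(exposure, "chrom")),
    pos = as.numeric(opt_col(exposure, "pos")),
    ea_x = toupper(exposure$effect_allele),
    oa_x = toupper(exposure$other_allele),
    beta_exposure = exposure$beta, se_exposure = exposure$se,
    pvalue_exposure = as.numeric(opt_col(exposure, "pvalue")),
    eaf_exposure = as.numeric(opt_col(exposure, "eaf"))
  )
  y <- tibble::tibble(
    variant_id = outcome$variant_id,
    ea_y = toupper(outcome$effect_allele),
    oa_y = toupper(outcome$other_allele),
    beta_outcome = outcome$beta, se_outcome = outcome$se,
    pvalue_outcome = as.numeric(opt_col(outcome, "pvalue")),
    eaf_outcome = as.numeric(opt_col(outcome, "eaf"))
  )
  h <- dplyr::inner_join(x, y, by = "variant_id")
  if (nrow(h) == 0) {
    abort("no shared variants between exposure and outcome summary statistics")
  }

  pal <- is_palindromic_pair(h$ea_x, h$oa_x)
  same <- h$ea_y == h$ea_x & h$oa_y == h$oa_x
  swap <- h$ea_y == h$oa_x & h$oa_y == h$ea_x
  csame <- complement_allele(h$ea_y) == h$ea_x &
    complement_allele(h$oa_y) == h$oa_x
  cswap <- complement_allele(h$ea_y) == h$oa_x &
    complement_allele(h$oa_y) == h$ea_x

  action <- rep("dropped_mismatch", nrow(h))
  flip <- rep(FALSE, nrow(h))

  # Non-palindromic: orientation is unambiguous (try strand complement before
  # declaring mismatch).
  np <- !pal
  action[np & (same | csame)] <- "direct"
  action[np & !same & !csame & (swap | cswap)] <- "flipped"
  flip[np & !same & !csame & (swap | cswap)] <- TRUE

  # Palindromic: label orientation is strand-ambiguous.
  if (any(pal)) {
    pal_match <- pal & (same | swap)   # allele set at least compatible
    action[pal & !pal_match] <- "dropped_mismatch"
    if (palindrome_policy == "drop_all") {
      action[pal_match] <- "dropped_palindromic"
    } else if (palindrome_policy == "keep_as_is") {
      action[pal_match & same] <- "direct"
      action[pal_match & swap] <- "flipped"
      flip[pal_match & swap] <- TRUE
    } else {
      # infer_by_frequency: first put the outcome on the exposure's labels,
      # then require both frequencies unambiguous and on the same side of 0.5.
      eaf_out_aligned <- ifelse(swap, 1 - h$eaf_outcome, h$eaf_outcome)
      maf_x <- pmin(h$eaf_exposure, 1 - h$eaf_exposure)
      maf_y <- pmin(eaf_out_aligned, 1 - eaf_out_aligned)
      have_freq <- !is.na(h$eaf_exposure) & !is.na(h$eaf_outcome)
      if (any(pal_match & !have_freq)) {
        warn(sprintf(
          "%d palindromic variant(s) lack eaf; dropped instead of inferred",
          sum(pal_match & !have_freq)
        ))
      }
      same_side <- (h$eaf_exposure - 0.5) * (eaf_out_aligned - 0.5) > 0
      unambiguous <- maf_x < maf_ambiguity_threshold &
        maf_y < maf_ambiguity_threshold
      ok <- pal_match & have_freq & !is.na(same_side) & same_side & unambiguous
      action[pal_match] <- "dropped_palindromic"
      action[ok] <- "frequency_inferred"
      flip[ok] <- swap[ok]
    }
  }

  h$beta_outcome <- ifelse(flip, -h$beta_outcome, h$beta_outcome)
  h$eaf_outcome <- ifelse(flip, 1 - h$eaf_outcome, h$eaf_outcome)
  h$action <- action

  out <- tibble::tibble(
    variant_id = h$variant_id, chrom = h$chrom, pos = h$pos,
    effect_allele = h$ea_x, other_allele = h$oa_x,
    beta_exposure = h$beta_exposure, se_exposure = h$se_exposure,
    pvalue_exposure = h$pvalue_exposure, eaf_exposure = h$eaf_exposure,
    beta_outcome = h$beta_outcome, se_outcome = h$se_outcome,
    pvalue_outcome = h$pvalue_outcome, eaf_outcome = h$eaf_outcome,
    action = h$action
  )
  dropped <- out[startsWith(out$action, "dropped"), ]
  attr(out, "audit") <- tibble::tibble(
    variant_id = dropped$variant_id,
    stage = "harmonization",
    reason = dropped$action
  )
  class(out) <- c("mr_harmonized", class(out))
  out
}

#' Orient instruments so every exposure effect is non-negative
#'
#' Flips the sign of both the exposure and the outcome effect (and swaps the
#' allele labels, complementing frequencies) wherever the exposure effect is
#' negative, leaving every Wald ratio unchanged. This is the conventional
#' orientation required for MR-Egger and the weighted median to be invariant
#' to which allele the input files call the effect allele. Variants with an
#' exposure effect of exactly zero are excluded with a warning.
#'
#' @param instruments A harmonized instrument tibble from [harmonize()].
#' @return The oriented tibble (dropped rows from harmonization are passed
#'   through untouched).
#' @export
orient_exposure_increasing <- function(instruments) {
  assert_columns(instruments, c("beta_exposure", "beta_outcome"),
                 "instrument table")
  keep_class <- class(instruments)
  act <- if ("action" %in% names(instruments)) instruments$action
         else rep("direct", nrow(instruments))
  live <- !startsWith(act, "dropped")
  zero <- live & instruments$beta_exposure == 0
  if (any(zero)) {
    warn(sprintf(
      "%d variant(s) with exposure effect exactly 0 excluded: %s",
      sum(zero),
      paste(head(instruments$variant_id[zero], 5), collapse = ", ")
    ))
    instruments <- instruments[!zero, , drop = FALSE]
    live <- live[!zero]
  }
  neg <- live & instruments$beta_exposure < 0
  instruments$beta_exposure[neg] <- -instruments$beta_exposure[neg]
  instruments$beta_outcome[neg] <- -instruments$beta_outcome[neg]
  if (all(c("effect_allele", "other_allele") %in% names(instruments))) {
    ea <- instruments$effect_allele[neg]
    instruments$effect_allele[neg] <- instruments$other_allele[neg]
    instruments$other_allele[neg] <- ea
  }
  for (col in c("eaf_exposure", "eaf_outcome")) {
    if (col %in% names(instruments)) {
      instruments[[col]][neg] <- 1 - instruments[[col]][neg]
    }
  }
  class(instruments) <- keep_class
  instruments
}

#' Write a harmonized instrument table to TSV
#'
#' @param instruments A harmonized tibble from [harmonize()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(instruments, path) {
  readr::write_tsv(tibble::as_tibble(instruments), path, progress = FALSE)
  invisible(path)
}
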