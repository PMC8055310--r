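# Independent oracles and fixture builders used across the suite. Every
# oracle is written directly from the definition it checks and stays
# independent of the package's implementation path.

# Build a harmonized-format instrument tibble from raw effect vectors.
make_instruments <- function(g, sg, G, sG, ids = NULL) {
  tibble::tibble(
    variant_id = ids %||% sprintf("v%03d", seq_along(g)),
    beta_exposure = g, se_exposure = sg,
    beta_outcome = G, se_outcome = sG,
    action = "direct"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Precision-weighted-mean oracle for fixed-effect IVW on Wald ratios with
# first-order simple weights.
oracle_ivw_fixed <- function(g, sg, G, sG) {
  ratio <- G / g
  w <- (abs(g) / sG)^2
  sum(w * ratio) / sum(w)
}

# Step-by-step greedy clumping trace: rank by (p, chrom, pos, id); retain the
# top candidate; discard same-chromosome candidates within the window whose
# r2 with it exceeds the cap; repeat. Written as an explicit trace loop.
oracle_clump <- function(candidates, ld_pairs, r2_max, window_kb) {
  df <- candidates[order(candidates$pvalue, candidates$chrom, candidates$pos,
                         candidates$variant_id), ]
  r2_of <- function(a, b) {
    hit <- (ld_pairs$id_a == a & ld_pairs$id_b == b) |
      (ld_pairs$id_a == b & ld_pairs$id_b == a)
    if (any(hit)) max(ld_pairs$r2[hit]) else 0
  }
  kept <- character(0)
  while (nrow(df) > 0) {
    top <- df[1, ]
    kept <- c(kept, top$variant_id)
    df <- df[-1, , drop = FALSE]
    if (nrow(df) > 0) {
      drop <- df$chrom == top$chrom &
        abs(df$pos - top$pos) <= window_kb * 1000 &
        vapply(df$variant_id, function(v) r2_of(top$variant_id, v),
               numeric(1)) > r2_max
      df <- df[!drop, , drop = FALSE]
    }
  }
  kept
}

# Hand-stepped Benjamini-Hochberg: q_i = min over j >= rank(i) of p_(j)*m/j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Brute-force percentile oracle for the weighted median: walk the sorted
# ratios accumulating weight; interpolate the ratio where the centered
# cumulative weight crosses one half.
oracle_weighted_median <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  pos <- cw - w / (2 * sum(w))
  if (pos[1] >= 0.5) return(r[1])
  if (pos[length(r)] <= 0.5) return(r[length(r)])
  i <- max(which(pos < 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - pos[i]) / (pos[i + 1] - pos[i])
}

# Write a summary-statistics tibble to a temporary TSV in the default column
# dialect and return the path.
write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  out <- data.frame(
    SNP = df$variant_id, CHR = df$chrom, POS = df$pos,
    EA = df$effect_allele, OA = df$other_allele, EAF = df$eaf,
    BETA = df$beta, SE = df$se, P = df$pvalue, N = df$n
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
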