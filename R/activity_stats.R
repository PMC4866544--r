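#' Per-replicate normalized log activity ratio
#'
#' The per-replicate statistic for comparing two constructs is the natural
#' log of the RT-minus-subtracted RNA tag-count ratio, normalized by the
#' DNA-input ratio of the same two constructs:
#'
#' \deqn{ln\left(\frac{(d_{RT+} - d_{RT-}) / (a_{RT+} - a_{RT-})}
#'                    {d_{DNA} / a_{DNA}}\right)}
#'
#' Subtracting the RT- counts removes plasmid-DNA carryover from the RNA
#' measurement; dividing by the DNA ratio corrects for unequal molar ratios
#' of the two plasmids in the transfected cells.  A replicate in which a
#' background-subtracted RNA count is not positive, or a DNA count is zero,
#' has no defined log ratio and is marked invalid rather than floored.
#'
#' All arguments are vectorized over replicates.
#'
#' @param d_rtplus,d_rtminus RT+ and RT- tag counts for the derived allele
#'   (or, in [negcontrol_log_ratio()], the focal construct).
#' @param a_rtplus,a_rtminus RT+ and RT- tag counts for the ancestral allele
#'   (or the negative control).
#' @param d_dna,a_dna DNA-input tag counts for the two constructs.
#' @return A `data.frame` with columns `value` (finite iff valid), `valid`,
#'   and `invalid_reason` (`"none"`, `"nonpositive_after_subtraction"`,
#'   `"zero_denominator"`).
#' @export
replicate_log_ratio <- function(d_rtplus, d_rtminus, a_rtplus, a_rtminus,
                                d_dna, a_dna) {
  n <- length(d_rtplus)
  args <- list(d_rtplus, d_rtminus, a_rtplus, a_rtminus, d_dna, a_dna)
  if (any(vapply(args, length, integer(1)) != n))
    stop("all six count vectors must have equal length")
  if (any(unlist(args) < 0, na.rm = TRUE))
    stop("negative counts are not allowed")
  num <- d_rtplus - d_rtminus
  den <- a_rtplus - a_rtminus
  reason <- rep("none", n)
  reason[num <= 0 | den <= 0] <- "nonpositive_after_subtraction"
  reason[d_dna == 0 | a_dna == 0] <- "zero_denominator"
  valid <- reason == "none"
  value <- rep(NA_real_, n)
  value[valid] <- log((num[valid] / den[valid]) /
                        (d_dna[valid] / a_dna[valid]))
  data.frame(value = value, valid = valid, invalid_reason = reason,
             stringsAsFactors = FALSE)
}

#' Per-replicate log ratio of a construct over the negative control
#'
#' Identical computation to [replicate_log_ratio()] with the focal
#' construct's counts in the numerator role and the insert-less negative
#' control's counts in the denominator role; measures activity relative to
#' the bare minimal promoter.
#'
#' @param v_rtplus,v_rtminus,v_dna Counts for the focal construct.
#' @param n_rtplus,n_rtminus,n_dna Counts for the negative control.
#' @return As [replicate_log_ratio()].
#' @export
negcontrol_log_ratio <- function(v_rtplus, v_rtminus, n_rtplus, n_rtminus,
                                 v_dna, n_dna) {
  replicate_log_ratio(v_rtplus, v_rtminus, n_rtplus, n_rtminus, v_dna, n_dna)
}

#' Robust replicate quality control
#'
#' Operationalizes the exclusion of replicates whose counts for a construct
#' are unusually high in the RT- sample or unusually low in the RT+ sample
#' compared with all other replicates.  Counts are first depth-normalized by
#' the supplied per-replicate totals; replicate *r* is then excluded when
#' its normalized RT- count exceeds `median + k * mad` of the remaining
#' replicates, or its normalized RT+ count falls below `median - k * mad` of
#' the remaining replicates (one-sided each, leave-one-out).  `mad` is the
#' scaled median absolute deviation ([stats::mad()], consistency constant
#' 1.4826).
#'
#' The recommended normalizer is the DNA-channel sample total of the same
#' replicate: the DNA library is unaffected by reverse-transcription or
#' carryover pathologies, so replicate-wide failures (a blown-up RT- library
#' or a collapsed RT+ library) remain visible after normalization, which
#' they would not if each channel were divided by its own total.
#'
#' @param rtplus,rtminus Per-replicate raw counts for one construct in one
#'   cell line (equal length, order = replicate 1..R).
#' @param totals_rtplus,totals_rtminus Per-replicate normalizing totals for
#'   the two channels (default 1 = counts are already normalized).
#' @param k Robustness constant (default 3).
#' @param external_exclusions Integer vector of replicate indices excluded
#'   unconditionally (e.g. an exclusion list curated by eye).
#' @return A `data.frame` with columns `replicate`, `excluded`, `reason`
#'   (`"none"`, `"high_rtminus"`, `"low_rtplus"`, `"external"`).
#' @export
qc_flag_replicates <- function(rtplus, rtminus,
                               totals_rtplus = 1, totals_rtminus = 1,
                               k = 3, external_exclusions = integer(0)) {
  R <- length(rtplus)
  if (length(rtminus) != R)
    stop("rtplus and rtminus must have equal length")
  x_plus <- rtplus / totals_rtplus
  x_minus <- rtminus / totals_rtminus
  reason <- rep("none", R)
  if (R >= 4) {
    for (r in seq_len(R)) {
      others_m <- x_minus[-r]
      others_p <- x_plus[-r]
      if (x_minus[r] > stats::median(others_m) + k * stats::mad(others_m)) {
        reason[r] <- "high_rtminus"
      } else if (x_plus[r] <
                 stats::median(others_p) - k * stats::mad(others_p)) {
        reason[r] <- "low_rtplus"
      }
    }
  } else {
    warning("fewer than 4 replicates: automatic QC flagging disabled")
  }
  reason[external_exclusions] <- "external"
  data.frame(replicate = seq_len(R), excluded = reason != "none",
             reason = reason, stringsAsFactors = FALSE)
}

#' One-sample t-test of mean zero
#'
#' Two-sided one-sample t-test of the null hypothesis that the mean equals
#' zero, as applied to the per-replicate log ratios.  Degenerate inputs are
#' handled explicitly: with fewer than 2 values the result is flagged
#' untestable; with zero standard deviation the p-value is 0 (mean != 0) or
#' 1 (mean == 0), with a degeneracy flag.
#'
#' @param values Numeric vector of finite values.
#' @return A list with `t`, `df`, `p`, `mean`, `n`, `testable`, `degenerate`.
#' @export
one_sample_t_test <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean = if (n == 1) values else NA_real_, n = n,
                testable = FALSE, degenerate = FALSE))
  m <- mean(values)
  s <- stats::sd(values)
  df <- n - 1
  if (s == 0) {
    return(list(t = if (m == 0) 0 else sign(m) * Inf, df = df,
                p = if (m == 0) 1 else 0, mean = m, n = n,
                testable = TRUE, degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean = m, n = n, testable = TRUE,
       degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; `NA` p-values are passed through
#' as `NA` and do not count toward the family size.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Signed fold change
#'
#' Converts a mean natural-log ratio to the signed fold-change scale used
#' for reporting: `exp(m)` for increases and `-exp(-m)` for decreases, so
#' the scale has no values between +1 and -1 and both +1 and -1 mean no
#' difference.
#'
#' @param mean_log_ratio Numeric vector of mean log ratios.
#' @return Numeric vector with `|value| >= 1` (sign matches the log ratio;
#'   +1 at zero).
#' @export
signed_fold_change <- function(mean_log_ratio) {
  ifelse(mean_log_ratio >= 0, exp(mean_log_ratio), -exp(-mean_log_ratio))
}

#' Pairwise Pearson correlations of mean ratios across cell lines
#'
#' @param mean_ratios Numeric matrix, variants x cell lines, of mean log
#'   ratios (`NA` allowed for untestable variants).
#' @param min_overlap Minimum number of variants with valid means in both
#'   members of a pair (default 3); pairs below it are flagged.
#' @return A `data.frame` with columns `cell_line_a`, `cell_line_b`, `R`,
#'   `n` and `flag` (`"ok"`, `"insufficient_overlap"`, `"zero_variance"`).
#' @export
cell_line_correlations <- function(mean_ratios, min_overlap = 3) {
  cl <- colnames(mean_ratios)
  if (is.null(cl)) cl <- paste0("cell_line_", seq_len(ncol(mean_ratios)))
  pairs <- utils::combn(seq_along(cl), 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    x <- mean_ratios[, a]; y <- mean_ratios[, b]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < min_overlap) {
      R <- NA_real_; flag <- "insufficient_overlap"
    } else if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      R <- NA_real_; flag <- "zero_variance"
    } else {
      R <- stats::cor(x[ok], y[ok], method = "pearson"); flag <- "ok"
    }
    data.frame(cell_line_a = cl[a], cell_line_b = cl[b], R = R, n = n,
               flag = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify variants by significance pattern
#'
#' Summarizes the per-cell-line test results for each variant: in how many
#' cell lines the derived-vs-ancestral ratio is significant (and in which
#' direction), and in how many cell lines either allele differs
#' significantly from the negative control (positive direction =
#' enhancer-like, negative = repressor-like).
#'
#' @param results_da Derived-vs-ancestral results table (one row per
#'   variant x cell line) with columns `variant_id`, `cell_line`,
#'   `mean_log_ratio`, `significant`.
#' @param results_nc Variant-vs-negative-control results with columns
#'   `variant_id`, `allele_state`, `cell_line`, `mean_log_ratio`,
#'   `significant`.
#' @return One row per variant: `n_cell_lines_da_significant`,
#'   `da_directions` (comma-joined `cell_line:up/down`),
#'   `n_cell_lines_enhancer`, `n_cell_lines_repressor`.
#' @export
classify_variants <- function(results_da, results_nc) {
  variants <- unique(c(results_da$variant_id, results_nc$variant_id))
  rows <- lapply(variants, function(v) {
    da <- results_da[results_da$variant_id == v & results_da$significant %in% TRUE, ]
    nc <- results_nc[results_nc$variant_id == v & results_nc$significant %in% TRUE, ]
    dirs <- if (nrow(da) > 0)
      paste0(da$cell_line, ":", ifelse(da$mean_log_ratio > 0, "up", "down"),
             collapse = ",") else ""
    data.frame(
      variant_id = v,
      n_cell_lines_da_significant = length(unique(da$cell_line)),
      da_directions = dirs,
      n_cell_lines_enhancer =
        length(unique(nc$cell_line[nc$mean_log_ratio > 0])),
      n_cell_lines_repressor =
        length(unique(nc$cell_line[nc$mean_log_ratio < 0])),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
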