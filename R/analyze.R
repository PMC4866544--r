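#' Full activity analysis from construct-level counts
#'
#' Runs the complete statistical chain for one experiment: replicate quality
#' control, per-replicate background-subtracted DNA-normalized log ratios
#' (derived vs ancestral, and each allele vs the negative control),
#' one-sample t-tests per variant and cell line, Benjamini-Hochberg
#' correction within each cell line, signed fold changes, cross-cell-line
#' Pearson correlations, and a per-variant classification.
#'
#' @param agg_counts Construct-aggregated count table with columns
#'   `cell_line`, `replicate`, `assay` (`RTplus`/`RTminus`/`DNA`),
#'   `construct_id`, `count`.
#' @param constructs Construct table from [build_constructs()] (or the
#'   simulator); used to pair alleles and find the negative control.
#' @param alpha Significance threshold on the BH-adjusted q-value
#'   (default 0.05).
#' @param qc_k Robustness constant for [qc_flag_replicates()] (default 3).
#' @param exclusions Optional external exclusion table with columns
#'   `cell_line`, `replicate` and optionally `construct_id` (`NA` or absent
#'   column = all constructs of that replicate).
#' @param bh_family `"separate"` (default): the derived-vs-ancestral tests
#'   and the vs-negative-control tests are corrected as separate families
#'   within each cell line; `"combined"`: one family per cell line.
#' @param qc Apply automatic replicate QC (default `TRUE`).
#' @return A list of class `mpra_analysis` with elements
#'   `replicate_ratios`, `qc_flags`, `results_da`, `results_nc`,
#'   `correlations`, `classification`, and the options used.
#' @export
analyze_activity <- function(agg_counts, constructs, alpha = 0.05, qc_k = 3,
                             exclusions = NULL,
                             bh_family = c("separate", "combined"),
                             qc = TRUE) {
  bh_family <- match.arg(bh_family)
  stopifnot(alpha > 0, alpha < 1)
  check_complete_samples(agg_counts)

  neg_id <- constructs$construct_id[constructs$kind == "negative_control"]
  if (length(neg_id) != 1)
    stop("constructs must contain exactly one negative_control")
  vc <- constructs[constructs$kind == "variant_allele", ]
  variants <- unique(vc$variant_id)

  cell_lines <- sort(unique(agg_counts$cell_line))
  per_cl <- lapply(cell_lines, function(cl)
    analyze_cell_line(agg_counts[agg_counts$cell_line == cl, ], cl,
                      vc, neg_id, variants, qc_k, exclusions, qc))

  replicate_ratios <- do.call(rbind, lapply(per_cl, `[[`, "replicate_ratios"))
  qc_flags <- do.call(rbind, lapply(per_cl, `[[`, "qc_flags"))
  results_da <- do.call(rbind, lapply(per_cl, `[[`, "results_da"))
  results_nc <- do.call(rbind, lapply(per_cl, `[[`, "results_nc"))

  # BH within each cell line; family composition per `bh_family`
  results_da$q_value <- NA_real_
  results_nc$q_value <- NA_real_
  for (cl in cell_lines) {
    ida <- which(results_da$cell_line == cl)
    inc <- which(results_nc$cell_line == cl)
    if (bh_family == "separate") {
      results_da$q_value[ida] <- bh_adjust(results_da$p_value[ida])
      results_nc$q_value[inc] <- bh_adjust(results_nc$p_value[inc])
    } else {
      q <- bh_adjust(c(results_da$p_value[ida], results_nc$p_value[inc]))
      results_da$q_value[ida] <- q[seq_along(ida)]
      results_nc$q_value[inc] <- q[length(ida) + seq_along(inc)]
    }
  }
  results_da$significant <- results_da$q_value < alpha
  results_nc$significant <- results_nc$q_value < alpha
  results_da$signed_fold_change <- signed_fold_change(results_da$mean_log_ratio)
  results_nc$signed_fold_change <- signed_fold_change(results_nc$mean_log_ratio)

  mean_mat <- matrix(NA_real_, nrow = length(variants),
                     ncol = length(cell_lines),
                     dimnames = list(variants, cell_lines))
  for (i in seq_len(nrow(results_da)))
    mean_mat[results_da$variant_id[i], results_da$cell_line[i]] <-
      results_da$mean_log_ratio[i]

  out <- list(
    replicate_ratios = replicate_ratios,
    qc_flags = qc_flags,
    results_da = results_da,
    results_nc = results_nc,
    mean_log_ratio_matrix = mean_mat,
    correlations = if (length(cell_lines) >= 2)
      cell_line_correlations(mean_mat) else NULL,
    classification = classify_variants(results_da, results_nc),
    options = list(alpha = alpha, qc_k = qc_k, bh_family = bh_family, qc = qc)
  )
  class(out) <- "mpra_analysis"
  out
}

# every (cell line, replicate) must have all three assays
check_complete_samples <- function(agg_counts) {
  need <- c("cell_line", "replicate", "assay", "construct_id", "count")
  missing <- setdiff(need, names(agg_counts))
  if (length(missing) > 0)
    stop("count table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(agg_counts$count < 0)) stop("negative counts are not allowed")
  tab <- unique(agg_counts[c("cell_line", "replicate", "assay")])
  wide <- table(paste(tab$cell_line, tab$replicate, sep = "/"), tab$assay)
  for (a in ASSAYS) {
    if (!a %in% colnames(wide) || any(wide[, a] == 0)) {
      bad <- if (a %in% colnames(wide))
        rownames(wide)[wide[, a] == 0] else rownames(wide)
      stop("missing ", a, " sample for: ", paste(bad, collapse = ", "))
    }
  }
  invisible(TRUE)
}

analyze_cell_line <- function(counts, cl, vc, neg_id, variants, qc_k,
                              exclusions, qc) {
  reps <- sort(unique(counts$replicate))
  R <- length(reps)
  cons <- sort(unique(counts$construct_id))
  mats <- lapply(ASSAYS, function(a) {
    sub <- counts[counts$assay == a, ]
    m <- matrix(0, nrow = length(cons), ncol = R,
                dimnames = list(cons, as.character(reps)))
    m[cbind(match(sub$construct_id, cons), match(sub$replicate, reps))] <-
      sub$count
    m
  })
  names(mats) <- ASSAYS
  dna_totals <- colSums(mats$DNA)

  # external exclusions for this cell line: list of (construct or NA, rep)
  ext_all <- integer(0)          # replicate indices excluded for everything
  ext_per <- list()              # construct_id -> replicate indices
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    ex <- exclusions[exclusions$cell_line == cl, , drop = FALSE]
    has_con <- "construct_id" %in% names(ex)
    for (i in seq_len(nrow(ex))) {
      r <- match(ex$replicate[i], reps)
      if (is.na(r)) next
      cid <- if (has_con) ex$construct_id[i] else NA_character_
      if (is.na(cid)) ext_all <- union(ext_all, r)
      else ext_per[[cid]] <- union(ext_per[[cid]], r)
    }
  }

  # QC per construct: normalized by the replicate's DNA sample total
  qc_rows <- vector("list", length(cons))
  excluded <- matrix(FALSE, nrow = length(cons), ncol = R,
                     dimnames = list(cons, as.character(reps)))
  for (i in seq_along(cons)) {
    extern <- union(ext_all, ext_per[[cons[i]]])
    if (qc) {
      fl <- qc_flag_replicates(mats$RTplus[i, ], mats$RTminus[i, ],
                               totals_rtplus = dna_totals,
                               totals_rtminus = dna_totals,
                               k = qc_k, external_exclusions = extern)
    } else {
      fl <- data.frame(replicate = seq_len(R), excluded = FALSE,
                       reason = "none", stringsAsFactors = FALSE)
      fl$excluded[extern] <- TRUE
      fl$reason[extern] <- "external"
    }
    excluded[i, ] <- fl$excluded
    qc_rows[[i]] <- data.frame(cell_line = cl, construct_id = cons[i],
                               replicate = reps, excluded = fl$excluded,
                               reason = fl$reason, stringsAsFactors = FALSE)
  }
  qc_flags <- do.call(rbind, qc_rows)

  ratio_rows <- list()
  res_da <- list()
  res_nc <- list()

  ratios_for <- function(num_id, den_id, label_id, comparison, extra = NULL) {
    lr <- replicate_log_ratio(mats$RTplus[num_id, ], mats$RTminus[num_id, ],
                              mats$RTplus[den_id, ], mats$RTminus[den_id, ],
                              mats$DNA[num_id, ], mats$DNA[den_id, ])
    qc_bad <- excluded[num_id, ] | excluded[den_id, ]
    lr$valid <- lr$valid & !qc_bad
    lr$invalid_reason[qc_bad] <- "qc_excluded"
    lr$value[qc_bad] <- NA_real_
    row <- data.frame(id = label_id, cell_line = cl, replicate = reps,
                      comparison = comparison, value = lr$value,
                      valid = lr$valid, invalid_reason = lr$invalid_reason,
                      stringsAsFactors = FALSE)
    tt <- one_sample_t_test(lr$value[lr$valid])
    list(rows = row,
         res = cbind(data.frame(cell_line = cl,
                                n_valid_replicates = tt$n,
                                mean_log_ratio = tt$mean, t_statistic = tt$t,
                                degrees_of_freedom = tt$df, p_value = tt$p,
                                testable = tt$testable,
                                stringsAsFactors = FALSE), extra))
  }

  for (v in variants) {
    d_id <- vc$construct_id[vc$variant_id == v & vc$allele_state == "derived"]
    a_id <- vc$construct_id[vc$variant_id == v & vc$allele_state == "ancestral"]
    if (!all(c(d_id, a_id) %in% cons)) next
    r <- ratios_for(d_id, a_id, v, "derived_vs_ancestral",
                    extra = data.frame(variant_id = v))
    ratio_rows[[length(ratio_rows) + 1]] <- r$rows
    res_da[[length(res_da) + 1]] <- r$res
    for (st in c("ancestral", "derived")) {
      c_id <- vc$construct_id[vc$variant_id == v & vc$allele_state == st]
      rn <- ratios_for(c_id, neg_id, c_id, "variant_vs_negcontrol",
                       extra = data.frame(variant_id = v, allele_state = st,
                                          construct_id = c_id))
      ratio_rows[[length(ratio_rows) + 1]] <- rn$rows
      res_nc[[length(res_nc) + 1]] <- rn$res
    }
  }

  reorder <- function(df, first) df[, c(first, setdiff(names(df), first))]
  list(replicate_ratios = do.call(rbind, ratio_rows),
       qc_flags = qc_flags,
       results_da = reorder(do.call(rbind, res_da), "variant_id"),
       results_nc = reorder(do.call(rbind, res_nc),
                            c("variant_id", "allele_state", "construct_id")))
}

#' @export
print.mpra_analysis <- function(x, ...) {
  cat("MPRA activity analysis\n")
  cat("  cell lines:", paste(unique(x$results_da$cell_line), collapse = ", "),
      "\n")
  cat("  variants:  ", length(unique(x$results_da$variant_id)), "\n")
  nsig <- sum(x$results_da$significant, na.rm = TRUE)
  cat("  significant derived-vs-ancestral calls (q <",
      x$options$alpha, "):", nsig, "\n")
  nsn <- sum(x$results_nc$significant, na.rm = TRUE)
  cat("  significant vs-negative-control calls:", nsn, "\n")
  invisible(x)
}

#' Write the analysis result tables as TSVs
#'
#' @param analysis An `mpra_analysis` object.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- list(replicate_log_ratios = analysis$replicate_ratios,
               qc_flags = analysis$qc_flags,
               results_derived_vs_ancestral = analysis$results_da,
               results_vs_negcontrol = analysis$results_nc,
               correlations = analysis$correlations,
               classification = analysis$classification)
  paths <- character(0)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tabs[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
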