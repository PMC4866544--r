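#' Read a variant-library table
#'
#' Reads the TSV that describes the TFBS allele pairs assayed by the
#' experiment.  Each row is one variable site with its ancestral and derived
#' allele and 25 nt of flanking sequence on each side; the reporter insert
#' for an allele is `flank5 + allele + flank3`.
#'
#' @param path Path to a tab-separated file with header columns
#'   `variant_id`, `chrom`, `pos`, `ancestral`, `derived`, `flank5`,
#'   `flank3`, `tf_name`.  `pos` is the 1-based genomic position of the
#'   variable site; allele strings are reported on the plus strand.  Indels
#'   use a shared left anchor (e.g. ancestral `"AG"`, derived `"A"`), as in
#'   `chr2:9983591AG>A`.
#' @return A `data.frame` of class `variant_library`, one row per variant
#'   pair, row order preserved.
#' @seealso [write_variant_table()], [build_constructs()]
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  required <- c("variant_id", "chrom", "pos", "ancestral", "derived",
                "flank5", "flank3", "tf_name")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("variant table is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[required]
  df$pos <- suppressWarnings(as.integer(df$pos))
  validate_variant_library(df, source = path)
  class(df) <- c("variant_library", "data.frame")
  df
}

#' Write a variant-library table
#'
#' Inverse of [read_variant_table()]; the round trip is field-for-field exact.
#'
#' @param library A `variant_library` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(library, path) {
  validate_variant_library(library)
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_variant_library <- function(df, source = "variant library") {
  err <- function(row, msg)
    stop(sprintf("%s, row %d (%s): %s", source, row,
                 as.character(df$variant_id[row]), msg), call. = FALSE)
  if (nrow(df) == 0) stop(source, ": no variant rows", call. = FALSE)
  dup <- duplicated(df$variant_id)
  if (any(dup)) err(which(dup)[1], "duplicate variant_id")
  for (i in seq_len(nrow(df))) {
    for (col in c("flank5", "flank3")) {
      if (nchar(df[[col]][i]) != 25L)
        err(i, sprintf("%s must be exactly 25 nt (got %d)", col,
                       nchar(df[[col]][i])))
    }
    for (col in c("ancestral", "derived", "flank5", "flank3")) {
      if (!is_dna(df[[col]][i]) || nchar(df[[col]][i]) < 1L)
        err(i, sprintf("%s must be a non-empty A/C/G/T string", col))
    }
    if (df$ancestral[i] == df$derived[i])
      err(i, "ancestral and derived alleles are identical")
    if (is.na(df$pos[i]) || df$pos[i] < 1L)
      err(i, "pos must be a positive integer")
  }
  invisible(df)
}

is_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  grepl(pat, x)
}

#' Build the construct set for a variant library
#'
#' Expands each allele pair into two reporter constructs (insert =
#' `flank5 + allele + flank3`, 51 nt for SNVs) and appends the two controls:
#' a strong positive-control enhancer and the insert-less negative control
#' that defines baseline minimal-promoter activity.
#'
#' @param library A `variant_library` data frame.
#' @param positive_control_insert Insert sequence for the positive-control
#'   construct.  The default is a synthetic stand-in for a CMV-type enhancer
#'   (the analysis never uses the positive control statistically).
#' @return A `data.frame` with columns `construct_id`, `kind`
#'   (`variant_allele` / `positive_control` / `negative_control`),
#'   `variant_id`, `allele_state` (`ancestral` / `derived`, `NA` for
#'   controls) and `insert_sequence` (empty string for the negative
#'   control).  Construct ids are `<variant_id>:ancestral` etc.
#' @export
build_constructs <- function(library,
                             positive_control_insert = synthetic_cmv_insert()) {
  validate_variant_library(library)
  rows <- lapply(seq_len(nrow(library)), function(i) {
    v <- library[i, ]
    data.frame(
      construct_id = paste0(v$variant_id, ":", c("ancestral", "derived")),
      kind = "variant_allele",
      variant_id = v$variant_id,
      allele_state = c("ancestral", "derived"),
      insert_sequence = paste0(v$flank5, c(v$ancestral, v$derived), v$flank3),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(construct_id = c("positive_control", "negative_control"),
               kind = c("positive_control", "negative_control"),
               variant_id = NA_character_, allele_state = NA_character_,
               insert_sequence = c(positive_control_insert, ""),
               stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  nonempty <- out$insert_sequence[out$insert_sequence != ""]
  if (anyDuplicated(nonempty))
    warning("duplicate insert sequences across constructs; ",
            "sequence-based tag association will be ambiguous for these")
  out
}

# Fixed synthetic stand-in for the CMV positive-control enhancer insert
# (not the GenBank sequence; screened to be free of the cloning/tag anchor
# restriction sites so simulated reads stay well-formed).
synthetic_cmv_insert <- function() {
  paste0("ATTGACGTCAATGGGAGTTTGTTTTGGCACCAAAATCAACGGGACTTTCC",
         "AAAATGTCGTAACAACTCCGCCCCATTGACGCAAATGGGCGGTAGGCGTG")
}

#' Export construct inserts as FASTA
#'
#' One record per construct, id = `construct_id`.  The insert-less negative
#' control is skipped (FASTA cannot represent an empty sequence usefully).
#'
#' @param constructs Output of [build_constructs()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_construct_fasta <- function(constructs, path) {
  keep <- constructs$insert_sequence != ""
  seqs <- Biostrings::DNAStringSet(constructs$insert_sequence[keep])
  names(seqs) <- constructs$construct_id[keep]
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
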