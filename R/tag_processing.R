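#' Extract the 20-nt tag from reads
#'
#' Locates the 5' tag anchor `TCTAGATAG` (XbaI site + `TAG`) and returns the
#' 20 nt immediately following it, provided those 20 nt contain no `N` and
#' are immediately followed by the 3' anchor `GGCCGGCC` (FseI site).  Reads
#' in which the 5' anchor occurs more than once are treated as chimeric and
#' yield no tag.  Absence of a tag is a valid outcome, returned as `NA`.
#'
#' @param reads Character vector of pre-merged read sequences (A/C/G/T/N).
#' @return Character vector of the same length: the tag, or `NA` where no
#'   well-formed tag is present.
#' @export
extract_tag <- function(reads) {
  reads <- toupper(as.character(reads))
  out <- rep(NA_character_, length(reads))
  if (length(reads) == 0) return(out)
  hits <- gregexpr(TAG_ANCHOR_5, reads, fixed = TRUE)
  n_hits <- vapply(hits, function(h) if (h[1] == -1L) 0L else length(h),
                   integer(1))
  single <- which(n_hits == 1L)
  if (length(single) == 0) return(out)
  start <- vapply(hits[single], `[`, integer(1), 1L) + nchar(TAG_ANCHOR_5)
  tag <- substr(reads[single], start, start + TAG_LENGTH - 1L)
  after <- substr(reads[single], start + TAG_LENGTH,
                  start + TAG_LENGTH + nchar(TAG_ANCHOR_3) - 1L)
  ok <- nchar(tag) == TAG_LENGTH & is_dna(tag) & after == TAG_ANCHOR_3
  out[single[ok]] <- tag[ok]
  out
}

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]; qualities are
#' ignored.  Format is taken from the file extension (`.fq`/`.fastq` with
#' optional `.gz` read as FASTQ, anything else as FASTA).
#'
#' @param path Path to a FASTA or FASTQ file.
#' @return Character vector of read sequences.
#' @export
read_sequences <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  as.character(Biostrings::readDNAStringSet(path, format = fmt))
}

#' Associate tags with constructs from plasmid sequencing reads
#'
#' Each construct-sequencing read may contain both the regulatory insert and
#' the tag region.  The construct is identified by exact substring match of
#' its full insert sequence within the read; the insert-less negative
#' control is recognized by the adjacent cloning-site junction
#' (`negctrl_signature`).  A tag observed with exactly one construct in at
#' least `min_support` reads becomes a `unique` assignment; a tag observed
#' with two or more constructs is `ambiguous`; everything else is
#' `unassigned`.
#'
#' @param reads Character vector of pre-merged construct-sequencing reads.
#' @param constructs Construct table from [build_constructs()].
#' @param min_support Minimum number of concordant reads required for a
#'   `unique` assignment (default 2, suppressing chimeric/PCR singletons).
#' @param negctrl_signature Sequence identifying reads from the insert-less
#'   negative-control plasmid.  Vector-layout configuration, default the
#'   KpnI/NheI junction used by the simulator.
#' @return A `data.frame` with columns `tag`, `construct_id` (`NA` unless
#'   `status == "unique"`), `status` (`unique`/`ambiguous`/`unassigned`) and
#'   `support` (reads backing the call); one row per distinct tag.
#' @export
associate_tags <- function(reads, constructs, min_support = 2L,
                           negctrl_signature = NEGCTRL_SIGNATURE) {
  reads <- toupper(as.character(reads))
  tags <- extract_tag(reads)
  keep <- !is.na(tags)
  reads <- reads[keep]
  tags <- tags[keep]
  if (length(reads) == 0)
    stop("no reads with an extractable tag; cannot associate any construct")

  ids <- constructs$construct_id
  patterns <- constructs$insert_sequence
  patterns[constructs$kind == "negative_control"] <- negctrl_signature
  # match matrix: reads x constructs (52-ish constructs, vectorized per column)
  match_count <- integer(length(reads))
  match_id <- rep(NA_character_, length(reads))
  for (j in seq_along(ids)) {
    hit <- grepl(patterns[j], reads, fixed = TRUE)
    match_id[hit & match_count == 0L] <- ids[j]
    match_count <- match_count + hit
  }
  match_id[match_count > 1L] <- NA_character_  # multi-insert read

  res <- lapply(split(seq_along(tags), tags), function(idx) {
    cons <- unique(match_id[idx][!is.na(match_id[idx])])
    multi_read <- any(match_count[idx] > 1L)
    if (length(cons) >= 2L || multi_read) {
      list(construct_id = NA_character_, status = "ambiguous",
           support = length(idx))
    } else if (length(cons) == 1L) {
      support <- sum(match_id[idx] == cons, na.rm = TRUE)
      if (support >= min_support)
        list(construct_id = cons, status = "unique", support = support)
      else
        list(construct_id = NA_character_, status = "unassigned",
             support = support)
    } else {
      list(construct_id = NA_character_, status = "unassigned",
           support = length(idx))
    }
  })
  out <- data.frame(
    tag = names(res),
    construct_id = vapply(res, `[[`, character(1), "construct_id"),
    status = vapply(res, `[[`, character(1), "status"),
    support = vapply(res, function(r) as.integer(r$support), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  covered <- unique(out$construct_id[out$status == "unique"])
  orphan <- setdiff(ids, covered)
  if (length(orphan) > 0)
    stop("no unique tag recovered for construct(s): ",
         paste(orphan, collapse = ", "))
  out
}

#' Count whitelist tags in an assay sample
#'
#' Applies [extract_tag()] to every read and tallies exact occurrences of
#' the uniquely assigned (whitelist) tags.  Reads without a well-formed tag,
#' or whose tag is not on the whitelist, are counted as discards, so that
#' `sum(counts) + discards == length(reads)`.
#'
#' @param reads Character vector of assay reads.
#' @param assignments Tag assignment table from [associate_tags()]; only
#'   rows with `status == "unique"` form the whitelist.
#' @param cell_line,replicate,assay Sample metadata; `assay` must be one of
#'   `"RTplus"`, `"RTminus"`, `"DNA"`.
#' @return A `data.frame` (class `sample_counts`) with columns `cell_line`,
#'   `replicate`, `assay`, `tag`, `count` — one row per whitelist tag,
#'   including zero counts — with the number of discarded reads in
#'   `attr(, "discards")`.
#' @export
count_tags <- function(reads, assignments, cell_line, replicate, assay) {
  assay <- match.arg(assay, ASSAYS)
  whitelist <- assignments$tag[assignments$status == "unique"]
  tags <- extract_tag(reads)
  counted <- tags[!is.na(tags) & tags %in% whitelist]
  tab <- table(factor(counted, levels = whitelist))
  out <- data.frame(cell_line = cell_line,
                    replicate = as.integer(replicate),
                    assay = assay,
                    tag = whitelist,
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  attr(out, "discards") <- length(reads) - sum(out$count)
  class(out) <- c("sample_counts", "data.frame")
  out
}

#' Pool tag counts per construct
#'
#' Sums counts over all tags uniquely assigned to each construct; constructs
#' with no observed tags get an explicit 0.  Ambiguous and unassigned tags
#' never contribute.
#'
#' @param counts Tag-level count table (columns `cell_line`, `replicate`,
#'   `assay`, `tag`, `count`), e.g. from [count_tags()] or
#'   [read_sample_counts()]; may span many samples.
#' @param assignments Tag assignment table from [associate_tags()].
#' @param constructs Optional construct table; if supplied, every construct
#'   appears in the output for every sample present, with zero fill.
#' @return A `data.frame` with columns `cell_line`, `replicate`, `assay`,
#'   `construct_id`, `count`.
#' @export
aggregate_by_construct <- function(counts, assignments, constructs = NULL) {
  uni <- assignments[assignments$status == "unique", c("tag", "construct_id")]
  m <- merge(counts, uni, by = "tag")
  agg <- stats::aggregate(count ~ cell_line + replicate + assay + construct_id,
                          data = m, FUN = sum)
  if (!is.null(constructs)) {
    samples <- unique(counts[c("cell_line", "replicate", "assay")])
    full <- merge(samples, data.frame(construct_id = constructs$construct_id))
    agg <- merge(full, agg,
                 by = c("cell_line", "replicate", "assay", "construct_id"),
                 all.x = TRUE)
    agg$count[is.na(agg$count)] <- 0L
  }
  agg <- agg[order(agg$cell_line, agg$replicate, agg$assay, agg$construct_id), ]
  rownames(agg) <- NULL
  agg$count <- as.integer(agg$count)
  agg
}

#' Read / write tag or construct count tables
#'
#' The on-disk layout is a TSV with columns `cell_line`, `replicate`,
#' `assay`, then `tag` (tag level) or `construct_id` (construct level), then
#' `count`.  This is the layout the synthetic generator writes and the
#' statistics layer reads.
#'
#' @param path TSV path.
#' @param counts Count table to write.
#' @return `read_sample_counts`: the count `data.frame`;
#'   `write_sample_counts`: `path`, invisibly.
#' @export
read_sample_counts <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("cell_line", "replicate", "assay", "count")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0 || !any(c("tag", "construct_id") %in% names(df)))
    stop("count table ", path, " lacks required column(s): ",
         paste(c(missing,
                 if (!any(c("tag", "construct_id") %in% names(df)))
                   "tag|construct_id"), collapse = ", "))
  if (any(df$count < 0)) stop("negative counts in ", path)
  bad <- setdiff(unique(df$assay), ASSAYS)
  if (length(bad) > 0)
    stop("unknown assay value(s) in ", path, ": ", paste(bad, collapse = ", "))
  df$replicate <- as.integer(df$replicate)
  df$count <- as.integer(df$count)
  df
}

#' @rdname read_sample_counts
#' @export
write_sample_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write tag assignments as TSV
#'
#' @param assignments Output of [associate_tags()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tag_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tag_assignments
#' @param path Path to a tag-assignment TSV.
#' @return `read_tag_assignments`: the assignment `data.frame`.
#' @export
read_tag_assignments <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}
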