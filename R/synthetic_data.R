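# Fixed oligo-layout pieces used to assemble simulated reads.  OLIGO_5P /
# OLIGO_3P are the constant regions around the 20 random bases of the tag
# oligo (the 5' piece ends in the XbaI+TAG anchor, the 3' piece starts with
# the FseI anchor); SPACER is a neutral stretch between the cloning site and
# the tag cassette.
OLIGO_5P <- "AACCATAGGATTCGCGTCAGTCTAGATAG"
OLIGO_3P <- "GGCCGGCCGTCTGGCGTCTTGGCTAATC"
READ_SPACER <- "ATACGAAGTTATCACTG"

# Motifs that must not occur inside simulated inserts or tags: the cloning
# and tag-cassette restriction sites.  Real inserts cannot contain them
# either (the enzymes would cut them during cloning), so screening is
# faithfulness, not convenience.
FORBIDDEN_MOTIFS <- c("TCTAGA", "GGCCGGCC", "GGTACC", "GCTAGC")

has_forbidden_motif <- function(x) {
  out <- rep(FALSE, length(x))
  for (m in FORBIDDEN_MOTIFS) out <- out | grepl(m, x, fixed = TRUE)
  out
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# random DNA strings free of the forbidden motifs, resampling as needed
random_clean_dna <- function(n, len, max_tries = 1000L) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > max_tries) stop("could not generate motif-free sequences")
    cand <- random_dna(n - length(out), len)
    out <- c(out, cand[!has_forbidden_motif(cand)])
  }
  out
}

#' Simulation parameters
#'
#' Collects all knobs of the synthetic experiment with defaults matching the
#' emulated study design: 25 TFBS allele pairs, 3 neuronal cell lines, 10
#' transfection replicates, one 20-nt tag per construct, and sequencing
#' depths of 1e5 per sample.  See the methods vignette for the rationale
#' behind each noise default.
#'
#' @param n_variants Number of TFBS allele pairs (default 25).
#' @param cell_lines Character vector of cell-line labels (default
#'   `c("SH-SY5Y", "IMR-32", "NPC")`).
#' @param n_replicates Transfection replicates per cell line (default 10).
#' @param tags_per_construct Distinct tags per construct (default 1).
#' @param molar_ratio_dispersion Lognormal sigma of per-construct plasmid
#'   copy numbers around equimolar (default 0.4).
#' @param activity_ratios True derived/ancestral activity ratio per variant
#'   (recycled to `n_variants`; default 1 = null).
#' @param enhancer_strength Activity of the ancestral allele relative to the
#'   negative control baseline (recycled; default 2).
#' @param baseline_activity Transcripts per plasmid copy for the insert-less
#'   negative control (default 1).
#' @param positive_control_strength Activity multiple of the CMV-type
#'   positive control (default 20; never analyzed statistically).
#' @param carryover_fraction Fraction of plasmid DNA molecules surviving
#'   into the RT- channel, relative to baseline transcription (default
#'   0.05).
#' @param depth_rtplus,depth_rtminus,depth_dna Expected sequencing depth per
#'   sample; RT- depth is interpreted on the same molar scale as RT+, so the
#'   default `depth_rtminus = depth_rtplus` makes raw-count background
#'   subtraction unbiased, as the matched amplification of the two channels
#'   does in the real assay (defaults 1e5).
#' @param overdispersion Gamma shape of the per-construct, per-replicate
#'   multiplier on RNA rates (mean 1); smaller = noisier (default 20).
#' @param outlier_replicates Optional `data.frame` with columns `cell_line`,
#'   `replicate`, `mode` (`"high_rtminus"` / `"low_rtplus"`), `factor`;
#'   injects replicate-level channel failures.
#' @param assoc_reads_per_tag Construct-sequencing reads emitted per tag for
#'   association (default 20).
#' @param error_rate Uniform per-base substitution rate in simulated reads
#'   (default 0).
#' @param seed Integer seed; all outputs are bit-for-bit reproducible.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_variants = 25L,
                       cell_lines = c("SH-SY5Y", "IMR-32", "NPC"),
                       n_replicates = 10L,
                       tags_per_construct = 1L,
                       molar_ratio_dispersion = 0.4,
                       activity_ratios = 1,
                       enhancer_strength = 2,
                       baseline_activity = 1,
                       positive_control_strength = 20,
                       carryover_fraction = 0.05,
                       depth_rtplus = 1e5,
                       depth_rtminus = 1e5,
                       depth_dna = 1e5,
                       overdispersion = 20,
                       outlier_replicates = NULL,
                       assoc_reads_per_tag = 20L,
                       error_rate = 0,
                       seed = 1L) {
  p <- list(n_variants = as.integer(n_variants), cell_lines = cell_lines,
            n_replicates = as.integer(n_replicates),
            tags_per_construct = as.integer(tags_per_construct),
            molar_ratio_dispersion = molar_ratio_dispersion,
            activity_ratios = rep_len(activity_ratios, n_variants),
            enhancer_strength = rep_len(enhancer_strength, n_variants),
            baseline_activity = baseline_activity,
            positive_control_strength = positive_control_strength,
            carryover_fraction = carryover_fraction,
            depth_rtplus = depth_rtplus, depth_rtminus = depth_rtminus,
            depth_dna = depth_dna, overdispersion = overdispersion,
            outlier_replicates = outlier_replicates,
            assoc_reads_per_tag = as.integer(assoc_reads_per_tag),
            error_rate = error_rate, seed = as.integer(seed))
  stopifnot(p$n_variants >= 0, p$n_replicates >= 1,
            p$tags_per_construct >= 1,
            all(p$activity_ratios > 0),
            p$carryover_fraction >= 0, p$carryover_fraction <= 1,
            p$depth_rtplus > 0, p$depth_rtminus > 0, p$depth_dna > 0,
            p$overdispersion > 0, p$error_rate >= 0, p$error_rate < 1)
  class(p) <- "sim_params"
  p
}

#' Simulate a variant library with tags
#'
#' Generates `n_variants` SNV allele pairs with random 25-nt flanks, builds
#' the construct set (including both controls), and draws distinct random
#' 20-nt tags for every construct.  Flanks and tags are screened against the
#' cloning/tag restriction-site motifs (as real cloned inserts must be) so
#' that every simulated read carries exactly one well-formed tag cassette.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `mpra_sim` with elements `library` (variant
#'   table), `constructs`, and `tag_map` (tag, construct_id, status
#'   `"unique"`) — the ground-truth tag assignment.
#' @export
simulate_library <- function(params) {
  set.seed(params$seed)
  nv <- params$n_variants
  if (nv > 0) {
    chrom <- paste0("chr", sample(1:22, nv, replace = TRUE))
    pos <- sample(1e6:2e8, nv)
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, nv, replace = TRUE)
    der <- vapply(anc, function(b) sample(setdiff(bases, b), 1), character(1))
    flank5 <- flank3 <- character(nv)
    for (i in seq_len(nv)) {
      repeat {
        f5 <- random_clean_dna(1, 25)
        f3 <- random_clean_dna(1, 25)
        ins <- paste0(f5, c(anc[i], der[i]), f3)
        if (!any(has_forbidden_motif(ins))) { flank5[i] <- f5; flank3[i] <- f3; break }
      }
    }
    lib <- data.frame(
      variant_id = sprintf("%s:%d%s>%s", chrom, pos, anc, der),
      chrom = chrom, pos = pos, ancestral = anc, derived = der,
      flank5 = flank5, flank3 = flank3,
      tf_name = sprintf("TF%02d", seq_len(nv)),
      stringsAsFactors = FALSE)
    class(lib) <- c("variant_library", "data.frame")
    constructs <- build_constructs(lib)
  } else {
    lib <- NULL
    constructs <- data.frame(
      construct_id = c("positive_control", "negative_control"),
      kind = c("positive_control", "negative_control"),
      variant_id = NA_character_, allele_state = NA_character_,
      insert_sequence = c(synthetic_cmv_insert(), ""),
      stringsAsFactors = FALSE)
  }
  n_tags <- nrow(constructs) * params$tags_per_construct
  tags <- character(0)
  budget <- 50L
  while (length(tags) < n_tags && budget > 0L) {
    budget <- budget - 1L
    tags <- unique(c(tags, random_clean_dna(n_tags - length(tags), TAG_LENGTH)))
  }
  if (length(tags) < n_tags) stop("tag collision retry budget exhausted")
  tag_map <- data.frame(
    tag = tags,
    construct_id = rep(constructs$construct_id,
                       each = params$tags_per_construct),
    status = "unique", support = NA_integer_,
    stringsAsFactors = FALSE)
  out <- list(library = lib, constructs = constructs, tag_map = tag_map,
              params = params)
  class(out) <- "mpra_sim"
  out
}

#' Simulate RT+/RT-/DNA tag-count tables with known ground truth
#'
#' Emulates the DNA -> RNA -> sequencing chain per replicate: plasmid copy
#' numbers are lognormal around equimolar; DNA counts are multinomial in the
#' copy numbers; reporter RNA rates are `activity * copies` times a gamma
#' overdispersion multiplier, plus DNA carryover `kappa * copies`; the RT+
#' and RT- channels are Poisson on a common per-molecule scale fixed by the
#' RT+ depth, so that raw-count background subtraction is unbiased.
#' Injected outlier replicates multiply the targeted channel's rates by the
#' stated factor.
#'
#' @param sim Output of [simulate_library()].
#' @param params A [sim_params()] object (defaults to `sim$params`).
#' @return A list with `counts` (tag-level long table: `cell_line`,
#'   `replicate`, `assay`, `tag`, `count`) and `truth` (list: `rho` named by
#'   variant, `activity` named by construct, `copies` construct x replicate
#'   x cell-line array, `outliers`).
#' @export
simulate_counts <- function(sim, params = sim$params) {
  set.seed(params$seed + 1L)
  cons <- sim$constructs
  nc <- nrow(cons)
  kappa <- params$carryover_fraction

  activity <- numeric(nc)
  names(activity) <- cons$construct_id
  for (i in seq_len(nc)) {
    activity[i] <- switch(cons$kind[i],
      negative_control = params$baseline_activity,
      positive_control = params$baseline_activity *
        params$positive_control_strength,
      variant_allele = {
        v <- match(cons$variant_id[i], unique(cons$variant_id[
          cons$kind == "variant_allele"]))
        a <- params$baseline_activity * params$enhancer_strength[v]
        if (cons$allele_state[i] == "derived") a * params$activity_ratios[v]
        else a
      })
  }

  cls <- params$cell_lines
  R <- params$n_replicates
  copies <- array(NA_real_, dim = c(nc, R, length(cls)),
                  dimnames = list(cons$construct_id, NULL, cls))
  out_rows <- vector("list", length(cls) * R * 3L)
  k_out <- 0L
  ol <- params$outlier_replicates
  tag_map <- sim$tag_map

  for (ci in seq_along(cls)) {
    for (r in seq_len(R)) {
      cvec <- exp(stats::rnorm(nc, 0, params$molar_ratio_dispersion))
      copies[, r, ci] <- cvec
      dna <- as.integer(stats::rmultinom(1, params$depth_dna,
                                         prob = cvec / sum(cvec)))
      g <- stats::rgamma(nc, shape = params$overdispersion,
                         rate = params$overdispersion)
      rate_plus <- (activity + kappa * params$baseline_activity) * cvec * g
      rate_minus <- kappa * params$baseline_activity * cvec
      s <- params$depth_rtplus /
        sum((activity + kappa * params$baseline_activity) * cvec)
      f_minus <- params$depth_rtminus / params$depth_rtplus
      if (!is.null(ol) && nrow(ol) > 0) {
        hit <- ol[ol$cell_line == cls[ci] & ol$replicate == r, , drop = FALSE]
        for (j in seq_len(nrow(hit))) {
          if (hit$mode[j] == "high_rtminus")
            rate_minus <- rate_minus * hit$factor[j]
          else if (hit$mode[j] == "low_rtplus")
            rate_plus <- rate_plus / hit$factor[j]
          else stop("unknown outlier mode: ", hit$mode[j])
        }
      }
      rtplus <- stats::rpois(nc, s * rate_plus)
      rtminus <- stats::rpois(nc, s * f_minus * rate_minus)
      for (a in ASSAYS) {
        ccount <- switch(a, RTplus = rtplus, RTminus = rtminus, DNA = dna)
        tcount <- spread_to_tags(ccount, cons$construct_id, tag_map)
        k_out <- k_out + 1L
        out_rows[[k_out]] <- data.frame(
          cell_line = cls[ci], replicate = r, assay = a,
          tag = tag_map$tag, count = tcount, stringsAsFactors = FALSE)
      }
    }
  }
  counts <- do.call(rbind, out_rows)
  rho <- params$activity_ratios
  names(rho) <- unique(cons$variant_id[cons$kind == "variant_allele"])
  list(counts = counts,
       truth = list(rho = rho, activity = activity, copies = copies,
                    outliers = ol))
}

# split one construct's count uniformly among its tags
spread_to_tags <- function(ccount, construct_ids, tag_map) {
  idx <- split(seq_len(nrow(tag_map)), tag_map$construct_id)
  out <- integer(nrow(tag_map))
  for (i in seq_along(construct_ids)) {
    rows <- idx[[construct_ids[i]]]
    n <- ccount[i]
    if (length(rows) == 1L) out[rows] <- n
    else out[rows] <- as.integer(stats::rmultinom(
      1, n, prob = rep(1 / length(rows), length(rows))))
  }
  out
}

# assemble the full amplicon template for one construct + tag
read_template <- function(insert, tag) {
  read <- paste0(INSERT_SITE_5, insert, INSERT_SITE_3, READ_SPACER,
                 OLIGO_5P, tag, OLIGO_3P)
  stopifnot(identical(extract_tag(read), tag))
  read
}

#' Simulate assay reads from a count table
#'
#' Emits one read per counted tag occurrence, each assembled as cloning
#' site + insert + cloning site + spacer + tag cassette, optionally with
#' uniform per-base substitution errors.  With `error_rate = 0`, running
#' [count_tags()] on the reads of one sample reproduces that sample's count
#' table exactly.
#'
#' @param sim Output of [simulate_library()].
#' @param counts Tag-level count table for a single sample or several (the
#'   reads of all rows are concatenated in row order).
#' @param params A [sim_params()] object (defaults to `sim$params`);
#'   `error_rate` and `seed` are used.
#' @return Character vector of reads.
#' @export
simulate_reads <- function(sim, counts, params = sim$params) {
  set.seed(params$seed + 2L)
  tpl_map <- tag_templates(sim)
  counts <- counts[counts$count > 0, , drop = FALSE]
  reads <- rep(tpl_map[counts$tag], counts$count)
  names(reads) <- NULL
  apply_read_errors(reads, params$error_rate)
}

#' Simulate construct-sequencing (association) reads
#'
#' Emits `assoc_reads_per_tag` error-free copies of each tag's full
#' construct template, as input for [associate_tags()].
#'
#' @param sim Output of [simulate_library()].
#' @param params A [sim_params()] object (defaults to `sim$params`).
#' @return Character vector of reads.
#' @export
simulate_association_reads <- function(sim, params = sim$params) {
  set.seed(params$seed + 3L)
  tpl_map <- tag_templates(sim)
  reads <- rep(tpl_map, each = params$assoc_reads_per_tag)
  names(reads) <- NULL
  apply_read_errors(reads, 0)
}

tag_templates <- function(sim) {
  ins <- sim$constructs$insert_sequence[
    match(sim$tag_map$construct_id, sim$constructs$construct_id)]
  tpl <- vapply(seq_len(nrow(sim$tag_map)),
                function(i) read_template(ins[i], sim$tag_map$tag[i]),
                character(1))
  names(tpl) <- sim$tag_map$tag
  tpl
}

apply_read_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(rd) {
    ch <- strsplit(rd, "", fixed = TRUE)[[1]]
    hit <- stats::runif(length(ch)) < error_rate
    if (any(hit))
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1),
                        character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write a complete simulated dataset to disk
#'
#' Writes the variant table, construct FASTA, ground-truth tag map, tag
#' count table, association-read FASTA and a ground-truth TSV into `dir`.
#' Identical seeds produce byte-identical files.
#'
#' @param sim Output of [simulate_library()].
#' @param counts_truth Output of [simulate_counts()].
#' @param dir Output directory.
#' @param reads Also write per-dataset assay reads (can be large;
#'   default `FALSE`).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, counts_truth, dir, reads = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    variants = file.path(dir, "variants.tsv"),
    constructs = file.path(dir, "constructs.fasta"),
    tag_map = file.path(dir, "tag_map.tsv"),
    counts = file.path(dir, "tag_counts.tsv"),
    assoc_reads = file.path(dir, "association_reads.fasta"),
    truth = file.path(dir, "ground_truth.tsv"))
  if (!is.null(sim$library)) write_variant_table(sim$library, paths["variants"])
  write_construct_fasta(sim$constructs, paths["constructs"])
  write_tag_assignments(sim$tag_map, paths["tag_map"])
  write_sample_counts(counts_truth$counts, paths["counts"])
  assoc <- simulate_association_reads(sim)
  seqs <- Biostrings::DNAStringSet(assoc)
  names(seqs) <- sprintf("assoc_%06d", seq_along(assoc))
  Biostrings::writeXStringSet(seqs, paths["assoc_reads"])
  truth_df <- data.frame(variant_id = names(counts_truth$truth$rho),
                         true_activity_ratio = counts_truth$truth$rho)
  utils::write.table(truth_df, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (reads) {
    paths <- c(paths, assay_reads = file.path(dir, "assay_reads.fasta"))
    rd <- simulate_reads(sim, counts_truth$counts)
    seqs <- Biostrings::DNAStringSet(rd)
    names(seqs) <- sprintf("read_%08d", seq_along(rd))
    Biostrings::writeXStringSet(seqs, paths["assay_reads"])
  }
  invisible(paths)
}
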