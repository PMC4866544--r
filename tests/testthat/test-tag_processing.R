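test_that("extract_tag honours both anchors and rejects malformed reads", {
  set.seed(1)
  tag <- paste(rep("T", 20), collapse = "")
  read <- paste0("AACCATAGGATTCGCGTCAGTCTAGATAG", tag,
                 "GGCCGGCCGTCTGGCGTCTTGGCTAATC")
  expect_identical(extract_tag(read), tag)

  expect_identical(extract_tag("ACGTACGTACGTACGT"), NA_character_)   # no anchor
  # truncated 10 nt after the 5' anchor: 3'-anchor check fails
  trunc <- substr(read, 1, 29 + 10)
  expect_identical(extract_tag(trunc), NA_character_)
  # N inside the tag region
  readN <- read
  substr(readN, 35, 35) <- "N"
  expect_identical(extract_tag(readN), NA_character_)
  # two 5' anchors: chimeric, discarded
  expect_identical(extract_tag(paste0(read, read)), NA_character_)
  # vectorized, order-preserving
  expect_identical(extract_tag(c(read, "AAAA", read)),
                   c(tag, NA_character_, tag))
})

test_that("extract_tag agrees with the brute-force scanner on random reads", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  reads <- character(1000)
  for (i in seq_len(1000)) {
    tag <- paste(sample(bases, 20, replace = TRUE), collapse = "")
    r <- runif(1)
    reads[i] <- if (r < 0.5) {
      random_read_with_tag(tag)
    } else if (r < 0.7) {   # broken 3' anchor
      sub("GGCCGGCC", "GGCCGGCA", random_read_with_tag(tag), fixed = TRUE)
    } else if (r < 0.85) {  # random sequence, usually anchor-free
      paste(sample(bases, 80, replace = TRUE), collapse = "")
    } else {                # duplicated anchor region
      paste0(random_read_with_tag(tag), random_read_with_tag(tag))
    }
  }
  expect_identical(extract_tag(reads),
                   vapply(reads, oracle_extract_tag, character(1),
                          USE.NAMES = FALSE))
})

make_assoc_fixture <- function(n_reads_per_tag = 5) {
  cons <- build_constructs(tiny_library())
  tags <- c("ACGTACGTACGTACGTACGA", "TGCATGCATGCATGCATGCC",
            "AAAACCCCGGGGTTTTACGG", "GATCGATCGATCGATCGATC",
            "CCGGAATTCCGGAATTAAGG", "TTGGCCAATTGGCCAATTAA",
            "ACACACACGTGTGTGTACAC", "AGAGAGAGTCTCTCTCAGAG")
  stopifnot(length(tags) == nrow(cons))
  ins <- cons$insert_sequence
  ins[cons$kind == "negative_control"] <- NA  # handled via signature
  reads <- unlist(lapply(seq_len(nrow(cons)), function(i) {
    body <- if (is.na(ins[i])) "GGTACCGCTAGC" else
      paste0("GGTACC", ins[i], "GCTAGC")
    rep(paste0(body, "ATACG", "TCTAGATAG", tags[i], "GGCCGGCC", "TTACG"),
        n_reads_per_tag)
  }))
  list(constructs = cons, tags = tags, reads = reads)
}

test_that("associate_tags recovers a clean tag-construct truth exactly", {
  fx <- make_assoc_fixture()
  asn <- associate_tags(fx$reads, fx$constructs)
  expect_equal(nrow(asn), length(fx$tags))
  expect_true(all(asn$status == "unique"))
  expect_equal(asn$construct_id[match(fx$tags, asn$tag)],
               fx$constructs$construct_id)
  expect_true(all(asn$support == 5))
})

test_that("associate_tags flags ambiguous and low-support tags", {
  fx <- make_assoc_fixture()
  cons <- fx$constructs
  # tag 1 also observed with construct 2's insert -> ambiguous; construct 1
  # keeps a second unique tag so it stays covered
  conflict <- paste0("GGTACC", cons$insert_sequence[2], "GCTAGC",
                     "ATACG", "TCTAGATAG", fx$tags[1], "GGCCGGCC")
  spare <- paste0("GGTACC", cons$insert_sequence[1], "GCTAGC",
                  "ATACG", "TCTAGATAG", "ACGTAACCGGTTACGTTGCA", "GGCCGGCC")
  asn <- associate_tags(c(fx$reads, rep(conflict, 5), rep(spare, 5)), cons)
  row <- asn[asn$tag == fx$tags[1], ]
  expect_equal(row$status, "ambiguous")
  expect_true(is.na(row$construct_id))

  # a singleton tag stays unassigned under min_support = 2
  single <- paste0("GGTACC", cons$insert_sequence[1], "GCTAGC", "ATACG",
                   "TCTAGATAG", "GGGGGGGGGGGGGGGGGGGG", "GGCCGGCC")
  asn2 <- associate_tags(c(fx$reads, single), cons, min_support = 2)
  expect_equal(asn2$status[asn2$tag == "GGGGGGGGGGGGGGGGGGGG"], "unassigned")

  # reads with an insert matching no construct -> unassigned
  orphan <- paste0("GGTACC", paste(rep("ACGGT", 10), collapse = ""), "GCTAGC",
                   "TCTAGATAG", "CCCCCCCCCCCCCCCCCCCC", "GGCCGGCC")
  asn3 <- associate_tags(c(fx$reads, rep(orphan, 4)), cons)
  expect_equal(asn3$status[asn3$tag == "CCCCCCCCCCCCCCCCCCCC"], "unassigned")

  # losing every read for one construct is a pipeline-level error
  keep <- !grepl(cons$insert_sequence[1], fx$reads, fixed = TRUE)
  expect_error(associate_tags(fx$reads[keep], cons),
               cons$construct_id[1], fixed = TRUE)
})

test_that("count_tags counts exact whitelist tags and conserves reads", {
  fx <- make_assoc_fixture()
  asn <- associate_tags(fx$reads, fx$constructs)
  X <- fx$tags[1]; Y <- fx$tags[2]
  set.seed(3)
  reads <- c(replicate(3, random_read_with_tag(X)),
             replicate(2, random_read_with_tag(Y)),
             "ACGTACGT")                                  # no tag
  mm <- sub("^(.)", ifelse(substr(X, 1, 1) == "A", "C", "A"), X)
  reads <- c(reads, random_read_with_tag(mm))             # 1-mismatch variant
  sc <- count_tags(reads, asn, "SH-SY5Y", 1, "RTplus")
  expect_s3_class(sc, "sample_counts")
  expect_equal(sc$count[sc$tag == X], 3)
  expect_equal(sc$count[sc$tag == Y], 2)
  expect_equal(sum(sc$count) + attr(sc, "discards"), length(reads))
  expect_equal(attr(sc, "discards"), 2)                   # no-tag + mismatch
  expect_error(count_tags(reads, asn, "x", 1, "RNA"))     # bad assay enum
})

test_that("aggregate_by_construct pools unique tags and conserves totals", {
  fx <- make_assoc_fixture()
  cons <- fx$constructs
  asn <- associate_tags(fx$reads, cons)
  counts <- data.frame(cell_line = "A", replicate = 1L, assay = "RTplus",
                       tag = fx$tags, count = seq_along(fx$tags))
  agg <- aggregate_by_construct(counts, asn, cons)
  expect_equal(sum(agg$count), sum(counts$count))
  expect_equal(nrow(agg), nrow(cons))
  # a two-tag construct pools by summation
  asn2 <- asn
  asn2$construct_id[asn2$tag == fx$tags[2]] <-
    asn2$construct_id[asn2$tag == fx$tags[1]]
  agg2 <- aggregate_by_construct(counts, asn2, cons)
  target <- asn$construct_id[asn$tag == fx$tags[1]]
  expect_equal(agg2$count[agg2$construct_id == target], 1 + 2)
  # ambiguous tags never contribute
  asn3 <- asn
  asn3$status[asn3$tag == fx$tags[1]] <- "ambiguous"
  asn3$construct_id[asn3$tag == fx$tags[1]] <- NA
  agg3 <- aggregate_by_construct(counts, asn3, cons)
  expect_equal(sum(agg3$count), sum(counts$count) - 1)
  expect_equal(agg3$count[agg3$construct_id == target], 0)
})

test_that("count tables round-trip through TSV, FASTA and FASTQ read", {
  fx <- make_assoc_fixture()
  asn <- associate_tags(fx$reads, fx$constructs)
  sc <- count_tags(fx$reads, asn, "IMR-32", 2, "DNA")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_counts(sc, path)
  back <- read_sample_counts(path)
  expect_equal(back$count, sc$count)
  expect_equal(back$assay, sc$assay)

  fa <- withr::local_tempfile(fileext = ".fasta")
  seqs <- Biostrings::DNAStringSet(fx$reads[1:4])
  names(seqs) <- paste0("r", 1:4)
  Biostrings::writeXStringSet(seqs, fa)
  expect_identical(read_sequences(fa), setNames(fx$reads[1:4], paste0("r", 1:4)))

  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(paste0("@r", 1:4), fx$reads[1:4], "+",
                             vapply(nchar(fx$reads[1:4]),
                                    function(n) strrep("I", n), ""))), fq)
  expect_identical(unname(read_sequences(fq)), fx$reads[1:4])
})
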