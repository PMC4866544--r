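# Fixture builders shared across test files.  Everything is generated in
# code; no data files.

# deterministic miniature variant library (2 SNVs + 1 indel)
tiny_library <- function() {
  f <- function(seed) {
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")
  }
  df <- data.frame(
    variant_id = c("chr10:118707481G>C", "chr2:9983591AG>A",
                   "chr8:53608138C>G"),
    chrom = c("chr10", "chr2", "chr8"),
    pos = c(118707481L, 9983591L, 53608138L),
    ancestral = c("G", "AG", "C"),
    derived = c("C", "A", "G"),
    flank5 = c(f(101), f(102), f(103)),
    flank3 = c(f(201), f(202), f(203)),
    tf_name = c("AP-1", "KLF11", "AP-1"),
    stringsAsFactors = FALSE)
  class(df) <- c("variant_library", "data.frame")
  df
}

# brute-force quadratic substring-scan oracle for extract_tag
oracle_extract_tag <- function(read) {
  read <- toupper(read)
  a5 <- "TCTAGATAG"; a3 <- "GGCCGGCC"
  n <- nchar(read)
  pos <- integer(0)
  for (i in seq_len(max(0, n - nchar(a5) + 1)))
    if (substr(read, i, i + nchar(a5) - 1) == a5) pos <- c(pos, i)
  if (length(pos) != 1) return(NA_character_)
  s <- pos + nchar(a5)
  tag <- substr(read, s, s + 19)
  after <- substr(read, s + 20, s + 20 + nchar(a3) - 1)
  if (nchar(tag) == 20 && grepl("^[ACGT]{20}$", tag) && after == a3) tag
  else NA_character_
}

# direct-arithmetic oracle for the normalized log ratio
oracle_log_ratio <- function(dp, dm, ap, am, dd, ad) {
  rna <- (dp - dm) / (ap - am)
  dna <- dd / ad
  log(rna / dna)
}

# hand step-up BH oracle: sort ascending, q_(i) = min_{j >= i} m * p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  vals <- m * p[o] / seq_len(m)
  q_sorted <- pmin(1, rev(cummin(rev(vals))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

random_read_with_tag <- function(tag, prefix_len = 30, suffix_len = 20) {
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  paste0(rand(prefix_len), "TCTAGATAG", tag, "GGCCGGCC", rand(suffix_len))
}
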