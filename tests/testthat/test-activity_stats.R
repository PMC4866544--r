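test_that("replicate_log_ratio matches direct arithmetic and flags invalids", {
  # perfect symmetry -> 0
  expect_equal(replicate_log_ratio(110, 10, 110, 10, 50, 50)$value, 0)
  # frozen oracle value: ln((300/100) / (40/40)) = ln 3
  r <- replicate_log_ratio(310, 10, 110, 10, 40, 40)
  expect_equal(r$value, log(3), tolerance = 1e-12)
  expect_true(r$valid)
  # nonpositive after subtraction
  r <- replicate_log_ratio(15, 20, 110, 10, 40, 40)
  expect_false(r$valid)
  expect_equal(r$invalid_reason, "nonpositive_after_subtraction")
  expect_true(is.na(r$value))
  # zero DNA denominator (either side)
  expect_equal(replicate_log_ratio(310, 10, 110, 10, 40, 0)$invalid_reason,
               "zero_denominator")
  expect_equal(negcontrol_log_ratio(210, 10, 110, 10, 30, 0)$invalid_reason,
               "zero_denominator")
  # negative raw counts violate the contract
  expect_error(replicate_log_ratio(-1, 0, 10, 0, 5, 5), "negative")
  # negcontrol variant: frozen ln 2 example and identity at equal counts
  expect_equal(negcontrol_log_ratio(210, 10, 110, 10, 30, 30)$value,
               log(2), tolerance = 1e-12)
  expect_equal(negcontrol_log_ratio(110, 10, 110, 10, 30, 30)$value, 0)
})

test_that("log ratio: oracle equivalence, antisymmetry, depth invariance", {
  set.seed(99)
  n <- 2000
  dp <- rpois(n, 300); dm <- rpois(n, 20)
  ap <- rpois(n, 250); am <- rpois(n, 15)
  dd <- rpois(n, 100) + 1L; ad <- rpois(n, 100) + 1L
  r <- replicate_log_ratio(dp, dm, ap, am, dd, ad)
  ok <- r$valid
  expect_true(mean(ok) > 0.95)
  expect_equal(r$value[ok],
               oracle_log_ratio(dp, dm, ap, am, dd, ad)[ok],
               tolerance = 1e-12)
  # antisymmetry: swapping d and a roles negates the value
  swapped <- replicate_log_ratio(ap, am, dp, dm, ad, dd)
  expect_equal(swapped$value[ok & swapped$valid],
               -r$value[ok & swapped$valid], tolerance = 1e-12)
  # depth invariance, exact for power-of-two scaling
  r2 <- replicate_log_ratio(4 * dp, 4 * dm, 4 * ap, 4 * am, dd, ad)
  expect_identical(r2$value[ok], r$value[ok])
  r3 <- replicate_log_ratio(dp, dm, ap, am, 8 * dd, 8 * ad)
  expect_identical(r3$value[ok], r$value[ok])
  # and to 1e-12 for arbitrary scaling
  r4 <- replicate_log_ratio(3 * dp, 3 * dm, 3 * ap, 3 * am, 7 * dd, 7 * ad)
  expect_equal(r4$value[ok], r$value[ok], tolerance = 1e-12)
})

test_that("qc_flag_replicates applies one-sided leave-one-out median/MAD", {
  # identical replicates: nothing excluded
  fl <- qc_flag_replicates(rep(100, 10), rep(5, 10))
  expect_false(any(fl$excluded))

  # one blown-up RT- replicate among ten
  rtminus <- c(rep(0.001, 5), 0.05, rep(0.001, 4)) * 1000
  fl <- qc_flag_replicates(rep(100, 10), rtminus)
  expect_identical(which(fl$excluded), 6L)
  expect_equal(fl$reason[6], "high_rtminus")
  # ... and the rule is one-sided: an unusually LOW RT- is fine
  fl <- qc_flag_replicates(rep(100, 10), c(rep(10, 9), 0))
  expect_false(any(fl$excluded))

  # one collapsed RT+ replicate
  jitter <- c(99, 101, 100, 98, 102, 100, 99, 101, 10, 100)
  fl <- qc_flag_replicates(jitter, rep(5, 10))
  expect_identical(which(fl$excluded), 9L)
  expect_equal(fl$reason[9], "low_rtplus")
  # one-sided: unusually HIGH RT+ is fine
  fl <- qc_flag_replicates(c(99, 101, 100, 98, 102, 100, 99, 101, 1000, 100),
                           rep(5, 10))
  expect_false(any(fl$excluded))

  # external exclusions pass through unconditionally
  fl <- qc_flag_replicates(rep(100, 10), rep(5, 10),
                           external_exclusions = 7L)
  expect_identical(which(fl$excluded), 7L)
  expect_equal(fl$reason[7], "external")

  # normalizing totals change the verdict
  tot <- c(rep(1, 9), 10)  # replicate 10's depth was 10x: counts comparable
  fl <- qc_flag_replicates(c(rep(100, 9), 1000), c(rep(5, 9), 50),
                           totals_rtplus = tot, totals_rtminus = tot)
  expect_false(any(fl$excluded))

  # fewer than 4 replicates: no automatic flagging, warning
  expect_warning(fl <- qc_flag_replicates(c(1, 1, 100), c(1, 1, 1)),
                 "fewer than 4")
  expect_false(any(fl$excluded))
})

test_that("one_sample_t_test matches closed form, t.test, and edge contract", {
  # frozen example: (0.5, 1.5) -> t = 2, df = 1, p = 1 - 2*atan(2)/pi
  r <- one_sample_t_test(c(0.5, 1.5))
  expect_equal(r$t, 2)
  expect_equal(r$df, 1)
  expect_equal(r$p, 1 - 2 * atan(2) / pi, tolerance = 1e-12)

  # agreement with the reference implementation on random vectors
  set.seed(7)
  for (n in c(3, 5, 10)) {
    x <- rnorm(n, 0.3, 1)
    r <- one_sample_t_test(x)
    tt <- t.test(x)
    expect_equal(r$t, unname(tt$statistic))
    expect_equal(r$p, tt$p.value)
    expect_equal(r$df, unname(tt$parameter))
    # sign flip flips t, preserves p
    rf <- one_sample_t_test(-x)
    expect_equal(rf$t, -r$t)
    expect_equal(rf$p, r$p)
  }

  # degenerate inputs
  expect_equal(one_sample_t_test(rep(0, 5))$p, 1)
  z <- one_sample_t_test(rep(2, 5))
  expect_equal(z$p, 0)
  expect_true(z$degenerate)
  expect_false(one_sample_t_test(c(1))$testable)
  expect_false(one_sample_t_test(numeric(0))$testable)
})

test_that("bh_adjust matches the hand step-up oracle and preserves order", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(numeric(0)), "empty")

  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
  }
})

test_that("signed_fold_change maps log ratios onto the gapped fold scale", {
  expect_equal(signed_fold_change(0), 1)
  expect_equal(signed_fold_change(log(0.38)), -1 / 0.38, tolerance = 1e-12)
  expect_equal(round(signed_fold_change(log(0.38)), 2), -2.63)
  expect_equal(signed_fold_change(log(1.8)), 1.8, tolerance = 1e-12)
  set.seed(2)
  m <- rnorm(100)
  fc <- signed_fold_change(m)
  expect_true(all(abs(fc) >= 1))
  expect_true(all(sign(fc[m != 0]) == sign(m[m != 0])))
  expect_equal(signed_fold_change(-m), -fc, tolerance = 1e-12)
})

test_that("cell_line_correlations computes pairwise Pearson with flags", {
  m <- cbind(A = c(1, 2, 3), B = c(1, 2, 3), C = -c(1, 2, 3))
  out <- cell_line_correlations(m)
  expect_equal(out$R[out$cell_line_a == "A" & out$cell_line_b == "B"], 1)
  expect_equal(out$R[out$cell_line_a == "A" & out$cell_line_b == "C"], -1)

  # frozen hand-computed Pearson for (1,2,3) vs (1,2,4)
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  m2 <- cbind(A = x, B = y)
  expect_equal(cell_line_correlations(m2)$R, num / den, tolerance = 1e-12)
  expect_equal(round(cell_line_correlations(m2)$R, 4), 0.982)

  # insufficient overlap and zero variance are flagged, not errors
  m3 <- cbind(A = c(1, 2, NA), B = c(1, NA, 3))
  expect_equal(cell_line_correlations(m3)$flag, "insufficient_overlap")
  m4 <- cbind(A = c(1, 1, 1), B = c(1, 2, 3))
  expect_equal(cell_line_correlations(m4)$flag, "zero_variance")
})

test_that("classify_variants counts cell lines by significance and direction", {
  da <- data.frame(
    variant_id = rep(c("v1", "v2", "v3"), each = 3),
    cell_line = rep(c("A", "B", "C"), 3),
    mean_log_ratio = c(1, 1, 1, -1, 1, 0.2, 0.1, 0.1, 0.1),
    significant = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, rep(FALSE, 3)))
  nc <- data.frame(
    variant_id = rep(c("v1", "v2", "v3"), each = 6),
    allele_state = rep(c("ancestral", "derived"), 9),
    cell_line = rep(rep(c("A", "B", "C"), each = 2), 3),
    mean_log_ratio = c(rep(2, 6), -0.5, 2, -0.5, 0.3, 0.3, 0.3,
                       rep(0.1, 6)),
    significant = c(rep(TRUE, 6), TRUE, FALSE, TRUE, FALSE, FALSE, FALSE,
                    rep(FALSE, 6)))
  cls <- classify_variants(da, nc)
  v1 <- cls[cls$variant_id == "v1", ]
  expect_equal(v1$n_cell_lines_da_significant, 2)
  expect_match(v1$da_directions, "A:up,B:up")
  expect_equal(v1$n_cell_lines_enhancer, 3)   # both alleles up, 3 lines
  expect_equal(v1$n_cell_lines_repressor, 0)
  v2 <- cls[cls$variant_id == "v2", ]
  expect_equal(v2$n_cell_lines_da_significant, 1)
  expect_match(v2$da_directions, "A:down")
  expect_equal(v2$n_cell_lines_repressor, 2)  # ancestral down in A and B
  v3 <- cls[cls$variant_id == "v3", ]
  expect_equal(v3$n_cell_lines_da_significant, 0)
  expect_equal(v3$n_cell_lines_enhancer + v3$n_cell_lines_repressor, 0)
})
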