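test_that("exact substrings align perfectly on either strand", {
  ref <- make_reference(500, 0.5, seed = 1)
  q <- substr(ref$bases, 101, 200)
  a <- align_read(q, ref, min_span = 50)
  expect_true(a$aligned)
  expect_equal(a$identity, 1)
  expect_identical(a$ref_start, 100L)
  expect_identical(a$ref_end, 200L)
  expect_identical(a$strand, "+")
  expect_identical(a$matches, 100L)
  expect_identical(a$mismatches + a$insertions + a$deletions, 0L)

  a2 <- align_read(poredose:::revcomp(q), ref, min_span = 50)
  expect_true(a2$aligned)
  expect_equal(a2$identity, 1)
  expect_identical(a2$strand, "-")
  expect_identical(a2$ref_start, 100L)
  expect_identical(a2$ref_end, 200L)

  expect_error(align_read("", ref), "non-empty")
})

test_that("aligner identity equals the exhaustive DP oracle on random pairs", {
  set.seed(42)
  for (i in 1:60) {
    q <- random_seq(sample(5:50, 1))
    r <- new_ref <- poredose:::new_reference("r", random_seq(sample(30:60, 1)))
    a <- align_read(q, r, min_identity = 0, min_span = 1)
    expect_equal(a$identity, oracle_identity(q, r$bases), tolerance = 1e-12)
    # the reported counts reproduce the reported identity
    expect_equal(a$identity, a$matches /
                   (a$matches + a$mismatches + a$insertions + a$deletions))
  }
})

test_that("banded seeded alignment works on large references", {
  ref <- make_reference(30000, 0.5, seed = 3)
  # a noisy slice: substitutions plus a deletion
  q <- substr(ref$bases, 5001, 6000)
  qc <- strsplit(q, "")[[1]]
  set.seed(7)
  mut <- sample(1000, 60)
  qc[mut] <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  q <- paste(qc[-c(200, 500)], collapse = "")
  a <- align_read(q, ref)
  expect_true(a$aligned)
  expect_gt(a$identity, 0.9)
  expect_lt(abs(a$ref_start - 5000), 10)
  expect_lt(abs(a$ref_end - 6000), 10)
  expect_identical(a$strand, "+")

  # a foreign sequence finds no credible seed cluster
  set.seed(8)
  f <- align_read(random_seq(300), ref)
  expect_false(f$aligned)
  expect_true(is.na(f$identity))
})

test_that("reverse-complementing the query flips strand and preserves identity", {
  ref <- make_reference(800, 0.5, seed = 4)
  set.seed(9)
  for (i in 1:10) {
    s <- sample(700, 1)
    q <- substr(ref$bases, s, s + 59)
    qc <- strsplit(q, "")[[1]]
    qc[sample(60, 3)] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
    q <- paste(qc, collapse = "")
    a <- align_read(q, ref, min_span = 30)
    b <- align_read(poredose:::revcomp(q), ref, min_span = 30)
    expect_equal(a$identity, b$identity, tolerance = 1e-12)
    expect_false(identical(a$strand, b$strand))
  }
})

test_that("alignment summaries and acceptance gates behave as specified", {
  ref <- make_reference(500, 0.5, seed = 1)
  set.seed(10)
  qs <- c(a = substr(ref$bases, 1, 120), b = substr(ref$bases, 101, 230),
          c = substr(ref$bases, 201, 340), d = random_seq(50))
  res <- align_reads(qs, ref)  # read d fails the 100-base span gate
  expect_identical(sum(res$aligned), 3L)
  s <- summarize_alignments(res)
  expect_equal(s$pct_reads_aligned, 75)
  expect_equal(s$mean_identity, 100)

  s0 <- summarize_alignments(res[0, ])
  expect_true(is.na(s0$pct_reads_aligned))
  expect_true(is.na(s0$mean_identity))

  # identity is reported even when the span gate fails
  short <- align_read(substr(ref$bases, 11, 60), ref, min_span = 100)
  expect_false(short$aligned)
  expect_equal(short$identity, 1)
})

test_that("coverage maps count depth exactly and flag completeness", {
  ref_len <- 100L
  rows <- data.frame(
    read_id = c("a", "b"), aligned = TRUE,
    ref_start = c(0L, 40L), ref_end = c(60L, 100L), strand = "+",
    matches = 1L, mismatches = 0L, insertions = 0L, deletions = 0L,
    identity = 1)
  cm <- coverage_map(rows, ref_len)
  expect_identical(cm$depth[41:60], rep(2L, 20))
  expect_identical(cm$depth[c(1:40, 61:100)], rep(1L, 80))
  expect_true(cm$complete)
  expect_identical(sum(cm$depth), 120L)

  full <- coverage_map(data.frame(aligned = TRUE, ref_start = 0L,
                                  ref_end = 100L), ref_len)
  expect_identical(unique(full$depth), 1L)
  expect_true(full$complete)

  none <- coverage_map(rows[0, ], ref_len)
  expect_identical(sum(none$depth), 0L)
  expect_false(none$complete)

  bad <- rows
  bad$ref_end[2] <- 101L
  expect_error(coverage_map(bad, ref_len), "out of reference bounds")
})

test_that("coverage conserves aligned span totals on a simulated bundle", {
  ref <- make_reference(4000, 0.5, seed = 6)
  b <- simulate_run(ref, build_pore_model(5, seed = 1), tiny_config(rate = 0.15),
                    degradation_params(), dose = 50, seed = 12)
  aln <- align_reads(b, ref)
  cm <- coverage_map(aln, ref$length)
  expect_identical(sum(cm$depth),
                   sum(aln$ref_end[aln$aligned] - aln$ref_start[aln$aligned]))
})
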