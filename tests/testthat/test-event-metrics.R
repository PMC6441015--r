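test_that("per-read metrics match hand-counted move streams", {
  m <- read_metrics(events_from_moves(c(0, 1, 1, 1, 1, 1)))
  expect_identical(m$read_length, 10L)
  expect_identical(m$n_skips, 0L)
  expect_identical(m$n_stays, 0L)

  m <- read_metrics(events_from_moves(c(0, 1, 1, 0, 2, 1)))
  expect_identical(m$read_length, 10L)
  expect_identical(m$n_stays, 1L)
  expect_identical(m$n_skips, 1L)
  expect_equal(m$skips_per_base, 0.1)
  expect_equal(m$stays_per_base, 0.1)
  expect_identical(m$n_events, 6L)

  # degenerate single-event read: just the initial k-mer
  m <- read_metrics(events_from_moves(0))
  expect_identical(m$read_length, 5L)
  expect_identical(m$n_stays + m$n_skips, 0L)

  # a move of 3 counts as two skipped k-mers
  expect_identical(read_metrics(events_from_moves(c(0, 3)))$n_skips, 2L)

  expect_error(read_metrics(events_from_moves(integer(0))), "empty event list")
  expect_error(read_metrics(events_from_moves(c(1, 1))), "first event")
})

test_that("pooling is base-weighted, reorder-invariant, and absent when empty", {
  r10 <- read_metrics(events_from_moves(c(0, 2, 1, 1, 1)))       # 10 bases, 1 skip
  r30 <- read_metrics(events_from_moves(c(0, 2, rep(1, 23))))    # 30 bases, 1 skip
  expect_identical(r10$read_length, 10L)
  expect_identical(r30$read_length, 30L)

  p <- pool_metrics(rbind(r10, r30))
  expect_equal(p$skips_per_base, 2 / 40)
  expect_equal(p$mean_read_length, 20)
  expect_equal(pool_metrics(rbind(r30, r10))$skips_per_base, p$skips_per_base)

  # the per-read-mean alternative weights reads equally
  pm <- pool_metrics(rbind(r10, r30), method = "per_read_mean")
  expect_equal(pm$skips_per_base, mean(c(1 / 10, 1 / 30)))

  # singleton pooling is the read itself
  p1 <- pool_metrics(r10)
  expect_equal(p1$skips_per_base, 0.1)
  expect_identical(p1$reads, 1L)

  p0 <- pool_metrics(r10[0, ])
  expect_identical(p0$reads, 0L)
  expect_true(is.na(p0$skips_per_base))
  expect_true(is.na(p0$stays_per_base))
})

test_that("time chunks tile the run, conserve reads, and detect MUX stops", {
  ref <- make_reference(4000, 0.5, seed = 2)
  model <- build_pore_model(5, seed = 1)
  b <- simulate_run(ref, model, tiny_config(rate = 0.6, hours = 1),
                    degradation_params(), dose = 0, seed = 3)
  s <- time_chunks(b, chunk_minutes = 10)
  expect_identical(nrow(s$chunks), 6L)
  expect_identical(sum(s$chunks$n_reads), length(b$reads))
  expect_true(all(s$chunks$n_reads > 0))
  expect_false(s$stopped_at_mux_boundary)
  expect_equal(s$chunks$t_start_s, (0:5) * 600)

  # a 24 h run whose reads stop at the first 8 h MUX change
  cfg24 <- tiny_config(rate = 0.3, hours = 24)
  b24 <- simulate_run(ref, model, cfg24, degradation_params(), dose = 0, seed = 4)
  keep <- vapply(b24$reads, function(r) r$start_time_s < 8 * 3600, logical(1))
  b24$reads <- b24$reads[keep]
  s24 <- time_chunks(b24, chunk_minutes = 10)
  expect_identical(nrow(s24$chunks), 144L)
  expect_identical(sum(s24$chunks$n_reads), length(b24$reads))
  expect_true(all(s24$chunks$n_reads[49:144] == 0))
  expect_true(s24$stopped_at_mux_boundary)
  expect_lte(abs(s24$stop_time_s - 8 * 3600), 600)

  # zero-read run: every chunk empty, no stop flag
  b0 <- simulate_run(ref, model, tiny_config(rate = 0.2),
                     degradation_params(), dose = 750, seed = 5)
  s0 <- time_chunks(b0, chunk_minutes = 10)
  expect_true(all(s0$chunks$n_reads == 0))
  expect_identical(s0$stop_time_s, 0)
  expect_false(s0$stopped_at_mux_boundary)

  expect_error(time_chunks(b, chunk_minutes = 0), "positive")
})

test_that("zero-noise runs have exactly zero pooled skips and stays", {
  ref <- make_reference(3000, 0.5, seed = 2)
  b <- simulate_run(ref, build_pore_model(5, seed = 1), tiny_config(rate = 0.1),
                    zero_noise_params(), dose = 0, seed = 6)
  p <- pool_metrics(bundle_metrics(b))
  expect_identical(p$skips_per_base, 0)
  expect_identical(p$stays_per_base, 0)
})

test_that("stay and skip event fractions recover generator probabilities", {
  ref <- make_reference(5000, 0.5, seed = 2)
  model <- build_pore_model(5, seed = 1)
  params <- zero_noise_params(p_stay0 = 0.10, p_skip0 = 0.05)
  b <- simulate_run(ref, model, tiny_config(rate = 1.5, frag_mean = 400),
                    params, dose = 0, seed = 8)
  f <- pooled_event_fractions(bundle_metrics(b))
  expect_lt(abs(f$stay - 0.10), 3 * sqrt(0.10 * 0.90 / f$n))
  expect_lt(abs(f$skip - 0.05), 3 * sqrt(0.05 * 0.95 / f$n))
})
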