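test_that("reference generation is seeded and respects length, alphabet and GC", {
  expect_identical(make_reference(20, 0.5, seed = 7)$bases,
                   make_reference(20, 0.5, seed = 7)$bases)
  expect_false(identical(make_reference(20, 0.5, seed = 7)$bases,
                         make_reference(20, 0.5, seed = 8)$bases))

  r5 <- make_reference(5, 0.5, seed = 1)
  expect_identical(r5$length, 5L)
  expect_true(grepl("^[ACGT]{5}$", r5$bases))

  # GC count of a 100 kb draw within 3 binomial SDs of its expectation
  r <- make_reference(100000, 0.5, seed = 3)
  gc <- sum(strsplit(r$bases, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 50000), 3 * sqrt(100000 * 0.25))
  r7 <- make_reference(100000, 0.7, seed = 4)
  gc7 <- sum(strsplit(r7$bases, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc7 - 70000), 3 * sqrt(100000 * 0.7 * 0.3))

  expect_error(make_reference(0), "positive integer")
  expect_error(make_reference(100, gc_fraction = 0), "strictly between")
  expect_error(make_reference(100, gc_fraction = 1), "strictly between")
})

test_that("pore model enumerates 4^k current levels deterministically", {
  m1 <- build_pore_model(1, seed = 2)
  expect_identical(m1$kmers, c("A", "C", "G", "T"))

  m5 <- build_pore_model(5, seed = 2)
  expect_length(m5$kmers, 1024L)
  expect_false(anyDuplicated(m5$kmers) > 0)
  expect_true(all(m5$mean >= 60 & m5$mean <= 130))
  expect_true(all(m5$sd > 0))
  expect_identical(m5, build_pore_model(5, seed = 2))
  expect_false(identical(m5$mean, build_pore_model(5, seed = 3)$mean))

  # k-mer table order matches the base-4 code used by the simulator
  expect_identical(m5$kmers[poredose:::kmer_codes(
    poredose:::base_codes("ACGTT"), 5) + 1L], "ACGTT")

  expect_error(build_pore_model(0), "between 1 and 8")
  expect_error(build_pore_model(9), "between 1 and 8")
})

test_that("effective rates follow the survival curve and linear inflation", {
  p <- degradation_params()
  r0 <- effective_rates(p, 0)
  expect_identical(r0$survival, 1)
  expect_identical(r0$p_stay, p$p_stay0)
  expect_identical(r0$p_sub, p$p_sub0)
  expect_identical(r0$current_shift, 0)
  expect_true(r0$run_alive)

  expect_equal(effective_rates(p, p$d50_pore)$survival, 0.5)

  # hand evaluation of the linear form
  p2 <- degradation_params(p_stay0 = 0.10, c_stay = 1e-4)
  expect_equal(effective_rates(p2, 300)$p_stay, 0.13)

  # clamping and the run-death threshold
  expect_equal(effective_rates(p2, 1e9)$p_stay, 0.95)
  expect_false(effective_rates(p, p$d_fail)$run_alive)
  expect_true(effective_rates(p, p$d_fail - 1e-9)$run_alive)
  expect_error(effective_rates(p, -1), "non-negative")

  # monotonicity over a dose grid
  doses <- seq(0, 1200, by = 60)
  rr <- lapply(doses, effective_rates, params = p)
  surv <- vapply(rr, `[[`, numeric(1), "survival")
  expect_true(all(diff(surv) <= 0))
  for (f in c("p_stay", "p_skip", "p_sub", "p_ins")) {
    expect_true(all(diff(vapply(rr, `[[`, numeric(1), f)) >= 0))
  }
})

test_that("simulated reads honor length conservation and the move grammar", {
  ref <- make_reference(6000, 0.5, seed = 11)
  model <- build_pore_model(5, seed = 1)
  b <- simulate_run(ref, model, tiny_config(rate = 0.15),
                    degradation_params(), dose = 150, seed = 21)
  expect_gt(length(b$reads), 30)
  for (r in b$reads) {
    moves <- r$events$move
    expect_identical(moves[1], 0L)
    expect_true(all(moves %in% 0:2))
    expect_identical(nchar(r$called_bases), b$k + sum(moves))
    expect_false(is.unsorted(r$events$start_s))
    expect_true(b$well_alive[r$well])
    expect_identical(r$channel, as.integer((r$well - 1) %% b$config$n_channels + 1))
    expect_true(r$true_interval$ref_start >= 0)
    expect_true(r$true_interval$ref_end <= ref$length)
  }
})

test_that("zero-noise reads reproduce their true fragments exactly", {
  ref <- make_reference(5000, 0.5, seed = 2)
  b <- simulate_run(ref, build_pore_model(5, seed = 1), tiny_config(rate = 0.1),
                    zero_noise_params(), dose = 0, seed = 31)
  expect_gt(length(b$reads), 20)
  for (r in b$reads) {
    expect_true(all(r$events$move[-1] == 1L))
    frag <- substr(ref$bases, r$true_interval$ref_start + 1, r$true_interval$ref_end)
    if (r$true_interval$strand == "-") frag <- poredose:::revcomp(frag)
    expect_identical(r$called_bases, frag)
  }
})

test_that("identical inputs and seed reproduce the identical bundle", {
  ref <- make_reference(3000, 0.5, seed = 5)
  model <- build_pore_model(5, seed = 1)
  cfg <- tiny_config(rate = 0.05)
  b1 <- simulate_run(ref, model, cfg, degradation_params(), dose = 50, seed = 9)
  b2 <- simulate_run(ref, model, cfg, degradation_params(), dose = 50, seed = 9)
  expect_identical(b1, b2)
  b3 <- simulate_run(ref, model, cfg, degradation_params(), dose = 50, seed = 10)
  expect_false(identical(b1, b3))
})

test_that("doses at or above the failure threshold yield zero reads", {
  ref <- make_reference(3000, 0.5, seed = 5)
  model <- build_pore_model(5, seed = 1)
  cfg <- tiny_config(rate = 0.2)
  p <- degradation_params()  # d_fail = 500
  expect_length(simulate_run(ref, model, cfg, p, dose = 500, seed = 1)$reads, 0)
  expect_length(simulate_run(ref, model, cfg, p, dose = 750, seed = 1)$reads, 0)
  expect_gt(length(simulate_run(ref, model, cfg, p, dose = 300, seed = 1)$reads), 0)
})

test_that("alive-well fraction recovers the survival curve across seeds", {
  ref <- make_reference(1000, 0.5, seed = 5)
  model <- build_pore_model(5, seed = 1)
  cfg <- tiny_config(rate = 0)  # wells only, no reads
  p <- degradation_params()
  s <- effective_rates(p, 300)$survival
  alive <- vapply(1:20, function(i) {
    sum(simulate_run(ref, model, cfg, p, dose = 300, seed = 100 + i)$well_alive)
  }, numeric(1))
  n <- 20 * 2048
  expect_lt(abs(sum(alive) - n * s), 3 * sqrt(n * s * (1 - s)))
})

test_that("skip and stay rates are non-decreasing in dose", {
  ref <- make_reference(4000, 0.5, seed = 5)
  model <- build_pore_model(5, seed = 1)
  cfg <- tiny_config(rate = 0.5, frag_mean = 400)
  p <- degradation_params()
  f <- lapply(c(0, 300), function(d) {
    b <- simulate_run(ref, model, cfg, p, dose = d, seed = 77)
    pooled_event_fractions(bundle_metrics(b))
  })
  se <- function(pr, n) sqrt(pr * (1 - pr) / n)
  expect_gt(f[[2]]$stay, f[[1]]$stay - 3 * se(f[[1]]$stay, f[[1]]$n))
  expect_gt(f[[2]]$skip, f[[1]]$skip - 3 * se(f[[1]]$skip, f[[1]]$n))
})
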