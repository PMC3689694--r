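test_that("simulator is deterministic and validates class sizes", {
  cfg <- sim_config(n_genes = 50, class_sizes = c(POLY_ONLY_UP = 5),
                    seed = 9)
  s1 <- simulate_polysome_dataset(cfg)
  s2 <- simulate_polysome_dataset(cfg)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth, s2$truth)
  expect_error(sim_config(n_genes = 10, class_sizes = c(POLY_ONLY_UP = 11)),
               "exceed")
  expect_error(sim_config(class_sizes = c(NOT_A_CLASS = 1)), "unknown class")
})

test_that("noiseless recovery is exact for the documented small case", {
  cfg <- sim_config(n_genes = 10, class_sizes = c(POLY_ONLY_UP = 5),
                    noise_sd_log2 = 0, seed = 4)
  sim <- simulate_polysome_dataset(cfg)
  tab <- classify_pipeline(sim)
  counts <- summarize_classes(tab)$class_counts
  expect_equal(counts[["POLY_ONLY_UP"]], 5L)
  expect_equal(counts[["UNCHANGED"]], 5L)
})

test_that("noiseless recovery is exact over random class configurations", {
  classes <- setdiff(regulation_classes(), "UNCHANGED")
  for (seed in 1:8) {
    set.seed(seed)
    sizes <- setNames(sample(0:20, length(classes), replace = TRUE), classes)
    sizes <- sizes[sizes > 0]
    cfg <- sim_config(n_genes = sum(sizes) + sample(5:30, 1),
                      class_sizes = sizes, noise_sd_log2 = 0, seed = seed)
    sim <- simulate_polysome_dataset(cfg)
    tab <- classify_pipeline(sim)
    got <- summarize_classes(tab)$class_counts
    planted <- table(sim$truth$class)
    expect_equal(got[names(planted)], setNames(as.integer(planted),
                                               names(planted)),
                 label = paste("seed", seed))
  }
})

test_that("planted effects land on the knockdown condition only", {
  cfg <- sim_config(n_genes = 6, class_sizes = c(POLY_ONLY_UP = 3),
                    noise_sd_log2 = 0, seed = 2)
  sim <- simulate_polysome_dataset(cfg)
  poly <- condition_ratio(filter_detected(sim$matrix, sim$design),
                          sim$design, "polysomal")
  expect_equal(unname(poly[1:3, "r1"]), rep(2, 3))
  expect_equal(unname(poly[4:6, "r1"]), rep(1, 3))
})

test_that("recovery at the default noise level succeeds across seeds", {
  # margins are >= 2 noise SDs beyond thresholds on the log scale; at this
  # reduced scale (350 genes) recovered counts equal planted counts in
  # effectively all seeds
  sizes <- c(POLY_ONLY_UP = 60, POLY_ONLY_DOWN = 30, BUFFERED_UP = 50,
             BUFFERED_DOWN = 25, OPPOSITE = 35, CONCOMITANT_UNMODIFIED = 15)
  ok <- vapply(1:25, function(seed) {
    sim <- simulate_polysome_dataset(
      sim_config(n_genes = 350, class_sizes = sizes, noise_sd_log2 = 0.1,
                 seed = seed))
    got <- summarize_classes(classify_pipeline(sim))$class_counts
    all(got[names(sizes)] == sizes)
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("UTR simulator respects alphabet, shared lengths and shifts", {
  sets <- simulate_utr_sets(n_per_set = 80, seed = 3)
  expect_named(sets, c("positive", "negative", "neutral"))
  all_seq <- unlist(lapply(sets, function(s) s$sequences))
  expect_false(any(grepl("[^ACGT]", all_seq)))
  # deterministic from seed
  sets2 <- simulate_utr_sets(n_per_set = 80, seed = 3)
  expect_identical(sets$positive$sequences, sets2$positive$sequences)
  # +/- shifts order the mean GC as expected
  gcs <- vapply(sets, function(s) mean(gc_content(s$sequences)), numeric(1))
  expect_true(gcs[["negative"]] < gcs[["neutral"]])
  expect_true(gcs[["neutral"]] < gcs[["positive"]])
  expect_error(simulate_utr_sets(gc_shift_positive = 60), "invalid")
})

test_that("null UTR sets rarely separate on GC", {
  # shift 0 everywhere: positive-vs-neutral GC KS p > 0.01 in >= 95% of seeds
  ok <- vapply(1:40, function(seed) {
    sets <- simulate_utr_sets(n_per_set = 120, gc_shift_positive = 0,
                              gc_shift_negative = 0, seed = seed)
    ks_two_sample(gc_content(sets$positive$sequences),
                  gc_content(sets$neutral$sequences))$p > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("qPCR simulator is deterministic and invertible at zero noise", {
  t1 <- simulate_qpcr("G1", 2, ct_noise_sd = 0.1, seed = 12)
  t2 <- simulate_qpcr("G1", 2, ct_noise_sd = 0.1, seed = 12)
  expect_identical(t1, t2)
  t0 <- simulate_qpcr("G1", 2, ct_noise_sd = 0, seed = 12)
  res <- qpcr_analysis(t0)
  expect_equal(res$mean_ratio, c(2, 2))
})

test_that("write_simulation emits a complete, readable bundle", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 30, class_sizes = c(POLY_ONLY_UP = 4),
                    noise_sd_log2 = 0, seed = 5)
  paths <- write_simulation(cfg, dir, n_utr = 10)
  expect_true(all(file.exists(unlist(paths))))
  back <- read_expression_table(paths$matrix, paths$design, paths$flags)
  expect_equal(nrow(back$matrix$values), 30L)
  expect_equal(length(read_fasta_utrs(paths$utr_positive, "positive")), 10L)
  expect_s3_class(read_ct_table(paths$ct), "ct_table")
})
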