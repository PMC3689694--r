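test_that("gc_content counts G+C over ACGT, excluding N", {
  expect_equal(gc_content(c("ATAT", "GCGC", "ATGC")), c(0, 100, 50))
  expect_equal(gc_content("acgt"), 50)          # case-insensitive
  expect_equal(gc_content("GCNNAT"), 50)        # N out of both counts
  expect_warning(v <- gc_content("NNN"), "undefined")
  expect_true(is.na(v))
  expect_error(gc_content(""), "non-empty")
})

test_that("utr_features excludes all-N genes with a warning", {
  set <- utr_set(c(a = "GGCC", b = "NNNN", c = "ATAT"), "neutral")
  expect_warning(f <- utr_features(set), "undefined")
  expect_equal(f$gene_id, c("a", "c"))
  expect_equal(f$gc, c(100, 0))
  expect_equal(f$length, c(4L, 4L))
})

test_that("bin_distribution builds equal-width percentage histograms", {
  # ten values, one per decade, into 11 classes over [0, 100]
  b <- bin_distribution(seq(5, 95, by = 10), 11, 0, 100)
  w <- 100 / 11
  expected <- 100 * tabulate(pmin(floor(seq(5, 95, by = 10) / w) + 1, 11),
                             11) / 10
  expect_equal(b$percent, expected)
  expect_equal(sum(b$percent), 100, tolerance = 1e-9)
  expect_length(b$edges, 12L)
  # all values in one class; right edge lands in the last class
  one <- bin_distribution(c(rep(3, 9), 100), 10, 0, 100)
  expect_equal(one$percent[1], 90)
  expect_equal(one$percent[10], 10)
  expect_error(bin_distribution(numeric(0), 5, 0, 1), "at least one")
  expect_error(bin_distribution(c(0.5, 2), 5, 0, 1), "out of range.*2")
})

test_that("KS statistic and exact p match brute-force enumeration", {
  enum_ks_p <- function(a, b) {
    # permutation oracle: all assignments of pooled ranks to sample a
    m <- length(a)
    pooled <- c(a, b)
    d_obs <- asNamespace("polytrans")$ks_statistic(a, b)
    picks <- combn(length(pooled), m)
    ds <- apply(picks, 2, function(ix) {
      asNamespace("polytrans")$ks_statistic(pooled[ix], pooled[-ix])
    })
    mean(ds >= d_obs - 1e-12)
  }
  cases <- list(list(a = c(1, 2), b = c(1.5, 2.5)),
                list(a = c(1, 2, 3), b = c(2.5, 3.5)),
                list(a = c(0.3, 1.1, 2.2, 4.0), b = c(0.9, 1.5, 3.1)),
                list(a = c(5, 1, 9), b = c(2, 8, 4, 6, 7)))
  for (cs in cases) {
    k <- ks_two_sample(cs$a, cs$b)
    expect_equal(k$mode, "exact")
    expect_equal(k$p, enum_ks_p(cs$a, cs$b), tolerance = 1e-12,
                 label = paste("a =", paste(cs$a, collapse = ",")))
  }
  # trivial cases
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  expect_equal(ks_two_sample(1:3, 10:12)$D, 1)  # complete separation
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("KS properties: symmetry, monotone invariance, stats agreement", {
  set.seed(21)
  a <- rnorm(25)
  b <- rnorm(30, 0.4)
  k1 <- ks_two_sample(a, b)
  expect_equal(k1$D, ks_two_sample(b, a)$D)
  # invariant under a strictly monotone transform of both samples
  k2 <- ks_two_sample(exp(a), exp(b))
  expect_equal(k2$D, k1$D)
  expect_equal(k2$p, k1$p)
  # agrees with stats::ks.test on tie-free data (exact regime)
  r <- ks.test(a, b)
  expect_equal(k1$D, unname(r$statistic))
  expect_equal(k1$p, r$p.value, tolerance = 1e-10)
  # asymptotic regime agrees with stats::ks.test(exact = FALSE)
  set.seed(22)
  a2 <- rnorm(150); b2 <- rnorm(140)
  k3 <- ks_two_sample(a2, b2)
  expect_equal(k3$mode, "asymptotic")
  expect_equal(k3$p, ks.test(a2, b2, exact = FALSE)$p.value, tolerance = 1e-6)
})

test_that("exact and asymptotic p agree within 0.01 at n1 = n2 = 100", {
  ns <- asNamespace("polytrans")
  set.seed(31)
  for (i in 1:40) {
    a <- rnorm(100); b <- rnorm(100)
    d <- ns$ks_statistic(a, b)
    expect_lt(abs(ns$ks_exact_p(d, 100, 100) - ns$ks_asymptotic_p(d, 100, 100)),
              0.01)
  }
})

test_that("compare_utr_sets handles identical, shifted and missing sets", {
  set.seed(41)
  sets <- simulate_utr_sets(n_per_set = 60, gc_shift_positive = 25,
                            gc_shift_negative = 0, seed = 41)
  # identical sets give pairwise D = 0
  same <- compare_utr_sets(sets$neutral, sets$neutral, sets$neutral)
  for (pair in same$ks) expect_equal(pair$gc$D, 0)
  # strongly shifted positive set separates on GC
  cmp <- compare_utr_sets(sets$positive, sets$negative, sets$neutral)
  expect_lt(cmp$ks$positive_vs_neutral$gc$p, 0.05)
  expect_equal(nrow(cmp$stats), 3L)
  expect_equal(sum(cmp$distributions$positive$gc$percent), 100)
  expect_length(cmp$distributions$positive$length$percent, 21L)
  # empty neutral set: only the remaining pair is reported
  expect_warning(two <- compare_utr_sets(sets$positive, sets$negative, NULL),
                 "neutral")
  expect_named(two$ks, "positive_vs_negative")
  expect_error(suppressWarnings(compare_utr_sets(sets$positive, NULL, NULL)),
               "at least two")
})
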