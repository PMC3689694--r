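test_that("condition ratios match hand-computed values", {
  design <- tiny_design()
  # hand-set 3-gene fixture: kd/ctrl per fraction and replicate
  genes <- c("gA", "gB", "gC")
  values <- matrix(100, 3, 8, dimnames = list(genes, design$sample_id))
  values["gA", "kd_poly_r1"] <- 200   # ratio 2.0
  values["gB", "kd_poly_r1"] <- 50    # ratio 0.5
  values["gC", "ctrl_poly_r1"] <- 400 # ratio 0.25
  values["gA", "kd_tot_r2"] <- 150    # ratio 1.5
  x <- expr_matrix(values)
  poly <- condition_ratio(x, design, "polysomal")
  tot <- condition_ratio(x, design, "total")
  expect_equal(poly[, "r1"], c(gA = 2, gB = 0.5, gC = 0.25))
  expect_equal(poly[, "r2"], c(gA = 1, gB = 1, gC = 1))
  expect_equal(tot["gA", "r2"], 1.5)
  # identity when kd == ctrl
  expect_true(all(condition_ratio(tiny_matrix(), design, "total") == 1))
  # missing paired sample is named
  broken <- design[design$sample_id != "ctrl_poly_r2", ]
  expect_error(condition_ratio(x, broken, "polysomal"),
               "fraction 'polysomal', replicate 2")
})

test_that("relative translatability reproduces published example rows", {
  # single-column ratio matrices built from printed candidate fold changes
  poly <- matrix(c(0.45, 1.8, 1.0), 3, 1,
                 dimnames = list(c("ACVR1B", "DNASE1L3", "SAME"), "r1"))
  tot <- matrix(c(0.9, 1.0, 1.0), 3, 1, dimnames = dimnames(poly))
  tab <- relative_translatability(poly, tot)
  expect_equal(tab$rr_r1, c(0.5, 1.8, 1.0))
  expect_equal(tab$rr_geomean, tab$rr_r1)
  # rr_i * tot_i == poly_i within floating tolerance
  expect_equal(tab$rr_r1 * tab$tot_r1, tab$poly_r1, tolerance = 1e-12)
  # genes in only one fraction are dropped with a warning
  expect_warning(
    joined <- relative_translatability(poly, tot[1:2, , drop = FALSE]),
    "1 gene")
  expect_equal(joined$gene_id, c("ACVR1B", "DNASE1L3"))
  # zero / negative ratios refused
  expect_error(relative_translatability(poly * 0, tot), "> 0")
})

test_that("calls require concordance across replicates", {
  rr_cases <- list(c(1.6, 1.7), c(1.6, 1.2), c(0.5, 0.6), c(1.5, 1.5),
                   c(0.67, 0.67), c(1.0, 1.0))
  expected <- c("UP", "NOT_RETAINED", "DOWN", "UP", "DOWN", "NOT_RETAINED")
  for (i in seq_along(rr_cases)) {
    rr <- rr_cases[[i]]
    tab <- data.frame(gene_id = "g", poly_r1 = rr[1], poly_r2 = rr[2],
                      tot_r1 = 1, tot_r2 = 1, rr_r1 = rr[1], rr_r2 = rr[2],
                      poly_geomean = exp(mean(log(rr))), tot_geomean = 1,
                      rr_geomean = exp(mean(log(rr))))
    expect_equal(as.character(call_regulated(tab)), expected[i],
                 label = paste("rr =", paste(rr, collapse = ", ")))
  }
  # boundary values are excluded under strict thresholds
  tab <- data.frame(gene_id = "g", poly_r1 = 1.5, poly_r2 = 1.5,
                    tot_r1 = 1, tot_r2 = 1, rr_r1 = 1.5, rr_r2 = 1.5,
                    poly_geomean = 1.5, tot_geomean = 1, rr_geomean = 1.5)
  expect_equal(as.character(call_regulated(tab, thresholds(inclusive = FALSE))),
               "NOT_RETAINED")
  # single replicate: error unless allowed
  tab1 <- tab[c("gene_id", "poly_r1", "tot_r1", "rr_r1",
                "poly_geomean", "tot_geomean", "rr_geomean")]
  expect_error(call_regulated(tab1), "2 replicates")
  expect_warning(c1 <- call_regulated(tab1, allow_single = TRUE), "single")
  expect_equal(as.character(c1), "UP")
})

test_that("classification grid matches the published archetypes", {
  cases <- list(
    list(0.45, 0.9, 0.5, "POLY_ONLY_DOWN"),   # poly-only candidate row
    list(1.8, 1.0, 1.8, "POLY_ONLY_UP"),
    list(0.9, 0.3, 2.7, "BUFFERED_UP"),       # buffered candidate row
    list(1.0, 1.8, 0.56, "BUFFERED_DOWN"),
    list(0.6, 1.9, 0.3, "OPPOSITE"),          # opposite candidate row
    list(2.0, 2.0, 1.0, "CONCOMITANT_UNMODIFIED"),
    list(0.5, 0.5, 1.0, "CONCOMITANT_UNMODIFIED"),
    list(4.0, 1.6, 2.5, "OTHER_MODIFIED"),    # both up, RR still beyond
    list(1.4, 0.9, 1.56, "OTHER_MODIFIED"),   # neither direction, RR beyond
    list(1.0, 1.0, 1.0, "UNCHANGED"),
    list(1.2, 1.6, 0.75, "UNCHANGED"))        # tot changed alone, RR in band
  for (cs in cases) {
    expect_equal(as.character(classify_gene(cs[[1]], cs[[2]], cs[[3]])),
                 cs[[4]], label = paste(unlist(cs[1:3]), collapse = "/"))
  }
  expect_error(classify_gene(-1, 1, 1), "positive")
})

test_that("classification is a partition and summaries are consistent", {
  set.seed(11)
  poly <- exp(rnorm(500, 0, 0.7))
  tot <- exp(rnorm(500, 0, 0.7))
  cls <- classify_gene(poly, tot, poly / tot)
  expect_false(anyNA(cls))
  s <- summarize_classes(cls)
  expect_equal(sum(s$class_counts), 500L)
  expect_equal(s$n_expressed, 500L)
  expect_true(is.na(s$n_tot_modified))
  # empty and one-per-class inputs
  empty <- summarize_classes(factor(character(0), regulation_classes()))
  expect_true(all(empty$class_counts == 0L))
  each <- summarize_classes(regulation_classes())
  expect_true(all(each$class_counts == 1L))
  expect_equal(each$n_rr_modified, 6L)
})

test_that("pipeline calls equal the brute-force oracle on tiny matrices", {
  design <- tiny_design()
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:10, 1)
    values <- matrix(2^runif(n * 8, 2, 10), n, 8,
                     dimnames = list(sprintf("g%02d", 1:n), design$sample_id))
    detected <- matrix(runif(n * 8) > 0.2, n, 8, dimnames = dimnames(values))
    x <- expr_matrix(values, detected)
    expected <- oracle_calls(x, design)
    tab <- suppressWarnings(
      classify_pipeline(list(matrix = x, design = design)))
    got <- setNames(as.character(tab$call), tab$gene_id)
    expect_equal(got[names(expected)], expected)
  }
})

test_that("ratios are scale invariant and condition-swap symmetric", {
  design <- tiny_design()
  set.seed(3)
  values <- matrix(2^runif(5 * 8, 3, 9), 5, 8,
                   dimnames = list(paste0("g", 1:5), design$sample_id))
  x <- expr_matrix(values)
  base_poly <- condition_ratio(x, design, "polysomal")
  # scaling kd and ctrl of one sample pair by the same c leaves ratios fixed
  scaled <- values
  scaled[, c("kd_poly_r1", "ctrl_poly_r1")] <-
    scaled[, c("kd_poly_r1", "ctrl_poly_r1")] * 7.3
  expect_equal(condition_ratio(expr_matrix(scaled), design, "polysomal"),
               base_poly)
  # swapping condition labels maps ratios to reciprocals and, under
  # reciprocal thresholds, UP calls to DOWN
  swapped <- design
  swapped$condition <- ifelse(design$condition == "knockdown",
                              "control", "knockdown")
  swap_poly <- condition_ratio(x, swapped, "polysomal")
  expect_equal(swap_poly, 1 / base_poly)
  tab <- relative_translatability(base_poly,
                                  condition_ratio(x, design, "total"))
  tab_sw <- relative_translatability(swap_poly,
                                     condition_ratio(x, swapped, "total"))
  th <- thresholds(up = 1.5, down = 0.67)
  th_rec <- thresholds(up = 1 / 0.67, down = 1 / 1.5)
  calls <- call_regulated(tab, th)
  calls_sw <- call_regulated(tab_sw, th_rec)
  expect_equal(as.character(calls_sw),
               c(UP = "DOWN", DOWN = "UP",
                 NOT_RETAINED = "NOT_RETAINED")[as.character(calls)],
               ignore_attr = TRUE)
})

test_that("count_threshold_calls respects inclusivity and rejects bad input", {
  expect_equal(count_threshold_calls(c(1.5, 0.67, 1.0)),
               c(n_up = 1L, n_down = 1L))
  expect_equal(count_threshold_calls(c(1.5, 0.67, 1.0),
                                     thresholds(inclusive = FALSE)),
               c(n_up = 0L, n_down = 0L))
  expect_equal(count_threshold_calls(numeric(0)), c(n_up = 0L, n_down = 0L))
  expect_error(count_threshold_calls(c(1.2, 0)), "> 0")
})
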