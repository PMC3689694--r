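# small in-code fixtures shared across test files

# 8-sample design: 2 conditions x 2 fractions x 2 replicates
tiny_design <- function(replicates = 2) {
  grid <- expand.grid(condition = c("knockdown", "control"),
                      fraction = c("polysomal", "total"),
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%s_r%d",
                            ifelse(grid$condition == "knockdown", "kd", "ctrl"),
                            ifelse(grid$fraction == "polysomal", "poly", "tot"),
                            grid$replicate)
  sample_design(grid)
}

# deterministic matrix: every ratio equals `ratio` in both fractions
tiny_matrix <- function(genes = c("g1", "g2"), design = tiny_design(),
                        ratio = 1, ctrl_value = 100) {
  values <- matrix(ctrl_value, length(genes), nrow(design),
                   dimnames = list(genes, design$sample_id))
  kd <- design$sample_id[design$condition == "knockdown"]
  values[, kd] <- ctrl_value * ratio
  expr_matrix(values)
}

# literal reimplementation of the filtering + ratio + RR + call rules as
# written in the methods description, enumerated gene by gene; serves as
# the brute-force oracle for the pipeline path on tiny matrices
oracle_calls <- function(x, design, up = 1.5, down = 0.67) {
  genes <- rownames(x$values)
  vals <- x$values
  vals[vals == 0] <- 1e-6 * median(vals[vals > 0])
  out <- character(0)
  for (g in genes) {
    # detection: considered if signal above background for >= 1 compared
    # group, per fraction
    ok_frac <- vapply(c("polysomal", "total"), function(f) {
      ids <- design$sample_id[design$fraction == f]
      any(x$detected[g, ids])
    }, logical(1))
    if (!all(ok_frac)) next  # no RR without both fractions
    reps <- sort(unique(design$replicate))
    rr <- vapply(reps, function(r) {
      one <- function(f, cond) {
        vals[g, design$sample_id[design$fraction == f &
                                   design$replicate == r &
                                   design$condition == cond]]
      }
      (one("polysomal", "knockdown") / one("polysomal", "control")) /
        (one("total", "knockdown") / one("total", "control"))
    }, numeric(1))
    out[g] <- if (all(rr >= up)) "UP" else if (all(rr <= down)) "DOWN"
              else "NOT_RETAINED"
  }
  out
}

# run the standard matrix -> classified table path
classify_pipeline <- function(sim, th = thresholds()) {
  f <- filter_detected(sim$matrix, sim$design)
  classify_table(relative_translatability(
    condition_ratio(f, sim$design, "polysomal"),
    condition_ratio(f, sim$design, "total")), th)
}
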