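#' Configuration for the polysome-profiling simulator
#'
#' The defaults mirror the scale and design of a two-replicate
#' knockdown/control polysome-profiling microarray study: 17,416 expressed
#' genes, 2 biological replicates, log-normal multiplicative noise
#' (sd 0.1 on the log2 scale), planted effects of 2.0 (up) and 0.5 (down),
#' and planted regulation-group sizes of 326/148 polysome-only (up/down),
#' 266/131 buffered, 194 opposite and 66 concomitant-unmodified, the
#' remaining genes unchanged. Tests and desk-scale runs use reduced
#' `n_genes`; class sizes are then supplied explicitly.
#'
#' @param n_genes total number of genes.
#' @param replicates biological replicates per condition and fraction.
#' @param class_sizes named integer vector over [regulation_classes()]
#'   (classes absent default to 0; the remainder is `UNCHANGED`).
#' @param effect_up,effect_down multiplicative planted effects.
#' @param noise_sd_log2 sd of the log2-scale measurement noise on the
#'   knockdown samples.
#' @param baseline_log2_mean,baseline_log2_sd log2-normal intensity
#'   baseline parameters.
#' @param detection_dropout_rate probability that a low-intensity cell is
#'   flagged absent (0 disables MAS5-style absent calls; the default,
#'   because planted-recovery checks are defined without dropout).
#' @param seed integer RNG seed; every simulator output is reproducible
#'   from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 17416,
                       replicates = 2,
                       class_sizes = default_class_sizes(n_genes),
                       effect_up = 2.0, effect_down = 0.5,
                       noise_sd_log2 = 0.1,
                       baseline_log2_mean = 7, baseline_log2_sd = 2,
                       detection_dropout_rate = 0,
                       seed = 1L) {
  stopifnot(n_genes >= 1, replicates >= 1, effect_up > 1,
            effect_down > 0, effect_down < 1, noise_sd_log2 >= 0,
            baseline_log2_sd >= 0,
            detection_dropout_rate >= 0, detection_dropout_rate <= 1)
  bad <- setdiff(names(class_sizes), setdiff(regulation_classes(), "UNCHANGED"))
  if (length(bad)) stop("unknown class in class_sizes: ", paste(bad, collapse = ", "))
  class_sizes <- class_sizes[class_sizes > 0]
  if (sum(class_sizes) > n_genes) {
    stop("class sizes (", sum(class_sizes), ") exceed n_genes (", n_genes, ")")
  }
  structure(list(n_genes = as.integer(n_genes),
                 replicates = as.integer(replicates),
                 class_sizes = class_sizes,
                 effect_up = effect_up, effect_down = effect_down,
                 noise_sd_log2 = noise_sd_log2,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 detection_dropout_rate = detection_dropout_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Reference regulation-group sizes, scaled to a gene count
#'
#' The reference study reports, out of 17,416 expressed genes, 326/148
#' polysome-only (up/down), 266/131 buffered, 194 opposite and 66
#' concomitant-unmodified genes. At `n_genes = 17416` those sizes are
#' returned verbatim; smaller simulations scale them proportionally
#' (rounded).
#'
#' @param n_genes total genes the sizes should scale to.
#' @return named integer vector of class sizes.
#' @export
default_class_sizes <- function(n_genes = 17416) {
  ref <- c(POLY_ONLY_UP = 326, POLY_ONLY_DOWN = 148, BUFFERED_UP = 266,
           BUFFERED_DOWN = 131, OPPOSITE = 194, CONCOMITANT_UNMODIFIED = 66)
  sizes <- as.integer(round(ref * n_genes / 17416))
  stats::setNames(sizes, names(ref))
}

# planted (poly, tot) fold changes for one class; `idx` is the 1-based
# position within the class block and alternates the direction variant
# where the class admits two
planted_fold_changes <- function(class, idx, u, d) {
  alt <- idx %% 2L == 1L
  n <- length(idx)
  poly <- tot <- rep(1, n)
  switch(class,
    POLY_ONLY_UP = { poly[] <- u },
    POLY_ONLY_DOWN = { poly[] <- d },
    BUFFERED_UP = { tot[] <- d },     # RR = 1/d, translatability up
    BUFFERED_DOWN = { tot[] <- u },   # RR = 1/u, translatability down
    OPPOSITE = { poly <- ifelse(alt, u, d); tot <- ifelse(alt, d, u) },
    CONCOMITANT_UNMODIFIED = { poly <- tot <- ifelse(alt, u, d) },
    OTHER_MODIFIED = { poly <- ifelse(alt, u * u, d * d)
                       tot <- ifelse(alt, u, d) },
    UNCHANGED = NULL,
    stop("unknown class: ", class))
  cbind(poly_fc = poly, tot_fc = tot)
}

#' Simulate a two-fraction knockdown/control expression dataset
#'
#' Control intensities are drawn log-normally per (gene, fraction,
#' replicate); knockdown intensities equal the paired control times the
#' planted fold change for the gene's class times multiplicative log-normal
#' noise. Effects are planted on the knockdown condition only. At
#' `noise_sd_log2 = 0` the classification pipeline recovers every planted
#' class exactly by construction.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (an [expr_matrix()]), `design`
#'   (a [sample_design()]) and `truth` (data.frame `gene_id`, `class`,
#'   `poly_fc`, `tot_fc`).
#' @export
simulate_polysome_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  reps <- seq_len(config$replicates)
  gene_ids <- sprintf("gene_%05d", seq_len(n))

  classes <- rep("UNCHANGED", n)
  fc <- cbind(poly_fc = rep(1, n), tot_fc = rep(1, n))
  pos <- 1L
  for (cl in names(config$class_sizes)) {
    sz <- config$class_sizes[[cl]]
    block <- pos:(pos + sz - 1L)
    classes[block] <- cl
    fc[block, ] <- planted_fold_changes(cl, seq_len(sz),
                                        config$effect_up, config$effect_down)
    pos <- pos + sz
  }

  design <- expand.grid(condition = c("knockdown", "control"),
                        fraction = c("polysomal", "total"),
                        replicate = reps, stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_r%d",
                              ifelse(design$condition == "knockdown", "kd", "ctrl"),
                              ifelse(design$fraction == "polysomal", "poly", "tot"),
                              design$replicate)
  design <- sample_design(design)

  values <- matrix(NA_real_, n, nrow(design),
                   dimnames = list(gene_ids, design$sample_id))
  for (f in c("polysomal", "total")) {
    fc_col <- if (f == "polysomal") fc[, "poly_fc"] else fc[, "tot_fc"]
    for (r in reps) {
      pair <- design_pair(design, f, r)
      ctrl <- 2^stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
      noise <- 2^stats::rnorm(n, 0, config$noise_sd_log2)
      values[, pair$control] <- ctrl
      values[, pair$knockdown] <- ctrl * fc_col * noise
    }
  }

  detected <- matrix(TRUE, n, ncol(values), dimnames = dimnames(values))
  if (config$detection_dropout_rate > 0) {
    low <- values < stats::quantile(values, 0.1)
    drop <- low & matrix(stats::runif(length(values)) < config$detection_dropout_rate,
                         n, ncol(values))
    detected[drop] <- FALSE
  }

  truth <- data.frame(gene_id = gene_ids,
                      class = factor(classes, levels = regulation_classes()),
                      poly_fc = fc[, "poly_fc"], tot_fc = fc[, "tot_fc"],
                      stringsAsFactors = FALSE)
  list(matrix = expr_matrix(values, detected), design = design, truth = truth)
}

#' Simulate three 5'UTR sets with controlled GC shifts
#'
#' Lengths are drawn from one shared log-normal distribution (median 150
#' nt by default) for all three sets, so length distributions differ only
#' by sampling noise; the per-base GC probability is the baseline plus the
#' set's shift (percentage points), clamped to (0.05, 0.95).
#'
#' @param n_per_set sequences per set.
#' @param gc_shift_positive,gc_shift_negative GC shift of the positively /
#'   negatively regulated set, in percentage points.
#' @param gc_baseline baseline per-base GC probability (default 0.5).
#' @param length_meanlog,length_sdlog log-normal length parameters.
#' @param seed RNG seed.
#' @return list of three [utr_set()]s: `positive`, `negative`, `neutral`.
#' @export
simulate_utr_sets <- function(n_per_set = 300, gc_shift_positive = 15,
                              gc_shift_negative = -15, gc_baseline = 0.5,
                              length_meanlog = log(150), length_sdlog = 0.5,
                              seed = 1L) {
  stopifnot(n_per_set >= 1)
  probs <- gc_baseline + c(positive = gc_shift_positive,
                           negative = gc_shift_negative, neutral = 0) / 100
  if (any(probs <= 0 | probs >= 1)) {
    stop("GC shift gives an invalid per-base probability: ",
         paste(round(probs, 3), collapse = ", "))
  }
  probs <- pmin(pmax(probs, 0.05), 0.95)
  set.seed(seed)
  out <- lapply(names(probs), function(nm) {
    p <- probs[[nm]]
    lens <- pmax(1L, as.integer(round(stats::rlnorm(n_per_set, length_meanlog,
                                                    length_sdlog))))
    seqs <- vapply(lens, function(L) {
      paste(sample(c("G", "C", "A", "T"), L, replace = TRUE,
                   prob = c(p / 2, p / 2, (1 - p) / 2, (1 - p) / 2)),
            collapse = "")
    }, character(1))
    utr_set(stats::setNames(seqs, sprintf("%s_%04d", nm, seq_len(n_per_set))), nm)
  })
  stats::setNames(out, names(probs))
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' The reference gene's true Ct is constant across conditions; each
#' target's control Ct is fixed and its knockdown Ct is shifted by
#' `-log2(planted ratio)`. Measurement noise of sd `ct_noise_sd` cycles is
#' added independently to every technical-replicate well (targets and
#' reference, both conditions), so at zero noise [ddct_ratio()] inverts
#' the generator exactly and under the null the log-ratio is exactly
#' normal.
#'
#' @param genes character vector of target gene ids.
#' @param planted_ratios positive knockdown/control ratios, recycled over
#'   `genes`; applied to both fractions.
#' @param n_experiments independent experiments.
#' @param ct_noise_sd per-well measurement noise (cycles).
#' @param seed RNG seed.
#' @param reference reference gene id.
#' @param n_tech technical replicates per well.
#' @param target_base_ct,ref_base_ct true control-condition Ct values.
#' @return a [ct_table()] including the reference gene's rows.
#' @export
simulate_qpcr <- function(genes, planted_ratios, n_experiments = 4,
                          ct_noise_sd = 0.1, seed = 1L, reference = "HPRT1",
                          n_tech = 3, target_base_ct = 25, ref_base_ct = 20) {
  stopifnot(length(genes) >= 1, all(planted_ratios > 0), n_experiments >= 1)
  planted_ratios <- rep_len(planted_ratios, length(genes))
  set.seed(seed)
  grid <- expand.grid(gene = c(genes, reference),
                      condition = c("knockdown", "control"),
                      fraction = c("polysomal", "total"),
                      experiment = seq_len(n_experiments),
                      tech_rep = seq_len(n_tech),
                      stringsAsFactors = FALSE)
  ratio_of <- stats::setNames(c(planted_ratios, 1), c(genes, reference))
  base_of <- stats::setNames(c(rep(target_base_ct, length(genes)), ref_base_ct),
                             c(genes, reference))
  true_ct <- base_of[grid$gene] -
    ifelse(grid$condition == "knockdown", log2(ratio_of[grid$gene]), 0)
  grid$ct <- true_ct + stats::rnorm(nrow(grid), 0, ct_noise_sd)
  ct_table(grid[order(grid$gene, grid$condition, grid$fraction,
                      grid$experiment, grid$tech_rep), ])
}

#' Write a complete simulated input bundle to a directory
#'
#' Emits `matrix.tsv`, `flags.tsv`, `design.tsv`, `truth.tsv`,
#' `utr_positive.fasta` / `utr_negative.fasta` / `utr_neutral.fasta` and
#' `ct.tsv`, i.e. every input [run_pipeline()] consumes.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param qpcr_genes,qpcr_ratios targets and planted ratios for the Ct
#'   table.
#' @param n_utr sequences per UTR set.
#' @return invisibly, the list of written paths.
#' @export
write_simulation <- function(config, dir, qpcr_genes = c("TGT1", "TGT2"),
                             qpcr_ratios = c(2, 0.5), n_utr = 100) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_polysome_dataset(config)
  paths <- list(matrix = file.path(dir, "matrix.tsv"),
                flags = file.path(dir, "flags.tsv"),
                design = file.path(dir, "design.tsv"),
                truth = file.path(dir, "truth.tsv"),
                ct = file.path(dir, "ct.tsv"))
  write_expression_table(sim$matrix, paths$matrix, paths$flags)
  write_tsv(as.data.frame(sim$design), paths$design)
  write_tsv(sim$truth, paths$truth)
  utrs <- simulate_utr_sets(n_per_set = n_utr, seed = config$seed)
  for (nm in names(utrs)) {
    paths[[paste0("utr_", nm)]] <- file.path(dir, paste0("utr_", nm, ".fasta"))
    write_fasta_utrs(utrs[[nm]], paths[[paste0("utr_", nm)]])
  }
  ct <- simulate_qpcr(qpcr_genes, qpcr_ratios, seed = config$seed)
  write_tsv(ct, paths$ct)
  invisible(paths)
}
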