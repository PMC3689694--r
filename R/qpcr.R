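#' Read a qPCR Ct table
#'
#' @param path TSV with columns `gene`, `condition`, `fraction`,
#'   `experiment`, `tech_rep`, `ct`.
#' @return validated data.frame of class `ct_table`.
#' @export
read_ct_table <- function(path) {
  ct_table(read_tsv(path))
}

#' Validate a qPCR Ct table
#'
#' @param df data.frame with columns `gene`, `condition`, `fraction`,
#'   `experiment`, `tech_rep`, `ct` (threshold cycles).
#' @return the validated data.frame, class `ct_table`.
#' @export
ct_table <- function(df) {
  required <- c("gene", "condition", "fraction", "experiment", "tech_rep", "ct")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("Ct table is missing column(s): ",
                            paste(missing, collapse = ", "))
  df <- as.data.frame(df)[required]
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct))) stop("Ct values must be finite")
  bad_cond <- setdiff(unique(df$condition), c("knockdown", "control"))
  if (length(bad_cond)) stop("condition must be 'knockdown' or 'control'; found: ",
                             paste(bad_cond, collapse = ", "))
  bad_frac <- setdiff(unique(df$fraction), c("polysomal", "total"))
  if (length(bad_frac)) stop("fraction must be 'polysomal' or 'total'; found: ",
                             paste(bad_frac, collapse = ", "))
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Mean Ct over technical replicates, with outlier flagging
#'
#' Technical replicates are averaged arithmetically. Replicates deviating
#' more than `flag_dev` cycles (default 0.5) from the replicate median are
#' flagged but never dropped — the mean always uses every value.
#'
#' @param technical_cts numeric vector of Ct values (>= 1).
#' @param flag_dev deviation from the median (cycles) beyond which a
#'   replicate is flagged.
#' @return list with `mean` (numeric) and `outliers` (logical vector).
#' @examples
#' mean_ct(c(20, 20, 25))$outliers  # third replicate flagged
#' @export
mean_ct <- function(technical_cts, flag_dev = 0.5) {
  if (!length(technical_cts)) stop("mean_ct needs at least one Ct value")
  if (any(!is.finite(technical_cts))) stop("Ct values must be finite")
  med <- stats::median(technical_cts)
  list(mean = mean(technical_cts),
       outliers = abs(technical_cts - med) > flag_dev)
}

#' Delta-delta-Ct relative quantification
#'
#' Classic relative quantification against a housekeeping reference:
#' `dCt_kd = target_kd - ref_kd`, `dCt_ctrl = target_ctrl - ref_ctrl`,
#' `ddCt = dCt_kd - dCt_ctrl`, ratio `= efficiency^(-ddCt)`. With the
#' default efficiency 2 this is `2^(-ddCt)`, i.e. perfect doubling per
#' cycle.
#'
#' @param target_kd,ref_kd,target_ctrl,ref_ctrl mean Ct values for the
#'   target and reference gene under knockdown and control.
#' @param efficiency amplification efficiency E (default 2.0).
#' @return the knockdown/control expression ratio.
#' @examples
#' ddct_ratio(24, 20, 25.5, 20.5)  # ddCt = -1 -> ratio 2
#' @export
ddct_ratio <- function(target_kd, ref_kd, target_ctrl, ref_ctrl,
                       efficiency = 2) {
  cts <- c(target_kd, ref_kd, target_ctrl, ref_ctrl)
  if (any(!is.finite(cts))) stop("Ct inputs must be finite")
  stopifnot(is.numeric(efficiency), efficiency > 1)
  ddct <- (target_kd - ref_kd) - (target_ctrl - ref_ctrl)
  efficiency^(-ddct)
}

#' Test per-experiment expression ratios against no change
#'
#' The experimental pairing of knockdown and control within each
#' independent experiment arrives here already collapsed to one ratio per
#' experiment, so the paired two-tailed t test is performed as a one-sample
#' t test of log(ratio) against 0 (the equivalent formulation on the log
#' scale). Returns the geometric mean ratio, the arithmetic SEM of the
#' ratios (for error bars), t, the two-tailed p from the t distribution
#' with n - 1 df, and a degenerate-variance flag: when the log-ratios have
#' exactly zero variance and a nonzero mean, p is reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param ratios positive per-experiment ratios, length >= 2.
#' @return list with `mean_ratio`, `sem`, `t`, `p`, `df`, `degenerate`.
#' @export
ratio_test <- function(ratios) {
  n <- length(ratios)
  if (n < 2L) stop("ratio_test needs at least 2 experiments")
  if (any(!is.finite(ratios) | ratios <= 0)) stop("ratios must be finite and > 0")
  lr <- log(ratios)
  s <- stats::sd(lr)
  m <- mean(lr)
  degenerate <- FALSE
  if (s == 0) {
    if (m == 0) {
      t <- 0; p <- 1
    } else {
      t <- sign(m) * Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    t <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1L)
  }
  list(mean_ratio = geomean(ratios), sem = stats::sd(ratios) / sqrt(n),
       t = t, p = p, df = n - 1L, degenerate = degenerate)
}

#' Full delta-delta-Ct analysis of a Ct table
#'
#' For every target gene and fraction: technical replicates are averaged
#' per (condition, experiment) well, the per-experiment knockdown/control
#' ratio is computed by [ddct_ratio()] against the reference gene, and the
#' per-experiment ratios are tested by [ratio_test()].
#'
#' @param ct a [ct_table()] (or data.frame coercible to one).
#' @param reference housekeeping reference gene id (default `"HPRT1"`).
#' @param efficiency amplification efficiency (default 2.0).
#' @param flag_dev technical-replicate outlier threshold in cycles.
#' @return data.frame with one row per (gene, fraction): `n_experiments`,
#'   `mean_ratio`, `sem`, `t`, `p`, `degenerate`, `n_ct_outliers`, plus the
#'   per-experiment ratios in `attr(, "ratios")`.
#' @export
qpcr_analysis <- function(ct, reference = "HPRT1", efficiency = 2,
                          flag_dev = 0.5) {
  ct <- ct_table(ct)
  if (!reference %in% ct$gene) stop("reference gene '", reference,
                                    "' not present in the Ct table")
  targets <- setdiff(unique(ct$gene), reference)
  if (!length(targets)) stop("no target genes besides the reference")

  well_mean <- function(g, cond, frac, exp) {
    v <- ct$ct[ct$gene == g & ct$condition == cond & ct$fraction == frac &
                 ct$experiment == exp]
    if (!length(v)) {
      stop(sprintf("missing Ct well: gene %s, %s, %s, experiment %s",
                   g, cond, frac, exp))
    }
    mean_ct(v, flag_dev)
  }

  rows <- list()
  all_ratios <- list()
  for (g in targets) {
    for (frac in intersect(c("polysomal", "total"),
                           unique(ct$fraction[ct$gene == g]))) {
      exps <- sort(unique(ct$experiment[ct$gene == g & ct$fraction == frac]))
      ratios <- numeric(length(exps))
      n_out <- 0L
      for (i in seq_along(exps)) {
        tk <- well_mean(g, "knockdown", frac, exps[i])
        rk <- well_mean(reference, "knockdown", frac, exps[i])
        tc <- well_mean(g, "control", frac, exps[i])
        rc <- well_mean(reference, "control", frac, exps[i])
        n_out <- n_out + sum(tk$outliers, rk$outliers, tc$outliers, rc$outliers)
        ratios[i] <- ddct_ratio(tk$mean, rk$mean, tc$mean, rc$mean, efficiency)
      }
      rt <- ratio_test(ratios)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, fraction = frac, n_experiments = length(exps),
        mean_ratio = rt$mean_ratio, sem = rt$sem, t = rt$t, p = rt$p,
        degenerate = rt$degenerate, n_ct_outliers = n_out,
        stringsAsFactors = FALSE)
      all_ratios[[paste(g, frac, sep = ".")]] <- stats::setNames(ratios, exps)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ratios") <- all_ratios
  out
}
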