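#' GC content of nucleotide sequences
#'
#' `100 * (#G + #C) / (#A + #C + #G + #T)`, case-insensitive. `N` bases are
#' excluded from both numerator and denominator; a sequence consisting only
#' of `N` has undefined GC content and yields `NA` with a warning.
#'
#' @param sequence character vector of non-empty nucleotide sequences.
#' @return numeric vector of GC percentages in `[0, 100]` (or `NA`).
#' @examples
#' gc_content(c("ATAT", "GCGC", "ATGC"))
#' @export
gc_content <- function(sequence) {
  sequence <- as.character(sequence)
  if (!length(sequence) || any(!nzchar(sequence))) {
    stop("gc_content requires non-empty sequences")
  }
  s <- toupper(sequence)
  n_gc <- nchar(gsub("[^GC]", "", s))
  n_acgt <- nchar(gsub("[^ACGT]", "", s))
  out <- ifelse(n_acgt > 0, 100 * n_gc / n_acgt, NA_real_)
  if (anyNA(out)) {
    warning(sum(is.na(out)), " all-N sequence(s) have undefined GC content")
  }
  out
}

#' Feature vector (GC percent and length) of a UTR set
#'
#' Genes whose GC content is undefined (all-N sequence) are excluded with a
#' warning.
#'
#' @param set a [utr_set()].
#' @return data.frame with columns `gene_id`, `set`, `gc`, `length`.
#' @export
utr_features <- function(set) {
  stopifnot(inherits(set, "utr_set"))
  gc <- gc_content(set$sequences)
  keep <- !is.na(gc)
  data.frame(gene_id = names(set$sequences)[keep], set = set$label,
             gc = gc[keep], length = nchar(set$sequences)[keep],
             stringsAsFactors = FALSE)
}

#' Bin values into equal-width classes and report percentages
#'
#' Classes partition `[lo, hi]` into `n_classes` equal-width intervals,
#' left edge inclusive, with the right edge inclusive on the last class
#' only. The published distribution figures use 11 classes for GC content
#' over `[0, 100]` and 21 classes for UTR length.
#'
#' @param values numeric values, all within `[lo, hi]`.
#' @param n_classes number of classes (>= 1).
#' @param lo,hi range limits.
#' @return a `binned_distribution` list with `edges` (length
#'   `n_classes + 1`) and `percent` (sums to 100).
#' @export
bin_distribution <- function(values, n_classes, lo, hi) {
  if (!length(values)) stop("bin_distribution requires at least one value")
  stopifnot(n_classes >= 1L, lo < hi)
  out_of_range <- values < lo | values > hi | !is.finite(values)
  if (any(out_of_range)) {
    stop("value out of range [", lo, ", ", hi, "]: ",
         values[which(out_of_range)[1L]])
  }
  width <- (hi - lo) / n_classes
  idx <- pmin(floor((values - lo) / width) + 1L, n_classes)
  counts <- tabulate(idx, nbins = n_classes)
  structure(list(edges = seq(lo, hi, length.out = n_classes + 1L),
                 percent = 100 * counts / length(values)),
            class = "binned_distribution")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes `D = sup_x |ECDF_a(x) - ECDF_b(x)|`. The p-value is exact
#' (lattice-path counting over all orderings) when `n1 * n2 <= exact_limit`
#' and the pooled sample has no ties; otherwise the asymptotic Kolmogorov
#' distribution is used at the standard effective sample size,
#' `lambda = sqrt(ne) * D` with `ne = n1 n2 / (n1 + n2)`.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact_limit exact-p crossover on `n1 * n2` (default 10000).
#' @return a `ks_result` list with `D`, `p`, `n1`, `n2`, `mode`.
#' @export
ks_two_sample <- function(a, b, exact_limit = 10000) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("samples must be finite")
  n1 <- length(a); n2 <- length(b)
  D <- ks_statistic(a, b)
  ties <- anyDuplicated(c(a, b)) > 0
  if (n1 * n2 <= exact_limit && !ties) {
    p <- ks_exact_p(D, n1, n2)
    mode <- "exact"
  } else {
    p <- ks_asymptotic_p(D, n1, n2)
    mode <- "asymptotic"
  }
  structure(list(D = D, p = min(max(p, 0), 1), n1 = n1, n2 = n2, mode = mode),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("two-sample KS: D = %.4f, p = %.4g (%s, n1 = %d, n2 = %d)\n",
              x$D, x$p, x$mode, x$n1, x$n2))
  invisible(x)
}

# max absolute ECDF difference, evaluated at the pooled support
ks_statistic <- function(a, b) {
  u <- sort(unique(c(a, b)))
  fa <- findInterval(u, sort(a)) / length(a)
  fb <- findInterval(u, sort(b)) / length(b)
  max(abs(fa - fb))
}

# exact P(D >= d) for tie-free samples of sizes m, n: count monotone
# lattice paths (0,0) -> (m,n) that stay strictly inside |i*n - j*m| < d*m*n.
# Counts are doubles; C(200, 100) ~ 9e58 is far below double overflow.
ks_exact_p <- function(d, m, n) {
  if (d <= 0) return(1)
  k <- d * m * n - 0.5  # d is a multiple of 1/(m*n); violation iff |in-jm| >= round(dmn)
  A <- matrix(0, m + 1L, n + 1L)
  A[1L, 1L] <- 1
  for (i in 0:m) {
    for (j in 0:n) {
      if (i == 0L && j == 0L) next
      if (abs(i * n - j * m) > k) { A[i + 1L, j + 1L] <- 0; next }
      left <- if (i > 0L) A[i, j + 1L] else 0
      down <- if (j > 0L) A[i + 1L, j] else 0
      A[i + 1L, j + 1L] <- left + down
    }
  }
  1 - A[m + 1L, n + 1L] / choose(m + n, m)
}

# asymptotic Kolmogorov tail at the effective sample size ne = mn/(m+n);
# the plain sqrt(ne)*D argument tracks the exact two-sample distribution
# far better than the one-sample small-n corrections
ks_asymptotic_p <- function(d, m, n) {
  if (d <= 0) return(1)
  ne <- m * n / (m + n)
  lambda <- sqrt(ne) * d
  kk <- 1:100
  p <- 2 * sum((-1)^(kk - 1) * exp(-2 * kk^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Compare regulated and neutral 5'UTR sets
#'
#' Extracts GC content and length per set, bins them into the standard
#' class layouts (11 equal-width GC classes over `[0, 100]`, 21 length
#' classes over `[0, max length]`), computes per-set summary statistics and
#' pairwise two-sample KS tests for both features. Empty (`NULL`) sets are
#' skipped with a warning and only the remaining pairs are compared.
#'
#' @param positive,negative,neutral [utr_set()] objects (any may be NULL).
#' @param gc_classes,length_classes number of histogram classes.
#' @return list with `features` (combined data.frame), `distributions`,
#'   `stats` (mean/median/SD per set and feature) and `ks` (per pair, KS
#'   results for `gc` and `length`).
#' @export
compare_utr_sets <- function(positive = NULL, negative = NULL, neutral = NULL,
                             gc_classes = 11, length_classes = 21) {
  sets <- list(positive = positive, negative = negative, neutral = neutral)
  empty <- names(sets)[vapply(sets, is.null, logical(1))]
  if (length(empty)) {
    warning("skipping empty set(s): ", paste(empty, collapse = ", "))
    sets <- sets[setdiff(names(sets), empty)]
  }
  if (length(sets) < 2L) stop("need at least two non-empty UTR sets to compare")
  feats <- do.call(rbind, lapply(names(sets), function(nm) {
    f <- utr_features(sets[[nm]])
    f$set <- nm
    f
  }))
  max_len <- max(feats$length)
  distributions <- lapply(split(feats, feats$set), function(f) {
    list(gc = bin_distribution(f$gc, gc_classes, 0, 100),
         length = bin_distribution(f$length, length_classes, 0, max_len))
  })
  stats_tab <- do.call(rbind, lapply(split(feats, feats$set), function(f) {
    data.frame(set = f$set[1L],
               gc_mean = mean(f$gc), gc_median = stats::median(f$gc),
               gc_sd = stats::sd(f$gc),
               length_mean = mean(f$length),
               length_median = stats::median(f$length),
               length_sd = stats::sd(f$length), stringsAsFactors = FALSE)
  }))
  rownames(stats_tab) <- NULL
  pairs <- utils::combn(names(sets), 2L, simplify = FALSE)
  ks <- lapply(pairs, function(pr) {
    fa <- feats[feats$set == pr[1L], ]
    fb <- feats[feats$set == pr[2L], ]
    list(gc = ks_two_sample(fa$gc, fb$gc),
         length = ks_two_sample(fa$length, fb$length))
  })
  names(ks) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  list(features = feats, distributions = distributions, stats = stats_tab,
       ks = ks)
}
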