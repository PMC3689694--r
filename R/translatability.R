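#' Per-replicate knockdown/control ratios for one RNA fraction
#'
#' For each biological replicate, pairs the knockdown and control sample of
#' the requested fraction and computes the per-gene intensity ratio
#' knockdown / control. Genes not retained for this fraction by
#' [filter_detected()] (when the matrix carries a retention attribute) are
#' absent from the result.
#'
#' @param x an [expr_matrix()], typically after [filter_detected()].
#' @param design a [sample_design()].
#' @param fraction `"polysomal"` or `"total"`.
#' @param floor apply [floor_intensities()] before dividing (default TRUE).
#' @return numeric matrix, genes x replicates (columns `r1`, `r2`, ...),
#'   with the fraction recorded in `attr(, "fraction")`.
#' @export
condition_ratio <- function(x, design, fraction = c("polysomal", "total"),
                            floor = TRUE) {
  fraction <- match.arg(fraction)
  stopifnot(inherits(x, "expr_matrix"))
  if (floor) x <- suppressWarnings(floor_intensities(x))
  ret <- attr(x, "retention")
  genes <- rownames(x$values)
  if (!is.null(ret)) genes <- genes[ret[, fraction]]
  reps <- sort(unique(design$replicate[design$fraction == fraction]))
  if (!length(reps)) stop("design has no samples for fraction '", fraction, "'")
  out <- matrix(NA_real_, length(genes), length(reps),
                dimnames = list(genes, paste0("r", reps)))
  for (i in seq_along(reps)) {
    pair <- design_pair(design, fraction, reps[i])
    out[, i] <- x$values[genes, pair$knockdown] / x$values[genes, pair$control]
  }
  attr(out, "fraction") <- fraction
  out
}

#' Relative translatability table
#'
#' Joins the polysomal and total fold-change tables on their common genes
#' and computes, per replicate i, the relative translatability
#' `RR_i = polyRNA_i / totRNA_i`, plus geometric-mean summaries across
#' replicates. Genes present in only one fraction are dropped with a
#' warning (they cannot contribute an RR).
#'
#' @param poly_ratios,tot_ratios matrices from [condition_ratio()] with the
#'   same replicate columns.
#' @return a `translatability_table` data.frame with columns `gene_id`,
#'   `poly_r*`, `tot_r*`, `rr_r*`, `poly_geomean`, `tot_geomean`,
#'   `rr_geomean`.
#' @export
relative_translatability <- function(poly_ratios, tot_ratios) {
  poly_ratios <- as.matrix(poly_ratios)
  tot_ratios <- as.matrix(tot_ratios)
  if (!identical(colnames(poly_ratios), colnames(tot_ratios))) {
    stop("polysomal and total ratio tables must have the same replicate columns")
  }
  common <- intersect(rownames(poly_ratios), rownames(tot_ratios))
  lost <- length(union(rownames(poly_ratios), rownames(tot_ratios))) - length(common)
  if (lost > 0) {
    warning(lost, " gene(s) present in only one fraction were dropped from the RR table")
  }
  if (!length(common)) stop("no genes shared between the two fractions")
  p <- poly_ratios[common, , drop = FALSE]
  t <- tot_ratios[common, , drop = FALSE]
  if (any(!is.finite(p)) || any(!is.finite(t)) || any(p <= 0) || any(t <= 0)) {
    stop("ratios must be finite and > 0 (floor intensities before dividing)")
  }
  rr <- p / t
  reps <- colnames(p)
  out <- data.frame(gene_id = common, stringsAsFactors = FALSE)
  for (r in reps) out[[paste0("poly_", r)]] <- p[, r]
  for (r in reps) out[[paste0("tot_", r)]] <- t[, r]
  for (r in reps) out[[paste0("rr_", r)]] <- rr[, r]
  out$poly_geomean <- apply(p, 1L, geomean)
  out$tot_geomean <- apply(t, 1L, geomean)
  out$rr_geomean <- apply(rr, 1L, geomean)
  rownames(out) <- NULL
  class(out) <- c("translatability_table", "data.frame")
  out
}

# replicate column names of a translatability table, e.g. c("r1","r2")
tt_replicates <- function(tab) {
  sub("^rr_", "", grep("^rr_r", names(tab), value = TRUE))
}

# matrix of per-replicate values for one measure ("rr", "poly", "tot")
tt_matrix <- function(tab, measure) {
  cols <- paste0(measure, "_", tt_replicates(tab))
  m <- as.matrix(tab[cols])
  rownames(m) <- tab$gene_id
  m
}

#' Concordance-thresholded translational calls
#'
#' A gene is called `UP` when its RR reaches the upper threshold in every
#' replicate, `DOWN` when it reaches the lower threshold in every
#' replicate, and `NOT_RETAINED` otherwise (discordant replicates or RR
#' within the unmodified band).
#'
#' @param tab a [relative_translatability()] table.
#' @param th an [thresholds()] object.
#' @param allow_single permit a single-replicate table (that replicate then
#'   decides, with a warning); default FALSE.
#' @return factor with levels `UP`, `DOWN`, `NOT_RETAINED`, named by gene.
#' @export
call_regulated <- function(tab, th = thresholds(), allow_single = FALSE) {
  rr <- tt_matrix(tab, "rr")
  if (ncol(rr) < 2L) {
    if (!allow_single) {
      stop("call_regulated needs >= 2 replicates (set allow_single = TRUE to override)")
    }
    warning("single replicate: its RR alone decides the call")
  }
  up <- if (th$inclusive) rr >= th$up else rr > th$up
  down <- if (th$inclusive) rr <= th$down else rr < th$down
  call <- ifelse(rowSums(up) == ncol(rr), "UP",
                 ifelse(rowSums(down) == ncol(rr), "DOWN", "NOT_RETAINED"))
  factor(stats::setNames(call, tab$gene_id),
         levels = c("UP", "DOWN", "NOT_RETAINED"))
}

#' The mutually exclusive regulation classes
#'
#' Taxonomy of how a change in relative translatability (or lack of one)
#' decomposes into polysomal and total abundance changes:
#' * `POLY_ONLY_UP` / `POLY_ONLY_DOWN` — polysome abundance changed, total
#'   unchanged (translational regulation proper);
#' * `BUFFERED_UP` / `BUFFERED_DOWN` — total abundance changed while
#'   polysome association held constant (translational buffering); the
#'   suffix is the direction of the RR change;
#' * `OPPOSITE` — polysomal and total abundance moved in opposite
#'   directions;
#' * `CONCOMITANT_UNMODIFIED` — both moved in the same direction with RR
#'   inside the unmodified band;
#' * `OTHER_MODIFIED` — RR beyond threshold but none of the patterns above;
#' * `UNCHANGED` — everything else.
#'
#' @return character vector of the class labels, in canonical order.
#' @export
regulation_classes <- function() {
  c("POLY_ONLY_UP", "POLY_ONLY_DOWN", "BUFFERED_UP", "BUFFERED_DOWN",
    "OPPOSITE", "CONCOMITANT_UNMODIFIED", "OTHER_MODIFIED", "UNCHANGED")
}

#' Classify a gene into the regulation taxonomy
#'
#' Deterministic total function on the 3 x 3 grid of (polysomal direction,
#' total direction) crossed with the RR band; see [regulation_classes()]
#' for the labels. Directions of the polysomal and total summaries use
#' `dir_th` (defaulting to the RR thresholds).
#'
#' @param poly,tot,rr positive summary fold changes (vectorized).
#' @param th RR [thresholds()].
#' @param dir_th thresholds for the per-fraction directions.
#' @return factor over [regulation_classes()].
#' @examples
#' classify_gene(0.45, 0.9, 0.5)   # POLY_ONLY_DOWN
#' classify_gene(0.9, 0.3, 2.7)    # BUFFERED_UP
#' classify_gene(0.6, 1.9, 0.3)    # OPPOSITE
#' @export
classify_gene <- function(poly, tot, rr, th = thresholds(), dir_th = th) {
  stopifnot(length(poly) == length(tot), length(tot) == length(rr))
  if (any(!is.finite(poly) | !is.finite(tot) | !is.finite(rr) |
            poly <= 0 | tot <= 0 | rr <= 0)) {
    stop("classify_gene requires positive finite poly, tot and rr values")
  }
  pd <- ratio_direction(poly, dir_th)
  td <- ratio_direction(tot, dir_th)
  modified <- rr_is_modified(rr, th)
  rr_dir <- ifelse(rr > 1, "UP", "DOWN")
  cls <- ifelse(
    modified,
    ifelse(pd != "none" & td == "none", paste0("POLY_ONLY_", rr_dir),
    ifelse(pd == "none" & td != "none", paste0("BUFFERED_", rr_dir),
    ifelse(pd != "none" & td != "none" & pd != td, "OPPOSITE",
           "OTHER_MODIFIED"))),
    ifelse(pd != "none" & td != "none" & pd == td, "CONCOMITANT_UNMODIFIED",
           "UNCHANGED"))
  factor(cls, levels = regulation_classes())
}

#' Classify every gene of a translatability table
#'
#' Adds `call` (from [call_regulated()]) and `class` (from
#' [classify_gene()] on the geometric-mean summaries) columns.
#'
#' @inheritParams call_regulated
#' @param dir_th thresholds for per-fraction directions.
#' @return the table with `call` and `class` columns appended.
#' @export
classify_table <- function(tab, th = thresholds(), dir_th = th,
                           allow_single = FALSE) {
  tab$call <- call_regulated(tab, th, allow_single = allow_single)
  tab$class <- classify_gene(tab$poly_geomean, tab$tot_geomean,
                             tab$rr_geomean, th, dir_th)
  tab
}

#' Summarize regulation classes
#'
#' Counts genes per regulation class and reports the totals
#' `n_expressed`, `n_rr_modified` (RR summary beyond threshold) and
#' `n_tot_modified` (total-abundance summary beyond threshold). When only
#' class labels are supplied (no table), `n_rr_modified` is derived from
#' class membership and `n_tot_modified` is `NA` (it cannot be recovered
#' from labels alone).
#'
#' @param classes factor/character of class labels, or a classified table
#'   from [classify_table()] (then `classes` is taken from its `class`
#'   column).
#' @param th [thresholds()] used for the modified totals.
#' @return a `class_count_summary` list with elements `class_counts`,
#'   `n_expressed`, `n_rr_modified`, `n_tot_modified`.
#' @export
summarize_classes <- function(classes, th = thresholds()) {
  tab <- NULL
  if (is.data.frame(classes)) {
    tab <- classes
    if (is.null(tab$class)) stop("table has no 'class' column; run classify_table() first")
    classes <- tab$class
  }
  classes <- factor(as.character(classes), levels = regulation_classes())
  if (anyNA(classes)) stop("unknown regulation class label")
  counts <- table(classes)
  modified_cls <- setdiff(regulation_classes(),
                          c("CONCOMITANT_UNMODIFIED", "UNCHANGED"))
  if (!is.null(tab)) {
    n_rr <- sum(rr_is_modified(tab$rr_geomean, th))
    n_tot <- sum(ratio_direction(tab$tot_geomean, th) != "none")
  } else {
    n_rr <- sum(counts[modified_cls])
    n_tot <- NA_integer_
  }
  structure(list(class_counts = stats::setNames(as.integer(counts), names(counts)),
                 n_expressed = length(classes),
                 n_rr_modified = as.integer(n_rr),
                 n_tot_modified = as.integer(n_tot)),
            class = "class_count_summary")
}

#' @export
print.class_count_summary <- function(x, ...) {
  cat("regulation class counts (", x$n_expressed, " genes, ",
      x$n_rr_modified, " RR-modified):\n", sep = "")
  for (cl in names(x$class_counts)) {
    cat(sprintf("  %-24s %d\n", cl, x$class_counts[[cl]]))
  }
  invisible(x)
}

#' Count RR values beyond the thresholds
#'
#' @param rr_values positive RR values (e.g. a published candidate table's
#'   poly/tot column).
#' @param th [thresholds()].
#' @return named integer vector `c(n_up, n_down)`.
#' @examples
#' count_threshold_calls(c(1.5, 0.67, 1.0))  # 1 up, 1 down
#' @export
count_threshold_calls <- function(rr_values, th = thresholds()) {
  if (!length(rr_values)) return(c(n_up = 0L, n_down = 0L))
  if (any(!is.finite(rr_values) | rr_values <= 0)) {
    stop("RR values must be finite and > 0")
  }
  up <- if (th$inclusive) rr_values >= th$up else rr_values > th$up
  down <- if (th$inclusive) rr_values <= th$down else rr_values < th$down
  c(n_up = sum(up), n_down = sum(down))
}

#' Write a classified translatability table to TSV
#'
#' @param tab a (classified) translatability table.
#' @param path output TSV.
#' @export
write_translatability <- function(tab, path) {
  write_tsv(as.data.frame(tab), path)
  invisible(path)
}
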