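#' Sample design table for a two-fraction knockdown/control experiment
#'
#' Validates a design mapping each array/sample to its experimental cell:
#' `condition` (knockdown or control), `fraction` (polysomal or total
#' cytoplasmic RNA) and biological `replicate`. Ratio computation pairs the
#' knockdown and control sample of the same fraction and replicate.
#'
#' @param df data.frame with columns `sample_id`, `condition`, `fraction`,
#'   `replicate`.
#' @return a validated `sample_design` data.frame.
#' @export
sample_design <- function(df) {
  required <- c("sample_id", "condition", "fraction", "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("design is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df$sample_id <- as.character(df$sample_id)
  df$condition <- as.character(df$condition)
  df$fraction <- as.character(df$fraction)
  bad_cond <- setdiff(unique(df$condition), c("knockdown", "control"))
  if (length(bad_cond)) {
    stop("condition must be 'knockdown' or 'control'; found: ",
         paste(bad_cond, collapse = ", "))
  }
  bad_frac <- setdiff(unique(df$fraction), c("polysomal", "total"))
  if (length(bad_frac)) {
    stop("fraction must be 'polysomal' or 'total'; found: ",
         paste(bad_frac, collapse = ", "))
  }
  rep_num <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(rep_num) || any(rep_num < 1L)) {
    stop("replicate must be a positive integer")
  }
  df$replicate <- rep_num
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id in design: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  key <- paste(df$condition, df$fraction, df$replicate)
  if (anyDuplicated(key)) {
    stop("duplicated (condition, fraction, replicate) triple in design: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Read a sample design TSV
#'
#' @param path TSV with header `sample_id  condition  fraction  replicate`.
#' @return a `sample_design` data.frame.
#' @export
read_sample_design <- function(path) {
  sample_design(read_tsv(path))
}

# knockdown/control sample ids for one (fraction, replicate) pair;
# errors naming the missing pair
design_pair <- function(design, fraction, replicate) {
  sel <- design$fraction == fraction & design$replicate == replicate
  kd <- design$sample_id[sel & design$condition == "knockdown"]
  ctrl <- design$sample_id[sel & design$condition == "control"]
  if (length(kd) != 1L || length(ctrl) != 1L) {
    stop(sprintf("missing paired sample for fraction '%s', replicate %d",
                 fraction, replicate))
  }
  list(knockdown = kd, control = ctrl)
}

#' Expression matrix with detection flags
#'
#' Container for a normalized gene-by-sample intensity matrix (e.g. MAS5
#' output) plus parallel present/absent detection flags. Values must be
#' finite and non-negative; gene identifiers must be unique.
#'
#' @param values numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param detected logical matrix of the same shape, or `NULL` for all
#'   detected.
#' @return an object of class `expr_matrix` with elements `values` and
#'   `detected`.
#' @export
expr_matrix <- function(values, detected = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) && nrow(values) > 0) {
    stop("values must have gene ids as rownames")
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) stop("values must have sample ids as colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop("duplicated gene id: ", paste(unique(dup), collapse = ", "))
  check_intensities(values)
  if (is.null(detected)) {
    detected <- matrix(TRUE, nrow(values), ncol(values),
                       dimnames = dimnames(values))
  } else {
    detected <- as.matrix(detected)
    if (!identical(dim(detected), dim(values))) {
      stop("detection flags do not match the matrix dimensions")
    }
    dimnames(detected) <- dimnames(values)
    storage.mode(detected) <- "logical"
    if (anyNA(detected)) stop("detection flags must be 0/1 with no missing values")
  }
  structure(list(values = values, detected = detected), class = "expr_matrix")
}

# error naming the first offending (gene, sample) cell
check_intensities <- function(values) {
  bad <- !is.finite(values) | values < 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid intensity at (%s, %s): values must be finite and >= 0",
                 rownames(values)[idx[1L]], colnames(values)[idx[2L]]))
  }
  invisible(TRUE)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%.1f%% detected)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$detected)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression table and its design
#'
#' Expects a TSV whose first column holds the gene id and whose remaining
#' columns are samples, a design TSV (see [read_sample_design()]), and
#' optionally a parallel 0/1 detection-flag TSV of the same shape. Absent
#' flags mean every value is treated as detected.
#'
#' @param path expression TSV.
#' @param design_path design TSV.
#' @param flags_path optional detection-flag TSV.
#' @return list with elements `matrix` (an [expr_matrix()]) and `design`.
#' @export
read_expression_table <- function(path, design_path, flags_path = NULL) {
  tab <- read_tsv(path)
  if (ncol(tab) < 2L) stop("expression table needs a gene id column plus samples")
  gene_ids <- as.character(tab[[1L]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) stop("duplicated gene id: ", paste(dup, collapse = ", "))
  raw <- tab[-1L]
  values <- matrix(NA_real_, nrow(tab), ncol(raw),
                   dimnames = list(gene_ids, names(raw)))
  for (j in seq_along(raw)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) | !is.finite(v) | v < 0)
    if (length(bad)) {
      stop(sprintf(
        "invalid value '%s' at (%s, %s): intensities must be numeric and >= 0",
        as.character(raw[[j]][bad[1L]]), gene_ids[bad[1L]], names(raw)[j]))
    }
    values[, j] <- v
  }
  design <- read_sample_design(design_path)
  extra <- setdiff(colnames(values), design$sample_id)
  absent <- setdiff(design$sample_id, colnames(values))
  if (length(extra) || length(absent)) {
    stop("design/matrix sample mismatch",
         if (length(extra)) paste0("; samples missing from design: ",
                                   paste(extra, collapse = ", ")),
         if (length(absent)) paste0("; design samples missing from matrix: ",
                                    paste(absent, collapse = ", ")))
  }
  values <- values[, design$sample_id, drop = FALSE]
  detected <- NULL
  if (!is.null(flags_path)) {
    ftab <- read_tsv(flags_path)
    fid <- as.character(ftab[[1L]])
    if (!identical(fid, gene_ids)) stop("detection flags gene ids do not match the matrix")
    fm <- as.matrix(ftab[-1L])
    rownames(fm) <- fid
    if (!all(colnames(values) %in% colnames(fm))) {
      stop("detection flags samples do not match the matrix")
    }
    fm <- fm[, colnames(values), drop = FALSE]
    if (!all(fm %in% c(0, 1))) stop("detection flags must be 0 or 1")
    detected <- fm == 1
  }
  list(matrix = expr_matrix(values, detected), design = design)
}

#' Write an expression matrix (and optional flags) to TSV
#'
#' @param x an [expr_matrix()].
#' @param path output TSV for intensities.
#' @param flags_path optional output TSV for 0/1 detection flags.
#' @export
write_expression_table <- function(x, path, flags_path = NULL) {
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE)
  write_tsv(df, path)
  if (!is.null(flags_path)) {
    fd <- data.frame(gene_id = rownames(x$values), 1L * x$detected,
                     check.names = FALSE)
    write_tsv(fd, flags_path)
  }
  invisible(path)
}

#' Apply the detection filter
#'
#' A gene is retained for a fraction's analysis when its signal is flagged
#' detected (above background) in at least one sample of at least one
#' condition group of that fraction. Genes retained in neither fraction are
#' dropped. The returned matrix carries a per-fraction retention matrix in
#' `attr(, "retention")`.
#'
#' @param x an [expr_matrix()].
#' @param design a [sample_design()].
#' @return filtered `expr_matrix` with a logical `retention` attribute
#'   (genes x fractions).
#' @export
filter_detected <- function(x, design) {
  stopifnot(inherits(x, "expr_matrix"))
  fractions <- c("polysomal", "total")
  ret <- matrix(FALSE, nrow(x$values), 2L,
                dimnames = list(rownames(x$values), fractions))
  for (f in fractions) {
    ids <- design$sample_id[design$fraction == f]
    if (length(ids)) {
      ret[, f] <- rowSums(x$detected[, ids, drop = FALSE]) > 0
    }
  }
  keep <- ret[, 1L] | ret[, 2L]
  out <- expr_matrix(x$values[keep, , drop = FALSE],
                     x$detected[keep, , drop = FALSE])
  attr(out, "retention") <- ret[keep, , drop = FALSE]
  out
}

#' Replace zero intensities by a small floor
#'
#' Zero intensities are permitted on input but would break ratio
#' computation; they are replaced by `eps` (default `1e-6` times the median
#' of the positive values) with a warning reporting how many cells were
#' floored.
#'
#' @param x an [expr_matrix()].
#' @param eps floor value; `NULL` for the default.
#' @return the floored `expr_matrix` (retention attribute preserved).
#' @export
floor_intensities <- function(x, eps = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  zero <- x$values == 0
  if (any(zero)) {
    if (is.null(eps)) {
      pos <- x$values[x$values > 0]
      if (!length(pos)) stop("matrix has no positive values to derive a floor from")
      eps <- 1e-6 * stats::median(pos)
    }
    warning(sprintf("floored %d zero intensit%s to %g", sum(zero),
                    if (sum(zero) == 1L) "y" else "ies", eps))
    x$values[zero] <- eps
  }
  x
}

#' A labelled set of 5'UTR sequences
#'
#' @param sequences named character vector of nucleotide sequences
#'   (alphabet ACGTN); names are gene ids, unique within the set.
#' @param label set label, e.g. "positive", "negative", "neutral".
#' @return an object of class `utr_set`.
#' @export
utr_set <- function(sequences, label = "utr") {
  if (!length(sequences)) stop("utr_set must contain at least one sequence")
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    stop("all sequences must be named by gene id")
  }
  dup <- unique(names(sequences)[duplicated(names(sequences))])
  if (length(dup)) stop("duplicated gene id in UTR set: ", paste(dup, collapse = ", "))
  sequences <- stats::setNames(toupper(as.character(sequences)), names(sequences))
  if (any(!nzchar(sequences))) {
    stop("empty sequence for record: ",
         paste(names(sequences)[!nzchar(sequences)], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("non-nucleotide characters (outside ACGTN) in record: ",
         paste(names(sequences)[bad], collapse = ", "))
  }
  structure(list(label = as.character(label), sequences = sequences),
            class = "utr_set")
}

#' @export
print.utr_set <- function(x, ...) {
  cat(sprintf("utr_set '%s': %d sequences (median length %d nt)\n", x$label,
              length(x$sequences), as.integer(stats::median(nchar(x$sequences)))))
  invisible(x)
}

#' @export
length.utr_set <- function(x) length(x$sequences)

#' Read a FASTA file of 5'UTR sequences
#'
#' Record ids (the first whitespace-delimited token of each header) are the
#' gene ids. Sequences are uppercased and validated against the ACGTN
#' alphabet.
#'
#' @param path FASTA file.
#' @param label label for the resulting [utr_set()].
#' @return a `utr_set`.
#' @export
read_fasta_utrs <- function(path, label = "utr") {
  seqs <- Biostrings::readBStringSet(path)
  if (!length(seqs)) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  utr_set(stats::setNames(as.character(seqs), ids), label)
}

#' Write a UTR set to FASTA
#'
#' @param x a [utr_set()].
#' @param path output FASTA path.
#' @export
write_fasta_utrs <- function(x, path) {
  stopifnot(inherits(x, "utr_set"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x$sequences), path)
  invisible(path)
}
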