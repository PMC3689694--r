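#' A collection of functional gene sets over a universe
#'
#' Category sets are restricted to the universe (the detected genes is the
#' standard choice of universe for over-representation analysis).
#'
#' @param sets named list of character vectors (category -> gene ids).
#' @param universe character vector of gene ids (non-empty).
#' @return a `gene_set_collection` list with `sets` and `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty")
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be a non-empty named list of gene id vectors")
  }
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Read gene sets from a two-column TSV or a GMT file
#'
#' Two-column format: header `category	gene_id`, one gene per row. GMT
#' format (detected by the `.gmt` extension): `category`, description,
#' then member genes, tab-separated.
#'
#' @param path annotation file.
#' @param universe gene universe for [gene_set_collection()].
#' @return a `gene_set_collection`.
#' @export
read_gene_sets <- function(path, universe) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- vapply(parts, `[`, character(1), 1L)
  } else {
    tab <- read_tsv(path)
    if (ncol(tab) < 2L) stop("gene set TSV needs columns category and gene_id")
    sets <- split(as.character(tab[[2L]]), as.character(tab[[1L]]))
  }
  gene_set_collection(sets, universe)
}

#' Hypergeometric over-representation analysis
#'
#' For each category, tests whether the gene list contains more category
#' members than expected when drawing `n` genes from the universe without
#' replacement: upper-tail hypergeometric p-value
#' `P(X >= k)` with `k` hits, category size `K`, list size `n`, universe
#' size `N`, followed by Benjamini-Hochberg adjustment across categories.
#' List genes outside the universe are dropped with a warning. This is a
#' generic open stand-in for proprietary pathway-analysis tools; it makes
#' no attempt to reproduce their curated statistics.
#'
#' @param gene_list character vector of genes of interest.
#' @param collection a [gene_set_collection()].
#' @return data.frame with columns `category`, `k`, `K`, `n`, `N`, `p`,
#'   `fdr`, sorted by increasing p.
#' @export
hypergeometric_enrichment <- function(gene_list, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  gene_list <- unique(as.character(gene_list))
  outside <- setdiff(gene_list, collection$universe)
  if (length(outside)) {
    warning(length(outside), " gene(s) outside the universe were dropped")
    gene_list <- setdiff(gene_list, outside)
  }
  N <- length(collection$universe)
  n <- length(gene_list)
  rows <- lapply(names(collection$sets), function(cat) {
    K <- length(collection$sets[[cat]])
    k <- length(intersect(gene_list, collection$sets[[cat]]))
    p <- if (K == 0L) 1 else stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cat, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$category), ]
  rownames(out) <- NULL
  out
}
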