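#' Published candidate-gene fold-change table
#'
#' The 35-row table of selected candidate mRNAs shipped with the package
#' (transcribed from a knockdown polysome-profiling study's printed
#' candidate table): per gene, the functional category, the polysomal and
#' total fold changes (knockdown/control), the printed relative
#' translatability (poly/tot, one decimal) and the GenBank accession.
#' Applying the default inclusive thresholds to the printed poly/tot
#' column yields 23 up and 12 down calls.
#'
#' Note the printed RR column is rounded to one decimal and for a few rows
#' (e.g. REV1: 1.0 / 0.2 printed as 4.5) disagrees with the quotient of
#' the printed fold changes, presumably because unrounded values were used
#' upstream; exact arithmetic checks are therefore meaningful only for
#' rows where quotient and printed value agree.
#'
#' @return data.frame with columns `gene_symbol`, `category`, `poly_rna`,
#'   `tot_rna`, `rr_printed`, `genbank`.
#' @export
candidate_table <- function() {
  read_tsv(system.file("extdata", "candidate_table.tsv",
                       package = "polytrans", mustWork = TRUE))
}
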