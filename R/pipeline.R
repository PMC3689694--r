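#' Pipeline configuration
#'
#' Collects every path and tuning parameter the end-to-end pipeline needs.
#' Only `matrix`, `design` and `out` are mandatory; the qPCR, UTR and
#' enrichment stages run when their inputs are supplied.
#'
#' @param matrix,design,flags expression / design / detection-flag TSVs
#'   (`flags` optional).
#' @param out output directory.
#' @param up,down,inclusive RR thresholds (see [thresholds()]).
#' @param ct optional Ct TSV; `reference`, `efficiency` configure the
#'   delta-delta-Ct stage.
#' @param utr_positive,utr_negative,utr_neutral optional 5'UTR FASTAs.
#' @param gene_sets optional gene-set annotation file (TSV or GMT).
#' @param gc_classes,length_classes histogram class counts for the UTR
#'   stage.
#' @param seed integer recorded in the run log (the analysis itself is
#'   deterministic).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(matrix, design, out, flags = NULL,
                            up = 1.5, down = 0.67, inclusive = TRUE,
                            ct = NULL, reference = "HPRT1", efficiency = 2,
                            utr_positive = NULL, utr_negative = NULL,
                            utr_neutral = NULL, gene_sets = NULL,
                            gc_classes = 11, length_classes = 21,
                            seed = 1L) {
  cfg <- list(matrix = matrix, design = design, flags = flags, out = out,
              thresholds = thresholds(up, down, inclusive),
              ct = ct, reference = reference, efficiency = efficiency,
              utr_positive = utr_positive, utr_negative = utr_negative,
              utr_neutral = utr_neutral, gene_sets = gene_sets,
              gc_classes = gc_classes, length_classes = length_classes,
              seed = as.integer(seed))
  for (key in c("matrix", "design", "flags", "ct", "utr_positive",
                "utr_negative", "utr_neutral", "gene_sets")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p)) {
      stop("config path for '", key, "' does not exist: ", p)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose keys match the [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

# run one stage with an error wrapper that names the stage
run_stage <- function(name, log, expr) {
  log(sprintf("stage %s: start", name))
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full translatome pipeline
#'
#' Executes detection filtering, per-fraction knockdown/control ratios,
#' relative translatability, thresholded calls, regulation classification
#' and class-count summaries, followed by the optional qPCR, UTR-feature
#' and enrichment stages. All outputs are written under the configured
#' output directory: `translatability.tsv`, `summary.json`, and (when run)
#' `qpcr_results.tsv`, `utr_features.tsv`, `utr_comparison.json`,
#' `enrichment.tsv`, plus `run.log` with the package version, the config
#' echo and the seed. Reruns with identical inputs produce byte-identical
#' TSV outputs.
#'
#' @param config a [pipeline_config()] (or a JSON path for one).
#' @return invisibly, a list with the classified table, the class summary
#'   and any optional stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out, "run.log")
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  log(sprintf("polytrans %s | seed %d",
              as.character(utils::packageVersion("polytrans")), config$seed))
  log(paste0("config: ", jsonlite::toJSON(
    config[c("matrix", "design", "flags", "ct", "out")], auto_unbox = TRUE,
    null = "null")))

  th <- config$thresholds
  inputs <- run_stage("read", log,
                      read_expression_table(config$matrix, config$design,
                                            config$flags))
  filtered <- run_stage("filter", log,
                        filter_detected(inputs$matrix, inputs$design))
  log(sprintf("filter: %d of %d genes retained", nrow(filtered$values),
              nrow(inputs$matrix$values)))
  tab <- run_stage("ratios", log, {
    poly <- condition_ratio(filtered, inputs$design, "polysomal")
    tot <- condition_ratio(filtered, inputs$design, "total")
    relative_translatability(poly, tot)
  })
  tab <- run_stage("classify", log, classify_table(tab, th))
  summary <- run_stage("summarize", log, summarize_classes(tab, th))
  run_stage("write", log, {
    write_translatability(tab, file.path(config$out, "translatability.tsv"))
    jsonlite::write_json(
      list(class_counts = as.list(summary$class_counts),
           n_expressed = summary$n_expressed,
           n_rr_modified = summary$n_rr_modified,
           n_tot_modified = summary$n_tot_modified,
           thresholds = list(up = th$up, down = th$down,
                             inclusive = th$inclusive)),
      file.path(config$out, "summary.json"), auto_unbox = TRUE, digits = NA)
  })

  result <- list(table = tab, summary = summary)

  if (!is.null(config$ct)) {
    result$qpcr <- run_stage("qpcr", log, {
      res <- qpcr_analysis(read_ct_table(config$ct), config$reference,
                           config$efficiency)
      write_tsv(res, file.path(config$out, "qpcr_results.tsv"))
      res
    })
  }

  utr_paths <- list(positive = config$utr_positive,
                    negative = config$utr_negative,
                    neutral = config$utr_neutral)
  if (any(!vapply(utr_paths, is.null, logical(1)))) {
    result$utr <- run_stage("utr", log, {
      sets <- lapply(names(utr_paths), function(nm) {
        if (is.null(utr_paths[[nm]])) NULL
        else read_fasta_utrs(utr_paths[[nm]], nm)
      })
      names(sets) <- names(utr_paths)
      cmp <- compare_utr_sets(sets$positive, sets$negative, sets$neutral,
                              config$gc_classes, config$length_classes)
      write_tsv(cmp$features, file.path(config$out, "utr_features.tsv"))
      jsonlite::write_json(
        list(stats = cmp$stats,
             distributions = lapply(cmp$distributions, function(d) {
               lapply(d, function(b) list(edges = b$edges, percent = b$percent))
             }),
             ks = lapply(cmp$ks, function(pair) {
               lapply(pair, function(k) k[c("D", "p", "n1", "n2", "mode")])
             })),
        file.path(config$out, "utr_comparison.json"), auto_unbox = TRUE,
        digits = NA)
      cmp
    })
  }

  if (!is.null(config$gene_sets)) {
    result$enrichment <- run_stage("enrich", log, {
      universe <- tab$gene_id
      coll <- read_gene_sets(config$gene_sets, universe)
      hits <- tab$gene_id[tab$call != "NOT_RETAINED"]
      enr <- hypergeometric_enrichment(hits, coll)
      write_tsv(enr, file.path(config$out, "enrichment.tsv"))
      enr
    })
  }

  log("done")
  writeLines(log_lines, log_path)
  invisible(result)
}

# minimal "--key value" / "--flag" argv parser for the CLI entry point
parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      out[[key]] <- TRUE
      i <- i + 1L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic input bundle), `quantify`
#' (matrix + design to classified translatability table), `qpcr`, `utr`,
#' `enrich`, and `run` (full pipeline from a JSON config or flags). Invoke
#' via `Rscript -e 'polytrans::pipeline_main()' <subcommand> --flag value ...`
#' or the installed `inst/cli/polytrans` script.
#'
#' @param args character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status 0 invisibly on success; errors propagate (nonzero
#'   exit under Rscript) with a stage-tagged message.
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    stop("usage: polytrans <simulate|quantify|qpcr|utr|enrich|run> [--flag value ...]")
  }
  cmd <- args[[1L]]
  opt <- parse_cli_args(args[-1L])
  num <- function(x, default) if (is.null(x)) default else as.numeric(x)
  switch(cmd,
    simulate = {
      cfg <- sim_config(n_genes = num(opt$genes, 2000),
                        replicates = num(opt$replicates, 2),
                        noise_sd_log2 = num(opt$noise, 0.1),
                        seed = num(opt$seed, 1))
      write_simulation(cfg, opt$out %||% "sim")
    },
    quantify = ,
    run = {
      cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
      else pipeline_config(matrix = opt$matrix, design = opt$design,
                           flags = opt$flags, out = opt$out %||% "results",
                           up = num(opt$up, 1.5), down = num(opt$down, 0.67),
                           inclusive = !isTRUE(opt$`strict-thresholds`),
                           ct = opt$ct, reference = opt$reference %||% "HPRT1",
                           efficiency = num(opt$efficiency, 2),
                           utr_positive = opt$positive,
                           utr_negative = opt$negative,
                           utr_neutral = opt$neutral,
                           gene_sets = opt$`gene-sets`,
                           seed = num(opt$seed, 1))
      run_pipeline(cfg)
    },
    qpcr = {
      res <- qpcr_analysis(read_ct_table(opt$ct),
                           reference = opt$reference %||% "HPRT1",
                           efficiency = num(opt$efficiency, 2))
      write_tsv(res, opt$out %||% "qpcr_results.tsv")
    },
    utr = {
      cmp <- compare_utr_sets(
        if (!is.null(opt$positive)) read_fasta_utrs(opt$positive, "positive"),
        if (!is.null(opt$negative)) read_fasta_utrs(opt$negative, "negative"),
        if (!is.null(opt$neutral)) read_fasta_utrs(opt$neutral, "neutral"))
      write_tsv(cmp$features, opt$out %||% "utr_features.tsv")
    },
    enrich = {
      tab <- read_tsv(opt$table)
      coll <- read_gene_sets(opt$`gene-sets`, tab$gene_id)
      hits <- tab$gene_id[tab$call != "NOT_RETAINED"]
      write_tsv(hypergeometric_enrichment(hits, coll),
                opt$out %||% "enrichment.tsv")
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}
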