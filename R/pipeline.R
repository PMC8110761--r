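## End-to-end orchestration: counts + design (+ optional tx2gene, annotation)
## -> per-trio DE tables, DEG summaries, transgressive sets and bias tests,
## inheritance profiles, reciprocal-cross comparison, shared sets, enrichment.

#' Assemble a pipeline run configuration
#'
#' @param counts count matrix or TSV path.
#' @param design design data.frame or TSV path.
#' @param tx2gene optional transcript-to-gene data.frame or TSV path; when
#'   given, `counts` is transcript-level and is aggregated first.
#' @param annotation optional annotation list (see [read_annotation()]) or
#'   `c(ortholog_path, term_path)`.
#' @param alpha FDR level for DE calls (default 0.01).
#' @param lfc_threshold log2 fold-change gate (default 1).
#' @param min_reads low-count filter threshold (default 10).
#' @param enrich_alpha FDR level for enrichment significance (default 0.05).
#' @param trios optional list of trios, each
#'   `list(P1 =, P2 =, H =, tissue =)`; default: every non-parental line
#'   crossed with the first two lines, per tissue.
#' @param out_dir output directory for TSV tables and the run log, or `NULL`
#'   for in-memory results only.
#' @param seed integer recorded in the log (the analysis itself is
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(counts, design, tx2gene = NULL, annotation = NULL,
                       alpha = 0.01, lfc_threshold = 1, min_reads = 10,
                       enrich_alpha = 0.05, trios = NULL, out_dir = NULL,
                       seed = 1L) {
  structure(list(counts = counts, design = design, tx2gene = tx2gene,
                 annotation = annotation, alpha = alpha,
                 lfc_threshold = lfc_threshold, min_reads = min_reads,
                 enrich_alpha = enrich_alpha, trios = trios,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a pipeline configuration from JSON
#'
#' JSON mirror of [run_config()]: path-valued fields `counts`, `design`,
#' `tx2gene`, `annotation` (two paths: ortholog, terms) plus the scalar
#' thresholds.
#'
#' @param path JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, j[intersect(names(j), names(formals(run_config)))])
}

## stage-context wrapper: any stage failure aborts naming the stage and
## leaving the log so far as a partial manifest
with_stage <- function(stage, expr, log) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s\npartial results:\n%s",
                 stage, conditionMessage(e),
                 paste(log(), collapse = "\n")), call. = FALSE)
  })
}

resolve_inputs <- function(config) {
  counts <- config$counts
  if (is.character(counts)) counts <- read_counts(counts)
  design <- config$design
  if (is.character(design)) design <- read_design(design)
  tx2gene <- config$tx2gene
  if (is.character(tx2gene)) tx2gene <- read_tx2gene(tx2gene)
  annotation <- config$annotation
  if (is.character(annotation) && length(annotation) == 2)
    annotation <- read_annotation(annotation[[1]], annotation[[2]])
  list(counts = counts, design = design, tx2gene = tx2gene,
       annotation = annotation)
}

default_trios <- function(design) {
  lines <- unique(design$line)
  if (length(lines) < 3) stop("design needs two parents and a hybrid line")
  parents <- lines[1:2]
  hybrids <- setdiff(lines, parents)
  out <- list()
  for (t in unique(design$tissue))
    for (h in hybrids)
      out[[length(out) + 1L]] <- list(P1 = parents[1], P2 = parents[2],
                                      H = h, tissue = t)
  out
}

#' Run the full hybrid-expression analysis
#'
#' For each trio (P1, P2, hybrid) x tissue: low-count filtering on the trio's
#' conditions, size factors, pooled dispersion, the three pairwise contrasts,
#' DEG percentages against the trio's expressed-gene universe, transgressive
#' sets with the over/under bias test, and the inheritance classification.
#' Reciprocal hybrids of the same tissue are then compared by profile
#' chi-square and their transgressive sets intersected; if annotation is
#' supplied, transgressive genes are tested for term enrichment against the
#' expressed background. All tables (and a run log recording seed, thresholds
#' and gene counts at each filter step) are written under `out_dir` when set.
#'
#' @param config a [run_config()] (or JSON path).
#' @return nested result list (per-trio `de`, `summary`, `transgressive`,
#'   `bias`, `inheritance`; per-tissue `reciprocal_comparison`, `shared`,
#'   `enrichment`; plus `log`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  inp <- resolve_inputs(config)
  counts <- inp$counts; design <- inp$design
  check_design(design)
  logline <- character(0)
  say <- function(...) logline <<- c(logline, sprintf(...))
  say("hybridexpr run: seed=%d alpha=%g lfc=%g min_reads=%g enrich_alpha=%g",
      config$seed, config$alpha, config$lfc_threshold, config$min_reads,
      config$enrich_alpha)
  if (!is.null(inp$tx2gene)) {
    say("transcript aggregation: %d transcripts", nrow(counts))
    counts <- with_stage("aggregate_transcripts",
                         aggregate_transcripts(counts, inp$tx2gene),
                         function() logline)
  }
  say("input genes: %d, samples: %d", nrow(counts), ncol(counts))
  trios <- if (is.null(config$trios)) default_trios(design) else config$trios

  results <- list(trios = list(), tissues = list())
  for (trio in trios) {
    tname <- sprintf("%s_vs_%s_%s_%s", trio$H, trio$P1, trio$P2, trio$tissue)
    sub <- design[design$tissue == trio$tissue &
                    design$line %in% c(trio$P1, trio$P2, trio$H), ]
    tc <- counts[, sub$sample_id, drop = FALSE]
    flt <- with_stage(paste0("filter:", tname),
                      filter_low_counts(tc, sub, min_reads = config$min_reads),
                      function() logline)
    expressed <- nrow(flt$counts)
    say("[%s] expressed %d / %d genes (removed %d)", tname, expressed,
        nrow(tc), length(flt$removed))
    sf <- with_stage(paste0("size_factors:", tname),
                     estimate_size_factors(flt$counts), function() logline)
    disp <- with_stage(paste0("dispersion:", tname),
                       estimate_dispersion(flt$counts, sf, sub),
                       function() logline)
    cond <- function(l) condition_label(l, trio$tissue)
    de <- with_stage(paste0("de:", tname), list(
      HP1 = run_contrast(flt$counts, sf, disp, sub,
                         c(cond(trio$H), cond(trio$P1)),
                         config$lfc_threshold, config$alpha),
      HP2 = run_contrast(flt$counts, sf, disp, sub,
                         c(cond(trio$H), cond(trio$P2)),
                         config$lfc_threshold, config$alpha),
      P1P2 = run_contrast(flt$counts, sf, disp, sub,
                          c(cond(trio$P1), cond(trio$P2)),
                          config$lfc_threshold, config$alpha)),
                     function() logline)
    summary <- do.call(rbind, lapply(names(de), function(nm) {
      d <- de[[nm]]
      n_over <- sum(d$call == "over"); n_under <- sum(d$call == "under")
      data.frame(contrast = nm, expressed = expressed,
                 n_deg = n_over + n_under,
                 pct_deg = 100 * (n_over + n_under) / expressed,
                 n_over = n_over, n_under = n_under,
                 stringsAsFactors = FALSE)
    }))
    for (i in seq_len(nrow(summary)))
      say("[%s] %s: %d DEGs / %d expressed (%.2f%%; %d over, %d under)",
          tname, summary$contrast[i], summary$n_deg[i], expressed,
          summary$pct_deg[i], summary$n_over[i], summary$n_under[i])
    trans <- transgressive_sets(de$HP1, de$HP2)
    bias <- if (length(trans$over_both) + length(trans$under_both) >= 1)
      bias_test(length(trans$over_both), length(trans$under_both)) else NULL
    if (!is.null(bias))
      say("[%s] transgressive: %d over, %d under; bias X2=%.3f p=%.3g",
          tname, bias$n_over, bias$n_under, bias$statistic, bias$p.value)
    inh <- with_stage(paste0("inheritance:", tname),
                      classify_all(de$HP1, de$HP2, de$P1P2),
                      function() logline)
    results$trios[[tname]] <- list(trio = trio, de = de, summary = summary,
                                   expressed_genes = de$HP1$gene_id,
                                   transgressive = trans, bias = bias,
                                   inheritance = inh)
  }

  for (t in unique(vapply(trios, `[[`, "", "tissue"))) {
    tt <- Filter(function(x) x$trio$tissue == t, results$trios)
    tissue_res <- list()
    if (length(tt) >= 2) {
      tissue_res$reciprocal_comparison <- tryCatch(
        compare_profiles(tt[[1]]$inheritance$profile,
                         tt[[2]]$inheritance$profile),
        error = function(e) {
          say("[%s] reciprocal profile comparison skipped: %s", t,
              conditionMessage(e))
          NULL
        })
      if (!is.null(tissue_res$reciprocal_comparison))
        say("[%s] reciprocal profile X2=%.3f df=%d p=%.3g", t,
            tissue_res$reciprocal_comparison$statistic,
            tissue_res$reciprocal_comparison$df,
            tissue_res$reciprocal_comparison$p.value)
      over <- lapply(tt, function(x) x$transgressive$over_both)
      under <- lapply(tt, function(x) x$transgressive$under_both)
      names(over) <- names(under) <- names(tt)
      if (sum(lengths(over)) > 0) tissue_res$shared_over <- shared_sets(over)
      if (sum(lengths(under)) > 0) tissue_res$shared_under <- shared_sets(under)
    }
    if (!is.null(inp$annotation)) {
      tissue_res$enrichment <- lapply(tt, function(x) {
        study <- c(x$transgressive$over_both, x$transgressive$under_both)
        if (!length(study)) return(NULL)
        with_stage(paste0("enrichment:", t),
                   enrich(study, x$expressed_genes, inp$annotation,
                          alpha = config$enrich_alpha), function() logline)
      })
    }
    results$tissues[[t]] <- tissue_res
  }
  results$log <- logline

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    for (nm in names(results$trios)) {
      r <- results$trios[[nm]]
      for (cn in names(r$de))
        write_de_table(r$de[[cn]], file.path(od, sprintf("de_%s_%s.tsv", nm, cn)))
      write.table(r$summary, file.path(od, sprintf("summary_%s.tsv", nm)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(r$inheritance$genes,
                  file.path(od, sprintf("inheritance_%s.tsv", nm)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(r$inheritance$profile,
                  file.path(od, sprintf("profile_%s.tsv", nm)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      ts <- r$transgressive
      gs <- data.frame(
        label = rep(c("over_both", "under_both"),
                    c(length(ts$over_both), length(ts$under_both))),
        gene_id = c(ts$over_both, ts$under_both), stringsAsFactors = FALSE)
      write.table(gs, file.path(od, sprintf("transgressive_%s.tsv", nm)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (t in names(results$tissues)) {
      tr <- results$tissues[[t]]
      for (nm in intersect(c("shared_over", "shared_under"), names(tr)))
        write.table(tr[[nm]], file.path(od, sprintf("%s_%s.tsv", nm, t)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(tr$enrichment))
        for (en in names(tr$enrichment))
          if (!is.null(tr$enrichment[[en]]))
            write.table(tr$enrichment[[en]],
                        file.path(od, sprintf("enrichment_%s.tsv", en)),
                        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(logline, file.path(od, "run.log"))
  }
  results
}
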