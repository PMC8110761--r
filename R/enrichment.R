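## Ortholog-mediated term enrichment: hypergeometric over-representation of
## annotation terms in a study set against an expressed-gene background.

#' Translate focal gene ids through an ortholog map
#'
#' @param genes character vector of focal gene ids.
#' @param annotation list with `ortholog_map` (gene_id, ortholog_id; NA for
#'   unmapped) as produced by [simulate_annotation()] or [read_annotation()].
#' @return list: `mapped` (data.frame gene_id, ortholog_id for mapped genes),
#'   `unmapped` (gene ids without ortholog). Counts satisfy
#'   |mapped| + |unmapped| = |genes|.
#' @export
map_orthologs <- function(genes, annotation) {
  om <- annotation$ortholog_map
  idx <- match(genes, om$gene_id)
  orth <- om$ortholog_id[idx]
  ok <- !is.na(orth)
  list(mapped = data.frame(gene_id = genes[ok], ortholog_id = orth[ok],
                           stringsAsFactors = FALSE),
       unmapped = genes[!ok])
}

#' Hypergeometric term over-representation
#'
#' Genes are first translated to ortholog space; per term the enrichment
#' p-value is the upper-tail hypergeometric probability `P(X >= k)` with
#' `X ~ Hypergeom(N, K, n)` (N background size, K background genes with the
#' term, n mapped study size, k study genes with the term), BH-adjusted across
#' terms. Terms annotating identical background gene sets are merged into one
#' row (exact-duplicate collapse), recorded in `merged_terms`. A two-sided
#' Fisher exact test is available by flag.
#'
#' @param study character vector of study gene ids (must map into the
#'   background).
#' @param background character vector of background (expressed) gene ids.
#' @param annotation list with `ortholog_map` and `term_map`.
#' @param alpha significance level on padj for the `significant` flag.
#' @param two_sided use `fisher.test` (two-sided) instead of the upper tail.
#' @return data.frame sorted by padj: term_id, term_name, k, n, K, N,
#'   fold_enrichment, pvalue, padj, significant, merged_terms.
#' @export
enrich <- function(study, background, annotation, alpha = 0.05,
                   two_sided = FALSE) {
  ms <- map_orthologs(unique(study), annotation)
  mb <- map_orthologs(unique(background), annotation)
  study_o <- unique(ms$mapped$ortholog_id)
  bg_o <- unique(mb$mapped$ortholog_id)
  if (length(setdiff(study_o, bg_o)) > 0)
    stop("study set is not a subset of the background after ortholog mapping")
  n <- length(study_o); N <- length(bg_o)
  if (n < 1) stop("no study gene maps to an ortholog")
  tm <- annotation$term_map
  tm <- tm[tm$ortholog_id %in% bg_o, , drop = FALSE]
  if (nrow(tm) == 0)
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), fold_enrichment = numeric(),
                      pvalue = numeric(), padj = numeric(),
                      significant = logical(), merged_terms = character(),
                      stringsAsFactors = FALSE))
  sets <- split(tm$ortholog_id, tm$term_id)
  sets <- lapply(sets, unique)
  term_names <- tm$term_name[match(names(sets), tm$term_id)]
  ## exact-duplicate collapse: terms with identical background gene sets
  key <- vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1))
  first <- !duplicated(key)
  merged <- vapply(key[first], function(k0) {
    others <- names(sets)[key == k0]
    if (length(others) > 1) paste(others[-1], collapse = ",") else ""
  }, character(1))
  sets <- sets[first]; term_names <- term_names[first]
  K <- lengths(sets)
  k <- vapply(sets, function(s) sum(study_o %in% s), integer(1))
  if (two_sided) {
    pvalue <- mapply(function(ki, Ki) {
      stats::fisher.test(matrix(c(ki, Ki - ki, n - ki, N - Ki - n + ki), 2))$p.value
    }, k, K)
  } else {
    pvalue <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  out <- data.frame(term_id = names(sets), term_name = term_names,
                    k = k, n = n, K = K, N = N,
                    fold_enrichment = (k / n) / (K / N),
                    pvalue = pvalue, padj = adjust_fdr(pvalue),
                    merged_terms = unname(merged),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$significant <- out$padj < alpha
  out[order(out$padj, out$pvalue, out$term_id), , drop = FALSE]
}

#' Read annotation tables from TSV
#'
#' `ortholog_path`: two columns (gene_id, ortholog_id); `term_path`: three
#' columns (ortholog_id, term_id, term_name).
#'
#' @param ortholog_path,term_path TSV paths.
#' @return list with `ortholog_map` and `term_map`.
#' @export
read_annotation <- function(ortholog_path, term_path) {
  om <- read.delim(ortholog_path, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  names(om)[1:2] <- c("gene_id", "ortholog_id")
  if (anyDuplicated(om$gene_id))
    stop("ortholog map is not single-valued: ",
         om$gene_id[duplicated(om$gene_id)][1])
  tm <- read.delim(term_path, sep = "\t", quote = "", stringsAsFactors = FALSE)
  names(tm)[1:min(3, ncol(tm))] <- c("ortholog_id", "term_id",
                                     "term_name")[1:min(3, ncol(tm))]
  if (is.null(tm$term_name)) tm$term_name <- tm$term_id
  list(ortholog_map = om, term_map = tm)
}
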