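## Tabular IO: count matrices, sample designs, transcript-to-gene maps;
## transcript aggregation and the low-count filter.
##
## TSV dialect: tab-separated, UTF-8, header row, no quoting; gene identifiers
## are opaque strings.

#' Read a gene x sample count matrix from TSV
#'
#' First column holds gene identifiers, remaining columns one sample each.
#' Counts must be non-negative integers; estimated fractional counts are
#' rejected unless `round_counts = TRUE`.
#'
#' @param path TSV file path.
#' @param round_counts round fractional counts instead of erroring.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path, round_counts = FALSE) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("count TSV needs a gene column plus >= 1 sample")
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene identifier(s): ",
         paste(unique(genes[duplicated(genes)])[1:min(3, sum(duplicated(genes)))],
               collapse = ", "))
  if (anyDuplicated(names(df)[-1]))
    stop("duplicate sample identifier(s) in header")
  m <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1,
              dimnames = list(genes, names(df)[-1]))
  for (j in 2:ncol(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric count '%s' at line %d, sample '%s'",
                   df[[j]][bad[1]], bad[1] + 1L, names(df)[j]))
    m[, j - 1] <- v
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative count %s at line %d (gene '%s')",
                 format(m[neg[1, 1], neg[1, 2]]), neg[1, 1] + 1L,
                 genes[neg[1, 1]]))
  if (round_counts) m <- round(m)
  frac <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(frac))
    stop(sprintf("non-integer count %s at line %d (gene '%s'); use round_counts = TRUE",
                 format(m[frac[1, 1], frac[1, 2]]), frac[1, 1] + 1L,
                 genes[frac[1, 1]]))
  storage.mode(m) <- "integer"
  check_counts(m)
}

#' Write a count matrix as TSV
#' @param counts matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  check_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample design table
#'
#' Columns: sample_id, line, tissue, replicate.
#' @param path TSV path.
#' @export
read_design <- function(path) {
  df <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
  check_design(df)
  df
}

#' @rdname read_design
#' @param design a design data.frame.
#' @export
write_design <- function(design, path) {
  check_design(design)
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcript-to-gene map
#'
#' Two-column TSV (transcript_id, gene_id); every transcript mapped exactly
#' once.
#' @param path TSV path.
#' @export
read_tx2gene <- function(path) {
  df <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
  names(df)[1:2] <- c("transcript_id", "gene_id")
  if (anyDuplicated(df$transcript_id))
    stop("transcript mapped more than once: ",
         df$transcript_id[duplicated(df$transcript_id)][1])
  df
}

#' Aggregate transcript-level counts to gene level
#'
#' Gene counts are the per-sample sums of their transcripts' counts, so
#' per-sample totals are conserved exactly.
#'
#' @param tx_counts transcript x sample count matrix.
#' @param tx2gene data.frame (transcript_id, gene_id) covering all transcripts.
#' @return gene x sample count matrix.
#' @export
aggregate_transcripts <- function(tx_counts, tx2gene) {
  unmapped <- setdiff(rownames(tx_counts), tx2gene$transcript_id)
  if (length(unmapped))
    stop("unmapped transcript(s): ",
         paste(utils::head(unmapped, 5), collapse = ", "),
         if (length(unmapped) > 5) sprintf(" (and %d more)", length(unmapped) - 5))
  g <- tx2gene$gene_id[match(rownames(tx_counts), tx2gene$transcript_id)]
  m <- rowsum(tx_counts, group = g, reorder = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Remove genes weakly covered in every condition
#'
#' A gene is excluded iff its summed count across replicates is below
#' `min_reads` in every condition (line x tissue); genes clearing the bar in
#' any one condition are kept untouched. With `per = "sample"` the threshold
#' is applied to individual samples instead of condition totals.
#'
#' @param counts gene x sample count matrix.
#' @param design sample design covering all samples.
#' @param min_reads threshold (default 10).
#' @param per `"condition"` (replicates summed) or `"sample"`.
#' @return list with `counts` (retained genes) and `removed` (gene ids).
#' @export
filter_low_counts <- function(counts, design, min_reads = 10,
                              per = c("condition", "sample")) {
  per <- match.arg(per)
  check_design(design)
  miss <- setdiff(colnames(counts), design$sample_id)
  if (length(miss))
    stop("samples absent from design: ", paste(miss, collapse = ", "))
  design <- design[match(colnames(counts), design$sample_id), ]
  if (per == "condition") {
    cond <- condition_label(design$line, design$tissue)
    sums <- t(rowsum(t(counts), group = cond))   # genes x conditions
  } else {
    sums <- counts
  }
  keep <- apply(sums, 1, max) >= min_reads
  list(counts = counts[keep, , drop = FALSE],
       removed = rownames(counts)[!keep])
}
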