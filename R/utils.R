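## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @importFrom stats median pnorm pchisq phyper rnbinom rpois rlnorm runif
#'   rbinom chisq.test prop.test lm coef var setNames
#' @importFrom utils read.delim write.table
NULL

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

## row-wise variance of a numeric matrix (one pass, no deps)
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

## condition label used throughout: line and tissue joined by '.'
condition_label <- function(line, tissue) paste(line, tissue, sep = ".")

## samples of a design belonging to one condition
condition_samples <- function(design, condition) {
  design$sample_id[condition_label(design$line, design$tissue) == condition]
}

check_design <- function(design) {
  need <- c("sample_id", "line", "tissue", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("sample design lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design", call. = FALSE)
  invisible(design)
}

## counts matrix validator: integral, non-negative, unique dimnames
check_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must carry gene (row) and sample (column) names",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers in count matrix", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers in count matrix", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("non-integer counts (use round_counts = TRUE at IO to permit rounding)",
         call. = FALSE)
  invisible(counts)
}
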