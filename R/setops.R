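## Transgressive-gene set logic: filtering against both parents, testing the
## over/under balance, and shared-DEG Venn regions across crosses.

#' Genes transgressive relative to both parents
#'
#' @param de_HP1,de_HP2 called DE tables (hybrid vs each parent) over the same
#'   gene universe.
#' @return list of character vectors `over_both` (called over in both
#'   comparisons) and `under_both` (under in both); disjoint by construction.
#' @export
transgressive_sets <- function(de_HP1, de_HP2) {
  if (length(de_HP1$gene_id) != length(de_HP2$gene_id) ||
      length(setdiff(de_HP1$gene_id, de_HP2$gene_id)) > 0)
    stop("the two DE tables must cover the same gene universe")
  de_HP2 <- de_HP2[match(de_HP1$gene_id, de_HP2$gene_id), ]
  list(over_both = de_HP1$gene_id[de_HP1$call == "over" & de_HP2$call == "over"],
       under_both = de_HP1$gene_id[de_HP1$call == "under" & de_HP2$call == "under"])
}

#' Proportion test for over/under-expression bias
#'
#' One-sample two-sided test of proportion 0.5 on (n_over, n_under), the
#' chi-square form of `prop.test`: with Yates continuity correction the
#' statistic is `sum((|obs - exp| - 0.5)^2 / exp)` over the two cells, the
#' correction capped so it never exceeds |obs - exp|; p from chi-square with
#' one degree of freedom.
#'
#' The correction is applied as written (not capped at |obs - exp|), so the
#' balanced case (n_over = n_under) yields a small positive statistic rather
#' than `prop.test`'s hard zero; the two agree whenever |obs - exp| >= 0.5,
#' i.e. everywhere except exact balance.
#'
#' @param n_over,n_under non-negative counts, not both zero.
#' @param correct apply the continuity correction (default TRUE, the
#'   behaviour of the proportion test family).
#' @return list: n_over, n_under, statistic, df (= 1), p.value.
#' @export
bias_test <- function(n_over, n_under, correct = TRUE) {
  if (n_over < 0 || n_under < 0) stop("counts must be non-negative")
  n <- n_over + n_under
  if (n < 1) stop("need at least one over- or underexpressed gene")
  obs <- c(n_over, n_under)
  expd <- c(n / 2, n / 2)
  yates <- if (correct) 0.5 else 0
  stat <- sum((abs(obs - expd) - yates)^2 / expd)
  list(n_over = n_over, n_under = n_under, statistic = stat, df = 1L,
       p.value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Membership-region (Venn) counts for 2-5 gene sets
#'
#' @param sets named list of 2-5 character vectors (duplicates removed).
#' @return data.frame with one row per nonempty membership region: `region`
#'   (set names joined by `&`), `degree`, `count`. Regions partition the
#'   union.
#' @export
shared_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 5)
    stop("shared_sets takes between 2 and 5 gene sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("S", seq_along(sets))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  region <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  tab <- table(region)
  out <- data.frame(region = names(tab),
                    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$degree, out$region), , drop = FALSE]
}
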