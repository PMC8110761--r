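## Six-category inheritance-mode classification of hybrid gene expression from
## three pairwise DE calls, plus chi-square comparison of category profiles.

INHERITANCE_CATEGORIES <- c("conserved", "additive", "P1_dominant",
                            "P2_dominant", "overdominant", "underdominant",
                            "ambiguous")

#' Classify hybrid inheritance mode from three pairwise calls
#'
#' Calls are signed three-valued DE outcomes at the shared thresholds
#' (twofold, FDR 0.01): `c1` = hybrid vs P1, `c2` = hybrid vs P2, `cp` = P1 vs
#' P2, each one of `"+"`, `"-"`, `"0"`. The mapping:
#' \describe{
#'   \item{conserved}{hybrid differs from neither parent (c1 = c2 = 0).}
#'   \item{overdominant}{hybrid above both parents (c1 = c2 = +).}
#'   \item{underdominant}{hybrid below both parents (c1 = c2 = -).}
#'   \item{additive}{parents differ, hybrid intermediate: c1 and c2 nonzero
#'     with opposite signs, cp nonzero with sign(cp) = sign(c2).}
#'   \item{P1_dominant}{hybrid matches P1 and tracks it away from P2: c1 = 0,
#'     c2 nonzero, cp nonzero with sign(cp) = sign(c2).}
#'   \item{P2_dominant}{hybrid matches P2: c2 = 0, c1 nonzero, cp nonzero with
#'     sign(cp) = -sign(c1).}
#'   \item{ambiguous}{any residual pattern (sign-inconsistent threshold
#'     artifacts); reported separately, never merged.}
#' }
#'
#' @param c1,c2,cp character vectors over `"+"`, `"-"`, `"0"` (recycled).
#' @return character vector of categories.
#' @export
classify_trio <- function(c1, c2, cp) {
  n <- max(length(c1), length(c2), length(cp))
  c1 <- rep_len(as.character(c1), n)
  c2 <- rep_len(as.character(c2), n)
  cp <- rep_len(as.character(cp), n)
  allowed <- c("+", "-", "0")
  if (!all(c(c1, c2, cp) %in% allowed))
    stop("calls must be one of '+', '-', '0'")
  opp <- function(x) c(`+` = "-", `-` = "+", `0` = "0")[x]
  out <- rep("ambiguous", n)
  out[c1 == "0" & c2 == "0"] <- "conserved"
  out[c1 == "+" & c2 == "+"] <- "overdominant"
  out[c1 == "-" & c2 == "-"] <- "underdominant"
  out[c1 != "0" & c2 != "0" & c1 == opp(c2) & cp != "0" & cp == c2] <- "additive"
  out[c1 == "0" & c2 != "0" & cp != "0" & cp == c2] <- "P1_dominant"
  out[c2 == "0" & c1 != "0" & cp != "0" & cp == opp(c1)] <- "P2_dominant"
  out
}

## DE call -> signed three-valued call
call_to_sign <- function(call) {
  c(over = "+", under = "-", ns = "0")[call]
}

#' Classify every gene from three DE result tables
#'
#' The three tables must cover the same (post-filter) gene universe; the
#' hybrid-vs-parent tables are oriented hybrid over parent and the parental
#' table P1 over P2.
#'
#' @param de_HP1,de_HP2,de_P1P2 DE tables from [run_contrast()] (with `call`).
#' @return list with `genes` (per-gene calls, log2fc triple, category) and
#'   `profile` (category, n, fraction).
#' @export
classify_all <- function(de_HP1, de_HP2, de_P1P2) {
  u1 <- de_HP1$gene_id; u2 <- de_HP2$gene_id; u3 <- de_P1P2$gene_id
  sd12 <- length(union(setdiff(u1, u2), setdiff(u2, u1)))
  sd13 <- length(union(setdiff(u1, u3), setdiff(u3, u1)))
  if (sd12 > 0 || sd13 > 0)
    stop(sprintf(
      "gene universes differ (symmetric difference: %d vs HP2, %d vs P1P2)",
      sd12, sd13))
  de_HP2 <- de_HP2[match(u1, de_HP2$gene_id), ]
  de_P1P2 <- de_P1P2[match(u1, de_P1P2$gene_id), ]
  c1 <- unname(call_to_sign(de_HP1$call))
  c2 <- unname(call_to_sign(de_HP2$call))
  cp <- unname(call_to_sign(de_P1P2$call))
  genes <- data.frame(gene_id = u1, c1 = c1, c2 = c2, cp = cp,
                      log2fc_HP1 = de_HP1$log2fc, log2fc_HP2 = de_HP2$log2fc,
                      log2fc_P1P2 = de_P1P2$log2fc,
                      category = classify_trio(c1, c2, cp),
                      stringsAsFactors = FALSE)
  tab <- table(factor(genes$category, INHERITANCE_CATEGORIES))
  profile <- data.frame(category = names(tab), n = as.integer(tab),
                        fraction = as.integer(tab) / nrow(genes),
                        stringsAsFactors = FALSE)
  list(genes = genes, profile = profile)
}

#' Pearson chi-square comparison of two category profiles
#'
#' Builds the 2 x k contingency table of category counts (categories whose
#' total is zero in both profiles are dropped symmetrically and reported) and
#' applies Pearson's chi-square test without continuity correction,
#' df = k - 1.
#'
#' @param a,b named count vectors (or profile data.frames with `category`,
#'   `n`) over the same category set.
#' @return list: statistic, df, p.value, dropped (categories removed).
#' @export
compare_profiles <- function(a, b) {
  as_counts <- function(x) {
    if (is.data.frame(x)) setNames(x$n, x$category) else x
  }
  a <- as_counts(a); b <- as_counts(b)
  cats <- union(names(a), names(b))
  av <- setNames(rep(0, length(cats)), cats); av[names(a)] <- a
  bv <- setNames(rep(0, length(cats)), cats); bv[names(b)] <- b
  if (sum(av) == 0 || sum(bv) == 0)
    stop("a profile with zero total cannot be compared")
  dropped <- cats[av + bv == 0]
  keep <- av + bv > 0
  av <- av[keep]; bv <- bv[keep]
  if (length(av) < 2) stop("fewer than two informative categories")
  ct <- suppressWarnings(chisq.test(rbind(av, bv), correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, dropped = dropped)
}
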