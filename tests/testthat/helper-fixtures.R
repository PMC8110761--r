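## Shared fixture builders; everything is generated in code under fixed seeds.

## two-group toy design: lines A/B, one tissue, `reps` replicates each
toy_design <- function(reps = 3, lines = c("A", "B"), tissue = "t") {
  d <- expand.grid(replicate = seq_len(reps), line = lines,
                   stringsAsFactors = FALSE)
  d$tissue <- tissue
  d$sample_id <- sprintf("%s_%s_r%d", d$line, d$tissue, d$replicate)
  d[, c("sample_id", "line", "tissue", "replicate")]
}

## count matrix with given rows (list of per-sample vectors) and names
toy_counts <- function(rows, samples) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), samples)
  storage.mode(m) <- "integer"
  m
}

unit_sf <- function(samples) stats::setNames(rep(1, length(samples)), samples)

## an all-conserved single-tissue simulation config
conserved_config <- function(n_genes, n_replicates = 2, dispersion = 0.05,
                             seed = 1, depth_factors = NULL) {
  props <- list(t = c(conserved = 1, additive = 0, P1_dominant = 0,
                      P2_dominant = 0, overdominant = 0, underdominant = 0))
  sim_config(n_genes = n_genes, n_replicates = n_replicates, tissues = "t",
             category_proportions = props, dispersion = dispersion,
             depth_factors = depth_factors, seed = seed)
}

## run the three contrasts of one trio and classify, returning everything
run_trio <- function(sim, tissue, hybrid = "H_fwd", alpha = 0.01,
                     lfc = 1, min_reads = 10) {
  des <- sim$design[sim$design$tissue == tissue &
                      sim$design$line %in% c("P1", "P2", hybrid), ]
  flt <- filter_low_counts(sim$counts[, des$sample_id, drop = FALSE], des,
                           min_reads = min_reads)
  sf <- estimate_size_factors(flt$counts)
  disp <- estimate_dispersion(flt$counts, sf, des)
  cond <- function(l) paste(l, tissue, sep = ".")
  de_HP1 <- run_contrast(flt$counts, sf, disp, des,
                         c(cond(hybrid), cond("P1")), lfc, alpha)
  de_HP2 <- run_contrast(flt$counts, sf, disp, des,
                         c(cond(hybrid), cond("P2")), lfc, alpha)
  de_P1P2 <- run_contrast(flt$counts, sf, disp, des,
                          c(cond("P1"), cond("P2")), lfc, alpha)
  list(de_HP1 = de_HP1, de_HP2 = de_HP2, de_P1P2 = de_P1P2,
       classified = classify_all(de_HP1, de_HP2, de_P1P2))
}

## independently coded 27-pattern lookup for the trio classifier, written
## directly from the category definitions (hybrid-vs-P1, hybrid-vs-P2, P1-vs-P2)
oracle_trio_table <- function() {
  tab <- expand.grid(c1 = c("+", "-", "0"), c2 = c("+", "-", "0"),
                     cp = c("+", "-", "0"), stringsAsFactors = FALSE)
  expected <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    c1 <- tab$c1[i]; c2 <- tab$c2[i]; cp <- tab$cp[i]
    expected[i] <-
      if (c1 == "0" && c2 == "0") "conserved"
      else if (c1 == "+" && c2 == "+") "overdominant"
      else if (c1 == "-" && c2 == "-") "underdominant"
      else if (c1 == "+" && c2 == "-" && cp == "-") "additive"   # P2 > H > P1
      else if (c1 == "-" && c2 == "+" && cp == "+") "additive"   # P1 > H > P2
      else if (c1 == "0" && c2 == "+" && cp == "+") "P1_dominant"
      else if (c1 == "0" && c2 == "-" && cp == "-") "P1_dominant"
      else if (c1 == "+" && c2 == "0" && cp == "-") "P2_dominant"
      else if (c1 == "-" && c2 == "0" && cp == "+") "P2_dominant"
      else "ambiguous"
  }
  tab$expected <- expected
  tab
}
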