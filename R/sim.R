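## Synthetic experiment generator: parent/parent/reciprocal-hybrid count data
## with known per-gene inheritance-mode ground truth.

CATEGORIES <- c("conserved", "additive", "P1_dominant", "P2_dominant",
                "overdominant", "underdominant")

default_category_proportions <- function(under_bias = c(ovary = 0.5, testis = 0.675)) {
  ## Ovary: ~2% misregulation; testis: ~17% with a strong dominant component and
  ## an underdominant excess, emulating the reported tissue asymmetry.
  trans <- c(ovary = 0.0006, testis = 0.051)
  mk <- function(tissue, additive, p1, p2) {
    under <- trans[[tissue]] * under_bias[[tissue]]
    over <- trans[[tissue]] - under
    p <- c(additive = additive, P1_dominant = p1, P2_dominant = p2,
           overdominant = over, underdominant = under)
    c(conserved = 1 - sum(p), p)
  }
  list(ovary  = mk("ovary", additive = 0.0005, p1 = 0.018, p2 = 0.002),
       testis = mk("testis", additive = 0.0145, p1 = 0.095, p2 = 0.012))
}

#' Simulation configuration for a hybrid-transcriptome experiment
#'
#' Describes a two-parent / reciprocal-hybrid RNA-seq experiment with
#' negative-binomial counts and a configurable mixture of inheritance modes.
#' Defaults emulate the scale of a *Drosophila* gonad study: 11,654 genes, two
#' biological replicates per condition, ovary and testis tissues, a mildly
#' misregulated ovary and a strongly misregulated testis with an
#' underexpression bias among transgressive genes (67.5% underdominant).
#'
#' @param n_genes number of genes.
#' @param n_replicates biological replicates per condition.
#' @param tissues character vector of tissue labels.
#' @param lines condition (line) labels: two parents then the two reciprocal
#'   hybrids, in that order.
#' @param category_proportions named list (one element per tissue) of
#'   six-category probability vectors over
#'   `c("conserved","additive","P1_dominant","P2_dominant","overdominant","underdominant")`;
#'   each must sum to 1 within 1e-9. Default built from `under_bias`.
#' @param parental_divergence_log2 |log2(P1/P2)| for parent-diverged genes.
#' @param transgressive_shift_log2 log2 deviation of transgressive hybrids
#'   beyond both parents.
#' @param under_bias named fraction (per tissue) of transgressive genes that
#'   are underdominant; used only to build the default proportions.
#' @param mean_log_mu `c(meanlog, sdlog)` of the log-normal baseline mean;
#'   baselines are floored at 1 expected read.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2); scalar
#'   or per-gene vector; 0 gives Poisson counts.
#' @param depth_factors per-sample positive depth multipliers, recycled over
#'   samples, or `NULL` to draw Uniform(0.5, 2) at simulation time.
#' @param independent_reciprocal draw the two reciprocal hybrids' modes
#'   independently (within the gene's parental-divergence state)?
#' @param seed integer seed; all randomness flows from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 11654L,
                       n_replicates = 2L,
                       tissues = c("ovary", "testis"),
                       lines = c("P1", "P2", "H_fwd", "H_rev"),
                       category_proportions = NULL,
                       parental_divergence_log2 = 2,
                       transgressive_shift_log2 = 2,
                       under_bias = c(ovary = 0.5, testis = 0.675),
                       mean_log_mu = c(meanlog = log(200), sdlog = 1.5),
                       dispersion = 0.05,
                       depth_factors = NULL,
                       independent_reciprocal = TRUE,
                       seed = 1L) {
  if (!is.numeric(n_genes) || n_genes < 1) stop_config("n_genes", "must be >= 1")
  if (!is.numeric(n_replicates) || n_replicates < 1)
    stop_config("n_replicates", "must be >= 1")
  if (length(lines) != 4L) stop_config("lines", "must name P1, P2 and two hybrids")
  if (is.null(category_proportions)) {
    if (!all(tissues %in% c("ovary", "testis"))) {
      ub <- rep_len(if (is.null(names(under_bias))) under_bias else mean(under_bias),
                    length(tissues))
      names(ub) <- tissues
      defaults <- lapply(tissues, function(t) {
        p <- default_category_proportions(setNames(rep(ub[[t]], 2),
                                                   c("ovary", "testis")))$testis
        p
      })
      names(defaults) <- tissues
      category_proportions <- defaults
    } else {
      category_proportions <- default_category_proportions(under_bias)[tissues]
    }
  }
  for (t in tissues) {
    p <- category_proportions[[t]]
    if (is.null(p) || !all(CATEGORIES %in% names(p)))
      stop_config("category_proportions",
                  sprintf("must give all six categories for tissue '%s'", t))
    if (any(p < -1e-12))
      stop_config("category_proportions", "has a negative fraction")
    if (abs(sum(p) - 1) > 1e-9)
      stop_config("category_proportions",
                  sprintf("must sum to 1 for tissue '%s' (got %.12f)", t, sum(p)))
  }
  if (parental_divergence_log2 < 0)
    stop_config("parental_divergence_log2", "must be >= 0")
  if (transgressive_shift_log2 < 0)
    stop_config("transgressive_shift_log2", "must be >= 0")
  if (any(dispersion < 0)) stop_config("dispersion", "must be >= 0")
  if (!is.null(depth_factors) && any(depth_factors <= 0))
    stop_config("depth_factors", "must all be > 0")
  structure(list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    tissues = tissues, lines = lines,
    category_proportions = category_proportions,
    parental_divergence_log2 = parental_divergence_log2,
    transgressive_shift_log2 = transgressive_shift_log2,
    mean_log_mu = mean_log_mu, dispersion = dispersion,
    depth_factors = depth_factors,
    independent_reciprocal = isTRUE(independent_reciprocal),
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d genes, %d replicates, tissues: %s\n",
              x$n_genes, x$n_replicates, paste(x$tissues, collapse = ", ")))
  invisible(x)
}

## Draw hybrid modes conditional on the parental-divergence state.
## Diverged genes can be additive or parent-dominant; equal-parent genes can be
## conserved or transgressive. Marginals equal the configured proportions.
draw_truth_tissue <- function(cfg, tissue) {
  n <- cfg$n_genes
  p <- cfg$category_proportions[[tissue]]
  p_div <- p[["additive"]] + p[["P1_dominant"]] + p[["P2_dominant"]]
  diverged <- runif(n) < p_div
  div_cats <- c("additive", "P1_dominant", "P2_dominant")
  eq_cats <- c("conserved", "overdominant", "underdominant")
  draw_one <- function() {
    cat <- character(n)
    nd <- sum(diverged)
    if (nd > 0)
      cat[diverged] <- sample(div_cats, nd, replace = TRUE,
                              prob = p[div_cats] / p_div)
    ne <- n - nd
    if (ne > 0)
      cat[!diverged] <- sample(eq_cats, ne, replace = TRUE,
                               prob = p[eq_cats] / (1 - p_div))
    cat
  }
  cat_fwd <- draw_one()
  cat_rev <- if (cfg$independent_reciprocal) draw_one() else cat_fwd

  mu0 <- pmax(rlnorm(n, cfg$mean_log_mu[[1]], cfg$mean_log_mu[[2]]), 1)
  d <- cfg$parental_divergence_log2
  s <- cfg$transgressive_shift_log2
  hi_is_p1 <- runif(n) < 0.5    # which parent carries the higher expression
  half <- ifelse(diverged, d / 2, 0)
  mu_P1 <- mu0 * 2^(ifelse(hi_is_p1, half, -half))
  mu_P2 <- mu0 * 2^(ifelse(hi_is_p1, -half, half))
  hybrid_mu <- function(cat) {
    mu <- mu0                                  # conserved & additive: log midpoint
    mu[cat == "P1_dominant"] <- mu_P1[cat == "P1_dominant"]
    mu[cat == "P2_dominant"] <- mu_P2[cat == "P2_dominant"]
    ov <- cat == "overdominant"
    un <- cat == "underdominant"
    mu[ov] <- pmax(mu_P1, mu_P2)[ov] * 2^s
    mu[un] <- pmin(mu_P1, mu_P2)[un] * 2^(-s)
    mu
  }
  data.frame(
    gene_id = sprintf("G%05d", seq_len(n)),
    tissue = tissue,
    true_category = cat_fwd,
    true_category_rev = cat_rev,
    mu_P1 = mu_P1, mu_P2 = mu_P2,
    mu_H_fwd = hybrid_mu(cat_fwd), mu_H_rev = hybrid_mu(cat_rev),
    stringsAsFactors = FALSE)
}

#' Simulate a parent/hybrid count experiment with known ground truth
#'
#' Draws per-gene condition means according to the configured inheritance-mode
#' mixture, then samples counts independently per gene and sample from
#' NB(mean = depth_factor x true_mu, dispersion alpha). Identical seeds give
#' bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (genes x samples integer matrix), `design`
#'   (sample_id, line, tissue, replicate), and `truth` (gene_id, tissue,
#'   true_category, true_category_rev, mu_P1, mu_P2, mu_H_fwd, mu_H_rev).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, config)
  set.seed(config$seed)
  truth <- do.call(rbind, lapply(config$tissues, function(t)
    draw_truth_tissue(config, t)))

  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        line = config$lines, tissue = config$tissues,
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_r%d", design$line, design$tissue,
                              design$replicate)
  design <- design[, c("sample_id", "line", "tissue", "replicate")]

  nsamp <- nrow(design)
  depth <- if (is.null(config$depth_factors)) runif(nsamp, 0.5, 2)
           else rep_len(config$depth_factors, nsamp)
  names(depth) <- design$sample_id

  alpha <- rep_len(config$dispersion, config$n_genes)
  mu_col <- c(P1 = "mu_P1", P2 = "mu_P2", H_fwd = "mu_H_fwd", H_rev = "mu_H_rev")
  names(mu_col) <- config$lines

  counts <- matrix(0L, nrow = config$n_genes, ncol = nsamp,
                   dimnames = list(truth$gene_id[truth$tissue == config$tissues[1]],
                                   design$sample_id))
  for (j in seq_len(nsamp)) {
    tt <- truth[truth$tissue == design$tissue[j], ]
    mu <- depth[j] * tt[[mu_col[[design$line[j]]]]]
    ## alpha = 0 degenerates to Poisson (size -> Inf handled via a huge cap)
    y <- rnbinom(config$n_genes, mu = mu, size = 1 / pmax(alpha, 1e-12))
    counts[, j] <- as.integer(y)
  }
  attr(counts, "depth_factors") <- depth
  list(counts = counts, design = design, truth = truth)
}

#' Simulate an ortholog map and gene-to-term annotation
#'
#' Each focal gene receives a reference-species ortholog with probability
#' `mapping_rate` (default 0.85, emulating partial ortholog coverage); each
#' term annotates a random ortholog subset whose size is drawn from
#' `genes_per_term`.
#'
#' @param n_genes number of focal genes (ids `G00001`...).
#' @param n_terms number of terms (>= 1).
#' @param genes_per_term function(n) returning n positive set sizes, or a
#'   fixed integer; default Uniform{5,...,50}.
#' @param mapping_rate per-gene probability of having an ortholog.
#' @param seed integer seed.
#' @return list with `ortholog_map` (gene_id, ortholog_id; unmapped genes have
#'   NA) and `term_map` (ortholog_id, term_id, term_name).
#' @export
simulate_annotation <- function(n_genes, n_terms, genes_per_term = NULL,
                                mapping_rate = 0.85, seed = 1L) {
  if (n_terms < 1) stop_config("n_terms", "must be >= 1")
  if (mapping_rate < 0 || mapping_rate > 1)
    stop_config("mapping_rate", "must be in [0, 1]")
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  mapped <- runif(n_genes) < mapping_rate
  orth <- ifelse(mapped, sprintf("REF%05d", seq_len(n_genes)), NA_character_)
  size_fun <- if (is.function(genes_per_term)) genes_per_term
              else if (is.numeric(genes_per_term))
                function(n) rep_len(genes_per_term, n)
              else function(n) sample(5:50, n, replace = TRUE)
  pool <- orth[mapped]
  sizes <- pmin(pmax(as.integer(size_fun(n_terms)), 1L), length(pool))
  term_ids <- sprintf("T%04d", seq_len(n_terms))
  term_map <- do.call(rbind, lapply(seq_len(n_terms), function(i) {
    data.frame(ortholog_id = sample(pool, sizes[i]),
               term_id = term_ids[i],
               term_name = sprintf("term %d", i),
               stringsAsFactors = FALSE)
  }))
  list(ortholog_map = data.frame(gene_id = genes, ortholog_id = orth,
                                 stringsAsFactors = FALSE),
       term_map = term_map)
}

#' Tabulate true inheritance categories
#'
#' @param truth a truth table from [simulate_experiment()].
#' @param hybrid count the forward (`"fwd"`) or reciprocal (`"rev"`) hybrid's
#'   category.
#' @return data.frame (tissue, category, n); per tissue, n sums to n_genes.
#' @export
truth_summary <- function(truth, hybrid = c("fwd", "rev")) {
  hybrid <- match.arg(hybrid)
  col <- if (hybrid == "fwd") "true_category" else "true_category_rev"
  out <- as.data.frame(table(tissue = truth$tissue,
                             category = factor(truth[[col]], CATEGORIES)),
                       stringsAsFactors = FALSE)
  names(out)[3] <- "n"
  out[order(out$tissue, match(out$category, CATEGORIES)), , drop = FALSE]
}
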