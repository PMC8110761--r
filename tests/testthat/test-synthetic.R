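test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 300, seed = 11)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_experiment(sim_config(n_genes = 300, seed = 12))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("zero-divergence all-conserved world has identical condition means", {
  props <- list(ovary = c(conserved = 1, additive = 0, P1_dominant = 0,
                          P2_dominant = 0, overdominant = 0, underdominant = 0))
  cfg <- sim_config(n_genes = 100, tissues = "ovary",
                    category_proportions = props,
                    parental_divergence_log2 = 0, seed = 2)
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$truth$mu_P1 == sim$truth$mu_P2))
  expect_true(all(sim$truth$mu_P1 == sim$truth$mu_H_fwd))
  expect_true(all(sim$truth$mu_P1 == sim$truth$mu_H_rev))
})

test_that("invalid configurations are rejected naming the field", {
  props <- list(t = c(conserved = 0.9, additive = 0.2, P1_dominant = 0,
                      P2_dominant = 0, overdominant = 0, underdominant = 0))
  expect_error(sim_config(tissues = "t", category_proportions = props),
               "category_proportions")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(depth_factors = c(1, 0)), "depth_factors")
  expect_error(sim_config(n_replicates = 0), "n_replicates")
  expect_error(simulate_annotation(10, 0), "n_terms")
})

test_that("counts follow the configured NB moments", {
  ## 10 replicates so the CLT bound on the mean estimator is meaningful
  cfg <- sim_config(n_genes = 2000, n_replicates = 10, tissues = "t",
                    category_proportions = list(
                      t = c(conserved = 1, additive = 0, P1_dominant = 0,
                            P2_dominant = 0, overdominant = 0,
                            underdominant = 0)),
                    dispersion = 0.05, depth_factors = 1, seed = 5)
  sim <- simulate_experiment(cfg)
  idx <- sim$design$line == "P1"
  mu <- sim$truth$mu_P1
  m <- rowMeans(sim$counts[, idx])
  se <- sqrt((mu + 0.05 * mu^2) / sum(idx))
  within3 <- abs(m - mu) <= 3 * se
  expect_gt(mean(within3), 0.985)   # 3-sigma bound, NB skew allowed for

  ## mean/variance law: pooled empirical variance tracks mu + alpha mu^2
  v <- apply(sim$counts[, idx], 1, var)
  hi <- mu > 100
  ratio <- v[hi] / (mu[hi] + 0.05 * mu[hi]^2)
  expect_lt(abs(median(ratio) - 1), 0.15)
})

test_that("simulated annotation honours the mapping rate", {
  ann <- simulate_annotation(500, 20, mapping_rate = 1, seed = 1)
  expect_true(all(!is.na(ann$ortholog_map$ortholog_id)))
  ## 576 genes at the observed ortholog coverage 440/576: 3-sigma binomial band
  rate <- 440 / 576
  ann2 <- simulate_annotation(576, 5, mapping_rate = rate, seed = 3)
  n_mapped <- sum(!is.na(ann2$ortholog_map$ortholog_id))
  sigma <- sqrt(576 * rate * (1 - rate))
  expect_lt(abs(n_mapped - 440), 3 * sigma)
  ## deterministic under seed
  expect_identical(ann2, simulate_annotation(576, 5, mapping_rate = rate,
                                             seed = 3))
})

test_that("truth_summary conserves gene totals and matches the mixture", {
  cfg <- sim_config(n_genes = 8000, seed = 8)
  sim <- simulate_experiment(cfg)
  prof <- truth_summary(sim$truth)
  sums <- tapply(prof$n, prof$tissue, sum)
  expect_true(all(sums == 8000))
  for (t in c("ovary", "testis")) {
    p <- cfg$category_proportions[[t]]
    obs <- setNames(prof$n[prof$tissue == t], prof$category[prof$tissue == t])
    for (cat in names(p)) {
      sigma <- sqrt(8000 * p[[cat]] * (1 - p[[cat]]))
      expect_lt(abs(obs[[cat]] - 8000 * p[[cat]]), 3 * sigma + 1e-9,
                label = sprintf("%s/%s count deviation", t, cat))
    }
  }
  ## the reciprocal hybrid draw follows the same mixture
  prof_rev <- truth_summary(sim$truth, hybrid = "rev")
  expect_true(all(tapply(prof_rev$n, prof_rev$tissue, sum) == 8000))
})

test_that("larger transgressive shifts do not reduce transgressive recovery", {
  rates <- sapply(c(1.5, 3), function(shift) {
    cfg <- sim_config(n_genes = 1500, n_replicates = 3,
                      transgressive_shift_log2 = shift, dispersion = 0.05,
                      seed = 77)
    sim <- simulate_experiment(cfg)
    out <- run_trio(sim, "testis", alpha = 0.05)
    tr <- sim$truth[sim$truth$tissue == "testis", ]
    m <- merge(out$classified$genes[, c("gene_id", "category")],
               tr[, c("gene_id", "true_category")], by = "gene_id")
    trans <- m$true_category %in% c("overdominant", "underdominant")
    mean(m$category[trans] == m$true_category[trans])
  })
  expect_gte(rates[2], rates[1])
})
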