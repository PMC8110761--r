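test_that("size factors: symmetry, hand-computed ratios, scale equivariance", {
  m <- toy_counts(list(g1 = c(10L, 10L, 10L), g2 = c(50L, 50L, 50L)),
                  c("s1", "s2", "s3"))
  expect_equal(estimate_size_factors(m), c(s1 = 1, s2 = 1, s3 = 1))

  ## column 2 = 2 x column 1: ratios to the geometric-mean reference
  m2 <- toy_counts(list(g1 = c(10L, 20L), g2 = c(30L, 60L), g3 = c(7L, 14L)),
                  c("s1", "s2"))
  sf <- estimate_size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))  # hand computation

  ## a global rescaling cancels in the ratios to the rescaled reference:
  ## size factors are invariant (the per-sample ratios are what matters)
  sf_scaled <- estimate_size_factors(m2 * 3L)
  expect_equal(unname(sf_scaled), unname(sf))

  ## no gene nonzero everywhere -> error suggesting the fallback
  m3 <- toy_counts(list(g1 = c(5L, 0L), g2 = c(0L, 5L)), c("s1", "s2"))
  expect_error(estimate_size_factors(m3), "poscounts")
  expect_silent(estimate_size_factors(m3, fallback = "poscounts"))
})

test_that("dispersion estimation recovers the generating alpha", {
  ## Poisson truth: median estimate must stay near zero
  cfgP <- conserved_config(2000, n_replicates = 2, dispersion = 0,
                           depth_factors = 1, seed = 4)
  simP <- simulate_experiment(cfgP)
  dispP <- estimate_dispersion(simP$counts,
                               estimate_size_factors(simP$counts), simP$design)
  expect_lte(median(dispP), 0.01)

  ## alpha = 0.1 with 6 replicates: median within [0.05, 0.2]
  cfg <- conserved_config(2000, n_replicates = 6, dispersion = 0.1,
                          depth_factors = 1, seed = 3)
  sim <- simulate_experiment(cfg)
  disp <- estimate_dispersion(sim$counts, estimate_size_factors(sim$counts),
                              sim$design)
  expect_gte(median(disp), 0.05)
  expect_lte(median(disp), 0.2)

  ## constant counts within conditions: zero variance -> (near-)zero alpha
  des <- toy_design(reps = 3)
  mc <- toy_counts(list(g1 = c(20L, 20L, 20L, 80L, 80L, 80L),
                        g2 = c(5L, 5L, 5L, 5L, 5L, 5L)), des$sample_id)
  d0 <- estimate_dispersion(mc, unit_sf(des$sample_id), des)
  expect_true(all(d0 < 1e-6))
})

test_that("NB Wald test: exact small cases", {
  des <- toy_design(reps = 3)
  sf <- unit_sf(des$sample_id)

  ## identical groups: log2fc = 0, p = 1
  m_eq <- toy_counts(list(g1 = rep(40L, 6)), des$sample_id)
  r <- nb_wald_test(m_eq, sf, 0.1, des, c("A.t", "B.t"))
  expect_equal(r$log2fc, 0)
  expect_equal(r$pvalue, 1)

  ## normalized means 100 vs 25: log2fc = 2 exactly
  m4 <- toy_counts(list(g1 = c(90L, 100L, 110L, 20L, 25L, 30L)),
                   des$sample_id)
  r4 <- nb_wald_test(m4, sf, 0.05, des, c("A.t", "B.t"))
  expect_equal(r4$log2fc, 2)

  ## all-zero gene: flagged, p = 1, lfc = 0
  m0 <- toy_counts(list(g0 = rep(0L, 6), g1 = c(9L, 10L, 11L, 39L, 40L, 41L)),
                   des$sample_id)
  r0 <- nb_wald_test(m0, sf, 0.05, des, c("A.t", "B.t"))
  expect_true(r0$all_zero[1])
  expect_equal(r0$pvalue[1], 1)
  expect_equal(r0$log2fc[1], 0)
  ## zero-group floor keeps the other gene's fold change finite
  mz <- toy_counts(list(g = c(0L, 0L, 0L, 39L, 40L, 41L)), des$sample_id)
  rz <- nb_wald_test(mz, sf, 0.05, des, c("A.t", "B.t"))
  expect_true(is.finite(rz$log2fc))
  expect_equal(rz$log2fc, log2(0.5 / 40))

  ## single-replicate condition: permitted with a warning
  des1 <- toy_design(reps = 1)
  m1 <- toy_counts(list(g1 = c(10L, 20L)), des1$sample_id)
  expect_warning(nb_wald_test(m1, unit_sf(des1$sample_id), 0.05, des1,
                              c("A.t", "B.t")), "single replicate")
})

test_that("swapping the contrast negates log2fc and preserves p exactly", {
  cfg <- conserved_config(300, n_replicates = 3, seed = 9)
  sim <- simulate_experiment(cfg)
  sf <- estimate_size_factors(sim$counts)
  fwd <- nb_wald_test(sim$counts, sf, 0.05, sim$design, c("H_fwd.t", "P1.t"))
  rev <- nb_wald_test(sim$counts, sf, 0.05, sim$design, c("P1.t", "H_fwd.t"))
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(rev$pvalue, fwd$pvalue)
})

test_that("null p-values are approximately uniform", {
  cfg <- conserved_config(5000, n_replicates = 2, dispersion = 0.05, seed = 11)
  sim <- simulate_experiment(cfg)
  flt <- filter_low_counts(sim$counts, sim$design)
  sf <- estimate_size_factors(flt$counts)
  r <- nb_wald_test(flt$counts, sf, 0.05, sim$design, c("H_fwd.t", "P1.t"))
  ks <- suppressWarnings(stats::ks.test(r$pvalue, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  ## order preservation, bounds, and agreement with the stats implementation
  set.seed(1)
  p <- runif(200)^2
  padj <- adjust_fdr(p)
  expect_true(all(padj >= p))
  expect_true(all(diff(padj[order(p)]) >= -1e-12))
  expect_equal(padj, stats::p.adjust(p, "BH"))
  ## NA passthrough and validation
  expect_equal(adjust_fdr(c(0.1, NA))[2], NA_real_)
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the twofold / FDR rule gates calls on both criteria", {
  tbl <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(1.5, 0.9, 3, -2),
                    padj = c(0.005, 0.005, 0.02, 0.001))
  out <- call_deg(tbl)
  expect_equal(out$call, c("over", "ns", "ns", "under"))
  expect_error(call_deg(tbl[, c("gene_id", "log2fc")]), "padj")
})

test_that("power is monotone in the true effect size", {
  des <- toy_design(reps = 3)
  sf <- unit_sf(des$sample_id)
  called <- sapply(c(0, 1, 2, 3), function(lfc) {
    set.seed(100 + lfc)
    n <- 400
    muA <- rep(200, n); muB <- muA * 2^lfc
    m <- cbind(matrix(rnbinom(3 * n, mu = muA, size = 20), n),
               matrix(rnbinom(3 * n, mu = muB, size = 20), n))
    dimnames(m) <- list(sprintf("g%03d", 1:n), des$sample_id)
    r <- run_contrast(m, sf, 0.05, des, c("B.t", "A.t"))
    mean(r$call != "ns")
  })
  expect_true(all(diff(called) >= 0))
})
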