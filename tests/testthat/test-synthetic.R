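small_cfg <- function(seed, n_probes = 600, n_genes = 500, n_de_probes = 40,
                      ...) {
  sim_config(seed = seed, n_probes = n_probes, n_genes = n_genes,
             n_de_probes = n_de_probes, n_snps = 12,
             ld_block_sizes = rep(4, 3), ...)
}

test_that("the generator is deterministic given its seed", {
  s1 <- simulate_cohort(small_cfg(99))
  s2 <- simulate_cohort(small_cfg(99))
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$geno$dosage, s2$geno$dosage)
  expect_identical(s1$truth$de, s2$truth$de)
  s3 <- simulate_cohort(small_cfg(100))
  expect_false(identical(s1$expr, s3$expr))
})

test_that("group sizes, covariate structure and truth bookkeeping hold", {
  sim <- simulate_cohort(small_cfg(7))
  expect_equal(sum(sim$samples$status == "case"), 27)
  expect_equal(sum(sim$samples$status == "control"), 26)
  expect_true(all(is.na(
    sim$samples$age_at_onset[sim$samples$status == "control"])))
  # cases have shorter post-mortem intervals on average (lognormal shift)
  expect_lt(mean(sim$samples$pmi[sim$samples$status == "case"]),
            mean(sim$samples$pmi[sim$samples$status == "control"]))
  # truth identifies hub, mediators, eSNP target among TFBS DE probes
  tr <- sim$truth
  expect_true(all(c(tr$hub_probe, tr$mediators$probe_id,
                    tr$esnp$probe_id) %in%
                    tr$de$probe_id[tr$de$tfbs & tr$de$de]))
  expect_false(tr$esnp$probe_id %in% tr$mediators$probe_id)
  # raw intensities are strictly positive
  expect_true(all(as.matrix(sim$expr[, -1]) > 0))
  # cases sit above controls on the liability score by construction
  sc <- tr$liability$score
  expect_gt(min(sc[sim$samples$status == "case"]),
            max(sc[sim$samples$status == "control"]) - 1e-12)
})

test_that("a null configuration yields calibrated false-positive rates", {
  cfg <- small_cfg(13, n_probes = 2000, n_genes = 1800, n_de_probes = 60,
                   de_effect_log2 = 0, hub_a = 0, hub_b = 0,
                   hub_c_direct = 0, esnp_beta_geno = 0,
                   esnp_beta_interaction = 0)
  # with all effects zeroed, the DE scan should reject ~ alpha
  sim <- simulate_cohort(cfg)
  expr <- collapse_replicates(sim$expr)
  logged <- expr
  for (j in seq.int(2, ncol(logged))) logged[[j]] <- log2(logged[[j]])
  de <- run_diffexpr(logged, sim$samples)
  expect_lt(abs(mean(de$p < 0.05) - 0.05), 0.012)
})

test_that("LD genotypes hit their MAFs and correlation structure", {
  # r = 0: mean absolute off-diagonal correlation is small at n = 2000
  g0 <- simulate_ld_genotypes(2000, rep(4, 3), r = 0,
                              mafs = rep(0.3, 12), seed = 61)
  cc <- cor(as.matrix(as.data.frame(g0$dosage[, -1])))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.05)

  # maf = 0.5 recovered within 0.02 at n = 10000
  g5 <- simulate_ld_genotypes(10000, 2, r = 0, mafs = c(0.5, 0.5), seed = 62)
  expect_equal(g5$maf$maf, c(0.5, 0.5), tolerance = 0.02 / 0.5)

  # near-perfect LD with equal MAFs collapses a block to one effective test
  g99 <- simulate_ld_genotypes(400, 4, r = 1 - 1e-9, mafs = rep(0.3, 4),
                               seed = 63)
  expect_equal(effective_tests(g99)$m_eff, 1L)

  expect_error(simulate_ld_genotypes(10, 2, r = 1, mafs = c(0.3, 0.3),
                                     seed = 1), "r must")
  expect_error(simulate_ld_genotypes(10, 2, r = 0.5, mafs = 0.3, seed = 1),
               "length")
})

test_that("DE truth assignment meets its expected count and odds ratio", {
  withr::with_seed(64, {
    probes <- tibble::tibble(probe_id = sprintf("P%04d", 1:3000),
                             tfbs = rbinom(3000, 1, 0.32) == 1)
    counts <- numeric(300); ors <- numeric(300)
    for (i in 1:300) {
      tr <- simulate_de_truth(probes, 200, 2, 0.78, 0.66, 0.4)
      counts[i] <- sum(tr$de)
      tab <- table(tr$tfbs, tr$de)
      ors[i] <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
    }
  })
  expect_equal(mean(counts), 200, tolerance = 0.02)
  expect_equal(mean(ors), 2, tolerance = 0.05)
})

test_that("status betas for true DE probes are estimated without bias", {
  errs <- c()
  for (i in 1:8) {
    sim <- simulate_cohort(small_cfg(700 + i, n_probes = 1200,
                                     n_genes = 1000, n_de_probes = 60))
    expr <- collapse_replicates(sim$expr)
    logged <- expr
    for (j in seq.int(2, ncol(logged))) logged[[j]] <- log2(logged[[j]])
    de <- run_diffexpr(logged, sim$samples)
    tr <- sim$truth$de[sim$truth$de$effect != 0, ]
    est <- de$beta_status[match(tr$probe_id, de$probe_id)]
    errs <- c(errs, est - tr$effect)
  }
  cfg <- small_cfg(1)
  expect_lt(abs(mean(errs)), cfg$noise_sd / sqrt(53))
})

test_that("simulated study statistics carry the meta-analysis structure", {
  st <- simulate_study_stats(paste0("rs", 1:30), n_studies = 6,
                             true_beta = 0, seed = 65)
  expect_length(st, 6)
  expect_true(all(purrr::map_int(st, nrow) == 30))
  one <- st[[1]]
  expect_true(all(is.na(one$rsq[one$geno_status == "G"])))
  expect_true(all(one$se > 0))
  expect_true(any(purrr::map_lgl(st, ~ any(.x$rsq < 0.30, na.rm = TRUE))))
})
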