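test_that("dominant coding is correct and idempotent", {
  expect_equal(dominant_code(c(0, 1, 2, NA)), c(0, 1, 1, NA))
  expect_equal(dominant_code(dominant_code(c(0, 1, 2, NA))),
               c(0, 1, 1, NA))
  expect_equal(dominant_code(rep(0, 5)), rep(0, 5))
  expect_error(dominant_code(c(0, 3)), "dosage")
})

sim_esnp_data <- function(n = 50, maf = 0.3, beta_geno = 0,
                          beta_case_extra = 0, noise_sd = 0.25, seed = 1) {
  withr::with_seed(seed, {
    samples <- make_samples(n %/% 2, n - n %/% 2, seed = seed + 1)
    d <- dominant_code(rbinom(n, 2, maf))
    while (length(unique(d)) < 2) d <- dominant_code(rbinom(n, 2, maf))
    st <- samples$status == "case"
    y <- rnorm(n, 8, noise_sd) + (beta_geno + beta_case_extra * st) * d
    list(y = y, d = d, samples = samples)
  })
}

test_that("the 2-df model estimates, stratifies, and matches the LRT at large n", {
  dat <- sim_esnp_data(n = 200, beta_geno = -0.4, beta_case_extra = -0.3,
                       seed = 30)
  fit <- fit_2df(dat$y, dat$d, dat$samples)
  expect_lt(fit$p_2df, 1e-6)
  expect_lt(abs(fit$beta_geno - (-0.4)), 0.2)
  expect_lt(abs(fit$beta_interaction - (-0.3)), 0.25)
  expect_lt(fit$case$p, fit$control$p)

  # F-based and likelihood-ratio p agree at n = 200 for a moderate signal
  dat2 <- sim_esnp_data(n = 200, beta_geno = -0.08, seed = 36)
  fit_mod <- fit_2df(dat2$y, dat2$d, dat2$samples)
  expect_gt(fit_mod$p_2df, 1e-4)
  expect_lt(abs(fit_mod$p_2df - fit_mod$p_lrt) / fit_mod$p_2df, 0.1)

  # monomorphic within one stratum: stratified fit missing, joint fit falls
  # back to the 1-df genotype model
  d2 <- dat$d
  d2[dat$samples$status == "control"] <- 0
  d2[dat$samples$status == "case"][1:40] <- 1
  fit2 <- fit_2df(dat$y, d2, dat$samples)
  expect_true(is.na(fit2$control$beta))
  expect_true(is.na(fit2$beta_interaction))
  expect_false(is.na(fit2$p_2df))
  expect_equal(fit2$test_df, 1)

  expect_error(fit_2df(dat$y, rep(0, 200), dat$samples), "monomorphic")
})

test_that("the 2-df p-value is invariant to affine covariate rescaling", {
  dat <- sim_esnp_data(n = 60, beta_geno = -0.3, seed = 31)
  fit <- fit_2df(dat$y, dat$d, dat$samples)
  rescaled <- dat$samples
  rescaled$rin <- (rescaled$rin - 5) / 2
  rescaled$pmi <- rescaled$pmi / 24
  rescaled$age_at_death <- rescaled$age_at_death - 70
  fit2 <- fit_2df(dat$y, dat$d, rescaled)
  expect_equal(fit$p_2df, fit2$p_2df, tolerance = 1e-10)
  expect_equal(fit$beta_geno, fit2$beta_geno, tolerance = 1e-10)
})

test_that("a case-specific effect yields smaller case-stratum p-values", {
  hits <- 0
  for (i in 1:200) {
    dat <- sim_esnp_data(n = 50, beta_geno = 0, beta_case_extra = -0.73,
                         seed = 3000 + i)
    fit <- fit_2df(dat$y, dat$d, dat$samples)
    if (!is.na(fit$case$p) && !is.na(fit$control$p) &&
        fit$case$p < fit$control$p) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.90)
})

test_that("effective tests counts principal components as specified", {
  # exactly uncorrelated columns: every component is needed
  withr::with_seed(32, raw <- matrix(rnorm(400), 40, 10))
  ortho <- prcomp(raw, center = TRUE, scale. = TRUE)$x  # orthogonal scores
  colnames(ortho) <- paste0("rs", 1:10)
  expect_equal(effective_tests(ortho)$m_eff, 10L)

  # two perfectly correlated SNPs collapse to one test
  withr::with_seed(33, x <- rbinom(100, 2, 0.3))
  pair <- cbind(rs1 = x, rs2 = x)
  expect_equal(effective_tests(pair)$m_eff, 1L)

  # blocked matrix against an independent PCA oracle
  g <- simulate_ld_genotypes(300, block_sizes = c(5, 5, 5, 5), r = 0.8,
                             mafs = rep(c(0.2, 0.3, 0.4, 0.25), 5), seed = 34)
  m <- as.matrix(as.data.frame(g$dosage[, -1]))
  res <- effective_tests(g)
  ev_oracle <- prcomp(m, scale. = TRUE)$sdev^2
  oracle <- which(cumsum(ev_oracle) >= 0.995 * sum(ev_oracle))[1]
  expect_equal(res$m_eff, as.integer(oracle))

  # constant SNPs are excluded with a warning
  m2 <- cbind(m[, 1:3], rs_const = 1)
  expect_warning(res2 <- effective_tests(m2), "constant")
  expect_equal(res2$m_nominal, 3L)

  # blocked counting sums per-region counts
  blocks <- rep(1:4, each = 5)
  res_blocked <- effective_tests(g, blocks = blocks)
  expect_gte(res_blocked$m_eff, res$m_eff)
})

test_that("m_eff decreases as within-block LD tightens", {
  meffs <- vapply(c(0, 0.5, 0.9, 0.99), function(r) {
    g <- simulate_ld_genotypes(500, block_sizes = rep(4, 5), r = r,
                               mafs = rep(0.3, 20), seed = 35)
    effective_tests(g)$m_eff
  }, integer(1))
  expect_true(all(diff(meffs) <= 0))
  expect_equal(meffs[1], 20L)  # independent SNPs at r = 0
})

test_that("corrected thresholds follow the Bonferroni and Sidak forms", {
  expect_equal(corrected_threshold(1, 0.05, "bonferroni"), 0.05)
  expect_equal(corrected_threshold(1, 0.05, "sidak"), 0.05)
  expect_equal(corrected_threshold(34, 0.05), 0.05 / 34)
  expect_equal(corrected_threshold(34, 0.05), 1.47e-3, tolerance = 1e-2)
  expect_equal(corrected_threshold(933, 0.05), 5.36e-5, tolerance = 1e-3)
  expect_lt(corrected_threshold(10, 0.05, "sidak"),
            corrected_threshold(1, 0.05, "sidak"))
})
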