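test_that("weighted Z combination matches hand values and Stouffer", {
  one <- weighted_z_meta(0.05, "+", 100)
  expect_equal(one$z, qnorm(1 - 0.025), tolerance = 1e-12)
  expect_equal(one$p, 0.05, tolerance = 1e-12)

  two <- weighted_z_meta(c(0.05, 0.05), c("+", "+"), c(80, 80))
  expect_equal(two$z, 2 * qnorm(0.975) / sqrt(2), tolerance = 1e-12)
  expect_equal(two$z, 2.772, tolerance = 1e-3)
  expect_equal(two$p, 0.0056, tolerance = 1e-2)

  # opposite directions with equal evidence cancel
  cancel <- weighted_z_meta(c(0.05, 0.05), c("+", "-"), c(80, 80))
  expect_equal(cancel$z, 0)
  expect_equal(cancel$p, 1)

  # '?' studies contribute nothing; all-excluded returns a missing result
  with_q <- weighted_z_meta(c(0.05, 0.05, 0.001), "++?", c(80, 80, 9999))
  expect_equal(with_q$z, two$z)
  expect_equal(with_q$n_studies_used, 2L)
  expect_true(is.na(weighted_z_meta(0.05, "?", 100)$z))

  # equal sample sizes reduce to unweighted Stouffer (direct-sum oracle)
  withr::with_seed(50, {
    p <- runif(6, 0.001, 0.999)
    dir <- sample(c("+", "-"), 6, replace = TRUE)
  })
  res <- weighted_z_meta(p, dir, rep(123, 6))
  z_i <- qnorm(1 - p / 2) * ifelse(dir == "+", 1, -1)
  expect_equal(res$z, sum(z_i) / sqrt(6), tolerance = 1e-10)
})

test_that("inverse-variance combination weights, floors lambda, and bounds the SE", {
  two <- inverse_variance_meta(c(1, 1), c(1, 1))
  expect_equal(two$beta, 1)
  expect_equal(two$se, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(two$n_studies_used, 2L)

  # lambda = 4 quarters a study's weight
  gc <- inverse_variance_meta(c(1, 0), c(1, 1), lambda = c(1, 4))
  expect_equal(gc$beta, (1 + 0 / 4) / (1 + 1 / 4), tolerance = 1e-12)

  # lambda below 1 is never used to up-weight
  floor <- inverse_variance_meta(c(1, 0), c(1, 1), lambda = c(1, 0.8))
  expect_equal(floor$beta, 0.5)

  # single study: its own (GC-adjusted) values
  single <- inverse_variance_meta(0.3, 0.1, lambda = 4)
  expect_equal(single$beta, 0.3)
  expect_equal(single$se, 0.2)

  # combined SE never exceeds the best adjusted per-study SE
  withr::with_seed(51, {
    for (i in 1:20) {
      se <- runif(4, 0.05, 1)
      lam <- runif(4, 0.7, 2)
      res <- inverse_variance_meta(rnorm(4), se, lam)
      expect_lte(res$se, min(se * sqrt(pmax(lam, 1))) + 1e-12)
    }
  })

  # cross-check against metafor's fixed-effect model
  skip_if_not_installed("metafor")
  withr::with_seed(52, {
    b <- rnorm(5); s <- runif(5, 0.1, 0.5)
  })
  mine <- inverse_variance_meta(b, s)
  rma <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(mine$beta, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(mine$se, rma$se, tolerance = 1e-8)
})

test_that("genomic lambda follows the chi-square median definition", {
  expect_equal(genomic_lambda(rep(qchisq(0.5, 1), 10)), 1, tolerance = 1e-12)
  withr::with_seed(53, x <- rchisq(101, 1))
  expect_equal(genomic_lambda(2 * x), 2 * genomic_lambda(x), tolerance = 1e-12)
  withr::with_seed(54, big <- rchisq(1e5, 1))
  expect_equal(genomic_lambda(big), 1, tolerance = 0.01)
})

test_that("imputation-quality filtering uses a strict cutoff on imputed entries", {
  stats <- tibble::tibble(snp_id = "rs1", study = c("a", "b", "c", "d"),
                          beta = 0.1, se = 0.1, p = 0.3, n = 100,
                          rsq = c(0.25, 0.30, NA, 0.10),
                          geno_status = c("I", "I", "G", "G"),
                          direction = "+")
  out <- rsq_filter(stats, 0.30)
  expect_identical(out$stats$direction, c("?", "+", "+", "+"))
  expect_equal(nrow(out$excluded), 1)
})

test_that("null per-study statistics combine to uniform p-values", {
  withr::with_seed(55, {
    n_snp <- 10000
    z1 <- rnorm(n_snp); z2 <- rnorm(n_snp); z3 <- rnorm(n_snp)
    p_comb <- vapply(seq_len(n_snp), function(i) {
      z <- (z1[i] + z2[i] + z3[i]) / sqrt(3)
      2 * pnorm(-abs(z))
    }, numeric(1))
    # same combination through the package path on a sample of SNPs
    idx <- sample.int(n_snp, 50)
    for (i in idx) {
      res <- weighted_z_meta(2 * pnorm(-abs(c(z1[i], z2[i], z3[i]))),
                             ifelse(c(z1[i], z2[i], z3[i]) >= 0, "+", "-"),
                             rep(200, 3))
      expect_equal(res$p, p_comb[i], tolerance = 1e-10)
    }
  })
  ks <- suppressWarnings(stats::ks.test(p_comb, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the table-level driver assembles direction strings and estimates", {
  studies <- simulate_study_stats(paste0("rs", 1:20), n_studies = 4,
                                  true_beta = c(rep(0, 19), 0.5), seed = 56)
  dir <- withr::local_tempdir()
  paths <- purrr::imap_chr(studies, function(s, nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_study_stats(s, p)
    p
  })
  stats <- read_study_stats(paths)
  res <- run_meta(stats, mode = "ivw")
  expect_equal(nrow(res), 20)
  expect_true(all(nchar(res$direction) == 4))
  expect_lt(res$p[res$snp_id == "rs20"], 0.01)
  resz <- run_meta(stats, mode = "weighted_z")
  expect_lt(resz$p[resz$snp_id == "rs20"], 0.01)
})
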