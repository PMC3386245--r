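test_that("2x2 chi-square matches chisq.test and is symmetric", {
  tab <- c(146, 41, 211, 107)
  res <- chi2_2x2(tab)
  oracle <- suppressWarnings(
    chisq.test(matrix(tab, 2, byrow = TRUE), correct = FALSE))
  expect_equal(res$chi2, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)

  # equal proportions: no association
  flat <- chi2_2x2(c(10, 10, 20, 20))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
  expect_equal(flat$odds_ratio, 1)

  # invariant under simultaneous row and column swap; oracle on random tables
  withr::with_seed(20, {
    for (i in 1:100) {
      t4 <- matrix(rpois(4, 40) + 1, 2)
      res <- chi2_2x2(t4)
      swapped <- chi2_2x2(t4[2:1, 2:1])
      expect_equal(res$chi2, swapped$chi2, tolerance = 1e-12)
      o <- suppressWarnings(chisq.test(t4, correct = FALSE))
      expect_equal(res$chi2, unname(o$statistic), tolerance = 1e-9)
    }
  })

  expect_error(chi2_2x2(c(0, 0, 5, 5)), "zero margin")
})

test_that("set enrichment reproduces fraction arithmetic and identities", {
  # sig fraction 44.8%, background fraction 32.0% -> fold enrichment 1.4
  bg <- sprintf("G%04d", 1:1000)
  set <- bg[1:320]
  sig <- c(bg[1:177], bg[321:538])   # 177 of 395 in the set
  res <- set_enrichment(sig, bg, tibble::tibble(set_name = "S", gene = set))
  expect_equal(res$k_sig_in_set / res$n_sig, 0.448, tolerance = 1e-3)
  expect_equal(res$fold_enrichment, 0.448 / 0.32, tolerance = 1e-2)

  # sig == background: every set has fold enrichment exactly 1
  sets <- tibble::tibble(set_name = rep(c("A", "B"), c(100, 50)),
                         gene = c(bg[1:100], bg[101:150]))
  res <- set_enrichment(bg, bg, sets)
  expect_equal(res$fold_enrichment, c(1, 1))

  # odds ratio and fold enrichment sit on the same side of 1
  withr::with_seed(21, {
    for (i in 1:20) {
      sig_i <- sample(bg, 150)
      set_i <- sample(bg, 250)
      r <- set_enrichment(sig_i, bg,
                          tibble::tibble(set_name = "S", gene = set_i))
      if (abs(r$fold_enrichment - 1) > 1e-8) {
        expect_equal(r$odds_ratio > 1, r$fold_enrichment > 1)
      }
    }
  })

  expect_error(set_enrichment("G1", character(), sets), "empty background")
  expect_error(set_enrichment("NOT_THERE", bg, sets), "outside the background")
})

test_that("an injected enriched set ranks first among decoys", {
  withr::with_seed(22, {
    n_genes <- 2000
    genes <- sprintf("G%04d", seq_len(n_genes))
    tfbs <- rbinom(n_genes, 1, 0.32) == 1
    sets <- dplyr::bind_rows(
      tibble::tibble(set_name = "target", gene = genes[tfbs]),
      purrr::map_dfr(1:5, ~ tibble::tibble(
        set_name = paste0("decoy", .x),
        gene = sample(genes, round(0.32 * n_genes)))))
    probes <- tibble::tibble(probe_id = genes, tfbs = tfbs)
    wins <- 0
    for (i in 1:200) {
      truth <- simulate_de_truth(probes, n_de = 260, enrichment_or = 2,
                                 frac_up_in_tfbs = 0.78,
                                 frac_up_in_other = 0.66,
                                 de_effect_log2 = 0.4)
      res <- set_enrichment(truth$probe_id[truth$de], genes, sets)
      wins <- wins + (res$set_name[1] == "target")
    }
  })
  expect_gte(wins / 200, 0.95)
})

test_that("direction-of-change testing handles strata and nulls", {
  # reconstructed two-strata table: 78.07% of 187 vs 66.35% of 318
  sig <- tibble::tibble(
    probe_id = sprintf("P%03d", 1:505),
    direction = c(rep("up_in_case", 146), rep("down_in_case", 41),
                  rep("up_in_case", 211), rep("down_in_case", 107)))
  res <- direction_enrichment(sig, set_probes = sig$probe_id[1:187])
  expect_equal(round(res$chi2, 2), 7.81)
  expect_equal(unname(res$percent_up), c(78.07, 66.35))

  # the excluded probes do not contribute
  sig2 <- dplyr::bind_rows(
    tibble::tibble(probe_id = c("HUB1", "HUB2"),
                   direction = "up_in_case"), sig)
  res2 <- direction_enrichment(sig2, set_probes = c("HUB1", "HUB2",
                                                    sig$probe_id[1:187]),
                               exclude = c("HUB1", "HUB2"))
  expect_equal(res2$chi2, res$chi2)

  # all probes in one direction: zero margin
  allup <- tibble::tibble(probe_id = sprintf("P%02d", 1:20),
                          direction = "up_in_case")
  expect_error(direction_enrichment(allup, allup$probe_id[1:10]),
               "zero margin")

  # equal up-fractions in both strata: rejection rate ~ alpha
  withr::with_seed(23, {
    rej <- replicate(1000, {
      up_set <- rbinom(1, 150, 0.7)
      up_out <- rbinom(1, 350, 0.7)
      tab <- rbind(c(up_set, 150 - up_set), c(up_out, 350 - up_out))
      chi2_2x2(tab)$p < 0.05
    })
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("top-gene overlap testing matches expectation arithmetic", {
  universe <- sprintf("G%05d", 1:11191)
  top_a <- universe[1:278]
  # force the overlap to its null expectation (~25)
  top_b <- c(universe[1:25], universe[279:1265])
  res <- overlap_test(top_a, top_b, universe)
  expect_equal(res$expected, 278 * 1012 / 11191, tolerance = 1e-12)
  expect_equal(res$overlap, 25)
  expect_gt(res$p, 0.5)

  # identical lists maximize the statistic for the given margins
  res_same <- overlap_test(top_a, top_a, universe)
  withr::with_seed(24, {
    for (i in 1:10) {
      part <- c(top_a[1:100], sample(setdiff(universe, top_a), 178))
      expect_lt(overlap_test(top_a, part, universe)$chi2, res_same$chi2)
    }
  })

  expect_error(overlap_test(top_a, top_b, character()), "empty universe")
  expect_error(overlap_test(universe, top_b, universe), "zero margin")
})
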