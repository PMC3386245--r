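test_that("probe filtering applies the two removal rules exactly", {
  samples <- make_samples(10, 10)
  m <- matrix(100, nrow = 4, ncol = 20,
              dimnames = list(NULL, samples$sample_id))
  expr <- make_expr(m)
  flags <- make_clean_flags(expr)

  # probe 1: IsWellAboveBG fails (value FALSE) in 80% of all arrays
  flags <- set_flag_rows(flags, "IsWellAboveBG", 1, 0.80, FALSE)
  # probe 2: out of detectable range in 60% of controls but only 40% of cases
  ctrl <- samples$sample_id[samples$status == "control"]
  case <- samples$sample_id[samples$status == "case"]
  for (s in ctrl[1:6]) flags$InDetectableRange[[s]][2] <- FALSE
  for (s in case[1:4]) flags$InDetectableRange[[s]][2] <- FALSE
  # probe 3: out of range in 60% of both groups
  for (s in c(ctrl[1:6], case[1:6])) flags$InDetectableRange[[s]][3] <- FALSE

  res <- filter_probes(expr, flags, samples)
  expect_setequal(res$removed$probe_id, c("P001", "P003"))
  expect_match(res$removed$reason[res$removed$probe_id == "P001"],
               "IsWellAboveBG")
  expect_true("P002" %in% res$expr$probe_id)  # one-group failure retained
  expect_true("P004" %in% res$expr$probe_id)  # clean probe retained

  # missing flag tensor is an error naming the flag
  expect_error(filter_probes(expr, flags[-2], samples), "IsWellAboveBG")
})

test_that("tightening the flag fraction never re-admits a removed probe", {
  samples <- make_samples(8, 8)
  withr::with_seed(42, {
    expr <- make_expr(matrix(runif(30 * 16, 50, 150), 30, 16,
                             dimnames = list(NULL, samples$sample_id)))
    flags <- make_clean_flags(expr)
    for (r in 1:30) {
      frac <- runif(1)
      flags <- set_flag_rows(flags, "IsWellAboveBG", r, frac, FALSE, seed = r)
    }
  })
  removed_75 <- filter_probes(expr, flags, samples,
                              filter_policy(flag_frac = 0.75))$removed$probe_id
  removed_50 <- filter_probes(expr, flags, samples,
                              filter_policy(flag_frac = 0.50))$removed$probe_id
  expect_true(all(removed_75 %in% removed_50))
})

test_that("replicated probes collapse to the per-sample median", {
  expr <- make_expr(matrix(c(1, 3,   # P1 replicate a
                             5, 6),  # P2
                           2, 2, byrow = TRUE),
                    probe_ids = c("P1", "P2"))
  expr <- dplyr::bind_rows(expr,
                           tibble::tibble(probe_id = c("P1", "P1"),
                                          S01 = c(3, 9), S02 = c(2, 1)))
  out <- collapse_replicates(expr)
  expect_equal(nrow(out), 2)
  expect_equal(out$S01[out$probe_id == "P1"], 3)       # median(1, 3, 9)
  expect_equal(out$S02[out$probe_id == "P1"], 2)       # median(3, 2, 1)

  # even count: median of {1, 3} is 2
  even <- make_expr(matrix(c(1, 10, 3, 10), 2, 2, byrow = TRUE),
                    probe_ids = c("P1", "P1"))
  expect_equal(collapse_replicates(even)$S01, 2)

  # no duplicates: identity
  expect_identical(collapse_replicates(expr[1:2, ]), expr[1:2, ])
})

test_that("quantile normalization matches hand values and the brute-force oracle", {
  expr <- make_expr(cbind(c(3, 1, 2), c(6, 2, 4)))
  out <- quantile_normalize(expr, log2_transform = FALSE)
  expect_equal(out$S01, c(4.5, 1.5, 3))
  expect_equal(out$S02, c(4.5, 1.5, 3))

  # identical columns are a fixed point
  same <- make_expr(cbind(c(5, 1, 9), c(5, 1, 9)))
  fixed <- quantile_normalize(same, log2_transform = FALSE)
  expect_equal(fixed$S01, c(5, 1, 9))

  # random matrix: all columns share one multiset; sort-and-average oracle
  withr::with_seed(7, m <- matrix(runif(50 * 6, 1, 100), 50, 6))
  expr <- make_expr(m)
  norm <- as.matrix(quantile_normalize(expr, log2_transform = FALSE)[, -1])
  ref <- rowMeans(apply(m, 2, sort))
  oracle <- apply(m, 2, function(col) ref[rank(col)])
  expect_equal(unname(norm), oracle, tolerance = 1e-12)
  for (j in 2:6) {
    expect_identical(sort(norm[, 1]), sort(norm[, j]))
  }

  # within-column rank order is preserved
  expect_identical(unname(apply(norm, 2, rank)), unname(apply(m, 2, rank)))

  # non-positive values cannot be log-transformed
  neg <- make_expr(cbind(c(0.5, -1, 2), c(1, 2, 3)))
  expect_error(quantile_normalize(neg), "non-positive")
})

test_that("validation-panel normalization follows the five steps", {
  samples <- make_samples(5, 4, seed = 3)
  n <- nrow(samples)
  # target gene net counts 8, control genes 2 and 8 -> geometric mean 4,
  # normalized 2, log2 = 1
  counts <- tidyr::expand_grid(sample_id = samples$sample_id,
                               gene = c("TG", "CTRL1", "CTRL2"),
                               replicate = 1:3)
  counts$background <- 10
  counts$raw <- 10 + dplyr::case_when(counts$gene == "TG" ~ 8,
                                      counts$gene == "CTRL1" ~ 2,
                                      TRUE ~ 8)
  res <- quantigene_normalize(counts, samples, c("CTRL1", "CTRL2"))
  expect_equal(res$values$log2_norm[res$values$gene == "TG"], rep(1, n))
  # identical case/control values: status beta 0 under the degenerate-fit rule
  expect_equal(res$fits$beta_status, 0)
  expect_equal(res$fits$p, 1)

  # background >= raw count is rejected
  bad <- counts; bad$background[1] <- bad$raw[1]
  expect_error(quantigene_normalize(bad, samples, c("CTRL1", "CTRL2")),
               "background")

  # injected positive status effect gives a positive fold-change sign,
  # concordant with the array-side fit on the same samples
  withr::with_seed(9, {
    log2_true <- 0.8 * (samples$status == "case") + rnorm(n, 5, 0.1)
    counts2 <- tidyr::expand_grid(sample_id = samples$sample_id,
                                  gene = c("TG", "CTRL1", "CTRL2"),
                                  replicate = 1:3)
    counts2$background <- 50
    base <- 2^log2_true[match(counts2$sample_id, samples$sample_id)]
    counts2$raw <- 50 + ifelse(counts2$gene == "TG", base * 20, 40) *
      exp(rnorm(nrow(counts2), 0, 0.02))
  })
  res2 <- quantigene_normalize(counts2, samples, c("CTRL1", "CTRL2"))
  expect_gt(res2$fits$beta_status, 0)
  array_fit <- fit_probe(setNames(log2_true, samples$sample_id), samples,
                         adjust = c("age_at_death", "pmi"))
  expect_identical(res2$fits$direction, array_fit$direction)
})
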