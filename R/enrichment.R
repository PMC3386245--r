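#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected Pearson chi-square (1 df) with two-sided p-value from the
#' chi-square distribution, plus the cross-product odds ratio `ad/bc`.
#' Continuity correction is off by default; the classic Yates correction is
#' available behind `correction = TRUE`.
#'
#' @param tab A 2x2 matrix of non-negative counts, or a length-4 vector
#'   `c(a, b, c, d)` read row-wise (rows = groups, columns = outcomes).
#' @param correction Apply the Yates continuity correction.
#' @return One-row tibble `chi2`, `p`, `odds_ratio`.
#' @export
chi2_2x2 <- function(tab, correction = FALSE) {
  if (!is.matrix(tab)) {
    stopifnot(length(tab) == 4)
    tab <- matrix(tab, nrow = 2, byrow = TRUE)
  }
  stopifnot(dim(tab) == c(2, 2))
  if (any(tab < 0)) abort("counts must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    abort("zero margin: every row and column of the 2x2 table needs counts")
  }
  expected <- outer(rs, cs) / n
  dev <- abs(tab - expected)
  if (correction) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  tibble::tibble(chi2 = chi2,
                 p = pchisq(chi2, df = 1, lower.tail = FALSE),
                 odds_ratio = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))
}

#' Gene-set enrichment of a significant gene list
#'
#' For each gene set, compares membership among significant genes against
#' the analysis background. Two complementary summaries are returned:
#' \describe{
#'   \item{fold enrichment}{the ratio of the fraction of significant genes
#'     in the set to the fraction of background genes in the set;}
#'   \item{chi-square}{an uncorrected Pearson test on the 2x2 table
#'     (significant vs not) x (in set vs not) over the background, with the
#'     odds ratio and a Bonferroni-adjusted p over the number of sets.}
#' }
#'
#' @param sig_genes Character vector of significant genes (must be a subset
#'   of `background`).
#' @param background Character vector: the gene universe actually analyzed.
#' @param sets Tidy gene-set tibble (`set_name`, `gene`), e.g. from
#'   [read_gmt()].
#' @return Tibble of class `"enrichment_results"`: one row per set with
#'   counts, `fold_enrichment`, `chi2`, `p`, `odds_ratio`, `bonferroni_p`,
#'   sorted by `p`.
#' @export
set_enrichment <- function(sig_genes, background, sets) {
  background <- unique(background)
  sig_genes <- unique(sig_genes)
  if (length(background) == 0) abort("empty background")
  extra <- setdiff(sig_genes, background)
  if (length(extra) > 0) {
    abort(paste0("significant genes outside the background: ",
                 paste(head(extra, 5), collapse = ", ")))
  }
  set_names <- unique(sets$set_name)
  n_sets <- length(set_names)
  n_sig <- length(sig_genes)
  n_bg <- length(background)

  res <- purrr::map_dfr(set_names, function(s) {
    members <- intersect(sets$gene[sets$set_name == s], background)
    k_sig <- length(intersect(sig_genes, members))
    k_bg <- length(members)
    fold <- (k_sig / n_sig) / (k_bg / n_bg)
    tab <- matrix(c(k_sig, n_sig - k_sig,
                    k_bg - k_sig, (n_bg - n_sig) - (k_bg - k_sig)),
                  nrow = 2, byrow = TRUE)
    # degenerate margins (e.g. sig == background) leave the test undefined
    test <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      tibble::tibble(chi2 = NA_real_, p = NA_real_, odds_ratio = NA_real_)
    } else {
      chi2_2x2(tab)
    }
    tibble::tibble(set_name = s, k_sig_in_set = k_sig, n_sig = n_sig,
                   k_bg_in_set = k_bg, n_bg = n_bg,
                   fold_enrichment = fold, chi2 = test$chi2, p = test$p,
                   odds_ratio = test$odds_ratio)
  })
  res$bonferroni_p <- pmin(1, res$p * n_sets)
  res <- dplyr::arrange(res, is.na(.data$p), .data$p)
  class(res) <- c("enrichment_results", class(res))
  res
}

#' Direction-of-change test within a gene set
#'
#' Among significant probes, tests whether probes in a given set (e.g.
#' genes carrying a transcription factor's binding site) go up in cases
#' more often than the remaining significant probes: an uncorrected Pearson
#' chi-square on the table (in set, not in set) x (up, down). Probes in
#' `exclude` (typically the factor's own probes) are removed first.
#'
#' @param sig_results A `"de_results"` tibble restricted to significant
#'   probes (needs `probe_id` and `direction`).
#' @param set_probes Character vector of probe ids belonging to the set.
#' @param exclude Probe ids to drop before testing.
#' @return A list: `table` (2x2 matrix with informative dimnames),
#'   `percent_up` (two-decimal percent up in each stratum), `chi2`, `p`,
#'   `odds_ratio`.
#' @export
direction_enrichment <- function(sig_results, set_probes, exclude = character()) {
  dat <- sig_results[!sig_results$probe_id %in% exclude, ]
  in_set <- dat$probe_id %in% set_probes
  if (!any(in_set) || all(in_set)) {
    abort("empty stratum: need significant probes both in and out of the set")
  }
  up <- dat$direction == "up_in_case"
  tab <- rbind(in_set = c(up = sum(in_set & up), down = sum(in_set & !up)),
               out_set = c(up = sum(!in_set & up), down = sum(!in_set & !up)))
  test <- chi2_2x2(tab)
  list(table = tab,
       percent_up = round(100 * tab[, "up"] / rowSums(tab), 2),
       chi2 = test$chi2, p = test$p, odds_ratio = test$odds_ratio)
}

#' Overlap of two top-gene lists
#'
#' Tests whether two studies' top-gene lists share more genes than
#' expected, via an uncorrected Pearson chi-square on the 2x2 membership
#' table over the common gene universe.
#'
#' @param top_a,top_b Character vectors of top genes, subsets of
#'   `universe`.
#' @param universe Character vector: genes assayed by both studies.
#' @return One-row tibble `overlap`, `expected`, `chi2`, `p`, `odds_ratio`.
#' @export
overlap_test <- function(top_a, top_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  top_a <- unique(top_a); top_b <- unique(top_b)
  if (length(setdiff(top_a, universe)) > 0 ||
      length(setdiff(top_b, universe)) > 0) {
    abort("top lists must be subsets of the universe")
  }
  in_a <- universe %in% top_a
  in_b <- universe %in% top_b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                nrow = 2, byrow = TRUE)
  test <- chi2_2x2(tab)
  tibble::tibble(overlap = tab[1, 1],
                 expected = length(top_a) * length(top_b) / length(universe),
                 chi2 = test$chi2, p = test$p, odds_ratio = test$odds_ratio)
}

#' Dot plot of gene-set enrichment results
#'
#' @param object An `"enrichment_results"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_results <- function(object, ...) {
  dat <- dplyr::mutate(tibble::as_tibble(object),
                       set_name = stats::reorder(.data$set_name,
                                                 .data$fold_enrichment))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fold_enrichment,
                                    y = .data$set_name,
                                    size = .data$k_sig_in_set,
                                    colour = -log10(.data$p))) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "fold enrichment", y = NULL, size = "genes in set",
                  colour = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}
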