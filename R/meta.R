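#' Sample-size weighted Z-score meta-analysis
#'
#' Combines per-study two-sided p-values with their directions of effect:
#' each study contributes `z_i = qnorm(1 - p_i/2)` signed by its direction,
#' and the combined statistic is `sum(w_i z_i) / sqrt(sum(w_i^2))` with
#' `w_i = sqrt(n_i)`. Studies with direction `"?"` (excluded or failed
#' imputation) contribute nothing.
#'
#' @param p Per-study two-sided p-values in (0, 1].
#' @param direction Per-study `"+"`, `"-"` or `"?"`; a direction string
#'   such as `"+++?++"` is also accepted.
#' @param n Per-study sample sizes (> 0).
#' @return One-row tibble `z`, `p`, `n_studies_used`; `NA` values when all
#'   studies are excluded.
#' @export
weighted_z_meta <- function(p, direction, n) {
  if (length(direction) == 1 && nchar(direction) > 1) {
    direction <- parse_direction(direction)
  }
  stopifnot(length(p) == length(direction), length(p) == length(n))
  use <- direction %in% c("+", "-")
  if (!any(use)) {
    return(tibble::tibble(z = NA_real_, p = NA_real_, n_studies_used = 0L))
  }
  p_u <- p[use]; n_u <- n[use]
  if (any(is.na(p_u)) || any(p_u <= 0 | p_u > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  if (any(is.na(n_u)) || any(n_u <= 0)) abort("sample sizes must be positive")
  z_i <- qnorm(p_u / 2, lower.tail = FALSE) *
    ifelse(direction[use] == "+", 1, -1)
  w <- sqrt(n_u)
  z <- sum(w * z_i) / sqrt(sum(w^2))
  tibble::tibble(z = z, p = two_sided_p(z), n_studies_used = sum(use))
}

#' Inverse-variance fixed-effect meta-analysis with genomic control
#'
#' Per-study standard errors are first inflated by `sqrt(lambda)` for
#' studies whose genomic-control lambda exceeds 1 (lambdas below 1 are
#' floored at 1 -- studies are never up-weighted). The combined effect is
#' the precision-weighted mean, `se = 1/sqrt(sum(1/se_i^2))`, with a
#' two-sided normal p-value. A single study returns its own GC-adjusted
#' values.
#'
#' @param beta Per-study effect estimates.
#' @param se Per-study standard errors (> 0).
#' @param lambda Per-study genomic-control factors (recycled; default 1).
#' @return One-row tibble `beta`, `se`, `z`, `p`, `n_studies_used`.
#' @export
inverse_variance_meta <- function(beta, se, lambda = 1) {
  use <- !is.na(beta) & !is.na(se)
  beta <- beta[use]; se <- se[use]
  lambda <- rep_len(lambda, length(use))[use]
  if (length(beta) == 0) {
    return(tibble::tibble(beta = NA_real_, se = NA_real_, z = NA_real_,
                          p = NA_real_, n_studies_used = 0L))
  }
  if (any(se <= 0)) abort("standard errors must be positive")
  k <- length(beta)
  se_adj <- se * sqrt(pmax(lambda, 1))
  w <- 1 / se_adj^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  tibble::tibble(beta = b, se = s, z = z, p = two_sided_p(z),
                 n_studies_used = k)
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chi2) / qchisq(0.5, 1)` (the null median 0.4549...),
#' computed from a study's full set of 1-df association statistics.
#'
#' @param chi2 Vector of per-SNP 1-df chi-square statistics.
#' @return The inflation factor (not floored; flooring at 1 happens where
#'   the factor is applied).
#' @export
genomic_lambda <- function(chi2) {
  if (length(chi2) == 0) abort("need at least one statistic")
  median(chi2) / qchisq(0.5, df = 1)
}

#' Imputation-quality filter for summary statistics
#'
#' Marks SNP-study pairs whose imputation quality falls below `threshold`
#' (strict `<`) as non-contributing by setting their `direction` to `"?"`.
#' Genotyped entries (`geno_status == "G"`) and entries without an `rsq`
#' value are retained.
#'
#' @param stats Long summary-statistic tibble (see [read_study_stats()]).
#' @param threshold Quality threshold in `[0, 1]` (default 0.30).
#' @return List with `stats` (updated tibble) and `excluded` (tibble of
#'   newly excluded `snp_id`, `study`, `rsq`).
#' @export
rsq_filter <- function(stats, threshold = 0.30) {
  stopifnot(threshold >= 0, threshold <= 1)
  hit <- stats$geno_status == "I" & !is.na(stats$rsq) &
    stats$rsq < threshold & stats$direction != "?"
  hit[is.na(hit)] <- FALSE
  excluded <- stats[hit, c("snp_id", "study", "rsq")]
  stats$direction[hit] <- "?"
  list(stats = stats, excluded = excluded)
}

#' Meta-analyze a summary-statistic table
#'
#' Applies the imputation-quality filter, optionally computes each study's
#' genomic-control lambda from its full set of statistics, and combines
#' every SNP across studies with either engine. Only studies whose
#' `direction` is `"+"`/`"-"` contribute.
#'
#' @param stats Long summary-statistic tibble from [read_study_stats()].
#' @param mode `"ivw"` (inverse-variance, default) or `"weighted_z"`.
#' @param rsq_min Imputation-quality threshold (default 0.30).
#' @param gc Apply genomic control (IVW mode; default `TRUE`).
#' @param study_order Study ordering for the output direction string.
#' @return Tibble: one row per SNP with combined estimate, p-value, number
#'   of contributing studies and the compact direction string.
#' @export
run_meta <- function(stats, mode = c("ivw", "weighted_z"), rsq_min = 0.30,
                     gc = TRUE, study_order = unique(stats$study)) {
  mode <- match.arg(mode)
  stats <- rsq_filter(stats, rsq_min)$stats

  lambdas <- stats |>
    dplyr::filter(.data$direction != "?") |>
    dplyr::group_by(.data$study) |>
    dplyr::summarise(lambda = if (gc) genomic_lambda((.data$beta / .data$se)^2)
                     else 1, .groups = "drop")
  stats <- dplyr::left_join(stats, lambdas, by = "study")

  dirs <- direction_strings(stats, study_order)
  combined <- stats |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::group_modify(function(d, key) {
      use <- d$direction != "?"
      if (mode == "ivw") {
        inverse_variance_meta(d$beta[use], d$se[use], d$lambda[use])
      } else {
        weighted_z_meta(d$p[use], d$direction[use], d$n[use])
      }
    }) |>
    dplyr::ungroup()
  dplyr::left_join(combined, dirs, by = "snp_id")
}
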