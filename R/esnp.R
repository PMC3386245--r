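#' Dominant genotype coding
#'
#' Recodes minor-allele dosages to carrier status: 0 stays 0, 1 and 2
#' become 1, missing is preserved. Idempotent.
#'
#' @param dosage Numeric vector with values in \{0, 1, 2, NA\}.
#' @return Numeric vector in \{0, 1, NA\}.
#' @export
dominant_code <- function(dosage) {
  bad <- !dosage %in% c(0, 1, 2) & !is.na(dosage)
  if (any(bad)) abort("dosage values must be 0, 1, 2 or NA")
  pmin(dosage, 1)
}

#' 2-df eSNP model: genotype and genotype-by-status
#'
#' Tests a SNP's association with a probe's expression jointly for a main
#' genotype effect and a genotype-by-status interaction: the full model
#' `y ~ genotype + status + genotype:status + covariates` is compared to
#' the reduced model `y ~ status + covariates` with a 2-df F test.
#' Stratified case-only and control-only fits (`y ~ genotype + covariates`)
#' are attached; a stratum where the genotype is monomorphic reports
#' missing stratified estimates while the joint fit is still returned.
#'
#' @param y Per-sample expression (named by sample id or positional).
#' @param d Dominant-coded genotype (see [dominant_code()]), same length.
#' @param samples Sample tibble.
#' @param adjust Covariate adjustment set
#'   (default `c("rin", "pmi", "age_at_death")`).
#' @param snp_id,probe_id Optional labels carried into the result.
#' @return An object of class `"esnp_fit"`; see [tidy.esnp_fit()] /
#'   [glance.esnp_fit()] for tabular views.
#' @export
fit_2df <- function(y, d, samples, adjust = c("rin", "pmi", "age_at_death"),
                    snp_id = NA_character_, probe_id = NA_character_) {
  validate_samples(samples)
  if (!is.null(names(y))) y <- y[match(samples$sample_id, names(y))]
  stopifnot(length(y) == nrow(samples), length(d) == nrow(samples))
  dat <- dplyr::bind_cols(
    tibble::tibble(.y = y, .d = d,
                   .status = status_indicator(samples$status)),
    samples[, adjust, drop = FALSE])
  dat <- dat[complete.cases(dat), ]
  if (length(unique(dat$.d)) < 2) {
    abort("monomorphic genotype within the analysis sample")
  }
  covs <- paste(adjust, collapse = " + ")
  reduced <- lm(stats::as.formula(paste(".y ~ .status +", covs)), data = dat)
  mono_case <- length(unique(dat$.d[dat$.status == 1])) < 2
  mono_ctrl <- length(unique(dat$.d[dat$.status == 0])) < 2
  if (mono_case || mono_ctrl) {
    # dominant coding makes the interaction inestimable when a stratum is
    # monomorphic; fall back to the 1-df genotype model
    full <- lm(stats::as.formula(paste(".y ~ .d + .status +", covs)),
               data = dat)
    beta_int <- NA_real_
    test_df <- 1
  } else {
    full <- lm(stats::as.formula(paste(".y ~ .d * .status +", covs)),
               data = dat)
    beta_int <- unname(coef(full)[".d:.status"])
    test_df <- 2
  }
  if (anyNA(coef(full))) {
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(names(coef(full))[is.na(coef(full))], collapse = ", ")))
  }
  an <- anova(reduced, full)
  f_stat <- an$F[2]
  p_2df <- an$`Pr(>F)`[2]
  # likelihood-ratio alternative (asymptotic chi-square)
  n <- nrow(dat)
  lrt <- n * log(sum(reduced$residuals^2) / sum(full$residuals^2))
  p_lrt <- pchisq(lrt, df = test_df, lower.tail = FALSE)

  strat <- function(rows) {
    sd_ <- dat[rows, ]
    if (length(unique(sd_$.d)) < 2 || nrow(sd_) < length(adjust) + 3) {
      return(list(beta = NA_real_, se = NA_real_, p = NA_real_, n = nrow(sd_)))
    }
    f <- lm(stats::as.formula(paste(".y ~ .d +",
                                    paste(adjust, collapse = " + "))),
            data = sd_)
    sm <- summary(f)$coefficients
    list(beta = sm[".d", "Estimate"], se = sm[".d", "Std. Error"],
         p = sm[".d", "Pr(>|t|)"], n = nrow(sd_))
  }
  structure(list(snp_id = snp_id, probe_id = probe_id,
                 p_2df = p_2df, f = f_stat, p_lrt = p_lrt, test_df = test_df,
                 beta_geno = unname(coef(full)[".d"]),
                 beta_interaction = beta_int,
                 case = strat(dat$.status == 1),
                 control = strat(dat$.status == 0),
                 n_used = n, data = dat),
            class = "esnp_fit")
}

#' @export
print.esnp_fit <- function(x, ...) {
  cat("<esnp_fit> ", x$snp_id, " x ", x$probe_id,
      ": 2-df p = ", format(x$p_2df, digits = 3),
      " (n = ", x$n_used, ")\n", sep = "")
  invisible(x)
}

#' Tidy / summarize an eSNP fit
#'
#' @param x An `"esnp_fit"` object.
#' @param ... Unused.
#' @return `tidy()`: one row per estimated quantity (joint genotype and
#'   interaction betas, stratified case/control slopes); `glance()`: a
#'   one-row overview with the 2-df p-value.
#' @export
tidy.esnp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("genotype", "genotype:status", "genotype (cases)",
             "genotype (controls)"),
    estimate = c(x$beta_geno, x$beta_interaction, x$case$beta, x$control$beta),
    std.error = c(NA, NA, x$case$se, x$control$se),
    p.value = c(NA, NA, x$case$p, x$control$p))
}

#' @rdname tidy.esnp_fit
#' @export
glance.esnp_fit <- function(x, ...) {
  tibble::tibble(snp_id = x$snp_id, probe_id = x$probe_id,
                 statistic = x$f, p_2df = x$p_2df, p_lrt = x$p_lrt,
                 n_used = x$n_used)
}

#' Expression-by-genotype boxplot for an eSNP fit
#'
#' @param object An `"esnp_fit"` object.
#' @param ... Unused.
#' @return A ggplot object faceted by case/control status.
#' @export
autoplot.esnp_fit <- function(object, ...) {
  dat <- dplyr::mutate(object$data,
                       genotype = factor(.data$.d, levels = c(0, 1),
                                         labels = c("non-carrier", "carrier")),
                       status = factor(.data$.status, levels = c(0, 1),
                                       labels = c("control", "case")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$genotype, y = .data$.y)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~status) +
    ggplot2::labs(x = paste0(object$snp_id, " (dominant)"),
                  y = paste0(object$probe_id, " expression (log2)")) +
    ggplot2::theme_minimal()
}

#' Run the 2-df eSNP scan over SNP-probe pairs
#'
#' Dominant-codes each SNP, applies the minor-allele-frequency pre-filter,
#' and fits [fit_2df()] for every retained SNP against every requested
#' probe.
#'
#' @param expr Log2 expression tibble.
#' @param samples Sample tibble.
#' @param geno A `"genotypes"` object.
#' @param probes Probe ids to test (default: all rows of `expr`).
#' @param snps SNP ids to test (default: all SNPs passing `maf_min`).
#' @param adjust Covariate adjustment set.
#' @param maf_min Minimum minor-allele frequency (default 0.1).
#' @return Tibble with one row per SNP-probe pair: 2-df p, joint betas,
#'   stratified estimates, `n_used`.
#' @export
run_esnp <- function(expr, samples, geno, probes = expr$probe_id,
                     snps = NULL, adjust = c("rin", "pmi", "age_at_death"),
                     maf_min = 0.1) {
  keep_snps <- geno$maf$snp_id[geno$maf$maf >= maf_min]
  if (!is.null(snps)) keep_snps <- intersect(keep_snps, snps)
  m <- expr_matrix(expr)
  common <- intersect(colnames(m), geno$dosage$sample_id)
  common <- intersect(common, samples$sample_id)
  samples <- samples[match(common, samples$sample_id), ]
  dose <- geno$dosage[match(common, geno$dosage$sample_id), ]

  purrr::map_dfr(keep_snps, function(s) {
    d <- dominant_code(dose[[s]])
    if (length(unique(na.omit(d))) < 2) return(NULL)  # monomorphic after coding
    purrr::map_dfr(probes, function(pr) {
      fit <- fit_2df(m[pr, common], d, samples, adjust,
                     snp_id = s, probe_id = pr)
      tibble::tibble(snp_id = s, probe_id = pr, p_2df = fit$p_2df,
                     beta_geno = fit$beta_geno,
                     beta_interaction = fit$beta_interaction,
                     beta_case = fit$case$beta, p_case = fit$case$p,
                     beta_control = fit$control$beta, p_control = fit$control$p,
                     n_used = fit$n_used)
    })
  })
}

#' Effective number of independent tests (eigenvalue method)
#'
#' Computes the SNP-by-SNP Pearson correlation matrix of dosages and
#' returns the smallest number of principal components whose eigenvalues
#' sum to at least `variance_threshold` of the total variance -- the
#' effective number of independent SNPs under linkage disequilibrium.
#' Constant SNPs are excluded with a warning. With `blocks`, the count is
#' computed per block and summed (per-region correction).
#'
#' @param geno A `"genotypes"` object, or a numeric samples-by-SNPs matrix.
#' @param variance_threshold Fraction of variance to capture
#'   (default 0.995).
#' @param coding `"additive"` (default) or `"dominant"` dosage coding for
#'   the correlation matrix.
#' @param blocks Optional vector (one entry per SNP) assigning SNPs to
#'   regions.
#' @return One-row tibble `m_nominal`, `m_eff`, `variance_threshold`.
#' @export
effective_tests <- function(geno, variance_threshold = 0.995,
                            coding = c("additive", "dominant"),
                            blocks = NULL) {
  coding <- match.arg(coding)
  m <- if (inherits(geno, "genotypes")) {
    as.matrix(as.data.frame(geno$dosage[, -1, drop = FALSE]))
  } else {
    as.matrix(geno)
  }
  storage.mode(m) <- "double"
  if (coding == "dominant") m <- pmin(m, 1)
  keep <- apply(m, 2, function(x) var(x, na.rm = TRUE) > 0)
  if (any(!keep)) {
    warn(paste0("excluding constant SNP(s): ",
                paste(colnames(m)[!keep], collapse = ", ")))
    m <- m[, keep, drop = FALSE]
    if (!is.null(blocks)) blocks <- blocks[keep]
  }
  if (ncol(m) < 2) abort("need at least 2 polymorphic SNPs")

  count_one <- function(mm) {
    cc <- cor(mm, use = "pairwise.complete.obs")
    ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
    which(cumsum(ev) >= variance_threshold * sum(ev))[1]
  }
  m_eff <- if (is.null(blocks)) {
    count_one(m)
  } else {
    sum(purrr::map_int(split(seq_len(ncol(m)), blocks), function(idx) {
      if (length(idx) == 1) 1L else as.integer(count_one(m[, idx, drop = FALSE]))
    }))
  }
  tibble::tibble(m_nominal = ncol(m), m_eff = as.integer(m_eff),
                 variance_threshold = variance_threshold)
}

#' Multiplicity-corrected significance threshold
#'
#' @param m_eff Effective number of tests (>= 1).
#' @param alpha Family-wise alpha (default 0.05).
#' @param method `"bonferroni"` (`alpha / m_eff`) or `"sidak"`
#'   (`1 - (1 - alpha)^(1/m_eff)`).
#' @return The per-test threshold.
#' @export
corrected_threshold <- function(m_eff, alpha = 0.05,
                                method = c("bonferroni", "sidak")) {
  method <- match.arg(method)
  stopifnot(m_eff >= 1)
  switch(method,
         bonferroni = alpha / m_eff,
         sidak = 1 - (1 - alpha)^(1 / m_eff))
}
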