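#' Covariate-adjusted differential expression for one probe
#'
#' Ordinary least squares of log2 expression on an intercept, a
#' case/control indicator (case = 1, so positive betas mean higher
#' expression in cases) and an adjustment set of covariates, with a
#' two-sided t test on the status coefficient. Samples with a missing
#' response or any missing covariate are dropped and `n_used` reported.
#'
#' A response with zero variance among the used samples returns `beta = 0`,
#' `p = 1` (keeping the downstream FDR vector total) rather than `NaN`.
#'
#' @param y Numeric vector of per-sample expression; if named, names are
#'   matched to `samples$sample_id`, otherwise positional alignment is
#'   assumed.
#' @param samples Sample tibble with `status` and the adjustment columns.
#' @param adjust Character vector of covariate names
#'   (default `c("rin", "pmi", "age_at_death")`).
#' @param probe_id Optional probe label carried into the result.
#' @return One-row tibble: `probe_id`, `beta_status`, `se`, `t`, `p`,
#'   `fold_change`, `direction`, `n_used`.
#' @export
fit_probe <- function(y, samples, adjust = c("rin", "pmi", "age_at_death"),
                      probe_id = NA_character_) {
  validate_samples(samples)
  if (!is.null(names(y))) {
    y <- y[match(samples$sample_id, names(y))]
  }
  if (length(y) != nrow(samples)) {
    abort("y must have one value per sample")
  }
  des <- build_design(samples, adjust)
  keep <- des$keep[!is.na(y[des$keep])]
  X <- des$X[!is.na(y[des$keep]), , drop = FALSE]
  yy <- y[keep]
  if (length(yy) < ncol(X) + 1) {
    abort("too few complete samples for the requested model")
  }
  check_full_rank(X)

  if (var(yy) == 0) {
    res <- tibble::tibble(probe_id = probe_id, beta_status = 0,
                          se = NA_real_, t = 0, p = 1, n_used = length(yy))
  } else {
    fit <- lm.fit(X, yy)
    df <- length(yy) - ncol(X)
    sigma2 <- sum(fit$residuals^2) / df
    xtx_inv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(sigma2 * xtx_inv[2, 2])
    beta <- unname(fit$coefficients["status"])
    tval <- beta / se
    res <- tibble::tibble(probe_id = probe_id, beta_status = beta, se = se,
                          t = tval, p = 2 * pt(abs(tval), df, lower.tail = FALSE),
                          n_used = length(yy))
  }
  fc <- fold_change(res$beta_status)
  dplyr::mutate(res, fold_change = fc$magnitude, direction = fc$direction,
                .before = "n_used")
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment, order-preserving with the input vector.
#' Delegates to [stats::p.adjust()] after validating the input range.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of adjusted q-values, `q[i] >= p[i]`, monotone in `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1] with no missing values")
  }
  p.adjust(p, method = "BH")
}

#' Fold change from a log2-scale status coefficient
#'
#' @param beta_status Numeric vector of log2-scale betas.
#' @return Tibble `magnitude` (`2^|beta|`, always >= 1) and `direction`
#'   (`"up_in_case"` for `beta >= 0` -- ties resolve up -- else
#'   `"down_in_case"`).
#' @export
fold_change <- function(beta_status) {
  tibble::tibble(magnitude = 2^abs(beta_status),
                 direction = ifelse(beta_status >= 0,
                                    "up_in_case", "down_in_case"))
}

#' Differential expression across all probes
#'
#' Fits the [fit_probe()] model to every row of an expression table in one
#' vectorized pass (all probes share the design matrix), then applies
#' Benjamini-Hochberg FDR adjustment across probes. Numerically identical
#' to looping [fit_probe()] over rows.
#'
#' @param expr Log2-scale expression tibble (`probe_id` + sample columns),
#'   one row per probe (collapse replicates first).
#' @param samples Sample tibble.
#' @param adjust Covariate adjustment set
#'   (default `c("rin", "pmi", "age_at_death")`).
#' @param annotation Optional probe-to-gene tibble (`probe_id`, `gene`).
#' @return A tibble of class `"de_results"`: `probe_id`, `gene` (if
#'   annotated), `beta_status`, `se`, `t`, `p`, `q`, `fold_change`,
#'   `direction`, `n_used`, sorted as the input.
#' @export
run_diffexpr <- function(expr, samples, adjust = c("rin", "pmi", "age_at_death"),
                         annotation = NULL) {
  validate_samples(samples)
  m <- expr_matrix(expr)
  sids <- colnames(m)
  if (!setequal(sids, samples$sample_id)) {
    abort("expression sample ids and sample table do not match")
  }
  samples <- samples[match(sids, samples$sample_id), ]
  des <- build_design(samples, adjust)
  X <- des$X
  check_full_rank(X)
  Y <- t(m[, des$keep, drop = FALSE])

  if (anyNA(Y)) {
    # rare path: per-probe complete cases
    res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
      fit_probe(m[i, ], samples, adjust, probe_id = rownames(m)[i])
    })
  } else {
    n <- nrow(X); pcols <- ncol(X); df <- n - pcols
    fit <- lm.fit(X, Y)
    betas <- fit$coefficients["status", ]
    resid <- Y - X %*% fit$coefficients
    sigma2 <- colSums(resid^2) / df
    xtx_inv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(sigma2 * xtx_inv[2, 2])
    tval <- betas / se
    p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
    zero_var <- apply(Y, 2, var) == 0
    betas[zero_var] <- 0; tval[zero_var] <- 0; p[zero_var] <- 1
    se[zero_var] <- NA_real_
    fc <- fold_change(unname(betas))
    res <- tibble::tibble(probe_id = rownames(m), beta_status = unname(betas),
                          se = unname(se), t = unname(tval), p = unname(p),
                          fold_change = fc$magnitude, direction = fc$direction,
                          n_used = n)
  }
  res$q <- bh_fdr(res$p)
  res <- dplyr::relocate(res, "q", .after = "p")
  if (!is.null(annotation)) {
    res <- dplyr::left_join(res, annotation[, c("probe_id", "gene")],
                            by = "probe_id") |>
      dplyr::relocate("gene", .after = "probe_id")
  }
  class(res) <- c("de_results", class(res))
  res
}

#' @importFrom stats pt
NULL

#' @export
glance.de_results <- function(x, ...) {
  tibble::tibble(n_probes = nrow(x),
                 n_fdr_significant = sum(x$q < 0.05),
                 n_fc_gt_1.5 = sum(x$q < 0.05 & x$fold_change > 1.5),
                 frac_up_in_case = mean(x$direction == "up_in_case"))
}

#' Volcano plot of differential-expression results
#'
#' @param object A `"de_results"` tibble from [run_diffexpr()].
#' @param q_cutoff FDR threshold highlighted in the plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_results <- function(object, q_cutoff = 0.05, ...) {
  dat <- dplyr::mutate(tibble::as_tibble(object),
                       significant = .data$q < q_cutoff)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$beta_status,
                                    y = -log10(.data$p),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(log[2] ~ "difference (case - control)"),
                  y = expression(-log[10] ~ p),
                  colour = paste0("FDR < ", q_cutoff)) +
    ggplot2::theme_minimal()
}
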