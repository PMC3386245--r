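#' Sobel Z test for an indirect effect
#'
#' First-order delta-method test of the null that the product of the
#' exposure-to-mediator slope `a` and the mediator-to-outcome slope `b` is
#' zero: `z = a b / sqrt(a^2 se_b^2 + b^2 se_a^2)`, two-sided normal
#' p-value. When the numerator is exactly zero the statistic is defined as
#' 0 (p = 1).
#'
#' @param a,se_a Slope and standard error from the exposure-to-mediator
#'   regression.
#' @param b,se_b Slope and standard error of the mediator in the outcome
#'   regression.
#' @return One-row tibble `z`, `p`.
#' @export
sobel_z <- function(a, se_a, b, se_b) {
  stopifnot(se_a > 0, se_b > 0)
  num <- a * b
  if (num == 0) return(tibble::tibble(z = 0, p = 1))
  z <- num / sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  tibble::tibble(z = z, p = two_sided_p(z))
}

#' Standardize a regression coefficient across model families
#'
#' Puts linear and logistic slopes on one scale so they can be multiplied
#' in a mediation decomposition: `beta_std = beta * sd(predictor) /
#' outcome_scale`, with the standard error scaled by the same factor (so
#' `beta/se` is unchanged). For a linear model the outcome scale is the
#' response standard deviation; for a logistic model it is the
#' latent-variable scale `sqrt(var(linear predictor) + pi^2/3)` computed
#' over the fitted sample.
#'
#' @param beta,se Coefficient and standard error.
#' @param model_kind `"linear"` or `"logistic"` (informational; the caller
#'   supplies the matching `outcome_scale`).
#' @param predictor_sd Standard deviation of the predictor (> 0).
#' @param outcome_scale Outcome scale as defined above (> 0).
#' @return One-row tibble `beta_std`, `se_std`.
#' @export
standardize_beta <- function(beta, se, model_kind = c("linear", "logistic"),
                             predictor_sd, outcome_scale) {
  match.arg(model_kind)
  if (predictor_sd <= 0) abort("predictor_sd must be positive")
  if (outcome_scale <= 0) abort("outcome_scale must be positive")
  k <- predictor_sd / outcome_scale
  tibble::tibble(beta_std = beta * k, se_std = se * k)
}

#' Latent-scale outcome SD of a fitted logistic model
#'
#' `sqrt(var(linear predictor) + pi^2/3)`: the standard deviation of the
#' latent continuous liability implied by the logistic model. With a null
#' linear predictor this is `pi/sqrt(3)`.
#'
#' @param fit A fitted `glm` with binomial family.
#' @return A positive scalar.
#' @export
logistic_outcome_scale <- function(fit) {
  lp <- predict(fit, type = "link")
  sqrt(var(lp) * (length(lp) - 1) / length(lp) + pi^2 / 3)
}

#' Mediation decomposition for one candidate mediator
#'
#' Decomposes a hub gene's effect on binary disease status into a direct
#' path and an indirect path through one mediator gene, using three
#' covariate-adjusted regressions:
#' \enumerate{
#'   \item logistic `status ~ hub + covariates` (total effect `c`);
#'   \item linear `mediator ~ hub + covariates` (path `a`);
#'   \item logistic `status ~ mediator + hub + covariates` (paths `b` on
#'     the mediator, `c'` on the hub).
#' }
#' Betas are standardized to a common latent outcome scale
#' ([standardize_beta()]; the step-3 scale is shared by `b` and `c'` so the
#' decomposition is internally consistent), the indirect effect is
#' `a_std * b_std`, and its null is tested with [sobel_z()].
#'
#' @param samples Sample tibble with `status` and the adjustment columns.
#' @param hub Numeric per-sample expression of the hub gene (named by
#'   sample id or positional).
#' @param mediator Numeric per-sample expression of the candidate mediator.
#' @param adjust Covariate adjustment set
#'   (default `c("age_at_death", "pmi", "rin")`).
#' @param mediator_id Optional label.
#' @return Object of class `"mediation_fit"` with standardized total,
#'   direct and indirect effects, `ratio_indirect_direct`,
#'   `pct_total_mediated` (= indirect / (direct + indirect)), `z`, `p`.
#' @export
mediation_fit <- function(samples, hub, mediator,
                          adjust = c("age_at_death", "pmi", "rin"),
                          mediator_id = NA_character_) {
  validate_samples(samples)
  if (!is.null(names(hub))) hub <- hub[match(samples$sample_id, names(hub))]
  if (!is.null(names(mediator))) {
    mediator <- mediator[match(samples$sample_id, names(mediator))]
  }
  dat <- dplyr::bind_cols(
    tibble::tibble(.status = status_indicator(samples$status),
                   .x = hub, .m = mediator),
    samples[, adjust, drop = FALSE])
  dat <- dat[complete.cases(dat), ]
  if (nrow(dat) < 20) abort("fewer than 20 complete cases")
  if (var(dat$.x) == 0 || var(dat$.m) == 0) {
    abort("hub and mediator expression must vary")
  }

  covs <- paste(adjust, collapse = " + ")
  safe_glm <- function(formula, step) {
    fit <- suppressWarnings(glm(stats::as.formula(formula), data = dat,
                                family = binomial()))
    if (!fit$converged) abort(paste0("logistic step ", step, " did not converge"))
    # complete/quasi-complete separation: vanishing deviance or a diverging
    # linear predictor (finite-MLE fits never reach these)
    if (fit$deviance < 1e-6 || max(abs(predict(fit, type = "link"))) > 30) {
      abort(paste0("perfect separation in logistic step ", step))
    }
    if (anyNA(coef(fit))) {
      abort(paste0("collinear predictors in logistic step ", step))
    }
    fit
  }

  step1 <- safe_glm(paste(".status ~ .x +", covs), 1)
  step2 <- lm(stats::as.formula(paste(".m ~ .x +", covs)), data = dat)
  step3 <- safe_glm(paste(".status ~ .m + .x +", covs), 3)

  sd_x <- sd(dat$.x); sd_m <- sd(dat$.m)
  s1 <- logistic_outcome_scale(step1)
  s3 <- logistic_outcome_scale(step3)

  c_tot <- unname(summary(step1)$coefficients[".x", 1:2])
  a_cf <- unname(summary(step2)$coefficients[".x", 1:2])
  b_cf <- unname(summary(step3)$coefficients[".m", 1:2])
  cp_cf <- unname(summary(step3)$coefficients[".x", 1:2])

  total <- standardize_beta(c_tot[1], c_tot[2], "logistic", sd_x, s1)
  a_std <- standardize_beta(a_cf[1], a_cf[2], "linear", sd_x, sd_m)
  b_std <- standardize_beta(b_cf[1], b_cf[2], "logistic", sd_m, s3)
  direct <- standardize_beta(cp_cf[1], cp_cf[2], "logistic", sd_x, s3)

  indirect <- a_std$beta_std * b_std$beta_std
  sz <- sobel_z(a_std$beta_std, a_std$se_std, b_std$beta_std, b_std$se_std)

  structure(list(
    mediator_id = mediator_id,
    total_effect_std = total$beta_std,
    direct_effect_std = direct$beta_std,
    indirect_effect_std = indirect,
    a_std = a_std$beta_std, se_a_std = a_std$se_std,
    b_std = b_std$beta_std, se_b_std = b_std$se_std,
    ratio_indirect_direct = indirect / direct$beta_std,
    pct_total_mediated = indirect / (direct$beta_std + indirect),
    z = sz$z, p = sz$p, n_used = nrow(dat),
    outcome_scale = s3, scale_convention = "latent (pi^2/3)"),
    class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("<mediation_fit> ", x$mediator_id,
      ": direct = ", format(x$direct_effect_std, digits = 3),
      ", indirect = ", format(x$indirect_effect_std, digits = 3),
      " (", format(100 * x$pct_total_mediated, digits = 3),
      "% mediated), Sobel p = ", format(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Tidy / summarize a mediation fit
#'
#' @param x A `"mediation_fit"` object.
#' @param ... Unused.
#' @return `tidy()`: one row per standardized effect; `glance()`: one-row
#'   overview with the mediated proportion and Sobel test.
#' @export
tidy.mediation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("total", "direct", "indirect", "a (hub -> mediator)",
             "b (mediator -> status)"),
    estimate = c(x$total_effect_std, x$direct_effect_std,
                 x$indirect_effect_std, x$a_std, x$b_std),
    std.error = c(NA, NA, NA, x$se_a_std, x$se_b_std))
}

#' @rdname tidy.mediation_fit
#' @export
glance.mediation_fit <- function(x, ...) {
  tibble::tibble(mediator_id = x$mediator_id,
                 direct_effect = x$direct_effect_std,
                 indirect_effect = x$indirect_effect_std,
                 ratio_indirect_direct = x$ratio_indirect_direct,
                 pct_total_mediated = x$pct_total_mediated,
                 z = x$z, p = x$p, n_used = x$n_used)
}

#' Mediation bookkeeping from direct and indirect effects
#'
#' @param direct,indirect Standardized direct and indirect effects.
#' @return Tibble `ratio` (= indirect/direct) and `pct_mediated`
#'   (= indirect / (direct + indirect), as a percentage).
#' @export
mediation_proportions <- function(direct, indirect) {
  tibble::tibble(ratio = indirect / direct,
                 pct_mediated = 100 * indirect / (direct + indirect))
}

#' Run the mediation scan over candidate mediators
#'
#' @param expr Log2 expression tibble.
#' @param samples Sample tibble.
#' @param hub_probe Probe id of the hub gene.
#' @param mediator_probes Probe ids of candidate mediators (the hub probe
#'   is skipped if present).
#' @param adjust Covariate adjustment set.
#' @return Tibble (one row per mediator) of glance summaries.
#' @export
run_mediation <- function(expr, samples, hub_probe, mediator_probes,
                          adjust = c("age_at_death", "pmi", "rin")) {
  m <- expr_matrix(expr)
  if (!hub_probe %in% rownames(m)) abort(paste0("hub probe not found: ", hub_probe))
  hub <- m[hub_probe, ]
  mediator_probes <- setdiff(mediator_probes, hub_probe)
  purrr::map_dfr(mediator_probes, function(pr) {
    tryCatch(
      glance(mediation_fit(samples, hub, m[pr, ], adjust, mediator_id = pr)),
      error = function(e) {
        warn(paste0("mediator ", pr, " skipped: ", conditionMessage(e)))
        tibble::tibble(mediator_id = pr, direct_effect = NA_real_,
                       indirect_effect = NA_real_,
                       ratio_indirect_direct = NA_real_,
                       pct_total_mediated = NA_real_, z = NA_real_,
                       p = NA_real_, n_used = NA_integer_)
      })
  })
}

#' Filter and rank a mediation scan
#'
#' Keeps mediators with Sobel `p <= p_cutoff` and sorts by the percentage
#' of the total effect mediated, mirroring the usual presentation of
#' partial-mediation tables.
#'
#' @param results Tibble from [run_mediation()].
#' @param p_cutoff Retention threshold (default 0.05, inclusive).
#' @return Filtered, ranked tibble.
#' @export
summarize_mediation <- function(results, p_cutoff = 0.05) {
  results |>
    dplyr::filter(.data$p <= p_cutoff) |>
    dplyr::arrange(dplyr::desc(.data$pct_total_mediated))
}

#' Bar chart of mediated proportions
#'
#' @param results Tibble from [run_mediation()] or [summarize_mediation()].
#' @return A ggplot object.
#' @export
plot_mediation_summary <- function(results) {
  dat <- dplyr::mutate(results,
                       mediator_id = stats::reorder(.data$mediator_id,
                                                    .data$pct_total_mediated))
  ggplot2::ggplot(dat, ggplot2::aes(x = 100 * .data$pct_total_mediated,
                                    y = .data$mediator_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "% of total effect mediated", y = NULL) +
    ggplot2::theme_minimal()
}
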