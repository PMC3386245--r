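# Small in-code fixtures shared across test files.

# expression tibble from a matrix (probes x samples)
make_expr <- function(m, probe_ids = sprintf("P%03d", seq_len(nrow(m))),
                      sample_ids = colnames(m) %||%
                        sprintf("S%02d", seq_len(ncol(m)))) {
  colnames(m) <- sample_ids
  out <- dplyr::bind_cols(tibble::tibble(probe_id = probe_ids),
                          tibble::as_tibble(as.data.frame(m,
                                                          check.names = FALSE)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal covariate table: n1 controls then n2 cases
make_samples <- function(n_control, n_case, seed = 1) {
  withr::with_seed(seed, {
    n <- n_control + n_case
    tibble::tibble(
      sample_id = sprintf("S%02d", seq_len(n)),
      status = rep(c("control", "case"), c(n_control, n_case)),
      age_at_death = rnorm(n, 76, 8),
      pmi = exp(rnorm(n, log(9), 0.6)),
      rin = pmin(pmax(rnorm(n, 7.4, 0.8), 0.5), 10),
      ph = rnorm(n, 6.7, 0.2),
      age_at_onset = ifelse(rep(c(FALSE, TRUE), c(n_control, n_case)),
                            rnorm(n, 65, 8), NA_real_))
  })
}

# all-pass flag list aligned with an expression tibble
make_clean_flags <- function(expr) {
  sids <- names(expr)[-1]
  one <- function(val) {
    fl <- expr
    for (s in sids) fl[[s]] <- rep(val, nrow(expr))
    fl
  }
  list(InDetectableRange = one(TRUE), IsWellAboveBG = one(TRUE),
       gIsSaturated = one(FALSE), gIsFeatPopnOL = one(FALSE),
       gIsFeatNonUnifOL = one(FALSE))
}

# set specific cells of a flag table
set_flag_rows <- function(flags, name, rows, frac_fail, fail_value, seed = 1) {
  sids <- names(flags[[name]])[-1]
  withr::with_seed(seed, {
    for (r in rows) {
      hit <- sample(sids, round(frac_fail * length(sids)))
      for (s in hit) flags[[name]][[s]][r] <- fail_value
    }
  })
  flags
}
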