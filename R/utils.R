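# Internal helpers shared across modules.

two_sided_p <- function(z) {
  # survival function keeps precision at extreme |z|
  2 * pnorm(abs(z), lower.tail = FALSE)
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Validate a sample covariate table
#'
#' Checks the invariants every downstream stage assumes: unique sample ids,
#' status restricted to `"case"`/`"control"`, RIN in (0, 10], PMI >= 0, and
#' age at onset missing for controls.
#'
#' @param samples A data frame with columns `sample_id`, `status` and any of
#'   `age_at_death`, `pmi`, `rin`, `ph`, `age_at_onset`.
#' @return The input, invisibly, as a tibble (called for its side effect of
#'   failing loudly on malformed tables).
#' @export
validate_samples <- function(samples) {
  samples <- tibble::as_tibble(samples)
  need <- c("sample_id", "status")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    abort(paste0("sample table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort(paste0("duplicate sample_id: ",
                 paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
                       collapse = ", ")))
  }
  bad_status <- setdiff(unique(samples$status), c("case", "control"))
  if (length(bad_status) > 0) {
    abort(paste0("status must be 'case' or 'control'; found: ",
                 paste(bad_status, collapse = ", ")))
  }
  if ("rin" %in% names(samples)) {
    rin <- samples$rin[!is.na(samples$rin)]
    if (any(rin <= 0 | rin > 10)) abort("rin must lie in (0, 10]")
  }
  if ("pmi" %in% names(samples)) {
    pmi <- samples$pmi[!is.na(samples$pmi)]
    if (any(pmi < 0)) abort("pmi must be non-negative")
  }
  if ("age_at_onset" %in% names(samples)) {
    ctrl <- samples$status == "control"
    if (any(!is.na(samples$age_at_onset[ctrl]))) {
      abort("age_at_onset must be missing for controls")
    }
  }
  invisible(samples)
}

# status indicator: case = 1, control = 0 (so positive beta = up in cases)
status_indicator <- function(status) as.integer(status == "case")

# Build the regression design used by diffexpr / esnp / mediation stages:
# intercept + status + adjustment covariates, complete cases only.
# Returns list(X, keep) where keep indexes rows of `samples` retained.
build_design <- function(samples, adjust) {
  miss <- setdiff(adjust, names(samples))
  if (length(miss) > 0) {
    abort(paste0("adjustment covariate(s) not in sample table: ",
                 paste(miss, collapse = ", ")))
  }
  covs <- as.matrix(as.data.frame(samples[, adjust, drop = FALSE]))
  storage.mode(covs) <- "double"
  st <- status_indicator(samples$status)
  keep <- !is.na(st)
  if (length(adjust) > 0) keep <- keep & complete.cases(covs)
  X <- cbind(`(Intercept)` = 1, status = st, covs)[keep, , drop = FALSE]
  list(X = X, keep = which(keep))
}

# Error if the design matrix is rank deficient, naming offending columns.
check_full_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  invisible(X)
}

# Expression tables are tibbles: first column `probe_id`, remaining columns
# one per sample. These helpers move between tibble and matrix form.
expr_matrix <- function(expr) {
  m <- as.matrix(as.data.frame(expr[, -1, drop = FALSE]))
  storage.mode(m) <- "double"
  rownames(m) <- expr$probe_id
  m
}

expr_tibble <- function(m, probe_id = rownames(m)) {
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(probe_id = probe_id), out)
}

expr_sample_ids <- function(expr) names(expr)[-1]

validate_expression <- function(expr, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (names(expr)[1] != "probe_id") {
    abort("expression table must have 'probe_id' as its first column")
  }
  sids <- expr_sample_ids(expr)
  if (anyDuplicated(sids)) {
    abort(paste0("duplicate sample id(s): ",
                 paste(unique(sids[duplicated(sids)]), collapse = ", ")))
  }
  m <- expr_matrix(expr)
  if (any(is.infinite(m))) abort("expression values must be finite")
  if (scale == "raw" && any(m <= 0, na.rm = TRUE)) {
    abort("raw-scale expression values must be strictly positive")
  }
  invisible(expr)
}

# deterministic substream seeds: one master seed fans out to named streams
# so e.g. enlarging the probe set cannot perturb the genotype draws
stream_seeds <- function(seed, streams) {
  force(seed)   # evaluate before snapshotting the caller's RNG state
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, length(streams)), streams)
}

with_seed <- function(seed, code) {
  force(seed)   # evaluate before snapshotting the caller's RNG state
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
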