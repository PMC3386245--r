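#' Probe-filtering policy
#'
#' Encodes the two removal rules applied to one-color array probes before
#' analysis:
#' \enumerate{
#'   \item a probe is removed if its signal lies outside the detectable
#'     spike-in range (flag `InDetectableRange == FALSE`) in more than
#'     `detect_frac` of the control arrays \emph{and} more than
#'     `detect_frac` of the case arrays;
#'   \item a probe is removed if any single quality flag takes its failing
#'     value in more than `flag_frac` of all arrays.
#' }
#' The default checked flags and their failing values follow the Agilent
#' feature-extraction conventions: `IsWellAboveBG = 0`, `gIsSaturated = 1`,
#' `gIsFeatPopnOL = 1`, `gIsFeatNonUnifOL = 1`.
#'
#' @param detect_frac Per-group fraction for the detectable-range rule
#'   (strict `>`; default 0.50).
#' @param flag_frac All-array fraction for the flag rule (strict `>`;
#'   default 0.75).
#' @param flags_checked Named logical vector: names are flag-table names,
#'   values the \emph{failing} flag value.
#' @param detect_flag Name of the detectable-range flag table.
#' @return A list of class `"filter_policy"`.
#' @export
filter_policy <- function(detect_frac = 0.50, flag_frac = 0.75,
                          flags_checked = c(IsWellAboveBG = FALSE,
                                            gIsSaturated = TRUE,
                                            gIsFeatPopnOL = TRUE,
                                            gIsFeatNonUnifOL = TRUE),
                          detect_flag = "InDetectableRange") {
  stopifnot(detect_frac > 0, detect_frac <= 1, flag_frac > 0, flag_frac <= 1)
  structure(list(detect_frac = detect_frac, flag_frac = flag_frac,
                 flags_checked = flags_checked, detect_flag = detect_flag),
            class = "filter_policy")
}

#' Filter probes on quality flags
#'
#' Applies a [filter_policy()] to an expression table and its flag tables.
#' Flag tables must be row-aligned with the expression table (same probes,
#' same order; replicated probe rows are filtered row-wise).
#'
#' @param expr Expression tibble (`probe_id` + sample columns).
#' @param flags Named list of logical flag tibbles (see [read_flags()]);
#'   must contain the policy's `detect_flag` and every checked flag.
#' @param samples Sample tibble with `sample_id` and `status`.
#' @param policy A [filter_policy()].
#' @return A list with `expr` (retained rows), `flags` (subset likewise) and
#'   `removed`, a tibble of `probe_id` and semicolon-joined `reason`.
#' @export
filter_probes <- function(expr, flags, samples, policy = filter_policy()) {
  validate_samples(samples)
  sids <- expr_sample_ids(expr)
  if (!setequal(sids, samples$sample_id)) {
    abort("expression sample ids and sample table do not match")
  }
  needed <- c(policy$detect_flag, names(policy$flags_checked))
  for (nm in needed) {
    fl <- flags[[nm]]
    if (is.null(fl)) abort(paste0("missing flag table: ", nm))
    if (nrow(fl) != nrow(expr) || !identical(fl$probe_id, expr$probe_id)) {
      abort(paste0("flag table ", nm, " is not row-aligned with expression"))
    }
  }
  flag_mat <- function(nm) {
    m <- as.matrix(as.data.frame(flags[[nm]][, sids, drop = FALSE]))
    storage.mode(m) <- "logical"
    m
  }

  is_case <- samples$status[match(sids, samples$sample_id)] == "case"
  out_of_range <- !flag_mat(policy$detect_flag)
  frac_ctrl <- rowMeans(out_of_range[, !is_case, drop = FALSE])
  frac_case <- rowMeans(out_of_range[, is_case, drop = FALSE])
  rm_detect <- frac_ctrl > policy$detect_frac & frac_case > policy$detect_frac

  reasons <- ifelse(rm_detect, "out_of_detectable_range", NA_character_)
  rm_any <- rm_detect
  for (nm in names(policy$flags_checked)) {
    fails <- flag_mat(nm) == policy$flags_checked[[nm]]
    rm_flag <- rowMeans(fails) > policy$flag_frac
    reasons <- ifelse(rm_flag, ifelse(is.na(reasons), nm,
                                      paste(reasons, nm, sep = ";")), reasons)
    rm_any <- rm_any | rm_flag
  }

  removed <- tibble::tibble(probe_id = expr$probe_id[rm_any],
                            reason = reasons[rm_any])
  list(expr = expr[!rm_any, , drop = FALSE],
       flags = purrr::map(flags, ~ .x[!rm_any, , drop = FALSE]),
       removed = removed)
}

#' Collapse replicated probes to their per-sample median
#'
#' Replicated probes (duplicate `probe_id` rows surviving the quality
#' filter) are summarized by the per-sample median across replicates. Probe
#' order of first appearance is preserved; tables without duplicates pass
#' through unchanged.
#'
#' @param expr Expression tibble, possibly with duplicate `probe_id` rows.
#' @return Expression tibble with one row per probe.
#' @export
collapse_replicates <- function(expr) {
  if (!anyDuplicated(expr$probe_id)) return(expr)
  scale <- attr(expr, "scale")
  out <- expr |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(dplyr::across(dplyr::everything(),
                                   ~ median(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$probe_id, unique(expr$probe_id)))
  attr(out, "scale") <- scale
  out
}

#' Quantile-normalize and log2-transform an expression table
#'
#' Forces every array to share the same distribution: each column's order
#' statistics are replaced by the cross-column mean of order statistics
#' (ties within a column receive the mean of the reference values at their
#' tied ranks), then values are base-2 log transformed. Normalization is
#' performed by [limma::normalizeQuantiles()] with `ties = TRUE`.
#'
#' @param expr Raw-scale expression tibble (strictly positive values).
#' @param log2_transform Apply `log2` after normalization (default `TRUE`).
#' @return Expression tibble with `"scale"` attribute `"log2"` (or `"raw"`
#'   when `log2_transform = FALSE`).
#' @export
quantile_normalize <- function(expr, log2_transform = TRUE) {
  m <- expr_matrix(expr)
  norm <- limma::normalizeQuantiles(m, ties = TRUE)
  if (log2_transform) {
    if (any(norm <= 0, na.rm = TRUE)) {
      abort("non-positive value encountered at the log2 step")
    }
    norm <- log2(norm)
  }
  out <- expr_tibble(norm, expr$probe_id)
  attr(out, "scale") <- if (log2_transform) "log2" else "raw"
  out
}

#' Flag outlier arrays by inter-array distance (optional heuristic)
#'
#' A lightweight stand-in for interactive array-quality review: computes
#' each array's mean Spearman correlation distance (1 - rho) to all other
#' arrays and flags arrays whose mean distance exceeds the median by more
#' than `k` MADs. Off by default in the pipeline.
#'
#' @param expr Expression tibble.
#' @param k MAD multiplier (default 3).
#' @return Tibble `sample_id`, `mean_distance`, `outlier`.
#' @export
detect_outlier_arrays <- function(expr, k = 3) {
  m <- expr_matrix(expr)
  rho <- cor(m, method = "spearman", use = "pairwise.complete.obs")
  d <- 1 - rho
  diag(d) <- NA
  md <- rowMeans(d, na.rm = TRUE)
  cut <- median(md) + k * mad(md)
  tibble::tibble(sample_id = colnames(m), mean_distance = unname(md),
                 outlier = unname(md > cut))
}

#' @importFrom stats mad
NULL
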