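#' Read per-study GWAS summary statistics
#'
#' Reads one tab-delimited file per study with columns `snp_id`, `a1`, `a2`,
#' `a1_freq`, `beta`, `se`, `p`, `n`, `rsq`, `geno_status` (`I` imputed /
#' `G` genotyped) and stacks them into one long table keyed by SNP and
#' study. A study's `direction` is `"+"`/`"-"` from the sign of its beta and
#' `"?"` when the study does not contribute that SNP: the SNP is absent from
#' the study file, or it was imputed with quality `rsq` below `rsq_min`.
#'
#' Alleles are harmonized across studies against the first study reporting
#' each SNP. With `allele_policy = "strict"` (default) any mismatch is an
#' error naming the SNP; with `"flip"`, studies reporting the same pair in
#' swapped order have beta negated and frequency complemented. Strand flips
#' are never attempted.
#'
#' @param paths Character vector of file paths, one per study.
#' @param study_names Names for the studies; default the `names(paths)` or
#'   file basenames.
#' @param rsq_min Imputation-quality threshold below which an imputed
#'   SNP-study pair is excluded (strict `<`).
#' @param allele_policy `"strict"` or `"flip"`.
#' @return A long tibble: one row per SNP per study with the columns above
#'   plus `study` and `direction`. Excluded pairs keep their row with
#'   `direction == "?"`.
#' @export
read_study_stats <- function(paths, study_names = NULL, rsq_min = 0.30,
                             allele_policy = c("strict", "flip")) {
  allele_policy <- match.arg(allele_policy)
  if (is.null(study_names)) {
    study_names <- names(paths) %||% tools::file_path_sans_ext(basename(paths))
  }
  stopifnot(length(paths) == length(study_names))

  one <- function(path, study) {
    tbl <- read_strict_tsv(path)
    need <- c("snp_id", "a1", "a2", "beta", "se", "p")
    miss <- setdiff(need, names(tbl))
    if (length(miss) > 0) {
      abort(paste0(path, ": missing column(s): ", paste(miss, collapse = ", ")))
    }
    for (nm in intersect(c("a1_freq", "beta", "se", "p", "n", "rsq"), names(tbl))) {
      tbl[[nm]] <- parse_numeric_column(tbl[[nm]], nm, path)
    }
    if (!"rsq" %in% names(tbl)) tbl$rsq <- NA_real_
    if (!"geno_status" %in% names(tbl)) tbl$geno_status <- "I"
    if (!"n" %in% names(tbl)) tbl$n <- NA_real_
    if (!"a1_freq" %in% names(tbl)) tbl$a1_freq <- NA_real_
    if (any(tbl$se <= 0, na.rm = TRUE)) abort(paste0(path, ": se must be positive"))
    if (any(tbl$p <= 0 | tbl$p > 1, na.rm = TRUE)) {
      abort(paste0(path, ": p-values must lie in (0, 1]"))
    }
    tbl$study <- study
    tbl
  }

  stats <- dplyr::bind_rows(purrr::map2(paths, study_names, one))

  # harmonize alleles to the first study reporting each SNP
  ref <- stats |>
    dplyr::distinct(.data$snp_id, .keep_all = TRUE) |>
    dplyr::select("snp_id", ref_a1 = "a1", ref_a2 = "a2")
  stats <- dplyr::left_join(stats, ref, by = "snp_id")
  same <- stats$a1 == stats$ref_a1 & stats$a2 == stats$ref_a2
  swapped <- stats$a1 == stats$ref_a2 & stats$a2 == stats$ref_a1
  if (any(!same & !swapped)) {
    abort(paste0("allele mismatch across studies for SNP(s): ",
                 paste(unique(stats$snp_id[!same & !swapped]), collapse = ", ")))
  }
  if (any(swapped)) {
    if (allele_policy == "strict") {
      abort(paste0("alleles swapped across studies for SNP(s): ",
                   paste(unique(stats$snp_id[swapped]), collapse = ", "),
                   " (set allele_policy = 'flip' to harmonize)"))
    }
    stats$beta[swapped] <- -stats$beta[swapped]
    stats$a1_freq[swapped] <- 1 - stats$a1_freq[swapped]
    stats$a1[swapped] <- stats$ref_a1[swapped]
    stats$a2[swapped] <- stats$ref_a2[swapped]
  }
  stats$ref_a1 <- NULL
  stats$ref_a2 <- NULL

  # complete the SNP x study grid; absent pairs get direction '?'
  grid <- tidyr::expand_grid(snp_id = unique(stats$snp_id),
                             study = study_names)
  stats <- dplyr::left_join(grid, stats, by = c("snp_id", "study"))
  stats$direction <- dplyr::case_when(
    is.na(stats$beta) ~ "?",
    stats$geno_status == "I" & !is.na(stats$rsq) & stats$rsq < rsq_min ~ "?",
    stats$beta >= 0 ~ "+",
    TRUE ~ "-")
  dplyr::arrange(stats, .data$snp_id,
                 match(.data$study, study_names))
}

#' Write one study's summary statistics
#'
#' @param stats A tibble with at least `snp_id`, `a1`, `a2`, `beta`, `se`, `p`.
#' @param path Output path.
#' @export
write_study_stats <- function(stats, path) {
  keep <- intersect(c("snp_id", "a1", "a2", "a1_freq", "beta", "se", "p",
                      "n", "rsq", "geno_status"), names(stats))
  readr::write_tsv(stats[, keep], path, na = "NA")
  invisible(path)
}

#' Direction strings
#'
#' Collapse the per-study `direction` column into one compact string per
#' SNP (e.g. `"+++?++"`), and parse such strings back into per-study
#' symbols.
#'
#' @param stats Long summary-statistic tibble from [read_study_stats()].
#' @param study_order Optional study ordering for the string.
#' @return `direction_strings()`: tibble `snp_id`, `direction`;
#'   `parse_direction()`: character vector of single symbols.
#' @export
direction_strings <- function(stats, study_order = unique(stats$study)) {
  stats |>
    dplyr::mutate(study = factor(.data$study, levels = study_order)) |>
    dplyr::arrange(.data$snp_id, .data$study) |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(direction = paste(.data$direction, collapse = ""),
                     .groups = "drop")
}

#' @rdname direction_strings
#' @param x A direction string such as `"+++?++"`.
#' @export
parse_direction <- function(x) {
  sym <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- setdiff(sym, c("+", "-", "?"))
  if (length(bad) > 0) {
    abort(paste0("invalid direction symbol(s): ", paste(bad, collapse = ", ")))
  }
  sym
}
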