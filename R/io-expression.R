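#' Read a probe-by-sample expression table
#'
#' Reads a tab-delimited export with one header row of sample ids and the
#' probe id in the first column, the layout produced by one-color array
#' feature-extraction pipelines once the processed signal column has been
#' pivoted to a matrix. Duplicate probe rows (replicated probes on the
#' array) are retained; collapsing happens in [collapse_replicates()].
#'
#' @param path Path to a tab-delimited file.
#' @param scale Either `"raw"` (strictly positive intensities) or `"log2"`.
#' @return A tibble with first column `probe_id` and one numeric column per
#'   sample, carrying a `"scale"` attribute.
#' @seealso [write_expression()], [read_flags()]
#' @export
read_expression <- function(path, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  tbl <- read_strict_tsv(path)
  if (ncol(tbl) < 2) abort(paste0(path, ": expected a probe column plus sample columns"))
  names(tbl)[1] <- "probe_id"
  sids <- names(tbl)[-1]
  if (anyDuplicated(sids)) {
    abort(paste0(path, ": duplicate sample id(s): ",
                 paste(unique(sids[duplicated(sids)]), collapse = ", ")))
  }
  out <- tbl
  for (j in seq_along(sids)) {
    out[[j + 1]] <- parse_numeric_column(tbl[[j + 1]], sids[j], path)
  }
  validate_expression(out, scale)
  attr(out, "scale") <- scale
  out
}

#' Write a probe-by-sample expression table
#'
#' @param expr Expression tibble (`probe_id` + sample columns).
#' @param path Output path; tab-delimited, UTF-8, LF endings, missing values
#'   written as `NA`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path, na = "NA")
  invisible(path)
}

#' Read or write per-probe-per-sample boolean flag tables
#'
#' Flag tables (e.g. `IsWellAboveBG`, `gIsSaturated`, `InDetectableRange`)
#' share the expression layout, with cells coded 0/1.
#'
#' @param path Path to a tab-delimited 0/1 table.
#' @return A tibble of logicals with first column `probe_id`.
#' @export
read_flags <- function(path) {
  tbl <- read_strict_tsv(path)
  names(tbl)[1] <- "probe_id"
  for (j in seq.int(2L, ncol(tbl))) {
    v <- parse_numeric_column(tbl[[j]], names(tbl)[j], path)
    if (any(!v %in% c(0, 1) & !is.na(v))) {
      abort(paste0(path, ": flag values must be 0 or 1 (column ", names(tbl)[j], ")"))
    }
    tbl[[j]] <- as.logical(v)
  }
  tbl
}

#' @rdname read_flags
#' @param flags A logical flag tibble as returned by [read_flags()].
#' @export
write_flags <- function(flags, path) {
  out <- flags
  for (j in seq.int(2L, ncol(out))) out[[j]] <- as.integer(out[[j]])
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Read and write the sample covariate table
#'
#' Columns: `sample_id`, `status` (`case`/`control`), `age_at_death` (years),
#' `pmi` (hours), `rin`, `ph`, `age_at_onset` (years; always missing for
#' controls). Validated with [validate_samples()].
#'
#' @param path Path to a tab-delimited table.
#' @return A tibble, one row per sample.
#' @export
read_sample_table <- function(path) {
  tbl <- read_strict_tsv(path)
  for (nm in intersect(c("age_at_death", "pmi", "rin", "ph", "age_at_onset"),
                       names(tbl))) {
    tbl[[nm]] <- parse_numeric_column(tbl[[nm]], nm, path)
  }
  validate_samples(tbl)
  tbl
}

#' @rdname read_sample_table
#' @param samples A sample tibble.
#' @export
write_sample_table <- function(samples, path) {
  validate_samples(samples)
  readr::write_tsv(tibble::as_tibble(samples), path, na = "NA")
  invisible(path)
}

#' Read and write gene sets in GMT format
#'
#' One set per line: set name, description, then member gene ids, all
#' tab-separated. Returned in tidy long form.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble with columns `set_name`, `description`, `gene`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  rows <- purrr::map(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(paste0(path, ": GMT line with no members: ", substr(l, 1, 40)))
    }
    tibble::tibble(set_name = parts[1], description = parts[2],
                   gene = unique(parts[-(1:2)]))
  })
  set_names <- purrr::map_chr(rows, ~ .x$set_name[1])
  if (anyDuplicated(set_names)) {
    abort(paste0(path, ": duplicate set name: ",
                 paste(unique(set_names[duplicated(set_names)]), collapse = ", ")))
  }
  dplyr::bind_rows(rows)
}

#' @rdname read_gmt
#' @param sets A tidy gene-set tibble (`set_name`, optional `description`,
#'   `gene`).
#' @export
write_gmt <- function(sets, path) {
  if (!"description" %in% names(sets)) sets$description <- ""
  lines <- sets |>
    dplyr::group_by(.data$set_name) |>
    dplyr::summarise(
      line = paste(c(.data$set_name[1], .data$description[1], .data$gene),
                   collapse = "\t"),
      .groups = "drop")
  readr::write_lines(lines$line, path)
  invisible(path)
}

#' Read and write the probe-to-gene annotation
#'
#' @param path Tab-delimited two-column table (`probe_id`, `gene`).
#' @return A tibble mapping each annotated probe to one gene.
#' @export
read_annotation <- function(path) {
  tbl <- read_strict_tsv(path)
  names(tbl)[1:2] <- c("probe_id", "gene")
  if (anyDuplicated(tbl$probe_id)) {
    abort(paste0(path, ": probe annotated to more than one gene"))
  }
  tbl
}

#' @rdname read_annotation
#' @param annotation Annotation tibble.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(tibble::as_tibble(annotation), path, na = "NA")
  invisible(path)
}

# ---- strict low-level readers -------------------------------------------

# Read a tab-delimited file, refusing ragged rows (silent truncation).
read_strict_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tbl <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    name_repair = "minimal", progress = FALSE, na = character()))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    p1 <- probs[1, ]
    abort(paste0(path, ": malformed table (row ", p1$row, ": expected ",
                 p1$expected, ", got ", p1$actual, ")"))
  }
  tbl
}

# Convert a character column to numeric; "NA" and "" are missing, anything
# else non-numeric is a parse error naming row and column.
parse_numeric_column <- function(x, col_name, path) {
  miss <- x %in% c("NA", "")
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !miss)
  if (length(bad) > 0) {
    abort(paste0(path, ": non-numeric value '", x[bad[1]], "' at row ",
                 bad[1], ", column '", col_name, "'"))
  }
  v
}
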