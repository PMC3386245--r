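#' Read genotypes from PLINK .raw / .map files
#'
#' The `.raw` file (additive recoding export) has header columns
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP named
#' `<snp>_<counted allele>`, with dosages in 0/1/2/NA counting the exported
#' allele. The `.map` file has columns chromosome, SNP id, genetic distance
#' and 1-based physical position, optionally followed by the two alleles.
#'
#' Dosages are re-expressed as minor-allele counts: if the counted allele's
#' frequency exceeds 0.5 the column is recoded `2 - dosage` and the counted
#' allele swapped; at exactly 0.5 the exported allele is kept as counted.
#'
#' @param raw_path,map_path Paths to the `.raw` and `.map` files.
#' @return A list of class `"genotypes"` with elements
#'   \describe{
#'     \item{dosage}{tibble `sample_id` + one 0/1/2/NA column per SNP, in
#'       map order, counting the minor allele}
#'     \item{map}{tibble `snp_id`, `chr`, `pos`, `a1` (counted allele),
#'       `a2` (other allele or `NA`)}
#'     \item{maf}{tibble `snp_id`, `maf` computed from non-missing dosages}
#'   }
#' @export
read_genotypes_raw <- function(raw_path, map_path) {
  raw <- tibble::as_tibble(read.table(raw_path, header = TRUE,
                                      check.names = FALSE,
                                      colClasses = "character"))
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!identical(names(raw)[seq_along(fixed)], fixed)) {
    abort(paste0(raw_path, ": expected header FID IID PAT MAT SEX PHENOTYPE"))
  }
  snp_cols <- names(raw)[-seq_along(fixed)]
  snp_ids <- sub("_[^_]*$", "", snp_cols)
  counted <- sub("^.*_", "", snp_cols)

  map <- tibble::as_tibble(read.table(map_path, header = FALSE,
                                      colClasses = "character"))
  if (ncol(map) < 4) abort(paste0(map_path, ": expected >= 4 columns"))
  names(map)[1:4] <- c("chr", "snp_id", "cm", "pos")
  map$pos <- parse_numeric_column(map$pos, "pos", map_path)
  if (any(map$pos <= 0 | map$pos != round(map$pos))) {
    abort(paste0(map_path, ": positions must be positive integers"))
  }
  if (ncol(map) >= 6) {
    names(map)[5:6] <- c("a1", "a2")
  } else {
    map$a1 <- NA_character_
    map$a2 <- NA_character_
  }

  missing_snps <- setdiff(snp_ids, map$snp_id)
  if (length(missing_snps) > 0) {
    abort(paste0(raw_path, ": SNP(s) absent from map: ",
                 paste(missing_snps, collapse = ", ")))
  }

  dose <- matrix(NA_real_, nrow = nrow(raw), ncol = length(snp_cols),
                 dimnames = list(NULL, snp_ids))
  for (j in seq_along(snp_cols)) {
    v <- parse_numeric_column(raw[[snp_cols[j]]], snp_cols[j], raw_path)
    if (any(!v %in% c(0, 1, 2) & !is.na(v))) {
      abort(paste0(raw_path, ": dosage outside {0,1,2,NA} in column ",
                   snp_cols[j]))
    }
    dose[, j] <- v
  }

  # minor-allele orientation
  freq <- colMeans(dose, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  other <- rep(NA_character_, length(snp_ids))
  dose[, flip] <- 2 - dose[, flip, drop = FALSE]
  counted_out <- counted
  counted_out[flip] <- NA_character_   # minor allele unknown unless map has it
  map_order <- match(map$snp_id, snp_ids)
  map_order <- map_order[!is.na(map_order)]

  ord_ids <- snp_ids[map_order]
  dosage <- dplyr::bind_cols(
    tibble::tibble(sample_id = raw$IID),
    tibble::as_tibble(as.data.frame(dose[, ord_ids, drop = FALSE],
                                    check.names = FALSE)))

  map_out <- map[map$snp_id %in% snp_ids, c("snp_id", "chr", "pos", "a1", "a2")]
  map_out <- map_out[match(ord_ids, map_out$snp_id), ]
  # prefer map alleles; fall back to the .raw header's counted allele
  no_a1 <- is.na(map_out$a1)
  map_out$a1[no_a1] <- counted_out[map_order][no_a1]

  maf <- pmin(freq, 1 - freq)[ord_ids]
  structure(list(dosage = dosage,
                 map = tibble::as_tibble(map_out),
                 maf = tibble::tibble(snp_id = ord_ids, maf = unname(maf))),
            class = "genotypes")
}

#' Write genotypes to PLINK .raw / .map files
#'
#' @param geno A `"genotypes"` object (see [read_genotypes_raw()]).
#' @param raw_path,map_path Output paths.
#' @export
write_genotypes_raw <- function(geno, raw_path, map_path) {
  snps <- geno$map$snp_id
  a1 <- ifelse(is.na(geno$map$a1), "A", geno$map$a1)
  hdr <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
           paste0(snps, "_", a1))
  n <- nrow(geno$dosage)
  body <- cbind(geno$dosage$sample_id, geno$dosage$sample_id,
                "0", "0", "0", "-9",
                format_na(as.matrix(geno$dosage[, snps, drop = FALSE])))
  lines <- c(paste(hdr, collapse = " "),
             apply(body, 1, paste, collapse = " "))
  readr::write_lines(lines, raw_path)

  map <- geno$map
  map_cols <- cbind(map$chr, map$snp_id, "0", format(map$pos, scientific = FALSE,
                                                     trim = TRUE),
                    format_na(map$a1), format_na(map$a2))
  readr::write_lines(apply(map_cols, 1, paste, collapse = "\t"), map_path)
  invisible(raw_path)
}

format_na <- function(x) {
  x <- format(x, trim = TRUE, scientific = FALSE)
  x[grepl("^ *NA *$", x)] <- "NA"
  x
}

#' @export
print.genotypes <- function(x, ...) {
  cat("<genotypes> ", nrow(x$dosage), " samples x ", nrow(x$map), " SNPs\n",
      sep = "")
  print(head(x$map), ...)
  invisible(x)
}
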