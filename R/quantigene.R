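#' Normalize and test a bead-based validation panel
#'
#' Implements the five-step procedure used to validate array hits on a
#' QuantiGene-style multiplex panel measured in triplicate:
#' \enumerate{
#'   \item subtract the per-measurement background from each raw count;
#'   \item average the three background-subtracted replicates per gene per
#'     sample;
#'   \item normalize each sample's gene means by the geometric mean of the
#'     two control genes in that sample;
#'   \item take base-2 logarithms;
#'   \item fit, per target gene, a linear model of the log2 normalized
#'     value on case/control status adjusted for age at death and PMI.
#' }
#'
#' @param counts Long tibble with columns `sample_id`, `gene`, `replicate`,
#'   `raw`, `background` (one row per measurement).
#' @param samples Sample tibble with `sample_id`, `status`, `age_at_death`,
#'   `pmi`.
#' @param control_genes Character vector of exactly two housekeeping genes
#'   present in `counts`.
#' @return A list with `values` (tibble `sample_id`, `gene`, `log2_norm`)
#'   and `fits` (tibble `gene`, `beta_status`, `se`, `t`, `p`,
#'   `fold_change`, `direction`, `n_used`; control genes excluded).
#' @export
quantigene_normalize <- function(counts, samples, control_genes) {
  validate_samples(samples)
  if (length(control_genes) != 2) abort("exactly two control genes required")
  miss <- setdiff(control_genes, unique(counts$gene))
  if (length(miss) > 0) {
    abort(paste0("control gene(s) absent from panel: ",
                 paste(miss, collapse = ", ")))
  }
  if (any(counts$background >= counts$raw)) {
    abort("background must be smaller than the raw count for every measurement")
  }
  n_rep <- counts |>
    dplyr::count(.data$sample_id, .data$gene)
  if (length(unique(n_rep$n)) != 1) {
    abort("incomplete replicate sets: every sample x gene needs the same number of replicates")
  }

  means <- counts |>
    dplyr::mutate(net = .data$raw - .data$background) |>
    dplyr::group_by(.data$sample_id, .data$gene) |>
    dplyr::summarise(mean_net = mean(.data$net), .groups = "drop")

  ctrl <- means |>
    dplyr::filter(.data$gene %in% control_genes) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(gm = geometric_mean(.data$mean_net), .groups = "drop")
  if (any(!is.finite(ctrl$gm) | ctrl$gm <= 0)) {
    abort("control-gene value <= 0; cannot normalize")
  }

  values <- means |>
    dplyr::left_join(ctrl, by = "sample_id") |>
    dplyr::mutate(log2_norm = log2(.data$mean_net / .data$gm)) |>
    dplyr::select("sample_id", "gene", "log2_norm")

  targets <- setdiff(unique(values$gene), control_genes)
  fits <- purrr::map_dfr(targets, function(g) {
    v <- values[values$gene == g, ]
    dat <- dplyr::inner_join(v, samples, by = "sample_id")
    fit <- fit_probe(setNames(dat$log2_norm, dat$sample_id),
                     dat, adjust = c("age_at_death", "pmi"))
    dplyr::mutate(fit, gene = g, .before = 1)
  })
  list(values = values,
       fits = dplyr::select(fits, -"probe_id"))
}
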