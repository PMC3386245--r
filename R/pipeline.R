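#' Pipeline configuration
#'
#' Assembles stage toggles, input paths and thresholds for
#' [run_pipeline()]. Any argument can also be supplied through a YAML file
#' (values given directly override the file). Thresholds default to the
#' conventional analysis settings: FDR q < 0.05, fold-change report cut
#' 1.5, MAF >= 0.1, imputation Rsq >= 0.30, alpha 0.05, mediation
#' p <= 0.05.
#'
#' @param expr_path,samples_path,annotation_path,gmt_path Paths to the
#'   expression table, sample table, probe-to-gene annotation and GMT gene
#'   sets.
#' @param flag_paths Named character vector of flag-table paths.
#' @param raw_path,map_path PLINK-style genotype paths (eSNP stage).
#' @param study_paths Named character vector of per-study summary-statistic
#'   paths (meta stage).
#' @param stages Character vector of stages to run, in pipeline order.
#' @param hub_set Gene-set name whose genes define the TFBS stratum.
#' @param hub_gene Hub gene; default: the set's most significant DE gene.
#' @param adjust_expr,adjust_mediation Covariate adjustment sets.
#' @param fdr_q,fc_report,maf_min,rsq_min,alpha,mediation_p Thresholds.
#' @param meta_mode `"ivw"` or `"weighted_z"`.
#' @param seed Integer seed recorded in the manifest.
#' @param yaml_path Optional YAML file of the same fields.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expr_path = NULL, samples_path = NULL,
                            annotation_path = NULL, gmt_path = NULL,
                            flag_paths = NULL, raw_path = NULL,
                            map_path = NULL, study_paths = NULL,
                            stages = c("preprocess", "diffexpr", "enrichment",
                                       "esnp", "mediation", "meta"),
                            hub_set = "TFBS_hub", hub_gene = NULL,
                            adjust_expr = c("rin", "pmi", "age_at_death"),
                            adjust_mediation = c("age_at_death", "pmi", "rin"),
                            fdr_q = 0.05, fc_report = 1.5, maf_min = 0.1,
                            rsq_min = 0.30, alpha = 0.05, mediation_p = 0.05,
                            meta_mode = "ivw", seed = 1L,
                            yaml_path = NULL) {
  cfg <- as.list(environment())
  cfg$yaml_path <- NULL
  if (!is.null(yaml_path)) {
    from_file <- yaml::read_yaml(yaml_path)
    given <- names(as.list(match.call()))[-1]
    for (nm in setdiff(names(from_file), given)) cfg[[nm]] <- from_file[[nm]]
  }
  stopifnot(cfg$fdr_q > 0, cfg$fdr_q < 1, cfg$maf_min >= 0, cfg$maf_min <= 0.5,
            cfg$rsq_min >= 0, cfg$rsq_min <= 1)
  structure(cfg, class = "pipeline_config")
}

stage_deps <- list(preprocess = character(),
                   diffexpr = "preprocess",
                   enrichment = "diffexpr",
                   esnp = "diffexpr",
                   mediation = "diffexpr",
                   meta = character())

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (preprocess, diffexpr, enrichment,
#' eSNP, mediation, meta), writing each stage's tables under `out_dir` and
#' a `manifest.json` recording the package version, seed, configuration,
#' input-file hashes and per-stage record counts -- enough to reproduce
#' the run exactly. A stage error aborts with the stage name; outputs of
#' completed stages are kept.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  for (s in stages) {
    need <- setdiff(stage_deps[[s]], stages)
    if (length(need) > 0) {
      abort(paste0("stage '", s, "' requires disabled stage(s): ",
                   paste(need, collapse = ", ")))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  manifest <- list(package = "decohort",
                   version = as.character(utils::packageVersion("decohort")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "stages")],
                   stages = list())
  inputs <- unlist(config[c("expr_path", "samples_path", "annotation_path",
                            "gmt_path", "flag_paths", "raw_path", "map_path",
                            "study_paths")])
  inputs <- inputs[!is.na(inputs) & file.exists(inputs)]
  manifest$input_md5 <- as.list(tools::md5sum(inputs))

  log_stage <- function(stage, n_in, n_out, t0) {
    message(sprintf("[%s] %d records in, %d out (%.1fs)", stage, n_in, n_out,
                    as.numeric(Sys.time()) - t0))
    manifest$stages[[stage]] <<- list(n_in = n_in, n_out = n_out)
  }
  run_stage <- function(stage, fn) {
    t0 <- as.numeric(Sys.time())
    tryCatch(fn(t0), error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }

  samples <- read_sample_table(config$samples_path)
  annotation <- if (!is.null(config$annotation_path)) {
    read_annotation(config$annotation_path)
  }

  if ("preprocess" %in% stages) {
    run_stage("preprocess", function(t0) {
      expr <- read_expression(config$expr_path, scale = "raw")
      flags <- purrr::map(config$flag_paths, read_flags)
      filt <- filter_probes(expr, flags, samples)
      norm <- quantile_normalize(collapse_replicates(filt$expr))
      readr::write_tsv(filt$removed, file.path(out_dir, "removed_probes.tsv"))
      write_expression(norm, file.path(out_dir, "expression_normalized.tsv"))
      results$expr <<- norm
      log_stage("preprocess", nrow(expr), nrow(norm), t0)
    })
  }

  if ("diffexpr" %in% stages) {
    run_stage("diffexpr", function(t0) {
      de <- run_diffexpr(results$expr, samples, config$adjust_expr, annotation)
      readr::write_tsv(de, file.path(out_dir, "diffexpr.tsv"))
      results$de <<- de
      log_stage("diffexpr", nrow(results$expr), nrow(de), t0)
    })
  }

  sig <- function() dplyr::filter(results$de, .data$q < config$fdr_q)

  if ("enrichment" %in% stages) {
    run_stage("enrichment", function(t0) {
      sets <- read_gmt(config$gmt_path)
      sg <- sig()
      enr <- set_enrichment(unique(na.omit(sg$gene)),
                            unique(na.omit(results$de$gene)), sets)
      readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
      hub_genes <- sets$gene[sets$set_name == config$hub_set]
      hub_probes <- annotation$probe_id[annotation$gene %in% hub_genes]
      hub_gene <- config$hub_gene %||%
        sg$gene[sg$gene %in% hub_genes][which.min(sg$p[sg$gene %in% hub_genes])]
      dir_res <- direction_enrichment(
        sg, hub_probes,
        exclude = annotation$probe_id[annotation$gene %in% hub_gene])
      dir_tbl <- tibble::tibble(
        set = config$hub_set,
        pct_up_in_set = dir_res$percent_up[["in_set"]],
        pct_up_out_set = dir_res$percent_up[["out_set"]],
        chi2 = dir_res$chi2, p = dir_res$p, odds_ratio = dir_res$odds_ratio)
      readr::write_tsv(dir_tbl, file.path(out_dir, "direction_enrichment.tsv"))
      results$enrichment <<- enr
      results$direction <<- dir_res
      results$hub_gene <<- hub_gene
      log_stage("enrichment", nrow(sg), nrow(enr), t0)
    })
  }

  if ("esnp" %in% stages) {
    run_stage("esnp", function(t0) {
      geno <- read_genotypes_raw(config$raw_path, config$map_path)
      sets <- read_gmt(config$gmt_path)
      hub_genes <- sets$gene[sets$set_name == config$hub_set]
      sg <- sig()
      probes <- sg$probe_id[!is.na(sg$gene) & sg$gene %in% hub_genes]
      res <- run_esnp(results$expr, samples, geno, probes = probes,
                      adjust = config$adjust_expr, maf_min = config$maf_min)
      eff <- effective_tests(geno, blocks = geno$map$chr)
      thr <- corrected_threshold(eff$m_eff * length(probes), config$alpha)
      readr::write_tsv(res, file.path(out_dir, "esnp.tsv"))
      readr::write_tsv(
        dplyr::mutate(eff, n_probes = length(probes),
                      corrected_threshold = thr),
        file.path(out_dir, "esnp_threshold.tsv"))
      results$esnp <<- res
      results$esnp_threshold <<- thr
      log_stage("esnp", length(probes) * nrow(geno$maf), nrow(res), t0)
    })
  }

  if ("mediation" %in% stages) {
    run_stage("mediation", function(t0) {
      sets <- read_gmt(config$gmt_path)
      hub_genes <- sets$gene[sets$set_name == config$hub_set]
      sg <- sig()
      hub_gene <- results$hub_gene %||% config$hub_gene %||%
        sg$gene[sg$gene %in% hub_genes][which.min(sg$p[sg$gene %in% hub_genes])]
      hub_rows <- results$de[!is.na(results$de$gene) &
                               results$de$gene == hub_gene, ]
      hub_probe <- hub_rows$probe_id[which.min(hub_rows$p)]
      mediators <- sg$probe_id[!is.na(sg$gene) & sg$gene %in% hub_genes &
                                 sg$gene != hub_gene]
      med <- run_mediation(results$expr, samples, hub_probe, mediators,
                           adjust = config$adjust_mediation)
      ranked <- summarize_mediation(med, config$mediation_p)
      readr::write_tsv(med, file.path(out_dir, "mediation_all.tsv"))
      readr::write_tsv(ranked, file.path(out_dir, "mediation.tsv"))
      results$mediation <<- ranked
      log_stage("mediation", length(mediators), nrow(ranked), t0)
    })
  }

  if ("meta" %in% stages) {
    run_stage("meta", function(t0) {
      stats <- read_study_stats(config$study_paths,
                                rsq_min = config$rsq_min)
      met <- run_meta(stats, mode = config$meta_mode,
                      rsq_min = config$rsq_min)
      readr::write_tsv(met, file.path(out_dir, "meta.tsv"))
      results$meta <<- met
      log_stage("meta", nrow(stats), nrow(met), t0)
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

#' End-to-end synthetic demonstration run
#'
#' Simulates a cohort with [simulate_cohort()] (plus summary statistics
#' from [simulate_study_stats()]), writes every artifact in its exchange
#' format under `out_dir/inputs`, then runs the full pipeline on those
#' files. One seed drives everything.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param config Optional [sim_config()] (its seed is overridden by
#'   `seed`).
#' @return Invisibly, the [run_pipeline()] results (with the simulation
#'   truth attached as `$truth`).
#' @export
run_demo <- function(out_dir, seed = 1L, config = NULL) {
  cfg <- config %||% sim_config(seed = seed)
  cfg$seed <- seed
  sim <- simulate_cohort(cfg)
  ind <- file.path(out_dir, "inputs")
  dir.create(ind, recursive = TRUE, showWarnings = FALSE)

  write_expression(sim$expr, file.path(ind, "expression_raw.tsv"))
  flag_paths <- purrr::imap_chr(sim$flags, function(fl, nm) {
    p <- file.path(ind, paste0("flag_", nm, ".tsv"))
    write_flags(fl, p)
    p
  })
  write_sample_table(sim$samples, file.path(ind, "samples.tsv"))
  write_annotation(sim$annotation, file.path(ind, "annotation.tsv"))
  write_gmt(sim$sets, file.path(ind, "sets.gmt"))
  write_genotypes_raw(sim$geno, file.path(ind, "genotypes.raw"),
                      file.path(ind, "genotypes.map"))
  studies <- simulate_study_stats(sim$geno$map$snp_id, seed = seed + 7L)
  study_paths <- purrr::imap_chr(studies, function(s, nm) {
    p <- file.path(ind, paste0(nm, ".tsv"))
    write_study_stats(s, p)
    p
  })
  jsonlite::write_json(
    list(hub_probe = sim$truth$hub_probe,
         mediators = sim$truth$mediators$probe_id,
         esnp = sim$truth$esnp,
         n_de = sum(sim$truth$de$de)),
    file.path(ind, "truth.json"), auto_unbox = TRUE, pretty = TRUE)

  cfg_run <- pipeline_config(
    expr_path = file.path(ind, "expression_raw.tsv"),
    samples_path = file.path(ind, "samples.tsv"),
    annotation_path = file.path(ind, "annotation.tsv"),
    gmt_path = file.path(ind, "sets.gmt"),
    flag_paths = flag_paths,
    raw_path = file.path(ind, "genotypes.raw"),
    map_path = file.path(ind, "genotypes.map"),
    study_paths = study_paths,
    hub_gene = sim$annotation$gene[match(sim$truth$hub_probe,
                                         sim$annotation$probe_id)],
    seed = seed)
  res <- run_pipeline(cfg_run, out_dir)
  res$truth <- sim$truth
  invisible(res)
}
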