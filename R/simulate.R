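#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of [simulate_cohort()]. Defaults emulate the
#' statistical structure of a post-mortem prefrontal-cortex case/control
#' microarray study: 27 cases / 26 controls, a shorter post-mortem
#' interval in cases, RIN around 7.4, a modest log2 differential-expression
#' effect with TFBS-enriched, upward-biased direction of change, one
#' injected eSNP with a stronger effect in cases, and a hub-to-mediator
#' liability model that makes the case/control labels causally downstream
#' of the hub gene (so mediation holds by construction). Probe and gene
#' counts are desk-scale (10,000 probes) while preserving the fraction of
#' differentially expressed probes and the TFBS background fraction.
#'
#' @param n_case,n_control Group sizes (defaults 27 and 26).
#' @param n_probes Number of distinct probes.
#' @param n_genes Number of genes (probes map many-to-one onto genes).
#' @param frac_replicated Fraction of probes duplicated on the array.
#' @param frac_tfbs_genes Fraction of genes carrying the hub TF's binding
#'   site.
#' @param n_de_probes Number of probes given an explicit status effect.
#' @param de_effect_log2 Magnitude of that effect (log2 units).
#' @param tfbs_de_enrichment_or Odds ratio of being differentially
#'   expressed for TFBS vs non-TFBS probes.
#' @param frac_up_in_tfbs,frac_up_in_other Probability a DE probe goes up
#'   in cases, by TFBS stratum.
#' @param age_mean,age_sd Age at death (years), both groups.
#' @param pmi_meanlog_case,pmi_meanlog_control,pmi_sdlog Lognormal PMI
#'   (hours); cases shorter, the one covariate tied to status.
#' @param rin_mean,rin_sd RIN, truncated to (0, 10].
#' @param ph_mean,ph_sd Tissue pH.
#' @param rin_effect_sd,pmi_effect_sd,age_effect_sd Per-probe SDs of the
#'   covariate slopes on log2 expression.
#' @param baseline_mean,baseline_sd Per-probe baseline log2 intensity.
#' @param noise_sd Residual SD on the log2 scale.
#' @param n_mediators Number of mediator genes downstream of the hub.
#' @param hub_a Hub-to-mediator latent slope (per mediator).
#' @param hub_b Mediator-to-liability slope (per mediator).
#' @param hub_c_direct Direct hub-to-liability slope.
#' @param hub_expr_scale,mediator_expr_scale log2 units of expression per
#'   latent SD for hub and mediator probes.
#' @param esnp_maf Minor-allele frequency of the injected eSNP.
#' @param esnp_beta_geno Genotype main effect on the target probe
#'   (dominant coding, log2 units).
#' @param esnp_beta_interaction Additional genotype effect in cases.
#' @param n_snps Total SNPs on the genotyping panel.
#' @param ld_block_sizes Sizes of the LD blocks (must sum to `n_snps`).
#' @param within_block_r Latent within-block correlation in `[0, 1)`.
#' @param maf_range Range for the remaining SNPs' MAFs.
#' @param frac_fail_detect,frac_fail_flag Fractions of probes engineered to
#'   fail the detectable-range rule and the quality-flag rule.
#' @param seed Integer seed (mandatory); one master seed feeds separate
#'   substreams for structure, covariates, liability, genotypes, expression
#'   and flags, so enlarging one component does not perturb the others.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_case = 27, n_control = 26,
                       n_probes = 10000, n_genes = 8000,
                       frac_replicated = 0.03,
                       frac_tfbs_genes = 0.32,
                       n_de_probes = 130, de_effect_log2 = 0.4,
                       tfbs_de_enrichment_or = 2,
                       frac_up_in_tfbs = 0.78, frac_up_in_other = 0.66,
                       age_mean = 76, age_sd = 8,
                       pmi_meanlog_case = log(6.5),
                       pmi_meanlog_control = log(12),
                       pmi_sdlog = 0.7,
                       rin_mean = 7.4, rin_sd = 0.8,
                       ph_mean = 6.67, ph_sd = 0.2,
                       rin_effect_sd = 0.04, pmi_effect_sd = 0.01,
                       age_effect_sd = 0.005,
                       baseline_mean = 8, baseline_sd = 1.5,
                       noise_sd = 0.25,
                       n_mediators = 10, hub_a = 0.4, hub_b = 0.3,
                       hub_c_direct = 0.4,
                       hub_expr_scale = 0.8, mediator_expr_scale = 0.8,
                       esnp_maf = 0.15, esnp_beta_geno = -0.49,
                       esnp_beta_interaction = -0.24,
                       n_snps = 52, ld_block_sizes = rep(4, 13),
                       within_block_r = 0.8, maf_range = c(0.1, 0.5),
                       frac_fail_detect = 0.02, frac_fail_flag = 0.01,
                       seed) {
  if (missing(seed)) abort("seed is mandatory")
  fracs <- c(frac_replicated, frac_tfbs_genes, frac_up_in_tfbs,
             frac_up_in_other, frac_fail_detect, frac_fail_flag)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (n_de_probes > n_probes) abort("n_de_probes must not exceed n_probes")
  if (tfbs_de_enrichment_or < 1) abort("tfbs_de_enrichment_or must be >= 1")
  if (sum(ld_block_sizes) != n_snps) {
    abort("ld_block_sizes must sum to n_snps")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Assign differential expression status with a target set-enrichment OR
#'
#' Draws per-probe Bernoulli differential-expression indicators whose
#' stratum-specific probabilities satisfy a target odds ratio between TFBS
#' and non-TFBS probes while keeping the expected number of DE probes at
#' `n_de`; signed effects are then drawn with stratum-specific
#' up-in-case fractions.
#'
#' @param probes Tibble with `probe_id` and logical `tfbs`.
#' @param n_de Expected number of DE probes.
#' @param enrichment_or Target odds ratio (>= 1).
#' @param frac_up_in_tfbs,frac_up_in_other Up-in-case probabilities.
#' @param de_effect_log2 Effect magnitude.
#' @return Input tibble plus `de` (logical) and `effect` (signed log2
#'   effect, 0 for non-DE probes).
#' @export
simulate_de_truth <- function(probes, n_de, enrichment_or,
                              frac_up_in_tfbs, frac_up_in_other,
                              de_effect_log2) {
  n1 <- sum(probes$tfbs); n0 <- sum(!probes$tfbs)
  stopifnot(n1 > 0, n0 > 0, n_de < n1 + n0)
  # solve per-stratum rates: odds(p1)/odds(p0) = OR, n1 p1 + n0 p0 = n_de
  fn <- function(p0) {
    p1 <- enrichment_or * p0 / (1 - p0 + enrichment_or * p0)
    n1 * p1 + n0 * p0 - n_de
  }
  p0 <- stats::uniroot(fn, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  p1 <- enrichment_or * p0 / (1 - p0 + enrichment_or * p0)
  de <- rbinom(nrow(probes), 1, ifelse(probes$tfbs, p1, p0)) == 1
  up_prob <- ifelse(probes$tfbs, frac_up_in_tfbs, frac_up_in_other)
  sign <- ifelse(rbinom(nrow(probes), 1, up_prob) == 1, 1, -1)
  dplyr::mutate(probes, de = de,
                effect = ifelse(de, sign * de_effect_log2, 0))
}

#' Simulate a full synthetic cohort
#'
#' Generates every artifact the pipeline consumes, under the structure
#' described in [sim_config()]: expression = per-probe baseline +
#' covariate effects + explicit status effects on DE probes + hub and
#' mediator signal + one eSNP effect + Gaussian noise, on the log2 scale
#' (returned as raw intensities `2^x` for the normalization stage to
#' process). Case/control status is assigned by ranking a latent liability
#' (direct hub effect + mediator effects + logistic noise) and labelling
#' the top `n_case` samples as cases, so mediation through the mediator
#' genes is true by construction and group sizes are exact.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expr` (raw-scale expression tibble,
#'   including replicated probe rows), `flags` (named list of flag
#'   tibbles), `samples`, `annotation` (probe-to-gene), `sets` (tidy gene
#'   sets; the hub TFBS set is `"TFBS_hub"`), `geno` (a `"genotypes"`
#'   object) and `truth` (everything needed to score recovery: DE effects,
#'   TFBS membership, mediators with their slopes, the injected eSNP,
#'   per-sample latent liability).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  n <- cf$n_case + cf$n_control
  seeds <- stream_seeds(cf$seed, c("structure", "covariates", "liability",
                                   "genotypes", "expression", "flags"))
  sample_ids <- sprintf("S%03d", seq_len(n))

  # ---- structure: genes, probes, sets, DE truth -------------------------
  structure_ <- with_seed(seeds["structure"], {
    genes <- sprintf("G%05d", seq_len(cf$n_genes))
    tfbs_genes <- sample(genes, round(cf$frac_tfbs_genes * cf$n_genes))
    probe_ids <- sprintf("P%06d", seq_len(cf$n_probes))
    gene_of <- c(genes[seq_len(min(cf$n_genes, cf$n_probes))],
                 sample(genes, max(0, cf$n_probes - cf$n_genes), replace = TRUE))
    probes <- tibble::tibble(probe_id = probe_ids, gene = gene_of,
                             tfbs = gene_of %in% tfbs_genes)
    truth_de <- simulate_de_truth(probes, cf$n_de_probes,
                                  cf$tfbs_de_enrichment_or,
                                  cf$frac_up_in_tfbs, cf$frac_up_in_other,
                                  cf$de_effect_log2)
    # hub + mediators live in the TFBS stratum
    tfbs_de <- truth_de$probe_id[truth_de$tfbs & truth_de$de]
    if (length(tfbs_de) < cf$n_mediators + 2) {
      abort("not enough TFBS DE probes to host the hub and its mediators")
    }
    hub_probe <- tfbs_de[1]
    mediator_probes <- tfbs_de[seq.int(2, cf$n_mediators + 1)]
    # eSNP targets a TFBS DE probe outside the mediator set: mediator probes
    # carry an extra unit-scale latent that would mask a log2-scale genotype
    # effect at n ~ 50
    esnp_probe <- tfbs_de[cf$n_mediators + 2]
    # hub and mediators get their signal from the liability model, not an
    # explicit status effect
    truth_de$effect[truth_de$probe_id %in% c(hub_probe, mediator_probes)] <- 0

    decoys <- purrr::map(1:5, ~ sample(genes, round(0.1 * cf$n_genes)))
    sets <- dplyr::bind_rows(
      tibble::tibble(set_name = "TFBS_hub", gene = tfbs_genes),
      purrr::imap_dfr(decoys, ~ tibble::tibble(
        set_name = paste0("TFBS_decoy", .y), gene = .x)))
    sets$description <- "synthetic"

    replicated <- sample(probe_ids, round(cf$frac_replicated * cf$n_probes))
    list(probes = truth_de, sets = sets, hub_probe = hub_probe,
         mediator_probes = mediator_probes, esnp_probe = esnp_probe,
         replicated = replicated)
  })
  probes <- structure_$probes

  # ---- liability model and status ---------------------------------------
  liab <- with_seed(seeds["liability"], {
    x <- rnorm(n)
    m_lat <- vapply(seq_len(cf$n_mediators), function(j) {
      cf$hub_a * x + sqrt(1 - cf$hub_a^2) * rnorm(n)
    }, numeric(n))
    liability <- cf$hub_c_direct * x + cf$hub_b * rowSums(m_lat)
    score <- liability + rlogis(n)
    list(x = x, m_lat = m_lat, liability = liability, score = score)
  })
  status <- rep("control", n)
  status[order(liab$score, decreasing = TRUE)[seq_len(cf$n_case)]] <- "case"
  is_case <- status == "case"

  # ---- covariates -------------------------------------------------------
  samples <- with_seed(seeds["covariates"], {
    rin <- pmin(pmax(rnorm(n, cf$rin_mean, cf$rin_sd), 1e-3), 10)
    pmi <- exp(rnorm(n, ifelse(is_case, cf$pmi_meanlog_case,
                               cf$pmi_meanlog_control), cf$pmi_sdlog))
    age <- rnorm(n, cf$age_mean, cf$age_sd)
    onset <- ifelse(is_case, pmax(age - exp(rnorm(n, log(8), 0.5)), 30),
                    NA_real_)
    tibble::tibble(sample_id = sample_ids, status = status,
                   age_at_death = round(age, 1), pmi = round(pmi, 2),
                   rin = round(rin, 1), ph = round(rnorm(n, cf$ph_mean,
                                                         cf$ph_sd), 2),
                   age_at_onset = round(onset, 1))
  })

  # ---- genotypes --------------------------------------------------------
  mafs <- with_seed(seeds["genotypes"],
                    c(cf$esnp_maf,
                      runif(cf$n_snps - 1, cf$maf_range[1], cf$maf_range[2])))
  geno <- simulate_ld_genotypes(n, cf$ld_block_sizes, cf$within_block_r,
                                mafs, seed = seeds["genotypes"] + 1L,
                                sample_ids = sample_ids)
  esnp_snp <- geno$map$snp_id[1]
  esnp_dom <- dominant_code(geno$dosage[[esnp_snp]])

  # ---- expression -------------------------------------------------------
  expr <- with_seed(seeds["expression"], {
    row_probes <- c(probes$probe_id,
                    structure_$replicated)   # replicate rows appended
    idx <- match(row_probes, probes$probe_id)
    n_rows <- length(row_probes)
    baseline <- rnorm(cf$n_probes, cf$baseline_mean, cf$baseline_sd)
    rin_sl <- rnorm(cf$n_probes, 0, cf$rin_effect_sd)
    pmi_sl <- rnorm(cf$n_probes, 0, cf$pmi_effect_sd)
    age_sl <- rnorm(cf$n_probes, 0, cf$age_effect_sd)

    st <- as.numeric(is_case)
    m <- matrix(baseline[idx], n_rows, n) +
      outer(rin_sl[idx], samples$rin - mean(samples$rin)) +
      outer(pmi_sl[idx], samples$pmi - mean(samples$pmi)) +
      outer(age_sl[idx], samples$age_at_death - mean(samples$age_at_death)) +
      outer(probes$effect[idx], st) +
      matrix(rnorm(n_rows * n, 0, cf$noise_sd), n_rows, n)

    hub_rows <- which(row_probes == structure_$hub_probe)
    m[hub_rows, ] <- m[hub_rows, , drop = FALSE] +
      rep(cf$hub_expr_scale * liab$x, each = length(hub_rows))
    for (j in seq_len(cf$n_mediators)) {
      rows_j <- which(row_probes == structure_$mediator_probes[j])
      m[rows_j, ] <- m[rows_j, , drop = FALSE] +
        rep(cf$mediator_expr_scale * liab$m_lat[, j], each = length(rows_j))
    }
    esnp_rows <- which(row_probes == structure_$esnp_probe)
    esnp_term <- (cf$esnp_beta_geno + cf$esnp_beta_interaction * st) * esnp_dom
    esnp_term[is.na(esnp_term)] <- 0
    m[esnp_rows, ] <- m[esnp_rows, , drop = FALSE] +
      rep(esnp_term, each = length(esnp_rows))

    colnames(m) <- sample_ids
    out <- expr_tibble(2^m, row_probes)   # raw intensities
    attr(out, "scale") <- "raw"
    out
  })

  # ---- flags ------------------------------------------------------------
  flags <- with_seed(seeds["flags"], {
    n_rows <- nrow(expr)
    protected <- expr$probe_id %in% c(probes$probe_id[probes$de],
                                      structure_$hub_probe,
                                      structure_$mediator_probes,
                                      structure_$esnp_probe)
    eligible <- which(!protected)
    bad_detect <- sample(eligible, round(cf$frac_fail_detect * n_rows))
    eligible2 <- setdiff(eligible, bad_detect)
    bad_flag <- sample(eligible2, round(cf$frac_fail_flag * n_rows))

    mk <- function(fill = TRUE) {
      mm <- matrix(fill, n_rows, n, dimnames = list(NULL, sample_ids))
      mm
    }
    detect <- mk(TRUE)
    detect[sample.int(length(detect), round(0.02 * length(detect)))] <- FALSE
    detect[bad_detect, ] <- matrix(runif(length(bad_detect) * n) > 0.7,
                                   length(bad_detect), n)
    wab <- mk(TRUE)
    wab[sample.int(length(wab), round(0.01 * length(wab)))] <- FALSE
    wab[bad_flag, ] <- matrix(runif(length(bad_flag) * n) > 0.85,
                              length(bad_flag), n)
    to_tbl <- function(mm) {
      out <- expr_tibble(mm * 1, expr$probe_id)
      for (j in seq.int(2, ncol(out))) out[[j]] <- as.logical(out[[j]])
      out
    }
    list(InDetectableRange = to_tbl(detect),
         IsWellAboveBG = to_tbl(wab),
         gIsSaturated = to_tbl(mk(FALSE)),
         gIsFeatPopnOL = to_tbl(mk(FALSE)),
         gIsFeatNonUnifOL = to_tbl(mk(FALSE)))
  })

  truth <- list(
    de = dplyr::select(probes, "probe_id", "gene", "tfbs", "de", "effect"),
    hub_probe = structure_$hub_probe,
    mediators = tibble::tibble(probe_id = structure_$mediator_probes,
                               a = cf$hub_a, b = cf$hub_b),
    c_direct = cf$hub_c_direct,
    esnp = list(snp_id = esnp_snp, probe_id = structure_$esnp_probe,
                beta_geno = cf$esnp_beta_geno,
                beta_interaction = cf$esnp_beta_interaction),
    liability = tibble::tibble(sample_id = sample_ids, x_hub = liab$x,
                               liability = liab$liability,
                               score = liab$score),
    config = cf)

  list(expr = expr, flags = flags, samples = samples,
       annotation = dplyr::select(probes, "probe_id", "gene"),
       sets = structure_$sets[, c("set_name", "description", "gene")],
       geno = geno, truth = truth)
}

#' Simulate genotypes with block linkage disequilibrium
#'
#' Haplotypes are generated from a latent Gaussian factor model: within a
#' block each SNP's latent value is `sqrt(r)` times a shared block factor
#' plus independent noise, thresholded at the allele frequency; dosages
#' are the sum of two independent haplotypes. Realized genotype
#' correlations are therefore attenuated relative to the latent `r`
#' (tetrachoric-style), approach 1 as `r` approaches 1, and are ~0 across
#' blocks.
#'
#' @param n_samples Number of samples.
#' @param block_sizes Integer vector of block sizes.
#' @param r Latent within-block correlation in `[0, 1)`.
#' @param mafs Per-SNP minor-allele frequencies (length = total SNPs).
#' @param seed Integer seed.
#' @param sample_ids Optional sample ids.
#' @return A `"genotypes"` object (see [read_genotypes_raw()]).
#' @export
simulate_ld_genotypes <- function(n_samples, block_sizes, r, mafs, seed,
                                  sample_ids = sprintf("S%03d",
                                                       seq_len(n_samples))) {
  if (r >= 1 || r < 0) abort("r must lie in [0, 1)")
  n_snps <- sum(block_sizes)
  if (length(mafs) != n_snps) abort("length(mafs) must equal sum(block_sizes)")
  if (any(mafs <= 0 | mafs > 0.5)) abort("mafs must lie in (0, 0.5]")

  dose <- with_seed(seed, {
    hap <- function() {
      lat <- matrix(NA_real_, n_samples, n_snps)
      start <- 1L
      for (b in block_sizes) {
        zb <- rnorm(n_samples)
        for (j in seq_len(b)) {
          lat[, start + j - 1L] <- sqrt(r) * zb + sqrt(1 - r) * rnorm(n_samples)
        }
        start <- start + b
      }
      lat < matrix(qnorm(mafs), n_samples, n_snps, byrow = TRUE)
    }
    (hap() + hap()) * 1
  })
  snp_ids <- sprintf("rs%05d", seq_len(n_snps))
  colnames(dose) <- snp_ids
  freq <- colMeans(dose) / 2
  block_id <- rep(seq_along(block_sizes), block_sizes)
  alleles <- c("A", "C", "G", "T")
  map <- tibble::tibble(snp_id = snp_ids,
                        chr = as.character(block_id),
                        pos = 1e6 * block_id + 1e3 * seq_len(n_snps),
                        a1 = alleles[(seq_len(n_snps) - 1) %% 4 + 1],
                        a2 = alleles[seq_len(n_snps) %% 4 + 1])
  dosage <- dplyr::bind_cols(tibble::tibble(sample_id = sample_ids),
                             tibble::as_tibble(as.data.frame(dose)))
  structure(list(dosage = dosage, map = map,
                 maf = tibble::tibble(snp_id = snp_ids,
                                      maf = unname(pmin(freq, 1 - freq)))),
            class = "genotypes")
}

#' Simulate a minimal mediation cohort
#'
#' A direct generator for the hub-mediator-status triangle used to
#' calibrate and validate the mediation stage: `x ~ N(0,1)`,
#' `m = a x + sqrt(1-a^2) e` (unit variance), and
#' `status ~ Bernoulli(plogis(c_direct x + b m))`. On the latent scale the
#' true proportion of the total effect mediated is
#' `a b / (c_direct + a b)`. Independent nuisance covariates (age, PMI,
#' RIN) are included so the standard adjustment set can be exercised.
#'
#' @param n Number of samples.
#' @param a Hub-to-mediator slope.
#' @param b Mediator-to-liability slope.
#' @param c_direct Direct hub-to-liability slope.
#' @param seed Integer seed.
#' @return Tibble `sample_id`, `status`, `x`, `m`, `age_at_death`, `pmi`,
#'   `rin`, with attribute `"true_pct_mediated"`.
#' @export
simulate_mediation_cohort <- function(n, a, b, c_direct, seed) {
  out <- with_seed(seed, {
    x <- rnorm(n)
    m <- a * x + sqrt(max(0, 1 - a^2)) * rnorm(n)
    lp <- c_direct * x + b * m
    status <- ifelse(rbinom(n, 1, stats::plogis(lp)) == 1, "case", "control")
    tibble::tibble(sample_id = sprintf("S%05d", seq_len(n)),
                   status = status, x = x, m = m,
                   age_at_death = rnorm(n, 76, 8),
                   pmi = exp(rnorm(n, log(9), 0.7)),
                   rin = pmin(pmax(rnorm(n, 7.4, 0.8), 1e-3), 10))
  })
  attr(out, "true_pct_mediated") <- a * b / (c_direct + a * b)
  out
}

#' Simulate per-study GWAS summary statistics
#'
#' Generates the meta-analysis input: per-SNP effect estimates for several
#' studies drawn around shared true effects, with per-study sample sizes,
#' imputation-quality values (a fraction falling below the usual 0.30
#' exclusion threshold) and genotyped/imputed status.
#'
#' @param snp_ids SNP identifiers.
#' @param n_studies Number of studies (default 6).
#' @param true_beta True per-SNP effects (recycled; default 0).
#' @param n_range Range of per-study sample sizes.
#' @param frac_low_rsq Fraction of imputed SNP-study pairs with rsq below
#'   0.30.
#' @param seed Integer seed.
#' @return Named list of per-study tibbles in the [write_study_stats()]
#'   layout.
#' @export
simulate_study_stats <- function(snp_ids, n_studies = 6, true_beta = 0,
                                 n_range = c(500, 2000), frac_low_rsq = 0.08,
                                 seed) {
  true_beta <- rep_len(true_beta, length(snp_ids))
  alleles <- c("A", "C", "G", "T")
  with_seed(seed, {
    a1 <- sample(alleles, length(snp_ids), replace = TRUE)
    a2 <- purrr::map_chr(a1, ~ sample(setdiff(alleles, .x), 1))
    freq <- runif(length(snp_ids), 0.05, 0.95)
    out <- purrr::map(seq_len(n_studies), function(s) {
      n <- round(runif(1, n_range[1], n_range[2]))
      se <- 2 / sqrt(n) * exp(rnorm(length(snp_ids), 0, 0.1))
      beta <- true_beta + rnorm(length(snp_ids), 0, se)
      geno <- ifelse(runif(length(snp_ids)) < 0.2, "G", "I")
      rsq <- ifelse(geno == "G", NA_real_,
                    ifelse(runif(length(snp_ids)) < frac_low_rsq,
                           runif(length(snp_ids), 0.05, 0.29),
                           runif(length(snp_ids), 0.30, 1)))
      tibble::tibble(snp_id = snp_ids, a1 = a1, a2 = a2, a1_freq = freq,
                     beta = beta, se = se,
                     p = two_sided_p(beta / se), n = n, rsq = rsq,
                     geno_status = geno)
    })
    setNames(out, paste0("study", seq_len(n_studies)))
  })
}
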