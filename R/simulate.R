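#' Configuration for the synthetic meta-cohort generator
#'
#' Collects and validates all parameters of [simulate_meta_cohort()]. The
#' defaults describe a moderately sized meta-cohort of four datasets whose
#' probeset-level intensities carry additive center and scan-batch offsets,
#' technical-metric-dependent artifacts, dataset-specific clinical
#' composition, and survival endpoints whose hazard depends on a designated
#' target gene.
#'
#' @param n_datasets number of independent datasets to generate.
#' @param samples_per_dataset samples in each dataset.
#' @param n_genes number of genes.
#' @param probesets_per_gene integer range `c(min, max)`; each gene is
#'   measured by a number of probesets drawn uniformly from this range.
#' @param loading_range range of the (positive) probeset loadings on the
#'   underlying gene signal.
#' @param probeset_intercept_sd sd of per-probeset intercepts (log2 units).
#' @param center_effect_sd sd of per-center additive offsets (log2 units).
#' @param batch_effect_sd sd of per-scan-batch additive offsets (log2 units).
#' @param n_centers_per_dataset centers of origin per dataset.
#' @param n_batches_per_dataset scan batches per dataset.
#' @param metric_slope_sd sd of per-probeset slopes on the three technical
#'   quality metrics (pm_iqr, rma_iqr, rna_deg).
#' @param noise_sd residual Gaussian noise sd (log2 units).
#' @param bio_sd per-sample biological sd of the gene signal (log2 units).
#' @param msi_effect_genes fraction of genes carrying an MSI-associated
#'   expression shift.
#' @param msi_effect_size size of that shift (log2 units, added in MSI
#'   samples).
#' @param target_gene_id gene whose (standardized) signal drives the hazard.
#' @param cox_log_hr log hazard ratio per 1 SD of target-gene signal.
#' @param baseline_hazard exponential baseline hazard, events per month.
#' @param censor_time administrative censoring time in months.
#' @param covariate_shift per-dataset clinical composition: a list with one
#'   element per dataset, each a list with elements `gender` (P(M)), `site`
#'   (P(colon)), `msi` (P(MSI)), `stage` (probabilities for I, II, III, IV,
#'   unknown; must sum to 1), `age_mean` and `age_sd` (years). `NULL` uses a
#'   built-in composition that differs across datasets.
#' @param seed integer seed; identical config + seed reproduce the output
#'   byte for byte.
#'
#' @return A validated list of class `"simulation_config"`.
#' @seealso [simulate_meta_cohort()]
#' @export
simulation_config <- function(n_datasets = 4,
                              samples_per_dataset = 120,
                              n_genes = 400,
                              probesets_per_gene = c(1L, 4L),
                              loading_range = c(0.4, 1.2),
                              probeset_intercept_sd = 0.25,
                              center_effect_sd = 0.5,
                              batch_effect_sd = 0.5,
                              n_centers_per_dataset = 2,
                              n_batches_per_dataset = 3,
                              metric_slope_sd = 0.15,
                              noise_sd = 0.3,
                              bio_sd = 1,
                              msi_effect_genes = 0.1,
                              msi_effect_size = 0.5,
                              target_gene_id = "G0001",
                              cox_log_hr = 0.5,
                              baseline_hazard = 0.02,
                              censor_time = 60,
                              covariate_shift = NULL,
                              seed = 1L) {
  cfg <- list(
    n_datasets = as.integer(n_datasets),
    samples_per_dataset = as.integer(samples_per_dataset),
    n_genes = as.integer(n_genes),
    probesets_per_gene = as.integer(probesets_per_gene),
    loading_range = as.numeric(loading_range),
    probeset_intercept_sd = probeset_intercept_sd,
    center_effect_sd = center_effect_sd,
    batch_effect_sd = batch_effect_sd,
    n_centers_per_dataset = as.integer(n_centers_per_dataset),
    n_batches_per_dataset = as.integer(n_batches_per_dataset),
    metric_slope_sd = metric_slope_sd,
    noise_sd = noise_sd,
    bio_sd = bio_sd,
    msi_effect_genes = msi_effect_genes,
    msi_effect_size = msi_effect_size,
    target_gene_id = target_gene_id,
    cox_log_hr = cox_log_hr,
    baseline_hazard = baseline_hazard,
    censor_time = censor_time,
    covariate_shift = covariate_shift,
    seed = as.integer(seed)
  )
  if (cfg$n_datasets < 1L || cfg$samples_per_dataset < 1L || cfg$n_genes < 1L)
    stop("configuration error: counts must be >= 1", call. = FALSE)
  if (length(cfg$probesets_per_gene) != 2L ||
      any(cfg$probesets_per_gene < 1L) ||
      cfg$probesets_per_gene[1] > cfg$probesets_per_gene[2])
    stop("configuration error: probesets_per_gene must be a valid range",
         call. = FALSE)
  sds <- c(cfg$probeset_intercept_sd, cfg$center_effect_sd,
           cfg$batch_effect_sd, cfg$metric_slope_sd, cfg$noise_sd, cfg$bio_sd)
  if (any(sds < 0)) stop("configuration error: sds must be >= 0",
                         call. = FALSE)
  if (cfg$censor_time <= 0)
    stop("configuration error: censor_time must be > 0", call. = FALSE)
  if (cfg$baseline_hazard < 0)
    stop("configuration error: baseline_hazard must be >= 0", call. = FALSE)
  if (is.null(cfg$covariate_shift))
    cfg$covariate_shift <- default_covariate_shift(cfg$n_datasets)
  if (length(cfg$covariate_shift) != cfg$n_datasets)
    stop("configuration error: covariate_shift needs one entry per dataset",
         call. = FALSE)
  for (cs in cfg$covariate_shift) {
    if (abs(sum(cs$stage) - 1) > 1e-8)
      stop("configuration error: stage probabilities must sum to 1",
           call. = FALSE)
  }
  class(cfg) <- "simulation_config"
  cfg
}

# Built-in clinical composition: deliberately different across datasets so
# that IPW standardization has a real composition shift to remove.
default_covariate_shift <- function(n_datasets) {
  gender <- rep(c(0.55, 0.45, 0.60, 0.40), length.out = n_datasets)
  site <- rep(c(0.85, 0.65, 0.90, 0.55), length.out = n_datasets)
  msi <- rep(c(0.15, 0.30, 0.10, 0.35), length.out = n_datasets)
  age_mean <- rep(c(66, 62, 70, 60), length.out = n_datasets)
  stage <- list(
    c(0.18, 0.32, 0.30, 0.15, 0.05),
    c(0.10, 0.25, 0.35, 0.25, 0.05),
    c(0.22, 0.35, 0.28, 0.10, 0.05),
    c(0.12, 0.28, 0.30, 0.25, 0.05)
  )
  lapply(seq_len(n_datasets), function(d) {
    list(gender = gender[d], site = site[d], msi = msi[d],
         stage = stage[[(d - 1L) %% 4L + 1L]],
         age_mean = age_mean[d], age_sd = 10)
  })
}

# Per-dataset RNG stream: derived deterministically from the master seed so
# that datasets are independent and adding a dataset does not perturb the
# earlier ones.
dataset_seed <- function(seed, d) {
  as.integer((as.numeric(seed) * 1009 + d * 9973) %% 2147483647)
}

#' Simulate a multi-dataset probeset-level expression meta-cohort
#'
#' Generates several datasets of probeset-level log2 expression with known
#' technical structure so that every downstream harmonization stage can be
#' checked against ground truth. Each probeset value is
#' `intercept + loading * gene_signal + center_offset + batch_offset +
#' metric_slopes . metrics + noise`. Relapse and overall-survival times are
#' drawn from an exponential hazard
#' `baseline_hazard * exp(cox_log_hr * z)` where `z` is the within-dataset
#' standardized signal of the target gene, with administrative censoring at
#' `censor_time`; the relapse endpoint is only generated for stage I-III
#' samples.
#'
#' Draw order (fixed so that runs are reproducible): first the global layer
#' (gene means, probeset map, loadings, intercepts, metric slopes, MSI gene
#' set) under the master seed, then one independent stream per dataset for
#' clinical covariates, center/batch structure and offsets, technical
#' metrics, gene signal, survival times and probeset noise.
#'
#' @param config a [simulation_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{expression}{named list of probeset-by-sample matrices, one per
#'       dataset.}
#'     \item{clinical}{one data frame over all samples (dataset_id, center,
#'       scan_batch, technical metrics, gender, age, site, msi, stage,
#'       relapse/OS time and event).}
#'     \item{annotation}{data frame mapping probeset_id to gene_id.}
#'     \item{truth}{ground truth: gene_signal matrix (genes x all samples),
#'       probeset loadings/intercepts/metric slopes, per-dataset center and
#'       batch offsets, MSI-affected genes, true log hazard ratio.}
#'   }
#' @examples
#' cfg <- simulation_config(n_datasets = 2, samples_per_dataset = 30,
#'                          n_genes = 20, seed = 7)
#' sim <- simulate_meta_cohort(cfg)
#' dim(sim$expression[[1]])
#' @export
simulate_meta_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  cfg <- config

  ## ---- global layer ----
  set.seed(cfg$seed)
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  gene_mu <- rnorm(cfg$n_genes, mean = 7, sd = 1)
  names(gene_mu) <- gene_ids
  nps <- if (cfg$probesets_per_gene[1] == cfg$probesets_per_gene[2]) {
    rep(cfg$probesets_per_gene[1], cfg$n_genes)
  } else {
    sample(seq(cfg$probesets_per_gene[1], cfg$probesets_per_gene[2]),
           cfg$n_genes, replace = TRUE)
  }
  annotation <- data.frame(
    probeset_id = unlist(lapply(seq_len(cfg$n_genes), function(g)
      sprintf("%s_at%02d", gene_ids[g], seq_len(nps[g])))),
    gene_id = rep(gene_ids, nps),
    stringsAsFactors = FALSE
  )
  n_ps <- nrow(annotation)
  loadings <- runif(n_ps, cfg$loading_range[1], cfg$loading_range[2])
  intercepts <- rnorm(n_ps, 0, cfg$probeset_intercept_sd)
  slopes <- matrix(rnorm(n_ps * 3, 0, cfg$metric_slope_sd), nrow = n_ps,
                   dimnames = list(annotation$probeset_id,
                                   c("pm_iqr", "rma_iqr", "rna_deg")))
  names(loadings) <- names(intercepts) <- annotation$probeset_id
  n_msi_genes <- round(cfg$msi_effect_genes * cfg$n_genes)
  msi_genes <- if (n_msi_genes > 0) sample(gene_ids, n_msi_genes) else
    character(0)
  if (!cfg$target_gene_id %in% gene_ids)
    stop("configuration error: target_gene_id not among generated genes",
         call. = FALSE)

  ## ---- per-dataset streams ----
  metric_chol <- chol(matrix(c(1, 0.5, 0.3,
                               0.5, 1, 0.4,
                               0.3, 0.4, 1), 3, 3))
  expr <- vector("list", cfg$n_datasets)
  clin_list <- vector("list", cfg$n_datasets)
  signal_list <- vector("list", cfg$n_datasets)
  center_offsets <- vector("list", cfg$n_datasets)
  batch_offsets <- vector("list", cfg$n_datasets)

  for (d in seq_len(cfg$n_datasets)) {
    set.seed(dataset_seed(cfg$seed, d))
    n <- cfg$samples_per_dataset
    did <- sprintf("DS%02d", d)
    sample_ids <- sprintf("%s_S%03d", did, seq_len(n))
    cs <- cfg$covariate_shift[[d]]

    center <- sprintf("%s_C%d", did,
                      sample(seq_len(cfg$n_centers_per_dataset), n,
                             replace = TRUE))
    batch <- sprintf("%s_B%d", did,
                     sample(seq_len(cfg$n_batches_per_dataset), n,
                            replace = TRUE))
    coff <- rnorm(cfg$n_centers_per_dataset, 0, cfg$center_effect_sd)
    names(coff) <- sprintf("%s_C%d", did,
                           seq_len(cfg$n_centers_per_dataset))
    boff <- rnorm(cfg$n_batches_per_dataset, 0, cfg$batch_effect_sd)
    names(boff) <- sprintf("%s_B%d", did,
                           seq_len(cfg$n_batches_per_dataset))

    metrics <- matrix(rnorm(n * 3), ncol = 3) %*% metric_chol
    colnames(metrics) <- c("pm_iqr", "rma_iqr", "rna_deg")

    gender <- ifelse(runif(n) < cs$gender, "M", "F")
    site <- ifelse(runif(n) < cs$site, "colon", "rectum")
    msi <- ifelse(runif(n) < cs$msi, "MSI", "MSS")
    age <- rnorm(n, cs$age_mean, cs$age_sd)
    stage <- apply(rmultinom(n, 1, cs$stage), 2, which.max)
    stage <- c("I", "II", "III", "IV", "unknown")[stage]

    signal <- gene_mu + matrix(rnorm(cfg$n_genes * n, 0, cfg$bio_sd),
                               nrow = cfg$n_genes)
    dimnames(signal) <- list(gene_ids, sample_ids)
    if (length(msi_genes) > 0) {
      is_msi <- msi == "MSI"
      signal[msi_genes, is_msi] <- signal[msi_genes, is_msi] +
        cfg$msi_effect_size
    }

    tsig <- signal[cfg$target_gene_id, ]
    z <- if (sd(tsig) > 0) (tsig - mean(tsig)) / sd(tsig) else tsig * 0
    hazard <- cfg$baseline_hazard * exp(cfg$cox_log_hr * z)
    draw_endpoint <- function(h) {
      t_raw <- if (all(h > 0)) rexp(n, rate = h) else rep(Inf, n)
      event <- as.integer(t_raw <= cfg$censor_time)
      time <- pmin(t_raw, cfg$censor_time)
      list(time = time, event = event)
    }
    os <- draw_endpoint(hazard)
    rel <- draw_endpoint(hazard)
    premet <- stage %in% c("I", "II", "III")
    rel$time[!premet] <- NA_real_
    rel$event[!premet] <- NA_integer_

    noise <- matrix(rnorm(n_ps * n, 0, cfg$noise_sd), nrow = n_ps)
    mat <- intercepts +
      loadings * signal[annotation$gene_id, , drop = FALSE] +
      matrix(coff[center], nrow = n_ps, ncol = n, byrow = TRUE) +
      matrix(boff[batch], nrow = n_ps, ncol = n, byrow = TRUE) +
      slopes %*% t(metrics) +
      noise
    dimnames(mat) <- list(annotation$probeset_id, sample_ids)

    expr[[d]] <- mat
    names(expr)[d] <- did
    signal_list[[d]] <- signal
    center_offsets[[d]] <- coff
    batch_offsets[[d]] <- boff
    clin_list[[d]] <- data.frame(
      sample_id = sample_ids, dataset_id = did, center = center,
      scan_batch = batch,
      pm_iqr = metrics[, "pm_iqr"], rma_iqr = metrics[, "rma_iqr"],
      rna_deg = metrics[, "rna_deg"],
      gender = gender, age = age, site = site, msi = msi, stage = stage,
      relapse_time = rel$time, relapse_event = rel$event,
      os_time = os$time, os_event = os$event,
      stringsAsFactors = FALSE
    )
  }

  clinical <- do.call(rbind, clin_list)
  rownames(clinical) <- NULL
  truth <- list(
    gene_signal = do.call(cbind, signal_list),
    probeset_loadings = loadings,
    probeset_intercepts = intercepts,
    metric_slopes = slopes,
    center_offsets = center_offsets,
    batch_offsets = batch_offsets,
    msi_genes = msi_genes,
    msi_effect_size = cfg$msi_effect_size,
    true_log_hr = cfg$cox_log_hr
  )
  structure(list(expression = expr, clinical = clinical,
                 annotation = annotation, truth = truth, config = cfg),
            class = "meta_cohort_sim")
}

#' Write a simulated meta-cohort to plain-text files
#'
#' Writes one expression TSV per dataset (probesets x samples), a clinical
#' CSV over all samples, the probeset-to-gene annotation TSV, and the
#' ground truth as JSON.
#'
#' @param sim result of [simulate_meta_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_meta_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "meta_cohort_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (did in names(sim$expression)) {
    write.table(sim$expression[[did]],
                file.path(dir, paste0("expression_", did, ".tsv")),
                sep = "\t", quote = FALSE, col.names = NA)
  }
  write.csv(sim$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  write.table(sim$annotation, file.path(dir, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$gene_signal <- NULL  # large; regenerate from config + seed instead
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
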