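#' Harmonize several probeset-level datasets into one gene-level meta-cohort
#'
#' Runs the full integration pipeline over a list of datasets, with a
#' designated reference cohort: per dataset, (1) per-feature mixed-effects
#' technical correction (center, scan batch, quality metrics; MSI
#' retained), (2) probeset-to-gene collapse by the first principal
#' component, (3) quantile normalization to the reference's gene-level
#' quantile vector, (4) IPW-weighted median/MAD standardization to the
#' reference (affiliation model selected by forward stepwise AIC), (5)
#' truncation to the reference range, and finally (6) merging on the gene
#' intersection with unknown-stage samples dropped. The reference dataset
#' itself is corrected and summarized, then enters the merge unchanged.
#'
#' @param expression named list of probeset-by-sample matrices, one per
#'   dataset.
#' @param clinical clinical data frame over all samples.
#' @param annotation probeset-to-gene annotation data frame.
#' @param reference_id name of the reference dataset in `expression`.
#' @param design model design passed to [fit_feature_models()].
#' @param w_max IPW truncation limit.
#' @param verbose print per-stage sample/feature counts.
#' @return a `"harmonized_cohort"` (see [merge_cohorts()]) with extra
#'   elements `weights` (per-dataset IPW weights), `affiliation` (selection
#'   traces) and `stage_log` (per-stage counts).
#' @export
harmonize_cohorts <- function(expression, clinical, annotation,
                              reference_id = names(expression)[1],
                              design = "microarray", w_max = 5,
                              verbose = TRUE) {
  stopifnot(reference_id %in% names(expression))
  say <- function(...) if (verbose) message(...)
  stage_log <- list()

  ## 1-2: correct and summarize every dataset
  gene_level <- list()
  for (did in names(expression)) {
    mat <- expression[[did]]
    clin_d <- clinical[clinical$dataset_id == did, , drop = FALSE]
    fits <- fit_feature_models(mat, clin_d, design = design)
    corrected <- remove_technical_effects(mat, fits)
    genes <- summarize_first_pc(corrected, annotation)
    gene_level[[did]] <- genes
    stage_log[[did]] <- c(samples = ncol(mat), probesets = nrow(mat),
                          genes = nrow(genes),
                          fallback_fits = sum(fits$fallback))
    say("dataset ", did, ": ", ncol(mat), " samples, ", nrow(mat),
        " probesets -> ", nrow(genes), " genes (",
        sum(fits$fallback), " fallback fits)")
  }

  ref_mat <- gene_level[[reference_id]]
  ref_clin <- clinical[clinical$dataset_id == reference_id, , drop = FALSE]
  ref_quantiles <- sort(apply(ref_mat, 2L, sort) |> rowMeans())

  ## 3-5: per non-reference dataset, normalize + standardize + truncate
  weights <- list()
  affiliation <- list()
  standardized <- list()
  standardized[[reference_id]] <- ref_mat
  for (did in setdiff(names(gene_level), reference_id)) {
    m <- quantile_normalize_to_reference(gene_level[[did]], ref_quantiles)
    clin_d <- clinical[clinical$dataset_id == did, , drop = FALSE]
    aff <- fit_affiliation_model(clin_d, ref_clin)
    w <- compute_ipw_weights(aff, clin_d, w_max = w_max)
    m <- standardize_to_reference(m, w$weights, ref_mat)
    m <- truncate_to_reference(m, ref_mat)
    standardized[[did]] <- m
    weights[[did]] <- w$weights
    affiliation[[did]] <- aff[c("selected", "trace")]
    say("dataset ", did, ": affiliation covariates {",
        paste(aff$selected, collapse = ", "), "}, ",
        w$n_truncated, " weights truncated at ", w_max)
  }

  ## 6: merge
  cohort <- merge_cohorts(standardized, clinical, reference_id)
  say("merged cohort: ", nrow(cohort$matrix), " genes x ",
      ncol(cohort$matrix), " samples (",
      sum(cohort$log$dropped), " unknown-stage samples dropped)")
  cohort$weights <- weights
  cohort$affiliation <- affiliation
  cohort$stage_log <- stage_log
  cohort
}

#' Expression-outcome association battery for one gene
#'
#' Convenience wrapper: selects the endpoint-specific samples, stratifies
#' the gene's expression into tertiles, and runs the matching association
#' analysis — Cox proportional hazards with Kaplan-Meier curves for the
#' survival endpoints, the stage linear model otherwise.
#'
#' @param cohort a `"harmonized_cohort"` (or any list with `matrix` and
#'   `clinical`).
#' @param gene gene identifier (row of the matrix).
#' @param endpoint `"relapse"`, `"os_premet"`, `"os_met"` or `"stage"`.
#' @param exclude_rectum_datasets passed to [select_endpoint_samples()].
#' @return for survival endpoints, a list with `cox`, `km`, `groups`, `n`;
#'   for `"stage"`, a list with `stage_model`, `n`.
#' @export
associate_gene <- function(cohort, gene,
                           endpoint = c("relapse", "os_premet", "os_met",
                                        "stage"),
                           exclude_rectum_datasets = character(0)) {
  endpoint <- match.arg(endpoint)
  stopifnot(gene %in% rownames(cohort$matrix))
  clin <- select_endpoint_samples(cohort$clinical, endpoint,
                                  exclude_rectum_datasets)
  x <- cohort$matrix[gene, clin$sample_id]
  if (endpoint == "stage")
    return(list(stage_model = stage_linear_association(x, clin$stage),
                n = nrow(clin)))
  tg <- tertile_groups(x)
  time <- if (endpoint == "relapse") clin$relapse_time else clin$os_time
  event <- if (endpoint == "relapse") clin$relapse_event else clin$os_event
  list(cox = cox_tertile_association(time, event, tg$groups),
       km = km_estimate(time, event, tg$groups),
       groups = tg, n = nrow(clin))
}
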