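#' Collapse probeset-level expression to gene level by the first principal
#' component
#'
#' For each gene, the probesets mapping to it are treated as variables and
#' the samples as observations; the first principal component (covariance
#' based, probesets mean-centered) gives one score per sample. The score is
#' re-centered and re-scaled so that its mean equals the loading-weighted
#' mean of the probeset means and its SD equals the loading-weighted mean of
#' the probeset SDs (weights are the absolute first-eigenvector loadings),
#' and its sign is flipped, if necessary, so that it correlates positively
#' with the probeset of largest absolute loading. This makes the output
#' invariant to the arbitrary sign of the numerical eigenvector.
#'
#' Genes measured by a single probeset pass through unchanged. Genes whose
#' probesets have zero total variance return the (constant) weighted mean
#' row with a warning.
#'
#' @param expr probeset-by-sample matrix of log2 intensities with row and
#'   column names; at least 2 samples; no missing values.
#' @param annotation data frame with columns `probeset_id` and `gene_id`;
#'   each probeset maps to at most one gene. Probesets of `expr` without a
#'   mapping are dropped (with a message).
#' @param use_correlation logical; use the correlation instead of the
#'   covariance matrix of the probesets. Default `FALSE`.
#' @param weight_type how eigenvector loadings become weights for the
#'   re-centering/re-scaling: `"abs"` (default), `"signed"` or `"squared"`.
#' @return gene-by-sample matrix; rows ordered by first appearance of the
#'   gene in `annotation`.
#' @examples
#' m <- matrix(rnorm(12), 2, 6,
#'             dimnames = list(c("p1", "p2"), paste0("s", 1:6)))
#' ann <- data.frame(probeset_id = c("p1", "p2"), gene_id = c("g", "g"))
#' summarize_first_pc(m, ann)
#' @export
summarize_first_pc <- function(expr, annotation, use_correlation = FALSE,
                               weight_type = c("abs", "signed", "squared")) {
  weight_type <- match.arg(weight_type)
  if (ncol(expr) < 2L) stop("at least 2 samples are required", call. = FALSE)
  if (anyNA(expr)) stop("missing values in expression matrix; impute first",
                        call. = FALSE)
  if (anyDuplicated(annotation$probeset_id))
    stop("each probeset must map to at most one gene", call. = FALSE)
  ann <- annotation[annotation$probeset_id %in% rownames(expr), , drop = FALSE]
  dropped <- setdiff(rownames(expr), ann$probeset_id)
  if (length(dropped) > 0)
    message(length(dropped), " unmapped probesets dropped")
  genes <- unique(ann$gene_id)
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(expr),
                dimnames = list(genes, colnames(expr)))
  for (g in genes) {
    ps <- ann$probeset_id[ann$gene_id == g]  # annotation order
    x <- expr[ps, , drop = FALSE]
    out[g, ] <- if (length(ps) == 1L) x[1L, ] else
      first_pc_score(x, use_correlation, weight_type, g)
  }
  out
}

# First-PC score for one gene: x is probesets x samples, >= 2 probesets.
first_pc_score <- function(x, use_correlation, weight_type, gene_id) {
  row_sds <- apply(x, 1L, sd)        # n - 1 denominator
  if (all(row_sds == 0)) {
    warning("degenerate gene ", gene_id,
            ": zero variance in all probesets; returning mean row",
            call. = FALSE)
    return(colMeans(x))
  }
  if (use_correlation && any(row_sds == 0)) {
    # constant probesets carry no direction in correlation space
    x <- x[row_sds > 0, , drop = FALSE]
    row_sds <- row_sds[row_sds > 0]
  }
  row_means <- rowMeans(x)
  cm <- if (use_correlation) stats::cor(t(x)) else stats::cov(t(x))
  v <- eigen(cm, symmetric = TRUE)$vectors[, 1L]
  score <- drop(crossprod(x - row_means, v))
  w <- switch(weight_type,
              abs = abs(v),
              signed = v,
              squared = v^2)
  target_mean <- sum(w * row_means) / sum(w)
  target_sd <- sum(w * row_sds) / sum(w)
  # sign congruence with the probeset contributing the most (ties broken by
  # the first probeset in annotation order, which is which.max's behavior)
  top <- which.max(abs(v))
  if (stats::cor(score, x[top, ]) < 0) score <- -score
  s <- sd(score)
  if (s == 0) return(rep(target_mean, length(score)))
  (score - mean(score)) / s * target_sd + target_mean
}
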