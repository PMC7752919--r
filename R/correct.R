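#' Fit per-feature mixed-effects models of technical structure
#'
#' For every feature (probeset or gene) of an expression matrix, fits a
#' linear mixed-effects model of its intensity on technical and biological
#' covariates from the clinical table, within one dataset. Two designs are
#' supported:
#' \describe{
#'   \item{`"microarray"`}{fixed effects: center of origin, MSI status and
#'     the three per-array quality metrics (pm_iqr, rma_iqr, rna_deg);
#'     random intercept: scan batch.}
#'   \item{`"rnaseq"`}{fixed effect: center; random intercept: plate (the
#'     `scan_batch` column carries the plate identifier).}
#' }
#' Estimation is REML via \pkg{lme4}; the metrics are mean-centered before
#' fitting so that removing their contribution cannot shift feature means.
#' MSI is a biological covariate: it is estimated so the technical terms are
#' not confounded with it, but it is never removed by
#' [remove_technical_effects()]. Unknown MSI is kept as its own level.
#'
#' Degenerate designs are handled and logged: a single center level drops
#' the center term; a single batch level, a non-convergent fit or a
#' boundary (singular) random-effect estimate falls back to ordinary least
#' squares without the batch term, flagged per feature.
#'
#' @param expr feature-by-sample matrix (one dataset).
#' @param clin clinical data frame with `sample_id`, `center`, `scan_batch`
#'   and, for the microarray design, `msi`, `pm_iqr`, `rma_iqr`, `rna_deg`.
#'   Must cover every column of `expr`.
#' @param design `"microarray"` or `"rnaseq"`.
#' @return An object of class `"feature_model_fits"`: per-feature fixed
#'   effects, per-batch random-intercept predictions, residual variance and
#'   fallback flags, plus the design information needed to reconstruct the
#'   technical component.
#' @seealso [remove_technical_effects()]
#' @export
fit_feature_models <- function(expr, clin,
                               design = c("microarray", "rnaseq")) {
  design <- match.arg(design)
  clin <- align_clinical(clin, colnames(expr))
  n <- ncol(expr)

  has_center <- length(unique(clin$center)) > 1L
  if (!has_center)
    message("single center level: center term dropped")
  has_batch <- length(unique(clin$scan_batch)) > 1L
  if (!has_batch)
    message("single batch level: falling back to fixed-effects-only models")

  df <- data.frame(row.names = clin$sample_id)
  if (has_center)
    df$center <- factor(clin$center)
  if (design == "microarray") {
    df$msi <- factor(ifelse(is.na(clin$msi), "unknown", clin$msi))
    if (nlevels(df$msi) < 2L) df$msi <- NULL
    for (m in c("pm_iqr", "rma_iqr", "rna_deg"))
      df[[m]] <- clin[[m]] - mean(clin[[m]])      # mean-centered metrics
  }
  df$batch <- factor(clin$scan_batch)

  fixed_terms <- setdiff(names(df), "batch")
  tech_terms <- setdiff(fixed_terms, "msi")
  rhs <- if (length(fixed_terms) > 0)
    paste(fixed_terms, collapse = " + ") else "1"
  contr <- list()
  if (has_center) contr$center <- "contr.sum"
  if (!is.null(df$msi)) contr$msi <- "contr.sum"
  X <- model.matrix(as.formula(paste("~", rhs)), df,
                    contrasts.arg = if (length(contr)) contr else NULL)
  asgn <- attr(X, "assign")
  term_labels <- attr(stats::terms(as.formula(paste("~", rhs))),
                      "term.labels")
  tech_cols <- which(asgn %in% which(term_labels %in% tech_terms))

  batch_levels <- levels(df$batch)
  n_feat <- nrow(expr)
  beta <- matrix(0, n_feat, ncol(X),
                 dimnames = list(rownames(expr), colnames(X)))
  ranef_mat <- matrix(0, n_feat, length(batch_levels),
                      dimnames = list(rownames(expr), batch_levels))
  sigma2 <- numeric(n_feat)
  fallback <- logical(n_feat)
  converged <- rep(TRUE, n_feat)

  ols_fit <- function(y) {
    fit <- lm.fit(X, y)
    b <- fit$coefficients
    b[is.na(b)] <- 0                 # aliased columns dropped
    list(beta = b, ranef = setNames(rep(0, length(batch_levels)),
                                    batch_levels),
         sigma2 = sum(fit$residuals^2) / max(1, fit$df.residual))
  }

  template <- NULL
  if (has_batch) {
    fml <- as.formula(paste("y ~", rhs, "+ (1 | batch)"))
    df$y <- expr[1L, ]
    template <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = df, REML = TRUE,
                   contrasts = if (length(contr)) contr else NULL,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     calc.derivs = FALSE)))),
      error = function(e) NULL)
  }

  for (i in seq_len(n_feat)) {
    y <- expr[i, ]
    fit_i <- NULL
    if (!is.null(template)) {
      fit_i <- tryCatch(
        suppressMessages(suppressWarnings(
          if (i == 1L) template else lme4::refit(template, newresp = y))),
        error = function(e) NULL)
      if (!is.null(fit_i) && lme4::isSingular(fit_i, tol = 1e-6))
        fit_i <- NULL                # boundary variance: use OLS fallback
    }
    if (is.null(fit_i)) {
      res <- ols_fit(y)
      fallback[i] <- TRUE
    } else {
      b <- lme4::fixef(fit_i)
      full <- setNames(rep(0, ncol(X)), colnames(X))
      full[names(b)[!is.na(b)]] <- b[!is.na(b)]
      re <- lme4::ranef(fit_i)$batch
      rv <- setNames(rep(0, length(batch_levels)), batch_levels)
      rv[rownames(re)] <- re[, 1L]
      res <- list(beta = full, ranef = rv,
                  sigma2 = stats::sigma(fit_i)^2)
    }
    beta[i, ] <- res$beta
    ranef_mat[i, ] <- res$ranef
    sigma2[i] <- res$sigma2
  }
  if (any(fallback))
    message(sum(fallback), " of ", n_feat,
            " features used the fixed-effects-only fallback")

  structure(list(beta = beta, ranef = ranef_mat, sigma2 = sigma2,
                 fallback = fallback, converged = converged,
                 design = design, X = X, tech_cols = tech_cols,
                 batch = as.character(df$batch),
                 sample_ids = clin$sample_id),
            class = "feature_model_fits")
}

#' Remove estimated technical effects from an expression matrix
#'
#' Subtracts, per feature, the fitted technical component — center effect,
#' shrunken (BLUP) batch intercept and quality-metric contribution — from
#' the observed values. The technical component is centered across samples
#' before subtraction, so the grand mean of every feature is preserved
#' exactly; MSI effects and residual biological variation are retained.
#'
#' @param expr feature-by-sample matrix; same features and samples used in
#'   [fit_feature_models()].
#' @param fits a `"feature_model_fits"` object.
#' @return corrected matrix of the same dimension.
#' @export
remove_technical_effects <- function(expr, fits) {
  stopifnot(inherits(fits, "feature_model_fits"))
  missing <- setdiff(colnames(expr), fits$sample_ids)
  if (length(missing) > 0)
    stop("clinical rows missing for samples: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!identical(rownames(expr), rownames(fits$beta)))
    stop("fits are not aligned to the features of 'expr'", call. = FALSE)
  idx <- match(colnames(expr), fits$sample_ids)
  Xt <- fits$X[idx, fits$tech_cols, drop = FALSE]
  tech <- fits$beta[, fits$tech_cols, drop = FALSE] %*% t(Xt) +
    fits$ranef[, fits$batch[idx], drop = FALSE]
  tech <- tech - rowMeans(tech)      # preserve each feature's grand mean
  out <- expr - tech
  dimnames(out) <- dimnames(expr)
  out
}

#' Estimate the per-feature fraction of variance attributable to a grouping
#'
#' One-way between/total variance share, used to quantify how much batch or
#' center structure remains in a matrix before and after correction.
#'
#' @param expr feature-by-sample matrix.
#' @param groups grouping vector aligned to the columns of `expr`.
#' @return numeric vector, one fraction in `[0, 1]` per feature.
#' @export
variance_fraction <- function(expr, groups) {
  groups <- as.factor(groups)
  gm <- rowMeans(expr)
  tot <- rowSums((expr - gm)^2)
  between <- numeric(nrow(expr))
  for (g in levels(groups)) {
    cols <- which(groups == g)
    between <- between + length(cols) * (rowMeans(expr[, cols, drop = FALSE]) - gm)^2
  }
  frac <- between / tot
  frac[tot == 0] <- 0
  frac
}

# Order clinical rows to the expression columns; error on missing samples.
align_clinical <- function(clin, sample_ids) {
  idx <- match(sample_ids, clin$sample_id)
  if (anyNA(idx))
    stop("clinical rows missing for samples: ",
         paste(sample_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  clin[idx, , drop = FALSE]
}
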