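#' Prepare RNA-seq expression estimates for integration
#'
#' Log2-transforms non-negative expression estimates (with a pseudo-count)
#' and quantile-normalizes the samples within the dataset, the standard
#' preparation of count-based data before cross-cohort standardization.
#'
#' @param mat gene-by-sample matrix of non-negative expression estimates.
#' @param offset pseudo-count added before the log2 transform; default 1.
#' @return log2-scale quantile-normalized matrix of the same dimension.
#' @export
prepare_rnaseq <- function(mat, offset = 1) {
  if (any(mat < 0)) stop("negative expression estimates", call. = FALSE)
  lx <- log2(mat + offset)
  out <- limma::normalizeQuantiles(lx, ties = TRUE)
  dimnames(out) <- dimnames(lx)
  out
}

#' Quantile-normalize a matrix to a reference quantile vector
#'
#' Replaces each sample column by the reference quantiles at the column's
#' ranks, so that every sorted column equals the reference quantile vector;
#' ties are mapped to the mean of their span. When the reference vector has
#' a different length than the number of features, it is linearly
#' interpolated on an equally spaced probability grid.
#'
#' @param mat feature-by-sample matrix.
#' @param reference_quantiles numeric vector of finite reference quantiles
#'   (sorted internally).
#' @return normalized matrix of the same dimension.
#' @export
quantile_normalize_to_reference <- function(mat, reference_quantiles) {
  if (any(!is.finite(reference_quantiles)))
    stop("non-finite reference quantiles", call. = FALSE)
  rq <- sort(reference_quantiles)
  n <- nrow(mat)
  if (length(rq) != n) {
    if (length(rq) < 2L)
      stop("reference quantile vector too short to interpolate",
           call. = FALSE)
    rq <- approx(seq(0, 1, length.out = length(rq)), rq,
                 xout = seq(0, 1, length.out = n))$y
  }
  out <- apply(mat, 2L, function(x) {
    r <- rank(x, ties.method = "average")
    (rq[floor(r)] + rq[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Fit a dataset-affiliation logistic model by forward stepwise AIC
#'
#' Pools the clinical tables of dataset D and the reference cohort, labels
#' each sample by its affiliation, and selects clinical predictors of that
#' affiliation (candidates: gender, age, site, MSI, stage) by forward
#' stepwise logistic regression: starting from the intercept-only model, the
#' candidate with the largest AIC improvement is added until none improves.
#' A candidate whose addition yields complete separation is skipped with a
#' warning.
#'
#' @param clin_d clinical data frame of dataset D.
#' @param clin_ref clinical data frame of the reference cohort.
#' @param candidates character vector of candidate covariate columns.
#' @return list with `model` (the fitted [stats::glm()] object, response 1 =
#'   affiliation to D), `selected` covariates in selection order, and
#'   `trace` (data frame of step, added covariate and AIC; monotone
#'   decreasing).
#' @export
fit_affiliation_model <- function(clin_d, clin_ref,
                                  candidates = c("gender", "age", "site",
                                                 "msi", "stage")) {
  pooled <- rbind(
    cbind(clin_d[intersect(candidates, names(clin_d))], .is_d = 1L),
    cbind(clin_ref[intersect(candidates, names(clin_ref))], .is_d = 0L)
  )
  for (v in setdiff(names(pooled), c(".is_d", "age")))
    pooled[[v]] <- factor(ifelse(is.na(pooled[[v]]), "unknown",
                                 as.character(pooled[[v]])))
  usable <- Filter(function(v) {
    x <- pooled[[v]]
    if (is.factor(x)) nlevels(droplevels(x)) > 1L else var(x) > 0
  }, intersect(candidates, names(pooled)))

  current <- glm(.is_d ~ 1, family = binomial(), data = pooled)
  selected <- character(0)
  trace <- data.frame(step = 0L, added = "(intercept)", aic = AIC(current),
                      stringsAsFactors = FALSE)
  remaining <- usable
  step_i <- 0L
  while (length(remaining) > 0) {
    fits <- lapply(remaining, function(v) {
      fml <- as.formula(paste(".is_d ~",
                              paste(c(selected, v), collapse = " + ")))
      sep <- FALSE
      fit <- withCallingHandlers(
        glm(fml, family = binomial(), data = pooled),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1",
                    conditionMessage(w)))
            sep <<- TRUE
          invokeRestart("muffleWarning")
        })
      list(fit = fit, separated = sep)
    })
    names(fits) <- remaining
    seps <- vapply(fits, `[[`, logical(1), "separated")
    if (any(seps)) {
      warning("complete separation for covariate(s) ",
              paste(remaining[seps], collapse = ", "),
              "; not added", call. = FALSE)
      remaining <- remaining[!seps]
      fits <- fits[!seps]
      if (length(remaining) == 0) break
    }
    aics <- vapply(fits, function(f) AIC(f$fit), numeric(1))
    best <- which.min(aics)
    if (aics[best] >= AIC(current) - 1e-8) break
    step_i <- step_i + 1L
    current <- fits[[best]]$fit
    selected <- c(selected, remaining[best])
    trace <- rbind(trace, data.frame(step = step_i,
                                     added = remaining[best],
                                     aic = aics[best]))
    remaining <- remaining[-best]
  }
  list(model = current, selected = selected, trace = trace)
}

#' Compute truncated inverse-probability weights for one dataset
#'
#' From a fitted affiliation model, retrieves each D sample's conditional
#' probabilities of belonging to D (`Pd`) and to the reference (`Pr = 1 -
#' Pd`), forms the weight `Pd / Pr`, and truncates it at `w_max` so no
#' sample is over-represented in the standardization. A numerically zero
#' `Pr` yields the truncation limit, with a warning.
#'
#' @param model result of [fit_affiliation_model()].
#' @param clin_d clinical data frame of dataset D (the samples to weight).
#' @param w_max truncation limit; default 5.
#' @param direction `"as_published"` uses `Pd / Pr`; `"to_reference"` uses
#'   the reciprocal `Pr / Pd`, which up-weights D samples that resemble the
#'   reference composition.
#' @return list with `weights` (named by sample id), `n_truncated`, and the
#'   raw untruncated ratios.
#' @export
compute_ipw_weights <- function(model, clin_d, w_max = 5,
                                direction = c("as_published",
                                              "to_reference")) {
  direction <- match.arg(direction)
  nd <- clin_d
  for (v in names(model$model$model)) {
    if (v %in% names(nd) && is.character(nd[[v]]))
      nd[[v]] <- factor(ifelse(is.na(nd[[v]]), "unknown", nd[[v]]))
  }
  pd <- predict(model$model, newdata = nd, type = "response")
  pr <- 1 - pd
  raw <- if (direction == "as_published") pd / pr else pr / pd
  bad <- !is.finite(raw)
  if (any(bad)) {
    warning(sum(bad), " sample(s) with numerically zero denominator; ",
            "weight set to w_max", call. = FALSE)
    raw[bad] <- w_max
  }
  w <- pmin(raw, w_max)
  names(w) <- clin_d$sample_id
  list(weights = w, n_truncated = sum(raw > w_max), raw = unname(raw))
}

#' Weighted median by the cumulative-weight rule
#'
#' The weighted median is the smallest value whose cumulative weight share
#' reaches one half; when it is reached exactly, the midpoint with the next
#' distinct order statistic is returned. With unit weights this reproduces
#' [stats::median()].
#'
#' @param x numeric values.
#' @param w non-negative weights, same length.
#' @return the weighted median.
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1L]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1L]) / 2
  else x[i]
}

#' Weighted median absolute deviation
#'
#' `weighted_median(|x - weighted_median(x, w)|, w)`, with no consistency
#' constant (the reference side of the standardization uses the raw
#' unweighted MAD, so neither side rescales).
#'
#' @inheritParams weighted_median
#' @return the weighted MAD.
#' @export
weighted_mad <- function(x, w = rep(1, length(x))) {
  m <- weighted_median(x, w)
  weighted_median(abs(x - m), w)
}

#' Standardize a dataset's genes to a reference cohort
#'
#' Per gene, maps dataset D's values onto the reference location and scale:
#' `x' = (x - m_D) / s_D * s_ref + m_ref`, where `m_D`, `s_D` are the
#' IPW-weighted median and weighted MAD of D and `m_ref`, `s_ref` the
#' unweighted median and raw MAD (no consistency constant) of the
#' reference. Genes with zero weighted MAD in D get a location-only shift,
#' with a warning.
#'
#' @param mat_d gene-by-sample matrix of dataset D.
#' @param weights per-sample weights for D (e.g. from
#'   [compute_ipw_weights()]), aligned to `colnames(mat_d)`.
#' @param mat_ref gene-by-sample matrix of the reference cohort; gene rows
#'   must cover those of `mat_d`.
#' @return standardized matrix, same dimension as `mat_d`.
#' @export
standardize_to_reference <- function(mat_d, weights, mat_ref) {
  genes <- rownames(mat_d)
  if (!all(genes %in% rownames(mat_ref)))
    stop("genes absent from reference: ",
         paste(head(setdiff(genes, rownames(mat_ref))), collapse = ", "),
         call. = FALSE)
  if (!is.null(names(weights))) weights <- weights[colnames(mat_d)]
  stopifnot(length(weights) == ncol(mat_d))
  out <- mat_d
  n_degenerate <- 0L
  for (g in genes) {
    x <- mat_d[g, ]
    m_d <- weighted_median(x, weights)
    s_d <- weighted_mad(x, weights)
    ref <- mat_ref[g, ]
    m_ref <- median(ref)
    s_ref <- mad(ref, constant = 1)
    if (s_d == 0) {
      n_degenerate <- n_degenerate + 1L
      out[g, ] <- x - m_d + m_ref
    } else {
      out[g, ] <- (x - m_d) / s_d * s_ref + m_ref
    }
  }
  if (n_degenerate > 0)
    warning(n_degenerate, " gene(s) with zero weighted MAD: ",
            "location-only shift applied", call. = FALSE)
  out
}

#' Truncate expression values to the range observed in the reference
#'
#' Clips each gene's values to the minimum and maximum observed for that
#' gene in the reference cohort.
#'
#' @param mat gene-by-sample matrix.
#' @param mat_ref reference gene-by-sample matrix covering the genes of
#'   `mat`.
#' @return clipped matrix.
#' @export
truncate_to_reference <- function(mat, mat_ref) {
  genes <- rownames(mat)
  missing <- setdiff(genes, rownames(mat_ref))
  if (length(missing) > 0)
    stop("genes absent from reference: ",
         paste(head(missing), collapse = ", "), call. = FALSE)
  lo <- apply(mat_ref[genes, , drop = FALSE], 1L, min)
  hi <- apply(mat_ref[genes, , drop = FALSE], 1L, max)
  out <- pmax(pmin(mat, hi), lo)
  dimnames(out) <- dimnames(mat)
  out
}

#' Merge standardized datasets into one harmonized cohort
#'
#' Column-concatenates the datasets on the intersection of their gene
#' lists, drops samples with unknown tumor stage, and records per-dataset
#' retained/dropped counts.
#'
#' @param matrices named list (>= 2) of gene-by-sample matrices.
#' @param clinical clinical data frame covering all samples (columns
#'   `sample_id`, `dataset_id`, `stage`).
#' @param reference_id name of the reference dataset.
#' @return An object of class `"harmonized_cohort"`: `matrix` (gene x
#'   sample), `clinical` (retained rows, aligned), `reference_id`, `flags`,
#'   and `log` (per-dataset retained/dropped counts).
#' @export
merge_cohorts <- function(matrices, clinical, reference_id) {
  if (length(matrices) < 2L) stop("need >= 2 datasets", call. = FALSE)
  genes <- Reduce(intersect, lapply(matrices, rownames))
  if (length(genes) == 0) stop("empty shared gene space", call. = FALSE)
  all_ids <- unlist(lapply(matrices, colnames))
  if (anyDuplicated(all_ids))
    stop("duplicate sample ids across datasets", call. = FALSE)
  merged <- do.call(cbind, lapply(matrices, function(m)
    m[genes, , drop = FALSE]))
  clin <- align_clinical(clinical, colnames(merged))
  keep <- !is.na(clin$stage) & clin$stage != "unknown"
  log <- aggregate(keep, by = list(dataset_id = clin$dataset_id),
                   FUN = function(k) c(retained = sum(k),
                                       dropped = sum(!k)))
  log <- data.frame(dataset_id = log$dataset_id,
                    retained = log$x[, "retained"],
                    dropped = log$x[, "dropped"])
  structure(list(matrix = merged[, keep, drop = FALSE],
                 clinical = clin[keep, , drop = FALSE],
                 reference_id = reference_id,
                 flags = c(corrected = TRUE, quantile_normalized = TRUE,
                           standardized = TRUE, truncated = TRUE),
                 log = log),
            class = "harmonized_cohort")
}

#' Weighted standardized mean difference of a covariate between two groups
#'
#' Diagnostic for IPW balance: for a numeric covariate, the (weighted) mean
#' difference divided by the pooled unweighted SD; for a categorical one,
#' the maximum absolute difference in (weighted) level proportions.
#'
#' @param x_d covariate values in dataset D.
#' @param x_ref covariate values in the reference.
#' @param w_d weights for D (default unit).
#' @return absolute standardized mean difference.
#' @export
standardized_mean_difference <- function(x_d, x_ref,
                                         w_d = rep(1, length(x_d))) {
  if (is.numeric(x_d)) {
    md <- sum(w_d * x_d) / sum(w_d)
    s <- sqrt((var(x_d) + var(x_ref)) / 2)
    abs(md - mean(x_ref)) / s
  } else {
    lev <- union(unique(x_d), unique(x_ref))
    pd <- vapply(lev, function(l) sum(w_d * (x_d == l)) / sum(w_d),
                 numeric(1))
    pr <- vapply(lev, function(l) mean(x_ref == l), numeric(1))
    max(abs(pd - pr))
  }
}
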