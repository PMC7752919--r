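#' Select the samples entering an endpoint-specific analysis
#'
#' Applies the endpoint definitions used for the expression-outcome
#' analyses: time to relapse is analyzed in patients diagnosed at stage
#' I-III; overall survival is analyzed separately in pre-metastatic (stage
#' I-III) and metastatic (stage IV) tumors; the stage analysis keeps every
#' sample with a known stage. Samples with unknown stage are always
#' excluded, and rectum samples of designated datasets can be excluded as
#' well.
#'
#' @param clin clinical data frame (`sample_id`, `stage`, `site`,
#'   `dataset_id`, endpoint columns).
#' @param endpoint one of `"relapse"`, `"os_premet"`, `"os_met"`,
#'   `"stage"`.
#' @param exclude_rectum_datasets dataset ids whose rectum samples are
#'   dropped.
#' @return the retained rows of `clin`.
#' @export
select_endpoint_samples <- function(clin,
                                    endpoint = c("relapse", "os_premet",
                                                 "os_met", "stage"),
                                    exclude_rectum_datasets = character(0)) {
  endpoint <- match.arg(endpoint)
  known <- !is.na(clin$stage) & clin$stage != "unknown"
  keep <- switch(endpoint,
    relapse = known & clin$stage %in% c("I", "II", "III") &
      !is.na(clin$relapse_time) & !is.na(clin$relapse_event),
    os_premet = known & clin$stage %in% c("I", "II", "III"),
    os_met = known & clin$stage == "IV",
    stage = known)
  if (length(exclude_rectum_datasets) > 0)
    keep <- keep & !(clin$dataset_id %in% exclude_rectum_datasets &
                       clin$site == "rectum")
  if (!any(keep))
    stop("empty cohort for endpoint '", endpoint, "'", call. = FALSE)
  clin[keep, , drop = FALSE]
}

#' Assign samples to expression tertile groups
#'
#' Splits a gene's per-sample expression values into low, medium and high
#' groups at the 33.3% and 66.7% quantiles of the distribution. Assignment
#' is rank-based: the cut values are the `ceiling(n/3)`-th and
#' `ceiling(2n/3)`-th order statistics, and every value less than or equal
#' to a cut (ties spanning it included) falls in the lower group — so the
#' grouping is invariant under strictly monotone transforms of the
#' expression scale.
#'
#' @param values named numeric vector of expression values, at least 3
#'   distinct.
#' @return list with `groups` (factor low/medium/high, named like
#'   `values`) and `cuts` (the two cut values).
#' @export
tertile_groups <- function(values) {
  if (length(unique(values)) < 3L)
    stop("degenerate distribution: fewer than 3 distinct values",
         call. = FALSE)
  n <- length(values)
  s <- sort(values)
  c1 <- s[ceiling(n / 3)]
  c2 <- s[ceiling(2 * n / 3)]
  g <- ifelse(values <= c1, "low", ifelse(values <= c2, "medium", "high"))
  groups <- factor(g, levels = c("low", "medium", "high"))
  names(groups) <- names(values)
  list(groups = groups, cuts = c(c1, c2))
}

#' Cox proportional-hazards association of survival with tertile groups
#'
#' Fits a Cox model with two indicators for the medium and high expression
#' groups (low is the reference) using Breslow tie handling (Efron
#' optional). Overall significance is the likelihood-ratio test against the
#' null model; hazard ratios come with 95% Wald confidence intervals, and
#' all three pairwise group comparisons get Wald tests. A group in which
#' all or no subjects have events makes the partial likelihood monotone;
#' the fit is still reported, flagged.
#'
#' @param time follow-up times (months).
#' @param event event indicators (0/1).
#' @param groups factor with levels low/medium/high (e.g. from
#'   [tertile_groups()]).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return list of class `"cox_association"`: `hr` (data frame of contrast,
#'   HR, CI bounds, Wald p), `lrt_p`, `loglik`, `n_per_group`,
#'   `monotone_flag`, and the underlying [survival::coxph()] `fit`.
#' @export
cox_tertile_association <- function(time, event, groups,
                                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (sum(event) < 1L) stop("no events in the cohort", call. = FALSE)
  if (sum(groups == "low") == 0)
    stop("reference (low) group is empty", call. = FALSE)
  groups <- droplevels(factor(groups, levels = c("low", "medium", "high")))
  dat <- data.frame(time = time, event = event, group = groups)
  fit <- survival::coxph(survival::Surv(time, event) ~ group, data = dat,
                         ties = ties)
  b <- coef(fit)
  V <- vcov(fit)
  z975 <- qnorm(0.975)
  contrast <- function(l, name) {
    est <- drop(l %*% b)
    se <- sqrt(drop(l %*% V %*% l))
    z <- est / se
    data.frame(contrast = name, hr = exp(est),
               ci_lower = exp(est - z975 * se),
               ci_upper = exp(est + z975 * se),
               wald_p = 2 * pnorm(-abs(z)))
  }
  k <- length(b)
  hr <- rbind(
    if (k >= 1) contrast(c(1, rep(0, k - 1)),
                         paste0(names(b)[1], "_vs_low")),
    if (k >= 2) contrast(c(0, 1, rep(0, k - 2)), "grouphigh_vs_low"),
    if (k >= 2) contrast(c(-1, 1, rep(0, k - 2)), "grouphigh_vs_medium")
  )
  hr$contrast <- sub("^group", "", hr$contrast)
  ll <- fit$loglik
  lrt_stat <- 2 * (ll[2] - ll[1])
  lrt_p <- pchisq(lrt_stat, df = k, lower.tail = FALSE)
  per_group_events <- tapply(event, groups, sum)
  per_group_n <- table(groups)
  monotone <- any(per_group_events == 0) ||
    any(per_group_events == per_group_n)
  if (monotone)
    warning("a group has all or no events: monotone partial likelihood, ",
            "estimates unreliable", call. = FALSE)
  structure(list(hr = hr, lrt_stat = lrt_stat, lrt_p = lrt_p,
                 loglik = ll, n_per_group = as.vector(per_group_n),
                 monotone_flag = monotone, ties = ties, fit = fit),
            class = "cox_association")
}

#' Linear-model association of expression with tumor stage
#'
#' Fits `expression ~ stage` (stage as a factor), reports the overall
#' F-test, per-stage adjusted means with 95% confidence intervals, and
#' pairwise Wald comparisons between stages.
#'
#' @param expression numeric vector of expression values.
#' @param stage factor or character of tumor stages; >= 2 levels with >= 2
#'   samples each.
#' @return list of class `"stage_association"`: `f_stat`, `f_p`,
#'   `means` (stage, adjusted mean, CI), `pairwise` (Wald p per stage
#'   pair), `fit`.
#' @export
stage_linear_association <- function(expression, stage) {
  stage <- droplevels(factor(stage))
  if (nlevels(stage) < 2L)
    stop("need >= 2 stage levels", call. = FALSE)
  dat <- data.frame(y = expression, stage = stage)
  fit <- lm(y ~ stage, data = dat)
  a <- anova(fit)
  f_stat <- a[["F value"]][1]
  f_p <- a[["Pr(>F)"]][1]
  if (var(expression) == 0) {   # constant response: no between-stage signal
    f_stat <- 0
    f_p <- 1
  }
  nd <- data.frame(stage = factor(levels(stage), levels = levels(stage)))
  pr <- predict(fit, newdata = nd, interval = "confidence", level = 0.95)
  means <- data.frame(stage = levels(stage), mean = pr[, "fit"],
                      ci_lower = pr[, "lwr"], ci_upper = pr[, "upr"])
  # pairwise Wald tests on differences of adjusted means
  L <- model.matrix(~stage, nd)
  V <- vcov(fit)
  b <- coef(fit)
  sigdf <- fit$df.residual
  combs <- utils::combn(nlevels(stage), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
    l <- L[combs[2, j], ] - L[combs[1, j], ]
    est <- drop(l %*% b)
    se <- sqrt(drop(l %*% V %*% l))
    data.frame(pair = paste(levels(stage)[combs[2, j]], "vs",
                            levels(stage)[combs[1, j]]),
               diff = est, wald_p = 2 * pt(-abs(est / se), df = sigdf))
  }))
  structure(list(f_stat = f_stat, f_p = f_p, means = means,
                 pairwise = pairwise, fit = fit),
            class = "stage_association")
}

#' Kaplan-Meier survival curves per expression group
#'
#' Product-limit estimates of the survival function in each group, with
#' right censoring. Empty groups are omitted with a warning.
#'
#' @inheritParams cox_tertile_association
#' @return named list of data frames (one per non-empty group) with
#'   columns time, n_risk, n_event, survival; each curve starts at
#'   `S(0) = 1` and is non-increasing.
#' @export
km_estimate <- function(time, event, groups) {
  if (!is.factor(groups)) groups <- factor(groups)
  empty <- levels(groups)[table(groups) == 0]
  if (length(empty) > 0)
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "),
            call. = FALSE)
  out <- list()
  for (g in levels(droplevels(groups))) {
    sel <- groups == g
    sf <- survival::survfit(
      survival::Surv(time[sel], event[sel]) ~ 1)
    out[[g]] <- data.frame(
      time = c(0, sf$time), n_risk = c(sum(sel), sf$n.risk),
      n_event = c(0, sf$n.event), survival = c(1, sf$surv))
  }
  out
}
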