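test_that("prepare_rnaseq handles degenerate inputs and matches the
           rank-average oracle", {
  z <- matrix(0, 3, 3)
  expect_equal(prepare_rnaseq(z, offset = 1), z)
  expect_error(prepare_rnaseq(matrix(-1, 2, 2)), "negative")

  same <- matrix(c(1, 4, 9), 3, 3)  # identical columns
  expect_equal(prepare_rnaseq(same), log2(same + 1))

  m <- matrix(c(3, 1, 8,
                2, 9, 4,
                7, 5, 6), 3, 3)
  out <- prepare_rnaseq(m)
  # oracle: mean of sorted log2 columns, assigned back by rank
  lx <- log2(m + 1)
  s <- rowMeans(apply(lx, 2, sort))
  expected <- apply(lx, 2, function(x) s[rank(x)])
  expect_equal(out, expected, tolerance = 1e-12)
})

test_that("quantile normalization to a reference is exact", {
  rq <- c(2, 5, 7, 9, 11)
  x <- matrix(c(9, 2, 11, 5, 7), ncol = 1)  # permutation of the reference
  expect_equal(drop(quantile_normalize_to_reference(x, rq)),
               c(9, 2, 11, 5, 7))
  cst <- quantile_normalize_to_reference(matrix(rnorm(5), ncol = 1),
                                         rep(4, 5))
  expect_equal(drop(cst), rep(4, 5))
  expect_error(quantile_normalize_to_reference(x, c(1, NA, 3, 4, 5)),
               "non-finite")

  # sorted columns equal the reference quantiles, ties tie-averaged
  set.seed(4)
  m <- matrix(rnorm(50), 5, 10)
  out <- quantile_normalize_to_reference(m, rq)
  for (j in 1:10) expect_equal(sort(out[, j]), rq)

  # mismatched lengths: linear interpolation oracle on a 5-point toy;
  # reference (0, 10, 20) on grid (0, .5, 1) interpolates to
  # (0, 5, 10, 15, 20) at probabilities (0, .25, .5, .75, 1)
  x5 <- matrix(c(3, 1, 4, 1, 5), ncol = 1)
  out5 <- drop(quantile_normalize_to_reference(x5, c(0, 10, 20)))
  # ranks: 3, 1.5, 4, 1.5, 5 -> 10, (0+5)/2, 15, 2.5, 20
  expect_equal(out5, c(10, 2.5, 15, 2.5, 20))
})

test_that("affiliation model selects informative covariates by AIC", {
  # empty candidate list: intercept-only, Pd = 0.5 with equal group sizes
  clin_d <- data.frame(sample_id = paste0("d", 1:50), gender = "M")
  clin_r <- data.frame(sample_id = paste0("r", 1:50), gender = "M")
  fit0 <- fit_affiliation_model(clin_d, clin_r, candidates = character(0))
  expect_equal(fit0$selected, character(0))
  w0 <- compute_ipw_weights(fit0, clin_d)
  expect_equal(unname(w0$weights), rep(1, 50), tolerance = 1e-10)

  # one binary covariate with prevalence 0.9 vs 0.1 must be selected, and
  # the trace must match a direct AIC computation of both candidate models
  set.seed(6)
  n <- 500
  clin_d <- data.frame(sample_id = paste0("d", 1:n),
                       msi = ifelse(runif(n) < 0.9, "MSI", "MSS"),
                       age = rnorm(n, 65, 10))
  clin_r <- data.frame(sample_id = paste0("r", 1:n),
                       msi = ifelse(runif(n) < 0.1, "MSI", "MSS"),
                       age = rnorm(n, 65, 10))
  fit <- fit_affiliation_model(clin_d, clin_r,
                               candidates = c("msi", "age"))
  expect_true("msi" %in% fit$selected)
  expect_equal(fit$selected[1], "msi")

  # oracle: binomial log-likelihood of the intercept-only and the
  # msi-stratified model from the 2x2 counts
  lab <- c(rep(1, n), rep(0, n))
  msi <- c(clin_d$msi, clin_r$msi)
  ll_null <- n * log(0.5) * 2
  aic_null <- -2 * ll_null + 2
  ll_msi <- sum(vapply(c("MSI", "MSS"), function(s) {
    k <- sum(lab == 1 & msi == s); m <- sum(msi == s)
    p <- k / m
    k * log(p) + (m - k) * log(1 - p)
  }, numeric(1)))
  aic_msi <- -2 * ll_msi + 2 * 2
  expect_equal(fit$trace$aic[1], aic_null, tolerance = 1e-6)
  expect_equal(fit$trace$aic[2], aic_msi, tolerance = 1e-6)
  expect_true(all(diff(fit$trace$aic) < 0))
})

test_that("IPW weights are the truncated Pd/Pr ratios", {
  # saturated single-binary-covariate model: per-stratum Pd/Pr equals the
  # stratum count ratio n_D(x) / n_ref(x)
  clin_d <- data.frame(sample_id = paste0("d", 1:100),
                       site = rep(c("colon", "rectum"), c(80, 20)))
  clin_r <- data.frame(sample_id = paste0("r", 1:100),
                       site = rep(c("colon", "rectum"), c(40, 60)))
  fit <- fit_affiliation_model(clin_d, clin_r, candidates = "site")
  w <- compute_ipw_weights(fit, clin_d)
  expect_equal(unname(w$weights[clin_d$site == "colon"][1]), 80 / 40,
               tolerance = 1e-6)
  expect_equal(unname(w$weights[clin_d$site == "rectum"][1]), 20 / 60,
               tolerance = 1e-6)
  expect_true(all(w$weights > 0 & w$weights <= 5))

  # truncation contract: a raw ratio above 5 is reported as exactly 5
  clin_d2 <- data.frame(sample_id = paste0("d", 1:100),
                        site = rep(c("colon", "rectum"), c(88, 12)))
  fit2 <- fit_affiliation_model(clin_d2, clin_r, candidates = "site")
  w2 <- compute_ipw_weights(fit2, clin_d2)
  expect_equal(max(w2$raw[clin_d2$site == "colon"]), 88 / 40,
               tolerance = 1e-6)
  expect_equal(unname(w2$weights[1]), 88 / 40, tolerance = 1e-6)
  clin_r3 <- data.frame(sample_id = paste0("r", 1:100),
                        site = rep(c("colon", "rectum"), c(10, 90)))
  fit3 <- fit_affiliation_model(clin_d2, clin_r3, candidates = "site")
  w3 <- compute_ipw_weights(fit3, clin_d2)
  expect_equal(max(w3$raw), 88 / 10, tolerance = 1e-6)  # raw ratio 8.8
  expect_equal(unname(w3$weights[1]), 5)                # truncated to 5
  expect_gt(w3$n_truncated, 0)
})

test_that("weighted median and MAD follow the cumulative-weight rule", {
  # 7-sample toy with one up-weighted sample; enumeration oracle
  x <- 1:7
  w <- c(1, 1, 1, 5, 1, 1, 1)
  enum_wmedian <- function(x, w) {
    o <- order(x); xs <- x[o]; ws <- w[o]
    total <- sum(ws); cum <- 0
    for (i in seq_along(xs)) {
      cum <- cum + ws[i]
      if (cum > total / 2) return(xs[i])
      if (cum == total / 2) return((xs[i] + xs[i + 1]) / 2)
    }
  }
  expect_equal(weighted_median(x, w), enum_wmedian(x, w))
  expect_equal(weighted_median(x, w), 4)
  # unit weights reduce to the sample median (odd and even n, with ties)
  for (v in list(1:7, 1:8, c(2, 2, 3, 9), c(1, 1, 1, 5))) {
    expect_equal(weighted_median(v), median(v))
    expect_equal(weighted_mad(v), mad(v, constant = 1))
  }
  # random weighted cases against the enumeration oracle
  set.seed(10)
  for (i in 1:20) {
    v <- rnorm(sample(3:15, 1))
    wt <- sample(1:5, length(v), replace = TRUE)
    expect_equal(weighted_median(v, wt), enum_wmedian(v, wt))
  }
})

test_that("standardization maps median/MAD onto the reference exactly", {
  set.seed(12)
  ref <- matrix(rnorm(5 * 30, 6), 5, 30,
                dimnames = list(paste0("g", 1:5), paste0("r", 1:30)))
  d <- matrix(rnorm(5 * 21, 8, 2), 5, 21,
              dimnames = list(paste0("g", 1:5), paste0("d", 1:21)))
  out <- standardize_to_reference(d, rep(1, 21), ref)
  for (g in rownames(d)) {
    expect_equal(median(out[g, ]), median(ref[g, ]), tolerance = 1e-10)
    expect_equal(mad(out[g, ], constant = 1), mad(ref[g, ], constant = 1),
                 tolerance = 1e-10)
  }
  # fixed point: standardizing the reference onto itself changes nothing
  self <- standardize_to_reference(ref, rep(1, 30), ref)
  expect_equal(self, ref, tolerance = 1e-10)
  # zero-MAD gene: location-only shift with warning
  d2 <- d; d2["g1", ] <- 4
  expect_warning(out2 <- standardize_to_reference(d2, rep(1, 21), ref),
                 "zero weighted MAD")
  expect_equal(unname(out2["g1", 1]), median(ref["g1", ]))
})

test_that("truncation clips per gene to the reference range", {
  ref <- rbind(g1 = c(0, 10), g2 = c(-5, 5))
  m <- rbind(g1 = c(-3, 4, 12), g2 = c(-5, 0, 5))
  out <- truncate_to_reference(m, ref)
  expect_equal(out, rbind(g1 = c(0, 4, 10), g2 = c(-5, 0, 5)))
  expect_error(truncate_to_reference(rbind(g3 = 1:3), ref), "absent")
})

test_that("merging intersects genes, drops unknown stages, keeps provenance", {
  m1 <- matrix(1, 3, 5, dimnames = list(c("g1", "g2", "g3"),
                                        paste0("a", 1:5)))
  m2 <- matrix(2, 3, 5, dimnames = list(c("g2", "g3", "g4"),
                                        paste0("b", 1:5)))
  clin <- data.frame(sample_id = c(paste0("a", 1:5), paste0("b", 1:5)),
                     dataset_id = rep(c("A", "B"), each = 5),
                     stage = c("I", "II", "unknown", "III", "IV",
                               "I", "unknown", "II", "III", "IV"))
  h <- merge_cohorts(list(A = m1, B = m2), clin, reference_id = "A")
  expect_equal(rownames(h$matrix), c("g2", "g3"))
  expect_equal(ncol(h$matrix), 8)
  expect_equal(sum(h$log$dropped), 2)
  expect_equal(h$reference_id, "A")

  m2dup <- m2; colnames(m2dup) <- paste0("a", 1:5)
  expect_error(merge_cohorts(list(A = m1, B = m2dup), clin, "A"),
               "duplicate")
  expect_error(merge_cohorts(list(A = m1), clin, "A"), ">= 2")
})

test_that("IPW improves covariate balance on shifted synthetic cohorts", {
  cfg <- simulation_config(n_datasets = 2, samples_per_dataset = 250,
                           n_genes = 5, seed = 31)
  sim <- simulate_meta_cohort(cfg)
  clin_r <- sim$clinical[sim$clinical$dataset_id == "DS01", ]
  clin_d <- sim$clinical[sim$clinical$dataset_id == "DS02", ]
  aff <- suppressWarnings(fit_affiliation_model(clin_d, clin_r))
  w <- compute_ipw_weights(aff, clin_d, direction = "to_reference")
  expect_gt(length(aff$selected), 0)
  for (v in aff$selected) {
    smd_raw <- standardized_mean_difference(clin_d[[v]], clin_r[[v]])
    smd_w <- standardized_mean_difference(clin_d[[v]], clin_r[[v]],
                                          w$weights)
    expect_lt(smd_w, smd_raw)
  }
})
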