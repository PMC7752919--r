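# Independent oracles used across the test files. These deliberately avoid
# the code paths of the package functions they check.

# First principal component via power iteration on a hand-assembled
# covariance matrix, followed by the same re-centering/re-scaling/sign
# rules applied independently.
oracle_first_pc <- function(x, iterations = 2000) {
  n <- ncol(x)
  centered <- x - rowMeans(x)
  cm <- matrix(0, nrow(x), nrow(x))
  for (j in seq_len(n)) cm <- cm + tcrossprod(centered[, j])
  cm <- cm / (n - 1)
  v <- rep(1, nrow(x)) + seq_len(nrow(x)) * 1e-3  # break symmetry
  for (i in seq_len(iterations)) {
    v <- cm %*% v
    v <- v / sqrt(sum(v^2))
  }
  v <- drop(v)
  score <- drop(crossprod(centered, v))
  w <- abs(v)
  means <- rowMeans(x)
  sds <- apply(x, 1, sd)
  target_mean <- sum(w * means) / sum(w)
  target_sd <- sum(w * sds) / sum(w)
  top <- which.max(abs(v))
  if (cor(score, x[top, ]) < 0) score <- -score
  (score - mean(score)) / sd(score) * target_sd + target_mean
}

# Breslow partial log-likelihood for group indicators, written from the
# definition (sum over event times of x_i beta - d_t * log sum of risk-set
# exp(x beta)).
oracle_partial_loglik <- function(beta, time, event, X) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(time == t & event == 1)
    risk <- which(time >= t)
    eta <- X %*% beta
    ll <- ll + sum(eta[dead]) -
      length(dead) * log(sum(exp(eta[risk])))
  }
  ll
}

# Nested grid-search maximizer of the partial likelihood (two coefficients),
# refined over successive rounds; deterministic.
oracle_cox_grid <- function(time, event, X, lo = -4, hi = 4) {
  center <- c(0, 0); half <- (hi - lo) / 2
  for (round in 1:8) {
    g1 <- seq(center[1] - half, center[1] + half, length.out = 21)
    g2 <- seq(center[2] - half, center[2] + half, length.out = 21)
    best <- -Inf
    for (b1 in g1) for (b2 in g2) {
      ll <- oracle_partial_loglik(c(b1, b2), time, event, X)
      if (ll > best) { best <- ll; center <- c(b1, b2) }
    }
    half <- half / 5
  }
  center
}

# Exhaustive hypergeometric upper tail: fraction of |A|-subsets of the
# universe overlapping a fixed B in at least k elements.
oracle_hyper_enum <- function(universe, size_a, b, k) {
  subsets <- utils::combn(universe, size_a)
  hits <- apply(subsets, 2, function(s) length(intersect(s, b)) >= k)
  mean(hits)
}

# Tertile survival data with a known hazard ratio between expression
# groups; exponential baseline, administrative censoring.
simulate_tertile_survival <- function(n, hr_medium = 1, hr_high = 1,
                                      baseline = 0.02, censor = 60) {
  x <- rnorm(n)
  tg <- tertile_groups(setNames(x, paste0("s", seq_len(n))))
  hz <- baseline * c(low = 1, medium = hr_medium,
                     high = hr_high)[as.character(tg$groups)]
  t_raw <- rexp(n, rate = hz)
  list(time = pmin(t_raw, censor), event = as.integer(t_raw <= censor),
       groups = tg$groups)
}
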