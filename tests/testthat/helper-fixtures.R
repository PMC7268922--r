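# Fixtures built in code plus independent oracles used across the suite.

# Minimal study from an explicit log2-scale matrix (marked preprocessed so
# effect computations can run on it directly).
make_log2_study <- function(mat, groups, study_id = "S1",
                            region = "Spain", year = 2010L) {
  s <- expression_study(study_id, mat, groups, region, year)
  s$preprocessed <- TRUE
  s
}

# Random effect records for estimator property tests.
random_effects <- function(k, gene = "g") {
  data.frame(gene = gene,
             study_id = sprintf("s%02d", seq_len(k)),
             y = rnorm(k, 0, 1),
             se = runif(k, 0.05, 1),
             stringsAsFactors = FALSE)
}

# Independent oracle: loop-based inverse-variance pooling (no vectorized
# shortcuts shared with the implementation).
oracle_fixed <- function(y, se) {
  num <- 0; den <- 0
  for (i in seq_along(y)) {
    w <- 1 / se[i]^2
    num <- num + w * y[i]
    den <- den + w
  }
  pooled <- num / den
  Q <- 0
  for (i in seq_along(y)) Q <- Q + (y[i] - pooled)^2 / se[i]^2
  list(pooled = pooled, se = sqrt(1 / den), Q = Q)
}

# Independent oracle: hypergeometric upper tail by explicit enumeration of
# the pmf in log space.
oracle_hyper_tail <- function(n_A, n_B, n_overlap, n_universe) {
  xs <- max(0, n_A + n_B - n_universe):min(n_A, n_B)
  lp <- lchoose(n_A, xs) + lchoose(n_universe - n_A, n_B - xs) -
    lchoose(n_universe, n_B)
  sum(exp(lp)[xs >= n_overlap])
}

# Independent oracle: textbook BH step-up transform.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}

# Independent oracle: OLS via the normal equations, solved on centered
# predictors (mathematically identical, numerically stable) with the
# intercept recovered exactly.
oracle_ols <- function(X, y) {
  Xc <- X[, -1, drop = FALSE]
  mx <- colMeans(Xc)
  my <- mean(y)
  Xd <- sweep(Xc, 2, mx)
  b <- solve(t(Xd) %*% Xd, t(Xd) %*% (y - my))
  c(my - sum(mx * b), b)
}

# Pipeline config without cross-sample normalization, for simulations whose
# planted shift is shared by every gene (normalization would remove it by
# design).
config_no_norm <- function() {
  cfg <- mega_defaults()
  cfg$normalization <- "none"
  cfg
}
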