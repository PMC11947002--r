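# Independent oracles used across the suite. Each is written from the
# defining construction, not from the package implementation.

# Truncated-power natural cubic spline basis (intercept included).
# knots_all: all knots, boundaries included, sorted. Cubic between
# knots, linear beyond the extreme knots:
#   N1 = 1, N2 = x, N_{k+2} = d_k(x) - d_{M-1}(x),
#   d_k(x) = [(x - xi_k)_+^3 - (x - xi_M)_+^3] / (xi_M - xi_k)
tp_natural_basis <- function(x, knots_all) {
  xi <- sort(knots_all)
  M <- length(xi)
  pp3 <- function(u) pmax(u, 0)^3
  d <- function(k) (pp3(x - xi[k]) - pp3(x - xi[M])) / (xi[M] - xi[k])
  cols <- list(rep(1, length(x)), x)
  for (k in seq_len(M - 2)) cols[[k + 2]] <- d(k) - d(M - 1)
  do.call(cbind, cols)
}

# column-space projection matrix via QR (rank-tolerant)
proj_matrix <- function(B) {
  q <- qr.Q(qr(B))
  tcrossprod(q)
}

# scalar DerSimonian-Laird random-effects pooling
dl_pool_scalar <- function(beta, v) {
  w <- 1 / v
  bf <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - bf)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (length(beta) - 1)) / cc)
  wr <- 1 / (v + tau2)
  list(beta = sum(wr * beta) / sum(wr), v = 1 / sum(wr), tau2 = tau2)
}

# hand-rolled type-7 sample quantile from order statistics
quantile_type7_oracle <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# brute-force cross-basis: quadruple loop over (t, j, k, l) with
# repeated-first-value unavailable -> NA semantics handled by the caller
cross_basis_bruteforce <- function(x, exposure_basis_fn, lag_basis, max_lag) {
  n <- length(x)
  C <- lag_basis  # (max_lag + 1) x vl
  vl <- ncol(C)
  R_all <- exposure_basis_fn(x)  # n x vx
  vx <- ncol(R_all)
  W <- matrix(NA_real_, n, vx * vl)
  for (t in (max_lag + 1):n) {
    for (k in seq_len(vl)) {
      for (j in seq_len(vx)) {
        acc <- 0
        for (l in 0:max_lag) {
          acc <- acc + R_all[t - l, j] * C[l + 1, k]
        }
        W[t, (k - 1) * vx + j] <- acc
      }
    }
  }
  W
}

# small null-effect simulation config used by several model tests
null_config <- function(n_zones, years = 2, seed = 1, overdispersion = 1,
                        baseline_rate = 5, stratum_sd = 0.1, ...) {
  sim_config(
    n_zones = n_zones,
    date_start = as.Date("2016-01-01"),
    date_end = as.Date(sprintf("%d-12-31", 2015 + years)),
    baseline_rate = baseline_rate,
    stratum_sd = stratum_sd,
    overdispersion = overdispersion,
    seed = seed,
    ...
  )
}

# explicit stratum-dummy Poisson fit: the estimation oracle
dummy_glm_fit <- function(design) {
  use <- design$mask
  df <- data.frame(y = design$y[use], design$X[use, , drop = FALSE],
                   check.names = FALSE)
  df$.s <- droplevels(design$stratum[use])
  # drop all-zero strata, mirroring the conditional likelihood
  tot <- tapply(df$y, df$.s, sum)
  df <- df[df$.s %in% names(tot)[tot > 0], , drop = FALSE]
  df$.s <- droplevels(df$.s)
  g <- glm(y ~ . - 1, data = df, family = poisson(),
           control = list(epsilon = 1e-12, maxit = 100))
  keep <- colnames(design$X)
  phi <- sum(residuals(g, type = "pearson")^2) / g$df.residual
  list(
    beta = coef(g)[keep],
    vcov_unscaled = vcov(g)[keep, keep] / summary(g)$dispersion,
    dispersion = phi
  )
}
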