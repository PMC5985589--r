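# Internal numerical helpers: log-sum-exp, multivariate normal density,
# HPD intervals, autocorrelation-based effective sample size.

logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
#' Cholesky of a covariance matrix with an informative error for
#' non-positive-definite input.
.chol_pd <- function(D, what = "covariance matrix") {
  R <- tryCatch(chol(D), error = function(e) NULL)
  if (is.null(R)) stop(what, " is not positive definite", call. = FALSE)
  R
}

# log MVN density; `R` an optional pre-computed upper Cholesky factor of D
.dmvn_log <- function(b, mu, D, R = NULL) {
  if (is.null(R)) R <- .chol_pd(D)
  q <- length(mu)
  z <- backsolve(R, b - mu, transpose = TRUE)
  -0.5 * q * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

# Rows of B evaluated at once; returns a vector of log densities.
.dmvn_log_rows <- function(B, mu, D, R = NULL) {
  if (is.null(R)) R <- .chol_pd(D)
  q <- length(mu)
  Z <- backsolve(R, t(B) - mu, transpose = TRUE)
  -0.5 * q * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(Z^2)
}

.rmvn <- function(n, mu, Sigma) {
  if (length(mu) == 1L) {
    matrix(stats::rnorm(n, mu, sqrt(Sigma[1L, 1L])), ncol = 1L)
  } else {
    MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
  }
}

# Inverse-Wishart draw: D ~ IW(df, S) <=> D^{-1} ~ Wishart(df, S^{-1})
.riwish <- function(df, S) {
  W <- stats::rWishart(1L, df = df, Sigma = solve(S))[, , 1L]
  solve(W)
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1   # degenerate underflow guard
  g / sum(g)
}

# Shortest interval containing fraction `prob` of the draws.
.hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  M <- length(x)
  keep <- max(1L, ceiling(prob * M))
  if (keep >= M) return(c(x[1L], x[M]))
  starts <- seq_len(M - keep)
  widths <- x[starts + keep] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + keep])
}

# ESS via Geyer's initial positive sequence: Gamma_m = rho_{2m} +
# rho_{2m+1}, summed while positive; tau = 2 * sum(Gamma) - 1.
.ess <- function(x) {
  M <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v < .Machine$double.eps) return(NA_real_)
  lag_max <- min(M - 1L, 10L * floor(sqrt(M)))
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
  s <- 0
  m <- 0L
  while (2L * m + 2L <= length(ac)) {
    g <- ac[2L * m + 1L] + ac[2L * m + 2L]
    if (g <= 0) break
    s <- s + g
    m <- m + 1L
  }
  tau <- max(1, 2 * s - 1)
  max(1, M / tau)
}

# Split-chain potential scale reduction factor over a list of numeric chains.
.rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    M <- length(x)
    h <- floor(M / 2)
    list(x[seq_len(h)], x[(M - h + 1L):M])
  }), recursive = FALSE)
  m <- length(halves)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(x) x[seq_len(n)])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (!is.finite(W) || W < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# deterministic small-integer sub-seed from a parent seed and a label
.subseed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483543
  as.integer(h + 1)
}
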