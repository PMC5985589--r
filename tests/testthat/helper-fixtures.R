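# Shared in-code fixtures: tiny specs, parameter sets and histories.

gauss_spec <- function(K = 1L, fixed = "time_since_diagnosis", group = 0L) {
  group_model_spec(group, list(marker_spec("g1", "gaussian", fixed = fixed)),
                   K = K)
}

bern_spec <- function(K = 1L, group = 0L) {
  group_model_spec(group, list(marker_spec("b1", "bernoulli")), K = K)
}

three_marker_specs <- function() sanad_like_scenario(10L, 1L)$group_specs

simple_subject <- function(id = "s1", times = c(100, 400, 800),
                           values = c(1.2, 0.7, 1.9), marker = "g1",
                           group = 0L) {
  mk <- list(list(times = times, values = values))
  names(mk) <- marker
  subject_data(id, group = group, markers = mk)
}

# mixture-implied first two moments of the random effects
implied_moments <- function(theta) {
  K <- length(theta$w)
  m <- Reduce(`+`, lapply(seq_len(K), function(k) theta$w[k] * theta$mu[[k]]))
  V <- Reduce(`+`, lapply(seq_len(K), function(k)
    theta$w[k] * (theta$D[[k]] + tcrossprod(theta$mu[[k]])))) -
    tcrossprod(m)
  list(mean = m, cov = V)
}

# brute-force AUC: pairwise concordance with half credit for ties
auc_brute <- function(scores, truths) {
  pos <- scores[as.logical(truths)]
  neg <- scores[!as.logical(truths)]
  grid <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(grid)
}

# random small mixed-family instance for Laplace-vs-quadrature checks
random_instance <- function(seed) {
  set.seed(seed)
  fams <- sample(c("gaussian", "bernoulli", "poisson"), 3, replace = TRUE)
  specs <- lapply(seq_along(fams), function(r)
    marker_spec(paste0("m", r), fams[r]))
  spec <- group_model_spec(0L, specs, K = sample(1:2, 1))
  markers <- list()
  for (r in seq_along(fams)) {
    n_r <- sample(1:6, 1)
    tt <- sort(sample(50:1800, n_r))
    vals <- switch(fams[r],
      gaussian = rnorm(n_r, 0.5, 1),
      bernoulli = rbinom(n_r, 1, 0.5),
      poisson = rpois(n_r, 1.5))
    markers[[paste0("m", r)]] <- list(times = tt, values = vals)
  }
  subj <- subject_data("rs", 0L, markers = markers)
  K <- spec$K
  q <- 3L
  theta <- list(
    w = { w <- runif(K, 0.2, 1); w / sum(w) },
    mu = lapply(seq_len(K), function(k) rnorm(q, 0, 0.8)),
    D = lapply(seq_len(K), function(k) {
      A <- matrix(rnorm(q * q, 0, 0.3), q)
      crossprod(A) + diag(0.3, q)
    }))
  psi <- list(alpha = stats::setNames(lapply(fams, function(f) numeric(0)),
                                      paste0("m", seq_along(fams))),
              phi = stats::setNames(ifelse(fams == "gaussian", 0.6, 1),
                                    paste0("m", seq_along(fams))))
  list(h = evaluated_history(subj, spec), psi = psi, theta = theta,
       spec = spec, subject = subj)
}
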