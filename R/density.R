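# Density layer of the discriminant machinery: conditional density of a
# marker history given random effects, mixture density of the random
# effects, and the marginal density with random effects integrated out,
# the latter per mixture component by Laplace approximation (default) or
# adaptive Gauss-Hermite quadrature (oracle for small q).
#
# All arithmetic is on the log scale with log-sum-exp combination; long
# histories underflow otherwise.

#' Evaluate a subject's history against a group model
#'
#' Packages the truncated marker values together with their design
#' matrices into the form the density functions consume.
#'
#' @param subject a [subject_data()] object.
#' @param spec the [group_model_spec()] providing families and designs.
#' @param t time (days) at which the history is cut ([truncate_history()]
#'   semantics); default `Inf` keeps everything.
#' @return an object of class `loda_history`.
#' @export
evaluated_history <- function(subject, spec, t = Inf) {
  subject <- truncate_history(subject, min(t, .Machine$double.xmax))
  design <- build_design_rows(subject, spec)
  lay <- .ranef_layout(spec)
  markers <- lapply(.marker_names(spec), function(nm) {
    list(name = nm,
         family = spec$markers[[nm]]$family,
         y = subject$markers[[nm]]$values,
         X = design[[nm]]$X, Z = design[[nm]]$Z,
         cols = lay$offsets[[nm]] + seq_len(lay$q_r[[nm]]))
  })
  names(markers) <- .marker_names(spec)
  structure(list(markers = markers, q = lay$q,
                 subject_id = subject$subject_id),
            class = "loda_history")
}

.n_obs <- function(h) sum(vapply(h$markers, function(m) length(m$y), 0L))

# family log density at linear predictor eta (vectorized over obs)
.family_logdens <- function(y, eta, family, phi) {
  switch(family,
    gaussian  = stats::dnorm(y, mean = eta, sd = sqrt(phi), log = TRUE),
    bernoulli = stats::dbinom(y, size = 1L, prob = stats::plogis(eta), log = TRUE),
    poisson   = stats::dpois(y, lambda = exp(eta), log = TRUE))
}

#' Conditional log density of a history given the random effects
#'
#' Sum over markers and visits of the exponential-family log density
#' with linear predictor \eqn{x'\alpha_r + z' b_r} under the canonical
#' link.  An empty history contributes 0 (log of an empty product).
#'
#' @param h an [evaluated_history()].
#' @param b numeric random-effects vector of length `h$q`.
#' @param psi fixed-effect/dispersion parameters: list with `alpha`
#'   (named list of coefficient vectors per marker) and `phi` (named
#'   numeric; 1 for bernoulli/poisson).
#' @return scalar log density.
#' @export
conditional_log_density <- function(h, b, psi) {
  stopifnot(length(b) == h$q)
  ll <- 0
  for (m in h$markers) {
    if (!length(m$y)) next
    eta <- drop(m$X %*% psi$alpha[[m$name]]) + drop(m$Z %*% b[m$cols])
    ll <- ll + sum(.family_logdens(m$y, eta, m$family, psi$phi[[m$name]]))
  }
  ll
}

# conditional log density at many b's at once: B is (n_pts x q)
.conditional_log_density_rows <- function(h, B, psi) {
  ll <- numeric(nrow(B))
  for (m in h$markers) {
    if (!length(m$y)) next
    eta0 <- drop(m$X %*% psi$alpha[[m$name]])
    Eta <- matrix(eta0, nrow = length(eta0), ncol = nrow(B)) +
      m$Z %*% t(B[, m$cols, drop = FALSE])
    ll <- ll + colSums(matrix(
      .family_logdens(m$y, Eta, m$family, psi$phi[[m$name]]),
      nrow = length(m$y)))
  }
  ll
}

#' Log density of the normal-mixture random-effects law
#'
#' \eqn{\log \sum_k w_k \phi(b; \mu_k, D_k)}, combined by log-sum-exp.
#'
#' @param b numeric vector.
#' @param theta mixture parameters: list with `w` (weights), `mu` (list
#'   of mean vectors), `D` (list of covariance matrices).
#' @return scalar log density.
#' @export
ranef_log_density <- function(b, theta) {
  K <- length(theta$w)
  lk <- vapply(seq_len(K), function(k)
    log(theta$w[k]) + .dmvn_log(b, theta$mu[[k]], theta$D[[k]]), 0)
  logsumexp(lk)
}

# same over rows of B
.ranef_log_density_rows <- function(B, theta) {
  K <- length(theta$w)
  L <- vapply(seq_len(K), function(k)
    log(theta$w[k]) + .dmvn_log_rows(B, theta$mu[[k]], theta$D[[k]]),
    numeric(nrow(B)))
  L <- matrix(L, nrow = nrow(B))
  mx <- do.call(pmax, c(as.data.frame(L), list(-Inf)))
  mx + log(rowSums(exp(L - mx)))
}

# gradient and negative Hessian of b -> cond ll(b) + log N(b; mu, D)
# for canonical links; Dinv = D^{-1}
.joint_grad_hess <- function(h, b, psi, mu, Dinv) {
  q <- h$q
  g <- -Dinv %*% (b - mu)
  H <- Dinv   # negative Hessian (positive definite part from prior)
  for (m in h$markers) {
    if (!length(m$y)) next
    eta <- drop(m$X %*% psi$alpha[[m$name]]) + drop(m$Z %*% b[m$cols])
    res_w <- switch(m$family,
      gaussian  = list(r = (m$y - eta) / psi$phi[[m$name]],
                       w = rep(1 / psi$phi[[m$name]], length(eta))),
      bernoulli = { p <- stats::plogis(eta); list(r = m$y - p, w = p * (1 - p)) },
      poisson   = { lam <- exp(eta); list(r = m$y - lam, w = lam) })
    g[m$cols] <- g[m$cols] + drop(crossprod(m$Z, res_w$r))
    H[m$cols, m$cols] <- H[m$cols, m$cols] +
      crossprod(m$Z * res_w$w, m$Z)
  }
  list(grad = drop(g), negH = H)
}

# Newton ascent with step halving to the mode of
# b -> cond ll(b) + log N(b; mu, D).  Log-concave in b for canonical
# links, so ascent from mu (or a warm start) is reliable.
.component_mode <- function(h, psi, mu, D, start = NULL,
                            tol = 1e-8, max_iter = 50L) {
  Dinv <- chol2inv(.chol_pd(D))
  obj <- function(b) conditional_log_density(h, b, psi) + .dmvn_log(b, mu, D)
  b <- if (is.null(start)) mu else start
  f <- obj(b)
  if (!is.finite(f)) { b <- mu; f <- obj(b) }      # bad warm start
  if (!is.finite(f)) { b <- rep(0, h$q); f <- obj(b) }  # extreme component
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    gh <- .joint_grad_hess(h, b, psi, mu, Dinv)
    step <- tryCatch(drop(solve(gh$negH, gh$grad)), error = function(e) NULL)
    if (is.null(step)) step <- gh$grad   # fall back to gradient ascent
    # scale-invariant Newton decrement; also accept tiny gradients
    dec <- sum(step * gh$grad)
    if (is.finite(dec) && (dec < tol || max(abs(gh$grad)) < tol)) {
      converged <- TRUE
      break
    }
    lambda <- 1
    repeat {
      b_new <- b + lambda * step
      f_new <- obj(b_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { b_new <- b; f_new <- f; break }
    }
    if (f_new - f < 1e-12 && it > 1L) {      # stalled on a flat stretch
      b <- b_new; f <- f_new
      converged <- is.finite(dec) && dec < 1e-4
      break
    }
    b <- b_new; f <- f_new
  }
  gh <- .joint_grad_hess(h, b, psi, mu, Dinv)
  dec_f <- tryCatch(sum(drop(solve(gh$negH, gh$grad)) * gh$grad),
                    error = function(e) Inf)
  if (is.finite(dec_f) && dec_f < 1e-6) converged <- TRUE
  list(mode = b, value = f, negH = gh$negH, converged = converged)
}

#' Marginal log density via per-component Laplace approximation
#'
#' The marginal density of a history under the mixture model is a
#' weighted sum over components of single-component integrals; each is
#' approximated by a Laplace expansion at its own mode (a global Laplace
#' on the multimodal integrand would be unsafe) and the components are
#' combined by log-sum-exp.  Exact when all markers are gaussian.
#'
#' An empty history has marginal density 1, i.e. log density 0.
#'
#' @param h an [evaluated_history()].
#' @param psi,theta parameters as in [conditional_log_density()] and
#'   [ranef_log_density()].
#' @param start optional list of per-component starting values for the
#'   Newton mode search (warm starts across MCMC draws).
#' @return scalar log density, with attribute `"modes"` (list of
#'   per-component modes) for reuse.
#' @export
marginal_log_density_laplace <- function(h, psi, theta, start = NULL) {
  if (.n_obs(h) == 0L) {
    out <- 0
    attr(out, "modes") <- theta$mu
    return(out)
  }
  K <- length(theta$w)
  lk <- numeric(K)
  modes <- vector("list", K)
  neghs <- vector("list", K)
  ok <- TRUE
  for (k in seq_len(K)) {
    mk <- .component_mode(h, psi, theta$mu[[k]], theta$D[[k]],
                          start = if (!is.null(start)) start[[k]] else NULL)
    ok <- ok && mk$converged
    modes[[k]] <- mk$mode
    neghs[[k]] <- mk$negH
    R <- tryCatch(chol(mk$negH), error = function(e) NULL)
    if (is.null(R)) { ok <- FALSE; lk[k] <- -Inf; next }
    lk[k] <- log(theta$w[k]) + mk$value +
      0.5 * h$q * log(2 * pi) - sum(log(diag(R)))
  }
  if (!ok && h$q <= 4L) {
    warning("Laplace mode search did not converge; falling back to quadrature")
    return(marginal_log_density_quadrature(h, psi, theta))
  }
  out <- logsumexp(lk)
  attr(out, "modes") <- modes
  attr(out, "neg_hessians") <- neghs
  out
}

#' Marginal log density by adaptive Gauss-Hermite quadrature (oracle)
#'
#' Per mixture component, tensor-product Gauss-Hermite quadrature
#' centred and scaled at the Laplace mode, combined across components by
#' log-sum-exp.  Intended as an accuracy oracle for small random-effect
#' dimension (`q <= 4`); cost grows as `n_nodes^q`.
#'
#' @inheritParams marginal_log_density_laplace
#' @param n_nodes nodes per dimension (default 64, matching the
#'   reference tolerance used in the tests).
#' @return scalar log density.
#' @export
marginal_log_density_quadrature <- function(h, psi, theta, n_nodes = 64L) {
  if (h$q > 4L) stop("quadrature oracle supports q <= 4 only")
  if (.n_obs(h) == 0L) return(0)
  gh <- pracma::gaussHermite(n_nodes)
  q <- h$q
  U <- as.matrix(expand.grid(rep(list(gh$x), q)))
  logw_grid <- rowSums(matrix(
    log(gh$w)[match(U, gh$x)] + U^2, nrow = nrow(U)))
  K <- length(theta$w)
  lk <- numeric(K)
  for (k in seq_len(K)) {
    mk <- .component_mode(h, psi, theta$mu[[k]], theta$D[[k]])
    Sigma <- chol2inv(.chol_pd(mk$negH, "negative Hessian"))
    Cu <- chol(Sigma)                       # upper; t(Cu) %*% Cu = Sigma
    B <- matrix(mk$mode, nrow(U), q, byrow = TRUE) + sqrt(2) * (U %*% Cu)
    ll <- .conditional_log_density_rows(h, B, psi) +
      .dmvn_log_rows(B, theta$mu[[k]], theta$D[[k]])
    lk[k] <- log(theta$w[k]) + 0.5 * q * log(2) + sum(log(diag(Cu))) +
      logsumexp(logw_grid + ll)
  }
  logsumexp(lk)
}

#' Sample the predictive distribution of a new subject's random effects
#'
#' Draws from \eqn{p(b \mid y, \psi, \theta) \propto
#' f^{cond}(y \mid b)\, f^{ranef}(b)} by independence
#' Metropolis-Hastings whose proposal is the mixture of per-component
#' Laplace normal approximations (weights proportional to the Laplace
#' component marginals).  With an empty history the proposal equals the
#' target exactly, so the draws are i.i.d. from the mixture prior.
#'
#' @inheritParams marginal_log_density_laplace
#' @param n_draws number of retained draws.
#' @param seed optional integer seed for reproducibility.
#' @param start optional starting value (defaults to the dominant
#'   component's mode, the maximum-a-posteriori random effect).
#' @return list with `draws` (`n_draws x q` matrix), `mode` (the MAP
#'   random-effects value), `accept_rate`.
#' @export
sample_ranef_predictive <- function(h, psi, theta, n_draws, seed = NULL,
                                    start = NULL) {
  stopifnot(n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  prop <- .predictive_proposal(h, psi, theta)
  b <- if (is.null(start)) prop$map else start
  lp_b <- .predictive_logpost(h, b, psi, theta)
  lq_b <- .mixture_proposal_logdens(b, prop)
  draws <- matrix(0, n_draws, h$q)
  acc <- 0L
  for (i in seq_len(n_draws)) {
    cand <- .mixture_proposal_draw(prop)
    lp_c <- .predictive_logpost(h, cand, psi, theta)
    lq_c <- .mixture_proposal_logdens(cand, prop)
    if (log(stats::runif(1)) < (lp_c - lp_b) - (lq_c - lq_b)) {
      b <- cand; lp_b <- lp_c; lq_b <- lq_c; acc <- acc + 1L
    }
    draws[i, ] <- b
  }
  list(draws = draws, mode = prop$map, accept_rate = acc / n_draws)
}

# Laplace-based mixture proposal for the predictive distribution
.predictive_proposal <- function(h, psi, theta) {
  K <- length(theta$w)
  if (.n_obs(h) == 0L) {
    comps <- lapply(seq_len(K), function(k)
      list(mu = theta$mu[[k]], R = .chol_pd(theta$D[[k]]),
           value = 0))
    lw <- log(theta$w)
  } else {
    comps <- vector("list", K)
    lw <- numeric(K)
    for (k in seq_len(K)) {
      mk <- .component_mode(h, psi, theta$mu[[k]], theta$D[[k]])
      Sigma <- chol2inv(.chol_pd(mk$negH, "negative Hessian"))
      comps[[k]] <- list(mu = mk$mode, R = chol(Sigma), value = mk$value)
      lw[k] <- log(theta$w[k]) + mk$value - sum(log(diag(chol(mk$negH))))
    }
  }
  lw <- lw - logsumexp(lw)
  map <- comps[[which.max(lw)]]$mu
  list(comps = comps, logw = lw, map = map, q = h$q)
}

.mixture_proposal_draw <- function(prop) {
  k <- sample.int(length(prop$logw), 1L, prob = exp(prop$logw))
  c0 <- prop$comps[[k]]
  drop(c0$mu + crossprod(c0$R, stats::rnorm(prop$q)))
}

.mixture_proposal_logdens <- function(b, prop) {
  lk <- vapply(seq_along(prop$comps), function(k) {
    c0 <- prop$comps[[k]]
    z <- backsolve(c0$R, b - c0$mu, transpose = TRUE)
    prop$logw[k] - 0.5 * prop$q * log(2 * pi) -
      sum(log(diag(c0$R))) - 0.5 * sum(z^2)
  }, 0)
  logsumexp(lk)
}

.predictive_logpost <- function(h, b, psi, theta) {
  conditional_log_density(h, b, psi) + ranef_log_density(b, theta)
}
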