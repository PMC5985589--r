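# MCMC estimation of one prognostic group's MGLMM with normal-mixture
# random effects.  The sampler works on the augmented model (mixture
# allocations and subject random effects as latent variables); one sweep
# updates, in order: allocations | b, theta; weights | allocations;
# (mu_k, D_k) | b, allocations (conjugate normal / inverse-Wishart);
# b_i by random-walk Metropolis, vectorized across subjects; alpha_r by
# Gibbs for gaussian markers and random-walk Metropolis otherwise; and
# gaussian dispersions by inverse-gamma Gibbs.  Proposal scales adapt
# toward ~0.3 acceptance during burn-in and are frozen afterwards.

# stack a group's data into flat per-marker arrays
.prepare_group_data <- function(subjects, spec) {
  lay <- .ranef_layout(spec)
  n <- length(subjects)
  stack <- list()
  for (mspec in spec$markers) {
    nm <- mspec$name
    ys <- list(); Xs <- list(); Zs <- list(); subs <- list()
    for (i in seq_len(n)) {
      s <- subjects[[i]]
      m <- s$markers[[nm]]
      if (is.null(m) || !length(m$times)) next
      d <- build_design_rows(s, spec)[[nm]]
      ys[[length(ys) + 1L]] <- m$values
      Xs[[length(Xs) + 1L]] <- d$X
      Zs[[length(Zs) + 1L]] <- d$Z
      subs[[length(subs) + 1L]] <- rep(i, length(m$times))
    }
    if (!length(ys))
      stop("marker '", nm, "' has no observations in group ", spec$group)
    stack[[nm]] <- list(
      name = nm, family = mspec$family,
      y = unlist(ys), X = do.call(rbind, Xs), Z = do.call(rbind, Zs),
      sub = unlist(subs), cols = lay$offsets[[nm]] + seq_len(lay$q_r[[nm]]))
  }
  list(stack = stack, lay = lay, n = n,
       ids = vapply(subjects, `[[`, "", "subject_id"))
}

# per-marker fixed-effects-only GLM fit: init coefficients, proposal
# Cholesky, and per-subject crude intercepts from working residuals
.init_marker <- function(st, n) {
  fam <- switch(st$family, gaussian = stats::gaussian(),
                bernoulli = stats::binomial(), poisson = stats::poisson())
  if (ncol(st$X) == 0L) {
    alpha <- numeric(0)
  } else {
    fit <- suppressWarnings(stats::glm.fit(st$X, st$y, family = fam))
    alpha <- fit$coefficients
    alpha[!is.finite(alpha)] <- 0
  }
  eta <- if (length(alpha)) drop(st$X %*% alpha) else numeric(length(st$y))
  mu <- fam$linkinv(eta)
  wres <- (st$y - mu) / pmax(fam$mu.eta(eta), 1e-6)
  crude <- rep(0, n)
  agg <- rowsum(wres, st$sub)
  cnt <- rowsum(rep(1, length(wres)), st$sub)
  crude[as.integer(rownames(agg))] <- agg / cnt
  # winsorize: working residuals of near-saturated binary/count fits can
  # be enormous and would blow up the data-driven mixture priors
  lim <- stats::quantile(crude, c(0.02, 0.98))
  crude <- pmin(pmax(crude, lim[1L]), lim[2L])
  phi <- if (st$family == "gaussian")
    max(stats::var(st$y - mu), 1e-4) else 1
  if (ncol(st$X) == 0L)
    return(list(alpha = alpha, prop_chol = matrix(0, 0, 0),
                crude = crude, phi = phi))
  W <- pmax(fam$mu.eta(eta)^2 / pmax(fam$variance(mu), 1e-8), 1e-8)
  XtWX <- crossprod(st$X * W, st$X)
  V <- tryCatch(chol2inv(chol(XtWX)), error = function(e)
    diag(ncol(st$X)))
  list(alpha = alpha, prop_chol = chol((V + diag(1e-8, ncol(V))) * 2.4^2 /
                                         max(1, ncol(V))),
       crude = crude, phi = phi)
}

# per-subject conditional log likelihood given caches
.cond_ll_subjects <- function(pd, xalpha, zb, phi) {
  ll <- numeric(pd$n)
  for (nm in names(pd$stack)) {
    st <- pd$stack[[nm]]
    lr <- .family_logdens(st$y, xalpha[[nm]] + zb[[nm]], st$family, phi[[nm]])
    agg <- rowsum(lr, st$sub)
    ll[as.integer(rownames(agg))] <- ll[as.integer(rownames(agg))] + agg
  }
  ll
}

.zb_cache <- function(pd, b) {
  lapply(pd$stack, function(st)
    rowSums(st$Z * b[st$sub, st$cols, drop = FALSE]))
}

#' Fit one group's MGLMM by MCMC
#'
#' @param data_g a `loda_dataset` (subjects labelled with
#'   `spec$group` are used) or a plain list of [subject_data()].
#' @param spec the group's [group_model_spec()].
#' @param settings list: `n_iter` (total sweeps), `burn_in`, `thin`,
#'   `seed`, `keep_ranef` (retain per-subject random-effect draws),
#'   `n_chains` (independent chains; draws of the first are returned,
#'   all chains kept in `$chains`).
#' @return an object of class `loda_posterior`: list with `draws` (list
#'   of `M` parameter draws, each `list(psi, theta)`), `meta`, and the
#'   resolved `prior`.
#' @export
fit_group_model <- function(data_g, spec, settings = list()) {
  set0 <- utils::modifyList(
    list(n_iter = 2000L, burn_in = 500L, thin = 2L, seed = 1L,
         keep_ranef = FALSE, n_chains = 1L), settings)
  subjects <- if (inherits(data_g, "loda_dataset"))
    .group_subjects(data_g, spec$group) else data_g
  if (!length(subjects)) stop("no subjects in group ", spec$group)
  if (spec$K > length(subjects))
    stop("K = ", spec$K, " exceeds the number of subjects (",
         length(subjects), ")")
  chains <- lapply(seq_len(set0$n_chains), function(ch) {
    s <- set0
    s$seed <- .subseed(set0$seed, "chain", ch)
    .run_chain(subjects, spec, s)
  })
  out <- chains[[1L]]
  if (set0$n_chains > 1L) out$chains <- chains
  out
}

.run_chain <- function(subjects, spec, set0) {
  set.seed(set0$seed)
  pd <- .prepare_group_data(subjects, spec)
  n <- pd$n; q <- pd$lay$q; K <- spec$K
  pr <- spec$prior

  # --- initialization from fixed-effects-only fits -----------------------
  init <- lapply(pd$stack, .init_marker, n = n)
  alpha <- lapply(init, `[[`, "alpha")
  phi <- vapply(init, `[[`, 0, "phi")
  crude <- matrix(0, n, q)
  for (nm in names(pd$stack))
    crude[, pd$stack[[nm]]$cols[1L]] <- init[[nm]]$crude

  # --- resolve data-driven mixture hyperparameters -----------------------
  rng <- apply(crude, 2, function(x) diff(range(x)))
  m0 <- if (!is.null(pr$mu_mean)) pr$mu_mean else rep(0, q)
  s0d <- if (!is.null(pr$mu_var)) {
    if (is.matrix(pr$mu_var)) diag(pr$mu_var) else rep(pr$mu_var, q)
  } else pmax(4 * rng, 4)
  S0inv <- diag(1 / s0d, q)
  nu0 <- if (!is.null(pr$wishart_df)) pr$wishart_df else q + 1
  Psi0 <- if (!is.null(pr$wishart_scale)) pr$wishart_scale else
    diag(pmax(apply(crude, 2, stats::var), 0.1), q)

  # mixture initialization: k-means on crude intercepts (or jittered
  # centres when K exceeds the number of distinct crude rows)
  if (K > 1L && nrow(unique(crude)) >= K) {
    km <- stats::kmeans(crude, centers = K, nstart = 5L)
    mu <- lapply(seq_len(K), function(k) km$centers[k, ])
    alloc <- km$cluster
  } else {
    mu <- lapply(seq_len(K), function(k)
      colMeans(crude) + (k - (K + 1) / 2) * 0.1)
    alloc <- rep(1L, n)
  }
  Dk <- lapply(seq_len(K), function(k)
    diag(pmax(apply(crude, 2, stats::var), 0.2), q))
  w <- rep(1 / K, K)
  b <- matrix(0, n, q)

  # --- proposal scales ---------------------------------------------------
  b_sd <- pmax(apply(crude, 2, stats::sd), 0.2)
  ls_b <- 0        # log multiplier for b proposals
  ls_a <- stats::setNames(rep(0, length(pd$stack)), names(pd$stack))
  acc_b <- 0; try_b <- 0
  acc_a <- ls_a; try_a <- ls_a

  xalpha <- lapply(names(pd$stack), function(nm)
    drop(pd$stack[[nm]]$X %*% alpha[[nm]]))
  names(xalpha) <- names(pd$stack)
  zb <- .zb_cache(pd, b)

  M_target <- floor((set0$n_iter - set0$burn_in) / set0$thin)
  draws <- vector("list", M_target)
  b_draws <- if (isTRUE(set0$keep_ranef)) vector("list", M_target) else NULL
  m_idx <- 0L
  acc_b_post <- 0; try_b_post <- 0
  acc_a_post <- ls_a; try_a_post <- ls_a

  a_var <- pr$alpha_var

  for (it in seq_len(set0$n_iter)) {
    ## -- allocations r_i | b, theta -------------------------------------
    if (K > 1L) {
      logp <- vapply(seq_len(K), function(k)
        log(w[k]) + .dmvn_log_rows(b, mu[[k]], Dk[[k]]), numeric(n))
      gum <- -log(-log(matrix(stats::runif(n * K), n, K)))
      alloc <- max.col(logp + gum)
    } else alloc <- rep(1L, n)

    ## -- weights | allocations ------------------------------------------
    cnt <- tabulate(alloc, K)
    w <- .rdirichlet(pr$dirichlet + cnt)

    ## -- (mu_k, D_k) | b, allocations ------------------------------------
    for (k in seq_len(K)) {
      idx <- which(alloc == k)
      if (!length(idx)) {           # refresh empty component from prior
        mu[[k]] <- stats::rnorm(q, m0, sqrt(s0d))
        Dk[[k]] <- .riwish(nu0 + q, Psi0)
        next
      }
      bk <- b[idx, , drop = FALSE]
      Sk <- crossprod(sweep(bk, 2, mu[[k]]))
      Dk[[k]] <- .riwish(nu0 + length(idx), Psi0 + Sk)
      Dinv <- chol2inv(.chol_pd(Dk[[k]]))
      prec <- S0inv + length(idx) * Dinv
      Rp <- chol(prec)
      mean_k <- backsolve(Rp, backsolve(
        Rp, S0inv %*% m0 + Dinv %*% colSums(bk), transpose = TRUE))
      mu[[k]] <- drop(mean_k + backsolve(Rp, stats::rnorm(q)))
    }

    ## -- b_i random-walk Metropolis, all subjects at once -----------------
    prop <- b + matrix(stats::rnorm(n * q), n, q) *
      rep(exp(ls_b) * b_sd, each = n)
    zb_prop <- .zb_cache(pd, prop)
    ll_old <- .cond_ll_subjects(pd, xalpha, zb, phi)
    ll_new <- .cond_ll_subjects(pd, xalpha, zb_prop, phi)
    pri_old <- numeric(n); pri_new <- numeric(n)
    for (k in seq_len(K)) {
      idx <- which(alloc == k)
      if (!length(idx)) next
      R <- .chol_pd(Dk[[k]])
      pri_old[idx] <- .dmvn_log_rows(b[idx, , drop = FALSE], mu[[k]],
                                     Dk[[k]], R)
      pri_new[idx] <- .dmvn_log_rows(prop[idx, , drop = FALSE], mu[[k]],
                                     Dk[[k]], R)
    }
    accept <- log(stats::runif(n)) < (ll_new + pri_new) - (ll_old + pri_old)
    b[accept, ] <- prop[accept, ]
    if (any(accept)) zb <- .zb_cache(pd, b)
    acc_b <- acc_b + mean(accept); try_b <- try_b + 1
    if (it > set0$burn_in) {
      acc_b_post <- acc_b_post + mean(accept); try_b_post <- try_b_post + 1
    }

    ## -- alpha_r ----------------------------------------------------------
    for (nm in names(pd$stack)) {
      st <- pd$stack[[nm]]
      p <- length(alpha[[nm]])
      if (p == 0L) next
      if (st$family == "gaussian") {       # conjugate Gibbs
        ystar <- st$y - zb[[nm]]
        prec <- crossprod(st$X) / phi[[nm]] + diag(1 / a_var, p)
        Rp <- chol(prec)
        mean_a <- backsolve(Rp, backsolve(
          Rp, crossprod(st$X, ystar) / phi[[nm]], transpose = TRUE))
        alpha[[nm]] <- drop(mean_a + backsolve(Rp, stats::rnorm(p)))
        xalpha[[nm]] <- drop(st$X %*% alpha[[nm]])
      } else {                             # random-walk Metropolis
        cand <- alpha[[nm]] + exp(ls_a[[nm]]) *
          drop(crossprod(init[[nm]]$prop_chol, stats::rnorm(p)))
        eta_old <- xalpha[[nm]] + zb[[nm]]
        eta_new <- drop(st$X %*% cand) + zb[[nm]]
        lr <- sum(.family_logdens(st$y, eta_new, st$family, 1)) -
          sum(.family_logdens(st$y, eta_old, st$family, 1)) +
          sum(stats::dnorm(cand, 0, sqrt(a_var), log = TRUE)) -
          sum(stats::dnorm(alpha[[nm]], 0, sqrt(a_var), log = TRUE))
        ok <- is.finite(lr) && log(stats::runif(1)) < lr
        if (ok) {
          alpha[[nm]] <- cand
          xalpha[[nm]] <- drop(st$X %*% cand)
        }
        acc_a[[nm]] <- acc_a[[nm]] + ok; try_a[[nm]] <- try_a[[nm]] + 1
        if (it > set0$burn_in) {
          acc_a_post[[nm]] <- acc_a_post[[nm]] + ok
          try_a_post[[nm]] <- try_a_post[[nm]] + 1
        }
      }
    }

    ## -- gaussian dispersions by inverse-gamma Gibbs ----------------------
    for (nm in names(pd$stack)) {
      st <- pd$stack[[nm]]
      if (st$family != "gaussian") next
      res <- st$y - xalpha[[nm]] - zb[[nm]]
      phi[[nm]] <- 1 / stats::rgamma(1,
        shape = pr$phi_shape + length(res) / 2,
        rate = pr$phi_rate + sum(res^2) / 2)
    }

    ## -- adaptation (burn-in only; frozen afterwards) ---------------------
    if (it <= set0$burn_in && it %% 50L == 0L) {
      ls_b <- ls_b + min(0.5, max(-0.5, (acc_b / try_b - 0.30)))
      acc_b <- 0; try_b <- 0
      for (nm in names(ls_a)) {
        if (try_a[[nm]] > 0) {
          ls_a[[nm]] <- ls_a[[nm]] +
            min(0.5, max(-0.5, acc_a[[nm]] / try_a[[nm]] - 0.30))
          acc_a[[nm]] <- 0; try_a[[nm]] <- 0
        }
      }
    }

    ## -- retention --------------------------------------------------------
    if (it > set0$burn_in && (it - set0$burn_in) %% set0$thin == 0L &&
        m_idx < M_target) {
      m_idx <- m_idx + 1L
      draws[[m_idx]] <- list(
        psi = list(alpha = alpha, phi = phi),
        theta = list(w = w, mu = mu, D = Dk))
      if (!is.null(b_draws)) b_draws[[m_idx]] <- b
    }
  }

  acc_rates <- c(b = if (try_b_post) acc_b_post / try_b_post else NA)
  for (nm in names(ls_a))
    if (try_a_post[[nm]] > 0)
      acc_rates[[paste0("alpha_", nm)]] <-
        acc_a_post[[nm]] / try_a_post[[nm]]
  warn <- acc_rates[!is.na(acc_rates)]
  meta <- list(n_iter = set0$n_iter, burn_in = set0$burn_in,
               thin = set0$thin, seed = set0$seed, M = m_idx,
               group = spec$group, K = K, q = q, n_subjects = n,
               acceptance = acc_rates,
               acceptance_ok = all(warn >= 0.1 & warn <= 0.6),
               prior = list(m0 = m0, s0 = s0d, nu0 = nu0, Psi0 = Psi0))
  structure(list(draws = draws[seq_len(m_idx)], meta = meta,
                 ranef_draws = b_draws, spec = spec),
            class = "loda_posterior")
}

#' @export
print.loda_posterior <- function(x, ...) {
  cat("<loda_posterior> group ", x$meta$group, ", K = ", x$meta$K,
      ", M = ", x$meta$M, " retained draws (", x$meta$n_iter,
      " sweeps, burn-in ", x$meta$burn_in, ", thin ", x$meta$thin, ")\n",
      sep = "")
  invisible(x)
}

# flatten one draw to a named numeric vector, with optional relabeling
# of components by increasing first coordinate of mu
.flatten_draw <- function(d, relabel = TRUE) {
  th <- d$theta
  K <- length(th$w)
  ord <- if (relabel && K > 1L)
    order(vapply(th$mu, `[[`, 0, 1L)) else seq_len(K)
  out <- c()
  for (nm in names(d$psi$alpha)) {
    a <- d$psi$alpha[[nm]]
    if (!length(a)) next
    names(a) <- paste0("alpha_", nm, "[", seq_along(a), "]")
    out <- c(out, a)
  }
  phi <- d$psi$phi
  names(phi) <- paste0("phi_", names(phi))
  out <- c(out, phi)
  for (j in seq_len(K)) {
    k <- ord[j]
    out[paste0("w[", j, "]")] <- th$w[k]
    mu <- th$mu[[k]]
    names(mu) <- paste0("mu[", j, "][", seq_along(mu), "]")
    out <- c(out, mu)
    D <- th$D[[k]]
    for (a in seq_len(nrow(D))) for (bb in a:ncol(D))
      out[paste0("D[", j, "][", a, ",", bb, "]")] <- D[a, bb]
  }
  out
}

#' Posterior summaries with HPD intervals
#'
#' Mixture-specific scalars (weights, means, covariances) are summarized
#' after relabeling components within each draw by increasing first
#' coordinate of the mixture mean; prediction never needs identified
#' labels, but summaries do.
#'
#' @param sample a `loda_posterior`.
#' @param prob HPD mass, in (0, 1).
#' @param relabel apply the ordering-based relabeling (default TRUE).
#' @return data frame with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
posterior_summary <- function(sample, prob = 0.95, relabel = TRUE) {
  if (prob <= 0 || prob >= 1) stop("prob must be in (0, 1)")
  if (sample$meta$M < 10L) stop("need at least 10 retained draws")
  mat <- t(vapply(sample$draws, .flatten_draw, relabel = relabel,
                  .flatten_draw(sample$draws[[1L]], relabel)))
  out <- data.frame(
    parameter = colnames(mat),
    mean = colMeans(mat),
    sd = apply(mat, 2, stats::sd))
  hpd <- t(apply(mat, 2, .hpd_interval, prob = prob))
  out$lower <- hpd[, 1L]
  out$upper <- hpd[, 2L]
  rownames(out) <- NULL
  out
}

#' MCMC diagnostics on mixture-invariant functionals
#'
#' Effective sample sizes are reported for the fixed effects and
#' dispersions and for label-invariant mixture functionals (the mixture
#' density evaluated at fixed points of the random-effects space), so
#' label switching cannot masquerade as poor mixing.  With two or more
#' chains, split-chain potential scale reduction factors are added.
#'
#' @param sample a `loda_posterior` (if fitted with `n_chains > 1`, all
#'   chains are used).
#' @return list with `ess`, `rhat` (or NULL), `acceptance`.
#' @export
mcmc_diagnostics <- function(sample) {
  chains <- if (!is.null(sample$chains)) sample$chains else list(sample)
  if (chains[[1L]]$meta$M < 10L) stop("need at least 10 retained draws")
  q <- chains[[1L]]$meta$q
  pts <- list(rep(0, q), rep(1, q), rep(-1, q))
  functionals <- function(ch) {
    sapply(ch$draws, function(d) {
      v <- c()
      for (nm in names(d$psi$alpha))
        if (length(d$psi$alpha[[nm]]))
          v[paste0("alpha_", nm, "[1]")] <- d$psi$alpha[[nm]][1L]
      for (j in seq_along(pts))
        v[paste0("log_franef_p", j)] <- ranef_log_density(pts[[j]], d$theta)
      v
    })
  }
  mats <- lapply(chains, functionals)
  pooled <- do.call(cbind, mats)
  ess <- apply(pooled, 1, function(x) {
    if (stats::var(x) < .Machine$double.eps) return(NA_real_)  # constant chain
    .ess(x)
  })
  rhat <- if (length(chains) >= 2L) {
    vapply(rownames(mats[[1L]]), function(pn)
      .rhat(lapply(mats, function(m) m[pn, ])), 0)
  } else NULL
  list(ess = ess, rhat = rhat,
       acceptance = chains[[1L]]$meta$acceptance,
       constant_flag = any(is.na(ess)))
}
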