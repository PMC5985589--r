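# Posterior group-membership probabilities for a new subject: the
# marginal rule (random effects integrated out, Laplace layer), and the
# conditional and random-effects rules, which represent the subject by a
# random-effects value sampled per retained MCMC draw from its
# predictive distribution (data-augmentation style).  All rules average
# per-draw probabilities over the retained draws of every group's
# posterior sample — the posterior-mean estimator, not probabilities at
# averaged parameters.

#' Bundle fitted group posteriors with prior group probabilities
#'
#' @param samples list of `loda_posterior` objects, ordered by group
#'   label `0..G-1`.
#' @param pi prior (population prevalence) group probabilities; if
#'   `NULL`, training-set group frequencies are used with a warning.
#' @return an object of class `group_posteriors`.  Samples are
#'   truncated to a common number of retained draws `M`.
#' @export
group_posteriors <- function(samples, pi = NULL) {
  G <- length(samples)
  stopifnot(G >= 2L)
  if (is.null(pi)) {
    ns <- vapply(samples, function(s) s$meta$n_subjects, 0)
    pi <- ns / sum(ns)
    warning("prior group probabilities not supplied; using training-set ",
            "group frequencies (", paste(round(pi, 3), collapse = ", "), ")")
  }
  stopifnot(length(pi) == G, all(pi >= 0), abs(sum(pi) - 1) < 1e-8)
  M <- min(vapply(samples, function(s) s$meta$M, 0L))
  samples <- lapply(samples, function(s) {
    s$draws <- s$draws[seq_len(M)]
    s$meta$M <- M
    s
  })
  structure(list(samples = samples, pi = pi, G = G, M = M),
            class = "group_posteriors")
}

#' Group probabilities at one parameter draw
#'
#' Bayes' rule with the marginal (Laplace) density of the observed
#' history under each group's model:
#' \eqn{P_g = \pi_g f_g / \sum_{g'} \pi_{g'} f_{g'}}, computed in log
#' space.
#'
#' @param histories list of [evaluated_history()] objects, one per group
#'   (the same data evaluated under each group's design).
#' @param draws list of one `(psi, theta)` draw per group.
#' @param pi prior group probabilities.
#' @param starts optional per-group lists of Laplace warm starts.
#' @return probability vector over groups (sums to 1); attribute
#'   `"modes"` holds per-group Laplace modes for warm starting.
#' @export
group_probs_given_params <- function(histories, draws, pi, starts = NULL) {
  G <- length(histories)
  lf <- numeric(G)
  modes <- vector("list", G)
  for (g in seq_len(G)) {
    v <- marginal_log_density_laplace(
      histories[[g]], draws[[g]]$psi, draws[[g]]$theta,
      start = if (!is.null(starts)) starts[[g]] else NULL)
    modes[[g]] <- attr(v, "modes")
    lf[g] <- as.numeric(v)
  }
  lp <- log(pi) + lf
  if (all(!is.finite(lp))) stop("all group marginal densities are zero")
  p <- exp(lp - logsumexp(lp))
  p <- p / sum(p)
  attr(p, "modes") <- modes
  p
}

.new_prediction <- function(subject, t, method, probs, per_draw = NULL) {
  structure(list(subject_id = subject$subject_id, time = t,
                 method = method, probs = probs, per_draw = per_draw),
            class = "loda_prediction")
}

#' @export
print.loda_prediction <- function(x, ...) {
  cat("<loda_prediction> subject ", x$subject_id, " at t = ", x$time,
      " (", x$method, "): ",
      paste(sprintf("P%d=%.3f", seq_along(x$probs) - 1L, x$probs),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

.histories_per_group <- function(subject, posts, t) {
  lapply(posts$samples, function(s) evaluated_history(subject, s$spec, t))
}

#' Marginal prediction of group membership
#'
#' Averages, over the retained MCMC draws of all group models, the
#' Bayes-rule group probabilities based on the marginal density of the
#' history truncated at `t` (random effects integrated out by Laplace
#' approximation).  With an empty history every marginal density is 1
#' and the result is exactly the prior probabilities.
#'
#' @param subject a [subject_data()].
#' @param t prediction time in days; only history with visit times
#'   `<= t` is used.
#' @param posts a [group_posteriors()].
#' @param max_draws optionally thin to at most this many draws.
#' @param keep_draws retain the per-draw probability matrix.
#' @return a `loda_prediction`.
#' @export
predict_marginal <- function(subject, t, posts, max_draws = NULL,
                             keep_draws = FALSE) {
  hist_g <- .histories_per_group(subject, posts, t)
  idx <- .draw_index(posts$M, max_draws)
  P <- matrix(0, length(idx), posts$G)
  starts <- NULL
  for (j in seq_along(idx)) {
    m <- idx[j]
    p <- group_probs_given_params(
      hist_g, lapply(posts$samples, function(s) s$draws[[m]]),
      posts$pi, starts = starts)
    starts <- attr(p, "modes")
    P[j, ] <- as.numeric(p)
  }
  probs <- colMeans(P)
  probs <- probs / sum(probs)
  .new_prediction(subject, t, "marginal", probs,
                  if (keep_draws) P else NULL)
}

.draw_index <- function(M, max_draws) {
  if (is.null(max_draws) || max_draws >= M) seq_len(M)
  else unique(round(seq(1L, M, length.out = max_draws)))
}

# shared engine for the conditional and random-effects rules: per draw m
# and group g, advance a data-augmentation chain for b_new^{g} by one
# independence Metropolis-Hastings step under draw m's parameters, then
# form the per-draw numerators.
.predict_sampled <- function(subject, t, posts, method, max_draws,
                             seed, keep_draws) {
  hist_g <- .histories_per_group(subject, posts, t)
  idx <- .draw_index(posts$M, max_draws)
  G <- posts$G
  set.seed(.subseed(seed, subject$subject_id, method, t))
  b_cur <- vector("list", G)
  P <- matrix(0, length(idx), G)
  for (j in seq_along(idx)) {
    m <- idx[j]
    lnum <- numeric(G)
    for (g in seq_len(G)) {
      d <- posts$samples[[g]]$draws[[m]]
      prop <- .predictive_proposal(hist_g[[g]], d$psi, d$theta)
      if (is.null(b_cur[[g]])) b_cur[[g]] <- prop$map
      cand <- .mixture_proposal_draw(prop)
      lp_c <- .predictive_logpost(hist_g[[g]], cand, d$psi, d$theta)
      lp_b <- .predictive_logpost(hist_g[[g]], b_cur[[g]], d$psi, d$theta)
      lq_c <- .mixture_proposal_logdens(cand, prop)
      lq_b <- .mixture_proposal_logdens(b_cur[[g]], prop)
      if (log(stats::runif(1)) < (lp_c - lp_b) - (lq_c - lq_b))
        b_cur[[g]] <- cand
      lnum[g] <- log(posts$pi[g]) + if (method == "ranef")
        ranef_log_density(b_cur[[g]], d$theta)
      else
        conditional_log_density(hist_g[[g]], b_cur[[g]], d$psi)
    }
    if (all(!is.finite(lnum))) stop("all group densities are zero")
    p <- exp(lnum - logsumexp(lnum))
    P[j, ] <- p / sum(p)
  }
  probs <- colMeans(P)
  probs <- probs / sum(probs)
  .new_prediction(subject, t, method, probs, if (keep_draws) P else NULL)
}

#' Random-effects prediction of group membership
#'
#' Represents the subject, per retained draw and per group, by a
#' random-effects value sampled from its predictive distribution under
#' that group's parameters; group probabilities are then based on the
#' mixture random-effects density of those values.
#'
#' @inheritParams predict_marginal
#' @param seed integer; the sampling is seeded deterministically from
#'   `(seed, subject_id, method, t)`, so repeated calls are identical.
#' @return a `loda_prediction`.
#' @export
predict_ranef <- function(subject, t, posts, max_draws = NULL, seed = 1L,
                          keep_draws = FALSE) {
  .predict_sampled(subject, t, posts, "ranef", max_draws, seed, keep_draws)
}

#' Conditional prediction of group membership
#'
#' As [predict_ranef()], but the per-draw numerators use the conditional
#' density of the observed history given the sampled random-effects
#' value.  With an empty history the conditional density is 1 for every
#' group and the result is exactly the prior probabilities.
#'
#' @inheritParams predict_ranef
#' @return a `loda_prediction`.
#' @export
predict_conditional <- function(subject, t, posts, max_draws = NULL,
                                seed = 1L, keep_draws = FALSE) {
  .predict_sampled(subject, t, posts, "conditional", max_draws, seed,
                   keep_draws)
}

.predict_one <- function(subject, t, posts, method, max_draws, seed) {
  switch(method,
    marginal = predict_marginal(subject, t, posts, max_draws),
    conditional = predict_conditional(subject, t, posts, max_draws, seed),
    ranef = predict_ranef(subject, t, posts, max_draws, seed),
    stop("unknown method: ", method))
}

#' Dynamic prediction sequence over a subject's visits
#'
#' Evaluates the chosen prediction rule at each successive visit time
#' (the sorted union of the per-marker visit grids), each time using
#' only the history up to and including that visit.
#'
#' @inheritParams predict_marginal
#' @param method one of `"marginal"`, `"conditional"`, `"ranef"`.
#' @param times optional vector of prediction times; defaults to the
#'   union of the subject's marker visit times.
#' @param seed seed for the sampling-based rules.
#' @return list of `loda_prediction`, one per prediction time.
#' @export
predict_sequence <- function(subject, posts, method = "marginal",
                             times = NULL, max_draws = NULL, seed = 1L) {
  if (is.null(times)) {
    times <- sort(unique(unlist(lapply(subject$markers, `[[`, "times"))))
    if (!length(times)) stop("subject has no visits")
  }
  lapply(times, function(t)
    .predict_one(subject, t, posts, method, max_draws, seed))
}
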