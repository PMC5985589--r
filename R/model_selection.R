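# Mixture-order selection: deviance-based criteria on the
# subject-marginal likelihood (random effects integrated out), plus
# cross-validated predictive accuracy via the CV harness.

# per-subject, per-draw deviance matrix: d[i, m] = -2 log f_marg(y_i)
# under draw m; Laplace layer with warm-started modes across draws
.deviance_matrix <- function(sample, data_g, spec, max_draws = NULL) {
  subjects <- if (inherits(data_g, "loda_dataset"))
    .group_subjects(data_g, spec$group) else data_g
  idx <- .draw_index(sample$meta$M, max_draws)
  n <- length(subjects)
  D <- matrix(0, n, length(idx))
  for (i in seq_len(n)) {
    h <- evaluated_history(subjects[[i]], spec)
    start <- NULL
    for (j in seq_along(idx)) {
      d <- sample$draws[[idx[j]]]
      v <- marginal_log_density_laplace(h, d$psi, d$theta, start = start)
      start <- attr(v, "modes")
      D[i, j] <- -2 * as.numeric(v)
    }
  }
  rownames(D) <- vapply(subjects, `[[`, "", "subject_id")
  D
}

#' Posterior expected deviance of a fitted group model
#'
#' Mean over retained draws of \eqn{-2 \sum_i \log f^{marg}(y_i)}, the
#' subject-marginal likelihood with random effects integrated out
#' (Laplace layer); invariant to mixture relabeling because only the
#' mixture density enters.
#'
#' @param sample a `loda_posterior`.
#' @param data_g the group's data (dataset or subject list).
#' @param spec the group's [group_model_spec()].
#' @param max_draws optionally thin the draws used.
#' @return scalar expected deviance, with attribute `"matrix"` (the
#'   per-subject per-draw deviance matrix).
#' @export
expected_deviance <- function(sample, data_g, spec, max_draws = NULL) {
  D <- .deviance_matrix(sample, data_g, spec, max_draws)
  out <- mean(colSums(D))
  attr(out, "matrix") <- D
  out
}

#' Penalized expected deviance for mixture-order comparison
#'
#' `method = "dic"` uses one chain: penalty `2 * (Dbar - Dhat)` with the
#' plug-in deviance taken at the retained draw minimizing the total
#' deviance (a mixture-invariant plug-in).  `method = "ped_pair"` uses
#' two independent chains: the per-subject plug-in for each chain is
#' evaluated at the *other* chain's best draw, removing the within-chain
#' optimism of the plug-in; the two directions are summed.  This is a
#' deliberately simple cross-chain approximation to the
#' importance-sampling optimism estimator; lower penalized values mean
#' a better expected out-of-sample deviance.
#'
#' @param samples for `"ped_pair"` a list of two `loda_posterior` chains
#'   of equal length (or one sample fitted with `n_chains = 2`); for
#'   `"dic"` a single sample.
#' @inheritParams expected_deviance
#' @param method `"ped_pair"` or `"dic"`.
#' @return list (one `DevianceReport` row): `K`, `expected_deviance`,
#'   `penalty`, `penalized`, `method`, `penalty_negative` flag.
#' @export
penalized_deviance <- function(samples, data_g, spec,
                               method = c("ped_pair", "dic"),
                               max_draws = NULL) {
  method <- match.arg(method)
  if (inherits(samples, "loda_posterior"))
    samples <- if (!is.null(samples$chains)) samples$chains else
      list(samples)
  if (method == "ped_pair") {
    if (length(samples) < 2L)
      stop("ped_pair needs two independent chains")
    if (samples[[1L]]$meta$M != samples[[2L]]$meta$M)
      stop("chains must have equal numbers of retained draws")
    DA <- .deviance_matrix(samples[[1L]], data_g, spec, max_draws)
    DB <- .deviance_matrix(samples[[2L]], data_g, spec, max_draws)
    dbar <- (mean(colSums(DA)) + mean(colSums(DB))) / 2
    bestA <- which.min(colSums(DA))
    bestB <- which.min(colSums(DB))
    # cross-chain plug-ins: chain A's mean deviance against chain B's
    # best draw and vice versa
    pen <- sum(rowMeans(DA) - DB[, bestB]) +
      sum(rowMeans(DB) - DA[, bestA])
  } else {
    DA <- do.call(cbind, lapply(samples, .deviance_matrix,
                                data_g = data_g, spec = spec,
                                max_draws = max_draws))
    dbar <- mean(colSums(DA))
    best <- which.min(colSums(DA))
    pen <- 2 * (dbar - sum(DA[, best]))
  }
  list(K = spec$K, expected_deviance = dbar, penalty = pen,
       penalized = dbar + pen, method = method,
       penalty_negative = pen < 0)
}

#' Choose the mixture order per group
#'
#' Fits each candidate `K` per group (two chains, so the paired-chain
#' penalized deviance is available), reports the deviance criteria and,
#' optionally, cross-validated predictive accuracy of each candidate.
#' Selection prefers predictive accuracy (AUC of the dynamic scheme)
#' when computed, with penalized deviance as tiebreak; otherwise the
#' smallest penalized deviance wins.  Groups may choose different `K`.
#'
#' @param dataset labelled `loda_dataset`.
#' @param specs_by_K list over candidate K values; each element a list
#'   of per-group [group_model_spec()] sharing that `K` (per-group
#'   candidate sets may be emulated by repeated calls).
#' @param settings list: `mcmc` (fit settings), `deviance_method`
#'   (`"ped_pair"` default), `max_draws`, `cv` (logical, default FALSE:
#'   also run [cross_validate()] per candidate), `cv_settings`, `seed`.
#' @return list: `chosen` (named per-group K), `report` (data frame,
#'   one row per candidate per group), `cv` (per-candidate CV averages
#'   or NULL).
#' @export
choose_K <- function(dataset, specs_by_K, settings = list()) {
  cfg <- utils::modifyList(
    list(mcmc = list(n_iter = 1200L, burn_in = 400L, thin = 4L),
         deviance_method = "ped_pair", max_draws = 60L,
         cv = FALSE, cv_settings = list(), seed = 1L), settings)
  stopifnot(length(specs_by_K) >= 1L)
  G <- length(specs_by_K[[1L]])
  rows <- list()
  cv_res <- if (cfg$cv) list() else NULL
  for (ci in seq_along(specs_by_K)) {
    specs <- specs_by_K[[ci]]
    for (gi in seq_len(G)) {
      spec <- specs[[gi]]
      mc <- cfg$mcmc
      mc$seed <- .subseed(cfg$seed, "chooseK", ci, gi)
      mc$n_chains <- if (cfg$deviance_method == "ped_pair") 2L else 1L
      fit <- fit_group_model(dataset, spec, mc)
      pd <- penalized_deviance(fit, dataset, spec,
                               method = cfg$deviance_method,
                               max_draws = cfg$max_draws)
      rows[[length(rows) + 1L]] <- data.frame(
        candidate = ci, group = spec$group, K = spec$K,
        expected_deviance = pd$expected_deviance, penalty = pd$penalty,
        penalized = pd$penalized, method = pd$method,
        penalty_negative = pd$penalty_negative)
    }
    if (cfg$cv) {
      cvs <- cfg$cv_settings
      cvs$seed <- .subseed(cfg$seed, "chooseKcv", ci)
      cv <- cross_validate(dataset, specs, cvs)
      cv_res[[ci]] <- cv$average
    }
  }
  report <- do.call(rbind, rows)
  chosen <- integer(G)
  names(chosen) <- paste0("group", vapply(specs_by_K[[1L]],
                                          `[[`, 0L, "group"))
  for (gi in seq_len(G)) {
    g <- specs_by_K[[1L]][[gi]]$group
    sub <- report[report$group == g, ]
    if (cfg$cv) {
      aucs <- vapply(cv_res, function(a) a$auc, 0)
      best <- which(aucs == max(aucs))
      if (length(best) > 1L)    # tiebreak on penalized deviance
        best <- best[which.min(sub$penalized[best])]
      chosen[gi] <- sub$K[best]
    } else {
      chosen[gi] <- sub$K[which.min(sub$penalized)]
    }
  }
  list(chosen = chosen, report = report, cv = cv_res)
}
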