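# Simulator producing datasets with exactly the statistical structure
# the discriminant model assumes: per group, a latent random-effects
# vector drawn from a finite normal mixture, irregular per-subject visit
# schedules with per-marker thinning, and exponential-family marker
# values around the linear predictor of the group's MGLMM.

#' Define a simulation scenario
#'
#' @param group_specs list of [group_model_spec()], one per group.
#' @param true_params list, one element per group, each a list with
#'   `psi` (fixed effects `alpha` and dispersions `phi` per marker) and
#'   `theta` (mixture `w`, `mu`, `D`).
#' @param prevalences group prevalence vector \eqn{\pi} (positive, sums
#'   to 1).
#' @param n_subjects number of subjects to simulate.
#' @param visit_model list: `mean_gap` (mean inter-visit gap, days),
#'   `gap_sd` (gap jitter), `max_follow_up` (per-group follow-up cap in
#'   days, recycled), `obs_prob` (named per-marker probability that a
#'   marker is observed at a visit), `min_visits` (minimum visits per
#'   subject, default 2).
#' @param seed integer seed.
#' @param baseline_sampler optional `function()` returning a named list
#'   of baseline covariates for one subject.
#' @return an object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(group_specs, true_params, prevalences,
                                n_subjects, visit_model, seed = 1L,
                                baseline_sampler = NULL) {
  stopifnot(length(group_specs) == length(true_params),
            length(prevalences) == length(group_specs),
            all(prevalences > 0), abs(sum(prevalences) - 1) < 1e-8,
            n_subjects >= 1)
  vm <- utils::modifyList(
    list(mean_gap = 330, gap_sd = 80, max_follow_up = 1825,
         obs_prob = 1, min_visits = 2L), visit_model)
  stopifnot(all(vm$max_follow_up > 0))
  structure(list(group_specs = group_specs, true_params = true_params,
                 prevalences = prevalences, n_subjects = n_subjects,
                 visit_model = vm, seed = as.integer(seed),
                 baseline_sampler = baseline_sampler),
            class = "simulation_scenario")
}

# visit schedule: first gap and subsequent gaps i.i.d. gamma around the
# configured mean, truncated below at 30 days; at least min_visits
.draw_visits <- function(vm, cap) {
  shape <- (vm$mean_gap / vm$gap_sd)^2
  rate <- vm$mean_gap / vm$gap_sd^2
  for (attempt in 1:50) {
    gaps <- pmax(30, stats::rgamma(ceiling(cap / vm$mean_gap) + 10,
                                   shape = shape, rate = rate))
    tt <- cumsum(gaps)
    tt <- tt[tt <= cap]
    if (length(tt) >= vm$min_visits) return(tt)
  }
  # degenerate configuration: fall back to an equally spaced grid
  seq(cap / (vm$min_visits + 1), cap, length.out = vm$min_visits)
}

#' Simulate one subject from a scenario
#'
#' Draws a mixture component and a random-effects vector from the
#' group's mixture, a visit schedule, thins it per marker, and draws
#' marker values from the family with mean
#' \eqn{h_r(x'\alpha_r + z' b_r)}.  The latent component and random
#' effects are retained in the `"latent"` attribute for recovery tests.
#'
#' @param group integer group label.
#' @param scenario a [simulation_scenario()].
#' @param seed optional integer seed (per-subject stream).
#' @param subject_id identifier for the returned record.
#' @return a [subject_data()] object with attributes `"latent"` (list
#'   `component`, `b`) and `"follow_up"` (the cap used).
#' @export
simulate_subject <- function(group, scenario, seed = NULL,
                             subject_id = "s1") {
  if (!is.null(seed)) set.seed(seed)
  gi <- group + 1L
  spec <- scenario$group_specs[[gi]]
  tp <- scenario$true_params[[gi]]
  lay <- .ranef_layout(spec)
  K <- length(tp$theta$w)
  for (k in seq_len(K)) .chol_pd(tp$theta$D[[k]])   # validate PD up front
  comp <- sample.int(K, 1L, prob = tp$theta$w)
  b <- drop(.rmvn(1L, tp$theta$mu[[comp]], tp$theta$D[[comp]]))

  vm <- scenario$visit_model
  cap <- rep(vm$max_follow_up, length.out = length(scenario$group_specs))[gi]
  visits <- .draw_visits(vm, cap)
  baseline <- if (!is.null(scenario$baseline_sampler))
    scenario$baseline_sampler() else list()

  obs_prob <- vm$obs_prob
  if (length(obs_prob) == 1L && is.null(names(obs_prob)))
    obs_prob <- stats::setNames(rep(obs_prob, length(spec$markers)),
                                names(spec$markers))
  markers <- list()
  for (mspec in spec$markers) {
    keep <- stats::runif(length(visits)) <= obs_prob[[mspec$name]]
    if (!any(keep)) keep[sample.int(length(visits), 1L)] <- TRUE
    tt <- visits[keep]
    markers[[mspec$name]] <- list(times = tt,
                                  values = rep(NA_real_, length(tt)),
                                  covariates = NULL)
  }
  subj <- subject_data(subject_id, group = group, markers = markers,
                       baseline = baseline)
  design <- build_design_rows(subj, spec)
  for (mspec in spec$markers) {
    nm <- mspec$name
    eta <- drop(design[[nm]]$X %*% tp$psi$alpha[[nm]]) +
      drop(design[[nm]]$Z %*% b[lay$offsets[[nm]] + seq_len(lay$q_r[[nm]])])
    subj$markers[[nm]]$values <- switch(mspec$family,
      gaussian  = stats::rnorm(length(eta), eta, sqrt(tp$psi$phi[[nm]])),
      bernoulli = stats::rbinom(length(eta), 1L, stats::plogis(eta)),
      poisson   = stats::rpois(length(eta), exp(eta)))
  }
  attr(subj, "latent") <- list(component = comp, b = b)
  attr(subj, "follow_up") <- cap
  subj
}

#' Simulate a full labelled dataset
#'
#' Group labels are i.i.d. categorical with the scenario prevalences;
#' subjects are independent.  One global seed is split deterministically
#' into per-subject streams, so the result is reproducible and does not
#' depend on subject order.
#'
#' @param scenario a [simulation_scenario()].
#' @return a `loda_dataset` with attribute `"latents"`: per subject a
#'   list with `group`, `component`, `b`, `follow_up`.
#' @export
simulate_dataset <- function(scenario) {
  set.seed(scenario$seed)
  n <- scenario$n_subjects
  G <- length(scenario$prevalences)
  groups <- sample.int(G, n, replace = TRUE,
                       prob = scenario$prevalences) - 1L
  sub_seeds <- vapply(seq_len(n), function(i)
    .subseed(scenario$seed, "subject", i), 1L)
  subjects <- vector("list", n)
  latents <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("S%04d", i)
    s <- simulate_subject(groups[i], scenario, seed = sub_seeds[i],
                          subject_id = id)
    subjects[[i]] <- s
    latents[[i]] <- c(list(group = groups[i]), attr(s, "latent"),
                      list(follow_up = attr(s, "follow_up")))
  }
  ids <- vapply(subjects, `[[`, "", "subject_id")
  names(subjects) <- ids
  names(latents) <- ids
  structure(list(subjects = subjects,
                 covariates = character()),
            class = "loda_dataset",
            latents = latents)
}

#' Flatten a dataset to the long/subject CSV tables
#'
#' Inverse of [load_dataset()] (up to value transforms, which are
#' assumed already applied): returns the long observation table and the
#' subject table as data frames suitable for `write.csv`.
#'
#' @param dataset a `loda_dataset`.
#' @return list with data frames `long` and `subjects`.
#' @export
dataset_to_tables <- function(dataset) {
  rows <- list()
  for (s in dataset$subjects) {
    for (nm in names(s$markers)) {
      m <- s$markers[[nm]]
      if (!length(m$times)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$subject_id, marker = nm,
        time = m$times, value = m$values)
    }
  }
  long <- do.call(rbind, rows)
  base_names <- unique(unlist(lapply(dataset$subjects,
                                     function(s) names(s$baseline))))
  subjects <- do.call(rbind, lapply(dataset$subjects, function(s) {
    row <- data.frame(subject_id = s$subject_id, group = s$group)
    for (bn in base_names) row[[bn]] <- s$baseline[[bn]]
    row
  }))
  rownames(subjects) <- NULL
  list(long = long, subjects = subjects)
}

#' Packaged default scenario mirroring the motivating epilepsy study
#'
#' Two prognostic groups with prevalences (0.9, 0.1) — remission-like
#' (group 0) and refractory-like (group 1) — and three markers observed
#' at roughly annual, jittered visits over at most five years: a binary
#' seizure indicator (bernoulli-logit), a continuous log-scale seizure
#' count (gaussian) and an adverse-event count (poisson-log).  The three
#' random intercepts are correlated; in group 0 they follow a
#' two-component mixture (a low-seizure and a moderate-seizure
#' subpopulation), in group 1 a single elevated component.  The
#' time-since-diagnosis slopes of both seizure markers switch sign
#' between groups: seizure activity decays in the remission-like group
#' and grows in the refractory-like group.  Both groups share the
#' five-year follow-up cap; group-dependent caps (emulating the shorter
#' observation of subjects whose status is confirmed early) can be set
#' through `visit_model$max_follow_up`.
#'
#' @param n_subjects total number of subjects.
#' @param seed integer seed.
#' @return a [simulation_scenario()].
#' @export
sanad_like_scenario <- function(n_subjects = 300L, seed = 1L) {
  mk <- function() list(
    marker_spec("seizure", "bernoulli", fixed = "time_since_diagnosis"),
    marker_spec("logseiz", "gaussian", fixed = "time_since_diagnosis"),
    marker_spec("adverse", "poisson", fixed = "time_since_diagnosis"))
  specs <- list(
    group_model_spec(0L, mk(), K = 2L),
    group_model_spec(1L, mk(), K = 1L))
  corr <- function(sd, rho = 0.4) {
    C <- diag(3) * (1 - rho) + rho
    diag(sd) %*% C %*% diag(sd)
  }
  true_params <- list(
    list(psi = list(alpha = list(seizure = -0.0012,
                                 logseiz = -0.0008,
                                 adverse = -0.0003),
                    phi = c(seizure = 1, logseiz = 0.25, adverse = 1)),
         theta = list(w = c(0.6, 0.4),
                      mu = list(c(-1.5, 0.2, -0.2), c(0.6, 1.4, 0.3)),
                      D = list(corr(c(0.6, 0.5, 0.4)),
                               corr(c(0.6, 0.5, 0.4))))),
    list(psi = list(alpha = list(seizure = 0.0010,
                                 logseiz = 0.0006,
                                 adverse = -0.0003),
                    phi = c(seizure = 1, logseiz = 0.25, adverse = 1)),
         theta = list(w = 1,
                      mu = list(c(1.25, 2.9, 0.35)),
                      D = list(corr(c(0.7, 0.6, 0.5))))))
  simulation_scenario(
    group_specs = specs, true_params = true_params,
    prevalences = c(0.9, 0.1), n_subjects = n_subjects,
    visit_model = list(mean_gap = 330, gap_sd = 80,
                       max_follow_up = 1825,
                       obs_prob = c(seizure = 0.95, logseiz = 0.95,
                                    adverse = 0.9),
                       min_visits = 2L),
    seed = seed)
}
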