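# Visit-by-visit allocation: a subject is assigned to the target group
# at the first visit where the target-group probability strictly
# exceeds the cutoff; a subject never allocated by the last visit
# before their status-confirmation time is assigned to the other group
# at that final visit.  Exactly one decision is taken per subject, so
# classical ROC machinery applies to the scheme's decision scores.

#' Status-confirmation times from known group labels
#'
#' The time at which group membership becomes clinically known: the
#' horizon (e.g. five years) for target-group subjects, whose status is
#' only confirmed by the horizon passing, and the final visit time for
#' the others, whose status is confirmed at that visit.
#'
#' @param dataset a `loda_dataset` with labelled subjects.
#' @param target_group the group confirmed only at the horizon.
#' @param horizon confirmation horizon in days (default 1825, five
#'   years).
#' @return named numeric vector of confirmation times.
#' @export
confirmation_from_truth <- function(dataset, target_group = 1L,
                                    horizon = 1825) {
  vapply(dataset$subjects, function(s) {
    if (!is.na(s$group) && s$group == target_group) return(horizon)
    tmax <- max(unlist(lapply(s$markers, `[[`, "times")), 0)
    max(tmax, 1)
  }, 0)
}

# core allocation rule on a precomputed probability trajectory
.allocate_trajectory <- function(times, ptarget, cutoff, target_group,
                                 other_group) {
  hit <- which(ptarget > cutoff)
  if (length(hit)) {
    list(predicted = target_group, decision_time = times[hit[1L]],
         stopped_early = hit[1L] < length(times))
  } else {
    list(predicted = other_group, decision_time = times[length(times)],
         stopped_early = FALSE)
  }
}

#' Dynamic allocation of one subject
#'
#' Scans the subject's visits in time order (those strictly before the
#' confirmation time); at the first visit where the target-group
#' probability strictly exceeds `cutoff` the subject is allocated to
#' the target group and prediction stops.  Otherwise the subject is
#' allocated to the other group at the final considered visit.  Ties
#' with the cutoff never allocate (strict inequality).
#'
#' @param subject a [subject_data()].
#' @param posts a [group_posteriors()].
#' @param target_group group to detect (default 1).
#' @param cutoff allocation cutoff in (0, 1).
#' @param method prediction rule, see [predict_sequence()].
#' @param confirmation named vector of confirmation times (days), see
#'   [confirmation_from_truth()].
#' @param max_draws,seed passed to the prediction rule.
#' @return an object of class `loda_allocation`: `subject_id`,
#'   `predicted`, `decision_time`, `times`, `probs` (target-group
#'   trajectory), `score` (maximum probability reached), `cutoff`.
#' @export
dynamic_allocate <- function(subject, posts, target_group = 1L, cutoff,
                             method = "marginal", confirmation,
                             max_draws = NULL, seed = 1L) {
  stopifnot(cutoff > 0, cutoff < 1)
  conf_t <- confirmation[[subject$subject_id]]
  if (is.null(conf_t) || is.na(conf_t))
    stop("no confirmation time for subject ", subject$subject_id)
  times <- sort(unique(unlist(lapply(subject$markers, `[[`, "times"))))
  times <- times[times < conf_t]
  if (!length(times))
    stop("subject ", subject$subject_id,
         " has no visits before confirmation")
  preds <- predict_sequence(subject, posts, method = method, times = times,
                            max_draws = max_draws, seed = seed)
  ptarget <- vapply(preds, function(p) p$probs[target_group + 1L], 0)
  other <- if (posts$G == 2L) 1L - target_group else
    which.max(preds[[length(preds)]]$probs[-(target_group + 1L)]) - 1L
  a <- .allocate_trajectory(times, ptarget, cutoff, target_group, other)
  structure(list(subject_id = subject$subject_id, predicted = a$predicted,
                 decision_time = a$decision_time, times = times,
                 probs = ptarget, score = max(ptarget), cutoff = cutoff),
            class = "loda_allocation")
}

# empirical ROC over candidate thresholds (midpoints of sorted unique
# scores, plus infinite endpoints for the curve itself)
.roc_curve <- function(scores, labels) {
  u <- sort(unique(scores))
  mids <- if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2 else numeric()
  ths <- c(Inf, rev(mids), -Inf)
  pos <- labels
  sens <- vapply(ths, function(c0) mean(scores[pos] > c0), 0)
  spec <- vapply(ths, function(c0) mean(scores[!pos] <= c0), 0)
  data.frame(threshold = ths, sens = sens, spec = spec)
}

.auc_trapezoid <- function(roc) {
  fpr <- 1 - roc$spec
  tpr <- roc$sens
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
}

#' Select an allocation cutoff from the ROC of decision scores
#'
#' @param scores per-subject decision scores (the maximum target-group
#'   probability reached over the considered visits).
#' @param truths logical (or 0/1) vector: subject truly in the target
#'   group.
#' @param rule `"topleft"` (minimize squared distance to the perfect
#'   corner), `"youden"` (maximize sens + spec - 1), `"fixed_sens"` or
#'   `"fixed_spec"` (most specific/sensitive cutoff achieving at least
#'   `fixed_value` of the fixed quantity).
#' @param fixed_value target value for the `fixed_*` rules.
#' @return list with `cutoff`, `roc` (data frame threshold/sens/spec),
#'   `auc`.
#' @export
select_cutoff <- function(scores, truths,
                          rule = c("topleft", "youden", "fixed_sens",
                                   "fixed_spec"),
                          fixed_value = 0.9) {
  rule <- match.arg(rule)
  truths <- as.logical(truths)
  if (length(unique(truths)) < 2L)
    stop("both classes must be present to build a ROC curve")
  roc <- .roc_curve(scores, truths)
  auc <- .auc_trapezoid(roc)
  cand <- which(is.finite(roc$threshold))
  if (!length(cand)) {            # single unique score: degenerate ROC
    return(list(cutoff = unique(scores)[1L], roc = roc, auc = auc))
  }
  pick <- switch(rule,
    topleft = cand[which.min((1 - roc$sens[cand])^2 +
                               (1 - roc$spec[cand])^2)],
    youden = cand[which.max(roc$sens[cand] + roc$spec[cand] - 1)],
    fixed_sens = {
      ok <- cand[roc$sens[cand] >= fixed_value]
      if (!length(ok)) cand[which.max(roc$sens[cand])]
      else ok[which.max(roc$spec[ok])]
    },
    fixed_spec = {
      ok <- cand[roc$spec[cand] >= fixed_value]
      if (!length(ok)) cand[which.max(roc$spec[cand])]
      else ok[which.max(roc$sens[ok])]
    })
  list(cutoff = roc$threshold[pick], roc = roc, auc = auc)
}

#' Classification accuracy of a set of allocations
#'
#' @param allocs list of `loda_allocation` objects.
#' @param truths vector of true group labels aligned with `allocs` (or
#'   named by subject id).
#' @param target_group the positive class.
#' @return an object of class `loda_metrics`: sensitivity, specificity,
#'   PPV, NPV, PCC, AUC (from the per-subject maximum-probability
#'   decision scores), confusion counts, cutoff.  Metrics with a zero
#'   denominator are `NA`.
#' @export
evaluate_classification <- function(allocs, truths, target_group = 1L) {
  ids <- vapply(allocs, `[[`, "", "subject_id")
  if (!is.null(names(truths))) truths <- truths[ids]
  pred <- vapply(allocs, `[[`, 0L, "predicted")
  scores <- vapply(allocs, `[[`, 0, "score")
  pos <- truths == target_group
  ppos <- pred == target_group
  tp <- sum(pos & ppos); fn <- sum(pos & !ppos)
  tn <- sum(!pos & !ppos); fp <- sum(!pos & ppos)
  safe <- function(a, b) if (b > 0) a / b else NA_real_
  auc <- if (length(unique(pos)) == 2L)
    .auc_trapezoid(.roc_curve(scores, pos)) else NA_real_
  structure(list(
    sensitivity = safe(tp, tp + fn), specificity = safe(tn, tn + fp),
    ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn),
    pcc = safe(tp + tn, tp + tn + fp + fn), auc = auc,
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    cutoff = allocs[[1L]]$cutoff), class = "loda_metrics")
}

#' @export
print.loda_metrics <- function(x, ...) {
  cat(sprintf(
    "<loda_metrics> sens %.3f spec %.3f ppv %.3f npv %.3f pcc %.3f auc %.3f (cutoff %.3f)\n",
    x$sensitivity, x$specificity, x$ppv, x$npv, x$pcc, x$auc, x$cutoff))
  invisible(x)
}

#' Lead and prediction times of true-positive allocations
#'
#' Over the subjects truly in the target group *and* allocated to it:
#' lead time is confirmation time minus decision time (how much earlier
#' than clinical confirmation the scheme decided); prediction time is
#' the decision time itself (days since diagnosis).
#'
#' @inheritParams evaluate_classification
#' @param confirmation named vector of confirmation times.
#' @return list with `mean_lead`, `mean_prediction`, `n_tp`; means are
#'   `NA` when there is no true positive.
#' @export
lead_times <- function(allocs, truths, confirmation, target_group = 1L) {
  ids <- vapply(allocs, `[[`, "", "subject_id")
  if (!is.null(names(truths))) truths <- truths[ids]
  pred <- vapply(allocs, `[[`, 0L, "predicted")
  dec <- vapply(allocs, `[[`, 0, "decision_time")
  conf <- confirmation[ids]
  tp <- truths == target_group & pred == target_group
  if (!any(tp))
    return(list(mean_lead = NA_real_, mean_prediction = NA_real_, n_tp = 0L))
  list(mean_lead = mean(conf[tp] - dec[tp]),
       mean_prediction = mean(dec[tp]), n_tp = sum(tp))
}

# stratified train/test split of subject ids by group
.stratified_split <- function(dataset, train_frac) {
  groups <- vapply(dataset$subjects, `[[`, 1L, "group")
  train <- character()
  for (g in unique(groups)) {
    ids <- names(groups)[groups == g]
    n_tr <- max(1L, round(train_frac * length(ids)))
    if (n_tr >= length(ids)) n_tr <- length(ids) - 1L
    train <- c(train, sample(ids, n_tr))
  }
  list(train = train, test = setdiff(names(groups), train))
}

# trajectories (times + target-group probabilities) for a set of
# subjects; the shared expensive step of the CV harness
.trajectories <- function(ids, dataset, posts, method, confirmation,
                          target_group, max_draws, seed) {
  lapply(ids, function(sid) {
    s <- dataset$subjects[[sid]]
    times <- sort(unique(unlist(lapply(s$markers, `[[`, "times"))))
    times <- times[times < confirmation[[sid]]]
    if (!length(times)) return(NULL)
    preds <- predict_sequence(s, posts, method = method, times = times,
                              max_draws = max_draws, seed = seed)
    list(subject_id = sid, truth = s$group, times = times,
         probs = vapply(preds, function(p) p$probs[target_group + 1L], 0))
  })
}

.allocs_from_trajectories <- function(trajs, cutoff, target_group, G) {
  other <- if (G == 2L) 1L - target_group else 0L
  lapply(trajs, function(tr) {
    a <- .allocate_trajectory(tr$times, tr$probs, cutoff, target_group,
                              other)
    structure(list(subject_id = tr$subject_id, predicted = a$predicted,
                   decision_time = a$decision_time, times = tr$times,
                   probs = tr$probs, score = max(tr$probs),
                   cutoff = cutoff), class = "loda_allocation")
  })
}

#' Cross-validated evaluation of the dynamic allocation scheme
#'
#' Repeated stratified train/test splits: the group models are fitted
#' on the training portion, the cutoff is selected from the ROC of
#' training-subject decision scores (no test leakage; set
#' `cutoff_select = "test"` to reproduce pooled selection), the dynamic
#' scheme is run on the test subjects, and per-split metrics are
#' averaged by unweighted arithmetic mean.
#'
#' @param dataset labelled `loda_dataset`.
#' @param specs list of [group_model_spec()], one per group.
#' @param settings list overriding any of: `n_splits` (default 5),
#'   `train_frac` (0.7), `seed`, `mcmc` (settings for
#'   [fit_group_model()]), `pi` (prior group probabilities; default the
#'   dataset's group frequencies), `target_group` (1), `horizon` (1825),
#'   `max_draws` (50, prediction-stage thinning), `cutoff_select`
#'   (`"train"` or `"test"`), `cutoff_train_max` (cap on training
#'   subjects scored for cutoff selection, default 60),
#'   `keep_trajectories` (FALSE).
#' @param method prediction rule.
#' @param cutoff_rule passed to [select_cutoff()].
#' @return an object of class `loda_cv`: `average` (mean metrics),
#'   `per_split` data frame, optional `trajectories`, `meta`.
#' @export
cross_validate <- function(dataset, specs, settings = list(),
                           method = "marginal", cutoff_rule = "topleft") {
  cfg <- utils::modifyList(
    list(n_splits = 5L, train_frac = 0.7, seed = 1L,
         mcmc = list(n_iter = 1200L, burn_in = 400L, thin = 4L),
         pi = NULL, target_group = 1L, horizon = 1825,
         max_draws = 50L, cutoff_select = "train",
         cutoff_train_max = 60L, keep_trajectories = FALSE),
    settings)
  groups <- vapply(dataset$subjects, `[[`, 1L, "group")
  if (any(is.na(groups))) stop("all subjects must be labelled")
  if (min(table(groups)) < 2L) stop("each group needs at least 2 subjects")
  pi <- cfg$pi
  if (is.null(pi)) {
    tb <- table(factor(groups, levels = sort(unique(groups))))
    pi <- as.numeric(tb) / sum(tb)
  }
  confirmation <- confirmation_from_truth(dataset, cfg$target_group,
                                          cfg$horizon)
  truths <- groups
  per_split <- list()
  traj_keep <- list()
  for (s in seq_len(cfg$n_splits)) {
    set.seed(.subseed(cfg$seed, "split", s))
    sp <- .stratified_split(dataset, cfg$train_frac)
    train_ds <- structure(list(subjects = dataset$subjects[sp$train],
                               covariates = dataset$covariates),
                          class = "loda_dataset")
    samples <- lapply(seq_along(specs), function(gi) {
      mc <- cfg$mcmc
      mc$seed <- .subseed(cfg$seed, "fit", s, gi)
      fit_group_model(train_ds, specs[[gi]], mc)
    })
    posts <- group_posteriors(samples, pi)

    score_ids <- sp$train
    set.seed(.subseed(cfg$seed, "cutoffsub", s))
    if (cfg$cutoff_select == "train" &&
        length(score_ids) > cfg$cutoff_train_max) {
      g_tr <- groups[score_ids]
      keep <- unlist(lapply(unique(g_tr), function(g) {
        ids <- score_ids[g_tr == g]
        n_keep <- max(2L, round(cfg$cutoff_train_max * length(ids) /
                                  length(score_ids)))
        sample(ids, min(length(ids), n_keep))
      }))
      score_ids <- keep
    }
    test_trajs <- Filter(Negate(is.null), .trajectories(
      sp$test, dataset, posts, method, confirmation, cfg$target_group,
      cfg$max_draws, .subseed(cfg$seed, "predtest", s)))
    if (cfg$cutoff_select == "train") {
      train_trajs <- Filter(Negate(is.null), .trajectories(
        score_ids, dataset, posts, method, confirmation, cfg$target_group,
        cfg$max_draws, .subseed(cfg$seed, "predtrain", s)))
      sc <- vapply(train_trajs, function(tr) max(tr$probs), 0)
      tr_truth <- vapply(train_trajs, `[[`, 0L, "truth") == cfg$target_group
    } else {
      sc <- vapply(test_trajs, function(tr) max(tr$probs), 0)
      tr_truth <- vapply(test_trajs, `[[`, 0L, "truth") == cfg$target_group
    }
    cut <- select_cutoff(sc, tr_truth, rule = cutoff_rule)
    allocs <- .allocs_from_trajectories(test_trajs, cut$cutoff,
                                        cfg$target_group, posts$G)
    met <- evaluate_classification(allocs, truths, cfg$target_group)
    lt <- lead_times(allocs, truths, confirmation, cfg$target_group)
    per_split[[s]] <- data.frame(
      split = s, cutoff = cut$cutoff, sensitivity = met$sensitivity,
      specificity = met$specificity, ppv = met$ppv, npv = met$npv,
      pcc = met$pcc, auc = met$auc, mean_lead = lt$mean_lead,
      mean_prediction = lt$mean_prediction, n_tp = lt$n_tp)
    if (cfg$keep_trajectories)
      traj_keep[[s]] <- list(trajectories = test_trajs,
                             cutoff = cut$cutoff)
  }
  tab <- do.call(rbind, per_split)
  avg <- colMeans(tab[, -1L], na.rm = TRUE)
  structure(list(average = as.list(avg), per_split = tab,
                 trajectories = if (cfg$keep_trajectories) traj_keep,
                 meta = list(method = method, cutoff_rule = cutoff_rule,
                             settings = cfg, pi = pi,
                             score = "max target-group probability over considered visits")),
            class = "loda_cv")
}

#' @export
print.loda_cv <- function(x, ...) {
  cat("<loda_cv> ", nrow(x$per_split), " splits, method ", x$meta$method,
      "\n", sep = "")
  a <- x$average
  cat(sprintf("  mean: sens %.3f spec %.3f pcc %.3f auc %.3f lead %.0f days\n",
              a$sensitivity, a$specificity, a$pcc, a$auc, a$mean_lead))
  invisible(x)
}

#' Dynamic versus full-data classification
#'
#' Runs the cross-validation harness once and evaluates, on the same
#' fitted models and probability trajectories, both the dynamic scheme
#' (first strict cutoff exceedance) and a full-data scheme that uses
#' only the probability at the last visit before confirmation (no early
#' stopping).  Full-data decision times are always the final visit, so
#' dynamic lead times are at least as large subject by subject.
#'
#' @inheritParams cross_validate
#' @return list with `dynamic` and `full` averaged metric lists, their
#'   AUC and lead-time differences, and `per_subject` decision-time
#'   pairs for subjects that are true positives under both schemes.
#' @export
full_data_compare <- function(dataset, specs, settings = list(),
                              method = "marginal",
                              cutoff_rule = "topleft") {
  settings$keep_trajectories <- TRUE
  cv <- cross_validate(dataset, specs, settings, method, cutoff_rule)
  cfg <- cv$meta$settings
  groups <- vapply(dataset$subjects, `[[`, 1L, "group")
  confirmation <- confirmation_from_truth(dataset, cfg$target_group,
                                          cfg$horizon)
  full_rows <- list()
  pairs <- list()
  for (s in seq_along(cv$trajectories)) {
    tk <- cv$trajectories[[s]]
    other <- 1L - cfg$target_group
    full_allocs <- lapply(tk$trajectories, function(tr) {
      nT <- length(tr$times)
      pfinal <- tr$probs[nT]
      structure(list(subject_id = tr$subject_id,
                     predicted = if (pfinal > tk$cutoff) cfg$target_group
                       else other,
                     decision_time = tr$times[nT], times = tr$times,
                     probs = tr$probs, score = pfinal,
                     cutoff = tk$cutoff), class = "loda_allocation")
    })
    dyn_allocs <- .allocs_from_trajectories(tk$trajectories, tk$cutoff,
                                            cfg$target_group, 2L)
    met <- evaluate_classification(full_allocs, groups, cfg$target_group)
    lt <- lead_times(full_allocs, groups, confirmation, cfg$target_group)
    full_rows[[s]] <- data.frame(
      split = s, cutoff = tk$cutoff, sensitivity = met$sensitivity,
      specificity = met$specificity, ppv = met$ppv, npv = met$npv,
      pcc = met$pcc, auc = met$auc, mean_lead = lt$mean_lead,
      mean_prediction = lt$mean_prediction, n_tp = lt$n_tp)
    for (i in seq_along(dyn_allocs)) {
      d <- dyn_allocs[[i]]; f <- full_allocs[[i]]
      truth <- groups[[d$subject_id]]
      if (truth == cfg$target_group && d$predicted == cfg$target_group &&
          f$predicted == cfg$target_group)
        pairs[[length(pairs) + 1L]] <- data.frame(
          subject_id = d$subject_id, split = s,
          dynamic_time = d$decision_time, full_time = f$decision_time)
    }
  }
  full_tab <- do.call(rbind, full_rows)
  full_avg <- as.list(colMeans(full_tab[, -1L], na.rm = TRUE))
  list(dynamic = cv$average, full = full_avg,
       auc_difference = cv$average$auc - full_avg$auc,
       lead_time_difference = cv$average$mean_lead - full_avg$mean_lead,
       per_subject = if (length(pairs)) do.call(rbind, pairs) else NULL,
       per_split = list(dynamic = cv$per_split, full = full_tab))
}
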