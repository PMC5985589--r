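fake_alloc <- function(id, predicted, decision_time, score, cutoff = 0.5) {
  structure(list(subject_id = id, predicted = predicted,
                 decision_time = decision_time, times = decision_time,
                 probs = score, score = score, cutoff = cutoff),
            class = "loda_allocation")
}

test_that("allocation fires at the first strict exceedance and defaults otherwise", {
  a1 <- dloda:::.allocate_trajectory(c(365, 730), c(0.30, 0.80),
                                     cutoff = 0.74, 1L, 0L)
  expect_equal(a1$predicted, 1L)
  expect_equal(a1$decision_time, 730)
  # never exceeds: allocated to the other group at the final visit
  a2 <- dloda:::.allocate_trajectory(c(365, 730, 1100), c(0.30, 0.50, 0.60),
                                     cutoff = 0.74, 1L, 0L)
  expect_equal(a2$predicted, 0L)
  expect_equal(a2$decision_time, 1100)
  # exact ties with the cutoff never allocate to the target group
  a3 <- dloda:::.allocate_trajectory(c(100, 200), c(0.74, 0.74),
                                     cutoff = 0.74, 1L, 0L)
  expect_equal(a3$predicted, 0L)
  # stops at the first exceedance, not a later higher one
  a4 <- dloda:::.allocate_trajectory(c(100, 200, 300), c(0.8, 0.2, 0.99),
                                     cutoff = 0.74, 1L, 0L)
  expect_equal(a4$decision_time, 100)
})

test_that("dynamic_allocate runs end to end and respects confirmation times", {
  d0 <- list(psi = list(alpha = list(g1 = numeric(0)), phi = c(g1 = 0.3)),
             theta = list(w = 1, mu = list(0), D = list(matrix(0.4))))
  d1 <- list(psi = list(alpha = list(g1 = numeric(0)), phi = c(g1 = 0.3)),
             theta = list(w = 1, mu = list(2), D = list(matrix(0.4))))
  mk <- function(draws, spec) structure(
    list(draws = draws, spec = spec,
         meta = list(M = length(draws), n_subjects = 5L)),
    class = "loda_posterior")
  posts <- group_posteriors(
    list(mk(list(d0), gauss_spec(group = 0L, fixed = character())),
         mk(list(d1), gauss_spec(group = 1L, fixed = character()))),
    pi = c(0.5, 0.5))
  s <- simple_subject(times = c(200, 500, 900), values = c(1.8, 2.2, 2.1))
  conf <- c(s1 = 800)
  a <- dynamic_allocate(s, posts, target_group = 1L, cutoff = 0.6,
                        confirmation = conf)
  # the visit at 900 is at/after confirmation and must not be used
  expect_true(all(a$times < 800))
  expect_equal(a$predicted, 1L)
  expect_true(a$decision_time %in% c(200, 500))
  expect_error(dynamic_allocate(s, posts, cutoff = 0.6,
                                confirmation = c(s1 = 100)),
               "no visits before confirmation")
  expect_error(dynamic_allocate(s, posts, cutoff = 1.2,
                                confirmation = conf))
})

test_that("cutoff selection reproduces hand-computed ROC results", {
  # perfectly separated scores
  sel <- select_cutoff(c(0.1, 0.15, 0.8, 0.9), c(0, 0, 1, 1), "topleft")
  expect_equal(sel$auc, 1)
  i <- which(sel$roc$threshold == sel$cutoff)
  expect_equal(sel$roc$sens[i], 1)
  expect_equal(sel$roc$spec[i], 1)
  expect_gt(sel$cutoff, 0.15); expect_lt(sel$cutoff, 0.8)
  # constant scores: chance AUC by the tie convention
  sel2 <- select_cutoff(rep(0.4, 10), rep(c(0, 1), 5), "topleft")
  expect_equal(sel2$auc, 0.5)
  # enumerated fixture: pairs (.15>.1)+, (.15>.2)-, (.9>.1)+, (.9>.2)+
  sel3 <- select_cutoff(c(0.1, 0.2, 0.15, 0.9), c(0, 0, 1, 1), "youden")
  expect_equal(sel3$auc, 0.75)
  expect_error(select_cutoff(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("trapezoid AUC equals brute-force pairwise concordance", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    truths <- c(0, 1, rbinom(n - 2, 1, 0.4))   # both classes present
    scores <- round(runif(n), sample(1:3, 1))  # rounding creates ties
    sel <- select_cutoff(scores, truths)
    expect_equal(sel$auc, auc_brute(scores, truths), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on random fixtures", {
  skip_if_not_installed("pROC")
  set.seed(29)
  for (i in 1:5) {
    truths <- c(0, 1, rbinom(28, 1, 0.5))
    scores <- round(runif(30), 2)
    sel <- select_cutoff(scores, truths)
    ref <- suppressMessages(pROC::auc(pROC::roc(
      truths, scores, quiet = TRUE, levels = c(0, 1), direction = "<")))
    expect_equal(sel$auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("raising the cutoff never raises sensitivity nor lowers specificity", {
  set.seed(37)
  trajs <- lapply(1:40, function(i) {
    nv <- sample(2:6, 1)
    list(subject_id = paste0("s", i), truth = rbinom(1, 1, 0.3),
         times = sort(sample(100:1800, nv)), probs = runif(nv))
  })
  truths <- vapply(trajs, `[[`, 0, "truth")
  names(truths) <- vapply(trajs, `[[`, "", "subject_id")
  prev <- NULL
  for (cutoff in seq(0.05, 0.95, by = 0.1)) {
    allocs <- dloda:::.allocs_from_trajectories(trajs, cutoff, 1L, 2L)
    met <- evaluate_classification(allocs, truths, 1L)
    if (!is.null(prev)) {
      expect_lte(met$sensitivity, prev$sensitivity + 1e-12)
      expect_gte(met$specificity, prev$specificity - 1e-12)
    }
    # one-decision property: decision time is the first exceedance
    for (a in allocs) {
      hits <- which(a$probs > cutoff)
      if (length(hits)) expect_equal(a$decision_time, a$times[hits[1]])
      else expect_equal(a$decision_time, a$times[length(a$times)])
    }
    prev <- met
  }
})

test_that("classification metrics match hand-computed confusion tables", {
  allocs <- c(
    lapply(1:9, function(i) fake_alloc(paste0("tp", i), 1L, 400, 0.9)),
    lapply(1, function(i) fake_alloc("fn1", 0L, 800, 0.3)),
    lapply(1:8, function(i) fake_alloc(paste0("tn", i), 0L, 700, 0.2)),
    lapply(1:2, function(i) fake_alloc(paste0("fp", i), 1L, 500, 0.85)))
  truths <- c(rep(1, 10), rep(0, 10))
  names(truths) <- vapply(allocs, `[[`, "", "subject_id")
  met <- evaluate_classification(allocs, truths, 1L)
  expect_equal(met$sensitivity, 0.90)
  expect_equal(met$specificity, 0.80)
  expect_equal(met$ppv, 9 / 11, tolerance = 1e-3)
  expect_equal(met$npv, 8 / 9, tolerance = 1e-3)
  expect_equal(met$pcc, 0.85)
  expect_equal(unname(met$confusion), c(9, 2, 8, 1))
  # all predicted positive: sens 1, spec 0, PCC = prevalence, NPV undefined
  all_pos <- lapply(seq_along(truths), function(i)
    fake_alloc(names(truths)[i], 1L, 300, 0.9))
  met2 <- evaluate_classification(all_pos, truths, 1L)
  expect_equal(met2$sensitivity, 1)
  expect_equal(met2$specificity, 0)
  expect_equal(met2$pcc, 0.5)
  expect_true(is.na(met2$npv))
  # all correct
  all_ok <- lapply(seq_along(truths), function(i)
    fake_alloc(names(truths)[i], as.integer(truths[i]), 300,
               ifelse(truths[i] == 1, 0.9, 0.1)))
  met3 <- evaluate_classification(all_ok, truths, 1L)
  expect_equal(c(met3$sensitivity, met3$specificity, met3$pcc, met3$auc),
               c(1, 1, 1, 1))
})

test_that("lead and prediction times average over true positives only", {
  allocs <- list(fake_alloc("a", 1L, 1149, 0.9),
                 fake_alloc("b", 1L, 1700, 0.8),
                 fake_alloc("c", 0L, 900, 0.3),   # false negative: excluded
                 fake_alloc("d", 1L, 700, 0.9))   # false positive: excluded
  truths <- c(a = 1, b = 1, c = 1, d = 0)
  conf <- c(a = 1800, b = 1800, c = 1800, d = 1400)
  lt <- lead_times(allocs, truths, conf, 1L)
  expect_equal(lt$n_tp, 2L)
  expect_equal(lt$mean_lead, mean(c(1800 - 1149, 1800 - 1700)))
  expect_equal(lt$mean_prediction, mean(c(1149, 1700)))
  # decision at confirmation -> zero lead
  lt0 <- lead_times(list(fake_alloc("a", 1L, 1800, 0.9)), c(a = 1),
                    c(a = 1800), 1L)
  expect_equal(lt0$mean_lead, 0)
  # no true positives -> undefined
  ltna <- lead_times(allocs[3:4], truths[3:4], conf[3:4], 1L)
  expect_true(is.na(ltna$mean_lead))
})

test_that("stratified splits preserve group proportions", {
  sc <- sanad_like_scenario(n_subjects = 100L, seed = 31)
  ds <- simulate_dataset(sc)
  groups <- vapply(ds$subjects, `[[`, 1L, "group")
  for (i in 1:5) {
    set.seed(i)
    sp <- dloda:::.stratified_split(ds, 0.7)
    for (g in 0:1) {
      ids_g <- names(groups)[groups == g]
      n_train_g <- sum(sp$train %in% ids_g)
      expect_lte(abs(n_train_g - 0.7 * length(ids_g)), 1)
    }
    expect_setequal(c(sp$train, sp$test), names(groups))
  }
})

test_that("the cross-validation harness is reproducible and consistent", {
  sc <- sanad_like_scenario(n_subjects = 80L, seed = 51)
  ds <- simulate_dataset(sc)
  st <- list(n_splits = 2L, seed = 7L, max_draws = 10L,
             cutoff_train_max = 16L,
             mcmc = list(n_iter = 250L, burn_in = 100L, thin = 3L))
  cv1 <- cross_validate(ds, sc$group_specs, st)
  cv2 <- cross_validate(ds, sc$group_specs, st)
  expect_identical(cv1$per_split, cv2$per_split)
  expect_equal(nrow(cv1$per_split), 2L)
  expect_true(all(cv1$per_split$cutoff > 0 & cv1$per_split$cutoff < 1))
  expect_true(all(is.na(cv1$per_split$auc) |
                    (cv1$per_split$auc >= 0 & cv1$per_split$auc <= 1)))
  # full-data comparison reports both AUCs, their difference, and
  # never-later dynamic decisions
  fc <- full_data_compare(ds, sc$group_specs, st)
  expect_true(is.finite(fc$dynamic$auc) && is.finite(fc$full$auc))
  expect_equal(fc$auc_difference, fc$dynamic$auc - fc$full$auc)
  if (!is.null(fc$per_subject))
    expect_true(all(fc$per_subject$dynamic_time <=
                      fc$per_subject$full_time))
})
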