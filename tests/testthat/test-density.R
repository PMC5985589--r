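test_that("conditional log density matches hand values for each family", {
  # one bernoulli observation, linear predictor 0 -> log 0.5
  sb <- subject_data("a", 0L, markers = list(
    b1 = list(times = 1, values = 1)))
  hb <- evaluated_history(sb, bern_spec())
  psi_b <- list(alpha = list(b1 = numeric(0)), phi = c(b1 = 1))
  expect_equal(conditional_log_density(hb, 0, psi_b), log(0.5),
               tolerance = 1e-10)
  # one poisson observation y = 0 at log-mean 0 -> log e^{-1} = -1
  sp <- subject_data("a", 0L, markers = list(
    p1 = list(times = 1, values = 0)))
  spec_p <- group_model_spec(0L, list(marker_spec("p1", "poisson")))
  hp <- evaluated_history(sp, spec_p)
  expect_equal(conditional_log_density(hp, 0,
    list(alpha = list(p1 = numeric(0)), phi = c(p1 = 1))), -1,
    tolerance = 1e-10)
  # one gaussian observation at its mean, phi = 1 -> -0.5 log(2 pi)
  sg <- subject_data("a", 0L, markers = list(
    g1 = list(times = 1, values = 0.4)))
  hg <- evaluated_history(sg, gauss_spec(fixed = character()))
  expect_equal(conditional_log_density(hg, 0.4,
    list(alpha = list(g1 = numeric(0)), phi = c(g1 = 1))),
    -0.5 * log(2 * pi), tolerance = 1e-10)
})

test_that("conditional log density is additive over markers and visits", {
  set.seed(5)
  for (i in 1:10) {
    inst <- random_instance(100 + i)
    q <- inst$h$q
    b <- rnorm(q)
    full <- conditional_log_density(inst$h, b, inst$psi)
    # split: evaluate each marker alone and sum
    parts <- 0
    for (nm in names(inst$subject$markers)) {
      sub1 <- inst$subject
      for (other in setdiff(names(sub1$markers), nm)) {
        sub1$markers[[other]]$times <- numeric(0)
        sub1$markers[[other]]$values <- numeric(0)
      }
      h1 <- evaluated_history(sub1, inst$spec)
      parts <- parts + conditional_log_density(h1, b, inst$psi)
    }
    expect_equal(full, parts, tolerance = 1e-12)
  }
})

test_that("mixture random-effects log density matches hand evaluation", {
  # K = 1, b = mu, D = 1
  expect_equal(ranef_log_density(0, list(w = 1, mu = list(0),
                                         D = list(matrix(1)))),
               -0.5 * log(2 * pi), tolerance = 1e-12)
  # two identical components collapse to one
  th2 <- list(w = c(0.5, 0.5), mu = list(0.3, 0.3),
              D = list(matrix(2), matrix(2)))
  th1 <- list(w = 1, mu = list(0.3), D = list(matrix(2)))
  expect_equal(ranef_log_density(1.1, th2), ranef_log_density(1.1, th1),
               tolerance = 1e-12)
  # hand value: log(0.3 phi(1) + 0.7 phi(1)) = log phi(1)
  th <- list(w = c(0.3, 0.7), mu = list(-1, 1),
             D = list(matrix(1), matrix(1)))
  expect_equal(ranef_log_density(0, th), log(dnorm(1)), tolerance = 1e-9)
  expect_error(ranef_log_density(0, list(w = 1, mu = list(0),
                                         D = list(matrix(-1)))),
               "positive definite")
})

test_that("ranef density is label-invariant and integrates to one", {
  th <- list(w = c(0.2, 0.8), mu = list(-2, 1),
             D = list(matrix(0.5), matrix(1.5)))
  perm <- list(w = th$w[2:1], mu = th$mu[2:1], D = th$D[2:1])
  for (b in seq(-4, 4, by = 0.5))
    expect_equal(ranef_log_density(b, th), ranef_log_density(b, perm),
                 tolerance = 1e-12)
  grid <- seq(-12, 12, by = 0.001)
  dens <- vapply(grid, function(b) exp(ranef_log_density(b, th)), 0)
  expect_equal(sum(dens) * 0.001, 1, tolerance = 1e-4)
})

test_that("Laplace marginal is exact for gaussian models", {
  set.seed(2)
  for (i in 1:10) {
    n <- sample(1:6, 1)
    tt <- sort(sample(1:1500, n))
    y <- rnorm(n, 1, 1)
    s <- simple_subject(times = tt, values = y)
    spec <- gauss_spec()
    h <- evaluated_history(s, spec)
    alpha <- rnorm(1, 0, 0.001)
    phi <- runif(1, 0.2, 2)
    mu <- rnorm(1); Dv <- runif(1, 0.2, 2)
    psi <- list(alpha = list(g1 = alpha), phi = c(g1 = phi))
    theta <- list(w = 1, mu = list(mu), D = list(matrix(Dv)))
    lap <- as.numeric(marginal_log_density_laplace(h, psi, theta))
    X <- h$markers$g1$X; Z <- h$markers$g1$Z
    V <- Dv * tcrossprod(Z) + diag(phi, n)
    closed <- mvn_logdens <- {
      R <- chol(V)
      z <- backsolve(R, y - drop(X %*% alpha) - mu, transpose = TRUE)
      -0.5 * n * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
    }
    expect_equal(lap, closed, tolerance = 1e-8)
    # quadrature agrees with the closed form too
    expect_equal(marginal_log_density_quadrature(h, psi, theta, 16),
                 closed, tolerance = 1e-8)
  }
})

test_that("empty history has log marginal density zero", {
  s <- truncate_history(simple_subject(), 0)
  h <- evaluated_history(s, gauss_spec())
  psi <- list(alpha = list(g1 = 0.001), phi = c(g1 = 1))
  theta <- list(w = 1, mu = list(2), D = list(matrix(3)))
  expect_identical(as.numeric(marginal_log_density_laplace(h, psi, theta)), 0)
  expect_identical(marginal_log_density_quadrature(h, psi, theta), 0)
})

test_that("Laplace tracks the quadrature oracle on non-gaussian toys", {
  sb <- subject_data("a", 0L, markers = list(
    b1 = list(times = c(100, 400, 900), values = c(1, 0, 1))))
  h <- evaluated_history(sb, bern_spec(K = 2L))
  psi <- list(alpha = list(b1 = numeric(0)), phi = c(b1 = 1))
  theta <- list(w = c(0.4, 0.6), mu = list(-1, 1.5),
                D = list(matrix(0.3), matrix(0.5)))
  lap <- as.numeric(marginal_log_density_laplace(h, psi, theta))
  q64 <- marginal_log_density_quadrature(h, psi, theta, 64)
  expect_lt(abs(lap - q64), 5e-3)
  # node count convergence: 32 -> 64 change is tiny
  q8 <- marginal_log_density_quadrature(h, psi, theta, 8)
  q32 <- marginal_log_density_quadrature(h, psi, theta, 32)
  expect_lt(abs(q32 - q64), 1e-6)
  expect_lt(abs(q32 - q64), abs(q8 - q64) + 1e-12)
  # a zero-weight component changes nothing
  theta3 <- list(w = c(0.4, 0.6, 0), mu = c(theta$mu, list(5)),
                 D = c(theta$D, list(matrix(1))))
  expect_equal(marginal_log_density_quadrature(h, psi, theta3, 32), q32,
               tolerance = 1e-12)
  # oracle refuses large random-effect dimension
  spec5 <- group_model_spec(0L, list(
    marker_spec("b1", "bernoulli",
                random = c("time_since_diagnosis",
                           "time_since_last_visit")),
    marker_spec("b2", "bernoulli")))
  sb5 <- subject_data("a", 0L, markers = list(
    b1 = list(times = c(100, 300), values = c(1, 0)),
    b2 = list(times = 200, values = 1)))
  h5 <- evaluated_history(sb5, spec5)
  expect_equal(h5$q, 4L)
  spec6 <- group_model_spec(0L, list(
    marker_spec("b1", "bernoulli",
                random = c("time_since_diagnosis",
                           "time_since_last_visit")),
    marker_spec("b2", "bernoulli", random = "time_since_diagnosis")))
  h6 <- evaluated_history(sb5, spec6)
  expect_error(marginal_log_density_quadrature(h6, psi, theta), "q <= 4")
})

test_that("joint density factorizes as conditional plus ranef everywhere", {
  set.seed(9)
  for (i in 1:10) {
    inst <- random_instance(200 + i)
    b <- rnorm(inst$h$q)
    joint <- dloda:::.predictive_logpost(inst$h, b, inst$psi, inst$theta)
    expect_equal(joint,
                 conditional_log_density(inst$h, b, inst$psi) +
                   ranef_log_density(b, inst$theta),
                 tolerance = 1e-12)
  }
})

test_that("predictive sampler reduces to the mixture prior with no data", {
  s <- truncate_history(simple_subject(marker = "b1"), 0)
  spec <- bern_spec(K = 2L)
  h <- evaluated_history(s, spec)
  psi <- list(alpha = list(b1 = numeric(0)), phi = c(b1 = 1))
  theta <- list(w = c(0.35, 0.65), mu = list(-2, 1),
                D = list(matrix(0.4), matrix(0.9)))
  sr <- sample_ranef_predictive(h, psi, theta, n_draws = 2000, seed = 11)
  expect_equal(sr$accept_rate, 1)   # proposal equals target exactly
  set.seed(12)
  direct <- vapply(1:2000, function(i) {
    k <- sample.int(2, 1, prob = theta$w)
    rnorm(1, theta$mu[[k]], sqrt(theta$D[[k]]))
  }, 0)
  ks <- suppressWarnings(ks.test(sr$draws[, 1], direct))
  expect_gt(ks$p.value, 0.001)
})

test_that("predictive sampler matches the conjugate normal posterior", {
  s <- simple_subject(times = c(100, 500, 900), values = c(1.4, 0.9, 2.0))
  spec <- gauss_spec()
  h <- evaluated_history(s, spec)
  alpha <- 0.0005; phi <- 0.3; mu <- 0.5; Dv <- 0.8
  psi <- list(alpha = list(g1 = alpha), phi = c(g1 = phi))
  theta <- list(w = 1, mu = list(mu), D = list(matrix(Dv)))
  sr <- sample_ranef_predictive(h, psi, theta, n_draws = 4000, seed = 21)
  y <- s$markers$g1$values
  r <- y - h$markers$g1$X[, 1] * alpha
  prec <- 3 / phi + 1 / Dv
  post_mean <- (sum(r) / phi + mu / Dv) / prec
  post_var <- 1 / prec
  expect_lt(abs(mean(sr$draws) - post_mean), 3 * sqrt(post_var / 4000) + 0.01)
  expect_lt(abs(var(sr$draws[, 1]) - post_var), 3 * post_var * sqrt(2 / 4000) + 0.01)
  # returned mode equals the dominant-component Laplace mode
  lap <- marginal_log_density_laplace(h, psi, theta)
  expect_equal(sr$mode, attr(lap, "modes")[[1]], tolerance = 1e-8)
})

test_that("Laplace and quadrature agree and rank groups identically on random instances", {
  diffs <- numeric(0)
  agree <- logical(0)
  for (i in 1:50) {
    inst <- random_instance(3000 + i)
    lap <- as.numeric(marginal_log_density_laplace(inst$h, inst$psi,
                                                   inst$theta))
    qua <- marginal_log_density_quadrature(inst$h, inst$psi, inst$theta, 32)
    diffs <- c(diffs, abs(lap - qua))
    # paired-group comparison: same instance under an alternative theta
    inst2 <- random_instance(6000 + i)
    lap2 <- as.numeric(marginal_log_density_laplace(inst$h, inst$psi,
                                                    inst2$theta))
    qua2 <- marginal_log_density_quadrature(inst$h, inst$psi, inst2$theta, 32)
    agree <- c(agree, sign(lap - lap2) == sign(qua - qua2))
  }
  expect_lt(max(diffs), 0.05)
  expect_gte(mean(agree), 0.98)
})
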