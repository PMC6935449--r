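rand_hmm <- function(Q, M, D) {
  b <- runif(Q) + 0.1; b <- b / sum(b)
  C <- matrix(runif(Q * Q) + 0.1, Q, Q); C <- C / rowSums(C)
  ems <- lapply(seq_len(Q), function(l) rand_params(1, M, D)$emissions[[1]])
  gaussian_hmm(b, C, ems)
}

test_that("HMM forward likelihood: closed forms and enumeration oracle", {
  set.seed(51)
  h1 <- rand_hmm(1, 1, 2)
  s <- rand_seq(5, 2)
  direct <- sum(vapply(1:5, function(t)
    log_mixture_density(s$frames[t, ], h1$emissions[[1]]), numeric(1)))
  expect_equal(hmm_log_likelihood(h1, s), direct, tolerance = 1e-10)

  # identical state emissions + uniform chain: likelihood independent of Q
  mix <- rand_params(1, 1, 2)$emissions[[1]]
  lls <- vapply(1:3, function(Q) {
    h <- gaussian_hmm(rep(1 / Q, Q), matrix(1 / Q, Q, Q),
                      replicate(Q, mix, simplify = FALSE))
    hmm_log_likelihood(h, s)
  }, numeric(1))
  expect_equal(lls[2], lls[1], tolerance = 1e-10)
  expect_equal(lls[3], lls[1], tolerance = 1e-10)

  # enumeration oracle, T = 5, Q = 3
  h <- rand_hmm(3, 1, 2)
  paths <- as.matrix(expand.grid(rep(list(1:3), 5)))
  dens <- t(vapply(1:5, function(t) vapply(1:3, function(l)
    exp(log_mixture_density(s$frames[t, ], h$emissions[[l]])), numeric(1)),
    numeric(3)))
  tot <- sum(apply(paths, 1, function(p) {
    v <- h$initial[p[1]] * dens[1, p[1]]
    for (t in 2:5) v <- v * h$transition[p[t - 1], p[t]] * dens[t, p[t]]
    v
  }))
  expect_equal(hmm_log_likelihood(h, s), log(tot), tolerance = 1e-10)

  expect_error(gaussian_hmm(c(0.5, 0.4), matrix(0.5, 2, 2),
                            list(mix, mix)), "probability")
})

test_that("HMM-to-HCRF mapping is score-exact and invertible", {
  set.seed(52)
  # a concrete two-state instance
  mk <- function(mu) state_mixture(1, list(gaussian_component(mu, matrix(1))))
  h <- gaussian_hmm(c(0.5, 0.5), matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                    list(mk(0), mk(3)))
  s <- rand_seq(6, 1)
  expect_lt(abs(forward(hcrf_from_hmm(h), s)$log_score -
                  hmm_log_likelihood(h, s)), 1e-10)
  # mapping then exponentiating recovers b and C exactly
  cp <- hcrf_from_hmm(h)
  expect_equal(exp(cp$prior), h$initial, tolerance = 1e-15)
  expect_equal(exp(cp$transition), h$transition, tolerance = 1e-15)

  # deterministic chain: identity C, b = delta_1 -> single-path closed form
  hd <- gaussian_hmm(c(1, 0), diag(2), list(mk(0), mk(3)))
  sd_ <- rand_seq(4, 1)
  closed <- sum(dnorm(sd_$frames[, 1], 0, 1, log = TRUE))
  expect_equal(forward(hcrf_from_hmm(hd), sd_)$log_score, closed,
               tolerance = 1e-10)

  for (i in 1:30) {
    Q <- sample(1:4, 1); M <- sample(1:2, 1); D <- sample(1:2, 1)
    h <- rand_hmm(Q, M, D)
    s <- rand_seq(sample(1:10, 1), D)
    expect_lt(abs(forward(hcrf_from_hmm(h), s)$log_score -
                    hmm_log_likelihood(h, s)), 1e-9)
  }
})

test_that("moment-feature weights complete the diagonal Gaussian exactly", {
  set.seed(53)
  Q <- 2; D <- 3
  mu <- matrix(rnorm(Q * D), Q, D)
  s2 <- matrix(runif(Q * D, 0.3, 2), Q, D)
  cl <- diagonal_hcrf_from_gaussians(rnorm(Q), matrix(rnorm(Q * Q), Q, Q),
                                     mu, s2)
  for (i in 1:10) {
    u <- rnorm(D, sd = 2)
    for (l in 1:Q) {
      pot <- cl$occurrence[l] + sum(cl$M1[l, ] * u) + sum(cl$M2[l, ] * u^2)
      ref <- sum(dnorm(u, mu[l, ], sqrt(s2[l, ]), log = TRUE))
      expect_equal(pot, ref, tolerance = 1e-12)
    }
  }
  # hence full sequence scores match the diagonal-Gaussian HCRF block
  ems <- lapply(1:Q, function(l) state_mixture(1, list(
    gaussian_component(mu[l, ], diag(s2[l, ], D)))))
  cp <- class_params(cl$prior, cl$transition, ems)
  dm <- diagonal_hcrf(list(cl), "a")
  s <- rand_seq(7, D)
  expect_equal(unname(diagonal_hcrf_score(dm, s)["a"]),
               forward(cp, s)$log_score, tolerance = 1e-10)
})

test_that("zero moment weights reduce to a discrete-potential chain", {
  set.seed(54)
  Q <- 2
  cl <- list(prior = rnorm(Q), transition = matrix(rnorm(Q * Q), Q, Q),
             occurrence = rnorm(Q), M1 = matrix(0, Q, 1),
             M2 = matrix(0, Q, 1))
  expect_warning(dm <- diagonal_hcrf(list(cl), "a"), "quadratic")
  s <- rand_seq(4, 1)
  # enumeration over paths of prior + transitions + occurrence
  paths <- as.matrix(expand.grid(rep(list(1:Q), 4)))
  vals <- apply(paths, 1, function(p) {
    v <- cl$prior[p[1]] + cl$occurrence[p[1]]
    for (t in 2:4) v <- v + cl$transition[p[t - 1], p[t]] + cl$occurrence[p[t]]
    v
  })
  expect_equal(unname(diagonal_hcrf_score(dm, s)["a"]), logsumexp(vals),
               tolerance = 1e-10)
  # T = 1, Q = 1: directly computable sum of terms
  cl1 <- list(prior = 0.3, transition = matrix(0.7), occurrence = -0.2,
              M1 = matrix(1.5), M2 = matrix(-0.5))
  dm1 <- diagonal_hcrf(list(cl1), "a")
  s1 <- feature_sequence(matrix(2), seq_id = "x")
  expect_equal(unname(diagonal_hcrf_score(dm1, s1)["a"]),
               0.3 - 0.2 + 1.5 * 2 - 0.5 * 4, tolerance = 1e-12)
})

test_that("diagonal training: constrained model, init identity, matched-model control", {
  # diagonal fit keeps covariances diagonal and the moment-feature form of a
  # fitted M = 1 diagonal model reproduces its scores
  ds <- tiny_labeled_dataset(n_per_class = 5, T_ = 8, D = 2, gap = 4, seed = 9)
  cfg <- train_config(Q = 1, M = 1, max_iter = 0, seed = 2, cov = "diagonal")
  f0 <- fit_diagonal(ds, cfg)
  expect_equal(f0$model, initialize_model(ds, cfg))
  fit_d <- fit_diagonal(ds, train_config(Q = 1, M = 1, max_iter = 25, seed = 2))
  for (cp in fit_d$model$classes) {
    S <- cp$emissions[[1]]$components[[1]]$covariance
    expect_equal(S, diag(diag(S), 2), tolerance = 1e-12)
  }
  dm <- diagonal_hcrf_from_model(fit_d$model)
  s <- ds[[1]]
  sc_mf <- diagonal_hcrf_score(dm, s)
  sc_full <- vapply(fit_d$model$classes, function(cp) forward(cp, s)$log_score,
                    numeric(1))
  expect_equal(unname(sc_mf), unname(sc_full), tolerance = 1e-10)

  # on diagonally-generated data, full and diagonal objectives agree within 2%
  fit_f <- fit_gmhcrf(ds, train_config(Q = 1, M = 1, max_iter = 25, seed = 2))
  of <- utils::tail(fit_f$history, 1); od <- utils::tail(fit_d$history, 1)
  expect_lt(abs(of - od) / max(abs(of), abs(od), 1), 0.02)
})
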