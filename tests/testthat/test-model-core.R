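test_that("Gaussian log-density matches closed forms and the explicit-inverse oracle", {
  expect_equal(log_gaussian_density(0, gaussian_component(0, matrix(1))),
               -0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(log_gaussian_density(c(1, -2),
                                    gaussian_component(c(1, -2), diag(2))),
               -log(2 * pi), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    D <- sample(1:3, 1)
    mu <- rnorm(D); S <- rand_spd(D); u <- rnorm(D, sd = 2)
    got <- log_gaussian_density(u, gaussian_component(mu, S))
    want <- oracle_log_gauss(u, mu, S)
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(log_gaussian_density(c(1, 2), gaussian_component(0, matrix(1))),
               "dimension")
  expect_error(gaussian_component(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(gaussian_component(c(0, 0), matrix(c(1, 0.5, 0, 1), 2)),
               "symmetric")
})

test_that("mixture log-density degenerates correctly and matches the direct-sum oracle", {
  set.seed(12)
  comp <- gaussian_component(rnorm(2), rand_spd(2))
  u <- rnorm(2)
  expect_identical(log_mixture_density(u, state_mixture(1, list(comp))),
                   log_gaussian_density(u, comp))
  dup <- state_mixture(c(0.5, 0.5), list(comp, comp))
  expect_equal(log_mixture_density(u, dup), log_gaussian_density(u, comp),
               tolerance = 1e-12)
  for (i in 1:10) {
    mix <- rand_params(1, 3, 2)$emissions[[1]]
    u <- rnorm(2, sd = 2)
    naive <- log(sum(vapply(1:3, function(m)
      mix$weights[m] * exp(log_gaussian_density(u, mix$components[[m]])),
      numeric(1))))
    expect_equal(log_mixture_density(u, mix), naive, tolerance = 1e-12)
  }
})

test_that("forward handles the no-transition and single-path closed forms", {
  set.seed(13)
  p <- rand_params(3, 2, 2)
  s1 <- rand_seq(1, 2)
  le1 <- vapply(1:3, function(l)
    log_mixture_density(s1$frames[1, ], p$emissions[[l]]), numeric(1))
  expect_equal(forward(p, s1)$log_score, logsumexp(p$prior + le1),
               tolerance = 1e-12)
  expect_equal(backward(p, s1), matrix(0, 1, 3))

  q1 <- rand_params(1, 2, 2)
  s <- rand_seq(5, 2)
  les <- vapply(1:5, function(t)
    log_mixture_density(s$frames[t, ], q1$emissions[[1]]), numeric(1))
  closed <- q1$prior[1] + 4 * q1$transition[1, 1] + sum(les)
  expect_equal(forward(q1, s)$log_score, closed, tolerance = 1e-10)
  bw <- backward(q1, s)
  for (t in 1:5)
    expect_equal(bw[t, 1], (5 - t) * q1$transition[1, 1] +
                   sum(les[seq_len(5 - t) + t]), tolerance = 1e-10)
})

test_that("forward/backward agree with path enumeration and each other (property)", {
  set.seed(14)
  for (i in 1:30) {
    Q <- sample(1:3, 1); M <- sample(1:2, 1); D <- sample(1:3, 1)
    T_ <- sample(1:5, 1)
    p <- rand_params(Q, M, D)
    s <- rand_seq(T_, D)
    fw <- forward(p, s)
    bf <- brute_force_log_score(p, s)
    expect_lt(abs(fw$log_score - bf) / max(1, abs(fw$log_score)), 1e-10)
    # score identity: sum_l alpha_T(l) = sum_l (prior + emis_1 + beta_1)(l)
    bw <- backward(p, s)
    le1 <- vapply(seq_len(Q), function(l)
      log_mixture_density(s$frames[1, ], p$emissions[[l]]), numeric(1))
    expect_equal(logsumexp(p$prior + le1 + bw[1, ]), fw$log_score,
                 tolerance = 1e-9)
  }
  expect_error(brute_force_log_score(rand_params(3, 1, 1), rand_seq(20, 1)),
               "refusing")
})

test_that("class posterior: symmetry, potential shifts, enumeration oracle, invariances", {
  set.seed(15)
  p <- rand_params(2, 1, 2)
  twin <- gmhcrf_model(c("a", "b"), list(p, p))
  s <- rand_seq(4, 2)
  expect_equal(unname(class_posterior(twin, s)), c(0.5, 0.5),
               tolerance = 1e-12)
  # +c on one class's prior multiplies its posterior odds by e^c
  cshift <- 0.7
  p2 <- p; p2$prior <- p$prior + cshift
  shifted <- gmhcrf_model(c("a", "b"), list(p2, p))
  post0 <- class_posterior(twin, s); post1 <- class_posterior(shifted, s)
  expect_equal((post1[1] / post1[2]) / (post0[1] / post0[2]),
               c(a = exp(cshift)), tolerance = 1e-9)

  m <- rand_model(3, 2, 1, 2)
  s3 <- rand_seq(3, 2)
  post <- class_posterior(m, s3)
  expect_equal(sum(post), 1, tolerance = 1e-12)
  bscores <- vapply(m$classes, brute_force_log_score, numeric(1), seq = s3)
  expect_equal(unname(post), unname(exp(bscores - logsumexp(bscores))),
               tolerance = 1e-12)

  # translation invariance: +c on every class's prior leaves posterior alone
  m2 <- m
  for (v in 1:3) m2$classes[[v]]$prior <- m$classes[[v]]$prior + 3.3
  expect_equal(class_posterior(m2, s3), post, tolerance = 1e-12)

  # hidden-state relabeling invariance
  perm <- c(2, 1)
  m3 <- m
  cp <- m$classes[[1]]
  m3$classes[[1]] <- class_params(cp$prior[perm],
                                  cp$transition[perm, perm],
                                  cp$emissions[perm])
  expect_equal(class_posterior(m3, s3), post, tolerance = 1e-10)
})

test_that("predict breaks ties by label order and agrees with brute-force argmax", {
  set.seed(16)
  p <- rand_params(2, 1, 2)
  twin <- gmhcrf_model(c("first", "second"), list(p, p))
  s <- rand_seq(3, 2)
  expect_identical(predict(twin, s), "first")
  p2 <- p; p2$prior <- p$prior + 10
  expect_identical(predict(gmhcrf_model(c("a", "b"), list(p, p2)), s), "b")
  for (i in 1:5) {
    m <- rand_model(3, 2, 1, 2)
    s <- rand_seq(3, 2)
    bscores <- vapply(m$classes, brute_force_log_score, numeric(1), seq = s)
    expect_identical(predict(m, s), m$labels[which.max(bscores)])
  }
})
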