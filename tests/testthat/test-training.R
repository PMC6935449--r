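test_that("pack/unpack: round-trip, zero-vector conventions, layout bookkeeping", {
  set.seed(31)
  m <- rand_model(2, 2, 2, 3)
  pk <- make_packing(m)
  th <- pack_model(m, pk)
  m2 <- unpack_model(th, pk)
  expect_equal(pack_model(m2, pk), th, tolerance = 1e-12)
  for (v in 1:2) {
    expect_equal(m2$classes[[v]]$prior, m$classes[[v]]$prior, tolerance = 1e-12)
    expect_equal(m2$classes[[v]]$emissions[[1]]$weights,
                 m$classes[[v]]$emissions[[1]]$weights, tolerance = 1e-12)
    expect_equal(m2$classes[[v]]$emissions[[2]]$components[[1]]$covariance,
                 m$classes[[v]]$emissions[[2]]$components[[1]]$covariance,
                 tolerance = 1e-12)
  }
  z <- unpack_model(numeric(pk$n_params), pk)
  expect_equal(z$classes[[1]]$emissions[[1]]$weights, c(0.5, 0.5))
  expect_equal(z$classes[[1]]$emissions[[1]]$components[[1]]$covariance,
               diag(3))
  expect_equal(z$classes[[1]]$prior, c(0, 0))

  # perturbing one flat coordinate changes exactly one parameter family
  fam_of <- function(i, pk) {
    for (v in seq_along(pk$offsets))
      for (fam in names(pk$offsets[[v]]))
        if (i %in% pk$offsets[[v]][[fam]]) return(c(v, fam))
    stop("coordinate outside layout")
  }
  families <- function(mod, pk) list(
    prior = lapply(mod$classes, `[[`, "prior"),
    transition = lapply(mod$classes, `[[`, "transition"),
    weights = lapply(mod$classes, function(cp)
      lapply(cp$emissions, `[[`, "weights")),
    means = lapply(mod$classes, function(cp)
      lapply(cp$emissions, function(e) lapply(e$components, `[[`, "mean"))),
    covariances = lapply(mod$classes, function(cp)
      lapply(cp$emissions, function(e)
        lapply(e$components, `[[`, "covariance"))))
  base <- families(m2, pk)
  for (i in sample(pk$n_params, 8)) {
    th2 <- th; th2[i] <- th2[i] + 0.3
    pert <- families(unpack_model(th2, pk), pk)
    hit <- fam_of(i, pk)
    for (fam in names(base)) {
      for (v in 1:2) {
        same <- isTRUE(all.equal(base[[fam]][[v]], pert[[fam]][[v]],
                                 tolerance = 1e-12))
        should_differ <- fam == hit[2] && v == as.integer(hit[1])
        expect_identical(!same, should_differ,
                         info = sprintf("coord %d fam %s class %d", i, fam, v))
      }
    }
  }
})

test_that("initialization: determinism, zero potentials, k-means recovery", {
  ds <- tiny_labeled_dataset(n_per_class = 6, T_ = 8, D = 2, seed = 5)
  cfg <- train_config(Q = 2, M = 1, seed = 9, init = "random")
  a <- initialize_model(ds, cfg)
  b <- initialize_model(ds, cfg)
  expect_equal(a, b)
  expect_equal(a$classes[[1]]$prior, c(0, 0))
  expect_equal(a$classes[[2]]$transition, matrix(0, 2, 2))

  # two well-separated 2-D blobs, Q = 1, M = 2: means near the true centers
  set.seed(41)
  blob <- function(ctr) sweep(matrix(rnorm(2 * 40, sd = 0.3), 40, 2), 2, ctr,
                              `+`)
  X <- rbind(blob(c(-2, 0)), blob(c(2, 0)))
  ds2 <- list(feature_sequence(X, label = "a"),
              feature_sequence(matrix(rnorm(4), 2, 2), label = "b"))
  init <- initialize_model(ds2, train_config(Q = 1, M = 2, seed = 3))
  mus <- t(vapply(init$classes[["a"]]$emissions[[1]]$components, `[[`,
                  numeric(2), "mean"))
  mus <- mus[order(mus[, 1]), ]
  expect_lt(sqrt(sum((mus[1, ] - c(-2, 0))^2)), 0.5)
  expect_lt(sqrt(sum((mus[2, ] - c(2, 0))^2)), 0.5)

  expect_error(initialize_model(list(feature_sequence(matrix(0, 1, 1),
                                                      label = "only")),
                                train_config(Q = 2, M = 2)),
               "only")
})

test_that("fit: max_iter = 0 identity, monotone history, separable training accuracy", {
  ds <- tiny_labeled_dataset(n_per_class = 5, T_ = 10, D = 2, gap = 6, seed = 6)
  cfg0 <- train_config(Q = 1, M = 1, max_iter = 0, seed = 2)
  f0 <- fit_gmhcrf(ds, cfg0)
  expect_equal(f0$model, initialize_model(ds, cfg0))
  expect_length(f0$history, 1)

  # strictly separable 2-class set: class means 6 apart, Q = 1, M = 1
  set.seed(42)
  ds2 <- c(lapply(1:10, function(i) feature_sequence(
             matrix(rnorm(20 * 2), 20, 2) + 3, label = "hi",
             seq_id = paste0("h", i))),
           lapply(1:10, function(i) feature_sequence(
             matrix(rnorm(20 * 2), 20, 2) - 3, label = "lo",
             seq_id = paste0("l", i))))
  fit <- fit_gmhcrf(ds2, train_config(Q = 1, M = 1, max_iter = 30, seed = 4))
  expect_true(all(diff(fit$history) <= 0))
  expect_lte(utils::tail(fit$history, 1), fit$history[1])
  truth <- vapply(ds2, `[[`, character(1), "label")
  expect_equal(mean(predict(fit$model, ds2) == truth), 1)
})

test_that("fit is deterministic at serialization precision", {
  ds <- tiny_labeled_dataset(n_per_class = 4, T_ = 6, D = 2, seed = 7)
  cfg <- train_config(Q = 2, M = 1, max_iter = 10, seed = 11)
  f1 <- fit_gmhcrf(ds, cfg)
  f2 <- fit_gmhcrf(ds, cfg)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_model(f1$model, p1); write_model(f2$model, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("ridge dominates as l2 grows: parameters shrink, posteriors flatten", {
  ds <- tiny_labeled_dataset(n_per_class = 3, T_ = 6, D = 2, gap = 3, seed = 8)
  norms <- c(); gaps <- c()
  for (l2 in c(1e-2, 1, 1e2, 1e6)) {
    fit <- fit_gmhcrf(ds, train_config(Q = 1, M = 1, l2 = l2, max_iter = 25,
                                       seed = 3))
    th <- pack_model(fit$model, fit$packing)
    norms <- c(norms, sqrt(sum(th^2)))
    post <- predict(fit$model, ds, type = "posterior")
    gaps <- c(gaps, max(abs(post - 0.5)))
  }
  expect_true(all(diff(norms) < 0))
  expect_lt(gaps[4], gaps[1])
  expect_lt(gaps[4], 0.05)
})
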