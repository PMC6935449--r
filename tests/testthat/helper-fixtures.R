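# Random fixtures and independent oracles, regenerated in code at test time.

rand_spd <- function(D, jitter = 0.5) {
  A <- matrix(rnorm(D * D, sd = 0.4), D, D)
  crossprod(A) + diag(jitter, D)
}

rand_params <- function(Q, M, D, spread = 1.5) {
  emissions <- lapply(seq_len(Q), function(l) {
    comps <- lapply(seq_len(M), function(m)
      gaussian_component(rnorm(D, sd = spread), rand_spd(D)))
    w <- runif(M, 0.2, 1); w <- w / sum(w)
    state_mixture(w, comps)
  })
  class_params(rnorm(Q, sd = 0.5), matrix(rnorm(Q * Q, sd = 0.5), Q, Q),
               emissions)
}

rand_model <- function(nV, Q, M, D, spread = 1.5) {
  gmhcrf_model(paste0("c", seq_len(nV)),
               lapply(seq_len(nV), function(v) rand_params(Q, M, D, spread)))
}

rand_seq <- function(T_, D, label = NULL, group_id = NULL, seq_id = "s") {
  feature_sequence(matrix(rnorm(T_ * D), T_, D), seq_id = seq_id,
                   label = label, group_id = group_id)
}

# explicit-inverse Gaussian log density (independent of the Cholesky path)
oracle_log_gauss <- function(u, mean, covariance) {
  D <- length(mean)
  Sinv <- solve(covariance)
  -0.5 * (D * log(2 * pi) + log(det(covariance)) +
            drop(t(u - mean) %*% Sinv %*% (u - mean)))
}

# enumerate all hidden paths; returns per-path log potentials and the paths
enumerate_paths <- function(params, s) {
  T_ <- nrow(s$frames); Q <- params$Q
  le <- t(vapply(seq_len(T_), function(t)
    vapply(seq_len(Q), function(l)
      log_mixture_density(s$frames[t, ], params$emissions[[l]]), numeric(1)),
    numeric(Q)))
  le <- matrix(le, T_, Q)
  paths <- as.matrix(expand.grid(rep(list(seq_len(Q)), T_)))
  vals <- apply(paths, 1L, function(p) {
    v <- params$prior[p[1L]] + le[1L, p[1L]]
    if (T_ > 1L)
      for (t in 2:T_) v <- v + params$transition[p[t - 1L], p[t]] + le[t, p[t]]
    v
  })
  list(paths = paths, log_potentials = vals)
}

tiny_labeled_dataset <- function(n_per_class = 4L, T_ = 6L, D = 2L,
                                 gap = 6, n_groups = 4L, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (v in 1:2) {
    for (i in seq_len(n_per_class)) {
      X <- matrix(rnorm(T_ * D), T_, D) + (v - 1) * gap
      out[[length(out) + 1L]] <- feature_sequence(
        X, seq_id = sprintf("c%d_%d", v, i), label = paste0("c", v),
        group_id = sprintf("g%d", ((i - 1L) %% n_groups) + 1L))
    }
  }
  out
}
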