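#' Synthetic dataset specification
#'
#' Per-class GMM-HMM generators plus global sampling settings. Emulates the
#' statistical structure the classifier assumes: per-class hidden Markov
#' chains emitting from per-state full-covariance Gaussian mixtures, with
#' controllable inter-class separation and feature correlation.
#'
#' @param labels character vector of class labels.
#' @param classes list of \code{gaussian_hmm}, one per label, sharing D.
#' @param T_range sequence length: a single integer (fixed T) or a length-2
#'   integer range sampled uniformly per sequence.
#' @param n_sequences sequences generated per class.
#' @param n_groups number of pseudo-subjects; sequences are assigned to
#'   groups round-robin within each class so grouped cross-validation is
#'   exercisable.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(labels, classes, T_range = 30L, n_sequences = 20L,
                           n_groups = 10L) {
  labels <- as.character(labels)
  if (length(labels) != length(classes))
    stop("synthetic_spec: one gaussian_hmm per label")
  Ds <- vapply(classes, `[[`, numeric(1), "D")
  if (length(unique(Ds)) != 1L)
    stop("synthetic_spec: all classes must share D")
  T_range <- as.integer(T_range)
  if (!length(T_range) %in% c(1L, 2L) || any(T_range < 1L))
    stop("synthetic_spec: T_range must be one positive integer or a range")
  names(classes) <- labels
  structure(list(labels = labels, classes = classes, D = Ds[1L],
                 T_range = T_range, n_sequences = as.integer(n_sequences),
                 n_groups = as.integer(n_groups)),
            class = "synthetic_spec")
}

#' Sample one sequence from a Gaussian(-mixture) HMM
#'
#' Ancestral sampling: l_1 ~ initial, l_t+1 ~ transition row l_t; per frame a
#' mixture component m ~ weights, then u_t ~ N(mu_{l,m}, Sigma_{l,m}) via the
#' Cholesky factor. Uses R's global RNG stream; seed with \code{set.seed}.
#'
#' @param hmm a \code{gaussian_hmm}.
#' @param T_ sequence length (>= 1).
#' @param seq_id,label,group_id passed to \code{feature_sequence}.
#' @return a \code{feature_sequence}.
#' @export
simulate_sequence <- function(hmm, T_, seq_id = "sim", label = NULL,
                              group_id = NULL) {
  T_ <- as.integer(T_)
  if (T_ < 1L) stop("simulate_sequence: T must be >= 1")
  D <- hmm$D
  X <- matrix(0, T_, D)
  l <- sample.int(hmm$Q, 1L, prob = hmm$initial)
  for (t in seq_len(T_)) {
    if (t > 1L) l <- sample.int(hmm$Q, 1L, prob = hmm$transition[l, ])
    mix <- hmm$emissions[[l]]
    m <- if (length(mix$weights) == 1L) 1L
         else sample.int(length(mix$weights), 1L, prob = mix$weights)
    comp <- mix$components[[m]]
    X[t, ] <- comp$mean + drop(rnorm(D) %*% comp$chol_u)
  }
  feature_sequence(X, seq_id = seq_id, label = label, group_id = group_id)
}

#' Simulate a labeled dataset from a synthetic specification
#'
#' n_sequences per class, labels attached, group ids assigned round-robin
#' over the spec's pseudo-subjects. Deterministic per seed.
#'
#' @param spec a \code{synthetic_spec}.
#' @param seed integer seed.
#' @return list of labeled \code{feature_sequence} objects.
#' @export
simulate_dataset <- function(spec, seed = 1L) {
  set.seed(as.integer(seed))
  out <- list()
  for (v in seq_along(spec$labels)) {
    for (i in seq_len(spec$n_sequences)) {
      T_ <- if (length(spec$T_range) == 1L) spec$T_range
            else sample(spec$T_range[1L]:spec$T_range[2L], 1L)
      g <- ((i - 1L) %% spec$n_groups) + 1L
      out[[length(out) + 1L]] <- simulate_sequence(
        spec$classes[[v]], T_,
        seq_id = sprintf("%s_%03d", spec$labels[v], i),
        label = spec$labels[v],
        group_id = sprintf("g%02d", g))
    }
  }
  out
}

cov2 <- function(v1, v2, rho) {
  matrix(c(v1, rho * sqrt(v1 * v2), rho * sqrt(v1 * v2), v2), 2L, 2L)
}

mix1 <- function(mean, covariance) {
  state_mixture(1, list(gaussian_component(mean, covariance)))
}

#' Built-in synthetic dataset presets
#'
#' Three fully specified worlds (all parameters printed in the methods
#' vignette):
#' \describe{
#'   \item{separable}{3 classes, D = 2, Q = 2, M = 1, unit-variance isotropic
#'     states. Class centers sit 120 degrees apart on a circle of radius 6
#'     (inter-class gaps > 3 standard deviations); the two states of a class
#'     are offset +/-1.5 along the x-axis from its center. Sticky transitions
#'     (0.9 stay / 0.1 switch), uniform initial distribution. Essentially
#'     noise-free for a sequence-level classifier.}
#'   \item{correlated}{2 classes, D = 2, Q = 1, M = 1. Class means (0, 0) and
#'     (0.25, 0.25); covariances have unit variances and feature correlation
#'     +0.9 (class A) vs -0.9 (class B). The class difference lives almost
#'     entirely in the correlation structure, which a diagonal-covariance
#'     model cannot represent.}
#'   \item{hard}{3 classes, D = 2, Q = 2, M = 2 bimodal states with centers
#'     ~1.5 standard deviations apart across classes and overlapping mixture
#'     components; weak transition structure (0.7/0.3).}
#' }
#' Defaults: T = 30 frames, 20 sequences/class, 10 pseudo-subjects.
#'
#' @return named list of \code{synthetic_spec} presets.
#' @export
default_specs <- function() {
  I2 <- diag(1, 2L)
  sticky <- matrix(c(0.9, 0.1, 0.1, 0.9), 2L, 2L)
  # separable: class centers on a radius-6 circle, states offset +/-1.5 in x
  sep_classes <- lapply(0:2, function(k) {
    ang <- 2 * pi * k / 3
    ctr <- 6 * c(cos(ang), sin(ang))
    gaussian_hmm(c(0.5, 0.5), sticky,
                 list(mix1(ctr + c(-1.5, 0), I2), mix1(ctr + c(1.5, 0), I2)))
  })
  separable <- synthetic_spec(c("A", "B", "C"), sep_classes,
                              T_range = 30L, n_sequences = 20L, n_groups = 10L)
  # correlated: identical variances, opposite feature correlation
  corr_classes <- list(
    gaussian_hmm(1, matrix(1), list(mix1(c(0, 0), cov2(1, 1, 0.9)))),
    gaussian_hmm(1, matrix(1), list(mix1(c(0.25, 0.25), cov2(1, 1, -0.9)))))
  correlated <- synthetic_spec(c("A", "B"), corr_classes,
                               T_range = 30L, n_sequences = 20L,
                               n_groups = 10L)
  # hard: overlapping bimodal states, weak transitions
  loose <- matrix(c(0.7, 0.3, 0.3, 0.7), 2L, 2L)
  hard_classes <- lapply(0:2, function(k) {
    ctr <- c(1.5 * k, 0.75 * (k %% 2))
    st <- function(off) state_mixture(
      c(0.6, 0.4),
      list(gaussian_component(ctr + off + c(-1, 0), cov2(1, 1, 0.3)),
           gaussian_component(ctr + off + c(1, 0.5), cov2(1.2, 0.8, -0.2))))
    gaussian_hmm(c(0.5, 0.5), loose, list(st(c(0, 0)), st(c(0.5, 1))))
  })
  hard <- synthetic_spec(c("A", "B", "C"), hard_classes,
                         T_range = 30L, n_sequences = 20L, n_groups = 10L)
  list(separable = separable, correlated = correlated, hard = hard)
}
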