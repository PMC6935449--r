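#' Gaussian(-mixture) hidden Markov model
#'
#' Generative comparison model: initial distribution b, row-stochastic
#' transition matrix C, and per-state Gaussian mixture emissions. Also the
#' generator behind the synthetic datasets.
#'
#' @param initial Q-vector of initial state probabilities (sums to 1).
#' @param transition Q x Q row-stochastic matrix.
#' @param emissions list of Q \code{state_mixture} objects.
#' @return object of class \code{gaussian_hmm}.
#' @export
gaussian_hmm <- function(initial, transition, emissions) {
  initial <- as.numeric(initial)
  transition <- as.matrix(transition)
  Q <- length(initial)
  if (!identical(dim(transition), c(Q, Q)) || length(emissions) != Q)
    stop("gaussian_hmm: inconsistent Q across initial/transition/emissions")
  if (any(initial < 0) || abs(sum(initial) - 1) > 1e-12)
    stop("gaussian_hmm: initial must be a probability vector")
  rs <- rowSums(transition)
  if (any(transition < 0) || any(abs(rs - 1) > 1e-12))
    stop("gaussian_hmm: transition rows must be probability vectors")
  structure(list(initial = initial, transition = transition,
                 emissions = emissions, Q = Q,
                 M = length(emissions[[1L]]$weights),
                 D = length(emissions[[1L]]$components[[1L]]$mean)),
            class = "gaussian_hmm")
}

# mixture density (probability domain) via explicit inversion -- kept
# deliberately independent of the log-space code path it cross-checks
hmm_emission_density <- function(hmm, u) {
  vapply(hmm$emissions, function(mix) {
    sum(vapply(seq_along(mix$weights), function(m) {
      comp <- mix$components[[m]]
      D <- length(comp$mean)
      Sinv <- solve(comp$covariance)
      dets <- det(comp$covariance)
      q <- drop(t(u - comp$mean) %*% Sinv %*% (u - comp$mean))
      mix$weights[m] * (2 * pi)^(-D / 2) * dets^(-0.5) * exp(-q / 2)
    }, numeric(1)))
  }, numeric(1))
}

#' Gaussian-HMM log-likelihood (independent scaled forward pass)
#'
#' Standard probability-domain forward algorithm with per-step rescaling,
#' implemented independently of the HCRF log-space forward recursion: it is
#' the oracle for the HMM-to-HCRF parameter-mapping equivalence.
#'
#' @param hmm a \code{gaussian_hmm}.
#' @param seq a \code{feature_sequence}.
#' @return scalar log p(U) under the HMM.
#' @export
hmm_log_likelihood <- function(hmm, seq) {
  if (ncol(seq$frames) != hmm$D)
    stop("hmm_log_likelihood: dimension mismatch")
  T_ <- nrow(seq$frames)
  a <- hmm$initial * hmm_emission_density(hmm, seq$frames[1L, ])
  c1 <- sum(a)
  if (c1 == 0) return(-Inf)
  loglik <- log(c1)
  a <- a / c1
  if (T_ > 1L) {
    for (t in 2:T_) {
      a <- drop(a %*% hmm$transition) * hmm_emission_density(hmm, seq$frames[t, ])
      ct <- sum(a)
      if (ct == 0) return(-Inf)
      loglik <- loglik + log(ct)
      a <- a / ct
    }
  }
  loglik
}

#' Map a Gaussian HMM onto an HCRF class block
#'
#' prior = log b, transition = log C, emissions copied verbatim. Under this
#' mapping the HCRF forward score of the block equals the HMM log-likelihood
#' exactly; zero HMM probabilities map to -Inf potentials (allowed).
#'
#' @param hmm a \code{gaussian_hmm}.
#' @return a \code{class_params}.
#' @export
hcrf_from_hmm <- function(hmm) {
  class_params(log(hmm$initial), log(hmm$transition), hmm$emissions)
}

#' Diagonal moment-feature HCRF
#'
#' The earlier HCRF parameterization whose per-frame state potential is
#' occurrence + sum_d (M1_{l,d} u_{t,d} + M2_{l,d} u_{t,d}^2): an explicit
#' linear/quadratic feature expansion that can only represent diagonal
#' Gaussians. M2 entries must be negative for the potential to complete to a
#' proper Gaussian; a violation warns.
#'
#' @param classes list (one element per class label) of lists with fields
#'   \code{prior} (Q), \code{transition} (Q x Q), \code{occurrence} (Q),
#'   \code{M1} (Q x D), \code{M2} (Q x D).
#' @param labels character vector of class labels.
#' @return object of class \code{diagonal_hcrf}.
#' @export
diagonal_hcrf <- function(classes, labels) {
  for (cl in classes) {
    if (any(cl$M2 >= 0))
      warning("diagonal_hcrf: non-negative quadratic weights do not ",
              "correspond to a proper Gaussian")
  }
  names(classes) <- labels
  structure(list(classes = classes, labels = as.character(labels)),
            class = "diagonal_hcrf")
}

#' Moment-feature weights of a diagonal Gaussian
#'
#' The exact parameter completion: occurrence_l = sum_d -(1/2)(log(2 pi
#' sigma2_{l,d}) + mu_{l,d}^2 / sigma2_{l,d}), M1 = mu / sigma2,
#' M2 = -1 / (2 sigma2), so that the per-frame potential equals
#' log N(u_t; mu_l, diag(sigma2_l)) exactly.
#'
#' @param prior Q-vector of prior potentials.
#' @param transition Q x Q transition potentials.
#' @param mu Q x D matrix of state means.
#' @param sigma2 Q x D matrix of state variances (> 0).
#' @return single-class parameter list suitable for \code{diagonal_hcrf}.
#' @export
diagonal_hcrf_from_gaussians <- function(prior, transition, mu, sigma2) {
  mu <- as.matrix(mu); sigma2 <- as.matrix(sigma2)
  if (any(sigma2 <= 0)) stop("variances must be positive")
  list(prior = as.numeric(prior), transition = as.matrix(transition),
       occurrence = rowSums(-0.5 * (log(2 * pi * sigma2) + mu^2 / sigma2)),
       M1 = mu / sigma2, M2 = -1 / (2 * sigma2))
}

#' Represent a diagonal-covariance M = 1 model in moment-feature form
#'
#' @param model a \code{gmhcrf_model} with M = 1 and diagonal covariances.
#' @return a \code{diagonal_hcrf} with identical class scores.
#' @export
diagonal_hcrf_from_model <- function(model) {
  if (model$dims["M"] != 1L)
    stop("moment-feature form is defined for M = 1 models")
  classes <- lapply(model$classes, function(cp) {
    mu <- t(vapply(cp$emissions, function(e) e$components[[1L]]$mean,
                   numeric(cp$D)))
    s2 <- t(vapply(cp$emissions, function(e) diag(e$components[[1L]]$covariance),
                   numeric(cp$D)))
    mu <- matrix(mu, cp$Q, cp$D); s2 <- matrix(s2, cp$Q, cp$D)
    diagonal_hcrf_from_gaussians(cp$prior, cp$transition, mu, s2)
  })
  diagonal_hcrf(classes, model$labels)
}

#' Score a sequence under the diagonal moment-feature HCRF
#'
#' Log-space forward recursion with the explicit per-frame potential
#' occurrence + M1 u + M2 u^2, same transition convention as the full model
#' (transitions apply for t >= 2).
#'
#' @param model a \code{diagonal_hcrf}.
#' @param seq a \code{feature_sequence}.
#' @return named vector of per-class log scores.
#' @export
diagonal_hcrf_score <- function(model, seq) {
  X <- seq$frames; T_ <- nrow(X)
  vapply(model$classes, function(cl) {
    Q <- length(cl$prior)
    # T x Q per-frame state potentials
    pot <- matrix(cl$occurrence, T_, Q, byrow = TRUE) +
      X %*% t(cl$M1) + (X^2) %*% t(cl$M2)
    la <- cl$prior + pot[1L, ]
    if (T_ > 1L) {
      for (t in 2:T_) {
        acc <- la + cl$transition
        la <- apply(acc, 2L, logsumexp) + pot[t, ]
      }
    }
    logsumexp(la)
  }, numeric(1))
}

#' Bayes-reference classifier from true generative parameters
#'
#' Likelihood-ratio classification of sequences under the true per-class
#' GMM-HMMs of a synthetic specification; upper-bounds achievable accuracy on
#' simulated data. Optionally diagonalizes every covariance first, to
#' quantify what ignoring feature correlations costs.
#'
#' @param spec a \code{synthetic_spec}.
#' @param sequences list of \code{feature_sequence} objects.
#' @param diagonalize if TRUE, zero all covariance off-diagonals before
#'   scoring.
#' @return character vector of predicted labels.
#' @export
bayes_classify <- function(spec, sequences, diagonalize = FALSE) {
  hmms <- spec$classes
  if (diagonalize) {
    hmms <- lapply(hmms, function(h) {
      ems <- lapply(h$emissions, function(mix) {
        comps <- lapply(mix$components, function(cp)
          gaussian_component(cp$mean, diag(diag(cp$covariance),
                                           length(cp$mean))))
        state_mixture(mix$weights, comps)
      })
      gaussian_hmm(h$initial, h$transition, ems)
    })
  }
  blocks <- lapply(hmms, hcrf_from_hmm)
  vapply(sequences, function(s) {
    ll <- vapply(blocks, function(b) forward(b, s)$log_score, numeric(1))
    spec$labels[which.max(ll)]
  }, character(1))
}
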