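# responsibilities r_{t,l,m} from the cached component log-density array.
# If every component underflows at some (t,l) (log mixture density -Inf) the
# responsibility is undefined; fall back to uniform 1/M with a warning so a
# line search at bad interim parameters can continue.
responsibilities_from_array <- function(comp_arr, log_emis) {
  d <- dim(comp_arr)
  resp <- array(0, dim = d)
  bad <- !is.finite(log_emis)
  for (m in seq_len(d[3]))
    resp[, , m] <- exp(matrix(comp_arr[, , m], d[1], d[2]) - log_emis)
  if (any(bad)) {
    warning("responsibilities: total emission underflow at ", sum(bad),
            " (frame, state) cells; using uniform 1/M fallback")
    for (m in seq_len(d[3])) {
      slab <- matrix(resp[, , m], d[1], d[2])
      slab[bad] <- 1 / d[3]
      resp[, , m] <- slab
    }
  }
  resp
}

#' Mixture-component responsibilities
#'
#' r_{t,l,m} = Gamma_{l,m} N(u_t; mu_{l,m}, Sigma_{l,m}) / sum_m' of the same,
#' computed in log space. If all components underflow at a (frame, state)
#' cell the row falls back to uniform 1/M with a warning.
#'
#' @inheritParams forward
#' @return T x Q x M array; each (t, l) slice sums to 1.
#' @export
responsibilities <- function(params, seq) {
  check_dims(params, seq)
  comp_arr <- component_log_density_array(params, seq$frames)
  responsibilities_from_array(comp_arr, log_emission_matrix(comp_arr))
}

check_cache <- function(cache) {
  if (!inherits(cache, "fb_cache")) stop("expected an fb_cache")
  T_ <- nrow(cache$log_alpha)
  lhs <- logsumexp(cache$log_alpha[T_, ])
  rhs <- logsumexp(cache$params$prior + cache$log_emis[1L, ] +
                     cache$log_beta[1L, ])
  tol <- 1e-6 * max(1, abs(lhs))
  if (!isTRUE(abs(lhs - rhs) <= tol))
    stop("fb_cache internally inconsistent: forward score ", lhs,
         " vs backward score ", rhs)
  invisible(cache)
}

#' Hidden-state marginals from cached forward/backward results
#'
#' Single marginals p(l_t = l | U, v) and pairwise marginals
#' p(l_t = l, l_t+1 = l' | U, v), computed from the cache without re-running
#' forward or backward.
#'
#' @param cache an \code{fb_cache}.
#' @return list with \code{single} (T x Q) and \code{pairwise}
#'   ((T-1) x Q x Q array; NULL when T = 1).
#' @export
state_marginals <- function(cache) {
  check_cache(cache)
  T_ <- nrow(cache$log_alpha); Q <- ncol(cache$log_alpha)
  single <- exp(cache$log_alpha + cache$log_beta - cache$log_score)
  pairwise <- NULL
  if (T_ > 1L) {
    pairwise <- array(0, dim = c(T_ - 1L, Q, Q))
    trans <- cache$params$transition
    for (t in seq_len(T_ - 1L)) {
      nxt <- cache$log_emis[t + 1L, ] + cache$log_beta[t + 1L, ]
      lp <- outer(cache$log_alpha[t, ], nxt, `+`) + trans - cache$log_score
      pairwise[t, , ] <- exp(lp)
    }
  }
  list(single = single, pairwise = pairwise)
}

#' Analytic gradient of the class log score
#'
#' Gradient of log Score(U, v) with respect to all parameters of one class
#' block, in the model's natural (constrained) coordinates, computed entirely
#' from the cached forward/backward results:
#' prior gradient = p(l_1 = l); transition gradient = summed pairwise
#' marginals; mixture weight, mean and covariance gradients via the
#' state marginals, the mixture responsibilities, and the Gaussian
#' log-density derivatives dlogN/dmu = Sigma^-1 (u - mu) and
#' dlogN/dSigma = 0.5 (Sigma^-1 (u-mu)(u-mu)' Sigma^-1 - Sigma^-1).
#'
#' @param params the \code{class_params} the cache was built from.
#' @param seq the \code{feature_sequence} the cache was built from.
#' @param cache an \code{fb_cache} for (params, seq).
#' @return a \code{gradient_block}: list with \code{d_prior} (Q),
#'   \code{d_transition} (Q x Q), \code{d_weights} (Q x M), \code{d_means}
#'   (Q x M x D), \code{d_covariances} (Q x M x D x D). Attribute \code{ops}
#'   counts accumulation operations (linear in T at fixed Q, M).
#' @export
grad_log_score <- function(params, seq, cache) {
  marg <- state_marginals(cache)
  T_ <- nrow(seq$frames); Q <- params$Q; M <- params$M; D <- params$D
  ops <- 0
  d_prior <- marg$single[1L, ]
  d_transition <- matrix(0, Q, Q)
  if (!is.null(marg$pairwise)) {
    for (t in seq_len(T_ - 1L)) d_transition <- d_transition + marg$pairwise[t, , ]
    ops <- ops + (T_ - 1L) * Q * Q
  }
  d_weights <- matrix(0, Q, M)
  d_means <- array(0, dim = c(Q, M, D))
  d_covariances <- array(0, dim = c(Q, M, D, D))
  X <- seq$frames
  for (l in seq_len(Q)) {
    mix <- params$emissions[[l]]
    p_l <- marg$single[, l]
    for (m in seq_len(M)) {
      w <- p_l * cache$resp[, l, m]              # per-frame weight on (l, m)
      s0 <- sum(w)
      gamma_lm <- mix$weights[m]
      d_weights[l, m] <- if (gamma_lm > 0) s0 / gamma_lm else 0
      comp <- mix$components[[m]]
      R <- comp$chol_u                           # Sigma = R'R
      Xc <- sweep(X, 2L, comp$mean)              # T x D, u_t - mu
      # Sigma^-1 (u_t - mu) for all t: solve R'R Y = Xc'
      Y <- backsolve(R, backsolve(R, t(Xc), transpose = TRUE))   # D x T
      d_means[l, m, ] <- Y %*% w
      # Sigma^-1 (sum_t w_t (u-mu)(u-mu)') Sigma^-1 = Y diag(w) Y'
      A <- Y %*% (t(Y) * w)
      Sinv <- chol2inv(R)
      d_covariances[l, m, , ] <- 0.5 * (A - s0 * Sinv)
      ops <- ops + T_ * (D + 1)
    }
  }
  structure(list(d_prior = d_prior, d_transition = d_transition,
                 d_weights = d_weights, d_means = d_means,
                 d_covariances = d_covariances),
            class = "gradient_block", ops = ops)
}

#' Regularized conditional negative log-likelihood and its gradient
#'
#' objective = -sum_i log post(v_i | U_i) + (l2/2) ||theta||^2 over the
#' unconstrained parameter vector theta, with gradient in the packed
#' coordinates. Performs exactly one forward and one backward pass per
#' (sequence, class) per evaluation; all gradients reuse the cached results.
#'
#' @param model a \code{gmhcrf_model}.
#' @param batch list of labeled \code{feature_sequence} objects.
#' @param l2 ridge strength (>= 0) on the unconstrained coordinates.
#' @param packing a \code{gmhcrf_packing} for the model (built from the model
#'   if missing).
#' @return list with \code{objective} (scalar) and \code{gradient} (flat
#'   vector in packing order).
#' @export
grad_conditional_nll <- function(model, batch, l2 = 0, packing = NULL) {
  if (inherits(batch, "feature_sequence")) batch <- list(batch)
  labs <- vapply(batch, function(s)
    if (is.null(s$label)) NA_character_ else s$label, character(1))
  if (anyNA(labs) || !all(labs %in% model$labels))
    stop("grad_conditional_nll: every sequence must carry a label in the model's label set")
  if (is.null(packing)) packing <- make_packing(model)
  theta <- pack_model(model, packing)
  nV <- length(model$labels)
  obj <- 0
  flat_grad <- numeric(length(theta))
  for (s in batch) {
    caches <- lapply(model$classes, function(cp) fb_cache(cp, s))
    scores <- unname(vapply(caches, `[[`, numeric(1), "log_score"))
    z <- logsumexp(scores)
    post <- exp(scores - z)
    vi <- match(s$label, model$labels)
    obj <- obj - (scores[vi] - z)
    # d(-log post_v)/d theta_v' = (post_v' - 1[v'=v]) * d logScore_v'/d theta
    for (v in seq_len(nV)) {
      coef <- post[v] - as.numeric(v == vi)
      gb <- grad_log_score(model$classes[[v]], s, caches[[v]])
      flat_grad <- flat_grad +
        coef * map_gradient_to_flat(gb, model$classes[[v]], v, packing)
    }
  }
  list(objective = obj + (l2 / 2) * sum(theta^2),
       gradient = flat_grad + l2 * theta)
}

# objective only (forward passes, no gradient machinery); used by the
# finite-difference oracle so each perturbed evaluation stays cheap
obj_conditional_nll <- function(model, batch, l2 = 0, packing = NULL) {
  if (inherits(batch, "feature_sequence")) batch <- list(batch)
  if (is.null(packing)) packing <- make_packing(model)
  theta <- pack_model(model, packing)
  obj <- 0
  for (s in batch) {
    scores <- unname(vapply(model$classes, function(cp) forward(cp, s)$log_score,
                            numeric(1)))
    vi <- match(s$label, model$labels)
    obj <- obj - (scores[vi] - logsumexp(scores))
  }
  obj + (l2 / 2) * sum(theta^2)
}

#' Deliberately naive objective/gradient (reference for the caching contract)
#'
#' Computes the identical objective and gradient but re-runs the forward and
#' backward recursions once per parameter family (prior, transition, weights,
#' means, covariances) for every (sequence, class) pair, the way a
#' per-family gradient implementation without result caching would. Exists
#' only so tests can assert, on the call counters, that the cached
#' implementation performs a fraction of the passes.
#'
#' @inheritParams grad_conditional_nll
#' @return as \code{grad_conditional_nll}.
#' @export
naive_grad_conditional_nll <- function(model, batch, l2 = 0, packing = NULL) {
  if (inherits(batch, "feature_sequence")) batch <- list(batch)
  if (is.null(packing)) packing <- make_packing(model)
  theta <- pack_model(model, packing)
  nV <- length(model$labels)
  obj <- 0
  flat_grad <- numeric(length(theta))
  families <- c("prior", "transition", "weights", "means", "covariances")
  for (s in batch) {
    vi <- match(s$label, model$labels)
    scores <- unname(vapply(model$classes, function(cp) forward(cp, s)$log_score,
                            numeric(1)))
    z <- logsumexp(scores)
    post <- exp(scores - z)
    obj <- obj - (scores[vi] - z)
    for (v in seq_len(nV)) {
      coef <- post[v] - as.numeric(v == vi)
      gb <- NULL
      for (fam in families) {
        # one fresh forward + backward per family: the cost being measured
        cache <- fb_cache(model$classes[[v]], s)
        gb_f <- grad_log_score(model$classes[[v]], s, cache)
        if (is.null(gb)) gb <- gb_f
        else gb[[paste0("d_", fam)]] <- gb_f[[paste0("d_", fam)]]
      }
      flat_grad <- flat_grad +
        coef * map_gradient_to_flat(gb, model$classes[[v]], v, packing)
    }
  }
  list(objective = obj + (l2 / 2) * sum(theta^2),
       gradient = flat_grad + l2 * theta)
}
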