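#' Constrained-to-unconstrained parameter packing
#'
#' Maps a \code{gmhcrf_model} to one flat real vector and back, so a
#' quasi-Newton optimizer can run unconstrained while every iterate decodes
#' to a valid model. Transform per family: identity for prior, transition and
#' means; centered softmax logits for mixture weights; lower-triangular
#' Cholesky factor with log diagonal for full covariances (log variances for
#' diagonal covariances). Any finite flat vector therefore unpacks to SPD
#' covariances and simplex weights.
#'
#' @param model a \code{gmhcrf_model} fixing labels and (Q, M, D).
#' @param cov \code{"full"} or \code{"diagonal"} covariance parameterization.
#' @return object of class \code{gmhcrf_packing} describing the layout.
#' @export
make_packing <- function(model, cov = c("full", "diagonal")) {
  cov <- match.arg(cov)
  Q <- unname(model$dims["Q"]); M <- unname(model$dims["M"])
  D <- unname(model$dims["D"])
  P <- if (cov == "full") D * (D + 1L) / 2L else D
  per_fam <- c(prior = Q, transition = Q * Q, weights = Q * M,
               means = Q * M * D, covariances = Q * M * P)
  per_class <- sum(per_fam)
  offsets <- vector("list", length(model$labels))
  base <- 0L
  for (v in seq_along(model$labels)) {
    o <- base
    fam_off <- list()
    for (fam in names(per_fam)) {
      fam_off[[fam]] <- o + seq_len(per_fam[[fam]])
      o <- o + per_fam[[fam]]
    }
    offsets[[v]] <- fam_off
    base <- base + per_class
  }
  lower_idx <- which(lower.tri(matrix(0, D, D), diag = TRUE))
  diag_pos <- match(which(diag(D) == 1), lower_idx)   # positions of L_ii
  structure(list(labels = model$labels, Q = Q, M = M, D = D, P = P,
                 cov = cov, n_params = base, offsets = offsets,
                 lower_idx = lower_idx, diag_pos = diag_pos),
            class = "gmhcrf_packing")
}

#' Pack a model into a flat unconstrained vector
#'
#' @param model a \code{gmhcrf_model} matching the packing's dimensions.
#' @param packing a \code{gmhcrf_packing}.
#' @return numeric vector of length \code{packing$n_params}.
#' @export
pack_model <- function(model, packing) {
  theta <- numeric(packing$n_params)
  Q <- packing$Q; M <- packing$M; D <- packing$D
  for (v in seq_along(packing$labels)) {
    cp <- model$classes[[v]]
    off <- packing$offsets[[v]]
    theta[off$prior] <- cp$prior
    theta[off$transition] <- as.vector(cp$transition)
    wl <- numeric(0); ml <- numeric(0); cl <- numeric(0)
    for (l in seq_len(Q)) {
      mix <- cp$emissions[[l]]
      if (any(mix$weights <= 0))
        stop("pack_model: zero mixture weights cannot be represented as logits")
      lg <- log(mix$weights)
      wl <- c(wl, lg - mean(lg))
      for (m in seq_len(M)) {
        comp <- mix$components[[m]]
        ml <- c(ml, comp$mean)
        if (packing$cov == "diagonal") {
          offd <- comp$covariance - diag(diag(comp$covariance), D)
          if (max(abs(offd)) > 1e-10)
            stop("pack_model: diagonal packing given non-diagonal covariance")
          cl <- c(cl, log(diag(comp$covariance)))
        } else {
          L <- t(chol(comp$covariance))
          p <- L[packing$lower_idx]
          p[packing$diag_pos] <- log(p[packing$diag_pos])
          cl <- c(cl, p)
        }
      }
    }
    theta[off$weights] <- wl
    theta[off$means] <- ml
    theta[off$covariances] <- cl
  }
  theta
}

#' Unpack a flat vector into a model
#'
#' Inverse of \code{pack_model} on its image; any finite vector yields a
#' valid model (simplex weights, SPD covariances).
#'
#' @param theta numeric vector of length \code{packing$n_params}.
#' @param packing a \code{gmhcrf_packing}.
#' @return a \code{gmhcrf_model}.
#' @export
unpack_model <- function(theta, packing) {
  if (length(theta) != packing$n_params)
    stop("unpack_model: theta has length ", length(theta), ", expected ",
         packing$n_params)
  Q <- packing$Q; M <- packing$M; D <- packing$D; P <- packing$P
  classes <- vector("list", length(packing$labels))
  for (v in seq_along(packing$labels)) {
    off <- packing$offsets[[v]]
    prior <- theta[off$prior]
    transition <- matrix(theta[off$transition], Q, Q)
    wl <- theta[off$weights]; ml <- theta[off$means]; cl <- theta[off$covariances]
    emissions <- vector("list", Q)
    for (l in seq_len(Q)) {
      lg <- wl[(l - 1L) * M + seq_len(M)]
      w <- exp(lg - max(lg)); w <- w / sum(w)
      comps <- vector("list", M)
      for (m in seq_len(M)) {
        mu <- ml[((l - 1L) * M + m - 1L) * D + seq_len(D)]
        p <- cl[((l - 1L) * M + m - 1L) * P + seq_len(P)]
        if (packing$cov == "diagonal") {
          Sigma <- diag(exp(p), D)
        } else {
          L <- matrix(0, D, D)
          p[packing$diag_pos] <- exp(p[packing$diag_pos])
          L[packing$lower_idx] <- p
          Sigma <- L %*% t(L)
          Sigma <- (Sigma + t(Sigma)) / 2
        }
        comps[[m]] <- gaussian_component(mu, Sigma)
      }
      emissions[[l]] <- state_mixture(w, comps)
    }
    classes[[v]] <- class_params(prior, transition, emissions)
  }
  gmhcrf_model(packing$labels, classes)
}

# Map one class's constrained gradient_block to the flat unconstrained
# coordinates (chain rule through softmax and Cholesky transforms). Returns a
# full-length vector, zero outside the class's block.
map_gradient_to_flat <- function(gb, params, class_index, packing) {
  Q <- packing$Q; M <- packing$M; D <- packing$D; P <- packing$P
  out <- numeric(packing$n_params)
  off <- packing$offsets[[class_index]]
  out[off$prior] <- gb$d_prior
  out[off$transition] <- as.vector(gb$d_transition)
  wl <- numeric(0); ml <- numeric(0); cl <- numeric(0)
  for (l in seq_len(Q)) {
    mix <- params$emissions[[l]]
    g <- gb$d_weights[l, ]
    w <- mix$weights
    wl <- c(wl, w * (g - sum(w * g)))            # softmax Jacobian
    for (m in seq_len(M)) {
      ml <- c(ml, gb$d_means[l, m, ])
      G <- matrix(gb$d_covariances[l, m, , ], D, D)
      G <- (G + t(G)) / 2                        # Sigma is symmetric
      if (packing$cov == "diagonal") {
        cl <- c(cl, diag(G) * diag(mix$components[[m]]$covariance))
      } else {
        L <- t(mix$components[[m]]$chol_u)
        GL <- 2 * (G %*% L)                      # df/dL for Sigma = L L'
        p <- GL[packing$lower_idx]
        p[packing$diag_pos] <- p[packing$diag_pos] * diag(L)  # log-diag chain
        cl <- c(cl, p)
      }
    }
  }
  out[off$weights] <- wl
  out[off$means] <- ml
  out[off$covariances] <- cl
  out
}

#' Central finite-difference gradient
#'
#' Independent oracle for gradient checks: central differences of a scalar
#' function over a flat coordinate vector.
#'
#' @param fn function of a numeric vector returning a scalar.
#' @param theta evaluation point.
#' @param h step size per coordinate.
#' @return numeric gradient vector of the same length as \code{theta}.
#' @export
finite_diff_grad <- function(fn, theta, h = 1e-5) {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (fn(tp) - fn(tm)) / (2 * h)
  }, numeric(1))
}
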