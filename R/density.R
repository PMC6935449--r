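#' Numerically stable log-sum-exp
#'
#' @param x numeric vector; \code{-Inf} entries are allowed and drop out.
#' @return log(sum(exp(x))) computed without overflow.
#' @export
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)      # all -Inf (or contains +Inf/NaN upstream)
  m + log(sum(exp(x - m)))
}

# row-wise logsumexp over the columns of a matrix
row_logsumexp <- function(X) {
  m <- apply(X, 1L, max)
  out <- m + log(rowSums(exp(X - m)))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

#' Log-density of a full-covariance Gaussian
#'
#' Evaluates log N(u; mu, Sigma) via the cached Cholesky factorization of
#' Sigma; the covariance is never explicitly inverted.
#'
#' @param u numeric D-vector.
#' @param comp a \code{gaussian_component}.
#' @return scalar log-density.
#' @export
log_gaussian_density <- function(u, comp) {
  u <- as.numeric(u)
  if (length(u) != length(comp$mean))
    stop("log_gaussian_density: dimension mismatch")
  as.numeric(log_gaussian_density_rows(matrix(u, nrow = 1L), comp))
}

# vectorized over rows of X (T x D): returns T-vector of log N(x_t; mu, Sigma)
log_gaussian_density_rows <- function(X, comp) {
  D <- length(comp$mean)
  R <- comp$chol_u                       # upper: Sigma = R'R
  logdet <- 2 * sum(log(diag(R)))
  Z <- backsolve(R, t(X) - comp$mean, transpose = TRUE)   # R' Z = (x - mu)
  quad <- colSums(Z * Z)
  -0.5 * (D * log(2 * pi) + logdet + quad)
}

#' Log-density of a Gaussian mixture
#'
#' logsumexp over components of log(weight) + component log-density.
#' Zero weights contribute \code{-Inf} terms and drop out.
#'
#' @param u numeric D-vector.
#' @param mix a \code{state_mixture}.
#' @return scalar log mixture density.
#' @export
log_mixture_density <- function(u, mix) {
  terms <- vapply(seq_along(mix$weights), function(m) {
    if (mix$weights[m] == 0) return(-Inf)
    log(mix$weights[m]) + log_gaussian_density(u, mix$components[[m]])
  }, numeric(1))
  logsumexp(terms)
}

# Weighted per-component log densities for a whole sequence under one class
# block: T x Q x M array of log(Gamma_{l,m}) + log N(u_t; mu_{l,m}, Sigma_{l,m}).
# This is the single expensive density sweep; everything downstream (forward,
# backward, responsibilities, gradients) reuses it.
component_log_density_array <- function(params, frames) {
  T_ <- nrow(frames); Q <- params$Q; M <- params$M
  arr <- array(-Inf, dim = c(T_, Q, M))
  for (l in seq_len(Q)) {
    mix <- params$emissions[[l]]
    for (m in seq_len(M)) {
      if (mix$weights[m] == 0) next
      arr[, l, m] <- log(mix$weights[m]) +
        log_gaussian_density_rows(frames, mix$components[[m]])
    }
  }
  arr
}

# T x Q matrix of per-frame per-state log mixture densities from the array
log_emission_matrix <- function(comp_arr) {
  d <- dim(comp_arr)
  if (d[3] == 1L) return(matrix(comp_arr[, , 1L], d[1], d[2]))
  out <- matrix(0, d[1], d[2])
  for (l in seq_len(d[2]))
    out[, l] <- row_logsumexp(matrix(comp_arr[, l, ], d[1], d[3]))
  out
}
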