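#' Labeled feature-vector sequence
#'
#' Container for one observation sequence: a T x D matrix of real-valued
#' feature vectors (one row per frame), an identifier, and optionally a class
#' label and a group identifier (e.g. the subject a video clip came from,
#' used for grouped cross-validation).
#'
#' @param frames numeric matrix, T rows (frames) by D columns (features);
#'   all entries must be finite, T >= 1, D >= 1.
#' @param seq_id scalar identifier for the sequence.
#' @param label optional class label (character scalar), NULL if unlabeled.
#' @param group_id optional group identifier (character scalar).
#' @return an object of class \code{feature_sequence}.
#' @export
feature_sequence <- function(frames, seq_id = "seq", label = NULL,
                             group_id = NULL) {
  frames <- as.matrix(frames)
  storage.mode(frames) <- "double"
  if (nrow(frames) < 1L || ncol(frames) < 1L)
    stop("feature_sequence: frames must be a T x D matrix with T >= 1, D >= 1")
  if (!all(is.finite(frames)))
    stop("feature_sequence: all frame entries must be finite")
  if (!is.null(label)) label <- as.character(label)
  if (!is.null(group_id)) group_id <- as.character(group_id)
  structure(list(seq_id = as.character(seq_id), group_id = group_id,
                 label = label, frames = frames),
            class = "feature_sequence")
}

#' Single full-covariance Gaussian component
#'
#' @param mean numeric D-vector.
#' @param covariance D x D symmetric positive-definite matrix. Symmetry is
#'   required to 1e-12 relative tolerance; positive definiteness is checked by
#'   Cholesky factorization.
#' @return an object of class \code{gaussian_component} carrying the upper
#'   Cholesky factor of the covariance (cached for density evaluation).
#' @export
gaussian_component <- function(mean, covariance) {
  mean <- as.numeric(mean)
  covariance <- as.matrix(covariance)
  D <- length(mean)
  if (!identical(dim(covariance), c(D, D)))
    stop("gaussian_component: covariance must be ", D, " x ", D)
  if (!all(is.finite(mean)) || !all(is.finite(covariance)))
    stop("gaussian_component: parameters must be finite")
  asym <- max(abs(covariance - t(covariance)))
  scale <- max(abs(covariance), 1)
  if (asym > 1e-12 * scale)
    stop("gaussian_component: covariance not symmetric (max asymmetry ",
         format(asym), ")")
  covariance <- (covariance + t(covariance)) / 2
  chol_u <- tryCatch(chol(covariance), error = function(e) NULL)
  if (is.null(chol_u))
    stop("gaussian_component: covariance is not positive definite")
  structure(list(mean = mean, covariance = covariance, chol_u = chol_u),
            class = "gaussian_component")
}

#' Gaussian mixture attached to one hidden state
#'
#' @param weights numeric M-vector on the probability simplex (non-negative,
#'   sums to 1 within 1e-12).
#' @param components list of M \code{gaussian_component} objects sharing D.
#' @return an object of class \code{state_mixture}.
#' @export
state_mixture <- function(weights, components) {
  weights <- as.numeric(weights)
  if (length(components) < 1L || length(weights) != length(components))
    stop("state_mixture: need M >= 1 weights matching M components")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("state_mixture: weights must be non-negative and sum to 1")
  Ds <- vapply(components, function(cp) length(cp$mean), integer(1))
  if (length(unique(Ds)) != 1L)
    stop("state_mixture: all components must share dimension D")
  structure(list(weights = weights, components = components),
            class = "state_mixture")
}

#' One class's HCRF potential block
#'
#' Prior and transition entries are unnormalized log-potentials, not
#' probabilities: no simplex constraint applies (the HCRF is globally
#' normalized). Each hidden state carries a Gaussian mixture whose
#' log-density is the state's emission potential.
#'
#' @param prior numeric Q-vector of prior potentials.
#' @param transition Q x Q matrix of transition potentials (row = from state).
#' @param emissions list of Q \code{state_mixture} objects sharing (M, D).
#' @return an object of class \code{class_params}.
#' @export
class_params <- function(prior, transition, emissions) {
  prior <- as.numeric(prior)
  transition <- as.matrix(transition)
  Q <- length(prior)
  if (Q < 1L) stop("class_params: need Q >= 1 states")
  if (!identical(dim(transition), c(Q, Q)))
    stop("class_params: transition must be Q x Q with Q = ", Q)
  if (length(emissions) != Q)
    stop("class_params: need one state_mixture per state")
  ok_fin <- all(is.finite(prior)) && all(is.finite(transition))
  # -Inf potentials are legal (zero-probability HMM entries map to them)
  if (!ok_fin && (any(is.na(prior)) || any(is.na(transition)) ||
                  any(prior == Inf) || any(transition == Inf)))
    stop("class_params: prior/transition must not contain NA or +Inf")
  Ms <- vapply(emissions, function(e) length(e$weights), integer(1))
  Ds <- vapply(emissions, function(e) length(e$components[[1]]$mean),
               integer(1))
  if (length(unique(Ms)) != 1L || length(unique(Ds)) != 1L)
    stop("class_params: all emissions must share (M, D)")
  structure(list(prior = prior, transition = transition,
                 emissions = emissions,
                 Q = Q, M = Ms[1], D = Ds[1]),
            class = "class_params")
}

#' Multi-class Gaussian-mixture HCRF model
#'
#' The model is the standard HCRF-as-discriminative-HMM construction: one
#' disjoint \code{class_params} potential block per class label, scored by the
#' forward algorithm and normalized across classes (global normalization).
#'
#' @param labels character vector of unique class labels (their order fixes
#'   tie-breaking in prediction and the posterior column order).
#' @param classes list of \code{class_params}, one per label, all sharing
#'   (Q, M, D).
#' @return an object of class \code{gmhcrf_model} with \code{dims = c(Q, M, D)}.
#' @export
gmhcrf_model <- function(labels, classes) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("gmhcrf_model: labels must be unique")
  if (length(labels) != length(classes) || length(labels) < 1L)
    stop("gmhcrf_model: need one class_params per label")
  dims <- vapply(classes, function(cp) c(cp$Q, cp$M, cp$D), numeric(3))
  if (any(dims != dims[, 1]))
    stop("gmhcrf_model: every class must share identical (Q, M, D)")
  names(classes) <- labels
  structure(list(labels = labels, classes = classes,
                 dims = c(Q = dims[1, 1], M = dims[2, 1], D = dims[3, 1])),
            class = "gmhcrf_model")
}

#' @export
print.gmhcrf_model <- function(x, ...) {
  cat("Gaussian-mixture HCRF model\n")
  cat(sprintf("  classes: %d (%s)\n", length(x$labels),
              paste(x$labels, collapse = ", ")))
  cat(sprintf("  hidden states Q = %d, mixture components M = %d, feature dim D = %d\n",
              x$dims["Q"], x$dims["M"], x$dims["D"]))
  invisible(x)
}
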