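# Call counters instrumenting the forward/backward passes. One objective+
# gradient evaluation must run exactly one forward and one backward pass per
# (sequence, class); the counters make that contract testable.
.gmhcrf_counters <- new.env(parent = emptyenv())
.gmhcrf_counters$n_forward <- 0L
.gmhcrf_counters$n_backward <- 0L

#' Reset the forward/backward call counters to zero
#' @export
reset_call_counts <- function() {
  .gmhcrf_counters$n_forward <- 0L
  .gmhcrf_counters$n_backward <- 0L
  invisible(NULL)
}

#' Read the forward/backward call counters
#' @return named list with \code{n_forward} and \code{n_backward}.
#' @export
call_counts <- function() {
  list(n_forward = .gmhcrf_counters$n_forward,
       n_backward = .gmhcrf_counters$n_backward)
}

check_dims <- function(params, seq) {
  if (!inherits(seq, "feature_sequence"))
    stop("expected a feature_sequence")
  if (ncol(seq$frames) != params$D)
    stop("dimension mismatch: sequence D = ", ncol(seq$frames),
         ", model D = ", params$D)
}

#' Forward recursion (log space)
#'
#' Computes log alpha_t(l) for one class block. The prior potential covers
#' t = 1; transition potentials apply for t = 2..T. The class score is
#' log Score(U, v) = logsumexp_l log alpha_T(l).
#'
#' @param params a \code{class_params}.
#' @param seq a \code{feature_sequence}.
#' @param log_emis optional precomputed T x Q log emission matrix (per-frame
#'   per-state log mixture densities); computed if missing.
#' @return list with \code{log_alpha} (T x Q) and \code{log_score} (scalar).
#' @export
forward <- function(params, seq, log_emis = NULL) {
  check_dims(params, seq)
  .gmhcrf_counters$n_forward <- .gmhcrf_counters$n_forward + 1L
  if (is.null(log_emis))
    log_emis <- log_emission_matrix(component_log_density_array(params, seq$frames))
  T_ <- nrow(seq$frames); Q <- params$Q
  log_alpha <- matrix(-Inf, T_, Q)
  log_alpha[1L, ] <- params$prior + log_emis[1L, ]
  if (T_ > 1L) {
    for (t in 2:T_) {
      prev <- log_alpha[t - 1L, ]
      # column l of (prev + trans[, l]) summed in log space
      acc <- prev + params$transition            # Q x Q, recycled by column
      log_alpha[t, ] <- apply(acc, 2L, logsumexp) + log_emis[t, ]
    }
  }
  list(log_alpha = log_alpha, log_score = logsumexp(log_alpha[T_, ]))
}

#' Backward recursion (log space)
#'
#' log beta_T(l) = 0; log beta_t(l) = logsumexp over l' of transition(l, l')
#' + log emission_{t+1}(l') + log beta_{t+1}(l').
#'
#' @inheritParams forward
#' @return T x Q matrix of log beta values.
#' @export
backward <- function(params, seq, log_emis = NULL) {
  check_dims(params, seq)
  .gmhcrf_counters$n_backward <- .gmhcrf_counters$n_backward + 1L
  if (is.null(log_emis))
    log_emis <- log_emission_matrix(component_log_density_array(params, seq$frames))
  T_ <- nrow(seq$frames); Q <- params$Q
  log_beta <- matrix(0, T_, Q)
  if (T_ > 1L) {
    for (t in (T_ - 1L):1L) {
      nxt <- log_emis[t + 1L, ] + log_beta[t + 1L, ]
      acc <- t(params$transition) + nxt          # column l = trans[l, ] + nxt
      log_beta[t, ] <- apply(acc, 2L, logsumexp)
    }
  }
  log_beta
}

#' Cached forward/backward results for one (sequence, class) pair
#'
#' Runs one density sweep, one forward and one backward pass and stores
#' everything the gradient computations need: log alpha, log beta, per-frame
#' per-state log mixture densities, per-frame per-state mixture
#' responsibilities, and the class log score. Gradients reuse this cache and
#' never re-run forward/backward.
#'
#' @inheritParams forward
#' @return object of class \code{fb_cache} with fields \code{log_alpha},
#'   \code{log_beta}, \code{log_emis}, \code{resp} (T x Q x M), and
#'   \code{log_score}; the generating \code{params} are carried along.
#' @export
fb_cache <- function(params, seq) {
  check_dims(params, seq)
  comp_arr <- component_log_density_array(params, seq$frames)
  log_emis <- log_emission_matrix(comp_arr)
  fw <- forward(params, seq, log_emis)
  bw <- backward(params, seq, log_emis)
  structure(list(log_alpha = fw$log_alpha, log_beta = bw,
                 log_emis = log_emis,
                 resp = responsibilities_from_array(comp_arr, log_emis),
                 log_score = fw$log_score,
                 params = params, frames = seq$frames),
            class = "fb_cache")
}

#' Brute-force log score by path enumeration (reference oracle)
#'
#' Sums the exponentiated path potential over all Q^T hidden-state paths in
#' log space. Reference implementation only; refuses instances with more than
#' 1e6 paths.
#'
#' @inheritParams forward
#' @return scalar log score.
#' @export
brute_force_log_score <- function(params, seq) {
  check_dims(params, seq)
  T_ <- nrow(seq$frames); Q <- params$Q
  if (Q^T_ > 1e6)
    stop("brute_force_log_score: refusing ", Q, "^", T_, " paths (> 1e6)")
  log_emis <- log_emission_matrix(component_log_density_array(params, seq$frames))
  paths <- as.matrix(expand.grid(rep(list(seq_len(Q)), T_)))
  vals <- apply(paths, 1L, function(p) {
    v <- params$prior[p[1L]] + log_emis[1L, p[1L]]
    if (T_ > 1L)
      for (t in 2:T_)
        v <- v + params$transition[p[t - 1L], p[t]] + log_emis[t, p[t]]
    v
  })
  logsumexp(vals)
}

#' Class posterior probabilities
#'
#' post(v | U) = exp(log Score_v - logsumexp_v' log Score_v'), the globally
#' normalized HCRF posterior over the model's label set, computed entirely in
#' log space.
#'
#' @param model a \code{gmhcrf_model}.
#' @param seq a \code{feature_sequence}.
#' @return named numeric vector of posterior probabilities (sums to 1),
#'   ordered by the model's label order.
#' @export
class_posterior <- function(model, seq) {
  scores <- vapply(model$classes, function(cp) forward(cp, seq)$log_score,
                   numeric(1))
  z <- logsumexp(scores)
  setNames(exp(scores - z), model$labels)
}

#' Predict class labels for sequences
#'
#' Argmax of the class posterior; ties broken by lowest index in the model's
#' ordered label set.
#'
#' @param object a \code{gmhcrf_model}.
#' @param newdata a \code{feature_sequence} or a list of them.
#' @param type \code{"class"} for labels, \code{"posterior"} for the full
#'   posterior matrix (rows = sequences, columns = labels).
#' @param ... unused.
#' @return character vector of labels, or a posterior matrix.
#' @export
predict.gmhcrf_model <- function(object, newdata, type = c("class", "posterior"),
                                 ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_sequence")) newdata <- list(newdata)
  post <- t(vapply(newdata, function(s) class_posterior(object, s),
                   numeric(length(object$labels))))
  colnames(post) <- object$labels
  if (type == "posterior") return(post)
  object$labels[apply(post, 1L, which.max)]
}
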