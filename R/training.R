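#' Training configuration
#'
#' @param Q hidden states per class (>= 1).
#' @param M Gaussian mixture components per state (>= 1).
#' @param l2 ridge strength on the unconstrained parameter vector (>= 0).
#' @param lbfgs_memory number of L-BFGS correction pairs.
#' @param grad_tol projected-gradient tolerance for convergence.
#' @param max_iter maximum L-BFGS iterations (0 returns the initialization).
#' @param seed integer seed controlling initialization.
#' @param init \code{"kmeans"} (seeded k-means on pooled per-class frames) or
#'   \code{"random"} (random frames as means).
#' @param cov \code{"full"} or \code{"diagonal"} covariance parameterization.
#' @return object of class \code{train_config}.
#' @export
train_config <- function(Q = 2L, M = 1L, l2 = 0.01, lbfgs_memory = 10L,
                         grad_tol = 1e-5, max_iter = 200L, seed = 1L,
                         init = c("kmeans", "random"),
                         cov = c("full", "diagonal"), verbose = FALSE) {
  init <- match.arg(init); cov <- match.arg(cov)
  if (Q < 1L || M < 1L) stop("train_config: Q and M must be >= 1")
  if (l2 < 0) stop("train_config: l2 must be >= 0")
  if (max_iter < 0L) stop("train_config: max_iter must be >= 0")
  structure(list(Q = as.integer(Q), M = as.integer(M), l2 = l2,
                 lbfgs_memory = as.integer(lbfgs_memory),
                 grad_tol = grad_tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), init = init, cov = cov,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

dataset_labels <- function(dataset) {
  labs <- vapply(dataset, function(s)
    if (is.null(s$label)) NA_character_ else s$label, character(1))
  if (anyNA(labs)) stop("all sequences must be labeled for training")
  labs
}

#' Initialize a model from labeled data
#'
#' Per class: pool all frames, cluster them into Q*M groups (seeded k-means,
#' or random frame picks for \code{init = "random"}), assign clusters to
#' (state, component) slots in order; means are the cluster centers,
#' covariances the cluster scatter plus a ridge of 1e-6 * tr(S)/D on the
#' diagonal (S = pooled class scatter), mixture weights uniform 1/M, prior
#' and transition potentials all zero. Deterministic given the seed.
#'
#' @param dataset list of labeled \code{feature_sequence} objects.
#' @param config a \code{train_config}.
#' @return a \code{gmhcrf_model} over the sorted unique labels.
#' @export
initialize_model <- function(dataset, config) {
  labs <- dataset_labels(dataset)
  labels <- sort(unique(labs))
  Q <- config$Q; M <- config$M
  D <- ncol(dataset[[1L]]$frames)
  classes <- vector("list", length(labels))
  for (v in seq_along(labels)) {
    pool <- do.call(rbind, lapply(dataset[labs == labels[v]],
                                  function(s) s$frames))
    k <- Q * M
    if (nrow(pool) < k)
      stop("initialize_model: class '", labels[v], "' has ", nrow(pool),
           " frames, fewer than Q*M = ", k)
    S <- cov(pool)
    if (nrow(pool) < 2L) S <- diag(1, D)
    ridge <- 1e-6 * sum(diag(as.matrix(S))) / D
    if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-6
    set.seed(config$seed + 7919L * v)
    if (k > 1L && nrow(pool) == k) {
      centers <- pool                  # one frame per cluster; kmeans needs k < n
      assign <- seq_len(k)
    } else if (config$init == "kmeans" && k > 1L) {
      km <- tryCatch(kmeans(pool, centers = k, nstart = 5L, iter.max = 50L),
                     error = function(e) NULL)
      if (is.null(km)) {               # e.g. fewer distinct points than k
        idx <- sample.int(nrow(pool), k)
        centers <- pool[idx, , drop = FALSE]
        assign <- apply(pool, 1L, function(u)
          which.min(colSums((t(centers) - u)^2)))
      } else {
        centers <- km$centers
        assign <- km$cluster
      }
    } else if (k == 1L) {
      centers <- matrix(colMeans(pool), 1L, D)
      assign <- rep(1L, nrow(pool))
    } else {
      idx <- sample.int(nrow(pool), k)
      centers <- pool[idx, , drop = FALSE]
      assign <- apply(pool, 1L, function(u)
        which.min(colSums((t(centers) - u)^2)))
    }
    emissions <- vector("list", Q)
    for (l in seq_len(Q)) {
      comps <- vector("list", M)
      for (m in seq_len(M)) {
        j <- (l - 1L) * M + m
        members <- pool[assign == j, , drop = FALSE]
        scatter <- if (nrow(members) >= max(2L, D + 1L))
          cov(members) else as.matrix(S)
        scatter <- as.matrix(scatter)
        if (config$cov == "diagonal")
          scatter <- diag(diag(scatter), D)
        Sigma <- scatter + diag(ridge + 1e-8, D)
        ok <- !inherits(tryCatch(chol(Sigma), error = identity), "error")
        if (!ok) Sigma <- diag(diag(scatter) + ridge + 1e-6, D)
        comps[[m]] <- gaussian_component(centers[j, ], Sigma)
      }
      emissions[[l]] <- state_mixture(rep(1 / M, M), comps)
    }
    classes[[v]] <- class_params(rep(0, Q), matrix(0, Q, Q), emissions)
  }
  gmhcrf_model(labels, classes)
}

#' Fit the Gaussian-mixture HCRF by L-BFGS
#'
#' Maximizes the conditional log-likelihood (minimizes the ridge-regularized
#' conditional NLL of \code{grad_conditional_nll}) over the unconstrained
#' packed coordinates with L-BFGS. Returns the best-objective iterate
#' encountered; the recorded history is the non-increasing sequence of
#' accepted (improving) objective values.
#'
#' @param dataset list of labeled \code{feature_sequence} objects.
#' @param config a \code{train_config}.
#' @return object of class \code{gmhcrf_fit}: list with \code{model},
#'   \code{history} (objective values, non-increasing), \code{converged},
#'   \code{n_eval}, \code{config}, \code{packing}.
#' @export
fit_gmhcrf <- function(dataset, config = train_config()) {
  model0 <- initialize_model(dataset, config)
  packing <- make_packing(model0, cov = config$cov)
  theta0 <- pack_model(model0, packing)
  ev <- new.env(parent = emptyenv())
  ev$best_obj <- Inf; ev$best_theta <- theta0
  ev$history <- numeric(0); ev$n_eval <- 0L
  ev$theta <- NULL; ev$val <- NULL
  eval_at <- function(theta) {
    # optim calls fn then gr at the same point; compute both once
    if (!is.null(ev$theta) && identical(theta, ev$theta)) return(ev$val)
    val <- grad_conditional_nll(unpack_model(theta, packing), dataset,
                                l2 = config$l2, packing = packing)
    ev$theta <- theta; ev$val <- val
    ev$n_eval <- ev$n_eval + 1L
    if (is.finite(val$objective) && val$objective < ev$best_obj) {
      ev$best_obj <- val$objective
      ev$best_theta <- theta
      ev$history <- c(ev$history, val$objective)
      if (isTRUE(config$verbose))
        message(sprintf("iter=%d objective=%.8g grad_norm=%.4g",
                        length(ev$history) - 1L, val$objective,
                        sqrt(sum(val$gradient^2))))
    }
    val
  }
  v0 <- eval_at(theta0)
  if (!is.finite(v0$objective))
    stop("fit_gmhcrf: non-finite objective at initialization; ",
         "increase the covariance ridge or rescale the features")
  if (config$max_iter == 0L) {
    return(structure(list(model = model0, history = ev$history,
                          converged = FALSE, n_eval = ev$n_eval,
                          config = config, packing = packing),
                     class = "gmhcrf_fit"))
  }
  fn <- function(theta) {
    v <- eval_at(theta)$objective
    if (!is.finite(v)) 1e10 else v
  }
  gr <- function(theta) {
    g <- eval_at(theta)$gradient
    g[!is.finite(g)] <- 0
    g
  }
  res <- tryCatch(
    optim(theta0, fn = fn, gr = gr, method = "L-BFGS-B",
          control = list(maxit = config$max_iter, lmm = config$lbfgs_memory,
                         pgtol = config$grad_tol, factr = 1e3)),
    error = function(e) e)
  if (inherits(res, "error") || (is.list(res) && res$convergence == 52L))
    warning("fit_gmhcrf: line search failed; returning best iterate (",
            if (inherits(res, "error")) conditionMessage(res) else res$message,
            ")")
  structure(list(model = unpack_model(ev$best_theta, packing),
                 history = ev$history,
                 converged = is.list(res) && !inherits(res, "error") &&
                   res$convergence == 0L,
                 n_eval = ev$n_eval, config = config, packing = packing),
            class = "gmhcrf_fit")
}

#' Fit the diagonal-covariance HCRF baseline
#'
#' Same training loop as \code{fit_gmhcrf} with the covariances constrained
#' to be diagonal (the moment-feature HCRF: per-state per-dimension linear
#' and quadratic weights, equivalent to diagonal Gaussians).
#'
#' @inheritParams fit_gmhcrf
#' @return a \code{gmhcrf_fit} whose model has diagonal covariances.
#' @export
fit_diagonal <- function(dataset, config = train_config()) {
  config$cov <- "diagonal"
  fit_gmhcrf(dataset, config)
}

#' Randomized analytic-vs-finite-difference gradient check
#'
#' Draws random small models and sequences and compares the analytic
#' gradient of the regularized conditional NLL against central finite
#' differences over the packed coordinates.
#'
#' @param seed integer seed.
#' @param trials number of random instances.
#' @param tol maximum allowed relative error (with a 1e-6 absolute floor for
#'   near-zero coordinates).
#' @return list with \code{ok}, \code{worst} (worst relative error),
#'   \code{worst_coord}, and per-trial errors. \code{ok} is TRUE when every
#'   trial is within \code{tol}.
#' @export
gradcheck <- function(seed = 1L, trials = 10L, tol = 1e-4) {
  set.seed(seed)
  errs <- numeric(trials); coords <- integer(trials)
  for (i in seq_len(trials)) {
    Q <- sample(1:3, 1); M <- sample(1:2, 1); D <- sample(1:3, 1)
    T_ <- sample(2:8, 1); nV <- sample(2:3, 1)
    model <- random_model(nV, Q, M, D)
    packing <- make_packing(model)
    batch <- lapply(seq_len(2L), function(j)
      feature_sequence(matrix(rnorm(T_ * D), T_, D), seq_id = paste0("s", j),
                       label = model$labels[sample(nV, 1)]))
    theta <- pack_model(model, packing)
    an <- grad_conditional_nll(model, batch, l2 = 0.05, packing = packing)
    fd <- finite_diff_grad(function(th)
      obj_conditional_nll(unpack_model(th, packing), batch, l2 = 0.05,
                          packing = packing), theta)
    rel <- abs(an$gradient - fd) / pmax(abs(fd), 1e-6 / tol)
    errs[i] <- max(rel); coords[i] <- which.max(rel)
  }
  list(ok = all(errs <= tol), worst = max(errs),
       worst_coord = coords[which.max(errs)], errors = errs)
}

# random valid model used by gradcheck and the test helpers
random_model <- function(n_classes, Q, M, D, spread = 1.5) {
  classes <- lapply(seq_len(n_classes), function(v) {
    emissions <- lapply(seq_len(Q), function(l) {
      comps <- lapply(seq_len(M), function(m) {
        A <- matrix(rnorm(D * D, sd = 0.4), D, D)
        gaussian_component(rnorm(D, sd = spread),
                           crossprod(A) + diag(0.5, D))
      })
      w <- runif(M, 0.2, 1); w <- w / sum(w)
      state_mixture(w, comps)
    })
    class_params(rnorm(Q, sd = 0.5), matrix(rnorm(Q * Q, sd = 0.5), Q, Q),
                 emissions)
  })
  gmhcrf_model(paste0("c", seq_len(n_classes)), classes)
}
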