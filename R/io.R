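#' Read a sequence dataset from CSV
#'
#' Expected header: \code{seq_id, group_id, label, t, f0..f<D-1>} (comma
#' separated, '.' decimal, UTF-8). Within a sequence the label and group must
#' be constant and \code{t} must run 0..T-1 without gaps or duplicates; empty
#' \code{label}/\code{group_id} cells mean unlabeled/ungrouped. Violations
#' raise a parse error naming the offending file line.
#'
#' @param path CSV file path.
#' @return list of \code{feature_sequence} objects with attributes \code{D}
#'   and \code{labels} (observed label set).
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("read_sequences: no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(seq_id = "character", group_id = "character",
                                label = "character"))
  need <- c("seq_id", "group_id", "label", "t")
  if (!identical(names(df)[1:4], need))
    stop("read_sequences: header must start with ",
         paste(need, collapse = ", "))
  fcols <- names(df)[-(1:4)]
  D <- length(fcols)
  if (D < 1L || !identical(fcols, paste0("f", seq_len(D) - 1L)))
    stop("read_sequences: feature columns must be f0..f", D - 1L)
  if (!all(vapply(df[fcols], is.numeric, logical(1))))
    stop("read_sequences: feature columns must be numeric")
  lines <- seq_len(nrow(df)) + 1L      # header is file line 1
  out <- list()
  for (id in unique(df$seq_id)) {
    rows <- which(df$seq_id == id)
    sub <- df[rows, , drop = FALSE]
    dup <- duplicated(sub$t)
    if (any(dup))
      stop("read_sequences: duplicated (seq_id, t) at line ",
           lines[rows[dup][1L]], " (seq_id = ", id, ")")
    o <- order(sub$t)
    sub <- sub[o, , drop = FALSE]
    if (!identical(as.integer(sub$t), seq_len(nrow(sub)) - 1L))
      stop("read_sequences: t values of seq_id ", id,
           " are not contiguous from 0 (near line ", lines[rows[1L]], ")")
    if (length(unique(sub$label)) != 1L)
      stop("read_sequences: conflicting labels within seq_id ", id,
           " (near line ", lines[rows[1L]], ")")
    if (length(unique(sub$group_id)) != 1L)
      stop("read_sequences: conflicting group_id within seq_id ", id,
           " (near line ", lines[rows[1L]], ")")
    lab <- sub$label[1L]; grp <- sub$group_id[1L]
    out[[length(out) + 1L]] <- feature_sequence(
      as.matrix(sub[fcols]), seq_id = id,
      label = if (is.na(lab) || lab == "") NULL else lab,
      group_id = if (is.na(grp) || grp == "") NULL else grp)
  }
  labs <- unlist(lapply(out, `[[`, "label"))
  attr(out, "D") <- D
  attr(out, "labels") <- sort(unique(labs))
  out
}

#' Write a sequence dataset to CSV
#'
#' Inverse of \code{\link{read_sequences}}; unlabeled/ungrouped sequences get
#' empty cells.
#'
#' @param dataset list of \code{feature_sequence} objects sharing D.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_sequences <- function(dataset, path) {
  D <- ncol(dataset[[1L]]$frames)
  rows <- lapply(dataset, function(s) {
    T_ <- nrow(s$frames)
    fr <- as.data.frame(s$frames)
    names(fr) <- paste0("f", seq_len(D) - 1L)
    cbind(data.frame(seq_id = s$seq_id,
                     group_id = if (is.null(s$group_id)) "" else s$group_id,
                     label = if (is.null(s$label)) "" else s$label,
                     t = seq_len(T_) - 1L),
          fr)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

model_format_version <- "1.0"

#' Serialize a model to JSON
#'
#' Schema-versioned JSON with full covariance matrices, written at full
#' double precision so read/write round-trips are lossless.
#'
#' @param model a \code{gmhcrf_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- list(
    format_version = model_format_version,
    labels = model$labels,
    Q = unname(model$dims["Q"]), M = unname(model$dims["M"]),
    D = unname(model$dims["D"]),
    classes = lapply(model$classes, function(cp) list(
      prior = cp$prior,
      transition = cp$transition,
      states = lapply(cp$emissions, function(mix) list(
        weights = mix$weights,
        means = lapply(mix$components, `[[`, "mean"),
        covariances = lapply(mix$components, `[[`, "covariance"))))))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a model from JSON
#'
#' Validates the schema version and every type invariant (simplex weights,
#' symmetric positive-definite covariances); corrupt files are refused.
#'
#' @param path JSON path written by \code{\link{write_model}}.
#' @return a \code{gmhcrf_model}.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(doc$format_version) ||
      !identical(as.character(doc$format_version), model_format_version))
    stop("read_model: unknown format_version: ",
         if (is.null(doc$format_version)) "<missing>" else doc$format_version)
  D <- as.integer(doc$D)
  classes <- lapply(seq_along(doc$labels), function(v) {
    cl <- doc$classes[[v]]
    emissions <- lapply(cl$states, function(st) {
      means <- st$means; covs <- st$covariances
      comps <- lapply(seq_along(st$weights), function(m) {
        mu <- as.numeric(if (is.matrix(means)) means[m, ] else means[[m]])
        Sg <- if (is.array(covs) && length(dim(covs)) == 3L)
          matrix(covs[m, , ], D, D) else as.matrix(covs[[m]])
        gaussian_component(mu, Sg)
      })
      state_mixture(as.numeric(st$weights), comps)
    })
    class_params(as.numeric(cl$prior), matrix(as.numeric(cl$transition),
                                              as.integer(doc$Q),
                                              as.integer(doc$Q),
                                              byrow = FALSE),
                 emissions)
  })
  gmhcrf_model(as.character(doc$labels), classes)
}
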