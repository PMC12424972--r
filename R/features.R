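# Feature assembly, robust scaling and top-k univariate selection.

#' Assemble the subjects x features matrix
#'
#' Builds the predictor matrix for one feature set: per-subject aligned node
#' embeddings flattened parcel-major (parcel 1 dims 1..d, parcel 2 dims 1..d,
#' ...), and/or observed and embedding-implied connectivity edges, with the
#' demographic covariates always appended last. Column provenance (parcel and
#' dimension, edge endpoints, or covariate name) is kept alongside the matrix.
#'
#' @param embeddings named list (by subject id) of aligned `node_embedding`s;
#'   required for the `embeddings`, `implied`, `observed+embeddings` and `all`
#'   sets.
#' @param covariates a `covariate_matrix` covering the same subjects.
#' @param feature_set one of `"embeddings"`, `"observed"`, `"implied"`,
#'   `"observed+embeddings"`, `"all"`.
#' @param conns named list of `connectivity_matrix` per subject (needed for
#'   `observed` sets).
#' @param parcellation a `parcellation` (for column metadata).
#' @return An object of class `feature_matrix`: `subject`, `values`
#'   (subjects x features), `meta` (data frame: type, parcel, dim, i, j,
#'   name), `feature_set`.
#' @export
assemble_features <- function(embeddings = NULL, covariates = NULL,
                              feature_set = c("embeddings", "observed",
                                              "implied",
                                              "observed+embeddings", "all"),
                              conns = NULL, parcellation = NULL) {
  feature_set <- match.arg(feature_set)
  need_emb <- feature_set != "observed"
  need_obs <- feature_set %in% c("observed", "observed+embeddings", "all")
  if (need_emb && is.null(embeddings)) stop("this feature set needs embeddings")
  if (need_obs && is.null(conns)) stop("this feature set needs connectivity matrices")
  subjects <- if (need_emb) names(embeddings) else names(conns)
  if (is.null(subjects)) stop("inputs must be named by subject id")

  blocks <- list(); metas <- list()
  if (feature_set %in% c("embeddings", "observed+embeddings", "all")) {
    P <- nrow(embeddings[[1L]]$vectors); d <- ncol(embeddings[[1L]]$vectors)
    emb_mat <- t(vapply(embeddings,
                        function(e) as.numeric(t(e$vectors)), numeric(P * d)))
    pid <- if (!is.null(parcellation)) parcellation$parcel_ids else
      paste0("p", seq_len(P))
    metas[[length(metas) + 1L]] <- data.frame(
      type = "embedding", parcel = rep(pid, each = d),
      dim = rep(seq_len(d), times = P), i = NA_integer_, j = NA_integer_,
      name = paste0(rep(pid, each = d), ".e", rep(seq_len(d), times = P)))
    blocks[[length(blocks) + 1L]] <- emb_mat
  }
  if (need_obs) {
    ev1 <- vectorize_edges(conns[[1L]])
    idx <- attr(ev1, "index")
    obs_mat <- t(vapply(conns, function(cn) as.numeric(vectorize_edges(cn)),
                        numeric(length(ev1))))
    metas[[length(metas) + 1L]] <- data.frame(
      type = "observed_edge", parcel = NA_character_, dim = NA_integer_,
      i = idx[, 1L], j = idx[, 2L],
      name = paste0("obs.", idx[, 1L], ".", idx[, 2L]))
    blocks[[length(blocks) + 1L]] <- obs_mat
  }
  if (feature_set %in% c("implied", "all")) {
    imp <- lapply(embeddings, implied_connectivity)
    ev1 <- vectorize_edges(imp[[1L]])
    idx <- attr(ev1, "index")
    imp_mat <- t(vapply(imp, function(m) as.numeric(vectorize_edges(m)),
                        numeric(length(ev1))))
    metas[[length(metas) + 1L]] <- data.frame(
      type = "implied_edge", parcel = NA_character_, dim = NA_integer_,
      i = idx[, 1L], j = idx[, 2L],
      name = paste0("imp.", idx[, 1L], ".", idx[, 2L]))
    blocks[[length(blocks) + 1L]] <- imp_mat
  }
  if (!is.null(covariates)) {
    ord <- match(subjects, covariates$subject)
    if (anyNA(ord)) stop("covariates missing for some subjects")
    cov_mat <- covariates$values[ord, , drop = FALSE]
    metas[[length(metas) + 1L]] <- data.frame(
      type = "covariate", parcel = NA_character_, dim = NA_integer_,
      i = NA_integer_, j = NA_integer_, name = colnames(cov_mat))
    blocks[[length(blocks) + 1L]] <- cov_mat
  }
  values <- do.call(cbind, blocks)
  meta <- do.call(rbind, metas)
  rownames(values) <- subjects
  colnames(values) <- meta$name
  if (!all(is.finite(values))) stop("feature matrix contains non-finite values")
  structure(list(subject = subjects, values = values, meta = meta,
                 feature_set = feature_set),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d subjects x %d features (%d covariates)\n",
              x$feature_set, nrow(x$values), ncol(x$values),
              sum(x$meta$type == "covariate")))
  invisible(x)
}

#' Fit a robust (median / IQR) scaler on discovery data
#'
#' Per-column center = median, scale = interquartile range, both computed on
#' the discovery rows only. Zero-IQR columns get scale 1 and are flagged so
#' they pass through as centered constants.
#'
#' @param X numeric matrix (discovery rows).
#' @return An object of class `scaler_params`: `center`, `scale`,
#'   `zero_iqr` (logical per column).
#' @export
fit_scaler <- function(X) {
  if (nrow(X) == 0L) stop("cannot fit a scaler on an empty matrix")
  center <- apply(X, 2, median)
  qs <- apply(X, 2, quantile, probs = c(0.25, 0.75), names = FALSE)
  scale <- qs[2L, ] - qs[1L, ]
  zero <- scale == 0
  scale[zero] <- 1
  structure(list(center = center, scale = scale, zero_iqr = zero),
            class = "scaler_params")
}

#' Apply stored scaler parameters
#' @param X numeric matrix.
#' @param params a `scaler_params` fit on discovery data.
#' @return the scaled matrix `(X - center) / scale`.
#' @export
apply_scaler <- function(X, params) {
  if (ncol(X) != length(params$center)) stop("column count does not match scaler")
  sweep(sweep(X, 2, params$center, "-"), 2, params$scale, "/")
}

#' Top-k univariate feature selection
#'
#' Ranks every column by its simple-linear-regression F statistic against y
#' (equivalently by squared Pearson correlation) and returns the indices of
#' the k strongest, ties broken by ascending column index. Zero-variance
#' columns rank last.
#'
#' @param X numeric matrix (scaled discovery features).
#' @param y numeric outcome, no missing values.
#' @param k number of features to keep (default 1000).
#' @return integer vector of column indices, ordered strongest first, with the
#'   per-column F statistics in attribute `scores`.
#' @export
select_top_k <- function(X, y, k = 1000L) {
  if (anyNA(y)) stop("y must have no missing values in discovery")
  n <- nrow(X)
  if (length(y) != n) stop("y length must match rows of X")
  r <- suppressWarnings(as.numeric(cor(X, y)))
  r[!is.finite(r)] <- 0
  r2 <- pmin(r^2, 1 - 1e-15)
  f <- (n - 2) * r2 / (1 - r2)
  if (k > ncol(X)) {
    warning(sprintf("k = %d exceeds the %d available columns; keeping all", k,
                    ncol(X)))
    k <- ncol(X)
  }
  ord <- order(-f, seq_along(f))[seq_len(k)]
  attr(ord, "scores") <- f
  ord
}
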