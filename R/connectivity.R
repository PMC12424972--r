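#' Connectivity matrix container
#'
#' Symmetric P x P Pearson correlation matrix with unit diagonal, optionally
#' carrying its parcellation.
#'
#' @param values numeric P x P matrix.
#' @param parcellation optional `parcellation` of matching size.
#' @param tol symmetry tolerance.
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, parcellation = NULL, tol = 1e-8) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity matrix must be square")
  if (!all(is.finite(values))) stop("connectivity contains non-finite values")
  if (max(abs(values - t(values))) > tol) stop("connectivity matrix is not symmetric")
  values <- (values + t(values)) / 2
  if (max(abs(diag(values) - 1)) > tol) stop("diagonal must be 1")
  if (any(values < -1 - tol) || any(values > 1 + tol))
    stop("entries must lie in [-1, 1]")
  diag(values) <- 1
  if (!is.null(parcellation) && n_parcels(parcellation) != nrow(values))
    stop("parcellation size does not match the matrix")
  if (!is.null(parcellation))
    dimnames(values) <- list(parcellation$parcel_ids, parcellation$parcel_ids)
  structure(list(values = values, parcellation = parcellation),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: %d x %d, mean off-diagonal %.3f\n",
              nrow(x$values), ncol(x$values),
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Vectorize the unique edges of a connectivity matrix
#'
#' Strict upper triangle in row-major order (edge (1,2), (1,3), ..., (2,3),
#' ...), so a P-parcel matrix yields P(P-1)/2 values; for the 352-parcel atlas
#' that is 61,776 edges.
#'
#' @param conn a `connectivity_matrix` or symmetric numeric matrix.
#' @return numeric vector of length P(P-1)/2 with an `index` attribute giving
#'   the (i, j) pair for every entry.
#' @export
vectorize_edges <- function(conn) {
  m <- if (inherits(conn, "connectivity_matrix")) conn$values else as.matrix(conn)
  if (nrow(m) != ncol(m)) stop("edge vectorization needs a square matrix")
  P <- nrow(m)
  # row-major strict upper triangle: transpose trick over the lower triangle
  idx <- which(lower.tri(m), arr.ind = TRUE)  # column-major over t(m)
  tm <- t(m)
  v <- tm[lower.tri(tm)]
  attr(v, "index") <- cbind(i = idx[, 2L], j = idx[, 1L])
  v
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_edges()]: fills the strict upper triangle in
#' row-major order, mirrors it, and sets a unit diagonal.
#'
#' @param edges numeric vector of length P(P-1)/2.
#' @param P parcel count.
#' @return P x P symmetric numeric matrix with unit diagonal.
#' @export
edges_to_matrix <- function(edges, P) {
  if (length(edges) != P * (P - 1) / 2)
    stop("edge vector length must be P(P-1)/2")
  m <- matrix(0, P, P)
  tm <- t(m)
  tm[lower.tri(tm)] <- edges
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- 1
  m
}

#' Write a connectivity matrix as delimited text
#' @param conn a `connectivity_matrix`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_connectivity <- function(conn, path, sep = "\t") {
  utils::write.table(conn$values, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a connectivity matrix from delimited text
#' @param path input path (square matrix with parcel-id header).
#' @param parcellation optional `parcellation`.
#' @param sep field separator.
#' @return a `connectivity_matrix`.
#' @export
read_connectivity <- function(path, parcellation = NULL, sep = "\t") {
  m <- as.matrix(read.delim(path, sep = sep, check.names = FALSE))
  connectivity_matrix(unname(m), parcellation)
}
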