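#' Embedding configuration
#'
#' Settings for the biased-random-walk + skip-gram node embedding. The latent
#' dimensionality follows the reference analysis (30 dimensions at full
#' scale); the walk and training knobs use conventional node2vec settings and
#' are all overridable.
#'
#' @param dims latent dimensions (>= 2); 30 at full scale.
#' @param p return bias: probability of revisiting the previous node scales
#'   with 1/p.
#' @param q in-out bias: probability of moving beyond the previous node's
#'   neighborhood scales with 1/q.
#' @param walk_length steps per walk (must exceed `window`).
#' @param walks_per_node walks started at every node.
#' @param window skip-gram context half-width.
#' @param negatives negative samples per positive pair.
#' @param epochs training passes over the corpus.
#' @param lr,lr_min initial and final learning rate (linear decay).
#' @param seed integer seed driving walks and training.
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(dims = 30L, p = 1, q = 1, walk_length = 80L,
                             walks_per_node = 10L, window = 10L,
                             negatives = 5L, epochs = 5L, lr = 0.025,
                             lr_min = 1e-4, seed = 42L) {
  if (dims < 2L) stop("dims must be >= 2")
  if (p <= 0 || q <= 0) stop("p and q must be positive")
  if (walk_length < window + 1L) stop("walk_length must be >= window + 1")
  if (any(c(walk_length, walks_per_node, window, negatives, epochs) < 1L))
    stop("all counts must be positive")
  structure(list(dims = as.integer(dims), p = p, q = q,
                 walk_length = as.integer(walk_length),
                 walks_per_node = as.integer(walks_per_node),
                 window = as.integer(window), negatives = as.integer(negatives),
                 epochs = as.integer(epochs), lr = lr, lr_min = lr_min,
                 seed = as.integer(seed)),
            class = "embedding_config")
}

#' Turn a connectivity matrix into a non-negative walk graph
#'
#' Random-walk transition weights must be non-negative, so negative
#' correlations are either clipped to zero (default) or replaced by their
#' absolute value. The diagonal is zeroed.
#'
#' @param conn a `connectivity_matrix`.
#' @param negative_policy `"zero"` (clip) or `"absolute"`.
#' @return An object of class `walk_graph` with fields `weights` (P x P) and
#'   `parcellation`.
#' @export
to_walk_graph <- function(conn, negative_policy = c("zero", "absolute")) {
  negative_policy <- match.arg(negative_policy)
  w <- conn$values
  diag(w) <- 0
  w <- if (negative_policy == "zero") pmax(w, 0) else abs(w)
  deg <- rowSums(w > 0)
  if (any(deg == 0)) {
    bad <- rownames(w)[deg == 0]
    if (is.null(bad)) bad <- which(deg == 0)
    stop("isolated node(s) after weight policy: ", paste(bad, collapse = ", "))
  }
  structure(list(weights = w, parcellation = conn$parcellation),
            class = "walk_graph")
}

#' Simulate biased random walks
#'
#' Starts `walks_per_node` walks at every node; each step moves to a neighbor
#' with probability proportional to edge weight times the second-order bias
#' (1/p toward the previous node, 1 within its neighborhood, 1/q outward).
#' Walks hitting a dead end truncate; the count is recorded in the
#' `n_truncated` attribute.
#'
#' @param graph a `walk_graph`.
#' @param cfg an `embedding_config`.
#' @return list of integer walks (1-based node indices), class `walk_corpus`.
#' @export
simulate_walks <- function(graph, cfg = embedding_config()) {
  walks <- .simulate_walks_cpp(graph$weights, cfg$p, cfg$q, cfg$walk_length,
                               cfg$walks_per_node, cfg$seed)
  class(walks) <- "walk_corpus"
  walks
}

#' Train node vectors with skip-gram negative sampling
#'
#' Slides a window over every walk and trains (center, context) pairs with
#' negative sampling; returns the input-side vectors. Deterministic under a
#' fixed seed (single-threaded).
#'
#' @param corpus a `walk_corpus` (list of integer walks).
#' @param n_nodes number of nodes P; every node must appear in the corpus.
#' @param cfg an `embedding_config`.
#' @param init optional warm start: a `node_embedding` (or list with `vectors`
#'   and `context`) whose vectors initialize training, e.g. a group reference.
#' @return An object of class `node_embedding`: `vectors` (P x dims),
#'   `context` (output-side vectors), `aligned` flag, `config`.
#' @export
train_embedding <- function(corpus, n_nodes, cfg = embedding_config(),
                            init = NULL) {
  seen <- unique(unlist(corpus, use.names = FALSE))
  missing_nodes <- setdiff(seq_len(n_nodes), seen)
  if (length(missing_nodes) > 0L)
    stop("node(s) absent from the walk corpus: ",
         paste(head(missing_nodes, 5L), collapse = ", "))
  init_w <- init_c <- NULL
  if (!is.null(init)) {
    init_w <- init$vectors
    init_c <- init$context
  }
  fit <- .sgns_train_cpp(unclass(corpus), n_nodes, cfg$dims, cfg$window,
                         cfg$negatives, cfg$epochs, cfg$lr, cfg$lr_min,
                         cfg$seed, init_w, init_c)
  structure(list(vectors = fit$w, context = fit$c, aligned = FALSE,
                 config = cfg),
            class = "node_embedding")
}

#' @export
print.node_embedding <- function(x, ...) {
  cat(sprintf("node_embedding: %d nodes x %d dims%s\n", nrow(x$vectors),
              ncol(x$vectors), if (isTRUE(x$aligned)) " (aligned)" else ""))
  invisible(x)
}

#' Embed one connectivity matrix
#'
#' Convenience wrapper: build the walk graph, simulate walks, train, and (if a
#' reference is supplied) warm-start from the reference vectors and align the
#' result to it with orthogonal Procrustes.
#'
#' @param conn a `connectivity_matrix`.
#' @param cfg an `embedding_config`.
#' @param ref optional `reference_embedding` for warm start + alignment.
#' @param negative_policy passed to [to_walk_graph()].
#' @return a `node_embedding`.
#' @export
embed_connectivity <- function(conn, cfg = embedding_config(), ref = NULL,
                               negative_policy = "zero") {
  graph <- to_walk_graph(conn, negative_policy)
  corpus <- simulate_walks(graph, cfg)
  emb <- train_embedding(corpus, nrow(graph$weights), cfg, init = ref)
  if (!is.null(ref)) emb <- align_to_reference(emb, ref)
  emb
}

#' Element-wise mean of connectivity matrices
#' @param conns list of `connectivity_matrix` objects of equal size.
#' @return a `connectivity_matrix` (the group mean).
#' @export
group_mean_connectivity <- function(conns) {
  if (length(conns) < 2L) stop("need at least 2 subjects for a group mean")
  m <- Reduce(`+`, lapply(conns, function(cn) cn$values)) / length(conns)
  connectivity_matrix(m, conns[[1L]]$parcellation)
}

#' Train the group reference embedding
#'
#' Embeds the group-mean connectivity under a fixed seed. Subjects are
#' warm-started from and aligned to this reference so their latent dimensions
#' are comparable across the cohort.
#'
#' @param group_mean_conn a `connectivity_matrix` (mean over >= 2 subjects).
#' @param cfg an `embedding_config`.
#' @return a `node_embedding` with class `reference_embedding` prepended.
#' @export
build_reference <- function(group_mean_conn, cfg = embedding_config()) {
  emb <- embed_connectivity(group_mean_conn, cfg)
  class(emb) <- c("reference_embedding", class(emb))
  emb
}

#' Align an embedding to a reference by orthogonal Procrustes
#'
#' Finds the orthogonal matrix R minimizing ||emb R - ref||_F (no scaling,
#' no translation) and applies it. Cosine similarities among the subject's own
#' nodes are rotation invariant, so implied connectivity is unchanged.
#'
#' @param emb a `node_embedding`.
#' @param ref a `reference_embedding` (or any embedding of matching shape).
#' @return the aligned `node_embedding`.
#' @export
align_to_reference <- function(emb, ref) {
  A <- emb$vectors
  B <- ref$vectors
  if (!all(dim(A) == dim(B))) stop("embedding and reference dimensions differ")
  sv <- svd(crossprod(A, B))
  R <- sv$u %*% t(sv$v)
  emb$vectors <- A %*% R
  if (!is.null(emb$context)) emb$context <- emb$context %*% R
  emb$aligned <- TRUE
  emb
}

#' Embedding-implied connectivity
#'
#' Pairwise cosine similarity among all node vectors: the latent-space
#' reconstruction of the connectivity matrix.
#'
#' @param emb a `node_embedding`.
#' @return symmetric P x P numeric matrix with unit diagonal, entries in
#'   [-1, 1].
#' @export
implied_connectivity <- function(emb) {
  V <- emb$vectors
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm == 0))
    stop("zero-norm node vector(s): ", paste(which(nrm == 0), collapse = ", "))
  Vn <- V / nrm
  s <- tcrossprod(Vn)
  s[s > 1] <- 1; s[s < -1] <- -1
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

#' Fidelity of implied connectivity
#'
#' Pearson correlation between the unique edges of the implied and observed
#' connectivity matrices; high values mean the latent space faithfully
#' reconstructs observed connectivity.
#'
#' @param implied P x P matrix (e.g. from [implied_connectivity()]).
#' @param observed a `connectivity_matrix` or P x P matrix.
#' @return scalar Pearson r over the strict upper triangles.
#' @export
embedding_fidelity <- function(implied, observed) {
  a <- vectorize_edges(implied)
  b <- vectorize_edges(observed)
  if (length(a) != length(b)) stop("matrices have different sizes")
  if (sd(a) == 0 || sd(b) == 0) stop("constant edge vector: fidelity undefined")
  cor(a, b)
}

#' Write node vectors with a metadata sidecar
#' @param emb a `node_embedding`.
#' @param path output path for the P x dims matrix (tab-separated, parcel ids
#'   as row names when available).
#' @param parcellation optional `parcellation` supplying row labels.
#' @export
write_embedding <- function(emb, path, parcellation = NULL) {
  m <- emb$vectors
  if (!is.null(parcellation)) rownames(m) <- parcellation$parcel_ids
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  meta <- c(unclass(emb$config), list(aligned = isTRUE(emb$aligned)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Derive a reproducible stream seed from a global seed and a label
#'
#' Stable polynomial hash of the label folded with the global seed, so
#' per-subject / per-specification streams never collide with or perturb each
#' other when items are added. Always in [0, 2^31).
#'
#' @param seed integer global seed.
#' @param label character scope label (e.g. subject id, spec id).
#' @return integer in [0, 2^31).
#' @export
derive_seed <- function(seed, label) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(paste0(seed, ":", label)))
    h <- (h * 131 + b) %% 2147483647  # stays exact in doubles
  as.integer(h)
}
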