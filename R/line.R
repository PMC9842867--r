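#' LINE node embeddings of a contact-map graph
#'
#' Learns an E-dimensional representation for every locus of the weighted
#' graph defined by a contact map, by edge-sampling stochastic gradient
#' descent on the LINE objective (KL divergence between the empirical edge
#' distribution and the model's conditional context distribution). Edges are
#' sampled with probability proportional to their weight, so heavily
#' interacting locus pairs dominate the objective; negative nodes are drawn
#' from the weighted-degree^(3/4) noise distribution. The default trains
#' second-order proximity (separate context vectors); first-order proximity
#' is available behind `order = 1`.
#'
#' Embeddings are computed on the raw-weight graph; the Knight-Ruiz balanced
#' matrix is reserved for the graph-convolution adjacency.
#'
#' @param g a [contact_map], `normalized_map`, or bare symmetric weight matrix.
#' @param e_dim embedding size E (default 512).
#' @param epochs training epochs; each epoch draws `samples_per_epoch` edges.
#' @param negative_samples negative nodes per positive edge.
#' @param seed RNG seed; the result is bitwise reproducible given the seed and
#'   graph.
#' @param rho0 initial SGD learning rate (linearly decayed).
#' @param samples_per_epoch edge samples per epoch; default
#'   `max(10 * n_edges, 10000)`.
#' @param order proximity order, 2 (default) or 1.
#' @return object of class `embedding_matrix`: `u` (N x E node vectors),
#'   `context` (N x E second-order context vectors), `e_dim`, `neighbors`
#'   (adjacency list), `loss` (per-epoch sampled objective), and `meta`
#'   (seed, epochs, isolated-node flags).
#' @export
line_embed <- function(g, e_dim = 512L, epochs = 50L, negative_samples = 5L,
                       seed = 1L, rho0 = 0.025, samples_per_epoch = NULL,
                       order = 2L) {
  w <- graph_weights(g)
  n <- nrow(w)
  if (e_dim <= 0) stop("e_dim must be positive")
  if (n < 2) stop("graph must have at least 2 nodes")
  ut <- upper.tri(w)
  idx <- which(ut & w > 0, arr.ind = TRUE)
  if (nrow(idx) < 1) stop("graph must have at least one positive-weight edge")
  isolated <- which(rowSums(w > 0) - (diag(w) > 0) == 0)
  if (is.null(samples_per_epoch)) {
    samples_per_epoch <- max(10L * nrow(idx), 10000L)
  }
  fit <- line_embed_cpp(as.integer(idx[, 1] - 1L), as.integer(idx[, 2] - 1L),
                        w[idx], n, as.integer(e_dim), as.integer(epochs),
                        as.integer(samples_per_epoch),
                        as.integer(negative_samples), rho0,
                        as.integer(order), as.integer(seed))
  if (length(isolated)) {
    message("line_embed: ", length(isolated),
            " isolated node(s) kept at their initialization")
  }
  neighbors <- lapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    nb[nb != i]
  })
  structure(
    list(u = fit$u, context = fit$context, e_dim = as.integer(e_dim),
         neighbors = neighbors, loss = as.numeric(fit$loss),
         meta = list(seed = as.integer(seed), epochs = as.integer(epochs),
                     negative_samples = as.integer(negative_samples),
                     samples_per_epoch = as.integer(samples_per_epoch),
                     rho0 = rho0, order = as.integer(order),
                     isolated_nodes = isolated)),
    class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d nodes x %d dims (seed %d, %d epochs)\n",
              nrow(x$u), x$e_dim, x$meta$seed, x$meta$epochs))
  invisible(x)
}

# weight matrix of whatever graph-like object we are given
graph_weights <- function(g) {
  if (inherits(g, "contact_map")) return(g$counts)
  if (inherits(g, "normalized_map")) return(g$weights)
  as.matrix(g)
}

#' Second-order conditional context probability
#'
#' The probability, under the trained embedding model, of observing neighbor
#' `j` as the context of node `i`:
#' `exp(context_j . u_i) / sum_k in N(i) exp(context_k . u_i)`,
#' a softmax over the neighborhood of `i`.
#'
#' @param emb an `embedding_matrix` (carries the neighborhood structure).
#' @param i,j node indices (1-based); `j` must be a neighbor of `i`.
#' @return probability in (0, 1]; probabilities over `N(i)` sum to 1.
#' @export
second_order_conditional <- function(emb, i, j) {
  stopifnot(inherits(emb, "embedding_matrix"))
  nb <- emb$neighbors[[i]]
  if (length(nb) == 0) stop("node ", i, " has an empty neighborhood; conditional undefined")
  if (!(j %in% nb)) stop("node ", j, " is not a neighbor of node ", i)
  scores <- as.numeric(emb$context[nb, , drop = FALSE] %*% emb$u[i, ])
  scores <- scores - max(scores)
  p <- exp(scores) / sum(exp(scores))
  p[match(j, nb)]
}

#' Save / load embeddings as dense text with a metadata sidecar
#'
#' @param emb an `embedding_matrix`.
#' @param path output path for the node-vector matrix; the context matrix goes
#'   to `<path>.context` and metadata (JSON) to `<path>.meta.json`.
#' @export
write_embeddings <- function(emb, path) {
  stopifnot(inherits(emb, "embedding_matrix"))
  write_contact_matrix(emb$u, path)
  write_contact_matrix(emb$context, paste0(path, ".context"))
  jsonlite::write_json(emb$meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_embeddings
#' @param g the graph the embeddings were trained on (restores neighborhoods).
#' @export
read_embeddings <- function(path, g = NULL) {
  u <- unname(as.matrix(utils::read.table(path)))
  ctx <- unname(as.matrix(utils::read.table(paste0(path, ".context"))))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  neighbors <- NULL
  if (!is.null(g)) {
    w <- graph_weights(g)
    neighbors <- lapply(seq_len(nrow(w)), function(i) {
      nb <- which(w[i, ] > 0)
      nb[nb != i]
    })
  }
  structure(list(u = u, context = ctx, e_dim = ncol(u),
                 neighbors = neighbors, loss = numeric(0), meta = meta),
            class = "embedding_matrix")
}
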