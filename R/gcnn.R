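#' Consolidate neighbor features of one node
#'
#' The consolidation step of the graph convolutional layer: the weighted mean
#' of the neighbors' feature vectors,
#' `C(x_i) = sum_{j in N(i)} e_ij x_j / sum_{j in N(i)} e_ij`,
#' where `N(i) = { j != i : e_ij > 0 }` on the balanced adjacency. Neighbors
#' with stronger interaction pull the consolidated vector toward their own
#' features. A node whose neighborhood weight sum is zero consolidates to the
#' zero vector (reported via a message).
#'
#' @param x an `embedding_matrix` or bare N x E feature matrix.
#' @param w a `normalized_map` or bare N x N weight matrix.
#' @param i node index (1-based).
#' @return numeric vector of length E.
#' @export
consolidate <- function(x, w, i) {
  xm <- feature_matrix(x)
  wm <- graph_weights(w)
  ei <- wm[i, ]
  ei[i] <- 0
  s <- sum(ei)
  if (s == 0) {
    message("consolidate: node ", i, " is isolated; returning zero vector")
    return(numeric(ncol(xm)))
  }
  as.numeric(crossprod(xm, ei)) / s
}

#' Consolidate all nodes at once
#'
#' Matrix form of [consolidate]: `P %*% X` with `P` the row-normalized
#' off-diagonal weight matrix. Rows of isolated nodes are zero.
#'
#' @inheritParams consolidate
#' @return N x E matrix of consolidated features.
#' @export
consolidate_all <- function(x, w) {
  xm <- feature_matrix(x)
  p <- aggregation_matrix(w)
  p %*% xm
}

# row-normalized off-diagonal adjacency (the fixed aggregation operator)
aggregation_matrix <- function(w) {
  wm <- graph_weights(w)
  diag(wm) <- 0
  rs <- rowSums(wm)
  rs[rs == 0] <- 1   # isolated nodes consolidate to zero
  wm / rs
}

feature_matrix <- function(x) {
  if (inherits(x, "embedding_matrix")) x$u else as.matrix(x)
}

#' Update one node's features from its own and consolidated features
#'
#' The update step of the graph convolutional layer:
#' `x'_i = W1 x_i + W2 C(x_i)`. No bias and no activation are applied inside
#' the graph layer itself; the following ReLU belongs to the network forward
#' pass. `W1` routes the node's own information, `W2` its neighborhood's.
#'
#' @param x_i node feature vector (length E).
#' @param c_i consolidated neighbor feature vector (length E).
#' @param p a `gcnn_params` object (or any list with `W1`, `W2`).
#' @return updated feature vector of length E.
#' @export
gcnn_update <- function(x_i, c_i, p) {
  if (length(x_i) != ncol(p$W1) || length(c_i) != ncol(p$W2)) {
    stop("feature length does not match parameter dimension E = ", ncol(p$W1))
  }
  as.numeric(p$W1 %*% x_i + p$W2 %*% c_i)
}

#' Initialize graph-convolution network parameters
#'
#' Creates the trainable parameter set: the E x E graph-layer matrices `W1`
#' (self) and `W2` (neighborhood) and a four-layer MLP
#' `E -> h1 -> h2 -> h3 -> 3` with ReLU hidden activations and a linear
#' 3-unit output (xyz). All parameters are shared across nodes, so the same
#' parameter set applies to graphs of any node count - the property that
#' makes stored models reusable on other contact maps. Weights are
#' Glorot-uniform, biases zero, deterministic per seed. Default widths
#' (E = 512, MLP 256/128/64) follow the grid-searched configuration; tests
#' and small problems typically use reduced widths.
#'
#' @param e_dim embedding size E.
#' @param hidden integer vector of the three MLP hidden widths.
#' @param seed RNG seed for initialization.
#' @return object of class `gcnn_params`.
#' @export
gcnn_params <- function(e_dim = 512L, hidden = c(256L, 128L, 64L), seed = 1L) {
  stopifnot(length(hidden) == 3, all(hidden >= 1), e_dim >= 1)
  glorot <- function(rows, cols) {
    lim <- sqrt(6 / (rows + cols))
    matrix(stats::runif(rows * cols, -lim, lim), rows, cols)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  p <- list(
    W1 = glorot(e_dim, e_dim), W2 = glorot(e_dim, e_dim),
    V1 = glorot(hidden[1], e_dim), b1 = numeric(hidden[1]),
    V2 = glorot(hidden[2], hidden[1]), b2 = numeric(hidden[2]),
    V3 = glorot(hidden[3], hidden[2]), b3 = numeric(hidden[3]),
    V4 = glorot(3, hidden[3]), b4 = numeric(3),
    e_dim = as.integer(e_dim), hidden = as.integer(hidden),
    activation = "relu")
  class(p) <- "gcnn_params"
  p
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.gcnn_params <- function(x, ...) {
  cat(sprintf("<gcnn_params> E = %d, MLP %s -> 3\n",
              x$e_dim, paste(x$hidden, collapse = "/")))
  invisible(x)
}

#' Forward pass: embeddings + balanced adjacency -> 3D structure
#'
#' Applies, per node: consolidate-update graph layer, ReLU, then the shared
#' four-layer MLP (ReLU after each hidden layer, linear 3-unit output). The
#' identical parameters act on every node, so the forward pass is defined for
#' any node count and is equivariant to joint permutations of features and
#' adjacency.
#'
#' @param x an `embedding_matrix` or N x E matrix of node features.
#' @param w a `normalized_map` or N x N weight matrix (same N).
#' @param p a `gcnn_params`.
#' @param bin_size,chromosome_label optional metadata for the output.
#' @return a [structure3d] of predicted coordinates (N x 3).
#' @export
gcnn_forward <- function(x, w, p, bin_size = NA_real_, chromosome_label = "chr") {
  xm <- feature_matrix(x)
  wm <- graph_weights(w)
  if (nrow(xm) != nrow(wm)) stop("features and adjacency disagree on node count")
  if (ncol(xm) != p$e_dim) {
    stop("embedding dimension ", ncol(xm), " does not match model E = ", p$e_dim)
  }
  cm <- aggregation_matrix(wm) %*% xm
  xp <- xm %*% t(p$W1) + cm %*% t(p$W2)
  h <- pmax(xp, 0)
  dense <- function(h, v, b, act, name) {
    z <- sweep(h %*% t(v), 2, b, `+`)
    if (any(!is.finite(z))) stop("non-finite values in layer ", name)
    if (act) pmax(z, 0) else z
  }
  h <- dense(h, p$V1, p$b1, TRUE, "mlp1")
  h <- dense(h, p$V2, p$b2, TRUE, "mlp2")
  h <- dense(h, p$V3, p$b3, TRUE, "mlp3")
  y <- dense(h, p$V4, p$b4, FALSE, "output")
  structure3d(y, bin_size = bin_size, chromosome_label = chromosome_label)
}

#' Save a trained model checkpoint as JSON text
#'
#' Serializes the full parameter set plus the training conversion factor and
#' configuration, so a stored model can be reloaded and applied to a
#' different contact map of the same chromosome without retraining.
#'
#' @param model a `trained_gcnn` (from [fit_gcnn]) or a `gcnn_params`.
#' @param path output path (JSON).
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "gcnn_params")) {
    model <- list(params = model, gamma_star = NA_real_)
  }
  payload <- list(
    params = lapply(unclass(model$params), function(v) {
      if (is.matrix(v)) unname(v) else unname(v)
    }),
    gamma_star = model$gamma_star,
    dscc_by_gamma = model$dscc_by_gamma,
    final_loss = model$final_loss,
    epochs_run = model$epochs_run,
    config = model$config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns a `trained_gcnn` list.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- payload$params
  for (nm in c("W1", "W2", "V1", "V2", "V3", "V4")) p[[nm]] <- as.matrix(p[[nm]])
  for (nm in c("b1", "b2", "b3", "b4")) p[[nm]] <- as.numeric(p[[nm]])
  p$e_dim <- as.integer(p$e_dim)
  p$hidden <- as.integer(p$hidden)
  class(p) <- "gcnn_params"
  out <- list(params = p,
              gamma_star = payload$gamma_star,
              dscc_by_gamma = payload$dscc_by_gamma,
              final_loss = payload$final_loss,
              epochs_run = payload$epochs_run,
              config = payload$config)
  class(out) <- "trained_gcnn"
  out
}
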