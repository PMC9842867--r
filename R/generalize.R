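#' Expand a low-resolution embedding matrix across resolutions
#'
#' When generalizing a model across resolutions, the low-resolution embedding
#' matrix has fewer rows than the high-resolution one (a 1 mb map has half
#' the loci of a 500 kb map, a quarter of a 250 kb map). Each low-resolution
#' row is repeated `k = n_target / N` consecutive times so that row r of the
#' output equals row `floor(r / k)` of the input: corresponding rows of the
#' two matrices then describe the same chromosomal region (the 1 mb bin
#' covering 0-1 mb maps onto the 500 kb bins 0-0.5 and 0.5-1, or the 250 kb
#' bins 0-0.25 ... 0.75-1). Because zero-contact bins are retained at read
#' time, the high-resolution locus count is guaranteed to be an exact
#' multiple of the low-resolution one.
#'
#' @param a an `embedding_matrix` (or bare matrix) of the lower-resolution map.
#' @param n_target number of rows required (the higher-resolution locus
#'   count); must be an integer multiple of `nrow(a)`.
#' @return an object of the same kind as `a` with `n_target` rows.
#' @export
expand_embeddings <- function(a, n_target) {
  am <- feature_matrix(a)
  n <- nrow(am)
  if (n_target %% n != 0) {
    stop("target locus count ", n_target, " is not a multiple of ", n,
         "; re-read the maps retaining zero-contact bins")
  }
  k <- n_target %/% n
  idx <- rep(seq_len(n), each = k)
  out <- am[idx, , drop = FALSE]
  if (inherits(a, "embedding_matrix")) {
    a$u <- out
    if (!is.null(a$context) && nrow(a$context) == n) {
      a$context <- a$context[idx, , drop = FALSE]
    }
    a$neighbors <- NULL
    a$meta$expansion_factor <- k
    return(a)
  }
  out
}

#' Orthogonal Procrustes alignment of two embedding matrices
#'
#' Finds the transform minimizing the Frobenius distance between two N x E
#' embedding matrices, under the assumption that embeddings of the same
#' chromosome from different maps agree up to rotation, translation, and
#' scaling. The default aligns in the E-dimensional feature space: after
#' mean-centering, the orthogonal `T` (E x E) minimizing `||A_c T - B_c||_F`
#' is `U V'` from the SVD of `A_c' B_c`, with an optional closed-form uniform
#' scale; this closed form requires no training. `side = "n"` instead solves
#' the literal N x N left-transform `||Omega A - B||_F` via the SVD of
#' `B A'` (only defined when the two maps share N, and without
#' centering/scaling).
#'
#' @param a embedding matrix to be transformed (N x E, or `embedding_matrix`).
#' @param b reference embedding matrix of identical shape.
#' @param scale also apply the optimal uniform scale (default TRUE).
#' @param side `"e"` (feature-space, default) or `"n"` (literal left
#'   transform).
#' @return object of class `alignment_result`: `aligned` (transformed copy of
#'   `a`), `T` (orthogonal transform), `residual` (Frobenius norm after
#'   alignment), `scale`, `side`.
#' @export
procrustes_align <- function(a, b, scale = TRUE, side = c("e", "n")) {
  side <- match.arg(side)
  am <- feature_matrix(a)
  bm <- feature_matrix(b)
  if (!all(dim(am) == dim(bm))) {
    stop("embedding matrices differ in shape (", nrow(am), "x", ncol(am),
         " vs ", nrow(bm), "x", ncol(bm),
         "); expand the lower-resolution matrix first")
  }
  if (all(am == 0) || all(bm == 0)) stop("degenerate (all-zero) embedding matrix")
  if (side == "e") {
    mu_a <- colMeans(am); mu_b <- colMeans(bm)
    ac <- sweep(am, 2, mu_a); bc <- sweep(bm, 2, mu_b)
    sv <- svd(crossprod(ac, bc))
    tr <- sv$u %*% t(sv$v)
    s <- if (scale) sum(sv$d) / sum(ac^2) else 1
    aligned <- s * (ac %*% tr)
    aligned <- sweep(aligned, 2, mu_b, `+`)
  } else {
    sv <- svd(tcrossprod(bm, am))   # SVD of B A^T
    tr <- sv$u %*% t(sv$v)
    s <- 1
    aligned <- tr %*% am
  }
  structure(
    list(aligned = aligned, T = tr, residual = norm(aligned - bm, "F"),
         scale = s, side = side,
         naive_residual = norm(am - bm, "F")),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> side=%s scale=%.4g residual=%.4g (unaligned %.4g)\n",
              x$side, x$scale, x$residual, x$naive_residual))
  invisible(x)
}

#' Apply a stored model to a different contact map of the same chromosome
#'
#' Inference without retraining: the target map is KR-balanced internally,
#' the target embeddings are (optionally) aligned into the embedding space
#' the model was trained in - after expanding the source embeddings if the
#' resolutions differ - and the stored parameters produce the structure. The
#' reported dSCC scores the structure against the target map's wish distances
#' at a conversion factor of 1 (rank correlation does not depend on the
#' conversion factor, so any positive gamma gives the same value). The
#' checkpoint is never modified.
#'
#' @param model a `trained_gcnn` (from [fit_gcnn] or [load_checkpoint]).
#' @param target_map the new [contact_map] to predict on.
#' @param target_emb `embedding_matrix` of the target map.
#' @param source_emb `embedding_matrix` the model was trained on; expanded by
#'   row repetition when the target has `k` times as many loci.
#' @param align align target embeddings to the (expanded) source embeddings
#'   before the forward pass (default TRUE).
#' @return list: `structure` ([structure3d]), `dscc`, `alignment` (an
#'   `alignment_result`, or NULL when `align = FALSE`), `kept_indices`.
#' @export
generalized_predict <- function(model, target_map, target_emb, source_emb,
                                align = TRUE) {
  stopifnot(inherits(model, "trained_gcnn"), inherits(target_map, "contact_map"))
  p <- model$params
  xt <- feature_matrix(target_emb)
  xs <- feature_matrix(source_emb)
  if (ncol(xt) != p$e_dim || ncol(xs) != p$e_dim) {
    stop("embedding dimension does not match model E = ", p$e_dim)
  }
  norm <- kr_balance(target_map)
  keep <- norm$kept_indices
  counts <- target_map$counts
  if (length(keep) < target_map$n_loci) {
    xt <- xt[keep, , drop = FALSE]
    counts <- counts[keep, keep, drop = FALSE]
  }
  alignment <- NULL
  if (align) {
    xs_exp <- if (nrow(xs) != nrow(xt)) {
      feature_matrix(expand_embeddings(xs, nrow(xt)))
    } else xs
    alignment <- procrustes_align(xt, xs_exp)
    xt <- alignment$aligned
  }
  s <- gcnn_forward(xt, norm, p, bin_size = target_map$bin_size,
                    chromosome_label = target_map$chromosome_label)
  wd <- wish_distances(contact_map(counts, bin_size = target_map$bin_size,
                                   validate = FALSE), gamma = 1)
  list(structure = s, dscc = dscc(s, wd), alignment = alignment,
       kept_indices = keep)
}
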