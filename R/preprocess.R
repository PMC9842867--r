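#' Knight-Ruiz balancing of a contact map
#'
#' Rescales a symmetric non-negative contact matrix to a doubly stochastic
#' matrix `D %*% M %*% D` (positive diagonal `D`), which both removes
#' locus-level coverage biases and maps all edge weights into `[0, 1]` for
#' numerically stable network training. The primary solver is the Knight-Ruiz
#' inner-outer Newton iteration (conjugate-gradient inner solves); if it fails
#' to converge a Sinkhorn-Knopp fallback is used and noted in the result.
#'
#' Rows that are entirely zero cannot be balanced and are removed first; the
#' surviving loci are reported in `kept_indices`.
#'
#' @param m a [contact_map] or a bare symmetric non-negative matrix.
#' @param tol maximum allowed deviation of any row/column sum from 1.
#' @param max_iter iteration cap (outer Newton iterations / Sinkhorn sweeps).
#' @return object of class `normalized_map`: `weights` (N' x N' doubly
#'   stochastic matrix), `kept_indices`, `residual`, `method`, `scale_note`.
#' @export
kr_balance <- function(m, tol = 1e-6, max_iter = 1000L) {
  cm <- if (inherits(m, "contact_map")) m$counts else as.matrix(m)
  if (any(cm < 0)) stop("kr_balance requires a non-negative matrix")
  if (max(abs(cm - t(cm))) > 1e-9 * max(cm, 1)) stop("kr_balance requires a symmetric matrix")
  keep <- which(rowSums(cm) > 0)
  a <- cm[keep, keep, drop = FALSE]
  if (nrow(a) < 2) stop("fewer than 2 non-empty loci; nothing to balance")

  x <- kr_newton(a, tol = tol, max_outer = max_iter)
  method <- "knight-ruiz"
  if (is.null(x)) {
    x <- kr_sinkhorn(a, tol = tol, max_iter = max_iter)
    method <- "sinkhorn-knopp"
  }
  if (is.null(x)) {
    stop("balancing failed to converge in ", max_iter, " iterations; ",
         "the map may not be fully indecomposable - consider drop_empty ",
         "re-reading or removing sparse bins")
  }
  w <- a * tcrossprod(x)          # diag(x) %*% a %*% diag(x)
  w <- (w + t(w)) / 2
  res <- max(abs(rowSums(w) - 1))
  if (res > tol) {
    stop("balancing residual ", format(res), " exceeds tolerance ", format(tol))
  }
  structure(
    list(weights = w,
         kept_indices = keep,
         residual = res,
         method = method,
         scale_note = "doubly stochastic; entries in [0,1]"),
    class = "normalized_map")
}

#' @export
print.normalized_map <- function(x, ...) {
  cat(sprintf("<normalized_map> %d loci, method %s, residual %.3g\n",
              nrow(x$weights), x$method, x$residual))
  invisible(x)
}

# Knight-Ruiz inner-outer Newton iteration with CG inner solves.
# Returns the positive scaling vector x, or NULL on failure.
kr_newton <- function(a, tol = 1e-6, max_outer = 1000L,
                      delta = 0.1, Delta = 3) {
  n <- nrow(a)
  e <- rep(1, n)
  g <- 0.9; etamax <- 0.1
  eta <- etamax
  stop_tol <- tol * 0.5
  x <- e
  rt <- tol^2
  v <- x * (a %*% x)[, 1]
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  outer <- 0L
  while (rout > rt) {
    outer <- outer + 1L
    if (outer > max_outer) return(NULL)
    k <- 0L; y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1L
      if (k > 10L * n + 50L) break
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * (a %*% (x * p))[, 1] + v * p
      denom <- sum(p * w)
      if (!is.finite(denom) || denom == 0) break
      alpha <- rho_km1 / denom
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- which(ap < 0)
        gam <- min((delta - y[ind]) / ap[ind])
        y <- y + gam * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- which(ynew > Delta)
        gam <- min((Delta - y[ind]) / ap[ind])
        y <- y + gam * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
    }
    x <- x * y
    if (any(!is.finite(x)) || any(x <= 0)) return(NULL)
    v <- x * (a %*% x)[, 1]
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  x
}

# Symmetric Sinkhorn-Knopp fallback: alternate row scaling, symmetrized.
kr_sinkhorn <- function(a, tol = 1e-6, max_iter = 1000L) {
  n <- nrow(a)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    r <- (a %*% x)[, 1] * x
    if (any(r <= 0) || any(!is.finite(r))) return(NULL)
    x <- x / sqrt(r)
    w <- a * tcrossprod(x)
    if (max(abs(rowSums(w) - 1)) <= tol) return(x)
  }
  NULL
}

#' Convert contact frequencies to wish distances
#'
#' Distance-restraint methods estimate the unknown true pairwise distance
#' between loci i and j from the contact frequency via the inverse power law
#' `d(i, j) = (1 / CF_ij)^gamma`. The exponent `gamma` (the conversion factor)
#' is chromosome-dependent; empirically it lies in `[0.1, 2]` for common cell
#' types, so values outside that range only produce a warning. Pairs with zero
#' contacts are undefined under the conversion and are excluded from the mask
#' (they never contribute to training or evaluation); the diagonal is likewise
#' excluded.
#'
#' @param m a [contact_map] (raw counts are used).
#' @param gamma conversion factor.
#' @return object of class `wish_distances`: `gamma`, `d` (N x N matrix, zero
#'   off-mask), `mask` (logical N x N; TRUE where `CF > 0` and `i != j`).
#' @export
wish_distances <- function(m, gamma) {
  stopifnot(length(gamma) == 1, is.finite(gamma), gamma > 0)
  if (gamma < 0.1 || gamma > 2) {
    warning("conversion factor ", gamma,
            " lies outside the empirical range [0.1, 2]")
  }
  cm <- if (inherits(m, "contact_map")) m$counts else as.matrix(m)
  mask <- cm > 0
  diag(mask) <- FALSE
  d <- matrix(0, nrow(cm), ncol(cm))
  d[mask] <- (1 / cm[mask])^gamma
  structure(list(gamma = gamma, d = d, mask = mask),
            class = "wish_distances")
}

#' The conversion-factor search grid
#'
#' The candidate set for the contact-to-distance conversion factor:
#' `0.1, 0.2, ..., 2.0` (20 values). One model is trained per grid value and
#' the structure with the highest distance Spearman correlation is selected.
#'
#' @return numeric vector of length 20.
#' @export
gamma_grid <- function() {
  (1:20) / 10
}
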