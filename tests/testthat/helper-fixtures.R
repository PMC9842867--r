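# Shared fixtures and independent oracles, built in code at test time.

# Independent Spearman oracle: explicit average ranks + explicit Pearson sums.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Brute-force consolidate: scalar loops over the neighborhood definition.
consolidate_oracle <- function(x, w, i) {
  e <- ncol(x)
  num <- numeric(e)
  den <- 0
  for (j in seq_len(nrow(x))) {
    if (j != i && w[i, j] > 0) {
      num <- num + w[i, j] * x[j, ]
      den <- den + w[i, j]
    }
  }
  if (den == 0) return(numeric(e))
  num / den
}

# Brute-force update: explicit row-by-row matrix arithmetic.
update_oracle <- function(x_i, c_i, W1, W2) {
  out <- numeric(nrow(W1))
  for (r in seq_len(nrow(W1))) {
    out[r] <- sum(W1[r, ] * x_i) + sum(W2[r, ] * c_i)
  }
  out
}

# Random orthogonal matrix via QR, sign-fixed for determinism.
rand_orth <- function(e, seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(e * e), e)))
  q %*% diag(sign(diag(q) + (diag(q) == 0)))
}

# Random symmetric positive matrix (strictly positive entries).
rand_sym_pos <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n, 0.05, 1), n)
  (a + t(a)) / 2
}

# Hand-made wish_distances container for metric tests.
fake_wd <- function(d, mask = NULL, gamma = 1) {
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(d), ncol(d))
    diag(mask) <- FALSE
  }
  structure(list(gamma = gamma, d = d, mask = mask), class = "wish_distances")
}

# Small helix instance reused across training tests.
small_instance <- function(n = 30, kind = "helix", seed = 11) {
  s <- make_structure(n, kind, seed = seed)
  list(s = s, m = structure_to_map(s, gamma = 1))
}

# Compact training configuration for unit tests.
tiny_cfg <- function(max_epochs = 600L, seed = 3L) {
  train_config(hidden = c(16L, 8L, 4L), max_epochs = max_epochs, seed = seed)
}
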