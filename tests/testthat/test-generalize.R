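test_that("row expansion repeats each coarse row k consecutive times", {
  a <- matrix(as.numeric(1:8), 4, 2)
  e2 <- expand_embeddings(a, 8)
  expect_equal(e2[1, ], a[1, ]); expect_equal(e2[2, ], a[1, ])
  expect_equal(e2[3, ], a[2, ]); expect_equal(e2[4, ], a[2, ])
  expect_equal(e2, a[rep(1:4, each = 2), ])

  e4 <- expand_embeddings(a, 16)
  expect_equal(e4[1:4, ], a[rep(1, 4), ])
  for (r in seq_len(16)) expect_equal(e4[r, ], a[floor((r - 1) / 4) + 1, ])

  expect_identical(expand_embeddings(a, 4), a)       # k = 1
  expect_error(expand_embeddings(a, 10), "multiple")
})

test_that("expansion carries embedding_matrix objects along", {
  m <- small_instance(n = 12)$m
  emb <- line_embed(m, e_dim = 4, epochs = 2, seed = 1)
  out <- expand_embeddings(emb, 24)
  expect_s3_class(out, "embedding_matrix")
  expect_equal(nrow(out$u), 24)
  expect_equal(out$u[3, ], emb$u[2, ])
  expect_equal(out$meta$expansion_factor, 2)
})

test_that("aligning a matrix to itself is the identity transform", {
  set.seed(3)
  a <- matrix(rnorm(60), 20, 3)
  al <- procrustes_align(a, a)
  expect_equal(al$T, diag(3), tolerance = 1e-10)
  expect_lt(al$residual, 1e-10)
  expect_equal(al$aligned, a, tolerance = 1e-10)
})

test_that("feature-space alignment recovers a planted rotation", {
  set.seed(8)
  a <- matrix(rnorm(40 * 6), 40, 6)
  r <- rand_orth(6, seed = 21)
  b <- a %*% r
  al <- procrustes_align(a, b)
  expect_lt(al$residual, 1e-8)
  expect_equal(al$T, r, tolerance = 1e-6)
  expect_lt(max(abs(crossprod(al$T) - diag(6))), 1e-8)
})

test_that("N-side alignment recovers a planted left rotation", {
  # N <= E keeps B A^T full rank, so the SVD solution is unique
  set.seed(9)
  a <- matrix(rnorm(5 * 8), 5, 8)
  r <- rand_orth(5, seed = 22)
  b <- r %*% a
  al <- procrustes_align(a, b, side = "n")
  expect_lt(al$residual, 1e-8)
  expect_equal(al$T, r, tolerance = 1e-6)
})

test_that("alignment never hurts the Frobenius objective", {
  set.seed(10)
  a <- matrix(rnorm(30 * 4), 30, 4)
  b <- a + matrix(rnorm(30 * 4, sd = 0.1), 30, 4)
  al <- procrustes_align(a, b)
  expect_lte(al$residual, norm(a - b, "F"))
})

test_that("alignment matches a brute-force rotation search in 2D", {
  set.seed(11)
  a <- matrix(rnorm(24), 12, 2)
  b <- a %*% rand_orth(2, seed = 5) + matrix(rnorm(24, sd = 0.05), 12, 2)
  al <- procrustes_align(a, b, scale = FALSE)
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  best <- Inf
  for (th in seq(0, 2 * pi, length.out = 20001)) {
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    for (rot2 in list(rot, rot %*% diag(c(1, -1)))) {
      best <- min(best, norm(ac %*% rot2 - bc, "F"))
    }
  }
  expect_equal(al$residual, best, tolerance = 1e-6)
})

test_that("degenerate or mismatched inputs are rejected", {
  a <- matrix(rnorm(20), 10, 2)
  expect_error(procrustes_align(a, matrix(rnorm(12), 6, 2)), "expand")
  expect_error(procrustes_align(a * 0, a), "degenerate")
})

test_that("self-generalization reproduces the trained model's accuracy", {
  inst <- small_instance(n = 24)
  emb <- line_embed(inst$m, e_dim = 16, epochs = 10, seed = 2)
  cfg <- train_config(hidden = c(8L, 6L, 4L), max_epochs = 400L, seed = 3L)
  model <- fit_gcnn(inst$m, emb, cfg, gammas = 1)
  before <- model$params$W1
  pred <- generalized_predict(model, inst$m, emb, emb, align = TRUE)
  expect_equal(pred$dscc, dscc(model$structure, wish_distances(inst$m, 1)),
               tolerance = 1e-9)
  expect_equal(pred$structure$coords, model$structure$coords, tolerance = 1e-9)
  # inference never mutates the stored parameters
  expect_identical(model$params$W1, before)

  # align = FALSE simply forwards the raw target embeddings
  plain <- generalized_predict(model, inst$m, emb, emb, align = FALSE)
  norm <- kr_balance(inst$m)
  direct <- gcnn_forward(emb$u, norm, model$params)
  expect_equal(plain$structure$coords, direct$coords, tolerance = 1e-12)
  expect_null(plain$alignment)

  # embedding-dimension mismatch is caught
  bad <- line_embed(inst$m, e_dim = 8, epochs = 2, seed = 2)
  expect_error(generalized_predict(model, inst$m, bad, emb), "E = 16")
})
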