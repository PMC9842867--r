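test_that("embeddings are bitwise reproducible under a fixed seed", {
  m <- small_instance(n = 15)$m
  e1 <- line_embed(m, e_dim = 8, epochs = 3, seed = 42)
  e2 <- line_embed(m, e_dim = 8, epochs = 3, seed = 42)
  expect_identical(e1$u, e2$u)
  expect_identical(e1$context, e2$context)
  e3 <- line_embed(m, e_dim = 8, epochs = 3, seed = 43)
  expect_false(identical(e1$u, e3$u))
})

test_that("a single-edge graph embeds finitely and the objective decreases", {
  w <- matrix(c(0, 1, 1, 0), 2)
  emb <- line_embed(w, e_dim = 4, epochs = 10, seed = 1)
  expect_true(all(is.finite(emb$u)))
  expect_lt(emb$loss[length(emb$loss)], emb$loss[1])
})

test_that("disconnected cliques are more similar within than between", {
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 1; w[4:6, 4:6] <- 1; diag(w) <- 0
  emb <- line_embed(w, e_dim = 8, epochs = 20, seed = 4)
  u <- emb$u
  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  intra <- c(cs(u[1, ], u[2, ]), cs(u[1, ], u[3, ]), cs(u[2, ], u[3, ]),
             cs(u[4, ], u[5, ]), cs(u[4, ], u[6, ]), cs(u[5, ], u[6, ]))
  inter <- as.vector(outer(1:3, 4:6, Vectorize(function(i, j) cs(u[i, ], u[j, ]))))
  expect_gt(mean(intra), mean(inter))
})

test_that("barbell communities separate in embedding space", {
  n <- 13
  w <- matrix(0, n, n)
  w[1:5, 1:5] <- 1; w[9:13, 9:13] <- 1; diag(w) <- 0
  path <- c(5, 6, 7, 8, 9)
  for (k in 1:4) { w[path[k], path[k + 1]] <- 1; w[path[k + 1], path[k]] <- 1 }
  emb <- line_embed(w, e_dim = 8, epochs = 60, seed = 4)
  du <- as.matrix(dist(emb$u))
  intra <- c(du[1:5, 1:5][upper.tri(diag(5))], du[9:13, 9:13][upper.tri(diag(5))])
  inter <- as.vector(du[1:5, 9:13])
  expect_gt(mean(inter), mean(intra))
})

test_that("embedding geometry correlates with the planted 3D geometry", {
  s <- make_structure(50, "random_walk", seed = 6)
  m <- structure_to_map(s, 1)
  emb <- line_embed(m, e_dim = 32, epochs = 20, seed = 9)
  du <- as.matrix(dist(emb$u))
  dt <- structure_distances(s)
  expect_gt(cor(du[upper.tri(du)], dt[upper.tri(dt)], method = "spearman"), 0)
})

test_that("degenerate inputs are rejected and isolated nodes flagged", {
  m <- small_instance(n = 15)$m
  expect_error(line_embed(m, e_dim = 0), "e_dim")
  expect_error(line_embed(matrix(0, 3, 3), e_dim = 4), "edge")
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1   # node 4 isolated
  expect_message(emb <- line_embed(w, e_dim = 4, epochs = 2, seed = 1),
                 "isolated")
  expect_equal(emb$meta$isolated_nodes, 4L)
  expect_true(all(is.finite(emb$u[4, ])))
})

test_that("second-order conditionals form a softmax over the neighborhood", {
  # single neighbor -> probability 1
  w <- matrix(c(0, 1, 1, 0), 2)
  emb <- line_embed(w, e_dim = 4, epochs = 2, seed = 1)
  expect_equal(second_order_conditional(emb, 1, 2), 1)

  # all-zero embeddings, m neighbors -> uniform 1/m
  w4 <- matrix(1, 4, 4); diag(w4) <- 0
  emb0 <- line_embed(w4, e_dim = 4, epochs = 1, seed = 1)
  emb0$u[] <- 0; emb0$context[] <- 0
  for (j in 2:4) expect_equal(second_order_conditional(emb0, 1, j), 1 / 3)

  # trained embeddings: probabilities over N(i) sum to 1 within 1e-12
  m <- small_instance(n = 12)$m
  emb2 <- line_embed(m, e_dim = 8, epochs = 3, seed = 2)
  for (i in c(1, 5, 12)) {
    nb <- emb2$neighbors[[i]]
    p <- vapply(nb, function(j) second_order_conditional(emb2, i, j), numeric(1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0 & p <= 1))
  }

  # empty neighborhood -> error
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1
  emb3 <- line_embed(w, e_dim = 4, epochs = 1, seed = 1)
  expect_error(second_order_conditional(emb3, 3, 1), "empty neighborhood")
})

test_that("embeddings survive a save/load round trip", {
  m <- small_instance(n = 12)$m
  emb <- line_embed(m, e_dim = 8, epochs = 2, seed = 5)
  f <- withr::local_tempfile()
  write_embeddings(emb, f)
  back <- read_embeddings(f, g = m)
  expect_equal(back$u, emb$u, tolerance = 1e-12)
  expect_equal(back$context, emb$context, tolerance = 1e-12)
  expect_equal(back$meta$seed, 5)
  expect_equal(back$neighbors, emb$neighbors)
})
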