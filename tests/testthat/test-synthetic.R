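test_that("helix backbones have equal consecutive spacing", {
  s <- make_structure(10, "helix")
  gaps <- sqrt(rowSums(diff(s$coords)^2))
  expect_lt(max(gaps) - min(gaps), 1e-9)
})

test_that("structure generation is deterministic per seed", {
  for (kind in c("helix", "random_walk", "two_domain")) {
    s1 <- make_structure(20, kind, seed = 7)
    s2 <- make_structure(20, kind, seed = 7)
    expect_identical(s1$coords, s2$coords)
  }
  expect_false(identical(make_structure(20, "random_walk", seed = 1)$coords,
                         make_structure(20, "random_walk", seed = 2)$coords))
  expect_error(make_structure(5, "helix"), "n >= 10")
  expect_error(make_structure(20, "spiral"), "arg")
})

test_that("two-domain structures are compact within and separated between", {
  s <- make_structure(30, "two_domain", seed = 5)
  dom <- attr(s, "domain")
  dm <- structure_distances(s)
  same <- outer(dom, dom, "==")
  expect_lt(mean(dm[same & upper.tri(dm)]), mean(dm[!same & upper.tri(dm)]))
})

test_that("the contact map inverts the power law exactly at zero noise", {
  s <- structure3d(matrix(c(0, 0, 0, 2, 0, 0, 0, 3, 0), 3, byrow = TRUE))
  m <- structure_to_map(s, gamma = 1)
  expect_equal(m$counts[1, 2], 0.5)        # d = 2, gamma = 1 -> CF = 1/2
  expect_equal(diag(m$counts), rep(0, 3))
  expect_equal(m$counts, t(m$counts))
})

test_that("wish distances recover the true distances (round-trip identity)", {
  s <- make_structure(25, "random_walk", seed = 8)
  dm <- structure_distances(s)
  for (g in c(0.3, 1.0, 1.7)) {
    wd <- wish_distances(structure_to_map(s, g), g)
    sel <- upper.tri(dm)
    expect_lt(max(abs(wd$d[sel] - dm[sel])), 1e-9)
    expect_true(all(wd$mask[sel]))
  }
})

test_that("log-normal noise keeps contacts correlated with proximity", {
  s <- make_structure(100, "random_walk", seed = 12)
  m <- structure_to_map(s, gamma = 1, noise_alpha = 0.3, seed = 13)
  dm <- structure_distances(s)
  sel <- upper.tri(dm)
  expect_gt(cor(m$counts[sel], 1 / dm[sel], method = "spearman"), 0.8)
  # determinism of the noise
  m2 <- structure_to_map(s, gamma = 1, noise_alpha = 0.3, seed = 13)
  expect_identical(m$counts, m2$counts)
  expect_error(structure_to_map(structure3d(matrix(0, 12, 3)), 1),
               "coincident")
})

test_that("coarsening block-sums counts and conserves the total", {
  s <- make_structure(12, "random_walk", seed = 3)
  m <- structure_to_map(s, 1)
  expect_identical(coarsen_map(m, 1), m)
  c2 <- coarsen_map(m, 2)
  expect_equal(c2$n_loci, 6)
  expect_equal(c2$bin_size, 2 * m$bin_size)
  expect_equal(sum(c2$counts), sum(m$counts))
  expect_equal(c2$counts[1, 2], sum(m$counts[1:2, 3:4]))

  ones <- contact_map(matrix(1, 4, 4))
  expect_equal(coarsen_map(ones, 2)$counts, matrix(4, 2, 2))

  expect_message(c5 <- coarsen_map(m, 5), "padding")
  expect_equal(c5$n_loci, 3)
  expect_equal(sum(c5$counts), sum(m$counts))
  expect_error(coarsen_map(m, 0), "k")
})

test_that("binomial thinning halves coverage in expectation", {
  s <- make_structure(40, "random_walk", seed = 9)
  m <- structure_to_map(s, 0.5)           # large integer-ish counts
  m <- contact_map(round(m$counts * 50))
  thin <- split_coverage(m, 0.5, seed = 21)
  tot <- sum(round(m$counts)[upper.tri(m$counts, diag = TRUE)])
  got <- sum(thin$counts[upper.tri(thin$counts, diag = TRUE)])
  sd3 <- 3 * sqrt(tot * 0.5 * 0.5)
  expect_lt(abs(got - 0.5 * tot), sd3)
  expect_equal(thin$counts, t(thin$counts))
  expect_identical(split_coverage(m, 0.5, seed = 21)$counts, thin$counts)
  expect_error(split_coverage(m, 1.5), "fraction")
})

test_that("synthetic instances bundle structure and multi-resolution maps", {
  inst <- synthetic_instance(24, "helix", gamma_true = 1, coarsen = c(2, 4),
                             seed = 2)
  expect_equal(inst$true_structure$n_loci, 24)
  expect_equal(vapply(inst$maps, function(m) m$n_loci, numeric(1)),
               c(k1 = 24, k2 = 12, k4 = 6))
  expect_equal(inst$maps$k2$n_loci * 2, inst$maps$k1$n_loci)
})
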