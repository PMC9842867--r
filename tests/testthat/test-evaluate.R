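test_that("dSCC is 1 for perfect rank agreement and -1 for reversal", {
  s <- make_structure(10, "random_walk", seed = 3)
  dm <- structure_distances(s)
  expect_equal(dscc(s, fake_wd(dm)), 1)
  # any strictly decreasing function of the structure distances reverses ranks
  rev_wd <- fake_wd(max(dm) + 1 - dm)
  expect_equal(dscc(s, rev_wd), -1)
})

test_that("dSCC matches the independent rank-correlation oracle", {
  set.seed(14)
  s <- structure3d(matrix(rnorm(18), 6, 3))
  dm <- structure_distances(s)
  d <- matrix(0, 6, 6)
  mask <- matrix(FALSE, 6, 6)
  pairs <- rbind(c(1, 2), c(1, 4), c(2, 5), c(3, 6), c(4, 5))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    d[i, j] <- d[j, i] <- runif(1)
    mask[i, j] <- mask[j, i] <- TRUE
  }
  wd <- fake_wd(d, mask)
  sel <- mask & upper.tri(mask)
  expect_equal(dscc(s, wd), spearman_oracle(dm[sel], d[sel]), tolerance = 1e-12)
})

test_that("dSCC is invariant to rigid motion and uniform scaling", {
  s <- make_structure(15, "random_walk", seed = 5)
  m <- structure_to_map(s, 1)
  wd <- wish_distances(m, 0.6)
  base <- dscc(s, wd)
  r <- rand_orth(3, seed = 7)
  moved <- structure3d(sweep(3.7 * s$coords %*% r, 2, c(5, -2, 9), `+`))
  expect_equal(dscc(moved, wd), base, tolerance = 1e-12)
  expect_gte(base, -1); expect_lte(base, 1)
})

test_that("dSCC rejects degenerate inputs", {
  s <- structure3d(cbind(c(0, 1, 2, 3), 0, 0))
  expect_error(dscc(s, fake_wd(matrix(1, 4, 4) - diag(4))), "constant")
  wd_small <- fake_wd(matrix(0, 4, 4), mask = matrix(FALSE, 4, 4))
  expect_error(dscc(s, wd_small), "3 masked pairs")
})

test_that("dRMSD matches hand arithmetic and rescaling never hurts", {
  s <- structure3d(cbind(c(0, 1, 2), 0, 0))
  wd1 <- fake_wd(matrix(1, 3, 3) - diag(3))
  expect_equal(drmsd(s, wd1), sqrt(1 / 3))
  dm <- structure_distances(s)
  expect_equal(drmsd(s, fake_wd(dm)), 0)
  set.seed(6)
  s2 <- make_structure(20, "random_walk", seed = 6)
  wd <- wish_distances(structure_to_map(s2, 1), 1)   # wish = true distances
  scaled <- structure3d(4 * s2$coords)
  expect_lte(drmsd(scaled, wd, rescale = TRUE), drmsd(scaled, wd, rescale = FALSE))
  expect_lt(drmsd(scaled, wd, rescale = TRUE), 1e-9)  # pure scale is fully removed
  wd9 <- wish_distances(structure_to_map(s2, 1), 0.9) # mismatched exponent
  expect_lte(drmsd(scaled, wd9, rescale = TRUE), drmsd(scaled, wd9, rescale = FALSE))
})

test_that("linear interpolation inserts equally spaced collinear points", {
  s <- structure3d(matrix(c(0, 0, 0, 2, 0, 0), 2, byrow = TRUE))
  out <- interpolate_structure(s, 2)
  expect_equal(out$coords, rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(interpolate_structure(s, 1)$coords, s$coords)

  out4 <- interpolate_structure(s, 4)
  expect_equal(nrow(out4$coords), 5)
  gaps <- sqrt(rowSums(diff(out4$coords)^2))
  expect_equal(gaps, rep(0.5, 4), tolerance = 1e-12)

  s3 <- make_structure(10, "helix")
  big <- interpolate_structure(s3, 2)
  expect_equal(nrow(big$coords), 2 * (10 - 1) + 1)
  expect_message(pad <- interpolate_structure(s3, 2, n_target = 20), "padding")
  expect_equal(nrow(pad$coords), 20)
  expect_equal(pad$coords[20, ], pad$coords[19, ])
  expect_error(interpolate_structure(s3, 0), "k")
})

test_that("compartment calling splits a planted two-block map exactly", {
  s <- make_structure(40, "two_domain", seed = 2)
  dom <- attr(s, "domain")
  m <- structure_to_map(s, 1)
  cc <- call_compartments(m)
  expect_length(cc$labels, 40)
  # partition identity (label names aside) matches the planted domains
  agree <- mean((cc$labels == "A") == (dom == dom[1]))
  expect_true(agree %in% c(0, 1))
  # the A/B split separates the two spatial domains in the true structure
  dm <- structure_distances(s)
  same <- outer(cc$labels, cc$labels, "==")
  intra <- dm[same & upper.tri(dm)]
  inter <- dm[!same & upper.tri(dm)]
  expect_lt(mean(intra), mean(inter))
})

test_that("compartment labels are invariant to eigenvector sign flips", {
  s <- make_structure(30, "two_domain", seed = 4)
  m <- structure_to_map(s, 1)
  cc <- call_compartments(m)
  # the convention fixes A to the larger compartment, so the partition is
  # reproducible regardless of the arbitrary eigenvector sign
  expect_gte(sum(cc$labels == "A"), sum(cc$labels == "B"))
  cc2 <- call_compartments(m)
  expect_identical(cc$labels, cc2$labels)
})

test_that("compartment calls serialize to BED-like text", {
  s <- make_structure(20, "two_domain", seed = 3)
  m <- structure_to_map(s, 1)
  cc <- call_compartments(m)
  f <- withr::local_tempfile()
  write_compartments(cc, f)
  tab <- read.table(f, sep = "\t")
  expect_equal(nrow(tab), length(cc$labels))
  expect_true(all(tab$V4 %in% c("A", "B")))
  expect_true(all(tab$V3 - tab$V2 == m$bin_size))
})

test_that("region distance comparison orders near and far pairs", {
  s <- structure3d(cbind(0:19, 0, 0))
  near <- cbind(1:10, 2:11)
  far <- cbind(1:10, 11:20)
  out <- region_distance_compare(s, near, far)
  expect_lt(out$mean1, out$mean2)
  expect_lt(out$p_value, 0.05)
  same <- region_distance_compare(s, near, near)
  expect_equal(same$mean1, same$mean2)
  expect_error(region_distance_compare(s, near[0, , drop = FALSE], far), "empty")
  expect_error(region_distance_compare(s, cbind(1, 99), far), "invalid")
})

test_that("planted loops sit significantly closer than control pairs", {
  set.seed(31)
  s <- make_structure(60, "random_walk", seed = 31)
  xyz <- s$coords
  loops <- rbind(c(5, 45), c(10, 50), c(15, 55), c(20, 58), c(3, 40))
  for (k in seq_len(nrow(loops))) {   # pull loop anchors together
    i <- loops[k, 1]; j <- loops[k, 2]
    mid <- (xyz[i, ] + xyz[j, ]) / 2
    xyz[i, ] <- mid + 0.05 * (xyz[i, ] - mid)
    xyz[j, ] <- mid + 0.05 * (xyz[j, ] - mid)
  }
  s2 <- structure3d(xyz)
  ctrl <- cbind(sample(1:25, 12), sample(35:60, 12))
  out <- region_distance_compare(s2, loops, ctrl)
  expect_lt(out$mean1, out$mean2)
  expect_lt(out$p_value, 0.05)
})
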