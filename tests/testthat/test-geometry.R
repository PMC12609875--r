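test_that("angle_between returns the acute angle between lines", {
  expect_equal(angle_between(c(0, 0, 0, 1), c(0, 0, 0, 5)), 0)
  expect_equal(angle_between(c(0, 0, 1, 0), c(0, 0, 0, 1)), 90)
  expect_equal(angle_between(c(0, 0, 1, 0), c(0, 0, 1, 1)), 45)
  # symmetric, and invariant to reversing either axis
  a <- c(2, 3, 7, -1); b <- c(0, 0, -4, 9)
  expect_equal(angle_between(a, b), angle_between(b, a))
  expect_equal(angle_between(a, b), angle_between(c(a[3:4], a[1:2]), b))
  expect_lte(angle_between(a, b), 90)
  expect_error(angle_between(c(1, 1, 1, 1), b), "zero-length")
})

test_that("simulated feet invert to their generative angles", {
  p <- foot_params(hva = 30, ima = 12, dmaa = 10, hia = 8)
  ang <- compute_angles(simulate_foot(p))
  expect_equal(ang$hva, 30, tolerance = 1e-9)
  expect_equal(ang$ima, 12, tolerance = 1e-9)
  expect_equal(ang$dmaa, 10, tolerance = 1e-9)
  expect_equal(ang$hia, 8, tolerance = 1e-9)

  # undeformed construction: everything zero
  ang0 <- compute_angles(simulate_foot(foot_params()))
  expect_equal(unlist(ang0[c("hva", "ima", "dmaa", "hia")]),
               c(hva = 0, ima = 0, dmaa = 0, hia = 0), tolerance = 1e-9)
})

test_that("angles survive a similarity transform unchanged", {
  p <- foot_params(hva = 22, ima = 9, dmaa = 14, hia = 5)
  g <- simulate_foot(p)
  gt <- transform_geometry(g, rotation_deg = 37, translation = c(100, -50))
  gt$y <- gt$y + 600  # keep coordinates positive-ish; irrelevant to angles
  expect_equal(as.data.frame(compute_angles(gt)[, c("hva", "ima", "dmaa", "hia")]),
               as.data.frame(compute_angles(g)[, c("hva", "ima", "dmaa", "hia")]),
               tolerance = 1e-9)
})

test_that("angle recovery holds across the full parameter grid", {
  grid <- expand.grid(hva = c(5, 15, 25, 35, 45), ima = c(6, 10, 14, 18))
  for (i in seq_len(nrow(grid))) {
    ang <- compute_angles(simulate_foot(foot_params(hva = grid$hva[i], ima = grid$ima[i])))
    expect_lt(abs(ang$hva - grid$hva[i]), 1e-6)
    expect_lt(abs(ang$ima - grid$ima[i]), 1e-6)
  }
})

test_that("degenerate axes raise errors naming the axis", {
  g <- simulate_foot(foot_params())
  g$x[g$landmark_name == "pp_head_midpoint"] <- g$x[g$landmark_name == "pp_base_midpoint"]
  g$y[g$landmark_name == "pp_head_midpoint"] <- g$y[g$landmark_name == "pp_base_midpoint"]
  expect_error(compute_angles(g), "hva")
})

test_that("pairwise distances match the brute-force oracle and count 276", {
  set.seed(42)
  g <- random_geometry()
  d <- pairwise_distances(g)
  expect_equal(nrow(d), 276L)
  expect_false(any(d$normalized))
  pts <- as.matrix(dplyr::arrange(g, landmark_index)[, c("x", "y")])
  expect_equal(d$distance, oracle_distances(pts), tolerance = 1e-12)

  # 3-4-5 triangle on a specific pair
  g2 <- g
  g2$x[1:2] <- c(0, 3); g2$y[1:2] <- c(0, 4)
  d2 <- pairwise_distances(g2)
  expect_equal(d2$distance[d2$landmark_i == 0 & d2$landmark_j == 1], 5)
})

test_that("pairwise distances satisfy the triangle inequality", {
  set.seed(7)
  g <- random_geometry()
  d <- pairwise_distances(g)
  key <- function(i, j) d$distance[d$landmark_i == min(i, j) & d$landmark_j == max(i, j)]
  trips <- utils::combn(0:23, 3)[, sample(2024, 60)]
  for (k in seq_len(ncol(trips))) {
    i <- trips[1, k]; j <- trips[2, k]; l <- trips[3, k]
    expect_lte(key(i, j), key(i, l) + key(j, l) + 1e-9)
  }
})

test_that("count_pairs is n(n-1)/2", {
  expect_equal(count_pairs(24), 276L)
  expect_equal(count_pairs(2), 1L)
  expect_equal(count_pairs(5), 10L)
  expect_error(count_pairs(1), ">= 2")
})

test_that("normalization divides by proximal phalanx length and cancels scale", {
  g <- simulate_foot(foot_params(hva = 18, ima = 8, pp_len = 100))
  d <- pairwise_distances(g)
  nd <- normalize_distances(d, g)
  expect_true(all(nd$normalized))
  expect_equal(unique(nd$normalizer), 100, tolerance = 1e-9)
  expect_equal(nd$distance[nd$pair_name == "pp_head_midpoint__pp_base_midpoint"], 1)
  expect_equal(nd$distance, d$distance / 100, tolerance = 1e-12)

  g2 <- transform_geometry(g, scale = 2)
  nd2 <- normalize_distances(pairwise_distances(g2), g2)
  expect_equal(nd2$distance, nd$distance, tolerance = 1e-12)

  # double normalization and collapsed normalizer are errors
  expect_error(normalize_distances(nd, g), "already")
  gz <- g
  gz[gz$landmark_name == "pp_head_midpoint", c("x", "y")] <-
    gz[gz$landmark_name == "pp_base_midpoint", c("x", "y")]
  expect_error(normalize_distances(pairwise_distances(gz), gz), "zero")
})

test_that("normalized distances are similarity-invariant", {
  set.seed(19)
  for (rep in 1:5) {
    p <- random_foot_params()
    base <- foot_params(hva = p$hva, ima = p$ima, dmaa = p$dmaa, hia = p$hia)
    g0 <- simulate_foot(base)
    g1 <- simulate_foot(p)  # same angles, random pose baked into params
    nd0 <- normalize_distances(pairwise_distances(g0), g0)
    nd1 <- normalize_distances(pairwise_distances(g1), g1)
    expect_equal(nd1$distance, nd0$distance, tolerance = 1e-9)
  }
})

test_that("measure_cohort produces the wide feet-by-features table", {
  sim <- simulate_cohort(cohort_params(n_feet = 6, annotators = 1, sigma = 0, seed = 2))
  co <- sim$cohort
  expect_equal(nrow(co), 6)
  expect_true(all(hv_pairs()$pair_name %in% names(co)))
  expect_equal(sum(names(co) %in% hv_pairs()$pair_name), 276)
  expect_true(all(c("hva", "ima", "dmaa", "hia", "hva_severity") %in% names(co)))
  # distance columns follow canonical pair order
  expect_identical(names(co)[names(co) %in% hv_pairs()$pair_name], hv_pairs()$pair_name)
})
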