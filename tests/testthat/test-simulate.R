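test_that("foot construction is deterministic and validates parameters", {
  p <- foot_params(hva = 20, ima = 10, dmaa = 5, hia = 3)
  expect_identical(simulate_foot(p), simulate_foot(p))
  expect_error(foot_params(hva = -1), "\\[0, 60\\]")
  expect_error(foot_params(hva = 75), "\\[0, 60\\]")
  expect_error(foot_params(pp_len = 0), "positive")
  expect_error(foot_params(scale = 0), "positive")
})

test_that("round-trip identity holds over the full parameter grid", {
  grid <- expand.grid(hva = c(5, 15, 25, 35, 45), ima = c(6, 10, 14, 18),
                      dmaa = c(0, 10, 20), hia = c(0, 8, 16))
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    ang <- compute_angles(simulate_foot(foot_params(
      hva = grid$hva[i], ima = grid$ima[i], dmaa = grid$dmaa[i], hia = grid$hia[i]
    )))
    worst <- max(worst, abs(ang$hva - grid$hva[i]), abs(ang$ima - grid$ima[i]),
                 abs(ang$dmaa - grid$dmaa[i]), abs(ang$hia - grid$hia[i]))
  }
  expect_lt(worst, 1e-6)
})

test_that("global pose changes no angle and no normalized distance", {
  set.seed(20)
  for (rep in 1:5) {
    hva <- runif(1, 0, 45); ima <- runif(1, 0, 18)
    dmaa <- runif(1, 0, 20); hia <- runif(1, 0, 15)
    g0 <- simulate_foot(foot_params(hva = hva, ima = ima, dmaa = dmaa, hia = hia))
    g1 <- simulate_foot(foot_params(hva = hva, ima = ima, dmaa = dmaa, hia = hia,
                                    rotation = runif(1, -180, 180),
                                    translation = runif(2, -300, 300),
                                    scale = runif(1, 0.3, 3)))
    expect_equal(as.data.frame(compute_angles(g1)[-1]),
                 as.data.frame(compute_angles(g0)[-1]), tolerance = 1e-9)
    nd0 <- normalize_distances(pairwise_distances(g0), g0)
    nd1 <- normalize_distances(pairwise_distances(g1), g1)
    expect_equal(nd1$distance, nd0$distance, tolerance = 1e-9)
  }
})

test_that("simulated annotators jitter reproducibly and sigma = 0 is exact", {
  g <- simulate_foot(foot_params(hva = 25, ima = 11))
  a0 <- simulate_annotators(g, k = 3, sigma = 0, seed = 1)
  expect_equal(unique(a0$annotator_id), c("ann_1", "ann_2", "ann_3"))
  for (a in unique(a0$annotator_id)) {
    expect_equal(a0$x[a0$annotator_id == a], g$x)
    expect_equal(a0$y[a0$annotator_id == a], g$y)
  }
  a1 <- simulate_annotators(g, k = 3, sigma = 2.1, seed = 2)
  a2 <- simulate_annotators(g, k = 3, sigma = 2.1, seed = 2)
  expect_identical(a1, a2)
  a3 <- simulate_annotators(g, k = 3, sigma = 2.1, seed = 3)
  expect_false(identical(a1$x, a3$x))
})

test_that("consensus over many annotation draws converges to the true geometry", {
  g <- simulate_foot(foot_params(hva = 30, ima = 12))
  xs <- matrix(0, 24, 50)
  for (s in 1:50) {
    m <- merge_annotations(simulate_annotators(g, k = 3, sigma = 2.1, seed = 100 + s))
    xs[, s] <- m$x
  }
  expect_lt(max(abs(rowMeans(xs) - g$x)), 0.5)
})

test_that("cohort generation is seed-deterministic and matches its truth record", {
  cp <- cohort_params(n_feet = 12, seed = 21)
  s1 <- simulate_cohort(cp)
  s2 <- simulate_cohort(cp)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$truth$angles, s2$truth$angles)

  # zero jitter, no couplings: measured angles equal the generative truth
  s0 <- simulate_cohort(cohort_params(n_feet = 15, annotators = 1, sigma = 0, seed = 22))
  for (a in c("hva", "ima", "dmaa", "hia")) {
    expect_equal(s0$cohort[[a]], s0$truth$angles[[a]], tolerance = 1e-9)
  }
})

test_that("decoupling preserves marginals while severing distance-angle links", {
  cp <- cohort_params(n_feet = 200, annotators = 1, sigma = 0, seed = 23)
  cpd <- cohort_params(n_feet = 200, annotators = 1, sigma = 0, decouple = TRUE, seed = 23)
  sc <- simulate_cohort(cp)$cohort
  sd_ <- simulate_cohort(cpd)$cohort
  pair <- "mt2_head_center__pp_head_midpoint"
  expect_equal(sort(sc[[pair]]), sort(sd_[[pair]]))  # same values, permuted
  expect_equal(sc$hva, sd_$hva)
  # the geometric correlation is strong in the coupled cohort, null after
  expect_gt(abs(pearson_r(sc[[pair]], sc$hva)), 0.5)
  expect_lt(abs(pearson_r(sd_[[pair]], sd_$hva)), 0.2)
})

test_that("cohort parameter validation rejects bad settings", {
  expect_error(cohort_params(n_feet = 0), "n_feet")
  expect_error(cohort_params(sigma = -1), "sigma")
  expect_error(cohort_params(severity_weights = list(hva = c(1, 1, 1))), "hva, ima")
  expect_error(
    cohort_params(couplings = tibble::tibble(pair_name = "nope", angle = "hva", r = 0.5)),
    "unknown pair"
  )
  expect_error(
    cohort_params(couplings = tibble::tibble(
      pair_name = "mt1_head_center__mt1_head_medial", angle = "hva", r = 1.2)),
    "< 1"
  )
})
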