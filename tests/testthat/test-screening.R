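test_that("pearson_r matches hand computations and the sum-formula oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(2, 1, 4, 3)), 0.6)

  set.seed(5)
  for (i in 1:25) {
    a <- rnorm(20); b <- rnorm(20)
    expect_equal(pearson_r(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  }
})

test_that("pearson_r is invariant under positive affine maps and flips sign", {
  set.seed(6)
  a <- rnorm(30); b <- rnorm(30)
  r <- pearson_r(a, b)
  expect_equal(pearson_r(3 * a + 7, b), r, tolerance = 1e-12)
  expect_equal(pearson_r(a, 0.2 * b - 4), r, tolerance = 1e-12)
  expect_equal(pearson_r(-2 * a, b), -r, tolerance = 1e-12)
})

test_that("pearson_r rejects degenerate input", {
  expect_error(pearson_r(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("pearson p-values follow the t-transform and its monotonicities", {
  expect_equal(pearson_pvalue(0, 50), 1)
  # agrees with the standard test
  set.seed(8)
  x <- rnorm(40); y <- x + rnorm(40, 0, 2)
  ct <- stats::cor.test(x, y)
  expect_equal(pearson_pvalue(unname(ct$estimate), 40), ct$p.value, tolerance = 1e-12)
  # r = 0.4 at n = 335 is overwhelming evidence
  expect_lt(pearson_pvalue(0.4, 335), 1e-10)
  # decreasing in |r| at fixed n, and in n at fixed |r|
  rs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(pearson_pvalue(rs, 30)) < 0))
  expect_gt(pearson_pvalue(0.3, 20), pearson_pvalue(0.3, 200))
  expect_warning(p1 <- pearson_pvalue(1, 10), "limiting")
  expect_equal(p1, 0)
})

test_that("screening flags an exact affine feature with r = 1", {
  sim <- simulate_cohort(cohort_params(n_feet = 50, annotators = 1, sigma = 0,
                                       decouple = TRUE, seed = 9))
  co <- sim$cohort
  pair <- "mt1_head_center__mt2_head_center"
  co[[pair]] <- 0.01 * co$hva + 2
  scr <- suppressWarnings(screen_correlations(co))
  rec <- dplyr::filter(tidy(scr), pair_name == pair, angle == "hva")
  expect_equal(rec$r, 1, tolerance = 1e-12)
  expect_true(rec$flagged)
  expect_equal(rec$sign, "positive")
})

test_that("screening returns 1104 deterministic records ordered by angle then pair", {
  sim <- simulate_cohort(cohort_params(n_feet = 40, seed = 10))
  scr <- suppressWarnings(screen_correlations(sim$cohort))
  expect_s3_class(scr, "hv_screen")
  expect_equal(nrow(scr), 276 * 4)
  expect_equal(unique(scr$angle), c("hva", "ima", "dmaa", "hia"))
  expect_identical(scr$pair_name[1:276], hv_pairs()$pair_name)
  # permuting cohort rows changes nothing
  scr2 <- suppressWarnings(screen_correlations(sim$cohort[sample(40), ]))
  expect_equal(tidy(scr), tidy(scr2))
  # the self-normalized pair is NA and unflagged, everything else defined
  self_rec <- dplyr::filter(tidy(scr), pair_name == "pp_head_midpoint__pp_base_midpoint")
  expect_true(all(is.na(self_rec$r)))
  expect_false(any(self_rec$flagged))
  expect_equal(sum(is.na(scr$r)), 4)
})

test_that("screening errors name missing columns", {
  sim <- simulate_cohort(cohort_params(n_feet = 10, seed = 11))
  broken <- dplyr::select(sim$cohort, -"mt1_head_center__mt1_head_medial")
  expect_error(suppressWarnings(screen_correlations(broken)),
               "mt1_head_center__mt1_head_medial")
  no_angle <- dplyr::select(sim$cohort, -"dmaa")
  expect_error(suppressWarnings(screen_correlations(no_angle)), "dmaa")
})

test_that("injected couplings are recovered and independent noise is not flagged", {
  pairs <- hv_pairs()$pair_name
  injected <- pairs[c(3, 50, 120, 200, 260)]
  cp <- cohort_params(
    n_feet = 300, annotators = 3, sigma = 2.1, decouple = TRUE,
    couplings = tibble::tibble(pair_name = injected, angle = "hva", r = 0.6),
    seed = 12
  )
  scr <- suppressWarnings(screen_correlations(simulate_cohort(cp)$cohort))
  hva_flags <- dplyr::filter(tidy(scr), angle == "hva", flagged)
  expect_true(all(injected %in% hva_flags$pair_name))
  false_flags <- setdiff(hva_flags$pair_name, injected)
  expect_lte(length(false_flags), 1)
})

test_that("an all-noise cohort produces no |r| >= 0.4 flags at n = 300", {
  scr <- suppressWarnings(screen_correlations(
    simulate_cohort(cohort_params(n_feet = 300, annotators = 1, sigma = 0,
                                  decouple = TRUE, seed = 13))$cohort
  ))
  expect_equal(sum(dplyr::filter(tidy(scr), angle %in% c("hva", "ima"))$flagged), 0)
})

test_that("permutation p-values broadly agree with the t-transform", {
  sim <- simulate_cohort(cohort_params(n_feet = 60, decouple = TRUE, seed = 14))
  scr_t <- suppressWarnings(screen_correlations(sim$cohort))
  scr_p <- suppressWarnings(screen_correlations(sim$cohort, method = "permutation",
                                                n_perm = 199, seed = 15))
  ok <- !is.na(scr_t$p)
  expect_gt(cor(scr_t$p[ok], scr_p$p[ok], method = "spearman"), 0.95)
})

test_that("BH flagging is at least as conservative as raw flagging", {
  sim <- simulate_cohort(cohort_params(n_feet = 80, seed = 16))
  raw <- suppressWarnings(screen_correlations(sim$cohort))
  adj <- suppressWarnings(screen_correlations(sim$cohort, fdr = TRUE))
  expect_lte(sum(adj$flagged), sum(raw$flagged))
  expect_true(all(adj$p_adj >= adj$p, na.rm = TRUE))
})

test_that("the correlation matrix round-trips record values", {
  sim <- simulate_cohort(cohort_params(n_feet = 30, seed = 18))
  scr <- suppressWarnings(screen_correlations(sim$cohort))
  M <- correlation_matrix(scr)
  expect_equal(dim(M), c(276L, 4L))
  expect_identical(rownames(M), hv_pairs()$pair_name)
  rec <- tidy(scr)
  for (a in colnames(M)) {
    expect_equal(unname(M[, a]), rec$r[rec$angle == a])
  }
  expect_error(correlation_matrix(scr[-1, ]), "incomplete")
})

test_that("tidy and glance summarize a screen", {
  sim <- simulate_cohort(cohort_params(n_feet = 30, seed = 19))
  scr <- suppressWarnings(screen_correlations(sim$cohort))
  td <- tidy(scr)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "hv_screen"))
  gl <- glance(scr)
  expect_equal(gl$n_feet, 30)
  expect_equal(gl$n_records, 1104)
  expect_equal(gl$n_flagged,
               gl$flagged_hva + gl$flagged_ima + gl$flagged_dmaa + gl$flagged_hia)
})
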