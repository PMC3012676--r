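test_that("welch_test agrees with stats::t.test on random small-sample fixtures", {
  set.seed(401)
  for (rep in 1:200) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    m <- cbind(
      matrix(rnorm(20 * na, mean = runif(1, -2, 2)), 20),
      matrix(rnorm(20 * nb, sd = runif(1, 0.2, 3)), 20)
    )
    v <- make_values(m, scale = "m")
    ga <- paste0("A", seq_len(na)); gb <- paste0("A", na + seq_len(nb))
    out <- welch_test(v, ga, gb)
    i <- sample(20, 1)
    ref <- t.test(m[i, seq_len(na)], m[i, na + seq_len(nb)])
    expect_equal(out$t_statistic[i], unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(out$df[i], unname(ref$parameter), tolerance = 1e-10)
    expect_equal(out$p_value[i], ref$p.value, tolerance = 1e-10)
  }
})

test_that("welch_test matches a hand-worked example to 4 decimals", {
  # classic unequal-variance fixture: A = {27.5, 21.0, 19.0, 23.6, 17.0,
  # 17.9, 16.9, 20.1, 21.9, 22.6, 23.1, 19.6, 19.0, 21.7, 21.4},
  # B = {27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2,
  # 21.9, 22.8, 23.0, 24.2, 25.4}
  a_vals <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9,
              22.6, 23.1, 19.6, 19.0, 21.7, 21.4)
  b_vals <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8,
              20.2, 21.9, 22.8, 23.0, 24.2, 25.4)
  m <- rbind(c(a_vals, b_vals))
  v <- make_values(m, scale = "m", site_id = "cg001",
                   array_id = paste0("A", 1:30))
  out <- welch_test(v, paste0("A", 1:15), paste0("A", 16:30))
  # Welch-Satterthwaite worked by hand: t = -2.9036, df = 24.4995,
  # p = 0.0077 (cross-checked against an independent implementation)
  expect_lt(abs(out$t_statistic - -2.9036), 1e-4)
  expect_lt(abs(out$df - 24.4995), 1e-3)
  expect_lt(abs(out$p_value - 0.0077), 1e-4)
})

test_that("degenerate zero-variance sites take their continuity limits", {
  m <- rbind(c(1, 2, 1, 2),     # identical groups
             c(1, 1, 1, 1),     # zero variance, equal means
             c(0, 0, 10, 10))   # zero variance, unequal means
  v <- make_values(m, scale = "m")
  expect_warning(
    out <- welch_test(v, c("A1", "A2"), c("A3", "A4")),
    "zero variance"
  )
  expect_equal(out$t_statistic[1], 0)
  expect_equal(out$p_value[1], 1)
  expect_equal(out$p_value[2], 1)
  expect_equal(out$p_value[3], 0)
  expect_true(out$degenerate[2] && out$degenerate[3])
  expect_false(out$degenerate[1])
})

test_that("welch_test separates clear differences and errors on undersized groups", {
  m <- rbind(c(0, 1e-4, 10, 10.0001))
  v <- make_values(m, scale = "m")
  out <- welch_test(v, c("A1", "A2"), c("A3", "A4"))
  expect_lt(out$p_value, 0.001)
  expect_error(welch_test(v, "A1", c("A3", "A4")), "at least 2")
  expect_error(welch_test(v, c("A1", "zz"), c("A3", "A4")), "zz")
})

test_that("range groups follow the printed boundaries with a closed middle interval", {
  expect_identical(
    as.character(assign_range_group(c(0.19, 0.2, 0.5, 0.8, 0.81), "beta")),
    c("low", "middle", "middle", "middle", "high")
  )
  expect_identical(
    as.character(assign_range_group(c(-2.0001, -2, 0, 2, 2.0001), "m")),
    c("low", "middle", "middle", "middle", "high")
  )
  expect_error(assign_range_group(0.5, "logit"))
  # transform consistency away from the boundary: 0.19 -> M ~ -2.063
  expect_identical(as.character(assign_range_group(beta_to_m(0.19), "m")),
                   "low")
})

test_that("every site lands in exactly one range group", {
  set.seed(402)
  means <- runif(500)
  g <- assign_range_group(means, "beta")
  expect_false(any(is.na(g)))
  expect_identical(length(g), 500L)
  expect_identical(sum(table(g)), 500L)
})

test_that("candidate selection gates strictly, ranks by difference, and breaks ties by id", {
  result <- structure(
    tibble::tibble(
      site_id = c("cg5", "cg1", "cg2", "cg3", "cg4"),
      mean_a = 0, mean_b = 0,
      abs_diff = c(0.30, 0.10, 0.25, 0.25, 0.40),
      t_statistic = 1, p_value = c(0.01, 0.04, 0.02, 0.03, 0.06),
      range_group = factor("middle", c("low", "middle", "high"))
    ),
    class = c("meth_diff", class(tibble::tibble())), scale = "beta"
  )
  # cg4 fails the p gate; cg2/cg3 tie on abs_diff -> id order
  expect_identical(select_candidates(result),
                   c("cg5", "cg2", "cg3", "cg1"))
  expect_identical(select_candidates(result, diff_threshold = 0.25),
                   "cg5")
  # threshold 0 reproduces the pure p-gate set
  expect_setequal(select_candidates(result, diff_threshold = 0),
                  result$site_id[result$p_value < 0.05])
})

test_that("selection is monotone in both the p cutoff and the difference threshold", {
  set.seed(403)
  result <- structure(
    tibble::tibble(
      site_id = sprintf("cg%03d", 1:200),
      mean_a = 0, mean_b = 0,
      abs_diff = runif(200), t_statistic = 1, p_value = runif(200),
      range_group = factor("middle", c("low", "middle", "high"))
    ),
    class = c("meth_diff", class(tibble::tibble())), scale = "beta"
  )
  for (th in seq(0, 1, by = 0.2)) {
    s1 <- select_candidates(result, 0.05, th)
    s2 <- select_candidates(result, 0.05, th + 0.1)
    expect_true(all(s2 %in% s1))
    p1 <- select_candidates(result, 0.01, th)
    expect_true(all(p1 %in% s1))
  }
})

test_that("diff_methylation assembles means, differences and groups consistently", {
  sim <- simulate_titration(300, diff_fraction = 0.4, seed = 404)
  beta <- compute_beta(sim$intensities)
  res <- diff_methylation(beta, c("Array1", "Array2"),
                          c("Array7", "Array8"))
  expect_identical(nrow(res), 300L)
  expect_equal(res$abs_diff, abs(res$mean_a - res$mean_b))
  expect_false(any(is.na(res$range_group)))
  gl <- glance(res)
  expect_identical(gl$scale, "beta")
  expect_identical(gl$n_low + gl$n_middle + gl$n_high, 300L)
})

test_that("p-values are approximately uniform under the null titration simulation", {
  sim <- simulate_titration(10000, diff_fraction = 0, seed = 405)
  m <- compute_m(sim$intensities)
  res <- diff_methylation(m, c("Array1", "Array2"),
                          c("Array7", "Array8"))
  type1 <- mean(res$p_value < 0.05, na.rm = TRUE)
  # 2-vs-2 Welch runs markedly conservative (the Welch-Satterthwaite df
  # is itself noisy at n = 2); the band documents that the rate stays in
  # the right decade without pretending exact calibration
  expect_gt(type1, 0.005)
  expect_lt(type1, 0.07)
})
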