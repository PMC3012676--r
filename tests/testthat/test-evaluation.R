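test_that("titration profile carries each replicate's mixing fraction", {
  expect_equal(unname(titration_profile(default_design())),
               c(1, 1, 0.9, 0.9, 0.75, 0.5, 0, 0))
  const <- titration_design(rep(0.5, 3), array_id = paste0("A", 1:3),
                            mix_label = rep("Mix1", 3))
  expect_equal(unname(titration_profile(const)), rep(0.5, 3))
  expect_length(titration_profile(default_design()), 8L)
})

test_that("true positives require |r| above threshold on both scales", {
  d <- default_design()
  f <- titration_profile(d)
  # site 1 exactly affine in f (nonzero slope), site 2 constant,
  # site 3 affine decreasing, site 4 uncorrelated wiggle
  beta_m <- rbind(0.1 + 0.6 * f,
                  rep(0.4, 8),
                  0.8 - 0.5 * f,
                  c(0.2, 0.8, 0.3, 0.7, 0.25, 0.75, 0.35, 0.65))
  beta <- make_values(beta_m, scale = "beta", array_id = d$array_id)
  m <- beta_to_m(beta)
  tp <- define_true_positives(beta, m, d)
  expect_identical(tp$site_ids, c("cg001", "cg003"))
  cors <- tidy(tp)
  expect_equal(cors$r_beta[1], 1)
  expect_equal(cors$r_beta[3], -1)
  expect_true(is.na(cors$r_beta[2]))  # zero variance: excluded
  expect_false(cors$is_tp[4])
  expect_identical(glance(tp)$n_tp, 2L)
})

test_that("true-positive definition checks inputs and supports per-scale modes", {
  d <- default_design()
  beta <- make_values(matrix(runif(16), 2), scale = "beta",
                      array_id = d$array_id[1:8])
  m <- beta_to_m(beta)
  wrong <- make_values(matrix(runif(4), 2), scale = "m")
  expect_error(define_true_positives(beta, wrong, d), "different arrays")
  expect_error(define_true_positives(m, m, d), "identical")
  # the both-scale set is the intersection of the per-scale sets
  set.seed(506)
  bm <- matrix(runif(30 * 8, 0.05, 0.95), 30) +
    outer(runif(30, -0.04, 0.04), titration_profile(d))
  bm <- pmin(pmax(bm, 0.01), 0.99)
  beta2 <- make_values(bm, scale = "beta", array_id = d$array_id)
  m2 <- beta_to_m(beta2)
  both <- define_true_positives(beta2, m2, d, r_threshold = 0.3)
  per_beta <- define_true_positives(beta2, m2, d, 0.3, scales = "beta")
  per_m <- define_true_positives(beta2, m2, d, 0.3, scales = "m")
  expect_setequal(both$site_ids,
                  intersect(per_beta$site_ids, per_m$site_ids))
})

test_that("TPR and DR implement the set formulas", {
  tp <- letters[1:8]
  detected <- c("a", "b", "c", "d", "z")
  expect_equal(tpr(detected, tp), 0.8)
  expect_equal(dr(detected, tp), 0.5)
  expect_equal(tpr(c("a", "b"), tp), 1)
  expect_equal(dr(letters[1:10], tp), 1)
  expect_equal(tpr(c("x", "y"), tp), 0)
  expect_equal(dr(character(0), tp), 0)
  expect_true(is.na(tpr(character(0), tp)))
  expect_error(dr("a", character(0)), "empty")
})

test_that("top-N grids step by 50 with a terminal point at the full list", {
  set.seed(501)
  tp <- sprintf("cg%03d", 1:80)
  ranked <- sprintf("cg%03d", sample(1:200, 120))
  curve <- top_n_curve(ranked, tp, step = 50)
  expect_equal(curve$x, c(50, 100, 120))
  expect_true(all(diff(curve$dr) >= 0))  # nested sets
  expect_equal(curve$one_minus_dr, 1 - curve$dr)

  exact <- top_n_curve(sprintf("cg%03d", 1:100), tp, step = 50)
  expect_equal(exact$x, c(50, 100))
})

test_that("top-N curve equals brute-force recomputation on a 200-site fixture", {
  set.seed(502)
  universe <- sprintf("cg%03d", 1:400)
  tp <- sample(universe, 90)
  ranked <- sample(universe, 200)
  curve <- top_n_curve(ranked, tp, step = 50)
  for (k in seq_len(nrow(curve))) {
    det <- ranked[seq_len(curve$x[k])]
    hits <- length(intersect(det, tp))
    expect_equal(curve$tpr[k], hits / length(det))
    expect_equal(curve$dr[k], hits / length(tp))
  }
})

test_that("a ranking that is exactly the TP set has TPR 1 at every N", {
  set.seed(503)
  tp <- sprintf("cg%03d", 1:130)
  curve <- top_n_curve(sample(tp), tp, step = 50)
  expect_true(all(curve$tpr == 1))
  expect_equal(curve$dr[nrow(curve)], 1)
})

test_that("TPR and DR are invariant to site relabeling", {
  set.seed(504)
  tp <- sprintf("cg%03d", 1:40)
  detected <- sprintf("cg%03d", sample(1:100, 30))
  relabel <- stats::setNames(sprintf("s%03d", 1:100), sprintf("cg%03d", 1:100))
  expect_equal(tpr(unname(relabel[detected]), unname(relabel[tp])),
               tpr(detected, tp))
  expect_equal(dr(unname(relabel[detected]), unname(relabel[tp])),
               dr(detected, tp))
})

test_that("threshold sweeps anchor at the p-gate, shrink monotonically, and mark empty sets NA", {
  result <- structure(
    tibble::tibble(
      site_id = sprintf("cg%03d", 1:100),
      mean_a = 0, mean_b = 0,
      abs_diff = seq(0.01, 1, length.out = 100),
      t_statistic = 1,
      p_value = rep(c(0.01, 0.2), 50),
      range_group = factor("middle", c("low", "middle", "high"))
    ),
    class = c("meth_diff", class(tibble::tibble())), scale = "m"
  )
  tp <- sprintf("cg%03d", seq(2, 100, by = 2))
  sweep <- threshold_sweep(result, tp, c(0, 0.25, 0.5, 2))
  gate <- select_candidates(result, 0.05, 0)
  expect_equal(sweep$n_detected[1], length(gate))
  expect_equal(sweep$tpr[1], tpr(gate, tp))
  expect_true(all(diff(sweep$n_detected) <= 0))
  expect_equal(sweep$n_detected[4], 0L)
  expect_true(is.na(sweep$tpr[4]))
  expect_equal(sweep$dr[4], 0)
  expect_error(threshold_sweep(result, tp, c(0.5, 0)), "non-decreasing")
})

test_that("threshold guidance reads the plateau turning points", {
  # step-shaped toy sweep: DR flat until 0.4 then falling; TPR rising
  # until it plateaus at 1.4
  x <- seq(0, 2, by = 0.2)
  dr_curve <- c(rep(0.9, 3), 0.9 - 0.08 * seq_len(8))
  tpr_curve <- pmin(0.5 + 0.05 * (0:10), 0.85)
  curve <- structure(
    tibble::tibble(x = x, n_detected = 100:90, tpr = tpr_curve,
                   dr = dr_curve),
    axis = "threshold", class = c("eval_curve", class(tibble::tibble()))
  )
  out <- suggest_thresholds(curve)
  expect_equal(out$lower, 0.4)
  expect_equal(out$upper, 1.4)
  expect_false(out$flagged)

  # entirely flat curves degenerate to (last, first) and are flagged
  flat <- structure(
    tibble::tibble(x = x, n_detected = 100, tpr = 0.8, dr = 0.9),
    axis = "threshold", class = c("eval_curve", class(tibble::tibble()))
  )
  expect_warning(out_flat <- suggest_thresholds(flat), "not the expected")
  expect_equal(out_flat$lower, max(x))
  expect_equal(out_flat$upper, min(x))
  expect_true(out_flat$flagged)

  # zero tolerance on an exactly plateaued curve gives identical output
  out0 <- suggest_thresholds(curve, plateau_tolerance = 0)
  expect_equal(out0$lower, 0.4)
  expect_equal(out0$upper, 1.4)
  expect_error(suggest_thresholds(curve[1:2, ]), "at least 3")
  expect_error(suggest_thresholds(structure(curve, axis = "top_n")),
               "threshold-axis")
})

test_that("simulated differential sites with large true differences are recovered as TPs", {
  sim <- simulate_titration(4000, diff_fraction = 0.3, seed = 505)
  beta <- compute_beta(sim$intensities)
  m <- compute_m(sim$intensities)
  tp <- define_true_positives(beta, m, default_design())
  truth <- sim$truth
  big <- truth$is_differential & abs(truth$p_a - truth$p_b) >= 0.3
  expect_gte(mean(truth$site_id[big] %in% tp$site_ids), 0.95)
  null_leak <- mean(truth$site_id[!truth$is_differential] %in% tp$site_ids)
  expect_lte(null_leak, 0.07)
})
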