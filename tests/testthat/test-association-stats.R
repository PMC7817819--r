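# Full-enumeration oracle for the two-sided rank-sum p-value: distribute the
# combined ranks over all choose(n, n1) assignments and count rank sums at
# least as extreme as observed (two-sided by doubling the smaller tail).
enum_ranksum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(n, n1)
  w_all <- colSums(matrix(sort(r)[combos], nrow = n1))
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

test_that("pearson correlation matches hand-computed anchors", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x + 10), -1)
  expect_equal(pearson_r(x, c(1, 2, 4)), 3 / sqrt(2 * 14 / 3),
               tolerance = 1e-9)
  expect_warning(r0 <- pearson_r(x, c(2, 2, 2)), "zero variance")
  expect_true(is.na(r0))
  expect_error(pearson_r(x, 1:4), "lengths differ")
  # invariance to positive affine transforms
  set.seed(1)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(pearson_r(2.3 * a + 7, b), pearson_r(a, b), tolerance = 1e-12)
})

test_that("per-cycle correlation record summarises r with strength classes", {
  leg <- one_muscle_leg()
  phi <- seq(0, 1, length.out = 101)
  act <- 0.4 + 0.3 * sin(2 * pi * phi)^2
  st <- lapply(1:3, function(c)
    stiffness_series(leg, list(mus = act), list(knee_flexion = 0.2 * phi),
                     "knee_flexion", cycle_index = c))
  cci <- structure(list(pair = c("a", "b"), formulation = "CCI1",
                        variant = "delayed",
                        cycles = lapply(1:3, function(c) st[[c]]$k_joint)),
                   class = "cci_series")
  rec <- correlate_per_cycle(cci, st)
  expect_equal(rec$r_per_cycle, rep(1, 3))
  expect_equal(rec$r_sd, 0)
  expect_equal(rec$strength, "strong")
})

test_that("strength classification uses half-open magnitude intervals", {
  classify <- ccistiff:::.strength_class
  expect_equal(classify(0.29), "negligible")
  expect_equal(classify(0.3), "weak")
  expect_equal(classify(0.49), "weak")
  expect_equal(classify(0.5), "moderate")
  expect_equal(classify(0.6), "moderate")
  expect_equal(classify(0.7), "strong")
  expect_equal(classify(0.75), "strong")
  expect_equal(classify(-0.75), "strong")  # sign carried by the mean
})

test_that("rank-sum test reproduces textbook anchors", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$p_value, 0.1, tolerance = 1e-12)
  expect_equal(rs$method, "exact")
  expect_false(rs$significant)
  same <- suppressWarnings(rank_sum_test(c(1, 2, 3), c(1, 2, 3)))
  expect_gte(same$p_value, 0.99)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("exact rank-sum p equals the enumeration oracle for combined n <= 12", {
  set.seed(10)
  for (n1 in 2:6) for (n2 in 2:(min(6, 12 - n1))) {
    x <- round(rnorm(n1), 6); y <- round(rnorm(n2, 0.5), 6)
    p_pkg <- rank_sum_test(x, y)$p_value
    expect_equal(p_pkg, enum_ranksum_p(x, y), tolerance = 1e-12,
                 label = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("normal approximation tracks the exact p at the study sample size", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10, 0.4)
    p_ex <- rank_sum_test(x, y, exact = TRUE)$p_value
    p_ap <- rank_sum_test(x, y, exact = FALSE)$p_value
    expect_lt(abs(p_ex - p_ap), 0.02)
  }
})

test_that("best-pair report picks the highest mean r with a documented tie-break", {
  mk_rec <- function(pair, r, dof = "knee_flexion", formulation = "CCI1",
                     variant = "delayed")
    structure(list(dof = dof, pair = pair, formulation = formulation,
                   variant = variant, r_per_cycle = r, r_mean = mean(r),
                   r_sd = stats::sd(r),
                   strength = ccistiff:::.strength_class(mean(r))),
              class = "correlation_record")
  single <- best_pair_report(list(mk_rec(c("a", "b"), c(0.5, 0.6, 0.7))))
  expect_equal(single$best$pair, "a+b")
  # tie: lexicographically first pair wins, message emitted
  expect_message(
    tied <- best_pair_report(list(mk_rec(c("z", "q"), c(0.5, 0.6)),
                                  mk_rec(c("a", "b"), c(0.6, 0.5)))),
    "tie")
  expect_equal(tied$best$pair, "a+b")
  # contrast table pairs best CCI1 against best CCI2 per (dof, variant)
  recs <- list(mk_rec(c("a", "b"), c(0.8, 0.85, 0.9)),
               mk_rec(c("a", "c"), c(0.5, 0.55, 0.6)),
               mk_rec(c("a", "b"), c(0.2, 0.25, 0.3), formulation = "CCI2"))
  rep2 <- best_pair_report(recs)
  expect_equal(nrow(rep2$formulation_contrast), 1)
  expect_gt(rep2$formulation_contrast$diff, 0)
})
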