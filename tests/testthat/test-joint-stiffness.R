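test_that("joint moment assembles r times F over spanning muscles", {
  leg <- one_muscle_leg(r0 = 0.05)
  m <- leg$muscles[[1]]
  th <- c(knee_flexion = 0)
  # inactive on the ascending limb: no force, no moment
  expect_equal(joint_moment(leg, c(mus = 0), th, "knee_flexion"), 0)
  # single-term product against directly computed r * F
  f <- tendon_force(m$params, 0.7, mtu_length(m$geometry, th))
  expect_equal(joint_moment(leg, c(mus = 0.7), th, "knee_flexion"),
               0.05 * f)
  # mirror-image antagonists at equal activation cancel
  leg2 <- antagonist_leg(r0 = 0.05)
  expect_equal(joint_moment(leg2, c(flex = 0.4, ext = 0.4), th,
                            "knee_flexion"), 0, tolerance = 1e-12)
})

test_that("constant-moment-arm muscle stiffness is exactly r^2 times the force slope", {
  leg <- one_muscle_leg(r0 = 0.05)
  m <- leg$muscles[[1]]
  th <- c(knee_flexion = 0.2)
  k <- tendon_force_slope(m$params, 0.8, mtu_length(m$geometry, th))
  expect_equal(muscle_stiffness(leg, "mus", 0.8, th, "knee_flexion"),
               0.05^2 * k, tolerance = 1e-9)
  # slack and inactive: no force, no slope, no stiffness
  slack_leg <- one_muscle_leg(l_tilde0 = 0.8)
  expect_equal(muscle_stiffness(slack_leg, "mus", 0, th, "knee_flexion"), 0)
})

test_that("analytic stiffness equals the central-difference of the joint moment", {
  h <- 1e-5
  for (seed in 1:15) {
    leg <- random_leg(seed, n_muscles = 1)
    set.seed(seed + 100)
    a <- stats::setNames(runif(1), names(leg$muscles))
    th0 <- runif(1, -0.4, 0.4)
    k_an <- muscle_stiffness(leg, names(leg$muscles), unname(a),
                             c(knee_flexion = th0), "knee_flexion")
    m_up <- joint_moment(leg, a, c(knee_flexion = th0 + h), "knee_flexion")
    m_dn <- joint_moment(leg, a, c(knee_flexion = th0 - h), "knee_flexion")
    k_fd <- -(m_up - m_dn) / (2 * h)
    expect_equal(k_an, k_fd, tolerance = 1e-4)
  }
})

test_that("stiffness series is constant for constant inputs and additive across muscles", {
  leg <- random_leg(7, n_muscles = 3)
  nms <- names(leg$muscles)
  act <- stats::setNames(lapply(c(0.3, 0.6, 0.1), rep, 101), nms)
  ang <- list(knee_flexion = rep(0.1, 101))
  s <- stiffness_series(leg, act, ang, "knee_flexion")
  expect_length(s$k_joint, 101)
  expect_lt(diff(range(s$k_joint)), 1e-12)
  # additivity: sum of per-muscle columns reproduces the joint series
  expect_equal(s$k_joint, rowSums(s$k_mus), tolerance = 1e-12)
  # and matches single-muscle legs summed
  singles <- vapply(nms, function(nm) {
    leg1 <- leg_model(leg$muscles[nm], 82, dofs = "knee_flexion")
    stiffness_series(leg1, act[nm], ang, "knee_flexion")$k_joint[1]
  }, numeric(1))
  expect_equal(s$k_joint[1], sum(singles), tolerance = 1e-10)
  expect_error(stiffness_series(leg, act, list(knee_flexion = rep(0.1, 50)),
                                "knee_flexion"), "same length")
})

test_that("full-series finite-difference oracle holds at every grid point", {
  leg <- random_leg(21, n_muscles = 3)
  nms <- names(leg$muscles)
  set.seed(5)
  phi <- seq(0, 1, length.out = 101)
  act <- stats::setNames(lapply(nms, function(n)
    pmin(pmax(0.4 + 0.3 * sin(2 * pi * phi + runif(1, 0, 6)), 0), 1)), nms)
  th <- 0.3 * sin(2 * pi * phi)
  s <- stiffness_series(leg, act, list(knee_flexion = th), "knee_flexion")
  h <- 1e-5
  rel_err <- vapply(1:101, function(i) {
    a_i <- vapply(act, `[[`, numeric(1), i)
    m_up <- joint_moment(leg, a_i, c(knee_flexion = th[i] + h),
                         "knee_flexion")
    m_dn <- joint_moment(leg, a_i, c(knee_flexion = th[i] - h),
                         "knee_flexion")
    k_fd <- -(m_up - m_dn) / (2 * h)
    abs(s$k_joint[i] - k_fd) / max(abs(k_fd), 1)
  }, numeric(1))
  expect_lt(max(rel_err), 1e-4)
})

test_that("passive antagonist joint on the stretch limb has positive stiffness", {
  # both fibres beyond optimal length at neutral: passive springs engage
  leg <- leg_model(list(linear_muscle("flex", 0.04, "FLEX", l_tilde0 = 1.15),
                        linear_muscle("ext", -0.04, "EXT", l_tilde0 = 1.15)),
                   82, dofs = "knee_flexion")
  s <- stiffness_series(leg, list(flex = rep(0, 11), ext = rep(0, 11)),
                        list(knee_flexion = seq(-0.1, 0.1, length.out = 11)),
                        "knee_flexion")
  expect_true(all(s$k_joint > 0))
})

test_that("raising activation on the ascending limb does not reduce stiffness", {
  leg <- one_muscle_leg(l_tilde0 = 0.9)
  th <- c(knee_flexion = 0)
  k <- vapply(seq(0, 1, 0.1), function(a)
    muscle_stiffness(leg, "mus", a, th, "knee_flexion"), numeric(1))
  expect_true(all(diff(k) >= 0))
})

test_that("contribution fractions follow hand arithmetic and sum to one", {
  leg <- random_leg(3, n_muscles = 3)
  nms <- names(leg$muscles)
  act <- stats::setNames(lapply(c(0.5, 0.2, 0.8), rep, 101), nms)
  ang <- list(knee_flexion = rep(0.05, 101))
  s <- stiffness_series(leg, act, ang, "knee_flexion")
  fr <- contribution_fractions(s)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  # single-muscle joint: the one muscle owns all stiffness
  leg1 <- one_muscle_leg()
  s1 <- stiffness_series(leg1, list(mus = rep(0.5, 101)),
                         list(knee_flexion = rep(0, 101)), "knee_flexion")
  expect_equal(unname(contribution_fractions(s1)), 1)
  # constructed 1:1:98 magnitude split lands on 0.01 / 0.01 / 0.98
  fake <- s
  fake$k_mus <- matrix(rep(c(1, 1, 98), each = 101), ncol = 3,
                       dimnames = list(NULL, nms))
  fake$k_joint <- rowSums(fake$k_mus)
  fr3 <- contribution_fractions(fake)
  expect_equal(unname(fr3), c(0.01, 0.01, 0.98))
  expect_true(all(fr3[1:2] < 0.02))
  fake$k_mus[] <- 0
  expect_error(contribution_fractions(fake), "all-zero")
})
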