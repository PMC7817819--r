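test_that("subject generation is deterministic and carries the study delays", {
  s1 <- make_subject(seed = 5)
  s2 <- make_subject(seed = 5)
  expect_identical(s1, s2)
  expect_equal(s1$legs[["non-paretic"]]$electromechanical_delay, 82)
  expect_equal(s1$legs[["paretic"]]$electromechanical_delay, 93)
  expect_length(s1$legs[["non-paretic"]]$muscles, 16)
  scales <- vapply(s1$legs[[1]]$muscles, `[[`, numeric(1), "emg_scale")
  expect_true(all(scales >= 0.05 & scales <= 1))
  s3 <- make_subject(seed = 6)
  expect_false(identical(
    vapply(s3$legs[[1]]$muscles, `[[`, numeric(1), "emg_scale"), scales))
})

test_that("a configuration without antagonism is rejected", {
  ros <- default_muscle_roster()
  ros <- lapply(ros, function(m) {
    if (identical(unname(m$roles["knee_flexion"]), "FLEX"))
      m$roles["knee_flexion"] <- "EXT"
    m
  })
  expect_error(make_subject(subject_config(muscles = ros), seed = 1),
               "no antagonism")
})

test_that("trial generation counts cycles and is seed-reproducible", {
  subj <- make_subject(seed = 3)
  sim <- make_gait_trial(subj, n_cycles = 10, coupling = "coupled", seed = 3,
                         ground_truth = FALSE)
  expect_length(sim$trial$heel_strikes, 11)
  sim2 <- make_gait_trial(subj, n_cycles = 10, coupling = "coupled",
                          seed = 3, ground_truth = FALSE)
  expect_identical(sim$trial, sim2$trial)
  expect_error(make_gait_trial(subj, n_cycles = 0, seed = 1), "n_cycles")
  # angles stay inside the declared physiologic boxes
  box <- ccistiff:::.dof_boxes()
  for (d in rownames(box)) {
    a <- sim$trial$joint_angles[[d]]
    expect_true(all(a >= box[d, 1] & a <= box[d, 2]))
  }
})

test_that("ground-truth envelopes are bounded and raw EMG is zero-mean", {
  sc <- tiny_scenario(seed = 12, n_cycles = 2)
  leg <- sc$truth$legs[["non-paretic"]]
  for (e in leg$true_envelopes) expect_true(all(e >= 0 & e <= 1))
  for (a in leg$true_activations) expect_true(all(a >= 0 & a <= 1))
  for (ch in sc$trial$legs[["non-paretic"]]$emg) {
    se <- stats::sd(ch) / sqrt(length(ch))
    expect_lt(abs(mean(ch)), 3 * se)
  }
})

test_that("independent scenario decorrelates antagonist burst amplitudes across cycles", {
  subj <- make_subject(seed = 7)
  sim <- make_gait_trial(subj, n_cycles = 50, coupling = "independent",
                         seed = 7, ground_truth = FALSE)
  env <- sim$truth$legs[["non-paretic"]]$true_envelopes
  hs <- sim$trial$heel_strikes
  amp_per_cycle <- function(e) vapply(
    resample_cycles(e, sim$trial$emg_rate, hs), max, numeric(1))
  pairs <- list(c("tibant", "soleus"), c("vasmed", "gasmed"),
                c("recfem", "bflh"), c("addlong", "glmax"))
  for (p in pairs) {
    r <- stats::cor(amp_per_cycle(env[[p[1]]]), amp_per_cycle(env[[p[2]]]))
    expect_lt(abs(r), 0.3, label = paste(p, collapse = "+"))
  }
  # coupled scenario: shared per-cycle amplitude factor couples the same pairs
  simc <- make_gait_trial(subj, n_cycles = 50, coupling = "coupled",
                          seed = 7, ground_truth = FALSE)
  envc <- simc$truth$legs[["non-paretic"]]$true_envelopes
  hsc <- simc$trial$heel_strikes
  ampc <- function(e) vapply(resample_cycles(e, 1000, hsc), max, numeric(1))
  r_c <- stats::cor(ampc(envc[["tibant"]]), ampc(envc[["soleus"]]))
  expect_gt(r_c, 0.5)
})

test_that("zero burst amplitudes leave only passive, activation-free stiffness", {
  ros <- lapply(default_muscle_roster(), function(m) { m$amp <- 0; m })
  subj <- make_subject(subject_config(muscles = ros), seed = 2)
  sim <- make_gait_trial(subj, n_cycles = 2, coupling = "coupled", seed = 2,
                         noise_floor = 0)
  truth <- sim$truth$legs[["non-paretic"]]
  for (a in truth$true_activations) expect_true(all(a == 0))
  # stiffness identical across cycles (pure function of the periodic angles)
  k <- truth$true_stiffness$knee_flexion
  expect_equal(k[[1]]$k_joint, k[[2]]$k_joint, tolerance = 1e-9)
})

test_that("coupled scenario makes summed antagonist activity track true stiffness", {
  subj <- make_subject(seed = 9)
  sim <- make_gait_trial(subj, n_cycles = 5, coupling = 1.0, seed = 9)
  leg <- subj$legs[["non-paretic"]]
  truth <- sim$truth$legs[["non-paretic"]]
  hs <- sim$trial$heel_strikes
  for (d in c("knee_flexion", "ankle_dorsiflexion")) {
    spanning <- names(leg$muscles)[vapply(leg$muscles, spans_dof, logical(1),
                                          dof = d)]
    summed <- Reduce(`+`, lapply(truth$true_envelopes[spanning], function(e)
      delay_shift(e, 1000, leg$electromechanical_delay)))
    cyc <- resample_cycles(summed, 1000, hs)
    r <- vapply(seq_along(cyc), function(c)
      pearson_r(cyc[[c]], truth$true_stiffness[[d]][[c]]$k_joint),
      numeric(1))
    expect_gt(mean(r), 0.7)
  }
})

test_that("raw EMG synthesis respects its modulation contract", {
  expect_identical(synthesize_raw_emg(rep(0, 2000), 1000, noise_floor = 0,
                                      seed = 1), rep(0, 2000))
  # constant envelope: zero-mean carrier, reproducible for a fixed seed
  x1 <- synthesize_raw_emg(rep(0.5, 5000), 1000, seed = 4)
  x2 <- synthesize_raw_emg(rep(0.5, 5000), 1000, seed = 4)
  expect_identical(x1, x2)
  expect_lt(abs(mean(x1)), 3 * stats::sd(x1) / sqrt(length(x1)))
  expect_error(synthesize_raw_emg(rep(0.5, 100), 800, seed = 1), "900")
  expect_warning(synthesize_raw_emg(rep(0.5, 3000), 950, seed = 1),
                 "below 1000")
  expect_error(synthesize_raw_emg(rep(0.5, 100), 1000, noise_floor = 0.5,
                                  seed = 1), "noise_floor")
})

test_that("synthesized EMG round-trips through envelope processing", {
  period <- 1.4
  t <- seq(0, 0.5 + 3 * period + 0.5, by = 1e-3)
  hs <- 0.5 + period * (0:3)
  env_true <- numeric(length(t))
  for (c in 0:4) env_true <- env_true +
    0.7 * exp(-(t - (0.5 + (c - 1 + 0.45) * period))^2 / (2 * (0.07 * period)^2))
  env_true <- pmin(env_true, 1)
  raw <- synthesize_raw_emg(env_true, 1000, noise_floor = 0.02, seed = 21)
  est <- segment_normalize(emg_envelope(raw, 1000, period), 1000, hs)$cycles
  ref <- segment_normalize(env_true, 1000, hs)$cycles
  rmse <- sqrt(mean((unlist(est) - unlist(ref))^2))
  expect_lt(rmse, 0.1)  # relative to unit peak after normalisation
})
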