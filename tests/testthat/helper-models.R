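# Shared fixtures, built in code.

# Linear-geometry muscle: constant moment arm r0 about one DOF.
linear_muscle <- function(name = "mus", r0 = 0.05, role = "FLEX",
                          dof = "knee_flexion", f_max = 1500, l_opt = 0.1,
                          l_tilde0 = 0.95, alpha_opt = 0, l_slack = 0.2) {
  pr <- muscle_params(f_max = f_max, l_opt = l_opt, l_slack = l_slack,
                      alpha_opt = alpha_opt)
  w <- l_opt * sin(alpha_opt)
  l0 <- l_slack + sqrt((l_tilde0 * l_opt)^2 - w^2)
  geom <- muscle_geometry(dof, matrix(0:1, ncol = 1), c(l0, -r0),
                          angle_box = matrix(c(-1, 1), ncol = 1))
  roles <- stats::setNames(role, dof)
  muscle_entry(name, name, roles, pr, geom, emg_scale = 1)
}

one_muscle_leg <- function(...) {
  leg_model(list(linear_muscle(...)), electromechanical_delay = 82,
            dofs = "knee_flexion", label = "toy")
}

antagonist_leg <- function(r0 = 0.05) {
  leg_model(list(linear_muscle("flex", r0 = r0, role = "FLEX"),
                 linear_muscle("ext", r0 = -r0, role = "EXT")),
            electromechanical_delay = 82, dofs = "knee_flexion",
            label = "toy2")
}

# Random single-DOF leg with quadratic geometry, for oracle sweeps.
random_leg <- function(seed, n_muscles = 3) {
  set.seed(seed)
  muscles <- lapply(seq_len(n_muscles), function(i) {
    sgn <- if (i %% 2 == 0) -1 else 1
    pr <- muscle_params(f_max = runif(1, 500, 3000),
                        l_opt = runif(1, 0.08, 0.14),
                        l_slack = runif(1, 0.1, 0.3),
                        alpha_opt = runif(1, 0, 0.25))
    w <- pr$l_opt * sin(pr$alpha_opt)
    l0 <- pr$l_slack + sqrt((runif(1, 0.9, 1.1) * pr$l_opt)^2 - w^2)
    geom <- muscle_geometry(
      "knee_flexion", matrix(0:2, ncol = 1),
      c(l0, -sgn * runif(1, 0.02, 0.05), runif(1, -0.008, 0.008)),
      angle_box = matrix(c(-0.6, 0.6), ncol = 1))
    roles <- stats::setNames(if (sgn > 0) "FLEX" else "EXT", "knee_flexion")
    muscle_entry(paste0("m", i), paste0("m", i), roles, pr, geom)
  })
  leg_model(muscles, electromechanical_delay = 82, dofs = "knee_flexion",
            label = paste0("rand", seed))
}

# Small, fast synthetic scenario shared by pipeline-level tests.
tiny_scenario <- function(seed = 11, n_cycles = 2, coupling = "coupled") {
  subj <- make_subject(seed = seed)
  sim <- make_gait_trial(subj, n_cycles = n_cycles, coupling = coupling,
                         seed = seed)
  list(subject = subj, trial = sim$trial, truth = sim$truth)
}
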