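# Run expr with a private RNG stream; the caller's RNG state is untouched.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

.derive_seed <- function(seed, k) {
  as.integer((as.double(seed) + 7919 * k) %% (.Machine$integer.max - 1)) + 1L
}

#' Default muscle roster for the virtual subject
#'
#' Sixteen muscles per leg mirroring a typical lower-limb surface +
#' fine-wire EMG montage: hip flexors/extensors, knee
#' extensors/flexors (including the biarticular rectus femoris, hamstrings
#' and gastrocnemii) and ankle dorsi-/plantarflexors. Deep muscles recorded
#' by fine-wire electrodes (iliacus, psoas, tibialis posterior) carry the
#' \code{fine_wire} flag so the surface-EMG-only restriction of the CCI
#' analysis is exercised. Burst centres/widths (fractions of the gait cycle)
#' and amplitudes parameterise the Gaussian activation bursts of the
#' generator and are laid out as a stance/swing alternation typical of gait.
#'
#' @return list of per-muscle specification lists.
#' @export
default_muscle_roster <- function() {
  m <- function(name, fine_wire, roles, f_max, l_opt, arms,
                center, width, amp)
    list(name = name, fine_wire = fine_wire, roles = roles, f_max = f_max,
         l_opt = l_opt, arms = arms, center = center, width = width,
         amp = amp)
  hip <- "hip_flexion"; knee <- "knee_flexion"; ank <- "ankle_dorsiflexion"
  list(
    m("glmax",   FALSE, c(hip_flexion = "EXT"), 2000, 0.14,
      c(hip_flexion = -0.045), 0.10, 0.05, 0.65),
    m("glmed",   FALSE, c(hip_flexion = "EXT"), 1500, 0.10,
      c(hip_flexion = -0.035), 0.12, 0.05, 0.55),
    m("iliacus", TRUE,  c(hip_flexion = "FLEX"), 1200, 0.11,
      c(hip_flexion = 0.040), 0.65, 0.05, 0.60),
    m("psoas",   TRUE,  c(hip_flexion = "FLEX"), 1200, 0.12,
      c(hip_flexion = 0.040), 0.67, 0.05, 0.60),
    m("addlong", FALSE, c(hip_flexion = "FLEX"), 900, 0.11,
      c(hip_flexion = 0.035), 0.65, 0.05, 0.55),
    m("recfem",  FALSE, c(hip_flexion = "FLEX", knee_flexion = "EXT"),
      1200, 0.13, c(hip_flexion = 0.030, knee_flexion = -0.035),
      0.65, 0.05, 0.60),
    m("vasmed",  FALSE, c(knee_flexion = "EXT"), 1800, 0.10,
      c(knee_flexion = -0.045), 0.15, 0.05, 0.70),
    m("vaslat",  FALSE, c(knee_flexion = "EXT"), 2000, 0.10,
      c(knee_flexion = -0.045), 0.17, 0.05, 0.70),
    m("bflh",    FALSE, c(hip_flexion = "EXT", knee_flexion = "FLEX"),
      1300, 0.13, c(hip_flexion = -0.030, knee_flexion = 0.030),
      0.90, 0.05, 0.60),
    m("semimem", FALSE, c(hip_flexion = "EXT", knee_flexion = "FLEX"),
      1500, 0.13, c(hip_flexion = -0.030, knee_flexion = 0.030),
      0.92, 0.05, 0.60),
    m("semiten", FALSE, c(hip_flexion = "EXT", knee_flexion = "FLEX"),
      600, 0.14, c(hip_flexion = -0.030, knee_flexion = 0.030),
      0.92, 0.05, 0.50),
    m("gasmed",  FALSE, c(knee_flexion = "FLEX", ankle_dorsiflexion = "PF"),
      1600, 0.10, c(knee_flexion = 0.025, ankle_dorsiflexion = -0.040),
      0.40, 0.05, 0.70),
    m("gaslat",  FALSE, c(knee_flexion = "FLEX", ankle_dorsiflexion = "PF"),
      900, 0.10, c(knee_flexion = 0.025, ankle_dorsiflexion = -0.040),
      0.42, 0.05, 0.60),
    m("soleus",  FALSE, c(ankle_dorsiflexion = "PF"), 3000, 0.08,
      c(ankle_dorsiflexion = -0.040), 0.40, 0.05, 0.80),
    m("tibant",  FALSE, c(ankle_dorsiflexion = "DF"), 1200, 0.10,
      c(ankle_dorsiflexion = 0.040), 0.68, 0.05, 0.70),
    m("tibpost", TRUE,  c(ankle_dorsiflexion = "PF"), 1400, 0.09,
      c(ankle_dorsiflexion = -0.035), 0.40, 0.05, 0.50))
}

#' Generator configuration for the virtual subject
#'
#' @param muscles muscle roster (see \code{\link{default_muscle_roster}}).
#' @param delays_ms per-leg electromechanical delays (ms); defaults 82 and
#'   93 ms for the non-paretic and paretic leg.
#' @param cycle_period gait-cycle period (s); default 1.4 s, a slow
#'   hemiparetic gait.
#' @param scale_range range the muscle-specific EMG scale factors are drawn
#'   from, within (0, 1].
#' @param neutral_norm_fiber normalised fibre length at the neutral pose
#'   (slightly below optimal so fibres work on the ascending limb).
#' @return a list of class \code{subject_config}.
#' @export
subject_config <- function(muscles = default_muscle_roster(),
                           delays_ms = c(82, 93), cycle_period = 1.4,
                           scale_range = c(0.05, 1),
                           neutral_norm_fiber = 0.95) {
  stopifnot(length(delays_ms) == 2L, all(delays_ms >= 0), cycle_period > 0,
            scale_range[1] > 0, scale_range[2] <= 1)
  structure(list(muscles = muscles, delays_ms = delays_ms,
                 cycle_period = cycle_period, scale_range = scale_range,
                 neutral_norm_fiber = neutral_norm_fiber),
            class = "subject_config")
}

.dof_boxes <- function() {
  rbind(hip_flexion = c(-0.6, 0.7), knee_flexion = c(-0.3, 1.0),
        ankle_dorsiflexion = c(-0.5, 0.5))
}

# Geometry for one roster muscle: quadratic polynomial per spanned DOF
# (linear term sets the moment arm at neutral; a small quadratic gives a
# nonzero moment-arm gradient) plus a small bilinear cross-term for
# biarticular muscles.
.roster_geometry <- function(spec, params, neutral_norm_fiber) {
  dofs <- names(spec$arms)
  w <- params$l_opt * sin(params$alpha_opt)
  h0 <- sqrt((neutral_norm_fiber * params$l_opt)^2 - w^2)
  l0 <- params$l_slack + h0
  exps <- matrix(0L, nrow = 1, ncol = length(dofs))
  coefs <- l0
  for (j in seq_along(dofs)) {
    e1 <- integer(length(dofs)); e1[j] <- 1L
    e2 <- integer(length(dofs)); e2[j] <- 2L
    exps <- rbind(exps, e1, e2)
    coefs <- c(coefs, spec$arms[[j]] * -1, 0.004)
  }
  if (length(dofs) == 2L) {
    exps <- rbind(exps, c(1L, 1L))
    coefs <- c(coefs, 0.002)
  }
  box <- t(.dof_boxes()[dofs, , drop = FALSE])
  muscle_geometry(dofs, exps, coefs, angle_box = box)
}

#' Generate a virtual hemiparetic subject
#'
#' Builds a two-legged subject model from a generator configuration:
#' Hill-type parameters and polynomial geometry per muscle, leg-specific
#' electromechanical delays (82 / 93 ms by default) and seeded
#' muscle-specific EMG scale factors drawn uniformly from the configured
#' range. Deterministic for a fixed (config, seed).
#'
#' @param config a \code{\link{subject_config}}.
#' @param seed integer seed.
#' @return a \code{\link{virtual_subject}}.
#' @export
make_subject <- function(config = subject_config(), seed = 1L) {
  dofs <- c("hip_flexion", "knee_flexion", "ankle_dorsiflexion")
  for (d in dofs) {
    roles <- vapply(config$muscles, function(s)
      if (d %in% names(s$roles)) s$roles[[d]] else "none", character(1))
    if (!any(roles %in% c("FLEX", "DF")) || !any(roles %in% c("EXT", "PF")))
      stop("DOF ", d, " has no opposing muscle roles: no antagonism possible")
  }
  .with_seed(seed, {
    legs <- list()
    leg_names <- c("non-paretic", "paretic")
    for (li in 1:2) {
      entries <- lapply(config$muscles, function(spec) {
        pr <- muscle_params(
          f_max = spec$f_max, l_opt = spec$l_opt,
          l_slack = 2 * spec$l_opt, alpha_opt = 0.1)
        geom <- .roster_geometry(spec, pr, config$neutral_norm_fiber)
        roles <- spec$roles
        sc <- stats::runif(1, config$scale_range[1], config$scale_range[2])
        muscle_entry(spec$name, spec$name, roles, pr, geom,
                     emg_scale = round(sc, 2), fine_wire = spec$fine_wire)
      })
      legs[[leg_names[li]]] <- leg_model(
        entries, electromechanical_delay = config$delays_ms[li],
        dofs = dofs, label = leg_names[li])
    }
    subj <- virtual_subject(sprintf("synthetic-%d", seed), legs,
                            config$cycle_period)
    subj$roster <- config$muscles
    subj
  })
}

.default_kinematics <- function(phi) {
  list(
    hip_flexion = 0.05 + 0.20 * cos(2 * pi * phi) + 0.03 * sin(4 * pi * phi),
    knee_flexion = 0.25 - 0.15 * cos(2 * pi * phi) + 0.05 * sin(4 * pi * phi),
    ankle_dorsiflexion = 0.04 * sin(2 * pi * phi) + 0.06 * sin(4 * pi * phi))
}

.default_kinematics_rate <- function(phi, period) {
  f <- 2 * pi / period
  list(
    hip_flexion = -0.20 * f * sin(2 * pi * phi) +
      0.03 * 2 * f * cos(4 * pi * phi),
    knee_flexion = 0.15 * f * sin(2 * pi * phi) +
      0.05 * 2 * f * cos(4 * pi * phi),
    ankle_dorsiflexion = 0.04 * f * cos(2 * pi * phi) +
      0.06 * 2 * f * cos(4 * pi * phi))
}

#' Synthesize raw surface EMG from an envelope
#'
#' Amplitude-modulates a zero-mean band-limited (40-450 Hz) Gaussian carrier
#' by \code{envelope + noise_floor}. The carrier is scaled to unit mean
#' absolute value so the standard rectify-and-low-pass pipeline recovers the
#' envelope amplitude.
#'
#' @param envelope numeric series in [0, 1], sampled at \code{rate}.
#' @param rate sample rate (Hz). Below 1000 Hz a warning is issued; at or
#'   below 900 Hz (twice the 450 Hz carrier band edge) an error is raised.
#' @param noise_floor baseline modulation in [0, 0.2).
#' @param seed integer seed.
#' @return zero-mean raw EMG series, same length as \code{envelope}.
#' @export
synthesize_raw_emg <- function(envelope, rate, noise_floor = 0.02,
                               seed = 1L) {
  if (rate <= 900) stop("sample rate must exceed 900 Hz (2 x 450 Hz carrier band)")
  if (rate < 1000) warning("sample rate below 1000 Hz")
  if (noise_floor < 0 || noise_floor >= 0.2)
    stop("noise_floor must lie in [0, 0.2)")
  if (any(envelope < 0)) stop("envelope must be non-negative")
  mod <- envelope + noise_floor
  if (all(mod == 0)) return(numeric(length(envelope)))
  .with_seed(seed, {
    carrier <- stats::rnorm(length(envelope))
    carrier <- .zero_phase_filter(carrier, rate, c(40, 450), "pass", order = 2)
    carrier <- carrier / mean(abs(carrier))
    carrier * mod
  })
}

#' Generate a multi-cycle gait trial with ground truth
#'
#' Produces, for each leg of the subject: smooth two-harmonic joint-angle
#' trajectories, per-muscle envelopes built from per-cycle Gaussian bursts
#' with lognormal amplitude jitter, raw EMG synthesized from those
#' envelopes, and ground-truth activations and joint stiffness. The
#' ground-truth mechanics use excitations delayed by the leg's
#' electromechanical delay and scaled by the muscle's EMG scale factor, so
#' both calibration parameters are genuinely present in the synthetic data
#' and recoverable downstream.
#'
#' Coupling between antagonist co-activation and stiffness is controlled by
#' \code{coupling}: under \code{"coupled"} (strength 1) every muscle of a leg
#' bursts in a common window with a shared per-cycle amplitude factor, so
#' co-contraction tracks joint stiffness within each cycle; under
#' \code{"independent"} (strength 0) each muscle keeps its own roster burst
#' phase, jittered per cycle, with independent amplitudes.
#'
#' @param subject a \code{\link{virtual_subject}}.
#' @param n_cycles number of analysable gait cycles (>= 1); the trial has
#'   \code{n_cycles + 1} heel strikes plus lead-in and tail padding.
#' @param coupling \code{"coupled"}, \code{"independent"}, or a numeric
#'   coupling strength in [0, 1].
#' @param seed integer seed.
#' @param emg_rate,kin_rate EMG and kinematics sample rates (Hz).
#' @param amp_jitter_sd lognormal sigma of cycle-to-cycle amplitude jitter.
#' @param center_jitter half-width (fraction of cycle) of the per-cycle
#'   burst-centre jitter applied in the independent scenario.
#' @param noise_floor carrier noise floor passed to
#'   \code{\link{synthesize_raw_emg}}.
#' @param lead lead-in (and tail) duration before the first (after the last)
#'   heel strike (s); must exceed the electromechanical delay.
#' @param ground_truth compute ground-truth activations and stiffness
#'   (default TRUE); FALSE skips the mechanics for envelope-only studies.
#' @return list with \code{trial} (class \code{gait_trial}) and \code{truth}
#'   (class \code{ground_truth}).
#' @export
make_gait_trial <- function(subject, n_cycles = 10,
                            coupling = c("coupled", "independent"),
                            seed = 1L, emg_rate = 1000, kin_rate = 100,
                            amp_jitter_sd = 0.15, center_jitter = 0.05,
                            noise_floor = 0.02, lead = 0.5,
                            ground_truth = TRUE) {
  if (n_cycles < 1) stop("n_cycles must be at least 1")
  if (is.character(coupling)) {
    coupling <- match.arg(coupling)
    s <- if (coupling == "coupled") 1 else 0
  } else {
    s <- as.numeric(coupling)
    if (s < 0 || s > 1) stop("coupling strength must lie in [0, 1]")
  }
  period <- subject$cycle_period
  max_delay <- max(vapply(subject$legs, `[[`, numeric(1),
                          "electromechanical_delay")) / 1000
  if (lead <= max_delay) stop("lead-in must exceed the electromechanical delay")
  heel_strikes <- lead + period * (0:n_cycles)
  total <- lead + n_cycles * period + lead
  t_emg <- seq(0, total, by = 1 / emg_rate)
  t_kin <- seq(0, total, by = 1 / kin_rate)
  phi_kin <- (t_kin - lead) / period
  angles <- .default_kinematics(phi_kin)
  velocities <- .default_kinematics_rate(phi_kin, period)
  cc_center <- 0.30

  out_legs <- list(); truth_legs <- list()
  midx <- 0L
  for (leg_name in names(subject$legs)) {
    leg <- subject$legs[[leg_name]]
    # per-cycle amplitude factor shared by all muscles of the leg in the
    # coupled scenario
    z_common <- .with_seed(
      .derive_seed(seed, 500000L + match(leg_name, names(subject$legs))),
      stats::rnorm(n_cycles + 2L))
    emg <- list(); env_true <- list(); act_true <- list()
    for (m in leg$muscles) {
      midx <- midx + 1L
      ros <- .roster_lookup(subject, m$name)
      draw_seed <- .derive_seed(seed, midx)
      env <- .with_seed(draw_seed, {
        z_own <- stats::rnorm(n_cycles + 2L)
        u_center <- stats::runif(n_cycles + 2L, -center_jitter, center_jitter)
        amps <- pmin(ros$amp * exp(amp_jitter_sd *
                                     (s * z_common + sqrt(1 - s^2) * z_own)), 1)
        centers <- s * cc_center + (1 - s) * (ros$center + u_center)
        e <- numeric(length(t_emg))
        for (c in seq_len(n_cycles + 2L)) {
          tc <- lead + (c - 2L + centers[c]) * period
          e <- e + amps[c] * exp(-(t_emg - tc)^2 / (2 * (ros$width * period)^2))
        }
        pmin(e, 1)
      })
      env_true[[m$name]] <- env
      if (ground_truth) {
        excitation <- delay_shift(env, emg_rate,
                                  leg$electromechanical_delay) * m$emg_scale
        act_true[[m$name]] <- excitation_to_activation(excitation, m$params,
                                                       emg_rate)
      }
      emg[[m$name]] <- synthesize_raw_emg(env, emg_rate, noise_floor,
                                          seed = .derive_seed(seed, 100000L + midx))
    }
    # ground-truth joint stiffness on the 101-point grid per analysed cycle
    k_true <- list()
    if (ground_truth) {
      ang101 <- lapply(angles, function(a)
        resample_cycles(a, kin_rate, heel_strikes))
      act101 <- lapply(act_true, function(a)
        resample_cycles(a, emg_rate, heel_strikes))
      for (d in leg$dofs) {
        k_true[[d]] <- lapply(seq_len(n_cycles), function(c) {
          stiffness_series(
            leg,
            lapply(act101, `[[`, c),
            lapply(ang101, `[[`, c),
            dof = d, cycle_index = c)
        })
      }
    }
    out_legs[[leg_name]] <- list(emg = emg)
    truth_legs[[leg_name]] <- list(true_envelopes = env_true,
                                   true_activations = act_true,
                                   true_stiffness = k_true)
  }
  trial <- structure(list(emg_rate = emg_rate, kin_rate = kin_rate,
                          heel_strikes = heel_strikes,
                          joint_angles = angles,
                          joint_velocities = velocities,
                          legs = out_legs, seed = seed, coupling = s),
                     class = "gait_trial")
  truth <- structure(list(legs = truth_legs), class = "ground_truth")
  list(trial = trial, truth = truth)
}

# Roster lookup for burst parameters: taken from the roster the subject was
# generated with, falling back to the default roster, then to a generic burst.
.roster_lookup <- function(subject, name) {
  for (ros in list(subject$roster, default_muscle_roster())) {
    if (is.null(ros)) next
    nm <- vapply(ros, `[[`, character(1), "name")
    hit <- match(name, nm)
    if (!is.na(hit)) return(ros[[hit]])
  }
  list(center = 0.3, width = 0.05, amp = 0.6)
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("Gait trial: %d heel strikes (%d cycles), EMG %g Hz, kinematics %g Hz\n",
              length(x$heel_strikes), length(x$heel_strikes) - 1L,
              x$emg_rate, x$kin_rate))
  cat(sprintf("  coupling strength %.2f, seed %d\n", x$coupling, x$seed))
  invisible(x)
}
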