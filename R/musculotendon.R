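#' Hill-type muscle parameters (rigid tendon)
#'
#' Parameter container for a rigid-tendon Hill-type musculotendon actuator
#' with Gaussian active force-length, exponential passive force-length and
#' constant-thickness pennation. Stiffness is evaluated isometrically (the
#' force-velocity multiplier is held at 1), because joint stiffness is the
#' elastic response of the joint moment to changes in joint position only.
#'
#' @param f_max maximal isometric force (N), > 0.
#' @param l_opt optimal fibre length (m), > 0.
#' @param l_slack tendon slack length (m), >= 0; the tendon is rigid so this
#'   is the constant tendon length.
#' @param alpha_opt pennation angle at optimal fibre length (rad), in
#'   [0, pi/2).
#' @param tau_act,tau_deact activation / deactivation time constants (s);
#'   physiologically tau_act <= tau_deact.
#' @param shape_A activation-nonlinearity shape in [-3, 0); values near 0
#'   approach a linear excitation-activation map.
#' @param fl_width width of the Gaussian active force-length curve
#'   (dimensionless, > 0).
#' @param passive_strain_ref fibre strain at which the passive curve reaches
#'   its reference force (dimensionless).
#' @param passive_exp_shape exponential shape of the passive curve.
#' @return an object of class \code{muscle_params}.
#' @export
muscle_params <- function(f_max, l_opt, l_slack, alpha_opt = 0,
                          tau_act = 0.015, tau_deact = 0.05,
                          shape_A = -2, fl_width = 0.45,
                          passive_strain_ref = 0.6,
                          passive_exp_shape = 4) {
  stopifnot(f_max > 0, l_opt > 0, l_slack >= 0,
            alpha_opt >= 0, alpha_opt < pi / 2,
            tau_act > 0, tau_deact > 0, fl_width > 0,
            passive_strain_ref > 0, passive_exp_shape > 0,
            shape_A >= -3, shape_A < 0)
  if (tau_act > tau_deact)
    stop("tau_act must not exceed tau_deact (activation is faster than deactivation)")
  structure(list(f_max = f_max, l_opt = l_opt, l_slack = l_slack,
                 alpha_opt = alpha_opt, tau_act = tau_act,
                 tau_deact = tau_deact, shape_A = shape_A,
                 fl_width = fl_width,
                 passive_strain_ref = passive_strain_ref,
                 passive_exp_shape = passive_exp_shape),
            class = "muscle_params")
}

#' Activation dynamics: excitation to activation
#'
#' First-order activation dynamics with an activation-dependent time constant
#' (fast during activation, slow during deactivation), integrated by backward
#' Euler, followed by an optional exponential shape nonlinearity
#' a' = (exp(A a) - 1) / (exp(A) - 1).
#'
#' @param excitation numeric series in [0, 1] (the neural excitation; in this
#'   pipeline, the delayed + scaled EMG envelope).
#' @param params a \code{\link{muscle_params}} object.
#' @param rate sample rate of \code{excitation} (Hz), > 0.
#' @param a0 initial activation; defaults to the first excitation sample so a
#'   trial that starts at rest starts at rest.
#' @param nonlinearity apply the exponential shape nonlinearity (default TRUE).
#' @return numeric activation series in [0, 1], same length as
#'   \code{excitation}.
#' @export
excitation_to_activation <- function(excitation, params, rate,
                                     a0 = excitation[1],
                                     nonlinearity = TRUE) {
  if (rate <= 0) stop("rate must be positive")
  u <- pmin(pmax(as.numeric(excitation), 0), 1)
  a <- .activation_ode(u, params$tau_act, params$tau_deact, 1 / rate, a0)
  if (nonlinearity) {
    A <- params$shape_A
    a <- (exp(A * a) - 1) / (exp(A) - 1)
  }
  pmin(pmax(a, 0), 1)
}

# Backward-Euler integration of da/dt = (u - a) / tau(a, u) with
# tau = tau_act * (0.5 + 1.5 a) when u > a, else tau_deact / (0.5 + 1.5 a).
# The implicit step is resolved by fixed-point iteration on a_{k+1}.
.activation_ode <- function(u, tau_act, tau_deact, dt, a0) {
  n <- length(u)
  a <- numeric(n)
  cur <- min(max(a0, 0), 1)
  a[1] <- cur
  for (k in seq_len(n - 1L)) {
    uk <- u[k + 1L]
    nxt <- cur
    for (it in 1:3) {
      tau <- if (uk > nxt) tau_act * (0.5 + 1.5 * nxt)
             else tau_deact / (0.5 + 1.5 * nxt)
      nxt <- (cur + dt * uk / tau) / (1 + dt / tau)
    }
    cur <- min(max(nxt, 0), 1)
    a[k + 1L] <- cur
  }
  a
}

# Rigid-tendon fibre state: fibre length along tendon = l_mt - l_slack,
# constant-thickness pennation keeps l_f * sin(alpha) = l_opt * sin(alpha_opt).
.fiber_state <- function(params, l_mt) {
  h <- l_mt - params$l_slack
  w <- params$l_opt * sin(params$alpha_opt)
  if (any(h <= 0) && params$alpha_opt == 0)
    stop("musculotendon length at or below tendon slack length with zero pennation: fibre length would be non-positive")
  l_f <- sqrt(h^2 + w^2)
  list(h = h, w = w, l_f = l_f, cos_a = h / l_f,
       l_tilde = l_f / params$l_opt)
}

.active_fl <- function(l_tilde, fl_width) exp(-(l_tilde - 1)^2 / fl_width)

.passive_fl <- function(l_tilde, strain_ref, shape) {
  f <- (exp(shape * (l_tilde - 1) / strain_ref) - 1) / (exp(shape) - 1)
  ifelse(l_tilde > 1, f, 0)
}

#' Tendon force of a rigid-tendon Hill muscle (isometric)
#'
#' F = f_max * (a * f_act(lt) + f_pas(lt)) * cos(alpha), with normalised
#' fibre length lt determined kinematically from the musculotendon length
#' (rigid tendon). The force-velocity multiplier is unity.
#'
#' @param params a \code{\link{muscle_params}} object.
#' @param a activation in [0, 1] (scalar or vector).
#' @param l_mt musculotendon length (m, scalar or vector).
#' @return tendon force (N), non-negative.
#' @export
tendon_force <- function(params, a, l_mt) {
  if (any(a < 0 | a > 1)) stop("activation must lie in [0, 1]")
  st <- .fiber_state(params, l_mt)
  g <- a * .active_fl(st$l_tilde, params$fl_width) +
    .passive_fl(st$l_tilde, params$passive_strain_ref, params$passive_exp_shape)
  pmax(params$f_max * g * st$cos_a, 0)
}

#' Analytic slope of tendon force with respect to musculotendon length
#'
#' Closed-form dF/dl_mt at fixed activation, chain-ruled through the rigid
#' tendon fibre kinematics and the pennation geometry. This is the muscle-level
#' stiffness term of the analytic joint-stiffness assembly.
#'
#' @inheritParams tendon_force
#' @return slope in N/m.
#' @export
tendon_force_slope <- function(params, a, l_mt) {
  if (any(a < 0 | a > 1)) stop("activation must lie in [0, 1]")
  st <- .fiber_state(params, l_mt)
  lt <- st$l_tilde
  fw <- params$fl_width
  f_act <- .active_fl(lt, fw)
  f_pas <- .passive_fl(lt, params$passive_strain_ref, params$passive_exp_shape)
  g <- a * f_act + f_pas
  # d g / d l_tilde
  dact <- f_act * (-2 * (lt - 1) / fw)
  sh <- params$passive_exp_shape / params$passive_strain_ref
  dpas <- ifelse(lt > 1,
                 sh * exp(params$passive_exp_shape * (lt - 1) /
                            params$passive_strain_ref) /
                   (exp(params$passive_exp_shape) - 1),
                 0)
  dg <- a * dact + dpas
  # d l_f / d l_mt = cos(alpha);  d l_tilde / d l_mt = cos(alpha) / l_opt
  # d cos(alpha) / d l_mt = w^2 / l_f^3
  params$f_max * (dg * st$cos_a / params$l_opt * st$cos_a +
                    g * st$w^2 / st$l_f^3)
}
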