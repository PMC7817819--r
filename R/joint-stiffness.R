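#' Net joint moment from muscle forces
#'
#' M_j = sum_i r_ij * F_i over the muscles spanning the DOF, with r the
#' analytic moment arm from the polynomial geometry and F the rigid-tendon
#' Hill force at the given activation and pose.
#'
#' @param leg a \code{\link{leg_model}}.
#' @param activations named numeric vector (muscle -> activation in [0, 1]);
#'   muscles not listed are treated as inactive.
#' @param angles named numeric vector of joint angles (radians).
#' @param dof DOF label.
#' @return joint moment (N m).
#' @export
joint_moment <- function(leg, activations, angles, dof) {
  total <- 0
  for (m in leg$muscles) {
    if (!spans_dof(m, dof)) next
    missing <- setdiff(m$geometry$dofs, names(angles))
    if (length(missing))
      stop("missing geometry angles for muscle ", m$name, ": ",
           paste(missing, collapse = ", "))
    a <- if (m$name %in% names(activations)) activations[[m$name]] else 0
    r <- moment_arm(m$geometry, angles, dof)
    l <- mtu_length(m$geometry, angles)
    total <- total + r * tendon_force(m$params, a, l)
  }
  total
}

#' Single-muscle contribution to joint stiffness
#'
#' K_mus = r^2 * dF/dl_mt - (dr/dtheta) * F, the analytic expansion of
#' K = -dM/dtheta for one muscle at fixed activation (isometric evaluation).
#'
#' @inheritParams joint_moment
#' @param muscle muscle name (must span \code{dof}).
#' @param a activation in [0, 1].
#' @return stiffness contribution (N m / rad).
#' @export
muscle_stiffness <- function(leg, muscle, a, angles, dof) {
  m <- leg$muscles[[muscle]]
  if (is.null(m)) stop("unknown muscle: ", muscle)
  if (!spans_dof(m, dof))
    stop("muscle ", muscle, " does not span ", dof)
  r <- moment_arm(m$geometry, angles, dof)
  dr <- moment_arm_gradient(m$geometry, angles, dof)
  l <- mtu_length(m$geometry, angles)
  f <- tendon_force(m$params, a, l)
  df <- tendon_force_slope(m$params, a, l)
  r^2 * df - dr * f
}

#' Joint stiffness, moment and per-muscle contributions along a gait cycle
#'
#' Assembles, at each of the 101 normalised time points of a cycle, the
#' analytic joint stiffness K_joint = sum_i K_mus,i together with the net
#' joint moment, from per-muscle activation cycles and joint-angle cycles.
#'
#' @param leg a \code{\link{leg_model}}.
#' @param activation_cycles named list (muscle -> numeric vector of
#'   activations on the percent-of-cycle grid); all series must share one
#'   length (101 on the standard grid). Missing muscles are inactive.
#' @param angle_cycles named list (DOF -> numeric vector of angles, radians)
#'   on the same grid.
#' @param dof DOF label for which stiffness is assembled.
#' @param cycle_index integer tag stored in the result.
#' @return an object of class \code{stiffness_series}: list with \code{dof},
#'   \code{cycle_index}, \code{percent}, \code{k_joint}, \code{k_mus}
#'   (matrix, point x muscle) and \code{m_joint}.
#' @export
stiffness_series <- function(leg, activation_cycles, angle_cycles, dof,
                             cycle_index = 1L) {
  lens <- c(vapply(activation_cycles, length, integer(1)),
            vapply(angle_cycles, length, integer(1)))
  if (length(unique(lens)) != 1L)
    stop("activation and angle series must all have the same length")
  n <- lens[[1]]
  ang <- do.call(cbind, angle_cycles)
  spanning <- names(leg$muscles)[vapply(leg$muscles, spans_dof, logical(1),
                                        dof = dof)]
  if (length(spanning) == 0L) stop("no muscle spans ", dof)
  k_mus <- matrix(0, nrow = n, ncol = length(spanning),
                  dimnames = list(NULL, spanning))
  m_joint <- numeric(n)
  for (nm in spanning) {
    m <- leg$muscles[[nm]]
    a <- if (nm %in% names(activation_cycles)) activation_cycles[[nm]]
         else rep(0, n)
    r <- moment_arm(m$geometry, ang, dof)
    dr <- moment_arm_gradient(m$geometry, ang, dof)
    l <- mtu_length(m$geometry, ang)
    f <- tendon_force(m$params, a, l)
    df <- tendon_force_slope(m$params, a, l)
    k_mus[, nm] <- r^2 * df - dr * f
    m_joint <- m_joint + r * f
  }
  structure(list(dof = dof, cycle_index = as.integer(cycle_index),
                 percent = seq(0, 100, length.out = n),
                 k_joint = rowSums(k_mus), k_mus = k_mus,
                 m_joint = m_joint),
            class = "stiffness_series")
}

#' Mean fractional stiffness contribution per muscle
#'
#' At each time point the fraction |K_mus,i| / sum_m |K_mus,m| is formed, then
#' averaged over the points of the cycle where total stiffness magnitude is
#' nonzero. Fractions sum to 1. Used to exclude muscles contributing less
#' than 2\% on average from the antagonist-pair catalogue.
#'
#' @param series a \code{stiffness_series}, or a list of them (cycles), in
#'   which case per-cycle fractions are averaged.
#' @return named numeric vector of fractions summing to 1.
#' @export
contribution_fractions <- function(series) {
  if (inherits(series, "stiffness_series")) series <- list(series)
  per_cycle <- lapply(series, function(s) {
    absk <- abs(s$k_mus)
    tot <- rowSums(absk)
    keep <- tot > 0
    if (!any(keep)) stop("all-zero stiffness: contribution fractions undefined")
    colMeans(absk[keep, , drop = FALSE] / tot[keep])
  })
  fr <- Reduce(`+`, per_cycle) / length(per_cycle)
  fr / sum(fr)
}

#' @export
print.stiffness_series <- function(x, ...) {
  cat(sprintf("Joint stiffness series: %s, cycle %d, %d points\n",
              x$dof, x$cycle_index, length(x$k_joint)))
  cat(sprintf("  K_joint range: %.2f to %.2f N m/rad\n",
              min(x$k_joint), max(x$k_joint)))
  invisible(x)
}
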