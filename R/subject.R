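#' Muscle entry of a leg model
#'
#' Bundles everything the pipeline needs to know about one muscle: its EMG
#' source channel, its functional role about each spanned DOF, Hill-type
#' parameters, polynomial geometry, and the calibrated EMG scale factor.
#'
#' @param name muscle label, unique within a leg.
#' @param emg_source label of the EMG channel the muscle's envelope is taken
#'   from (several muscles may share a surface channel).
#' @param roles named character vector mapping DOF labels to one of
#'   \code{"FLEX"}, \code{"EXT"}, \code{"PF"}, \code{"DF"}, \code{"none"}.
#' @param params a \code{\link{muscle_params}} object.
#' @param geometry a \code{\link{muscle_geometry}} object.
#' @param emg_scale calibrated EMG scale factor in (0, 1].
#' @param fine_wire logical; TRUE when the EMG source is an indwelling
#'   fine-wire electrode (such muscles are excluded from surface-EMG CCIs).
#' @return an object of class \code{muscle_entry}.
#' @export
muscle_entry <- function(name, emg_source, roles, params, geometry,
                         emg_scale = 1, fine_wire = FALSE) {
  stopifnot(inherits(params, "muscle_params"),
            inherits(geometry, "muscle_geometry"))
  if (emg_scale <= 0 || emg_scale > 1)
    stop("emg_scale must lie in (0, 1]")
  ok <- c("FLEX", "EXT", "PF", "DF", "none")
  if (!all(roles %in% ok))
    stop("roles must be one of ", paste(ok, collapse = ", "))
  structure(list(name = name, emg_source = emg_source,
                 roles = roles, params = params, geometry = geometry,
                 emg_scale = emg_scale, fine_wire = isTRUE(fine_wire)),
            class = "muscle_entry")
}

#' Does a muscle span a DOF?
#'
#' A muscle spans DOF j iff its geometry polynomial has a term with nonzero
#' coefficient that depends on theta_j (equivalently, its moment arm about j
#' is not identically zero).
#'
#' @param muscle a \code{\link{muscle_entry}}.
#' @param dof DOF label.
#' @export
spans_dof <- function(muscle, dof) {
  g <- muscle$geometry
  j <- match(dof, g$dofs)
  if (is.na(j)) return(FALSE)
  any(g$exponents[, j] > 0L & g$coef != 0)
}

#' Leg model
#'
#' One leg: a set of muscles, the leg's electromechanical delay (the same for
#' all muscles of the leg), and the ordered sagittal-plane DOFs. Functional
#' roles are validated against the moment-arm sign at the neutral pose:
#' FLEX/DF muscles must have r > 0 there, EXT/PF muscles r < 0 (the
#' agonist-positive convention).
#'
#' @param muscles list of \code{\link{muscle_entry}} objects.
#' @param electromechanical_delay delay in milliseconds, >= 0.
#' @param dofs ordered DOF labels.
#' @param label leg label (e.g. \code{"non-paretic"}).
#' @return an object of class \code{leg_model}.
#' @export
leg_model <- function(muscles, electromechanical_delay,
                      dofs = c("hip_flexion", "knee_flexion",
                               "ankle_dorsiflexion"),
                      label = "leg") {
  if (electromechanical_delay < 0) stop("delay must be non-negative")
  nm <- vapply(muscles, function(m) m$name, character(1))
  if (anyDuplicated(nm)) stop("muscle names must be unique within a leg")
  names(muscles) <- nm
  for (m in muscles) {
    spanned <- dofs[vapply(dofs, function(d) spans_dof(m, d), logical(1))]
    if (length(spanned) == 0L)
      stop("muscle ", m$name, " spans no listed DOF")
    neutral <- stats::setNames(rep(0, length(m$geometry$dofs)),
                               m$geometry$dofs)
    for (d in spanned) {
      role <- if (d %in% names(m$roles)) m$roles[[d]] else "none"
      if (role == "none") next
      r0 <- moment_arm(m$geometry, neutral, d)
      agonist <- role %in% c("FLEX", "DF")
      if ((agonist && r0 <= 0) || (!agonist && r0 >= 0))
        stop("muscle ", m$name, ": role ", role, " about ", d,
             " inconsistent with moment-arm sign ", signif(r0, 3),
             " at the neutral pose")
    }
  }
  structure(list(muscles = muscles,
                 electromechanical_delay = electromechanical_delay,
                 dofs = dofs, label = label),
            class = "leg_model")
}

#' Virtual subject
#'
#' A two-legged subject model (non-paretic and paretic leg) plus the nominal
#' gait-cycle period used for the variable EMG low-pass cutoff.
#'
#' @param subject_id label.
#' @param legs named list of exactly two \code{\link{leg_model}} objects
#'   (\code{"non-paretic"}, \code{"paretic"}).
#' @param cycle_period nominal gait-cycle period (s), > 0.
#' @return an object of class \code{virtual_subject}.
#' @export
virtual_subject <- function(subject_id, legs, cycle_period) {
  if (length(legs) != 2L)
    stop("a subject has exactly two legs")
  if (cycle_period <= 0) stop("cycle_period must be positive")
  if (is.null(names(legs)))
    names(legs) <- c("non-paretic", "paretic")
  structure(list(subject_id = subject_id, legs = legs,
                 cycle_period = cycle_period),
            class = "virtual_subject")
}

#' @export
print.virtual_subject <- function(x, ...) {
  cat("Virtual subject:", x$subject_id, "\n")
  for (nm in names(x$legs)) {
    leg <- x$legs[[nm]]
    cat(sprintf("  %-12s %d muscles, delay %g ms\n",
                nm, length(leg$muscles), leg$electromechanical_delay))
  }
  cat("  cycle period:", x$cycle_period, "s\n")
  invisible(x)
}

#' @export
print.leg_model <- function(x, ...) {
  cat("Leg model:", x$label, "-", length(x$muscles), "muscles, delay",
      x$electromechanical_delay, "ms\n")
  invisible(x)
}
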