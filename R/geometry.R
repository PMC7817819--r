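#' Polynomial musculotendon geometry
#'
#' A muscle's path length over the joints it spans is represented by a
#' multivariate polynomial in the joint angles. Moment arms and their
#' angle-gradients then follow analytically from the identity
#' r_j = -dL/dtheta_j, which is what makes joint stiffness computable in
#' closed form.
#'
#' @param dofs character vector of degree-of-freedom labels the polynomial
#'   depends on (e.g. \code{"knee_flexion"}).
#' @param exponents integer matrix, one row per monomial and one column per
#'   DOF in \code{dofs}; entry \code{[t, j]} is the exponent of angle j in
#'   term t.
#' @param coef numeric vector of monomial coefficients (metres at zero
#'   exponents; metres/radian^k otherwise). The constant term must be
#'   positive: a muscle has positive length at the neutral pose.
#' @param angle_box optional 2 x length(dofs) matrix of (min, max) physiologic
#'   angles (radians) over which the geometry is declared valid.
#' @return an object of class \code{muscle_geometry}.
#' @examples
#' g <- muscle_geometry("knee_flexion", matrix(0:1, ncol = 1), c(0.30, 0.05))
#' mtu_length(g, c(knee_flexion = 0))   # 0.30
#' moment_arm(g, c(knee_flexion = 0), "knee_flexion")  # -0.05
#' @export
muscle_geometry <- function(dofs, exponents, coef, angle_box = NULL) {
  exponents <- as.matrix(exponents)
  storage.mode(exponents) <- "integer"
  dimnames(exponents) <- NULL
  if (nrow(exponents) != length(coef))
    stop("one coefficient per monomial row is required")
  if (ncol(exponents) != length(dofs))
    stop("one exponent column per DOF is required")
  if (any(exponents < 0L)) stop("exponents must be non-negative")
  const <- which(rowSums(exponents) == 0L)
  if (length(const) == 0L || sum(coef[const]) <= 0)
    stop("geometry must have a positive constant term (length at neutral pose)")
  if (is.null(angle_box)) {
    angle_box <- rbind(rep(-1.0, length(dofs)), rep(1.0, length(dofs)))
  }
  angle_box <- as.matrix(angle_box)
  colnames(angle_box) <- dofs
  structure(
    list(dofs = as.character(dofs), exponents = exponents,
         coef = as.numeric(coef), max_degree = max(rowSums(exponents)),
         angle_box = angle_box),
    class = "muscle_geometry")
}

# Pull angle columns (in geometry DOF order) out of a named vector or a
# matrix/data.frame of pose(s); returns an n x n_dof matrix.
.angle_matrix <- function(geom, angles) {
  if (is.null(dim(angles))) {
    if (is.null(names(angles))) {
      if (length(angles) != length(geom$dofs))
        stop("unnamed angle vector must match geometry DOF count")
      ang <- matrix(angles, nrow = 1)
    } else {
      missing <- setdiff(geom$dofs, names(angles))
      if (length(missing))
        stop("missing angles for DOF(s): ", paste(missing, collapse = ", "))
      ang <- matrix(angles[geom$dofs], nrow = 1)
    }
  } else {
    angles <- as.matrix(angles)
    if (is.null(colnames(angles))) {
      if (ncol(angles) != length(geom$dofs))
        stop("unnamed angle matrix must match geometry DOF count")
      ang <- angles
    } else {
      missing <- setdiff(geom$dofs, colnames(angles))
      if (length(missing))
        stop("missing angles for DOF(s): ", paste(missing, collapse = ", "))
      ang <- angles[, geom$dofs, drop = FALSE]
    }
  }
  ang
}

# Evaluate sum_t coef[t] * prod_j theta_j ^ exponents[t, j] (and derivative
# variants) for n poses at once.
.poly_eval <- function(geom, ang, d1 = NULL, d2 = NULL) {
  n <- nrow(ang)
  ex <- geom$exponents
  out <- numeric(n)
  for (t in seq_along(geom$coef)) {
    term <- rep(geom$coef[t], n)
    e <- ex[t, ]
    if (!is.null(d1)) {
      k <- e[d1]
      reps <- if (identical(d1, d2)) 2L else 1L
      if (!is.null(d2) && !identical(d1, d2)) {
        if (k < 1L || e[d2] < 1L) next
      } else if (k < reps) next
    }
    for (j in seq_along(e)) {
      p <- e[j]
      if (!is.null(d1) && j == d1) {
        if (identical(d1, d2)) {
          term <- term * p * (p - 1L)
          p <- p - 2L
        } else {
          term <- term * p
          p <- p - 1L
        }
      }
      if (!is.null(d2) && !identical(d1, d2) && j == d2) {
        term <- term * p
        p <- p - 1L
      }
      if (p > 0L) term <- term * ang[, j]^p
    }
    out <- out + term
  }
  unname(out)
}

.check_box <- function(geom, ang) {
  lo <- geom$angle_box[1, ]
  hi <- geom$angle_box[2, ]
  outside <- any(sweep(ang, 2, lo, "<") | sweep(ang, 2, hi, ">"))
  if (outside)
    warning("pose outside declared physiologic angle box; extrapolating polynomial geometry")
  invisible(NULL)
}

#' Musculotendon length at a pose
#'
#' @param geom a \code{\link{muscle_geometry}} object.
#' @param angles named numeric vector of joint angles (radians), or a matrix /
#'   data.frame with one pose per row (columns named by DOF).
#' @return length(s) in metres; error if the polynomial evaluates non-positive
#'   (invalid geometry for that pose).
#' @export
mtu_length <- function(geom, angles) {
  ang <- .angle_matrix(geom, angles)
  .check_box(geom, ang)
  l <- .poly_eval(geom, ang)
  if (any(!is.finite(l)) || any(l <= 0))
    stop("non-positive musculotendon length: geometry invalid at this pose")
  l
}

#' Moment arm about a DOF
#'
#' Returns r = -dL/dtheta for the named DOF. Positive r means the muscle
#' generates positive (flexion / dorsiflexion) moment under this package's
#' sign convention.
#'
#' @inheritParams mtu_length
#' @param dof DOF label (must be one of \code{geom$dofs}).
#' @return moment arm(s) in metres.
#' @export
moment_arm <- function(geom, angles, dof) {
  j <- match(dof, geom$dofs)
  if (is.na(j)) stop("unknown DOF label: ", dof)
  ang <- .angle_matrix(geom, angles)
  -.poly_eval(geom, ang, d1 = j)
}

#' Moment-arm gradient about a DOF
#'
#' Returns dr/dtheta = -d2L/dtheta^2 for the named DOF; this is the
#' geometric term of the analytic joint-stiffness assembly.
#'
#' @inheritParams moment_arm
#' @return gradient(s) in metres/radian.
#' @export
moment_arm_gradient <- function(geom, angles, dof) {
  j <- match(dof, geom$dofs)
  if (is.na(j)) stop("unknown DOF label: ", dof)
  ang <- .angle_matrix(geom, angles)
  -.poly_eval(geom, ang, d1 = j, d2 = j)
}

#' @export
print.muscle_geometry <- function(x, ...) {
  cat("Polynomial musculotendon geometry\n")
  cat("  DOFs:", paste(x$dofs, collapse = ", "), "\n")
  cat("  terms:", length(x$coef), " max degree:", x$max_degree, "\n")
  invisible(x)
}
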