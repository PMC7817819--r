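#' Co-contraction index, Rudolph formulation (CCI1)
#'
#' CCI1(t) = (L/H) * (L + H) with L the lower and H the higher of the two
#' envelope values at time t. Measures antagonist activity relative to both
#' the agonist level and the total level; degree-1 homogeneous, so EMG
#' scaling changes it. Defined as 0 when both inputs are 0.
#'
#' @param a,b non-negative envelope values (scalars or equal-length vectors).
#' @return CCI1 values, >= 0.
#' @export
cci1_point <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("envelope values must be non-negative")
  lo <- pmin(abs(a), abs(b))
  hi <- pmax(abs(a), abs(b))
  ifelse(hi == 0, 0, lo / hi * (lo + hi))
}

#' Co-contraction index, Falconer-Winter formulation (CCI2)
#'
#' CCI2(t) = 2 L / (L + H); the fraction of total activity that is common to
#' the pair. Bounded in [0, 1] and scale-invariant, so EMG scaling leaves it
#' unchanged. Defined as 0 when both inputs are 0.
#'
#' @inheritParams cci1_point
#' @return CCI2 values in [0, 1].
#' @export
cci2_point <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("envelope values must be non-negative")
  lo <- pmin(abs(a), abs(b))
  hi <- pmax(abs(a), abs(b))
  s <- lo + hi
  ifelse(s == 0, 0, 2 * lo / s)
}

#' Antagonist pair catalogue for one DOF
#'
#' Classifies a leg's muscles into agonists (FLEX or DF role about the DOF)
#' and antagonists (EXT or PF), excluding fine-wire-recorded muscles
#' (surface-EMG-only analysis) and muscles whose mean fractional stiffness
#' contribution falls below a threshold (default 2\%).
#'
#' @param leg a \code{\link{leg_model}}.
#' @param dof DOF label.
#' @param stiffness_fractions named fractions from
#'   \code{\link{contribution_fractions}}; muscles absent from the vector are
#'   treated as not assessable and kept.
#' @param min_fraction exclusion threshold on the mean contribution.
#' @return an object of class \code{pair_catalog}: \code{dof},
#'   \code{agonists}, \code{antagonists}, \code{pairs} (2-column character
#'   matrix), \code{exclusions} (data.frame muscle/reason).
#' @export
build_pair_catalog <- function(leg, dof, stiffness_fractions = NULL,
                               min_fraction = 0.02) {
  agonists <- character(0); antagonists <- character(0)
  excl_m <- character(0); excl_r <- character(0)
  for (m in leg$muscles) {
    role <- if (dof %in% names(m$roles)) m$roles[[dof]] else "none"
    if (is.na(role) || role == "none" || !spans_dof(m, dof))
      next
    if (m$fine_wire) {
      excl_m <- c(excl_m, m$name); excl_r <- c(excl_r, "fine_wire")
      next
    }
    if (!is.null(stiffness_fractions) &&
        m$name %in% names(stiffness_fractions) &&
        stiffness_fractions[[m$name]] < min_fraction) {
      excl_m <- c(excl_m, m$name); excl_r <- c(excl_r, "below_2pct")
      next
    }
    if (role %in% c("FLEX", "DF")) agonists <- c(agonists, m$name)
    else antagonists <- c(antagonists, m$name)
  }
  if (length(agonists) == 0L || length(antagonists) == 0L)
    stop("no antagonist pairing possible about ", dof,
         " after exclusions (need at least one agonist and one antagonist)")
  pairs <- as.matrix(expand.grid(agonist = agonists,
                                 antagonist = antagonists,
                                 stringsAsFactors = FALSE))
  structure(list(dof = dof, agonists = agonists, antagonists = antagonists,
                 pairs = pairs,
                 exclusions = data.frame(muscle = excl_m, reason = excl_r,
                                         stringsAsFactors = FALSE)),
            class = "pair_catalog")
}

#' CCI time series for a muscle pair
#'
#' Applies a CCI formulation pointwise over each cycle of two envelope cycle
#' sets. The lower/higher assignment is made independently at every time
#' point (the series may swap roles within a cycle).
#'
#' @param envA,envB \code{\link{emg_cycle_set}} objects of the same variant
#'   and cycle count.
#' @param formulation \code{"CCI1"} or \code{"CCI2"}.
#' @return an object of class \code{cci_series}: \code{pair},
#'   \code{formulation}, \code{variant}, \code{cycles} (list of numeric
#'   vectors, one per gait cycle).
#' @export
cci_series <- function(envA, envB, formulation = c("CCI1", "CCI2")) {
  formulation <- match.arg(formulation)
  if (envA$variant != envB$variant)
    stop("EMG variants differ: ", envA$variant, " vs ", envB$variant)
  if (length(envA$cycles) != length(envB$cycles))
    stop("cycle counts differ between the two muscles")
  f <- if (formulation == "CCI1") cci1_point else cci2_point
  cycles <- Map(f, envA$cycles, envB$cycles)
  structure(list(pair = c(envA$muscle, envB$muscle),
                 formulation = formulation, variant = envA$variant,
                 cycles = cycles),
            class = "cci_series")
}

#' @export
print.pair_catalog <- function(x, ...) {
  cat("Antagonist pair catalogue for", x$dof, "\n")
  cat("  agonists:   ", paste(x$agonists, collapse = ", "), "\n")
  cat("  antagonists:", paste(x$antagonists, collapse = ", "), "\n")
  if (nrow(x$exclusions))
    cat("  excluded:   ",
        paste(sprintf("%s (%s)", x$exclusions$muscle, x$exclusions$reason),
              collapse = ", "), "\n")
  cat("  pairs:", nrow(x$pairs), "\n")
  invisible(x)
}
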