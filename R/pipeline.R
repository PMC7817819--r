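#' Co-contraction index vs joint stiffness analysis
#'
#' The package's top-level analysis. For each requested leg it: (1) extracts
#' the linear envelope of every EMG channel and builds the four signal
#' variants (basic, scaled, delayed, calibrated); (2) drives the rigid-tendon
#' Hill-type model with the calibrated excitations through activation
#' dynamics and assembles analytic joint stiffness at 101 points per gait
#' cycle for each sagittal DOF; (3) enumerates admissible antagonist pairs
#' (surface EMG only, mean stiffness contribution >= 2\%), computes both CCI
#' formulations for every pair, variant and cycle; and (4) correlates each
#' CCI series with joint stiffness per cycle and summarises best pairs and
#' CCI1-vs-CCI2 contrasts.
#'
#' @param subject a \code{\link{virtual_subject}} (or one read from JSON).
#' @param trial a \code{gait_trial} (from \code{\link{make_gait_trial}} or
#'   read from exported files).
#' @param legs leg names to analyse (default: all legs of the subject).
#' @param variants subset of \code{c("basic", "scaled", "delayed",
#'   "calibrated")}.
#' @param formulations subset of \code{c("CCI1", "CCI2")}.
#' @param min_fraction stiffness-contribution exclusion threshold
#'   (default 0.02).
#' @return an object of class \code{cci_stiffness}; see
#'   \code{\link{print.cci_stiffness}}, \code{\link{summary.cci_stiffness}},
#'   \code{\link{plot.cci_stiffness}}.
#' @export
cci_stiffness <- function(subject, trial, legs = names(subject$legs),
                          variants = c("basic", "scaled", "delayed",
                                       "calibrated"),
                          formulations = c("CCI1", "CCI2"),
                          min_fraction = 0.02) {
  variants <- match.arg(variants, several.ok = TRUE)
  formulations <- match.arg(formulations, several.ok = TRUE)
  hs <- trial$heel_strikes
  n_cycles <- length(hs) - 1L
  out <- list()
  for (leg_name in legs) {
    leg <- subject$legs[[leg_name]]
    if (is.null(leg)) stop("subject has no leg named ", leg_name)
    channels <- trial$legs[[leg_name]]$emg
    env_sets <- list()
    act101 <- list()
    # analysed window for the trial-max normalisation of excitations
    win <- max(1, round(hs[1] * trial$emg_rate) + 1L):
      min(length(trial$legs[[leg_name]]$emg[[1]]),
          round(hs[length(hs)] * trial$emg_rate) + 1L)
    for (m in leg$muscles) {
      raw <- channels[[m$emg_source]]
      if (is.null(raw)) raw <- channels[[m$name]]
      if (is.null(raw)) stop("no EMG channel for muscle ", m$name)
      env_sets[[m$name]] <- make_variants(
        raw, trial$emg_rate, subject$cycle_period, hs,
        scale = m$emg_scale, delay = leg$electromechanical_delay,
        muscle = m$name)
      env <- emg_envelope(raw, trial$emg_rate, subject$cycle_period)
      mx <- max(env[win])
      env_n <- if (mx > 0) env / mx else env
      exc <- pmin(delay_shift(env_n, trial$emg_rate,
                              leg$electromechanical_delay) * m$emg_scale, 1)
      a <- excitation_to_activation(exc, m$params, trial$emg_rate)
      act101[[m$name]] <- resample_cycles(a, trial$emg_rate, hs)
    }
    ang101 <- lapply(trial$joint_angles, function(x)
      resample_cycles(x, trial$kin_rate, hs))
    stiff <- list(); fractions <- list(); catalogs <- list()
    records <- list()
    for (d in leg$dofs) {
      stiff[[d]] <- lapply(seq_len(n_cycles), function(c)
        stiffness_series(leg, lapply(act101, `[[`, c),
                         lapply(ang101, `[[`, c), dof = d, cycle_index = c))
      fractions[[d]] <- contribution_fractions(stiff[[d]])
      catalogs[[d]] <- build_pair_catalog(leg, d, fractions[[d]],
                                          min_fraction = min_fraction)
      for (p in seq_len(nrow(catalogs[[d]]$pairs))) {
        ag <- catalogs[[d]]$pairs[p, 1]; an <- catalogs[[d]]$pairs[p, 2]
        for (v in variants) for (f in formulations) {
          cs <- cci_series(env_sets[[ag]][[v]], env_sets[[an]][[v]], f)
          records[[length(records) + 1L]] <-
            correlate_per_cycle(cs, stiff[[d]])
        }
      }
    }
    out[[leg_name]] <- list(records = records,
                            report = best_pair_report(records),
                            stiffness = stiff, fractions = fractions,
                            catalogs = catalogs, envelopes = env_sets)
  }
  structure(list(subject_id = subject$subject_id, legs = out,
                 n_cycles = n_cycles, variants = variants,
                 formulations = formulations, call = match.call()),
            class = "cci_stiffness")
}

#' @rdname cci_stiffness
#' @param x,object a \code{cci_stiffness} object.
#' @param ... unused.
#' @export
print.cci_stiffness <- function(x, ...) {
  cat("CCI vs joint-stiffness analysis:", x$subject_id, "\n")
  cat(sprintf("  %d cycles; variants: %s; formulations: %s\n",
              x$n_cycles, paste(x$variants, collapse = ", "),
              paste(x$formulations, collapse = ", ")))
  for (leg in names(x$legs)) {
    cat("Leg:", leg, "- best pairs per (DOF, formulation, variant):\n")
    b <- x$legs[[leg]]$report$best
    b$r_mean <- round(b$r_mean, 3); b$r_sd <- round(b$r_sd, 3)
    print(b, row.names = FALSE)
  }
  invisible(x)
}

#' @rdname cci_stiffness
#' @export
summary.cci_stiffness <- function(object, ...) {
  best <- do.call(rbind, lapply(names(object$legs), function(leg) {
    b <- object$legs[[leg]]$report$best
    cbind(leg = leg, b)
  }))
  contrast <- do.call(rbind, lapply(names(object$legs), function(leg) {
    ct <- object$legs[[leg]]$report$formulation_contrast
    if (is.null(ct)) return(NULL)
    cbind(leg = leg, ct)
  }))
  structure(list(subject_id = object$subject_id, best = best,
                 contrast = contrast, n_cycles = object$n_cycles),
            class = "summary.cci_stiffness")
}

#' @export
print.summary.cci_stiffness <- function(x, ...) {
  cat("CCI vs joint-stiffness analysis:", x$subject_id,
      sprintf("(%d cycles)\n\n", x$n_cycles))
  cat("Best antagonist pair per (leg, DOF, formulation, variant):\n")
  b <- x$best
  b$r_mean <- round(b$r_mean, 3); b$r_sd <- round(b$r_sd, 3)
  print(b, row.names = FALSE)
  if (!is.null(x$contrast)) {
    cat("\nCCI1 vs CCI2 best-pair contrast (rank-sum on per-cycle r):\n")
    ct <- x$contrast
    for (cc in c("r1_mean", "r2_mean", "diff")) ct[[cc]] <- round(ct[[cc]], 3)
    ct$p_value <- signif(ct$p_value, 3)
    print(ct, row.names = FALSE)
  }
  invisible(x)
}

#' @rdname cci_stiffness
#' @param leg leg to plot (default: first analysed leg).
#' @param dof DOF to plot (default: first DOF with records).
#' @param variant EMG variant whose best pair is overlaid.
#' @export
plot.cci_stiffness <- function(x, leg = names(x$legs)[1],
                               dof = NULL, variant = "delayed", ...) {
  lg <- x$legs[[leg]]
  if (is.null(dof)) dof <- names(lg$stiffness)[1]
  st <- lg$stiffness[[dof]]
  kmat <- vapply(st, `[[`, numeric(length(st[[1]]$k_joint)), "k_joint")
  pct <- st[[1]]$percent
  km <- rowMeans(kmat); ks <- apply(kmat, 1, stats::sd)
  b <- lg$report$best
  sel <- b$dof == dof & b$variant == variant & b$formulation == "CCI1"
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(pct, km, type = "l", lwd = 2,
                 ylim = range(km - ks, km + ks),
                 xlab = "% gait cycle", ylab = "K_joint (N m/rad)",
                 main = sprintf("%s, %s", leg, dof), ...)
  graphics::polygon(c(pct, rev(pct)), c(km - ks, rev(km + ks)),
                    col = grDevices::adjustcolor("grey", 0.4), border = NA)
  graphics::lines(pct, km, lwd = 2)
  if (any(sel)) {
    rec <- lg$report$records[[which(sel)[1]]]
    pair <- strsplit(b$pair[sel][1], "\\+")[[1]]
    env <- lg$envelopes
    cs <- cci_series(env[[pair[1]]][[variant]], env[[pair[2]]][[variant]],
                     "CCI1")
    cmat <- do.call(cbind, cs$cycles)
    cm <- rowMeans(cmat)
    sc <- max(km) / max(cm, 1e-12)
    graphics::lines(pct, cm * sc, col = "firebrick", lwd = 2, lty = 2)
    graphics::axis(4, at = pretty(range(cm * sc)),
                   labels = signif(pretty(range(cm * sc)) / sc, 2))
    graphics::mtext(sprintf("CCI1 %s (%s), mean r = %.2f", b$pair[sel][1],
                            variant, rec$r_mean), side = 4, line = 2.5,
                    col = "firebrick")
  }
  invisible(x)
}
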