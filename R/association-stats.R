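#' Pearson correlation between two cycle series
#'
#' Plain product-moment correlation. A zero-variance input makes the
#' coefficient undefined; it is reported as NA with a warning rather than 0.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return correlation coefficient in [-1, 1], or NA.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance: correlation undefined, reported as NA")
    return(NA_real_)
  }
  stats::cor(x, y)
}

.strength_class <- function(r_mean) {
  if (is.na(r_mean)) return(NA_character_)
  m <- abs(r_mean)
  if (m >= 0.7) "strong"
  else if (m >= 0.5) "moderate"
  else if (m >= 0.3) "weak"
  else "negligible"
}

#' Per-cycle correlation between a CCI series and a stiffness series
#'
#' Computes one Pearson r per gait cycle between the 101-point CCI and the
#' matching 101-point joint stiffness, then summarises with the mean, sample
#' standard deviation, and a strength class on |mean r|: negligible
#' [0, 0.3), weak [0.3, 0.5), moderate [0.5, 0.7), strong [0.7, 1] (the sign
#' is carried by the mean itself).
#'
#' @param cci a \code{cci_series} (see \code{\link{cci_series}}).
#' @param stiffness list of \code{stiffness_series}, one per cycle, in
#'   matching cycle order.
#' @return an object of class \code{correlation_record}: \code{dof},
#'   \code{pair}, \code{formulation}, \code{variant}, \code{r_per_cycle},
#'   \code{r_mean}, \code{r_sd}, \code{strength}.
#' @export
correlate_per_cycle <- function(cci, stiffness) {
  if (inherits(stiffness, "stiffness_series")) stiffness <- list(stiffness)
  if (length(cci$cycles) != length(stiffness))
    stop("cycle counts differ between CCI and stiffness")
  r <- mapply(function(cc, st) pearson_r(cc, st$k_joint),
              cci$cycles, stiffness)
  r_mean <- mean(r, na.rm = TRUE)
  r_sd <- if (sum(!is.na(r)) >= 2L) stats::sd(r, na.rm = TRUE) else NA_real_
  structure(list(dof = stiffness[[1]]$dof, pair = cci$pair,
                 formulation = cci$formulation, variant = cci$variant,
                 r_per_cycle = r, r_mean = r_mean, r_sd = r_sd,
                 strength = .strength_class(r_mean)),
            class = "correlation_record")
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact null distribution when there are no ties and the combined sample
#' size is at most 20 (the study regime: two sets of 10 per-cycle
#' correlations); normal approximation with tie correction and continuity
#' correction otherwise. Significance is assessed at alpha = 0.05.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact force exact (TRUE) / approximate (FALSE); default chooses by
#'   the rule above.
#' @return an object of class \code{rank_sum_result}: \code{statistic}
#'   (Mann-Whitney U of \code{x}), \code{p_value}, \code{significant},
#'   \code{method}.
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- !ties && (length(x) + length(y)) <= 20L
  if (exact && ties) {
    warning("ties present: falling back to the normal approximation")
    exact <- FALSE
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  p <- min(unname(wt$p.value), 1)
  structure(list(statistic = unname(wt$statistic), p_value = p,
                 significant = p < 0.05,
                 method = if (exact) "exact" else "normal approximation"),
            class = "rank_sum_result")
}

#' Best-pair report across correlation records
#'
#' For every (DOF, formulation, variant) cell, selects the record with the
#' highest mean per-cycle correlation (ties broken by the lexicographically
#' first pair name, and logged), and, per DOF and variant, compares the
#' best CCI1 record against the best CCI2 record with a rank-sum test on
#' their per-cycle correlation sets.
#'
#' @param records list of \code{correlation_record} objects.
#' @return list with \code{best} (data.frame: dof, formulation, variant,
#'   pair, r_mean, r_sd, strength) and \code{formulation_contrast}
#'   (data.frame: dof, variant, r1_mean, r2_mean, diff, p_value,
#'   significant).
#' @export
best_pair_report <- function(records) {
  key <- vapply(records, function(r)
    paste(r$dof, r$formulation, r$variant, sep = "|"), character(1))
  best_idx <- integer(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    rm <- vapply(records[idx], function(r) r$r_mean, numeric(1))
    top <- rm == max(rm)
    if (sum(top) > 1L) {
      nms <- vapply(records[idx][top], function(r)
        paste(r$pair, collapse = "+"), character(1))
      message("tie on mean r in cell ", k, "; keeping ", sort(nms)[1])
      pick <- idx[top][order(nms)][1]
    } else pick <- idx[which.max(rm)]
    best_idx <- c(best_idx, pick)
  }
  bestrec <- records[best_idx]
  best <- data.frame(
    dof = vapply(bestrec, `[[`, character(1), "dof"),
    formulation = vapply(bestrec, `[[`, character(1), "formulation"),
    variant = vapply(bestrec, `[[`, character(1), "variant"),
    pair = vapply(bestrec, function(r) paste(r$pair, collapse = "+"),
                  character(1)),
    r_mean = vapply(bestrec, `[[`, numeric(1), "r_mean"),
    r_sd = vapply(bestrec, `[[`, numeric(1), "r_sd"),
    strength = vapply(bestrec, `[[`, character(1), "strength"),
    stringsAsFactors = FALSE)
  contrast <- NULL
  for (d in unique(best$dof)) for (v in unique(best$variant)) {
    b1 <- bestrec[best$dof == d & best$variant == v &
                    best$formulation == "CCI1"]
    b2 <- bestrec[best$dof == d & best$variant == v &
                    best$formulation == "CCI2"]
    if (length(b1) != 1L || length(b2) != 1L) next
    rs <- rank_sum_test(b1[[1]]$r_per_cycle, b2[[1]]$r_per_cycle)
    contrast <- rbind(contrast, data.frame(
      dof = d, variant = v,
      r1_mean = b1[[1]]$r_mean, r2_mean = b2[[1]]$r_mean,
      diff = b1[[1]]$r_mean - b2[[1]]$r_mean,
      p_value = rs$p_value, significant = rs$significant,
      stringsAsFactors = FALSE))
  }
  list(best = best, formulation_contrast = contrast, records = bestrec)
}

#' @export
print.correlation_record <- function(x, ...) {
  cat(sprintf("%s | %s | %s | pair %s: mean r = %.3f (SD %.3f), %s\n",
              x$dof, x$formulation, x$variant,
              paste(x$pair, collapse = "+"), x$r_mean, x$r_sd, x$strength))
  invisible(x)
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): U = %g, p = %.4g%s\n",
              x$method, x$statistic, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}
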