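#' Pipeline run configuration
#'
#' @param seed integer seed driving every stochastic stage.
#' @param n_cycles analysable gait cycles (default 10).
#' @param coupling \code{"coupled"}, \code{"independent"} or a numeric
#'   strength in [0, 1].
#' @param out_dir output directory.
#' @param variants,formulations passed to \code{\link{cci_stiffness}}.
#' @param legs legs to analyse (default both).
#' @param write_cci_series also write the full per-point CCI series (large;
#'   default FALSE).
#' @param verbose print per-stage progress.
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, n_cycles = 10, coupling = "coupled",
                       out_dir = tempfile("ccistiff_run_"),
                       variants = c("basic", "scaled", "delayed",
                                    "calibrated"),
                       formulations = c("CCI1", "CCI2"),
                       legs = NULL, write_cci_series = FALSE,
                       verbose = TRUE) {
  structure(list(seed = as.integer(seed), n_cycles = n_cycles,
                 coupling = coupling, out_dir = out_dir,
                 variants = variants, formulations = formulations,
                 legs = legs, write_cci_series = write_cci_series,
                 verbose = verbose),
            class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose top-level fields match the arguments of
#'   \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, j[intersect(names(j), names(formals(run_config)))])
}

.stage_msg <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' One-command end-to-end pipeline
#'
#' simulate -> process -> stiffness -> cci -> correlate -> report, with all
#' intermediates written to \code{config$out_dir} under documented text
#' schemas, each carrying a provenance header (package version, seed, config
#' hash). Idempotent for a fixed seed.
#'
#' @param config a \code{\link{run_config}}.
#' @return invisibly, a list with the \code{\link{cci_stiffness}} object
#'   (\code{fit}), the \code{subject}, \code{trial}, \code{truth} and the
#'   output \code{paths}.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  v <- config$verbose
  hdr <- .provenance_header(config$seed,
                            unclass(config)[setdiff(names(config),
                                                    c("out_dir", "verbose"))])

  .stage_msg(v, "simulate", "virtual subject + %d-cycle trial (coupling %s, seed %d)",
             config$n_cycles, as.character(config$coupling), config$seed)
  subject <- make_subject(seed = config$seed)
  sim <- make_gait_trial(subject, n_cycles = config$n_cycles,
                         coupling = config$coupling, seed = config$seed)
  subj_path <- file.path(config$out_dir, "subject.json")
  write_subject_json(subject, subj_path)
  trial_paths <- write_gait_trial(sim$trial, config$out_dir)

  legs <- if (is.null(config$legs)) names(subject$legs) else config$legs
  .stage_msg(v, "process", "envelopes for %d leg(s), variants: %s",
             length(legs), paste(config$variants, collapse = ", "))
  fit <- tryCatch(
    cci_stiffness(subject, sim$trial, legs = legs,
                  variants = config$variants,
                  formulations = config$formulations),
    error = function(e)
      stop("pipeline stage process/stiffness/cci/correlate failed for inputs in ",
           config$out_dir, ": ", conditionMessage(e)))

  paths <- c(subject = subj_path, trial_paths)
  for (leg in legs) {
    tag <- gsub("[^a-z]", "_", leg)
    lg <- fit$legs[[leg]]

    env_rows <- list()
    for (ms in lg$envelopes) for (vn in names(ms)) {
      cy <- ms[[vn]]$cycles
      for (c in seq_along(cy))
        env_rows[[length(env_rows) + 1L]] <- data.frame(
          muscle = ms[[vn]]$muscle, variant = vn, cycle = c,
          percent = seq(0, 100, length.out = length(cy[[c]])),
          value = cy[[c]])
    }
    p_env <- file.path(config$out_dir, sprintf("envelopes_%s.csv", tag))
    .write_table_with_header(do.call(rbind, env_rows), p_env, hdr, sep = ",")

    .stage_msg(v, "stiffness", "writing %s joint stiffness", leg)
    st_rows <- list()
    for (d in names(lg$stiffness)) for (s in lg$stiffness[[d]])
      st_rows[[length(st_rows) + 1L]] <- data.frame(
        dof = d, cycle = s$cycle_index, percent = s$percent,
        k_joint = s$k_joint, m_joint = s$m_joint)
    p_st <- file.path(config$out_dir, sprintf("stiffness_%s.csv", tag))
    .write_table_with_header(do.call(rbind, st_rows), p_st, hdr, sep = ",")

    fr_rows <- do.call(rbind, lapply(names(lg$fractions), function(d)
      data.frame(dof = d, muscle = names(lg$fractions[[d]]),
                 fraction = unname(lg$fractions[[d]]))))
    p_fr <- file.path(config$out_dir, sprintf("fractions_%s.csv", tag))
    .write_table_with_header(fr_rows, p_fr, hdr, sep = ",")

    .stage_msg(v, "correlate", "%d correlation records for %s",
               length(lg$records), leg)
    cor_rows <- do.call(rbind, lapply(lg$records, function(r)
      data.frame(dof = r$dof, pair = paste(r$pair, collapse = "+"),
                 formulation = r$formulation, variant = r$variant,
                 cycle = seq_along(r$r_per_cycle), r = r$r_per_cycle)))
    p_cor <- file.path(config$out_dir, sprintf("correlations_%s.csv", tag))
    .write_table_with_header(cor_rows, p_cor, hdr, sep = ",")
    paths <- c(paths, p_env, p_st, p_fr, p_cor)

    if (isTRUE(config$write_cci_series)) {
      cci_rows <- list()
      for (d in names(lg$catalogs)) {
        cat_d <- lg$catalogs[[d]]
        for (p in seq_len(nrow(cat_d$pairs))) {
          ag <- cat_d$pairs[p, 1]; an <- cat_d$pairs[p, 2]
          for (vn in config$variants) for (f in config$formulations) {
            cs <- cci_series(lg$envelopes[[ag]][[vn]],
                             lg$envelopes[[an]][[vn]], f)
            for (c in seq_along(cs$cycles))
              cci_rows[[length(cci_rows) + 1L]] <- data.frame(
                dof = d, pair = paste(cs$pair, collapse = "+"),
                formulation = f, variant = vn, cycle = c,
                percent = seq(0, 100, length.out = length(cs$cycles[[c]])),
                value = cs$cycles[[c]])
          }
        }
      }
      p_cci <- file.path(config$out_dir, sprintf("cci_%s.csv", tag))
      .write_table_with_header(do.call(rbind, cci_rows), p_cci, hdr,
                               sep = ",")
      paths <- c(paths, p_cci)
    }
  }

  .stage_msg(v, "report", "best-pair report")
  sm <- summary(fit)
  p_best <- file.path(config$out_dir, "report_best_pairs.csv")
  .write_table_with_header(sm$best, p_best, hdr, sep = ",")
  paths <- c(paths, p_best)
  if (!is.null(sm$contrast)) {
    p_ct <- file.path(config$out_dir, "report_formulation_contrast.csv")
    .write_table_with_header(sm$contrast, p_ct, hdr, sep = ",")
    paths <- c(paths, p_ct)
  }
  invisible(list(fit = fit, subject = subject, trial = sim$trial,
                 truth = sim$truth, paths = paths))
}
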