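# FNV-1a hash of a deparsed object, for provenance headers.
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 216613626L
  for (b in utf8ToInt(s)) {
    h <- bitwXor(h, b)
    h <- as.integer((as.double(h) * 16777619) %% 2147483647)
  }
  sprintf("%08x", h)
}

.provenance_header <- function(seed = NA, extra = NULL) {
  v <- as.character(utils::packageVersion("ccistiff"))
  c(sprintf("# ccistiff %s", v),
    sprintf("# seed=%s", seed),
    if (!is.null(extra)) sprintf("# config_hash=%s", .config_hash(extra)))
}

.write_table_with_header <- function(df, path, header_lines, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read a labelled time-series table
#'
#' Accepts either a delimited table with a header row (CSV or TSV; comment
#' lines starting with \code{#} are skipped) or an OpenSim-style storage
#' text file: a free header block terminated by a line reading
#' \code{endheader}, followed by a tab- or whitespace-delimited column-label
#' row and numeric rows, with a time column. The time column must be
#' strictly increasing.
#'
#' @param path file path.
#' @return data.frame with named columns including \code{time}.
#' @export
read_storage_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- which(trimws(tolower(lines)) == "endheader")
  if (length(endh)) {
    body <- lines[(endh[1] + 1L):length(lines)]
    body <- body[nzchar(trimws(body))]
    labels <- strsplit(trimws(body[1]), "[\t ]+")[[1]]
    df <- utils::read.table(text = paste(body[-1], collapse = "\n"),
                            col.names = labels, check.names = FALSE)
  } else {
    body <- lines[!startsWith(trimws(lines), "#")]
    body <- body[nzchar(trimws(body))]
    first <- body[1]
    sep <- if (grepl(",", first)) "," else "\t"
    df <- tryCatch(
      utils::read.table(text = paste(body, collapse = "\n"), header = TRUE,
                        sep = sep, check.names = FALSE),
      error = function(e) stop("unknown table dialect in ", path, ": ",
                               conditionMessage(e)))
  }
  tc <- grep("^time$", names(df), ignore.case = TRUE)
  if (length(tc) != 1L) stop("no unique time column in ", path)
  names(df)[tc] <- "time"
  if (any(diff(df$time) <= 0)) {
    bad <- which(diff(df$time) <= 0)[1] + 1L
    stop("non-monotonic time at data row ", bad, " of ", path)
  }
  df
}

#' Write a gait trial to delimited text files
#'
#' Writes one kinematics file (time + one column per DOF, radians), one EMG
#' file per leg (time + one column per muscle), and a JSON events file
#' (heel-strike times). All delimited files carry a provenance header.
#'
#' @param trial a \code{gait_trial} from \code{\link{make_gait_trial}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_gait_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .provenance_header(trial$seed, trial[c("emg_rate", "coupling")])
  t_kin <- (seq_along(trial$joint_angles[[1]]) - 1) / trial$kin_rate
  kin <- data.frame(time = t_kin, trial$joint_angles, check.names = FALSE)
  kin_path <- file.path(dir, "kinematics.tsv")
  .write_table_with_header(kin, kin_path, hdr)
  paths <- kin_path
  for (leg in names(trial$legs)) {
    emg <- trial$legs[[leg]]$emg
    t_emg <- (seq_along(emg[[1]]) - 1) / trial$emg_rate
    df <- data.frame(time = t_emg, emg, check.names = FALSE)
    p <- file.path(dir, paste0("emg_", gsub("[^a-z]", "_", leg), ".tsv"))
    .write_table_with_header(df, p, hdr)
    paths <- c(paths, p)
  }
  ev_path <- file.path(dir, "events.json")
  jsonlite::write_json(list(heel_strikes = trial$heel_strikes,
                            emg_rate = trial$emg_rate,
                            kin_rate = trial$kin_rate,
                            seed = trial$seed),
                       ev_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, ev_path))
}

#' Serialize a virtual subject to JSON
#'
#' Writes the full subject model (per-leg delays, per-muscle Hill
#' parameters, polynomial geometry as exponent rows + coefficients, roles,
#' scale factors, fine-wire flags) to a documented JSON schema readable by
#' \code{\link{read_subject_json}}.
#'
#' @param subject a \code{\link{virtual_subject}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_subject_json <- function(subject, path) {
  legs <- lapply(subject$legs, function(leg) {
    list(
      electromechanical_delay_ms = leg$electromechanical_delay,
      dofs = leg$dofs, label = leg$label,
      muscles = lapply(unname(leg$muscles), function(m) list(
        name = m$name, emg_source = m$emg_source,
        roles = as.list(m$roles), emg_scale = m$emg_scale,
        fine_wire = m$fine_wire,
        params = unclass(m$params),
        geometry = list(dofs = m$geometry$dofs,
                        exponents = unname(apply(m$geometry$exponents, 1,
                                                 as.list, simplify = FALSE)),
                        coef = m$geometry$coef,
                        angle_box = unname(apply(m$geometry$angle_box, 2,
                                                 as.list, simplify = FALSE))))))
  })
  jsonlite::write_json(
    list(subject_id = subject$subject_id,
         cycle_period = subject$cycle_period, legs = legs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a virtual subject from JSON
#'
#' @param path a file written by \code{\link{write_subject_json}}.
#' @return a \code{\link{virtual_subject}}.
#' @export
read_subject_json <- function(path) {
  j <- jsonlite::read_json(path)
  legs <- lapply(j$legs, function(leg) {
    muscles <- lapply(leg$muscles, function(m) {
      pj <- m$params
      pr <- muscle_params(pj$f_max, pj$l_opt, pj$l_slack, pj$alpha_opt,
                          pj$tau_act, pj$tau_deact, pj$shape_A, pj$fl_width,
                          pj$passive_strain_ref, pj$passive_exp_shape)
      gj <- m$geometry
      exps <- do.call(rbind, lapply(gj$exponents, function(r)
        vapply(r, as.integer, integer(1))))
      box <- do.call(cbind, lapply(gj$angle_box, function(r)
        vapply(r, as.numeric, numeric(1))))
      geom <- muscle_geometry(unlist(gj$dofs), exps,
                              vapply(gj$coef, as.numeric, numeric(1)), box)
      muscle_entry(m$name, m$emg_source,
                   unlist(m$roles), pr, geom,
                   emg_scale = m$emg_scale, fine_wire = m$fine_wire)
    })
    leg_model(muscles, leg$electromechanical_delay_ms,
              dofs = unlist(leg$dofs), label = leg$label)
  })
  names(legs) <- names(j$legs)
  virtual_subject(j$subject_id, legs, j$cycle_period)
}

#' Read a gait trial from exported files
#'
#' Reconstructs a \code{gait_trial} from the kinematics, per-leg EMG and
#' events files written by \code{\link{write_gait_trial}} (or equivalently
#' formatted exported laboratory data). Joint velocities, if absent, are
#' obtained by central differences of the angle columns.
#'
#' @param dir directory holding \code{kinematics.tsv}, \code{emg_*.tsv} and
#'   \code{events.json}.
#' @return a \code{gait_trial}.
#' @export
read_gait_trial <- function(dir) {
  ev <- jsonlite::read_json(file.path(dir, "events.json"),
                            simplifyVector = TRUE)
  kin <- read_storage_table(file.path(dir, "kinematics.tsv"))
  dofs <- setdiff(names(kin), "time")
  kin_rate <- ev$kin_rate
  angles <- lapply(kin[dofs], as.numeric)
  velocities <- lapply(angles, function(a) {
    n <- length(a)
    v <- numeric(n)
    v[2:(n - 1)] <- (a[3:n] - a[1:(n - 2)]) * kin_rate / 2
    v[1] <- (a[2] - a[1]) * kin_rate
    v[n] <- (a[n] - a[n - 1]) * kin_rate
    v
  })
  legs <- list()
  for (f in list.files(dir, pattern = "^emg_.*\\.tsv$", full.names = TRUE)) {
    leg <- sub("^emg_", "", sub("\\.tsv$", "", basename(f)))
    leg <- gsub("_", "-", leg)
    emg <- read_storage_table(f)
    legs[[leg]] <- list(emg = lapply(emg[setdiff(names(emg), "time")],
                                     as.numeric))
  }
  structure(list(emg_rate = ev$emg_rate, kin_rate = kin_rate,
                 heel_strikes = as.numeric(ev$heel_strikes),
                 joint_angles = angles, joint_velocities = velocities,
                 legs = legs, seed = ev$seed, coupling = NA_real_),
            class = "gait_trial")
}
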