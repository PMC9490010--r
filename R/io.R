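# Trial bundles on disk: one table per channel group (excitations, angles,
# velocities, moments) plus a YAML manifest with metadata. Tables are either
# CSV (header row, first column "time") or OpenSim STO/MOT text tables.

.bundle_tables <- c(excitations = "excitations",
                    joint_angles = "joint_angles",
                    joint_velocities = "joint_velocities",
                    id_moments = "id_moments")

#' Read an OpenSim STO/MOT text table
#'
#' Parses the plain-text table format used by OpenSim: a free-form header
#' terminated by a line `endheader`, then a tab/space-separated column-name
#' row (first column `time`) and the numeric data.
#'
#' @param path file path.
#' @return data.frame with a `time` column first.
#' @export
read_sto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  end <- which(trimws(lines) == "endheader")
  if (length(end) == 0) stop("not an STO/MOT file (no 'endheader'): ", path)
  end <- end[1]
  header <- strsplit(trimws(lines[end + 1]), "[\t ]+")[[1]]
  body <- lines[(end + 2):length(lines)]
  body <- body[nzchar(trimws(body))]
  dat <- utils::read.table(text = body, col.names = header,
                           colClasses = "numeric", check.names = FALSE)
  names(dat) <- header
  dat
}

#' Write an OpenSim STO/MOT text table
#'
#' @param x data.frame whose first column is `time`.
#' @param path output file path.
#' @param name dataset name recorded in the header.
#' @export
write_sto <- function(x, path, name = "data") {
  x <- as.data.frame(x)
  if (names(x)[1] != "time") stop("first column must be 'time'")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(name,
               "version=1",
               paste0("nRows=", nrow(x)),
               paste0("nColumns=", ncol(x)),
               "inDegrees=no",
               "endheader",
               paste(names(x), collapse = "\t")), con)
  body <- apply(x, 1L, function(row)
    paste(formatC(row, format = "g", digits = 17), collapse = "\t"))
  writeLines(body, con)
  invisible(NULL)
}

.read_channel_table <- function(path, dialect) {
  dat <- switch(dialect,
                csv = utils::read.csv(path, check.names = FALSE),
                sto_mot = read_sto(path),
                stop("unknown dialect: ", dialect))
  if (names(dat)[1] != "time")
    stop("first column of ", path, " must be 'time'")
  if (any(diff(dat$time) <= 0))
    stop("non-monotone time column in ", path)
  dat
}

.write_channel_table <- function(time, mat, path, dialect, name) {
  dat <- data.frame(time = time, check.names = FALSE)
  dat[colnames(mat)] <- mat
  switch(dialect,
         csv = utils::write.csv(format(dat, digits = 17, trim = TRUE,
                                       scientific = 10),
                                path, row.names = FALSE, quote = FALSE),
         sto_mot = write_sto(dat, path, name = name),
         stop("unknown dialect: ", dialect))
  invisible(NULL)
}

#' Write a gait trial as a bundle of time-series tables plus a manifest
#'
#' Creates `<path>/<table>.<ext>` for excitations, joint angles, joint
#' velocities and ID moments, and `<path>/trial.yaml` with the metadata
#' (ids, leg, speed, cycle duration, units).
#'
#' @param trial a [gait_trial()].
#' @param path directory to create/write into.
#' @param dialect `"csv"` or `"sto_mot"`.
#' @export
write_trial_bundle <- function(trial, path, dialect = c("csv", "sto_mot")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(trial, "gait_trial"))
  if (ncol(trial$excitations) == 0) stop("trial has an empty muscle list")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create bundle directory: ", path)
  ext <- if (dialect == "csv") "csv" else "sto"
  for (tab in names(.bundle_tables)) {
    .write_channel_table(trial$time, trial[[tab]],
                         file.path(path, paste0(tab, ".", ext)),
                         dialect, name = tab)
  }
  meta <- list(trial_id = trial$trial_id,
               speed_label = trial$speed_label,
               leg = trial$leg,
               cycle_duration = trial$cycle_duration,
               n_pre = trial$n_pre,
               n_cycle = trial$n_cycle,
               dialect = dialect,
               units = list(time = "s", excitations = "unitless",
                            joint_angles = "rad", joint_velocities = "rad/s",
                            id_moments = "N*m"))
  yaml::write_yaml(meta, file.path(path, "trial.yaml"))
  invisible(NULL)
}

#' Read a gait trial bundle written by [write_trial_bundle()]
#'
#' @param path bundle directory.
#' @param dialect `"csv"` or `"sto_mot"`; defaults to the dialect recorded in
#'   the manifest.
#' @return a [gait_trial()].
#' @export
read_trial_bundle <- function(path, dialect = NULL) {
  meta_path <- file.path(path, "trial.yaml")
  if (!file.exists(meta_path)) stop("missing trial manifest: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  if (is.null(dialect)) dialect <- meta$dialect
  dialect <- match.arg(dialect, c("csv", "sto_mot"))
  ext <- if (dialect == "csv") "csv" else "sto"
  tabs <- list()
  for (tab in names(.bundle_tables)) {
    f <- file.path(path, paste0(tab, ".", ext))
    if (!file.exists(f))
      stop("missing ", gsub("_", " ", tab), " table: ", f)
    tabs[[tab]] <- .read_channel_table(f, dialect)
  }
  time <- tabs$excitations$time
  for (tab in names(tabs)) {
    if (nrow(tabs[[tab]]) != length(time))
      stop("frame count of ", tab, " differs from excitations")
  }
  as_mat <- function(d) {
    m <- as.matrix(d[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    m
  }
  gait_trial(trial_id = meta$trial_id, speed_label = meta$speed_label,
             leg = meta$leg, time = time,
             excitations = as_mat(tabs$excitations),
             joint_angles = as_mat(tabs$joint_angles),
             joint_velocities = as_mat(tabs$joint_velocities),
             id_moments = as_mat(tabs$id_moments),
             cycle_duration = meta$cycle_duration,
             n_pre = meta$n_pre, n_cycle = meta$n_cycle)
}

#' Write a whole dataset as a directory of trial bundles plus a manifest
#'
#' @param dataset a [gait_dataset()].
#' @param path output directory.
#' @param dialect `"csv"` or `"sto_mot"`.
#' @export
write_dataset <- function(dataset, path, dialect = c("csv", "sto_mot")) {
  dialect <- match.arg(dialect)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (tr in dataset$trials)
    write_trial_bundle(tr, file.path(path, tr$trial_id), dialect)
  manifest <- list(
    trials = unname(vapply(dataset$trials, function(tr) tr$trial_id,
                           character(1))),
    unmeasured_muscles = as.list(dataset$unmeasured_muscles),
    dialect = dialect)
  yaml::write_yaml(manifest, file.path(path, "dataset.yaml"))
  invisible(NULL)
}

#' Read a dataset directory written by [write_dataset()]
#' @param path dataset directory containing `dataset.yaml`.
#' @return a [gait_dataset()].
#' @export
read_dataset <- function(path) {
  manifest <- yaml::read_yaml(file.path(path, "dataset.yaml"))
  trials <- lapply(manifest$trials, function(id)
    read_trial_bundle(file.path(path, id), manifest$dialect))
  gait_dataset(trials, unlist(manifest$unmeasured_muscles) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
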