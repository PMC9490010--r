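#' Gait trial container
#'
#' A `gait_trial` holds one gait cycle's aligned time series on the
#' normalised 121-frame grid: 20 pre-frames (retained so that an
#' electromechanical delay of up to ~100 ms can be applied causally)
#' followed by 101 frames spanning heel-strike (0% cycle) to the next
#' ipsilateral heel-strike (100% cycle).
#'
#' @param trial_id character scalar identifying the trial.
#' @param speed_label character scalar, e.g. `"self-selected"` or `"fastest"`.
#' @param leg character scalar, e.g. `"left"` or `"right"`.
#' @param time numeric vector of frame times in seconds, strictly increasing,
#'   length `n_pre + n_cycle`.
#' @param excitations numeric matrix, frames x muscles, processed muscle
#'   excitations in `[0, 1]`; column names are the muscle names.
#' @param joint_angles numeric matrix, frames x DOFs, radians; column names
#'   are the DOF names.
#' @param joint_velocities numeric matrix, frames x DOFs, rad/s.
#' @param id_moments numeric matrix, frames x DOFs, inverse-dynamics net
#'   joint moments in N·m (the calibration target).
#' @param cycle_duration gait-cycle period `tf` in seconds (heel-strike to
#'   heel-strike).
#' @param n_pre number of pre-frames before heel-strike (default 20).
#' @param n_cycle number of frames covering 0--100% of the cycle (default 101).
#'
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(trial_id, speed_label, leg, time, excitations,
                       joint_angles, joint_velocities, id_moments,
                       cycle_duration, n_pre = 20L, n_cycle = 101L) {
  n_frames <- n_pre + n_cycle
  time <- as.numeric(time)
  if (length(time) != n_frames)
    stop("time must have ", n_frames, " frames (", n_pre, " pre-frames + ",
         n_cycle, " cycle frames), got ", length(time))
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing")
  excitations <- as.matrix(excitations)
  joint_angles <- as.matrix(joint_angles)
  joint_velocities <- as.matrix(joint_velocities)
  id_moments <- as.matrix(id_moments)
  for (nm in c("excitations", "joint_angles", "joint_velocities", "id_moments")) {
    m <- get(nm)
    if (nrow(m) != n_frames)
      stop("channel '", nm, "' has ", nrow(m), " frames; expected ", n_frames)
  }
  if (is.null(colnames(excitations)))
    stop("excitations must have muscle names as column names")
  if (anyDuplicated(colnames(excitations)))
    stop("muscle names must be unique")
  if (is.null(colnames(joint_angles)))
    stop("joint_angles must have DOF names as column names")
  if (anyDuplicated(colnames(joint_angles)))
    stop("DOF names must be unique")
  if (!identical(colnames(joint_angles), colnames(joint_velocities)) ||
      !identical(colnames(joint_angles), colnames(id_moments)))
    stop("joint_angles, joint_velocities and id_moments must share DOF names")
  if (!is.numeric(cycle_duration) || cycle_duration <= 0)
    stop("cycle_duration must be a positive number of seconds")
  structure(
    list(trial_id = as.character(trial_id),
         speed_label = as.character(speed_label),
         leg = as.character(leg),
         time = time,
         excitations = excitations,
         joint_angles = joint_angles,
         joint_velocities = joint_velocities,
         id_moments = id_moments,
         cycle_duration = as.numeric(cycle_duration),
         n_pre = as.integer(n_pre),
         n_cycle = as.integer(n_cycle)),
    class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat("<gait_trial> ", x$trial_id, " (", x$speed_label, ", ", x$leg, " leg)\n",
      sep = "")
  cat("  frames: ", length(x$time), " (", x$n_pre, " pre + ", x$n_cycle,
      " cycle), tf = ", signif(x$cycle_duration, 4), " s\n", sep = "")
  cat("  muscles:", ncol(x$excitations), " DOFs:", ncol(x$joint_angles), "\n")
  invisible(x)
}

#' Muscle and DOF names of a trial or dataset
#' @param x a `gait_trial` or `gait_dataset`.
#' @return character vector of names.
#' @export
muscle_names <- function(x) UseMethod("muscle_names")
#' @export
muscle_names.gait_trial <- function(x) colnames(x$excitations)
#' @export
muscle_names.gait_dataset <- function(x) muscle_names(x$trials[[1]])

#' @rdname muscle_names
#' @export
dof_names <- function(x) UseMethod("dof_names")
#' @export
dof_names.gait_trial <- function(x) colnames(x$joint_angles)
#' @export
dof_names.gait_dataset <- function(x) dof_names(x$trials[[1]])

#' Percent gait cycle of each frame
#'
#' Frame `n_pre + 1` (1-based) is heel-strike at 0%; the last frame is 100%.
#' Pre-frames carry negative percent.
#'
#' @param trial a `gait_trial`.
#' @return numeric vector of length `n_pre + n_cycle`.
#' @export
percent_cycle <- function(trial) {
  (seq_len(trial$n_pre + trial$n_cycle) - trial$n_pre - 1) /
    (trial$n_cycle - 1) * 100
}

#' Indices of the cycle frames (0--100%) within the 121-frame grid
#' @param trial a `gait_trial`.
#' @return integer vector of length `n_cycle`.
#' @export
cycle_frames <- function(trial) {
  trial$n_pre + seq_len(trial$n_cycle)
}

#' Gait dataset: a set of trials with a measured/unmeasured muscle split
#'
#' @param trials list of [gait_trial()] objects sharing muscle and DOF
#'   ordering.
#' @param unmeasured_muscles character vector of muscle names treated as
#'   unmeasured (their excitations, if present, are ground truth for scoring
#'   only and are never shown to the calibration); may be empty.
#' @return An object of class `gait_dataset`.
#' @export
gait_dataset <- function(trials, unmeasured_muscles = character()) {
  if (length(trials) == 0) stop("at least one trial is required")
  if (!all(vapply(trials, inherits, logical(1), "gait_trial")))
    stop("all elements of trials must be gait_trial objects")
  mus <- muscle_names(trials[[1]])
  dofs <- dof_names(trials[[1]])
  for (tr in trials) {
    if (!identical(muscle_names(tr), mus))
      stop("all trials must share the same muscle ordering")
    if (!identical(dof_names(tr), dofs))
      stop("all trials must share the same DOF ordering")
  }
  unmeasured_muscles <- as.character(unmeasured_muscles)
  if (!all(unmeasured_muscles %in% mus))
    stop("unknown unmeasured muscle(s): ",
         paste(setdiff(unmeasured_muscles, mus), collapse = ", "))
  ids <- vapply(trials, function(tr) tr$trial_id, character(1))
  if (anyDuplicated(ids)) stop("trial ids must be unique")
  names(trials) <- ids
  structure(
    list(trials = trials,
         measured_muscles = setdiff(mus, unmeasured_muscles),
         unmeasured_muscles = unmeasured_muscles),
    class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat("<gait_dataset> ", length(x$trials), " trials, speeds: ",
      paste(dataset_speeds(x), collapse = ", "), "\n", sep = "")
  cat("  measured muscles: ", length(x$measured_muscles),
      "; unmeasured: ", length(x$unmeasured_muscles),
      if (length(x$unmeasured_muscles))
        paste0(" (", paste(x$unmeasured_muscles, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Distinct speed labels of a dataset (in order of first appearance)
#' @param dataset a `gait_dataset`.
#' @return character vector.
#' @export
dataset_speeds <- function(dataset) {
  unique(vapply(dataset$trials, function(tr) tr$speed_label, character(1)))
}

#' Extract the measured-muscle excitation matrix of one trial
#' @param dataset a `gait_dataset`.
#' @param trial_id a trial id present in the dataset.
#' @return frames x measured-muscles matrix.
#' @export
measured_excitations <- function(dataset, trial_id) {
  tr <- dataset$trials[[trial_id]]
  if (is.null(tr)) stop("unknown trial id: ", trial_id)
  tr$excitations[, dataset$measured_muscles, drop = FALSE]
}
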