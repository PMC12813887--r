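#' Construct a trajectory object
#'
#' A trajectory is an ordered set of frames sharing a single topology: every
#' frame has the same atoms in the same order, only coordinates change.
#' Coordinates are stored as a `n_atoms x 3 x n_frames` array in Angstrom.
#'
#' @param atoms data.frame topology with columns `serial` (integer),
#'   `name` (atom name, e.g. `"CA"`), `elem` (element symbol),
#'   `resname` (3-letter residue code), `resid` (author residue number,
#'   1-based), `chain` (single character), `het` (logical, TRUE for
#'   HETATM records such as membrane pseudo-atoms).
#' @param xyz numeric array `c(n_atoms, 3, n_frames)` (a single `n x 3`
#'   matrix is promoted to one frame), Angstrom.
#' @param time_per_frame optional time spacing between frames, ns.
#' @return object of class `"Trajectory"`.
#' @export
new_trajectory <- function(atoms, xyz, time_per_frame = NULL) {
  req <- c("serial", "name", "elem", "resname", "resid", "chain", "het")
  if (!is.data.frame(atoms) || !all(req %in% names(atoms)))
    stop_data("trajectory topology must be a data.frame with columns %s",
              paste(req, collapse = ", "))
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), 3L, 1L))
  if (length(dim(xyz)) != 3L || dim(xyz)[2] != 3L)
    stop_data("xyz must be an n_atoms x 3 x n_frames array")
  if (dim(xyz)[1] != nrow(atoms))
    stop_data("xyz has %d atoms but topology has %d", dim(xyz)[1], nrow(atoms))
  if (dim(xyz)[3] < 1L) stop_data("a trajectory needs at least one frame")
  if (!all(is.finite(xyz))) stop_data("non-finite coordinates in trajectory")
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key))
    stop_data("duplicate (chain, resid, name) in topology: %s",
              key[anyDuplicated(key)])
  atoms$resid <- as.integer(atoms$resid)
  atoms$serial <- as.integer(atoms$serial)
  structure(list(atoms = atoms, xyz = xyz, time_per_frame = time_per_frame),
            class = "Trajectory")
}

#' Number of frames in a trajectory
#' @param traj a [new_trajectory()] object.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Number of atoms in a trajectory topology
#' @param traj a [new_trajectory()] object.
#' @return integer atom count.
#' @export
n_atoms <- function(traj) dim(traj$xyz)[1]

#' Coordinates of one frame
#' @param traj a [new_trajectory()] object.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` matrix, Angstrom.
#' @export
frame_xyz <- function(traj, i) {
  if (i < 1L || i > n_frames(traj))
    stop_data("frame index %d out of range (1..%d)", i, n_frames(traj))
  m <- traj$xyz[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Extract a single frame (topology + coordinates)
#' @inheritParams frame_xyz
#' @return object of class `"Frame"`: list with `atoms` and `xyz`.
#' @export
get_frame <- function(traj, i) {
  structure(list(atoms = traj$atoms, xyz = frame_xyz(traj, i), index = i),
            class = "Frame")
}

#' Keep a subset of frames
#' @param traj a [new_trajectory()] object.
#' @param idx frame indices to keep (1-based).
#' @return a new `Trajectory`.
#' @export
subset_frames <- function(traj, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > n_frames(traj))) stop_data("frame index out of range")
  new_trajectory(traj$atoms, traj$xyz[, , idx, drop = FALSE], traj$time_per_frame)
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %d atoms (%d HETATM), %d chains\n",
              n_frames(x), n_atoms(x), sum(x$atoms$het),
              length(unique(x$atoms$chain))))
  invisible(x)
}

#' @export
print.Frame <- function(x, ...) {
  cat(sprintf("Frame %d: %d atoms\n", x$index, nrow(x$atoms)))
  invisible(x)
}

# Per-frame scalar measurement series; the common output of geometry stages.
new_metric_series <- function(name, values, units = "Å",
                              fit = "", measure = "") {
  if (any(!is.finite(values)))
    stop_numeric("non-finite value in metric series '%s'", name)
  structure(list(name = name, values = as.numeric(values), units = units,
                 fit = fit, measure = measure),
            class = "MetricSeries")
}

#' @export
print.MetricSeries <- function(x, ...) {
  cat(sprintf("MetricSeries '%s' [%s]: %d frames, mean %.3f, sd %.3f (fit: %s, measure: %s)\n",
              x$name, x$units, length(x$values), mean(x$values),
              stats::sd(x$values), x$fit, x$measure))
  invisible(x)
}

#' @export
as.data.frame.MetricSeries <- function(x, ...) {
  data.frame(frame = seq_along(x$values) - 1L, value = x$values)
}
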