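#' Frame-by-frame domain-center point cloud
#'
#' After superposing every frame onto the reference over `fit_sel`
#' (the TM domain by convention, so z is the membrane normal and x, y the
#' membrane plane), returns the domain's C-alpha centroid per frame. The
#' spatial spread of this cloud is the quantity the apo/holo comparison is
#' about: wide extracellular AB sampling with narrow intracellular SI
#' sampling in the apo state, and the reverse after antigen binding.
#'
#' @inheritParams center_distance_series
#' @param domain domain name.
#' @return object of class `"PointCloud"`: `n_frames x 3` matrix (Angstrom)
#'   with attribute `domain`.
#' @export
center_cloud <- function(traj, map, domain, fit_sel, reference = NULL) {
  ia <- ca_indices(traj, select_atoms(traj, map, domain))
  aligned <- align_frames(traj, fit_sel$indices, reference)
  pts <- t(vapply(seq_len(n_frames(traj)), function(m)
    colMeans(aligned[ia, , m, drop = FALSE], dims = 1)[, 1], numeric(3)))
  structure(pts, domain = domain, class = c("PointCloud", "matrix", "array"))
}

#' Spread statistics of a domain-center point cloud
#'
#' Eigen-decomposition of the 3x3 covariance of the points, plus simple
#' axis-aligned spreads in the membrane frame: `planar_spread` =
#' `sqrt(var(x) + var(y))` (the membrane plane), `normal_spread` = sd of z
#' (the membrane normal), and the convex-hull volume of the cloud.
#' The covariance trace equals the sum of squared principal extents.
#'
#' @param cloud a [center_cloud()] matrix (or any `n x 3` matrix, n >= 2).
#' @return object of class `"SamplingSummary"`: list with `centroid`,
#'   `covariance_trace` (Angstrom^2), `principal_extents` (3 decreasing
#'   eigenvalue square roots, Angstrom), `planar_spread`, `normal_spread`
#'   (Angstrom), `hull_volume` (Angstrom^3, 0 if fewer than 4 non-coplanar
#'   points), `n_points`.
#' @export
sampling_summary <- function(cloud) {
  pts <- as.matrix(cloud)
  if (nrow(pts) < 2L) stop_data("sampling summary needs at least 2 points")
  cv <- stats::cov(pts)
  ev <- eigen(cv, symmetric = TRUE)$values
  ev <- sort(pmax(ev, 0), decreasing = TRUE)
  structure(list(centroid = colMeans(pts),
                 covariance_trace = sum(ev),
                 principal_extents = sqrt(ev),
                 planar_spread = sqrt(cv[1, 1] + cv[2, 2]),
                 normal_spread = sqrt(cv[3, 3]),
                 hull_volume = convex_hull_volume(pts),
                 n_points = nrow(pts)),
            class = "SamplingSummary")
}

#' @export
print.SamplingSummary <- function(x, ...) {
  cat(sprintf(paste0("SamplingSummary (%d points): trace %.2f Å², planar %.2f Å,",
                     " normal %.2f Å, hull %.1f Å³\n"),
              x$n_points, x$covariance_trace, x$planar_spread,
              x$normal_spread, x$hull_volume))
  invisible(x)
}

#' Binding-induced domain-dynamics-switch score
#'
#' A single dimensionless statistic of the switch signature: antigen
#' binding shrinking the extracellular AB sampling volume while growing the
#' intracellular SI one. Defined as
#' `ln(trace_AB_apo / trace_AB_holo) + ln(trace_SI_holo / trace_SI_apo)`
#' over covariance traces of the domain-center clouds, so a positive value
#' means the switch signature is present (net AB shrinkage and/or SI
#' growth) and swapping the apo/holo labels flips the sign exactly.
#'
#' @param ab_apo,ab_holo,si_apo,si_holo [sampling_summary()] objects for
#'   the AB and SI domain-center clouds in the two states.
#' @return dimensionless score.
#' @export
bidds_switch_score <- function(ab_apo, ab_holo, si_apo, si_holo) {
  tr <- vapply(list(ab_apo, ab_holo, si_apo, si_holo),
               function(s) s$covariance_trace, numeric(1))
  if (any(tr <= 0))
    stop_numeric("switch score undefined: zero covariance trace in an input cloud")
  # difference-of-logs form: swapping the apo/holo labels negates the
  # score exactly, bit for bit
  (log(tr[1]) - log(tr[2])) + (log(tr[4]) - log(tr[3]))
}

#' Per-frame membrane contact counts for a residue group
#'
#' Counts, per frame, the (group heavy atom, membrane heavy atom) pairs
#' within the cutoff distance. Hydrogens must already be excluded from the
#' selections (the default in [select_atoms()]).
#'
#' @param traj a [new_trajectory()] object.
#' @param group_sel [select_atoms()] selection for the residue group
#'   (e.g. a polybasic region or the ITAM tyrosines).
#' @param membrane_sel membrane atom selection.
#' @param cutoff contact distance cutoff, Angstrom (default 2.5).
#' @return object of class `"ContactSeries"`: list with `group`, `counts`
#'   (integer per frame), `cutoff`.
#' @export
contact_count_series <- function(traj, group_sel, membrane_sel, cutoff = 2.5) {
  gi <- group_sel$indices; mi <- membrane_sel$indices
  if (!length(gi) || !length(mi)) stop_data("empty selection for contact counting")
  if (cutoff <= 0) stop_config("contact cutoff must be > 0")
  cut2 <- cutoff^2
  counts <- vapply(seq_len(n_frames(traj)), function(m) {
    a <- traj$xyz[gi, , m, drop = FALSE]; dim(a) <- dim(a)[1:2]
    b <- traj$xyz[mi, , m, drop = FALSE]; dim(b) <- dim(b)[1:2]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    sum(d2 <= cut2)
  }, numeric(1))
  structure(list(group = group_sel$label, counts = as.integer(counts),
                 cutoff = cutoff),
            class = "ContactSeries")
}

#' @export
print.ContactSeries <- function(x, ...) {
  cat(sprintf("ContactSeries '%s' (cutoff %.1f Å): %d frames, mean %.1f contacts\n",
              x$group, x$cutoff, length(x$counts), mean(x$counts)))
  invisible(x)
}

#' Per-frame membrane burial depth of selected atoms
#'
#' With the membrane slab centered at z = 0 in the TM-aligned frame, the
#' burial depth of a frame is the maximum over selected atoms of
#' `slab_halfwidth - |z|`: positive when some atom is inside the slab. A
#' positive series mean flags burial -- the test of the safety-on/off
#' picture in which ITAM tyrosines would sit inside the bilayer core.
#'
#' @param traj a trajectory already in the TM-aligned frame.
#' @param atom_sel [select_atoms()] selection (heavy atoms).
#' @param slab_halfwidth membrane slab half-thickness, Angstrom.
#' @param center_z z of the slab center (default 0).
#' @return a `MetricSeries` (Angstrom; negative = outside the slab).
#' @export
burial_depth_series <- function(traj, atom_sel, slab_halfwidth,
                                center_z = 0) {
  idx <- atom_sel$indices
  if (!length(idx)) stop_data("empty selection for burial depth")
  z <- traj$xyz[idx, 3, , drop = FALSE]
  dim(z) <- dim(z)[c(1, 3)]
  vals <- apply(slab_halfwidth - abs(z - center_z), 2, max)
  structure(list(name = sprintf("burial[%s]", atom_sel$label),
                 values = as.numeric(vals), units = "Å",
                 fit = "TM-aligned", measure = atom_sel$label),
            class = "MetricSeries")
}
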