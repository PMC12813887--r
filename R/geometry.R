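#' Kabsch superposition of two coordinate sets
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `mobile` and `reference` (SVD of the cross-covariance, with the
#' reflection branch corrected to a proper rotation). Points are rows.
#'
#' @param mobile,reference `n x 3` matrices, `n >= 3`, not collinear.
#' @return list with `rotation` (3x3, det +1), `translation` (length-3
#'   vector; aligned = mobile %*% rotation + translation), and `aligned`
#'   (the transformed mobile coordinates).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop_data("mobile and reference must be equal-sized n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3L) stop_numeric("superposition needs at least 3 points, got %d", n)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  am <- sweep(mobile, 2, cm); ar <- sweep(reference, 2, cr)
  k <- crossprod(ar, am)                 # t(ar) %*% am
  sv <- svd(k)
  scale <- max(sv$d[1], sqrt(sum(am^2) * sum(ar^2)) / n, .Machine$double.eps)
  if (sv$d[2] < 1e-10 * scale)
    stop_numeric("degenerate geometry: points are collinear or coincident, rotation under-determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.numeric(cr - cm %*% rot)
  list(rotation = rot, translation = trans,
       aligned = am %*% rot + matrix(cr, n, 3, byrow = TRUE))
}

apply_transform <- function(xyz, tf) {
  xyz %*% tf$rotation + matrix(tf$translation, nrow(xyz), 3, byrow = TRUE)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' Plain RMSD: `sqrt(mean(|a_i - b_i|^2))`. No fitting is performed inside
#' this function; superpose first if a fitted value is wanted.
#'
#' @param a,b `n x 3` matrices with corresponding rows.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop_data("coordinate sets differ in size (%d vs %d points)", nrow(a), nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

# resolve a reference to an n_atoms x 3 matrix; default frame 1 of traj
resolve_reference <- function(traj, reference) {
  if (is.null(reference)) return(frame_xyz(traj, 1L))
  if (inherits(reference, "Frame")) return(reference$xyz)
  if (inherits(reference, "Trajectory")) return(frame_xyz(reference, 1L))
  as.matrix(reference)
}

# superpose every frame onto the reference using fit_idx; returns the
# aligned coordinate array (all atoms transformed by the fit)
align_frames <- function(traj, fit_idx, reference = NULL) {
  ref <- resolve_reference(traj, reference)
  out <- traj$xyz
  for (m in seq_len(n_frames(traj))) {
    tf <- kabsch_superpose(traj$xyz[fit_idx, , m], ref[fit_idx, , drop = FALSE])
    out[, , m] <- apply_transform(traj$xyz[, , m], tf)
  }
  out
}

#' Per-frame RMSD series with separate fit and measure selections
#'
#' For each frame: superpose onto the reference over `fit_sel`, then
#' measure the RMSD over `measure_sel`. With `fit_sel` = TM and
#' `measure_sel` = a domain this is the "overall" (fit-to-TM) series that
#' includes inter-domain motion; with `fit_sel = measure_sel` = the domain
#' it is the "fit-to-self" (intra-domain) series.
#'
#' @param traj a [new_trajectory()] object.
#' @param fit_sel,measure_sel [select_atoms()] selections.
#' @param reference reference structure (`Frame`, `n x 3` matrix over the
#'   full topology, or `NULL` for frame 1 of `traj`).
#' @param name series name.
#' @return a `MetricSeries` (Angstrom, one value per frame).
#' @export
rmsd_series <- function(traj, fit_sel, measure_sel, reference = NULL,
                        name = NULL) {
  ref <- resolve_reference(traj, reference)
  fi <- fit_sel$indices; mi <- measure_sel$indices
  vals <- vapply(seq_len(n_frames(traj)), function(m) {
    fx <- traj$xyz[fi, , m, drop = FALSE]; dim(fx) <- dim(fx)[1:2]
    mx <- traj$xyz[mi, , m, drop = FALSE]; dim(mx) <- dim(mx)[1:2]
    tf <- kabsch_superpose(fx, ref[fi, , drop = FALSE])
    rmsd(apply_transform(mx, tf), ref[mi, , drop = FALSE])
  }, numeric(1))
  new_metric_series(name %||% sprintf("rmsd[%s|fit %s]", measure_sel$label,
                                      fit_sel$label),
                    vals, "Å", fit_sel$label, measure_sel$label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-residue root-mean-square fluctuation profile
#'
#' After superposing every frame onto the reference over `fit_sel`, the
#' RMSF of each measured C-alpha is the root-mean-square deviation from its
#' time-mean position.
#'
#' @inheritParams rmsd_series
#' @param measure_sel selection whose CA atoms are profiled.
#' @return object of class `"ResidueProfile"`: data.frame with `chain`,
#'   `resid`, `value` (Angstrom).
#' @export
rmsf_profile <- function(traj, fit_sel, measure_sel, reference = NULL) {
  if (n_frames(traj) < 2L)
    stop_data("RMSF needs at least 2 frames (fluctuation undefined for 1)")
  ca <- ca_indices(traj, measure_sel)
  aligned <- align_frames(traj, fit_sel$indices, reference)[ca, , , drop = FALSE]
  mean_pos <- apply(aligned, c(1, 2), mean)
  dev2 <- (aligned - array(mean_pos, dim = dim(aligned)))^2
  vals <- sqrt(apply(dev2, 1, sum) / dim(aligned)[3])
  structure(data.frame(chain = traj$atoms$chain[ca],
                       resid = traj$atoms$resid[ca],
                       value = as.numeric(vals)),
            class = c("ResidueProfile", "data.frame"))
}

#' Radius of gyration of a selection in one frame
#'
#' `sqrt(mean(|r_i - centroid|^2))`, unweighted by default; with
#' `mass_weighted = TRUE` standard atomic masses are used for both the
#' centroid and the average.
#'
#' @param frame a `Frame` (from [get_frame()]) or an `n x 3` matrix.
#' @param sel optional [select_atoms()] selection (required when `frame`
#'   carries a topology and a subset is wanted).
#' @param mass_weighted logical.
#' @return Rgyr in Angstrom.
#' @export
radius_of_gyration <- function(frame, sel = NULL, mass_weighted = FALSE) {
  if (inherits(frame, "Frame")) {
    idx <- if (is.null(sel)) seq_len(nrow(frame$atoms)) else sel$indices
    xyz <- frame$xyz[idx, , drop = FALSE]
    elems <- frame$atoms$elem[idx]
  } else {
    xyz <- as.matrix(frame)
    elems <- rep("C", nrow(xyz))
  }
  if (nrow(xyz) == 0L) stop_data("empty selection for radius of gyration")
  w <- if (mass_weighted) atomic_masses(elems) else rep(1, nrow(xyz))
  w <- w / sum(w)
  ctr <- colSums(xyz * w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)))
}

atomic_masses <- function(elems) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974, D = 2.014)
  m <- tab[elems]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Per-frame radius-of-gyration series
#' @inheritParams rmsd_series
#' @param sel selection over which Rgyr is computed.
#' @param mass_weighted logical.
#' @return a `MetricSeries` (Angstrom).
#' @export
rgyr_series <- function(traj, sel, mass_weighted = FALSE, name = NULL) {
  vals <- vapply(seq_len(n_frames(traj)), function(m)
    radius_of_gyration(get_frame(traj, m), sel, mass_weighted), numeric(1))
  new_metric_series(name %||% sprintf("rgyr[%s]", sel$label), vals, "Å",
                    "", sel$label)
}

#' Geometric center of a domain's C-alpha atoms
#' @param frame a `Frame`.
#' @param map a [domain_map()] object.
#' @param domain domain name.
#' @return length-3 numeric vector, Angstrom.
#' @export
domain_center <- function(frame, map, domain) {
  traj_like <- list(atoms = frame$atoms)
  sel <- select_atoms(structure(traj_like, class = "Trajectory"),
                      map, domain, atom_names = "CA")
  colMeans(frame$xyz[sel$indices, , drop = FALSE])
}

#' Per-frame distance between two domain centers
#'
#' Each frame is superposed onto the reference over `fit_sel` before the
#' Euclidean distance between the two domains' C-alpha centroids is taken
#' (the distance itself is invariant under the rigid fit; fitting keeps the
#' series consistent with the other TM-aligned quantities).
#'
#' @inheritParams rmsd_series
#' @param map a [domain_map()] object.
#' @param domain_a,domain_b domain names.
#' @return a `MetricSeries` (Angstrom).
#' @export
center_distance_series <- function(traj, map, domain_a, domain_b, fit_sel,
                                   reference = NULL) {
  ia <- ca_indices(traj, select_atoms(traj, map, domain_a))
  ib <- ca_indices(traj, select_atoms(traj, map, domain_b))
  aligned <- align_frames(traj, fit_sel$indices, reference)
  vals <- vapply(seq_len(n_frames(traj)), function(m) {
    ca <- colMeans(aligned[ia, , m, drop = FALSE])
    cb <- colMeans(aligned[ib, , m, drop = FALSE])
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  new_metric_series(sprintf("dist[%s-%s]", domain_a, domain_b), vals, "Å",
                    fit_sel$label, sprintf("%s,%s", domain_a, domain_b))
}

#' Per-frame end-to-end distance of the receptor chain
#'
#' Distance between the C-alpha atoms of the first and last residues of the
#' receptor (non-HETATM atoms of the given chain, author numbering order).
#'
#' @inheritParams rmsd_series
#' @param chain chain id; default: the non-HETATM chain with the most
#'   residues (the receptor chain, as opposed to a bound antigen chain).
#' @return a `MetricSeries` (Angstrom).
#' @export
end_to_end_series <- function(traj, chain = NULL) {
  at <- traj$atoms
  prot <- !at$het
  if (!any(prot)) stop_data("no receptor (non-HETATM) atoms in trajectory")
  if (is.null(chain)) {
    per_chain <- tapply(at$resid[prot], at$chain[prot],
                        function(r) length(unique(r)))
    chain <- names(per_chain)[which.max(per_chain)]
  }
  idx <- which(prot & at$chain == chain & at$name == "CA")
  if (length(idx) < 2L)
    stop_data("chain %s needs CA atoms on at least 2 residues for end-to-end distance", chain)
  first <- idx[which.min(at$resid[idx])]
  last <- idx[which.max(at$resid[idx])]
  a <- traj$xyz[first, , , drop = FALSE]; dim(a) <- dim(a)[2:3]
  b <- traj$xyz[last, , , drop = FALSE]; dim(b) <- dim(b)[2:3]
  vals <- sqrt(colSums((a - b)^2))
  new_metric_series(sprintf("end_to_end[%s]", chain), vals, "Å", "",
                    sprintf("resid %d-%d", at$resid[first], at$resid[last]))
}

#' Inter-domain contribution to an apo-vs-holo RMSD difference
#'
#' The overall (fit-to-TM) Ca-RMSD difference between two states mixes
#' rigid-body domain rearrangement with internal deformation; subtracting
#' the intra-domain (fit-to-self) difference isolates the inter-domain
#' contribution. The result may be negative when the intra-domain change
#' exceeds the overall change.
#'
#' @param overall_diff apo-vs-holo difference of mean fit-to-TM Ca-RMSD,
#'   Angstrom.
#' @param intra_diff same for the fit-to-self series.
#' @return `overall_diff - intra_diff`, Angstrom.
#' @export
decompose_interdomain <- function(overall_diff, intra_diff) {
  if (!is.finite(overall_diff) || !is.finite(intra_diff))
    stop_numeric("non-finite input to inter-domain decomposition")
  overall_diff - intra_diff
}

#' Batch inter/intra decomposition per domain
#' @param overall_diffs,intra_diffs named numeric vectors (names = domains).
#' @return data.frame with `domain`, `overall_diff`, `intra_diff`,
#'   `inter_diff` (Angstrom); `inter_diff = overall_diff - intra_diff`
#'   exactly, by construction.
#' @export
decompose_domains <- function(overall_diffs, intra_diffs) {
  doms <- names(overall_diffs)
  if (is.null(doms) || !setequal(doms, names(intra_diffs)))
    stop_config("overall and intra difference vectors must share domain names")
  intra_diffs <- intra_diffs[doms]
  data.frame(domain = doms,
             overall_diff = as.numeric(overall_diffs),
             intra_diff = as.numeric(intra_diffs),
             inter_diff = vapply(doms, function(d)
               decompose_interdomain(overall_diffs[[d]], intra_diffs[[d]]),
               numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare a metric between the apo and holo states
#'
#' Means and standard deviations over the post-equilibration window
#' (frames with 0-based index `>= equilibration_cut`); the signed
#' difference is holo minus apo throughout the package.
#'
#' @param apo,holo `MetricSeries` objects or plain numeric vectors.
#' @param equilibration_cut 0-based frame index at which averaging starts
#'   (frames before it are discarded as equilibration).
#' @return object of class `"StateComparison"`: list with `metric`,
#'   `apo_mean`, `apo_sd`, `holo_mean`, `holo_sd`, `signed_diff`
#'   (holo - apo), `abs_diff`, `n_apo`, `n_holo`, `cut`.
#' @export
compare_states <- function(apo, holo, equilibration_cut = 0L) {
  name <- if (inherits(apo, "MetricSeries")) apo$name else "metric"
  va <- if (inherits(apo, "MetricSeries")) apo$values else as.numeric(apo)
  vh <- if (inherits(holo, "MetricSeries")) holo$values else as.numeric(holo)
  cut <- as.integer(equilibration_cut)
  if (cut < 0L) stop_config("equilibration cut must be >= 0")
  if (cut >= length(va) || cut >= length(vh))
    stop_config("equilibration cut %d leaves no frames (series lengths %d, %d)",
                cut, length(va), length(vh))
  va <- va[(cut + 1L):length(va)]
  vh <- vh[(cut + 1L):length(vh)]
  sm <- mean(vh) - mean(va)
  structure(list(metric = name,
                 apo_mean = mean(va), apo_sd = stats::sd(va),
                 holo_mean = mean(vh), holo_sd = stats::sd(vh),
                 signed_diff = sm, abs_diff = abs(sm),
                 n_apo = length(va), n_holo = length(vh), cut = cut),
            class = "StateComparison")
}

#' @export
print.StateComparison <- function(x, ...) {
  cat(sprintf("%s: apo %.1f ± %.1f, holo %.1f ± %.1f, diff %+.1f Å\n",
              x$metric, x$apo_mean, x$apo_sd, x$holo_mean, x$holo_sd,
              x$signed_diff))
  invisible(x)
}
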