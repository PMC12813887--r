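#' Dihedral (torsion) angle of four points
#'
#' IUPAC sign convention: looking from `p2` to `p3`, a clockwise rotation
#' of the far bond relative to the near bond is positive.
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees, in (-180, 180].
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2; b1 <- p3 - p2; b2 <- p4 - p3
  b1 <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1) * b1           # projections normal to the axis
  w <- b2 - sum(b2 * b1) * b1
  ang <- atan2(sum(cross3(b1, v) * w), sum(v * w)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Backbone phi/psi dihedrals of one frame
#'
#' `phi_i` from C(i-1)-N(i)-CA(i)-C(i), `psi_i` from
#' N(i)-CA(i)-C(i)-N(i+1). Chain termini (and residues missing a backbone
#' atom, which additionally trigger a warning) are reported as `NA`.
#'
#' @param frame a `Frame` from [get_frame()].
#' @param chain chain id; default: first non-HETATM chain.
#' @return data.frame with `resid`, `phi`, `psi` (degrees).
#' @export
backbone_dihedrals <- function(frame, chain = NULL) {
  at <- frame$atoms
  prot <- !at$het
  if (is.null(chain)) chain <- at$chain[which(prot)[1]]
  sel <- prot & at$chain == chain
  resids <- sort(unique(at$resid[sel]))
  bb <- function(resid, name) {
    i <- which(sel & at$resid == resid & at$name == name)
    if (length(i)) frame$xyz[i[1], ] else NULL
  }
  phi <- psi <- rep(NA_real_, length(resids))
  missing_bb <- logical(length(resids))
  for (k in seq_along(resids)) {
    n_k <- bb(resids[k], "N"); ca_k <- bb(resids[k], "CA")
    c_k <- bb(resids[k], "C")
    if (is.null(n_k) || is.null(ca_k) || is.null(c_k)) {
      missing_bb[k] <- TRUE
      next
    }
    if (k > 1L) {
      c_prev <- bb(resids[k - 1L], "C")
      if (!is.null(c_prev)) phi[k] <- torsion_angle(c_prev, n_k, ca_k, c_k)
    }
    if (k < length(resids)) {
      n_next <- bb(resids[k + 1L], "N")
      if (!is.null(n_next)) psi[k] <- torsion_angle(n_k, ca_k, c_k, n_next)
    }
  }
  if (any(missing_bb))
    warning(sprintf("residue(s) %s missing backbone atoms; dihedrals marked NA",
                    paste(resids[missing_bb], collapse = ",")))
  data.frame(resid = resids, phi = phi, psi = psi)
}

#' Assign secondary structure from backbone dihedrals
#'
#' Dihedral-window rules: H (alpha-helix) iff phi in (-120, -30) and psi in
#' (-80, -5); E (beta/extended) iff phi in (-180, -70) and psi in
#' (90, 180] or [-180, -150); else C (coil/turn). Raw H/E runs shorter
#' than 3 residues are reassigned to C. Residues with undefined dihedrals
#' (termini) are C.
#'
#' @inheritParams backbone_dihedrals
#' @return object of class `"SseString"`: character vector of per-residue
#'   labels in `{"H","E","C"}`, names = residue ids.
#' @export
assign_sse <- function(frame, chain = NULL) {
  dih <- backbone_dihedrals(frame, chain)
  lab <- rep("C", nrow(dih))
  ok <- is.finite(dih$phi) & is.finite(dih$psi)
  h <- ok & dih$phi > -120 & dih$phi < -30 & dih$psi > -80 & dih$psi < -5
  e <- ok & dih$phi > -180 & dih$phi < -70 &
    ((dih$psi > 90 & dih$psi <= 180) | (dih$psi >= -180 & dih$psi < -150))
  lab[e] <- "E"
  lab[h] <- "H"
  # minimum run length 3 for H and E
  r <- rle(lab)
  r$values[r$values %in% c("H", "E") & r$lengths < 3L] <- "C"
  lab <- inverse.rle(r)
  structure(stats::setNames(lab, dih$resid), class = "SseString")
}

#' Time-averaged secondary-structure fractions of a domain
#'
#' @param traj a trajectory whose residues carry full N/CA/C backbones.
#' @param map a [domain_map()] object.
#' @param domain domain name.
#' @param chain chain id passed to [assign_sse()].
#' @return named numeric `c(H=, E=, C=)` summing to 1.
#' @export
sse_fractions <- function(traj, map, domain, chain = NULL) {
  dom <- map$domains[[domain]]
  if (is.null(dom)) stop_config("unknown domain '%s'", domain)
  counts <- c(H = 0, E = 0, C = 0)
  for (m in seq_len(n_frames(traj))) {
    sse <- assign_sse(get_frame(traj, m), chain)
    resid <- as.integer(names(sse))
    in_dom <- rep(FALSE, length(resid))
    for (i in seq_len(nrow(dom)))
      in_dom <- in_dom | (resid >= dom$start[i] & resid <= dom$end[i])
    if (!any(in_dom)) stop_data("domain '%s' has no residues in trajectory", domain)
    tb <- table(factor(unclass(sse)[in_dom], levels = c("H", "E", "C")))
    counts <- counts + as.numeric(tb)
  }
  counts / sum(counts)
}

#' Leader-algorithm trajectory clustering at an RMSD cutoff
#'
#' Deterministic single-pass scan: each frame is assigned to the first
#' existing cluster whose representative is within `cutoff` (RMSD over
#' `sel` after pairwise superposition), otherwise it founds a new cluster
#' with itself as representative. By construction every frame is within
#' the cutoff of its representative.
#'
#' @param traj a [new_trajectory()] object.
#' @param sel [select_atoms()] selection used both to fit and to measure.
#' @param cutoff RMSD cutoff, Angstrom (default 2.5).
#' @return object of class `"ClusterAssignment"`: list with `labels`
#'   (0-based cluster id per frame), `representatives` (1-based frame index
#'   per cluster), `cutoff`, `n_clusters`.
#' @export
cluster_trajectory <- function(traj, sel, cutoff = 2.5) {
  idx <- sel$indices
  if (!length(idx)) stop_data("empty selection for clustering")
  if (cutoff <= 0) stop_config("cluster cutoff must be > 0")
  nf <- n_frames(traj)
  coords <- lapply(seq_len(nf), function(m) {
    x <- traj$xyz[idx, , m, drop = FALSE]; dim(x) <- dim(x)[1:2]; x
  })
  reps <- integer(0)
  labels <- integer(nf)
  for (m in seq_len(nf)) {
    assigned <- FALSE
    for (ci in seq_along(reps)) {
      r <- kabsch_superpose(coords[[m]], coords[[reps[ci]]])
      if (rmsd(r$aligned, coords[[reps[ci]]]) <= cutoff) {
        labels[m] <- ci - 1L
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, m)
      labels[m] <- length(reps) - 1L
    }
  }
  structure(list(labels = labels, representatives = reps, cutoff = cutoff,
                 n_clusters = length(reps)),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d frames in %d clusters (cutoff %.1f Å)\n",
              length(x$labels), x$n_clusters, x$cutoff))
  invisible(x)
}

#' Normalized displacement cross-correlation matrix
#'
#' After superposing every frame onto the reference over `fit_sel`, node
#' `i`'s displacement is its deviation from its time-mean position;
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)`.
#'
#' @param traj a [new_trajectory()] object, >= 2 frames.
#' @param sel C-alpha node selection.
#' @param fit_sel selection to superpose on.
#' @param reference as in [rmsd_series()].
#' @return object of class `"CorrelationMatrix"`: symmetric matrix with
#'   unit diagonal, dimnames = residue ids.
#' @export
correlation_matrix <- function(traj, sel, fit_sel, reference = NULL) {
  if (n_frames(traj) < 2L) stop_data("correlation matrix needs >= 2 frames")
  ca <- ca_indices(traj, sel)
  aligned <- align_frames(traj, fit_sel$indices, reference)[ca, , , drop = FALSE]
  nf <- dim(aligned)[3]
  mean_pos <- apply(aligned, c(1, 2), mean)
  dev <- aligned - array(mean_pos, dim = dim(aligned))
  # S_ij = mean_t dr_i . dr_j, accumulated per coordinate
  x <- t(dev[, 1, ]); y <- t(dev[, 2, ]); z <- t(dev[, 3, ])
  s <- (crossprod(x) + crossprod(y) + crossprod(z)) / nf
  v <- diag(s)
  zero <- which(v <= .Machine$double.eps)
  if (length(zero))
    stop_numeric("zero-variance node(s): residue %s",
                 paste(traj$atoms$resid[ca][zero], collapse = ","))
  cmat <- s / sqrt(outer(v, v))
  cmat <- (cmat + t(cmat)) / 2
  diag(cmat) <- 1
  dimnames(cmat) <- list(traj$atoms$resid[ca], traj$atoms$resid[ca])
  structure(cmat, class = c("CorrelationMatrix", "matrix", "array"))
}

#' Build the correlated-motion network
#'
#' Nodes are the residues of the correlation matrix; an edge joins
#' residues `i`, `j` when any heavy-atom pair of the two residues is
#' within `contact_cutoff` in at least an `occupancy` fraction of frames.
#' Edge weight `-log|C_ij|`, capped at `-log(1e-6)` for vanishing
#' correlations, so strongly correlated contacts are "short".
#'
#' @param traj a [new_trajectory()] object.
#' @param corr a [correlation_matrix()] over the same residues.
#' @param node_sel the C-alpha selection the matrix was built from.
#' @param contact_cutoff heavy-atom contact distance, Angstrom (default 4.5).
#' @param occupancy minimum fraction of frames in contact (default 0.75).
#' @return an igraph graph with vertex attribute `resid` and edge
#'   attributes `weight` and `occupancy`.
#' @export
build_network <- function(traj, corr, node_sel, contact_cutoff = 4.5,
                          occupancy = 0.75) {
  ca <- ca_indices(traj, node_sel)
  resids <- traj$atoms$resid[ca]
  chains <- traj$atoms$chain[ca]
  if (nrow(corr) != length(resids))
    stop_config("correlation matrix (%d nodes) does not match selection (%d residues)",
                nrow(corr), length(resids))
  at <- traj$atoms
  heavy <- !(at$elem %in% c("H", "D")) & !at$het
  res_atoms <- lapply(seq_along(resids), function(k)
    which(heavy & at$resid == resids[k] & at$chain == chains[k]))
  nf <- n_frames(traj)
  nn <- length(resids)
  cut2 <- contact_cutoff^2
  occ <- matrix(0, nn, nn)
  for (m in seq_len(nf)) {
    fx <- frame_xyz(traj, m)
    for (i in seq_len(nn - 1L)) {
      a <- fx[res_atoms[[i]], , drop = FALSE]
      for (j in (i + 1L):nn) {
        b <- fx[res_atoms[[j]], , drop = FALSE]
        d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
        if (min(d2) <= cut2) occ[i, j] <- occ[i, j] + 1
      }
    }
  }
  occ <- occ / nf
  edges <- which(occ >= occupancy, arr.ind = TRUE)
  w <- -log(pmax(abs(corr[edges]), 1e-6))
  g <- igraph::make_empty_graph(n = nn, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "resid", value = resids)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(resids))
  if (nrow(edges))
    g <- igraph::add_edges(g, t(edges), weight = w,
                           occupancy = occ[edges])
  g
}

#' Girvan-Newman community detection maximizing weighted modularity
#'
#' Removes, repeatedly, the edge of highest (weighted, distance-style)
#' edge betweenness -- ties broken deterministically by lowest edge index
#' -- and returns the partition along the dendrogram that maximizes Newman
#' modularity on the original graph. Disconnected input is allowed;
#' components seed separate communities from the start.
#'
#' @param graph an igraph graph, e.g. from [build_network()].
#' @param map optional [domain_map()]; when given, the number of distinct
#'   communities intersecting each domain is reported.
#' @return object of class `"CommunityPartition"`: list with `membership`
#'   (1-based community id per node, named), `modularity`, `n_communities`,
#'   `per_domain_counts`.
#' @export
detect_communities <- function(graph, map = NULL) {
  nv <- igraph::vcount(graph)
  if (nv == 0L) stop_data("empty graph")
  has_w <- "weight" %in% igraph::edge_attr_names(graph)
  total_w <- if (has_w) sum(igraph::E(graph)$weight) else igraph::ecount(graph)
  mod_of <- function(memb) {
    if (igraph::ecount(graph) == 0L) return(0)
    if (has_w && total_w > 0)
      igraph::modularity(graph, memb, weights = igraph::E(graph)$weight)
    else
      igraph::modularity(graph, memb)
  }
  g <- graph
  best_memb <- igraph::components(g)$membership
  best_mod <- mod_of(best_memb)
  while (igraph::ecount(g) > 0L) {
    bet <- igraph::edge_betweenness(g, weights = if (has_w)
      igraph::E(g)$weight else NULL)
    drop <- which(bet >= max(bet) * (1 - 1e-12))[1]  # lowest index on ties
    g <- igraph::delete_edges(g, drop)
    memb <- igraph::components(g)$membership
    m <- mod_of(memb)
    if (m > best_mod + 1e-12) {
      best_mod <- m
      best_memb <- memb
    }
  }
  resids <- igraph::vertex_attr(graph, "resid")
  per_domain <- NULL
  if (!is.null(map) && !is.null(resids)) {
    per_domain <- vapply(names(map$domains), function(nm) {
      d <- map$domains[[nm]]
      in_dom <- rep(FALSE, nv)
      for (i in seq_len(nrow(d)))
        in_dom <- in_dom | (resids >= d$start[i] & resids <= d$end[i])
      length(unique(best_memb[in_dom]))
    }, numeric(1))
  }
  names(best_memb) <- igraph::vertex_attr(graph, "name")
  structure(list(membership = best_memb, modularity = best_mod,
                 n_communities = length(unique(best_memb)),
                 per_domain_counts = per_domain),
            class = "CommunityPartition")
}

#' @export
print.CommunityPartition <- function(x, ...) {
  cat(sprintf("CommunityPartition: %d communities, modularity %.3f\n",
              x$n_communities, x$modularity))
  invisible(x)
}
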