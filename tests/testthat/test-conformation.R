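test_that("torsion angles agree with an independent implementation", {
  # constructed 90-degree torsion
  p1 <- c(1, 0, 0); p2 <- c(0, 0, 0); p3 <- c(0, 0, 1); p4 <- c(0, 1, 1)
  expect_equal(abs(torsion_angle(p1, p2, p3, p4)), 90, tolerance = 1e-9)
  # torsions are invariant under reversing the atom order
  expect_equal(torsion_angle(p4, p3, p2, p1),
               torsion_angle(p1, p2, p3, p4), tolerance = 1e-9)
  # cross-check against bio3d on random quadruples
  set.seed(41)
  for (i in 1:20) {
    q <- random_points(4)
    expect_equal(torsion_angle(q[1, ], q[2, ], q[3, ], q[4, ]),
                 bio3d::torsion.xyz(as.numeric(t(q))),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("ideal helix and strand fixtures return their construction dihedrals", {
  h <- backbone_dihedrals(get_frame(make_fixture("helix", n_res = 12), 1))
  expect_true(all(abs(h$phi[2:11] - (-57)) < 0.5))
  expect_true(all(abs(h$psi[2:11] - (-47)) < 0.5))
  expect_true(is.na(h$phi[1]) && is.na(h$psi[12]))
  s <- backbone_dihedrals(get_frame(make_fixture("strand", n_res = 8), 1))
  expect_true(all(abs(s$phi[2:7] - (-139)) < 0.5))
  expect_true(all(abs(s$psi[2:7] - 135) < 0.5))
})

test_that("secondary-structure assignment labels ideal fixtures and smooths short runs", {
  sse_h <- assign_sse(get_frame(make_fixture("helix", n_res = 12), 1))
  expect_true(all(unclass(sse_h)[2:11] == "H"))
  sse_e <- assign_sse(get_frame(make_fixture("strand", n_res = 8), 1))
  expect_true(all(unclass(sse_e)[2:7] == "E"))
  # raw pattern C,H,H,C,H,H,C (runs of 2) must smooth to all C
  phi <- c(-57, -57, -57, 60, -57, -57, -57)
  psi <- c(-47, -47, -47, 60, -47, -47, -47)
  tr <- cardyn:::build_backbone(7, phi, psi)
  sse <- assign_sse(get_frame(tr, 1))
  expect_true(all(unclass(sse) == "C"))
})

test_that("per-domain SSE fractions are pure on a half-helix half-strand chain and sum to 1", {
  phi <- c(rep(-57, 7), rep(-139, 7))
  psi <- c(rep(-47, 7), rep(135, 7))
  tr <- cardyn:::build_backbone(14, phi, psi)
  map <- domain_map(list(AB = c(2, 6), HI = c(7, 8), TM = c(10, 13),
                         CS = c(20, 21), SI = c(22, 23)))
  fr_ab <- sse_fractions(tr, map, "AB")
  fr_tm <- sse_fractions(tr, map, "TM")
  expect_equal(fr_ab[["H"]], 1)
  expect_equal(fr_tm[["E"]], 1)
  # fractions sum to 1 on noisy multi-frame input
  noisy <- make_fixture("rigid_copies", base = tr, n_frames = 3,
                        sigma = 0.25, seed = 7)
  fr <- sse_fractions(noisy, map, "AB")
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_true(all(fr >= 0))
})

test_that("leader clustering is deterministic, respects its invariant, and is monotone in cutoff", {
  pts <- random_points(5)
  same <- ca_traj(rep(list(pts), 6))
  sel <- select_atoms(same, NULL, data.frame(chain = "A", start = 1, end = 5))
  expect_equal(cluster_trajectory(same, sel)$n_clusters, 1L)
  # two genuinely different conformers (not rigid motions of each other);
  # slight zig-zag so superposition is well-conditioned
  extended <- cbind(5 * (0:4), c(0, 0.5, 0, 0.5, 0), 0)
  folded <- rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0), c(0, 5, 0), c(0, 5, 5))
  alt <- ca_traj(rep(list(extended, folded), 4))
  sel2 <- select_atoms(alt, NULL, data.frame(chain = "A", start = 1, end = 5))
  ca <- cluster_trajectory(alt, sel2, cutoff = 2.5)
  expect_equal(ca$n_clusters, 2L)
  expect_equal(ca$labels, rep(c(0L, 1L), 4))
  # invariant: every frame within cutoff of its representative
  for (m in seq_along(ca$labels)) {
    rep_xyz <- frame_xyz(alt, ca$representatives[ca$labels[m] + 1L])[sel2$indices, ]
    fr_xyz <- frame_xyz(alt, m)[sel2$indices, ]
    fit <- kabsch_superpose(fr_xyz, rep_xyz)
    expect_lte(rmsd(fit$aligned, rep_xyz), 2.5)
  }
  # cluster count is monotone non-increasing in cutoff
  set.seed(43)
  noisy <- ca_traj(lapply(1:15, function(i) pts + matrix(rnorm(15, sd = 1.2), 5, 3)))
  n_by_cut <- vapply(c(0.5, 1, 2, 4, 8), function(cut)
    cluster_trajectory(noisy, sel, cut)$n_clusters, integer(1))
  expect_true(all(diff(n_by_cut) <= 0))
})

test_that("correlation matrix hits +/-1 for programmed motions and stays small for noise", {
  static3 <- random_points(3) + 50
  set.seed(44)
  walk <- matrix(rnorm(60), 20, 3)
  frames <- lapply(1:20, function(m)
    rbind(static3, c(0, 0, 0) + walk[m, ], c(10, 0, 0) + walk[m, ],
          c(20, 0, 0) - walk[m, ]))
  tr <- ca_traj(frames)
  fit <- select_atoms(tr, NULL, data.frame(chain = "A", start = 1, end = 3))
  nodes <- select_atoms(tr, NULL, data.frame(chain = "A", start = 4, end = 6))
  cm <- correlation_matrix(tr, nodes, fit)
  expect_equal(diag(cm), rep(1, 3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(cm[1, 2], 1, tolerance = 1e-9)
  expect_equal(cm[1, 3], -1, tolerance = 1e-9)
  expect_equal(cm, t(cm), ignore_attr = TRUE)
  # independent noise: off-diagonals vanish with sampling
  set.seed(45)
  nf <- 20000
  noise <- array(rnorm(4 * 3 * nf), c(4, 3, nf))
  frames <- lapply(seq_len(nf), function(m)
    rbind(static3, matrix(c(0, 0, 0, 15, 0, 0, 30, 0, 0, 45, 0, 0),
                          4, 3, byrow = TRUE) + noise[, , m]))
  trn <- ca_traj(frames)
  fitn <- select_atoms(trn, NULL, data.frame(chain = "A", start = 1, end = 3))
  noden <- select_atoms(trn, NULL, data.frame(chain = "A", start = 4, end = 7))
  cmn <- correlation_matrix(trn, noden, fitn)
  offdiag <- cmn[upper.tri(cmn)]
  expect_true(all(abs(offdiag) < 0.1))
  # zero-variance node is an error naming the residue
  frames0 <- lapply(1:5, function(m) rbind(static3, c(0, 0, 0)))
  tr0 <- ca_traj(frames0)
  expect_error(correlation_matrix(
    tr0, select_atoms(tr0, NULL, data.frame(chain = "A", start = 4, end = 4)),
    select_atoms(tr0, NULL, data.frame(chain = "A", start = 1, end = 3))),
    "4", class = "cardyn_numeric_error")
})

test_that("network construction follows the contact-occupancy rule and the weight convention", {
  static3 <- random_points(3) + 100
  set.seed(46)
  walk <- matrix(rnorm(24, sd = 0.5), 8, 3)
  # residues 4 and 5 stay ~3 A apart (always in contact, identical motion
  # so C = 1); residue 6 is 50 A away (never in contact)
  frames <- lapply(1:8, function(m)
    rbind(static3, c(0, 0, 0) + walk[m, ], c(3, 0, 0) + walk[m, ],
          c(50, 0, 0) + 0.5 * walk[m, ]))
  tr <- ca_traj(frames)
  fit <- select_atoms(tr, NULL, data.frame(chain = "A", start = 1, end = 3))
  nodes <- select_atoms(tr, NULL, data.frame(chain = "A", start = 4, end = 6))
  cm <- correlation_matrix(tr, nodes, fit)
  g <- build_network(tr, cm, nodes, contact_cutoff = 4.5, occupancy = 0.75)
  expect_equal(igraph::ecount(g), 1L)
  e <- igraph::as_data_frame(g)
  expect_setequal(as.character(unlist(e[, c("from", "to")])), c("4", "5"))
  expect_equal(e$weight, 0, tolerance = 1e-9)
  expect_equal(e$occupancy, 1)
})

test_that("network edges equal a brute-force occupancy count on a toy system", {
  set.seed(47)
  n_res <- 6; nf <- 10
  base <- cbind(seq(0, 22, length.out = n_res), 0, 0)
  static3 <- random_points(3) + 100
  frames <- lapply(1:nf, function(m)
    rbind(static3, base + matrix(rnorm(n_res * 3, sd = 2), n_res, 3)))
  tr <- ca_traj(frames)
  fit <- select_atoms(tr, NULL, data.frame(chain = "A", start = 1, end = 3))
  nodes <- select_atoms(tr, NULL, data.frame(chain = "A", start = 4,
                                             end = 3 + n_res))
  cm <- correlation_matrix(tr, nodes, fit)
  cutoff <- 6; occ_min <- 0.5
  g <- build_network(tr, cm, nodes, contact_cutoff = cutoff,
                     occupancy = occ_min)
  # brute force: count frames with pair distance <= cutoff
  got <- igraph::as_data_frame(g)
  got_pairs <- sort(paste(pmin(got$from, got$to), pmax(got$from, got$to)))
  want_pairs <- character()
  node_idx <- nodes$indices
  for (i in 1:(n_res - 1)) for (j in (i + 1):n_res) {
    hits <- 0
    for (m in 1:nf) {
      fx <- frame_xyz(tr, m)
      if (sqrt(sum((fx[node_idx[i], ] - fx[node_idx[j], ])^2)) <= cutoff)
        hits <- hits + 1
    }
    if (hits / nf >= occ_min)
      want_pairs <- c(want_pairs,
                      paste(tr$atoms$resid[node_idx[i]],
                            tr$atoms$resid[node_idx[j]]))
  }
  expect_setequal(got_pairs, sort(want_pairs))
})

test_that("community detection separates disconnected cliques and handles singletons", {
  tri2 <- igraph::make_graph(c(1,2, 2,3, 3,1, 4,5, 5,6, 6,4), directed = FALSE)
  igraph::E(tri2)$weight <- 1
  cp <- detect_communities(tri2)
  expect_equal(cp$n_communities, 2L)
  expect_equal(sort(unique(cp$membership)), 1:2)
  one <- igraph::make_empty_graph(1, directed = FALSE)
  cp1 <- detect_communities(one)
  expect_equal(cp1$n_communities, 1L)
  expect_equal(cp1$modularity, 0)
  # returned modularity is at least that of the all-singletons partition
  set.seed(48)
  g <- igraph::sample_gnp(10, 0.35)
  igraph::E(g)$weight <- runif(igraph::ecount(g), 0.5, 2)
  cp2 <- detect_communities(g)
  singletons <- igraph::modularity(g, seq_len(10), weights = igraph::E(g)$weight)
  expect_gte(cp2$modularity, singletons)
  expect_length(cp2$membership, 10)
})
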