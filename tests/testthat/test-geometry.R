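test_that("Kabsch recovers rigid motions exactly and returns a proper rotation", {
  set.seed(21)
  a <- random_points(6)
  expect_equal(rmsd(kabsch_superpose(a, a)$aligned, a), 0, tolerance = 1e-10)
  b <- a %*% rotation_z(90) + matrix(c(3, 4, 0), 6, 3, byrow = TRUE)
  fit <- kabsch_superpose(a, b)
  expect_lt(rmsd(fit$aligned, b), 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # applying the returned transform reproduces the aligned coordinates
  expect_equal(a %*% fit$rotation +
                 matrix(fit$translation, 6, 3, byrow = TRUE),
               fit$aligned, tolerance = 1e-12)
})

test_that("degenerate geometries are refused", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear",
               class = "cardyn_numeric_error")
  expect_error(kabsch_superpose(random_points(2), random_points(2)),
               class = "cardyn_numeric_error")
})

test_that("superposed RMSD never exceeds unsuperposed RMSD", {
  set.seed(22)
  for (i in 1:25) {
    a <- random_points(sample(4:12, 1))
    b <- a + matrix(rnorm(length(a), sd = runif(1, 0.1, 4)), nrow(a), 3)
    expect_lte(rmsd(kabsch_superpose(a, b)$aligned, b), rmsd(a, b) + 1e-12)
  }
})

test_that("plain RMSD matches closed forms and the definitional oracle", {
  a <- random_points(8)
  expect_equal(rmsd(a, a), 0)
  expect_equal(rmsd(a, a + matrix(c(3, 4, 0), 8, 3, byrow = TRUE)), 5)
  set.seed(23)
  b <- random_points(8)
  naive <- sqrt(mean(vapply(1:8, function(i) sum((a[i, ] - b[i, ])^2),
                            numeric(1))))
  expect_equal(rmsd(a, b), naive)
  expect_equal(rmsd(a, b), rmsd(b, a))
  # invariance under a common rigid motion
  r <- rotation_z(37); t <- c(1, -2, 3)
  shift <- function(x) x %*% r + matrix(t, nrow(x), 3, byrow = TRUE)
  expect_equal(rmsd(shift(a), shift(b)), rmsd(a, b), tolerance = 1e-12)
  expect_error(rmsd(a, b[1:5, ]), class = "cardyn_data_error")
})

test_that("rmsd_series is zero on rigid-motion trajectories and matches the 2-frame closed form", {
  base <- ca_traj(list(random_points(10)))
  rigid <- make_fixture("rigid_copies", base = base, n_frames = 6,
                        rotation = rotation_z(25), translation = c(1, 2, -1))
  sel <- select_atoms(rigid, NULL,
                      data.frame(chain = "A", start = 1, end = 10))
  s <- rmsd_series(rigid, sel, sel)
  expect_true(all(abs(s$values) < 1e-8))
  # frame 1 = reference; frame 2 moves one of 4 measured atoms by 2 A
  f1 <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0),      # fit atoms (static)
              c(10, 0, 0), c(12, 0, 0), c(10, 2, 0), c(12, 2, 0))
  f2 <- f1; f2[4, ] <- f2[4, ] + c(0, 0, 2)
  tr <- ca_traj(list(f1, f2))
  fit <- select_atoms(tr, NULL, data.frame(chain = "A", start = 1, end = 3))
  meas <- select_atoms(tr, NULL, data.frame(chain = "A", start = 4, end = 7))
  s2 <- rmsd_series(tr, fit, meas)
  expect_equal(s2$values, c(0, 1), tolerance = 1e-9)
})

test_that("fit-to-self hides a domain's rigid translation, fit-to-TM shows it", {
  set.seed(24)
  ab <- random_points(5) + matrix(c(0, 0, 30), 5, 3, byrow = TRUE)
  tm <- random_points(4)
  frames <- lapply(0:4, function(m)
    rbind(ab + matrix(c(3 * m, 0, 0), 5, 3, byrow = TRUE), tm))
  tr <- ca_traj(frames)
  ab_sel <- select_atoms(tr, NULL, data.frame(chain = "A", start = 1, end = 5))
  tm_sel <- select_atoms(tr, NULL, data.frame(chain = "A", start = 6, end = 9))
  fit_self <- rmsd_series(tr, ab_sel, ab_sel)
  fit_tm <- rmsd_series(tr, tm_sel, ab_sel)
  expect_true(all(abs(fit_self$values) < 1e-8))
  expect_gt(fit_tm$values[5], 1)
})

test_that("RMSF matches closed forms: zero, alternation, sinusoid a/sqrt(2)", {
  static3 <- random_points(3)
  const <- ca_traj(rep(list(rbind(static3, c(5, 5, 5))), 10))
  all_sel <- select_atoms(const, NULL,
                          data.frame(chain = "A", start = 1, end = 4))
  expect_true(all(rmsf_profile(const, all_sel, all_sel)$value < 1e-10))
  expect_error(rmsf_profile(ca_traj(list(random_points(4))), all_sel, all_sel),
               class = "cardyn_data_error")
  # one atom alternating x = +1/-1, fit atoms static
  frames <- lapply(1:200, function(m)
    rbind(static3, c(ifelse(m %% 2 == 0, 1, -1), 0, 0)))
  tr <- ca_traj(frames)
  fit <- select_atoms(tr, NULL, data.frame(chain = "A", start = 1, end = 3))
  meas <- select_atoms(tr, NULL, data.frame(chain = "A", start = 4, end = 4))
  expect_equal(rmsf_profile(tr, fit, meas)$value, 1, tolerance = 1e-9)
  # sinusoidal displacement of amplitude a over whole periods
  a <- 2.5
  frames <- lapply(1:400, function(m)
    rbind(static3, c(a * sin(2 * pi * m / 40), 0, 0)))
  tr <- ca_traj(frames)
  expect_equal(rmsf_profile(tr, fit, meas)$value, a / sqrt(2),
               tolerance = 0.02)
})

test_that("RMSF of stationary Gaussian noise converges to sigma*sqrt(3)", {
  set.seed(25)
  sigma <- 0.8
  nf <- 20000
  static3 <- random_points(3)
  noise <- matrix(rnorm(3 * nf, sd = sigma), nf, 3)
  frames <- lapply(seq_len(nf), function(m)
    rbind(static3, c(30, 30, 30) + noise[m, ]))
  tr <- ca_traj(frames)
  fit <- select_atoms(tr, NULL, data.frame(chain = "A", start = 1, end = 3))
  meas <- select_atoms(tr, NULL, data.frame(chain = "A", start = 4, end = 4))
  expect_equal(rmsf_profile(tr, fit, meas)$value, sigma * sqrt(3),
               tolerance = 0.03)
})

test_that("radius of gyration matches closed forms and invariances", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  square <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))
  expect_equal(radius_of_gyration(square), sqrt(2))
  set.seed(26)
  pts <- random_points(20)
  rg <- radius_of_gyration(pts)
  moved <- pts %*% rotation_z(63) + matrix(c(9, -4, 2), 20, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(moved), rg, tolerance = 1e-12)
  expect_equal(radius_of_gyration(pts * 2.5), rg * 2.5, tolerance = 1e-12)
})

test_that("domain centers equal the naive average of domain CA atoms", {
  tr <- ca_traj(list(bead_frame()))
  map <- bead_map()
  fr <- get_frame(tr, 1)
  expect_equal(domain_center(fr, map, "AB"), c(0, 0, 40))
  expect_equal(domain_center(fr, map, "TM"),
               colMeans(bead_frame()[3:5, ]))
  # two-residue domain: center is the midpoint of the two CA atoms
  two <- ca_traj(list(rbind(c(0, 0, 0), c(2, 0, 0), bead_frame()[3:7, ])),
                 resid = c(1, 2, 3:7))
  map2 <- domain_map(list(AB = c(1, 2), HI = c(8, 9), TM = c(3, 5),
                          CS = c(6, 6), SI = c(7, 7)))
  expect_equal(domain_center(get_frame(two, 1), map2, "AB"), c(1, 0, 0))
  expect_error(domain_center(get_frame(two, 1), map2, "HI"),
               class = "cardyn_data_error")
})

test_that("center distances and end-to-end distances match constructions", {
  tr <- ca_traj(rep(list(bead_frame()), 4))
  map <- bead_map()
  fit <- select_atoms(tr, map, "TM", atom_names = "CA")
  d <- center_distance_series(tr, map, "AB", "SI", fit)
  expect_equal(d$values, rep(80, 4), tolerance = 1e-9)
  dz <- center_distance_series(tr, map, "AB", "AB", fit)
  expect_equal(dz$values, rep(0, 4), tolerance = 1e-12)
  # extended chain with 3.8 A steps
  n <- 12
  chainxyz <- cbind(3.8 * (seq_len(n) - 1), 0, 0)
  e <- end_to_end_series(ca_traj(list(chainxyz)))
  expect_equal(e$values, 3.8 * (n - 1), tolerance = 1e-12)
  e2 <- end_to_end_series(ca_traj(list(rbind(c(0, 0, 0), c(3.8, 0, 0)))))
  expect_equal(e2$values, 3.8)
  # collapsed conformer is shorter than the extended one
  set.seed(27)
  collapsed <- ca_traj(list(random_points(n, scale = 2)))
  expect_lt(end_to_end_series(collapsed)$values[1], e$values[1])
})

test_that("inter-domain decomposition is exact arithmetic, sign allowed", {
  expect_equal(decompose_interdomain(10, 10), 0)
  expect_equal(decompose_interdomain(10, 12), -2)
  set.seed(28)
  ov <- stats::setNames(rnorm(5, 50, 20), c("AB", "HI", "TM", "CS", "SI"))
  intra <- stats::setNames(rnorm(5, 2), names(ov))
  d <- decompose_domains(ov, intra)
  expect_identical(d$inter_diff, d$overall_diff - d$intra_diff)
  expect_error(decompose_interdomain(NA_real_, 1),
               class = "cardyn_numeric_error")
})

test_that("state comparison applies the equilibration cut and the holo-minus-apo sign", {
  apo <- new_metric_series("d", c(100, 100, 10, 20), "Å")
  holo <- new_metric_series("d", c(100, 100, 30, 50), "Å")
  cmp <- compare_states(apo, holo, equilibration_cut = 2)
  expect_equal(cmp$apo_mean, 15)
  expect_equal(cmp$holo_mean, 40)
  expect_equal(cmp$signed_diff, 25)
  expect_equal(cmp$abs_diff, 25)
  expect_equal(cmp$n_apo, 2)
  same <- compare_states(apo, apo)
  expect_equal(same$signed_diff, 0)
  expect_error(compare_states(apo, holo, equilibration_cut = 4),
               class = "cardyn_config_error")
})
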