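#' Preset simulation configuration for the apo or holo state
#'
#' The synthetic receptor is a coarse-grained coupled-pendulum model: one
#' antigen-binding (AB) blob bead atop a hinge (HI) linker, an anchored
#' transmembrane (TM) rod spanning a membrane slab, a costimulatory (CS)
#' linker and one signaling (SI) blob bead below. Bending stiffness of the
#' two linkers programs the state contrast: the apo preset has a soft HI
#' and stiff CS (wide extracellular AB sampling, narrow intracellular SI
#' sampling); the holo preset stiffens HI six-fold, softens CS six-fold
#' and adds an antigen (AG) bead bonded to AB and anchored to a fixed
#' extracellular site (the target-cell tether), reversing the contrast.
#' The six-fold stiffness ratio programs at least a four-fold
#' covariance-trace contrast in the AB and SI center clouds even after
#' finite-sampling noise at the default run length.
#'
#' Reduced units: kT = 1, friction gamma = 1, lengths Angstrom-like,
#' dt = 1e-3. The Euler-Maruyama stability bound
#' `dt * k_max / gamma < 0.1` is enforced with `k_max` the largest
#' effective curvature of the potential (4 k_bond for the bond network,
#' 16 k_bend for the bending terms, anchor and wall constants as given).
#'
#' @param state `"apo"` or `"holo"`.
#' @param seed integer PRNG seed (mandatory for a run; default 1).
#' @param n_steps,stride integration steps and frame-recording stride.
#' @param ... overrides for any config field (e.g. `k_bend_hi`, `kT`).
#' @return object of class `"SimulationConfig"`.
#' @export
preset_config <- function(state = c("apo", "holo"), seed = 1L,
                          n_steps = 2e6, stride = 1000L, ...) {
  if (!is.character(state) || !state[1] %in% c("apo", "holo"))
    stop_config("unknown state '%s' (must be \"apo\" or \"holo\")",
                as.character(state[1]))
  state <- state[1]
  cfg <- list(
    state = state,
    n_steps = as.integer(n_steps), stride = as.integer(stride),
    dt = 1e-3, gamma = 1, kT = 1, seed = as.integer(seed),
    spacing = 7.5, slab_halfwidth = 15,
    n_hi = 3L, n_tm = 5L, n_cs = 3L,
    k_bond = 15, k_anchor_tm = 40, k_wall = 10,
    k_bend_tm = 5,
    # six-fold bending contrasts between the states, so the programmed
    # >= 4-fold covariance-trace contrast survives finite-sampling noise
    k_bend_hi = if (state == "apo") 0.5 else 3.0,
    k_bend_cs = if (state == "apo") 4.8 else 0.8,
    k_anchor_ag = if (state == "apo") 0 else 2.0,
    membrane = TRUE, membrane_nx = 6L, membrane_ny = 6L,
    membrane_spacing = 8)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop_config("unknown config field(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg <- structure(cfg, class = "SimulationConfig")
  validate_sim_config(cfg)
  cfg
}

sim_k_max <- function(cfg) {
  max(4 * cfg$k_bond, cfg$k_anchor_tm, cfg$k_anchor_ag, cfg$k_wall,
      16 * max(cfg$k_bend_hi, cfg$k_bend_tm, cfg$k_bend_cs))
}

validate_sim_config <- function(cfg) {
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop_config("seed is mandatory")
  if (cfg$n_steps < cfg$stride)
    stop_config("n_steps (%d) < stride (%d): no frames would be written",
                cfg$n_steps, cfg$stride)
  bound <- cfg$dt * sim_k_max(cfg) / cfg$gamma
  if (bound >= 0.1)
    stop_config("stability bound violated: dt*k_max/gamma = %.3f >= 0.1", bound)
  invisible(cfg)
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf("SimulationConfig [%s]: %d steps, dt %g, stride %d, seed %d\n",
              x$state, x$n_steps, x$dt, x$stride, x$seed))
  cat(sprintf("  k_bend HI %.2f / CS %.2f, AG anchor %.2f\n",
              x$k_bend_hi, x$k_bend_cs, x$k_anchor_ag))
  invisible(x)
}

#' Build the bead-spring receptor topology from a configuration
#'
#' Deterministic layout along z: AB blob at the top, `n_hi` hinge beads,
#' `n_tm` transmembrane beads spanning `[-halfwidth, +halfwidth]` (each
#' harmonically anchored to its rest site), `n_cs` costimulatory beads and
#' one SI blob at the bottom; the holo state adds one AG bead above AB,
#' bonded to it and anchored extracellularly. Consecutive beads are bonded
#' at the rest spacing; every interior bead carries a bending (discrete
#' curvature) term whose stiffness is the softest among the three domains
#' the joint touches (so the membrane-exit joints flex like their
#' linkers); non-TM beads see a half-harmonic wall that keeps them out of
#' the membrane slab.
#'
#' @param config a [preset_config()] object.
#' @return object of class `"BeadTopology"`: list of `beads` (data.frame
#'   role/x/y/z), `bonds` (i, j, k, r0), `angles` (i, j, k, k_angle),
#'   `anchors` (i, sx, sy, sz, k), `walls` (i, side, z0, k), and
#'   `slab_halfwidth`.
#' @export
build_receptor_model <- function(config) {
  validate_sim_config(config)
  sp <- config$spacing; h <- config$slab_halfwidth
  if (abs((config$n_tm - 1) * sp - 2 * h) > 1e-9)
    stop_config("TM linker does not span the slab: (n_tm-1)*spacing = %.2f but slab thickness = %.2f",
                (config$n_tm - 1) * sp, 2 * h)
  roles <- c("AB", rep("HI", config$n_hi), rep("TM", config$n_tm),
             rep("CS", config$n_cs), "SI")
  n <- length(roles)
  z_top <- h + (config$n_hi + 1) * sp
  z <- z_top - sp * (seq_len(n) - 1)
  beads <- data.frame(role = roles, x = 0, y = 0, z = z,
                      stringsAsFactors = FALSE)
  holo <- config$state == "holo"
  if (holo)
    beads <- rbind(data.frame(role = "AG", x = 0, y = 0, z = z_top + sp,
                              stringsAsFactors = FALSE), beads)
  nb <- nrow(beads)
  chain <- seq_len(nb)  # AG (if present) -> AB -> ... -> SI, top to bottom
  bonds <- cbind(i = chain[-nb], j = chain[-1],
                 k = config$k_bond, r0 = sp)
  k_bend <- c(AG = config$k_bend_hi, AB = config$k_bend_hi,
              HI = config$k_bend_hi, TM = config$k_bend_tm,
              CS = config$k_bend_cs, SI = config$k_bend_cs)
  interior <- chain[-c(1, nb)]
  # a joint bends like the softest of the three domains it touches, so a
  # membrane-exit joint flexes like its linker, not like the TM rod
  angles <- cbind(i = interior - 1L, j = interior, k = interior + 1L,
                  k_angle = vapply(interior, function(j)
                    min(k_bend[beads$role[(j - 1L):(j + 1L)]]), numeric(1)))
  tm <- which(beads$role == "TM")
  anchors <- cbind(i = tm, sx = beads$x[tm], sy = beads$y[tm],
                   sz = beads$z[tm], k = config$k_anchor_tm)
  if (holo) {
    ag <- which(beads$role == "AG")
    anchors <- rbind(anchors,
                     c(ag, beads$x[ag], beads$y[ag], beads$z[ag],
                       config$k_anchor_ag))
  }
  extra <- which(beads$role %in% c("AG", "AB", "HI"))
  intra <- which(beads$role %in% c("CS", "SI"))
  walls <- rbind(cbind(i = extra, side = 1, z0 = h, k = config$k_wall),
                 cbind(i = intra, side = -1, z0 = -h, k = config$k_wall))
  structure(list(beads = beads, bonds = bonds, angles = angles,
                 anchors = anchors, walls = walls,
                 slab_halfwidth = h),
            class = "BeadTopology")
}

#' Run the overdamped Langevin simulation of a bead topology
#'
#' Euler-Maruyama integration of
#' `x <- x + (dt/gamma) F(x) + sqrt(2 kT dt/gamma) eta` from the rest
#' configuration, with frames written every `stride` steps. Beads are
#' emitted as one `CA` pseudo-atom each: receptor beads on chain A with
#' sequential residue ids, the AG bead (holo) on chain B, and -- when
#' `config$membrane` is set -- a static HETATM lattice of membrane
#' pseudo-atoms at the slab faces. Identical seed and config reproduce the
#' trajectory exactly.
#'
#' @param topology a [build_receptor_model()] object.
#' @param config the matching [preset_config()] object.
#' @return a [new_trajectory()] object; its matching [domain_map()] is
#'   available from [simulated_domain_map()].
#' @export
simulate_receptor_trajectory <- function(topology, config) {
  validate_sim_config(config)
  x0 <- as.matrix(topology$beads[, c("x", "y", "z")])
  set.seed(config$seed)
  frames <- simulate_langevin_cpp(x0, topology$bonds, topology$angles,
                                  topology$anchors, topology$walls,
                                  config$dt, config$gamma, config$kT,
                                  as.integer(config$n_steps),
                                  as.integer(config$stride))
  nb <- nrow(topology$beads)
  nf <- nrow(frames)
  is_ag <- topology$beads$role == "AG"
  atoms <- data.frame(
    serial = seq_len(nb),
    name = "CA", elem = "C", resname = "ALA",
    resid = ifelse(is_ag, 1L, cumsum(!is_ag)),
    chain = ifelse(is_ag, "B", "A"),
    het = FALSE, stringsAsFactors = FALSE)
  xyz <- array(0, dim = c(nb, 3L, nf))
  for (m in seq_len(nf))
    xyz[, , m] <- matrix(frames[m, ], nb, 3, byrow = TRUE)
  if (isTRUE(config$membrane)) {
    slab <- membrane_lattice(config$membrane_nx, config$membrane_ny,
                             config$membrane_spacing,
                             config$slab_halfwidth)
    slab$atoms$serial <- nb + seq_len(nrow(slab$atoms))
    atoms <- rbind(atoms, slab$atoms)
    xyz2 <- array(0, dim = c(nrow(atoms), 3L, nf))
    xyz2[seq_len(nb), , ] <- xyz
    for (m in seq_len(nf)) xyz2[nb + seq_len(nrow(slab$xyz)), , m] <- slab$xyz
    xyz <- xyz2
  }
  new_trajectory(atoms, xyz)
}

#' Convenience wrapper: preset config -> topology -> trajectory
#' @inheritParams preset_config
#' @return a [new_trajectory()] object.
#' @export
simulate_receptor <- function(state = c("apo", "holo"), seed = 1L, ...) {
  cfg <- preset_config(state, seed = seed, ...)
  simulate_receptor_trajectory(build_receptor_model(cfg), cfg)
}

#' Domain map matching a simulated receptor trajectory
#' @param config the [preset_config()] used for the simulation.
#' @return a [domain_map()] with bead residue ranges; the SI bead doubles
#'   as the `ITAM_TYR` group so contact/burial stages run on synthetic
#'   data.
#' @export
simulated_domain_map <- function(config) {
  n_hi <- config$n_hi; n_tm <- config$n_tm; n_cs <- config$n_cs
  e_hi <- 1L + n_hi; e_tm <- e_hi + n_tm; e_cs <- e_tm + n_cs
  doms <- list(AB = c(1, 1), HI = c(2, e_hi), TM = c(e_hi + 1, e_tm),
               CS = c(e_tm + 1, e_cs), SI = c(e_cs + 1, e_cs + 1))
  if (config$state == "holo")
    doms$AG <- list(chain = "B", start = 1, end = 1)
  domain_map(doms,
             groups = list(ITAM_TYR = data.frame(chain = "A",
                                                 resid = e_cs + 1L)),
             membrane_resname = "MEM",
             membrane_slab_halfwidth = config$slab_halfwidth)
}

# HETATM pseudo-lipid lattice at z = +/- halfwidth (plus optional interior
# planes); shared by simulate_receptor_trajectory and make_fixture.
membrane_lattice <- function(nx, ny, spacing, halfwidth,
                             interior_planes = numeric(0)) {
  gx <- (seq_len(nx) - (nx + 1) / 2) * spacing
  gy <- (seq_len(ny) - (ny + 1) / 2) * spacing
  zs <- c(halfwidth, -halfwidth, interior_planes)
  grid <- expand.grid(x = gx, y = gy, z = zs)
  n <- nrow(grid)
  atoms <- data.frame(serial = seq_len(n), name = "P", elem = "P",
                      resname = "MEM", resid = seq_len(n), chain = "M",
                      het = TRUE, stringsAsFactors = FALSE)
  list(atoms = atoms, xyz = as.matrix(grid))
}

#' Build a deterministic test fixture
#'
#' Kinds:
#' * `helix` / `strand`: ideal N/CA/C backbone built at exactly the
#'   requested `(phi, psi)` (defaults -57/-47 and -139/135) with canonical
#'   bond lengths and angles; single frame.
#' * `rigid_copies`: a base structure plus `n_frames - 1` copies obtained
#'   by applying `rotation`/`translation` cumulatively, with optional
#'   per-frame Gaussian coordinate noise `sigma` (seeded).
#' * `membrane_slab`: HETATM lattice of `nx * ny` pseudo-lipid atoms on the
#'   `z = +/- halfwidth` planes plus configurable `interior_planes`.
#'
#' @param kind one of `"helix"`, `"strand"`, `"rigid_copies"`,
#'   `"membrane_slab"`.
#' @param n_res number of residues (helix/strand; >= 3).
#' @param phi,psi backbone dihedrals, degrees.
#' @param base a `Trajectory` or `Frame` (rigid_copies).
#' @param n_frames number of frames (rigid_copies).
#' @param rotation 3x3 rotation matrix applied per step (rigid_copies).
#' @param translation length-3 vector applied per step (rigid_copies).
#' @param sigma Gaussian noise sd, Angstrom (rigid_copies).
#' @param seed PRNG seed when `sigma > 0`.
#' @param nx,ny,spacing,halfwidth,interior_planes lattice parameters
#'   (membrane_slab).
#' @return a [new_trajectory()] object (single frame for the static kinds).
#' @export
make_fixture <- function(kind = c("helix", "strand", "rigid_copies",
                                  "membrane_slab"),
                         n_res = 12L, phi = NULL, psi = NULL,
                         base = NULL, n_frames = 2L,
                         rotation = diag(3), translation = c(0, 0, 0),
                         sigma = 0, seed = 1L,
                         nx = 10L, ny = 10L, spacing = 8,
                         halfwidth = 15, interior_planes = numeric(0)) {
  kind <- match.arg(kind)
  if (kind %in% c("helix", "strand")) {
    if (n_res < 3L) stop_config("helix/strand fixture needs n_res >= 3")
    if (is.null(phi)) phi <- if (kind == "helix") -57 else -139
    if (is.null(psi)) psi <- if (kind == "helix") -47 else 135
    return(build_backbone(n_res, phi, psi))
  }
  if (kind == "rigid_copies") {
    if (is.null(base)) stop_config("rigid_copies fixture needs a base structure")
    atoms <- if (inherits(base, "Trajectory")) base$atoms else base$atoms
    xyz0 <- if (inherits(base, "Trajectory")) frame_xyz(base, 1L) else base$xyz
    nf <- as.integer(n_frames)
    out <- array(0, dim = c(nrow(xyz0), 3L, nf))
    cur <- xyz0
    if (sigma > 0) set.seed(seed)
    for (m in seq_len(nf)) {
      frame <- cur
      if (sigma > 0)
        frame <- frame + matrix(stats::rnorm(length(frame), sd = sigma),
                                nrow(frame), 3)
      out[, , m] <- frame
      cur <- cur %*% rotation +
        matrix(translation, nrow(cur), 3, byrow = TRUE)
    }
    return(new_trajectory(atoms, out))
  }
  # membrane_slab
  slab <- membrane_lattice(nx, ny, spacing, halfwidth, interior_planes)
  new_trajectory(slab$atoms, array(slab$xyz, dim = c(nrow(slab$xyz), 3L, 1L)))
}

# Sequential chain construction (natural extension reference frame):
# place each atom from the previous three at given bond length, bond
# angle and torsion. Canonical backbone geometry, omega fixed at 180.
build_backbone <- function(n_res, phi, psi) {
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.0; a_cacn <- 116.2; a_cnca <- 121.7
  coords <- matrix(0, 3L * n_res, 3)
  # first residue in the xy-plane
  coords[1, ] <- c(0, 0, 0)                          # N1
  coords[2, ] <- c(b_nca, 0, 0)                      # CA1
  th <- a_ncac * pi / 180
  coords[3, ] <- coords[2, ] + b_cac * c(-cos(th), sin(th), 0)  # C1
  k <- 3L
  for (i in 2:n_res) {
    coords[k + 1, ] <- place_nerf(coords[k - 2, ], coords[k - 1, ],
                                  coords[k, ], b_cn, a_cacn, psi[i - 1]) # N_i
    coords[k + 2, ] <- place_nerf(coords[k - 1, ], coords[k, ],
                                  coords[k + 1, ], b_nca, a_cnca, 180)  # CA_i
    coords[k + 3, ] <- place_nerf(coords[k, ], coords[k + 1, ],
                                  coords[k + 2, ], b_cac, a_ncac, phi[i]) # C_i
    k <- k + 3L
  }
  atoms <- data.frame(
    serial = seq_len(3L * n_res),
    name = rep(c("N", "CA", "C"), n_res),
    elem = rep(c("N", "C", "C"), n_res),
    resname = "ALA",
    resid = rep(seq_len(n_res), each = 3L),
    chain = "A", het = FALSE, stringsAsFactors = FALSE)
  new_trajectory(atoms, array(coords, dim = c(3L * n_res, 3L, 1L)))
}

place_nerf <- function(p1, p2, p3, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  chi <- torsion_deg * pi / 180
  bc <- p3 - p2; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(p2 - p1, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- c(-bond * cos(th), bond * sin(th) * cos(chi),
         bond * sin(th) * sin(chi))
  p3 + bc * d[1] + m * d[2] + n * d[3]
}
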