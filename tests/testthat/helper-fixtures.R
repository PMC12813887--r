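# Shared fixture builders; everything is generated in code at test time.

# full-length construct numbering: five domains on one chain
toy_map <- function() {
  domain_map(list(AB = c(1, 250), HI = c(251, 295), TM = c(296, 320),
                  CS = c(321, 362), SI = c(363, 475)))
}

# minimal bead receptor: 1 AB, 1 HI, 3 TM, 1 CS, 1 SI residue (CA only)
bead_map <- function() {
  domain_map(list(AB = c(1, 1), HI = c(2, 2), TM = c(3, 5),
                  CS = c(6, 6), SI = c(7, 7)))
}

# CA-only trajectory from a list of n x 3 coordinate matrices
ca_traj <- function(frames, resid = NULL, chain = "A", het = FALSE,
                    name = "CA", elem = "C", resname = "ALA") {
  n <- nrow(frames[[1]])
  if (is.null(resid)) resid <- seq_len(n)
  atoms <- data.frame(serial = seq_len(n), name = name, elem = elem,
                      resname = resname, resid = resid, chain = chain,
                      het = het, stringsAsFactors = FALSE)
  xyz <- array(0, dim = c(n, 3, length(frames)))
  for (m in seq_along(frames)) xyz[, , m] <- frames[[m]]
  new_trajectory(atoms, xyz)
}

# bead-receptor geometry matching bead_map(): TM triangle near origin,
# AB above, SI below
bead_frame <- function() {
  rbind(c(0, 0, 40),    # AB
        c(0, 0, 25),    # HI
        c(0, 0, 10), c(2, 0, 0), c(0, 0, -10),   # TM (non-collinear)
        c(0, 0, -25),   # CS
        c(0, 0, -40))   # SI
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# a well-conditioned random point set
random_points <- function(n, scale = 5) matrix(stats::rnorm(n * 3, sd = scale), n, 3)
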