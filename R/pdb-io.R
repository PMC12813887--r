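#' Read a multi-model PDB file as a trajectory
#'
#' MODEL/ENDMDL blocks become frames; a file without MODEL records is read as
#' a single frame. ATOM and HETATM records are parsed by fixed columns;
#' HETATM atoms (membrane/pseudo-atoms) are kept with `het = TRUE`. All
#' models must contain the same atoms in the same order. Where alternate
#' locations are present the first one wins.
#'
#' @param path path to a PDB file.
#' @return a [new_trajectory()] object.
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop_data("PDB file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_starts <- which(startsWith(lines, "MODEL"))

  if (length(model_starts) == 0L) {
    blocks <- list(which(is_atom))
    model_ids <- 1L
  } else {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) != length(model_starts))
      stop_data("unbalanced MODEL/ENDMDL records in %s", path)
    blocks <- mapply(function(s, e) {
      idx <- s:e
      idx[is_atom[idx]]
    }, model_starts, model_ends, SIMPLIFY = FALSE)
    model_ids <- suppressWarnings(as.integer(substr(lines[model_starts], 7, 14)))
    model_ids[is.na(model_ids)] <- seq_along(model_starts)[is.na(model_ids)]
  }
  if (length(blocks[[1]]) == 0L) stop_data("no ATOM/HETATM records in %s", path)

  parse_block <- function(idx, model_id) {
    ln <- lines[idx]
    altloc <- substr(ln, 17, 17)
    x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
    resid <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) | is.na(resid))
    if (length(bad))
      stop_data("unparsable ATOM/HETATM record at line %d of %s",
                idx[bad[1]], path)
    name <- trimws(substr(ln, 13, 16))
    elem <- trimws(substr(ln, 77, 78))
    guess <- toupper(substr(gsub("[^A-Za-z].*", "",
                                 sub("^[0-9]*", "", name)), 1, 1))
    elem <- ifelse(elem == "", guess, elem)
    df <- data.frame(
      serial = suppressWarnings(as.integer(substr(ln, 7, 11))),
      name = name,
      elem = elem,
      resname = trimws(substr(ln, 18, 20)),
      resid = resid,
      chain = substr(ln, 22, 22),
      het = substr(ln, 1, 6) == "HETATM",
      x = x, y = y, z = z,
      altloc = altloc,
      stringsAsFactors = FALSE)
    # first altloc wins
    key <- paste(df$chain, df$resid, df$name)
    df <- df[!duplicated(key), , drop = FALSE]
    df
  }

  first <- parse_block(blocks[[1]], model_ids[1])
  nat <- nrow(first)
  xyz <- array(NA_real_, dim = c(nat, 3L, length(blocks)))
  xyz[, , 1] <- as.matrix(first[, c("x", "y", "z")])
  if (length(blocks) > 1L) {
    sig1 <- paste(first$chain, first$resid, first$name)
    for (m in seq_along(blocks)[-1]) {
      b <- parse_block(blocks[[m]], model_ids[m])
      if (nrow(b) != nat ||
          !identical(paste(b$chain, b$resid, b$name), sig1))
        stop_data("MODEL %d of %s has different atoms than MODEL %d (%d vs %d)",
                  model_ids[m], path, model_ids[1], nrow(b), nat)
      xyz[, , m] <- as.matrix(b[, c("x", "y", "z")])
    }
  }
  atoms <- first[, c("serial", "name", "elem", "resname", "resid",
                     "chain", "het")]
  rownames(atoms) <- NULL
  new_trajectory(atoms, xyz)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Emits the standard dialect: `MODEL n` / `ATOM` / `HETATM` / `ENDMDL` /
#' `END`, coordinates `%8.3f`, occupancy 1.00, B-factor 0.00.
#'
#' @param traj a [new_trajectory()] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "Trajectory"))
  if (any(traj$xyz >= 1e4 | traj$xyz <= -1e3))
    stop_data("coordinate magnitude overflows the fixed-width PDB columns (|x| >= 10000 or x <= -1000)")
  at <- traj$atoms
  rectype <- ifelse(at$het, "HETATM", "ATOM  ")
  # atom names of up to 3 characters start in column 14 (PDB convention)
  name_fmt <- ifelse(nchar(at$name) <= 3L,
                     sprintf(" %-3s", at$name), sprintf("%-4s", at$name))
  pre <- sprintf("%s%5d %s %-3s %1s%4d    ",
                 rectype, at$serial %% 100000L, name_fmt, at$resname,
                 at$chain, at$resid %% 10000L)
  post <- sprintf("  1.00  0.00          %2s", at$elem)
  nf <- n_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(nf)) {
    xyz <- traj$xyz[, , m, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    coords <- sprintf("%8.3f%8.3f%8.3f", xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(paste0(pre, coords, post), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
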