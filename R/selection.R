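#' Select atoms by domain, group, residue ranges, or membrane
#'
#' Resolves a selection against the trajectory topology and a domain map.
#' Hydrogens are excluded by default (all analyses here are heavy-atom or
#' C-alpha quantities). The result is deterministic and ordered by topology
#' index; an empty selection is an error, never a silent empty result.
#'
#' @param traj a [new_trajectory()] object.
#' @param map a [domain_map()] object (may be `NULL` when `spec` is a
#'   data.frame of ranges).
#' @param spec a domain name (`"AB"`, ..., `"SI"`, `"AG"`), a group name
#'   (`"PBR1"`, ..., `"ITAM_TYR"`), the keyword `"membrane"`, the keyword
#'   `"receptor"` (all non-HETATM atoms), or a data.frame with columns
#'   `chain`, `start`, `end`.
#' @param atom_names optional atom-name filter, e.g. `"CA"`.
#' @param include_hydrogens keep hydrogen atoms (default FALSE).
#' @return object of class `"AtomSelection"`: list with strictly increasing
#'   `indices` into the topology and a `label`.
#' @export
select_atoms <- function(traj, map = NULL, spec, atom_names = NULL,
                         include_hydrogens = FALSE) {
  at <- traj$atoms
  keep <- rep(TRUE, nrow(at))
  label <- NULL

  if (is.data.frame(spec)) {
    keep <- keep & resolve_ranges(at, spec)
    label <- "ranges"
  } else if (is.character(spec) && length(spec) == 1L) {
    if (spec == "membrane") {
      if (is.null(map)) stop_config("membrane selection needs a domain map")
      keep <- keep & at$het & at$resname == map$membrane_resname
    } else if (spec == "receptor") {
      keep <- keep & !at$het
    } else if (!is.null(map) && spec %in% names(map$domains)) {
      keep <- keep & !at$het & resolve_ranges(at, map$domains[[spec]])
    } else if (!is.null(map) && spec %in% names(map$groups)) {
      g <- map$groups[[spec]]
      keep <- keep & !at$het &
        (paste(at$chain, at$resid) %in% paste(g$chain, g$resid))
    } else {
      stop_config("selection '%s' is not a domain, group, or keyword known to the domain map",
                  spec)
    }
    label <- spec
  } else {
    stop_config("selection spec must be a name or a data.frame of ranges")
  }

  if (!include_hydrogens) keep <- keep & !(at$elem %in% c("H", "D"))
  if (!is.null(atom_names)) keep <- keep & at$name %in% atom_names
  idx <- which(keep)
  if (length(idx) == 0L)
    stop_data("selection '%s'%s matches no atoms", label,
              if (is.null(atom_names)) ""
              else sprintf(" (atom names %s)", paste(atom_names, collapse = ",")))
  structure(list(indices = idx,
                 label = if (is.null(atom_names)) label
                         else paste0(label, ":", paste(atom_names, collapse = ","))),
            class = "AtomSelection")
}

resolve_ranges <- function(at, ranges) {
  keep <- rep(FALSE, nrow(at))
  for (i in seq_len(nrow(ranges)))
    keep <- keep | (at$chain == ranges$chain[i] &
                    at$resid >= ranges$start[i] & at$resid <= ranges$end[i])
  keep
}

#' @export
print.AtomSelection <- function(x, ...) {
  cat(sprintf("AtomSelection '%s': %d atoms\n", x$label, length(x$indices)))
  invisible(x)
}

# indices of the C-alpha atoms of a selection, in topology order
ca_indices <- function(traj, sel) {
  idx <- sel$indices[traj$atoms$name[sel$indices] == "CA"]
  if (length(idx) == 0L)
    stop_data("selection '%s' contains no CA atoms", sel$label)
  idx
}
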