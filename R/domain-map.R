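DOMAIN_NAMES <- c("AB", "HI", "TM", "CS", "SI", "AG")
REQUIRED_DOMAINS <- c("AB", "HI", "TM", "CS", "SI")
GROUP_NAMES <- c("PBR1", "PBR2", "PBR3", "ITAM1", "ITAM2", "ITAM3", "ITAM_TYR")
# CD3zeta polybasic regions in construct numbering
DEFAULT_PBR <- list(PBR1 = 395:399, PBR2 = 406:410, PBR3 = 435:442)

#' Construct a domain map
#'
#' A domain map names the residue ranges of the five receptor domains --
#' antigen-binding (AB), hinge (HI), transmembrane (TM), costimulatory (CS)
#' and signaling (SI), optionally the bound antigen (AG) -- plus residue
#' groups (the three CD3zeta polybasic regions, the ITAMs and their
#' tyrosines) and the membrane atom convention. Every selection downstream
#' is driven by it.
#'
#' If the polybasic-region groups are not given and the SI range covers the
#' construct numbering 395-442, they default to PBR1 395-399, PBR2 406-410,
#' PBR3 435-442.
#'
#' @param domains named list; each element either `c(start, end)` (chain
#'   `"A"` assumed), `list(chain=, start=, end=)`, or a data.frame with
#'   columns `chain`, `start`, `end` (several ranges allowed). Must contain
#'   AB, HI, TM, CS, SI; AG is optional.
#' @param groups named list of residue groups; each element an integer
#'   vector of residue ids (chain of the enclosing domain assumed, `"A"`
#'   otherwise) or a data.frame with columns `chain`, `resid`. Allowed
#'   names: PBR1, PBR2, PBR3, ITAM1, ITAM2, ITAM3, ITAM_TYR.
#' @param membrane_resname HETATM residue code identifying membrane atoms
#'   (real lipid or synthetic slab pseudo-atoms).
#' @param membrane_slab_halfwidth half-thickness of the membrane slab,
#'   Angstrom; the slab is centered at z = 0 in the TM-aligned frame.
#' @return object of class `"DomainMap"`.
#' @export
domain_map <- function(domains, groups = list(),
                       membrane_resname = "MEM",
                       membrane_slab_halfwidth = 15) {
  norm_range <- function(d, nm) {
    if (is.data.frame(d)) {
      if (!all(c("chain", "start", "end") %in% names(d)))
        stop_config("domain '%s': range data.frame needs chain/start/end", nm)
      return(data.frame(chain = as.character(d$chain),
                        start = as.integer(d$start), end = as.integer(d$end),
                        stringsAsFactors = FALSE))
    }
    if (is.list(d)) {
      ch <- if (is.null(d$chain)) "A" else as.character(d$chain)
      return(data.frame(chain = ch, start = as.integer(d$start),
                        end = as.integer(d$end), stringsAsFactors = FALSE))
    }
    if (is.numeric(d) && length(d) == 2L)
      return(data.frame(chain = "A", start = as.integer(d[1]),
                        end = as.integer(d[2]), stringsAsFactors = FALSE))
    stop_config("domain '%s': cannot interpret range specification", nm)
  }
  if (is.null(names(domains)) || any(names(domains) == ""))
    stop_config("domains must be a named list")
  unknown <- setdiff(names(domains), DOMAIN_NAMES)
  if (length(unknown))
    stop_config("unknown domain name(s): %s", paste(unknown, collapse = ", "))
  missing <- setdiff(REQUIRED_DOMAINS, names(domains))
  if (length(missing))
    stop_config("missing required domain(s): %s", paste(missing, collapse = ", "))
  domains <- lapply(stats::setNames(names(domains), names(domains)),
                    function(nm) norm_range(domains[[nm]], nm))
  for (nm in names(domains))
    if (any(domains[[nm]]$end < domains[[nm]]$start))
      stop_config("domain '%s': end < start", nm)

  # pairwise overlap check on the same chain
  flat <- do.call(rbind, lapply(names(domains), function(nm)
    cbind(domains[[nm]], domain = nm)))
  for (i in seq_len(nrow(flat))) for (j in seq_len(nrow(flat))) {
    if (i < j && flat$chain[i] == flat$chain[j] &&
        flat$start[i] <= flat$end[j] && flat$start[j] <= flat$end[i] &&
        flat$domain[i] != flat$domain[j])
      stop_config("domain ranges overlap: %s %d-%d collides with %s %d-%d (chain %s)",
                  flat$domain[i], flat$start[i], flat$end[i],
                  flat$domain[j], flat$start[j], flat$end[j], flat$chain[i])
  }

  si_chain <- domains$SI$chain[1]
  unknown_g <- setdiff(names(groups), GROUP_NAMES)
  if (length(unknown_g))
    stop_config("unknown group name(s): %s", paste(unknown_g, collapse = ", "))
  norm_group <- function(g, nm) {
    if (is.data.frame(g)) {
      if (!all(c("chain", "resid") %in% names(g)))
        stop_config("group '%s': data.frame needs chain/resid", nm)
      return(data.frame(chain = as.character(g$chain),
                        resid = as.integer(g$resid), stringsAsFactors = FALSE))
    }
    data.frame(chain = si_chain, resid = as.integer(g),
               stringsAsFactors = FALSE)
  }
  groups <- lapply(stats::setNames(names(groups), names(groups)),
                   function(nm) norm_group(groups[[nm]], nm))
  # default PBRs when SI numbering covers them
  si <- domains$SI
  covers <- function(res) any(si$start <= min(res) & si$end >= max(res))
  for (nm in names(DEFAULT_PBR)) {
    if (is.null(groups[[nm]]) && covers(DEFAULT_PBR[[nm]]))
      groups[[nm]] <- data.frame(chain = si_chain, resid = DEFAULT_PBR[[nm]],
                                 stringsAsFactors = FALSE)
  }

  structure(list(domains = domains, groups = groups,
                 membrane_resname = as.character(membrane_resname),
                 membrane_slab_halfwidth = as.numeric(membrane_slab_halfwidth)),
            class = "DomainMap")
}

#' Load a domain map from a YAML configuration file
#'
#' Schema (unknown keys are rejected):
#' \preformatted{
#' domains:
#'   AB: {chain: A, start: 1, end: 250}   # or a list of such ranges
#'   HI: {start: 251, end: 295}           # chain defaults to A
#'   ...
#' groups:                                # optional
#'   PBR1: {chain: A, start: 395, end: 399}
#'   ITAM_TYR: {chain: A, residues: [371, 382, 400, 411, 431, 443]}
#' membrane:                              # optional
#'   resname: MEM
#'   slab_halfwidth: 15.0
#' }
#'
#' @param path path to the YAML file.
#' @return a [domain_map()] object.
#' @export
load_domain_map <- function(path) {
  if (!file.exists(path)) stop_config("domain map file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("domains", "groups", "membrane"))
  if (length(unknown))
    stop_config("unknown key(s) in domain map config: %s",
                paste(unknown, collapse = ", "))
  if (is.null(cfg$domains)) stop_config("domain map config has no 'domains' key")
  parse_ranges <- function(d, nm) {
    if (!is.null(d$start)) d <- list(d)
    do.call(rbind, lapply(d, function(r) {
      extra <- setdiff(names(r), c("chain", "start", "end"))
      if (length(extra))
        stop_config("domain '%s': unknown key(s) %s", nm,
                    paste(extra, collapse = ", "))
      data.frame(chain = if (is.null(r$chain)) "A" else as.character(r$chain),
                 start = as.integer(r$start), end = as.integer(r$end),
                 stringsAsFactors = FALSE)
    }))
  }
  domains <- lapply(stats::setNames(names(cfg$domains), names(cfg$domains)),
                    function(nm) parse_ranges(cfg$domains[[nm]], nm))
  groups <- list()
  for (nm in names(cfg$groups)) {
    g <- cfg$groups[[nm]]
    extra <- setdiff(names(g), c("chain", "start", "end", "residues"))
    if (length(extra))
      stop_config("group '%s': unknown key(s) %s", nm,
                  paste(extra, collapse = ", "))
    res <- if (!is.null(g$residues)) as.integer(unlist(g$residues))
           else seq.int(as.integer(g$start), as.integer(g$end))
    ch <- if (is.null(g$chain)) "A" else as.character(g$chain)
    groups[[nm]] <- data.frame(chain = ch, resid = res,
                               stringsAsFactors = FALSE)
  }
  mem <- cfg$membrane
  if (!is.null(mem)) {
    extra <- setdiff(names(mem), c("resname", "slab_halfwidth"))
    if (length(extra))
      stop_config("membrane: unknown key(s) %s", paste(extra, collapse = ", "))
  }
  domain_map(domains, groups,
             membrane_resname = if (is.null(mem$resname)) "MEM" else mem$resname,
             membrane_slab_halfwidth =
               if (is.null(mem$slab_halfwidth)) 15 else mem$slab_halfwidth)
}

#' Write a domain map to a YAML file
#' @param map a [domain_map()] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_domain_map <- function(map, path) {
  stopifnot(inherits(map, "DomainMap"))
  dom <- lapply(map$domains, function(d) {
    rs <- lapply(seq_len(nrow(d)), function(i)
      list(chain = d$chain[i], start = d$start[i], end = d$end[i]))
    if (length(rs) == 1L) rs[[1]] else rs
  })
  grp <- lapply(map$groups, function(g)
    list(chain = g$chain[1], residues = as.list(g$resid)))
  out <- list(domains = dom,
              membrane = list(resname = map$membrane_resname,
                              slab_halfwidth = map$membrane_slab_halfwidth))
  if (length(grp)) out$groups <- grp
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.DomainMap <- function(x, ...) {
  cat("DomainMap:\n")
  for (nm in names(x$domains)) {
    d <- x$domains[[nm]]
    cat(sprintf("  %-3s %s\n", nm,
                paste(sprintf("%s:%d-%d", d$chain, d$start, d$end),
                      collapse = ", ")))
  }
  if (length(x$groups))
    cat("  groups:", paste(names(x$groups), collapse = ", "), "\n")
  cat(sprintf("  membrane: resname %s, slab halfwidth %.1f Å\n",
              x$membrane_resname, x$membrane_slab_halfwidth))
  invisible(x)
}
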