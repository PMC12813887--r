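#' Run the full single-trajectory analysis and write a result bundle
#'
#' Executes the analysis stages on one trajectory and writes every series
#' as TSV plus a single machine-readable `summary.json` to `out_dir`.
#' Outputs are deterministic for fixed inputs (no timestamps); progress is
#' logged to stderr.
#'
#' Stages (toggle via `stages`):
#' * `geometry`: receptor and per-domain fit-to-TM ("overall") and
#'   fit-to-self ("intra") Ca-RMSD series, Ca-RMSF profile, radii of
#'   gyration (receptor, extracellular AB+HI, intracellular CS+SI),
#'   AB-TM and SI-TM center distances, end-to-end distance.
#' * `cloud`: AB/CS/SI domain-center clouds in the TM-aligned frame and
#'   their sampling summaries.
#' * `contacts`: membrane contact counts per configured residue group and
#'   the burial-depth series of the ITAM tyrosines (needs membrane atoms).
#' * `sse`: per-domain secondary-structure fractions (needs N/CA/C
#'   backbones; written as unavailable for C-alpha-only models).
#' * `cluster`: leader clustering of receptor C-alpha conformations.
#' * `network`: correlation network and community detection.
#'
#' @param trajectory a `Trajectory` or a multi-model PDB path.
#' @param map a [domain_map()] or a YAML domain-map path.
#' @param out_dir output directory (created if needed).
#' @param fit_domain domain used for superposition (default `"TM"`).
#' @param equil_cut 0-based frame index where averaging starts.
#' @param contact_cutoff membrane contact cutoff, Angstrom (default 2.5).
#' @param cluster_cutoff clustering RMSD cutoff, Angstrom (default 2.5).
#' @param network_contact_cutoff,network_occupancy network edge rule
#'   (defaults 4.5 Angstrom, 0.75).
#' @param stages character vector of stage names to run.
#' @param reference optional reference structure (default frame 1).
#' @return invisibly, the summary list that was written as JSON.
#' @export
run_analyze <- function(trajectory, map, out_dir,
                        fit_domain = "TM", equil_cut = 0L,
                        contact_cutoff = 2.5, cluster_cutoff = 2.5,
                        network_contact_cutoff = 4.5,
                        network_occupancy = 0.75,
                        stages = c("geometry", "cloud", "contacts",
                                   "sse", "cluster", "network"),
                        reference = NULL) {
  if (contact_cutoff <= 0 || cluster_cutoff <= 0 || network_contact_cutoff <= 0)
    stop_config("cutoffs must be > 0")
  if (is.character(trajectory)) {
    if (!file.exists(trajectory))
      stop_data("trajectory file not found: %s", trajectory)
    trajectory <- read_multimodel_pdb(trajectory)
  }
  if (is.character(map)) map <- load_domain_map(map)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- list(fit_domain = fit_domain, equil_cut = as.integer(equil_cut),
              contact_cutoff = contact_cutoff,
              cluster_cutoff = cluster_cutoff,
              network_contact_cutoff = network_contact_cutoff,
              network_occupancy = network_occupancy,
              stages = as.list(stages))
  summary <- list(
    provenance = list(package = "cardyn",
                      version = as.character(utils::packageVersion("cardyn")),
                      config = cfg, config_hash = config_hash(deparse(cfg)),
                      n_frames = n_frames(trajectory),
                      n_atoms = n_atoms(trajectory)),
    domains = lapply(map$domains, function(d)
      lapply(seq_len(nrow(d)), function(i)
        list(chain = d$chain[i], start = d$start[i], end = d$end[i]))))

  fit_sel <- select_atoms(trajectory, map, fit_domain, atom_names = "CA")
  receptor_ranges <- do.call(rbind, map$domains[intersect(
    names(map$domains), REQUIRED_DOMAINS)])
  rec_sel <- select_atoms(trajectory, map, receptor_ranges,
                          atom_names = "CA")
  rec_sel$label <- "receptor"
  cut <- as.integer(equil_cut)
  stat <- function(ms) {
    v <- ms$values
    if (cut >= length(v)) stop_config("equilibration cut >= series length")
    v <- v[(cut + 1L):length(v)]
    list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
         n_frames = length(v), cut = cut, units = ms$units,
         fit = ms$fit, measure = ms$measure)
  }
  emit <- function(ms, file) {
    utils::write.table(as.data.frame(ms), file.path(out_dir, file),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    stat(ms)
  }
  banner <- function(s) message(sprintf("[cardyn] stage: %s", s))
  doms <- intersect(names(map$domains), REQUIRED_DOMAINS)

  if ("geometry" %in% stages) {
    banner("geometry")
    series <- list()
    series$rmsd_overall_receptor <-
      emit(rmsd_series(trajectory, fit_sel, rec_sel, reference),
           "rmsd_overall_receptor.tsv")
    for (d in doms) {
      dsel <- select_atoms(trajectory, map, d, atom_names = "CA")
      series[[paste0("rmsd_overall_", d)]] <-
        emit(rmsd_series(trajectory, fit_sel, dsel, reference),
             sprintf("rmsd_overall_%s.tsv", d))
      # a 1- or 2-point domain superposes onto itself exactly: its
      # fit-to-self (intra-domain) deformation is identically zero
      intra <- if (length(dsel$indices) < 3L)
        new_metric_series(sprintf("rmsd[%s|fit %s]", d, d),
                          rep(0, n_frames(trajectory)), "Å", d, d)
      else rmsd_series(trajectory, dsel, dsel, reference)
      series[[paste0("rmsd_intra_", d)]] <-
        emit(intra, sprintf("rmsd_intra_%s.tsv", d))
    }
    rgyr_groups <- list(receptor = rec_sel)
    rgyr_groups$extracellular <- select_atoms(
      trajectory, map, do.call(rbind, map$domains[c("AB", "HI")]),
      atom_names = "CA")
    rgyr_groups$extracellular$label <- "AB+HI"
    rgyr_groups$intracellular <- select_atoms(
      trajectory, map, do.call(rbind, map$domains[c("CS", "SI")]),
      atom_names = "CA")
    rgyr_groups$intracellular$label <- "CS+SI"
    for (g in names(rgyr_groups))
      series[[paste0("rgyr_", g)]] <-
        emit(rgyr_series(trajectory, rgyr_groups[[g]]),
             sprintf("rgyr_%s.tsv", g))
    series$dist_AB_TM <- emit(
      center_distance_series(trajectory, map, "AB", "TM", fit_sel, reference),
      "dist_AB_TM.tsv")
    series$dist_SI_TM <- emit(
      center_distance_series(trajectory, map, "SI", "TM", fit_sel, reference),
      "dist_SI_TM.tsv")
    series$end_to_end <- emit(end_to_end_series(trajectory), "end_to_end.tsv")
    summary$series <- series

    if (n_frames(trajectory) >= 2L) {
      prof <- rmsf_profile(trajectory, fit_sel, rec_sel, reference)
      utils::write.table(prof, file.path(out_dir, "rmsf.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      summary$rmsf <- lapply(stats::setNames(doms, doms), function(d) {
        dr <- map$domains[[d]]
        keep <- resolve_ranges(
          data.frame(chain = prof$chain, resid = prof$resid,
                     het = FALSE, stringsAsFactors = FALSE), dr)
        list(mean = mean(prof$value[keep]), n_residues = sum(keep))
      })
    }
  }

  if ("cloud" %in% stages) {
    banner("cloud")
    summary$clouds <- list()
    for (d in intersect(c("AB", "CS", "SI"), names(map$domains))) {
      cl <- center_cloud(trajectory, map, d, fit_sel, reference)
      df <- data.frame(frame = seq_len(nrow(cl)) - 1L,
                       x = cl[, 1], y = cl[, 2], z = cl[, 3])
      utils::write.table(df, file.path(out_dir, sprintf("cloud_%s.tsv", d)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      ss <- sampling_summary(cl[(cut + 1L):nrow(cl), , drop = FALSE])
      summary$clouds[[d]] <- list(
        centroid = as.numeric(ss$centroid),
        covariance_trace = ss$covariance_trace,
        principal_extents = as.numeric(ss$principal_extents),
        planar_spread = ss$planar_spread,
        normal_spread = ss$normal_spread,
        hull_volume = ss$hull_volume, n_points = ss$n_points)
    }
  }

  if ("contacts" %in% stages) {
    banner("contacts")
    has_mem <- any(trajectory$atoms$het &
                     trajectory$atoms$resname == map$membrane_resname)
    summary$contacts <- list(available = has_mem)
    if (has_mem && length(map$groups)) {
      mem_sel <- select_atoms(trajectory, map, "membrane")
      for (g in names(map$groups)) {
        gsel <- select_atoms(trajectory, map, g)
        cs <- contact_count_series(trajectory, gsel, mem_sel, contact_cutoff)
        utils::write.table(
          data.frame(frame = seq_along(cs$counts) - 1L, count = cs$counts),
          file.path(out_dir, sprintf("contacts_%s.tsv", g)),
          sep = "\t", row.names = FALSE, quote = FALSE)
        v <- cs$counts[(cut + 1L):length(cs$counts)]
        summary$contacts[[g]] <- list(mean = mean(v),
                                      mean_rounded = round(mean(v)),
                                      max = max(v), cutoff = contact_cutoff)
      }
      if ("ITAM_TYR" %in% names(map$groups)) {
        bsel <- select_atoms(trajectory, map, "ITAM_TYR")
        bs <- burial_depth_series(trajectory, bsel,
                                  map$membrane_slab_halfwidth)
        summary$series_burial <- emit(bs, "burial_ITAM_TYR.tsv")
        v <- bs$values[(cut + 1L):length(bs$values)]
        summary$burial <- list(mean_depth = mean(v), max_depth = max(v),
                               buried = mean(v) > 0)
      }
    }
  }

  if ("sse" %in% stages) {
    banner("sse")
    at <- trajectory$atoms
    has_backbone <- all(c("N", "CA", "C") %in% at$name[!at$het])
    summary$sse <- list(available = has_backbone)
    if (has_backbone) {
      rows <- lapply(doms, function(d) {
        fr <- sse_fractions(trajectory, map, d)
        data.frame(domain = d, H = fr[["H"]], E = fr[["E"]], C = fr[["C"]])
      })
      tab <- do.call(rbind, rows)
      utils::write.table(tab, file.path(out_dir, "sse_fractions.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      summary$sse$fractions <- stats::setNames(lapply(rows, function(r)
        list(H = r$H, E = r$E, C = r$C)), tab$domain)
    } else {
      utils::write.table(
        data.frame(domain = doms, H = NA, E = NA, C = NA,
                   note = "no N/CA/C backbone in topology"),
        file.path(out_dir, "sse_fractions.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  if ("cluster" %in% stages) {
    banner("cluster")
    ca <- cluster_trajectory(trajectory, rec_sel, cluster_cutoff)
    utils::write.table(
      data.frame(frame = seq_along(ca$labels) - 1L, cluster = ca$labels),
      file.path(out_dir, "clusters.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    summary$clusters <- list(n_clusters = ca$n_clusters,
                             cutoff = ca$cutoff,
                             representatives = as.integer(ca$representatives))
  }

  if ("network" %in% stages) {
    banner("network")
    corr <- correlation_matrix(trajectory, rec_sel, fit_sel, reference)
    g <- build_network(trajectory, corr, rec_sel,
                       network_contact_cutoff, network_occupancy)
    el <- igraph::as_data_frame(g, what = "edges")
    utils::write.table(el, file.path(out_dir, "network_edges.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    cp <- detect_communities(g, map)
    summary$network <- list(
      n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
      n_communities = cp$n_communities, modularity = cp$modularity,
      per_domain_counts = as.list(cp$per_domain_counts),
      membership = as.integer(cp$membership))
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}

#' Assemble the apo-vs-holo comparison report from two result bundles
#'
#' Reads the `summary.json` of an apo and a holo bundle (as written by
#' [run_analyze()]) and assembles the state comparison: the per-domain
#' overall/intra/inter Ca-RMSD decomposition (signed holo - apo
#' differences of means; `inter = overall - intra` exactly), state
#' comparisons for the distances and radii of gyration, per-domain RMSF
#' deltas, the domain-sampling switch report with its score, contact and
#' secondary-structure deltas, and cluster/community counts. Two JSON
#' files are written: a report rounded in the conventional style (1
#' decimal for Angstrom quantities, 3 for dimensionless scores) and a
#' full-precision `*_raw.json`.
#'
#' @param apo,holo bundle directories (or summary lists) from
#'   [run_analyze()].
#' @param out_path path of the rounded report JSON (the raw twin gets a
#'   `_raw.json` suffix); `NULL` to skip writing.
#' @return invisibly, the full-precision report list.
#' @export
run_compare <- function(apo, holo, out_path = NULL) {
  load_bundle <- function(b) {
    if (is.character(b)) {
      f <- file.path(b, "summary.json")
      if (!file.exists(f)) stop_data("bundle summary not found: %s", f)
      jsonlite::read_json(f, simplifyVector = FALSE)
    } else b
  }
  a <- load_bundle(apo); h <- load_bundle(holo)
  if (!identical(a$domains, h$domains[names(a$domains)]))
    stop_config("incompatible domain maps between bundles: %s vs %s",
                paste(names(a$domains), collapse = ","),
                paste(names(h$domains), collapse = ","))

  doms <- intersect(names(a$domains), REQUIRED_DOMAINS)
  overall <- vapply(doms, function(d)
    h$series[[paste0("rmsd_overall_", d)]]$mean -
      a$series[[paste0("rmsd_overall_", d)]]$mean, numeric(1))
  intra <- vapply(doms, function(d)
    h$series[[paste0("rmsd_intra_", d)]]$mean -
      a$series[[paste0("rmsd_intra_", d)]]$mean, numeric(1))
  decomp <- decompose_domains(overall, intra)

  cmp_series <- function(key) {
    sa <- a$series[[key]]; sh <- h$series[[key]]
    if (is.null(sa) || is.null(sh)) return(NULL)
    list(metric = key, apo_mean = sa$mean, apo_sd = sa$sd,
         holo_mean = sh$mean, holo_sd = sh$sd,
         signed_diff = sh$mean - sa$mean,
         abs_diff = abs(sh$mean - sa$mean), units = "Å")
  }
  comparisons <- Filter(Negate(is.null), lapply(
    stats::setNames(nm = c("rmsd_overall_receptor", "dist_AB_TM", "dist_SI_TM",
                           "rgyr_receptor", "rgyr_extracellular",
                           "rgyr_intracellular", "end_to_end")),
    cmp_series))

  rmsf_delta <- NULL
  if (!is.null(a$rmsf) && !is.null(h$rmsf))
    rmsf_delta <- lapply(stats::setNames(nm = doms), function(d)
      list(apo_mean = a$rmsf[[d]]$mean, holo_mean = h$rmsf[[d]]$mean,
           signed_diff = h$rmsf[[d]]$mean - a$rmsf[[d]]$mean))

  switch_report <- NULL
  if (!is.null(a$clouds$AB) && !is.null(a$clouds$SI) &&
      !is.null(h$clouds$AB) && !is.null(h$clouds$SI)) {
    as_ss <- function(x) structure(x, class = "SamplingSummary")
    score <- bidds_switch_score(as_ss(a$clouds$AB), as_ss(h$clouds$AB),
                                as_ss(a$clouds$SI), as_ss(h$clouds$SI))
    switch_report <- list(
      ab_apo = a$clouds$AB, ab_holo = h$clouds$AB,
      si_apo = a$clouds$SI, si_holo = h$clouds$SI,
      ab_trace_ratio_apo_over_holo =
        a$clouds$AB$covariance_trace / h$clouds$AB$covariance_trace,
      si_trace_ratio_holo_over_apo =
        h$clouds$SI$covariance_trace / a$clouds$SI$covariance_trace,
      switch_score = score)
  }

  contacts <- NULL
  if (isTRUE(a$contacts$available) && isTRUE(h$contacts$available)) {
    gnames <- setdiff(intersect(names(a$contacts), names(h$contacts)),
                      "available")
    contacts <- lapply(stats::setNames(nm = gnames), function(g)
      list(apo_mean = a$contacts[[g]]$mean,
           apo_mean_rounded = round(a$contacts[[g]]$mean),
           holo_mean = h$contacts[[g]]$mean,
           holo_mean_rounded = round(h$contacts[[g]]$mean),
           signed_diff = h$contacts[[g]]$mean - a$contacts[[g]]$mean))
  }

  sse_delta <- NULL
  if (isTRUE(a$sse$available) && isTRUE(h$sse$available))
    sse_delta <- lapply(stats::setNames(nm = doms), function(d) {
      fa <- a$sse$fractions[[d]]; fh <- h$sse$fractions[[d]]
      list(dH = fh$H - fa$H, dE = fh$E - fa$E, dC = fh$C - fa$C)
    })

  counts <- list()
  if (!is.null(a$clusters))
    counts$clusters <- list(apo = a$clusters$n_clusters,
                            holo = h$clusters$n_clusters)
  if (!is.null(a$network))
    counts$communities <- list(
      apo = a$network$n_communities, holo = h$network$n_communities,
      per_domain_apo = a$network$per_domain_counts,
      per_domain_holo = h$network$per_domain_counts)

  report <- list(
    provenance = list(package = "cardyn",
                      version = as.character(utils::packageVersion("cardyn")),
                      apo_hash = a$provenance$config_hash,
                      holo_hash = h$provenance$config_hash),
    units = "Å",
    decomposition = decomp,
    comparisons = comparisons,
    rmsf_delta = rmsf_delta,
    switch_report = switch_report,
    contacts = contacts,
    sse_delta = sse_delta,
    counts = counts)

  if (!is.null(out_path)) {
    jsonlite::write_json(report, sub("\\.json$", "_raw.json", out_path),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", dataframe = "rows")
    jsonlite::write_json(round_report(report), out_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", dataframe = "rows")
  }
  invisible(report)
}

# report rounding convention: 1 decimal for Angstrom quantities,
# 3 decimals for dimensionless scores/ratios/fractions
round_report <- function(x, digits = 1) {
  rec <- function(node, nm) {
    if (is.list(node) || is.data.frame(node)) {
      out <- node
      for (k in seq_along(node))
        out[[k]] <- rec(node[[k]],
                        if (!is.null(names(node))) names(node)[k] else "")
      return(out)
    }
    if (is.numeric(node)) {
      dimless <- grepl("score|ratio|modularity|fraction|^d[HEC]$|hash|occupancy",
                       nm)
      counts <- grepl("^n_|count|cut|start|end|rounded|membership|representatives",
                      nm)
      if (counts) return(node)
      return(round(node, if (dimless) 3 else digits))
    }
    node
  }
  rec(x, "")
}

# deterministic djb2-style string hash for config provenance
config_hash <- function(s) {
  s <- paste(s, collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
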