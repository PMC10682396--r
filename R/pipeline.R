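#' End-to-end pose-ensemble analysis
#'
#' Orchestrates the full pipeline for one ensemble (one drug form docked to
#' one channel variant): ranked selection from the score table, descriptor
#' computation, two-stage clustering, pore-radius profiling, region
#' classification with occupancy statistics, and interaction fingerprinting
#' of each cluster representative, assembled into a summary report row
#' (top-cluster size, interface energy in REU, key residues, pore-region
#' labels, occupancy percentages).
#'
#' Inputs may be in-memory objects or file paths (channel PDB, pose PDBs,
#' Rosetta-style score table). When `out_dir` is given, every intermediate is
#' serialised there (descriptors, cluster tables, pore profile, region map,
#' locations, interaction tables, report JSON).
#'
#' @param channel A `channel_model` or path to a channel PDB.
#' @param poses List of `ligand_pose` objects or character vector of pose
#'   PDB paths.
#' @param scores Score table data frame or path to a `.sc` file.
#' @param n_pool,n_top Selection sizes (defaults 10000 and 50; clamped with
#'   a warning when the table is smaller).
#' @param cutoff,min_size Clustering parameters (see [pose_cluster()]).
#' @param ligand_resname Ligand residue name for path input.
#' @param residue_config Residue sets (see [herg_residue_config()]).
#' @param thresholds Interaction thresholds.
#' @param drug_band Axial band `c(lo, hi)` (frame z, Angstrom) for the
#'   reported drug-binding-region pore radius; defaults to the span between
#'   the gate and the SF base.
#' @param out_dir Optional output directory for artifacts.
#' @param label Ensemble label used in the report.
#' @param ... Further arguments passed to [build_region_map()].
#' @return A `pose_analysis` object: list with `selection`, `descriptors`,
#'   `clusters`, `profile`, `region_map`, `locations`, `occupancy`,
#'   `interactions` (per representative), `report` (one-row data frame).
#' @export
run_analysis <- function(channel, poses, scores,
                         n_pool = 10000L, n_top = 50L,
                         cutoff = 0.3, min_size = 3L,
                         ligand_resname = "LIG",
                         residue_config = herg_residue_config(),
                         thresholds = default_interaction_thresholds(),
                         drug_band = NULL, out_dir = NULL,
                         label = "ensemble", ...) {
  if (is.character(channel)) {
    channel <- read_channel_pdb(channel, residue_config)
  }
  if (is.character(scores)) scores <- read_score_table(scores)
  if (is.character(poses)) {
    poses <- read_pose_set(poses, ligand_resname, score_table = scores)
  } else {
    # attach scores to in-memory poses lacking them
    tab <- .validate_score_table(scores)
    poses <- lapply(poses, function(p) {
      if (is.na(p$interface_score)) {
        row <- match(p$pose_id, tab$pose_id)
        if (!is.na(row)) {
          p$total_score <- tab$total_score[row]
          p$interface_score <- tab$interface_delta_X[row]
        }
      }
      p
    })
  }
  if (!length(poses)) stop("stage read_pose_set: no poses available")
  if (is.null(channel$frame)) stop("stage compute_pore_frame: no pore frame")

  selection <- rank_and_select(scores, n_pool = n_pool, n_top = n_top)
  ids <- vapply(poses, `[[`, character(1), "pose_id")
  selected <- poses[match(intersect(selection, ids), ids)]
  if (!length(selected)) stop("stage select: no selected pose has coordinates")

  descriptors <- pose_descriptors(selected, channel$frame)
  clusters <- if (nrow(descriptors) >= 2L) {
    pose_cluster(descriptors, cutoff = cutoff, min_size = min_size)
  } else {
    # single-pose ensemble: a trivial cluster of size one
    lab <- stats::setNames(1L, descriptors$pose_id)
    .new_pose_clusters(descriptors, lab, lab, centers = NULL,
                       norms = descriptor_norms(descriptors),
                       params = list(cutoff = cutoff, min_size = min_size),
                       iterations = 0L)
  }

  profile <- pore_radius_profile(channel)
  map <- build_region_map(channel, profile, ...)
  locations <- classify_poses(selected, map)
  occupancy <- ensemble_percentages(locations)

  report_tab <- cluster_report(clusters)
  reps <- selected[match(report_tab$representative_id,
                         vapply(selected, `[[`, character(1), "pose_id"))]
  interactions <- lapply(reps, function(p) {
    detect_interactions(channel, p, thresholds)
  })
  names(interactions) <- report_tab$representative_id

  if (is.null(drug_band)) drug_band <- c(map$z_gate, map$z_sf_base)
  band_radius <- tryCatch(
    max_radius_in_band(profile, drug_band[1], drug_band[2]),
    error = function(e) NA_real_
  )

  key <- if (length(interactions)) key_residues(interactions[[1]]) else
    key_residues(data.frame())
  regions_label <- .report_region_labels(clusters, locations, occupancy, map)
  report <- data.frame(
    label = label,
    top_cluster_size = if (nrow(report_tab)) report_tab$size[1] else NA_integer_,
    top_cluster_ie = if (nrow(report_tab)) report_tab$interface_score[1] else NA_real_,
    key_residues = paste(utils::head(key$label, 6), collapse = " "),
    pore_regions = regions_label,
    pct_pocket = occupancy$pct_pocket,
    pct_enclosed = occupancy$pct_enclosed,
    n_poses = occupancy$n,
    drug_band_radius = band_radius,
    stringsAsFactors = FALSE
  )

  out <- structure(
    list(selection = selection, poses = selected, descriptors = descriptors,
         clusters = clusters, profile = profile, region_map = map,
         locations = locations, occupancy = occupancy,
         interactions = interactions, report = report),
    class = "pose_analysis"
  )
  if (!is.null(out_dir)) .write_analysis(out, out_dir)
  out
}

# Fixed mapping from occupancy statistics to Table-style pore-region labels:
# pocket occupancy adds "hydrophobic pocket", fenestration poses add
# "fenestration", a top-cluster representative whose COM sits within 8 A
# below the SF base adds "SF base", otherwise "central cavity".
.report_region_labels <- function(clusters, locations, occupancy, map) {
  labels <- character(0)
  rep_id <- if (!is.null(clusters$summary)) clusters$summary$representative_id[1] else NA
  if (!is.na(rep_id)) {
    d <- clusters$descriptors
    z_rep <- d$z[d$pose_id == rep_id]
    if (length(z_rep) && z_rep >= map$z_sf_base - 8 && z_rep <= map$z_sf_base + map$r_slack) {
      labels <- c(labels, "SF base")
    } else {
      labels <- c(labels, "central cavity")
    }
  }
  if (occupancy$pct_pocket > 0) labels <- c(labels, "hydrophobic pocket")
  if (occupancy$counts[["fenestration"]] > 0) labels <- c(labels, "fenestration")
  paste(labels, collapse = ", ")
}

.write_analysis <- function(x, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_descriptor_table(x$descriptors, file.path(out_dir, "descriptors.tsv"))
  write_cluster_tables(x$clusters,
                       file.path(out_dir, "clusters.tsv"),
                       file.path(out_dir, "summary.tsv"))
  write_pore_profile(x$profile, file.path(out_dir, "profile.tsv"))
  write_region_map(x$region_map, file.path(out_dir, "regions.json"))
  utils::write.table(x$locations, file.path(out_dir, "locations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in names(x$interactions)) {
    write_interaction_table(x$interactions[[id]],
                            file.path(out_dir, sprintf("interactions_%s.tsv", id)))
  }
  jsonlite::write_json(as.list(x$report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a run configuration file
#'
#' YAML-style key-value configuration naming the input paths and analysis
#' parameters. Recognised keys mirror the arguments of [run_analysis()]
#' (`channel`, `poses` (a directory or vector of paths), `scores`, `n_pool`,
#' `n_top`, `cutoff`, `min_size`, `ligand_resname`, `out_dir`, `label`);
#' unknown keys are ignored with a warning.
#'
#' @param path Path to a YAML config file.
#' @return Named list of arguments suitable for `do.call(run_analysis, ...)`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files")
  }
  cfg <- yaml::read_yaml(path)
  known <- c("channel", "poses", "scores", "n_pool", "n_top", "cutoff",
             "min_size", "ligand_resname", "drug_band", "out_dir", "label")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    warning("ignoring unknown config key(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  cfg <- cfg[intersect(names(cfg), known)]
  if (!is.null(cfg$poses) && length(cfg$poses) == 1L && dir.exists(cfg$poses)) {
    cfg$poses <- list.files(cfg$poses, pattern = "\\.pdb$", full.names = TRUE)
  }
  cfg
}

#' @export
print.pose_analysis <- function(x, ...) {
  r <- x$report
  cat("Pose-ensemble analysis:", r$label, "\n")
  cat(sprintf("  %d poses analysed; top cluster size %d (IE %.1f REU)\n",
              r$n_poses, r$top_cluster_size, r$top_cluster_ie))
  cat("  key residues:", r$key_residues, "\n")
  cat("  pore regions:", r$pore_regions, "\n")
  cat(sprintf("  %% in hydrophobic pocket: %.1f; %% fully enclosed: %.1f\n",
              r$pct_pocket, r$pct_enclosed))
  if (is.finite(r$drug_band_radius)) {
    cat(sprintf("  drug-binding region pore radius: %.2f A\n", r$drug_band_radius))
  }
  invisible(x)
}
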