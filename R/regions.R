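#' Build a geometric pore-region map
#'
#' Derives deterministic region definitions from a channel model and its pore
#' profile, all expressed in the pore frame (origin at the SF C-alpha centre
#' of mass, z along the pore axis):
#' \itemize{
#'   \item per-chain hydrophobic-pocket anchors: centroid of the sidechain
#'     heavy atoms of the pocket residues, with capture radius `r_pocket`;
#'   \item per-chain fenestration anchors: centroid of the sidechain heavy
#'     atoms of the fenestration residues (all heavy atoms when no sidechain
#'     atoms resolve), with capture radius `r_fen`;
#'   \item axial bands: `z_sf_base` (minimum z of SF C-alpha atoms) and
#'     `z_gate` (mean z of gate-residue C-alpha atoms);
#'   \item the lumen radial bound R_lumen(z), interpolated from the pore
#'     profile.
#' }
#' Pockets are flagged closed when every pocket anchor lies within
#' `r_collapse` of the protein-occluded part of the axis (slices whose pore
#' radius falls below a water-probe threshold `r_occl`), the situation in a
#' closed-state channel where the pockets disappear; occupancy statistics are
#' still computed in that case.
#'
#' @param model A `channel_model` with a valid frame.
#' @param profile A `pore_profile` from [pore_radius_profile()].
#' @param r_pocket Pocket capture radius, Angstrom (default 5.0).
#' @param r_fen Fenestration capture radius (default 5.5).
#' @param d_enc Enclosure contact cutoff (default 6.0).
#' @param r_slack Axial band slack (default 2.0).
#' @param r_collapse Pocket-collapse distance threshold (default 2.5).
#' @param r_occl Occlusion probe radius (default 1.15, a water probe).
#' @param r_gate_capture Radial capture for the intracellular-gate category
#'   (default 8.0).
#' @return A `region_map` object.
#' @export
build_region_map <- function(model, profile,
                             r_pocket = 5.0, r_fen = 5.5, d_enc = 6.0,
                             r_slack = 2.0, r_collapse = 2.5, r_occl = 1.15,
                             r_gate_capture = 8.0) {
  stopifnot(inherits(model, "channel_model"))
  frame <- model$frame
  if (is.null(frame)) stop("model has no pore frame")
  at <- model$atoms
  protein <- at[!at$het, , drop = FALSE]
  pxyz <- .to_frame(.coords(protein), frame)

  backbone <- c("N", "CA", "C", "O")
  set_anchors <- function(resnos, sidechain_only = TRUE) {
    anchors <- list()
    for (ch in model$chains) {
      sel <- protein$chain == ch & protein$resno %in% resnos &
        protein$elesy != "H"
      sub <- sel & !(protein$elety %in% backbone)
      if (!any(sub) && !sidechain_only) sub <- sel
      if (!any(sub) && sidechain_only && any(sel)) sub <- sel  # CA-only models
      if (!any(sub)) next
      anchors[[ch]] <- colMeans(pxyz[sub, , drop = FALSE])
    }
    anchors
  }

  pocket <- set_anchors(model$residue_config$pocket_residues)
  if (!length(pocket)) stop("region error: pocket residues unresolved in all chains")
  if (length(pocket) < 4L) {
    warning(sprintf("pocket anchors resolved in %d of 4 chains",
                    length(pocket)), call. = FALSE)
  }
  fen <- set_anchors(model$residue_config$fenestration_residues,
                     sidechain_only = FALSE)

  sf_ca <- protein$elety == "CA" &
    protein$resno %in% model$residue_config$sf_residues
  if (!any(sf_ca)) stop("region error: no SF C-alpha atoms")
  z_sf_base <- min(pxyz[sf_ca, 3])
  gate_ca <- protein$elety == "CA" &
    protein$resno %in% model$residue_config$gate_residues
  if (!any(gate_ca)) {
    gate_ca <- protein$resno %in% model$residue_config$gate_residues
  }
  if (!any(gate_ca)) stop("region error: gate residues unresolved")
  z_gate <- mean(pxyz[gate_ca, 3])
  if (!(z_gate < z_sf_base)) {
    stop("region error: gate band must lie below the SF base")
  }

  # occluded axis slices and the pocket-collapse flag
  occl <- profile$radius < r_occl
  pockets_closed <- FALSE
  if (any(occl)) {
    anchor_mat <- do.call(rbind, pocket)
    collapse_dist <- vapply(seq_len(nrow(anchor_mat)), function(i) {
      r_a <- sqrt(sum(anchor_mat[i, 1:2]^2))
      min(sqrt((anchor_mat[i, 3] - profile$z[occl])^2 +
                 pmax(0, r_a - profile$radius[occl])^2))
    }, numeric(1))
    pockets_closed <- all(collapse_dist <= r_collapse)
  }

  structure(
    list(
      frame = frame,
      pocket_anchors = pocket, fenestration_anchors = fen,
      z_sf_base = z_sf_base, z_gate = z_gate,
      profile = data.frame(z = profile$z, radius = profile$radius,
                           capped = profile$capped),
      protein_xyz = pxyz[protein$elesy != "H", , drop = FALSE],
      r_pocket = r_pocket, r_fen = r_fen, d_enc = d_enc,
      r_slack = r_slack, r_collapse = r_collapse, r_occl = r_occl,
      r_gate_capture = r_gate_capture,
      pockets_closed = pockets_closed
    ),
    class = "region_map"
  )
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf(
    "Region map: %d pocket anchor(s), %d fenestration anchor(s)\n",
    length(x$pocket_anchors), length(x$fenestration_anchors)
  ))
  cat(sprintf("  SF base z = %.2f A, gate z = %.2f A, pockets %s\n",
              x$z_sf_base, x$z_gate,
              if (x$pockets_closed) "closed" else "open"))
  invisible(x)
}

# Lumen radial bound at axial position z, linearly interpolated over the
# uncapped profile slices (nearest slice outside the grid).
.lumen_radius <- function(map, z) {
  ok <- !map$profile$capped
  if (!any(ok)) return(rep(Inf, length(z)))
  stats::approx(map$profile$z[ok], map$profile$radius[ok], xout = z,
                rule = 2)$y
}

.region_categories <- c("pore_lumen", "fenestration", "intracellular_gate",
                        "membrane")

#' Classify a pose against a region map
#'
#' Heavy atoms only. `in_pocket` is true when at least one heavy atom lies
#' within `r_pocket` of any pocket anchor (the criterion behind "at least one
#' atom positioned at or in the hydrophobic pocket"). The location category
#' is assigned by precedence fenestration > pore_lumen > intracellular_gate >
#' membrane: a pose reaching a fenestration anchor while its centre of mass
#' sits radially outside the lumen bound is a fenestration pose even though
#' it also overlaps the lumen. `fully_enclosed` requires every heavy atom to
#' lie within the gate-to-SF axial band (extended by `r_slack`) and within
#' `d_enc` of at least one protein atom — the operational reading of "fully
#' encapsulated within the channel pore or fenestration region".
#'
#' @param pose A `ligand_pose` (coordinates in the same frame as the model
#'   the map was built from).
#' @param map A `region_map`.
#' @return One-row data frame: `pose_id`, `category`, `in_pocket`,
#'   `fully_enclosed`.
#' @export
classify_pose <- function(pose, map) {
  atoms <- pose$atoms[pose$atoms$elesy != "H", , drop = FALSE]
  xyz <- .to_frame(.coords(atoms), map$frame)
  com <- colMeans(xyz)
  r_com <- sqrt(sum(com[1:2]^2))
  lumen_at_com <- .lumen_radius(map, com[3])

  anchor_hit <- function(anchors, radius) {
    if (!length(anchors)) return(FALSE)
    amat <- do.call(rbind, anchors)
    any(.cross_dist(xyz, amat) <= radius)
  }
  in_pocket <- anchor_hit(map$pocket_anchors, map$r_pocket)
  fen_reach <- anchor_hit(map$fenestration_anchors, map$r_fen)

  # precedence: fenestration > pore_lumen > intracellular_gate > membrane;
  # a pocket-captured pose counts as pore_lumen (the pockets extend up from
  # the central cavity) unless it also reaches a fenestration anchor
  category <- if (fen_reach && r_com > lumen_at_com) {
    "fenestration"
  } else if (com[3] >= map$z_gate && com[3] <= map$z_sf_base + map$r_slack &&
             (r_com <= lumen_at_com + map$r_slack || in_pocket)) {
    "pore_lumen"
  } else if (com[3] <= map$z_gate + map$r_slack &&
             r_com <= map$r_gate_capture) {
    "intracellular_gate"
  } else {
    "membrane"
  }

  z_ok <- all(xyz[, 3] >= map$z_gate - map$r_slack &
                xyz[, 3] <= map$z_sf_base + map$r_slack)
  fully_enclosed <- FALSE
  if (z_ok) {
    d <- .cross_dist(xyz, map$protein_xyz)
    fully_enclosed <- all(apply(d, 1, min) <= map$d_enc)
  }
  data.frame(pose_id = pose$pose_id, category = category,
             in_pocket = in_pocket, fully_enclosed = fully_enclosed,
             stringsAsFactors = FALSE)
}

#' Classify every pose of an ensemble
#'
#' @param poses List of `ligand_pose` objects.
#' @param map A `region_map`.
#' @return Data frame with one row per pose (see [classify_pose()]).
#' @export
classify_poses <- function(poses, map) {
  do.call(rbind, lapply(poses, classify_pose, map = map))
}

#' Occupancy statistics over classified poses
#'
#' The percentage within the hydrophobic pocket is the proportion of poses
#' with at least one atom captured by a pocket anchor; the percentage within
#' the (closed) pore is the proportion of fully enclosed poses. Category
#' counts partition the ensemble.
#'
#' @param locations Data frame from [classify_poses()].
#' @return List with `n`, `counts` (named vector over the four categories),
#'   `pct_pocket`, `pct_enclosed`.
#' @export
ensemble_percentages <- function(locations) {
  stopifnot(nrow(locations) >= 1L)
  counts <- table(factor(locations$category, levels = .region_categories))
  list(
    n = nrow(locations),
    counts = stats::setNames(as.integer(counts), names(counts)),
    pct_pocket = 100 * sum(locations$in_pocket) / nrow(locations),
    pct_enclosed = 100 * sum(locations$fully_enclosed) / nrow(locations)
  )
}

#' Serialise a region map to JSON
#'
#' Writes anchors, bands, radii and flags for audit.
#'
#' @param map A `region_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_region_map <- function(map, path) {
  payload <- list(
    pocket_anchors = lapply(map$pocket_anchors, as.numeric),
    fenestration_anchors = lapply(map$fenestration_anchors, as.numeric),
    z_sf_base = map$z_sf_base, z_gate = map$z_gate,
    r_pocket = map$r_pocket, r_fen = map$r_fen, d_enc = map$d_enc,
    r_slack = map$r_slack, r_collapse = map$r_collapse,
    r_gate_capture = map$r_gate_capture,
    pockets_closed = map$pockets_closed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
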