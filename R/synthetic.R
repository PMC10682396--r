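# Synthetic C4-symmetric channel scaffolds and pose ensembles with planted
# ground truth. Scaffold residues are reduced to a C-alpha plus a
# pseudo-sidechain centroid atom (named SC) per landmark residue; this is
# sufficient for every geometric operation in the package while staying tiny
# and fully controllable.

#' Specification of a synthetic channel scaffold
#'
#' Defaults emulate an open-state homotetrameric K-channel pore domain in
#' hERG numbering: a 6.0 A open bore lined by carbon rings, a five-residue
#' selectivity filter (624-628) whose C-alpha centre of mass sits at
#' z = +15 A in the construction frame, four hydrophobic pockets behind the
#' SF base, four lateral fenestration sites, and an intracellular gate ring
#' (S660). The closed state narrows the lower pore to `bore_closed`
#' (2.0 A, an occluding constriction once van der Waals radii are taken into
#' account) and collapses the pocket centroids toward the occluded axis so
#' that the pockets disappear.
#'
#' @param state `"open"` or `"closed"`.
#' @param bore_open Open-state wall ring radius, Angstrom (6.0 A rings of
#'   carbon give a 4.3 A pore radius).
#' @param bore_closed Closed-state constriction radius (2.0 A: occluding
#'   once van der Waals radii are subtracted).
#' @param bore_mid_closed Closed-state bore above the constriction (4.5 A:
#'   a 2.8 A pore radius in the drug-binding region, emulating the narrower
#'   closed pore).
#' @param sf_z Target z of the SF C-alpha centre of mass (construction
#'   frame).
#' @param ring_step Axial spacing of wall rings (default 0.5 A).
#' @param atoms_per_ring Wall atoms per ring (default 24; multiple of 4 for
#'   exact C4 symmetry).
#' @return A `scaffold_spec` list.
#' @export
scaffold_spec <- function(state = c("open", "closed"),
                          bore_open = 6.0, bore_closed = 2.0,
                          bore_mid_closed = 4.5,
                          sf_z = 15, ring_step = 0.5, atoms_per_ring = 24L) {
  state <- match.arg(state)
  if (bore_closed > bore_open) stop("spec error: open bore must be >= closed bore")
  if (atoms_per_ring %% 4L != 0L) stop("spec error: atoms_per_ring must be a multiple of 4")
  structure(list(
    state = state, bore_open = bore_open, bore_closed = bore_closed,
    bore_mid_closed = bore_mid_closed,
    sf_z = sf_z, ring_step = ring_step, atoms_per_ring = atoms_per_ring,
    # closed-state SF breathes radially outward by 0.4 A (preserves exact C4
    # and makes the open/closed SF C-alpha RMSD 0.4 A by construction)
    sf_resnos = 624:628,
    sf_radius = if (state == "closed") 3.4 else 3.0,
    sf_spacing = 2.5,
    wall_z = c(-22, 9.5),
    constriction_z = c(-22, -14),   # closed-state occluding band
    drug_band = c(-5, 7),           # putative drug-binding band (construction z)
    gate_z = -20, gate_resno = 660L,
    pocket_center = list(radius = 8.5, z = 8),          # open state
    pocket_center_closed = list(radius = 2.5, z = -18), # collapsed
    fen_center = list(radius = 9.0, z = 2),
    membrane_radius = 15
  ), class = "scaffold_spec")
}

.chain_azimuths <- c(A = 45, B = 135, C = 225, D = 315)

# place one point per chain by exact 90-degree rotation of a base point
.c4_points <- function(radius, z, azimuth0 = 45) {
  t(vapply(.chain_azimuths - 45 + azimuth0, function(a) {
    c(radius * cos(a * pi / 180), radius * sin(a * pi / 180), z)
  }, numeric(3)))
}

# zero-sum offsets used to scatter pseudo-sidechain atoms around an anchor
# so the anchor equals the construction centre exactly; rotated per chain to
# keep the scaffold C4-exact.
.anchor_offsets <- function(n) {
  base <- rbind(c(0.4, 0, 0.2), c(-0.4, 0, 0.2), c(0, 0.4, -0.2),
                c(0, -0.4, -0.2), c(0, 0, 0),
                c(0.3, 0.3, 0), c(-0.3, -0.3, 0), c(0.3, -0.3, 0),
                c(-0.3, 0.3, 0))
  off <- base[seq_len(n), , drop = FALSE]
  sweep(off, 2, colMeans(off))
}

#' Generate a synthetic C4 channel scaffold
#'
#' Builds the scaffold described by a [scaffold_spec()] as a `channel_model`
#' (four chains by exact 90-degree rotation) and emits the ground-truth
#' landmarks alongside: frame origin/axis, pocket and fenestration anchors,
#' axial bands, the expected interior pore radius, and whether the pockets
#' are expected to be flagged closed.
#'
#' @param spec A `scaffold_spec`.
#' @param seed Unused (construction is deterministic); kept for interface
#'   symmetry with [make_pose_ensemble()].
#' @return List with `model` (a `channel_model`) and `truth` (named list of
#'   construction values).
#' @export
make_scaffold <- function(spec = scaffold_spec(), seed = NULL) {
  stopifnot(inherits(spec, "scaffold_spec"))
  rows <- list()
  emit <- function(chain, resno, resid, elety, elesy, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = as.integer(resno), resid = resid, elety = elety,
      elesy = elesy, x = xyz[1], y = xyz[2], z = xyz[3], het = FALSE,
      stringsAsFactors = FALSE
    )
  }
  chains <- names(.chain_azimuths)

  ## selectivity filter C-alphas
  sf_resnames <- c("SER", "VAL", "GLY", "PHE", "GLY")
  sf_zs <- spec$sf_z + spec$sf_spacing * (seq_along(spec$sf_resnos) -
                                            (length(spec$sf_resnos) + 1) / 2)
  for (i in seq_along(spec$sf_resnos)) {
    pts <- .c4_points(spec$sf_radius, sf_zs[i])
    for (k in seq_along(chains)) {
      emit(chains[k], spec$sf_resnos[i], sf_resnames[i], "CA", "C", pts[k, ])
    }
  }

  ## pore wall rings (generic residues, one CA per wall atom)
  wall_z <- seq(spec$wall_z[1], spec$wall_z[2], by = spec$ring_step)
  per_chain <- spec$atoms_per_ring / 4L
  wall_res0 <- 700L
  for (j in seq_along(wall_z)) {
    zj <- wall_z[j]
    in_constriction <- spec$state == "closed" && zj <= spec$constriction_z[2]
    radius <- if (spec$state == "open") {
      spec$bore_open
    } else if (in_constriction) {
      spec$bore_closed
    } else {
      spec$bore_mid_closed
    }
    # around the closed constriction, an outer ring at the open-bore radius
    # stands in for the helix-bundle bulk that encloses the narrow gate
    radii <- if (in_constriction) c(radius, spec$bore_open) else radius
    for (r_i in seq_along(radii)) {
      res0 <- if (r_i == 1L) wall_res0 else 3000L
      for (k in seq_along(chains)) {
        for (m in seq_len(per_chain)) {
          az <- .chain_azimuths[k] - 45 + (m - 0.5) * 90 / per_chain
          xyz <- c(radii[r_i] * cos(az * pi / 180),
                   radii[r_i] * sin(az * pi / 180), zj)
          emit(chains[k], res0 + (j - 1L) * per_chain + m, "GLY", "CA", "C", xyz)
        }
      }
    }
  }

  ## gate ring (S660)
  gate_radius <- if (spec$state == "closed") spec$bore_closed else spec$bore_open
  pts <- .c4_points(gate_radius, spec$gate_z)
  for (k in seq_along(chains)) {
    emit(chains[k], spec$gate_resno, "SER", "CA", "C", pts[k, ])
  }

  ## pocket residues: CA near the wall plus SC pseudo-sidechain centroids
  cfg <- herg_residue_config()
  pocket_resnos <- cfg$pocket_residues
  pocket_ca_z <- c(9, NA, NA, 6, 3)   # 624/625 already have SF CAs
  for (i in seq_along(pocket_resnos)) {
    if (is.na(pocket_ca_z[i])) next
    pts <- .c4_points(spec$bore_open, pocket_ca_z[i])
    resname <- c("THR", "SER", "VAL", "GLY", "TYR")[i]
    for (k in seq_along(chains)) {
      emit(chains[k], pocket_resnos[i], resname, "CA", "C", pts[k, ])
    }
  }
  pocket_ctr <- if (spec$state == "closed") spec$pocket_center_closed else
    spec$pocket_center
  offs <- .anchor_offsets(length(pocket_resnos))
  pocket_anchor_pts <- .c4_points(pocket_ctr$radius, pocket_ctr$z)
  for (k in seq_along(chains)) {
    Rk <- .rotation_about_axis(c(0, 0, 1), .chain_azimuths[k] - 45)
    for (i in seq_along(pocket_resnos)) {
      resname <- c("THR", "SER", "VAL", "GLY", "TYR")[i]
      emit(chains[k], pocket_resnos[i], resname, "SC", "C",
           pocket_anchor_pts[k, ] + as.numeric(Rk %*% offs[i, ]))
    }
  }

  ## fenestration residues: SC centroids at the fenestration centre
  ## (residue 623 is shared with the pocket set and keeps its pocket SC)
  fen_resnos <- setdiff(cfg$fenestration_residues, pocket_resnos)
  fen_resnames <- c("MET", "PHE", "ALA", "LEU", "LEU", "SER", "LEU", "ALA")
  offs <- .anchor_offsets(length(fen_resnos))
  fen_pts <- .c4_points(spec$fen_center$radius, spec$fen_center$z,
                        azimuth0 = 0)
  for (k in seq_along(chains)) {
    Rk <- .rotation_about_axis(c(0, 0, 1), .chain_azimuths[k] - 45)
    for (i in seq_along(fen_resnos)) {
      emit(chains[k], fen_resnos[i], fen_resnames[i], "SC", "C",
           fen_pts[k, ] + as.numeric(Rk %*% offs[i, ]))
    }
  }

  atoms <- do.call(rbind, rows)
  model <- suppressWarnings(.new_channel_model(atoms, cfg))

  vdw_c <- vdw_radii()[["C"]]
  truth <- list(
    state = spec$state,
    sf_com = c(0, 0, spec$sf_z), axis = c(0, 0, 1),
    z_sf_base = min(sf_zs) - spec$sf_z,
    z_gate = spec$gate_z - spec$sf_z,
    bore = spec$bore_open,
    interior_radius = spec$bore_open - vdw_c,
    drug_band = spec$drug_band - spec$sf_z,
    drug_band_radius = if (spec$state == "closed")
      spec$bore_mid_closed - vdw_c else spec$bore_open - vdw_c,
    constriction_radius = if (spec$state == "closed")
      spec$bore_closed - vdw_c else spec$bore_open - vdw_c,
    constriction_band = spec$constriction_z - spec$sf_z,
    pocket_anchors = lapply(seq_along(chains), function(k) {
      p <- pocket_anchor_pts[k, ] - c(0, 0, spec$sf_z)
      stats::setNames(p, c("x", "y", "z"))
    }),
    fen_anchors = lapply(seq_along(chains), function(k) {
      p <- fen_pts[k, ] - c(0, 0, spec$sf_z)
      stats::setNames(p, c("x", "y", "z"))
    }),
    pockets_closed = spec$state == "closed",
    sf_rmsd_vs_other_state = 0.4,
    membrane_radius = spec$membrane_radius
  )
  names(truth$pocket_anchors) <- chains
  names(truth$fen_anchors) <- chains
  list(model = model, truth = truth)
}

#' Specification of a synthetic pose ensemble
#'
#' Poses are drawn from a mixture of clusters in (z, l, phi) descriptor
#' space, realised as rigid rod ligands placed with a uniformly random
#' azimuth about the pore axis (exercising the rotation invariance of the
#' descriptors). Interface scores are correlated with cluster membership
#' through per-cluster offsets. The default emulates a well-converged
#' top-50 docking ensemble: two clusters weighted 0.8/0.2, a dominant
#' hydrophobic-pocket cluster at a favourable interface score and a smaller
#' lumen cluster, descriptor spreads far below the inter-cluster separation.
#'
#' @param n_poses Number of poses (default 50, a top-50 selection).
#' @param clusters List of cluster specs: each a list with `weight`, `mean`
#'   = c(z, l, phi), `sd` = c(z, l, phi), `region` (one of `"pocket"`,
#'   `"lumen"`, `"gate"`, `"membrane"`, `"fenestration"`), `score_base`
#'   (interface REU).
#' @param rod_atoms Number of rod heavy atoms (default 9).
#' @param sd_score Interface-score noise SD in REU (default 0.5).
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(n_poses = 50L,
                          clusters = list(
                            list(weight = 0.8, mean = c(z = -7, l = 12, phi = 90),
                                 sd = c(0.25, 0.15, 2.5), region = "pocket",
                                 score_base = -19),
                            list(weight = 0.2, mean = c(z = -12, l = 10, phi = 20),
                                 sd = c(0.25, 0.15, 2.5), region = "lumen",
                                 score_base = -15)
                          ),
                          rod_atoms = 9L, sd_score = 0.5) {
  w <- vapply(clusters, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) stop("spec error: cluster weights must sum to 1")
  if (any(vapply(clusters, function(cl) any(cl$sd < 0), logical(1)))) {
    stop("spec error: descriptor sds must be non-negative")
  }
  structure(list(n_poses = as.integer(n_poses), clusters = clusters,
                 rod_atoms = as.integer(rod_atoms), sd_score = sd_score),
            class = "ensemble_spec")
}

# build a rod ligand pose: m collinear carbons of length l, centred at com,
# oriented along the unit vector u (frame: construction coordinates)
.rod_pose <- function(pose_id, com, u, l, m) {
  ts <- (seq_len(m) - 1) / (m - 1) - 0.5
  xyz <- t(vapply(ts, function(t) com + t * l * u, numeric(3)))
  data.frame(
    chain = "X", resno = 1L, resid = "LIG",
    elety = paste0("C", seq_len(m)), elesy = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], het = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic pose ensemble with planted ground truth
#'
#' Samples cluster memberships and descriptor triples from the mixture in
#' `espec`, realises each pose as a rigid rod at the sampled (z, phi) with a
#' random azimuth, places its centre of mass according to the cluster's
#' region tag (pocket poses at a pocket anchor, lumen poses on the axis,
#' gate poses below the gate, fenestration poses at a fenestration anchor,
#' membrane poses radially outside the protein), and draws interface scores
#' from the cluster's score model. Ground-truth labels, realised cluster
#' sizes and occupancy percentages are emitted alongside; tests consume
#' these truth values rather than re-deriving them.
#'
#' @param scaffold Result of [make_scaffold()].
#' @param espec An [ensemble_spec()].
#' @param seed Integer seed; the same seed reproduces the ensemble exactly.
#' @return List with `poses` (list of `ligand_pose`), `scores` (score
#'   table), `truth` (list: `labels`, `sizes`, `regions`, `n_pocket`,
#'   `pct_pocket`, `endpoint_atoms`, `descriptors`).
#' @export
make_pose_ensemble <- function(scaffold, espec = ensemble_spec(), seed = 1L) {
  stopifnot(inherits(espec, "ensemble_spec"))
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }
  truth <- scaffold$truth
  sf_z <- truth$sf_com[3]
  n <- espec$n_poses
  w <- vapply(espec$clusters, `[[`, numeric(1), "weight")
  labels <- sample(seq_along(w), n, replace = TRUE, prob = w)

  poses <- vector("list", n)
  iface <- numeric(n)
  regions <- character(n)
  desc_truth <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("z", "l", "phi")))
  chains <- names(.chain_azimuths)

  for (i in seq_len(n)) {
    cl <- espec$clusters[[labels[i]]]
    z <- stats::rnorm(1, cl$mean[["z"]], cl$sd[1])
    l <- max(0.5, stats::rnorm(1, cl$mean[["l"]], cl$sd[2]))
    phi <- min(180, max(0, stats::rnorm(1, cl$mean[["phi"]], cl$sd[3])))
    psi <- stats::runif(1, 0, 360) * pi / 180
    u <- c(sin(phi * pi / 180) * cos(psi), sin(phi * pi / 180) * sin(psi),
           cos(phi * pi / 180))
    region <- cl$region
    com_xy <- switch(region,
      pocket = {
        k <- sample(4L, 1)
        a <- truth$pocket_anchors[[chains[k]]]
        c(a[["x"]], a[["y"]]) + stats::runif(2, -0.7, 0.7)
      },
      fenestration = {
        k <- sample(4L, 1)
        a <- truth$fen_anchors[[chains[k]]]
        c(a[["x"]], a[["y"]]) + stats::runif(2, -0.7, 0.7)
      },
      lumen = {
        r <- stats::runif(1, 0, 1.5); th <- stats::runif(1, 0, 2 * pi)
        c(r * cos(th), r * sin(th))
      },
      gate = {
        r <- stats::runif(1, 0, 1.5); th <- stats::runif(1, 0, 2 * pi)
        c(r * cos(th), r * sin(th))
      },
      membrane = {
        th <- stats::runif(1, 0, 2 * pi)
        (truth$membrane_radius + 3) * c(cos(th), sin(th))
      },
      stop("spec error: unknown region tag '", region, "'")
    )
    com <- c(com_xy, sf_z + z)
    id <- sprintf("pose_%04d", i)
    atoms <- .rod_pose(id, com, u, l, espec$rod_atoms)
    iface[i] <- cl$score_base + stats::rnorm(1, 0, espec$sd_score)
    regions[i] <- region
    desc_truth[i, ] <- c(z, l, phi)
    poses[[i]] <- .pose_from_atoms(id, atoms)
  }

  ids <- vapply(poses, `[[`, character(1), "pose_id")
  total <- -1000 + iface + stats::rnorm(n, 0, 2)
  scores <- data.frame(pose_id = ids, total_score = total,
                       interface_delta_X = iface, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    poses[[i]]$total_score <- total[i]
    poses[[i]]$interface_score <- iface[i]
  }

  # realised pocket occupancy: any heavy atom within the default capture
  # radius (5 A) of a pocket anchor, measured on the constructed coordinates
  anchor_mat <- do.call(rbind, lapply(truth$pocket_anchors, as.numeric))
  anchor_mat[, 3] <- anchor_mat[, 3] + sf_z
  in_pocket <- vapply(poses, function(p) {
    any(.cross_dist(.coords(p$atoms), anchor_mat) <= 5.0)
  }, logical(1))

  sizes <- tabulate(labels, nbins = length(w))
  truth_out <- list(
    labels = stats::setNames(labels, ids),
    sizes = sizes,
    regions = stats::setNames(regions, ids),
    in_pocket = stats::setNames(in_pocket, ids),
    n_pocket = sum(in_pocket),
    pct_pocket = 100 * sum(in_pocket) / n,
    n_pocket_tagged = sum(regions == "pocket"),
    endpoint_atoms = c(a = "C1", b = paste0("C", espec$rod_atoms)),
    descriptors = data.frame(pose_id = ids, desc_truth,
                             stringsAsFactors = FALSE)
  )
  list(poses = poses, scores = scores, truth = truth_out)
}

#' Write a synthetic ensemble to disk
#'
#' Standard artifacts: one PDB per pose, a Rosetta-style `.sc` score table,
#' and a `truth.json` with the planted ground truth.
#'
#' @param ensemble Result of [make_pose_ensemble()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_ensemble <- function(ensemble, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_pose_pdb(ensemble$poses, file.path(dir, "poses"))
  write_score_table(ensemble$scores, file.path(dir, "scores.sc"))
  tr <- ensemble$truth
  tr$labels <- as.list(tr$labels)
  tr$regions <- as.list(tr$regions)
  tr$in_pocket <- as.list(tr$in_pocket)
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}
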