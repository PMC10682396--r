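#' Default geometric interaction thresholds
#'
#' Distance/angle criteria (Angstrom, degrees) in the style of the published
#' behaviour of standard protein-ligand interaction profilers; all
#' configurable.
#'
#' @return Named list of thresholds.
#' @export
default_interaction_thresholds <- function() {
  list(
    hydrophobic_max = 4.0,
    hbond_max = 4.1, hbond_noH_max = 3.5, hbond_angle_min = 100,
    halogen_max = 4.0,
    pistack_parallel_max = 5.5, pistack_perp_max = 7.5,
    pistack_offset_max = 2.0, pistack_parallel_angle = 30,
    pistack_perp_angle = 60,
    cation_pi_max = 6.0,
    salt_bridge_max = 5.5
  )
}

# --- protein residue typing (coarse, atom-name based) -----------------------

.protein_donors <- list(
  ALL = "N",
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", TRP = "NE1",
  HIS = c("ND1", "NE2"), LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
  ASN = "ND2", GLN = "NE2"
)
.protein_acceptors <- list(
  ALL = "O",
  SER = "OG", THR = "OG1", TYR = "OH", MET = "SD",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2")
)
.protein_rings <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)
.protein_pos_centers <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ"
)
.protein_neg_centers <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
)

# --- ligand templates -------------------------------------------------------

.ligand_templates <- new.env(parent = emptyenv())

#' Register a ligand typing template
#'
#' Interaction detection needs chemical typing of ligand atoms (hydrogen-bond
#' donors/acceptors, aromatic rings, charged groups, halogens bonded to
#' carbon). Templates are keyed by the ligand residue name. Ligands without a
#' template fall back to element-based rules: O/N treated as both donor and
#' acceptor, F/Cl/Br/I as halogen-bond donors, carbons as hydrophobic; no
#' rings or formal charges are inferred (a one-time warning is emitted).
#'
#' @param resname Ligand residue name (e.g. `"LIG"`).
#' @param donors,acceptors Atom-name vectors of H-bond donors/acceptors.
#' @param halogens Atom names of halogens available for halogen bonding.
#' @param rings List of atom-name vectors, one per aromatic ring.
#' @param charged_pos,charged_neg Lists of atom-name vectors defining
#'   positive/negative charge centres (centroids).
#' @param hydrophobic Atom names of hydrophobic (carbon) atoms; `NULL` means
#'   all carbons.
#' @return Invisibly, the stored template.
#' @export
register_ligand_template <- function(resname, donors = character(0),
                                     acceptors = character(0),
                                     halogens = character(0),
                                     rings = list(),
                                     charged_pos = list(),
                                     charged_neg = list(),
                                     hydrophobic = NULL) {
  tpl <- list(donors = donors, acceptors = acceptors, halogens = halogens,
              rings = rings, charged_pos = charged_pos,
              charged_neg = charged_neg, hydrophobic = hydrophobic)
  assign(resname, tpl, envir = .ligand_templates)
  invisible(tpl)
}

.builtin_templates <- function() {
  # synthetic rod ligand: plain hydrophobic carbons
  register_ligand_template("LIG")
  # bent three-arm test ligand
  register_ligand_template("TRI")
  # benzene-like aromatic test ligand
  register_ligand_template("BNZ",
    rings = list(c("C1", "C2", "C3", "C4", "C5", "C6")))
}

.ligand_typing <- function(atoms, resname) {
  if (!length(ls(.ligand_templates))) .builtin_templates()
  heavy <- atoms[atoms$elesy != "H", , drop = FALSE]
  if (exists(resname, envir = .ligand_templates, inherits = FALSE)) {
    tpl <- get(resname, envir = .ligand_templates, inherits = FALSE)
    hydro <- tpl$hydrophobic
    if (is.null(hydro)) hydro <- heavy$elety[heavy$elesy == "C"]
    tpl$hydrophobic <- hydro
    return(tpl)
  }
  warning("no typing template for ligand '", resname,
          "'; using element-based fallback rules", call. = FALSE)
  halo <- heavy$elety[heavy$elesy %in% c("F", "CL", "BR", "I")]
  list(
    donors = heavy$elety[heavy$elesy %in% c("N", "O")],
    acceptors = heavy$elety[heavy$elesy %in% c("N", "O")],
    halogens = halo,
    rings = list(), charged_pos = list(), charged_neg = list(),
    hydrophobic = heavy$elety[heavy$elesy == "C"]
  )
}

# centroid and unit normal of a ring given its atom coordinates
.ring_geometry <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(center = ctr, normal = .unit(sv$v[, 3]))
}

# perpendicular offset between two ring centres: displacement of one centre
# projected into the other ring's plane (minimum over both rings)
.ring_offset <- function(g1, g2) {
  v <- g2$center - g1$center
  o1 <- sqrt(max(0, sum(v^2) - sum(v * g1$normal)^2))
  o2 <- sqrt(max(0, sum(v^2) - sum(v * g2$normal)^2))
  min(o1, o2)
}

.lig_coords <- function(atoms, names_) {
  idx <- match(names_, atoms$elety)
  idx <- idx[!is.na(idx)]
  .coords(atoms)[idx, , drop = FALSE]
}

#' Detect geometric protein-ligand interactions
#'
#' Applies simplified geometric criteria for seven interaction categories:
#' hydrophobic contacts (C...C), hydrogen bonds (heavy-atom donor-acceptor
#' distance, with the donor-angle test applied only when the pose carries
#' hydrogens; otherwise the record is flagged `no-H`), halogen bonds,
#' parallel and perpendicular pi-stacking (ring centroid distance, normal
#' angle and in-plane offset), cation-pi, and salt bridges between
#' residue-level charge centres. Hydrophobic contacts are deduplicated to one
#' record per residue/ligand-atom pair at the minimum distance. Records are
#' sorted by (type, chain, residue number).
#'
#' @param model A `channel_model`.
#' @param pose A `ligand_pose` in the model frame.
#' @param thresholds See [default_interaction_thresholds()].
#' @return Data frame of interaction records: `type`, `chain`, `resno`,
#'   `resid`, `res_atom`, `lig_atom`, `distance`, `angle` (NA where not
#'   applicable), `criterion`.
#' @export
detect_interactions <- function(model, pose,
                                thresholds = default_interaction_thresholds()) {
  th <- thresholds
  prot <- model$atoms[!model$atoms$het, , drop = FALSE]
  lig <- pose$atoms
  lig_heavy <- lig[lig$elesy != "H", , drop = FALSE]
  has_h <- any(lig$elesy == "H") && any(prot$elesy == "H")
  typing <- .ligand_typing(lig, lig$resid[1])

  recs <- list()
  add <- function(type, chain, resno, resid, res_atom, lig_atom, distance,
                  angle = NA_real_, criterion = "geometric") {
    recs[[length(recs) + 1L]] <<- data.frame(
      type = type, chain = chain, resno = resno, resid = resid,
      res_atom = res_atom, lig_atom = lig_atom, distance = distance,
      angle = angle, criterion = criterion, stringsAsFactors = FALSE
    )
  }

  pxyz <- .coords(prot)
  lxyz <- .coords(lig_heavy)

  ## hydrophobic: protein carbons vs ligand hydrophobic carbons
  pc <- which(prot$elesy == "C")
  lc <- which(lig_heavy$elety %in% typing$hydrophobic)
  if (length(pc) && length(lc)) {
    d <- .cross_dist(pxyz[pc, , drop = FALSE], lxyz[lc, , drop = FALSE])
    hit <- which(d <= th$hydrophobic_max, arr.ind = TRUE)
    if (nrow(hit)) {
      key <- paste(prot$chain[pc[hit[, 1]]], prot$resno[pc[hit[, 1]]],
                   lig_heavy$elety[lc[hit[, 2]]])
      for (grp in split(seq_len(nrow(hit)), key)) {
        i <- grp[which.min(d[hit[grp, , drop = FALSE]])]
        pi_ <- pc[hit[i, 1]]; li <- lc[hit[i, 2]]
        add("hydrophobic", prot$chain[pi_], prot$resno[pi_], prot$resid[pi_],
            prot$elety[pi_], lig_heavy$elety[li], d[hit[i, 1], hit[i, 2]])
      }
    }
  }

  ## hydrogen bonds: both donor->acceptor directions on heavy atoms
  hb_pairs <- function(don_idx, acc_xyz, acc_names, donor_is_protein) {
    if (!length(don_idx) || !nrow(acc_xyz)) return()
    dmax <- if (has_h) th$hbond_max else th$hbond_noH_max
    dxyz <- if (donor_is_protein) pxyz[don_idx, , drop = FALSE] else
      .lig_coords(lig_heavy, don_idx)
    d <- .cross_dist(dxyz, acc_xyz)
    hit <- which(d <= dmax & d > 0, arr.ind = TRUE)
    for (i in seq_len(nrow(hit))) {
      ang <- NA_real_
      crit <- if (has_h) "D-H...A" else "no-H"
      if (donor_is_protein) {
        pi_ <- don_idx[hit[i, 1]]
        if (has_h) {
          ang <- .donor_angle(pxyz[pi_, ], prot, pxyz,
                              acc_xyz[hit[i, 2], ])
          if (!is.na(ang) && ang < th$hbond_angle_min) next
        }
        add("hbond", prot$chain[pi_], prot$resno[pi_], prot$resid[pi_],
            prot$elety[pi_], acc_names[hit[i, 2]], d[hit[i, 1], hit[i, 2]],
            ang, crit)
      } else {
        # ligand donor, protein acceptor: record carries the protein residue
        acc_i <- attr(acc_xyz, "prot_idx")[hit[i, 2]]
        add("hbond", prot$chain[acc_i], prot$resno[acc_i], prot$resid[acc_i],
            prot$elety[acc_i], don_idx[hit[i, 1]], d[hit[i, 1], hit[i, 2]],
            ang, crit)
      }
    }
  }
  sel_prot_atoms <- function(table) {
    idx <- integer(0)
    for (i in seq_len(nrow(prot))) {
      allowed <- c(table[["ALL"]], table[[prot$resid[i]]])
      if (prot$elety[i] %in% allowed) idx <- c(idx, i)
    }
    idx
  }
  pd <- sel_prot_atoms(.protein_donors)
  pa <- sel_prot_atoms(.protein_acceptors)
  lig_acc_xyz <- .lig_coords(lig_heavy, typing$acceptors)
  hb_pairs(pd, lig_acc_xyz,
           typing$acceptors[typing$acceptors %in% lig_heavy$elety],
           donor_is_protein = TRUE)
  pa_xyz <- pxyz[pa, , drop = FALSE]
  attr(pa_xyz, "prot_idx") <- pa
  hb_pairs(typing$donors[typing$donors %in% lig_heavy$elety], pa_xyz, NULL,
           donor_is_protein = FALSE)

  ## halogen bonds: ligand halogen vs protein acceptor
  if (length(typing$halogens) && length(pa)) {
    hx <- .lig_coords(lig_heavy, typing$halogens)
    if (nrow(hx)) {
      d <- .cross_dist(hx, pxyz[pa, , drop = FALSE])
      hit <- which(d <= th$halogen_max, arr.ind = TRUE)
      for (i in seq_len(nrow(hit))) {
        acc_i <- pa[hit[i, 2]]
        add("halogen_bond", prot$chain[acc_i], prot$resno[acc_i],
            prot$resid[acc_i], prot$elety[acc_i],
            typing$halogens[hit[i, 1]], d[hit[i, 1], hit[i, 2]])
      }
    }
  }

  ## pi-stacking and cation-pi need protein rings per residue instance
  prot_rings <- list()
  ring_res <- unique(prot[prot$resid %in% names(.protein_rings),
                          c("chain", "resno", "resid")])
  if (nrow(ring_res)) {
    for (i in seq_len(nrow(ring_res))) {
      names_ <- .protein_rings[[ring_res$resid[i]]]
      sel <- prot$chain == ring_res$chain[i] & prot$resno == ring_res$resno[i] &
        prot$elety %in% names_
      if (sum(sel) >= length(names_)) {
        prot_rings[[length(prot_rings) + 1L]] <- c(
          ring_res[i, ], list(geom = .ring_geometry(pxyz[sel, , drop = FALSE]))
        )
      }
    }
  }
  lig_rings <- lapply(typing$rings, function(names_) {
    xyz <- .lig_coords(lig_heavy, names_)
    if (nrow(xyz) >= 3) .ring_geometry(xyz) else NULL
  })
  lig_rings <- Filter(Negate(is.null), lig_rings)

  for (pr in prot_rings) {
    for (lr in lig_rings) {
      dc <- sqrt(sum((pr$geom$center - lr$center)^2))
      ang <- .angle_deg(pr$geom$normal, lr$normal)
      ang <- min(ang, 180 - ang)
      off <- .ring_offset(pr$geom, lr)
      if (off > th$pistack_offset_max) next
      if (ang <= th$pistack_parallel_angle && dc <= th$pistack_parallel_max) {
        add("pi_stack_parallel", pr$chain, pr$resno, pr$resid, "ring", "ring",
            dc, ang)
      } else if (ang >= th$pistack_perp_angle && dc <= th$pistack_perp_max) {
        add("pi_stack_perpendicular", pr$chain, pr$resno, pr$resid, "ring",
            "ring", dc, ang)
      }
    }
  }

  ## charge centres
  centers_of <- function(table) {
    out <- list()
    res <- unique(prot[prot$resid %in% names(table), c("chain", "resno", "resid")])
    for (i in seq_len(nrow(res))) {
      names_ <- table[[res$resid[i]]]
      sel <- prot$chain == res$chain[i] & prot$resno == res$resno[i] &
        prot$elety %in% names_
      if (any(sel)) {
        out[[length(out) + 1L]] <- c(res[i, ],
                                     list(xyz = colMeans(pxyz[sel, , drop = FALSE])))
      }
    }
    out
  }
  prot_pos <- centers_of(.protein_pos_centers)
  prot_neg <- centers_of(.protein_neg_centers)
  lig_charge <- function(groups) {
    lapply(groups, function(names_) {
      xyz <- .lig_coords(lig_heavy, names_)
      if (nrow(xyz)) colMeans(xyz) else NULL
    })
  }
  lig_pos <- Filter(Negate(is.null), lig_charge(typing$charged_pos))
  lig_neg <- Filter(Negate(is.null), lig_charge(typing$charged_neg))

  ## cation-pi: protein cation vs ligand ring, and ligand cation vs protein ring
  for (pp in prot_pos) {
    for (lr in lig_rings) {
      dc <- sqrt(sum((pp$xyz - lr$center)^2))
      if (dc <= th$cation_pi_max) {
        add("cation_pi", pp$chain, pp$resno, pp$resid, "charge", "ring", dc)
      }
    }
  }
  for (lp in lig_pos) {
    for (pr in prot_rings) {
      dc <- sqrt(sum((lp - pr$geom$center)^2))
      if (dc <= th$cation_pi_max) {
        add("cation_pi", pr$chain, pr$resno, pr$resid, "ring", "charge", dc)
      }
    }
  }

  ## salt bridges
  bridge <- function(prot_centers, lig_centers) {
    for (pc_ in prot_centers) {
      for (lc_ in lig_centers) {
        dc <- sqrt(sum((pc_$xyz - lc_)^2))
        if (dc <= th$salt_bridge_max) {
          add("salt_bridge", pc_$chain, pc_$resno, pc_$resid, "charge",
              "charge", dc)
        }
      }
    }
  }
  bridge(prot_pos, lig_neg)
  bridge(prot_neg, lig_pos)

  if (!length(recs)) {
    return(data.frame(type = character(0), chain = character(0),
                      resno = integer(0), resid = character(0),
                      res_atom = character(0), lig_atom = character(0),
                      distance = numeric(0), angle = numeric(0),
                      criterion = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  out[order(out$type, out$chain, out$resno), , drop = FALSE]
}

# donor angle D-H...A using the hydrogen bonded to the donor (within 1.3 A)
.donor_angle <- function(donor_xyz, prot, pxyz, acc_xyz) {
  h_idx <- which(prot$elesy == "H")
  if (!length(h_idx)) return(NA_real_)
  dh <- .cross_dist(matrix(donor_xyz, ncol = 3), pxyz[h_idx, , drop = FALSE])
  near <- h_idx[dh <= 1.3]
  if (!length(near)) return(NA_real_)
  max(vapply(near, function(h) {
    .angle_deg(donor_xyz - pxyz[h, ], acc_xyz - pxyz[h, ])
  }, numeric(1)))
}

#' Aggregate interaction records into key residues
#'
#' Unique residue labels (one-letter code + residue number for standard amino
#' acids), ranked by record count and then residue number, with the number of
#' distinct chains contacted reported as multiplicity.
#'
#' @param records Interaction records from [detect_interactions()].
#' @param min_chains Keep only residues contacted on at least this many
#'   chains (default 1).
#' @return Data frame with `label`, `resid`, `resno`, `n_records`,
#'   `n_chains`.
#' @export
key_residues <- function(records, min_chains = 1L) {
  if (!nrow(records)) {
    return(data.frame(label = character(0), resid = character(0),
                      resno = integer(0), n_records = integer(0),
                      n_chains = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(records$resid, records$resno)
  agg <- do.call(rbind, lapply(split(records, key), function(g) {
    one <- suppressWarnings(bio3d::aa321(g$resid[1]))
    if (is.na(one) || one == "X") one <- g$resid[1]
    data.frame(label = paste0(one, g$resno[1]), resid = g$resid[1],
               resno = g$resno[1], n_records = nrow(g),
               n_chains = length(unique(g$chain)), stringsAsFactors = FALSE)
  }))
  agg <- agg[agg$n_chains >= min_chains, , drop = FALSE]
  agg <- agg[order(-agg$n_records, agg$resno), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Write interaction records as TSV
#'
#' @param records Data frame from [detect_interactions()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_interaction_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
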