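# hexagonal ring coordinates in the xy plane at height z, ring radius 1.39 A
hex_ring <- function(z = 0, center = c(0, 0), radius = 1.39) {
  az <- (0:5) * pi / 3
  cbind(center[1] + radius * cos(az), center[2] + radius * sin(az), z)
}

tyr_ring_model <- function(z = 0) {
  make_tiny_model(make_atoms(
    c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    as.vector(t(hex_ring(z))), resid = "TYR", chain = "A", resno = 652L,
    het = FALSE
  ))
}

benzene_pose <- function(z, angle = 0, center = c(0, 0)) {
  xyz <- hex_ring(z, center)
  if (angle != 0) {
    R <- porepose:::.rotation_about_axis(c(1, 0, 0), angle)
    ctr <- colMeans(xyz)
    xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, "+")
  }
  make_pose("bz", make_atoms(paste0("C", 1:6), as.vector(t(xyz)),
                             resid = "BNZ"))
}

test_that("parallel and perpendicular pi-stacking follow the geometric criteria", {
  model <- tyr_ring_model(0)
  rec <- detect_interactions(model, benzene_pose(z = 3.8))
  stack <- rec[rec$type == "pi_stack_parallel", ]
  expect_equal(nrow(stack), 1L)
  expect_equal(stack$resno, 652L)
  expect_equal(stack$distance, 3.8, tolerance = 1e-6)

  perp <- detect_interactions(model, benzene_pose(z = 5.5, angle = 90))
  expect_equal(nrow(perp[perp$type == "pi_stack_perpendicular", ]), 1L)

  # too large an in-plane offset suppresses stacking
  off <- detect_interactions(model, benzene_pose(z = 3.8, center = c(3, 0)))
  expect_equal(nrow(off[grepl("pi_stack", off$type), ]), 0L)

  # far apart: nothing at all
  none <- detect_interactions(model, benzene_pose(z = 25))
  expect_equal(nrow(none), 0L)
})

test_that("heavy-atom hydrogen bonds are detected with the no-H criterion", {
  model <- make_tiny_model(make_atoms(
    c("CB", "OG"), c(0, 0, 0, 0, 0, 1.4), elesy = c("C", "O"),
    resid = "SER", chain = "B", resno = 624L, het = FALSE
  ))
  register_ligand_template("CBO", acceptors = "O1")
  lig <- make_pose("cb", make_atoms(c("C1", "O1"),
                                    c(0, 3, 4.4, 0, 0, 4.4),
                                    elesy = c("C", "O"), resid = "CBO"))
  rec <- detect_interactions(model, lig)
  hb <- rec[rec$type == "hbond", ]
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$criterion, "no-H")
  expect_equal(hb$distance, 3.0, tolerance = 1e-6)
  expect_equal(hb$res_atom, "OG")

  # past the heavy-atom cutoff: no bond
  lig_far <- make_pose("cf", make_atoms(c("C1", "O1"),
                                        c(0, 5, 4.4, 0, 3.7, 4.4),
                                        elesy = c("C", "O"), resid = "CBO"))
  rec2 <- detect_interactions(model, lig_far)
  expect_equal(nrow(rec2[rec2$type == "hbond", ]), 0L)
})

test_that("halogen bonds and salt bridges use element and charge typing", {
  model <- make_tiny_model(rbind(
    make_atoms(c("C", "O"), c(0, 0, 0, 0, 0, 1.2), elesy = c("C", "O"),
               resid = "GLY", chain = "A", resno = 648L, het = FALSE),
    make_atoms(c("CZ", "NH1", "NH2", "NE"),
               c(8, 0, 0, 8, 1, 0, 8, -1, 0, 8, 0, 1),
               elesy = c("C", "N", "N", "N"),
               resid = "ARG", chain = "A", resno = 665L, het = FALSE)
  ))
  register_ligand_template("XLG", halogens = "F1",
                           charged_neg = list(c("O2", "O3")))
  lig <- make_pose("xl", make_atoms(
    c("C1", "F1", "O2", "O3"),
    c(0, 2, 4.2, 0, 0.5, 3.0, 8, 3, 1, 8, 4, 1),
    elesy = c("C", "F", "O", "O"), resid = "XLG"))
  rec <- detect_interactions(model, lig)
  expect_equal(nrow(rec[rec$type == "halogen_bond", ]), 1L)
  expect_equal(rec[rec$type == "halogen_bond", "resno"], 648L)
  sb <- rec[rec$type == "salt_bridge", ]
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$resno, 665L)
})

test_that("cation-pi couples charged centres with aromatic rings", {
  model <- make_tiny_model(make_atoms(
    c("CZ", "NH1", "NH2"), c(0, 0, 4, 0, 1, 4, 0, -1, 4),
    elesy = c("C", "N", "N"), resid = "ARG", chain = "C", resno = 665L,
    het = FALSE))
  rec <- detect_interactions(model, benzene_pose(z = 0))
  cp <- rec[rec$type == "cation_pi", ]
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$chain, "C")
  expect_equal(cp$distance, 4.0, tolerance = 1e-6)
})

test_that("unknown ligands fall back to element rules with a warning", {
  model <- tyr_ring_model(0)
  lig <- make_pose("uk", make_atoms(c("C1", "N1"),
                                    c(0, 0, 3.5, 1.5, 0, 3.5),
                                    elesy = c("C", "N"), resid = "UNK"))
  expect_warning(rec <- detect_interactions(model, lig), "fallback")
  expect_true(all(rec$type %in% c("hydrophobic", "hbond")))
})

test_that("interaction records respect C4 equivariance on the scaffold", {
  sc <- open_scaffold()
  anchor <- as.numeric(sc$truth$pocket_anchors[["A"]]) + c(0, 0, sc$truth$sf_com[3])
  pose <- make_pose("c4", make_atoms(
    paste0("C", 1:3),
    c(anchor[1], anchor[2], anchor[3],
      anchor[1] + 1.2, anchor[2], anchor[3],
      anchor[1], anchor[2] + 1.2, anchor[3])))
  rec_a <- detect_interactions(sc$model, pose)
  expect_gt(nrow(rec_a), 0)
  rec_b <- detect_interactions(
    sc$model, rotate_pose_z(pose, 90, center = sc$model$frame$origin))
  chain_map <- c(A = "B", B = "C", C = "D", D = "A")
  expect_equal(nrow(rec_b), nrow(rec_a))
  key_a <- paste(rec_a$type, chain_map[rec_a$chain], rec_a$resno, rec_a$lig_atom)
  key_b <- paste(rec_b$type, rec_b$chain, rec_b$resno, rec_b$lig_atom)
  expect_setequal(key_b, key_a)
  ord_a <- order(key_a); ord_b <- order(key_b)
  expect_lt(max(abs(rec_a$distance[ord_a] - rec_b$distance[ord_b])), 1e-6)
})

test_that("records always satisfy their own thresholds and shrink monotonically", {
  sc <- open_scaffold()
  ens <- default_ensemble()
  th <- default_interaction_thresholds()
  pose <- ens$poses[[which(ens$truth$regions == "pocket")[1]]]
  rec <- detect_interactions(sc$model, pose, th)
  expect_gt(nrow(rec), 0)
  lims <- c(hydrophobic = th$hydrophobic_max, hbond = th$hbond_max,
            halogen_bond = th$halogen_max,
            pi_stack_parallel = th$pistack_parallel_max,
            pi_stack_perpendicular = th$pistack_perp_max,
            cation_pi = th$cation_pi_max, salt_bridge = th$salt_bridge_max)
  expect_true(all(rec$distance <= lims[rec$type] + 1e-9))

  th_small <- th
  th_small$hydrophobic_max <- 3.0
  rec_small <- detect_interactions(sc$model, pose, th_small)
  expect_lte(nrow(rec_small), nrow(rec))
  key_small <- paste(rec_small$chain, rec_small$resno, rec_small$lig_atom)
  key_full <- paste(rec$chain, rec$resno, rec$lig_atom)
  expect_true(all(key_small %in% key_full))

  # hydrophobic contacts deduplicate to one record per residue/ligand atom
  expect_false(any(duplicated(
    rec[rec$type == "hydrophobic", c("chain", "resno", "lig_atom")])))
})

test_that("key residues aggregate records by count, residue and chain multiplicity", {
  records <- data.frame(
    type = "hydrophobic",
    chain = c("A", "B", "C", "A"),
    resno = c(652L, 652L, 652L, 624L),
    resid = c("TYR", "TYR", "TYR", "SER"),
    res_atom = "X", lig_atom = "C1", distance = 3.5, angle = NA,
    criterion = "geometric", stringsAsFactors = FALSE
  )
  kr <- key_residues(records)
  expect_equal(kr$label, c("Y652", "S624"))
  expect_equal(kr$n_chains, c(3L, 1L))
  expect_equal(nrow(key_residues(records, min_chains = 2)), 1L)
  expect_equal(nrow(key_residues(records[0, ])), 0L)
})
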