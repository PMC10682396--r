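# Shared fixtures, built once per test run and cached (pore profiling is the
# only expensive step).

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

open_scaffold <- function() cached("open_scaffold", function() {
  make_scaffold(scaffold_spec("open"))
})

closed_scaffold <- function() cached("closed_scaffold", function() {
  make_scaffold(scaffold_spec("closed"))
})

open_profile <- function() cached("open_profile", function() {
  pore_radius_profile(open_scaffold()$model)
})

closed_profile <- function() cached("closed_profile", function() {
  pore_radius_profile(closed_scaffold()$model)
})

open_region_map <- function() cached("open_region_map", function() {
  build_region_map(open_scaffold()$model, open_profile())
})

default_ensemble <- function() cached("default_ensemble", function() {
  make_pose_ensemble(open_scaffold(), ensemble_spec(), seed = 101)
})

default_descriptors <- function() cached("default_descriptors", function() {
  pose_descriptors(default_ensemble()$poses, open_scaffold()$model$frame)
})

# minimal atom table for hand-built poses
make_atoms <- function(elety, xyz, elesy = "C", resid = "LIG", chain = "X",
                       resno = 1L, het = TRUE) {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             elesy = rep_len(elesy, length(elety)),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             het = het, stringsAsFactors = FALSE)
}

make_pose <- function(pose_id, atoms, total_score = -1000,
                      interface_score = -10) {
  structure(list(pose_id = pose_id, atoms = atoms,
                 total_score = total_score,
                 interface_score = interface_score),
            class = "ligand_pose")
}

# minimal channel model wrapper for hand-built protein geometry (no frame)
make_tiny_model <- function(atoms) {
  structure(list(atoms = atoms, chains = sort(unique(atoms$chain[!atoms$het])),
                 residue_config = herg_residue_config(),
                 missing_residues = list(), frame = NULL),
            class = "channel_model")
}

# an axis-aligned frame at the origin
identity_frame <- function(origin = c(0, 0, 0)) {
  structure(list(origin = origin, axis = c(0, 0, 1)), class = "pore_frame")
}

# ring-stack cylinder of carbon atoms (analytic pore oracle geometry)
cylinder_model <- function(bore = 6.0, z_lo = -10, z_hi = 10, step = 0.5,
                           n_ring = 24L) {
  zs <- seq(z_lo, z_hi, by = step)
  rows <- lapply(seq_along(zs), function(j) {
    az <- (seq_len(n_ring) - 0.5) * 2 * pi / n_ring
    make_atoms(
      elety = rep("CA", n_ring),
      xyz = as.vector(t(cbind(bore * cos(az), bore * sin(az), zs[j]))),
      resid = "GLY", chain = "A", resno = 100L + j, het = FALSE
    )
  })
  make_tiny_model(do.call(rbind, rows))
}

cylinder_profile <- function() cached("cylinder_profile", function() {
  pore_radius_profile(cylinder_model(), frame = identity_frame(),
                      z_range = c(-8, 8))
})

# rotate a pose (or any atoms data frame) about the z axis through a point
rotate_pose_z <- function(pose, angle_deg, center = c(0, 0, 0)) {
  R <- porepose:::.rotation_about_axis(c(0, 0, 1), angle_deg)
  xyz <- as.matrix(pose$atoms[, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, center) %*% t(R), 2, center, "+")
  pose$atoms$x <- xyz[, 1]; pose$atoms$y <- xyz[, 2]; pose$atoms$z <- xyz[, 3]
  pose
}

# brute-force double-loop dissimilarity oracle (kept deliberately naive)
brute_similarity_matrix <- function(descriptors, root = TRUE) {
  norms <- descriptor_norms(descriptors)
  n <- nrow(descriptors)
  m <- matrix(0, n, n, dimnames = list(descriptors$pose_id, descriptors$pose_id))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- pose_similarity(descriptors[i, ], descriptors[j, ], norms,
                                 root = root)
    }
  }
  m
}

# planted multi-cluster ensemble spec for recovery experiments: K clusters on
# a grid in (z, l, phi) with spreads far below the inter-center separation
recovery_spec <- function(K, n_poses = 50L) {
  zs <- seq(-16, -4, length.out = K)
  ls <- seq(9, 13, length.out = K)
  phis <- seq(20, 120, length.out = K)
  w <- rep(1 / K, K)
  clusters <- lapply(seq_len(K), function(k) {
    list(weight = w[k], mean = c(z = zs[k], l = ls[k], phi = phis[k]),
         sd = c(0.3, 0.2, 3), region = "lumen",
         score_base = -20 + 2 * k)
  })
  ensemble_spec(n_poses = n_poses, clusters = clusters)
}
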