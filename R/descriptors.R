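#' Endpoint atoms of a ligand
#'
#' Returns the names of the heavy-atom pair at maximal interatomic distance in
#' the given (reference) pose. Ties are broken by the smallest lexicographic
#' `(name_a, name_b)` pair (each pair sorted alphabetically first). The same
#' atom identities are then reused for every pose of the same ligand, so the
#' end-to-end length l and tilt angle remain comparable across an ensemble.
#'
#' @param atoms Atom data frame of a pose (or a `ligand_pose`).
#' @return Character vector `c(a, b)` of the two endpoint atom names.
#' @export
endpoint_atoms <- function(atoms) {
  if (inherits(atoms, "ligand_pose")) atoms <- atoms$atoms
  heavy <- atoms[atoms$elesy != "H", , drop = FALSE]
  if (nrow(heavy) < 2L) stop("descriptor error: fewer than 2 heavy atoms")
  d <- as.matrix(stats::dist(.coords(heavy)))
  dmax <- max(d)
  hits <- which(d >= dmax - 1e-9, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  pairs <- t(apply(hits, 1, function(ij) sort(heavy$elety[ij])))
  best <- order(pairs[, 1], pairs[, 2])[1]
  c(a = unname(pairs[best, 1]), b = unname(pairs[best, 2]))
}

.endpoint_coords <- function(atoms, endpoints) {
  get1 <- function(nm) {
    i <- which(atoms$elety == nm & atoms$elesy != "H")[1]
    if (is.na(i)) stop("descriptor error: endpoint atom '", nm, "' missing in pose")
    as.numeric(atoms[i, c("x", "y", "z")])
  }
  list(a = get1(endpoints[["a"]]), b = get1(endpoints[["b"]]))
}

#' Compute the pose descriptor triple (z, l, phi)
#'
#' For one pose: `z` is the ligand heavy-atom centre of mass projected on the
#' pore axis, relative to the SF C-alpha centre of mass (the frame origin);
#' `l` is the distance between the two endpoint atoms; `phi` is the polar
#' angle (degrees, in \[0, 180\]) between the oriented endpoint vector a->b
#' and the +z axis. All three are invariant to rotation about the pore axis,
#' which is what makes the descriptor respect the channel's 4-fold symmetry.
#'
#' @param pose A `ligand_pose` (or atom data frame).
#' @param frame A `pore_frame`.
#' @param endpoints Endpoint atom names from [endpoint_atoms()].
#' @return Named numeric vector `c(z, l, phi)`.
#' @export
pose_descriptor <- function(pose, frame, endpoints) {
  atoms <- if (inherits(pose, "ligand_pose")) pose$atoms else pose
  heavy <- atoms[atoms$elesy != "H", , drop = FALSE]
  if (nrow(heavy) < 2L) stop("descriptor error: fewer than 2 heavy atoms")
  axis <- .unit(frame$axis)
  com <- colMeans(.coords(heavy))
  ep <- .endpoint_coords(atoms, endpoints)
  v <- ep$b - ep$a
  l <- sqrt(sum(v^2))
  if (l <= 0) stop("descriptor error: coincident endpoint atoms")
  c(z = sum((com - frame$origin) * axis), l = l, phi = .angle_deg(v, axis))
}

#' Descriptor table for a pose ensemble
#'
#' Computes (z, l, phi) for every pose against a common frame. Endpoint atoms
#' default to the maximal-distance heavy-atom pair of the first pose and are
#' held fixed across the ensemble.
#'
#' @param poses List of `ligand_pose` objects.
#' @param frame A `pore_frame`.
#' @param endpoints Optional endpoint atom names; derived from the first pose
#'   when `NULL`.
#' @return Data frame with columns `pose_id`, `z`, `l`, `phi`, and (when
#'   available on the poses) `total_score`, `interface_score`; the endpoint
#'   names are attached as attribute `"endpoints"`.
#' @export
pose_descriptors <- function(poses, frame, endpoints = NULL) {
  if (!length(poses)) stop("empty pose list")
  if (is.null(endpoints)) endpoints <- endpoint_atoms(poses[[1]])
  rows <- t(vapply(poses, pose_descriptor, numeric(3),
                   frame = frame, endpoints = endpoints))
  out <- data.frame(
    pose_id = vapply(poses, `[[`, character(1), "pose_id"),
    z = rows[, "z"], l = rows[, "l"], phi = rows[, "phi"],
    total_score = vapply(poses, `[[`, numeric(1), "total_score"),
    interface_score = vapply(poses, `[[`, numeric(1), "interface_score"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "endpoints") <- endpoints
  out
}

#' Normalisation constants over a descriptor ensemble
#'
#' Component-wise minima and maxima of (z, l, phi) over exactly the ensemble
#' being clustered (not any larger docking pool).
#'
#' @param descriptors Descriptor data frame from [pose_descriptors()].
#' @return List with elements `z`, `l`, `phi`, each `c(min, max)`.
#' @export
descriptor_norms <- function(descriptors) {
  lapply(descriptors[c("z", "l", "phi")], range)
}

.norm_term <- function(x, xref, rng) {
  span <- rng[2] - rng[1]
  if (span <= 0) return(0)          # degenerate range contributes nothing
  (x - xref) / span
}

#' Pairwise pose dissimilarity in normalised descriptor space
#'
#' The distance between two descriptor triples after range normalisation of
#' each component over the ensemble: the square root of the sum of the three
#' squared normalised differences (Euclidean distance in the unit-normalised
#' space). A component whose ensemble range is degenerate (max == min)
#' contributes zero. Smaller values mean more similar poses; the value is 0
#' for identical triples and at most sqrt(3) when both poses lie inside the
#' normalisation ensemble. `root = FALSE` returns the un-rooted sum of
#' squares, which orders pose pairs identically.
#'
#' @param d_i,d_ref Descriptor triples (named vectors or one-row data frames
#'   with `z`, `l`, `phi`).
#' @param norms Normalisation constants from [descriptor_norms()].
#' @param root Apply the square root? Default `TRUE`.
#' @return Non-negative dissimilarity.
#' @export
pose_similarity <- function(d_i, d_ref, norms, root = TRUE) {
  s <- .norm_term(d_i[["z"]], d_ref[["z"]], norms$z)^2 +
    .norm_term(d_i[["l"]], d_ref[["l"]], norms$l)^2 +
    .norm_term(d_i[["phi"]], d_ref[["phi"]], norms$phi)^2
  if (root) sqrt(s) else s
}

# Range-normalise descriptor columns; degenerate ranges map to 0.
.normalised_features <- function(descriptors, norms) {
  f <- vapply(c("z", "l", "phi"), function(cmp) {
    span <- norms[[cmp]][2] - norms[[cmp]][1]
    if (span <= 0) rep(0, nrow(descriptors)) else descriptors[[cmp]] / span
  }, numeric(nrow(descriptors)))
  f <- matrix(f, nrow = nrow(descriptors),
              dimnames = list(descriptors$pose_id, c("z", "l", "phi")))
  f
}

#' Pairwise dissimilarity matrix for a pose ensemble
#'
#' Symmetric matrix of [pose_similarity()] values between all poses, with
#' normalisation constants taken over this ensemble.
#'
#' @param descriptors Descriptor data frame from [pose_descriptors()]
#'   (>= 2 rows, unique pose ids).
#' @param root Apply the square root (see [pose_similarity()])?
#' @return n x n numeric matrix with `pose_id` dimnames, zero diagonal, and
#'   attribute `"norms"`.
#' @export
similarity_matrix <- function(descriptors, root = TRUE) {
  if (nrow(descriptors) < 2L) stop("need at least 2 descriptors")
  if (anyDuplicated(descriptors$pose_id)) stop("duplicate pose_id values")
  norms <- descriptor_norms(descriptors)
  f <- .normalised_features(descriptors, norms)
  m <- as.matrix(stats::dist(f))
  if (!root) m <- m^2
  dimnames(m) <- list(descriptors$pose_id, descriptors$pose_id)
  attr(m, "norms") <- norms
  attr(m, "root") <- root
  m
}

#' Export a descriptor table as TSV
#'
#' @param descriptors Descriptor data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_descriptor_table <- function(descriptors, path) {
  utils::write.table(descriptors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a dissimilarity matrix as TSV
#'
#' Row and column order is the pose-id order of the matrix.
#'
#' @param matrix Matrix from [similarity_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_similarity_matrix <- function(matrix, path) {
  utils::write.table(as.data.frame(matrix), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
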