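#' Leader clustering of a pose dissimilarity matrix
#'
#' Deterministic cutoff/minimum-size clustering: poses are visited in
#' ascending interface-score order (ties by pose id), so the best-scoring
#' poses found clusters. Each pose joins the first existing cluster whose
#' leader is within `cutoff`; otherwise it founds a new cluster with itself
#' as leader. Clusters smaller than `min_size` are then relabelled as noise
#' (`NA`).
#'
#' @param matrix Dissimilarity matrix from [similarity_matrix()].
#' @param interface_scores Named numeric vector of interface scores (REU) for
#'   every pose id in the matrix.
#' @param cutoff Leader-distance cutoff (default 0.3, in normalised
#'   descriptor-space units).
#' @param min_size Minimum cluster size (default 3).
#' @return List with `labels` (named integer vector, `NA` = noise) and
#'   `leaders` (pose id of each cluster's leader, in cluster order).
#' @export
leader_cluster <- function(matrix, interface_scores, cutoff = 0.3, min_size = 3L) {
  stopifnot(cutoff > 0, min_size >= 1)
  ids <- rownames(matrix)
  if (is.null(ids)) stop("matrix must carry pose_id dimnames")
  if (!all(ids %in% names(interface_scores))) {
    stop("interface scores missing for some pose ids")
  }
  sc <- interface_scores[ids]
  order_ids <- ids[order(sc, ids)]
  labels <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  leaders <- character(0)
  for (id in order_ids) {
    joined <- FALSE
    for (k in seq_along(leaders)) {
      if (matrix[id, leaders[k]] <= cutoff) {
        labels[id] <- k
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      leaders <- c(leaders, id)
      labels[id] <- length(leaders)
    }
  }
  sizes <- tabulate(labels, nbins = length(leaders))
  keep <- which(sizes >= min_size)
  relabel <- stats::setNames(rep(NA_integer_, length(leaders)), seq_along(leaders))
  relabel[keep] <- seq_along(keep)
  labels <- relabel[as.character(labels)]
  names(labels) <- ids
  list(labels = labels, leaders = leaders[keep])
}

# Lloyd iterations on the range-normalised (z, l, phi) features, K centers
# initialised at the lowest-interface-score member of each provisional
# cluster. Empty clusters keep their previous center. Noise poses do not
# steer the iterations and are assigned to the nearest *final* center.
.lloyd <- function(features, init_centers, active, max_iter = 100L, tol = 1e-6) {
  centers <- init_centers
  assign_nearest <- function(rows, ctrs) {
    d <- .cross_dist(rows, ctrs)
    apply(d, 1, which.min)   # ties -> lowest cluster index
  }
  labels <- assign_nearest(features[active, , drop = FALSE], centers)
  it <- 0L
  for (it in seq_len(max_iter)) {
    new_centers <- centers
    for (k in seq_len(nrow(centers))) {
      members <- which(labels == k)
      if (length(members)) {
        new_centers[k, ] <- colMeans(features[active, , drop = FALSE][members, , drop = FALSE])
      }
    }
    shift <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    labels <- assign_nearest(features[active, , drop = FALSE], centers)
    if (shift < tol) break
  }
  full <- integer(nrow(features))
  full[active] <- labels
  if (any(!active)) {
    full[!active] <- assign_nearest(features[!active, , drop = FALSE], centers)
  }
  list(labels = full, centers = centers, iterations = it)
}

#' K-means refinement of provisional pose clusters
#'
#' Refines leader-clustering labels by Lloyd's algorithm on the
#' range-normalised (z, l, phi) triples, with K equal to the number of
#' provisional clusters and the centers initialised at the
#' lowest-interface-score member of each provisional cluster. Noise poses do
#' not influence the iterations and are reassigned to the nearest final
#' center, so every pose in the ensemble receives a final label (occupancy
#' percentages are reported over all selected poses).
#'
#' @param descriptors Descriptor data frame including `interface_score`.
#' @param provisional Result of [leader_cluster()].
#' @param norms Normalisation constants; recomputed from `descriptors` when
#'   `NULL`.
#' @param max_iter,tol Lloyd convergence controls.
#' @return A `pose_clusters` object; see [pose_cluster()].
#' @export
kmeans_refine <- function(descriptors, provisional, norms = NULL,
                          max_iter = 100L, tol = 1e-6) {
  ids <- descriptors$pose_id
  prov <- provisional$labels[ids]
  if (is.null(norms)) norms <- descriptor_norms(descriptors)
  features <- .normalised_features(descriptors, norms)
  K <- max(c(0L, prov), na.rm = TRUE)
  if (K == 0L) {
    warning("no non-noise provisional clusters; all poses remain noise",
            call. = FALSE)
    return(.new_pose_clusters(
      descriptors, stats::setNames(rep(NA_integer_, length(ids)), ids),
      prov, centers = NULL, norms = norms,
      params = list(max_iter = max_iter, tol = tol), iterations = 0L
    ))
  }
  init <- matrix(NA_real_, K, 3, dimnames = list(NULL, c("z", "l", "phi")))
  for (k in seq_len(K)) {
    members <- which(prov == k)
    seed <- members[order(descriptors$interface_score[members],
                          ids[members])][1]
    init[k, ] <- features[seed, ]
  }
  fit <- .lloyd(features, init, active = !is.na(prov),
                max_iter = max_iter, tol = tol)
  labels <- stats::setNames(fit$labels, ids)
  .new_pose_clusters(descriptors, labels, prov, fit$centers, norms,
                     params = list(max_iter = max_iter, tol = tol),
                     iterations = fit$iterations)
}

# Assemble the classed result: clusters are relabelled 1..K in rank order
# (descending size, ties by lower representative interface score, then by
# representative pose id).
.new_pose_clusters <- function(descriptors, labels, provisional, centers,
                               norms, params, iterations) {
  ids <- descriptors$pose_id
  summary_df <- NULL
  if (!all(is.na(labels))) {
    K <- max(labels, na.rm = TRUE)
    reps <- integer(K); sizes <- integer(K)
    for (k in seq_len(K)) {
      members <- which(labels == k)
      sizes[k] <- length(members)
      reps[k] <- members[order(descriptors$interface_score[members],
                               ids[members])][1]
    }
    rep_score <- descriptors$interface_score[reps]
    ord <- order(-sizes, rep_score, ids[reps])
    relabel <- match(seq_len(K), ord)
    labels <- stats::setNames(relabel[labels], ids)
    if (!is.null(centers)) centers <- centers[ord, , drop = FALSE]
    summary_df <- data.frame(
      rank = seq_len(K),
      cluster = seq_len(K),
      size = sizes[ord],
      representative_id = ids[reps][ord],
      interface_score = rep_score[ord],
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      labels = labels, provisional = provisional, summary = summary_df,
      centers = centers, norms = norms, params = params,
      iterations = iterations, descriptors = descriptors
    ),
    class = "pose_clusters"
  )
}

#' Two-stage clustering of a docking pose ensemble
#'
#' The central fitting function: computes the pairwise pose dissimilarity
#' matrix from the descriptor table, runs deterministic leader clustering
#' under a cutoff and minimum cluster size, then refines the partition by
#' K-means seeded with the lowest-interface-score member of each provisional
#' cluster. Clusters in the result are numbered in rank order (largest
#' first; ties broken by the lower representative interface score).
#'
#' @param descriptors Descriptor data frame from [pose_descriptors()]
#'   (must include `interface_score`).
#' @param cutoff Leader-clustering cutoff (default 0.3).
#' @param min_size Minimum provisional cluster size (default 3).
#' @param root Use the rooted (Euclidean) dissimilarity? See
#'   [pose_similarity()].
#' @param max_iter,tol K-means controls (defaults 100, 1e-6).
#' @return A `pose_clusters` object with elements `labels` (named integer
#'   vector of final cluster labels), `provisional` (leader-stage labels,
#'   `NA` = noise), `summary` (ranked cluster table: size, representative
#'   pose, interface score in REU), `centers` (normalised-space centers),
#'   `norms`, and the call parameters.
#' @seealso [leader_cluster()], [kmeans_refine()], [cluster_report()]
#' @export
pose_cluster <- function(descriptors, cutoff = 0.3, min_size = 3L,
                         root = TRUE, max_iter = 100L, tol = 1e-6) {
  m <- similarity_matrix(descriptors, root = root)
  sc <- stats::setNames(descriptors$interface_score, descriptors$pose_id)
  prov <- leader_cluster(m, sc, cutoff = cutoff, min_size = min_size)
  out <- kmeans_refine(descriptors, prov, norms = attr(m, "norms"),
                       max_iter = max_iter, tol = tol)
  out$params <- c(out$params, list(cutoff = cutoff, min_size = min_size,
                                   root = root))
  out
}

#' Ranked cluster report
#'
#' One row per final cluster, ranked by descending size with ties broken by
#' the lower representative interface score: cluster size (number of poses)
#' and the representative's interface energy in Rosetta Energy Units.
#'
#' @param clusters A `pose_clusters` object.
#' @return Data frame with columns `rank`, `size`, `representative_id`,
#'   `interface_score`.
#' @export
cluster_report <- function(clusters) {
  stopifnot(inherits(clusters, "pose_clusters"))
  if (is.null(clusters$summary)) {
    return(data.frame(rank = integer(0), size = integer(0),
                      representative_id = character(0),
                      interface_score = numeric(0)))
  }
  clusters$summary[, c("rank", "size", "representative_id", "interface_score")]
}

#' @export
print.pose_clusters <- function(x, ...) {
  n <- length(x$labels)
  K <- if (is.null(x$summary)) 0L else nrow(x$summary)
  cat(sprintf("Pose clustering: %d poses, %d cluster(s)", n, K))
  noise <- sum(is.na(x$provisional))
  if (noise) cat(sprintf(" (%d noise pose(s) reassigned at refinement)", noise))
  cat("\n")
  if (K) {
    top <- x$summary[1, ]
    cat(sprintf("Top cluster: size %d, representative %s (IE %.1f REU)\n",
                top$size, top$representative_id, top$interface_score))
  }
  invisible(x)
}

#' @export
summary.pose_clusters <- function(object, ...) {
  rep <- cluster_report(object)
  cat("Two-stage pose clustering\n")
  cat(sprintf("  cutoff %.3f, min_size %d, %d Lloyd iteration(s)\n",
              object$params$cutoff %||% NA_real_,
              object$params$min_size %||% NA_integer_, object$iterations))
  print(rep, row.names = FALSE)
  invisible(rep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot pose clusters in descriptor space
#'
#' Scatter of (z, l), (z, phi) and (l, phi) coloured by final cluster label,
#' with cluster representatives marked.
#'
#' @param x A `pose_clusters` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pose_clusters <- function(x, ...) {
  d <- x$descriptors
  lab <- x$labels[d$pose_id]
  cols <- grDevices::hcl.colors(max(1, max(lab, na.rm = TRUE)), "Dark 3")
  reps <- if (!is.null(x$summary)) d$pose_id %in% x$summary$representative_id else FALSE
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  panels <- list(c("z", "l"), c("z", "phi"), c("l", "phi"))
  units <- c(z = "z (A)", l = "l (A)", phi = "phi (deg)")
  for (p in panels) {
    graphics::plot(d[[p[1]]], d[[p[2]]], col = cols[lab],
                   pch = ifelse(reps, 17, 19),
                   xlab = units[p[1]], ylab = units[p[2]], ...)
  }
  invisible(x)
}

#' Write cluster assignments and summary as TSV
#'
#' @param clusters A `pose_clusters` object.
#' @param assignments_path,summary_path Output paths (either may be `NULL`
#'   to skip).
#' @return Invisibly, the paths written.
#' @export
write_cluster_tables <- function(clusters, assignments_path = NULL,
                                 summary_path = NULL) {
  if (!is.null(assignments_path)) {
    reps <- if (!is.null(clusters$summary)) clusters$summary$representative_id else character(0)
    df <- data.frame(
      pose_id = names(clusters$labels),
      provisional_label = unname(clusters$provisional[names(clusters$labels)]),
      final_label = unname(clusters$labels),
      is_representative = names(clusters$labels) %in% reps,
      stringsAsFactors = FALSE
    )
    utils::write.table(df, assignments_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(summary_path)) {
    utils::write.table(cluster_report(clusters), summary_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(assignments_path, summary_path))
}

#' Sweep the leader-clustering cutoff toward a target top-cluster size
#'
#' Calibration helper: re-clusters the ensemble over a grid of cutoffs and
#' reports the top-cluster size at each, returning the cutoff whose top
#' cluster is closest to `target_size` (smallest cutoff on ties). Useful for
#' matching a reported cluster size when the cutoff used upstream is unknown.
#'
#' @param descriptors Descriptor data frame.
#' @param target_size Desired top-cluster size.
#' @param cutoffs Grid of cutoffs to try.
#' @param ... Further arguments to [pose_cluster()].
#' @return List with `cutoff` (selected value) and `sweep` (data frame of
#'   cutoff, top-cluster size, number of clusters).
#' @export
calibrate_cutoff <- function(descriptors, target_size,
                             cutoffs = seq(0.05, 0.6, by = 0.05), ...) {
  rows <- lapply(cutoffs, function(co) {
    cl <- pose_cluster(descriptors, cutoff = co, ...)
    rep <- cluster_report(cl)
    data.frame(cutoff = co,
               top_size = if (nrow(rep)) rep$size[1] else 0L,
               n_clusters = nrow(rep))
  })
  sweep <- do.call(rbind, rows)
  best <- sweep$cutoff[order(abs(sweep$top_size - target_size), sweep$cutoff)][1]
  list(cutoff = best, sweep = sweep)
}
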