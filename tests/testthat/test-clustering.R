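# small helper: descriptor table with given cluster centres and exact-zero
# spread, one pose per row
blob_descriptors <- function(centers, sizes, score_base = NULL) {
  rows <- list()
  idx <- 0
  for (k in seq_along(sizes)) {
    for (j in seq_len(sizes[k])) {
      idx <- idx + 1
      jitter <- (j - 1) * 1e-3
      rows[[idx]] <- data.frame(
        pose_id = sprintf("p%03d", idx),
        z = centers[k, 1] + jitter, l = centers[k, 2] + jitter,
        phi = centers[k, 3] + jitter,
        total_score = -1000,
        interface_score = if (is.null(score_base)) -20 + idx * 0.1 else
          score_base[k] + j * 0.1,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

test_that("leader clustering honours cutoff, visit order and min size", {
  # all-zero dissimilarity: a single cluster of size n
  d <- blob_descriptors(matrix(c(-5, 10, 45), 1), sizes = 6)
  d$z <- -5; d$l <- 10; d$phi <- 45   # exactly identical
  m <- similarity_matrix(d)
  sc <- stats::setNames(d$interface_score, d$pose_id)
  out <- leader_cluster(m, sc, cutoff = 0.2, min_size = 3)
  expect_equal(unname(out$labels), rep(1L, 6))

  # two planted blobs further apart than the cutoff
  d2 <- blob_descriptors(rbind(c(-5, 10, 45), c(-15, 12, 120)), c(7, 5))
  m2 <- similarity_matrix(d2)
  sc2 <- stats::setNames(d2$interface_score, d2$pose_id)
  out2 <- leader_cluster(m2, sc2, cutoff = 0.3, min_size = 3)
  expect_equal(length(out2$leaders), 2L)
  expect_equal(unname(out2$labels[d2$pose_id[1:7]]), rep(1L, 7))
  expect_equal(unname(out2$labels[d2$pose_id[8:12]]), rep(2L, 5))

  # a lone outlier below min_size becomes noise
  d3 <- blob_descriptors(rbind(c(-5, 10, 45), c(-18, 14, 170)), c(8, 1))
  m3 <- similarity_matrix(d3)
  sc3 <- stats::setNames(d3$interface_score, d3$pose_id)
  out3 <- leader_cluster(m3, sc3, cutoff = 0.3, min_size = 3)
  expect_equal(sum(!is.na(out3$labels)), 8L)
  expect_true(is.na(out3$labels[d3$pose_id[9]]))
})

test_that("kmeans refinement is a fixed point on clean partitions and reassigns noise", {
  d <- blob_descriptors(rbind(c(-5, 10, 45), c(-15, 12, 120)), c(7, 5))
  m <- similarity_matrix(d)
  sc <- stats::setNames(d$interface_score, d$pose_id)
  prov <- leader_cluster(m, sc, cutoff = 0.3, min_size = 3)
  fit <- kmeans_refine(d, prov)
  # partition unchanged (labels may be renumbered by rank)
  expect_equal(length(unique(fit$labels[d$pose_id[1:7]])), 1L)
  expect_equal(length(unique(fit$labels[d$pose_id[8:12]])), 1L)
  expect_false(fit$labels[d$pose_id[1]] == fit$labels[d$pose_id[8]])

  # noise poses receive a final label at the nearest centre
  d3 <- blob_descriptors(rbind(c(-5, 10, 45), c(-18, 14, 170)), c(8, 1))
  m3 <- similarity_matrix(d3)
  sc3 <- stats::setNames(d3$interface_score, d3$pose_id)
  prov3 <- leader_cluster(m3, sc3, cutoff = 0.3, min_size = 3)
  fit3 <- kmeans_refine(d3, prov3)
  expect_true(all(!is.na(fit3$labels)))
  expect_equal(sum(is.na(prov3$labels)), 1L)

  # K = 1: everything in one cluster, representative = global minimum score
  d1 <- blob_descriptors(matrix(c(-5, 10, 45), 1), 6)
  d1$z <- -5; d1$l <- 10; d1$phi <- 45    # exactly coincident poses
  m1 <- similarity_matrix(d1)
  sc1 <- stats::setNames(d1$interface_score, d1$pose_id)
  fit1 <- kmeans_refine(d1, leader_cluster(m1, sc1, cutoff = 1, min_size = 3))
  expect_equal(nrow(fit1$summary), 1L)
  expect_equal(fit1$summary$representative_id,
               d1$pose_id[which.min(d1$interface_score)])

  # all-noise input degrades with a warning, not an error
  dn <- blob_descriptors(rbind(c(-5, 10, 45), c(-18, 14, 170)), c(1, 1))
  mn <- similarity_matrix(dn)
  scn <- stats::setNames(dn$interface_score, dn$pose_id)
  provn <- leader_cluster(mn, scn, cutoff = 0.1, min_size = 3)
  expect_warning(fitn <- kmeans_refine(dn, provn), "noise")
  expect_true(all(is.na(fitn$labels)))
})

test_that("the Lloyd loop agrees with stats::kmeans under identical seeding", {
  ens <- make_pose_ensemble(open_scaffold(), recovery_spec(3), seed = 77)
  d <- pose_descriptors(ens$poses, open_scaffold()$model$frame)
  fit <- pose_cluster(d)
  norms <- fit$norms
  features <- porepose:::.normalised_features(d, norms)

  # same init as the package: lowest-interface member of each provisional blob
  prov <- fit$provisional[d$pose_id]
  K <- max(prov, na.rm = TRUE)
  init <- t(vapply(seq_len(K), function(k) {
    members <- which(prov == k)
    features[members[which.min(d$interface_score[members])], ]
  }, numeric(3)))
  ref <- suppressWarnings(
    stats::kmeans(features, centers = init, iter.max = 100,
                  algorithm = "Lloyd")
  )
  # identical partitions (label numbering may differ)
  expect_equal(mclust::adjustedRandIndex(fit$labels[d$pose_id], ref$cluster), 1)
})

test_that("refinement never increases within-cluster sum of squares", {
  skip_if_not_installed("mclust")
  wss <- function(features, labels, centers) {
    sum(vapply(seq_len(nrow(centers)), function(k) {
      members <- which(labels == k)
      if (!length(members)) return(0)
      sum(sweep(features[members, , drop = FALSE], 2, centers[k, ])^2)
    }, numeric(1)))
  }
  for (s in 1:10) {
    ens <- make_pose_ensemble(open_scaffold(), recovery_spec(2 + s %% 3),
                              seed = 500 + s)
    d <- pose_descriptors(ens$poses, open_scaffold()$model$frame)
    m <- similarity_matrix(d)
    sc <- stats::setNames(d$interface_score, d$pose_id)
    prov <- leader_cluster(m, sc, cutoff = 0.3, min_size = 3)
    fit <- kmeans_refine(d, prov, norms = attr(m, "norms"))
    features <- porepose:::.normalised_features(d, attr(m, "norms"))
    active <- !is.na(prov$labels[d$pose_id])
    K <- max(prov$labels, na.rm = TRUE)
    init <- t(vapply(seq_len(K), function(k) {
      members <- which(prov$labels[d$pose_id] == k)
      features[members[which.min(d$interface_score[members])], ]
    }, numeric(3)))
    d_init <- porepose:::.cross_dist(features[active, , drop = FALSE], init)
    init_lab <- apply(d_init, 1, which.min)
    wss_init <- wss(features[active, , drop = FALSE], init_lab, init)
    # recompute final WSS on the active poses with the fitted centres
    lab_final <- fit$labels[d$pose_id][active]
    centers_final <- fit$centers
    wss_final <- wss(features[active, , drop = FALSE], lab_final, centers_final)
    expect_lte(wss_final, wss_init + 1e-9)
  }
})

test_that("cluster report ranks by size then representative energy", {
  d <- blob_descriptors(rbind(c(-5, 10, 40), c(-12, 12, 90), c(-17, 9, 150)),
                        sizes = c(41, 6, 3),
                        score_base = c(-19, -16, -14))
  fit <- pose_cluster(d, cutoff = 0.3, min_size = 3)
  rep <- cluster_report(fit)
  expect_equal(rep$size, c(41, 6, 3))
  expect_equal(rep$rank, 1:3)

  # representative interface score is the member minimum (brute force)
  for (k in seq_len(nrow(rep))) {
    members <- names(fit$labels)[fit$labels == k]
    expect_equal(rep$interface_score[k],
                 min(d$interface_score[d$pose_id %in% members]))
    expect_true(rep$representative_id[k] %in% members)
  }

  # single cluster: one row
  d1 <- blob_descriptors(matrix(c(-5, 10, 45), 1), 5)
  expect_equal(nrow(cluster_report(pose_cluster(d1, cutoff = 1))), 1L)
})

test_that("clustering is deterministic and invariant to input order", {
  ens <- make_pose_ensemble(open_scaffold(), recovery_spec(4), seed = 99)
  d <- pose_descriptors(ens$poses, open_scaffold()$model$frame)
  fit1 <- pose_cluster(d)
  fit2 <- pose_cluster(d)
  expect_identical(fit1$labels, fit2$labels)

  set.seed(5)
  shuffled <- d[sample(nrow(d)), ]
  fit3 <- pose_cluster(shuffled)
  expect_equal(fit3$labels[names(fit1$labels)], fit1$labels)
  expect_equal(cluster_report(fit3), cluster_report(fit1))
})

test_that("cutoff calibration sweeps toward a target top-cluster size", {
  d <- default_descriptors()
  truth <- default_ensemble()$truth
  cal <- calibrate_cutoff(d, target_size = max(truth$sizes),
                          cutoffs = seq(0.1, 0.5, by = 0.1))
  expect_true(cal$cutoff %in% seq(0.1, 0.5, by = 0.1))
  best <- cal$sweep[cal$sweep$cutoff == cal$cutoff, ]
  expect_equal(best$top_size, max(truth$sizes))
})
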