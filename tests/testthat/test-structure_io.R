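test_that("channel PDB round-trip preserves chains, residue sets and coordinates", {
  sc <- open_scaffold()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_channel_pdb(sc$model, path)
  model <- read_channel_pdb(path)
  expect_s3_class(model, "channel_model")
  expect_equal(model$chains, c("A", "B", "C", "D"))
  expect_true(all(lengths(model$missing_residues) == 0))
  expect_lt(
    max(abs(as.matrix(model$atoms[, c("x", "y", "z")]) -
              as.matrix(sc$model$atoms[, c("x", "y", "z")]))),
    1e-3
  )
})

test_that("degenerate channel inputs are reported, not fatal", {
  sc <- open_scaffold()
  one_chain <- sc$model$atoms[sc$model$atoms$chain == "A", , drop = FALSE]
  path <- withr::local_tempfile(fileext = ".pdb")
  write_channel_pdb(make_tiny_model(one_chain), path)
  expect_warning(model <- read_channel_pdb(path), "C4 statistics")
  expect_equal(model$chains, "A")
  expect_s3_class(model$frame, "pore_frame")

  # renumbering Y652 away makes the pocket set report it missing everywhere
  renamed <- sc$model$atoms
  renamed$resno[renamed$resno == 652L] <- 999L
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_channel_pdb(make_tiny_model(renamed), path2)
  expect_warning(model2 <- read_channel_pdb(path2), "652")
  expect_true(652L %in% model2$missing_residues$pocket_residues)

  expect_error(read_channel_pdb(withr::local_tempfile(fileext = ".pdb")))
})

test_that("pore frame reproduces construction values and is equivariant", {
  sc <- open_scaffold()
  frame <- compute_pore_frame(sc$model)
  expect_lt(max(abs(frame$origin - sc$truth$sf_com)), 1e-6)
  expect_lt(max(abs(frame$axis - sc$truth$axis)), 1e-6)

  # rigid rotation + translation transforms the frame identically
  set.seed(11)
  ang <- stats::runif(3, 0, 360)
  R <- porepose:::.rotation_about_axis(c(1, 0, 0), ang[1]) %*%
    porepose:::.rotation_about_axis(c(0, 1, 0), ang[2]) %*%
    porepose:::.rotation_about_axis(c(0, 0, 1), ang[3])
  shift <- c(3, -7, 12)
  moved <- sc$model
  xyz <- as.matrix(moved$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]; moved$atoms$z <- xyz[, 3]
  frame2 <- compute_pore_frame(moved)
  expect_lt(max(abs(frame2$origin - (as.numeric(R %*% frame$origin) + shift))), 1e-6)
  expect_lt(max(abs(frame2$axis - as.numeric(R %*% frame$axis))), 1e-6)

  # a single chain with >= 3 SF C-alphas is enough
  one <- make_tiny_model(sc$model$atoms[sc$model$atoms$chain == "A", ])
  frame1 <- compute_pore_frame(one)
  expect_equal(unname(frame1$origin[3]), 15, tolerance = 1e-6)
})

test_that("frame computation fails cleanly without SF landmarks", {
  sc <- open_scaffold()
  no_sf <- sc$model$atoms[!(sc$model$atoms$resno %in% 624:628 &
                              sc$model$atoms$elety == "CA"), ]
  expect_error(compute_pore_frame(make_tiny_model(no_sf)),
               "insufficient landmarks")
})

test_that("ranked selection pools by total score then sorts by interface score", {
  tab <- data.frame(
    pose_id = c("a", "b", "c", "d", "e"),
    total_score = c(1, 2, 3, 4, 5),
    interface_delta_X = c(9, 1, 8, 2, 7),
    stringsAsFactors = FALSE
  )
  expect_equal(rank_and_select(tab, n_pool = 4, n_top = 2), c("b", "d"))
  expect_equal(rank_and_select(tab, n_pool = 5, n_top = 5),
               c("b", "d", "e", "c", "a"))

  # invariant to row order
  shuffled <- tab[c(4, 1, 5, 3, 2), ]
  expect_equal(rank_and_select(shuffled, n_pool = 4, n_top = 2), c("b", "d"))

  # all-tied scores fall back to lexicographic pose ids
  tied <- data.frame(pose_id = c("q", "p", "r"), total_score = 1,
                     interface_delta_X = 2, stringsAsFactors = FALSE)
  expect_equal(rank_and_select(tied, n_pool = 3, n_top = 2), c("p", "q"))

  expect_warning(out <- rank_and_select(tab, n_pool = 50, n_top = 3), "clamped")
  expect_equal(out, c("b", "d", "e"))
  expect_error(rank_and_select(tab, n_pool = 2, n_top = 3), "n_top")
})

test_that("kabsch_rmsd matches closed forms and the bio3d reference", {
  tri <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), ncol = 3, byrow = TRUE)
  expect_equal(kabsch_rmsd(tri, tri, superpose = FALSE), 0)
  expect_equal(kabsch_rmsd(tri, sweep(tri, 2, c(5, 0, 0), "+")), 0,
               tolerance = 1e-9)

  displaced <- tri
  displaced[1, 3] <- 1   # one vertex moved 1 A
  expect_equal(kabsch_rmsd(tri, displaced, superpose = FALSE), sqrt(1 / 3))

  set.seed(21)
  for (rep in 1:5) {
    a <- matrix(stats::rnorm(30), ncol = 3)
    b <- matrix(stats::rnorm(30), ncol = 3)
    expect_equal(kabsch_rmsd(a, b, superpose = FALSE),
                 kabsch_rmsd(b, a, superpose = FALSE))
    fit <- kabsch_rmsd(a, b, superpose = TRUE)
    expect_lte(fit, kabsch_rmsd(a, b, superpose = FALSE) + 1e-12)
    # independent reference: bio3d fitted RMSD (reported to 3 decimals)
    ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
    expect_lt(abs(fit - ref), 6e-4)
  }
  expect_error(kabsch_rmsd(tri, tri[1:2, ]), "pairing")
})

test_that("score tables round-trip and enforce required columns", {
  ens <- default_ensemble()
  path <- withr::local_tempfile(fileext = ".sc")
  write_score_table(ens$scores, path)
  tab <- read_score_table(path)
  expect_equal(tab$pose_id, ens$scores$pose_id)
  expect_equal(tab$interface_delta_X, ens$scores$interface_delta_X,
               tolerance = 1e-3)

  bad <- ens$scores[, c("pose_id", "total_score")]
  expect_error(porepose:::.validate_score_table(bad), "interface_delta_X")
  dup <- ens$scores
  dup$pose_id[2] <- dup$pose_id[1]
  expect_error(porepose:::.validate_score_table(dup), "duplicate")
})

test_that("pose sets read from per-file and multi-model PDB with score joins", {
  ens <- default_ensemble()
  dir <- withr::local_tempdir()
  files <- write_pose_pdb(ens$poses[1:10], file.path(dir, "poses"))
  poses <- read_pose_set(files, score_table = ens$scores)
  expect_length(poses, 10)
  expect_true(all(is.finite(vapply(poses, `[[`, numeric(1), "interface_score"))))

  multi <- file.path(dir, "multi.pdb")
  write_pose_pdb(ens$poses[1:10], multi, multi = TRUE)
  mposes <- read_pose_set(multi)
  expect_length(mposes, 10)
  expect_match(mposes[[3]]$pose_id, "_m3$")
  expect_equal(as.matrix(mposes[[5]]$atoms[, c("x", "y", "z")]),
               as.matrix(ens$poses[[5]]$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)

  # score rows missing for some poses: those poses are dropped with warnings
  short <- ens$scores[-(1:3), ]
  warns <- capture_warnings(kept <- read_pose_set(files, score_table = short))
  expect_length(warns, 3)
  expect_match(warns, "no score row", all = TRUE)
  expect_length(kept, 7)

  # a file without ligand records is skipped, the rest still load
  empty <- file.path(dir, "empty.pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A 700       0.000   0.000   0.000  1.00  0.00           C",
    "END"
  ), empty)
  expect_warning(some <- read_pose_set(c(empty, files[1:2])), "no LIG")
  expect_length(some, 2)
})

test_that("model comparison over a residue span matches closed forms", {
  sc <- open_scaffold()
  expect_equal(compare_models(sc$model, sc$model, 624:628), 0, tolerance = 1e-9)

  moved <- sc$model
  sel <- moved$atoms$elety == "CA" & moved$atoms$resno %in% 624:628
  moved$atoms$x[sel] <- moved$atoms$x[sel] + 0.5
  expect_equal(compare_models(sc$model, moved, 624:628, superpose = FALSE), 0.5,
               tolerance = 1e-9)

  # open and closed SFs are built 0.4 A apart (radial breathing)
  expect_equal(compare_models(sc$model, closed_scaffold()$model, 624:628,
                              superpose = FALSE), 0.4, tolerance = 1e-9)

  chopped <- make_tiny_model(
    sc$model$atoms[!(sc$model$atoms$resno == 626 & sc$model$atoms$chain == "B"), ])
  expect_error(compare_models(sc$model, chopped, 624:628), "mismatch")
})
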