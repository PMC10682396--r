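#' Default hERG pore-domain residue sets
#'
#' Named residue sets used to anchor the pore reference frame and the
#' geometric region definitions, in hERG (Kv11.1) numbering. The selectivity
#' filter (SF) span defaults to the five residues 624-628 per chain, the
#' standard K-channel SF definition; the hydrophobic pockets behind the SF are
#' lined by T623/S624/V625/G648/Y652; the lateral fenestrations by
#' M554/F557/A558 (S5), L622/T623 (pore helix) and L646/S649/L650/A653 (S6);
#' the intracellular gate is anchored at S660. All sets are configurable for
#' other channels.
#'
#' @return A named list of integer residue-number vectors with elements
#'   `sf_residues`, `pocket_residues`, `fenestration_residues`,
#'   `gate_residues`.
#' @export
herg_residue_config <- function() {
  list(
    sf_residues = 624:628,
    pocket_residues = c(623L, 624L, 625L, 648L, 652L),
    fenestration_residues = c(554L, 557L, 558L, 622L, 623L, 646L, 649L, 650L, 653L),
    gate_residues = 660L
  )
}

.required_atom_cols <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z", "het")

.validate_atoms <- function(atoms) {
  stopifnot(is.data.frame(atoms), all(.required_atom_cols %in% names(atoms)))
  if (!all(is.finite(.coords(atoms)))) stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$elesy))) stop("empty element symbols")
  invisible(atoms)
}

# Derive an element symbol from a PDB atom name when the element column is
# absent/blank (common in minimal files).
.element_from_name <- function(elety) {
  nm <- toupper(gsub("[^A-Za-z]", "", elety))
  two <- substr(nm, 1, 2)
  known2 <- c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")
  ifelse(two %in% known2, two, substr(nm, 1, 1))
}

.bio3d_to_atoms <- function(at) {
  elesy <- at$elesy
  if (is.null(elesy)) elesy <- rep("", nrow(at))
  elesy <- trimws(as.character(elesy))
  miss <- is.na(elesy) | !nzchar(elesy)
  elesy[miss] <- .element_from_name(at$elety[miss])
  chain <- as.character(at$chain)
  chain[is.na(chain)] <- " "
  data.frame(
    chain = chain,
    resno = as.integer(at$resno),
    resid = as.character(at$resid),
    elety = trimws(as.character(at$elety)),
    elesy = toupper(elesy),
    x = at$x, y = at$y, z = at$z,
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
}

# Resolve named residue sets against the atom table; warn about members with
# no atoms in any chain.
.resolve_residue_sets <- function(atoms, residue_config) {
  protein <- atoms[!atoms$het, , drop = FALSE]
  missing <- list()
  for (set in names(residue_config)) {
    members <- residue_config[[set]]
    absent <- members[!members %in% protein$resno]
    missing[[set]] <- absent
    if (length(absent)) {
      warning(sprintf(
        "%s: residue(s) %s missing in all chains", set,
        paste(absent, collapse = ", ")
      ), call. = FALSE)
    }
  }
  missing
}

.new_channel_model <- function(atoms, residue_config) {
  .validate_atoms(atoms)
  protein <- atoms[!atoms$het, , drop = FALSE]
  if (nrow(protein) == 0L) stop("no protein (ATOM) records found")
  chains <- sort(unique(protein$chain))
  if (length(chains) < 4L) {
    warning(sprintf(
      "model has %d chain(s); C4 statistics are unavailable for fewer than 4 chains",
      length(chains)
    ), call. = FALSE)
  }
  missing <- .resolve_residue_sets(atoms, residue_config)
  model <- structure(
    list(
      atoms = atoms, chains = chains,
      residue_config = residue_config,
      missing_residues = missing, frame = NULL
    ),
    class = "channel_model"
  )
  model$frame <- tryCatch(compute_pore_frame(model), error = function(e) {
    warning("pore frame not computed: ", conditionMessage(e), call. = FALSE)
    NULL
  })
  model
}

#' Read a channel model from a PDB file
#'
#' Loads a (typically homotetrameric) channel structure, resolves the named
#' residue sets of `residue_config` against it, and computes the pore
#' reference frame from the selectivity-filter C-alpha atoms. Residue-set
#' members that resolve to no atom in any chain are reported as warnings, as
#' is a chain count below four (C4 statistics are then unavailable).
#'
#' @param path Path to a PDB file.
#' @param residue_config Named residue sets; see [herg_residue_config()].
#' @return A `channel_model` object: a list with elements `atoms` (data frame
#'   of atom records), `chains`, `residue_config`, `missing_residues`, and
#'   `frame` (a `pore_frame`, or `NULL` if it could not be derived).
#' @export
read_channel_pdb <- function(path, residue_config = herg_residue_config()) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- .bio3d_to_atoms(pdb$atom)
  .new_channel_model(atoms, residue_config)
}

#' Write a channel model to a PDB file
#'
#' @param model A `channel_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_channel_pdb <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(.coords(at))),
    type = ifelse(at$het, "HETATM", "ATOM"),
    resno = at$resno, resid = at$resid,
    eleno = seq_len(nrow(at)), elety = at$elety,
    chain = at$chain, elesy = at$elesy
  )
  invisible(path)
}

#' @export
print.channel_model <- function(x, ...) {
  cat("Channel model:", nrow(x$atoms), "atoms,",
      length(x$chains), "chain(s) [", paste(x$chains, collapse = ","), "]\n")
  if (!is.null(x$frame)) {
    cat(sprintf(
      "Pore frame: origin (%.2f, %.2f, %.2f) A, axis (%.3f, %.3f, %.3f)\n",
      x$frame$origin[1], x$frame$origin[2], x$frame$origin[3],
      x$frame$axis[1], x$frame$axis[2], x$frame$axis[3]
    ))
  }
  invisible(x)
}

#' Read a Rosetta-style score table
#'
#' Whitespace-delimited score file with a header line naming the columns; an
#' optional leading `SCORE:` tag per line (Rosetta `.sc` convention) is
#' stripped, and the trailing `description` column is used as the pose
#' identifier. Columns `total_score` and `interface_delta_X` must be present.
#'
#' @param path Path to the score file.
#' @return Data frame with a `pose_id` column plus the numeric score columns.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("cannot read score table: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^SEQUENCE:", lines)]
  lines <- sub("^SCORE:\\s*", "", lines)
  if (!length(lines)) stop("empty score table: ", path)
  con <- textConnection(lines)
  on.exit(close(con))
  tab <- utils::read.table(con, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if ("description" %in% names(tab)) {
    names(tab)[names(tab) == "description"] <- "pose_id"
  }
  .validate_score_table(tab)
}

.validate_score_table <- function(tab) {
  req <- c("pose_id", "total_score", "interface_delta_X")
  absent <- setdiff(req, names(tab))
  if (length(absent)) {
    stop("score table lacks required column(s): ", paste(absent, collapse = ", "))
  }
  tab$pose_id <- as.character(tab$pose_id)
  if (anyDuplicated(tab$pose_id)) stop("duplicate pose_id values in score table")
  if (!all(is.finite(tab$total_score)) || !all(is.finite(tab$interface_delta_X))) {
    stop("non-finite scores in score table")
  }
  tab
}

#' Write a Rosetta-style score table
#'
#' @param table Data frame with `pose_id`, `total_score`, `interface_delta_X`
#'   (and optionally further numeric columns).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(table, path) {
  tab <- .validate_score_table(table)
  num_cols <- setdiff(names(tab), "pose_id")
  header <- paste("SCORE:", paste(num_cols, collapse = " "), "description")
  body <- vapply(seq_len(nrow(tab)), function(i) {
    paste("SCORE:",
          paste(sprintf("%.3f", as.numeric(tab[i, num_cols])), collapse = " "),
          tab$pose_id[i])
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Ranked pose selection from a score table
#'
#' Reproduces the two-stage docking triage: keep the `n_pool` rows with the
#' lowest `total_score`, re-sort that pool ascending by `interface_delta_X`
#' (the ligand binding-energy term), and return the first `n_top` pose ids.
#' Ties are broken by `(score, pose_id)` lexicographic order, making the
#' result invariant to input row order.
#'
#' @param table Score table (see [read_score_table()]).
#' @param n_pool Pool size kept by total score (default 10000).
#' @param n_top Number of top interface-score poses returned (default 50).
#' @return Character vector of `n_top` pose ids, ordered by interface score.
#' @export
rank_and_select <- function(table, n_pool = 10000L, n_top = 50L) {
  tab <- .validate_score_table(table)
  if (n_top > n_pool) stop("n_top must not exceed n_pool")
  if (n_pool > nrow(tab)) {
    warning(sprintf("n_pool (%d) exceeds table size (%d); clamped",
                    n_pool, nrow(tab)), call. = FALSE)
    n_pool <- nrow(tab)
  }
  n_top <- min(n_top, n_pool)
  pool <- tab[order(tab$total_score, tab$pose_id), , drop = FALSE][seq_len(n_pool), ]
  pool <- pool[order(pool$interface_delta_X, pool$pose_id), , drop = FALSE]
  pool$pose_id[seq_len(n_top)]
}

.pose_from_atoms <- function(pose_id, atoms, total_score = NA_real_,
                             interface_score = NA_real_) {
  heavy <- atoms[atoms$elesy != "H", , drop = FALSE]
  if (nrow(heavy) < 2L) stop("pose ", pose_id, " has fewer than 2 heavy atoms")
  structure(
    list(pose_id = pose_id, atoms = atoms,
         total_score = total_score, interface_score = interface_score),
    class = "ligand_pose"
  )
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("Ligand pose %s: %d atoms, total_score %.3f, interface %.3f REU\n",
              x$pose_id, nrow(x$atoms), x$total_score, x$interface_score))
  invisible(x)
}

#' Read a set of docked ligand poses
#'
#' Reads one `ligand_pose` per PDB file, or one per `MODEL` block for
#' multi-model files (pose ids are then suffixed `_m<k>`). The ligand is
#' identified by HETATM records with residue name `ligand_resname`. When a
#' score table is supplied, scores are joined by pose id and poses lacking a
#' score row are dropped with a warning. A file containing no ligand atoms
#' yields a warning and is skipped; the remaining files are still read.
#'
#' @param paths Character vector of pose PDB paths.
#' @param ligand_resname Ligand residue name (default `"LIG"`).
#' @param score_table Optional score table (see [read_score_table()]).
#' @return List of `ligand_pose` objects.
#' @export
read_pose_set <- function(paths, ligand_resname = "LIG", score_table = NULL) {
  poses <- list()
  for (path in paths) {
    stem <- sub("\\.[Pp][Dd][Bb]$", "", basename(path))
    pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                    error = function(e) NULL)
    if (is.null(pdb)) {
      warning("could not parse pose file ", path, call. = FALSE)
      next
    }
    atoms <- .bio3d_to_atoms(pdb$atom)
    lig <- which(atoms$het & atoms$resid == ligand_resname)
    if (!length(lig)) {
      warning("no ", ligand_resname, " HETATM records in ", path, call. = FALSE)
      next
    }
    n_models <- nrow(pdb$xyz)
    for (m in seq_len(n_models)) {
      xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
      at <- atoms[lig, , drop = FALSE]
      at$x <- xyz[lig, 1]; at$y <- xyz[lig, 2]; at$z <- xyz[lig, 3]
      id <- if (n_models > 1L) sprintf("%s_m%d", stem, m) else stem
      poses[[id]] <- .pose_from_atoms(id, at)
    }
  }
  if (!is.null(score_table)) {
    tab <- .validate_score_table(score_table)
    keep <- character(0)
    for (id in names(poses)) {
      row <- match(id, tab$pose_id)
      if (is.na(row)) {
        warning("pose ", id, " has no score row; dropped", call. = FALSE)
      } else {
        poses[[id]]$total_score <- tab$total_score[row]
        poses[[id]]$interface_score <- tab$interface_delta_X[row]
        keep <- c(keep, id)
      }
    }
    poses <- poses[keep]
  }
  unname(poses)
}

#' Write ligand poses to PDB
#'
#' One file per pose, or a single multi-model file when `multi = TRUE`.
#'
#' @param poses List of `ligand_pose` objects.
#' @param path Output file (multi-model) or directory (one file per pose).
#' @param multi Write a single MODEL/ENDMDL-separated file?
#' @return Invisibly, the path(s) written.
#' @export
write_pose_pdb <- function(poses, path, multi = FALSE) {
  fmt_atom <- function(i, at) {
    sprintf("HETATM%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, at$elety[i], at$resid[i], at$chain[i], at$resno[i],
            at$x[i], at$y[i], at$z[i], at$elesy[i])
  }
  if (multi) {
    lines <- character(0)
    for (m in seq_along(poses)) {
      at <- poses[[m]]$atoms
      lines <- c(lines, sprintf("MODEL     %4d", m),
                 vapply(seq_len(nrow(at)), fmt_atom, character(1), at = at),
                 "ENDMDL")
    }
    writeLines(c(lines, "END"), path)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  out <- character(length(poses))
  for (m in seq_along(poses)) {
    at <- poses[[m]]$atoms
    f <- file.path(path, paste0(poses[[m]]$pose_id, ".pdb"))
    writeLines(c(vapply(seq_len(nrow(at)), fmt_atom, character(1), at = at), "END"), f)
    out[m] <- f
  }
  invisible(out)
}

#' RMSD between paired coordinate sets, with optional Kabsch superposition
#'
#' @param coords_a,coords_b Equal-size n x 3 coordinate matrices with rows
#'   paired (n >= 1; n >= 3 when superposing).
#' @param superpose Remove the optimal rigid motion (Kabsch) before computing
#'   the RMSD?
#' @return RMSD in Angstrom (non-negative).
#' @export
kabsch_rmsd <- function(coords_a, coords_b, superpose = TRUE) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!identical(dim(a), dim(b))) stop("coordinate sets differ in size: pairing error")
  if (ncol(a) != 3L) stop("coordinates must be n x 3 matrices")
  n <- nrow(a)
  if (n < 1L) stop("need at least one atom pair")
  if (superpose) {
    if (n < 3L) stop("superposition needs at least 3 atom pairs")
    ca <- sweep(a, 2, colMeans(a))
    cb <- sweep(b, 2, colMeans(b))
    s <- svd(t(cb) %*% ca)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    cb <- cb %*% t(R)
    return(sqrt(mean(rowSums((ca - cb)^2))))
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Compare two channel models by C-alpha RMSD over a residue span
#'
#' Extracts C-alpha atoms of the given residue numbers (per chain, in
#' chain/residue order) from both models and computes their paired RMSD,
#' optionally after Kabsch superposition. Used e.g. to compare
#' selectivity-filter conformations between channel states.
#'
#' @param model_a,model_b `channel_model` objects.
#' @param resno_span Integer residue numbers defining the span.
#' @param superpose Superpose before computing the RMSD?
#' @return RMSD in Angstrom.
#' @export
compare_models <- function(model_a, model_b, resno_span, superpose = TRUE) {
  grab <- function(model) {
    at <- model$atoms
    sel <- !at$het & at$elety == "CA" & at$resno %in% resno_span
    ca <- at[sel, , drop = FALSE]
    ca <- ca[order(ca$chain, ca$resno), , drop = FALSE]
    ca
  }
  ca_a <- grab(model_a); ca_b <- grab(model_b)
  key_a <- paste(ca_a$chain, ca_a$resno)
  key_b <- paste(ca_b$chain, ca_b$resno)
  if (!identical(key_a, key_b)) {
    miss <- union(setdiff(key_a, key_b), setdiff(key_b, key_a))
    stop("residue span mismatch between models: ", paste(miss, collapse = ", "))
  }
  kabsch_rmsd(.coords(ca_a), .coords(ca_b), superpose = superpose)
}
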