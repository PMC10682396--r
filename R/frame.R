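#' Compute the pore reference frame of a channel model
#'
#' The frame origin is the centre of mass of the selectivity-filter (SF)
#' C-alpha atoms across all chains; the axis is the best-fit C4/pore axis,
#' taken as the eigenvector of the SF C-alpha covariance whose eigenvalue is
#' most separated from the other two (for a C4-symmetric point set the two
#' in-plane eigenvalues are degenerate and the distinct one belongs to the
#' symmetry axis). The sign is chosen so that +z points from the
#' intracellular gate toward the SF (extracellular side): the gate-residue
#' centre of mass must project below the SF origin. When no gate residues
#' resolve, pocket residues are used instead; failing both, the axis keeps a
#' non-negative projection on the global +z.
#'
#' @param model A `channel_model`.
#' @return A `pore_frame`: list with `origin` (3-vector, Angstrom) and `axis`
#'   (unit 3-vector).
#' @export
compute_pore_frame <- function(model) {
  at <- model$atoms
  sf <- at[!at$het & at$elety == "CA" &
             at$resno %in% model$residue_config$sf_residues, , drop = FALSE]
  if (nrow(sf) < 3L) {
    stop("insufficient landmarks: need >= 3 SF C-alpha atoms, found ", nrow(sf))
  }
  xyz <- .coords(sf)
  origin <- unname(colMeans(xyz))
  cv <- stats::cov(xyz)
  eig <- eigen(cv, symmetric = TRUE)
  # pick the eigenvalue most separated from the other two
  gaps <- vapply(1:3, function(i) min(abs(eig$values[i] - eig$values[-i])), numeric(1))
  axis <- .unit(eig$vectors[, which.max(gaps)])

  sign_anchor <- function(resnos, elety_only_ca = TRUE) {
    sel <- !at$het & at$resno %in% resnos
    if (elety_only_ca) {
      ca <- sel & at$elety == "CA"
      if (any(ca)) sel <- ca
    }
    if (!any(sel)) return(NULL)
    colMeans(.coords(at[sel, , drop = FALSE]))
  }
  anchor <- sign_anchor(model$residue_config$gate_residues)
  if (is.null(anchor)) anchor <- sign_anchor(model$residue_config$pocket_residues)
  if (!is.null(anchor)) {
    if (sum((anchor - origin) * axis) > 0) axis <- -axis
  } else if (axis[3] < 0) {
    axis <- -axis
  }
  structure(list(origin = origin, axis = axis), class = "pore_frame")
}

#' @export
print.pore_frame <- function(x, ...) {
  cat(sprintf("Pore frame: origin (%.3f, %.3f, %.3f) A, axis (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}
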