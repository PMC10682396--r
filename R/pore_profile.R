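#' Default van der Waals radii
#'
#' Bondi-type radii in Angstrom, configurable. Elements not listed fall back
#' to the carbon radius.
#'
#' @return Named numeric vector of radii.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, P = 1.80)
}

.vdw_lookup <- function(elements, vdw) {
  r <- vdw[toupper(elements)]
  r[is.na(r)] <- vdw[["C"]]
  unname(r)
}

#' Pore-radius profile along the channel axis
#'
#' For each slice of a z grid along the pore axis, finds the largest
#' spherical probe centred in the slice plane that avoids overlap with every
#' atom's van der Waals sphere (3-D distances, so atoms above and below the
#' plane also constrain the probe). The maximisation is a deterministic
#' multi-start local search: a 3 x 3 grid of starting points around the axis,
#' each refined by Nelder-Mead. Radii are capped at `r_cap`, with the capped
#' flag set where the cap (or an atom-free neighbourhood) is reached. Protein
#' atoms only, unless `include_het = TRUE`.
#'
#' @param model A `channel_model`.
#' @param frame Pore frame (defaults to the model's).
#' @param z_range Axial range `c(lo, hi)` in frame coordinates; defaults to
#'   the protein's axial extent.
#' @param step Grid spacing in Angstrom (default 0.5).
#' @param r_cap Radius cap in Angstrom (default 15).
#' @param vdw Van der Waals radius table (see [vdw_radii()]).
#' @param include_het Include HETATM records as obstacles?
#' @return A `pore_profile`: data frame with columns `z`, `radius`, `capped`.
#' @export
pore_radius_profile <- function(model, frame = model$frame, z_range = NULL,
                                step = 0.5, r_cap = 15, vdw = vdw_radii(),
                                include_het = FALSE) {
  stopifnot(inherits(model, "channel_model"))
  if (is.null(frame)) stop("model has no pore frame")
  at <- model$atoms
  if (!include_het) at <- at[!at$het, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms available for pore profiling")
  xyz <- .to_frame(.coords(at), frame)
  radii <- .vdw_lookup(at$elesy, vdw)
  if (is.null(z_range)) z_range <- range(xyz[, 3])
  z_grid <- seq(z_range[1], z_range[2], by = step)
  max_vdw <- max(radii)

  starts <- as.matrix(expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2)))
  profile <- vapply(z_grid, function(zs) {
    near <- abs(xyz[, 3] - zs) <= r_cap + max_vdw
    if (!any(near)) return(c(r_cap, 1))
    axyz <- xyz[near, , drop = FALSE]
    ar <- radii[near]
    clearance <- function(p) {
      min(sqrt((p[1] - axyz[, 1])^2 + (p[2] - axyz[, 2])^2 +
                 (zs - axyz[, 3])^2) - ar)
    }
    best <- -Inf
    for (s in seq_len(nrow(starts))) {
      opt <- stats::optim(starts[s, ], clearance, method = "Nelder-Mead",
                          control = list(fnscale = -1, maxit = 500,
                                         reltol = 1e-10))
      if (opt$value > best) best <- opt$value
    }
    capped <- best >= r_cap
    c(max(0, min(best, r_cap)), as.numeric(capped))
  }, numeric(2))

  structure(
    data.frame(z = z_grid, radius = profile[1, ],
               capped = as.logical(profile[2, ])),
    class = c("pore_profile", "data.frame"),
    step = step, r_cap = r_cap
  )
}

#' Maximum pore radius within an axial band
#'
#' @param profile A `pore_profile`.
#' @param z_lo,z_hi Band limits in frame coordinates (Angstrom).
#' @return Maximum radius over the uncapped slices in the band, or `NA` with
#'   a warning when every slice in the band is capped.
#' @export
max_radius_in_band <- function(profile, z_lo, z_hi) {
  stopifnot(z_lo <= z_hi)
  in_band <- profile$z >= z_lo & profile$z <= z_hi
  if (!any(in_band)) stop("range error: band does not overlap the profile grid")
  ok <- in_band & !profile$capped
  if (!any(ok)) {
    warning("all slices in band are capped", call. = FALSE)
    return(NA_real_)
  }
  max(profile$radius[ok])
}

#' @export
plot.pore_profile <- function(x, ...) {
  graphics::plot(x$radius, x$z, type = "l", xlab = "pore radius (A)",
                 ylab = "z (A)", ...)
  graphics::abline(v = 1.15, lty = 3)
  invisible(x)
}

#' Write a pore profile as TSV
#'
#' @param profile A `pore_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pore_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
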