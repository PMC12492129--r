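# Shrake-Rupley solvent-accessible surface area

# van der Waals radii (Angstrom) used when the structure carries no
# per-atom radii; hydrogens are included whenever present in the file
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

#' Quasi-uniform points on the unit sphere (golden-spiral construction)
#'
#' Deterministic for a given `n`, so SASA values are bit-reproducible.
#'
#' @param n Number of points.
#' @return An n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area of one frame (Shrake-Rupley)
#'
#' For each atom, test points are placed quasi-uniformly on the sphere of
#' radius `r_atom + probe`; the accessible fraction (points not inside any
#' neighbour's expanded sphere) times `4 pi (r_atom + probe)^2` is the atom's
#' contribution.
#'
#' @param structure An `adk_structure` supplying elements (for radii) and,
#'   by default, coordinates.
#' @param coords Optional n x 3 coordinate matrix overriding the topology
#'   coordinates (e.g. a trajectory frame).
#' @param probe Probe radius, Angstrom (default 1.4, water).
#' @param n_sphere_points Test points per atom (default 960).
#' @param radii Named per-element radius table, Angstrom.
#' @return List: `total` (Angstrom^2) and `per_atom` (numeric vector).
#' @export
compute_sasa <- function(structure, coords = NULL, probe = 1.4,
                         n_sphere_points = 960, radii = VDW_RADII) {
  atoms <- structure$atoms
  if (is.null(coords)) coords <- as.matrix(atoms[, c("x", "y", "z")])
  el <- atoms$element
  missing <- setdiff(unique(el), names(radii))
  if (length(missing) > 0) {
    abort(paste0("no van der Waals radius for element(s): ", paste(missing, collapse = ", ")))
  }
  r <- unname(radii[el]) + probe
  if (any(r <= probe)) abort("non-positive atom radius")
  n <- nrow(coords)
  pts <- sphere_points(n_sphere_points)
  per_atom <- numeric(n)
  d2 <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    # neighbours whose expanded spheres can reach atom i's test sphere
    nb <- which(d2[i, ] < (r[i] + r)^2)
    nb <- nb[nb != i]
    test <- sweep(pts * r[i], 2, coords[i, ], FUN = "+")
    if (length(nb) == 0) {
      acc <- n_sphere_points
    } else {
      buried <- rep(FALSE, n_sphere_points)
      for (j in nb) {
        if (all(buried)) break
        dx <- sweep(test[!buried, , drop = FALSE], 2, coords[j, ])
        buried[!buried] <- rowSums(dx^2) < r[j]^2
      }
      acc <- sum(!buried)
    }
    per_atom[i] <- acc / n_sphere_points * 4 * pi * r[i]^2
  }
  list(total = sum(per_atom), per_atom = per_atom)
}
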