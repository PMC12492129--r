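# Structural descriptors from trajectories: RMSF, radius of gyration,
# replicate aggregation. SASA lives in sasa.R.

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation + translation of `mobile` minimising the RMSD to
#' `reference` over a selection of atoms, and applies it to all atoms of
#' `mobile`.
#'
#' @param mobile n x 3 coordinate matrix to move.
#' @param reference n x 3 coordinate matrix to fit onto.
#' @param selection Integer atom indices used for the fit (>= 3, non-degenerate).
#' @return List with `coords` (transformed mobile, all atoms) and `rmsd`
#'   (Angstrom, over the selection).
#' @export
kabsch_superpose <- function(mobile, reference, selection = seq_len(nrow(mobile))) {
  if (length(selection) < 3) abort("selection must contain at least 3 atoms")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  if (nrow(A) != nrow(B)) abort("selection maps to different atom counts")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(A0, B0))
  # guard against a degenerate (collinear/planar-rank-deficient) selection
  if (s$d[2] < 1e-10 * max(s$d[1], 1e-300)) {
    abort("numerical degeneracy: selection is (near-)collinear")
  }
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)  # proper rotation, det +1
  moved <- sweep(mobile, 2, ca) %*% t(R)
  moved <- sweep(moved, 2, cb, FUN = "+")
  dev <- moved[selection, , drop = FALSE] - B
  list(coords = moved, rmsd = sqrt(mean(rowSums(dev^2))))
}

#' Root mean square fluctuation of selected atoms
#'
#' Each frame is superposed on the (iterated) mean structure over the
#' selection, then `RMSF_i = sqrt(mean_t ||r_i(t) - <r_i>||^2)`. Two
#' mean-structure/fit iterations are used, seeded by the first frame.
#'
#' @param traj An `adk_trajectory` (>= 2 frames).
#' @param selection Atom indices; default all alpha carbons.
#' @param superpose Superpose frames before measuring (default `TRUE`).
#'   Disable only for fixtures whose frames share a fixed lab frame.
#' @return A tibble: `atom` (index into the selection), `residue_index`,
#'   `rmsf` (Angstrom).
#' @export
compute_rmsf <- function(traj, selection = NULL, superpose = TRUE) {
  if (n_frames(traj) < 2) abort("RMSF needs at least 2 frames")
  if (is.null(selection)) selection <- alpha_carbons(traj$topology)
  frames <- lapply(traj$frames, function(f) f[selection, , drop = FALSE])
  if (superpose) {
    ref <- frames[[1]]
    for (iter in 1:2) {
      fitted <- lapply(frames, function(f) {
        kabsch_superpose(f, ref, seq_len(nrow(f)))$coords
      })
      ref <- Reduce(`+`, fitted) / length(fitted)
    }
    frames <- lapply(frames, function(f) kabsch_superpose(f, ref, seq_len(nrow(f)))$coords)
  }
  arr <- simplify2array(frames)                 # n_sel x 3 x n_frames
  mean_pos <- apply(arr, c(1, 2), mean)
  sq <- sweep(arr, c(1, 2), mean_pos)^2
  rmsf <- sqrt(apply(sq, 1, mean) * 3)          # mean over (coord, frame) of 3 * per-coord MS
  tibble(
    atom = selection,
    residue_index = traj$topology$atoms$residue_index[selection],
    rmsf = rmsf
  )
}

#' Radius of gyration of selected atoms, per frame
#'
#' `r_gyr = sqrt( sum_i ||r_i - centroid||^2 / N )` with unit weights.
#'
#' @param traj An `adk_trajectory`.
#' @param selection Atom indices; default all alpha carbons.
#' @return A tibble: `frame`, `rgyr` (Angstrom); attribute `mean` holds the
#'   trajectory mean.
#' @export
compute_rgyr <- function(traj, selection = NULL) {
  if (is.null(selection)) selection <- alpha_carbons(traj$topology)
  if (length(selection) < 1) abort("empty selection")
  vals <- map_dbl(traj$frames, function(f) {
    m <- f[selection, , drop = FALSE]
    ctr <- colMeans(m)
    sqrt(mean(rowSums(sweep(m, 2, ctr)^2)))
  })
  out <- tibble(frame = seq_along(vals), rgyr = vals)
  attr(out, "mean") <- mean(vals)
  out
}

#' Aggregate per-replicate descriptor values
#'
#' @param values Numeric vector of per-replicate scalars (one per replicate).
#' @return A tibble with `mean`, `se` (standard error of the mean; `NA` with
#'   a warning when only one replicate is supplied), `n_replicates`.
#' @export
aggregate_replicates <- function(values) {
  if (length(values) < 1 || any(!is.finite(values))) {
    abort("need at least one finite replicate value")
  }
  n <- length(values)
  se <- if (n == 1) {
    warn("single replicate: standard error undefined, returned as NA")
    NA_real_
  } else {
    sd(values) / sqrt(n)
  }
  tibble(mean = mean(values), se = se, n_replicates = n)
}

#' Descriptor row for one protein at one temperature
#'
#' Reduces replicate trajectories to the three per-protein structural
#' descriptors with replicate means and standard errors: scalar RMSF (the
#' unweighted mean over alpha carbons of per-residue RMSF), total SASA
#' (mean over frames), and radius of gyration (mean over frames).
#'
#' @param replicates List of `adk_trajectory` objects (the replicates).
#' @param adk Protein identifier.
#' @param temperature Simulation temperature, Kelvin.
#' @param probe Solvent probe radius, Angstrom (default 1.4).
#' @param n_sphere_points Sphere points per atom for SASA (default 960).
#' @param compute_sasa_values Set `FALSE` to skip SASA (it dominates runtime).
#' @return One-row tibble with `adk`, `temperature`, `{rmsf,sasa,rgyr}_mean`,
#'   `{rmsf,sasa,rgyr}_se` (Angstrom / Angstrom^2), nm-scale companions
#'   `rmsf_mean_nm`, `sasa_mean_nm2`, `rgyr_mean_nm`, and `n_replicates`.
#' @export
descriptor_row <- function(replicates, adk, temperature,
                           probe = 1.4, n_sphere_points = 960,
                           compute_sasa_values = TRUE) {
  stopifnot(length(replicates) >= 1)
  rmsf_rep <- map_dbl(replicates, function(tr) mean(compute_rmsf(tr)$rmsf))
  rgyr_rep <- map_dbl(replicates, function(tr) attr(compute_rgyr(tr), "mean"))
  sasa_rep <- if (compute_sasa_values) {
    map_dbl(replicates, function(tr) {
      mean(map_dbl(seq_len(n_frames(tr)), function(i) {
        compute_sasa(tr$topology, coords = tr$frames[[i]],
                     probe = probe, n_sphere_points = n_sphere_points)$total
      }))
    })
  } else {
    rep(NA_real_, length(replicates))
  }
  agg <- function(v) {
    if (all(is.na(v))) return(tibble(mean = NA_real_, se = NA_real_, n_replicates = length(v)))
    suppressWarnings(aggregate_replicates(v))
  }
  a_rmsf <- agg(rmsf_rep); a_sasa <- agg(sasa_rep); a_rgyr <- agg(rgyr_rep)
  tibble(
    adk = adk, temperature = temperature,
    rmsf_mean = a_rmsf$mean, rmsf_se = a_rmsf$se,
    sasa_mean = a_sasa$mean, sasa_se = a_sasa$se,
    rgyr_mean = a_rgyr$mean, rgyr_se = a_rgyr$se,
    rmsf_mean_nm = a_rmsf$mean / 10,
    sasa_mean_nm2 = a_sasa$mean / 100,
    rgyr_mean_nm = a_rgyr$mean / 10,
    n_replicates = length(replicates)
  )
}
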