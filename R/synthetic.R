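# Synthetic-data generators with known ground truth
#
# Every generator is a pure function of its arguments plus an explicit seed,
# and emulates the statistical structure the downstream analyses assume:
# phylogenetic signal via Brownian deviations on an ultrametric tree,
# temperature slopes within and across species, replicate measurement error,
# and liability-governed contact presence.

#' Simulate a pure-birth ultrametric tree
#'
#' @param n_tips Number of tips (>= 3).
#' @param seed Random seed.
#' @return An [ape::phylo] tree scaled to unit height, tips `sp01, sp02, ...`
#' @export
simulate_tree <- function(n_tips, seed = 1) {
  if (n_tips < 3) abort("need at least 3 tips")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length / tree_height(tree)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tree
}

# Brownian deviations on the tree: z ~ N(0, sigma2 * C_unit)
brownian_chol <- function(tree) {
  C <- scale_to_unit_height(tree_to_covariance(tree))
  chol(C + diag(1e-10, nrow(C)))
}

brownian_deviates <- function(tree, sigma2 = 1, L = NULL) {
  if (is.null(L)) L <- brownian_chol(tree)
  setNames(sqrt(sigma2) * drop(crossprod(L, rnorm(ncol(L)))), colnames(L))
}

#' Simulate per-protein metadata
#'
#' Optimal growth temperatures are assigned so thermal-group frequencies hit
#' the configured targets exactly, with phylogenetic structure: species are
#' ranked by a Brownian liability on the tree and the coldest ranks become
#' psychrophiles, and so on. LID length and ADK type come from independent
#' Brownian liabilities thresholded at the target proportions, giving both
#' traits phylogenetic autocorrelation.
#'
#' @param tree An [ape::phylo] tree.
#' @param seed Random seed.
#' @param group_counts Named target counts for the four thermal groups;
#'   defaults mirror the study composition scaled to the tip count
#'   (8/38/16/8 of 70).
#' @param n_short_lid Number of short-LID proteins (default: 21/70 of tips).
#' @param n_trimeric Number of trimeric proteins (default: 12/70 of tips).
#' @return A tibble: `species`, `adk`, `ogt`, `thermal_group`, `adk_type`,
#'   `lid`, `native_temperature` (K), `native_temperature_C`.
#' @export
simulate_metadata <- function(tree, seed = 1, group_counts = NULL,
                              n_short_lid = NULL, n_trimeric = NULL) {
  n <- length(tree$tip.label)
  if (is.null(group_counts)) {
    group_counts <- round(c(psychrophile = 8, mesophile = 38,
                            thermophile = 16, hyperthermophile = 8) / 70 * n)
    group_counts[2] <- n - sum(group_counts[-2])   # absorb rounding
  }
  if (sum(group_counts) != n) abort("group_counts must sum to the tip count")
  if (is.null(n_short_lid)) n_short_lid <- round(21 / 70 * n)
  if (is.null(n_trimeric)) n_trimeric <- round(12 / 70 * n)
  set.seed(seed)
  liab_ogt <- brownian_deviates(tree)
  liab_lid <- brownian_deviates(tree)
  liab_type <- brownian_deviates(tree)
  ranks <- rank(liab_ogt, ties.method = "first")
  group <- character(n)
  bounds <- cumsum(group_counts[THERMAL_GROUPS])
  group[ranks <= bounds[1]] <- "psychrophile"
  group[ranks > bounds[1] & ranks <= bounds[2]] <- "mesophile"
  group[ranks > bounds[2] & ranks <= bounds[3]] <- "thermophile"
  group[ranks > bounds[3]] <- "hyperthermophile"
  ogt_range <- list(
    psychrophile = c(1, 20), mesophile = c(20.5, 40),
    thermophile = c(40.5, 80), hyperthermophile = c(80.5, 105)
  )
  ogt <- map_dbl(seq_len(n), function(i) {
    r <- ogt_range[[group[i]]]
    round(runif(1, r[1], r[2]), 1)
  })
  lid <- ifelse(rank(liab_lid, ties.method = "first") <= n_short_lid, "short", "long")
  type <- ifelse(rank(liab_type, ties.method = "first") <= n_trimeric, "trimeric", "monomeric")
  tibble(
    species = tree$tip.label,
    adk = tree$tip.label,
    ogt = ogt,
    thermal_group = classify_thermal_group(ogt),
    adk_type = type,
    lid = lid,
    native_temperature = native_temperature(classify_thermal_group(ogt)),
    native_temperature_C = kelvin_to_celsius(native_temperature(classify_thermal_group(ogt)))
  )
}

# deterministic toy fold: an ideal alpha-helix of CA atoms (radius 2.3 A,
# rise 1.5 A, 100 degrees per residue)
helix_ca <- function(n_residues) {
  i <- seq_len(n_residues) - 1
  theta <- i * 100 * pi / 180
  cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
}

#' Simulate a toy trajectory with planted contacts
#'
#' A deterministic helical backbone carries Gaussian positional fluctuations
#' whose standard deviation grows linearly with temperature; selected
#' residue pairs get charged/polar side-chain groups whose centres are
#' placed within the 5 Angstrom contact cutoff for exactly a chosen fraction
#' of frames (and well outside it otherwise). No physics is claimed — the
#' fluctuation and contact statistics are what the downstream modules
#' consume.
#'
#' @param n_residues Number of residues (>= 5).
#' @param temperature Simulation temperature, K.
#' @param seed Random seed.
#' @param n_frames Number of frames (default 100).
#' @param rmsf_scale Function mapping temperature (K) to the per-coordinate
#'   fluctuation sd in Angstrom; default `0.25 + 0.003 * (T - 280)`,
#'   increasing with temperature.
#' @param planted Optional tibble of contacts to plant: `res_i`, `res_j`
#'   (0-based), `name_i`, `name_j` (3-letter codes of classed residues),
#'   `occupancy` (fraction of frames the pair is in contact; realised
#'   exactly, rounded to a frame count).
#' @param extra_classed Optional tibble `res`, `name` giving classed
#'   residues that are not part of a planted pair (their group centres sit
#'   on the backbone surface and may or may not contact anything).
#' @return A list: `trajectory` (`adk_trajectory`), `truth` (list with
#'   `sigma` — the fluctuation sd used — and the `planted` table with
#'   realised occupancies).
#' @export
simulate_trajectory <- function(n_residues, temperature = 300, seed = 1,
                                n_frames = 100,
                                rmsf_scale = function(T) 0.25 + 0.003 * (T - 280),
                                planted = NULL, extra_classed = NULL) {
  if (n_residues < 5) abort("need at least 5 residues")
  set.seed(seed)
  sigma <- rmsf_scale(temperature)
  ca <- helix_ca(n_residues)
  resnames <- rep("ALA", n_residues)
  if (!is.null(planted)) {
    resnames[planted$res_i + 1] <- toupper(planted$name_i)
    resnames[planted$res_j + 1] <- toupper(planted$name_j)
  }
  if (!is.null(extra_classed)) resnames[extra_classed$res + 1] <- toupper(extra_classed$name)

  # topology: CA for everyone; classed residues also carry their group atoms
  # on a small ring whose centroid is the controllable group centre
  atoms <- list()
  for (r in seq_len(n_residues)) {
    atoms[[length(atoms) + 1]] <- tibble(
      atom_name = "CA", element = "C", residue_index = r - 1L,
      residue_name = resnames[r], chain = "A",
      x = ca[r, 1], y = ca[r, 2], z = ca[r, 3]
    )
    grp <- GROUP_ATOMS[[resnames[r]]]
    if (!is.null(grp)) {
      k <- length(grp)
      offs <- if (k == 1) matrix(0, 1, 3) else {
        ang <- 2 * pi * (seq_len(k) - 1) / k
        cbind(0.5 * cos(ang) - mean(0.5 * cos(ang)),
              0.5 * sin(ang) - mean(0.5 * sin(ang)), 0)
      }
      ctr <- ca[r, ] + c(0, 0, 0)
      ctr[1:2] <- ctr[1:2] * (1 + 2 / sqrt(sum(ctr[1:2]^2)))  # 2 A outward
      for (a in seq_len(k)) {
        el <- substr(grp[a], 1, 1)
        atoms[[length(atoms) + 1]] <- tibble(
          atom_name = grp[a], element = el, residue_index = r - 1L,
          residue_name = resnames[r], chain = "A",
          x = ctr[1] + offs[a, 1], y = ctr[2] + offs[a, 2], z = ctr[3] + offs[a, 3]
        )
      }
    }
  }
  atom_tbl <- bind_rows(atoms)
  topo <- new_adk_structure(atom_tbl)
  base <- as.matrix(atom_tbl[, c("x", "y", "z")])

  # planted-contact frame schedules: exactly round(occ * n_frames) on-frames
  schedules <- NULL
  if (!is.null(planted)) {
    schedules <- map(seq_len(nrow(planted)), function(k) {
      n_on <- round(planted$occupancy[k] * n_frames)
      sample(n_frames, n_on)
    })
  }
  group_rows <- function(res) {
    which(atom_tbl$residue_index == res & atom_tbl$atom_name != "CA")
  }
  frames <- map(seq_len(n_frames), function(f) {
    coords <- base + matrix(rnorm(nrow(base) * 3, 0, sigma), ncol = 3)
    if (!is.null(planted)) {
      for (k in seq_len(nrow(planted))) {
        ri <- planted$res_i[k]; rj <- planted$res_j[k]
        rows_i <- group_rows(ri); rows_j <- group_rows(rj)
        # each pair gets its own lateral region, far from the backbone and
        # from other pairs, so planted contacts cannot cross-react
        shift <- 15 * k * c(cos(2.399963 * k), sin(2.399963 * k), 0)
        mid <- (ca[ri + 1, ] + ca[rj + 1, ]) / 2 + shift
        dir <- ca[rj + 1, ] - ca[ri + 1, ]
        dir <- dir / sqrt(sum(dir^2))
        half <- if (f %in% schedules[[k]]) 1.75 else 4.5   # centre gap 3.5 / 9 A
        ctr_i <- mid - half * dir
        ctr_j <- mid + half * dir
        coords[rows_i, ] <- sweep(base[rows_i, , drop = FALSE],
                                  2, colMeans(base[rows_i, , drop = FALSE])) +
          matrix(ctr_i, length(rows_i), 3, byrow = TRUE)
        coords[rows_j, ] <- sweep(base[rows_j, , drop = FALSE],
                                  2, colMeans(base[rows_j, , drop = FALSE])) +
          matrix(ctr_j, length(rows_j), 3, byrow = TRUE)
      }
    }
    coords
  })
  truth_planted <- if (is.null(planted)) NULL else {
    mutate(planted, realised_occupancy = map_dbl(schedules, length) / n_frames)
  }
  list(
    trajectory = new_adk_trajectory(topo, frames),
    truth = list(sigma = sigma, planted = truth_planted)
  )
}

#' Ground-truth parameter set for descriptor simulations
#'
#' Defaults echo the qualitative pattern of thermally adapting flexibility:
#' positive intra- and interspecific temperature slopes on an RMSF-like
#' response (nm scale), a short-LID offset, phylogenetic signal, and small
#' residual plus replicate measurement error. All values are configuration,
#' not constants.
#'
#' @param intercept Baseline response at 0 degC for a long-LID monomeric
#'   protein (default 0.15 nm).
#' @param slope_tnat Interspecific slope per degC of native temperature
#'   (default 0.001).
#' @param slope_deltat Intraspecific slope per degC of temperature offset
#'   from native (default 0.002).
#' @param effect_lid_short Offset for short-LID proteins (default -0.02).
#' @param effect_trimeric Offset for trimeric proteins (default 0).
#' @param sigma2_phylo Phylogenetic variance (default 4e-4).
#' @param sigma2_e Residual variance (default 1e-4).
#' @param se_scale Per-row replicate standard error (default 5e-3).
#' @return A named list of class `adk_truth`.
#' @export
adk_truth <- function(intercept = 0.15, slope_tnat = 0.001,
                      slope_deltat = 0.002, effect_lid_short = -0.02,
                      effect_trimeric = 0, sigma2_phylo = 4e-4,
                      sigma2_e = 1e-4, se_scale = 5e-3) {
  structure(
    list(intercept = intercept, slope_tnat = slope_tnat,
         slope_deltat = slope_deltat, effect_lid_short = effect_lid_short,
         effect_trimeric = effect_trimeric, sigma2_phylo = sigma2_phylo,
         sigma2_e = sigma2_e, se_scale = se_scale),
    class = "adk_truth"
  )
}

#' Simulate a merged descriptor dataset
#'
#' Builds the response table the Gaussian meta-analytic models consume:
#' `y = X beta + u + e + measurement noise`, with `u` Brownian on the tree.
#' By default five designated species receive the full temperature ladder
#' (native plus seven more temperatures spanning 6.85-94.35 degC) and every
#' other species only its native temperature.
#'
#' @param tree An [ape::phylo] tree.
#' @param metadata Tibble from [simulate_metadata()].
#' @param truth An [adk_truth()] parameter set.
#' @param seed Random seed.
#' @param ladder_species Species receiving the multi-temperature ladder
#'   (default: the first 5 monomeric species in tip order).
#' @param response Name for the response column (default `"rmsf"`).
#' @return A tibble: `species`, `adk`, `temperature` (K), `tnat_C`,
#'   `delta_T` (degC from native), `adk_type`, `lid`, response column, `se`;
#'   attribute `truth` carries the generating parameters and the realised
#'   `u`.
#' @export
simulate_descriptor_dataset <- function(tree, metadata, truth = adk_truth(),
                                        seed = 1, ladder_species = NULL,
                                        response = "rmsf") {
  set.seed(seed)
  if (is.null(ladder_species)) {
    mono <- metadata$species[metadata$adk_type == "monomeric"]
    ladder_species <- head(mono, 5)
  }
  grid_K <- seq(280, 367.5, by = 12.5)
  rows <- map(seq_len(nrow(metadata)), function(i) {
    md <- metadata[i, ]
    temps <- md$native_temperature
    if (md$species %in% ladder_species) {
      others <- grid_K[-which.min(abs(grid_K - md$native_temperature))]
      temps <- c(temps, others)
    }
    tibble(
      species = md$species, adk = md$adk, temperature = temps,
      tnat_C = md$native_temperature_C,
      delta_T = kelvin_to_celsius(temps) - md$native_temperature_C,
      adk_type = md$adk_type, lid = md$lid
    )
  }) %>% bind_rows()
  u <- brownian_deviates(tree, truth$sigma2_phylo)
  mu <- truth$intercept +
    truth$slope_tnat * rows$tnat_C +
    truth$slope_deltat * rows$delta_T +
    truth$effect_lid_short * (rows$lid == "short") +
    truth$effect_trimeric * (rows$adk_type == "trimeric")
  e <- rnorm(nrow(rows), 0, sqrt(truth$sigma2_e))
  se <- rep(truth$se_scale, nrow(rows))
  meas <- rnorm(nrow(rows), 0, se)
  rows[[response]] <- mu + u[rows$species] + e + meas
  rows$se <- se
  attr(rows, "truth") <- c(truth, list(u = u))
  rows
}

#' Simulate binary contact matrices from liabilities on a tree
#'
#' Each contact column's presence/absence vector derives from a liability
#' `l = intercept + b + e` with `b ~ N(0, sigma2_phylo C_unit)` and
#' `e ~ N(0, 1)`; presence means `l >= 0`. The intercept is chosen as
#' `qnorm(p) * sqrt(1 + sigma2_phylo)` so the marginal presence probability
#' equals the requested `p`.
#'
#' @param tree An [ape::phylo] tree (tips = proteins).
#' @param probabilities Numeric vector of requested marginal presence
#'   probabilities, one per contact column.
#' @param seed Random seed.
#' @param sigma2_phylo Phylogenetic liability variance (default 1).
#' @param contact_ids Optional column names (default `"c<k>"`).
#' @return A list: `matrix` (tips x contacts binary, dimnames set), `truth`
#'   (tibble: `contact_id`, `probability`, `intercept`).
#' @export
simulate_contact_matrices <- function(tree, probabilities, seed = 1,
                                      sigma2_phylo = 1, contact_ids = NULL) {
  if (any(probabilities < 0 | probabilities > 1)) abort("probabilities must be in [0, 1]")
  set.seed(seed)
  n <- length(tree$tip.label)
  k <- length(probabilities)
  if (is.null(contact_ids)) contact_ids <- paste0("c", seq_len(k))
  intercepts <- qnorm(probabilities) * sqrt(1 + sigma2_phylo)
  m <- matrix(0L, n, k, dimnames = list(tree$tip.label, contact_ids))
  L <- brownian_chol(tree)
  for (j in seq_len(k)) {
    if (probabilities[j] == 0) next
    if (probabilities[j] == 1) { m[, j] <- 1L; next }
    b <- brownian_deviates(tree, sigma2_phylo, L = L)
    l <- intercepts[j] + b[tree$tip.label] + rnorm(n)
    m[, j] <- as.integer(l >= 0)
  }
  list(
    matrix = m,
    truth = tibble(contact_id = contact_ids, probability = probabilities,
                   intercept = intercepts)
  )
}

#' Simulate a gapped amino-acid alignment for a set of structures
#'
#' Takes each structure's one-letter sequence and inserts gaps at random
#' positions so all rows share one width; the ungapped rows equal the input
#' sequences, so alignment-column mapping of contacts round-trips.
#'
#' @param sequences Named character vector of ungapped sequences.
#' @param seed Random seed.
#' @param width Alignment width (default: max sequence length + 4).
#' @return A tibble with `id`, `sequence` as from [read_fasta_alignment()].
#' @export
simulate_alignment <- function(sequences, seed = 1, width = NULL) {
  set.seed(seed)
  lens <- nchar(sequences)
  if (is.null(width)) width <- max(lens) + 4
  if (width < max(lens)) abort("width smaller than the longest sequence")
  rows <- map_chr(seq_along(sequences), function(i) {
    chars <- strsplit(sequences[[i]], "")[[1]]
    keep_cols <- sort(sample(width, lens[i]))
    row <- rep("-", width)
    row[keep_cols] <- chars
    paste(row, collapse = "")
  })
  out <- tibble(id = names(sequences), sequence = rows)
  attr(out, "n_columns") <- as.integer(width)
  out
}
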