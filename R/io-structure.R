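# Structure and Trajectory containers
#
# A structure is a tibble of atoms plus a derived residue grouping; a
# trajectory is one topology shared by an ordered stack of coordinate frames.
# Coordinates are Angstrom throughout.

WATER_IONS <- c("HOH", "WAT", "SOL", "TIP", "TIP3", "NA", "CL", "K", "MG", "CA2", "ZN")

new_adk_structure <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  needed <- c("atom_name", "element", "residue_index", "residue_name", "chain", "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("structure atoms table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("non-finite atom coordinates")
  }
  for (ch in unique(atoms$chain)) {
    ri <- atoms$residue_index[atoms$chain == ch]
    if (is.unsorted(ri)) abort(paste0("residue_index not non-decreasing within chain ", ch))
  }
  structure(list(atoms = as_tibble(atoms)), class = "adk_structure")
}

#' @export
print.adk_structure <- function(x, ...) {
  cat(sprintf(
    "<adk_structure> %d atoms, %d residues, %d chain(s)\n",
    nrow(x$atoms), n_residues(x), length(unique(x$atoms$chain))
  ))
  invisible(x)
}

#' Number of residues in a structure
#'
#' Residues are the distinct (chain, residue_index) pairs, in file order.
#'
#' @param structure An `adk_structure`.
#' @return Integer count.
#' @export
n_residues <- function(structure) {
  nrow(distinct(structure$atoms, .data$chain, .data$residue_index))
}

#' Residue table of a structure
#'
#' @param structure An `adk_structure`.
#' @return A tibble with one row per residue: `chain`, `residue_index`
#'   (0-based), `residue_name`, `n_atoms`, in file order.
#' @export
residues <- function(structure) {
  structure$atoms %>%
    group_by(.data$chain, .data$residue_index) %>%
    summarise(
      residue_name = .data$residue_name[1],
      n_atoms = dplyr::n(),
      .groups = "drop"
    )
}

#' One-letter amino-acid sequence of a structure chain
#'
#' @param structure An `adk_structure`.
#' @param chain Chain identifier (default: first chain in file order).
#' @return Character scalar; unknown residue names become `"X"`.
#' @export
structure_sequence <- function(structure, chain = NULL) {
  atoms <- structure$atoms
  if (is.null(chain)) chain <- atoms$chain[1]
  res <- residues(structure) %>% filter(.data$chain == !!chain)
  aa3 <- toupper(res$residue_name)
  one <- AA_3TO1[aa3]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q", GLU = "E",
  GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
  PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

new_adk_trajectory <- function(topology, frames, frame_interval = 0.5) {
  stopifnot(inherits(topology, "adk_structure"))
  n_atoms <- nrow(topology$atoms)
  if (length(frames) < 1) abort("trajectory needs at least one frame")
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n_atoms && ncol(f) == 3, logical(1))
  if (!all(ok)) {
    abort(sprintf(
      "structural mismatch: frame(s) %s do not have %d x 3 coordinates",
      paste(which(!ok), collapse = ","), n_atoms
    ))
  }
  structure(
    list(topology = topology, frames = frames, frame_interval = frame_interval),
    class = "adk_trajectory"
  )
}

#' @export
print.adk_trajectory <- function(x, ...) {
  cat(sprintf(
    "<adk_trajectory> %d frames x %d atoms, interval %.2f ns\n",
    length(x$frames), nrow(x$topology$atoms), x$frame_interval
  ))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `adk_trajectory`.
#' @return Integer.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Indices of alpha-carbon atoms
#' @param structure An `adk_structure`.
#' @param chain Optional chain id to restrict to.
#' @return Integer vector of row indices into the atom table.
#' @export
alpha_carbons <- function(structure, chain = NULL) {
  atoms <- structure$atoms
  sel <- atoms$atom_name == "CA" & toupper(atoms$residue_name) %in% names(AA_3TO1)
  if (!is.null(chain)) sel <- sel & atoms$chain == chain
  which(sel)
}

# --- PDB reading (bio3d backend) ------------------------------------------

bio3d_to_atoms <- function(pdb, drop_solvent = TRUE) {
  at <- pdb$atom
  keep <- rep(TRUE, nrow(at))
  if (drop_solvent) keep <- !(toupper(at$resid) %in% WATER_IONS)
  # altLoc: keep highest occupancy, tie broken by file order
  if (!is.null(at$alt) && any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    best <- tapply(seq_len(nrow(at)), key, function(idx) {
      idx[which.max(occ[idx])]
    })
    keep_alt <- logical(nrow(at))
    keep_alt[unlist(best)] <- TRUE
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    keep <- keep & (!dup | keep_alt)
  }
  at <- at[keep, , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("[^A-Za-z].*", "", at$elety), 1, 1)
  }
  elem <- ifelse(is.na(elem) | elem == "", substr(at$elety, 1, 1), elem)
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  # residue_index: 0-based, renumbered per chain in order of appearance
  ridx <- integer(nrow(at))
  for (ch in unique(chain)) {
    i <- chain == ch
    ridx[i] <- match(at$resno[i], unique(at$resno[i])) - 1L
  }
  tibble(
    atom_name = at$elety,
    element = toupper(elem),
    residue_index = ridx,
    residue_name = toupper(at$resid),
    chain = chain,
    x = at$x, y = at$y, z = at$z
  )
}

#' Read a single-model PDB file
#'
#' Parses ATOM/HETATM records via [bio3d::read.pdb()]; waters and common ions
#' are dropped, and alternate locations are resolved to the highest-occupancy
#' conformer (ties: first encountered).
#'
#' @param path Path to a PDB file.
#' @param drop_solvent Drop water and ion records (default `TRUE`).
#' @return An `adk_structure`.
#' @export
read_pdb <- function(path, drop_solvent = TRUE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) abort(paste0("PDB parse error in ", path, ": ", conditionMessage(e)))
  )
  new_adk_structure(bio3d_to_atoms(pdb, drop_solvent))
}

#' Read a multi-model PDB file as a trajectory
#'
#' MODEL/ENDMDL blocks delimit frames; all frames must share the topology of
#' the first.
#'
#' @param path Path to a multi-model PDB file.
#' @param frame_interval Time between consecutive frames, ns (default 0.5).
#' @param drop_solvent Drop water and ion records (default `TRUE`).
#' @return An `adk_trajectory`.
#' @export
read_multimodel_pdb <- function(path, frame_interval = 0.5, drop_solvent = TRUE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) abort(paste0("PDB parse error in ", path, ": ", conditionMessage(e)))
  )
  atoms <- bio3d_to_atoms(pdb, drop_solvent)
  keep <- if (drop_solvent) !(toupper(pdb$atom$resid) %in% WATER_IONS) else rep(TRUE, nrow(pdb$atom))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
    if (any(!is.finite(m))) {
      abort(sprintf("structural mismatch: frame %d has missing coordinates", i))
    }
    colnames(m) <- c("x", "y", "z")
    m
  })
  topology <- new_adk_structure(atoms)
  new_adk_trajectory(topology, frames, frame_interval)
}

# --- PDB writing -----------------------------------------------------------

format_atom_line <- function(i, name, resname, chain, resno, x, y, z, element) {
  # PDB fixed columns; atom names of <4 chars start in column 14
  nm <- if (nchar(name) < 4) paste0(" ", formatC(name, width = -3)) else formatC(name, width = -4)
  sprintf(
    "ATOM  %5d %s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    i %% 100000, nm, "", resname, chain, resno %% 10000, x, y, z, 1.0, 0.0, element
  )
}

structure_atom_lines <- function(structure, coords = NULL) {
  at <- structure$atoms
  if (is.null(coords)) coords <- as.matrix(at[, c("x", "y", "z")])
  vapply(seq_len(nrow(at)), function(i) {
    format_atom_line(
      i, at$atom_name[i], at$residue_name[i], at$chain[i],
      at$residue_index[i] + 1L, coords[i, 1], coords[i, 2], coords[i, 3], at$element[i]
    )
  }, character(1))
}

#' Write a structure to a PDB file
#'
#' @param structure An `adk_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  writeLines(c(structure_atom_lines(structure), "END"), path)
  invisible(path)
}

#' Write a trajectory to a multi-model PDB file
#'
#' Frames become MODEL/ENDMDL blocks sharing the trajectory topology.
#' Coordinates are written at PDB precision (1e-3 Angstrom).
#'
#' @param traj An `adk_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(structure_atom_lines(traj$topology, traj$frames[[i]]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
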