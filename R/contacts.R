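# Side-chain contact detection and classification
#
# Contacts are pairs of residues whose interacting chemical-group centres lie
# within a distance cutoff (default 5 Angstrom = 0.5 nm). Only four type
# classes exist: salt bridges (negative-positive) and the three charged/polar
# combinations. Persistent contacts must be present in at least half of the
# pooled trajectory frames.

RESIDUE_CLASS <- c(
  ARG = "positive", LYS = "positive",
  ASP = "negative", GLU = "negative",
  ASN = "polar", GLN = "polar", SER = "polar", THR = "polar", TYR = "polar"
)

# atoms defining the interacting chemical group of each classed residue
# (carboxyl for Asp/Glu, guanidinium for Arg, ammonium for Lys, amide for
# Asn/Gln, hydroxyl for Ser/Thr/Tyr)
GROUP_ATOMS <- list(
  ASP = c("CG", "OD1", "OD2"),
  GLU = c("CD", "OE1", "OE2"),
  ARG = c("CZ", "NE", "NH1", "NH2"),
  LYS = "NZ",
  ASN = c("CG", "OD1", "ND2"),
  GLN = c("CD", "OE1", "NE2"),
  SER = "OG",
  THR = "OG1",
  TYR = "OH"
)

CONTACT_TYPES <- c("sb", "pos-pol", "neg-pol", "pol-pol")

#' Chemical class of an amino-acid residue
#'
#' Arg/Lys are positively charged, Asp/Glu negatively charged,
#' Asn/Gln/Ser/Thr/Tyr polar; every other standard residue (including His,
#' Trp, Cys, Met) is `other` and takes no part in contact typing.
#'
#' @param residue_name 3-letter residue code(s), case-insensitive.
#' @return Character vector in `{positive, negative, polar, other}`.
#' @export
residue_class <- function(residue_name) {
  code <- toupper(residue_name)
  bad <- setdiff(unique(code), names(AA_3TO1))
  if (length(bad) > 0) abort(paste0("unknown residue code(s): ", paste(bad, collapse = ", ")))
  cls <- unname(RESIDUE_CLASS[code])
  cls[is.na(cls)] <- "other"
  cls
}

pair_contact_type <- function(class_i, class_j) {
  key <- paste(pmin(class_i, class_j), pmax(class_i, class_j))
  unname(c(
    "negative positive" = "sb",
    "polar positive"    = "pos-pol",
    "negative polar"    = "neg-pol",
    "polar polar"       = "pol-pol"
  )[key])
}

#' Interacting-group centres of all classed residues in a frame
#'
#' @param structure An `adk_structure` (topology).
#' @param coords Optional n x 3 coordinates overriding the topology's.
#' @param chain Chain to analyse (default: first chain).
#' @return A tibble: `residue_index`, `residue_name`, `class`, `cx`, `cy`,
#'   `cz` — one row per residue of class other than `other`.
#' @export
group_centers <- function(structure, coords = NULL, chain = NULL) {
  atoms <- structure$atoms
  if (is.null(coords)) coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (is.null(chain)) chain <- atoms$chain[1]
  in_chain <- atoms$chain == chain
  res <- residues(structure) %>% filter(.data$chain == !!chain)
  res$class <- residue_class(res$residue_name)
  res <- filter(res, .data$class != "other")
  if (nrow(res) == 0) {
    return(tibble(
      residue_index = integer(), residue_name = character(), class = character(),
      cx = numeric(), cy = numeric(), cz = numeric()
    ))
  }
  centers <- map(seq_len(nrow(res)), function(k) {
    want <- GROUP_ATOMS[[res$residue_name[k]]]
    rows <- which(in_chain &
                    atoms$residue_index == res$residue_index[k] &
                    atoms$atom_name %in% want)
    if (length(rows) != length(want)) {
      abort(sprintf(
        "residue %s %d: group atom(s) %s missing",
        res$residue_name[k], res$residue_index[k],
        paste(setdiff(want, atoms$atom_name[rows]), collapse = ",")
      ))
    }
    colMeans(coords[rows, , drop = FALSE])
  })
  m <- do.call(rbind, centers)
  tibble(
    residue_index = res$residue_index, residue_name = res$residue_name,
    class = res$class, cx = m[, 1], cy = m[, 2], cz = m[, 3]
  )
}

#' Group centre of a single residue
#'
#' @param structure An `adk_structure`.
#' @param residue_index 0-based residue index.
#' @param chain Chain id (default first chain).
#' @return Numeric xyz (Angstrom), or `NULL` for class `other`.
#' @export
group_center <- function(structure, residue_index, chain = NULL) {
  gc <- group_centers(structure, chain = chain)
  row <- gc[gc$residue_index == residue_index, ]
  if (nrow(row) == 0) return(NULL)
  c(row$cx, row$cy, row$cz)
}

#' Detect typed side-chain contacts in one frame
#'
#' Unordered residue pairs at sequence separation `|i - j| >= min_separation`
#' whose group centres are within `cutoff`, typed by their residue classes.
#' Like-charge pairs and pairs involving class `other` are not contacts.
#'
#' @param structure An `adk_structure` (topology).
#' @param coords Optional frame coordinates.
#' @param cutoff Distance cutoff, Angstrom (default 5.0 = 0.5 nm).
#' @param min_separation Minimum sequence separation (default 2: adjacent
#'   residues excluded).
#' @param chain Chain id (default first chain).
#' @return A tibble: `res_i`, `res_j` (0-based, `res_i < res_j`), `type`,
#'   `distance` (Angstrom).
#' @export
detect_frame_contacts <- function(structure, coords = NULL, cutoff = 5.0,
                                  min_separation = 2, chain = NULL) {
  gc <- group_centers(structure, coords = coords, chain = chain)
  empty <- tibble(
    res_i = integer(), res_j = integer(), type = character(), distance = numeric()
  )
  if (nrow(gc) < 2) return(empty)
  idx <- which(upper.tri(matrix(0, nrow(gc), nrow(gc))), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  sep_ok <- abs(gc$residue_index[i] - gc$residue_index[j]) >= min_separation
  type <- pair_contact_type(gc$class[i], gc$class[j])
  d <- sqrt((gc$cx[i] - gc$cx[j])^2 + (gc$cy[i] - gc$cy[j])^2 + (gc$cz[i] - gc$cz[j])^2)
  keep <- sep_ok & !is.na(type) & d <= cutoff
  if (!any(keep)) return(empty)
  tibble(
    res_i = gc$residue_index[i][keep], res_j = gc$residue_index[j][keep],
    type = type[keep], distance = d[keep]
  ) %>%
    mutate(
      lo = pmin(.data$res_i, .data$res_j), hi = pmax(.data$res_i, .data$res_j),
      res_i = .data$lo, res_j = .data$hi
    ) %>%
    select(-"lo", -"hi") %>%
    arrange(.data$res_i, .data$res_j)
}

#' Contacts of every frame of a trajectory
#'
#' @param traj An `adk_trajectory`.
#' @inheritParams detect_frame_contacts
#' @return A tibble with a `frame` column prepended to the per-frame contact
#'   rows.
#' @export
trajectory_contacts <- function(traj, cutoff = 5.0, min_separation = 2, chain = NULL) {
  map(seq_len(n_frames(traj)), function(f) {
    ct <- detect_frame_contacts(traj$topology, coords = traj$frames[[f]],
                                cutoff = cutoff, min_separation = min_separation,
                                chain = chain)
    if (nrow(ct) > 0) ct$frame <- f
    ct
  }) %>%
    bind_rows()
}

#' Filter per-frame contacts by occupancy
#'
#' Keeps residue pairs present in at least `threshold` of all pooled frames
#' (replicates concatenated; a pair present in exactly half the frames is
#' kept). Per-replicate filtering is available via `per_replicate`, in which
#' case a `replicate` column must be present and the pair must pass within
#' every replicate.
#'
#' @param frame_contacts Tibble from [trajectory_contacts()] (needs `frame`);
#'   frames from several replicates may be concatenated with distinct frame
#'   ids or an extra `replicate` column.
#' @param n_frames Total number of pooled frames the occupancy is measured
#'   against.
#' @param threshold Minimum occupancy fraction (default 0.5).
#' @param per_replicate Apply the threshold within each replicate instead of
#'   pooling (default `FALSE`).
#' @return A tibble: `res_i`, `res_j`, `type`, `occupancy`.
#' @export
occupancy_filter <- function(frame_contacts, n_frames, threshold = 0.5,
                             per_replicate = FALSE) {
  if (n_frames < 1) abort("n_frames must be >= 1")
  if (nrow(frame_contacts) == 0) {
    return(tibble(res_i = integer(), res_j = integer(),
                  type = character(), occupancy = numeric()))
  }
  pooled <- frame_contacts %>%
    group_by(.data$res_i, .data$res_j, .data$type) %>%
    summarise(occupancy = dplyr::n() / n_frames, .groups = "drop")
  if (per_replicate) {
    if (!"replicate" %in% names(frame_contacts)) {
      abort("per_replicate filtering needs a 'replicate' column")
    }
    n_rep <- length(unique(frame_contacts$replicate))
    frames_per_rep <- n_frames / n_rep
    ok <- frame_contacts %>%
      group_by(.data$res_i, .data$res_j, .data$replicate) %>%
      summarise(occ = dplyr::n() / frames_per_rep, .groups = "drop_last") %>%
      summarise(pass = dplyr::n() == n_rep && all(.data$occ >= threshold), .groups = "drop") %>%
      filter(.data$pass)
    pooled <- dplyr::semi_join(pooled, ok, by = c("res_i", "res_j"))
  } else {
    pooled <- filter(pooled, .data$occupancy >= threshold)
  }
  arrange(pooled, .data$res_i, .data$res_j)
}

#' Map residue-pair contacts to alignment-column contact ids
#'
#' The protein's ungapped alignment row must equal its structure-derived
#' sequence; residue positions are then carried through the gapped row to
#' 1-based alignment columns, giving a contact id `(column_i, column_j)` with
#' `column_i < column_j` comparable across proteins.
#'
#' @param contacts Tibble with `res_i`, `res_j` (0-based residue indices) and
#'   any other columns to carry along.
#' @param sequence The protein's one-letter sequence (from
#'   [structure_sequence()]).
#' @param alignment_row The protein's gapped row of the master alignment.
#' @return `contacts` with `column_i`, `column_j` added.
#' @export
map_to_alignment <- function(contacts, sequence, alignment_row) {
  ungapped <- gsub("-", "", alignment_row)
  if (ungapped != sequence) {
    s1 <- strsplit(ungapped, "")[[1]]; s2 <- strsplit(sequence, "")[[1]]
    k <- if (length(s1) != length(s2)) min(length(s1), length(s2)) + 1 else which(s1 != s2)[1]
    abort(sprintf("alignment row disagrees with structure sequence at position %d", k))
  }
  colmap <- alignment_column_map(alignment_row)
  ci <- colmap[contacts$res_i + 1L]
  cj <- colmap[contacts$res_j + 1L]
  contacts %>%
    mutate(column_i = pmin(ci, cj), column_j = pmax(ci, cj)) %>%
    arrange(.data$column_i, .data$column_j)
}

#' Count persistent contacts by type
#'
#' @param contacts Tibble with a `type` column.
#' @return One-row tibble with columns `sb`, `pos-pol`, `neg-pol`, `pol-pol`,
#'   `total`.
#' @export
contact_counts <- function(contacts) {
  counts <- table(factor(contacts$type, levels = CONTACT_TYPES))
  out <- as_tibble(as.list(counts))
  out$total <- nrow(contacts)
  out
}

#' Binary contact matrices per thermal group and contact type
#'
#' Rows are proteins, columns are alignment-column contact ids
#' (`"<column_i>-<column_j>"`); a cell is 1 when that protein has the contact.
#' Separate matrices are built for every (thermal group, contact type)
#' combination observed.
#'
#' @param contact_table Tibble of persistent, alignment-mapped contacts for
#'   all proteins: columns `adk`, `column_i`, `column_j`, `type`.
#' @param metadata Tibble mapping `adk` to `thermal_group` (and any other
#'   columns); proteins absent from `contact_table` contribute all-zero rows.
#' @param adk_subset Optional protein ids to restrict rows to (e.g. the
#'   monomeric subset used for networks).
#' @return A named list of binary matrices, names `"<group>.<type>"`.
#' @export
build_contact_matrices <- function(contact_table, metadata, adk_subset = NULL) {
  stopifnot(all(c("adk", "column_i", "column_j", "type") %in% names(contact_table)))
  if (!is.null(adk_subset)) {
    metadata <- filter(metadata, .data$adk %in% adk_subset)
    contact_table <- filter(contact_table, .data$adk %in% adk_subset)
  }
  missing <- setdiff(unique(contact_table$adk), metadata$adk)
  if (length(missing) > 0) {
    abort(paste0("contact table has proteins missing from metadata: ",
                 paste(missing, collapse = ", ")))
  }
  contact_table <- mutate(
    contact_table,
    contact_id = paste0(.data$column_i, "-", .data$column_j)
  )
  out <- list()
  for (g in intersect(THERMAL_GROUPS, unique(metadata$thermal_group))) {
    adks_g <- metadata$adk[metadata$thermal_group == g]
    sub_g <- filter(contact_table, .data$adk %in% adks_g)
    for (ty in intersect(CONTACT_TYPES, unique(sub_g$type))) {
      sub <- filter(sub_g, .data$type == ty)
      ids <- sort(unique(sub$contact_id))
      m <- matrix(0L, nrow = length(adks_g), ncol = length(ids),
                  dimnames = list(adks_g, ids))
      m[cbind(match(sub$adk, adks_g), match(sub$contact_id, ids))] <- 1L
      out[[paste(g, ty, sep = ".")]] <- m
    }
  }
  out
}
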