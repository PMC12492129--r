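# Shared in-code fixtures

# a bare structure from residue specs: list of (residue_name, atoms tibble rows)
make_structure <- function(atom_df) {
  thermadk:::new_adk_structure(atom_df)
}

atom_row <- function(atom_name, element, residue_index, residue_name,
                     x, y, z, chain = "A") {
  tibble::tibble(
    atom_name = atom_name, element = element,
    residue_index = as.integer(residue_index), residue_name = residue_name,
    chain = chain, x = x, y = y, z = z
  )
}

# two-residue Asp/Arg structure whose group centres sit `gap` Angstrom apart
# (residue indices 0 and 5 so the sequence-separation filter passes)
asp_arg_pair <- function(gap) {
  dplyr::bind_rows(
    atom_row("CA", "C", 0, "ASP", -gap / 2 - 3, 0, 0),
    atom_row("CG", "C", 0, "ASP", -gap / 2, 0, 0.5),
    atom_row("OD1", "O", 0, "ASP", -gap / 2 - 0.43, 0.25, -0.25),
    atom_row("OD2", "O", 0, "ASP", -gap / 2 + 0.43, -0.25, -0.25),
    atom_row("CA", "C", 5, "ARG", gap / 2 + 3, 0, 0),
    atom_row("CZ", "C", 5, "ARG", gap / 2, 0, 0.4),
    atom_row("NE", "N", 5, "ARG", gap / 2 - 0.3, 0.3, -0.2),
    atom_row("NH1", "N", 5, "ARG", gap / 2 + 0.3, -0.3, -0.2),
    atom_row("NH2", "N", 5, "ARG", gap / 2, 0, 0)
  ) %>% make_structure()
}

# random rigid motion: proper rotation + translation
random_rigid_motion <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, 0, 10))
}

apply_rigid <- function(coords, motion) {
  sweep(coords %*% t(motion$R), 2, motion$t, FUN = "+")
}

# independent all-pairs contact scan (the oracle detect_frame_contacts is
# checked against); deliberately loop-based and free of the package's
# vectorised pair machinery
brute_contacts <- function(structure, coords) {
  gc <- group_centers(structure, coords = coords)
  out <- list()
  if (nrow(gc) >= 2) {
    for (i in seq_len(nrow(gc) - 1)) {
      for (j in (i + 1):nrow(gc)) {
        if (abs(gc$residue_index[i] - gc$residue_index[j]) < 2) next
        cls <- sort(c(gc$class[i], gc$class[j]))
        type <- if (identical(cls, c("negative", "positive"))) "sb"
        else if (identical(cls, c("polar", "positive"))) "pos-pol"
        else if (identical(cls, c("negative", "polar"))) "neg-pol"
        else if (identical(cls, c("polar", "polar"))) "pol-pol"
        else NA_character_
        if (is.na(type)) next
        d <- sqrt(sum((c(gc$cx[i], gc$cy[i], gc$cz[i]) -
                         c(gc$cx[j], gc$cy[j], gc$cz[j]))^2))
        if (d <= 5.0) {
          out[[length(out) + 1]] <- tibble::tibble(
            res_i = min(gc$residue_index[i], gc$residue_index[j]),
            res_j = max(gc$residue_index[i], gc$residue_index[j]),
            type = type
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(res_i = integer(), res_j = integer(), type = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), res_i, res_j)
}

# minimal hand-built adk_fit for post-processing unit tests
fake_fit <- function(samples, family = "gaussian_mev", X = NULL,
                     phylo = "sigma2_phylo" %in% colnames(samples),
                     d_bar = NA_real_, d_hat = NA_real_, se2 = 0,
                     latent_mean = NULL) {
  structure(
    list(
      family = family, response = "y",
      fixed = setdiff(colnames(samples),
                      c("(Intercept)", "sigma2_phylo", "sigma2_e", "deviance")),
      phylo = phylo,
      control = thermadk::mcmc_control(family, n_iter = 300, burn_in = 100,
                                       thin = 1, n_chains = 1),
      X = X, species = character(0),
      chains = list(samples), samples = samples,
      u_mean = NULL, latent_mean = latent_mean,
      d_bar = d_bar, d_hat = d_hat, se2 = se2, y = numeric(0)
    ),
    class = "adk_fit"
  )
}
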