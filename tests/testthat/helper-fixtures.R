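# Random in-memory docked ligand with values at 3-decimal precision, so that
# file round-trips are exact.
rand_ligand <- function(id = "ZINC000000001", n_modes = sample(2:12, 1),
                        with_atoms = TRUE) {
  e1 <- round(runif(1, -12, -6), 3)
  gaps <- round(runif(n_modes - 1, 0, 0.8), 3)
  lb <- c(0, round(runif(n_modes - 1, 0.5, 5), 3))
  atoms <- NULL
  if (with_atoms) {
    n <- sample(4:12, 1)
    types <- sample(c("C", "A", "N", "OA", "HD", "SA"), n, replace = TRUE)
    atoms <- data.frame(
      serial = seq_len(n),
      name = paste0(dockselect::autodock_element(types), seq_len(n)),
      type = types,
      element = dockselect::autodock_element(types),
      x = round(runif(n, -10, 10), 3),
      y = round(runif(n, -10, 10), 3),
      z = round(runif(n, -10, 10), 3),
      charge = round(runif(n, -0.8, 0.8), 3),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(ligand_id = id,
         modes = data.frame(rank = seq_len(n_modes),
                            affinity = e1 + cumsum(c(0, gaps)),
                            rmsd_lb = lb,
                            rmsd_ub = lb + c(0, round(runif(n_modes - 1, 0, 3), 3))),
         mode1_atoms = atoms, torsdof = sample(0:20, 1),
         order_violation = FALSE, source_path = NA_character_),
    class = "docked_ligand"
  )
}

# One-mode ligand with a given first-mode energy, for selectivity tests.
one_mode_ligand <- function(id, ea) {
  structure(
    list(ligand_id = id,
         modes = data.frame(rank = 1L, affinity = ea, rmsd_lb = 0, rmsd_ub = 0),
         mode1_atoms = NULL, torsdof = 0L, order_violation = FALSE,
         source_path = NA_character_),
    class = "docked_ligand"
  )
}

screen_from_energies <- function(energies) {
  out <- Map(one_mode_ligand, names(energies), energies)
  names(out) <- names(energies)
  out
}

# selectivity_records built directly from signed values, for summary tests.
records_from_signed <- function(s, threshold = 0.1) {
  structure(
    data.frame(
      ligand_id = sprintf("L%06d", seq_along(s)),
      ea_target_a = -9, ea_target_b = -9 - s,
      s_signed = s, delta_ea = abs(s),
      label = dockselect::classify_selectivity(s, threshold),
      stringsAsFactors = FALSE
    ),
    class = c("selectivity_records", "data.frame"),
    threshold = threshold, target_names = c("A", "B"),
    n_unpaired_a = 0L, n_unpaired_b = 0L
  )
}

# Random receptor whose atoms are grouped into residues, for contact tests.
rand_receptor <- function(n_residues = 5, atoms_per_res = 3, spread = 8) {
  rows <- lapply(seq_len(n_residues), function(r) {
    center <- runif(3, -spread, spread)
    n <- atoms_per_res
    data.frame(
      serial = (r - 1L) * n + seq_len(n),
      atom_name = paste0("A", seq_len(n)),
      residue_name = sample(c("SER", "HIS", "GLU", "TYR"), 1),
      residue_number = r,
      chain = "A",
      x = round(center[1] + runif(n, -1, 1), 3),
      y = round(center[2] + runif(n, -1, 1), 3),
      z = round(center[3] + runif(n, -1, 1), 3),
      charge = round(runif(n, -0.5, 0.5), 3),
      type = sample(c("C", "OA", "N"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  atoms <- do.call(rbind, rows)
  atoms$element <- dockselect::autodock_element(atoms$type)
  structure(list(target_name = "rand", atoms = atoms), class = "receptor")
}

# Exhaustive all-pairs contact oracle: for every ligand atom and residue,
# the minimum atom-atom distance, kept when <= the element's cutoff.
contact_oracle <- function(ligand, receptor, cutoffs) {
  la <- ligand$mode1_atoms
  ra <- receptor$atoms
  out <- list()
  for (i in seq_len(nrow(la))) {
    el <- la$element[i]
    if (!el %in% names(cutoffs)) next
    for (key in unique(paste(ra$chain, ra$residue_number, sep = "|"))) {
      idx <- paste(ra$chain, ra$residue_number, sep = "|") == key
      dmin <- Inf
      for (j in which(idx)) {
        d <- sqrt((la$x[i] - ra$x[j])^2 + (la$y[i] - ra$y[j])^2 +
                    (la$z[i] - ra$z[j])^2)
        if (d < dmin) dmin <- d
      }
      if (dmin <= cutoffs[[el]]) {
        out[[length(out) + 1L]] <- data.frame(
          atom_serial = la$serial[i], element = el,
          residue_number = ra$residue_number[idx][1],
          min_distance = dmin, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(atom_serial = integer(0), element = character(0),
                      residue_number = integer(0), min_distance = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$residue_number, res$atom_serial), , drop = FALSE]
}
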