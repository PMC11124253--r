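#' Configuration for a synthetic paired screen
#'
#' Describes the distributional shape of a mock dual-target virtual screen
#' with planted ground truth. The defaults emulate the empirical features of
#' paired cholinesterase screens: first-mode energies around -8.5 kcal/mol;
#' roughly 48% / 46% / 6% A-selective / B-selective / nonselective ligands;
#' |dEA| magnitudes that are gamma-shaped above the selectivity threshold and
#' concentrated below ~10 kcal/mol, with the A-selective side tighter (its
#' observed maximum is a few kcal/mol) than the B-selective side; and a small
#' extreme tail of B-selective ligands whose target-A energies turn positive
#' (repulsive), producing |dEA| values beyond 100 kcal/mol. That tail is a
#' separate uniform component rather than a stretched gamma, since it arises
#' from a distinct mechanism (large ligands that cannot fit the narrower
#' gorge). Mode counts vary over 6-20 as screens are commonly run.
#'
#' Selective magnitudes are drawn as `threshold + guard + rgamma(shape,
#' scale)` and nonselective signed values uniformly on
#' `(-(threshold - guard), threshold - guard)`; the guard band (default 0.005
#' kcal/mol) keeps every planted label strictly on its side of the threshold
#' even after energies are rounded to `digits` decimals, so planted labels
#' are recoverable exactly.
#'
#' @param n_ligands number of ligands in each screen.
#' @param seed integer seed; fully determines the output. Each ligand uses
#'   its own RNG substream derived from `seed` and the ligand index, so
#'   changing `n_ligands` never reshuffles earlier ligands.
#' @param energy_mean,energy_sd normal distribution of the base first-mode
#'   energy, kcal/mol.
#' @param class_fractions named fractions (`A_selective`, `B_selective`,
#'   `nonselective`) summing to 1.
#' @param gamma_shape,gamma_scale named per-class (`A_selective`,
#'   `B_selective`) gamma parameters for the |dEA| magnitude above the
#'   threshold.
#' @param threshold selectivity threshold, kcal/mol.
#' @param guard guard band, kcal/mol (see above).
#' @param tail_fraction fraction of B-selective ligands drawn from the
#'   extreme repulsive tail.
#' @param tail_range |dEA| range (kcal/mol) of that tail.
#' @param n_modes_range integer range of binding modes per ligand.
#' @param gap_rate rate of the exponential inter-mode energy gaps (mean gap
#'   `1/gap_rate` kcal/mol; gaps are nonnegative so mode energies are
#'   nondecreasing with rank).
#' @param n_atoms_range integer range of mode-1 atoms per ligand.
#' @param digits decimals energies are rounded to (3 matches the fixture
#'   write precision; 1 is Vina-faithful).
#' @return validated list of class `synthetic_screen_config`.
#' @seealso [generate_paired_screen()]
#' @export
synthetic_screen_config <- function(
    n_ligands = 1000,
    seed = 1,
    energy_mean = -8.5,
    energy_sd = 1.0,
    class_fractions = c(A_selective = 0.48, B_selective = 0.46,
                        nonselective = 0.06),
    gamma_shape = c(A_selective = 1.2, B_selective = 1.3),
    gamma_scale = c(A_selective = 0.45, B_selective = 1.6),
    threshold = 0.1,
    guard = 0.005,
    tail_fraction = 0.02,
    tail_range = c(100, 120),
    n_modes_range = c(6L, 20L),
    gap_rate = 4,
    n_atoms_range = c(8L, 24L),
    digits = 3) {
  stopifnot(n_ligands >= 1, energy_sd > 0,
            all(c("A_selective", "B_selective", "nonselective") %in%
                  names(class_fractions)),
            abs(sum(class_fractions) - 1) < 1e-9,
            all(gamma_shape > 0), all(gamma_scale > 0),
            threshold >= 0, guard >= 0, guard < threshold || threshold == 0,
            tail_fraction >= 0, tail_fraction <= 1,
            length(tail_range) == 2L, tail_range[1] <= tail_range[2],
            n_modes_range[1] >= 1, n_modes_range[1] <= n_modes_range[2],
            gap_rate > 0)
  structure(
    list(n_ligands = as.integer(n_ligands), seed = as.integer(seed),
         energy_mean = energy_mean, energy_sd = energy_sd,
         class_fractions = class_fractions,
         gamma_shape = gamma_shape, gamma_scale = gamma_scale,
         threshold = threshold, guard = guard,
         tail_fraction = tail_fraction, tail_range = tail_range,
         n_modes_range = as.integer(n_modes_range), gap_rate = gap_rate,
         n_atoms_range = as.integer(n_atoms_range), digits = digits),
    class = "synthetic_screen_config"
  )
}

# Deterministic per-ligand RNG substream; kept below 2^31.
ligand_seed <- function(seed, i) {
  (abs(seed) %% 1000003L) * 2011L + i * 7L
}

#' Draw a planted selectivity magnitude
#'
#' The magnitude component of the generator, exposed so that distributional
#' checks (e.g. a Kolmogorov-Smirnov test of the gamma body) can sample it
#' directly without writing files. Uses the current RNG state.
#'
#' @param config a `synthetic_screen_config`.
#' @param class `"A_selective"` or `"B_selective"`.
#' @param tail draw from the extreme tail component instead of the gamma.
#' @return one magnitude, kcal/mol (strictly above the threshold).
#' @export
draw_delta_magnitude <- function(config, class, tail = FALSE) {
  if (tail) {
    stats::runif(1, config$tail_range[1], config$tail_range[2])
  } else {
    config$threshold + config$guard +
      stats::rgamma(1, shape = config$gamma_shape[[class]],
                    scale = config$gamma_scale[[class]])
  }
}

draw_modes <- function(config, ea) {
  n <- sample(seq(config$n_modes_range[1], config$n_modes_range[2]), 1)
  gaps <- stats::rexp(max(n - 1, 0), rate = config$gap_rate)
  affinity <- round(ea + cumsum(c(0, gaps)), config$digits)
  lb <- c(0, round(stats::runif(max(n - 1, 0), 1, 5), 3))
  ub <- c(0, round(lb[-1] + stats::runif(max(n - 1, 0), 0, 4), 3))
  data.frame(rank = seq_len(n), affinity = affinity, rmsd_lb = lb, rmsd_ub = ub)
}

draw_atoms <- function(config) {
  n <- sample(seq(config$n_atoms_range[1], config$n_atoms_range[2]), 1)
  types <- rep(c("C", "N", "OA", "HD"), length.out = n)
  charge <- pmin(pmax(stats::rnorm(n, 0, 0.2), -1), 1)
  data.frame(
    serial = seq_len(n),
    name = paste0(autodock_element(types), seq_len(n)),
    type = types,
    element = autodock_element(types),
    x = round(stats::runif(n, -5, 5), 3),
    y = round(stats::runif(n, -5, 5), 3),
    z = round(stats::runif(n, -5, 5), 3),
    charge = round(charge, 3),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic paired screen with planted ground truth
#'
#' Simulates a dual-target docking screen: for each ligand a class label is
#' drawn from the configured fractions, a base energy from the configured
#' normal, and a selectivity magnitude per class (see
#' [synthetic_screen_config()]); the two targets' first-mode energies are
#' then set so that the planted signed selectivity has the planted label.
#' A-selective ligands get the lower (stronger) energy against target A;
#' B-selective tail ligands get a large positive (repulsive) target-A energy.
#' Full rank-sorted mode lists with nondecreasing energies, RMSD bounds and
#' mode-1 atom records are attached so every downstream stage can run.
#'
#' All energies are rounded to `config$digits` decimals in memory, so the
#' in-memory screens agree exactly with what [write_vina_output()] emits and
#' re-reads. With `dir_a`/`dir_b` set, the two screens are also written as
#' directories of Vina-style PDBQT files (one per ligand, `<id>_out.pdbqt`);
#' the same seed always reproduces them byte-identically.
#'
#' @param config a `synthetic_screen_config`.
#' @param dir_a,dir_b optional output directories for the two screens.
#' @return list with `screen_a`, `screen_b` (named lists of `docked_ligand`)
#'   and `truth`, a data frame with `ligand_id`, `class`, `s_signed`, `ea_a`,
#'   `ea_b`, `tail`, `n_modes_a`, `n_modes_b`.
#' @export
generate_paired_screen <- function(config, dir_a = NULL, dir_b = NULL) {
  stopifnot(inherits(config, "synthetic_screen_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  fr <- config$class_fractions
  cum <- cumsum(fr[c("A_selective", "B_selective", "nonselective")])
  n <- config$n_ligands
  screen_a <- screen_b <- vector("list", n)
  truth <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(ligand_seed(config$seed, i))
    id <- sprintf("ZINC%09d", i)
    u <- stats::runif(1)
    class <- names(cum)[which(u <= cum + 1e-12)[1]]
    e <- stats::rnorm(1, config$energy_mean, config$energy_sd)
    tail <- FALSE
    if (class == "A_selective") {
      mag <- draw_delta_magnitude(config, class)
      ea_a <- e; ea_b <- e + mag
    } else if (class == "B_selective") {
      tail <- stats::runif(1) < config$tail_fraction
      mag <- draw_delta_magnitude(config, class, tail = tail)
      ea_a <- e + mag; ea_b <- e
    } else {
      s <- stats::runif(1, -(config$threshold - config$guard),
                        config$threshold - config$guard)
      ea_a <- e; ea_b <- e - s
    }
    ea_a <- round(ea_a, config$digits)
    ea_b <- round(ea_b, config$digits)

    make_ligand <- function(ea) {
      structure(
        list(ligand_id = id, modes = draw_modes(config, ea),
             mode1_atoms = draw_atoms(config),
             torsdof = sample(0:18, 1), order_violation = FALSE,
             source_path = NA_character_),
        class = "docked_ligand"
      )
    }
    la <- make_ligand(ea_a)
    lb <- make_ligand(ea_b)
    screen_a[[i]] <- la
    screen_b[[i]] <- lb
    truth[[i]] <- data.frame(
      ligand_id = id, class = class, s_signed = ea_a - ea_b,
      ea_a = ea_a, ea_b = ea_b, tail = tail,
      n_modes_a = nrow(la$modes), n_modes_b = nrow(lb$modes),
      stringsAsFactors = FALSE
    )
  }
  names(screen_a) <- names(screen_b) <-
    vapply(screen_a, `[[`, character(1), "ligand_id")
  truth <- do.call(rbind, truth)

  write_dir <- function(screen, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (l in screen) {
      write_vina_output(l, file.path(dir, paste0(l$ligand_id, "_out.pdbqt")),
                        digits = config$digits)
    }
  }
  if (!is.null(dir_a)) write_dir(screen_a, dir_a)
  if (!is.null(dir_b)) write_dir(screen_b, dir_b)

  list(screen_a = screen_a, screen_b = screen_b, truth = truth)
}

#' Geometric fixture with planted ligand-residue contacts
#'
#' Builds a small receptor and a one-mode ligand in which every contact is
#' planted by construction: residue anchors are spaced far apart (25 A grid),
#' each planted ligand atom sits at an exact requested distance from its
#' residue's anchor atom, and all other pairwise distances exceed any
#' reasonable cutoff by construction. The planted table is therefore the
#' ground truth that [find_contacts()] and [accumulate_profile()] must
#' recover exactly.
#'
#' @param n_residues number of receptor residues (anchor + one offset atom
#'   each; names cycle SER/HIS/GLU/TYR/GLY/ASP).
#' @param planted data frame with columns `residue` (index in
#'   `1:n_residues`), `element` (`"H"`, `"O"` or `"N"`; AutoDock types HD,
#'   OA, N), `multiplicity` (atoms planted at that distance) and `distance`
#'   (Angstroms, > 0).
#' @param seed integer seed (used for receptor partial charges).
#' @param cutoffs cutoffs the fixture will be tested against; planted
#'   distances must differ from each element's cutoff by at least 0.01 A
#'   unless `boundary_ok = TRUE`, so that write-precision rounding cannot
#'   flip a contact.
#' @param boundary_ok allow planting exactly at a cutoff boundary.
#' @return list with `receptor`, `ligand` (a `docked_ligand`) and `truth`
#'   (the planted table with residue identity columns added).
#' @export
generate_proximity_fixture <- function(n_residues, planted, seed = 1,
                                       cutoffs = proximity_cutoffs(),
                                       boundary_ok = FALSE) {
  stopifnot(is.data.frame(planted),
            all(c("residue", "element", "multiplicity", "distance") %in%
                  names(planted)),
            all(planted$residue >= 1), all(planted$residue <= n_residues),
            all(planted$element %in% c("H", "O", "N")),
            all(planted$multiplicity >= 1), all(planted$distance > 0))
  if (any(planted$distance > 10)) {
    stop("planted distances above 10 A cannot be isolated on the fixture grid")
  }
  if (!boundary_ok) {
    near <- abs(planted$distance - cutoffs[planted$element]) < 0.01
    if (any(near)) {
      stop("planted distance within 0.01 A of its cutoff; ",
           "set boundary_ok = TRUE for boundary testing")
    }
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(ligand_seed(seed, 0L))

  res_names <- rep(c("SER", "HIS", "GLU", "TYR", "GLY", "ASP"),
                   length.out = n_residues)
  anchor <- cbind(25 * seq_len(n_residues), 0, 0)
  rec_rows <- lapply(seq_len(n_residues), function(r) {
    data.frame(
      serial = c(2L * r - 1L, 2L * r),
      atom_name = c("CA", "O"),
      residue_name = res_names[r],
      residue_number = 100L + r,
      chain = "A",
      x = c(anchor[r, 1], anchor[r, 1]),
      y = c(0, 0),
      z = c(0, -15),
      charge = round(stats::rnorm(2, 0, 0.2), 3),
      type = c("C", "OA"),
      stringsAsFactors = FALSE
    )
  })
  rec_atoms <- do.call(rbind, rec_rows)
  rec_atoms$element <- autodock_element(rec_atoms$type)
  receptor <- structure(list(target_name = "synthetic", atoms = rec_atoms),
                        class = "receptor")

  el2type <- c(H = "HD", O = "OA", N = "N")
  lig_rows <- list()
  serial <- 0L
  for (p in seq_len(nrow(planted))) {
    r <- planted$residue[p]
    m <- planted$multiplicity[p]
    d <- planted$distance[p]
    theta <- 2 * pi * (seq_len(m) - 1) / max(m, 3) + 0.05 * p
    for (j in seq_len(m)) {
      serial <- serial + 1L
      lig_rows[[serial]] <- data.frame(
        serial = serial,
        name = paste0(planted$element[p], serial),
        type = el2type[[planted$element[p]]],
        element = planted$element[p],
        x = anchor[r, 1] + d * cos(theta[j]),
        y = d * sin(theta[j]),
        z = 0,
        charge = round(stats::rnorm(1, 0, 0.2), 3),
        stringsAsFactors = FALSE
      )
    }
  }
  ligand <- structure(
    list(ligand_id = "SYNFIX", modes = data.frame(rank = 1L, affinity = -8,
                                                  rmsd_lb = 0, rmsd_ub = 0),
         mode1_atoms = do.call(rbind, lig_rows), torsdof = 0L,
         order_violation = FALSE, source_path = NA_character_),
    class = "docked_ligand"
  )
  truth <- planted
  truth$chain <- "A"
  truth$residue_number <- 100L + truth$residue
  truth$residue_name <- res_names[truth$residue]
  list(receptor = receptor, ligand = ligand, truth = truth)
}

#' Docked-ligand fixture with exact requested mode statistics
#'
#' Constructs a mode-energy list whose sample mean and sample standard
#' deviation equal the requested values to numerical precision, by affinely
#' rescaling a random normal draw and sorting ascending (so mode 1 is the
#' minimum and energies are nondecreasing with rank, as Vina emits them).
#'
#' @param mean_ea requested mean mode energy, kcal/mol.
#' @param sd_ea requested sample standard deviation (>= 0).
#' @param n_modes number of modes (>= 2 when `sd_ea > 0`).
#' @param seed integer seed.
#' @param ligand_id identifier for the fixture ligand.
#' @return a `docked_ligand`.
#' @export
generate_mode_stat_fixture <- function(mean_ea, sd_ea, n_modes, seed = 1,
                                       ligand_id = "SYNSTAT") {
  stopifnot(sd_ea >= 0, n_modes >= 1)
  if (sd_ea > 0 && n_modes < 2) {
    stop("a positive standard deviation needs at least 2 modes")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(ligand_seed(seed, 0L))

  e <- if (sd_ea == 0) {
    rep(mean_ea, n_modes)
  } else {
    z <- stats::rnorm(n_modes)
    sort(mean_ea + sd_ea * (z - mean(z)) / stats::sd(z))
  }
  lb <- c(0, round(stats::runif(n_modes - 1, 1, 3), 3))
  ub <- c(0, round(lb[-1] + stats::runif(n_modes - 1, 0, 3), 3))
  structure(
    list(ligand_id = ligand_id,
         modes = data.frame(rank = seq_len(n_modes), affinity = e,
                            rmsd_lb = lb, rmsd_ub = ub),
         mode1_atoms = data.frame(
           serial = 1:3, name = c("C1", "O2", "N3"),
           type = c("C", "OA", "N"), element = c("C", "O", "N"),
           x = c(0, 1, 2), y = c(0, 1, 0), z = c(0, 0, 1),
           charge = c(0.1, -0.3, -0.2), stringsAsFactors = FALSE),
         torsdof = 0L, order_violation = FALSE, source_path = NA_character_),
    class = "docked_ligand"
  )
}
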