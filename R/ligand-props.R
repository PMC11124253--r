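# IUPAC 2021 conventional (abridged) atomic weights, g/mol.
atomic_weights <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845, Co = 58.933,
  Ni = 58.693, Cu = 63.546, Zn = 65.38, Se = 78.971, Br = 79.904,
  I = 126.904
)

parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  tokens <- regmatches(formula,
                       gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (length(tokens) == 0L || paste(tokens, collapse = "") != formula) {
    stop("cannot parse molecular formula: ", formula)
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- as.integer(sub("^[A-Za-z]+", "", tokens))
  cnt[is.na(cnt)] <- 1L
  tapply(cnt, sym, sum)
}

#' Molecular weight from a molecular formula
#'
#' Sums conventional (IUPAC 2021 abridged) atomic weights over the element
#' counts of a Hill-style formula such as `"C8H10N4O2"`, or over a named
#' count vector. The result is reported to two decimals, the precision
#' molecular weights are conventionally quoted at.
#'
#' @param formula a formula string (e.g. `"C8H10N4O2"`) or a named numeric
#'   vector of element counts (e.g. `c(C = 8, H = 10, N = 4, O = 2)`).
#' @return molecular weight in g/mol, rounded to 2 decimals.
#' @export
#' @examples
#' molecular_weight("C8H10N4O2")  # caffeine, 194.19
#' molecular_weight("H2O")
molecular_weight <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("element counts must be named")
  }
  unknown <- setdiff(names(counts), names(atomic_weights))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  round(sum(counts * atomic_weights[names(counts)]), 2)
}

#' Rotatable-bond filter on the PDBQT TORSDOF record
#'
#' Virtual-screening libraries are commonly pruned of overly flexible ligands
#' before docking; the conventional rule drops ligands with more than 18
#' rotatable bonds. The rotor count used is the `TORSDOF` (torsional degrees
#' of freedom) value the ligand PDBQT carries — the only rotor count present
#' in those files — so no bond perception is performed. A ligand whose file
#' lacks `TORSDOF` is kept, with a warning and an `NA` count.
#'
#' @param x a `docked_ligand`, a path to a ligand PDBQT file, or a numeric
#'   rotor count.
#' @param max_rotatable keep ligands with at most this many rotatable bonds
#'   (drop iff strictly greater). Default 18.
#' @return list with `keep` (logical) and `n_rotatable` (integer, `NA` if
#'   unknown).
#' @export
rotatable_filter <- function(x, max_rotatable = 18) {
  n <- if (inherits(x, "docked_ligand")) {
    x$torsdof
  } else if (is.character(x)) {
    line <- grep("^TORSDOF", readLines(x, warn = FALSE), value = TRUE)
    if (length(line) == 0L) NA_integer_ else
      suppressWarnings(as.integer(strsplit(trimws(line[1]), "\\s+")[[1]][2]))
  } else {
    as.integer(x)
  }
  if (is.na(n)) {
    warning("TORSDOF record missing; ligand kept with unknown rotor count")
    return(list(keep = TRUE, n_rotatable = NA_integer_))
  }
  list(keep = n <= max_rotatable, n_rotatable = n)
}

#' Axis-aligned bounding box of a ligand pose
#'
#' Extent (max minus min) of the atom coordinates along each axis, sorted in
#' descending order, and the box volume as their product. This is the simple
#' size descriptor used to reason about whether a ligand can fit down a
#' narrow active-site gorge; it is a bounding-box volume, not a van der Waals
#' or solvent-excluded volume.
#'
#' Axis-aligned extents depend on the pose's orientation in the receptor
#' frame; with `principal_axes = TRUE` the coordinates are first rotated to
#' their principal axes (eigenvectors of the coordinate covariance), which
#' makes the result rotation-invariant up to reflection.
#'
#' @param atoms a data frame with `x`, `y`, `z` columns (e.g. `mode1_atoms`
#'   of a `docked_ligand`) or an n-by-3 coordinate matrix.
#' @param principal_axes rotate to the inertia frame first (default `FALSE`,
#'   i.e. the docking frame as figures and tables report it).
#' @return list with `dims` (three extents, Angstroms, descending) and
#'   `volume` (Angstroms cubed).
#' @export
bounding_box <- function(atoms, principal_axes = FALSE) {
  xyz <- if (is.matrix(atoms)) atoms else cbind(atoms$x, atoms$y, atoms$z)
  stopifnot(nrow(xyz) >= 1, ncol(xyz) == 3)
  if (principal_axes && nrow(xyz) > 1) {
    centered <- sweep(xyz, 2, colMeans(xyz))
    xyz <- centered %*% eigen(stats::cov(centered), symmetric = TRUE)$vectors
  }
  dims <- sort(apply(xyz, 2, function(v) max(v) - min(v)), decreasing = TRUE)
  list(dims = unname(dims), volume = prod(dims))
}

#' Lipinski rule-of-five subset check
#'
#' Rule-by-rule drug-likeness booleans: molecular weight <= 500 g/mol,
#' hydrogen-bond donors <= 5, acceptors <= 10, and logP <= 5 when a logP
#' value is supplied (it cannot be computed from a PDBQT file, so it is
#' optional and skipped when absent). Rules whose input is missing are
#' reported as `NA` and excluded from the overall verdict, which makes the
#' check usable as a "select parameters" subset.
#'
#' @param props list or one-row data frame with (any of) `mw`, `hbd`, `hba`,
#'   `logp`.
#' @param mw_max,hbd_max,hba_max,logp_max rule thresholds.
#' @return list with `rules` (named logical, `NA` where not evaluable) and
#'   `overall` (all evaluated rules pass).
#' @export
lipinski_check <- function(props, mw_max = 500, hbd_max = 5, hba_max = 10,
                           logp_max = 5) {
  val <- function(name) {
    v <- props[[name]]
    if (is.null(v) || length(v) == 0L) NA_real_ else as.numeric(v[1])
  }
  rules <- c(
    mw = val("mw") <= mw_max,
    hbd = val("hbd") <= hbd_max,
    hba = val("hba") <= hba_max,
    logp = val("logp") <= logp_max
  )
  list(rules = rules, overall = all(rules, na.rm = TRUE))
}

#' Structural ligand descriptors from a docked pose
#'
#' Computes the descriptor row used for property filtering directly from the
#' parsed PDBQT content: rotor count from `TORSDOF`; hydrogen-bond donors
#' approximated as the polar-hydrogen count and acceptors as the N + O count
#' (the classical structural operationalization — PDBQT files carry no bond
#' table); the bounding box of the mode-1 pose; and an approximate molecular
#' weight summed over the atoms present. PDBQT ligands are united-atom
#' (non-polar hydrogens are merged), so this weight omits those hydrogens and
#' underestimates the true molecular weight; supply a formula-derived weight
#' via [molecular_weight()] when exactness matters.
#'
#' @param ligand a `docked_ligand` with parsed mode-1 atoms.
#' @return one-row data frame: `ligand_id`, `mw`, `n_rotatable`, `hbd`,
#'   `hba`, `bbox_x`, `bbox_y`, `bbox_z` (descending extents), `bbox_volume`.
#' @export
ligand_properties <- function(ligand) {
  stopifnot(inherits(ligand, "docked_ligand"))
  a <- ligand$mode1_atoms
  if (is.null(a) || nrow(a) == 0L) stop("ligand has no parsed mode-1 atoms")
  type2sym <- c(A = "C", C = "C", OA = "O", OS = "O", O = "O",
                N = "N", `NA` = "N", NS = "N", HD = "H", HS = "H", H = "H",
                SA = "S", S = "S", P = "P", F = "F", Cl = "Cl", CL = "Cl",
                Br = "Br", BR = "Br", I = "I")
  sym <- type2sym[a$type]
  if (anyNA(sym)) {
    warning("atoms with unmapped AutoDock type(s) ",
            paste(unique(a$type[is.na(sym)]), collapse = ","),
            " excluded from the molecular weight")
    sym <- sym[!is.na(sym)]
  }
  bb <- bounding_box(a)
  data.frame(
    ligand_id = ligand$ligand_id,
    mw = round(sum(atomic_weights[sym]), 2),
    n_rotatable = ligand$torsdof,
    hbd = sum(a$element == "H"),
    hba = sum(a$element %in% c("N", "O")),
    bbox_x = bb$dims[1], bbox_y = bb$dims[2], bbox_z = bb$dims[3],
    bbox_volume = bb$volume,
    stringsAsFactors = FALSE
  )
}
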