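#' Per-element residue-proximity distance cutoffs
#'
#' The contact analysis asks which receptor residues the docked ligands' polar
#' hydrogen, oxygen and nitrogen atoms sit near. Each element has its own
#' cutoff; the defaults (H 1.5, O 1.5, N 2.5 Angstroms) follow the
#' spatial-coordinate figures of cholinesterase screens, where active-site
#' residues within 1.5 A of H/O clouds and 2.5 A of N clouds are annotated.
#' Sulfur or halogens can be added as extra named arguments.
#'
#' @param H,O,N cutoffs in Angstroms (> 0).
#' @param ... further named per-element cutoffs, e.g. `S = 2.0`.
#' @return named numeric vector of cutoffs.
#' @export
proximity_cutoffs <- function(H = 1.5, O = 1.5, N = 2.5, ...) {
  cutoffs <- c(H = H, O = O, N = N, ...)
  if (any(cutoffs <= 0) || anyNA(cutoffs)) stop("cutoffs must be positive")
  cutoffs
}

#' Ligand-residue contact events for one docked ligand
#'
#' For every mode-1 ligand atom whose element has a cutoff, computes the
#' minimum distance to each receptor residue (over that residue's atoms) and
#' records a contact event for each residue with minimum distance at or below
#' the element's cutoff. The boundary is inclusive (`d <= cutoff`), and each
#' (ligand atom, residue) pair contributes at most one event, at the minimum
#' distance — so a large residue is not counted once per receptor atom. Set
#' `per_receptor_atom = TRUE` to additionally record, in `n_pairs`, how many
#' of the residue's atoms fall within the cutoff; profile accumulation then
#' weights events by that count (a sensitivity analysis, not the default).
#'
#' Only mode-1 poses are analyzed: the lowest-energy binding mode is the one
#' whose atom records the ligand parser retains.
#'
#' @param ligand a `docked_ligand` with parsed `mode1_atoms`.
#' @param receptor a `receptor` object.
#' @param cutoffs named per-element cutoffs, see [proximity_cutoffs()].
#' @param per_receptor_atom count receptor atoms within the cutoff into
#'   `n_pairs` instead of 1 per pair.
#' @return data frame with one row per contact event: `ligand_id`,
#'   `atom_serial`, `element`, `charge`, `chain`, `residue_number`,
#'   `residue_name`, `min_distance`, `n_pairs`; attribute `target_name`.
#' @seealso [accumulate_profile()], [top_residues()]
#' @export
find_contacts <- function(ligand, receptor, cutoffs = proximity_cutoffs(),
                          per_receptor_atom = FALSE) {
  stopifnot(inherits(ligand, "docked_ligand"), inherits(receptor, "receptor"))
  if (is.null(ligand$mode1_atoms) || nrow(ligand$mode1_atoms) == 0L) {
    stop("ligand ", ligand$ligand_id,
         " has no parsed mode-1 atoms (use parse_atoms = TRUE)")
  }
  la <- ligand$mode1_atoms[ligand$mode1_atoms$element %in% names(cutoffs), ,
                           drop = FALSE]
  empty <- data.frame(
    ligand_id = character(0), atom_serial = integer(0), element = character(0),
    charge = numeric(0), chain = character(0), residue_number = integer(0),
    residue_name = character(0), min_distance = numeric(0), n_pairs = integer(0),
    stringsAsFactors = FALSE
  )
  attr(empty, "target_name") <- receptor$target_name
  if (nrow(la) == 0L) return(empty)

  ra <- receptor$atoms
  # all-pairs distances, ligand atoms x receptor atoms
  d <- sqrt(outer(la$x, ra$x, "-")^2 +
            outer(la$y, ra$y, "-")^2 +
            outer(la$z, ra$z, "-")^2)
  res_key <- paste(ra$chain, ra$residue_number, sep = "|")
  res_groups <- split(seq_len(nrow(ra)), res_key)

  rows <- vector("list", length(res_groups))
  cut_per_atom <- cutoffs[la$element]
  for (g in seq_along(res_groups)) {
    cols <- res_groups[[g]]
    dmin <- if (length(cols) == 1L) d[, cols] else
      apply(d[, cols, drop = FALSE], 1, min)
    hit <- dmin <= cut_per_atom
    if (!any(hit)) next
    n_pairs <- if (per_receptor_atom) {
      vapply(which(hit), function(i)
        sum(d[i, cols] <= cut_per_atom[i]), integer(1))
    } else {
      rep(1L, sum(hit))
    }
    first <- cols[1]
    rows[[g]] <- data.frame(
      ligand_id = ligand$ligand_id,
      atom_serial = la$serial[hit],
      element = la$element[hit],
      charge = la$charge[hit],
      chain = ra$chain[first],
      residue_number = ra$residue_number[first],
      residue_name = ra$residue_name[first],
      min_distance = dmin[hit],
      n_pairs = n_pairs,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- empty
  out <- out[order(out$chain, out$residue_number, out$atom_serial), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "target_name") <- receptor$target_name
  out
}

#' Accumulate contact events into a residue-proximity density profile
#'
#' Aggregates contact events from many ligands docked against the same
#' receptor into per-(residue, element) contact counts — the table behind
#' "which residues are targeted most frequently" rankings. Counts are sums of
#' `n_pairs`, so the result is invariant to the order in which ligands are
#' supplied. Mixing contacts computed against different targets is an error.
#'
#' @param contacts a single contact data frame from [find_contacts()], or a
#'   list of them (one per ligand).
#' @return object of class `proximity_profile`: a data frame with columns
#'   `chain`, `residue_number`, `residue_name`, `element`, `count`, sorted by
#'   residue then element, with attributes `target_name` and `n_ligands`.
#' @export
accumulate_profile <- function(contacts) {
  if (is.data.frame(contacts)) contacts <- list(contacts)
  targets <- unique(vapply(contacts, function(x) {
    t <- attr(x, "target_name")
    if (is.null(t)) NA_character_ else t
  }, character(1)))
  targets <- targets[!is.na(targets)]
  if (length(targets) > 1L) {
    stop("contacts were computed against different targets: ",
         paste(targets, collapse = ", "))
  }
  all <- do.call(rbind, lapply(contacts, as.data.frame))
  n_ligands <- length(unique(all$ligand_id))
  if (is.null(all) || nrow(all) == 0L) {
    prof <- data.frame(chain = character(0), residue_number = integer(0),
                       residue_name = character(0), element = character(0),
                       count = integer(0), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(
      n_pairs ~ chain + residue_number + residue_name + element,
      data = all, FUN = sum
    )
    names(agg)[names(agg) == "n_pairs"] <- "count"
    prof <- agg[order(agg$chain, agg$residue_number, agg$element), ,
                drop = FALSE]
    rownames(prof) <- NULL
  }
  structure(prof,
            class = c("proximity_profile", "data.frame"),
            target_name = if (length(targets)) targets else NA_character_,
            n_ligands = n_ligands)
}

#' @export
print.proximity_profile <- function(x, ...) {
  cat("Residue-proximity profile vs", attr(x, "target_name"), "-",
      attr(x, "n_ligands"), "ligand(s),", nrow(x), "residue-element cells\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Top-k residues by ligand-atom proximity density
#'
#' Ranks residues by summed contact count over the requested elements,
#' descending; ties are broken by ascending residue number. This is the
#' ranking used to display, e.g., the ten active-site residues with the
#' highest density of nearby ligand-bound H, O or N atoms.
#'
#' @param profile a `proximity_profile`.
#' @param k number of residues to return (>= 1).
#' @param elements elements to sum over (default all present).
#' @return data frame `chain`, `residue_number`, `residue_name`, `count` with
#'   at most `k` rows.
#' @export
top_residues <- function(profile, k = 10, elements = NULL) {
  stopifnot(k >= 1)
  df <- as.data.frame(profile)
  if (!is.null(elements)) df <- df[df$element %in% elements, , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(chain = character(0), residue_number = integer(0),
                      residue_name = character(0), count = integer(0)))
  }
  agg <- stats::aggregate(count ~ chain + residue_number + residue_name,
                          data = df, FUN = sum)
  agg <- agg[order(-agg$count, agg$residue_number), , drop = FALSE]
  rownames(agg) <- NULL
  utils::head(agg, k)
}

#' Spatial cloud of ligand atoms of given elements
#'
#' Collects the coordinates and partial charges of every mode-1 ligand atom of
#' the requested elements across a screen — the point cloud plotted as
#' "spatial coordinate distribution of heavy atoms excluding carbon" with a
#' charge colormap. Coordinates are in the receptor frame the docking was run
#' in. Carbon is excluded from the default element set.
#'
#' @param ligands list of `docked_ligand` objects with parsed mode-1 atoms.
#' @param elements elements to include; default all but carbon.
#' @return data frame with columns `ligand_id`, `element`, `x`, `y`, `z`,
#'   `charge`. Empty, with a warning, when no atom matches.
#' @export
export_cloud <- function(ligands,
                         elements = c("N", "O", "H", "S", "P", "halogen",
                                      "other")) {
  rows <- lapply(ligands, function(l) {
    a <- l$mode1_atoms
    if (is.null(a)) stop("ligand ", l$ligand_id, " has no parsed mode-1 atoms")
    a <- a[a$element %in% elements, , drop = FALSE]
    if (nrow(a) == 0L) return(NULL)
    data.frame(ligand_id = l$ligand_id, element = a$element,
               x = a$x, y = a$y, z = a$z, charge = a$charge,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    warning("no atoms of element(s) ", paste(elements, collapse = ","),
            " found in any ligand")
    out <- data.frame(ligand_id = character(0), element = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      charge = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
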