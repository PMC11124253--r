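#' Map an AutoDock atom type to a coarse element class
#'
#' AutoDock PDBQT files carry AutoDock atom types, not element symbols.
#' The mapping used throughout the package is: `A`/`C` -> carbon, `OA`/`OS`/`O`
#' -> oxygen, `N`/`NA`/`NS` -> nitrogen, `HD`/`HS`/`H` -> hydrogen (ligand
#' PDBQT files carry only polar hydrogens, AutoDock merges the non-polar ones),
#' `SA`/`S` -> sulfur, `P` -> phosphorus, `F`/`Cl`/`Br`/`I` -> `"halogen"`.
#' Every other type maps to `"other"`; nothing is dropped.
#'
#' @param type character vector of AutoDock atom types.
#' @return character vector with values in
#'   `c("C","N","O","H","S","P","halogen","other")`.
#' @export
#' @examples
#' autodock_element(c("A", "OA", "HD", "NA", "Cl", "Zn"))
autodock_element <- function(type) {
  type <- trimws(type)
  out <- rep("other", length(type))
  out[type %in% c("A", "C")] <- "C"
  out[type %in% c("OA", "OS", "O")] <- "O"
  out[type %in% c("N", "NA", "NS")] <- "N"
  out[type %in% c("HD", "HS", "H")] <- "H"
  out[type %in% c("SA", "S")] <- "S"
  out[type == "P"] <- "P"
  out[toupper(type) %in% c("F", "CL", "BR", "I")] <- "halogen"
  out
}

# Fixed-column PDBQT atom record fields. PDBQT follows PDB columns for the
# first 66 characters; partial charge sits in cols 67-76 and the AutoDock
# atom type in cols 78-79.
parse_atom_records <- function(lines) {
  num <- function(s) suppressWarnings(as.numeric(s))
  data.frame(
    serial = suppressWarnings(as.integer(substr(lines, 7, 11))),
    name = trimws(substr(lines, 13, 16)),
    residue_name = trimws(substr(lines, 18, 20)),
    chain = trimws(substr(lines, 22, 22)),
    residue_number = suppressWarnings(as.integer(substr(lines, 23, 26))),
    x = num(substr(lines, 31, 38)),
    y = num(substr(lines, 39, 46)),
    z = num(substr(lines, 47, 54)),
    charge = num(substr(lines, 67, 76)),
    type = trimws(substr(lines, 78, 79)),
    stringsAsFactors = FALSE
  )
}

format_atom_record <- function(record, serial, name, resname, chain, resnum,
                               x, y, z, charge, type) {
  name4 <- ifelse(nchar(name) <= 3, sprintf(" %-3s", name), sprintf("%-4s", name))
  paste0(
    sprintf("%-6s", record),
    sprintf("%5d", serial), " ",
    name4, " ",
    sprintf("%3s", resname), " ",
    sprintf("%1s", ifelse(nzchar(chain), chain, " ")),
    sprintf("%4d", resnum), "    ",
    sprintf("%8.3f%8.3f%8.3f", x, y, z),
    sprintf("%6.2f%6.2f", 1, 0),
    sprintf("%10.3f", charge), " ",
    sprintf("%-2s", type)
  )
}

#' Read a multi-model AutoDock Vina ligand output file
#'
#' Parses the `MODEL`/`ENDMDL` blocks of a Vina (or QVina) docking output,
#' extracting for each binding mode the predicted binding free energy and the
#' RMSD lower/upper bounds from its `REMARK VINA RESULT:` line, and optionally
#' the atom records (coordinates, partial charges, AutoDock types) of the
#' lowest-energy mode. Mode rank is the 1-based `MODEL` position; modes are
#' never re-sorted, so tied energies keep file order.
#'
#' The ligand identifier is taken from a `REMARK  Name =` record when present,
#' otherwise from the file name stem with a trailing `_out` stripped (the
#' conventional Vina batch-output suffix).
#'
#' @param path path to a Vina-style PDBQT output file.
#' @param parse_atoms logical; parse the atom records of mode 1 (default
#'   `TRUE`).
#' @return an object of class `docked_ligand`: a list with elements
#'   `ligand_id`, `modes` (data frame with `rank`, `affinity`, `rmsd_lb`,
#'   `rmsd_ub`), `mode1_atoms` (data frame with `serial`, `name`, `type`,
#'   `element`, `x`, `y`, `z`, `charge`, or `NULL`), `torsdof`,
#'   `order_violation` and `source_path`.
#'
#'   Vina ranks modes by increasing energy; a file whose energies decrease
#'   with rank is accepted with a warning and `order_violation = TRUE`, since
#'   third-party outputs may have been hand-edited.
#' @seealso [write_vina_output()], [read_receptor()]
#' @export
read_vina_output <- function(path, parse_atoms = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {
    stop("no MODEL block found in ", path)
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) < length(model_starts)) {
    model_ends <- c(model_ends, length(lines))
  }

  n <- length(model_starts)
  affinity <- rmsd_lb <- rmsd_ub <- numeric(n)
  mode1_atoms <- NULL
  for (i in seq_len(n)) {
    block <- lines[model_starts[i]:model_ends[i]]
    res_rel <- grep("^REMARK VINA RESULT:", block)
    if (length(res_rel) == 0L) {
      stop("MODEL block ", i, " of ", path, " has no REMARK VINA RESULT line")
    }
    res_line_no <- model_starts[i] + res_rel[1] - 1L
    fields <- strsplit(trimws(sub("^REMARK VINA RESULT:", "", block[res_rel[1]])),
                       "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 3L || anyNA(vals)) {
      stop("malformed REMARK VINA RESULT line at line ", res_line_no,
           " of ", path)
    }
    affinity[i] <- vals[1]
    rmsd_lb[i] <- vals[2]
    rmsd_ub[i] <- vals[3]
    if (i == 1L && isTRUE(parse_atoms)) {
      atom_lines <- block[grepl("^(ATOM  |HETATM)", block)]
      if (length(atom_lines) > 0L) {
        at <- parse_atom_records(atom_lines)
        mode1_atoms <- data.frame(
          serial = at$serial, name = at$name, type = at$type,
          element = autodock_element(at$type),
          x = at$x, y = at$y, z = at$z, charge = at$charge,
          stringsAsFactors = FALSE
        )
      }
    }
  }

  order_violation <- any(diff(affinity) < 0)
  if (order_violation) {
    warning("binding-mode energies are not nondecreasing with rank in ", path)
  }

  name_line <- grep("^REMARK\\s+Name\\s*=", lines, value = TRUE)
  ligand_id <- if (length(name_line) > 0L) {
    trimws(sub("^REMARK\\s+Name\\s*=", "", name_line[1]))
  } else {
    sub("_out$", "", tools::file_path_sans_ext(basename(path)))
  }

  torsdof_line <- grep("^TORSDOF", lines, value = TRUE)
  torsdof <- if (length(torsdof_line) > 0L) {
    suppressWarnings(as.integer(strsplit(trimws(torsdof_line[1]), "\\s+")[[1]][2]))
  } else {
    NA_integer_
  }

  structure(
    list(
      ligand_id = ligand_id,
      modes = data.frame(rank = seq_len(n), affinity = affinity,
                         rmsd_lb = rmsd_lb, rmsd_ub = rmsd_ub),
      mode1_atoms = mode1_atoms,
      torsdof = torsdof,
      order_violation = order_violation,
      source_path = path
    ),
    class = "docked_ligand"
  )
}

#' @export
print.docked_ligand <- function(x, ...) {
  cat("Docked ligand:", x$ligand_id, "\n")
  cat("  modes:", nrow(x$modes),
      sprintf(" (first-mode affinity %.3f kcal/mol)\n", x$modes$affinity[1]))
  if (!is.null(x$mode1_atoms)) {
    cat("  mode-1 atoms:", nrow(x$mode1_atoms), "\n")
  }
  if (!is.na(x$torsdof)) cat("  rotatable bonds (TORSDOF):", x$torsdof, "\n")
  if (isTRUE(x$order_violation)) cat("  [mode-energy order violated in source]\n")
  invisible(x)
}

#' Write a docked ligand back to a Vina-style PDBQT file
#'
#' Emits one `MODEL`/`ENDMDL` block per binding mode, each with a
#' `REMARK VINA RESULT:` line. Vina itself prints energies with one decimal;
#' fixtures for statistical work use three decimals so that round-tripping is
#' not quantization-dominated, hence `digits` defaults to 3 and a
#' Vina-faithful file is obtained with `digits = 1`. RMSD values and atom
#' coordinates are always written at three decimals; a file written with
#' `digits = 3` re-reads to the same ligand at that precision.
#'
#' @param ligand a `docked_ligand` object.
#' @param path output file path.
#' @param digits number of decimals for the mode energies (1 or 3 in
#'   practice).
#' @return `path`, invisibly.
#' @seealso [read_vina_output()]
#' @export
write_vina_output <- function(ligand, path, digits = 3) {
  stopifnot(inherits(ligand, "docked_ligand"), nrow(ligand$modes) >= 1)
  atoms <- ligand$mode1_atoms
  atom_lines <- character(0)
  if (!is.null(atoms) && nrow(atoms) > 0L) {
    atom_lines <- c(
      "ROOT",
      vapply(seq_len(nrow(atoms)), function(i) {
        format_atom_record("ATOM", atoms$serial[i], atoms$name[i], "LIG", "",
                           1L, atoms$x[i], atoms$y[i], atoms$z[i],
                           atoms$charge[i], atoms$type[i])
      }, character(1)),
      "ENDROOT"
    )
  }
  torsdof <- if (is.na(ligand$torsdof)) 0L else ligand$torsdof
  out <- character(0)
  for (i in seq_len(nrow(ligand$modes))) {
    m <- ligand$modes[i, ]
    out <- c(
      out,
      sprintf("MODEL %d", i),
      sprintf("REMARK VINA RESULT: %8.*f %10.3f %10.3f",
              digits, m$affinity, m$rmsd_lb, m$rmsd_ub),
      sprintf("REMARK  Name = %s", ligand$ligand_id),
      atom_lines,
      sprintf("TORSDOF %d", torsdof),
      "ENDMDL"
    )
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a rigid-receptor PDBQT (or PDB-like) file
#'
#' Reads every `ATOM`/`HETATM` record of a single-model receptor file into an
#' atom table, carrying coordinates, the partial charge the file was prepared
#' with (never recomputed here) and the AutoDock atom type. Residues are keyed
#' by `(chain, residue_number)`.
#'
#' @param path path to the receptor file.
#' @param target_name name of the target enzyme (e.g. `"AChE"`).
#' @param skip_water drop water records (`HOH`/`WAT`/`TIP3`/`SOL`), as is
#'   standard for docking-prepared structures. Default `TRUE`.
#' @return an object of class `receptor`: a list with `target_name` and
#'   `atoms`, a data frame with columns `serial`, `atom_name`, `residue_name`,
#'   `residue_number`, `chain`, `x`, `y`, `z`, `charge`, `type`, `element`.
#' @export
read_receptor <- function(path, target_name, skip_water = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  atom_lines <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(atom_lines) == 0L) stop("no atoms found in ", path)
  at <- parse_atom_records(atom_lines)
  if (skip_water) {
    at <- at[!(at$residue_name %in% c("HOH", "WAT", "TIP", "TIP3", "SOL")), ,
             drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no atoms left after water removal in ", path)
  if (anyDuplicated(at$serial)) {
    warning("duplicate atom serial numbers in ", path)
  }
  atoms <- data.frame(
    serial = at$serial, atom_name = at$name,
    residue_name = at$residue_name, residue_number = at$residue_number,
    chain = at$chain, x = at$x, y = at$y, z = at$z,
    charge = at$charge, type = at$type,
    element = autodock_element(at$type),
    stringsAsFactors = FALSE
  )
  structure(list(target_name = target_name, atoms = atoms), class = "receptor")
}

#' @export
print.receptor <- function(x, ...) {
  keys <- unique(paste(x$atoms$chain, x$atoms$residue_number))
  cat("Receptor:", x$target_name, "-", nrow(x$atoms), "atoms,",
      length(keys), "residues\n")
  invisible(x)
}

#' Write a receptor atom table to a PDBQT file
#'
#' @param receptor a `receptor` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_receptor <- function(receptor, path) {
  stopifnot(inherits(receptor, "receptor"))
  a <- receptor$atoms
  out <- vapply(seq_len(nrow(a)), function(i) {
    format_atom_record("ATOM", a$serial[i], a$atom_name[i], a$residue_name[i],
                       a$chain[i], a$residue_number[i], a$x[i], a$y[i], a$z[i],
                       a$charge[i], a$type[i])
  }, character(1))
  writeLines(c(out, "TER", "END"), path)
  invisible(path)
}

#' Read every ligand output file in a screen directory
#'
#' @param dir directory containing `*.pdbqt` Vina output files.
#' @param parse_atoms passed to [read_vina_output()].
#' @return named list of `docked_ligand` objects, keyed by ligand id, in
#'   lexicographic file order.
#' @export
read_screen <- function(dir, parse_atoms = TRUE) {
  files <- sort(list.files(dir, pattern = "\\.pdbqt$", full.names = TRUE))
  if (length(files) == 0L) stop("no .pdbqt files in ", dir)
  ligands <- lapply(files, read_vina_output, parse_atoms = parse_atoms)
  names(ligands) <- vapply(ligands, `[[`, character(1), "ligand_id")
  ligands
}
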