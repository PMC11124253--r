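write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Configuration for an end-to-end pipeline run
#'
#' Validates and bundles everything [run_pipeline()] needs. Screens may be
#' given as directories of Vina-style PDBQT files or as in-memory lists of
#' `docked_ligand` objects; receptors (paths or `receptor` objects) are
#' optional and enable the residue-proximity stage.
#'
#' @param screen_a,screen_b screen directories or lists of `docked_ligand`.
#' @param receptor_a,receptor_b optional receptor PDBQT paths or `receptor`
#'   objects.
#' @param target_names length-2 character names for the two targets.
#' @param threshold selectivity threshold, kcal/mol.
#' @param cutoffs per-element proximity cutoffs, see [proximity_cutoffs()].
#' @param bin_width histogram bin width, kcal/mol.
#' @param histogram_cutoff overflow-bin cutoff for |dEA| histograms.
#' @param top_k residues reported per target in the proximity ranking.
#' @param out_dir output directory (created if missing).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(screen_a, screen_b,
                       receptor_a = NULL, receptor_b = NULL,
                       target_names = c("A", "B"),
                       threshold = 0.1,
                       cutoffs = proximity_cutoffs(),
                       bin_width = 0.1,
                       histogram_cutoff = Inf,
                       top_k = 10,
                       out_dir = "dockselect_out") {
  stopifnot(length(target_names) == 2L, threshold >= 0, bin_width > 0,
            top_k >= 1)
  check_screen <- function(s, which) {
    ok <- (is.character(s) && length(s) == 1L && dir.exists(s)) ||
      (is.list(s) && length(s) > 0L && inherits(s[[1]], "docked_ligand"))
    if (!ok) stop("screen_", which,
                  " must be an existing directory or a list of docked ligands")
  }
  check_screen(screen_a, "a")
  check_screen(screen_b, "b")
  structure(
    list(screen_a = screen_a, screen_b = screen_b,
         receptor_a = receptor_a, receptor_b = receptor_b,
         target_names = target_names, threshold = threshold,
         cutoffs = cutoffs, bin_width = bin_width,
         histogram_cutoff = histogram_cutoff, top_k = top_k,
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full post-docking analysis pipeline
#'
#' Orchestrates every stage on a paired screen and writes a plain-text output
#' bundle: per-target mode-statistics TSVs (with the per-ligand |dEA| joined
#' on, in the conventional table column order), the selectivity records TSV,
#' a JSON screen summary, signed and per-class occurrence histogram TSVs, a
#' Mann-Whitney report comparing the A-selective and B-selective |dEA|
#' samples, and — when receptors are supplied — per-target contact,
#' residue-profile, top-residue and spatial-cloud TSVs. Counts are logged at
#' every stage via `message()`. The pipeline contains no randomness and never
#' mutates its inputs, so a rerun on identical inputs writes byte-identical
#' tables.
#'
#' @param config a `run_config`.
#' @return invisibly, a list with the in-memory results (`stats_a`,
#'   `stats_b`, `records`, `summary`, `mwu`, `profiles`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tn <- config$target_names
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write_tsv(df, p)
    paths[[name]] <<- p
    p
  }

  load_screen <- function(s) {
    if (is.character(s)) read_screen(s, parse_atoms = TRUE) else s
  }
  screen_a <- load_screen(config$screen_a)
  screen_b <- load_screen(config$screen_b)
  message("read: ", length(screen_a), " ligands vs ", tn[1], ", ",
          length(screen_b), " vs ", tn[2])

  stats_a <- mode_statistics_table(screen_a)
  stats_b <- mode_statistics_table(screen_b)

  records <- pair_screens(screen_a, screen_b, threshold = config$threshold,
                          target_names = tn)
  message("paired: ", nrow(records), " ligands (",
          attr(records, "n_unpaired_a"), "/", attr(records, "n_unpaired_b"),
          " unpaired)")
  message("classified: ",
          paste(names(table(records$label)), table(records$label),
                sep = "=", collapse = ", "))

  table_order <- function(stats) {
    m <- merge(stats, records[, c("ligand_id", "delta_ea")],
               by = "ligand_id", all.x = TRUE, sort = FALSE)
    m <- m[match(stats$ligand_id, m$ligand_id),
           c("ligand_id", "delta_ea", "first_ea", "mean_ea", "sd_ea",
             "mean_rmsd_lb", "mean_rmsd_ub")]
    rownames(m) <- NULL
    m
  }
  emit(table_order(stats_a), paste0("mode_stats_", tn[1], ".tsv"))
  emit(table_order(stats_b), paste0("mode_stats_", tn[2], ".tsv"))
  emit(as.data.frame(records), "selectivity.tsv")

  summary <- summarize_screen(records, bin_width = config$bin_width,
                              histogram_cutoff = config$histogram_cutoff)
  emit(summary$signed_hist, "hist_signed.tsv")
  for (cls in names(summary$class_hists)) {
    if (!is.null(summary$class_hists[[cls]])) {
      emit(summary$class_hists[[cls]], paste0("hist_", cls, ".tsv"))
    }
  }
  summary_json <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(
    list(n_paired = summary$n_paired, counts = as.list(summary$counts),
         pct = as.list(summary$pct), pct_full = as.list(summary$pct_full),
         max_delta = as.list(summary$max_delta), threshold = summary$threshold),
    summary_json, auto_unbox = TRUE, digits = NA, na = "null"
  )
  paths[["summary.json"]] <- summary_json

  mwu <- NULL
  da <- records$delta_ea[records$label == "A_selective"]
  db <- records$delta_ea[records$label == "B_selective"]
  if (length(da) > 0 && length(db) > 0) {
    mwu <- mann_whitney(da, db)
    emit(data.frame(n1 = mwu$n1, n2 = mwu$n2, u = mwu$u_statistic,
                    z = mwu$z_statistic, p_two_sided = mwu$p_two_sided,
                    degenerate = mwu$degenerate),
         "mann_whitney.tsv")
  }

  profiles <- list()
  run_proximity <- function(screen, receptor, name) {
    if (is.null(receptor)) return(NULL)
    if (is.character(receptor)) receptor <- read_receptor(receptor, name)
    contacts <- lapply(screen, find_contacts, receptor = receptor,
                       cutoffs = config$cutoffs)
    profile <- accumulate_profile(contacts)
    message("proximity vs ", name, ": ",
            sum(vapply(contacts, nrow, integer(1))), " contact events")
    emit(do.call(rbind, contacts), paste0("contacts_", name, ".tsv"))
    emit(as.data.frame(profile), paste0("profile_", name, ".tsv"))
    emit(top_residues(profile, k = config$top_k),
         paste0("top_residues_", name, ".tsv"))
    emit(export_cloud(screen), paste0("cloud_", name, ".tsv"))
    profile
  }
  profiles[[tn[1]]] <- run_proximity(screen_a, config$receptor_a, tn[1])
  profiles[[tn[2]]] <- run_proximity(screen_b, config$receptor_b, tn[2])

  cfg_json <- file.path(config$out_dir, "run_config.json")
  jsonlite::write_json(
    list(target_names = tn, threshold = config$threshold,
         cutoffs = as.list(config$cutoffs), bin_width = config$bin_width,
         histogram_cutoff = config$histogram_cutoff, top_k = config$top_k),
    cfg_json, auto_unbox = TRUE, digits = NA
  )
  paths[["run_config.json"]] <- cfg_json

  invisible(list(stats_a = stats_a, stats_b = stats_b, records = records,
                 summary = summary, mwu = mwu, profiles = profiles,
                 paths = paths))
}

#' Emit a Vina-family docking configuration file
#'
#' Writes the `key = value` text configuration that AutoDock Vina and its
#' forks accept: receptor path, search-box center and size, exhaustiveness
#' and number of binding modes. Screens are typically run with boxes between
#' 15 x 15 x 15 and 40 x 40 x 40 Angstroms, exhaustiveness 5-20 and 6-20
#' modes; the arguments default to the middle of those ranges.
#'
#' @param receptor receptor PDBQT path to record.
#' @param center numeric length 3, box center (Angstroms).
#' @param size numeric length 3, box edge lengths (Angstroms, > 0).
#' @param exhaustiveness search effort (>= 1).
#' @param num_modes number of binding modes requested (1-20).
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_vina_config()]
#' @export
emit_vina_config <- function(receptor, center, size, exhaustiveness = 8,
                             num_modes = 9, path) {
  stopifnot(length(center) == 3L, length(size) == 3L, all(size > 0),
            exhaustiveness >= 1, num_modes >= 1, num_modes <= 20)
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.3f", x))
  writeLines(c(
    paste0("receptor = ", receptor),
    paste0("center_x = ", fmt(center[1])),
    paste0("center_y = ", fmt(center[2])),
    paste0("center_z = ", fmt(center[3])),
    paste0("size_x = ", fmt(size[1])),
    paste0("size_y = ", fmt(size[2])),
    paste0("size_z = ", fmt(size[3])),
    paste0("exhaustiveness = ", as.integer(exhaustiveness)),
    paste0("num_modes = ", as.integer(num_modes))
  ), path)
  invisible(path)
}

#' Read a Vina-family docking configuration file
#'
#' @param path path to a `key = value` configuration file.
#' @return list with `receptor`, `center`, `size`, `exhaustiveness`,
#'   `num_modes`.
#' @export
read_vina_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- do.call(rbind, strsplit(lines, "\\s*=\\s*"))
  get <- function(k) kv[kv[, 1] == k, 2]
  list(
    receptor = get("receptor"),
    center = as.numeric(c(get("center_x"), get("center_y"), get("center_z"))),
    size = as.numeric(c(get("size_x"), get("size_y"), get("size_z"))),
    exhaustiveness = as.integer(get("exhaustiveness")),
    num_modes = as.integer(get("num_modes"))
  )
}
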