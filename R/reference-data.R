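#' Curated reference rows from a dual-target cholinesterase screen
#'
#' Per-ligand binding-mode summary rows for representative top-ranked ligands
#' of an AChE/BChE virtual screen of an FDA-approved library (10 binding
#' modes per ligand) and a clean-metabolites-in-vivo library (6 modes):
#' ligand name, which target it is selective for, |dEA|, first-mode energy,
#' mean and standard deviation of the mode energies against the selective
#' target, and mean RMSD bounds. Useful as realistic worked-example input and
#' for consistency checks (e.g. the first-mode energy can never exceed the
#' mode-energy mean).
#'
#' @param dataset `"fda"` or `"metabolite"`.
#' @return data frame with columns `ligand`, `selective_for`, `n_modes`,
#'   `delta_ea`, `first_ea`, `mean_ea`, `sd_ea`, `mean_rmsd_lb`,
#'   `mean_rmsd_ub`.
#' @export
#' @examples
#' rows <- reference_screen_rows("fda")
#' max(rows$delta_ea[rows$selective_for == "A"])  # 1.9 kcal/mol
reference_screen_rows <- function(dataset = c("fda", "metabolite")) {
  dataset <- match.arg(dataset)
  path <- system.file("extdata",
                      paste0(dataset, "_screen_top_ligands.tsv"),
                      package = "dockselect", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
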