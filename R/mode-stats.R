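#' Per-ligand binding-mode statistics
#'
#' Summarizes a ligand's ranked binding modes the way dual-target screen
#' tables report them: the first-mode (lowest) energy, the mean and standard
#' deviation of all mode energies, the standard error of that mean, and the
#' mean RMSD lower/upper bounds relative to mode 1.
#'
#' The number of modes varies per ligand (docking is typically run with 6-20
#' modes), so `n_modes` is reported alongside the statistics. With a single
#' mode the standard deviation is 0 by convention.
#'
#' @param ligand a `docked_ligand` object.
#' @param sd_type `"sample"` (n-1 denominator, the default) or
#'   `"population"` (n denominator).
#' @return one-row data frame with columns `ligand_id`, `n_modes`,
#'   `first_ea`, `mean_ea`, `sd_ea`, `se_ea`, `mean_rmsd_lb`, `mean_rmsd_ub`.
#'   Energies in kcal/mol, RMSDs in Angstroms.
#' @seealso [mode_statistics_table()], [rank_and_filter()]
#' @export
compute_mode_statistics <- function(ligand, sd_type = c("sample", "population")) {
  stopifnot(inherits(ligand, "docked_ligand"))
  sd_type <- match.arg(sd_type)
  e <- ligand$modes$affinity
  n <- length(e)
  if (n == 0L) stop("ligand ", ligand$ligand_id, " has no binding modes")
  m <- mean(e)
  s <- if (n == 1L) {
    0
  } else if (sd_type == "sample") {
    stats::sd(e)
  } else {
    sqrt(mean((e - m)^2))
  }
  data.frame(
    ligand_id = ligand$ligand_id,
    n_modes = n,
    first_ea = e[1],
    mean_ea = m,
    sd_ea = s,
    se_ea = s / sqrt(n),
    mean_rmsd_lb = mean(ligand$modes$rmsd_lb),
    mean_rmsd_ub = mean(ligand$modes$rmsd_ub),
    stringsAsFactors = FALSE
  )
}

#' Mode statistics for a whole screen
#'
#' @param ligands list of `docked_ligand` objects (e.g. from [read_screen()]).
#' @param sd_type passed to [compute_mode_statistics()].
#' @return data frame with one row per ligand.
#' @export
mode_statistics_table <- function(ligands, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  do.call(rbind, lapply(ligands, compute_mode_statistics, sd_type = sd_type))
}

#' Filter and rank ligand statistics
#'
#' Applies an optional predicate, then a stable sort on one statistics column,
#' and truncates to at most `limit` rows — the screening workflow of keeping,
#' say, the `limit` most strongly binding ligands with a mode-energy spread
#' below some bound.
#'
#' @param stats data frame of per-ligand statistics (any data frame works;
#'   typically the output of [mode_statistics_table()]).
#' @param key column to sort by.
#' @param limit maximum number of rows returned (default all).
#' @param predicate optional function taking the data frame and returning a
#'   logical keep-vector, applied before ranking.
#' @param decreasing sort direction; the default `FALSE` puts the most
#'   negative (strongest) binding energies first.
#' @return the filtered, ranked data frame.
#' @export
rank_and_filter <- function(stats, key, limit = Inf, predicate = NULL,
                            decreasing = FALSE) {
  if (!key %in% names(stats)) stop("unknown key: ", key)
  if (!is.null(predicate)) {
    keep <- predicate(stats)
    stopifnot(is.logical(keep), length(keep) == nrow(stats))
    stats <- stats[keep & !is.na(keep), , drop = FALSE]
  }
  # order() is a stable sort, so ties keep input order
  stats <- stats[order(stats[[key]], decreasing = decreasing), , drop = FALSE]
  if (is.finite(limit)) stats <- utils::head(stats, limit)
  rownames(stats) <- NULL
  stats
}
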