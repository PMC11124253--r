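#' Pair two screens and compute per-ligand selectivity
#'
#' Matches ligands by identifier across two docking screens of the same
#' library against two targets (conventionally A = AChE, B = BChE) and
#' computes, from the first-mode (lowest) binding energies, the signed
#' selectivity statistic
#' \deqn{s = E_A - E_B}
#' and its magnitude \eqn{\Delta E_A = |s|}. Under the
#' more-negative-is-stronger convention, \eqn{s < 0} means the ligand is
#' predicted to bind target A more strongly. A ligand is called selective only
#' when the magnitude strictly exceeds `threshold`:
#' `A_selective` iff `s < -threshold`, `B_selective` iff `s > threshold`,
#' otherwise `nonselective`. The default threshold of 0.1 kcal/mol is the
#' energy resolution Vina prints.
#'
#' Ligands present in only one screen are never silently dropped: they are
#' counted, reported via `message()`, and recorded in the attributes
#' `n_unpaired_a` / `n_unpaired_b` of the result.
#'
#' @param screen_a,screen_b lists of `docked_ligand` objects (named or not),
#'   e.g. from [read_screen()] or [generate_paired_screen()].
#' @param threshold selectivity threshold in kcal/mol, `>= 0`.
#' @param target_names length-2 character, names for the two targets.
#' @return data frame of class `selectivity_records` with columns
#'   `ligand_id`, `ea_target_a`, `ea_target_b`, `s_signed`, `delta_ea`,
#'   `label`, plus attributes `threshold`, `target_names`, `n_unpaired_a`,
#'   `n_unpaired_b`.
#' @seealso [summarize_screen()], [mann_whitney()]
#' @export
pair_screens <- function(screen_a, screen_b, threshold = 0.1,
                         target_names = c("A", "B")) {
  stopifnot(threshold >= 0, length(target_names) == 2L)
  first_ea <- function(screen) {
    vapply(screen, function(l) l$modes$affinity[1], numeric(1))
  }
  ids_a <- vapply(screen_a, `[[`, character(1), "ligand_id")
  ids_b <- vapply(screen_b, `[[`, character(1), "ligand_id")
  ea_a <- stats::setNames(first_ea(screen_a), ids_a)
  ea_b <- stats::setNames(first_ea(screen_b), ids_b)

  shared <- ids_a[ids_a %in% ids_b]
  n_unpaired_a <- sum(!ids_a %in% ids_b)
  n_unpaired_b <- sum(!ids_b %in% ids_a)
  if (length(shared) == 0L) stop("no ligands shared between the two screens")
  if (n_unpaired_a + n_unpaired_b > 0L) {
    message(n_unpaired_a, " ligand(s) only in screen A and ", n_unpaired_b,
            " only in screen B were left unpaired")
  }

  s <- unname(ea_a[shared] - ea_b[shared])
  records <- data.frame(
    ligand_id = shared,
    ea_target_a = unname(ea_a[shared]),
    ea_target_b = unname(ea_b[shared]),
    s_signed = s,
    delta_ea = abs(s),
    label = classify_selectivity(s, threshold),
    stringsAsFactors = FALSE
  )
  structure(records,
            class = c("selectivity_records", "data.frame"),
            threshold = threshold, target_names = target_names,
            n_unpaired_a = n_unpaired_a, n_unpaired_b = n_unpaired_b)
}

#' Classify signed selectivity values
#'
#' Strict-threshold classification of the signed selectivity statistic:
#' values below `-threshold` are `A_selective`, above `+threshold`
#' `B_selective`, everything else (including exactly the threshold)
#' `nonselective`.
#'
#' @param s_signed numeric vector of signed selectivity values, kcal/mol.
#' @param threshold nonnegative threshold, kcal/mol.
#' @return character vector of labels.
#' @export
classify_selectivity <- function(s_signed, threshold = 0.1) {
  stopifnot(threshold >= 0)
  ifelse(s_signed < -threshold, "A_selective",
         ifelse(s_signed > threshold, "B_selective", "nonselective"))
}

#' Occurrence histogram of selectivity values
#'
#' Bins values at a fixed width, with every value beyond `cutoff` pooled into
#' a single final overflow bin — the device used to display the long
#' repulsion-driven tail of |dEA| values (which can exceed 100 kcal/mol) on
#' one axis. Bin edges are multiples of `bin_width`; intervals are
#' `[lower, lower + bin_width)`. Counts, including the overflow bin, always
#' sum to `length(values)`.
#'
#' @param values numeric vector.
#' @param bin_width bin width, kcal/mol (> 0).
#' @param cutoff pool values `> cutoff` into one overflow bin (default none).
#' @return data frame with columns `bin_lower`, `count`, `overflow`.
#' @export
delta_histogram <- function(values, bin_width = 0.1, cutoff = Inf) {
  stopifnot(bin_width > 0, length(values) > 0)
  over <- values > cutoff
  v <- values[!over]
  out <- NULL
  if (length(v) > 0L) {
    idx <- floor(v / bin_width + 1e-9)
    rng <- seq(min(idx), max(idx))
    counts <- tabulate(idx - min(idx) + 1L, nbins = length(rng))
    out <- data.frame(bin_lower = rng * bin_width, count = counts,
                      overflow = FALSE)
  }
  if (any(over)) {
    out <- rbind(out, data.frame(bin_lower = cutoff, count = sum(over),
                                 overflow = TRUE))
  }
  rownames(out) <- NULL
  out
}

#' Summarize a paired screen
#'
#' Dataset-level view of the selectivity records: per-class counts and
#' percentages (on the paired-ligand denominator), the maximum |dEA| within
#' each selective class, a signed-selectivity occurrence histogram (negative
#' side = A-selective ligands), and per-class |dEA| occurrence histograms
#' with an overflow bin beyond `histogram_cutoff`.
#'
#' Percentages are reported rounded to the nearest integer (`pct`), as such
#' summaries are conventionally quoted, with full-precision values alongside
#' (`pct_full`).
#'
#' @param records a `selectivity_records` data frame from [pair_screens()].
#' @param bin_width histogram bin width, kcal/mol.
#' @param histogram_cutoff pool |dEA| values beyond this into an overflow bin
#'   (default none).
#' @return object of class `screen_summary`: a list with `n_paired`, `counts`,
#'   `pct`, `pct_full`, `max_delta`, `threshold`, `signed_hist`,
#'   `class_hists`.
#' @export
summarize_screen <- function(records, bin_width = 0.1, histogram_cutoff = Inf) {
  stopifnot(nrow(records) > 0, bin_width > 0)
  labels <- c("A_selective", "B_selective", "nonselective")
  counts <- vapply(labels, function(l) sum(records$label == l), integer(1))
  n <- nrow(records)
  pct_full <- 100 * counts / n
  max_delta <- c(
    A = if (counts["A_selective"] > 0)
      max(records$delta_ea[records$label == "A_selective"]) else NA_real_,
    B = if (counts["B_selective"] > 0)
      max(records$delta_ea[records$label == "B_selective"]) else NA_real_
  )
  class_hists <- lapply(stats::setNames(labels, labels), function(l) {
    v <- records$delta_ea[records$label == l]
    if (length(v) == 0L) return(NULL)
    delta_histogram(v, bin_width, histogram_cutoff)
  })
  structure(
    list(
      n_paired = n,
      counts = counts,
      pct = round(pct_full),
      pct_full = pct_full,
      max_delta = max_delta,
      threshold = attr(records, "threshold"),
      signed_hist = delta_histogram(records$s_signed, bin_width),
      class_hists = class_hists
    ),
    class = "screen_summary"
  )
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("Paired screen summary:", x$n_paired, "ligands\n")
  cat(sprintf("  A-selective:  %6d  (%d%%)\n",
              x$counts["A_selective"], x$pct["A_selective"]))
  cat(sprintf("  B-selective:  %6d  (%d%%)\n",
              x$counts["B_selective"], x$pct["B_selective"]))
  cat(sprintf("  nonselective: %6d  (%d%%)\n",
              x$counts["nonselective"], x$pct["nonselective"]))
  if (!is.na(x$max_delta["A"]))
    cat(sprintf("  max |dEA|, A-selective: %.1f kcal/mol\n", x$max_delta["A"]))
  if (!is.na(x$max_delta["B"]))
    cat(sprintf("  max |dEA|, B-selective: %.1f kcal/mol\n", x$max_delta["B"]))
  invisible(x)
}
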