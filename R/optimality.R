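# Per-position sequence-optimality score Gamma: the sum of the predicted
# stability changes of all stabilizing mutations at a position.  Strongly
# negative Gamma marks a structural weakness.

#' Compute the per-position optimality profile from a saturation scan
#'
#' \deqn{\Gamma_i = \sum_m \Delta\Delta G_{P,wi\to m}\,
#'   H(-\Delta\Delta G_{P,wi\to m})}
#' over the 19 substitutions m at position i; H is the Heaviside function,
#' so only strictly stabilizing predictions (ddG_P < 0) contribute and
#' Gamma is never positive.  Positions not covered by all 19 mutants are
#' flagged `partial`.
#'
#' @param scan Data frame from [systematic_scan()].
#' @return Object of class `gamma_profile`: data frame `positions`
#'   (`chain`, `resnum`, `wt`, `gamma`, `n_stabilizing`, `n_scanned`,
#'   `partial`) plus `contributions`, the stabilizing mutations with
#'   their ddG_P per position.
#' @export
gamma_profile <- function(scan) {
  key <- paste(scan$chain, scan$resnum, sep = "\r")
  pos_keys <- unique(key)
  rows <- vector("list", length(pos_keys))
  contrib <- vector("list", length(pos_keys))
  for (p in seq_along(pos_keys)) {
    sel <- key == pos_keys[p]
    sub <- scan[sel, , drop = FALSE]
    stab <- sub$ddG < 0
    rows[[p]] <- data.frame(
      chain = sub$chain[1L], resnum = sub$resnum[1L], wt = sub$wt[1L],
      gamma = sum(sub$ddG[stab]),
      n_stabilizing = sum(stab), n_scanned = nrow(sub),
      partial = nrow(sub) != 19L, stringsAsFactors = FALSE)
    contrib[[p]] <- sub[stab, c("mut", "ddG"), drop = FALSE]
  }
  positions <- do.call(rbind, rows)
  if (is.null(positions))
    positions <- data.frame(chain = character(), resnum = character(),
                            wt = character(), gamma = numeric(),
                            n_stabilizing = integer(), n_scanned = integer(),
                            partial = logical())
  names(contrib) <- paste(positions$chain, positions$resnum)
  structure(list(positions = positions, contributions = contrib),
            class = "gamma_profile")
}

#' @export
print.gamma_profile <- function(x, ...) {
  p <- x$positions
  cat(sprintf("gamma_profile: %d positions, %d with gamma < 0, min gamma = %.2f kcal/mol\n",
              nrow(p), sum(p$gamma < 0),
              if (nrow(p)) min(p$gamma) else NA_real_))
  invisible(x)
}

#' Flag non-optimal (structurally weak) positions
#'
#' @param profile A `gamma_profile`.
#' @param threshold Gamma cutoff, kcal/mol (default -5); positions with
#'   `gamma <= threshold` are flagged.
#' @return The flagged rows of the position table, ordered by ascending
#'   gamma (most non-optimal first).
#' @export
flag_weak_positions <- function(profile, threshold = -5) {
  p <- profile$positions
  out <- p[p$gamma <= threshold, , drop = FALSE]
  out <- out[order(out$gamma), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratify the Gamma profile by residue class and burial
#'
#' For each Gamma threshold and each cell (label x {all, core, surface}),
#' the fraction of positions with `gamma < threshold` (strict, matching
#' the threshold-row convention of catalytic-site analyses), with counts.
#'
#' @param profile A `gamma_profile`.
#' @param labels Character vector, one class label per position (e.g.
#'   `"catalytic"` / `"other"`); must cover all positions.
#' @param core_surface Character vector per position, `"core"` or
#'   `"surface"` (e.g. from [classify_core_surface()]).
#' @param thresholds Numeric Gamma cutoffs, kcal/mol.
#' @return Data frame: `threshold`, `label`, `burial`
#'   (all/core/surface), `n`, `n_below`, `fraction` (NA when the cell is
#'   empty).
#' @export
stratify_gamma <- function(profile, labels, core_surface,
                           thresholds = c(0, -0.25, -0.5, -1, -2, -3, -5,
                                          -7.5, -10)) {
  p <- profile$positions
  stopifnot(length(labels) == nrow(p), length(core_surface) == nrow(p))
  out <- list()
  for (th in thresholds) for (lb in unique(labels))
    for (bu in c("all", "core", "surface")) {
      sel <- labels == lb & (bu == "all" | core_surface == bu)
      sel[is.na(sel)] <- FALSE
      n <- sum(sel)
      nb <- sum(p$gamma[sel] < th)
      out[[length(out) + 1L]] <- data.frame(
        threshold = th, label = lb, burial = bu, n = n, n_below = nb,
        fraction = if (n > 0L) nb / n else NA_real_)
    }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Render the Gamma profile
#'
#' Writes the machine-readable per-position table (tab-separated:
#' `CHAIN RESNUM WT GAMMA N_STABILIZING`) and, unless `plot_file` is
#' `NULL`, a per-position Gamma track as a PDF, optionally colored by
#' a secondary-structure annotation.
#'
#' @param profile A `gamma_profile`.
#' @param table_file Output path for the table (always written).
#' @param plot_file Optional PDF path for the plot.
#' @param secondary_structure Optional character vector of per-position
#'   labels (`"H"` helix, `"E"` strand, anything else coil) used for
#'   coloring.
#' @return Invisibly, the table path.
#' @export
render_profile <- function(profile, table_file, plot_file = NULL,
                           secondary_structure = NULL) {
  p <- profile$positions
  lines <- sprintf("%s\t%s\t%s\t%.4f\t%d", p$chain, p$resnum, p$wt,
                   p$gamma, p$n_stabilizing)
  writeLines(c("CHAIN\tRESNUM\tWT\tGAMMA\tN_STABILIZING", lines), table_file)
  if (!is.null(plot_file) && nrow(p) > 0L) {
    cols <- rep("darkgreen", nrow(p))
    if (!is.null(secondary_structure)) {
      cols[secondary_structure == "H"] <- "firebrick"
      cols[secondary_structure == "E"] <- "steelblue"
    }
    grDevices::pdf(plot_file, width = 8, height = 3.2)
    on.exit(grDevices::dev.off())
    graphics::plot(seq_len(nrow(p)), p$gamma, type = "h", col = cols,
                   lwd = 2, xlab = "position", ylab = "Gamma (kcal/mol)",
                   main = "sequence optimality")
    graphics::abline(h = -5, lty = 2, col = "grey40")
  }
  invisible(table_file)
}
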