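#' Background-correct a raw intensity panel
#'
#' Subtracts, per chip, the median intensity of that chip's anti-genomic
#' probes and floors the result at a small positive constant so that
#' downstream ratios stay defined on the linear scale. Anti-genomic rows are
#' corrected too and retained: they are needed later for background
#' thresholding.
#'
#' @param raw Probe-by-chip matrix (linear scale).
#' @param design A `probe_design`; must contain at least one anti-genomic
#'   probe present in `raw`.
#' @param floor Lower bound applied after subtraction (default 1.0).
#' @return Corrected matrix, same dimensions as `raw`.
#' @export
background_correct <- function(raw, design, floor = 1) {
  ag <- intersect(design$probe_id[design$antigenomic], rownames(raw))
  if (length(ag) == 0L)
    stop("no anti-genomic probes in the panel; background cannot be estimated")
  med <- apply(raw[ag, , drop = FALSE], 2, stats::median)
  out <- sweep(raw, 2, med, "-")
  out[out < floor] <- floor
  out
}

#' Quantile-normalize chip columns
#'
#' Forces every chip column onto a common distribution: the across-chip mean
#' of order statistics. Ties within a column receive the mean of their
#' assigned quantile values. Delegates to [limma::normalizeQuantiles()].
#'
#' @param mat Probe-by-chip matrix with at least two chips.
#' @return Normalized matrix with the dimnames of `mat`.
#' @export
quantile_normalize <- function(mat) {
  if (is.null(dim(mat)) || ncol(mat) < 2L)
    stop("quantile normalization needs at least 2 chips")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Per-chip background thresholds
#'
#' The background threshold of a chip is a percentile (default the 90th) of
#' that chip's anti-genomic probe intensities, computed with linear
#' interpolation between order statistics. Probes above this threshold are
#' "informative".
#'
#' @param mat Probe-by-chip matrix (normalized).
#' @param design A `probe_design` with anti-genomic probes.
#' @param percentile Percentile in (0, 1); default 0.90.
#' @return Named numeric vector, one threshold per chip.
#' @export
background_threshold <- function(mat, design, percentile = 0.90) {
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile >= 1)
    stop("percentile must lie strictly between 0 and 1")
  ag <- intersect(design$probe_id[design$antigenomic], rownames(mat))
  if (length(ag) == 0L) stop("no anti-genomic probes in the panel")
  apply(mat[ag, , drop = FALSE], 2, stats::quantile,
        probs = percentile, type = 7, names = FALSE)
}

#' Normalize a raw panel end to end
#'
#' Convenience wrapper: background correction, quantile normalization across
#' all chips (anti-genomic probes included, so they remain comparable for
#' thresholding) and per-chip background thresholds.
#'
#' @inheritParams background_correct
#' @param manifest A `chip_manifest` covering the chip columns of `raw`.
#' @param percentile Background threshold percentile, see
#'   [background_threshold()].
#' @return A `norm_panel` list with elements `intensities`, `manifest`,
#'   `design`, `thresholds` and `provenance`.
#' @export
normalize_panel <- function(raw, design, manifest, floor = 1,
                            percentile = 0.90) {
  raw <- validate_intensity_matrix(raw, design, manifest)
  corr <- background_correct(raw, design, floor = floor)
  norm <- quantile_normalize(corr)
  thr <- background_threshold(norm, design, percentile = percentile)
  structure(list(
    intensities = norm,
    manifest = manifest,
    design = design,
    thresholds = thr,
    provenance = list(background = "median anti-genomic, per chip",
                      floor = floor,
                      normalization = "quantile, across all chips",
                      threshold_percentile = percentile)
  ), class = "norm_panel")
}

#' @export
print.norm_panel <- function(x, ...) {
  cat("Normalized panel:", nrow(x$intensities), "probes x",
      ncol(x$intensities), "chips (",
      length(unique(x$manifest$line_id)), "lines )\n")
  cat("Background thresholds (", x$provenance$threshold_percentile * 100,
      "th percentile of anti-genomic probes ): ",
      sprintf("%.1f-%.1f", min(x$thresholds), max(x$thresholds)), "\n",
      sep = "")
  invisible(x)
}

#' Hybridization performance by probe G/C content
#'
#' For each G/C count, the fraction of tiling probes hybridized above the
#' per-chip background threshold, averaged over chips. On this array class,
#' probes with intermediate G/C (roughly 9-13) perform best.
#'
#' @param panel A `norm_panel`.
#' @return Data frame with columns `gc`, `n_probes`,
#'   `fraction_above_background`.
#' @export
gc_performance_summary <- function(panel) {
  design <- panel$design
  tiling <- design$probe_id[!design$antigenomic]
  tiling <- intersect(tiling, rownames(panel$intensities))
  above <- panel$intensities[tiling, , drop = FALSE] >
    matrix(panel$thresholds, nrow = length(tiling),
           ncol = ncol(panel$intensities), byrow = TRUE)
  gc <- design$gc[match(tiling, design$probe_id)]
  frac_by_probe <- rowMeans(above)
  agg <- tapply(frac_by_probe, gc, mean)
  data.frame(gc = as.integer(names(agg)),
             n_probes = as.integer(table(gc)[names(agg)]),
             fraction_above_background = as.numeric(agg),
             row.names = NULL)
}

#' Replicate concordance by hierarchical clustering
#'
#' Checks that the replicate chips of each line cluster together before any
#' polymorphism calling. Chips are clustered on the normalized intensities of
#' a probe subset (intended: probes covering known polymorphisms) with
#' Euclidean distance and average linkage; a line passes when its replicate
#' chips form an exclusive clade of the resulting tree.
#'
#' @param panel A `norm_panel`.
#' @param probe_subset Character vector of probe ids used for clustering.
#' @return List with `pass` (named logical per line; `NA` when a line has
#'   fewer than two chips and is not evaluable), `newick` (tree as Newick
#'   text) and `tree` (an [ape::as.phylo()] object).
#' @export
replicate_concordance <- function(panel, probe_subset) {
  probe_subset <- unique(as.character(probe_subset))
  if (length(probe_subset) == 0L) stop("probe_subset is empty")
  missing <- setdiff(probe_subset, rownames(panel$intensities))
  if (length(missing) > 0L)
    stop("probe_subset contains unknown probes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  sub <- panel$intensities[probe_subset, , drop = FALSE]
  hc <- stats::hclust(stats::dist(t(sub), method = "euclidean"),
                      method = "average")
  tree <- ape::as.phylo(hc)
  manifest <- panel$manifest
  lines <- unique(manifest$line_id)
  pass <- vapply(lines, function(l) {
    chips <- intersect(manifest$chip_id[manifest$line_id == l],
                       colnames(sub))
    if (length(chips) < 2L) return(NA)
    ape::is.monophyletic(tree, chips)
  }, logical(1))
  names(pass) <- lines
  list(pass = pass, newick = ape::write.tree(tree), tree = tree)
}
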