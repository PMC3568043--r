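#' Read a truth variant table
#'
#' Sequence-derived truth variants (high-quality SNPs, heterozygous
#' positions, indels and deletion ranges) used to estimate the false
#' discovery rate of SPP detection.
#'
#' @param path TSV with columns `line_id`, `unigene_id`, `pos_start`,
#'   `pos_end`, `type` (one of `snp`, `het`, `indel`, `deletion`).
#' @return Data frame of class `truth_set`.
#' @export
read_truth_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("line_id", "unigene_id", "pos_start", "pos_end", "type")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop("truth table is missing column(s): ", paste(miss, collapse = ", "))
  df$pos_start <- as.integer(df$pos_start)
  df$pos_end <- as.integer(df$pos_end)
  if (any(df$pos_end < df$pos_start)) stop("ill-ordered truth range(s)")
  class(df) <- c("truth_set", "data.frame")
  df
}

#' Write a truth variant table
#' @param truth A `truth_set` data frame.
#' @param path Output TSV path.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Classify SPPs against a truth set
#'
#' A marker is a true positive when any truth variant lies within `window`
#' bases of its range, i.e. overlaps `[start - window, end + window]`
#' (inclusive; the window absorbs the positional blur of overlapping 25 nt
#' probes). Markers whose windowed range has no truth-sequence coverage are
#' `unrepresented` and excluded from rate estimates, since they can be
#' verified neither way. Everything else is a false positive. Heterozygous
#' truth positions count as variants: they perturb hybridization.
#'
#' @param spps An `spp_set`.
#' @param truth A `truth_set` (any line's variant counts).
#' @param coverage Optional truth-sequence coverage: either a data frame
#'   `unigene_id`, `start`, `end` of covered intervals (per-base mask) or a
#'   character vector of fully covered unigenes (per-unigene fallback).
#'   `NULL` treats everything as covered.
#' @param window Flank width in bases (default 8).
#' @return Data frame `spp_id`, `unigene_id`, `start`, `end`, `label` with
#'   `label` in `{TP, FP, unrepresented}`.
#' @export
classify_spps <- function(spps, truth, coverage = NULL, window = 8L) {
  m <- spps$markers
  lo <- m$start - window
  hi <- m$end + window

  covered <- rep(TRUE, nrow(m))
  if (!is.null(coverage)) {
    if (is.character(coverage)) {
      covered <- m$unigene_id %in% coverage
    } else {
      covered <- vapply(seq_len(nrow(m)), function(i) {
        cc <- coverage[coverage$unigene_id == m$unigene_id[i], , drop = FALSE]
        any(cc$start <= hi[i] & cc$end >= lo[i])
      }, logical(1))
    }
  }

  tp <- vapply(seq_len(nrow(m)), function(i) {
    tt <- truth[truth$unigene_id == m$unigene_id[i], , drop = FALSE]
    any(tt$pos_start <= hi[i] & tt$pos_end >= lo[i])
  }, logical(1))

  label <- ifelse(!covered, "unrepresented", ifelse(tp, "TP", "FP"))
  data.frame(spp_id = m$spp_id, unigene_id = m$unigene_id,
             start = m$start, end = m$end, label = label,
             stringsAsFactors = FALSE)
}

#' Estimate the false discovery rate from classified SPPs
#'
#' `fdr = FP / (TP + FP)`, with unrepresented markers excluded. When given
#' a named list of classifications (e.g. one per filter setting), a
#' per-setting table is returned so the stringency/FDR trade-off can be
#' inspected.
#'
#' @param labels A classification from [classify_spps()], or a named list of
#'   them.
#' @return For a single input, a `validation_report` list (`n`, `tp`, `fp`,
#'   `unrepresented`, `fdr`; `fdr` is `NA` when no marker could be
#'   verified). For a list, a data frame with one row per setting.
#' @export
estimate_fdr <- function(labels) {
  if (is.data.frame(labels)) {
    tp <- sum(labels$label == "TP")
    fp <- sum(labels$label == "FP")
    un <- sum(labels$label == "unrepresented")
    fdr <- if (tp + fp == 0L) NA_real_ else fp / (tp + fp)
    return(structure(list(n = nrow(labels), tp = tp, fp = fp,
                          unrepresented = un, fdr = fdr),
                     class = "validation_report"))
  }
  stopifnot(is.list(labels), !is.null(names(labels)))
  rows <- lapply(names(labels), function(nm) {
    r <- estimate_fdr(labels[[nm]])
    data.frame(setting = nm, n = r$n, tp = r$tp, fp = r$fp,
               unrepresented = r$unrepresented, fdr = r$fdr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("SPPs evaluated:", x$n, "( TP", x$tp, ", FP", x$fp,
      ", unrepresented", x$unrepresented, ")\n")
  if (is.na(x$fdr)) cat("FDR: undefined (no verifiable marker)\n")
  else cat(sprintf("FDR: %.1f%%\n", 100 * x$fdr))
  invisible(x)
}

#' Concordance between SPP calls and independent genotyping assays
#'
#' Compares array-derived allele calls with an independent SNP assay over
#' the shared (marker, line) pairs. Assay alleles are mapped onto the
#' marker's A/B orientation by majority agreement per marker; markers whose
#' two orientations agree equally well are ambiguous and excluded (and
#' reported, never silently absorbed). SPP calls `C`/`D` are converted to
#' `B`/`A` for the overall comparison.
#'
#' @param spp_calls Data frame `marker_id`, `line_id`, `call` (SPP symbols).
#' @param assay_calls Data frame `marker_id`, `line_id`, `call` (two allele
#'   labels per marker; `NA` or `-` is missing).
#' @return List: `overall_match_fraction` (both assays made a call),
#'   `unambiguous_match_fraction` (both calls strictly A/B),
#'   `markers` (per-marker table with the chosen orientation, comparisons,
#'   matches and ambiguity flag).
#' @export
genotyping_concordance <- function(spp_calls, assay_calls) {
  req <- c("marker_id", "line_id", "call")
  stopifnot(all(req %in% names(spp_calls)), all(req %in% names(assay_calls)))
  merged <- merge(spp_calls, assay_calls, by = c("marker_id", "line_id"),
                  suffixes = c("_spp", "_assay"))
  merged <- merged[!is.na(merged$call_assay) & merged$call_assay != "-", ,
                   drop = FALSE]
  if (nrow(merged) == 0L)
    stop("no overlapping (marker, line) pairs between the two call sets")

  conv <- merged$call_spp
  conv[conv == "C"] <- "B"
  conv[conv == "D"] <- "A"
  merged$spp_ab <- conv
  merged$unambiguous <- merged$call_spp %in% c("A", "B")

  marker_rows <- lapply(split(merged, merged$marker_id), function(mm) {
    alleles <- sort(unique(mm$call_assay))
    if (length(alleles) > 2L)
      stop("more than two assay alleles at marker ", mm$marker_id[1])
    usable <- mm$spp_ab %in% c("A", "B")
    score <- function(a_allele) {
      mapped <- ifelse(mm$call_assay == a_allele, "A", "B")
      sum(mapped[usable] == mm$spp_ab[usable])
    }
    s1 <- score(alleles[1])
    s2 <- if (length(alleles) == 2L) score(alleles[2]) else -1L
    ambiguous <- length(alleles) == 2L && s1 == s2
    a_allele <- if (s1 >= s2) alleles[1] else alleles[2]
    mapped <- ifelse(mm$call_assay == a_allele, "A", "B")
    data.frame(marker_id = mm$marker_id[1],
               allele_mapped_to_A = a_allele,
               flipped = length(alleles) == 2L && s1 < s2,
               n_compared = sum(usable),
               n_match = sum(mapped[usable] == mm$spp_ab[usable]),
               ambiguous = ambiguous,
               stringsAsFactors = FALSE)
  })
  markers <- do.call(rbind, marker_rows)
  rownames(markers) <- NULL

  ok_marker <- markers$marker_id[!markers$ambiguous]
  use <- merged[merged$marker_id %in% ok_marker, , drop = FALSE]
  a_of <- stats::setNames(markers$allele_mapped_to_A, markers$marker_id)
  use$assay_ab <- ifelse(use$call_assay == a_of[use$marker_id], "A", "B")

  overall <- use$spp_ab %in% c("A", "B")   # C/D already converted; I and - excluded
  unamb <- use$unambiguous
  list(
    overall_match_fraction =
      sum(use$assay_ab[overall] == use$spp_ab[overall]) / sum(overall),
    unambiguous_match_fraction =
      sum(use$assay_ab[unamb] == use$spp_ab[unamb]) / sum(unamb),
    markers = markers)
}
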