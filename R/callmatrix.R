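#' @rdname detect_spps
#' @param markers Marker table (one row per SPP).
#' @param calls Marker-by-line summarized call matrix.
#' @param chip_calls Optional marker-by-chip raw call matrix.
#' @export
new_spp_set <- function(markers, calls, chip_calls = NULL) {
  stopifnot(is.data.frame(markers), nrow(markers) == nrow(calls))
  ok <- c("A", "B", "C", "D", "I", "-")
  bad <- setdiff(unique(as.vector(calls)), ok)
  if (length(bad) > 0L)
    stop("invalid call symbol(s): ", paste(bad, collapse = ", "))
  structure(list(markers = markers, calls = calls, chip_calls = chip_calls),
            class = "spp_set")
}

empty_spp_set <- function(manifest) {
  lines <- unique(manifest$line_id)
  markers <- data.frame(spp_id = character(0), unigene_id = character(0),
                        start = integer(0), end = integer(0),
                        span = integer(0), sppdev_ratio = numeric(0),
                        informative_probes = numeric(0),
                        stringsAsFactors = FALSE)
  calls <- matrix(character(0), nrow = 0, ncol = length(lines),
                  dimnames = list(NULL, lines))
  new_spp_set(markers, calls)
}

#' @export
print.spp_set <- function(x, ...) {
  cat("SPP set:", nrow(x$markers), "markers on",
      length(unique(x$markers$unigene_id)), "unigenes x",
      ncol(x$calls), "lines\n")
  if (nrow(x$markers) > 0L) {
    cat("Span:", min(x$markers$span), "-", max(x$markers$span),
        "bases; SPPdev ratio >=",
        sprintf("%.2f", min(x$markers$sppdev_ratio)), "\n")
    tab <- table(factor(as.vector(x$calls),
                        levels = c("A", "B", "C", "D", "I", "-")))
    cat("Calls:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of SPP markers in a set
#' @param spps An `spp_set`.
#' @export
n_spps <- function(spps) nrow(spps$markers)

#' Line ids covered by a call matrix
#' @param spps An `spp_set`.
#' @export
spp_lines <- function(spps) colnames(spps$calls)

#' Subset an SPP set by marker
#'
#' @param spps An `spp_set`.
#' @param keep Logical or integer index, or character `spp_id`s.
#' @return The reduced `spp_set` (marker order preserved).
#' @export
subset_spps <- function(spps, keep) {
  if (is.character(keep)) keep <- match(keep, spps$markers$spp_id)
  if (is.logical(keep)) keep <- which(keep)
  if (anyNA(keep)) stop("unknown spp_id in subset")
  markers <- spps$markers[keep, , drop = FALSE]
  rownames(markers) <- markers$spp_id
  new_spp_set(markers,
              spps$calls[keep, , drop = FALSE],
              if (!is.null(spps$chip_calls))
                spps$chip_calls[keep, , drop = FALSE])
}

#' Write an SPP call matrix
#'
#' Tab-delimited layout: marker columns (`spp_id`, `unigene_id`, `start`,
#' `end`, `span`, `sppdev_ratio`, `informative_probes`), one call column per
#' line, then panel allele-frequency columns (`freq_A`, `freq_B`, `maf`).
#' Rows are ordered by unigene id, then start.
#'
#' @param spps An `spp_set`.
#' @param path Output TSV path.
#' @export
write_call_matrix <- function(spps, path) {
  freq <- allele_frequencies(spps)
  df <- cbind(spps$markers,
              as.data.frame(spps$calls, stringsAsFactors = FALSE),
              freq[c("freq_A", "freq_B", "maf")])
  df <- df[order(df$unigene_id, df$start), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an SPP call matrix written by [write_call_matrix()]
#'
#' @param path TSV path.
#' @return An `spp_set` (without chip-level calls; frequency columns are
#'   recomputed on demand rather than trusted from the file).
#' @export
read_call_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  marker_cols <- c("spp_id", "unigene_id", "start", "end", "span",
                   "sppdev_ratio", "informative_probes")
  miss <- setdiff(marker_cols, names(df))
  if (length(miss) > 0L)
    stop("call matrix is missing column(s): ", paste(miss, collapse = ", "))
  freq_cols <- intersect(c("freq_A", "freq_B", "maf"), names(df))
  line_cols <- setdiff(names(df), c(marker_cols, freq_cols))
  if (length(line_cols) == 0L) stop("call matrix has no line columns")
  markers <- df[marker_cols]
  rownames(markers) <- markers$spp_id
  calls <- as.matrix(df[line_cols])
  rownames(calls) <- markers$spp_id
  new_spp_set(markers, calls)
}
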