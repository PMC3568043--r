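#' Read a probe design table
#'
#' Reads the tab-delimited catalog describing every feature on the array:
#' genomic tiling probes addressed by unigene and 1-based start position, and
#' anti-genomic (AG) control probes that match no known sequence and are used
#' to estimate background hybridization.
#'
#' @param path Path to a tab-delimited file with columns `probe_id`,
#'   `unigene_id`, `start`, `length`, `gc`, `antigenomic` (0/1). For
#'   anti-genomic probes `unigene_id` and `start` may be empty/NA.
#' @return A `probe_design` data frame. The attribute
#'   `"probes_per_unigene"` holds the per-unigene tiling probe counts.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("probe_id\tunigene_id\tstart\tlength\tgc\tantigenomic",
#'              "p1\tu1\t1\t25\t12\t0",
#'              "p2\tu1\t3\t25\t11\t0",
#'              "ag1\t\t\t25\t9\t1"), tf)
#' pd <- read_probe_design(tf)
#' summary(attr(pd, "probes_per_unigene"))
#' @export
read_probe_design <- function(path) {
  if (!file.exists(path)) stop("probe design file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c("NA", ""))
  as_probe_design(df)
}

#' Construct and validate a probe design
#'
#' Validates the invariants of a probe catalog (unique probe ids, 1-based
#' starts, G/C count bounded by probe length) and attaches the
#' `probe_design` class. Called by [read_probe_design()] and by the
#' simulator; useful directly when a design is assembled in code.
#'
#' @param df Data frame with columns `probe_id`, `unigene_id`, `start`,
#'   `length`, `gc`, `antigenomic`.
#' @return A validated `probe_design` data frame.
#' @export
as_probe_design <- function(df) {
  required <- c("probe_id", "unigene_id", "start", "length", "gc", "antigenomic")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop("probe design is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[required]
  df$probe_id <- as.character(df$probe_id)
  df$unigene_id <- as.character(df$unigene_id)
  df$antigenomic <- df$antigenomic %in% c(1L, "1", TRUE, "TRUE")
  df$start <- as.integer(df$start)
  df$length <- as.integer(df$length)
  df$gc <- as.integer(df$gc)

  dup <- duplicated(df$probe_id)
  if (any(dup))
    stop("duplicate probe_id at row(s) ", paste(which(dup), collapse = ", "),
         ": ", paste(unique(df$probe_id[dup]), collapse = ", "))
  bad_gc <- which(is.na(df$gc) | df$gc < 0L | df$gc > df$length)
  if (length(bad_gc) > 0L)
    stop("gc outside [0, length] at row(s) ", paste(bad_gc, collapse = ", "))
  tiling <- !df$antigenomic
  bad_start <- which(tiling & (is.na(df$start) | df$start < 1L))
  if (length(bad_start) > 0L)
    stop("tiling probes need a 1-based start >= 1; offending row(s) ",
         paste(bad_start, collapse = ", "))
  bad_uni <- which(tiling & is.na(df$unigene_id))
  if (length(bad_uni) > 0L)
    stop("tiling probes must reference a unigene; offending row(s) ",
         paste(bad_uni, collapse = ", "))
  df$start[df$antigenomic] <- NA_integer_
  df$unigene_id[df$antigenomic] <- NA_character_

  rownames(df) <- NULL
  class(df) <- c("probe_design", "data.frame")
  attr(df, "probes_per_unigene") <- table(df$unigene_id[tiling])
  df
}

#' @export
print.probe_design <- function(x, ...) {
  tiling <- sum(!x$antigenomic)
  ppu <- attr(x, "probes_per_unigene")
  cat("Probe design:", nrow(x), "probes (", tiling, "tiling,",
      nrow(x) - tiling, "anti-genomic ) on", length(ppu), "unigenes\n")
  if (length(ppu) > 0L) {
    cat("Tiling probes per unigene:\n")
    print(summary(as.integer(ppu)))
  }
  invisible(x)
}

#' Write a probe design table
#'
#' @param design A `probe_design` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_probe_design <- function(design, path) {
  out <- as.data.frame(design)
  out$antigenomic <- as.integer(out$antigenomic)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a chip manifest
#'
#' The manifest maps physical chips to germplasm lines and replicate numbers.
#' Three replicate hybridizations per line is the expected design.
#'
#' @param path TSV with columns `chip_id`, `line_id`, `replicate`.
#' @param replicates_expected Expected replicates per line (default 3); a
#'   deviation produces a warning, not an error, so partial panels can load.
#' @return Data frame of class `chip_manifest`.
#' @export
read_chip_manifest <- function(path, replicates_expected = 3L) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  as_chip_manifest(df, replicates_expected)
}

#' @rdname read_chip_manifest
#' @param df Data frame with manifest columns.
#' @export
as_chip_manifest <- function(df, replicates_expected = 3L) {
  required <- c("chip_id", "line_id", "replicate")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[required]
  df$chip_id <- as.character(df$chip_id)
  df$line_id <- as.character(df$line_id)
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df$chip_id) > 0L) stop("duplicate chip_id in manifest")
  key <- paste(df$line_id, df$replicate)
  if (anyDuplicated(key) > 0L)
    stop("duplicate (line_id, replicate) pair in manifest")
  n_rep <- table(df$line_id)
  if (any(n_rep != replicates_expected))
    warning("lines without exactly ", replicates_expected, " replicates: ",
            paste(names(n_rep)[n_rep != replicates_expected], collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("chip_manifest", "data.frame")
  df
}

#' Write a chip manifest
#' @param manifest A `chip_manifest`.
#' @param path Output TSV path.
#' @export
write_chip_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a probe-by-chip intensity matrix
#'
#' Rows are probes, columns are chips; values are linear-scale hybridization
#' intensities. Every row must be a probe known to the design and every
#' column a chip known to the manifest; missing or negative cells are
#' rejected.
#'
#' @param path TSV with a `probe_id` column followed by one column per chip.
#' @param design A `probe_design`.
#' @param manifest A `chip_manifest`.
#' @return Numeric matrix with probe ids as rownames and chip ids as
#'   colnames.
#' @export
read_intensity_matrix <- function(path, design, manifest) {
  if (!file.exists(path)) stop("intensity file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  if (names(df)[1] != "probe_id")
    stop("first column of the intensity table must be 'probe_id'")
  probes <- as.character(df$probe_id)
  mat <- as.matrix(df[-1])
  rownames(mat) <- probes
  validate_intensity_matrix(mat, design, manifest)
}

validate_intensity_matrix <- function(mat, design, manifest) {
  if (!is.numeric(mat)) stop("non-numeric intensity cell(s) found")
  unknown_p <- setdiff(rownames(mat), design$probe_id)
  if (length(unknown_p) > 0L)
    stop("intensity rows for probes absent from the design: ",
         paste(utils::head(unknown_p, 5), collapse = ", "))
  unknown_c <- setdiff(colnames(mat), manifest$chip_id)
  if (length(unknown_c) > 0L)
    stop("intensity columns for chips absent from the manifest: ",
         paste(unknown_c, collapse = ", "))
  if (anyNA(mat)) stop("missing intensity cell(s) found")
  if (any(mat < 0)) stop("negative intensity cell(s) found")
  mat
}

#' Write an intensity matrix
#' @param mat Probe-by-chip numeric matrix.
#' @param path Output TSV path.
#' @param digits Decimal places written (fixed-format, for byte-stable
#'   fixtures).
#' @export
write_intensity_matrix <- function(mat, path, digits = 4L) {
  df <- data.frame(probe_id = rownames(mat),
                   apply(mat, 2, function(x) sprintf("%.*f", digits, x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
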