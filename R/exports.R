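#' Write a Structure input file
#'
#' Selects markers in mapped unigenes and, within each genetic bin, keeps
#' one representative per distinct allele profile across the included lines
#' (completely linked markers carry no extra information for the linkage
#' model). Writes the tab-delimited Structure input: a marker-name row, a
#' map-distance row (inter-marker cM distance, `-1` for the first marker of
#' each linkage group) and one row per line with integer-recoded alleles
#' (A-like 1, B-like 0, missing or inconsistent -9). Inbred panels are
#' written haploid (one row per line) by default.
#'
#' @param spps An `spp_set`.
#' @param map Data frame `unigene_id`, `linkage_group`, `cM`, `bin` (bin =
#'   co-segregating marker group id).
#' @param path Output path.
#' @param lines Line subset (default: all).
#' @param diploid Duplicate each line's genotype row (for software
#'   configured with ploidy 2)?
#' @return Invisibly, the marker table kept for export (`spp_id`,
#'   `linkage_group`, `cM`, `bin`).
#' @export
export_structure_input <- function(spps, map, path, lines = NULL,
                                   diploid = FALSE) {
  req <- c("unigene_id", "linkage_group", "cM", "bin")
  miss <- setdiff(req, names(map))
  if (length(miss) > 0L)
    stop("map is missing column(s): ", paste(miss, collapse = ", "))
  calls <- select_lines(convert_cd(spps), lines)
  m <- spps$markers
  hit <- match(m$unigene_id, map$unigene_id)
  keep <- which(!is.na(hit))
  if (length(keep) == 0L) stop("no markers fall in mapped unigenes")

  info <- data.frame(spp_id = m$spp_id[keep],
                     linkage_group = map$linkage_group[hit[keep]],
                     cM = map$cM[hit[keep]], bin = map$bin[hit[keep]],
                     unigene_id = m$unigene_id[keep],
                     start = m$start[keep], stringsAsFactors = FALSE)
  info <- info[order(info$linkage_group, info$cM, info$unigene_id,
                     info$start), , drop = FALSE]
  profile <- apply(calls[info$spp_id, , drop = FALSE], 1, paste,
                   collapse = "")
  dup <- duplicated(paste(info$bin, profile))
  info <- info[!dup, , drop = FALSE]

  geno <- calls[info$spp_id, , drop = FALSE]
  code <- matrix(-9L, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  code[geno == "A"] <- 1L
  code[geno == "B"] <- 0L

  dist_row <- numeric(nrow(info))
  for (lg in unique(info$linkage_group)) {
    ix <- which(info$linkage_group == lg)
    dist_row[ix] <- c(-1, diff(info$cM[ix]))
  }

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(info$spp_id, collapse = "\t"), con)
  writeLines(paste(sprintf("%g", dist_row), collapse = "\t"), con)
  for (l in colnames(code)) {
    row <- paste(c(l, code[, l]), collapse = "\t")
    writeLines(row, con)
    if (diploid) writeLines(row, con)
  }
  invisible(info[c("spp_id", "linkage_group", "cM", "bin")])
}

#' Write a PHYLIP restriction-site file
#'
#' Recodes biallelic markers as presence/absence characters (A to 1, B to
#' 0) for distance-based phylogeny programs that accept restriction-site
#' data. Markers must be polymorphic among the included lines (alleles
#' private to excluded lines drop out automatically) and, within each
#' unigene, one representative per distinct allele profile is kept to thin
#' completely linked markers. Taxon names are padded to the standard
#' 10-character field; calls other than A/B are written `?`.
#'
#' @param spps An `spp_set`.
#' @param path Output path.
#' @param lines Lines to include (default: all).
#' @param exclude Lines to leave out entirely (e.g. a distant species whose
#'   private alleles would dominate).
#' @param outgroup Optional line ids; validated as present, and listed
#'   first in the file for convenience downstream.
#' @return Invisibly, the exported 0/1 character matrix (taxa by sites).
#' @export
export_phylip_restriction <- function(spps, path, lines = NULL,
                                      exclude = NULL, outgroup = NULL) {
  all_lines <- if (is.null(lines)) spp_lines(spps) else lines
  included <- setdiff(all_lines, exclude)
  if (length(included) < 2L) stop("need at least two included lines")
  if (!is.null(outgroup)) {
    missing <- setdiff(outgroup, included)
    if (length(missing) > 0L)
      stop("outgroup line(s) not among included lines: ",
           paste(missing, collapse = ", "))
    included <- c(outgroup, setdiff(included, outgroup))
  }
  calls <- select_lines(convert_cd(spps), included)

  nA <- rowSums(calls == "A")
  nB <- rowSums(calls == "B")
  poly <- nA > 0L & nB > 0L
  sub <- subset_spps(spps, poly)
  calls <- calls[poly, , drop = FALSE]

  profile <- apply(calls, 1, paste, collapse = "")
  dup <- duplicated(paste(sub$markers$unigene_id, profile))
  sub <- subset_spps(sub, !dup)
  calls <- calls[!dup, , drop = FALSE]
  if (nrow(calls) == 0L) stop("no polymorphic markers to export")

  name10 <- formatC(substr(included, 1L, 10L), width = 10L, flag = "-")
  if (anyDuplicated(name10) > 0L) {
    clash <- included[duplicated(name10) | duplicated(name10, fromLast = TRUE)]
    stop("taxon names collide after truncation to 10 characters: ",
         paste(clash, collapse = ", "),
         "; rename, e.g. append a numeric suffix before exporting")
  }

  chars <- matrix("?", ncol(calls), nrow(calls),
                  dimnames = list(included, sub$markers$spp_id))
  chars[t(calls == "A")] <- "1"
  chars[t(calls == "B")] <- "0"

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("    %d    %d", length(included), ncol(chars)), con)
  for (i in seq_along(included)) {
    writeLines(paste0(name10[i], paste(chars[i, ], collapse = "")), con)
  }
  invisible(chars)
}

#' Read a PHYLIP restriction-site file
#'
#' Round-trip companion to [export_phylip_restriction()].
#'
#' @param path File path.
#' @return Character matrix (taxa by sites) of `0`/`1`/`?` with taxon
#'   rownames.
#' @export
read_phylip_restriction <- function(path) {
  ln <- readLines(path)
  hdr <- as.integer(strsplit(trimws(ln[1]), "\\s+")[[1]])
  n_taxa <- hdr[1]; n_sites <- hdr[2]
  body <- ln[2:(1 + n_taxa)]
  taxa <- trimws(substr(body, 1L, 10L))
  dat <- substr(body, 11L, 10L + n_sites)
  out <- do.call(rbind, strsplit(dat, ""))
  rownames(out) <- taxa
  out
}
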