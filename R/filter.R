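#' Convert partial consensus calls
#'
#' Replaces every `C` ("not A") by `B` and every `D` ("not B") by `A`,
#' leaving all other symbols untouched. Applied before frequency-based
#' filtering when a strictly biallelic matrix is wanted. Idempotent.
#'
#' @param spps An `spp_set`.
#' @return The converted `spp_set`.
#' @export
convert_cd <- function(spps) {
  calls <- spps$calls
  calls[calls == "C"] <- "B"
  calls[calls == "D"] <- "A"
  new_spp_set(spps$markers, calls, spps$chip_calls)
}

#' Dataset-shaping filter parameters
#'
#' Bundles the post-detection filter chain settings. Allele counts treat
#' `A` and `D` as A-like and `B` and `C` as B-like. `NA` disables a
#' criterion.
#'
#' @param min_ratio Minimum SPPdev ratio.
#' @param min_informative Minimum informative probes.
#' @param min_span Minimum bases spanned.
#' @param min_allele_count_a,min_allele_count_b Minimum number of lines
#'   carrying the A-like / B-like allele.
#' @param max_missing_fraction Maximum fraction of `-` calls per marker.
#' @param max_inconsistent_fraction Maximum fraction of `I` calls per marker.
#' @param convert_cd Convert C/D to B/A before the frequency filters?
#' @param drop_multicopy Drop markers flagged as lying in multi-copy
#'   sequence (needs `multicopy` in [apply_filters()])?
#' @return A `filter_params` list.
#' @seealso [preset_params()] for the shipped profiles.
#' @export
filter_params <- function(min_ratio = NA, min_informative = NA,
                          min_span = NA, min_allele_count_a = NA,
                          min_allele_count_b = NA,
                          max_missing_fraction = NA,
                          max_inconsistent_fraction = NA,
                          convert_cd = FALSE, drop_multicopy = FALSE) {
  for (f in c(max_missing_fraction, max_inconsistent_fraction))
    if (!is.na(f) && (f < 0 || f > 1))
      stop("call fractions must lie in [0, 1]")
  for (n in c(min_allele_count_a, min_allele_count_b))
    if (!is.na(n) && n < 0) stop("allele counts must be >= 0")
  structure(list(min_ratio = min_ratio, min_informative = min_informative,
                 min_span = min_span,
                 min_allele_count_a = min_allele_count_a,
                 min_allele_count_b = min_allele_count_b,
                 max_missing_fraction = max_missing_fraction,
                 max_inconsistent_fraction = max_inconsistent_fraction,
                 convert_cd = convert_cd, drop_multicopy = drop_multicopy),
            class = "filter_params")
}

#' Named filter presets
#'
#' Three shipped parameter profiles: `"diversity-1.2"` (ratio 1.2, 2
#' informative probes, 4 bases spanned, both alleles in at least one line,
#' zero inconsistent and zero missing calls, multi-copy markers dropped) —
#' the stringent maximum-coverage profile for diversity and population
#' structure work; `"lowFDR-1.5"` (as above but ratio 1.5) — the lowest
#' false-discovery profile; and `"loose-1.5-span2"` (ratio 1.5, span 2, zero
#' inconsistent) — a line-specific discovery profile that tolerates missing
#' calls.
#'
#' @param name Preset name.
#' @return A `filter_params` object.
#' @export
preset_params <- function(name = c("diversity-1.2", "lowFDR-1.5",
                                   "loose-1.5-span2")) {
  name <- match.arg(name)
  switch(name,
    "diversity-1.2" = filter_params(
      min_ratio = 1.2, min_informative = 2, min_span = 4,
      min_allele_count_a = 1, min_allele_count_b = 1,
      max_missing_fraction = 0, max_inconsistent_fraction = 0,
      convert_cd = TRUE, drop_multicopy = TRUE),
    "lowFDR-1.5" = filter_params(
      min_ratio = 1.5, min_informative = 2, min_span = 4,
      min_allele_count_a = 1, min_allele_count_b = 1,
      max_missing_fraction = 0, max_inconsistent_fraction = 0,
      convert_cd = TRUE, drop_multicopy = TRUE),
    "loose-1.5-span2" = filter_params(
      min_ratio = 1.5, min_informative = 2, min_span = 2,
      min_allele_count_a = 1, min_allele_count_b = 1,
      max_missing_fraction = 0.96, max_inconsistent_fraction = 0,
      convert_cd = TRUE, drop_multicopy = TRUE))
}

#' Apply the post-detection filter chain
#'
#' Retains the markers satisfying every enabled criterion, in the order used
#' for the diversity dataset: detection stringency (ratio, informative
#' probes, span), multi-copy removal, C/D conversion, then allele-count,
#' missing-call and inconsistent-call filters. The number removed at each
#' step is recorded in the `"provenance"` attribute of the result.
#'
#' @param spps An `spp_set`.
#' @param params A `filter_params`.
#' @param multicopy Optional result of [flag_multicopy()]; required when
#'   `params$drop_multicopy` is TRUE.
#' @return The filtered `spp_set` with a provenance log attribute (data
#'   frame `criterion`, `removed`, `remaining`).
#' @export
apply_filters <- function(spps, params, multicopy = NULL) {
  stopifnot(inherits(params, "filter_params"))
  n_lines <- ncol(spps$calls)
  for (cnt in c(params$min_allele_count_a, params$min_allele_count_b))
    if (!is.na(cnt) && cnt > n_lines)
      stop("minimum allele count exceeds the number of lines (", n_lines, ")")

  log <- data.frame(criterion = character(0), removed = integer(0),
                    remaining = integer(0), stringsAsFactors = FALSE)
  note <- function(criterion, keep) {
    log[nrow(log) + 1L, ] <<- list(criterion, sum(!keep),
                                   sum(keep))
    keep
  }

  m <- spps$markers
  if (!is.na(params$min_ratio))
    spps <- subset_spps(spps, note("min_ratio",
                                   m$sppdev_ratio >= params$min_ratio))
  m <- spps$markers
  if (!is.na(params$min_informative))
    spps <- subset_spps(spps, note("min_informative",
                                   m$informative_probes >= params$min_informative))
  m <- spps$markers
  if (!is.na(params$min_span))
    spps <- subset_spps(spps, note("min_span", m$span >= params$min_span))

  if (isTRUE(params$drop_multicopy)) {
    if (is.null(multicopy))
      stop("drop_multicopy is set but no multicopy flags were supplied")
    flagged <- multicopy$spp_id[multicopy$flagged]
    spps <- subset_spps(spps, note("multicopy",
                                   !(spps$markers$spp_id %in% flagged)))
  }

  if (isTRUE(params$convert_cd)) spps <- convert_cd(spps)

  calls <- spps$calls
  a_like <- rowSums(calls == "A" | calls == "D")
  b_like <- rowSums(calls == "B" | calls == "C")
  if (!is.na(params$min_allele_count_a))
    spps <- subset_spps(spps, note("min_allele_count_a",
                                   a_like >= params$min_allele_count_a))
  calls <- spps$calls
  b_like <- rowSums(calls == "B" | calls == "C")
  if (!is.na(params$min_allele_count_b))
    spps <- subset_spps(spps, note("min_allele_count_b",
                                   b_like >= params$min_allele_count_b))
  calls <- spps$calls
  if (!is.na(params$max_missing_fraction))
    spps <- subset_spps(spps, note("max_missing_fraction",
                                   rowMeans(calls == "-") <=
                                     params$max_missing_fraction))
  calls <- spps$calls
  if (!is.na(params$max_inconsistent_fraction))
    spps <- subset_spps(spps, note("max_inconsistent_fraction",
                                   rowMeans(calls == "I") <=
                                     params$max_inconsistent_fraction))

  attr(spps, "provenance") <- log
  spps
}

#' Write a filter provenance log
#' @param spps A filtered `spp_set` (from [apply_filters()]).
#' @param path Output TSV path.
#' @export
write_filter_log <- function(spps, path) {
  log <- attr(spps, "provenance")
  if (is.null(log)) stop("no provenance log on this spp_set")
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flag SPPs lying in multi-copy (paralogous) sequence
#'
#' Polymorphism calls inside sequence duplicated elsewhere in the
#' transcriptome can reflect paralog cross-hybridization rather than
#' allelic variation. For each marker, the unigene subsequence from
#' `flank` bases before its start to `flank` bases after its end (clipped
#' to the unigene) is searched, ungapped and on both strands, against all
#' database sequences. A hit qualifies when the aligned region covers at
#' least `min_cov` of the query with at most `max_mismatch` substitutions;
#' a marker is flagged when it has any qualifying hit besides the perfect
#' self-match at its own coordinates.
#'
#' @param spps An `spp_set`.
#' @param unigene_seqs Named [Biostrings::DNAStringSet] holding every
#'   unigene referenced by the markers.
#' @param extra_seqs Optional additional [Biostrings::DNAStringSet] (e.g. an
#'   independent transcriptome assembly) searched alongside the unigenes.
#' @param flank Bases added on either side of the SPP range (default 8).
#' @param min_cov Minimum query coverage of a qualifying hit (default 0.95).
#' @param max_mismatch Maximum substitutions in a qualifying hit (default 2).
#' @return Data frame `spp_id`, `n_hits` (non-self qualifying hits),
#'   `flagged`; the `"hits"` attribute details every qualifying hit
#'   (`spp_id`, `subject`, `subject_start`, `strand`, `mismatches`,
#'   `coverage`).
#' @export
flag_multicopy <- function(spps, unigene_seqs, extra_seqs = NULL,
                           flank = 8L, min_cov = 0.95, max_mismatch = 2L) {
  markers <- spps$markers
  missing <- setdiff(unique(markers$unigene_id), names(unigene_seqs))
  if (length(missing) > 0L)
    stop("unigene sequence(s) missing from FASTA: ",
         paste(missing, collapse = ", "))
  db <- unigene_seqs
  if (!is.null(extra_seqs)) db <- c(db, extra_seqs)

  # concatenate the database with N spacers long enough that no query can
  # bridge two subjects, then search once per query variant
  spacer_len <- max(vapply(seq_len(nrow(markers)), function(i) {
    markers$end[i] - markers$start[i] + 1L + 2L * flank
  }, integer(1)), 1L) + max_mismatch + 2L
  widths <- Biostrings::width(db)
  spacer <- strrep("N", spacer_len)
  cat_seq <- Biostrings::DNAString(
    paste(as.character(db), collapse = spacer))
  sub_start <- cumsum(c(1L, utils::head(widths + spacer_len, -1L)))
  names(sub_start) <- names(db)

  locate <- function(pos) {
    i <- findInterval(pos, sub_start)
    c(i, pos - sub_start[i] + 1L)
  }

  hits <- list()
  n_hits <- integer(nrow(markers))
  for (k in seq_len(nrow(markers))) {
    uni <- markers$unigene_id[k]
    useq <- unigene_seqs[[uni]]
    qs <- max(1L, markers$start[k] - flank)
    qe <- min(length(useq), markers$end[k] + flank)
    query <- Biostrings::subseq(useq, qs, qe)
    qlen <- length(query)
    clip_allow <- floor((1 - min_cov) * qlen)

    seen <- character(0)
    for (ct in 0:clip_allow) for (cl in 0:ct) {
      cr <- ct - cl
      pat <- Biostrings::subseq(query, 1L + cl, qlen - cr)
      for (strand in c("+", "-")) {
        p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
        m <- Biostrings::matchPattern(p, cat_seq,
                                      max.mismatch = max_mismatch,
                                      fixed = TRUE)
        if (length(m) > 0L)   # matches hanging over the ends are not real
          m <- m[Biostrings::start(m) >= 1L &
                   Biostrings::end(m) <= length(cat_seq)]
        if (length(m) == 0L) next
        mm <- vapply(seq_along(m), function(j) {
          sum(strsplit(as.character(m[[j]]), "")[[1]] !=
                strsplit(as.character(p), "")[[1]])
        }, numeric(1))
        for (j in seq_along(m)) {
          loc <- locate(Biostrings::start(m)[j])
          subj <- names(db)[loc[1L]]
          # aligned start of the *full* query on the subject (plus strand)
          full_start <- if (strand == "+") loc[2L] - cl else loc[2L] - cr
          key <- paste(subj, strand, full_start)
          if (key %in% seen) next
          seen <- c(seen, key)
          coverage <- (qlen - ct) / qlen
          is_self <- subj == uni && strand == "+" && mm[j] == 0 &&
            ct == 0L && loc[2L] == qs
          if (is_self) next
          hits[[length(hits) + 1L]] <- data.frame(
            spp_id = markers$spp_id[k], subject = subj,
            subject_start = loc[2L], strand = strand,
            mismatches = mm[j], coverage = coverage,
            stringsAsFactors = FALSE)
          n_hits[k] <- n_hits[k] + 1L
        }
      }
    }
  }

  out <- data.frame(spp_id = markers$spp_id, n_hits = n_hits,
                    flagged = n_hits > 0L, stringsAsFactors = FALSE)
  attr(out, "hits") <- if (length(hits) > 0L) do.call(rbind, hits) else
    data.frame(spp_id = character(0), subject = character(0),
               subject_start = integer(0), strand = character(0),
               mismatches = numeric(0), coverage = numeric(0))
  out
}
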