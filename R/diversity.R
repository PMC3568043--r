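#' Per-marker allele frequencies
#'
#' Frequencies over the non-missing, non-inconsistent calls of the chosen
#' line subset, counting `A`/`D` as the A-like allele and `B`/`C` as
#' B-like. At an exact 0.5/0.5 tie the minor allele frequency is reported
#' as 0.5 with A (arbitrarily) the minor allele.
#'
#' @param spps An `spp_set`.
#' @param lines Line ids to evaluate (default: all lines).
#' @return Data frame `spp_id`, `n_called`, `freq_A`, `freq_B`, `maf`,
#'   `minor_count`, `minor_allele`. Markers with no called line get `NA`
#'   frequencies.
#' @export
allele_frequencies <- function(spps, lines = NULL) {
  calls <- select_lines(spps, lines)
  nA <- rowSums(calls == "A" | calls == "D")
  nB <- rowSums(calls == "B" | calls == "C")
  n <- nA + nB
  freq_A <- ifelse(n > 0, nA / n, NA_real_)
  freq_B <- ifelse(n > 0, nB / n, NA_real_)
  minor_A <- !is.na(freq_A) & freq_A <= freq_B
  data.frame(spp_id = spps$markers$spp_id,
             n_called = as.integer(n),
             freq_A = freq_A, freq_B = freq_B,
             maf = pmin(freq_A, freq_B),
             minor_count = ifelse(n > 0, as.integer(ifelse(minor_A, nA, nB)),
                                  NA_integer_),
             minor_allele = ifelse(is.na(freq_A), NA_character_,
                                   ifelse(minor_A, "A", "B")),
             stringsAsFactors = FALSE)
}

select_lines <- function(spps, lines) {
  if (is.null(lines)) return(spps$calls)
  missing <- setdiff(lines, colnames(spps$calls))
  if (length(missing) > 0L)
    stop("unknown line(s): ", paste(missing, collapse = ", "))
  if (length(lines) == 0L) stop("empty line subset")
  spps$calls[, lines, drop = FALSE]
}

#' Unique (line-specific) allele counts
#'
#' For each line, the number of markers at which that line is the only
#' carrier of one of the two alleles within the evaluated subset.
#'
#' @param spps An `spp_set`.
#' @param lines Line subset (default: all; at least 2).
#' @return List: `per_line` (named integer vector) and `n_spp_with_unique`
#'   (markers carrying any singleton allele).
#' @export
unique_allele_counts <- function(spps, lines = NULL) {
  calls <- select_lines(spps, lines)
  if (ncol(calls) < 2L) stop("unique alleles need at least 2 lines")
  isA <- calls == "A" | calls == "D"
  isB <- calls == "B" | calls == "C"
  nA <- rowSums(isA)
  nB <- rowSums(isB)
  per_line <- stats::setNames(integer(ncol(calls)), colnames(calls))
  singleA <- nA == 1L
  singleB <- nB == 1L
  if (any(singleA)) {
    carrier <- max.col(isA[singleA, , drop = FALSE], ties.method = "first")
    tab <- table(colnames(calls)[carrier])
    per_line[names(tab)] <- per_line[names(tab)] + as.integer(tab)
  }
  if (any(singleB)) {
    carrier <- max.col(isB[singleB, , drop = FALSE], ties.method = "first")
    tab <- table(colnames(calls)[carrier])
    per_line[names(tab)] <- per_line[names(tab)] + as.integer(tab)
  }
  list(per_line = per_line, n_spp_with_unique = sum(singleA | singleB))
}

#' Polymorphism membership across named groups (Venn counts)
#'
#' Restricts to markers whose overall minor-allele count exceeds
#' `min_minor_count_overall`, classifies each as polymorphic-within each
#' named group (both alleles present among the group's called lines) and
#' tabulates every intersection region, including markers polymorphic
#' across but within no group (`none`). Groups with fewer than two lines
#' cannot be polymorphic and are structural zeros.
#'
#' @param spps An `spp_set`.
#' @param groups Named list of line-id vectors.
#' @param min_minor_count_overall Keep markers with overall minor-allele
#'   count strictly greater than this (default 2).
#' @return Data frame `region` (`+`-separated group names or `none`),
#'   `n_spp`, `n_unigene`; the `"membership"` attribute holds the per-marker
#'   logical matrix.
#' @export
group_polymorphism <- function(spps, groups, min_minor_count_overall = 2L) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  freq <- allele_frequencies(spps)
  keep <- !is.na(freq$maf) & freq$minor_count > min_minor_count_overall
  sub <- subset_spps(spps, keep)

  membership <- vapply(names(groups), function(g) {
    ln <- groups[[g]]
    if (length(ln) < 2L) return(rep(FALSE, n_spps(sub)))
    f <- allele_frequencies(sub, ln)
    !is.na(f$maf) & f$minor_count > 0L
  }, logical(n_spps(sub)))
  membership <- matrix(membership, nrow = n_spps(sub),
                       dimnames = list(sub$markers$spp_id, names(groups)))

  region <- apply(membership, 1, function(r) {
    if (!any(r)) "none" else paste(names(groups)[r], collapse = "+")
  })
  regions <- c(unlist(lapply(seq_along(groups), function(k) {
    utils::combn(names(groups), k, paste, collapse = "+")
  })), "none")
  n_spp <- vapply(regions, function(r) sum(region == r), integer(1))
  n_uni <- vapply(regions, function(r)
    length(unique(sub$markers$unigene_id[region == r])), integer(1))
  out <- data.frame(region = regions, n_spp = n_spp, n_unigene = n_uni,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "membership") <- membership
  out
}

#' Two-group minor-allele-frequency matrix
#'
#' Cross-tabulates markers by their minor allele frequency in two line
#' groups (markers already selected upstream, e.g. those polymorphic in
#' both groups).
#'
#' @param spps An `spp_set`.
#' @param group_a,group_b Line-id vectors.
#' @param breaks Bin boundaries on `[0, 0.5]` (default steps of 0.05).
#' @return Contingency matrix (rows: group A bins, columns: group B bins)
#'   with row/column marginals as attributes.
#' @export
maf_matrix <- function(spps, group_a, group_b,
                       breaks = seq(0, 0.5, by = 0.05)) {
  fa <- allele_frequencies(spps, group_a)$maf
  fb <- allele_frequencies(spps, group_b)$maf
  ok <- !is.na(fa) & !is.na(fb)
  ba <- cut(fa[ok], breaks, include.lowest = TRUE)
  bb <- cut(fb[ok], breaks, include.lowest = TRUE)
  tab <- table(group_a = ba, group_b = bb)
  out <- unclass(tab)
  attr(out, "marginal_a") <- rowSums(out)
  attr(out, "marginal_b") <- colSums(out)
  out
}

#' Highly informative markers across groups
#'
#' Markers whose minor allele frequency strictly exceeds `maf_threshold`
#' within every named group.
#'
#' @param spps An `spp_set`.
#' @param groups Named list of line-id vectors.
#' @param maf_threshold Strict lower bound (default 0.25).
#' @return List: `spp_id` (character vector) and `n`.
#' @export
informative_markers <- function(spps, groups, maf_threshold = 0.25) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  keep <- rep(TRUE, n_spps(spps))
  for (ln in groups) {
    f <- allele_frequencies(spps, ln)$maf
    keep <- keep & !is.na(f) & f > maf_threshold
  }
  list(spp_id = spps$markers$spp_id[keep], n = sum(keep))
}

#' Gene diversity (expected heterozygosity)
#'
#' Per-marker `H_e = 1 - sum(p_i^2)` over the allele frequencies within the
#' line subset — the probability that two randomly drawn alleles differ —
#' and the unweighted mean over the evaluated marker set. Monomorphic
#' markers contribute 0; markers with fewer than two called lines are
#' excluded and reported.
#'
#' @param spps An `spp_set`.
#' @param lines Line subset (default: all).
#' @return List: `per_spp` (data frame `spp_id`, `he`; `NA` where
#'   excluded), `mean_he`, `n_evaluated`, `n_excluded`.
#' @export
gene_diversity <- function(spps, lines = NULL) {
  f <- allele_frequencies(spps, lines)
  he <- ifelse(f$n_called >= 2L, 1 - f$freq_A^2 - f$freq_B^2, NA_real_)
  list(per_spp = data.frame(spp_id = f$spp_id, he = he,
                            stringsAsFactors = FALSE),
       mean_he = mean(he, na.rm = TRUE),
       n_evaluated = sum(!is.na(he)),
       n_excluded = sum(is.na(he)))
}

#' Unigene haplotypes from SPP allele profiles
#'
#' Within each unigene, the ordered tuple of a line's SPP alleles is its
#' allele profile; distinct profiles are the unigene's haplotypes. Lines
#' with any missing or inconsistent call at the unigene have no complete
#' profile; they are excluded from that unigene and logged. Haplotype
#' frequency is the number of carrier lines divided by the number of lines
#' with complete profiles, so frequencies sum to 1 per unigene.
#'
#' @param spps An `spp_set` (C/D are counted as B/A).
#' @param lines Line subset (default: all).
#' @return A `haplotype_table` list: `haplotypes` (`unigene_id`,
#'   `haplotype_id`, `profile`, `count`, `frequency`), `assignments`
#'   (`unigene_id`, `line_id`, `haplotype_id`, `frequency`) and `excluded`
#'   (`unigene_id`, `line_id`).
#' @export
unigene_haplotypes <- function(spps, lines = NULL) {
  spps_conv <- convert_cd(spps)
  calls <- select_lines(spps_conv, lines)
  m <- spps_conv$markers
  uni_of <- split(seq_len(nrow(m)), m$unigene_id)

  haps <- list(); assigns <- list(); excl <- list()
  for (u in names(uni_of)) {
    ix <- uni_of[[u]][order(m$start[uni_of[[u]]])]
    prof_mat <- calls[ix, , drop = FALSE]
    complete <- colSums(prof_mat == "A" | prof_mat == "B") == length(ix)
    if (any(!complete))
      excl[[u]] <- data.frame(unigene_id = u,
                              line_id = colnames(calls)[!complete],
                              stringsAsFactors = FALSE)
    if (!any(complete)) next
    prof <- apply(prof_mat[, complete, drop = FALSE], 2, paste,
                  collapse = "")
    n_complete <- length(prof)
    uniq <- unique(prof)
    hid <- paste0(u, ".h", seq_along(uniq))
    counts <- as.integer(table(factor(prof, levels = uniq)))
    haps[[u]] <- data.frame(unigene_id = u, haplotype_id = hid,
                            profile = uniq, count = counts,
                            frequency = counts / n_complete,
                            stringsAsFactors = FALSE)
    ix_h <- match(prof, uniq)
    assigns[[u]] <- data.frame(unigene_id = u, line_id = names(prof),
                               haplotype_id = hid[ix_h],
                               frequency = (counts / n_complete)[ix_h],
                               stringsAsFactors = FALSE)
  }
  structure(list(
    haplotypes = if (length(haps)) do.call(rbind, c(haps, list(make.row.names = FALSE))) else NULL,
    assignments = if (length(assigns)) do.call(rbind, c(assigns, list(make.row.names = FALSE))) else NULL,
    excluded = if (length(excl)) do.call(rbind, c(excl, list(make.row.names = FALSE))) else
      data.frame(unigene_id = character(0), line_id = character(0))),
    class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  if (is.null(x$haplotypes)) { cat("Empty haplotype table\n"); return(invisible(x)) }
  cat("Haplotype table:", length(unique(x$haplotypes$unigene_id)),
      "unigenes,", nrow(x$haplotypes), "haplotypes\n")
  cat("Haplotypes per unigene:\n")
  print(summary(as.integer(table(x$haplotypes$unigene_id))))
  invisible(x)
}

#' Line-by-unigene haplotype frequency matrix
#'
#' Cell (line, unigene) holds the panel frequency of the haplotype that
#' line carries at that unigene — the standard input for a principal
#' component analysis of the panel. Lines without a complete profile at a
#' unigene are `NA`.
#'
#' @param haps A `haplotype_table`.
#' @return Numeric matrix, lines by unigenes.
#' @export
haplotype_frequency_matrix <- function(haps) {
  a <- haps$assignments
  if (is.null(a)) stop("empty haplotype table")
  lines <- sort(unique(a$line_id))
  unis <- sort(unique(a$unigene_id))
  out <- matrix(NA_real_, length(lines), length(unis),
                dimnames = list(lines, unis))
  out[cbind(match(a$line_id, lines), match(a$unigene_id, unis))] <- a$frequency
  out
}

#' Scan for monomorphic map regions
#'
#' Orders mapped markers along each linkage group and reports maximal runs
#' of consecutive markers monomorphic within the line subset — the
#' signature of a shared conserved region or introgression (e.g. around a
#' selected locus). Unmapped markers are skipped.
#'
#' @param spps An `spp_set`.
#' @param map Data frame `unigene_id`, `linkage_group`, `cM` (optionally
#'   `bin`).
#' @param lines Line subset defining "monomorphic within" (default: all).
#' @param min_spp Minimum markers per reported run (default 2).
#' @param anchor_unigene Optional unigene id; keep only runs containing it.
#' @return Data frame `linkage_group`, `start_cM`, `end_cM`, `extent_cM`
#'   (`max - min` of member positions), `n_spp`, `n_unigene`.
#' @export
monomorphic_region_scan <- function(spps, map, lines = NULL, min_spp = 2L,
                                    anchor_unigene = NULL) {
  f <- allele_frequencies(spps, lines)
  m <- spps$markers
  hit <- match(m$unigene_id, map$unigene_id)
  mapped <- !is.na(hit)
  if (!all(mapped))
    message(sum(!mapped), " unmapped marker(s) skipped")
  df <- data.frame(unigene_id = m$unigene_id[mapped],
                   start = m$start[mapped],
                   lg = map$linkage_group[hit[mapped]],
                   cM = map$cM[hit[mapped]],
                   mono = f$minor_count[mapped] == 0L,
                   stringsAsFactors = FALSE)
  df <- df[order(df$lg, df$cM, df$unigene_id, df$start), , drop = FALSE]

  out <- list()
  for (lg in unique(df$lg)) {
    d <- df[df$lg == lg, , drop = FALSE]
    r <- rle(d$mono)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_spp)) {
      run <- d[starts[j]:ends[j], , drop = FALSE]
      if (!is.null(anchor_unigene) && !(anchor_unigene %in% run$unigene_id))
        next
      out[[length(out) + 1L]] <- data.frame(
        linkage_group = lg, start_cM = min(run$cM), end_cM = max(run$cM),
        extent_cM = max(run$cM) - min(run$cM), n_spp = nrow(run),
        n_unigene = length(unique(run$unigene_id)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(linkage_group = character(0), start_cM = numeric(0),
                      end_cM = numeric(0), extent_cM = numeric(0),
                      n_spp = integer(0), n_unigene = integer(0)))
  do.call(rbind, out)
}
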