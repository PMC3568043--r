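#' Positional weight of a base within a probe
#'
#' Bases near the center of a short oligo are the most sensitive to sequence
#' polymorphisms, so hybridization values are weighted by the distance of
#' the interrogated base from the probe center. The default form is a
#' symmetric quadratic falloff,
#' `w(d) = 1 - (|d| / ((L + 1) / 2))^2`,
#' which is 1 at the center and strictly decreasing in `|d|`; it can be
#' replaced via the `weight_fun` argument of the callers for users holding
#' an empirically calibrated curve.
#'
#' @param offset Signed distance (bases) of the interrogated position from
#'   the probe center; vectorized.
#' @param probe_length Probe length in bases (default 25).
#' @return Weights in `[0, 1]`.
#' @examples
#' probe_weight(0)            # 1
#' probe_weight(c(-12, 12))   # symmetric, about 0.148
#' @export
probe_weight <- function(offset, probe_length = 25L) {
  half <- (probe_length - 1) / 2
  if (any(abs(offset) > half))
    stop("offset outside the probe: |offset| must be <= ", half)
  1 - (abs(offset) / ((probe_length + 1) / 2))^2
}

#' Per-position weighted hybridization signals
#'
#' Integrates the multiple probes overlapping each unigene base position into
#' one signal per (position, chip): the weighted mean of the linear
#' intensities of overlapping probes that exceed that chip's background
#' threshold, with weights from `weight_fun`. A position/chip signal is
#' undefined (NA) when fewer than `min_informative` overlapping probes are
#' above background.
#'
#' @param panel A `norm_panel`.
#' @param min_informative Minimum informative probes for a defined signal.
#'   The default (`NULL`) derives it from the array: the background
#'   threshold is an upper percentile of the anti-genomic probes, so any
#'   single background-level probe exceeds it with probability
#'   `1 - percentile` by construction; the default picks the smallest
#'   count that keeps the chance of a fully-background chip looking
#'   informative at a position below 5% given the median tiling redundancy
#'   (`qbinom(0.95, redundancy, 1 - percentile) + 1`).
#' @param weight_fun Weighting function `f(offset, probe_length)`; default
#'   [probe_weight()].
#' @return A `position_profiles` list: `positions` (data frame `unigene_id`,
#'   `position`), `signal` and `informative` (position-by-chip matrices),
#'   `probe_above_fraction` (per tiling probe, fraction of chips where it is
#'   above background) and `tiling` (the tiling probe table).
#' @export
position_signals <- function(panel, min_informative = NULL,
                             weight_fun = probe_weight) {
  design <- panel$design
  tiling <- as.data.frame(design[!design$antigenomic, , drop = FALSE])
  tiling <- tiling[tiling$probe_id %in% rownames(panel$intensities), ,
                   drop = FALSE]
  if (nrow(tiling) == 0L) stop("no tiling probes with intensities")
  L <- unique(tiling$length)
  if (length(L) != 1L)
    stop("mixed probe lengths are not supported (found: ",
         paste(L, collapse = ", "), ")")

  n_probe <- nrow(tiling)
  within <- 0:(L - 1L)
  offsets <- within - (L - 1) / 2
  w <- weight_fun(offsets, L)

  probe_ix <- rep(seq_len(n_probe), each = L)
  pos <- rep(tiling$start, each = L) + within
  uni <- rep(tiling$unigene_id, each = L)
  key <- paste(uni, pos, sep = "\r")
  ukey <- unique(key)
  # deterministic position order: unigene id, then coordinate
  first <- !duplicated(key)
  ord <- order(uni[first], pos[first])
  ukey <- ukey[ord]
  pos_ix <- match(key, ukey)
  n_pos <- length(ukey)

  W <- Matrix::sparseMatrix(i = pos_ix, j = probe_ix, x = rep(w, n_probe),
                            dims = c(n_pos, n_probe))
  A <- Matrix::sparseMatrix(i = pos_ix, j = probe_ix, x = 1,
                            dims = c(n_pos, n_probe))

  X <- panel$intensities[tiling$probe_id, , drop = FALSE]
  thr <- panel$thresholds[colnames(X)]
  above <- X > matrix(thr, nrow = nrow(X), ncol = ncol(X), byrow = TRUE)
  ind <- above + 0
  num <- as.matrix(W %*% (X * ind))
  den <- as.matrix(W %*% ind)
  cnt <- as.matrix(A %*% ind)
  if (is.null(min_informative)) {
    redundancy <- stats::median(Matrix::rowSums(A))
    flicker <- 1 - panel$provenance$threshold_percentile
    min_informative <- stats::qbinom(0.95, redundancy, flicker) + 1L
  }
  signal <- num / den
  signal[cnt < min_informative] <- NA_real_
  colnames(signal) <- colnames(cnt) <- colnames(X)

  positions <- data.frame(
    unigene_id = sub("\r.*$", "", ukey),
    position = as.integer(sub("^.*\r", "", ukey)),
    stringsAsFactors = FALSE)

  structure(list(positions = positions,
                 signal = signal,
                 informative = cnt,
                 probe_above_fraction = stats::setNames(rowMeans(above),
                                                        tiling$probe_id),
                 tiling = tiling),
            class = "position_profiles")
}

#' @export
print.position_profiles <- function(x, ...) {
  cat("Position profiles:", nrow(x$positions), "positions on",
      length(unique(x$positions$unigene_id)), "unigenes x",
      ncol(x$signal), "chips\n")
  cat("Defined signals:",
      sprintf("%.1f%%", 100 * mean(!is.na(x$signal))), "\n")
  invisible(x)
}

#' Fit the two hybridization modes at one position
#'
#' Splits the across-chip signals at a position into a low and a high mode
#' by the exact optimal one-dimensional two-cluster partition: signals are
#' sorted and every contiguous cut is scored by total within-cluster sum of
#' squares; the minimizing cut is exact and deterministic (no seed, no
#' iteration). Ties in the criterion are broken toward the larger gap
#' between adjacent sorted values, then toward the more balanced partition.
#' The separation statistic (SPPdev ratio) is the high-mode mean divided by
#' the low-mode mean.
#'
#' @param signal Named numeric vector of per-chip signals; NAs are chips
#'   without a defined signal.
#' @return `NULL` when fewer than 4 chips have defined signals (position not
#'   evaluable). Otherwise a `mode_fit` list: `low_mean`, `high_mean`,
#'   `ratio`, `midpoint`, `high_members` (chip names in the high mode),
#'   `low_members`, `n`, `withinss`, `gap`. Degenerate positions (all
#'   signals equal) return `ratio = 1` with an empty high mode.
#' @export
fit_modes <- function(signal) {
  x <- signal[!is.na(signal)]
  n <- length(x)
  if (n < 4L) return(NULL)
  nm <- names(x)
  o <- order(x)
  xs <- x[o]
  if (xs[n] == xs[1]) {
    return(structure(list(low_mean = unname(xs[1]), high_mean = unname(xs[1]),
                          ratio = 1,
                          midpoint = unname(xs[1]), high_members = character(0),
                          low_members = nm, n = n, withinss = 0, gap = 0),
                     class = "mode_fit"))
  }
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1L)
  ss_low <- cs2[k] - cs[k]^2 / k
  ss_high <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  ss <- ss_low + ss_high
  best <- min(ss)
  cand <- which(ss <= best + 1e-9 * max(best, 1))
  if (length(cand) > 1L) {
    gaps <- xs[cand + 1L] - xs[cand]
    cand <- cand[gaps == max(gaps)]
    if (length(cand) > 1L) {
      bal <- abs(cand - n / 2)
      cand <- cand[bal == min(bal)]
    }
  }
  k <- cand[1L]
  low_mean <- unname(cs[k] / k)
  high_mean <- unname((cs[n] - cs[k]) / (n - k))
  structure(list(low_mean = low_mean, high_mean = high_mean,
                 ratio = high_mean / low_mean,
                 midpoint = (low_mean + high_mean) / 2,
                 high_members = if (is.null(nm)) character(0) else
                   nm[o][(k + 1L):n],
                 low_members = if (is.null(nm)) character(0) else nm[o][1:k],
                 n = n, withinss = unname(ss[k]),
                 gap = unname(xs[k + 1L] - xs[k])),
            class = "mode_fit")
}

#' Per-chip allele call at one position
#'
#' Chips in the high-intensity mode are called `A` (A is always the
#' high-hybridization allele), chips in the low mode `B`. Chips whose signal
#' falls within `nocall_margin` times the inter-mode gap of the midpoint, or
#' whose signal is undefined, are left uncalled (`-`).
#'
#' @param signal Named per-chip signal vector (NAs allowed).
#' @param fit A `mode_fit` from [fit_modes()] with `ratio > 1`.
#' @param nocall_margin No-call half-width as a fraction of the mode gap
#'   (default 0.1).
#' @return Character vector of calls in `{A, B, -}`, named by chip.
#' @export
call_chip_allele <- function(signal, fit, nocall_margin = 0.1) {
  if (is.null(fit) || fit$ratio <= 1)
    stop("call_chip_allele needs a bimodal fit with ratio > 1")
  nm <- names(signal)
  calls <- ifelse(nm %in% fit$high_members, "A",
                  ifelse(nm %in% fit$low_members, "B",
                         ifelse(!is.na(signal) & signal > fit$midpoint,
                                "A", "B")))
  gap <- fit$high_mean - fit$low_mean
  nc <- is.na(signal) | abs(signal - fit$midpoint) < nocall_margin * gap
  calls[nc] <- "-"
  names(calls) <- names(signal)
  calls
}

#' Summarize replicate chip calls into a line call
#'
#' Collapses the per-chip calls of one line's replicate chips into a single
#' symbol. For the standard three-replicate design: unanimous A/A/A gives
#' `A` and B/B/B gives `B`; B/B/- gives `C` ("not A") and A/A/- gives `D`
#' ("not B"); -/-/- stays `-`; any conflict between A and B, or a single
#' call with two missing (A/A/B, B/B/A, A/B/-, -/-/A, -/-/B), is
#' inconsistent, `I`. With other replicate counts the same logic applies:
#' unanimous maps to the allele, a majority with only missing others maps to
#' C/D, anything conflicting or short of a majority is `I`.
#'
#' @param calls Character vector of per-chip calls, each in `{A, B, -}`.
#' @return One of `"A"`, `"B"`, `"C"`, `"D"`, `"I"`, `"-"`.
#' @export
summarize_replicates <- function(calls) {
  bad <- setdiff(unique(calls), c("A", "B", "-"))
  if (length(bad) > 0L)
    stop("invalid chip call symbol(s): ", paste(bad, collapse = ", "))
  r <- length(calls)
  nA <- sum(calls == "A")
  nB <- sum(calls == "B")
  if (nA == r) return("A")
  if (nB == r) return("B")
  if (nA == 0L && nB == 0L) return("-")
  if (nA > 0L && nB > 0L) return("I")
  if (nA * 2L > r) return("D")
  if (nB * 2L > r) return("C")
  "I"
}

# vectorized over many markers: calls is a markers x chips character matrix
summarize_replicate_matrix <- function(chip_calls, manifest) {
  lines <- unique(manifest$line_id)
  out <- matrix("-", nrow = nrow(chip_calls), ncol = length(lines),
                dimnames = list(rownames(chip_calls), lines))
  for (l in lines) {
    chips <- manifest$chip_id[manifest$line_id == l]
    chips <- chips[order(manifest$replicate[match(chips, manifest$chip_id)])]
    chips <- intersect(chips, colnames(chip_calls))
    sub <- chip_calls[, chips, drop = FALSE]
    out[, l] <- apply(sub, 1, summarize_replicates)
  }
  out
}

#' Assemble per-position calls into SPP markers
#'
#' Scans each unigene for maximal runs of adjacent evaluable positions whose
#' chip partitions agree — identical A/B membership among the chips called
#' on both of two neighboring positions — and merges each run into one SPP
#' marker. A run's SPPdev ratio is the maximum position ratio in the run;
#' its informative-probe count is the number of distinct probes overlapping
#' the run that are above background on at least half of the chips; its
#' per-line calls are [summarize_replicates()] applied to each chip's
#' majority call across the run's positions. Only markers meeting
#' `min_ratio`, `min_informative` and `min_span` are emitted.
#'
#' @param profiles A `position_profiles` object (for probe/position
#'   bookkeeping).
#' @param chip_calls Position-by-chip character matrix of `{A, B, -}` calls
#'   (NA rows mark non-evaluable positions).
#' @param ratios Numeric vector of per-position SPPdev ratios (NA where not
#'   evaluable).
#' @param manifest A `chip_manifest`.
#' @param min_ratio Minimum SPPdev ratio (default 1.2).
#' @param min_informative Minimum informative probes per SPP (default 2).
#' @param min_span Minimum bases spanned (default 4).
#' @return An `spp_set`; see [detect_spps()].
#' @export
assemble_spps <- function(profiles, chip_calls, ratios, manifest,
                          min_ratio = 1.2, min_informative = 2L,
                          min_span = 4L) {
  positions <- profiles$positions
  n_pos <- nrow(positions)
  stopifnot(nrow(chip_calls) == n_pos, length(ratios) == n_pos)
  evaluable <- !is.na(ratios) & ratios > 1

  # run id per position: break on unigene change, coordinate gap,
  # non-evaluable position, or chip-partition disagreement. Agreement is
  # checked against the run's established partition (each chip's first
  # non-missing call in the run), not merely the previous position, so a
  # run cannot drift across a transition between two different underlying
  # polymorphisms through a band of no-calls.
  run_id <- integer(n_pos)
  cur <- 0L
  prev_ok <- FALSE
  run_call <- NULL
  for (i in seq_len(n_pos)) {
    if (!evaluable[i]) {
      run_id[i] <- NA_integer_
      prev_ok <- FALSE
      next
    }
    b <- chip_calls[i, ]
    new_run <- TRUE
    if (prev_ok &&
        positions$unigene_id[i] == positions$unigene_id[i - 1L] &&
        positions$position[i] == positions$position[i - 1L] + 1L) {
      both <- run_call != "-" & b != "-"
      if (any(both) && all(run_call[both] == b[both])) new_run <- FALSE
    }
    if (new_run) {
      cur <- cur + 1L
      run_call <- b
    } else {
      fill <- run_call == "-" & b != "-"
      run_call[fill] <- b[fill]
    }
    run_id[i] <- cur
    prev_ok <- TRUE
  }

  keep <- which(!is.na(run_id))
  if (length(keep) == 0L) return(empty_spp_set(manifest))
  runs <- split(keep, run_id[keep])

  tiling <- profiles$tiling
  above_frac <- profiles$probe_above_fraction
  chips <- colnames(chip_calls)

  rows <- lapply(runs, function(ix) {
    uni <- positions$unigene_id[ix[1L]]
    s <- positions$position[ix[1L]]
    e <- positions$position[ix[length(ix)]]
    sub <- chip_calls[ix, , drop = FALSE]
    nA <- colSums(sub == "A")
    nB <- colSums(sub == "B")
    chip_call <- ifelse(nA > nB, "A", ifelse(nB > nA, "B", "-"))
    names(chip_call) <- chips
    in_uni <- tiling$unigene_id == uni
    overlap <- in_uni & tiling$start <= e & (tiling$start + tiling$length - 1L) >= s
    informative <- sum(above_frac[tiling$probe_id[overlap]] >= 0.5)
    list(unigene_id = uni, start = s, end = e, span = e - s + 1L,
         sppdev_ratio = max(ratios[ix]), informative_probes = informative,
         chip_call = chip_call)
  })

  markers <- data.frame(
    unigene_id = vapply(rows, `[[`, character(1), "unigene_id"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    span = vapply(rows, `[[`, integer(1), "span"),
    sppdev_ratio = vapply(rows, `[[`, numeric(1), "sppdev_ratio"),
    informative_probes = vapply(rows, `[[`, numeric(1), "informative_probes"),
    stringsAsFactors = FALSE)
  chip_mat <- do.call(rbind, lapply(rows, `[[`, "chip_call"))

  pass <- markers$sppdev_ratio >= min_ratio &
    markers$informative_probes >= min_informative &
    markers$span >= min_span
  markers <- markers[pass, , drop = FALSE]
  chip_mat <- chip_mat[pass, , drop = FALSE]
  if (nrow(markers) == 0L) return(empty_spp_set(manifest))

  ord <- order(markers$unigene_id, markers$start)
  markers <- markers[ord, , drop = FALSE]
  chip_mat <- chip_mat[ord, , drop = FALSE]
  markers$spp_id <- paste0(markers$unigene_id, ":", markers$start)
  rownames(markers) <- rownames(chip_mat) <- markers$spp_id
  markers <- markers[c("spp_id", "unigene_id", "start", "end", "span",
                       "sppdev_ratio", "informative_probes")]

  calls <- summarize_replicate_matrix(chip_mat, manifest)
  new_spp_set(markers, calls, chip_mat)
}

#' Detect SPP markers from a normalized panel
#'
#' Full caller: per-position weighted signals, exact bimodal mode fits,
#' per-chip allele calls, replicate summarization and run assembly into SPP
#' markers.
#'
#' @param panel A `norm_panel`.
#' @param min_ratio,min_informative,min_span Detection stringency; defaults
#'   (ratio 1.2, 2 informative probes, 4 bases spanned) match the
#'   diversity-oriented preset, see [preset_params()].
#' @param nocall_margin See [call_chip_allele()].
#' @param min_informative_position Minimum informative probes for a
#'   defined position signal; `NULL` (default) derives it from the tiling
#'   redundancy, see [position_signals()].
#' @param weight_fun See [position_signals()].
#' @return An `spp_set`: list with `markers` (data frame: `spp_id`,
#'   `unigene_id`, `start`, `end`, `span`, `sppdev_ratio`,
#'   `informative_probes`), `calls` (marker-by-line summarized calls in
#'   `{A,B,C,D,I,-}`) and `chip_calls` (marker-by-chip raw calls).
#' @export
detect_spps <- function(panel, min_ratio = 1.2, min_informative = 2L,
                        min_span = 4L, nocall_margin = 0.1,
                        min_informative_position = NULL,
                        weight_fun = probe_weight) {
  profiles <- position_signals(panel, min_informative_position, weight_fun)
  n_pos <- nrow(profiles$positions)
  chips <- colnames(profiles$signal)
  ratios <- rep(NA_real_, n_pos)
  chip_calls <- matrix(NA_character_, n_pos, length(chips),
                       dimnames = list(NULL, chips))
  for (i in seq_len(n_pos)) {
    fit <- fit_modes(profiles$signal[i, ])
    if (is.null(fit)) next
    ratios[i] <- fit$ratio
    if (fit$ratio > 1)
      chip_calls[i, ] <- call_chip_allele(profiles$signal[i, ], fit,
                                          nocall_margin)
  }
  assemble_spps(profiles, chip_calls, ratios, panel$manifest,
                min_ratio = min_ratio, min_informative = min_informative,
                min_span = min_span)
}
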