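#' Hybridization simulator configuration
#'
#' Defines the conditions emulated by [simulate_panel()]: a germplasm panel
#' of inbred lines hybridized in triplicate to a 25 nt array tiling unigene
#' transcripts at a 2 bp step, with planted SNPs, deletion alleles and
#' paralog (duplicated-segment) pairs, a G/C-dependent probe affinity
#' curve, mismatch attenuation from the same positional family as
#' [probe_weight()], lognormal background drawn by the anti-genomic probes
#' and multiplicative lognormal chip noise.
#'
#' Default sizes (20 lines, 3 replicates, 100 unigenes around 400 bases)
#' give a panel large enough for stable mode fitting yet fast to analyse.
#' Within a unigene, successive SNPs reuse one line bipartition with
#' probability `ld_within_unigene`: inbred germplasm carries strong
#' within-gene linkage, so polymorphisms in one transcript largely sort the
#' panel the same way.
#'
#' @param n_lines,n_replicates,n_unigenes Panel dimensions.
#' @param unigene_length_mean,unigene_length_sd Unigene length distribution
#'   (bases, normal, floored at 150).
#' @param tiling_step,probe_length Array geometry (2 bp step, 25 nt probes).
#' @param snps_per_unigene Mean planted SNP sites per unigene (Poisson).
#' @param snp_line_prob Probability a line carries the alternate allele at
#'   a SNP site.
#' @param ld_within_unigene Probability a SNP site reuses the unigene's
#'   primary line bipartition.
#' @param deletion_rate Probability a unigene segregates a deletion allele.
#' @param deletion_length Deleted bases.
#' @param paralog_rate Probability a unigene donates a duplicated segment
#'   to another unigene.
#' @param paralog_length Duplicated bases.
#' @param paralog_max_mismatch Mismatches planted in the duplicate (0-2
#'   sampled uniformly up to this).
#' @param cross_hyb_frac Cross-hybridization intensity contributed by a
#'   duplicated segment, as a fraction of full affinity.
#' @param attenuation_center Residual signal fraction for a probe carrying
#'   a mismatch at its center (attenuation elsewhere follows the
#'   [probe_weight()] falloff).
#' @param gc_peak,gc_width,gc_scale Probe affinity by G/C count:
#'   `gc_scale * exp(-((gc - gc_peak) / gc_width)^2)`.
#' @param probe_affinity_sdlog Lognormal spread of per-probe affinity
#'   around the G/C curve. Affinity is sequence-driven, and probes tiled
#'   2 bp apart share 23 of 25 bases, so the field is spatially smoothed
#'   along each unigene (moving average over the tiling redundancy) rather
#'   than independent per probe; fixed across chips.
#' @param poor_probe_frac,poor_probe_factor Fraction of tiling probes that
#'   hybridize poorly regardless of G/C — transcript-derived probes
#'   spanning splice junctions or otherwise mismatching the genomic
#'   target, modelled as junction points that silence every probe
#'   overlapping them — and the residual affinity factor those probes
#'   keep. Together with `probe_affinity_sdlog` this reproduces the smooth
#'   wide intensity continuum of real arrays, where roughly a quarter of
#'   tiling probes sit below background.
#' @param background_meanlog,background_sdlog Lognormal background
#'   hybridization.
#' @param noise_sdlog Multiplicative lognormal noise per probe and chip.
#' @param n_antigenomic Anti-genomic control probes.
#' @param seed Mandatory RNG seed; the whole panel is reproducible from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_lines = 20L, n_replicates = 3L, n_unigenes = 100L,
                       unigene_length_mean = 400, unigene_length_sd = 60,
                       tiling_step = 2L, probe_length = 25L,
                       snps_per_unigene = 1.5, snp_line_prob = 0.3,
                       ld_within_unigene = 0.8,
                       deletion_rate = 0.05, deletion_length = 120L,
                       paralog_rate = 0.05, paralog_length = 120L,
                       paralog_max_mismatch = 2L, cross_hyb_frac = 0.5,
                       attenuation_center = 0.3,
                       gc_peak = 11, gc_width = 6, gc_scale = 3000,
                       probe_affinity_sdlog = 0.6,
                       poor_probe_frac = 0.3, poor_probe_factor = 0.005,
                       background_meanlog = log(100), background_sdlog = 0.3,
                       noise_sdlog = 0.1, n_antigenomic = 500L,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  cfg <- as.list(environment())
  if (cfg$n_lines < 2L) stop("need at least 2 lines")
  if (cfg$n_unigenes < 1L) stop("need at least 1 unigene")
  if (cfg$n_replicates < 1L) stop("need at least 1 replicate")
  for (p in c("snp_line_prob", "ld_within_unigene", "deletion_rate",
              "paralog_rate", "cross_hyb_frac", "attenuation_center",
              "poor_probe_frac"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(p, " must lie in [0, 1]")
  if (cfg$n_antigenomic < 1L)
    stop("at least one anti-genomic probe is required for backgrounding")
  class(cfg) <- "sim_config"
  cfg
}

# attenuation of a probe's signal by a mismatch at signed offset d from the
# probe center: full attenuation_center at the center, none at the edge,
# following the same positional falloff as probe_weight
mismatch_attenuation <- function(offset, probe_length, attenuation_center) {
  1 - (1 - attenuation_center) * probe_weight(offset, probe_length)
}

#' Simulate a hybridization panel
#'
#' Generates unigene sequences, a probe design tiling them, a chip manifest
#' with replicate hybridizations, a raw probe-by-chip intensity matrix and
#' the truth tables needed for validation. The expected intensity of a
#' tiling probe on a line's chip is
#' `affinity(gc) * prod(mismatch attenuations) * deletion factor +
#' cross-hybridization + background`, all multiplied by lognormal noise;
#' anti-genomic probes carry background only. Deletion carriers lose the
#' self term for probes inside the deleted range, so their residual signal
#' is background — unless a paralogous duplicate elsewhere contributes
#' cross-hybridization, which reproduces the classic paralog-confounded
#' calls inside a deletion.
#'
#' @param config A `sim_config`.
#' @return List with `design` (a `probe_design`), `manifest`
#'   (`chip_manifest`), `intensities` (raw matrix), `sequences`
#'   ([Biostrings::DNAStringSet]), `truth` (`truth_set` rows per carrier
#'   line), `snp_sites` (planted SNP sites with their carrier partitions),
#'   `paralogs` (duplicated-segment registry) and `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  L <- cfg$probe_length

  lines <- sprintf("L%02d", seq_len(cfg$n_lines))
  manifest <- as_chip_manifest(data.frame(
    chip_id = paste0(rep(lines, each = cfg$n_replicates), "_r",
                     rep(seq_len(cfg$n_replicates), cfg$n_lines)),
    line_id = rep(lines, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), cfg$n_lines),
    stringsAsFactors = FALSE), cfg$n_replicates)

  lens <- pmax(150L, as.integer(round(stats::rnorm(
    cfg$n_unigenes, cfg$unigene_length_mean, cfg$unigene_length_sd))))
  unis <- sprintf("UG%04d", seq_len(cfg$n_unigenes))
  seqs <- vapply(lens, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- unis

  # paralog pairs: copy a segment of a source unigene into a target
  paralogs <- NULL
  src <- which(stats::runif(cfg$n_unigenes) < cfg$paralog_rate &
                 lens >= cfg$paralog_length + 2L * L)
  for (i in src) {
    cand <- setdiff(which(lens >= cfg$paralog_length + 2L * L), i)
    if (length(cand) == 0L) next
    j <- cand[sample.int(length(cand), 1L)]
    s_src <- sample.int(lens[i] - cfg$paralog_length + 1L, 1L)
    s_tgt <- sample.int(lens[j] - cfg$paralog_length + 1L, 1L)
    n_mm <- sample.int(cfg$paralog_max_mismatch + 1L, 1L) - 1L
    seg <- strsplit(substr(seqs[i], s_src, s_src + cfg$paralog_length - 1L),
                    "")[[1]]
    mm_pos <- if (n_mm > 0L) sort(sample.int(cfg$paralog_length, n_mm)) else
      integer(0)
    for (p in mm_pos)
      seg[p] <- sample(setdiff(c("A", "C", "G", "T"), seg[p]), 1L)
    substr(seqs[j], s_tgt, s_tgt + cfg$paralog_length - 1L) <-
      paste(seg, collapse = "")
    paralogs <- rbind(paralogs, data.frame(
      source = unis[i], src_start = s_src,
      src_end = s_src + cfg$paralog_length - 1L,
      target = unis[j], tgt_start = s_tgt,
      tgt_end = s_tgt + cfg$paralog_length - 1L,
      mismatches = n_mm,
      mismatch_offsets = paste(mm_pos, collapse = ","),
      stringsAsFactors = FALSE))
  }
  if (is.null(paralogs))
    paralogs <- data.frame(source = character(0), src_start = integer(0),
                           src_end = integer(0), target = character(0),
                           tgt_start = integer(0), tgt_end = integer(0),
                           mismatches = integer(0),
                           mismatch_offsets = character(0))

  # planted variants
  snp_sites <- list()
  deletions <- list()
  for (i in seq_len(cfg$n_unigenes)) {
    primary <- stats::runif(cfg$n_lines) < cfg$snp_line_prob
    n_snp <- stats::rpois(1L, cfg$snps_per_unigene)
    lo <- L; hi <- lens[i] - L
    if (hi > lo && n_snp > 0L) {
      pos <- sort(sample(lo:hi, min(n_snp, hi - lo + 1L)))
      for (p in pos) {
        carriers <- if (stats::runif(1) < cfg$ld_within_unigene) primary else
          stats::runif(cfg$n_lines) < cfg$snp_line_prob
        if (!any(carriers) || all(carriers)) next
        snp_sites[[length(snp_sites) + 1L]] <- data.frame(
          unigene_id = unis[i], position = p,
          carriers = paste(lines[carriers], collapse = ","),
          n_carriers = sum(carriers), stringsAsFactors = FALSE)
      }
    }
    if (stats::runif(1) < cfg$deletion_rate &&
        lens[i] > cfg$deletion_length + 2L * L) {
      ds <- sample.int(lens[i] - cfg$deletion_length + 1L, 1L)
      carriers <- stats::runif(cfg$n_lines) < cfg$snp_line_prob
      if (any(carriers) && !all(carriers))
        deletions[[length(deletions) + 1L]] <- data.frame(
          unigene_id = unis[i], start = ds,
          end = ds + cfg$deletion_length - 1L,
          carriers = paste(lines[carriers], collapse = ","),
          stringsAsFactors = FALSE)
    }
  }
  snp_sites <- if (length(snp_sites)) do.call(rbind, snp_sites) else
    data.frame(unigene_id = character(0), position = integer(0),
               carriers = character(0), n_carriers = integer(0))
  deletions <- if (length(deletions)) do.call(rbind, deletions) else
    data.frame(unigene_id = character(0), start = integer(0),
               end = integer(0), carriers = character(0))

  design <- sim_design(cfg, unis, lens, seqs)
  expected <- sim_expected(cfg, design, lines, snp_sites, deletions,
                           paralogs)
  inten <- sim_intensities(cfg, design, expected, manifest)
  truth <- sim_truth(snp_sites, deletions)

  list(design = design, manifest = manifest, intensities = inten,
       sequences = Biostrings::DNAStringSet(seqs),
       truth = truth, snp_sites = snp_sites, deletions = deletions,
       paralogs = paralogs,
       probe_affinity = attr(expected, "probe_affinity"), config = cfg)
}

# probe design tiling the given sequences, plus anti-genomic controls
sim_design <- function(cfg, unis, lens, seqs) {
  L <- cfg$probe_length
  gc_count <- function(s) {
    v <- strsplit(s, "")[[1]]
    sum(v == "G" | v == "C")
  }
  des_rows <- lapply(seq_along(unis), function(i) {
    starts <- seq(1L, lens[i] - L + 1L, by = cfg$tiling_step)
    gc <- vapply(starts, function(s)
      gc_count(substr(seqs[i], s, s + L - 1L)), numeric(1))
    data.frame(probe_id = sprintf("%s_p%04d", unis[i], starts),
               unigene_id = unis[i], start = starts, length = L,
               gc = as.integer(gc), antigenomic = FALSE,
               stringsAsFactors = FALSE)
  })
  ag <- data.frame(probe_id = sprintf("AG%05d", seq_len(cfg$n_antigenomic)),
                   unigene_id = NA_character_, start = NA_integer_,
                   length = L,
                   gc = sample(5:18, cfg$n_antigenomic, replace = TRUE),
                   antigenomic = TRUE, stringsAsFactors = FALSE)
  as_probe_design(rbind(do.call(rbind, des_rows), ag))
}

# expected noise-free self + cross-hybridization signal, tiling probe x line
sim_expected <- function(cfg, design, lines, snp_sites, deletions,
                         paralogs) {
  L <- cfg$probe_length
  tiling <- design[!design$antigenomic, , drop = FALSE]
  affinity <- cfg$gc_scale *
    exp(-((design$gc - cfg$gc_peak) / cfg$gc_width)^2)
  names(affinity) <- design$probe_id
  # per-probe sequence idiosyncrasy, shared by self and cross terms:
  # a smooth lognormal field along each unigene (overlapping probes share
  # most of their sequence) plus silenced runs at splice-junction points
  redundancy <- max(1L, as.integer(round(L / max(1L, cfg$tiling_step))))
  for (u in unique(tiling$unigene_id)) {
    ix <- which(tiling$unigene_id == u)
    ix <- ix[order(tiling$start[ix])]
    n_u <- length(ix)
    e <- stats::rnorm(n_u + redundancy)
    sm <- vapply(seq_len(n_u), function(i)
      sum(e[i:(i + redundancy - 1L)]) / sqrt(redundancy), numeric(1))
    fac <- exp(cfg$probe_affinity_sdlog * sm)
    n_junction <- stats::rpois(1L, cfg$poor_probe_frac * n_u / redundancy)
    if (n_junction > 0L) {
      jpos <- sample.int(max(tiling$start[ix]) + L - 1L, n_junction)
      hit <- vapply(ix, function(i) any(jpos >= tiling$start[i] &
                                          jpos <= tiling$start[i] + L - 1L),
                    logical(1))
      fac[hit] <- fac[hit] * cfg$poor_probe_factor
    }
    affinity[tiling$probe_id[ix]] <- affinity[tiling$probe_id[ix]] * fac
  }

  # per-line expected self signal of every tiling probe
  n_lines <- length(lines)
  probe_factor <- matrix(1, nrow(tiling), n_lines,
                         dimnames = list(tiling$probe_id, lines))
  half <- (L - 1) / 2
  for (k in seq_len(nrow(snp_sites))) {
    u <- snp_sites$unigene_id[k]; p <- snp_sites$position[k]
    carr <- strsplit(snp_sites$carriers[k], ",")[[1]]
    sel <- tiling$unigene_id == u & tiling$start <= p &
      tiling$start + L - 1L >= p
    if (!any(sel)) next
    d <- p - (tiling$start[sel] + half)
    att <- mismatch_attenuation(d, L, cfg$attenuation_center)
    probe_factor[sel, carr] <- probe_factor[sel, carr] * att
  }
  for (k in seq_len(nrow(deletions))) {
    u <- deletions$unigene_id[k]
    ds <- deletions$start[k]; de <- deletions$end[k]
    carr <- strsplit(deletions$carriers[k], ",")[[1]]
    sel <- which(tiling$unigene_id == u & tiling$start <= de &
                   tiling$start + L - 1L >= ds)
    if (length(sel) == 0L) next
    ov <- pmin(de, tiling$start[sel] + L - 1L) -
      pmax(ds, tiling$start[sel]) + 1L
    fac <- (1 - ov / L)^2        # fully inside -> no self signal
    probe_factor[sel, carr] <- probe_factor[sel, carr] * fac
  }

  # cross-hybridization between duplicated segments, both directions; the
  # contribution tracks the *other* copy's genotype (its deletions/SNPs)
  cross <- matrix(0, nrow(tiling), n_lines,
                  dimnames = list(tiling$probe_id, lines))
  for (k in seq_len(nrow(paralogs))) {
    pr <- paralogs[k, ]
    mm <- if (nzchar(pr$mismatch_offsets))
      as.integer(strsplit(pr$mismatch_offsets, ",")[[1]]) else integer(0)
    # probes on the source receive signal from the target copy
    # (donor genotype approximated by the aligned target probe where the
    # tiling admits one, else the duplicate is treated as intact)
    sel_src <- which(tiling$unigene_id == pr$source &
                       tiling$start <= pr$src_end &
                       tiling$start + L - 1L >= pr$src_start)
    for (s in sel_src) {
      aligned_tgt <- pr$tgt_start + (tiling$start[s] - pr$src_start)
      donor <- which(tiling$unigene_id == pr$target &
                       tiling$start == aligned_tgt)
      donor_fac <- if (length(donor) == 1L) probe_factor[donor, ] else
        rep(1, n_lines)
      ov <- (min(pr$src_end, tiling$start[s] + L - 1L) -
               max(pr$src_start, tiling$start[s]) + 1L) / L
      mm_att <- 1
      for (pm in mm) {
        pos_on <- pr$src_start + pm - 1L
        if (tiling$start[s] <= pos_on && tiling$start[s] + L - 1L >= pos_on)
          mm_att <- mm_att * mismatch_attenuation(
            pos_on - (tiling$start[s] + half), L, cfg$attenuation_center)
      }
      cross[s, ] <- cross[s, ] + cfg$cross_hyb_frac *
        affinity[tiling$probe_id[s]] * ov^2 * mm_att * donor_fac
    }
    # probes on the target receive signal from the source copy
    sel_tgt <- which(tiling$unigene_id == pr$target &
                       tiling$start <= pr$tgt_end &
                       tiling$start + L - 1L >= pr$tgt_start)
    for (s in sel_tgt) {
      aligned_src <- pr$src_start + (tiling$start[s] - pr$tgt_start)
      donor <- which(tiling$unigene_id == pr$source &
                       tiling$start == aligned_src)
      donor_fac <- if (length(donor) == 1L) probe_factor[donor, ] else
        rep(1, n_lines)
      ov <- (min(pr$tgt_end, tiling$start[s] + L - 1L) -
               max(pr$tgt_start, tiling$start[s]) + 1L) / L
      mm_att <- 1
      for (pm in mm) {
        pos_on <- pr$tgt_start + pm - 1L
        if (tiling$start[s] <= pos_on && tiling$start[s] + L - 1L >= pos_on)
          mm_att <- mm_att * mismatch_attenuation(
            pos_on - (tiling$start[s] + half), L, cfg$attenuation_center)
      }
      cross[s, ] <- cross[s, ] + cfg$cross_hyb_frac *
        affinity[tiling$probe_id[s]] * ov^2 * mm_att * donor_fac
    }
  }

  expected <- affinity[tiling$probe_id] * probe_factor + cross
  attr(expected, "probe_affinity") <- affinity[tiling$probe_id]
  expected
}

# raw intensities: expected value per line, then per-chip background + noise
sim_intensities <- function(cfg, design, expected, manifest) {
  tiling <- design[!design$antigenomic, , drop = FALSE]
  n_chips <- nrow(manifest)
  n_tiling <- nrow(tiling)
  n_ag <- sum(design$antigenomic)
  inten <- matrix(0, nrow(design), n_chips,
                  dimnames = list(design$probe_id, manifest$chip_id))
  for (c_ix in seq_len(n_chips)) {
    l <- manifest$line_id[c_ix]
    bg_t <- stats::rlnorm(n_tiling, cfg$background_meanlog,
                          cfg$background_sdlog)
    noise_t <- stats::rlnorm(n_tiling, 0, cfg$noise_sdlog)
    inten[tiling$probe_id, c_ix] <- (expected[, l] + bg_t) * noise_t
    bg_a <- stats::rlnorm(n_ag, cfg$background_meanlog,
                          cfg$background_sdlog)
    noise_a <- stats::rlnorm(n_ag, 0, cfg$noise_sdlog)
    inten[design$probe_id[design$antigenomic], c_ix] <- bg_a * noise_a
  }
  inten
}

# truth tables (per carrier line)
sim_truth <- function(snp_sites, deletions) {
  truth_rows <- list()
  for (k in seq_len(nrow(snp_sites))) {
    carr <- strsplit(snp_sites$carriers[k], ",")[[1]]
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      line_id = carr, unigene_id = snp_sites$unigene_id[k],
      pos_start = snp_sites$position[k], pos_end = snp_sites$position[k],
      type = "snp", stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(deletions))) {
    carr <- strsplit(deletions$carriers[k], ",")[[1]]
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      line_id = carr, unigene_id = deletions$unigene_id[k],
      pos_start = deletions$start[k], pos_end = deletions$end[k],
      type = "deletion", stringsAsFactors = FALSE)
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(line_id = character(0), unigene_id = character(0),
               pos_start = integer(0), pos_end = integer(0),
               type = character(0))
  class(truth) <- c("truth_set", "data.frame")
  truth
}

#' Write a simulated panel as a file fixture
#'
#' Emits the standard artifact formats — probe design TSV, chip manifest
#' TSV, intensity TSV, unigene FASTA, truth TSV — plus the simulation
#' configuration (seed included) as YAML, so a simulated panel round-trips
#' through the readers unchanged. Output is byte-stable for a fixed seed.
#'
#' @param sim Output of [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return Named vector of the file paths written.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stop("directory not writable: ", dir)
  paths <- c(design = file.path(dir, "probes.tsv"),
             manifest = file.path(dir, "manifest.tsv"),
             intensities = file.path(dir, "intensities.tsv"),
             fasta = file.path(dir, "unigenes.fasta"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "sim_config.yaml"))
  write_probe_design(sim$design, paths["design"])
  write_chip_manifest(sim$manifest, paths["manifest"])
  write_intensity_matrix(sim$intensities, paths["intensities"])
  Biostrings::writeXStringSet(sim$sequences, paths["fasta"], width = 70L)
  write_truth_table(sim$truth, paths["truth"])
  yaml::write_yaml(unclass(sim$config), paths["config"])
  paths
}

#' Simulate a deletion confounded by a paralog
#'
#' A focused scenario reproducing the classic failure mode of tiling-array
#' genotyping at a presence/absence locus: a gene carries a large 5'
#' deletion in part of the panel, while a paralog elsewhere in the
#' transcriptome shares the deleted region at high but imperfect identity
#' (scattered substitutions, roughly one per `shared_mismatch_every`
#' bases). Cross-hybridization from the intact paralog is weak enough that
#' deletion carriers rise above background only where a probe meets a
#' locally mismatch-free stretch, so short carrier/non-carrier polymorphic
#' markers appear at conserved cores *inside* the deleted region — reading
#' as local polymorphisms rather than the deletion — and their flanks are
#' exactly the multi-copy sequence that [flag_multicopy()] is designed to
#' catch. Variant-free background unigenes pad the array so quantile
#' normalization is not distorted by the deletion itself.
#'
#' @param n_lines Panel size; the first `n_carriers` lines carry the
#'   deletion allele.
#' @param n_carriers Deletion carriers (default half the panel).
#' @param gene_length Length of the deletion-bearing gene.
#' @param deletion `c(start, end)` of the deleted region (default the 5'
#'   200 bases); also the region the paralog shares.
#' @param shared_mismatch_every Mean spacing (bases) of substitutions
#'   between the gene and the paralog copy (default 28, about 96%
#'   identity).
#' @param cross_hyb_frac Cross-hybridization fraction for a mismatch-free
#'   probe (default 0.02; marginal by design, see above).
#' @param n_background_unigenes Variant-free unigenes padding the array.
#' @param seed RNG seed.
#' @param ... Overrides passed to [sim_config()] (noise, affinity, ...).
#' @return Same shape as [simulate_panel()]; `truth` holds the deletion,
#'   `paralogs` the duplicated-segment registry with its planted mismatch
#'   offsets.
#' @export
simulate_deletion_paralog <- function(n_lines = 20L,
                                      n_carriers = n_lines %/% 2L,
                                      gene_length = 600L,
                                      deletion = c(1L, 200L),
                                      shared_mismatch_every = 28L,
                                      cross_hyb_frac = 0.02,
                                      n_background_unigenes = 30L,
                                      seed, ...) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- sim_config(n_lines = n_lines, n_unigenes = 2L,
                    snps_per_unigene = 0, deletion_rate = 0,
                    paralog_rate = 0, cross_hyb_frac = cross_hyb_frac,
                    seed = seed, ...)
  set.seed(cfg$seed)
  L <- cfg$probe_length

  lines <- sprintf("L%02d", seq_len(n_lines))
  carriers <- lines[seq_len(n_carriers)]
  manifest <- as_chip_manifest(data.frame(
    chip_id = paste0(rep(lines, each = cfg$n_replicates), "_r",
                     rep(seq_len(cfg$n_replicates), n_lines)),
    line_id = rep(lines, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), n_lines),
    stringsAsFactors = FALSE), cfg$n_replicates)

  seg_len <- deletion[2] - deletion[1] + 1L
  paralog_length <- seg_len + 2L * L + 150L
  unis <- c("GENE", "PARALOG",
            if (n_background_unigenes > 0L)
              sprintf("BG%03d", seq_len(n_background_unigenes)))
  lens <- c(gene_length, paralog_length,
            rep(400L, n_background_unigenes))
  seqs <- vapply(lens, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- unis

  # scattered substitutions: one per spacing window, uniform within it
  n_mm <- seg_len %/% shared_mismatch_every
  mm_pos <- sort(vapply(seq_len(n_mm), function(k) {
    lo <- (k - 1L) * shared_mismatch_every + 1L
    hi <- min(k * shared_mismatch_every, seg_len)
    if (hi > lo) sample(lo:hi, 1L) else lo
  }, integer(1)))
  seg <- strsplit(substr(seqs["GENE"], deletion[1], deletion[2]), "")[[1]]
  for (q in mm_pos)
    seg[q] <- sample(setdiff(c("A", "C", "G", "T"), seg[q]), 1L)
  tgt_start <- L + 1L
  substr(seqs["PARALOG"], tgt_start, tgt_start + seg_len - 1L) <-
    paste(seg, collapse = "")

  paralogs <- data.frame(
    source = "GENE", src_start = deletion[1], src_end = deletion[2],
    target = "PARALOG", tgt_start = tgt_start,
    tgt_end = tgt_start + seg_len - 1L,
    mismatches = n_mm,
    mismatch_offsets = paste(mm_pos, collapse = ","),
    stringsAsFactors = FALSE)
  deletions <- data.frame(unigene_id = "GENE",
                          start = deletion[1], end = deletion[2],
                          carriers = paste(carriers, collapse = ","),
                          stringsAsFactors = FALSE)
  snp_sites <- data.frame(unigene_id = character(0), position = integer(0),
                          carriers = character(0), n_carriers = integer(0))

  design <- sim_design(cfg, unis, lens, seqs)
  expected <- sim_expected(cfg, design, lines, snp_sites, deletions,
                           paralogs)
  inten <- sim_intensities(cfg, design, expected, manifest)
  truth <- sim_truth(snp_sites, deletions)

  list(design = design, manifest = manifest, intensities = inten,
       sequences = Biostrings::DNAStringSet(seqs),
       truth = truth, snp_sites = snp_sites, deletions = deletions,
       paralogs = paralogs,
       probe_affinity = attr(expected, "probe_affinity"), config = cfg)
}

#' Score recovery of planted SNP sites
#'
#' For every planted SNP site of a simulation, checks whether some marker
#' contains the site within `window` bases of its range and carries exactly
#' the planted line partition (carriers `B`, the attenuated low mode;
#' non-carriers `A`; C/D read as B/A). Sites are additionally labelled
#' `high_contrast` when the planted SNP is the sole driver of local
#' hybridization contrast: no planted deletion or duplicated segment within
#' probe reach (`probe_length - 1` bases) and no neighboring SNP with a
#' different carrier set within probe reach — and when the site is
#' adequately probed: around the SNP, enough overlapping probes are
#' expected above background for carriers and non-carriers alike, judged
#' from the generator's own realized probe affinities against the
#' configured background distribution. A SNP falling where the array's
#' probes sit below background (about a quarter of real tiling probes)
#' produces no hybridization contrast and is undetectable by any caller.
#' Confounded or unprobed sites remain in the table so the caller's
#' behavior on them can be studied, but recovery guarantees only make
#' sense for the high-contrast subset.
#'
#' @param sim Output of [simulate_panel()].
#' @param spps An `spp_set` detected from the simulated panel.
#' @param window Containment window in bases (default 8).
#' @return Data frame: one row per planted SNP site with `unigene_id`,
#'   `position`, `n_carriers`, `high_contrast`, `recovered`.
#' @export
planted_snp_recovery <- function(sim, spps, window = 8L) {
  sites <- sim$snp_sites
  if (nrow(sites) == 0L)
    return(data.frame(unigene_id = character(0), position = integer(0),
                      n_carriers = integer(0), high_contrast = logical(0),
                      recovered = logical(0)))
  spps <- convert_cd(spps)
  m <- spps$markers
  lines <- spp_lines(spps)
  reach <- sim$config$probe_length - 1L
  tiling_probes <- as.data.frame(sim$design[!sim$design$antigenomic, ,
                                            drop = FALSE])

  out <- lapply(seq_len(nrow(sites)), function(k) {
    s <- sites[k, ]
    del <- sim$deletions[sim$deletions$unigene_id == s$unigene_id, ,
                         drop = FALSE]
    near_del <- nrow(del) > 0L && any(del$start - reach <= s$position &
                                        del$end + reach >= s$position)
    pr <- sim$paralogs
    near_par <- any(
      (pr$source == s$unigene_id & pr$src_start - reach <= s$position &
         pr$src_end + reach >= s$position) |
      (pr$target == s$unigene_id & pr$tgt_start - reach <= s$position &
         pr$tgt_end + reach >= s$position))
    near_snp <- sites[sites$unigene_id == s$unigene_id &
                        sites$position != s$position &
                        abs(sites$position - s$position) <= reach, ,
                      drop = FALSE]
    discordant <- nrow(near_snp) > 0L && any(near_snp$carriers != s$carriers)

    # adequately probed: at 4 consecutive positions containing the SNP,
    # at least min_inf overlapping probes are expected above background
    # for both modes (carrier values carry the SNP attenuation)
    cfg <- sim$config
    thr_eff <- stats::qlnorm(0.9, cfg$background_meanlog,
                             cfg$background_sdlog) -
      exp(cfg$background_meanlog)
    min_inf <- 4L
    tp <- tiling_probes[tiling_probes$unigene_id == s$unigene_id, ,
                        drop = FALSE]
    half <- (cfg$probe_length - 1) / 2
    probed <- vapply((s$position - 1L):(s$position + 2L), function(p) {
      ov <- tp[tp$start <= p & tp$start + cfg$probe_length - 1L >= p, ,
               drop = FALSE]
      if (nrow(ov) < min_inf) return(FALSE)
      aff <- sim$probe_affinity[ov$probe_id]
      covers_snp <- ov$start <= s$position &
        ov$start + cfg$probe_length - 1L >= s$position
      att <- rep(1, nrow(ov))
      att[covers_snp] <- mismatch_attenuation(
        s$position - (ov$start[covers_snp] + half), cfg$probe_length,
        cfg$attenuation_center)
      sum(aff > thr_eff) >= min_inf && sum(aff * att > thr_eff) >= min_inf
    }, logical(1))
    hc <- !near_del && !near_par && !discordant && all(probed)

    carr <- strsplit(s$carriers, ",")[[1]]
    planted <- ifelse(lines %in% carr, "B", "A")
    hit <- which(m$unigene_id == s$unigene_id &
                   m$start - window <= s$position &
                   m$end + window >= s$position)
    rec <- any(vapply(hit, function(h)
      all(spps$calls[h, lines] == planted), logical(1)))
    data.frame(unigene_id = s$unigene_id, position = s$position,
               n_carriers = s$n_carriers, high_contrast = hc,
               recovered = rec, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
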