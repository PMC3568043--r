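# Shared in-code fixtures for the unit tests. Everything is built
# programmatically; nothing is read from disk.

# a minimal probe design data frame (3 tiling probes on one unigene + 1 AG)
toy_design_df <- function() {
  data.frame(
    probe_id = c("p1", "p2", "p3", "ag1"),
    unigene_id = c("u1", "u1", "u1", NA),
    start = c(1L, 3L, 5L, NA),
    length = 25L,
    gc = c(12L, 11L, 13L, 9L),
    antigenomic = c(0L, 0L, 0L, 1L),
    stringsAsFactors = FALSE)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

# a norm_panel-shaped object with fully controlled values, bypassing
# normalization, for unit tests of downstream operations
fake_panel <- function(intensities, design, manifest, thresholds,
                       percentile = 0.9) {
  structure(list(intensities = intensities, manifest = manifest,
                 design = design, thresholds = thresholds,
                 provenance = list(threshold_percentile = percentile)),
            class = "norm_panel")
}

toy_manifest <- function(n_lines = 2, n_rep = 3) {
  lines <- sprintf("L%02d", seq_len(n_lines))
  as_chip_manifest(data.frame(
    chip_id = paste0(rep(lines, each = n_rep), "_r",
                     rep(seq_len(n_rep), n_lines)),
    line_id = rep(lines, each = n_rep),
    replicate = rep(seq_len(n_rep), n_lines),
    stringsAsFactors = FALSE), n_rep)
}

# an spp_set built directly from a call matrix (markers get plausible stats)
toy_spp_set <- function(calls, unigene_id = NULL, start = NULL, end = NULL,
                        ratio = 2, informative = 5) {
  n <- nrow(calls)
  if (is.null(unigene_id)) unigene_id <- rep("u1", n)
  if (is.null(start)) start <- seq_len(n) * 50L
  if (is.null(end)) end <- start + 3L
  markers <- data.frame(
    spp_id = paste0(unigene_id, ":", start),
    unigene_id = unigene_id, start = as.integer(start),
    end = as.integer(end), span = as.integer(end - start + 1L),
    sppdev_ratio = rep_len(ratio, n),
    informative_probes = rep_len(informative, n),
    stringsAsFactors = FALSE)
  rownames(markers) <- markers$spp_id
  rownames(calls) <- markers$spp_id
  new_spp_set(markers, calls)
}

# deterministic pseudo-random call matrix over {A,B} with optional extras
random_calls <- function(n_spp, lines, seed = 1,
                         symbols = c("A", "B"), prob = NULL) {
  withr::with_seed(seed, {
    matrix(sample(symbols, n_spp * length(lines), replace = TRUE,
                  prob = prob),
           nrow = n_spp, ncol = length(lines),
           dimnames = list(NULL, lines))
  })
}

# small simulated panel shared by several tests (computed once per run)
.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_cache$small_sim)) {
    .fixture_cache$small_sim <-
      simulate_panel(sim_config(n_lines = 8, n_unigenes = 12,
                                n_antigenomic = 200, seed = 424242))
  }
  .fixture_cache$small_sim
}

small_run <- function() {
  if (is.null(.fixture_cache$small_run)) {
    sim <- small_sim()
    .fixture_cache$small_run <-
      run_pipeline(sim$intensities, sim$design, sim$manifest,
                   sim$sequences)
  }
  .fixture_cache$small_run
}
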