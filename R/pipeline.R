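#' Run the discovery pipeline on a panel
#'
#' Convenience wrapper chaining normalization, SPP detection, multi-copy
#' flagging and the post-detection filter chain under one parameter
#' profile. Inputs can come from files (via the readers) or from
#' [simulate_panel()].
#'
#' @param raw Raw probe-by-chip intensity matrix.
#' @param design A `probe_design`.
#' @param manifest A `chip_manifest`.
#' @param sequences Named [Biostrings::DNAStringSet] of unigenes; needed
#'   when the profile drops multi-copy markers.
#' @param params A `filter_params`; default the `"diversity-1.2"` preset.
#' @param nocall_margin,min_informative_position,weight_fun Passed to
#'   [detect_spps()]. Detection stringency (`min_ratio`,
#'   `min_informative`, `min_span`) is taken from `params`.
#' @return List: `panel` (`norm_panel`), `spps_raw` (detected, unfiltered),
#'   `spps` (filtered `spp_set` with provenance log), `multicopy` (flag
#'   table or NULL).
#' @export
run_pipeline <- function(raw, design, manifest, sequences = NULL,
                         params = preset_params("diversity-1.2"),
                         nocall_margin = 0.1,
                         min_informative_position = NULL,
                         weight_fun = probe_weight) {
  panel <- normalize_panel(raw, design, manifest)
  spps_raw <- detect_spps(
    panel,
    min_ratio = if (is.na(params$min_ratio)) 1 else params$min_ratio,
    min_informative = if (is.na(params$min_informative)) 1L else
      params$min_informative,
    min_span = if (is.na(params$min_span)) 1L else params$min_span,
    nocall_margin = nocall_margin,
    min_informative_position = min_informative_position,
    weight_fun = weight_fun)
  multicopy <- NULL
  if (isTRUE(params$drop_multicopy)) {
    if (is.null(sequences))
      stop("params drop multi-copy markers but no sequences were supplied")
    multicopy <- flag_multicopy(spps_raw, sequences)
  }
  spps <- apply_filters(spps_raw, params, multicopy = multicopy)
  list(panel = panel, spps_raw = spps_raw, spps = spps,
       multicopy = multicopy)
}
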