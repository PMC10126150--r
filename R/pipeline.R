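#' Run the screen analysis end to end on a run directory
#'
#' Convenience wrapper over the individual stages: reads the run's FASTQ and
#' cycle map, links reads to clusters tile by tile ([build_cluster_table()]),
#' summarizes per-condition intensities ([summarize_conditions()]), applies
#' the intensity-window and RSD filters ([apply_filters()]), and ranks
#' candidates at cluster and unique-SD level ([rank_clusters()],
#' [aggregate_unique_sd()]).
#'
#' Expects the directory layout written by [generate_screen()]:
#' `run.fastq`, `locs/s_1_<tile>.locs`, `cif/s_1_<tile>_C<cycle>.cif`,
#' `cycle_map.yaml`.
#'
#' @param run_dir Run directory.
#' @param condition Target condition to rank on; defaults to the first
#'   target in the cycle map (for multi-concentration screens, rank on the
#'   lowest concentration and keep the others as consistency columns).
#' @param direction `"on"` or `"off"`.
#' @param cfg A [filter_config()].
#' @param layout A [library_layout()].
#' @param verbose Log per-tile linking counts.
#' @return A list: `table`, `summaries`, `retained`, `removed`,
#'   `ranked_clusters`, `ranked_sd`, `cmap`.
#' @export
analyze_screen <- function(run_dir, condition = NULL,
                           direction = c("on", "off"),
                           cfg = filter_config(),
                           layout = library_layout(), verbose = FALSE) {
  direction <- match.arg(direction)
  cmap <- read_cycle_map(file.path(run_dir, "cycle_map.yaml"))
  reads <- read_fastq(file.path(run_dir, "run.fastq"))
  table <- build_cluster_table(reads,
                               locs_dir = file.path(run_dir, "locs"),
                               cif_dir = file.path(run_dir, "cif"),
                               cycles = cmap$cycle, layout = layout,
                               channel = cfg$channel, verbose = verbose)
  summaries <- summarize_conditions(table, cmap, cfg)
  parts <- apply_filters(summaries, cfg)
  if (is.null(condition)) condition <- target_conditions(cmap)[1]
  ranked <- rank_clusters(parts$retained, condition, direction)
  list(table = table, summaries = summaries,
       retained = parts$retained, removed = parts$removed,
       ranked_clusters = ranked, ranked_sd = aggregate_unique_sd(ranked),
       cmap = cmap)
}
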