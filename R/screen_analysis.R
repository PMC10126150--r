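#' Map imaging cycles to conditions and replicates
#'
#' Each imaging cycle of the screen is taken under one condition -- buffer,
#' or the target at some concentration -- and the screen repeats each
#' condition several times. The cycle map records that assignment. At least
#' two replicates per condition are required so a replicate RSD can be
#' computed, and a `"buffer"` condition must be present as the ratio
#' denominator.
#'
#' @param cycle Integer vector of unique cycle indices.
#' @param condition Condition label per cycle; `"buffer"` or a target label
#'   such as `"ATP@500uM"` or `"glucose@10mM"`.
#' @param replicate Optional replicate index per cycle; defaults to 1, 2, ...
#'   within each condition in cycle order.
#' @return A `cycle_map` data.frame with columns `cycle`, `condition`,
#'   `replicate`.
#' @examples
#' cycle_map_alternating(c("buffer", "ATP@500uM"), n_each = 5)
#' @export
cycle_map <- function(cycle, condition, replicate = NULL) {
  cycle <- as.integer(cycle)
  condition <- as.character(condition)
  stopifnot(length(cycle) == length(condition))
  if (anyDuplicated(cycle))
    stop("cycle indices must be unique", call. = FALSE)
  if (!"buffer" %in% condition)
    stop("cycle map must contain a 'buffer' condition", call. = FALSE)
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(cycle)[order(cycle)], condition[order(cycle)],
                            FUN = seq_along)[order(order(cycle))]
  }
  counts <- table(condition)
  if (any(counts < 2L))
    stop("every condition needs at least 2 replicate cycles; got: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  out <- data.frame(cycle = cycle, condition = condition,
                    replicate = as.integer(replicate))
  class(out) <- c("cycle_map", "data.frame")
  out
}

#' @rdname cycle_map
#' @param conditions Condition labels to alternate, buffer first.
#' @param n_each Number of cycles per condition.
#' @export
cycle_map_alternating <- function(conditions, n_each) {
  cond <- rep(conditions, times = n_each)
  cycle_map(seq_along(cond), cond)
}

#' Read or write a cycle map as YAML
#'
#' The on-disk form is a YAML list of `{cycle, condition, replicate}`
#' entries.
#'
#' @param path Path to a YAML file.
#' @param cmap A [cycle_map()].
#' @name cycle_map_io
#' @export
read_cycle_map <- function(path) {
  y <- yaml::read_yaml(path)
  cycle_map(vapply(y, `[[`, numeric(1), "cycle"),
            vapply(y, `[[`, character(1), "condition"),
            vapply(y, `[[`, numeric(1), "replicate"))
}

#' @rdname cycle_map_io
#' @export
write_cycle_map <- function(cmap, path) {
  entries <- lapply(seq_len(nrow(cmap)), function(i)
    list(cycle = cmap$cycle[i], condition = cmap$condition[i],
         replicate = cmap$replicate[i]))
  yaml::write_yaml(entries, path)
  invisible(path)
}

target_conditions <- function(cmap) setdiff(unique(cmap$condition), "buffer")

#' Screen filter configuration
#'
#' Thresholds used to discard unreliable clusters before ranking: clusters
#' whose buffer-cycle mean intensity lies outside the `[rfu_min, rfu_max]`
#' window (dim clusters are noisy; very bright ones are typically image
#' artifacts or debris), and clusters whose replicate relative standard
#' deviation in any condition exceeds `rsd_max`.
#'
#' @param rfu_min,rfu_max Buffer-mean intensity window in RFU (defaults 100
#'   and 1000).
#' @param rsd_max Maximum replicate RSD, as a fraction (default 0.30).
#' @param channel Imaging channel carrying the switch signal, 0-based;
#'   recorded for provenance and used when the table is built from raw
#'   intensity files.
#' @return A `filter_config` object.
#' @export
filter_config <- function(rfu_min = 100, rfu_max = 1000, rsd_max = 0.30,
                          channel = 0L) {
  stopifnot(rfu_min >= 0, rfu_min < rfu_max, rsd_max > 0, rsd_max < 1,
            channel %in% 0:3)
  structure(list(rfu_min = rfu_min, rfu_max = rfu_max, rsd_max = rsd_max,
                 channel = as.integer(channel)), class = "filter_config")
}

#' Summarize cluster intensities per condition
#'
#' For every cluster, computes the mean intensity and the replicate RSD
#' (sample standard deviation over the condition's replicate cycles divided
#' by the mean) for each condition in the cycle map, and the intensity ratio
#' of every target condition relative to buffer.
#'
#' @param table A cluster table from [build_cluster_table()] or
#'   [read_cluster_table()].
#' @param cmap A [cycle_map()]; every cycle it references must exist as a
#'   `cyc<k>` column of `table`.
#' @param cfg A [filter_config()]; carried along so the thresholds and the
#'   signal channel the table was built from travel with the summaries.
#' @return A `cluster_summary` data.frame: the identifying columns of
#'   `table` plus `mean_<condition>` and `rsd_<condition>` for every
#'   condition and `ratio_<condition>` for every target condition, and a
#'   `status` column (initially `"retained"` for all rows). Target
#'   conditions are recorded in the `"targets"` attribute.
#' @export
summarize_conditions <- function(table, cmap, cfg = filter_config()) {
  stopifnot(inherits(cmap, "cycle_map"), inherits(cfg, "filter_config"))
  need <- paste0("cyc", cmap$cycle)
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("cluster table lacks cycle columns referenced by the cycle map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- table[, intersect(c("sd_sequence", "tile", "x", "y"), names(table)),
               drop = FALSE]
  conds <- unique(cmap$condition)
  for (cond in conds) {
    cols <- paste0("cyc", cmap$cycle[cmap$condition == cond])
    m <- as.matrix(table[, cols, drop = FALSE])
    mu <- rowMeans(m)
    sdv <- apply(m, 1L, stats::sd)
    out[[paste0("mean_", cond)]] <- mu
    out[[paste0("rsd_", cond)]] <- ifelse(mu == 0, NA_real_, sdv / mu)
  }
  for (cond in target_conditions(cmap))
    out[[paste0("ratio_", cond)]] <-
      out[[paste0("mean_", cond)]] / out[["mean_buffer"]]
  out$status <- "retained"
  attr(out, "targets") <- target_conditions(cmap)
  class(out) <- c("cluster_summary", "data.frame")
  out
}

#' Partition cluster summaries into retained and removed
#'
#' A cluster is removed when its buffer mean lies below `rfu_min` or above
#' `rfu_max`, or when its replicate RSD in buffer or in any target condition
#' exceeds `rsd_max`. Each removed cluster is annotated with the first
#' triggered reason, checked in the order `low_rfu`, `high_rfu`,
#' `buffer_rsd`, `target_rsd`; the check order affects only the recorded
#' reason, never membership.
#'
#' @param summaries A `cluster_summary` from [summarize_conditions()].
#' @param cfg A [filter_config()].
#' @return A list with components `retained` and `removed` (both
#'   `cluster_summary` data.frames; `removed$status` is
#'   `"removed:<reason>"`). The two parts partition the input.
#' @export
apply_filters <- function(summaries, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  targets <- attr(summaries, "targets")
  mu_b <- summaries$mean_buffer
  rsd_b <- summaries$rsd_buffer
  low <- mu_b < cfg$rfu_min
  high <- mu_b > cfg$rfu_max
  brsd <- !is.na(rsd_b) & rsd_b > cfg$rsd_max
  trsd <- rep(FALSE, nrow(summaries))
  for (cond in targets) {
    r <- summaries[[paste0("rsd_", cond)]]
    trsd <- trsd | (!is.na(r) & r > cfg$rsd_max)
  }
  reason <- rep(NA_character_, nrow(summaries))
  reason[trsd] <- "target_rsd"
  reason[brsd] <- "buffer_rsd"
  reason[high] <- "high_rfu"
  reason[low] <- "low_rfu"   # assigned last so it wins as first-checked reason
  removed_idx <- !is.na(reason)
  retained <- summaries[!removed_idx, , drop = FALSE]
  removed <- summaries[removed_idx, , drop = FALSE]
  if (nrow(removed))
    removed$status <- paste0("removed:", reason[removed_idx])
  rownames(retained) <- rownames(removed) <- NULL
  attr(retained, "targets") <- attr(removed, "targets") <- targets
  class(retained) <- class(removed) <- c("cluster_summary", "data.frame")
  list(retained = retained, removed = removed)
}

#' Rank clusters by target/buffer intensity ratio
#'
#' Signal-on screens rank by descending ratio (largest fluorescence increase
#' first); signal-off screens by ascending ratio. Ties are broken by higher
#' buffer mean (better-measured cluster first), then lexicographically by SD
#' sequence, making the ordering total and the output deterministic.
#'
#' @param retained Retained `cluster_summary` rows from [apply_filters()].
#' @param condition Target condition label to rank on.
#' @param direction `"on"` (fluorescence increases with target) or `"off"`.
#' @return A data.frame `sd_sequence`, `ratio`, `buffer_mean`, `rank`,
#'   ordered by rank, with `condition`/`direction` attributes.
#' @export
rank_clusters <- function(retained, condition, direction = c("on", "off")) {
  direction <- match.arg(direction)
  col <- paste0("ratio_", condition)
  if (!col %in% names(retained))
    stop("unknown target condition '", condition, "'", call. = FALSE)
  ratio <- retained[[col]]
  key <- if (direction == "on") -ratio else ratio
  ord <- order(key, -retained$mean_buffer, retained$sd_sequence)
  out <- data.frame(sd_sequence = retained$sd_sequence[ord],
                    ratio = ratio[ord],
                    buffer_mean = retained$mean_buffer[ord])
  out$rank <- seq_len(nrow(out))
  attr(out, "condition") <- condition
  attr(out, "direction") <- direction
  out
}

#' Collapse a cluster-level ranking to unique switching domains
#'
#' Clusters sharing an SD sequence collapse to one entry whose aggregate
#' ratio is the median of the cluster ratios (robust to stray clusters), with
#' the number of supporting clusters recorded; entries are then re-ranked
#' under the same ordering rule as [rank_clusters()], using the median buffer
#' mean for the tie-break.
#'
#' @param ranked Cluster-level ranking from [rank_clusters()].
#' @return A data.frame `sd_sequence`, `ratio`, `buffer_mean`, `n_clusters`,
#'   `rank`.
#' @export
aggregate_unique_sd <- function(ranked) {
  direction <- attr(ranked, "direction")
  if (is.null(direction))
    stop("input must come from rank_clusters()", call. = FALSE)
  agg_ratio <- tapply(ranked$ratio, ranked$sd_sequence, stats::median)
  agg_buf <- tapply(ranked$buffer_mean, ranked$sd_sequence, stats::median)
  n_cl <- tapply(ranked$ratio, ranked$sd_sequence, length)
  out <- data.frame(sd_sequence = names(agg_ratio),
                    ratio = as.numeric(agg_ratio),
                    buffer_mean = as.numeric(agg_buf),
                    n_clusters = as.integer(n_cl))
  key <- if (direction == "on") -out$ratio else out$ratio
  ord <- order(key, -out$buffer_mean, out$sd_sequence)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "condition") <- attr(ranked, "condition")
  attr(out, "direction") <- direction
  out
}

#' Count clusters passing a fold-change threshold
#'
#' Signal-on: clusters whose target/buffer ratio is at least `threshold`.
#' Signal-off: clusters whose ratio is at most `1/threshold`.
#'
#' @param retained Retained `cluster_summary` rows.
#' @param condition Target condition label.
#' @param threshold Fold change, `>= 1`.
#' @param direction `"on"` or `"off"`.
#' @return Integer count.
#' @export
count_by_fold_change <- function(retained, condition, threshold,
                                 direction = c("on", "off")) {
  direction <- match.arg(direction)
  if (!is.numeric(threshold) || threshold < 1)
    stop("fold-change threshold must be >= 1", call. = FALSE)
  col <- paste0("ratio_", condition)
  if (!col %in% names(retained))
    stop("unknown target condition '", condition, "'", call. = FALSE)
  ratio <- retained[[col]]
  if (direction == "on") sum(ratio >= threshold) else sum(ratio <= 1 / threshold)
}

#' Export top-ranked switching domains as FASTA
#'
#' Writes the top `n` SD sequences in rank order, with headers of the form
#' `sd_rank<k>|ratio=<r>|n_clusters=<c>` so the ranking metadata survives the
#' round trip into motif-discovery tools (e.g. MEME input).
#'
#' @param ranked An SD-level ranking from [aggregate_unique_sd()] (or a
#'   cluster-level one; `n_clusters` then defaults to 1).
#' @param n How many top entries to export; must not exceed the list length.
#' @param path Output path; if `NULL`, the FASTA text is returned only.
#' @return Invisibly, the FASTA lines.
#' @export
export_fasta <- function(ranked, n = nrow(ranked), path = NULL) {
  if (n > nrow(ranked))
    stop("requested top ", n, " of only ", nrow(ranked), " entries",
         call. = FALSE)
  top <- ranked[seq_len(n), , drop = FALSE]
  n_cl <- if ("n_clusters" %in% names(top)) top$n_clusters else rep(1L, n)
  headers <- sprintf(">sd_rank%d|ratio=%.6g|n_clusters=%d",
                     top$rank, top$ratio, n_cl)
  lines <- as.vector(rbind(headers, top$sd_sequence))
  if (length(lines) == 0L) lines <- character(0)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Parse rank/ratio metadata back out of exported FASTA headers
#'
#' @param lines FASTA lines as written by [export_fasta()].
#' @return A data.frame `rank`, `ratio`, `n_clusters`, `sd_sequence`.
#' @export
parse_fasta_ranked <- function(lines) {
  hdr <- grep("^>", lines)
  data.frame(
    rank = as.integer(sub("^>sd_rank([0-9]+)\\|.*$", "\\1", lines[hdr])),
    ratio = as.numeric(sub("^.*\\|ratio=([^|]+)\\|.*$", "\\1", lines[hdr])),
    n_clusters = as.integer(sub("^.*\\|n_clusters=([0-9]+)$", "\\1", lines[hdr])),
    sd_sequence = lines[hdr + 1L])
}
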