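#' Convert a locs-space coordinate to FASTQ space
#'
#' FASTQ read names carry cluster positions as integers, while the locs files
#' store the same positions as floats. The instrument convention maps a locs
#' coordinate `c` to the integer `round(10 * c + 1000)`. Rounding here is
#' half-up; because the original software's rounding mode at exact `.5`
#' boundaries is not knowable from the data, linking never relies on this
#' choice alone -- [coord_candidates()] tries the floor and ceiling as well.
#'
#' @param c Numeric vector of locs-space coordinates (finite, non-negative).
#' @return Integer vector of FASTQ-space coordinates.
#' @examples
#' locs_to_fastq_coord(c(0, 1234.56))
#' @export
locs_to_fastq_coord <- function(c) {
  check_locs_coord(c)
  v <- round(10 * c + 1000, 6)  # clear float residue before the .5 test
  as.integer(floor(v + 0.5))
}

check_locs_coord <- function(c) {
  if (!is.numeric(c) || any(!is.finite(c)) || any(c < 0))
    stop("locs-space coordinates must be finite and non-negative",
         call. = FALSE)
  invisible(c)
}

#' Candidate FASTQ-space coordinates for a locs-space coordinate
#'
#' The FASTQ coordinates written by the instrument and the transform of the
#' float32 locs values can disagree by one unit at rounding boundaries (for
#' example 12345.6 reported as 12345). Matching therefore considers the
#' floor, the ceiling and the half-up rounding of `10 * c + 1000`; the set
#' has one element when the transformed value is integral and two otherwise.
#'
#' @param c A single locs-space coordinate.
#' @return Sorted integer vector of candidate FASTQ-space coordinates.
#' @examples
#' coord_candidates(1234.55)  # 13345 and 13346
#' @export
coord_candidates <- function(c) {
  stopifnot(length(c) == 1L)
  check_locs_coord(c)
  v <- round(10 * c + 1000, 6)
  sort(unique(as.integer(c(floor(v), ceiling(v), floor(v + 0.5)))))
}

# Vectorized low/high candidate bounds used by link_tile(). For any locs
# coordinate the candidate set is {floor(v), ceiling(v)} (which also contains
# the half-up rounding), i.e. a contiguous 1- or 2-integer window.
coord_candidate_bounds <- function(c) {
  check_locs_coord(c)
  v <- round(10 * c + 1000, 6)
  list(lo = as.integer(floor(v)), hi = as.integer(ceiling(v)))
}

#' Switching-domain position within the read
#'
#' Describes where the randomized switching domain (SD) sits in each read.
#' The default layout -- offset 0, length 10 -- corresponds to reads that
#' cover the N10 switching domain directly.
#'
#' @param sd_offset 0-based position of the SD within the read.
#' @param sd_length SD length in nucleotides.
#' @return A `library_layout` object.
#' @export
library_layout <- function(sd_offset = 0L, sd_length = 10L) {
  sd_offset <- as.integer(sd_offset)
  sd_length <- as.integer(sd_length)
  stopifnot(sd_offset >= 0L, sd_length >= 1L)
  structure(list(sd_offset = sd_offset, sd_length = sd_length),
            class = "library_layout")
}

#' Extract the switching domain from a read sequence
#'
#' @param sequence Character vector of read sequences.
#' @param layout A [library_layout()].
#' @return Uppercase SD sequences.
#' @export
extract_sd <- function(sequence, layout = library_layout()) {
  end <- layout$sd_offset + layout$sd_length
  if (any(nchar(sequence) < end))
    stop("read too short for SD layout: need at least ", end,
         " nt, shortest read has ", min(nchar(sequence)), call. = FALSE)
  toupper(substr(sequence, layout$sd_offset + 1L, end))
}

#' Link one tile's reads to its cluster indices
#'
#' Matches FASTQ reads (genotype) to locs/intensity cluster indices
#' (phenotype) for a single tile. A read links to cluster `i` when its
#' integer x coordinate falls in [coord_candidates()] of the cluster's locs
#' x, and likewise for y. Matches must be one-to-one: reads whose coordinates
#' hit no cluster are counted `unmatched`; reads or clusters involved in
#' multiple cross-matches are counted `ambiguous` and dropped rather than
#' resolved, which is conservative for downstream hit calling.
#'
#' @param reads Read records for one tile (a data.frame from [read_fastq()],
#'   already restricted to the tile).
#' @param locs A `tile_locations` object for the same tile.
#' @return A `link_result`: list with `linked` (the read records plus a
#'   `cluster_index` column, 1-based), and counts `unmatched` and
#'   `ambiguous`. `nrow(linked) + unmatched + ambiguous == nrow(reads)`.
#' @export
link_tile <- function(reads, locs) {
  stopifnot(inherits(locs, "tile_locations"))
  if (nrow(reads) && !is.null(locs$tile) && !is.na(locs$tile) &&
      any(reads$tile != locs$tile))
    stop("tile mismatch: reads carry tile ",
         paste(unique(reads$tile), collapse = ","),
         " but locs are for tile ", locs$tile, call. = FALSE)
  n_clusters <- nrow(locs$coords)
  empty <- reads[0, , drop = FALSE]
  empty$cluster_index <- integer(0)
  if (nrow(reads) == 0L)
    return(structure(list(tile = locs$tile, linked = empty,
                          unmatched = 0L, ambiguous = 0L),
                     class = "link_result"))
  if (n_clusters == 0L)
    return(structure(list(tile = locs$tile, linked = empty,
                          unmatched = nrow(reads), ambiguous = 0L),
                     class = "link_result"))

  bx <- coord_candidate_bounds(locs$coords[, "x"])
  by <- coord_candidate_bounds(locs$coords[, "y"])
  # Candidate (x, y) keys per cluster: the cross product of the 1- or
  # 2-integer windows, at most 4 keys. Encode as x * 2^16 + y (exact in
  # doubles for flow-cell-sized coordinates).
  enc <- function(x, y) x * 65536 + y
  keys <- c(enc(bx$lo, by$lo), enc(bx$lo, by$hi),
            enc(bx$hi, by$lo), enc(bx$hi, by$hi))
  key_cluster <- rep.int(seq_len(n_clusters), 4L)
  dup <- duplicated(paste0(key_cluster, "_", keys))  # collapse within-cluster repeats
  keys <- keys[!dup]
  key_cluster <- key_cluster[!dup]
  # A key claimed by more than one distinct cluster cannot be matched
  # unambiguously; within-cluster repeats were collapsed above, so any
  # duplicated key value now implies two different clusters.
  ambig_keys <- unique(keys[duplicated(keys)])

  read_key <- enc(reads$x, reads$y)
  hit <- match(read_key, keys)
  matched <- !is.na(hit)
  read_cluster <- ifelse(matched, key_cluster[hit], NA_integer_)
  read_ambig <- matched & (read_key %in% ambig_keys)
  # clusters hit by more than one read are also ambiguous
  ok <- matched & !read_ambig
  dup_cluster <- unique(read_cluster[ok][duplicated(read_cluster[ok])])
  read_ambig <- read_ambig | (ok & read_cluster %in% dup_cluster)
  linked_rows <- matched & !read_ambig

  linked <- reads[linked_rows, , drop = FALSE]
  linked$cluster_index <- as.integer(read_cluster[linked_rows])
  rownames(linked) <- NULL
  structure(list(tile = locs$tile, linked = linked,
                 unmatched = sum(!matched), ambiguous = sum(read_ambig)),
            class = "link_result")
}

#' @export
print.link_result <- function(x, ...) {
  cat("link_result: tile", x$tile, "-", nrow(x$linked), "linked,",
      x$unmatched, "unmatched,", x$ambiguous, "ambiguous\n")
  invisible(x)
}

#' Link a whole run and build the cluster table
#'
#' Iterates over tiles, links each tile's reads to its cluster indices with
#' [link_tile()], extracts the switching domain from each linked read, pulls
#' the selected channel's intensity for every requested cycle, and assembles
#' the per-cluster table used by the screen analysis.
#'
#' @param reads All read records of the run (from [read_fastq()]); they are
#'   split by tile internally.
#' @param locs_dir Directory containing `s_1_<tile>.locs` files.
#' @param cif_dir Directory containing `s_1_<tile>_C<cycle>.cif` files.
#' @param cycles Integer vector of cycle numbers to extract.
#' @param layout A [library_layout()] giving the SD position in the read.
#' @param channel Imaging channel carrying the switch signal, 0-based (0-3).
#' @param verbose Log per-tile linked/unmatched/ambiguous counts.
#' @return A cluster-table data.frame (`sd_sequence`, `tile`, `x`, `y`,
#'   `cyc<k>` per requested cycle) with attributes `unmatched` and
#'   `ambiguous` holding run totals.
#' @export
build_cluster_table <- function(reads, locs_dir, cif_dir, cycles,
                                layout = library_layout(), channel = 0L,
                                verbose = FALSE) {
  stopifnot(channel %in% 0:3)
  tiles <- sort(unique(reads$tile))
  pieces <- vector("list", length(tiles))
  unmatched <- ambiguous <- 0L
  for (k in seq_along(tiles)) {
    tl <- tiles[k]
    locs <- read_locs(file.path(locs_dir, sprintf("s_1_%d.locs", tl)), tile = tl)
    res <- link_tile(reads[reads$tile == tl, , drop = FALSE], locs)
    unmatched <- unmatched + res$unmatched
    ambiguous <- ambiguous + res$ambiguous
    if (verbose)
      message(sprintf("tile %d: %d linked, %d unmatched, %d ambiguous",
                      tl, nrow(res$linked), res$unmatched, res$ambiguous))
    if (nrow(res$linked) == 0L) next
    tab <- data.frame(sd_sequence = extract_sd(res$linked$sequence, layout),
                      tile = res$linked$tile,
                      x = res$linked$x, y = res$linked$y)
    for (cyc in cycles) {
      blk <- read_intensities(
        file.path(cif_dir, sprintf("s_1_%d_C%d.cif", tl, cyc)), tile = tl)
      if (nrow(blk$values) != nrow(locs$coords))
        stop("cluster index misalignment in tile ", tl, " cycle ", cyc, ": ",
             nrow(locs$coords), " locs positions vs ", nrow(blk$values),
             " intensity rows", call. = FALSE)
      tab[[paste0("cyc", cyc)]] <-
        blk$values[res$linked$cluster_index, channel + 1L]
    }
    pieces[[k]] <- tab
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(sd_sequence = character(), tile = integer(),
                      x = integer(), y = integer())
    for (cyc in cycles) out[[paste0("cyc", cyc)]] <- integer()
  }
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  attr(out, "ambiguous") <- ambiguous
  out
}
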