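#' Parse tile and coordinates from an Illumina-style read name
#'
#' Read names follow the colon-delimited convention
#' `instrument:run:flowcell:lane:tile:x:y`; the tile and the integer x/y
#' coordinates in the last three fields identify the cluster the read came
#' from and are the key used to link sequence to intensity data.
#'
#' @param read_id Character vector of read names (any leading `"@"` is
#'   stripped).
#' @return A data.frame with integer columns `tile`, `x`, `y`, one row per
#'   name.
#' @examples
#' parse_read_name("M00:1:FC:1:1101:13346:10234")
#' @export
parse_read_name <- function(read_id) {
  stopifnot(is.character(read_id))
  id <- sub("^@", "", read_id)
  id <- sub("[ /].*$", "", id)  # drop comment / pair suffix
  parts <- strsplit(id, ":", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields < 7)) {
    bad <- which(n_fields < 7)[1L]
    stop("malformed read name '", read_id[bad], "': expected at least 7 ",
         "colon-delimited fields, got ", n_fields[bad], call. = FALSE)
  }
  take_int <- function(k, what) {
    v <- vapply(parts, function(p) p[length(p) - k], character(1))
    out <- suppressWarnings(as.integer(v))
    if (anyNA(out)) {
      bad <- which(is.na(out))[1L]
      stop("malformed read name '", read_id[bad], "': ", what, " field '",
           v[bad], "' is not an integer", call. = FALSE)
    }
    out
  }
  data.frame(tile = take_int(2L, "tile"),
             x    = take_int(1L, "x"),
             y    = take_int(0L, "y"))
}

#' Compose an Illumina-style read name from tile and coordinates
#'
#' Inverse of [parse_read_name()] for a fixed instrument/run/flowcell/lane
#' prefix.
#'
#' @param tile,x,y Integer vectors (recycled to common length).
#' @param prefix Four leading fields, joined by `":"`.
#' @return Character vector of read names.
#' @export
make_read_name <- function(tile, x, y, prefix = "SIM:1:FLOWCELL:1") {
  paste(prefix, tile, x, y, sep = ":")
}

# ---- locs ------------------------------------------------------------------

#' Read a binary cluster-position ("locs") file
#'
#' A locs file stores the sub-pixel x/y positions of every cluster in one
#' flow-cell tile. The layout is a 12-byte header (int32 constant, float32
#' version, uint32 cluster count) followed by little-endian float32 (x, y)
#' pairs in cluster-index order; the position in the list is the cluster
#' index shared with the intensity files of the same tile. Header constants
#' are checked for presence, not value, to tolerate dialect drift.
#'
#' @param path Path to a locs file, or a raw vector.
#' @param tile Tile number; if `NULL`, inferred from a filename of the form
#'   `s_<lane>_<tile>.locs`.
#' @return A `tile_locations` object: list with `tile` and `coords`, an
#'   `n x 2` numeric matrix with columns `x`, `y`.
#' @seealso [write_locs()]
#' @export
read_locs <- function(path, tile = NULL) {
  bytes <- if (is.raw(path)) path else readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 12L)
    stop("locs stream too short for the 12-byte header (", length(bytes),
         " bytes)", call. = FALSE)
  n <- readBin(bytes[9:12], "integer", n = 1L, size = 4L, endian = "little")
  payload <- bytes[-(1:12)]
  n_avail <- length(payload) %/% 8L
  if (n_avail < n)
    stop("truncated locs payload: header declares ", n, " clusters but only ",
         n_avail, " complete (x, y) pairs are present", call. = FALSE)
  vals <- readBin(payload, "numeric", n = 2L * n, size = 4L, endian = "little")
  coords <- matrix(vals, ncol = 2L, byrow = TRUE,
                   dimnames = list(NULL, c("x", "y")))
  if (is.null(tile) && !is.raw(path))
    tile <- tile_from_filename(path, "\\.locs$")
  structure(list(tile = tile, coords = coords), class = "tile_locations")
}

#' Write a binary cluster-position ("locs") file
#'
#' @param coords An `n x 2` numeric matrix of (x, y) positions, or a
#'   `tile_locations` object.
#' @param path Output path; if `NULL`, the raw bytes are returned.
#' @return Invisibly, the raw bytes written.
#' @export
write_locs <- function(coords, path = NULL) {
  if (inherits(coords, "tile_locations")) coords <- coords$coords
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L)
  if (any(!is.finite(coords)) || any(coords < 0))
    stop("locs coordinates must be finite and non-negative", call. = FALSE)
  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con))
  writeBin(1L, con, size = 4L, endian = "little")
  writeBin(1.0, con, size = 4L, endian = "little")
  writeBin(nrow(coords), con, size = 4L, endian = "little")
  if (nrow(coords))
    writeBin(as.numeric(t(coords)), con, size = 4L, endian = "little")
  bytes <- rawConnectionValue(con)
  if (!is.null(path)) writeBin(bytes, path)
  invisible(bytes)
}

tile_from_filename <- function(path, ext_re) {
  m <- regmatches(basename(path),
                  regexec(paste0("s_[0-9]+_([0-9]+).*", ext_re), basename(path)))[[1]]
  if (length(m) == 2L) as.integer(m[2]) else NA_integer_
}

# ---- intensities (CIF-like dialect) ----------------------------------------

#' Read a per-tile, per-cycle binary intensity file
#'
#' Cluster intensities are stored in a simplified CIF-like dialect: a header
#' of 3-byte magic `"CIF"`, a version byte, a bytes-per-value byte (always
#' 2), the first cycle number (uint16), the cycle count (uint16, always 1 in
#' files written by this package: one file per imaging cycle) and the cluster
#' count (uint32), followed by little-endian int16 values in channel-major
#' order: all clusters of channel 1, then channel 2, 3, 4. Values are
#' relative fluorescence units (RFU) as reported by the imaging software.
#'
#' @param path Path to an intensity file, or a raw vector.
#' @param tile Tile number; if `NULL`, inferred from a filename of the form
#'   `s_<lane>_<tile>_C<cycle>.cif`.
#' @return An `intensity_block` object: list with `tile`, `cycle` and
#'   `values`, an `n_clusters x 4` integer matrix (rows are cluster indices
#'   shared with the tile's locs file).
#' @seealso [write_intensities()]
#' @export
read_intensities <- function(path, tile = NULL) {
  bytes <- if (is.raw(path)) path else readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 13L)
    stop("intensity stream too short for the 13-byte header", call. = FALSE)
  if (rawToChar(bytes[1:3]) != "CIF")
    stop("bad magic in intensity file: expected 'CIF', got '",
         rawToChar(bytes[1:3]), "'", call. = FALSE)
  bpv <- as.integer(bytes[5])
  if (bpv != 2L)
    stop("unsupported intensity dialect: bytes-per-value = ", bpv,
         " (only 2-byte values are supported)", call. = FALSE)
  first_cycle <- readBin(bytes[6:7], "integer", size = 2L, signed = FALSE,
                         endian = "little")
  n_cycles <- readBin(bytes[8:9], "integer", size = 2L, signed = FALSE,
                      endian = "little")
  if (n_cycles != 1L)
    stop("unsupported intensity dialect: ", n_cycles, " cycles per file ",
         "(this dialect stores one cycle per file)", call. = FALSE)
  n <- readBin(bytes[10:13], "integer", size = 4L, endian = "little")
  payload <- bytes[-(1:13)]
  need <- 4L * n
  avail <- length(payload) %/% 2L
  if (avail < need)
    stop("truncated intensity payload: expected ", need, " int16 values, got ",
         avail, call. = FALSE)
  vals <- readBin(payload, "integer", n = need, size = 2L, signed = TRUE,
                  endian = "little")
  values <- matrix(vals, nrow = max(n, 0L), ncol = 4L)  # channel-major in file
  if (is.null(tile) && !is.raw(path))
    tile <- tile_from_filename(path, "_C[0-9]+\\.cif$")
  structure(list(tile = tile, cycle = first_cycle, values = values),
            class = "intensity_block")
}

#' Write a per-tile, per-cycle binary intensity file
#'
#' @param values An `n_clusters x 4` integer matrix of RFU values (int16
#'   range), or an `intensity_block`.
#' @param cycle Cycle number (uint16) stored in the header.
#' @param path Output path; if `NULL`, raw bytes are returned.
#' @return Invisibly, the raw bytes written.
#' @export
write_intensities <- function(values, cycle = 1L, path = NULL) {
  if (inherits(values, "intensity_block")) {
    cycle <- values$cycle
    values <- values$values
  }
  values <- as.matrix(values)
  if (length(values) && ncol(values) != 4L)
    stop("intensity matrix must have 4 channel columns", call. = FALSE)
  if (any(values < -32768 | values > 32767))
    stop("intensity values outside the int16 range", call. = FALSE)
  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con))
  writeBin(charToRaw("CIF"), con)
  writeBin(as.raw(c(1L, 2L)), con)                       # version, bytes-per-value
  writeBin(as.integer(cycle), con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")        # cycles in file
  writeBin(nrow(values), con, size = 4L, endian = "little")
  if (length(values))
    writeBin(as.integer(values), con, size = 2L, endian = "little")
  bytes <- rawConnectionValue(con)
  if (!is.null(path)) writeBin(bytes, path)
  invisible(bytes)
}

# ---- FASTQ -----------------------------------------------------------------

#' Read a coordinate-bearing FASTQ file
#'
#' Reads standard 4-line FASTQ records and parses tile and integer x/y
#' coordinates out of each read name with [parse_read_name()].
#'
#' @param path Path to an uncompressed or gzip-compressed FASTQ file, or a
#'   character vector of FASTQ lines.
#' @return A data.frame of read records with columns `read_id`, `tile`, `x`,
#'   `y`, `sequence`, `quality`, in file order.
#' @seealso [write_fastq()]
#' @export
read_fastq <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L)
    return(data.frame(read_id = character(), tile = integer(), x = integer(),
                      y = integer(), sequence = character(),
                      quality = character()))
  if (length(lines) %% 4L != 0L)
    stop("FASTQ stream length is not a multiple of 4 lines (", length(lines),
         " lines)", call. = FALSE)
  idx <- seq(1L, length(lines), by = 4L)
  headers <- lines[idx]
  if (any(substr(headers, 1L, 1L) != "@")) {
    bad <- which(substr(headers, 1L, 1L) != "@")[1L]
    stop("malformed FASTQ record at line ", idx[bad],
         ": header does not start with '@'", call. = FALSE)
  }
  seqs <- toupper(lines[idx + 1L])
  quals <- lines[idx + 3L]
  if (any(nchar(seqs) != nchar(quals))) {
    bad <- which(nchar(seqs) != nchar(quals))[1L]
    stop("malformed FASTQ record at line ", idx[bad], ": sequence length ",
         nchar(seqs[bad]), " != quality length ", nchar(quals[bad]),
         call. = FALSE)
  }
  if (any(grepl("[^ACGTN]", seqs))) {
    bad <- which(grepl("[^ACGTN]", seqs))[1L]
    stop("malformed FASTQ record at line ", idx[bad],
         ": sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  ids <- sub("^@", "", headers)
  cbind(data.frame(read_id = ids), parse_read_name(ids),
        data.frame(sequence = seqs, quality = quals))
}

#' Write read records as FASTQ
#'
#' @param reads A data.frame with columns `read_id`, `sequence`, `quality`
#'   (as returned by [read_fastq()]).
#' @param path Output path; if `NULL`, the FASTQ lines are returned.
#' @return Invisibly, the character vector of FASTQ lines.
#' @export
write_fastq <- function(reads, path = NULL) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stop("sequence/quality length mismatch", call. = FALSE)
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", reads$quality))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# ---- cluster table ---------------------------------------------------------

#' Read or write the linked cluster table
#'
#' The cluster table is the product of linking: one row per linked cluster
#' with its switching-domain sequence, tile, FASTQ-space coordinates, and one
#' selected-channel intensity column per imaging cycle (`cyc1`, `cyc2`, ...,
#' ordered by cycle index). It is stored as tab-separated text with a header.
#'
#' @param path Path to a TSV file.
#' @param table A cluster-table data.frame.
#' @return `read_cluster_table()` returns the data.frame;
#'   `write_cluster_table()` returns `path` invisibly.
#' @name cluster_table_io
#' @export
read_cluster_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = c(sd_sequence = "character"))
  need <- c("sd_sequence", "tile", "x", "y")
  if (!all(need %in% names(tab)))
    stop("cluster table is missing required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  tab
}

#' @rdname cluster_table_io
#' @export
write_cluster_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

cycle_columns <- function(table) {
  cols <- grep("^cyc[0-9]+$", names(table), value = TRUE)
  cols[order(as.integer(sub("^cyc", "", cols)))]
}
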