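#' Aptamer specification
#'
#' The parent aptamer sequence, written 5' to 3', optionally annotated with
#' the positions of chemically modified bases (e.g. boronic-acid-modified
#' uracils in base-modified aptamers). Modified bases are carried as
#' annotation only: complementarity and alignment treat them as their
#' canonical letter, because the sequenced switching strands are canonical
#' DNA regardless of the aptamer chemistry.
#'
#' @param name Short construct name.
#' @param sequence DNA string over `{A,C,G,T}`, 5' to 3'.
#' @param modified_positions Integer vector of 1-based modified positions.
#' @return An `aptamer_spec` object.
#' @export
aptamer_spec <- function(name, sequence, modified_positions = integer()) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence))
    stop("aptamer sequence must be over {A,C,G,T}", call. = FALSE)
  modified_positions <- as.integer(modified_positions)
  if (any(modified_positions < 1L | modified_positions > nchar(sequence)))
    stop("modified positions outside 1..", nchar(sequence), call. = FALSE)
  structure(list(name = name, sequence = sequence,
                 modified_positions = modified_positions),
            class = "aptamer_spec")
}

#' @export
print.aptamer_spec <- function(x, ...) {
  cat("aptamer_spec:", x$name, "(", nchar(x$sequence), "nt )\n ", x$sequence, "\n")
  if (length(x$modified_positions))
    cat("  modified positions:", paste(x$modified_positions, collapse = ", "), "\n")
  invisible(x)
}

#' Reverse complement of DNA sequences
#'
#' Watson-Crick complement, reversed; `N` maps to `N`.
#'
#' @param s Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(s) {
  s <- toupper(s)
  if (any(grepl("[^ACGTN]", s)))
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Longest complementary run between a switching domain and the aptamer
#'
#' Finds the longest contiguous stretch over which the SD can form a perfect
#' antiparallel Watson-Crick duplex with the aptamer, i.e. the longest common
#' substring of `reverse_complement(sd)` and the aptamer sequence. Runs
#' shorter than `min_run` nucleotides are discarded (too short to report a
#' meaningful duplex). Equal-length ties resolve to the 5'-most aptamer
#' position so the downstream histogram is deterministic.
#'
#' @param sd SD sequence (DNA over `{A,C,G,T,N}`; `N` never matches).
#' @param aptamer An [aptamer_spec()].
#' @param min_run Minimum run length to report (default 3).
#' @return A list `sd_sequence`, `aptamer_start`, `aptamer_end`, `length`
#'   (1-based inclusive aptamer coordinates), or `NULL` when the longest run
#'   is shorter than `min_run`.
#' @export
longest_complementary_run <- function(sd, aptamer, min_run = 3L) {
  stopifnot(inherits(aptamer, "aptamer_spec"), nchar(sd) > 0L)
  rc <- reverse_complement(sd)
  a <- strsplit(rc, "")[[1]]
  b <- strsplit(aptamer$sequence, "")[[1]]
  n <- length(a); m <- length(b)
  best_len <- 0L; best_start <- NA_integer_
  prev <- integer(m)
  for (i in seq_len(n)) {
    cur <- integer(m)
    hit <- a[i] == b & a[i] != "N"
    cur[hit] <- 1L
    if (m > 1L) {
      idx <- which(hit & seq_len(m) > 1L)
      cur[idx] <- prev[idx - 1L] + 1L
    }
    for (j in which(cur > 0L)) {
      len <- cur[j]
      start <- j - len + 1L
      if (len > best_len || (len == best_len && start < best_start)) {
        best_len <- len
        best_start <- start
      }
    }
    prev <- cur
  }
  if (best_len < min_run) return(NULL)
  list(sd_sequence = toupper(sd), aptamer_start = best_start,
       aptamer_end = best_start + best_len - 1L, length = best_len)
}

#' Per-position complementarity histogram over the aptamer
#'
#' For every SD whose longest complementary run passes `min_run`, increments
#' each aptamer position covered by that run; SDs with no qualifying run
#' contribute nothing. The result shows which regions of the aptamer the
#' top switching domains preferentially base-pair with.
#'
#' @param sds Character vector of SD sequences.
#' @param aptamer An [aptamer_spec()].
#' @param min_run Minimum run length (default 3).
#' @return Integer vector of counts, one per aptamer position, named by the
#'   aptamer base at that position.
#' @export
position_histogram <- function(sds, aptamer, min_run = 3L) {
  counts <- integer(nchar(aptamer$sequence))
  for (sd in sds) {
    hit <- longest_complementary_run(sd, aptamer, min_run)
    if (!is.null(hit))
      counts[hit$aptamer_start:hit$aptamer_end] <-
        counts[hit$aptamer_start:hit$aptamer_end] + 1L
  }
  names(counts) <- strsplit(aptamer$sequence, "")[[1]]
  counts
}

#' Smith-Waterman scoring parameters
#'
#' Defaults score a match `+1` with mismatch and gaps `-1`, so a score of
#' `k` against a 10-nt SD reads directly as "about `k` of the 10 bases
#' predicted to hybridize". A gap of length `k` costs
#' `gap_open + k * gap_extend` (affine; both components non-positive).
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (<= 0).
#' @param gap_open Gap opening score (<= 0).
#' @param gap_extend Per-base gap extension score (<= 0).
#' @return An `sw_params` object.
#' @export
sw_params <- function(match = 1, mismatch = -1, gap_open = -1,
                      gap_extend = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "sw_params")
}

#' Smith-Waterman local alignment score
#'
#' Standard local-alignment dynamic program (Gotoh affine-gap recurrences)
#' with an empty-alignment floor at zero; returns the maximum cell value.
#'
#' @param a,b DNA sequences over `{A,C,G,T,N}` (`N` scores as a mismatch).
#' @param p An [sw_params()].
#' @return The optimal local alignment score (numeric; an integer under the
#'   default unit scores).
#' @export
smith_waterman_score <- function(a, b, p = sw_params()) {
  a <- toupper(a); b <- toupper(b)
  if (grepl("[^ACGTN]", a) || grepl("[^ACGTN]", b))
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  neg <- -Inf
  best <- 0
  Hprev <- numeric(m + 1L)
  Fcol <- rep(neg, m + 1L)        # gap in a (vertical), per column
  for (i in seq_len(n)) {
    Hcur <- numeric(m + 1L)
    Ecur <- neg
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j] && av[i] != "N") p$match else p$mismatch
      Ecur <- max(Hcur[j] + p$gap_open + p$gap_extend, Ecur + p$gap_extend)
      Fcol[j + 1L] <- max(Hprev[j + 1L] + p$gap_open + p$gap_extend,
                          Fcol[j + 1L] + p$gap_extend)
      h <- max(0, Hprev[j] + s, Ecur, Fcol[j + 1L])
      Hcur[j + 1L] <- h
      if (h > best) best <- h
    }
    Hprev <- Hcur
  }
  best
}

#' Smith-Waterman similarity of an SD's reverse complement to the aptamer
#'
#' Aligns `reverse_complement(sd)` locally against the aptamer sequence:
#' under the default unit-match scoring the score approximates how many SD
#' bases would be predicted to hybridize with the aptamer by canonical
#' Watson-Crick pairing, and is bounded above by the SD length.
#'
#' @param sd SD sequence (or vector of SDs).
#' @param aptamer An [aptamer_spec()].
#' @param p An [sw_params()].
#' @return Numeric vector of scores, one per SD.
#' @export
sw_to_aptamer <- function(sd, aptamer, p = sw_params()) {
  stopifnot(inherits(aptamer, "aptamer_spec"))
  rc <- reverse_complement(sd)
  vapply(rc, smith_waterman_score, numeric(1), b = aptamer$sequence, p = p,
         USE.NAMES = FALSE)
}

#' Score-frequency table of SD similarity to the aptamer
#'
#' @param sds Character vector of SD sequences.
#' @param aptamer An [aptamer_spec()].
#' @param p An [sw_params()].
#' @return A data.frame `score`, `count` (one row per observed score, in
#'   increasing score order); counts sum to `length(sds)`.
#' @export
sw_histogram <- function(sds, aptamer, p = sw_params()) {
  if (length(sds) == 0L)
    return(data.frame(score = numeric(), count = integer()))
  scores <- sw_to_aptamer(sds, aptamer, p)
  tab <- table(scores)
  data.frame(score = as.numeric(names(tab)), count = as.integer(tab))
}

#' Per-SD complementarity and similarity report
#'
#' Convenience wrapper combining [longest_complementary_run()] and
#' [sw_to_aptamer()] over a set of switching domains.
#'
#' @param sds Character vector of SD sequences.
#' @param aptamer An [aptamer_spec()].
#' @param min_run Minimum complementary run length.
#' @param p An [sw_params()].
#' @return A data.frame with one row per SD: `sd_sequence`,
#'   `aptamer_start`, `aptamer_end`, `run_length` (NA when below `min_run`)
#'   and `sw_score`.
#' @export
sd_report <- function(sds, aptamer, min_run = 3L, p = sw_params()) {
  hits <- lapply(sds, longest_complementary_run, aptamer = aptamer,
                 min_run = min_run)
  data.frame(
    sd_sequence = toupper(sds),
    aptamer_start = vapply(hits, function(h) h$aptamer_start %||% NA_integer_,
                           integer(1)),
    aptamer_end = vapply(hits, function(h) h$aptamer_end %||% NA_integer_,
                         integer(1)),
    run_length = vapply(hits, function(h) h$length %||% NA_integer_,
                        integer(1)),
    sw_score = sw_to_aptamer(sds, aptamer, p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
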