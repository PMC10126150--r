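# Independent oracles, kept deliberately separate from the implementations
# they check.

# Top-down memoized three-state (match / gap-in-a / gap-in-b) local
# alignment recursion. Written independently of the package's iterative
# sweep; gap of length k costs gap_open + k * gap_extend, empty alignment
# scores 0.
oracle_sw <- function(a, b, match = 1, mismatch = -1, gap_open = -1,
                      gap_extend = -1) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av); m <- length(bv)
  # memo[state, i+1, j+1]; states: 1 = diag-ended (H without E/F), we store
  # the three canonical matrices explicitly instead.
  H <- matrix(NA_real_, n + 1, m + 1)
  E <- matrix(NA_real_, n + 1, m + 1)  # ends with gap consuming b
  FF <- matrix(NA_real_, n + 1, m + 1) # ends with gap consuming a
  e_val <- function(i, j) {
    if (j == 0) return(-Inf)
    if (!is.na(E[i + 1, j + 1])) return(E[i + 1, j + 1])
    v <- max(h_val(i, j - 1) + gap_open + gap_extend,
             e_val(i, j - 1) + gap_extend)
    E[i + 1, j + 1] <<- v
    v
  }
  f_val <- function(i, j) {
    if (i == 0) return(-Inf)
    if (!is.na(FF[i + 1, j + 1])) return(FF[i + 1, j + 1])
    v <- max(h_val(i - 1, j) + gap_open + gap_extend,
             f_val(i - 1, j) + gap_extend)
    FF[i + 1, j + 1] <<- v
    v
  }
  h_val <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (!is.na(H[i + 1, j + 1])) return(H[i + 1, j + 1])
    s <- if (av[i] == bv[j] && av[i] != "N") match else mismatch
    v <- max(0, h_val(i - 1, j - 1) + s, e_val(i, j), f_val(i, j))
    H[i + 1, j + 1] <<- v
    v
  }
  best <- 0
  for (i in 0:n) for (j in 0:m) best <- max(best, h_val(i, j))
  best
}

# Third-party aligner at identical parameters (Biostrings charges a length-k
# gap gapOpening + k * gapExtension, matching the package's convention).
biostrings_sw <- function(a, b, match = 1, mismatch = -1, gap_open = -1,
                          gap_extend = -1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  as.numeric(Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = -gap_open, gapExtension = -gap_extend)))
}

# Exhaustive substring-pair scan for the longest perfect antiparallel
# duplex: every substring of reverse_complement(sd) against every substring
# of the aptamer, longest match wins, ties to the 5'-most aptamer position.
oracle_lcr <- function(sd, aptamer_seq, min_run = 3) {
  rc <- rc_string(sd)
  n <- nchar(rc); m <- nchar(aptamer_seq)
  best_len <- 0; best_start <- NA
  for (len in n:1) {
    if (len < best_len) break
    if (len > m) next
    for (i in 1:(n - len + 1)) {
      sub <- substr(rc, i, i + len - 1)
      if (grepl("N", sub, fixed = TRUE)) next
      for (j in 1:(m - len + 1)) {
        if (substr(aptamer_seq, j, j + len - 1) == sub) {
          if (len > best_len || (len == best_len && j < best_start)) {
            best_len <- len
            best_start <- j
          }
        }
      }
    }
  }
  if (best_len < min_run) return(NULL)
  list(aptamer_start = best_start, aptamer_end = best_start + best_len - 1,
       length = best_len)
}

# Reverse complement by lookup, independent of the package's Biostrings path.
rc_string <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Small screen fixture used by several suites.
small_screen <- function(seed, n_tiles = 1L, clusters_per_tile = 400L,
                         planted = NULL, replicate_rsd = 0.10, ...) {
  cfg <- sim_config(n_tiles = n_tiles, clusters_per_tile = clusters_per_tile,
                    planted = planted, replicate_rsd = replicate_rsd,
                    seed = seed, ...)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  manifest <- generate_screen(cfg, dir)
  list(cfg = cfg, dir = dir, manifest = manifest)
}
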