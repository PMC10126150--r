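#' Configuration of a synthetic flow-cell screen
#'
#' Describes a complete synthetic screen: flow-cell geometry, the baseline
#' intensity distribution, replicate noise, deliberate out-of-window
#' outliers, the cycle schedule, and the planted responsive switching
#' domains. Defaults emulate the ATP-style signal-on screen design: ten
#' imaging cycles alternating buffer and target (five each), cluster
#' baselines log-normally distributed across the 100--1000 RFU working
#' window, 10% replicate RSD, and 5% dim / 1% bright outlier clusters.
#'
#' @param n_tiles Number of flow-cell tiles.
#' @param clusters_per_tile Clusters per tile.
#' @param sd_length Switching-domain length (nt).
#' @param planted Data.frame with columns `sd_sequence`, `condition`,
#'   `ratio`: each planted SD responds to `condition` with the given
#'   target/buffer intensity ratio (`> 1` signal-on, `< 1` signal-off).
#'   SDs must be unique and of length `sd_length`.
#' @param planted_copies Clusters carrying each planted SD. Responsive SDs
#'   recur across clusters on a real flow cell (which is why the analysis
#'   aggregates to unique SDs), and multiple copies make recovery metrics
#'   robust to the loss of individual clusters to the intensity filters.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline (buffer) cluster intensity in RFU.
#' @param replicate_rsd Relative standard deviation of the multiplicative
#'   replicate-cycle noise (fraction).
#' @param frac_dim,frac_bright Fractions of clusters planted as dim
#'   (below the RFU window) or bright (above it) outliers.
#' @param cmap Cycle schedule, a [cycle_map()].
#' @param seed Mandatory RNG seed; the full file set is reproducible per
#'   seed.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_tiles = 10L, clusters_per_tile = 5000L,
                       sd_length = 10L,
                       planted = NULL, planted_copies = 4L,
                       baseline_meanlog = log(300), baseline_sdlog = 0.35,
                       replicate_rsd = 0.10,
                       frac_dim = 0.05, frac_bright = 0.01,
                       cmap = cycle_map_alternating(c("buffer", "ATP@500uM"), 5L),
                       seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed", call. = FALSE)
  if (is.null(planted))
    planted <- data.frame(sd_sequence = character(), condition = character(),
                          ratio = numeric())
  stopifnot(all(c("sd_sequence", "condition", "ratio") %in% names(planted)))
  if (nrow(planted)) {
    if (any(planted$ratio <= 0)) stop("planted ratios must be > 0", call. = FALSE)
    if (anyDuplicated(planted$sd_sequence))
      stop("planted SDs must be unique", call. = FALSE)
    if (any(nchar(planted$sd_sequence) != sd_length))
      stop("planted SDs must have length sd_length = ", sd_length,
           call. = FALSE)
    if (!all(planted$condition %in% target_conditions(cmap)))
      stop("planted conditions must appear in the cycle map", call. = FALSE)
  }
  stopifnot(replicate_rsd >= 0, frac_dim >= 0, frac_bright >= 0,
            frac_dim + frac_bright < 1, planted_copies >= 1L)
  structure(list(n_tiles = as.integer(n_tiles),
                 clusters_per_tile = as.integer(clusters_per_tile),
                 sd_length = as.integer(sd_length), planted = planted,
                 planted_copies = as.integer(planted_copies),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 replicate_rsd = replicate_rsd,
                 frac_dim = frac_dim, frac_bright = frac_bright,
                 cmap = cmap, seed = as.integer(seed)),
            class = "sim_config")
}

#' Random switching-domain sequences
#'
#' Uniform draws over the N-mer space, optionally excluding a set (e.g. the
#' planted SDs, so null and responsive truth sets stay separable).
#'
#' @param n Number of sequences.
#' @param sd_length Sequence length.
#' @param exclude Character vector of sequences that must not be produced.
#' @return Character vector of length `n` (duplicates possible, as on a real
#'   flow cell).
#' @export
random_sds <- function(n, sd_length = 10L, exclude = character()) {
  draw <- function(k)
    apply(matrix(sample(c("A", "C", "G", "T"), k * sd_length, replace = TRUE),
                 nrow = k), 1L, paste, collapse = "")
  out <- draw(n)
  bad <- out %in% exclude
  while (any(bad)) {
    out[bad] <- draw(sum(bad))
    bad <- out %in% exclude
  }
  out
}

# Round doubles through IEEE float32, as the locs files store them.
as_float32 <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "numeric", n = length(x), size = 4L, endian = "little")
}

lognormal_noise <- function(n, rsd) {
  if (rsd <= 0) return(rep(1, n))
  s <- sqrt(log(1 + rsd^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)  # unit mean, given RSD
}

#' Generate a complete synthetic screen
#'
#' Writes the full file set of a synthetic flow-cell screen -- a
#' coordinate-bearing FASTQ, per-tile locs files, per-tile per-cycle
#' intensity files, a cycle-map YAML and a truth manifest TSV -- and returns
#' the manifest.
#'
#' Per cluster `i`, a baseline `b_i` is drawn log-normally (or from the dim
#' or bright outlier ranges), and the intensity in cycle `c` under condition
#' `k` is `b_i * r_ik * eps`, where `r_ik` is the planted ratio (1 for
#' buffer cycles and null SDs) and `eps` is multiplicative log-normal noise
#' with the configured replicate RSD, rounded and clipped to the int16
#' range. The switch signal is placed in imaging channel 0; the other three
#' channels carry low background. Cluster positions sit on a jittered grid
#' (minimum separation 1.2 locs units, comfortably above the one-FASTQ-unit
#' matching window), are stored as float32, and the FASTQ coordinates are
#' the exact forward transform of the stored float32 values, so linking the
#' generated FASTQ against the generated locs recovers every cluster.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param coord_jitter Half-width of uniform locs-space jitter added to the
#'   *written* locs coordinates only (the FASTQ names keep the unjittered
#'   transform), emulating rounding drift between the instrument's FASTQ
#'   and locs outputs. Values below 0.049 are absorbed by the floor/ceiling
#'   candidate sets during linking.
#' @return The truth manifest data.frame (one row per cluster: `tile`,
#'   `cluster_index`, locs and FASTQ coordinates, `sd_sequence`,
#'   `outlier_class`, and one `ratio_<condition>` column per target
#'   condition, 1.0 for nulls), returned invisibly and written to
#'   `<outdir>/truth.tsv`.
#' @export
generate_screen <- function(cfg, outdir, coord_jitter = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  dir.create(file.path(outdir, "locs"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "cif"), recursive = TRUE, showWarnings = FALSE)

  n_total <- cfg$n_tiles * cfg$clusters_per_tile
  n_planted_cl <- nrow(cfg$planted) * cfg$planted_copies
  if (n_planted_cl > n_total)
    stop("more planted cluster copies than clusters", call. = FALSE)

  # Cluster-level SD assignment: planted SDs at random slots, nulls elsewhere.
  sd_seq <- random_sds(n_total, cfg$sd_length,
                       exclude = cfg$planted$sd_sequence)
  planted_row <- rep(NA_integer_, n_total)
  if (n_planted_cl) {
    slots <- sample.int(n_total, n_planted_cl)
    rows <- rep(seq_len(nrow(cfg$planted)), each = cfg$planted_copies)
    sd_seq[slots] <- cfg$planted$sd_sequence[rows]
    planted_row[slots] <- rows
  }

  # Baseline intensity class per cluster.
  cls <- sample(c("dim", "bright", "normal"), n_total, replace = TRUE,
                prob = c(cfg$frac_dim, cfg$frac_bright,
                         1 - cfg$frac_dim - cfg$frac_bright))
  baseline <- stats::rlnorm(n_total, cfg$baseline_meanlog, cfg$baseline_sdlog)
  baseline[cls == "dim"] <- stats::runif(sum(cls == "dim"), 20, 80)
  baseline[cls == "bright"] <- stats::runif(sum(cls == "bright"), 1500, 20000)

  targets <- target_conditions(cfg$cmap)
  ratio_mat <- matrix(1, n_total, length(targets),
                      dimnames = list(NULL, targets))
  if (n_planted_cl) {
    pl <- !is.na(planted_row)
    for (k in seq_along(targets)) {
      sel <- pl & cfg$planted$condition[planted_row] == targets[k]
      ratio_mat[sel, k] <- cfg$planted$ratio[planted_row[sel]]
    }
  }

  tile_ids <- 1100L + seq_len(cfg$n_tiles)
  tile_of <- rep(tile_ids, each = cfg$clusters_per_tile)
  fastq_lines <- vector("list", cfg$n_tiles)
  manifest <- vector("list", cfg$n_tiles)

  for (t in seq_len(cfg$n_tiles)) {
    idx <- which(tile_of == tile_ids[t])
    n <- length(idx)
    side <- ceiling(sqrt(n))
    gx <- (seq_len(n) - 1L) %% side
    gy <- (seq_len(n) - 1L) %/% side
    x <- as_float32(gx * 2 + 1 + stats::runif(n, -0.4, 0.4))
    y <- as_float32(gy * 2 + 1 + stats::runif(n, -0.4, 0.4))
    fx <- locs_to_fastq_coord(x)
    fy <- locs_to_fastq_coord(y)
    wx <- x; wy <- y
    if (coord_jitter > 0) {
      wx <- as_float32(pmax(x + stats::runif(n, -coord_jitter, coord_jitter), 0))
      wy <- as_float32(pmax(y + stats::runif(n, -coord_jitter, coord_jitter), 0))
    }
    write_locs(cbind(wx, wy),
               file.path(outdir, "locs", sprintf("s_1_%d.locs", tile_ids[t])))

    for (ci in seq_len(nrow(cfg$cmap))) {
      cyc <- cfg$cmap$cycle[ci]
      cond <- cfg$cmap$condition[ci]
      r <- if (cond == "buffer") rep(1, n) else ratio_mat[idx, cond]
      signal <- baseline[idx] * r * lognormal_noise(n, cfg$replicate_rsd)
      vals <- cbind(pmin(pmax(round(signal), 0), 32767),
                    matrix(round(stats::runif(3L * n, 0, 100)), n, 3L))
      write_intensities(vals, cycle = cyc,
                        path = file.path(outdir, "cif",
                                         sprintf("s_1_%d_C%d.cif",
                                                 tile_ids[t], cyc)))
    }

    ids <- make_read_name(tile_ids[t], fx, fy)
    fastq_lines[[t]] <- as.vector(rbind(
      paste0("@", ids), sd_seq[idx], "+",
      strrep("I", nchar(sd_seq[idx]))))
    man <- data.frame(tile = tile_ids[t], cluster_index = seq_len(n),
                      x_locs = x, y_locs = y, x_fastq = fx, y_fastq = fy,
                      sd_sequence = sd_seq[idx], outlier_class = cls[idx])
    for (k in seq_along(targets))
      man[[paste0("ratio_", targets[k])]] <- ratio_mat[idx, k]
    manifest[[t]] <- man
  }

  writeLines(unlist(fastq_lines), file.path(outdir, "run.fastq"))
  write_cycle_map(cfg$cmap, file.path(outdir, "cycle_map.yaml"))
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Simulate a plate-reader titration
#'
#' Replicate fluorescence values drawn from the one-site or two-site signal
#' model with multiplicative log-normal noise of the given RSD.
#'
#' @param model `"one_site"` or `"two_site"`.
#' @param params Named list of model parameters: `KD_eff` (one-site) or
#'   `K1`, `K2` (two-site), plus `Bmax` and `y0`.
#' @param concentrations Target concentrations.
#' @param noise_rsd Multiplicative noise RSD (fraction).
#' @param n_rep Number of replicates.
#' @param seed Optional RNG seed.
#' @param unit,construct_name Passed to [binding_dataset()].
#' @return A [binding_dataset()].
#' @export
simulate_titration <- function(model = c("one_site", "two_site"), params,
                               concentrations, noise_rsd = 0.02, n_rep = 3L,
                               seed = NULL, unit = "uM",
                               construct_name = "simulated") {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  mu <- if (model == "one_site")
    signal_one_site(concentrations, params$KD_eff, params$Bmax, params$y0)
  else
    signal_two_site(concentrations, params$K1, params$K2, params$Bmax,
                    params$y0)
  reps <- matrix(rep(mu, n_rep) *
                   lognormal_noise(length(mu) * n_rep, noise_rsd),
                 ncol = n_rep)
  binding_dataset(concentrations, reps, unit, construct_name)
}

#' Simulate a target spike-in time course
#'
#' Mono-exponential relaxation sampled at the plate reader's interval, with
#' multiplicative noise; signal is flat at `S0` before the spike.
#'
#' @param k_obs Observed rate (1/s).
#' @param S0,S_inf Pre-spike and equilibrium signal (RFU).
#' @param spike_time Spike time (s).
#' @param interval Sampling interval (s); 0.46 s emulates a fast kinetic
#'   read.
#' @param duration Total duration (s).
#' @param noise_rsd Multiplicative noise RSD.
#' @param seed Optional RNG seed.
#' @return A [time_course()].
#' @export
simulate_time_course <- function(k_obs, S0, S_inf, spike_time = 5,
                                 interval = 0.46, duration = 60,
                                 noise_rsd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, duration, by = interval)
  mu <- ifelse(times < spike_time, S0,
               S_inf + (S0 - S_inf) * exp(-k_obs * (times - spike_time)))
  time_course(times, mu * lognormal_noise(length(mu), noise_rsd), spike_time)
}

#' Precision and recall of planted switches in a ranking
#'
#' @param ranked An SD-level ranking from [aggregate_unique_sd()].
#' @param planted_sds Character vector of planted (truly responsive) SD
#'   sequences.
#' @param n Depth of the top list to evaluate (`<= nrow(ranked)`).
#' @return A list `precision` (planted in top-n divided by `n`) and
#'   `recall` (planted in top-n divided by number planted; `NA` when
#'   nothing was planted).
#' @export
evaluate_recovery <- function(ranked, planted_sds, n) {
  stopifnot(n <= nrow(ranked))
  top <- ranked$sd_sequence[seq_len(n)]
  hit <- sum(top %in% planted_sds)
  list(precision = hit / n,
       recall = if (length(planted_sds)) hit / length(planted_sds)
                else NA_real_)
}
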