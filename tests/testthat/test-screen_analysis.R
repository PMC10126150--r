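make_table <- function(rows) {
  # rows: list of named lists with sd, buffer and target cycle intensities
  do.call(rbind, lapply(rows, function(r) {
    out <- data.frame(sd_sequence = r$sd, tile = 1101L, x = 1L, y = 1L)
    vals <- c(r$buffer, r$target, r$target2)
    for (k in seq_along(vals)) out[[paste0("cyc", k)]] <- vals[k]
    out
  }))
}

atp_map <- function() cycle_map(1:10, rep(c("buffer", "ATP@500uM"), each = 5))

test_that("cycle maps enforce replicate structure", {
  cm <- cycle_map_alternating(c("buffer", "ATP@500uM"), 5L)
  expect_equal(nrow(cm), 10L)
  expect_equal(cm$condition[1:4], rep(c("buffer", "ATP@500uM"), 2))
  expect_equal(max(cm$replicate), 5L)
  expect_error(cycle_map(c(1, 1), c("buffer", "buffer")), "unique")
  expect_error(cycle_map(1:2, c("ATP", "ATP")), "buffer")
  expect_error(cycle_map(1:3, c("buffer", "buffer", "ATP")), "at least 2")
})

test_that("cycle maps round-trip through YAML", {
  cm <- cycle_map(1:12, rep(c("buffer", "glucose@10mM", "glucose@100mM"), 4))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cycle_map(cm, path)
  expect_equal(read_cycle_map(path), cm)
})

test_that("condition summaries compute means, RSDs and ratios", {
  tab <- make_table(list(list(sd = "AAAAAAAAAA",
                              buffer = rep(200, 5), target = rep(400, 5))))
  s <- summarize_conditions(tab, atp_map())
  expect_equal(s$mean_buffer, 200)
  expect_equal(s$rsd_buffer, 0)
  expect_equal(s[["ratio_ATP@500uM"]], 2.0)

  # spreadsheet oracle: mean 120, sample sd sqrt(250), RSD 0.1318
  tab2 <- make_table(list(list(sd = "AAAAAAAAAA",
                               buffer = c(100, 120, 110, 130, 140),
                               target = rep(240, 5))))
  s2 <- summarize_conditions(tab2, atp_map())
  expect_equal(s2$mean_buffer, 120)
  expect_equal(s2$rsd_buffer, sqrt(250) / 120)
  expect_equal(round(s2$rsd_buffer, 4), 0.1318)

  # two target conditions produce two ratio columns
  glu_map <- cycle_map(1:12, rep(c("buffer", "glucose@10mM", "glucose@100mM"),
                                 each = 4))
  tab3 <- data.frame(sd_sequence = "AAAAAAAAAA", tile = 1L, x = 1L, y = 1L)
  for (k in 1:12) tab3[[paste0("cyc", k)]] <- c(rep(200, 4), rep(100, 4),
                                                rep(50, 4))[k]
  s3 <- summarize_conditions(tab3, glu_map)
  expect_equal(s3[["ratio_glucose@10mM"]], 0.5)
  expect_equal(s3[["ratio_glucose@100mM"]], 0.25)

  expect_error(summarize_conditions(tab[, -5], atp_map()), "lacks cycle")
})

test_that("filters remove by first-triggered reason and partition the input", {
  mk <- function(buffer, target) make_table(list(list(
    sd = "AAAAAAAAAA", buffer = buffer, target = target)))
  cm <- atp_map()
  low <- summarize_conditions(mk(rep(50, 5), rep(100, 5)), cm)
  high <- summarize_conditions(mk(rep(1200, 5), rep(1300, 5)), cm)
  # buffer mean 500, buffer RSD ~0.10, target RSD ~0.35
  noisy <- summarize_conditions(mk(c(450, 475, 500, 525, 550),
                                   c(300, 400, 500, 600, 900)), cm)
  expect_true(noisy$rsd_buffer <= 0.30 && noisy[["rsd_ATP@500uM"]] > 0.30)
  ok <- summarize_conditions(mk(rep(500, 5), rep(600, 5)), cm)

  all4 <- rbind(low, high, noisy, ok)
  attr(all4, "targets") <- "ATP@500uM"
  class(all4) <- class(low)
  parts <- apply_filters(all4)
  expect_equal(parts$removed$status,
               c("removed:low_rfu", "removed:high_rfu", "removed:target_rsd"))
  expect_equal(nrow(parts$retained), 1L)
  expect_equal(nrow(parts$retained) + nrow(parts$removed), nrow(all4))
})

test_that("filter membership is the union of the four conditions", {
  set.seed(31)
  n <- 400
  s <- data.frame(sd_sequence = random_sds(n), tile = 1L, x = 1L, y = 1L,
                  mean_buffer = runif(n, 0, 1500),
                  rsd_buffer = runif(n, 0, 0.6))
  s[["mean_T"]] <- runif(n, 0, 1500)
  s[["rsd_T"]] <- runif(n, 0, 0.6)
  s[["ratio_T"]] <- s[["mean_T"]] / s$mean_buffer
  s$status <- "retained"
  attr(s, "targets") <- "T"
  class(s) <- c("cluster_summary", "data.frame")
  cfg <- filter_config()
  parts <- apply_filters(s, cfg)
  should_remove <- s$mean_buffer < cfg$rfu_min | s$mean_buffer > cfg$rfu_max |
    s$rsd_buffer > cfg$rsd_max | s$rsd_T > cfg$rsd_max
  expect_equal(nrow(parts$removed), sum(should_remove))
  expect_equal(sort(c(parts$retained$sd_sequence, parts$removed$sd_sequence)),
               sort(s$sd_sequence))
})

ranked_fixture <- function(ratios, buffer = NULL, sds = NULL) {
  n <- length(ratios)
  s <- data.frame(sd_sequence = sds %||% names(ratios), tile = 1L, x = 1L,
                  y = 1L, mean_buffer = buffer %||% rep(500, n),
                  rsd_buffer = 0.05)
  s[["mean_T"]] <- unname(ratios) * s$mean_buffer
  s[["rsd_T"]] <- 0.05
  s[["ratio_T"]] <- unname(ratios)
  s$status <- "retained"
  attr(s, "targets") <- "T"
  class(s) <- c("cluster_summary", "data.frame")
  s
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("ranking orders by ratio with a total, documented tie-break", {
  s <- ranked_fixture(c(A = 8.0, B = 2.0, C = 0.5),
                      sds = c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG"))
  on <- rank_clusters(s, "T", "on")
  expect_equal(on$ratio, c(8.0, 2.0, 0.5))
  off <- rank_clusters(s, "T", "off")
  expect_equal(off$ratio, c(0.5, 2.0, 8.0))
  expect_equal(on$rank, 1:3)

  tie <- ranked_fixture(c(2.0, 2.0), buffer = c(200, 300),
                        sds = c("AAAAAAAAAA", "CCCCCCCCCC"))
  expect_equal(rank_clusters(tie, "T", "on")$buffer_mean, c(300, 200))

  expect_error(rank_clusters(s, "nope", "on"), "unknown target")
  # determinism: identical input, identical output
  expect_identical(rank_clusters(s, "T", "on"), rank_clusters(s, "T", "on"))
})

test_that("unique-SD aggregation takes the median ratio across clusters", {
  s <- ranked_fixture(c(4.0, 6.0, 3.0),
                      sds = c("AAAAAAAAAA", "AAAAAAAAAA", "CCCCCCCCCC"))
  agg <- aggregate_unique_sd(rank_clusters(s, "T", "on"))
  expect_equal(agg$ratio[agg$sd_sequence == "AAAAAAAAAA"], 5.0)
  expect_equal(agg$n_clusters[agg$sd_sequence == "AAAAAAAAAA"], 2L)
  expect_equal(nrow(agg), 2L)
  expect_equal(agg$rank, 1:2)

  distinct <- ranked_fixture(c(4, 3, 2), sds = c("AAAAAAAAAA", "CCCCCCCCCC",
                                                 "GGGGGGGGGG"))
  agg2 <- aggregate_unique_sd(rank_clusters(distinct, "T", "on"))
  expect_equal(agg2$ratio, c(4, 3, 2))
  expect_equal(agg2$n_clusters, rep(1L, 3))
})

test_that("fold-change counting respects direction", {
  s <- ranked_fixture(c(1.5, 2.0, 3.0), sds = c("AAAAAAAAAA", "CCCCCCCCCC",
                                                "GGGGGGGGGG"))
  expect_equal(count_by_fold_change(s, "T", 2, "on"), 2L)
  soff <- ranked_fixture(c(0.9, 0.7, 0.5), sds = c("AAAAAAAAAA",
                                                   "CCCCCCCCCC",
                                                   "GGGGGGGGGG"))
  expect_equal(count_by_fold_change(soff, "T", 1.3, "off"), 2L)
  expect_equal(count_by_fold_change(s[0, ], "T", 2, "on"), 0L)
  expect_error(count_by_fold_change(s, "T", 0.5, "on"), ">= 1")
})

test_that("FASTA export preserves rank order and metadata", {
  s <- ranked_fixture(c(4, 3, 2), sds = c("AAAAAAAAAA", "CCCCCCCCCC",
                                          "GGGGGGGGGG"))
  agg <- aggregate_unique_sd(rank_clusters(s, "T", "on"))
  fa <- export_fasta(agg, 2)
  expect_length(fa, 4L)
  expect_match(fa[1], "^>sd_rank1")
  expect_equal(fa[2], "AAAAAAAAAA")
  expect_length(export_fasta(agg, 0), 0L)
  expect_error(export_fasta(agg, 5), "only 3")

  back <- parse_fasta_ranked(export_fasta(agg, 3))
  expect_equal(back$rank, agg$rank)
  expect_equal(back$ratio, agg$ratio, tolerance = 1e-6)
  expect_equal(back$n_clusters, agg$n_clusters)
  expect_equal(back$sd_sequence, agg$sd_sequence)
})
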