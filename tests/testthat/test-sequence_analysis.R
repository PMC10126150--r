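test_that("reverse complement is a Watson-Crick involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAA"), "TTTT")
  expect_equal(reverse_complement("ACGTN"), "NACGT")
  set.seed(41)
  mers <- replicate(100, random_dna(10))
  expect_equal(reverse_complement(reverse_complement(mers)), mers)
  expect_equal(reverse_complement(mers), vapply(mers, rc_string,
                                                character(1),
                                                USE.NAMES = FALSE))
  expect_error(reverse_complement("ACGU"), "outside")
})

test_that("aptamer specs validate sequence and modification positions", {
  apt <- aptamer_spec("test", "acgtacgt", modified_positions = c(2, 4))
  expect_equal(apt$sequence, "ACGTACGT")
  expect_error(aptamer_spec("bad", "ACGU"), "A,C,G,T")
  expect_error(aptamer_spec("bad", "ACGT", modified_positions = 5), "outside")
  expect_equal(nchar(atp_aptamer()$sequence), 27L)
})

test_that("longest complementary run finds planted duplexes", {
  apt <- atp_aptamer()
  # SD designed to pair perfectly with aptamer positions 1-10
  sd <- reverse_complement(substr(apt$sequence, 1, 10))
  hit <- longest_complementary_run(sd, apt)
  expect_equal(hit$aptamer_start, 1L)
  expect_equal(hit$aptamer_end, 10L)
  expect_equal(hit$length, 10L)

  # an SD with at most 2 complementary bases anywhere is discarded
  apt2 <- aptamer_spec("a", "AAAAAAAAAAAA")
  expect_null(longest_complementary_run("AATTAATTAA", apt2))  # runs of 2 Ts
  expect_equal(longest_complementary_run("AATTTATTAA", apt2)$length, 3L)
})

test_that("longest complementary run matches exhaustive substring scanning", {
  set.seed(42)
  apt_seqs <- c(replicate(20, random_dna(12)), atp_aptamer()$sequence)
  for (aseq in apt_seqs) {
    apt <- aptamer_spec("r", aseq)
    for (k in 1:5) {
      sd <- random_dna(sample(3:12, 1))
      got <- longest_complementary_run(sd, apt)
      want <- oracle_lcr(sd, aseq)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got[c("aptamer_start", "aptamer_end", "length")],
                     want, info = paste(sd, "vs", aseq))
      }
    }
  }
})

test_that("equal-length runs resolve to the 5'-most aptamer position", {
  apt <- aptamer_spec("rep", "GGGTAAAGGGTAAA")  # motif repeats at 1 and 8
  hit <- longest_complementary_run(reverse_complement("GGGT"), apt)
  expect_equal(hit$aptamer_start, 1L)
})

test_that("position histograms accumulate run windows", {
  apt <- atp_aptamer()
  sd <- reverse_complement(substr(apt$sequence, 5, 9))
  padded <- paste0(sd, "AAAAA")  # pad to 10 nt without extending the run
  hits <- position_histogram(rep(padded, 10), apt)
  got <- longest_complementary_run(padded, apt)
  expect_gte(got$length, 5L)
  win <- got$aptamer_start:got$aptamer_end
  expect_true(all(hits[win] == 10L))
  expect_true(all(hits[-win] == 0L))
  expect_equal(sum(position_histogram(character(0), apt)), 0L)
  expect_length(position_histogram(character(0), apt), 27L)

  # mixed planted set: histogram equals the sum of indicator windows
  sds <- vapply(c(1, 6, 11), function(p)
    reverse_complement(substr(apt$sequence, p, p + 9)), character(1))
  expected <- integer(27)
  for (p in c(1, 6, 11)) expected[p:(p + 9)] <- expected[p:(p + 9)] + 1L
  expect_equal(unname(position_histogram(sds, apt)), expected)
})

test_that("Smith-Waterman scores match hand-checked cases", {
  expect_equal(smith_waterman_score("ACGTACGTAC", "ACGTACGTAC"), 10)
  expect_equal(smith_waterman_score("AAAA", "TTTT"), 0)
  # 7 matches - 1 mismatch beats the 4-match suffix
  expect_equal(smith_waterman_score("ACGTACGT", "ACGGACGT"), 6)
  expect_error(smith_waterman_score("ACGU", "ACGT"), "outside")
  expect_error(sw_params(match = 0), "match > 0")
})

test_that("Smith-Waterman agrees with brute-force DP and Biostrings", {
  set.seed(43)
  p <- sw_params()
  for (k in 1:120) {
    a <- random_dna(sample(1:12, 1))
    b <- random_dna(sample(1:12, 1))
    expect_equal(smith_waterman_score(a, b, p), oracle_sw(a, b),
                 info = paste(a, b))
  }
  # third-party aligner cross-check at identical parameters, including
  # non-default scores
  for (k in 1:25) {
    a <- random_dna(sample(4:12, 1))
    b <- random_dna(sample(4:12, 1))
    expect_equal(smith_waterman_score(a, b, p), biostrings_sw(a, b),
                 info = paste(a, b))
    p2 <- sw_params(match = 2, mismatch = -3, gap_open = -4, gap_extend = -1)
    got <- smith_waterman_score(a, b, p2)
    expect_equal(got, oracle_sw(a, b, 2, -3, -4, -1), info = paste(a, b))
    if (got > 0)  # Biostrings reports 0-score local alignments differently
      expect_equal(got, biostrings_sw(a, b, 2, -3, -4, -1),
                   info = paste(a, b))
  }
})

test_that("SD similarity to the aptamer is bounded by the SD length", {
  apt <- atp_aptamer()
  sd <- reverse_complement(substr(apt$sequence, 8, 17))
  expect_equal(sw_to_aptamer(sd, apt), 10)
  set.seed(44)
  sds <- replicate(200, random_dna(10))
  scores <- sw_to_aptamer(sds, apt)
  expect_true(all(scores <= 10))
  expect_true(all(scores >= 0))

  # an SD sharing exactly one complementary 3-run and nothing else scores 3
  apt3 <- aptamer_spec("a3", "GGGGGAAAGGGGG")
  sd3 <- reverse_complement("CCCAAACCCC")  # rc back to CCCAAACCCC
  expect_equal(sw_to_aptamer(sd3, apt3), 3)
  expect_equal(oracle_sw(rc_string(sd3), "GGGGGAAAGGGGG"), 3)
})

test_that("score histograms partition the SD set", {
  apt <- atp_aptamer()
  same <- rep("ACGTACGTAC", 7)
  h <- sw_histogram(same, apt)
  expect_equal(nrow(h), 1L)
  expect_equal(h$count, 7L)
  expect_equal(nrow(sw_histogram(character(0), apt)), 0L)

  set.seed(45)
  sds <- replicate(60, random_dna(10))
  h2 <- sw_histogram(sds, apt)
  expect_equal(sum(h2$count), 60L)
  scores <- sw_to_aptamer(sds, apt)
  for (k in h2$score)
    expect_equal(sum(scores == k), h2$count[h2$score == k])
})

test_that("per-SD reports combine run mapping and similarity", {
  apt <- atp_aptamer()
  sds <- c(reverse_complement(substr(apt$sequence, 1, 10)), "AAAAAAAAAA")
  rep <- sd_report(sds, apt)
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$run_length[1], 10L)
  expect_equal(rep$sw_score[1], 10)
})
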