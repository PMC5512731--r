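test_that("FASTQ loading handles valid, empty and malformed files", {
  pop <- small_pop()
  rs0 <- simulate_reads(pop, 3, seed = 5)
  path <- temp_fastq(rs0)
  rs <- load_reads(path)
  expect_length(rs, 3)
  expect_identical(as.character(rs$seq), as.character(rs0$seq))
  expect_identical(as.character(rs$qual), as.character(rs0$qual))

  empty <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), empty)
  expect_length(load_reads(empty), 0)

  trunc <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), trunc)
  expect_error(load_reads(trunc), "record 2")

  mism <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "III"), mism)
  expect_error(load_reads(mism), "record 2.*mismatch")

  expect_error(load_reads("no/such/file.fastq"), "not found")
})

test_that("gzipped FASTQ round-trips", {
  pop <- small_pop()
  rs0 <- simulate_reads(pop, 50, seed = 6)
  gz <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(rs0, gz)
  rs <- load_reads(gz)
  expect_identical(as.character(rs$seq), as.character(rs0$seq))
})

test_that("quality filtering keeps reads with mean Phred above threshold", {
  mk <- function(n, q) {
    read_set(rep(strrep("A", 83), n),
             rep(strrep(intToUtf8(q + 33), 83), n))
  }
  high <- mk(20, 40)
  expect_length(quality_filter(high, q_min = 30), 20)
  low <- mk(20, 20)
  filt <- quality_filter(low, q_min = 30)
  expect_length(filt, 0)
  expect_equal(attr(filt, "n_filtered"), 20L)
  # deterministic 50/50 mix at Q35 / Q25
  mix <- read_set(rep(strrep("A", 83), 10000),
                  c(rep(strrep(intToUtf8(35 + 33), 83), 5000),
                    rep(strrep(intToUtf8(25 + 33), 83), 5000)))
  expect_length(quality_filter(mix, q_min = 30), 5000)
  expect_error(quality_filter(high, q_min = 50), "q_min")
})

test_that("barcode extraction anchors on the 5' flank with mismatch budget", {
  p <- barcode_pattern()
  bc <- strrep("C", 32)
  good <- paste0(p$flank5, bc, substr(p$flank3, 1, 31))
  q <- strrep("I", 83)
  rs <- read_set(good, q)
  raw <- extract_barcodes(rs, p, max_flank_mismatch = 0)
  expect_equal(raw$counts, c(stats::setNames(1L, bc)))

  # one mismatch in the flank: extracted only when the budget allows it
  flank_mm <- paste0("T", substr(p$flank5, 2, 20), bc, substr(p$flank3, 1, 31))
  rs_mm <- read_set(flank_mm, q)
  expect_equal(extract_barcodes(rs_mm, p, max_flank_mismatch = 1)$counts,
               c(stats::setNames(1L, bc)))
  raw0 <- extract_barcodes(rs_mm, p, max_flank_mismatch = 0)
  expect_length(raw0$counts, 0)
  expect_equal(raw0$n_unextractable, 1L)

  # read without any flank
  rs_no <- read_set(strrep("T", 83), q)
  expect_equal(extract_barcodes(rs_no, p)$n_unextractable, 1L)

  # fixed-position violation makes a read unextractable
  pf <- barcode_pattern(fixed = c("1" = "G"), flank5 = p$flank5,
                        flank3 = p$flank3)
  expect_equal(extract_barcodes(rs, pf)$n_unextractable, 1L)

  # accounting invariant
  mixed <- read_set(c(good, strrep("T", 83)), c(q, q))
  raw2 <- extract_barcodes(mixed, p)
  expect_equal(sum(raw2$counts) + raw2$n_unextractable + raw2$n_filtered,
               raw2$n_total)
})

test_that("error correction merges children per the greedy ratio rule", {
  raw <- raw_barcode_counts(c(AAAA = 1000L, AAAT = 3L))
  out <- error_correct(raw, max_dist = 1, min_ratio = 10)
  expect_equal(out$counts, c(AAAA = 1003L))
  # distance too large: unchanged
  raw2 <- raw_barcode_counts(c(AAAA = 500L, TTTT = 500L))
  expect_equal(error_correct(raw2, max_dist = 1)$counts,
               c(AAAA = 500L, TTTT = 500L))
  # ratio not met: unchanged
  raw3 <- raw_barcode_counts(c(AAAA = 90L, AAAT = 10L))
  expect_equal(error_correct(raw3, max_dist = 1, min_ratio = 10)$counts,
               c(AAAA = 90L, AAAT = 10L))
  expect_error(error_correct(raw_barcode_counts(c(AAAA = 5L, GGG = 2L))),
               "unequal length")
})

test_that("error correction conserves counts and is idempotent", {
  for (s in 1:25) {
    counts <- random_counts(30, len = 4, seed = s)
    raw <- raw_barcode_counts(counts)
    out <- error_correct(raw, max_dist = 2, min_ratio = 3)
    expect_equal(sum(out$counts), sum(counts))
    twice <- error_correct(out, max_dist = 2, min_ratio = 3)
    expect_identical(twice$counts, out$counts)
  }
})

test_that("greedy correction matches the brute-force oracle on small instances", {
  for (s in 1:40) {
    set.seed(s)
    n <- sample(3:12, 1)
    counts <- random_counts(n, len = 5)
    md <- sample(1:3, 1)
    mr <- sample(c(2, 5, 10), 1)
    mine <- error_correct(raw_barcode_counts(counts), max_dist = md,
                          min_ratio = mr)$counts
    oracle <- oracle_error_correct(counts, max_dist = md, min_ratio = mr)
    expect_identical(mine, oracle)
  }
})

test_that("the full pipeline recovers exact clone sets from zero-error reads", {
  pop <- small_pop(n_clones = 30)
  rs <- simulate_reads(pop, 5000, read_error_model(substitution_rate = 0),
                       seed = 41)
  corr <- quantify_reads(rs)
  tc <- attr(rs, "true_counts")
  names(tc) <- pop$barcode
  tc <- tc[tc > 0]
  expect_setequal(names(corr$counts), names(tc))
  expect_equal(corr$counts[names(tc)], tc)
})

test_that("clone tables zero-fill the union of barcodes across samples", {
  s1 <- c(AAAA = 10L, CCCC = 5L, GGGG = 1L)
  s2 <- c(AAAA = 7L, TTTT = 2L)
  tab <- build_clone_table(list(m1 = s1, m2 = s2),
                           metadata = data.frame(organ = c("BM", "Spl")))
  expect_equal(dim(tab$counts), c(4L, 2L))
  expect_equal(tab$counts["TTTT", "m1"], 0L)
  expect_equal(tab$counts["AAAA", "m2"], 7L)
  expect_equal(tab$metadata$organ, c("BM", "Spl"))
  # single sample and empty input
  expect_equal(dim(build_clone_table(list(only = s1))$counts), c(3L, 1L))
  expect_equal(dim(build_clone_table(list())$counts), c(0L, 0L))
  expect_error(build_clone_table(list(a = s1, a = s2)), "duplicate")
})

test_that("clone tables round-trip through TSV", {
  tab <- build_clone_table(list(m1 = c(AAAA = 10L, CCCC = 5L),
                                m2 = c(AAAA = 7L)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clone_table(tab, path)
  back <- read_clone_table(path)
  expect_equal(back$counts, tab$counts)
})

test_that("library overlap reproduces the 148-of-158 worked example", {
  lib <- generate_barcode_library(2000, seed = 1)
  inlib <- sample(lib$sequences, 148)
  novel <- generate_barcode_library(2000, barcode_pattern(
    flank5 = "AAAAAAAAAAAAAAAAAAAA", flank3 = "TTTTTTTTTTTTTTTTTTTT"),
    seed = 99)$sequences
  novel <- setdiff(novel, lib$sequences)[1:10]
  ov <- library_overlap(c(inlib, novel), lib)
  expect_equal(ov$n_sample_barcodes, 158L)
  expect_equal(ov$n_in_library, 148L)
  expect_equal(round(ov$fraction, 1), 93.7)
  # boundary cases
  expect_equal(library_overlap(inlib, lib)$fraction, 100)
  expect_equal(library_overlap(novel, lib)$fraction, 0)
  expect_error(library_overlap(character(0), lib), "empty")
})

test_that("QC JSON records the read accounting", {
  raw <- raw_barcode_counts(c(AAAA = 10L), n_total = 15L, n_filtered = 3L,
                            n_unextractable = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  write_qc_json(raw, path)
  qc <- jsonlite::read_json(path)
  expect_equal(qc$n_total, 15L)
  expect_equal(qc$n_filtered, 3L)
  expect_equal(qc$n_assigned, 10L)
  expect_error(raw_barcode_counts(c(AAAA = 10L), n_total = 11L),
               "accounting")
})
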