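test_that("FASTQ qualities decode against the declared ASCII offset", {
  reads <- make_reads(c("ACGT", "ACGT"),
                      quals = list(rep(40L, 4), rep(0L, 4)))
  path <- write_temp_fastq(reads, offset = 64)
  lines <- readLines(path)
  expect_equal(lines[4], "hhhh")   # 40 + 64 -> ASCII 104
  expect_equal(lines[8], "@@@@")   # 0 + 64 -> ASCII 64

  back <- read_fastq(path, 64)
  expect_equal(back$qual[[1]], rep(40L, 4))
  expect_equal(back$qual[[2]], rep(0L, 4))

  # "h" decodes to 71 at offset 33: out of range, other offset suggested
  expect_error(read_fastq(path, 33), "offset 64")
})

test_that("FASTQ round trip is exact for both offsets", {
  set.seed(11)
  reads <- make_reads(replicate(20, random_dna(sample(10:28, 1))))
  reads$qual <- lapply(nchar(reads$seq), function(n) sample(0:40, n, TRUE))
  for (off in c(33, 64)) {
    path <- write_temp_fastq(reads, off)
    back <- read_fastq(path, off)
    expect_identical(back$seq, reads$seq)
    expect_identical(lapply(back$qual, as.integer),
                     lapply(reads$qual, as.integer))
  }
})

test_that("malformed FASTQ records are reported with their index", {
  path <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "hhhh",
               "@r2", "ACGT", "+", "hhh"), path)   # length mismatch
  expect_error(read_fastq(path, 64), "record 2")
  writeLines(c("@r1", "ACGT", "x", "hhhh"), path)  # missing '+'
  expect_error(read_fastq(path, 64), "record 1.*\\+")
  writeLines(c("@r1", "ACGT", "+"), path)          # truncated
  expect_error(read_fastq(path, 64), "multiple of 4")
})

test_that("quality filter eliminates reads at the 80% low-quality boundary", {
  reads <- make_reads(
    rep(strrep("ACGT", 5), 3),
    quals = list(rep(30L, 20),                    # clean
                 c(rep(10L, 16), rep(30L, 4)),    # exactly 80% below Q20
                 c(rep(10L, 15), rep(30L, 5))))   # 75% below Q20
  expect_equal(passes_quality(reads), c(TRUE, FALSE, TRUE))
  # N bases count as low quality regardless of score
  nread <- make_reads(paste0(strrep("N", 16), "ACGT"), quals = 30)
  expect_false(passes_quality(nread))
  expect_error(passes_quality(make_reads("", quals = list(integer(0)))),
               "empty")
})

test_that("end trimming removes terminal artifacts and is idempotent", {
  r <- make_reads("GGGGGGACGTACGTACGT", quals = 30)
  expect_equal(trim_read_ends(r)$seq, "ACGTACGTACGT")

  r <- make_reads("ACGTACGTACGT", quals = 30)
  expect_equal(trim_read_ends(r)$seq, "ACGTACGTACGT")

  r <- make_reads("ACGTACGTACGT",
                  quals = list(c(rep(30L, 9), rep(5L, 3))))
  expect_equal(trim_read_ends(r)$seq, "ACGTACGTA")

  # terminal dinucleotide repeat of 3 units
  r <- make_reads("ACACACTTGGCATCA", quals = 30)
  expect_equal(trim_read_ends(r)$seq, "TTGGCATCA")

  # interior artifacts untouched
  r <- make_reads("TTCAAAAAAGCAT", quals = 30)
  expect_equal(trim_read_ends(r)$seq, "TTCAAAAAAGCAT")

  # idempotence and substring property on random reads
  set.seed(42)
  for (i in 1:50) {
    reads <- make_reads(random_dna(sample(15:35, 1)),
                        quals = list(sample(0:40, sample(15:35, 1), TRUE)))
    reads$qual <- lapply(nchar(reads$seq), function(n) sample(0:40, n, TRUE))
    once <- trim_read_ends(reads)
    twice <- trim_read_ends(once)
    expect_identical(twice$seq, once$seq)
    expect_true(grepl(once$seq, reads$seq, fixed = TRUE) ||
                  once$seq == "")
  }
})

test_that("collapsing conserves read counts with deterministic ordering", {
  out <- collapse_reads(c("ACGT", "ACGT", "TTTT"))
  expect_equal(out$seq, c("ACGT", "TTTT"))
  expect_equal(out$count, c(2L, 1L))

  expect_equal(nrow(collapse_reads(character(0))), 0L)

  out <- collapse_reads(rep("ACGTACGT", 1000))
  expect_equal(out$count, 1000L)

  # tie-break is lexicographic
  out <- collapse_reads(c("TTTT", "AAAA", "CCCC"))
  expect_equal(out$seq, c("AAAA", "CCCC", "TTTT"))

  set.seed(3)
  seqs <- replicate(500, random_dna(sample(10:20, 1)))
  expect_equal(sum(collapse_reads(seqs)$count), 500L)
})

test_that("length filter keeps the inclusive 10-28 nt window", {
  coll <- data.frame(seq = vapply(c(9, 10, 28, 29), function(n)
    strrep("A", n), character(1)), count = 1:4)
  kept <- filter_length(coll)
  expect_equal(nchar(kept$seq), c(10L, 28L))
  expect_equal(nrow(filter_length(data.frame(seq = strrep("A", 40),
                                             count = 1L))), 0L)
  expect_error(filter_length(coll, min_len = 20, max_len = 10), "min_len")
})

test_that("preprocess stage accounting conserves reads", {
  set.seed(5)
  good <- replicate(40, random_dna(22))
  short <- replicate(5, random_dna(6))        # lost to length filter
  reads <- make_reads(c(good, short), quals = 35)
  bad <- make_reads(replicate(10, random_dna(22)),
                    quals = lapply(1:10, function(i)
                      c(rep(5L, 20), rep(30L, 2))))  # >80% below Q20
  all_reads <- make_reads(c(reads$seq, bad$seq),
                          quals = c(reads$qual, bad$qual))
  path <- write_temp_fastq(all_reads)
  res <- preprocess_fastq(path)
  st <- res$stats
  expect_equal(st$n_raw, 55L)
  expect_equal(st$n_pass_quality, 45L)
  expect_equal(st$n_raw - st$n_pass_quality, 10L)
  expect_equal(st$n_in_length_range, 40L)
  expect_equal(sum(res$collapsed$count), st$n_in_length_range)
  expect_true(st$n_unique <= st$n_in_length_range)
})
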