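test_that("catalog entries shorter than 17 nt are rejected with a warning", {
  expect_warning(cat17 <- mirna_catalog(c("a", "b"),
                                        c("ACGTACGTACGTACGTACGT",
                                          "ACGTACGT")),
                 "shorter than 17")
  expect_equal(cat17$name, "a")
  expect_equal(nchar(cat17$seed), 17L)
  # U stored as T, seed is the first 17 nt
  cat_u <- mirna_catalog("u", "UGAGGUAGUAGGUUGUAUAGU")
  expect_equal(cat_u$seq, "TGAGGTAGTAGGTTGTATAGT")
  expect_equal(cat_u$seed, substr(cat_u$seq, 1, 17))
})

test_that("catalog FASTA reading takes the first header token as the name", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">mir-a-5p MIMAT000 some species", "UGAGGUAGUAGGUUGUAUAGU",
               ">mir-b-3p", "AACCGGUUAACCGGUUAACC"), path)
  cat2 <- read_mirna_catalog(path)
  expect_equal(cat2$name, c("mir-a-5p", "mir-b-3p"))
  expect_equal(cat2$seq[1], "TGAGGTAGTAGGTTGTATAGT")
})

test_that("contaminant index matches exact substrings on both strands", {
  ref <- tempfile(fileext = ".fa")
  writeLines(c(">ref1", "ACGTACGTACGTACGTACGT"), ref)
  idx <- contaminant_index(ref)
  expect_true(is_contaminant(idx, "GTACGTACGT"))
  expect_false(is_contaminant(idx, "TTTTTTTTTT"))

  # a query equal only to the reverse complement of a reference substring
  ref2 <- tempfile(fileext = ".fa")
  writeLines(c(">ref2", "AACCTTGGAACCTTGGAACC"), ref2)
  q_rc <- "CCAAGGTTCC"   # revcomp of GGAACCTTGG
  expect_true(is_contaminant(contaminant_index(ref2), q_rc))
  expect_false(is_contaminant(contaminant_index(ref2, both_strands = FALSE),
                              q_rc))
  expect_error(contaminant_index(character(0)), "empty")
})

test_that("contaminant screening partitions the input with counts intact", {
  ref <- tempfile(fileext = ".fa")
  writeLines(c(">ref1", paste0(strrep("AC", 15), strrep("GT", 15))), ref)
  idx <- contaminant_index(ref)
  coll <- data.frame(seq = c(strrep("AC", 6), strrep("GT", 6),
                             "TGAGGTAGTAGGTTGTA"),
                     count = c(5L, 7L, 11L))
  parts <- screen_contaminants(coll, idx)
  expect_equal(nrow(parts$kept) + nrow(parts$removed), nrow(coll))
  expect_equal(sum(parts$kept$count) + sum(parts$removed$count),
               sum(coll$count))
  expect_equal(parts$kept$seq, "TGAGGTAGTAGGTTGTA")
  # no index: everything kept
  none <- screen_contaminants(coll, NULL)
  expect_equal(nrow(none$removed), 0L)
})

test_that("seed matching is 5'-anchored, mismatch-free and isoMIR tolerant", {
  cat3 <- tiny_catalog()
  # 20-nt read whose first 17 nt equal the seed: extra 3' bases unchecked
  expect_equal(match_mirna("TGAGGTAGTAGGTTGTATAG", cat3), "mirX-5p")
  # 14-nt read matching the seed prefix exactly
  expect_equal(match_mirna("TGAGGTAGTAGGTT", cat3), "mirX-5p")
  # single mismatch inside the seed: no match
  expect_equal(match_mirna("TGAGCTAGTAGGTTGTATAG", cat3), character(0))
  # U/T and case insensitivity
  expect_equal(match_mirna("ugagguaguagguuguauag", cat3), "mirX-5p")
  # length contract
  expect_error(match_mirna("ACGTACGTA", cat3), "10-28")
  # a matching long read's 17-nt prefix also matches on its own
  long <- "TGAGGTAGTAGGTTGTATAGT"
  expect_equal(match_mirna(substr(long, 1, 17), cat3),
               match_mirna(long, cat3))
})

test_that("seed matcher agrees with a brute-force oracle on random cases", {
  set.seed(99)
  for (rep in 1:40) {
    n_cat <- sample(3:12, 1)
    seqs <- replicate(n_cat, random_dna(sample(18:24, 1)))
    cat_r <- suppressWarnings(
      mirna_catalog(sprintf("m%02d", seq_len(n_cat)), seqs))
    queries <- c(
      replicate(5, random_dna(sample(10:28, 1))),
      # near-miss and exact-hit queries derived from the catalog
      vapply(sample(seqs, 3, replace = TRUE), function(s) {
        q <- substr(s, 1, sample(12:nchar(s), 1))
        if (runif(1) < 0.5) {
          p <- sample(nchar(q), 1)
          substr(q, p, p) <- sample(c("A", "C", "G", "T"), 1)
        }
        q
      }, character(1)))
    for (q in queries) {
      expect_identical(sort(match_mirna(q, cat_r)),
                       sort(brute_match(q, cat_r)))
    }
  }
})

test_that("annotation merges isoMIRs and never creates or loses counts", {
  cat3 <- tiny_catalog()
  coll <- data.frame(
    seq = c("TGAGGTAGTAGGTTGTATAGT",  # mirX full
            "TGAGGTAGTAGGTTGTATA",    # mirX 3' variant
            "TGAGGTAGTAGGTT",         # mirX short variant
            "AACCGGTTAACCGGTTAACC",   # mirY
            "GGGGGGGGGGGGGGGGGGGG"),  # unassigned
    count = c(3L, 5L, 2L, 4L, 6L))
  prof <- annotate_library(coll, cat3, library_id = "L1",
                           total_raw_reads = 100L)
  expect_equal(prof$per_mirna[["mirX-5p"]], 10L)
  expect_equal(prof$per_mirna[["mirY-3p"]], 4L)
  expect_equal(sum(prof$per_mirna[["mirX-5p"]]),
               sum(prof$isomir_breakdown[["mirX-5p"]]))
  expect_equal(prof$unassigned, 6L)
  expect_equal(sum(prof$per_mirna) + prof$unassigned +
                 prof$ambiguous_discarded, sum(coll$count))

  # no matches at all
  none <- annotate_library(data.frame(seq = "GGGGGGGGGGGG", count = 2L),
                           cat3)
  expect_equal(length(none$per_mirna), 0L)
  expect_equal(none$unassigned, 2L)

  expect_error(annotate_library(coll, rbind(cat3, cat3)), "duplicate")
})

test_that("ambiguous sequences follow the selected policy", {
  cat_dup <- suppressWarnings(mirna_catalog(
    c("twin-a", "twin-b"),
    c("TGAGGTAGTAGGTTGTATAGT", "TGAGGTAGTAGGTTGTACCCC")))  # same seed
  coll <- data.frame(seq = "TGAGGTAGTAGGTTGTA", count = 9L)
  p_disc <- annotate_library(coll, cat_dup, ambiguity = "discard")
  expect_equal(length(p_disc$per_mirna), 0L)
  expect_equal(p_disc$ambiguous_discarded, 9L)
  p_all <- annotate_library(coll, cat_dup, ambiguity = "all")
  expect_equal(unname(p_all$per_mirna[c("twin-a", "twin-b")]), c(9L, 9L))
  p_first <- annotate_library(coll, cat_dup, ambiguity = "first")
  expect_equal(names(p_first$per_mirna), "twin-a")
})

test_that("low-abundance filtering drops the cumulative 0.01% tail", {
  prof <- function(counts, total) {
    structure(list(library_id = "x", total_raw_reads = total,
                   total_clean_reads = sum(counts), per_mirna = counts,
                   isomir_breakdown = list(), unassigned = 0L,
                   ambiguous_discarded = 0L), class = "library_profile")
  }
  p <- prof(c(a = 1L, b = 1L, c = 100000L), 1e6)
  res <- low_abundance_filter(list(p), pool_fraction = 1e-4)
  expect_setequal(res$dropped, c("a", "b"))
  expect_equal(res$kept, "c")

  # pool_fraction 0 drops nothing
  res0 <- low_abundance_filter(list(p), pool_fraction = 0)
  expect_equal(length(res0$dropped), 0L)

  # a single miRNA holding all counts is never dropped
  res1 <- low_abundance_filter(list(prof(c(only = 10L), 1e6)),
                               pool_fraction = 1)
  expect_equal(res1$kept, "only")

  # per-miRNA share variant
  res2 <- low_abundance_filter(list(p), pool_fraction = 1e-4,
                               method = "per_mirna")
  expect_setequal(res2$dropped, c("a", "b"))

  # the kept set is shared across libraries
  p2 <- prof(c(a = 50000L, d = 3L), 1e6)
  res3 <- low_abundance_filter(list(p, p2), pool_fraction = 1e-4)
  expect_true(all(c("a", "c") %in% res3$kept))
})
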