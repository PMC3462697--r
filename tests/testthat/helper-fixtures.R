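# In-code fixtures shared across test files.

make_reads <- function(seqs, quals = NULL, ids = NULL) {
  if (is.null(quals)) quals <- lapply(nchar(seqs), function(n) rep(30L, n))
  if (is.numeric(quals) && length(quals) == 1L) {
    quals <- lapply(nchar(seqs), function(n) rep(as.integer(quals), n))
  }
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  structure(list(read_id = ids, seq = seqs, qual = quals),
            class = "fastq_reads")
}

write_temp_fastq <- function(reads, offset = 64) {
  path <- tempfile(fileext = ".fastq")
  write_fastq(reads, path, offset)
  path
}

# A tiny fixed catalog around the let-7 seed used in worked examples.
tiny_catalog <- function() {
  mirna_catalog(
    name = c("mirX-5p", "mirY-3p", "mirZ-5p"),
    seq = c("TGAGGTAGTAGGTTGTATAGT",   # seed TGAGGTAGTAGGTTGTA
            "AACCGGTTAACCGGTTAACCT",   # seed AACCGGTTAACCGGTTA
            "CCCTGAGACCTCAAGTGTGAG")   # seed CCCTGAGACCTCAAGTG
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent character-by-character seed matcher (the oracle for
# match_mirna): scans every catalog entry, no hashing, no vectorized
# string ops.
brute_match <- function(seq, catalog) {
  seq <- chartr("Uu", "Tt", toupper(seq))
  q <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hits <- character(0)
  for (i in seq_len(nrow(catalog))) {
    s <- strsplit(catalog$seed[i], "", fixed = TRUE)[[1L]]
    k <- min(length(q), 17L)
    if (length(q) >= 17L) {
      ok <- all(q[1:17] == s[1:17])
    } else {
      ok <- all(q[1:k] == s[1:k])
    }
    if (ok) hits <- c(hits, catalog$name[i])
  }
  hits
}
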