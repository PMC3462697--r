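#' Read a FASTQ file into a set of quality reads
#'
#' Parses a 4-line-per-record FASTQ file (plain or gzip) and decodes the
#' quality string with the given ASCII offset. Small RNA libraries from
#' older Illumina pipelines use offset 64 (ASCII 64-104 encoding Phred
#' 0-40); modern data uses offset 33.
#'
#' @param path Path to a FASTQ file (".gz" accepted).
#' @param quality_offset ASCII offset of the quality encoding, 33 or 64.
#' @return An object of class `fastq_reads`: a list with character vectors
#'   `read_id` and `seq` and a list column `qual` of integer Phred scores.
#' @export
read_fastq <- function(path, quality_offset = 64) {
  if (!quality_offset %in% c(33L, 64L)) {
    stop("quality_offset must be 33 or 64")
  }
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: number of lines (", length(lines),
         ") is not a multiple of 4")
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]

  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    stop("malformed FASTQ record ", bad_hdr[1L], ": header does not start with '@'")
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    stop("malformed FASTQ record ", bad_plus[1L], ": missing '+' separator line")
  }
  bad_len <- which(nchar(seqs) != nchar(quals))
  if (length(bad_len)) {
    stop("malformed FASTQ record ", bad_len[1L],
         ": sequence and quality lengths differ")
  }
  qual <- lapply(quals, function(q) utf8ToInt(q) - quality_offset)
  rng <- range(unlist(qual, use.names = FALSE))
  if (rng[1L] < 0L || rng[2L] > 40L) {
    bad <- which(vapply(qual, function(q) any(q < 0L | q > 40L), logical(1)))[1L]
    other <- if (quality_offset == 64L) 33L else 64L
    stop("record ", bad, ": decoded quality outside 0-40 at offset ",
         quality_offset, "; the file may use offset ", other)
  }
  structure(
    list(read_id = sub("^@", "", hdr), seq = toupper(seqs), qual = qual),
    class = "fastq_reads"
  )
}

#' Write quality reads to a FASTQ file
#'
#' Inverse of [read_fastq()]: `read_fastq(write_fastq(x, f), offset)` recovers
#' `x` exactly for either offset.
#'
#' @param reads A `fastq_reads` object.
#' @param path Output path (".gz" to compress).
#' @param quality_offset ASCII offset for the quality encoding, 33 or 64.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_offset = 64) {
  if (!quality_offset %in% c(33L, 64L)) stop("quality_offset must be 33 or 64")
  qstr <- vapply(reads$qual, function(q) intToUtf8(q + quality_offset),
                 character(1))
  out <- character(4L * length(reads$seq))
  out[seq(1L, by = 4L, length.out = length(reads$seq))] <- paste0("@", reads$read_id)
  out[seq(2L, by = 4L, length.out = length(reads$seq))] <- reads$seq
  out[seq(3L, by = 4L, length.out = length(reads$seq))] <- "+"
  out[seq(4L, by = 4L, length.out = length(reads$seq))] <- qstr
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' @export
length.fastq_reads <- function(x) length(x$seq)

#' @export
print.fastq_reads <- function(x, ...) {
  cat("fastq_reads:", length(x), "reads\n")
  invisible(x)
}

n_reads <- function(reads) length(reads$seq)

subset_reads <- function(reads, idx) {
  structure(list(read_id = reads$read_id[idx], seq = reads$seq[idx],
                 qual = reads$qual[idx]), class = "fastq_reads")
}

#' Quality filter for small RNA reads
#'
#' A read is eliminated when at least `bad_fraction` of its positions have a
#' quality below `q_min`. `N` calls count as below `q_min` regardless of
#' their score.
#'
#' @param reads A `fastq_reads` object.
#' @param q_min Minimum acceptable per-base quality (default 20).
#' @param bad_fraction Fraction of sub-`q_min` positions at or above which a
#'   read is eliminated (default 0.8; the boundary is inclusive, so a read
#'   with exactly 80% low-quality bases is removed).
#' @return Logical vector, `TRUE` for reads that pass.
#' @export
passes_quality <- function(reads, q_min = 20, bad_fraction = 0.8) {
  if (any(nchar(reads$seq) == 0L)) stop("empty sequence in reads")
  mapply(function(s, q) {
    bad <- (q < q_min) | (strsplit(s, "", fixed = TRUE)[[1L]] == "N")
    mean(bad) < bad_fraction
  }, reads$seq, reads$qual, USE.NAMES = FALSE)
}

# One trimming pass over a single read held as character/integer vectors.
# Rules, applied at both ends until stable:
#   (a) terminal bases with quality < q_min
#   (b) terminal homopolymer runs of >= homopolymer_min bases
#   (c) terminal perfect dinucleotide repeats (two distinct bases) of
#       >= dimer_units_min units
trim_one <- function(chars, qual, q_min, homopolymer_min, dimer_units_min) {
  repeat {
    n0 <- length(chars)
    if (n0 == 0L) break
    # (a) low-quality ends
    while (length(qual) && qual[1L] < q_min) {
      chars <- chars[-1L]; qual <- qual[-1L]
    }
    while (length(qual) && qual[length(qual)] < q_min) {
      chars <- chars[-length(chars)]; qual <- qual[-length(qual)]
    }
    # (b) terminal homopolymer runs
    if (length(chars)) {
      r <- rle(chars)
      if (r$lengths[1L] >= homopolymer_min) {
        k <- r$lengths[1L]
        chars <- chars[-seq_len(k)]; qual <- qual[-seq_len(k)]
        r <- if (length(chars)) rle(chars) else NULL
      }
      if (!is.null(r) && length(r$lengths) &&
          r$lengths[length(r$lengths)] >= homopolymer_min) {
        k <- r$lengths[length(r$lengths)]
        idx <- seq(length(chars) - k + 1L, length(chars))
        chars <- chars[-idx]; qual <- qual[-idx]
      }
    }
    # (c) terminal dinucleotide repeats
    if (length(chars) >= 2L * dimer_units_min) {
      a <- chars[1L]; b <- chars[2L]
      if (a != b) {
        k <- 1L
        while (2L * (k + 1L) <= length(chars) &&
               chars[2L * k + 1L] == a && chars[2L * k + 2L] == b) {
          k <- k + 1L
        }
        if (k >= dimer_units_min) {
          chars <- chars[-seq_len(2L * k)]; qual <- qual[-seq_len(2L * k)]
        }
      }
    }
    if (length(chars) >= 2L * dimer_units_min) {
      n <- length(chars)
      a <- chars[n - 1L]; b <- chars[n]
      if (a != b) {
        k <- 1L
        while (n - 2L * (k + 1L) >= 0L &&
               chars[n - 2L * k - 1L] == a && chars[n - 2L * k] == b) {
          k <- k + 1L
        }
        if (k >= dimer_units_min) {
          idx <- seq(n - 2L * k + 1L, n)
          chars <- chars[-idx]; qual <- qual[-idx]
        }
      }
    }
    if (length(chars) == n0) break
  }
  list(chars = chars, qual = qual)
}

#' Trim artifact-prone read ends
#'
#' Iteratively removes, from either end of each read until stable: terminal
#' bases below `q_min`, terminal homopolymer runs of at least
#' `homopolymer_min` bases, and terminal perfect dinucleotide repeats of at
#' least `dimer_units_min` units. Interior bases are never removed, so every
#' output is a contiguous substring of its input; the operation is
#' idempotent. Reads may be trimmed to length zero.
#'
#' @param reads A `fastq_reads` object.
#' @param q_min Quality threshold for rule (a).
#' @param homopolymer_min Minimum terminal homopolymer run removed.
#' @param dimer_units_min Minimum number of terminal dinucleotide units
#'   removed (units of two distinct bases; homopolymers are rule (b)'s job).
#' @return A `fastq_reads` object with trimmed sequences (possibly empty).
#' @export
trim_read_ends <- function(reads, q_min = 20, homopolymer_min = 5,
                           dimer_units_min = 3) {
  trimmed <- mapply(function(s, q) {
    res <- trim_one(strsplit(s, "", fixed = TRUE)[[1L]], q,
                    q_min, homopolymer_min, dimer_units_min)
    list(seq = paste(res$chars, collapse = ""), qual = res$qual)
  }, reads$seq, reads$qual, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  structure(
    list(read_id = reads$read_id,
         seq = vapply(trimmed, `[[`, character(1), "seq"),
         qual = lapply(trimmed, `[[`, "qual")),
    class = "fastq_reads"
  )
}

#' Collapse identical sequences into counted unique sequences
#'
#' @param seqs Character vector of (non-empty) read sequences.
#' @return A data.frame with columns `seq` and `count`, ordered by
#'   descending count, ties broken lexicographically (C locale). The counts
#'   sum to `length(seqs)`.
#' @export
collapse_reads <- function(seqs) {
  if (length(seqs) == 0L) {
    return(data.frame(seq = character(0), count = integer(0)))
  }
  if (any(nchar(seqs) == 0L)) stop("empty sequence passed to collapse_reads")
  tab <- table(seqs)
  out <- data.frame(seq = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$seq, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep collapsed sequences within a length window
#'
#' @param collapsed A collapsed-sequence data.frame (`seq`, `count`).
#' @param min_len,max_len Inclusive bounds on sequence length (defaults
#'   10 and 28 nt, the canonical small RNA window).
#' @return The rows of `collapsed` whose sequence length lies in
#'   `[min_len, max_len]`.
#' @export
filter_length <- function(collapsed, min_len = 10, max_len = 28) {
  if (min_len > max_len) stop("min_len must not exceed max_len")
  keep <- nchar(collapsed$seq) >= min_len & nchar(collapsed$seq) <= max_len
  out <- collapsed[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Preprocess one small RNA FASTQ library
#'
#' Runs the full cleaning stage in fixed order: quality filter, end
#' trimming, collapsing, length filter.
#'
#' @param path FASTQ path.
#' @param quality_offset 33 or 64 (default 64).
#' @param q_min,bad_fraction Quality-filter parameters (see
#'   [passes_quality()]).
#' @param homopolymer_min,dimer_units_min Trimming parameters (see
#'   [trim_read_ends()]).
#' @param min_len,max_len Length window (see [filter_length()]).
#' @return A list with `collapsed` (data.frame `seq`, `count`) and `stats`,
#'   a one-row data.frame with `n_raw`, `n_pass_quality`, `n_after_trim`,
#'   `n_in_length_range`, `n_unique`.
#' @export
preprocess_fastq <- function(path, quality_offset = 64, q_min = 20,
                             bad_fraction = 0.8, homopolymer_min = 5,
                             dimer_units_min = 3, min_len = 10, max_len = 28) {
  reads <- read_fastq(path, quality_offset)
  n_raw <- n_reads(reads)
  ok <- passes_quality(reads, q_min, bad_fraction)
  reads <- subset_reads(reads, ok)
  n_pass <- n_reads(reads)
  reads <- trim_read_ends(reads, q_min, homopolymer_min, dimer_units_min)
  nonempty <- nchar(reads$seq) > 0L
  reads <- subset_reads(reads, nonempty)
  n_trim <- n_reads(reads)
  collapsed <- collapse_reads(reads$seq)
  kept <- filter_length(collapsed, min_len, max_len)
  stats <- data.frame(
    n_raw = n_raw, n_pass_quality = n_pass, n_after_trim = n_trim,
    n_in_length_range = sum(kept$count), n_unique = nrow(kept)
  )
  list(collapsed = kept, stats = stats)
}

#' Write collapsed sequences as collapsed-FASTA
#'
#' Headers follow the `seq<i>_x<count>` dialect produced by common read
#' collapsers.
#'
#' @param collapsed Collapsed-sequence data.frame.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  hdr <- sprintf(">seq%d_x%d", seq_len(nrow(collapsed)), collapsed$count)
  writeLines(as.vector(rbind(hdr, collapsed$seq)), path)
  invisible(path)
}
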