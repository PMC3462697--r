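#' Count-weighted effective length of a miRNA's isoMIR pool
#'
#' The RPKM length term for a miRNA is the mean length of its observed
#' isoMIR variants, weighted by their counts; with typical 3' length
#' variation around 21-22 nt mature sequences this lands near 18-20 nt.
#'
#' @param breakdown Named numeric vector: variant sequence -> count.
#' @return The count-weighted mean variant length (nt).
#' @export
effective_length <- function(breakdown) {
  if (length(breakdown) == 0L || sum(breakdown) == 0) {
    stop("empty isoMIR breakdown")
  }
  sum(nchar(names(breakdown)) * breakdown) / sum(breakdown)
}

#' Reads per kilobase per million mapped reads
#'
#' @param count Read count (vectorized).
#' @param effective_length_nt Effective length in nucleotides (> 0).
#' @param library_total Library read total used as denominator (> 0); by
#'   convention the raw (pre-filter) read total.
#' @return `count * 1e9 / (effective_length_nt * library_total)`.
#' @export
rpkm <- function(count, effective_length_nt, library_total) {
  if (any(effective_length_nt <= 0)) stop("effective length must be positive")
  if (any(library_total <= 0)) stop("library total must be positive")
  count * 1e9 / (effective_length_nt * library_total)
}

#' M-value and D-value of an expression pair
#'
#' For expression levels `x1`, `x2` (RPKM) the M-value is the log2 ratio
#' `log2(x1/x2)` and the D-value the absolute difference `|x1 - x2|`. Zeros
#' are replaced by `pseudo` before the ratio so M stays finite; D is always
#' computed on the unsubstituted values.
#'
#' @param x1,x2 Non-negative expression values (vectorized).
#' @param pseudo Positive pseudo-expression substituted for zeros.
#' @return A data.frame with columns `M` and `D`.
#' @export
m_d_values <- function(x1, x2, pseudo = 0.5) {
  if (any(x1 < 0) || any(x2 < 0)) stop("expression values must be non-negative")
  if (pseudo <= 0) stop("pseudo must be positive")
  x1p <- ifelse(x1 == 0, pseudo, x1)
  x2p <- ifelse(x2 == 0, pseudo, x2)
  data.frame(M = log2(x1p / x2p), D = abs(x1 - x2))
}

#' Build the two-library expression table from annotated profiles
#'
#' Computes per-miRNA effective lengths and RPKM for each library and
#' returns the wide per-miRNA table on which the differential-expression
#' stage operates.
#'
#' @param profile1,profile2 `library_profile` objects (see
#'   [annotate_library()]).
#' @param keep Optional character vector of miRNA names to retain (e.g. the
#'   `kept` set of [low_abundance_filter()]); default: union of both
#'   profiles.
#' @return A data.frame with columns `mirna`, `count_1`, `rpkm_1`,
#'   `count_2`, `rpkm_2`, with attributes `totals` (raw-read totals) and
#'   `library_ids`.
#' @export
expression_table <- function(profile1, profile2, keep = NULL) {
  nms <- sort(unique(c(names(profile1$per_mirna), names(profile2$per_mirna))),
              method = "radix")
  if (!is.null(keep)) nms <- nms[nms %in% keep]
  one <- function(p, nm) {
    cnt <- if (nm %in% names(p$per_mirna)) p$per_mirna[[nm]] else 0L
    if (cnt > 0) {
      len <- effective_length(p$isomir_breakdown[[nm]])
      c(count = cnt, rpkm = rpkm(cnt, len, p$total_raw_reads))
    } else c(count = 0, rpkm = 0)
  }
  m1 <- t(vapply(nms, one, numeric(2), p = profile1))
  m2 <- t(vapply(nms, one, numeric(2), p = profile2))
  out <- data.frame(mirna = nms,
                    count_1 = as.integer(m1[, "count"]), rpkm_1 = m1[, "rpkm"],
                    count_2 = as.integer(m2[, "count"]), rpkm_2 = m2[, "rpkm"])
  rownames(out) <- NULL
  attr(out, "totals") <- c(profile1$total_raw_reads, profile2$total_raw_reads)
  attr(out, "library_ids") <- c(profile1$library_id, profile2$library_id)
  out
}

#' Per-miRNA M/D contrasts from an expression table
#'
#' @param expr Expression table as returned by [expression_table()] or
#'   [bger_n5n6()].
#' @param pseudo Pseudo-expression for zeros, in RPKM; default: 0.5 counts
#'   converted to RPKM with the table's median RPKM/count scale.
#' @return A data.frame `mirna`, `x1`, `x2`, `M`, `D`.
#' @export
contrast_table <- function(expr, pseudo = NULL) {
  if (is.null(pseudo)) pseudo <- 0.5 * median_scale(expr)
  md <- m_d_values(expr$rpkm_1, expr$rpkm_2, pseudo)
  data.frame(mirna = expr$mirna, x1 = expr$rpkm_1, x2 = expr$rpkm_2,
             M = md$M, D = md$D)
}

# Median observed RPKM-per-count scale across both libraries (positive
# counts only); the natural unit for converting a pseudo-count to RPKM.
median_scale <- function(expr) {
  s <- c(expr$rpkm_1 / expr$count_1, expr$rpkm_2 / expr$count_2)
  s <- s[is.finite(s) & s > 0]
  if (!length(s)) stop("no positive counts to derive an RPKM scale from")
  stats::median(s)
}

#' Back-solve effective lengths implied by a count/RPKM table
#'
#' Inverts the RPKM formula, `L = 1e9 * count / (RPKM * N)`, for each
#' miRNA and library. Useful as a consistency check on externally
#' normalized tables: with raw-read totals as `N`, implied lengths should
#' fall in the plausible 17-21 nt isoMIR band.
#'
#' @param expr Expression table (see [expression_table()]).
#' @param totals Numeric length-2 raw-read totals; default
#'   `attr(expr, "totals")`.
#' @return A data.frame `mirna`, `length_1`, `length_2`.
#' @export
implied_lengths <- function(expr, totals = attr(expr, "totals")) {
  if (is.null(totals) || length(totals) != 2L) {
    stop("need a length-2 'totals' vector")
  }
  data.frame(
    mirna = expr$mirna,
    length_1 = 1e9 * expr$count_1 / (expr$rpkm_1 * totals[1L]),
    length_2 = 1e9 * expr$count_2 / (expr$rpkm_2 * totals[2L])
  )
}

#' Bundled two-library cockroach nymphal expression table
#'
#' Counts and RPKM of the 61 canonical miRNAs detected in two deeply
#' sequenced whole-body small RNA libraries of *Blattella germanica*: the
#' penultimate, pre-metamorphic nymphal instar (N5, library 1; 38,399,972
#' raw reads) and the last, metamorphic instar (N6, library 2; 23,689,204
#' raw reads). isoMIR variants are merged per miRNA and RPKM uses raw-read
#' totals with per-miRNA effective lengths.
#'
#' @return An expression table (`mirna`, `count_1`, `rpkm_1`, `count_2`,
#'   `rpkm_2`) with `totals` and `library_ids` attributes.
#' @export
bger_n5n6 <- function() {
  path <- system.file("extdata", "bger_n5n6_expression.tsv",
                      package = "mirnoise", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(mirna = tab$mirna,
                    count_1 = tab$count_N5, rpkm_1 = tab$rpkm_N5,
                    count_2 = tab$count_N6, rpkm_2 = tab$rpkm_N6)
  attr(out, "totals") <- c(38399972, 23689204)
  attr(out, "library_ids") <- c("N5", "N6")
  out
}
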