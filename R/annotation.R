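#' Build a mature-miRNA catalog from name and sequence vectors
#'
#' Sequences are uppercased and U is stored as T. The seed of each entry is
#' its first 17 nucleotides; matching against reads is anchored at the 5'
#' end and requires a perfect seed match. Entries shorter than 17 nt cannot
#' define a seed and are rejected with a warning.
#'
#' @param name Character vector of miRNA names (conventionally carrying
#'   -5p/-3p suffixes).
#' @param seq Character vector of mature sequences (U or T alphabet).
#' @return A data.frame with columns `name`, `seq`, `seed` (class
#'   `mirna_catalog`).
#' @export
mirna_catalog <- function(name, seq) {
  seq <- chartr("Uu", "Tt", toupper(seq))
  short <- nchar(seq) < 17L
  if (any(short)) {
    warning(sum(short), " catalog entr", if (sum(short) == 1) "y" else "ies",
            " shorter than 17 nt rejected: ",
            paste(name[short], collapse = ", "))
    name <- name[!short]
    seq <- seq[!short]
  }
  out <- data.frame(name = name, seq = seq, seed = substr(seq, 1L, 17L))
  class(out) <- c("mirna_catalog", "data.frame")
  out
}

#' Read a mature-miRNA FASTA catalog
#'
#' Accepts the miRBase mature-FASTA dialect: the first whitespace-separated
#' token of each header is the miRNA name; sequences may use U.
#'
#' @param path FASTA path.
#' @return A `mirna_catalog` data.frame (see [mirna_catalog()]).
#' @export
read_mirna_catalog <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty catalog FASTA: ", path)
  nm <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  mirna_catalog(nm, as.character(set))
}

#' Build an exact-substring contaminant index
#'
#' Loads one or more contaminant reference FASTA files (e.g. stand-ins for
#' non-miRNA Pfam families, endosymbiont or viral genomes) and indexes them
#' for exact substring membership of short queries, optionally on both
#' strands.
#'
#' @param fastas Character vector of FASTA paths.
#' @param both_strands Also match queries against the reverse complement of
#'   each reference (default TRUE).
#' @return An object of class `contaminant_index`.
#' @export
contaminant_index <- function(fastas, both_strands = TRUE) {
  if (length(fastas) == 0L) stop("empty contaminant reference set")
  sets <- lapply(fastas, Biostrings::readDNAStringSet)
  refs <- do.call(c, sets)
  if (length(refs) == 0L) stop("empty contaminant reference set")
  if (both_strands) {
    refs <- c(refs, Biostrings::reverseComplement(refs))
  }
  structure(list(refs = refs, sources = basename(fastas),
                 both_strands = both_strands),
            class = "contaminant_index")
}

#' @export
print.contaminant_index <- function(x, ...) {
  cat("contaminant_index:", length(x$refs), "indexed strands from",
      paste(x$sources, collapse = ", "), "\n")
  invisible(x)
}

#' Test sequences for exact contaminant hits
#'
#' @param index A `contaminant_index`.
#' @param seqs Character vector of query sequences.
#' @return Logical vector: `TRUE` where the query occurs exactly as a
#'   substring of an indexed reference strand.
#' @export
is_contaminant <- function(index, seqs) {
  vapply(seqs, function(s) {
    any(Biostrings::vcountPattern(s, index$refs) > 0L)
  }, logical(1), USE.NAMES = FALSE)
}

#' Partition collapsed sequences into kept and contaminant sets
#'
#' @param collapsed Collapsed-sequence data.frame (`seq`, `count`).
#' @param index A `contaminant_index`, or NULL to keep everything.
#' @return A list with data.frames `kept` and `removed`; counts untouched,
#'   the two parts partition the input.
#' @export
screen_contaminants <- function(collapsed, index) {
  if (is.null(index) || nrow(collapsed) == 0L) {
    return(list(kept = collapsed,
                removed = collapsed[integer(0), , drop = FALSE]))
  }
  hit <- is_contaminant(index, collapsed$seq)
  list(kept = `rownames<-`(collapsed[!hit, , drop = FALSE], NULL),
       removed = `rownames<-`(collapsed[hit, , drop = FALSE], NULL))
}

normalize_query <- function(seq) chartr("Uu", "Tt", toupper(seq))

#' Match one sequence against a mature-miRNA catalog
#'
#' The matching rule is 5'-anchored and mismatch-free: a read of 17 nt or
#' longer matches a catalog entry when its first 17 nt equal the entry's
#' seed exactly (additional 3' bases are isoMIR variation and are not
#' checked); a read shorter than 17 nt matches when it equals the
#' corresponding prefix of the seed exactly. `max_5p_offset > 0` relaxes the
#' anchor, allowing the read to start up to that many bases inside the
#' mature sequence.
#'
#' @param seq A single query sequence, length 10-28 nt (U or T, any case).
#' @param catalog A `mirna_catalog`.
#' @param max_5p_offset Maximum 5' start offset inside the mature sequence
#'   (default 0: strict anchoring).
#' @return Character vector of all matching catalog names (possibly empty).
#' @export
match_mirna <- function(seq, catalog, max_5p_offset = 0) {
  seq <- normalize_query(seq)
  n <- nchar(seq)
  if (n < 10L || n > 28L) {
    stop("query length ", n, " outside the supported 10-28 nt range")
  }
  hits <- character(0)
  for (off in 0:max_5p_offset) {
    cand <- substr(catalog$seq, off + 1L, off + 17L)
    ok <- nchar(cand) == 17L &
      if (n >= 17L) substr(seq, 1L, 17L) == cand
      else seq == substr(cand, 1L, n)
    hits <- c(hits, catalog$name[ok])
  }
  unique(hits)
}

# Hash-based matcher for the strict-anchor fast path: one lookup per query.
build_seed_lookup <- function(catalog, lengths) {
  env_for <- function(keys, values) {
    e <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_along(keys)) {
      k <- keys[i]
      assign(k, c(if (exists(k, envir = e, inherits = FALSE))
        get(k, envir = e), values[i]), envir = e)
    }
    e
  }
  lapply(stats::setNames(lengths, lengths), function(l) {
    env_for(substr(catalog$seed, 1L, l), catalog$name)
  })
}

#' Annotate a collapsed library against a miRNA catalog
#'
#' Each unique sequence is matched with the seed rule of [match_mirna()];
#' isoMIR length variants assigned to the same miRNA are merged into a
#' single per-miRNA count, with the per-variant breakdown retained.
#' Sequences matching no catalog entry are tallied as unassigned; sequences
#' matching more than one entry are handled per `ambiguity`.
#'
#' @param collapsed Collapsed-sequence data.frame (`seq`, `count`).
#' @param catalog A `mirna_catalog`; duplicate names are an error.
#' @param library_id Library label.
#' @param total_raw_reads Raw (pre-filter) read count of the library, used
#'   downstream as the RPKM denominator.
#' @param ambiguity Policy for multi-matching sequences: `"discard"`
#'   (default; counted separately, assigned to nobody), `"all"` (count to
#'   every match), or `"first"` (count to the alphabetically first match).
#' @param max_5p_offset See [match_mirna()].
#' @return An object of class `library_profile`: a list with `library_id`,
#'   `total_raw_reads`, `total_clean_reads`, `per_mirna` (named count
#'   vector), `isomir_breakdown` (named list of variant-count vectors),
#'   `unassigned` and `ambiguous_discarded` counts.
#' @export
annotate_library <- function(collapsed, catalog, library_id = "lib",
                             total_raw_reads = NULL,
                             ambiguity = c("discard", "all", "first"),
                             max_5p_offset = 0) {
  ambiguity <- match.arg(ambiguity)
  if (nrow(catalog) == 0L) stop("empty catalog")
  if (anyDuplicated(catalog$name)) {
    stop("duplicate catalog names: ",
         paste(unique(catalog$name[duplicated(catalog$name)]), collapse = ", "))
  }
  total_clean <- sum(collapsed$count)
  if (is.null(total_raw_reads)) total_raw_reads <- total_clean

  seqs <- normalize_query(collapsed$seq)
  if (max_5p_offset == 0 && nrow(collapsed) > 0L) {
    lens <- pmin(nchar(seqs), 17L)
    lookup <- build_seed_lookup(catalog, sort(unique(lens)))
    matches <- mapply(function(s, l) {
      e <- lookup[[as.character(l)]]
      k <- substr(s, 1L, l)
      if (exists(k, envir = e, inherits = FALSE)) get(k, envir = e)
      else character(0)
    }, seqs, lens, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  } else {
    matches <- lapply(seqs, match_mirna, catalog = catalog,
                      max_5p_offset = max_5p_offset)
  }

  n_match <- lengths(matches)
  unassigned <- sum(collapsed$count[n_match == 0L])
  ambiguous_discarded <- 0L
  assign_to <- matches
  amb <- n_match > 1L
  if (any(amb)) {
    if (ambiguity == "discard") {
      ambiguous_discarded <- sum(collapsed$count[amb])
      assign_to[amb] <- list(character(0))
    } else if (ambiguity == "first") {
      assign_to[amb] <- lapply(matches[amb], function(m) sort(m)[1L])
    }
  }

  per_mirna <- integer(0)
  breakdown <- list()
  for (i in which(lengths(assign_to) > 0L)) {
    for (nm in assign_to[[i]]) {
      per_mirna[nm] <- sum(per_mirna[nm], collapsed$count[i], na.rm = TRUE)
      breakdown[[nm]] <- c(breakdown[[nm]],
                           stats::setNames(collapsed$count[i], seqs[i]))
    }
  }
  if (length(per_mirna)) {
    ord <- order(names(per_mirna), method = "radix")
    per_mirna <- per_mirna[ord]
    breakdown <- breakdown[names(per_mirna)]
  }
  structure(
    list(library_id = library_id,
         total_raw_reads = total_raw_reads,
         total_clean_reads = total_clean,
         per_mirna = per_mirna,
         isomir_breakdown = breakdown,
         unassigned = unassigned,
         ambiguous_discarded = ambiguous_discarded),
    class = "library_profile"
  )
}

#' @export
print.library_profile <- function(x, ...) {
  cat("library_profile", x$library_id, "-", length(x$per_mirna), "miRNAs,",
      sum(x$per_mirna), "assigned /", x$total_clean_reads, "clean reads\n")
  invisible(x)
}

#' Drop the poorest-represented miRNAs across libraries
#'
#' With `method = "cumulative"` (default), miRNAs are sorted by ascending
#' summed count across libraries and the longest low-abundance prefix whose
#' cumulative count does not exceed `pool_fraction` of the summed raw-read
#' totals is dropped: the removed miRNAs jointly represent at most that
#' share of the experiment. With `method = "per_mirna"`, each miRNA whose
#' own summed share is below `pool_fraction` is dropped. The kept set is
#' identical across libraries.
#'
#' @param profiles List of `library_profile` objects.
#' @param pool_fraction Abundance threshold as a proportion of total raw
#'   reads (default 1e-4, i.e. 0.01%).
#' @param method `"cumulative"` or `"per_mirna"`.
#' @return A list with character vectors `kept` and `dropped`.
#' @export
low_abundance_filter <- function(profiles, pool_fraction = 1e-4,
                                 method = c("cumulative", "per_mirna")) {
  method <- match.arg(method)
  if (length(profiles) == 0L) stop("need at least one library profile")
  all_names <- sort(unique(unlist(lapply(profiles, function(p)
    names(p$per_mirna)))), method = "radix")
  summed <- vapply(all_names, function(nm) {
    sum(vapply(profiles, function(p)
      if (nm %in% names(p$per_mirna)) p$per_mirna[[nm]] else 0L, numeric(1)))
  }, numeric(1))
  total <- sum(vapply(profiles, function(p) p$total_raw_reads, numeric(1)))
  budget <- pool_fraction * total
  if (method == "cumulative") {
    ord <- order(summed, all_names, method = "radix")
    cum <- cumsum(summed[ord])
    # the tail never swallows the whole set: the top miRNA is always kept
    sel <- cum <= budget
    sel[length(sel)] <- FALSE
    dropped <- all_names[ord][sel]
  } else {
    dropped <- all_names[summed < budget]
  }
  list(kept = setdiff(all_names, dropped), dropped = dropped)
}
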