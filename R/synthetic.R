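#' Specification of a synthetic two-library small RNA experiment
#'
#' Defines the generative model used for validation: per-miRNA base
#' abundances drawn log-normally (spanning roughly 1e2-1e6 counts at the
#' default depth, like a deeply sequenced whole-body library), a fraction
#' of miRNAs with a planted fold-change between the two libraries, 3'
#' isoMIR length variation, and planted contaminant and low-quality reads.
#'
#' @param n_mirnas Number of catalog miRNAs (default 60).
#' @param abundance_meanlog,abundance_sdlog Parameters of the log-normal
#'   base-abundance model on the natural-log scale (defaults 6 and 2).
#' @param de_fraction Fraction of miRNAs carrying a planted fold-change
#'   (default 0.3).
#' @param fold_change Planted fold-change (> 1, default 4; direction
#'   random per miRNA).
#' @param isomir_probs Named probability vector over 3' length offsets
#'   -2..+2 (default 0.1, 0.15, 0.5, 0.15, 0.1).
#' @param contaminant_fraction Fraction of reads drawn from the decoy
#'   contaminant reference (default 0.05).
#' @param lowq_fraction Fraction of reads planted to fail the quality rule
#'   (default 0.02).
#' @param reads_per_library Reads per library (default 500000).
#' @param quality_offset FASTQ quality encoding offset (default 64).
#' @param seed Integer seed.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_mirnas = 60, abundance_meanlog = 6,
                       abundance_sdlog = 2, de_fraction = 0.3,
                       fold_change = 4,
                       isomir_probs = c(`-2` = 0.1, `-1` = 0.15, `0` = 0.5,
                                        `1` = 0.15, `2` = 0.1),
                       contaminant_fraction = 0.05, lowq_fraction = 0.02,
                       reads_per_library = 500000, quality_offset = 64,
                       seed = 1) {
  if (n_mirnas < 2) stop("n_mirnas must be at least 2")
  if (fold_change <= 1) stop("fold_change must exceed 1")
  for (p in c(de_fraction, contaminant_fraction, lowq_fraction)) {
    if (p < 0 || p > 1) stop("fractions must lie in [0, 1]")
  }
  if (contaminant_fraction + lowq_fraction >= 1) {
    stop("contaminant and low-quality fractions must leave room for miRNA reads")
  }
  if (!identical(names(isomir_probs), c("-2", "-1", "0", "1", "2")) ||
      abs(sum(isomir_probs) - 1) > 1e-8) {
    stop("isomir_probs must be named -2..2 and sum to 1")
  }
  structure(list(
    n_mirnas = as.integer(n_mirnas), abundance_meanlog = abundance_meanlog,
    abundance_sdlog = abundance_sdlog, de_fraction = de_fraction,
    fold_change = fold_change, isomir_probs = isomir_probs,
    contaminant_fraction = contaminant_fraction,
    lowq_fraction = lowq_fraction,
    reads_per_library = as.integer(reads_per_library),
    quality_offset = quality_offset, seed = as.integer(seed)
  ), class = "synth_spec")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# TRUE when trimming with all-high qualities leaves the sequence intact,
# i.e. the sequence carries no terminal artifact the preprocessor would eat.
trim_stable <- function(seq) {
  res <- trim_one(strsplit(seq, "", fixed = TRUE)[[1L]],
                  rep(40L, nchar(seq)), 20L, 5L, 3L)
  paste(res$chars, collapse = "") == seq
}

#' Generate a random mature-miRNA catalog
#'
#' Sequences of 20-23 nt with pairwise-distinct 17-nt seeds (rejection
#' sampling); a subset of entries is emitted as -5p/-3p pairs from the same
#' nominal precursor to exercise dual-strand accounting. Sequences are
#' additionally rejected when end trimming would alter them or any of
#' their 3'-shortened isoMIR variants, so that clean synthetic reads pass
#' preprocessing unchanged.
#'
#' @param n Number of catalog entries (>= 2).
#' @param seed Integer seed.
#' @return A `mirna_catalog` data.frame.
#' @export
generate_catalog <- function(n, seed = 1) {
  if (n < 2) stop("n must be at least 2")
  set.seed(seed)
  seqs <- character(0)
  seeds17 <- character(0)
  while (length(seqs) < n) {
    cand <- random_seq(sample(20:23, 1L))
    variants <- vapply(0:2, function(k) substr(cand, 1L, nchar(cand) - k),
                       character(1))
    if (substr(cand, 1L, 17L) %in% seeds17) next
    if (!all(vapply(variants, trim_stable, logical(1)))) next
    seqs <- c(seqs, cand)
    seeds17 <- c(seeds17, substr(cand, 1L, 17L))
  }
  n_pairs <- n %/% 5L
  name <- character(n)
  k <- 1L
  i <- 1L
  while (i <= n) {
    if (k <= n_pairs && i + 1L <= n) {
      name[i] <- sprintf("mir-s%d-5p", k)
      name[i + 1L] <- sprintf("mir-s%d-3p", k)
      i <- i + 2L
    } else {
      name[i] <- sprintf("mir-s%d-5p", k)
      i <- i + 1L
    }
    k <- k + 1L
  }
  mirna_catalog(name, seqs)
}

# 3' variant of a mature sequence at a length offset; positive offsets
# append a fixed per-sequence templated extension chosen to stay
# trim-stable.
isomir_variant <- function(seq, offset) {
  if (offset <= 0) return(substr(seq, 1L, nchar(seq) + offset))
  ext_pool <- c("AC", "AG", "CA", "CT", "GA", "GT", "TC", "TG")
  for (ext in ext_pool) {
    cand <- paste0(seq, substr(ext, 1L, offset))
    if (trim_stable(cand)) return(cand)
  }
  paste0(seq, strrep("A", offset))
}

#' Ground truth and per-library profiles of a synthetic experiment
#'
#' The count-level generator: draws per-miRNA base abundances, plants
#' fold-changes, allocates each library's miRNA read mass multinomially
#' and splits each miRNA's reads over 3' isoMIR variants. Returns
#' `library_profile` objects directly, bypassing FASTQ realization - the
#' fast path for validating the quantification and DE stages.
#'
#' @param spec A [synth_spec()].
#' @param catalog Catalog from [generate_catalog()]; defaults to one
#'   generated from `spec`.
#' @return A list with `profiles` (two `library_profile`s), `truth` (a
#'   data.frame `mirna`, `base_abundance`, `direction`, `prop_1`,
#'   `prop_2`: expected read proportions within each library's miRNA
#'   mass), and `catalog`.
#' @export
generate_library_profiles <- function(spec, catalog = NULL) {
  set.seed(spec$seed)
  if (is.null(catalog)) {
    catalog <- generate_catalog(spec$n_mirnas, seed = spec$seed)
  }
  n <- nrow(catalog)
  base <- stats::rlnorm(n, spec$abundance_meanlog, spec$abundance_sdlog)
  n_de <- floor(spec$de_fraction * n)
  de_idx <- sample(n, n_de)
  direction <- rep("null", n)
  direction[de_idx] <- sample(c("up_in_1", "up_in_2"), n_de, replace = TRUE)
  if (n_de >= 2L && length(unique(direction[de_idx])) == 1L) {
    # keep both directions represented so planted mass can be balanced
    direction[de_idx[1L]] <- setdiff(c("up_in_1", "up_in_2"),
                                     direction[de_idx][1L])
  }
  # Mass-balanced planting: each planted miRNA's expected ratio between
  # libraries is exactly fold_change, while the total planted mass is
  # equal in both libraries. Null miRNAs therefore keep identical
  # expected proportions across libraries (sequencing observes
  # proportions, so unbalanced planting would shift every null feature).
  f <- spec$fold_change
  up1 <- direction == "up_in_1"
  up2 <- direction == "up_in_2"
  ab1 <- base
  ab2 <- base
  if (n_de > 0L) {
    mass_up1 <- sum(base[up1])
    mass_up2 <- sum(base[up2])
    if (mass_up1 > 0 && mass_up2 > 0) {
      # scale a (up-in-1) and b (up-in-2) chosen so a*f*U1 + b*U2 =
      # a*U1 + b*f*U2, i.e. a*U1 = b*U2; normalized to keep total mass
      a <- mass_up2
      b <- mass_up1
      norm1 <- (a * f * mass_up1 + b * mass_up2) /
               (a * mass_up1 + b * mass_up2)
      ab1[up1] <- base[up1] * a * f / norm1
      ab1[up2] <- base[up2] * b / norm1
      ab2[up1] <- base[up1] * a / norm1
      ab2[up2] <- base[up2] * b * f / norm1
    } else {
      ab1[up1] <- base[up1] * f
      ab2[up2] <- base[up2] * f
    }
  }

  mirna_mass <- 1 - spec$contaminant_fraction - spec$lowq_fraction
  n_mirna_reads <- round(mirna_mass * spec$reads_per_library)

  make_profile <- function(ab, lib_id) {
    props <- ab / sum(ab)
    counts <- stats::rmultinom(1L, n_mirna_reads, props)[, 1L]
    breakdown <- vector("list", n)
    names(breakdown) <- catalog$name
    offs <- as.integer(names(spec$isomir_probs))
    for (i in seq_len(n)) {
      if (counts[i] == 0L) next
      vc <- stats::rmultinom(1L, counts[i], spec$isomir_probs)[, 1L]
      vs <- vapply(offs, function(o) isomir_variant(catalog$seq[i], o),
                   character(1))
      keep <- vc > 0L
      breakdown[[i]] <- stats::setNames(vc[keep], vs[keep])
    }
    keep <- counts > 0L
    structure(list(
      library_id = lib_id,
      total_raw_reads = spec$reads_per_library,
      total_clean_reads = sum(counts),
      per_mirna = stats::setNames(as.integer(counts[keep]),
                                  catalog$name[keep]),
      isomir_breakdown = breakdown[keep],
      unassigned = 0L, ambiguous_discarded = 0L
    ), class = "library_profile")
  }
  profiles <- list(make_profile(ab1, "lib1"), make_profile(ab2, "lib2"))
  truth <- data.frame(mirna = catalog$name, base_abundance = base,
                      direction = direction,
                      prop_1 = ab1 / sum(ab1), prop_2 = ab2 / sum(ab2))
  list(profiles = profiles, truth = truth, catalog = catalog)
}

random_qual <- function(n, lo, hi) sample(lo:hi, n, replace = TRUE)

# A planted low-quality read: >= 85% of positions below Q20, so it fails
# the default quality rule (bad fraction >= 0.8) with margin.
lowq_read <- function() {
  len <- sample(15:28, 1L)
  n_bad <- ceiling(0.85 * len)
  qual <- c(random_qual(n_bad, 2L, 19L),
            random_qual(len - n_bad, 20L, 40L))
  list(seq = random_seq(len), qual = sample(qual))
}

#' Generate a full synthetic two-library FASTQ experiment
#'
#' Realizes the count-level model of [generate_library_profiles()] as
#' FASTQ reads: miRNA reads as isoMIR variant sequences with clean
#' qualities, contaminant reads as exact substrings of a generated decoy
#' reference (so contaminant screening removes them), and low-quality
#' reads that fail the default quality filter. Read identifiers carry the
#' source label (`mir=<name>`, `src=contaminant`, `src=lowq`) for
#' validation. Writes two FASTQ files, the catalog FASTA, the decoy FASTA
#' and a ground-truth TSV into `dir`.
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory.
#' @param catalog Optional pre-built catalog.
#' @return A list with paths (`fastq_1`, `fastq_2`, `catalog_fasta`,
#'   `decoy_fasta`, `truth_tsv`), the `truth` data.frame, the `catalog`,
#'   and the expected per-library clean-read proportions.
#' @export
generate_libraries <- function(spec, dir, catalog = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_library_profiles(spec, catalog)
  catalog <- gen$catalog
  set.seed(spec$seed + 104729L)  # independent stream for read realization

  decoys <- vapply(1:3, function(i) random_seq(2000L), character(1))
  decoy_fasta <- file.path(dir, "decoys.fa")
  writeLines(as.vector(rbind(sprintf(">decoy%d synthetic", 1:3), decoys)),
             decoy_fasta)
  catalog_fasta <- file.path(dir, "catalog.fa")
  writeLines(as.vector(rbind(paste0(">", catalog$name), catalog$seq)),
             catalog_fasta)

  n_cont <- round(spec$contaminant_fraction * spec$reads_per_library)
  n_lowq <- round(spec$lowq_fraction * spec$reads_per_library)

  make_fastq <- function(profile, path) {
    seqs <- unlist(lapply(profile$isomir_breakdown, function(b)
      rep(names(b), b)), use.names = FALSE)
    labels <- unlist(mapply(function(nm, b) rep(nm, sum(b)),
                            names(profile$isomir_breakdown),
                            profile$isomir_breakdown, SIMPLIFY = FALSE),
                     use.names = FALSE)
    labels <- paste0("mir=", labels)
    if (n_cont > 0L) {
      lens <- sample(18:25, n_cont, replace = TRUE)
      ref <- sample(3L, n_cont, replace = TRUE)
      starts <- vapply(seq_len(n_cont), function(i)
        sample.int(2000L - lens[i] + 1L, 1L), integer(1))
      seqs <- c(seqs, substring(decoys[ref], starts, starts + lens - 1L))
      labels <- c(labels, rep("src=contaminant", n_cont))
    }
    if (n_lowq > 0L) {
      lq <- replicate(n_lowq, lowq_read(), simplify = FALSE)
      seqs <- c(seqs, vapply(lq, `[[`, character(1), "seq"))
      labels <- c(labels, rep("src=lowq", n_lowq))
    }
    qual <- lapply(nchar(seqs), random_qual, lo = 25L, hi = 40L)
    if (n_lowq > 0L) {
      idx <- seq(length(seqs) - n_lowq + 1L, length(seqs))
      qual[idx] <- lapply(seq_len(n_lowq), function(i) lq[[i]]$qual)
    }
    ord <- sample(length(seqs))
    reads <- structure(list(
      read_id = sprintf("r%07d %s", seq_along(ord), labels[ord]),
      seq = seqs[ord], qual = qual[ord]
    ), class = "fastq_reads")
    write_fastq(reads, path, spec$quality_offset)
    path
  }
  fq1 <- make_fastq(gen$profiles[[1L]], file.path(dir, "lib1.fastq.gz"))
  fq2 <- make_fastq(gen$profiles[[2L]], file.path(dir, "lib2.fastq.gz"))
  truth_tsv <- file.path(dir, "ground_truth.tsv")
  utils::write.table(gen$truth, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fastq_1 = fq1, fastq_2 = fq2, catalog_fasta = catalog_fasta,
       decoy_fasta = decoy_fasta, truth_tsv = truth_tsv,
       truth = gen$truth, catalog = catalog, profiles = gen$profiles)
}
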