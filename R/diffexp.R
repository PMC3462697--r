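#' Simulation parameters for no-replicate differential expression
#'
#' The no-replicate statistic simulates technical replicates of each
#' library by multinomial resampling of its counts. Defaults are the
#' published defaults of the simulated-replicate method: `nss = 5`
#' replicates per condition, each sequenced to a depth drawn uniformly from
#' `pnr` plus/minus `v` times the library's clean total.
#'
#' @param nss Number of simulated replicates per condition (>= 2).
#' @param pnr Simulated depth as a fraction of the library total (0 < pnr <= 1).
#' @param v Half-width of the uniform depth jitter (0 <= v < pnr).
#' @param seed Integer seed; all randomness in the DE stage flows from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(nss = 5, pnr = 0.2, v = 0.02, seed = 1) {
  if (nss < 2) stop("nss must be at least 2")
  if (pnr <= 0 || pnr > 1) stop("pnr must be in (0, 1]")
  if (v < 0 || v >= pnr) stop("v must satisfy 0 <= v < pnr")
  structure(list(nss = as.integer(nss), pnr = pnr, v = v,
                 seed = as.integer(seed)), class = "sim_params")
}

#' Simulate technical replicates of a count vector
#'
#' Each replicate is a multinomial draw with probabilities proportional to
#' the observed counts and size `round(depth_r * sum(counts))`, where
#' `depth_r` is uniform on `[pnr - v, pnr + v]`. Reproducible given
#' `params$seed`.
#'
#' @param counts Non-negative integer vector with positive sum.
#' @param params A [sim_params()] object.
#' @return Integer matrix, `length(counts)` rows by `nss` columns, with the
#'   realized depth fractions in attribute `depths`.
#' @export
simulate_replicates <- function(counts, params = sim_params()) {
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot == 0) stop("all-zero count vector cannot be resampled")
  set.seed(params$seed)
  depths <- stats::runif(params$nss, params$pnr - params$v,
                         params$pnr + params$v)
  sizes <- round(depths * tot)
  m <- vapply(sizes, function(s) {
    stats::rmultinom(1L, s, counts / tot)[, 1L]
  }, numeric(length(counts)))
  storage.mode(m) <- "integer"
  rownames(m) <- names(counts)
  attr(m, "depths") <- colSums(m) / tot
  m
}

#' Build the noise cloud from simulated within-condition replicates
#'
#' For every unordered pair of replicates within each condition (both
#' conditions pooled) and every feature, records the pair (|M|, D) computed
#' on normalized expression. These within-condition contrasts carry only
#' technical (resampling) noise; an observed between-condition signal is
#' later ranked against them.
#'
#' @param sim1,sim2 Count matrices from [simulate_replicates()], one per
#'   condition, same feature set.
#' @param normalizer Function `(counts_matrix, condition)` mapping a
#'   replicate count matrix (condition index 1 or 2) to a matrix of
#'   normalized expression values of the same shape.
#' @param pseudo Positive pseudo-expression substituted for zeros in the
#'   log-ratio.
#' @return A data.frame of class `noise_cloud` with columns `absM` and `D`,
#'   `n_features * (choose(nss1, 2) + choose(nss2, 2))` rows.
#' @export
build_noise <- function(sim1, sim2, normalizer, pseudo = 0.5) {
  if (nrow(sim1) != nrow(sim2)) stop("conditions must share a feature set")
  if (ncol(sim1) < 2L || ncol(sim2) < 2L) {
    stop("need at least 2 simulated replicates per condition")
  }
  absM <- numeric(0)
  D <- numeric(0)
  for (m in list(normalizer(sim1, 1L), normalizer(sim2, 2L))) {
    pairs <- utils::combn(ncol(m), 2L)
    for (k in seq_len(ncol(pairs))) {
      md <- m_d_values(m[, pairs[1L, k]], m[, pairs[2L, k]], pseudo)
      absM <- c(absM, abs(md$M))
      D <- c(D, md$D)
    }
  }
  structure(data.frame(absM = absM, D = D),
            class = c("noise_cloud", "data.frame"))
}

#' Probability of differential expression against a noise cloud
#'
#' The probability assigned to a signal (M, D) is the fraction of noise
#' pairs it strictly dominates on both coordinates: `mean(absM_noise <
#' |M| & D_noise < D)`. Ties count against the signal, so equal-noise
#' features are conservatively called not-DE. Monotone non-decreasing in
#' both |M| and D.
#'
#' @param M,D Numeric vectors of signal M-values and D-values (recycled to
#'   common length).
#' @param cloud A `noise_cloud`.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
de_probability <- function(M, D, cloud) {
  if (nrow(cloud) == 0L) stop("empty noise cloud")
  mapply(function(m, d) mean(cloud$absM < abs(m) & cloud$D < d), M, D,
         USE.NAMES = FALSE)
}

#' Call differential expression from probabilities
#'
#' @param contrasts Data.frame with columns `mirna`, `M`, `D`,
#'   `probability`.
#' @param threshold Probability threshold; calls require `probability >
#'   threshold` (default 0.8).
#' @return A data.frame of class `de_calls` with an added `direction`
#'   column (`up_in_1` for positive-M calls, `up_in_2` for negative-M
#'   calls, `not_DE` otherwise), rows ordered by direction group then
#'   descending |M|.
#' @export
call_de <- function(contrasts, threshold = 0.8) {
  if (any(contrasts$probability < 0 | contrasts$probability > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  dir <- ifelse(contrasts$probability <= threshold, "not_DE",
                ifelse(contrasts$M > 0, "up_in_1", "up_in_2"))
  out <- contrasts
  out$direction <- factor(dir, levels = c("up_in_1", "up_in_2", "not_DE"))
  out <- out[order(out$direction, -abs(out$M), out$mirna, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("de_calls", "data.frame")
  out
}

#' No-replicate differential expression between two libraries
#'
#' The full statistic: the observed per-miRNA (M, D) signal is computed
#' from the two libraries' RPKM values; technical replicates of each
#' library are simulated by multinomial resampling of its counts and
#' normalized on the observed per-miRNA RPKM scale; within-condition
#' replicate contrasts form the noise cloud; each miRNA's probability of
#' differential expression is the fraction of noise pairs its signal
#' strictly dominates, and calls require probability above `threshold`.
#'
#' Simulated replicate counts are placed on the observed RPKM scale via the
#' per-miRNA factor `rpkm/count` divided by the replicate's realized depth
#' fraction - algebraically, RPKM with library total equal to the depth
#' fraction times the raw-read total.
#'
#' @param expr Expression table (see [expression_table()], [bger_n5n6()]).
#' @param params A [sim_params()] object (replicate count, depth, jitter,
#'   seed).
#' @param threshold DE probability threshold (default 0.8).
#' @param pseudo_count Pseudo-count converted to RPKM for zero
#'   substitutions in log-ratios (default 0.5).
#' @return A `de_result` list: `calls` (a `de_calls` data.frame with
#'   columns `mirna`, `M`, `D`, `probability`, `direction`), `cloud`
#'   (the `noise_cloud`), `params`, `threshold`.
#' @export
diff_expression <- function(expr, params = sim_params(), threshold = 0.8,
                            pseudo_count = 0.5) {
  scale_med <- median_scale(expr)
  pseudo <- pseudo_count * scale_med
  sig <- contrast_table(expr, pseudo = pseudo)

  scale_for <- function(counts, rpkms) {
    s <- rpkms / counts
    s[!is.finite(s) | s <= 0] <- scale_med
    s
  }
  s1 <- scale_for(expr$count_1, expr$rpkm_1)
  s2 <- scale_for(expr$count_2, expr$rpkm_2)

  p1 <- params
  p2 <- params
  p2$seed <- params$seed + 1L
  sim1 <- simulate_replicates(expr$count_1, p1)
  sim2 <- simulate_replicates(expr$count_2, p2)

  normalizer <- function(m, cond) {
    s <- if (cond == 1L) s1 else s2
    sweep(m * s, 2L, attr(m, "depths"), "/")
  }
  # pseudo for the noise cloud lives on the same depth-corrected scale
  cloud <- build_noise(sim1, sim2, normalizer, pseudo = pseudo)

  prob <- de_probability(sig$M, sig$D, cloud)
  calls <- call_de(data.frame(mirna = sig$mirna, M = sig$M, D = sig$D,
                              probability = prob), threshold)
  structure(list(calls = calls, cloud = cloud, params = params,
                 threshold = threshold, library_ids = attr(expr, "library_ids")),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  n1 <- sum(x$calls$direction == "up_in_1")
  n2 <- sum(x$calls$direction == "up_in_2")
  ids <- if (!is.null(x$library_ids)) x$library_ids else c("1", "2")
  cat("de_result:", nrow(x$calls), "miRNAs;", n1, "up in", ids[1L], "/",
      n2, "up in", ids[2L], "at probability >", x$threshold, "\n")
  invisible(x)
}
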