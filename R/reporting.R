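#' Volcano plot of M-values against D-values
#'
#' Scatter of per-miRNA M (log2 expression ratio, x-axis) against D
#' (absolute expression difference, y-axis), with differentially expressed
#' miRNAs highlighted. D spans several orders of magnitude, so the y-axis
#' is log-scaled by default with a small floor applied to zero values.
#'
#' @param points Data.frame with columns `M`, `D` and logical `is_DE` (a
#'   `de_calls` data.frame is accepted and converted).
#' @param file Optional output path (".png" or ".svg"); when NULL the
#'   ggplot object is returned without writing.
#' @param log_d Log-scale the D axis (default TRUE).
#' @param d_floor Floor applied to D before log scaling (default 0.01).
#' @param cloud Optional `noise_cloud` to draw behind the signal points
#'   (mirrored to both signs of M).
#' @return The ggplot object, invisibly when `file` is given.
#' @export
volcano_plot <- function(points, file = NULL, log_d = TRUE, d_floor = 0.01,
                         cloud = NULL) {
  if (inherits(points, "de_calls")) {
    points <- data.frame(name = points$mirna, M = points$M, D = points$D,
                         is_DE = points$direction != "not_DE")
  }
  if (nrow(points) == 0L) stop("no points to plot")
  points$D_plot <- pmax(points$D, d_floor)
  p <- ggplot2::ggplot()
  if (!is.null(cloud) && nrow(cloud)) {
    cl <- data.frame(M = c(cloud$absM, -cloud$absM),
                     D_plot = pmax(rep(cloud$D, 2L), d_floor))
    p <- p + ggplot2::geom_point(
      data = cl, ggplot2::aes(x = M, y = D_plot),
      colour = "grey70", size = 0.4, alpha = 0.5)
  }
  p <- p +
    ggplot2::geom_point(
      data = points,
      ggplot2::aes(x = M, y = D_plot, colour = is_DE),
      size = 1.4) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "black", `TRUE` = "red"),
      labels = c(`FALSE` = "not DE", `TRUE` = "DE"),
      name = NULL, drop = FALSE) +
    ggplot2::labs(
      x = expression(M == log[2](x[1] / x[2])),
      y = if (log_d) sprintf("D = |x1 - x2| (RPKM, log scale, floor %g)", d_floor)
          else "D = |x1 - x2| (RPKM)") +
    ggplot2::theme_bw()
  if (log_d) p <- p + ggplot2::scale_y_log10()
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) {
      grDevices::svg(file, width = 6, height = 5)
      print(p)
      grDevices::dev.off()
    } else {
      ggplot2::ggsave(file, p, width = 6, height = 5, dpi = 150)
    }
    return(invisible(p))
  }
  p
}

fmt_num <- function(x, digits) {
  formatC(round(x, digits), format = "f", digits = digits)
}

#' Write the expression and differential-expression result tables
#'
#' Writes three TSV files into `dir`: `expression.tsv` (per-miRNA counts
#' and RPKM for both libraries), `de_up_in_1.tsv` (miRNAs called up in
#' library 1, descending |M|) and `de_up_in_2.tsv` (up in library 2,
#' descending |M|). M is rounded to 3 decimals, D to 2, RPKM to 3,
#' probability to 3; re-reading a table reproduces the values at that
#' precision. Output is deterministic given its inputs.
#'
#' @param expr Expression table.
#' @param calls A `de_calls` data.frame (e.g. `diff_expression(...)$calls`).
#' @param dir Output directory (created if needed).
#' @return Character vector of the three paths, invisibly.
#' @export
write_result_tables <- function(expr, calls, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("output directory not writable: ", dir)
  p_expr <- file.path(dir, "expression.tsv")
  etab <- data.frame(miRNA = expr$mirna,
                     counts_1 = expr$count_1, RPKM_1 = fmt_num(expr$rpkm_1, 3),
                     counts_2 = expr$count_2, RPKM_2 = fmt_num(expr$rpkm_2, 3),
                     check.names = FALSE)
  utils::write.table(etab, p_expr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  de_tab <- function(direction) {
    sub <- calls[calls$direction == direction, , drop = FALSE]
    data.frame(miRNA = sub$mirna,
               P = fmt_num(sub$probability, 3),
               `M-value` = fmt_num(sub$M, 3),
               `D-value` = fmt_num(sub$D, 2),
               check.names = FALSE)
  }
  p_up1 <- file.path(dir, "de_up_in_1.tsv")
  p_up2 <- file.path(dir, "de_up_in_2.tsv")
  utils::write.table(de_tab("up_in_1"), p_up1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(de_tab("up_in_2"), p_up2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p_expr, p_up1, p_up2))
}

required_config <- c("libraries", "catalog", "out_dir")

#' Run the full two-library pipeline
#'
#' Executes preprocess, annotate, quantify, differential expression and
#' reporting for a pair of FASTQ libraries, writing result tables, a
#' volcano plot and a machine-readable run manifest into the output
#' directory.
#'
#' @param config A named list, or path to a YAML file, with keys:
#'   `libraries` (list of two `list(id=, fastq=, total_raw_override=)`
#'   entries), `catalog` (mature-miRNA FASTA), `out_dir`, and optionally
#'   `contaminants` (FASTA paths), `quality_offset`, `q_min`,
#'   `bad_fraction`, `homopolymer_min`, `dimer_units_min`, `min_len`,
#'   `max_len`, `ambiguity`, `pool_fraction`, `nss`, `pnr`, `v`,
#'   `threshold`, `pseudo_count`, `seed`.
#' @return A list with `expr`, `de` (the `de_result`), `stats`,
#'   `manifest_path` and `out_dir`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  missing_keys <- setdiff(required_config, names(config))
  if (length(missing_keys)) {
    stop("config is missing required field(s): ",
         paste(missing_keys, collapse = ", "))
  }
  if (length(config$libraries) != 2L) {
    stop("config field 'libraries' must list exactly two libraries")
  }
  cfg <- utils::modifyList(list(
    quality_offset = 64, q_min = 20, bad_fraction = 0.8, homopolymer_min = 5,
    dimer_units_min = 3, min_len = 10, max_len = 28, ambiguity = "discard",
    pool_fraction = 1e-4, nss = 5, pnr = 0.2, v = 0.02, threshold = 0.8,
    pseudo_count = 0.5, seed = 1, contaminants = NULL
  ), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  catalog <- stage("annotate", function() read_mirna_catalog(cfg$catalog))
  index <- if (!is.null(cfg$contaminants) && length(cfg$contaminants)) {
    stage("annotate", function() contaminant_index(cfg$contaminants))
  }

  profiles <- list()
  stats_rows <- list()
  for (lib in cfg$libraries) {
    if (is.null(lib$id) || is.null(lib$fastq)) {
      stop("each library needs fields 'id' and 'fastq'")
    }
    pre <- stage("preprocess", function() preprocess_fastq(
      lib$fastq, quality_offset = cfg$quality_offset, q_min = cfg$q_min,
      bad_fraction = cfg$bad_fraction, homopolymer_min = cfg$homopolymer_min,
      dimer_units_min = cfg$dimer_units_min, min_len = cfg$min_len,
      max_len = cfg$max_len))
    say("preprocess ", lib$id, ": ", pre$stats$n_raw, " raw -> ",
        pre$stats$n_in_length_range, " clean reads (",
        pre$stats$n_unique, " unique)")
    scr <- stage("annotate", function() screen_contaminants(pre$collapsed, index))
    say("screen ", lib$id, ": removed ", sum(scr$removed$count),
        " contaminant reads")
    total_raw <- if (!is.null(lib$total_raw_override)) lib$total_raw_override
                 else pre$stats$n_raw
    prof <- stage("annotate", function() annotate_library(
      scr$kept, catalog, library_id = lib$id, total_raw_reads = total_raw,
      ambiguity = cfg$ambiguity))
    say("annotate ", lib$id, ": ", length(prof$per_mirna), " miRNAs, ",
        sum(prof$per_mirna), " assigned reads, ", prof$unassigned,
        " unassigned, ", prof$ambiguous_discarded, " ambiguous")
    profiles[[lib$id]] <- prof
    stats_rows[[lib$id]] <- cbind(library_id = lib$id, pre$stats)
  }

  filt <- stage("quantify", function() low_abundance_filter(
    profiles, pool_fraction = cfg$pool_fraction))
  say("low-abundance filter: kept ", length(filt$kept), ", dropped ",
      length(filt$dropped))
  expr <- stage("quantify", function() expression_table(
    profiles[[1L]], profiles[[2L]], keep = filt$kept))

  de <- stage("diffexp", function() diff_expression(
    expr, params = sim_params(nss = cfg$nss, pnr = cfg$pnr, v = cfg$v,
                              seed = cfg$seed),
    threshold = cfg$threshold, pseudo_count = cfg$pseudo_count))
  say("diffexp: ", sum(de$calls$direction == "up_in_1"), " up in ",
      cfg$libraries[[1L]]$id, ", ", sum(de$calls$direction == "up_in_2"),
      " up in ", cfg$libraries[[2L]]$id)

  stage("report", function() {
    write_result_tables(expr, de$calls, cfg$out_dir)
    volcano_plot(de$calls, file = file.path(cfg$out_dir, "volcano.png"),
                 cloud = de$cloud)
    volcano_plot(de$calls, file = file.path(cfg$out_dir, "volcano.svg"),
                 cloud = de$cloud)
  })
  stats <- do.call(rbind, stats_rows)
  utils::write.table(stats, file.path(cfg$out_dir, "preprocess_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "mirnoise",
    version = as.character(utils::packageVersion("mirnoise")),
    stages = c("preprocess", "screen", "annotate", "quantify", "diffexp",
               "report"),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("libraries", "out_dir"))],
    libraries = lapply(cfg$libraries, function(l) l[c("id", "fastq")]),
    read_accounting = stats,
    n_mirnas_retained = nrow(expr),
    de_calls = list(
      up_in_1 = sum(de$calls$direction == "up_in_1"),
      up_in_2 = sum(de$calls$direction == "up_in_2"))
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, dataframe = "rows")
  writeLines(log_lines, log_path)
  invisible(list(expr = expr, de = de, stats = stats,
                 manifest_path = manifest_path, out_dir = cfg$out_dir))
}
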