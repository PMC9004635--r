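## Static publication-style visual summaries. Every plot is drawn from an
## already-computed summary table and is written together with a sibling
## TSV of exactly the data drawn, so tests (and downstream users) read the
## export, never pixels.

save_plot_with_data <- function(p, data, path_png, width = 7, height = 4.5) {
  grDevices::png(path_png, width = width * 100, height = height * 100,
                 res = 100)
  print(p)
  grDevices::dev.off()
  write_tsv(data, sub("\\.png$", ".tsv", path_png))
  invisible(path_png)
}

#' Plot the read-length distribution
#' @param length_dist Table from [length_distribution()].
#' @param path_png Output PNG; the drawn data goes to the sibling `.tsv`.
#' @return `path_png`, invisibly.
#' @export
plot_length_distribution <- function(length_dist, path_png) {
  p <- ggplot2::ggplot(length_dist,
                       ggplot2::aes(x = .data$read_length, y = .data$n_reads)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "read length (nt)", y = "reads",
                  title = "Read length distribution") +
    ggplot2::theme_minimal()
  save_plot_with_data(p, length_dist, path_png)
}

#' Plot per-gene reading-frame proportions
#'
#' One point per gene and frame; low-coverage genes are dropped from the
#' display (they remain in the table export).
#'
#' @param frame_props Table from [frame_proportions_per_gene()].
#' @param path_png Output PNG (+ sibling `.tsv`).
#' @return `path_png`, invisibly.
#' @export
plot_frame_proportions <- function(frame_props, path_png) {
  fp <- frame_props[!frame_props$low_coverage & frame_props$n_total > 0, ,
                    drop = FALSE]
  long <- data.frame(
    transcript_id = rep(fp$transcript_id, 3),
    frame = rep(c("0", "+1", "+2"), each = nrow(fp)),
    proportion = c(fp$p0, fp$p1, fp$p2), stringsAsFactors = FALSE)
  long$frame <- factor(long$frame, levels = c("0", "+1", "+2"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$frame,
                                          y = .data$proportion)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = "reading frame", y = "proportion of reads per gene",
                  title = "Per-gene frame proportions") +
    ggplot2::theme_minimal()
  save_plot_with_data(p, frame_props, path_png)
}

#' Plot a metagene profile
#' @param profile A `metagene_profile`.
#' @param path_png Output PNG (+ sibling `.tsv`).
#' @return `path_png`, invisibly.
#' @export
plot_metagene <- function(profile, path_png) {
  anchor <- attr(profile, "anchor") %||% "anchor"
  p <- ggplot2::ggplot(as.data.frame(profile),
                       ggplot2::aes(x = .data$rel_position, y = .data$count)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = paste("nt relative to", anchor), y = "5' end count",
                  title = "Metagene profile") +
    ggplot2::theme_minimal()
  save_plot_with_data(p, as.data.frame(profile), path_png)
}

#' Heatmap of a ribogrid
#'
#' Footprint counts arranged by 5' position (x, 1-based labels) and read
#' length (y, ascending), log1p colour scale; start and stop codon
#' positions are marked. The data export contains the nonzero cells.
#'
#' @param grid A `ribogrid`.
#' @param path_png Output PNG (+ sibling `.tsv` of nonzero cells).
#' @param region Optional `c(p1, p2)` 0-based inclusive position window.
#' @return `path_png`, invisibly.
#' @export
plot_ribogrid_heatmap <- function(grid, path_png, region = NULL) {
  if (is.null(region)) region <- c(0L, grid$transcript_length - 1L)
  if (region[1] < 0 || region[2] >= grid$transcript_length) {
    stop("region outside transcript")
  }
  m <- slice_ribogrid(grid, position_window = region)
  nz <- which(m > 0L, arr.ind = TRUE)
  cells <- data.frame(
    read_length = grid$min_length + nz[, 1L] - 1L,
    pos5 = region[1] + nz[, 2L] - 1L,
    count = m[nz])
  if (nrow(cells) == 0) {
    cells <- data.frame(read_length = integer(), pos5 = integer(),
                        count = integer())
  }
  p <- ggplot2::ggplot(cells,
                       ggplot2::aes(x = .data$pos5 + 1, y = .data$read_length,
                                    fill = log1p(.data$count))) +
    ggplot2::geom_tile() +
    ggplot2::geom_vline(xintercept = grid$cds_start + 1, linetype = 2) +
    ggplot2::geom_vline(xintercept = grid$cds_end, linetype = 2) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::lims(x = c(region[1] + 1, region[2] + 1),
                  y = c(grid$min_length, grid$max_length)) +
    ggplot2::labs(x = "5' end position (1-based)", y = "read length (nt)",
                  title = paste("Ribogrid:", grid$transcript_id)) +
    ggplot2::theme_minimal()
  save_plot_with_data(p, cells, path_png)
}

#' Scatter of codon-specific density vs a per-codon feature
#' @param per_codon The `per_codon` table from
#'   [codon_feature_correlation()].
#' @param path_png Output PNG (+ sibling `.tsv`).
#' @return `path_png`, invisibly.
#' @export
plot_codon_feature <- function(per_codon, path_png) {
  p <- ggplot2::ggplot(per_codon,
                       ggplot2::aes(x = .data$feature,
                                    y = .data$mean_norm_density)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "codon feature (e.g. tRNA gene copies)",
                  y = "mean normalised ribosome density",
                  title = "Codon density vs feature") +
    ggplot2::theme_minimal()
  save_plot_with_data(p, per_codon, path_png)
}

#' Render all standard plots for one sample
#'
#' @param grids A `ribogrid_set`.
#' @param annotation An `annotation_set`.
#' @param offsets An `asite_offset_table`.
#' @param outdir Output directory.
#' @param heatmap_transcript Transcript for the example heatmap (default:
#'   the one with most footprints).
#' @param feature_table Optional per-codon feature for the scatter.
#' @param min_reads Coverage threshold passed through to the statistics.
#' @return Named vector of PNG paths (class `plot_set` semantics: each has
#'   a sibling `.tsv` data export).
#' @export
render_plots <- function(grids, annotation, offsets, outdir,
                         heatmap_transcript = NULL, feature_table = NULL,
                         min_reads = 64L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- c()
  out["length_distribution"] <- plot_length_distribution(
    length_distribution(grids), file.path(outdir, "length_distribution.png"))
  out["frame_proportions"] <- plot_frame_proportions(
    frame_proportions_per_gene(grids, annotation, offsets,
                               min_reads = min_reads),
    file.path(outdir, "frame_proportions.png"))
  out["metagene"] <- plot_metagene(
    metagene_profile(grids, annotation, "start_codon"),
    file.path(outdir, "metagene_start.png"))
  if (is.null(heatmap_transcript) && length(grids$grids) > 0) {
    tot <- vapply(grids$grids, function(g) sum(g$counts), numeric(1))
    heatmap_transcript <- names(tot)[which.max(tot)]
  }
  if (!is.null(heatmap_transcript)) {
    out["ribogrid_heatmap"] <- plot_ribogrid_heatmap(
      grids$grids[[heatmap_transcript]],
      file.path(outdir, "ribogrid_heatmap.png"))
  }
  if (!is.null(feature_table)) {
    cf <- codon_feature_correlation(codon_densities(grids, annotation,
                                                    offsets),
                                    annotation, feature_table,
                                    min_reads = min_reads)
    out["codon_feature"] <- plot_codon_feature(
      cf$per_codon, file.path(outdir, "codon_feature.png"))
  }
  out
}

embed_png <- function(path) {
  if (!file.exists(path)) return(NULL)
  raw <- readBin(path, "raw", file.size(path))
  paste0("data:image/png;base64,", jsonlite::base64_enc(raw))
}

html_table <- function(df, max_rows = 15L) {
  df <- head(df, max_rows)
  head_row <- paste0("<tr>", paste0("<th>", names(df), "</th>",
                                    collapse = ""), "</tr>")
  body <- apply(df, 1L, function(r) {
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
  })
  paste0("<table border='1' cellpadding='3'>", head_row,
         paste(body, collapse = ""), "</table>")
}

#' Combine plots and tables into a single self-contained HTML report
#'
#' Images are base64-embedded; missing plots yield a visible placeholder
#' rather than an error. With a pinned `timestamp` the output is
#' byte-stable for identical inputs.
#'
#' @param plot_files Named character vector of PNG paths (e.g. from
#'   [render_plots()]).
#' @param summary_tables Named list of data.frames shown (truncated) in the
#'   report.
#' @param path Output `.html` path.
#' @param sample_name Shown in the header.
#' @param timestamp Report timestamp string; pass a fixed value for
#'   reproducible bytes.
#' @return `path`, invisibly.
#' @export
render_html_report <- function(plot_files, summary_tables, path,
                               sample_name = "sample",
                               timestamp = "1970-01-01T00:00:00Z") {
  sections <- character(0)
  for (nm in names(plot_files)) {
    uri <- embed_png(plot_files[[nm]])
    sections <- c(sections, paste0("<h2>", nm, "</h2>"),
                  if (is.null(uri)) {
                    paste0("<p><em>plot missing: ", plot_files[[nm]],
                           "</em></p>")
                  } else {
                    paste0("<img src='", uri, "' alt='", nm, "'/>")
                  })
  }
  for (nm in names(summary_tables)) {
    tb <- summary_tables[[nm]]
    sections <- c(sections, paste0("<h2>", nm, "</h2>"),
                  if (is.null(tb) || nrow(tb) == 0) {
                    "<p><em>no data</em></p>"
                  } else html_table(tb))
  }
  if (length(sections) == 0) sections <- "<p><em>no data</em></p>"
  html <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'/>",
            paste0("<title>ribogridkit report: ", sample_name, "</title>"),
            "</head><body>",
            paste0("<h1>ribogridkit sample report: ", sample_name, "</h1>"),
            paste0("<p>generated ", timestamp, " by ribogridkit ",
                   as.character(packageVersion("ribogridkit")), "</p>"),
            sections, "</body></html>")
  writeLines(html, path)
  invisible(path)
}
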