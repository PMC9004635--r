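## YAML-driven orchestration: validate a run configuration, then execute
## the stage sequence (demultiplex -> extract-umi -> [external alignment]
## -> trim-5p-mismatch -> dedup -> filter -> build-ribogrid -> summarize ->
## report) per sample, with a machine-readable run manifest.

config_defaults <- function() {
  list(
    fasta = NULL, gff3 = NULL,
    offsets = NULL,                 # TSV path; NULL = shipped eukaryote table
    asite_anchor = "five_prime",
    barcode_sheet = NULL,
    trna_table = NULL,
    samples = NULL,                 # named list: sample -> bam (or fastq)
    output_dir = "ribogridkit_out",
    demultiplex = FALSE,
    extract_umi = FALSE,
    umi5_length = 0L, umi3_length = 0L,
    dedup = FALSE,
    trim_5p = TRUE,
    max_trim = 2L,
    max_mismatches = 1L,
    min_length = 10L, max_length = 50L,
    min_reads = 64L,
    metagene_window = 25L,
    frame_from = "asite",
    seed = 1L,
    timestamp = "1970-01-01T00:00:00Z")
}

#' Validate a YAML run configuration
#'
#' Parses the YAML, rejects unknown keys by name, fills documented
#' defaults, checks every referenced path and parameter range, and returns
#' either a complete `run_config` or the *full* list of errors (never only
#' the first). A config is valid given only `fasta`, `gff3` and one
#' sample.
#'
#' @param path YAML file, or a named list (already parsed).
#' @return A list of class `run_config`, or an error of class
#'   `config_error` whose message lists every problem.
#' @export
validate_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else path
  defaults <- config_defaults()
  errors <- character(0)

  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    errors <- c(errors, paste0("unknown configuration key(s): ",
                               paste(unknown, collapse = ", ")))
  }
  cfg <- defaults
  for (k in intersect(names(raw), names(defaults))) cfg[[k]] <- raw[[k]]

  need_file <- function(key, required = FALSE) {
    v <- cfg[[key]]
    if (is.null(v)) {
      if (required) errors <<- c(errors, paste0("missing required key: ", key))
      return()
    }
    if (!file.exists(v)) {
      errors <<- c(errors, paste0(key, " file not found: ", v))
    }
  }
  need_file("fasta", required = TRUE)
  need_file("gff3", required = TRUE)
  need_file("offsets"); need_file("barcode_sheet"); need_file("trna_table")

  if (is.null(cfg$samples) || length(cfg$samples) == 0) {
    errors <- c(errors, "at least one sample (name: path) is required")
  } else {
    for (s in names(cfg$samples)) {
      if (!file.exists(cfg$samples[[s]])) {
        errors <- c(errors, paste0("sample '", s, "' input not found: ",
                                   cfg$samples[[s]]))
      }
    }
  }
  if (cfg$min_length > cfg$max_length) {
    errors <- c(errors, paste0("min_length (", cfg$min_length,
                               ") > max_length (", cfg$max_length, ")"))
  }
  for (k in c("max_trim", "max_mismatches", "min_reads", "metagene_window",
              "umi5_length", "umi3_length")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0) {
      errors <- c(errors, paste0(k, " must be a non-negative number"))
    }
  }
  if (!cfg$asite_anchor %in% c("five_prime", "three_prime")) {
    errors <- c(errors, "asite_anchor must be five_prime or three_prime")
  }
  if (!cfg$frame_from %in% c("asite", "five_prime")) {
    errors <- c(errors, "frame_from must be asite or five_prime")
  }
  if (cfg$demultiplex && is.null(cfg$barcode_sheet)) {
    errors <- c(errors, "demultiplex: true requires a barcode_sheet")
  }
  if (cfg$extract_umi && cfg$umi5_length + cfg$umi3_length == 0) {
    errors <- c(errors, "extract_umi: true requires umi5_length or umi3_length > 0")
  }
  if (cfg$dedup && !cfg$extract_umi) {
    # dedup needs UMI-suffixed identifiers; BAM input may already carry them
    if (is.null(cfg$samples) ||
        !all(grepl("\\.bam$", unlist(cfg$samples)))) {
      errors <- c(errors, "dedup: true requires extract_umi or BAM input with UMI-suffixed read names")
    }
  }
  if (length(errors) > 0) {
    stop(structure(class = c("config_error", "error", "condition"),
                   list(message = paste0("invalid configuration:\n  - ",
                                         paste(errors, collapse = "\n  - ")),
                        call = NULL, errors = errors)))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full per-sample pipeline from a configuration
#'
#' Validates the configuration before any computation, then runs the
#' enabled stages for each sample in order. A failing sample never aborts
#' the others: its error is recorded and the run manifest marks it
#' `failed`. Outputs per sample: ribogrid H5, summary TSVs, plots and an
#' HTML report. The run manifest records every output file with its md5,
#' the parameters, and the package version -- enough to re-execute the
#' run.
#'
#' @param config Path to a YAML config, a named list, or a `run_config`.
#' @return Data.frame run manifest (also written to
#'   `<output_dir>/run_manifest.tsv`), one row per file/event; attribute
#'   `"sample_status"` is a named vector `ok`/`failed`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  annotation <- load_annotation(cfg$fasta, cfg$gff3)
  offsets <- if (is.null(cfg$offsets)) default_asite_offsets() else
    read_asite_offsets(cfg$offsets, cfg$asite_anchor)
  feature_table <- if (is.null(cfg$trna_table)) NULL else {
    ft <- read_tsv(cfg$trna_table)
    names(ft)[1:2] <- c("codon", "value")
    ft
  }

  manifest <- list()
  log_event <- function(sample, stage, file, status = "ok") {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      sample = sample, stage = stage, file = file,
      md5 = if (file.exists(file)) unname(tools::md5sum(file)) else "",
      status = status,
      tool_version = as.character(packageVersion("ribogridkit")),
      stringsAsFactors = FALSE)
  }

  status <- setNames(rep("ok", length(cfg$samples)), names(cfg$samples))
  for (s in names(cfg$samples)) {
    res <- tryCatch({
      run_one_sample(s, cfg$samples[[s]], cfg, annotation, offsets,
                     feature_table, log_event)
      "ok"
    }, error = function(e) paste0("failed: ", conditionMessage(e)))
    status[s] <- res
    if (res != "ok") log_event(s, "sample", cfg$samples[[s]], res)
  }

  mdf <- do.call(rbind, manifest)
  if (is.null(mdf)) {
    mdf <- data.frame(sample = character(), stage = character(),
                      file = character(), md5 = character(),
                      status = character(), tool_version = character())
  }
  params <- cfg[!vapply(cfg, is.null, logical(1))]
  params$samples <- NULL
  mdf <- rbind(mdf, data.frame(
    sample = "*", stage = "config", file = "",
    md5 = "", status = jsonlite::toJSON(params, auto_unbox = TRUE),
    tool_version = as.character(packageVersion("ribogridkit")),
    stringsAsFactors = FALSE))
  write_tsv(mdf, file.path(cfg$output_dir, "run_manifest.tsv"))
  attr(mdf, "sample_status") <- status
  if (any(status != "ok")) {
    warning("sample(s) failed: ",
            paste(names(status)[status != "ok"], collapse = ", "),
            call. = FALSE)
  }
  mdf
}

run_one_sample <- function(sample, input, cfg, annotation, offsets,
                           feature_table, log_event) {
  sdir <- file.path(cfg$output_dir, sample)
  dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
  is_fastq <- grepl("\\.(fastq|fq)(\\.gz)?$", input)

  if (is_fastq) {
    fq <- input
    if (cfg$demultiplex) {
      sheet <- read_barcode_sheet(cfg$barcode_sheet, cfg$max_mismatches)
      counts <- demultiplex(fq, sheet, file.path(sdir, "demux"),
                            counts_tsv = file.path(sdir, "demux_counts.tsv"))
      log_event(sample, "demultiplex", file.path(sdir, "demux_counts.tsv"))
      files <- attr(counts, "files")
      if (!sample %in% names(files)) {
        stop("sample '", sample, "' not present in barcode sheet")
      }
      fq <- files[[sample]]
    }
    if (cfg$extract_umi) {
      out_fq <- file.path(sdir, "umi_extracted.fastq.gz")
      extract_umi_fastq(fq, out_fq,
                        umi_spec(cfg$umi5_length, cfg$umi3_length),
                        fastq_rejected = file.path(sdir, "umi_rejected.fastq"))
      log_event(sample, "extract_umi", out_fq)
      fq <- out_fq
    }
    stop("sample '", sample, "' is FASTQ-only: alignment is delegated to ",
         "an external aligner; supply a transcriptome BAM to continue ",
         "(preprocessed FASTQ left in ", sdir, ")")
  }

  fp <- read_alignments(input)
  if (cfg$trim_5p) {
    tres <- trim_5p_mismatch(fp, max_trim = cfg$max_trim)
    write_tsv(data.frame(category = names(tres$summary),
                         n = unname(tres$summary)),
              file.path(sdir, "trim_summary.tsv"))
    log_event(sample, "trim_5p_mismatch", file.path(sdir, "trim_summary.tsv"))
    fp <- tres$kept
  }
  if (cfg$dedup) {
    dres <- dedup_exact(fp)
    fp <- dres$kept
    log_event(sample, "dedup_exact", "")
  }
  fp <- filter_alignments(fp, annotation, cfg$min_length, cfg$max_length)
  write_tsv(data.frame(reason = names(attr(fp, "filter_report")),
                       n = unname(attr(fp, "filter_report"))),
            file.path(sdir, "filter_report.tsv"))
  log_event(sample, "filter_alignments", file.path(sdir, "filter_report.tsv"))

  grids <- build_ribogrid(fp, annotation, cfg$min_length, cfg$max_length,
                          sample_name = sample)
  h5 <- file.path(sdir, paste0(sample, ".h5"))
  write_ribogrid_h5(grids, h5, source_bam = basename(input),
                    created = cfg$timestamp)
  log_event(sample, "build_ribogrid", h5)

  sfiles <- write_summaries(grids, annotation, offsets, sdir,
                            min_reads = cfg$min_reads,
                            window_codons = cfg$metagene_window,
                            feature_table = feature_table)
  for (f in sfiles) log_event(sample, "summarize", f)

  plots <- render_plots(grids, annotation, offsets, file.path(sdir, "plots"),
                        feature_table = feature_table,
                        min_reads = cfg$min_reads)
  tables <- list(
    read_length_distribution = length_distribution(grids),
    gene_quant = head(read_tsv(sfiles[["gene_quant"]]), 15))
  html <- file.path(sdir, paste0(sample, "_report.html"))
  render_html_report(plots, tables, html, sample_name = sample,
                     timestamp = cfg$timestamp)
  log_event(sample, "report", html)
  invisible(NULL)
}
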