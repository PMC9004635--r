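## Pre-alignment handling of multiplexed Ribo-seq libraries: sample-barcode
## demultiplexing with a Hamming mismatch budget, and UMI extraction into
## read identifiers (underscore-suffix convention, interoperable with
## standard deduplication tools).

#' Read a sample barcode sheet
#'
#' Headerless two-column TSV: sample name, barcode sequence. All barcodes
#' must be the same length and mutually distinguishable: any two barcodes
#' within `2 * max_mismatches` of each other make assignment ambiguous by
#' construction and are a hard error.
#'
#' @param path TSV path.
#' @param max_mismatches Hamming budget per read (default 1).
#' @return An object of class `barcode_sheet`: list with `entries`
#'   (data.frame `sample`, `barcode`), `barcode_length`, `max_mismatches`.
#' @export
read_barcode_sheet <- function(path, max_mismatches = 1L) {
  df <- read_tsv(path, header = FALSE)
  names(df)[1:2] <- c("sample", "barcode")
  barcode_sheet(df$sample, df$barcode, max_mismatches)
}

#' @rdname read_barcode_sheet
#' @param samples,barcodes Parallel vectors of sample names and barcodes.
#' @export
barcode_sheet <- function(samples, barcodes, max_mismatches = 1L) {
  samples <- as.character(samples); barcodes <- toupper(as.character(barcodes))
  if (anyDuplicated(samples)) stop("duplicate sample names in barcode sheet")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in barcode sheet")
  if (length(unique(nchar(barcodes))) != 1) {
    stop("all barcodes must have equal length")
  }
  max_mismatches <- as.integer(max_mismatches)
  if (max_mismatches < 0) stop("max_mismatches must be >= 0")
  if (length(barcodes) > 1) {
    for (i in seq_along(barcodes)[-1]) {
      # strictly inside twice the budget a read can sit closer to the wrong
      # barcode; at exactly 2*max_mismatches ties still resolve (Unassigned)
      d <- hamming_to(barcodes[seq_len(i - 1)], barcodes[i])
      if (any(d < 2L * max_mismatches)) {
        j <- which(d < 2L * max_mismatches)[1]
        stop("barcodes ", barcodes[j], " and ", barcodes[i],
             " are within 2*max_mismatches (", 2L * max_mismatches,
             ") of each other: assignment would be ambiguous")
      }
    }
  }
  structure(list(entries = data.frame(sample = samples, barcode = barcodes,
                                      stringsAsFactors = FALSE),
                 barcode_length = nchar(barcodes[1]),
                 max_mismatches = max_mismatches),
            class = "barcode_sheet")
}

#' Assign reads to samples by barcode
#'
#' Vectorised core of [demultiplex()]: each observed barcode string is
#' assigned to the unique sample whose sheet barcode lies within
#' `max_mismatches` (Hamming). No qualifying sample, or two or more samples
#' tied at the minimal qualifying distance, yields `"Unassigned"` -- ties
#' are resolved conservatively, never first-wins.
#'
#' @param observed Character vector of barcode-length strings.
#' @param sheet A `barcode_sheet`.
#' @return Character vector of sample names or `"Unassigned"`.
#' @export
assign_barcodes <- function(observed, sheet) {
  stopifnot(inherits(sheet, "barcode_sheet"))
  if (length(observed) == 0) return(character(0))
  if (any(nchar(observed) != sheet$barcode_length)) {
    stop("observed barcode length differs from sheet barcode length")
  }
  D <- vapply(sheet$entries$barcode, function(b) hamming_to(observed, b),
              numeric(length(observed)))
  D <- matrix(D, nrow = length(observed))
  best <- apply(D, 1L, min)
  n_best <- rowSums(D == best)
  hit <- max.col(-D, ties.method = "first")
  out <- ifelse(best <= sheet$max_mismatches & n_best == 1L,
                sheet$entries$sample[hit], "Unassigned")
  out
}

## FASTQ in-memory representation: list(id, seq, qual), parallel character
## vectors. Biostrings does the file parsing.
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(id = names(x), seq = unname(as.character(x)),
       qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  q <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

subset_reads <- function(reads, i) {
  list(id = reads$id[i], seq = reads$seq[i], qual = reads$qual[i])
}

#' Demultiplex a FASTQ file by in-read sample barcode
#'
#' The barcode is read from `barcode_offset` (0-based, default 0: the first
#' `L` bases). Reads go to one FASTQ per sample plus an `Unassigned` file;
#' the barcode bases are *not* removed here (composition of this step with
#' [extract_umi()] handles removal). Read conservation holds: input count
#' equals the sum over all output files.
#'
#' @param fastq_path Input FASTQ (optionally gzipped).
#' @param sheet A `barcode_sheet`.
#' @param outdir Output directory (created if needed).
#' @param barcode_offset 0-based offset of the barcode within the read.
#' @param counts_tsv Optional path for the per-sample counts table.
#' @return Data.frame `sample`, `n_reads` (includes `Unassigned`), with
#'   attribute `"files"` naming the written FASTQs.
#' @export
demultiplex <- function(fastq_path, sheet, outdir, barcode_offset = 0L,
                        counts_tsv = NULL) {
  stopifnot(inherits(sheet, "barcode_sheet"))
  reads <- read_fastq(fastq_path)
  L <- sheet$barcode_length
  if (length(reads$seq) > 0 && any(nchar(reads$seq) < barcode_offset + L)) {
    stop("read(s) shorter than barcode_offset + barcode length")
  }
  obs <- substr(reads$seq, barcode_offset + 1L, barcode_offset + L)
  assignment <- if (length(obs)) assign_barcodes(obs, sheet) else character(0)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  groups <- c(sheet$entries$sample, "Unassigned")
  files <- setNames(file.path(outdir, paste0(groups, ".fastq")), groups)
  counts <- integer(length(groups))
  for (gi in seq_along(groups)) {
    i <- which(assignment == groups[gi])
    counts[gi] <- length(i)
    write_fastq(subset_reads(reads, i), files[[gi]])
  }
  res <- data.frame(sample = groups, n_reads = counts,
                    stringsAsFactors = FALSE)
  if (!is.null(counts_tsv)) write_tsv(res, counts_tsv)
  attr(res, "files") <- files
  res
}

#' UMI / in-read barcode layout of a read
#'
#' @param umi5_length,umi3_length UMIs at the read 5' / 3' ends, nt.
#' @param barcode_length Length of an in-read sample barcode to remove,
#'   located at `barcode_offset` (0-based, after no removal). Use 0 for
#'   none. The barcode is assumed to precede the 5' UMI when both present
#'   at offset 0 layouts are composed.
#' @param barcode_offset 0-based position of the in-read barcode.
#' @return An object of class `umi_spec`.
#' @export
umi_spec <- function(umi5_length = 0L, umi3_length = 0L,
                     barcode_length = 0L, barcode_offset = 0L) {
  s <- list(umi5_length = as.integer(umi5_length),
            umi3_length = as.integer(umi3_length),
            barcode_length = as.integer(barcode_length),
            barcode_offset = as.integer(barcode_offset))
  if (any(unlist(s) < 0)) stop("umi_spec fields must be >= 0")
  structure(s, class = "umi_spec")
}

#' Extract UMIs (and an optional in-read barcode) from reads
#'
#' Removes `umi5_length` bases from the 5' end and `umi3_length` from the 3'
#' end of each read (after removing any in-read barcode), slicing the
#' quality string in lockstep, and appends `_<umi5><umi3>` to the read
#' identifier -- the convention consumed by standard UMI deduplication
#' tools. Reads too short to contain the configured layout are routed to a
#' `rejected` stream with a reason, never silently dropped.
#'
#' @param reads A read list from `read_fastq()` (or a file path).
#' @param spec A [umi_spec()].
#' @return List: `reads` (processed), `rejected` (reads + `reason`),
#'   `umi` (character vector parallel to `reads`).
#' @export
extract_umi <- function(reads, spec) {
  stopifnot(inherits(spec, "umi_spec"))
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  need <- spec$umi5_length + spec$umi3_length + spec$barcode_length
  len <- nchar(reads$seq)
  ok <- len > need
  rejected <- subset_reads(reads, !ok)
  rejected$reason <- rep("too_short_for_umi_layout", sum(!ok))
  r <- subset_reads(reads, ok)

  if (spec$barcode_length > 0 && length(r$seq) > 0) {
    b1 <- spec$barcode_offset + 1L
    b2 <- spec$barcode_offset + spec$barcode_length
    r$seq <- paste0(substr(r$seq, 1L, b1 - 1L),
                    substring(r$seq, b2 + 1L))
    r$qual <- paste0(substr(r$qual, 1L, b1 - 1L),
                     substring(r$qual, b2 + 1L))
  }
  len <- nchar(r$seq)
  u5 <- substr(r$seq, 1L, spec$umi5_length)
  u3 <- if (spec$umi3_length > 0) {
    substring(r$seq, len - spec$umi3_length + 1L)
  } else rep("", length(r$seq))
  umi <- paste0(u5, u3)
  r$seq <- substr(r$seq, spec$umi5_length + 1L, len - spec$umi3_length)
  r$qual <- substr(r$qual, spec$umi5_length + 1L, len - spec$umi3_length)
  if (spec$umi5_length + spec$umi3_length > 0 && length(r$id) > 0) {
    # suffix goes on the first identifier token so it survives alignment
    first <- sub("\\s.*$", "", r$id)
    rest <- substring(r$id, nchar(first) + 1L)
    r$id <- paste0(first, "_", umi, rest)
  }
  list(reads = r, rejected = rejected, umi = umi)
}

#' Extract UMIs file-to-file
#'
#' @param fastq_in,fastq_out,fastq_rejected FASTQ paths (rejected optional).
#' @param spec A [umi_spec()].
#' @return Named integer vector `c(n_processed, n_rejected)`, invisibly.
#' @export
extract_umi_fastq <- function(fastq_in, fastq_out, spec,
                              fastq_rejected = NULL) {
  res <- extract_umi(read_fastq(fastq_in), spec)
  write_fastq(res$reads, fastq_out)
  if (!is.null(fastq_rejected)) write_fastq(res$rejected, fastq_rejected)
  invisible(c(n_processed = length(res$reads$id),
              n_rejected = length(res$rejected$id)))
}
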