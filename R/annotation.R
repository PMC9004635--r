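## Transcript annotation: FASTA sequences plus ORF (CDS) intervals from GFF3.
##
## All coordinates held in memory are 0-based half-open: cds_start is the
## first base of the start codon, cds_end is one past the last base of the
## stop codon. 1-based inclusive coordinates exist only at the GFF3 and
## text-report boundaries.

#' Load a transcript annotation from FASTA + GFF3
#'
#' Reads transcript sequences from a FASTA file and ORF coordinates from a
#' GFF3 file whose `seqid` values name FASTA records. Each transcript may
#' carry one CDS (multiple CDS lines for one transcript are merged if
#' contiguous, an error if gapped). GFF3 1-based inclusive `[start, end]`
#' is converted to 0-based half-open `[start - 1, end)`.
#'
#' Transcripts present in the FASTA but lacking any CDS feature are not
#' silently dropped: they are listed in the `no_cds` component. Transcripts
#' whose CDS length is not a multiple of 3 are excluded with a warning by
#' default (frame statistics are undefined for them), or rejected with an
#' error when `on_bad_cds = "error"`.
#'
#' @param fasta_path Path to transcript FASTA.
#' @param gff3_path Path to GFF3 with CDS features in transcript coordinates.
#' @param on_bad_cds `"warn"` (default) to exclude CDSs whose length is not
#'   divisible by 3 with a warning, `"error"` to stop.
#' @return An object of class `annotation_set`: a list with `transcripts`
#'   (data.frame: `transcript_id`, `length`, `cds_start`, `cds_end`, 0-based
#'   half-open), `sequences` (named [Biostrings::DNAStringSet]), `no_cds`
#'   (ids without CDS) and `excluded` (data.frame of excluded ids + reason).
#' @export
load_annotation <- function(fasta_path, gff3_path, on_bad_cds = c("warn", "error")) {
  on_bad_cds <- match.arg(on_bad_cds)
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(gff3_path)) stop("GFF3 file not found: ", gff3_path)

  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate transcript ids in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }

  gff <- read_gff3(gff3_path)
  cds <- gff[gff$type == "CDS", , drop = FALSE]

  bad_seqid <- setdiff(unique(cds$seqid), names(seqs))
  if (length(bad_seqid) > 0) {
    stop("GFF3 seqid(s) absent from FASTA: ", paste(bad_seqid, collapse = ", "))
  }
  if (any(cds$strand == "-")) {
    stop("minus-strand CDS on a transcript is not meaningful for ",
         "transcriptome annotation: ",
         paste(unique(cds$seqid[cds$strand == "-"]), collapse = ", "))
  }

  tx_len <- setNames(Biostrings::width(seqs), names(seqs))
  excluded <- data.frame(transcript_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  rows <- list()
  for (id in unique(cds$seqid)) {
    feats <- cds[cds$seqid == id, , drop = FALSE]
    feats <- feats[order(feats$start), , drop = FALSE]
    # merge multi-line CDS; only contiguous pieces form one ORF
    if (nrow(feats) > 1 && any(feats$start[-1] != feats$end[-nrow(feats)] + 1)) {
      stop("gapped CDS for transcript ", id,
           ": multiple CDS lines must be contiguous in transcript coordinates")
    }
    start0 <- feats$start[1] - 1L              # 0-based inclusive
    end0 <- feats$end[nrow(feats)]             # 0-based exclusive
    if (start0 < 0 || end0 > tx_len[[id]]) {
      stop("CDS [", feats$start[1], ",", feats$end[nrow(feats)],
           "] extends beyond transcript ", id, " (length ", tx_len[[id]], ")")
    }
    if ((end0 - start0) %% 3L != 0L) {
      msg <- paste0("CDS length ", end0 - start0, " of transcript ", id,
                    " is not a multiple of 3")
      if (on_bad_cds == "error") stop(msg)
      warning(msg, "; transcript excluded", call. = FALSE)
      excluded <- rbind(excluded, data.frame(
        transcript_id = id, reason = "cds_length_not_multiple_of_3",
        stringsAsFactors = FALSE))
      next
    }
    rows[[id]] <- data.frame(transcript_id = id, length = unname(tx_len[[id]]),
                             cds_start = start0, cds_end = end0,
                             stringsAsFactors = FALSE)
  }

  # keep FASTA order: deterministic iteration
  kept_ids <- names(seqs)[names(seqs) %in% names(rows)]
  transcripts <- do.call(rbind, rows[kept_ids])
  if (is.null(transcripts)) {
    transcripts <- data.frame(transcript_id = character(), length = integer(),
                              cds_start = integer(), cds_end = integer(),
                              stringsAsFactors = FALSE)
  }
  rownames(transcripts) <- NULL
  no_cds <- setdiff(names(seqs), c(unique(cds$seqid)))

  structure(list(transcripts = transcripts,
                 sequences = seqs[transcripts$transcript_id],
                 no_cds = no_cds, excluded = excluded),
            class = "annotation_set")
}

## GFF3 read via rtracklayer, flattened to the 5 columns every caller needs.
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             type = as.character(gr$type),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$transcripts), "transcripts with CDS,",
      length(x$no_cds), "without CDS,", nrow(x$excluded), "excluded\n")
  invisible(x)
}

#' Number of transcripts with a usable CDS
#' @param annotation An `annotation_set`.
#' @return Integer count.
#' @export
n_transcripts <- function(annotation) nrow(annotation$transcripts)

#' Write an annotation set back to FASTA + GFF3
#'
#' Inverse of [load_annotation()]: coordinates are converted back to
#' 1-based inclusive GFF3 convention, so `load_annotation(write_annotation(x))`
#' reproduces `x` exactly.
#'
#' @param annotation An `annotation_set`.
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_annotation <- function(annotation, fasta_path, gff3_path) {
  Biostrings::writeXStringSet(annotation$sequences, fasta_path)
  tr <- annotation$transcripts
  gff_lines <- c("##gff-version 3",
                 sprintf("%s\tribogridkit\tCDS\t%d\t%d\t.\t+\t0\tID=%s.CDS",
                         tr$transcript_id, tr$cds_start + 1L, tr$cds_end,
                         tr$transcript_id))
  writeLines(gff_lines, gff3_path)
  invisible(c(fasta = fasta_path, gff3 = gff3_path))
}

#' Validate start and stop codons of annotated ORFs
#'
#' Checks, per transcript, whether the CDS begins with ATG and ends with a
#' stop codon (TAA/TAG/TGA). Failures are reported, never fatal:
#' non-canonical starts are biologically valid.
#'
#' @param annotation An `annotation_set` (must carry sequences).
#' @param check_codons If `FALSE`, only coordinates are tabulated.
#' @return A data.frame with one row per transcript: `transcript_id`,
#'   `length`, `cds_start_1based`, `cds_end_1based`, `start_codon`,
#'   `stop_codon`, `start_ok`, `stop_ok`, `flags`.
#' @export
validate_annotation <- function(annotation, check_codons = TRUE) {
  tr <- annotation$transcripts
  if (nrow(tr) == 0) {
    return(data.frame(transcript_id = character(), length = integer(),
                      cds_start_1based = integer(), cds_end_1based = integer(),
                      start_codon = character(), stop_codon = character(),
                      start_ok = logical(), stop_ok = logical(),
                      flags = character(), stringsAsFactors = FALSE))
  }
  rep_df <- data.frame(transcript_id = tr$transcript_id, length = tr$length,
                       cds_start_1based = tr$cds_start + 1L,
                       cds_end_1based = tr$cds_end,
                       stringsAsFactors = FALSE)
  if (check_codons) {
    seqs <- annotation$sequences[tr$transcript_id]
    rep_df$start_codon <- as.character(Biostrings::subseq(
      seqs, tr$cds_start + 1L, tr$cds_start + 3L))
    rep_df$stop_codon <- as.character(Biostrings::subseq(
      seqs, tr$cds_end - 2L, tr$cds_end))
    rep_df$start_ok <- rep_df$start_codon == "ATG"
    rep_df$stop_ok <- rep_df$stop_codon %in% STOP_CODONS
    rep_df$flags <- paste0(ifelse(rep_df$start_ok, "", "noncanonical_start;"),
                           ifelse(rep_df$stop_ok, "", "no_stop_codon;"))
  } else {
    rep_df$start_codon <- rep_df$stop_codon <- NA_character_
    rep_df$start_ok <- rep_df$stop_ok <- NA
    rep_df$flags <- ""
  }
  rownames(rep_df) <- NULL
  rep_df
}

## Fetch per-transcript CDS coordinates as a lookup (used by downstream
## modules); errors on unknown ids so grid/annotation mismatches surface.
annotation_lookup <- function(annotation, ids) {
  tr <- annotation$transcripts
  idx <- match(ids, tr$transcript_id)
  if (anyNA(idx)) {
    stop("transcript id(s) not in annotation: ",
         paste(head(ids[is.na(idx)], 5), collapse = ", "))
  }
  tr[idx, , drop = FALSE]
}
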