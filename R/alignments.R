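## Transcriptome BAM handling. Alignments are carried in-memory as a
## "footprint table": one row per BAM record with 0-based coordinates.
## Columns: qname, flag, transcript_id, pos5 (0-based leftmost aligned
## reference base), read_length (aligned nt, soft clips excluded), pos3,
## mapq, cigar, seq, qual, md, nm.

#' Read a transcriptome BAM into a footprint table
#'
#' Wraps [Rsamtools::scanBam()]; SAM's 1-based POS is converted to the
#' package's 0-based `pos5` at this boundary. `read_length` is the aligned
#' span on the read excluding soft clips; for the ungapped alignments this
#' package targets it equals the reference span, and `pos3 = pos5 +
#' read_length - 1`.
#'
#' @param bam_path Path to BAM (or SAM with `is_sam = TRUE`).
#' @param is_sam Convert from SAM first.
#' @return A data.frame footprint table (see file header for columns).
#' @export
read_alignments <- function(bam_path, is_sam = FALSE) {
  if (!file.exists(bam_path)) stop("no such file: ", bam_path)
  if (is_sam) {
    tmp <- tempfile(fileext = "")
    bam_path <- Rsamtools::asBam(bam_path, tmp, overwrite = TRUE,
                                 indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = c("MD", "NM"))
  x <- Rsamtools::scanBam(bam_path, param = p)[[1]]
  n <- length(x$qname)
  df <- data.frame(
    qname = x$qname,
    flag = x$flag,
    transcript_id = as.character(x$rname),
    pos5 = ifelse(is.na(x$pos), NA_integer_, x$pos - 1L),
    mapq = x$mapq,
    cigar = x$cigar,
    seq = as.character(x$seq),
    qual = as.character(x$qual),
    md = if (is.null(x$tag$MD)) rep(NA_character_, n) else x$tag$MD,
    nm = if (is.null(x$tag$NM)) rep(NA_integer_, n) else x$tag$NM,
    stringsAsFactors = FALSE)
  df$read_length <- cigar_aligned_length(df$cigar)
  df$pos3 <- df$pos5 + df$read_length - 1L
  df
}

## Aligned read length from CIGAR: sum of M/=/X operations (soft clips,
## insertions against the reference excluded). NA for missing CIGAR.
cigar_aligned_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

## SAM @SQ header lines for an annotation set.
sam_header <- function(annotation) {
  tr <- annotation$transcripts
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", tr$transcript_id, tr$length))
}

#' Write a footprint table as BAM
#'
#' Emits SAM text (1-based POS at this boundary) and converts with
#' [Rsamtools::asBam()].
#'
#' @param footprints Footprint table.
#' @param annotation An `annotation_set` supplying the `@SQ` header.
#' @param bam_path Output path (final file gets `.bam` appended by
#'   Rsamtools if absent; the returned value is the real path).
#' @return Path to the written BAM.
#' @export
write_alignments <- function(footprints, annotation, bam_path) {
  fp <- footprints
  sam <- tempfile(fileext = ".sam")
  mapped <- !is.na(fp$pos5)
  lines <- character(nrow(fp))
  opt <- function(ok, fmt, v) ifelse(ok & !is.na(v), sprintf(fmt, v), "")
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  fp$qname, fp$flag,
                  ifelse(mapped, fp$transcript_id, "*"),
                  ifelse(mapped, fp$pos5 + 1L, 0L),
                  ifelse(is.na(fp$mapq), 255L, fp$mapq),
                  ifelse(mapped & !is.na(fp$cigar), fp$cigar, "*"),
                  fp$seq, fp$qual)
  body <- paste0(body, opt(mapped, "\tMD:Z:%s", fp$md),
                 opt(mapped, "\tNM:i:%d", fp$nm))
  writeLines(c(sam_header(annotation), body), sam)
  dest <- sub("\\.bam$", "", bam_path)
  out <- Rsamtools::asBam(sam, dest, overwrite = TRUE,
                          indexDestination = FALSE)
  file.remove(sam)
  out
}

#' Filter alignments to the footprint stream entering the ribogrid
#'
#' Keeps primary, mapped, plus-strand records whose aligned length lies in
#' `[min_length, max_length]`. Every rejected record is counted by reason;
#' kept + rejected always equals the input count.
#'
#' @param alignments Footprint table from [read_alignments()].
#' @param annotation An `annotation_set`; mapped reference names outside it
#'   are an error.
#' @param min_length,max_length Inclusive aligned-length bounds.
#' @return The accepted footprint table, with attribute `"filter_report"`:
#'   named integer vector `c(accepted, unmapped, secondary, supplementary,
#'   minus_strand, too_short, too_long)`.
#' @export
filter_alignments <- function(alignments, annotation, min_length = 10L,
                              max_length = 50L) {
  fp <- alignments
  flag <- fp$flag
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- !unmapped & bitwAnd(flag, 256L) != 0L
  supplementary <- !unmapped & !secondary & bitwAnd(flag, 2048L) != 0L
  minus <- !unmapped & !secondary & !supplementary & bitwAnd(flag, 16L) != 0L
  candidate <- !(unmapped | secondary | supplementary | minus)
  too_short <- candidate & fp$read_length < min_length
  too_long <- candidate & fp$read_length > max_length
  keep <- candidate & !too_short & !too_long

  bad_ref <- setdiff(unique(fp$transcript_id[keep]),
                     annotation$transcripts$transcript_id)
  if (length(bad_ref) > 0) {
    stop("BAM reference name(s) absent from annotation: ",
         paste(head(bad_ref, 5), collapse = ", "))
  }
  report <- c(accepted = sum(keep), unmapped = sum(unmapped),
              secondary = sum(secondary), supplementary = sum(supplementary),
              minus_strand = sum(minus), too_short = sum(too_short),
              too_long = sum(too_long))
  out <- fp[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- report
  out
}

## ---- MD-tag arithmetic ------------------------------------------------

## Read offsets (0-based) of substitution mismatches described by an MD tag,
## valid for ungapped ("<n>M") alignments. Deletions (^) are not expected
## here; their presence raises an error so gapped records are handled by the
## caller's pass-through path.
md_mismatch_offsets <- function(md) {
  if (grepl("^", md, fixed = TRUE)) stop("MD tag with deletion: ", md)
  toks <- regmatches(md, gregexpr("[0-9]+|[A-Z]", md))[[1]]
  off <- integer(0)
  pos <- 0L
  for (t in toks) {
    if (grepl("^[0-9]", t)) {
      pos <- pos + as.integer(t)
    } else {
      off <- c(off, pos)
      pos <- pos + 1L
    }
  }
  off
}

## Number of consecutive mismatches anchored at read offset 0.
md_leading_mismatches <- function(md) {
  off <- md_mismatch_offsets(md)
  k <- 0L
  while (k < length(off) && off[k + 1L] == k) k <- k + 1L
  k
}

## Drop the first k (leading-mismatch) entries of an MD tag.
md_strip_leading <- function(md, k) {
  for (i in seq_len(k)) md <- sub("^0[A-Z]", "", md)
  if (md == "" || grepl("^[A-Z]", md)) md <- paste0("0", md)
  md
}

#' Trim non-templated 5' mismatches from transcriptome alignments
#'
#' Some viral reverse transcriptases append non-templated bases to cDNA 5'
#' ends; after alignment these appear as a run of mismatches anchored at
#' read offset 0 and shift the apparent 5' end, distorting reading-frame
#' statistics. For each primary, plus-strand, ungapped record this locates
#' the run of `k` consecutive mismatched bases starting at offset 0 (from
#' the MD tag) and, when `k <= max_trim`, removes those bases from
#' sequence/quality, advances POS by `k`, and rewrites CIGAR, MD and NM
#' consistently. Records with `k > max_trim` go to the discard stream
#' (likely mis-mappings). An isolated internal mismatch never triggers
#' trimming. Gapped 5' termini pass through untrimmed with a warning count.
#'
#' The operation is idempotent: a trimmed record has no offset-0 mismatch.
#'
#' @param alignments Footprint table (with `md`/`nm` columns).
#' @param max_trim Maximum run length to trim (default 2).
#' @return List: `kept` (trimmed/passed footprint table), `discarded`
#'   (rejected rows), `summary` (named integer vector: `n_trimmed_0` ..
#'   `n_trimmed_<max_trim>`, `n_rejected`, `n_gapped_passthrough`,
#'   `n_not_eligible` for unmapped/secondary/minus records passed through).
#' @export
trim_5p_mismatch <- function(alignments, max_trim = 2L) {
  fp <- alignments
  max_trim <- as.integer(max_trim)
  n <- nrow(fp)
  eligible <- !is.na(fp$pos5) &
    bitwAnd(fp$flag, 4L + 16L + 256L + 2048L) == 0L
  simple <- eligible & !is.na(fp$cigar) & grepl("^[0-9]+M$", fp$cigar)
  if (any(eligible & is.na(fp$md))) {
    bad <- fp$qname[eligible & is.na(fp$md)][1]
    stop("record lacks MD tag (no reference available): ", bad)
  }

  k <- integer(n)
  k[simple] <- vapply(fp$md[simple], md_leading_mismatches, integer(1),
                      USE.NAMES = FALSE)
  reject <- simple & k > max_trim
  trim <- simple & !reject & k > 0L

  if (any(trim)) {
    i <- which(trim)
    ki <- k[i]
    fp$seq[i] <- substring(fp$seq[i], ki + 1L)
    fp$qual[i] <- substring(fp$qual[i], ki + 1L)
    fp$pos5[i] <- fp$pos5[i] + ki
    fp$read_length[i] <- fp$read_length[i] - ki
    fp$cigar[i] <- sprintf("%dM", fp$read_length[i])
    fp$md[i] <- mapply(md_strip_leading, fp$md[i], ki, USE.NAMES = FALSE)
    fp$nm[i] <- fp$nm[i] - ki
  }
  fp$pos3 <- fp$pos5 + fp$read_length - 1L

  summary <- setNames(
    c(vapply(0:max_trim, function(j) sum(k[simple & !reject] == j),
             integer(1)),
      sum(reject), sum(eligible & !simple), sum(!eligible)),
    c(sprintf("n_trimmed_%d", 0:max_trim),
      "n_rejected", "n_gapped_passthrough", "n_not_eligible"))

  kept <- fp[!reject, , drop = FALSE]
  rownames(kept) <- NULL
  discarded <- fp[reject, , drop = FALSE]
  rownames(discarded) <- NULL
  list(kept = kept, discarded = discarded, summary = summary)
}

#' Trim 5' mismatches file-to-file
#'
#' BAM-path wrapper around [trim_5p_mismatch()].
#'
#' @param bam_in Input BAM.
#' @param annotation `annotation_set` for the output header.
#' @param bam_out Output BAM of kept records.
#' @param bam_discarded Optional output BAM of rejected records.
#' @param max_trim See [trim_5p_mismatch()].
#' @param summary_tsv Optional path for the trim-count summary.
#' @return The summary vector, invisibly.
#' @export
trim_5p_mismatch_bam <- function(bam_in, annotation, bam_out,
                                 bam_discarded = NULL, max_trim = 2L,
                                 summary_tsv = NULL) {
  res <- trim_5p_mismatch(read_alignments(bam_in), max_trim = max_trim)
  write_alignments(res$kept, annotation, bam_out)
  if (!is.null(bam_discarded)) {
    write_alignments(res$discarded, annotation, bam_discarded)
  }
  if (!is.null(summary_tsv)) {
    write_tsv(data.frame(category = names(res$summary),
                         n = unname(res$summary)), summary_tsv)
  }
  invisible(res$summary)
}

#' Remove exact UMI duplicates
#'
#' Among alignments sharing (transcript, 5' position, read length, UMI
#' string) only the first in sort order (transcript, position, qname) is
#' kept. The UMI is taken from the `_<UMI>` suffix of the read identifier,
#' the convention written by [extract_umi()]. Exact string matching only;
#' near-miss UMIs are treated as distinct molecules.
#'
#' @param footprints Footprint table whose qnames carry UMI suffixes.
#' @return List: `kept` (deduplicated table), `n_removed`.
#' @export
dedup_exact <- function(footprints) {
  fp <- footprints
  has_umi <- grepl("_[ACGTN]+$", fp$qname)
  if (!all(has_umi)) {
    stop("read lacks _UMI identifier suffix: ", fp$qname[!has_umi][1])
  }
  umi <- sub("^.*_", "", fp$qname)
  ord <- order(fp$transcript_id, fp$pos5, fp$qname)
  fp <- fp[ord, , drop = FALSE]
  key <- paste(fp$transcript_id, fp$pos5, fp$read_length, umi[ord], sep = "\r")
  keep <- !duplicated(key)
  out <- fp[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(kept = out, n_removed = sum(!keep))
}
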