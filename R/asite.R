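## A-site assignment: per-read-length displacement from either read end to
## the first nucleotide of the A-site codon.

#' Construct an A-site offset table
#'
#' Associates each usable read length with a displacement (in nt) from an
#' anchor end of the read to the **first nucleotide of the A-site codon**.
#' With a `five_prime` anchor the A-site nucleotide is `pos5 + offset`;
#' with a `three_prime` anchor it is `(pos5 + length - 1) - offset`
#' (eukaryotic protocols typically anchor 5', bacterial 3'). Read lengths
#' absent from the table contribute no A-site assignment and are tallied
#' as exclusions downstream.
#'
#' @param offsets Named integer vector or list: names are read lengths (nt),
#'   values are displacements (nt, `0 <= offset < length`).
#' @param anchor `"five_prime"` or `"three_prime"`.
#' @return An object of class `asite_offset_table`.
#' @examples
#' tab <- asite_offset_table(c(`28` = 15, `29` = 15), anchor = "five_prime")
#' asite_position(100, 28, tab)  # 115
#' @export
asite_offset_table <- function(offsets, anchor = c("five_prime", "three_prime")) {
  anchor <- match.arg(anchor)
  offsets <- unlist(offsets)
  if (is.null(names(offsets)) || any(!nzchar(names(offsets)))) {
    stop("offsets must be named by read length")
  }
  lens <- as.integer(names(offsets))
  offs <- as.integer(offsets)
  if (anyNA(lens) || anyNA(offs)) stop("offsets must be integer-valued")
  if (any(offs < 0) || any(offs >= lens)) {
    stop("each displacement must satisfy 0 <= offset < read_length")
  }
  structure(list(anchor = anchor, offsets = setNames(offs, lens)),
            class = "asite_offset_table")
}

#' Default eukaryote-style A-site offsets
#'
#' The conventional yeast-style table: 5'-anchored displacements of
#' 14--16 nt for 26--32 nt footprints (15 for the canonical 28-mer).
#' Users with other organisms or protocols supply their own table.
#'
#' @return An `asite_offset_table` with anchor `five_prime`.
#' @export
default_asite_offsets <- function() {
  asite_offset_table(
    c(`26` = 14, `27` = 14, `28` = 15, `29` = 15, `30` = 15,
      `31` = 16, `32` = 16),
    anchor = "five_prime")
}

#' Read / write an A-site offset table as TSV
#'
#' The file has a header `read_length<TAB>offset`; the anchor is not stored
#' in the file (it comes from run configuration) and must be supplied.
#'
#' @param path TSV path.
#' @param anchor Anchor end for the loaded table.
#' @param table An `asite_offset_table` (for writing).
#' @return The table (read) or the path, invisibly (write).
#' @export
read_asite_offsets <- function(path, anchor = c("five_prime", "three_prime")) {
  anchor <- match.arg(anchor)
  df <- read_tsv(path)
  if (!all(c("read_length", "offset") %in% names(df))) {
    stop("offset TSV must have columns read_length and offset")
  }
  asite_offset_table(setNames(df$offset, df$read_length), anchor)
}

#' @rdname read_asite_offsets
#' @export
write_asite_offsets <- function(table, path) {
  write_tsv(data.frame(read_length = as.integer(names(table$offsets)),
                       offset = unname(table$offsets)), path)
}

#' @export
print.asite_offset_table <- function(x, ...) {
  cat("asite_offset_table (anchor:", x$anchor, ")\n")
  print(x$offsets)
  invisible(x)
}

#' Invert the anchor of an offset table
#'
#' For a fixed read length `l`, a 5'-anchored displacement `d` addresses the
#' same nucleotide as a 3'-anchored displacement `l - 1 - d`. This helper
#' returns the equivalent table with the opposite anchor.
#'
#' @param table An `asite_offset_table`.
#' @return The equivalent table anchored at the other end.
#' @export
flip_asite_anchor <- function(table) {
  lens <- as.integer(names(table$offsets))
  flipped <- lens - 1L - table$offsets
  asite_offset_table(setNames(flipped, lens),
                     if (table$anchor == "five_prime") "three_prime" else "five_prime")
}

#' A-site nucleotide position of a footprint
#'
#' Vectorised over `pos5`/`length`. Returns the 0-based transcript position
#' of the first nucleotide of the A-site codon, or `NA` for read lengths
#' absent from the table (such footprints are excluded, never guessed).
#' Positions outside the transcript must be screened by the caller (the
#' transcript length is not known here).
#'
#' @param pos5 0-based position(s) of the footprint 5' end.
#' @param length Aligned read length(s), nt.
#' @param table An `asite_offset_table`.
#' @return Integer vector; `NA` where the length is not in the table.
#' @export
asite_position <- function(pos5, length, table) {
  stopifnot(inherits(table, "asite_offset_table"))
  off <- table$offsets[as.character(length)]
  pos5 <- as.integer(pos5)
  length <- as.integer(length)
  if (table$anchor == "five_prime") {
    as.integer(pos5 + off)
  } else {
    as.integer(pos5 + length - 1L - off)
  }
}

#' Reading frame of a transcript position relative to the start codon
#'
#' `(a - cds_start) mod 3` with the mathematical mod, so positions upstream
#' of the start codon also land in \{0, 1, 2\} (e.g. `cds_start - 1` is
#' frame 2). Frame 0 is the primary (annotated) frame.
#'
#' @param a 0-based nucleotide position(s).
#' @param cds_start 0-based position of the first base of the start codon.
#' @return Integer vector in \{0, 1, 2\}; `NA` propagates.
#' @export
frame_of_position <- function(a, cds_start) {
  as.integer(pos_mod(as.integer(a) - as.integer(cds_start), 3L))
}

#' Codon-level ribosome density of one transcript
#'
#' Applies [asite_position()] to every nonzero ribogrid cell and increments
#' the codon `(a - cds_start) %/% 3` for A-sites falling inside the CDS.
#' Footprints whose length is not in the offset table, whose A-site falls
#' outside the transcript, or whose A-site falls outside the CDS (UTRs /
#' pads) are tallied by exclusion reason; the conservation
#' `sum(density) + sum(exclusions) == sum(grid)` always holds.
#'
#' @param grid A `ribogrid` (see [build_ribogrid()]).
#' @param annot One-row annotation for the same transcript (or an
#'   `annotation_set`, from which the row is selected).
#' @param table An `asite_offset_table`.
#' @return A list of class `codon_density`: `transcript_id`, `counts`
#'   (integer vector, one per CDS codon), `cds_length_codons`, and
#'   `exclusions` (named integer vector: `unlisted_length`,
#'   `out_of_transcript`, `outside_cds`).
#' @export
codon_density_from_grid <- function(grid, annot, table) {
  stopifnot(inherits(grid, "ribogrid"))
  if (inherits(annot, "annotation_set")) {
    annot <- annotation_lookup(annot, grid$transcript_id)
  }
  if (annot$transcript_id != grid$transcript_id) {
    stop("annotation/grid transcript mismatch: ", annot$transcript_id,
         " vs ", grid$transcript_id)
  }
  n_codons <- (annot$cds_end - annot$cds_start) %/% 3L
  counts <- integer(n_codons)
  excl <- c(unlisted_length = 0L, out_of_transcript = 0L, outside_cds = 0L)

  nz <- which(grid$counts > 0L, arr.ind = TRUE)
  if (nrow(nz) > 0) {
    lens <- grid$min_length + nz[, 1L] - 1L
    pos5 <- nz[, 2L] - 1L
    w <- grid$counts[nz]
    a <- asite_position(pos5, lens, table)

    unlisted <- is.na(a)
    excl[["unlisted_length"]] <- sum(w[unlisted])
    a <- a[!unlisted]; w <- w[!unlisted]

    oot <- a < 0L | a >= grid$transcript_length
    excl[["out_of_transcript"]] <- sum(w[oot])
    a <- a[!oot]; w <- w[!oot]

    inside <- a >= annot$cds_start & a < annot$cds_end
    excl[["outside_cds"]] <- sum(w[!inside])
    a <- a[inside]; w <- w[inside]

    if (length(a) > 0) {
      codon <- (a - annot$cds_start) %/% 3L + 1L
      tab <- tapply(w, codon, sum)
      counts[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  structure(list(transcript_id = grid$transcript_id, counts = counts,
                 cds_length_codons = n_codons, exclusions = excl),
            class = "codon_density")
}

#' Codon densities for every transcript in a ribogrid set
#'
#' @param grids A `ribogrid_set`.
#' @param annotation An `annotation_set` covering every grid.
#' @param table An `asite_offset_table`.
#' @return Named list of `codon_density`, in grid order.
#' @export
codon_densities <- function(grids, annotation, table) {
  lapply(grids$grids, codon_density_from_grid, annot = annotation, table = table)
}

#' Export codon densities as a long TSV
#' @param densities List of `codon_density`.
#' @param path Output TSV (`transcript_id`, `codon_index`, `count`);
#'   codon_index is 0-based (codon 0 is the start codon).
#' @export
write_codon_densities <- function(densities, path) {
  df <- do.call(rbind, lapply(densities, function(d) {
    data.frame(transcript_id = d$transcript_id,
               codon_index = seq_along(d$counts) - 1L,
               count = d$counts, stringsAsFactors = FALSE)
  }))
  write_tsv(df, path)
}
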