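# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from stored data files.

# Write a FASTA + GFF3 pair to a scratch dir and return the paths.
write_fixture_annotation <- function(records, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixann")
    dir.create(dir)
  }
  fasta <- file.path(dir, "fix.fasta")
  gff3 <- file.path(dir, "fix.gff3")
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]]$seq)
  })), fasta)
  gff_lines <- "##gff-version 3"
  for (id in names(records)) {
    r <- records[[id]]
    if (!is.null(r$cds)) {
      gff_lines <- c(gff_lines, sprintf(
        "%s\tfixture\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.CDS",
        id, r$cds[1], r$cds[2], r$strand %||% "+", id))
    }
  }
  writeLines(gff_lines, gff3)
  list(fasta = fasta, gff3 = gff3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A 60 nt transcript whose CDS (1-based 16..45) is ATG + 8 codons + TAA.
fixture_t1_seq <- function(start_codon = "ATG", stop_codon = "TAA") {
  paste0(strrep("GT", 7), "A",                       # 15 nt 5' pad
         start_codon, strrep("GCT", 8), stop_codon,  # 30 nt CDS
         strrep("CA", 7), "C")                       # 15 nt 3' pad
}

# Minimal in-memory annotation_set with one transcript.
fixture_annotation <- function(seq = fixture_t1_seq(), id = "T1",
                               cds_start = 15L, cds_end = 45L) {
  dna <- Biostrings::DNAStringSet(seq)
  names(dna) <- id
  structure(list(
    transcripts = data.frame(transcript_id = id, length = nchar(seq),
                             cds_start = cds_start, cds_end = cds_end,
                             stringsAsFactors = FALSE),
    sequences = dna, no_cds = character(0),
    excluded = data.frame(transcript_id = character(), reason = character(),
                          stringsAsFactors = FALSE)),
    class = "annotation_set")
}

# Footprint-table row(s) for perfectly matching reads on an annotation.
fixture_footprints <- function(annotation, transcript_id, pos5, read_length,
                               qname = NULL) {
  seqs <- annotation$sequences
  n <- length(pos5)
  if (n == 0) {
    return(data.frame(qname = character(), flag = integer(),
                      transcript_id = character(), pos5 = integer(),
                      mapq = integer(), cigar = character(),
                      seq = character(), qual = character(),
                      md = character(), nm = integer(),
                      read_length = integer(), pos3 = integer(),
                      stringsAsFactors = FALSE))
  }
  seq <- vapply(seq_len(n), function(i) {
    as.character(Biostrings::subseq(seqs[[transcript_id[i]]],
                                    pos5[i] + 1L, pos5[i] + read_length[i]))
  }, "")
  data.frame(qname = qname %||% sprintf("fx%03d", seq_len(n)),
             flag = 0L, transcript_id = transcript_id,
             pos5 = as.integer(pos5), mapq = 255L,
             cigar = sprintf("%dM", read_length), seq = seq,
             qual = strrep("I", read_length),
             md = as.character(read_length), nm = 0L,
             read_length = as.integer(read_length),
             pos3 = as.integer(pos5 + read_length - 1L),
             stringsAsFactors = FALSE)
}

# The recurring 3-footprint grid: T1 (60 nt), (28,10) x2 and (30,11),
# bounds 25..35.
fixture_three_footprint_grid <- function() {
  ann <- fixture_annotation()
  fp <- fixture_footprints(ann, rep("T1", 3), c(10L, 10L, 11L),
                           c(28L, 28L, 30L))
  build_ribogrid(fp, ann, 25L, 35L)
}

# In-memory FASTQ read list.
fixture_reads <- function(seqs, ids = sprintf("q%03d", seq_along(seqs))) {
  list(id = ids, seq = seqs, qual = strrep("I", nchar(seqs)))
}

# Independent mismatch oracle: compare read bases to the reference.
naive_mismatch_offsets <- function(seq, transcript_seq, pos5) {
  rd <- strsplit(seq, "")[[1]]
  rf <- strsplit(as.character(Biostrings::subseq(
    transcript_seq, pos5 + 1L, pos5 + nchar(seq))), "")[[1]]
  which(rd != rf) - 1L
}
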