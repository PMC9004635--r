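## Synthetic padded-ORFeome transcriptomes and footprint libraries with a
## per-read ground-truth manifest. Every downstream stage is testable
## against the manifest exactly (counts) or statistically (proportions).
##
## All randomness flows from spec$seed; the transcriptome uses the seed
## itself and the footprint library uses seed + 1. Within footprint
## simulation, molecule-level draws (gene, codon, frame, length, UMI, PCR
## copies, barcode) happen before 5' non-templated-addition draws, so two
## runs differing only in p_5p_addition share identical molecules.

#' Specification of a simulated Ribo-seq experiment
#'
#' Defaults describe a compact but realistic eukaryote-style library: a
#' padded ORFeome (fixed 50 nt pads), footprints 26--32 nt dominated by
#' 28-mers, strong primary-frame preference (0.85/0.10/0.05), and the
#' shipped 5'-anchored A-site displacements as planted truth.
#'
#' @param n_transcripts Number of transcripts.
#' @param cds_codon_range Inclusive range of CDS lengths, in codons,
#'   counting both the start and the stop codon (CDS nt = 3 x codons).
#' @param pad_length Fixed pad on both transcript ends, nt.
#' @param length_weights Named probabilities of read lengths (sum 1).
#' @param frame_weights Probabilities of the A-site landing in frame
#'   0/1/2 (sum 1).
#' @param offsets_truth `asite_offset_table` used to place 5' ends from
#'   planted A-sites; every name of `length_weights` must be present.
#' @param per_codon_dwell Optional named vector over the 61 sense codons:
#'   relative dwell (occupancy) rates; `NULL` for uniform.
#' @param abundance_sdlog sdlog of the log-normal planted gene abundances.
#' @param depth Number of molecules drawn (before PCR duplication).
#' @param p_5p_addition Probability a read gains 1--2 non-templated 5'
#'   bases (sampled to always mismatch the reference).
#' @param pcr_duplication Mean copies per molecule (1 = no duplication;
#'   copies are `1 + Poisson(mean - 1)`).
#' @param umi5_length,umi3_length UMI lengths, nt (0 = no UMI).
#' @param barcodes Optional named character vector sample -> barcode for a
#'   multiplexed library.
#' @param barcode_mismatch_weights Probabilities that a read's barcode is
#'   planted with 0, 1, 2 mismatches.
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_transcripts = 100L,
                            cds_codon_range = c(80L, 250L),
                            pad_length = 50L,
                            length_weights = c(`26` = 0.03, `27` = 0.07,
                                               `28` = 0.60, `29` = 0.15,
                                               `30` = 0.08, `31` = 0.05,
                                               `32` = 0.02),
                            frame_weights = c(0.85, 0.10, 0.05),
                            offsets_truth = default_asite_offsets(),
                            per_codon_dwell = NULL,
                            abundance_sdlog = 1,
                            depth = 50000L,
                            p_5p_addition = 0,
                            pcr_duplication = 1,
                            umi5_length = 0L, umi3_length = 0L,
                            barcodes = NULL,
                            barcode_mismatch_weights = c(0.90, 0.08, 0.02),
                            seed = 1L) {
  stopifnot(abs(sum(length_weights) - 1) < 1e-9,
            abs(sum(frame_weights) - 1) < 1e-9,
            all(length_weights >= 0), all(frame_weights >= 0),
            p_5p_addition >= 0, p_5p_addition <= 1,
            pcr_duplication >= 1)
  lens <- as.integer(names(length_weights))
  missing_len <- setdiff(lens, as.integer(names(offsets_truth$offsets)))
  if (length(missing_len) > 0) {
    stop("offsets_truth lacks displacement for read length(s): ",
         paste(missing_len, collapse = ", "))
  }
  if (!is.null(per_codon_dwell)) {
    if (!all(sense_codons() %in% names(per_codon_dwell))) {
      stop("per_codon_dwell must cover all 61 sense codons")
    }
    if (any(per_codon_dwell <= 0)) stop("dwell rates must be > 0")
  }
  if (!is.null(barcodes)) {
    barcode_sheet(names(barcodes), unname(barcodes))  # validity check
    stopifnot(abs(sum(barcode_mismatch_weights) - 1) < 1e-9)
  }
  structure(list(n_transcripts = as.integer(n_transcripts),
                 cds_codon_range = as.integer(cds_codon_range),
                 pad_length = as.integer(pad_length),
                 length_weights = length_weights,
                 frame_weights = frame_weights,
                 offsets_truth = offsets_truth,
                 per_codon_dwell = per_codon_dwell,
                 abundance_sdlog = abundance_sdlog,
                 depth = as.integer(depth),
                 p_5p_addition = p_5p_addition,
                 pcr_duplication = pcr_duplication,
                 umi5_length = as.integer(umi5_length),
                 umi3_length = as.integer(umi3_length),
                 barcodes = barcodes,
                 barcode_mismatch_weights = barcode_mismatch_weights,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a padded-ORFeome transcriptome
#'
#' Each transcript is `pad + ATG + random sense codons + stop + pad`, with
#' the CDS coordinates recorded exactly. Deterministic under the spec seed.
#'
#' @param spec A [simulation_spec()].
#' @return An `annotation_set` (write to disk with [write_annotation()]).
#' @export
simulate_transcriptome <- function(spec) {
  set.seed(spec$seed)
  codons <- sense_codons()
  ids <- sprintf("G%04d", seq_len(spec$n_transcripts))
  cand_cod <- spec$cds_codon_range[1]:spec$cds_codon_range[2]
  n_cod <- if (length(cand_cod) == 1L) {
    rep(cand_cod, spec$n_transcripts)     # sample() would misread a scalar
  } else {
    sample(cand_cod, spec$n_transcripts, replace = TRUE)
  }
  seqs <- character(spec$n_transcripts)
  for (i in seq_len(spec$n_transcripts)) {
    # n_cod counts all codons incl. start and stop: cds length = 3 * n_cod
    body <- c("ATG", sample(codons, n_cod[i] - 2L, replace = TRUE),
              sample(STOP_CODONS, 1L))
    seqs[i] <- paste0(random_dna(spec$pad_length),
                      paste(body, collapse = ""),
                      random_dna(spec$pad_length))
  }
  cds_len <- 3L * n_cod
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  transcripts <- data.frame(transcript_id = ids,
                            length = nchar(seqs),
                            cds_start = spec$pad_length,
                            cds_end = spec$pad_length + cds_len,
                            stringsAsFactors = FALSE)
  structure(list(transcripts = transcripts, sequences = dna,
                 no_cds = character(0),
                 excluded = data.frame(transcript_id = character(),
                                       reason = character(),
                                       stringsAsFactors = FALSE)),
            class = "annotation_set")
}

#' Simulate an aligned footprint library with ground truth
#'
#' Molecules are drawn per gene in proportion to planted log-normal
#' abundances; within a gene the A-site codon is drawn uniformly over
#' codons 0..(n-2) (stop codon excluded) or in proportion to
#' `per_codon_dwell` of the codon identity; the frame offset and read
#' length follow `frame_weights` / `length_weights`; the 5' position is
#' then derived by inverting `offsets_truth`. Optional UMIs, PCR
#' duplicates, sample barcodes, and non-templated 5' additions (always
#' mismatching the reference) are layered on. Alignments are emitted as if
#' perfectly aligned: positions are ground truth and CIGAR/MD/NM are
#' internally consistent.
#'
#' @param spec A [simulation_spec()].
#' @param annotation The `annotation_set` from [simulate_transcriptome()]
#'   (same spec).
#' @return List of class `simulated_sample`:
#'   `footprints` -- footprint table of the aligned reads (BAM-equivalent;
#'     `pos5`/`read_length` include any 5' addition, as an aligner would
#'     report them);
#'   `manifest` -- per-read truth: `read_id`, `transcript_id`,
#'     `molecule_id`, `codon`, `frame`, `frag_length`, `true_pos5`,
#'     `asite`, `k_added`, `umi`, `sample`, `n_barcode_mut`, `barcode_obs`;
#'   `abundances` -- planted per-gene molecule probabilities;
#'   `spec`.
#' @export
simulate_footprints <- function(spec, annotation) {
  force(annotation)   # must evaluate before seeding (may consume RNG)
  set.seed(spec$seed + 1L)
  tr <- annotation$transcripts
  ntx <- nrow(tr)
  stopifnot(ntx == spec$n_transcripts)

  ab <- rlnorm(ntx, meanlog = 0, sdlog = spec$abundance_sdlog)
  ab <- ab / sum(ab)

  n <- spec$depth
  if (n == 0) {
    empty <- empty_simulated_sample(spec, ab, tr)
    return(empty)
  }
  gene <- sample.int(ntx, n, replace = TRUE, prob = ab)

  # codon identities per gene (for dwell weighting)
  cds_seq <- as.character(Biostrings::subseq(annotation$sequences,
                                             tr$cds_start + 1L, tr$cds_end))
  codon <- integer(n)
  for (g in sort(unique(gene))) {
    i <- which(gene == g)
    nc <- (tr$cds_end[g] - tr$cds_start[g]) %/% 3L  # incl. stop
    cand <- 0:(nc - 2L)                              # sense codons only
    if (is.null(spec$per_codon_dwell)) {
      codon[i] <- sample(cand, length(i), replace = TRUE)
    } else {
      ident <- substring(cds_seq[g], cand * 3L + 1L, cand * 3L + 3L)
      wgt <- unname(spec$per_codon_dwell[ident])
      codon[i] <- sample(cand, length(i), replace = TRUE, prob = wgt)
    }
  }
  frame <- sample(0:2, n, replace = TRUE, prob = spec$frame_weights)
  lens_avail <- as.integer(names(spec$length_weights))
  frag_len <- sample(lens_avail, n, replace = TRUE,
                     prob = spec$length_weights)

  asite <- tr$cds_start[gene] + 3L * codon + frame
  off <- spec$offsets_truth$offsets[as.character(frag_len)]
  true_pos5 <- if (spec$offsets_truth$anchor == "five_prime") {
    asite - off
  } else {
    asite + off - frag_len + 1L
  }
  tx_len <- tr$length[gene]
  if (any(true_pos5 < 0L | true_pos5 + frag_len > tx_len)) {
    stop("planted offset incompatible with read length / pad geometry")
  }

  umi_n <- spec$umi5_length + spec$umi3_length
  umi <- if (umi_n > 0) random_dna_vector(n, umi_n) else rep("", n)

  if (!is.null(spec$barcodes)) {
    smp_idx <- sample.int(length(spec$barcodes), n, replace = TRUE)
    n_mut <- sample(0:2, n, replace = TRUE,
                    prob = spec$barcode_mismatch_weights)
    barcode_obs <- mutate_barcodes(unname(spec$barcodes)[smp_idx], n_mut)
    sample_name <- names(spec$barcodes)[smp_idx]
  } else {
    n_mut <- integer(n)
    barcode_obs <- rep("", n)
    sample_name <- rep("sample", n)
  }

  # PCR duplication: expand molecules into reads
  copies <- if (spec$pcr_duplication > 1) {
    1L + rpois(n, spec$pcr_duplication - 1)
  } else rep(1L, n)
  mol <- rep(seq_len(n), copies)
  nr <- length(mol)

  # non-templated 5' additions: last RNG stage (see file header)
  k <- integer(nr)
  if (spec$p_5p_addition > 0) {
    hit <- runif(nr) < spec$p_5p_addition
    k[hit] <- sample(1:2, sum(hit), replace = TRUE)
    k <- pmin(k, true_pos5[mol])       # cannot extend past transcript start
  }

  manifest <- data.frame(
    read_id = sprintf("r%07d", seq_len(nr)),
    transcript_id = tr$transcript_id[gene[mol]],
    molecule_id = mol,
    codon = codon[mol],
    frame = frame[mol],
    frag_length = frag_len[mol],
    true_pos5 = true_pos5[mol],
    asite = asite[mol],
    k_added = k,
    umi = umi[mol],
    sample = sample_name[mol],
    n_barcode_mut = n_mut[mol],
    barcode_obs = barcode_obs[mol],
    stringsAsFactors = FALSE)

  footprints <- manifest_to_alignments(manifest, annotation,
                                       umi_in_qname = umi_n > 0)
  structure(list(footprints = footprints, manifest = manifest,
                 abundances = setNames(ab, tr$transcript_id), spec = spec),
            class = "simulated_sample")
}

empty_simulated_sample <- function(spec, ab, tr) {
  manifest <- data.frame(read_id = character(), transcript_id = character(),
                         molecule_id = integer(), codon = integer(),
                         frame = integer(), frag_length = integer(),
                         true_pos5 = integer(), asite = integer(),
                         k_added = integer(), umi = character(),
                         sample = character(), n_barcode_mut = integer(),
                         barcode_obs = character(), stringsAsFactors = FALSE)
  footprints <- data.frame(qname = character(), flag = integer(),
                           transcript_id = character(), pos5 = integer(),
                           mapq = integer(), cigar = character(),
                           seq = character(), qual = character(),
                           md = character(), nm = integer(),
                           read_length = integer(), pos3 = integer(),
                           stringsAsFactors = FALSE)
  structure(list(footprints = footprints, manifest = manifest,
                 abundances = setNames(ab, tr$transcript_id), spec = spec),
            class = "simulated_sample")
}

random_dna_vector <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste, collapse = "")
}

## Plant n_mut[i] mismatches at distinct positions of each barcode.
mutate_barcodes <- function(bc, n_mut) {
  out <- bc
  for (i in which(n_mut > 0)) {
    ch <- strsplit(bc[i], "")[[1]]
    pos <- sample(length(ch), n_mut[i])
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    out[i] <- paste(ch, collapse = "")
  }
  out
}

## Build the aligned footprint table (BAM-equivalent rows) from the
## manifest: read = added mismatching bases + exact reference fragment,
## POS shifted left by k, MD/NM consistent by construction.
manifest_to_alignments <- function(manifest, annotation, umi_in_qname) {
  m <- manifest
  tr <- annotation$transcripts
  gi <- match(m$transcript_id, tr$transcript_id)
  aligned_pos5 <- m$true_pos5 - m$k_added
  aligned_len <- m$frag_length + m$k_added

  frag <- character(nrow(m))
  seqs <- annotation$sequences
  for (g in sort(unique(gi))) {
    i <- which(gi == g)
    frag[i] <- as.character(Biostrings::extractAt(
      seqs[[tr$transcript_id[g]]],
      IRanges::IRanges(m$true_pos5[i] + 1L,
                       m$true_pos5[i] + m$frag_length[i])))
  }
  # added bases must mismatch the reference base they align against
  added <- character(nrow(m))
  ref_prefix <- character(nrow(m))
  need <- which(m$k_added > 0)
  if (length(need) > 0) {
    for (j in need) {
      refb <- strsplit(as.character(Biostrings::subseq(
        seqs[[m$transcript_id[j]]], aligned_pos5[j] + 1L,
        m$true_pos5[j])), "")[[1]]
      addb <- vapply(refb, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      added[j] <- paste(addb, collapse = "")
      ref_prefix[j] <- paste(refb, collapse = "")
    }
  }
  md <- ifelse(m$k_added == 0,
               as.character(m$frag_length),
               paste0(vapply(strsplit(ref_prefix, ""), function(b)
                 paste0("0", b, collapse = ""), ""), m$frag_length))
  qname <- if (umi_in_qname) paste0(m$read_id, "_", m$umi) else m$read_id
  data.frame(
    qname = qname, flag = 0L,
    transcript_id = m$transcript_id,
    pos5 = aligned_pos5, mapq = 255L,
    cigar = sprintf("%dM", aligned_len),
    seq = paste0(added, frag),
    qual = strrep("I", aligned_len),
    md = md, nm = m$k_added,
    read_length = aligned_len,
    pos3 = aligned_pos5 + aligned_len - 1L,
    stringsAsFactors = FALSE)
}

#' FASTQ reads of a simulated sample
#'
#' Pre-alignment view: `barcode + 5' UMI + (added bases + fragment) + 3'
#' UMI`, identifiers are the bare read ids (no UMI suffix -- that is what
#' [extract_umi()] adds).
#'
#' @param sim A `simulated_sample`.
#' @return Read list (`id`, `seq`, `qual`) for [demultiplex()] /
#'   [extract_umi()]; write with the internal FASTQ writer via
#'   [simulate_sample_files()].
#' @export
simulated_fastq <- function(sim) {
  m <- sim$manifest
  spec <- sim$spec
  umi5 <- substr(m$umi, 1L, spec$umi5_length)
  umi3 <- substring(m$umi, spec$umi5_length + 1L)
  insert <- substring(sim$footprints$seq, 1L)   # added + fragment
  seq <- paste0(m$barcode_obs, umi5, insert, umi3)
  list(id = m$read_id, seq = seq, qual = strrep("I", nchar(seq)))
}

## ---- manifest-side oracles (independent of the grid builders) ---------

#' Expected ribogrid tally from the manifest
#'
#' Brute-force per-cell tally of the *aligned* reads (5' position and
#' length as an aligner would report them, i.e. including any
#' non-templated addition). Independent of [build_ribogrid()].
#'
#' @param sim A `simulated_sample`.
#' @param annotation The matching `annotation_set`.
#' @param transcript_id One transcript.
#' @param min_length,max_length Grid bounds.
#' @return Integer matrix, rows = lengths, columns = positions (0-based).
#' @export
manifest_grid_tally <- function(sim, annotation, transcript_id,
                                min_length, max_length) {
  ann <- annotation_lookup(annotation, transcript_id)
  m <- sim$manifest[sim$manifest$transcript_id == transcript_id, ,
                    drop = FALSE]
  lens <- min_length:max_length
  tally <- matrix(0L, nrow = length(lens), ncol = ann$length,
                  dimnames = list(read_length = lens,
                                  pos5 = 0:(ann$length - 1L)))
  if (nrow(m) > 0) {
    al_len <- m$frag_length + m$k_added
    al_pos <- m$true_pos5 - m$k_added
    for (j in seq_len(nrow(m))) {
      tally[al_len[j] - min_length + 1L, al_pos[j] + 1L] <-
        tally[al_len[j] - min_length + 1L, al_pos[j] + 1L] + 1L
    }
  }
  tally
}

#' Per-gene expected CDS A-site counts from the manifest
#'
#' Counts manifest reads whose planted A-site codon exists -- by
#' construction every planted A-site lies in the CDS, so this equals the
#' per-gene read count (all transcripts, explicit zeros).
#'
#' @param sim A `simulated_sample`.
#' @param annotation The matching `annotation_set`.
#' @return Data.frame `transcript_id`, `n_reads`.
#' @export
manifest_gene_counts <- function(sim, annotation) {
  ids <- annotation$transcripts$transcript_id
  tab <- table(factor(sim$manifest$transcript_id, levels = ids))
  data.frame(transcript_id = ids, n_reads = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Write all files of a simulated sample
#'
#' FASTA + GFF3 (transcriptome), BAM (aligned reads), FASTQ (raw reads),
#' manifest TSV and the spec as YAML -- everything a pipeline run needs.
#'
#' @param spec A [simulation_spec()].
#' @param outdir Output directory.
#' @return Named character vector of paths; also returns (invisibly
#'   attached as attributes) nothing else -- reload files with the
#'   package readers.
#' @export
simulate_sample_files <- function(spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_transcriptome(spec)
  sim <- simulate_footprints(spec, ann)
  paths <- c(fasta = file.path(outdir, "transcriptome.fasta"),
             gff3 = file.path(outdir, "transcriptome.gff3"),
             bam = file.path(outdir, "sample.bam"),
             fastq = file.path(outdir, "sample.fastq.gz"),
             manifest = file.path(outdir, "manifest.tsv"),
             spec = file.path(outdir, "simulation_spec.yaml"))
  write_annotation(ann, paths["fasta"], paths["gff3"])
  write_alignments(sim$footprints, ann, paths["bam"])
  write_fastq(simulated_fastq(sim), paths["fastq"])
  write_tsv(sim$manifest, paths["manifest"])
  spec_out <- sim$spec
  spec_out$offsets_truth <- list(
    anchor = spec$offsets_truth$anchor,
    offsets = as.list(spec$offsets_truth$offsets))
  yaml::write_yaml(spec_out, paths["spec"])
  paths
}
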