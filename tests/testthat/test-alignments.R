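test_that("footprint tables survive a BAM write/read roundtrip", {
  spec <- simulation_spec(n_transcripts = 8L, depth = 500L,
                          p_5p_addition = 0.2, seed = 21L)
  ann <- simulate_transcriptome(spec)
  sim <- simulate_footprints(spec, ann)
  bam <- tempfile(fileext = ".bam")
  write_alignments(sim$footprints, ann, bam)
  back <- read_alignments(bam)
  back <- back[order(match(back$qname, sim$footprints$qname)), ]
  rownames(back) <- NULL
  cols <- c("qname", "flag", "transcript_id", "pos5", "cigar", "seq",
            "qual", "md", "nm", "read_length", "pos3")
  expect_equal(back[cols], sim$footprints[cols])
})

test_that("alignment filtering counts every rejection reason and conserves records", {
  ann <- fixture_annotation()
  ok <- fixture_footprints(ann, rep("T1", 2), c(10L, 12L), c(28L, 30L))
  short <- fixture_footprints(ann, "T1", 5L, 9L)
  unmapped <- ok[1, ]; unmapped$flag <- 4L; unmapped$pos5 <- NA_integer_
  secondary <- ok[1, ]; secondary$flag <- 256L
  fp <- rbind(ok, short, unmapped, secondary)

  out <- filter_alignments(fp, ann, min_length = 10L, max_length = 50L)
  rep <- attr(out, "filter_report")
  expect_equal(nrow(out), 2L)
  expect_equal(rep[["accepted"]], 2L)
  expect_equal(rep[["unmapped"]], 1L)
  expect_equal(rep[["secondary"]], 1L)
  expect_equal(rep[["too_short"]], 1L)
  expect_equal(sum(rep), nrow(fp))  # accepted + all reasons == input

  # empty input
  empty <- filter_alignments(fp[0, ], ann)
  expect_equal(nrow(empty), 0L)
  expect_true(all(attr(empty, "filter_report") == 0L))

  # unknown reference
  bad <- ok; bad$transcript_id <- "GHOST"
  expect_error(filter_alignments(bad, ann), "GHOST")
})

test_that("filter report matches the simulation manifest composition", {
  spec <- simulation_spec(n_transcripts = 10L, depth = 2000L, seed = 3L)
  ann <- simulate_transcriptome(spec)
  sim <- simulate_footprints(spec, ann)
  out <- filter_alignments(sim$footprints, ann, 10L, 50L)
  rep <- attr(out, "filter_report")
  expect_equal(rep[["accepted"]], nrow(sim$manifest))
  expect_equal(sum(rep), nrow(sim$manifest))  # nothing rejected
})

test_that("5' mismatch trimming rewrites POS/CIGAR/MD/NM consistently", {
  ann <- fixture_annotation()
  clean <- fixture_footprints(ann, "T1", 10L, 28L)

  # no mismatches: identity
  res <- trim_5p_mismatch(clean, max_trim = 2L)
  expect_equal(res$kept, clean)
  expect_equal(res$summary[["n_trimmed_0"]], 1L)

  # one leading mismatch: reconstruct against the reference
  one <- clean
  ref_base <- substr(one$seq, 1, 1)
  sub_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  one$seq <- paste0(sub_base, substring(one$seq, 2))
  one$md <- paste0("0", ref_base, "27")
  one$nm <- 1L
  res1 <- trim_5p_mismatch(one, max_trim = 2L)
  expect_equal(res1$kept$pos5, 11L)
  expect_equal(res1$kept$read_length, 27L)
  expect_equal(res1$kept$nm, 0L)
  expect_equal(res1$kept$cigar, "27M")
  expect_equal(res1$kept$md, "27")
  # independent naive re-aligner: no mismatch anywhere after trimming
  expect_equal(naive_mismatch_offsets(res1$kept$seq, ann$sequences[["T1"]],
                                      res1$kept$pos5), integer(0))

  # three leading mismatches exceed max_trim = 2: rejected
  three <- clean
  ref3 <- substr(three$seq, 1, 3)
  sub3 <- vapply(strsplit(ref3, "")[[1]], function(b) {
    setdiff(c("A", "C", "G", "T"), b)[1]
  }, "")
  three$seq <- paste0(paste(sub3, collapse = ""), substring(three$seq, 4))
  three$md <- paste0(paste0("0", strsplit(ref3, "")[[1]], collapse = ""), "25")
  three$nm <- 3L
  res3 <- trim_5p_mismatch(three, max_trim = 2L)
  expect_equal(nrow(res3$kept), 0L)
  expect_equal(nrow(res3$discarded), 1L)
  expect_equal(res3$summary[["n_rejected"]], 1L)
})

test_that("an isolated internal mismatch never triggers trimming", {
  ann <- fixture_annotation()
  fp <- fixture_footprints(ann, "T1", 10L, 28L)
  ref_base <- substr(fp$seq, 5, 5)
  fp$seq <- paste0(substr(fp$seq, 1, 4),
                   setdiff(c("A", "C", "G", "T"), ref_base)[1],
                   substring(fp$seq, 6))
  fp$md <- paste0("4", ref_base, "23")
  fp$nm <- 1L
  res <- trim_5p_mismatch(fp, max_trim = 2L)
  expect_equal(res$kept$pos5, 10L)
  expect_equal(res$kept$nm, 1L)
})

test_that("trimming is idempotent and conserves records", {
  spec <- simulation_spec(n_transcripts = 10L, depth = 1000L,
                          p_5p_addition = 0.4, seed = 9L)
  ann <- simulate_transcriptome(spec)
  sim <- simulate_footprints(spec, ann)
  res <- trim_5p_mismatch(sim$footprints, max_trim = 2L)
  expect_equal(nrow(res$kept) + nrow(res$discarded), nrow(sim$footprints))
  res2 <- trim_5p_mismatch(res$kept, max_trim = 2L)
  expect_equal(res2$kept, res$kept)
  expect_equal(sum(res2$summary[c("n_trimmed_1", "n_trimmed_2")]), 0L)
  # MD-derived mismatches agree with a naive re-aligner at offset 0
  off0 <- vapply(seq_len(nrow(res$kept)), function(i) {
    mm <- naive_mismatch_offsets(res$kept$seq[i],
                                 ann$sequences[[res$kept$transcript_id[i]]],
                                 res$kept$pos5[i])
    length(mm) > 0 && mm[1] == 0L
  }, logical(1))
  expect_false(any(off0))
  # trimmed positions equal the simulator's ground truth
  m <- sim$manifest[match(res$kept$qname, sim$manifest$read_id), ]
  expect_equal(res$kept$pos5, m$true_pos5)
  expect_equal(res$kept$read_length, m$frag_length)
})

test_that("records without usable MD information are handled explicitly", {
  ann <- fixture_annotation()
  fp <- fixture_footprints(ann, "T1", 10L, 28L)
  fp$md <- NA_character_
  expect_error(trim_5p_mismatch(fp), "MD")

  gapped <- fixture_footprints(ann, "T1", 10L, 28L)
  gapped$cigar <- "2S26M"
  res <- trim_5p_mismatch(gapped, max_trim = 2L)
  expect_equal(res$summary[["n_gapped_passthrough"]], 1L)
  expect_equal(res$kept$seq, gapped$seq)  # untouched
})

test_that("BAM-file trimming wrapper writes kept/discarded/summary outputs", {
  spec <- simulation_spec(n_transcripts = 5L, depth = 200L,
                          p_5p_addition = 0.3, seed = 15L)
  ann <- simulate_transcriptome(spec)
  sim <- simulate_footprints(spec, ann)
  dir <- tempfile("trim"); dir.create(dir)
  bam <- file.path(dir, "in.bam")
  write_alignments(sim$footprints, ann, bam)
  s <- trim_5p_mismatch_bam(bam, ann, file.path(dir, "out.bam"),
                            bam_discarded = file.path(dir, "rej.bam"),
                            summary_tsv = file.path(dir, "trim.tsv"))
  expect_true(file.exists(file.path(dir, "out.bam")))
  expect_true(file.exists(file.path(dir, "trim.tsv")))
  kept <- read_alignments(file.path(dir, "out.bam"))
  expect_equal(nrow(kept), sum(s[grepl("n_trimmed", names(s))]) +
                 s[["n_gapped_passthrough"]] + s[["n_not_eligible"]])
})
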