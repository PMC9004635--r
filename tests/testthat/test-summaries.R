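test_that("length distribution sums per-grid collapses and is additive", {
  grids <- fixture_three_footprint_grid()
  ld <- length_distribution(grids)
  expect_equal(ld$n_reads[ld$read_length == 28], 2L)
  expect_equal(ld$n_reads[ld$read_length == 30], 1L)
  expect_equal(sum(ld$n_reads), 3L)

  # additivity over two samples built on one annotation
  ann <- fixture_annotation()
  fpA <- fixture_footprints(ann, rep("T1", 2), c(10L, 12L), c(28L, 29L))
  fpB <- fixture_footprints(ann, rep("T1", 3), c(5L, 10L, 20L),
                            c(28L, 30L, 31L))
  gA <- build_ribogrid(fpA, ann, 25L, 35L)
  gB <- build_ribogrid(fpB, ann, 25L, 35L)
  gAB <- build_ribogrid(rbind(fpA, fpB), ann, 25L, 35L)
  expect_equal(length_distribution(gAB)$n_reads,
               length_distribution(gA)$n_reads +
                 length_distribution(gB)$n_reads)
})

test_that("empirical length proportions recover the planted distribution", {
  spec <- simulation_spec(n_transcripts = 10L, depth = 10000L, seed = 61L)
  ann <- simulate_transcriptome(spec)
  grids <- build_ribogrid(simulate_footprints(spec, ann)$footprints, ann,
                          10L, 50L)
  ld <- length_distribution(grids)
  p_hat <- ld$n_reads / sum(ld$n_reads)
  names(p_hat) <- ld$read_length
  for (l in names(spec$length_weights)) {
    p <- spec$length_weights[[l]]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(p_hat[[l]] - p), 3 * se + 1e-12)
  }
})

test_that("frame proportions are exact ratios of frame counts", {
  # counts (6,3,3): A-sites planted at known frames via offset 15 / length 28
  ann <- fixture_annotation()  # cds_start 15
  tab <- asite_offset_table(c(`28` = 15), "five_prime")
  pos_f0 <- rep(0L, 6)           # A-site 15, frame 0
  pos_f1 <- rep(1L, 3)           # A-site 16, frame 1
  pos_f2 <- rep(2L, 3)           # A-site 17, frame 2
  fp <- fixture_footprints(ann, rep("T1", 12), c(pos_f0, pos_f1, pos_f2),
                           rep(28L, 12))
  grids <- build_ribogrid(fp, ann, 25L, 35L)
  fr <- frame_proportions_per_gene(grids, ann, tab, min_reads = 4L)
  expect_equal(c(fr$n_frame0, fr$n_frame1, fr$n_frame2), c(6, 3, 3))
  expect_equal(c(fr$p0, fr$p1, fr$p2), c(0.5, 0.25, 0.25))
  expect_false(fr$low_coverage)
  expect_equal(fr$p0 + fr$p1 + fr$p2, 1)

  # all at codon boundaries -> (1, 0, 0)
  g0 <- build_ribogrid(fixture_footprints(ann, rep("T1", 5), rep(0L, 5),
                                          rep(28L, 5)), ann, 25L, 35L)
  fr0 <- frame_proportions_per_gene(g0, ann, tab, min_reads = 1L)
  expect_equal(c(fr0$p0, fr0$p1, fr0$p2), c(1, 0, 0))

  # zero-coverage transcript: proportions undefined and flagged
  gz <- build_ribogrid(fp[0, ], ann, 25L, 35L)
  frz <- frame_proportions_per_gene(gz, ann, tab)
  expect_true(is.na(frz$p0) && frz$low_coverage)
})

test_that("per-gene frame proportions recover planted multinomial weights", {
  spec <- simulation_spec(n_transcripts = 4L, depth = 8000L, seed = 67L)
  ann <- simulate_transcriptome(spec)
  grids <- build_ribogrid(simulate_footprints(spec, ann)$footprints, ann,
                          10L, 50L)
  fr <- frame_proportions_per_gene(grids, ann, spec$offsets_truth,
                                   min_reads = 500L)
  fr <- fr[!fr$low_coverage, ]
  expect_gt(nrow(fr), 0L)
  for (i in seq_len(nrow(fr))) {
    n <- fr$n_total[i]
    for (j in 1:3) {
      p <- spec$frame_weights[j]
      phat <- fr[[c("p0", "p1", "p2")[j]]][i]
      expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
    }
  }
})

test_that("metagene profile anchors at the start codon with coverage counts", {
  ann <- fixture_annotation()  # 60 nt, cds 15..45
  fp <- fixture_footprints(ann, "T1", 15L, 28L)  # 5' end exactly at start
  grids <- build_ribogrid(fp, ann, 25L, 35L)
  mg <- metagene_profile(grids, ann, "start_codon", window_codons = 4L)
  expect_equal(mg$count[mg$rel_position == 0], 1)
  expect_equal(sum(mg$count), 1)
  # 60 nt transcript covers only rel -12..+12 of a wider window fully
  expect_equal(mg$n_transcripts[mg$rel_position == -12], 1L)

  mg0 <- metagene_profile(build_ribogrid(fp[0, ], ann, 25L, 35L), ann)
  expect_true(all(mg0$count == 0))
})

test_that("metagene is additive across samples", {
  spec <- simulation_spec(n_transcripts = 4L, depth = 2000L, seed = 71L)
  ann <- simulate_transcriptome(spec)
  fp <- simulate_footprints(spec, ann)$footprints
  half <- seq_len(nrow(fp)) <= nrow(fp) / 2
  gA <- build_ribogrid(fp[half, ], ann, 10L, 50L)
  gB <- build_ribogrid(fp[!half, ], ann, 10L, 50L)
  gAB <- build_ribogrid(fp, ann, 10L, 50L)
  expect_equal(metagene_profile(gAB, ann)$count,
               metagene_profile(gA, ann)$count +
                 metagene_profile(gB, ann)$count)
})

test_that("periodicity score isolates the period-3 spectral line", {
  # exact 3-periodic impulse train
  y <- rep(c(1, 0, 0), 20)
  ps <- periodicity_score(y)
  expect_gt(ps$score, 0.95)
  expect_equal(ps$dominant_period, 3)

  # constant profile: no non-DC energy
  expect_equal(periodicity_score(rep(5, 30))$score, 0)

  # window length contract
  expect_error(periodicity_score(c(1, 0, 0)), "length")
})

test_that("periodic simulations outscore frame-uniform ones", {
  score_for <- function(fw, seed) {
    spec <- simulation_spec(n_transcripts = 6L, depth = 4000L,
                            frame_weights = fw, seed = seed)
    ann <- simulate_transcriptome(spec)
    grids <- build_ribogrid(simulate_footprints(spec, ann)$footprints, ann,
                            10L, 50L)
    periodicity_score(metagene_profile(grids, ann))$score
  }
  for (seed in c(201L, 202L, 203L)) {
    expect_gt(score_for(c(0.9, 0.05, 0.05), seed),
              score_for(c(1, 1, 1) / 3, seed))
  }
})

test_that("the 90/5/5 metagene spectrum peaks at period 3 (DFT oracle)", {
  spec <- simulation_spec(n_transcripts = 6L, depth = 6000L,
                          frame_weights = c(0.9, 0.05, 0.05), seed = 73L)
  ann <- simulate_transcriptome(spec)
  grids <- build_ribogrid(simulate_footprints(spec, ann)$footprints, ann,
                          10L, 50L)
  mg <- metagene_profile(grids, ann, window_codons = 20L)
  y <- mg$count[-length(mg$count)]
  y <- y - mean(y)
  # brute-force DFT magnitudes
  n <- length(y)
  mags <- vapply(1:(n %/% 2), function(k) {
    Mod(sum(y * exp(-2i * pi * k * (0:(n - 1)) / n)))
  }, numeric(1))
  expect_equal(which.max(mags), n %/% 3L)  # maximal non-DC line at period 3
  expect_equal(periodicity_score(mg)$dominant_period, 3)
})

test_that("TPM normalisation matches hand-computed values and sums to 1e6", {
  mk <- function(id, count, codons) {
    structure(list(transcript_id = id,
                   counts = c(count, rep(0L, codons - 1L)),
                   cds_length_codons = codons,
                   exclusions = c(unlisted_length = 0L,
                                  out_of_transcript = 0L, outside_cds = 0L)),
              class = "codon_density")
  }
  # equal counts, equal lengths -> 500k each
  q <- gene_counts_and_tpm(list(mk("A", 50L, 100L), mk("B", 50L, 100L)))
  expect_equal(q$tpm, c(500000, 500000))

  # 100/100 codons vs 100/400 codons -> rates 1.0 vs 0.25 -> 800k / 200k
  q2 <- gene_counts_and_tpm(list(mk("A", 100L, 100L), mk("B", 100L, 400L)))
  expect_equal(q2$tpm, c(800000, 200000))

  # single expressed gene -> 1e6
  q3 <- gene_counts_and_tpm(list(mk("A", 7L, 50L), mk("B", 0L, 50L)))
  expect_equal(q3$tpm, c(1e6, 0))
  expect_true(all((q3$tpm == 0) == (q3$count == 0)))

  # degenerate all-zero sample: flagged, not NaN
  q4 <- gene_counts_and_tpm(list(mk("A", 0L, 50L), mk("B", 0L, 50L)))
  expect_true(attr(q4, "degenerate"))
  expect_true(all(is.na(q4$tpm)))

  # invariant on a simulated sample
  spec <- simulation_spec(n_transcripts = 20L, depth = 5000L, seed = 79L)
  ann <- simulate_transcriptome(spec)
  grids <- build_ribogrid(simulate_footprints(spec, ann)$footprints, ann,
                          10L, 50L)
  q5 <- gene_counts_and_tpm(codon_densities(grids, ann,
                                            default_asite_offsets()))
  expect_equal(sum(q5$tpm), 1e6, tolerance = 1e-6)
  expect_equal(nrow(q5), 20L)  # explicit zeros for all genes
})

test_that("gene count matrices join samples with explicit zeros", {
  mk <- function(id, count) {
    structure(list(transcript_id = id, counts = count,
                   cds_length_codons = length(count),
                   exclusions = c(unlisted_length = 0L,
                                  out_of_transcript = 0L, outside_cds = 0L)),
              class = "codon_density")
  }
  qA <- gene_counts_and_tpm(list(mk("G1", c(3L, 2L)), mk("G2", c(0L, 0L))))
  qB <- gene_counts_and_tpm(list(mk("G1", c(1L, 0L)), mk("G2", c(4L, 4L))))
  m <- gene_count_matrix(list(s1 = qA, s2 = qB))
  expect_equal(m$s1, c(5L, 0L))
  expect_equal(m$s2, c(1L, 8L))
  expect_true(is.integer(m$s1))
})

test_that("planted inverse-feature dwell yields strong negative rank correlation", {
  codons <- sense_codons()
  set.seed(83)
  feature <- data.frame(codon = codons,
                        value = sample(1:20, 61, replace = TRUE))
  dwell <- setNames(1 / feature$value, codons)
  spec <- simulation_spec(n_transcripts = 30L, depth = 60000L,
                          per_codon_dwell = dwell, seed = 89L)
  ann <- simulate_transcriptome(spec)
  grids <- build_ribogrid(simulate_footprints(spec, ann)$footprints, ann,
                          10L, 50L)
  dens <- codon_densities(grids, ann, spec$offsets_truth)
  cf <- codon_feature_correlation(dens, ann, feature, min_reads = 64L,
                                  n_permutations = 199L, seed = 7L)
  expect_lt(cf$rho, -0.8)
  expect_lt(cf$p_value, 0.05)
  expect_equal(nrow(cf$per_codon), 61L)

  # permuting feature labels destroys the correlation
  set.seed(97)
  perm_rho <- replicate(100, {
    pf <- feature; pf$value <- sample(pf$value)
    suppressWarnings(cor(cf$per_codon$mean_norm_density,
                         pf$value[match(cf$per_codon$codon, pf$codon)],
                         method = "spearman", use = "complete.obs"))
  })
  expect_lt(median(abs(perm_rho)), 0.2)

  # degenerate feature
  flat <- data.frame(codon = codons, value = 1)
  cf_flat <- codon_feature_correlation(dens, ann, flat, min_reads = 64L)
  expect_true(cf_flat$degenerate)
  expect_equal(cf_flat$rho, 0)

  # missing codons rejected
  expect_error(codon_feature_correlation(dens, ann, feature[-1, ]),
               "missing sense codon")
})
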