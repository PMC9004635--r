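test_that("footprints land in exactly one cell each", {
  g <- fixture_three_footprint_grid()$grids[["T1"]]
  expect_equal(dim(g$counts), c(11L, 60L))          # lengths 25..35 x 60 nt
  expect_equal(g$counts["28", "10"], 2L)
  expect_equal(g$counts["30", "11"], 1L)
  expect_equal(sum(g$counts), 3L)

  # empty stream: all-zero grids still present
  ann <- fixture_annotation()
  g0 <- build_ribogrid(fixture_footprints(ann, character(0), integer(0),
                                          integer(0)),
                       ann, 25L, 35L)
  expect_equal(sum(g0$grids[["T1"]]$counts), 0L)
})

test_that("grid construction enforces its upstream filtering contract", {
  ann <- fixture_annotation()
  fp <- fixture_footprints(ann, "T1", 10L, 28L)
  expect_error(build_ribogrid(fp, ann, 30L, 35L), "contract")
  bad_pos <- fp; bad_pos$pos5 <- 70L
  expect_error(
    suppressWarnings(build_ribogrid(bad_pos, ann, 25L, 35L)),
    "bounds|subscript")
  bad_id <- fp; bad_id$transcript_id <- "GHOST"
  expect_error(build_ribogrid(bad_id, ann, 25L, 35L), "GHOST")
})

test_that("grid equals the simulator's own tally matrix cell-for-cell", {
  spec <- simulation_spec(n_transcripts = 6L, depth = 10000L, seed = 23L)
  ann <- simulate_transcriptome(spec)
  sim <- simulate_footprints(spec, ann)
  grids <- build_ribogrid(sim$footprints, ann, 10L, 50L)
  for (id in ann$transcripts$transcript_id) {
    expect_equal(unname(grids$grids[[id]]$counts),
                 unname(manifest_grid_tally(sim, ann, id, 10L, 50L)))
  }
  expect_equal(ribogrid_total(grids), nrow(sim$manifest))
})

test_that("grid construction is order-independent", {
  spec <- simulation_spec(n_transcripts = 5L, depth = 2000L, seed = 29L)
  ann <- simulate_transcriptome(spec)
  sim <- simulate_footprints(spec, ann)
  g1 <- build_ribogrid(sim$footprints, ann, 10L, 50L)
  set.seed(1)
  shuffled <- sim$footprints[sample(nrow(sim$footprints)), ]
  g2 <- build_ribogrid(shuffled, ann, 10L, 50L)
  expect_equal(g1, g2)
})

test_that("H5 roundtrip is bit-exact for counts, bounds, ids and attributes", {
  for (seed in c(101L, 102L, 103L)) {
    spec <- simulation_spec(n_transcripts = 12L, depth = 3000L, seed = seed)
    ann <- simulate_transcriptome(spec)
    sim <- simulate_footprints(spec, ann)
    grids <- build_ribogrid(sim$footprints, ann, 10L, 50L,
                            sample_name = paste0("s", seed))
    h5 <- tempfile(fileext = ".h5")
    write_ribogrid_h5(grids, h5)
    back <- read_ribogrid_h5(h5)
    expect_identical(names(back$grids), names(grids$grids))
    expect_identical(back$min_length, grids$min_length)
    expect_identical(back$max_length, grids$max_length)
    expect_identical(back$sample_name, grids$sample_name)
    for (id in names(grids$grids)) {
      expect_identical(back$grids[[id]]$counts, grids$grids[[id]]$counts)
      expect_identical(back$grids[[id]]$cds_start, grids$grids[[id]]$cds_start)
      expect_identical(back$grids[[id]]$cds_end, grids$grids[[id]]$cds_end)
      expect_identical(back$grids[[id]]$transcript_length,
                       grids$grids[[id]]$transcript_length)
    }
    file.remove(h5)
  }
})

test_that("schema violations are reported by name", {
  grids <- fixture_three_footprint_grid()
  h5 <- tempfile(fileext = ".h5")
  write_ribogrid_h5(grids, h5)
  rhdf5::h5deleteAttribute(h5, "T1", "cds_start")
  expect_error(read_ribogrid_h5(h5), "cds_start")

  h5b <- tempfile(fileext = ".h5")
  write_ribogrid_h5(grids, h5b)
  rhdf5::h5deleteAttribute(h5b, "/", "min_length")
  expect_error(read_ribogrid_h5(h5b), "min_length")
  file.remove(h5, h5b)
})

test_that("slices are exact sub-matrices verified by brute-force recount", {
  grids <- fixture_three_footprint_grid()
  g <- grids$grids[["T1"]]
  expect_equal(slice_ribogrid(g), g$counts)                     # identity
  expect_equal(unname(slice_ribogrid(g, c(28L, 28L), c(10L, 10L))),
               matrix(2L, 1, 1))
  expect_error(slice_ribogrid(g, c(30L, 28L)), "inverted")
  expect_error(slice_ribogrid(g, c(25L, 40L)), "bounds")

  # brute-force recount oracle over random windows of a simulated grid
  spec <- simulation_spec(n_transcripts = 3L, depth = 3000L, seed = 37L)
  ann <- simulate_transcriptome(spec)
  sim <- simulate_footprints(spec, ann)
  gs <- build_ribogrid(sim$footprints, ann, 10L, 50L)
  id <- ann$transcripts$transcript_id[1]
  gg <- gs$grids[[id]]
  m <- sim$manifest[sim$manifest$transcript_id == id, ]
  set.seed(41)
  for (i in 1:25) {
    l <- sort(sample(10:50, 2)); p <- sort(sample(0:(gg$transcript_length - 1L), 2))
    brute <- sum(m$frag_length >= l[1] & m$frag_length <= l[2] &
                   m$true_pos5 >= p[1] & m$true_pos5 <= p[2])
    expect_equal(sum(slice_ribogrid(gg, l, p)), brute)
  }
})

test_that("collapses are row/column sums that conserve the total", {
  g <- fixture_three_footprint_grid()$grids[["T1"]]
  bl <- collapse_by_length(g)
  bp <- collapse_by_position(g)
  expect_equal(bl[["28"]], 2L)
  expect_equal(bl[["30"]], 1L)
  expect_equal(bp[["10"]], 2L)
  expect_equal(bp[["11"]], 1L)
  expect_equal(sum(bl), sum(g$counts))
  expect_equal(sum(bp), sum(g$counts))

  zero <- g; zero$counts[] <- 0L
  expect_true(all(collapse_by_length(zero) == 0L))
  expect_true(all(collapse_by_position(zero) == 0L))

  # collapse equals slice-then-sum
  spec <- simulation_spec(n_transcripts = 2L, depth = 1000L, seed = 43L)
  ann <- simulate_transcriptome(spec)
  gs <- build_ribogrid(simulate_footprints(spec, ann)$footprints, ann,
                       10L, 50L)
  gg <- gs$grids[[1]]
  for (l in 26:32) {
    expect_equal(unname(collapse_by_length(gg)[as.character(l)]),
                 sum(slice_ribogrid(gg, c(l, l))))
  }
})
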