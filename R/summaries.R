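## Sample- and gene-level quantifications computed from ribogrids: the grid
## is a sufficient statistic (only counts by 5' position and read length are
## used), so everything here must agree exactly with brute-force
## recomputation from the footprint stream.

#' Read-length distribution of a sample
#'
#' Sum over transcripts of each grid's per-length collapse. The table sums
#' to the total number of accepted footprints.
#'
#' @param grids A `ribogrid_set`.
#' @return Data.frame `read_length`, `n_reads`.
#' @export
length_distribution <- function(grids) {
  stopifnot(inherits(grids, "ribogrid_set"))
  lens <- grids$min_length:grids$max_length
  total <- integer(length(lens))
  for (g in grids$grids) {
    if (g$min_length != grids$min_length || g$max_length != grids$max_length) {
      stop("mixed length bounds across grids")
    }
    total <- total + collapse_by_length(g)
  }
  data.frame(read_length = lens, n_reads = as.integer(total))
}

#' Per-gene reading-frame proportions
#'
#' For each transcript, counts CDS-assigned positions by reading frame and
#' reports exact proportions. Two counting modes: `"asite"` (default)
#' assigns each footprint to its A-site via the offset table and keeps
#' those falling inside the CDS; `"five_prime"` uses the raw 5'-end
#' position (no offset table needed) restricted to 5' ends inside the CDS
#' -- the diagnostic view in which untrimmed non-templated 5' additions
#' visibly distort the frame.
#'
#' @param grids A `ribogrid_set`.
#' @param annotation An `annotation_set`.
#' @param offsets An `asite_offset_table` (ignored for `mode =
#'   "five_prime"`).
#' @param min_reads Transcripts with fewer in-frame-counted reads are
#'   flagged `low_coverage` (proportions from a handful of reads are
#'   noise); default 64.
#' @param mode `"asite"` or `"five_prime"`.
#' @return Data.frame: `transcript_id`, `n_frame0/1/2`, `n_total`,
#'   `p0/p1/p2` (NA when `n_total == 0`), `low_coverage`.
#' @export
frame_proportions_per_gene <- function(grids, annotation, offsets = NULL,
                                       min_reads = 64L,
                                       mode = c("asite", "five_prime")) {
  mode <- match.arg(mode)
  if (mode == "asite" && is.null(offsets)) {
    stop("mode='asite' requires an offset table")
  }
  rows <- lapply(grids$grids, function(g) {
    ann <- annotation_lookup(annotation, g$transcript_id)
    nf <- frame_counts_of_grid(g, ann, offsets, mode)
    data.frame(transcript_id = g$transcript_id,
               n_frame0 = nf[1L], n_frame1 = nf[2L], n_frame2 = nf[3L],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df$n_total <- df$n_frame0 + df$n_frame1 + df$n_frame2
  df$p0 <- ifelse(df$n_total > 0, df$n_frame0 / df$n_total, NA_real_)
  df$p1 <- ifelse(df$n_total > 0, df$n_frame1 / df$n_total, NA_real_)
  df$p2 <- ifelse(df$n_total > 0, df$n_frame2 / df$n_total, NA_real_)
  df$low_coverage <- df$n_total < min_reads
  df
}

## Frame tallies (frame 0,1,2) of one grid under either counting mode.
frame_counts_of_grid <- function(g, ann, offsets, mode) {
  nz <- which(g$counts > 0L, arr.ind = TRUE)
  nf <- integer(3)
  if (nrow(nz) == 0) return(nf)
  lens <- g$min_length + nz[, 1L] - 1L
  pos5 <- nz[, 2L] - 1L
  w <- g$counts[nz]
  a <- if (mode == "asite") asite_position(pos5, lens, offsets) else pos5
  keep <- !is.na(a) & a >= ann$cds_start & a < ann$cds_end
  if (!any(keep)) return(nf)
  fr <- frame_of_position(a[keep], ann$cds_start)
  for (f in 0:2) nf[f + 1L] <- sum(w[keep][fr == f])
  nf
}

#' Sample-level frame counts
#'
#' Sums per-gene frame tallies over all transcripts (no coverage filter):
#' the sample-wide view used by the trimming diagnostics.
#'
#' @inheritParams frame_proportions_per_gene
#' @return Named numeric vector `c(n_frame0, n_frame1, n_frame2)`.
#' @export
frame_counts_total <- function(grids, annotation, offsets = NULL,
                               mode = c("asite", "five_prime")) {
  mode <- match.arg(mode)
  nf <- c(0, 0, 0)
  for (g in grids$grids) {
    ann <- annotation_lookup(annotation, g$transcript_id)
    nf <- nf + frame_counts_of_grid(g, ann, offsets, mode)
  }
  setNames(nf, c("n_frame0", "n_frame1", "n_frame2"))
}

#' Metagene profile around the start or stop codon
#'
#' Aggregates footprint counts at positions relative to an anchor -- the
#' first nucleotide of the start codon, or of the stop codon -- across all
#' transcripts. By default 5'-end counts are profiled (the standard
#' diagnostic in which the length-dependent offset and three-nucleotide
#' periodicity are visible); `use_asite = TRUE` profiles A-site-assigned
#' positions instead. Transcripts whose pad/UTR is shorter than the
#' upstream window contribute only their covered positions;
#' `n_transcripts` records, per relative position, how many transcripts
#' covered it (for normalisation).
#'
#' @param grids A `ribogrid_set`.
#' @param annotation An `annotation_set`.
#' @param anchor `"start_codon"` or `"stop_codon"`.
#' @param window_codons Half-window, codons; positions span
#'   `-3*window_codons .. +3*window_codons` nt.
#' @param use_asite Profile A-site positions instead of 5' ends.
#' @param offsets Offset table, required when `use_asite = TRUE`.
#' @param length_range Optional `c(l1, l2)` to stratify by read length.
#' @return Data.frame of class `metagene_profile`: `rel_position`, `count`,
#'   `n_transcripts`; attribute `anchor`.
#' @export
metagene_profile <- function(grids, annotation,
                             anchor = c("start_codon", "stop_codon"),
                             window_codons = 25L, use_asite = FALSE,
                             offsets = NULL, length_range = NULL) {
  anchor <- match.arg(anchor)
  stopifnot(window_codons >= 1L)
  if (use_asite && is.null(offsets)) stop("use_asite requires an offset table")
  w <- 3L * as.integer(window_codons)
  rel <- (-w):w
  count <- numeric(length(rel))
  ntx <- integer(length(rel))
  for (g in grids$grids) {
    ann <- annotation_lookup(annotation, g$transcript_id)
    a0 <- if (anchor == "start_codon") ann$cds_start else ann$cds_end - 3L
    covered <- (a0 + rel) >= 0L & (a0 + rel) < g$transcript_length
    ntx <- ntx + covered
    if (sum(g$counts) == 0) next
    if (use_asite) {
      nz <- which(g$counts > 0L, arr.ind = TRUE)
      lens <- g$min_length + nz[, 1L] - 1L
      if (!is.null(length_range)) {
        sel <- lens >= length_range[1] & lens <= length_range[2]
        nz <- nz[sel, , drop = FALSE]; lens <- lens[sel]
      }
      if (nrow(nz) == 0) next
      a <- asite_position(nz[, 2L] - 1L, lens, offsets)
      wgt <- g$counts[nz]
      ok <- !is.na(a) & a >= 0L & a < g$transcript_length
      pos_counts <- tapply(wgt[ok], a[ok], sum)
      at <- as.integer(names(pos_counts)) - a0
      sel <- at >= -w & at <= w
      count[at[sel] + w + 1L] <- count[at[sel] + w + 1L] +
        as.numeric(pos_counts[sel])
    } else {
      m <- if (is.null(length_range)) g$counts else
        slice_ribogrid(g, length_range, c(0L, g$transcript_length - 1L))
      cc <- colSums(m)
      p <- (a0 + rel)
      ok <- covered
      count[ok] <- count[ok] + cc[p[ok] + 1L]
    }
  }
  out <- data.frame(rel_position = rel, count = count, n_transcripts = ntx)
  attr(out, "anchor") <- anchor
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Three-nucleotide periodicity score of a metagene profile
#'
#' Discrete-Fourier summary of codon stepping: the magnitude at period 3
#' of the mean-subtracted profile divided by the total non-DC magnitude
#' (one-sided spectrum), in `[0, 1]`. A flat profile has no non-DC energy
#' and scores 0 by convention. The dominant period (among one-sided
#' frequencies) is returned alongside.
#'
#' @param profile A `metagene_profile` (or numeric vector) whose length is
#'   a multiple of 3 and at least 6; the standard `2*3*w + 1`-point profile
#'   is trimmed of its last point to satisfy this.
#' @return List: `score`, `dominant_period`, `n`.
#' @export
periodicity_score <- function(profile) {
  y <- if (is.data.frame(profile)) profile$count else as.numeric(profile)
  if (length(y) %% 3L == 1L) y <- y[-length(y)]  # 2w+1-point window
  n <- length(y)
  if (n < 6L || n %% 3L != 0L) {
    stop("profile length must be >= 6 and a multiple of 3")
  }
  y <- y - mean(y)
  sp <- Mod(fft(y))[2:(n %/% 2L + 1L)]          # one-sided, DC removed
  if (sum(sp) == 0) {
    return(list(score = 0, dominant_period = NA_real_, n = n))
  }
  k3 <- n %/% 3L                                 # frequency 1/3 <-> period 3
  score <- sp[k3] / sum(sp)
  kdom <- which.max(sp)
  list(score = score, dominant_period = n / kdom, n = n)
}

#' Gene-level counts, densities and TPM
#'
#' The gene count is the number of CDS-assigned A-site footprints (an
#' ORF-level quantity; reads mapping to UTRs/pads are not counted). TPM is
#' the per-codon rate normalised to sum to one million across genes:
#' `tpm_g = 1e6 * (count_g / L_g) / sum_h (count_h / L_h)` with `L` in
#' codons. An all-zero sample leaves TPM as `NA` with a `degenerate` flag
#' rather than propagating NaN.
#'
#' @param densities List of `codon_density` covering all transcripts
#'   (explicit zeros included).
#' @return Data.frame: `transcript_id`, `count`, `cds_length_codons`,
#'   `density` (count per codon), `tpm`; attribute `"degenerate"`.
#' @export
gene_counts_and_tpm <- function(densities) {
  df <- data.frame(
    transcript_id = vapply(densities, `[[`, "", "transcript_id"),
    count = vapply(densities, function(d) sum(d$counts), numeric(1)),
    cds_length_codons = vapply(densities, `[[`, integer(1),
                               "cds_length_codons"),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df$density <- df$count / df$cds_length_codons
  total_rate <- sum(df$density)
  degenerate <- total_rate == 0
  df$tpm <- if (degenerate) NA_real_ else 1e6 * df$density / total_rate
  attr(df, "degenerate") <- degenerate
  df
}

#' Join per-sample gene counts into a genes x samples matrix
#'
#' Explicit zeros for every gene in every sample: the complete integer
#' matrix differential-expression tools expect.
#'
#' @param quant_list Named list of [gene_counts_and_tpm()] tables.
#' @return Data.frame: `transcript_id` then one integer column per sample.
#' @export
gene_count_matrix <- function(quant_list) {
  ids <- quant_list[[1]]$transcript_id
  out <- data.frame(transcript_id = ids, stringsAsFactors = FALSE)
  for (s in names(quant_list)) {
    q <- quant_list[[s]]
    out[[s]] <- as.integer(q$count[match(ids, q$transcript_id)])
  }
  out
}

#' Codon-specific density vs a per-codon feature
#'
#' Compares ribosome dwell per codon identity with a user-supplied
#' per-codon feature (e.g. tRNA gene copy numbers, expected to correlate
#' with decoding speed). Each qualifying gene's codon-density vector is
#' normalised by its own mean over covered codons (removing gene-level
#' abundance); normalised densities are then averaged per codon identity
#' across all genes and positions, paired with the feature, and summarised
#' by the Spearman rank correlation with a seeded permutation p-value
#' (assumption-free under ties).
#'
#' @param densities List of `codon_density`.
#' @param annotation `annotation_set` with sequences (codon identities are
#'   read from the CDS).
#' @param feature_table Data.frame `codon`, `value` covering all 61 sense
#'   codons.
#' @param min_reads Genes with fewer CDS-assigned footprints are excluded
#'   (default 64).
#' @param n_permutations Label permutations for the p-value (default 1999).
#' @param seed RNG seed for the permutations.
#' @return List: `per_codon` (data.frame `codon`, `mean_norm_density`,
#'   `n_positions`, `feature`), `rho`, `p_value`, `degenerate` flag.
#' @export
codon_feature_correlation <- function(densities, annotation, feature_table,
                                      min_reads = 64L, n_permutations = 1999L,
                                      seed = 1L) {
  codons <- sense_codons()
  missing <- setdiff(codons, feature_table$codon)
  if (length(missing) > 0) {
    stop("feature table missing sense codon(s): ",
         paste(head(missing, 5), collapse = ", "))
  }
  sum_norm <- setNames(numeric(length(codons)), codons)
  n_pos <- setNames(numeric(length(codons)), codons)
  any_gene <- FALSE
  for (d in densities) {
    if (sum(d$counts) < min_reads) next
    ann <- annotation_lookup(annotation, d$transcript_id)
    cds <- as.character(Biostrings::subseq(
      annotation$sequences[[d$transcript_id]], ann$cds_start + 1L, ann$cds_end))
    cod <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    covered <- d$counts > 0
    if (!any(covered)) next
    norm <- d$counts / mean(d$counts[covered])
    keep <- cod %in% codons           # stop codon positions excluded
    tt <- tapply(norm[keep], cod[keep], sum)
    nn <- table(factor(cod[keep], levels = codons))
    sum_norm[names(tt)] <- sum_norm[names(tt)] + tt
    n_pos <- n_pos + as.numeric(nn)
    any_gene <- TRUE
  }
  if (!any_gene) stop("no gene passes min_reads = ", min_reads)
  per_codon <- data.frame(
    codon = codons,
    mean_norm_density = ifelse(n_pos > 0, sum_norm / n_pos, NA_real_),
    n_positions = as.numeric(n_pos),
    feature = feature_table$value[match(codons, feature_table$codon)],
    stringsAsFactors = FALSE)

  ok <- !is.na(per_codon$mean_norm_density)
  x <- per_codon$mean_norm_density[ok]
  y <- per_codon$feature[ok]
  degenerate <- length(unique(y)) < 2 || length(unique(x)) < 2
  if (degenerate) {
    return(list(per_codon = per_codon, rho = 0, p_value = NA_real_,
                degenerate = TRUE))
  }
  rho <- cor(x, y, method = "spearman")
  set.seed(seed)
  perm <- replicate(n_permutations, cor(x, sample(y), method = "spearman"))
  p <- (1 + sum(abs(perm) >= abs(rho))) / (1 + n_permutations)
  list(per_codon = per_codon, rho = rho, p_value = p, degenerate = FALSE)
}

#' Write the standard summary TSVs for one sample
#'
#' @param grids A `ribogrid_set`.
#' @param annotation An `annotation_set`.
#' @param offsets An `asite_offset_table`.
#' @param outdir Output directory.
#' @param min_reads Coverage threshold for frame/codon statistics.
#' @param window_codons Metagene half-window.
#' @param feature_table Optional per-codon feature (tRNA copies) table.
#' @return Named character vector of written files, invisibly.
#' @export
write_summaries <- function(grids, annotation, offsets, outdir,
                            min_reads = 64L, window_codons = 25L,
                            feature_table = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  f <- file.path(outdir, "read_length_distribution.tsv")
  write_tsv(length_distribution(grids), f); files["length_distribution"] <- f

  f <- file.path(outdir, "frame_proportions.tsv")
  write_tsv(frame_proportions_per_gene(grids, annotation, offsets,
                                       min_reads = min_reads), f)
  files["frame_proportions"] <- f

  mg <- metagene_profile(grids, annotation, "start_codon",
                         window_codons = window_codons)
  f <- file.path(outdir, "metagene_start.tsv")
  write_tsv(mg, f); files["metagene_start"] <- f

  dens <- codon_densities(grids, annotation, offsets)
  quant <- gene_counts_and_tpm(dens)
  f <- file.path(outdir, "gene_quant.tsv")
  write_tsv(quant, f); files["gene_quant"] <- f
  f <- file.path(outdir, "codon_densities.tsv")
  write_codon_densities(dens, f); files["codon_densities"] <- f

  if (!is.null(feature_table)) {
    cf <- codon_feature_correlation(dens, annotation, feature_table,
                                    min_reads = min_reads)
    f <- file.path(outdir, "codon_feature.tsv")
    write_tsv(cf$per_codon, f); files["codon_feature"] <- f
    write_tsv(data.frame(statistic = c("spearman_rho", "p_value"),
                         value = c(cf$rho, cf$p_value)),
              file.path(outdir, "codon_feature_stats.tsv"))
    files["codon_feature_stats"] <- file.path(outdir, "codon_feature_stats.tsv")
  }
  invisible(files)
}
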