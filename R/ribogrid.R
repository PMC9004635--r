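## The ribogrid: per-transcript footprint count matrices indexed by read
## length (rows) and 0-based 5'-end position (columns), serialised in HDF5.
##
## H5 schema (version "1.0"):
##   /                  attrs: schema_version, sample_name, min_length,
##                             max_length
##   /<transcript_id>   one group per transcript
##     attrs: transcript_length, cds_start, cds_end   (0-based half-open)
##     reads            integer matrix, rows = read lengths min..max,
##                      columns = 5'-end positions 0..transcript_length-1

RIBOGRID_SCHEMA_VERSION <- "1.0"

new_ribogrid <- function(transcript_id, counts, min_length, max_length,
                         transcript_length, cds_start, cds_end) {
  structure(list(transcript_id = transcript_id, counts = counts,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 transcript_length = as.integer(transcript_length),
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end)),
            class = "ribogrid")
}

#' @export
print.ribogrid <- function(x, ...) {
  cat("ribogrid", x$transcript_id, ": lengths", x$min_length, "-",
      x$max_length, ",", x$transcript_length, "nt,",
      sum(x$counts), "footprints\n")
  invisible(x)
}

#' Build ribogrids from a footprint table
#'
#' Tallies each accepted footprint into exactly one cell
#' `(read_length, pos5)` of its transcript's matrix. Every transcript of the
#' annotation receives a grid; transcripts with no footprints get explicit
#' all-zero grids by default so that downstream gene tables contain explicit
#' zeros (as DESeq2-style count matrices require).
#'
#' @param footprints Data.frame with columns `transcript_id`,
#'   `pos5` (0-based), `read_length` -- the accepted-alignment stream
#'   produced by [filter_alignments()] (or the simulator manifest).
#' @param annotation An `annotation_set`.
#' @param min_length,max_length Inclusive read-length bounds of the matrix
#'   rows. Footprints outside these bounds are a contract violation
#'   (filtering is upstream) and raise an error.
#' @param keep_empty Keep all-zero grids for footprint-free transcripts.
#' @param sample_name Stored with the set; lands in the H5 root attributes.
#' @return An object of class `ribogrid_set`: list with `grids` (named list
#'   of `ribogrid`, annotation order), `min_length`, `max_length`,
#'   `sample_name`.
#' @export
build_ribogrid <- function(footprints, annotation, min_length = 10L,
                           max_length = 50L, keep_empty = TRUE,
                           sample_name = "sample") {
  min_length <- as.integer(min_length); max_length <- as.integer(max_length)
  stopifnot(min_length <= max_length)
  tr <- annotation$transcripts
  fp <- footprints

  if (nrow(fp) > 0) {
    bad_id <- setdiff(unique(fp$transcript_id), tr$transcript_id)
    if (length(bad_id) > 0) {
      stop("footprint transcript id(s) not in annotation: ",
           paste(head(bad_id, 5), collapse = ", "))
    }
    if (any(fp$read_length < min_length | fp$read_length > max_length)) {
      stop("footprint length outside [min_length, max_length]: ",
           "filtering contract violated upstream")
    }
    tlen <- tr$length[match(fp$transcript_id, tr$transcript_id)]
    if (any(fp$pos5 < 0L | fp$pos5 >= tlen)) {
      stop("footprint pos5 outside transcript bounds")
    }
  }

  n_len <- max_length - min_length + 1L
  idx_by_tx <- split(seq_len(nrow(fp)), factor(fp$transcript_id,
                                               levels = tr$transcript_id))
  grids <- vector("list", nrow(tr))
  names(grids) <- tr$transcript_id
  for (i in seq_len(nrow(tr))) {
    L <- tr$length[i]
    rows_i <- idx_by_tx[[tr$transcript_id[i]]]
    if (length(rows_i) == 0 && !keep_empty) next
    # encode (length row, position col) as one index and tabulate
    cell <- (fp$pos5[rows_i]) * n_len + (fp$read_length[rows_i] - min_length) + 1L
    counts <- matrix(tabulate(cell, nbins = n_len * L), nrow = n_len)
    dimnames(counts) <- list(read_length = min_length:max_length,
                             pos5 = 0:(L - 1L))
    grids[[tr$transcript_id[i]]] <- new_ribogrid(
      tr$transcript_id[i], counts, min_length, max_length,
      L, tr$cds_start[i], tr$cds_end[i])
  }
  grids <- grids[!vapply(grids, is.null, logical(1))]
  structure(list(grids = grids, min_length = min_length,
                 max_length = max_length, sample_name = sample_name),
            class = "ribogrid_set")
}

#' @export
print.ribogrid_set <- function(x, ...) {
  cat("ribogrid_set '", x$sample_name, "': ", length(x$grids),
      " transcripts, lengths ", x$min_length, "-", x$max_length, ", ",
      sum(vapply(x$grids, function(g) sum(g$counts), numeric(1))),
      " footprints\n", sep = "")
  invisible(x)
}

#' Total footprints in a ribogrid set
#' @param grids A `ribogrid_set`.
#' @return Numeric total of all matrix entries.
#' @export
ribogrid_total <- function(grids) {
  sum(vapply(grids$grids, function(g) sum(g$counts), numeric(1)))
}

#' Write a ribogrid set to HDF5
#'
#' Serialises under the documented schema (see the package vignette): root
#' attributes `schema_version`, `sample_name`, `min_length`, `max_length`,
#' plus provenance (`source_bam`, `created`, `tool_version`); one group per
#' transcript holding the integer `reads` matrix and the transcript's
#' coordinates. Datasets are chunked and gzip-compressed; compression never
#' affects roundtrip equality.
#'
#' @param grids A `ribogrid_set`.
#' @param path Output `.h5` path (overwritten).
#' @param source_bam Optional provenance string.
#' @param created Timestamp string recorded in the file; pass a fixed value
#'   for byte-reproducible output.
#' @return `path`, invisibly.
#' @export
write_ribogrid_h5 <- function(grids, path, source_bam = "",
                              created = "1970-01-01T00:00:00Z") {
  stopifnot(inherits(grids, "ribogrid_set"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(RIBOGRID_SCHEMA_VERSION, fid, "schema_version")
  rhdf5::h5writeAttribute(grids$sample_name, fid, "sample_name")
  rhdf5::h5writeAttribute(grids$min_length, fid, "min_length")
  rhdf5::h5writeAttribute(grids$max_length, fid, "max_length")
  rhdf5::h5writeAttribute(source_bam, fid, "source_bam")
  rhdf5::h5writeAttribute(created, fid, "created")
  rhdf5::h5writeAttribute(as.character(packageVersion("ribogridkit")),
                          fid, "tool_version")
  # HDF5 iterates links in name order; record build order so reads restore it
  if (length(grids$grids) > 0) {
    rhdf5::h5writeAttribute(names(grids$grids), fid, "transcript_order")
  }
  for (g in grids$grids) {
    gid <- rhdf5::H5Gcreate(fid, g$transcript_id)
    rhdf5::h5writeAttribute(g$transcript_length, gid, "transcript_length")
    rhdf5::h5writeAttribute(g$cds_start, gid, "cds_start")
    rhdf5::h5writeAttribute(g$cds_end, gid, "cds_end")
    rhdf5::H5Gclose(gid)
    counts <- g$counts
    storage.mode(counts) <- "integer"
    rhdf5::h5createDataset(fid, paste0(g$transcript_id, "/reads"),
                           dims = dim(counts), storage.mode = "integer",
                           chunk = pmin(dim(counts), c(64L, 1024L)),
                           level = 6)
    rhdf5::h5write(counts, fid, paste0(g$transcript_id, "/reads"))
  }
  invisible(path)
}

#' Read a ribogrid set from HDF5
#'
#' Validates the schema (version, required attributes, integer datasets)
#' and reconstructs the `ribogrid_set` exactly as written: `read(write(x))`
#' is bit-exact for counts, bounds, ids and attributes.
#'
#' @param path `.h5` file written by [write_ribogrid_h5()].
#' @return A `ribogrid_set`.
#' @export
read_ribogrid_h5 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  root_attrs <- rhdf5::h5readAttributes(path, "/")
  for (a in c("schema_version", "sample_name", "min_length", "max_length")) {
    if (is.null(root_attrs[[a]])) {
      stop("ribogrid H5 schema error: missing root attribute '", a, "'")
    }
  }
  if (root_attrs$schema_version != RIBOGRID_SCHEMA_VERSION) {
    stop("ribogrid H5 schema version mismatch: file has '",
         root_attrs$schema_version, "', reader supports '",
         RIBOGRID_SCHEMA_VERSION, "'")
  }
  min_length <- as.integer(root_attrs$min_length)
  max_length <- as.integer(root_attrs$max_length)

  contents <- rhdf5::h5ls(path)
  tx_ids <- contents$name[contents$group == "/" & contents$otype == "H5I_GROUP"]
  if (!is.null(root_attrs$transcript_order)) {
    ord <- as.character(root_attrs$transcript_order)
    if (!setequal(ord, tx_ids)) {
      stop("ribogrid H5 schema error: transcript_order does not match groups")
    }
    tx_ids <- ord
  } else {
    tx_ids <- sort(tx_ids)
  }

  grids <- vector("list", length(tx_ids))
  names(grids) <- tx_ids
  for (id in tx_ids) {
    attrs <- rhdf5::h5readAttributes(path, id)
    for (a in c("transcript_length", "cds_start", "cds_end")) {
      if (is.null(attrs[[a]])) {
        stop("ribogrid H5 schema error: group '", id,
             "' missing attribute '", a, "'")
      }
    }
    counts <- rhdf5::h5read(path, paste0(id, "/reads"))
    if (!is.integer(counts)) {
      stop("ribogrid H5 schema error: dataset '", id, "/reads' is not integer")
    }
    dimnames(counts) <- list(read_length = min_length:max_length,
                             pos5 = 0:(ncol(counts) - 1L))
    grids[[id]] <- new_ribogrid(id, counts, min_length, max_length,
                                attrs$transcript_length, attrs$cds_start,
                                attrs$cds_end)
  }
  structure(list(grids = grids, min_length = min_length,
                 max_length = max_length,
                 sample_name = as.character(root_attrs$sample_name)),
            class = "ribogrid_set")
}

#' Slice a ribogrid
#'
#' Exact sub-matrix by inclusive read-length range and inclusive 0-based
#' position window. The full-range slice is the whole matrix.
#'
#' @param grid A `ribogrid`.
#' @param length_range `c(l1, l2)`, inclusive, within the grid's bounds.
#' @param position_window `c(p1, p2)`, inclusive 0-based positions.
#' @return Integer matrix (dimnames kept).
#' @export
slice_ribogrid <- function(grid,
                           length_range = c(grid$min_length, grid$max_length),
                           position_window = c(0L, grid$transcript_length - 1L)) {
  l1 <- as.integer(length_range[1]); l2 <- as.integer(length_range[2])
  p1 <- as.integer(position_window[1]); p2 <- as.integer(position_window[2])
  if (l1 > l2 || p1 > p2) stop("inverted slice range")
  if (l1 < grid$min_length || l2 > grid$max_length ||
      p1 < 0L || p2 >= grid$transcript_length) {
    stop("slice range outside grid bounds")
  }
  grid$counts[(l1 - grid$min_length + 1L):(l2 - grid$min_length + 1L),
              (p1 + 1L):(p2 + 1L), drop = FALSE]
}

#' Collapse a ribogrid over positions or lengths
#'
#' `collapse_by_length()` returns row sums (reads per read length);
#' `collapse_by_position()` returns column sums (reads per 5' position).
#' Each collapse sums to the grid total.
#'
#' @param grid A `ribogrid`.
#' @return Named integer vector (names: read lengths / 0-based positions).
#' @export
collapse_by_length <- function(grid) {
  v <- rowSums(grid$counts)
  setNames(as.integer(v), rownames(grid$counts))
}

#' @rdname collapse_by_length
#' @export
collapse_by_position <- function(grid) {
  v <- colSums(grid$counts)
  setNames(as.integer(v), colnames(grid$counts))
}
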