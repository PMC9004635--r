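#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft rnorm runif setNames aggregate cor rlnorm rpois
#' @importFrom utils read.delim write.table packageVersion head tail
#' @importFrom ggplot2 .data
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' The 61 sense codons
#'
#' All 64 trinucleotides over \{A,C,G,T\} minus the three stop codons, in
#' lexicographic order. Codon-level tables (dwell rates, tRNA gene copy
#' numbers) are indexed by these.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  all64 <- sort(all64)
  setdiff(all64, STOP_CODONS)
}

## Pairwise Hamming distance between equal-length strings, vectorised over x.
hamming_to <- function(x, barcode) {
  n <- nchar(barcode)
  xm <- matrix(unlist(strsplit(x, "", fixed = TRUE)), ncol = n, byrow = TRUE)
  bm <- strsplit(barcode, "", fixed = TRUE)[[1]]
  rowSums(xm != matrix(bm, nrow = nrow(xm), ncol = n, byrow = TRUE))
}

## Write a data.frame as a plain TSV (no quoting, no row names) -- the
## package's uniform text-export convention.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

## Random DNA of given total length as a single string.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Mathematical mod that returns values in 0..(m-1) for negative input too.
pos_mod <- function(x, m) ((x %% m) + m) %% m
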