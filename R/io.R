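#' Read barcode reads from a FASTQ file
#'
#' @param path FASTQ file (plain or gzipped).
#' @return Character vector of read sequences, named by read id.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write reads to a FASTQ file with constant quality
#'
#' Base qualities are not modeled by the simulators, so every base gets the
#' same high Phred score.
#'
#' @param reads Character vector of sequences; names become read ids.
#' @param path Output file.
#' @param quality_char Single Phred quality character; default "I" (Q40).
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  if (is.null(names(reads)))
    names(reads) <- paste0("read_", seq_along(reads))
  qs <- Biostrings::PhredQuality(vapply(nchar(reads), function(L)
    paste(rep(quality_char, L), collapse = ""), character(1)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads), qs)
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a barcode count table from TSV
#'
#' Two-column tab-separated file (barcode, count), with or without header.
#'
#' @param path Input TSV.
#' @return A `barcode_counts` object (see [count_barcodes()]).
#' @export
read_counts_tsv <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  header <- suppressWarnings(is.na(as.numeric(first[[2]])))
  d <- read.delim(path, header = header, col.names = c("barcode", "count"),
                  colClasses = c("character", "integer"))
  counts <- setNames(d$count, d$barcode)
  counts <- counts[order(-counts, names(counts))]
  structure(counts,
            barcode_length = as.integer(unique(nchar(names(counts)))[[1]]),
            discarded = 0L, class = "barcode_counts")
}

#' Write a barcode count table to TSV
#'
#' @param counts Named counts (e.g. from [count_barcodes()]).
#' @param path Output TSV.
#' @export
write_counts_tsv <- function(counts, path) {
  write.table(data.frame(barcode = names(counts),
                         count = as.integer(counts)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a whitelist result to TSV files
#'
#' Writes `<prefix>_whitelist.tsv` (rank, barcode, count) and
#' `<prefix>_fdr_curve.tsv` (k, fdr).
#'
#' @param result A [estimate_whitelist()] result.
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_whitelist_tsv <- function(result, prefix) {
  stopifnot(inherits(result, "whitelist_result"))
  p1 <- paste0(prefix, "_whitelist.tsv")
  p2 <- paste0(prefix, "_fdr_curve.tsv")
  write.table(result$ranked[seq_len(result$k_star),
                            c("rank", "barcode", "count")],
              p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$fdr_curve, p2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(whitelist = p1, fdr_curve = p2))
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (one set per line: name, description, genes).
#' @return Named list of character vectors (via [fgsea::gmtPathways()]).
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write gene signatures to a GMT file
#'
#' @param signatures A [gene_signature()], or a named list of signatures /
#'   character vectors.
#' @param path Output GMT file.
#' @param description Description field per set; default "".
#' @export
write_gmt <- function(signatures, path, description = "") {
  if (inherits(signatures, "gene_signature"))
    signatures <- list(signature = signatures)
  lines <- vapply(names(signatures), function(nm) {
    genes <- signatures[[nm]]
    if (inherits(genes, "gene_signature")) genes <- genes$genes
    paste(c(nm, description, genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a labeled expression matrix as an MTX triplet directory
#'
#' Writes `matrix.mtx` (genes x cells, MatrixMarket), `genes.tsv`,
#' `cells.tsv` and `labels.tsv` (cell, class) into `dir`.
#'
#' @param x A [labeled_expression()] object.
#' @param dir Output directory (created if needed).
#' @export
write_expression_mtx <- function(x, dir) {
  stopifnot(inherits(x, "labeled_expression"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- Matrix::Matrix(t(x$values), sparse = TRUE)  # genes x cells on disk
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(x$values), file.path(dir, "genes.tsv"))
  writeLines(rownames(x$values), file.path(dir, "cells.tsv"))
  write.table(data.frame(cell = rownames(x$values),
                         class = as.character(x$labels)),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read a labeled expression matrix from an MTX triplet directory
#'
#' @param dir Directory written by [write_expression_mtx()].
#' @return A [labeled_expression()] object.
#' @export
read_expression_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "cells.tsv"))
  lab <- read.delim(file.path(dir, "labels.tsv"),
                    colClasses = c("character", "character"))
  values <- t(as.matrix(m))
  dimnames(values) <- list(cells, genes)
  labeled_expression(values, lab$class[match(cells, lab$cell)])
}

#' Write a labeled expression matrix as a dense TSV
#'
#' Cells in rows (first column `cell`, second `class`), genes in the
#' remaining columns.
#'
#' @param x A [labeled_expression()] object.
#' @param path Output TSV.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "labeled_expression"))
  d <- data.frame(cell = rownames(x$values), class = as.character(x$labels),
                  x$values, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled expression matrix from a dense TSV
#'
#' @param path TSV written by [write_expression_tsv()].
#' @return A [labeled_expression()] object.
#' @export
read_expression_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  values <- as.matrix(d[, -(1:2), drop = FALSE])
  rownames(values) <- d$cell
  labeled_expression(values, d$class)
}

#' Read a perturbation reference matrix from TSV
#'
#' Rows are genes, columns perturbation identifiers, first column the gene
#' id.
#'
#' @param path Input TSV.
#' @return Numeric matrix with dimnames.
#' @export
read_reference_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write a perturbation reference matrix to TSV
#'
#' @param reference Genes x perturbations matrix with dimnames.
#' @param path Output TSV.
#' @export
write_reference_tsv <- function(reference, path) {
  write.table(data.frame(gene = rownames(reference), reference,
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single-channel image
#'
#' Reads a grayscale TIFF (or PNG) channel as a numeric intensity matrix on
#' the 16-bit scale (0..65535).
#'
#' @param path Image file.
#' @return Numeric matrix.
#' @export
read_channel_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  round(img * 65535)
}

#' Write a single-channel image as 16-bit grayscale TIFF
#'
#' Intensities are clipped to the 16-bit range 0..65535.
#'
#' @param channel Numeric matrix of intensities.
#' @param path Output TIFF.
#' @export
write_channel_tiff <- function(channel, path) {
  m <- pmin(pmax(as.matrix(channel), 0), 65535) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}
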