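#' Hamming distance between two equal-length sequences
#'
#' @param a,b Character scalars of equal length.
#' @return Integer number of mismatching positions.
#' @examples
#' hamming("ACGT", "TGCA")
#' @export
hamming <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b))
    stop("sequences must have equal length", call. = FALSE)
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Tally barcode reads into a count table
#'
#' Counts distinct read sequences of the expected barcode length; reads of
#' any other length are discarded and the discard count reported.
#'
#' @param reads Character vector of read sequences (e.g. from [read_fastq()]).
#' @param barcode_length Expected barcode length in bases.
#' @return A named integer vector (barcode -> count), sorted by decreasing
#'   count, of class `barcode_counts` with attributes `barcode_length` and
#'   `discarded`.
#' @export
count_barcodes <- function(reads, barcode_length) {
  reads <- as.character(reads)
  if (length(reads) == 0L) stop("no reads supplied", call. = FALSE)
  stop_if_not_scalar_count(barcode_length, "barcode_length", min = 1)
  keep <- nchar(reads) == barcode_length
  discarded <- sum(!keep)
  if (!any(keep))
    stop(sprintf("no usable reads of length %d (%d discarded)",
                 barcode_length, discarded), call. = FALSE)
  tab <- table(reads[keep])
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts <- counts[order(-counts, names(counts))]
  structure(counts, barcode_length = as.integer(barcode_length),
            discarded = discarded, class = "barcode_counts")
}

#' @export
print.barcode_counts <- function(x, ...) {
  cat(sprintf("barcode_counts: %d distinct barcodes of length %d, %s reads (%d discarded)\n",
              length(x), attr(x, "barcode_length"),
              format(sum(as.numeric(x)), big.mark = ","), attr(x, "discarded")))
  print(head(unclass(x)), ...)
  if (length(x) > 6L) cat("...\n")
  invisible(x)
}

#' Estimate the true barcode whitelist by an empirical FDR cutoff
#'
#' Candidates are ranked by read count (ties broken lexicographically). For
#' each candidate whitelist size k, the empirical FDR is the fraction of the
#' top-k candidates that lie within Hamming distance `fp_hd` of another
#' top-k candidate — such near neighbours are treated as sequencing-error
#' false positives, on the logic that errors derive from more abundant true
#' barcodes. The accepted size `k_star` is the largest k whose FDR does not
#' exceed `threshold`.
#'
#' With `comparison = "higher"` (default) a candidate only counts as a false
#' positive when its near neighbour outranks it; `"all"` counts closeness to
#' any other top-k candidate regardless of rank.
#'
#' @param counts A [count_barcodes()] table, or a named numeric vector of
#'   barcode counts.
#' @param threshold Empirical FDR bound in (0, 1); default 0.05.
#' @param fp_hd Hamming radius defining a false positive (>= 1); default 1.
#' @param comparison `"higher"` or `"all"` (see Details).
#' @return An object of class `whitelist_result` with components
#'   `whitelist` (accepted barcodes in rank order), `k_star`, `threshold`,
#'   `fp_hd`, `comparison`, `fdr_curve` (data frame `k`, `fdr`) and `ranked`
#'   (data frame of all candidates with rank, count and nearest-neighbour
#'   rank).
#' @examples
#' counts <- c(AAAA = 100, CCCC = 90, AAAT = 3)
#' estimate_whitelist(counts)
#' @export
estimate_whitelist <- function(counts, threshold = 0.05, fp_hd = 1,
                               comparison = c("higher", "all")) {
  comparison <- match.arg(comparison)
  if (length(counts) == 0L) stop("empty count table", call. = FALSE)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by barcode", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  stop_if_not_scalar_count(fp_hd, "fp_hd", min = 1)
  if (length(unique(nchar(names(counts)))) != 1L)
    stop("all barcodes must have equal length", call. = FALSE)

  ord <- order(-as.numeric(counts), names(counts))
  bc <- names(counts)[ord]
  cnt <- as.numeric(counts)[ord]
  n <- length(bc)

  nn <- .hamming_neighbor_rank(bc, as.integer(fp_hd))
  if (comparison == "higher") {
    flagged <- nn > 0L & nn < seq_len(n)
    fdr <- cumsum(flagged) / seq_len(n)
  } else {
    # candidate i counts as false at size k iff its nearest neighbour rank
    # nn[i] <= k; build the curve incrementally
    fdr <- numeric(n)
    cnt_false <- 0L
    pending <- split(seq_len(n), factor(nn, levels = seq_len(n)))
    flagged <- logical(n)
    for (k in seq_len(n)) {
      if (nn[k] > 0L && nn[k] <= k) { cnt_false <- cnt_false + 1L; flagged[k] <- TRUE }
      late <- pending[[k]]
      late <- late[late < k]           # earlier candidates whose neighbour is k
      if (length(late)) { cnt_false <- cnt_false + length(late); flagged[late] <- TRUE }
      fdr[k] <- cnt_false / k
    }
  }
  k_star <- max(which(fdr <= threshold))
  structure(list(
    whitelist = bc[seq_len(k_star)],
    k_star = k_star,
    threshold = threshold,
    fp_hd = as.integer(fp_hd),
    comparison = comparison,
    fdr_curve = data.frame(k = seq_len(n), fdr = fdr),
    ranked = data.frame(rank = seq_len(n), barcode = bc, count = cnt,
                        neighbor_rank = ifelse(nn > 0L, nn, NA_integer_))
  ), class = "whitelist_result")
}

#' @export
print.whitelist_result <- function(x, ...) {
  n <- nrow(x$fdr_curve)
  cat(sprintf("whitelist_result: %d of %d candidate barcodes accepted\n",
              x$k_star, n))
  cat(sprintf("  empirical FDR at k* = %d: %.4f (threshold %.2f, fp_hd %d, comparison '%s')\n",
              x$k_star, x$fdr_curve$fdr[x$k_star], x$threshold, x$fp_hd,
              x$comparison))
  invisible(x)
}

#' @param x A `whitelist_result`.
#' @param ... Passed to [plot()].
#' @describeIn estimate_whitelist Plot the empirical FDR curve with the
#'   threshold and accepted size marked.
#' @export
plot.whitelist_result <- function(x, ...) {
  plot(x$fdr_curve$k, x$fdr_curve$fdr, type = "s", xlab = "candidate size k",
       ylab = "empirical FDR", ...)
  abline(h = x$threshold, lty = 2)
  abline(v = x$k_star, lty = 3)
  points(x$k_star, x$fdr_curve$fdr[x$k_star], pch = 19)
  invisible(x)
}

#' Assign reads to a barcode whitelist with single-mismatch correction
#'
#' Each read is matched to the unique whitelist barcode within `max_hd`
#' substitutions. Exact matches are labelled `exact`, unique near matches
#' `corrected`; reads with no whitelist barcode in range are `unassigned`
#' and reads equidistant-eligible to two or more are `ambiguous`. Reads of
#' the wrong length are `unassigned`.
#'
#' @param reads Character vector of reads.
#' @param whitelist Character vector of accepted barcodes (equal lengths),
#'   or a `whitelist_result`.
#' @param max_hd Maximum Hamming distance for correction; default 1.
#' @return Data frame with columns `read`, `barcode` (NA when not assigned),
#'   `hd` and `status`; attribute `summary` holds the category counts.
#' @export
assign_reads <- function(reads, whitelist, max_hd = 1) {
  if (inherits(whitelist, "whitelist_result")) whitelist <- whitelist$whitelist
  reads <- as.character(reads)
  if (length(reads) == 0L) stop("no reads supplied", call. = FALSE)
  if (length(whitelist) == 0L) stop("empty whitelist", call. = FALSE)
  stop_if_not_scalar_count(max_hd, "max_hd", min = 0)
  res <- .assign_nearest(reads, whitelist, as.integer(max_hd))
  status <- ifelse(res$n_hits == 0L, "unassigned",
            ifelse(res$n_hits > 1L, "ambiguous",
            ifelse(res$dist == 0L, "exact", "corrected")))
  barcode <- ifelse(res$n_hits == 1L, whitelist[res$best], NA_character_)
  out <- data.frame(read = reads, barcode = barcode,
                    hd = ifelse(res$n_hits == 1L, res$dist, NA_integer_),
                    status = status)
  counts <- table(factor(status, levels = c("exact", "corrected",
                                            "unassigned", "ambiguous")))
  attr(out, "summary") <- c(as.list(counts), total = length(reads))
  out
}

#' Size of the barcode sequence space
#'
#' The number of distinct barcodes of a given length,
#' `alphabet_size ^ length`. An 18-base random DNA barcode spans
#' 4^18 = 68,719,476,736 (~6.9e10) combinations. The value is returned as a
#' double; it is exact whenever representable in 53 bits (always, for
#' power-of-two alphabets).
#'
#' @param length Barcode length (>= 1).
#' @param alphabet_size Alphabet size; default 4 (DNA).
#' @return Numeric count.
#' @examples
#' barcode_space_size(18)
#' @export
barcode_space_size <- function(length, alphabet_size = 4) {
  stop_if_not_scalar_count(length, "length", min = 1)
  stop_if_not_scalar_count(alphabet_size, "alphabet_size", min = 2)
  alphabet_size^length
}
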