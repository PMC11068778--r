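#' Generate a set of true lineage barcodes
#'
#' Draws `n` distinct random DNA barcodes of the given length whose pairwise
#' Hamming distances are all at least `min_hd`, by rejection sampling.
#' Static lineage barcodes of this kind tag founding clones at low MOI, so
#' the true set is well separated in sequence space while sequencing errors
#' cluster within one or two substitutions of a true barcode.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in bases (the classic static barcode is 18 bp).
#' @param min_hd Minimum pairwise Hamming distance to enforce (>= 1).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param max_attempts Cap on candidate draws before declaring the
#'   (`n`, `length`, `min_hd`) combination infeasible. Default `10000 * n`.
#' @return Character vector of `n` barcodes.
#' @examples
#' gen_true_barcodes(5, length = 18, min_hd = 3, seed = 1)
#' @export
gen_true_barcodes <- function(n, length, min_hd = 3, seed = NULL,
                              max_attempts = 10000 * n) {
  stop_if_not_scalar_count(n, "n", min = 1)
  stop_if_not_scalar_count(length, "length", min = 1)
  stop_if_not_scalar_count(min_hd, "min_hd", min = 1)
  if (n > 4^length)
    stop("n exceeds the barcode space 4^length", call. = FALSE)
  with_seed(seed, {
    acc <- matrix(character(0), nrow = length, ncol = 0)
    attempts <- 0L
    while (ncol(acc) < n) {
      if (attempts >= max_attempts)
        stop(sprintf(
          "could not place %d barcodes of length %d at min Hamming distance %d within %d attempts",
          n, length, min_hd, max_attempts), call. = FALSE)
      attempts <- attempts + 1L
      cand <- sample(DNA_ALPHABET, length, replace = TRUE)
      if (ncol(acc) == 0L || all(colSums(acc != cand) >= min_hd))
        acc <- cbind(acc, cand)
    }
    unname(apply(acc, 2, paste, collapse = ""))
  })
}

#' Ground truth for a simulated barcode sequencing library
#'
#' Bundles the true barcode set, clone relative abundances and a per-base
#' substitution error rate, the three quantities that determine what an
#' amplicon sequencing run of a barcoded population looks like.
#'
#' @param barcodes Character vector of equal-length DNA barcodes.
#' @param abundance Relative clone abundances (non-negative, summing to 1
#'   within 1e-9). Default uniform.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param min_hd If supplied, validate that all pairwise Hamming distances
#'   are at least this value.
#' @return An object of class `sim_barcode_truth`.
#' @export
sim_barcode_truth <- function(barcodes, abundance = NULL, error_rate = 0.005,
                              min_hd = NULL) {
  if (length(barcodes) < 1L) stop("at least one barcode required", call. = FALSE)
  L <- nchar(barcodes)
  if (length(unique(L)) != 1L)
    stop("all barcodes must have the same length", call. = FALSE)
  if (anyDuplicated(barcodes)) stop("barcodes must be distinct", call. = FALSE)
  if (is.null(abundance))
    abundance <- rep(1 / length(barcodes), length(barcodes))
  if (length(abundance) != length(barcodes) || any(abundance < 0) ||
      abs(sum(abundance) - 1) > 1e-9)
    stop("abundance must be non-negative and sum to 1", call. = FALSE)
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 1)
    stop("error_rate must lie in [0, 1)", call. = FALSE)
  if (!is.null(min_hd) && length(barcodes) > 1L) {
    m <- .hamming_neighbor_rank(barcodes, as.integer(min_hd) - 1L)
    if (any(m > 0))
      stop(sprintf("barcodes violate the minimum pairwise Hamming distance %d", min_hd),
           call. = FALSE)
  }
  structure(list(barcodes = barcodes, abundance = abundance,
                 error_rate = error_rate, barcode_length = L[[1]],
                 min_hd = min_hd),
            class = "sim_barcode_truth")
}

#' @export
print.sim_barcode_truth <- function(x, ...) {
  cat(sprintf("sim_barcode_truth: %d barcodes of length %d, error rate %g\n",
              length(x$barcodes), x$barcode_length, x$error_rate))
  invisible(x)
}

#' Simulate amplicon reads from a barcoded population
#'
#' Draws reads from the clone abundance distribution and substitutes each
#' base independently with the truth's error rate; a substituted base is
#' replaced by one of the three other nucleotides uniformly. Indels, PCR
#' bias and quality-dependent errors are deliberately not modeled.
#'
#' @param truth A [sim_barcode_truth()] object.
#' @param n_reads Number of reads to draw (>= 1).
#' @param seed Integer seed.
#' @return Character vector of reads, with attribute `clone` giving the
#'   index of the originating barcode per read.
#' @export
gen_reads <- function(truth, n_reads, seed = NULL) {
  stopifnot(inherits(truth, "sim_barcode_truth"))
  stop_if_not_scalar_count(n_reads, "n_reads", min = 1)
  L <- truth$barcode_length
  with_seed(seed, {
    idx <- sample.int(length(truth$barcodes), n_reads, replace = TRUE,
                      prob = truth$abundance)
    reads <- truth$barcodes[idx]
    if (truth$error_rate > 0) {
      # mutate only reads that receive at least one substitution
      err <- matrix(runif(L * n_reads) < truth$error_rate, nrow = L)
      hit <- which(colSums(err) > 0L)
      if (length(hit)) {
        ch <- matrix(unlist(strsplit(reads[hit], "", fixed = TRUE),
                            use.names = FALSE), nrow = L)
        e <- err[, hit, drop = FALSE]
        k <- which(e)
        cur <- match(ch[k], DNA_ALPHABET)
        shift <- sample.int(3L, length(k), replace = TRUE)
        ch[k] <- DNA_ALPHABET[((cur - 1L + shift) %% 4L) + 1L]
        reads[hit] <- do.call(paste0, asplit(ch, 1))
      }
    }
    attr(reads, "clone") <- idx
    reads
  })
}
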