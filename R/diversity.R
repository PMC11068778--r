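#' Normalize barcode-group counts to relative abundances
#'
#' @param counts Non-negative counts per barcode group, optionally named.
#' @return An object of class `abundance_vector`: a list with `groups`,
#'   `p` (relative abundances summing to 1) and `n` (number of groups).
#' @export
normalize_abundance <- function(counts) {
  if (length(counts) == 0L || !is.numeric(counts) || any(is.na(counts)) ||
      any(counts < 0))
    stop("counts must be non-negative and non-missing", call. = FALSE)
  tot <- sum(counts)
  if (tot <= 0) stop("all counts are zero", call. = FALSE)
  groups <- if (is.null(names(counts))) as.character(seq_along(counts))
            else names(counts)
  structure(list(groups = groups, p = as.numeric(counts) / tot,
                 n = length(counts)),
            class = "abundance_vector")
}

as_abundance <- function(v) {
  if (inherits(v, "abundance_vector")) return(v)
  if (!is.numeric(v) || any(v < 0) || abs(sum(v) - 1) > 1e-9)
    stop("abundances must be non-negative and sum to 1", call. = FALSE)
  structure(list(groups = if (is.null(names(v))) as.character(seq_along(v))
                          else names(v),
                 p = as.numeric(v), n = length(v)),
            class = "abundance_vector")
}

#' Lineage diversity index
#'
#' The Simpson-type index `1 - sum(p_i^2)` over lineage relative abundances.
#' It is 0 when a single group carries all cells and reaches its maximum
#' `1 - 1/n` when all `n` groups are equally abundant.
#'
#' @param v An `abundance_vector` (see [normalize_abundance()]) or a numeric
#'   abundance vector summing to 1.
#' @return Value in `[0, 1 - 1/n]`.
#' @examples
#' diversity_index(c(0.9, 0.1))
#' @export
diversity_index <- function(v) {
  v <- as_abundance(v)
  1 - sum(v$p^2)
}

#' Scaled lineage diversity index
#'
#' [diversity_index()] divided by its maximum possible value `1 - 1/n` given
#' the number of groups, so that 1 means perfectly even clonal composition.
#' Undefined for a single group (the maximum is 0).
#'
#' @inheritParams diversity_index
#' @return Value in `[0, 1]`.
#' @export
scaled_diversity_index <- function(v) {
  v <- as_abundance(v)
  if (v$n < 2)
    stop("scaled index undefined for a single group (maximum is 0)",
         call. = FALSE)
  diversity_index(v) / (1 - 1 / v$n)
}

#' Diversity report for one timepoint
#'
#' @param counts Counts per barcode group.
#' @param timepoint Label for the timepoint.
#' @return One-row data frame with `timepoint`, `raw`, `scaled`, `n`.
#' @export
diversity_report <- function(counts, timepoint = "t0") {
  v <- normalize_abundance(counts)
  data.frame(timepoint = timepoint, raw = diversity_index(v),
             scaled = if (v$n >= 2) scaled_diversity_index(v) else NA_real_,
             n = v$n)
}

#' Test for barcode-group enrichment shifts between two timepoints
#'
#' Per group, compares the group's frequency at the two timepoints with
#' Fisher's exact test on the 2x2 table (group vs rest, t0 vs t1), then
#' adjusts across groups by Benjamini-Hochberg. Named count vectors are
#' merged over the union of group names with zeros for absent groups, since
#' disappearance of a group is itself a shift; unnamed vectors must have
#' matching lengths.
#'
#' @param counts_t0,counts_t1 Counts per group at each timepoint.
#' @param alpha FDR level for the "enriched subsets detected" flag.
#' @return Data frame with per-group counts, frequencies, odds ratio, `p`
#'   and `q`; attributes `alpha` and `enriched` (logical flag: any q <=
#'   alpha).
#' @export
enrichment_shift_test <- function(counts_t0, counts_t1, alpha = 0.05) {
  named0 <- !is.null(names(counts_t0))
  named1 <- !is.null(names(counts_t1))
  if (named0 != named1)
    stop("both count vectors must be named, or neither", call. = FALSE)
  if (named0) {
    groups <- sort(union(names(counts_t0), names(counts_t1)))
    x0 <- setNames(rep(0, length(groups)), groups)
    x0[names(counts_t0)] <- counts_t0
    x1 <- setNames(rep(0, length(groups)), groups)
    x1[names(counts_t1)] <- counts_t1
  } else {
    if (length(counts_t0) != length(counts_t1))
      stop("unnamed count vectors must cover the same group universe",
           call. = FALSE)
    groups <- as.character(seq_along(counts_t0))
    x0 <- as.numeric(counts_t0)
    x1 <- as.numeric(counts_t1)
  }
  if (any(x0 < 0) || any(x1 < 0)) stop("counts must be non-negative", call. = FALSE)
  n0 <- sum(x0); n1 <- sum(x1)
  if (n0 < 1 || n1 < 1) stop("each timepoint needs at least one read", call. = FALSE)
  res <- vapply(seq_along(groups), function(i) {
    ft <- fisher.test(matrix(c(x0[i], n0 - x0[i], x1[i], n1 - x1[i]), 2))
    c(ft$p.value, unname(ft$estimate))
  }, numeric(2))
  q <- bh_adjust(res[1, ])
  out <- data.frame(group = groups, count_t0 = x0, count_t1 = x1,
                    freq_t0 = x0 / n0, freq_t1 = x1 / n1,
                    odds_ratio = res[2, ], p = res[1, ], q = q,
                    row.names = NULL)
  attr(out, "alpha") <- alpha
  attr(out, "enriched") <- any(q <= alpha)
  out
}

#' Clonal expansion search space
#'
#' The number of possible daughter cells after a given number of doublings,
#' `2 ^ doublings`; ~112 doublings of a founder already spans ~5e33 cells.
#' Exact for any doublings count (powers of two are exactly representable).
#'
#' @param doublings Number of doublings (>= 0).
#' @return Numeric count.
#' @examples
#' clonal_expansion_space(112)
#' @export
clonal_expansion_space <- function(doublings) {
  stop_if_not_scalar_count(doublings, "doublings", min = 0)
  2^doublings
}
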