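#' Simulate a labeled expression matrix with planted signature genes
#'
#' Generates a cells x genes matrix for two or more cell classes in which a
#' chosen set of signature genes is shifted upward by `effect_size` in the
#' target class on the log scale; all other gene/class combinations are
#' exchangeable. Values are log-normal: per gene a baseline log-mean is
#' drawn, per cell a normal deviate with standard deviation `sigma` is
#' added, and the result exponentiated, giving strictly positive
#' expression on which log-scale t-tests are well behaved.
#'
#' @param n_cells_per_class Named integer vector of cells per class, e.g.
#'   `c(RD = 50, nonRD = 50)`; at least two classes of two cells each.
#' @param n_genes Number of genes (identifiers `gene_1`, ...), ignored when
#'   `genes` is given.
#' @param genes Optional character vector of gene identifiers.
#' @param signature_genes Gene identifiers to up-shift, or a count to pick
#'   the first so many; must be a subset of `genes`. May be empty.
#' @param target_class Class receiving the shift; default the first.
#' @param effect_size Mean log-scale shift (>= 0); default 1.
#' @param sigma Log-scale noise standard deviation; default 1.
#' @param baseline_log_mean,baseline_log_sd Distribution of per-gene
#'   baseline log-means.
#' @param seed Integer seed.
#' @return A [labeled_expression()] object with attribute `truth` (list
#'   with `signature_genes`, `target_class`, `effect_size`).
#' @export
gen_labeled_expression <- function(n_cells_per_class = c(RD = 50, nonRD = 50),
                                   n_genes = 2000, genes = NULL,
                                   signature_genes = character(),
                                   target_class = NULL, effect_size = 1,
                                   sigma = 1, baseline_log_mean = 2,
                                   baseline_log_sd = 0.5, seed = NULL) {
  if (length(n_cells_per_class) < 2L || any(n_cells_per_class < 2L))
    stop("need >= 2 classes with >= 2 cells each", call. = FALSE)
  if (is.null(names(n_cells_per_class)))
    names(n_cells_per_class) <- paste0("class", seq_along(n_cells_per_class))
  if (is.null(genes)) genes <- paste0("gene_", seq_len(n_genes))
  if (is.numeric(signature_genes) && length(signature_genes) == 1L)
    signature_genes <- head(genes, signature_genes)
  signature_genes <- as.character(signature_genes)
  if (!all(signature_genes %in% genes))
    stop("signature_genes must be a subset of genes", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (is.null(target_class)) target_class <- names(n_cells_per_class)[[1]]
  if (!target_class %in% names(n_cells_per_class))
    stop("target_class not among the classes", call. = FALSE)

  labels <- factor(rep(names(n_cells_per_class), n_cells_per_class),
                   levels = names(n_cells_per_class))
  n_cells <- length(labels)
  with_seed(seed, {
    baseline <- rnorm(length(genes), baseline_log_mean, baseline_log_sd)
    logv <- matrix(rnorm(n_cells * length(genes), sd = sigma),
                   nrow = n_cells) + rep(baseline, each = n_cells)
    if (length(signature_genes) && effect_size > 0) {
      sig_idx <- match(signature_genes, genes)
      tgt <- labels == target_class
      logv[tgt, sig_idx] <- logv[tgt, sig_idx] + effect_size
    }
    values <- exp(logv)
    dimnames(values) <- list(paste0("cell_", seq_len(n_cells)), genes)
    out <- labeled_expression(values, labels)
    attr(out, "truth") <- list(signature_genes = signature_genes,
                               target_class = target_class,
                               effect_size = effect_size, sigma = sigma)
    out
  })
}
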