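#' Simulate a drug-perturbation reference matrix with planted reversers
#'
#' Emulates a genes x perturbations differential-expression reference (the
#' layout of an L1000 Level-4 slice): background values are independent
#' standard normal; planted *reversers* push the signature genes strongly
#' negative in their profile (so the signature concentrates at the
#' down-regulated end and scores negatively downstream) and planted
#' *mimics* push them strongly positive.
#'
#' @param signature [gene_signature()] or character vector; must be
#'   non-empty and contained in the gene universe.
#' @param n_perturbations Number of perturbation profiles.
#' @param n_genes Size of the gene universe; extra genes `ref_gene_*` are
#'   added around the signature. Must exceed the signature size.
#' @param n_reversers,n_mimics Numbers of planted perturbations (disjoint
#'   sets, together at most `n_perturbations`).
#' @param effect Absolute mean shift applied to signature genes in planted
#'   profiles; default 4.
#' @param seed Integer seed.
#' @return List of class `sim_reference` with `reference` (matrix),
#'   `truth` (data frame `perturbation`, `role`) and `signature_genes`.
#' @export
gen_drug_reference <- function(signature, n_perturbations = 100,
                               n_genes = 978, n_reversers = 1, n_mimics = 0,
                               effect = 4, seed = NULL) {
  genes <- if (inherits(signature, "gene_signature")) signature$genes
           else as.character(signature)
  if (length(genes) == 0L) stop("empty signature", call. = FALSE)
  if (n_genes <= length(genes))
    stop("gene universe must exceed the signature size", call. = FALSE)
  stop_if_not_scalar_count(n_perturbations, "n_perturbations", min = 1)
  if (n_reversers + n_mimics > n_perturbations)
    stop("more planted perturbations than profiles", call. = FALSE)
  universe <- c(genes, sprintf("ref_gene_%03d", seq_len(n_genes - length(genes))))
  perts <- sprintf("pert_%03d", seq_len(n_perturbations))
  with_seed(seed, {
    ref <- matrix(rnorm(n_genes * n_perturbations), nrow = n_genes,
                  dimnames = list(universe, perts))
    role <- rep("noise", n_perturbations)
    planted <- sample.int(n_perturbations, n_reversers + n_mimics)
    rev_idx <- head(planted, n_reversers)
    mim_idx <- utils::tail(planted, n_mimics)
    sig_rows <- match(genes, universe)
    if (n_reversers > 0) {
      ref[sig_rows, rev_idx] <- ref[sig_rows, rev_idx] - effect
      role[rev_idx] <- "reverser"
    }
    if (n_mimics > 0) {
      ref[sig_rows, mim_idx] <- ref[sig_rows, mim_idx] + effect
      role[mim_idx] <- "mimic"
    }
    structure(list(reference = ref,
                   truth = data.frame(perturbation = perts, role = role),
                   signature_genes = genes),
              class = "sim_reference")
  })
}

#' @export
print.sim_reference <- function(x, ...) {
  cat(sprintf("sim_reference: %d genes x %d perturbations (%d reversers, %d mimics planted)\n",
              nrow(x$reference), ncol(x$reference),
              sum(x$truth$role == "reverser"), sum(x$truth$role == "mimic")))
  invisible(x)
}
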