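#' Labeled expression matrix
#'
#' A lightweight container for a cells x genes expression matrix with a
#' two-class label per cell (e.g. residual disease "RD" vs "nonRD", or
#' "DTP" vs "DMSO").
#'
#' @param values Non-negative numeric matrix, cells in rows, genes in
#'   columns; row and column names identify cells and genes.
#' @param labels Class label per cell (length `nrow(values)`).
#' @return An object of class `labeled_expression`.
#' @export
labeled_expression <- function(values, labels) {
  values <- as.matrix(values)
  if (any(is.na(values)) || any(values < 0))
    stop("expression values must be non-negative with no missing entries",
         call. = FALSE)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("values must carry unique gene (column) names", call. = FALSE)
  labels <- as.factor(labels)
  if (length(labels) != nrow(values))
    stop("one label per cell (row) required", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2L)
    stop("at least two classes required", call. = FALSE)
  if (any(table(labels) < 2L))
    stop("each class needs at least 2 cells", call. = FALSE)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("cell_", seq_len(nrow(values)))
  structure(list(values = values, labels = droplevels(labels)),
            class = "labeled_expression")
}

#' @export
print.labeled_expression <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("labeled_expression: %d cells x %d genes (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# Per-cell library-size normalization to counts-per-10k followed by
# log(1 + x); the default scale for testing and scoring.
normalize_cp10k_log1p <- function(values) {
  lib <- rowSums(values)
  lib[lib == 0] <- 1
  log1p(values * (1e4 / lib))
}

prepare_values <- function(x, labels, normalize) {
  if (inherits(x, "labeled_expression")) {
    values <- x$values
    labels <- x$labels
  } else {
    values <- as.matrix(x)
    if (is.null(labels)) stop("labels required with a plain matrix", call. = FALSE)
    labels <- as.factor(labels)
  }
  if (normalize) values <- normalize_cp10k_log1p(values)
  list(values = values, labels = labels)
}

# Vectorized two-sample t statistics over the columns of `values`.
# Pooled-variance Student's t by default, Welch when var_equal = FALSE.
# Sign convention: positive t means higher mean in the class of interest.
column_tstats <- function(values, is_interest, var_equal = TRUE) {
  nA <- sum(is_interest); nB <- sum(!is_interest)
  A <- values[is_interest, , drop = FALSE]
  B <- values[!is_interest, , drop = FALSE]
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- colSums(A^2) / (nA - 1) - mA^2 * (nA / (nA - 1))
  vB <- colSums(B^2) / (nB - 1) - mB^2 * (nB / (nB - 1))
  vA <- pmax(vA, 0); vB <- pmax(vB, 0)  # guard tiny negative rounding
  if (var_equal) {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- rep(nA + nB - 2, length(se))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  delta <- mA - mB
  t <- delta / se
  # degenerate genes: no variance at all
  zero <- se == 0
  t[zero & delta == 0] <- 0
  t[zero & delta > 0] <- Inf
  t[zero & delta < 0] <- -Inf
  p <- 2 * pt(-abs(t), df)
  p[zero & delta == 0] <- 1
  p[zero & delta != 0] <- 0
  list(t = t, p = p, mean_interest = mA, mean_other = mB, df = df)
}

#' Per-gene unpaired t-tests between two cell classes
#'
#' Tests every gene for differential expression between the class of
#' interest and the rest with the classical pooled-variance two-sample
#' t-test (Welch's variant behind `var_equal = FALSE`), two-sided, with
#' Benjamini-Hochberg adjustment across genes. Genes with zero pooled
#' variance and equal means get `t = 0`, `p = 1`. Expression is normalized
#' per cell to counts-per-10k and log(1 + x)-transformed first unless
#' `normalize = FALSE`.
#'
#' @param x A [labeled_expression()] object, or a cells x genes matrix.
#' @param labels Class labels when `x` is a plain matrix.
#' @param class_of_interest Level treated as the "up" direction; default the
#'   first level.
#' @param normalize Apply per-cell CP10k + log1p before testing.
#' @param var_equal Pooled-variance Student's t (TRUE, default) or Welch.
#' @return Data frame with one row per gene: `gene`, `mean_interest`,
#'   `mean_other`, `t`, `p`, `q`, `direction` ("up"/"down"/"none").
#' @export
per_gene_tstat <- function(x, labels = NULL, class_of_interest = NULL,
                           normalize = TRUE, var_equal = TRUE) {
  d <- prepare_values(x, labels, normalize)
  lv <- levels(droplevels(d$labels))
  if (length(lv) != 2L && is.null(class_of_interest))
    stop("name a class_of_interest when there are more than two classes",
         call. = FALSE)
  if (is.null(class_of_interest)) class_of_interest <- lv[[1]]
  if (!class_of_interest %in% lv)
    stop("class_of_interest not among the labels", call. = FALSE)
  is_int <- d$labels == class_of_interest
  if (sum(is_int) < 2L || sum(!is_int) < 2L)
    stop("each class needs at least 2 cells", call. = FALSE)
  st <- column_tstats(d$values, is_int, var_equal)
  genes <- colnames(d$values)
  if (is.null(genes)) genes <- paste0("gene_", seq_along(st$t))
  data.frame(gene = genes, mean_interest = st$mean_interest,
             mean_other = st$mean_other, t = st$t, p = st$p,
             q = bh_adjust(st$p),
             direction = ifelse(st$mean_interest > st$mean_other, "up",
                         ifelse(st$mean_interest < st$mean_other, "down",
                                "none")),
             row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (a validated wrapper around
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Gene signature
#'
#' An ordered set of up-regulated gene identifiers with provenance (the
#' names of the differential comparisons whose intersection produced it).
#'
#' @param genes Character vector of unique gene identifiers.
#' @param direction Direction of regulation; only "up" is used here.
#' @param provenance Character vector naming the source sets intersected.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(genes, direction = "up", provenance = character()) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("signature genes must be unique", call. = FALSE)
  structure(list(genes = genes, direction = direction,
                 provenance = as.character(provenance)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature: %d %s-regulated genes", length(x$genes),
              x$direction))
  if (length(x$provenance))
    cat(sprintf(" (intersection of %s)", paste(x$provenance, collapse = " & ")))
  cat("\n")
  if (length(x$genes)) {
    cat(" ", paste(head(x$genes, 10), collapse = ", "))
    if (length(x$genes) > 10) cat(", ...")
    cat("\n")
  }
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

#' Define a signature as the intersection of significantly up-regulated sets
#'
#' Takes two or more differential-expression tables (from
#' [per_gene_tstat()]) or plain character vectors of up-regulated genes and
#' intersects them: a gene enters the signature only if it is significantly
#' up-regulated (`q < alpha`, direction "up") in every table. This is how a
#' residual-disease signature is distilled from independent comparisons
#' (e.g. a YAP-activation gene set, DTP models, and the on-treatment patient
#' timepoint).
#'
#' @param stat_tables Named list of [per_gene_tstat()] data frames and/or
#'   character vectors of up-regulated gene identifiers.
#' @param alpha Adjusted-p cutoff for significance; default 0.05.
#' @return A [gene_signature()], ordered as in the first table. An empty
#'   intersection yields an empty signature with a warning.
#' @export
build_intersection_signature <- function(stat_tables, alpha = 0.05) {
  if (!is.list(stat_tables) || length(stat_tables) < 2L)
    stop("at least two tables or gene sets required", call. = FALSE)
  nms <- names(stat_tables)
  if (is.null(nms) || any(!nzchar(nms)))
    nms <- paste0("set", seq_along(stat_tables))
  up_sets <- lapply(stat_tables, function(tb) {
    if (is.character(tb)) return(unique(tb))
    if (is.data.frame(tb) && all(c("gene", "q", "direction") %in% names(tb)))
      return(tb$gene[tb$q < alpha & tb$direction == "up"])
    stop("each element must be a per_gene_tstat table or a character vector",
         call. = FALSE)
  })
  genes <- Reduce(intersect, up_sets)
  if (length(genes) == 0L)
    warning("empty intersection: no gene is significantly up in every set",
            call. = FALSE)
  gene_signature(genes, direction = "up", provenance = nms)
}

#' Permutation test of a gene set's differential expression
#'
#' The set statistic is the mean of the constituent genes' two-sample t
#' statistics; its null distribution is obtained by permuting the cell class
#' labels. The empirical p-value uses the add-one estimator
#' `p = (1 + #(|T_perm| >= |T_obs|)) / (B + 1)`. With `exact = TRUE` all
#' distinct label assignments are enumerated instead of sampled (feasible
#' for small cell numbers) and the p-value is the exact permutation p.
#'
#' @inheritParams per_gene_tstat
#' @param signature A [gene_signature()] or character vector of genes, all
#'   present in the matrix.
#' @param B Number of sampled label permutations; default 1000.
#' @param seed Integer seed for the permutation draws.
#' @param exact Enumerate all distinct class assignments instead of
#'   sampling.
#' @return An object of class `set_test_result`: list with `statistic`
#'   (observed mean t), `B`, `p`, `method`, `perm_stats`.
#' @export
permutation_set_test <- function(x, signature, labels = NULL,
                                 class_of_interest = NULL, B = 1000,
                                 seed = NULL, exact = FALSE,
                                 normalize = TRUE, var_equal = TRUE) {
  genes <- if (inherits(signature, "gene_signature")) signature$genes
           else as.character(signature)
  if (length(genes) == 0L) stop("empty signature", call. = FALSE)
  d <- prepare_values(x, labels, normalize)
  missing <- setdiff(genes, colnames(d$values))
  if (length(missing))
    stop(sprintf("%d signature genes absent from the matrix", length(missing)),
         call. = FALSE)
  lv <- levels(droplevels(d$labels))
  if (is.null(class_of_interest)) class_of_interest <- lv[[1]]
  is_int <- d$labels == class_of_interest
  vals <- d$values[, genes, drop = FALSE]
  t_obs <- mean(column_tstats(vals, is_int, var_equal)$t)
  n <- length(is_int); nA <- sum(is_int)
  if (exact) {
    combos <- utils::combn(n, nA)
    perm <- apply(combos, 2, function(ix) {
      flag <- logical(n); flag[ix] <- TRUE
      mean(column_tstats(vals, flag, var_equal)$t)
    })
    obs_col <- which(apply(combos, 2, function(ix) {
      flag <- logical(n); flag[ix] <- TRUE
      identical(flag, as.logical(is_int))
    }))
    p <- sum(abs(perm) >= abs(t_obs) - 1e-12) / ncol(combos)
    B_eff <- ncol(combos) - 1L
    perm <- perm[-obs_col]
    method <- "exact"
  } else {
    stop_if_not_scalar_count(B, "B", min = 1)
    perm <- with_seed(seed, vapply(seq_len(B), function(b) {
      flag <- logical(n)
      flag[sample.int(n, nA)] <- TRUE
      mean(column_tstats(vals, flag, var_equal)$t)
    }, numeric(1)))
    p <- (1 + sum(abs(perm) >= abs(t_obs) - 1e-12)) / (B + 1)
    B_eff <- B
    method <- "sampled"
  }
  structure(list(statistic = t_obs, B = B_eff, p = p, method = method,
                 signature_size = length(genes), perm_stats = perm),
            class = "set_test_result")
}

#' @export
print.set_test_result <- function(x, ...) {
  cat(sprintf("set_test_result: mean gene t = %.3f over %d genes, %s permutation p = %.4g (B = %d)\n",
              x$statistic, x$signature_size, x$method, x$p, x$B))
  invisible(x)
}

#' Combine several set tests with FDR adjustment across sets
#'
#' @param results Named list of [permutation_set_test()] results.
#' @return Data frame with `set`, `statistic`, `B`, `p`, `q` (BH across
#'   sets).
#' @export
set_test_table <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "set_test_result")))
  nms <- names(results)
  if (is.null(nms)) nms <- paste0("set", seq_along(results))
  p <- vapply(results, `[[`, numeric(1), "p")
  data.frame(set = nms,
             statistic = vapply(results, `[[`, numeric(1), "statistic"),
             B = vapply(results, `[[`, numeric(1), "B"),
             p = p, q = bh_adjust(p), row.names = NULL)
}

#' Score cells by mean signature expression
#'
#' Per cell, the mean of (normalized, log-scaled) expression over the
#' signature genes — the standard per-cell summary used to visualise a
#' signature along a treatment course.
#'
#' @param x A [labeled_expression()] object or a cells x genes matrix.
#' @param signature [gene_signature()] or character vector.
#' @param normalize Apply per-cell CP10k + log1p first (default TRUE).
#' @param allow_partial Drop (with a message) signature genes absent from
#'   the matrix instead of failing; at least one gene must remain.
#' @return Named numeric vector of per-cell scores.
#' @export
score_cells <- function(x, signature, normalize = TRUE,
                        allow_partial = FALSE) {
  genes <- if (inherits(signature, "gene_signature")) signature$genes
           else as.character(signature)
  if (length(genes) == 0L) stop("empty signature", call. = FALSE)
  values <- if (inherits(x, "labeled_expression")) x$values else as.matrix(x)
  missing <- setdiff(genes, colnames(values))
  if (length(missing) == length(genes))
    stop("no signature gene present in the matrix", call. = FALSE)
  if (length(missing)) {
    if (!allow_partial)
      stop(sprintf("%d signature genes absent (set allow_partial = TRUE to drop them)",
                   length(missing)), call. = FALSE)
    message(sprintf("dropping %d signature genes absent from the matrix",
                    length(missing)))
    genes <- setdiff(genes, missing)
  }
  if (normalize) values <- normalize_cp10k_log1p(values)
  rowMeans(values[, genes, drop = FALSE])
}
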