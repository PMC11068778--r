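# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops and textbook formulas only.

# position-wise Hamming distance
oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  d <- 0L
  for (k in seq_along(ca)) if (ca[k] != cb[k]) d <- d + 1L
  d
}

# sup-difference of the two empirical step functions over all N positions:
# a = sup_i (F_sig(i) - i/N), b = sup_i (i/N - F_sig(i - 1)), evaluated as
# integer numerators over the common denominator s*N so the a vs b
# comparison is exact
oracle_ks <- function(pos, N) {
  s <- length(pos)
  a_num <- 0; b_num <- 0
  hits <- 0L
  for (i in seq_len(N)) {
    before <- hits
    if (i %in% pos) hits <- hits + 1L
    a_num <- max(a_num, hits * N - i * s)
    b_num <- max(b_num, i * s - before * N)
  }
  if (a_num > b_num) a_num / (s * N) else -b_num / (s * N)
}

# textbook pooled-variance two-sample t statistic (class A minus class B)
oracle_pooled_t <- function(xa, xb) {
  na <- length(xa); nb <- length(xb)
  sp2 <- ((na - 1) * var(xa) + (nb - 1) * var(xb)) / (na + nb - 2)
  (mean(xa) - mean(xb)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# exhaustive permutation p for the mean-of-t set statistic at small n:
# enumerate every way of assigning na cells to class A
oracle_exact_set_p <- function(values, is_a) {
  n <- nrow(values); na <- sum(is_a)
  stat <- function(flag) {
    ts <- apply(values, 2, function(v) oracle_pooled_t(v[flag], v[!flag]))
    mean(ts)
  }
  t_obs <- stat(is_a)
  combos <- combn(n, na)
  hits <- 0L
  for (ci in seq_len(ncol(combos))) {
    flag <- seq_len(n) %in% combos[, ci]
    if (abs(stat(flag)) >= abs(t_obs) - 1e-12) hits <- hits + 1L
  }
  hits / ncol(combos)
}
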