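test_that("per-gene t matches the textbook pooled formula", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1, dimnames = list(NULL, "g1"))
  lab <- c("A", "A", "A", "B", "B", "B")
  tb <- per_gene_tstat(m, labels = lab, class_of_interest = "A",
                       normalize = FALSE)
  expect_equal(tb$t, -3.674235, tolerance = 1e-6)
  expect_equal(tb$p, 0.02131164, tolerance = 1e-6)
  expect_identical(tb$direction, "down")
  expect_equal(tb$q, tb$p)  # single p: q = p

  # random matrices against stats::t.test, pooled and Welch
  set.seed(1)
  vals <- matrix(rlnorm(20 * 6), nrow = 20,
                 dimnames = list(NULL, paste0("g", 1:6)))
  lab2 <- rep(c("A", "B"), c(8, 12))
  for (ve in c(TRUE, FALSE)) {
    tb2 <- per_gene_tstat(vals, labels = lab2, class_of_interest = "A",
                          normalize = FALSE, var_equal = ve)
    for (g in 1:6) {
      tt <- t.test(vals[lab2 == "A", g], vals[lab2 == "B", g],
                   var.equal = ve)
      expect_equal(tb2$t[g], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(tb2$p[g], tt$p.value, tolerance = 1e-10)
    }
  }
})

test_that("swapping the class of interest flips every t", {
  set.seed(2)
  vals <- matrix(rlnorm(30 * 10), nrow = 30,
                 dimnames = list(NULL, paste0("g", 1:10)))
  lab <- rep(c("A", "B"), 15)
  ta <- per_gene_tstat(vals, labels = lab, class_of_interest = "A")
  tb <- per_gene_tstat(vals, labels = lab, class_of_interest = "B")
  expect_equal(ta$t, -tb$t)
})

test_that("degenerate genes get t = 0, p = 1 and small classes fail", {
  m <- matrix(c(rep(2, 6), rep(2, 3), rep(5, 3)), ncol = 2,
              dimnames = list(NULL, c("flat", "split")))
  lab <- rep(c("A", "B"), each = 3)
  tb <- per_gene_tstat(m, labels = lab, class_of_interest = "A",
                       normalize = FALSE)
  expect_equal(tb$t[tb$gene == "flat"], 0)
  expect_equal(tb$p[tb$gene == "flat"], 1)
  # zero variance but different means: maximally significant
  expect_equal(tb$p[tb$gene == "split"], 0)
  expect_error(per_gene_tstat(m, labels = c("A", rep("B", 5)),
                              class_of_interest = "A"), "at least 2 cells")
})

test_that("bh_adjust reproduces step-up hand computations", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.001, 0.2, 0.9)),
               c(0.003, 0.3, 0.9))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "0, 1")
  # step-up structure: q >= p, clipped at 1, monotone in the p-ordering
  set.seed(3)
  p <- runif(50)^2
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= 0))
})

test_that("intersection signature keeps genes up-significant everywhere", {
  sig <- build_intersection_signature(
    list(s1 = c("A", "B", "C"), s2 = c("B", "C", "D"), s3 = c("C", "B")))
  expect_setequal(sig$genes, c("B", "C"))
  expect_identical(sig$provenance, c("s1", "s2", "s3"))

  expect_warning(
    empty <- build_intersection_signature(list(a = c("A"), b = c("B"))),
    "empty intersection")
  expect_length(empty$genes, 0)
  expect_error(build_intersection_signature(list(c("A"))), "at least two")
})

test_that("planted genes shared by three comparisons define the signature", {
  planted <- paste0("gene_", 1:30)
  tables <- lapply(1:3, function(s)
    per_gene_tstat(gen_labeled_expression(
      c(DTP = 40, ctrl = 40), n_genes = 400, signature_genes = planted,
      target_class = "DTP", effect_size = 2, seed = 100 + s)))
  names(tables) <- c("PC9", "H3122", "H358")
  sig <- build_intersection_signature(tables)
  expect_setequal(sig$genes, planted)
})

test_that("exact permutation set test agrees with exhaustive enumeration", {
  set.seed(4)
  vals <- matrix(rlnorm(6 * 4), nrow = 6,
                 dimnames = list(NULL, paste0("g", 1:4)))
  vals[1:3, 1:2] <- vals[1:3, 1:2] * 4  # some signal in two genes
  lab <- rep(c("A", "B"), each = 3)
  res <- permutation_set_test(vals, c("g1", "g2"), labels = lab,
                              class_of_interest = "A", exact = TRUE,
                              normalize = FALSE)
  expect_identical(res$B, 19L)  # choose(6, 3) - 1 distinct relabelings
  expect_equal(res$p, oracle_exact_set_p(vals[, c("g1", "g2")], lab == "A"))
  # relabeling invariance of the two-sided p
  res_b <- permutation_set_test(vals, c("g1", "g2"), labels = lab,
                                class_of_interest = "B", exact = TRUE,
                                normalize = FALSE)
  expect_equal(res_b$p, res$p)
  expect_equal(res_b$statistic, -res$statistic)
})

test_that("permutation p is approximately uniform under the null", {
  ps <- vapply(1:200, function(s) {
    le <- gen_labeled_expression(c(A = 10, B = 10), n_genes = 10,
                                 signature_genes = 10, effect_size = 0,
                                 seed = 1000 + s)
    permutation_set_test(le, paste0("gene_", 1:10), B = 199,
                         seed = 2000 + s, normalize = FALSE)$p
  }, numeric(1))
  d <- suppressWarnings(ks.test(ps, "punif"))$statistic
  expect_lt(unname(d), 0.1)
})

test_that("a strong planted effect saturates the permutation p", {
  le <- gen_labeled_expression(c(RD = 50, nonRD = 50), n_genes = 200,
                               signature_genes = 20, effect_size = 2,
                               seed = 5)
  res <- permutation_set_test(le, paste0("gene_", 1:20), B = 199, seed = 6)
  expect_equal(res$p, 1 / 200)
  expect_gt(res$statistic, 0)
})

test_that("score_cells averages signature expression per cell", {
  m <- matrix(c(2, 4, 6, 4, 8, 10), nrow = 3,
              dimnames = list(paste0("c", 1:3), c("g1", "g2")))
  expect_equal(score_cells(m, "g1", normalize = FALSE),
               c(c1 = 2, c2 = 4, c3 = 6))
  expect_equal(score_cells(m, c("g1", "g2"), normalize = FALSE),
               c(c1 = 3, c2 = 6, c3 = 8))
  expect_error(score_cells(m, "gX", normalize = FALSE), "no signature gene")
  expect_error(score_cells(m, c("g1", "gX"), normalize = FALSE),
               "allow_partial")
  expect_message(
    sc <- score_cells(m, c("g1", "gX"), normalize = FALSE,
                      allow_partial = TRUE),
    "dropping 1")
  expect_equal(sc, c(c1 = 2, c2 = 4, c3 = 6))
})

test_that("planted up-class cells score higher than the rest", {
  le <- gen_labeled_expression(c(RD = 40, nonRD = 40), n_genes = 300,
                               signature_genes = 25, effect_size = 1.5,
                               seed = 7)
  sc <- score_cells(le, attr(le, "truth")$signature_genes)
  w <- wilcox.test(sc[le$labels == "RD"], sc[le$labels == "nonRD"],
                   alternative = "greater")
  expect_lt(w$p.value, 1e-10)
})

test_that("set_test_table adjusts across sets", {
  le <- gen_labeled_expression(c(A = 20, B = 20), n_genes = 100,
                               signature_genes = 10, effect_size = 2,
                               seed = 8)
  res <- list(
    sig = permutation_set_test(le, paste0("gene_", 1:10), B = 99, seed = 9),
    rand = permutation_set_test(le, paste0("gene_", 51:60), B = 99,
                                seed = 10))
  tab <- set_test_table(res)
  expect_identical(tab$set, c("sig", "rand"))
  expect_equal(tab$q, bh_adjust(tab$p))
})
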