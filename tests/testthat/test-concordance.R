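test_that("rank_profile orders by value with deterministic tie-breaks", {
  expect_identical(rank_profile(c(g1 = 2, g2 = 1)), c("g1", "g2"))
  expect_identical(rank_profile(c(g2 = 1, g1 = 1)), c("g1", "g2"))
  v <- c(a = 3, b = 2, c = 1)
  expect_identical(rev(rank_profile(v)), rank_profile(-v))
  expect_error(rank_profile(setNames(c(1, 2), c("g1", "g1"))), "duplicate")
  expect_error(rank_profile(c(1, 2)), "named")
  expect_error(rank_profile(c(g1 = NA, g2 = 1)), "missing")
})

test_that("ks_score reproduces the block closed forms", {
  ranked <- paste0("g", 1:10)
  expect_equal(ks_score(ranked, paste0("g", 1:3)), 0.7)     # 1 - s/N
  expect_equal(ks_score(ranked, paste0("g", 8:10)), -0.8)   # -(1 - (s-1)/N)
  for (N in c(5, 12, 30, 50)) {
    ranked <- paste0("g", seq_len(N))
    for (s in seq_len(N - 1)) {
      top <- ks_score(ranked, paste0("g", seq_len(s)))
      if (s <= N - 2) {
        expect_equal(top, 1 - s / N)
      } else {
        # s = N - 1: the top block ties a = b = 1/N and the signed-max
        # convention resolves ties toward -b
        expect_equal(top, -1 / N)
      }
      expect_equal(ks_score(ranked, paste0("g", (N - s + 1):N)),
                   -(1 - (s - 1) / N))
    }
  }
  expect_error(ks_score(paste0("g", 1:10), paste0("g", 1:10)), "strict")
  expect_error(ks_score(paste0("g", 1:10), character(0)), "strict")
  expect_error(ks_score(paste0("g", 1:10), "missing_gene"), "missing")
})

test_that("ks_score equals the brute-force sup-difference oracle exhaustively", {
  for (N in c(5, 8, 12)) {
    ranked <- paste0("g", seq_len(N))
    for (s in seq_len(N - 1)) {
      combos <- combn(N, s)
      for (ci in seq_len(ncol(combos))) {
        pos <- combos[, ci]
        expect_equal(ks_score(ranked, ranked[pos]), oracle_ks(pos, N))
      }
    }
  }
})

test_that("reversing the ranking flips the score up to rank discretization", {
  # Reversal maps positions p -> N + 1 - p, which sends the top-excess a to
  # b - 1/N and the bottom-excess b to a + 1/N: the score negates up to the
  # exact 1/N step of the rank grid whenever the decisive side is clear.
  N <- 8; s <- 3
  ranked <- paste0("g", 1:N)
  combos <- combn(N, s)
  for (ci in seq_len(ncol(combos))) {
    pos <- combos[, ci]
    sc <- ks_score(ranked, ranked[pos])
    expect_lte(abs(sc), 1)
    rev_sc <- ks_score(rev(ranked), ranked[pos])
    j <- seq_len(s); p <- sort(pos)
    a <- max(j / s - p / N); b <- max(p / N - (j - 1) / s)
    if (a > b + 1e-12 || b > a + 2 / N + 1e-12) {
      expect_equal(abs(rev_sc + sc), 1 / N)
      expect_lte(sign(rev_sc) * sign(sc), 0)
    }
  }
})

test_that("concordance_screen is deterministic and bounded", {
  sig <- paste0("gene_", 1:10)
  ref <- gen_drug_reference(sig, n_perturbations = 20, n_genes = 100,
                            n_reversers = 0, seed = 1)$reference
  s1 <- concordance_screen(ref, sig, R = 100, seed = 42)
  s2 <- concordance_screen(ref, sig, R = 100, seed = 42)
  expect_identical(s1$score, s2$score)
  expect_identical(s1$p, s2$p)
  expect_true(all(abs(s1$score) <= 1))
  expect_true(all(s1$p >= 1 / 101 & s1$p <= 1))
  # R = 1: add-one estimator can only give 0.5 or 1
  s3 <- concordance_screen(ref, sig, R = 1, seed = 43)
  expect_true(all(s3$p %in% c(0.5, 1)))
})

test_that("the null score distribution is symmetric about zero", {
  sig <- paste0("gene_", 1:15)
  ref <- gen_drug_reference(sig, n_perturbations = 5, n_genes = 200,
                            n_reversers = 0, seed = 2)$reference
  s <- concordance_screen(ref, sig, R = 4000, seed = 3)
  null <- attr(s, "null_scores")
  expect_lt(abs(mean(null)), 3 * sd(null) / sqrt(length(null)))
  expect_lt(abs(mean(null > 0) - mean(null < 0)), 0.05)
})

test_that("a planted reverser gets the most negative, significant score", {
  sig <- paste0("gene_", 1:25)
  r <- gen_drug_reference(sig, n_perturbations = 50, n_genes = 500,
                          n_reversers = 1, n_mimics = 1, effect = 4,
                          seed = 4)
  s <- concordance_screen(r$reference, sig, R = 1999, seed = 5)
  truth_rev <- r$truth$perturbation[r$truth$role == "reverser"]
  truth_mim <- r$truth$perturbation[r$truth$role == "mimic"]
  expect_identical(s$perturbation[which.min(s$score)], truth_rev)
  expect_lte(s$q[s$perturbation == truth_rev], 0.05)
  expect_gt(s$score[s$perturbation == truth_mim], 0)
  sel <- select_reversers(s)
  expect_identical(sel$perturbation[[1]], truth_rev)
  expect_false(truth_mim %in% sel$perturbation)
})

test_that("signature genes absent from the universe are dropped with a count", {
  sig <- c(paste0("gene_", 1:10), "not_in_reference")
  ref <- gen_drug_reference(paste0("gene_", 1:10), n_perturbations = 5,
                            n_genes = 50, n_reversers = 0,
                            seed = 6)$reference
  expect_message(s <- concordance_screen(ref, sig, R = 50, seed = 7),
                 "1 of 11")
  expect_identical(attr(s, "signature_size"), 10L)
  expect_identical(attr(s, "dropped"), 1L)
  expect_error(concordance_screen(ref, c("x", "y"), R = 10),
               "does not intersect")
})

test_that("select_reversers filters on sign, significance and annotation", {
  rec <- data.frame(
    perturbation = c("p1", "p2", "p3", "p4", "p5"),
    score = c(-0.8, -0.8, 0.9, -0.5, -0.8),
    p = c(0.001, 0.2, 0.001, 0.01, 0.001),
    q = c(0.01, 0.2, 0.001, 0.04, 0.01),
    target = c("FAK", NA, "x", "", "SRC"))
  out <- select_reversers(rec)
  expect_identical(out$perturbation, c("p1", "p2", "p5", "p4")[c(1, 3, 4)])
  out2 <- select_reversers(rec, annotated_only = TRUE)
  expect_identical(out2$perturbation, c("p1", "p5"))
  # ties in score resolve by perturbation id
  expect_identical(out$perturbation[1:2], c("p1", "p5"))
  expect_identical(nrow(select_reversers(rec, alpha = 1e-6)), 0L)
})

test_that("annotation merges into the screen records", {
  sig <- paste0("gene_", 1:5)
  ref <- gen_drug_reference(sig, n_perturbations = 4, n_genes = 30,
                            n_reversers = 0, seed = 8)$reference
  ann <- data.frame(perturbation = c("pert_002", "pert_004"),
                    target = c("YAP", "FAK"))
  s <- concordance_screen(ref, sig, R = 20, seed = 9, annotation = ann)
  expect_identical(s$perturbation, colnames(ref))
  expect_identical(s$target[s$perturbation == "pert_002"], "YAP")
  expect_true(is.na(s$target[s$perturbation == "pert_001"]))
})
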