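test_that("kernel-ECDF statistic matches its definition", {
  m <- toy_matrix(10, 6, seed = 21)
  expect_equal(kernel_cdf_stat(m), oracle_kernel_z(m), tolerance = 1e-12)

  # constant gene: all 0.5 by the zero-variance rule
  m2 <- m; m2[1, ] <- 3
  expect_true(all(kernel_cdf_stat(m2)[1, ] == 0.5))

  # two samples: antisymmetry of the normal CDF
  m3 <- matrix(c(1, 2), 1, 2, dimnames = list("g", c("a", "b")))
  z <- kernel_cdf_stat(m3)
  expect_lt(z[1, "a"], 0.5)
  expect_gt(z[1, "b"], 0.5)
  expect_equal(unname(z[1, "a"] + z[1, "b"]), 1, tolerance = 1e-12)

  expect_error(kernel_cdf_stat(m[, 1, drop = FALSE]), "2 samples")
})

test_that("GSVA walk signs follow the set's position in the ranking", {
  # construct a matrix where set genes are extreme in one sample
  set.seed(2)
  m <- toy_matrix(20, 4, seed = 2)
  m[1:4, 1] <- m[1:4, 1] + 100   # set at the very top in sample 1
  m[1:4, 2] <- m[1:4, 2] - 100   # and at the very bottom in sample 2
  sets <- list(S = rownames(m)[1:4])
  sc <- gsva_scores(m, sets)
  expect_gt(sc["s001", "S"], 0)
  expect_lt(sc["s002", "S"], 0)
})

test_that("GSVA equals the literal walk oracle in both modes", {
  set.seed(31)
  for (k in 1:10) {
    p <- sample(8:20, 1); n <- sample(3:6, 1)
    m <- toy_matrix(p, n, seed = 1000 + k)
    genes <- sample(rownames(m), sample(2:4, 1))
    for (mode in c("magnitude_difference", "max_deviation")) {
      sc <- gsva_scores(m, list(S = genes),
                        enrichment_params(mode = mode))
      expect_equal(unname(sc[, "S"]),
                   unname(oracle_gsva(m, genes, mode = mode)),
                   tolerance = 1e-12)
    }
  }
})

test_that("duplicated sample columns get identical GSVA scores", {
  m <- toy_matrix(15, 3, seed = 5)
  m2 <- cbind(m, dup = m[, 2])
  colnames(m2) <- c(colnames(m), "dup")
  sc <- gsva_scores(m2, list(S = rownames(m)[1:3]))
  expect_equal(sc["s002", "S"], sc["dup", "S"], tolerance = 1e-12)
})

test_that("GSVA is row-permutation invariant and column equivariant", {
  m <- toy_matrix(18, 5, seed = 8)
  sets <- list(A = rownames(m)[c(2, 5, 9)], B = rownames(m)[c(1, 17)])
  sc <- gsva_scores(m, sets)
  perm_rows <- m[sample(nrow(m)), , drop = FALSE]
  expect_equal(gsva_scores(perm_rows, sets), sc, tolerance = 1e-12,
               ignore_attr = TRUE)
  cols <- sample(ncol(m))
  sc_perm <- gsva_scores(m[, cols, drop = FALSE], sets)
  expect_equal(sc_perm, sc[colnames(m)[cols], , drop = FALSE],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("GSVA scores stay within [-1, 1] and unscorable sets warn", {
  m <- toy_matrix(25, 6, seed = 13)
  sets <- list(ok = rownames(m)[1:5], empty = c("nope1", "nope2"),
               all = rownames(m))
  expect_warning(sc <- gsva_scores(m, sets), "not scorable")
  expect_true(all(abs(sc[, "ok"]) <= 1))
  expect_true(all(is.na(sc[, "empty"])))
  expect_true(all(is.na(sc[, "all"])))
  expect_true(all(is.finite(sc[, "ok"])))
})

test_that("complement sets score with opposite sign under uniform weights", {
  # with tau = 0 the walk weights are uniform and the complement walk is
  # the exact negation, so max_deviation scores flip sign
  params <- enrichment_params(tau = 0, mode = "max_deviation")
  for (k in 1:5) {
    m <- toy_matrix(16, 4, seed = 300 + k)
    genes <- rownames(m)[1:6]
    comp <- setdiff(rownames(m), genes)
    s1 <- gsva_scores(m, list(S = genes), params)[, "S"]
    s2 <- gsva_scores(m, list(S = comp), params)[, "S"]
    expect_true(all(sign(s1) == -sign(s2)))
  }
})

test_that("raising set-gene expression in a sample never lowers its score", {
  for (k in 1:5) {
    m <- toy_matrix(20, 5, seed = 400 + k)
    genes <- rownames(m)[c(3, 7, 11)]
    before <- gsva_scores(m, list(S = genes))["s001", "S"]
    m[genes, "s001"] <- m[genes, "s001"] + 50
    after <- gsva_scores(m, list(S = genes))["s001", "S"]
    expect_gte(after, before - 1e-12)
  }
})

test_that("ssGSEA matches the brute-force summation oracle", {
  m <- toy_matrix(15, 4, seed = 17)
  genes <- rownames(m)[c(2, 6, 9)]
  expect_equal(ssgsea_scores(m, genes), oracle_ssgsea(m, genes),
               tolerance = 1e-12)

  # set at the very top of the ranking maximizes the score
  m2 <- toy_matrix(12, 1, seed = 18)
  m2 <- cbind(m2, m2)  # need n >= 1; two identical samples
  colnames(m2) <- c("x", "y")
  genes2 <- rownames(m2)[order(-m2[, "x"])][1:3]
  top_score <- ssgsea_scores(m2, genes2)[["x"]]
  set.seed(20)
  for (k in 1:10) {
    rand_set <- sample(rownames(m2), 3)
    expect_lte(ssgsea_scores(m2, rand_set)[["x"]], top_score + 1e-12)
  }
})

test_that("ssGSEA with alpha = 0 reduces to uniform set weights", {
  m <- toy_matrix(14, 3, seed = 19)
  genes <- rownames(m)[c(1, 5, 8)]
  s0 <- ssgsea_scores(m, genes, alpha = 0)
  # uniform-weight oracle: P_in steps by 1/m
  p <- nrow(m)
  manual <- vapply(colnames(m), function(j) {
    ord <- order(-m[, j], rownames(m))
    inset <- rownames(m)[ord] %in% genes
    sum(cumsum(inset) / sum(inset) - cumsum(!inset) / (p - sum(inset)))
  }, numeric(1))
  expect_equal(s0, manual, tolerance = 1e-12)
})

test_that("paired delta scores subtract primary from metastasis", {
  scores <- matrix(c(0.2, 0.6, 0.1, 0.1, 0.3, -0.2), 3, 2,
                   dimnames = list(c("p1_P", "p1_M", "p2_P"),
                                   c("setA", "setB")))
  ann <- data.frame(sample_id = c("p1_P", "p1_M", "p2_P"),
                    patient_id = c("p1", "p1", "p2"),
                    lesion = c("primary", "metastasis", "primary"),
                    stringsAsFactors = FALSE)
  expect_warning(delta <- delta_paired_scores(scores, ann), "unpaired")
  expect_equal(delta["p1", "setA"], 0.4, tolerance = 1e-12)
  expect_equal(delta["p1", "setB"], 0.3 - 0.1, tolerance = 1e-12)
  expect_identical(rownames(delta), "p1")

  ann_dup <- rbind(ann, data.frame(sample_id = "p1_P2", patient_id = "p1",
                                   lesion = "primary"))
  scores_dup <- rbind(scores, p1_P2 = c(0, 0))
  expect_error(delta_paired_scores(scores_dup, ann_dup), "duplicate lesion")

  same <- matrix(c(0.5, 0.5), 2, 1,
                 dimnames = list(c("a_P", "a_M"), "s"))
  ann2 <- data.frame(sample_id = c("a_P", "a_M"),
                     patient_id = "a", lesion = c("primary", "metastasis"))
  expect_equal(unname(delta_paired_scores(same, ann2)[1, 1]), 0)
})

test_that("quartile stratification splits at interpolated percentiles", {
  s <- setNames(as.numeric(1:8), paste0("x", 1:8))
  res <- stratify_quartiles(s)
  expect_setequal(names(res$labels)[res$labels == "low"], c("x1", "x2"))
  expect_setequal(names(res$labels)[res$labels == "high"], c("x7", "x8"))

  flat <- setNames(rep(2, 6), paste0("x", 1:6))
  expect_warning(res2 <- stratify_quartiles(flat), "degenerate")
  expect_true(all(res2$labels == "mid"))

  set.seed(99)
  u <- setNames(runif(1000), paste0("u", 1:1000))
  res3 <- stratify_quartiles(u)
  expect_lte(abs(sum(res3$labels == "high") - 250), 1)
  expect_lte(abs(sum(res3$labels == "low") - 250), 1)
  n_high <- sum(res3$labels == "high")
  expect_lte(abs(n_high - ceiling(1000 / 4)), 1)

  expect_error(stratify_quartiles(setNames(1:3, c("a", "b", "c"))),
               "at least 4")
})
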