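test_that("SScore is -log10 of the best p over containing clusters", {
  net <- net_from_pairs("a", "b", "b", "c", "c", "d")
  enr <- make_enriched(list(c("a", "b"), c("b", "c")), c(1e-3, 1e-7),
                       known = character(0), network = net)
  sc <- sscore_table(enr, net)
  s <- stats::setNames(sc$sscore, sc$gene)
  expect_equal(s[["a"]], 3)
  expect_equal(s[["b"]], 7)      # min-p rule across overlapping clusters
  expect_equal(s[["d"]], 0)      # unclustered gene
  expect_equal(sc$best_cluster_id[sc$gene == "b"], 2L)
  expect_true(is.na(sc$best_cluster_id[sc$gene == "d"]))

  # SScore of the published worked table via the exact test itself
  p121 <- fisher_greater(47, 4, 65, 154)
  enr2 <- make_enriched(list(c("a", "b")), p121, character(0), net)
  sc2 <- sscore_table(enr2, net)
  expect_equal(sc2$sscore[sc2$gene == "a"], -log10(p121))
  expect_equal(sc2$sscore[sc2$gene == "a"], 16.237, tolerance = 1e-3)
})

test_that("ROC handles perfect separation, total ties, and mixed ranks", {
  s <- c(k1 = 10, k2 = 10, u1 = 0, u2 = 0, u3 = 0)
  r <- roc_curve(s, c("k1", "k2"))
  expect_equal(r$auc, 1.0)

  s2 <- c(a = 2, b = 2, c = 2, d = 2)
  r2 <- roc_curve(s2, c("a", "b"))
  expect_equal(r2$auc, 0.5)

  # two positive-negative pairs: one concordant, one discordant
  r3 <- roc_curve(c(g1 = 3, g2 = 2, g3 = 1), c("g1", "g3"))
  expect_equal(r3$auc, 0.5)

  expect_error(roc_curve(c(a = 1, b = 2), c("a", "b")), "negative")
  expect_error(roc_curve(c(a = 1, b = 2), "zz"), "positive")
})

test_that("ROC points are monotone and the curve is anchored at (0,0) and (1,1)", {
  set.seed(3)
  s <- stats::setNames(round(stats::runif(30), 2), sprintf("g%02d", 1:30))
  known <- sample(names(s), 12)
  r <- roc_curve(s, known)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_gte(r$auc, 0)
  expect_lte(r$auc, 1)
})

test_that("AUC equals the Mann-Whitney pair-enumeration oracle", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    # coarse scores force ties
    s <- stats::setNames(sample(0:6, n, replace = TRUE) / 2,
                         sprintf("g%02d", seq_len(n)))
    npos <- sample(1:(n - 1), 1)
    known <- sample(names(s), npos)
    r <- roc_curve(s, known)
    expect_equal(r$auc, oracle_auc_pairs(s, names(s) %in% known),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  s <- stats::setNames(stats::rnorm(60), sprintf("g%02d", 1:60))
  known <- sample(names(s), 25)
  r <- roc_curve(s, known)
  ref <- pROC::auc(pROC::roc(response = names(s) %in% known,
                             predictor = unname(s), quiet = TRUE,
                             direction = "<"))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(9)
  p <- stats::runif(40, 1e-12, 1)
  genes <- sprintf("g%02d", 1:40)
  known <- sample(genes, 15)
  a1 <- roc_curve(stats::setNames(-log10(p), genes), known)$auc
  a2 <- roc_curve(stats::setNames(-log(p), genes), known)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  # reversed labels mirror the AUC when scores are tie-free
  s <- stats::setNames(sample(seq_len(40)) / 10, genes)
  expect_equal(roc_curve(s, known)$auc,
               1 - roc_curve(s, setdiff(genes, known))$auc,
               tolerance = 1e-12)
})

test_that("density scan selects the argmax AUC with ties to the larger density", {
  ds <- generate_synthetic(synthetic_spec(
    n_background = 40, n_modules = 2, module_size = 12, seed = 4))
  scan <- scan_densities(ds$network, ds$known, densities = c(0.6, 0.8))
  expect_length(scan$per_density, 2)
  expect_equal(scan$selected_density,
               c(0.6, 0.8)[max(which(scan$auc == max(scan$auc)))])
  # single density -> selected trivially
  one <- scan_densities(ds$network, ds$known, densities = 0.7)
  expect_equal(one$selected_density, 0.7)
  # duplicated density: identical AUCs, larger (equal) density selected
  two <- scan_densities(ds$network, ds$known, densities = c(0.7, 0.7))
  expect_equal(unname(two$auc[1]), unname(two$auc[2]))
  expect_equal(two$selected_density, 0.7)
  expect_error(scan_densities(ds$network, ds$known, densities = numeric(0)),
               "no densities")
})
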