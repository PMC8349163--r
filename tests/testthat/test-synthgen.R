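test_that("generation is deterministic given the seed and leaves RNG state alone", {
  spec <- synthetic_spec(n_background = 30, n_modules = 2,
                         module_size = c(8, 12), seed = 7)
  a <- generate_synthetic(spec)
  set.seed(123)          # unrelated outer state must survive
  before <- .Random.seed
  b <- generate_synthetic(spec)
  expect_identical(before, .Random.seed)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$known, b$known)
  expect_identical(a$modules, b$modules)
  # a different seed changes the draw
  c <- generate_synthetic(synthetic_spec(n_background = 30, n_modules = 2,
                                         module_size = c(8, 12), seed = 8))
  expect_false(identical(a$network$edges, c$network$edges))
})

test_that("forced parameters produce the forced topology", {
  # p_within = 1, one module of 6, no background -> K6
  ds <- generate_synthetic(synthetic_spec(
    n_background = 0, n_modules = 1, module_size = 6, p_within = 1,
    p_background = 0, p_attach = 0, known_frac_background = 0, seed = 1))
  expect_length(ds$network$nodes, 6)
  expect_equal(nrow(ds$network$edges), 15)
  expect_equal(cluster_density(ds$modules[[1]], ds$network), 1.0)
})

test_that("within-module edge counts sit inside the binomial envelope", {
  ds <- generate_synthetic(synthetic_spec(
    n_background = 150, n_modules = 4, module_size = 30, p_within = 0.9,
    p_background = 0.02, p_attach = 0.01, known_frac_module = 0.9,
    known_frac_background = 0.1, seed = 1))
  n_pairs <- choose(30, 2)
  expected <- 0.9 * n_pairs
  sd3 <- 3 * sqrt(n_pairs * 0.9 * 0.1)
  for (m in ds$modules) {
    obs <- sum(ds$network$edges$from %in% m & ds$network$edges$to %in% m)
    expect_gte(obs, expected - sd3)
    expect_lte(obs, expected + sd3)
  }
})

test_that("the default spec emulates the real network's known-gene share", {
  fracs <- vapply(1:5, function(s) {
    ds <- generate_synthetic(synthetic_spec(seed = s))
    length(ds$known) / length(ds$network$nodes)
  }, numeric(1))
  expect_equal(mean(fracs), 112 / 270, tolerance = 0.05)
})

test_that("ground truth bookkeeping: disjoint modules, complementary candidates", {
  ds <- generate_synthetic(synthetic_spec(seed = 3))
  all_mod <- unlist(ds$modules)
  expect_equal(anyDuplicated(all_mod), 0)  # pairwise disjoint
  expect_setequal(ds$planted_candidates, setdiff(all_mod, ds$known))
  expect_error(generate_synthetic(structure(list(), class = "list")))
  expect_error(synthetic_spec(known_frac_module = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_spec(p_within = 0.01, p_background = 0.02),
               "exceed")
})

test_that("label holdout splits by the rounding rule, seeded and disjoint", {
  known <- sprintf("k%02d", 1:10)
  h <- holdout_known(known, 0.3, seed = 5)
  expect_length(h$hidden, 3)
  expect_length(h$visible, 7)
  expect_length(intersect(h$hidden, h$visible), 0)
  expect_identical(h, holdout_known(known, 0.3, seed = 5))
  h2 <- holdout_known(known, 0.3, seed = 6)
  expect_length(h2$hidden, 3)
  # 112 known at fraction 0.5 -> 56 hidden
  big <- holdout_known(sprintf("k%03d", 1:112), 0.5, seed = 1)
  expect_length(big$hidden, 56)
  expect_error(holdout_known(known, 0), "fraction")
})

test_that("written synthetic files round-trip through the readers", {
  ds <- generate_synthetic(synthetic_spec(
    n_background = 20, n_modules = 1, module_size = 8, seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(ds, dir)
  src <- read_edge_list(paths[["edges"]], "tsv2col")
  net <- merge_networks(list(src))
  expect_identical(net$edges, ds$network$edges)
  expect_identical(as.character(load_known_genes(paths[["known"]])),
                   ds$known)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_setequal(unlist(truth$modules), unlist(ds$modules))
})
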