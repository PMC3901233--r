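test_that("preset design matches the published platform blocks and layout", {
  d <- prunella_preset()
  expect_identical(as.integer(d$platform_counts[["non_targeted"]]), 222L)
  expect_identical(as.integer(d$platform_counts[["surface_lipid"]]), 119L)
  expect_identical(as.integer(d$platform_counts[["amino_acid"]]), 21L)
  expect_identical(as.integer(d$platform_counts[["fatty_acid"]]), 83L)
  expect_identical(sum(as.integer(d$platform_counts)), 445L)
  expect_identical(length(d$accessions), 5L)
  expect_identical(length(unique(d$group_of_accession)), 3L)
  expect_identical(length(d$organs), 5L)
  expect_identical(d$n_replicates, 5L)

  # one organ -> the canonical 25-sample slice
  one <- prunella_preset(organs = "vegetative organs of shoots")
  sim <- simulate_dataset(one, seed = 1)
  expect_identical(ncol(sim$dataset$abund), 25L)
  expect_identical(nrow(sim$dataset$abund), 445L)
})

test_that("simulation is deterministic in the seed and leaves global RNG alone", {
  d <- prunella_preset(organs = "shoots", n_replicates = 2L,
                       platform_counts = c(non_targeted = 30L))
  set.seed(999)
  before <- .Random.seed
  a <- simulate_dataset(d, seed = 11)
  expect_identical(.Random.seed, before)

  b <- simulate_dataset(d, seed = 11)
  expect_identical(a$dataset$abund, b$dataset$abund)
  expect_identical(a$truth, b$truth)

  c <- simulate_dataset(d, seed = 12)
  expect_false(identical(a$dataset$abund, c$dataset$abund))
})

test_that("noise-free limit collapses replicates and groups exactly", {
  d <- prunella_preset(organs = "shoots",
                       group_effect_sd = 0, organ_effect_sd = 0,
                       replicate_cv = 0, dropout_prob = 0,
                       scale_factor_range = c(1, 1))
  sim <- simulate_dataset(d, seed = 5)
  ab <- sim$dataset$abund
  # every sample identical per feature
  expect_true(all(ab == ab[, 1]))
  # and the profile is the baseline
  expect_equal(unname(ab[, 1]), unname(exp(sim$truth$baseline)))
  # weighted Manhattan distance is 0 between all pairs
  expect_true(all(fingerprint_dist(sim$dataset) == 0))
})

test_that("emitted abundances are non-negative and truth dimensions match", {
  sim <- simulate_dataset(prunella_preset(), seed = 2)
  ab <- sim$dataset$abund
  expect_true(all(ab >= 0))
  expect_false(anyNA(ab))

  tr <- sim$truth
  expect_identical(length(tr$baseline), nrow(ab))
  expect_identical(dim(tr$group_effects),
                   c(nrow(ab), length(unique(tr$group_of_accession))))
  expect_identical(dim(tr$organ_effects), c(nrow(ab), 5L))
  expect_identical(names(tr$scale_factors), colnames(ab))
  expect_identical(dim(tr$present), c(nrow(ab), 15L))  # 3 groups x 5 organs

  # dropout cells are exactly zero for every replicate of the cell
  g <- tr$group_of_accession[sim$dataset$samples$accession]
  cells <- paste(g, sim$dataset$samples$organ, sep = ":")
  absent <- !tr$present[, cells, drop = FALSE]
  expect_true(all(ab[absent] == 0))
  expect_true(all(ab[!absent] > 0))
})

test_that("larger group effects increase between-group distances (monotonicity)", {
  mean_between <- vapply(c(0.1, 0.5, 1.5), function(sd_g) {
    ds <- vapply(1:4, function(s) {
      sim <- simulate_dataset(prunella_preset(
        organs = "shoots", n_replicates = 2L,
        platform_counts = c(non_targeted = 80L),
        group_effect_sd = sd_g, dropout_prob = 0), seed = 100 + s)
      d <- fingerprint_dist(sim$dataset)
      g <- sim$truth$group_of_accession[sim$dataset$samples$accession]
      between <- outer(g, g, "!=") & upper.tri(d)
      mean(d[between])
    }, numeric(1))
    mean(ds)
  }, numeric(1))
  expect_true(all(diff(mean_between) > 0))
})

test_that("degenerate designs and two-group generator guard rails error", {
  expect_error(
    simulate_dataset(prunella_preset(platform_counts = c(non_targeted = 0L))),
    class = "mfp_degenerate_design")
  expect_error(null_two_group_dataset(10, n_per_group = 1),
               class = "mfp_bad_design")
  expect_error(simulation_design("a", c(a = "g"), organs = "o",
                                 dropout_prob = 1.5),
               class = "mfp_bad_design")
  expect_error(simulation_design("a", c(a = "g"), organs = "o",
                                 scale_factor_range = c(0, 1)),
               class = "mfp_bad_design")
})

test_that("null two-group generator has the stated shape and determinism", {
  sim <- null_two_group_dataset(1000, 5, seed = 8)
  expect_identical(dim(sim$dataset$abund), c(1000L, 10L))
  expect_true(all(!sim$truth$affected))
  expect_false(identical(null_two_group_dataset(50, 3, seed = 1)$dataset$abund,
                         null_two_group_dataset(50, 3, seed = 2)$dataset$abund))
  expect_identical(null_two_group_dataset(50, 3, seed = 1)$dataset$abund,
                   null_two_group_dataset(50, 3, seed = 1)$dataset$abund)

  # planted fold change lands on the affected features only
  tg <- two_group_dataset(100, 4, seed = 3, fold_change = 4, frac_affected = 0.2)
  expect_identical(sum(tg$truth$affected), 20L)
})
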