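test_that("welch_t matches the textbook-formula oracle and its conventions", {
  # frozen oracle values for x = 1:4, y = 3:6 (computed from the closed form):
  # t = -2.190890, df = 6, p = 0.0709289
  res <- welch_t(1:4, 3:6)
  orc <- oracle_welch(1:4, 3:6)
  expect_equal(res$t, orc$t)
  expect_equal(res$df, orc$df)
  expect_equal(res$p, orc$p)
  expect_equal(res$t, -2.19089023002066, tolerance = 1e-12)
  expect_equal(res$df, 6)

  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(5); y <- rnorm(7, 1, 2)
    res <- welch_t(x, y)
    orc <- oracle_welch(x, y)
    expect_equal(res$t, orc$t)
    expect_equal(res$df, orc$df)
    expect_equal(res$p, orc$p)
  }

  # equal means -> t = 0, p = 1; both constant & equal by convention too
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))[c("t", "p")], list(t = 0, p = 1))
  expect_identical(welch_t(c(5, 5, 5), c(5, 5, 5)), list(t = 0, df = 4, p = 1))
  expect_error(welch_t(c(5, 5, 5), c(7, 7, 7)),
               class = "mfp_degenerate_variance")
  expect_error(welch_t(1, c(1, 2)), class = "mfp_insufficient_data")
})

test_that("bh_adjust reproduces the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(1)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 0)), class = "mfp_bad_pvalue")
  expect_error(bh_adjust(c(0.5, 1.2)), class = "mfp_bad_pvalue")
})

test_that("volcano computes ratio coordinates and honours group symmetry", {
  x <- random_dataset(30, 8, seed = 21)
  a <- x$samples$sample_id[1:4]
  b <- x$samples$sample_id[5:8]

  v <- volcano(x, a, b, pseudocount = 0)
  expect_identical(nrow(v), 30L)
  expect_equal(v$log2_ratio,
               unname(log2(rowMeans(x$abund[, a]) / rowMeans(x$abund[, b]))))

  # swapping the groups negates the ratio and keeps p
  w <- volcano(x, b, a, pseudocount = 0)
  expect_equal(w$log2_ratio, -v$log2_ratio)
  expect_equal(w$p_value, v$p_value)
  expect_equal(w$t, -v$t)

  # mean_a = 8, mean_b = 2, c = 0 -> log2 ratio = 2
  y <- tiny_dataset()
  y$abund["f1", ] <- c(8, 8, 2, 2)
  v1 <- volcano(y, c("s1", "s2"), c("s3", "s4"), pseudocount = 0)
  expect_equal(v1$log2_ratio[v1$feature_id == "f1"], 2)

  # f3 has one NA in group b -> fewer than 2 replicates -> skipped
  expect_identical(v1$status[v1$feature_id == "f3"], "skipped")
  expect_true(is.na(v1$p_value[v1$feature_id == "f3"]))

  expect_error(volcano(x, a, c(a[1], b[1])), class = "mfp_overlapping_groups")
  expect_error(volcano(x, a, "missing_sample"), class = "mfp_unknown_sample")

  # q-values only on request, BH-consistent
  vq <- volcano(x, a, b, adjust = TRUE)
  ok <- vq$status == "ok"
  expect_equal(vq$q_value[ok], bh_adjust(vq$p_value[ok]))
  expect_false("q_value" %in% names(v))
})

test_that("planted fold-changes are recovered by the volcano ratio axis", {
  tg <- two_group_dataset(400, 5, seed = 13, fold_change = 4,
                          frac_affected = 0.25)
  x <- tg$dataset
  v <- volcano(x, samples_where(x, accession = "groupB"),
               samples_where(x, accession = "groupA"))
  up <- v$log2_ratio[tg$truth$affected]
  expect_equal(median(up), 2, tolerance = 0.15)
  expect_equal(median(v$log2_ratio[!tg$truth$affected]), 0, tolerance = 0.1)
})

test_that("ratio panels share one recorded ordering across accessions", {
  sim <- simulate_dataset(
    prunella_preset(organs = c("cauline leaves", "flowers"),
                    n_replicates = 3L), seed = 6)
  rp <- ratio_panels(sim$dataset, "cauline leaves", "flowers")
  expect_identical(ncol(rp$log2_ratio), 5L)
  expect_identical(rownames(rp$log2_ratio), rp$feature_order)
  expect_setequal(rp$feature_order, rownames(sim$dataset$abund))

  # permuting sample order leaves the panels identical
  perm <- sample(ncol(sim$dataset$abund))
  shuffled <- mfp_dataset(sim$dataset$abund[, perm],
                          sim$dataset$samples[perm, ],
                          sim$dataset$features)
  rp2 <- ratio_panels(shuffled, "cauline leaves", "flowers")
  expect_identical(rp2$log2_ratio, rp$log2_ratio)
  expect_identical(rp2$feature_order, rp$feature_order)

  # zero organ effect -> panel values concentrate near 0
  quiet <- simulate_dataset(
    prunella_preset(organs = c("cauline leaves", "flowers"),
                    n_replicates = 4L, organ_effect_sd = 0, replicate_cv = 0.05,
                    dropout_prob = 0, scale_factor_range = c(1, 1)), seed = 6)
  rp0 <- ratio_panels(quiet$dataset, "cauline leaves", "flowers")
  expect_lt(max(abs(rp0$log2_ratio)), 0.25)

  # an accession missing one organ yields a missing panel with a warning
  drop1 <- select_samples(sim$dataset, function(s) {
    !(s$accession == "PI 664889" & s$organ == "flowers")
  })
  expect_warning(rpm <- ratio_panels(drop1, "cauline leaves", "flowers"),
                 "PI 664889")
  expect_true(all(is.na(rpm$log2_ratio[, "PI 664889"])))
  expect_true(all(!is.na(rpm$log2_ratio[, "PI 664873"])))
})

test_that("accession fingerprints cover all ordered pairs antisymmetrically", {
  sim <- simulate_dataset(
    prunella_preset(organs = c("shoots", "flowers"), n_replicates = 2L,
                    platform_counts = c(amino_acid = 10L, non_targeted = 40L)),
    seed = 17)
  fp <- pairwise_accession_fingerprints(sim$dataset)
  expect_identical(ncol(fp$log2_ratio), 20L)  # 5 * 4 ordered pairs
  expect_identical(nrow(fp$pairs), 20L)

  for (i in seq_len(nrow(fp$pairs))) {
    a <- fp$pairs$numerator[i]; b <- fp$pairs$denominator[i]
    expect_equal(fp$log2_ratio[, paste(a, "vs", b)],
                 -fp$log2_ratio[, paste(b, "vs", a)],
                 tolerance = 1e-12)
  }

  # duplicated accession data -> all-zero profile
  x <- sim$dataset
  dup <- x$samples$accession %in% c("PI 664873", "PI 664874")
  x2 <- select_samples(x, dup)
  x2$abund[, x2$samples$accession == "PI 664874"] <-
    x2$abund[, x2$samples$accession == "PI 664873"]
  fp2 <- pairwise_accession_fingerprints(x2)
  expect_true(all(abs(fp2$log2_ratio) < 1e-12))

  expect_error(
    pairwise_accession_fingerprints(select_samples(sim$dataset,
                                                   accession = "PI 664873")),
    class = "mfp_insufficient_data")
})
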