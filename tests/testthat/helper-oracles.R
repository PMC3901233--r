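# Independent oracles and tiny in-code fixtures shared across test files.
# Every oracle is written from the defining formula, scalar-wise, so it never
# shares code paths with the implementation it checks.

# hand-sized 3-feature x 4-sample dataset (2 accessions x 2 replicates)
tiny_dataset <- function() {
  abund <- matrix(c(1, 2, 3, 4,
                    10, 20, 30, 40,
                    0, 5, NA, 2),
                  nrow = 3, byrow = TRUE,
                  dimnames = list(c("f1", "f2", "f3"),
                                  c("s1", "s2", "s3", "s4")))
  samples <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    species = "synthetic",
    accession = c("acc1", "acc1", "acc2", "acc2"),
    organ = "shoots",
    stage = "unspecified",
    replicate = c(1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE)
  features <- data.frame(
    feature_id = c("f1", "f2", "f3"),
    platform = c("amino_acid", "amino_acid", "non_targeted"),
    chemical_class = c("amino acid", "amino acid", NA),
    mass = c(75.03, 89.05, NA),
    retention_time = c(1.2, 2.5, NA),
    identified = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  mfp_dataset(abund, samples, features)
}

# random valid dataset for property tests
random_dataset <- function(n_feat, n_samp, seed, na_frac = 0, zero_frac = 0) {
  set.seed(seed)
  abund <- matrix(rlnorm(n_feat * n_samp, 5, 1), n_feat, n_samp,
                  dimnames = list(sprintf("f%03d", seq_len(n_feat)),
                                  sprintf("s%02d", seq_len(n_samp))))
  if (zero_frac > 0) {
    abund[sample(length(abund), round(zero_frac * length(abund)))] <- 0
  }
  if (na_frac > 0) {
    abund[sample(length(abund), round(na_frac * length(abund)))] <- NA
  }
  samples <- data.frame(
    sample_id = colnames(abund),
    species = "synthetic",
    accession = rep_len(c("accA", "accB"), n_samp),
    organ = rep_len(c("shoots", "flowers"), n_samp),
    stage = "unspecified",
    replicate = seq_len(n_samp),
    stringsAsFactors = FALSE)
  features <- data.frame(
    feature_id = rownames(abund),
    platform = rep_len(c("amino_acid", "non_targeted"), n_feat),
    chemical_class = NA_character_,
    mass = NA_real_,
    retention_time = NA_real_,
    identified = FALSE,
    stringsAsFactors = FALSE)
  mfp_dataset(abund, samples, features)
}

# scalar double-loop weighted Manhattan oracle, straight from the formula
oracle_wm <- function(y_i, y_j) {
  total <- 0
  kstar <- 0L
  for (k in seq_along(y_i)) {
    a <- y_i[k]; b <- y_j[k]
    if (is.na(a) || is.na(b)) next
    if (a + b > 0) {
      total <- total + abs(a - b) / sqrt(a^2 + b^2)
      kstar <- kstar + 1L
    }
  }
  unname(total / kstar)
}

# Welch t from the textbook formulas
oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# classical Spearman formula (valid without ties)
oracle_spearman_noties <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Procrustes (rotation/reflection/translation/scale) RMSE via SVD
procrustes_rmse <- function(target, points) {
  tc <- scale(target, scale = FALSE)
  pc <- scale(points, scale = FALSE)
  s <- svd(crossprod(tc, pc))
  rot <- s$v %*% t(s$u)
  scl <- sum(s$d) / sum(pc^2)
  fitted <- scl * pc %*% rot
  sqrt(mean((fitted - tc)^2))
}

# sum of squared discrepancies between a distance matrix and the pairwise
# Euclidean distances of a configuration
config_stress <- function(d, points) {
  emb <- as.matrix(dist(points))
  sum((as.matrix(d) - emb)[upper.tri(d)]^2)
}
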