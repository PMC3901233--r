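## Synthetic multi-accession, multi-organ metabolomics data.
##
## Generative model (log-normal with additive log-scale effects):
##   Y[k, j] = s_j * exp(mu_k + alpha[g(a_j), k] + beta[o_j, k] + eps[k, j])
##             * present[k, g(a_j), o_j]
## with mu_k ~ N(baseline_log_mean, baseline_log_sd), alpha ~ N(0,
## group_effect_sd), beta ~ N(0, organ_effect_sd), eps ~ N(0, replicate_cv),
## s_j ~ Uniform(scale_factor_range), and present a Bernoulli(1 -
## dropout_prob) mask drawn once per feature x accession-group x organ cell:
## constituent presence/absence is a property of the material, not of the
## replicate, so fully disjoint fingerprints (distance 1) are reachable.

#' Specify a simulation design
#'
#' All effect magnitudes are standard deviations on the natural-log scale;
#' `replicate_cv` ~ 0.2 corresponds to ~20% technical noise. `dropout_prob`
#' is the probability that a feature is absent (exact zero) in one
#' accession-group x organ cell.
#'
#' @param accessions character vector of accession names.
#' @param group_of_accession named character vector mapping each accession to
#'   its group label (accessions in one group share planted effects).
#' @param organs character vector of organ names.
#' @param n_replicates replicates per accession x organ cell.
#' @param platform_counts named integer vector of feature counts per platform
#'   (names among amino_acid, surface_lipid, fatty_acid, non_targeted).
#' @param baseline_log_mean,baseline_log_sd log-scale mean / sd of per-feature
#'   baselines.
#' @param group_effect_sd,organ_effect_sd sd of planted accession-group and
#'   organ effects (log scale).
#' @param replicate_cv sd of per-replicate technical noise (log scale).
#' @param dropout_prob probability in `[0,1]` of constituent absence per
#'   feature x group x organ cell.
#' @param scale_factor_range length-2 vector `c(lo, hi)`, `0 < lo <= hi`:
#'   bounds of the per-sample multiplicative scale factor.
#' @param species species label written to the sample table.
#' @return an object of class `mfp_design`.
#' @seealso [prunella_preset()], [simulate_dataset()]
#' @export
simulation_design <- function(accessions,
                              group_of_accession,
                              organs,
                              n_replicates = 5L,
                              platform_counts = c(non_targeted = 200L),
                              baseline_log_mean = 7,
                              baseline_log_sd = 1.5,
                              group_effect_sd = 1,
                              organ_effect_sd = 1,
                              replicate_cv = 0.2,
                              dropout_prob = 0.1,
                              scale_factor_range = c(0.8, 1.25),
                              species = "synthetic") {
  accessions <- as.character(accessions)
  if (!length(accessions) || anyDuplicated(accessions)) {
    mfp_stop("mfp_bad_design", "accessions must be a non-empty unique vector")
  }
  if (is.null(names(group_of_accession)) ||
      !setequal(names(group_of_accession), accessions)) {
    mfp_stop("mfp_bad_design",
             "group_of_accession must be named by exactly the accessions")
  }
  if (!length(organs)) mfp_stop("mfp_bad_design", "at least one organ required")
  if (n_replicates < 1L) mfp_stop("mfp_bad_design", "n_replicates must be >= 1")
  if (any(is.na(platform_counts)) || any(platform_counts < 0)) {
    mfp_stop("mfp_bad_design", "platform_counts must be non-negative")
  }
  if (!all(names(platform_counts) %in% PLATFORM_LEVELS)) {
    mfp_stop("mfp_bad_design", sprintf(
      "platform names must be among: %s", paste(PLATFORM_LEVELS, collapse = ", ")))
  }
  if (baseline_log_sd <= 0) mfp_stop("mfp_bad_design", "baseline_log_sd must be > 0")
  for (v in c(group_effect_sd, organ_effect_sd, replicate_cv)) {
    if (is.na(v) || v < 0) mfp_stop("mfp_bad_design", "effect sds must be >= 0")
  }
  if (is.na(dropout_prob) || dropout_prob < 0 || dropout_prob > 1) {
    mfp_stop("mfp_bad_design", "dropout_prob must lie in [0,1]")
  }
  if (length(scale_factor_range) != 2L || scale_factor_range[1L] <= 0 ||
      scale_factor_range[1L] > scale_factor_range[2L]) {
    mfp_stop("mfp_bad_design", "scale_factor_range must satisfy 0 < lo <= hi")
  }

  structure(list(
    accessions = accessions,
    group_of_accession = group_of_accession[accessions],
    organs = as.character(organs),
    n_replicates = as.integer(n_replicates),
    platform_counts = platform_counts,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    group_effect_sd = group_effect_sd,
    organ_effect_sd = organ_effect_sd,
    replicate_cv = replicate_cv,
    dropout_prob = dropout_prob,
    scale_factor_range = scale_factor_range,
    species = species
  ), class = "mfp_design")
}

#' @export
print.mfp_design <- function(x, ...) {
  cat(sprintf("<mfp_design> %d accessions (%d groups), %d organs, %d replicates\n",
              length(x$accessions), length(unique(x$group_of_accession)),
              length(x$organs), x$n_replicates))
  cat("  features:",
      paste(sprintf("%s=%d", names(x$platform_counts),
                    as.integer(x$platform_counts)), collapse = ", "),
      sprintf(" (total %d)\n", sum(x$platform_counts)))
  invisible(x)
}

#' Five-accession Prunella-style preset design
#'
#' The design of a five-accession *Prunella vulgaris* fingerprinting study:
#' five accessions falling into three provenance groups (three North American
#' accessions together, one North American outlier, one Georgian accession),
#' five aerial organs, five replicates per accession x organ, and four
#' analytical platform blocks of 21 amino acids, 119 surface lipids, 83 fatty
#' acids and 222 non-targeted metabolites (445 features in total). With a
#' single organ selected this yields the familiar 25-sample layout
#' (5 accessions x 5 replicates).
#'
#' @param ... overrides passed on to [simulation_design()].
#' @return an `mfp_design`.
#' @export
prunella_preset <- function(...) {
  acc <- c("PI 664873", "PI 664874", "PI 664875", "PI 664876", "PI 664889")
  groups <- c("PI 664873" = "NA_core", "PI 664874" = "NA_core",
              "PI 664875" = "NA_outlier", "PI 664876" = "NA_core",
              "PI 664889" = "Georgia")
  defaults <- list(
    accessions = acc,
    group_of_accession = groups,
    organs = c("shoots", "cauline leaves", "flowers",
               "vegetative organs of shoots", "stems"),
    n_replicates = 5L,
    platform_counts = c(amino_acid = 21L, surface_lipid = 119L,
                        fatty_acid = 83L, non_targeted = 222L),
    species = "Prunella vulgaris")
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_design, args)
}

slug <- function(x) gsub("(^_)|(_$)", "", gsub("[^A-Za-z0-9]+", "_", x))

platform_prefix <- c(amino_acid = "aa", surface_lipid = "sl",
                     fatty_acid = "fa", non_targeted = "nt")

#' Simulate a dataset with known ground truth
#'
#' Draws a dataset from the log-normal generative model of the design (see
#' the package vignette) and returns it together with a truth record holding
#' every planted quantity, enabling parameter- and structure-recovery tests.
#' The same `seed` always yields a byte-identical dataset; the caller's RNG
#' state is left untouched.
#'
#' @param design an `mfp_design` from [simulation_design()] or
#'   [prunella_preset()].
#' @param seed integer seed controlling all randomness.
#' @return an object of class `mfp_sim`: list with `dataset`
#'   (an [mfp_dataset]), `truth` (see Details), `design`, `seed`.
#'   `truth` holds `group_of_accession`, `baseline` (mu_k), `group_effects`
#'   (K x groups), `organ_effects` (K x organs), `scale_factors` (per sample),
#'   `present` (K x group:organ logical presence mask) and `noise_sd`.
#' @export
simulate_dataset <- function(design, seed = 1L) {
  if (!inherits(design, "mfp_design")) {
    mfp_stop("mfp_bad_design", "`design` must be an mfp_design")
  }
  n_feat <- sum(design$platform_counts)
  n_samp <- length(design$accessions) * length(design$organs) * design$n_replicates
  if (n_feat == 0L || n_samp == 0L) {
    mfp_stop("mfp_degenerate_design",
             "design yields zero features or zero samples")
  }

  platforms <- rep(names(design$platform_counts),
                   times = as.integer(design$platform_counts))
  feature_id <- unlist(lapply(names(design$platform_counts), function(p) {
    n <- as.integer(design$platform_counts[[p]])
    if (n == 0L) return(character(0))
    sprintf("%s_%03d", platform_prefix[[p]], seq_len(n))
  }), use.names = FALSE)

  samples <- expand.grid(replicate = seq_len(design$n_replicates),
                         organ = design$organs,
                         accession = design$accessions,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("accession", "organ", "replicate")]
  samples$sample_id <- sprintf("%s.%s.r%d", slug(samples$accession),
                               slug(samples$organ), samples$replicate)
  samples$species <- design$species
  samples$stage <- "unspecified"
  samples <- samples[SAMPLE_COLS]

  groups <- sort(unique(design$group_of_accession))
  organs <- design$organs
  cells <- as.vector(outer(groups, organs, paste, sep = ":"))

  out <- with_seed(seed, {
    mu <- stats::rnorm(n_feat, design$baseline_log_mean, design$baseline_log_sd)
    alpha <- matrix(stats::rnorm(n_feat * length(groups), 0, design$group_effect_sd),
                    n_feat, length(groups), dimnames = list(feature_id, groups))
    beta <- matrix(stats::rnorm(n_feat * length(organs), 0, design$organ_effect_sd),
                   n_feat, length(organs), dimnames = list(feature_id, organs))
    present <- matrix(stats::runif(n_feat * length(cells)) >= design$dropout_prob,
                      n_feat, length(cells), dimnames = list(feature_id, cells))
    s <- stats::runif(nrow(samples), design$scale_factor_range[1L],
                      design$scale_factor_range[2L])
    eps <- matrix(stats::rnorm(n_feat * nrow(samples), 0, design$replicate_cv),
                  n_feat, nrow(samples))

    ## identified fraction and masses for the feature table (cosmetic metadata)
    identified <- ifelse(platforms == "non_targeted",
                         stats::runif(n_feat) < 1 / 3, TRUE)
    mass <- round(stats::runif(n_feat, 75, 1000), 4)
    rt <- round(stats::runif(n_feat, 0.5, 30), 3)
    list(mu = mu, alpha = alpha, beta = beta, present = present, s = s,
         eps = eps, identified = identified, mass = mass, rt = rt)
  })

  g_of_sample <- design$group_of_accession[samples$accession]
  abund <- matrix(0, n_feat, nrow(samples),
                  dimnames = list(feature_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    g <- g_of_sample[[j]]
    o <- samples$organ[j]
    y <- out$s[j] * exp(out$mu + out$alpha[, g] + out$beta[, o] + out$eps[, j])
    y[!out$present[, paste(g, o, sep = ":")]] <- 0
    abund[, j] <- y
  }

  class_of <- c(amino_acid = "amino acid", surface_lipid = "surface lipid",
                fatty_acid = "fatty acid", non_targeted = NA_character_)
  features <- data.frame(
    feature_id = feature_id,
    platform = platforms,
    chemical_class = unname(class_of[platforms]),
    mass = out$mass,
    retention_time = out$rt,
    identified = out$identified,
    stringsAsFactors = FALSE)

  truth <- list(
    group_of_accession = design$group_of_accession,
    baseline = stats::setNames(out$mu, feature_id),
    group_effects = out$alpha,
    organ_effects = out$beta,
    scale_factors = stats::setNames(out$s, samples$sample_id),
    present = out$present,
    noise_sd = design$replicate_cv)

  structure(list(dataset = mfp_dataset(abund, samples, features),
                 truth = truth, design = design, seed = as.integer(seed)),
            class = "mfp_sim")
}

#' @export
print.mfp_sim <- function(x, ...) {
  cat(sprintf("<mfp_sim> seed %d\n", x$seed))
  print(x$design)
  print(x$dataset)
  invisible(x)
}

#' Two-group datasets for test calibration
#'
#' `null_two_group_dataset()` draws every feature of both groups from one
#' log-normal, so every feature is truly null: it calibrates the type-I error
#' of the volcano t-tests. `two_group_dataset()` generalizes it by planting a
#' fold-change on a fraction of features (group B multiplied by
#' `fold_change`), for power studies.
#'
#' @param n_features number of features.
#' @param n_per_group replicates per group (>= 2; the t-test is undefined
#'   below that).
#' @param seed integer seed.
#' @param meanlog,sdlog log-normal parameters shared by both groups
#'   (`sdlog = 0.25` ~ 25% technical CV).
#' @param fold_change multiplicative effect planted in group B.
#' @param frac_affected fraction of features carrying the effect.
#' @return an `mfp_sim` whose `truth` is a data.frame with columns
#'   `feature_id`, `affected`, `fold_change`.
#' @export
two_group_dataset <- function(n_features, n_per_group, seed = 1L,
                              meanlog = 7, sdlog = 0.25,
                              fold_change = 1, frac_affected = 0) {
  if (n_per_group < 2L) {
    mfp_stop("mfp_bad_design",
             "n_per_group must be >= 2 (t-test undefined otherwise)")
  }
  if (n_features < 1L) mfp_stop("mfp_degenerate_design", "n_features must be >= 1")
  feature_id <- sprintf("nt_%04d", seq_len(n_features))
  samples <- data.frame(
    sample_id = c(sprintf("A.r%d", seq_len(n_per_group)),
                  sprintf("B.r%d", seq_len(n_per_group))),
    species = "synthetic",
    accession = rep(c("groupA", "groupB"), each = n_per_group),
    organ = "bulk",
    stage = "unspecified",
    replicate = rep(seq_len(n_per_group), 2L),
    stringsAsFactors = FALSE)

  n_aff <- round(frac_affected * n_features)
  abund <- with_seed(seed, {
    m <- matrix(stats::rlnorm(n_features * 2L * n_per_group, meanlog, sdlog),
                n_features, 2L * n_per_group,
                dimnames = list(feature_id, samples$sample_id))
    if (n_aff > 0L) {
      b_cols <- seq.int(n_per_group + 1L, 2L * n_per_group)
      m[seq_len(n_aff), b_cols] <- m[seq_len(n_aff), b_cols] * fold_change
    }
    m
  })

  features <- data.frame(feature_id = feature_id, platform = "non_targeted",
                         chemical_class = NA_character_, mass = NA_real_,
                         retention_time = NA_real_, identified = FALSE,
                         stringsAsFactors = FALSE)
  truth <- data.frame(feature_id = feature_id,
                      affected = seq_len(n_features) <= n_aff,
                      fold_change = ifelse(seq_len(n_features) <= n_aff,
                                           fold_change, 1),
                      stringsAsFactors = FALSE)
  structure(list(dataset = mfp_dataset(abund, samples, features),
                 truth = truth, design = NULL, seed = as.integer(seed)),
            class = "mfp_sim")
}

#' @rdname two_group_dataset
#' @export
null_two_group_dataset <- function(n_features, n_per_group, seed = 1L,
                                   meanlog = 7, sdlog = 0.25) {
  two_group_dataset(n_features, n_per_group, seed = seed, meanlog = meanlog,
                    sdlog = sdlog, fold_change = 1, frac_affected = 0)
}
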